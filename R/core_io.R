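#' Channel roles recognised by the pipeline
#' @export
CHANNEL_ROLES <- c("synaptic_pre", "synaptic_post", "donor", "acceptor",
                   "fret_raw", "other")

#' A single fluorescence channel of a serial-section stack
#'
#' @param intensities numeric array H x W x S of non-negative finite values
#'   (row, column, section).
#' @param role one of [CHANNEL_ROLES].
#' @return a `channel_volume` object.
#' @export
channel_volume <- function(intensities, role = "other") {
  role <- match.arg(role, CHANNEL_ROLES)
  stopifnot(is.numeric(intensities), length(dim(intensities)) == 3)
  if (any(!is.finite(intensities)) || any(intensities < 0))
    stop("channel_volume: intensities must be finite and non-negative")
  structure(list(intensities = intensities, role = role),
            class = "channel_volume")
}

#' An ordered multi-channel serial-section volume
#'
#' The central container of the pipeline: one 2D image per physical section
#' per channel, all channels sharing the same frame and section count, plus
#' the physical voxel geometry. Section index increases along the cutting
#' axis.
#'
#' @param channels named list of [channel_volume()] objects with identical
#'   dimensions.
#' @param geometry a [voxel_geometry()].
#' @param alignment_state `"raw"` or `"aligned"`.
#' @param metadata optional [case_metadata()].
#' @param valid_mask optional logical H x W x S array marking pixels that map
#'   from inside the original frame after alignment; defaults to all-TRUE.
#' @return a `section_stack` object.
#' @export
section_stack <- function(channels, geometry, alignment_state = "raw",
                          metadata = NULL, valid_mask = NULL) {
  alignment_state <- match.arg(alignment_state, c("raw", "aligned"))
  stopifnot(is.list(channels), length(channels) >= 1)
  if (is.null(names(channels)) || anyDuplicated(names(channels)) ||
      any(names(channels) == ""))
    stop("section_stack: channels must be uniquely named")
  dims <- lapply(channels, function(ch) dim(ch$intensities))
  for (nm in names(channels))
    if (!identical(dims[[nm]], dims[[1]]))
      stop(sprintf("section_stack: channel '%s' has shape %s, expected %s",
                   nm, paste(dims[[nm]], collapse = "x"),
                   paste(dims[[1]], collapse = "x")))
  if (dims[[1]][3] < 2)
    stop("section_stack: at least 2 sections required")
  stopifnot(inherits(geometry, "voxel_geometry"))
  if (is.null(valid_mask)) valid_mask <- array(TRUE, dim = dims[[1]])
  stopifnot(identical(dim(valid_mask), dims[[1]]))
  structure(list(channels = channels, geometry = geometry,
                 alignment_state = alignment_state, metadata = metadata,
                 valid_mask = valid_mask),
            class = "section_stack")
}

#' @export
print.section_stack <- function(x, ...) {
  d <- dim(x$channels[[1]]$intensities)
  cat(sprintf("section_stack: %d sections of %dx%d px, %d channel(s) [%s], %s\n",
              d[3], d[1], d[2], length(x$channels),
              paste(names(x$channels), collapse = ", "), x$alignment_state))
  invisible(x)
}

#' Number of sections in a stack
#' @param stack a [section_stack()].
#' @export
n_sections <- function(stack) dim(stack$channels[[1]]$intensities)[3]

#' Frame size (H, W) of a stack in pixels
#' @param stack a [section_stack()].
#' @export
frame_shape <- function(stack) dim(stack$channels[[1]]$intensities)[1:2]

#' Case-level metadata attached to a stack
#'
#' @param case_id,sample_id identifiers; the (case, sample) pair identifies a
#'   stack. Samples are nested in cases in the study design.
#' @param diagnosis `"AD"` or `"control"`.
#' @param sex `"F"` or `"M"`.
#' @export
case_metadata <- function(case_id, sample_id, diagnosis, sex) {
  diagnosis <- match.arg(diagnosis, c("AD", "control"))
  sex <- match.arg(sex, c("F", "M"))
  stopifnot(nzchar(case_id), nzchar(sample_id))
  structure(list(case_id = as.character(case_id),
                 sample_id = as.character(sample_id),
                 diagnosis = diagnosis, sex = sex),
            class = "case_metadata")
}

#' Load a raw section stack from per-channel TIFF files
#'
#' Each channel is either one multi-page TIFF (page index = section index) or
#' a vector of single-page TIFFs in section order. Section and channel order
#' are preserved exactly as given; the returned stack is unaligned.
#'
#' @param paths named list; one entry per channel, each a character vector of
#'   TIFF paths (length 1 for a multi-page file).
#' @param geometry a [voxel_geometry()].
#' @param roles optional named character vector mapping channel name to role.
#' @param metadata optional [case_metadata()].
#' @return a raw [section_stack()].
#' @export
load_stack <- function(paths, geometry, roles = NULL, metadata = NULL) {
  stopifnot(is.list(paths), !is.null(names(paths)))
  channels <- list()
  ref_dim <- NULL
  for (nm in names(paths)) {
    vols <- lapply(paths[[nm]], read_tiff_stack)
    arr <- if (length(vols) == 1) vols[[1]] else {
      shapes <- vapply(vols, function(v) paste(dim(v)[1:2], collapse = "x"), "")
      if (length(unique(shapes)) != 1)
        stop(sprintf("load_stack: channel '%s' mixes frame sizes (%s)",
                     nm, paste(unique(shapes), collapse = ", ")))
      do.call(function(...) {
        pages <- list(...)
        a <- array(0, c(dim(pages[[1]])[1:2], sum(vapply(pages, function(p) dim(p)[3], 0))))
        s <- 0
        for (p in pages) for (k in seq_len(dim(p)[3])) { s <- s + 1; a[, , s] <- p[, , k] }
        a
      }, vols)
    }
    if (is.null(ref_dim)) ref_dim <- dim(arr)
    if (!identical(dim(arr), ref_dim))
      stop(sprintf("load_stack: channel '%s' has %d sections of %dx%d px, expected %dx%dx%d",
                   nm, dim(arr)[3], dim(arr)[1], dim(arr)[2],
                   ref_dim[1], ref_dim[2], ref_dim[3]))
    role <- if (!is.null(roles) && nm %in% names(roles)) roles[[nm]] else "other"
    channels[[nm]] <- channel_volume(arr, role)
  }
  section_stack(channels, geometry, alignment_state = "raw", metadata = metadata)
}

#' Save a section stack as one multi-page TIFF per channel
#'
#' @param stack a [section_stack()].
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
save_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(stack$channels), function(nm) {
    p <- file.path(dir, paste0(nm, ".tif"))
    write_tiff_stack(stack$channels[[nm]]$intensities, p)
    p
  }, "")
  invisible(paths)
}

# ---- measurement tables ----------------------------------------------------

MEASUREMENT_COLUMNS <- c("case_id", "sample_id", "diagnosis", "sex",
                         "measurement", "value")

#' Construct or validate a per-sample measurement table
#'
#' One row per (case, sample, measurement): the unit feeding the statistics
#' layer. Metadata columns must be complete and each (case, sample,
#' measurement) may appear once.
#'
#' @param df data.frame with columns case_id, sample_id, diagnosis, sex,
#'   measurement, value.
#' @export
measurement_table <- function(df) {
  missing_cols <- setdiff(MEASUREMENT_COLUMNS, names(df))
  if (length(missing_cols))
    stop("measurement_table: missing columns: ", paste(missing_cols, collapse = ", "))
  df <- df[, MEASUREMENT_COLUMNS, drop = FALSE]
  meta <- df[, c("case_id", "sample_id", "diagnosis", "sex", "measurement")]
  if (nrow(df) && any(!stats::complete.cases(meta) | apply(meta == "", 1, any)))
    stop("measurement_table: incomplete metadata rows")
  key <- do.call(paste, c(df[, c("case_id", "sample_id", "measurement")], sep = "\r"))
  if (anyDuplicated(key))
    stop("measurement_table: duplicate (case, sample, measurement) rows")
  class(df) <- c("measurement_table", "data.frame")
  df
}

#' Write a measurement table as delimited text
#'
#' Column order is stable; numeric values keep at least 15 significant digits
#' so the table round-trips.
#'
#' @param table a [measurement_table()].
#' @param path output CSV path.
#' @export
save_results <- function(table, path) {
  table <- measurement_table(as.data.frame(table))
  out <- table
  out$value <- formatC(out$value, digits = 15, format = "g")
  tryCatch(
    write.csv(out, path, row.names = FALSE, quote = FALSE),
    error = function(e) stop("save_results: cannot write '", path, "': ",
                             conditionMessage(e)))
  invisible(path)
}

#' Read a measurement table written by [save_results()]
#' @param path CSV path.
#' @export
read_results <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(case_id = "character", sample_id = "character"))
  df$value <- as.numeric(df$value)
  measurement_table(df)
}
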