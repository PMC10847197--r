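#' Segmentation parameters
#'
#' The thresholding rule mirrors the semi-automatic local mean threshold of
#' the array-tomography workflow: a pixel is foreground when its intensity
#' exceeds the local mean (square window `local_window`) by the fractional
#' offset `threshold_offset`. The offset is chosen once per channel and then
#' held fixed across every stack of a study.
#'
#' @param local_window odd window size in pixels (>= 3).
#' @param threshold_offset fraction of the local mean a pixel must exceed.
#' @param min_area_px minimum in-plane component area (pixels) kept per
#'   section.
#' @param linking_min_overlap_px minimum pixel overlap for linking in-plane
#'   components across consecutive sections (>= 1).
#' @param exclusion_mask optional logical H x W x S array of pixels (vessels,
#'   cell bodies) forced to background.
#' @export
segmentation_params <- function(local_window = 15, threshold_offset = 1,
                                min_area_px = 2, linking_min_overlap_px = 1,
                                exclusion_mask = NULL) {
  stopifnot(local_window >= 3, local_window %% 2 == 1, min_area_px >= 1,
            linking_min_overlap_px >= 1, threshold_offset > -1)
  structure(list(local_window = as.integer(local_window),
                 threshold_offset = threshold_offset,
                 min_area_px = as.integer(min_area_px),
                 linking_min_overlap_px = as.integer(linking_min_overlap_px),
                 exclusion_mask = exclusion_mask),
            class = "segmentation_params")
}

# windowed mean with border-adjusted window size, via integral image
.box_mean <- function(img, w) {
  h <- (w - 1L) %/% 2L
  nr <- nrow(img); nc <- ncol(img)
  pad <- matrix(0, nr + 1, nc + 1)
  pad[-1, -1] <- img
  ii <- apply(apply(pad, 2, cumsum), 1, cumsum)  # transposed integral image
  ii <- t(ii)
  r0 <- pmax(0L, seq_len(nr) - h - 1L); r1 <- pmin(nr, seq_len(nr) + h)
  c0 <- pmax(0L, seq_len(nc) - h - 1L); c1 <- pmin(nc, seq_len(nc) + h)
  sums <- ii[r1 + 1L, c1 + 1L, drop = FALSE] - ii[r0 + 1L, c1 + 1L, drop = FALSE] -
    ii[r1 + 1L, c0 + 1L, drop = FALSE] + ii[r0 + 1L, c0 + 1L, drop = FALSE]
  counts <- outer(r1 - r0, c1 - c0)
  sums / counts
}

#' Local mean threshold of a channel
#'
#' A pixel is foreground iff
#' `intensity > local_mean * (1 + threshold_offset)`; exclusion-mask pixels
#' are forced to background. A constant image yields no foreground (no pixel
#' exceeds its own mean by a positive offset).
#'
#' @param channel a [channel_volume()] or numeric 3D array.
#' @param params a [segmentation_params()].
#' @return logical H x W x S foreground mask.
#' @export
local_threshold <- function(channel, params) {
  arr <- if (inherits(channel, "channel_volume")) channel$intensities else channel
  stopifnot(length(dim(arr)) == 3, inherits(params, "segmentation_params"))
  if (params$local_window > min(dim(arr)[1:2]))
    stop("local_threshold: window larger than frame")
  mask <- array(FALSE, dim = dim(arr))
  for (s in seq_len(dim(arr)[3])) {
    lm <- .box_mean(arr[, , s], params$local_window)
    mask[, , s] <- arr[, , s] > lm * (1 + params$threshold_offset)
  }
  if (!is.null(params$exclusion_mask)) {
    stopifnot(identical(dim(params$exclusion_mask), dim(arr)))
    mask[params$exclusion_mask] <- FALSE
  }
  mask
}

#' Link a binary volume into 3D objects
#'
#' In-plane components are found per section with 8-connectivity; components
#' in consecutive sections are merged when they share at least
#' `linking_min_overlap_px` pixels at identical (row, col) positions, and the
#' transitive closure of this relation defines one 3D object. Components
#' smaller than `min_area_px` are discarded before linking.
#'
#' @param mask logical H x W x S volume (from [local_threshold()]).
#' @param geometry a [voxel_geometry()] for physical centroids/volumes.
#' @param params a [segmentation_params()].
#' @return list of `object3d`: each has id, channel_role, voxels (data frame
#'   of section/row/col), centroid_nm (x = col, y = row, z = section axis),
#'   volume_nm3, span, per_section_area.
#' @export
link_objects <- function(mask, geometry, params = segmentation_params(),
                         channel_role = "other") {
  stopifnot(is.logical(mask) || is.numeric(mask), length(dim(mask)) == 3)
  S <- dim(mask)[3]
  labels <- array(0L, dim = dim(mask))
  n_comp <- integer(S)
  offset <- 0L
  for (s in seq_len(S)) {
    lab <- cpp_label2d(array(as.logical(mask[, , s]), dim = dim(mask)[1:2]))
    if (params$min_area_px > 1 && max(lab) > 0) {
      sizes <- tabulate(lab, nbins = max(lab))
      drop <- which(sizes < params$min_area_px)
      if (length(drop)) lab[lab %in% drop] <- 0L
      # compact renumber
      keep <- sort(unique(lab[lab > 0]))
      if (length(keep)) {
        remap <- integer(max(keep)); remap[keep] <- seq_along(keep)
        lab[lab > 0] <- remap[lab[lab > 0]]
      }
    }
    n_comp[s] <- max(lab)
    lab[lab > 0] <- lab[lab > 0] + offset
    labels[, , s] <- lab
    offset <- offset + n_comp[s]
  }
  total <- offset
  if (total == 0) return(list())

  # union-find over per-section component ids
  parent <- seq_len(total)
  findp <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (s in seq_len(S - 1)) {
    a <- labels[, , s]; b <- labels[, , s + 1]
    sel <- a > 0 & b > 0
    if (!any(sel)) next
    pairs <- table(paste(a[sel], b[sel]))
    ok <- pairs >= params$linking_min_overlap_px
    if (!any(ok)) next
    for (key in names(pairs)[ok]) {
      ids <- as.integer(strsplit(key, " ")[[1]])
      ra <- findp(ids[1]); rb <- findp(ids[2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(total), findp, 1L)
  obj_id <- match(root, sort(unique(root)))

  idx <- which(labels > 0)
  dims <- dim(mask)
  sec <- (idx - 1) %/% (dims[1] * dims[2]) + 1
  rem <- (idx - 1) %% (dims[1] * dims[2])
  col <- rem %/% dims[1] + 1
  row <- rem %% dims[1] + 1
  oid <- obj_id[labels[idx]]

  px <- geometry$pixel_size_xy; th <- geometry$section_thickness
  vox_vol <- px^2 * th
  objs <- lapply(split(seq_along(idx), oid), function(ii) {
    vox <- data.frame(section = sec[ii], row = row[ii], col = col[ii])
    secs <- sort(unique(vox$section))
    structure(list(
      id = NA_integer_, channel_role = channel_role, voxels = vox,
      centroid_nm = c(x = mean(vox$col - 1) * px, y = mean(vox$row - 1) * px,
                      z = mean(vox$section - 1) * th),
      volume_nm3 = nrow(vox) * vox_vol,
      span = length(secs),
      per_section_area = as.integer(table(factor(vox$section, levels = secs)))),
      class = "object3d")
  })
  objs <- unname(objs)
  for (i in seq_along(objs)) objs[[i]]$id <- i
  objs
}

#' @export
print.object3d <- function(x, ...) {
  cat(sprintf("object3d #%d [%s]: %d voxels, span %d, centroid (%.0f, %.0f, %.0f) nm\n",
              x$id, x$channel_role, nrow(x$voxels), x$span,
              x$centroid_nm[1], x$centroid_nm[2], x$centroid_nm[3]))
  invisible(x)
}

#' Consecutive-section persistence filter
#'
#' Retains only objects detected in more than one consecutive section
#' (span >= 2), the rule that suppresses single-section non-specific signal
#' in array tomography. Idempotent and subset-preserving.
#'
#' @param objects list of `object3d` from [link_objects()].
#' @param min_span minimum consecutive-section span (default 2).
#' @return filtered list (a subset of the input).
#' @export
persistence_filter <- function(objects, min_span = 2) {
  Filter(function(o) o$span >= min_span, objects)
}

#' Neuropil object density
#'
#' `count(objects) / valid tissue volume`, with the volume computed from the
#' valid voxel count and the physical voxel geometry, expressed per mm^3 of
#' neuropil. The validity mask excludes registration-invalid pixels and
#' confounding structures.
#'
#' @param objects list of `object3d`.
#' @param stack the [section_stack()] the objects came from.
#' @param valid_mask logical volume; defaults to the stack's validity mask.
#' @return density in objects per mm^3.
#' @export
object_density <- function(objects, stack, valid_mask = NULL) {
  if (is.null(valid_mask)) valid_mask <- stack$valid_mask
  n_valid <- sum(valid_mask)
  if (n_valid == 0) stop("object_density: zero valid volume")
  vol_mm3 <- n_valid * voxel_volume_mm3(stack$geometry)
  length(objects) / vol_mm3
}

#' Rasterize objects into a labelled volume
#' @param objects list of `object3d`.
#' @param dims volume dimensions c(H, W, S).
#' @return integer array; 0 = background, k = object id.
#' @export
label_volume <- function(objects, dims) {
  lab <- array(0L, dim = dims)
  for (o in objects) {
    v <- o$voxels
    lab[cbind(v$row, v$col, v$section)] <- o$id
  }
  lab
}

#' Automatic exclusion mask for confounding structures
#'
#' Marks large bright structures (blood vessels, cell bodies): thresholded
#' components whose in-plane equivalent diameter exceeds `max_diameter_um`
#' are excluded, the size rule standing in for the manual masking step.
#'
#' @param channel a [channel_volume()] or array.
#' @param geometry a [voxel_geometry()].
#' @param params a [segmentation_params()].
#' @param max_diameter_um equivalent-diameter cutoff in um (default 20).
#' @return logical exclusion mask.
#' @export
exclusion_mask_by_size <- function(channel, geometry,
                                   params = segmentation_params(),
                                   max_diameter_um = 20) {
  mask <- local_threshold(channel, params)
  out <- array(FALSE, dim = dim(mask))
  max_area_px <- pi * (max_diameter_um * 1000 / 2 / geometry$pixel_size_xy)^2
  for (s in seq_len(dim(mask)[3])) {
    lab <- cpp_label2d(array(mask[, , s], dim = dim(mask)[1:2]))
    if (max(lab) == 0) next
    sizes <- tabulate(lab, nbins = max(lab))
    big <- which(sizes > max_area_px)
    if (length(big)) out[, , s] <- array(lab %in% big, dim = dim(lab))
  }
  out
}
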