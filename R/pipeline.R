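#' Validate a pipeline configuration
#'
#' A pipeline run is fully described by one config: either a simulation block
#' (passed to [sim_config()]) or per-channel input paths, plus per-module
#' parameter blocks, a global seed and an output directory. The config is
#' validated before any stage runs and serialized alongside the outputs.
#'
#' @param sim list of [sim_config()] arguments (simulate mode), or NULL.
#' @param paths named list of per-channel TIFF paths (load mode), or NULL.
#' @param geometry a [voxel_geometry()] (required in load mode).
#' @param metadata list of [case_metadata()] arguments.
#' @param segmentation list of [segmentation_params()] arguments.
#' @param coloc list(min_fraction =).
#' @param fret list(k_sigma =, floor_mads =).
#' @param misalign apply [perturb_sections()] before alignment (simulate
#'   mode), exercising the registration stage.
#' @param seed integer; fans out to per-stage substreams.
#' @param outdir output directory.
#' @export
pipeline_config <- function(sim = list(), paths = NULL, geometry = NULL,
                            metadata = list(case_id = "case01",
                                            sample_id = "s1",
                                            diagnosis = "AD", sex = "F"),
                            segmentation = list(),
                            coloc = list(min_fraction = 0.10),
                            fret = list(k_sigma = 0, floor_mads = 5),
                            misalign = TRUE, seed = 1L, outdir = tempfile("atfret_")) {
  if (is.null(sim) && is.null(paths))
    stop("pipeline_config: either a 'sim' block or input 'paths' is required")
  if (!is.null(paths) && is.null(geometry))
    stop("pipeline_config: 'geometry' is required with input paths")
  # validate eagerly so errors precede any compute
  if (!is.null(sim)) do.call(sim_config, modifyList(sim, list(seed = as.integer(seed))))
  do.call(segmentation_params, segmentation)
  stopifnot(coloc$min_fraction >= 0, coloc$min_fraction <= 1)
  do.call(case_metadata, metadata)
  structure(list(sim = sim, paths = paths, geometry = geometry,
                 metadata = metadata, segmentation = segmentation,
                 coloc = coloc, fret = fret, misalign = isTRUE(misalign),
                 seed = as.integer(seed), outdir = outdir),
            class = "pipeline_config")
}

.stage_seed <- function(seed, stage) {
  (as.integer(seed) + 10007L * match(stage, c("simulate", "align", "segment",
                                              "coloc", "fret", "stats"))) %% .Machine$integer.max
}

#' Run the full pipeline: simulate/load, align, segment, coloc, fret, stats
#'
#' Stages form a DAG; each writes its outputs under its own subdirectory of
#' `config$outdir` and never mutates another stage's outputs. A manifest
#' records the package version, seed and config hash, so a rerun with the
#' same config is bit-identical for the deterministic stages.
#'
#' @param config a [pipeline_config()].
#' @return result bundle (invisible list): per-stage outputs, measurement
#'   table and manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  meta <- do.call(case_metadata, config$metadata)

  # -- simulate / load -------------------------------------------------------
  truth <- NULL; calib_stacks <- NULL
  stack <- run_stage("simulate", function() {
    if (!is.null(config$sim)) {
      cfg <- do.call(sim_config, modifyList(
        config$sim, list(seed = .stage_seed(config$seed, "simulate"))))
      gen <- generate_stack(cfg)
      truth <<- gen$truth
      calib_stacks <<- generate_calibration_stacks(cfg)
      st <- gen$stack
      if (config$misalign) st <- perturb_sections(st, cfg)
      d <- file.path(out, "simulate")
      save_stack(st, d)
      jsonlite::write_json(config$sim, file.path(d, "sim_config.json"),
                           auto_unbox = TRUE, digits = NA)
      write.csv(truth$objects, file.path(d, "truth_objects.csv"),
                row.names = FALSE)
      st
    } else {
      load_stack(config$paths, config$geometry, metadata = meta)
    }
  })

  # -- align -----------------------------------------------------------------
  aligned <- run_stage("align", function() {
    if (stack$alignment_state == "aligned")
      return(list(stack = stack,
                  transforms = replicate(n_sections(stack), affine_identity(),
                                         simplify = FALSE)))
    res <- align_stack(stack)
    d <- file.path(out, "align")
    dir.create(d, showWarnings = FALSE)
    write_transforms(res$transforms, file.path(d, "transforms.csv"))
    res
  })
  st <- aligned$stack

  # -- segment ---------------------------------------------------------------
  seg <- run_stage("segment", function() {
    params <- do.call(segmentation_params, config$segmentation)
    dims <- c(frame_shape(st), n_sections(st))
    per_channel <- lapply(names(st$channels), function(nm) {
      role <- st$channels[[nm]]$role
      if (role == "fret_raw") return(NULL)
      objs <- persistence_filter(link_objects(
        local_threshold(st$channels[[nm]], params), st$geometry, params,
        channel_role = role))
      objs
    })
    names(per_channel) <- names(st$channels)
    per_channel <- Filter(Negate(is.null), per_channel)
    d <- file.path(out, "segment")
    dir.create(d, showWarnings = FALSE)
    rows <- do.call(rbind, lapply(names(per_channel), function(nm) {
      objs <- per_channel[[nm]]
      if (!length(objs)) return(NULL)
      data.frame(channel = nm,
                 id = vapply(objs, function(o) o$id, 1),
                 x_nm = vapply(objs, function(o) o$centroid_nm[["x"]], 1),
                 y_nm = vapply(objs, function(o) o$centroid_nm[["y"]], 1),
                 z_nm = vapply(objs, function(o) o$centroid_nm[["z"]], 1),
                 span = vapply(objs, function(o) o$span, 1),
                 volume_nm3 = vapply(objs, function(o) o$volume_nm3, 1))
    }))
    write.csv(rows, file.path(d, "objects.csv"), row.names = FALSE)
    densities <- vapply(per_channel, object_density, 1, stack = st)
    list(objects = per_channel, densities = densities, params = params,
         dims = dims)
  })

  # -- coloc -----------------------------------------------------------------
  coloc <- run_stage("coloc", function() {
    roles <- vapply(st$channels, function(ch) ch$role, "")
    syn_nm <- names(roles)[match(c("synaptic_post", "synaptic_pre"), roles)]
    syn_nm <- syn_nm[!is.na(syn_nm)][1]
    don_nm <- names(roles)[match("donor", roles)]
    if (is.na(syn_nm) || is.na(don_nm)) return(NULL)
    cl <- colocalize(seg$objects[[syn_nm]], seg$objects[[don_nm]], seg$dims,
                     min_fraction = config$coloc$min_fraction)
    d <- file.path(out, "coloc")
    dir.create(d, showWarnings = FALSE)
    write.csv(cl$pairs, file.path(d, "pairs.csv"), row.names = FALSE)
    plaque <- segment_plaque(st$channels[[don_nm]], st$geometry)
    profile <- NULL
    if (plaque$present) {
      profile <- distance_profile(seg$objects[[syn_nm]], plaque, st)
      write.csv(profile, file.path(d, "distance_profile.csv"), row.names = FALSE)
    }
    list(coloc = cl, plaque = plaque, profile = profile)
  })

  # -- fret ------------------------------------------------------------------
  fret <- run_stage("fret", function() {
    roles <- vapply(st$channels, function(ch) ch$role, "")
    if (!all(c("donor", "acceptor", "fret_raw") %in% roles)) return(NULL)
    calib <- if (!is.null(calib_stacks)) {
      fret_calibration(estimate_beta(calib_stacks$donor_only,
                                     config$fret$floor_mads),
                       estimate_gamma(calib_stacks$acceptor_only,
                                      config$fret$floor_mads))
    } else NULL
    if (is.null(calib)) return(NULL)
    params <- seg$params
    masks <- fret_object_masks(st, params)
    Fc <- correct_fret(.find_role(st, "fret_raw"), .find_role(st, "donor"),
                       .find_role(st, "acceptor"), calib)
    pos <- fret_positive_fraction(Fc, masks$donor, masks$acceptor,
                                  masks$synapse, k_sigma = config$fret$k_sigma)
    d <- file.path(out, "fret")
    dir.create(d, showWarnings = FALSE)
    jsonlite::write_json(list(beta = calib$beta, gamma = calib$gamma,
                              session_id = calib$session_id),
                         file.path(d, "calibration.json"), auto_unbox = TRUE,
                         digits = NA)
    list(calibration = calib, percent_positive = pos$percent,
         n_eligible = pos$n_eligible)
  })

  # -- stats: assemble the per-sample measurement table ----------------------
  tab <- run_stage("stats", function() {
    rows <- data.frame(case_id = meta$case_id, sample_id = meta$sample_id,
                       diagnosis = meta$diagnosis, sex = meta$sex,
                       measurement = paste0("density_", names(seg$densities)),
                       value = as.numeric(seg$densities))
    if (!is.null(coloc) && !is.null(coloc$coloc))
      rows <- rbind(rows, data.frame(case_id = meta$case_id,
                                     sample_id = meta$sample_id,
                                     diagnosis = meta$diagnosis, sex = meta$sex,
                                     measurement = "coloc_percent",
                                     value = coloc$coloc$percent))
    if (!is.null(fret))
      rows <- rbind(rows, data.frame(case_id = meta$case_id,
                                     sample_id = meta$sample_id,
                                     diagnosis = meta$diagnosis, sex = meta$sex,
                                     measurement = "fret_percent",
                                     value = fret$percent_positive))
    tab <- measurement_table(rows)
    d <- file.path(out, "stats")
    dir.create(d, showWarnings = FALSE)
    save_results(tab, file.path(d, "measurements.csv"))
    tab
  })

  # -- manifest --------------------------------------------------------------
  cfg_file <- file.path(out, "pipeline_config.json")
  ser <- config
  ser$outdir <- NULL  # path-independent hash
  jsonlite::write_json(lapply(unclass(ser), function(x)
    if (inherits(x, "voxel_geometry")) unclass(x) else x),
    cfg_file, auto_unbox = TRUE, digits = NA, null = "null")
  manifest <- list(package = "atfret",
                   version = as.character(utils::packageVersion("atfret")),
                   seed = config$seed,
                   config_md5 = unname(tools::md5sum(cfg_file)),
                   stages = c("simulate", "align", "segment", "coloc", "fret",
                              "stats"))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(stack = st, truth = truth, alignment = aligned$transforms,
                 segmentation = seg, coloc = coloc, fret = fret,
                 table = tab, manifest = manifest, outdir = out))
}
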