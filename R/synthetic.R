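#' Configuration for the synthetic serial-section generator
#'
#' The generator emulates the statistical structure the analysis assumes:
#' diffraction-limited synaptic puncta spanning at least two consecutive 70 nm
#' sections, donor/acceptor co-labelling at a controllable colocalization
#' fraction, a sensitized-emission FRET channel contaminated by spectral
#' bleed-through (beta, gamma), an optional bright contiguous plaque with a
#' surrounding density gradient and halo puncta, per-section affine
#' misalignment, and Poisson-Gaussian noise. Defaults describe a plausible
#' confocal acquisition (100 nm pixels, puncta of 200-400 nm half-max radius,
#' ~6% shot noise at peak); they are chosen for testability, not fitted to any
#' real acquisition.
#'
#' @param n_sections number of serial sections (>= 2).
#' @param frame_size c(H, W) frame in pixels.
#' @param geometry a [voxel_geometry()].
#' @param n_synapses number of persistent synaptic puncta.
#' @param synapse_radius_xy half-maximum radius range in nm, c(min, max).
#' @param synapse_span_sections consecutive-section span range, c(min, max),
#'   min >= 2.
#' @param synapse_amplitude peak amplitude range above background, c(min, max).
#' @param background constant background offset added to every channel.
#' @param frac_donor_in_synapse,frac_acceptor_in_synapse marginal fraction of
#'   synapses carrying donor / acceptor label, each in `[0, 1]`.
#' @param frac_coloc fraction of synapses carrying *both* labels (must not
#'   exceed either marginal fraction).
#' @param fret_efficiency sensitized-emission amplitude as a fraction of the
#'   donor signal, applied only at colocalized synapses; in `[0, 1]`.
#' @param beta_true donor-emission crosstalk coefficient (>= 0).
#' @param gamma_true direct acceptor-excitation coefficient (>= 0).
#' @param plaque list(present, radius_um, gradient_slope, n_halo_puncta):
#'   gradient_slope is the synapse density multiplier per 10 um distance bin
#'   moving away from the plaque edge (1 = flat, > 1 = synapse loss near the
#'   plaque).
#' @param misalignment list(max_translation_px, max_rotation_deg, max_shear)
#'   bounds for [perturb_sections()].
#' @param noise list(gaussian_sd, poisson_scale); poisson_scale is the
#'   photon-per-intensity-unit conversion for shot noise (0 disables).
#' @param single_section_noise_objects number of single-section puncta added
#'   to the synaptic channel as persistence-filter negatives.
#' @param n_distractors number of extra-synaptic donor and acceptor puncta
#'   (each channel) placed away from synapses.
#' @param seed integer RNG seed; a fixed seed reproduces the stack
#'   bit-for-bit.
#' @return a `sim_config` object (validated list).
#' @export
sim_config <- function(n_sections = 10,
                       frame_size = c(256, 256),
                       geometry = voxel_geometry(100, 70),
                       n_synapses = 120,
                       synapse_radius_xy = c(200, 400),
                       synapse_span_sections = c(2, 4),
                       synapse_amplitude = c(1500, 3000),
                       background = 100,
                       frac_donor_in_synapse = 0.5,
                       frac_acceptor_in_synapse = 0.4,
                       frac_coloc = 0.3,
                       fret_efficiency = 0.3,
                       beta_true = 0.2,
                       gamma_true = 0.1,
                       plaque = list(present = FALSE, radius_um = 5,
                                     gradient_slope = 1, n_halo_puncta = 12),
                       misalignment = list(max_translation_px = 4,
                                           max_rotation_deg = 1.5,
                                           max_shear = 0.01),
                       noise = list(gaussian_sd = 8, poisson_scale = 0.25),
                       single_section_noise_objects = 25,
                       n_distractors = 15,
                       seed = 1L) {
  plaque <- modifyList(list(present = FALSE, radius_um = 5,
                            gradient_slope = 1, n_halo_puncta = 12), plaque)
  misalignment <- modifyList(list(max_translation_px = 4, max_rotation_deg = 1.5,
                                  max_shear = 0.01), misalignment)
  noise <- modifyList(list(gaussian_sd = 8, poisson_scale = 0.25), noise)
  fr <- c(frac_donor_in_synapse, frac_acceptor_in_synapse, frac_coloc,
          fret_efficiency)
  stopifnot(n_sections >= 2, all(frame_size >= 16),
            inherits(geometry, "voxel_geometry"),
            n_synapses >= 0, all(fr >= 0), all(fr <= 1),
            synapse_span_sections[1] >= 2,
            synapse_span_sections[2] <= n_sections,
            beta_true >= 0, gamma_true >= 0,
            plaque$gradient_slope > 0)
  if (frac_coloc > frac_donor_in_synapse + 1e-12 ||
      frac_coloc > frac_acceptor_in_synapse + 1e-12)
    stop("sim_config: frac_coloc cannot exceed the marginal label fractions")
  structure(list(n_sections = as.integer(n_sections),
                 frame_size = as.integer(frame_size), geometry = geometry,
                 n_synapses = as.integer(n_synapses),
                 synapse_radius_xy = synapse_radius_xy,
                 synapse_span_sections = as.integer(synapse_span_sections),
                 synapse_amplitude = synapse_amplitude,
                 background = background,
                 frac_donor_in_synapse = frac_donor_in_synapse,
                 frac_acceptor_in_synapse = frac_acceptor_in_synapse,
                 frac_coloc = frac_coloc, fret_efficiency = fret_efficiency,
                 beta_true = beta_true, gamma_true = gamma_true,
                 plaque = plaque, misalignment = misalignment, noise = noise,
                 single_section_noise_objects = as.integer(single_section_noise_objects),
                 n_distractors = as.integer(n_distractors),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# half-max radius r (nm) -> Gaussian sigma (px)
.sigma_px <- function(radius_nm, geometry) {
  radius_nm / geometry$pixel_size_xy / sqrt(2 * log(2))
}

# additive Gaussian punctum on one section plane, within a 3-sigma box
.render_punctum <- function(plane, r0, c0, sigma, amplitude) {
  H <- nrow(plane); W <- ncol(plane)
  w <- ceiling(3 * sigma)
  rr <- max(1, round(r0) - w):min(H, round(r0) + w)
  cc <- max(1, round(c0) - w):min(W, round(c0) + w)
  d2 <- outer((rr - r0)^2, (cc - c0)^2, "+")
  plane[rr, cc] <- plane[rr, cc] + amplitude * exp(-d2 / (2 * sigma^2))
  plane
}

# truth voxels: in-plane half-max disk, one row per (section, row, col)
.punctum_voxels <- function(r0, c0, s0, s1, radius_px, shape) {
  w <- ceiling(radius_px)
  rr <- max(1, round(r0) - w):min(shape[1], round(r0) + w)
  cc <- max(1, round(c0) - w):min(shape[2], round(c0) + w)
  d2 <- outer((rr - r0)^2, (cc - c0)^2, "+")
  idx <- which(d2 <= radius_px^2, arr.ind = TRUE)
  if (!nrow(idx)) idx <- cbind(round(r0) - rr[1] + 1, round(c0) - cc[1] + 1)
  sections <- rep(s0:s1, each = nrow(idx))
  data.frame(section = sections,
             row = rep(rr[idx[, 1]], s1 - s0 + 1),
             col = rep(cc[idx[, 2]], s1 - s0 + 1))
}

.apply_noise <- function(arr, noise) {
  if (noise$poisson_scale > 0) {
    lam <- pmax(arr, 0) * noise$poisson_scale
    arr <- array(rpois(length(lam), lam), dim = dim(arr)) / noise$poisson_scale
  }
  if (noise$gaussian_sd > 0)
    arr <- arr + array(rnorm(length(arr), 0, noise$gaussian_sd), dim = dim(arr))
  pmin(pmax(arr, 0), 65535)
}

# Rejection-sample object centres with a minimum separation, an exclusion
# radius around the plaque, and a distance-dependent acceptance weight.
.place_centres <- function(n, shape, margin, min_sep, weight_fn = NULL,
                           existing = NULL, max_tries = 500) {
  centres <- if (is.null(existing)) matrix(numeric(0), 0, 2) else existing
  placed <- matrix(numeric(0), 0, 2)
  tries <- 0
  while (nrow(placed) < n) {
    tries <- tries + 1
    if (tries > max_tries * max(n, 1))
      stop("generate_stack: infeasible packing - too many objects for the frame")
    cand <- c(runif(1, margin, shape[1] - margin),
              runif(1, margin, shape[2] - margin))
    if (!is.null(weight_fn) && runif(1) > weight_fn(cand)) next
    all_pts <- rbind(centres, placed)
    if (nrow(all_pts) &&
        min((all_pts[, 1] - cand[1])^2 + (all_pts[, 2] - cand[2])^2) < min_sep^2)
      next
    placed <- rbind(placed, cand)
  }
  placed
}

.plaque_distance_um <- function(rows, cols, plaque_centre, radius_px, geometry) {
  d_px <- sqrt((rows - plaque_centre[1])^2 + (cols - plaque_centre[2])^2)
  (d_px - radius_px) * geometry$pixel_size_xy / 1000  # negative inside core
}

#' Generate a synthetic serial-section stack with ground truth
#'
#' Renders synaptic, donor, acceptor and raw-FRET channels of a perfectly
#' aligned stack. The raw FRET channel is built per pixel as
#' `E * donor_signal` (only at colocalized synapses) `+ beta_true * donor +
#' gamma_true * acceptor + noise`. Use [perturb_sections()] afterwards to
#' exercise registration.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `stack` (a [section_stack()], aligned) and
#'   `truth` (ground-truth record: `objects` data frame, per-object voxel
#'   list, colocalization flags, true-FRET mask, section transforms, plaque
#'   truth, per-bin densities).
#' @export
generate_stack <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  H <- cfg$frame_size[1]; W <- cfg$frame_size[2]; S <- cfg$n_sections
  g <- cfg$geometry
  px <- g$pixel_size_xy
  r_px_max <- cfg$synapse_radius_xy[2] / px
  margin <- ceiling(r_px_max + cfg$misalignment$max_translation_px +
                    sin(cfg$misalignment$max_rotation_deg * pi / 180) * max(H, W) / 2 +
                    cfg$misalignment$max_shear * max(H, W) / 2) + 2
  min_sep <- 2 * r_px_max + 3

  plaque_centre <- NULL; plaque_radius_px <- NULL
  if (isTRUE(cfg$plaque$present)) {
    plaque_radius_px <- cfg$plaque$radius_um * 1000 / px
    plaque_centre <- c(H / 2, W / 2)
  }

  weight_fn <- NULL
  if (!is.null(plaque_centre)) {
    slope <- cfg$plaque$gradient_slope
    max_bin <- 5
    weight_fn <- function(p) {
      d <- .plaque_distance_um(p[1], p[2], plaque_centre, plaque_radius_px, g)
      if (d < r_px_max * px / 1000) return(0)  # keep puncta off the core
      b <- min(floor(d / 10), max_bin)
      # normalise so the densest bin has acceptance 1
      s <- slope^b
      s / slope^(if (slope >= 1) max_bin else 0)
    }
  }

  syn_centres <- .place_centres(cfg$n_synapses, c(H, W), margin, min_sep,
                                weight_fn = weight_fn)

  n <- cfg$n_synapses
  radius_nm <- runif(n, cfg$synapse_radius_xy[1], cfg$synapse_radius_xy[2])
  span <- if (n) sample(seq(cfg$synapse_span_sections[1],
                            cfg$synapse_span_sections[2]), n, replace = TRUE)
          else integer(0)
  s0 <- if (n) vapply(span, function(sp) sample(seq_len(S - sp + 1), 1), 1L)
        else integer(0)
  amp <- runif(n, cfg$synapse_amplitude[1], cfg$synapse_amplitude[2])

  # label assignment: the configured fractions are realized exactly (rounded
  # counts, random placement) rather than as Bernoulli probabilities, so the
  # generating fraction is a property of every stack, not just its
  # expectation. Coloc synapses carry both fluorophores; the remaining
  # marginal counts are spread at random over the rest.
  fc <- cfg$frac_coloc
  n_coloc <- round(fc * n)
  coloc <- logical(n)
  coloc[sample.int(n, n_coloc)] <- TRUE
  assign_extra <- function(frac) {
    extra <- logical(n)
    k <- max(0, round(frac * n) - n_coloc)
    pool <- which(!coloc)
    if (k > 0 && length(pool))
      extra[sample(pool, min(k, length(pool)))] <- TRUE
    extra
  }
  has_donor <- coloc | assign_extra(cfg$frac_donor_in_synapse)
  has_acceptor <- coloc | assign_extra(cfg$frac_acceptor_in_synapse)

  blank <- function() array(0, dim = c(H, W, S))
  syn <- blank(); don <- blank(); acc <- blank(); sens <- blank()

  objects <- data.frame()
  voxels <- list()
  add_obj <- function(objects, channel, r0, c0, s_first, s_last, rad_nm, a) {
    id <- nrow(objects) + 1L
    rbind(objects, data.frame(
      id = id, channel = channel, row = r0, col = c0, s0 = s_first,
      s1 = s_last, span = s_last - s_first + 1L, radius_nm = rad_nm,
      amplitude = a,
      x_nm = (c0 - 1) * px, y_nm = (r0 - 1) * px,
      z_nm = (mean(c(s_first, s_last)) - 1) * g$section_thickness))
  }

  for (i in seq_len(n)) {
    r0 <- syn_centres[i, 1]; c0 <- syn_centres[i, 2]
    sig <- .sigma_px(radius_nm[i], g)
    sl <- s0[i]:(s0[i] + span[i] - 1)
    for (s in sl) syn[, , s] <- .render_punctum(syn[, , s], r0, c0, sig, amp[i])
    objects <- add_obj(objects, "synaptic_post", r0, c0, sl[1], sl[length(sl)],
                       radius_nm[i], amp[i])
    voxels[[nrow(objects)]] <- .punctum_voxels(r0, c0, sl[1], sl[length(sl)],
                                               radius_nm[i] / px, c(H, W))
    if (has_donor[i])
      for (s in sl) don[, , s] <- .render_punctum(don[, , s], r0, c0, sig, amp[i])
    if (has_acceptor[i])
      for (s in sl) acc[, , s] <- .render_punctum(acc[, , s], r0, c0, sig, amp[i])
    if (coloc[i] && cfg$fret_efficiency > 0)
      for (s in sl) sens[, , s] <- .render_punctum(sens[, , s], r0, c0, sig,
                                                   cfg$fret_efficiency * amp[i])
  }

  # extra-synaptic distractor puncta in donor and acceptor channels
  distract <- data.frame()
  if (cfg$n_distractors > 0) {
    for (ch in c("donor", "acceptor")) {
      prior <- if (nrow(distract)) rbind(syn_centres, as.matrix(distract))
               else syn_centres
      ctr <- .place_centres(cfg$n_distractors, c(H, W), margin, min_sep,
                            weight_fn = weight_fn, existing = prior)
      for (i in seq_len(nrow(ctr))) {
        rad <- runif(1, cfg$synapse_radius_xy[1], cfg$synapse_radius_xy[2])
        a <- runif(1, cfg$synapse_amplitude[1], cfg$synapse_amplitude[2])
        sp <- sample(seq(cfg$synapse_span_sections[1],
                         cfg$synapse_span_sections[2]), 1)
        sf <- sample(seq_len(S - sp + 1), 1)
        sig <- .sigma_px(rad, g)
        for (s in sf:(sf + sp - 1)) {
          if (ch == "donor")
            don[, , s] <- .render_punctum(don[, , s], ctr[i, 1], ctr[i, 2], sig, a)
          else
            acc[, , s] <- .render_punctum(acc[, , s], ctr[i, 1], ctr[i, 2], sig, a)
        }
        objects <- add_obj(objects, ch, ctr[i, 1], ctr[i, 2], sf, sf + sp - 1L,
                           rad, a)
        voxels[[nrow(objects)]] <- .punctum_voxels(ctr[i, 1], ctr[i, 2], sf,
                                                   sf + sp - 1L, rad / px, c(H, W))
        distract <- rbind(distract, data.frame(row = ctr[i, 1], col = ctr[i, 2]))
      }
    }
  }

  # persistence-filter negatives: single-section puncta in the synaptic
  # channel; deliberately NOT part of truth$objects
  noise_objects <- data.frame()
  if (cfg$single_section_noise_objects > 0) {
    prior <- if (nrow(distract)) rbind(syn_centres, as.matrix(distract))
             else syn_centres
    ctr <- .place_centres(cfg$single_section_noise_objects, c(H, W), margin,
                          min_sep, weight_fn = weight_fn, existing = prior)
    for (i in seq_len(nrow(ctr))) {
      rad <- runif(1, cfg$synapse_radius_xy[1], cfg$synapse_radius_xy[2])
      a <- runif(1, cfg$synapse_amplitude[1], cfg$synapse_amplitude[2])
      s <- sample(seq_len(S), 1)
      syn[, , s] <- .render_punctum(syn[, , s], ctr[i, 1], ctr[i, 2],
                                    .sigma_px(rad, g), a)
      noise_objects <- rbind(noise_objects,
                             data.frame(row = ctr[i, 1], col = ctr[i, 2],
                                        section = s, radius_nm = rad))
    }
  }

  # plaque: one bright contiguous disk through all sections in the donor
  # (amyloid) channel, plus small single-section halo puncta near the edge
  plaque_truth <- list(present = FALSE)
  if (!is.null(plaque_centre)) {
    rows <- matrix(seq_len(H), H, W)
    cols <- matrix(seq_len(W), H, W, byrow = TRUE)
    core2d <- (rows - plaque_centre[1])^2 + (cols - plaque_centre[2])^2 <=
      plaque_radius_px^2
    amp_plq <- cfg$synapse_amplitude[2] * 1.5
    for (s in seq_len(S)) don[, , s] <- don[, , s] + amp_plq * core2d
    if (cfg$plaque$n_halo_puncta > 0) {
      ang <- runif(cfg$plaque$n_halo_puncta, 0, 2 * pi)
      rr <- plaque_radius_px + runif(cfg$plaque$n_halo_puncta, 3, 10)
      for (i in seq_len(cfg$plaque$n_halo_puncta)) {
        hr <- plaque_centre[1] + rr[i] * sin(ang[i])
        hc <- plaque_centre[2] + rr[i] * cos(ang[i])
        if (hr < 2 || hc < 2 || hr > H - 1 || hc > W - 1) next
        s <- sample(seq_len(S), 1)
        don[, , s] <- .render_punctum(don[, , s], hr, hc,
                                      .sigma_px(cfg$synapse_radius_xy[1], g),
                                      cfg$synapse_amplitude[1])
      }
    }
    plaque_truth <- list(present = TRUE, centre = plaque_centre,
                         radius_px = plaque_radius_px,
                         core_area_px = sum(core2d))
  }

  syn <- syn + cfg$background
  don <- don + cfg$background
  acc <- acc + cfg$background
  fret <- sens + cfg$beta_true * don + cfg$gamma_true * acc

  true_fret_positive <- sens > 0

  syn <- .apply_noise(syn, cfg$noise)
  don <- .apply_noise(don, cfg$noise)
  acc <- .apply_noise(acc, cfg$noise)
  fret <- .apply_noise(fret, cfg$noise)

  stack <- section_stack(
    list(synaptic = channel_volume(syn, "synaptic_post"),
         donor = channel_volume(don, "donor"),
         acceptor = channel_volume(acc, "acceptor"),
         fret_raw = channel_volume(fret, "fret_raw")),
    g, alignment_state = "aligned")

  # truth densities of synaptic objects per 10 um plaque-edge bin
  true_bin_densities <- NULL
  if (plaque_truth$present && n > 0) {
    d_obj <- .plaque_distance_um(syn_centres[, 1], syn_centres[, 2],
                                 plaque_centre, plaque_radius_px, g)
    d_obj <- pmax(d_obj, 0)
    rows <- matrix(seq_len(H), H, W)
    cols <- matrix(seq_len(W), H, W, byrow = TRUE)
    d_pix <- .plaque_distance_um(rows, cols, plaque_centre, plaque_radius_px, g)
    edges <- c(0, 10, 20, 30, 40, 50, Inf)
    counts <- volumes <- numeric(length(edges) - 1)
    for (b in seq_len(length(edges) - 1)) {
      counts[b] <- sum(d_obj >= edges[b] & d_obj < edges[b + 1])
      volumes[b] <- sum(d_pix >= edges[b] & d_pix < edges[b + 1]) * S *
        voxel_volume_mm3(g)
    }
    true_bin_densities <- data.frame(
      bin_lo = edges[-length(edges)], bin_hi = edges[-1],
      count = counts, volume_mm3 = volumes,
      density = ifelse(volumes > 0, counts / volumes, NA_real_))
  }

  truth <- list(
    placement_margin_px = margin,
    objects = objects,
    voxels = voxels,
    coloc = data.frame(synapse_id = seq_len(n), coloc = coloc,
                       has_donor = has_donor, has_acceptor = has_acceptor),
    noise_objects = noise_objects,
    true_fret_positive = true_fret_positive,
    section_transforms = replicate(S, affine_identity(), simplify = FALSE),
    plaque = plaque_truth,
    true_bin_densities = true_bin_densities,
    config = cfg)
  list(stack = stack, truth = truth)
}

#' Generate donor-only and acceptor-only calibration stacks
#'
#' Emulates the single-fluorophore control samples imaged in each session to
#' estimate the bleed-through coefficients: the donor-only stack has zero
#' acceptor signal and a raw FRET channel equal to `beta_true * donor` plus
#' noise; the acceptor-only stack is the symmetric case with `gamma_true`.
#'
#' @param cfg a [sim_config()].
#' @return list(donor_only =, acceptor_only =) of [section_stack()]s.
#' @export
generate_calibration_stacks <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1000003L)
  H <- cfg$frame_size[1]; W <- cfg$frame_size[2]; S <- cfg$n_sections
  g <- cfg$geometry
  margin <- ceiling(cfg$synapse_radius_xy[2] / g$pixel_size_xy) + 2
  min_sep <- 2 * cfg$synapse_radius_xy[2] / g$pixel_size_xy + 3

  render_control <- function() {
    arr <- array(0, dim = c(H, W, S))
    ctr <- .place_centres(cfg$n_synapses, c(H, W), margin, min_sep)
    for (i in seq_len(nrow(ctr))) {
      rad <- runif(1, cfg$synapse_radius_xy[1], cfg$synapse_radius_xy[2])
      a <- runif(1, cfg$synapse_amplitude[1], cfg$synapse_amplitude[2])
      sp <- sample(seq(cfg$synapse_span_sections[1],
                       cfg$synapse_span_sections[2]), 1)
      sf <- sample(seq_len(S - sp + 1), 1)
      sig <- .sigma_px(rad, g)
      for (s in sf:(sf + sp - 1))
        arr[, , s] <- .render_punctum(arr[, , s], ctr[i, 1], ctr[i, 2], sig, a)
    }
    arr + cfg$background
  }

  don <- render_control()
  don_fret <- .apply_noise(cfg$beta_true * don, cfg$noise)
  donor_only <- section_stack(
    list(donor = channel_volume(.apply_noise(don, cfg$noise), "donor"),
         fret_raw = channel_volume(don_fret, "fret_raw")),
    g, alignment_state = "aligned")

  acc <- render_control()
  acc_fret <- .apply_noise(cfg$gamma_true * acc, cfg$noise)
  acceptor_only <- section_stack(
    list(acceptor = channel_volume(.apply_noise(acc, cfg$noise), "acceptor"),
         fret_raw = channel_volume(acc_fret, "fret_raw")),
    g, alignment_state = "aligned")

  list(donor_only = donor_only, acceptor_only = acceptor_only)
}

#' Apply a recorded random affine misalignment to every section
#'
#' Each section receives one random affine (translation, rotation about the
#' frame centre, shear) within the configured bounds; the identical transform
#' is applied to every channel of that section. The applied transforms are
#' returned as the `"section_transforms"` attribute of the perturbed stack
#' (retrievable with [section_transforms()]).
#'
#' @param stack an aligned [section_stack()].
#' @param cfg a [sim_config()]; only the `misalignment` block and `seed` are
#'   used.
#' @return the perturbed [section_stack()] with alignment_state `"raw"`.
#' @export
perturb_sections <- function(stack, cfg) {
  stopifnot(inherits(stack, "section_stack"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2000003L)
  S <- n_sections(stack)
  shape <- frame_shape(stack)
  centre <- (shape - 1) / 2
  m <- cfg$misalignment
  transforms <- vector("list", S)
  channels <- lapply(stack$channels, function(ch) ch$intensities)
  for (s in seq_len(S)) {
    tr <- runif(2, -m$max_translation_px, m$max_translation_px)
    th <- runif(1, -m$max_rotation_deg, m$max_rotation_deg)
    sh <- runif(2, -m$max_shear, m$max_shear)
    A <- affine_rigid(th, tr, centre)
    shear <- affine2d(matrix(c(1, sh[1], sh[2], 1), 2, 2),
                      -matrix(c(1, sh[1], sh[2], 1), 2, 2) %*% centre + centre)
    transforms[[s]] <- affine_compose(A, shear)
    if (max(abs(unclass(transforms[[s]]) - unclass(affine_identity()))) < 1e-12)
      next
    for (nm in names(channels)) {
      w <- warp_image(channels[[nm]][, , s], transforms[[s]], fill = 0)
      channels[[nm]][, , s] <- w$image
    }
  }
  out_channels <- lapply(names(channels), function(nm)
    channel_volume(channels[[nm]], stack$channels[[nm]]$role))
  names(out_channels) <- names(channels)
  out <- section_stack(out_channels, stack$geometry, alignment_state = "raw",
                       metadata = stack$metadata)
  attr(out, "section_transforms") <- transforms
  out
}

#' Recorded per-section transforms of a perturbed stack
#' @param stack a stack returned by [perturb_sections()].
#' @export
section_transforms <- function(stack) attr(stack, "section_transforms")
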