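# Sensitized-emission FRET: bleed-through calibration and correction.
#
# Channel conventions: I_DD = donor excitation / donor emission,
# I_AA = acceptor excitation / acceptor emission, I_DA = donor excitation /
# acceptor emission (the raw FRET image). The corrected image is
# Fc = I_DA - beta * I_DD - gamma * I_AA per pixel, with beta the
# donor-emission crosstalk and gamma the direct acceptor excitation, both
# estimated from single-fluorophore control stacks of the same imaging
# session.

.find_role <- function(stack, role) {
  roles <- vapply(stack$channels, function(ch) ch$role, "")
  i <- which(roles == role)
  if (!length(i))
    stop("no channel with role '", role, "' in stack")
  stack$channels[[i[1]]]$intensities
}

# Robust slope through the origin: median of per-pixel ratios over pixels
# with clear signal. The floor sits well above the background (median +
# k * MAD of the donor/acceptor channel) so background pixels - whose noisy
# ratios would attenuate the estimate - are excluded.
.robust_origin_slope <- function(x, y, floor_mads = 5, min_pixels = 100) {
  bg <- median(x)
  floor_val <- bg + floor_mads * max(stats::mad(x), 1e-8)
  sel <- x > floor_val
  if (sum(sel) < min_pixels)
    stop("calibration error: too few suprathreshold pixels (",
         sum(sel), " < ", min_pixels, ")")
  ratios <- y[sel] / x[sel]
  list(slope = max(0, median(ratios)),
       n_pixels = sum(sel),
       dispersion = stats::mad(ratios))
}

#' Estimate the donor-emission crosstalk coefficient (beta)
#'
#' From a donor-only control stack (no acceptor present), beta is the robust
#' slope through the origin of the raw FRET intensity against the donor
#' intensity, over pixels with donor signal above an intensity floor.
#'
#' @param donor_only a [section_stack()] with channels of role `donor` and
#'   `fret_raw`.
#' @param floor_mads inclusion floor in background MADs above the channel median
#'   (pixels below it are excluded from the slope).
#' @return a `fret_calibration` contribution: list(beta, diagnostics).
#' @export
estimate_beta <- function(donor_only, floor_mads = 5) {
  I_DD <- .find_role(donor_only, "donor")
  I_DA <- .find_role(donor_only, "fret_raw")
  if (all(I_DD == 0)) stop("estimate_beta: donor channel is all zero")
  fit <- .robust_origin_slope(as.vector(I_DD), as.vector(I_DA), floor_mads)
  list(beta = fit$slope,
       diagnostics = list(n_pixels = fit$n_pixels, dispersion = fit$dispersion))
}

#' Estimate the direct acceptor-excitation coefficient (gamma)
#'
#' Symmetric to [estimate_beta()], from an acceptor-only control stack:
#' robust origin slope of the raw FRET intensity against the acceptor
#' intensity.
#'
#' @param acceptor_only a [section_stack()] with channels of role `acceptor`
#'   and `fret_raw`.
#' @inheritParams estimate_beta
#' @export
estimate_gamma <- function(acceptor_only, floor_mads = 5) {
  I_AA <- .find_role(acceptor_only, "acceptor")
  I_DA <- .find_role(acceptor_only, "fret_raw")
  if (all(I_AA == 0)) stop("estimate_gamma: acceptor channel is all zero")
  fit <- .robust_origin_slope(as.vector(I_AA), as.vector(I_DA), floor_mads)
  list(gamma = fit$slope,
       diagnostics = list(n_pixels = fit$n_pixels, dispersion = fit$dispersion))
}

#' Bundle beta and gamma into a session calibration
#'
#' Calibrations are scoped to one imaging session: controls are imaged in
#' each session and the coefficients must not be applied across sessions
#' without explicit override.
#'
#' @param beta,gamma non-negative coefficients, or the outputs of
#'   [estimate_beta()] / [estimate_gamma()].
#' @param session_id identifier of the imaging session.
#' @export
fret_calibration <- function(beta, gamma, session_id = "session1") {
  diag_b <- diag_g <- NULL
  if (is.list(beta)) { diag_b <- beta$diagnostics; beta <- beta$beta }
  if (is.list(gamma)) { diag_g <- gamma$diagnostics; gamma <- gamma$gamma }
  stopifnot(is.numeric(beta), beta >= 0, is.numeric(gamma), gamma >= 0)
  structure(list(beta = beta, gamma = gamma, session_id = session_id,
                 diagnostics = list(beta = diag_b, gamma = diag_g)),
            class = "fret_calibration")
}

#' @export
print.fret_calibration <- function(x, ...) {
  cat(sprintf("fret_calibration [%s]: beta = %.4f, gamma = %.4f\n",
              x$session_id, x$beta, x$gamma))
  invisible(x)
}

#' Bleed-through-correct a raw sensitized-emission volume
#'
#' `Fc = I_DA - beta * I_DD - gamma * I_AA` per pixel. Negative values are
#' retained (not clipped) so the positivity rule downstream sees the full
#' corrected distribution. The operation is linear in each input volume.
#'
#' @param I_DA raw FRET volume (donor excitation, acceptor emission).
#' @param I_DD donor volume. @param I_AA acceptor volume.
#' @param calib a [fret_calibration()].
#' @param session_id session of the images; must match the calibration unless
#'   `allow_cross_session = TRUE`.
#' @param allow_cross_session explicit override of the session-scoping guard.
#' @return corrected volume Fc (same shape, possibly negative).
#' @export
correct_fret <- function(I_DA, I_DD, I_AA, calib, session_id = calib$session_id,
                         allow_cross_session = FALSE) {
  stopifnot(inherits(calib, "fret_calibration"))
  if (!identical(session_id, calib$session_id) && !allow_cross_session)
    stop("correct_fret: calibration from session '", calib$session_id,
         "' applied to images from session '", session_id,
         "'; set allow_cross_session = TRUE to override")
  get_arr <- function(x) if (inherits(x, "channel_volume")) x$intensities else x
  I_DA <- get_arr(I_DA); I_DD <- get_arr(I_DD); I_AA <- get_arr(I_AA)
  if (!identical(dim(I_DA), dim(I_DD)) || !identical(dim(I_DA), dim(I_AA)))
    stop("correct_fret: volume shapes differ")
  I_DA - calib$beta * I_DD - calib$gamma * I_AA
}

#' Percent of FRET-positive pixels within triple-overlap synaptic masks
#'
#' Eligible pixels are those inside all three segmented object masks (donor,
#' acceptor and synaptic terminal); the statistic is the percentage of
#' eligible pixels whose corrected FRET intensity exceeds the positivity
#' threshold. The default threshold 0 implements the literal "any FRET
#' signal" rule; `k_sigma > 0` instead requires `Fc > k_sigma * sd(background
#' Fc)` with the background taken as pixels outside all masks.
#'
#' @param Fc corrected FRET volume from [correct_fret()].
#' @param donor_mask,acceptor_mask,synapse_mask logical volumes of segmented
#'   object voxels (post persistence filter).
#' @param k_sigma noise multiple for the positivity threshold (default 0).
#' @return list(percent, n_eligible, threshold); `percent` is NA when no
#'   pixel is eligible.
#' @export
fret_positive_fraction <- function(Fc, donor_mask, acceptor_mask, synapse_mask,
                                   k_sigma = 0) {
  stopifnot(identical(dim(Fc), dim(donor_mask)),
            identical(dim(Fc), dim(acceptor_mask)),
            identical(dim(Fc), dim(synapse_mask)))
  eligible <- donor_mask & acceptor_mask & synapse_mask
  n <- sum(eligible)
  thr <- 0
  if (k_sigma > 0) {
    bg <- Fc[!(donor_mask | acceptor_mask | synapse_mask)]
    thr <- k_sigma * sd(bg)
  }
  if (n == 0)
    return(list(percent = NA_real_, n_eligible = 0L, threshold = thr))
  list(percent = 100 * sum(Fc[eligible] > thr) / n,
       n_eligible = as.integer(n), threshold = thr)
}

#' Masks of segmented objects for the three FRET channels
#'
#' Convenience wrapper: thresholds and links each channel, applies the
#' persistence filter, and returns the voxel masks of the retained objects.
#'
#' @param stack an aligned [section_stack()] with donor, acceptor and
#'   synaptic channels.
#' @param params a [segmentation_params()].
#' @param synaptic_role role of the synaptic reference channel.
#' @return list of logical volumes: donor, acceptor, synapse, plus the
#'   retained object lists.
#' @export
fret_object_masks <- function(stack, params = segmentation_params(),
                              synaptic_role = "synaptic_post") {
  dims <- c(frame_shape(stack), n_sections(stack))
  one <- function(role) {
    arr <- .find_role(stack, role)
    objs <- persistence_filter(
      link_objects(local_threshold(arr, params), stack$geometry, params,
                   channel_role = role))
    mask <- label_volume(objs, dims) > 0
    list(objects = objs, mask = mask)
  }
  d <- one("donor"); a <- one("acceptor"); s <- one(synaptic_role)
  list(donor = d$mask, acceptor = a$mask, synapse = s$mask,
       objects = list(donor = d$objects, acceptor = a$objects,
                      synapse = s$objects))
}
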