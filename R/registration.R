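# Rigid-then-affine pairwise section registration.
#
# Transform convention: estimate_pairwise(fixed, moving) returns the affine P
# that generated the moving image from the fixed one, i.e.
# moving == warp_image(fixed, P) up to noise. The correction that re-aligns
# the moving image onto the fixed frame is therefore warp_image(moving,
# affine_invert(P)).

.ncc <- function(a, b, valid = NULL) {
  keep <- a != 0 & b != 0  # exact zeros mark out-of-frame fill
  if (!is.null(valid)) keep <- keep & valid
  if (any(keep)) { a <- a[keep]; b <- b[keep] }
  if (sd(a) == 0 || sd(b) == 0) return(0)
  mean((a - mean(a)) * (b - mean(b))) / (sd(a) * sd(b))
}

# Integer-pixel translation by phase correlation with parabolic subpixel
# refinement. Returns t such that moving(q) ~= fixed(q - t).
.phase_translation <- function(fixed, moving) {
  Ff <- fft(fixed); Fm <- fft(moving)
  R <- Ff * Conj(Fm)
  mag <- Mod(R)
  R <- R / pmax(mag, 1e-12)
  corr <- Re(fft(R, inverse = TRUE))
  peak <- which.max(corr)
  nr <- nrow(fixed); nc <- ncol(fixed)
  pr <- (peak - 1) %% nr
  pc <- (peak - 1) %/% nr

  subpix <- function(vals, p, n) {
    # parabolic fit over wrapped neighbours
    get <- function(i) vals[((i %% n) + n) %% n + 1]
    y0 <- get(p - 1); y1 <- get(p); y2 <- get(p + 1)
    den <- y0 - 2 * y1 + y2
    if (abs(den) < 1e-12) 0 else 0.5 * (y0 - y2) / den
  }
  dr <- subpix(corr[, pc + 1], pr, nr)
  dc <- subpix(corr[pr + 1, ], pc, nc)
  sr <- pr + dr; sc <- pc + dc
  if (sr > nr / 2) sr <- sr - nr
  if (sc > nc / 2) sc <- sc - nc
  # correlation peak at d with f(q + d) matching m(q) means content moved by -d
  -c(sr, sc)
}

# Robust Gauss-Newton refinement of the full affine resampling map W
# (6 params) minimizing a Cauchy-weighted SSD of moving(W q) against
# fixed(q). The robust weights downweight pixels whose residual is dominated
# by genuine content difference between consecutive physical sections
# (objects starting or ending), which would otherwise bias the fit; weights
# rescale each iteration from the residual MAD. Returns P = W.
.refine_affine <- function(fixed, moving, init, max_iter = 80, tol_px = 5e-3) {
  nr <- nrow(fixed); nc <- ncol(fixed)
  gr <- moving * 0; gc <- moving * 0
  gr[2:(nr - 1), ] <- (moving[3:nr, ] - moving[1:(nr - 2), ]) / 2
  gc[, 2:(nc - 1)] <- (moving[, 3:nc] - moving[, 1:(nc - 2)]) / 2
  qr <- matrix(0:(nr - 1), nr, nc)
  qc <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  W <- unclass(init)
  for (iter in seq_len(max_iter)) {
    wm <- cpp_warp_affine(moving, W, 0)
    wgr <- cpp_warp_affine(gr, W, 0)
    wgc <- cpp_warp_affine(gc, W, 0)
    v <- wm$valid & fixed != 0 & wm$image != 0
    r <- (wm$image - fixed)[v]
    s <- stats::mad(r)
    wt <- if (s < 1e-9) rep(1, length(r)) else 1 / (1 + (r / (3 * s))^2)
    # Jacobian columns: l11, l12, t1 couple through the row gradient;
    # l21, l22, t2 through the column gradient
    J <- cbind(wgr$image[v] * qr[v], wgr$image[v] * qc[v], wgr$image[v],
               wgc$image[v] * qr[v], wgc$image[v] * qc[v], wgc$image[v])
    Jw <- J * wt
    rhs <- -crossprod(Jw, r)
    JtJ <- crossprod(Jw, J)
    step <- tryCatch(solve(JtJ + diag(1e-8 * diag(JtJ) + 1e-12), rhs),
                     error = function(e) rep(0, 6))
    W <- W + rbind(step[c(1, 2, 3)], step[c(4, 5, 6)])
    disp <- max(abs(step[c(3, 6)])) +
      max(abs(step[c(1, 2, 4, 5)])) * max(nr, nc)
    if (disp < tol_px) break
  }
  affine2d(W[, 1:2], W[, 3])
}

#' Estimate the pairwise transform between two section images
#'
#' Two-stage intensity-based registration: a rigid stage (phase-correlation
#' translation plus a bounded rotation search scored by normalized
#' cross-correlation) seeds a full-affine Gauss-Newton refinement of the mean
#' squared intensity error. Returns the transform P such that
#' `moving ~ warp_image(fixed, P)`.
#'
#' @param fixed,moving 2D numeric matrices of identical shape.
#' @param model `"affine"` (default, rigid-seeded) or `"rigid"`.
#' @param max_rotation_deg rotation search bound in degrees.
#' @param rotation_step_deg rotation search grid step.
#' @param ncc_floor similarity floor; below it a warning is raised and the
#'   identity transform returned.
#' @param crop_margin optional border width (px) excluded from estimation
#'   (default 0: full frame; exact-zero fill pixels are always excluded).
#' @return an [affine2d()] transform.
#' @export
estimate_pairwise <- function(fixed, moving, model = c("affine", "rigid"),
                              max_rotation_deg = 3, rotation_step_deg = 0.75,
                              ncc_floor = 0.2, crop_margin = NULL) {
  model <- match.arg(model)
  stopifnot(is.matrix(fixed), is.matrix(moving),
            identical(dim(fixed), dim(moving)))
  if (sd(fixed) == 0 || sd(moving) == 0)
    stop("estimate_pairwise: constant image (degenerate input)")
  if (is.null(crop_margin)) crop_margin <- 0L
  full_dim <- dim(fixed)
  m <- as.integer(crop_margin)
  if (2 * m < min(full_dim) - 16) {
    rows <- (m + 1):(full_dim[1] - m); cols <- (m + 1):(full_dim[2] - m)
    fixed <- fixed[rows, cols]; moving <- moving[rows, cols]
  } else m <- 0L
  if (sd(fixed) == 0 || sd(moving) == 0)
    stop("estimate_pairwise: constant image (degenerate input)")
  centre <- (dim(fixed) - 1) / 2

  try_theta <- function(th) {
    Rth <- affine_rigid(th, c(0, 0), centre)
    un <- if (th == 0) list(image = moving, valid = NULL)
          else cpp_warp_affine(moving, unclass(Rth), 0)
    t0 <- .phase_translation(fixed, un$image)
    P <- affine_compose(Rth, affine2d(diag(2), t0))
    w <- cpp_warp_affine(moving, unclass(P), 0)  # re-aligned moving
    list(P = P, score = .ncc(w$image, fixed, w$valid), theta = th)
  }
  thetas <- seq(-max_rotation_deg, max_rotation_deg, by = rotation_step_deg)
  if (!0 %in% thetas) thetas <- sort(c(0, thetas))
  cands <- lapply(thetas, try_theta)
  scores <- vapply(cands, function(x) x$score, 1)
  k <- which.max(scores)
  best <- cands[[k]]
  if (k > 1 && k < length(thetas)) {
    # parabolic sub-grid refinement of the rotation angle
    y0 <- scores[k - 1]; y1 <- scores[k]; y2 <- scores[k + 1]
    den <- y0 - 2 * y1 + y2
    if (abs(den) > 1e-12) {
      th_ref <- thetas[k] + 0.5 * (y0 - y2) / den * rotation_step_deg
      cand <- try_theta(th_ref)
      if (cand$score >= best$score) best <- cand
    }
  }

  P <- best$P
  if (model == "affine") {
    P <- .refine_affine(fixed, moving, P)
    w <- cpp_warp_affine(moving, unclass(P), 0)
    best$score <- .ncc(w$image, fixed, w$valid)
  }
  if (best$score < ncc_floor) {
    warning(sprintf("estimate_pairwise: similarity %.3f below floor %.2f; returning identity",
                    best$score, ncc_floor))
    return(affine_identity())
  }
  if (m > 0) {
    # re-express in full-frame coordinates (crop offset conjugation)
    To <- affine2d(diag(2), c(m, m))
    P <- affine_compose(To, affine_compose(P, affine_invert(To)))
  }
  P
}

#' Align a serial-section stack
#'
#' Pairwise transforms are estimated on one reference channel between each
#' section and its predecessor, composed against a fixed reference section
#' (the middle section, minimizing compounded drift), and the identical
#' per-section correction is applied to every channel. Pixels mapped from
#' outside the frame are filled with 0 and flagged invalid in the stack's
#' validity mask so they are excluded from later density denominators.
#'
#' @param stack a [section_stack()].
#' @param reference_channel channel name driving registration; defaults to
#'   the first channel whose role is `synaptic_post`, else the first channel.
#' @param model passed to [estimate_pairwise()].
#' @return list with `stack` (aligned [section_stack()]) and `transforms`
#'   (per-section correction [affine2d()] list; reference section = identity).
#' @export
align_stack <- function(stack, reference_channel = NULL,
                        model = c("affine", "rigid")) {
  model <- match.arg(model)
  stopifnot(inherits(stack, "section_stack"))
  if (is.null(reference_channel)) {
    roles <- vapply(stack$channels, function(ch) ch$role, "")
    reference_channel <- if (any(roles == "synaptic_post"))
      names(stack$channels)[which(roles == "synaptic_post")[1]]
    else names(stack$channels)[1]
  }
  if (!reference_channel %in% names(stack$channels))
    stop("align_stack: reference channel '", reference_channel, "' not present")
  ref <- stack$channels[[reference_channel]]$intensities
  S <- dim(ref)[3]
  r <- (S + 1L) %/% 2L  # middle section

  pairwise <- vector("list", S)  # P_i maps section i-1 -> section i
  for (i in 2:S) {
    pairwise[[i]] <- tryCatch(
      estimate_pairwise(ref[, , i - 1], ref[, , i], model = model),
      error = function(e) stop("align_stack: pairwise registration failed at section ",
                               i, ": ", conditionMessage(e)))
  }

  corrections <- vector("list", S)
  corrections[[r]] <- affine_identity()
  if (r < S)
    for (i in (r + 1):S)
      corrections[[i]] <- affine_compose(corrections[[i - 1]],
                                         affine_invert(pairwise[[i]]))
  if (r > 1)
    for (i in (r - 1):1)
      corrections[[i]] <- affine_compose(corrections[[i + 1]], pairwise[[i + 1]])

  channels <- lapply(stack$channels, function(ch) ch$intensities)
  valid <- array(TRUE, dim = dim(ref))
  for (i in seq_len(S)) {
    if (max(abs(unclass(corrections[[i]]) - unclass(affine_identity()))) < 1e-12)
      next
    for (nm in names(channels)) {
      w <- warp_image(channels[[nm]][, , i], corrections[[i]], fill = 0)
      channels[[nm]][, , i] <- w$image
      valid[, , i] <- valid[, , i] & w$valid
    }
  }
  out_channels <- lapply(names(channels), function(nm)
    channel_volume(channels[[nm]], stack$channels[[nm]]$role))
  names(out_channels) <- names(channels)
  aligned <- section_stack(out_channels, stack$geometry,
                           alignment_state = "aligned",
                           metadata = stack$metadata, valid_mask = valid)
  list(stack = aligned, transforms = corrections)
}

#' Write per-section transforms to a sidecar text file
#' @param transforms list of [affine2d()] (one per section).
#' @param path output path.
#' @export
write_transforms <- function(transforms, path) {
  mat <- do.call(rbind, lapply(transforms, function(a) as.vector(t(unclass(a)))))
  colnames(mat) <- c("a11", "a12", "t1", "a21", "a22", "t2")
  write.csv(cbind(section = seq_along(transforms), as.data.frame(mat)),
            path, row.names = FALSE)
  invisible(path)
}

#' Read transforms written by [write_transforms()]
#' @param path sidecar path.
#' @export
read_transforms <- function(path) {
  df <- read.csv(path)
  lapply(seq_len(nrow(df)), function(i)
    affine2d(matrix(c(df$a11[i], df$a21[i], df$a12[i], df$a22[i]), 2, 2),
             c(df$t1[i], df$t2[i])))
}
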