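#' Physical voxel geometry of a serial-section stack
#'
#' Array tomography cuts resin-embedded tissue into ultrathin physical
#' sections (70 nm in this workflow), so the axial sampling is fixed by the
#' microtome, not the optics. The in-plane pixel size depends on the
#' acquisition settings and must be supplied.
#'
#' @param pixel_size_xy In-plane pixel size in nm (> 0).
#' @param section_thickness Physical section thickness in nm (> 0, default 70).
#' @return A `voxel_geometry` object.
#' @examples
#' voxel_geometry(100)
#' @export
voxel_geometry <- function(pixel_size_xy, section_thickness = 70) {
  stopifnot(is.numeric(pixel_size_xy), length(pixel_size_xy) == 1,
            is.finite(pixel_size_xy), pixel_size_xy > 0,
            is.numeric(section_thickness), length(section_thickness) == 1,
            is.finite(section_thickness), section_thickness > 0)
  structure(list(pixel_size_xy = pixel_size_xy,
                 section_thickness = section_thickness),
            class = "voxel_geometry")
}

#' @export
print.voxel_geometry <- function(x, ...) {
  cat(sprintf("voxel geometry: %g nm/px in-plane, %g nm sections\n",
              x$pixel_size_xy, x$section_thickness))
  invisible(x)
}

# voxel volume in mm^3 (1 nm = 1e-6 mm)
voxel_volume_mm3 <- function(geometry) {
  (geometry$pixel_size_xy * 1e-6)^2 * (geometry$section_thickness * 1e-6)
}

# ---- 2D affine transforms --------------------------------------------------
# Convention: 2x3 matrix A acting on 0-based (row, col) coordinates,
#   (row', col')^T = A[,1:2] %*% (row, col)^T + A[,3]
# mapping points of the *moving* frame into the *fixed* frame.

#' Build a 2D affine transform
#'
#' @param linear 2x2 linear part (must be invertible).
#' @param translation length-2 translation (row, col) in pixels.
#' @return A 2x3 matrix of class `affine2d`.
#' @export
affine2d <- function(linear = diag(2), translation = c(0, 0)) {
  linear <- matrix(as.numeric(linear), 2, 2)
  if (abs(det(linear)) < 1e-12)
    stop("affine2d: linear part is singular")
  structure(cbind(linear, as.numeric(translation)), class = c("affine2d", "matrix"))
}

#' @rdname affine2d
#' @export
affine_identity <- function() affine2d()

#' Rigid (rotation + translation) transform about a centre point
#'
#' @param angle_deg rotation angle in degrees (positive = row axis towards
#'   column axis).
#' @param translation length-2 (row, col) shift in pixels.
#' @param centre length-2 centre of rotation, 0-based (row, col).
#' @export
affine_rigid <- function(angle_deg = 0, translation = c(0, 0), centre = c(0, 0)) {
  th <- angle_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  t0 <- as.numeric(centre) - R %*% as.numeric(centre) + as.numeric(translation)
  affine2d(R, t0)
}

#' Compose two affine transforms (apply `b` first, then `a`)
#' @param a,b `affine2d` transforms.
#' @export
affine_compose <- function(a, b) {
  A <- a[, 1:2, drop = FALSE] %*% b[, 1:2, drop = FALSE]
  t0 <- a[, 1:2, drop = FALSE] %*% b[, 3] + a[, 3]
  affine2d(A, t0)
}

#' Invert an affine transform
#' @param a an `affine2d` transform.
#' @export
affine_invert <- function(a) {
  Ai <- solve(a[, 1:2, drop = FALSE])
  affine2d(Ai, -Ai %*% a[, 3])
}

#' Apply an affine transform to 0-based (row, col) points
#' @param a an `affine2d` transform.
#' @param pts n x 2 matrix of (row, col) points.
#' @export
affine_apply <- function(a, pts) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  t(a[, 1:2, drop = FALSE] %*% t(pts) + a[, 3])
}

#' Mean corner displacement between two transforms
#'
#' The standard registration-accuracy summary: the four frame corners are
#' pushed through both transforms and the mean Euclidean distance between the
#' two images of the corners (in pixels) is returned.
#'
#' @param a,b `affine2d` transforms to compare.
#' @param shape frame size `c(H, W)` in pixels.
#' @export
mean_corner_displacement <- function(a, b, shape) {
  H <- shape[1]; W <- shape[2]
  corners <- rbind(c(0, 0), c(0, W - 1), c(H - 1, 0), c(H - 1, W - 1))
  d <- affine_apply(a, corners) - affine_apply(b, corners)
  mean(sqrt(rowSums(d^2)))
}

# Warp a 2D image by an affine transform (moving -> fixed convention):
# output pixel q samples the input at A^{-1}(q). Returns image + validity mask.
warp_image <- function(img, transform, fill = 0) {
  inv <- affine_invert(transform)
  res <- cpp_warp_affine(img, unclass(inv), fill)
  res
}
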