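#' Overlap fraction of a partner object with a synaptic object
#'
#' The denominator is always the synaptic object, following the rule that
#' colocalization requires a minimum overlap of 10% of the synaptic
#' terminal's area: `|voxels(synapse) n voxels(partner)| / |voxels(synapse)|`.
#' Computed on the full 3D voxel sets of both objects.
#'
#' @param synapse,partner `object3d` objects from the same aligned stack.
#' @return fraction in `[0, 1]`.
#' @export
overlap_fraction <- function(synapse, partner) {
  vs <- synapse$voxels
  if (is.null(vs) || nrow(vs) == 0)
    stop("overlap_fraction: empty synapse voxel set")
  vp <- partner$voxels
  ks <- paste(vs$section, vs$row, vs$col)
  kp <- paste(vp$section, vp$row, vp$col)
  sum(ks %in% kp) / nrow(vs)
}

#' Colocalize synaptic objects with candidate partners
#'
#' A synapse counts as colocalized (once) if any partner object overlaps at
#' least `min_fraction` of the synapse's voxels. Implemented on label
#' volumes, so cost scales with total voxels rather than object pairs.
#'
#' @param synapses,partners lists of `object3d` from the same stack.
#' @param dims volume dimensions c(H, W, S).
#' @param min_fraction minimum synapse-overlap fraction (default 0.10).
#' @return list with `pairs` (data frame synapse_id, partner_id, fraction;
#'   all pairs meeting the threshold), `colocalized` (logical per synapse)
#'   and `percent` (100 x colocalized / total synapses).
#' @export
colocalize <- function(synapses, partners, dims, min_fraction = 0.10) {
  if (length(synapses) == 0)
    stop("colocalize: no synaptic objects; percent undefined")
  partner_lab <- label_volume(partners, dims)
  pairs <- data.frame(synapse_id = integer(), partner_id = integer(),
                      fraction = numeric())
  colocalized <- logical(length(synapses))
  for (i in seq_along(synapses)) {
    v <- synapses[[i]]$voxels
    pl <- partner_lab[cbind(v$row, v$col, v$section)]
    hits <- pl[pl > 0]
    if (length(hits)) {
      counts <- table(hits)
      frac <- as.numeric(counts) / nrow(v)
      ok <- frac >= min_fraction
      if (any(ok)) {
        colocalized[i] <- TRUE
        pairs <- rbind(pairs, data.frame(
          synapse_id = synapses[[i]]$id,
          partner_id = as.integer(names(counts))[ok],
          fraction = frac[ok]))
      }
    }
  }
  list(pairs = pairs, colocalized = colocalized,
       percent = 100 * mean(colocalized))
}

#' Segment the plaque core and edge from the amyloid channel
#'
#' Restrictive segmentation: a high global threshold (`threshold_factor`
#' times the channel mean) keeps only bright contiguous staining; the largest
#' 3D-connected component is retained as the plaque core if its largest
#' single-section area exceeds `min_core_area_um2`, which excludes the small
#' amyloid puncta of the halo. The edge is the in-plane morphological
#' boundary of the core.
#'
#' @param abeta_channel a [channel_volume()] or array (aligned).
#' @param geometry a [voxel_geometry()].
#' @param threshold_factor multiple of the global channel mean (default 3).
#' @param min_core_area_um2 minimum single-section core area (default 25).
#' @return a `plaque_model`: list(present, core_voxels, edge_voxels) with
#'   voxel data frames (section, row, col).
#' @export
segment_plaque <- function(abeta_channel, geometry, threshold_factor = 3,
                           min_core_area_um2 = 25) {
  arr <- if (inherits(abeta_channel, "channel_volume")) abeta_channel$intensities
         else abeta_channel
  thr <- threshold_factor * mean(arr)
  mask <- arr > thr
  empty <- structure(list(present = FALSE,
                          core_voxels = data.frame(), edge_voxels = data.frame()),
                     class = "plaque_model")
  if (!any(mask)) return(empty)
  # 3D components: in-plane 8-connectivity + same-pixel linking across sections
  objs <- link_objects(mask, geometry,
                       segmentation_params(min_area_px = 1,
                                           linking_min_overlap_px = 1),
                       channel_role = "other")
  if (!length(objs)) return(empty)
  sizes <- vapply(objs, function(o) nrow(o$voxels), 1)
  core <- objs[[which.max(sizes)]]
  px_um2 <- (geometry$pixel_size_xy / 1000)^2
  max_area <- max(core$per_section_area) * px_um2
  if (max_area < min_core_area_um2) return(empty)

  cv <- core$voxels
  dims <- dim(arr)
  core_arr <- array(FALSE, dims)
  core_arr[cbind(cv$row, cv$col, cv$section)] <- TRUE
  # in-plane 4-neighbour boundary
  edge <- array(FALSE, dims)
  H <- dims[1]; W <- dims[2]
  for (s in unique(cv$section)) {
    m <- core_arr[, , s]
    interior <- m
    interior[2:(H - 1), 2:(W - 1)] <-
      m[2:(H - 1), 2:(W - 1)] & m[1:(H - 2), 2:(W - 1)] & m[3:H, 2:(W - 1)] &
      m[2:(H - 1), 1:(W - 2)] & m[2:(H - 1), 3:W]
    edge[, , s] <- m & !interior
  }
  ev <- which(edge, arr.ind = TRUE)
  structure(list(present = TRUE,
                 core_voxels = cv,
                 edge_voxels = data.frame(section = ev[, 3], row = ev[, 1],
                                          col = ev[, 2])),
            class = "plaque_model")
}

#' @export
print.plaque_model <- function(x, ...) {
  if (!x$present) cat("plaque_model: no plaque detected\n")
  else cat(sprintf("plaque_model: core %d voxels, edge %d voxels\n",
                   nrow(x$core_voxels), nrow(x$edge_voxels)))
  invisible(x)
}

#' Distance from an object centroid to the plaque edge
#'
#' Minimum anisotropic 3D Euclidean distance (physical units) between the
#' object's centroid and any plaque-edge voxel centre; centroids inside the
#' plaque core get distance 0.
#'
#' @param object an `object3d`.
#' @param plaque a `plaque_model` with `present = TRUE`.
#' @param geometry a [voxel_geometry()].
#' @return distance in um.
#' @export
distance_to_plaque <- function(object, plaque, geometry) {
  if (!isTRUE(plaque$present))
    stop("distance_to_plaque: no plaque present; distance profile not applicable")
  px <- geometry$pixel_size_xy; th <- geometry$section_thickness
  cen <- object$centroid_nm
  cv <- plaque$core_voxels
  # centroid voxel inside the core?
  vr <- round(cen["y"] / px) + 1; vc <- round(cen["x"] / px) + 1
  vs <- round(cen["z"] / th) + 1
  if (nrow(cv) && any(cv$row == vr & cv$col == vc & cv$section == vs))
    return(0)
  ev <- plaque$edge_voxels
  d2 <- ((ev$col - 1) * px - cen["x"])^2 + ((ev$row - 1) * px - cen["y"])^2 +
    ((ev$section - 1) * th - cen["z"])^2
  sqrt(min(d2)) / 1000
}

#' Distance-binned density profile around the plaque
#'
#' Objects are binned by the distance of their centroid from the plaque edge
#' in 10 um bins (`[0,10), [10,20), ..., [50, Inf)`, the last bin serving as
#' the far-field reference). Each bin's density divides its object count by
#' its own neuropil volume: the valid voxels whose distance to the edge falls
#' in the bin (plaque-core voxels are excluded from the neuropil). Empty-bin
#' densities are reported as NA, not zero.
#'
#' @param objects list of `object3d`.
#' @param plaque a `plaque_model` with `present = TRUE`.
#' @param stack the [section_stack()] (for geometry and validity mask).
#' @param valid_mask optional logical volume overriding the stack's mask.
#' @return data frame: bin_lo, bin_hi, count, volume_mm3, density.
#' @export
distance_profile <- function(objects, plaque, stack, valid_mask = NULL) {
  if (!isTRUE(plaque$present))
    stop("distance_profile: no plaque present")
  if (is.null(valid_mask)) valid_mask <- stack$valid_mask
  g <- stack$geometry
  dims <- dim(valid_mask)
  seed <- array(FALSE, dims)
  ev <- plaque$edge_voxels
  seed[cbind(ev$row, ev$col, ev$section)] <- TRUE
  dist_um <- cpp_edt3d(seed, dims,
                       c(g$pixel_size_xy, g$pixel_size_xy,
                         g$section_thickness)) / 1000
  cv <- plaque$core_voxels
  core <- array(FALSE, dims)
  if (nrow(cv)) core[cbind(cv$row, cv$col, cv$section)] <- TRUE

  edges <- c(0, 10, 20, 30, 40, 50, Inf)
  d_obj <- vapply(objects, distance_to_plaque, 1, plaque = plaque, geometry = g)
  usable <- valid_mask & !core
  counts <- volumes <- numeric(length(edges) - 1)
  for (b in seq_len(length(edges) - 1)) {
    counts[b] <- sum(d_obj >= edges[b] & d_obj < edges[b + 1])
    volumes[b] <- sum(usable & dist_um >= edges[b] & dist_um < edges[b + 1]) *
      voxel_volume_mm3(g)
  }
  data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
             count = counts, volume_mm3 = volumes,
             density = ifelse(volumes > 0, counts / volumes, NA_real_))
}
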