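# Independent oracles, deliberately naive: these re-derive expected results
# from first principles and never call the implementation paths they check.

# Flood-fill 2D labelling (8-connectivity) by breadth-first search.
oracle_label2d <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (c0 in seq_len(nc)) for (r0 in seq_len(nr)) {
    if (!mask[r0, c0] || lab[r0, c0] > 0) next
    cur <- cur + 1L
    queue <- list(c(r0, c0))
    lab[r0, c0] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        rr <- p[1] + dr; cc <- p[2] + dc
        if (rr < 1 || cc < 1 || rr > nr || cc > nc) next
        if (mask[rr, cc] && lab[rr, cc] == 0) {
          lab[rr, cc] <- cur
          queue[[length(queue) + 1]] <- c(rr, cc)
        }
      }
    }
  }
  lab
}

# Exhaustive union-find 3D linking oracle: per-section 8-connected
# components merged when >= min_overlap pixels coincide across consecutive
# sections. Returns the number of 3D objects and their spans.
oracle_link3d <- function(mask, min_overlap = 1) {
  S <- dim(mask)[3]
  labs <- lapply(seq_len(S), function(s) oracle_label2d(mask[, , s]))
  counts <- vapply(labs, max, 1L)
  offsets <- cumsum(c(0L, counts))[seq_len(S)]
  total <- sum(counts)
  if (total == 0) return(list(n = 0L, spans = integer(0)))
  parent <- seq_len(total)
  findp <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (s in seq_len(S - 1)) {
    a <- labs[[s]]; b <- labs[[s + 1]]
    for (la in seq_len(max(a))) for (lb in seq_len(max(b))) {
      if (sum(a == la & b == lb) >= min_overlap) {
        ra <- findp(la + offsets[s]); rb <- findp(lb + offsets[s + 1])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  root <- vapply(seq_len(total), findp, 1L)
  sections <- unlist(lapply(seq_len(S), function(s)
    rep(s, counts[s])))
  spans <- vapply(split(sections, root), function(sec) length(unique(sec)), 1L)
  list(n = length(unique(root)), spans = unname(spans))
}

# Direct local-mean computation for tiny images (definition, no integral
# image).
oracle_box_mean <- function(img, w) {
  h <- (w - 1) / 2
  out <- img * 0
  for (r in seq_len(nrow(img))) for (c in seq_len(ncol(img))) {
    rr <- max(1, r - h):min(nrow(img), r + h)
    cc <- max(1, c - h):min(ncol(img), c + h)
    out[r, c] <- mean(img[rr, cc])
  }
  out
}

# Brute-force centroid-to-edge distance straight from the definition.
oracle_distance_um <- function(centroid_nm, edge_voxels, geometry) {
  px <- geometry$pixel_size_xy; th <- geometry$section_thickness
  d <- sqrt(((edge_voxels$col - 1) * px - centroid_nm[["x"]])^2 +
            ((edge_voxels$row - 1) * px - centroid_nm[["y"]])^2 +
            ((edge_voxels$section - 1) * th - centroid_nm[["z"]])^2)
  min(d) / 1000
}

# Shared small configs ------------------------------------------------------

fast_cfg <- function(seed, ...) {
  args <- modifyList(list(n_sections = 6, frame_size = c(160, 160),
                          n_synapses = 40, n_distractors = 8,
                          single_section_noise_objects = 8, seed = seed),
                     list(...))
  do.call(sim_config, args)
}

noise_off <- list(gaussian_sd = 0, poisson_scale = 0)
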