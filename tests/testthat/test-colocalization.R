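mk_obj <- function(id, vox) {
  structure(list(id = id, channel_role = "other", voxels = vox,
                 span = length(unique(vox$section))),
            class = "object3d")
}

test_that("overlap_fraction uses the synaptic denominator", {
  syn <- mk_obj(1, data.frame(section = 1, row = rep(1:5, 8), col = rep(1:8, each = 5)))
  expect_equal(nrow(syn$voxels), 40)
  # disjoint
  far <- mk_obj(2, data.frame(section = 1, row = 20, col = 20))
  expect_equal(overlap_fraction(syn, far), 0)
  # superset
  sup <- mk_obj(3, data.frame(section = rep(1, 100),
                              row = rep(1:10, 10), col = rep(1:10, each = 10)))
  expect_equal(overlap_fraction(syn, sup), 1)
  # 6 of 40 voxels -> 0.15; asymmetric by construction
  six <- mk_obj(4, syn$voxels[1:6, ])
  expect_equal(overlap_fraction(syn, six), 0.15)
  expect_equal(overlap_fraction(six, syn), 1)
  expect_error(overlap_fraction(mk_obj(5, data.frame()[0, ]), syn), "empty")
})

test_that("colocalize counts each synapse once and is monotone in the threshold", {
  dims <- c(30, 30, 3)
  syn1 <- mk_obj(1, data.frame(section = 1, row = rep(2:5, 4), col = rep(2:5, each = 4)))
  syn2 <- mk_obj(2, data.frame(section = 2, row = rep(12:15, 4), col = rep(12:15, each = 4)))
  # partner overlapping 2/16 = 12.5% of syn1; two partners on syn2
  p1 <- mk_obj(1, data.frame(section = 1, row = 2:3, col = 2))
  p2 <- mk_obj(2, data.frame(section = 2, row = 12:15, col = 12))
  p3 <- mk_obj(3, data.frame(section = 2, row = 12:13, col = 13))
  res <- colocalize(list(syn1, syn2), list(p1, p2, p3), dims, min_fraction = 0.10)
  expect_equal(res$percent, 100)
  expect_equal(sum(res$pairs$synapse_id == 2), 2)  # both partners listed
  expect_equal(res$pairs$fraction[res$pairs$synapse_id == 1], 2 / 16)

  # min_fraction = 0 admits any voxel overlap; raising it never raises percent
  percents <- vapply(c(0, 0.1, 0.2, 0.3), function(f)
    colocalize(list(syn1, syn2), list(p1, p2, p3), dims, f)$percent, 1)
  expect_true(all(diff(percents) <= 0))
  expect_equal(percents[1], 100)
  expect_error(colocalize(list(), list(p1), dims), "percent undefined")
})

test_that("colocalization fraction is recovered from synthetic studies", {
  # donor present exactly in the colocalized synapses (marginal = coloc)
  recovered <- vapply(c(411, 412, 413), function(seed) {
    cfg <- fast_cfg(seed = seed, n_synapses = 120,
                    frame_size = c(256, 256),
                    frac_donor_in_synapse = 0.3, frac_acceptor_in_synapse = 0.3,
                    frac_coloc = 0.3)
    gen <- generate_stack(cfg)
    p <- segmentation_params()
    st <- gen$stack
    syn <- persistence_filter(link_objects(
      local_threshold(st$channels$synaptic, p), st$geometry, p))
    don <- persistence_filter(link_objects(
      local_threshold(st$channels$donor, p), st$geometry, p))
    colocalize(syn, don, c(frame_shape(st), n_sections(st)))$percent
  }, 1)
  expect_lt(abs(mean(recovered) - 30), 3)
})

test_that("segment_plaque isolates the contiguous core and its edge", {
  g <- voxel_geometry(100)
  # no suprathreshold component
  flat <- array(100, c(64, 64, 3))
  expect_false(segment_plaque(flat, g)$present)

  cfg <- fast_cfg(seed = 414, frame_size = c(256, 256), n_synapses = 60,
                  plaque = list(present = TRUE, radius_um = 5,
                                gradient_slope = 1, n_halo_puncta = 10))
  gen <- generate_stack(cfg)
  pl <- segment_plaque(gen$stack$channels$donor, gen$stack$geometry)
  expect_true(pl$present)
  expect_gt(nrow(pl$edge_voxels), 0)
  # per-section core area within 15% of the rendered disk
  est_area <- max(table(pl$core_voxels$section))
  expect_lt(abs(est_area - gen$truth$plaque$core_area_px) /
            gen$truth$plaque$core_area_px, 0.15)
  # halo puncta are excluded: core is one contiguous in-plane region whose
  # extent stays near the disk radius
  ctr <- gen$truth$plaque$centre
  d_px <- sqrt((pl$core_voxels$row - ctr[1])^2 + (pl$core_voxels$col - ctr[2])^2)
  expect_lt(max(d_px), gen$truth$plaque$radius_px + 3)
})

test_that("distance_to_plaque equals the brute-force edge minimum", {
  g <- voxel_geometry(100, 70)
  edge <- data.frame(section = c(1, 2, 3), row = c(5, 10, 15), col = c(5, 10, 15))
  pl <- structure(list(present = TRUE, core_voxels = data.frame(),
                       edge_voxels = edge), class = "plaque_model")
  set.seed(415)
  for (i in 1:20) {
    o <- structure(list(centroid_nm = c(x = runif(1, 0, 2000),
                                        y = runif(1, 0, 2000),
                                        z = runif(1, 0, 140))),
                   class = "object3d")
    expect_equal(distance_to_plaque(o, pl, g),
                 oracle_distance_um(o$centroid_nm, edge, g))
  }
  # centroid on an edge voxel -> 0
  on_edge <- structure(list(centroid_nm = c(x = 400, y = 400, z = 0)),
                       class = "object3d")
  expect_equal(distance_to_plaque(on_edge, pl, g), 0)
  # 10 um straight-line in-plane from a single edge voxel
  pl1 <- structure(list(present = TRUE, core_voxels = data.frame(),
                        edge_voxels = edge[1, ]), class = "plaque_model")
  far <- structure(list(centroid_nm = c(x = 400 + 10000, y = 400, z = 0)),
                   class = "object3d")
  expect_equal(distance_to_plaque(far, pl1, g), 10)
  expect_error(distance_to_plaque(far, structure(list(present = FALSE),
                                                 class = "plaque_model"), g),
               "not applicable")
})

test_that("distance profiles recover flatness and gradients", {
  p <- segmentation_params()
  run_profile <- function(seed, slope) {
    cfg <- fast_cfg(seed = seed, frame_size = c(384, 384), n_sections = 5,
                    n_synapses = 180, n_distractors = 6,
                    plaque = list(present = TRUE, radius_um = 4,
                                  gradient_slope = slope))
    gen <- generate_stack(cfg)
    st <- gen$stack
    pl <- segment_plaque(st$channels$donor, st$geometry)
    syn <- persistence_filter(link_objects(
      local_threshold(st$channels$synaptic, p), st$geometry, p))
    # mask off the placement margin so bin volumes match the seeded region
    m <- gen$truth$placement_margin_px
    valid <- array(FALSE, dim(st$valid_mask))
    valid[(m + 1):(384 - m), (m + 1):(384 - m), ] <- TRUE
    list(profile = distance_profile(syn, pl, st, valid), truth = gen$truth)
  }

  # flat simulation: populated bins agree within sampling error
  fl <- run_profile(416, 1)$profile
  dens <- fl$density[fl$count > 5]
  expect_gte(length(dens), 2)
  expect_lt(max(dens) / min(dens), 1.5)
  # counts sum to all objects profiled
  expect_equal(sum(fl$count), 180)

  # imposed gradient: density increases away from the plaque (slope > 1)
  gr <- run_profile(417, 2.2)$profile
  dens_g <- gr$density[1:3]
  expect_gte(length(dens_g[!is.na(dens_g)]), 2)
  expect_true(dens_g[1] < dens_g[2])

  # empty bins report NA density, not zero
  expect_true(all(is.na(fl$density[fl$volume_mm3 == 0])))
})

test_that("all-distant objects fall in the far-field reference bin", {
  g <- voxel_geometry(100, 70)
  dims <- c(700, 700, 2)
  ch <- list(x = channel_volume(array(0, dims), "other"))
  st <- section_stack(ch, g)
  edge <- data.frame(section = 1, row = 5, col = 5)
  pl <- structure(list(present = TRUE, core_voxels = data.frame(),
                       edge_voxels = edge), class = "plaque_model")
  objs <- list(structure(list(centroid_nm = c(x = 60000, y = 60000, z = 0),
                              voxels = data.frame(section = 1, row = 600,
                                                  col = 600)),
                         class = "object3d"))
  prof <- distance_profile(objs, pl, st)
  expect_equal(prof$count, c(0, 0, 0, 0, 0, 1))
})
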