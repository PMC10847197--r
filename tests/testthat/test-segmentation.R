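test_that("local_threshold follows the local-mean rule exactly", {
  p <- segmentation_params(local_window = 5, threshold_offset = 1)
  # constant image: nothing exceeds its own mean by a positive offset
  expect_false(any(local_threshold(array(7, c(20, 20, 2)), p)))

  # single bright 3x3 square on zero background: exactly that square
  img <- array(0, c(21, 21, 2))
  img[10:12, 10:12, 1] <- 100
  mask <- local_threshold(img, p)
  expected <- array(FALSE, dim(img))
  expected[10:12, 10:12, 1] <- TRUE
  expect_identical(mask, expected)

  # agreement with the direct windowed-mean definition on a random image
  set.seed(401)
  ri <- matrix(runif(15 * 17, 0, 100), 15, 17)
  got <- atfret:::.box_mean(ri, 5)
  expect_equal(got, oracle_box_mean(ri, 5))

  expect_error(local_threshold(array(1, c(8, 8, 2)),
                               segmentation_params(local_window = 9)),
               "window larger")
  # exclusion mask forces background
  excl <- array(FALSE, dim(img)); excl[10, 10, 1] <- TRUE
  p2 <- segmentation_params(local_window = 5, threshold_offset = 1,
                            exclusion_mask = excl)
  m2 <- local_threshold(img, p2)
  expect_false(m2[10, 10, 1])
  expect_true(m2[11, 11, 1])
})

test_that("threshold monotonicity: larger offsets never add foreground", {
  set.seed(402)
  img <- array(runif(32 * 32 * 4, 0, 100), c(32, 32, 4))
  offs <- c(0.1, 0.3, 0.6, 1, 1.5)
  counts <- vapply(offs, function(o) {
    sum(local_threshold(img, segmentation_params(threshold_offset = o,
                                                 local_window = 9)))
  }, 1)
  expect_true(all(diff(counts) <= 0))
})

test_that("link_objects agrees with the exhaustive union-find oracle", {
  g <- voxel_geometry(100)
  # empty mask
  expect_equal(length(link_objects(array(FALSE, c(8, 8, 3)), g)), 0)

  # two components overlapping across sections 3-4 merge into span 2
  m <- array(FALSE, c(10, 10, 5))
  m[3:5, 3:5, 3] <- TRUE
  m[4:6, 4:6, 4] <- TRUE
  objs <- link_objects(m, g, segmentation_params(min_area_px = 1))
  expect_equal(length(objs), 1)
  expect_equal(objs[[1]]$span, 2)

  # random volumes vs oracle, both overlap thresholds
  set.seed(403)
  for (rep in 1:3) {
    vol <- array(runif(48 * 48 * 5) < 0.18, c(48, 48, 5))
    for (k in c(1, 3)) {
      p <- segmentation_params(min_area_px = 1, linking_min_overlap_px = k)
      got <- link_objects(vol, g, p)
      want <- oracle_link3d(vol, min_overlap = k)
      expect_equal(length(got), want$n)
      expect_equal(sort(vapply(got, function(o) o$span, 1)), sort(want$spans))
    }
  }
})

test_that("object3d geometry fields are consistent", {
  g <- voxel_geometry(100, 70)
  m <- array(FALSE, c(12, 12, 4))
  m[4:6, 4:6, 2] <- TRUE
  m[4:6, 4:6, 3] <- TRUE
  o <- link_objects(m, g, segmentation_params(min_area_px = 1))[[1]]
  expect_equal(nrow(o$voxels), 18)
  expect_equal(o$volume_nm3, 18 * 100^2 * 70)
  expect_equal(o$per_section_area, c(3L * 3L, 3L * 3L))
  # centroid: mean of voxel centres, x = col axis, z = section axis
  expect_equal(unname(o$centroid_nm["x"]), mean(3:5) * 100)
  expect_equal(unname(o$centroid_nm["z"]), mean(1:2) * 70)
})

test_that("persistence_filter keeps exactly the multi-section objects", {
  g <- voxel_geometry(100)
  m <- array(FALSE, c(20, 20, 4))
  m[2:3, 2:3, 1] <- TRUE                      # span 1
  m[8:9, 8:9, 2] <- TRUE; m[8:9, 8:9, 3] <- TRUE  # span 2
  m[14:15, 14:15, 1:3] <- TRUE                # span 3
  objs <- link_objects(m, g, segmentation_params(min_area_px = 1))
  kept <- persistence_filter(objs)
  expect_setequal(vapply(kept, function(o) o$span, 1), c(2, 3))
  # all spans 1 -> empty
  m1 <- array(FALSE, c(10, 10, 3)); m1[2:3, 2:3, 2] <- TRUE
  expect_equal(length(persistence_filter(
    link_objects(m1, g, segmentation_params(min_area_px = 1)))), 0)
  # idempotent and subset-preserving
  expect_identical(persistence_filter(kept), kept)
  expect_true(all(vapply(kept, function(o) o$id, 1) %in%
                  vapply(objs, function(o) o$id, 1)))
})

test_that("density follows the voxel-geometry arithmetic", {
  g <- voxel_geometry(100, 70)
  ch <- list(x = channel_volume(array(0, c(100, 100, 10)), "other"))
  st <- section_stack(ch, g)
  one <- list(structure(list(id = 1L, voxels = data.frame(section = 1, row = 1,
                                                          col = 1)),
                        class = "object3d"))
  # 1 object / (1e5 voxels x 100^2 x 70 nm^3) = 1 / 7e-8 mm^3
  expect_equal(object_density(one, st), 1 / 7e-8, tolerance = 1e-12)
  # halving the valid volume doubles the density
  half <- st$valid_mask; half[, , 6:10] <- FALSE
  expect_equal(object_density(one, st, half), 2 / 7e-8, tolerance = 1e-12)
  expect_error(object_density(one, st, st$valid_mask & FALSE), "zero valid")
})

test_that("object counts recover within 10% at the default noise level", {
  errs <- vapply(c(405, 406, 407), function(seed) {
    cfg <- fast_cfg(seed = seed, n_synapses = 50)
    gen <- generate_stack(cfg)
    p <- segmentation_params()
    objs <- link_objects(local_threshold(gen$stack$channels$synaptic, p),
                         gen$stack$geometry, p)
    kept <- persistence_filter(objs)
    # the single-section noise objects are all rejected
    expect_gte(length(objs) - length(kept), nrow(gen$truth$noise_objects))
    abs(length(kept) - 50) / 50
  }, 1)
  expect_true(all(errs <= 0.10))
})
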