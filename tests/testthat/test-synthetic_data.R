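test_that("generation is deterministic under a fixed seed", {
  cfg <- fast_cfg(seed = 301)
  a <- generate_stack(cfg)
  b <- generate_stack(cfg)
  for (nm in names(a$stack$channels))
    expect_identical(a$stack$channels[[nm]]$intensities,
                     b$stack$channels[[nm]]$intensities)
  expect_identical(a$truth$objects, b$truth$objects)
  c2 <- generate_calibration_stacks(cfg)
  d2 <- generate_calibration_stacks(cfg)
  expect_identical(c2$donor_only$channels$fret_raw$intensities,
                   d2$donor_only$channels$fret_raw$intensities)
})

test_that("degenerate configurations produce the forced outputs", {
  # no synapses: empty truth, channels are pure noise around background
  cfg0 <- fast_cfg(seed = 302, n_synapses = 0, n_distractors = 0,
                   single_section_noise_objects = 0)
  gen0 <- generate_stack(cfg0)
  expect_equal(nrow(gen0$truth$objects), 0)
  syn <- gen0$stack$channels$synaptic$intensities
  expect_equal(mean(syn), cfg0$background, tolerance = 0.05)

  # noise off, E = 0: fret_raw is exactly beta*donor + gamma*acceptor
  cfg1 <- fast_cfg(seed = 303, fret_efficiency = 0, noise = noise_off)
  gen1 <- generate_stack(cfg1)
  ch <- gen1$stack$channels
  expect_equal(ch$fret_raw$intensities,
               0.2 * ch$donor$intensities + 0.1 * ch$acceptor$intensities,
               tolerance = 1e-12)

  # infeasible packing is a config error
  expect_error(generate_stack(fast_cfg(seed = 304, frame_size = c(64, 64),
                                       n_synapses = 500)),
               "infeasible packing")
  # invalid fractions rejected up front
  expect_error(sim_config(frac_coloc = 0.5, frac_donor_in_synapse = 0.2),
               "frac_coloc")
})

test_that("ground truth matches the rendered placements", {
  cfg <- fast_cfg(seed = 305, n_synapses = 40)
  gen <- generate_stack(cfg)
  obj <- gen$truth$objects
  expect_equal(sum(obj$channel == "synaptic_post"), 40)
  expect_true(all(obj$span >= 2))
  expect_equal(obj$span, obj$s1 - obj$s0 + 1)
  # single-section noise objects are recorded separately, never as objects
  expect_equal(nrow(gen$truth$noise_objects), 8)
  # every truth object has voxels spanning exactly its section range
  for (i in sample(nrow(obj), 10)) {
    v <- gen$truth$voxels[[i]]
    expect_setequal(unique(v$section), obj$s0[i]:obj$s1[i])
  }
})

test_that("truth-consistency: segmenting the clean render recovers every synapse", {
  # noise off but the background pedestal kept: without it the local mean
  # vanishes far from puncta and the renderer's 3-sigma tails fragment.
  # The frozen offset for this clean scene is 0.3 - high enough to separate
  # neighbouring puncta, low enough that a bright neighbour inside the local
  # window cannot push the threshold past another object's half-max shell
  cfg <- fast_cfg(seed = 306, noise = noise_off, n_distractors = 0)
  gen <- generate_stack(cfg)
  p <- segmentation_params(threshold_offset = 0.3)
  objs <- persistence_filter(link_objects(
    local_threshold(gen$stack$channels$synaptic, p), gen$stack$geometry, p))
  expect_equal(length(objs), cfg$n_synapses)
  # the threshold mask contains every truth voxel strictly above half-max
  # (boundary voxels sit exactly at half-max and may fall either side)
  mask <- local_threshold(gen$stack$channels$synaptic, p)
  clean <- gen$stack$channels$synaptic$intensities
  obj <- gen$truth$objects
  syn_ids <- which(obj$channel == "synaptic_post")
  covered <- vapply(syn_ids, function(i) {
    v <- gen$truth$voxels[[i]]
    idx <- cbind(v$row, v$col, v$section)
    above <- clean[idx] > cfg$background + obj$amplitude[i] / 2 + 1e-9
    if (!any(above)) return(1)
    mean(mask[idx][above])
  }, 1)
  expect_true(all(covered == 1))
})

test_that("calibration stacks obey their construction", {
  # noise off: fret_raw / donor == beta everywhere the donor is positive
  cfg <- fast_cfg(seed = 307, noise = noise_off)
  cal <- generate_calibration_stacks(cfg)
  don <- cal$donor_only$channels$donor$intensities
  fr <- cal$donor_only$channels$fret_raw$intensities
  expect_equal(fr[don > 0] / don[don > 0], rep(0.2, sum(don > 0)),
               tolerance = 1e-12)
  expect_null(cal$donor_only$channels$acceptor)

  # beta_true = 0: donor-only fret channel is pure noise (mean ~ 0)
  cfg0 <- fast_cfg(seed = 308, beta_true = 0,
                   noise = list(gaussian_sd = 3, poisson_scale = 0))
  cal0 <- generate_calibration_stacks(cfg0)
  expect_lt(mean(cal0$donor_only$channels$fret_raw$intensities), 3)
})

test_that("perturb_sections records exactly the transforms it applies", {
  cfg <- fast_cfg(seed = 309)
  gen <- generate_stack(cfg)

  # zero-magnitude misalignment: output identical to input
  cfg_zero <- fast_cfg(seed = 309, misalignment = list(
    max_translation_px = 0, max_rotation_deg = 0, max_shear = 0))
  pz <- perturb_sections(gen$stack, cfg_zero)
  expect_identical(pz$channels$synaptic$intensities,
                   gen$stack$channels$synaptic$intensities)
  for (tr in section_transforms(pz))
    expect_equal(unclass(tr), unclass(affine_identity()))

  # recorded transforms equal applied: re-applying them to the clean stack
  # reproduces the perturbed stack bit-for-bit
  pert <- perturb_sections(gen$stack, cfg)
  tr <- section_transforms(pert)
  redo <- gen$stack$channels$donor$intensities
  for (i in seq_len(n_sections(gen$stack)))
    redo[, , i] <- atfret:::warp_image(redo[, , i], tr[[i]])$image
  expect_identical(redo, pert$channels$donor$intensities)

  # a pure translation moves the cross-correlation peak accordingly
  sec <- gen$stack$channels$synaptic$intensities[, , 3]
  shifted <- atfret:::warp_image(sec, affine2d(diag(2), c(3, -2)))$image
  expect_equal(atfret:::.phase_translation(sec, shifted), c(3, -2),
               tolerance = 0.15)
})
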