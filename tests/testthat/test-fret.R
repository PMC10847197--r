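test_that("beta and gamma are exact on noise-free controls", {
  cfg <- fast_cfg(seed = 501, noise = noise_off)
  cal <- generate_calibration_stacks(cfg)
  expect_equal(estimate_beta(cal$donor_only)$beta, 0.2, tolerance = 1e-10)
  expect_equal(estimate_gamma(cal$acceptor_only)$gamma, 0.1, tolerance = 1e-10)
})

test_that("beta and gamma recover within 0.01 at the default noise level", {
  for (seed in c(502, 503)) {
    cal <- generate_calibration_stacks(fast_cfg(seed = seed))
    expect_equal(estimate_beta(cal$donor_only)$beta, 0.2, tolerance = 0.05)
    expect_lt(abs(estimate_beta(cal$donor_only)$beta - 0.2), 0.01)
    expect_lt(abs(estimate_gamma(cal$acceptor_only)$gamma - 0.1), 0.01)
  }
})

test_that("degenerate calibration inputs error", {
  g <- voxel_geometry(100)
  zero <- section_stack(list(
    donor = channel_volume(array(0, c(32, 32, 2)), "donor"),
    fret_raw = channel_volume(array(0, c(32, 32, 2)), "fret_raw")), g)
  expect_error(estimate_beta(zero), "all zero")
  const <- section_stack(list(
    acceptor = channel_volume(array(5, c(32, 32, 2)), "acceptor"),
    fret_raw = channel_volume(array(1, c(32, 32, 2)), "fret_raw")), g)
  expect_error(estimate_gamma(const), "too few suprathreshold")
})

test_that("correct_fret is the stated linear per-pixel correction", {
  set.seed(504)
  dims <- c(24, 24, 3)
  I_DD <- array(runif(prod(dims), 0, 1000), dims)
  I_AA <- array(runif(prod(dims), 0, 1000), dims)
  I_DA <- array(runif(prod(dims), 0, 400), dims)

  # beta = gamma = 0 is the identity
  cal0 <- fret_calibration(0, 0)
  expect_identical(correct_fret(I_DA, I_DD, I_AA, cal0), I_DA)

  cal <- fret_calibration(0.2, 0.1)
  Fc <- correct_fret(I_DA, I_DD, I_AA, cal)
  expect_equal(Fc, I_DA - 0.2 * I_DD - 0.1 * I_AA)
  # negatives retained
  expect_true(any(Fc < 0))
  # linear in each argument
  expect_equal(correct_fret(2 * I_DA, I_DD, I_AA, cal),
               Fc + I_DA)
  expect_error(correct_fret(I_DA, I_DD[, , 1:2], I_AA, cal), "shapes differ")
})

test_that("calibrations are session-scoped", {
  cal <- fret_calibration(0.2, 0.1, session_id = "sessionA")
  x <- array(1, c(4, 4, 2))
  expect_error(correct_fret(x, x, x, cal, session_id = "sessionB"),
               "session")
  expect_silent(correct_fret(x, x, x, cal, session_id = "sessionB",
                             allow_cross_session = TRUE))
})

test_that("no-FRET stacks correct to exactly zero without noise", {
  cfg <- fast_cfg(seed = 505, fret_efficiency = 0, noise = noise_off)
  gen <- generate_stack(cfg)
  ch <- gen$stack$channels
  cal <- fret_calibration(0.2, 0.1)
  Fc <- correct_fret(ch$fret_raw, ch$donor, ch$acceptor, cal)
  expect_equal(max(abs(Fc)), 0, tolerance = 1e-9)
})

test_that("corrected FRET amplitude matches the injected sensitized emission", {
  cfg <- fast_cfg(seed = 506, frac_donor_in_synapse = 0.6,
                  frac_acceptor_in_synapse = 0.6, frac_coloc = 0.5)
  gen <- generate_stack(cfg)
  ch <- gen$stack$channels
  cal <- fret_calibration(0.2, 0.1)
  Fc <- correct_fret(ch$fret_raw, ch$donor, ch$acceptor, cal)
  truth <- gen$truth$true_fret_positive
  # mean corrected signal over true-FRET pixels ~ E * (donor - background)
  injected <- 0.3 * (mean(ch$donor$intensities[truth]) - cfg$background)
  expect_equal(mean(Fc[truth]), injected, tolerance = 0.1)
})

test_that("fret_positive_fraction implements the triple-overlap rule", {
  dims <- c(10, 10, 2)
  Fc <- array(-1, dims)
  d <- array(FALSE, dims); a <- array(FALSE, dims); s <- array(FALSE, dims)
  d[1:5, 1:5, 1] <- TRUE; a[1:5, 1:5, 1] <- TRUE; s[1:5, 1:5, 1] <- TRUE
  # Fc <= 0 everywhere -> 0%
  expect_equal(fret_positive_fraction(Fc, d, a, s)$percent, 0)
  # half the eligible pixels positive
  Fc[1:5, 1:5, 1] <- rep(c(1, -1), length.out = 25)
  res <- fret_positive_fraction(Fc, d, a, s)
  expect_equal(res$n_eligible, 25L)
  expect_equal(res$percent, 100 * 13 / 25)
  # no eligible pixels -> missing, not zero
  expect_true(is.na(fret_positive_fraction(Fc, d, a, array(FALSE, dims))$percent))
})

test_that("positive pairs separate from the pre/post negative control", {
  run_condition <- function(seed, efficiency) {
    cfg <- fast_cfg(seed = seed, n_sections = 5, frame_size = c(128, 128),
                    n_synapses = 30, n_distractors = 4,
                    single_section_noise_objects = 4,
                    frac_donor_in_synapse = 0.6, frac_acceptor_in_synapse = 0.6,
                    frac_coloc = 0.5, fret_efficiency = efficiency)
    cal <- generate_calibration_stacks(cfg)
    calib <- fret_calibration(estimate_beta(cal$donor_only),
                              estimate_gamma(cal$acceptor_only))
    gen <- generate_stack(cfg)
    ch <- gen$stack$channels
    Fc <- correct_fret(ch$fret_raw, ch$donor, ch$acceptor, calib)
    m <- fret_object_masks(gen$stack)
    fret_positive_fraction(Fc, m$donor, m$acceptor, m$synapse)$percent
  }
  for (seed in c(507, 508, 509)) {
    pos <- run_condition(seed, 0.3)
    neg <- run_condition(seed + 50, 0)
    expect_gt(pos, neg)
    expect_gt(pos, 85)
  }
})
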