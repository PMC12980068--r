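# Ensemble generator: planted BI/BII and twist recovery, determinism.

test_that("generators are bit-identical given the same seed", {
  d <- short_duplex()
  sp <- ensemble_spec(n_frames = 4, seed = 99)
  e1 <- perturb_ensemble(d, sp)
  e2 <- perturb_ensemble(d, sp)
  expect_identical(e1$xyz, e2$xyz)
  expect_identical(e1$truth$bii, e2$truth$bii)
  i1 <- place_ions(d, ion_spec(n_bulk = 10, seed = 5))
  i2 <- place_ions(d, ion_spec(n_bulk = 10, seed = 5))
  expect_identical(i1$cation_xyz, i2$cation_xyz)
  c1 <- gen_hat_curve(hat_spec(seed = 3))
  c2 <- gen_hat_curve(hat_spec(seed = 3))
  expect_identical(c1$extension, c2$extension)
})

test_that("zero BII fraction yields zero analyzed BII population", {
  d <- build_duplex(helix_spec())
  e <- perturb_ensemble(d, ensemble_spec(n_frames = 3, twist_jitter_sd = 1,
                                         bii_fraction = 0,
                                         coord_noise_sd = 0, seed = 2))
  expect_identical(bi_bii(e)$bii_fraction, 0)
})

test_that("planted BII fraction is recovered within 3 binomial SEs", {
  d <- build_duplex(helix_spec())
  for (p in c(0.22, 0.5, 0.8)) {
    e <- perturb_ensemble(d, ensemble_spec(n_frames = 25,
                                           twist_jitter_sd = 1,
                                           bii_fraction = p,
                                           coord_noise_sd = 0.05,
                                           seed = 7 + round(100 * p)))
    n_draws <- length(e$truth$bii)
    se <- sqrt(p * (1 - p) / n_draws)
    expect_lt(abs(bi_bii(e)$bii_fraction - p), 3 * se + 1e-12)
    # analyzer agrees with the planted per-nucleotide labels when noiseless
  }
})

test_that("zero twist jitter reproduces the base twist to numerical precision", {
  d <- build_duplex(helix_spec(bp_per_turn = 9.97))
  e <- perturb_ensemble(d, ensemble_spec(n_frames = 2, twist_jitter_sd = 0,
                                         bii_fraction = 0.3,
                                         coord_noise_sd = 0, seed = 4))
  for (f in 1:2) {
    sp <- step_params(base_pair_frames(e, frame = f))
    expect_equal(sp$twist, rep(360 / 9.97, nrow(sp)), tolerance = 1e-9)
  }
})

test_that("per-frame jittered twists are recovered exactly without coordinate noise", {
  d <- build_duplex(helix_spec())
  e <- perturb_ensemble(d, ensemble_spec(n_frames = 3, twist_jitter_sd = 2,
                                         bii_fraction = 0.22,
                                         coord_noise_sd = 0, seed = 31))
  for (f in 1:3) {
    sp <- step_params(base_pair_frames(e, frame = f))
    expect_equal(sp$twist, unname(e$truth$twist[f, ]), tolerance = 1e-6)
  }
})

test_that("invalid BII fractions are rejected", {
  expect_error(ensemble_spec(bii_fraction = 1.2), "bii_fraction")
  expect_error(ensemble_spec(bii_fraction = -0.1), "bii_fraction")
})

test_that("coordinate jitter propagates to frame origins at the expected scale", {
  # linear propagation through the 4-atom anchor fit: sigma = 0.1 A gives
  # origin displacements of a few tenths of an Angstrom (lever arm ~3 A)
  d <- build_duplex(helix_spec())
  o0 <- do.call(rbind, lapply(base_pair_frames(d), `[[`, "origin"))
  set.seed(12)
  m <- as.matrix(d$atoms[, c("x", "y", "z")]) +
    matrix(rnorm(3 * nrow(d$atoms), 0, 0.1), ncol = 3)
  d$atoms$x <- m[, 1]; d$atoms$y <- m[, 2]; d$atoms$z <- m[, 3]
  o1 <- do.call(rbind, lapply(base_pair_frames(d), `[[`, "origin"))
  disp <- sqrt(rowSums((o1 - o0)^2))
  expect_lt(mean(disp), 0.35)
  expect_lt(max(disp), 0.8)
})
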