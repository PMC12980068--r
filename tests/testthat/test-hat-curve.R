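# Synthetic rotation-extension curves and their fits.

test_that("noiseless symmetric hats are symmetric about the planted center", {
  sp <- hat_spec(center_turns = 17, noise_sd = 0, slope_pos = 45,
                 slope_neg = 45)
  cv <- gen_hat_curve(sp)
  rel <- cv$turns - 17
  left <- cv$extension[match(-rel, rel)]
  expect_equal(cv$extension, left, tolerance = 1e-12)
})

test_that("the linear arms decrease linearly beyond the buckling offset", {
  sp <- hat_spec(center_turns = 0, noise_sd = 0, buckling_offset = 25,
                 turn_step = 5, slope_pos = 45, slope_neg = 45)
  cv <- gen_hat_curve(sp)
  k <- 0:5
  at <- 25 + k * 5
  ext <- cv$extension[match(at, cv$turns)]
  expect_equal(diff(ext), rep(-45 * 5 / 1000, 5), tolerance = 1e-12)
})

test_that("segmentation excludes the rounded cap on noiseless hats", {
  sp <- hat_spec(center_turns = 0, noise_sd = 0, buckling_offset = 25)
  cv <- gen_hat_curve(sp)
  seg <- segment_plectonemic(cv, threshold = 0.85)
  sel <- c(seg$neg_range, seg$pos_range)
  expect_true(all(abs(cv$turns[sel]) > 25))
  expect_gte(length(seg$neg_range), 3)
  expect_gte(length(seg$pos_range), 3)
})

test_that("noisy segmentation stays within one turn step of noiseless", {
  sp0 <- hat_spec(center_turns = 10, noise_sd = 0, seed = 1)
  sp1 <- hat_spec(center_turns = 10, noise_sd = 20, seed = 21)
  s0 <- segment_plectonemic(gen_hat_curve(sp0))
  s1 <- segment_plectonemic(gen_hat_curve(sp1))
  cv <- gen_hat_curve(sp0)
  expect_lte(abs(max(cv$turns[s0$neg_range]) - max(cv$turns[s1$neg_range])), 5)
  expect_lte(abs(min(cv$turns[s0$pos_range]) - min(cv$turns[s1$pos_range])), 5)
})

test_that("one-sided curves are rejected", {
  sp <- hat_spec(center_turns = 0, noise_sd = 0)
  cv <- gen_hat_curve(sp)
  onesided <- rotation_curve(cv$turns[cv$turns >= -10],
                             cv$extension[cv$turns >= -10])
  expect_error(segment_plectonemic(onesided), "rejected")
  expect_error(hat_spec(turn_range = c(-20, 120)), "3 points")
})

test_that("noiseless fits recover the planted center exactly", {
  f <- fit_hat(gen_hat_curve(hat_spec(center_turns = 10, noise_sd = 0)))
  expect_equal(f$center_turns, 10, tolerance = 1e-9)
  # asymmetric slopes: the fitted center equals the intersection abscissa of
  # the two noiseless arm lines, offset from the cap center by
  # b (s_pos - s_neg) / (2 (s_pos + s_neg))
  b <- 25; s_p <- 40; s_n <- 50
  fa <- fit_hat(gen_hat_curve(hat_spec(center_turns = -7, noise_sd = 0,
                                       slope_pos = s_p, slope_neg = s_n,
                                       buckling_offset = b)))
  expect_equal(fa$center_turns, -7 + b * (s_p - s_n) / (2 * (s_p + s_n)),
               tolerance = 1e-6)
  expect_lt(fa$slope_neg * fa$slope_pos, 0)  # opposite signed slopes
})

test_that("fit covariance covers planted slopes and centers", {
  # 100 seeded noisy curves: planted values inside +/- 2 SE ~95% of the time
  hits_slope <- 0L; hits_center <- 0L
  for (s in 1:100) {
    f <- fit_hat(gen_hat_curve(hat_spec(center_turns = 5, noise_sd = 20,
                                        slope_pos = 45, slope_neg = 45,
                                        seed = s)))
    if (abs(f$slope_pos - (-45)) <= 2 * f$slope_pos_se)
      hits_slope <- hits_slope + 1L
    if (abs(f$center_turns - 5) <= 2 * f$center_se)
      hits_center <- hits_center + 1L
  }
  expect_gte(hits_slope, 85)
  expect_gte(hits_center, 90)
})

test_that("fit center is invariant to extension offsets and equivariant in turns", {
  cv <- gen_hat_curve(hat_spec(center_turns = 3, noise_sd = 20, seed = 11))
  f0 <- fit_hat(cv)
  cv_shift <- cv; cv_shift$extension <- cv$extension + 0.15
  expect_equal(fit_hat(cv_shift)$center_turns, f0$center_turns,
               tolerance = 1e-9)
  cv_t <- rotation_curve(cv$turns + 40, cv$extension, n_bp = cv$n_bp)
  expect_equal(fit_hat(cv_t)$center_turns, f0$center_turns + 40,
               tolerance = 1e-9)
})

test_that("extensions are never negative", {
  cv <- gen_hat_curve(hat_spec(center_turns = 0, noise_sd = 300, seed = 2,
                               max_extension = 1))
  expect_true(all(cv$extension >= 0))
})
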