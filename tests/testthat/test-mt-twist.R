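# Twist-change extraction, force calibration, power law, table recovery.

test_that("delta_twist matches closed-form conversions and is antisymmetric", {
  mk <- function(center) structure(list(center_turns = center, n_bp = 20600),
                                   class = "hat_fit")
  expect_equal(delta_twist(mk(42.34), mk(0)), 42.34 * 360 / 20600)
  expect_equal(delta_twist(mk(42.34), mk(0)), 0.74, tolerance = 2e-3)
  expect_identical(delta_twist(mk(5), mk(5)), 0)
  expect_equal(delta_twist(mk(-10), mk(0), n_bp = 7900), -10 * 360 / 7900)
  f1 <- mk(13.7); f2 <- mk(-4.1)
  expect_identical(delta_twist(f1, f2), -delta_twist(f2, f1))
  expect_error(delta_twist(f1, f2, n_bp = 0), "n_bp")
})

test_that("equipartition force calibration inverts the closed form", {
  expect_equal(calibrate_force(97776, 6000, 295.15), 0.25, tolerance = 1e-3)
  expect_equal(calibrate_force(2 * 97776, 6000),
               calibrate_force(97776, 6000) / 2)
  expect_error(calibrate_force(-1, 6000), "positive")
})

test_that("force is recovered within 10% from finite fluctuation samples", {
  # n = 3480 samples (58 Hz x 60 s); var of the variance estimator gives
  # relative SE sqrt(2/n) ~ 2.4%, so 10% is a > 4 sigma envelope
  kBT <- 1.380649e-2 * 295.15
  ext <- 6000
  F_true <- 0.25
  sd_x <- sqrt(kBT * ext / F_true)
  set.seed(17)
  for (rep in 1:5) {
    x <- rnorm(3480, 0, sd_x)
    F_hat <- calibrate_force(var(x), ext)
    expect_lt(abs(F_hat - F_true) / F_true, 0.10)
  }
})

test_that("power-law fits recover exact square-root data and printed LiCl values", {
  conc <- c(0.1, 0.5, 1, 2)
  exact <- data.frame(concentration = conc, delta_tw = 0.5 * sqrt(conc))
  f <- fit_power_law(exact, "fixed_half")
  expect_equal(f$a, 0, tolerance = 1e-10)
  expect_equal(f$b, 0.5, tolerance = 1e-10)
  f2 <- fit_power_law(rbind(exact,
                            data.frame(concentration = 1.5,
                                       delta_tw = 0.5 * sqrt(1.5))),
                      "free_alpha")
  expect_equal(f2$alpha, 0.5, tolerance = 1e-3)
  # published LiCl twist changes up to 2 M follow sqrt(c) closely
  ref <- alkali_twist_reference()
  li <- ref[ref$salt == "LiCl", ]
  fli <- fit_power_law(data.frame(concentration = li$concentration,
                                  delta_tw = li$delta_tw, sd = li$sd),
                       "fixed_half", c_max = 2)
  expect_lt(fli$residual_sd, 0.03)
})

test_that("degenerate power-law inputs error", {
  expect_error(fit_power_law(data.frame(concentration = c(1, 1, 1),
                                        delta_tw = c(1, 2, 3))),
               "singular")
  expect_error(fit_power_law(data.frame(concentration = 1, delta_tw = 1)),
               "records")
})

test_that("noiseless table recovery reproduces the plants to 1e-10", {
  conds <- data.frame(salt = c("KCl", "LiCl", "LiCl"),
                      concentration = c(0.1, 1, 4),
                      delta_tw = c(0, 0.38, 0.74))
  tab <- recover_table(conds, n_molecules = 3, noise_sd = 0, seed = 5)
  expect_lt(max(abs(tab$delta_tw_deg_per_bp - tab$planted)), 1e-10)
  expect_true(all(tab$n_failed == 0))
})

test_that("noisy table recovery hits plants within 2 SE over molecules", {
  conds <- data.frame(salt = "LiCl", concentration = c(1, 4),
                      delta_tw = c(0.38, 0.74))
  tab <- recover_table(conds, n_molecules = 11, noise_sd = 20, seed = 1)
  tol <- 2 * tab$sd / sqrt(tab$n)
  expect_true(all(abs(tab$delta_tw_deg_per_bp - tab$planted) <= tol))
})
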