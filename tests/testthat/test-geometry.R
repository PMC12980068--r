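# Structure descriptors: frames, radius, pucker, BI/BII classification,
# rigid-motion invariance, terminal-exclusion consistency.

test_that("pair-frame z axes of a builder duplex align with the helix axis", {
  d <- build_duplex(helix_spec(bp_per_turn = 10.2))
  fr <- base_pair_frames(d)
  for (f in fr) {
    ang <- acos(min(1, abs(f$R[3, 3])))
    expect_lt(ang, 1e-6)
  }
})

test_that("frames co-rotate exactly under rigid motion of the structure", {
  d <- short_duplex(n = 8)
  f0 <- base_pair_frames(d)
  set.seed(2)
  ax <- rnorm(3); th <- runif(1, 0, 360); shift <- rnorm(3, 0, 30)
  R <- saltwist:::rot_about(ax, th)
  d2 <- d
  m <- as.matrix(d$atoms[, c("x", "y", "z")]) %*% t(R)
  m <- sweep(m, 2, shift, FUN = "+")
  d2$atoms$x <- m[, 1]; d2$atoms$y <- m[, 2]; d2$atoms$z <- m[, 3]
  f1 <- base_pair_frames(d2)
  for (i in seq_along(f0)) {
    expect_equal(f1[[i]]$R, R %*% f0[[i]]$R, tolerance = 1e-8)
    expect_equal(f1[[i]]$origin, as.numeric(R %*% f0[[i]]$origin + shift),
                 tolerance = 1e-8)
  }
})

test_that("all scalar descriptors are invariant under rigid motion", {
  d <- build_duplex(helix_spec())
  d2 <- rigid_motion(d, seed = 33)
  expect_equal(mean_step_params(d2)$twist, mean_step_params(d)$twist,
               tolerance = 1e-8)
  expect_equal(helix_axis_and_radius(d2)$radius,
               helix_axis_and_radius(d)$radius, tolerance = 1e-8)
  expect_equal(sugar_pucker(d2)$P, sugar_pucker(d)$P, tolerance = 1e-6)
  expect_equal(bi_bii(d2)$records$diff, bi_bii(d)$records$diff,
               tolerance = 1e-6)
})

test_that("radius round-trips the planted backbone radius and shrinks with it", {
  expect_equal(helix_axis_and_radius(
    build_duplex(helix_spec(backbone_radius = 9.4)))$radius, 9.4,
    tolerance = 1e-9)
  radii <- vapply(c(10, 9.5, 9.0, 8.5), function(r)
    helix_axis_and_radius(short_duplex(n = 12, backbone_radius = r))$radius,
    numeric(1))
  expect_true(all(diff(radii) < 0))
})

test_that("pucker phase formula reproduces the cosine-wave identity", {
  # Altona-Sundaralingam parametrization: nu_j = nu_max cos(P + 144 (j - 2)),
  # i.e. nu_2 = nu_max cos(P); the formula must return P exactly
  for (P in c(0, 18, 90, 162, 250)) {
    nu <- 40 * cos((P + 144 * ((0:4) - 2)) * pi / 180)
    expect_equal(pucker_phase(nu), P, tolerance = 1e-9)
  }
  expect_error(pucker_phase(rep(0, 5)), "planar")
})

test_that("BI/BII classification uses a closed boundary at zero", {
  expect_identical(saltwist::wrap_angle(-90) >= 0, FALSE)  # BI
  expect_identical(saltwist::wrap_angle(0) >= 0, TRUE)     # BII boundary
  expect_identical(saltwist::wrap_angle(360) >= 0, TRUE)
  expect_identical(saltwist::wrap_angle(181), -179)        # wrap convention
})

test_that("mean twist is insensitive to excluding 3 versus 4 terminal bp", {
  d <- build_duplex(helix_spec(bp_per_turn = 9.97))
  t3 <- mean_step_params(d, exclude_terminal = 3)$twist
  t4 <- mean_step_params(d, exclude_terminal = 4)$twist
  expect_lt(abs(t3 - t4), 1e-9)
})

test_that("frames error on a single strand and skip incomplete pairs", {
  d <- short_duplex(n = 6)
  one <- d
  one$atoms <- one$atoms[one$atoms$chain == "A", ]
  expect_error(base_pair_frames(one), "both strands")
  broken <- d
  drop <- broken$atoms$chain == "B" & broken$atoms$resno == 3 &
    broken$atoms$elety == "C1'"
  broken$atoms <- broken$atoms[!drop, ]
  expect_warning(fr <- base_pair_frames(broken), "skipped")
  expect_identical(length(fr), 5L)
})
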