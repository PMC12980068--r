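# Idealized duplex builder: planted geometry, helical symmetry, validation.

test_that("builder round-trips planted twist and rise exactly over a grid", {
  for (bpt in c(9.30, 9.97, 12)) {
    for (rise in c(3.0, 3.38, 3.5)) {
      d <- build_duplex(helix_spec(sequence = "ACGTACGTACGT",
                                   bp_per_turn = bpt, rise = rise))
      sp <- step_params(base_pair_frames(d))
      expect_equal(sp$twist, rep(360 / bpt, 11), tolerance = 1e-9)
      expect_equal(sp$rise, rep(rise, 11), tolerance = 1e-9)
    }
  }
})

test_that("per-step twist lists are recovered elementwise", {
  set.seed(42)
  tw <- runif(12, 30, 40)
  d <- build_duplex(helix_spec(sequence = "ACGTACGTACGTA",
                               twist_per_step = tw))
  sp <- step_params(base_pair_frames(d))
  expect_equal(sp$twist, tw, tolerance = 1e-6)
})

test_that("worked fiber-geometry examples give 36.1 and 38.7 deg per bp", {
  b <- build_duplex(helix_spec(bp_per_turn = 9.97, rise = 3.38))
  c_ <- build_duplex(helix_spec(bp_per_turn = 9.30, rise = 3.32))
  expect_equal(mean_step_params(b, exclude_terminal = 3)$twist, 36.1,
               tolerance = 0.05 / 36.1)
  expect_equal(mean_step_params(c_, exclude_terminal = 3)$twist, 38.7,
               tolerance = 0.05 / 38.7)
})

test_that("helical screw symmetry maps base pair i onto i+1", {
  d <- build_duplex(helix_spec(sequence = "ACGTACGT", bp_per_turn = 10.4,
                               rise = 3.31))
  S <- saltwist:::rot_z(360 / 10.4)
  a <- d$atoms
  # interior residues only: the 5'-terminal O5' of each strand has no
  # preceding linkage and keeps its raw template position
  for (i in c(2, 4, 6)) {
    for (ch in c("A", "B")) {
      xi <- as.matrix(a[a$chain == ch & a$resno == i, c("x", "y", "z")])
      xj <- as.matrix(a[a$chain == ch & a$resno == i + 1, c("x", "y", "z")])
      mapped <- xi %*% t(S)
      mapped[, 3] <- mapped[, 3] + 3.31
      expect_lt(max(abs(mapped - xj)), 1e-6)
    }
  }
})

test_that("intra-strand C1'-C1' distances are constant along each strand", {
  d <- build_duplex(helix_spec(bp_per_turn = 9.97))
  a <- d$atoms
  for (ch in c("A", "B")) {
    c1 <- as.matrix(a[a$chain == ch & a$elety == "C1'", c("x", "y", "z")])
    dists <- sqrt(rowSums(diff(c1)^2))
    expect_lt(diff(range(dists)), 1e-9)
  }
})

test_that("sugar pucker templates land in the canonical phase windows", {
  d2 <- short_duplex(pucker_mode = "C2'-endo")
  p2 <- sugar_pucker(d2)$P
  expect_true(all(p2 >= 144 & p2 <= 180))
  d3 <- short_duplex(pucker_mode = "C3'-endo")
  p3 <- sugar_pucker(d3)$P
  expect_true(all(p3 >= 0 & p3 <= 36))
})

test_that("builder rejects degenerate or invalid specifications", {
  expect_error(helix_spec(sequence = "ACX T"), "non-ACGT")
  expect_error(helix_spec(sequence = "ACG"), "length >= 4")
  expect_error(helix_spec(bp_per_turn = 2), "degenerate")
  expect_error(helix_spec(rise = -1), "rise")
})

test_that("phosphates sit exactly at the planted backbone radius", {
  for (rad in c(8.5, 9.4, 10.2)) {
    d <- short_duplex(backbone_radius = rad)
    a <- d$atoms
    p <- as.matrix(a[a$elety == "P", c("x", "y", "z")])
    # builder helix axis is global z
    expect_equal(unname(sqrt(p[, 1]^2 + p[, 2]^2)), rep(rad, nrow(p)),
                 tolerance = 1e-9)
  }
})
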