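# Shared fixtures: small, fast synthetic objects built in code.

short_duplex <- function(n = 10, bp_per_turn = 10, rise = 3.3,
                         backbone_radius = 9.4,
                         pucker_mode = "C2'-endo") {
  seqs <- paste(rep(c("A", "C", "G", "T"), length.out = n), collapse = "")
  build_duplex(helix_spec(sequence = seqs, bp_per_turn = bp_per_turn,
                          rise = rise, backbone_radius = backbone_radius,
                          pucker_mode = pucker_mode))
}

# apply a random rigid motion to all coordinates of a duplex
rigid_motion <- function(duplex, seed = 1) {
  set.seed(seed)
  R <- saltwist:::rot_about(rnorm(3), runif(1, 0, 360))
  t0 <- rnorm(3, 0, 20)
  m <- as.matrix(duplex$atoms[, c("x", "y", "z")]) %*% t(R)
  m <- sweep(m, 2, t0, FUN = "+")
  duplex$atoms$x <- m[, 1]; duplex$atoms$y <- m[, 2]; duplex$atoms$z <- m[, 3]
  duplex
}

table1_conditions <- function(salts = NULL) {
  ref <- alkali_twist_reference()
  if (!is.null(salts)) ref <- ref[ref$salt %in% salts, ]
  ref
}
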