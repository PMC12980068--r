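# Conformational ensembles: a stand-in for production trajectories.
#
# An ensemble perturbs a planted duplex frame by frame: per-step twist jitter
# (the duplex is regenerated with jittered twists), explicit BI/BII backbone
# substate planting by repositioning the phosphate linkage atoms, and
# isotropic Gaussian coordinate noise. All planted labels are recorded.

#' Specification of a synthetic conformational ensemble
#'
#' @param n_frames number of structures (>= 1).
#' @param twist_jitter_sd per-frame, per-step twist jitter SD, degrees.
#' @param bii_fraction probability that a scored nucleotide is planted in the
#'   BII backbone substate (independent Bernoulli draw per nucleotide per
#'   frame); in `[0, 1]`.
#' @param coord_noise_sd isotropic Gaussian coordinate noise SD, Angstrom,
#'   added after twist/backbone planting.
#' @param exclude_terminal terminal base pairs at each end whose nucleotides
#'   are left unplanted (matching the analyzer's exclusion; default 3).
#' @param seed integer seed; the ensemble is bit-identical for a given seed.
#' @return object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(n_frames = 100, twist_jitter_sd = 2,
                          bii_fraction = 0.22, coord_noise_sd = 0.05,
                          exclude_terminal = 3, seed = 1) {
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (bii_fraction < 0 || bii_fraction > 1)
    stop("bii_fraction must be in [0, 1]")
  if (twist_jitter_sd < 0 || coord_noise_sd < 0)
    stop("noise SDs must be non-negative")
  structure(list(n_frames = as.integer(n_frames),
                 twist_jitter_sd = twist_jitter_sd,
                 bii_fraction = bii_fraction,
                 coord_noise_sd = coord_noise_sd,
                 exclude_terminal = as.integer(exclude_terminal),
                 seed = seed),
            class = "ensemble_spec")
}

# number of frames in a structure object
n_frames <- function(x) {
  if (inherits(x, "dna_ensemble")) nrow(x$xyz) else 1L
}

# N x 3 coordinates of one frame of a duplex or ensemble
structure_frame_xyz <- function(x, frame = 1) {
  if (inherits(x, "dna_ensemble")) {
    if (frame < 1 || frame > nrow(x$xyz)) stop("frame index out of range")
    matrix(x$xyz[frame, ], ncol = 3, byrow = TRUE)
  } else {
    as.matrix(x$atoms[, c("x", "y", "z")])
  }
}

# package a list of N x 3 frames plus an atom table into an ensemble
make_ensemble <- function(atoms, frames_xyz, base = NULL, truth = NULL) {
  xyz <- do.call(rbind, lapply(frames_xyz, function(m) as.numeric(t(m))))
  structure(list(atoms = atoms[, setdiff(names(atoms), c("x", "y", "z"))],
                 xyz = xyz, base = base, truth = truth),
            class = "dna_ensemble")
}

#' Concatenate ensembles over the same atom set
#'
#' @param ... `dna_ensemble` objects sharing one atom table.
#' @return a `dna_ensemble` with the frames of all inputs, in order.
#' @export
bind_ensembles <- function(...) {
  es <- list(...)
  stopifnot(length(es) >= 1, all(vapply(es, inherits, logical(1),
                                        "dna_ensemble")))
  natom <- vapply(es, function(e) nrow(e$atoms), integer(1))
  if (length(unique(natom)) != 1) stop("ensembles differ in atom count")
  structure(list(atoms = es[[1]]$atoms,
                 xyz = do.call(rbind, lapply(es, `[[`, "xyz")),
                 base = es[[1]]$base,
                 truth = list(parts = lapply(es, `[[`, "truth"))),
            class = "dna_ensemble")
}

#' @export
print.dna_ensemble <- function(x, ...) {
  cat(sprintf("dna_ensemble: %d frames, %d atoms\n",
              nrow(x$xyz), nrow(x$atoms)))
  invisible(x)
}

# Rotate atoms `move` (rows of xyz) about the axis through point `p0` along
# `axis` by `theta` degrees, where positive theta INCREASES the torsion
# angle measured about that bond (atoms 1,2 fixed, atoms 3,4 side moving):
# with the IUPAC torsion convention this is a rotation by -theta about the
# 2->3 bond direction.
.rotate_about_bond <- function(xyz, move, p0, axis, theta) {
  R <- rot_about(axis, -theta)
  xyz[move, ] <- sweep(sweep(xyz[move, , drop = FALSE], 2, p0) %*% t(R),
                       2, p0, FUN = "+")
  xyz
}

# Set only zeta of a linkage (epsilon left as built) so that the wrapped
# epsilon - zeta difference equals diff_target: rotates O5' of the successor
# about the O3'-P bond. P itself does not move, so planted phosphate radii
# are preserved.
.set_zeta_diff <- function(atoms, xyz, chain, resno, next_resno, diff_target) {
  gi <- function(rn, name) which(atoms$chain == chain & atoms$resno == rn &
                                   atoms$elety == name)
  c4 <- gi(resno, "C4'"); c3 <- gi(resno, "C3'"); o3 <- gi(resno, "O3'")
  p  <- gi(next_resno, "P"); o5 <- gi(next_resno, "O5'")
  if (!all(lengths(list(c4, c3, o3, p, o5)) == 1)) return(xyz)
  eps <- torsion_angle(xyz[c4, ], xyz[c3, ], xyz[o3, ], xyz[p, ])
  zeta0 <- torsion_angle(xyz[c3, ], xyz[o3, ], xyz[p, ], xyz[o5, ])
  zeta_target <- wrap_angle(eps - diff_target)
  .rotate_about_bond(xyz, o5, xyz[p, ], xyz[p, ] - xyz[o3, ],
                     zeta_target - zeta0)
}

# Scored linkages of a duplex: data frame chain, resno, next_resno, where
# next_resno is the 5'->3' successor carrying the linkage phosphate. Chain B
# is stored pairing-aligned with chain A, so its 5'->3' successor is
# resno - 1.
.scored_linkages <- function(duplex, exclude_terminal) {
  n <- max(duplex$atoms$resno)
  lo <- exclude_terminal + 1L
  hi <- n - exclude_terminal
  if (hi < lo) stop("terminal exclusion leaves no scored nucleotides")
  res <- seq(lo, hi)
  a <- data.frame(chain = "A", resno = res, next_resno = res + 1L,
                  stringsAsFactors = FALSE)
  b <- data.frame(chain = "B", resno = res, next_resno = res - 1L,
                  stringsAsFactors = FALSE)
  rbind(a[a$next_resno <= n, ], b[b$next_resno >= 1, ])
}

#' Perturb a duplex into a synthetic conformational ensemble
#'
#' Per frame: (1) the duplex is regenerated with per-step twist equal to the
#' planted twist plus independent `N(0, twist_jitter_sd^2)` jitter; (2) every
#' scored nucleotide (terminal base pairs excluded) is planted into the BII
#' backbone substate with probability `bii_fraction`, else BI, by rotating
#' the successor's O5' about the O3'-P bond so the wrapped epsilon - zeta
#' difference sits at +90 degrees (BII) or -90 degrees (BI); phosphates stay
#' at the planted backbone radius; (3) isotropic Gaussian coordinate noise
#' is added.
#'
#' @param base a `dna_duplex` produced by [build_duplex()].
#' @param spec an [ensemble_spec()].
#' @return object of class `dna_ensemble` with the atom table, an
#'   `n_frames x 3N` coordinate matrix (frame per row), the base duplex, and
#'   `truth`: per-frame planted twists (`twist`, matrix frames x steps),
#'   planted BII labels (`bii`, logical matrix frames x scored nucleotides),
#'   the scored-linkage table, and the realized planted BII fraction.
#' @export
perturb_ensemble <- function(base, spec) {
  stopifnot(inherits(base, "dna_duplex"), inherits(spec, "ensemble_spec"))
  links <- .scored_linkages(base, spec$exclude_terminal)
  n_steps <- length(base$truth$twist_per_step)
  with_seed(spec$seed, {
    twist_mat <- matrix(0, spec$n_frames, n_steps)
    bii_mat <- matrix(FALSE, spec$n_frames, nrow(links))
    frames <- vector("list", spec$n_frames)
    for (f in seq_len(spec$n_frames)) {
      tw <- base$truth$twist_per_step +
        stats::rnorm(n_steps, 0, spec$twist_jitter_sd)
      twist_mat[f, ] <- tw
      sp <- base$spec
      sp$twist_per_step <- tw
      d <- build_duplex(sp)
      xyz <- duplex_xyz(d)
      is_bii <- stats::runif(nrow(links)) < spec$bii_fraction
      bii_mat[f, ] <- is_bii
      for (k in seq_len(nrow(links))) {
        diff_target <- if (is_bii[k]) 90 else -90
        xyz <- .set_zeta_diff(d$atoms, xyz, links$chain[k], links$resno[k],
                              links$next_resno[k], diff_target)
      }
      if (spec$coord_noise_sd > 0)
        xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, spec$coord_noise_sd),
                            nrow(xyz), 3)
      frames[[f]] <- xyz
    }
    make_ensemble(base$atoms, frames, base = base,
                  truth = list(twist = twist_mat, bii = bii_mat,
                               links = links,
                               bii_fraction_planted = mean(bii_mat),
                               spec = spec))
  })
}
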