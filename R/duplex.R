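# Idealized double-stranded DNA builder.
#
# Duplexes are generated directly from helical parameters (twist per step,
# rise, phosphate radius) rather than from fiber-diffraction atom lists: the
# analysis pipeline only consumes the planted geometry, so the builder is the
# ground truth. Each nucleotide carries a minimal atom set sufficient for
# every downstream descriptor: the full phosphate group, the sugar ring with
# a selectable pucker template, and a planar three-atom base anchor plus C1'
# used for base-pair frame fitting.

# The 33-mer duplex sequence used throughout (reference strand, 5'->3').
#' @rdname helix_spec
#' @export
DEFAULT_DUPLEX_SEQUENCE <- "CAGGTTCCTTAGTCGCTAGTCCCAATCGTAGAG"

# Local base-anchor template, coordinates in Angstrom relative to the
# base-pair frame (origin on the helix axis, z along the axis, reference
# strand on the +y side). Rows: glycosidic N, base atom 1, base atom 2, C1'.
# C1' is lifted off the base plane so that the four points are non-coplanar
# and the fitted frame is unique.
.base_fit_template <- function() {
  m <- rbind(
    NGLY = c(-1.50, 3.55, 0.00),
    B1   = c(-0.20, 3.75, 0.00),
    B2   = c(-0.75, 2.30, 0.00),
    C1p  = c(-2.47, 4.57, 0.50)
  )
  colnames(m) <- c("x", "y", "z")
  m
}

.COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")
.RESID <- c(A = "DA", C = "DC", G = "DG", T = "DT")

# Atom names of the frame-fit anchors by base class.
.anchor_names <- function(base) {
  if (base %in% c("A", "G")) c("N9", "C8", "C4", "C1'")
  else c("N1", "C6", "C2", "C1'")
}

#' Pseudorotation phase from endocyclic torsions
#'
#' Altona--Sundaralingam phase from the five furanose ring torsions
#' nu0..nu4, with quadrant correction to `[0, 360)`.
#'
#' @param nu numeric length-5 vector of ring torsions (degrees), in the order
#'   nu0 = C4'-O4'-C1'-C2', nu1 = O4'-C1'-C2'-C3', nu2 = C1'-C2'-C3'-C4',
#'   nu3 = C2'-C3'-C4'-O4', nu4 = C3'-C4'-O4'-C1'.
#' @return phase angle P in degrees, in `[0, 360)`.
#' @export
pucker_phase <- function(nu) {
  stopifnot(length(nu) == 5)
  num <- (nu[5] + nu[2]) - (nu[4] + nu[1])
  den <- 2 * nu[3] * (sin(36 * pi / 180) + sin(72 * pi / 180))
  if (abs(den) < 1e-12 && abs(num) < 1e-12)
    stop("planar ring: pseudorotation phase undefined")
  P <- atan2(num, den) * 180 / pi   # atan2 handles nu2 sign (quadrant)
  P - 360 * floor(P / 360)
}

# Ring torsions from 5x3 ring coordinates ordered (C1',C2',C3',C4',O4').
.ring_nu <- function(xyz) {
  idx <- list(c(4, 5, 1, 2), c(5, 1, 2, 3), c(1, 2, 3, 4),
              c(2, 3, 4, 5), c(3, 4, 5, 1))
  vapply(idx, function(q)
    torsion_angle(xyz[q[1], ], xyz[q[2], ], xyz[q[3], ], xyz[q[4], ]),
    numeric(1))
}

# Construct a puckered furanose ring hitting a target pseudorotation phase.
# Regular pentagon in xy (bond length ~1.52 A) with Cremer-Pople style
# out-of-plane displacements z_j = A cos(phi + 144 deg * j); phi is solved so
# that the Altona-Sundaralingam phase of the resulting torsions equals
# `target_P`. Returned in a canonical pose: C1' at the origin, centroid
# direction along +x, mean plane normal near +z.
.template_cache <- new.env(parent = emptyenv())

.ring_template <- function(target_P, amplitude = 0.38, radius = 1.30) {
  key <- paste("ring", target_P, amplitude, radius, sep = "|")
  hit <- .template_cache[[key]]
  if (!is.null(hit)) return(hit)
  out <- .ring_template_solve(target_P, amplitude, radius)
  .template_cache[[key]] <- out
  out
}

.ring_template_solve <- function(target_P, amplitude = 0.38, radius = 1.30) {
  build <- function(phi) {
    j <- 0:4
    ang <- 72 * j
    xyz <- cbind(radius * cos(ang * pi / 180),
                 radius * sin(ang * pi / 180),
                 amplitude * cos((phi + 144 * j) * pi / 180))
    colnames(xyz) <- c("x", "y", "z")
    xyz
  }
  objective <- function(phi) {
    P <- pucker_phase(.ring_nu(build(phi)))
    d <- abs(wrap_angle(P - target_P))
    d
  }
  # coarse grid then local refinement; deterministic
  grid <- seq(0, 359.5, by = 0.5)
  vals <- vapply(grid, objective, numeric(1))
  phi0 <- grid[which.min(vals)]
  opt <- stats::optimize(objective, c(phi0 - 1, phi0 + 1))
  xyz <- build(opt$minimum)
  # canonical pose: C1' (row 1) at origin
  xyz <- sweep(xyz, 2, xyz[1, ])
  cen <- colMeans(xyz)
  a <- cen / sqrt(sum(cen^2))                       # +x: centroid direction
  sv <- svd(sweep(xyz, 2, colMeans(xyz)))
  n <- sv$v[, 3]
  if (n[3] < 0) n <- -n                             # +z-ish normal
  n <- n - sum(n * a) * a
  n <- n / sqrt(sum(n^2))
  B <- cbind(a, cross3(n, a), n)
  xyz %*% B
}

# Backbone/sugar placement constants (Angstrom / degrees). psi_P is the
# azimuth of the phosphorus atom in the base-pair frame; z_P its offset along
# the local helix axis. Values give a B-DNA-like backbone with the O3'(i) -
# P(i+1) virtual bond short and the epsilon/zeta linkage well-conditioned.
.BB <- list(
  psi_P = 76, z_P = -2.6,
  sugar_tilt = -55,           # rotation of the ring about its attach axis
  d_O3 = 1.42, d_C5 = 1.51, d_O5 = 1.42, d_PO5 = 1.59, d_OP = 1.48
)

# Build one nucleotide (reference-strand local coordinates relative to the
# base-pair frame). Returns a named list of atom-name -> length-3 coords.
# Memoized: the template depends only on (base, pucker_mode, radius).
.nucleotide_template <- function(base, pucker_mode, backbone_radius) {
  key <- paste("nt", base, pucker_mode, backbone_radius, sep = "|")
  hit <- .template_cache[[key]]
  if (!is.null(hit)) return(hit)
  out <- .nucleotide_template_build(base, pucker_mode, backbone_radius)
  .template_cache[[key]] <- out
  out
}

.nucleotide_template_build <- function(base, pucker_mode, backbone_radius) {
  tmpl <- .base_fit_template()
  an <- .anchor_names(base)
  atoms <- list()
  atoms[[an[1]]] <- tmpl["NGLY", ]
  atoms[[an[2]]] <- tmpl["B1", ]
  atoms[[an[3]]] <- tmpl["B2", ]
  c1 <- tmpl["C1p", ]
  atoms[["C1'"]] <- c1

  target_P <- if (pucker_mode == "C2'-endo") 162 else 18
  ring <- .ring_template(target_P)        # rows C1',C2',C3',C4',O4'
  # attach: +x of ring pose points from C1' away from the glycosidic N,
  # tilted about that axis to incline the sugar out of the base plane.
  u <- c1 - atoms[[an[1]]]
  u <- u / sqrt(sum(u^2))
  w <- c(0, 0, 1) - sum(c(0, 0, 1) * u) * u
  w <- w / sqrt(sum(w^2))
  v <- cross3(w, u)
  R_att <- cbind(u, v, w) %*% rot_about(c(1, 0, 0), .BB$sugar_tilt)
  # ring pose has C1' at the origin; rotate then translate onto C1'
  ringg <- sweep(ring %*% t(R_att), 2, c1, FUN = "+")
  rn <- c("C1'", "C2'", "C3'", "C4'", "O4'")
  for (k in 2:5) atoms[[rn[k]]] <- ringg[k, ]

  cen <- colMeans(ringg)
  # phosphorus anchored exactly at the planted backbone radius
  psi <- .BB$psi_P * pi / 180
  P <- c(backbone_radius * cos(psi), backbone_radius * sin(psi), .BB$z_P)
  atoms[["P"]] <- P
  radial <- c(cos(psi), sin(psi), 0)
  d1 <- radial + c(0, 0, 0.9); d1 <- d1 / sqrt(sum(d1^2))
  d2 <- radial - c(0, 0, 0.9); d2 <- d2 / sqrt(sum(d2^2))
  atoms[["OP1"]] <- P + .BB$d_OP * d1
  atoms[["OP2"]] <- P + .BB$d_OP * d2
  c4 <- ringg[4, ]; c3 <- ringg[3, ]
  dir5 <- (c4 - cen) / sqrt(sum((c4 - cen)^2)) + c(0, 0, -0.7)
  dir5 <- dir5 / sqrt(sum(dir5^2))
  c5 <- c4 + .BB$d_C5 * dir5
  atoms[["C5'"]] <- c5
  # O5' sits on the C5'-P line, bonded to P
  atoms[["O5'"]] <- P + .BB$d_PO5 * (c5 - P) / sqrt(sum((c5 - P)^2))
  dir3 <- (c3 - cen) / sqrt(sum((c3 - cen)^2)) + c(0, 0, 1.0)
  dir3 <- dir3 / sqrt(sum(dir3^2))
  atoms[["O3'"]] <- c3 + .BB$d_O3 * dir3
  atoms
}

#' Specification of an idealized DNA duplex
#'
#' Collects the helical parameters from which [build_duplex()] generates an
#' all-atom (minimal atom set) double helix. Twist can be given either as a
#' uniform `bp_per_turn` (twist per step = 360 / `bp_per_turn` degrees) or as
#' an explicit per-step twist vector.
#'
#' @param sequence reference-strand sequence, 5'->3', characters in ACGT.
#'   Defaults to the 33-mer duplex used for the simulation-style analyses.
#' @param bp_per_turn base pairs per helical turn (> 2); ignored if
#'   `twist_per_step` is supplied.
#' @param twist_per_step optional vector of per-step twists in degrees
#'   (length `nchar(sequence) - 1`, or length 1, recycled).
#' @param rise rise per step along the helix axis, Angstrom.
#' @param backbone_radius radial distance of the phosphorus atoms from the
#'   helix axis, Angstrom.
#' @param pucker_mode sugar pucker template, `"C2'-endo"` (B-like, phase
#'   ~162 deg) or `"C3'-endo"` (A-like, phase ~18 deg).
#' @param seed integer seed (kept for provenance; the builder itself is
#'   deterministic).
#' @return an object of class `helix_spec`.
#' @export
helix_spec <- function(sequence = DEFAULT_DUPLEX_SEQUENCE,
                       bp_per_turn = 9.97,
                       twist_per_step = NULL,
                       rise = 3.38,
                       backbone_radius = 9.4,
                       pucker_mode = c("C2'-endo", "C3'-endo"),
                       seed = NULL) {
  pucker_mode <- match.arg(pucker_mode)
  sequence <- toupper(sequence)
  if (nchar(sequence) < 4) stop("sequence must have length >= 4")
  if (grepl("[^ACGT]", sequence)) stop("sequence contains non-ACGT characters")
  n <- nchar(sequence)
  if (is.null(twist_per_step)) {
    if (!is.finite(bp_per_turn) || bp_per_turn <= 2)
      stop("bp_per_turn must be finite and > 2 (degenerate helix)")
    twist_per_step <- rep(360 / bp_per_turn, n - 1)
  } else {
    twist_per_step <- rep_len(as.numeric(twist_per_step), n - 1)
  }
  if (!all(is.finite(twist_per_step)))
    stop("twist_per_step must be finite")
  if (!is.finite(rise) || rise <= 0) stop("rise must be positive")
  if (!is.finite(backbone_radius) || backbone_radius <= 0)
    stop("backbone_radius must be positive")
  structure(list(sequence = sequence,
                 twist_per_step = twist_per_step,
                 rise = rise,
                 backbone_radius = backbone_radius,
                 pucker_mode = pucker_mode,
                 seed = seed),
            class = "helix_spec")
}

#' Build an idealized DNA duplex from helical parameters
#'
#' Generates both strands of a Watson-Crick paired duplex by rigid screw
#' placement of a per-nucleotide template: base-pair frame i is rotated by
#' the cumulative planted twist about the global z axis and translated by the
#' cumulative rise along it. The complementary strand is the template mapped
#' through the base-pair dyad (180 degrees about the frame x axis), so every
#' descriptor computed from base-pair frames round-trips the planted values
#' exactly.
#'
#' Atom set per nucleotide: P, OP1, OP2, O5', C5', C4', C3', O3', C2', C1',
#' O4', the glycosidic nitrogen and two base-plane atoms (N9/C8/C4 for
#' purines, N1/C6/C2 for pyrimidines). Every residue carries a 5'-phosphate.
#'
#' @param spec a [helix_spec()].
#' @return object of class `dna_duplex`: a list with `atoms` (data frame with
#'   columns eleno, elety, resid, chain, resno, x, y, z), the `spec`, and
#'   `truth` (planted twist per step, rise, backbone radius, pucker mode).
#'   Chain A is the reference strand (resno 1..n, 5'->3'); chain B residue i
#'   is the Watson-Crick partner of chain A residue i.
#' @examples
#' d <- build_duplex(helix_spec(sequence = "ACGTACGT", bp_per_turn = 10))
#' head(d$atoms)
#' @export
build_duplex <- function(spec) {
  stopifnot(inherits(spec, "helix_spec"))
  seq1 <- strsplit(spec$sequence, "")[[1]]
  n <- length(seq1)
  theta <- cumsum(c(0, spec$twist_per_step))
  zpos <- (seq_len(n) - 1) * spec$rise

  flip <- diag(c(1, -1, -1))
  rows <- vector("list", 2L * n)
  for (i in seq_len(n)) {
    Ri <- rot_z(theta[i])
    offs <- c(0, 0, zpos[i])
    b1 <- seq1[i]
    b2 <- .COMPLEMENT[[b1]]
    t1 <- .nucleotide_template(b1, spec$pucker_mode, spec$backbone_radius)
    t2 <- .nucleotide_template(b2, spec$pucker_mode, spec$backbone_radius)
    place <- function(tmpl, pre = diag(3)) {
      loc <- do.call(rbind, tmpl)
      glob <- t(Ri %*% pre %*% t(loc)) + matrix(offs, nrow(loc), 3, byrow = TRUE)
      data.frame(elety = names(tmpl), x = glob[, 1], y = glob[, 2],
                 z = glob[, 3], stringsAsFactors = FALSE)
    }
    a1 <- place(t1)
    a1$resid <- .RESID[[b1]]; a1$chain <- "A"; a1$resno <- i
    a2 <- place(t2, pre = flip)
    a2$resid <- .RESID[[b2]]; a2$chain <- "B"; a2$resno <- i
    rows[[i]] <- a1
    rows[[n + i]] <- a2
  }
  atoms <- do.call(rbind, rows)
  atoms$eleno <- seq_len(nrow(atoms))
  atoms <- atoms[, c("eleno", "elety", "resid", "chain", "resno",
                     "x", "y", "z")]
  rownames(atoms) <- NULL

  # Finalize the backbone in the canonical BI substate: every linkage's zeta
  # is set (by rotating the successor's O5' about the O3'-P bond, leaving P
  # at the planted radius) so that wrapped(epsilon - zeta) = -90 degrees.
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  for (ch in c("A", "B")) {
    dirn <- if (ch == "A") 1L else -1L
    for (r in seq_len(n)) {
      nx <- r + dirn
      if (nx < 1L || nx > n) next
      xyz <- .set_zeta_diff(atoms, xyz, ch, r, nx, -90)
    }
  }
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  structure(list(atoms = atoms,
                 spec = spec,
                 truth = list(twist_per_step = spec$twist_per_step,
                              rise = spec$rise,
                              backbone_radius = spec$backbone_radius,
                              pucker_mode = spec$pucker_mode,
                              sequence = spec$sequence)),
            class = "dna_duplex")
}

#' @export
print.dna_duplex <- function(x, ...) {
  n <- max(x$atoms$resno)
  cat(sprintf("dna_duplex: %d bp, %d atoms, mean planted twist %.3f deg/step, rise %.2f A\n",
              n, nrow(x$atoms), mean(x$truth$twist_per_step), x$truth$rise))
  invisible(x)
}

# coordinate matrix (N x 3) of a duplex, optionally restricted
duplex_xyz <- function(duplex, sel = NULL) {
  a <- duplex$atoms
  if (!is.null(sel)) a <- a[sel, , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

# logical index of backbone heavy atoms
backbone_selection <- function(atoms) {
  atoms$elety %in% c("P", "OP1", "OP2", "O5'", "C5'", "C4'",
                     "C3'", "O3'", "C2'", "C1'", "O4'")
}
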