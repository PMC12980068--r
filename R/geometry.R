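# Structure descriptors: helix axis and radius, sugar pucker, BI/BII
# backbone substates, inner-sphere cation counting.

#' Helix axis and radius
#'
#' The axis is the principal direction (total-least-squares line) of the
#' base-pair frame origins; the radius is the root-mean-square distance of
#' the phosphorus atoms to that line. The `exclude_terminal` outermost base
#' pairs at each end are excluded from the radius (their P atoms are not
#' counted), but all origins inform the axis fit.
#'
#' The "DNA radius" here is a definition, not a universal convention: it is
#' the RMS P-atom distance to the fitted axis.
#'
#' @param duplex a `dna_duplex` or `dna_ensemble`.
#' @param exclude_terminal terminal base pairs excluded at each end.
#' @param frame ensemble frame index.
#' @return list with `axis` (unit vector), `center` (point on the axis) and
#'   `radius` (Angstrom).
#' @export
helix_axis_and_radius <- function(duplex, exclude_terminal = 3, frame = 1) {
  fr <- base_pair_frames(duplex, frame = frame)
  if (length(fr) < 4) stop("need at least 4 base pairs")
  origins <- do.call(rbind, lapply(fr, `[[`, "origin"))
  ctr <- colMeans(origins)
  sv <- svd(sweep(origins, 2, ctr))
  if (sv$d[1] < 1e-9) stop("degenerate base-pair origins: no axis direction")
  axis <- sv$v[, 1]

  atoms <- duplex$atoms
  xyz <- structure_frame_xyz(duplex, frame)
  n <- max(atoms$resno)
  keep_res <- seq(exclude_terminal + 1L, n - exclude_terminal)
  sel <- which(atoms$elety == "P" & atoms$resno %in% keep_res)
  if (!length(sel)) stop("no phosphorus atoms after terminal exclusion")
  rel <- sweep(xyz[sel, , drop = FALSE], 2, ctr)
  par <- rel %*% axis
  perp2 <- rowSums(rel^2) - as.numeric(par)^2
  list(axis = axis, center = ctr, radius = sqrt(mean(pmax(perp2, 0))))
}

#' Sugar pseudorotation phase per nucleotide
#'
#' Computes the five endocyclic torsions nu0..nu4 of each furanose ring and
#' the Altona--Sundaralingam phase (see [pucker_phase()]), quadrant-corrected
#' to `[0, 360)`.
#'
#' @param duplex a `dna_duplex` or `dna_ensemble`.
#' @param frame ensemble frame index.
#' @return data frame with columns `chain`, `resno`, `P` (degrees; `NA` with
#'   a warning where the ring is planar or atoms are missing).
#' @export
sugar_pucker <- function(duplex, frame = 1) {
  atoms <- duplex$atoms
  xyz <- structure_frame_xyz(duplex, frame)
  ring_names <- c("C1'", "C2'", "C3'", "C4'", "O4'")
  res <- unique(atoms[, c("chain", "resno")])
  res$P <- NA_real_
  for (k in seq_len(nrow(res))) {
    idx <- which(atoms$chain == res$chain[k] & atoms$resno == res$resno[k])
    pos <- match(ring_names, atoms$elety[idx])
    if (anyNA(pos)) next
    ring <- xyz[idx[pos], , drop = FALSE]
    res$P[k] <- tryCatch(pucker_phase(.ring_nu(ring)), error = function(e) {
      warning(sprintf("nucleotide %s:%d: %s", res$chain[k], res$resno[k],
                      conditionMessage(e)))
      NA_real_
    })
  }
  res
}

#' Backbone BI/BII substate analysis
#'
#' For each scored nucleotide computes epsilon = torsion(C4', C3', O3',
#' P(next)) and zeta = torsion(C3', O3', P(next), O5'(next)), where "next" is
#' the 5'->3' successor (identified as the neighbouring residue whose P atom
#' is nearest this residue's O3'). The difference is wrapped to
#' `(-180, 180]`; a nucleotide is BII iff wrapped(epsilon - zeta) >= 0
#' (closed boundary at 0). The fraction is taken over all scored nucleotides
#' and all frames; terminal nucleotides lacking a successor phosphate are
#' skipped.
#'
#' @param x a `dna_duplex` or `dna_ensemble`.
#' @param exclude_terminal terminal base pairs excluded at each end.
#' @return list with `records` (data frame: frame, chain, resno, eps, zeta,
#'   diff, bii) and `bii_fraction`.
#' @export
bi_bii <- function(x, exclude_terminal = 3) {
  atoms <- x$atoms
  n <- max(atoms$resno)
  keep <- seq(exclude_terminal + 1L, n - exclude_terminal)
  nf <- n_frames(x)
  recs <- vector("list", nf)
  for (f in seq_len(nf)) {
    xyz <- structure_frame_xyz(x, f)
    rows <- list()
    for (ch in unique(atoms$chain)) {
      for (r in keep) {
        gi <- function(rn, name)
          which(atoms$chain == ch & atoms$resno == rn & atoms$elety == name)
        c4 <- gi(r, "C4'"); c3 <- gi(r, "C3'"); o3 <- gi(r, "O3'")
        if (!all(lengths(list(c4, c3, o3)) == 1)) next
        # successor = neighbour with the P atom closest to this O3'
        cand <- c(r - 1L, r + 1L)
        cand <- cand[cand >= 1 & cand <= n]
        pidx <- vapply(cand, function(rn) {
          i <- gi(rn, "P"); if (length(i) == 1) i else NA_integer_
        }, integer(1))
        cand <- cand[!is.na(pidx)]; pidx <- pidx[!is.na(pidx)]
        if (!length(cand)) next
        d2 <- vapply(pidx, function(i) sum((xyz[i, ] - xyz[o3, ])^2),
                     numeric(1))
        nx <- cand[which.min(d2)]
        p <- gi(nx, "P"); o5 <- gi(nx, "O5'")
        if (length(o5) != 1) next
        eps <- torsion_angle(xyz[c4, ], xyz[c3, ], xyz[o3, ], xyz[p, ])
        zeta <- torsion_angle(xyz[c3, ], xyz[o3, ], xyz[p, ], xyz[o5, ])
        dd <- wrap_angle(eps - zeta)
        rows[[length(rows) + 1L]] <-
          data.frame(frame = f, chain = ch, resno = r, eps = eps,
                     zeta = zeta, diff = dd, bii = dd >= 0,
                     stringsAsFactors = FALSE)
      }
    }
    recs[[f]] <- do.call(rbind, rows)
  }
  records <- do.call(rbind, recs)
  if (is.null(records) || !nrow(records))
    stop("no scorable nucleotides (missing backbone atoms?)")
  list(records = records, bii_fraction = mean(records$bii))
}

#' Inner-sphere cations per phosphate
#'
#' Counts, per frame, the distinct cations lying within `cutoff` of at least
#' one non-bridging phosphate oxygen (OP1/OP2) -- each ion counted once even
#' if close to several oxygens -- divides by the number of phosphate groups,
#' and averages over frames.
#'
#' @param x a `dna_duplex` or `dna_ensemble` with OP1/OP2 atoms.
#' @param ions an `ion_set` (see [place_ions()]) or an N x 3 matrix of cation
#'   coordinates in Angstrom, in the same frame of reference.
#' @param cutoff counting cutoff in nm (default 0.3 nm).
#' @return mean number of inner-sphere cations per phosphate.
#' @export
count_adsorbed <- function(x, ions, cutoff = 0.3) {
  if (cutoff <= 0) stop("cutoff must be positive")
  cut_A <- cutoff * 10            # nm -> Angstrom
  atoms <- x$atoms
  osel <- which(atoms$elety %in% c("OP1", "OP2"))
  if (!length(osel)) stop("no non-bridging phosphate oxygens (OP1/OP2)")
  n_phos <- length(which(atoms$elety == "P"))
  ion_xyz <- if (inherits(ions, "ion_set")) ions$cation_xyz else as.matrix(ions)
  if (is.null(ion_xyz) || !nrow(ion_xyz)) return(0)
  nf <- n_frames(x)
  per_frame <- numeric(nf)
  for (f in seq_len(nf)) {
    oxy <- structure_frame_xyz(x, f)[osel, , drop = FALSE]
    # distinct-ion rule: an ion counts once if any oxygen is within cutoff
    close <- vapply(seq_len(nrow(ion_xyz)), function(i) {
      d2 <- (oxy[, 1] - ion_xyz[i, 1])^2 + (oxy[, 2] - ion_xyz[i, 2])^2 +
        (oxy[, 3] - ion_xyz[i, 3])^2
      any(d2 <= cut_A^2)
    }, logical(1))
    per_frame[f] <- sum(close) / n_phos
  }
  mean(per_frame)
}
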