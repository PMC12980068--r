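# Base-pair reference frames and step parameters.
#
# Frames follow the standard convention: z along the local helix direction,
# y towards the reference-strand backbone, x towards the major groove. Each
# base frame is obtained by rigid superposition (quaternion method) of a
# fixed non-coplanar four-atom anchor template (glycosidic N, two base-plane
# atoms, C1') onto the observed atoms; the complementary-strand frame has its
# y and z axes flipped before averaging into the pair frame.

# fit one base: returns list(R = 3x3, origin = length 3) or NULL
.fit_base_frame <- function(atoms, xyz, idx) {
  resid <- atoms$resid[idx[1]]
  base <- substr(resid, 2, 2)
  an <- .anchor_names(base)
  pos <- match(an, atoms$elety[idx])
  if (anyNA(pos)) return(NULL)
  obs <- xyz[idx[pos], , drop = FALSE]
  tmpl <- .base_fit_template()
  tc <- colMeans(tmpl); oc <- colMeans(obs)
  R <- quaternion_rotation(sweep(tmpl, 2, tc), sweep(obs, 2, oc))
  # row convention: obs ~ tmpl %*% t(R) + t  ->  frame rotation is R
  origin <- unname(oc) - as.numeric(R %*% tc)
  list(R = R, origin = origin)
}

#' Base-pair reference frames of a duplex
#'
#' Computes one orthonormal frame per base pair by least-squares
#' superposition of a fixed base-anchor template onto each base (quaternion
#' method), flipping the complementary-strand frame's y/z axes, and averaging
#' the two base frames (origins averaged; rotations averaged and projected
#' back onto SO(3)).
#'
#' @param duplex a `dna_duplex` (from [build_duplex()] or [read_structure()]).
#'   Pairs are identified by residue number: chain A residue i with chain B
#'   residue i.
#' @param frame for ensembles, the frame index (default 1).
#' @return list of class `bp_frames`: for each base pair, `R` (3x3 rotation,
#'   columns x/y/z axes, det +1) and `origin` (Angstrom). Pairs with missing
#'   anchor atoms are skipped with a warning and recorded in
#'   `attr(, "skipped")`.
#' @export
base_pair_frames <- function(duplex, frame = 1) {
  atoms <- duplex$atoms
  xyz <- structure_frame_xyz(duplex, frame)
  chains <- sort(unique(atoms$chain))
  if (length(chains) < 2) stop("both strands must be present")
  resnos <- sort(unique(atoms$resno[atoms$chain == chains[1]]))
  flip <- diag(c(1, -1, -1))
  frames <- list()
  skipped <- integer(0)
  for (r in resnos) {
    i1 <- which(atoms$chain == chains[1] & atoms$resno == r)
    i2 <- which(atoms$chain == chains[2] & atoms$resno == r)
    f1 <- if (length(i1)) .fit_base_frame(atoms, xyz, i1) else NULL
    f2 <- if (length(i2)) .fit_base_frame(atoms, xyz, i2) else NULL
    if (is.null(f1) || is.null(f2)) {
      skipped <- c(skipped, r)
      next
    }
    R2 <- f2$R %*% flip           # undo the dyad flip of strand 2
    R <- orthonormalize_rotation((f1$R + R2) / 2)
    origin <- (f1$origin + f2$origin) / 2
    frames[[length(frames) + 1L]] <- list(R = R, origin = origin, resno = r)
  }
  if (length(skipped))
    warning("skipped base pairs with missing anchor atoms: ",
            paste(skipped, collapse = ", "))
  structure(frames, class = "bp_frames", skipped = skipped)
}

#' Base-pair step twist and rise
#'
#' For consecutive pair frames i, i+1 with relative rotation
#' `R = t(F_i) %*% F_{i+1}`, the mid-frame is F_i composed with half the
#' relative rotation; twist is the signed angle between the two x axes
#' projected onto the plane normal to the mid-frame z axis, and rise is the
#' projection of the origin displacement onto that axis.
#'
#' @param frames a `bp_frames` list (>= 2 frames).
#' @return data frame with columns `step`, `twist` (degrees), `rise`
#'   (Angstrom).
#' @export
step_params <- function(frames) {
  if (length(frames) < 2) stop("need at least 2 base-pair frames")
  out <- data.frame(step = integer(0), twist = numeric(0), rise = numeric(0))
  for (i in seq_len(length(frames) - 1)) {
    F1 <- frames[[i]]$R; F2 <- frames[[i + 1]]$R
    Rrel <- crossprod(F1, F2)
    Rh <- .half_rotation(Rrel)
    Fm <- F1 %*% Rh
    zm <- Fm[, 3]
    x1 <- F1[, 1]; x2 <- F2[, 1]
    p1 <- x1 - sum(x1 * zm) * zm; p1 <- p1 / sqrt(sum(p1^2))
    p2 <- x2 - sum(x2 * zm) * zm; p2 <- p2 / sqrt(sum(p2^2))
    tw <- atan2(sum(cross3(p1, p2) * zm), sum(p1 * p2)) * 180 / pi
    rise <- sum((frames[[i + 1]]$origin - frames[[i]]$origin) * zm)
    out <- rbind(out, data.frame(step = i, twist = tw, rise = rise))
  }
  out
}

# half of a rotation via axis-angle
.half_rotation <- function(R) {
  tr <- (sum(diag(R)) - 1) / 2
  tr <- min(1, max(-1, tr))
  ang <- acos(tr)
  if (ang < 1e-12) return(diag(3))
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  if (sqrt(sum(ax^2)) < 1e-12) {
    # 180-degree rotation: axis from R + I
    M <- R + diag(3)
    ax <- M[, which.max(colSums(M^2))]
  }
  rot_about(ax, ang * 90 / pi)
}

#' Mean twist and rise with terminal exclusion
#'
#' Convenience wrapper: computes base-pair frames and step parameters and
#' averages them, leaving out steps that touch the `exclude_terminal`
#' outermost base pairs at each end.
#'
#' @param duplex a `dna_duplex`.
#' @param exclude_terminal number of terminal base pairs excluded at each end
#'   (default 3).
#' @param frame ensemble frame index.
#' @return list with `twist` and `rise` means and the per-step table.
#' @export
mean_step_params <- function(duplex, exclude_terminal = 3, frame = 1) {
  fr <- base_pair_frames(duplex, frame = frame)
  sp <- step_params(fr)
  keep <- steps_within(nrow(sp) + 1L, exclude_terminal)
  sp_use <- sp[keep, , drop = FALSE]
  list(twist = mean(sp_use$twist), rise = mean(sp_use$rise), steps = sp_use)
}

# which steps (between n_bp frames) survive excluding k terminal bp each end
steps_within <- function(n_bp, exclude_terminal) {
  lo <- exclude_terminal + 1L
  hi <- n_bp - exclude_terminal - 1L
  if (hi < lo) stop("terminal exclusion leaves no steps")
  seq(lo, hi)
}
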