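# Synthetic cation configurations around the DNA backbone.

#' Specification of a synthetic ion configuration
#'
#' @param ions_per_phosphate mean number of shell cations per phosphate
#'   group (>= 0); the total shell count is
#'   `round(ions_per_phosphate * n_phosphates)`.
#' @param shell_range numeric length 2, (min, max) distance in nm from the
#'   nearest non-bridging oxygen at which shell ions are placed.
#' @param n_bulk number of bulk cations placed uniformly in the box, at least
#'   `bulk_exclusion` nm from every DNA atom.
#' @param box box edge lengths in nm (length 1 or 3), centered on the DNA.
#' @param bulk_exclusion minimum bulk-ion distance to any DNA atom, nm
#'   (default 0.5).
#' @param counting_cutoff reference inner-sphere counting cutoff in nm used
#'   to warn when `shell_range` extends to or beyond it (planted shell ions
#'   would not all be counted); default 0.3.
#' @param seed integer seed.
#' @return object of class `ion_spec`.
#' @export
ion_spec <- function(ions_per_phosphate = 2, shell_range = c(0.19, 0.25),
                     n_bulk = 100, box = 12, bulk_exclusion = 0.5,
                     counting_cutoff = 0.3, seed = 1) {
  if (ions_per_phosphate < 0) stop("ions_per_phosphate must be >= 0")
  if (length(shell_range) != 2 || shell_range[1] <= 0 ||
      shell_range[2] <= shell_range[1])
    stop("shell_range must be (min, max) with 0 < min < max")
  if (shell_range[2] >= counting_cutoff)
    warning(sprintf(paste("shell_range maximum (%.3f nm) reaches the",
                          "counting cutoff (%.3f nm): planted shell ions",
                          "may not all be counted"),
                    shell_range[2], counting_cutoff))
  structure(list(ions_per_phosphate = ions_per_phosphate,
                 shell_range = shell_range, n_bulk = as.integer(n_bulk),
                 box = rep_len(box, 3), bulk_exclusion = bulk_exclusion,
                 counting_cutoff = counting_cutoff, seed = seed),
            class = "ion_spec")
}

#' Place cations around a duplex
#'
#' Plants exactly `round(ions_per_phosphate * n_phosphates)` shell cations,
#' each at a uniformly drawn distance within `shell_range` of a non-bridging
#' oxygen (phosphates visited cyclically, OP1/OP2 alternating, isotropic
#' random direction), plus `n_bulk` bulk cations uniform in a box centered on
#' the DNA and excluded from within `bulk_exclusion` of any DNA atom. No two
#' ions are placed closer than 0.15 nm (rejection sampling).
#'
#' @param structure a `dna_duplex` with OP1/OP2 atoms.
#' @param spec an [ion_spec()].
#' @return object of class `ion_set`: `cation_xyz` (N x 3, Angstrom),
#'   `is_shell` (logical), `truth` (planted ions per phosphate, shell count,
#'   spec).
#' @export
place_ions <- function(structure, spec) {
  stopifnot(inherits(spec, "ion_spec"))
  atoms <- structure$atoms
  xyz <- duplex_xyz(structure)
  osel <- which(atoms$elety %in% c("OP1", "OP2"))
  if (!length(osel)) stop("structure has no OP1/OP2 atoms")
  n_phos <- sum(atoms$elety == "P")
  n_shell <- round(spec$ions_per_phosphate * n_phos)
  min_sep <- 1.5                        # 0.15 nm in Angstrom
  shell_A <- spec$shell_range * 10
  phos_res <- atoms[atoms$elety == "P", c("chain", "resno")]

  with_seed(spec$seed, {
    placed <- matrix(numeric(0), 0, 3)
    is_shell <- logical(0)
    ok_sep <- function(p) {
      !nrow(placed) || min(rowSums(sweep(placed, 2, p)^2)) >= min_sep^2
    }
    for (k in seq_len(n_shell)) {
      ph <- (k - 1L) %% n_phos + 1L
      oname <- if (((k - 1L) %/% n_phos) %% 2 == 0) "OP1" else "OP2"
      oi <- which(atoms$chain == phos_res$chain[ph] &
                    atoms$resno == phos_res$resno[ph] & atoms$elety == oname)
      o <- xyz[oi, ]
      placed_ok <- FALSE
      for (try in 1:200) {
        r <- stats::runif(1, shell_A[1], shell_A[2])
        p <- o + r * as.numeric(runif_sphere(1))
        # the *nearest* non-bridging oxygen must stay within shell_range
        d2 <- rowSums(sweep(xyz[osel, , drop = FALSE], 2, p)^2)
        if (min(d2) < shell_A[1]^2) next
        if (!ok_sep(p)) next
        placed <- rbind(placed, p)
        is_shell <- c(is_shell, TRUE)
        placed_ok <- TRUE
        break
      }
      if (!placed_ok)
        stop("could not place a shell ion respecting the 0.15 nm separation")
    }
    ctr <- colMeans(xyz)
    box_A <- spec$box * 10
    excl_A <- spec$bulk_exclusion * 10
    n_put <- 0L
    guard <- 0L
    while (n_put < spec$n_bulk) {
      guard <- guard + 1L
      if (guard > 200L * spec$n_bulk + 200L)
        stop("could not place bulk ions: box too small for exclusion zone")
      p <- ctr + (stats::runif(3) - 0.5) * box_A
      if (min(rowSums(sweep(xyz, 2, p)^2)) < excl_A^2) next
      if (!ok_sep(p)) next
      placed <- rbind(placed, p)
      is_shell <- c(is_shell, FALSE)
      n_put <- n_put + 1L
    }
    rownames(placed) <- NULL
    structure(list(cation_xyz = placed, is_shell = is_shell,
                   truth = list(ions_per_phosphate = n_shell / n_phos,
                                n_shell = n_shell, n_phosphates = n_phos,
                                spec = spec)),
              class = "ion_set")
  })
}

#' @export
print.ion_set <- function(x, ...) {
  cat(sprintf("ion_set: %d cations (%d shell, %d bulk); planted %.3f per phosphate\n",
              nrow(x$cation_xyz), sum(x$is_shell), sum(!x$is_shell),
              x$truth$ions_per_phosphate))
  invisible(x)
}
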