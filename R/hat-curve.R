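# Synthetic magnetic-tweezers rotation-extension ("hat") curves.
#
# The model is piecewise: a rounded (quadratic) cap of half-width
# `buckling_offset` turns around the curve center at the plateau extension,
# and linear plectonemic arms with the planted slopes beyond. Value and
# first derivative are continuous at the buckling points. Only the linear
# arms are ever fit; the cap shape is a smoothness convenience.

#' Specification of a synthetic rotation-extension curve
#'
#' Defaults describe a ~20.6 kbp tether measured in 5-turn steps at 0.25 pN.
#'
#' @param n_bp tether length in base pairs.
#' @param center_turns planted center of the curve (turns at which the
#'   tether is torsionally relaxed).
#' @param max_extension plateau extension, micrometer.
#' @param slope_pos,slope_neg magnitudes of the plectonemic slopes on the
#'   positive- and negative-turn side, nm per turn.
#' @param buckling_offset half-width of the rounded cap, turns.
#' @param turn_step sampling step, turns (default 5).
#' @param turn_range sampled turn window relative to `center_turns`
#'   (length 2); the default spans both linear regimes while keeping the
#'   extension positive everywhere.
#' @param noise_sd Gaussian extension noise per point, nm.
#' @param force stretching force label, pN.
#' @param salt,concentration condition label (salt name, molar).
#' @param seed integer seed.
#' @return object of class `hat_spec`.
#' @export
hat_spec <- function(n_bp = 20600, center_turns = 0, max_extension = 5.5,
                     slope_pos = 45, slope_neg = 45, buckling_offset = 25,
                     turn_step = 5, turn_range = c(-120, 120),
                     noise_sd = 20, force = 0.25,
                     salt = "KCl", concentration = 0.1, seed = 1) {
  if (n_bp <= 0) stop("n_bp must be positive")
  if (slope_pos <= 0 || slope_neg <= 0)
    stop("slopes are magnitudes and must be positive")
  if (buckling_offset <= 0) stop("buckling_offset must be positive")
  if (turn_step <= 0) stop("turn_step must be positive")
  if (length(turn_range) != 2 || diff(turn_range) <= 0)
    stop("turn_range must be an increasing (min, max) pair")
  spec <- structure(list(n_bp = as.integer(n_bp), center_turns = center_turns,
                         max_extension = max_extension, slope_pos = slope_pos,
                         slope_neg = slope_neg,
                         buckling_offset = buckling_offset,
                         turn_step = turn_step, turn_range = turn_range,
                         noise_sd = noise_sd, force = force, salt = salt,
                         concentration = concentration, seed = seed),
                    class = "hat_spec")
  # each linear regime must contain at least 3 sampled points
  turns <- .hat_turns(spec)
  rel <- turns - center_turns
  if (sum(rel <= -buckling_offset) < 3 || sum(rel >= buckling_offset) < 3)
    stop("turn_range too narrow: need >= 3 points per linear regime")
  spec
}

.hat_turns <- function(spec) {
  seq(spec$center_turns + spec$turn_range[1],
      spec$center_turns + spec$turn_range[2], by = spec$turn_step)
}

# noiseless model extension in micrometer at absolute turns t
.hat_model <- function(spec, turns) {
  rel <- turns - spec$center_turns
  b <- spec$buckling_offset
  slope <- ifelse(rel >= 0, spec$slope_pos, spec$slope_neg) / 1000  # um/turn
  cap <- spec$max_extension - slope * rel^2 / (2 * b)
  arm <- spec$max_extension - slope * (abs(rel) - b / 2)
  ext <- ifelse(abs(rel) <= b, cap, arm)
  pmax(ext, 0)
}

#' Generate a synthetic rotation-extension curve
#'
#' @param spec a [hat_spec()].
#' @return object of class `rotation_curve`: data frame fields `turns`,
#'   `extension` (micrometer) plus metadata (`force`, `n_bp`, `salt`,
#'   `concentration`) and `truth` (the spec, i.e. planted center and slopes).
#' @export
gen_hat_curve <- function(spec) {
  stopifnot(inherits(spec, "hat_spec"))
  turns <- .hat_turns(spec)
  ext <- .hat_model(spec, turns)
  with_seed(spec$seed, {
    if (spec$noise_sd > 0)
      ext <- ext + stats::rnorm(length(ext), 0, spec$noise_sd / 1000)
  })
  rotation_curve(turns, pmax(ext, 0), force = spec$force, n_bp = spec$n_bp,
                 salt = spec$salt, concentration = spec$concentration,
                 truth = spec)
}

#' Construct a rotation-extension curve object
#'
#' @param turns strictly increasing numeric vector of applied turns.
#' @param extension tether extensions, micrometer (same length, >= 7 points).
#' @param force stretching force, pN.
#' @param n_bp tether length, base pairs.
#' @param salt,concentration condition label.
#' @param truth optional planted-truth record.
#' @return object of class `rotation_curve`.
#' @export
rotation_curve <- function(turns, extension, force = NA_real_,
                           n_bp = NA_integer_, salt = NA_character_,
                           concentration = NA_real_, truth = NULL) {
  if (length(turns) != length(extension)) stop("turns/extension length mismatch")
  if (length(turns) < 7) stop("need at least 7 points")
  if (any(diff(turns) <= 0)) stop("turns must be strictly increasing")
  structure(list(turns = as.numeric(turns), extension = as.numeric(extension),
                 force = force, n_bp = n_bp, salt = salt,
                 concentration = concentration, truth = truth),
            class = "rotation_curve")
}

#' @export
print.rotation_curve <- function(x, ...) {
  cat(sprintf("rotation_curve: %d points, turns [%g, %g], %s %g M, F = %g pN\n",
              length(x$turns), min(x$turns), max(x$turns),
              x$salt, x$concentration, x$force))
  invisible(x)
}
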