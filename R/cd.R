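# Circular dichroism spectra series: synthetic generator, SVD
# decomposition, and the 280 nm band trend.

#' Specification of a synthetic CD spectra series
#'
#' The generated matrix is `sum_k basis_k outer weight_k(c)` plus Gaussian
#' noise. Defaults emulate a B-form DNA spectrum (positive bands near 225
#' and 280 nm, negative near 250 nm) whose 280 nm band is progressively
#' depressed with the square root of the salt concentration, crossing zero
#' near 4.5 M.
#'
#' @param wavelengths wavelength grid, nm.
#' @param concentrations condition axis, M (>= 2 values).
#' @param basis list of basis spectra (each `length(wavelengths)`).
#' @param weights list of functions of concentration, one per basis.
#' @param noise_sd Gaussian noise SD, M^-1 cm^-1.
#' @param seed integer seed.
#' @return object of class `cd_spec`.
#' @export
cd_spec <- function(wavelengths = seq(210, 320, by = 1),
                    concentrations = c(0.1, 0.5, 1, 2, 3, 4, 5, 6, 7, 8),
                    basis = NULL, weights = NULL,
                    noise_sd = 0.02, seed = 1) {
  if (length(concentrations) < 2) stop("need >= 2 concentrations")
  gauss <- function(l, mu, s) exp(-(l - mu)^2 / (2 * s^2))
  if (is.null(basis)) {
    basis <- list(
      b_form = 2.4 * gauss(wavelengths, 280, 14) -
        2.8 * gauss(wavelengths, 248, 12) + 1.2 * gauss(wavelengths, 222, 8),
      salt_response = -gauss(wavelengths, 281, 15)
    )
    if (is.null(weights)) {
      # second weight grows as sqrt(c), normalized to zero at 0.1 M and
      # sized so the 280 nm band changes sign near 4.5 M
      weights <- list(function(c) rep(1, length(c)),
                      function(c) 1.28812 * (sqrt(c) - sqrt(0.1)))
    }
  }
  if (is.null(weights)) stop("weights must be supplied with custom basis")
  if (length(basis) != length(weights))
    stop("basis and weights must have equal length")
  if (!all(vapply(basis, length, integer(1)) == length(wavelengths)))
    stop("basis spectra on mismatched wavelength grids")
  structure(list(wavelengths = wavelengths, concentrations = concentrations,
                 basis = basis, weights = weights, noise_sd = noise_sd,
                 seed = seed),
            class = "cd_spec")
}

#' Generate a synthetic CD spectra series
#'
#' @param spec a [cd_spec()].
#' @return object of class `spectra_set`: `wavelengths` (nm),
#'   `concentrations` (M), `dEps` matrix (rows = wavelengths, columns =
#'   conditions, M^-1 cm^-1), and `truth` (planted basis spectra and weight
#'   matrix).
#' @export
gen_cd_set <- function(spec) {
  stopifnot(inherits(spec, "cd_spec"))
  W <- vapply(spec$weights, function(w) w(spec$concentrations),
              numeric(length(spec$concentrations)))  # n_cond x n_basis
  B <- do.call(cbind, spec$basis)                    # n_wl x n_basis
  M <- B %*% t(W)
  with_seed(spec$seed, {
    if (spec$noise_sd > 0)
      M <- M + matrix(stats::rnorm(length(M), 0, spec$noise_sd), nrow(M))
  })
  spectra_set(spec$wavelengths, spec$concentrations, M,
              truth = list(basis = B, weights = W, spec = spec))
}

#' Construct a CD spectra set
#'
#' @param wavelengths wavelength grid, nm.
#' @param concentrations condition axis, M.
#' @param dEps matrix `length(wavelengths) x length(concentrations)` of
#'   Delta-epsilon values, M^-1 cm^-1.
#' @param truth optional planted-truth record.
#' @return object of class `spectra_set`.
#' @export
spectra_set <- function(wavelengths, concentrations, dEps, truth = NULL) {
  dEps <- as.matrix(dEps)
  if (nrow(dEps) != length(wavelengths) ||
      ncol(dEps) != length(concentrations))
    stop("dEps must be |wavelengths| x |concentrations|")
  structure(list(wavelengths = wavelengths, concentrations = concentrations,
                 dEps = dEps, truth = truth),
            class = "spectra_set")
}

#' SVD decomposition of a CD spectra series
#'
#' Full singular value decomposition of the (by default uncentered) matrix.
#' The signal rank is estimated as the number of singular values above a
#' noise floor computed from the trailing half of the spectrum as
#' `median + 5 * MAD`.
#'
#' @param set a `spectra_set`.
#' @param center if TRUE, column-center before decomposing (off by
#'   default).
#' @return object of class `cd_svd`: `d` (singular values, descending),
#'   `basis` (left singular vectors, columns), `coefficients` (right
#'   singular vectors scaled by singular values: condition weights),
#'   `rank`, `noise_floor`, `centered`.
#' @export
svd_decompose <- function(set, center = FALSE) {
  stopifnot(inherits(set, "spectra_set"))
  M <- set$dEps
  if (anyNA(M)) stop("NAs in spectra matrix")
  if (ncol(M) < 2) stop("need >= 2 conditions")
  if (center) M <- sweep(M, 2, colMeans(M))
  s <- svd(M)
  k <- length(s$d)
  tail_idx <- seq(floor(k / 2) + 1L, k)
  floor_est <- stats::median(s$d[tail_idx]) +
    5 * stats::mad(s$d[tail_idx], constant = 1.4826)
  structure(list(d = s$d, basis = s$u,
                 coefficients = t(s$d * t(s$v)),  # v scaled: d_j * v[, j]
                 rank = sum(s$d > floor_est + 1e-12 * s$d[1]),
                 noise_floor = floor_est, centered = center,
                 wavelengths = set$wavelengths,
                 concentrations = set$concentrations),
            class = "cd_svd")
}

#' @export
print.cd_svd <- function(x, ...) {
  cat(sprintf("cd_svd: estimated signal rank %d; singular values %s ...\n",
              x$rank, paste(signif(utils::head(x$d, 4), 4), collapse = ", ")))
  invisible(x)
}

#' Band trend at a fixed wavelength across the concentration series
#'
#' Extracts the band amplitude at the grid wavelength nearest `lambda0`,
#' references it to the `ref_conc` condition
#' (`dd = dEps(c) - dEps(ref)`), fits the square-root law
#' `dd = b (sqrt(c) - sqrt(ref))` and a free-exponent variant
#' `dd = b (c^alpha - ref^alpha)`, and locates sign changes of the band by
#' linear interpolation in concentration.
#'
#' @param set a `spectra_set`.
#' @param lambda0 band wavelength, nm (default 280).
#' @param ref_conc reference concentration, M (default 0.1; must be a
#'   condition of the set).
#' @return object of class `band_trend`: `table` (concentration, band
#'   value, referenced difference), `b`, `residual_sd`, `alpha_free`,
#'   `b_free`, `sign_changes` (concentrations where the band crosses
#'   zero), `lambda_used`.
#' @export
band_trend <- function(set, lambda0 = 280, ref_conc = 0.1) {
  stopifnot(inherits(set, "spectra_set"))
  iw <- which.min(abs(set$wavelengths - lambda0))
  band <- set$dEps[iw, ]
  ir <- which(abs(set$concentrations - ref_conc) < 1e-9)
  if (!length(ir)) stop("reference concentration not in the series")
  conc <- set$concentrations
  dd <- band - band[ir[1]]
  x_half <- sqrt(conc) - sqrt(ref_conc)
  b <- sum(x_half * dd) / sum(x_half^2)
  resid <- dd - b * x_half
  rss_free <- function(alpha) {
    x <- conc^alpha - ref_conc^alpha
    bb <- sum(x * dd) / sum(x^2)
    sum((dd - bb * x)^2)
  }
  opt <- stats::optimize(rss_free, c(0.05, 3))
  alpha_free <- opt$minimum
  xf <- conc^alpha_free - ref_conc^alpha_free
  b_free <- sum(xf * dd) / sum(xf^2)
  sc <- numeric(0)
  for (i in seq_len(length(conc) - 1)) {
    if (band[i] == 0) sc <- c(sc, conc[i])
    else if (band[i] * band[i + 1] < 0)
      sc <- c(sc, conc[i] + (conc[i + 1] - conc[i]) *
                abs(band[i]) / (abs(band[i]) + abs(band[i + 1])))
  }
  structure(list(table = data.frame(concentration = conc, band = band,
                                    dd = dd),
                 b = b, residual_sd = stats::sd(resid),
                 alpha_free = alpha_free, b_free = b_free,
                 sign_changes = sc,
                 lambda_used = set$wavelengths[iw], ref_conc = ref_conc),
            class = "band_trend")
}

#' @export
print.band_trend <- function(x, ...) {
  cat(sprintf("band_trend @ %g nm: b = %.4f (sqrt law), free exponent %.3f; sign changes at %s M\n",
              x$lambda_used, x$b, x$alpha_free,
              if (length(x$sign_changes))
                paste(signif(x$sign_changes, 3), collapse = ", ") else "none"))
  invisible(x)
}
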