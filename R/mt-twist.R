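# Twist quantification from rotation-extension curves: plectonemic
# segmentation, linear slope fits, intersection centers, twist changes
# relative to a reference condition, force calibration, and the
# concentration power law.

#' Segment the plectonemic regimes of a rotation curve
#'
#' The plateau is estimated as the mean of the three largest extensions;
#' points with extension below `threshold * plateau` on each side of the
#' curve maximum belong to the plectonemic (linear) regimes.
#'
#' @param curve a `rotation_curve`.
#' @param threshold fraction of the plateau below which a point is
#'   plectonemic (default 0.85).
#' @return list with integer index vectors `neg_range` and `pos_range` and
#'   the `plateau` estimate; errors if either side has fewer than 3 points
#'   (the curve is rejected, as an unsuitable tether would be).
#' @export
segment_plectonemic <- function(curve, threshold = 0.85) {
  stopifnot(inherits(curve, "rotation_curve"))
  ext <- curve$extension
  plateau <- mean(sort(ext, decreasing = TRUE)[1:3])
  peak <- curve$turns[which.max(ext)]
  low <- ext < threshold * plateau
  neg <- which(low & curve$turns < peak)
  pos <- which(low & curve$turns > peak)
  if (length(neg) < 3 || length(pos) < 3)
    stop("curve rejected: fewer than 3 plectonemic points on one side")
  list(neg_range = neg, pos_range = pos, plateau = plateau,
       threshold = threshold)
}

#' Fit the plectonemic slopes and the curve center
#'
#' Ordinary least-squares lines are fit to the extension (nm) versus turns
#' on each plectonemic side; the curve center is the abscissa of the
#' intersection of the two lines, with its standard error propagated from
#' the two fit covariance matrices. Optionally (`method = "midpoint"`) the
#' center is instead the midpoint of the two lines' intersections with the
#' plateau level.
#'
#' @param curve a `rotation_curve`.
#' @param threshold passed to [segment_plectonemic()].
#' @param method `"intersection"` (default) or `"midpoint"`.
#' @return object of class `hat_fit`: slopes (nm/turn, signed) with SEs,
#'   `center_turns` with SE, fit ranges, residual SD.
#' @export
fit_hat <- function(curve, threshold = 0.85,
                    method = c("intersection", "midpoint")) {
  method <- match.arg(method)
  seg <- segment_plectonemic(curve, threshold)
  ext_nm <- curve$extension * 1000
  # OLS per side with covariance computed directly (a perfect noiseless fit
  # then simply yields a zero covariance, no degenerate-summary warnings)
  fitside <- function(idx) {
    t <- curve$turns[idx]; e <- ext_nm[idx]
    X <- cbind(1, t)
    XtXi <- solve(crossprod(X))
    beta <- as.numeric(XtXi %*% crossprod(X, e))
    res <- e - X %*% beta
    sigma2 <- sum(res^2) / (length(e) - 2)
    list(coef = beta, vcov = sigma2 * XtXi, resid = as.numeric(res))
  }
  fn <- fitside(seg$neg_range)
  fp <- fitside(seg$pos_range)
  bn <- fn$coef; bp_ <- fp$coef
  if (abs(bp_[2] - bn[2]) < 1e-9)
    stop("plectonemic lines are parallel: no intersection")
  # intersection abscissa and its SE by the delta method
  num <- bn[1] - bp_[1]
  den <- bp_[2] - bn[2]
  center <- as.numeric(num / den)
  Vn <- fn$vcov; Vp <- fp$vcov
  g <- c(1 / den, center / den)   # d center / d (a, b) for the neg line
  h <- c(-1 / den, -center / den)
  se <- sqrt(as.numeric(t(g) %*% Vn %*% g + t(h) %*% Vp %*% h))
  if (method == "midpoint") {
    plateau_nm <- seg$plateau * 1000
    tn <- (plateau_nm - bn[1]) / bn[2]
    tp <- (plateau_nm - bp_[1]) / bp_[2]
    center <- (tn + tp) / 2
  }
  peak <- curve$turns[which.max(curve$extension)]
  rsd <- sqrt((sum(fn$resid^2) + sum(fp$resid^2)) /
                (length(seg$neg_range) + length(seg$pos_range) - 4))
  structure(list(slope_neg = as.numeric(bn[2]),
                 slope_neg_se = sqrt(Vn[2, 2]),
                 slope_pos = as.numeric(bp_[2]),
                 slope_pos_se = sqrt(Vp[2, 2]),
                 center_turns = center, center_se = se,
                 neg_range = range(curve$turns[seg$neg_range]),
                 pos_range = range(curve$turns[seg$pos_range]),
                 residual_sd = rsd, method = method,
                 n_bp = curve$n_bp, salt = curve$salt,
                 concentration = curve$concentration),
            class = "hat_fit")
}

#' @export
print.hat_fit <- function(x, ...) {
  cat(sprintf("hat_fit: center %.2f +/- %.2f turns; slopes %+.1f / %+.1f nm/turn\n",
              x$center_turns, x$center_se, x$slope_neg, x$slope_pos))
  invisible(x)
}

#' Twist change between two rotation-curve fits
#'
#' `Delta Tw = (center - center_ref) * 360 / n_bp` in degrees per base pair;
#' positive when the curve shifts to larger turns (increasing helical
#' twist).
#'
#' @param fit,ref `hat_fit` objects for the test and reference condition of
#'   the same tether.
#' @param n_bp tether length in base pairs (default taken from `fit`).
#' @return twist change in degrees per bp.
#' @export
delta_twist <- function(fit, ref, n_bp = fit$n_bp) {
  if (is.null(n_bp) || is.na(n_bp) || n_bp <= 0) stop("n_bp must be positive")
  (fit$center_turns - ref$center_turns) * 360 / n_bp
}

#' Force from transverse bead fluctuations (equipartition)
#'
#' `F = kB T * extension / var_x` with kB T = 4.075 pN nm at 295.15 K
#' (~22 C room temperature).
#'
#' @param var_x variance of the transverse bead position, nm^2.
#' @param extension mean tether extension, nm.
#' @param temperature absolute temperature, K.
#' @return force in pN.
#' @export
calibrate_force <- function(var_x, extension, temperature = 295.15) {
  if (any(var_x <= 0) || any(extension <= 0) || temperature <= 0)
    stop("var_x, extension and temperature must be positive")
  kB <- 1.380649e-2   # pN nm / K
  kB * temperature * extension / var_x
}

#' Power-law fit of twist change versus concentration
#'
#' Weighted least squares of `dTw = a + b * c^alpha` over records with
#' concentration at most `c_max`. The `fixed_half` variant holds alpha at
#' 0.5 (square-root dependence, linear WLS); `free_alpha` profiles alpha by
#' 1-D optimization with the linear parameters solved per alpha.
#'
#' @param records data frame with columns `concentration` (M), `delta_tw`
#'   (deg/bp) and optionally `sd` (used as 1/sd^2 weights; unweighted when
#'   absent or non-positive).
#' @param variant `"fixed_half"` or `"free_alpha"`.
#' @param c_max concentration cutoff, M (default 2).
#' @return object of class `power_law_fit` with `a`, `b`, `alpha`,
#'   `residual_sd` (weighted RMS residual), covariance of (a, b), fitted
#'   values, and the variant flag.
#' @export
fit_power_law <- function(records, variant = c("fixed_half", "free_alpha"),
                          c_max = 2) {
  variant <- match.arg(variant)
  r <- records[records$concentration <= c_max, , drop = FALSE]
  need <- if (variant == "free_alpha") 4 else 3
  if (nrow(r) < need)
    stop(sprintf("need >= %d records for variant %s", need, variant))
  if (length(unique(r$concentration)) < 2)
    stop("singular design: all concentrations equal")
  w <- if (!is.null(r$sd) && all(is.finite(r$sd)) && all(r$sd > 0))
    1 / r$sd^2 else rep(1, nrow(r))
  wls <- function(alpha) {
    x <- r$concentration^alpha
    f <- stats::lm(delta_tw ~ x, data = data.frame(delta_tw = r$delta_tw,
                                                   x = x), weights = w)
    list(fit = f, rss = sum(w * stats::resid(f)^2))
  }
  if (variant == "fixed_half") {
    alpha <- 0.5
    sol <- wls(alpha)
  } else {
    opt <- stats::optimize(function(a) wls(a)$rss, c(0.05, 3))
    alpha <- opt$minimum
    sol <- wls(alpha)
  }
  cf <- stats::coef(sol$fit)
  structure(list(a = as.numeric(cf[1]), b = as.numeric(cf[2]), alpha = alpha,
                 covariance = suppressWarnings(stats::vcov(sol$fit)),
                 residual_sd = sqrt(sol$rss / sum(w) * nrow(r) /
                                      max(1, nrow(r) - 2)),
                 fitted = stats::fitted(sol$fit),
                 records = r, variant = variant, c_max = c_max),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("power_law_fit (%s): dTw = %.4f + %.4f * c^%.3f; resid SD %.4f deg/bp\n",
              x$variant, x$a, x$b, x$alpha, x$residual_sd))
  invisible(x)
}

#' Recover a twist-change table from planted synthetic curves
#'
#' For each condition, generates `n_molecules` seeded hat curves with the
#' planted twist change encoded as a center shift (together with an
#' identically generated reference curve per molecule), fits every curve,
#' computes the per-molecule twist change, and aggregates the unweighted
#' mean and SD over molecules. Per-curve fit failures are counted and
#' reported, not propagated.
#'
#' @param conditions data frame with columns `salt`, `concentration` (M) and
#'   `delta_tw` (planted twist change, deg/bp). The reference condition is
#'   planted at zero shift.
#' @param n_molecules curves per condition (default 11).
#' @param noise_sd extension noise per point, nm (default 20).
#' @param n_bp tether length (default 20600).
#' @param seed master seed; per-curve seeds are derived deterministically.
#' @param hat_defaults optional named list overriding [hat_spec()] defaults.
#' @return data frame of class `twist_change_table`: `salt`, `conc_M`,
#'   `delta_tw_deg_per_bp`, `sd`, `n`, `planted`, `n_failed`.
#' @export
recover_table <- function(conditions, n_molecules = 11, noise_sd = 20,
                          n_bp = 20600, seed = 1, hat_defaults = list()) {
  if (!all(c("salt", "concentration", "delta_tw") %in% names(conditions)))
    stop("conditions needs columns salt, concentration, delta_tw")
  out <- vector("list", nrow(conditions))
  for (i in seq_len(nrow(conditions))) {
    shift <- conditions$delta_tw[i] * n_bp / 360
    vals <- numeric(0)
    failed <- 0L
    for (m in seq_len(n_molecules)) {
      # derived in double precision to avoid 32-bit overflow for any seed
      s_test <- as.integer((as.numeric(seed) * 100003 + i * 613 + m * 2) %%
                             2147483587)
      s_ref <- s_test + 1L
      args_t <- utils::modifyList(
        list(n_bp = n_bp, center_turns = shift, noise_sd = noise_sd,
             salt = conditions$salt[i],
             concentration = conditions$concentration[i], seed = s_test),
        hat_defaults)
      args_r <- utils::modifyList(
        list(n_bp = n_bp, center_turns = 0, noise_sd = noise_sd,
             salt = "KCl", concentration = 0.1, seed = s_ref),
        hat_defaults)
      dtw <- tryCatch({
        ft <- fit_hat(gen_hat_curve(do.call(hat_spec, args_t)))
        fr <- fit_hat(gen_hat_curve(do.call(hat_spec, args_r)))
        delta_twist(ft, fr, n_bp)
      }, error = function(e) NA_real_)
      if (is.na(dtw)) failed <- failed + 1L else vals <- c(vals, dtw)
    }
    out[[i]] <- data.frame(
      salt = conditions$salt[i], conc_M = conditions$concentration[i],
      delta_tw_deg_per_bp = mean(vals),
      sd = if (length(vals) > 1) stats::sd(vals) else 0,
      n = length(vals), planted = conditions$delta_tw[i], n_failed = failed,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  class(res) <- c("twist_change_table", class(res))
  res
}

#' Published twist-change measurements for alkali chlorides
#'
#' Mean +/- SD twist changes of a 20.6 kbp DNA tether relative to 100 mM
#' KCl, from multiplexed magnetic-tweezers measurements (at least three,
#' typically 10-20 molecules per condition). Used as planted ground truth
#' for synthetic reconstructions and as input to the concentration power
#' law.
#'
#' @return data frame with columns `salt`, `concentration` (M), `delta_tw`
#'   (deg/bp), `sd` (deg/bp).
#' @export
alkali_twist_reference <- function() {
  rbind(
    data.frame(salt = "LiCl",
               concentration = c(0.1, 0.5, 1, 2, 3, 4, 5, 6, 7, 8),
               delta_tw = c(0.03, 0.21, 0.38, 0.59, 0.71, 0.74, 0.72,
                            0.69, 0.66, 0.66),
               sd = c(0.03, 0.02, 0.02, 0.05, 0.05, 0.04, 0.04, 0.05,
                      0.05, 0.07)),
    data.frame(salt = "NaCl",
               concentration = c(0.1, 0.5, 1, 2, 3, 4, 5),
               delta_tw = c(-0.12, 0.01, 0.12, 0.24, 0.32, 0.37, 0.40),
               sd = c(0.02, 0.01, 0.01, 0.02, 0.02, 0.02, 0.02)),
    data.frame(salt = "KCl",
               concentration = c(0.1, 0.5, 1, 2, 3, 4),
               delta_tw = c(0, 0.14, 0.26, 0.40, 0.49, 0.52),
               sd = c(0, 0.03, 0.03, 0.03, 0.02, 0.01)),
    data.frame(salt = "CsCl",
               concentration = c(0.1, 0.5, 1, 2, 3, 4, 5, 6, 7),
               delta_tw = c(0.12, 0.27, 0.37, 0.49, 0.56, 0.56, 0.52,
                            0.44, 0.37),
               sd = c(0.01, 0.01, 0.01, 0.02, 0.01, 0.01, 0.02, 0.02,
                      0.02))
  )
}
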