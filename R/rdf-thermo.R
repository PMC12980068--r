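# Synthetic radial distribution functions and Kirkwood-Buff analysis for a
# binary 1:1 electrolyte. Lengths in nm; number densities in ions/nm^3.

#' Specification of synthetic cation-cation / cation-anion RDFs
#'
#' Three analytic models, each with a closed-form Kirkwood-Buff integral
#' recorded as planted truth:
#' `ideal` (g = 1 everywhere), `square_well` (g = 1 + delta on
#' `[r_lo, r_hi]`), and `gaussian_peaks` (g = 1 + sum of Gaussian bumps).
#'
#' @param model one of `"ideal"`, `"square_well"`, `"gaussian_peaks"`.
#' @param params list per pair (`cc`, `ca`), each a list of model
#'   parameters: square_well needs `r_lo`, `r_hi` (nm) and `delta` (height
#'   above 1, may be negative but g must stay >= 0); gaussian_peaks needs
#'   vectors `centers`, `widths` (nm) and `amplitudes`.
#' @param rho_c cation number density, ions/nm^3.
#' @param r_max grid maximum, nm.
#' @param dr grid spacing, nm.
#' @return object of class `rdf_spec`.
#' @export
rdf_spec <- function(model = c("ideal", "square_well", "gaussian_peaks"),
                     params = list(cc = list(), ca = list()),
                     rho_c = 2.65, r_max = 2.0, dr = 0.002) {
  model <- match.arg(model)
  if (dr <= 0 || r_max <= dr) stop("need r_max > dr > 0")
  structure(list(model = model, params = params, rho_c = rho_c,
                 r_max = r_max, dr = dr),
            class = "rdf_spec")
}

# evaluate one model g(r) and its analytic KB integral
.rdf_eval <- function(model, p, r) {
  if (model == "ideal") {
    list(g = rep(1, length(r)), G = 0)
  } else if (model == "square_well") {
    w <- as.numeric(r > p$r_lo & r < p$r_hi)
    # grid points landing exactly on a discontinuity carry the mean value,
    # which makes the trapezoid-rule KB integral exact to O(dr^2)
    w[abs(r - p$r_lo) < 1e-12 | abs(r - p$r_hi) < 1e-12] <- 0.5
    g <- 1 + p$delta * w
    G <- 4 * pi * p$delta * (p$r_hi^3 - p$r_lo^3) / 3
    list(g = g, G = G)
  } else {
    g <- rep(1, length(r))
    G <- 0
    for (k in seq_along(p$centers)) {
      mu <- p$centers[k]; s <- p$widths[k]; A <- p$amplitudes[k]
      g <- g + A * exp(-(r - mu)^2 / (2 * s^2))
      # closed form of 4 pi A int_0^inf exp(-(r-mu)^2/2s^2) r^2 dr
      G <- G + 4 * pi * A * (sqrt(2 * pi) * s * (mu^2 + s^2) *
                               stats::pnorm(mu / s) +
                               s^2 * mu * exp(-mu^2 / (2 * s^2)))
    }
    list(g = g, G = G)
  }
}

#' Generate tabulated cation-cation and cation-anion RDFs
#'
#' @param spec an [rdf_spec()].
#' @return object of class `rdf_table`: data frame `r_nm`, `g_cc`, `g_ca`
#'   plus `rho_c` and `truth` (planted analytic Kirkwood-Buff integrals
#'   `G_cc`, `G_ca` in nm^3).
#' @export
gen_rdf <- function(spec) {
  stopifnot(inherits(spec, "rdf_spec"))
  r <- seq(spec$dr, spec$r_max, by = spec$dr)
  cc <- .rdf_eval(spec$model, spec$params$cc, r)
  ca <- .rdf_eval(spec$model, spec$params$ca, r)
  if (any(cc$g < 0) || any(ca$g < 0)) stop("negative g(r) in generated RDF")
  structure(list(table = data.frame(r_nm = r, g_cc = cc$g, g_ca = ca$g),
                 rho_c = spec$rho_c,
                 truth = list(G_cc = cc$G, G_ca = ca$G, spec = spec)),
            class = "rdf_table")
}

#' Kirkwood-Buff integral of a tabulated RDF
#'
#' `G = 4 pi int_0^Rc (g(r) - 1) r^2 dr` by the composite trapezoid rule on
#' the tabulated grid (the implicit point g(0) = 0 at r = 0 is included).
#' Also reports the running integral averaged over a tail window
#' `[Rc - w, Rc]`, a simple guard against truncation ripple.
#'
#' @param rdf an `rdf_table` (or data frame with columns `r_nm` and the
#'   requested pair column).
#' @param pair `"cc"` or `"ca"`.
#' @param R_c integration cutoff, nm (default: the full tabulated range).
#' @param tail_window width of the tail averaging window, nm (default 0.3).
#' @return list with `G` (nm^3), `G_tail` (tail-window average), and the
#'   running-integral data frame `running` (`r_nm`, `G`).
#' @export
kb_integral <- function(rdf, pair = c("cc", "ca"), R_c = NULL,
                        tail_window = 0.3) {
  pair <- match.arg(pair)
  tab <- if (inherits(rdf, "rdf_table")) rdf$table else rdf
  col <- paste0("g_", pair)
  if (!col %in% names(tab)) stop("missing column ", col)
  r <- tab$r_nm
  if (is.null(R_c)) R_c <- max(r)
  if (R_c > max(r) + 1e-9) stop("R_c beyond tabulated range")
  keep <- r <= R_c + 1e-12
  r <- c(0, r[keep])
  h <- c(-1, tab[[col]][keep] - 1)  # g(0) = 0
  f <- 4 * pi * h * r^2
  # cumulative trapezoid
  G_run <- cumsum(c(0, diff(r) * (utils::head(f, -1) + utils::tail(f, -1)) / 2))
  running <- data.frame(r_nm = r, G = G_run)
  G <- G_run[length(G_run)]
  tw <- running[running$r_nm >= R_c - tail_window, , drop = FALSE]
  list(G = G, G_tail = mean(tw$G), running = running, R_c = R_c)
}

#' Activity derivative of a binary 1:1 electrolyte
#'
#' Standard Kirkwood-Buff form `a_cc = 1 / (1 + rho_c (G_cc - G_ca))`,
#' equal to 1 in the ideal limit. A custom `formula` hook may replace the
#' convention (signature `function(G_cc, G_ca, rho_c)`).
#'
#' @param G_cc,G_ca cation-cation and cation-anion Kirkwood-Buff integrals,
#'   nm^3.
#' @param rho_c cation number density, ions/nm^3.
#' @param formula optional replacement convention.
#' @return dimensionless activity derivative (> 0 on the stable domain).
#' @export
activity_derivative <- function(G_cc, G_ca, rho_c, formula = NULL) {
  if (!is.null(formula)) return(formula(G_cc, G_ca, rho_c))
  den <- 1 + rho_c * (G_cc - G_ca)
  if (any(den <= 0))
    stop("denominator <= 0: thermodynamically unstable input")
  1 / den
}

#' Molality to molarity conversion
#'
#' Given a molality (mol salt per kg water), the number of water molecules
#' in the simulation box, and the averaged box volume, computes the molar
#' concentration: `n_salt = m * n_water * M_w` with the molar mass of water
#' `M_w = 0.0180153 kg/mol`, and `c = n_salt / (N_A V)`.
#'
#' @param m molality, mol/kg.
#' @param box_volume averaged box volume, nm^3.
#' @param n_water number of water molecules.
#' @return concentration in mol/L.
#' @export
molality_to_molarity <- function(m, box_volume, n_water) {
  if (any(box_volume <= 0)) stop("box volume must be positive")
  NA_const <- 6.02214076e23
  n_salt <- m * n_water * 0.0180153
  n_salt / (NA_const * box_volume * 1e-24)
}

#' Number of ion pairs to molarity
#'
#' @param n_pairs number of salt ion pairs in the box.
#' @param box_volume box volume, nm^3.
#' @return concentration in mol/L.
#' @export
pairs_to_molarity <- function(n_pairs, box_volume) {
  if (any(box_volume <= 0)) stop("box volume must be positive")
  n_pairs / (6.02214076e23 * box_volume * 1e-24)
}

#' Map twist changes onto the activity-derivative scale
#'
#' Annotates each twist-change record with the activity derivative
#' interpolated (linearly in concentration) from an
#' `a_cc`-versus-concentration curve, and sorts by `a_cc`. Records outside
#' the curve's concentration range are flagged (`extrapolated = TRUE`,
#' `a_cc = NA`) rather than silently extrapolated.
#'
#' Also reports a plateau estimate: the smallest `a_cc` beyond which the
#' local slope `d(dTw)/d(a_cc)` stays below `plateau_frac` times the
#' initial slope.
#'
#' @param twist_records data frame with columns `concentration`, `delta_tw`.
#' @param activity_curve data frame with columns `concentration`, `a_cc`
#'   (monotone in concentration).
#' @param plateau_frac slope fraction defining the plateau (default 0.1).
#' @return list with `table` (records + `a_cc`, `extrapolated`, sorted by
#'   `a_cc`) and `plateau_acc` (NA if no plateau is reached).
#' @export
twist_vs_activity <- function(twist_records, activity_curve,
                              plateau_frac = 0.1) {
  stopifnot(all(c("concentration", "delta_tw") %in% names(twist_records)),
            all(c("concentration", "a_cc") %in% names(activity_curve)))
  ac <- activity_curve[order(activity_curve$concentration), ]
  if (any(ac$a_cc <= 0)) stop("activity derivatives must be positive")
  lo <- min(ac$concentration); hi <- max(ac$concentration)
  out <- twist_records
  out$extrapolated <- out$concentration < lo - 1e-12 |
    out$concentration > hi + 1e-12
  out$a_cc <- NA_real_
  inr <- !out$extrapolated
  out$a_cc[inr] <- stats::approx(ac$concentration, ac$a_cc,
                                 xout = out$concentration[inr])$y
  ord <- order(out$a_cc, na.last = TRUE)
  out <- out[ord, ]
  plat <- NA_real_
  tt <- out[!is.na(out$a_cc), ]
  if (nrow(tt) >= 3) {
    sl <- diff(tt$delta_tw) / diff(tt$a_cc)
    ref_slope <- abs(sl[1])
    if (ref_slope > 0) {
      below <- abs(sl) < plateau_frac * ref_slope
      # plateau = first point from which all later slopes stay small
      idx <- which(rev(cumprod(rev(below))) == 1)
      if (length(idx)) plat <- tt$a_cc[min(idx)]
    }
  }
  list(table = out, plateau_acc = plat)
}
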