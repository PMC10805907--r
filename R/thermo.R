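#' Boltzmann fit of an equilibrium denaturant titration
#'
#' Single form: `y = (I1 - I2) / (1 + exp((c - c0)/dc)) + I2`, so that
#' `y -> I1` at low denaturant, `y -> I2` at high denaturant and
#' `y(c0) = (I1 + I2)/2`. The double form adds a second transition with
#' shared width and fractional amplitude `f1`:
#' `y = I2 + (I1-I2) f1 / (1 + exp((c - c01)/dc)) +
#'  (I1-I2)(1-f1) / (1 + exp((c - c02)/dc))`.
#'
#' @param conc denaturant concentrations (M), strictly increasing.
#' @param y observable (tryptophan intensity or mean FRET efficiency).
#' @param double fit the double-Boltzmann form.
#' @param weights optional fit weights.
#' @param start optional named start values.
#' @return list with the fitted parameters (`I1`, `I2`, `c0` or
#'   `c0_1`/`c0_2`/`f1`, `dc`), `chi2_red`, a `predict` function of
#'   concentration, and the underlying fit object.
#' @export
boltzmann_fit <- function(conc, y, double = FALSE, weights = NULL,
                          start = NULL) {
  stopifnot(length(conc) == length(y), all(diff(conc) > 0))
  if (length(conc) < (if (double) 8 else 6))
    stop("too few titration points")
  d <- data.frame(c = conc, y = y)
  if (is.null(weights)) weights <- rep(1, nrow(d))
  I1s <- y[1]; I2s <- y[length(y)]
  mid <- conc[which.min(abs(y - (I1s + I2s) / 2))]
  if (!double) {
    st <- list(I1 = I1s, I2 = I2s, c0 = mid,
               dc = diff(range(conc)) / 10)
    if (!is.null(start)) st[names(start)] <- start
    fit <- minpack.lm::nlsLM(y ~ (I1 - I2) / (1 + exp((c - c0) / dc)) + I2,
                             data = d, start = st, weights = weights,
                             control = minpack.lm::nls.lm.control(maxiter = 500))
  } else {
    st <- list(I1 = I1s, I2 = I2s, c0_1 = mid * 0.7, c0_2 = mid * 1.3,
               dc = diff(range(conc)) / 10, f1 = 0.5)
    if (!is.null(start)) st[names(start)] <- start
    dbl_eval <- function(p, cc)
      p[["I2"]] + (p[["I1"]] - p[["I2"]]) * p[["f1"]] /
        (1 + exp((cc - p[["c0_1"]]) / p[["dc"]])) +
      (p[["I1"]] - p[["I2"]]) * (1 - p[["f1"]]) /
        (1 + exp((cc - p[["c0_2"]]) / p[["dc"]]))
    ## raw Levenberg-Marquardt interface: a single-transition data set
    ## makes the double form rank-deficient, which the nls-style gradient
    ## check rejects outright while damped LM handles it gracefully
    fit <- minpack.lm::nls.lm(
      par = unlist(st),
      fn = function(p) sqrt(weights) * (y - dbl_eval(as.list(p), conc)),
      lower = c(-Inf, -Inf, min(conc), min(conc), 1e-6, 0),
      upper = c(Inf, Inf, max(conc), max(conc), Inf, 1),
      control = minpack.lm::nls.lm.control(maxiter = 500))
    cf <- as.list(fit$par)
    cf$chi2_red <- sum(fit$fvec^2) / max(length(y) - 6, 1)
    cf$fit <- fit
    cf$predict <- function(cc) dbl_eval(as.list(fit$par), cc)
    return(cf)
  }
  cf <- as.list(stats::coef(fit))
  res <- stats::resid(fit)
  cf$chi2_red <- sum(weights * res^2) / max(length(y) - length(stats::coef(fit)), 1)
  cf$fit <- fit
  cf$predict <- function(cc) stats::predict(fit, newdata = data.frame(c = cc))
  cf
}

#' Single-exponential refolding kinetics fit
#'
#' Fits baseline-subtracted refolding traces (signal rising from 0) with
#' `y = A (1 - exp(-k t))` and reports the rate and the half-life
#' `t_1/2 = ln(2)/k`.
#'
#' @param t time (s).
#' @param y baseline-subtracted signal.
#' @return list with `k_per_s`, `t_half_s`, `A`, and the fit object.
#' @export
refolding_fit <- function(t, y) {
  stopifnot(length(t) == length(y))
  if (length(t) < 5) stop("too few time points")
  if (stats::sd(y) < 1e-12 * max(abs(y), 1))
    stop("flat trace: rate unidentifiable")
  if (any(diff(y) < -3 * stats::sd(diff(y))))
    warning("non-monotone refolding trace")
  A0 <- max(y)
  k0 <- 1 / t[which.min(abs(y - 0.63 * A0))]
  fit <- minpack.lm::nlsLM(y ~ A * (1 - exp(-k * t)),
                           data = data.frame(t = t, y = y),
                           start = list(A = A0, k = k0),
                           control = minpack.lm::nls.lm.control(maxiter = 500))
  k <- stats::coef(fit)[["k"]]
  list(k_per_s = k, t_half_s = log(2) / k, A = stats::coef(fit)[["A"]],
       fit = fit)
}

#' Apparent folding barrier from the Kramers relation
#'
#' Inverts `tau_f ~ 2 pi tau_0 exp(dG_f / (R T))` to
#' `dG_f = R T ln(tau_f / (2 pi tau_0))`, where `tau_0` is the
#' reconfiguration time of the unfolded chain (the pre-exponential
#' factor, here taken from the relaxation time of the fast
#' unfolded/compact interconversion) and `tau_f` the characteristic
#' folding time. When a folding rate is supplied it is converted to a
#' time via the half-life `tau_f = ln(2)/k_f` (default) or `tau_f = 1/k_f`.
#'
#' @param k_f folding rate (1/s); alternatively give `tau_f_s` directly.
#' @param tau_f_s folding time (s).
#' @param tau0_s reconfiguration time (s).
#' @param temperature_K temperature (K); default 295 (room temperature).
#' @param rate_convention "half_life" (`ln 2 / k`) or "inverse" (`1/k`).
#' @return Gibbs free-energy barrier in kJ/mol.
#' @export
kramers_dG <- function(k_f = NULL, tau_f_s = NULL, tau0_s,
                       temperature_K = 295,
                       rate_convention = c("half_life", "inverse")) {
  rate_convention <- match.arg(rate_convention)
  if (is.null(tau_f_s)) {
    if (is.null(k_f)) stop("supply k_f or tau_f_s")
    tau_f_s <- if (rate_convention == "half_life") log(2) / k_f else 1 / k_f
  }
  stopifnot(tau_f_s > 0, tau0_s > 0, temperature_K > 0)
  if (tau_f_s < 2 * pi * tau0_s)
    warning("tau_f below 2 pi tau_0: negative barrier")
  R <- 8.314462618e-3 # kJ/(mol K)
  R * temperature_K * log(tau_f_s / (2 * pi * tau0_s))
}
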