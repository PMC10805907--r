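## Model TCSPC channel probabilities: single-exponential decay circularly
## convolved with the (normalized) IRF histogram. Circular convolution via
## FFT handles the periodic wrap of late photons exactly.
.decay_model <- function(tau_ch, n_ch, irf) {
  ## bin-start sampling: with a one-bin (delta) IRF this reproduces the
  ## binned exponential exactly up to normalization
  d <- exp(-(seq_len(n_ch) - 1) / tau_ch)
  irf <- irf / sum(irf)
  m <- Re(stats::fft(stats::fft(irf) * stats::fft(d), inverse = TRUE)) / n_ch
  m <- pmax(m, 1e-300)
  m / sum(m)
}

#' Burst-wise donor lifetime by photon maximum likelihood
#'
#' Estimates a single-exponential fluorescence lifetime from the microtime
#' channels of one burst's donor photons, with the instrument response
#' function accounted for by circular convolution (which also models the
#' periodic wrap at the excitation period). The estimate maximizes the
#' multinomial photon likelihood; the standard error comes from the
#' observed Fisher information.
#'
#' @param micro_ch integer microtime channels, relative to the start of
#'   the donor excitation window (`0 .. n_ch-1`).
#' @param irf IRF microtime histogram over the same `n_ch` channels (any
#'   scale; a delta IRF is `c(1, 0, 0, ...)`).
#' @param n_ch number of TCSPC channels in the window.
#' @param resolution_ns TCSPC channel width (ns).
#' @param min_photons bursts with fewer donor photons are flagged
#'   (`NA` lifetime) and excluded from E-tau analysis.
#' @param bg_fraction expected fraction of uniform-microtime background
#'   photons in the burst (background rate times duration over counts);
#'   modeled as a flat mixture component.
#' @param tau_range_ns search range for the lifetime (ns).
#' @return list with `tau_ns`, `se_ns`, `flag` ("ok", "insufficient
#'   photons", or "boundary").
#' @export
fit_burst_lifetime <- function(micro_ch, irf, n_ch = length(irf),
                               resolution_ns, min_photons = 20,
                               bg_fraction = 0,
                               tau_range_ns = c(0.05, 20)) {
  if (length(micro_ch) < min_photons)
    return(list(tau_ns = NA_real_, se_ns = NA_real_,
                flag = "insufficient photons"))
  fbg <- min(max(bg_fraction, 0), 0.8)
  counts <- tabulate(micro_ch + 1L, nbins = n_ch)
  nll <- function(log_tau) {
    m <- (1 - fbg) * .decay_model(exp(log_tau) / resolution_ns, n_ch, irf) +
      fbg / n_ch
    -sum(counts * log(m))
  }
  opt <- stats::optimize(nll, log(tau_range_ns))
  tau <- exp(opt$minimum)
  flag <- if (tau <= tau_range_ns[1] * 1.02 || tau >= tau_range_ns[2] / 1.02)
    "boundary" else "ok"
  h <- 1e-3
  d2 <- (nll(opt$minimum + h) - 2 * opt$objective + nll(opt$minimum - h)) / h^2
  se <- if (is.finite(d2) && d2 > 0) tau / sqrt(d2) else NA_real_
  list(tau_ns = tau, se_ns = se, flag = flag)
}

#' Subensemble donor decay: biexponential + scatter fit
#'
#' Pools the donor microtimes of many selected bursts and fits a
#' biexponential decay convolved with the IRF plus a scatter component
#' (the IRF pattern itself), by multinomial maximum likelihood. Reports
#' the two lifetimes, their normalized amplitudes, the scatter fraction
#' and the Pearson reduced chi-square. If the two lifetimes collapse onto
#' each other the fit is non-identifiable and a single-component fallback
#' is returned with a warning.
#'
#' @param micro_ch pooled microtime channels (window-relative).
#' @param irf IRF histogram over `n_ch` channels.
#' @param n_ch number of channels.
#' @param resolution_ns channel width (ns).
#' @param n_components 1 or 2 exponential components.
#' @param bg_fraction known fraction of uniform-microtime background
#'   photons (flat mixture component, fixed).
#' @return list with `tau_ns` (vector), `amplitude` (sums to 1), `scatter`,
#'   `chi2_red`, `n_photons`.
#' @export
fit_subensemble_decay <- function(micro_ch, irf, n_ch = length(irf),
                                  resolution_ns, n_components = 2,
                                  bg_fraction = 0) {
  counts <- tabulate(micro_ch + 1L, nbins = n_ch)
  n <- sum(counts)
  if (n < 1000) stop("need >= 1000 photons for a subensemble fit")
  irf_n <- irf / sum(irf)
  model <- function(p) {
    if (n_components == 2) {
      tau1 <- exp(p[1]); tau2 <- exp(p[2])
      a1 <- stats::plogis(p[3]); fsc <- stats::plogis(p[4]) * 0.5
      mix <- a1 * .decay_model(tau1 / resolution_ns, n_ch, irf) +
        (1 - a1) * .decay_model(tau2 / resolution_ns, n_ch, irf)
    } else {
      tau1 <- exp(p[1]); fsc <- stats::plogis(p[2]) * 0.5
      mix <- .decay_model(tau1 / resolution_ns, n_ch, irf)
    }
    fbg <- min(max(bg_fraction, 0), 0.8)
    (1 - fbg) * ((1 - fsc) * mix + fsc * irf_n) + fbg / n_ch
  }
  nll <- function(p) -sum(counts * log(pmax(model(p), 1e-300)))
  if (n_components == 2) {
    ## moment-based starting points bracketing the mean delay
    mean_tau <- max(stats::weighted.mean(seq_len(n_ch) - 0.5, counts) *
                      resolution_ns / 2, 0.3)
    p0 <- c(log(mean_tau * 0.4), log(mean_tau * 2.2), 0, -4)
  } else {
    p0 <- c(log(1.5), -4)
  }
  opt <- stats::optim(p0, nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  p <- opt$par
  if (n_components == 2) {
    taus <- exp(p[1:2]); a1 <- stats::plogis(p[3])
    fsc <- stats::plogis(p[4]) * 0.5
    ## degenerate either by collapsing lifetimes or by one component's
    ## amplitude vanishing
    if (abs(diff(log(taus))) < 0.05 || min(a1, 1 - a1) < 0.02) {
      warning("lifetime components degenerate; returning single-component fit")
      return(fit_subensemble_decay(micro_ch, irf, n_ch, resolution_ns,
                                   n_components = 1,
                                   bg_fraction = bg_fraction))
    }
    ord <- order(taus)
    taus <- taus[ord]
    amps <- c(a1, 1 - a1)[ord]
  } else {
    taus <- exp(p[1]); amps <- 1
    fsc <- stats::plogis(p[2]) * 0.5
  }
  expd <- model(p) * n
  use <- expd >= 5
  chi2 <- sum((counts[use] - expd[use])^2 / expd[use])
  npar <- length(p)
  list(tau_ns = unname(taus), amplitude = unname(amps), scatter = fsc,
       chi2_red = chi2 / max(sum(use) - npar - 1, 1), n_photons = n)
}

#' Gaussian IRF microtime histogram
#'
#' Convenience constructor for the instrument response histogram used by
#' the lifetime fitters, matching the Gaussian IRF model of the
#' simulator.
#'
#' @param n_ch TCSPC channels in the excitation window.
#' @param resolution_ns channel width (ns).
#' @param mu_ns,sigma_ns IRF position and width (ns).
#' @return numeric vector of length `n_ch`.
#' @export
gaussian_irf <- function(n_ch, resolution_ns, mu_ns = 1.5, sigma_ns = 0.25) {
  stats::dnorm((seq_len(n_ch) - 0.5) * resolution_ns, mu_ns, sigma_ns)
}

#' Burst-wise donor lifetimes for a burst table
#'
#' Runs [fit_burst_lifetime()] on the donor-channel (GG) photons of every
#' burst; microtimes are taken relative to the start of the donor
#' excitation window.
#'
#' @param stream a [photon_stream()].
#' @param bursts burst table ([burst_search()] output or later).
#' @param scheme a [pie_scheme()].
#' @param irf IRF histogram over the donor window channels; defaults to
#'   the simulator's Gaussian IRF.
#' @param background_khz donor-channel (GG) background rate used for the
#'   per-burst flat component; defaults to the rate stored on the burst
#'   table by [burst_features()].
#' @param min_photons minimum donor photons per burst.
#' @return The burst table with columns `tau_ns` and `tau_se_ns` added
#'   (`NA` where too few donor photons).
#' @export
burst_lifetimes <- function(stream, bursts, scheme, irf = NULL,
                            background_khz = NULL, min_photons = 20) {
  lab <- assign_pie_channels(stream, scheme)$label
  w <- scheme$windows[scheme$windows$label == "G", ]
  n_ch <- w$end - w$start
  res_ns <- stream$tcspc_resolution * 1e9
  if (is.null(irf)) irf <- gaussian_irf(n_ch, res_ns)
  if (is.null(background_khz)) {
    bgs <- attr(bursts, "background_khz")
    background_khz <- if (!is.null(bgs) && "GG" %in% names(bgs))
      bgs[["GG"]] else 0
  }
  out <- vapply(seq_len(nrow(bursts)), function(i) {
    idx <- bursts$first[i]:bursts$last[i]
    mic <- stream$microtime[idx][lab[idx] == "GG"] - w$start
    fbg <- if (length(mic)) background_khz * bursts$duration_ms[i] /
      length(mic) else 0
    f <- fit_burst_lifetime(mic, irf, n_ch, res_ns,
                            min_photons = min_photons, bg_fraction = fbg)
    c(f$tau_ns, f$se_ns)
  }, numeric(2))
  bursts$tau_ns <- out[1, ]
  bursts$tau_se_ns <- out[2, ]
  bursts
}

#' FRET lines in the E versus donor-lifetime plane
#'
#' The diagnostic lines of the E-tau plot:
#' * `static`: `E = 1 - tau/tau_D0` — molecules whose conformation is
#'   fixed during the transit fall on this line.
#' * `linker_static`: the dye-linker-corrected static line, a third-order
#'   polynomial in the lifetime with coefficients (-0.0178, 0.6226,
#'   0.2188, 0.0312) calibrated for the Atto532-Alexa647 pair; outside
#'   the lifetime range where the polynomial returns E in `[0, 1]` the
#'   plain static line is used.
#' * `dynamic`: for two states with donor lifetimes `tau1`, `tau2`,
#'   `E = 1 - tau1*tau2 / (tau_D0 * (tau1 + tau2 - tau))` where `tau` is
#'   the intensity-averaged burst lifetime; molecules switching between
#'   the states during the transit fall on this curve, above the static
#'   line.
#'
#' @param tau donor lifetime(s), ns. For the dynamic line this is the
#'   intensity-weighted mean lifetime and must satisfy
#'   `tau < tau1 + tau2`.
#' @param kind "static", "linker_static" or "dynamic".
#' @param tau_D0 donor-only lifetime (ns); 3.6 ns for Atto532.
#' @param tau1,tau2 endpoint-state donor lifetimes (dynamic line only).
#' @param linker_coef polynomial coefficients for the linker line.
#' @return FRET efficiency (same length as `tau`).
#' @export
fret_line <- function(tau, kind = c("static", "linker_static", "dynamic"),
                      tau_D0 = 3.6, tau1 = NULL, tau2 = NULL,
                      linker_coef = c(-0.0178, 0.6226, 0.2188, 0.0312)) {
  kind <- match.arg(kind)
  if (any(tau < 0)) stop("tau must be >= 0")
  switch(kind,
    static = 1 - tau / tau_D0,
    linker_static = {
      p <- linker_coef
      e <- 1 - (p[1] + p[2] * tau + p[3] * tau^2 + p[4] * tau^3) / tau_D0
      bad <- e < 0 | e > 1
      e[bad] <- 1 - tau[bad] / tau_D0
      e
    },
    dynamic = {
      if (is.null(tau1) || is.null(tau2))
        stop("dynamic line needs tau1 and tau2")
      if (any(tau >= tau1 + tau2))
        stop("dynamic line undefined for tau >= tau1 + tau2")
      1 - tau1 * tau2 / (tau_D0 * (tau1 + tau2 - tau))
    })
}

#' Perrin equation for steady-state anisotropy
#'
#' `r = r0 / (1 + tau/rho)`: the steady-state anisotropy of a dye with
#' fluorescence lifetime `tau` and rotational correlation time `rho`.
#'
#' @param tau fluorescence lifetime (ns).
#' @param r0 fundamental anisotropy, in (0, 0.4].
#' @param rho_ns rotational correlation time (ns).
#' @return anisotropy value(s).
#' @export
perrin_anisotropy <- function(tau, r0 = 0.4, rho_ns) {
  if (r0 <= 0 || r0 > 0.4) stop("r0 must be in (0, 0.4]")
  if (any(rho_ns <= 0)) stop("rho must be > 0")
  r0 / (1 + tau / rho_ns)
}

#' Convert between FRET efficiency, inter-dye distance and donor lifetime
#'
#' Forster relation `E = 1 / (1 + (R/R0)^6)` and its inverse
#' `R = R0 * (1/E - 1)^(1/6)`, plus the lifetime form
#' `E = 1 - tau_DA/tau_D0`. `e_from_r` and `r_from_e` are exact inverses.
#'
#' @param R distance (Angstrom).
#' @param E FRET efficiency; must be strictly inside (0, 1) for
#'   inversion to a distance.
#' @param R0 Forster distance (Angstrom); 62 for Atto532-Alexa647.
#' @param tau_DA,tau_D0 donor lifetime with/without acceptor (ns).
#' @return the converted quantity.
#' @name e_r_convert
NULL

#' @rdname e_r_convert
#' @export
e_from_r <- function(R, R0 = 62) {
  if (any(R <= 0) || R0 <= 0) stop("R and R0 must be > 0")
  1 / (1 + (R / R0)^6)
}

#' @rdname e_r_convert
#' @export
r_from_e <- function(E, R0 = 62) {
  if (any(E <= 0 | E >= 1))
    stop("E must be strictly inside (0, 1) for distance inversion")
  R0 * (1 / E - 1)^(1 / 6)
}

#' @rdname e_r_convert
#' @export
e_from_lifetime <- function(tau_DA, tau_D0 = 3.6) 1 - tau_DA / tau_D0

#' Two-dimensional E versus donor-lifetime histogram
#'
#' Bins bursts in the (lifetime, efficiency) plane for the E-tau
#' diagnostic plot; the matrix can be written as plain text with
#' [write.table()] or drawn with `image()`.
#'
#' @param bursts burst table carrying `E` and `tau_ns` columns (see
#'   [burst_lifetimes()]).
#' @param tau_breaks,e_breaks bin edges.
#' @return integer matrix (lifetime bins x efficiency bins) with the bin
#'   centers as dimnames.
#' @export
etau_histogram <- function(bursts,
                           tau_breaks = seq(0, 5, by = 0.1),
                           e_breaks = seq(-0.1, 1.1, by = 0.025)) {
  ok <- !is.na(bursts$tau_ns) & !is.na(bursts$E)
  ti <- pmin(pmax(findInterval(bursts$tau_ns[ok], tau_breaks), 1),
             length(tau_breaks) - 1)
  ei <- pmin(pmax(findInterval(bursts$E[ok], e_breaks), 1),
             length(e_breaks) - 1)
  m <- matrix(0L, length(tau_breaks) - 1, length(e_breaks) - 1)
  for (i in seq_along(ti)) m[ti[i], ei[i]] <- m[ti[i], ei[i]] + 1L
  mid <- function(b) sprintf("%.3f", (b[-1] + b[-length(b)]) / 2)
  dimnames(m) <- list(tau_ns = mid(tau_breaks), E = mid(e_breaks))
  m
}
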