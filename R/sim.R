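#' Define a simulated molecular species
#'
#' A species is a set of conformational states plus (optionally) a
#' continuous-time Markov rate matrix connecting them. For two-color
#' species each state carries a FRET efficiency `E` and a donor lifetime;
#' for triple-labeled species each state carries the three pairwise
#' efficiencies `E_BG`, `E_BR`, `E_GR`.
#'
#' @param states data.frame with columns `E` (two-color) or
#'   `E_BG`,`E_BR`,`E_GR` (three-color) and `tau_ns` (green-donor lifetime,
#'   ns). Optional `tau_b_ns` (blue-donor lifetime) for three-color states.
#' @param rates_ms square matrix of interconversion rates (1/ms,
#'   off-diagonal entries; diagonal ignored), or `NULL` for a static
#'   species.
#' @param stoichiometry one of "dual", "donor_only", "acceptor_only",
#'   "triple".
#' @param fraction relative abundance of the species in the mixture.
#' @param label species name.
#' @return A `sim_species` object.
#' @export
sim_species <- function(states, rates_ms = NULL, stoichiometry = "dual",
                        fraction = 1, label = stoichiometry) {
  stoichiometry <- match.arg(stoichiometry,
                             c("dual", "donor_only", "acceptor_only", "triple"))
  ns <- nrow(states)
  if (is.null(rates_ms)) rates_ms <- matrix(0, ns, ns)
  rates_ms <- as.matrix(rates_ms)
  if (any(rates_ms[row(rates_ms) != col(rates_ms)] < 0))
    stop("negative interconversion rate")
  if (max(rates_ms) > 1e5) stop("rate out of supported range")
  if ("E" %in% names(states) && (any(states$E < 0) || any(states$E > 1)))
    stop("E must lie in [0, 1]")
  structure(list(states = states, rates_ms = rates_ms,
                 stoichiometry = stoichiometry, fraction = fraction,
                 label = label),
            class = "sim_species")
}

#' Configuration for the synthetic photon-stream generator
#'
#' Defaults emulate a typical confocal MFD-PIE measurement of a 50-100 pM
#' labeled protein: mean occupancy well below one molecule in the focus,
#' ~1 ms diffusion time, 50 kHz peak molecular brightness and ~1 kHz
#' background per detection channel.
#'
#' @param species list of [sim_species()] objects.
#' @param n_mean mean number of molecules in the confocal volume.
#' @param tau_diff_ms diffusion (transit) time in ms.
#' @param brightness_khz peak detected molecular brightness per excitation
#'   laser, named vector (kHz); `G` is the donor-excitation photon budget.
#' @param background_khz named per-PIE-channel background rates (kHz),
#'   e.g. `c(GG = 1, GR = 1, RR = 0.5)`.
#' @param corrections a [correction_set()] to imprint on the emitted
#'   photons (crosstalk, direct excitation, gamma).
#' @param n_colors 2 or 3.
#' @param acquisition_s acquisition length (s).
#' @param irf_mu_ns,irf_sigma_ns Gaussian IRF offset and width (ns).
#' @param tau_acceptor_ns lifetime used for directly excited acceptor
#'   photons (ns).
#' @param acceptor_bleach_prob per-transit probability that the (red)
#'   acceptor photobleaches at a uniform time inside the transit; used to
#'   exercise the ALEX-2CDE filter.
#' @param seed integer random seed; the simulation is deterministic given
#'   the seed.
#' @return A `sim_config` object (list).
#' @export
sim_config <- function(species,
                       n_mean = 0.05,
                       tau_diff_ms = 1,
                       brightness_khz = c(B = 15, G = 50, R = NA),
                       background_khz = NULL,
                       corrections = correction_set(),
                       n_colors = 2,
                       acquisition_s = 10,
                       irf_mu_ns = 1.5,
                       irf_sigma_ns = 0.25,
                       tau_acceptor_ns = 1.2,
                       acceptor_bleach_prob = 0,
                       seed = 1L) {
  if (inherits(species, "sim_species")) species <- list(species)
  scheme <- if (n_colors == 2) pie_scheme_2c() else pie_scheme_3c()
  if (is.na(brightness_khz["R"]))
    brightness_khz["R"] <- brightness_khz["G"] * corrections$gamma["GR"]
  if (is.null(background_khz)) {
    background_khz <- if (n_colors == 2)
      c(GG = 1, GR = 1, RR = 0.5)
    else
      c(BB = 0.5, BG = 0.5, BR = 0.5, GG = 1, GR = 1, RR = 0.5)
  }
  structure(list(species = species, n_mean = n_mean,
                 tau_diff_ms = tau_diff_ms, brightness_khz = brightness_khz,
                 background_khz = background_khz, corrections = corrections,
                 n_colors = n_colors, scheme = scheme,
                 acquisition_s = acquisition_s,
                 irf_mu_ns = irf_mu_ns, irf_sigma_ns = irf_sigma_ns,
                 tau_acceptor_ns = tau_acceptor_ns,
                 acceptor_bleach_prob = acceptor_bleach_prob,
                 seed = as.integer(seed)),
            class = "sim_config")
}

## Per-transit peak-amplitude distribution: straight paths through a
## Gaussian beam at uniform impact area give amplitude density f(a) = 1/(a L)
## on [a_min, 1], L = log(1/a_min). Moments are analytic and used to
## calibrate arrival rate and brightness so that (i) the mean total count
## rate equals brightness * n_mean and (ii) the shot-noise-free correlation
## amplitude equals gamma_geom / n_mean.
.amp_min <- 0.05
.amp_m1 <- function() (1 - .amp_min) / log(1 / .amp_min)
.amp_m2 <- function() (1 - .amp_min^2) / (2 * log(1 / .amp_min))
.gamma_geom <- 2^(-1.5)

.sample_amp <- function(n) .amp_min^stats::runif(n)

## Transit envelope width as a fraction of the configured diffusion time,
## calibrated so that the standard 3D-Gaussian diffusion fit of the
## resulting correlation curve recovers tau_diff (the Gaussian transit
## envelope has a lighter tail than the diffusion model, so the fitted
## diffusion time sits below the envelope's half-decay time).
.transit_sigma_factor <- 0.62

## Exact CTMC (Gillespie) trajectory of the state index on [t0, t1] (ms).
## Returns data.frame(start, end, state).
.gillespie <- function(rates_ms, p0, t0, t1) {
  ns <- nrow(rates_ms)
  if (ns == 1 || all(rates_ms[row(rates_ms) != col(rates_ms)] == 0))
    return(data.frame(start = t0, end = t1,
                      state = sample.int(ns, 1, prob = p0)))
  s <- sample.int(ns, 1, prob = p0)
  t <- t0
  seg <- list()
  repeat {
    out <- rates_ms[s, ]
    out[s] <- 0
    ktot <- sum(out)
    dwell <- if (ktot > 0) stats::rexp(1, ktot) else Inf
    tend <- min(t + dwell, t1)
    seg[[length(seg) + 1L]] <- c(t, tend, s)
    if (tend >= t1) break
    t <- tend
    s <- sample.int(ns, 1, prob = out / ktot)
  }
  m <- do.call(rbind, seg)
  data.frame(start = m[, 1], end = m[, 2], state = as.integer(m[, 3]))
}

## Stationary distribution of a CTMC rate matrix (off-diagonal rates).
.stationary <- function(rates_ms) {
  ns <- nrow(rates_ms)
  if (ns == 1) return(1)
  Q <- rates_ms
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  A <- rbind(t(Q), rep(1, ns))
  p <- stats::lsfit(A, c(rep(0, ns), 1), intercept = FALSE)$coefficients
  pmax(p, 0) / sum(pmax(p, 0))
}

## Photon-budget rates (kHz) per PIE channel and generating component for
## one state of one species. Components follow the correction equations, so
## that analysis with the same correction set recovers the configured E
## exactly in expectation. Returns data.frame(channel, origin, rate, tau).
.state_rates <- function(species, state_row, cfg) {
  cs <- cfg$corrections
  B <- cfg$brightness_khz
  tauA <- cfg$tau_acceptor_ns
  st <- species$stoichiometry
  a_GR <- cs$alpha["GR"]; d_GR <- cs$delta["GR"]; g_GR <- cs$gamma["GR"]
  rows <- list()
  add <- function(channel, origin, rate, tau) {
    if (rate > 0)
      rows[[length(rows) + 1L]] <<- data.frame(channel = channel,
                                               origin = origin,
                                               rate = rate, tau = tau)
  }
  if (st == "dual" || st == "donor_only" || st == "acceptor_only") {
    E <- if (st == "dual") state_row$E else 0
    tauD <- state_row$tau_ns
    r_GG <- if (st == "acceptor_only") 0 else B["G"] * (1 - E)
    r_RR <- if (st == "donor_only") 0 else B["R"]
    add("GG", "donor", r_GG, tauD)
    add("GR", "fret", if (st == "dual") g_GR * B["G"] * E else 0, tauD)
    add("GR", "crosstalk", a_GR * r_GG, tauD)
    add("GR", "direct_exc", d_GR * r_RR, tauA)
    add("RR", "acceptor", r_RR, tauA)
  } else { # triple
    E_BG <- state_row$E_BG; E_BR <- state_row$E_BR; E_GR <- state_row$E_GR
    tauD <- state_row$tau_ns
    tauB <- if (!is.null(state_row$tau_b_ns)) state_row$tau_b_ns else 2.5
    a_BG <- cs$alpha["BG"]; d_BG <- cs$delta["BG"]; g_BG <- cs$gamma["BG"]
    a_BR <- cs$alpha["BR"]; d_BR <- cs$delta["BR"]; g_BR <- cs$gamma["BR"]
    ## green-red pair under green excitation (standard two-color scheme)
    r_GG <- B["G"] * (1 - E_GR)
    r_RR <- B["R"]
    add("GG", "donor", r_GG, tauD)
    add("GR", "fret", g_GR * B["G"] * E_GR, tauD)
    add("GR", "crosstalk", a_GR * r_GG, tauD)
    add("GR", "direct_exc", d_GR * r_RR, tauA)
    add("RR", "acceptor", r_RR, tauA)
    ## blue excitation cascade: exclusive pairwise efficiencies inverted to
    ## per-quantum routing probabilities (blue emits a, green b, red c)
    den <- 1 - E_BG * E_BR
    eps_G <- E_BG * (1 - E_BR) / den
    eps_R <- E_BR * (1 - E_BG) / den
    pa <- 1 - eps_G - eps_R
    pb <- eps_G * (1 - E_GR)
    pc <- eps_R + eps_G * E_GR
    r_BB <- B["B"] * pa
    add("BB", "donor", r_BB, tauB)
    add("BG", "fret", g_BG * B["B"] * pb, tauD)
    add("BG", "crosstalk", a_BG * r_BB, tauB)
    add("BG", "direct_exc", d_BG * r_GG, tauD)
    add("BR", "fret", g_BR * B["B"] * pc, tauA)
    add("BR", "crosstalk",
        a_BR * r_BB + a_GR * (g_BG * B["B"] * pb + d_BG * r_GG), tauA)
    add("BR", "direct_exc",
        d_BR * r_RR + if (E_GR < 1) d_BG * E_GR / (1 - E_GR) * r_GG else 0,
        tauA)
  }
  if (!length(rows))
    return(data.frame(channel = character(), origin = character(),
                      rate = numeric(), tau = numeric()))
  do.call(rbind, rows)
}

## Draw microtime channels for photons of one component.
.draw_microtimes <- function(n, exc, tau_ns, cfg, uniform = FALSE) {
  sch <- cfg$scheme
  w <- sch$windows[sch$windows$label == exc, ]
  res_ns <- 1e9 / (sch$repetition_rate * max(sch$windows$end))
  len_ch <- w$end - w$start
  if (uniform) return(w$start + sample.int(len_ch, n, replace = TRUE) - 1L)
  delay <- cfg$irf_mu_ns + stats::rnorm(n, 0, cfg$irf_sigma_ns) +
    stats::rexp(n, 1 / tau_ns)
  delay <- delay %% (len_ch * res_ns)
  w$start + pmin(floor(delay / res_ns), len_ch - 1L)
}

## Detector id for a detection color (random polarization split).
.draw_detectors <- function(n, color, scheme, p_par = 0.5) {
  dm <- scheme$detector_map
  ids <- dm$detector[dm$color == color]
  ids[1 + stats::rbinom(n, 1, 1 - p_par)]
}

#' Simulate a PIE photon stream of freely diffusing labeled molecules
#'
#' Molecules transit a Gaussian intensity envelope (width tied to the
#' diffusion time, per-transit peak amplitude drawn from the straight-path
#' Gaussian-beam distribution); within a transit the conformational state
#' evolves by an exact event-driven Markov simulation at the configured
#' rates; each excitation window yields Poisson photons whose channel
#' probabilities follow the state's FRET efficiencies with crosstalk,
#' direct excitation and gamma imprinted; donor microtimes are exponential
#' with the state's lifetime convolved with a Gaussian IRF and wrapped at
#' the excitation window; per-channel Poisson background is added. The
#' arrival rate and peak brightness are calibrated so that the mean total
#' count rate is `sum(background) + brightness * n_mean` and the
#' shot-noise-free correlation amplitude is `2^(-3/2) / n_mean`.
#'
#' @param config a [sim_config()].
#' @return list with `stream` (a [photon_stream()]) and `truth`, a list
#'   holding the per-photon ground truth (`photons`: data.frame aligned
#'   with the stream, columns `t_s`, `channel`, `origin`, `species`,
#'   `state`, `transit`), the per-transit table and the config.
#' @export
simulate_stream <- function(config) {
  set.seed(config$seed)
  sch <- config$scheme
  clock_period <- 1 / sch$repetition_rate
  n_tcspc <- max(sch$windows$end)
  T_s <- config$acquisition_s
  sigma_ms <- .transit_sigma_factor * config$tau_diff_ms
  m1 <- .amp_m1(); m2 <- .amp_m2()
  ## calibration (see block comment above .amp_min)
  rate_transit <- config$n_mean * m2 / (.gamma_geom * m1^2 * 2 * sqrt(pi) * sigma_ms) # per ms
  fr <- vapply(config$species, function(s) s$fraction, 0)
  fr <- fr / sum(fr)

  n_tr <- if (length(config$species) && config$n_mean > 0)
    stats::rpois(1, rate_transit * T_s * 1e3) else 0L
  centers <- sort(stats::runif(n_tr, 0, T_s * 1e3)) # ms
  sp_idx <- if (n_tr > 0)
    sample.int(length(config$species), n_tr, replace = TRUE, prob = fr)
  else integer(0)
  amps <- .sample_amp(n_tr)

  transits <- data.frame(transit = seq_len(n_tr), center_ms = centers,
                         species = sp_idx, amplitude = amps)
  ## peak brightness calibrated so mean count rate = brightness * N
  scale_b <- .gamma_geom * m1 * sqrt(2) / m2 # = B_peak / B_config
  env_area <- scale_b * sigma_ms * sqrt(2 * pi)

  ## per-species component tables, computed once (normal + bleached form)
  comp_tabs <- lapply(config$species, function(sp) {
    lapply(seq_len(nrow(sp$states)), function(si) {
      bl <- NULL
      if (config$acceptor_bleach_prob > 0 &&
          sp$stoichiometry %in% c("dual", "triple")) {
        spx <- sp
        spx$stoichiometry <- "donor_only"
        bl <- .state_rates(spx, sp$states[si, , drop = FALSE], config)
      }
      list(normal = .state_rates(sp, sp$states[si, , drop = FALSE], config),
           bleached = bl)
    })
  })
  is_static <- vapply(config$species, function(sp) {
    Q <- sp$rates_ms
    nrow(sp$states) == 1 || all(Q[row(Q) != col(Q)] == 0)
  }, TRUE)
  fast <- is_static & (config$acceptor_bleach_prob == 0)

  acc <- list(t_ms = list(), channel = list(), origin = list(),
              tau = list(), species = list(), state = list(),
              transit = list())
  push <- function(t_ms, channel, origin, tau, species, state, transit) {
    k <- length(acc$t_ms) + 1L
    acc$t_ms[[k]] <<- t_ms
    acc$channel[[k]] <<- rep_len(channel, length(t_ms))
    acc$origin[[k]] <<- rep_len(origin, length(t_ms))
    acc$tau[[k]] <<- rep_len(tau, length(t_ms))
    acc$species[[k]] <<- rep_len(species, length(t_ms))
    acc$state[[k]] <<- rep_len(state, length(t_ms))
    acc$transit[[k]] <<- transit
  }

  ## vectorized path: static species without bleaching
  for (s in which(fast)) {
    idx <- which(sp_idx == s)
    if (!length(idx)) next
    nst <- nrow(config$species[[s]]$states)
    st_of <- if (nst == 1) rep(1L, length(idx))
             else sample.int(nst, length(idx), replace = TRUE,
                             prob = .stationary(config$species[[s]]$rates_ms))
    for (si in seq_len(nst)) {
      tr <- idx[st_of == si]
      if (!length(tr)) next
      rt <- comp_tabs[[s]][[si]]$normal
      for (k in seq_len(nrow(rt))) {
        lam <- rt$rate[k] * amps[tr] * env_area
        nph <- stats::rpois(length(tr), lam)
        tot <- sum(nph)
        if (!tot) next
        tms <- rep(centers[tr], nph) + sigma_ms * stats::rnorm(tot)
        push(tms, rt$channel[k], rt$origin[k], rt$tau[k], s, si,
             rep(tr, nph))
      }
    }
  }

  ## event-driven path: switching species and bleach emulation
  for (i in which(sp_idx %in% which(!fast))) {
    sp <- config$species[[sp_idx[i]]]
    tabs <- comp_tabs[[sp_idx[i]]]
    t0 <- centers[i] - 4 * sigma_ms
    t1 <- centers[i] + 4 * sigma_ms
    segs <- .gillespie(sp$rates_ms, .stationary(sp$rates_ms), t0, t1)
    bleach_t <- if (config$acceptor_bleach_prob > 0 &&
                    stats::runif(1) < config$acceptor_bleach_prob)
      stats::runif(1, t0, t1) else Inf
    ## split segments at the bleach time, if any
    if (is.finite(bleach_t)) {
      hit <- which(segs$start < bleach_t & segs$end > bleach_t)
      if (length(hit)) {
        seg2 <- segs[hit, ]
        segs$end[hit] <- bleach_t
        seg2$start <- bleach_t
        segs <- rbind(segs, seg2)
      }
      segs$bleached <- segs$start >= bleach_t
    } else segs$bleached <- FALSE
    pp0 <- stats::pnorm((segs$start - centers[i]) / sigma_ms)
    pp1 <- stats::pnorm((segs$end - centers[i]) / sigma_ms)
    for (grp in split(seq_len(nrow(segs)),
                      paste(segs$state, segs$bleached))) {
      st_j <- segs$state[grp[1]]
      rt <- if (segs$bleached[grp[1]] && !is.null(tabs[[st_j]]$bleached))
        tabs[[st_j]]$bleached else tabs[[st_j]]$normal
      if (!nrow(rt)) next
      wseg <- amps[i] * env_area * (pp1[grp] - pp0[grp])
      for (k in seq_len(nrow(rt))) {
        nph <- stats::rpois(length(grp), rt$rate[k] * wseg)
        tot <- sum(nph)
        if (!tot) next
        u <- stats::runif(tot, rep(pp0[grp], nph), rep(pp1[grp], nph))
        push(centers[i] + sigma_ms * stats::qnorm(u), rt$channel[k],
             rt$origin[k], rt$tau[k], sp_idx[i], st_j, rep(i, tot))
      }
    }
  }
  ## background
  for (ch in names(config$background_khz)) {
    nb <- stats::rpois(1, config$background_khz[[ch]] * T_s * 1e3)
    if (nb > 0)
      push(stats::runif(nb, 0, T_s * 1e3), ch, "bg", NA_real_, 0L, 0L,
           rep(0L, nb))
  }
  all <- if (length(acc$t_ms))
    data.frame(t_ms = unlist(acc$t_ms), channel = unlist(acc$channel),
               origin = unlist(acc$origin), tau = unlist(acc$tau),
               species = unlist(acc$species), state = unlist(acc$state),
               transit = unlist(acc$transit))
  else NULL
  if (is.null(all) || !nrow(all)) {
    stream <- photon_stream(numeric(0), integer(0), integer(0),
                            clock_period, clock_period / n_tcspc, n_tcspc)
    return(list(stream = stream,
                truth = list(photons = data.frame(), transits = transits,
                             config = config)))
  }
  all <- all[all$t_ms >= 0 & all$t_ms < T_s * 1e3, ]
  ord <- order(all$t_ms)
  all <- all[ord, ]
  macro <- floor(all$t_ms * 1e-3 / clock_period)
  exc <- substr(all$channel, 1, 1)
  det_color <- substr(all$channel, 2, 2)
  micro <- integer(nrow(all))
  det <- integer(nrow(all))
  for (ch in unique(all$channel)) {
    sel <- which(all$channel == ch)
    isbg <- all$origin[sel] == "bg"
    ex <- substr(ch, 1, 1); co <- substr(ch, 2, 2)
    if (any(!isbg)) {
      ## component lifetimes can differ within a channel
      for (tv in unique(all$tau[sel][!isbg])) {
        s2 <- sel[!isbg & !is.na(all$tau[sel]) & all$tau[sel] == tv]
        micro[s2] <- .draw_microtimes(length(s2), ex, tv, config)
      }
    }
    if (any(isbg))
      micro[sel[isbg]] <- .draw_microtimes(sum(isbg), ex, 1, config,
                                           uniform = TRUE)
    det[sel] <- .draw_detectors(length(sel), co, sch)
  }
  stream <- photon_stream(macro, micro, det, clock_period,
                          clock_period / n_tcspc, n_tcspc)
  truth <- list(photons = data.frame(t_s = all$t_ms * 1e-3,
                                     channel = all$channel,
                                     origin = all$origin,
                                     species = all$species,
                                     state = all$state,
                                     transit = all$transit),
                transits = transits, config = config)
  list(stream = stream, truth = truth)
}
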