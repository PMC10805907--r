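#' Expected proximity ratio of a FRET state given correction factors
#'
#' The PDA forward model is written in the uncorrected proximity ratio
#' `PR = F_GR / (F_GR + F_GG)`. For a state with corrected efficiency `E`,
#' the expected PR under crosstalk `alpha`, direct excitation `delta` and
#' `gamma` is
#' `(gamma E + alpha (1-E) + delta rr) / (gamma E + alpha (1-E) +
#'  delta rr + (1-E))` where `rr` is the acceptor-excitation brightness
#' relative to the donor-excitation budget.
#'
#' @param E corrected FRET efficiency.
#' @param corrections a [correction_set()].
#' @param rr_ratio relative direct-acceptor brightness (defaults to
#'   `gamma_GR`, the package simulator's convention for S = 0.5).
#' @return expected proximity ratio.
#' @export
pr_from_e <- function(E, corrections = correction_set(), rr_ratio = NULL) {
  a <- corrections$alpha["GR"]; d <- corrections$delta["GR"]
  g <- corrections$gamma["GR"]
  if (is.null(rr_ratio)) rr_ratio <- g
  num <- g * E + a * (1 - E) + d * rr_ratio
  unname(num / (num + (1 - E)))
}

#' Slice selected bursts into fixed time windows and histogram the PR
#'
#' Each burst's photon record is cut into consecutive windows of width
#' `bin_ms` starting at the first burst photon; trailing partial windows
#' are discarded. Per window the uncorrected proximity ratio
#' `PR = F_GR / (F_GR + F_GG)` is computed from the green-excitation
#' photons; windows without green-excitation photons are skipped.
#'
#' @param stream a [photon_stream()].
#' @param bursts selected burst table (rows of [burst_search()] output).
#' @param scheme a [pie_scheme()].
#' @param bin_ms vector of window widths (ms); the defaults are the
#'   0.5 / 1 / 1.5 ms set used for global dynamic-PDA fits.
#' @param min_n minimum photons per window; windows below are discarded
#'   (burst-edge windows carry almost no signal and are background
#'   dominated).
#' @param n_bins number of PR histogram bins on [0, 1].
#' @return list over bin widths; each element holds `windows`
#'   (data.frame `N`, `F_GR`, `PR`, `burst`), `counts` (histogram over
#'   the PR grid), `breaks`, and `bin_ms`.
#' @export
pr_slice_histogram <- function(stream, bursts, scheme,
                               bin_ms = c(0.5, 1, 1.5), min_n = 10,
                               n_bins = 51) {
  lab <- assign_pie_channels(stream, scheme)$label
  t <- stream_seconds(stream)
  breaks <- seq(0, 1, length.out = n_bins + 1)
  out <- lapply(bin_ms, function(w) {
    rows <- vector("list", nrow(bursts))
    for (i in seq_len(nrow(bursts))) {
      idx <- bursts$first[i]:bursts$last[i]
      tb <- t[idx] - t[idx[1]]
      lb <- lab[idx]
      nwin <- floor((tb[length(tb)]) / (w * 1e-3))
      if (nwin < 1) next
      win <- floor(tb / (w * 1e-3))
      sel <- win < nwin
      gg <- tabulate(win[sel & lb == "GG"] + 1L, nbins = nwin)
      gr <- tabulate(win[sel & lb == "GR"] + 1L, nbins = nwin)
      N <- gg + gr
      keep <- N >= max(min_n, 1)
      if (!any(keep)) next
      rows[[i]] <- data.frame(N = N[keep], F_GR = gr[keep],
                              PR = gr[keep] / N[keep], burst = i)
    }
    windows <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
    if (is.null(windows))
      windows <- data.frame(N = integer(0), F_GR = integer(0),
                            PR = numeric(0), burst = integer(0))
    ## same binning convention as the forward model (left-closed)
    bins <- pmin(findInterval(windows$PR, breaks, rightmost.closed = TRUE),
                 n_bins)
    counts <- tabulate(bins, n_bins)
    list(windows = windows, counts = counts, breaks = breaks, bin_ms = w)
  })
  names(out) <- paste0("bin_", bin_ms)
  out
}

#' Two-state dynamic PDA model
#'
#' Defines the kinetic scheme fitted by dynamic PDA: two interconverting
#' states (unfolded U and compact C) with apparent proximity ratios
#' derived from the state efficiencies (themselves fixed from donor
#' lifetimes), interconversion rates `k_fold` (U to C) and `k_unfold`
#' (C to U), and optional static auxiliary states (impurities,
#' donor-only) with fixed PR positions and free per-histogram fractions.
#' Static states defined by an inter-dye distance are broadened with the
#' empirical width rule `sigma = sigma_factor * R` in distance space.
#'
#' @param e_states length-2 vector: corrected FRET efficiencies of U and
#'   C (converted to PR via [pr_from_e()]), or proximity ratios directly
#'   if `corrections` is `NULL`.
#' @param k_fold,k_unfold rates in 1/ms.
#' @param corrections optional [correction_set()] for the E-to-PR map.
#' @param aux_pr numeric vector of auxiliary static-state PR positions
#'   (may be empty).
#' @param R0 Forster distance (Angstrom) used for distance-space
#'   broadening.
#' @param sigma_factor width rule coefficient (0.07); set 0 to disable
#'   broadening.
#' @return A `pda_model` list.
#' @export
pda_model <- function(e_states, k_fold, k_unfold,
                      corrections = NULL, aux_pr = numeric(0),
                      R0 = 62, sigma_factor = 0.07) {
  stopifnot(length(e_states) == 2, k_fold >= 0, k_unfold >= 0)
  pr <- if (is.null(corrections)) e_states
        else pr_from_e(e_states, corrections)
  structure(list(e_states = e_states, pr_states = pr,
                 k_fold = k_fold, k_unfold = k_unfold,
                 corrections = corrections, aux_pr = aux_pr, R0 = R0,
                 sigma_factor = sigma_factor),
            class = "pda_model")
}

#' Occupation-time distribution of a two-state Markov chain
#'
#' Probability distribution of the fraction of a window of length
#' `window_ms` spent in state 2 (C), for a chain with rates `k12` (1 to
#' 2) and `k21` (2 to 1), started from the stationary distribution.
#' Computed by transition-matrix discretization of the window into
#' `n_slices` slices (each slice attributed to the state at its start).
#'
#' @param k12,k21 rates (1/ms).
#' @param window_ms window length (ms).
#' @param n_slices discretization (>= 200 recommended).
#' @return list with `f` (occupancy fractions, length `n_slices + 1`) and
#'   `p` (probabilities summing to 1).
#' @export
occupation_time_dist <- function(k12, k21, window_ms, n_slices = 200) {
  n <- n_slices
  if (k12 + k21 == 0) {
    ## frozen chain: occupancy is 0 or 1 with the initial probabilities;
    ## an isolated zero-rate chain is taken as equally likely in either state
    p <- rep(0, n + 1)
    p[1] <- 0.5; p[n + 1] <- 0.5
    return(list(f = (0:n) / n, p = p))
  }
  pi1 <- k21 / (k12 + k21); pi2 <- 1 - pi1
  dt <- window_ms / n
  ktot <- k12 + k21
  e <- exp(-ktot * dt)
  ## exact 2-state transition probabilities over one slice
  P11 <- pi1 + pi2 * e; P12 <- 1 - P11
  P22 <- pi2 + pi1 * e; P21 <- 1 - P22
  ## M[k+1, s]: probability of k slices in state 2 so far, currently s
  M <- matrix(0, n + 1, 2)
  M[1, 1] <- pi1; M[1, 2] <- pi2
  for (j in seq_len(n)) {
    occ1 <- M[, 1]                 # slice spent in state 1: k unchanged
    occ2 <- c(0, M[seq_len(n), 2]) # slice spent in state 2: k + 1
    M[, 1] <- occ1 * P11 + occ2 * P21
    M[, 2] <- occ1 * P12 + occ2 * P22
  }
  list(f = (0:n) / n, p = rowSums(M))
}

## Gauss-Hermite style broadening of a static state: distance-space
## Normal(R, sigma_factor*R) pushed through the Forster relation back to
## an apparent-PR mixture. Returns data.frame(pr, w).
.broaden_state <- function(pr, R0, sigma_factor, corrections,
                           n_nodes = 9) {
  if (sigma_factor <= 0 || pr <= 0 || pr >= 1)
    return(data.frame(pr = pr, w = 1))
  ## invert the PR back to an effective E (identity when corrections NULL)
  E <- if (is.null(corrections)) pr else {
    f <- function(E) pr_from_e(E, corrections) - pr
    if (f(1e-9) > 0 || f(1 - 1e-9) < 0) return(data.frame(pr = pr, w = 1))
    stats::uniroot(f, c(1e-9, 1 - 1e-9))$root
  }
  R <- r_from_e(min(max(E, 1e-6), 1 - 1e-6), R0)
  nodes <- stats::qnorm(seq(0.5, n_nodes - 0.5) / n_nodes)
  Rs <- pmax(R + sigma_factor * R * nodes, 1)
  Es <- e_from_r(Rs, R0)
  prs <- if (is.null(corrections)) Es else pr_from_e(Es, corrections)
  data.frame(pr = prs, w = rep(1 / n_nodes, n_nodes))
}

#' PDA forward model: expected proximity-ratio histogram
#'
#' Combines two-state Markov switching within each time window (the
#' occupation-time distribution at the model rates), per-state apparent
#' proximity ratios, static auxiliary states with distance-space
#' broadening, and binomial photon shot noise, mixed over the empirical
#' per-window photon-count distribution. When the expected number of
#' switching events per window exceeds 1000 the fast-exchange closed form
#' (a single averaged state) is used.
#'
#' @param model a [pda_model()].
#' @param N_counts integer vector of per-window total photon counts (the
#'   empirical N distribution from [pr_slice_histogram()]).
#' @param window_ms window width (ms).
#' @param breaks PR histogram breaks.
#' @param fractions named fractions: `dynamic` plus one per auxiliary
#'   state (`aux1`, ...); must sum to 1. Default: all dynamic.
#' @param background_khz named background rates `c(GG = , GR = )`;
#'   background photons (Poisson per window, split between the channels
#'   at the background color ratio) are convolved exactly with the
#'   binomial signal, conditional on each window's total count.
#' @param n_slices occupancy discretization.
#' @param n_groups photon-count distribution is collapsed to at most
#'   this many representative window sizes (speed/accuracy trade-off).
#' @return numeric vector of bin probabilities (sums to 1).
#' @export
pda_forward <- function(model, N_counts, window_ms,
                        breaks = seq(0, 1, length.out = 52),
                        fractions = NULL,
                        background_khz = c(GG = 0, GR = 0),
                        n_slices = 200, n_groups = 48) {
  if (!length(N_counts)) stop("empty count distribution")
  n_aux <- length(model$aux_pr)
  if (is.null(fractions)) fractions <- c(dynamic = 1, rep(0, n_aux))
  stopifnot(abs(sum(fractions) - 1) < 1e-8)
  eU <- model$pr_states[1]; eC <- model$pr_states[2]
  ktot <- model$k_fold + model$k_unfold
  if (ktot * window_ms > 1000) {
    piC <- model$k_fold / ktot
    occ <- list(f = piC, p = 1)
  } else {
    occ <- occupation_time_dist(model$k_fold, model$k_unfold, window_ms,
                                n_slices)
    ## quantize the occupancy support to 1% steps: negligible against
    ## binomial shot noise, large saving in the mixture evaluation
    qf <- round(occ$f * 100) / 100
    pq <- rowsum(occ$p, qf)
    occ <- list(f = as.numeric(rownames(pq)), p = as.numeric(pq))
    keep <- occ$p > 1e-12
    occ <- list(f = occ$f[keep], p = occ$p[keep] / sum(occ$p[keep]))
  }
  eps_dyn <- occ$f * eC + (1 - occ$f) * eU
  comp <- list(list(eps = eps_dyn, w = occ$p, frac = fractions[1]))
  for (a in seq_len(n_aux)) {
    br <- .broaden_state(model$aux_pr[a], model$R0, model$sigma_factor,
                         model$corrections)
    comp[[a + 1]] <- list(eps = br$pr, w = br$w, frac = fractions[a + 1])
  }
  Ntab <- table(N_counts)
  Nvals <- as.integer(names(Ntab))
  Nw <- as.numeric(Ntab) / length(N_counts)
  ## group the count distribution into at most ~48 representative N values
  if (length(Nvals) > n_groups) {
    grp <- cut(Nvals, breaks = unique(round(exp(seq(log(min(Nvals)),
                                                    log(max(Nvals) + 1),
                                                    length.out = n_groups + 1)))) - 0.5,
               labels = FALSE)
    grp[is.na(grp)] <- max(grp, na.rm = TRUE)
    Nrep <- as.integer(round(tapply(Nvals * Nw, grp, sum) /
                               tapply(Nw, grp, sum)))
    Nwg <- as.numeric(tapply(Nw, grp, sum))
    Nvals <- Nrep; Nw <- Nwg
  }
  nb <- length(breaks) - 1
  hist_p <- numeric(nb)
  eps_all <- unlist(lapply(comp, `[[`, "eps"))
  w_all <- unlist(lapply(comp, function(cm) cm$frac * cm$w))
  use_c <- w_all > 0
  eps_all <- eps_all[use_c]; w_all <- w_all[use_c]
  lam_bg <- sum(background_khz) * window_ms
  eps_bg <- if (lam_bg > 0) background_khz[["GR"]] / sum(background_khz)
            else 0
  ## background photon-number distribution (Poisson, truncated)
  b_max <- if (lam_bg > 0) stats::qpois(0.999, lam_bg) else 0L
  pb <- stats::dpois(0:b_max, lam_bg)
  pb <- pb / sum(pb)
  for (iN in seq_along(Nvals)) {
    N <- Nvals[iN]
    cvals <- 0:N
    bin <- pmin(findInterval(cvals / N, breaks, rightmost.closed = TRUE), nb)
    ## exact convolution of binomial signal with binomial-thinned
    ## Poisson background, conditional on the window total N
    pc <- numeric(N + 1)
    for (b in 0:min(b_max, N - 1)) {
      ns <- N - b
      pm <- stats::dbinom(rep(0:ns, times = length(eps_all)), ns,
                          rep(eps_all, each = ns + 1))
      sig <- as.numeric(matrix(pm, ns + 1) %*% w_all)
      if (b == 0) {
        pc <- pc + pb[1] * c(sig, rep(0, N - ns))
      } else {
        bgv <- stats::dbinom(0:b, b, eps_bg)
        tot <- numeric(N + 1)
        for (g in 0:b)
          tot[(g + 1):(g + ns + 1)] <- tot[(g + 1):(g + ns + 1)] +
            bgv[g + 1] * sig
        pc <- pc + pb[b + 1] * tot
      }
    }
    pc <- pc / sum(pc)
    rs <- rowsum(pc, bin)
    ib <- as.integer(rownames(rs))
    hist_p[ib] <- hist_p[ib] + Nw[iN] * as.numeric(rs)
  }
  hist_p / sum(hist_p)
}

#' Global dynamic-PDA fit across bin widths
#'
#' Minimizes the summed Pearson chi-square of the forward model against
#' the measured PR histograms at all bin widths simultaneously, sharing
#' the two interconversion rates (and state positions) while leaving
#' auxiliary-state fractions free per histogram. 95% confidence intervals
#' for the rates come from the profile chi-square (delta chi-square =
#' 3.84 with the co-rate re-optimized).
#'
#' @param slices output of [pr_slice_histogram()] (>= 2 bin widths).
#' @param model0 initial [pda_model()]; its `e_states`, `aux_pr`,
#'   `corrections` and broadening are kept fixed, the rates are fitted.
#' @param background_khz named `c(GG = , GR = )` rates passed to
#'   [pda_forward()].
#' @param profile_ci compute profile-likelihood CIs (slower).
#' @return list with `k_fold`, `k_unfold` (1/ms), `ci_fold`, `ci_unfold`,
#'   `relaxation_ms = 1/(k_fold + k_unfold)`, per-bin-width `chi2_red`,
#'   fitted `fractions`, and the refitted `model`.
#' @export
pda_fit <- function(slices, model0,
                    background_khz = c(GG = 0, GR = 0),
                    profile_ci = TRUE) {
  stopifnot(length(slices) >= 2)
  n_aux <- length(model0$aux_pr)
  nh <- length(slices)
  ## parameter vector: log k_fold, log k_unfold, then per histogram n_aux
  ## logit aux fractions
  frac_of <- function(p, h) {
    if (n_aux == 0) return(c(dynamic = 1))
    lg <- p[2 + (h - 1) * n_aux + seq_len(n_aux)]
    fa <- stats::plogis(lg) / (1 + sum(stats::plogis(lg)))
    c(dynamic = 1 - sum(fa), fa)
  }
  chi2_one <- function(sl, model, fr) {
    p <- pda_forward(model, sl$windows$N, sl$bin_ms, sl$breaks, fr,
                     background_khz = background_khz)
    n <- sum(sl$counts)
    e <- n * p
    use <- e > 0.5
    sum((sl$counts[use] - e[use])^2 / e[use])
  }
  ## multinomial deviance: more efficient than Pearson chi-square for the
  ## sparse minority-state bins that carry the slower rate
  dev_one <- function(sl, model, fr) {
    p <- pda_forward(model, sl$windows$N, sl$bin_ms, sl$breaks, fr,
                     background_khz = background_khz)
    -2 * sum(sl$counts * log(pmax(p, 1e-12)))
  }
  obj <- function(p) {
    m <- model0
    m$k_fold <- exp(p[1]); m$k_unfold <- exp(p[2])
    tot <- 0
    for (h in seq_len(nh))
      tot <- tot + dev_one(slices[[h]], m, frac_of(p, h))
    tot
  }
  p0 <- c(log(max(model0$k_fold, 1e-3)), log(max(model0$k_unfold, 1e-3)),
          rep(-2, n_aux * nh))
  opt <- stats::optim(p0, obj, method = "Nelder-Mead",
                      control = list(maxit = 3000, reltol = 1e-10))
  pbest <- opt$par
  model <- model0
  model$k_fold <- exp(pbest[1]); model$k_unfold <- exp(pbest[2])
  chi2s <- vapply(seq_len(nh), function(h) {
    sl <- slices[[h]]
    chi2_one(sl, model, frac_of(pbest, h)) /
      max(sum(sl$counts > 0) - 2 - n_aux, 1)
  }, 0)
  ci <- function(which_par) {
    if (!profile_ci) return(c(NA_real_, NA_real_))
    target <- opt$value + 3.84
    prof <- function(lk) {
      pr <- pbest
      pr[which_par] <- lk
      other <- setdiff(1:2, which_par)
      o <- stats::optim(pbest[-which_par],
                        function(q) { pr[-which_par] <- q; obj(pr) },
                        method = if (length(pbest) > 3) "Nelder-Mead"
                                 else "Brent",
                        lower = if (length(pbest) <= 3) pbest[other] - 6,
                        upper = if (length(pbest) <= 3) pbest[other] + 6,
                        control = list(maxit = 500))
      o$value
    }
    bound <- function(dir) {
      lo <- pbest[which_par]
      hi <- lo + dir * 2.5
      if (prof(hi) < target) return(if (dir > 0) Inf else 0)
      for (it in 1:20) {
        mid <- (lo + hi) / 2
        if (prof(mid) < target) lo <- mid else hi <- mid
      }
      exp((lo + hi) / 2)
    }
    c(bound(-1), bound(1))
  }
  list(k_fold = model$k_fold, k_unfold = model$k_unfold,
       ci_fold = ci(1), ci_unfold = ci(2),
       relaxation_ms = 1 / (model$k_fold + model$k_unfold),
       chi2_red = chi2s,
       fractions = lapply(seq_len(nh), function(h) frac_of(pbest, h)),
       model = model, convergence = opt$convergence)
}
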