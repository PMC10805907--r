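#' Correction factors for FRET burst analysis
#'
#' Bundles, per dye pair `XY` in `{GR, BG, BR}`, the crosstalk fraction
#' `alpha` (donor emission detected in the acceptor channel), the
#' direct-excitation fraction `delta` (acceptor excited by the donor
#' laser) and the detection-efficiency/quantum-yield ratio `gamma`,
#' plus per-PIE-channel background rates.
#'
#' @param alpha,delta named numeric vectors over pairs `GR`,`BG`,`BR`
#'   (missing pairs default to 0).
#' @param gamma named numeric vector over the same pairs (defaults to 1).
#' @param background_khz named per-channel background rates (kHz), used by
#'   [burst_features()] when not estimated from the stream.
#' @return A `correction_set` object.
#' @export
correction_set <- function(alpha = c(GR = 0, BG = 0, BR = 0),
                           delta = c(GR = 0, BG = 0, BR = 0),
                           gamma = c(GR = 1, BG = 1, BR = 1),
                           background_khz = NULL) {
  fill <- function(x, default) {
    out <- c(GR = default, BG = default, BR = default)
    out[names(x)] <- x
    out
  }
  alpha <- fill(alpha, 0); delta <- fill(delta, 0); gamma <- fill(gamma, 1)
  if (any(alpha < 0) || any(delta < 0)) stop("alpha and delta must be >= 0")
  if (any(gamma <= 0)) stop("gamma must be > 0")
  structure(list(alpha = alpha, delta = delta, gamma = gamma,
                 background_khz = background_khz),
            class = "correction_set")
}

#' @export
print.correction_set <- function(x, ...) {
  cat("correction_set:\n")
  for (p in c("GR", "BG", "BR"))
    cat(sprintf("  %s: alpha=%.4g delta=%.4g gamma=%.4g\n", p,
                x$alpha[p], x$delta[p], x$gamma[p]))
  invisible(x)
}

#' Fully corrected two-color FRET efficiency and stoichiometry
#'
#' Computes, from background-corrected counts,
#' \deqn{E = \frac{F_{GR} - \alpha F_{GG} - \delta F_{RR}}
#'            {\gamma F_{GG} + F_{GR} - \alpha F_{GG} - \delta F_{RR}}}
#' \deqn{S = \frac{\gamma F_{GG} + F_{GR} - \alpha F_{GG} - \delta F_{RR}}
#'            {\gamma F_{GG} + F_{GR} - \alpha F_{GG} - \delta F_{RR} + F_{RR}}}
#'
#' Counts may be vectors (one element per burst). A zero denominator flags
#' the burst invalid (`NA`) rather than erroring.
#'
#' @param F_GG,F_GR,F_RR background-corrected counts: donor and acceptor
#'   signal after donor excitation, and acceptor signal after acceptor
#'   excitation.
#' @param corrections a [correction_set()]; the `GR` entries are used.
#' @return data.frame with columns `E` and `S`.
#' @export
fret_2c <- function(F_GG, F_GR, F_RR, corrections = correction_set()) {
  a <- corrections$alpha["GR"]; d <- corrections$delta["GR"]
  g <- corrections$gamma["GR"]
  Fa <- F_GR - a * F_GG - d * F_RR
  den_e <- g * F_GG + Fa
  den_s <- den_e + F_RR
  E <- ifelse(den_e == 0, NA_real_, Fa / den_e)
  S <- ifelse(den_s == 0, NA_real_, den_e / den_s)
  data.frame(E = E, S = S)
}

#' Three-color stoichiometries
#'
#' Uncorrected (as-counted) label stoichiometries for the three dye pairs:
#' `S_BG = (F_BB+F_BG)/(F_BB+F_BG+F_GG)`,
#' `S_BR = (F_BB+F_BR)/(F_BB+F_BR+F_RR)`,
#' `S_GR = (F_GG+F_GR)/(F_GG+F_GR+F_RR)`.
#'
#' @param F_BB,F_BG,F_BR,F_GG,F_GR,F_RR per-burst PIE channel counts.
#' @return data.frame with columns `S_BG`, `S_BR`, `S_GR` (`NA` where a
#'   denominator vanishes).
#' @export
stoich_3c <- function(F_BB, F_BG, F_BR, F_GG, F_GR, F_RR) {
  sdiv <- function(num, den) ifelse(den == 0, NA_real_, num / den)
  data.frame(
    S_BG = sdiv(F_BB + F_BG, F_BB + F_BG + F_GG),
    S_BR = sdiv(F_BB + F_BR, F_BB + F_BR + F_RR),
    S_GR = sdiv(F_GG + F_GR, F_GG + F_GR + F_RR))
}

#' Fully corrected three-color FRET efficiencies
#'
#' Returns the three pairwise efficiencies for triple-labeled molecules.
#' `E_GR` uses the standard two-color formula on the green-excitation
#' counts. The blue-excitation signals are first corrected for crosstalk
#' and direct excitation,
#' `F_BG^cor = F_BG - alpha_BG F_BB - delta_BG F_GG` and
#' `F_BR^cor = F_BR - alpha_BR F_BB - delta_BR F_RR
#'  - alpha_GR (F_BG - alpha_BG F_BB) - delta_BG E_GR/(1-E_GR) F_GG`,
#' then
#' `E_BG = F_BG^cor / (gamma_BG F_BB (1-E_GR) + F_BG^cor)` and
#' `E_BR = (F_BR^cor - E_GR (gamma_GR F_BG^cor + F_BR^cor)) /
#'  (gamma_BR F_BB + F_BR^cor - E_GR (gamma_BR F_BB + gamma_GR F_BG^cor +
#'   F_BR^cor))`.
#'
#' The donor term of the `E_BG` denominator uses `F_BB`, which makes the
#' `E_GR -> 0` limit reduce exactly to the two-color expression.
#' Bursts with `E_GR = 1` are flagged invalid (`NA`): the
#' `(1-E_GR)^{-1}` term is singular there.
#'
#' @inheritParams stoich_3c
#' @param corrections a [correction_set()] with entries for all three
#'   pairs. For a physically consistent detection model
#'   `gamma_BR = gamma_BG * gamma_GR`.
#' @return data.frame with columns `E_GR`, `E_BG`, `E_BR`.
#' @export
fret_3c <- function(F_BB, F_BG, F_BR, F_GG, F_GR, F_RR,
                    corrections = correction_set()) {
  cs <- corrections
  E_GR <- fret_2c(F_GG, F_GR, F_RR, cs)$E
  bad <- is.na(E_GR) | E_GR >= 1
  Fbg_cor <- F_BG - cs$alpha["BG"] * F_BB - cs$delta["BG"] * F_GG
  Fbr_cor <- F_BR - cs$alpha["BR"] * F_BB - cs$delta["BR"] * F_RR -
    cs$alpha["GR"] * (F_BG - cs$alpha["BG"] * F_BB) -
    cs$delta["BG"] * ifelse(bad, NA_real_, E_GR / (1 - E_GR)) * F_GG
  den_bg <- cs$gamma["BG"] * F_BB * (1 - E_GR) + Fbg_cor
  E_BG <- ifelse(bad | den_bg == 0, NA_real_, Fbg_cor / den_bg)
  num_br <- Fbr_cor - E_GR * (cs$gamma["GR"] * Fbg_cor + Fbr_cor)
  den_br <- cs$gamma["BR"] * F_BB + Fbr_cor -
    E_GR * (cs$gamma["BR"] * F_BB + cs$gamma["GR"] * Fbg_cor + Fbr_cor)
  E_BR <- ifelse(bad | den_br == 0, NA_real_, num_br / den_br)
  data.frame(E_GR = E_GR, E_BG = E_BG, E_BR = E_BR)
}

#' Estimate two-color correction factors from a burst table
#'
#' Community-standard calibration from the populations present in a PIE
#' measurement: crosstalk `alpha` from the aggregate apparent
#' (proximity-ratio) E of donor-only bursts, direct excitation `delta`
#' from the aggregate apparent S of acceptor-only bursts, and `gamma`
#' from the requirement that the corrected stoichiometry of dual-labeled
#' bursts be independent of E across FRET populations (linear fit of
#' `1/S_app` vs alpha/delta-corrected proximity ratio over >= 2
#' populations).
#'
#' The donor-only (acceptor-only) population is selected by apparent
#' stoichiometry plus the requirement that the complementary excitation
#' channel is statistically consistent with pure background: any
#' co-diffusing acceptor (donor) molecule deposits counts there, and
#' such multi-molecule bursts otherwise bias the crosstalk and
#' direct-excitation estimates upward.
#'
#' @param bursts a burst table from [burst_features()] (raw counts,
#'   background-corrected counts and durations).
#' @param background_khz per-channel background rates; defaults to the
#'   rates stored by [burst_features()].
#' @param s_app_dual apparent-S window selecting dual-labeled bursts; kept
#'   wide because truncating the S distribution biases the per-population
#'   acceptor-signal means that carry the gamma information.
#' @param s_app_donor_only lower apparent-S bound for donor-only bursts.
#' @param s_app_acceptor_only upper apparent-S bound for acceptor-only
#'   bursts.
#' @param min_counts minimum burst brightness (corrected counts in the
#'   relevant channel) for the calibration populations.
#' @param n_populations number of FRET populations used for the gamma fit
#'   (k-means clusters on E); must be >= 2.
#' @param background_floor_khz optional per-channel instrumental
#'   background floor (e.g. [estimate_background()] with a
#'   `floor_quantile`). When given, the gamma aggregates are computed
#'   from counts corrected with the floor rates instead of the
#'   diffuse-inclusive rates: the robust population cores handle
#'   multi-molecule contamination themselves, and subtracting the
#'   diffuse average from already-clean bursts biases the
#'   per-population acceptor signal.
#' @param alex2cde optional per-burst ALEX-2CDE scores (green-red pair);
#'   when given, dual bursts used for the gamma fit must score at or
#'   below `alex2cde_max`, removing photobleaching and multi-molecule
#'   events.
#' @param alex2cde_max score threshold for the dual population.
#' @return A [correction_set()] with the estimated `GR` entries.
#' @export
estimate_corrections <- function(bursts, background_khz = NULL,
                                 s_app_dual = c(0.25, 0.75),
                                 s_app_donor_only = 0.85,
                                 s_app_acceptor_only = 0.15,
                                 min_counts = 60, n_populations = 2,
                                 background_floor_khz = NULL,
                                 alex2cde = NULL, alex2cde_max = 12) {
  if (is.null(background_khz))
    background_khz <- attr(bursts, "background_khz")
  if (is.null(background_khz))
    background_khz <- c(GG = 0, GR = 0, RR = 0)
  ## with a floor estimate available, all calibration counts use it: the
  ## purity gates below already bound the per-burst molecular
  ## contamination, and subtracting the diffuse-average background from
  ## gated (clean) bursts overcorrects them
  if (!is.null(background_floor_khz)) {
    Fgg_a <- bursts$F_GG - background_floor_khz[["GG"]] * bursts$duration_ms
    Fgr_a <- bursts$F_GR - background_floor_khz[["GR"]] * bursts$duration_ms
    Frr_a <- bursts$F_RR - background_floor_khz[["RR"]] * bursts$duration_ms
    gate_bg <- background_floor_khz
  } else {
    Fgg_a <- bursts$F_GG_c
    Fgr_a <- bursts$F_GR_c
    Frr_a <- bursts$F_RR_c
    gate_bg <- background_khz
  }
  app <- fret_2c(Fgg_a, Fgr_a, Frr_a)
  pure_bg <- function(raw, ch)
    raw <= stats::qpois(0.9, pmax(gate_bg[[ch]], 1e-6) *
                          bursts$duration_ms)
  don <- which(app$S >= s_app_donor_only & Fgg_a > min_counts &
                 pure_bg(bursts$F_RR, "RR"))
  acc <- which(app$S <= s_app_acceptor_only & Frr_a > min_counts &
                 pure_bg(bursts$F_GG, "GG"))
  if (length(don) < 10 || length(acc) < 10)
    stop("insufficient calibration bursts")
  ## donor-only: E_app = alpha/(1+alpha); acceptor-only: S_app = delta/(1+delta)
  e_do <- sum(Fgr_a[don]) / sum(Fgr_a[don] + Fgg_a[don])
  alpha <- max(e_do / (1 - e_do), 0)
  s_ao <- sum(Fgr_a[acc]) / sum(Fgr_a[acc] + Frr_a[acc])
  delta <- max(s_ao / (1 - s_ao), 0)

  clean <- if (is.null(alex2cde)) rep(TRUE, nrow(bursts))
           else !is.na(alex2cde) & alex2cde <= alex2cde_max
  Fa_a <- Fgr_a - alpha * Fgg_a - delta * Frr_a
  Epr <- Fa_a / (Fa_a + Fgg_a)               # gamma = 1 proximity ratio
  invS <- 1 + Frr_a / (Fa_a + Fgg_a)
  dual <- which(app$S > s_app_dual[1] & app$S < s_app_dual[2] &
                  (Fgg_a + Fgr_a) > min_counts & clean &
                  is.finite(Epr) & is.finite(invS))
  if (length(dual) < 20) stop("insufficient calibration bursts")
  cl <- stats::kmeans(Epr[dual], centers = n_populations, nstart = 5)
  ## per-population aggregates over a robust two-dimensional core:
  ## bursts far from the population's (E, 1/S) center are mostly
  ## multi-molecule events and impurities, and they corrupt the
  ## aggregates the gamma fit relies on
  mE <- mS <- rep(NA_real_, n_populations)
  for (ci in seq_len(n_populations)) {
    sel <- dual[cl$cluster == ci]
    medE <- stats::median(Epr[sel]); medS <- stats::median(invS[sel])
    madS <- stats::mad(invS[sel])
    s2 <- sel[abs(Epr[sel] - medE) < 0.12 &
                abs(invS[sel] - medS) < 1.5 * madS]
    if (length(s2) < 10) next
    mE[ci] <- sum(Fa_a[s2]) / sum(Fa_a[s2] + Fgg_a[s2])
    mS[ci] <- 1 + sum(Frr_a[s2]) / sum(Fa_a[s2] + Fgg_a[s2])
  }
  ## 1/S_app is linear in E_PR with intercept/slope (Omega, Sigma) and
  ## gamma = (Omega-1)/(Omega+Sigma-1)
  if (sum(is.finite(mE)) < 2 || diff(range(mE, na.rm = TRUE)) < 0.1)
    stop("gamma estimation ill-posed: need >= 2 separated FRET populations")
  fit <- stats::lm(mS ~ mE)
  Om <- stats::coef(fit)[1]; Sg <- stats::coef(fit)[2]
  gamma <- (Om - 1) / (Om + Sg - 1)
  if (!is.finite(gamma) || gamma <= 0)
    stop("gamma estimation failed (non-positive estimate)")
  correction_set(alpha = c(GR = unname(alpha)),
                 delta = c(GR = unname(delta)),
                 gamma = c(GR = unname(gamma)))
}
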