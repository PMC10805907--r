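#' Sliding-window burst search
#'
#' A photon is "in burst" iff at least `m` photons (all channels) fall
#' within the centered window of width `T_us` around it; maximal runs of
#' consecutive in-burst photons with at least `L` photons total become
#' bursts. The defaults are the two-color settings (`m = 5`, 500 us,
#' `L = 50`); three-color analysis uses `m = 30`, `L = 100`.
#'
#' @param stream a [photon_stream()].
#' @param m minimum photons within the sliding window.
#' @param T_us window width in microseconds.
#' @param L minimum total photons per burst.
#' @return data.frame with one row per burst: `first`, `last` (photon
#'   indices), `n_photons`, `start_tick`, `duration_ms`.
#' @export
burst_search <- function(stream, m = 5, T_us = 500, L = 50) {
  stopifnot(m >= 1, T_us > 0, L >= m)
  if (T_us * 1e-6 < stream$clock_period) stop("window too small")
  n <- length(stream$macrotime)
  empty <- data.frame(first = integer(0), last = integer(0),
                      n_photons = integer(0), start_tick = numeric(0),
                      duration_ms = numeric(0))
  if (n == 0) return(empty)
  t <- stream_seconds(stream)
  half <- T_us * 1e-6 / 2
  cnt <- findInterval(t + half, t) - findInterval(t - half, t, left.open = TRUE)
  inb <- cnt >= m
  r <- rle(inb)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= L
  if (!any(keep)) return(empty)
  first <- starts[keep]; last <- ends[keep]
  data.frame(first = first, last = last, n_photons = last - first + 1L,
             start_tick = stream$macrotime[first],
             duration_ms = (t[last] - t[first]) * 1e3)
}

#' Estimate per-channel background rates from the out-of-burst stream
#'
#' The default is the mean out-of-burst rate per channel, which includes
#' the diffuse signal of sub-threshold molecules. With `floor_quantile`
#' set, the rate is instead a low quantile of chunked out-of-burst rates
#' — an estimate of the instrumental background floor that excludes the
#' diffuse molecular contribution (useful for calibration analyses that
#' handle multi-molecule contamination separately).
#'
#' @param stream a [photon_stream()].
#' @param bursts result of [burst_search()].
#' @param scheme a [pie_scheme()].
#' @param floor_quantile optional quantile in (0, 1) of per-chunk rates.
#' @param chunk_ms chunk length for the quantile estimate (ms).
#' @return named numeric vector of background rates (kHz) per PIE channel.
#' @export
estimate_background <- function(stream, bursts, scheme,
                                floor_quantile = NULL, chunk_ms = 100) {
  lab <- assign_pie_channels(stream, scheme)$label
  inb <- rep(FALSE, length(stream$macrotime))
  for (i in seq_len(nrow(bursts)))
    inb[bursts$first[i]:bursts$last[i]] <- TRUE
  t <- stream_seconds(stream)
  chans <- setdiff(unique(lab), "outside")
  if (is.null(floor_quantile)) {
    t_total <- diff(range(t))
    t_free <- t_total - sum(bursts$duration_ms) * 1e-3
    rates <- vapply(chans, function(ch) sum(lab == ch & !inb), 0) /
      (t_free * 1e3) # kHz
    return(rates)
  }
  chunk <- floor(t / (chunk_ms * 1e-3))
  lv <- seq(min(chunk), max(chunk))
  vapply(chans, function(ch) {
    cnt <- tabulate(chunk[!inb & lab == ch] - lv[1] + 1L, length(lv))
    stats::quantile(cnt, floor_quantile) / chunk_ms
  }, 0)
}

#' Per-burst PIE channel counts, duration, and background correction
#'
#' Builds the burst table: raw counts `F_XY` per PIE channel, the
#' background expectation `rate * duration` per channel, and corrected
#' counts `F_XY_c = F_XY - b_XY * duration`. Corrected counts are not
#' floored at zero: downstream E/S algebra needs the unclamped values.
#'
#' @param stream a [photon_stream()].
#' @param bursts result of [burst_search()].
#' @param scheme a [pie_scheme()].
#' @param background_khz named per-channel background rates (kHz); if
#'   `NULL`, estimated with [estimate_background()].
#' @return The burst data.frame with columns `F_XY` (raw) and `F_XY_c`
#'   (background-corrected) appended.
#' @export
burst_features <- function(stream, bursts, scheme, background_khz = NULL) {
  asg <- assign_pie_channels(stream, scheme)
  if (is.null(background_khz))
    background_khz <- estimate_background(stream, bursts, scheme)
  chans <- setdiff(names(asg$counts), NA)
  chan_short <- sub("^F_", "", chans)
  nb <- nrow(bursts)
  cmat <- matrix(0L, nb, length(chans), dimnames = list(NULL, chans))
  for (i in seq_len(nb)) {
    lb <- asg$label[bursts$first[i]:bursts$last[i]]
    tb <- table(factor(lb, levels = chan_short))
    cmat[i, ] <- as.integer(tb)
  }
  out <- cbind(bursts, as.data.frame(cmat))
  for (j in seq_along(chans)) {
    b <- background_khz[chan_short[j]]
    if (is.na(b)) b <- 0
    out[[paste0(chans[j], "_c")]] <- cmat[, j] - b * bursts$duration_ms
  }
  attr(out, "background_khz") <- background_khz
  out
}

## Exponential kernel density of the photon set `t_ref` evaluated at times
## `t_eval` (all in the same unit as tau).
.exp_kde <- function(t_eval, t_ref, tau) {
  if (!length(t_ref)) return(rep(0, length(t_eval)))
  colSums(exp(-abs(outer(t_ref, t_eval, "-")) / tau))
}

#' ALEX-2CDE burst filter score
#'
#' Kernel-density-based score detecting intra-burst brightness asymmetry
#' between two excitation classes (acceptor photobleaching, blinking).
#' For each class, an exponential KDE of its photon density is evaluated
#' at the other class's photon times; the score is
#' `110 - 50 * (r_XY + r_YX)` where `r_XY` is the mean ratio of the class-X
#' KDE to the class-Y KDE at class-Y photons. Well-interleaved bursts
#' score near 10; bursts whose classes separate in time approach 110.
#' Filtering keeps scores at or below the threshold (12 in two-color
#' practice).
#'
#' @param t_x,t_y arrival times (seconds) of the burst's photons in the
#'   two excitation classes (e.g. donor-excitation and
#'   acceptor-excitation).
#' @param tau_kde_us KDE time constant in microseconds.
#' @return The score, or `NA` if either class is empty (such bursts fail
#'   the filter).
#' @export
alex_2cde_score <- function(t_x, t_y, tau_kde_us = 100) {
  nx <- length(t_x); ny <- length(t_y)
  if (nx < 2 || ny < 2) return(NA_real_)
  tau <- tau_kde_us * 1e-6
  ## ratio of mean densities (not mean of ratios, which carries a Jensen
  ## bias at the few-photon densities typical of bursts); same-class KDE
  ## excludes the evaluation photon itself (exp(0) = 1), and the
  ## (n-1)/n normalization makes the ratio rate-independent: a
  ## well-interleaved burst scores 10 regardless of the class rates
  r_xy <- (ny - 1) / nx * mean(.exp_kde(t_y, t_x, tau)) /
    mean(.exp_kde(t_y, t_y, tau) - 1)
  r_yx <- (nx - 1) / ny * mean(.exp_kde(t_x, t_y, tau)) /
    mean(.exp_kde(t_x, t_x, tau) - 1)
  110 - 50 * (r_xy + r_yx)
}

#' ALEX-2CDE scores for every burst and laser pair
#'
#' @param stream a [photon_stream()].
#' @param bursts burst table from [burst_search()] / [burst_features()].
#' @param scheme a [pie_scheme()].
#' @param tau_kde_us KDE time constant (microseconds).
#' @return The burst table with a column `alex2cde_XY` per excitation-laser
#'   pair (e.g. `alex2cde_GR`; three-color adds `alex2cde_BG`,
#'   `alex2cde_BR`).
#' @export
alex_2cde <- function(stream, bursts, scheme, tau_kde_us = 100) {
  asg <- assign_pie_channels(stream, scheme)
  exc <- substr(asg$label, 1, 1) # excitation window label or "o"
  t <- stream_seconds(stream)
  lasers <- scheme$windows$label
  pairs <- utils::combn(lasers, 2, simplify = FALSE)
  for (p in pairs) {
    sc <- vapply(seq_len(nrow(bursts)), function(i) {
      idx <- bursts$first[i]:bursts$last[i]
      alex_2cde_score(t[idx][exc[idx] == p[1]], t[idx][exc[idx] == p[2]],
                      tau_kde_us)
    }, 0)
    bursts[[paste0("alex2cde_", p[1], p[2])]] <- sc
  }
  bursts
}

#' Flag bursts that are isolated from neighboring molecules
#'
#' A burst is isolated when (i) the out-of-burst photon rate in a margin
#' around it is consistent with the background level and (ii) no other
#' burst starts or ends within the margin. Multi-molecule events — a
#' second molecule grazing the confocal volume during a transit — distort
#' per-burst FRET observables and mimic conformational dynamics in
#' sliced-window analyses; isolation filtering removes most of them.
#'
#' @param stream a [photon_stream()].
#' @param bursts burst table.
#' @param background_khz total background rate (kHz; sum over channels).
#'   Defaults to the rates stored by [burst_features()].
#' @param margin_ms margin examined on each side of the burst.
#' @param rate_factor local out-of-burst rate must stay below
#'   `rate_factor * background`.
#' @return logical vector, one entry per burst.
#' @export
burst_isolation <- function(stream, bursts, background_khz = NULL,
                            margin_ms = 5, rate_factor = 1.4) {
  if (is.null(background_khz))
    background_khz <- attr(bursts, "background_khz")
  bg_tot <- sum(background_khz)
  t <- stream_seconds(stream)
  inb <- rep(FALSE, length(t))
  for (i in seq_len(nrow(bursts))) inb[bursts$first[i]:bursts$last[i]] <- TRUE
  tout <- t[!inb]
  t_start <- t[bursts$first]; t_end <- t[bursts$last]
  marg <- margin_ms * 1e-3
  nloc <- findInterval(t_end + marg, tout) - findInterval(t_start - marg, tout)
  local_rate <- nloc / (2 * marg + (t_end - t_start)) / 1e3 # kHz
  nb <- nrow(bursts)
  gap_prev <- c(Inf, t_start[-1] - t_end[-nb])
  gap_next <- c(t_start[-1] - t_end[-nb], Inf)
  local_rate < rate_factor * bg_tot & gap_prev > marg & gap_next > marg
}

#' Select bursts by interval criteria
#'
#' Pure row filtering of a burst table: each criterion is a named
#' `c(lower, upper)` interval (open on both sides, infinite bounds
#' allowed) on a table column. `NA` values fail every criterion.
#'
#' @param bursts a burst table.
#' @param criteria named list of `c(lower, upper)` intervals, e.g.
#'   `list(S = c(0.3, 0.7), alex2cde_GR = c(-Inf, 12))`. An empty list
#'   returns the table unchanged.
#' @return The filtered burst table.
#' @export
select_bursts <- function(bursts, criteria = list()) {
  keep <- rep(TRUE, nrow(bursts))
  for (fld in names(criteria)) {
    if (!fld %in% names(bursts)) stop("unknown field: ", fld)
    v <- bursts[[fld]]
    rng <- criteria[[fld]]
    keep <- keep & !is.na(v) & v > rng[1] & v < rng[2]
  }
  bursts[keep, , drop = FALSE]
}
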