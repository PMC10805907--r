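test_that("the pair-count correlator matches a brute-force O(n^2) oracle", {
  set.seed(61)
  t1 <- sort(runif(3000, 0, 1))
  t2 <- sort(runif(3000, 0, 1))
  lags <- lag_grid(1e-4, 0.05, 4)
  cc <- correlate_photons(t1, t2, lags = lags, T_s = 1)
  brute <- vapply(seq_along(lags), function(k) {
    dl <- lags[k] / 8
    keep <- t1 + lags[k] < 1
    dmat <- outer(t1[keep], t2, function(a, b) b - a)
    C <- sum(dmat >= lags[k] & dmat < lags[k] + dl)
    C * (1 - lags[k]) / (sum(keep) * sum(t2 >= lags[k] & t2 < 1) * dl) - 1
  }, 0)
  expect_equal(cc$G, brute, tolerance = 1e-12)
  ## independent streams: no correlation beyond noise
  expect_lt(max(abs(cc$G)), 5 * max(cc$sem, na.rm = TRUE))
})

test_that("3D-Gaussian diffusion model values and noise-free recovery", {
  gam <- 2^(-1.5)
  shape <- function(tau, tD, rho) gam /
    ((1 + tau / tD) * sqrt(1 + tau / (tD * rho^2)))
  ## zero-lag amplitude gamma/N and the tau = tau_D point
  expect_equal(shape(0, 1e-3, 5) / 4, 0.0884, tolerance = 2e-4)
  expect_equal(shape(1e-3, 1e-3, 5), gam * 0.5 * (1 + 1 / 25)^-0.5,
               tolerance = 1e-12)
  lags <- lag_grid(1e-6, 1, 8)
  curve <- data.frame(lag_s = lags, G = shape(lags, 1e-3, 5) / 4,
                      sem = NA_real_)
  fit <- fit_fcs_diffusion(curve, rho = 5)
  expect_equal(fit$N, 4, tolerance = 1e-6)
  expect_equal(fit$tau_D_ms, 1, tolerance = 1e-6)
  expect_equal(fit$y0, 0, tolerance = 1e-9)
})

test_that("a simulated diffusing species reproduces its occupancy and
           diffusion time", {
  sp <- sim_species(data.frame(E = 0.5, tau_ns = 1.8))
  cfg <- sim_config(list(sp), n_mean = 0.5, acquisition_s = 20,
                    tau_diff_ms = 1, seed = 62L)
  sim <- simulate_stream(cfg)
  cv <- correlate_channels(sim$stream, cfg$scheme, "GG", "GG",
                           lags = lag_grid(2e-6, 0.1, 8))
  fit <- fit_fcs_diffusion(cv)
  expect_equal(fit$N, 0.5, tolerance = 0.1)
  expect_equal(fit$tau_D_ms, 1, tolerance = 0.25)
})

test_that("FCCS amplitude algebra", {
  gam <- 2^(-1.5)
  ## fully double-labeled: CCF amplitude equals both ACF amplitudes
  r <- fccs_fraction(gam / 10, gam / 10, gam / 10)
  expect_equal(r$N_GR, 10)
  expect_equal(r$N_G, 0)
  ## no co-diffusion: zero cross-amplitude
  r0 <- fccs_fraction(gam / 10, gam / 20, 0)
  expect_equal(r0$N_GR, 0)
  expect_equal(r0$N_G, 10)
  expect_equal(r0$N_R, 20)
  ## equal thirds: CCF/ACF = 0.5
  NGT <- 20; NRT <- 20
  gcc <- gam * 10 / (NGT * NRT)
  r5 <- fccs_fraction(gam / NGT, gam / NRT, gcc)
  expect_equal(r5$N_GR, 10)
  expect_equal(gcc / (gam / NRT), 0.5)
  expect_error(fccs_fraction(gam / 10, gam / 10, gam / 5), "inconsistent")
})

test_that("species filters are unbiased and unmix a two-species stream", {
  ## disjoint-support patterns give indicator filters
  P <- cbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
  f <- build_species_filters(P, mean_counts = rep(1, 4))
  expect_equal(unname(f$weights %*% f$patterns), diag(2), tolerance = 1e-12)
  expect_error(build_species_filters(cbind(P[, 1], P[, 1])), "singular")

  ## random patterns: unbiasedness to 1e-10
  set.seed(63)
  Pr <- matrix(rexp(64 * 3), 64, 3)
  fr <- build_species_filters(Pr, mean_counts = rowSums(Pr))
  expect_equal(unname(fr$weights %*% fr$patterns), diag(3),
               tolerance = 1e-10)

  ## two exponential decay patterns: recover per-species photon counts
  n_ch <- 64
  ch <- seq_len(n_ch) - 0.5
  p1 <- dexp(ch, 1 / 8); p2 <- dexp(ch, 1 / 24)
  n1 <- 20000; n2 <- 30000
  draw <- function(p, n) tabulate(sample.int(n_ch, n, TRUE, p), n_ch)
  cnt <- draw(p1, n1) + draw(p2, n2)
  filt <- build_species_filters(cbind(p1, p2), mean_counts = cnt)
  est <- filt$weights %*% cnt
  expect_equal(est[1], n1, tolerance = 2 * sqrt(n1) * 6 / n1)
  expect_equal(est[2], n2, tolerance = 2 * sqrt(n2) * 6 / n2)
})

test_that("global kinetic fit recovers shared relaxation terms from
           constructed curves", {
  gam <- 2^(-1.5)
  lags <- lag_grid(1e-6, 0.5, 10)
  gd <- function(tau) gam / 2 /
    ((1 + tau / 1e-3) * sqrt(1 + tau / (1e-3 * 25)))
  kin <- function(tau, sgn) 1 + sgn * (0.25 * exp(-tau / 5e-6) +
                                         0.4 * exp(-tau / 2.5e-4))
  mk <- function(sgn, amp) {
    data.frame(lag_s = lags, G = amp * gd(lags) * kin(lags, sgn),
               sem = NA_real_)
  }
  fit <- fit_fcs_kinetics(mk(1, 1), mk(1, 0.8), mk(-1, 0.9), mk(-1, 1.1),
                          rho = 5)
  expect_equal(sort(fit$tau_R_us), c(5, 250), tolerance = 0.02)
  expect_equal(fit$tau_D_ms, 1, tolerance = 0.05)
  expect_equal(sort(fit$A), c(0.25, 0.4), tolerance = 0.02)

  ## static control: no kinetic amplitude
  fit0 <- fit_fcs_kinetics(mk(1, 1) |> transform(G = gd(lags)),
                           mk(1, 1) |> transform(G = gd(lags)),
                           mk(1, 1) |> transform(G = gd(lags)),
                           mk(1, 1) |> transform(G = gd(lags)), rho = 5)
  expect_lt(sum(fit0$A), 0.02)
})
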