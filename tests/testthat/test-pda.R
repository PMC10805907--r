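test_that("burst slicing produces fixed windows with the proximity-ratio
           definition", {
  sch <- pie_scheme_2c()
  ## construct one burst: 3.2 ms of photons; per 1 ms window 10 GG then
  ## 30 GR photons
  times <- c()
  det <- c()
  for (w in 0:2) {
    times <- c(times, w * 1e-3 + seq(0, 0.9e-3, length.out = 40))
    det <- c(det, rep(0L, 10), rep(2L, 30))
  }
  times <- c(times, 3.15e-3)
  det <- c(det, 0L)
  clock <- 1 / sch$repetition_rate
  ## all microtimes in the G window; red detector makes the photon GR
  st <- photon_stream(round(times / clock), rep(10L, length(times)),
                      det, clock, clock / 4096, 4096)
  bursts <- data.frame(first = 1L, last = length(times))
  sl <- pr_slice_histogram(st, bursts, sch, bin_ms = 1)
  w <- sl$bin_1$windows
  expect_equal(nrow(w), 3) # trailing 0.15 ms partial window discarded
  expect_equal(w$N, rep(40, 3))
  expect_equal(w$PR, rep(0.75, 3))
})

test_that("a static species yields shot-noise-limited PR histograms", {
  sp <- sim_species(data.frame(E = 0.5, tau_ns = 1.8))
  cfg <- sim_config(list(sp), n_mean = 0.05, acquisition_s = 15,
                    background_khz = c(GG = 0, GR = 0, RR = 0), seed = 71L)
  sim <- simulate_stream(cfg)
  b <- burst_search(sim$stream)
  sl <- pr_slice_histogram(sim$stream, b, cfg$scheme, bin_ms = 1)$bin_1
  ## binomial mixture over the empirical N distribution
  expected <- pda_forward(pda_model(c(0.5, 0.5), 0, 0, sigma_factor = 0),
                          sl$windows$N, 1)
  n <- sum(sl$counts)
  expect_gt(n, 300)
  chi <- sum((sl$counts - n * expected)^2 /
               pmax(n * expected, 1e-9))[expected > 1e-6]
  use <- n * expected > 5
  chi <- sum((sl$counts[use] - n * expected[use])^2 / (n * expected[use]))
  expect_lt(chi / sum(use), 2)
})

test_that("occupation-time distribution matches the two-state law", {
  occ <- occupation_time_dist(1.5, 0.5, 1, n_slices = 400)
  expect_equal(sum(occ$p), 1, tolerance = 1e-12)
  ## mean occupancy equals the stationary probability of state 2
  expect_equal(sum(occ$f * occ$p), 1.5 / 2, tolerance = 2e-3)
  ## frozen chain: mass only at the endpoints
  occ0 <- occupation_time_dist(0, 0, 1)
  expect_equal(sum(occ0$p[c(1, length(occ0$p))]), 1)
})

test_that("PDA forward model: frozen and fast-exchange limits", {
  N <- rep(50L, 5)
  ## frozen: two shot-noise peaks at the state PRs
  m0 <- pda_model(c(0.2, 0.8), 0, 0, sigma_factor = 0)
  h0 <- pda_forward(m0, N, 1)
  grid <- seq(0.01, 0.99, length.out = 51)
  half <- sum(h0[grid < 0.5])
  expect_equal(half, 0.5, tolerance = 1e-4)
  expect_equal(sum(h0), 1, tolerance = 1e-12)
  ## two local maxima near 0.2 and 0.8
  expect_gt(h0[which.min(abs(grid - 0.2))], h0[which.min(abs(grid - 0.5))])
  ## fast exchange: single peak at the stationary mean
  mf <- pda_model(c(0.2, 0.8), 2000, 2000, sigma_factor = 0)
  hf <- pda_forward(mf, N, 1)
  expect_gt(sum(hf[abs(grid - 0.5) < 0.1]), 0.84)
})

test_that("PDA forward model agrees with an event-driven Monte-Carlo
           oracle", {
  model <- pda_model(c(0.2, 0.8), 1, 1, sigma_factor = 0)
  pf <- pda_forward(model, rep(50L, 10), 1)
  set.seed(72)
  n_mc <- 1e5
  mc_pr <- replicate(n_mc, {
    s <- sample(1:2, 1); t <- 0; occ <- 0
    while (t < 1) {
      d <- stats::rexp(1, 1)
      if (s == 2) occ <- occ + min(d, 1 - t)
      t <- t + d
      s <- 3 - s
    }
    stats::rbinom(1, 50, 0.2 + 0.6 * occ) / 50
  })
  h_mc <- hist(mc_pr, breaks = seq(0, 1, length.out = 52),
               plot = FALSE)$counts / n_mc
  expect_lt(sum(abs(pf - h_mc)) / 2, 0.015)
})

test_that("global PDA fit recovers rates from forward-model histograms", {
  truth <- pda_model(c(0.25, 0.8), k_fold = 2, k_unfold = 1,
                     sigma_factor = 0)
  set.seed(73)
  slices <- lapply(c(0.5, 1, 1.5), function(w) {
    N <- pmax(rpois(4000 / w, 40 * w), 5)
    p <- pda_forward(truth, N, w)
    list(windows = data.frame(N = N), counts = round(p * length(N) * 3),
         breaks = seq(0, 1, length.out = 52), bin_ms = w)
  })
  names(slices) <- paste0("bin_", c(0.5, 1, 1.5))
  start <- pda_model(c(0.25, 0.8), k_fold = 1, k_unfold = 0.5,
                     sigma_factor = 0)
  fit <- pda_fit(slices, start, profile_ci = FALSE)
  expect_equal(fit$k_fold, 2, tolerance = 0.05)
  expect_equal(fit$k_unfold, 1, tolerance = 0.05)
  expect_equal(fit$relaxation_ms, 1 / 3, tolerance = 0.05)
})

test_that("expected PR maps corrected E through the correction factors", {
  cs <- correction_set(alpha = c(GR = 0.05), delta = c(GR = 0.08),
                       gamma = c(GR = 1.3))
  expect_equal(pr_from_e(0, correction_set()), 0)
  expect_equal(pr_from_e(0.6, correction_set()), 0.6)
  pr <- pr_from_e(0.6, cs)
  num <- 1.3 * 0.6 + 0.05 * 0.4 + 0.08 * 1.3
  expect_equal(pr, num / (num + 0.4))
})
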