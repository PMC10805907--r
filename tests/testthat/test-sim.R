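test_that("a static species reproduces its proximity ratio at the burst
           level", {
  sp <- sim_species(data.frame(E = 0.85, tau_ns = 0.54))
  cfg <- sim_config(list(sp), n_mean = 0.05, acquisition_s = 15,
                    background_khz = c(GG = 0, GR = 0, RR = 0), seed = 51L)
  sim <- simulate_stream(cfg)
  b <- burst_search(sim$stream)
  bf <- burst_features(sim$stream, b, cfg$scheme,
                       background_khz = c(GG = 0, GR = 0, RR = 0))
  pr <- sum(bf$F_GR) / sum(bf$F_GR + bf$F_GG)
  expect_equal(pr, 0.85, tolerance = 0.01 / 0.85)
})

test_that("background-only streams contain no bursts", {
  cfg <- sim_config(list(), n_mean = 0, acquisition_s = 10, seed = 52L)
  cfg$species <- list()
  sim <- simulate_stream(cfg)
  expect_gt(length(sim$stream), 1e4) # background photons are there
  expect_equal(nrow(burst_search(sim$stream)), 0)
})

test_that("the stream is deterministic given the seed", {
  sp <- sim_species(data.frame(E = 0.5, tau_ns = 1.8))
  cfg <- sim_config(list(sp), acquisition_s = 2, seed = 53L)
  s1 <- simulate_stream(cfg)
  s2 <- simulate_stream(cfg)
  expect_identical(s1$stream$macrotime, s2$stream$macrotime)
  expect_identical(s1$stream$microtime, s2$stream$microtime)
})

test_that("mean count rate matches background plus brightness times
           occupancy", {
  sp <- sim_species(data.frame(E = 0.5, tau_ns = 1.8))
  cfg <- sim_config(list(sp), n_mean = 0.3, acquisition_s = 20, seed = 54L)
  sim <- simulate_stream(cfg)
  ## per-laser budgets: G window (1-E) + gamma E = 1 of B_G, plus B_R
  budget <- unname(cfg$brightness_khz["G"] + cfg$brightness_khz["R"])
  expected <- sum(cfg$background_khz) + 0.3 * budget
  rate <- length(sim$stream) / cfg$acquisition_s / 1e3
  ## transit-number and amplitude fluctuations dominate shot noise
  expect_equal(rate, expected, tolerance = 0.15)
})

test_that("donor-only and acceptor-only species land at S near 1 and 0", {
  sps <- list(
    sim_species(data.frame(E = 0, tau_ns = 3.6),
                stoichiometry = "donor_only", fraction = 0.5),
    sim_species(data.frame(E = 0, tau_ns = 3.6),
                stoichiometry = "acceptor_only", fraction = 0.5))
  cs <- correction_set(alpha = c(GR = 0.04), delta = c(GR = 0.06),
                       gamma = c(GR = 1.2))
  cfg <- sim_config(sps, n_mean = 0.05, acquisition_s = 10,
                    corrections = cs, seed = 55L)
  sim <- simulate_stream(cfg)
  b <- burst_search(sim$stream)
  bf <- burst_features(sim$stream, b, cfg$scheme)
  es <- fret_2c(bf$F_GG_c, bf$F_GR_c, bf$F_RR_c, cs)
  hi <- es$S > 0.5
  expect_gt(mean(es$S[hi]), 0.9)
  expect_lt(mean(es$S[!hi]), 0.1)
  expect_gt(sum(hi), 20)
  expect_gt(sum(!hi), 20)
})

test_that("two-state switching produces mixed-occupancy windows at the
           rate an independent Markov simulation predicts", {
  sim <- sim_switcher()
  ph <- sim$truth$photons
  sig <- ph[ph$origin != "bg", ]
  ## fraction of 1-ms windows (within transits) containing both states
  win <- paste(sig$transit, floor(sig$t_s * 1e3))
  mixed <- tapply(sig$state, win, function(s) length(unique(s)) > 1)
  n_ph <- tapply(sig$state, win, length)
  obs <- mean(mixed[n_ph >= 20])

  ## independent CTMC oracle: windows of 1 ms, k12 = k21 = 2/ms, detection
  ## requires both states to emit >= 1 of ~20 photons; approximate with
  ## occupancy time > 1/20 in each state
  set.seed(56)
  orc <- replicate(4000, {
    s <- sample(1:2, 1); t <- 0; occ <- c(0, 0)
    while (t < 1) {
      d <- stats::rexp(1, 2)
      occ[s] <- occ[s] + min(d, 1 - t)
      t <- t + d
      s <- 3 - s
    }
    min(occ) > 0.05
  })
  expect_equal(obs, mean(orc), tolerance = 0.12)
})

test_that("three-color generation inverts the correction algebra exactly
           in expectation", {
  cs <- correction_set(alpha = c(GR = 0.04, BG = 0.03, BR = 0.02),
                       delta = c(GR = 0.05, BG = 0.04, BR = 0.03),
                       gamma = c(GR = 1.2, BG = 0.9, BR = 1.08))
  sp <- sim_species(data.frame(E_BG = 0.3, E_BR = 0.2, E_GR = 0.6,
                               tau_ns = 1.44, tau_b_ns = 2.0),
                    stoichiometry = "triple")
  cfg <- sim_config(list(sp), n_mean = 0.05, acquisition_s = 20,
                    corrections = cs, n_colors = 3,
                    brightness_khz = c(B = 25, G = 50, R = NA),
                    background_khz = c(BB = 0, BG = 0, BR = 0, GG = 0,
                                       GR = 0, RR = 0),
                    seed = 57L)
  sim <- simulate_stream(cfg)
  b <- burst_search(sim$stream, m = 30, T_us = 500, L = 100)
  expect_gt(nrow(b), 30)
  bf <- burst_features(sim$stream, b, cfg$scheme,
                       background_khz = c(BB = 0, BG = 0, BR = 0, GG = 0,
                                          GR = 0, RR = 0))
  e3 <- fret_3c(sum(bf$F_BB), sum(bf$F_BG), sum(bf$F_BR), sum(bf$F_GG),
                sum(bf$F_GR), sum(bf$F_RR), cs)
  expect_equal(e3$E_GR, 0.6, tolerance = 0.02 / 0.6)
  expect_equal(e3$E_BG, 0.3, tolerance = 0.02 / 0.3)
  expect_equal(e3$E_BR, 0.2, tolerance = 0.03 / 0.2)
})
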