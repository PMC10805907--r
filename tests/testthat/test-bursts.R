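test_that("sliding-window burst search follows the m/T/L criterion", {
  sch <- pie_scheme_2c()
  clock <- 1 / sch$repetition_rate
  empty <- photon_stream(numeric(0), integer(0), integer(0), clock,
                         clock / 4096, 4096)
  expect_equal(nrow(burst_search(empty)), 0)

  ## 100 photons uniformly covering 0.5 ms -> one burst holding all 100
  st <- stream_from_times(seq(0, 5e-4, length.out = 100))
  b <- burst_search(st, m = 5, T_us = 500, L = 50)
  expect_equal(nrow(b), 1)
  expect_equal(b$n_photons, 100)

  ## 40-photon cluster fails the total-count threshold
  st40 <- stream_from_times(seq(0, 4e-4, length.out = 40))
  expect_equal(nrow(burst_search(st40, m = 5, T_us = 500, L = 50)), 0)

  expect_error(burst_search(st, T_us = 1e-3), "window too small")
})

test_that("burst search is translation-invariant, deterministic and
           monotone in m and L", {
  sim <- sim_static_high_e()
  b1 <- burst_search(sim$stream)
  b2 <- burst_search(sim$stream)
  expect_identical(b1, b2)
  shifted <- photon_stream(sim$stream$macrotime + 1e7, sim$stream$microtime,
                           sim$stream$detector, sim$stream$clock_period,
                           sim$stream$tcspc_resolution, sim$stream$n_tcspc)
  b3 <- burst_search(shifted)
  expect_equal(b3$start_tick - 1e7, b1$start_tick)
  expect_equal(b3$n_photons, b1$n_photons)
  ## relaxing either threshold never loses bursts
  expect_gte(nrow(burst_search(sim$stream, m = 4)), nrow(b1))
  expect_gte(nrow(burst_search(sim$stream, L = 30)), nrow(b1))
})

test_that("burst features: counts, duration, background subtraction", {
  sch <- pie_scheme_2c()
  ## 100 GG photons over exactly 2 ms
  st <- stream_from_times(seq(0, 2e-3, length.out = 100))
  b <- burst_search(st, m = 5, T_us = 5000, L = 50)
  bf <- burst_features(st, b, sch, background_khz = c(GG = 2, GR = 0, RR = 0))
  expect_equal(bf$F_GG, 100)
  expect_equal(bf$duration_ms, 2, tolerance = 1e-4)
  expect_equal(bf$F_GG_c, 100 - 2 * bf$duration_ms, tolerance = 1e-6)
  ## zero background: corrected equals raw
  bf0 <- burst_features(st, b, sch, background_khz = c(GG = 0, GR = 0, RR = 0))
  expect_equal(bf0$F_GG_c, bf0$F_GG)
})

test_that("background-corrected burst counts match the generated signal", {
  sim <- sim_static_high_e()
  cfg <- sim$config
  b <- burst_search(sim$stream)
  bf <- burst_features(sim$stream, b, cfg$scheme)
  ## per-burst true signal counts from ground truth
  ph <- sim$truth$photons
  sig <- vapply(seq_len(nrow(bf)), function(i)
    sum(ph$origin[bf$first[i]:bf$last[i]] != "bg"), 0)
  tot_c <- bf$F_GG_c + bf$F_GR_c + bf$F_RR_c
  expect_equal(sum(tot_c) / sum(sig), 1, tolerance = 0.05)
})

test_that("ALEX-2CDE separates well-interleaved from bleached bursts", {
  set.seed(21)
  t_d <- sort(runif(120, 0, 2e-3))
  ## strictly alternating classes at equal rate
  t_all <- seq(0, 2e-3, length.out = 240)
  sc_alt <- alex_2cde_score(t_all[c(TRUE, FALSE)], t_all[c(FALSE, TRUE)])
  expect_lt(sc_alt, 12)
  ## random interleaving passes on average (single draws fluctuate
  ## around the ideal score of 10)
  med <- median(replicate(25, alex_2cde_score(sort(runif(120, 0, 2e-3)),
                                              sort(runif(120, 0, 2e-3)))))
  expect_lt(med, 12)
  ## acceptor photons confined to the first half (bleach) fails
  sc_bleach <- alex_2cde_score(t_d, sort(runif(120, 0, 1e-3)))
  expect_gt(sc_bleach, 12)
  ## the kernel construction is time-reversal symmetric
  rev_d <- sort(2e-3 - t_d)
  t_a <- sort(runif(120, 0, 1e-3))
  expect_equal(alex_2cde_score(rev_d, sort(2e-3 - t_a)),
               alex_2cde_score(t_d, t_a), tolerance = 1e-9)
  ## flat-kernel limit never exceeds the finite-kernel score
  expect_lte(alex_2cde_score(t_d, t_a, tau_kde_us = 1e8),
             alex_2cde_score(t_d, t_a) + 1e-6)
  ## empty class: undefined
  expect_true(is.na(alex_2cde_score(t_d, numeric(0))))
})

test_that("simulated acceptor bleaching is caught by the filter", {
  sp <- sim_species(data.frame(E = 0.6, tau_ns = 1.44))
  cfg <- sim_config(list(sp), n_mean = 0.05, acquisition_s = 10,
                    acceptor_bleach_prob = 0.5, seed = 44L)
  sim <- simulate_stream(cfg)
  b <- burst_search(sim$stream)
  bsc <- alex_2cde(sim$stream, b, cfg$scheme)
  expect_true(mean(bsc$alex2cde_GR > 12, na.rm = TRUE) > 0.2)
})

test_that("burst selection is pure interval filtering", {
  tb <- data.frame(S = c(0.1, 0.5, 0.9), E = c(0.2, 0.6, 0.4))
  expect_identical(select_bursts(tb), tb)
  expect_equal(nrow(select_bursts(tb, list(S = c(0.3, 0.7)))), 1)
  expect_error(select_bursts(tb, list(Z = c(0, 1))), "unknown field")
  tb$S[2] <- NA
  expect_equal(nrow(select_bursts(tb, list(S = c(0, 1)))), 2)
})
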