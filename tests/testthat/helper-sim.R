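## Shared small simulations, built once per test run.
.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(name, maker) {
  if (!exists(name, envir = .sim_cache))
    assign(name, maker(), envir = .sim_cache)
  get(name, envir = .sim_cache)
}

## A static high-FRET two-color measurement with defaults.
sim_static_high_e <- function() cached_sim("static_high_e", function() {
  sp <- sim_species(data.frame(E = 0.85, tau_ns = 3.6 * 0.15))
  cfg <- sim_config(list(sp), n_mean = 0.05, acquisition_s = 15, seed = 101L)
  c(simulate_stream(cfg), list(config = cfg))
})

## Two-state switcher, k12 = k21 = 2 / ms.
sim_switcher <- function() cached_sim("switcher", function() {
  sp <- sim_species(data.frame(E = c(0.2, 0.8),
                               tau_ns = 3.6 * c(0.8, 0.2)),
                    rates_ms = matrix(c(0, 2, 2, 0), 2, byrow = TRUE))
  cfg <- sim_config(list(sp), n_mean = 0.05, acquisition_s = 15, seed = 102L)
  c(simulate_stream(cfg), list(config = cfg))
})

## Hand-built photon stream from arrival times in seconds (single channel
## layout: all photons on the green-parallel detector, microtime 10).
stream_from_times <- function(t_s, detector = 0L, micro = 10L,
                              scheme = pie_scheme_2c()) {
  clock <- 1 / scheme$repetition_rate
  n_tcspc <- max(scheme$windows$end)
  ticks <- sort(round(t_s / clock))
  photon_stream(ticks, rep_len(micro, length(ticks)),
                rep_len(detector, length(ticks)),
                clock, clock / n_tcspc, n_tcspc)
}
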