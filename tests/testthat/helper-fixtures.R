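# Shared fixtures: the experimentally motivated G178D study conditions used
# throughout the recovery tests.

g178d_amplitudes <- c(0, 0.45, 0.74, 0.92, 1.00)
g178d_occupancies_ph74 <- c(0.06, 0.02, 0.07, 0.26, 0.59)

std_acq <- function(noise_sd = 0.3, ...) {
  acquisition_params(sample_rate = 3000, filter_corner = 1000,
                     noise_sd = noise_sd, voltage = -120,
                     full_conductance = 60, pH = 7.4, ...)
}

# one benchmark trace shared by several tests (built lazily, cached)
.bench_env <- new.env()
benchmark_trace <- function(duration = 40, seed = 11, noise_sd = 0.3) {
  key <- paste0("tr_", duration, "_", seed, "_", noise_sd)
  if (is.null(.bench_env[[key]])) {
    .bench_env[[key]] <- simulate_occupancy_trace(
      g178d_amplitudes, g178d_occupancies_ph74, mean_dwells = 0.010,
      acq = std_acq(noise_sd), duration = duration, seed = seed)
  }
  .bench_env[[key]]
}

benchmark_levels <- function(...) {
  key <- paste0("lv_", paste(c(...), collapse = "_"))
  if (is.null(.bench_env[[key]]))
    .bench_env[[key]] <- detect_levels(benchmark_trace(...))
  .bench_env[[key]]
}

# two-state (open + brief closures) generator realizing a target closure
# frequency per second of total time and mean closed dwell
closure_generator <- function(freq = 3.7, tau_c = 0.0064) {
  lambda_c <- freq / (1 - freq * tau_c)
  mp <- model_params(site_class("HBC", 0L, 2e-7), K_OC = lambda_c * tau_c,
                     conductance_map = 1, aggregation = 1L)
  build_generator(kinetic_params(mp, tau_c = tau_c, lambda_c = lambda_c),
                  pH = 7.4)
}
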