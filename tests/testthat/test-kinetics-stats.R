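make_events <- function(levels, durations) {
  om <- grep("^O[0-9]+$", unique(levels), value = TRUE)
  m <- if (length(om)) max(as.integer(sub("O", "", om))) else 1L
  lv <- c("C", paste0("O", seq_len(m)))
  out <- data.frame(level = factor(levels, lv),
                    start_s = cumsum(c(0, durations[-length(durations)])),
                    duration_s = durations,
                    mean_pA = 0)
  class(out) <- c("event_table", "data.frame")
  out
}

test_that("transition matrix counts ordered boundary pairs", {
  ev <- make_events(rep(c("O4", "C"), 10), rep(0.01, 20))
  tm <- transition_matrix(ev)
  expect_identical(sum(tm), 19L)
  expect_identical(tm["O4", "C"], 10L)
  expect_identical(tm["C", "O4"], 9L)
  expect_true(all(diag(tm) == 0))
  expect_error(transition_matrix(ev[1, ]), "at least 2")
})

test_that("nearest-neighbour simulations transition mostly between adjacent levels", {
  acq <- std_acq(noise_sd = 0)
  tr <- simulate_occupancy_trace(g178d_amplitudes, g178d_occupancies_ph74,
                                 0.01, acq, duration = 60, seed = 61)
  ev <- path_events(tr$true_path, acq)
  tm <- transition_matrix(ev)
  open_lab <- setdiff(rownames(tm), "C")
  oo <- tm[open_lab, open_lab]
  idx <- abs(outer(seq_along(open_lab), seq_along(open_lab), "-"))
  expect_gt(sum(oo[idx == 1]) / sum(oo), 0.9)
})

test_that("occupancies are duration-weighted and normalized", {
  ev1 <- make_events("O1", 0.5)
  expect_equal(unname(occupancies(ev1)), c(0, 1))
  ev <- make_events(c("O2", "C", "O1", "O2"), c(0.4, 0.1, 0.2, 0.3))
  occ <- occupancies(ev)
  expect_equal(sum(occ), 1)
  expect_equal(unname(occ[c("C", "O1", "O2")]), c(0.1, 0.2, 0.7))
})

test_that("occupancy recovery matches the generating stationary vector", {
  acq <- std_acq(noise_sd = 0)
  tr <- simulate_occupancy_trace(g178d_amplitudes, g178d_occupancies_ph74,
                                 0.01, acq, duration = 300, seed = 62)
  occ <- occupancies(path_events(tr$true_path, acq))
  expect_lt(max(abs(occ - g178d_occupancies_ph74)), 0.02)
})

test_that("closure selection rules are enforced", {
  # no closures at all
  ev <- make_events(c("O1", "O2", "O1"), c(0.1, 0.1, 0.1))
  cs <- closure_stats(ev)
  expect_identical(cs$n, 0L)
  expect_true(is.na(cs$mean_dwell))
  # Oi -> C -> Oj excluded by the same-level rule, kept without it
  ev2 <- make_events(c("O2", "C", "O1", "C", "O1"),
                     c(0.1, 0.005, 0.1, 0.005, 0.1))
  expect_identical(closure_stats(ev2, same_level_only = TRUE)$n, 1L)
  expect_identical(closure_stats(ev2, same_level_only = FALSE)$n, 2L)
  # closures at or beyond the burst cutoff are not intra-burst
  ev3 <- make_events(c("O1", "C", "O1", "C", "O1"),
                     c(0.1, 0.2, 0.1, 0.005, 0.1))
  expect_identical(closure_stats(ev3, burst_cutoff = 0.1)$n, 1L)
})

test_that("closure statistics recover the generating rate and dwell", {
  gen <- closure_generator(freq = 3.7, tau_c = 0.0064)
  p <- simulate_path(gen, 100, seed = 63)
  ev <- path_events(p)
  cs <- closure_stats(ev, burst_cutoff = 0.1, same_level_only = TRUE)
  expect_lt(abs(cs$frequency - 3.7), 2 * sqrt(370) / 100)
  expect_lt(abs(cs$mean_dwell - 0.0064), 2 * 0.0064 / sqrt(cs$n))
})

test_that("statistics are invariant under a uniform time shift", {
  ev <- make_events(c("O1", "C", "O1", "O2"), c(0.3, 0.01, 0.2, 0.5))
  ev2 <- ev
  ev2$start_s <- ev2$start_s + 123.4
  expect_identical(transition_matrix(ev), transition_matrix(ev2))
  expect_identical(occupancies(ev), occupancies(ev2))
  expect_identical(closure_stats(ev)$frequency, closure_stats(ev2)$frequency)
})

test_that("exponential dwell MLE equals the (shifted) sample mean", {
  expect_equal(dwell_exponential_fit(rep(0.004, 6))$tau, 0.004)
  set.seed(504)
  d <- stats::rexp(1000, 1 / 0.0064)
  fit <- dwell_exponential_fit(d)
  expect_lt(abs(fit$tau - 0.0064), 0.0004)  # 2 SE at n = 1000
  expect_equal(fit$se, fit$tau / sqrt(1000))
  expect_error(dwell_exponential_fit(c(-1, 1, 1, 1, 1)), "positive")
  expect_error(dwell_exponential_fit(c(1, 2)), "at least 5")
})

test_that("dead-time correction removes censoring bias", {
  set.seed(505)
  d <- stats::rexp(20000, 1 / 0.0064)
  obs <- d[d >= 5e-4]  # recording censors short dwells
  naive <- dwell_exponential_fit(obs)$tau
  corrected <- dwell_exponential_fit(obs, dead_time = 5e-4)$tau
  expect_gt(naive - 0.0064, 3e-4)              # biased upward by ~dead time
  expect_lt(abs(corrected - 0.0064), 2e-4)     # unbiased
})

test_that("dwell comparison behaves under null and alternative", {
  expect_equal(compare_dwells(c(1, 2, 3), c(1, 2, 3)), 1)
  set.seed(506)
  # null calibration: p approximately uniform across seeds
  pv <- replicate(60, compare_dwells(stats::rexp(200, 1 / 6.4),
                                     stats::rexp(200, 1 / 6.4)))
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.01)
  # power: doubling the time constant is detected
  pv2 <- compare_dwells(stats::rexp(500, 1 / 6.4), stats::rexp(500, 1 / 12.8))
  expect_lt(pv2, 0.001)
  expect_error(compare_dwells(c(1, 1), c(2, 2)), "zero variance")
})

test_that("i-V fits report slope conductance in pS", {
  exact <- iv_fit(data.frame(voltage_mV = c(-120, -60),
                             current_pA = c(-7.2, -3.6)))
  expect_equal(exact$slope_pS, 60)
  expect_equal(exact$intercept_pA, 0, tolerance = 1e-10)
  # slope ratios equal amplitude ratios for scaled levels
  v <- seq(-160, -60, 20)
  d <- rbind(data.frame(voltage_mV = v, current_pA = 0.060 * v, level = "O4"),
             data.frame(voltage_mV = v, current_pA = 0.45 * 0.060 * v,
                        level = "O1"))
  f <- iv_fit(d)
  expect_equal(f$slope_pS[f$level == "O1"] / f$slope_pS[f$level == "O4"],
               0.45, tolerance = 1e-10)
  expect_error(iv_fit(data.frame(voltage_mV = -120, current_pA = -7.2)),
               "2 distinct voltages")
})

test_that("noisy i-V data recover the unitary conductance within 2 pS", {
  set.seed(507)
  v <- seq(-160, -60, 20)
  d <- data.frame(voltage_mV = rep(v, each = 50),
                  current_pA = 0.060 * rep(v, each = 50) +
                    stats::rnorm(300, 0, 0.2))
  expect_lt(abs(iv_fit(d)$slope_pS - 60), 2)
})

test_that("re-entry destinations consistent with occupancies test correctly", {
  build_reentry <- function(probs, n = 200, seed = 1) {
    set.seed(seed)
    lv <- paste0("O", seq_along(probs))
    dest <- sample(lv, n, replace = TRUE, prob = probs)
    lev <- as.vector(rbind("C", dest))
    # durations chosen so time-weighted open occupancies equal probs
    dur <- as.vector(rbind(0.005, 0.1 * probs[match(dest, lv)] /
                             table(dest)[dest] * n))
    make_events(lev, dur)
  }
  # null: destinations drawn proportional to occupancies
  pv <- vapply(1:20, function(s) {
    reentry_consistency(build_reentry(c(0.02, 0.07, 0.26, 0.59) / 0.94,
                                      seed = s))$p_value
  }, numeric(1))
  expect_gt(mean(pv > 0.05), 0.7)
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.01)
  # extreme violation: every re-entry to one level despite spread occupancies
  ev_bad <- make_events(as.vector(rbind("C", rep("O1", 40),
                                        c(rep("O2", 20), rep("O3", 20)))),
                        rep(0.01, 120))
  expect_lt(reentry_consistency(ev_bad)$p_value, 1e-6)
  # pooling engages for very rare levels
  rt <- reentry_consistency(build_reentry(c(0.001, 0.049, 0.35, 0.6),
                                          n = 100, seed = 3))
  expect_true(length(rt$pooled) >= 1)
  expect_error(reentry_consistency(make_events(c("O1", "C", "O1"),
                                               c(0.1, 0.01, 0.1))),
               "at least 20")
})
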