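#' Transition count matrix of an event table
#'
#' Counts ordered level pairs at event boundaries. Self-transitions cannot
#' occur in a well-formed event table, so the diagonal is zero; the total
#' count equals the number of events minus one.
#'
#' @param events An `"event_table"` (see [idealize()] / [path_events()]).
#' @return A square integer matrix of class `"transition_matrix"` over the
#'   level labels, with attribute `total_time` (s).
#' @export
transition_matrix <- function(events) {
  events <- check_events(events)
  if (nrow(events) < 2L) stop("need at least 2 events")
  lv <- levels(events$level)
  from <- events$level[-nrow(events)]
  to <- events$level[-1L]
  tm <- table(factor(from, lv), factor(to, lv))
  out <- matrix(as.integer(tm), length(lv), length(lv),
                dimnames = list(from = lv, to = lv))
  attr(out, "total_time") <- sum(events$duration_s)
  class(out) <- c("transition_matrix", class(out))
  out
}

check_events <- function(events) {
  if (!inherits(events, "event_table")) {
    if (!is.data.frame(events) ||
        !all(c("level", "duration_s") %in% names(events)))
      stop("'events' must be an event_table")
    if (!is.factor(events$level)) {
      m <- sum(grepl("^O[0-9]+$", unique(events$level)))
      events$level <- factor(events$level, c("C", paste0("O", seq_len(m))))
    }
    class(events) <- c("event_table", class(events))
  }
  events
}

#' Time-weighted level occupancies
#'
#' Fraction of total recording time spent at each level.
#'
#' @param events An `"event_table"`.
#' @return Named numeric vector over the level labels, summing to 1.
#' @export
occupancies <- function(events) {
  events <- check_events(events)
  tt <- sum(events$duration_s)
  if (tt <= 0) stop("events cover no time")
  tl <- tapply(events$duration_s, events$level, sum, default = 0)
  as.numeric(tl) / tt -> out
  names(out) <- names(tl)
  out
}

#' Intra-burst closure statistics
#'
#' Analyses the brief full closures within bursts: closed (`C`) events
#' shorter than the burst cutoff. With `same_level_only` (the rule used for
#' the mutant channels), only closures flanked by the same conducting
#' sub-state (`Oi -> C -> Oi`) are kept. The closure frequency is normalized
#' per second of total analysis time by default (`per_open_time = TRUE`
#' normalizes per second spent conducting instead).
#'
#' @param events An `"event_table"`.
#' @param burst_cutoff Longest closed dwell still counted as an intra-burst
#'   closure, s (default 0.1).
#' @param same_level_only Keep only `Oi -> C -> Oi` closures.
#' @param per_open_time Normalize frequency by open time rather than total
#'   time.
#' @return Object of class `"closure_stats"`: list with `n`, `frequency`
#'   (1/s), `mean_dwell` (s), `se_dwell` (s), `dwells` (the kept closed
#'   dwell times), `total_time`, and the selection rule. With zero kept
#'   closures the dwell statistics are `NA` (undefined), not zero.
#' @export
closure_stats <- function(events, burst_cutoff = 0.1,
                          same_level_only = TRUE, per_open_time = FALSE) {
  events <- check_events(events)
  if (burst_cutoff <= 0) stop("'burst_cutoff' must be > 0")
  total_time <- sum(events$duration_s)
  open_time <- sum(events$duration_s[events$level != "C"])
  is_c <- events$level == "C"
  keep <- which(is_c & events$duration_s < burst_cutoff)
  if (same_level_only) {
    nr <- nrow(events)
    keep <- keep[keep > 1L & keep < nr &
                   events$level[pmax(keep - 1L, 1L)] ==
                   events$level[pmin(keep + 1L, nr)]]
  }
  dwells <- events$duration_s[keep]
  n <- length(dwells)
  denom <- if (per_open_time) open_time else total_time
  structure(list(
    n = n,
    frequency = if (denom > 0) n / denom else NA_real_,
    mean_dwell = if (n > 0) mean(dwells) else NA_real_,
    se_dwell = if (n > 1) stats::sd(dwells) / sqrt(n) else NA_real_,
    dwells = dwells,
    total_time = total_time,
    burst_cutoff = burst_cutoff,
    same_level_only = same_level_only,
    per_open_time = per_open_time),
    class = "closure_stats")
}

#' @export
print.closure_stats <- function(x, ...) {
  cat(sprintf("Intra-burst closures: n = %d over %.1f s\n", x$n, x$total_time))
  cat(sprintf("  frequency %.3g /s (%s), cutoff %g s%s\n",
              x$frequency, if (x$per_open_time) "per open time" else "per total time",
              x$burst_cutoff,
              if (x$same_level_only) ", Oi->C->Oi only" else ""))
  if (x$n > 0)
    cat(sprintf("  closed dwell %.3g +/- %.2g ms (mean +/- SE)\n",
                1000 * x$mean_dwell, 1000 * x$se_dwell))
  invisible(x)
}

#' Exponential dwell-time fit
#'
#' Maximum-likelihood estimate of the mean dwell (time constant) of an
#' exponential dwell distribution. Dwells below the dead time are censored
#' by the recording; for dwells observed only above `dead_time` the MLE of
#' the underlying time constant is `mean(d) - dead_time` (shifted
#' exponential), which removes the upward bias of the naive mean.
#'
#' @param durations Positive dwell times, s (n >= 5).
#' @param dead_time Censoring threshold, s (default 0: no correction).
#' @param conf_level Confidence level for the normal-approximation CI.
#' @return Object of class `"dwell_fit"`: `tau` (s), `se`, `ci`, `n`,
#'   `dead_time`.
#' @export
dwell_exponential_fit <- function(durations, dead_time = 0,
                                  conf_level = 0.95) {
  if (length(durations) < 5L) stop("need at least 5 dwell times")
  if (any(!is.finite(durations)) || any(durations <= 0))
    stop("dwell times must be positive and finite")
  if (dead_time < 0) stop("'dead_time' must be >= 0")
  if (dead_time > 0 && any(durations < dead_time))
    warning("some dwells are below the stated dead time")
  tau <- mean(durations) - dead_time
  if (tau <= 0) stop("mean dwell does not exceed the dead time")
  se <- tau / sqrt(length(durations))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(tau = tau, se = se,
                 ci = c(lower = tau - zq * se, upper = tau + zq * se),
                 n = length(durations), dead_time = dead_time,
                 conf_level = conf_level),
            class = "dwell_fit")
}

#' @export
print.dwell_fit <- function(x, ...) {
  cat(sprintf("Exponential dwell fit: tau = %.4g s (SE %.2g, n = %d)\n",
              x$tau, x$se, x$n))
  cat(sprintf("  %g%% CI [%.4g, %.4g] s; dead time %g s\n",
              100 * x$conf_level, x$ci[1], x$ci[2], x$dead_time))
  invisible(x)
}

#' Compare two dwell-time samples
#'
#' Two-sided unpaired Welch t-test on the mean dwells.
#'
#' @param a,b Numeric dwell-time samples (each n >= 2).
#' @return The two-sided p-value.
#' @export
compare_dwells <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("both samples need n >= 2")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (isTRUE(all.equal(mean(a), mean(b)))) return(1)
    stop("both samples have zero variance; t-test undefined")
  }
  stats::t.test(a, b, var.equal = FALSE)$p.value
}

#' Current-voltage (i-V) slope conductance fit
#'
#' Ordinary least squares of level current against membrane potential, per
#' level. Slopes are reported in pS (pA/mV x 1000). Sub-state conductances
#' that scale linearly with voltage give straight lines through the
#' reversal potential.
#'
#' @param data Data frame with columns `voltage_mV`, `current_pA` and
#'   optionally `level` (fits are per level when present).
#' @param fix_reversal Force the fit through 0 pA at 0 mV.
#' @return Object of class `"iv_fit"`: data frame with one row per level
#'   (`level`, `slope_pS`, `intercept_pA`, `r_squared`, `n_voltages`).
#' @examples
#' iv_fit(data.frame(voltage_mV = c(-120, -60), current_pA = c(-7.2, -3.6)))
#' @export
iv_fit <- function(data, fix_reversal = FALSE) {
  if (!is.data.frame(data) ||
      !all(c("voltage_mV", "current_pA") %in% names(data)))
    stop("'data' needs columns voltage_mV and current_pA")
  if (is.null(data$level)) data$level <- "O"
  res <- lapply(split(data, data$level), function(d) {
    if (length(unique(d$voltage_mV)) < 2L)
      stop("need at least 2 distinct voltages per level (singular design)")
    fit <- if (fix_reversal) stats::lm(current_pA ~ 0 + voltage_mV, d)
    else stats::lm(current_pA ~ voltage_mV, d)
    cf <- stats::coef(fit)
    data.frame(level = d$level[1L],
               slope_pS = 1000 * unname(cf[["voltage_mV"]]),
               intercept_pA = if (fix_reversal) 0 else unname(cf[[1L]]),
               r_squared = suppressWarnings(summary(fit)$r.squared),
               n_voltages = length(unique(d$voltage_mV)))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("iv_fit", "data.frame")
  out
}

#' Consistency of closed-state re-entries with sub-state occupancies
#'
#' Tests whether the destinations of `C -> Oi` transitions follow the
#' time-weighted occupancy distribution of the conducting sub-states
#' (conditioned on being open), by a chi-square goodness-of-fit test. Cells
#' with expected count below 1 are pooled with the next smallest cell.
#'
#' @param events An `"event_table"` with at least 20 `C -> O` transitions.
#' @return List of class `"reentry_test"`: `statistic`, `df`, `p_value`,
#'   `observed`, `expected` (after pooling), `pooled` (labels merged).
#' @export
reentry_consistency <- function(events) {
  events <- check_events(events)
  nr <- nrow(events)
  from <- events$level[-nr]; to <- events$level[-1L]
  dest <- to[from == "C" & to != "C"]
  dest <- droplevels(factor(dest))
  if (length(dest) < 20L)
    stop("need at least 20 C->O transitions (got ", length(dest), ")")
  occ <- occupancies(events)
  open_lab <- setdiff(names(occ), "C")
  p <- occ[open_lab] / sum(occ[open_lab])
  obs <- as.numeric(table(factor(dest, open_lab)))
  names(obs) <- open_lab
  exp_ <- length(dest) * p
  # pool cells with expected count < 1
  pooled <- character(0)
  while (length(exp_) > 1L && min(exp_) < 1) {
    o <- order(exp_)
    i <- o[1L]; j <- o[2L]
    pooled <- c(pooled, paste(names(exp_)[i], names(exp_)[j], sep = "+"))
    nm <- paste(names(exp_)[i], names(exp_)[j], sep = "+")
    newe <- exp_[i] + exp_[j]; newo <- obs[i] + obs[j]
    exp_ <- c(exp_[-c(i, j)], stats::setNames(newe, nm))
    obs <- c(obs[-c(i, j)], stats::setNames(newo, nm))
  }
  stat <- sum((obs - exp_)^2 / exp_)
  df <- length(exp_) - 1L
  structure(list(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 observed = obs, expected = exp_, pooled = pooled),
            class = "reentry_test")
}

#' @export
print.reentry_test <- function(x, ...) {
  cat(sprintf("Re-entry consistency: X2 = %.3g, df = %d, p = %.3g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}
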