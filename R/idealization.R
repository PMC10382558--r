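#' All-point histogram of a current trace
#'
#' Histogram of every current sample; peaks mark conductance levels.
#'
#' @param trace A `"kir_trace"` or numeric vector of currents (pA).
#' @param bin_width Bin width, pA (default 0.1).
#' @return List of class `"allpoint_histogram"` with `mids` (bin centres,
#'   pA), `counts` and `bin_width`; counts sum to the number of samples.
#' @export
allpoint_histogram <- function(trace, bin_width = 0.1) {
  x <- trace_current(trace)
  if (!length(x)) stop("empty trace")
  if (!is.numeric(bin_width) || bin_width <= 0) stop("'bin_width' must be > 0")
  lo <- floor(min(x) / bin_width) * bin_width - bin_width / 2
  nb <- ceiling((max(x) - lo) / bin_width) + 1L
  idx <- pmin.int(floor((x - lo) / bin_width) + 1L, nb)
  counts <- tabulate(idx, nb)
  structure(list(mids = lo + (seq_len(nb) - 0.5) * bin_width,
                 counts = counts, bin_width = bin_width),
            class = "allpoint_histogram")
}

#' @export
plot.allpoint_histogram <- function(x, ...) {
  graphics::plot(x$mids, x$counts, type = "h", xlab = "current (pA)",
                 ylab = "samples", ...)
  invisible(x)
}

trace_current <- function(trace) {
  if (inherits(trace, "kir_trace")) trace$current
  else if (is.numeric(trace)) trace
  else stop("'trace' must be a kir_trace or a numeric vector")
}

# smooth histogram counts with a Gaussian kernel of sd `sd_pA`
smooth_counts <- function(counts, bin_width, sd_pA) {
  sdb <- max(sd_pA / bin_width, 0.5)
  hw <- ceiling(4 * sdb)
  k <- stats::dnorm(seq.int(-hw, hw), 0, sdb)
  k <- k / sum(k)
  padded <- c(rep(0, hw), counts, rep(0, hw))
  as.numeric(stats::filter(padded, k, sides = 2L)[(hw + 1L):(hw + length(counts))])
}

#' Detect conductance levels from a trace
#'
#' Peak-seeded Gaussian-mixture estimate of the discrete current levels in a
#' trace. Candidate levels are local maxima of the kernel-smoothed all-point
#' histogram; peaks closer than `min_separation` are merged; the zero
#' (closed) level is always present and anchored at 0 pA (recordings are
#' baseline-subtracted). Means (except zero), standard deviations and
#' weights are then refined by expectation-maximization.
#'
#' @param trace A `"kir_trace"` or numeric current vector (pA).
#' @param expected_max_levels Maximum number of levels including the closed
#'   level (>= 2).
#' @param min_separation Minimum distance between reported levels, pA.
#' @param bin_width Histogram bin width, pA.
#' @param smooth_sd Smoothing kernel sd for peak counting, pA.
#' @param peak_frac Minimum smoothed peak height, as a fraction of the
#'   largest peak.
#' @param max_samples Cap on samples used in the EM refinement (the trace is
#'   thinned deterministically above this).
#' @return Object of class `"level_set"`: data frame with `level` (labels
#'   `C`, `O1`..`Om` by increasing amplitude), `current` (pA), `sd` (pA),
#'   `weight`, and `rel_amplitude` (|current| / max |current|).
#' @export
detect_levels <- function(trace, expected_max_levels = 5L,
                          min_separation = 0.3, bin_width = 0.1,
                          smooth_sd = 0.1, peak_frac = 0.01,
                          max_samples = 200000L) {
  x <- trace_current(trace)
  if (!length(x)) stop("empty trace")
  if (expected_max_levels < 2L) stop("'expected_max_levels' must be >= 2")
  h <- allpoint_histogram(x, bin_width)
  cs <- smooth_counts(h$counts, bin_width, smooth_sd)
  n <- length(cs)
  is_peak <- cs >= c(-Inf, cs[-n]) & cs > c(cs[-1L], -Inf) &
    cs >= peak_frac * max(cs)
  cand <- h$mids[is_peak]
  mass <- cs[is_peak]
  # anchor the closed level at exactly 0 pA
  near0 <- which(abs(cand) < min_separation)
  if (length(near0)) {
    cand[near0[which.min(abs(cand[near0]))]] <- 0
  } else {
    cand <- c(cand, 0)
    mass <- c(mass, 0)
  }
  ord <- order(cand)
  cand <- cand[ord]; mass <- mass[ord]
  # merge peaks closer than min_separation (keep 0 fixed when involved)
  repeat {
    if (length(cand) < 2L) break
    gaps <- diff(cand)
    j <- which.min(gaps)
    if (gaps[j] >= min_separation) break
    pair <- c(j, j + 1L)
    zero_in <- which(abs(cand[pair]) < 1e-9)
    newm <- if (length(zero_in)) 0 else
      sum(cand[pair] * mass[pair]) / max(sum(mass[pair]), 1e-12)
    cand <- c(cand[-pair], newm)
    mass <- c(mass[-pair], sum(mass[pair]))
    ord <- order(cand); cand <- cand[ord]; mass <- mass[ord]
  }
  zero_i <- which(abs(cand) < 1e-9)[1L]
  nonzero <- setdiff(seq_along(cand), zero_i)
  if (!length(nonzero))
    stop("no resolvable non-zero conductance peak: check polarity, ",
         "noise level, or bin/smoothing settings")
  if (length(nonzero) > expected_max_levels - 1L)
    nonzero <- nonzero[order(mass[nonzero],
                             decreasing = TRUE)][seq_len(expected_max_levels - 1L)]
  keep <- sort(c(zero_i, nonzero))
  mu <- cand[keep]
  fixed <- abs(mu) < 1e-9
  xs <- if (length(x) > max_samples)
    x[seq.int(1L, length(x), length.out = max_samples)] else x
  sd0 <- max(min_separation / 2, bin_width)
  em <- em_refine(xs, mu, fixed, sd0 = sd0, max_iter = 40L)
  # overlapping levels need not produce separate histogram modes; expand the
  # mixture to the expected level count by splitting, at each step, the free
  # component whose split most improves the likelihood (noise is common to
  # all levels, so genuine sub-structure shows up as excess spread); the
  # merge rule below undoes superfluous splits
  xt <- if (length(xs) > 50000L)
    xs[seq.int(1L, length(xs), length.out = 50000L)] else xs
  while (length(em$mu) < expected_max_levels) {
    freei <- which(!fixed & em$w > 2e-3)
    if (!length(freei)) break
    ref <- em_refine(xt, em$mu, fixed, sd0 = sd0, max_iter = 30L)
    trials <- lapply(freei, function(j) {
      mu2 <- c(em$mu[-j], em$mu[j] - em$sigma, em$mu[j] + em$sigma)
      fx2 <- c(fixed[-j], FALSE, FALSE)
      fit <- em_refine(xt, mu2, fx2, sd0 = sd0, max_iter = 30L)
      list(fit = fit, fixed = fx2)
    })
    best <- which.max(vapply(trials, function(t) t$fit$ll, numeric(1)))
    if (trials[[best]]$fit$ll <= ref$ll + 1e-6 * abs(ref$ll)) break
    fixed <- trials[[best]]$fixed
    em <- em_refine(xs, trials[[best]]$fit$mu, fixed, sd0 = sd0,
                    max_iter = 40L, start = trials[[best]]$fit)
  }
  em <- em_refine(xs, em$mu, fixed, sd0 = sd0, start = em)
  mu <- em$mu; sds <- em$sd; w <- em$w
  # merge refined components closer than min_separation (zero stays at 0)
  repeat {
    if (length(mu) < 2L) break
    ordm <- order(mu)
    mu <- mu[ordm]; sds <- sds[ordm]; w <- w[ordm]; fixed <- fixed[ordm]
    gaps <- diff(mu)
    j <- which.min(gaps)
    if (gaps[j] >= min_separation) break
    pair <- c(j, j + 1L)
    wsum <- max(sum(w[pair]), 1e-12)
    newmu <- if (any(fixed[pair])) 0 else sum(mu[pair] * w[pair]) / wsum
    newsd <- sqrt(sum(w[pair] * (sds[pair]^2 + (mu[pair] - newmu)^2)) / wsum)
    mu <- c(mu[-pair], newmu); sds <- c(sds[-pair], newsd)
    w <- c(w[-pair], wsum); fixed <- c(fixed[-pair], any(fixed[pair]))
  }
  # a component can starve during refinement; drop it rather than report it
  alive <- fixed | w > 5e-4
  mu <- mu[alive]; sds <- sds[alive]; w <- w[alive]
  if (sum(!(abs(mu) < 1e-9)) == 0L)
    stop("no resolvable non-zero conductance peak after refinement")
  ord <- order(abs(mu))
  mu <- mu[ord]; sds <- sds[ord]; w <- w[ord]
  top <- max(abs(mu))
  lab <- c("C", paste0("O", seq_len(length(mu) - 1L)))
  out <- data.frame(level = factor(lab, levels = lab), current = mu,
                    sd = sds, weight = w, rel_amplitude = abs(mu) / top)
  class(out) <- c("level_set", "data.frame")
  out
}

# 1-D Gaussian-mixture EM with a common component variance (recording noise
# is level-independent); components with fixed[i] keep their mean. Returns
# per-component posterior spreads in `sd` alongside the common `sigma`.
em_refine <- function(x, mu, fixed, sd0, max_iter = 100L, tol = 1e-8,
                      start = NULL) {
  m <- length(mu)
  sigma <- if (!is.null(start)) start$sigma else sd0
  w <- if (!is.null(start)) start$w else rep(1 / m, m)
  n <- length(x)
  ll <- ll_old <- -Inf
  r <- NULL
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(m),
                   function(j) w[j] * stats::dnorm(x, mu[j], sigma),
                   numeric(n))
    tot <- rowSums(dens)
    tot[tot <= 0 | !is.finite(tot)] <- .Machine$double.xmin
    ll <- sum(log(tot))
    r <- dens / tot
    nk <- colSums(r)
    w <- nk / n
    for (j in seq_len(m))
      if (!fixed[j] && nk[j] > 1e-9) mu[j] <- sum(r[, j] * x) / nk[j]
    sq <- vapply(seq_len(m), function(j) sum(r[, j] * (x - mu[j])^2),
                 numeric(1))
    sigma <- max(sqrt(sum(sq) / n), 1e-4)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll)) break
    ll_old <- ll
  }
  nk <- colSums(r)
  sds <- vapply(seq_len(m), function(j)
    if (nk[j] > 1e-9) sqrt(sum(r[, j] * (x - mu[j])^2) / nk[j]) else sigma,
    numeric(1))
  list(mu = mu, sd = pmax(sds, 1e-4), w = w, sigma = sigma, ll = ll)
}

#' Normalized sub-state amplitudes
#'
#' Each level's absolute current divided by the largest absolute level
#' current, so the fully open level reads 1.0. Invariant under sign flips
#' and uniform scaling of the currents.
#'
#' @param levels A `"level_set"` (from [detect_levels()]) or numeric vector
#'   of level currents in pA (0 allowed for the closed level).
#' @return Named numeric vector of relative amplitudes, one per level.
#' @examples
#' relative_amplitudes(c(0, -3.24, -5.33, -6.62, -7.2))
#' @export
relative_amplitudes <- function(levels) {
  cur <- if (inherits(levels, "level_set")) levels$current else levels
  if (!is.numeric(cur) || !length(cur)) stop("no levels supplied")
  top <- max(abs(cur))
  if (top == 0) stop("all levels are zero; relative amplitudes undefined")
  out <- abs(cur) / top
  names(out) <- if (inherits(levels, "level_set")) as.character(levels$level)
  else {
    ord_lab <- rank(abs(cur), ties.method = "first")
    ifelse(cur == 0, "C", paste0("O", ord_lab - any(cur == 0)))
  }
  out
}

#' Idealize a trace into an event table
#'
#' Assigns every sample to a conductance level by the most probable (Viterbi)
#' path under Gaussian emissions with a sticky uniform transition prior,
#' merges events shorter than the dead time into their neighbours, and
#' recomputes event mean currents from the raw samples.
#'
#' @param trace A `"kir_trace"`.
#' @param levels A `"level_set"` (default: [detect_levels()] on the trace).
#' @param dead_time Shortest resolvable event, s (default 0.5 ms, about 1.5x
#'   the 1 kHz filter rise time). Must be at least one sample.
#' @param stay_prob Per-sample probability of staying in the current level
#'   under the transition prior (default 0.999).
#' @return An `"event_table"` data frame: `level` (factor, `C`/`O1`..),
#'   `start_s`, `duration_s`, `mean_pA`; events tile the trace contiguously.
#' @export
idealize <- function(trace, levels = detect_levels(trace),
                     dead_time = 5e-4, stay_prob = 0.999) {
  stopifnot(inherits(trace, "kir_trace"), inherits(levels, "level_set"))
  fs <- trace$acquisition$sample_rate
  if (dead_time < 1 / fs) stop("'dead_time' must be at least one sample")
  if (stay_prob <= 0 || stay_prob >= 1) stop("'stay_prob' must be in (0,1)")
  x <- trace$current
  m <- nrow(levels)
  sds <- pmax(levels$sd, 1e-6)
  sw <- if (m > 1L) log((1 - stay_prob) / (m - 1L)) else log(1e-12)
  z <- viterbi_gaussian(x, levels$current, sds, log(stay_prob), sw)
  ev <- runs_to_events(z, fs)
  ev <- merge_short_events(ev, x, fs, dead_time, levels$current)
  ev$mean_pA <- event_means(ev, x, fs)
  out <- data.frame(level = factor(as.character(levels$level)[ev$state],
                                   levels = levels(levels$level)),
                    start_s = ev$start, duration_s = ev$duration,
                    mean_pA = ev$mean_pA)
  class(out) <- c("event_table", "data.frame")
  attr(out, "sample_rate") <- fs
  out
}

runs_to_events <- function(z, fs) {
  n <- length(z)
  new_run <- c(TRUE, z[-1L] != z[-n])
  starts <- which(new_run)
  lens <- diff(c(starts, n + 1L))
  data.frame(state = z[starts], start = (starts - 1L) / fs,
             duration = lens / fs)
}

merge_short_events <- function(ev, x, fs, dead_time, level_currents) {
  repeat {
    if (nrow(ev) <= 1L) break
    short <- which(ev$duration < dead_time - 1e-12)
    if (!length(short)) break
    i <- short[which.min(ev$duration[short])]
    # raw mean of the short stretch decides which neighbour absorbs it
    idx <- sample_range(ev$start[i], ev$duration[i], fs, length(x))
    xbar <- mean(x[idx])
    nb <- c(if (i > 1L) i - 1L, if (i < nrow(ev)) i + 1L)
    nb_dist <- abs(level_currents[ev$state[nb]] - xbar)
    j <- nb[which.min(nb_dist)]
    lo <- min(i, j); hi <- max(i, j)
    ev$duration[lo] <- ev$duration[lo] + ev$duration[hi]
    ev$state[lo] <- ev$state[j]
    ev <- ev[-hi, , drop = FALSE]
    # coalesce with neighbours that now share the level
    ev <- coalesce_events(ev)
  }
  ev
}

coalesce_events <- function(ev) {
  if (nrow(ev) <= 1L) return(ev)
  grp <- cumsum(c(TRUE, ev$state[-1L] != ev$state[-nrow(ev)]))
  if (max(grp) == nrow(ev)) return(ev)
  data.frame(state = ev$state[!duplicated(grp)],
             start = ev$start[!duplicated(grp)],
             duration = as.numeric(tapply(ev$duration, grp, sum)))
}

sample_range <- function(start, duration, fs, n) {
  a <- round(start * fs) + 1L
  b <- min(round((start + duration) * fs), n)
  a:max(a, b)
}

event_means <- function(ev, x, fs) {
  vapply(seq_len(nrow(ev)),
         function(i) mean(x[sample_range(ev$start[i], ev$duration[i], fs,
                                         length(x))]),
         numeric(1))
}

#' Read / write event tables and level sets
#'
#' Event tables use CSV with header `level,start_s,duration_s,mean_pA`;
#' level sets use JSON.
#'
#' @param events An `"event_table"`.
#' @param levels A `"level_set"`.
#' @param path File path.
#' @return Readers return the corresponding object.
#' @export
write_events <- function(events, path) {
  stopifnot(inherits(events, "event_table"))
  utils::write.csv(events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  x <- utils::read.csv(path)
  need <- c("level", "start_s", "duration_s", "mean_pA")
  if (!all(need %in% names(x))) stop("event CSV needs columns ",
                                     paste(need, collapse = ","))
  m <- sum(grepl("^O[0-9]+$", unique(x$level)))
  x$level <- factor(x$level, levels = c("C", paste0("O", seq_len(m))))
  class(x) <- c("event_table", "data.frame")
  x
}

#' @rdname write_events
#' @export
write_levels <- function(levels, path) {
  stopifnot(inherits(levels, "level_set"))
  jsonlite::write_json(as.data.frame(levels), path, auto_unbox = FALSE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_events
#' @export
read_levels <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$level <- factor(x$level, levels = x$level)
  class(x) <- c("level_set", "data.frame")
  x
}
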