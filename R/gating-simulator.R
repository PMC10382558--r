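#' Kinetic parameters for the protonation-gating simulator
#'
#' Rate parameterization of the gating scheme: per-site protonation at
#' `k_on * [H+]` (diffusion-limited association by default), per-site
#' deprotonation at `k_off = k_on * K_H`, closure of any conducting state
#' into its paired brief-closed state at `lambda_c`, and re-opening at
#' `1 / tau_c`. With the default `K_H = 2e-7` M the protonation and
#' deprotonation rates at neutral pH are both in the 1e3/s range, i.e.
#' millisecond sub-state dwells.
#'
#' @param model A [model_params()] object. The simulator requires a single
#'   effective site class (one `K_H`); combine classes before simulating.
#' @param k_on Per-site protonation rate constant, 1/(M s).
#' @param tau_c Mean brief-closed dwell, s.
#' @param lambda_c Closure rate of a conducting state, 1/s. Default
#'   `K_OC / tau_c`, so the open/brief-closed equilibrium of the simulator
#'   matches the model's `K_OC`.
#' @param rate_scale Overall multiplier on the protonation/deprotonation
#'   rates (an effective pKa-shift factor; default 1).
#' @return Object of class `"kinetic_params"`.
#' @export
kinetic_params <- function(model = model_params(), k_on = 1e10,
                           tau_c = 0.0064,
                           lambda_c = model$K_OC / tau_c,
                           rate_scale = 1) {
  stopifnot(inherits(model, "model_params"))
  kh <- unique(vapply(model$site_classes, `[[`, numeric(1), "K_H"))
  if (length(kh) != 1L)
    stop("the kinetic simulator needs a single K_H; got ", length(kh),
         " distinct site classes")
  if (any(!is.finite(c(k_on, tau_c, lambda_c, rate_scale))) ||
      k_on < 0 || tau_c <= 0 || lambda_c < 0 || rate_scale < 0)
    stop("rates must be non-negative (tau_c strictly positive)")
  structure(list(model = model, K_H = kh, k_on = k_on * rate_scale,
                 k_off = k_on * rate_scale * kh,
                 lambda_c = lambda_c, tau_c = tau_c),
            class = "kinetic_params")
}

#' Build the transition-rate generator of the gating scheme
#'
#' States are `(k, O)` and `(k, C)` for protonation count `k = 0..N`.
#' Protonation from `(k, .)` proceeds at `(N - k) * k_on * [H+]`,
#' deprotonation at `k * k_off`; closures (`O -> C` at `lambda_c`,
#' `C -> O` at `1/tau_c`) are permitted from every protonation state and do
#' not change `k` (closures are independent of the protonation ladder).
#'
#' @param kp A [kinetic_params()] object.
#' @param pH Acidity setting `[H+] = 10^-pH`.
#' @return Object of class `"gating_generator"`: list with the rate matrix
#'   `Q` (rows = from-state, diagonal = negative exit rate), a `states`
#'   data frame (`k`, `open`, `g_rel`), and the parameters.
#' @export
build_generator <- function(kp, pH = 7.4) {
  stopifnot(inherits(kp, "kinetic_params"))
  if (!is.numeric(pH) || length(pH) != 1L || !is.finite(pH))
    stop("'pH' must be a single finite number")
  N <- kp$model$n_total
  h <- 10^(-pH)
  n_states <- 2L * (N + 1L)
  # state order: open k = 0..N, then closed k = 0..N
  states <- data.frame(
    k = rep(0:N, 2L),
    open = rep(c(TRUE, FALSE), each = N + 1L))
  states$g_rel <- ifelse(states$open, kp$model$conductance_map[states$k + 1L], 0)
  Q <- matrix(0, n_states, n_states)
  io <- function(k) k + 1L          # open state index
  ic <- function(k) N + 2L + k      # closed state index
  for (k in 0:N) {
    if (k < N) {
      Q[io(k), io(k + 1L)] <- (N - k) * kp$k_on * h
      Q[ic(k), ic(k + 1L)] <- (N - k) * kp$k_on * h
    }
    if (k > 0) {
      Q[io(k), io(k - 1L)] <- k * kp$k_off
      Q[ic(k), ic(k - 1L)] <- k * kp$k_off
    }
    Q[io(k), ic(k)] <- kp$lambda_c
    Q[ic(k), io(k)] <- 1 / kp$tau_c
  }
  diag(Q) <- -rowSums(Q)
  structure(list(Q = Q, states = states, kp = kp, pH = pH),
            class = "gating_generator")
}

#' Stationary distribution of a gating generator
#'
#' Solves the null space of the rate matrix (`pi Q = 0`, `sum(pi) = 1`). At
#' equilibrium this equals the analytic binomial [state_distribution()] when
#' `lambda_c * tau_c = K_OC`.
#'
#' @param gen A `"gating_generator"`.
#' @return Numeric stationary probability vector over the generator's states.
#' @export
stationary_distribution <- function(gen) {
  stopifnot(inherits(gen, "gating_generator"))
  n <- nrow(gen$Q)
  A <- rbind(t(gen$Q), rep(1, n))
  drop(qr.solve(A, c(rep(0, n), 1)))
}

#' Exact stochastic simulation of the gating state path
#'
#' Gillespie-type sampling of the continuous-time Markov chain defined by a
#' generator: the dwell in each state is exponential with the state's total
#' exit rate, and the successor is drawn proportionally to the outgoing
#' rates. The final dwell is truncated at `duration`.
#'
#' @param gen A `"gating_generator"` (or any list with `Q` and `states`).
#' @param duration Simulated time, s.
#' @param seed Optional RNG seed for reproducibility.
#' @param init Initial state index, or `"stationary"` to draw it from the
#'   stationary distribution (default, so time averages are unbiased).
#' @return A `"state_path"` data frame with columns `state` (index), `k`,
#'   `open`, `g_rel`, `time` (entry, s) and `dwell` (s).
#' @export
simulate_path <- function(gen, duration, seed = NULL, init = "stationary") {
  stopifnot(inherits(gen, "gating_generator") || is.list(gen))
  if (!is.numeric(duration) || duration <= 0) stop("'duration' must be > 0")
  if (!is.null(seed)) set.seed(seed)
  if (identical(init, "stationary")) {
    pi0 <- stationary_distribution(gen)
    init <- sample.int(length(pi0), 1L, prob = pmax(pi0, 0))
  }
  path <- gillespie(gen$Q, init, duration)
  st <- gen$states[path$state, , drop = FALSE]
  out <- data.frame(state = path$state, k = st$k, open = st$open,
                    g_rel = st$g_rel, time = path$time, dwell = path$dwell)
  attr(out, "duration") <- duration
  class(out) <- c("state_path", "data.frame")
  out
}

# core CTMC sampler over a rate matrix (diagonal ignored)
gillespie <- function(Q, init, duration) {
  n <- nrow(Q)
  R <- Q; diag(R) <- 0
  exit <- rowSums(R)
  targets <- lapply(seq_len(n), function(i) which(R[i, ] > 0))
  cump <- lapply(seq_len(n), function(i) {
    p <- R[i, targets[[i]]]
    cumsum(p) / sum(p)
  })
  cap <- 1024L
  s_state <- integer(cap); s_time <- numeric(cap); s_dwell <- numeric(cap)
  m <- 0L; t <- 0; i <- init
  while (t < duration) {
    dwell <- if (exit[i] > 0) stats::rexp(1L, exit[i]) else Inf
    m <- m + 1L
    if (m > cap) {
      cap <- cap * 2L
      length(s_state) <- cap; length(s_time) <- cap; length(s_dwell) <- cap
    }
    s_state[m] <- i; s_time[m] <- t; s_dwell[m] <- min(dwell, duration - t)
    t <- t + dwell
    if (t >= duration) break
    tg <- targets[[i]]
    i <- if (length(tg) == 1L) tg else
      tg[findInterval(stats::runif(1L), cump[[i]]) + 1L]
  }
  list(state = s_state[seq_len(m)], time = s_time[seq_len(m)],
       dwell = s_dwell[seq_len(m)])
}

#' Acquisition settings for trace rendering
#'
#' Emulates the experimental recording chain: sampling at `sample_rate`
#' (default 3 kHz) after low-pass filtering at `filter_corner` (default
#' 1 kHz, a Bessel-type corner), at a holding `voltage` relative to
#' `reversal`, with white background noise of post-filter RMS `noise_sd`.
#'
#' @param sample_rate Output sampling rate, Hz.
#' @param filter_corner Low-pass -3 dB corner, Hz; `Inf` disables filtering.
#' @param noise_sd RMS noise in the delivered trace, pA.
#' @param voltage Membrane potential, mV.
#' @param reversal Reversal potential, mV.
#' @param full_conductance Fully open single-channel conductance, pS.
#' @param pH Acidity tag carried in the metadata.
#' @param seed Optional RNG seed used when rendering.
#' @return Object of class `"acquisition_params"`.
#' @export
acquisition_params <- function(sample_rate = 3000, filter_corner = 1000,
                               noise_sd = 0.35, voltage = -120, reversal = 0,
                               full_conductance = 60, pH = 7.4, seed = NULL) {
  if (is.finite(filter_corner) && sample_rate <= 2 * filter_corner * 0.9)
    stop("'sample_rate' must exceed 1.8x the filter corner")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  structure(list(sample_rate = sample_rate, filter_corner = filter_corner,
                 noise_sd = noise_sd, voltage = voltage, reversal = reversal,
                 full_conductance = full_conductance, pH = pH, seed = seed),
            class = "acquisition_params")
}

# Gaussian FIR low-pass kernel with -3 dB corner fc at sampling rate fs
# (sigma_t = 0.1325 / fc, the standard software emulation of a multi-pole
# Bessel response in single-channel work)
gaussian_fir <- function(fc, fs) {
  sigma <- 0.1325 * fs / fc
  hw <- max(1L, ceiling(4 * sigma))
  h <- stats::dnorm(seq.int(-hw, hw), 0, sigma)
  h / sum(h)
}

# filter with edge replication so long constant segments keep their mean
apply_fir <- function(x, h) {
  hw <- (length(h) - 1L) %/% 2L
  xp <- c(rep(x[1L], hw), x, rep(x[length(x)], hw))
  y <- stats::filter(xp, h, method = "convolution", sides = 2L)
  as.numeric(y[(hw + 1L):(hw + length(x))])
}

#' Render a noisy, filtered current trace from a state path
#'
#' Converts a gating state path into a sampled single-channel current trace:
#' the ideal piecewise-constant current is `i(t) = g_rel * full_conductance *
#' (V - E_rev) / 1000` pA (0 when closed), white Gaussian noise is added at
#' an oversampled internal rate, the sum is low-pass filtered with a
#' Gaussian (Bessel-emulating) kernel at the filter corner, and the result
#' is decimated to the acquisition sampling rate. `noise_sd` is calibrated
#' so that the delivered (post-filter) trace has that RMS noise.
#'
#' @param path A `"state_path"` (from [simulate_path()] or
#'   [simulate_occupancy_trace()]'s internals) with a `g_rel` column, or any
#'   data frame with `time`, `dwell` and either `g_rel` or `k`/`open`.
#' @param acq An [acquisition_params()] object.
#' @param conductance_map Optional map used to derive `g_rel` from `k` when
#'   the path lacks a `g_rel` column.
#' @param oversample Internal oversampling factor for filtering (default 8).
#' @return Object of class `"kir_trace"`: list with `times` (s), `current`
#'   (pA), `ideal_current` (noiseless, unfiltered ground truth, pA),
#'   `acquisition`, and `true_path`.
#' @export
render_trace <- function(path, acq, conductance_map = NULL, oversample = 8L) {
  stopifnot(is.data.frame(path), inherits(acq, "acquisition_params"))
  if (is.null(path$g_rel)) {
    if (is.null(conductance_map))
      stop("path has no 'g_rel'; supply 'conductance_map'")
    path$g_rel <- ifelse(path$open, conductance_map[path$k + 1L], 0)
  }
  if (!is.null(acq$seed)) set.seed(acq$seed)
  duration <- sum(path$dwell)
  fs <- acq$sample_rate
  n_out <- floor(duration * fs + 1e-9)
  if (n_out < 1L) stop("path too short for one sample at the acquisition rate")
  amp <- acq$full_conductance * (acq$voltage - acq$reversal) / 1000  # pA
  seg_current <- path$g_rel * amp
  do_filter <- is.finite(acq$filter_corner)
  os <- if (do_filter) as.integer(oversample) else 1L
  fs_i <- fs * os
  t_i <- seq.int(0L, n_out * os - 1L) / fs_i
  seg <- findInterval(t_i, path$time, rightmost.closed = FALSE)
  seg[seg < 1L] <- 1L
  ideal_i <- seg_current[seg]
  if (do_filter) {
    h <- gaussian_fir(acq$filter_corner, fs_i)
    att <- sqrt(sum(h^2))  # white-noise RMS attenuation of the kernel
    x <- ideal_i
    if (acq$noise_sd > 0)
      x <- x + stats::rnorm(length(x), 0, acq$noise_sd / att)
    y <- apply_fir(x, h)
  } else {
    y <- ideal_i
    if (acq$noise_sd > 0)
      y <- y + stats::rnorm(length(y), 0, acq$noise_sd)
  }
  keep <- seq.int(1L, by = os, length.out = n_out)
  structure(list(times = t_i[keep], current = y[keep],
                 ideal_current = ideal_i[keep],
                 acquisition = acq, true_path = path),
            class = "kir_trace")
}

#' @export
print.kir_trace <- function(x, ...) {
  cat(sprintf("Single-channel trace: %.3f s at %g Hz (%d samples)\n",
              length(x$times) / x$acquisition$sample_rate,
              x$acquisition$sample_rate, length(x$times)))
  cat(sprintf("  V = %g mV, full conductance %g pS, filter %g Hz, noise %g pA\n",
              x$acquisition$voltage, x$acquisition$full_conductance,
              x$acquisition$filter_corner, x$acquisition$noise_sd))
  invisible(x)
}

#' Simulate a trace with prescribed level occupancies
#'
#' Semi-Markov simulation over a set of conductance levels whose long-run
#' time-weighted occupancies equal a target stationary vector. Conducting
#' levels exchange only with their nearest (adjacent) conducting neighbours
#' via Metropolis-balanced rates; the zero level (brief closures), when
#' present, is reachable from every conducting level at a uniform rate, with
#' re-openings distributed proportionally to the conducting occupancies --
#' matching the observed behaviour that closed-state re-entries follow the
#' sub-state distribution. The whole chain satisfies detailed balance with
#' the target vector, so the target is realized exactly in expectation.
#'
#' @param levels Relative amplitudes of the levels (0 denotes the closed
#'   level; at most one zero entry).
#' @param occupancies Target stationary occupancy of each level; sums to 1.
#' @param mean_dwells Mean dwell scale, s: a scalar or one value per level
#'   (the closed entry sets the mean closed dwell exactly).
#' @param acq An [acquisition_params()] object.
#' @param duration Simulated time, s.
#' @param seed Optional RNG seed.
#' @return A `"kir_trace"` (see [render_trace()]); its `true_path` carries
#'   `level` (index into `levels`) and `g_rel` per segment.
#' @export
simulate_occupancy_trace <- function(levels, occupancies,
                                     mean_dwells = 0.010, acq,
                                     duration = 30, seed = NULL) {
  stopifnot(length(levels) == length(occupancies))
  if (any(occupancies < 0) || abs(sum(occupancies) - 1) > 1e-8)
    stop("'occupancies' must be non-negative and sum to 1")
  if (sum(levels == 0) > 1L) stop("at most one zero (closed) level")
  nl <- length(levels)
  d <- rep_len(mean_dwells, nl)
  if (any(d <= 0)) stop("'mean_dwells' must be positive")
  Q <- matrix(0, nl, nl)
  closed <- which(levels == 0 & occupancies > 0)
  open_act <- setdiff(which(occupancies > 0), closed)
  if (!length(open_act)) stop("no conducting level with positive occupancy")
  op <- open_act[order(abs(levels[open_act]))]
  pi_ <- occupancies
  if (length(op) > 1L) {
    for (j in seq_len(length(op) - 1L)) {
      i1 <- op[j]; i2 <- op[j + 1L]
      a <- 2 / (d[i1] + d[i2])              # symmetric edge weight
      Q[i1, i2] <- a * min(1, pi_[i2] / pi_[i1])
      Q[i2, i1] <- a * min(1, pi_[i1] / pi_[i2])
    }
  }
  if (length(closed) == 1L) {
    pc <- pi_[closed]
    kappa <- pc / (d[closed] * (1 - pc))    # uniform closure rate
    for (i in op) {
      Q[i, closed] <- kappa
      Q[closed, i] <- kappa * pi_[i] / pc   # re-entry proportional to occupancy
    }
  } else if (length(op) == 1L) {
    stop("stationary vector unreachable: a single isolated level cannot gate")
  }
  diag(Q) <- -rowSums(Q)
  if (!is.null(seed)) set.seed(seed)
  init <- sample.int(nl, 1L, prob = pmax(pi_, 0))
  raw <- gillespie(Q, init, duration)
  path <- data.frame(state = raw$state, level = raw$state,
                     g_rel = levels[raw$state],
                     open = levels[raw$state] != 0,
                     time = raw$time, dwell = raw$dwell)
  attr(path, "duration") <- duration
  class(path) <- c("state_path", "data.frame")
  render_trace(path, acq)
}

#' Convert a true state path into an event table
#'
#' Collapses consecutive path segments with equal conductance into events
#' and labels them by amplitude rank (`C` for zero, then `O1`..`Om` in
#' increasing amplitude) -- the same format produced by [idealize()], useful
#' as ground truth for downstream statistics.
#'
#' @param path A `"state_path"` with `g_rel`, `time`, `dwell`.
#' @param acq Optional [acquisition_params()] to convert relative amplitudes
#'   to pA (otherwise `mean_pA` is the relative amplitude).
#' @return An `"event_table"` data frame: `level` (factor `C`, `O1`..),
#'   `start_s`, `duration_s`, `mean_pA`.
#' @export
path_events <- function(path, acq = NULL) {
  stopifnot(is.data.frame(path), !is.null(path$g_rel))
  g <- path$g_rel
  amp <- if (is.null(acq)) 1 else
    acq$full_conductance * (acq$voltage - acq$reversal) / 1000
  run <- c(TRUE, g[-1L] != g[-length(g)])
  id <- cumsum(run)
  start <- path$time[run]
  durs <- as.numeric(tapply(path$dwell, id, sum))
  gs <- g[run]
  ulev <- sort(unique(abs(gs[gs != 0])))
  lab <- ifelse(gs == 0, "C", paste0("O", match(abs(gs), ulev)))
  out <- data.frame(
    level = factor(lab, levels = c("C", paste0("O", seq_along(ulev)))),
    start_s = start, duration_s = durs, mean_pA = gs * amp)
  class(out) <- c("event_table", "data.frame")
  out
}

#' Read / write traces as delimited text with JSON sidecar metadata
#'
#' The trace is stored as two-column CSV (`time_s,current_pA`); the
#' acquisition metadata go to `<path>.meta.json`.
#'
#' @param trace A `"kir_trace"`.
#' @param path CSV file path.
#' @return `read_trace()` returns a `"kir_trace"` (without ground truth).
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "kir_trace"))
  utils::write.csv(data.frame(time_s = trace$times,
                              current_pA = trace$current),
                   path, row.names = FALSE, quote = FALSE)
  meta <- trace$acquisition
  class(meta) <- NULL
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))],
                       paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  x <- utils::read.csv(path)
  if (!all(c("time_s", "current_pA") %in% names(x)))
    stop("trace CSV needs columns time_s,current_pA")
  meta_path <- paste0(path, ".meta.json")
  acq <- if (file.exists(meta_path)) {
    m <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    do.call(acquisition_params, m[names(m) %in% names(formals(acquisition_params))])
  } else {
    dt <- stats::median(diff(x$time_s))
    acquisition_params(sample_rate = round(1 / dt), filter_corner = Inf,
                       noise_sd = 0)
  }
  structure(list(times = x$time_s, current = x$current_pA,
                 ideal_current = NULL, acquisition = acq, true_path = NULL),
            class = "kir_trace")
}
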