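# Independent brute-force oracles used to cross-check the package's
# implementations. Deliberately written with the simplest possible logic.

# joint protonation-count distribution by enumeration of all 2^N per-site
# on/off configurations
enumerate_count_dist <- function(n_sites_per_class, f_per_class) {
  N <- sum(n_sites_per_class)
  f_site <- rep(f_per_class, n_sites_per_class)
  pk <- numeric(N + 1L)
  for (code in 0:(2^N - 1L)) {
    on <- as.logical(bitwAnd(code, bitwShiftL(1L, 0:(N - 1L))))
    p <- prod(ifelse(on, f_site, 1 - f_site))
    pk[sum(on) + 1L] <- pk[sum(on) + 1L] + p
  }
  pk
}

# per-ion permeation count by explicit membership series + pattern scan
brute_force_permeations <- function(traj) {
  fr <- split(as.data.frame(traj), traj$frame)
  nfr <- length(fr)
  geom <- lapply(fr, function(fd) {
    lo <- com(fd, "T143O"); hi <- com(fd, "Y146O")
    list(zlo = min(lo[3], hi[3]), zhi = max(lo[3], hi[3]),
         cx = (lo[1] + hi[1]) / 2, cy = (lo[2] + hi[2]) / 2)
  })
  ions <- sort(unique(traj$id[traj$tag == "K"]))
  total <- 0L
  for (ion in ions) {
    rows <- lapply(fr, function(fd) fd[fd$id == ion, ])
    state <- "out"
    for (i in seq_len(nfr)) {
      g <- geom[[i]]; r <- rows[[i]]
      inside <- (r$x - g$cx)^2 + (r$y - g$cy)^2 <= 0.25^2 &&
        r$z >= g$zlo && r$z <= g$zhi
      if (inside) state <- "sf"
      else {
        if (state == "sf" && r$z > g$zhi) total <- total + 1L
        state <- "out"
      }
    }
  }
  total
}

# O(n^2) scan over all atom pairs on opposing chains, one frame
brute_force_min_dist <- function(fd, residue, chains) {
  a <- fd[fd$tag == residue & fd$chain == chains[1], c("x", "y", "z")]
  b <- fd[fd$tag == residue & fd$chain == chains[2], c("x", "y", "z")]
  best <- Inf
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b)))
    best <- min(best, sqrt(sum((a[i, ] - b[j, ])^2)))
  10 * best  # Angstrom
}

# per-frame in-cylinder membership by direct per-particle scan
brute_force_pore_trace <- function(traj, group, radius, height) {
  fr <- split(as.data.frame(traj), traj$frame)
  out <- list()
  for (fd in fr) {
    ctr <- com(fd, "M181")
    for (i in which(fd$tag == group)) {
      dx <- fd$x[i] - ctr[1]; dy <- fd$y[i] - ctr[2]
      if (sqrt(dx^2 + dy^2) <= radius && abs(fd$z[i] - ctr[3]) <= height / 2)
        out[[length(out) + 1L]] <- data.frame(frame = fd$frame[i],
                                              id = fd$id[i], z = fd$z[i])
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(frame = integer(), id = integer(), z = numeric())
}
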