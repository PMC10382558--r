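#' Labeled particle trajectory frames
#'
#' Core container for trajectory analysis: a long-format table with one row
#' per particle per frame, columns `frame`, `id`, `tag` (group label, e.g.
#' `"K"`, `"W"` for water oxygens, or residue-atom tags such as `"M181"`,
#' `"T143O"`, `"I177"`), `chain` (`"A"`..`"D"` for protein atoms, `""`
#' otherwise), and coordinates `x`, `y`, `z` in nm (+z = extracellular).
#'
#' @param df Data frame with the columns above.
#' @param frame_interval_ps Time between frames, ps.
#' @param box Numeric length-3 box dimensions, nm.
#' @param label System tag (e.g. `"Qcav-8"`).
#' @return Object of class `"trajectory_frames"` (a validated data frame
#'   with metadata attributes).
#' @export
trajectory_frames <- function(df, frame_interval_ps = 1000,
                              box = c(10, 10, 12), label = "") {
  need <- c("frame", "id", "tag", "chain", "x", "y", "z")
  if (!is.data.frame(df) || !all(need %in% names(df)))
    stop("trajectory needs columns ", paste(need, collapse = ","))
  if (frame_interval_ps <= 0) stop("'frame_interval_ps' must be > 0")
  if (any(!is.finite(as.matrix(df[c("x", "y", "z")]))))
    stop("coordinates must be finite")
  fr <- sort(unique(df$frame))
  if (length(fr) > 1L && any(diff(fr) != 1L))
    stop("frame indices must be contiguous (gap after frame ",
         fr[which(diff(fr) != 1L)[1L]], ")")
  ids <- split(df$id, df$frame)
  ref <- sort(ids[[1L]])
  same <- vapply(ids, function(v) identical(sort(v), ref), logical(1))
  if (!all(same))
    stop("particle id set varies across frames (first differing frame ",
         names(ids)[which(!same)[1L]], ")")
  df <- df[order(df$frame, df$id), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "frame_interval_ps") <- frame_interval_ps
  attr(df, "box") <- box
  attr(df, "label") <- label
  class(df) <- c("trajectory_frames", "data.frame")
  df
}

#' Read / write trajectory frame tables
#'
#' TSV with header `frame,id,tag,chain,x,y,z`; metadata
#' (`frame_interval_ps`, `box`, `label`) in a `<path>.meta.json` sidecar.
#'
#' @param path TSV file path.
#' @param traj A `"trajectory_frames"` object.
#' @return `read_frames()` returns a validated `"trajectory_frames"`.
#' @export
read_frames <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("frame", "id", "tag", "chain", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s) ", paste(miss, collapse = ","), " in ", path)
  df$chain[is.na(df$chain)] <- ""
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  trajectory_frames(df,
                    frame_interval_ps = meta$frame_interval_ps %||% 1000,
                    box = meta$box %||% c(10, 10, 12),
                    label = meta$label %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_frames
#' @export
write_frames <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory_frames"))
  utils::write.table(as.data.frame(traj), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(frame_interval_ps = attr(traj, "frame_interval_ps"),
                            box = attr(traj, "box"),
                            label = attr(traj, "label")),
                       paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Geometric centre of a tagged group in one frame
#'
#' Unweighted geometric mean of the member coordinates (the trajectory
#' dialect carries no masses, so this stands in for the centre of mass).
#'
#' @param frame_df Rows of a single frame.
#' @param tag Group tag to select.
#' @param chain Optional chain filter.
#' @return Numeric `c(x, y, z)` in nm.
#' @export
com <- function(frame_df, tag, chain = NULL) {
  sel <- frame_df$tag == tag
  if (!is.null(chain)) sel <- sel & frame_df$chain %in% chain
  if (!any(sel)) stop("group '", tag, "' is empty in this frame")
  colMeans(frame_df[sel, c("x", "y", "z"), drop = FALSE])
}

#' Cylinder membership test
#'
#' A particle is inside the cylinder iff its radial (xy) distance from the
#' axis is at most `radius` and its z lies within the cylinder's z-range
#' (closed boundaries).
#'
#' @param x,y,z Particle coordinates (vectorized), nm.
#' @param center `c(x, y, z)` of the cylinder centre, nm.
#' @param radius Cylinder radius, nm.
#' @param height Cylinder height, nm (z-range `center[3] +/- height/2`);
#'   ignored when `z_range` is given.
#' @param z_range Optional explicit `c(zlo, zhi)` bounds, nm.
#' @return Logical vector.
#' @export
in_cylinder <- function(x, y, z, center, radius, height = NULL,
                        z_range = NULL) {
  if (is.null(z_range)) {
    if (is.null(height)) stop("give 'height' or 'z_range'")
    z_range <- center[3L] + c(-height, height) / 2
  }
  z_range <- sort(z_range)
  r2 <- (x - center[1L])^2 + (y - center[2L])^2
  r2 <= radius^2 & z >= z_range[1L] & z <= z_range[2L]
}

# default pore-analysis geometry, following the trajectory-analysis
# conventions used throughout: 11 nm high cylinders on the M181 geometric
# centre, radius 2.5 nm for K+ and 1 nm for water; SF cylinder of radius
# 0.25 nm between the T143/Y146 backbone-oxygen centres
pore_geometry <- function(group = c("K", "W")) {
  group <- match.arg(group)
  list(radius = if (group == "K") 2.5 else 1.0, height = 11,
       center_tag = "M181", sf_lower_tag = "T143O", sf_upper_tag = "Y146O",
       sf_radius = 0.25)
}

split_frames <- function(traj) split(as.data.frame(traj), traj$frame)

#' Axial positions of pore particles over time
#'
#' For every frame, reports the z coordinate of each particle of the group
#' (`"K"` ions or `"W"` water oxygens) inside the group's selection
#' cylinder, centred on the M181 geometric centre. Suitable for flux and
#' solvation plots.
#'
#' @param traj A `"trajectory_frames"`.
#' @param group `"K"` or `"W"`.
#' @return Data frame `frame`, `id`, `z` (nm), one row per in-pore particle
#'   per frame.
#' @export
pore_trace <- function(traj, group = c("K", "W")) {
  group <- match.arg(group)
  geo <- pore_geometry(group)
  out <- lapply(split_frames(traj), function(fd) {
    ctr <- com(fd, geo$center_tag)
    p <- fd[fd$tag == group, , drop = FALSE]
    ins <- in_cylinder(p$x, p$y, p$z, ctr, geo$radius, geo$height)
    data.frame(frame = p$frame[ins], id = p$id[ins], z = p$z[ins])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Count ion permeation (conduction) events
#'
#' State machine per K+ ion: an ion becomes "SF-occupying" when it enters
#' the selectivity-filter cylinder (radius 0.25 nm between the T143 and
#' Y146 backbone-oxygen centres) from below the upper bound; a conduction
#' event fires when it subsequently exits across the SF upper boundary into
#' the extracellular solvent (+z). Re-entry from above resets the state. A
#' warning is raised if any ion jumps more than half the box between frames
#' (a sign of wrapped coordinates).
#'
#' @param traj A `"trajectory_frames"` containing `"K"` particles and the SF
#'   marker groups.
#' @return Object of class `"permeation_count"`: list with `events` (data
#'   frame `id`, `frame` of the crossing), `total`, `rate_per_us`, and
#'   `duration_ps`.
#' @export
count_permeations <- function(traj) {
  geo <- pore_geometry("K")
  frames <- split_frames(traj)
  nfr <- length(frames)
  dt <- attr(traj, "frame_interval_ps")
  box <- attr(traj, "box")
  ions <- sort(unique(traj$id[traj$tag == "K"]))
  if (!length(ions)) stop("no K particles in trajectory")
  # per-frame SF geometry
  zlo <- zhi <- numeric(nfr); cx <- cy <- numeric(nfr)
  for (i in seq_len(nfr)) {
    lo <- com(frames[[i]], geo$sf_lower_tag)
    hi <- com(frames[[i]], geo$sf_upper_tag)
    zlo[i] <- min(lo[3L], hi[3L]); zhi[i] <- max(lo[3L], hi[3L])
    cc <- (lo + hi) / 2
    cx[i] <- cc[1L]; cy[i] <- cc[2L]
  }
  # ion coordinates as frame x ion matrices
  kk <- traj[traj$tag == "K", , drop = FALSE]
  ord <- order(kk$frame, kk$id)
  X <- matrix(kk$x[ord], nfr, length(ions), byrow = TRUE)
  Y <- matrix(kk$y[ord], nfr, length(ions), byrow = TRUE)
  Z <- matrix(kk$z[ord], nfr, length(ions), byrow = TRUE)
  if (nfr > 1L && any(abs(diff(Z)) > box[3L] / 2))
    warning("ion z-jump larger than half the box between frames; ",
            "coordinates may be wrapped")
  ev_id <- integer(0); ev_frame <- integer(0)
  for (j in seq_along(ions)) {
    occupying <- FALSE
    for (i in seq_len(nfr)) {
      inside <- (X[i, j] - cx[i])^2 + (Y[i, j] - cy[i])^2 <= geo$sf_radius^2 &&
        Z[i, j] >= zlo[i] && Z[i, j] <= zhi[i]
      if (inside) {
        occupying <- TRUE
      } else if (occupying) {
        if (Z[i, j] > zhi[i]) {     # exited across the extracellular bound
          ev_id <- c(ev_id, ions[j])
          ev_frame <- c(ev_frame, sort(unique(traj$frame))[i])
        }
        occupying <- FALSE
      }
    }
  }
  duration_ps <- (nfr - 1L) * dt
  structure(list(events = data.frame(id = ev_id, frame = ev_frame),
                 total = length(ev_id),
                 rate_per_us = if (duration_ps > 0)
                   length(ev_id) / duration_ps * 1e6 else NA_real_,
                 duration_ps = duration_ps),
            class = "permeation_count")
}

#' @export
print.permeation_count <- function(x, ...) {
  cat(sprintf("Permeation events: %d in %g ps (%.3g per us)\n",
              x$total, x$duration_ps, x$rate_per_us))
  invisible(x)
}

#' Axial K+ occupancy histogram and mean pore ion count
#'
#' Histograms the z positions of in-pore K+ ions over all frames (0.05 nm
#' bins by default) and reports the mean per-frame number of ions between
#' the G-loop (M308 centre) and the lower end of the selectivity filter.
#'
#' @param traj A `"trajectory_frames"`.
#' @param bin z-bin width, nm (default 0.05 nm = 0.5 A).
#' @return List of class `"pore_occupancy"`: `breaks`, `mids`, `counts`,
#'   `mean_count` (ions per frame between M308 and SF), `n_frames`.
#' @export
occupancy_histogram <- function(traj, bin = 0.05) {
  if (bin <= 0) stop("'bin' must be > 0")
  pt <- pore_trace(traj, "K")
  frames <- split_frames(traj)
  nfr <- length(frames)
  region_n <- numeric(nfr)
  for (i in seq_len(nfr)) {
    fd <- frames[[i]]
    z_top <- min(com(fd, "T143O")[3L], com(fd, "Y146O")[3L])
    z_bot <- com(fd, "M308")[3L]
    zz <- pt$z[pt$frame == fd$frame[1L]]
    region_n[i] <- sum(zz >= min(z_bot, z_top) & zz <= max(z_bot, z_top))
  }
  if (nrow(pt)) {
    lo <- floor(min(pt$z) / bin) * bin
    breaks <- seq(lo, max(pt$z) + bin, by = bin)
    hc <- graphics::hist(pt$z, breaks = breaks, plot = FALSE)
    counts <- hc$counts; mids <- hc$mids
  } else {
    breaks <- mids <- counts <- numeric(0)
  }
  structure(list(breaks = breaks, mids = mids, counts = counts,
                 mean_count = mean(region_n), per_frame = region_n,
                 n_frames = nfr, bin = bin),
            class = "pore_occupancy")
}

#' Minimum distance between opposing subunits for a residue
#'
#' Per frame, the minimum pairwise atom distance between the residue's atoms
#' on opposing chains -- pairs (A, C) and (B, D) -- reported in Angstrom, as
#' a gate-diameter proxy, with a histogram (default 0.1 A bins) and its
#' modal value.
#'
#' @param traj A `"trajectory_frames"`.
#' @param residue Residue tag (e.g. `"I177"`, `"M181"`, `"M302"`).
#' @param bin Histogram bin width, Angstrom.
#' @return List of class `"gate_distance"`: `per_frame` (data frame `frame`,
#'   `pair`, `dist_A`), `histogram` (`mids`, `counts`), `mode_A`.
#' @export
min_cross_subunit_distance <- function(traj, residue, bin = 0.1) {
  frames <- split_frames(traj)
  pairs <- list(AC = c("A", "C"), BD = c("B", "D"))
  rows <- list()
  for (fd in frames) {
    for (pn in names(pairs)) {
      p1 <- fd[fd$tag == residue & fd$chain == pairs[[pn]][1L], c("x", "y", "z")]
      p2 <- fd[fd$tag == residue & fd$chain == pairs[[pn]][2L], c("x", "y", "z")]
      if (!nrow(p1) || !nrow(p2))
        stop("residue '", residue, "' absent on chain ",
             pairs[[pn]][which(c(nrow(p1), nrow(p2)) == 0L)[1L]],
             " in frame ", fd$frame[1L])
      d2 <- outer(seq_len(nrow(p1)), seq_len(nrow(p2)), function(i, j)
        (p1$x[i] - p2$x[j])^2 + (p1$y[i] - p2$y[j])^2 + (p1$z[i] - p2$z[j])^2)
      rows[[length(rows) + 1L]] <- data.frame(
        frame = fd$frame[1L], pair = pn, dist_A = 10 * sqrt(min(d2)))
    }
  }
  pf <- do.call(rbind, rows)
  lo <- floor(min(pf$dist_A) / bin) * bin
  breaks <- seq(lo, max(pf$dist_A) + bin, by = bin)
  hc <- graphics::hist(pf$dist_A, breaks = breaks, plot = FALSE)
  structure(list(per_frame = pf,
                 histogram = list(mids = hc$mids, counts = hc$counts),
                 mode_A = hc$mids[which.max(hc$counts)], bin = bin),
            class = "gate_distance")
}

#' Synthetic pore trajectory generator
#'
#' Random-walk ions and waters inside a reflective-walled cylinder with
#' optional axial drift, plus fixed marker particles for the analysis
#' groups: four M181 markers (chains A-D) at the pore midpoint, SF
#' backbone-oxygen markers (`T143O`, `Y146O`), an M308 G-loop marker, and
#' four atoms of a `residue` tag per chain for gate-distance analysis.
#' Everything is seeded and reproducible.
#'
#' @param n_frames Number of frames.
#' @param n_ions,n_waters Numbers of mobile K+ ions / water oxygens.
#' @param drift Per-frame mean z displacement of mobile particles, nm
#'   (positive = extracellular).
#' @param step_sd Per-frame random-walk step sd per axis, nm.
#' @param radius,height Cylinder radius and height, nm.
#' @param sf_z `c(zlo, zhi)` of the SF marker centres, nm (relative to the
#'   cylinder centre at z = 0).
#' @param m308_z z of the M308 marker, nm.
#' @param residue Residue tag for the per-chain gate atoms.
#' @param gate_radius Radial distance of the gate atoms from the axis, nm.
#' @param frame_interval_ps Frame spacing, ps.
#' @param seed RNG seed.
#' @return A `"trajectory_frames"` object.
#' @export
synth_trajectory <- function(n_frames = 100L, n_ions = 10L, n_waters = 0L,
                             drift = 0, step_sd = 0.15, radius = 1.2,
                             height = 8, sf_z = c(1.5, 2.0), m308_z = -2.5,
                             residue = "I177", gate_radius = 0.41,
                             frame_interval_ps = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_mobile <- n_ions + n_waters
  # markers: 4 x M181 (mid-pore), SF bounds, M308, 4 x gate residue atoms
  ang <- seq(0, 3) * pi / 2
  mk <- rbind(
    data.frame(tag = "M181", chain = c("A", "B", "C", "D"),
               x = 0.9 * radius * cos(ang), y = 0.9 * radius * sin(ang), z = 0),
    data.frame(tag = "T143O", chain = "", x = 0, y = 0, z = sf_z[1L]),
    data.frame(tag = "Y146O", chain = "", x = 0, y = 0, z = sf_z[2L]),
    data.frame(tag = "M308", chain = "", x = 0, y = 0, z = m308_z),
    data.frame(tag = residue, chain = c("A", "B", "C", "D"),
               x = gate_radius * cos(ang), y = gate_radius * sin(ang),
               z = -1.5))
  n_mark <- nrow(mk)
  pos <- matrix(0, n_mobile, 3L)
  if (n_mobile) {
    rr <- radius * sqrt(stats::runif(n_mobile))
    th <- stats::runif(n_mobile, 0, 2 * pi)
    pos[, 1L] <- rr * cos(th); pos[, 2L] <- rr * sin(th)
    pos[, 3L] <- stats::runif(n_mobile, -height / 2, height / 2)
  }
  out <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    if (f > 1L && n_mobile) {
      pos <- pos + matrix(stats::rnorm(n_mobile * 3L, 0, step_sd), n_mobile)
      pos[, 3L] <- pos[, 3L] + drift
      # reflective walls
      pos[, 3L] <- reflect(pos[, 3L], -height / 2, height / 2)
      r <- sqrt(pos[, 1L]^2 + pos[, 2L]^2)
      over <- r > radius
      if (any(over)) {
        scale <- (2 * radius - r[over]) / r[over]
        pos[over, 1L] <- pos[over, 1L] * scale
        pos[over, 2L] <- pos[over, 2L] * scale
      }
    }
    tags <- c(rep("K", n_ions), rep("W", n_waters))
    out[[f]] <- data.frame(
      frame = f - 1L,
      id = c(seq_len(n_mobile), n_mobile + seq_len(n_mark)),
      tag = c(tags, mk$tag),
      chain = c(rep("", n_mobile), mk$chain),
      x = c(pos[, 1L], mk$x), y = c(pos[, 2L], mk$y), z = c(pos[, 3L], mk$z))
  }
  trajectory_frames(do.call(rbind, out),
                    frame_interval_ps = frame_interval_ps,
                    box = c(2.5 * radius, 2.5 * radius, height + 2),
                    label = "synthetic")
}

reflect <- function(z, lo, hi) {
  span <- hi - lo
  zz <- (z - lo) %% (2 * span)
  lo + ifelse(zz > span, 2 * span - zz, zz)
}
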