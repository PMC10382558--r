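test_that("trajectory tables validate and round-trip", {
  tj <- synth_trajectory(n_frames = 3, n_ions = 2, seed = 1)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_frames(tj, f)
  tj2 <- read_frames(f)
  expect_equal(as.data.frame(tj2), as.data.frame(tj), tolerance = 1e-12)
  expect_equal(attr(tj2, "frame_interval_ps"), attr(tj, "frame_interval_ps"))
  # missing column
  bad <- as.data.frame(tj)[, -5]
  fb <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(bad, fb, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_frames(fb), "missing column")
  # frame gap
  gap <- as.data.frame(tj)
  gap$frame[gap$frame == 1] <- 5L
  expect_error(trajectory_frames(gap), "contiguous")
  # varying id set
  drop1 <- as.data.frame(tj)[-1, ]
  expect_error(trajectory_frames(drop1), "id set varies")
  expect_error(read_frames(withr::local_tempfile(fileext = ".x")), "no such file")
})

test_that("geometric centres follow their definition", {
  fd <- data.frame(frame = 0, id = 1:6,
                   tag = c("A", "B", "B", "Q", "Q", "Q"),
                   chain = "",
                   x = c(1, -2, 2, 1, -1, 0), y = c(2, 0, 0, 1, -1, 0),
                   z = c(3, 5, -5, 0, 0, 6))
  expect_equal(unname(com(fd, "A")), c(1, 2, 3))
  expect_equal(unname(com(fd, "B")), c(0, 0, 0))
  expect_equal(unname(com(fd, "Q")), c(0, 0, 2))
  expect_error(com(fd, "missing"), "empty")
})

test_that("cylinder membership uses closed boundaries", {
  ctr <- c(0, 0, 0)
  expect_true(in_cylinder(0, 0, 0, ctr, radius = 1, height = 2))
  expect_false(in_cylinder(1 + 1e-9, 0, 0, ctr, radius = 1, height = 2))
  expect_true(in_cylinder(1, 0, 0, ctr, radius = 1, height = 2))   # boundary
  expect_true(in_cylinder(0, 0, 1, ctr, radius = 1, height = 2))
  expect_false(in_cylinder(0, 0, 1.01, ctr, radius = 1, height = 2))
  expect_true(in_cylinder(0.5, 0, 3, ctr, radius = 1, z_range = c(2, 4)))
})

test_that("pore traces match a brute-force membership scan", {
  for (seed in c(71, 72, 73)) {
    tj <- synth_trajectory(n_frames = 25, n_ions = 8, n_waters = 6,
                           radius = 2.8, height = 12, step_sd = 0.5,
                           seed = seed)
    got_k <- pore_trace(tj, "K")
    ora_k <- brute_force_pore_trace(tj, "K", 2.5, 11)
    expect_equal(got_k[order(got_k$frame, got_k$id), ],
                 ora_k[order(ora_k$frame, ora_k$id), ],
                 ignore_attr = TRUE)
    got_w <- pore_trace(tj, "W")
    ora_w <- brute_force_pore_trace(tj, "W", 1.0, 11)
    expect_identical(nrow(got_w), nrow(ora_w))
  }
  # everything inside a narrow pore is reported every frame
  tj2 <- synth_trajectory(n_frames = 10, n_ions = 5, radius = 0.5, height = 6,
                          seed = 74)
  expect_identical(nrow(pore_trace(tj2, "K")), 50L)
})

test_that("scripted ion paths produce the defined permeation events", {
  # one ion passing below -> SF -> above: exactly one event
  mk <- synth_trajectory(n_frames = 5, n_ions = 0, seed = 1)
  markers <- as.data.frame(mk)[mk$frame == 0, -1]
  script_traj <- function(zs) {
    rows <- do.call(rbind, lapply(seq_along(zs) - 1L, function(f) {
      ion <- data.frame(id = 999L, tag = "K", chain = "",
                        x = 0, y = 0, z = zs[f + 1L])
      cbind(frame = f, rbind(ion, markers))
    }))
    trajectory_frames(rows)
  }
  # SF sits at z in [1.5, 2.0] on the axis
  up <- script_traj(c(0, 1.0, 1.7, 2.5, 3.0))
  expect_identical(count_permeations(up)$total, 1L)
  # oscillating below the SF never fires
  low <- script_traj(c(0, 1.0, 0.2, 1.2, 0.1))
  expect_identical(count_permeations(low)$total, 0L)
  # re-entry from above then exit above again: occupancy resets each time
  wig <- script_traj(c(0, 1.7, 3, 1.8, 3))
  expect_identical(count_permeations(wig)$total, 2L)
})

test_that("permeation counts equal the brute-force oracle on random walks", {
  for (seed in 81:100) {
    tj <- synth_trajectory(n_frames = 60, n_ions = 50, drift = 0.15,
                           step_sd = 0.25, radius = 0.2, seed = seed)
    expect_identical(count_permeations(tj)$total, brute_force_permeations(tj))
  }
})

test_that("plane crossings balance net displacement", {
  tj <- synth_trajectory(n_frames = 400, n_ions = 40, drift = 0,
                         step_sd = 0.3, radius = 0.5, seed = 101)
  zb <- 2.0  # upper SF bound in the synthetic geometry
  kk <- as.data.frame(tj)[tj$tag == "K", ]
  ups <- downs <- 0L
  for (ion in unique(kk$id)) {
    z <- kk$z[kk$id == ion][order(kk$frame[kk$id == ion])]
    above <- z > zb
    ups <- ups + sum(!above[-length(z)] & above[-1])
    downs <- downs + sum(above[-length(z)] & !above[-1])
    net <- (above[length(z)] - above[1])
    expect_identical(sum(!above[-length(z)] & above[-1]) -
                       sum(above[-length(z)] & !above[-1]), as.integer(net))
  }
  # a driftless walk crosses both ways about equally
  expect_lt(abs(ups - downs), 3 * sqrt(ups + downs))
})

test_that("occupancy histogram counts in-pore ions", {
  # single static ion between M308 and the SF: mean count exactly 1
  mk <- synth_trajectory(n_frames = 4, n_ions = 0, seed = 1)
  markers <- as.data.frame(mk)[mk$frame == 0, -1]
  rows <- do.call(rbind, lapply(0:3, function(f) {
    ion <- data.frame(id = 999L, tag = "K", chain = "", x = 0.1, y = 0,
                      z = -1)
    cbind(frame = f, rbind(ion, markers))
  }))
  oh <- occupancy_histogram(trajectory_frames(rows))
  expect_equal(oh$mean_count, 1)
  expect_identical(sum(oh$counts), 4L)   # one in-pore record per frame
  # histogram mass equals total in-pore records
  tj <- synth_trajectory(n_frames = 30, n_ions = 12, seed = 102)
  oh2 <- occupancy_histogram(tj)
  expect_identical(sum(oh2$counts), nrow(pore_trace(tj, "K")))
})

test_that("uniform ion clouds give density * volume ions in the region", {
  # ions uniform in a cylinder radius 1.2, height 8 centred at z = 0;
  # region spans M308 (z = -2.5) to SF lower bound (z = 1.5), radius 2.5
  # encloses the whole walk radially, so expected count = n * 4/8
  tj <- synth_trajectory(n_frames = 200, n_ions = 24, drift = 0,
                         step_sd = 0.6, radius = 1.2, height = 8, seed = 103)
  oh <- occupancy_histogram(tj)
  expect_lt(abs(oh$mean_count - 12), 3 * sqrt(12) / sqrt(200 / 10))
})

test_that("cross-subunit minimum distances match the pairwise oracle", {
  # two single atoms 0.82 nm apart read 8.2 Angstrom
  base <- synth_trajectory(n_frames = 1, n_ions = 0, gate_radius = 0.41,
                           seed = 1)
  gd <- min_cross_subunit_distance(base, "I177")
  expect_equal(gd$per_frame$dist_A, c(8.2, 8.2), tolerance = 1e-9)
  expect_equal(gd$mode_A, 8.2, tolerance = 0.06)
  # random multi-atom residues: equals O(n^2) scan; min unchanged by a far atom
  set.seed(104)
  fd <- data.frame(frame = 0, id = 1:8, tag = "M181",
                   chain = rep(c("A", "C"), each = 4),
                   x = stats::rnorm(8), y = stats::rnorm(8), z = stats::rnorm(8))
  tj <- trajectory_frames(rbind(fd,
                                data.frame(frame = 0, id = 9:16, tag = "M181",
                                           chain = rep(c("B", "D"), each = 4),
                                           x = stats::rnorm(8) + 3,
                                           y = stats::rnorm(8),
                                           z = stats::rnorm(8))))
  gd2 <- min_cross_subunit_distance(tj, "M181")
  expect_equal(gd2$per_frame$dist_A[gd2$per_frame$pair == "AC"],
               brute_force_min_dist(as.data.frame(tj), "M181", c("A", "C")),
               tolerance = 1e-9)
  far <- rbind(as.data.frame(tj),
               data.frame(frame = 0, id = 17, tag = "M181", chain = "A",
                          x = 50, y = 50, z = 50))
  gd3 <- min_cross_subunit_distance(trajectory_frames(far), "M181")
  expect_equal(gd3$per_frame$dist_A, gd2$per_frame$dist_A)
  expect_error(min_cross_subunit_distance(base, "M302"), "absent on")
})

test_that("metrics are equivariant under translation and scaling", {
  tj <- synth_trajectory(n_frames = 20, n_ions = 10, radius = 0.3,
                         drift = 0.2, seed = 105)
  shifted <- as.data.frame(tj)
  shifted$x <- shifted$x + 4.2
  shifted$y <- shifted$y - 1.7
  tj_s <- trajectory_frames(shifted,
                            frame_interval_ps = attr(tj, "frame_interval_ps"))
  expect_identical(count_permeations(tj_s)$total, count_permeations(tj)$total)
  expect_equal(occupancy_histogram(tj_s)$mean_count,
               occupancy_histogram(tj)$mean_count)
  gd <- min_cross_subunit_distance(tj, "I177")
  gd_s <- min_cross_subunit_distance(tj_s, "I177")
  expect_equal(gd_s$per_frame$dist_A, gd$per_frame$dist_A)
  # scaling all coordinates scales distances, counts unchanged
  scaled <- as.data.frame(tj)
  scaled[c("x", "y", "z")] <- scaled[c("x", "y", "z")] * 2
  tj_2 <- trajectory_frames(scaled)
  gd_2 <- min_cross_subunit_distance(tj_2, "I177")
  expect_equal(gd_2$per_frame$dist_A, 2 * gd$per_frame$dist_A)
})

test_that("synthetic trajectories are seed-deterministic", {
  a <- synth_trajectory(n_frames = 15, n_ions = 7, n_waters = 3, seed = 9)
  b <- synth_trajectory(n_frames = 15, n_ions = 7, n_waters = 3, seed = 9)
  expect_identical(as.data.frame(a), as.data.frame(b))
  # strong upward drift conducts
  up <- synth_trajectory(n_frames = 150, n_ions = 30, drift = 0.3,
                         step_sd = 0.1, radius = 0.15, seed = 10)
  expect_gt(count_permeations(up)$total, 0L)
})
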