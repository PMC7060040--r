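test_that("segment collapse: two-point mean, boundary sharing, single run", {
  # one trajectory, 4 positions, per-step states F,F,N
  ts <- make_ts(data.frame(traj_id = 1L, frame = 1:4,
                           x = c(0, 0.1, 0.2, 0.2), y = c(0, 0, 0, 0.1)))
  asg <- make_assignment(ts, c(1L, 1L, 2L))
  segs <- collapse_state_segments(ts, asg)
  expect_equal(nrow(segs), 2L)
  fseg <- segs[segs$state == 1L]
  nseg <- segs[segs$state == 2L]
  # F-run: positions 1-3; N-run: positions 3-4 sharing the boundary point
  expect_equal(fseg$n_points, 3L)
  expect_equal(nseg$n_points, 2L)
  expect_equal(fseg$x, mean(c(0, 0.1, 0.2)))
  expect_equal(nseg$x, 0.2)
  expect_equal(nseg$y, 0.05)
  expect_equal(fseg$max_span, 0.2)
  expect_equal(nseg$max_span, 0.1)

  # a one-step run of endpoints (0,0), (0.1,0)
  ts1 <- make_ts(data.frame(traj_id = 1L, frame = 1:2, x = c(0, 0.1), y = 0))
  seg1 <- collapse_state_segments(ts1, make_assignment(ts1, 1L))
  expect_equal(seg1$x, 0.05)
  expect_equal(seg1$max_span, 0.1)

  # all-one-state trajectory collapses to exactly one segment
  ts2 <- make_ts(data.frame(traj_id = 1L, frame = 1:5,
                            x = cumsum(rep(0.1, 5)), y = 0))
  seg2 <- collapse_state_segments(ts2, make_assignment(ts2, rep(1L, 4)))
  expect_equal(nrow(seg2), 1L)
  expect_equal(seg2$n_points, 5L)

  # misaligned assignment is rejected
  expect_error(collapse_state_segments(ts2, make_assignment(ts1, 1L)),
               "aligned")

  # minimum-run-length filter drops short runs
  segs_f <- collapse_state_segments(ts, asg, min_run_len = 2L)
  expect_equal(segs_f$state, 1L)
})

test_that("max_span equals the exhaustive pairwise maximum and is rigid-motion invariant", {
  xy <- data.frame(x = c(0, 0.05, 0.05), y = c(0, 0, 0.03))
  ts <- make_ts(cbind(traj_id = 1L, frame = 1:3, xy))
  segs <- collapse_state_segments(ts, make_assignment(ts, c(1L, 1L)))
  brute <- max(dist(xy))
  expect_equal(segs$max_span, brute)
  expect_equal(round(segs$max_span, 4), 0.0583)
  # translation + rotation leave the span unchanged
  th <- 0.7
  rot <- cbind(x = cos(th) * xy$x - sin(th) * xy$y + 3,
               y = sin(th) * xy$x + cos(th) * xy$y - 1)
  ts_r <- make_ts(cbind(traj_id = 1L, frame = 1:3, as.data.frame(rot)))
  segs_r <- collapse_state_segments(ts_r, make_assignment(ts_r, c(1L, 1L)))
  expect_equal(segs_r$max_span, segs$max_span, tolerance = 1e-12)
  # larger random segment against the dist() oracle
  set.seed(41)
  xy2 <- data.frame(x = runif(12), y = runif(12))
  ts2 <- make_ts(cbind(traj_id = 1L, frame = 1:12, xy2))
  segs2 <- collapse_state_segments(ts2, make_assignment(ts2, rep(1L, 11)))
  expect_equal(segs2$max_span, max(dist(xy2)))
})

test_that("g(r) is 1 for complete spatial randomness", {
  set.seed(42)
  pts <- data.frame(x = runif(10000, 0, 10), y = runif(10000, 0, 10))
  gr <- pair_correlation(pts, field_size = 10, boundary = "periodic")
  expect_gt(mean(gr$g), 0.95)
  expect_lt(mean(gr$g), 1.05)
  # every well-populated bin within 3 standard errors of 1
  ok <- gr$expected >= 50
  se <- sqrt(2 / gr$expected[ok])
  expect_true(all(abs(gr$g[ok] - 1) < 3.5 * se))
  # rect edge correction gives the same flat answer
  gr_rect <- pair_correlation(pts, field_size = 10, boundary = "rect")
  expect_gt(mean(gr_rect$g), 0.95)
  expect_lt(mean(gr_rect$g), 1.05)
})

test_that("g(r) matches the brute-force all-pairs oracle on a square of points", {
  s <- 0.095
  pts <- data.frame(x = c(5, 5 + s, 5, 5 + s), y = c(5, 5, 5 + s, 5 + s))
  gr <- pair_correlation(pts, field_size = 10, dr = 0.01, r_max = 0.3,
                         boundary = "periodic")
  brute <- brute_pair_counts(pts, seq(0, 0.3, by = 0.01))
  expect_equal(gr$count, brute)
  # only the annuli containing s (4 side pairs) and s*sqrt(2) (2 diagonals)
  nz <- which(gr$count > 0)
  expect_equal(gr$r_lo[nz], c(0.09, 0.13))
  expect_equal(gr$count[nz], c(8, 4))
  expect_equal(gr$g[nz], brute[nz] / gr$expected[nz])
})

test_that("cross correlation is symmetric and auto excludes self-pairs", {
  set.seed(43)
  a <- data.frame(x = runif(300, 0, 5), y = runif(300, 0, 5))
  b <- data.frame(x = runif(200, 0, 5), y = runif(200, 0, 5))
  ab <- pair_correlation(a, b, field_size = 5, boundary = "periodic")
  ba <- pair_correlation(b, a, field_size = 5, boundary = "periodic")
  expect_equal(ab$g, ba$g, tolerance = 1e-12)
  # duplicated points: self-pairs excluded, coincident others kept
  dup <- data.frame(x = c(1, 1, 2), y = c(1, 1, 1))
  gr <- pair_correlation(dup, field_size = 5, dr = 0.01, r_max = 0.2)
  expect_equal(sum(gr$count), 2)   # only the coincident pair, both ways
  expect_error(pair_correlation(dup[1, ], field_size = 5), ">= 2")
})

test_that("deflection angles: reversal 0, straight 180, Brownian uniform", {
  ts_f <- make_ts(data.frame(traj_id = 1L, frame = 1:3,
                             x = c(0, 0.1, 0.2), y = 0))
  da_f <- deflection_angles(ts_f, make_assignment(ts_f, c(1L, 1L)))
  expect_equal(da_f[["1"]]$angles, 180)
  ts_r <- make_ts(data.frame(traj_id = 1L, frame = 1:3,
                             x = c(0, 0.1, 0), y = 0))
  da_r <- deflection_angles(ts_r, make_assignment(ts_r, c(1L, 1L)))
  expect_equal(da_r[["1"]]$angles, 0)

  m <- diffusion_model(1.0, frame_interval = 0.012)
  ts <- simulate_markov_trajectories(m, n_traj = 6000, seed = 44)
  da <- deflection_angles(ts, true_state_assignment(ts, n_states = 1))
  th <- da[["1"]]$angles
  expect_gt(length(th), 10000)
  expect_equal(da[["1"]]$acute_fraction, 0.5, tolerance = 0.03)
  gof <- chisq.test(table(cut(th, seq(0, 180, 10))))
  expect_gt(gof$p.value, 0.01)
  expect_equal(sum(da[["1"]]$histogram$density), 1)
})

test_that("span histogram reports the state summary and rejects empty states", {
  ts <- make_ts(data.frame(traj_id = 1L, frame = 1:4,
                           x = c(0, 0.05, 0.05, 0.3), y = 0))
  segs <- collapse_state_segments(ts, make_assignment(ts, c(2L, 2L, 1L)))
  sh <- domain_span_histogram(segs, state = 2)
  expect_equal(sh$mean_span, 0.05)
  expect_equal(sh$n_segments, 1L)
  expect_error(domain_span_histogram(segs, state = 3), "no qualifying")
})

test_that("immobile particles with no noise have zero span", {
  m <- diffusion_model(0, frame_interval = 0.012)
  ts <- simulate_markov_trajectories(m, n_traj = 30, seed = 45)
  segs <- collapse_state_segments(ts, true_state_assignment(ts, 1))
  expect_true(all(segs$max_span == 0))
})

test_that("time-course windows: static structure is flat over intervals", {
  # static clustered points: same 12 cluster centres revisited all movie
  set.seed(46)
  centres <- data.frame(x = runif(12, 1, 4), y = runif(12, 1, 4))
  n_tr <- 600
  idx <- sample(12, n_tr, replace = TRUE)
  tracks <- data.frame(
    traj_id = rep(seq_len(n_tr), each = 2),
    frame = as.vector(vapply(seq_len(n_tr), function(i)
      c(2 * i - 1, 2 * i), numeric(2))),
    x = rep(centres$x[idx], each = 2) + rnorm(2 * n_tr, sd = 0.01),
    y = rep(centres$y[idx], each = 2) + rnorm(2 * n_tr, sd = 0.01))
  ts <- trajectory_set(tracks, frame_interval = 0.05, field_size = 5)
  asg <- make_assignment(ts, rep(1L, n_tr))
  tc <- gr_time_course(ts, asg, intervals_min = c(0.25, 0.5), min_points = 10)
  expect_equal(unique(tc$state), 1)
  a1 <- tc$amplitude[tc$interval_min == 0.25]
  a2 <- tc$amplitude[tc$interval_min == 0.5]
  expect_gt(a1, 5)
  expect_equal(a2 / a1, 1, tolerance = 0.25)
  # an interval longer than the movie is skipped with a warning
  expect_warning(gr_time_course(ts, asg, intervals_min = c(0.25, 999)),
                 "skipped")
})
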