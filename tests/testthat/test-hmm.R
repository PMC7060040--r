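test_that("forward likelihood equals the exhaustive path sum on short chains", {
  m <- demo_two_state_model(diff_coeffs = c(1.0, 0.05),
                            frame_interval = 0.012, loc_sigma = 0.02)
  sim <- simulate_markov_trajectories(m, n_traj = 25, mean_track_len = 3,
                                      seed = 31)
  # keep only chains short enough to enumerate (<= 5 steps)
  tk <- sim$tracks[, if (.N <= 6L) .SD, by = traj_id]
  ts <- make_ts(tk)
  ll_forward <- hmm_loglik(ts, m)
  sp <- traj_steps(ts)
  ll_brute <- sum(vapply(split(sp$r2, sp$traj_id), brute_force_loglik,
                         numeric(1), model = m))
  expect_equal(ll_forward, ll_brute, tolerance = 1e-10)

  m3 <- demo_three_state_model(loc_sigma = 0)
  sim3 <- simulate_markov_trajectories(m3, n_traj = 15, mean_track_len = 3,
                                       seed = 32)
  tk3 <- sim3$tracks[, if (.N <= 5L) .SD, by = traj_id]
  ts3 <- make_ts(tk3)
  ll3 <- sum(vapply(split(traj_steps(ts3)$r2, traj_steps(ts3)$traj_id),
                    brute_force_loglik, numeric(1), model = m3))
  expect_equal(hmm_loglik(ts3, m3), ll3, tolerance = 1e-10)
})

test_that("single-state fit recovers D with a trivial transition matrix", {
  m <- diffusion_model(0.5, frame_interval = 0.012)
  ts <- simulate_markov_trajectories(m, n_traj = 3000, seed = 33)
  fit <- fit_hmm(ts, K = 1, loc_sigma = 0, seed = 1)
  expect_equal(fit$model$diff_coeffs, 0.5, tolerance = 0.05)
  expect_equal(fit$model$transition_matrix, matrix(1, 1, 1))
})

test_that("EM log-likelihood is non-decreasing across iterations", {
  fit <- recovery_fit()
  tr <- fit$convergence$trace
  expect_true(all(diff(tr) > -1e-8))
})

test_that("three-state recovery at the canonical parameters", {
  truth <- recovery_sim()$model
  fit <- recovery_fit()
  expect_lt(max(abs(fit$model$diff_coeffs / truth$diff_coeffs - 1)), 0.15)
  expect_lt(max(abs(fit$model$occupancies - truth$occupancies)), 0.05)
  expect_lt(max(abs(fit$model$transition_matrix -
                      truth$transition_matrix)), 0.02)
})

test_that("permuted restarts land on the same canonical model", {
  ts <- simulate_markov_trajectories(
    demo_two_state_model(diff_coeffs = c(1.0, 0.05), loc_sigma = 0),
    n_traj = 2500, seed = 34)
  f1 <- fit_hmm(ts, K = 2, loc_sigma = 0, seed = 5)
  f2 <- fit_hmm(ts, K = 2, loc_sigma = 0, seed = 99)
  expect_equal(f1$model$diff_coeffs, f2$model$diff_coeffs, tolerance = 1e-3)
  expect_equal(f1$model$occupancies, f2$model$occupancies, tolerance = 1e-3)
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-6)
})

test_that("decoding is accurate for well-separated states and trivial for K = 1", {
  m <- demo_two_state_model(diff_coeffs = c(1.0, 0.01),
                            occupancies = c(0.5, 0.5),
                            switch_prob = 0.05, loc_sigma = 0)
  ts <- simulate_markov_trajectories(m, n_traj = 3000, seed = 35)
  asg <- assign_states(ts, m)
  truth <- true_state_assignment(ts)
  expect_gte(mean(asg$state == truth$state), 0.95)

  m1 <- diffusion_model(1.0, frame_interval = 0.012)
  ts1 <- simulate_markov_trajectories(m1, n_traj = 50, seed = 36)
  asg1 <- assign_states(ts1, m1)
  expect_true(all(asg1$state == 1L))
  # one label per step: positions - 1 per trajectory
  expect_equal(nrow(asg1), nrow(ts1$tracks) - n_trajectories(ts1))
})

test_that("immobile-step, neighbour-step and other-step lengths separate", {
  ts <- recovery_sim()$trajs
  sp <- traj_steps(ts)
  sp[, state := true_state_assignment(ts, 3)$state]
  sp[, prev_imm := c(NA, state[-.N] == 3L), by = traj_id]
  sp[, next_imm := c(state[-1L] == 3L, NA), by = traj_id]
  imm <- sp[state == 3L, r]
  nb <- sp[state != 3L & (prev_imm %in% TRUE | next_imm %in% TRUE), r]
  other <- sp[state != 3L & !(prev_imm %in% TRUE) & !(next_imm %in% TRUE), r]
  expect_gt(length(imm), 500)
  expect_gt(length(nb), 300)
  # three distinct step-size populations, ordered immobile < neighbour < rest:
  # steps flanking an immobilization come from the intermediate state only
  expect_lt(median(imm), median(nb))
  expect_lt(median(nb), median(other))
  expect_lt(suppressWarnings(stats::ks.test(nb, other)$p.value), 1e-3)
  # the fitted model reproduces the immobile < neighbour ordering when the
  # states are decoded rather than known
  asg <- assign_states(ts, recovery_fit())
  spd <- traj_steps(ts)
  spd[, state := asg$state]
  spd[, nb_imm := {
    s <- state
    c(NA, s[-.N] == 3L) %in% TRUE | c(s[-1L] == 3L, NA) %in% TRUE
  }, by = traj_id]
  expect_lt(median(spd[state == 3L, r]),
            median(spd[state != 3L & nb_imm, r]))
})

test_that("model-size selection under noise and for small true K", {
  m1 <- diffusion_model(1.0, frame_interval = 0.012)
  ts1 <- simulate_markov_trajectories(m1, n_traj = 1500, seed = 37)
  sel1 <- suppressWarnings(select_hmm_K(ts1, K_max = 3, loc_sigma = 0,
                                        seed = 2))
  expect_equal(sel1$selected_K, 1L)
  expect_equal(min(sel1$candidates$score_rel), 0)
  ts2 <- simulate_markov_trajectories(
    demo_two_state_model(diff_coeffs = c(1.0, 0.05), loc_sigma = 0),
    n_traj = 2500, seed = 38)
  sel2 <- suppressWarnings(select_hmm_K(ts2, K_max = 3, loc_sigma = 0,
                                        seed = 2))
  expect_equal(sel2$selected_K, 2L)
})

test_that("apparent immobile D follows sigma^2 / dt", {
  expect_equal(apparent_immobile_D(0, 0.012), 0)
  expect_equal(apparent_immobile_D(0.04, 0.035), 0.04^2 / 0.035)
  expect_equal(round(apparent_immobile_D(0.04, 0.035), 4), 0.0457)
  expect_error(apparent_immobile_D(0.04, 0), "frame_interval")
  # simulated immobile molecules fitted while ignoring sigma
  m <- diffusion_model(0, frame_interval = 0.012)
  ts <- simulate_markov_trajectories(m, n_traj = 3000, seed = 39)
  ts <- add_localization_noise(ts, 0.04, seed = 40)
  fit <- fit_hmm(ts, K = 1, loc_sigma = 0, seed = 1)
  expect_equal(fit$model$diff_coeffs, apparent_immobile_D(0.04, 0.012),
               tolerance = 0.1)
})

test_that("CDF and HMM estimates agree on the same data", {
  ts <- recovery_sim()$trajs
  hmm <- recovery_fit()
  cdf <- fit_cdf_mixture(traj_steps(ts)$r2, K = 3, frame_interval = 0.012)
  expect_equal(cdf$diff_coeffs, hmm$model$diff_coeffs, tolerance = 0.35)
  expect_lt(max(abs(cdf$weights - hmm$model$occupancies)), 0.1)
})
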