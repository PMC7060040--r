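test_that("empirical occupancies and transitions from a hand-counted assignment", {
  ts <- make_ts(data.frame(traj_id = 1L, frame = 1:5,
                           x = c(0, 0.1, 0.2, 0.21, 0.22), y = 0))
  asg <- make_assignment(ts, c(1L, 1L, 2L, 2L))
  emp <- occupancies_and_transitions(asg)
  expect_equal(emp$occupancies, c(0.5, 0.5))
  expect_equal(emp$transition_matrix,
               rbind(c(0.5, 0.5), c(0, 1)))
  # all-one-state degenerate case
  asg1 <- make_assignment(ts, rep(1L, 4))
  emp1 <- occupancies_and_transitions(asg1)
  expect_equal(emp1$occupancies, 1)
  expect_equal(emp1$transition_matrix, matrix(1, 1, 1))
})

test_that("transition counts recover the generating matrix from ground truth", {
  m <- demo_three_state_model(loc_sigma = 0)
  ts <- simulate_markov_trajectories(m, n_traj = 30000, seed = 51)
  emp <- occupancies_and_transitions(true_state_assignment(ts, 3))
  expect_gt(sum(emp$transition_counts), 70000)
  expect_lt(max(abs(emp$transition_matrix - m$transition_matrix)), 0.02)
})

test_that("net flows, ratios and arm flows match hand arithmetic", {
  ex <- flux_example()
  fl <- net_flow_per_state(ex$p, ex$A)
  expect_equal(fl[3], 0.31 * 0.05 - 0.11 * 0.10)
  expect_equal(sum(fl), 0, tolerance = 1e-15)
  fr <- flux_ratio(ex$p, ex$A)
  expect_equal(fr[3], 0.0155 / 0.011)
  expect_equal(round(fr[3], 3), 1.409)
  arm <- net_flow_per_arm(ex$p, ex$A)
  expect_equal(unname(arm["N->I"]), 0.0045)
  expect_named(arm, c("F->N", "N->I", "I->F"))
  # per-state flow is the signed sum of its incident arm flows
  expect_equal(fl[1], unname(-arm["F->N"] + arm["I->F"]), tolerance = 1e-15)
  expect_equal(fl[3], unname(arm["N->I"] - arm["I->F"]), tolerance = 1e-15)
  expect_error(net_flow_per_state(c(0.5, 0.5), ex$A), "dimension")
})

test_that("stationarity zeroes flows; detailed balance at equilibrium of reversible A", {
  ex <- flux_example()
  pi_eq <- stationary_distribution(ex$A)
  expect_lt(max(abs(net_flow_per_state(pi_eq, ex$A))), 1e-12)
  m <- demo_three_state_model()
  db <- detailed_balance_residuals(m$occupancies, m$transition_matrix)
  expect_true(db$balanced)
  expect_true(all(abs(db$residuals + t(db$residuals)) < 1e-15))
  # any 2-state chain is reversible at its stationary point
  A2 <- rbind(c(0.7, 0.3), c(0.4, 0.6))
  db2 <- detailed_balance_residuals(stationary_distribution(A2), A2)
  expect_true(db2$balanced)
  # flux ratios are exactly 1 at detailed balance
  expect_equal(flux_ratio(m$occupancies, m$transition_matrix),
               rep(1, 3), tolerance = 1e-12)
})

test_that("a one-way cycle violates detailed balance at its own stationary point", {
  # Kolmogorov criterion broken: A12 A23 A31 != A13 A32 A21
  A <- rbind(c(0.7, 0.25, 0.05),
             c(0.05, 0.7, 0.25),
             c(0.25, 0.05, 0.7))
  pi_eq <- stationary_distribution(A)
  expect_lt(max(abs(as.numeric(pi_eq %*% A) - pi_eq)), 1e-12)
  db <- detailed_balance_residuals(pi_eq, A, tol = 1e-9)
  expect_false(db$balanced)
  expect_gt(db$max_abs_residual, 1e-3)
  # yet the net state flows vanish: steady but not reversible
  expect_lt(max(abs(net_flow_per_state(pi_eq, A))), 1e-12)
})

test_that("stationary distribution: hand-solved 2-state, doubly stochastic, reducible", {
  A <- rbind(c(0.9, 0.1), c(0.2, 0.8))
  expect_equal(stationary_distribution(A), c(2, 1) / 3, tolerance = 1e-12)
  Ad <- rbind(c(0.5, 0.3, 0.2), c(0.2, 0.5, 0.3), c(0.3, 0.2, 0.5))
  expect_equal(stationary_distribution(Ad), rep(1 / 3, 3), tolerance = 1e-12)
  Ar <- rbind(c(1, 0), c(0.5, 0.5))
  expect_error(stationary_distribution(Ar), "reducible")
  # agreement with the occupancy-evolution fixed point
  m <- demo_three_state_model()
  ev <- evolve_occupancies(m$transition_matrix, p0 = c(1, 0, 0),
                           n_steps = 5000)
  expect_lt(max(abs(ev[5001, ] - stationary_distribution(m$transition_matrix))),
            1e-9)
})

test_that("relaxation inverts occupancies for a chain with net fast-to-immobile drive", {
  # observed occupancies held away from the chain's stationary point by an
  # external source/sink: relaxing raises the immobile share, lowers fast
  p_obs <- c(0.58, 0.31, 0.11)
  A <- rbind(c(0.92, 0.08, 0.00),
             c(0.08, 0.84, 0.08),
             c(0.00, 0.02, 0.98))
  fl <- net_flow_per_state(p_obs, A)
  expect_gt(fl[3], 0)
  expect_lt(fl[1], 0)
  pi_eq <- stationary_distribution(A)
  expect_gt(pi_eq[3], p_obs[3])
  expect_lt(pi_eq[1], p_obs[1])
})

test_that("flux report assembles sources and bootstrap CIs cover the truth", {
  m <- demo_three_state_model(loc_sigma = 0)
  ts <- simulate_markov_trajectories(m, n_traj = 4000, seed = 52)
  asg <- true_state_assignment(ts, 3)
  rep_emp <- flux_report(assignment = asg, n_boot = 200,
                         frame_interval = 0.012, seed = 3)
  expect_equal(sum(rep_emp$net_flow_per_state), 0, tolerance = 1e-12)
  ci <- rep_emp$bootstrap_ci
  for (k in 1:3) {
    expect_lte(ci[paste0("occ_", c("F", "N", "I")[k]), 1], m$occupancies[k])
    expect_gte(ci[paste0("occ_", c("F", "N", "I")[k]), 2], m$occupancies[k])
  }
  # truth is at detailed balance: flow CIs straddle zero
  expect_lt(ci["flow_I", 1], 0)
  expect_gt(ci["flow_I", 2], 0)
  rep_mod <- flux_report(model = m)
  expect_equal(rep_mod$stationary_distribution, m$occupancies,
               tolerance = 1e-9)
  expect_error(flux_report(), "exactly one")
})

test_that("time-sliced fits are stable for a stationary dataset and flag a shift", {
  m <- demo_two_state_model(diff_coeffs = c(1.0, 0.05), loc_sigma = 0)
  ts <- simulate_markov_trajectories(m, n_traj = 8000, seed = 53)
  qs <- suppressWarnings(quarter_stability(ts, n_slices = 2, K = 2,
                                           loc_sigma = 0, seed = 1))
  expect_lt(max(qs$dispersion$occ_max_diff), 0.03)
  expect_lt(max(qs$dispersion$D_max_rel_diff), 0.1)
  # a mid-run occupancy shift shows up in the dispersion report
  m_shift <- demo_two_state_model(diff_coeffs = c(1.0, 0.05),
                                  occupancies = c(0.25, 0.75),
                                  loc_sigma = 0)
  ts2 <- simulate_markov_trajectories(m_shift, n_traj = 8000, seed = 54)
  tk2 <- data.table::copy(ts2$tracks)
  off <- max(ts$tracks$frame) + 1L
  tk2[, `:=`(frame = frame + off, traj_id = traj_id + max(ts$tracks$traj_id))]
  both <- trajectory_set(rbind(ts$tracks, tk2),
                         frame_interval = 0.012)
  qs2 <- suppressWarnings(quarter_stability(both, n_slices = 2, K = 2,
                                            loc_sigma = 0, seed = 1))
  expect_gt(max(qs2$dispersion$occ_max_diff), 0.2)
  expect_error(quarter_stability(ts, n_slices = 1e6, K = 2), "fewer")
})
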