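#' Empirical occupancies and transition matrix from decoded states
#'
#' The empirical counterpart of a fitted model: occupancies are state
#' frequencies over all steps; the transition matrix row-normalizes the
#' counts of within-trajectory consecutive step pairs. Raw counts are
#' returned for confidence-interval computation.
#'
#' @param assignment a `state_assignment` (per-step labels).
#' @param n_states number of states; defaults to the assignment attribute
#'   or the largest observed label.
#' @return list: `occupancies`, `transition_matrix`, `step_counts` (per
#'   state), `transition_counts` (K x K), `unvisited` (states with no
#'   visits; their transition rows are uniform and flagged).
#' @export
occupancies_and_transitions <- function(assignment, n_states = NULL) {
  if (nrow(assignment) == 0) stop_invariant("empty assignment")
  K <- n_states %||% attr(assignment, "n_states") %||% max(assignment$state)
  s <- assignment$state
  step_counts <- tabulate(s, nbins = K)
  pi_hat <- step_counts / sum(step_counts)
  n <- length(s)
  same <- assignment$traj_id[-1] == assignment$traj_id[-n]
  i <- which(same)
  counts <- matrix(0, K, K)
  if (length(i)) {
    tab <- table(factor(s[i], levels = seq_len(K)),
                 factor(s[i + 1L], levels = seq_len(K)))
    counts <- matrix(as.numeric(tab), K, K)
  }
  unvisited <- which(rowSums(counts) == 0)
  A <- row_normalize(counts)
  list(occupancies = pi_hat, transition_matrix = A,
       step_counts = step_counts, transition_counts = counts,
       unvisited = unvisited)
}

#' Net mass flow per state
#'
#' flow_i = sum_j!=i pi_j A_ji - pi_i sum_j!=i A_ij: the difference between
#' influx and outflux for each state, as a fraction of the total tracked
#' population per frame interval. Positive values mean the state is
#' accumulating mass. The flows sum to zero exactly (closed-system
#' bookkeeping); a nonzero flow pattern at observed steady-state occupancies
#' is the signature of exchange with an external reservoir.
#'
#' @param occupancies occupancy vector pi.
#' @param transition_matrix per-frame transition matrix A.
#' @return numeric K-vector, fraction of population per frame.
#' @export
net_flow_per_state <- function(occupancies, transition_matrix) {
  check_pi_A(occupancies, transition_matrix)
  influx <- influx_outflux(occupancies, transition_matrix)
  influx$influx - influx$outflux
}

#' Influx/outflux ratio per state
#'
#' ratio_i = influx_i / outflux_i; 1 means balanced, > 1 net accumulation.
#' A state with zero outflux gets an infinite ratio (flagged by `Inf`).
#'
#' @inheritParams net_flow_per_state
#' @return numeric K-vector.
#' @export
flux_ratio <- function(occupancies, transition_matrix) {
  check_pi_A(occupancies, transition_matrix)
  fl <- influx_outflux(occupancies, transition_matrix)
  ifelse(fl$outflux > 0, fl$influx / fl$outflux, Inf)
}

influx_outflux <- function(p, A) {
  K <- length(p)
  off <- A; diag(off) <- 0
  list(influx = as.numeric(p %*% off),        # sum_j pi_j A_ji
       outflux = p * rowSums(off))            # pi_i sum_j A_ij
}

#' Net mass flow per arm (ordered state pair)
#'
#' flow(i -> j) = pi_i A_ij - pi_j A_ji for each arm of the state cycle.
#' For a three-state model the arms are reported in the clockwise order
#' F -> N, N -> I, I -> F; positive values mean net flow in the indicated
#' direction. For other K all ordered pairs i < j are reported.
#'
#' @inheritParams net_flow_per_state
#' @return named numeric vector of signed arm flows (fraction of population
#'   per frame).
#' @export
net_flow_per_arm <- function(occupancies, transition_matrix) {
  check_pi_A(occupancies, transition_matrix)
  p <- occupancies; A <- transition_matrix
  K <- length(p)
  lab <- state_labels(K)
  arm <- function(i, j) p[i] * A[i, j] - p[j] * A[j, i]
  if (K == 3) {
    out <- c(arm(1, 2), arm(2, 3), arm(3, 1))
    names(out) <- c("F->N", "N->I", "I->F")
  } else {
    pairs <- which(upper.tri(A), arr.ind = TRUE)
    out <- mapply(arm, pairs[, 1], pairs[, 2])
    names(out) <- paste0(lab[pairs[, 1]], "->", lab[pairs[, 2]])
  }
  out
}

#' Stationary distribution of a transition matrix
#'
#' The unique probability vector with pi A = pi, computed by
#' eigen-decomposition of t(A) and cross-checked against the fixed point of
#' iterated occupancy evolution; the two must agree within 1e-9. Fails for
#' reducible chains, listing the closed communicating classes.
#'
#' @param transition_matrix row-stochastic K x K matrix (irreducible).
#' @return stationary probability vector.
#' @export
stationary_distribution <- function(transition_matrix) {
  A <- as.matrix(transition_matrix)
  K <- nrow(A)
  if (K == 1) return(1)
  reach <- (diag(K) + A) %*% (diag(K) + A)
  for (i in seq_len(ceiling(log2(K)) + 1)) reach <- reach %*% reach
  if (any(reach == 0)) {
    bad <- which(rowSums(reach == 0) > 0)
    stop_invariant("transition matrix is reducible; state(s) %s cannot reach every other state",
                   paste(bad, collapse = ", "))
  }
  e <- eigen(t(A))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  pi_eig <- v / sum(v)
  # cross-check: fixed point of deterministic evolution
  p <- rep(1 / K, K)
  for (t in seq_len(100000L)) {
    p_new <- as.numeric(p %*% A)
    if (max(abs(p_new - p)) < 1e-15) { p <- p_new; break }
    p <- p_new
  }
  if (max(abs(p - pi_eig)) > 1e-9)
    stop_invariant("eigen and iterative stationary distributions disagree (%.3g)",
                   max(abs(p - pi_eig)))
  pi_eig
}

#' Detailed-balance residuals
#'
#' residual_ij = pi_i A_ij - pi_j A_ji. At true equilibrium of a reversible
#' chain every residual is zero; persistent nonzero residuals at the
#' stationary distribution diagnose a non-equilibrium steady state (a
#' chain violating the Kolmogorov cycle criterion).
#'
#' @inheritParams net_flow_per_state
#' @param tol residual magnitude below which balance is accepted
#'   (default 1e-9, appropriate for an analytic stationary distribution;
#'   use a CI-based tolerance for empirical occupancies).
#' @return list: `residuals` (K x K antisymmetric matrix), `balanced`
#'   (verdict), `max_abs_residual`.
#' @export
detailed_balance_residuals <- function(occupancies, transition_matrix,
                                       tol = 1e-9) {
  check_pi_A(occupancies, transition_matrix)
  p <- occupancies; A <- transition_matrix
  R <- p * A - t(p * A)
  list(residuals = R, balanced = max(abs(R)) < tol,
       max_abs_residual = max(abs(R)))
}

check_pi_A <- function(p, A) {
  if (length(p) != nrow(A) || nrow(A) != ncol(A))
    stop_invariant("dimension mismatch between occupancies (%d) and transition matrix (%d x %d)",
                   length(p), nrow(A), ncol(A))
  invisible(TRUE)
}

#' Full flux report for a diffusion model or decoded states
#'
#' Assembles the non-equilibrium steady-state diagnostics: occupancies,
#' transition matrix, net flow per state, influx/outflux ratios, net flow
#' per arm, the stationary (relaxed) distribution of the transition matrix,
#' and detailed-balance residuals evaluated at the observed occupancies.
#' Per-second flows are the per-frame flows divided by the frame interval.
#' If a `state_assignment` is supplied, (pi, A) are the empirical estimates
#' and nonparametric bootstrap CIs (resampling trajectories with
#' replacement, percentile intervals) are attached; if a model is supplied,
#' its fitted (pi, A) are used.
#'
#' @param model a `diffusion_model` or `hmm_fit` (fitted source), or `NULL`.
#' @param assignment a `state_assignment` (empirical source), or `NULL`.
#'   Exactly one source must be given.
#' @param frame_interval frame interval, s (taken from the model if given).
#' @param n_boot bootstrap replicates for empirical CIs (default 1000;
#'   0 disables).
#' @param conf confidence level (default 0.95).
#' @param seed bootstrap seed.
#' @return list of class `flux_report`.
#' @export
flux_report <- function(model = NULL, assignment = NULL,
                        frame_interval = NULL, n_boot = 1000,
                        conf = 0.95, seed = 1) {
  if (is.null(model) == is.null(assignment))
    stop_invariant("supply exactly one of model or assignment")
  ci <- NULL
  if (!is.null(model)) {
    if (inherits(model, "hmm_fit")) model <- model$model
    validate_diffusion_model(model)
    p <- model$occupancies
    A <- model$transition_matrix
    frame_interval <- frame_interval %||% model$frame_interval
    source <- "fitted model"
  } else {
    emp <- occupancies_and_transitions(assignment)
    p <- emp$occupancies
    A <- emp$transition_matrix
    source <- "decoded states (empirical)"
    if (n_boot > 0) ci <- boot_flux_ci(assignment, n_boot, conf, seed)
  }
  flows <- net_flow_per_state(p, A)
  rep <- structure(list(
    occupancies = p, transition_matrix = A,
    net_flow_per_state = flows,
    net_flow_per_state_per_s = if (!is.null(frame_interval))
      flows / frame_interval else NULL,
    flux_ratio = flux_ratio(p, A),
    net_flow_per_arm = net_flow_per_arm(p, A),
    stationary_distribution = stationary_distribution(A),
    detailed_balance = detailed_balance_residuals(p, A),
    frame_interval = frame_interval, source = source,
    bootstrap_ci = ci), class = "flux_report")
  rep
}

boot_flux_ci <- function(assignment, n_boot, conf, seed) {
  ids <- unique(assignment$traj_id)
  K <- attr(assignment, "n_states") %||% max(assignment$state)
  idx <- split(seq_len(nrow(assignment)), assignment$traj_id)
  probs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  stats <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      take <- sample(length(idx), replace = TRUE)
      rows <- unlist(idx[take], use.names = FALSE)
      boot_a <- assignment[rows]
      # traj ids repeat across resamples; re-key so each draw is a chain
      boot_a[, traj_id := rep(seq_along(take),
                              lengths(idx)[take])]
      setattr(boot_a, "n_states", K)
      emp <- occupancies_and_transitions(boot_a, n_states = K)
      c(emp$occupancies,
        net_flow_per_state(emp$occupancies, emp$transition_matrix),
        net_flow_per_arm(emp$occupancies, emp$transition_matrix))
    }, numeric(2 * K + if (K == 3) 3 else K * (K - 1) / 2))
  })
  lab <- state_labels(K)
  rn <- c(paste0("occ_", lab), paste0("flow_", lab),
          names(net_flow_per_arm(rep(1 / K, K), diag(K))))
  t(apply(stats, 1, quantile, probs = probs)) |>
    (\(m) { rownames(m) <- rn; m })()
}

#' @export
print.flux_report <- function(x, ...) {
  K <- length(x$occupancies)
  lab <- state_labels(K)
  cat(sprintf("flux report (source: %s)\n", x$source))
  cat("  occupancies:", paste(sprintf("%s=%.3f", lab, x$occupancies),
                              collapse = ", "), "\n")
  cat("  net flow/frame:",
      paste(sprintf("%s=%+.3e", lab, x$net_flow_per_state),
            collapse = ", "), "\n")
  cat("  influx/outflux:",
      paste(sprintf("%s=%.3f", lab, x$flux_ratio), collapse = ", "), "\n")
  cat("  arm flows:",
      paste(sprintf("%s=%+.3e", names(x$net_flow_per_arm),
                    x$net_flow_per_arm), collapse = ", "), "\n")
  cat("  stationary (relaxed):",
      paste(sprintf("%s=%.3f", lab, x$stationary_distribution),
            collapse = ", "), "\n")
  cat(sprintf("  detailed balance: %s (max |residual| = %.3e)\n",
              if (x$detailed_balance$balanced) "holds" else "violated",
              x$detailed_balance$max_abs_residual))
  invisible(x)
}

#' Time-sliced model stability
#'
#' Splits a dataset into contiguous acquisition-time blocks with equal
#' trajectory counts (ordered by trajectory start frame), fits the HMM at
#' fixed K in every block and reports the across-slice dispersion of the
#' parameters. Stable parameters across slices indicate the system is in a
#' steady state over the acquisition.
#'
#' @param trajs a `trajectory_set`.
#' @param n_slices number of time blocks (default 4).
#' @param K model size for the per-slice fits.
#' @param loc_sigma localization error, um.
#' @param warn_below warn when a slice holds fewer trajectories than this
#'   (default 3000).
#' @param ... passed to [fit_hmm()].
#' @return list of class `quarter_stability`: `fits` (per slice),
#'   `diff_coeffs`, `occupancies` (slice x state matrices), `dispersion`
#'   (per-state CV of D and max pairwise occupancy difference).
#' @export
quarter_stability <- function(trajs, n_slices = 4, K, loc_sigma = 0,
                              warn_below = 3000, ...) {
  starts <- trajs$tracks[, .(start = min(frame)), by = traj_id]
  setorder(starts, start, traj_id)
  n <- nrow(starts)
  if (n < n_slices)
    stop_invariant("fewer trajectories (%d) than slices (%d)", n, n_slices)
  slice <- ceiling(seq_len(n) / (n / n_slices))
  slice <- pmin(slice, n_slices)
  if (n / n_slices < warn_below)
    warning(sprintf("only ~%d trajectories per slice; fits may be unstable",
                    floor(n / n_slices)))
  fits <- lapply(seq_len(n_slices), function(sl) {
    ids <- starts$traj_id[slice == sl]
    sub <- trajectory_set(trajs$tracks[traj_id %in% ids],
                          frame_interval = trajs$frame_interval,
                          field_size = trajs$field_size)
    fit_hmm(sub, K = K, loc_sigma = loc_sigma, ...)
  })
  Dm <- t(vapply(fits, function(f) f$model$diff_coeffs, numeric(K)))
  Pm <- t(vapply(fits, function(f) f$model$occupancies, numeric(K)))
  disp <- list(
    D_cv = apply(Dm, 2, function(z) sd(z) / mean(z)),
    D_max_rel_diff = apply(Dm, 2, function(z)
      (max(z) - min(z)) / mean(z)),
    occ_max_diff = apply(Pm, 2, function(z) max(z) - min(z)))
  structure(list(fits = fits, diff_coeffs = Dm, occupancies = Pm,
                 dispersion = disp, n_slices = n_slices),
            class = "quarter_stability")
}

#' @export
print.quarter_stability <- function(x, ...) {
  cat(sprintf("model stability over %d time slices\n", x$n_slices))
  cat("  D (um^2/s) per slice:\n"); print(round(x$diff_coeffs, 4))
  cat("  occupancies per slice:\n"); print(round(x$occupancies, 4))
  cat(sprintf("  max occupancy spread: %.3f; max relative D spread: %.3f\n",
              max(x$dispersion$occ_max_diff),
              max(x$dispersion$D_max_rel_diff)))
  invisible(x)
}
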