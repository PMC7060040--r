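# Hidden Markov model over per-step displacements.
#
# Each trajectory is an independent chain; the observation at step t is the
# displacement vector (dx, dy), modelled per state k as an isotropic 2D
# Gaussian with per-axis variance v_k = 2 (D_k dt + sigma^2) (equivalently a
# Rayleigh distribution on the step length). The squared step length r^2 is
# a sufficient statistic: f_k(r^2) = exp(-r^2 / (2 v_k)) / (2 pi v_k).
# Parameters are estimated by EM (Baum-Welch) jointly over all trajectories,
# vectorized across chains of equal length. Localization error sigma is a
# fixed, user-supplied input inflating the per-step variance; it is not
# estimated (identifiability with slow states is poor at these track
# lengths). The correlation between consecutive steps induced by the shared
# localization error of their common endpoint is ignored in the likelihood;
# this is a documented approximation.

V_MIN <- 1e-12

# group step records into per-length r2 matrices for vectorized recursions
prepare_chains <- function(trajs) {
  steps <- traj_steps(trajs)
  lens <- steps[, .(L = .N, frame0 = frame[1L]), by = traj_id]
  groups <- list()
  for (L in sort(unique(lens$L))) {
    ids <- lens$traj_id[lens$L == L]
    sub <- steps[traj_id %in% ids]
    setorder(sub, traj_id, frame)
    R2 <- matrix(sub$r2, nrow = length(ids), ncol = L, byrow = TRUE)
    groups[[length(groups) + 1L]] <-
      list(L = L, ids = ids, R2 = R2,
           frame0 = lens$frame0[match(ids, lens$traj_id)])
  }
  list(groups = groups, n_steps = nrow(steps),
       n_traj = nrow(lens), steps = steps)
}

dens_matrix <- function(r2, v) {
  # n x K emission densities
  exp(-outer(r2, 1 / (2 * v))) %*% diag(1 / (2 * pi * v), length(v))
}

# one EM run; returns parameters, log-likelihood trace and sufficient stats
hmm_em_run <- function(chains, K, dt, sigma, v0, A0, p0,
                       max_iter = 200, tol = 1e-7) {
  v <- pmax(v0, V_MIN)
  A <- A0
  p <- p0
  trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    ll <- 0
    Gsum <- numeric(K); Gr2 <- numeric(K); G1 <- numeric(K)
    Xi <- matrix(0, K, K)
    for (g in chains$groups) {
      R2 <- g$R2
      n <- nrow(R2); L <- ncol(R2)
      B <- lapply(seq_len(L), function(t) dens_matrix(R2[, t], v))
      alphas <- vector("list", L)
      cs <- matrix(0, n, L)
      a <- B[[1L]] * rep(p, each = n)
      cs[, 1L] <- rowSums(a)
      alphas[[1L]] <- a / cs[, 1L]
      if (L > 1) for (t in 2:L) {
        a <- (alphas[[t - 1L]] %*% A) * B[[t]]
        cs[, t] <- rowSums(a)
        alphas[[t]] <- a / cs[, t]
      }
      ll <- ll + sum(log(cs))
      beta <- matrix(1, n, K)
      gam <- alphas[[L]] * beta
      Gsum <- Gsum + colSums(gam)
      Gr2 <- Gr2 + colSums(gam * R2[, L])
      if (L > 1) for (t in (L - 1L):1L) {
        U <- (B[[t + 1L]] * beta) / cs[, t + 1L]
        Xi <- Xi + A * crossprod(alphas[[t]], U)
        beta <- U %*% t(A)
        gam <- alphas[[t]] * beta
        Gsum <- Gsum + colSums(gam)
        Gr2 <- Gr2 + colSums(gam * R2[, t])
        if (t == 1L) G1 <- G1 + colSums(gam)
      }
      if (L == 1L) G1 <- G1 + colSums(gam)
    }
    trace <- c(trace, ll)
    if (is.finite(ll_prev) &&
        abs(ll - ll_prev) < tol * (abs(ll_prev) + 1)) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
    # M-step
    p <- G1 / sum(G1)
    if (K > 1) A <- row_normalize(Xi)
    v_new <- ifelse(Gsum > 0, Gr2 / (2 * Gsum), v)
    D <- pmax(0, (v_new / 2 - sigma^2) / dt)
    v <- pmax(2 * (D * dt + sigma^2), V_MIN)
  }
  list(v = v, A = A, p = p, occ = Gsum / sum(Gsum), logLik = ll,
       trace = trace, converged = converged, iterations = length(trace))
}

#' Fit a diffusion HMM to trajectories
#'
#' Maximum-likelihood estimation of a K-state diffusion hidden Markov model
#' over per-step displacements (see the emission model above), via EM with
#' multiple deterministic restarts: every restart is run for a short burn-in
#' and the best is refined to convergence. The reported occupancies are the
#' expected fraction of steps in each state. The penalized score is
#' -2 logL + penalty * n_params * log(n_steps) (a Bayesian-type information
#' penalty with n_params = K^2 + K - 1); [select_hmm_K()] reports it
#' relative to the best candidate so the best model scores zero.
#'
#' @param trajs a `trajectory_set` (or the internal prepared-chain object).
#' @param K number of states (>= 1).
#' @param loc_sigma localization error, um (fixed, not estimated). Defaults
#'   used for membrane GTPase data: 0.04 um at 12 ms, 0.02 um at 35 ms.
#' @param frame_interval frame interval, s; taken from `trajs` if absent.
#' @param n_starts EM restarts (default 10).
#' @param max_iter maximum EM iterations for the refinement run.
#' @param tol relative log-likelihood convergence tolerance.
#' @param penalty multiplier on the information penalty (default 1).
#' @param seed deterministic seed for the restarts.
#' @return list of class `hmm_fit`: `model` (a [diffusion_model()] with
#'   descending-D state order), `initial` (initial-state distribution),
#'   `logLik`, `score`, `n_params`, `n_steps`, `n_traj`, `K` and
#'   `convergence` (iterations, converged flag, log-likelihood trace, which
#'   is non-decreasing across EM iterations).
#' @export
fit_hmm <- function(trajs, K, loc_sigma = NULL, frame_interval = NULL,
                    n_starts = 10, max_iter = 200, tol = 1e-7,
                    penalty = 1, seed = 1) {
  if (K < 1) stop_invariant("K must be >= 1")
  if (inherits(trajs, "trajectory_set")) {
    frame_interval <- frame_interval %||% trajs$frame_interval
    chains <- prepare_chains(trajs)
  } else {
    chains <- trajs
    if (is.null(frame_interval))
      stop_invariant("frame_interval required with prepared chains")
  }
  if (chains$n_steps == 0) stop_invariant("no steps to fit")
  sigma <- loc_sigma %||% 0
  dt <- frame_interval

  r2 <- chains$steps$r2
  probs <- seq(0, 1, length.out = K + 1)
  blocks <- cut(r2, breaks = unique(quantile(r2, probs)),
                include.lowest = TRUE)
  v_base <- pmax(tapply(r2, blocks, mean) / 2, V_MIN)
  v_base <- rep_len(as.numeric(v_base), K)
  v_base[!is.finite(v_base)] <- max(mean(r2) / 2, V_MIN)

  runs <- lapply(seq_len(n_starts), function(s) {
    ini <- with_seed(derive_seed(seed, s), {
      jit <- if (s == 1) rep(1, K) else exp(rnorm(K, sd = 0.6))
      v0 <- sort(v_base * jit, decreasing = TRUE)
      A0 <- row_normalize(diag(K) * 0.8 +
                            matrix(0.2 / K, K, K) +
                            if (s == 1) 0 else matrix(runif(K * K, 0, 0.1), K))
      list(v0 = v0, A0 = A0, p0 = rep(1 / K, K))
    })
    hmm_em_run(chains, K, dt, sigma, ini$v0, ini$A0, ini$p0,
               max_iter = 25, tol = tol)
  })
  best <- runs[[which.max(vapply(runs, `[[`, numeric(1), "logLik"))]]
  fit <- hmm_em_run(chains, K, dt, sigma, best$v, best$A, best$p,
                    max_iter = max_iter, tol = tol)
  if (!fit$converged)
    warning(sprintf("EM did not converge in %d iterations for K = %d; returning best-so-far",
                    max_iter, K))

  # canonical descending-D order
  D <- pmax(0, (fit$v / 2 - sigma^2) / dt)
  ord <- order(D, decreasing = TRUE)
  D <- D[ord]
  occ <- fit$occ[ord]
  A <- fit$A[ord, ord, drop = FALSE]
  p0 <- fit$p[ord]
  occ <- occ / sum(occ)
  A <- row_normalize(A)
  model <- diffusion_model(diff_coeffs = D, occupancies = occ,
                           transition_matrix = A, frame_interval = dt,
                           loc_sigma = sigma)
  n_params <- K^2 + K - 1
  structure(list(model = model, initial = p0 / sum(p0),
                 logLik = fit$logLik,
                 score = -2 * fit$logLik + penalty * n_params *
                   log(chains$n_steps),
                 n_params = n_params, n_steps = chains$n_steps,
                 n_traj = chains$n_traj, K = K,
                 convergence = list(iterations = fit$iterations,
                                    converged = fit$converged,
                                    trace = fit$trace)),
            class = "hmm_fit")
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat(sprintf("diffusion HMM fit: K = %d, logLik = %.2f, score = %.2f (%d steps, %d trajectories)\n",
              x$K, x$logLik, x$score, x$n_steps, x$n_traj))
  print(x$model)
  invisible(x)
}

#' Select the HMM model size
#'
#' Fits K = 1..K_max and selects the K minimizing the penalized score
#' (-2 logL + penalty * n_params * log(n_steps)); scores are reported
#' relative to the best so the selected model scores zero. Ties break toward
#' the smaller model.
#'
#' @inheritParams fit_hmm
#' @param K_max largest model size to try (default 5).
#' @return A `model_selection_report` with `method = "hmm"`.
#' @export
select_hmm_K <- function(trajs, K_max = 5, loc_sigma = NULL,
                         frame_interval = NULL, n_starts = 10,
                         max_iter = 200, tol = 1e-7, penalty = 1, seed = 1) {
  if (inherits(trajs, "trajectory_set")) {
    frame_interval <- frame_interval %||% trajs$frame_interval
    trajs <- prepare_chains(trajs)
  }
  fits <- lapply(seq_len(K_max), function(K)
    fit_hmm(trajs, K, loc_sigma = loc_sigma, frame_interval = frame_interval,
            n_starts = n_starts, max_iter = max_iter, tol = tol,
            penalty = penalty, seed = derive_seed(seed, 100 + K)))
  score <- vapply(fits, `[[`, numeric(1), "score")
  selected <- which.min(score)          # which.min breaks ties toward small K
  report <- data.table(K = seq_len(K_max), score = score,
                       score_rel = score - min(score))
  structure(list(method = "hmm", candidates = report,
                 selected_K = as.integer(selected), fits = fits),
            class = "model_selection_report")
}

#' Assign a diffusion state to every step
#'
#' Most-probable state path (Viterbi decoding) per trajectory under a fitted
#' model. One label per step: a trajectory with three coordinates gets two
#' labels. Labels follow the descending-D convention (1 = fastest).
#'
#' @param trajs a `trajectory_set`.
#' @param model a `diffusion_model` or an `hmm_fit`. The model must have
#'   been fitted with the same frame interval and localization error as the
#'   data.
#' @return A `state_assignment`: data.table with `traj_id`, `frame` (start
#'   frame of the step) and `state`, aligned with [traj_steps()].
#' @export
assign_states <- function(trajs, model) {
  initial <- NULL
  if (inherits(model, "hmm_fit")) {
    initial <- model$initial
    model <- model$model
  }
  validate_diffusion_model(model)
  K <- model$n_states
  initial <- initial %||% model$occupancies
  v <- pmax(2 * (model$diff_coeffs * model$frame_interval +
                   model$loc_sigma^2), V_MIN)
  logA <- log(pmax(model$transition_matrix, 1e-300))
  chains <- prepare_chains(trajs)

  out <- vector("list", length(chains$groups))
  for (gi in seq_along(chains$groups)) {
    g <- chains$groups[[gi]]
    R2 <- g$R2
    n <- nrow(R2); L <- ncol(R2)
    logB <- lapply(seq_len(L), function(t)
      -outer(R2[, t], 1 / (2 * v)) -
        rep(log(2 * pi * v), each = n))
    delta <- logB[[1L]] + rep(log(pmax(initial, 1e-300)), each = n)
    psi <- vector("list", L)
    if (L > 1) for (t in 2:L) {
      # cand[i, j, n]: delta[n, i] + logA[i, j]
      best <- matrix(-Inf, n, K)
      argb <- matrix(1L, n, K)
      for (i in seq_len(K)) {
        sc <- delta[, i] + rep(logA[i, ], each = n)
        upd <- sc > best
        best[upd] <- sc[upd]
        argb[upd] <- i
      }
      psi[[t]] <- argb
      delta <- best + logB[[t]]
    }
    lab <- matrix(NA_integer_, n, L)
    lab[, L] <- max.col(delta, ties.method = "first")
    if (L > 1) for (t in L:2) {
      lab[, t - 1L] <- psi[[t]][cbind(seq_len(n), lab[, t])]
    }
    out[[gi]] <- data.table(
      traj_id = rep(g$ids, times = L),
      frame = rep(g$frame0, times = L) + rep(seq_len(L) - 1L, each = n),
      state = as.integer(lab))
  }
  res <- rbindlist(out)
  setorder(res, traj_id, frame)
  setattr(res, "class", c("state_assignment", class(res)))
  setattr(res, "n_states", K)
  res[]
}

#' Forward log-likelihood of trajectories under a fixed model
#'
#' Exact forward-algorithm log-likelihood (no fitting). Exposed for oracle
#' checks against exhaustive path enumeration and for model comparison.
#'
#' @inheritParams assign_states
#' @return total log-likelihood over all trajectories.
#' @export
hmm_loglik <- function(trajs, model) {
  initial <- NULL
  if (inherits(model, "hmm_fit")) {
    initial <- model$initial
    model <- model$model
  }
  K <- model$n_states
  initial <- initial %||% model$occupancies
  v <- pmax(2 * (model$diff_coeffs * model$frame_interval +
                   model$loc_sigma^2), V_MIN)
  A <- model$transition_matrix
  chains <- prepare_chains(trajs)
  ll <- 0
  for (g in chains$groups) {
    R2 <- g$R2
    n <- nrow(R2); L <- ncol(R2)
    a <- dens_matrix(R2[, 1L], v) * rep(initial, each = n)
    c1 <- rowSums(a)
    ll <- ll + sum(log(c1))
    alpha <- a / c1
    if (L > 1) for (t in 2:L) {
      a <- (alpha %*% A) * dens_matrix(R2[, t], v)
      ct <- rowSums(a)
      ll <- ll + sum(log(ct))
      alpha <- a / ct
    }
  }
  ll
}

#' Apparent diffusion of an immobile particle from localization error
#'
#' A truly immobile particle still shows apparent motion because each
#' endpoint of a step carries independent localization error; under the
#' displacement emission model the apparent diffusion coefficient is
#' sigma^2 / dt.
#'
#' @param sigma localization error, um (>= 0).
#' @param frame_interval frame interval, s (> 0).
#' @return apparent diffusion coefficient, um^2/s.
#' @export
apparent_immobile_D <- function(sigma, frame_interval) {
  if (sigma < 0) stop_invariant("sigma must be >= 0")
  if (frame_interval <= 0) stop_invariant("frame_interval must be > 0")
  sigma^2 / frame_interval
}
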