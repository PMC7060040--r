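#' Fit a Brownian mixture to the squared-displacement CDF
#'
#' For K-state Brownian motion with localization error, the squared step
#' length r^2 is exponentially distributed within each state and the mixture
#' CDF is
#'   P(r^2 <= u) = 1 - sum_k alpha_k exp(-u / (4 (D_k dt + sigma^2))).
#' The fit minimizes the sum of squared residuals between this model and the
#' empirical CDF on a log-spaced grid of evaluation points between the 1st
#' and 99th percentile of r^2 (unweighted least squares), with multi-start
#' quasi-Newton optimization from perturbed quantile-based initializations
#' under deterministic seeding.
#'
#' @param steps a `trajectory_set`, a data.frame of step records with an
#'   `r2` column, or a numeric vector of squared displacements (um^2).
#' @param K number of diffusion states (>= 1).
#' @param frame_interval frame interval, s.
#' @param loc_sigma localization error, um (treated as known).
#' @param n_eval number of CDF evaluation points (default 200).
#' @param n_starts number of optimization restarts (default 10).
#' @param seed deterministic seed for the restarts (default 1).
#' @param init optional warm start: a list with `tau` and `weights` from a
#'   smaller fitted model; a split-component start is added to the restart
#'   pool (used by [select_cdf_K()] so the error is non-increasing in K).
#' @return list of class `cdf_fit`: `weights` (alpha, descending-D order),
#'   `diff_coeffs` (um^2/s), `rmse`, `K`, `degenerate` (TRUE if two fitted
#'   components are within 5% of each other, flagging an oversized model),
#'   `n_steps`, plus the evaluation grid and residuals.
#' @export
fit_cdf_mixture <- function(steps, K, frame_interval, loc_sigma = 0,
                            n_eval = 200, n_starts = 10, seed = 1,
                            init = NULL) {
  r2 <- extract_r2(steps)
  if (K < 1) stop_invariant("K must be >= 1")
  if (length(r2) < 10 * K)
    stop_invariant("too few steps (%d) to fit K = %d components",
                   length(r2), K)
  dt <- frame_interval
  qs <- quantile(r2[r2 > 0], c(0.01, 0.99), names = FALSE)
  u <- exp(seq(log(qs[1]), log(qs[2]), length.out = n_eval))
  Femp <- ecdf(r2)(u)

  # tau_k = 4 (D_k dt + sigma^2); parametrized as log(tau) + softmax weights
  obj <- function(theta) {
    tau <- exp(theta[seq_len(K)])
    a <- if (K > 1) softmax(c(theta[(K + 1):(2 * K - 1)], 0)) else 1
    Fmod <- 1 - colSums(a * exp(-outer(1 / tau, u)))
    sum((Fmod - Femp)^2)
  }

  # moment/quantile-based initialization: split r2 into K quantile blocks
  probs <- seq(0, 1, length.out = K + 1)
  blocks <- cut(r2, breaks = quantile(r2, probs), include.lowest = TRUE)
  tau0 <- pmax(tapply(r2, blocks, mean), 1e-6)
  best <- NULL
  if (!is.null(init) && length(init$tau) == K - 1L && K > 1) {
    # warm start from the smaller model: split its heaviest component
    h <- which.max(init$weights)
    tau_w <- c(init$tau, init$tau[h] * 2)
    w_w <- c(init$weights, 0.1)
    w_w <- pmax(w_w / sum(w_w), 1e-6)
    th_w <- c(log(tau_w), log(w_w[-K] / w_w[K]))
    fit_w <- tryCatch(
      optim(th_w, obj, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(fit_w)) best <- fit_w
  }
  for (s in seq_len(n_starts)) {
    th0 <- with_seed(derive_seed(seed, s), {
      jit <- if (s == 1) 0 else rnorm(K, sd = 0.5)
      c(log(tau0) + jit, if (K > 1) rnorm(K - 1, sd = 0.1) else NULL)
    })
    fit <- tryCatch(
      optim(th0, obj, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop_invariant("CDF fit failed for K = %d", K)

  tau <- exp(best$par[seq_len(K)])
  a <- if (K > 1) softmax(c(best$par[(K + 1):(2 * K - 1)], 0)) else 1
  D <- pmax(0, (tau / 4 - loc_sigma^2) / dt)
  ord <- order(D, decreasing = TRUE)
  D <- D[ord]; a <- as.numeric(a[ord]); tau <- tau[ord]
  degenerate <- K > 1 &&
    any(abs(diff(tau)) / pmax(tau[-K], 1e-12) < 0.05)
  Fmod <- 1 - colSums(a * exp(-outer(1 / tau, u)))
  structure(list(weights = a, diff_coeffs = D, tau = tau,
                 rmse = sqrt(mean((Fmod - Femp)^2)), K = K,
                 degenerate = degenerate, n_steps = length(r2),
                 frame_interval = dt, loc_sigma = loc_sigma,
                 u = u, residuals = Fmod - Femp),
            class = "cdf_fit")
}

#' @export
print.cdf_fit <- function(x, ...) {
  cat(sprintf("CDF mixture fit, K = %d (%d steps): rmse = %.3e%s\n", x$K,
              x$n_steps, x$rmse,
              if (x$degenerate) " [degenerate components]" else ""))
  for (k in seq_len(x$K))
    cat(sprintf("  D = %.4g um^2/s, weight = %.3f\n",
                x$diff_coeffs[k], x$weights[k]))
  invisible(x)
}

#' Select the CDF model size
#'
#' Fits mixtures with K = 1..K_max components and keeps the smallest model
#' beyond which adding a state no longer reduces the fit error appreciably:
#' the selected K is the largest one whose RMSE improvement over K - 1
#' exceeds `rel_tol` (relative), i.e. growth stops at the first K whose
#' improvement falls below the tolerance.
#'
#' @inheritParams fit_cdf_mixture
#' @param K_max largest model size to try (default 5).
#' @param rel_tol relative RMSE improvement below which an extra state is
#'   judged unsupported (default 0.1).
#' @return A `model_selection_report`: list with `method = "cdf"`,
#'   `candidates` (data.table of K, score = RMSE, and score relative to the
#'   best), `selected_K` and the per-K fits.
#' @export
select_cdf_K <- function(steps, K_max = 5, frame_interval, loc_sigma = 0,
                         rel_tol = 0.1, n_eval = 200, n_starts = 10,
                         seed = 1) {
  r2 <- extract_r2(steps)
  fits <- vector("list", K_max)
  for (K in seq_len(K_max)) {
    warm <- if (K > 1)
      list(tau = fits[[K - 1]]$tau, weights = fits[[K - 1]]$weights)
    fits[[K]] <- fit_cdf_mixture(r2, K, frame_interval = frame_interval,
                                 loc_sigma = loc_sigma, n_eval = n_eval,
                                 n_starts = n_starts,
                                 seed = derive_seed(seed, K), init = warm)
  }
  rmse <- vapply(fits, `[[`, numeric(1), "rmse")
  selected <- 1L
  for (K in seq_len(K_max)[-1]) {
    improvement <- (rmse[K - 1] - rmse[K]) / rmse[K - 1]
    if (!is.finite(improvement) || improvement < rel_tol) break
    selected <- K
  }
  report <- data.table(K = seq_len(K_max), score = rmse,
                       score_rel = rmse - min(rmse))
  structure(list(method = "cdf", candidates = report,
                 selected_K = selected, fits = fits),
            class = "model_selection_report")
}

#' @export
print.model_selection_report <- function(x, ...) {
  cat(sprintf("model-size selection (%s): selected K = %d\n",
              x$method, x$selected_K))
  print(x$candidates)
  invisible(x)
}

extract_r2 <- function(steps) {
  if (inherits(steps, "trajectory_set")) return(traj_steps(steps)$r2)
  if (is.data.frame(steps)) {
    if (!"r2" %in% names(steps))
      stop_invariant("step table must contain an r2 column")
    return(steps$r2)
  }
  as.numeric(steps)
}
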