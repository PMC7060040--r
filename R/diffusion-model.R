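#' Multi-state Brownian diffusion model
#'
#' Container for a K-state diffusion model of a membrane protein: one
#' diffusion coefficient per state, the state occupancies, the per-frame
#' transition matrix, the frame interval and the single-molecule
#' localization error. States are always stored in descending order of
#' diffusion coefficient, so for the canonical three-state membrane model
#' state 1 is the fast (F) state, state 2 the intermediate (N) state and
#' state 3 the immobile (I) state.
#'
#' @param diff_coeffs numeric vector of diffusion coefficients, um^2/s.
#' @param occupancies state occupancies (fractions of steps), summing to 1.
#'   Defaults to uniform.
#' @param transition_matrix K x K per-frame transition probability matrix
#'   (rows = from-state, rows sum to 1). Defaults to the identity.
#' @param frame_interval frame interval in seconds.
#' @param loc_sigma localization error (standard deviation per coordinate),
#'   um. Default 0.
#' @return An object of class `diffusion_model`.
#' @export
diffusion_model <- function(diff_coeffs, occupancies = NULL,
                            transition_matrix = NULL, frame_interval,
                            loc_sigma = 0) {
  K <- length(diff_coeffs)
  if (is.null(occupancies)) occupancies <- rep(1 / K, K)
  if (is.null(transition_matrix)) transition_matrix <- diag(K)
  transition_matrix <- as.matrix(transition_matrix)

  # canonical state order: descending diffusion coefficient
  ord <- order(diff_coeffs, decreasing = TRUE)
  diff_coeffs <- diff_coeffs[ord]
  occupancies <- occupancies[ord]
  transition_matrix <- transition_matrix[ord, ord, drop = FALSE]

  m <- structure(
    list(n_states = K,
         diff_coeffs = as.numeric(diff_coeffs),
         occupancies = as.numeric(occupancies),
         transition_matrix = unname(transition_matrix),
         frame_interval = frame_interval,
         loc_sigma = loc_sigma),
    class = "diffusion_model")
  validate_diffusion_model(m)
  m
}

#' Validate a diffusion model
#'
#' Checks every structural invariant of a [diffusion_model()] and fails with
#' a message naming the violated invariant.
#'
#' @param model a `diffusion_model`.
#' @return The model, invisibly, if valid.
#' @export
validate_diffusion_model <- function(model) {
  if (!inherits(model, "diffusion_model"))
    stop_invariant("not a diffusion_model object")
  K <- model$n_states
  D <- model$diff_coeffs
  p <- model$occupancies
  A <- model$transition_matrix
  if (K < 1) stop_invariant("n_states must be >= 1")
  if (length(D) != K || any(!is.finite(D)) || any(D < 0))
    stop_invariant("diff_coeffs must be %d finite values >= 0", K)
  if (is.unsorted(rev(D)))
    stop_invariant("diff_coeffs must be ordered descending")
  if (length(p) != K || any(p < 0) || any(p > 1))
    stop_invariant("occupancies must be %d fractions in [0, 1]", K)
  if (abs(sum(p) - 1) > 1e-9)
    stop_invariant("occupancies must sum to 1 (got %.12g)", sum(p))
  if (!is.matrix(A) || nrow(A) != K || ncol(A) != K)
    stop_invariant("transition_matrix must be %d x %d", K, K)
  if (any(A < 0) || any(A > 1))
    stop_invariant("transition_matrix entries must lie in [0, 1]")
  rs <- rowSums(A)
  if (any(abs(rs - 1) > 1e-9))
    stop_invariant("transition_matrix rows must sum to 1 (row %d sums to %.12g)",
                   which.max(abs(rs - 1)), rs[which.max(abs(rs - 1))])
  if (!is.numeric(model$frame_interval) || model$frame_interval <= 0)
    stop_invariant("frame_interval must be > 0")
  if (!is.numeric(model$loc_sigma) || model$loc_sigma < 0)
    stop_invariant("loc_sigma must be >= 0")
  invisible(model)
}

#' @export
print.diffusion_model <- function(x, ...) {
  cat(sprintf("%d-state diffusion model (dt = %g s, sigma = %g um)\n",
              x$n_states, x$frame_interval, x$loc_sigma))
  lab <- state_labels(x$n_states)
  for (k in seq_len(x$n_states))
    cat(sprintf("  state %d (%s): D = %.4g um^2/s, occupancy = %.3f\n",
                k, lab[k], x$diff_coeffs[k], x$occupancies[k]))
  cat("  per-frame transition matrix:\n")
  A <- round(x$transition_matrix, 4)
  dimnames(A) <- list(from = lab, to = lab)
  print(A)
  invisible(x)
}

state_labels <- function(K) {
  if (K == 3) c("F", "N", "I") else paste0("S", seq_len(K))
}

#' Canonical three-state membrane diffusion model
#'
#' A representative three-state model for an active Ras-family GTPase on the
#' plasma membrane: a fast state (~1 um^2/s), an intermediate state
#' (~0.3 um^2/s) and an immobile state (~0.08 um^2/s apparent at a 12 ms
#' frame interval), with occupancies 58/31/11%. The transition matrix is the
#' package's design point: a reversible chain whose stationary distribution
#' is exactly the stated occupancies, with all fast-immobile exchange routed
#' through the intermediate state (no direct F-I transitions).
#'
#' @param frame_interval frame interval in seconds (default 0.012).
#' @param loc_sigma localization error in um (default 0.04).
#' @return A `diffusion_model` with K = 3.
#' @export
demo_three_state_model <- function(frame_interval = 0.012, loc_sigma = 0.04) {
  p <- c(0.58, 0.31, 0.11)
  a_fn <- 0.05                      # F -> N per frame
  a_ni <- 0.03                      # N -> I per frame
  a_nf <- p[1] * a_fn / p[2]        # detailed balance on the F-N arm
  a_in <- p[2] * a_ni / p[3]        # detailed balance on the N-I arm
  A <- rbind(c(1 - a_fn, a_fn, 0),
             c(a_nf, 1 - a_nf - a_ni, a_ni),
             c(0, a_in, 1 - a_in))
  diffusion_model(diff_coeffs = c(1.0, 0.3, 0.08), occupancies = p,
                  transition_matrix = A, frame_interval = frame_interval,
                  loc_sigma = loc_sigma)
}

#' Simple two-state diffusion model
#'
#' Convenience two-state (fast/slow) model used for robustness checks, e.g.
#' model-size selection under heavy localization error.
#'
#' @param diff_coeffs two diffusion coefficients, um^2/s.
#' @param occupancies two occupancies summing to 1.
#' @param switch_prob per-frame probability of leaving the fast state; the
#'   reverse rate is set by detailed balance so the occupancies are the
#'   stationary distribution.
#' @param frame_interval frame interval, s.
#' @param loc_sigma localization error, um.
#' @return A `diffusion_model` with K = 2.
#' @export
demo_two_state_model <- function(diff_coeffs = c(1.0, 0.05),
                                 occupancies = c(0.6, 0.4),
                                 switch_prob = 0.1,
                                 frame_interval = 0.012, loc_sigma = 0.04) {
  p <- occupancies
  a12 <- switch_prob
  a21 <- p[1] * a12 / p[2]
  A <- rbind(c(1 - a12, a12), c(a21, 1 - a21))
  diffusion_model(diff_coeffs = diff_coeffs, occupancies = p,
                  transition_matrix = A, frame_interval = frame_interval,
                  loc_sigma = loc_sigma)
}
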