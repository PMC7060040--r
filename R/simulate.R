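#' Simulate 2D Markov-switching Brownian trajectories
#'
#' Generates trajectories from a K-state diffusion model: each particle is
#' initialized with a state drawn from the occupancies and a uniform position
#' in the field; at every step a displacement per axis is drawn from
#' Normal(0, 2 D \Delta t) for the current state, and the next state is drawn
#' from the transition-matrix row of the current state. Track lengths follow
#' a geometric distribution (memoryless photobleaching) with the given mean
#' number of positions, with a minimum of two positions. Start frames are
#' spread uniformly over the movie so the per-frame particle density matches
#' the requested value. Positions are continuous (no boundary is applied);
#' the field size is recorded for density and pair-correlation analysis.
#'
#' Localization error is not applied here; use [add_localization_noise()].
#' Ground-truth states are recorded per step.
#'
#' @param model a [diffusion_model()].
#' @param n_traj number of trajectories (>= 1).
#' @param mean_track_len mean track length in positions (>= 2); default 5.
#' @param density target per-frame particle density, particles/um^2
#'   (default 0.02). Together with `n_frames` this sets the field size.
#' @param n_frames movie length in frames; default chosen so that about 50
#'   particles are concurrently visible.
#' @param seed integer seed for reproducibility.
#' @return A [trajectory_set()] with `true_state` per step.
#' @export
simulate_markov_trajectories <- function(model, n_traj, mean_track_len = 5,
                                         density = 0.02, n_frames = NULL,
                                         seed = NULL) {
  validate_diffusion_model(model)
  if (n_traj < 1) stop_invariant("n_traj must be >= 1")
  if (mean_track_len < 2) stop_invariant("mean_track_len must be >= 2")
  if (density <= 0) stop_invariant("density must be > 0")
  K <- model$n_states
  dt <- model$frame_interval
  if (is.null(n_frames))
    n_frames <- max(1L, as.integer(ceiling(n_traj * mean_track_len / 50)))
  # field sized so that the mean concurrent particle count / area = density
  concurrent <- n_traj * mean_track_len / n_frames
  field <- sqrt(concurrent / density)

  with_seed(seed, {
    # geometric track lengths, minimum 2 positions, mean = mean_track_len
    extra <- if (mean_track_len > 2)
      rgeom(n_traj, prob = 1 / (mean_track_len - 1)) else 0L
    len <- 2L + extra                      # positions per trajectory
    n_steps <- len - 1L
    max_steps <- max(n_steps)

    start_frame <- sample.int(n_frames, n_traj, replace = TRUE)

    # state chains, vectorized across trajectories
    S <- matrix(NA_integer_, n_traj, max_steps)
    cumA <- t(apply(model$transition_matrix, 1L, cumsum))
    s <- findInterval(runif(n_traj), cumsum(model$occupancies)) + 1L
    s <- pmin(s, K)
    for (t in seq_len(max_steps)) {
      alive <- n_steps >= t
      S[alive, t] <- s[alive]
      if (t < max_steps) {
        u <- runif(n_traj)
        # next state: first column of cumA[s, ] exceeding u
        nxt <- rowSums(u > cumA[s, , drop = FALSE]) + 1L
        s <- pmin(nxt, K)
      }
    }

    # displacements: sd depends on the state of each step
    sd_step <- sqrt(2 * model$diff_coeffs * dt)
    DX <- matrix(NA_real_, n_traj, max_steps)
    DY <- matrix(NA_real_, n_traj, max_steps)
    live <- !is.na(S)
    n_live <- sum(live)
    DX[live] <- rnorm(n_live, sd = sd_step[S[live]])
    DY[live] <- rnorm(n_live, sd = sd_step[S[live]])

    # positions via cumulative sums (column loop keeps memory linear)
    X <- matrix(NA_real_, n_traj, max_steps + 1L)
    Y <- matrix(NA_real_, n_traj, max_steps + 1L)
    X[, 1L] <- runif(n_traj, 0, field)
    Y[, 1L] <- runif(n_traj, 0, field)
    for (t in seq_len(max_steps)) {
      X[, t + 1L] <- X[, t] + DX[, t]
      Y[, t + 1L] <- Y[, t] + DY[, t]
    }

    idx_traj <- rep.int(seq_len(n_traj), len)
    idx_pos <- sequence(len)
    flat <- cbind(idx_traj, idx_pos)
    # per-step state on the step's start row; NA on each trajectory's last row
    step_state <- ifelse(idx_pos < len[idx_traj],
                         S[cbind(idx_traj, pmin(idx_pos, max_steps))],
                         NA_integer_)
    tracks <- data.table(
      traj_id = idx_traj,
      frame = start_frame[idx_traj] + idx_pos - 1L,
      x = X[flat],
      y = Y[flat],
      true_state = step_state)
    trajectory_set(tracks, frame_interval = dt, field_size = field)
  })
}

#' Add localization error to trajectory coordinates
#'
#' Perturbs every coordinate independently by Normal(0, sigma^2) per axis.
#' Noise is applied to positions, not displacements, so consecutive steps
#' share the error of their common endpoint and are negatively correlated,
#' as in real localization data. Ground-truth states are untouched.
#'
#' @param trajs a `trajectory_set`.
#' @param sigma localization error (um per coordinate), >= 0.
#' @param seed integer seed.
#' @return A new `trajectory_set`.
#' @export
add_localization_noise <- function(trajs, sigma, seed = NULL) {
  if (!is.numeric(sigma) || sigma < 0) stop_invariant("sigma must be >= 0")
  if (sigma == 0) return(trajs)
  with_seed(seed, {
    tk <- copy(trajs$tracks)
    n <- nrow(tk)
    tk[, x := x + rnorm(n, sd = sigma)]
    tk[, y := y + rnorm(n, sd = sigma)]
    trajectory_set(tk, frame_interval = trajs$frame_interval,
                   field_size = trajs$field_size)
  })
}

#' Strip trajectory identities to a per-frame localization table
#'
#' Renders a trajectory set as the per-frame point detections a localization
#' pipeline would produce, removing the linking information, so the linking
#' stage can be exercised end to end.
#'
#' @param trajs a `trajectory_set`.
#' @param keep_identity if `TRUE`, retain the source trajectory id in a
#'   `source_id` column (used to score linking against ground truth).
#' @return A `localization_table`: data.table with columns `frame`, `x`, `y`
#'   (and optionally `source_id`), sorted by frame, with attributes
#'   `field_size` and `frame_interval`.
#' @export
render_localization_table <- function(trajs, keep_identity = FALSE) {
  if (nrow(trajs$tracks) == 0) stop_invariant("empty trajectory set")
  cols <- c("frame", "x", "y")
  locs <- trajs$tracks[, c(cols, if (keep_identity) "traj_id"), with = FALSE]
  if (keep_identity) setnames(locs, "traj_id", "source_id")
  setorder(locs, frame)
  setattr(locs, "field_size", trajs$field_size)
  setattr(locs, "frame_interval", trajs$frame_interval)
  setattr(locs, "class", c("localization_table", class(locs)))
  locs[]
}

#' Deterministic occupancy relaxation
#'
#' Iterates the master equation p(t+1) = p(t) A for a per-frame transition
#' matrix A, recording the occupancy vector at every step. Used to ask what
#' occupancies a fitted model would relax to if the system were closed
#' (no exchange with the cytosolic reservoir).
#'
#' @param model a `diffusion_model`, or a K x K transition matrix.
#' @param p0 initial occupancy vector (sums to 1); defaults to the model's
#'   occupancies.
#' @param n_steps number of frames to evolve.
#' @return numeric matrix with `n_steps + 1` rows (row 1 = p0), one column
#'   per state.
#' @export
evolve_occupancies <- function(model, p0 = NULL, n_steps) {
  if (inherits(model, "diffusion_model")) {
    A <- model$transition_matrix
    if (is.null(p0)) p0 <- model$occupancies
  } else {
    A <- as.matrix(model)
  }
  K <- nrow(A)
  if (is.null(p0)) stop_invariant("p0 required when model is a bare matrix")
  if (length(p0) != K) stop_invariant("p0 must have length %d", K)
  if (any(p0 < 0) || abs(sum(p0) - 1) > 1e-9)
    stop_invariant("p0 must be a probability distribution (sums to %.12g)",
                   sum(p0))
  rs <- rowSums(A)
  if (any(abs(rs - 1) > 1e-9))
    stop_invariant("transition matrix rows must sum to 1")
  out <- matrix(NA_real_, n_steps + 1L, K)
  out[1L, ] <- p0
  p <- p0
  for (t in seq_len(n_steps)) {
    p <- as.numeric(p %*% A)
    p <- p / sum(p)                        # guard accumulation drift
    out[t + 1L, ] <- p
  }
  colnames(out) <- state_labels(K)
  out
}
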