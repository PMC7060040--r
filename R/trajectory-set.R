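#' Set of linked 2D trajectories
#'
#' A `trajectory_set` holds linked single-particle trajectories as one long
#' table plus the acquisition metadata. Each trajectory occupies consecutive
#' frames and has at least two positions. Ground-truth states (from a
#' simulator) are per-step labels: the label stored on a row describes the
#' displacement that starts at that row, so the last row of each trajectory
#' carries `NA`.
#'
#' @param tracks data.frame with columns `traj_id`, `frame`, `x`, `y` and
#'   optionally `true_state` (per-step ground truth) and `source_id`
#'   (provenance through rendering/linking round trips). Coordinates in um.
#' @param frame_interval frame interval in seconds.
#' @param field_size linear size of the (square) field of view in um, or
#'   `c(width, height)`; may be `NA` when unknown.
#' @return An object of class `trajectory_set`.
#' @export
trajectory_set <- function(tracks, frame_interval, field_size = NA_real_) {
  tracks <- as.data.table(tracks)
  required <- c("traj_id", "frame", "x", "y")
  missing <- setdiff(required, names(tracks))
  if (length(missing))
    stop_invariant("tracks is missing column(s): %s",
                   paste(missing, collapse = ", "))
  if (nrow(tracks) == 0) stop_invariant("tracks must be non-empty")
  if (any(!is.finite(tracks$x)) || any(!is.finite(tracks$y)))
    stop_invariant("coordinates must be finite")
  setkey(tracks, traj_id, frame)
  n_pos <- tracks[, .N, by = traj_id]
  if (any(n_pos$N < 2))
    stop_invariant("every trajectory must have >= 2 positions (trajectory %s has %d)",
                   n_pos$traj_id[which.min(n_pos$N)], min(n_pos$N))
  gaps <- tracks[, any(diff(frame) != 1L), by = traj_id]
  if (any(gaps$V1))
    stop_invariant("frames within a trajectory must be strictly consecutive (trajectory %s)",
                   gaps$traj_id[which(gaps$V1)[1]])
  structure(list(tracks = tracks,
                 frame_interval = frame_interval,
                 field_size = rep_len(as.numeric(field_size), 2L)),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  n <- n_trajectories(x)
  cat(sprintf("trajectory_set: %d trajectories, %d positions (dt = %g s)\n",
              n, nrow(x$tracks), x$frame_interval))
  len <- x$tracks[, .N, by = traj_id]$N
  cat(sprintf("  track length: mean %.2f positions, range %d-%d\n",
              mean(len), min(len), max(len)))
  if (all(is.finite(x$field_size)))
    cat(sprintf("  field: %g x %g um\n", x$field_size[1], x$field_size[2]))
  invisible(x)
}

#' Number of trajectories in a set
#' @param trajs a `trajectory_set`.
#' @return integer count.
#' @export
n_trajectories <- function(trajs) {
  uniqueN(trajs$tracks$traj_id)
}

#' Per-step displacement records
#'
#' Converts a trajectory set to one record per adjacent frame pair: the
#' displacement components, step length and squared step length. State
#' inference operates on these displacements, not on the coordinates.
#'
#' @param trajs a `trajectory_set`.
#' @return data.table with columns `traj_id`, `frame` (frame at the start of
#'   the step), `dx`, `dy`, `r`, `r2`, and `true_state` when present.
#' @export
traj_steps <- function(trajs) {
  tk <- trajs$tracks
  id <- tk$traj_id
  same <- id[-1] == id[-length(id)]      # rows sorted by (traj_id, frame)
  i <- which(same)
  out <- data.table(traj_id = id[i],
                    frame = tk$frame[i],
                    dx = tk$x[i + 1L] - tk$x[i],
                    dy = tk$y[i + 1L] - tk$y[i])
  out[, r2 := dx^2 + dy^2]
  out[, r := sqrt(r2)]
  if ("true_state" %in% names(tk)) out[, true_state := tk$true_state[i]]
  out[]
}

# internal: split positions into per-trajectory index bookkeeping
traj_lengths <- function(trajs) {
  trajs$tracks[, .N, by = traj_id]
}

#' Ground-truth state assignment of a simulated trajectory set
#'
#' Wraps the simulator's per-step ground-truth labels as a
#' `state_assignment`, interchangeable with the output of
#' [assign_states()]. Used for oracle comparisons and positive controls.
#'
#' @param trajs a `trajectory_set` carrying `true_state`.
#' @param n_states number of states; default the largest label observed.
#' @return A `state_assignment` data.table (`traj_id`, `frame`, `state`).
#' @export
true_state_assignment <- function(trajs, n_states = NULL) {
  if (!"true_state" %in% names(trajs$tracks))
    stop_invariant("trajectory set carries no ground-truth states")
  st <- traj_steps(trajs)
  out <- data.table(traj_id = st$traj_id, frame = st$frame,
                    state = as.integer(st$true_state))
  setattr(out, "class", c("state_assignment", class(out)))
  setattr(out, "n_states",
          as.integer(n_states %||% max(out$state, na.rm = TRUE)))
  out[]
}
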