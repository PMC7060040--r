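#' Build a localization table
#'
#' Light constructor/validator for per-frame point detections.
#'
#' @param df data.frame with columns `frame` (integer >= 0), `x`, `y` (um),
#'   optionally `precision` and `source_id`.
#' @param field_size linear field size in um (or `c(w, h)`); needed for
#'   density gating and pair correlation.
#' @param frame_interval frame interval, s.
#' @return A `localization_table` (data.table, sorted by frame).
#' @export
localization_table <- function(df, field_size = NA_real_,
                               frame_interval = NA_real_) {
  locs <- as.data.table(df)
  missing <- setdiff(c("frame", "x", "y"), names(locs))
  if (length(missing))
    stop_invariant("localization table missing column(s): %s",
                   paste(missing, collapse = ", "))
  if (nrow(locs) == 0) stop_invariant("localization table is empty")
  if (any(locs$frame < 0)) stop_invariant("frames must be >= 0")
  if (any(!is.finite(locs$x)) || any(!is.finite(locs$y)))
    stop_invariant("coordinates must be finite")
  setorder(locs, frame)
  setattr(locs, "field_size", rep_len(as.numeric(field_size), 2L))
  setattr(locs, "frame_interval", frame_interval)
  if (!inherits(locs, "localization_table"))
    setattr(locs, "class", c("localization_table", class(locs)))
  locs[]
}

#' Step-size survey with a provisional linking threshold
#'
#' First-pass linking with a deliberately large threshold, from which the
#' step-size histogram is computed. The histogram of a well-behaved dataset
#' splits into a signal segment (true steps, Rayleigh-like, peaked near the
#' typical step) and a noise tail (misconnections, rising with distance);
#' the suggested cutoff is the first local minimum of the smoothed histogram
#' after the signal peak, to be confirmed by the user before final linking.
#'
#' @param locs a `localization_table`.
#' @param provisional_threshold large first-pass threshold, um (default 2).
#' @param binwidth histogram bin width, um (default 0.01).
#' @return A `step_histogram`: list with `breaks`, `counts`, `mids`,
#'   `suggested_cutoff` (um) and `provisional_threshold`.
#' @export
step_size_survey <- function(locs, provisional_threshold = 2.0,
                             binwidth = 0.01) {
  if (uniqueN(locs$frame) < 2)
    stop_invariant("need localizations in at least 2 frames")
  trajs <- link_trajectories(locs, max_step = provisional_threshold)
  r <- traj_steps(trajs)$r
  breaks <- seq(0, provisional_threshold + binwidth, by = binwidth)
  h <- hist(r, breaks = breaks, plot = FALSE)
  counts <- h$counts
  # smooth and find first local minimum after the global peak
  k <- 5L
  sm <- as.numeric(stats::filter(counts, rep(1 / k, k), sides = 2))
  sm[is.na(sm)] <- counts[is.na(sm)]
  peak <- which.max(sm)
  cutoff <- breaks[length(breaks)]
  if (peak < length(sm) - 1L) {
    after <- sm[(peak + 1L):length(sm)]
    d <- diff(after)
    turn <- which(d >= 0)
    # require the valley to be well below the peak to count as a minimum
    for (j in turn) {
      if (after[j] < 0.25 * sm[peak]) {
        cutoff <- h$mids[peak + j]
        break
      }
    }
  }
  structure(list(breaks = breaks, counts = counts, mids = h$mids,
                 suggested_cutoff = cutoff,
                 provisional_threshold = provisional_threshold),
            class = "step_histogram")
}

#' @export
print.step_histogram <- function(x, ...) {
  cat(sprintf(
    "step-size histogram: %d steps, provisional threshold %g um\n",
    sum(x$counts), x$provisional_threshold))
  cat(sprintf("  suggested cutoff: %.3f um (confirm before final linking)\n",
              x$suggested_cutoff))
  invisible(x)
}

#' Link localizations into trajectories
#'
#' Greedy frame-to-frame linking under a hard distance threshold with an
#' unambiguity rule applied in both directions: a track is extended only if
#' exactly one localization in the next frame lies within `max_step` of its
#' head, and that localization has no other track head within `max_step`.
#' Any ambiguity terminates the track; unclaimed localizations start new
#' tracks. No gap closing: a particle missing for one frame ends its track.
#' No localization is used twice. Only tracks with at least two positions
#' are returned.
#'
#' @param locs a `localization_table` (or data.frame with frame/x/y).
#' @param max_step linking threshold, um (> 0). The package defaults used
#'   for membrane GTPase data are 0.5 um at a 12 ms frame interval and
#'   0.8 um at 35 ms.
#' @param frame_interval frame interval, s; taken from `locs` if absent.
#' @return A [trajectory_set()]. If `locs` carries a `source_id` column the
#'   output tracks retain it for ground-truth scoring.
#' @export
link_trajectories <- function(locs, max_step, frame_interval = NULL) {
  if (!is.numeric(max_step) || max_step <= 0)
    stop_invariant("max_step must be > 0")
  if (!is.data.frame(locs)) stop_invariant("locs must be a data.frame")
  dt_attr <- attr(locs, "frame_interval")
  frame_interval <- frame_interval %||%
    (if (!is.null(dt_attr) && is.finite(dt_attr)) dt_attr else NA_real_)
  field <- attr(locs, "field_size") %||% NA_real_

  locs <- as.data.table(locs)
  setorder(locs, frame)
  n <- nrow(locs)
  track_of <- integer(n)                  # output track id per localization
  frames <- locs$frame
  xs <- locs$x; ys <- locs$y

  frame_rows <- split(seq_len(n), frames)
  frame_keys <- as.integer(names(frame_rows))

  next_track <- 0L
  active_rows <- integer(0)               # row indices of current heads
  prev_frame <- NA_integer_

  for (fi in seq_along(frame_keys)) {
    f <- frame_keys[fi]
    rows <- frame_rows[[fi]]
    if (!is.na(prev_frame) && f == prev_frame + 1L && length(active_rows)) {
      hx <- xs[active_rows]; hy <- ys[active_rows]
      px <- xs[rows]; py <- ys[rows]
      d2 <- outer(hx, px, "-")^2 + outer(hy, py, "-")^2
      within <- d2 <= max_step^2
      head_cand <- rowSums(within)
      pt_cand <- colSums(within)
      linked_pt <- rep(NA_integer_, length(rows))
      ext <- which(head_cand == 1L)
      if (length(ext)) {
        pt_idx <- max.col(within[ext, , drop = FALSE], ties.method = "first")
        ok <- pt_cand[pt_idx] == 1L
        ext <- ext[ok]; pt_idx <- pt_idx[ok]
        track_of[rows[pt_idx]] <- track_of[active_rows[ext]]
        linked_pt[pt_idx] <- ext
      }
      new_pts <- which(is.na(linked_pt))
      if (length(new_pts)) {
        ids <- seq.int(next_track + 1L, next_track + length(new_pts))
        next_track <- next_track + length(new_pts)
        track_of[rows[new_pts]] <- ids
      }
    } else {
      ids <- seq.int(next_track + 1L, next_track + length(rows))
      next_track <- next_track + length(rows)
      track_of[rows] <- ids
    }
    active_rows <- rows
    prev_frame <- f
  }

  locs[, traj_id := track_of]
  locs[, n_pos := .N, by = traj_id]
  out <- locs[n_pos >= 2L]
  if (nrow(out) == 0)
    stop_invariant("no trajectory with >= 2 positions at max_step = %g", max_step)
  keep <- c("traj_id", "frame", "x", "y",
            if ("source_id" %in% names(out)) "source_id")
  trajectory_set(out[, keep, with = FALSE], frame_interval = frame_interval,
                 field_size = field)
}

#' Misconnection rate of linked trajectories
#'
#' Fraction of links that join localizations from different ground-truth
#' particles. Requires the `source_id` column preserved by
#' [render_localization_table()] with `keep_identity = TRUE`.
#'
#' @param trajs a linked `trajectory_set` whose tracks carry `source_id`.
#' @return fraction of wrong links in `[0, 1]`.
#' @export
misconnection_rate <- function(trajs) {
  tk <- trajs$tracks
  if (!"source_id" %in% names(tk))
    stop_invariant("tracks carry no source_id ground truth")
  id <- tk$traj_id
  same_traj <- id[-1] == id[-length(id)]
  src <- tk$source_id
  wrong <- src[-1] != src[-length(src)]
  n_links <- sum(same_traj)
  if (n_links == 0) return(0)
  sum(wrong & same_traj) / n_links
}

#' Per-frame particle density and gate verdict
#'
#' Computes the per-frame localization density (count / field area) and
#' flags frames at or above the density cap. Datasets failing the gate are
#' prone to trajectory misconnection and should not be used for model-size
#' inference.
#'
#' @param locs a `localization_table`.
#' @param field_area field area in um^2; taken from the table's `field_size`
#'   attribute if absent.
#' @param cap density cap, particles/um^2 per frame (default 0.03). A frame
#'   exactly at the cap is flagged (the gate requires strictly fewer).
#' @return list with `density` (data.table: frame, n, density, above_cap),
#'   `pass` (logical), `cap` and `field_area`. Frames with no localizations
#'   have density 0.
#' @export
frame_density <- function(locs, field_area = NULL, cap = 0.03) {
  fs <- attr(locs, "field_size")
  if (is.null(field_area)) {
    if (is.null(fs) || any(!is.finite(fs)))
      stop_invariant("field_area unknown: supply it or set field_size on the table")
    field_area <- prod(rep_len(fs, 2L))
  }
  if (field_area <= 0) stop_invariant("field_area must be > 0")
  locs <- as.data.table(locs)
  counts <- locs[, .(n = .N), by = frame]
  all_frames <- data.table(frame = seq(min(locs$frame), max(locs$frame)))
  counts <- counts[all_frames, on = "frame"]
  counts[is.na(n), n := 0L]
  counts[, density := n / field_area]
  counts[, above_cap := density >= cap]
  list(density = counts[], pass = !any(counts$above_cap),
       cap = cap, field_area = field_area)
}
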