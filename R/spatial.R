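#' Collapse same-state runs to averaged state coordinates
#'
#' Every maximal run of consecutive same-state steps within a trajectory is
#' collapsed to a single segment whose coordinate is the arithmetic mean of
#' all member positions, including both endpoints of the run. A boundary
#' position shared by two adjacent runs contributes to both averages. This
#' prevents a molecule dwelling in one domain from being counted once per
#' frame in the pair correlation analysis.
#'
#' @param trajs a `trajectory_set`.
#' @param assignment a `state_assignment` aligned with `traj_steps(trajs)`.
#' @param min_run_len minimum number of steps for a run to qualify
#'   (default 1 = all runs). Set to 2 to keep only runs spanning more than
#'   two consecutive time points.
#' @param compute_span if `TRUE` (default) compute `max_span`, the largest
#'   pairwise distance among member positions (exhaustive).
#' @return A `state_segments` data.table: `traj_id`, `state`, `start_frame`,
#'   `end_frame`, `n_steps`, `n_points`, `x`, `y` (averaged coordinate) and
#'   `max_span` (um), with field metadata attached as attributes.
#' @export
collapse_state_segments <- function(trajs, assignment, min_run_len = 1L,
                                    compute_span = TRUE) {
  steps <- traj_steps(trajs)
  if (nrow(steps) != nrow(assignment) ||
      !identical(steps$traj_id, assignment$traj_id) ||
      !identical(as.integer(steps$frame), as.integer(assignment$frame)))
    stop_invariant("assignment is not aligned with the trajectory steps")
  st <- copy(steps)[, state := assignment$state]
  st[, j := seq_len(.N), by = traj_id]
  st[, seg := rleid(traj_id, state)]
  segs <- st[, .(traj_id = traj_id[1L], state = state[1L],
                 start_frame = frame[1L], end_frame = frame[.N] + 1L,
                 j1 = j[1L], j2 = j[.N], n_steps = .N), by = seg]

  pos <- copy(trajs$tracks)[, .(traj_id, frame, x, y)]
  pos[, pidx := seq_len(.N), by = traj_id]
  pos[, `:=`(cx = cumsum(x), cy = cumsum(y)), by = traj_id]

  # member positions are pidx j1 .. j2+1; means via cumulative sums
  segs[, phi := j2 + 1L]
  segs[, plo := j1 - 1L]
  segs[, c("cx_hi", "cy_hi") :=
         pos[segs, on = .(traj_id, pidx = phi), .(cx, cy)]]
  lo <- pos[segs, on = .(traj_id, pidx = plo), .(cx, cy)]
  segs[, `:=`(cx_lo = fifelse(is.na(lo$cx), 0, lo$cx),
              cy_lo = fifelse(is.na(lo$cy), 0, lo$cy))]
  segs[, n_points := n_steps + 1L]
  segs[, `:=`(x = (cx_hi - cx_lo) / n_points,
              y = (cy_hi - cy_lo) / n_points)]

  if (compute_span) {
    segs[, max_span := 0]
    # exhaustive pairwise span, vectorized across segments of equal size
    mem <- segs[, .(pidx = seq.int(j1, j2 + 1L)), by = .(seg, traj_id)]
    mem[pos, on = c("traj_id", "pidx"), `:=`(mx = i.x, my = i.y)]
    mem[, m := .N, by = seg]
    for (msize in unique(mem$m)) {
      sub <- mem[m == msize]
      ns <- nrow(sub) / msize
      X <- matrix(sub$mx, nrow = ns, ncol = msize, byrow = TRUE)
      Y <- matrix(sub$my, nrow = ns, ncol = msize, byrow = TRUE)
      sp2 <- numeric(ns)
      for (a in seq_len(msize - 1L)) for (b in (a + 1L):msize) {
        d2 <- (X[, a] - X[, b])^2 + (Y[, a] - Y[, b])^2
        upd <- d2 > sp2
        sp2[upd] <- d2[upd]
      }
      seg_ids <- sub$seg[seq(1L, nrow(sub), by = msize)]
      segs[match(seg_ids, seg), max_span := sqrt(sp2)]
    }
  }

  out <- segs[n_steps >= min_run_len,
              .(traj_id, state, start_frame, end_frame, n_steps, n_points,
                x, y, max_span = if (compute_span) max_span else NA_real_)]
  setattr(out, "field_size", trajs$field_size)
  setattr(out, "frame_interval", trajs$frame_interval)
  setattr(out, "class", c("state_segments", class(out)))
  out[]
}

#' Pair correlation function g(r)
#'
#' Ratio of the observed point density in an annulus at distance r from a
#' reference point to the density expected under complete spatial
#' randomness. `g = 1` means random, `g > 1` clustering. Auto mode
#' (`points_b = NULL`) correlates a point set with itself excluding
#' self-pairs; cross mode correlates two sets (e.g. two diffusion states).
#'
#' Edge handling: `"periodic"` uses minimum-image distances on the field
#' (exact for simulations on a periodic or statistically homogeneous
#' field; requires `r_max <= min(field)/2`). `"rect"` uses plain distances
#' with the isotropised set-covariance correction for a rectangular window,
#' gamma(r) = ab - 2(a+b)r/pi + r^2/pi, exact in expectation for uniformly
#' positioned reference points and valid for r < min(a, b).
#'
#' @param points_a data.frame/matrix with columns `x`, `y` (um), e.g. a
#'   `state_segments` table.
#' @param points_b optional second point set for cross correlation.
#' @param field_size field linear size, um (scalar or `c(w, h)`); defaults
#'   to the `field_size` attribute of `points_a`.
#' @param dr annulus width, um (default 0.01 = 10 nm).
#' @param r_max largest distance analyzed, um (default 1).
#' @param boundary `"periodic"` or `"rect"` (see above).
#' @return A `pair_correlation` data.table: `r_lo`, `r_hi`, `r_mid`,
#'   `count` (ordered pairs), `expected`, `g`; attributes `amplitude`
#'   (max g over bins with r_lo >= dr), `mode`, `n_a`, `n_b`.
#' @export
pair_correlation <- function(points_a, points_b = NULL, field_size = NULL,
                             dr = 0.01, r_max = 1.0,
                             boundary = c("periodic", "rect")) {
  boundary <- match.arg(boundary)
  field_size <- field_size %||% attr(points_a, "field_size")
  if (is.null(field_size) || any(!is.finite(field_size)))
    stop_invariant("field_size required for pair correlation")
  wh <- rep_len(as.numeric(field_size), 2L)
  area <- prod(wh)
  pa <- as_xy(points_a, "points_a")
  auto <- is.null(points_b)
  pb <- if (auto) pa else as_xy(points_b, "points_b")
  if (auto && nrow(pa) < 2)
    stop_invariant("points_a needs >= 2 points for auto correlation")
  if (!auto && (nrow(pa) < 1 || nrow(pb) < 1))
    stop_invariant("both point sets must be non-empty (%s is empty)",
                   if (nrow(pa) < 1) "points_a" else "points_b")
  if (boundary == "periodic" && r_max > min(wh) / 2)
    stop_invariant("periodic mode requires r_max <= min(field)/2")

  breaks <- seq(0, r_max, by = dr)
  if (max(breaks) < r_max) breaks <- c(breaks, max(breaks) + dr)
  nb <- length(breaks) - 1L
  counts <- numeric(nb)
  chunk <- max(1L, floor(2e6 / nrow(pb)))
  for (i0 in seq(1L, nrow(pa), by = chunk)) {
    i1 <- min(i0 + chunk - 1L, nrow(pa))
    dx <- outer(pa$x[i0:i1], pb$x, "-")
    dy <- outer(pa$y[i0:i1], pb$y, "-")
    if (boundary == "periodic") {
      dx <- dx - wh[1] * round(dx / wh[1])
      dy <- dy - wh[2] * round(dy / wh[2])
    }
    d <- sqrt(dx^2 + dy^2)
    if (auto) d[cbind(seq_len(i1 - i0 + 1L), i0:i1)] <- Inf
    d <- d[d < max(breaks)]
    if (length(d))
      counts <- counts + tabulate(findInterval(d, breaks,
                                               rightmost.closed = TRUE),
                                  nbins = nb)
  }

  r_lo <- breaks[-length(breaks)]
  r_hi <- breaks[-1L]
  ann_area <- pi * (r_hi^2 - r_lo^2)
  n_other <- if (auto) nrow(pa) - 1L else nrow(pb)
  expected <- as.numeric(nrow(pa)) * n_other * ann_area / area
  if (boundary == "rect") {
    r_mid <- (r_lo + r_hi) / 2
    gam <- area - 2 * (wh[1] + wh[2]) * r_mid / pi + r_mid^2 / pi
    expected <- expected * gam / area
  }
  res <- data.table(r_lo = r_lo, r_hi = r_hi, r_mid = (r_lo + r_hi) / 2,
                    count = counts, expected = expected,
                    g = counts / expected)
  amp_bins <- res$r_lo >= dr - 1e-12
  setattr(res, "amplitude", max(res$g[amp_bins], na.rm = TRUE))
  setattr(res, "mode", if (auto) "auto" else "cross")
  setattr(res, "n_a", nrow(pa))
  setattr(res, "n_b", nrow(pb))
  setattr(res, "class", c("pair_correlation", class(res)))
  res[]
}

as_xy <- function(p, what) {
  p <- as.data.table(p)
  if (!all(c("x", "y") %in% names(p)))
    stop_invariant("%s must have x and y columns", what)
  p[, .(x, y)]
}

#' @export
print.pair_correlation <- function(x, ...) {
  cat(sprintf("pair correlation (%s): %d x %d points, amplitude = %.3f\n",
              attr(x, "mode"), attr(x, "n_a"), attr(x, "n_b"),
              attr(x, "amplitude")))
  invisible(x)
}

#' g(r) amplitude versus analysis time interval
#'
#' Slices the acquisition into non-overlapping windows of each requested
#' length, collapses state runs within each window, computes the per-state
#' auto pair correlation per window and averages the amplitudes. If a
#' membrane domain has a finite lifetime, windows longer than the lifetime
#' mix points from several domain generations and the amplitude decays;
#' static structure gives a flat amplitude profile.
#'
#' @inheritParams collapse_state_segments
#' @param intervals_min window lengths in minutes (default 1, 5, 10, 20).
#'   Intervals longer than the dataset are skipped with a warning.
#' @param states states to analyze (default: all observed).
#' @param min_points minimum points per window per state to compute g(r)
#'   (default 20).
#' @inheritParams pair_correlation
#' @return data.table: `state`, `interval_min`, `n_windows`, `amplitude`
#'   (mean over windows), `amplitude_sd`.
#' @export
gr_time_course <- function(trajs, assignment,
                           intervals_min = c(1, 5, 10, 20),
                           states = NULL, dr = 0.01, r_max = 1.0,
                           boundary = c("periodic", "rect"),
                           min_points = 20, min_run_len = 1L) {
  boundary <- match.arg(boundary)
  dt <- trajs$frame_interval
  segs <- collapse_state_segments(trajs, assignment,
                                  min_run_len = min_run_len,
                                  compute_span = FALSE)
  f0 <- min(trajs$tracks$frame)
  duration_min <- (max(trajs$tracks$frame) - f0 + 1) * dt / 60
  states <- states %||% sort(unique(segs$state))
  out <- list()
  for (iv in intervals_min) {
    if (iv > duration_min + 1e-9) {
      warning(sprintf("interval %g min exceeds dataset duration (%.2f min); skipped",
                      iv, duration_min))
      next
    }
    w_frames <- max(1, round(iv * 60 / dt))
    win <- (segs$start_frame - f0) %/% w_frames
    n_win_total <- floor(duration_min / iv)
    for (s in states) {
      amps <- c()
      for (w in seq_len(n_win_total) - 1L) {
        pts <- segs[state == s & win == w]
        if (nrow(pts) < min_points) next
        gr <- pair_correlation(pts, field_size = trajs$field_size,
                               dr = dr, r_max = r_max, boundary = boundary)
        amps <- c(amps, attr(gr, "amplitude"))
      }
      if (length(amps))
        out[[length(out) + 1L]] <- data.table(
          state = s, interval_min = iv, n_windows = length(amps),
          amplitude = mean(amps),
          amplitude_sd = if (length(amps) > 1) sd(amps) else NA_real_)
    }
  }
  rbindlist(out)
}

#' Domain-span histogram (lower-bound domain size)
#'
#' Histogram of the maximum distance travelled while continuously in one
#' state (the `max_span` of each segment). Because short tracks undersample
#' the domain, the mean span is a lower bound on the true domain diameter.
#'
#' @param segments a `state_segments` table (with spans computed).
#' @param state the state to summarize.
#' @param binwidth histogram bin width, um (default 0.01).
#' @return list of class `span_histogram`: `breaks`, `counts`, `mids`,
#'   `mean_span`, `quantiles` (10/25/50/75/90%), `n_segments`, `state`.
#' @export
domain_span_histogram <- function(segments, state, binwidth = 0.01) {
  sp <- segments$max_span[segments$state == state &
                            segments$n_points >= 2]
  sp <- sp[is.finite(sp)]
  if (!length(sp))
    stop_invariant("no qualifying segments for state %s", state)
  breaks <- seq(0, max(sp) + binwidth, by = binwidth)
  h <- hist(sp, breaks = breaks, plot = FALSE)
  structure(list(breaks = h$breaks, counts = h$counts, mids = h$mids,
                 mean_span = mean(sp),
                 quantiles = quantile(sp, c(0.1, 0.25, 0.5, 0.75, 0.9)),
                 n_segments = length(sp), state = state),
            class = "span_histogram")
}

#' @export
print.span_histogram <- function(x, ...) {
  cat(sprintf("state %s: %d segments, mean span %.3f um (median %.3f)\n",
              x$state, x$n_segments, x$mean_span, x$quantiles[["50%"]]))
  invisible(x)
}

#' Deflection-angle distributions per state
#'
#' For every pair of successive same-state steps the deflection angle is
#' theta = 180 deg - angle(v1, v2), so a full reversal gives theta = 0
#' (a "returning" step) and straight continuation gives theta = 180.
#' Free Brownian motion yields a uniform distribution on [0, 180]; an
#' excess of acute angles (theta < 90) indicates confinement, with more
#' returning steps at domain boundaries.
#'
#' @inheritParams collapse_state_segments
#' @param binwidth histogram bin width in degrees (default 10).
#' @return list of class `deflection_result`, one element per state:
#'   `angles` (degrees), `histogram` (normalized, sums to 1),
#'   `acute_fraction`, `n`. States with no qualifying step pairs are
#'   omitted with a warning.
#' @export
deflection_angles <- function(trajs, assignment, binwidth = 10) {
  steps <- traj_steps(trajs)
  if (nrow(steps) != nrow(assignment))
    stop_invariant("assignment is not aligned with the trajectory steps")
  st <- copy(steps)[, state := assignment$state]
  n <- nrow(st)
  same <- st$traj_id[-1] == st$traj_id[-n] &
    st$state[-1] == st$state[-n] &
    st$frame[-1] == st$frame[-n] + 1L
  i <- which(same)
  v1x <- st$dx[i]; v1y <- st$dy[i]
  v2x <- st$dx[i + 1L]; v2y <- st$dy[i + 1L]
  len <- sqrt((v1x^2 + v1y^2) * (v2x^2 + v2y^2))
  ok <- len > 0
  cosphi <- pmin(1, pmax(-1, (v1x * v2x + v1y * v2y)[ok] / len[ok]))
  theta <- 180 - acos(cosphi) * 180 / pi
  state <- st$state[i][ok]

  states <- sort(unique(assignment$state))
  breaks <- seq(0, 180, by = binwidth)
  out <- list()
  for (s in states) {
    th <- theta[state == s]
    if (!length(th)) {
      warning(sprintf("no qualifying step pairs for state %s; omitted", s))
      next
    }
    h <- hist(th, breaks = breaks, plot = FALSE)
    out[[as.character(s)]] <- list(
      angles = th,
      histogram = data.table(theta_lo = breaks[-length(breaks)],
                             theta_hi = breaks[-1L],
                             density = h$counts / length(th)),
      acute_fraction = mean(th < 90),
      n = length(th))
  }
  structure(out, class = "deflection_result")
}

#' @export
print.deflection_result <- function(x, ...) {
  for (s in names(x))
    cat(sprintf("state %s: %d angle pairs, acute fraction %.3f\n",
                s, x[[s]]$n, x[[s]]$acute_fraction))
  invisible(x)
}
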