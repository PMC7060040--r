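#' Nested nanodomain configuration
#'
#' Geometry and kinetics for the spatial (positive-control) simulator:
#' intermediate-mobility domains (~200 nm) each containing one or more
#' immobilization subdomains (~70 nm), with finite lifetimes, a trapping
#' probability at the subdomains, a per-frame removal (sink) probability
#' while trapped, and a source rate injecting new fast molecules.
#'
#' @param field_size linear size of the square field, um.
#' @param intermediate data.frame of intermediate domains with columns
#'   `x`, `y`, `diameter` (um) and `lifetime` (s; `Inf` for static domains).
#' @param immobile data.frame of immobilization subdomains with columns
#'   `x`, `y`, `diameter`, `parent` (row index into `intermediate`) and
#'   `lifetime`. Every subdomain must lie geometrically inside its parent.
#' @param diff_coeffs named or ordered vector `c(fast, intermediate,
#'   trapped)` of region diffusion coefficients, um^2/s.
#' @param trap_prob probability per frame of becoming trapped when inside an
#'   immobilization subdomain.
#' @param escape_prob probability per frame of a trapped molecule escaping.
#' @param sink_prob probability per frame of a trapped molecule being
#'   removed from the membrane (internalization).
#' @param source_rate expected number of new fast molecules inserted per
#'   frame (Poisson).
#' @return An object of class `domain_config`.
#' @export
domain_config <- function(field_size, intermediate, immobile,
                          diff_coeffs = c(1.0, 0.3, 0.02),
                          trap_prob = 0.5, escape_prob = 0.05,
                          sink_prob = 0, source_rate = 0) {
  intermediate <- as.data.table(intermediate)
  immobile <- as.data.table(immobile)
  probs <- c(trap_prob = trap_prob, escape_prob = escape_prob,
             sink_prob = sink_prob)
  if (any(probs < 0 | probs > 1))
    stop_invariant("probabilities must lie in [0, 1] (%s)",
                   paste(names(probs)[probs < 0 | probs > 1], collapse = ", "))
  if (nrow(intermediate) && any(intermediate$diameter <= 0))
    stop_invariant("intermediate domain diameters must be > 0")
  if (nrow(immobile)) {
    if (any(immobile$diameter <= 0))
      stop_invariant("immobile subdomain diameters must be > 0")
    par <- immobile$parent
    if (any(par < 1 | par > nrow(intermediate)))
      stop_invariant("subdomain parent index out of range")
    d <- sqrt((immobile$x - intermediate$x[par])^2 +
              (immobile$y - intermediate$y[par])^2)
    bad <- d + immobile$diameter / 2 > intermediate$diameter[par] / 2 + 1e-12
    if (any(bad))
      stop_invariant("subdomain %d is not nested inside its parent domain %d",
                     which(bad)[1], par[which(bad)[1]])
  }
  structure(list(field_size = field_size,
                 intermediate = intermediate, immobile = immobile,
                 diff_coeffs = unname(diff_coeffs),
                 trap_prob = trap_prob, escape_prob = escape_prob,
                 sink_prob = sink_prob, source_rate = source_rate),
            class = "domain_config")
}

#' Random nested-domain configuration
#'
#' Draws intermediate domain centers uniformly over the field and places one
#' concentric immobilization subdomain inside each.
#'
#' @param field_size field size, um.
#' @param n_domains number of intermediate domains.
#' @param intermediate_diameter,immobile_diameter domain diameters, um.
#' @param lifetime domain lifetime in seconds (`Inf` = static). Expired
#'   domains are replaced by fresh ones at new random positions so the
#'   domain density stays constant.
#' @param seed integer seed.
#' @inheritParams domain_config
#' @return A `domain_config`.
#' @export
random_domain_config <- function(field_size, n_domains,
                                 intermediate_diameter = 0.2,
                                 immobile_diameter = 0.07,
                                 lifetime = Inf, seed = NULL,
                                 diff_coeffs = c(1.0, 0.3, 0.02),
                                 trap_prob = 0.5, escape_prob = 0.05,
                                 sink_prob = 0, source_rate = 0) {
  with_seed(seed, {
    ctr <- data.table(x = runif(n_domains, 0, field_size),
                      y = runif(n_domains, 0, field_size),
                      diameter = intermediate_diameter, lifetime = lifetime)
    sub <- data.table(x = ctr$x, y = ctr$y, diameter = immobile_diameter,
                      parent = seq_len(n_domains), lifetime = lifetime)
    domain_config(field_size, ctr, sub, diff_coeffs = diff_coeffs,
                  trap_prob = trap_prob, escape_prob = escape_prob,
                  sink_prob = sink_prob, source_rate = source_rate)
  })
}

#' Simulate diffusion in nested membrane nanodomains
#'
#' Positive-control simulator: particles diffuse with a region-dependent
#' diffusion coefficient (fast outside domains, intermediate inside an
#' intermediate domain), become trapped with probability `trap_prob` per
#' frame while inside an immobilization subdomain (reachable only from the
#' intermediate region, reflecting the nested-access geometry), and while
#' trapped move
#' with the trapped-state coefficient confined to the subdomain (reflecting
#' at its boundary). Trapped molecules escape with `escape_prob` per frame
#' and are removed with `sink_prob` per frame; new fast molecules are
#' injected at `source_rate` per frame (uniform positions). Domains expire
#' after their lifetime and are replaced at fresh random positions. Tracks
#' end by geometric photobleaching with mean `mean_track_len` positions.
#' The field boundary is reflecting, so positions stay in the field and
#' steps are never corrupted by wrap-around jumps.
#'
#' Ground truth per step records the region at the start of the step:
#' 1 = fast (outside any domain), 2 = intermediate domain, 3 = trapped.
#'
#' @param config a [domain_config()].
#' @param frame_interval frame interval, s.
#' @param n_frames number of frames to simulate.
#' @param n_init number of particles present at frame 1.
#' @param mean_track_len mean track length in positions (`Inf` disables
#'   photobleaching).
#' @param seed integer seed.
#' @return list with elements `trajs` (a [trajectory_set()]; tracks that
#'   ended with fewer than 2 positions are dropped) and `domain_history`
#'   (data.table of every domain generation with its active frame range).
#' @export
simulate_domain_trajectories <- function(config, frame_interval, n_frames,
                                         n_init, mean_track_len = 5,
                                         seed = NULL) {
  stopifnot(inherits(config, "domain_config"))
  if (n_frames < 2) stop_invariant("n_frames must be >= 2")
  L <- config$field_size
  dt <- frame_interval
  D <- config$diff_coeffs                  # fast, intermediate, trapped
  sd_step <- sqrt(2 * D * dt)
  p_bleach <- if (is.finite(mean_track_len)) 1 / (mean_track_len - 1) else 0
  life_frames <- function(s) ifelse(is.finite(s), pmax(1, round(s / dt)), Inf)

  with_seed(seed, {
    dom <- copy(config$intermediate)
    sub <- copy(config$immobile)
    dom[, `:=`(born = 1L, expires = life_frames(lifetime), gen = .I)]
    if (nrow(sub)) sub[, gen := dom$gen[parent]]
    history <- list(copy(dom))

    next_id <- n_init + 1L
    id <- seq_len(n_init)
    x <- runif(n_init, 0, L); y <- runif(n_init, 0, L)
    trapped <- rep(FALSE, n_init)
    trap_sub <- rep(NA_integer_, n_init)   # row of `sub` holding the particle

    rec <- vector("list", n_frames)
    region_of <- function(x, y, trapped) {
      reg <- rep(1L, length(x))
      if (nrow(dom)) {
        for (j in seq_len(nrow(dom))) {
          inside <- (x - dom$x[j])^2 + (y - dom$y[j])^2 <=
            (dom$diameter[j] / 2)^2
          reg[inside] <- 2L
        }
      }
      reg[trapped] <- 3L
      reg
    }

    for (f in seq_len(n_frames)) {
      # domain turnover: expired domains replaced at fresh positions
      expired <- which(f > dom$expires)
      if (length(expired)) {
        for (j in expired) {
          # release anyone trapped in a subdomain of the dying domain
          dying_sub <- which(sub$parent == j)
          freed <- trap_sub %in% dying_sub
          trapped[freed] <- FALSE
          trap_sub[freed] <- NA_integer_
          g <- max(dom$gen, if (nrow(sub)) sub$gen else 0L) + 1L
          dom$x[j] <- runif(1, 0, L); dom$y[j] <- runif(1, 0, L)
          dom$born[j] <- f
          dom$expires[j] <- f + life_frames(dom$lifetime[j]) - 1L
          dom$gen[j] <- g
          for (s_j in dying_sub) {
            sub$x[s_j] <- dom$x[j]; sub$y[s_j] <- dom$y[j]
            sub$gen[s_j] <- g
          }
        }
        history[[length(history) + 1L]] <- copy(dom)
      }

      n <- length(id)
      if (n) {
        reg <- region_of(x, y, trapped)
        rec[[f]] <- data.table(frame = f, traj_id = id, x = x, y = y,
                               state = reg)

        # move
        stp <- sd_step[reg]
        nx <- x + rnorm(n, sd = stp)
        ny <- y + rnorm(n, sd = stp)
        # trapped particles reflect at their subdomain boundary
        tr <- which(trapped)
        if (length(tr)) {
          cx <- sub$x[trap_sub[tr]]; cy <- sub$y[trap_sub[tr]]
          Rr <- sub$diameter[trap_sub[tr]] / 2
          ddx <- nx[tr] - cx; ddy <- ny[tr] - cy
          rr <- sqrt(ddx^2 + ddy^2)
          out <- rr > Rr
          if (any(out)) {
            # radial fold-back: r -> 2R - r (clamped inside)
            newr <- pmax(0, pmin(2 * Rr[out] - rr[out], Rr[out] * 0.999))
            sc <- ifelse(rr[out] > 0, newr / rr[out], 0)
            nx[tr][out] <- cx[out] + ddx[out] * sc
            ny[tr][out] <- cy[out] + ddy[out] * sc
          }
        }
        # reflecting field boundary
        nx <- abs(nx); nx <- L - abs(L - nx)
        ny <- abs(ny); ny <- L - abs(L - ny)
        x <- nx; y <- ny

        # escape / trapping transitions
        if (length(tr)) {
          esc <- tr[runif(length(tr)) < config$escape_prob]
          trapped[esc] <- FALSE
          trap_sub[esc] <- NA_integer_
        }
        if (nrow(sub)) {
          # immobilization sites are reached through the intermediate zone:
          # only molecules already inside a domain (region N) can be trapped
          free <- which(!trapped & reg == 2L)
          if (length(free)) {
            for (s_j in seq_len(nrow(sub))) {
              inside <- (x[free] - sub$x[s_j])^2 + (y[free] - sub$y[s_j])^2 <=
                (sub$diameter[s_j] / 2)^2
              cand <- free[inside]
              if (length(cand)) {
                hit <- cand[runif(length(cand)) < config$trap_prob]
                trapped[hit] <- TRUE
                trap_sub[hit] <- s_j
              }
              free <- free[!inside]
              if (!length(free)) break
            }
          }
        }

        # removal: sink (trapped only) and photobleaching
        u_sink <- runif(n)
        gone_sink <- trapped & u_sink < config$sink_prob
        gone_bleach <- runif(n) < p_bleach
        keep <- !(gone_sink | gone_bleach)
        id <- id[keep]; x <- x[keep]; y <- y[keep]
        trapped <- trapped[keep]; trap_sub <- trap_sub[keep]
      }

      # source: new fast molecules
      if (config$source_rate > 0) {
        n_new <- rpois(1, config$source_rate)
        if (n_new > 0) {
          id <- c(id, seq.int(next_id, next_id + n_new - 1L))
          next_id <- next_id + n_new
          x <- c(x, runif(n_new, 0, L))
          y <- c(y, runif(n_new, 0, L))
          trapped <- c(trapped, rep(FALSE, n_new))
          trap_sub <- c(trap_sub, rep(NA_integer_, n_new))
        }
      }
    }

    tk <- rbindlist(rec)
    setorder(tk, traj_id, frame)
    tk[, n_pos := .N, by = traj_id]
    tk <- tk[n_pos >= 2L][, n_pos := NULL]
    # per-step ground truth: region at the step start; NA on last row
    tk[, true_state := {
      s <- state
      s[.N] <- NA_integer_
      s
    }, by = traj_id]
    tk[, state := NULL]
    trajs <- trajectory_set(tk, frame_interval = dt, field_size = L)
    list(trajs = trajs,
         domain_history = rbindlist(history, idcol = "epoch"))
  })
}
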