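#' Parameters for the semi-Markov locomotion simulator
#'
#' The simulator generates single-fly sessions from a two-state semi-Markov
#' model: the fly alternates residences in ROSA and NoSA with independently
#' drawn durations (exponential by default), and within each residence its
#' position follows a correlated random walk confined to that zone. The
#' residence-time-driven design makes bout statistics analytically
#' controllable — mean bout duration, mean away time and the stationary
#' occupancy fraction `mean_bout / (mean_bout + mean_away)` are direct
#' consequences of the parameters — so pipeline output can be checked
#' against known generative values. `port_drift` shapes the within-zone
#' path (and hence the depth metric) without disturbing the bout law.
#'
#' @param fps Frame rate, default 15.
#' @param duration_s Session length in seconds, default 900 (15 min).
#' @param geometry An [arena_geometry()].
#' @param mean_bout_s Mean ROSA residence duration (s).
#' @param mean_away_s Mean NoSA residence duration (s).
#' @param residence Residence duration family: `"exponential"` (default,
#'   memoryless) or `"gamma"` (shape `gamma_shape`, for non-memoryless
#'   latency behavior).
#' @param gamma_shape Shape for the gamma family, default 2.
#' @param speed_mean,speed_sd Per-frame step speed distribution
#'   (units/second, normal truncated at 0).
#' @param turn_concentration Heading-persistence parameter of the correlated
#'   random walk; per-frame turning angles are normal with SD
#'   `1/sqrt(turn_concentration)` radians.
#' @param port_drift Scalar in `[-1, 1]` biasing movement along the long
#'   axis toward (positive) or away from (negative) the current zone's port.
#' @param wall_margin Confinement inset (units) keeping the body center off
#'   walls and the zone boundary, default 0.5.
#' @return A `sim_params` list.
#' @export
sim_params <- function(fps = 15, duration_s = 900,
                       geometry = arena_geometry(),
                       mean_bout_s = 10, mean_away_s = 10,
                       residence = c("exponential", "gamma"),
                       gamma_shape = 2,
                       speed_mean = 1, speed_sd = 0.5,
                       turn_concentration = 4, port_drift = 0,
                       wall_margin = 0.5) {
  residence <- match.arg(residence)
  stopifnot(fps > 0, duration_s > 0, mean_bout_s > 0, mean_away_s > 0,
            speed_mean >= 0, speed_sd >= 0, turn_concentration > 0,
            gamma_shape > 0)
  if (abs(port_drift) > 1) stop("`port_drift` must lie in [-1, 1]")
  g <- geometry
  lo_zone <- min(g$boundary, g$length - g$boundary)
  if (lo_zone <= 2 * wall_margin || g$width <= 2 * wall_margin)
    stop("degenerate geometry: a zone is too small for the wall margin")
  structure(
    list(fps = fps, duration_s = duration_s, geometry = g,
         mean_bout_s = mean_bout_s, mean_away_s = mean_away_s,
         residence = residence, gamma_shape = gamma_shape,
         speed_mean = speed_mean, speed_sd = speed_sd,
         turn_concentration = turn_concentration, port_drift = port_drift,
         wall_margin = wall_margin),
    class = "sim_params")
}

#' Valence presets for the simulator
#'
#' Named parameter sets encoding the qualitative behavioral contrasts
#' between stimulus valences: an appetitive stimulus elicits fewer but
#' longer self-administration bouts, short latencies to re-enter and deep
#' port approach; an aversive one elicits more frequent but shorter bouts,
#' long latencies and shallow penetration; neutral is symmetric.
#'
#' Preset values: appetitive `mean_bout_s = 20`, `mean_away_s = 8`,
#' `port_drift = 0.6`; aversive `mean_bout_s = 5`, `mean_away_s = 15`,
#' `port_drift = -0.6`; neutral `10 / 10 / 0`.
#'
#' @param name `"appetitive"`, `"aversive"` or `"neutral"`.
#' @param ... Overrides passed on to [sim_params()].
#' @return A `sim_params`.
#' @export
valence_preset <- function(name = c("appetitive", "aversive", "neutral"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    appetitive = list(mean_bout_s = 20, mean_away_s = 8, port_drift = 0.6),
    aversive   = list(mean_bout_s = 5, mean_away_s = 15, port_drift = -0.6),
    neutral    = list(mean_bout_s = 10, mean_away_s = 10, port_drift = 0))
  over <- list(...)
  base[names(over)] <- over
  do.call(sim_params, base)
}

# fold values into [lo, hi] by reflection (triangle wave)
fold_reflect <- function(v, lo, hi) {
  r <- hi - lo
  y <- (v - lo) %% (2 * r)
  lo + ifelse(y > r, 2 * r - y, y)
}

draw_residence <- function(n, mean_s, p) {
  if (p$residence == "exponential") stats::rexp(n, rate = 1 / mean_s)
  else stats::rgamma(n, shape = p$gamma_shape,
                     scale = mean_s / p$gamma_shape)
}

#' Simulate one single-fly session
#'
#' Draws an alternating ROSA/NoSA residence schedule (first zone chosen with
#' the stationary probability `mean_bout / (mean_bout + mean_away)`, so with
#' exponential residences the expected occupancy fraction equals the
#' stationary fraction at any session length), then fills each residence
#' with a correlated random walk confined to the zone: normal turning
#' angles, truncated-normal speeds, a `port_drift` bias along the long axis,
#' and reflecting walls (coordinates folded back into the zone box inset by
#' `wall_margin`). Zone transitions place the fly just across the boundary
#' by one step. With a degenerate zero-speed parameterization the fly
#' cannot execute transitions: it stays put and the session is a single
#' truncated bout in the starting zone.
#'
#' @param params A [sim_params()].
#' @param seed Integer seed; identical `(params, seed)` give bit-identical
#'   output.
#' @param fly_id Identifier for the generated trajectory.
#' @return List with `trajectory` (a [trajectory()]), `occupancy`
#'   (ground-truth `occupancy_series`), and `bouts` (ground-truth ROSA bout
#'   table in [segment_bouts()] layout).
#' @export
simulate_session <- function(params, seed = 1, fly_id = "sim") {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  g <- p$geometry
  set.seed(seed)
  n <- as.integer(round(p$duration_s * p$fps))
  m <- p$wall_margin
  rosa_high <- g$rosa_side == "high"
  # zone boxes along the long axis, inset by the wall margin
  box <- function(zone) {                # zone: 1 = ROSA, 0 = NoSA
    if ((zone == 1) == rosa_high) c(g$boundary + m, g$length - m)
    else c(m, g$boundary - m)
  }
  frozen <- p$speed_mean <= 0 && p$speed_sd <= 0
  p_rosa <- p$mean_bout_s / (p$mean_bout_s + p$mean_away_s)
  z1 <- as.integer(stats::runif(1) < p_rosa)
  if (frozen) {
    zones <- z1
    res_frames <- n
  } else {
    zones <- integer(0); res_frames <- integer(0); tot <- 0L; z <- z1
    while (tot < n) {
      sec <- draw_residence(1, if (z == 1) p$mean_bout_s else p$mean_away_s, p)
      fr <- max(1L, as.integer(round(sec * p$fps)))
      zones <- c(zones, z); res_frames <- c(res_frames, fr)
      tot <- tot + fr
      z <- 1L - z
    }
    res_frames[length(res_frames)] <- res_frames[length(res_frames)] -
      (tot - n)                                   # truncate at session end
    keep <- res_frames > 0
    zones <- zones[keep]; res_frames <- res_frames[keep]
  }
  score <- rep(zones, res_frames)
  # positions: per-residence correlated random walk with folding confinement
  x <- numeric(n); y <- numeric(n)
  b0 <- box(zones[1])
  pos <- c(stats::runif(1, b0[1], b0[2]), stats::runif(1, m, g$width - m))
  theta <- stats::runif(1, 0, 2 * pi)
  turn_sd <- 1 / sqrt(p$turn_concentration)
  off <- 0L
  for (k in seq_along(zones)) {
    nk <- res_frames[k]
    bk <- box(zones[k])
    if (k > 1 && !frozen) {
      # teleport across the boundary by one step into the new zone
      step <- abs(stats::rnorm(1, p$speed_mean, p$speed_sd)) / p$fps
      inner <- if (bk[1] > g$boundary) bk[1] else bk[2]   # edge nearest boundary
      dir <- if (bk[1] > g$boundary) 1 else -1
      pos[1] <- fold_reflect(inner + dir * step, bk[1], bk[2])
    }
    if (frozen) {
      xk <- rep(pos[1], nk); yk <- rep(pos[2], nk)
    } else {
      turns <- stats::rnorm(nk, 0, turn_sd)
      th <- theta + cumsum(turns)
      sp <- pmax(0, stats::rnorm(nk, p$speed_mean, p$speed_sd)) / p$fps
      # drift along the long axis toward (or away from) the zone's port
      port <- if (zones[k] == 1) g$rosa_port else g$nosa_port
      axis_dir <- sign(port[1] - mean(bk))
      if (axis_dir == 0) axis_dir <- 1
      dx <- (1 - abs(p$port_drift)) * sp * cos(th) +
        p$port_drift * axis_dir * (p$speed_mean / p$fps)
      dy <- (1 - abs(p$port_drift)) * sp * sin(th)
      xk <- fold_reflect(pos[1] + cumsum(dx), bk[1], bk[2])
      yk <- fold_reflect(pos[2] + cumsum(dy), m, g$width - m)
      theta <- th[nk]
    }
    idx <- off + seq_len(nk)
    x[idx] <- xk; y[idx] <- yk
    pos <- c(xk[nk], yk[nk])
    off <- off + nk
  }
  traj <- trajectory(
    data.frame(frame = 0:(n - 1L), x = x, y = y),
    fps = p$fps, fly_id = fly_id,
    meta = list(simulated = TRUE, seed = seed))
  occ <- structure(
    list(score = score, imputed = rep(FALSE, n), fps = p$fps, fly_id = fly_id),
    class = "occupancy_series")
  # ground-truth ROSA bouts straight from the residence schedule
  ends <- cumsum(res_frames)
  starts <- ends - res_frames + 1L
  rosa <- zones == 1L
  bouts <- data.frame(
    region = "ROSA",
    entry_frame = starts[rosa] - 1L,
    exit_frame = ends[rosa],
    truncated = ends[rosa] == n)
  bouts$initial <- bouts$entry_frame == 0L
  bouts$duration_s <- (bouts$exit_frame - bouts$entry_frame) / p$fps
  bouts <- bouts[, c("region", "entry_frame", "exit_frame", "duration_s",
                     "truncated", "initial")]
  rownames(bouts) <- NULL
  list(trajectory = traj, occupancy = occ, bouts = bouts)
}

#' Simulate a cohort of sessions
#'
#' Convenience wrapper: one [simulate_session()] per fly with seeds
#' `seed + 0:(n-1)`.
#'
#' @param n Number of flies.
#' @param params A [sim_params()].
#' @param seed Base seed.
#' @param id_prefix Fly id prefix.
#' @return List of session lists.
#' @export
simulate_cohort <- function(n, params, seed = 1, id_prefix = "sim") {
  lapply(seq_len(n), function(i)
    simulate_session(params, seed = seed + i - 1L,
                     fly_id = sprintf("%s%03d", id_prefix, i)))
}
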