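#' Session behaviors for one region
#'
#' The three session behaviors summarize a whole 15-min session in one
#' region: total time spent, total distance moved while there, and the
#' maximum depth reached toward the region's port.
#'
#' * `total_time` = (frames in region) / fps.
#' * `total_distance` = sum of Euclidean step lengths over steps whose
#'   destination frame is in the region; steps touching invalid or imputed
#'   frames contribute 0 (held positions must not fabricate movement).
#' * `max_depth` = maximum over region frames of [depth_toward_port()];
#'   0 if the fly never entered.
#'
#' @param traj A [trajectory()].
#' @param occ Matching `occupancy_series`.
#' @param g An [arena_geometry()].
#' @param region `"ROSA"` or `"NoSA"`.
#' @return Named list: `total_time`, `total_distance`, `max_depth`.
#' @export
session_metrics <- function(traj, occ, g, region = c("ROSA", "NoSA")) {
  region <- match.arg(region)
  fr <- traj$frames
  if (nrow(fr) != length(occ$score))
    stop("trajectory and occupancy series have different lengths")
  target <- if (region == "ROSA") 1L else 0L
  in_reg <- occ$score == target
  total_time <- sum(in_reg) / traj$fps
  steps <- step_lengths(fr)
  dest <- in_reg[-1]
  total_distance <- sum(steps[dest], na.rm = TRUE)
  depth_frames <- in_reg & fr$valid & !fr$imputed
  max_depth <- if (any(depth_frames)) {
    max(depth_toward_port(fr$x[depth_frames], g, region, y = fr$y[depth_frames]))
  } else 0
  list(total_time = total_time, total_distance = total_distance,
       max_depth = max_depth)
}

# Euclidean length of each frame-to-frame step (length n-1); steps whose
# either endpoint is invalid or imputed are 0.
step_lengths <- function(fr) {
  n <- nrow(fr)
  if (n < 2) return(numeric(0))
  ok <- fr$valid & !fr$imputed
  d <- sqrt(diff(fr$x)^2 + diff(fr$y)^2)
  d[!(ok[-n] & ok[-1])] <- 0
  d[is.na(d)] <- 0
  d
}

#' Bout behaviors for one region
#'
#' Counts and arithmetic means of the per-bout quantities: number of
#' entries (bouts), mean bout duration, mean bout distance, and mean latency
#' to re-enter. Means are undefined (`NA`), never zero, when their
#' denominator is empty — a fly with no bouts must not deflate group
#' averages.
#'
#' @param bouts Bout table for one region (see [annotate_bouts()] for
#'   distance).
#' @param latencies From [latencies_to_reenter()].
#' @return Named list: `n_bouts`, `mean_bout_duration`,
#'   `mean_bout_distance`, `mean_latency`.
#' @export
bout_metrics <- function(bouts, latencies = numeric(0)) {
  n <- nrow(bouts)
  list(
    n_bouts = n,
    mean_bout_duration = if (n > 0) mean(bouts$duration_s) else NA_real_,
    mean_bout_distance = if (n > 0 && "distance" %in% names(bouts))
      mean(bouts$distance) else NA_real_,
    mean_latency = if (length(latencies) > 0) mean(latencies) else NA_real_)
}

#' Add per-bout distance and maximum depth to a bout table
#'
#' Distance uses the same destination-frame step attribution as
#' [session_metrics()], restricted to each bout's frame range; max depth is
#' the deepest penetration toward the region's port during the bout.
#'
#' @param bouts From [segment_bouts()].
#' @param traj,g Matching trajectory and geometry.
#' @return The bout table with `entry_s`, `exit_s`, `distance`, `max_depth`
#'   columns added.
#' @export
annotate_bouts <- function(bouts, traj, g) {
  fr <- traj$frames
  steps <- c(0, step_lengths(fr))   # steps[i] = step landing on frame i
  n <- nrow(bouts)
  dist <- numeric(n)
  dep <- numeric(n)
  for (i in seq_len(n)) {
    idx <- (bouts$entry_frame[i] + 1L):bouts$exit_frame[i]  # 1-based rows
    dist[i] <- sum(steps[idx[-1]])
    ok <- idx[fr$valid[idx] & !fr$imputed[idx]]
    dep[i] <- if (length(ok))
      max(depth_toward_port(fr$x[ok], g, bouts$region[i], y = fr$y[ok]))
    else 0
  }
  bouts$entry_s <- bouts$entry_frame / traj$fps
  bouts$exit_s <- bouts$exit_frame / traj$fps
  bouts$distance <- dist
  bouts$max_depth <- dep
  bouts
}

#' Histogram of bout durations over occupation-duration categories
#'
#' Half-open bins `[e_i, e_{i+1})` over the supplied edges plus a terminal
#' open bin `[e_last, Inf)`; counts sum to the number of bouts. Default
#' edges every 5 s from 0 to 30 s, matching the usual occupation duration
#' categories.
#'
#' @param bouts Bout table (or numeric vector of durations in seconds).
#' @param edges Strictly increasing numeric vector of bin edges.
#' @return Named integer vector of counts.
#' @export
duration_histogram <- function(bouts, edges = seq(0, 30, by = 5)) {
  if (is.unsorted(edges, strictly = TRUE)) stop("`edges` must be strictly increasing")
  dur <- if (is.data.frame(bouts)) bouts$duration_s else as.numeric(bouts)
  if (any(dur < edges[1])) stop("bout duration below the first edge")
  # half-open [e_i, e_{i+1}) bins plus terminal [e_last, Inf)
  h <- tabulate(findInterval(dur, edges), nbins = length(edges))
  names(h) <- c(paste0("[", edges[-length(edges)], ",", edges[-1], ")"),
                paste0("[", edges[length(edges)], ",Inf)"))
  h
}

#' Preference index
#'
#' `PI = (time_ROSA - time_NoSA) / (time_ROSA + time_NoSA)`, computed over
#' the preference window (by convention the last seven minutes of tracking).
#' Positive values indicate ROSA preference. `preference_index()` applies
#' the formula to two times; [pi_from_occupancy()] extracts the windowed
#' times from an occupancy series first.
#'
#' @param time_rosa,time_nosa Times in seconds, both >= 0.
#' @return PI in `[-1, 1]`, or `NA` when both times are zero.
#' @export
preference_index <- function(time_rosa, time_nosa) {
  if (any(time_rosa < 0 | time_nosa < 0, na.rm = TRUE))
    stop("times must be non-negative")
  tot <- time_rosa + time_nosa
  ifelse(tot > 0, (time_rosa - time_nosa) / tot, NA_real_)
}

#' @rdname preference_index
#' @param occ An `occupancy_series`.
#' @param window Half-open time window `c(start_s, end_s)`; default the last
#'   seven minutes of a 15-min session, `[480, 900)`.
#' @export
pi_from_occupancy <- function(occ, window = c(480, 900)) {
  stopifnot(length(window) == 2, window[2] > window[1])
  i <- seq_along(occ$score) - 1L           # 0-based frames
  t <- i / occ$fps
  sel <- t >= window[1] & t < window[2]
  if (!any(sel)) return(NA_real_)
  r <- sum(occ$score[sel]) / occ$fps
  n <- sum(sel) / occ$fps - r
  preference_index(r, n)
}

#' Operant learning index
#'
#' `OLI = (late - early) / (late + early)` comparing a behavioral metric in
#' ROSA at the end versus the beginning of the session. "At 14 min" and
#' "at 1 min" are read as the 1-minute bins `[780, 840)` and `[0, 60)`:
#' the metrics are extensive (time, distance), so per-bin totals are the
#' consistent reading of the instantaneous phrasing. Equal bins give 0; two
#' zero bins give `NA` (undefined, excluded from aggregation).
#'
#' @param late,early Metric values in the late and early bin. Must be >= 0
#'   for time/distance; depth uses the per-bin maximum clipped at 0, which
#'   [metric_time_series()] produces already.
#' @return OLI in `[-1, 1]` or `NA`.
#' @export
operant_learning_index <- function(late, early) {
  if (any(late < 0 | early < 0, na.rm = TRUE))
    stop("operant learning index inputs must be non-negative")
  tot <- late + early
  ifelse(tot > 0, (late - early) / tot, NA_real_)
}

#' Per-minute metric time series in ROSA
#'
#' Per-bin value of a session behavior across the session, over half-open
#' 1-indexed bins (bin k covers `[(k-1)*b, k*b)` seconds):
#' * `time`: seconds spent in the region per bin (sums to the session
#'   total).
#' * `distance`: distance moved in the region per bin (destination-frame
#'   step attribution; sums to the session total).
#' * `depth`: maximum depth toward the region's port reached in the bin,
#'   0 if the region was not visited in that bin (`depth_stat = "mean"`
#'   averages over region frames instead).
#'
#' @param traj,occ,g Aligned trajectory, occupancy and geometry.
#' @param metric `"time"`, `"distance"` or `"depth"`.
#' @param bin_seconds Bin width, default 60.
#' @param region `"ROSA"` (default) or `"NoSA"`.
#' @param depth_stat `"max"` (default, matches the session definition of
#'   maximum depth) or `"mean"`.
#' @return Numeric vector, one value per bin; attribute `"partial"` flags an
#'   incomplete final bin.
#' @export
metric_time_series <- function(traj, occ, g,
                               metric = c("time", "distance", "depth"),
                               bin_seconds = 60,
                               region = c("ROSA", "NoSA"),
                               depth_stat = c("max", "mean")) {
  metric <- match.arg(metric)
  region <- match.arg(region)
  depth_stat <- match.arg(depth_stat)
  fr <- traj$frames
  n <- nrow(fr)
  if (n != length(occ$score)) stop("misaligned trajectory and occupancy")
  target <- if (region == "ROSA") 1L else 0L
  in_reg <- occ$score == target
  bpf <- bin_seconds * traj$fps
  bin <- floor((seq_len(n) - 1L) / bpf)
  nbins <- max(bin) + 1L
  out <- numeric(nbins)
  if (metric == "time") {
    agg <- rowsum(as.numeric(in_reg), bin, reorder = TRUE) / traj$fps
    out[as.integer(rownames(agg)) + 1L] <- agg
  } else if (metric == "distance") {
    steps <- c(0, step_lengths(fr))
    w <- ifelse(in_reg, steps, 0)
    agg <- rowsum(w, bin, reorder = TRUE)
    out[as.integer(rownames(agg)) + 1L] <- agg
  } else {
    ok <- in_reg & fr$valid & !fr$imputed
    if (any(ok)) {
      d <- depth_toward_port(fr$x[ok], g, region, y = fr$y[ok])
      f <- if (depth_stat == "max") max else mean
      agg <- tapply(d, bin[ok], f)
      out[as.integer(names(agg)) + 1L] <- agg
    }
    out <- pmax(out, 0)
  }
  partial <- logical(nbins)
  partial[nbins] <- (n %% bpf) != 0
  attr(out, "partial") <- partial
  out
}

#' Full metrics record for one fly and one region
#'
#' Runs the whole per-fly analysis — occupancy, bouts, session and bout
#' behaviors, duration histogram, preference index and operant learning
#' indices — and returns one tidy row. The PI is always the ROSA preference
#' (a fly-level index), whichever region the row describes; the operant
#' learning indices compare the late bin (minute 14, `[780, 840)`) to the
#' early bin (minute 1, `[0, 60)`) of the row's region.
#'
#' @param traj A repaired [trajectory()].
#' @param g An [arena_geometry()].
#' @param region `"ROSA"` (default) or `"NoSA"`.
#' @param pi_window Preference window, default `c(480, 900)`.
#' @param oli_bins 1-indexed `(early, late)` minute bins for the learning
#'   indices, default `c(1, 14)`.
#' @param bin_seconds Bin width for the per-minute series, default 60.
#' @param hist_edges Duration-category edges, default `seq(0, 30, 5)`.
#' @param min_bout_frames Passed to [segment_bouts()].
#' @return A one-row data frame (a `MetricsRecord`): identifiers, session
#'   behaviors, bout behaviors, histogram counts, `preference_index`,
#'   `oli_time`, `oli_distance`, `oli_depth`.
#' @export
fly_metrics <- function(traj, g, region = c("ROSA", "NoSA"),
                        pi_window = c(480, 900), oli_bins = c(1, 14),
                        bin_seconds = 60, hist_edges = seq(0, 30, by = 5),
                        min_bout_frames = 1) {
  region <- match.arg(region)
  occ <- occupancy_from_trajectory(traj, g)
  bouts <- segment_bouts(occ, region, min_bout_frames = min_bout_frames)
  bouts <- annotate_bouts(bouts, traj, g)
  lat <- latencies_to_reenter(bouts, traj$fps)
  sm <- session_metrics(traj, occ, g, region)
  bm <- bout_metrics(bouts, lat)
  hist <- duration_histogram(bouts, hist_edges)
  oli_of <- function(metric) {
    ts <- metric_time_series(traj, occ, g, metric, bin_seconds, region)
    if (max(oli_bins) > length(ts)) return(NA_real_)
    operant_learning_index(ts[oli_bins[2]], ts[oli_bins[1]])
  }
  row <- data.frame(
    fly_id = traj$fly_id, region = region,
    total_time = sm$total_time, total_distance = sm$total_distance,
    max_depth = sm$max_depth,
    n_bouts = bm$n_bouts, mean_bout_duration = bm$mean_bout_duration,
    mean_bout_distance = bm$mean_bout_distance, mean_latency = bm$mean_latency,
    preference_index = pi_from_occupancy(occ, pi_window),
    oli_time = oli_of("time"), oli_distance = oli_of("distance"),
    oli_depth = oli_of("depth"),
    stringsAsFactors = FALSE)
  hm <- as.data.frame(as.list(hist))
  names(hm) <- paste0("bouts_", gsub("[^0-9A-Za-z]+", "_", names(hist)))
  names(hm) <- sub("_$", "", names(hm))
  cbind(row, hm)
}
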