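#' Per-frame Boolean ROSA occupancy from a trajectory
#'
#' Recomputes the Boolean Occupation Score from geometry: 1 when the fly is
#' in ROSA, 0 in NoSA, for every frame. Invalid frames carry the last valid
#' frame's value (frames before the first valid one carry the first valid
#' value) and are flagged imputed. If the trajectory carries a stored
#' occupation column from the acquisition and it disagrees with the
#' recomputed score on at least 1% of comparable frames, a warning is
#' emitted — the hardware region of interest and the analysis region must be
#' auditable against one definition.
#'
#' @param traj A [trajectory()] (usually after [repair_gaps()]).
#' @param g An [arena_geometry()].
#' @return An `occupancy_series`: list with `score` (integer 0/1 per frame),
#'   `imputed` (logical), `fps`, `fly_id`.
#' @export
occupancy_from_trajectory <- function(traj, g) {
  stopifnot(inherits(traj, "fly_trajectory"), inherits(g, "arena_geometry"))
  fr <- traj$frames
  ok <- fr$valid
  if (!any(ok)) stop("cannot compute occupancy: all frames invalid")
  check_inside(fr$x[ok], fr$y[ok], g, frame = fr$frame[ok])
  score <- rep(NA_integer_, nrow(fr))
  score[ok] <- as.integer(region_mask(fr$x[ok], g))
  filled <- fill_hold(score)
  occ <- structure(
    list(score = filled, imputed = is.na(score) | fr$imputed,
         fps = traj$fps, fly_id = traj$fly_id),
    class = "occupancy_series")
  stored <- traj$meta$stored_occupation
  if (!is.null(stored) && length(stored) == length(filled)) {
    comp <- ok & !fr$imputed & !is.na(stored)
    if (any(comp)) {
      frac <- mean(stored[comp] != filled[comp])
      if (frac >= 0.01)
        warning(sprintf(
          "stored occupation column disagrees with geometry on %.1f%% of frames (%s)",
          100 * frac, traj$fly_id))
    }
  }
  occ
}

# last-observation-carried-forward, then backfill the leading NAs
fill_hold <- function(v) {
  n <- length(v)
  ok <- !is.na(v)
  idx <- cummax(ifelse(ok, seq_len(n), 0L))
  first <- which(ok)[1]
  idx[idx == 0L] <- first
  v[idx]
}

#' @export
print.occupancy_series <- function(x, ...) {
  cat(sprintf("<occupancy_series> %s: %d frames @ %g fps, ROSA fraction %.3f\n",
              x$fly_id, length(x$score), x$fps, mean(x$score)))
  invisible(x)
}

#' Time-binned averaged occupation score
#'
#' Mean of the per-frame Boolean Occupation Score over half-open time bins
#' `[k*b, (k+1)*b)`: the number of ROSA frames divided by the frames in the
#' bin. A final partial bin is kept and flagged via the `"partial"`
#' attribute.
#'
#' @param occ An `occupancy_series`.
#' @param bin_seconds Bin width in seconds (> 0); 60 by default, 30 also
#'   common.
#' @return Numeric vector of per-bin scores in `[0, 1]`; attribute
#'   `"partial"` is a logical marking an incomplete final bin.
#' @export
binned_occupation_score <- function(occ, bin_seconds = 60) {
  stopifnot(inherits(occ, "occupancy_series"), bin_seconds > 0)
  n <- length(occ$score)
  if (n == 0) stop("empty occupancy series")
  bpf <- bin_seconds * occ$fps
  bin <- floor((seq_len(n) - 1L) / bpf)         # 0-based bin of each frame
  counts <- tabulate(bin + 1L)
  sums <- as.numeric(rowsum(as.numeric(occ$score), bin, reorder = TRUE))
  out <- sums / counts
  partial <- logical(length(out))
  partial[length(out)] <- counts[length(counts)] < bpf
  attr(out, "partial") <- partial
  out
}

#' Segment an occupancy series into entry-to-exit bouts
#'
#' A bout is one maximal run of residence in a region — a single instance of
#' entering and subsequently exiting. Runs shorter than `min_bout_frames`
#' are discarded (default 1: keep everything — the assay reports no minimum
#' bout duration, and short bouts are informative; raise the knob only for
#' noisy trackers). A run still open at session end is returned with
#' `truncated = TRUE`: it counts toward bout number and duration (the
#' stimulus was experienced) but contributes no re-entry latency.
#'
#' Entries use destination-frame attribution: the bout starts at the first
#' frame whose position is in the region, and a fly already in the region at
#' frame 0 starts a bout at t = 0 (set `include_initial = FALSE` to drop a
#' session-start residence from the count).
#'
#' @param occ An `occupancy_series`.
#' @param region `"ROSA"` or `"NoSA"`.
#' @param min_bout_frames Minimum run length (frames) to keep, >= 1.
#' @param include_initial Keep a bout already in progress at frame 0?
#'   Default `TRUE`.
#' @return Data frame with `region`, `entry_frame`, `exit_frame` (exclusive,
#'   0-based half-open `[entry, exit)`), `duration_s`, `truncated`,
#'   `initial` (was in progress at frame 0).
#' @export
segment_bouts <- function(occ, region = c("ROSA", "NoSA"),
                          min_bout_frames = 1, include_initial = TRUE) {
  region <- match.arg(region)
  stopifnot(inherits(occ, "occupancy_series"), min_bout_frames >= 1)
  target <- if (region == "ROSA") 1L else 0L
  member <- occ$score == target
  r <- rle(member)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_bout_frames
  b <- data.frame(
    region = region,
    entry_frame = starts[keep] - 1L,           # 0-based
    exit_frame = ends[keep],                   # exclusive
    truncated = ends[keep] == length(member))
  b$initial <- b$entry_frame == 0L
  if (!include_initial) b <- b[!b$initial, , drop = FALSE]
  b$duration_s <- (b$exit_frame - b$entry_frame) / occ$fps
  rownames(b) <- NULL
  b[, c("region", "entry_frame", "exit_frame", "duration_s",
        "truncated", "initial")]
}

#' Latencies to re-enter a region after exiting
#'
#' For each consecutive pair of same-region bouts, the time between the exit
#' of one and the entry of the next. The final bout has no successor and
#' contributes nothing; a truncated final bout likewise.
#'
#' @param bouts Ordered bout table from [segment_bouts()] (one region).
#' @param fps Frame rate.
#' @return Numeric vector of latencies in seconds (empty for < 2 bouts).
#' @export
latencies_to_reenter <- function(bouts, fps) {
  n <- nrow(bouts)
  if (is.null(n) || n < 2) return(numeric(0))
  if (length(unique(bouts$region)) > 1)
    stop("latencies require bouts from a single region")
  (bouts$entry_frame[-1] - bouts$exit_frame[-n]) / fps
}

#' Occupancy heat-map matrix (fly x time bin)
#'
#' Stacks the per-fly binned occupation scores into the matrix plotted as an
#' occupancy heat map (one row per fly, one column per time bin; high scores
#' mean ROSA residence). Rows keep input order unless `sort_by` is given.
#'
#' @param occs List of `occupancy_series` with identical fps and duration.
#' @param bin_seconds Bin width, default 60 s.
#' @param sort_by Optional numeric key (one per fly) to order rows by,
#'   decreasing.
#' @param allow_partial Allow series whose length is not a multiple of the
#'   bin (the ragged final bin is still averaged)? Default `FALSE`: with
#'   heterogeneous inputs the caller must opt in explicitly.
#' @return Numeric matrix, rownames = fly ids.
#' @export
heatmap_matrix <- function(occs, bin_seconds = 60, sort_by = NULL,
                           allow_partial = FALSE) {
  stopifnot(length(occs) >= 1)
  fps <- vapply(occs, function(o) o$fps, numeric(1))
  len <- vapply(occs, function(o) length(o$score), numeric(1))
  if (length(unique(fps)) > 1 || length(unique(len)) > 1)
    stop("heatmap requires series with identical fps and duration")
  if (!allow_partial && len[1] %% (bin_seconds * fps[1]) != 0)
    stop("series length is not a whole number of bins; ",
         "set allow_partial = TRUE to keep the ragged final bin")
  rows <- lapply(occs, binned_occupation_score, bin_seconds = bin_seconds)
  m <- do.call(rbind, lapply(rows, as.numeric))
  rownames(m) <- vapply(occs, function(o) o$fly_id, character(1))
  if (!is.null(sort_by)) m <- m[order(sort_by, decreasing = TRUE), , drop = FALSE]
  m
}

#' Write a bout table CSV
#'
#' One row per bout: fly id, region, entry/exit in seconds, duration,
#' distance, max depth, truncated flag.
#'
#' @param bouts Annotated bout table (see [annotate_bouts()]) with a
#'   `fly_id` column.
#' @param path Output CSV path.
#' @export
write_bout_table <- function(bouts, path) {
  cols <- c("fly_id", "region", "entry_s", "exit_s", "duration_s",
            "distance", "max_depth", "truncated")
  utils::write.csv(bouts[, intersect(cols, names(bouts)), drop = FALSE],
                   path, row.names = FALSE)
  invisible(path)
}
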