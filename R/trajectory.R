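#' Construct a single-fly trajectory
#'
#' A trajectory is the per-frame position record of one fly over one session:
#' a data frame with columns `frame` (0-based, contiguous), `t` (seconds,
#' `frame / fps`), `x`, `y` (physical units; `NA` on invalid frames),
#' `valid` (position usable) and `imputed` (position filled by gap repair,
#' see [repair_gaps()]), plus session metadata.
#'
#' @param frames Data frame with at least `frame`, `x`, `y`; `valid` and
#'   `imputed` are derived if absent.
#' @param fps Frame rate (frames/second, > 0). Default 15.
#' @param fly_id Identifier string.
#' @param meta Named list of free-form condition metadata (stimulus label,
#'   sex, genotype, ATR status, ...).
#' @return An object of class `fly_trajectory`.
#' @export
trajectory <- function(frames, fps = 15, fly_id = "fly", meta = list()) {
  stopifnot(is.data.frame(frames), all(c("frame", "x", "y") %in% names(frames)))
  if (fps <= 0) stop("`fps` must be > 0")
  fr <- as.integer(frames$frame)
  if (anyDuplicated(fr)) stop("duplicate frame indices in trajectory")
  o <- order(fr)
  frames <- frames[o, , drop = FALSE]
  fr <- fr[o]
  if (nrow(frames) == 0) stop("empty trajectory")
  # make the frame stream contiguous from the first index: absent frames
  # become invalid placeholder rows
  full <- seq(fr[1], fr[length(fr)])
  idx <- match(full, fr)
  out <- data.frame(
    frame = full,
    t = full / fps,
    x = frames$x[idx],
    y = frames$y[idx])
  if ("valid" %in% names(frames)) {
    out$valid <- frames$valid[idx] & is.finite(out$x) & is.finite(out$y)
  } else {
    out$valid <- is.finite(out$x) & is.finite(out$y)
  }
  out$valid[is.na(out$valid)] <- FALSE
  out$imputed <- if ("imputed" %in% names(frames)) {
    imp <- frames$imputed[idx]
    imp[is.na(imp)] <- FALSE
    imp
  } else FALSE
  out$x[!out$valid] <- NA_real_
  out$y[!out$valid] <- NA_real_
  rownames(out) <- NULL
  structure(
    list(frames = out, fps = fps, fly_id = fly_id,
         session_duration = nrow(out) / fps, meta = meta),
    class = "fly_trajectory")
}

#' @export
print.fly_trajectory <- function(x, ...) {
  n <- nrow(x$frames)
  cat(sprintf(
    "<fly_trajectory> %s: %d frames @ %g fps (%.1f s), %d invalid, %d imputed\n",
    x$fly_id, n, x$fps, x$session_duration,
    sum(!x$frames$valid), sum(x$frames$imputed)))
  invisible(x)
}

#' Read a per-frame trajectory CSV
#'
#' Reads the per-fly CSV the acquisition produces: one row per frame with the
#' fly position in x/y (plus an optional stored Boolean occupation-score
#' column). Rows with unparseable or absent coordinates become invalid
#' frames. A stored occupation column is never used for analysis — occupancy
#' is always recomputed from geometry (see [occupancy_from_trajectory()]) —
#' but it is retained in `meta$stored_occupation` so the two definitions can
#' be audited against each other.
#'
#' @param path CSV file path.
#' @param fps Frame rate, default 15.
#' @param schema Named character vector mapping the canonical column names
#'   `frame`, `x`, `y` (and optionally `occupation`) to the file's column
#'   names; unmapped names default to themselves.
#' @param fly_id Identifier; defaults to the file name without extension.
#' @param meta Condition metadata list.
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path, fps = 15, schema = NULL, fly_id = NULL,
                            meta = list()) {
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0) stop("empty trajectory file: ", path)
  cols <- c(frame = "frame", x = "x", y = "y", occupation = "occupation")
  if (!is.null(schema)) cols[names(schema)] <- schema
  need <- cols[c("frame", "x", "y")]
  miss <- need[!need %in% names(raw)]
  if (length(miss))
    stop("missing required column(s) in ", path, ": ",
         paste(miss, collapse = ", "))
  if (is.null(fly_id)) fly_id <- sub("\\.[^.]*$", "", basename(path))
  df <- data.frame(
    frame = suppressWarnings(as.integer(raw[[cols["frame"]]])),
    x = suppressWarnings(as.numeric(raw[[cols["x"]]])),
    y = suppressWarnings(as.numeric(raw[[cols["y"]]])))
  if (anyNA(df$frame)) stop("unparseable frame index in ", path)
  if (cols["occupation"] %in% names(raw))
    meta$stored_occupation <- suppressWarnings(
      as.integer(raw[[cols["occupation"]]]))
  trajectory(df, fps = fps, fly_id = fly_id, meta = meta)
}

#' Fill short tracking dropouts by holding the last valid position
#'
#' Runs of at most `max_gap_frames` consecutive invalid frames are filled
#' with the last valid position and marked `imputed`; longer runs, and
#' invalid frames before the first valid one, stay invalid. Valid frames are
#' untouched, so the operation is idempotent. The default of 15 frames (1 s
#' at 15 fps) bridges brief occlusions without fabricating behavior across
#' long tracking losses.
#'
#' @param traj A [trajectory()].
#' @param max_gap_frames Longest gap (frames) to fill, >= 0.
#' @return The repaired trajectory.
#' @export
repair_gaps <- function(traj, max_gap_frames = 15) {
  stopifnot(inherits(traj, "fly_trajectory"), max_gap_frames >= 0)
  fr <- traj$frames
  if (!any(fr$valid)) stop("trajectory has no valid frames")
  if (all(fr$valid)) return(traj)
  r <- rle(fr$valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(!r$values)) {
    if (starts[k] == 1L) next                  # nothing to hold yet
    if (r$lengths[k] > max_gap_frames) next
    i <- starts[k]:ends[k]
    fr$x[i] <- fr$x[starts[k] - 1L]
    fr$y[i] <- fr$y[starts[k] - 1L]
    fr$valid[i] <- TRUE
    fr$imputed[i] <- TRUE
  }
  traj$frames <- fr
  traj
}

#' Write and read a metrics table
#'
#' One tidy CSV row per fly x region holding all session/bout metrics and
#' indices (see [fly_metrics()]). Undefined metrics (for example mean bout
#' statistics when a fly never entered) are written as empty cells and read
#' back as `NA`; the round trip is lossless to floating-point precision.
#'
#' @param records Data frame of metric rows.
#' @param path Output CSV path.
#' @return `path`, invisibly (`write_metrics_table`); the table
#'   (`read_metrics_table`).
#' @export
write_metrics_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  utils::write.csv(format_num_df(records), path, row.names = FALSE,
                   quote = TRUE, na = "")
  invisible(path)
}

#' @rdname write_metrics_table
#' @export
read_metrics_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# print numerics at full precision so write/read round-trips exactly
format_num_df <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      v <- df[[j]]
      s <- vapply(v, function(z)
        if (is.na(z)) NA_character_ else format(z, digits = 17), character(1))
      df[[j]] <- s
    }
  }
  df
}
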