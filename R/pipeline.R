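#' Analyze a set of trajectories into the standard report tables
#'
#' Per-fly analysis over both regions plus the cohort-level products: the
#' tidy metrics table (one row per fly x region), the annotated bout table,
#' the fly x bin occupancy heat-map matrix, and (when enough flies have
#' complete metrics) the PCA valence summary over the six canonical ROSA
#' behavioral metrics (total time, total distance, max depth, entries, mean
#' bout duration, mean latency).
#'
#' @param trajs List of [trajectory()] objects (repaired).
#' @param g An [arena_geometry()].
#' @param pi_window,oli_bins,bin_seconds,hist_edges,min_bout_frames Passed
#'   to [fly_metrics()].
#' @param regions Regions to analyze, default both.
#' @return List with `metrics` (data frame), `bouts` (data frame),
#'   `heatmap` (matrix), `pca` (a `pca_valence` or `NULL`).
#' @export
analyze_cohort <- function(trajs, g, pi_window = c(480, 900),
                           oli_bins = c(1, 14), bin_seconds = 60,
                           hist_edges = seq(0, 30, by = 5),
                           min_bout_frames = 1,
                           regions = c("ROSA", "NoSA")) {
  stopifnot(length(trajs) >= 1)
  metrics <- list(); bout_rows <- list()
  occs <- vector("list", length(trajs))
  for (i in seq_along(trajs)) {
    tr <- trajs[[i]]
    occs[[i]] <- occupancy_from_trajectory(tr, g)
    for (reg in regions) {
      metrics[[length(metrics) + 1L]] <-
        fly_metrics(tr, g, reg, pi_window, oli_bins, bin_seconds,
                    hist_edges, min_bout_frames)
      b <- annotate_bouts(
        segment_bouts(occs[[i]], reg, min_bout_frames = min_bout_frames),
        tr, g)
      if (nrow(b)) {
        b$fly_id <- tr$fly_id
        bout_rows[[length(bout_rows) + 1L]] <- b
      }
    }
  }
  metrics <- do.call(rbind, metrics)
  bouts <- if (length(bout_rows)) do.call(rbind, bout_rows) else
    data.frame()
  hm <- heatmap_matrix(occs, bin_seconds = bin_seconds)
  rosa <- metrics[metrics$region == "ROSA", , drop = FALSE]
  pca_cols <- c("total_time", "total_distance", "max_depth", "n_bouts",
                "mean_bout_duration", "mean_latency")
  pm <- as.matrix(rosa[, pca_cols])
  rownames(pm) <- rosa$fly_id
  pca <- if (sum(stats::complete.cases(pm)) >= 3)
    tryCatch(pca_valence(pm), error = function(e) NULL) else NULL
  list(metrics = metrics, bouts = bouts, heatmap = hm, pca = pca)
}

#' Run the full pipeline from a configuration
#'
#' Orchestrates simulate -> (render -> track) -> analyze -> report as one
#' reproducible run. The configuration is a named list (or YAML/JSON path)
#' with elements:
#'
#' * `mode`: `"simulate"` (default; analyze simulator ground-truth
#'   trajectories) or `"simulate_track"` (render frames and recover
#'   trajectories with the tracker before analysis).
#' * `n_flies`, `seed`, `preset` (or a `params` list for [sim_params()]).
#' * `geometry`: list of [arena_geometry()] arguments (optional).
#' * `analysis`: list of [analyze_cohort()] arguments (optional).
#' * `tracker`: list with `noise_sd`, `blob_sigma` for the rendering stage.
#' * `out_dir`: where to write the report bundle.
#'
#' Outputs: `metrics.csv`, `bouts.csv`, `heatmap.csv`, PCA loadings/scores
#' CSVs, and `manifest.json` recording every parameter, the seed and the
#' package version, so a run re-executed from its manifest reproduces all
#' outputs.
#'
#' @param config Named list or path to a YAML/JSON config file.
#' @return The [analyze_cohort()] result, invisibly, with the manifest
#'   attached as attribute `"manifest"`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  cfg <- utils::modifyList(
    list(mode = "simulate", n_flies = 4, seed = 1, preset = "neutral",
         params = list(), geometry = list(), analysis = list(),
         tracker = list(noise_sd = 2, blob_sigma = 2), out_dir = NULL),
    config)
  g <- do.call(arena_geometry, cfg$geometry)
  params <- do.call(valence_preset,
                    c(list(name = cfg$preset, geometry = g), cfg$params))
  sims <- simulate_cohort(cfg$n_flies, params, seed = cfg$seed)
  trajs <- lapply(sims, `[[`, "trajectory")
  if (cfg$mode == "simulate_track") {
    trajs <- lapply(seq_along(trajs), function(i) {
      stack <- render_frames(trajs[[i]], g,
                             noise_sd = cfg$tracker$noise_sd,
                             blob_sigma = cfg$tracker$blob_sigma)
      repair_gaps(track(stack, g, fly_id = trajs[[i]]$fly_id))
    })
  } else if (cfg$mode != "simulate") {
    stop("unknown pipeline mode: ", cfg$mode)
  }
  res <- do.call(analyze_cohort, c(list(trajs = trajs, g = g), cfg$analysis))
  manifest <- list(
    package = "flyoperant",
    version = as.character(utils::packageVersion("flyoperant")),
    config = cfg[setdiff(names(cfg), "out_dir")],
    sim_params = unclass(params)[setdiff(names(params), "geometry")],
    geometry = unclass(g),
    n_flies = cfg$n_flies, seed = cfg$seed)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(cfg$out_dir, f)
    write_metrics_table(res$metrics, out("metrics.csv"))
    if (nrow(res$bouts)) write_bout_table(res$bouts, out("bouts.csv"))
    utils::write.csv(res$heatmap, out("heatmap.csv"))
    if (!is.null(res$pca)) {
      utils::write.csv(res$pca$loadings, out("pca_loadings.csv"))
      utils::write.csv(res$pca$scores, out("pca_scores.csv"))
    }
    jsonlite::write_json(manifest, out("manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  attr(res, "manifest") <- manifest
  invisible(res)
}
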