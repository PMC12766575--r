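# shared fixtures and independent oracles

toy_geometry <- function(...) arena_geometry(length = 10, width = 2, ...)

# trajectory from an x path at y = 0.5, fps 1 (hand-checkable arithmetic)
toy_trajectory <- function(x, y = 0.5, fps = 1, fly_id = "toy") {
  trajectory(data.frame(frame = seq_along(x) - 1L, x = x,
                        y = rep_len(y, length(x))),
             fps = fps, fly_id = fly_id)
}

# wrap a raw 0/1 vector as an occupancy series
occ_series <- function(score, fps = 1, fly_id = "occ") {
  structure(list(score = as.integer(score),
                 imputed = rep(FALSE, length(score)),
                 fps = fps, fly_id = fly_id),
            class = "occupancy_series")
}

# independent run-length oracle: boundary detection by lagged comparison,
# deliberately not using rle()
runs_oracle <- function(v, target) {
  m <- v == target
  n <- length(m)
  starts <- which(m & !c(FALSE, m[-n]))
  ends <- which(m & !c(m[-1], FALSE))
  data.frame(entry_frame = starts - 1L, exit_frame = ends)
}

# brute-force per-bin mean over half-open bins
binned_mean_oracle <- function(score, fps, bin_seconds) {
  bpf <- bin_seconds * fps
  n <- length(score)
  nbins <- ceiling(n / bpf)
  vapply(seq_len(nbins), function(k) {
    i <- seq((k - 1) * bpf + 1, min(k * bpf, n))
    mean(score[i])
  }, numeric(1))
}

# brute-force histogram binning by per-value scan
hist_oracle <- function(dur, edges) {
  counts <- integer(length(edges))
  hi <- c(edges[-1], Inf)
  for (d in dur) {
    for (k in seq_along(edges)) {
      if (d >= edges[k] && d < hi[k]) {
        counts[k] <- counts[k] + 1L
        break
      }
    }
  }
  counts
}
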