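test_that("session behaviors match hand arithmetic on the toy path", {
  g <- toy_geometry()
  tr <- toy_trajectory(c(1, 6, 7, 7, 4, 8), y = 0)
  occ <- occupancy_from_trajectory(tr, g)
  sm <- session_metrics(tr, occ, g, "ROSA")
  expect_equal(sm$total_time, 4)
  expect_equal(sm$total_distance, 10)        # 5 + 1 + 0 + 4
  expect_equal(sm$max_depth, 3)
  never <- toy_trajectory(c(1, 2, 3), y = 0)
  sm0 <- session_metrics(never, occupancy_from_trajectory(never, g), g, "ROSA")
  expect_equal(unlist(sm0), c(total_time = 0, total_distance = 0, max_depth = 0))
})

test_that("imputed steps contribute no distance", {
  g <- toy_geometry()
  tr <- repair_gaps(toy_trajectory(c(6, NA, 8, 9)), max_gap_frames = 5)
  occ <- occupancy_from_trajectory(tr, g)
  sm <- session_metrics(tr, occ, g, "ROSA")
  # steps 6->held(6) and held->8 are imputed-adjacent: only 8->9 counts
  expect_equal(sm$total_distance, 1)
})

test_that("bout behavior means are undefined, not zero, without bouts", {
  b <- data.frame(duration_s = c(2, 1), distance = c(3, 4))
  bm <- bout_metrics(b, latencies = 1)
  expect_equal(bm$n_bouts, 2)
  expect_equal(bm$mean_bout_duration, 1.5)
  expect_equal(bm$mean_latency, 1)
  bm0 <- bout_metrics(b[0, ])
  expect_equal(bm0$n_bouts, 0)
  expect_true(is.na(bm0$mean_bout_duration))
  expect_true(is.na(bm0$mean_latency))
})

test_that("duration histogram bins half-open categories and keeps totals", {
  h <- duration_histogram(c(2, 7, 31))
  expect_equal(unname(h[c("[0,5)", "[5,10)", "[30,Inf)")]), c(1L, 1L, 1L))
  expect_equal(sum(h), 3L)
  expect_equal(sum(duration_histogram(numeric(0))), 0L)
  expect_equal(unname(duration_histogram(c(5, 10))[c("[5,10)", "[10,15)")]),
               c(1L, 1L))                     # edges belong to the right bin
  set.seed(17)
  dur <- runif(300, 0, 45)
  edges <- c(0, 3, 8, 20, 30)
  expect_equal(unname(duration_histogram(dur, edges)),
               hist_oracle(dur, edges))
  expect_error(duration_histogram(1, edges = c(5, 5, 10)), "increasing")
})

test_that("preference index follows the time formula and its identity", {
  expect_equal(preference_index(300, 120), 3 / 7)
  expect_equal(preference_index(420, 0), 1)
  expect_true(is.na(preference_index(0, 0)))
  expect_error(preference_index(-1, 3), "non-negative")
  # PI = 2 * (window occupation score) - 1
  set.seed(19)
  for (i in 1:25) {
    occ <- occ_series(rbinom(900, 1, runif(1, 0.05, 0.95)), fps = 1)
    w <- occ$score[481:900]
    expect_equal(pi_from_occupancy(occ), 2 * mean(w) - 1)
  }
})

test_that("growing ROSA residence never decreases the preference index", {
  set.seed(23)
  occ <- occ_series(rbinom(900, 1, 0.4), fps = 1)
  base <- pi_from_occupancy(occ)
  grown <- occ
  zero <- which(grown$score == 0)
  grown$score[sample(zero, 50)] <- 1L
  expect_gte(pi_from_occupancy(grown), base)
})

test_that("operant learning index handles bounds and degenerate bins", {
  expect_equal(operant_learning_index(30, 10), 0.5)
  expect_equal(operant_learning_index(7, 7), 0)
  expect_true(is.na(operant_learning_index(0, 0)))
  expect_error(operant_learning_index(-2, 1), "non-negative")
})

test_that("per-minute series localize behavior and conserve session totals", {
  g <- toy_geometry()
  # in ROSA exactly during [60, 120) seconds
  x <- c(rep(2, 60), rep(7, 60), rep(2, 60))
  tr <- toy_trajectory(x, y = 0)
  occ <- occupancy_from_trajectory(tr, g)
  ts_time <- metric_time_series(tr, occ, g, "time", 60)
  expect_equal(as.numeric(ts_time), c(0, 60, 0))
  sm <- session_metrics(tr, occ, g, "ROSA")
  expect_equal(sum(ts_time), sm$total_time)
  expect_error(metric_time_series(tr, occ, g, "speed"), "arg")
})

test_that("binned time/distance/depth equal brute-force recomputation", {
  g <- toy_geometry()
  set.seed(29)
  s <- simulate_session(sim_params(duration_s = 300, geometry = g), seed = 7)
  tr <- s$trajectory; occ <- s$occupancy
  fr <- tr$frames
  bpf <- 60 * tr$fps
  steps <- c(0, sqrt(diff(fr$x)^2 + diff(fr$y)^2))
  for (k in 1:5) {
    idx <- ((k - 1) * bpf + 1):(k * bpf)
    in_r <- occ$score[idx] == 1
    expect_equal(metric_time_series(tr, occ, g, "time")[k],
                 sum(in_r) / tr$fps)
    expect_equal(metric_time_series(tr, occ, g, "distance")[k],
                 sum(steps[idx][in_r]))
    dep <- if (any(in_r)) max(fr$x[idx][in_r] - 5) else 0
    expect_equal(metric_time_series(tr, occ, g, "depth")[k], max(dep, 0))
  }
  tot <- session_metrics(tr, occ, g, "ROSA")
  expect_equal(sum(metric_time_series(tr, occ, g, "time")), tot$total_time)
  expect_equal(sum(metric_time_series(tr, occ, g, "distance")),
               tot$total_distance)
})

test_that("fly_metrics assembles a coherent record", {
  g <- toy_geometry()
  s <- simulate_session(sim_params(geometry = g), seed = 11)
  m <- fly_metrics(s$trajectory, g, "ROSA")
  expect_equal(nrow(m), 1)
  expect_true(m$preference_index >= -1 && m$preference_index <= 1)
  expect_true(all(abs(na.omit(c(m$oli_time, m$oli_distance, m$oli_depth))) <= 1))
  hist_cols <- grep("^bouts_", names(m))
  expect_equal(sum(m[1, hist_cols]), m$n_bouts)
  expect_equal(m$total_time + fly_metrics(s$trajectory, g, "NoSA")$total_time,
               s$trajectory$session_duration)
})
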