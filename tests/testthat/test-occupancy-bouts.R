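test_that("occupancy recomputes the Boolean score from geometry", {
  g <- toy_geometry()
  tr <- toy_trajectory(c(1, 6, 7, 7, 4, 8))
  occ <- occupancy_from_trajectory(tr, g)
  expect_equal(occ$score, c(0L, 1L, 1L, 1L, 0L, 1L))
  # never crosses -> all zeros
  occ0 <- occupancy_from_trajectory(toy_trajectory(c(1, 2, 3)), g)
  expect_equal(occ0$score, c(0L, 0L, 0L))
  expect_error(occupancy_from_trajectory(toy_trajectory(c(NA, NA)), g),
               "invalid")
})

test_that("invalid frames inherit the neighboring value and imputed flag", {
  g <- toy_geometry()
  tr <- toy_trajectory(c(NA, 6, NA, 4))
  occ <- occupancy_from_trajectory(tr, g)
  expect_equal(occ$score, c(1L, 1L, 1L, 0L))   # lead backfilled, gap held
  expect_equal(occ$imputed, c(TRUE, FALSE, TRUE, FALSE))
})

test_that("stored occupation disagreements beyond 1% warn", {
  g <- toy_geometry()
  x <- c(rep(7, 99), 1)
  tr <- trajectory(data.frame(frame = 0:99, x = x, y = 0.5), fps = 15,
                   meta = list(stored_occupation = rep(1L, 100)))
  expect_warning(occupancy_from_trajectory(tr, g), "disagrees")
  tr2 <- trajectory(data.frame(frame = 0:99, x = rep(7, 100), y = 0.5),
                    fps = 15, meta = list(stored_occupation = rep(1L, 100)))
  expect_no_warning(occupancy_from_trajectory(tr2, g))
})

test_that("binned occupation score averages half-open bins", {
  expect_equal(as.numeric(binned_occupation_score(
    occ_series(c(1, 1, 0, 0), fps = 1), 4)), 0.5)
  all1 <- binned_occupation_score(occ_series(rep(1, 120), fps = 2), 10)
  expect_equal(as.numeric(all1), rep(1, 6))
  set.seed(21)
  occ <- occ_series(rbinom(900, 1, 0.35), fps = 1)
  got <- binned_occupation_score(occ, 60)
  expect_equal(as.numeric(got), binned_mean_oracle(occ$score, 1, 60))
  # partial final bin kept and flagged
  occ2 <- occ_series(rep(1, 70), fps = 1)
  got2 <- binned_occupation_score(occ2, 60)
  expect_equal(length(got2), 2)
  expect_equal(attr(got2, "partial"), c(FALSE, TRUE))
})

test_that("bout segmentation matches hand-worked and oracle runs", {
  occ <- occ_series(c(0, 1, 1, 0, 1, 0))
  b <- segment_bouts(occ, "ROSA")
  expect_equal(nrow(b), 2)
  expect_equal(b$duration_s, c(2, 1))
  expect_false(any(b$truncated))
  b2 <- segment_bouts(occ_series(c(1, 1, 0)), "ROSA")
  expect_equal(b2$duration_s, 2)
  expect_false(b2$truncated)
  b3 <- segment_bouts(occ_series(c(0, 0, 1)), "ROSA")
  expect_true(b3$truncated)
  set.seed(5)
  for (i in 1:20) {
    v <- rbinom(200, 1, runif(1, 0.2, 0.8))
    got <- segment_bouts(occ_series(v), "ROSA")
    exp <- runs_oracle(v, 1L)
    expect_equal(got$entry_frame, exp$entry_frame)
    expect_equal(got$exit_frame, exp$exit_frame)
  }
})

test_that("minimum-length filtering and initial-bout exclusion work", {
  occ <- occ_series(c(1, 0, 1, 1, 1, 0, 1))
  expect_equal(nrow(segment_bouts(occ, "ROSA")), 3)
  expect_equal(segment_bouts(occ, "ROSA", min_bout_frames = 2)$entry_frame, 2)
  kept <- segment_bouts(occ, "ROSA", include_initial = FALSE)
  expect_equal(nrow(kept), 2)
  expect_false(any(kept$initial))
})

test_that("bout conservation and alternation invariants hold", {
  set.seed(31)
  for (i in 1:10) {
    v <- rbinom(500, 1, runif(1, 0.2, 0.8))
    occ <- occ_series(v, fps = 5)
    br <- segment_bouts(occ, "ROSA")
    bn <- segment_bouts(occ, "NoSA")
    expect_equal(sum(br$duration_s), sum(v) / 5)
    expect_equal(sum(br$duration_s) + sum(bn$duration_s), 100)
    expect_lte(abs(nrow(br) - nrow(bn)), 1)
    # alternation: merged bout starts strictly interleave
    ord <- order(c(br$entry_frame, bn$entry_frame))
    lab <- c(rep(1, nrow(br)), rep(0, nrow(bn)))[ord]
    expect_true(all(diff(lab) != 0))
  }
})

test_that("latencies cover consecutive same-region bout pairs only", {
  occ <- occ_series(c(1, 0, 1, 1, 0, 0, 1))
  b <- segment_bouts(occ, "ROSA")
  expect_equal(latencies_to_reenter(b, 1), c(1, 2))
  expect_equal(latencies_to_reenter(b[1, ], 1), numeric(0))
  expect_equal(latencies_to_reenter(b[0, ], 1), numeric(0))
  b$region <- c("ROSA", "NoSA", "ROSA")
  expect_error(latencies_to_reenter(b, 1), "single region")
})

test_that("heatmap rows are binned scores and keep whole-session means", {
  set.seed(41)
  occs <- lapply(1:3, function(i)
    occ_series(rbinom(900, 1, 0.3 + 0.2 * i), fps = 1, fly_id = paste0("f", i)))
  m <- heatmap_matrix(occs, bin_seconds = 60)
  expect_equal(dim(m), c(3, 15))
  expect_equal(rownames(m), c("f1", "f2", "f3"))
  expect_true(all(m >= 0 & m <= 1))
  for (i in 1:3) expect_equal(mean(m[i, ]), mean(occs[[i]]$score))
  full <- occ_series(rep(1, 900), fps = 1)
  expect_equal(as.numeric(heatmap_matrix(list(full), 60)[1, ]), rep(1, 15))
  short <- occ_series(rep(1, 450), fps = 1)
  expect_error(heatmap_matrix(list(full, short), 60), "identical")
  expect_error(heatmap_matrix(list(occ_series(rep(1, 70), fps = 1)), 60),
               "partial")
})
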