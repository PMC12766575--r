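make_stack <- function(frames, fps = 15) frame_stack(frames, fps = fps)

test_that("background is the per-pixel median of sampled frames", {
  base <- matrix(100, 10, 12)
  stack <- make_stack(replicate(5, base, simplify = FALSE))
  expect_equal(estimate_background(stack, 5), base)
  # one outlier frame among five sampled: median ignores it
  frames <- replicate(5, base, simplify = FALSE)
  frames[[3]] <- matrix(0, 10, 12)
  expect_equal(estimate_background(make_stack(frames), 5), base)
  # random stack equals a brute-force per-pixel median
  set.seed(53)
  frames <- replicate(7, matrix(runif(120, 0, 255), 10, 12), simplify = FALSE)
  got <- estimate_background(make_stack(frames), 7)
  for (i in 1:10) for (j in 1:12)
    expect_equal(got[i, j], median(vapply(frames, function(f) f[i, j],
                                          numeric(1))))
  expect_error(frame_stack(frames[1]), "at least 2")
})

test_that("detection finds a dark square's center and ignores empty frames", {
  bg <- matrix(200, 20, 40)
  f <- bg
  f[8:12, 18:22] <- 50                       # 5x5 square, center (19.5, 9.5)
  p <- detect_fly(f, bg)
  expect_lt(abs(p["x"] - 19.5), 0.5)
  expect_lt(abs(p["y"] - 9.5), 0.5)
  expect_null(detect_fly(bg, bg))
  expect_null(detect_fly(bg - 1, bg))        # below the threshold floor
  expect_error(detect_fly(matrix(0, 5, 5), bg), "dimensions differ")
})

test_that("detection recovers a rendered noisy Gaussian blob within 1 px", {
  g <- arena_geometry(length = 10, width = 4, px_per_unit = 10)
  tr <- trajectory(data.frame(frame = 0:1, x = c(4.0, 4.0), y = c(1.2, 1.2)),
                   fps = 15)
  set.seed(59)
  stack <- render_frames(tr, g, noise_sd = 2, blob_sigma = 2)
  truth <- attr(stack, "truth_px")
  bg <- matrix(200, nrow(stack$frames[[1]]), ncol(stack$frames[[1]]))
  p <- detect_fly(stack$frames[[1]], bg)
  expect_lt(sqrt(sum((p - truth[1, ])^2)), 1)
})

test_that("tracking returns one frame per input frame with blanks invalid", {
  g <- toy_geometry()
  sim <- simulate_session(sim_params(fps = 5, duration_s = 10, geometry = g),
                          seed = 3)
  set.seed(61)
  stack <- render_frames(sim$trajectory, g, noise_sd = 1)
  # blank out three frames (fly vanishes)
  for (i in c(10, 20, 30)) stack$frames[[i]][] <- 200
  tr <- track(stack, g)
  expect_equal(nrow(tr$frames), length(stack$frames))
  expect_equal(which(!tr$frames$valid), c(10L, 20L, 30L))
})

test_that("rendered paths are recovered with sub-pixel median error", {
  g <- toy_geometry()
  sim <- simulate_session(sim_params(fps = 5, duration_s = 20, geometry = g),
                          seed = 13)
  set.seed(67)
  stack <- render_frames(sim$trajectory, g, noise_sd = 2)
  tr <- track(stack, g)
  truth <- attr(stack, "truth_px")
  est <- cbind(tr$frames$x, tr$frames$y) * g$px_per_unit + stack$origin_px[1]
  err <- sqrt(rowSums((est - truth)^2))
  expect_lt(median(err), 1)
})

test_that("integer frame shifts shift centroids equally", {
  bg <- matrix(200, 30, 50)
  f <- bg
  f[10:14, 20:24] <- 40
  p0 <- detect_fly(f, bg)
  sh <- bg
  sh[13:17, 26:30] <- 40                     # same blob shifted (+6, +3)
  p1 <- detect_fly(sh, bg)
  expect_equal(p1 - p0, c(x = 6, y = 3))
})

test_that("frame stacks round-trip through TIFF and PNG on disk", {
  skip_if_not_installed("tiff")
  skip_if_not_installed("png")
  set.seed(71)
  frames <- replicate(3, matrix(runif(200, 0, 1), 10, 20) * 255,
                      simplify = FALSE)
  ft <- tempfile(fileext = ".tif")
  tiff::writeTIFF(lapply(frames, function(f) f / 255), ft)
  st <- read_frame_stack(ft, fps = 5)
  expect_equal(length(st$frames), 3)
  expect_equal(st$frames[[2]], frames[[2]], tolerance = 1)
  pd <- tempfile()
  dir.create(pd)
  for (i in 1:3)
    png::writePNG(frames[[i]] / 255, file.path(pd, sprintf("f%02d.png", i)))
  sp <- read_frame_stack(pd, fps = 5)
  expect_equal(sp$frames[[3]], frames[[3]], tolerance = 1)
})
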