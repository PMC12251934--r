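# Synthetic eye-image generator: rendering, determinism, preprocessing,
# splitting, and I/O round trips.

test_that("config invariants are enforced with the offending field named", {
  expect_error(eye_config(pupil_intensity = 120, iris_intensity = 90),
               "pupil_intensity")
  expect_error(eye_config(iris_intensity = 200, sclera_intensity = 170),
               "iris_intensity")
  expect_error(eye_config(glint_probability = 1.5), "glint_probability")
  expect_error(eye_config(margin = 5, pupil_radius_range = c(15, 40)),
               "margin")
  expect_error(eye_config(noise_std = -1), "noise_std")
})

test_that("noise-free centered render has pupil-dark pixels centered at the midpoint", {
  cfg <- easy_eye_config(64, 48)
  mid <- c((64 - 1) / 2, (48 - 1) / 2)
  s <- generate_eye_image(cfg, seed = 3, center = mid)
  expect_equal(min(s$pixels), cfg$pupil_intensity)
  cen <- pupil_centroid(s$pixels)
  expect_lt(abs(cen["x"] - mid[1]), 0.5)
  expect_lt(abs(cen["y"] - mid[2]), 0.5)
})

test_that("generation is a pure function of (config, seed)", {
  cfg <- eye_config()  # defaults: noise, glints, occluders all active
  a <- generate_eye_image(cfg, seed = 11)
  b <- generate_eye_image(cfg, seed = 11)
  expect_identical(a$pixels, b$pixels)
  expect_identical(a$center_x, b$center_x)
  expect_identical(a$metadata, b$metadata)
  d1 <- generate_dataset(cfg, 5, seed = 12)
  d2 <- generate_dataset(cfg, 5, seed = 12)
  expect_identical(d1$labels, d2$labels)
})

test_that("darkest-decile centroid recovers the label on noise-free renders", {
  # brute-force centroid oracle over 500 generated images; the pupil is
  # sized to cover at least a decile of the frame so the darkest-10% mask
  # is exactly the pupil
  cfg <- eye_config(image_width = 64, image_height = 48,
                    pupil_radius_range = c(13, 15),
                    pupil_eccentricity_range = c(0.7, 1),
                    margin = 16, glint_probability = 0,
                    occluder_probability = 0,
                    illumination_gradient_amplitude = 0, noise_std = 0)
  hits <- 0L
  n <- 500L
  set.seed(42)
  for (i in seq_len(n)) {
    s <- generate_eye_image(cfg)
    px <- s$pixels
    thr <- quantile(px, 0.10)
    idx <- which(px <= thr, arr.ind = TRUE)
    cx <- mean(idx[, 2L]) - 1
    cy <- mean(idx[, 1L]) - 1
    if (sqrt((cx - s$center_x)^2 + (cy - s$center_y)^2) <= 2) hits <- hits + 1L
  }
  expect_gte(hits / n, 0.95)
})

test_that("intensity ordering pupil < iris < sclera holds in noise-free renders", {
  cfg <- easy_eye_config(96, 72)
  for (seed in 1:5) {
    s <- generate_eye_image(cfg, seed = seed)
    px <- s$pixels
    a <- s$metadata$pupil_a
    xg <- matrix(rep(0:(ncol(px) - 1), each = nrow(px)), nrow(px))
    yg <- matrix(rep(0:(nrow(px) - 1), times = ncol(px)), nrow(px))
    r2 <- (xg - s$center_x)^2 + (yg - s$center_y)^2
    pupil <- px[r2 <= (0.5 * s$metadata$pupil_b)^2]
    iris <- px[r2 > (1.2 * a)^2 & r2 <= (2 * a)^2]
    sclera <- px[r2 > (3.5 * a)^2]
    expect_lt(mean(pupil), mean(iris))
    expect_lt(mean(iris), mean(sclera))
  }
})

test_that("glint frequency tracks glint_probability within the binomial band", {
  cfg <- eye_config(image_width = 64, image_height = 48,
                    pupil_radius_range = c(4, 9), margin = 10,
                    glint_probability = 0.3, glint_radius = 1,
                    occluder_probability = 0, noise_std = 0,
                    illumination_gradient_amplitude = 0)
  n <- 1000L
  ds <- generate_dataset(cfg, n, seed = 77)
  frac <- mean(vapply(ds$samples, function(s) s$metadata$has_glint, logical(1)))
  band <- 3 * sqrt(0.3 * 0.7 / n)
  expect_lt(abs(frac - 0.3), band)
})

test_that("generate_dataset returns n samples with unique filenames and labels", {
  cfg <- easy_eye_config()
  ds <- generate_dataset(cfg, 10, seed = 5)
  expect_length(ds$samples, 10)
  expect_equal(nrow(ds$labels), 10)
  expect_equal(anyDuplicated(ds$labels$filename), 0L)
  expect_error(generate_dataset(cfg, 0), "n")
})

test_that("proportional downscale halves coordinates and area-averages pixels", {
  px <- matrix(0, 480, 640)
  px[241:480, ] <- 100  # bottom half bright
  s <- list(pixels = px, center_x = 320, center_y = 240)
  out <- preprocess_image(s, 320, 240)
  expect_equal(dim(out$pixels), c(240, 320))
  expect_equal(out$center_x, 160)
  expect_equal(out$center_y, 120)
  expect_equal(out$pixels[1, 1], 0)
  expect_equal(out$pixels[240, 1], 100)
  expect_equal(out$pixels[120, 1], 0)    # rows 239,240 of input
  expect_equal(out$pixels[121, 1], 100)  # rows 241,242 of input
})

test_that("center crop translates labels by the crop offset", {
  px <- matrix(seq_len(288 * 384), 288, 384)
  s <- list(pixels = px, center_x = 192, center_y = 144)
  out <- preprocess_image(s, 320, 240)
  expect_equal(dim(out$pixels), c(240, 320))
  expect_equal(out$offset, c(32, 24))
  expect_equal(out$center_x, 160)
  expect_equal(out$center_y, 120)
  expect_false(out$discarded)
  expect_equal(out$pixels[1, 1], px[25, 33])
})

test_that("preprocessing is identity at target size and errors below it", {
  px <- matrix(5, 240, 320)
  s <- list(pixels = px, center_x = 10, center_y = 20)
  out <- preprocess_image(s, 320, 240)
  expect_identical(out$pixels, px)
  expect_equal(out$center_x, 10)
  expect_error(preprocess_image(list(pixels = matrix(0, 100, 100),
                                     center_x = 1, center_y = 1), 320, 240),
               "smaller")
})

test_that("labels outside the crop flag the sample discarded, never clamped", {
  px <- matrix(0, 288, 384)
  s <- list(pixels = px, center_x = 5, center_y = 144)  # x < crop offset 32
  out <- preprocess_image(s, 320, 240)
  expect_true(out$discarded)
  expect_equal(out$center_x, 5 - 32)  # translated, not clamped
})

test_that("label consistency survives preprocessing on noise-free renders", {
  cfg <- eye_config(image_width = 384, image_height = 288,
                    pupil_radius_range = c(15, 40), margin = 48,
                    glint_probability = 0, occluder_probability = 0,
                    illumination_gradient_amplitude = 0, noise_std = 0)
  for (seed in 1:5) {
    s <- generate_eye_image(cfg, seed = seed)
    out <- preprocess_image(s, 320, 240)
    if (out$discarded) next
    cen <- pupil_centroid(out$pixels)
    expect_lt(abs(cen["x"] - out$center_x), 1)
    expect_lt(abs(cen["y"] - out$center_y), 1)
  }
})

test_that("split_dataset partitions 100 samples into 85/15 disjoint and exhaustive", {
  samples <- as.list(seq_len(100))
  sp <- split_dataset(samples, 0.85, seed = 9)
  expect_length(sp$train, 85)
  expect_length(sp$test, 15)
  expect_setequal(c(sp$train_idx, sp$test_idx), 1:100)
  expect_length(intersect(sp$train_idx, sp$test_idx), 0)
  sp2 <- split_dataset(samples, 0.85, seed = 9)
  expect_identical(sp$train_idx, sp2$train_idx)
  expect_warning(split_dataset(list(1), 0.85, seed = 1), "empty")
  expect_error(split_dataset(list(), 0.85), "empty")
})

test_that("PNG write/read round-trips integer gray levels and PGM reads both dialects", {
  tmp <- withr::local_tempdir()
  px <- matrix(sample(0:255, 48 * 64, replace = TRUE), 48, 64)
  p <- file.path(tmp, "x.png")
  write_eye_image(px, p)
  expect_equal(read_eye_image(p), px, ignore_attr = TRUE)
  # ASCII PGM
  p2 <- file.path(tmp, "y.pgm")
  writeLines(c("P2", "# comment", "4 2", "255",
               paste(c(0, 10, 20, 30, 40, 50, 60, 70), collapse = " ")), p2)
  m <- read_eye_image(p2)
  expect_equal(dim(m), c(2, 4))
  expect_equal(m[1, ], c(0, 10, 20, 30))
  # binary PGM
  p3 <- file.path(tmp, "z.pgm")
  con <- file(p3, "wb")
  writeChar("P5\n4 2\n255\n", con, eos = NULL)
  writeBin(as.raw(c(0, 10, 20, 30, 40, 50, 60, 70)), con)
  close(con)
  expect_equal(read_eye_image(p3), m)
})

test_that("dataset directory round trip preserves labels and pixels", {
  tmp <- withr::local_tempdir()
  cfg <- easy_eye_config()
  ds <- generate_dataset(cfg, 3, seed = 21, out_dir = tmp)
  back <- read_dataset(tmp)
  expect_length(back, 3)
  expect_equal(back[[2]]$center_x, ds$labels$center_x[2])
  expect_equal(back[[2]]$pixels, ds$samples[[2]]$pixels, ignore_attr = TRUE)
})
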