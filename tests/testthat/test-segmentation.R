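test_that("magnitude is the per-sample Euclidean norm", {
  expect_equal(magnitude(matrix(c(3, 4, 0), 1)), 5)
  expect_equal(magnitude(matrix(0, 1, 3)), 0)
  expect_equal(magnitude(matrix(c(-10.19, 0, 0), 1)), 10.19)
  expect_error(magnitude(matrix(0, 5, 2)), class = "strokesense_shape_error")
  expect_error(magnitude(matrix(c(1, NA, 0), 1)),
               class = "strokesense_value_error")
})

test_that("low-pass filter is zero-phase with unit DC gain", {
  # DC gain 1 away from the short forward-backward edge transients
  expect_equal(lowpass(rep(3.7, 200))[21:180], rep(3.7, 160),
               tolerance = 1e-6)

  t <- (0:599) / 60
  s2 <- sin(2 * pi * 2 * t)                     # 2 Hz, in the passband
  y <- lowpass(s2)
  lags <- -10:10
  cc <- vapply(lags, function(l) {
    idx <- 101:500
    cor(s2[idx], y[idx + l])
  }, numeric(1))
  expect_equal(lags[which.max(cc)], 0L)          # no phase shift

  s25 <- sin(2 * pi * 25 * t)                    # 25 Hz, in the stopband
  expect_lt(sqrt(mean(lowpass(s25)[101:500]^2)) /
              sqrt(mean(s25[101:500]^2)), 0.15)

  expect_error(lowpass(1:5), class = "strokesense_length_error")
})

spike_train <- function(heights, gap = 180L, width = 3L) {
  n <- length(heights)
  mag <- rep(0.5, 90L + n * (100L + gap))
  for (k in seq_len(n)) {
    ctr <- 90L + (k - 1L) * (100L + gap) + 41L
    mag[(ctr - width):(ctr + width)] <-
      heights[k] * (1 - abs(-width:width) / (width + 1))
  }
  mag
}

test_that("dynamic threshold detects at 20 g and falls back to 12 g", {
  mag25 <- spike_train(rep(25, 5))
  det <- detect_peaks(mag25)
  expect_length(det$peaks, 5L)
  expect_equal(det$threshold_used, 20)
  expect_false(det$fallback_fired)

  mag15 <- spike_train(rep(15, 5))
  det15 <- detect_peaks(mag15)
  expect_length(det15$peaks, 5L)
  expect_equal(det15$threshold_used, 12)
  expect_true(det15$fallback_fired)

  expect_warning(det_lo <- detect_peaks(spike_train(rep(8, 5))),
                 "fallback")
  expect_length(det_lo$peaks, 0L)
})

test_that("no two returned peaks are closer than the refractory span", {
  set.seed(5)
  mag <- abs(rnorm(3000, 0, 12)) + 10   # dense spiky magnitude
  det <- detect_peaks(mag)
  if (length(det$peaks) > 1L) {
    expect_gte(min(diff(det$peaks)), 100L)
  }
  cfg <- segmentation_config(refractory_samples = 25L)
  det2 <- detect_peaks(mag, cfg)
  expect_gte(min(diff(det2$peaks)), 25L)
})

test_that("window extraction takes 40 + 1 + 59 samples and rejects bounds", {
  data <- matrix(rnorm(200 * 12), 200, 12)
  w <- extract_window(data, peak = 45L)
  expect_true(w$accepted)
  expect_equal(nrow(w$data), 100L)
  expect_equal(w$data, data[5:104, ])

  expect_false(extract_window(data, peak = 30L)$accepted)
  expect_false(extract_window(data, peak = 150L)$accepted)
  expect_match(extract_window(data, peak = 30L)$reason, "pre-impact")
})

test_that("segmentation drops the first three strokes and centres windows", {
  cfg <- quiet_config()
  set.seed(13)
  rec <- simulate_recording("forehand", "amateur", 2L, cfg)  # 3 + 2 strokes
  seg <- segment_recording(rec$data)
  expect_length(seg$windows, 2L)   # 5 detected -> first 3 excluded

  rec0 <- simulate_recording("forehand", "amateur", 0L, cfg) # warm-ups only
  seg0 <- segment_recording(rec0$data)
  expect_length(seg0$windows, 0L)

  # full protocol recording: 3 + 20 -> 20 windows at the true impacts
  full_cfg <- simulation_config(noise_sd = 0)
  set.seed(17)
  rec20 <- simulate_recording("forehand", "amateur", 20L, full_cfg)
  seg20 <- segment_recording(rec20$data)
  expect_length(seg20$windows, 20L)
  truth <- rec20$truth$impact_index[!rec20$truth$is_warmup]
  expect_lte(max(abs(seg20$meta$peak_index_global - truth)), 1L)

  # alignment invariant: dominant-magnitude argmax at row 41 exactly
  for (w in seg20$windows) {
    expect_equal(which.max(magnitude(w[, 1:3])), 41L)
  }
})

test_that("tensor assembly stacks windows with a trailing singleton axis", {
  wins <- replicate(7, matrix(rnorm(1200), 100, 12), simplify = FALSE)
  tens <- assemble_tensor(wins)
  expect_equal(dim(tens$windows), c(7L, 100L, 12L, 1L))
  expect_equal(tensor_window(tens, 3), wins[[3]], ignore_attr = TRUE)

  expect_equal(dim(assemble_tensor(list())$windows), c(0L, 100L, 12L, 1L))
  expect_error(assemble_tensor(list(matrix(0, 50, 12))),
               class = "strokesense_shape_error")
})

test_that("segmentation_config enforces the windowing identity", {
  expect_error(segmentation_config(pre_samples = 50),
               class = "strokesense_value_error")
  expect_error(segmentation_config(fallback_threshold_g = 25),
               class = "strokesense_value_error")
  cfg <- segmentation_config()
  expect_equal(cfg$pre_samples + 1L + cfg$post_samples, 100L)
})
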