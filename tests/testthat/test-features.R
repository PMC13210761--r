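test_that("time-domain features match hand arithmetic", {
  # the [1, -1, 2] classics, on a length-4 input (repeat the last sample):
  # MAV, RMS and WL over the first three increments are hand-checkable
  td <- time_domain(c(1, -1, 2, 2))
  expect_equal(td$mav, 6 / 4)
  expect_equal(td$rms, sqrt(10 / 4))
  expect_equal(td$wl, 2 + 3 + 0)
  expect_equal(td$zc, 2L)
  expect_equal(time_domain(c(1, 2, 3, 4))$zc, 0L)

  alt <- rep(c(1, -1), 50)             # two-point symmetric distribution
  expect_equal(time_domain(alt)$kurtosis, 1)

  const <- time_domain(rep(2, 10))
  expect_true(const$degenerate)
  expect_equal(const$kurtosis, 0)
})

test_that("zero crossings use strict sign changes, zeros inherit the sign", {
  expect_equal(time_domain(c(1, 0, -1, 1))$zc, 2L)   # 0 keeps previous +
  expect_equal(time_domain(c(1, 0, 1, -1))$zc, 1L)
})

test_that("spectral features recover known spectra", {
  t <- (0:599) / 60
  sp <- spectral(sin(2 * pi * 5 * t))
  expect_equal(sp$mean_freq, 5, tolerance = 0.05)
  expect_equal(sp$median_freq, 5, tolerance = 0.15)

  set.seed(8)
  # flat spectrum: mean frequency ~ Nyquist / 2, averaged over replicates
  mf <- mean(vapply(1:5, function(i) spectral(rnorm(6000))$mean_freq,
                    numeric(1)))
  expect_equal(mf, 15, tolerance = 0.5 / 15)

  spz <- spectral(numeric(100))
  expect_true(spz$degenerate)
  expect_equal(c(spz$mean_freq, spz$median_freq), c(0, 0))
})

test_that("db4 band energies conserve signal energy exactly", {
  expect_equal(unlist(wavelet_energies(numeric(100))),
               c(e_a3 = 0, e_d1 = 0, e_d2 = 0, e_d3 = 0))

  set.seed(4)
  for (n in c(100L, 96L, 64L)) {
    x <- rnorm(n)
    we <- wavelet_energies(x)
    expect_equal(we$e_a3 + we$e_d1 + we$e_d2 + we$e_d3, sum(x^2),
                 tolerance = 1e-9)
  }

  alt <- rep(c(1, -1), 50)              # highest-frequency content -> d1
  wa <- wavelet_energies(alt)
  expect_gt(wa$e_d1, max(wa$e_a3, wa$e_d2, wa$e_d3))

  expect_error(wavelet_energies(rnorm(8)), class = "strokesense_length_error")
})

test_that("Hjorth parameters match closed forms", {
  const <- hjorth(rep(1, 50))
  expect_true(const$degenerate)
  expect_equal(c(const$activity, const$mobility, const$complexity), c(0, 0, 0))

  w <- 0.3                              # rad/sample
  x <- sin(w * (1:5000))
  expect_equal(hjorth(x)$mobility, 2 * sin(w / 2), tolerance = 1e-3)

  set.seed(10)
  expect_gt(hjorth(rnorm(20000))$complexity, 1)
})

test_that("Teager-Kaiser energy follows its defining identity", {
  expect_equal(tke(rep(3, 10))$psi, rep(0, 8))
  expect_equal(tke(c(1, 2, 3))$psi, 1)   # 2^2 - 1*3

  a <- 2.5; w <- 0.4; ph <- 1.1
  x <- a * cos(w * (0:99) + ph)
  psi <- tke(x)$psi
  expect_equal(psi, rep(a^2 * sin(w)^2, 98), tolerance = 1e-9)

  # sign-flip invariance
  set.seed(2)
  y <- rnorm(100)
  expect_equal(tke(-y)$psi, tke(y)$psi)
})

test_that("bilateral features capture inter-wrist relations", {
  set.seed(6)
  dom <- matrix(rnorm(600), 100, 6)
  w_same <- cbind(dom, dom)
  b1 <- bilateral(w_same)
  expect_equal(b1$correlation, rep(1, 6))
  expect_equal(b1$energy_ratio, rep(1, 6), tolerance = 1e-6)

  b2 <- bilateral(cbind(dom, -dom))
  expect_equal(b2$correlation, rep(-1, 6))

  b3 <- bilateral(cbind(dom, 0.5 * dom))
  expect_equal(b3$energy_ratio, rep(4, 6), tolerance = 1e-6)

  b4 <- bilateral(cbind(dom, matrix(0, 100, 6)))
  expect_true(all(b4$degenerate))
  expect_equal(b4$correlation, rep(0, 6))
})

test_that("the full bank yields 210 finite deterministic features", {
  tensor <- toy_tensor(3)
  fm <- extract_all(tensor)
  expect_equal(dim(fm), c(3L, 210L))
  expect_true(all(is.finite(as.matrix(fm))))
  expect_equal(names(fm), feature_names())

  # pure function: identical windows give identical rows
  t2 <- assemble_tensor(list(tensor_window(tensor, 1),
                             tensor_window(tensor, 1)))
  f2 <- extract_all(t2)
  expect_identical(f2[1, ], f2[2, ])

  # zero window: degenerate but finite
  fz <- extract_all(assemble_tensor(list(matrix(0, 100, 12))))
  expect_true(all(is.finite(as.matrix(fz))))
})

test_that("z-scoring is fitted on training rows only", {
  set.seed(31)
  x <- matrix(rnorm(200), 20, 10)
  colnames(x) <- paste0("f", 1:10)
  fit <- zscore_fit(x, 1:12)
  scaled <- as.matrix(zscore_apply(fit, x))
  expect_lt(max(abs(colMeans(scaled[1:12, ]))), 1e-10)
  expect_equal(unname(apply(scaled[1:12, ], 2, sd)), rep(1, 10))

  # train mean 10, sd 2, test value 14 -> 2
  x2 <- matrix(c(8, 10, 12, 14), ncol = 1)
  f2 <- zscore_fit(x2, 1:3)
  expect_equal(as.matrix(zscore_apply(f2, x2))[4, 1], 2, ignore_attr = TRUE)

  # degenerate column: centred, not divided
  x3 <- cbind(a = c(5, 5, 5, 9), b = 1:4)
  f3 <- zscore_fit(x3, 1:3)
  expect_equal(as.matrix(zscore_apply(f3, x3))[4, "a"], 4, ignore_attr = TRUE)

  expect_error(zscore_fit(x, integer(0)), class = "strokesense_value_error")
})

test_that("MRMR picks the informative feature first and stays unique", {
  set.seed(41)
  n <- 300
  y <- rep(c("a", "b"), n / 2)
  x <- cbind(signal = as.numeric(y == "b") + rnorm(n, 0, 0.01),
             n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n))
  sel <- mrmr_select(x, y, k = 3)
  expect_equal(sel$feature[1], "signal")
  expect_equal(anyDuplicated(sel$index), 0L)
  expect_error(mrmr_select(x, y, k = 10), class = "strokesense_value_error")
})

test_that("MRMR penalizes duplicated informative features", {
  set.seed(42)
  n <- 400
  y <- rep(c("a", "b"), n / 2)
  strong <- as.numeric(y == "b") + rnorm(n, 0, 0.05)
  weak <- as.numeric(y == "b") + rnorm(n, 0, 0.5)
  x <- cbind(strong = strong, dup = strong + rnorm(n, 0, 1e-4),
             weak = weak, noise = rnorm(n))
  sel <- mrmr_select(x, y, k = 3)
  expect_equal(sel$feature[1], "strong")
  # the near-copy is redundancy-penalized behind the independent weak feature
  expect_equal(sel$feature[2], "weak")
})

test_that("greedy MRMR matches an independently coded MID oracle", {
  # brute-force MID with plain loops and table(), independent of the package
  naive_mid <- function(x, y, k) {
    disc <- function(v) {
      r <- rank(v, ties.method = "first")
      as.integer(floor((r - 1) * 10 / length(v))) + 1L
    }
    mi <- function(a, b) {
      tab <- table(a, b) / length(a)
      pa <- rowSums(tab); pb <- colSums(tab)
      s <- 0
      for (i in seq_along(pa)) for (j in seq_along(pb)) {
        if (tab[i, j] > 0) s <- s + tab[i, j] * log(tab[i, j] / (pa[i] * pb[j]))
      }
      s
    }
    bx <- apply(x, 2, disc)
    rel <- apply(bx, 2, function(b) mi(b, y))
    sel <- integer(0)
    for (step in seq_len(k)) {
      best <- -Inf; pick <- NA
      for (j in seq_len(ncol(x))) {
        if (j %in% sel) next
        red <- if (length(sel)) mean(vapply(sel, function(s_)
          mi(bx[, j], bx[, s_]), numeric(1))) else 0
        sc <- rel[j] - red
        if (sc > best + 1e-12) { best <- sc; pick <- j }
      }
      sel <- c(sel, pick)
    }
    sel
  }
  set.seed(51)
  n <- 200
  y <- rep(c(1L, 2L), n / 2)
  x <- cbind(rnorm(n) + y, rnorm(n), rnorm(n) - y / 2, rnorm(n),
             rnorm(n) * y, rnorm(n))
  colnames(x) <- paste0("v", 1:6)
  for (k in 1:3) {
    expect_equal(mrmr_select(x, y, k = k)$index, naive_mid(x, y, k),
                 info = paste("k =", k))
  }
})
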