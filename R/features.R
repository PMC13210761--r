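# Handcrafted digital-biomarker features per stroke window.
#
# Per channel (12): 5 time-domain (MAV, RMS, WL, ZC, Pearson kurtosis),
# 2 spectral (mean/median frequency), 4 wavelet band energies (periodized
# db4, level 3), 3 Hjorth parameters, 2 Teager-Kaiser energy scalars.
# Per bilateral channel pair (6): correlation, energy ratio, covariance.
# Total 12 x 16 + 6 x 3 = 210 features, fixed order.

# Daubechies-4 (8-tap) orthonormal scaling filter, low-pass analysis side.
DB4_H <- c(0.23037781330889651, 0.71484657055291567, 0.63088076792985892,
           -0.027983769416859854, -0.18703481171909309, 0.030841381835560764,
           0.032883011666885197, -0.010597401785069032)
DB4_G <- (-1)^(0:7) * rev(DB4_H)  # quadrature mirror high-pass

#' Time-domain features of one channel
#'
#' Mean absolute value, root mean square, waveform length
#' (sum of absolute successive differences), zero-crossing count (strict
#' sign changes; exact zeros inherit the previous sign), and Pearson
#' (non-excess) kurtosis `m4/m2^2` (3 for a Gaussian).
#'
#' @param x Numeric vector (length >= 4).
#' @return Named list `mav`, `rms`, `wl`, `zc`, `kurtosis`, `degenerate`
#'   (TRUE for a constant signal, whose kurtosis is reported as 0).
#' @export
time_domain <- function(x) {
  n <- length(x)
  if (n < 4L) abort("Need at least 4 samples.", class = "strokesense_length_error")
  m2 <- mean((x - mean(x))^2)
  degenerate <- m2 == 0
  kurt <- if (degenerate) 0 else mean((x - mean(x))^4) / m2^2
  s <- sign(x)
  for (i in which(s == 0)) s[i] <- if (i > 1L) s[i - 1L] else 0
  zc <- sum(s[-n] * s[-1L] < 0)
  list(mav = mean(abs(x)), rms = sqrt(mean(x^2)),
       wl = sum(abs(diff(x))), zc = zc, kurtosis = kurt,
       degenerate = degenerate)
}

#' Spectral features via the periodogram
#'
#' Mean and median frequency of the unwindowed periodogram with the DC bin
#' excluded; the median interpolates linearly between frequency bins.
#'
#' @param x Numeric vector (length >= 8).
#' @param fs Sampling rate in Hz (default 60).
#' @return Named list `mean_freq`, `median_freq`, `degenerate` (both
#'   frequencies 0 for an all-zero/constant signal).
#' @export
spectral <- function(x, fs = 60) {
  n <- length(x)
  if (n < 8L) abort("Need at least 8 samples.", class = "strokesense_length_error")
  p <- Mod(fft(x))^2
  half <- 2:(floor(n / 2) + 1L)       # exclude DC, keep up to Nyquist
  p <- p[half]
  f <- (half - 1L) * fs / n
  tot <- sum(p)
  if (tot <= 0) {
    return(list(mean_freq = 0, median_freq = 0, degenerate = TRUE))
  }
  cum <- cumsum(p)
  j <- which(cum >= 0.5 * tot)[1]
  med <- if (j == 1L) {
    f[1] * (0.5 * tot) / p[1]
  } else {
    f[j - 1L] + (0.5 * tot - cum[j - 1L]) / p[j] * (f[j] - f[j - 1L])
  }
  list(mean_freq = sum(f * p) / tot, median_freq = med, degenerate = FALSE)
}

#' @noRd
dwt_step_periodized <- function(x) {
  n <- length(x)
  if (n %% 2L == 1L) { x <- c(x, 0); n <- n + 1L }  # keep energy exact
  half <- n / 2L
  a <- numeric(half); d <- numeric(half)
  for (k in seq_len(half)) {
    idx <- ((2L * (k - 1L) + 0:7) %% n) + 1L
    a[k] <- sum(DB4_H * x[idx])
    d[k] <- sum(DB4_G * x[idx])
  }
  list(a = a, d = d)
}

#' Wavelet band energies (db4, level 3, periodized)
#'
#' Energy (sum of squared coefficients) of the level-3 approximation band
#' and the three detail bands of a periodized db4 decomposition. Odd-length
#' intermediate signals are zero-padded by one sample before each periodized
#' step, so total band energy equals the signal energy exactly.
#'
#' @param x Numeric vector (length >= 16).
#' @return Named list `e_a3`, `e_d1`, `e_d2`, `e_d3`.
#' @export
wavelet_energies <- function(x) {
  if (length(x) < 16L) {
    abort("Need at least 16 samples for a level-3 decomposition.",
          class = "strokesense_length_error")
  }
  e_d <- numeric(3)
  a <- x
  for (lev in 1:3) {
    st <- dwt_step_periodized(a)
    e_d[lev] <- sum(st$d^2)
    a <- st$a
  }
  list(e_a3 = sum(a^2), e_d1 = e_d[1], e_d2 = e_d[2], e_d3 = e_d[3])
}

#' Hjorth parameters
#'
#' Activity (variance), mobility (root variance ratio of the first
#' difference to the signal), and complexity (mobility of the first
#' difference over mobility of the signal).
#'
#' @param x Numeric vector (length >= 3).
#' @return Named list `activity`, `mobility`, `complexity`, `degenerate`
#'   (all three 0 for a constant signal).
#' @export
hjorth <- function(x) {
  if (length(x) < 3L) abort("Need at least 3 samples.", class = "strokesense_length_error")
  v0 <- var(x)
  if (v0 == 0) {
    return(list(activity = 0, mobility = 0, complexity = 0, degenerate = TRUE))
  }
  d1 <- diff(x)
  v1 <- var(d1)
  mob <- sqrt(v1 / v0)
  comp <- if (v1 == 0) 0 else sqrt(var(diff(d1)) / v1) / mob
  list(activity = v0, mobility = mob, complexity = comp, degenerate = FALSE)
}

#' Teager-Kaiser energy operator
#'
#' `Psi[n] = x[n]^2 - x[n-1] * x[n+1]`, defined on interior samples, plus its
#' mean and max. The operator tracks amplitude and frequency simultaneously:
#' for a sampled cosine `A*cos(w*n)` it is the constant `A^2 * sin(w)^2`.
#'
#' @param x Numeric vector (length >= 3).
#' @return Named list `psi` (length `length(x) - 2`), `tke_mean`, `tke_max`.
#' @export
tke <- function(x) {
  n <- length(x)
  if (n < 3L) abort("Need at least 3 samples.", class = "strokesense_length_error")
  psi <- x[2:(n - 1L)]^2 - x[1:(n - 2L)] * x[3:n]
  list(psi = psi, tke_mean = mean(psi), tke_max = max(psi))
}

#' Bilateral coordination features of a stroke window
#'
#' For each of the six (dominant, non-dominant) channel pairs: Pearson
#' correlation (0 with a degenerate flag when either channel is constant),
#' energy ratio `sum(dom^2) / (sum(nondom^2) + 1e-8)`, and sample covariance.
#'
#' @param window 100 x 12 bilateral matrix.
#' @return A tibble with columns `pair`, `correlation`, `energy_ratio`,
#'   `covariance`, `degenerate`.
#' @export
bilateral <- function(window) {
  window <- as.matrix(window)
  if (ncol(window) != 12L) {
    abort("Window must have 12 columns.", class = "strokesense_shape_error")
  }
  purrr::map(1:6, function(i) {
    d <- window[, i]; nd <- window[, i + 6L]
    degen <- sd(d) == 0 || sd(nd) == 0
    tibble::tibble(
      pair = paste0("F", i, "F", i + 6L),
      correlation = if (degen) 0 else cor(d, nd),
      energy_ratio = sum(d^2) / (sum(nd^2) + 1e-8),
      covariance = cov(d, nd),
      degenerate = degen
    )
  }) |> dplyr::bind_rows()
}

CHANNEL_FEATURES <- c("mav", "rms", "wl", "zc", "kurtosis",
                      "mean_freq", "median_freq",
                      "e_a3", "e_d1", "e_d2", "e_d3",
                      "activity", "mobility", "complexity",
                      "tke_mean", "tke_max")

#' @noRd
channel_features <- function(x, fs = 60) {
  td <- time_domain(x)
  sp <- spectral(x, fs)
  we <- wavelet_energies(x)
  hj <- hjorth(x)
  tk <- tke(x)
  c(td$mav, td$rms, td$wl, td$zc, td$kurtosis,
    sp$mean_freq, sp$median_freq,
    we$e_a3, we$e_d1, we$e_d2, we$e_d3,
    hj$activity, hj$mobility, hj$complexity,
    tk$tke_mean, tk$tke_max)
}

#' Feature-bank column names, in extraction order
#' @return Character vector of length 210.
#' @export
feature_names <- function() {
  c(as.vector(vapply(1:12, function(ch) paste0("F", ch, "_", CHANNEL_FEATURES),
                     character(length(CHANNEL_FEATURES)))),
    as.vector(vapply(1:6, function(i) {
      paste0("F", i, "F", i + 6L, "_", c("correlation", "energy_ratio", "covariance"))
    }, character(3))))
}

#' Extract the full handcrafted feature bank for every window
#'
#' Applies the 16 per-channel features to all 12 channels and the 3 bilateral
#' features to all 6 channel pairs, giving a deterministic 210-column feature
#' matrix (one row per window). Degenerate channels (constant/zero) produce
#' 0 for the affected features, never `NaN`.
#'
#' @param tensor A [window_tensor] (or N x 100 x 12 (x 1) array).
#' @param fs Sampling rate in Hz.
#' @return A tibble of N rows and 210 named feature columns.
#' @export
extract_all <- function(tensor, fs = 60) {
  arr <- if (inherits(tensor, "window_tensor")) tensor$windows else tensor
  n <- dim(arr)[1]
  out <- matrix(0, nrow = n, ncol = 210L,
                dimnames = list(NULL, feature_names()))
  for (i in seq_len(n)) {
    w <- matrix(arr[i, , , 1L], 100L, 12L)
    vals <- as.vector(vapply(1:12, function(ch) channel_features(w[, ch], fs),
                             numeric(16L)))
    bl <- bilateral(w)
    out[i, ] <- c(vals, as.vector(t(as.matrix(bl[, c("correlation",
                                                     "energy_ratio",
                                                     "covariance")]))))
  }
  tibble::as_tibble(out)
}

#' Fit fold-internal z-score parameters
#'
#' Column means and standard deviations are derived solely from the rows
#' flagged as training, so held-out rows can never leak into the scaling.
#'
#' @param features Feature tibble/matrix (N x P).
#' @param train_rows Integer or logical index of training rows (non-empty).
#' @return An object of class `zscore_fit` holding per-column mean, sd and
#'   the training-row provenance.
#' @export
zscore_fit <- function(features, train_rows) {
  x <- as.matrix(features)
  if (is.logical(train_rows)) train_rows <- which(train_rows)
  if (length(train_rows) == 0L) {
    abort("Training set is empty.", class = "strokesense_value_error")
  }
  tr <- x[train_rows, , drop = FALSE]
  structure(
    list(mean = colMeans(tr), sd = apply(tr, 2L, sd),
         train_rows = as.integer(train_rows)),
    class = "zscore_fit"
  )
}

#' Apply fitted z-score parameters
#'
#' Non-degenerate columns (training sd > 0) are centred and scaled;
#' degenerate columns are centred only.
#'
#' @param fit A [zscore_fit()] object.
#' @param features Feature tibble/matrix with the same columns.
#' @return A tibble of scaled features.
#' @export
zscore_apply <- function(fit, features) {
  x <- as.matrix(features)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  x <- sweep(x, 2L, fit$mean, "-")
  ok <- fit$sd > 0
  x[, ok] <- sweep(x[, ok, drop = FALSE], 2L, fit$sd[ok], "/")
  tibble::as_tibble(x)
}

#' @noRd
discretize_ef <- function(x, bins = 10L) {
  r <- rank(x, ties.method = "first")
  as.integer(floor((r - 1L) * bins / length(x))) + 1L
}

#' @noRd
mi_from_bins <- function(b1, b2, n1, n2) {
  n <- length(b1)
  joint <- tabulate((b1 - 1L) * n2 + b2, nbins = n1 * n2) / n
  p1 <- tabulate(b1, nbins = n1) / n
  p2 <- tabulate(b2, nbins = n2) / n
  nz <- joint > 0
  # joint index = (b1-1)*n2 + b2, so b1 varies slowest
  prod <- rep(p1, each = n2) * rep.int(p2, n1)
  sum(joint[nz] * log(joint[nz] / prod[nz]))
}

#' Mutual information between each feature and the class label
#'
#' Features are discretized into equal-frequency bins (default 10) and the
#' plug-in discrete mutual information (nats) with the label is computed.
#'
#' @param features Feature tibble/matrix.
#' @param labels Class label vector (>= 2 classes).
#' @param bins Number of equal-frequency bins.
#' @return Numeric vector of MI values, one per column.
#' @export
feature_mi <- function(features, labels, bins = 10L) {
  x <- as.matrix(features)
  y <- as.integer(factor(labels))
  ny <- max(y)
  if (ny < 2L) abort("Need at least 2 classes.", class = "strokesense_value_error")
  apply(x, 2L, function(col) mi_from_bins(discretize_ef(col, bins), y, bins, ny))
}

#' Greedy minimum-redundancy maximum-relevance feature selection
#'
#' MID scheme: the first pick maximizes mutual information with the label;
#' each subsequent pick maximizes relevance minus the mean mutual information
#' with the already-selected features. MI is estimated on 10-bin
#' equal-frequency discretizations; ties break to the lowest column index,
#' so selection is deterministic.
#'
#' @param features Feature tibble/matrix (N x P).
#' @param labels Class labels (>= 2 classes).
#' @param k Number of features to select (default 50; must be <= P).
#' @return An object of class `mrmr_selection`: tibble with `rank`, `index`,
#'   `feature`, `relevance`, `redundancy`, `score`.
#' @export
mrmr_select <- function(features, labels, k = 50L) {
  x <- as.matrix(features)
  p <- ncol(x)
  if (k > p) abort("k exceeds the number of features.",
                   class = "strokesense_value_error")
  bins <- 10L
  y <- as.integer(factor(labels))
  ny <- max(y)
  if (ny < 2L) abort("Need at least 2 classes.", class = "strokesense_value_error")
  bx <- apply(x, 2L, discretize_ef, bins = bins)
  relevance <- apply(bx, 2L, function(b) mi_from_bins(b, y, bins, ny))
  selected <- integer(0)
  red_sum <- numeric(p)
  rows <- vector("list", k)
  for (step in seq_len(k)) {
    score <- if (step == 1L) relevance else
      relevance - red_sum / length(selected)
    score[selected] <- -Inf
    pick <- unname(which.max(score))  # lowest index wins ties
    rows[[step]] <- tibble::tibble(
      rank = step, index = pick,
      feature = colnames(x)[pick] %||% paste0("V", pick),
      relevance = unname(relevance[pick]),
      redundancy = if (step == 1L) 0 else unname(red_sum[pick]) / length(selected),
      score = if (step == 1L) unname(relevance[pick]) else unname(score[pick])
    )
    selected <- c(selected, pick)
    if (step < k) {
      new_mi <- apply(bx, 2L, function(b) mi_from_bins(bx[, pick], b, bins, bins))
      red_sum <- red_sum + new_mi
    }
  }
  structure(dplyr::bind_rows(rows), class = c("mrmr_selection", "tbl_df",
                                              "tbl", "data.frame"))
}
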