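# Impact detection and stroke windowing.
#
# Strokes are detected on the dominant wrist's acceleration magnitude with a
# dynamic threshold (20 g, falling back to 12 g when too few peaks are found),
# the first three strokes of each recording (warm-up/familiarization) are
# excluded, and 100-sample windows (40 before the peak, the peak, 59 after)
# are cut from the zero-phase low-passed 12-channel data.

#' Segmentation configuration
#'
#' @param threshold_g Primary detection threshold on the low-passed dominant
#'   acceleration magnitude, in g (default 20).
#' @param fallback_threshold_g Reduced threshold used when fewer than
#'   `min_detections_before_fallback` peaks are found at the primary
#'   threshold (default 12).
#' @param pre_samples,post_samples Samples kept before/after the peak
#'   (40 and 59; with the peak itself, 40 + 1 + 59 = 100).
#' @param skip_first Leading detected strokes excluded as warm-up (default 3).
#' @param min_detections_before_fallback Minimum peak count at the primary
#'   threshold before the fallback fires (default 4 = `skip_first` + 1, so at
#'   least one analyzable stroke survives).
#' @param refractory_samples Minimum separation between retained peaks
#'   (default 100 = one window, so windows never overlap).
#' @param butter_order,butter_cutoff_hz Butterworth low-pass filter order and
#'   cutoff (defaults 2 and 10 Hz), applied forward-backward (zero phase).
#' @return A list of class `segmentation_config`.
#' @export
segmentation_config <- function(threshold_g = 20, fallback_threshold_g = 12,
                                pre_samples = 40L, post_samples = 59L,
                                skip_first = 3L,
                                min_detections_before_fallback = 4L,
                                refractory_samples = 100L,
                                butter_order = 2L, butter_cutoff_hz = 10) {
  if (pre_samples + 1L + post_samples != 100L) {
    abort("pre_samples + 1 + post_samples must equal 100.",
          class = "strokesense_value_error")
  }
  if (fallback_threshold_g >= threshold_g) {
    abort("fallback_threshold_g must be below threshold_g.",
          class = "strokesense_value_error")
  }
  if (threshold_g <= 0 || refractory_samples < 1L) {
    abort("threshold_g must be positive and refractory_samples >= 1.",
          class = "strokesense_value_error")
  }
  structure(
    list(threshold_g = threshold_g,
         fallback_threshold_g = fallback_threshold_g,
         pre_samples = as.integer(pre_samples),
         post_samples = as.integer(post_samples),
         skip_first = as.integer(skip_first),
         min_detections_before_fallback = as.integer(min_detections_before_fallback),
         refractory_samples = as.integer(refractory_samples),
         butter_order = as.integer(butter_order),
         butter_cutoff_hz = butter_cutoff_hz),
    class = "segmentation_config"
  )
}

#' Euclidean acceleration magnitude
#'
#' Per-sample Euclidean norm of the tri-axial acceleration,
#' `sqrt(Acc_x^2 + Acc_y^2 + Acc_z^2)`.
#'
#' @param acc T x 3 acceleration matrix.
#' @return Non-negative T-vector.
#' @export
#' @examples
#' magnitude(matrix(c(3, 4, 0), nrow = 1))  # 5
magnitude <- function(acc) {
  acc <- as.matrix(acc)
  if (ncol(acc) != 3L) {
    abort("`acc` must have exactly 3 columns.", class = "strokesense_shape_error")
  }
  if (any(!is.finite(acc))) {
    abort("Non-finite values in `acc`.", class = "strokesense_value_error")
  }
  sqrt(rowSums(acc^2))
}

#' Zero-phase Butterworth low-pass filter
#'
#' Second-order (by default) Butterworth low-pass applied forward and
#' backward so the net response has zero phase and DC gain 1.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param config A [segmentation_config()] supplying order and cutoff.
#' @return Filtered vector, same length as `x`.
#' @export
lowpass <- function(x, fs = 60, config = segmentation_config()) {
  if (length(x) <= 3L * config$butter_order) {
    abort("Signal too short for the requested filter order.",
          class = "strokesense_length_error")
  }
  if (fs <= 2 * config$butter_cutoff_hz) {
    abort("Sampling rate must exceed twice the cutoff frequency.",
          class = "strokesense_value_error")
  }
  bf <- signal::butter(config$butter_order, config$butter_cutoff_hz / (fs / 2),
                       type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

#' @noRd
local_peaks_above <- function(mag, threshold, refractory) {
  t_len <- length(mag)
  if (t_len < 3L) return(integer(0))
  core <- mag[2:(t_len - 1L)]
  cand <- which(core > mag[1:(t_len - 2L)] & core >= mag[3:t_len] &
                core >= threshold) + 1L
  if (!length(cand)) return(integer(0))
  # within any refractory span keep the largest peak
  cand <- cand[order(mag[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (p in cand) {
    if (!length(kept) || all(abs(kept - p) >= refractory)) kept <- c(kept, p)
  }
  sort(kept)
}

#' Detect stroke impacts with the dynamic threshold
#'
#' Finds local maxima of the (already low-passed) acceleration magnitude at or
#' above 20 g, separated by at least the refractory span. If fewer than
#' `min_detections_before_fallback` peaks are found, detection reruns once at
#' the 12 g fallback and the run yielding more peaks is returned.
#'
#' @param mag Non-negative magnitude vector (g).
#' @param config A [segmentation_config()].
#' @return A list with `peaks` (integer indices), `threshold_used` (g) and
#'   `fallback_fired` (logical). An empty result at the fallback threshold
#'   emits a warning.
#' @export
detect_peaks <- function(mag, config = segmentation_config()) {
  if (any(mag < 0)) {
    abort("Magnitude must be non-negative.", class = "strokesense_value_error")
  }
  primary <- local_peaks_above(mag, config$threshold_g, config$refractory_samples)
  if (length(primary) >= config$min_detections_before_fallback) {
    return(list(peaks = primary, threshold_used = config$threshold_g,
                fallback_fired = FALSE))
  }
  fallback <- local_peaks_above(mag, config$fallback_threshold_g,
                                config$refractory_samples)
  if (length(fallback) == 0L) {
    warn("No stroke peaks found even at the fallback threshold.")
  }
  if (length(fallback) > length(primary)) {
    list(peaks = fallback, threshold_used = config$fallback_threshold_g,
         fallback_fired = TRUE)
  } else {
    list(peaks = primary, threshold_used = config$threshold_g,
         fallback_fired = FALSE)
  }
}

#' Cut one 100-sample stroke window around a peak
#'
#' Takes rows `peak - 40` to `peak + 59` inclusive from the bilateral data.
#' Windows whose span exceeds the recording bounds are rejected (returned as
#' a rejection value, not an error): padding would corrupt the pre-impact
#' phase the classifier learns from.
#'
#' @param data T x 12 bilateral matrix (already filtered).
#' @param peak Peak sample index (1-based).
#' @param config A [segmentation_config()].
#' @return A list: either `accepted = TRUE` with `data` (100 x 12) and
#'   `peak_index`, or `accepted = FALSE` with a `reason` string.
#' @export
extract_window <- function(data, peak, config = segmentation_config()) {
  t_len <- nrow(data)
  lo <- peak - config$pre_samples
  hi <- peak + config$post_samples
  if (lo < 1L) {
    return(list(accepted = FALSE, peak_index = peak,
                reason = "insufficient pre-impact samples"))
  }
  if (hi > t_len) {
    return(list(accepted = FALSE, peak_index = peak,
                reason = "insufficient post-impact samples"))
  }
  list(accepted = TRUE, data = data[lo:hi, , drop = FALSE], peak_index = peak)
}

#' Segment a bilateral recording into aligned stroke windows
#'
#' Runs the full per-recording chain: zero-phase low-pass of all 12 channels,
#' impact detection on the dominant-wrist magnitude with the dynamic
#' threshold, exclusion of the first `skip_first` detected strokes
#' (warm-up), window cutting, and peak re-centering. If filtering moved the
#' in-window magnitude argmax off the centre row by at most 2 samples the
#' window is re-cut at the shifted peak; larger shifts are rejected, so every
#' accepted window has its dominant-magnitude argmax exactly at row 41
#' (40 samples before it, 59 after).
#'
#' @param recording A `bilateral_recording` (from [synchronize()]) or a
#'   T x 12 matrix.
#' @param config A [segmentation_config()].
#' @param participant_id,stroke_type,skill_label Labels attached to windows
#'   (taken from the recording when available).
#' @return A list with `windows` (list of 100 x 12 matrices), `meta`
#'   (tibble: labels, global peak index, peak magnitude in g),
#'   `threshold_used`, `fallback_fired`, and `rejections` (tibble).
#' @export
segment_recording <- function(recording, config = segmentation_config(),
                              participant_id = NULL, stroke_type = NULL,
                              skill_label = NULL) {
  if (inherits(recording, "bilateral_recording")) {
    data <- recording$data
    participant_id <- participant_id %||% recording$participant_id
    stroke_type <- stroke_type %||% recording$stroke_type
    skill_label <- skill_label %||% recording$skill_label
    fs <- recording$sampling_rate_hz
  } else {
    data <- as.matrix(recording)
    fs <- 60
  }
  if (ncol(data) != 12L) {
    abort("Bilateral data must have 12 columns.", class = "strokesense_shape_error")
  }
  filt <- apply(data, 2L, lowpass, fs = fs, config = config)
  mag <- magnitude(filt[, 1:3, drop = FALSE])
  det <- detect_peaks(mag, config)
  peaks <- det$peaks
  if (length(peaks) > config$skip_first) {
    peaks <- peaks[-seq_len(config$skip_first)]
  } else {
    peaks <- integer(0)
  }
  windows <- list()
  meta <- list()
  rejections <- list()
  for (p in peaks) {
    w <- extract_window(filt, p, config)
    if (w$accepted) {
      local_arg <- which.max(magnitude(w$data[, 1:3, drop = FALSE]))
      shift <- local_arg - (config$pre_samples + 1L)
      if (shift != 0L && abs(shift) <= 2L) {
        w <- extract_window(filt, p + shift, config)
        if (w$accepted) {
          local_arg <- which.max(magnitude(w$data[, 1:3, drop = FALSE]))
          shift <- local_arg - (config$pre_samples + 1L)
        }
      }
      if (!w$accepted || shift != 0L) {
        rejections[[length(rejections) + 1L]] <-
          tibble::tibble(peak_index = p,
                         reason = if (!w$accepted) w$reason else
                           "peak not centerable within 2 samples")
        next
      }
      windows[[length(windows) + 1L]] <- w$data
      meta[[length(meta) + 1L]] <- tibble::tibble(
        participant_id = participant_id %||% NA_character_,
        stroke_type = stroke_type %||% NA_character_,
        skill = skill_label %||% NA_character_,
        peak_index_global = w$peak_index,
        peak_magnitude_g = mag[w$peak_index]
      )
    } else {
      rejections[[length(rejections) + 1L]] <-
        tibble::tibble(peak_index = p, reason = w$reason)
    }
  }
  list(
    windows = windows,
    meta = if (length(meta)) dplyr::bind_rows(meta) else
      tibble::tibble(participant_id = character(), stroke_type = character(),
                     skill = character(), peak_index_global = integer(),
                     peak_magnitude_g = numeric()),
    threshold_used = det$threshold_used,
    fallback_fired = det$fallback_fired,
    rejections = if (length(rejections)) dplyr::bind_rows(rejections) else
      tibble::tibble(peak_index = integer(), reason = character())
  )
}

#' Stack stroke windows into the model-ready tensor
#'
#' Stacks 100 x 12 windows into an `N x 100 x 12 x 1` array (the trailing
#' singleton is the image-style channel axis the convolutional front end
#' expects), preserving order and carrying the label table alongside.
#'
#' @param windows List of 100 x 12 matrices.
#' @param meta Tibble with one row per window (labels / provenance). A
#'   default empty-columns tibble is built when omitted.
#' @return An object of class `window_tensor`: list with `windows`
#'   (N x 100 x 12 x 1 array) and `meta`.
#' @export
assemble_tensor <- function(windows, meta = NULL) {
  n <- length(windows)
  if (n > 0L) {
    ok <- vapply(windows, function(w) all(dim(w) == c(100L, 12L)), logical(1))
    if (!all(ok)) {
      abort("All windows must be 100 x 12.", class = "strokesense_shape_error")
    }
  }
  arr <- array(0, dim = c(n, 100L, 12L, 1L))
  for (i in seq_len(n)) arr[i, , , 1L] <- windows[[i]]
  if (is.null(meta)) {
    meta <- tibble::tibble(participant_id = rep(NA_character_, n),
                           stroke_type = rep(NA_character_, n),
                           skill = rep(NA_character_, n))
  }
  if (nrow(meta) != n) {
    abort("`meta` must have one row per window.", class = "strokesense_shape_error")
  }
  structure(list(windows = arr, meta = tibble::as_tibble(meta)),
            class = "window_tensor")
}

#' @export
print.window_tensor <- function(x, ...) {
  cat(sprintf("<window_tensor> %d windows of 100 x 12 x 1\n",
              dim(x$windows)[1]))
  invisible(x)
}

#' @export
dim.window_tensor <- function(x) dim(x$windows)

#' Extract window i of a tensor as a 100 x 12 matrix
#' @param tensor A `window_tensor`.
#' @param i Window index.
#' @return 100 x 12 matrix.
#' @export
tensor_window <- function(tensor, i) {
  matrix(tensor$windows[i, , , 1L], nrow = 100L, ncol = 12L,
         dimnames = list(NULL, paste0("F", 1:12)))
}
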