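# Seeded simulator for bilateral 12-channel stroke recordings.
#
# Each stroke archetype is a deterministic 100-sample template (impact at row
# 41) built from three components: a low-frequency preparatory swing, a
# symmetric impact bump, and a damped post-impact ringing whose frequency and
# decay differ by stroke type (the volley is a short high-damping impulse,
# the serve carries the most high-frequency content). Elite strokes scale the
# dominant-wrist peak up by a configurable gain (default 12.5%) with lower
# relative variance; amateurs get added 3-8 Hz pre-impact fluctuation. The
# non-dominant wrist amplitude is set per stroke to hit a drawn bilateral
# asymmetry-index target, lower and tighter for elites.
#
# The simulator reproduces the relational structure of real stroke data
# (peak ratios, orderings, asymmetry gaps), not absolute field values.

#' Simulation configuration
#'
#' Defaults mirror the acquisition protocol the package models: 39
#' participants (11 elite, 28 amateur), each performing 20 forehands, 20
#' backhands, 10 serves and 10 volleys after 3 warm-up strokes per type.
#'
#' @param n_elite,n_amateur Participant counts (defaults 11 and 28).
#' @param strokes_per_type Named integer vector of protocol repetitions per
#'   stroke type.
#' @param elite_peak_gain Multiplicative dominant-peak gain for elite strokes
#'   (default 1.125, i.e. 12.5% higher; must lie in \[1, 1.5\]).
#' @param elite_peak_sd,amateur_peak_sd Relative SD of the per-stroke peak
#'   multiplier (elites are more consistent).
#' @param elite_asin_median,amateur_asin_median Target medians of the
#'   bilateral asymmetry index per class.
#' @param elite_asin_sd,amateur_asin_sd Spread of per-stroke asymmetry draws.
#' @param noise_sd Measurement noise SD on acceleration channels, in g
#'   (gyroscope noise is scaled proportionally). 0 gives noise-free signals.
#' @param inter_stroke_gap Samples between consecutive stroke windows
#'   (default 180 = 3 s, so windows never overlap).
#' @param warmup_strokes Familiarization strokes prepended per recording and
#'   excluded from the ground truth (default 3).
#' @param per_type_gain Optional named list overriding `elite_peak_gain` for
#'   individual stroke types (e.g. to emulate the amateur-over-elite volley
#'   inversion seen in real data).
#' @param seed Integer RNG seed; a fixed seed gives byte-identical output.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_elite = 11L, n_amateur = 28L,
                              strokes_per_type = c(forehand = 20L, backhand = 20L,
                                                   service = 10L, volley = 10L),
                              elite_peak_gain = 1.125,
                              elite_peak_sd = 0.05, amateur_peak_sd = 0.10,
                              elite_asin_median = 0.22,
                              amateur_asin_median = 0.32,
                              elite_asin_sd = 0.04, amateur_asin_sd = 0.09,
                              noise_sd = 0.5, inter_stroke_gap = 180L,
                              warmup_strokes = 3L, per_type_gain = NULL,
                              seed = 1L) {
  strokes_per_type <- unlist(strokes_per_type)
  if (n_elite < 0L || n_amateur < 0L || any(strokes_per_type < 0L)) {
    abort("Counts must be non-negative.", class = "strokesense_value_error")
  }
  if (elite_peak_gain < 1.0 || elite_peak_gain > 1.5) {
    abort("elite_peak_gain must lie in [1, 1.5].",
          class = "strokesense_value_error")
  }
  assert_stroke_type(names(strokes_per_type))
  structure(
    list(n_elite = as.integer(n_elite), n_amateur = as.integer(n_amateur),
         strokes_per_type = strokes_per_type,
         elite_peak_gain = elite_peak_gain,
         elite_peak_sd = elite_peak_sd, amateur_peak_sd = amateur_peak_sd,
         elite_asin_median = elite_asin_median,
         amateur_asin_median = amateur_asin_median,
         elite_asin_sd = elite_asin_sd, amateur_asin_sd = amateur_asin_sd,
         noise_sd = noise_sd, inter_stroke_gap = as.integer(inter_stroke_gap),
         warmup_strokes = as.integer(warmup_strokes),
         per_type_gain = per_type_gain, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Total protocol strokes implied by a simulation configuration
#'
#' The counting path of the acquisition design: participants times the sum
#' of per-type repetitions (warm-up strokes excluded), e.g. 39 x
#' (20 + 20 + 10 + 10) = 2340 for the defaults.
#'
#' @param config A [simulation_config()].
#' @return Integer stroke count.
#' @export
protocol_stroke_count <- function(config = simulation_config()) {
  as.integer((config$n_elite + config$n_amateur) * sum(config$strokes_per_type))
}

IMPACT_ROW <- 41L          # 40 samples before, 59 after
GYRO_PER_G <- 25           # deg/s of gyro swing per g of acceleration
TEMPLATE_PARAMS <- list(
  forehand = list(peak_g = 34, ring_f = 5.0, ring_tau = 8.0, ring_a = 0.45,
                  swing_a = 0.50, sigma = 2.8,
                  w_imp = c(0.35, -0.90, 0.25), asym_factor = 1.00,
                  extra_f = NULL),
  backhand = list(peak_g = 32, ring_f = 4.5, ring_tau = 9.0, ring_a = 0.40,
                  swing_a = 0.45, sigma = 3.0,
                  w_imp = c(0.40, 0.85, 0.30), asym_factor = 0.35,
                  extra_f = NULL),
  service  = list(peak_g = 38, ring_f = 12.0, ring_tau = 6.0, ring_a = 0.70,
                  swing_a = 0.35, sigma = 2.0,
                  w_imp = c(0.60, 0.60, 0.55), asym_factor = 1.00,
                  extra_f = 15.0),
  volley   = list(peak_g = 30, ring_f = 6.0, ring_tau = 2.5, ring_a = 0.50,
                  swing_a = 0.08, sigma = 2.2,
                  w_imp = c(0.45, 0.80, 0.30), asym_factor = 0.95,
                  extra_f = NULL)
)

#' @noRd
template_waveform <- function(p, sigma, ring_f, ring_tau, delay = 0L) {
  t <- 1:100
  s <- t - IMPACT_ROW - delay
  phases <- c(0, 1.2, 2.1)
  w_ring <- p$w_imp * 0.85
  w_sw <- abs(p$w_imp) * c(0.8, 1.0, 0.6)
  acc <- vapply(1:3, function(a) {
    bump <- p$w_imp[a] * exp(-s^2 / (2 * sigma^2))
    ring <- p$ring_a * w_ring[a] *
      sin(2 * pi * ring_f * s / 60 + phases[a]) * exp(-pmax(s, 0) / ring_tau) *
      as.numeric(s >= 1)
    if (!is.null(p$extra_f)) {
      ring <- ring + 0.5 * p$ring_a * w_ring[a] *
        sin(2 * pi * p$extra_f * s / 60 + phases[a] / 2) *
        exp(-pmax(s, 0) / ring_tau) * as.numeric(s >= 1)
    }
    swing <- p$swing_a * w_sw[a] * sin(pi * (s + 32) / 32) *
      as.numeric(s >= -32 & s <= 0)
    bump + ring + swing
  }, numeric(100))
  acc
}

#' Build the deterministic stroke template for one archetype
#'
#' @param stroke_type One of `"forehand"`, `"backhand"`, `"service"`,
#'   `"volley"`.
#' @return An object of class `stroke_template` with unit-peak dominant and
#'   non-dominant 6-channel waveforms (acc then gyr), the impact row (41),
#'   the default peak magnitude in g, and template mean magnitudes.
#' @export
make_template <- function(stroke_type) {
  assert_stroke_type(stroke_type)
  p <- TEMPLATE_PARAMS[[stroke_type]]
  acc_dom <- template_waveform(p, p$sigma, p$ring_f, p$ring_tau)
  # pin the magnitude argmax to the impact row (ringing onset can nudge it)
  delta <- IMPACT_ROW - which.max(magnitude(acc_dom))
  if (delta != 0L) {
    acc_dom <- acc_dom[pmin(pmax(1:100 - delta, 1L), 100L), , drop = FALSE]
  }
  acc_dom <- acc_dom / max(magnitude(acc_dom))  # unit peak at row 41
  # non-dominant: smoother, lower-frequency, delayed stabilizer at roughly
  # half the dominant amplitude (rescaled per stroke to the asymmetry target)
  acc_nd <- template_waveform(p, sigma = 4.0, ring_f = p$ring_f * 0.8,
                              ring_tau = p$ring_tau * 1.2, delay = 2L)
  acc_nd <- 0.5 * acc_nd / max(magnitude(acc_nd))
  shift3 <- function(m) m[pmax(1:100 - 3L, 1L), , drop = FALSE]
  structure(
    list(stroke_type = stroke_type,
         impact_row = IMPACT_ROW,
         base_peak_g = p$peak_g,
         asym_factor = p$asym_factor,
         dom = cbind(acc_dom, GYRO_PER_G * shift3(acc_dom)),
         nd = cbind(acc_nd, GYRO_PER_G * shift3(acc_nd)),
         mean_mag_dom = mean(magnitude(acc_dom)),
         mean_mag_nd = mean(magnitude(acc_nd))),
    class = "stroke_template"
  )
}

#' Simulate a single bilateral stroke window
#'
#' Draws one 100 x 12 stroke from a template using the current RNG state:
#' elite strokes scale the dominant peak by `elite_peak_gain` (lower relative
#' variance), amateurs add 3-8 Hz pre-impact fluctuation at 20% of the peak;
#' the non-dominant amplitude is set to achieve a drawn asymmetry-index
#' target, then measurement noise is added.
#'
#' @param template A [make_template()] result (or stroke type string).
#' @param skill `"elite"` or `"amateur"`.
#' @param config A [simulation_config()].
#' @return A list with `window` (100 x 12 matrix, g / deg/s), `impact_row`
#'   (41), `peak_g` (noiseless dominant peak) and `asin_target`.
#' @export
simulate_stroke <- function(template, skill, config = simulation_config()) {
  if (is.character(template)) template <- make_template(template)
  skill <- match.arg(skill, SKILL_LEVELS)
  gain <- if (skill == "elite") {
    (config$per_type_gain[[template$stroke_type]] %||% config$elite_peak_gain)
  } else 1.0
  rel_sd <- if (skill == "elite") config$elite_peak_sd else config$amateur_peak_sd
  mult <- gain * pmin(pmax(1 + rnorm(1, 0, rel_sd), 0.8), 1.5)
  peak_g <- template$base_peak_g * mult

  dom <- template$dom * peak_g
  # asymmetry target drawn per stroke; elites lower and tighter
  a_med <- if (skill == "elite") config$elite_asin_median else config$amateur_asin_median
  a_sd <- if (skill == "elite") config$elite_asin_sd else config$amateur_asin_sd
  a_tgt <- pmin(pmax(rnorm(1, a_med * template$asym_factor, a_sd), 0.02), 0.85)
  m_dom <- template$mean_mag_dom * peak_g
  nd_scale <- m_dom * (1 - a_tgt) / (1 + a_tgt) / template$mean_mag_nd
  nd <- template$nd * nd_scale

  if (skill == "amateur") {
    s <- (1:100) - IMPACT_ROW
    taper <- as.numeric(s <= -5) * pmin(1, (-s - 4) / 6)
    for (a in 1:3) {
      f <- runif(1, 3, 8)
      ph <- runif(1, 0, 2 * pi)
      dom[, a] <- dom[, a] + 0.2 * peak_g * abs(TEMPLATE_PARAMS[[template$stroke_type]]$w_imp[a]) *
        sin(2 * pi * f * (1:100) / 60 + ph) * taper
    }
  }
  win <- cbind(dom, nd)
  if (config$noise_sd > 0) {
    noise <- matrix(rnorm(1200, 0, config$noise_sd), 100, 12)
    noise[, c(4:6, 10:12)] <- noise[, c(4:6, 10:12)] * GYRO_PER_G
    win <- win + noise
  }
  colnames(win) <- paste0("F", 1:12)
  list(window = win, impact_row = IMPACT_ROW, peak_g = peak_g,
       asin_target = a_tgt)
}

#' Simulate one continuous recording of repeated strokes
#'
#' Concatenates `warmup + n_strokes` strokes of one type separated by
#' `inter_stroke_gap` background samples into a continuous bilateral stream,
#' with the true impact sample index of each stroke.
#'
#' @param stroke_type Stroke archetype.
#' @param skill `"elite"` or `"amateur"`.
#' @param n_strokes Protocol stroke count.
#' @param config A [simulation_config()].
#' @return A list with `data` (T x 12), `timestamps`, and `truth` (tibble:
#'   `impact_index`, `is_warmup`).
#' @export
simulate_recording <- function(stroke_type, skill, n_strokes,
                               config = simulation_config()) {
  template <- make_template(stroke_type)
  n_total <- config$warmup_strokes + n_strokes
  stride <- 100L + config$inter_stroke_gap
  t_len <- 90L + n_total * stride + 60L
  data <- matrix(0, t_len, 12L)
  if (config$noise_sd > 0) {
    data <- matrix(rnorm(t_len * 12L, 0, config$noise_sd), t_len, 12L)
    data[, c(4:6, 10:12)] <- data[, c(4:6, 10:12)] * GYRO_PER_G
  }
  impacts <- integer(n_total)
  for (k in seq_len(n_total)) {
    st <- simulate_stroke(template, skill, modifyList(config, list(noise_sd = 0)))
    b <- 90L + (k - 1L) * stride
    data[(b + 1L):(b + 100L), ] <- data[(b + 1L):(b + 100L), ] + st$window
    impacts[k] <- b + IMPACT_ROW
  }
  colnames(data) <- paste0("F", 1:12)
  list(
    data = data,
    timestamps = (seq_len(t_len) - 1L) / 60,
    truth = tibble::tibble(
      impact_index = impacts,
      is_warmup = seq_len(n_total) <= config$warmup_strokes
    )
  )
}

#' @noRd
write_wrist_csv <- function(path, timestamps, six, acc_in_ms2 = TRUE) {
  acc <- six[, 1:3, drop = FALSE]
  if (acc_in_ms2) acc <- acc * STANDARD_GRAVITY
  df <- tibble::tibble(
    timestamp = timestamps,
    Acc_X = acc[, 1], Acc_Y = acc[, 2], Acc_Z = acc[, 3],
    Gyr_X = six[, 4], Gyr_Y = six[, 5], Gyr_Z = six[, 6]
  )
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Simulate all recordings for one participant
#'
#' Writes one dominant (`sens1`) and one non-dominant (`sens2`) CSV per
#' stroke type into `out_dir/<participant_id>/`, in the raw logger unit
#' (m/s^2 for acceleration), and returns the protocol-stroke ground truth.
#' Warm-up strokes are present in the signals (so the first-3 exclusion rule
#' is exercised) but not listed in the truth table.
#'
#' @param participant_id E.g. `"P07"`.
#' @param skill `"elite"` or `"amateur"`.
#' @param config A [simulation_config()].
#' @param out_dir Dataset root directory.
#' @return Tibble: `participant_id`, `stroke_type`, `skill`, `file`
#'   (dominant CSV, relative to `out_dir`), `impact_index` (1-based sample).
#' @export
simulate_participant <- function(participant_id, skill,
                                 config = simulation_config(), out_dir) {
  pdir <- file.path(out_dir, participant_id)
  dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
  truth <- list()
  for (stroke in names(config$strokes_per_type)) {
    rec <- simulate_recording(stroke, skill, config$strokes_per_type[[stroke]],
                              config)
    f1 <- file.path(participant_id,
                    sprintf("%s_%s_sens1.csv", participant_id, stroke))
    f2 <- sub("sens1", "sens2", f1)
    write_wrist_csv(file.path(out_dir, f1), rec$timestamps, rec$data[, 1:6])
    write_wrist_csv(file.path(out_dir, f2), rec$timestamps, rec$data[, 7:12])
    keep <- !rec$truth$is_warmup
    truth[[stroke]] <- tibble::tibble(
      participant_id = participant_id, stroke_type = stroke, skill = skill,
      file = f1, impact_index = rec$truth$impact_index[keep]
    )
  }
  dplyr::bind_rows(truth)
}

#' Simulate a full multi-participant dataset on disk
#'
#' Deterministically (for a fixed seed) writes the whole acquisition
#' protocol: per participant and stroke type one pair of wrist CSVs, a
#' `ground_truth.csv` with one row per protocol stroke, and a
#' `manifest.json` listing every file with its MD5 checksum.
#'
#' @param config A [simulation_config()].
#' @param out_dir Target directory.
#' @param overwrite Refuse to write into a non-empty directory unless `TRUE`.
#' @return Invisibly, a list with `ground_truth` (tibble) and `manifest_path`.
#' @export
simulate_dataset <- function(config = simulation_config(), out_dir,
                             overwrite = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) && !overwrite) {
    abort(paste0("Target directory not empty: ", out_dir,
                 " (use overwrite = TRUE)."), class = "strokesense_io_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  n <- config$n_elite + config$n_amateur
  ids <- sprintf("P%02d", seq_len(n))
  skills <- rep(c("elite", "amateur"), c(config$n_elite, config$n_amateur))
  truth <- purrr::map2(ids, skills, simulate_participant,
                       config = config, out_dir = out_dir)
  truth <- dplyr::bind_rows(truth)
  readr::write_csv(truth, file.path(out_dir, "ground_truth.csv"),
                   progress = FALSE)
  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        "manifest.json"))
  manifest <- list(
    seed = config$seed,
    n_elite = config$n_elite, n_amateur = config$n_amateur,
    strokes_per_type = as.list(config$strokes_per_type),
    elite_peak_gain = config$elite_peak_gain,
    noise_sd = config$noise_sd,
    files = data.frame(
      file = files,
      md5 = unname(tools::md5sum(file.path(out_dir, files)))
    )
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(ground_truth = truth, manifest_path = manifest_path))
}

#' Simulate labelled stroke windows directly (no disk round trip)
#'
#' Convenience generator producing a ready [window_tensor] of raw (unfiltered)
#' stroke windows with class labels, useful for model and statistics
#' experiments. Stroke types are drawn in proportion to the protocol counts
#' unless a single type is requested.
#'
#' @param n_per_class Windows per skill class.
#' @param config A [simulation_config()].
#' @param stroke_types Stroke types to draw from.
#' @param seed RNG seed (defaults to `config$seed`).
#' @param n_participants Pseudo-participants per class for subject-level
#'   bookkeeping (default 10).
#' @return A `window_tensor` whose `meta` has `participant_id`, `stroke_type`,
#'   `skill`, `peak_g` and `asin_target` columns.
#' @export
simulate_windows <- function(n_per_class, config = simulation_config(),
                             stroke_types = STROKE_TYPES, seed = config$seed,
                             n_participants = 10L) {
  set.seed(seed)
  assert_stroke_type(stroke_types)
  templates <- lapply(stroke_types, make_template)
  names(templates) <- stroke_types
  wts <- config$strokes_per_type[stroke_types]
  wts <- wts / sum(wts)
  windows <- list(); meta <- list()
  i <- 0L
  for (skill in SKILL_LEVELS) {
    types <- rep(stroke_types, round(wts * n_per_class))
    types <- rep_len(types, n_per_class)
    for (k in seq_len(n_per_class)) {
      st <- simulate_stroke(templates[[types[k]]], skill, config)
      i <- i + 1L
      windows[[i]] <- st$window
      meta[[i]] <- tibble::tibble(
        participant_id = sprintf("%s%02d", toupper(substr(skill, 1, 1)),
                                 (k - 1L) %% n_participants + 1L),
        stroke_type = types[k], skill = skill,
        peak_g = st$peak_g, asin_target = st$asin_target
      )
    }
  }
  assemble_tensor(windows, dplyr::bind_rows(meta))
}
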