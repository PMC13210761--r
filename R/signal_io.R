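# Reading, pairing and synchronizing per-wrist sensor CSV files.
#
# CSV dialect: header `timestamp,Acc_X,Acc_Y,Acc_Z,Gyr_X,Gyr_Y,Gyr_Z`,
# comma-separated, UTF-8. Filename convention `P<id>_<stroke>_sens<1|2>.csv`
# with sens1 = dominant (racquet) wrist.

STANDARD_GRAVITY <- 9.81  # m/s^2 per g

SENSOR_COLUMNS <- c("timestamp", "Acc_X", "Acc_Y", "Acc_Z",
                    "Gyr_X", "Gyr_Y", "Gyr_Z")

#' Convert acceleration from m/s^2 to g
#'
#' Divides by the standard gravity constant (1 g = 9.81 m/s^2), preserving
#' sign, so e.g. a raw peak of -100 m/s^2 becomes approximately -10.19 g.
#'
#' @param values Numeric vector, matrix or array of accelerations in m/s^2.
#' @return The same structure in units of g.
#' @export
#' @examples
#' convert_to_g(c(0, 9.81, -100))
convert_to_g <- function(values) {
  if (!is.numeric(values)) {
    abort("`values` must be numeric.", class = "strokesense_value_error")
  }
  values / STANDARD_GRAVITY
}

#' Construct a single-wrist sensor recording
#'
#' @param participant_id Character scalar.
#' @param sensor_role `"dominant"` or `"non_dominant"`.
#' @param timestamps Strictly increasing numeric vector (seconds).
#' @param acc T x 3 acceleration matrix in g.
#' @param gyr T x 3 angular-velocity matrix in deg/s.
#' @param sampling_rate_hz Nominal sampling rate (default 60).
#' @param source_unit Unit the acceleration arrived in (`"m_s2"` or `"g"`).
#' @return An object of class `sensor_recording`.
#' @export
sensor_recording <- function(participant_id, sensor_role, timestamps, acc, gyr,
                             sampling_rate_hz = 60, source_unit = "g") {
  sensor_role <- match.arg(sensor_role, c("dominant", "non_dominant"))
  source_unit <- match.arg(source_unit, c("m_s2", "g"))
  acc <- as.matrix(acc); gyr <- as.matrix(gyr)
  if (ncol(acc) != 3L || ncol(gyr) != 3L) {
    abort("`acc` and `gyr` must each have 3 columns.",
          class = "strokesense_shape_error")
  }
  if (nrow(acc) != nrow(gyr) || nrow(acc) != length(timestamps)) {
    abort("`timestamps`, `acc` and `gyr` must have the same number of rows.",
          class = "strokesense_shape_error")
  }
  if (any(!is.finite(acc))) {
    abort("Non-finite acceleration values.", class = "strokesense_integrity_error")
  }
  if (length(timestamps) > 1L && any(diff(timestamps) <= 0)) {
    abort("Timestamps must be strictly increasing.",
          class = "strokesense_integrity_error")
  }
  if (!is.numeric(sampling_rate_hz) || sampling_rate_hz <= 0) {
    abort("`sampling_rate_hz` must be positive.", class = "strokesense_value_error")
  }
  structure(
    list(participant_id = as.character(participant_id),
         sensor_role = sensor_role,
         sampling_rate_hz = sampling_rate_hz,
         timestamps = as.numeric(timestamps),
         acc = acc, gyr = gyr, source_unit = source_unit),
    class = "sensor_recording"
  )
}

#' @export
print.sensor_recording <- function(x, ...) {
  cat(sprintf("<sensor_recording> participant %s, %s wrist, %d samples @ %g Hz\n",
              x$participant_id, x$sensor_role, length(x$timestamps),
              x$sampling_rate_hz))
  invisible(x)
}

#' Read one wrist's sensor CSV file
#'
#' Reads the sensor CSV dialect (`timestamp,Acc_X,Acc_Y,Acc_Z,Gyr_X,Gyr_Y,Gyr_Z`),
#' converting acceleration to the canonical unit g when the source logged
#' m/s^2. Participant id and sensor role are parsed from the filename
#' (`P<id>_..._sens<1|2>.csv`, sens1 = dominant) when possible.
#'
#' @param path Path to the CSV file.
#' @param unit_hint Unit of the stored acceleration columns: `"m_s2"`
#'   (default, the raw logger unit) or `"g"`.
#' @param participant_id,sensor_role Optional overrides for the values parsed
#'   from the filename.
#' @return A [sensor_recording()].
#' @export
read_recording <- function(path, unit_hint = c("m_s2", "g"),
                           participant_id = NULL, sensor_role = NULL) {
  unit_hint <- match.arg(unit_hint)
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "strokesense_io_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(SENSOR_COLUMNS, names(df))
  if (length(missing_cols)) {
    abort(paste0("Sensor CSV ", basename(path), " is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "strokesense_format_error")
  }
  fname <- basename(path)
  if (is.null(participant_id)) {
    m <- regmatches(fname, regexec("^P?([A-Za-z0-9]+)_", fname))[[1]]
    participant_id <- if (length(m) == 2L) m[2] else fname
  }
  if (is.null(sensor_role)) {
    sensor_role <- if (grepl("sens2", fname)) "non_dominant" else "dominant"
  }
  acc <- as.matrix(df[, c("Acc_X", "Acc_Y", "Acc_Z")])
  if (unit_hint == "m_s2") acc <- convert_to_g(acc)
  sensor_recording(
    participant_id = participant_id, sensor_role = sensor_role,
    timestamps = df$timestamp, acc = acc,
    gyr = as.matrix(df[, c("Gyr_X", "Gyr_Y", "Gyr_Z")]),
    sampling_rate_hz = 60, source_unit = unit_hint
  )
}

#' Pair per-wrist files by participant and recording
#'
#' Matches sens1 (dominant) and sens2 (non-dominant) files that belong to the
#' same recording, keyed on the filename with the sensor token removed, and
#' extracts the participant id with a regular expression. Unpaired files are
#' reported, never silently dropped.
#'
#' @param paths Character vector of file paths.
#' @param pattern Perl regex with named groups `participant` and `role`
#'   applied to the basename.
#' @return A list with `pairs` (tibble: `participant_id`, `dominant`,
#'   `non_dominant`) and `unpaired` (tibble: `file`, `reason`).
#' @export
pair_recordings <- function(paths,
                            pattern = "^P(?<participant>[A-Za-z0-9]+)_.*sens(?<role>[12])\\.csv$") {
  base <- basename(paths)
  m <- regexpr(pattern, base, perl = TRUE)
  starts <- attr(m, "capture.start"); lens <- attr(m, "capture.length")
  if (is.null(starts) || !all(c("participant", "role") %in% colnames(starts))) {
    abort("`pattern` must contain named groups `participant` and `role`.",
          class = "strokesense_value_error")
  }
  grab <- function(i, grp) {
    if (m[i] == -1L) return(NA_character_)
    substr(base[i], starts[i, grp], starts[i, grp] + lens[i, grp] - 1L)
  }
  info <- tibble::tibble(
    path = paths,
    file = base,
    participant = map_chr(seq_along(paths), grab, grp = "participant"),
    role = map_chr(seq_along(paths), grab, grp = "role"),
    key = sub("sens[12]", "sens*", base)
  )
  unmatched <- dplyr::filter(info, is.na(.data$participant))
  matched <- dplyr::filter(info, !is.na(.data$participant))
  dup <- dplyr::count(matched, .data$key, .data$role)
  dup <- dplyr::filter(dup, .data$n > 1L)
  if (nrow(dup)) {
    abort(paste0("Ambiguous pairing: multiple files claim the same ",
                 "(recording, sensor role): ",
                 paste(dup$key, collapse = "; ")),
          class = "strokesense_ambiguity_error")
  }
  wide <- tidyr::pivot_wider(
    dplyr::select(matched, "participant", "key", "role", "path"),
    names_from = "role", values_from = "path", names_prefix = "sens"
  )
  if (!"sens1" %in% names(wide)) wide$sens1 <- NA_character_
  if (!"sens2" %in% names(wide)) wide$sens2 <- NA_character_
  complete <- dplyr::filter(wide, !is.na(.data$sens1) & !is.na(.data$sens2))
  incomplete <- dplyr::filter(wide, is.na(.data$sens1) | is.na(.data$sens2))
  unpaired <- dplyr::bind_rows(
    tibble::tibble(file = unmatched$file,
                   reason = rep("filename does not match pattern",
                                nrow(unmatched))),
    if (nrow(incomplete)) {
      tibble::tibble(
        file = basename(ifelse(is.na(incomplete$sens1),
                               incomplete$sens2, incomplete$sens1)),
        reason = ifelse(is.na(incomplete$sens1),
                        "missing dominant (sens1) counterpart",
                        "missing non-dominant (sens2) counterpart")
      )
    } else {
      tibble::tibble(file = character(), reason = character())
    }
  )
  list(
    pairs = tibble::tibble(participant_id = complete$participant,
                           dominant = complete$sens1,
                           non_dominant = complete$sens2),
    unpaired = unpaired
  )
}

#' Synchronize two wrists into a bilateral 12-channel recording
#'
#' Aligns the dominant and non-dominant streams by nearest timestamp over
#' their overlapping time span (no resampling; both streams share the 60 Hz
#' nominal rate) so each row represents the same moment. Alignment residuals
#' beyond half a sample period are a synchronization error.
#'
#' @param a,b [sensor_recording()] objects for the two wrists (one dominant,
#'   one non-dominant, same participant), in either order.
#' @param stroke_type,skill_label Optional labels attached to the output.
#' @return An object of class `bilateral_recording` with a T x 12 `data`
#'   matrix (columns 1-6 dominant AccX..GyrZ, 7-12 non-dominant).
#' @export
synchronize <- function(a, b, stroke_type = NULL, skill_label = NULL) {
  stopifnot(inherits(a, "sensor_recording"), inherits(b, "sensor_recording"))
  if (a$sensor_role == b$sensor_role) {
    abort("Need one dominant and one non-dominant recording.",
          class = "strokesense_sync_error")
  }
  if (a$participant_id != b$participant_id) {
    abort("Recordings belong to different participants.",
          class = "strokesense_sync_error")
  }
  if (a$sampling_rate_hz != b$sampling_rate_hz) {
    abort("Sampling rates differ.", class = "strokesense_sync_error")
  }
  dom <- if (a$sensor_role == "dominant") a else b
  nd <- if (a$sensor_role == "dominant") b else a
  half_period <- 0.5 / dom$sampling_rate_hz
  lo <- max(min(dom$timestamps), min(nd$timestamps))
  hi <- min(max(dom$timestamps), max(nd$timestamps))
  if (lo > hi) {
    abort("Recordings have no overlapping time span.",
          class = "strokesense_sync_error")
  }
  keep <- which(dom$timestamps >= lo - half_period &
                dom$timestamps <= hi + half_period)
  # nearest-neighbour index of each dominant timestamp in the other stream
  idx <- findInterval(dom$timestamps[keep], nd$timestamps, all.inside = TRUE)
  d_lo <- abs(dom$timestamps[keep] - nd$timestamps[idx])
  d_hi <- abs(dom$timestamps[keep] - nd$timestamps[pmin(idx + 1L, length(nd$timestamps))])
  nn <- ifelse(d_hi < d_lo, idx + 1L, idx)
  resid <- abs(dom$timestamps[keep] - nd$timestamps[nn])
  ok <- resid <= half_period + 1e-12
  if (!any(ok)) {
    abort("No samples align within half a sample period.",
          class = "strokesense_sync_error")
  }
  if (any(!ok)) { keep <- keep[ok]; nn <- nn[ok]; resid <- resid[ok] }
  if (max(resid) > half_period + 1e-12) {
    abort("Clock offset exceeds half a sample period after alignment.",
          class = "strokesense_sync_error")
  }
  data <- cbind(dom$acc[keep, , drop = FALSE], dom$gyr[keep, , drop = FALSE],
                nd$acc[nn, , drop = FALSE], nd$gyr[nn, , drop = FALSE])
  colnames(data) <- paste0("F", 1:12)
  structure(
    list(participant_id = dom$participant_id,
         data = data,
         timestamps = dom$timestamps[keep],
         stroke_type = stroke_type,
         skill_label = skill_label,
         sampling_rate_hz = dom$sampling_rate_hz),
    class = "bilateral_recording"
  )
}

#' @export
print.bilateral_recording <- function(x, ...) {
  cat(sprintf("<bilateral_recording> participant %s, %d x 12 @ %g Hz%s\n",
              x$participant_id, nrow(x$data), x$sampling_rate_hz,
              if (!is.null(x$stroke_type)) paste0(", ", x$stroke_type) else ""))
  invisible(x)
}

#' Save / load a window tensor
#'
#' Round-trips a [window_tensor] (the N x 100 x 12 x 1 stroke-window stack
#' plus its label table) to disk bit-identically, metadata included.
#'
#' @param tensor A `window_tensor`.
#' @param path Destination file.
#' @return `save_tensor` returns `path` invisibly; `load_tensor` the tensor.
#' @export
save_tensor <- function(tensor, path) {
  stopifnot(inherits(tensor, "window_tensor"))
  saveRDS(tensor, path, version = 3)
  invisible(path)
}

#' @rdname save_tensor
#' @export
load_tensor <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "strokesense_io_error")
  }
  out <- tryCatch(readRDS(path), error = function(e) {
    abort(paste0("Corrupt tensor container: ", conditionMessage(e)),
          class = "strokesense_io_error")
  })
  if (!inherits(out, "window_tensor")) {
    abort("File does not contain a window tensor.",
          class = "strokesense_io_error")
  }
  out
}
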