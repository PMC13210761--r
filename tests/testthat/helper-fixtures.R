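# Shared fixtures: tiny sensor CSVs and small simulated tensors.

write_sensor_csv <- function(path, n = 10L, acc = NULL, gyr = NULL,
                             timestamps = NULL, drop_col = NULL) {
  if (is.null(acc)) acc <- matrix(0, n, 3)
  if (is.null(gyr)) gyr <- matrix(0, n, 3)
  if (is.null(timestamps)) timestamps <- (seq_len(n) - 1) / 60
  df <- data.frame(timestamp = timestamps,
                   Acc_X = acc[, 1], Acc_Y = acc[, 2], Acc_Z = acc[, 3],
                   Gyr_X = gyr[, 1], Gyr_Y = gyr[, 2], Gyr_Z = gyr[, 3])
  if (!is.null(drop_col)) df[[drop_col]] <- NULL
  readr::write_csv(df, path, progress = FALSE)
  path
}

# small, quiet simulation configuration for fast tests
quiet_config <- function(noise_sd = 0, ...) {
  simulation_config(n_elite = 1L, n_amateur = 1L,
                    strokes_per_type = c(forehand = 2L, backhand = 2L,
                                         service = 2L, volley = 2L),
                    noise_sd = noise_sd, ...)
}

# deterministic toy tensor: n copies of a fixed smooth window
toy_tensor <- function(n = 4L, seed = 99L) {
  set.seed(seed)
  tmpl <- make_template("forehand")
  windows <- lapply(seq_len(n), function(i) {
    w <- cbind(tmpl$dom * 30, tmpl$nd * 15)
    w + matrix(rnorm(1200, 0, 0.1), 100, 12)
  })
  meta <- tibble::tibble(
    participant_id = sprintf("P%02d", seq_len(n)),
    stroke_type = rep("forehand", n),
    skill = rep(c("elite", "amateur"), length.out = n)
  )
  assemble_tensor(windows, meta)
}
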