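# Bilateral asymmetry index and peak-acceleration group statistics.

#' Bilateral Asymmetry Index
#'
#' For a stroke window, the mean over the window of the per-sample Euclidean
#' acceleration magnitude is computed for each wrist, and the index is the
#' normalized absolute difference
#' `|m_dom - m_nd| / (m_dom + m_nd + eps)`, lying in \[0, 1) for
#' non-negative magnitudes. Lower values indicate better bilateral
#' coordination. The index is symmetric under hand swap and (up to the
#' negligible effect of `eps`) scale-invariant.
#'
#' @param x A 100 x 12 window matrix, or a [window_tensor] (one index value
#'   per window is returned, joined with the label table).
#' @param eps Stabilization constant preventing division by zero
#'   (default 1e-8).
#' @return A single value for a matrix input; for a tensor, a tibble with
#'   the window metadata plus an `asin` column.
#' @export
asymmetry_index <- function(x, eps = 1e-8) {
  if (inherits(x, "window_tensor")) {
    n <- dim(x$windows)[1]
    vals <- vapply(seq_len(n), function(i) {
      asymmetry_index(tensor_window(x, i), eps)
    }, numeric(1))
    return(dplyr::mutate(x$meta, asin = vals))
  }
  w <- as.matrix(x)
  m_dom <- mean(magnitude(w[, 1:3, drop = FALSE]))
  m_nd <- mean(magnitude(w[, 7:9, drop = FALSE]))
  abs(m_dom - m_nd) / (m_dom + m_nd + eps)
}

#' Per-group peak-acceleration summary
#'
#' For each (stroke type, skill) cell: the number of windows and the mean and
#' sample SD of the per-window peak acceleration magnitude of each wrist
#' (dominant: max over the window of the dominant-wrist Euclidean magnitude;
#' non-dominant analogously). Gyroscope channels are excluded. Cells with a
#' single window report `NA` SD; empty cells are absent.
#'
#' @param tensor A [window_tensor] whose `meta` has `stroke_type` and `skill`.
#' @return A tibble with columns `stroke_type`, `skill`, `n`, `dominant_mean`,
#'   `dominant_sd`, `non_dominant_mean`, `non_dominant_sd` (units g).
#' @export
group_summary <- function(tensor) {
  stopifnot(inherits(tensor, "window_tensor"))
  n <- dim(tensor$windows)[1]
  peaks <- purrr::map(seq_len(n), function(i) {
    w <- tensor_window(tensor, i)
    tibble::tibble(dom = max(magnitude(w[, 1:3])),
                   nd = max(magnitude(w[, 7:9])))
  }) |> dplyr::bind_rows()
  df <- dplyr::bind_cols(tensor$meta[, c("stroke_type", "skill")], peaks)
  df |>
    dplyr::group_by(.data$stroke_type, .data$skill) |>
    dplyr::summarise(
      n = dplyr::n(),
      dominant_mean = mean(.data$dom),
      dominant_sd = if (dplyr::n() > 1L) sd(.data$dom) else NA_real_,
      non_dominant_mean = mean(.data$nd),
      non_dominant_sd = if (dplyr::n() > 1L) sd(.data$nd) else NA_real_,
      .groups = "drop"
    )
}

#' Two-way ANOVA of peak acceleration by stroke type and skill
#'
#' Fits `peak ~ stroke * group` and reports Type-II sums of squares
#' (appropriate for the unbalanced elite/amateur design), F statistics,
#' p-values and partial eta squared
#' `SS_effect / (SS_effect + SS_residual)` for the two main effects and
#' their interaction.
#'
#' @param peaks Numeric response vector (per-window peak acceleration).
#' @param stroke Factor of stroke types (4 levels expected).
#' @param group Factor of skill levels (2 levels expected).
#' @return A tibble of class `stroke_anova` with rows `stroke`, `group`,
#'   `stroke:group`, `residual` and columns `term`, `ss`, `df`, `f`,
#'   `p_value`, `partial_eta_sq`.
#' @export
two_way_anova <- function(peaks, stroke, group) {
  stroke <- factor(stroke); group <- factor(group)
  if (nlevels(stroke) < 2L || nlevels(group) < 2L) {
    abort("Each factor needs at least two levels.",
          class = "strokesense_value_error")
  }
  cell_n <- table(stroke, group)
  if (any(cell_n > 0 & cell_n < 2)) {
    abort("Each non-empty (stroke, group) cell needs >= 2 observations.",
          class = "strokesense_value_error")
  }
  fit <- stats::lm(peaks ~ stroke * group)
  a2 <- car::Anova(fit, type = 2)
  ss <- a2[["Sum Sq"]]; df <- a2[["Df"]]
  f <- a2[["F value"]]; p <- a2[["Pr(>F)"]]
  terms <- rownames(a2)
  res_i <- which(terms == "Residuals")
  ss_res <- ss[res_i]
  out <- tibble::tibble(
    term = c("stroke", "group", "stroke:group", "residual"),
    ss = c(ss[terms == "stroke"], ss[terms == "group"],
           ss[terms == "stroke:group"], ss_res),
    df = c(df[terms == "stroke"], df[terms == "group"],
           df[terms == "stroke:group"], df[res_i]),
    f = c(f[terms == "stroke"], f[terms == "group"],
          f[terms == "stroke:group"], NA_real_),
    p_value = c(p[terms == "stroke"], p[terms == "group"],
                p[terms == "stroke:group"], NA_real_)
  )
  out$partial_eta_sq <- ifelse(out$term == "residual", NA_real_,
                               partial_eta_sq(out$ss, ss_res))
  class(out) <- c("stroke_anova", class(out))
  out
}

#' Partial eta squared from sums of squares
#'
#' `SS_effect / (SS_effect + SS_residual)`, the proportion of effect-plus-
#' error variance attributable to the effect.
#'
#' @param ss_effect,ss_residual Sums of squares.
#' @return Value in \[0, 1\].
#' @export
#' @examples
#' partial_eta_sq(3.485e5, 1.220e7)  # ~0.0278
partial_eta_sq <- function(ss_effect, ss_residual) {
  ss_effect / (ss_effect + ss_residual)
}

#' Cohen's d effect size
#'
#' Standardized mean difference `(mean(a) - mean(b)) / s_pooled` with the
#' (n-1)-weighted pooled standard deviation.
#'
#' @param a,b Numeric vectors, each with at least 2 observations.
#' @return Cohen's d (positive when `a` has the larger mean).
#' @export
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) {
    abort("Each group needs at least 2 observations.",
          class = "strokesense_value_error")
  }
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  if (sp2 == 0) {
    abort("Pooled standard deviation is zero.",
          class = "strokesense_value_error")
  }
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' @export
tidy.stroke_anova <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "stroke_anova")
  out
}

#' @export
glance.stroke_anova <- function(x, ...) {
  tibble::tibble(
    n = sum(x$df) + 1L,
    df_residual = x$df[x$term == "residual"],
    ss_total = sum(x$ss)
  )
}
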