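# Cross-validation, confusion-derived metrics, Polygon Area Metric,
# classical baselines, and mutual-information feature ranking.

#' Stratified (or subject-level) fold assignment
#'
#' `stroke_level` mode stratifies by class: within each class, rows are
#' shuffled and dealt round-robin, so every fold's class count is within one
#' window of the ideal proportion. `subject_level` assigns whole
#' participants to folds (no participant spans folds), balancing class
#' counts at the participant level.
#'
#' @param labels Class label vector (each class needs >= k members).
#' @param k Number of folds (default 5).
#' @param mode `"stroke_level"` (default) or `"subject_level"`.
#' @param seed RNG seed.
#' @param participants Participant id per row (required for subject level).
#' @return An object of class `fold_plan`: list with `fold` (integer vector),
#'   `k`, `mode`, `seed`.
#' @export
make_folds <- function(labels, k = 5L, mode = c("stroke_level", "subject_level"),
                       seed = 1L, participants = NULL) {
  mode <- match.arg(mode)
  labels <- as.character(labels)
  if (any(table(labels) < k)) {
    abort("Every class needs at least k members.",
          class = "strokesense_value_error")
  }
  set.seed(seed)
  fold <- integer(length(labels))
  if (mode == "stroke_level") {
    for (cl in unique(labels)) {
      rows <- which(labels == cl)
      rows <- rows[sample.int(length(rows))]
      fold[rows] <- rep_len(seq_len(k), length(rows))
    }
  } else {
    if (is.null(participants)) {
      abort("subject_level folds need `participants`.",
            class = "strokesense_value_error")
    }
    pt <- tibble::tibble(participant = as.character(participants),
                         label = labels) |>
      dplyr::distinct(.data$participant, .keep_all = TRUE)
    pfold <- setNames(integer(nrow(pt)), pt$participant)
    for (cl in unique(pt$label)) {
      ps <- pt$participant[pt$label == cl]
      ps <- ps[sample.int(length(ps))]
      pfold[ps] <- rep_len(seq_len(k), length(ps))
    }
    fold <- unname(pfold[as.character(participants)])
  }
  structure(list(fold = fold, k = as.integer(k), mode = mode,
                 seed = as.integer(seed)),
            class = "fold_plan")
}

#' Confusion matrix and derived metrics
#'
#' Builds the 2x2 confusion matrix (rows = truth, columns = prediction) and
#' standard per-class precision, recall and F1 plus overall accuracy. The
#' elite class is the positive class for sensitivity/specificity/Jaccard.
#'
#' @param y_true,y_pred Label vectors of equal length.
#' @param levels Class levels, negative class first.
#' @return A list of class `confusion_result`: `table` (matrix), `metrics`
#'   (per-class tibble), `accuracy`.
#' @export
confusion <- function(y_true, y_pred, levels = c("amateur", "elite")) {
  if (length(y_true) != length(y_pred)) {
    abort("y_true and y_pred must have equal length.",
          class = "strokesense_value_error")
  }
  yt <- factor(as.character(y_true), levels = levels)
  yp <- factor(as.character(y_pred), levels = levels)
  tab <- table(truth = yt, prediction = yp)
  metrics <- purrr::map(levels, function(cl) {
    tp <- tab[cl, cl]
    fp <- sum(tab[, cl]) - tp
    fn <- sum(tab[cl, ]) - tp
    precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
      2 * precision * recall / (precision + recall)
    } else NA_real_
    tibble::tibble(class = cl, precision = precision, recall = recall, f1 = f1)
  }) |> dplyr::bind_rows()
  structure(list(table = unclass(tab), metrics = metrics,
                 accuracy = sum(diag(tab)) / sum(tab)),
            class = "confusion_result")
}

#' @export
print.confusion_result <- function(x, ...) {
  print(x$table)
  cat(sprintf("accuracy %.4f\n", x$accuracy))
  invisible(x)
}

#' Area under the ROC curve
#'
#' Trapezoidal AUC over score thresholds (elite scores expected higher).
#'
#' @param y_true Labels (both classes must be present).
#' @param scores Numeric scores (e.g. elite-class probability).
#' @param levels Class levels, negative class first.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(y_true, scores, levels = c("amateur", "elite")) {
  yt <- factor(as.character(y_true), levels = levels)
  if (any(table(yt) == 0)) {
    abort("Both classes must be present.", class = "strokesense_value_error")
  }
  r <- pROC::roc(response = yt, predictor = scores, levels = levels,
                 direction = "<", quiet = TRUE)
  as.numeric(pROC::auc(r))
}

#' Jaccard index from a confusion matrix
#'
#' `TP / (TP + FP + FN)` with elite as the positive class.
#'
#' @param cm A `confusion_result` or 2x2 matrix (rows truth, elite second).
#' @return Jaccard index in \[0, 1\].
#' @export
jaccard <- function(cm) {
  tab <- if (inherits(cm, "confusion_result")) cm$table else cm
  tp <- tab[2, 2]; fp <- tab[1, 2]; fn <- tab[2, 1]
  tp / (tp + fp + fn)
}

PAM_METRICS <- c("CA", "SE", "SP", "AUC", "JI", "FM")

#' Polygon Area Metric
#'
#' Places the six metrics — classification accuracy (CA), sensitivity (SE),
#' specificity (SP), AUC, Jaccard index (JI) and F-measure (FM), in this
#' fixed order — on the spokes of a regular hexagon at their values as radii
#' and reports the polygon area normalized by the maximal hexagon area
#' `3*sqrt(3)/2`. Uniform metrics r give PAM = r^2; all ones give 1.
#'
#' @param metrics Numeric vector of the six metrics in \[0, 1\], order
#'   CA, SE, SP, AUC, JI, FM.
#' @return An object of class `pam_score`: list with `pam` and `metrics`.
#' @export
pam <- function(metrics) {
  if (length(metrics) != 6L || any(is.na(metrics)) ||
      any(metrics < 0 | metrics > 1)) {
    abort("`metrics` must be six values in [0, 1].",
          class = "strokesense_value_error")
  }
  r <- unname(metrics)
  area <- 0.5 * sin(pi / 3) * sum(r * r[c(2:6, 1)])
  structure(list(pam = area / (3 * sqrt(3) / 2),
                 metrics = setNames(r, PAM_METRICS)),
            class = "pam_score")
}

#' @export
print.pam_score <- function(x, ...) {
  cat(sprintf("PAM %.4f  (%s)\n", x$pam,
              paste(sprintf("%s=%.3f", names(x$metrics), x$metrics),
                    collapse = ", ")))
  invisible(x)
}

#' @noRd
pam_from_predictions <- function(truth, pred, prob_elite,
                                 levels = c("amateur", "elite")) {
  cm <- confusion(truth, pred, levels)
  tab <- cm$table
  se <- tab[2, 2] / sum(tab[2, ])
  sp <- tab[1, 1] / sum(tab[1, ])
  fm <- cm$metrics$f1[cm$metrics$class == levels[2]]
  auc <- roc_auc(truth, prob_elite, levels)
  pam(c(cm$accuracy, se, sp, auc, jaccard(cm), fm))
}

#' Cross-validated training and evaluation of the deep classifier
#'
#' For each fold the entire data-dependent pipeline runs strictly on the
#' training partition: augmentation (held-out windows stay bit-identical
#' unaltered signals), input scaling, and model training; the held-out fold
#' is then predicted. Reports per-fold accuracy (mean +/- SD), pooled
#' per-stroke-type confusion matrices and metrics, and the Polygon Area
#' Metric of the pooled predictions.
#'
#' @param tensor A [window_tensor] whose `meta` has `skill` (labels) and
#'   `stroke_type`.
#' @param folds A [make_folds()] plan over the windows.
#' @param arch An [architecture_config()].
#' @param train_cfg A [train_config()].
#' @param aug_cfg An [augment_config()], or `NULL` to skip augmentation.
#' @param keep_models Keep the per-fold trained models (default FALSE).
#' @return An object of class `cv_result`: `fold_metrics`,
#'   `per_stroke` (tibble), `pooled_confusion`, `pam`, `predictions`,
#'   `mean_accuracy`, `sd_accuracy`.
#' @export
cross_validate <- function(tensor, folds, arch = architecture_config(),
                           train_cfg = train_config(),
                           aug_cfg = augment_config(), keep_models = FALSE) {
  stopifnot(inherits(tensor, "window_tensor"), inherits(folds, "fold_plan"))
  labels <- tensor$meta$skill
  n <- dim(tensor$windows)[1]
  preds <- vector("list", folds$k)
  fold_rows <- vector("list", folds$k)
  models <- list()
  for (f in seq_len(folds$k)) {
    test_idx <- which(folds$fold == f)
    train_mask <- folds$fold != f
    if (length(unique(labels[test_idx])) < 2L ||
        length(unique(labels[train_mask])) < 2L) {
      abort("A fold contains a single class.", class = "strokesense_value_error")
    }
    set.seed(train_cfg$seed + 1000L * f)
    train_tensor <- if (is.null(aug_cfg)) {
      assemble_tensor(lapply(which(train_mask), tensor_window, tensor = tensor),
                      tensor$meta[train_mask, ])
    } else {
      aug <- augment(tensor, train_mask, aug_cfg)
      keep <- aug$meta$augmented | aug$meta$source_row %in% which(train_mask)
      assemble_tensor(lapply(which(keep), tensor_window, tensor = aug),
                      aug$meta[keep, ])
    }
    cfg_f <- train_cfg; cfg_f$seed <- train_cfg$seed + f
    model <- train_model(arch, train_tensor, train_tensor$meta$skill, cfg_f)
    test_tensor <- assemble_tensor(lapply(test_idx, tensor_window,
                                          tensor = tensor),
                                   tensor$meta[test_idx, ])
    p <- predict(model, test_tensor)
    preds[[f]] <- tibble::tibble(
      row = test_idx, fold = f,
      truth = labels[test_idx],
      stroke_type = tensor$meta$stroke_type[test_idx],
      pred = p$.pred_class,
      prob_elite = p$.prob_elite
    )
    if (keep_models) models[[f]] <- model
  }
  predictions <- dplyr::bind_rows(preds)
  fold_metrics <- predictions |>
    dplyr::group_by(.data$fold) |>
    dplyr::summarise(accuracy = mean(.data$pred == .data$truth),
                     n = dplyr::n(), .groups = "drop")
  per_stroke <- predictions |>
    dplyr::group_by(.data$stroke_type) |>
    dplyr::group_modify(function(d, key) {
      cm <- confusion(d$truth, d$pred)
      dplyr::mutate(cm$metrics, accuracy = cm$accuracy, n = nrow(d))
    }) |>
    dplyr::ungroup()
  pooled <- confusion(predictions$truth, predictions$pred)
  pam_score <- pam_from_predictions(predictions$truth, predictions$pred,
                                    predictions$prob_elite)
  structure(
    list(fold_metrics = fold_metrics, per_stroke = per_stroke,
         pooled_confusion = pooled, pam = pam_score,
         predictions = predictions,
         mean_accuracy = mean(fold_metrics$accuracy),
         sd_accuracy = sd(fold_metrics$accuracy),
         models = if (keep_models) models else NULL),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d folds: accuracy %.4f (+/- %.4f), PAM %.4f\n",
              nrow(x$fold_metrics), x$mean_accuracy, x$sd_accuracy,
              x$pam$pam))
  invisible(x)
}

#' @export
tidy.cv_result <- function(x, ...) x$fold_metrics

#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(mean_accuracy = x$mean_accuracy,
                 sd_accuracy = x$sd_accuracy,
                 pam = x$pam$pam,
                 n = nrow(x$predictions))
}

# ---- classical baselines ---------------------------------------------------

#' @noRd
knn_predict <- function(train_x, train_y, test_x, k = 5L, weighted = FALSE) {
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  d2 <- outer(rowSums(test_x^2), rowSums(train_x^2), "+") -
    2 * tcrossprod(test_x, train_x)
  d2[d2 < 0] <- 0
  lv <- levels(train_y)
  score <- numeric(nrow(test_x))
  for (i in seq_len(nrow(test_x))) {
    nn <- order(d2[i, ])[seq_len(k)]
    w <- if (weighted) 1 / (sqrt(d2[i, nn]) + 1e-8) else rep(1, k)
    score[i] <- sum(w * (train_y[nn] == lv[2])) / sum(w)
  }
  list(pred = lv[(score > 0.5) + 1L], score = score)
}

#' @noRd
bagged_trees_predict <- function(train_x, train_y, test_x, n_trees = 25L) {
  df_tr <- data.frame(y = train_y, train_x, check.names = FALSE)
  df_te <- data.frame(test_x, check.names = FALSE)
  lv <- levels(train_y)
  prob <- matrix(0, nrow(df_te), 1L)
  for (b in seq_len(n_trees)) {
    rows <- sample.int(nrow(df_tr), replace = TRUE)
    fit <- rpart::rpart(y ~ ., data = df_tr[rows, ], method = "class",
                        control = rpart::rpart.control(cp = 0.01, xval = 0))
    prob <- prob + predict(fit, df_te, type = "prob")[, lv[2], drop = FALSE]
  }
  score <- as.numeric(prob / n_trees)
  list(pred = lv[(score > 0.5) + 1L], score = score)
}

#' @noRd
adaboost_predict <- function(train_x, train_y, test_x, n_rounds = 30L) {
  # AdaBoost.M1 with depth-1 rpart stumps
  df_tr <- data.frame(y = train_y, train_x, check.names = FALSE)
  df_te <- data.frame(test_x, check.names = FALSE)
  lv <- levels(train_y)
  y01 <- ifelse(train_y == lv[2], 1, -1)
  w <- rep(1 / nrow(df_tr), nrow(df_tr))
  agg <- numeric(nrow(df_te))
  for (m in seq_len(n_rounds)) {
    fit <- rpart::rpart(y ~ ., data = df_tr, weights = w, method = "class",
                        control = rpart::rpart.control(maxdepth = 1, cp = -1,
                                                       minsplit = 2, xval = 0))
    htr <- ifelse(predict(fit, df_tr, type = "class") == lv[2], 1, -1)
    err <- sum(w * (htr != y01))
    if (err >= 0.5) break
    alpha <- 0.5 * log((1 - max(err, 1e-10)) / max(err, 1e-10))
    hte <- ifelse(predict(fit, df_te, type = "class") == lv[2], 1, -1)
    agg <- agg + alpha * hte
    if (err <= 1e-10) break   # perfect stump: nothing left to reweight
    w <- w * exp(-alpha * y01 * htr)
    w <- w / sum(w)
  }
  score <- 1 / (1 + exp(-2 * agg))
  list(pred = lv[(agg > 0) + 1L], score = score)
}

#' Registry of classical baseline learners
#'
#' Seven classical families plus the distance-weighted kNN variant:
#' RBF-SVM, bagged trees, random forest, kNN, weighted kNN, naive Bayes,
#' AdaBoost and LDA. Each entry is a function
#' `(train_x, train_y, test_x) -> list(pred, score)` where `score` is the
#' elite-class probability or decision score.
#'
#' @return Named list of learner functions.
#' @export
baseline_registry <- function() {
  list(
    rbf_svm = function(xtr, ytr, xte) {
      fit <- e1071::svm(as.matrix(xtr), ytr, kernel = "radial",
                        probability = TRUE)
      pr <- predict(fit, as.matrix(xte), probability = TRUE)
      list(pred = as.character(pr),
           score = attr(pr, "probabilities")[, levels(ytr)[2]])
    },
    bagged_trees = function(xtr, ytr, xte) bagged_trees_predict(xtr, ytr, xte),
    random_forest = function(xtr, ytr, xte) {
      fit <- randomForest::randomForest(as.matrix(xtr), ytr, ntree = 200)
      list(pred = as.character(predict(fit, as.matrix(xte))),
           score = predict(fit, as.matrix(xte), type = "prob")[, levels(ytr)[2]])
    },
    knn = function(xtr, ytr, xte) knn_predict(xtr, ytr, xte, weighted = FALSE),
    weighted_knn = function(xtr, ytr, xte) knn_predict(xtr, ytr, xte,
                                                       weighted = TRUE),
    naive_bayes = function(xtr, ytr, xte) {
      fit <- e1071::naiveBayes(as.matrix(xtr), ytr)
      list(pred = as.character(predict(fit, as.matrix(xte))),
           score = predict(fit, as.matrix(xte), type = "raw")[, levels(ytr)[2]])
    },
    adaboost = function(xtr, ytr, xte) adaboost_predict(xtr, ytr, xte),
    lda = function(xtr, ytr, xte) {
      fit <- MASS::lda(as.matrix(xtr), grouping = ytr)
      pr <- predict(fit, as.matrix(xte))
      list(pred = as.character(pr$class),
           score = pr$posterior[, levels(ytr)[2]])
    }
  )
}

#' Cross-validated classical baselines on handcrafted features
#'
#' Per fold, z-score parameters and the top-k MRMR feature subset are fitted
#' strictly on the training partition, then each requested classical model is
#' trained and evaluated on the held-out fold.
#'
#' @param features Feature tibble/matrix (N x P).
#' @param labels Class labels (length N).
#' @param folds A [make_folds()] plan.
#' @param models Model names from [baseline_registry()] (default: all).
#' @param k_select Number of MRMR-selected features (default 50, capped at P).
#' @param seed RNG seed for the stochastic learners.
#' @return A list with `summary` (tibble: model, mean/sd accuracy) and
#'   `fold_metrics` (tibble: model, fold, accuracy, auc).
#' @export
classical_baselines <- function(features, labels, folds,
                                models = names(baseline_registry()),
                                k_select = 50L, seed = 1L) {
  registry <- baseline_registry()
  unknown <- setdiff(models, names(registry))
  if (length(unknown)) {
    abort(paste0("Unknown model(s): ", paste(unknown, collapse = ", ")),
          class = "strokesense_value_error")
  }
  x <- as.matrix(features)
  y <- factor(as.character(labels))
  rows <- list()
  for (f in seq_len(folds$k)) {
    test_idx <- which(folds$fold == f)
    train_idx <- which(folds$fold != f)
    zs <- zscore_fit(x, train_idx)
    xs <- as.matrix(zscore_apply(zs, x))
    sel <- mrmr_select(xs[train_idx, , drop = FALSE], y[train_idx],
                       k = min(k_select, ncol(xs)))
    cols <- sel$index
    set.seed(seed + f)
    for (mname in models) {
      res <- registry[[mname]](xs[train_idx, cols, drop = FALSE], y[train_idx],
                               xs[test_idx, cols, drop = FALSE])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        model = mname, fold = f,
        accuracy = mean(res$pred == as.character(y[test_idx])),
        auc = roc_auc(y[test_idx], res$score, levels = levels(y))
      )
    }
  }
  fold_metrics <- dplyr::bind_rows(rows)
  list(
    summary = fold_metrics |>
      dplyr::group_by(.data$model) |>
      dplyr::summarise(mean_accuracy = mean(.data$accuracy),
                       sd_accuracy = sd(.data$accuracy),
                       mean_auc = mean(.data$auc), .groups = "drop") |>
      dplyr::arrange(dplyr::desc(.data$mean_accuracy)),
    fold_metrics = fold_metrics
  )
}

#' Mutual-information feature ranking
#'
#' Ranks every feature by its mutual information with the class label
#' (10-bin equal-frequency discretization, the same estimator used in MRMR),
#' in descending order with deterministic ties (lower column index first).
#'
#' @param features Feature tibble/matrix.
#' @param labels Class labels (>= 2 classes).
#' @return A tibble with `rank`, `feature`, `mi`.
#' @export
mi_ranking <- function(features, labels) {
  mi <- feature_mi(features, labels)
  nm <- colnames(as.matrix(features))
  if (is.null(nm)) nm <- paste0("V", seq_along(mi))
  ord <- order(-mi, seq_along(mi))
  tibble::tibble(rank = seq_along(mi), feature = nm[ord], mi = unname(mi[ord]))
}
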