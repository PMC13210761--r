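test_that("stratified folds keep class proportions within one window", {
  lab <- rep(c("a", "b"), c(60, 40))
  fp <- make_folds(lab, k = 5, seed = 1)
  counts <- table(fp$fold, lab)
  expect_true(all(counts[, "a"] == 12L))
  expect_true(all(counts[, "b"] == 8L))

  lab2 <- rep(c("a", "b"), c(61, 40))
  fp2 <- make_folds(lab2, k = 5, seed = 1)
  expect_true(all(table(fp2$fold, lab2)[, "a"] %in% c(12L, 13L)))

  expect_error(make_folds(rep(c("a", "b"), c(3, 97)), k = 5),
               class = "strokesense_value_error")
})

test_that("subject-level folds never split a participant", {
  participants <- rep(sprintf("P%02d", 1:10), each = 12)
  lab <- rep(rep(c("elite", "amateur"), 5), each = 12)
  fp <- make_folds(lab, k = 5, mode = "subject_level", seed = 2,
                   participants = participants)
  spread <- tapply(fp$fold, participants, function(f) length(unique(f)))
  expect_true(all(spread == 1L))
  expect_error(make_folds(lab, k = 5, mode = "subject_level"),
               class = "strokesense_value_error")
})

test_that("confusion metrics reproduce the printed forehand worked example", {
  # 948 amateur windows (942 correct), 605 elite (603 correct)
  y_true <- rep(c("amateur", "elite"), c(948, 605))
  y_pred <- c(rep("amateur", 942), rep("elite", 6),
              rep("elite", 603), rep("amateur", 2))
  cm <- confusion(y_true, y_pred)
  expect_equal(cm$table["amateur", "amateur"], 942)
  expect_equal(cm$table["elite", "elite"], 603)
  expect_equal(round(cm$accuracy, 2), 0.99)
  # accuracy equals the support-weighted mean of per-class recalls
  support <- rowSums(cm$table)
  expect_equal(cm$accuracy,
               sum(cm$metrics$recall * support) / sum(support))
})

test_that("degenerate predictions yield the expected confusion metrics", {
  cm1 <- confusion(rep(c("amateur", "elite"), 10),
                   rep(c("amateur", "elite"), 10))
  expect_true(all(unlist(cm1$metrics[, c("precision", "recall", "f1")]) == 1))
  expect_equal(cm1$accuracy, 1)

  cm2 <- confusion(rep(c("amateur", "elite"), 25), rep("amateur", 50))
  expect_equal(cm2$metrics$recall[cm2$metrics$class == "elite"], 0)
  expect_equal(cm2$accuracy, 0.5)

  expect_error(confusion(c("a", "b"), "a"), class = "strokesense_value_error")
})

test_that("AUC and Jaccard behave at their reference points", {
  y <- rep(c("amateur", "elite"), each = 20)
  expect_equal(roc_auc(y, c(rep(0.1, 20), rep(0.9, 20))), 1)

  set.seed(3)
  yl <- sample(rep(c("amateur", "elite"), 500))
  expect_equal(roc_auc(yl, runif(1000)), 0.5, tolerance = 0.03 / 0.5)

  expect_error(roc_auc(rep("elite", 5), runif(5)),
               class = "strokesense_value_error")

  cm <- matrix(c(5, 0, 0, 3), 2, 2)   # TP = 3, FP = 0, FN = 0
  expect_equal(jaccard(cm), 1)
  expect_equal(jaccard(matrix(c(4, 1, 0, 3), 2, 2, byrow = FALSE)), 0.75)
})

test_that("PAM follows the hexagon-area formula", {
  expect_equal(pam(rep(1, 6))$pam, 1)
  expect_equal(pam(rep(0.5, 6))$pam, 0.25)
  expect_equal(pam(rep(0, 6))$pam, 0)
  # quadratic scaling law on a grid of uniform metric values
  for (r in seq(0, 1, by = 0.1)) {
    expect_equal(pam(rep(r, 6))$pam, r^2, tolerance = 1e-12)
  }
  # adjacency order matters: permuting non-uniform metrics changes the score
  m <- c(1, 0.2, 1, 0.2, 1, 0.2)
  expect_false(isTRUE(all.equal(pam(m)$pam, pam(c(1, 1, 1, 0.2, 0.2, 0.2))$pam)))
  # monotone non-decreasing in each metric
  base <- c(0.7, 0.8, 0.6, 0.9, 0.5, 0.7)
  for (i in 1:6) {
    up <- base; up[i] <- up[i] + 0.1
    expect_gte(pam(up)$pam, pam(base)$pam)
  }
  expect_error(pam(c(1, 1, 1, 1, 1, 1.2)), class = "strokesense_value_error")
  expect_error(pam(rep(0.5, 5)), class = "strokesense_value_error")
})

test_that("the baseline registry holds the eight classical families", {
  reg <- baseline_registry()
  expect_setequal(names(reg),
                  c("rbf_svm", "bagged_trees", "random_forest", "knn",
                    "weighted_knn", "naive_bayes", "adaboost", "lda"))
  expect_error(
    classical_baselines(matrix(rnorm(40), 20), rep(c("a", "b"), 10),
                        make_folds(rep(c("a", "b"), 10), k = 2),
                        models = "deep_forest"),
    class = "strokesense_value_error")
})

test_that("perfect single-feature separation is learned by every baseline", {
  set.seed(4)
  n <- 80
  y <- rep(c("amateur", "elite"), each = n / 2)
  x <- cbind(sep = ifelse(y == "elite", 5, -5) + rnorm(n, 0, 0.1),
             j1 = rnorm(n), j2 = rnorm(n))
  folds <- make_folds(y, k = 4, seed = 5)
  res <- classical_baselines(x, y, folds, k_select = 3)
  expect_equal(nrow(res$summary), 8L)
  expect_true(all(res$summary$mean_accuracy == 1))
})

test_that("mutual-information ranking finds the label-aligned feature", {
  set.seed(6)
  n <- 400
  y <- rep(c("a", "b"), n / 2)
  x <- cbind(oracle = as.numeric(y == "b"), n1 = rnorm(n), n2 = rnorm(n))
  r <- mi_ranking(x, y)
  expect_equal(r$feature[1], "oracle")
  # independent noise has MI near the estimator bias floor
  expect_lt(r$mi[r$feature == "n1"], 0.05)
  expect_gt(r$mi[1], log(2) * 0.9)
})

test_that("wavelet/TKE channel signatures drive the MI ranking", {
  # classes differ only in dominant-wrist high-frequency burst energy
  set.seed(7)
  wins <- list(); lab <- character(0)
  for (i in 1:60) {
    w <- matrix(rnorm(1200, 0, 0.3), 100, 12)
    cls <- if (i %% 2 == 0) "elite" else "amateur"
    if (cls == "elite") {
      w[, 1] <- w[, 1] + rep(c(1, -1), 50) * 2   # alternating d1-band burst
    }
    wins[[i]] <- w; lab <- c(lab, cls)
  }
  tensor <- assemble_tensor(wins, tibble::tibble(
    participant_id = "S", stroke_type = "forehand", skill = lab))
  fm <- extract_all(tensor)
  r <- mi_ranking(fm, lab)
  expect_match(r$feature[1], "^F1_(e_d1|tke|wl|rms|mav|activity|mean_freq|median_freq|mobility)")
})

test_that("cross-validation hygiene: scalers and selections ignore held-out rows", {
  set.seed(8)
  x <- matrix(rnorm(600), 30, 20)
  colnames(x) <- paste0("f", 1:20)
  y <- rep(c("a", "b"), 15)
  train_rows <- 1:20
  fit1 <- zscore_fit(x, train_rows)
  sel1 <- mrmr_select(x[train_rows, ], y[train_rows], k = 5)
  x2 <- x
  x2[21:30, ] <- x2[21:30, ] + 100   # corrupt held-out rows arbitrarily
  fit2 <- zscore_fit(x2, train_rows)
  sel2 <- mrmr_select(x2[train_rows, ], y[train_rows], k = 5)
  expect_identical(fit1$mean, fit2$mean)
  expect_identical(fit1$sd, fit2$sd)
  expect_identical(sel1$index, sel2$index)
})

test_that("augmented sets are invariant to held-out window content", {
  tensor <- toy_tensor(8)
  mask <- rep(c(TRUE, FALSE), 4)
  set.seed(9)
  aug1 <- augment(tensor, mask)
  tensor2 <- tensor
  tensor2$windows[which(!mask), , , ] <- 0   # blank every held-out window
  set.seed(9)
  aug2 <- augment(tensor2, mask)
  n <- dim(tensor$windows)[1]
  aug_rows <- which(aug1$meta$augmented)
  expect_identical(aug1$windows[aug_rows, , , ], aug2$windows[aug_rows, , , ])
})
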