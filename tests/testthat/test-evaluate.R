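test_that("metric formulas match hand calculations", {
  # diagonal multi-class matrix: everything 1
  cm <- diag(15L, 5); dimnames(cm) <- list(true = 0:4, predicted = 0:4)
  m <- metrics_from_confusion(cm)
  expect_equal(unlist(m[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))
  # binary TP=3 FP=1 FN=1 TN=5
  cm2 <- matrix(c(3L, 1L, 1L, 5L), 2, byrow = TRUE,
                dimnames = list(true = 0:1, predicted = 0:1))
  m2 <- metrics_from_confusion(cm2)
  expect_equal(m2$accuracy, 0.8)
  expect_equal(unname(m2$precision), 0.75)
  expect_equal(unname(m2$recall), 0.75)
  expect_equal(unname(m2$f1), 0.75)
  # degenerate classifier: no predicted positives
  cm3 <- matrix(c(0L, 10L, 0L, 10L), 2, byrow = TRUE)
  expect_warning(m3 <- metrics_from_confusion(cm3), "zero denominator")
  expect_equal(unname(unlist(m3)), c(0.5, 0, 0, 0))
  expect_error(metrics_from_confusion(matrix(0, 2, 2)), "empty")
})

test_that("F1 is the harmonic mean of precision and recall in every row", {
  set.seed(2)
  for (rep in 1:20) {
    cm <- matrix(sample(0:20, 4), 2)
    if (sum(cm) == 0) next
    m <- suppressWarnings(metrics_from_confusion(cm))
    hm <- if (m$precision + m$recall > 0)
      2 * m$precision * m$recall / (m$precision + m$recall) else 0
    expect_equal(unname(m$f1), unname(hm), tolerance = 1e-12)
  }
})

test_that("confusion_matrix counts and balanced accuracy equals macro recall", {
  set.seed(7)
  truth <- rep(0:4, each = 12)
  pred <- truth
  flip <- sample(length(pred), 20)
  pred[flip] <- sample(0:4, 20, TRUE)
  cm <- confusion_matrix(truth, pred, 5L)
  expect_equal(sum(cm), 60)
  expect_equal(as.vector(rowSums(cm)), rep(12L, 5))
  m <- suppressWarnings(metrics_from_confusion(cm))
  expect_equal(m$accuracy, m$recall, tolerance = 1e-12)
})

test_that("roc_auc reproduces known values and the Mann-Whitney identity", {
  expect_equal(roc_auc(c(.9, .8, .4, .3), c(1, 0, 1, 0), 1)$auc, 0.75)
  expect_equal(roc_auc(c(.9, .8, .2, .1), c(1, 1, 0, 0), 1)$auc, 1.0)
  expect_equal(roc_auc(rep(0.5, 10), rep(0:1, 5), 1)$auc, 0.5)
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(6:30, 1)
    labels <- sample(0:1, n, TRUE)
    if (length(unique(labels)) < 2) next
    scores <- round(runif(n), sample(1:3, 1))  # force ties
    expect_equal(roc_auc(scores, labels, 1)$auc,
                 oracle_auc(scores, labels, 1), tolerance = 1e-12)
  }
  expect_error(roc_auc(runif(4), rep(1, 4), 1), "both classes")
})

test_that("gpr_distributions summarizes noise-free plans correctly", {
  ds <- generate_dataset(sim_config(n_per_class = 2, noise_sigma = 0,
                                    seed = 41))
  labs <- dataset_labels(ds)
  gd <- gpr_distributions(ds[labs %in% c(0L, 4L)])
  # noise-free normal plans: identical maps, GPR 100, zero spread
  norm <- gd$summary[gd$summary$class == "normal", ]
  expect_equal(norm$min, rep(100, nrow(norm)))
  expect_equal(norm$max, rep(100, nrow(norm)))
  # in-tolerance 2% dose errors pass 3%/3mm everywhere
  dose33 <- gd$gpr[gd$gpr$class == "dose" & gd$gpr$criterion == "3%/3mm", ]
  expect_equal(dose33$gpr, rep(100, nrow(dose33)))
  expect_true(all(dose33$pass))
  # permutation invariance in sample order
  gd2 <- gpr_distributions(rev(ds[labs %in% c(0L, 4L)]))
  expect_equal(gd2$summary[order(gd2$summary$class, gd2$summary$criterion), ],
               gd$summary[order(gd$summary$class, gd$summary$criterion), ],
               ignore_attr = TRUE)
})

test_that("binary_compare reproduces the oracle and degenerate cases", {
  ds <- generate_dataset(sim_config(n_per_class = 2, noise_sigma = 0,
                                    seed = 43))
  labs <- dataset_labels(ds)
  samples <- ds[labs %in% c(0L, 4L)]
  # perfect CNN predictions: every "X vs others" row is all ones
  truth <- vapply(samples, function(s) s$label$code, 0L)
  preds <- list(class = truth,
                probs = diag(5)[truth + 1L, ])
  tab <- suppressWarnings(binary_compare(preds, samples))
  cnn <- tab[tab$method == "CNN" & tab$pairing %in%
               c("normal vs others", "dose vs others"), ]
  expect_equal(cnn$accuracy, rep(1, 2))
  expect_equal(cnn$f1, rep(1, 2))
  # GPR rows: every in-tolerance dose plan passes -> accuracy 0.5, recall 0
  dose_rows <- tab[tab$pairing == "dose vs normal", ]
  expect_equal(nrow(dose_rows), 3)
  expect_equal(dose_rows$accuracy, rep(0.5, 3))
  expect_equal(dose_rows$recall, rep(0, 3))
  expect_equal(dose_rows$precision, rep(0, 3))
})

test_that("eval_report assembles consistent pieces", {
  ds <- generate_dataset(sim_config(n_per_class = 2, noise_sigma = 0,
                                    seed = 47))
  truth <- dataset_labels(ds)
  set.seed(1)
  probs <- matrix(runif(length(ds) * 5), ncol = 5)
  probs <- probs / rowSums(probs)
  # make predictions mostly right so every class is predicted
  probs[cbind(seq_along(truth), truth + 1L)] <- 2
  probs <- probs / rowSums(probs)
  preds <- list(probs = probs, class = max.col(probs, "first") - 1L)
  rep <- suppressWarnings(eval_report(preds, ds))
  expect_equal(sum(rep$confusion), length(ds))
  expect_true(all(rep$auc >= 0 & rep$auc <= 1))
  expect_equal(rep$metrics$accuracy, mean(preds$class == truth))
  # balanced test set: micro accuracy equals macro recall
  expect_equal(rep$metrics$accuracy, rep$metrics$recall, tolerance = 1e-12)
  # 5 CNN rows and 3 criteria x 5 GPR pairings
  expect_equal(sum(rep$comparison$method == "CNN"), 5)
  expect_equal(sum(rep$comparison$method != "CNN"), 15)
})
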