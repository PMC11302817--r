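#' Confusion matrix
#'
#' Rows are true classes, columns predicted classes.  For the binary case
#' the positive class is class 1 (row/column 1), so the cells are
#' `[TP FN; FP TN]`.
#'
#' @param truth,pred integer class codes (0-based) or factors.
#' @param n_classes number of classes (default: inferred).
#' @return integer matrix of counts with class dimnames.
#' @export
confusion_matrix <- function(truth, pred, n_classes = NULL) {
  truth <- as.integer(truth); pred <- as.integer(pred)
  if (is.null(n_classes)) n_classes <- max(truth, pred) + 1L
  cm <- matrix(0L, n_classes, n_classes,
               dimnames = list(true = 0:(n_classes - 1),
                               predicted = 0:(n_classes - 1)))
  for (i in seq_along(truth))
    cm[truth[i] + 1L, pred[i] + 1L] <- cm[truth[i] + 1L, pred[i] + 1L] + 1L
  cm
}

#' Accuracy, precision, recall and F1 from a confusion matrix
#'
#' Binary (2x2) matrices apply the textbook formulas literally with class
#' 1 positive: accuracy `(TP+TN)/N`, recall `TP/(TP+FN)`, precision
#' `TP/(TP+FP)` and F1 the harmonic mean of precision and recall.  Larger
#' matrices compute per-class one-vs-rest precision/recall/F1 and
#' macro-average them; accuracy is the trace over the total.  Cells with a
#' zero denominator (a never-predicted or absent class) are defined as 0,
#' with a warning.
#'
#' @param cm a [confusion_matrix()].
#' @return list with `accuracy`, `precision`, `recall`, `f1` (and
#'   `per_class` for the multi-class case).
#' @export
metrics_from_confusion <- function(cm) {
  cm <- as.matrix(cm)
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  safe_div <- function(num, den) {
    out <- ifelse(den > 0, num / ifelse(den > 0, den, 1), 0)
    if (any(den == 0 & num >= 0))
      warning("zero denominator in a metric; defining the value as 0",
              call. = FALSE)
    out
  }
  tp <- diag(cm)
  prec <- safe_div(tp, colSums(cm))
  rec <- safe_div(tp, rowSums(cm))
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  if (nrow(cm) == 2L) {
    list(accuracy = sum(tp) / total, precision = prec[1],
         recall = rec[1], f1 = f1[1])
  } else {
    list(accuracy = sum(tp) / total,
         precision = mean(prec), recall = mean(rec), f1 = mean(f1),
         per_class = data.frame(class = as.integer(rownames(cm)),
                                precision = as.numeric(prec),
                                recall = as.numeric(rec),
                                f1 = as.numeric(f1)))
  }
}

#' One-vs-rest ROC curve and AUC
#'
#' Sweeps a threshold over the positive-class score; the AUC is computed
#' by the trapezoidal rule over the resulting curve, which with tied
#' scores grouped equals the rank-sum (Mann-Whitney) statistic normalized
#' by `n_pos * n_neg`.
#'
#' @param scores numeric score for the positive class per instance.
#' @param labels true classes.
#' @param positive the value of `labels` treated as positive.
#' @return list with `auc` and `curve` (data.frame of `fpr`, `tpr`).
#' @export
roc_auc <- function(scores, labels, positive) {
  pos <- labels == positive
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be present to compute a ROC curve")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  # collapse tied scores into single threshold steps
  last <- c(s[-1] != s[-length(s)], TRUE)
  tpr <- cumsum(p)[last] / n_pos
  fpr <- cumsum(!p)[last] / n_neg
  tpr <- c(0, tpr); fpr <- c(0, fpr)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(auc = auc, curve = data.frame(fpr = fpr, tpr = tpr))
}

#' Per-class GPR distributions under several criteria
#'
#' Runs [gamma_analysis()] for every sample under every criterion and
#' summarizes the gamma pass rates per (class, criterion) with five-number
#' summaries — the numbers behind a per-class GPR box plot.
#'
#' @param samples a `qa_dataset` or list of `plan_sample`s.
#' @param criteria_list named list of [gamma_criteria()]
#'   (default [clinical_criteria()]).
#' @return list with `gpr` (long data.frame: `plan_id`, `class`,
#'   `criterion`, `gpr`, `pass`) and `summary` (per class x criterion:
#'   min, q1, median, q3, max).
#' @export
gpr_distributions <- function(samples, criteria_list = clinical_criteria()) {
  if (length(samples) == 0) stop("at least one sample is required")
  rows <- list()
  for (cn in names(criteria_list)) {
    crit <- criteria_list[[cn]]
    for (s in samples) {
      r <- gamma_analysis(s$measured, s$calculated, crit)
      rows[[length(rows) + 1L]] <-
        data.frame(plan_id = s$plan_id, class = s$label$class,
                   criterion = cn, gpr = r$gpr, pass = r$pass)
    }
  }
  gpr <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(gpr, list(gpr$class, gpr$criterion),
                                      drop = TRUE), function(d) {
    q <- stats::quantile(d$gpr, c(0, .25, .5, .75, 1), names = FALSE)
    data.frame(class = d$class[1], criterion = d$criterion[1],
               min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5])
  }))
  rownames(summ) <- NULL
  list(gpr = gpr, summary = summ)
}

#' Binary-collapse comparison of the CNN against GPR thresholding
#'
#' Collapses the multi-class problem into the binary tasks of the
#' comparison tables.  CNN rows ("X vs others") use the full test set with
#' "predicted X" as positive.  GPR rows for an error class X ("X vs
#' normal") use only the normal and X-error samples, call a plan an error
#' when it fails the criterion, and treat the error class as positive.
#' The GPR "normal vs others" rows use the full test set with normal
#' positive and "pass" meaning predicted normal.
#'
#' @param preds a [predict.cnn_ensemble()] result for `samples` (or any
#'   list with a `class` vector of hard labels).
#' @param samples the evaluated `plan_sample`s, same order as `preds`.
#' @param gpr a [gpr_distributions()] result for the same samples (or
#'   `NULL` to compute it).
#' @param criteria_list criteria to evaluate (default
#'   [clinical_criteria()]).
#' @return data.frame: `pairing`, `method`, `accuracy`, `precision`,
#'   `recall`, `f1`.
#' @export
binary_compare <- function(preds, samples,
                           gpr = NULL,
                           criteria_list = clinical_criteria()) {
  truth <- vapply(samples, function(s) s$label$code, 0L)
  if (is.null(gpr)) gpr <- gpr_distributions(samples, criteria_list)
  gd <- gpr$gpr
  classes <- c(normal = 0L, gantry = 1L, collimator = 2L, couch = 3L,
               dose = 4L)
  out <- list()
  add <- function(pairing, method, cm) {
    m <- suppressWarnings(metrics_from_confusion(cm))
    out[[length(out) + 1L]] <<-
      data.frame(pairing = pairing, method = method,
                 accuracy = m$accuracy, precision = unname(m$precision),
                 recall = unname(m$recall), f1 = unname(m$f1))
  }
  for (cl in names(classes)) {
    code <- classes[[cl]]
    # CNN: X vs others on the full set
    cm <- confusion_matrix(as.integer(truth != code),
                           as.integer(preds$class != code), 2L)
    add(sprintf("%s vs others", cl), "CNN", cm)
    for (cn in names(criteria_list)) {
      sub <- gd[gd$criterion == cn, ]
      sub <- sub[match(vapply(samples, function(s) s$plan_id, ""),
                       sub$plan_id), ]
      if (cl == "normal") {
        # full set; positive = normal, predicted normal iff pass
        cm <- confusion_matrix(as.integer(truth != 0L),
                               as.integer(!sub$pass), 2L)
        add("normal vs others", cn, cm)
      } else {
        keep <- truth %in% c(0L, code)
        if (!any(keep)) stop("empty pairing subset")
        # positive = the error class, predicted error iff fail
        cm <- confusion_matrix(as.integer(truth[keep] == 0L),
                               as.integer(sub$pass[keep]), 2L)
        add(sprintf("%s vs normal", cl), cn, cm)
      }
    }
  }
  do.call(rbind, out)
}

#' Full evaluation report
#'
#' Multi-class metrics on the ensemble predictions, one-vs-rest AUC per
#' class, the confusion matrix, per-criterion GPR distributions, and the
#' binary-collapse CNN-vs-GPR table.
#'
#' @param preds a [predict.cnn_ensemble()] result.
#' @param samples evaluated `plan_sample`s, same order.
#' @param criteria_list criteria (default [clinical_criteria()]).
#' @return object of class `eval_report`.
#' @export
eval_report <- function(preds, samples, criteria_list = clinical_criteria()) {
  truth <- vapply(samples, function(s) s$label$code, 0L)
  cm <- confusion_matrix(truth, preds$class, 5L)
  metrics <- suppressWarnings(metrics_from_confusion(cm))
  auc <- vapply(0:4, function(cl)
    roc_auc(preds$probs[, cl + 1], truth, cl)$auc, 0)
  names(auc) <- names(ERROR_CLASSES)
  gpr <- gpr_distributions(samples, criteria_list)
  comparison <- binary_compare(preds, samples, gpr, criteria_list)
  structure(list(confusion = cm, metrics = metrics, auc = auc,
                 gpr = gpr, comparison = comparison),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> accuracy %.3f, precision %.3f, recall %.3f, F1 %.3f\n",
              x$metrics$accuracy, x$metrics$precision, x$metrics$recall,
              x$metrics$f1))
  cat("one-vs-rest AUC:\n"); print(round(x$auc, 4))
  invisible(x)
}
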