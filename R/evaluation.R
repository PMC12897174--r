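#' One-vs-rest per-class and macro ROC-AUC
#'
#' For each class the AUC of its score column against the binary
#' class-vs-rest dichotomy, computed by the rank (Mann-Whitney) method with
#' midrank tie handling — tied score pairs contribute 1/2, identical to the
#' trapezoidal ROC area. The macro AUC is the unweighted mean over classes.
#' A class absent from `labels` has no defined AUC: it is reported as `NA`
#' and excluded from the macro mean with a warning.
#'
#' @param scores `n x K` matrix of class scores (columns named by class, or
#'   in `classes` order); rows are items.
#' @param labels true class per item.
#' @param classes the class alphabet (default: column names of `scores`).
#' @return list with `perClass` (named AUC vector) and `macro`.
#' @export
rocAucOvr <- function(scores, labels, classes = colnames(scores)) {
  if (is.null(classes))
    stop("rocAucOvr: classes must be given when scores has no column names")
  stopifnot(nrow(scores) == length(labels), ncol(scores) == length(classes))
  perClass <- setNames(rep(NA_real_, length(classes)), classes)
  for (k in seq_along(classes)) {
    pos <- labels == classes[k]
    if (any(pos) && any(!pos))
      perClass[k] <- aucMannWhitney(scores[, k], pos)
  }
  if (anyNA(perClass))
    warning("rocAucOvr: class(es) absent from labels excluded from macro AUC: ",
            paste(names(perClass)[is.na(perClass)], collapse = ", "))
  list(perClass = perClass, macro = mean(perClass, na.rm = TRUE))
}

# AUC via midranks: (sum of positive ranks - n1(n1+1)/2) / (n1 * n0);
# ties get the average rank, so tied pairs contribute exactly 1/2
aucMannWhitney <- function(score, positive) {
  r <- rank(score, ties.method = "average")
  n1 <- sum(positive)
  n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion matrix, accuracy and macro F1
#'
#' Counts by (true, predicted) over the full class alphabet; accuracy is
#' the diagonal fraction; per-class F1 is `2PR/(P+R)` with the convention
#' that a class with `P + R = 0` scores 0; macro F1 is the unweighted mean.
#'
#' @param predictions predicted class per item.
#' @param labels true class per item, same length.
#' @param classes class alphabet (default: union of observed values).
#' @param foldIndex optional fold number recorded in the report.
#' @return an [EvalReport-class] with `perClassAuc` unset (all `NA`).
#' @export
confusionAndF1 <- function(predictions, labels,
                           classes = sort(unique(c(predictions, labels))),
                           foldIndex = NA_integer_) {
  if (!length(labels)) stop("confusionAndF1: empty input")
  stopifnot(length(predictions) == length(labels))
  conf <- table(factor(labels, levels = classes),
                factor(predictions, levels = classes))
  conf <- unclass(matrix(as.integer(conf), nrow = length(classes),
                         dimnames = list(true = classes, predicted = classes)))
  acc <- sum(diag(conf)) / sum(conf)
  f1 <- vapply(seq_along(classes), function(k) {
    tp <- conf[k, k]
    prec <- if (sum(conf[, k]) > 0) tp / sum(conf[, k]) else 0
    rec <- if (sum(conf[k, ]) > 0) tp / sum(conf[k, ]) else 0
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }, numeric(1))
  new("EvalReport",
      perClassAuc = setNames(rep(NA_real_, length(classes)), classes),
      macroAuc = NA_real_, accuracy = acc, macroF1 = mean(f1),
      confusion = conf, nTest = length(labels),
      foldIndex = as.integer(foldIndex))
}

#' Full evaluation of a probability matrix
#'
#' Combines [rocAucOvr()] (on the probability scores) and
#' [confusionAndF1()] (on the argmax predictions) into one report.
#'
#' @param probs `K x n` class-probability matrix (rows = classes in
#'   `classes` order).
#' @param labels true class per item.
#' @param classes class alphabet.
#' @param foldIndex optional fold number.
#' @return an [EvalReport-class].
#' @export
evaluatePredictions <- function(probs, labels, classes,
                                foldIndex = NA_integer_) {
  pred <- classes[apply(probs, 2L, which.max)]
  rep_ <- confusionAndF1(pred, labels, classes, foldIndex)
  auc <- rocAucOvr(t(probs), labels, classes)
  rep_@perClassAuc <- auc$perClass
  rep_@macroAuc <- auc$macro
  rep_
}

#' Paired t-test between per-fold metrics of two models
#'
#' Two-sided paired t-test on the fold-wise differences `a - b`
#' (delegating to [stats::t.test()]), with explicit handling of the
#' degenerate zero-variance cases: all-zero differences give `t = 0, p = 1`;
#' constant nonzero differences give `p = 0` with the degenerate flag set.
#'
#' @param a,b per-fold metric vectors, paired by fold (equal length >= 2).
#' @param metric name recorded in the result.
#' @return a [PairedTestResult-class].
#' @export
pairedTTest <- function(a, b, metric = "accuracy") {
  if (length(a) != length(b))
    stop("pairedTTest: a and b must be paired (equal length)")
  if (length(a) < 2L) stop("pairedTTest: need at least 2 folds")
  d <- a - b
  n <- length(d)
  if (sd(d) == 0) {
    if (all(d == 0))
      return(new("PairedTestResult", metric = metric, differences = d,
                 statistic = 0, pValue = 1, df = n - 1, degenerate = TRUE))
    return(new("PairedTestResult", metric = metric, differences = d,
               statistic = sign(mean(d)) * Inf, pValue = 0, df = n - 1,
               degenerate = TRUE))
  }
  tt <- t.test(a, b, paired = TRUE)
  new("PairedTestResult", metric = metric, differences = d,
      statistic = unname(tt$statistic), pValue = tt$p.value,
      df = unname(tt$parameter), degenerate = FALSE)
}

#' Tidy training curves from one or two run histories
#'
#' Returns the epoch-indexed history as a plain table, optionally joined
#' with a second run for side-by-side comparison (suffixes `_a`/`_b` plus
#' the per-epoch accuracy difference).
#'
#' @param history data.frame with columns `epoch, lr, train_loss,
#'   train_acc, val_loss, val_acc` (as produced by [trainModel()]).
#' @param other optional second history to compare against.
#' @return data.frame of curves.
#' @export
trainingCurves <- function(history, other = NULL) {
  if (!nrow(history)) stop("trainingCurves: empty history")
  if (is.null(other)) return(history)
  n <- min(nrow(history), nrow(other))
  a <- history[seq_len(n), ]
  b <- other[seq_len(n), ]
  out <- data.frame(epoch = a$epoch)
  for (cl in setdiff(names(a), "epoch")) {
    out[[paste0(cl, "_a")]] <- a[[cl]]
    out[[paste0(cl, "_b")]] <- b[[cl]]
  }
  out$val_acc_diff <- a$val_acc - b$val_acc
  out
}

#' Plot loss and accuracy curves
#'
#' Base-graphics convenience: validation loss and accuracy per epoch, one
#' panel each, for one or more runs.
#'
#' @param histories named list of history data.frames.
#' @export
plotTrainingCurves <- function(histories) {
  stopifnot(length(histories) >= 1L)
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  cols <- seq_along(histories)
  for (what in c("val_loss", "val_acc")) {
    rng <- range(unlist(lapply(histories, `[[`, what)))
    graphics::plot(NULL, xlim = c(1, max(vapply(histories, nrow, 1L))),
                   ylim = rng, xlab = "epoch",
                   ylab = sub("_", " ", what))
    for (i in cols)
      graphics::lines(histories[[i]]$epoch, histories[[i]][[what]],
                      col = i, lwd = 2)
    graphics::legend("topright", legend = names(histories), col = cols,
                     lwd = 2, bty = "n")
  }
  invisible(NULL)
}
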