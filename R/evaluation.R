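#' 2x2 confusion matrix for binary trait classification
#'
#' Counts with positive class = high: \code{a} true-high predicted-high,
#' \code{b} true-low predicted-high, \code{c} true-high predicted-low,
#' \code{d} true-low predicted-low.
#'
#' @param pred predicted labels (low/high or 0/1).
#' @param truth true labels.
#' @return object of class \code{"confusion_matrix"}: named integer vector
#'   (a, b, c, d) with attribute \code{n}.
#' @examples
#' confusion(c(1, 1, 0, 0), c(1, 0, 0, 0))
#' @export
confusion <- function(pred, truth) {
  pred <- as_label(pred); truth <- as_label(truth)
  if (length(pred) != length(truth))
    stop("'pred' and 'truth' have different lengths", call. = FALSE)
  out <- c(a = sum(pred == "high" & truth == "high"),
           b = sum(pred == "high" & truth == "low"),
           c = sum(pred == "low" & truth == "high"),
           d = sum(pred == "low" & truth == "low"))
  structure(as.integer(out), names = names(out), n = length(pred),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(x, 2, 2, byrow = TRUE,
              dimnames = list(c("assigned high", "assigned low"),
                              c("true high", "true low")))
  m[2, ] <- c(x["c"], x["d"]); m[1, ] <- c(x["a"], x["b"])
  print(m)
  invisible(x)
}

#' The six confusion-matrix evaluation indicators
#'
#' accuracy = (a+d)/n, sensitivity (recall) = a/(a+c), specificity =
#' d/(b+d), positive predictive value (precision) = a/(a+b), negative
#' predictive value = d/(c+d), and F1 = the harmonic mean of sensitivity
#' and PPV. A metric whose denominator is zero is reported as 0 and
#' flagged in attribute \code{"undefined"} rather than returned as NaN.
#'
#' @param cm a \code{\link{confusion_matrix}} (or named vector a, b, c, d).
#' @return object of class \code{"metric_set"}: named numeric of the six
#'   indicators.
#' @examples
#' metric_set(confusion(c(1, 1, 0, 0), c(1, 0, 0, 0)))
#' @export
metric_set <- function(cm) {
  a <- cm[["a"]]; b <- cm[["b"]]; cc <- cm[["c"]]; d <- cm[["d"]]
  n <- a + b + cc + d
  if (n == 0) stop("empty confusion matrix", call. = FALSE)
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- safe(a, a + cc); spec <- safe(d, b + d)
  ppv <- safe(a, a + b); npv <- safe(d, cc + d)
  f1 <- if (is.na(sens) || is.na(ppv) || (sens + ppv) == 0) NA_real_ else
    2 / (1 / sens + 1 / ppv)
  out <- c(accuracy = (a + d) / n, sensitivity = sens, specificity = spec,
           ppv = ppv, npv = npv, f1 = f1)
  undef <- is.na(out)
  out[undef] <- 0
  structure(out, undefined = undef, class = "metric_set")
}

#' @export
print.metric_set <- function(x, digits = 3, ...) {
  v <- round(unclass(x), digits)
  attr(v, "undefined") <- NULL
  print(v)
  if (any(attr(x, "undefined")))
    cat("(", paste(names(x)[attr(x, "undefined")], collapse = ", "),
        "undefined: zero denominator, reported as 0 )\n")
  invisible(x)
}

#' Stratified k-fold assignment
#'
#' Shuffles subjects within each class and deals them cyclically into k
#' folds, so per-class fold counts differ by at most one and label
#' proportions per fold stay within one subject of the global proportions.
#' Deterministic given the seed.
#'
#' @param labels binary labels.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return integer vector of fold ids in 1..k.
#' @examples
#' table(stratified_kfold(rep(c(0, 1), each = 50), k = 5, seed = 1))
#' @export
stratified_kfold <- function(labels, k = 5L, seed = 1L) {
  labels <- as_label(labels)
  k <- as.integer(k)
  cnt <- table(labels)
  if (any(cnt < k))
    stop("each class needs at least k subjects (k = ", k, ")", call. = FALSE)
  set.seed(seed)
  folds <- integer(length(labels))
  for (c0 in levels(labels)) {
    idx <- sample(which(labels == c0))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Cross-validated evaluation of a classification runner
#'
#' Runs \code{runner(train_idx, test_idx)} per fold (it must return
#' low/high predictions for the test subjects), builds a confusion matrix
#' per validation fold, and averages the six indicators across folds
#' (macro average, the default) or pools the counts first
#' (\code{average = "pooled"}). A validation fold containing a single true
#' class has undefined metrics; it is excluded from the macro average with
#' a warning.
#'
#' @param runner function(train_idx, test_idx) -> predictions.
#' @param labels true labels of all subjects.
#' @param folds integer fold assignment.
#' @param average \code{"macro"} or \code{"pooled"}.
#' @return list of class \code{"cv_metrics"}: \code{metrics} (averaged
#'   metric set), \code{per_fold} (k x 6 matrix), \code{predictions}
#'   (full-length out-of-fold factor), \code{pooled} (pooled confusion
#'   matrix).
#' @export
cv_metrics <- function(runner, labels, folds, average = c("macro", "pooled")) {
  average <- match.arg(average)
  labels <- as_label(labels)
  ks <- sort(unique(folds))
  per_fold <- matrix(NA_real_, length(ks), 6,
                     dimnames = list(paste0("fold", ks),
                                     c("accuracy", "sensitivity", "specificity",
                                       "ppv", "npv", "f1")))
  pred_all <- factor(rep("low", length(labels)), levels = c("low", "high"))
  usable <- rep(TRUE, length(ks))
  for (j in seq_along(ks)) {
    te <- which(folds == ks[j]); tr <- which(folds != ks[j])
    p <- runner(tr, te)
    pred_all[te] <- p
    if (nlevels(droplevels(labels[te])) < 2L) {
      usable[j] <- FALSE
      warning("fold ", ks[j], " has a single true class; excluded from the ",
              "macro average", call. = FALSE)
    }
    per_fold[j, ] <- unclass(metric_set(confusion(p, labels[te])))
  }
  pooled <- confusion(pred_all, labels)
  metrics <- if (average == "pooled") metric_set(pooled) else {
    m <- colMeans(per_fold[usable, , drop = FALSE])
    structure(m, undefined = rep(FALSE, 6), class = "metric_set")
  }
  structure(list(metrics = metrics, per_fold = per_fold,
                 predictions = pred_all, pooled = pooled, average = average),
            class = "cv_metrics")
}

#' @export
print.cv_metrics <- function(x, digits = 3, ...) {
  cat("Cross-validated metrics (", x$average, " average over ",
      nrow(x$per_fold), " folds):\n", sep = "")
  print(x$metrics, digits = digits)
  invisible(x)
}
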