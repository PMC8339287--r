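#' Build a preprocessed corpus from per-subject text
#'
#' One text blob per subject (multiple posts should be concatenated with a
#' separator upstream). The default tokenizer lowercases, strips
#' punctuation and splits on whitespace; any function mapping a character
#' vector to a list of token vectors can be plugged in instead (e.g. a CJK
#' segmenter). Stopwords are removed after tokenization. Subjects whose
#' document is empty after filtering are kept with an empty token list and
#' flagged.
#'
#' @param texts character vector, one document per subject.
#' @param ids optional subject ids (default \code{"S1"}, ...).
#' @param tokenizer function(character) -> list of character vectors, or
#'   NULL for the whitespace default.
#' @param stopwords character vector of terms to drop.
#' @return object of class \code{"text_corpus"}: list with \code{tokens}
#'   (list of token vectors), \code{ids}, \code{n}, \code{empty} (logical
#'   flags).
#' @examples
#' text_corpus(c("the cat the mat", "a dog"), stopwords = c("the", "a"))
#' @export
text_corpus <- function(texts, ids = NULL, tokenizer = NULL,
                        stopwords = character()) {
  texts <- as.character(texts)
  if (is.null(ids)) ids <- paste0("S", seq_along(texts))
  if (is.null(tokenizer)) {
    tokenizer <- function(x) {
      x <- tolower(x)
      x <- gsub("[[:punct:]]+", " ", x)
      strsplit(trimws(x), "[[:space:]]+")
    }
  }
  toks <- tokenizer(texts)
  toks <- lapply(toks, function(tk) tk[nzchar(tk) & !(tk %in% stopwords)])
  empty <- lengths(toks) == 0L
  if (any(empty))
    warning(sum(empty), " document(s) empty after preprocessing", call. = FALSE)
  structure(list(tokens = toks, ids = as.character(ids),
                 n = length(toks), empty = empty),
            class = "text_corpus")
}

#' @export
print.text_corpus <- function(x, ...) {
  cat("Corpus of", x$n, "documents,",
      length(unique(unlist(x$tokens))), "distinct terms",
      if (any(x$empty)) paste0("(", sum(x$empty), " empty)") else "", "\n")
  invisible(x)
}

#' Term-count matrix of a corpus
#'
#' @param corpus a \code{\link{text_corpus}}.
#' @param vocabulary optional fixed term order; terms outside it are
#'   ignored. Default: sorted unique terms of the corpus.
#' @return integer matrix, documents x terms.
#' @export
term_counts <- function(corpus, vocabulary = NULL) {
  stopifnot(inherits(corpus, "text_corpus"))
  if (is.null(vocabulary)) vocabulary <- sort(unique(unlist(corpus$tokens)))
  X <- matrix(0L, corpus$n, length(vocabulary),
              dimnames = list(corpus$ids, vocabulary))
  for (d in seq_len(corpus$n)) {
    tb <- table(factor(corpus$tokens[[d]], levels = vocabulary))
    X[d, ] <- as.integer(tb)
  }
  X
}

#' Row-normalised TF-IDF feature weights
#'
#' Computes, for term t in document d,
#' \deqn{w(t,d) = \frac{tf(t,d)\,\log(N/(n_t + 0.01))}
#'   {\sqrt{\sum_{t \in d} [tf(t,d)\,\log(N/(n_t + 0.01))]^2}}}
#' with natural logarithms, where N is the number of training documents and
#' n_t the number of training documents containing t. The 0.01 smoothing
#' makes the idf of a term present in every document slightly negative;
#' this is kept literally by default (set \code{clamp_idf = TRUE} to floor
#' the idf at zero). Each nonzero row has unit Euclidean norm; a document
#' whose every term has zero raw weight yields a zero row with a warning.
#'
#' When \code{model} is supplied (a fit returned by a previous call), its
#' vocabulary and document frequencies are reused, so idf statistics are
#' fitted on training folds only and merely applied to test folds.
#'
#' @param x a \code{\link{text_corpus}} or a documents-x-terms count matrix.
#' @param model optional fitted tf-idf model to apply.
#' @param clamp_idf floor negative idf values at zero.
#' @return list of class \code{"tfidf"}: \code{weights} (dense matrix),
#'   \code{model} (vocabulary, N, document frequencies \code{n_t},
#'   \code{clamp_idf}).
#' @examples
#' cp <- text_corpus(c("cat cat dog", "dog fish", "fish cat"))
#' tfidf(cp)$weights
#' @export
tfidf <- function(x, model = NULL, clamp_idf = FALSE) {
  counts <- if (inherits(x, "text_corpus")) {
    term_counts(x, vocabulary = model$vocabulary)
  } else as.matrix(x)
  if (is.null(model)) {
    model <- list(vocabulary = colnames(counts), N = nrow(counts),
                  n_t = colSums(counts > 0), clamp_idf = clamp_idf)
  } else {
    counts <- counts[, model$vocabulary, drop = FALSE]
    clamp_idf <- model$clamp_idf
  }
  idf <- log(model$N / (model$n_t + 0.01))
  if (clamp_idf) idf <- pmax(idf, 0)
  raw <- sweep(counts, 2, idf, "*")
  nrm <- sqrt(rowSums(raw^2))
  zero <- nrm == 0
  if (any(zero))
    warning(sum(zero), " document(s) with all-zero feature weights",
            call. = FALSE)
  nrm[zero] <- 1
  structure(list(weights = raw / nrm, model = model), class = "tfidf")
}

#' Univariate F-test feature selection for a binary outcome
#'
#' Per feature, the one-way two-group F statistic (equal to the squared
#' pooled-variance t statistic) with degrees of freedom (1, n - 2);
#' features with p-value at most \code{alpha} are retained. Zero-variance
#' features have an undefined F and are dropped with p = 1. Fit on
#' training folds only and apply the returned mask to test folds.
#'
#' @param features numeric matrix, subjects x features.
#' @param labels binary labels (low/high or 0/1).
#' @param alpha significance level; 0.1 by default (0.05 also standard).
#' @return list with \code{keep} (logical mask), \code{p} (p-values),
#'   \code{statistic} (F values).
#' @export
f_test_select <- function(features, labels, alpha = 0.1) {
  labels <- as_label(labels)
  features <- as.matrix(features)
  n <- nrow(features)
  if (nlevels(droplevels(labels)) < 2L)
    stop("both classes must be present", call. = FALSE)
  g <- labels == "high"
  n1 <- sum(g); n0 <- n - n1
  m1 <- colMeans(features[g, , drop = FALSE])
  m0 <- colMeans(features[!g, , drop = FALSE])
  ssw <- colSums(sweep(features[g, , drop = FALSE], 2, m1)^2) +
         colSums(sweep(features[!g, , drop = FALSE], 2, m0)^2)
  gm <- colMeans(features)
  ssb <- n1 * (m1 - gm)^2 + n0 * (m0 - gm)^2
  Fstat <- (ssb / 1) / (ssw / (n - 2))
  Fstat[ssw == 0 & ssb > 0] <- Inf
  p <- stats::pf(Fstat, 1, n - 2, lower.tail = FALSE)
  p[!is.finite(Fstat) & ssb > 0] <- 0
  bad <- ssw == 0 & ssb == 0       # constant feature: F undefined
  p[bad] <- 1; Fstat[bad] <- NA_real_
  list(keep = p <= alpha, p = p, statistic = Fstat)
}

#' Calibrated linear-SVM class probabilities and likelihood-ratio score
#'
#' Trains a maximum-margin linear classifier (libsvm via \pkg{e1071}) on
#' the training rows, calibrates its margin into probabilities with a
#' Platt-style sigmoid (logistic regression of the training labels on the
#' decision values), and scores every supplied row: S1 = probability of
#' the high class, S2 = 1 - S1, both clipped into [1e-6, 1 - 1e-6], and
#' the log likelihood ratio y = ln(S1/S2). Deterministic given the data.
#'
#' @param features_train,labels_train training feature matrix and labels.
#' @param features_all feature matrix of every subject to score (same
#'   columns as \code{features_train}).
#' @param cost SVM cost parameter.
#' @param kernel SVM kernel (default \code{"linear"}).
#' @param seed integer seed (the fit itself is deterministic; kept for
#'   interface uniformity).
#' @return data.frame of class \code{"text_score"}: columns \code{S1},
#'   \code{S2}, \code{y}, one row per row of \code{features_all}.
#' @export
train_text_classifier <- function(features_train, labels_train, features_all,
                                  cost = 1, kernel = "linear", seed = 1L) {
  labels_train <- as_label(labels_train)
  features_train <- as.matrix(features_train)
  features_all <- as.matrix(features_all)
  if (all(features_train == 0))
    stop("degenerate all-zero feature matrix", call. = FALSE)
  set.seed(seed)
  fit <- e1071::svm(x = features_train, y = labels_train, kernel = kernel,
                    cost = cost, scale = FALSE, probability = FALSE)
  dv <- function(X) {
    d <- attr(stats::predict(fit, X, decision.values = TRUE),
              "decision.values")
    # orient so that positive decision values point at the high class
    if (grepl("^low", colnames(d)[1])) -d[, 1] else d[, 1]
  }
  d_train <- dv(features_train)
  y01 <- as.integer(labels_train == "high")
  platt <- withCallingHandlers(
    stats::glm(y01 ~ d_train, family = stats::binomial()),
    warning = function(w) invokeRestart("muffleWarning"))
  d_all <- dv(features_all)
  S1 <- stats::plogis(stats::coef(platt)[1] + stats::coef(platt)[2] * d_all)
  S1 <- pmin(pmax(S1, 1e-6), 1 - 1e-6)
  out <- data.frame(S1 = S1, S2 = 1 - S1, y = likelihood_ratio(S1, 1 - S1))
  attr(out, "decision_values") <- d_all
  class(out) <- c("text_score", "data.frame")
  out
}

#' Log likelihood-ratio of the two class probabilities
#'
#' y = ln(S1/S2) after clipping both probabilities into
#' [1e-6, 1 - 1e-6]; y > 0 predicts the high class.
#'
#' @param S1 probability of the high class.
#' @param S2 probability of the low class.
#' @return numeric vector of log likelihood ratios.
#' @examples
#' likelihood_ratio(0.8, 0.2)  # log(4)
#' @export
likelihood_ratio <- function(S1, S2) {
  S1 <- pmin(pmax(S1, 1e-6), 1 - 1e-6)
  S2 <- pmin(pmax(S2, 1e-6), 1 - 1e-6)
  log(S1 / S2)
}

# Per-fold text scoring used by the study runner: for fold f, fit idf,
# F-test mask and classifier on the training partition, then score every
# subject. Returns a list with an n x k matrix of y scores (one column per
# fold model) and the out-of-fold predictions.
text_cv_scores <- function(counts, labels, folds, alpha = 0.1, cost = 1,
                           kernel = "linear", clamp_idf = FALSE, seed = 1L) {
  labels <- as_label(labels)
  counts <- as.matrix(counts)
  k <- max(folds)
  n <- nrow(counts)
  y_mat <- matrix(NA_real_, n, k)
  S1_mat <- matrix(NA_real_, n, k)
  masks <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- folds != f
    tw <- tfidf(counts[tr, , drop = FALSE], clamp_idf = clamp_idf)
    w_all <- tfidf(counts, model = tw$model)$weights
    sel <- f_test_select(w_all[tr, , drop = FALSE], labels[tr], alpha)
    keep <- sel$keep
    if (!any(keep)) keep <- sel$p <= min(sel$p) # fall back to best feature
    masks[[f]] <- keep
    sc <- train_text_classifier(w_all[tr, keep, drop = FALSE], labels[tr],
                                w_all[, keep, drop = FALSE],
                                cost = cost, kernel = kernel, seed = seed + f)
    y_mat[, f] <- sc$y
    S1_mat[, f] <- sc$S1
  }
  oof_y <- y_mat[cbind(seq_len(n), folds)]
  pred <- factor(ifelse(oof_y > 0 | oof_y == 0, "high", "low"),
                 levels = c("low", "high"))
  list(y = y_mat, S1 = S1_mat, oof_y = oof_y, predictions = pred,
       masks = masks)
}
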