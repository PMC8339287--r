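#' @keywords internal
# normalise labels to a factor with levels c("low", "high")
as_label <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  if (is.numeric(x) || is.logical(x)) x <- ifelse(as.numeric(x) > 0, "high", "low")
  if (!all(x %in% c("low", "high")))
    stop("labels must be coded low/high (or 0/1, FALSE/TRUE)", call. = FALSE)
  factor(x, levels = c("low", "high"))
}

f1_score <- function(pred, truth) {
  a <- sum(pred == "high" & truth == "high")
  b <- sum(pred == "high" & truth == "low")
  cc <- sum(pred == "low" & truth == "high")
  if (a == 0) return(0)
  sens <- a / (a + cc); ppv <- a / (a + b)
  2 / (1 / sens + 1 / ppv)
}

#' Threshold rules that dichotomise a continuous trait
#'
#' Fits one of three rules mapping trait estimates to high/low calls
#' (positive class = high trait):
#' \describe{
#'   \item{\code{"logistic"}}{binary logistic regression of the label on
#'     theta; predict high when the fitted probability is at least 0.5
#'     (equivalently, thresholding theta at -intercept/slope). Unpenalised
#'     maximum likelihood (IRLS, tolerance 1e-8); on separable data the fit
#'     degenerates, so the rule falls back to the midpoint rule with a
#'     warning.}
#'   \item{\code{"midpoint"}}{threshold at the midpoint of the class
#'     medians: (median(theta | high) + median(theta | low)) / 2.}
#'   \item{\code{"best_f1"}}{scans every observed theta as a candidate cut
#'     (low strictly below, high at or above) and keeps the cut with the
#'     largest F1 for the high class; among ties, the smallest threshold.}
#' }
#' Values equal to a threshold are always classified high.
#'
#' @param theta numeric trait values (training set).
#' @param labels training labels (low/high, or 0/1).
#' @param method one of \code{"logistic"}, \code{"midpoint"},
#'   \code{"best_f1"}.
#' @return an object of class \code{"threshold_rule"} with a
#'   \code{predict} method.
#' @examples
#' rule <- threshold_rule(c(-2, -1, 1, 2), c(0, 0, 1, 1), "midpoint")
#' predict(rule, c(-0.5, 0.5))
#' @export
threshold_rule <- function(theta, labels,
                           method = c("logistic", "midpoint", "best_f1")) {
  method <- match.arg(method)
  labels <- as_label(labels)
  theta <- as.numeric(theta)
  stopifnot(length(theta) == length(labels))
  # best_f1 remains well defined when every subject is labelled high (the
  # minimal cut classifies everyone high with F1 = 1); the other rules and
  # an all-low sample need both classes
  single_ok <- method == "best_f1" && all(labels == "high")
  if (nlevels(droplevels(labels)) < 2L && !single_ok)
    stop("both classes must be present in the training labels", call. = FALSE)
  out <- switch(method,
    midpoint = {
      thr <- (stats::median(theta[labels == "high"]) +
              stats::median(theta[labels == "low"])) / 2
      list(threshold = thr, direction = 1)
    },
    best_f1 = {
      cand <- sort(unique(theta))
      f1 <- vapply(cand, function(t0) {
        pred <- factor(ifelse(theta >= t0, "high", "low"),
                       levels = c("low", "high"))
        f1_score(pred, labels)
      }, numeric(1))
      # ties (up to floating point) break towards the smallest threshold
      best <- min(cand[f1 >= max(f1) - 1e-10])
      list(threshold = best, direction = 1, f1_train = max(f1))
    },
    logistic = {
      y01 <- as.integer(labels == "high")
      fit <- withCallingHandlers(
        stats::glm(y01 ~ theta, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
        warning = function(w) invokeRestart("muffleWarning"))
      cf <- stats::coef(fit)
      y01hat <- fit$fitted.values
      separable <- all(abs(y01hat - y01) < 1e-4)
      if (any(!is.finite(cf)) || abs(cf[2]) > 1e3 || separable) {
        warning("separable data: logistic rule falls back to the midpoint rule",
                call. = FALSE)
        thr <- (stats::median(theta[labels == "high"]) +
                stats::median(theta[labels == "low"])) / 2
        list(threshold = thr, direction = 1, fallback = "midpoint")
      } else {
        list(coef = c(intercept = unname(cf[1]), slope = unname(cf[2])),
             threshold = unname(-cf[1] / cf[2]),
             direction = sign(unname(cf[2])))
      }
    })
  structure(c(out, list(method = method)), class = "threshold_rule")
}

#' @export
print.threshold_rule <- function(x, ...) {
  cat("Threshold rule (", x$method, "): classify high when theta ",
      if (x$direction >= 0) ">= " else "< ",
      format(x$threshold, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @rdname threshold_rule
#' @param object a fitted \code{threshold_rule}.
#' @param theta trait values to classify.
#' @param ... ignored.
#' @return \code{predict}: factor of low/high calls.
#' @export
predict.threshold_rule <- function(object, theta, ...) {
  theta <- as.numeric(theta)
  if (object$method == "logistic" && !is.null(object$coef)) {
    p <- stats::plogis(object$coef["intercept"] + object$coef["slope"] * theta)
    high <- p >= 0.5  # ties at 0.5 go to high
  } else {
    high <- theta >= object$threshold
  }
  factor(ifelse(high, "high", "low"), levels = c("low", "high"))
}

#' Midpoint-of-medians classification threshold
#'
#' @param theta trait values.
#' @param labels low/high labels.
#' @return the scalar threshold (classify high when theta >= threshold).
#' @examples
#' midpoint_threshold(c(-1, 0, 0, 1), c(0, 0, 1, 1))
#' @export
midpoint_threshold <- function(theta, labels) {
  threshold_rule(theta, labels, "midpoint")$threshold
}

#' Best-F1 classification threshold
#'
#' @inheritParams midpoint_threshold
#' @return the scalar threshold maximising training F1 for the high class
#'   (smallest among ties), with the achieved F1 as attribute
#'   \code{"f1"}.
#' @export
best_f1_threshold <- function(theta, labels) {
  r <- threshold_rule(theta, labels, "best_f1")
  structure(r$threshold, f1 = r$f1_train)
}

#' Logistic-regression classification of trait values
#'
#' Fits the logistic rule on the training data and predicts the test
#' values (cutoff 0.5 on the fitted probability).
#'
#' @param theta_train,labels_train training trait values and labels.
#' @param theta_test trait values to classify.
#' @return factor of low/high predictions for \code{theta_test}.
#' @export
logistic_classify <- function(theta_train, labels_train, theta_test) {
  predict(threshold_rule(theta_train, labels_train, "logistic"), theta_test)
}
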