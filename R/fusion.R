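#' Linear regression linking the text score to the latent trait prior
#'
#' Fits theta = b0 + b1 * y + eps by ordinary least squares on training
#' subjects, so that the person-specific prior theta | y ~ N(b0 + b1*y,
#' sigma^2) holds with the fitted coefficients (sigma = residual sd,
#' floored at 1e-3 to avoid a point-mass prior). The alternative reading
#' that regresses y on theta and reuses its coefficients for the prior
#' mean is available via \code{direction = "y_on_theta"}.
#'
#' @param theta trait estimates of the training subjects (e.g. MAP
#'   estimates under the standard-normal prior).
#' @param y text-derived log likelihood-ratio scores of the same subjects.
#' @param direction \code{"theta_on_y"} (default) or \code{"y_on_theta"}.
#' @return object of class \code{"prior_regression"}: list(b0, b1, sigma).
#' @examples
#' prior_regression(c(-1, 0, 1, 2, 0.5), c(-2, 0, 2, 4, 1))
#' @export
prior_regression <- function(theta, y, direction = c("theta_on_y", "y_on_theta")) {
  direction <- match.arg(direction)
  theta <- as.numeric(theta); y <- as.numeric(y)
  stopifnot(length(theta) == length(y))
  if (length(theta) < 3L)
    stop("too few training subjects for the prior regression", call. = FALSE)
  if (stats::var(y) == 0) {
    warning("constant text score: prior collapses to a shared normal",
            call. = FALSE)
    out <- list(b0 = mean(theta), b1 = 0,
                sigma = max(stats::sd(theta), 1e-3))
  } else if (direction == "theta_on_y") {
    fit <- stats::lm(theta ~ y)
    out <- list(b0 = unname(stats::coef(fit)[1]),
                b1 = unname(stats::coef(fit)[2]),
                sigma = max(summary(fit)$sigma, 1e-3))
  } else {
    fit <- stats::lm(y ~ theta)
    out <- list(b0 = unname(stats::coef(fit)[1]),
                b1 = unname(stats::coef(fit)[2]),
                sigma = max(summary(fit)$sigma, 1e-3))
  }
  out$direction <- direction
  structure(out, class = "prior_regression")
}

#' @export
print.prior_regression <- function(x, ...) {
  cat(sprintf("Text-prior regression: theta | y ~ N(%.4g + %.4g*y, %.4g^2)\n",
              x$b0, x$b1, x$sigma))
  invisible(x)
}

#' Person-specific normal prior from a text score
#'
#' @param reg a fitted \code{\link{prior_regression}}.
#' @param y text score(s).
#' @return a \code{\link{prior_spec}} with mean b0 + b1*y and sd sigma.
#' @export
personal_prior <- function(reg, y) {
  stopifnot(inherits(reg, "prior_regression"))
  prior_spec(mean = reg$b0 + reg$b1 * as.numeric(y), sd = reg$sigma)
}

#' MAP trait estimation under a text-informed personal prior
#'
#' Same grid machinery as \code{\link{ability}}, with the standard-normal
#' prior replaced by the person-specific prior N(b0 + b1*y, sigma^2).
#'
#' @param object a \code{grm} fit or \code{item_bank}.
#' @param responses response matrix.
#' @param y per-subject text scores (recycled if scalar).
#' @param reg a fitted \code{\link{prior_regression}}.
#' @param ... passed to \code{\link{ability}} (grid_points, bounds).
#' @return as \code{\link{ability}}.
#' @export
ability_with_text_prior <- function(object, responses, y, reg, ...) {
  ability(object, responses, prior = personal_prior(reg, y), ...)
}

#' Gaussian naive Bayes classifier
#'
#' Minimal Gaussian naive Bayes for the fused [y, theta] features:
#' per-class feature means and variances (variances floored at
#' \code{var_floor}) with empirical class priors.
#'
#' @param x numeric feature matrix.
#' @param labels binary labels.
#' @param var_floor lower bound on the within-class variances.
#' @return object of class \code{"gaussian_nb"}.
#' @export
gaussian_nb <- function(x, labels, var_floor = 1e-9) {
  x <- as.matrix(x)
  labels <- as_label(labels)
  if (nlevels(droplevels(labels)) < 2L)
    stop("both classes must be present", call. = FALSE)
  cls <- levels(labels)
  mu <- var <- matrix(NA_real_, 2, ncol(x), dimnames = list(cls, colnames(x)))
  for (c0 in cls) {
    xi <- x[labels == c0, , drop = FALSE]
    mu[c0, ] <- colMeans(xi)
    var[c0, ] <- pmax(apply(xi, 2, stats::var), var_floor)
  }
  structure(list(mu = mu, var = var,
                 log_prior = log(prop.table(table(labels))[cls])),
            class = "gaussian_nb")
}

#' @rdname gaussian_nb
#' @param object fitted \code{gaussian_nb}.
#' @param newdata feature matrix to classify.
#' @param type \code{"class"} or \code{"posterior"}.
#' @param ... ignored.
#' @export
predict.gaussian_nb <- function(object, newdata,
                                type = c("class", "posterior"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  lp <- vapply(rownames(object$mu), function(c0) {
    object$log_prior[c0] + rowSums(stats::dnorm(
      newdata, mean = rep(object$mu[c0, ], each = nrow(newdata)),
      sd = rep(sqrt(object$var[c0, ]), each = nrow(newdata)), log = TRUE))
  }, numeric(nrow(newdata)))
  lp <- matrix(lp, ncol = 2, dimnames = list(NULL, rownames(object$mu)))
  if (type == "posterior") {
    w <- exp(lp - apply(lp, 1, max))
    return(w / rowSums(w))
  }
  # tie goes to high, matching the package's positive-class convention
  factor(ifelse(lp[, "high"] >= lp[, "low"], "high", "low"),
         levels = c("low", "high"))
}

#' Cross-validated Gaussian naive Bayes on fused [y, theta] features
#'
#' Trains per fold on the training partition of the two-column fused
#' feature matrix and predicts the held-out fold.
#'
#' @param fused numeric matrix with columns y (text score) and theta
#'   (text-prior trait estimate).
#' @param labels binary labels for all subjects.
#' @param folds integer fold assignment from \code{\link{stratified_kfold}}.
#' @param var_floor passed to \code{\link{gaussian_nb}}.
#' @return factor of out-of-fold low/high predictions.
#' @export
fuse_and_classify <- function(fused, labels, folds, var_floor = 1e-9) {
  fused <- as.matrix(fused)
  labels <- as_label(labels)
  stopifnot(nrow(fused) == length(labels), length(folds) == length(labels))
  if (any(!is.finite(fused)))
    stop("fused features must be finite", call. = FALSE)
  pred <- factor(rep("low", length(labels)), levels = c("low", "high"))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    nb <- gaussian_nb(fused[tr, , drop = FALSE], labels[tr],
                      var_floor = var_floor)
    pred[!tr] <- predict(nb, fused[!tr, , drop = FALSE])
  }
  pred
}
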