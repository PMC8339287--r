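#' Item bank for the graded response model
#'
#' An item bank holds, for each polytomous item, a discrimination parameter
#' \code{a} and a non-decreasing vector of boundary difficulties \code{b} on
#' the latent-trait scale, together with the logistic scaling constant
#' \code{D}. Items may have different numbers of categories (e.g. after
#' collapsing categories never observed in a sample).
#'
#' @param a numeric vector of positive discriminations, one per item.
#' @param b boundary difficulties: either a numeric matrix with one row per
#'   item and \code{K - 1} columns, or a list of numeric vectors (one per
#'   item, each non-decreasing). An item with \code{k} boundaries has
#'   \code{k + 1} response categories.
#' @param D logistic scaling constant; 1.702 aligns the logistic with the
#'   normal ogive, 1 gives the pure-logistic parameterisation.
#' @param items optional character vector of item names.
#'
#' @return An object of class \code{"item_bank"}: a list with elements
#'   \code{a}, \code{b} (list of boundary vectors), \code{K} (categories per
#'   item) and \code{D}.
#' @examples
#' bank <- item_bank(a = c(1.2, 0.9), b = rbind(c(-1, 0, 1), c(-0.5, 0.2, 1.4)))
#' bank
#' @export
item_bank <- function(a, b, D = 1.702, items = NULL) {
  if (is.matrix(b)) b <- lapply(seq_len(nrow(b)), function(i) b[i, ])
  if (!is.list(b)) b <- list(as.numeric(b))
  a <- as.numeric(a)
  if (length(a) != length(b))
    stop("'a' and 'b' describe different numbers of items", call. = FALSE)
  if (any(!is.finite(a)) || any(a <= 0))
    stop("item discriminations must be positive and finite", call. = FALSE)
  b <- lapply(b, function(bi) as.numeric(bi[!is.na(bi)]))
  ord <- vapply(b, function(bi) !is.unsorted(bi), logical(1))
  if (!all(ord))
    stop("boundary difficulties must be non-decreasing within each item (items: ",
         paste(which(!ord), collapse = ", "), ")", call. = FALSE)
  if (!is.numeric(D) || length(D) != 1L || D <= 0)
    stop("'D' must be a single positive number", call. = FALSE)
  if (is.null(items)) items <- paste0("item_", seq_along(a))
  structure(list(a = a, b = b, K = vapply(b, length, integer(1)) + 1L,
                 D = D, items = as.character(items)),
            class = "item_bank")
}

#' @export
print.item_bank <- function(x, digits = 3, ...) {
  cat("Graded response model item bank: ", length(x$a), " items, D = ",
      format(x$D), "\n", sep = "")
  print(round(coef(x), digits))
  invisible(x)
}

#' @export
coef.item_bank <- function(object, ...) {
  Kmax <- max(object$K)
  m <- t(vapply(seq_along(object$a), function(i) {
    c(object$a[i], object$b[[i]], rep(NA_real_, Kmax - object$K[i]))
  }, numeric(Kmax)))
  dimnames(m) <- list(object$items, c("a", paste0("b", seq_len(Kmax - 1L))))
  m
}

#' @export
length.item_bank <- function(x) length(x$a)

#' Subset an item bank
#' @param x an \code{item_bank}.
#' @param i item index.
#' @param ... ignored.
#' @export
`[.item_bank` <- function(x, i, ...) {
  item_bank(x$a[i], x$b[i], D = x$D, items = x$items[i])
}

#' Boundary (cumulative) response probability
#'
#' Probability that a subject at trait level \code{theta} responds in a
#' category at or above the boundary with difficulty \code{b}, under the
#' two-parameter logistic boundary curve
#' \eqn{P^*(\theta) = 1 / (1 + e^{-D a (\theta - b)})}.
#'
#' @param theta latent trait value(s).
#' @param a positive item discrimination.
#' @param b boundary difficulty.
#' @param D scaling constant (default 1.702).
#' @return probabilities in (0, 1), strictly increasing in \code{theta}.
#' @examples
#' boundary_prob(0, a = 1, b = 0)            # 0.5 by symmetry
#' boundary_prob(1, a = 1.724, b = -1.173)   # ~0.998
#' @export
boundary_prob <- function(theta, a, b, D = 1.702) {
  if (any(!is.finite(a)) || any(a <= 0))
    stop("discrimination 'a' must be positive", call. = FALSE)
  stats::plogis(D * a * (theta - b))
}

#' Category response probabilities of one item
#'
#' Adjacent differences of the boundary curves: with cumulative
#' probabilities \eqn{P^*_0 = 1}, \eqn{P^*_K = 0} and
#' \eqn{P^*_x} from \code{\link{boundary_prob}} for \eqn{x = 1..K-1}, the
#' probability of responding in category \eqn{x} (0-based) is
#' \eqn{P_x = P^*_x - P^*_{x+1}}. Requires ordered boundaries, otherwise
#' some categories would get negative probability.
#'
#' @param theta latent trait value(s).
#' @param a positive discrimination.
#' @param b non-decreasing boundary difficulties (length K - 1).
#' @param D scaling constant.
#' @param check refuse unordered boundaries (default TRUE).
#' @return for scalar \code{theta} a probability vector of length K; for a
#'   vector a \code{length(theta) x K} matrix. Rows sum to 1.
#' @examples
#' category_probs(0, a = 1, b = c(-1, 1))  # ~ (0.154, 0.692, 0.154)
#' @export
category_probs <- function(theta, a, b, D = 1.702, check = TRUE) {
  b <- as.numeric(b)
  if (check && is.unsorted(b))
    stop("boundary difficulties must be non-decreasing", call. = FALSE)
  K <- length(b) + 1L
  Pstar <- cbind(1, boundary_prob(rep(theta, times = length(b)),
                                  a, rep(b, each = length(theta)), D) |>
                   matrix(nrow = length(theta)), 0)
  P <- Pstar[, seq_len(K), drop = FALSE] - Pstar[, seq_len(K) + 1L, drop = FALSE]
  P[P < 0] <- 0 # guard tiny negative from floating point
  colnames(P) <- paste0("cat", seq_len(K) - 1L)
  if (length(theta) == 1L) P[1L, ] else P
}

#' Log-likelihood of a response vector at a trait value
#'
#' Sum over items of the log category probability of the observed (0-based)
#' category. A category with probability zero contributes \code{-Inf}; the
#' offending items are attached as attribute \code{"zero_prob_items"} rather
#' than raising an error.
#'
#' @param row integer response vector (0-based categories), one per item.
#' @param bank an \code{\link{item_bank}}.
#' @param theta trait value(s); the log-likelihood is evaluated at each.
#' @return numeric vector, one log-likelihood per element of \code{theta}.
#' @export
response_loglik <- function(row, bank, theta) {
  stopifnot(inherits(bank, "item_bank"))
  row <- as.integer(row)
  if (length(row) != length(bank$a))
    stop("response row length (", length(row), ") != number of items (",
         length(bank$a), ")", call. = FALSE)
  if (any(row < 0L | row >= bank$K))
    stop("response categories must lie in 0..K-1 for each item", call. = FALSE)
  ll <- numeric(length(theta))
  zero_items <- integer(0)
  for (i in seq_along(row)) {
    P <- category_probs(theta, bank$a[i], bank$b[[i]], bank$D)
    p <- if (is.matrix(P)) P[, row[i] + 1L] else P[row[i] + 1L]
    if (any(p == 0)) zero_items <- c(zero_items, i)
    ll <- ll + unname(log(p))
  }
  if (length(zero_items)) attr(ll, "zero_prob_items") <- zero_items
  ll
}

# n x G log-likelihood matrix over a trait grid; the workhorse behind both
# quadrature EM and grid MAP scoring.
loglik_matrix <- function(bank, responses, grid) {
  responses <- as.matrix(responses)
  n <- nrow(responses)
  L <- matrix(0, n, length(grid))
  for (i in seq_along(bank$a)) {
    logP <- log(category_probs(grid, bank$a[i], bank$b[[i]], bank$D)) # G x K
    L <- L + t(logP[, responses[, i] + 1L, drop = FALSE])             # n x G
  }
  L
}
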