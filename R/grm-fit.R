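#' Control parameters for GRM estimation
#'
#' @param quad_points number of equally spaced quadrature nodes for the EM
#'   fit (doubling them should move estimates by well under 1e-3).
#' @param bounds trait interval for quadrature and scoring grids.
#' @param em_tol EM stops when the largest parameter change across one cycle
#'   falls below this.
#' @param em_max_cycles EM cycle cap.
#' @param mhrm_tol MH-RM convergence tolerance on the largest parameter
#'   change, required over \code{conv_window} consecutive cycles.
#' @param mhrm_max_cycles MH-RM cycle cap; exceeding it raises an error that
#'   carries the last iterate.
#' @param burn_in constant-gain MH-RM cycles before the Robbins-Monro
#'   1/k gain sequence starts.
#' @param proposal_sd sd of the normal random-walk proposal for the latent
#'   trait imputation step.
#' @param conv_window consecutive sub-tolerance cycles required to declare
#'   MH-RM convergence.
#' @param ridge ridge added to the accumulated information matrix before
#'   solving for the Robbins-Monro step (rare boundary categories carry
#'   almost no information).
#' @return a list of class \code{"grm_control"}.
#' @export
grm_control <- function(quad_points = 41L, bounds = c(-4, 4),
                        em_tol = 1e-5, em_max_cycles = 500L,
                        mhrm_tol = 1e-3, mhrm_max_cycles = 500L,
                        burn_in = 20L, proposal_sd = 1.0,
                        conv_window = 3L, ridge = 1e-3) {
  stopifnot(quad_points >= 5, bounds[1] < bounds[2], burn_in >= 1)
  structure(list(quad_points = as.integer(quad_points), bounds = bounds,
                 em_tol = em_tol, em_max_cycles = as.integer(em_max_cycles),
                 mhrm_tol = mhrm_tol,
                 mhrm_max_cycles = as.integer(mhrm_max_cycles),
                 burn_in = as.integer(burn_in), proposal_sd = proposal_sd,
                 conv_window = as.integer(conv_window), ridge = ridge),
            class = "grm_control")
}

# Map each item's observed category codes onto 0..k-1, dropping items that
# show fewer than two categories. Raw Likert codes (1..7) and already
# 0-based codes are both handled by the same rank mapping, and categories
# never observed in the sample are collapsed away (the GRM is undefined for
# them); the index map is retained so new responses can be scored.
prepare_responses <- function(responses) {
  responses <- as.matrix(responses)
  if (!is.numeric(responses) || any(!is.finite(responses)))
    stop("responses must be a complete numeric matrix (no missing entries)",
         call. = FALSE)
  if (any(responses != round(responses)))
    stop("responses must be integer category codes", call. = FALSE)
  m <- ncol(responses)
  cat_maps <- vector("list", m)
  keep <- logical(m)
  coded <- matrix(0L, nrow(responses), m)
  for (i in seq_len(m)) {
    lv <- sort(unique(responses[, i]))
    cat_maps[[i]] <- lv
    keep[i] <- length(lv) >= 2L
    if (keep[i]) coded[, i] <- match(responses[, i], lv) - 1L
  }
  if (!all(keep))
    warning("excluding item(s) with a single observed category: ",
            paste(which(!keep), collapse = ", "), call. = FALSE)
  items <- colnames(responses)
  if (is.null(items)) items <- paste0("item_", seq_len(m))
  list(coded = coded[, keep, drop = FALSE], cat_maps = cat_maps[keep],
       keep = keep, items = items[keep])
}

# Empirical starting values: a = 1, boundaries from the normal-ogive
# inverse of cumulative category proportions.
init_item_params <- function(coded) {
  m <- ncol(coded)
  K <- apply(coded, 2, max) + 1L
  b <- vector("list", m)
  for (i in seq_len(m)) {
    p_ge <- vapply(seq_len(K[i] - 1L), function(x) mean(coded[, i] >= x),
                   numeric(1))
    bi <- stats::qnorm(1 - pmin(pmax(p_ge, 1e-3), 1 - 1e-3))
    bi <- pmin(pmax(bi, -3.5), 3.5)
    # enforce a strictly increasing start
    for (j in seq_along(bi)[-1]) bi[j] <- max(bi[j], bi[j - 1] + 0.01)
    b[[i]] <- bi
  }
  list(a = rep(1, m), b = b, K = K)
}

# --- EM (Bock-Aitkin, fixed quadrature) -----------------------------------

# ordered parameterisation: par = (log a, b1, log gaps); guarantees
# monotone boundaries inside the optimiser.
par_encode <- function(a, b) {
  if (length(b) == 1L) c(log(a), b) else
    c(log(a), b[1], log(pmax(diff(b), 1e-4)))
}
par_decode <- function(par) {
  a <- exp(min(max(par[1], log(1e-3)), log(50)))
  b <- if (length(par) == 2L) par[2] else
    par[2] + cumsum(c(0, pmin(exp(par[-(1:2)]), 50)))
  list(a = a, b = b)
}

fit_grm_em <- function(coded, D, control) {
  n <- nrow(coded); m <- ncol(coded)
  init <- init_item_params(coded)
  a <- init$a; b <- init$b; K <- init$K
  nodes <- seq(control$bounds[1], control$bounds[2],
               length.out = control$quad_points)
  lw <- stats::dnorm(nodes); lw <- log(lw / sum(lw))
  ind <- lapply(seq_len(m), function(i)
    outer(coded[, i], seq_len(K[i]) - 1L, "==") * 1)
  cycles <- 0L
  repeat {
    cycles <- cycles + 1L
    bank <- item_bank(a, b, D = D)
    L <- loglik_matrix(bank, coded, nodes)
    A <- sweep(L, 2, lw, "+")
    A <- exp(A - apply(A, 1, max))
    post <- A / rowSums(A)                       # n x G
    delta <- 0
    for (i in seq_len(m)) {
      r <- crossprod(post, ind[[i]])             # G x K expected counts
      obj <- function(par) {
        if (any(!is.finite(par)) || any(abs(par) > 700)) return(1e10)
        p <- par_decode(par)
        P <- category_probs(nodes, p$a, p$b, D, check = FALSE)
        -sum(r * log(pmax(P, 1e-300)))
      }
      fit <- stats::optim(par_encode(a[i], b[[i]]), obj, method = "BFGS",
                          control = list(maxit = 100, reltol = 1e-10))
      p <- par_decode(fit$par)
      delta <- max(delta, abs(p$a - a[i]), abs(p$b - b[[i]]))
      a[i] <- p$a; b[[i]] <- p$b
    }
    if (delta < control$em_tol || cycles >= control$em_max_cycles) break
  }
  list(bank = item_bank(a, b, D = D), cycles = cycles,
       converged = cycles < control$em_max_cycles)
}

# --- MH-RM (stochastic approximation) -------------------------------------

# per-subject loglik at subject-specific theta values
loglik_at_theta <- function(a, b, D, coded, theta) {
  ll <- numeric(length(theta))
  for (i in seq_along(a)) {
    P <- category_probs(theta, a[i], b[[i]], D)
    ll <- ll + log(pmax(P[cbind(seq_along(theta), coded[, i] + 1L)], 1e-300))
  }
  ll
}

# analytic per-subject gradient of the complete-data loglik of one item,
# in the (log a, b_1..b_{K-1}) parameterisation
item_gradients <- function(a, b, D, x, theta) {
  n <- length(theta); Km1 <- length(b)
  Ps <- stats::plogis(D * a * outer(theta, b, "-"))   # n x (K-1)
  Q <- Ps * (1 - Ps)
  l <- x; u <- x + 1L
  has_l <- l >= 1L; has_u <- u <= Km1
  idx <- function(j) cbind(seq_len(n), j)
  Pl <- ifelse(has_l, Ps[idx(pmax(l, 1L))], 1)
  Pu <- ifelse(has_u, Ps[idx(pmin(u, Km1))], 0)
  P <- pmax(Pl - Pu, 1e-10)
  Ql <- ifelse(has_l, Q[idx(pmax(l, 1L))], 0)
  Qu <- ifelse(has_u, Q[idx(pmin(u, Km1))], 0)
  bl <- ifelse(has_l, b[pmax(l, 1L)], 0)
  bu <- ifelse(has_u, b[pmin(u, Km1)], 0)
  g <- matrix(0, n, 1L + Km1)
  g[, 1] <- a * D * (has_l * (theta - bl) * Ql - has_u * (theta - bu) * Qu) / P
  gl <- -D * a * Ql / P
  gu <-  D * a * Qu / P
  g[idx(pmax(l, 1L) + 1L)] <- g[idx(pmax(l, 1L) + 1L)] + ifelse(has_l, gl, 0)
  g[idx(pmin(u, Km1) + 1L)] <- g[idx(pmin(u, Km1) + 1L)] + ifelse(has_u, gu, 0)
  g
}

fit_grm_mhrm <- function(coded, D, control, seed) {
  set.seed(seed)
  n <- nrow(coded); m <- ncol(coded)
  init <- init_item_params(coded)
  a <- init$a; b <- init$b
  # crude starting imputation: standardised sum score
  theta <- as.numeric(scale(rowSums(coded)))
  theta[!is.finite(theta)] <- 0
  Gamma <- lapply(seq_len(m), function(i) diag(length(b[[i]]) + 1L))
  below <- 0L; cycles <- 0L; converged <- FALSE
  for (k in seq_len(control$mhrm_max_cycles)) {
    cycles <- k
    gain <- if (k <= control$burn_in) 1 else 1 / (k - control$burn_in)
    # Metropolis-Hastings imputation of theta (one draw per subject),
    # stationary for the N(0,1)-prior posterior at the current parameters
    prop <- theta + stats::rnorm(n, 0, control$proposal_sd)
    cur_lp <- loglik_at_theta(a, b, D, coded, theta) +
      stats::dnorm(theta, log = TRUE)
    prop_lp <- loglik_at_theta(a, b, D, coded, prop) +
      stats::dnorm(prop, log = TRUE)
    acc <- log(stats::runif(n)) < (prop_lp - cur_lp)
    theta[acc] <- prop[acc]
    # Robbins-Monro update per item with an accumulated empirical Fisher
    delta <- 0
    for (i in seq_len(m)) {
      g <- item_gradients(a[i], b[[i]], D, coded[, i], theta)
      gbar <- colMeans(g)
      Fk <- crossprod(g) / n
      Gamma[[i]] <- Gamma[[i]] + gain * (Fk - Gamma[[i]])
      H <- Gamma[[i]] + control$ridge * diag(nrow(Fk))
      step <- gain * solve(H, gbar)
      step <- pmin(pmax(step, -0.5), 0.5)
      par_new <- c(log(a[i]), b[[i]]) + step
      a_new <- exp(pmin(pmax(par_new[1], log(0.05)), log(5)))
      b_new <- sort(par_new[-1])  # enforce boundary order after each update
      delta <- max(delta, abs(a_new - a[i]), abs(b_new - b[[i]]))
      a[i] <- a_new; b[[i]] <- b_new
    }
    if (k > control$burn_in) {
      below <- if (delta < control$mhrm_tol) below + 1L else 0L
      if (below >= control$conv_window) { converged <- TRUE; break }
    }
  }
  if (!converged) {
    cond <- structure(
      class = c("irtfuse_nonconvergence", "error", "condition"),
      list(message = paste0("MH-RM did not converge within ",
                            control$mhrm_max_cycles, " cycles"),
           call = sys.call(-1),
           last_iterate = item_bank(a, b, D = D)))
    stop(cond)
  }
  list(bank = item_bank(a, b, D = D), cycles = cycles, converged = TRUE)
}

#' Fit a graded response model to a polytomous response matrix
#'
#' Estimates per-item discriminations and ordered boundary difficulties.
#' Two estimators are available: \code{"mhrm"}, a Metropolis-Hastings
#' Robbins-Monro stochastic approximation (latent traits imputed by a
#' random-walk MH step, parameters updated along a 1/k gain sequence with
#' an accumulated empirical information matrix), and \code{"em"}, a
#' deterministic Bock-Aitkin EM with fixed Gauss-grid quadrature that
#' serves as the reproducible reference. Both enforce boundary ordering.
#'
#' Category codes are mapped by rank onto 0..k-1 per item, so raw Likert
#' coding (1..7) is accepted directly and categories never observed in the
#' sample are collapsed away (with the index map retained in the fit).
#' Items showing a single observed category are excluded with a warning.
#'
#' @param responses integer matrix or data frame, subjects in rows, items
#'   in columns, no missing entries.
#' @param method \code{"em"} (default) or \code{"mhrm"}.
#' @param D logistic scaling constant, default 1.702.
#' @param control a \code{\link{grm_control}} list.
#' @param seed integer seed for the stochastic MH-RM trajectory (ignored by
#'   EM); the fit is deterministic given the seed.
#' @return an object of class \code{"grm"}: the fitted \code{\link{item_bank}}
#'   plus bookkeeping (category maps, kept items, cycles, convergence flag).
#' @examples
#' sim <- simulate_study(sim_config(n = 300, m = 5, seed = 7))
#' fit <- grm(sim$responses, method = "em")
#' coef(fit)
#' @export
grm <- function(responses, method = c("em", "mhrm"), D = 1.702,
                control = grm_control(), seed = 1L) {
  method <- match.arg(method)
  prep <- prepare_responses(responses)
  if (ncol(prep$coded) == 0L)
    stop("no item with at least two observed categories", call. = FALSE)
  fit <- switch(method,
    em = fit_grm_em(prep$coded, D, control),
    mhrm = fit_grm_mhrm(prep$coded, D, control, seed))
  fit$bank$items <- prep$items
  structure(list(bank = fit$bank, method = method, cycles = fit$cycles,
                 converged = fit$converged, cat_maps = prep$cat_maps,
                 keep = prep$keep, control = control, seed = seed,
                 n = nrow(prep$coded), call = match.call()),
            class = "grm")
}

#' @export
print.grm <- function(x, digits = 3, ...) {
  cat("Graded response model (", toupper(x$method), " fit, n = ", x$n,
      ", ", length(x$bank$a), " items, ", x$cycles, " cycles)\n", sep = "")
  print(round(coef(x), digits))
  invisible(x)
}

#' @export
coef.grm <- function(object, ...) coef(object$bank)

#' @export
summary.grm <- function(object, ...) {
  cf <- coef(object)
  out <- list(coef = cf, method = object$method, n = object$n,
              cycles = object$cycles, converged = object$converged,
              D = object$bank$D)
  class(out) <- "summary.grm"
  out
}

#' @export
print.summary.grm <- function(x, digits = 3, ...) {
  cat("Graded response model, D =", format(x$D), "\n")
  cat("Estimator:", toupper(x$method), "| subjects:", x$n,
      "| cycles:", x$cycles,
      if (x$converged) "(converged)" else "(NOT converged)", "\n\n")
  print(round(x$coef, digits))
  invisible(x)
}

# apply the stored category maps of a grm fit to (possibly raw-coded) new
# responses, returning the 0-based collapsed coding on the kept items
recode_responses <- function(object, responses) {
  responses <- as.matrix(responses)[, object$keep, drop = FALSE]
  coded <- responses
  for (i in seq_len(ncol(responses))) {
    mi <- match(responses[, i], object$cat_maps[[i]])
    if (anyNA(mi))
      stop("response codes outside the categories seen at fitting time (item ",
           i, ")", call. = FALSE)
    coded[, i] <- mi - 1L
  }
  storage.mode(coded) <- "integer"
  coded
}

#' Simulate response matrices from a fitted graded response model
#'
#' @param object a \code{grm} fit.
#' @param nsim number of response matrices.
#' @param seed integer seed.
#' @param thetas latent trait values to simulate at (default: standard
#'   normal draws matching the fitting sample size).
#' @param ... ignored.
#' @return a list of \code{nsim} response matrices in 0-based collapsed
#'   category coding (a single matrix if \code{nsim = 1}).
#' @export
simulate.grm <- function(object, nsim = 1, seed = NULL, thetas = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    th <- if (is.null(thetas)) stats::rnorm(object$n) else thetas
    out[[s]] <- simulate_responses(th, object$bank,
                                   seed = sample.int(2^31 - 1, 1))
  }
  if (nsim == 1) out[[1]] else out
}
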