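#' Configuration of an end-to-end study run
#'
#' @param k folds for the stratified cross-validation shared by all
#'   methods.
#' @param alpha F-test feature-selection level.
#' @param theta_rule threshold rule for the questionnaire-only method
#'   (\code{"logistic"}, \code{"midpoint"} or \code{"best_f1"}).
#' @param item_method GRM estimator (\code{"em"} or \code{"mhrm"}).
#' @param D logistic scaling constant.
#' @param grid_points,bounds trait grid for MAP scoring.
#' @param cost,kernel SVM settings of the text classifier.
#' @param clamp_idf floor negative idf values at zero.
#' @param prior_direction regression direction of the text prior (see
#'   \code{\link{prior_regression}}).
#' @param prior_sd_override if set, replaces the fitted residual sd of
#'   every personal prior (e.g. 1e6 to make the fused estimates collapse
#'   onto the questionnaire-only estimates).
#' @param average metric averaging across validation folds.
#' @param seed integer seed driving fold assignment and any stochastic
#'   estimation; mandatory.
#' @return list of class \code{"study_config"}.
#' @export
study_config <- function(k = 5L, alpha = 0.1, theta_rule = "logistic",
                         item_method = "em", D = 1.702, grid_points = 161L,
                         bounds = c(-4, 4), cost = 1, kernel = "linear",
                         clamp_idf = FALSE, prior_direction = "theta_on_y",
                         prior_sd_override = NULL, average = "macro",
                         seed = 1L) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  structure(list(k = as.integer(k), alpha = alpha, theta_rule = theta_rule,
                 item_method = item_method, D = D,
                 grid_points = as.integer(grid_points), bounds = bounds,
                 cost = cost, kernel = kernel, clamp_idf = clamp_idf,
                 prior_direction = prior_direction,
                 prior_sd_override = prior_sd_override, average = average,
                 seed = as.integer(seed)),
            class = "study_config")
}

# normalise a corpus input (texts, text_corpus, counts matrix, or a
# simulate_text result) to a term-count matrix
to_counts <- function(x) {
  if (is.list(x) && !inherits(x, "text_corpus") && !is.null(x$counts))
    return(as.matrix(x$counts))
  if (inherits(x, "text_corpus")) return(term_counts(x))
  if (is.character(x)) return(term_counts(text_corpus(x)))
  as.matrix(x)
}

# sum count matrices over the union of their vocabularies (document-level
# concatenation for token-count features)
combine_counts <- function(lst) {
  vocab <- sort(unique(unlist(lapply(lst, colnames))))
  out <- matrix(0L, nrow(lst[[1]]), length(vocab),
                dimnames = list(rownames(lst[[1]]), vocab))
  for (x in lst) out[, colnames(x)] <- out[, colnames(x)] + x
  out
}

#' Run the full three-method measurement study
#'
#' Under one shared stratified fold assignment, evaluates
#' \describe{
#'   \item{Method 1 (questionnaire only)}{GRM item fit on the full
#'     response matrix, MAP traits under the standard-normal prior, and a
#'     per-fold threshold rule on the trait estimates.}
#'   \item{Method 2 (text only)}{per text source and per fold: TF-IDF on
#'     the training partition, F-test feature selection, calibrated linear
#'     SVM; subjects are classified by the sign of the log likelihood
#'     ratio y.}
#'   \item{Method 3 (fused)}{per source and fold: regress the training
#'     subjects' Method-1 traits on their y scores, turn each subject's y
#'     into a personal normal prior, re-estimate traits by MAP under that
#'     prior, and classify the fused [y, theta] features with Gaussian
#'     naive Bayes.}
#' }
#' With two text sources the runner also evaluates their concatenation,
#' giving the seven standard model variants (1 questionnaire, 3 text, 3
#' fused).
#'
#' @param responses integer response matrix (subjects x items).
#' @param labels low/high labels.
#' @param corpora named list of text sources; each element may be a
#'   character vector of documents, a \code{\link{text_corpus}}, a
#'   term-count matrix, or a \code{\link{simulate_text}} result. NULL runs
#'   the questionnaire-only method alone.
#' @param config a \code{\link{study_config}}.
#' @return object of class \code{"trait_study"}; its \code{report} element
#'   is the models-by-indicators table, and every reported metric is
#'   recomputable from the stored per-subject out-of-fold predictions.
#' @examples
#' sim <- simulate_study(sim_config(n = 150, m = 5, vocab_size = 60, seed = 3))
#' st <- run_study(sim$responses, sim$labels, sim$corpora,
#'                 config = study_config(seed = 3))
#' st
#' @export
run_study <- function(responses, labels, corpora = NULL,
                      config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  labels <- as_label(labels)
  responses <- as.matrix(responses)
  folds <- stratified_kfold(labels, config$k, seed = config$seed)
  fit <- grm(responses, method = config$item_method, D = config$D,
             seed = config$seed)
  grid <- seq(config$bounds[1], config$bounds[2],
              length.out = config$grid_points)
  coded <- recode_responses(fit, responses)
  Lmat <- loglik_matrix(fit$bank, coded, grid)
  # prior_sd_override widens every prior in the run (the baseline standard
  # normal and the fitted personal priors alike), so a diffuse setting makes
  # all methods collapse onto the grid maximum likelihood estimate
  base_sd <- if (is.null(config$prior_sd_override)) 1 else
    config$prior_sd_override
  th1 <- map_from_loglik(Lmat, grid, prior_spec(0, base_sd))$theta

  metrics <- list(); scores <- list(); prior_fits <- list()
  theta_fused <- list()

  m1 <- cv_metrics(function(tr, te) {
    rule <- threshold_rule(th1[tr], labels[tr], config$theta_rule)
    predict(rule, th1[te])
  }, labels, folds, average = config$average)
  metrics[["irt"]] <- m1

  if (!is.null(corpora) && length(corpora)) {
    if (is.null(names(corpora)))
      names(corpora) <- paste0("source", seq_along(corpora))
    counts <- lapply(corpora, to_counts)
    if (length(counts) >= 2L)
      counts$combined <- combine_counts(counts)
    for (src in names(counts)) {
      ts <- text_cv_scores(counts[[src]], labels, folds,
                           alpha = config$alpha, cost = config$cost,
                           kernel = config$kernel,
                           clamp_idf = config$clamp_idf, seed = config$seed)
      scores[[src]] <- ts
      metrics[[paste0("text_", src)]] <- cv_metrics(
        function(tr, te) ts$predictions[te], labels, folds,
        average = config$average)
      # Method 3 for this source
      th3_oof <- numeric(length(labels))
      regs <- vector("list", config$k)
      runner <- function(tr, te) {
        f <- folds[te[1]]
        reg <- prior_regression(th1[tr], ts$y[tr, f],
                                direction = config$prior_direction)
        if (!is.null(config$prior_sd_override))
          reg$sigma <- config$prior_sd_override
        regs[[f]] <<- reg
        pr <- personal_prior(reg, ts$y[, f])
        th3 <- map_from_loglik(Lmat, grid, pr)$theta
        th3_oof[te] <<- th3[te]
        nb <- gaussian_nb(cbind(y = ts$y[tr, f], theta = th3[tr]), labels[tr])
        predict(nb, cbind(y = ts$y[te, f], theta = th3[te]))
      }
      metrics[[paste0("fused_", src)]] <- cv_metrics(
        runner, labels, folds, average = config$average)
      theta_fused[[src]] <- th3_oof
      prior_fits[[src]] <- do.call(rbind, lapply(seq_len(config$k), function(f)
        data.frame(fold = f, b0 = regs[[f]]$b0, b1 = regs[[f]]$b1,
                   sigma = regs[[f]]$sigma)))
    }
  }

  report <- do.call(rbind, lapply(names(metrics), function(nm) {
    m <- unclass(metrics[[nm]]$metrics)
    data.frame(model = nm, ACC = m["accuracy"], SEN = m["sensitivity"],
               SPE = m["specificity"], PPV = m["ppv"], NPV = m["npv"],
               F1 = m["f1"], row.names = NULL)
  }))

  ids <- rownames(responses)
  if (is.null(ids)) ids <- paste0("S", seq_len(nrow(responses)))
  structure(list(report = report, metrics = metrics, folds = folds,
                 ids = ids, fit = fit, theta = th1,
                 theta_fused = theta_fused,
                 scores = scores, prior_fits = prior_fits,
                 labels = labels, config = config, call = match.call()),
            class = "trait_study")
}

#' @export
print.trait_study <- function(x, digits = 3, ...) {
  cat("Three-method latent trait study (", length(x$labels), " subjects, ",
      x$config$k, "-fold stratified CV, seed ", x$config$seed, ")\n\n",
      sep = "")
  rep2 <- x$report
  rep2[-1] <- lapply(rep2[-1], round, digits)
  print(rep2, row.names = FALSE)
  invisible(x)
}

#' @export
summary.trait_study <- function(object, ...) {
  th_sum <- function(v) c(min = min(v), max = max(v), mean = mean(v),
                          sd = stats::sd(v))
  ts <- rbind(irt = th_sum(object$theta))
  for (src in names(object$theta_fused))
    ts <- rbind(ts, th_sum(object$theta_fused[[src]]))
  rownames(ts) <- c("irt", paste0("fused_", names(object$theta_fused)))
  out <- list(report = object$report, theta_summary = ts,
              config = object$config)
  class(out) <- "summary.trait_study"
  out
}

#' @export
print.summary.trait_study <- function(x, digits = 3, ...) {
  rep2 <- x$report
  rep2[-1] <- lapply(rep2[-1], round, digits)
  print(rep2, row.names = FALSE)
  cat("\nTrait estimate summaries:\n")
  print(round(x$theta_summary, digits))
  invisible(x)
}

#' Write a deterministic study report to disk
#'
#' Emits \code{metrics.csv} (the models-by-indicators table),
#' \code{item_parameters.csv}, \code{theta.csv} (questionnaire-only and
#' fused out-of-fold trait estimates), \code{predictions.csv}
#' (per-subject out-of-fold calls of every model, from which every
#' reported metric is recomputable) and \code{manifest.json} (effective
#' configuration, fold assignment and per-fold prior-regression
#' coefficients). Output bytes depend only on the study object, so a rerun
#' with the same seed reproduces the files byte for byte.
#'
#' @param study a \code{trait_study}.
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of files written.
#' @export
write_report <- function(study, dir) {
  stopifnot(inherits(study, "trait_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  utils::write.csv(study$report, p("metrics.csv"), row.names = FALSE)
  cf <- coef(study$fit)
  utils::write.csv(data.frame(item = rownames(cf), cf, row.names = NULL),
                   p("item_parameters.csv"), row.names = FALSE)
  th <- data.frame(subject = study$ids, theta_irt = study$theta)
  for (src in names(study$theta_fused))
    th[[paste0("theta_fused_", src)]] <- study$theta_fused[[src]]
  utils::write.csv(th, p("theta.csv"), row.names = FALSE)
  pr <- data.frame(subject = study$ids,
                   truth = as.character(study$labels),
                   fold = study$folds)
  for (nm in names(study$metrics))
    pr[[nm]] <- as.character(study$metrics[[nm]]$predictions)
  utils::write.csv(pr, p("predictions.csv"), row.names = FALSE)
  manifest <- list(config = unclass(study$config),
                   folds = study$folds,
                   prior_regressions = study$prior_fits,
                   grm = list(method = study$fit$method,
                              cycles = study$fit$cycles,
                              converged = study$fit$converged))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = 10, pretty = TRUE, null = "null")
  invisible(vapply(c("metrics.csv", "item_parameters.csv", "theta.csv",
                     "predictions.csv", "manifest.json"), p, character(1)))
}

#' Score one candidate item subset by cross-validated classification
#'
#' Fits the GRM (EM) on the given items only, scores traits by MAP, and
#' measures cross-validated downstream classification accuracy:
#' \code{"m1"} uses the threshold rule on the traits, \code{"m3"} the
#' fused naive-Bayes route (requires per-fold text scores \code{y}), and
#' \code{"composite"} averages the two.
#'
#' @param responses full response matrix.
#' @param labels low/high labels.
#' @param items integer indices of the candidate subset.
#' @param y optional n x k matrix of per-fold text scores (from
#'   \code{\link{text_cv_scores}}).
#' @param criterion \code{"composite"}, \code{"m1"} or \code{"m3"}.
#' @param config a \code{\link{study_config}}.
#' @return scalar cross-validated accuracy of the chosen criterion.
#' @export
score_item_subset <- function(responses, labels, items, y = NULL,
                              criterion = c("composite", "m1", "m3"),
                              config = study_config()) {
  criterion <- match.arg(criterion)
  labels <- as_label(labels)
  if (criterion != "m1" && is.null(y)) criterion <- "m1"
  folds <- stratified_kfold(labels, config$k, seed = config$seed)
  fit <- grm(as.matrix(responses)[, items, drop = FALSE], method = "em",
             D = config$D, seed = config$seed)
  grid <- seq(config$bounds[1], config$bounds[2],
              length.out = config$grid_points)
  coded <- recode_responses(fit, as.matrix(responses)[, items, drop = FALSE])
  Lmat <- loglik_matrix(fit$bank, coded, grid)
  th1 <- map_from_loglik(Lmat, grid, prior_spec(0, 1))$theta
  acc_m1 <- if (criterion %in% c("m1", "composite")) {
    cv_metrics(function(tr, te) {
      rule <- threshold_rule(th1[tr], labels[tr], config$theta_rule)
      predict(rule, th1[te])
    }, labels, folds, average = config$average)$metrics[["accuracy"]]
  } else NA_real_
  acc_m3 <- if (criterion %in% c("m3", "composite")) {
    cv_metrics(function(tr, te) {
      f <- folds[te[1]]
      reg <- prior_regression(th1[tr], y[tr, f],
                              direction = config$prior_direction)
      th3 <- map_from_loglik(Lmat, grid, personal_prior(reg, y[, f]))$theta
      nb <- gaussian_nb(cbind(y[tr, f], th3[tr]), labels[tr])
      predict(nb, cbind(y[te, f], th3[te]))
    }, labels, folds, average = config$average)$metrics[["accuracy"]]
  } else NA_real_
  switch(criterion, m1 = acc_m1, m3 = acc_m3,
         composite = mean(c(acc_m1, acc_m3)))
}

#' Exhaustive search for the best-classifying item subset
#'
#' Evaluates every non-empty subset of the candidate items by
#' \code{\link{score_item_subset}} and returns the argmax. Ties are broken
#' towards the smaller subset, then lexicographically. Capped at 15
#' candidates (2^15 subsets).
#'
#' @inheritParams score_item_subset
#' @param candidates integer indices of the candidate items (default: all
#'   columns).
#' @return list: \code{items} (winning indices), \code{score},
#'   \code{table} (data.frame of every subset and its score).
#' @export
select_items_exhaustive <- function(responses, labels, candidates = NULL,
                                    y = NULL,
                                    criterion = c("composite", "m1", "m3"),
                                    config = study_config()) {
  criterion <- match.arg(criterion)
  responses <- as.matrix(responses)
  if (is.null(candidates)) candidates <- seq_len(ncol(responses))
  p <- length(candidates)
  if (p > 15L)
    stop("more than 15 candidate items (", p, "): exhaustive search is ",
         "capped at 2^15 subsets; pre-screen the candidates", call. = FALSE)
  subsets <- lapply(seq_len(2^p - 1L), function(mask)
    candidates[bitwAnd(mask, 2^(seq_len(p) - 1L)) > 0])
  # order by (size, lexicographic) so strict improvement implements the
  # tie-break towards smaller, then lexicographically earlier subsets
  ord <- order(lengths(subsets),
               vapply(subsets, function(s) paste(sprintf("%03d", s),
                                                 collapse = ","), ""))
  subsets <- subsets[ord]
  sc <- vapply(subsets, function(s)
    score_item_subset(responses, labels, s, y = y, criterion = criterion,
                      config = config), numeric(1))
  best <- which.max(sc)  # first max under the (size, lexico) ordering
  list(items = subsets[[best]], score = sc[best],
       table = data.frame(
         subset = vapply(subsets, paste, character(1), collapse = "+"),
         size = lengths(subsets), score = sc))
}
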