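test_that("preprocessing tokenizes, strips punctuation and drops stopwords", {
  cp <- text_corpus(c("the cat the mat"), stopwords = "the")
  expect_equal(cp$tokens[[1]], c("cat", "mat"))
  cp2 <- text_corpus("a b a c")
  expect_equal(cp2$tokens[[1]], c("a", "b", "a", "c"))
  # hand-counted three-line fixture
  cp3 <- text_corpus(c("good, work. good!", "bad work", "work work work"),
                     stopwords = character())
  cnt <- term_counts(cp3)
  expect_equal(cnt["S1", ], c(bad = 0, good = 2, work = 1))
  expect_equal(cnt["S2", ], c(bad = 1, good = 0, work = 1))
  expect_equal(cnt["S3", ], c(bad = 0, good = 0, work = 3))
  expect_warning(cp4 <- text_corpus(c("the", "ok"), stopwords = "the"),
                 "empty")
  expect_true(cp4$empty[1] && !cp4$empty[2])
})

test_that("tf-idf matches the hand-computed smoothed formula", {
  cp <- text_corpus(c("good good work", "bad work", "work fish"))
  w <- tfidf(cp)$weights
  # independent arithmetic, N = 3, natural log, 0.01-smoothed idf,
  # row-normalised by the Euclidean norm
  idf <- function(nt) log(3 / (nt + 0.01))
  raw1 <- c(bad = 0, fish = 0, good = 2 * idf(1), work = 1 * idf(3))
  expect_equal(w[1, ], raw1 / sqrt(sum(raw1^2)))
  raw2 <- c(bad = 1 * idf(1), fish = 0, good = 0, work = 1 * idf(3))
  expect_equal(w[2, ], raw2 / sqrt(sum(raw2^2)))
  # a term present in every document gets a slightly negative weight
  expect_lt(w[1, "work"], 0)
  # clamping floors the negative idf at zero
  expect_equal(tfidf(cp, clamp_idf = TRUE)$weights[1, "work"], 0)
})

test_that("tf-idf rows have unit norm; single-term docs weigh +/-1", {
  cp <- text_corpus(c("solo", "alpha beta", "beta gamma delta"))
  w <- tfidf(cp)$weights
  expect_equal(abs(w[1, "solo"]), 1)
  set.seed(2)
  counts <- matrix(rpois(20 * 40, 1.2), 20, 40,
                   dimnames = list(NULL, paste0("t", 1:40)))
  counts[1, ] <- c(5, rep(0, 39))
  w2 <- tfidf(counts)$weights
  nz <- rowSums(w2^2) > 0
  expect_equal(sqrt(rowSums(w2[nz, ]^2)), rep(1, sum(nz)), tolerance = 1e-10)
})

test_that("idf is fitted on the training documents and applied to test", {
  train <- matrix(c(2, 0, 1, 1, 0, 3), 2, 3,
                  dimnames = list(NULL, c("a", "b", "c")))
  fitted <- tfidf(train)
  expect_equal(fitted$model$N, 2)
  test <- matrix(c(1, 1, 1), 1, 3, dimnames = list(NULL, c("a", "b", "c")))
  w_test <- tfidf(test, model = fitted$model)$weights
  idf <- log(2 / (fitted$model$n_t + 0.01))
  expect_equal(w_test[1, ], idf / sqrt(sum(idf^2)))
})

test_that("F-test selection equals the squared two-sample t test", {
  set.seed(4)
  n <- 60
  lab <- rep(c(0, 1), each = n / 2)
  X <- matrix(rnorm(n * 50), n, 50)
  X[, 1] <- X[, 1] + lab        # informative feature
  sel <- f_test_select(X, lab, alpha = 0.1)
  for (j in sample(50, 25)) {
    tt <- t.test(X[lab == 1, j], X[lab == 0, j], var.equal = TRUE)
    expect_equal(sel$p[j], tt$p.value, tolerance = 1e-12)
    expect_equal(sel$statistic[j], unname(tt$statistic)^2, tolerance = 1e-10)
  }
  # a feature identical across classes is dropped, a constant gets p = 1
  X2 <- cbind(rep(c(1, 2), n / 2), rep(3, n), lab * 2)
  sel2 <- f_test_select(X2, lab)
  expect_false(sel2$keep[1])
  expect_equal(sel2$p[2], 1)
  expect_true(sel2$keep[3])     # disjoint supports, zero within-class var
  expect_equal(sel2$p[3], 0)
})

test_that("informative terms get smaller p-values than noise terms", {
  set.seed(6)
  hits <- 0L
  for (r in 1:20) {
    sim <- simulate_study(sim_config(n = 120, m = 3, vocab_size = 40,
                                     informative = 6, lambda = 1,
                                     class_effect = 0.5, seed = 300 + r))
    w <- tfidf(sim$corpora$essay$counts)$weights
    p <- f_test_select(w, sim$labels)$p
    if (median(p[1:6]) < median(p[-(1:6)])) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("calibrated SVM separates a separable fixture and ranks by margin", {
  set.seed(8)
  n <- 40
  lab <- rep(c("low", "high"), each = n / 2)
  X <- matrix(rnorm(n * 4, sd = 0.3), n, 4)
  X[lab == "high", 1] <- X[lab == "high", 1] + 3
  sc <- train_text_classifier(X, lab, X)
  expect_true(all((sc$y > 0) == (lab == "high")))
  expect_equal(sc$S1 + sc$S2, rep(1, n))
  # probabilities are monotone in the decision values
  dv <- attr(sc, "decision_values")
  expect_true(all(diff(sc$S1[order(dv)]) >= 0))
  # swapping the labels swaps the two class probabilities
  sc_sw <- train_text_classifier(X, ifelse(lab == "high", "low", "high"), X)
  expect_equal(sc_sw$S1, sc$S2, tolerance = 0.05)
  expect_error(train_text_classifier(matrix(0, 10, 2), rep(c(0, 1), 5),
                                     matrix(0, 10, 2)), "all-zero")
})

test_that("likelihood ratio is the clipped log odds", {
  expect_equal(likelihood_ratio(0.5, 0.5), 0)
  expect_equal(likelihood_ratio(0.8, 0.2), log(4))
  expect_equal(likelihood_ratio(0.3, 0.7), -likelihood_ratio(0.7, 0.3))
  expect_equal(likelihood_ratio(1, 0), log((1 - 1e-6) / 1e-6))
})

test_that("per-fold text scoring never peeks at test labels", {
  sim <- tiny_sim()
  folds <- stratified_kfold(sim$labels, 5, seed = 1)
  ts <- text_cv_scores(sim$corpora$essay$counts, sim$labels, folds)
  expect_equal(dim(ts$y), c(150, 5))
  # flipping the test-fold labels must leave the fold-1 model untouched
  lab2 <- sim$labels
  lab2[folds == 1] <- factor(ifelse(sim$labels[folds == 1] == "high",
                                    "low", "high"), c("low", "high"))
  ts2 <- text_cv_scores(sim$corpora$essay$counts, lab2, folds)
  expect_equal(ts$y[, 1], ts2$y[, 1])
})
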