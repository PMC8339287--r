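test_that("confusion counts match a hand tally", {
  pred <- c(1, 1, 1, 0, 0, 0, 1, 0, 1, 0)
  truth <- c(1, 1, 0, 1, 0, 0, 1, 1, 0, 0)
  cm <- confusion(pred, truth)
  expect_equal(unclass(cm)[c("a", "b", "c", "d")], c(a = 3L, b = 2L, c = 2L, d = 3L))
  expect_equal(attr(cm, "n"), 10L)
  perfect <- confusion(truth, truth)
  expect_equal(perfect[["b"]] + perfect[["c"]], 0L)
  flipped <- confusion(1 - truth, truth)
  expect_equal(flipped[["a"]] + flipped[["d"]], 0L)
  expect_error(confusion(c(1, 0), c(1, 0, 1)), "length")
})

test_that("the six indicators match their defining formulas", {
  m <- metric_set(c(a = 40, b = 10, c = 10, d = 40))
  expect_equal(unclass(m), c(accuracy = 0.8, sensitivity = 0.8,
                             specificity = 0.8, ppv = 0.8, npv = 0.8,
                             f1 = 0.8), ignore_attr = "undefined")
  # harmonic mean: sensitivity 0.5, precision 1 -> F1 = 2/3
  m2 <- metric_set(c(a = 1, b = 0, c = 1, d = 2))
  expect_equal(m2[["f1"]], 2 / 3)
  set.seed(20)
  for (r in 1:20) {
    cm <- c(a = rpois(1, 20), b = rpois(1, 10), c = rpois(1, 10),
            d = rpois(1, 20)) + 1
    m <- metric_set(cm)
    n <- sum(cm)
    expect_equal(m[["accuracy"]], (cm[["a"]] + cm[["d"]]) / n)
    expect_equal(m[["sensitivity"]], cm[["a"]] / (cm[["a"]] + cm[["c"]]))
    expect_equal(m[["specificity"]], cm[["d"]] / (cm[["b"]] + cm[["d"]]))
    expect_equal(m[["ppv"]], cm[["a"]] / (cm[["a"]] + cm[["b"]]))
    expect_equal(m[["npv"]], cm[["d"]] / (cm[["c"]] + cm[["d"]]))
    expect_equal(m[["f1"]], 2 / (1 / m[["sensitivity"]] + 1 / m[["ppv"]]))
    # structural identities
    expect_equal(m[["accuracy"]],
                 (m[["sensitivity"]] * (cm[["a"]] + cm[["c"]]) +
                  m[["specificity"]] * (cm[["b"]] + cm[["d"]])) / n)
    expect_gte(m[["f1"]], min(m[["sensitivity"]], m[["ppv"]]))
    expect_lte(m[["f1"]], max(m[["sensitivity"]], m[["ppv"]]))
  }
})

test_that("zero-denominator metrics are flagged and reported as 0", {
  m <- metric_set(c(a = 0, b = 0, c = 5, d = 5))  # nothing predicted high
  expect_equal(m[["ppv"]], 0)
  expect_true(attr(m, "undefined")[["ppv"]])
  expect_false(attr(m, "undefined")[["accuracy"]])
})

test_that("stratified folds are balanced, exhaustive and deterministic", {
  lab <- rep(c(0, 1), each = 50)
  f <- stratified_kfold(lab, 5, seed = 3)
  expect_equal(unname(table(f, lab)), matrix(10L, 5, 2))
  expect_identical(f, stratified_kfold(lab, 5, seed = 3))
  expect_false(identical(f, stratified_kfold(lab, 5, seed = 4)))
  expect_error(stratified_kfold(c(0, 0, 0, 1), 5), "at least k")
  set.seed(99)
  for (r in 1:100) {
    n <- sample(30:200, 1)
    lab <- rbinom(n, 1, runif(1, 0.3, 0.7))
    if (min(table(lab)) < 5) next
    f <- stratified_kfold(lab, 5, seed = r)
    expect_equal(sort(unique(f)), 1:5)
    # per-class fold counts differ by at most one
    for (c0 in unique(lab)) {
      cnt <- table(f[lab == c0])
      expect_lte(max(cnt) - min(cnt), 1)
    }
    expect_equal(length(f), n)  # a partition: every subject in one fold
  }
})

test_that("cross-validated metrics average validation folds", {
  lab <- rep(c(0, 1), each = 50)
  folds <- stratified_kfold(lab, 5, seed = 1)
  perfect <- cv_metrics(function(tr, te) as_label(lab[te]), lab, folds)
  expect_equal(unclass(perfect$metrics), rep(1, 6), ignore_attr = TRUE)
  expect_equal(mean(perfect$per_fold[, "accuracy"]),
               perfect$metrics[["accuracy"]])
  # identical fold composition + deterministic rule: macro equals pooled
  fixed <- function(tr, te) as_label(as.integer(lab[te] == 1 | te %% 7 == 0))
  m_macro <- cv_metrics(fixed, lab, folds, average = "macro")
  m_pool <- cv_metrics(fixed, lab, folds, average = "pooled")
  expect_equal(m_macro$metrics[["accuracy"]], m_pool$metrics[["accuracy"]],
               tolerance = 0.02)
  # a coin-flip rule on balanced labels sits near 0.5 across seeds
  accs <- vapply(1:30, function(s) {
    set.seed(s)
    cv_metrics(function(tr, te) as_label(rbinom(length(te), 1, 0.5)),
               lab, folds)$metrics[["accuracy"]]
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.05)
})

test_that("single-class validation folds are excluded with a warning", {
  lab <- c(rep(0, 12), rep(1, 12))
  folds <- c(rep(1, 6), rep(2, 6), rep(1, 3), rep(2, 3), rep(3, 6))
  expect_warning(
    out <- cv_metrics(function(tr, te) as_label(lab[te]), lab, folds),
    "single true class")
  expect_equal(out$metrics[["accuracy"]], 1)
})
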