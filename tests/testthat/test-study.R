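run_tiny_study <- function() memo("tiny_study", function() {
  sim <- tiny_sim()
  run_study(sim$responses, sim$labels, sim$corpora,
            config = study_config(seed = 202))
})

test_that("the runner reports the seven standard model variants", {
  st <- run_tiny_study()
  expect_s3_class(st, "trait_study")
  expect_equal(st$report$model,
               c("irt", "text_essay", "fused_essay", "text_microblog",
                 "fused_microblog", "text_combined", "fused_combined"))
  for (col in c("ACC", "SEN", "SPE", "PPV", "NPV", "F1"))
    expect_true(all(st$report[[col]] >= 0 & st$report[[col]] <= 1))
  # one shared fold assignment across methods
  expect_equal(length(st$folds), length(st$labels))
  expect_equal(sort(unique(st$folds)), 1:5)
})

test_that("reported metrics are recomputable from stored predictions", {
  st <- run_tiny_study()
  for (nm in names(st$metrics)) {
    cvm <- st$metrics[[nm]]
    recompute <- t(vapply(1:5, function(f) {
      unclass(metric_set(confusion(cvm$predictions[st$folds == f],
                                   st$labels[st$folds == f])))
    }, numeric(6)))
    expect_equal(unname(colMeans(recompute)),
                 unname(unlist(st$report[st$report$model == nm, -1])))
  }
})

test_that("rerunning with the same seed reproduces the report byte for byte", {
  sim <- tiny_sim()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  st1 <- run_study(sim$responses, sim$labels, sim$corpora,
                   config = study_config(seed = 11))
  st2 <- run_study(sim$responses, sim$labels, sim$corpora,
                   config = study_config(seed = 11))
  write_report(st1, d1); write_report(st2, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 5e6),
                     readBin(file.path(d2, f), "raw", 5e6))
  }
  st3 <- run_study(sim$responses, sim$labels, sim$corpora,
                   config = study_config(seed = 12))
  expect_false(identical(st1$report, st3$report))
})

test_that("a diffuse prior override collapses fused traits onto baseline", {
  sim <- tiny_sim()
  st <- run_study(sim$responses, sim$labels, sim$corpora["essay"],
                  config = study_config(seed = 5, prior_sd_override = 1e6))
  expect_lte(max(abs(st$theta_fused$essay - st$theta)), 0.05 + 1e-12)
})

test_that("exhaustive item search finds the informative item", {
  set.seed(40)
  n <- 200
  theta <- rnorm(n)
  strong <- item_bank(a = 2.5, b = matrix(c(-1, 0, 1), 1))
  resp <- cbind(sample(0:3, n, TRUE), simulate_responses(theta, strong,
                                                         seed = 41)[, 1],
                sample(0:3, n, TRUE))
  colnames(resp) <- paste0("item_", 1:3)
  labels <- ifelse(theta + rnorm(n, 0, 0.3) > 0, "high", "low")
  cfg <- study_config(seed = 4)
  sel <- select_items_exhaustive(resp, labels, criterion = "m1", config = cfg)
  expect_true(2 %in% sel$items)
  # the winning score equals an independent enumeration's maximum
  all_scores <- vapply(list(1, 2, 3, c(1, 2), c(1, 3), c(2, 3), 1:3),
                       function(s) score_item_subset(resp, labels, s,
                                                     criterion = "m1",
                                                     config = cfg),
                       numeric(1))
  expect_equal(sel$score, max(all_scores))
  expect_equal(nrow(sel$table), 7)
  # an exact duplicate of an item never improves the best score
  resp4 <- cbind(resp, item_4 = resp[, 2])
  sel4 <- select_items_exhaustive(resp4, labels, criterion = "m1",
                                  config = cfg)
  expect_equal(sel4$score, sel$score, tolerance = 1e-12)
  expect_error(select_items_exhaustive(matrix(0L, 10, 16), rep(0:1, 5)),
               "15 candidate")
})
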