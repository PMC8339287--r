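test_that("prior regression matches the normal equations on a fixture", {
  y <- c(-1, 0, 1, 2, 3)
  th <- c(-0.8, -0.1, 0.4, 1.1, 1.3)
  reg <- prior_regression(th, y)
  # closed-form least squares computed by hand
  b1 <- sum((y - mean(y)) * (th - mean(th))) / sum((y - mean(y))^2)
  b0 <- mean(th) - b1 * mean(y)
  expect_equal(reg$b1, b1)
  expect_equal(reg$b0, b0)
  res <- th - (b0 + b1 * y)
  expect_equal(reg$sigma, sqrt(sum(res^2) / (5 - 2)))
})

test_that("degenerate prior regressions are handled", {
  y <- c(-1, 0, 1, 2)
  exact <- suppressWarnings(prior_regression(2 * y, y))
  expect_equal(exact$b1, 2)
  expect_equal(exact$sigma, 1e-3)  # floored residual sd
  expect_warning(reg <- prior_regression(c(0.1, 0.5, 0.2), c(1, 1, 1)),
                 "constant")
  expect_equal(reg$b1, 0)
  set.seed(2)
  reg0 <- prior_regression(rnorm(500), rnorm(500))
  expect_lt(abs(reg0$b1), 0.15)
})

test_that("personal priors are linear in the text score", {
  reg <- structure(list(b0 = 0.05, b1 = 0.3, sigma = 1.4,
                        direction = "theta_on_y"),
                   class = "prior_regression")
  pr <- personal_prior(reg, c(0, 1, 2))
  expect_equal(pr$mean, 0.05 + 0.3 * c(0, 1, 2))
  expect_equal(pr$sd, 1.4)
  expect_equal(diff(pr$mean), rep(reg$b1, 2))
  # b1 = 0 collapses to one shared prior
  reg$b1 <- 0
  expect_equal(personal_prior(reg, c(-5, 5))$mean, rep(0.05, 2))
})

test_that("text-prior MAP matches a dense grid scan and shrinks correctly", {
  sim <- tiny_sim()
  fit <- grm(sim$responses, method = "em")
  set.seed(7)
  y <- rnorm(nrow(sim$responses))
  reg <- prior_regression(ability(fit, sim$responses)$theta, y)
  est <- ability_with_text_prior(fit, sim$responses, y, reg)
  grid <- attr(est, "grid")
  for (s in sample(nrow(sim$responses), 20)) {
    lp <- response_loglik(sim$responses[s, ], fit$bank, grid) +
      dnorm(grid, reg$b0 + reg$b1 * y[s], reg$sigma, log = TRUE)
    expect_equal(est$theta[s], grid[which.max(lp)])
  }
  # diffuse personal prior collapses onto the flat-prior estimate
  reg_d <- reg; reg_d$sigma <- 1e6
  est_d <- ability_with_text_prior(fit, sim$responses, y, reg_d)
  flat <- ability(fit, sim$responses, prior = prior_spec(0, 1e6))
  expect_lte(max(abs(est_d$theta - flat$theta)), 0.05 + 1e-12)
})

test_that("fused estimates lie between the MLE and the prior mean", {
  sim <- tiny_sim()
  fit <- grm(sim$responses, method = "em")
  mle <- ability(fit, sim$responses, prior = prior_spec(0, 1e6))$theta
  set.seed(8)
  mu <- rnorm(nrow(sim$responses))
  est <- ability(fit, sim$responses, prior = prior_spec(mu, 0.8))$theta
  step <- 0.05
  expect_true(all(est >= pmin(mle, mu) - step & est <= pmax(mle, mu) + step))
})

test_that("a weakly informative item leaves the estimate at the prior mean", {
  bank <- item_bank(a = 0.06, b = matrix(0, 1, 1))
  x <- matrix(1L, 3, 1)
  reg <- structure(list(b0 = 0.4, b1 = 0.5, sigma = 0.3,
                        direction = "theta_on_y"),
                   class = "prior_regression")
  est <- ability_with_text_prior(bank, x, y = c(-2, 0, 2), reg = reg)
  expect_equal(est$theta, round((0.4 + 0.5 * c(-2, 0, 2)) / 0.05) * 0.05,
               tolerance = 0.051)
})

test_that("gaussian naive Bayes agrees with the e1071 reference", {
  set.seed(10)
  n <- 200
  lab <- rep(c("low", "high"), each = n / 2)
  X <- cbind(y = rnorm(n) + (lab == "high"),
             theta = rnorm(n) + 0.5 * (lab == "high"))
  nb <- gaussian_nb(X, lab)
  ref <- e1071::naiveBayes(x = as.data.frame(X), y = factor(lab, c("low", "high")))
  expect_equal(nb$mu["high", "y"], ref$tables$y[2, 1], ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(sqrt(nb$var["low", "theta"]), ref$tables$theta[1, 2],
               ignore_attr = TRUE, tolerance = 1e-9)
  pred_ref <- predict(ref, as.data.frame(X))
  expect_gte(mean(predict(nb, X) == pred_ref), 0.995)
})

test_that("duplicated features double-count evidence exactly as computed", {
  set.seed(11)
  lab <- rep(c("low", "high"), each = 30)
  th <- rnorm(60) + (lab == "high")
  nb <- gaussian_nb(cbind(th, th), lab)
  # oracle: with the feature duplicated, each class log-likelihood term
  # appears twice, so the decision equals comparing 2*logdens + logprior
  new <- seq(-2, 3, by = 0.25)
  for (c0 in c("low", "high")) {
    expect_equal(nb$mu[c0, 1], nb$mu[c0, 2])
  }
  lp_high <- nb$log_prior["high"] + 2 * dnorm(new, nb$mu["high", 1],
                                              sqrt(nb$var["high", 1]), log = TRUE)
  lp_low <- nb$log_prior["low"] + 2 * dnorm(new, nb$mu["low", 1],
                                            sqrt(nb$var["low", 1]), log = TRUE)
  pred <- predict(nb, cbind(new, new))
  expect_equal(pred == "high", lp_high >= lp_low, ignore_attr = TRUE)
})

test_that("fused classification is perfect when y alone separates", {
  set.seed(12)
  n <- 100
  lab <- rep(c("low", "high"), each = n / 2)
  y <- ifelse(lab == "high", 2, -2) + rnorm(n, 0, 0.1)
  th <- rnorm(n)
  folds <- stratified_kfold(lab, 5, seed = 3)
  pred <- fuse_and_classify(cbind(y, th), lab, folds)
  expect_equal(as.character(pred), lab)
  expect_error(fuse_and_classify(cbind(c(Inf, y[-1]), th), lab, folds),
               "finite")
})
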