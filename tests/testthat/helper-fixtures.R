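# lazily built, memoised fixtures shared across test files
.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

# a mid-sized synthetic study used by several estimation tests
small_sim <- function() memo("small_sim", function()
  simulate_study(sim_config(n = 800, m = 6, K = 5, vocab_size = 80,
                            informative = 12, seed = 101)))

small_em_fit <- function() memo("small_em_fit", function()
  grm(small_sim()$responses, method = "em"))

# a tiny study with text, for pipeline-level tests
tiny_sim <- function() memo("tiny_sim", function()
  simulate_study(sim_config(n = 150, m = 5, K = 4, vocab_size = 60,
                            informative = 10, seed = 202)))

# random ordered boundary vector
rand_bounds <- function(k, sd = 1.2, gap = 0.05) {
  b <- sort(stats::rnorm(k, 0, sd))
  for (j in seq_along(b)[-1]) b[j] <- max(b[j], b[j - 1] + gap)
  b
}

# independent F1 used as an oracle (deliberately simple arithmetic)
oracle_f1 <- function(pred_high, truth_high) {
  tp <- sum(pred_high & truth_high)
  fp <- sum(pred_high & !truth_high)
  fn <- sum(!pred_high & truth_high)
  if (tp == 0) return(0)
  prec <- tp / (tp + fp); rec <- tp / (tp + fn)
  2 * prec * rec / (prec + rec)
}
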