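# Small search budgets keep these structural checks fast; the full-budget
# end-to-end behaviour is exercised by the acceptance suite.

fit_small <- function(seed = 1, variant = "cni1", ...) {
  sim <- synth_dtm(synth_spec(n_docs = 120, vocab_size = 20, n_informative = 4,
                              seed = 3))
  gwo_knn(sim$dtm, variant = variant, pop_size = 8, max_iter = 10,
          seed = seed, ...)
}

test_that("fits are reproducible and expose a coherent model object", {
  f1 <- fit_small()
  f2 <- fit_small()
  expect_equal(f1$mask, f2$mask)
  expect_equal(f1$fitness, f2$fitness)
  expect_s3_class(f1, "gwo_knn")
  expect_equal(f1$n_features, sum(f1$mask))
  expect_lte(abs(f1$fitness -
                 (f1$spec$w1 * f1$val_accuracy + f1$spec$w2 * f1$feature_ratio)),
             1e-12)
  expect_identical(f1$run$evaluations, 8L + 2L * 8L * 10L)
  # the fitness of the returned mask matches the optimizer's best value
  expect_equal(f1$fitness, f1$run$best_fitness)
})

test_that("coef, predict, and summary operate on the fitted selection", {
  f <- fit_small(seed = 5)
  cf <- coef(f)
  expect_length(cf, 20L)
  expect_identical(sum(cf), f$n_features)
  sim2 <- synth_dtm(synth_spec(n_docs = 30, vocab_size = 20, n_informative = 4,
                               seed = 99))
  pred <- predict(f, sim2$dtm)
  expect_length(pred, 30L)
  expect_true(all(pred %in% 0:1))
  s <- summary(f)
  expect_s3_class(s, "summary.gwo_knn")
  expect_output(print(s), "accuracy term")
  expect_output(print(f), "terms selected")
  expect_error(predict(f, sim2$dtm$x[, 1:5]), "columns")
})

test_that("an external validation set can drive the fitness", {
  sim <- synth_dtm(synth_spec(n_docs = 150, vocab_size = 20, n_informative = 4,
                              seed = 3))
  sp <- split_dtm(sim$dtm, 0.8, seed = 1)
  f <- gwo_knn(sp$train$x, sp$train$labels, variant = "nigwo", pop_size = 8,
               max_iter = 10, seed = 2, x_val = sp$test$x,
               y_val = sp$test$labels)
  expect_s3_class(f, "gwo_knn")
  expect_gte(f$val_accuracy, 0.5)
})

test_that("repeated-run experiments summarize and recompute consistently", {
  sim <- synth_dtm(synth_spec(n_docs = 120, vocab_size = 20, n_informative = 4,
                              seed = 3))
  ex <- run_experiment(sim$dtm$x, sim$dtm$labels, variant = "cni1",
                       n_runs = 3L, seeds = c(11L, 12L, 13L),
                       pop_size = 8, max_iter = 8)
  expect_length(ex$fitness, 3L)
  expect_equal(unname(ex$summary["best"]), max(ex$fitness))
  expect_equal(unname(ex$summary["mean"]), mean(ex$fitness))
  expect_equal(unname(ex$summary["worst"]), min(ex$fitness))
  expect_gte(ex$summary["best"], ex$summary["mean"])
  expect_gte(ex$summary["mean"], ex$summary["worst"])
  expect_equal(unname(ex$summary["n_features_best"]),
               ex$n_features[ex$best_run])
  expect_equal(ex$quartiles, box_quartiles(ex$fitness))
  # single-run degenerate case: best = mean = worst
  e1 <- run_experiment(sim$dtm$x, sim$dtm$labels, n_runs = 1L, seeds = 21L,
                       pop_size = 8, max_iter = 5)
  expect_equal(unname(e1$summary["best"]), unname(e1$summary["worst"]))
  expect_error(run_experiment(sim$dtm$x, sim$dtm$labels, n_runs = 2L,
                              seeds = c(1L, 1L)), "distinct")
})

test_that("variant comparison blocks runs by seed and feeds the Friedman test", {
  sim <- synth_dtm(synth_spec(n_docs = 120, vocab_size = 20, n_informative = 4,
                              seed = 3))
  # a configuration compared against itself on shared seeds: no rank variation
  cmp <- compare_variants(sim$dtm$x, sim$dtm$labels,
                          variants = c("cni1", "cni1"),
                          n_runs = 3L, seeds = c(5L, 6L, 7L),
                          pop_size = 8, max_iter = 6)
  expect_equal(nrow(cmp$table), 2L)
  expect_equal(cmp$friedman$chi2, 0)
  expect_false(cmp$friedman$reject_h0)
  # re-feeding the persisted per-run values reproduces the same statistic
  results <- vapply(cmp$experiments, function(e) e$fitness, numeric(3))
  expect_equal(friedman_rank_test(results)$chi2, cmp$friedman$chi2)
})
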