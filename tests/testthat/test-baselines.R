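featurized_split <- function(seed = 61) {
  # strong compositional signal so descriptor tables are cleanly separable
  d <- generate_sequences(synth_config(n_pos = 60, n_neg = 80,
                                       length_range = c(30, 70),
                                       motif_prob = 1, composition_shift = 1,
                                       seed = seed))
  stratified_split(d, seed = seed)
}

test_that("the baseline grid is the 5 x 5 cross product", {
  specs <- baseline_specs()
  expect_equal(nrow(specs), 25L)
  expect_equal(nrow(dplyr::distinct(specs, algorithm, descriptor)), 25L)
  expect_setequal(unique(specs$algorithm),
                  c("knn", "logistic_regression", "random_forest", "svm",
                    "gradient_boosting"))
  expect_setequal(unique(specs$descriptor),
                  c("aac", "apaac", "ctdc", "ctdd", "dde"))
})

test_that("fit_baseline picks validation-optimal hyperparameters from the grid", {
  sp <- featurized_split()
  ftr <- featurize(partition(sp, "train"), "aac")
  fva <- featurize(partition(sp, "val"), "aac")

  # grid of size 1 returns that model
  fit1 <- fit_baseline("random_forest", list(list(num_trees = 50)), ftr, fva, seed = 1)
  expect_equal(fit1$hyperparameters$num_trees, 50)

  grid <- purrr::map(c(3, 5, 7, 9), ~list(k = .x))
  fitk <- fit_baseline("knn", grid, ftr, fva, seed = 1)
  expect_true(fitk$hyperparameters$k %in% c(3, 5, 7, 9))
  expect_length(fitk$grid_val_auroc, 4L)
  expect_equal(fitk$val_auroc, max(fitk$grid_val_auroc))
  # ties (and the maximum) resolve to the first grid entry attaining it
  expect_equal(fitk$hyperparameters$k,
               c(3, 5, 7, 9)[which.max(fitk$grid_val_auroc)])
})

test_that("random forest separates a planted-signal descriptor table", {
  sp <- featurized_split()
  ftr <- featurize(partition(sp, "train"), "aac")
  fva <- featurize(partition(sp, "val"), "aac")
  fit <- fit_baseline("random_forest", list(list(num_trees = 200)), ftr, fva,
                      seed = 4)
  expect_gte(fit$val_auroc, 0.9)
})

test_that("degenerate all-constant features are rejected", {
  const <- tibble::tibble(id = c("a", "b", "c", "d"), label = c(1L, 0L, 1L, 0L),
                          f1 = 1, f2 = 2)
  expect_error(fit_baseline("svm", list(list(cost = 1)), const, const),
               "zero variance")
})

test_that("classical baselines are deterministic given their seed", {
  sp <- featurized_split()
  ftr <- featurize(partition(sp, "train"), "dde")
  fva <- featurize(partition(sp, "val"), "dde")
  fte <- featurize(partition(sp, "test"), "dde")
  x <- as.matrix(dplyr::select(fte, -id, -label))
  for (algo in list(list("random_forest", list(num_trees = 100)),
                    list("gradient_boosting", list(max_depth = 3)),
                    list("svm", list(cost = 1)))) {
    f1 <- fit_baseline(algo[[1]], list(algo[[2]]), ftr, fva, seed = 5)
    f2 <- fit_baseline(algo[[1]], list(algo[[2]]), ftr, fva, seed = 5)
    expect_identical(f1$scorer(x), f2$scorer(x))
  }
})

test_that("benchmark_grid scores every row on the shared test set and annotates failures", {
  sp <- featurized_split()
  specs <- dplyr::filter(baseline_specs(),
                         (algorithm == "knn" & descriptor == "aac") |
                         (algorithm == "random_forest" & descriptor == "aac") |
                         (algorithm == "gradient_boosting" & descriptor == "dde"))
  specs <- dplyr::bind_rows(specs,
                            tibble::tibble(algorithm = "perceptron",
                                           descriptor = "aac",
                                           grid = list(list(list()))))
  deep <- list("Bi-LSTM-Att" = tiny_model_config())
  res <- benchmark_grid(sp, specs = specs, deep_configs = deep,
                        train_cfg = train_config(max_epochs = 2, seed = 1),
                        seed = 1)
  expect_equal(nrow(res), 5L)
  ok <- res[is.na(res$error), ]
  expect_equal(nrow(ok), 4L)
  expect_true(all(ok$auroc >= 0 & ok$auroc <= 1))
  # the unknown algorithm is annotated, not fatal
  expect_match(res$error[res$model == "perceptron"], "unknown algorithm")
})

test_that("attention never hurts much on planted-signal data", {
  aurocs <- purrr::map_dfr(1:3, function(s) {
    d <- generate_sequences(synth_config(n_pos = 30, n_neg = 40,
                                         length_range = c(30, 60),
                                         motif_prob = 1, seed = 70 + s))
    sp <- stratified_split(d, seed = s)
    fit_pair <- purrr::map(c(TRUE, FALSE), function(att) {
      cfg <- model_config(cell = "gru", attention = att, embed_dim = 16L,
                          hidden_per_direction = 12L, fc_hidden = 8L)
      train(partition(sp, "train"), partition(sp, "val"), cfg,
            train_config(max_epochs = 5, seed = s))
    })
    tibble::tibble(seed = s,
                   with_att = evaluate(fit_pair[[1]], partition(sp, "test"))$auroc,
                   without = evaluate(fit_pair[[2]], partition(sp, "test"))$auroc)
  })
  expect_true(all(aurocs$with_att >= aurocs$without - 0.05))
})

test_that("the five deep ablation variants cover the published grid", {
  cfgs <- deep_variant_configs()
  expect_named(cfgs, c("RNN", "RNN-Att", "GRU", "GRU-Att", "Bi-LSTM-Att"))
  expect_equal(purrr::map_chr(cfgs, "cell"),
               c(RNN = "rnn", `RNN-Att` = "rnn", GRU = "gru",
                 `GRU-Att` = "gru", `Bi-LSTM-Att` = "lstm"))
  expect_equal(purrr::map_lgl(cfgs, "attention"),
               c(RNN = FALSE, `RNN-Att` = TRUE, GRU = FALSE,
                 `GRU-Att` = TRUE, `Bi-LSTM-Att` = TRUE))
})
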