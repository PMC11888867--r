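#' The classical baseline grid
#'
#' The cross product of five learning algorithms (k-NN, logistic regression,
#' random forest, SVM with RBF kernel, gradient boosting) and five sequence
#' descriptors (AAC, APAAC, CTDC, CTDD, DDE): 25 baseline specifications,
#' each with a small hyperparameter grid resolved on the validation set.
#'
#' @return A tibble with columns `algorithm`, `descriptor` and `grid`
#'   (list-column of named candidate lists), 25 rows.
#' @export
baseline_specs <- function() {
  algos <- c("knn", "logistic_regression", "random_forest", "svm",
             "gradient_boosting")
  grids <- list(
    knn = purrr::map(c(3, 5, 7, 9), ~list(k = .x)),
    logistic_regression = list(list()),
    random_forest = purrr::map(c(100, 500), ~list(num_trees = .x)),
    svm = purrr::map(c(0.1, 1, 10), ~list(cost = .x)),
    gradient_boosting = purrr::map(c(3, 6), ~list(max_depth = .x))
  )
  tidyr::expand_grid(algorithm = algos,
                     descriptor = c("aac", "apaac", "ctdc", "ctdd", "dde")) |>
    dplyr::mutate(grid = grids[.data$algorithm])
}

feature_matrix <- function(feats) {
  as.matrix(dplyr::select(feats, -"id", -"label"))
}

# fit one algorithm at one grid point; returns a scorer closure
fit_one <- function(algorithm, hp, x, y, seed) {
  if (all(apply(x, 2, stats::var) < 1e-12)) {
    stop("degenerate features: zero variance in every column", call. = FALSE)
  }
  switch(algorithm,
    knn = {
      force(x); force(y)
      function(newx) {
        pred <- class::knn(x, newx, factor(y, levels = c(0, 1)), k = hp$k,
                           prob = TRUE)
        p <- attr(pred, "prob")
        ifelse(pred == "1", p, 1 - p)
      }
    },
    logistic_regression = {
      df <- as.data.frame(x)
      fit <- suppressWarnings(stats::glm(y ~ ., data = cbind(y = y, df),
                                         family = stats::binomial()))
      function(newx) {
        suppressWarnings(unname(stats::predict(fit, as.data.frame(newx),
                                               type = "response")))
      }
    },
    random_forest = {
      fit <- ranger::ranger(x = x, y = factor(y, levels = c(0, 1)),
                            num.trees = hp$num_trees, probability = TRUE,
                            seed = seed, num.threads = 1)
      function(newx) stats::predict(fit, data = newx, num.threads = 1)$predictions[, "1"]
    },
    svm = {
      # standardize with training statistics; flat columns contribute 0
      mu <- colMeans(x); s <- apply(x, 2, stats::sd); s[s < 1e-12] <- Inf
      xs <- sweep(sweep(x, 2, mu, "-"), 2, s, "/")
      fit <- e1071::svm(xs, factor(y, levels = c(0, 1)), kernel = "radial",
                        cost = hp$cost, scale = FALSE)
      function(newx) {
        ns <- sweep(sweep(newx, 2, mu, "-"), 2, s, "/")
        dv <- attr(stats::predict(fit, ns, decision.values = TRUE),
                   "decision.values")
        # orient decision values so larger = more positive
        if (grepl("^0/1", colnames(dv)[1])) -drop(dv) else drop(dv)
      }
    },
    gradient_boosting = {
      dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
      fit <- xgboost::xgb.train(params = list(objective = "binary:logistic",
                                              max_depth = hp$max_depth,
                                              eta = 0.3, nthread = 1,
                                              seed = seed),
                                data = dtrain, nrounds = 100, verbose = 0)
      function(newx) {
        stats::predict(fit, xgboost::xgb.DMatrix(newx, nthread = 1))
      }
    },
    stop("unknown algorithm: ", algorithm, call. = FALSE))
}

#' Fit one classical baseline with validation-driven hyperparameters
#'
#' Fits every grid point on the training features, scores validation AUROC,
#' and keeps the maximizer (ties broken by first-in-grid order).
#'
#' @param algorithm,grid One row of [baseline_specs()]: the algorithm name
#'   and its candidate hyperparameter list.
#' @param train_feats,val_feats Featurized tibbles from [featurize()] with
#'   identical feature columns.
#' @param seed Seed for stochastic learners.
#' @return An `amyl_baseline`: list with the scoring closure, the chosen
#'   hyperparameters, and the validation AUROC per grid point.
#' @export
fit_baseline <- function(algorithm, grid, train_feats, val_feats, seed = 1L) {
  xtr <- feature_matrix(train_feats); ytr <- as.integer(train_feats$label)
  xva <- feature_matrix(val_feats); yva <- as.integer(val_feats$label)
  scored <- purrr::map(grid, function(hp) {
    scorer <- withr::with_seed(seed, fit_one(algorithm, hp, xtr, ytr, seed))
    list(hp = hp, scorer = scorer, val_auroc = auroc(scorer(xva), yva))
  })
  val_auc <- purrr::map_dbl(scored, "val_auroc")
  best <- scored[[which.max(val_auc)]]   # which.max takes the first maximum
  structure(list(algorithm = algorithm, scorer = best$scorer,
                 hyperparameters = best$hp, val_auroc = best$val_auroc,
                 grid_val_auroc = val_auc),
            class = "amyl_baseline")
}

#' Benchmark the full model grid on a shared split
#'
#' Runs the 25 classical baselines and any number of deep recurrent
#' variants on one fixed train/val/test split and reports one evaluation
#' row per model, mirroring the benchmark comparison table layout
#' (model, features, AUROC, BA, MCC, F1). Per-model failures are reported
#' as annotated rows without aborting the grid.
#'
#' @param split_records Output of [stratified_split()].
#' @param specs Baseline specifications (default [baseline_specs()]); pass a
#'   subset for quick runs.
#' @param deep_configs Named list of [model_config()]s (default the five
#'   ablation variants: RNN, RNN-Att, GRU, GRU-Att, Bi-LSTM-Att).
#' @param train_cfg An [train_config()] shared by the deep variants.
#' @param seed Seed for the stochastic classical learners.
#' @return A tibble: `model`, `features`, `auroc`, `balanced_accuracy`,
#'   `mcc`, `f1`, `error`.
#' @export
benchmark_grid <- function(split_records, specs = baseline_specs(),
                           deep_configs = deep_variant_configs(),
                           train_cfg = train_config(), seed = 1L) {
  tr <- partition(split_records, "train")
  va <- partition(split_records, "val")
  te <- partition(split_records, "test")
  test_ids <- sort(te$id)   # every row is scored on this exact membership

  eval_row <- function(model, features, fun) {
    res <- tryCatch(fun(), error = function(e) conditionMessage(e))
    if (is.character(res)) {
      tibble::tibble(model = model, features = features, auroc = NA_real_,
                     balanced_accuracy = NA_real_, mcc = NA_real_,
                     f1 = NA_real_, error = res)
    } else {
      tibble::tibble(model = model, features = features, auroc = res$auroc,
                     balanced_accuracy = res$balanced_accuracy, mcc = res$mcc,
                     f1 = res$f1, error = NA_character_)
    }
  }

  classical <- purrr::pmap(specs, function(algorithm, descriptor, grid) {
    eval_row(algorithm, descriptor, function() {
      ftr <- featurize(tr, descriptor)
      fva <- featurize(va, descriptor)
      fte <- featurize(te, descriptor)
      stopifnot(identical(sort(fte$id), test_ids))
      fit <- fit_baseline(algorithm, grid, ftr, fva, seed = seed)
      eval_scores(fit$scorer(feature_matrix(fte)), fte$label)
    })
  })

  deep <- purrr::imap(deep_configs, function(cfg, nm) {
    eval_row(nm, "sequence", function() {
      fit <- train(tr, va, cfg, train_cfg)
      evaluate(fit, te)
    })
  })

  dplyr::bind_rows(c(classical, unname(deep)))
}

#' The five deep ablation variants
#'
#' @param hidden_per_direction,embed_dim Shared architecture sizes.
#' @return Named list of [model_config()]s: RNN and GRU with and without
#'   attention, plus the attention-pooled Bi-LSTM.
#' @export
deep_variant_configs <- function(hidden_per_direction = 64L, embed_dim = 100L) {
  mk <- function(cell, attention) {
    model_config(cell = cell, attention = attention, embed_dim = embed_dim,
                 hidden_per_direction = hidden_per_direction)
  }
  list("RNN" = mk("rnn", FALSE), "RNN-Att" = mk("rnn", TRUE),
       "GRU" = mk("gru", FALSE), "GRU-Att" = mk("gru", TRUE),
       "Bi-LSTM-Att" = mk("lstm", TRUE))
}
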