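#' Multi-trial robustness protocol
#'
#' Repeats training and evaluation over `n_trials` seeded trials on a fixed
#' data split: trial `t` uses seed `base_seed + t` for weight initialization
#' and minibatch shuffling, keeping the partition itself fixed. Reports
#' per-trial AUROC, balanced accuracy, MCC and F1 plus their mean and
#' standard deviation, mirroring the 10-trial robustness table of the
#' benchmark protocol.
#'
#' @param split_records Output of [stratified_split()] (needs train, val and
#'   test partitions).
#' @param config An [model_config()].
#' @param train_cfg An [train_config()]; its `seed` is the trial base seed.
#' @param n_trials Number of trials (default 10).
#' @return An `amyl_trials` object: list with `trials` (one row per trial)
#'   and `summary` (mean/sd rows per metric).
#' @export
run_trials <- function(split_records, config = model_config(),
                       train_cfg = train_config(), n_trials = 10L) {
  stopifnot(n_trials >= 1L)
  tr <- partition(split_records, "train")
  va <- partition(split_records, "val")
  te <- partition(split_records, "test")

  rows <- purrr::map(seq_len(n_trials), function(t) {
    cfg_t <- train_cfg
    cfg_t$seed <- train_cfg$seed + t
    fit <- tryCatch(train(tr, va, config, cfg_t),
                    error = function(e) {
                      stop("trial ", t, " failed: ", conditionMessage(e), call. = FALSE)
                    })
    ev <- evaluate(fit, te)
    tibble::tibble(trial = t, seed = cfg_t$seed, best_epoch = fit$best_epoch,
                   auroc = ev$auroc, balanced_accuracy = ev$balanced_accuracy,
                   mcc = ev$mcc, f1 = ev$f1)
  })
  trials <- dplyr::bind_rows(rows)
  metrics <- c("auroc", "balanced_accuracy", "mcc", "f1")
  summary <- tidyr::pivot_longer(trials, dplyr::all_of(metrics),
                                 names_to = "metric", values_to = "value")
  summary <- dplyr::summarise(dplyr::group_by(summary, .data$metric),
                              mean = mean(.data$value),
                              sd = if (dplyr::n() > 1L) stats::sd(.data$value) else 0,
                              .groups = "drop")
  structure(list(trials = trials, summary = summary, n_trials = n_trials),
            class = "amyl_trials")
}

#' @export
print.amyl_trials <- function(x, ...) {
  cat(sprintf("<amyl_trials> %d trials\n", x$n_trials))
  print(x$summary)
  invisible(x)
}
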