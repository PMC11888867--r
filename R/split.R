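#' Stratified split specification
#'
#' Per-class record counts for the train/validation/test partition. The
#' defaults reproduce the benchmark partition of the 165 amyloid / 382
#' non-amyloid reference set: positives 117/15/33 and negatives 276/29/77
#' (totals 393/44/110). Other class totals are apportioned with the same
#' per-class fractions by largest remainder, ties going to train first.
#'
#' @param n_pos,n_neg Total positive / negative records to be split.
#' @return An `amyl_split_spec`: list with integer vectors `pos` and `neg`
#'   of (train, val, test) counts summing to the class totals.
#' @examples
#' split_spec(165, 382)  # the benchmark counts
#' split_spec(11, 22)    # proportionally scaled
#' @export
split_spec <- function(n_pos = 165L, n_neg = 382L) {
  stopifnot(n_pos >= 3L, n_neg >= 3L)
  apportion <- function(n, frac) {
    exact <- frac * n
    counts <- floor(exact)
    rem <- n - sum(counts)
    if (rem > 0) {
      extra <- order(exact - counts, decreasing = TRUE)[seq_len(rem)]
      counts[extra] <- counts[extra] + 1
    }
    stats::setNames(as.integer(counts), c("train", "val", "test"))
  }
  structure(list(pos = apportion(n_pos, c(117, 15, 33) / 165),
                 neg = apportion(n_neg, c(276, 29, 77) / 382)),
            class = "amyl_split_spec")
}

#' Stratified train/validation/test split
#'
#' Randomly assigns records to disjoint partitions with exactly the
#' per-class counts of the `spec` argument. Validation is carved from the training
#' portion of the same seeded stream, so the train+val pool is stable under
#' the seed.
#'
#' @param records Labeled record tibble (`label` 0/1).
#' @param spec An [split_spec()]; defaults to one scaled to the input class
#'   counts.
#' @param seed Integer seed; identical seeds give identical partitions.
#' @return The input tibble with a `partition` factor column
#'   (train/val/test).
#' @export
stratified_split <- function(records, spec = NULL, seed = 1L) {
  stopifnot("label" %in% names(records))
  labels <- as.integer(records$label)
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (is.null(spec)) spec <- split_spec(n_pos, n_neg)
  if (n_pos < sum(spec$pos)) {
    stop("insufficient positive records: need ", sum(spec$pos), ", have ", n_pos,
         call. = FALSE)
  }
  if (n_neg < sum(spec$neg)) {
    stop("insufficient negative records: need ", sum(spec$neg), ", have ", n_neg,
         call. = FALSE)
  }
  partition <- rep(NA_character_, nrow(records))
  withr::with_seed(seed, {
    for (cls in c(1L, 0L)) {
      counts <- if (cls == 1L) spec$pos else spec$neg
      idx <- sample(which(labels == cls))
      partition[idx[seq_len(counts["train"])]] <- "train"
      partition[idx[counts["train"] + seq_len(counts["val"])]] <- "val"
      partition[idx[counts["train"] + counts["val"] + seq_len(counts["test"])]] <- "test"
    }
  })
  dplyr::mutate(records,
                partition = factor(partition, levels = c("train", "val", "test")))
}

#' Extract one partition from a split record tibble
#'
#' @param split_records Output of [stratified_split()].
#' @param which One of `"train"`, `"val"`, `"test"`.
#' @return The subset tibble without the `partition` column.
#' @export
partition <- function(split_records, which = c("train", "val", "test")) {
  which <- match.arg(which)
  out <- dplyr::filter(split_records, .data$partition == which, !is.na(.data$partition))
  dplyr::select(out, -"partition")
}
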