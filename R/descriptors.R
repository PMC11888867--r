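#' Sequence descriptors for classical amyloid classifiers
#'
#' Fixed-length numeric feature vectors computed from a single canonicalized
#' amino-acid sequence. Unknown tokens carry no physicochemical assignment
#' and are excluded from all counts and normalizers.
#'
#' * `aac()` — amino acid composition: 20 relative residue frequencies.
#' * `dde()` — dipeptide deviation from expected mean: 400 standardized
#'   deviations of observed dipeptide fractions from codon-usage-derived
#'   theoretical means.
#' * `ctdc()` — composition of 3 physicochemical groups under 13 attributes
#'   (39 values in `[0, 1]`).
#' * `ctdd()` — distribution: percent position of the first, 25%, 50%, 75%
#'   and 100% occurrences of each group (195 values in `[0, 100]`).
#' * `apaac()` — amphiphilic pseudo-amino-acid composition: normalized AAC
#'   block plus hydrophobicity/hydrophilicity lag-correlation factors
#'   (20 + 2*lambda values).
#'
#' @param sequence A single canonicalized sequence string.
#' @param lambda Maximum correlation lag for `apaac()` (default 4); the
#'   sequence must be longer than `lambda` after unknown-token removal.
#' @param weight Weight of the correlation block in `apaac()` (default 0.05).
#' @return A named numeric vector; length depends only on the descriptor
#'   (and `lambda`), never on the sequence.
#' @name descriptors
NULL

strip_unknown <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  chars <- strsplit(toupper(sequence), "")[[1]]
  chars[chars %in% AA20]
}

#' @rdname descriptors
#' @export
aac <- function(sequence) {
  chars <- strip_unknown(sequence)
  if (length(chars) == 0L) stop("empty sequence (no canonical residues)", call. = FALSE)
  counts <- table(factor(chars, levels = AA20))
  stats::setNames(as.numeric(counts) / length(chars), paste0("AAC.", AA20))
}

#' @rdname descriptors
#' @export
dde <- function(sequence) {
  chars <- strip_unknown(sequence)
  n <- length(chars)
  if (n < 2L) stop("DDE needs at least 2 canonical residues, got ", n, call. = FALSE)
  dipep <- paste0(chars[-n], chars[-1])
  pairs <- as.vector(t(outer(AA20, AA20, paste0)))  # alphabetical: AA, AC, ..., YY
  dc <- as.numeric(table(factor(dipep, levels = pairs))) / (n - 1)
  ci <- CODON_COUNTS[substr(pairs, 1, 1)] / 61
  cj <- CODON_COUNTS[substr(pairs, 2, 2)] / 61
  tm <- unname(ci * cj)
  tv <- tm * (1 - tm) / (n - 1)
  stats::setNames((dc - tm) / sqrt(tv), paste0("DDE.", pairs))
}

ctd_group_index <- function(chars, groups) {
  # 1/2/3 group id per residue under one attribute
  g1 <- strsplit(groups[1], "")[[1]]
  g2 <- strsplit(groups[2], "")[[1]]
  ifelse(chars %in% g1, 1L, ifelse(chars %in% g2, 2L, 3L))
}

#' @rdname descriptors
#' @export
ctdc <- function(sequence) {
  chars <- strip_unknown(sequence)
  if (length(chars) == 0L) stop("empty sequence (no canonical residues)", call. = FALSE)
  out <- purrr::imap(CTD_GROUPS, function(groups, attr) {
    gi <- ctd_group_index(chars, groups)
    v <- tabulate(gi, nbins = 3L) / length(chars)
    stats::setNames(v, paste0("CTDC.", attr, ".G", 1:3))
  })
  unlist(unname(out))
}

#' @rdname descriptors
#' @export
ctdd <- function(sequence) {
  chars <- strip_unknown(sequence)
  n <- length(chars)
  if (n == 0L) stop("empty sequence (no canonical residues)", call. = FALSE)
  out <- purrr::imap(CTD_GROUPS, function(groups, attr) {
    gi <- ctd_group_index(chars, groups)
    v <- numeric(15)
    for (g in 1:3) {
      pos <- which(gi == g)
      pts <- if (length(pos) == 0L) rep(0, 5) else {
        take <- c(1L, pmax(1L, floor(length(pos) * c(0.25, 0.5, 0.75, 1))))
        100 * pos[take] / n
      }
      v[(g - 1L) * 5L + 1:5] <- pts
    }
    stats::setNames(v, paste0("CTDD.", attr, ".G", rep(1:3, each = 5), ".",
                              rep(c("first", "p25", "p50", "p75", "p100"), 3)))
  })
  unlist(unname(out))
}

#' @rdname descriptors
#' @export
apaac <- function(sequence, lambda = 4L, weight = 0.05) {
  stopifnot(lambda >= 0L, weight > 0)
  chars <- strip_unknown(sequence)
  n <- length(chars)
  if (n == 0L) stop("empty sequence (no canonical residues)", call. = FALSE)
  if (n <= lambda) {
    stop("APAAC needs sequence length > lambda: length ", n, " <= lambda ", lambda,
         call. = FALSE)
  }
  h1 <- standardize_scale(APAAC_HYDROPHOBICITY)[chars]
  h2 <- standardize_scale(APAAC_HYDROPHILICITY)[chars]
  tau <- numeric(2L * lambda)
  if (lambda > 0L) {
    for (j in seq_len(lambda)) {
      i <- seq_len(n - j)
      tau[2L * j - 1L] <- sum(h1[i] * h1[i + j]) / (n - j)
      tau[2L * j]      <- sum(h2[i] * h2[i + j]) / (n - j)
    }
  }
  f <- as.numeric(table(factor(chars, levels = AA20))) / n
  denom <- 1 + weight * sum(tau)
  vals <- c(f / denom, weight * tau / denom)
  names(vals) <- c(paste0("APAAC.", AA20),
                   if (lambda > 0L) paste0("APAAC.tau", rep(seq_len(lambda), each = 2),
                                           ".", rep(c("hb", "hl"), lambda)))
  vals
}

#' Featurize a set of records with one descriptor
#'
#' Applies one of the five descriptors to every record, returning a wide
#' tibble suitable for the classical baseline fitters.
#'
#' @param records Record tibble with `id`, `sequence` and optionally `label`.
#' @param descriptor One of `"aac"`, `"apaac"`, `"ctdc"`, `"ctdd"`, `"dde"`.
#' @param ... Passed to the descriptor function (e.g. `lambda`, `weight`).
#' @return A tibble: `id`, `label`, then one column per feature.
#' @examples
#' featurize(tibble::tibble(id = "p1", sequence = "ACDEFGHIKL", label = 1L), "aac")
#' @export
featurize <- function(records, descriptor = c("aac", "apaac", "ctdc", "ctdd", "dde"),
                      ...) {
  descriptor <- match.arg(descriptor)
  fn <- switch(descriptor, aac = aac, apaac = apaac, ctdc = ctdc,
               ctdd = ctdd, dde = dde)
  feats <- purrr::map(records$sequence, fn, ...)
  mat <- do.call(rbind, feats)
  dplyr::bind_cols(
    tibble::tibble(id = records$id,
                   label = if ("label" %in% names(records)) as.integer(records$label)
                           else NA_integer_),
    tibble::as_tibble(mat)
  )
}
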