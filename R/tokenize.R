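#' Map protein records to a padded integer-token batch
#'
#' Encodes each canonicalized sequence as a row of integer token indices
#' (pad/unknown = 0), right-padded with 0 to the batch maximum length. The
#' mask marks real-residue positions; padded positions are never seen by the
#' recurrent encoder's attention pooling.
#'
#' @param records Tibble with a `sequence` column (and optionally `id`,
#'   `label`), or a character vector of sequences.
#' @param alphabet An [aa_alphabet()] object.
#' @param max_len Optional cap on sequence length; longer sequences keep
#'   their N-terminal prefix. Default 1000.
#' @return An `amyl_batch`: list with `indices` (n x L integer matrix),
#'   `lengths` (integer vector), `mask` (n x L logical matrix), `labels`
#'   (integer vector or NULL) and `ids`.
#' @examples
#' tokenize(tibble::tibble(sequence = c("AC", "ACDE")))
#' @export
tokenize <- function(records, alphabet = aa_alphabet(), max_len = 1000L) {
  if (is.character(records)) {
    records <- tibble::tibble(id = paste0("s", seq_along(records)),
                              sequence = records)
  }
  if (nrow(records) == 0L) stop("no records to tokenize", call. = FALSE)
  stopifnot(max_len >= 1L)

  seqs <- records$sequence
  lens <- pmin(nchar(seqs), as.integer(max_len))
  if (any(lens == 0L)) stop("empty sequence at record ", which(lens == 0L)[1], call. = FALSE)
  L <- max(lens)
  n <- length(seqs)

  idx <- matrix(0L, n, L)
  for (i in seq_len(n)) {
    chars <- strsplit(substr(seqs[i], 1L, lens[i]), "")[[1]]
    ix <- alphabet$index_of[chars]
    if (anyNA(ix)) {
      stop("non-canonical character in record ", i, "; canonicalize first", call. = FALSE)
    }
    idx[i, seq_len(lens[i])] <- unname(ix)
  }
  mask <- matrix(seq_len(L), n, L, byrow = TRUE) <=
    matrix(lens, n, L)

  structure(list(indices = idx, lengths = lens, mask = mask,
                 labels = if ("label" %in% names(records)) as.integer(records$label) else NULL,
                 ids = if ("id" %in% names(records)) records$id else NULL,
                 alphabet = alphabet),
            class = "amyl_batch")
}

#' Recover sequences from a tokenized batch
#'
#' Inverse of [tokenize()] restricted to the mask: padded positions are
#' dropped, so the canonicalized (possibly truncated) sequence is returned.
#'
#' @param batch An `amyl_batch`.
#' @return Character vector of sequences.
#' @export
detokenize <- function(batch) {
  stopifnot(inherits(batch, "amyl_batch"))
  tokens <- batch$alphabet$tokens
  vapply(seq_len(nrow(batch$indices)), function(i) {
    paste0(tokens[batch$indices[i, seq_len(batch$lengths[i])] + 1L], collapse = "")
  }, character(1))
}

#' @export
print.amyl_batch <- function(x, ...) {
  cat(sprintf("<amyl_batch> %d sequences, padded length %d, lengths %d-%d\n",
              nrow(x$indices), ncol(x$indices), min(x$lengths), max(x$lengths)))
  invisible(x)
}

# slice a batch to rows `i`, trimming padding columns to the new max length
batch_subset <- function(batch, i) {
  lens <- batch$lengths[i]
  L <- max(lens)
  structure(list(indices = batch$indices[i, seq_len(L), drop = FALSE],
                 lengths = lens,
                 mask = batch$mask[i, seq_len(L), drop = FALSE],
                 labels = batch$labels[i],
                 ids = batch$ids[i],
                 alphabet = batch$alphabet),
            class = "amyl_batch")
}
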