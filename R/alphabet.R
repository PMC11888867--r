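#' The 21-token amino-acid alphabet
#'
#' The model vocabulary: the 20 canonical residues in alphabetical order plus
#' a single combined pad/unknown token at index 0. Index 0 doubles as padding
#' in tokenized batches and as the replacement for non-canonical residue
#' codes (B, J, O, U, Z, X, `*`), so the embedding row for it can be pinned
#' at zero and masked out of attention.
#'
#' @return An object of class `amyl_alphabet`: a list with `tokens` (length
#'   21 character vector, pad/unknown first) and `index_of` (named integer
#'   vector mapping token to index in `[0, 20]`).
#' @examples
#' ab <- aa_alphabet()
#' ab$index_of[["A"]]  # 1
#' @export
aa_alphabet <- function() {
  residues <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  tokens <- c(AMYL_UNKNOWN, residues)
  index_of <- stats::setNames(seq_along(tokens) - 1L, tokens)
  structure(list(tokens = tokens, index_of = index_of),
            class = "amyl_alphabet")
}

# pad/unknown glyph; "?" is not a legal residue code in any FASTA dialect
AMYL_UNKNOWN <- "?"

# residue codes that are legal in FASTA but carry no single canonical residue
AMYL_NONCANONICAL <- c("B", "J", "O", "U", "Z", "X", "*")

#' Canonicalize an amino-acid sequence
#'
#' Uppercases the sequence and replaces every non-canonical residue code
#' (B, J, O, U, Z, X, `*`) with the unknown token. Any character outside the
#' amino-acid alphabet entirely (digits, gaps, ...) is an error.
#'
#' @param x Character vector of sequences.
#' @return A list with `sequence` (canonicalized character vector) and
#'   `n_substituted` (integer vector, substitutions per sequence).
#' @keywords internal
canonicalize_sequence <- function(x) {
  x <- toupper(x)
  pattern <- paste0("[", gsub("\\*", "\\\\*", paste(AMYL_NONCANONICAL, collapse = "")), "]")
  n_sub <- vapply(gregexpr(pattern, x), function(m) {
    if (m[1] == -1L) 0L else length(m)
  }, integer(1))
  out <- gsub(pattern, AMYL_UNKNOWN, x)
  bad <- grepl(paste0("[^ACDEFGHIKLMNPQRSTVWY", "\\", AMYL_UNKNOWN, "]"), out)
  if (any(bad)) {
    stop("sequence ", which(bad)[1], " contains characters outside the amino-acid alphabet",
         call. = FALSE)
  }
  list(sequence = out, n_substituted = n_sub)
}
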