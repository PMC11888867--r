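#' Read labeled protein records from FASTA
#'
#' Parses a (multi-line) FASTA file into a tibble of protein records,
#' uppercasing sequences and replacing non-canonical residue codes
#' (B, J, O, U, Z, X, `*`) with the unknown token. A warning reports the
#' total number of substitutions.
#'
#' @param path Path to a FASTA file.
#' @param label Optional binary label attached to every record
#'   (1 = amyloid/positive, 0 = non-amyloid/negative), or `NA` for unlabeled.
#' @return A tibble with columns `id` (first whitespace-delimited header
#'   token), `sequence` (canonicalized string) and `label` (integer or `NA`),
#'   one row per FASTA entry in file order.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "MKV", ">p2", "ACDE"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path, label = NA_integer_) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) == 0L) stop("empty FASTA input: ", path, call. = FALSE)

  is_header <- startsWith(lines, ">")
  if (!is_header[1]) {
    stop("malformed FASTA: sequence line before any header at line 1 of ", path,
         call. = FALSE)
  }
  entry <- cumsum(is_header)
  ids <- sub("^>\\s*", "", lines[is_header])
  ids <- vapply(strsplit(ids, "\\s+"), `[`, character(1), 1L)
  seqs <- vapply(split(lines[!is_header], entry[!is_header]),
                 paste0, character(1), collapse = "")
  # entries with a header but no sequence line are invalid
  if (length(seqs) != length(ids) || any(!nzchar(seqs))) {
    empty <- setdiff(seq_along(ids), as.integer(names(seqs)[nzchar(seqs)]))
    stop("FASTA entry without sequence: ", ids[empty[1]], call. = FALSE)
  }
  seqs <- gsub("\\s+", "", unname(seqs))

  canon <- canonicalize_sequence(seqs)
  if (sum(canon$n_substituted) > 0L) {
    warning(sum(canon$n_substituted),
            " non-canonical residue(s) replaced by the unknown token in ",
            basename(path), call. = FALSE)
  }
  tibble::tibble(id = ids, sequence = canon$sequence,
                 label = as.integer(label))
}

#' Write protein records to FASTA
#'
#' @param records A tibble with `id` and `sequence` columns (as returned by
#'   [read_fasta()] or [generate_sequences()]).
#' @param path Output path.
#' @param width Line width for wrapping sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  out <- purrr::map2(records$id, records$sequence, function(id, s) {
    starts <- seq(1L, nchar(s), by = width)
    c(paste0(">", id), substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  })
  writeLines(unlist(out), path)
  invisible(path)
}

#' Read a positive and a negative FASTA file as one labeled dataset
#'
#' @param pos,neg Paths to FASTA files holding the amyloid (label 1) and
#'   non-amyloid (label 0) sequences.
#' @return A labeled record tibble, positives first.
#' @export
read_labeled_fasta <- function(pos, neg) {
  dplyr::bind_rows(read_fasta(pos, label = 1L), read_fasta(neg, label = 0L))
}
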