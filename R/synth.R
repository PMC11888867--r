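#' Synthetic dataset configuration
#'
#' Controls the seeded generator of labeled synthetic protein sequences.
#' Negatives are i.i.d. draws from the background residue distribution;
#' positives optionally carry a planted amyloid-like motif (default the
#' polar-zipper-like heptamer "QNNQQNY") at a uniform random position and a
#' configurable hydrophobic composition shift. Defaults mirror the benchmark
#' class balance at reduced size: 150 positives, 380 negatives, lengths
#' uniform on 30-200.
#'
#' @param n_pos,n_neg Number of positive / negative sequences.
#' @param length_range Integer (min, max) sequence lengths, uniform.
#' @param motif Residue string planted in positives (canonical residues
#'   only); must fit within the minimum length.
#' @param motif_prob Fraction of positives carrying the motif, in `[0, 1]`.
#' @param background Length-20 residue frequency vector (alphabetical
#'   order), summing to 1. Default uniform.
#' @param composition_shift Nonnegative log-odds tilt of the positive-class
#'   background toward hydrophobic residues (AVLIMFWC); 0 disables it.
#' @param seed Integer seed.
#' @return An `amyl_synth_config` list.
#' @export
synth_config <- function(n_pos = 150L, n_neg = 380L, length_range = c(30L, 200L),
                         motif = "QNNQQNY", motif_prob = 1,
                         background = rep(1 / 20, 20),
                         composition_shift = 0, seed = 1L) {
  stopifnot(n_pos >= 1L, n_neg >= 1L, length(length_range) == 2L,
            length_range[1] <= length_range[2],
            motif_prob >= 0, motif_prob <= 1,
            length(background) == 20L, abs(sum(background) - 1) < 1e-9,
            composition_shift >= 0)
  motif_chars <- strsplit(toupper(motif), "")[[1]]
  if (!all(motif_chars %in% AA20)) {
    stop("motif contains non-canonical residues: ",
         paste(setdiff(motif_chars, AA20), collapse = ", "), call. = FALSE)
  }
  if (length(motif_chars) > length_range[1]) {
    stop("minimum length ", length_range[1], " is shorter than the motif (",
         length(motif_chars), ")", call. = FALSE)
  }
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 length_range = as.integer(length_range), motif = toupper(motif),
                 motif_prob = motif_prob, background = background,
                 composition_shift = composition_shift, seed = as.integer(seed)),
            class = "amyl_synth_config")
}

HYDROPHOBIC_SET <- strsplit("AVLIMFWC", "")[[1]]

#' Generate a labeled synthetic protein dataset
#'
#' @param config An [synth_config()].
#' @return A record tibble: `id`, `sequence`, `label`, `motif_planted`
#'   (logical). Same seed, same tibble.
#' @examples
#' generate_sequences(synth_config(n_pos = 3, n_neg = 3, seed = 7))
#' @export
generate_sequences <- function(config = synth_config()) {
  stopifnot(inherits(config, "amyl_synth_config"))
  bg_pos <- config$background *
    exp(config$composition_shift * (AA20 %in% HYDROPHOBIC_SET))
  bg_pos <- bg_pos / sum(bg_pos)
  m <- nchar(config$motif)

  withr::with_seed(config$seed, {
    draw <- function(n, freq) {
      lens <- sample(seq(config$length_range[1], config$length_range[2]),
                     n, replace = TRUE)
      vapply(lens, function(len) {
        paste0(sample(AA20, len, replace = TRUE, prob = freq), collapse = "")
      }, character(1))
    }
    pos <- draw(config$n_pos, bg_pos)
    planted <- stats::runif(config$n_pos) < config$motif_prob
    for (i in which(planted)) {
      len <- nchar(pos[i])
      start <- sample.int(len - m + 1L, 1L)
      substr(pos[i], start, start + m - 1L) <- config$motif
    }
    neg <- draw(config$n_neg, config$background)
  })

  tibble::tibble(
    id = c(sprintf("pos_%03d", seq_len(config$n_pos)),
           sprintf("neg_%03d", seq_len(config$n_neg))),
    sequence = c(pos, neg),
    label = rep(c(1L, 0L), c(config$n_pos, config$n_neg)),
    motif_planted = c(planted, rep(FALSE, config$n_neg))
  )
}
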