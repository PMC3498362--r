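# Shared internal helpers: sequence normalization, reverse complement,
# half-away-from-zero rounding, percentage formatting.

#' Normalize small-RNA sequences to the DNA alphabet
#'
#' Uppercases and converts U to T so that genome matching, quantification and
#' duplex scoring all operate in DNA space regardless of whether inputs were
#' written as RNA or DNA.
#'
#' @param x Character vector of sequences.
#' @param allow_n Allow the ambiguity letter N (default `TRUE`).
#' @return Character vector over `{A,C,G,T}` (and `N` if allowed).
#' @export
normalize_seq <- function(x, allow_n = TRUE) {
  x <- chartr("u", "T", toupper(as.character(x)))
  x <- chartr("U", "T", x)
  alphabet <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(alphabet, x)
  if (any(bad)) {
    stop("invalid characters in sequence(s): ",
         paste(utils::head(x[bad], 3L), collapse = ", "))
  }
  x
}

#' Reverse complement of DNA sequences
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# round half away from zero (base round() is banker's rounding)
round_half_away <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Composition-table percentage dialect: two decimals below 10 percent,
# one decimal at or above, half rounded away from zero.
format_pct <- function(x) {
  ifelse(is.na(x), NA_real_,
         ifelse(abs(x) < 10, round_half_away(x, 2L), round_half_away(x, 1L)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
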