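# fold: weighted base-pair-maximization secondary-structure prediction.
#
# A Nussinov-style dynamic program over nested structures with pair weights
# GC = 3, AU = 2, GU = 1, a minimum hairpin loop of 3 unpaired nucleotides,
# and a fully deterministic traceback: when scores tie, leaving the 5' base
# unpaired is preferred over pairing it, and among equal-scoring partners the
# smallest index wins. Deterministic and dependency-free, so every output is
# checkable against exhaustive enumeration on short sequences. A
# thermodynamic minimum-free-energy folder can be plugged in anywhere a
# dot-bracket string of the same length is supplied.

# pair weight lookup over codes A=1 C=2 G=3 T/U=4
PAIR_W <- matrix(0L, 4L, 4L)
PAIR_W[1L, 4L] <- PAIR_W[4L, 1L] <- 2L # A:U
PAIR_W[2L, 3L] <- PAIR_W[3L, 2L] <- 3L # C:G
PAIR_W[3L, 4L] <- PAIR_W[4L, 3L] <- 1L # G:U wobble

seq_codes <- function(seq) {
  s <- strsplit(normalize_seq(seq, allow_n = FALSE), "")[[1]]
  match(s, c("A", "C", "G", "T"))
}

#' Predict a nested secondary structure by weighted pair maximization
#'
#' @param seq Sequence over `{A,C,G,T,U}` (length <= 400 by default; the
#'   dynamic program is cubic).
#' @param min_loop Minimum number of unpaired bases in a hairpin loop
#'   (default 3).
#' @param max_len Guard against accidental genome-sized inputs.
#' @return List with `structure` (dot-bracket string), `score` (total pair
#'   weight) and `partner` (integer vector; 0 = unpaired, else 1-based index
#'   of the pairing partner).
#' @export
fold_rna <- function(seq, min_loop = 3L, max_len = 400L) {
  s <- seq_codes(seq)
  n <- length(s)
  if (n > max_len) stop("sequence longer than max_len (", max_len, ")")
  partner <- integer(n)
  if (n == 0L) return(list(structure = "", score = 0L, partner = partner))
  # M[i, j]: best score on s[i..j]; padded so empty intervals read 0
  M <- matrix(0L, n + 1L, n + 1L)
  gap <- min_loop + 1L
  if (n > gap) {
    for (span in (gap + 1L):n) {
      for (i in 1L:(n - span + 1L)) {
        j <- i + span - 1L
        best <- M[i + 1L, j]
        ks <- (i + gap):j
        w <- PAIR_W[s[i], s[ks]]
        ok <- w > 0L
        if (any(ok)) {
          ks <- ks[ok]
          cand <- w[ok] + M[i + 1L, ks - 1L] + M[cbind(ks + 1L, j)]
          best <- max(best, max(cand))
        }
        M[i, j] <- best
      }
    }
    # deterministic traceback
    stack <- list(c(1L, n))
    while (length(stack)) {
      ij <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      i <- ij[1L]; j <- ij[2L]
      while (i < j) {
        if (M[i, j] == M[i + 1L, j]) { # prefer i unpaired on ties
          i <- i + 1L
          next
        }
        ks <- (i + gap):j
        w <- PAIR_W[s[i], s[ks]]
        cand <- ifelse(w > 0L, w + M[i + 1L, ks - 1L] + M[cbind(ks + 1L, j)], -1L)
        k <- ks[which(cand == M[i, j])[1L]] # smallest partner wins ties
        partner[i] <- k
        partner[k] <- i
        if (k + 1L < j + 1L) stack[[length(stack) + 1L]] <- c(k + 1L, j)
        j <- k - 1L
        i <- i + 1L
      }
    }
  }
  db <- rep(".", n)
  db[partner > seq_len(n)] <- "("
  db[partner > 0L & partner < seq_len(n)] <- ")"
  list(structure = paste(db, collapse = ""),
       score = M[1L, n], partner = partner)
}

#' Parse a dot-bracket string into a partner vector
#'
#' @param structure Dot-bracket string (balanced).
#' @return Integer vector: 0 for unpaired, else partner index (1-based).
#' @export
parse_dot_bracket <- function(structure) {
  ch <- strsplit(structure, "")[[1]]
  partner <- integer(length(ch))
  open <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      open <- c(open, i)
    } else if (ch[i] == ")") {
      if (length(open) == 0L) stop("unbalanced dot-bracket string")
      j <- open[length(open)]
      open <- open[-length(open)]
      partner[i] <- j
      partner[j] <- i
    } else if (ch[i] != ".") {
      stop("invalid character in dot-bracket string: ", ch[i])
    }
  }
  if (length(open)) stop("unbalanced dot-bracket string")
  partner
}
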