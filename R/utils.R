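## Small sequence helpers shared across modules.  Sequences are plain
## uppercase character scalars over {A,C,G,T,N}; coordinates are 1-based
## closed intervals throughout (GenBank convention).

#' Reverse complement of a DNA string
#'
#' @param x character vector of DNA strings over \code{A,C,G,T,N,-}.
#' @return character vector of reverse complements.
#' @examples
#' revcomp("TTCCT")  # "AGGAA"
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  out <- chartr("ACGTN-", "TGCAN-", x)
  vapply(strsplit(out, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

## complement without reversal (used for arm checks)
comp <- function(x) chartr("ACGTN", "TGCAN", x)

## validate a DNA string; gaps optionally allowed
check_dna <- function(x, allow_gap = FALSE, what = "sequence") {
  alpha <- if (allow_gap) "ACGTN-" else "ACGTN"
  bad <- grepl(sprintf("[^%s]", alpha), x)
  if (any(bad))
    stop(sprintf("%s contains characters outside {%s}", what,
                 paste(strsplit(alpha, "")[[1]], collapse = ",")), call. = FALSE)
  invisible(x)
}

## circular modular index: map any integer position onto 1..n
wrap1 <- function(pos, n) ((pos - 1L) %% n) + 1L

## substring on a circular sequence: start 1..n, any length <= n
circ_substr <- function(seq, start, len) {
  n <- nchar(seq)
  stopifnot(len <= n)
  start <- wrap1(start, n)
  if (start + len - 1L <= n) {
    substr(seq, start, start + len - 1L)
  } else {
    paste0(substr(seq, start, n), substr(seq, 1L, start + len - 1L - n))
  }
}

## rotate a circular sequence so that position `start` becomes position 1
rotate_seq <- function(seq, start) circ_substr(seq, start, nchar(seq))

## Levenshtein distance via utils::adist
edit_dist <- function(a, b) as.integer(adist(a, b))

## canonical rotation of an SSR unit: lexicographically smallest rotation
canonical_rotation <- function(unit) {
  vapply(unit, function(u) {
    k <- nchar(u)
    if (k == 1L) return(u)
    rots <- vapply(seq_len(k), function(i)
      paste0(substr(u, i, k), substr(u, 1L, i - 1L)), character(1))
    min(rots)
  }, character(1), USE.NAMES = FALSE)
}

## deterministic per-purpose seed derived from a master seed (kept < 2^31)
derive_seed <- function(seed, salt) {
  (as.integer(seed) * 7919L + as.integer(salt) * 104729L) %% 2147483629L
}
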