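## diversity: sliding-window nucleotide diversity (pi) over an alignment.
## pi is Nei's average pairwise proportion of differing sites; a site is
## valid only when every row carries A/C/G/T there (complete deletion per
## window), and the denominator is the valid-site count, not the window
## length, so gap-rich spacers are not deflated.

#' Sliding-window nucleotide diversity
#'
#' For each window, \eqn{\pi = [n(n-1)/2]^{-1} \sum_{i<j} d_{ij} / m}
#' where \eqn{d_{ij}} counts differing valid sites between rows i and j and
#' m is the number of valid sites.  Windows with zero valid sites report
#' \code{NA} (undefined, not 0).  Partial windows at the alignment tail are
#' dropped.
#'
#' @param alignment \code{\link{make_alignment}} object with >= 2 rows.
#' @param window window length in alignment columns (default 600).
#' @param step step size in columns (default 200).
#' @param pairwise_deletion if \code{TRUE}, sites are validated per pair
#'   instead of across all rows.
#' @return data frame: \code{window_start, window_end, midpoint, pi,
#'   n_valid_sites}.
#' @export
pi_sliding <- function(alignment, window = 600L, step = 200L,
                       pairwise_deletion = FALSE) {
  n <- length(alignment$labels)
  if (n < 2L) stop("nucleotide diversity needs at least 2 alignment rows")
  if (step < 1L || window < step) stop("need window >= step >= 1")
  L <- alignment$n_col
  if (L < window)
    return(data.frame(window_start = integer(0), window_end = integer(0),
                      midpoint = integer(0), pi = numeric(0),
                      n_valid_sites = integer(0)))
  M <- do.call(rbind, strsplit(unname(alignment$seqs), "", fixed = TRUE))
  isb <- M == "A" | M == "C" | M == "G" | M == "T"
  npairs <- n * (n - 1) / 2

  starts <- seq(1L, L - window + 1L, by = step)
  out <- data.frame(window_start = starts, window_end = starts + window - 1L,
                    midpoint = starts + (window - 1L) %/% 2L,
                    pi = NA_real_, n_valid_sites = 0L)
  if (!pairwise_deletion) {
    valid_col <- colSums(isb) == n
    ## per-column pairwise difference count: C(n,2) - sum_b C(count_b, 2)
    diff_col <- numeric(L)
    cols <- which(valid_col)
    if (length(cols)) {
      cnt <- sapply(c("A", "C", "G", "T"), function(b)
        colSums(M[, cols, drop = FALSE] == b))
      if (is.null(dim(cnt))) cnt <- matrix(cnt, nrow = 1)
      same <- rowSums(cnt * (cnt - 1) / 2)
      diff_col[cols] <- npairs - same
    }
    cs_valid <- cumsum(valid_col)
    cs_diff <- cumsum(diff_col)
    v0 <- c(0, cs_valid); d0 <- c(0, cs_diff)
    for (k in seq_along(starts)) {
      a <- starts[k]; b <- a + window - 1L
      m <- v0[b + 1L] - v0[a]
      out$n_valid_sites[k] <- m
      if (m > 0) out$pi[k] <- (d0[b + 1L] - d0[a]) / npairs / m
    }
  } else {
    for (k in seq_along(starts)) {
      a <- starts[k]; b <- a + window - 1L
      tot <- 0; used <- 0L
      for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        ok <- isb[i, a:b] & isb[j, a:b]
        m <- sum(ok)
        if (m > 0) {
          tot <- tot + sum(M[i, a:b][ok] != M[j, a:b][ok]) / m
          used <- used + 1L
        }
      }
      out$n_valid_sites[k] <- sum(colSums(isb[, a:b, drop = FALSE]) == n)
      if (used > 0) out$pi[k] <- tot / npairs
    }
  }
  out
}

#' Rank contiguous high-diversity regions
#'
#' Maximal runs of windows with \eqn{\pi \ge} threshold are merged into
#' regions and ranked by peak \eqn{\pi}.  Windows with undefined \eqn{\pi}
#' break runs.
#'
#' @param windows \code{\link{pi_sliding}} output.
#' @param threshold \eqn{\pi} cutoff (default 0.015, a practical screen for
#'   plastome divergence hotspots).
#' @param record optional annotated \code{\link{plastome_record}} whose
#'   coordinates match alignment columns (gap-free alignments); used to
#'   label regions.
#' @return data frame ranked by peak pi: \code{start, end, n_windows,
#'   peak_pi, mean_pi, region}.
#' @export
hotspot_rank <- function(windows, threshold = 0.015, record = NULL) {
  hi <- !is.na(windows$pi) & windows$pi >= threshold
  out <- data.frame(start = integer(0), end = integer(0),
                    n_windows = integer(0), peak_pi = numeric(0),
                    mean_pi = numeric(0), region = character(0))
  if (!any(hi)) return(out)
  r <- rle(hi)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  runs <- which(r$values)
  rows <- lapply(runs, function(k) {
    w <- windows[idx_start[k]:idx_end[k], , drop = FALSE]
    data.frame(start = min(w$window_start), end = max(w$window_end),
               n_windows = nrow(w), peak_pi = max(w$pi),
               mean_pi = mean(w$pi), region = NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(record) && !is.null(record$features)) {
    for (i in seq_len(nrow(out))) {
      mid <- (out$start[i] + out$end[i]) %/% 2L
      mid <- min(mid, record$length_bp)
      cl <- classify_region(record, mid)
      out$region[i] <- if (cl$functional == "IGS") paste0("IGS:", cl$flanking)
                       else cl$functional
    }
  }
  out[order(-out$peak_pi), , drop = FALSE]
}
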