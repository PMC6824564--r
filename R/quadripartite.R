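## quadripartite: exact inverted-repeat detection and LSC/IRb/SSC/IRa
## partitioning of circular plastomes.

#' Construct a quadripartite partition
#'
#' Intervals are on the circle of the input sequence, stored as
#' \code{(start, len)} pairs (1-based; an interval may wrap the origin).
#' By plastome convention the genome reads LSC, IRb, SSC, IRa; the larger
#' single-copy region is the LSC.
#'
#' @param lsc,irb,ssc,ira integer \code{c(start, len)} pairs.
#' @param length_bp genome length.
#' @param at_content A+T fraction over the whole genome.
#' @return object of class \code{quadripartite_partition}.
#' @export
quadripartite_partition <- function(lsc, irb, ssc, ira, length_bp, at_content) {
  stopifnot(irb[2] == ira[2], lsc[2] >= ssc[2],
            lsc[2] + ssc[2] + irb[2] + ira[2] == length_bp)
  structure(list(lsc = lsc, irb = irb, ssc = ssc, ira = ira,
                 lsc_len = lsc[2], ir_len = irb[2], ssc_len = ssc[2],
                 length_bp = length_bp, at_content = at_content),
            class = "quadripartite_partition")
}

#' @export
print.quadripartite_partition <- function(x, ...) {
  cat(sprintf(
    "<quadripartite_partition> total %s bp: LSC %s | IR %s (x2) | SSC %s; AT %.1f%%\n",
    format(x$length_bp, big.mark = ","), format(x$lsc_len, big.mark = ","),
    format(x$ir_len, big.mark = ","), format(x$ssc_len, big.mark = ","),
    100 * x$at_content))
  invisible(x)
}

#' A+T content of a genome
#'
#' @param record \code{\link{plastome_record}} or a DNA string.
#' @return (A + T) / (A + C + G + T); \code{N} is excluded from both counts.
#' @export
at_content <- function(record) {
  s <- if (inherits(record, "plastome_record")) record$sequence else toupper(record)
  if (!nzchar(s)) stop("empty sequence")
  cnt <- table(strsplit(s, "", fixed = TRUE)[[1]])
  acgt <- sum(cnt[intersect(names(cnt), c("A", "C", "G", "T"))])
  if (acgt == 0) stop("sequence has no A/C/G/T bases")
  at <- sum(cnt[intersect(names(cnt), c("A", "T"))])
  as.numeric(at / acgt)
}

#' Detect the quadripartite structure of a circular plastome
#'
#' Finds the maximal-length pair of exact inverted-repeat copies (searching
#' across the circular origin) and derives the four compartments; the larger
#' single-copy interval is labelled LSC.  When two maximal pairs exist the
#' pair giving the smallest canonical LSC start is chosen.
#'
#' @param record \code{\link{plastome_record}} (circular).
#' @param min_ir_len minimum IR copy length in bp (default 10000; lower it
#'   for small synthetic genomes).
#' @return \code{\link{quadripartite_partition}}.
#' @export
detect_partition <- function(record, min_ir_len = 10000L) {
  s <- record$sequence
  n <- nchar(s)
  if (min_ir_len < 4L) stop("min_ir_len must be >= 4")
  s2 <- paste0(s, s)
  y <- revcomp(s2)
  hits <- .cpp_common_substrings(s2, y, as.integer(min_ir_len))
  cand <- NULL
  if (nrow(hits)) {
    ## a match X[i..] == Y[j..] means S2[p2..] == revcomp(S2[i..]) with
    ## p2 = 2n - (j + len - 1) + 1
    len <- hits$len
    i <- hits$x_start
    p2 <- 2L * n - (hits$y_start + len - 1L) + 1L
    a <- wrap1(i, n); b <- wrap1(p2, n)
    keep <- 2L * len <= n
    ## arms must not overlap on the circle
    gap_ab <- (b - (a + len)) %% n
    gap_ba <- (a - (b + len)) %% n
    keep <- keep & (gap_ab + gap_ba + 2L * len == n)
    cand <- unique(data.frame(a = pmin(a, b)[keep], b = pmax(a, b)[keep],
                              len = len[keep]))
  }
  if (is.null(cand) || !nrow(cand))
    stop("no quadripartite structure: no inverted repeat >= ", min_ir_len,
         " bp found in ", record$taxon_label)
  cand <- cand[cand$len == max(cand$len), , drop = FALSE]
  cand <- cand[order(cand$a, cand$b), , drop = FALSE][1, ]
  a <- cand$a; b <- cand$b; L <- cand$len
  gap1 <- (b - (a + L)) %% n          # circle gap following arm at a
  gap2 <- (a - (b + L)) %% n          # circle gap following arm at b
  if (gap1 >= gap2) {
    ## LSC is the gap after arm a: order LSC, arm(b)=IRb? No --
    ## reading around the circle: arm(a), gap1 (larger), arm(b), gap2.
    ## LSC = gap1 => preceding arm a is IRa, following arm b is IRb.
    lsc <- c(wrap1(a + L, n), gap1)
    irb <- c(b, L)
    ssc <- c(wrap1(b + L, n), gap2)
    ira <- c(a, L)
  } else {
    lsc <- c(wrap1(b + L, n), gap2)
    irb <- c(a, L)
    ssc <- c(wrap1(a + L, n), gap1)
    ira <- c(b, L)
  }
  quadripartite_partition(lsc, irb, ssc, ira, n, at_content(record))
}

## which compartment does each position fall in (positions on the input circle)
partition_compartment <- function(partition, position) {
  n <- partition$length_bp
  lab <- rep("unassigned", length(position))
  nice <- c(lsc = "LSC", irb = "IRb", ssc = "SSC", ira = "IRa")
  for (nm in names(nice)) {
    iv <- partition[[nm]]
    if (iv[2] == 0L) next
    off <- (position - iv[1]) %% n
    lab[off < iv[2]] <- nice[[nm]]
  }
  lab
}

#' Extract the four compartment sequences in canonical order
#'
#' @param record \code{\link{plastome_record}} with a partition (or one is
#'   detected with \code{min_ir_len}).
#' @param min_ir_len forwarded to \code{\link{detect_partition}} if needed.
#' @return named character vector \code{c(LSC=, IRb=, SSC=, IRa=)};
#'   concatenated they reproduce the canonical rotation of the genome
#'   (LSC first).
#' @export
partition_slices <- function(record, min_ir_len = 10000L) {
  p <- record$partition
  if (is.null(p)) p <- detect_partition(record, min_ir_len)
  s <- record$sequence
  c(LSC = circ_substr(s, p$lsc[1], p$lsc[2]),
    IRb = circ_substr(s, p$irb[1], p$irb[2]),
    SSC = circ_substr(s, p$ssc[1], p$ssc[2]),
    IRa = circ_substr(s, p$ira[1], p$ira[2]))
}

#' Rotate a record so the LSC starts at position 1
#'
#' Standard plastome reporting convention; feature coordinates are shifted
#' along (features spanning the new origin are dropped with a warning).
#'
#' @param record \code{\link{plastome_record}} with (or able to detect) a
#'   partition.
#' @param min_ir_len forwarded to \code{\link{detect_partition}}.
#' @return rotated \code{\link{plastome_record}} with partition attached.
#' @export
canonicalize_rotation <- function(record, min_ir_len = 10000L) {
  p <- record$partition
  if (is.null(p)) p <- detect_partition(record, min_ir_len)
  n <- record$length_bp
  shift <- p$lsc[1] - 1L
  s <- rotate_seq(record$sequence, p$lsc[1])
  f <- record$features
  if (!is.null(f) && nrow(f)) {
    ns <- wrap1(f$start - shift, n); ne <- wrap1(f$end - shift, n)
    drop <- ns > ne
    if (any(drop)) warning("dropping ", sum(drop),
                           " feature interval(s) spanning the new origin")
    f <- f[!drop, , drop = FALSE]
    f$start <- ns[!drop]; f$end <- ne[!drop]
  }
  newpos <- function(iv) c(wrap1(iv[1] - shift, n), iv[2])
  np <- quadripartite_partition(newpos(p$lsc), newpos(p$irb), newpos(p$ssc),
                                newpos(p$ira), n, p$at_content)
  plastome_record(record$taxon_label, s, features = f,
                  is_circular = record$is_circular, partition = np)
}

#' Tabulate partitions for a set of records
#'
#' @param records list of \code{\link{plastome_record}}.
#' @param min_ir_len forwarded to \code{\link{detect_partition}}.
#' @return data frame with one row per taxon: total, LSC, IR, SSC lengths and
#'   AT percentage (the layout of standard plastome summary tables).
#' @export
partition_report <- function(records, min_ir_len = 10000L) {
  rows <- lapply(records, function(r) {
    p <- if (is.null(r$partition)) detect_partition(r, min_ir_len) else r$partition
    data.frame(taxon = r$taxon_label, total_bp = p$length_bp,
               lsc_bp = p$lsc_len, ir_bp = p$ir_len, ssc_bp = p$ssc_len,
               at_pct = round(100 * p$at_content, 1), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
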