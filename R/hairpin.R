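## hairpin: stem-loop detection and nearest-neighbour free-energy scoring.

#' Nearest-neighbour thermodynamic parameters for DNA hairpins
#'
#' Loads a unified DNA stack table (kcal/mol at 37 C) and a length-indexed
#' hairpin loop initiation penalty.  Both are shipped as TSV files under
#' \code{inst/extdata} so alternative parameter sets can be swapped in.
#' Loop penalties beyond the table are extrapolated with a Jacobson-
#' Stockmayer \code{1.75 * R * T * log(n / n_max)} term.
#'
#' @param stacks_file,loops_file optional paths to replacement TSVs with the
#'   same columns as the shipped defaults.
#' @param temperature Celsius; parameters are tabulated at 37 C and the
#'   value is recorded on the object.
#' @return object of class \code{thermo_params} with elements
#'   \code{stack_energies} (named numeric, all 16 dinucleotides, negative)
#'   and \code{hairpin_loop_penalty} (numeric indexed by loop length,
#'   positive).
#' @export
default_thermo_params <- function(stacks_file = NULL, loops_file = NULL,
                                  temperature = 37) {
  if (is.null(stacks_file))
    stacks_file <- system.file("extdata", "nn_stacks.tsv",
                               package = "plastoflip", mustWork = TRUE)
  if (is.null(loops_file))
    loops_file <- system.file("extdata", "hairpin_loop_penalties.tsv",
                              package = "plastoflip", mustWork = TRUE)
  st <- read.delim(stacks_file, stringsAsFactors = FALSE)
  lp <- read.delim(loops_file, stringsAsFactors = FALSE)
  stacks <- setNames(st$dg37_kcal_mol, st$dinucleotide)
  dinucs <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                            paste0))
  if (!all(dinucs %in% names(stacks)))
    stop("stack table is missing dinucleotides: ",
         paste(setdiff(dinucs, names(stacks)), collapse = ", "))
  if (any(stacks >= 0)) stop("all stack energies must be negative")
  loops <- setNames(lp$dg37_kcal_mol, lp$loop_len)
  if (any(loops <= 0)) stop("all loop penalties must be positive")
  structure(list(stack_energies = stacks, hairpin_loop_penalty = loops,
                 temperature = temperature), class = "thermo_params")
}

loop_penalty <- function(params, loop_len) {
  tab <- params$hairpin_loop_penalty
  lens <- as.integer(names(tab))
  loop_len <- max(loop_len, min(lens))
  if (loop_len <= max(lens)) return(unname(tab[as.character(loop_len)]))
  rt <- 0.0019872 * (273.15 + params$temperature)
  unname(tab[as.character(max(lens))]) + 1.75 * rt * log(loop_len / max(lens))
}

#' Find stem-loop (hairpin) structures in a DNA sequence
#'
#' Enumerates loci where a 5' arm pairs with the reverse complement of a 3'
#' arm around an unpaired loop.  Returned loci are maximal: arms are
#' extended outward as far as the mismatch budget allows, never end on a
#' mismatch, and are not extendable inward; among candidates with
#' overlapping loops only the longest stem is kept (ties: leftmost start).
#'
#' @param seq DNA string over \code{A,C,G,T} (\code{N} never pairs).
#' @param min_stem,max_stem stem length bounds in bp (defaults 8 and 40).
#' @param min_loop,max_loop loop length bounds in bp (defaults 4 and 30).
#' @param max_mismatch allowed mismatched pairs within the stem (default 0).
#' @return data frame of hairpin loci, sorted by \code{genome_start}:
#'   columns \code{genome_start, genome_end, stem_len, loop_start, loop_end,
#'   loop_len, stem_seq} (5' arm), \code{arm3_seq}, \code{loop_seq},
#'   \code{mismatches_in_stem, delta_g} (NA until scored).
#' @export
find_hairpins <- function(seq, min_stem = 8L, max_stem = 40L, min_loop = 4L,
                          max_loop = 30L, max_mismatch = 0L) {
  seq <- toupper(seq)
  check_dna(seq)
  if (min_stem < 4L) stop("min_stem must be >= 4")
  if (min_loop < 1L || max_loop < min_loop || max_stem < min_stem)
    stop("inconsistent stem/loop bounds")
  h <- .cpp_find_hairpins(seq, as.integer(min_stem), as.integer(max_stem),
                          as.integer(min_loop), as.integer(max_loop),
                          as.integer(max_mismatch))
  h <- as.data.frame(h, stringsAsFactors = FALSE)
  if (!nrow(h)) {
    h$loop_len <- integer(0)
    h$arm3_seq <- character(0)
    h$delta_g <- numeric(0)
    return(h[, c("genome_start", "genome_end", "stem_len", "loop_start",
                 "loop_end", "loop_len", "stem_seq", "arm3_seq", "loop_seq",
                 "mismatches_in_stem", "delta_g")])
  }
  if (nrow(h)) {
    ## Suppress conflicting alternative folds: two candidates conflict
    ## unless their extents are disjoint or one lies entirely within the
    ## other's (unpaired) loop, in which case both can fold.  Among
    ## conflicting candidates the longest stem wins, then the most compact
    ## fold (shortest loop, i.e. lowest loop penalty), then leftmost start.
    ord <- order(-h$stem_len, h$loop_end - h$loop_start, h$genome_start,
                 h$loop_start)
    h <- h[ord, , drop = FALSE]
    keep <- logical(nrow(h))
    acc <- integer(0)
    compatible <- function(i, j) {
      h$genome_end[i] < h$genome_start[j] ||
        h$genome_end[j] < h$genome_start[i] ||
        (h$genome_start[i] >= h$loop_start[j] &&
           h$genome_end[i] <= h$loop_end[j]) ||
        (h$genome_start[j] >= h$loop_start[i] &&
           h$genome_end[j] <= h$loop_end[i])
    }
    for (i in seq_len(nrow(h))) {
      ok <- TRUE
      for (j in acc) if (!compatible(i, j)) { ok <- FALSE; break }
      if (ok) { keep[i] <- TRUE; acc <- c(acc, i) }
    }
    h <- h[keep, , drop = FALSE]
    h <- h[order(h$genome_start, h$loop_start), , drop = FALSE]
  }
  h$loop_len <- h$loop_end - h$loop_start + 1L
  h$arm3_seq <- substring(seq, h$loop_end + 1L, h$genome_end)
  h$delta_g <- rep(NA_real_, nrow(h))
  rownames(h) <- NULL
  h[, c("genome_start", "genome_end", "stem_len", "loop_start", "loop_end",
        "loop_len", "stem_seq", "arm3_seq", "loop_seq",
        "mismatches_in_stem", "delta_g")]
}

#' Free energy of a hairpin under the nearest-neighbour model
#'
#' \eqn{\Delta G} = sum of stack energies over consecutive matched stem
#' pairs + the hairpin-loop initiation penalty for the loop length.  The
#' model depends only on the stem and the loop length, so the two loop
#' orientations of a flip-flop locus score identically by construction.
#'
#' @param h one hairpin: a single row of \code{\link{find_hairpins}} output,
#'   or a list with \code{stem_seq}, \code{loop_len} and optionally
#'   \code{arm3_seq} (defaults to the perfect complement).
#' @param params \code{\link{default_thermo_params}} object.
#' @param include_loop if \code{FALSE} return the stem-only duplex energy
#'   without the loop initiation term.
#' @return kcal/mol (negative for stable stems), with attribute
#'   \code{"stem_dg"} carrying the stem-only energy.
#' @export
hairpin_delta_g <- function(h, params = default_thermo_params(),
                            include_loop = TRUE) {
  stem <- toupper(if (is.data.frame(h)) h$stem_seq[1] else h$stem_seq)
  k <- nchar(stem)
  if (k < 2L) stop("stem too short to stack")
  arm3 <- if (!is.null(h$arm3_seq) && !is.na(h$arm3_seq[1]))
    toupper(if (is.data.frame(h)) h$arm3_seq[1] else h$arm3_seq)
  else revcomp(stem)
  loop_len <- if (is.data.frame(h)) h$loop_len[1] else h$loop_len
  s5 <- strsplit(stem, "", fixed = TRUE)[[1]]
  s3 <- strsplit(arm3, "", fixed = TRUE)[[1]]
  ## pair t of the stem: s5[t] with s3[k + 1 - t]
  paired <- s3[k + 1L - seq_len(k)] == comp(s5)
  stem_dg <- 0
  for (t in seq_len(k - 1L)) {
    if (paired[t] && paired[t + 1L])
      stem_dg <- stem_dg + params$stack_energies[[substr(stem, t, t + 1L)]]
  }
  dg <- if (include_loop) stem_dg + loop_penalty(params, loop_len) else stem_dg
  structure(dg, stem_dg = stem_dg)
}

#' Score a table of hairpins in place
#'
#' @param hairpins output of \code{\link{find_hairpins}}.
#' @param params \code{\link{default_thermo_params}} object.
#' @return the same data frame with \code{delta_g} (full hairpin energy) and
#'   \code{stem_dg} (stem-only) filled in.
#' @export
score_hairpins <- function(hairpins, params = default_thermo_params()) {
  if (!nrow(hairpins)) {
    hairpins$stem_dg <- numeric(0)
    return(hairpins)
  }
  full <- numeric(nrow(hairpins)); stem_only <- numeric(nrow(hairpins))
  for (i in seq_len(nrow(hairpins))) {
    dg <- hairpin_delta_g(hairpins[i, , drop = FALSE], params)
    full[i] <- as.numeric(dg)
    stem_only[i] <- attr(dg, "stem_dg")
  }
  hairpins$delta_g <- full
  hairpins$stem_dg <- stem_only
  hairpins
}
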