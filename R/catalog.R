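## Published catalog of small-inversion loci among 20 Lauraceae plastomes
## (17 Lindera plus Actinodaphne lancifolia, Litsea japonica and Sassafras
## tzumu).  The catalog is shipped as a plain TSV and serves as a worked
## input: every stem, loop subtype and per-taxon assignment can be re-run
## through the classifier and the free-energy model.

#' Load the Lauraceae small-inversion catalog
#'
#' Eleven stem-loop loci with their intergenic/genic location, published
#' hairpin free energy, loop subtypes (A = common orientation, B = reverse
#' complement orientation) and member taxa.  A trailing \code{*} on a taxon
#' marks a modified stem sequence in that species.
#'
#' @param long if \code{TRUE} return one row per (locus, taxon) assignment
#'   with columns \code{locus, region, region_class, stem_seq, dg_published,
#'   subtype, orientation, loop_seq, taxon, stem_modified}.
#' @return data frame (one row per subtype, or per assignment when
#'   \code{long}).
#' @export
lauraceae_si_catalog <- function(long = FALSE) {
  path <- system.file("extdata", "lauraceae_si_catalog.tsv",
                      package = "plastoflip", mustWork = TRUE)
  cat <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(locus = "integer"))
  cat$orientation <- substr(cat$subtype, 1, 1)
  if (!long) return(cat)
  rows <- lapply(seq_len(nrow(cat)), function(i) {
    taxa <- strsplit(cat$taxa[i], ";", fixed = TRUE)[[1]]
    data.frame(locus = cat$locus[i], region = cat$region[i],
               region_class = cat$region_class[i], stem_seq = cat$stem_seq[i],
               dg_published = cat$dg_published[i], subtype = cat$subtype[i],
               orientation = cat$orientation[i], loop_seq = cat$loop_seq[i],
               taxon = sub("\\*$", "", taxa),
               stem_modified = grepl("\\*$", taxa), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Re-classify every catalog assignment and summarise the loci
#'
#' For each locus the reference A-form loop is the most widespread A
#' subtype; every observed loop is re-run through
#' \code{\link{classify_orientation}} and compared with the published
#' orientation.  Per-locus statistics (region class, loop length range,
#' autapomorphy) are derived from the assignments alone.
#'
#' @param catalog output of \code{lauraceae_si_catalog(long = TRUE)}.
#' @param params thermodynamic parameters for \eqn{\Delta G} rescoring.
#' @return list with \code{assignments} (per-taxon calls incl.
#'   \code{call_matches}), \code{loci} (per-locus summary: region class,
#'   minority count, autapomorphic flag, loop length range, recomputed
#'   \code{dg_a}/\code{dg_b} for the two orientations, published dG) and
#'   \code{closure} (per B subtype: edit distance to the nearest
#'   reverse-complemented A loop and whether the classifier's relative rule
#'   holds).
#' @export
si_catalog_analysis <- function(catalog = lauraceae_si_catalog(long = TRUE),
                                params = default_thermo_params()) {
  loci <- sort(unique(catalog$locus))
  assign_rows <- list(); locus_rows <- list(); closure_rows <- list()
  for (lc in loci) {
    sub <- catalog[catalog$locus == lc, , drop = FALSE]
    a_sub <- sub[sub$orientation == "A", , drop = FALSE]
    ## reference = the most widespread A subtype
    tab <- vapply(split(a_sub, a_sub$subtype), nrow, integer(1))
    ref_subtype <- names(tab)[which.max(tab)]
    ref_loop <- a_sub$loop_seq[a_sub$subtype == ref_subtype][1]

    calls <- lapply(seq_len(nrow(sub)), function(i)
      classify_orientation(ref_loop, sub$loop_seq[i]))
    called <- vapply(calls, `[[`, character(1), "orientation")
    sub$called_orientation <- called
    sub$call_matches <- called == sub$orientation
    assign_rows[[length(assign_rows) + 1L]] <- sub

    orient_by_taxon <- sub$orientation
    n_b <- sum(orient_by_taxon == "B")
    n_a <- sum(orient_by_taxon == "A")
    minority <- min(n_a, n_b)
    loop_lens <- nchar(sub$loop_seq)
    dg_a <- as.numeric(hairpin_delta_g(
      list(stem_seq = sub$stem_seq[1], loop_len = nchar(ref_loop)), params))
    dg_b <- as.numeric(hairpin_delta_g(
      list(stem_seq = sub$stem_seq[1], loop_len = nchar(revcomp(ref_loop))),
      params))
    locus_rows[[length(locus_rows) + 1L]] <- data.frame(
      locus = lc, region = sub$region[1], region_class = sub$region_class[1],
      n_taxa = nrow(sub), n_a = n_a, n_b = n_b, minority_count = minority,
      autapomorphic = minority == 1L, loop_len_min = min(loop_lens),
      loop_len_max = max(loop_lens), dg_a = dg_a, dg_b = dg_b,
      dg_published = sub$dg_published[1], stringsAsFactors = FALSE)

    a_loops <- unique(a_sub$loop_seq)
    for (bs in unique(sub$subtype[sub$orientation == "B"])) {
      b_loop <- sub$loop_seq[sub$subtype == bs][1]
      d_rc <- min(vapply(a_loops, function(al)
        edit_dist(b_loop, revcomp(al)), integer(1)))
      d_fwd <- min(vapply(a_loops, function(al)
        edit_dist(b_loop, al), integer(1)))
      closure_rows[[length(closure_rows) + 1L]] <- data.frame(
        locus = lc, subtype = bs, loop_seq = b_loop,
        dist_to_revcomp_a = d_rc, dist_to_a = d_fwd,
        relative_rule_holds = d_rc < d_fwd, stringsAsFactors = FALSE)
    }
  }
  list(assignments = do.call(rbind, assign_rows),
       loci = do.call(rbind, locus_rows),
       closure = do.call(rbind, closure_rows))
}

#' Binary character matrix from the catalog assignments
#'
#' @param catalog output of \code{lauraceae_si_catalog(long = TRUE)}.
#' @return character matrix (20 taxa x 11 loci) with states \code{"A"},
#'   \code{"B"} or \code{"?"} (taxa missing from a locus).
#' @export
si_catalog_matrix <- function(catalog = lauraceae_si_catalog(long = TRUE)) {
  taxa <- sort(unique(catalog$taxon))
  loci <- sort(unique(catalog$locus))
  m <- matrix("?", length(taxa), length(loci),
              dimnames = list(taxa, paste0("si", loci)))
  for (i in seq_len(nrow(catalog)))
    m[catalog$taxon[i], paste0("si", catalog$locus[i])] <-
      catalog$orientation[i]
  m
}
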