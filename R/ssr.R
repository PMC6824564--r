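## ssr_scanner: perfect microsatellite detection with per-class copy-number
## thresholds, plus regional summaries and cross-taxon locus comparison.

#' Default SSR copy-number thresholds
#'
#' Minimum copies per motif class: 10 for mono-, 5 for di-, 4 for tri-, 3
#' for tetra- and 2 for pentanucleotide repeats ("at least" reading: a
#' 10 bp mononucleotide run qualifies).
#' @return integer vector of length 5, indexed by unit length.
#' @export
ssr_thresholds <- function() c(10L, 5L, 4L, 3L, 2L)

#' Scan a genome for perfect simple sequence repeats
#'
#' Reports every maximal perfect tandem repeat of a primitive 1-5 bp motif
#' meeting its class threshold.  A locus is reported once, under its
#' primitive motif; runs containing \code{N} are broken.  The canonical
#' motif is the lexicographically smallest rotation of the repeat unit
#' (strand-specific: A-runs and T-runs stay distinct).
#'
#' @param record \code{\link{plastome_record}} or DNA string.
#' @param min_copies integer vector of per-class thresholds (index = unit
#'   length); default \code{\link{ssr_thresholds}}.
#' @return data frame sorted by start: \code{start, end, unit_len, copies,
#'   length_bp, unit, motif} (canonical), and \code{region}/\code{compartment}
#'   columns filled with \code{NA} until \code{\link{ssr_summary}} or
#'   \code{\link{classify_region}} is applied.
#' @export
scan_ssrs <- function(record, min_copies = ssr_thresholds()) {
  s <- if (inherits(record, "plastome_record")) record$sequence
       else { check_dna(toupper(record)); toupper(record) }
  out <- as.data.frame(.cpp_scan_ssrs(s, as.integer(min_copies)),
                       stringsAsFactors = FALSE)
  out$length_bp <- out$unit_len * out$copies
  out$motif <- canonical_rotation(out$unit)
  out <- out[order(out$start, out$unit_len), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("start", "end", "unit_len", "copies", "length_bp", "unit", "motif")]
}

#' Summarise SSR loci by motif class, functional region and compartment
#'
#' @param loci \code{\link{scan_ssrs}} output for one record.
#' @param record the annotated \code{\link{plastome_record}} the loci came
#'   from (optional; without it functional classes are \code{NA}).
#' @param partition optional \code{\link{quadripartite_partition}} (defaults
#'   to the record's).
#' @return list with \code{loci} (annotated with \code{functional},
#'   \code{compartment} and \code{ir_duplicate}), \code{by_class},
#'   \code{by_functional} and \code{by_compartment} count/percentage tables.
#' @export
ssr_summary <- function(loci, record = NULL, partition = NULL) {
  if (is.null(partition) && !is.null(record)) partition <- record$partition
  n <- nrow(loci)
  mid <- if (n) (loci$start + loci$end) %/% 2L else integer(0)
  functional <- rep(NA_character_, n)
  if (!is.null(record) && !is.null(record$features) && n)
    functional <- classify_region(record, mid)$functional
  compartment <- rep("unassigned", n)
  if (!is.null(partition) && n)
    compartment <- partition_compartment(partition, mid)
  loci$functional <- functional
  loci$compartment <- compartment
  loci$ir_duplicate <- compartment %in% c("IRa", "IRb")

  class_names <- c("mono", "di", "tri", "tetra", "penta")
  tab_of <- function(x, levels) {
    cnt <- table(factor(x, levels = levels))
    data.frame(level = levels, count = as.integer(cnt),
               pct = if (n) round(100 * as.integer(cnt) / n, 1) else 0,
               stringsAsFactors = FALSE)
  }
  by_class <- tab_of(class_names[loci$unit_len], class_names)
  names(by_class)[1] <- "class"
  by_functional <- tab_of(loci$functional, c("CDS", "intron", "IGS"))
  names(by_functional)[1] <- "functional"
  comp3 <- ifelse(loci$compartment %in% c("IRa", "IRb"), "IR", loci$compartment)
  by_compartment <- tab_of(comp3, c("LSC", "IR", "SSC"))
  names(by_compartment)[1] <- "compartment"
  list(loci = loci, by_class = by_class, by_functional = by_functional,
       by_compartment = by_compartment, n_loci = n)
}

#' Compare SSR loci across taxa and classify their phylogenetic status
#'
#' Loci of unit length >= 2 are matched across taxa when their alignment
#' column ranges overlap and the canonical motif agrees; the character state
#' is the copy number (0 = locus absent).  Status: \code{conserved} when all
#' taxa agree, \code{autapomorphic} when exactly one taxon deviates,
#' \code{synapomorphic} otherwise.
#'
#' @param per_taxon_loci named list (taxon -> \code{\link{scan_ssrs}} output).
#' @param alignment \code{\link{make_alignment}} over the same taxa.
#' @param min_unit_len smallest unit length compared (default 2: mono-runs
#'   are too labile to be characters).
#' @return list with \code{matrix} (taxa x loci copy numbers) and
#'   \code{status} data frame (locus, motif, status).
#' @export
ssr_locus_matrix <- function(per_taxon_loci, alignment, min_unit_len = 2L) {
  taxa <- alignment$labels
  if (!all(names(per_taxon_loci) %in% taxa))
    stop("per_taxon_loci names must match alignment labels")
  ## collect loci with alignment column ranges
  rows <- list()
  for (tx in names(per_taxon_loci)) {
    l <- per_taxon_loci[[tx]]
    l <- l[l$unit_len >= min_unit_len, , drop = FALSE]
    if (!nrow(l)) next
    map <- alignment_coord_map(alignment, tx)
    l$col_lo <- map$pos_to_col[l$start]
    l$col_hi <- map$pos_to_col[l$end]
    l$taxon <- tx
    rows[[length(rows) + 1L]] <- l
  }
  if (!length(rows))
    return(list(matrix = matrix(0L, length(taxa), 0,
                                dimnames = list(taxa, NULL)),
                status = data.frame(locus = character(0), motif = character(0),
                                    status = character(0))))
  all_l <- do.call(rbind, rows)
  ## single-linkage grouping by column-range overlap + same canonical motif
  m <- nrow(all_l)
  parent <- seq_len(m)
  findp <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  ord <- order(all_l$col_lo)
  for (ai in seq_len(max(m - 1L, 0L))) {
    i <- ord[ai]
    for (bi in (ai + 1L):m) {
      j <- ord[bi]
      if (all_l$col_lo[j] > all_l$col_hi[i]) break
      if (all_l$motif[i] == all_l$motif[j]) {
        ri <- findp(i); rj <- findp(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  groups <- split(seq_len(m), vapply(seq_len(m), findp, integer(1)))
  groups <- groups[order(vapply(groups, function(g) min(all_l$col_lo[g]),
                                numeric(1)))]
  mat <- matrix(0L, nrow = length(taxa), ncol = length(groups),
                dimnames = list(taxa, paste0("ssr", seq_along(groups))))
  motifs <- character(length(groups))
  for (k in seq_along(groups)) {
    g <- all_l[groups[[k]], , drop = FALSE]
    g <- g[order(-g$copies), , drop = FALSE]
    g <- g[!duplicated(g$taxon), , drop = FALSE]
    mat[g$taxon, k] <- g$copies
    motifs[k] <- g$motif[1]
  }
  status <- vapply(seq_along(groups), function(k) {
    v <- mat[, k]
    tb <- table(v)
    if (length(tb) == 1L) "conserved"
    else if (sum(v != as.integer(names(tb)[which.max(tb)])) == 1L) "autapomorphic"
    else "synapomorphic"
  }, character(1))
  list(matrix = mat,
       status = data.frame(locus = colnames(mat), motif = motifs,
                           status = status, stringsAsFactors = FALSE))
}
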