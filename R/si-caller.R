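## si_caller: cross-species small-inversion detection.  A small inversion
## (SI) is a hairpin locus whose loop orientation differs between species:
## the common orientation is the A form, the reverse-complemented one the B
## form.

#' Classify the orientation of an observed hairpin loop
#'
#' The observed loop is compared with a reference (A-form) loop by
#' Levenshtein distance: closer to the reference than to its reverse
#' complement is \code{A}, the converse is \code{B}, ties are
#' \code{ambiguous} (in particular any loop that is its own reverse
#' complement).  Relative distance, not a fixed cutoff, is used so that
#' loop-length variants classify naturally.
#'
#' @param ref_loop reference A-form loop sequence.
#' @param observed_loop observed loop sequence.
#' @param max_subtype_mismatch edit radius used when grouping loop variants
#'   into subtypes downstream (recorded on the call; the A/B decision itself
#'   is relative).
#' @return list with \code{orientation} (\code{"A"}, \code{"B"} or
#'   \code{"ambiguous"}), \code{loop_seq_observed}, \code{dist_a},
#'   \code{dist_b}.
#' @export
classify_orientation <- function(ref_loop, observed_loop,
                                 max_subtype_mismatch = 3L) {
  stopifnot(nchar(ref_loop) >= 1L, nchar(observed_loop) >= 1L)
  ref_loop <- toupper(ref_loop); observed_loop <- toupper(observed_loop)
  da <- edit_dist(observed_loop, ref_loop)
  db <- edit_dist(observed_loop, revcomp(ref_loop))
  orientation <- if (da < db) "A" else if (db < da) "B" else "ambiguous"
  list(orientation = orientation, loop_seq_observed = observed_loop,
       dist_a = da, dist_b = db,
       max_subtype_mismatch = as.integer(max_subtype_mismatch))
}

## subtype labels within one orientation: identical observed loops grouped,
## numbered by decreasing taxon count then first occurrence; a single group
## gets the bare orientation letter.
assign_subtypes <- function(orientation, loops) {
  grp <- split(seq_along(loops), loops)
  cnt <- vapply(grp, length, integer(1))
  first <- vapply(grp, min, integer(1))
  ord <- order(-cnt, first)
  labels <- character(length(loops))
  for (r in seq_along(ord)) {
    lab <- if (length(grp) == 1L) orientation else paste0(orientation, r)
    labels[grp[[ord[r]]]] <- lab
  }
  labels
}

#' Call small-inversion loci across a set of aligned plastomes
#'
#' Hairpins are detected per taxon on ungapped sequences, mapped to
#' alignment columns, and grouped into homologous loci when their stem-arm
#' column sets overlap (Jaccard >= 0.5).  At each locus the orientation
#' carried by the majority of taxa is named A (ties: the first taxon in
#' input order); loci monomorphic in orientation are discarded.
#'
#' @param alignment \code{\link{make_alignment}} object; rows correspond
#'   one-to-one to \code{records}.
#' @param records optional list of annotated \code{\link{plastome_record}}
#'   (same order/labels as the alignment); used for region labels.  When
#'   \code{NULL}, records are derived from the degapped alignment rows.
#' @param hairpin_params named list forwarded to \code{\link{find_hairpins}}.
#' @param min_taxa_with_stem discard loci whose stem is detected in fewer
#'   taxa than this (default 15, tuned to a 20-taxon dataset; lower it for
#'   smaller ones).
#' @param params thermodynamic parameters for \eqn{\Delta G} scoring.
#' @return list of \code{si_profile} objects: each has \code{si_id},
#'   \code{region}, \code{ref_stem_seq}, \code{ref_loop_seq},
#'   \code{delta_g}, \code{aln_cols} and an \code{assignments} data frame
#'   (taxon, orientation, subtype, loop_seq_observed, stem_modified).
#' @export
call_si_loci <- function(alignment, records = NULL, hairpin_params = list(),
                         min_taxa_with_stem = 15L,
                         params = default_thermo_params()) {
  labs <- alignment$labels
  if (is.null(records)) {
    records <- lapply(labs, function(l) plastome_record(l, ungap(alignment$seqs[[l]])))
  } else {
    rl <- vapply(records, `[[`, character(1), "taxon_label")
    if (length(records) != length(labs) || !setequal(rl, labs))
      stop("alignment rows and records do not match one-to-one")
    records <- records[match(labs, rl)]
    for (i in seq_along(labs))
      if (!identical(records[[i]]$sequence, ungap(alignment$seqs[[labs[i]]])))
        stop("sequence of record ", labs[i],
             " differs from its degapped alignment row")
  }

  ## per-taxon hairpins with stem-arm alignment-column sets
  per <- list()
  for (i in seq_along(labs)) {
    map <- alignment_coord_map(alignment, labs[i])
    h <- do.call(find_hairpins, c(list(records[[i]]$sequence), hairpin_params))
    if (!nrow(h)) next
    h$taxon <- labs[i]
    h$cols <- lapply(seq_len(nrow(h)), function(r) {
      arm_pos <- c(seq(h$genome_start[r], h$loop_start[r] - 1L),
                   seq(h$loop_end[r] + 1L, h$genome_end[r]))
      sort(map$pos_to_col[arm_pos])
    })
    per[[length(per) + 1L]] <- h
  }
  if (!length(per)) return(list())
  allh <- do.call(rbind, per)

  ## single-linkage grouping by Jaccard >= 0.5 on stem-arm column sets
  m <- nrow(allh)
  parent <- seq_len(m)
  findp <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  lo <- vapply(allh$cols, min, integer(1)); hi <- vapply(allh$cols, max, integer(1))
  ord <- order(lo)
  for (ai in seq_len(m - 1L)) {
    i <- ord[ai]
    for (bi in (ai + 1L):m) {
      j <- ord[bi]
      if (lo[j] > hi[i]) break
      inter <- length(intersect(allh$cols[[i]], allh$cols[[j]]))
      uni <- length(union(allh$cols[[i]], allh$cols[[j]]))
      if (inter / uni >= 0.5) {
        ri <- findp(i); rj <- findp(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  groups <- split(seq_len(m), vapply(seq_len(m), findp, integer(1)))

  annotated <- which(vapply(records, function(r)
    !is.null(r$features) && nrow(r$features) > 0, logical(1)))
  profiles <- list()
  for (g in groups) {
    gh <- allh[g, , drop = FALSE]
    ## one hairpin per taxon: longest stem, then leftmost
    gh <- gh[order(-gh$stem_len, gh$genome_start), , drop = FALSE]
    gh <- gh[!duplicated(gh$taxon), , drop = FALSE]
    if (nrow(gh) < min_taxa_with_stem) next
    gh <- gh[match(intersect(labs, gh$taxon), gh$taxon), , drop = FALSE]

    ref <- gh$loop_seq[1]
    calls <- lapply(gh$loop_seq, classify_orientation, ref_loop = ref)
    orient <- vapply(calls, `[[`, character(1), "orientation")
    nA <- sum(orient == "A"); nB <- sum(orient == "B")
    if (nB > nA || (nB == nA && nB > 0 && orient[1] == "B")) {
      orient[orient == "A"] <- "tmp"; orient[orient == "B"] <- "A"
      orient[orient == "tmp"] <- "B"
    }
    informative <- orient %in% c("A", "B")
    if (length(unique(orient[informative])) < 2L) next   # monomorphic

    subtype <- rep(NA_character_, nrow(gh))
    for (o in c("A", "B")) {
      sel <- orient == o
      if (any(sel)) subtype[sel] <- assign_subtypes(o, gh$loop_seq[sel])
    }
    ref_a <- gh$loop_seq[orient == "A"]
    ref_loop <- names(sort(table(ref_a), decreasing = TRUE))[1]
    stems_a <- gh$stem_seq[orient == "A"]
    ref_stem <- names(sort(table(stems_a), decreasing = TRUE))[1]
    stem_modified <- !(gh$stem_seq == ref_stem | gh$stem_seq == revcomp(ref_stem)) |
      gh$mismatches_in_stem > 0L

    region <- NA_character_
    if (length(annotated)) {
      ridx <- annotated[1]
      rh <- gh[gh$taxon == labs[ridx], , drop = FALSE]
      if (nrow(rh)) {
        mid <- (rh$loop_start[1] + rh$loop_end[1]) %/% 2L
        cl <- classify_region(records[[ridx]], mid)
        region <- if (cl$functional == "IGS") paste0("IGS:", cl$flanking)
                  else cl$functional
        if (cl$functional == "intron") {
          f <- records[[ridx]]$features
          hit <- f[f$kind == "intron" & f$start <= mid & f$end >= mid, , drop = FALSE]
          ## name the host gene when known
          if (nrow(hit)) region <- paste0("intron:", hit$name[1])
        }
        if (cl$functional == "CDS") {
          f <- records[[ridx]]$features
          hit <- f[f$kind %in% c("CDS", "tRNA", "rRNA", "pseudogene") &
                     f$start <= mid & f$end >= mid, , drop = FALSE]
          if (nrow(hit)) region <- paste0("CDS:", hit$name[1])
        }
      }
    }
    dg <- as.numeric(hairpin_delta_g(list(stem_seq = ref_stem,
                                          loop_len = nchar(ref_loop)), params))
    profiles[[length(profiles) + 1L]] <- structure(
      list(si_id = NA_integer_, region = region, ref_stem_seq = ref_stem,
           ref_loop_seq = ref_loop, delta_g = dg,
           aln_cols = range(unlist(gh$cols)),
           assignments = data.frame(taxon = gh$taxon, orientation = orient,
                                    subtype = subtype,
                                    loop_seq_observed = gh$loop_seq,
                                    stem_modified = stem_modified,
                                    stringsAsFactors = FALSE)),
      class = "si_profile")
  }
  if (!length(profiles)) return(list())
  pos <- vapply(profiles, function(p) p$aln_cols[1], numeric(1))
  profiles <- profiles[order(pos)]
  for (i in seq_along(profiles)) profiles[[i]]$si_id <- i
  profiles
}

#' @export
print.si_profile <- function(x, ...) {
  tab <- table(x$assignments$orientation)
  cat(sprintf("<si_profile> #%s %s stem %s loop %s dG %.2f kcal/mol [%s]\n",
              x$si_id, ifelse(is.na(x$region), "", x$region), x$ref_stem_seq,
              x$ref_loop_seq, x$delta_g,
              paste(names(tab), tab, sep = ":", collapse = " ")))
  invisible(x)
}

#' Tabular report of SI loci
#'
#' One row per (locus, subtype) with member taxa; taxa with modified stems
#' are flagged with \code{*}.
#'
#' @param profiles list of \code{si_profile}.
#' @return data frame with columns \code{si_id, region, stem_seq, stem_len,
#'   delta_g, subtype, loop_seq, loop_len, n_taxa, taxa}.
#' @export
si_report <- function(profiles) {
  cols <- c("si_id", "region", "stem_seq", "stem_len", "delta_g", "subtype",
            "loop_seq", "loop_len", "n_taxa", "taxa")
  if (!length(profiles)) {
    out <- data.frame(matrix(nrow = 0, ncol = length(cols)))
    names(out) <- cols
    return(out)
  }
  rows <- list()
  for (p in profiles) {
    a <- p$assignments
    for (st in unique(a$subtype[!is.na(a$subtype)])) {
      sel <- which(a$subtype %in% st)
      taxa <- paste0(a$taxon[sel], ifelse(a$stem_modified[sel], "*", ""))
      rows[[length(rows) + 1L]] <- data.frame(
        si_id = p$si_id, region = p$region, stem_seq = p$ref_stem_seq,
        stem_len = nchar(p$ref_stem_seq), delta_g = p$delta_g, subtype = st,
        loop_seq = a$loop_seq_observed[sel[1]],
        loop_len = nchar(a$loop_seq_observed[sel[1]]),
        n_taxa = length(sel), taxa = paste(taxa, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$si_id, out$subtype), cols]
}

#' Binary character matrix of SI orientations
#'
#' @param profiles list of \code{si_profile}.
#' @param taxa taxon labels for the rows (defaults to the union seen).
#' @return character matrix taxa x loci with entries \code{"A"},
#'   \code{"B"} or \code{"?"} (missing or ambiguous).
#' @export
si_matrix <- function(profiles, taxa = NULL) {
  if (is.null(taxa))
    taxa <- unique(unlist(lapply(profiles, function(p) p$assignments$taxon)))
  m <- matrix("?", nrow = length(taxa), ncol = length(profiles),
              dimnames = list(taxa, vapply(profiles, function(p)
                paste0("si", p$si_id), character(1))))
  for (j in seq_along(profiles)) {
    a <- profiles[[j]]$assignments
    ok <- a$orientation %in% c("A", "B") & a$taxon %in% taxa
    m[a$taxon[ok], j] <- a$orientation[ok]
  }
  m
}
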