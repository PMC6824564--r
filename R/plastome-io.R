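## plastome_io: genome/alignment readers and functional region classification.

#' Construct a plastome record
#'
#' A \code{plastome_record} holds one (usually circular) genome sequence, its
#' annotation features and, optionally, a quadripartite partition.
#'
#' @param taxon_label non-empty character scalar.
#' @param sequence DNA string over \code{A,C,G,T,N} (uppercased on input).
#' @param features \code{NULL} or a data frame with columns
#'   \code{feature_id, kind, name, start, end, strand, pseudo}; one row per
#'   interval (exon), 1-based closed coordinates.
#' @param is_circular logical flag.
#' @param partition optional \code{\link{quadripartite_partition}}.
#' @return object of class \code{plastome_record}.
#' @export
plastome_record <- function(taxon_label, sequence, features = NULL,
                            is_circular = TRUE, partition = NULL) {
  stopifnot(is.character(taxon_label), length(taxon_label) == 1L,
            nzchar(taxon_label), is.character(sequence), length(sequence) == 1L)
  sequence <- unname(toupper(sequence))
  if (!nzchar(sequence)) stop("empty sequence for taxon ", taxon_label)
  check_dna(sequence, what = paste0("sequence of ", taxon_label))
  n <- nchar(sequence)
  if (!is.null(features)) {
    features <- validate_features(features, n)
  }
  structure(list(taxon_label = taxon_label, sequence = sequence,
                 length_bp = n, is_circular = is_circular,
                 features = features, partition = partition),
            class = "plastome_record")
}

validate_features <- function(features, length_bp) {
  need <- c("feature_id", "kind", "name", "start", "end", "strand")
  miss <- setdiff(need, names(features))
  if (length(miss))
    stop("feature table lacks columns: ", paste(miss, collapse = ", "))
  if (!"pseudo" %in% names(features)) features$pseudo <- FALSE
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  bad <- features$start < 1L | features$start > features$end
  if (any(bad))
    stop("malformed interval for feature ", features$name[which(bad)[1]])
  over <- features$end > length_bp
  if (any(over))
    stop(sprintf("feature %s (%s) extends beyond sequence end (%d > %d)",
                 features$name[which(over)[1]], features$kind[which(over)[1]],
                 max(features$end), length_bp))
  rownames(features) <- NULL
  features
}

#' @export
print.plastome_record <- function(x, ...) {
  cat(sprintf("<plastome_record> %s: %s bp%s, %d feature interval(s)%s\n",
              x$taxon_label, format(x$length_bp, big.mark = ","),
              if (x$is_circular) " (circular)" else "",
              if (is.null(x$features)) 0L else nrow(x$features),
              if (is.null(x$partition)) "" else ", partitioned"))
  invisible(x)
}

#' Read unaligned FASTA into plastome records
#'
#' Labels are taken from headers up to the first whitespace.  Gap characters
#' are rejected here; use \code{\link{read_alignment}} for aligned FASTA.
#'
#' @param path FASTA file, one record per taxon.
#' @return list of \code{\link{plastome_record}}, in file order.
#' @export
read_fasta_many <- function(path) {
  set <- Biostrings::readBStringSet(path)
  labs <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(labs))
    stop("duplicate taxon labels in ", path, ": ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "))
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) stop("empty sequence for ", labs[!nzchar(seqs)][1])
  if (any(grepl("-", seqs, fixed = TRUE)))
    stop("gap characters found in ", path,
         "; this reader takes unaligned FASTA (see read_alignment)")
  lapply(seq_along(seqs), function(i) plastome_record(labs[i], seqs[i]))
}

#' Write records (or named sequences) to FASTA
#'
#' @param x list of \code{plastome_record}, or a named character vector.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (is.list(x) && length(x) && inherits(x[[1]], "plastome_record")) {
    seqs <- setNames(vapply(x, `[[`, character(1), "sequence"),
                     vapply(x, `[[`, character(1), "taxon_label"))
  } else seqs <- x
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read an aligned FASTA (multiple sequence alignment)
#'
#' @param path aligned FASTA over \code{A,C,G,T,N,-}; all rows equal length.
#' @return object of class \code{plastome_alignment}: a list with
#'   \code{labels}, \code{seqs} (aligned rows) and \code{n_col}.
#' @export
read_alignment <- function(path) {
  set <- Biostrings::readBStringSet(path)
  labs <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  make_alignment(labs, seqs)
}

#' Build an alignment object from aligned rows
#' @param labels taxon labels.
#' @param seqs aligned sequences (equal length, gaps as \code{-}).
#' @return \code{plastome_alignment}.
#' @export
make_alignment <- function(labels, seqs) {
  if (anyDuplicated(labels))
    stop("duplicate taxon labels in alignment")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("ragged alignment: row lengths ", paste(unique(lens), collapse = ", "))
  for (i in seq_along(seqs)) check_dna(seqs[i], allow_gap = TRUE,
                                       what = paste0("alignment row ", labels[i]))
  structure(list(labels = unname(labels),
                 seqs = setNames(unname(seqs), labels),
                 n_col = unname(lens[1])), class = "plastome_alignment")
}

#' @export
print.plastome_alignment <- function(x, ...) {
  cat(sprintf("<plastome_alignment> %d rows x %d columns\n",
              length(x$labels), x$n_col))
  invisible(x)
}

#' Write an alignment to aligned FASTA
#' @param alignment \code{plastome_alignment}.
#' @param path output file.
#' @export
write_alignment <- function(alignment, path) {
  write_fasta(alignment$seqs, path)
}

#' Map alignment columns to ungapped genome coordinates
#'
#' @param alignment \code{plastome_alignment}.
#' @param label row to map.
#' @return list with \code{col_to_pos} (length \code{n_col}; \code{NA} at gap
#'   columns) and \code{pos_to_col} (length = ungapped length).
#' @export
alignment_coord_map <- function(alignment, label) {
  row <- alignment$seqs[[label]]
  if (is.null(row)) stop("no alignment row labelled ", label)
  ch <- strsplit(row, "", fixed = TRUE)[[1]]
  isbase <- ch != "-"
  col_to_pos <- rep(NA_integer_, length(ch))
  col_to_pos[isbase] <- seq_len(sum(isbase))
  list(col_to_pos = col_to_pos, pos_to_col = which(isbase))
}

## degap one alignment row
ungap <- function(x) gsub("-", "", x, fixed = TRUE)

#' Classify genome positions as CDS, intron or intergenic spacer
#'
#' Gene bodies (CDS, tRNA, rRNA and pseudogenes) count as genic; positions
#' inside a gene but between its exons are introns; everything else is IGS,
#' labelled with the flanking gene pair ordered by genome coordinate
#' (wrapping around the origin on circular genomes).
#'
#' @param record annotated \code{\link{plastome_record}}.
#' @param position integer vector of 1-based positions.
#' @return data frame with columns \code{position, functional, compartment,
#'   flanking} (flanking is \code{NA} unless functional is \code{"IGS"}).
#' @export
classify_region <- function(record, position) {
  position <- as.integer(position)
  n <- record$length_bp
  if (any(position < 1L | position > n))
    stop("position out of range [1, ", n, "]")
  f <- record$features
  if (is.null(f) || !nrow(f)) stop("record has no annotation features")

  genic_kinds <- c("CDS", "tRNA", "rRNA", "pseudogene", "gene")
  exon <- f[f$kind %in% setdiff(genic_kinds, "gene"), , drop = FALSE]
  ## gene spans: prefer explicit `gene` rows, fall back to exon-group spans
  gene_rows <- f[f$kind == "gene", , drop = FALSE]
  if (nrow(gene_rows)) {
    spans <- data.frame(name = gene_rows$name, start = gene_rows$start,
                        end = gene_rows$end, stringsAsFactors = FALSE)
  } else spans <- NULL
  if (nrow(exon)) {
    sp2 <- do.call(rbind, lapply(split(exon, exon$feature_id), function(g)
      data.frame(name = g$name[1], start = min(g$start), end = max(g$end),
                 stringsAsFactors = FALSE)))
    spans <- rbind(spans, sp2)
  }
  spans <- spans[order(spans$start, spans$end), , drop = FALSE]
  ## collapse duplicate names covering the same span (gene + CDS rows)
  spans <- spans[!duplicated(spans[c("name", "start", "end")]), , drop = FALSE]

  in_any <- function(p, tab) {
    if (is.null(tab) || !nrow(tab)) return(FALSE)
    any(p >= tab$start & p <= tab$end)
  }
  functional <- character(length(position))
  flanking <- rep(NA_character_, length(position))
  for (i in seq_along(position)) {
    p <- position[i]
    if (in_any(p, exon)) {
      functional[i] <- "CDS"
    } else if (in_any(p, spans)) {
      functional[i] <- "intron"
    } else {
      functional[i] <- "IGS"
      if (nrow(spans)) {
        before <- spans[spans$end < p, , drop = FALSE]
        after <- spans[spans$start > p, , drop = FALSE]
        left <- if (nrow(before)) before$name[which.max(before$end)]
                else spans$name[which.max(spans$end)]       # wrap
        right <- if (nrow(after)) after$name[which.min(after$start)]
                 else spans$name[which.min(spans$start)]    # wrap
        flanking[i] <- paste0(left, "-", right)
      }
    }
  }
  compartment <- rep("unassigned", length(position))
  if (!is.null(record$partition))
    compartment <- partition_compartment(record$partition, position)
  data.frame(position = position, functional = functional,
             compartment = compartment, flanking = flanking,
             stringsAsFactors = FALSE)
}
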