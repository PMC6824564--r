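## Minimal GenBank flat-file reader/writer for annotated plastomes.  Parses
## LOCUS, the FEATURES table (gene/CDS/tRNA/rRNA keys, join/complement
## locations, /gene and /pseudo qualifiers) and the ORIGIN block.  No
## installed R package parses GenBank feature tables, so this is written by
## hand; the format subset covered is the one the package itself writes plus
## standard single/joined locations.

parse_location <- function(loc) {
  strand <- if (grepl("complement", loc, fixed = TRUE)) "-" else "+"
  inner <- gsub("complement\\(|join\\(|order\\(|\\)", "", loc)
  inner <- gsub("[<>]", "", inner)
  parts <- strsplit(inner, ",", fixed = TRUE)[[1]]
  ivs <- lapply(parts, function(p) {
    se <- as.integer(strsplit(p, "\\.\\.")[[1]])
    if (length(se) == 1L) se <- c(se, se)
    if (anyNA(se)) stop("unparseable location: ", loc)
    se
  })
  list(strand = strand,
       start = vapply(ivs, `[`, integer(1), 1L),
       end = vapply(ivs, `[`, integer(1), 2L))
}

#' Read a GenBank flat file into a plastome record
#'
#' Captures gene, CDS, tRNA and rRNA features (introns are derived as the
#' gaps between exon intervals of multi-interval features); \code{/pseudo}
#' features are kept with kind \code{pseudogene}.
#'
#' @param path GenBank flat file with an ORIGIN sequence block.
#' @return \code{\link{plastome_record}}.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  label <- if (length(locus)) strsplit(trimws(locus[1]), "\\s+")[[1]][2]
           else tools::file_path_sans_ext(basename(path))
  circular <- length(locus) && grepl("circular", locus[1], ignore.case = TRUE)

  ori <- grep("^ORIGIN", lines)
  if (!length(ori)) stop("missing sequence block (no ORIGIN) in ", path)
  endl <- grep("^//", lines)
  endl <- if (length(endl)) endl[endl > ori[1]][1] else length(lines) + 1L
  seq_lines <- lines[(ori[1] + 1L):(endl - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(sequence)) stop("missing sequence block (empty ORIGIN) in ", path)

  fstart <- grep("^FEATURES", lines)
  feats <- NULL
  if (length(fstart)) {
    block <- lines[(fstart[1] + 1L):(ori[1] - 1L)]
    ## stitch continuation lines: a new entry starts with a key in cols 6-20
    keypat <- "^ {5}\\S"
    entries <- list(); cur <- NULL
    for (ln in block) {
      if (grepl(keypat, ln)) {
        if (!is.null(cur)) entries[[length(entries) + 1L]] <- cur
        cur <- ln
      } else if (!is.null(cur)) cur <- c(cur, ln)
    }
    if (!is.null(cur)) entries[[length(entries) + 1L]] <- cur
    keep <- c("gene", "CDS", "tRNA", "rRNA")
    rows <- list(); fid <- 0L
    for (e in entries) {
      head1 <- trimws(e[1])
      key <- sub("\\s.*$", "", head1)
      if (!key %in% keep) next
      loc <- sub("^\\S+\\s+", "", head1)
      rest <- if (length(e) > 1L) trimws(e[-1]) else character(0)
      ## location may continue onto lines before the first qualifier
      qual_at <- grep("^/", rest)
      if (length(qual_at) && qual_at[1] > 1L) {
        loc <- paste0(loc, paste(rest[seq_len(qual_at[1] - 1L)], collapse = ""))
        rest <- rest[qual_at[1]:length(rest)]
      } else if (!length(qual_at) && length(rest)) {
        loc <- paste0(loc, paste(rest, collapse = ""))
        rest <- character(0)
      }
      quals <- rest[grepl("^/", rest)]
      getq <- function(nm) {
        hit <- grep(paste0("^/", nm, "="), quals, value = TRUE)
        if (!length(hit)) return(NA_character_)
        gsub("\"", "", sub(paste0("^/", nm, "="), "", hit[1]))
      }
      name <- getq("gene")
      if (is.na(name)) name <- getq("standard_name")
      if (is.na(name)) name <- getq("product")
      if (is.na(name)) name <- paste0(key, "_", fid + 1L)
      pseudo <- any(grepl("^/pseudo\\b", quals))
      pl <- parse_location(loc)
      fid <- fid + 1L
      kind <- if (pseudo) "pseudogene" else key
      rows[[fid]] <- data.frame(feature_id = fid, kind = kind, name = name,
                                start = pl$start, end = pl$end,
                                strand = pl$strand, pseudo = pseudo,
                                stringsAsFactors = FALSE)
    }
    if (length(rows)) {
      feats <- do.call(rbind, rows)
      ## derive introns from gaps between exon intervals
      introns <- list()
      for (id in unique(feats$feature_id)) {
        g <- feats[feats$feature_id == id & feats$kind != "gene", , drop = FALSE]
        if (nrow(g) < 2L) next
        g <- g[order(g$start), ]
        for (j in seq_len(nrow(g) - 1L)) {
          if (g$end[j] + 1L <= g$start[j + 1L] - 1L)
            introns[[length(introns) + 1L]] <-
              data.frame(feature_id = max(feats$feature_id) + length(introns) + 1L,
                         kind = "intron", name = g$name[1],
                         start = g$end[j] + 1L, end = g$start[j + 1L] - 1L,
                         strand = g$strand[1], pseudo = FALSE,
                         stringsAsFactors = FALSE)
        }
      }
      if (length(introns)) feats <- rbind(feats, do.call(rbind, introns))
    }
  }
  plastome_record(label, sequence, features = feats, is_circular = circular)
}

#' Write a plastome record to a GenBank flat file
#'
#' @param record \code{\link{plastome_record}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_genbank <- function(record, path) {
  n <- record$length_bp
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %s %d bp    DNA     %s PLN %s",
                     record$taxon_label, n,
                     if (record$is_circular) "circular" else "linear",
                     format(Sys.Date(), "%d-%b-%Y")), con)
  writeLines(sprintf("DEFINITION  %s plastome.", record$taxon_label), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  f <- record$features
  if (!is.null(f) && nrow(f)) {
    for (id in unique(f$feature_id)) {
      g <- f[f$feature_id == id, , drop = FALSE]
      g <- g[g$kind != "intron", , drop = FALSE]   # introns are derived, not stored
      if (!nrow(g)) next
      g <- g[order(g$start), ]
      key <- if (g$kind[1] == "pseudogene") "gene" else g$kind[1]
      locs <- sprintf("%d..%d", g$start, g$end)
      loc <- if (length(locs) > 1L) sprintf("join(%s)", paste(locs, collapse = ","))
             else locs
      if (g$strand[1] == "-") loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     %-15s %s", key, loc), con)
      writeLines(sprintf("                     /gene=\"%s\"", g$name[1]), con)
      if (isTRUE(g$pseudo[1]))
        writeLines("                     /pseudo", con)
    }
  }
  writeLines("ORIGIN", con)
  s <- tolower(record$sequence)
  starts <- seq(1L, n, by = 60L)
  for (st in starts) {
    chunk <- substr(s, st, min(st + 59L, n))
    tens <- substring(chunk, seq(1L, nchar(chunk), 10L),
                      pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    writeLines(sprintf("%9d %s", st, paste(tens, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}
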