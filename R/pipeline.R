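## pipeline_cli: orchestrate partition -> hairpins -> SI call -> SSR -> pi
## -> character mapping into one report bundle.  All inter-stage data passes
## through declared files; outputs are deterministic for identical inputs.

#' Build a run configuration
#'
#' @param genomes path to a directory of GenBank files, a multi-FASTA, or a
#'   list of \code{\link{plastome_record}}.
#' @param alignment path to aligned FASTA or a \code{plastome_alignment}.
#' @param tree optional newick path or \code{ape::phylo} (needed for
#'   character mapping).
#' @param outgroup optional outgroup label used to root the tree.
#' @param out_dir output directory for the report bundle.
#' @param params named list of stage parameter overrides:
#'   \code{min_ir_len, min_stem, max_stem, min_loop, max_loop,
#'   max_mismatch, min_taxa_with_stem, window, step, pi_threshold,
#'   ssr_min_copies}.
#' @return object of class \code{run_config}.
#' @export
run_config <- function(genomes, alignment, tree = NULL, outgroup = NULL,
                       out_dir = "plastoflip_out", params = list()) {
  defaults <- list(min_ir_len = 10000L, min_stem = 8L, max_stem = 40L,
                   min_loop = 4L, max_loop = 30L, max_mismatch = 0L,
                   min_taxa_with_stem = 15L, window = 600L, step = 200L,
                   pi_threshold = 0.015, ssr_min_copies = ssr_thresholds())
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  defaults[names(params)] <- params
  for (p in c("genomes", "alignment", "tree")) {
    v <- get(p)
    if (is.character(v) && !file.exists(v))
      stop("input ", p, " does not exist: ", v)
  }
  structure(list(genomes = genomes, alignment = alignment, tree = tree,
                 outgroup = outgroup, out_dir = out_dir, params = defaults),
            class = "run_config")
}

load_genomes <- function(genomes) {
  if (is.list(genomes) && length(genomes) &&
      inherits(genomes[[1]], "plastome_record")) return(genomes)
  if (dir.exists(genomes)) {
    files <- list.files(genomes, pattern = "\\.(gb|gbk|genbank)$",
                        full.names = TRUE)
    if (!length(files)) stop("no GenBank files in ", genomes)
    return(lapply(sort(files), read_genbank))
  }
  read_fasta_many(genomes)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full comparative analysis
#'
#' Stages: quadripartite partition, per-taxon hairpin scan, cross-species
#' SI calling, SSR scan and summary, sliding-window nucleotide diversity
#' with hotspot ranking and (when a tree is supplied) ACCTRAN character
#' mapping of the SI matrix.  Each stage writes its own TSV; a failing
#' stage is recorded in the log and does not corrupt the other outputs.
#'
#' @param config \code{\link{run_config}}.
#' @return list of stage results (also written under
#'   \code{config$out_dir}: partition.tsv, hairpins.tsv, si_table.tsv,
#'   si_matrix.tsv, ssr.tsv, ssr_summary.tsv, pi.tsv, hotspots.tsv,
#'   charmap.tsv, run.log, manifest.json).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  p <- config$params
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "",
                            file = log_path, append = TRUE)
  cat("", file = log_path)
  logf("parameters: %s", paste(names(p), vapply(p, function(v)
    paste(v, collapse = ","), character(1)), sep = "=", collapse = " "))

  results <- list()
  fail <- character(0)
  stage <- function(name, expr) {
    out <- tryCatch(expr, error = function(e) {
      logf("stage %s FAILED: %s", name, conditionMessage(e))
      fail <<- c(fail, name)
      NULL
    })
    if (!is.null(out)) logf("stage %s ok", name)
    out
  }

  records <- load_genomes(config$genomes)
  aln <- if (inherits(config$alignment, "plastome_alignment")) config$alignment
         else read_alignment(config$alignment)
  logf("inputs: %d genomes, alignment %d x %d", length(records),
       length(aln$labels), aln$n_col)

  results$partition <- stage("partition", {
    for (i in seq_along(records)) {
      if (is.null(records[[i]]$partition))
        records[[i]]$partition <- detect_partition(records[[i]], p$min_ir_len)
    }
    tab <- partition_report(records)
    write_tsv(tab, file.path(config$out_dir, "partition.tsv"))
    tab
  })

  hp_params <- p[c("min_stem", "max_stem", "min_loop", "max_loop",
                   "max_mismatch")]
  results$hairpins <- stage("hairpins", {
    tabs <- lapply(records, function(r) {
      h <- do.call(find_hairpins, c(list(r$sequence), hp_params))
      h <- score_hairpins(h)
      if (nrow(h)) h$taxon <- r$taxon_label
      h
    })
    tab <- do.call(rbind, tabs[vapply(tabs, nrow, integer(1)) > 0])
    if (is.null(tab)) tab <- data.frame()
    write_tsv(tab, file.path(config$out_dir, "hairpins.tsv"))
    tab
  })

  results$si <- stage("si_call", {
    prof <- call_si_loci(aln, records, hairpin_params = hp_params,
                         min_taxa_with_stem = p$min_taxa_with_stem)
    write_tsv(si_report(prof), file.path(config$out_dir, "si_table.tsv"))
    m <- si_matrix(prof, taxa = aln$labels)
    write_tsv(data.frame(taxon = rownames(m), m, check.names = FALSE),
              file.path(config$out_dir, "si_matrix.tsv"))
    prof
  })

  results$ssr <- stage("ssr", {
    per <- lapply(records, function(r) scan_ssrs(r, p$ssr_min_copies))
    names(per) <- vapply(records, `[[`, character(1), "taxon_label")
    summaries <- lapply(seq_along(records), function(i)
      ssr_summary(per[[i]], records[[i]]))
    loci_tab <- do.call(rbind, lapply(seq_along(per), function(i) {
      l <- summaries[[i]]$loci
      if (nrow(l)) l$taxon <- names(per)[i]
      l
    }))
    write_tsv(loci_tab, file.path(config$out_dir, "ssr.tsv"))
    sum_tab <- do.call(rbind, lapply(seq_along(summaries), function(i) {
      s <- summaries[[i]]
      data.frame(taxon = names(per)[i],
                 n_loci = s$n_loci,
                 t(setNames(s$by_class$count, s$by_class$class)),
                 t(setNames(s$by_functional$count,
                            s$by_functional$functional)),
                 t(setNames(s$by_compartment$count,
                            s$by_compartment$compartment)),
                 check.names = FALSE)
    }))
    write_tsv(sum_tab, file.path(config$out_dir, "ssr_summary.tsv"))
    list(per_taxon = per, summaries = summaries)
  })

  results$pi <- stage("pi", {
    pw <- pi_sliding(aln, window = p$window, step = p$step)
    write_tsv(pw, file.path(config$out_dir, "pi.tsv"))
    annotated <- records[vapply(records, function(r)
      !is.null(r$features) && nrow(r$features) > 0, logical(1))]
    hs <- hotspot_rank(pw, threshold = p$pi_threshold,
                       record = if (length(annotated)) annotated[[1]] else NULL)
    write_tsv(hs, file.path(config$out_dir, "hotspots.tsv"))
    list(windows = pw, hotspots = hs)
  })

  if (!is.null(config$tree)) {
    results$charmap <- stage("charmap", {
      tr <- if (inherits(config$tree, "phylo")) config$tree
            else read_newick(config$tree, outgroup = config$outgroup)
      m <- si_matrix(results$si, taxa = aln$labels)
      cm <- classify_characters(tr, m)
      write_tsv(cm$per_character, file.path(config$out_dir, "charmap.tsv"))
      cm
    })
  }

  outputs <- list.files(config$out_dir, pattern = "\\.tsv$", full.names = TRUE)
  manifest <- list(outputs = lapply(outputs, function(f)
    list(file = basename(f), md5 = unname(tools::md5sum(f)))),
    failed_stages = fail)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (length(fail))
    warning("stage(s) failed: ", paste(fail, collapse = ", "))
  invisible(results)
}
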