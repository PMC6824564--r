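## synthetic_data: plastome-like dataset simulator with fully known planted
## truth.  An ancestral quadripartite genome is assembled from a blueprint,
## hairpin and SSR loci are planted at fixed offsets, and the genome is
## evolved along a rooted tree under Jukes-Cantor substitutions.  Planted
## elements (plus 1 bp guard flanks) are protected from substitution, loop
## orientations are reverse-complemented on designated branches (inherited
## by descendants; double flips cancel), and the two IR copies are kept
## identical within each taxon (concerted evolution).  No indels are
## simulated, so the alignment is column-exact.

BASES <- c("A", "C", "G", "T")

#' Default balanced 20-taxon tree (ten cherries)
#'
#' Multi-flip characters place their flips on terminal branches of distinct
#' cherries; on such a tree the parsimony length of the resulting character
#' provably equals the planted flip count.
#'
#' @param rate branch length (expected substitutions/site) applied to every
#'   branch; about the divergence scale seen between congeneric plastomes.
#' @return rooted \code{ape::phylo} with branch lengths.
#' @export
default_tree <- function(rate = 0.003) {
  cherry <- function(i, j) sprintf("(sp%02d,sp%02d)", i, j)
  ch <- mapply(cherry, seq(1, 19, 2), seq(2, 20, 2))
  nwk <- sprintf("((((%s,%s),(%s,%s)),((%s,%s),(%s,%s))),(%s,%s));",
                 ch[1], ch[2], ch[3], ch[4], ch[5], ch[6], ch[7], ch[8],
                 ch[9], ch[10])
  tr <- ape::read.tree(text = nwk)
  tr$edge.length <- rep(rate, nrow(tr$edge))
  tr
}

#' Default genome blueprint
#'
#' Ordered blocks (genes and spacers) for the LSC, IRb and SSC; the IRa is
#' generated as the exact reverse complement of the IRb.  Gene names follow
#' the plastid genes whose neighbourhoods commonly harbour small inversions
#' (trnH-psbA, rps16-trnQ, rpoB-trnC, psbC-trnS, petA-psbJ, rpoA, ccsA-ndhD,
#' ndhA intron).  Genes named trn* become tRNA features, rrn* rRNA, the
#' rest CDS; kind \code{gene2} is a two-exon gene with an intron.
#'
#' @return data frame with columns \code{name, compartment, kind, len}.
#' @export
default_blueprint <- function() {
  b <- rbind(
    c("spacer_start",       "LSC", "spacer", 160),
    c("trnH",               "LSC", "gene",    80),
    c("spacer_trnH_psbA",   "LSC", "spacer", 300),
    c("psbA",               "LSC", "gene",   350),
    c("spacer_psbA_rps16",  "LSC", "spacer", 100),
    c("rps16",              "LSC", "gene2",  400),
    c("spacer_rps16_trnQ",  "LSC", "spacer", 250),
    c("trnQ",               "LSC", "gene",    80),
    c("spacer_trnQ_rpoB",   "LSC", "spacer", 100),
    c("rpoB",               "LSC", "gene",   600),
    c("spacer_rpoB_trnC",   "LSC", "spacer", 300),
    c("trnC",               "LSC", "gene",    80),
    c("spacer_trnC_psbC",   "LSC", "spacer", 100),
    c("psbC",               "LSC", "gene",   500),
    c("spacer_psbC_trnS",   "LSC", "spacer", 250),
    c("trnS",               "LSC", "gene",    90),
    c("spacer_trnS_petA",   "LSC", "spacer", 120),
    c("petA",               "LSC", "gene",   450),
    c("spacer_petA_psbJ",   "LSC", "spacer", 350),
    c("psbJ",               "LSC", "gene",   120),
    c("spacer_psbJ_rpoA",   "LSC", "spacer", 100),
    c("rpoA",               "LSC", "gene",   400),
    c("spacer_rpoA_end",    "LSC", "spacer", 150),
    c("spacer_irb_start",   "IRb", "spacer",  80),
    c("rrn16",              "IRb", "gene",   700),
    c("spacer_rrn16_rpl2",  "IRb", "spacer", 120),
    c("rpl2",               "IRb", "gene",   300),
    c("spacer_ssc_start",   "SSC", "spacer",  80),
    c("ccsA",               "SSC", "gene",   350),
    c("spacer_ccsA_ndhD",   "SSC", "spacer", 250),
    c("ndhD",               "SSC", "gene",   350),
    c("spacer_ndhD_ndhA",   "SSC", "spacer", 100),
    c("ndhA",               "SSC", "gene2",  500),
    c("spacer_ssc_end",     "SSC", "spacer", 100))
  data.frame(name = b[, 1], compartment = b[, 2], kind = b[, 3],
             len = as.integer(b[, 4]), stringsAsFactors = FALSE)
}

#' Default planted hairpin loci
#'
#' Eleven stem-loop loci using published Lauraceae SI stem/loop sequences
#' (see the catalog shipped under \code{inst/extdata}); five are flipped on
#' a single terminal branch (autapomorphies) and six on 5-7 terminal
#' branches of distinct cherries of \code{\link{default_tree}}.
#'
#' @return list of loci: \code{block, offset, stem, loop, flips}.
#' @export
default_planted_hairpins <- function() {
  list(
    list(block = "spacer_trnH_psbA", offset = 30, stem = "TTTGATTTT",
         loop = "TTCCT",
         flips = c("sp01", "sp03", "sp05", "sp07", "sp09")),
    list(block = "spacer_trnH_psbA", offset = 120, stem = "GGATCAATACCAAACTTCTT",
         loop = "AATAGAAC",
         flips = c("sp02", "sp04", "sp08", "sp11", "sp13", "sp17", "sp19")),
    list(block = "spacer_rps16_trnQ", offset = 40, stem = "TTAATTCCA",
         loop = "GCGA", flips = "sp02"),
    list(block = "spacer_rpoB_trnC", offset = 60, stem = "TTTGATCTCC",
         loop = "TTATGTCATTAAGGAAACCAAATT", flips = "sp06"),
    list(block = "spacer_psbC_trnS", offset = 50, stem = "TGGCTCGGCTA",
         loop = "GGTGGGA", flips = "sp10"),
    list(block = "spacer_petA_psbJ", offset = 30, stem = "TTTCGACACAAGAAAA",
         loop = "TTCC",
         flips = c("sp03", "sp06", "sp09", "sp15", "sp20")),
    list(block = "spacer_petA_psbJ", offset = 150,
         stem = "AGTAAGAACTCAATAGGACCTTACCCCT", loop = "CTTTGTCTGATTCG",
         flips = c("sp01", "sp05", "sp10", "sp12", "sp16", "sp18")),
    list(block = "rpoA", offset = 150, stem = "ACATCTTC", loop = "TATGC",
         flips = "sp14"),
    list(block = "ccsA", offset = 150, stem = "TTTTTATC", loop = "GAAA",
         flips = "sp18"),
    list(block = "spacer_ccsA_ndhD", offset = 60,
         stem = "AAGTTTTTTCGAACCATTTGAATCA", loop = "CTACT",
         flips = c("sp02", "sp03", "sp07", "sp09", "sp14", "sp15", "sp19")),
    list(block = "ndhA", offset = 190, stem = "ACCCCTTTCCT",
         loop = "GGAAATAA",
         flips = c("sp04", "sp08", "sp13", "sp17", "sp20")))
}

#' Default planted SSR loci
#' @return list of loci: \code{block, offset, motif, copies}.
#' @export
default_planted_ssrs <- function() {
  list(
    list(block = "spacer_start", offset = 20, motif = "A", copies = 12),
    list(block = "spacer_start", offset = 60, motif = "T", copies = 11),
    list(block = "spacer_psbA_rps16", offset = 20, motif = "AT", copies = 6),
    list(block = "spacer_trnQ_rpoB", offset = 20, motif = "AAT", copies = 5),
    list(block = "spacer_trnC_psbC", offset = 20, motif = "AATT", copies = 4),
    list(block = "spacer_trnS_petA", offset = 20, motif = "AATAG", copies = 3),
    list(block = "spacer_psbJ_rpoA", offset = 30, motif = "A", copies = 10),
    list(block = "spacer_ndhD_ndhA", offset = 20, motif = "AT", copies = 5))
}

#' Build and validate a simulation configuration
#'
#' @param seed master seed; every stochastic draw flows from it.
#' @param tree rooted \code{ape::phylo} with branch lengths in expected
#'   substitutions/site.
#' @param blueprint block table, see \code{\link{default_blueprint}}.
#' @param planted_hairpins,planted_ssrs planted element lists.
#' @param base_freqs ancestral base composition (default ~60.8\% A+T, the
#'   composition typical of plastomes).
#' @param hotspot optional \code{list(block=, multiplier=)}: one block
#'   evolves at \code{multiplier} times the branch rate (a planted
#'   divergence hotspot).
#' @return validated object of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L, tree = default_tree(),
                       blueprint = default_blueprint(),
                       planted_hairpins = default_planted_hairpins(),
                       planted_ssrs = default_planted_ssrs(),
                       base_freqs = c(A = 0.304, C = 0.196,
                                      G = 0.196, T = 0.304),
                       hotspot = NULL) {
  stopifnot(inherits(tree, "phylo"), ape::is.rooted(tree),
            !is.null(tree$edge.length))
  stopifnot(all(c("name", "compartment", "kind", "len") %in% names(blueprint)))
  if (anyDuplicated(blueprint$name)) stop("duplicate blueprint block names")
  if (!all(blueprint$compartment %in% c("LSC", "IRb", "SSC")))
    stop("blueprint compartments must be LSC, IRb or SSC (IRa is derived)")
  ## planted elements: block exists, fits, and non-overlapping within block
  occupied <- list()
  claim <- function(block, offset, len, what) {
    row <- blueprint[blueprint$name == block, , drop = FALSE]
    if (!nrow(row)) stop(what, " references unknown block ", block)
    if (offset < 2L || offset + len - 1L > row$len - 1L)
      stop(what, " does not fit inside block ", block,
           " (guard flanks need 1 bp on each side)")
    iv <- c(offset, offset + len - 1L)
    for (old in occupied[[block]] %||% list())
      if (iv[1] <= old[2] + 1L && iv[2] >= old[1] - 1L)
        stop("overlapping planted elements in block ", block)
    occupied[[block]] <<- c(occupied[[block]] %||% list(), list(iv))
  }
  for (h in planted_hairpins) {
    check_dna(toupper(h$stem)); check_dna(toupper(h$loop))
    claim(h$block, h$offset, 2L * nchar(h$stem) + nchar(h$loop),
          "planted hairpin")
    resolve_branches(tree, h$flips)   # errors if a branch is unknown
  }
  for (s in planted_ssrs)
    claim(s$block, s$offset, nchar(s$motif) * s$copies, "planted SSR")
  if (!is.null(hotspot) && !hotspot$block %in% blueprint$name)
    stop("hotspot references unknown block ", hotspot$block)
  structure(list(seed = as.integer(seed), tree = tree, blueprint = blueprint,
                 planted_hairpins = planted_hairpins,
                 planted_ssrs = planted_ssrs,
                 base_freqs = base_freqs / sum(base_freqs),
                 hotspot = hotspot),
            class = "sim_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## resolve flip branch specs to child-node ids: a tip label, or
## "labelA+labelB" for the branch above mrca(labelA, labelB)
resolve_branches <- function(tree, specs) {
  vapply(specs, function(sp) {
    if (grepl("+", sp, fixed = TRUE)) {
      ab <- strsplit(sp, "+", fixed = TRUE)[[1]]
      if (!all(ab %in% tree$tip.label))
        stop("unknown taxa in flip branch: ", sp)
      ape::getMRCA(tree, ab)
    } else {
      i <- match(sp, tree$tip.label)
      if (is.na(i)) stop("unknown taxon in flip branch: ", sp)
      i
    }
  }, integer(1))
}

## Break background hairpin arms and near-threshold repeat runs so that the
## only robustly detectable loci are the planted ones (which are protected).
## Near-stems within one substitution of the detection threshold are broken
## too (scan with a 1-mismatch budget), so a single later substitution on a
## branch cannot conjure a competing stem next to a planted locus.
sanitize_background <- function(vec, protected, base_freqs) {
  free <- !protected
  for (pass in 1:15) {
    s <- paste(vec, collapse = "")
    dirty <- FALSE
    h <- rbind(find_hairpins(s, min_stem = 6L, min_loop = 3L, max_loop = 36L),
               find_hairpins(s, min_stem = 7L, min_loop = 3L, max_loop = 36L,
                             max_mismatch = 1L))
    for (i in seq_len(nrow(h))) {
      arm5 <- seq(h$genome_start[i], h$loop_start[i] - 1L)
      partner <- h$genome_end[i] - (arm5 - h$genome_start[i])
      usable <- free[arm5]
      if (!any(usable)) {
        tmp <- arm5; arm5 <- partner; partner <- tmp
        usable <- free[arm5]
      }
      if (!any(usable)) next
      idx <- which(usable)
      picks <- unique(idx[ceiling(length(idx) * c(1, 2) / 3)])
      for (k in picks) {
        p <- arm5[k]; q <- partner[k]
        if (vec[p] != vec[q]) { vec[p] <- vec[q]; dirty <- TRUE }
      }
    }
    ssr <- scan_ssrs(paste(vec, collapse = ""),
                     min_copies = pmax(ssr_thresholds() - 2L, 2L))
    for (i in seq_len(nrow(ssr))) {
      run <- seq(ssr$start[i], ssr$end[i])
      run <- run[free[run]]
      if (!length(run)) next
      p <- run[ceiling(length(run) / 2)]
      vec[p] <- sample(setdiff(BASES, vec[p]), 1L)
      dirty <- TRUE
    }
    if (!dirty) break
  }
  vec
}

#' Simulate a plastome dataset with planted truth
#'
#' @param config \code{\link{sim_config}}.
#' @return list with \code{records} (annotated, partitioned
#'   \code{\link{plastome_record}} per tip), \code{alignment}
#'   (column-exact, gap-free) and \code{truth}: planted SI matrix, flip
#'   counts, autapomorphy status, partition lengths, SSR truth and planted
#'   coordinates.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 11L))
  bp <- config$blueprint
  tree <- config$tree

  ## --- assemble ancestor core (LSC + IRb + SSC); IRa derived per taxon ---
  block_start <- cumsum(c(1L, bp$len))[seq_len(nrow(bp))]
  names(block_start) <- bp$name
  core_len <- sum(bp$len)
  vec <- sample(BASES, core_len, replace = TRUE, prob = config$base_freqs)

  protected <- logical(core_len)
  ## IR-boundary guards pin the exact partition: LSC first/last and SSC
  ## first/last bases are 'A' so the exact IR pair cannot chance-extend
  lsc_len <- sum(bp$len[bp$compartment == "LSC"])
  ir_len <- sum(bp$len[bp$compartment == "IRb"])
  ssc_len <- sum(bp$len[bp$compartment == "SSC"])
  guard_pos <- c(1L, lsc_len, lsc_len + ir_len + 1L, core_len)
  vec[guard_pos] <- "A"
  protected[guard_pos] <- TRUE

  ## plant hairpins
  hp <- config$planted_hairpins
  hp_truth <- list()
  for (k in seq_along(hp)) {
    h <- hp[[k]]
    stem <- toupper(h$stem); loop <- toupper(h$loop)
    st <- block_start[[h$block]] + h$offset - 1L
    ins <- strsplit(paste0(stem, loop, revcomp(stem)), "", fixed = TRUE)[[1]]
    rng <- seq(st, st + length(ins) - 1L)
    vec[rng] <- ins
    guard <- c(st - 1L, st + length(ins))
    vec[guard] <- "C"           # C|C flanks cannot pair: no outward extension
    protected[c(rng, guard)] <- TRUE
    loop_rng <- seq(st + nchar(stem), st + nchar(stem) + nchar(loop) - 1L)
    hp_truth[[k]] <- list(id = k, start = st, loop_range = loop_rng,
                          stem = stem, loop = loop, flips = h$flips,
                          flip_nodes = resolve_branches(tree, h$flips),
                          block = h$block)
  }

  ## plant SSRs
  sr <- config$planted_ssrs
  sr_truth <- list()
  for (k in seq_along(sr)) {
    s <- sr[[k]]
    motif <- toupper(s$motif)
    st <- block_start[[s$block]] + s$offset - 1L
    ins <- strsplit(strrep(motif, s$copies), "", fixed = TRUE)[[1]]
    rng <- seq(st, st + length(ins) - 1L)
    vec[rng] <- ins
    guard <- c(st - 1L, st + length(ins))
    vec[guard] <- "C"           # motifs avoid C at their period positions
    protected[c(rng, guard)] <- TRUE
    sr_truth[[k]] <- data.frame(start = st, end = st + length(ins) - 1L,
                                motif = canonical_rotation(motif),
                                unit_len = nchar(motif), copies = s$copies,
                                block = s$block, stringsAsFactors = FALSE)
  }
  sr_truth <- if (length(sr_truth)) do.call(rbind, sr_truth) else NULL

  vec <- sanitize_background(vec, protected, config$base_freqs)

  ## per-site relative rate (planted divergence hotspot)
  rel_rate <- rep(1, core_len)
  if (!is.null(config$hotspot)) {
    hs <- config$hotspot
    rng <- seq(block_start[[hs$block]],
               block_start[[hs$block]] + bp$len[bp$name == hs$block] - 1L)
    rel_rate[rng] <- hs$multiplier
  }
  rel_rate[protected] <- 0

  ## --- evolve along the tree (preorder), flips applied on entry ---
  ntip <- length(tree$tip.label)
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[ntip + 1L]] <- vec
  E <- tree$edge
  ## root-outward edge order (robust to any internal node numbering)
  pre <- integer(0)
  remaining <- seq_len(nrow(E))
  done <- c(ntip + 1L)
  while (length(remaining)) {
    ready <- remaining[E[remaining, 1L] %in% done]
    if (!length(ready)) stop("tree edges do not form a rooted tree")
    pre <- c(pre, ready)
    done <- c(done, E[ready, 2L])
    remaining <- setdiff(remaining, ready)
  }
  flip_nodes <- lapply(hp_truth, `[[`, "flip_nodes")
  for (e in pre) {
    par <- E[e, 1L]; ch <- E[e, 2L]; t <- tree$edge.length[e]
    child <- seqs[[par]]
    p_site <- 0.75 * (1 - exp(-4 * t * rel_rate / 3))
    mut <- which(runif(core_len) < p_site)
    if (length(mut)) {
      shift <- sample(1:3, length(mut), replace = TRUE)
      child[mut] <- BASES[(match(child[mut], BASES) - 1L + shift) %% 4L + 1L]
    }
    for (k in seq_along(hp_truth)) {
      if (ch %in% flip_nodes[[k]]) {
        rng <- hp_truth[[k]]$loop_range
        child[rng] <- rev(chartr("ACGT", "TGCA", child[rng]))
      }
    }
    seqs[[ch]] <- child
  }

  ## --- truth: SI matrix from flip parity along root-to-tip paths ---
  paths <- lapply(seq_len(ntip), function(i) {
    nodes <- i
    cur <- i
    repeat {
      par <- E[E[, 2L] == cur, 1L]
      if (!length(par)) break
      nodes <- c(nodes, par)
      cur <- par
    }
    nodes
  })
  si_names <- if (length(hp_truth)) paste0("si", seq_along(hp_truth))
              else character(0)
  si_true <- matrix("A", nrow = ntip, ncol = length(hp_truth),
                    dimnames = list(tree$tip.label, si_names))
  for (k in seq_along(hp_truth)) {
    for (i in seq_len(ntip)) {
      nf <- sum(paths[[i]] %in% flip_nodes[[k]])
      if (nf %% 2L == 1L) si_true[i, k] <- "B"
    }
  }

  ## --- features (identical across taxa: no indels) ---
  feats <- list(); fid <- 0L
  for (r in seq_len(nrow(bp))) {
    if (bp$kind[r] == "spacer") next
    nm <- bp$name[r]; st <- block_start[[nm]]; len <- bp$len[r]
    kind <- if (grepl("^trn", nm)) "tRNA" else if (grepl("^rrn", nm)) "rRNA"
            else "CDS"
    fid <- fid + 1L
    feats[[length(feats) + 1L]] <- data.frame(
      feature_id = fid, kind = "gene", name = nm, start = st,
      end = st + len - 1L, strand = "+", pseudo = FALSE,
      stringsAsFactors = FALSE)
    fid <- fid + 1L
    if (bp$kind[r] == "gene2") {
      ex <- round(len * 0.3)
      feats[[length(feats) + 1L]] <- data.frame(
        feature_id = fid, kind = kind, name = nm,
        start = c(st, st + len - ex), end = c(st + ex - 1L, st + len - 1L),
        strand = "+", pseudo = FALSE, stringsAsFactors = FALSE)
      fid <- fid + 1L
      feats[[length(feats) + 1L]] <- data.frame(
        feature_id = fid, kind = "intron", name = nm, start = st + ex,
        end = st + len - ex - 1L, strand = "+", pseudo = FALSE,
        stringsAsFactors = FALSE)
    } else {
      feats[[length(feats) + 1L]] <- data.frame(
        feature_id = fid, kind = kind, name = nm, start = st,
        end = st + len - 1L, strand = "+", pseudo = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  feats <- do.call(rbind, feats)

  total_len <- core_len + ir_len
  part <- quadripartite_partition(
    lsc = c(1L, lsc_len), irb = c(lsc_len + 1L, ir_len),
    ssc = c(lsc_len + ir_len + 1L, ssc_len),
    ira = c(core_len + 1L, ir_len), length_bp = total_len,
    at_content = NA_real_)

  records <- vector("list", ntip)
  aln_rows <- character(ntip)
  irb_rng <- seq(lsc_len + 1L, lsc_len + ir_len)
  for (i in seq_len(ntip)) {
    core <- seqs[[i]]
    ira <- rev(chartr("ACGT", "TGCA", core[irb_rng]))
    s <- paste(c(core, ira), collapse = "")
    p <- part; p$at_content <- at_content(s)
    records[[i]] <- plastome_record(tree$tip.label[i], s, features = feats,
                                    partition = p)
    aln_rows[i] <- s
  }
  alignment <- make_alignment(tree$tip.label, aln_rows)

  region_truth <- vapply(hp_truth, function(h) {
    mid <- h$loop_range[1]
    cl <- classify_region(records[[1]], mid)
    cl$functional
  }, character(1))

  truth <- list(
    si_matrix = si_true,
    flip_counts = vapply(hp_truth, function(h) length(h$flips), integer(1)),
    flip_branches = lapply(hp_truth, `[[`, "flips"),
    autapomorphic = which(vapply(hp_truth, function(h)
      length(h$flips) == 1L, logical(1))),
    hairpins = hp_truth,
    regions = region_truth,
    partition = c(lsc_len = lsc_len, ir_len = ir_len, ssc_len = ssc_len,
                  total = total_len),
    ssrs = sr_truth)
  list(records = records, alignment = alignment, truth = truth,
       tree = tree)
}

#' Write simulated genomes as GenBank fixtures
#'
#' @param config \code{\link{sim_config}}.
#' @param dir output directory (created if needed).
#' @return character vector of written file paths (one per taxon),
#'   invisibly; the simulated dataset is attached as attribute
#'   \code{"dataset"}.
#' @export
make_fixture_genbank <- function(config, dir) {
  ds <- simulate_dataset(config)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(ds$records, function(r) {
    p <- file.path(dir, paste0(r$taxon_label, ".gb"))
    write_genbank(r, p)
    p
  }, character(1))
  invisible(structure(paths, dataset = ds))
}
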