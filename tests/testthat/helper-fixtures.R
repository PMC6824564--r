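## Small in-code fixtures shared across test files.

## an annotated toy record: petA - spacer - psbJ - spacer - 2-exon gene
toy_annotated_record <- function() {
  set.seed(91)
  seqs <- c(petA = rnd_dna(60), igs1 = rnd_dna(40), psbJ = rnd_dna(50),
            igs2 = rnd_dna(30), nd2a = rnd_dna(30), ndint = rnd_dna(40),
            nd2b = rnd_dna(30), tail = rnd_dna(20))
  starts <- cumsum(c(1, nchar(seqs)))[seq_along(seqs)]
  names(starts) <- names(seqs)
  feats <- rbind(
    data.frame(feature_id = 1L, kind = "gene", name = "petA",
               start = starts["petA"], end = starts["petA"] + 59L,
               strand = "+", pseudo = FALSE),
    data.frame(feature_id = 2L, kind = "CDS", name = "petA",
               start = starts["petA"], end = starts["petA"] + 59L,
               strand = "+", pseudo = FALSE),
    data.frame(feature_id = 3L, kind = "gene", name = "psbJ",
               start = starts["psbJ"], end = starts["psbJ"] + 49L,
               strand = "+", pseudo = FALSE),
    data.frame(feature_id = 4L, kind = "CDS", name = "psbJ",
               start = starts["psbJ"], end = starts["psbJ"] + 49L,
               strand = "+", pseudo = FALSE),
    data.frame(feature_id = 5L, kind = "gene", name = "ndhX",
               start = starts["nd2a"], end = starts["nd2b"] + 29L,
               strand = "+", pseudo = FALSE),
    data.frame(feature_id = 6L, kind = "CDS", name = "ndhX",
               start = c(starts["nd2a"], starts["nd2b"]),
               end = c(starts["nd2a"] + 29L, starts["nd2b"] + 29L),
               strand = "+", pseudo = FALSE))
  rec <- plastome_record("toy", paste(seqs, collapse = ""), features = feats)
  attr(rec, "starts") <- starts
  rec
}

## a small 8-taxon simulation: 3 flip loci + 5 monomorphic hairpins
small_sim_config <- function(seed = 7, rate = 0.002, flips = TRUE) {
  tr <- ape::read.tree(
    text = "(((a,b),(c,d)),((e,f),(g,h)));")
  tr$edge.length <- rep(rate, nrow(tr$edge))
  bp <- data.frame(
    name = c("spA", "g1", "spB", "g2", "spC", "g3", "spD",
             "irg", "spE", "g4", "spF"),
    compartment = c(rep("LSC", 7), "IRb", rep("SSC", 3)),
    kind = c("spacer", "gene", "spacer", "gene", "spacer", "gene", "spacer",
             "gene", "spacer", "gene", "spacer"),
    len = c(200L, 150L, 200L, 150L, 200L, 150L, 200L,
            400L, 150L, 150L, 200L),
    stringsAsFactors = FALSE)
  mk <- function(block, offset, stem, loop, fl)
    list(block = block, offset = offset, stem = stem, loop = loop,
         flips = if (flips) fl else character(0))
  hp <- list(
    mk("spA", 30, "TTTGATTTT", "TTCCT", c("a")),
    mk("spB", 30, "TGGCTCGGCTA", "GGTGGGA", c("c", "e", "g")),
    mk("spC", 30, "ACATCTTCC", "TATGC", c("e", "f")),      # cherry flip x2
    mk("spD", 30, "TTAATTCCA", "GCGA", character(0)),       # monomorphic
    mk("spD", 100, "TTTCGACACAAGAAAA", "TTCC", character(0)),
    mk("spE", 30, "TTTTTATCC", "GAAA", character(0)),
    mk("spF", 30, "ACCCCTTTCCT", "GGAAATAA", character(0)),
    mk("spF", 100, "AAGTTTTTTCGAACC", "CTACT", character(0)))
  sim_config(seed = seed, tree = tr, blueprint = bp, planted_hairpins = hp,
             planted_ssrs = list())
}
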