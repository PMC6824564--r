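## a fixed flank with no repeats at any class threshold
FLANK_L <- "GCATCGGATCCTAGGCATTGACTGCAGT"
FLANK_R <- "CAGTGCTAGCAATGCCTAGGATCCGATG"

test_that("class thresholds gate mono- through penta-repeats", {
  ## 10 x A qualifies (mono threshold 10)
  s <- paste0(FLANK_L, strrep("A", 10), FLANK_R)
  got <- scan_ssrs(s)
  expect_equal(nrow(got), 1)
  expect_equal(got$unit_len, 1)
  expect_equal(got$copies, 10)
  expect_equal(got$start, nchar(FLANK_L) + 1)
  ## 9 x A does not
  expect_equal(nrow(scan_ssrs(paste0(FLANK_L, strrep("A", 9), FLANK_R))), 0)
  ## (AT)5 is one di-SSR and no mono-SSR
  got <- scan_ssrs(paste0(FLANK_L, strrep("AT", 5), FLANK_R))
  expect_equal(nrow(got), 1)
  expect_equal(got$unit_len, 2)
  expect_equal(got$motif, "AT")
  expect_equal(got$copies, 5)
  ## (ATA)3 is below the tri threshold of 4
  expect_equal(nrow(scan_ssrs(paste0(FLANK_L, "ATAATAATA", FLANK_R))), 0)
})

test_that("loci are reported once, under their primitive motif", {
  ## a 12 x A run must not also be reported as (AA)6 or (AAA)4
  got <- scan_ssrs(paste0(FLANK_L, strrep("A", 12), FLANK_R))
  expect_equal(nrow(got), 1)
  expect_equal(got$unit, "A")
  ## N breaks runs
  s <- paste0(FLANK_L, strrep("A", 6), "N", strrep("A", 6), FLANK_R)
  expect_equal(nrow(scan_ssrs(s)), 0)
})

test_that("the scanner equals the brute-force enumeration oracle", {
  set.seed(101)
  for (rep in 1:10) {
    s <- rnd_dna(1000)
    got <- scan_ssrs(s)[, c("start", "end", "unit_len", "copies", "unit")]
    want <- oracle_scan_ssrs(s)
    rownames(got) <- NULL
    expect_equal(got, want, info = paste("replicate", rep))
  }
  ## low thresholds exercise every class on shorter sequences
  for (rep in 1:10) {
    s <- rnd_dna(300)
    thr <- c(4, 3, 2, 2, 2)
    got <- scan_ssrs(s, thr)[, c("start", "end", "unit_len", "copies", "unit")]
    want <- oracle_scan_ssrs(s, thr)
    rownames(got) <- NULL
    expect_equal(got, want, info = paste("low-threshold replicate", rep))
  }
})

test_that("reverse-complement scanning mirrors loci and preserves classes", {
  set.seed(55)
  s <- paste0(FLANK_L, strrep("AAG", 5), FLANK_R, strrep("A", 11), FLANK_L)
  n <- nchar(s)
  a <- scan_ssrs(s)
  b <- scan_ssrs(revcomp(s))
  expect_equal(nrow(a), nrow(b))
  b_mirr <- data.frame(start = n - b$end + 1, end = n - b$start + 1,
                       unit_len = b$unit_len, copies = b$copies)
  b_mirr <- b_mirr[order(b_mirr$start), ]
  rownames(b_mirr) <- NULL
  expect_equal(a[, c("start", "end", "unit_len", "copies")], b_mirr)
  ## canonical motifs of the mirrored loci are the revcomp classes
  expect_setequal(b$motif, canonical_rotation(revcomp(a$motif)))
})

test_that("doubling a junction-safe genome doubles locus counts", {
  s <- paste0(FLANK_L, strrep("A", 10), FLANK_R, strrep("AT", 5), "GC")
  one <- scan_ssrs(s)
  two <- scan_ssrs(strrep(s, 2))
  expect_equal(nrow(two), 2 * nrow(one))
})

test_that("summaries report class, functional and compartment splits", {
  empty <- ssr_summary(scan_ssrs("GCGCGC"))
  expect_true(all(empty$by_class$count == 0))
  expect_equal(empty$n_loci, 0)

  ## planted counts {mono: 6, di: 2, tetra: 1} give 66.7 / 22.2 / 11.1
  loci <- data.frame(start = seq(1, 900, 100)[1:9],
                     end = seq(1, 900, 100)[1:9] + 11,
                     unit_len = c(rep(1L, 6), 2L, 2L, 4L),
                     copies = c(rep(12L, 6), 6L, 6L, 3L))
  loci$length_bp <- loci$unit_len * loci$copies
  loci$unit <- loci$motif <- c(rep("A", 6), "AT", "AT", "AATT")
  s <- ssr_summary(loci)
  expect_equal(s$by_class$pct[s$by_class$class == "mono"], 66.7)
  expect_equal(s$by_class$pct[s$by_class$class == "di"], 22.2)
  expect_equal(s$by_class$pct[s$by_class$class == "tetra"], 11.1)

  ## three loci inside the LSC of a partitioned genome: LSC share 100%
  part <- quadripartite_partition(c(1L, 1000L), c(1001L, 300L),
                                  c(1301L, 400L), c(1701L, 300L),
                                  2000L, 0.5)
  loci3 <- loci[1:3, ]
  s3 <- ssr_summary(loci3, partition = part)
  expect_equal(s3$by_compartment$pct[s3$by_compartment$compartment == "LSC"],
               100)
  expect_false(any(s3$loci$ir_duplicate))
})

test_that("cross-taxon locus matrix classifies conservation status", {
  mk <- function(copies_at) paste0(FLANK_L, strrep("AT", 6), FLANK_R,
                                   strrep("AAT", copies_at), FLANK_L)
  seqs <- c(t1 = mk(5), t2 = mk(5), t3 = mk(6), t4 = mk(6))
  ## pad with gaps at the end so rows align despite copy-number indels
  width <- max(nchar(seqs))
  rows <- vapply(seqs, function(x)
    paste0(x, strrep("-", width - nchar(x))), character(1))
  aln <- make_alignment(names(seqs), rows)
  per <- lapply(seqs, scan_ssrs)
  res <- ssr_locus_matrix(per, aln)
  expect_equal(ncol(res$matrix), 2)
  st <- setNames(res$status$status, res$status$motif)
  expect_equal(unname(st["AT"]), "conserved")
  expect_equal(unname(st["AAT"]), "synapomorphic")   # two-clade 2/2 split

  ## a single deviant taxon is autapomorphic
  seqs2 <- c(t1 = mk(5), t2 = mk(5), t3 = mk(5), t4 = mk(7))
  width <- max(nchar(seqs2))
  rows2 <- vapply(seqs2, function(x)
    paste0(x, strrep("-", width - nchar(x))), character(1))
  aln2 <- make_alignment(names(seqs2), rows2)
  res2 <- ssr_locus_matrix(lapply(seqs2, scan_ssrs), aln2)
  st2 <- setNames(res2$status$status, res2$status$motif)
  expect_equal(unname(st2["AAT"]), "autapomorphic")
})
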