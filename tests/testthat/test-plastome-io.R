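test_that("unaligned FASTA reader uppercases, keeps order, rejects bad input", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">tx1 some description", "acgtacgt",
               ">tx2", "GGGCCC", ">tx3", "acgTN"), f)
  recs <- read_fasta_many(f)
  expect_length(recs, 3)
  expect_equal(vapply(recs, `[[`, character(1), "taxon_label"),
               c("tx1", "tx2", "tx3"))
  expect_equal(recs[[1]]$sequence, "ACGTACGT")
  expect_equal(recs[[3]]$sequence, "ACGTN")

  writeLines(c(">a", "ACGT", ">a", "GGGG"), f)
  expect_error(read_fasta_many(f), "duplicate")
  writeLines(c(">a", "AC-GT"), f)
  expect_error(read_fasta_many(f), "read_alignment")
  writeLines(c(">a", "ACGT", ">b", ""), f)
  expect_error(read_fasta_many(f), "empty sequence")
})

test_that("alignment reader enforces equal rows and maps columns to coordinates", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">r1", "ACGTACGTAC", ">r2", "ACGTACGTAC"), f)
  aln <- read_alignment(f)
  expect_equal(aln$n_col, 10)
  map <- alignment_coord_map(aln, "r1")
  expect_equal(map$col_to_pos, 1:10)
  expect_equal(map$pos_to_col, 1:10)

  aln2 <- make_alignment(c("r1", "r2"), c("AC-GT", "ACCGT"))
  m <- alignment_coord_map(aln2, "r1")
  expect_equal(m$col_to_pos, c(1L, 2L, NA, 3L, 4L))
  expect_equal(m$pos_to_col, c(1L, 2L, 4L, 5L))

  writeLines(c(">r1", "ACGT", ">r2", "ACG"), f)
  expect_error(read_alignment(f), "ragged")
})

test_that("alignment round-trips through aligned FASTA", {
  set.seed(11)
  rows <- vapply(1:5, function(i) {
    x <- strsplit(rnd_dna(40), "")[[1]]
    x[sample(40, 4)] <- "-"
    paste(x, collapse = "")
  }, character(1))
  aln <- make_alignment(paste0("t", 1:5), rows)
  f <- withr::local_tempfile(fileext = ".fasta")
  write_alignment(aln, f)
  back <- read_alignment(f)
  expect_equal(back$seqs, aln$seqs)
})

test_that("GenBank round-trip preserves sequence and feature intervals", {
  rec <- toy_annotated_record()
  f <- withr::local_tempfile(fileext = ".gb")
  write_genbank(rec, f)
  back <- read_genbank(f)
  expect_equal(back$sequence, rec$sequence)
  orig <- rec$features[order(rec$features$start, rec$features$kind),
                       c("kind", "name", "start", "end")]
  ## reader derives intron rows for the 2-exon gene; drop them to compare
  got <- back$features[back$features$kind != "intron", ]
  got <- got[order(got$start, got$kind), c("kind", "name", "start", "end")]
  rownames(orig) <- rownames(got) <- NULL
  expect_equal(got, orig)
  ## derived intron covers the gap between the two exons
  intr <- back$features[back$features$kind == "intron", ]
  expect_equal(nrow(intr), 1L)
  st <- attr(rec, "starts")
  expect_equal(intr$start, unname(st["ndint"]))
  expect_equal(intr$end, unname(st["ndint"]) + 39L)
})

test_that("GenBank reader fails cleanly on malformed input", {
  f <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("LOCUS       broken 40 bp DNA circular PLN",
               "FEATURES             Location/Qualifiers",
               "     CDS             10..90",
               '                     /gene="badgene"',
               "ORIGIN",
               "        1 acgtacgtac acgtacgtac acgtacgtac acgtacgtac",
               "//"), f)
  expect_error(read_genbank(f), "badgene")

  writeLines(c("LOCUS       noseq 40 bp DNA circular PLN",
               "FEATURES             Location/Qualifiers"), f)
  expect_error(read_genbank(f), "sequence block")
})

test_that("region classification partitions the genome into CDS/intron/IGS", {
  rec <- toy_annotated_record()
  st <- attr(rec, "starts")
  ## inside single-exon CDS
  expect_equal(classify_region(rec, st["petA"] + 5)$functional, "CDS")
  ## between the two exons of the 2-exon gene
  expect_equal(classify_region(rec, st["ndint"] + 10)$functional, "intron")
  ## between petA and psbJ
  igs <- classify_region(rec, st["igs1"] + 5)
  expect_equal(igs$functional, "IGS")
  expect_equal(igs$flanking, "petA-psbJ")
  ## total over every position; classes partition the genome
  all_cls <- classify_region(rec, seq_len(rec$length_bp))
  expect_true(all(all_cls$functional %in% c("CDS", "intron", "IGS")))
  expect_error(classify_region(rec, rec$length_bp + 1), "out of range")
  expect_error(classify_region(rec, 0), "out of range")
})

test_that("IGS flanking labels wrap around the circular origin", {
  rec <- toy_annotated_record()
  ## last block (tail) lies after the final gene: flanks wrap to the first
  cls <- classify_region(rec, rec$length_bp - 5L)
  expect_equal(cls$functional, "IGS")
  expect_equal(cls$flanking, "ndhX-petA")
})
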