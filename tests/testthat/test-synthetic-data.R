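test_that("zero branch lengths and no flips give identical taxa", {
  cfg <- small_sim_config(flips = FALSE, rate = 0)
  ds <- simulate_dataset(cfg)
  seqs <- unname(vapply(ds$records, `[[`, character(1), "sequence"))
  expect_equal(length(unique(seqs)), 1)
  pw <- pi_sliding(ds$alignment, window = 300, step = 100)
  expect_true(all(pw$pi == 0))
  expect_length(call_si_loci(ds$alignment, min_taxa_with_stem = 8), 0)
})

test_that("a single flip creates one autapomorphic SI", {
  cfg <- small_sim_config(seed = 23)
  cfg$planted_hairpins <- cfg$planted_hairpins[1]   # flip on taxon a only
  ds <- simulate_dataset(cfg)
  prof <- call_si_loci(ds$alignment, min_taxa_with_stem = 8)
  expect_length(prof, 1)
  a <- prof[[1]]$assignments
  expect_equal(a$taxon[a$orientation == "B"], "a")
  m <- si_matrix(prof)
  fit <- fitch_acctran(ds$tree, m[, 1])
  expect_equal(fit$parsimony_length, 1L)
  expect_equal(fit$changes$branch, "a")
})

test_that("double flips along one path cancel", {
  cfg <- small_sim_config(seed = 29)
  ## flip on the branch above mrca(a, b) and again on the branch to a:
  ## only b ends up reversed
  cfg$planted_hairpins <- cfg$planted_hairpins[1]
  cfg$planted_hairpins[[1]]$flips <- c("a+b", "a")
  ds <- simulate_dataset(cfg)
  expect_equal(unname(ds$truth$si_matrix[, 1]),
               ifelse(rownames(ds$truth$si_matrix) == "b", "B", "A"))
  prof <- call_si_loci(ds$alignment, min_taxa_with_stem = 8)
  a <- prof[[1]]$assignments
  expect_equal(a$taxon[a$orientation == "B"], "b")
})

test_that("invalid configurations are rejected at validation time", {
  bp <- default_blueprint()
  hp <- default_planted_hairpins()
  hp[[2]]$offset <- hp[[1]]$offset + 3   # overlaps the first locus
  expect_error(sim_config(planted_hairpins = hp), "overlapping")
  hp <- default_planted_hairpins()
  hp[[1]]$block <- "no_such_block"
  expect_error(sim_config(planted_hairpins = hp), "unknown block")
  hp <- default_planted_hairpins()
  hp[[1]]$flips <- "spXX"
  expect_error(sim_config(planted_hairpins = hp), "unknown taxon")
})

test_that("GenBank fixtures round-trip and classify planted regions", {
  dir <- withr::local_tempdir()
  cfg <- small_sim_config(seed = 31)
  paths <- make_fixture_genbank(cfg, dir)
  ds <- attr(paths, "dataset")
  expect_length(paths, 8)
  back <- read_genbank(paths[1])
  rec <- ds$records[[1]]
  expect_equal(back$sequence, rec$sequence)
  expect_equal(nrow(back$features[back$features$kind != "intron", ]),
               nrow(rec$features[rec$features$kind != "intron", ]))
  ## planted hairpin in the spacer between g1 and g2 classifies as IGS
  h2 <- ds$truth$hairpins[[2]]
  cls <- classify_region(back, h2$loop_range[1])
  expect_equal(cls$functional, "IGS")
  expect_equal(cls$flanking, "g1-g2")
})

test_that("the default 20-taxon dataset is fully recovered end to end", {
  ds <- simulate_dataset(sim_config(seed = 2))
  ## quadripartite truth
  p <- detect_partition(ds$records[[5]], min_ir_len = 200)
  expect_equal(unname(c(p$lsc_len, p$ir_len, p$ssc_len)),
               unname(ds$truth$partition[c("lsc_len", "ir_len", "ssc_len")]))
  ## SI truth: 11 loci, matrix exact, regions 8 IGS / 2 CDS / 1 intron
  prof <- call_si_loci(ds$alignment, ds$records, min_taxa_with_stem = 15)
  expect_length(prof, 11)
  m <- si_matrix(prof, taxa = ds$alignment$labels)
  expect_equal(unname(m), unname(ds$truth$si_matrix[rownames(m), ]))
  expect_equal(as.integer(table(ds$truth$regions)[c("IGS", "CDS", "intron")]),
               c(8L, 2L, 1L))
  ## ACCTRAN change counts equal the planted flip counts; 5 autapomorphies
  cm <- classify_characters(ds$tree, m)
  expect_equal(cm$per_character$parsimony_length, ds$truth$flip_counts)
  expect_equal(which(cm$per_character$status == "autapomorphic"),
               ds$truth$autapomorphic)
  expect_equal(cm$synapomorphic_change_range, c(5L, 7L))
  ## planted SSRs recovered with exact copy numbers in every taxon
  for (i in c(1, 10, 20)) {
    got <- scan_ssrs(ds$records[[i]])
    key_got <- paste(got$start, got$unit_len, got$copies)
    key_want <- paste(ds$truth$ssrs$start, ds$truth$ssrs$unit_len,
                      ds$truth$ssrs$copies)
    expect_true(all(key_want %in% key_got))
  }
})

test_that("simulation is deterministic under its seed", {
  d1 <- simulate_dataset(small_sim_config(seed = 3))
  d2 <- simulate_dataset(small_sim_config(seed = 3))
  expect_identical(vapply(d1$records, `[[`, character(1), "sequence"),
                   vapply(d2$records, `[[`, character(1), "sequence"))
  d3 <- simulate_dataset(small_sim_config(seed = 4))
  expect_false(identical(d1$records[[1]]$sequence, d3$records[[1]]$sequence))
})
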