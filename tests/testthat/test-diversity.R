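test_that("identical rows give zero diversity everywhere", {
  set.seed(2)
  row <- rnd_dna(1400)
  aln <- make_alignment(c("a", "b", "c"), rep(row, 3))
  pw <- pi_sliding(aln)
  expect_true(all(pw$pi == 0))
  expect_true(all(pw$n_valid_sites == 600))
  ## midpoints advance by the step
  expect_equal(diff(pw$midpoint), rep(200, nrow(pw) - 1))
})

test_that("pairwise differences are averaged the Nei way", {
  ## two rows differing at 6 of 600 sites
  r1 <- strrep("A", 600)
  r2 <- paste0(strrep("A", 594), strrep("C", 6))
  expect_equal(pi_sliding(make_alignment(c("a", "b"), c(r1, r2)))$pi, 0.01)
  ## three rows with pairwise differences 2, 4, 6: mean 4 over 600 sites
  r2 <- paste0(strrep("C", 2), strrep("A", 598))
  r3 <- paste0(strrep("A", 596), strrep("G", 4))
  pi3 <- pi_sliding(make_alignment(c("x", "y", "z"), c(r1, r2, r3)))$pi
  expect_equal(pi3, ((2 + 4 + 6) / 3) / 600)
})

test_that("gapped and N sites are excluded and the denominator shrinks", {
  r1 <- paste0(strrep("A", 300), strrep("-", 100), strrep("A", 200))
  r2 <- paste0(strrep("A", 294), strrep("C", 6), strrep("A", 300))
  pw <- pi_sliding(make_alignment(c("a", "b"), c(r1, r2)))
  expect_equal(pw$n_valid_sites, 500)
  expect_equal(pw$pi, 6 / 500)
  ## a window of only gaps is undefined, not zero
  r1 <- paste0(strrep("-", 600), strrep("A", 600))
  r2 <- strrep("A", 1200)
  pw <- pi_sliding(make_alignment(c("a", "b"), c(r1, r2)), step = 600)
  expect_true(is.na(pw$pi[1]))
  expect_equal(pw$pi[2], 0)
})

test_that("sliding windows match the direct per-window oracle", {
  set.seed(31)
  rows <- vapply(1:4, function(i) {
    x <- strsplit(rnd_dna(1500), "")[[1]]
    x[sample(1500, 30)] <- "-"
    paste(x, collapse = "")
  }, character(1))
  aln <- make_alignment(paste0("t", 1:4), rows)
  pw <- pi_sliding(aln, window = 400, step = 150)
  for (k in seq_len(nrow(pw))) {
    expect_equal(pw$pi[k],
                 oracle_pi(rows, pw$window_start[k], pw$window_end[k]),
                 info = paste("window", k))
  }
  ## partial tail windows are dropped
  expect_true(max(pw$window_end) <= 1500)
  expect_equal(nrow(pw), length(seq(1, 1500 - 400 + 1, by = 150)))
})

test_that("diversity is invariant to row order and strand", {
  set.seed(8)
  rows <- c(a = rnd_dna(900), b = rnd_dna(900), c = rnd_dna(900))
  aln <- make_alignment(names(rows), unname(rows))
  p1 <- pi_sliding(aln)$pi
  p2 <- pi_sliding(make_alignment(c("c", "a", "b"),
                                  unname(rows[c(3, 1, 2)])))$pi
  expect_equal(p1, p2)
  rc <- make_alignment(names(rows), revcomp(unname(rows)))
  ## a full-width window is strand-symmetric (sliding windows mirror)
  expect_equal(pi_sliding(aln, window = 900, step = 900)$pi,
               pi_sliding(rc, window = 900, step = 900)$pi)
})

test_that("hotspot ranking merges runs above the threshold", {
  w <- data.frame(window_start = seq(1, 2001, 200),
                  window_end = seq(600, 2600, 200))
  w$midpoint <- (w$window_start + w$window_end) %/% 2
  w$pi <- c(0.001, 0.002, 0.02, 0.025, 0.018, 0.001, 0.001, 0.016, 0.002,
            0.001, 0.003)
  w$n_valid_sites <- 600
  hs <- hotspot_rank(w)
  expect_equal(nrow(hs), 2)
  expect_equal(hs$peak_pi, c(0.025, 0.016))
  expect_equal(hs$start[1], w$window_start[3])
  expect_equal(hs$end[1], w$window_end[5])
  ## nothing above threshold
  expect_equal(nrow(hotspot_rank(w, threshold = 0.5)), 0)
  ## zero threshold spans all defined windows
  hs0 <- hotspot_rank(w, threshold = 0)
  expect_equal(nrow(hs0), 1)
  expect_equal(c(hs0$start, hs0$end), c(1, 2600))
})

test_that("a planted fast-evolving spacer surfaces as the top hotspot", {
  cfg <- small_sim_config(seed = 19, rate = 0.004)
  cfg$hotspot <- list(block = "spC", multiplier = 12)
  ds <- simulate_dataset(cfg)
  pw <- pi_sliding(ds$alignment, window = 300, step = 100)
  hs <- hotspot_rank(pw, threshold = 0.01, record = ds$records[[1]])
  expect_gte(nrow(hs), 1)
  ## the top region covers the planted block
  bp <- cfg$blueprint
  blk_start <- cumsum(c(1, bp$len))[which(bp$name == "spC")]
  expect_lte(hs$start[1], blk_start + bp$len[bp$name == "spC"])
  expect_gte(hs$end[1], blk_start)
})

test_that("mean window diversity approaches the Jukes-Cantor expectation", {
  tr <- ape::read.tree(text = "(a:0.01,b:0.01);")
  bp <- data.frame(name = c("sp1", "ir", "sp2"),
                   compartment = c("LSC", "IRb", "SSC"),
                   kind = "spacer", len = c(4000L, 600L, 2000L),
                   stringsAsFactors = FALSE)
  cfg <- sim_config(seed = 77, tree = tr, blueprint = bp,
                    planted_hairpins = list(), planted_ssrs = list())
  ds <- simulate_dataset(cfg)
  pw <- pi_sliding(ds$alignment)
  p_expect <- 0.75 * (1 - exp(-4 * 0.02 / 3))
  n_sites <- sum(pw$n_valid_sites)
  se <- sqrt(p_expect * (1 - p_expect) / n_sites)
  ## IR windows are perfectly correlated copies; compare on the core
  core <- pw[pw$window_end <= 6600, ]
  mean_pi <- sum(core$pi * core$n_valid_sites) / sum(core$n_valid_sites)
  expect_lt(abs(mean_pi - p_expect), 4 * se)
})

test_that("degenerate alignments are rejected", {
  expect_error(pi_sliding(make_alignment("a", strrep("A", 700))),
               "at least 2")
  aln <- make_alignment(c("a", "b"), c(strrep("A", 700), strrep("A", 700)))
  expect_error(pi_sliding(aln, window = 100, step = 200), "window >= step")
})
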