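test_that("newick reading, rooting and round-trip work", {
  tr <- read_newick("((a,b),(c,d));")
  expect_equal(ape::Ntip(tr), 4)
  expect_equal(tr$Nnode, 3)
  ## unrooted input must be rooted on an outgroup
  expect_error(read_newick("(a,b,c,d);"), "unrooted")
  tr2 <- read_newick("(a,b,c,d);", outgroup = "d")
  expect_true(ape::is.rooted(tr2))
  expect_error(read_newick("(a,b,c,d);", outgroup = "zz"), "outgroup")
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, f)
  back <- read_newick(f)
  expect_equal(suppressWarnings(ape::dist.topo(tr, back))[1], 0)
})

test_that("simple four-taxon reconstructions place changes correctly", {
  tr <- read_newick("((w,x),(y,z));")
  ## balanced split: one change on an internal branch
  fit <- fitch_acctran(tr, c(w = "A", x = "A", y = "B", z = "B"))
  expect_equal(fit$parsimony_length, 1L)
  expect_equal(nrow(fit$changes), 1)
  expect_false(fit$changes$branch %in% c("w", "x", "y", "z"))
  ## autapomorphy: one change on the deviant terminal branch
  fit <- fitch_acctran(tr, c(w = "A", x = "A", y = "A", z = "B"))
  expect_equal(fit$parsimony_length, 1L)
  expect_equal(fit$changes$branch, "z")
  expect_equal(fit$changes$from, "A")
  expect_equal(fit$changes$to, "B")
})

test_that("alternating states on a caterpillar reach the exhaustive minimum", {
  tr <- read_newick("(((((((a,b),c),d),e),f),g),h);")
  x <- setNames(rep(c("A", "B"), 4), letters[1:8])
  fit <- fitch_acctran(tr, x)
  expect_equal(fit$parsimony_length, oracle_fitch_length(tr, x))
  expect_equal(nrow(fit$changes), fit$parsimony_length)
})

test_that("parsimony length equals the exhaustive minimum on random trees", {
  set.seed(400)
  for (rep in 1:25) {
    n <- sample(4:12, 1)
    tr <- ape::rtree(n, rooted = TRUE)
    states <- sample(c("A", "B", "?"), n, replace = TRUE,
                     prob = c(0.45, 0.45, 0.1))
    if (!any(states %in% c("A", "B"))) states[1] <- "A"
    x <- setNames(states, tr$tip.label)
    fit <- fitch_acctran(tr, x)
    expect_equal(fit$parsimony_length, oracle_fitch_length(tr, x),
                 info = paste("replicate", rep))
    expect_equal(nrow(fit$changes), fit$parsimony_length)
  }
})

test_that("polytomies are handled natively", {
  tr <- read_newick("((a,b,c),(d,e));")   # internal trichotomy
  expect_equal(tr$Nnode, 3)
  fit <- fitch_acctran(tr, c(a = "A", b = "A", c = "A", d = "B", e = "B"))
  expect_equal(fit$parsimony_length, 1L)
  fit2 <- fitch_acctran(tr, c(a = "B", b = "A", c = "B", d = "A", e = "B"))
  expect_equal(fit2$parsimony_length,
               oracle_fitch_length(tr, c(a = "B", b = "A", c = "B",
                                         d = "A", e = "B")))
})

test_that("state relabelling flips change directions but not the length", {
  set.seed(61)
  tr <- ape::rtree(10, rooted = TRUE)
  x <- setNames(sample(c("A", "B"), 10, replace = TRUE), tr$tip.label)
  y <- chartr("AB", "BA", x)
  f1 <- fitch_acctran(tr, x)
  f2 <- fitch_acctran(tr, y)
  expect_equal(f1$parsimony_length, f2$parsimony_length)
  expect_equal(sum(f1$changes$from == "A"), sum(f2$changes$from == "B"))
})

test_that("bad characters are rejected", {
  tr <- read_newick("((a,b),(c,d));")
  expect_error(fitch_acctran(tr, c(a = "A", zz = "B")), "absent from tree")
  expect_error(fitch_acctran(tr, c(a = "?", b = "?")), "no non-missing")
  expect_error(fitch_acctran(tr, c(a = "A", b = "X")), "states must be")
})

test_that("character classification splits invariant/autapomorphic/synapomorphic", {
  tr <- read_newick("((a,b),(c,d));")
  m <- matrix("A", 4, 2, dimnames = list(letters[1:4], c("c1", "c2")))
  cm <- classify_characters(tr, m)
  expect_true(all(cm$per_character$status == "invariant"))
  expect_true(all(cm$per_character$parsimony_length == 0))
  expect_true(all(is.na(cm$synapomorphic_change_range)))

  m2 <- cbind(c1 = c(a = "A", b = "A", c = "A", d = "B"),
              c2 = c(a = "A", b = "A", c = "B", d = "B"))
  cm2 <- classify_characters(tr, m2)
  expect_equal(cm2$per_character$status, c("autapomorphic", "synapomorphic"))
  expect_equal(cm2$per_character$parsimony_length, c(1L, 1L))
  expect_equal(cm2$synapomorphic_change_range, c(1L, 1L))
})

test_that("catalog SI characters map as published on any containing tree", {
  m <- si_catalog_matrix()
  set.seed(99)
  tr <- ape::rtree(20, rooted = TRUE)
  tr$tip.label <- sample(rownames(m))
  cm <- classify_characters(tr, m)
  ## loci 3, 4, 5, 8 and 9 are single-minority-taxon characters
  auta <- cm$per_character$character[cm$per_character$status == "autapomorphic"]
  expect_setequal(auta, paste0("si", c(3, 4, 5, 8, 9)))
  ## autapomorphies always map with a single change, on any topology
  expect_true(all(cm$per_character$parsimony_length[
    cm$per_character$status == "autapomorphic"] == 1L))
})
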