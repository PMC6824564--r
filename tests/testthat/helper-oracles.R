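## Independent brute-force oracles used to validate the scan kernels and the
## parsimony mapper.  These are deliberately written in plain R, from the
## operation definitions, and share no code with the implementation.

rnd_dna <- function(n, freqs = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)) {
  paste(sample(names(freqs), n, replace = TRUE, prob = freqs), collapse = "")
}

## exhaustive hairpin enumeration: every (loop start, loop length) candidate,
## greedy outward arm extension under the mismatch budget, trailing
## mismatches trimmed, inward-extendable candidates dropped, then the same
## conflicting-fold suppression rule applied pairwise
oracle_find_hairpins <- function(seq, min_stem = 8, max_stem = 40,
                                 min_loop = 4, max_loop = 30,
                                 max_mismatch = 0) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  comp1 <- c(A = "T", C = "G", G = "C", T = "A")
  is_pair <- function(a, b) a %in% names(comp1) && unname(comp1[a]) == b
  cand <- list()
  for (l in 2:max(2, n)) {
    for (L in min_loop:max_loop) {
      le <- l + L - 1
      if (le + 1 > n || l > n) next
      i <- l - 1; j <- le + 1; flags <- logical(0)
      while (length(flags) < max_stem && i >= 1 && j <= n) {
        if (is_pair(ch[i], ch[j])) {
          flags <- c(flags, TRUE)
        } else if (sum(!flags) < max_mismatch &&
                   ch[i] %in% names(comp1) && ch[j] %in% names(comp1)) {
          flags <- c(flags, FALSE)
        } else break
        i <- i - 1; j <- j + 1
      }
      while (length(flags) && !flags[length(flags)])
        flags <- flags[-length(flags)]
      k <- length(flags)
      if (k < min_stem) next
      if (L - 2 >= min_loop && is_pair(ch[l], ch[le])) next
      cand[[length(cand) + 1L]] <- data.frame(
        genome_start = l - k, genome_end = le + k, stem_len = k,
        loop_start = l, loop_end = le,
        mismatches_in_stem = sum(!flags))
    }
  }
  if (!length(cand))
    return(data.frame(genome_start = integer(0), genome_end = integer(0),
                      stem_len = integer(0), loop_start = integer(0),
                      loop_end = integer(0), mismatches_in_stem = integer(0)))
  h <- do.call(rbind, cand)
  ord <- order(-h$stem_len, h$loop_end - h$loop_start, h$genome_start,
               h$loop_start)
  h <- h[ord, , drop = FALSE]
  acc <- integer(0)
  ok_both <- function(i, j) {
    h$genome_end[i] < h$genome_start[j] ||
      h$genome_end[j] < h$genome_start[i] ||
      (h$genome_start[i] >= h$loop_start[j] && h$genome_end[i] <= h$loop_end[j]) ||
      (h$genome_start[j] >= h$loop_start[i] && h$genome_end[j] <= h$loop_end[i])
  }
  keep <- logical(nrow(h))
  for (i in seq_len(nrow(h))) {
    good <- TRUE
    for (j in acc) if (!ok_both(i, j)) { good <- FALSE; break }
    if (good) { keep[i] <- TRUE; acc <- c(acc, i) }
  }
  h <- h[keep, , drop = FALSE]
  h <- h[order(h$genome_start, h$loop_start), , drop = FALSE]
  rownames(h) <- NULL
  h
}

## exhaustive SSR enumeration over every (start, unit length) pair
oracle_scan_ssrs <- function(seq, thr = c(10, 5, 4, 3, 2)) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  loci <- list()
  for (u in seq_along(thr)) {
    a <- 1L
    for (a in seq_len(max(n - u + 1L, 0L))) {
      unit <- substr(seq, a, a + u - 1L)
      if (grepl("[^ACGT]", unit)) next
      prim <- TRUE
      for (d in seq_len(u - 1L))
        if (u %% d == 0L && strrep(substr(unit, 1L, d), u %/% d) == unit)
          prim <- FALSE
      if (!prim) next
      cp <- 1L
      while (a + (cp + 1L) * u - 1L <= n &&
             substr(seq, a + cp * u, a + (cp + 1L) * u - 1L) == unit)
        cp <- cp + 1L
      if (cp < thr[u]) next
      if (a > 1L && ch[a - 1L] == ch[a - 1L + u]) next   # not run-leftmost
      loci[[length(loci) + 1L]] <- data.frame(
        start = a, end = a + cp * u - 1L, unit_len = u, copies = cp,
        unit = unit, stringsAsFactors = FALSE)
    }
  }
  if (!length(loci))
    return(data.frame(start = integer(0), end = integer(0),
                      unit_len = integer(0), copies = integer(0),
                      unit = character(0)))
  out <- do.call(rbind, loci)
  out <- out[order(out$start, out$unit_len), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## exact minimum parsimony length by bit-parallel enumeration of all
## internal-node state assignments (binary character, missing tips free)
oracle_fitch_length <- function(tree, x) {
  nt <- length(tree$tip.label)
  K <- tree$Nnode
  idx <- 0:(2^K - 1)
  bit <- function(node) (idx %/% 2^(node - nt - 1L)) %% 2
  s <- setNames(rep(NA_integer_, nt), tree$tip.label)
  s[names(x)[x == "A"]] <- 0L
  s[names(x)[x == "B"]] <- 1L
  total <- rep(0, length(idx))
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]; k <- tree$edge[e, 2L]
    bp <- bit(p)
    if (k <= nt) {
      if (!is.na(s[k])) total <- total + abs(bp - s[k])
    } else total <- total + abs(bp - bit(k))
  }
  min(total)
}

## Nei's average pairwise diversity over one window, by direct double loop
oracle_pi <- function(rows, a, b) {
  n <- length(rows)
  M <- do.call(rbind, strsplit(substr(rows, a, b), "", fixed = TRUE))
  valid <- apply(M, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  m <- sum(valid)
  if (m == 0) return(NA_real_)
  tot <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    tot <- tot + sum(M[i, valid] != M[j, valid])
  tot / (n * (n - 1) / 2) / m
}
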