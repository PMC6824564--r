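## char_evolution: Fitch parsimony mapping of binary characters on a rooted
## tree, with deterministic ACCTRAN-style change placement (on ties, a
## change is taken on the most rootward admissible branch).

#' Read a newick tree, optionally rooting on an outgroup
#'
#' @param path newick file (or a newick string).
#' @param outgroup optional taxon label; unrooted input must provide one.
#' @return rooted \code{ape::phylo}.
#' @export
read_newick <- function(path, outgroup = NULL) {
  tr <- if (file.exists(path)) ape::read.tree(path) else ape::read.tree(text = path)
  if (is.null(tr)) stop("unparseable newick in ", path)
  if (!is.null(outgroup)) {
    if (!outgroup %in% tr$tip.label)
      stop("outgroup label not in tree: ", outgroup)
    tr <- ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
  }
  if (!ape::is.rooted(tr))
    stop("tree is unrooted; supply an outgroup label")
  tr
}

#' Write a tree to newick
#' @param tree \code{ape::phylo}.
#' @param path output file.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

## human-readable branch id: the branch above `node`
branch_id <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  if (!is.null(tree$node.label) && nzchar(tree$node.label[node - ntip]))
    return(tree$node.label[node - ntip])
  paste0("node", node)
}

#' Fitch parsimony with ACCTRAN-style change placement
#'
#' Bottom-up dynamic programming over states \code{{A, B}} (missing
#' \code{"?"} states are unrestricted) computes the minimum number of state
#' changes; the top-down pass assigns ancestral states, breaking ties in
#' favour of a change on the current (most rootward admissible) branch.
#' Polytomies are handled natively; with tied root states \code{"A"} wins
#' (deterministic output).
#'
#' @param tree rooted \code{ape::phylo}.
#' @param character named character vector (taxon -> \code{"A"},
#'   \code{"B"} or \code{"?"}); every named taxon must be in the tree, and
#'   at least one state must be non-missing.
#' @return list with \code{parsimony_length}, \code{changes} (data frame
#'   \code{branch, from, to}; branch = name of the node below the branch)
#'   and \code{node_states} (reconstructed state per node).
#' @export
fitch_acctran <- function(tree, character) {
  stopifnot(inherits(tree, "phylo"))
  states <- c("A", "B")
  tips <- tree$tip.label
  extra <- setdiff(names(character), tips)
  if (length(extra))
    stop("taxa in character absent from tree: ", paste(extra, collapse = ", "))
  x <- setNames(rep("?", length(tips)), tips)
  x[names(character)] <- as.character(character)
  if (!any(x %in% states)) stop("character has no non-missing states")
  if (!all(x %in% c(states, "?")))
    stop("states must be in {A, B, ?}")

  ntip <- length(tips)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  tre <- ape::reorder.phylo(tree, "postorder")
  E <- tre$edge
  INF <- .Machine$integer.max %/% 4L
  cost <- matrix(0L, nrow = nnode, ncol = 2L)
  for (i in seq_len(ntip)) {
    if (x[i] == "A") cost[i, 2L] <- INF
    if (x[i] == "B") cost[i, 1L] <- INF
  }
  for (e in seq_len(nrow(E))) {
    par <- E[e, 1L]; ch <- E[e, 2L]
    for (s in 1:2) {
      inc <- min(cost[ch, s], cost[ch, 3L - s] + 1L)
      cost[par, s] <- cost[par, s] + inc
    }
  }
  plen <- min(cost[root, ])

  ## top-down assignment, preorder; prefer a change on ties (ACCTRAN)
  assign_state <- integer(nnode)
  rs <- which(cost[root, ] == plen)
  assign_state[root] <- rs[1]             # "A" on ties
  Epre <- tree$edge[order(tree$edge[, 1L]), , drop = FALSE]
  ## children listing per parent, processed root-outward
  kids <- split(Epre[, 2L], Epre[, 1L])
  queue <- root
  changes <- list()
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    ps <- assign_state[v]
    for (ch in kids[[as.character(v)]]) {
      keep <- cost[ch, ps]
      move <- cost[ch, 3L - ps] + 1L
      cs <- if (move <= keep) 3L - ps else ps   # tie -> change here
      assign_state[ch] <- cs
      if (cs != ps)
        changes[[length(changes) + 1L]] <-
          data.frame(branch = branch_id(tree, ch), from = states[ps],
                     to = states[cs], stringsAsFactors = FALSE)
      if (ch > ntip) queue <- c(queue, ch)
    }
  }
  changes <- if (length(changes)) do.call(rbind, changes)
             else data.frame(branch = character(0), from = character(0),
                             to = character(0))
  stopifnot(nrow(changes) == plen)
  node_states <- setNames(states[assign_state],
                          vapply(seq_len(nnode), function(v)
                            branch_id(tree, v), character(1)))
  list(parsimony_length = as.integer(plen), changes = changes,
       node_states = node_states)
}

#' Map a character matrix on a tree and classify each character
#'
#' Runs \code{\link{fitch_acctran}} per character and classifies each one
#' from its observed states: \code{invariant} (one state only),
#' \code{autapomorphic} (exactly one taxon carries the minority state) or
#' \code{synapomorphic} (otherwise).
#'
#' @param tree rooted \code{ape::phylo}.
#' @param matrix character matrix taxa x characters with entries \code{"A"},
#'   \code{"B"}, \code{"?"} (e.g. \code{\link{si_matrix}} output).
#' @return list with \code{per_character} data frame (\code{character,
#'   status, parsimony_length, n_a_to_b, n_b_to_a}), \code{changes} (long
#'   data frame of all placed changes) and \code{synapomorphic_change_range}
#'   (min/max change count over synapomorphic characters, \code{NA} if
#'   none).
#' @export
classify_characters <- function(tree, matrix) {
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)))
  chars <- colnames(matrix)
  if (is.null(chars)) chars <- paste0("char", seq_len(ncol(matrix)))
  rows <- list(); all_changes <- list()
  for (j in seq_len(ncol(matrix))) {
    v <- matrix[, j]
    obs <- v[v %in% c("A", "B")]
    status <- if (length(unique(obs)) <= 1L) "invariant" else {
      tb <- sort(table(obs))
      if (tb[1] == 1L) "autapomorphic" else "synapomorphic"
    }
    if (status == "invariant") {
      plen <- 0L; n_ab <- 0L; n_ba <- 0L
    } else {
      fit <- fitch_acctran(tree, v)
      plen <- fit$parsimony_length
      n_ab <- sum(fit$changes$from == "A" & fit$changes$to == "B")
      n_ba <- sum(fit$changes$from == "B" & fit$changes$to == "A")
      if (nrow(fit$changes)) {
        fit$changes$character <- chars[j]
        all_changes[[length(all_changes) + 1L]] <- fit$changes
      }
    }
    rows[[j]] <- data.frame(character = chars[j], status = status,
                            parsimony_length = plen, n_a_to_b = n_ab,
                            n_b_to_a = n_ba, stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, rows)
  syn <- per$parsimony_length[per$status == "synapomorphic"]
  list(per_character = per,
       changes = if (length(all_changes)) do.call(rbind, all_changes)
                 else data.frame(branch = character(0), from = character(0),
                                 to = character(0), character = character(0)),
       synapomorphic_change_range = if (length(syn)) range(syn)
                                    else c(NA_integer_, NA_integer_))
}
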