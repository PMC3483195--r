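# Independent oracles and generators used across the suite. These are kept
# deliberately naive (enumeration, brute force) and share no code with the
# package implementations they check.

# All rooted binary leaf-labeled topologies on the given labels, built by
# inserting each new leaf on every edge (including above the root).
allRootedTrees <- function(labels) {
  if (length(labels) == 1L) return(labels)
  if (length(labels) == 2L) return(sprintf("(%s,%s)", labels[1], labels[2]))
  prev <- allRootedTrees(labels[-length(labels)])
  leaf <- labels[length(labels)]
  out <- character(0)
  for (t in prev) {
    # insert on every edge: replace each subtree occurrence once
    spots <- subtreeSpans(t)
    for (s in spots)
      out <- c(out, paste0(substr(t, 1, s[1] - 1), "(",
                           substr(t, s[1], s[2]), ",", leaf, ")",
                           substr(t, s[2] + 1, nchar(t))))
    out <- c(out, sprintf("(%s,%s)", t, leaf))   # above the old root
  }
  out
}

# character spans [start, end] of every proper subtree in a newick-like
# string without lengths: every balanced "(...)" group and every leaf label
subtreeSpans <- function(t) {
  ch <- strsplit(t, "")[[1]]
  spans <- list()
  # parenthesized groups
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (j > 1) spans[[length(spans) + 1L]] <- c(j, i)  # skip whole tree
    }
  }
  # leaf labels
  i <- 1L
  while (i <= length(ch)) {
    if (!ch[i] %in% c("(", ")", ",")) {
      j <- i
      while (j < length(ch) && !ch[j + 1L] %in% c("(", ")", ",")) j <- j + 1L
      spans[[length(spans) + 1L]] <- c(i, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  spans
}

# random rooted binary tree with branch lengths, as phylo
randomTree <- function(n, lengths = TRUE) {
  tr <- ape::rtree(n, br = if (lengths) stats::runif else NULL)
  tr$tip.label <- sprintf("t%02d", seq_len(n))
  tr
}

# Brute-force Dollo oracle: minimal loss count over all single-gain
# placements for a presence set, plus the attained birth node(s).
dolloOracle <- function(tree, present) {
  stopifnot(length(present) >= 1L)
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  tu <- lapply(seq_len(nn), function(v)
    if (v <= ntip) tree$tip.label[v] else
      ape::extract.clade(tree, v)$tip.label)
  kid <- vector("list", nn)
  for (i in seq_len(nrow(tree$edge)))
    kid[[tree$edge[i, 1]]] <- c(kid[[tree$edge[i, 1]]], tree$edge[i, 2])
  lossCount <- function(v) {          # minimal losses with gain above v
    if (!any(present %in% tu[[v]])) return(Inf)
    count <- 0L
    recurse <- function(u) {
      for (k in kid[[u]]) {
        if (!any(present %in% tu[[k]])) count <<- count + 1L
        else recurse(k)
      }
    }
    recurse(v)
    count
  }
  feasible <- which(vapply(seq_len(nn), function(v)
    all(present %in% tu[[v]]), TRUE))
  costs <- vapply(feasible, lossCount, 0)
  list(min_losses = min(costs),
       best_nodes = feasible[costs == min(costs)])
}

# Brute-force duplication-loss reconciliation: minimum cost over all valid
# mappings of gene-tree internal nodes to species-tree nodes.
reconcileOracle <- function(gt, speciesMap, st) {
  ntipS <- ape::Ntip(st)
  nnS <- ntipS + st$Nnode
  parS <- integer(nnS); parS[st$edge[, 2]] <- st$edge[, 1]
  depthS <- integer(nnS)
  for (i in rev(ape::postorder(st)))
    depthS[st$edge[i, 2]] <- depthS[st$edge[i, 1]] + 1L
  anc <- function(v) { out <- v; while (parS[v] != 0) { v <- parS[v]; out <- c(out, v) }; out }
  lcaS <- function(u, v) { au <- anc(u); for (w in anc(v)) if (w %in% au) return(w); NA }
  childS <- vector("list", nnS)
  for (i in seq_len(nrow(st$edge)))
    childS[[st$edge[i, 1]]] <- c(childS[[st$edge[i, 1]]], st$edge[i, 2])
  sameChildSubtree <- function(g, a, b) {
    # are species nodes a and b inside the same child subtree of g?
    for (k in childS[[g]])
      if ((k %in% anc(a)) && (k %in% anc(b))) return(TRUE)
    FALSE
  }
  ntipG <- ape::Ntip(gt)
  nnG <- ntipG + gt$Nnode
  kidG <- vector("list", nnG)
  for (i in seq_len(nrow(gt$edge)))
    kidG[[gt$edge[i, 1]]] <- c(kidG[[gt$edge[i, 1]]], gt$edge[i, 2])
  post <- c(gt$edge[ape::postorder(gt), 2], ntipG + 1L)
  internals <- post[post > ntipG]
  Mleaf <- integer(nnG)
  Mleaf[seq_len(ntipG)] <- match(speciesMap[gt$tip.label], st$tip.label)
  best <- Inf
  assign_next <- function(idx, M) {
    if (idx > length(internals)) {
      cost <- 0L
      for (g in internals) {
        cs <- kidG[[g]]
        dup <- (M[g] == M[cs[1]]) || (M[g] == M[cs[2]]) ||
               sameChildSubtree(M[g], M[cs[1]], M[cs[2]])
        cost <- cost + as.integer(dup)
        for (c in cs) {
          d <- depthS[M[c]] - depthS[M[g]]
          cost <- cost + (if (dup) d else d - 1L)
        }
        if (cost >= best) return(invisible(NULL))
      }
      best <<- min(best, cost)
      return(invisible(NULL))
    }
    g <- internals[idx]
    cs <- kidG[[g]]
    l <- lcaS(M[cs[1]], M[cs[2]])
    for (cand in anc(l)) {     # ancestor-or-equal of the children's LCA
      M[g] <- cand
      assign_next(idx + 1L, M)
    }
  }
  assign_next(1L, Mleaf)
  best
}

# exhaustive hypergeometric tail by enumerating all draws of size n from N
hyperOracle <- function(k, n, K, N) {
  draws <- utils::combn(N, n)
  ann <- seq_len(K)                     # first K items annotated
  hits <- apply(draws, 2, function(d) sum(d %in% ann))
  c(p_enriched = mean(hits >= k), p_depleted = mean(hits <= k))
}

# independent dense-matrix MCL (no pruning, plain loop) for cross-checking
mclOracle <- function(edges, inflation = 2, iters = 200) {
  nodes <- sort(unique(c(edges$from, edges$to)))
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  A[cbind(edges$from, edges$to)] <- edges$weight
  A[cbind(edges$to, edges$from)] <- edges$weight
  diag(A) <- pmax(apply(A, 1, max), 1e-12)
  A <- sweep(A, 2, colSums(A), "/")
  for (i in seq_len(iters)) {
    A2 <- A %*% A
    A2 <- A2^inflation
    A2 <- sweep(A2, 2, colSums(A2), "/")
    if (max(abs(A2 - A)) < 1e-10) { A <- A2; break }
    A <- A2
  }
  memb <- igraph::components(igraph::graph_from_adjacency_matrix(
    (A > 1e-6) | t(A > 1e-6), mode = "undirected"))$membership
  split(nodes, memb)
}

# ---- bitmask Dollo oracle (fast enough for full small-tree sweeps) ------

# per-node tip bitmask; bit j-1 stands for the j-th label in sorted order
tipsUnderMasks <- function(tr) {
  labels <- sort(tr$tip.label)
  ntip <- ape::Ntip(tr)
  nn <- ntip + tr$Nnode
  m <- integer(nn)
  m[seq_len(ntip)] <- 2L^(match(tr$tip.label, labels) - 1L)
  for (i in ape::postorder(tr))
    m[tr$edge[i, 1]] <- bitwOr(m[tr$edge[i, 1]], m[tr$edge[i, 2]])
  m
}

maskTips <- function(tr, tu, v) {
  labels <- sort(tr$tip.label)
  labels[bitwAnd(tu[v], 2L^(seq_along(labels) - 1L)) > 0]
}

# exhaustive single-gain minimization over all feasible birth nodes
dolloBitOracle <- function(tr, tu, code) {
  nn <- length(tu)
  kid <- vector("list", nn)
  for (i in seq_len(nrow(tr$edge)))
    kid[[tr$edge[i, 1]]] <- c(kid[[tr$edge[i, 1]]], tr$edge[i, 2])
  lossCount <- function(v) {
    total <- 0L
    for (k in kid[[v]]) {
      if (bitwAnd(tu[k], code) == 0L) total <- total + 1L
      else total <- total + lossCount(k)
    }
    total
  }
  feasible <- which(bitwAnd(tu, code) == code)
  costs <- vapply(feasible, lossCount, 0L)
  list(min_losses = min(costs), best_nodes = feasible[costs == min(costs)])
}
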