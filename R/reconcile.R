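# Gene-tree / species-tree reconciliation by LCA mapping, minimum
# duplication+loss rooting of unrooted gene trees, and aggregation of
# per-branch duplication/deletion counts across families.

# Species-tree context reused across many gene trees.
speciesContext <- function(st) {
  ntip <- ape::Ntip(st)
  list(st = st, ntip = ntip, root = ntip + 1L,
       par = nodeParents(st), depth = nodeDepths(st),
       children = nodeChildren(st),
       tipindex = setNames(seq_len(ntip), st$tip.label),
       nnode = ntip + st$Nnode)
}

stLcaPair <- function(ctx, u, v) {
  while (u != v) {
    if (ctx$depth[u] >= ctx$depth[v]) u <- ctx$par[u] else v <- ctx$par[v]
  }
  u
}

stSibling <- function(ctx, v) {
  p <- ctx$par[v]
  if (p == 0L) return(0L)
  setdiff(ctx$children[[p]], v)[1]
}

#' Reconcile a rooted gene tree with the species tree
#'
#' LCA mapping: each gene leaf maps to its species; each internal gene node
#' maps to the species-tree LCA of its children's images. A node is a
#' duplication when it maps to the same species node as one of its children.
#' Losses along a child edge are the species branches skipped by the path
#' from the node's image to the child's image; a duplication contributes one
#' extra loss (the unsampled sister at its own image). This mapping attains
#' the minimum duplication+loss cost over all reconciliations.
#'
#' @param gt Rooted binary `phylo` gene tree, leaves labeled by protein ID.
#' @param speciesMap Named character vector, protein ID -> species (a leaf
#'   label of the species tree).
#' @param st Rooted binary `phylo` species tree (or a context from
#'   `speciesContext`, used internally).
#' @return List with `dup` and `loss` (named integer vectors over species
#'   branches, canonical names; the species-root name stands for the virtual
#'   branch above the root), `n_dup`, `n_loss`, `cost`, and `mapping`
#'   (species node per gene node).
#' @export
reconcile <- function(gt, speciesMap, st) {
  ctx <- if (is.list(st) && !inherits(st, "phylo")) st else speciesContext(st)
  ngt <- ape::Ntip(gt)
  sp <- speciesMap[gt$tip.label]
  if (anyNA(sp)) stop("gene-tree leaf (leaves) missing from species map: ",
                      paste(gt$tip.label[is.na(sp)], collapse = ", "))
  bad <- setdiff(sp, names(ctx$tipindex))
  if (length(bad)) stop("species not in species tree: ", paste(bad, collapse = ", "))
  nn <- ngt + gt$Nnode
  M <- integer(nn)
  M[seq_len(ngt)] <- ctx$tipindex[sp]
  kids <- nodeChildren(gt)
  dup_at <- integer(ctx$nnode)
  loss_at <- integer(ctx$nnode)
  ord <- unique(tree_postorder_nodes(gt))
  for (g in ord) {
    cs <- kids[[g]]
    if (length(cs) == 0L) next
    if (length(cs) != 2L) stop("gene tree must be binary")
    m <- stLcaPair(ctx, M[cs[1]], M[cs[2]])
    M[g] <- m
    is_dup <- (m == M[cs[1]]) || (m == M[cs[2]])
    if (is_dup) dup_at[m] <- dup_at[m] + 1L
    for (c in cs) {
      chain <- integer(0)               # path below m, bottom-up
      w <- M[c]
      while (w != m) { chain <- c(chain, w); w <- ctx$par[w] }
      k <- length(chain)
      if (k == 0L) next
      # siblings of all chain nodes are lost, except the topmost one's
      # sibling which survives through the speciation at m (unless dup)
      take <- if (is_dup) seq_len(k) else seq_len(k - 1L)
      for (i in take) {
        s <- stSibling(ctx, chain[i])
        loss_at[s] <- loss_at[s] + 1L
      }
    }
  }
  nm <- canonicalNodeName(ctx$st, seq_len(ctx$nnode))
  list(dup = setNames(dup_at, nm), loss = setNames(loss_at, nm),
       n_dup = sum(dup_at), n_loss = sum(loss_at),
       cost = sum(dup_at) + sum(loss_at), mapping = M)
}

# postorder node sequence (children before parents) for any rooted phylo
tree_postorder_nodes <- function(phy) {
  ord <- ape::postorder(phy)
  c(phy$edge[ord, 2], ape::Ntip(phy) + 1L)
}

#' Root an unrooted gene tree by minimum duplication+loss cost
#'
#' Evaluates the LCA reconciliation for the rooting on every edge of the
#' unrooted gene tree and returns the rooting of minimum duplication+loss
#' cost. Ties are broken by fewer duplications, then by the smallest
#' canonical edge label (the lexicographically smaller of the two sorted
#' leaf-set strings of the edge's bipartition).
#'
#' @param gt Unrooted `phylo` gene tree (>= 3 leaves).
#' @param speciesMap Named character vector, protein ID -> species.
#' @param st Rooted binary `phylo` species tree.
#' @return List with `tree` (rooted `phylo`), `reconciliation` (as from
#'   [reconcile()]), `edge_label` of the chosen rooting, and `costs` (cost
#'   per candidate edge, named by edge label).
#' @export
rootByMinCost <- function(gt, speciesMap, st) {
  stopifnot(ape::Ntip(gt) >= 3L)
  ctx <- speciesContext(st)
  work <- gt
  work$edge.length <- rep(1, nrow(work$edge))
  tu <- tipsUnder(work)
  all_tips <- sort(work$tip.label)
  labels <- vapply(seq_len(nrow(work$edge)), function(e) {
    below <- tu[[work$edge[e, 2]]]
    above <- setdiff(all_tips, below)
    min(paste(below, collapse = ","), paste(above, collapse = ","))
  }, character(1))
  best <- NULL
  costs <- setNames(numeric(nrow(work$edge)), labels)
  for (e in seq_len(nrow(work$edge))) {
    rooted <- phytools::reroot(work, work$edge[e, 2], position = 0.5)
    rec <- reconcile(rooted, speciesMap, ctx)
    costs[e] <- rec$cost
    cand <- list(tree = rooted, reconciliation = rec, edge_label = labels[e])
    if (is.null(best) ||
        rec$cost < best$reconciliation$cost ||
        (rec$cost == best$reconciliation$cost &&
         rec$n_dup < best$reconciliation$n_dup) ||
        (rec$cost == best$reconciliation$cost &&
         rec$n_dup == best$reconciliation$n_dup &&
         labels[e] < best$edge_label))
      best <- cand
  }
  best$costs <- costs
  best
}

#' Aggregate reconciliation results per species branch
#'
#' Gene trees larger than `size_cap` leaves are excluded (and reported);
#' duplication and loss counts of the rest are summed per species branch.
#'
#' @param results Named list of [reconcile()] results (names = family IDs).
#' @param sizes Integer vector of gene-tree leaf counts, parallel to
#'   `results`.
#' @param st Rooted species `phylo` tree.
#' @param size_cap Exclusion threshold (default 1000): trees with more
#'   leaves than this are dropped.
#' @return Data.frame `lineage`, `dup`, `del` (one row per species branch
#'   plus the root row); attribute `excluded` lists dropped family IDs.
#' @export
aggregateReconciliations <- function(results, sizes, st, size_cap = 1000L) {
  ctx <- speciesContext(st)
  nm <- canonicalNodeName(st, seq_len(ctx$nnode))
  keep <- sizes <= size_cap
  excluded <- names(results)[!keep]
  dup <- setNames(integer(length(nm)), nm)
  del <- setNames(integer(length(nm)), nm)
  for (r in results[keep]) {
    dup[names(r$dup)] <- dup[names(r$dup)] + r$dup
    del[names(r$loss)] <- del[names(r$loss)] + r$loss
  }
  out <- data.frame(lineage = nm, dup = as.integer(dup), del = as.integer(del),
                    stringsAsFactors = FALSE)
  attr(out, "excluded") <- excluded
  out
}
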