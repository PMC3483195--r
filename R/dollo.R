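# Dollo parsimony on presence/absence characters: each character (protein
# family or domain) is gained exactly once, on the branch above the LCA of
# the taxa carrying it, and lost on the branches into the maximal subtrees of
# the birth clade containing no carrier. This minimizes losses for any
# single-gain scenario.

#' Build a presence/absence matrix
#'
#' @param pairs data.frame with columns `character` (family or domain ID) and
#'   `species`; one row per observed (character, species) occurrence.
#' @param taxa Character vector of all taxa (species-tree leaves); columns of
#'   the result, in this order.
#' @return Binary integer matrix, characters x taxa. Characters present in no
#'   taxon are an error.
#' @export
presenceMatrix <- function(pairs, taxa) {
  stopifnot(all(c("character", "species") %in% names(pairs)))
  unknown <- setdiff(unique(pairs$species), taxa)
  if (length(unknown)) stop("unknown taxa: ", paste(unknown, collapse = ", "))
  chars <- sort(unique(pairs$character))
  if (length(chars) == 0L)
    return(matrix(0L, 0, length(taxa), dimnames = list(NULL, taxa)))
  P <- matrix(0L, length(chars), length(taxa), dimnames = list(chars, taxa))
  P[cbind(match(pairs$character, chars), match(pairs$species, taxa))] <- 1L
  if (any(rowSums(P) == 0)) stop("character present in no taxon")
  P
}

#' Dollo reconstruction of one character
#'
#' @param present Character vector of taxa carrying the character, or a
#'   named binary vector over the tree's leaves.
#' @param tree Rooted binary `phylo` tree.
#' @return List with `birth_node` (node below the birth branch; the root
#'   means the character predates the tree and its birth sits on the virtual
#'   root branch), `birth_is_root`, and `loss_nodes` (child nodes of the loss
#'   branches).
#' @export
dolloReconstruct <- function(present, tree) {
  if (!is.null(names(present)) && all(present %in% c(0, 1)))
    present <- names(present)[present == 1]
  if (length(present) == 0L) stop("all-absent character: no Dollo birth exists")
  birth <- treeLca(tree, present)
  root <- ape::Ntip(tree) + 1L
  ch <- nodeChildren(tree)
  tu <- tipsUnder(tree)
  losses <- integer(0)
  recurse <- function(v) {
    for (c in ch[[v]]) {
      if (!any(tu[[c]] %in% present)) losses <<- c(losses, c)
      else recurse(c)
    }
  }
  recurse(birth)
  list(birth_node = birth, birth_is_root = identical(birth, root),
       loss_nodes = losses)
}

#' Count Dollo birth/death events per branch
#'
#' Runs the single-character reconstruction over every row of a presence
#' matrix and sums births and deaths per species-tree branch. Characters
#' whose birth falls on the virtual root branch are tallied against the root
#' row (which has no branch length and is excluded from rates).
#'
#' @param P Binary presence matrix (characters x taxa), taxa matching the
#'   tree's leaves.
#' @param tree Rooted binary `phylo` tree.
#' @return A data.frame with one row per branch plus the root row: `lineage`
#'   (canonical name), `node`, `length` (NA for the root), `birth`, `death`.
#'   Attribute `birth_node` maps each character to its birth node.
#' @export
countDolloEvents <- function(P, tree) {
  stopifnot(is.matrix(P))
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  root <- ntip + 1L
  taxa <- colnames(P)
  if (!setequal(taxa, tree$tip.label))
    stop("presence-matrix taxa do not match tree leaves")
  tu <- tipsUnder(tree)
  # incidence: node x tip (tips in P column order)
  Z <- matrix(0L, nn, ncol(P))
  for (v in seq_len(nn)) Z[v, match(tu[[v]], taxa)] <- 1L
  counts <- Z %*% t(P)                      # node x character carrier counts
  total <- rowSums(P)
  subtree_size <- rowSums(Z)
  # birth node: smallest subtree containing all carriers
  birth <- vapply(seq_len(nrow(P)), function(k) {
    cand <- which(counts[, k] == total[k])
    cand[which.min(subtree_size[cand])]
  }, 0L)
  par <- nodeParents(tree)
  depth <- nodeDepths(tree)
  # ancestor test via depth walk is cheap at species-tree size
  anc_of <- function(a, v) { while (v != 0 && v != a) v <- par[v]; v == a }
  births_per_node <- tabulate(birth, nbins = nn)
  deaths_per_node <- integer(nn)
  for (k in seq_len(nrow(P))) {
    b <- birth[k]
    if (total[k] == subtree_size[b]) next   # no absence inside birth clade
    e_loss <- which(counts[tree$edge[, 2], k] == 0 &
                    counts[tree$edge[, 1], k] > 0)
    for (e in e_loss) {
      p <- tree$edge[e, 1]
      if (p == b || anc_of(b, p))
        deaths_per_node[tree$edge[e, 2]] <- deaths_per_node[tree$edge[e, 2]] + 1L
    }
  }
  bt <- branchTable(tree)
  out <- rbind(
    data.frame(lineage = canonicalNodeName(tree, root), node = root,
               length = NA_real_, stringsAsFactors = FALSE),
    bt[, c("lineage", "node", "length")])
  out$birth <- births_per_node[out$node]
  out$death <- deaths_per_node[out$node]
  rownames(out) <- NULL
  attr(out, "birth_node") <- setNames(birth, rownames(P))
  out
}

#' Classify families (or domains) by taxonomic distribution
#'
#' Categories follow the published scheme: `universal` (present in all taxa),
#' `clade_specific_single_species` (confined to one clade, one species),
#' `clade_specific_shared` (confined to one clade, two or more species), and
#' `other`.
#'
#' @param P Binary presence matrix (characters x taxa).
#' @param clades Named character vector mapping taxa to clades (taxa absent
#'   from the map, e.g. outgroups, belong to no clade); defaults to
#'   [metazoanClades()].
#' @return Factor of categories, one per matrix row.
#' @export
classifyFamilies <- function(P, clades = metazoanClades()) {
  lv <- c("universal", "clade_specific_single_species",
          "clade_specific_shared", "other")
  cl <- clades[colnames(P)]
  res <- apply(P, 1, function(row) {
    present <- colnames(P)[row == 1]
    if (length(present) == ncol(P)) return("universal")
    pc <- unique(cl[match(present, colnames(P))])
    if (length(pc) == 1L && !is.na(pc))
      return(if (length(present) == 1L) "clade_specific_single_species"
             else "clade_specific_shared")
    "other"
  })
  factor(res, levels = lv)
}

#' Unique losses per species
#'
#' A character contributes a unique loss to species s when it is present in
#' every other taxon and absent only from s.
#'
#' @param P Binary presence matrix (characters x taxa).
#' @return Named integer vector of counts per taxon.
#' @export
uniqueLosses <- function(P) {
  one_zero <- rowSums(P) == ncol(P) - 1L
  counts <- colSums((1L - P[one_zero, , drop = FALSE]))
  setNames(as.integer(counts), colnames(P))
}

#' Domain content of newborn families and its overlaps
#'
#' For each queried branch, collects the set of domain accessions occurring
#' in families born there and reports its size, its intersection with the
#' domain set of the universal families, and pairwise intersections between
#' the queried branches.
#'
#' @param birth_lineage Named character vector: family ID -> lineage
#'   (canonical branch name) of its Dollo birth.
#' @param fam_domains Named list: family ID -> character vector of domain
#'   accessions found in its members.
#' @param universal_families Character vector of universal-family IDs.
#' @param branches Character vector of lineage names to query.
#' @return List with `sets` (domain set per branch), `sizes`,
#'   `universal_overlap` (per branch), and `pairwise` (matrix of
#'   intersection sizes).
#' @export
birthDomainOverlap <- function(birth_lineage, fam_domains,
                               universal_families, branches) {
  uset <- sort(unique(unlist(fam_domains[intersect(names(fam_domains),
                                                   universal_families)])))
  sets <- lapply(branches, function(b) {
    fams <- names(birth_lineage)[birth_lineage == b]
    sort(unique(unlist(fam_domains[intersect(fams, names(fam_domains))])))
  })
  names(sets) <- branches
  pw <- outer(seq_along(sets), seq_along(sets),
              Vectorize(function(i, j) length(intersect(sets[[i]], sets[[j]]))))
  dimnames(pw) <- list(branches, branches)
  list(sets = sets,
       sizes = vapply(sets, length, 0L),
       universal_overlap = vapply(sets, function(s) length(intersect(s, uset)), 0L),
       pairwise = pw)
}
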