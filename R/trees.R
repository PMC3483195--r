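#' @importFrom stats cor pt phyper rgeom rpois rbinom runif rnorm rexp setNames
#' @importFrom utils read.table write.table head
NULL

# Trees are ape "phylo" objects throughout: rooted binary species trees for
# Dollo reconstruction and reconciliation, unrooted binary trees out of NJ.
# The root node index is ape's convention, Ntip + 1.

#' Parse a Newick string into a rooted tree
#'
#' Thin validating wrapper around [ape::read.tree()]. Leaf labels must be
#' unique and parentheses balanced; branch lengths, when present, must be
#' non-negative.
#'
#' @param text A single Newick string, terminated by a semicolon.
#' @return An object of class `phylo`.
#' @examples
#' tr <- parseNewick("((A:1,B:2):0.5,C:3);")
#' @export
parseNewick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  depth <- cumsum((strsplit(text, "")[[1]] == "(") - (strsplit(text, "")[[1]] == ")"))
  if (any(depth < 0))
    stop("malformed Newick: unbalanced ')' at character ", which(depth < 0)[1])
  if (depth[length(depth)] != 0)
    stop("malformed Newick: ", depth[length(depth)], " unclosed '(' at end of string")
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) stop("Newick parse error: ", conditionMessage(e)))
  if (is.null(phy)) stop("Newick parse error: no tree in string")
  if (anyDuplicated(phy$tip.label))
    stop("duplicate leaf label(s): ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  if (!is.null(phy$edge.length) && any(phy$edge.length < 0))
    stop("negative branch length in Newick input")
  phy
}

#' Serialize a tree to Newick
#'
#' Round-trips with [parseNewick()]: topology, labels, and branch lengths are
#' preserved at full double precision. Trees without branch lengths are
#' written without `:` tokens.
#'
#' @param tree A `phylo` object.
#' @return A Newick string (with trailing semicolon).
#' @export
writeNewick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, digits = 17)
}

#' Read a species tree from a Newick file
#'
#' @param path Path to a file holding a single Newick tree.
#' @return A `phylo` object.
#' @export
readSpeciesTree <- function(path) parseNewick(paste(readLines(path), collapse = ""))

#' Lowest common ancestor of a set of leaves
#'
#' @param tree A rooted `phylo` object.
#' @param leaves Character vector of leaf labels (non-empty).
#' @return Internal node number (or tip number if a single leaf is given).
#' @export
treeLca <- function(tree, leaves) {
  stopifnot(inherits(tree, "phylo"), length(leaves) >= 1L)
  idx <- match(leaves, tree$tip.label)
  if (anyNA(idx))
    stop("unknown leaf label(s): ", paste(leaves[is.na(idx)], collapse = ", "))
  idx <- unique(idx)
  if (length(idx) == 1L) return(idx)
  ape::getMRCA(tree, idx)
}

# ---- internal tree bookkeeping -------------------------------------------

#' Per-node parent vector (0 for the root)
#' @keywords internal
#' @noRd
nodeParents <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  par <- integer(n)
  par[tree$edge[, 2]] <- tree$edge[, 1]
  par
}

#' List of child node numbers per node
#' @keywords internal
#' @noRd
nodeChildren <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  ch <- vector("list", n)
  for (i in seq_len(nrow(tree$edge)))
    ch[[tree$edge[i, 1]]] <- c(ch[[tree$edge[i, 1]]], tree$edge[i, 2])
  ch
}

#' Tip labels under each node, in postorder-filled list
#' @keywords internal
#' @noRd
tipsUnder <- function(tree) {
  ntip <- ape::Ntip(tree)
  n <- ntip + tree$Nnode
  out <- vector("list", n)
  for (i in seq_len(ntip)) out[[i]] <- tree$tip.label[i]
  ord <- rev(ape::postorder(tree))          # edges, root-first
  for (i in rev(ord)) {                     # children before parents
    e <- tree$edge[i, ]
    out[[e[1]]] <- c(out[[e[1]]], out[[e[2]]])
  }
  lapply(out, sort)
}

#' Node depth in edges from the root (root = 0)
#' @keywords internal
#' @noRd
nodeDepths <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  d <- integer(n)
  ord <- rev(ape::postorder(tree))
  for (i in ord) d[tree$edge[i, 2]] <- d[tree$edge[i, 1]] + 1L
  d
}

#' Canonical branch/node name: sorted leaf set joined by commas
#'
#' Every branch of the species tree is identified by the leaf set of the node
#' below it, sorted and comma-joined, so lineage labels are reproducible
#' independent of node numbering.
#'
#' @param tree A `phylo` object.
#' @param node Node number(s).
#' @return Character vector of canonical names.
#' @export
canonicalNodeName <- function(tree, node) {
  tu <- tipsUnder(tree)
  vapply(node, function(v) paste(tu[[v]], collapse = ","), character(1))
}

#' Branch table of a rooted tree
#'
#' One row per branch (edge), identified by its child node, with the canonical
#' lineage name and branch length.
#'
#' @param tree A rooted `phylo` object.
#' @return A data.frame with columns `node`, `parent`, `lineage`, `length`.
#' @export
branchTable <- function(tree) {
  len <- if (is.null(tree$edge.length)) rep(NA_real_, nrow(tree$edge)) else tree$edge.length
  data.frame(node = tree$edge[, 2],
             parent = tree$edge[, 1],
             lineage = canonicalNodeName(tree, tree$edge[, 2]),
             length = len,
             stringsAsFactors = FALSE)
}

# ---- packaged fixtures ----------------------------------------------------

#' The 11-taxon metazoan species tree fixture
#'
#' Topology `(Sce,(Mbr,((Tsp,(Cbr,Cel)),((Bmo,(Aae,Dme)),(Gga,(Hsa,Mmu))))))`
#' with the published branch lengths (substitutions/site) on the 17 metazoan
#' branches. The two outgroup pendant branches (Sce, Mbr) and the stem joining
#' Mbr to the metazoans carry placeholder length 1.0 and are excluded from all
#' rate and index computations (see `analyzableLineages`).
#'
#' @return A `phylo` object with attribute `analyzable`: the canonical names of
#'   the 17 metazoan lineages.
#' @export
speciesTreeFixture <- function() {
  path <- system.file("extdata", "species_tree.nwk", package = "famdomevo")
  tree <- readSpeciesTree(path)
  ev <- table2Events()
  attr(tree, "analyzable") <- ev$lineage
  tree
}

#' Per-lineage birth/death and duplication/deletion event counts
#'
#' The packaged 17-lineage event table: branch length, protein-family and
#' domain birth/death counts, and universal-family / universal-domain
#' duplication and deletion counts. Lineages are named canonically by their
#' sorted leaf sets.
#'
#' @return A data.frame with columns `lineage`, `branch_length`, `fam_birth`,
#'   `fam_death`, `dom_birth`, `dom_death`, `ufam_dup`, `ufam_del`,
#'   `udom_dup`, `udom_del`.
#' @export
table2Events <- function() {
  path <- system.file("extdata", "table2_events.tsv", package = "famdomevo")
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Clade membership of the nine metazoan taxa
#'
#' @return Named character vector mapping taxon to clade
#'   (`nematodes`, `arthropods`, `vertebrates`).
#' @export
metazoanClades <- function() {
  c(Tsp = "nematodes", Cbr = "nematodes", Cel = "nematodes",
    Bmo = "arthropods", Aae = "arthropods", Dme = "arthropods",
    Gga = "vertebrates", Hsa = "vertebrates", Mmu = "vertebrates")
}
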