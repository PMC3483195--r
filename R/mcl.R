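# Markov clustering of the protein similarity graph, and the family
# definition built on top of it (multi-member clusters only).

#' Read an ABC-format edge list
#'
#' Tab-separated `node1 node2 weight` rows describing an undirected weighted
#' similarity graph. Self-edges are dropped; duplicate pairs keep the maximum
#' weight.
#'
#' @param path Path to the edge list.
#' @return A data.frame with columns `from`, `to`, `weight`.
#' @export
readAbcGraph <- function(path) {
  d <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE,
                  col.names = c("from", "to", "weight"))
  similarityGraph(d)
}

#' Normalize an edge table into a similarity graph
#'
#' @param edges data.frame with columns `from`, `to`, `weight` (weight >= 0).
#' @return Canonicalized edge data.frame (no self-edges, unordered pairs
#'   deduplicated keeping the maximum weight).
#' @export
similarityGraph <- function(edges) {
  stopifnot(all(c("from", "to", "weight") %in% names(edges)))
  if (any(!is.finite(edges$weight)) || any(edges$weight < 0))
    stop("edge weights must be finite and non-negative")
  edges <- edges[edges$from != edges$to, , drop = FALSE]
  if (nrow(edges) == 0L)
    return(data.frame(from = character(0), to = character(0),
                      weight = numeric(0), stringsAsFactors = FALSE))
  a <- pmin(edges$from, edges$to)
  b <- pmax(edges$from, edges$to)
  key <- paste(a, b, sep = "\r")
  w <- tapply(edges$weight, key, max)
  parts <- strsplit(names(w), "\r", fixed = TRUE)
  data.frame(from = vapply(parts, `[`, "", 1),
             to = vapply(parts, `[`, "", 2),
             weight = as.numeric(w),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Convert tabular sequence-search hits to similarity-graph weights
#'
#' Each directed hit contributes `min(-log10(E), 200)` (E = 0 maps to the cap
#' 200); the weight of an unordered pair is the mean of its directed
#' contributions. Self-hits are dropped.
#'
#' @param hits data.frame with at least columns `query`, `subject`, `evalue`;
#'   the 12-column tabular search layout is also accepted (columns 1, 2, 11).
#' @return A similarity graph edge data.frame (`from`, `to`, `weight`).
#' @export
weightsFromSearch <- function(hits) {
  if (!all(c("query", "subject", "evalue") %in% names(hits))) {
    if (ncol(hits) >= 11) {
      hits <- data.frame(query = hits[[1]], subject = hits[[2]],
                         evalue = as.numeric(hits[[11]]),
                         stringsAsFactors = FALSE)
    } else stop("hits must have columns query, subject, evalue (or 12-column layout)")
  }
  if (any(hits$evalue < 0)) stop("negative E-value in search hits")
  hits <- hits[hits$query != hits$subject, , drop = FALSE]
  if (nrow(hits) == 0L)
    return(data.frame(from = character(0), to = character(0),
                      weight = numeric(0), stringsAsFactors = FALSE))
  w <- ifelse(hits$evalue == 0, 200, pmin(-log10(hits$evalue), 200))
  w <- pmax(w, 0)
  a <- pmin(hits$query, hits$subject)
  b <- pmax(hits$query, hits$subject)
  key <- paste(a, b, sep = "\r")
  m <- tapply(w, key, mean)
  parts <- strsplit(names(m), "\r", fixed = TRUE)
  data.frame(from = vapply(parts, `[`, "", 1),
             to = vapply(parts, `[`, "", 2),
             weight = as.numeric(m),
             stringsAsFactors = FALSE, row.names = NULL)
}

# Sparse MCL on one connected component. Columns are kept stochastic; the
# expansion/inflation loop prunes entries below `prune` and stops when the
# matrix change drops below `tol`. Sparsity plus pruning keeps even large
# near-block-diagonal components cheap.
mclComponent <- function(M, inflation, prune, tol, max_iter) {
  norm_cols <- function(A) {
    cs <- Matrix::colSums(A)
    cs[cs == 0] <- 1
    A %*% Matrix::Diagonal(x = 1 / cs)
  }
  M <- norm_cols(M)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M                 # expansion
    M2 <- M2^inflation            # inflation
    M2 <- Matrix::drop0(M2 * (M2 >= prune))
    M2 <- norm_cols(M2)
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) { converged <- TRUE; break }
  }
  list(M = M, converged = converged)
}

#' Markov clustering of a weighted similarity graph
#'
#' Classic MCL: self-loops are added with weight equal to the node's maximum
#' incident edge weight (1 for isolated nodes), columns are normalized, and
#' expansion (matrix squaring) alternates with inflation (entrywise power and
#' renormalization) and pruning until convergence. Clusters are read from the
#' converged attractor structure; a node attracted by several attractor
#' systems is assigned to the one holding its largest converged weight, ties
#' going to the lexicographically smallest cluster. Connected components are
#' clustered independently, so large sparse graphs stay cheap.
#'
#' @param graph Edge data.frame (`from`, `to`, `weight`) as from
#'   [similarityGraph()], or a path-less node set via `nodes`.
#' @param inflation Inflation exponent, > 1 (default 2.0).
#' @param prune_threshold Entries below this are dropped each iteration
#'   (default 1e-5).
#' @param max_iter Iteration cap (default 200); non-convergence warns and
#'   returns the current clustering.
#' @param tol Convergence tolerance on the maximum entry change (default 1e-8).
#' @param nodes Optional character vector of node IDs to include even when
#'   isolated (no incident edges).
#' @return Named integer vector: cluster ID per node.
#' @export
mclCluster <- function(graph, inflation = 2.0, prune_threshold = 1e-5,
                       max_iter = 200L, tol = 1e-8, nodes = NULL) {
  if (inflation <= 1) stop("inflation must be > 1")
  all_nodes <- sort(unique(c(graph$from, graph$to, nodes)))
  if (length(all_nodes) == 0L) return(setNames(integer(0), character(0)))
  g <- igraph::graph_from_data_frame(graph[, c("from", "to")],
                                     directed = FALSE, vertices = all_nodes)
  comp <- igraph::components(g)$membership[all_nodes]
  cluster_of <- setNames(rep(NA_character_, length(all_nodes)), all_nodes)
  warned <- FALSE
  comp_of_edge <- comp[graph$from]
  sub_edges <- split(seq_len(nrow(graph)), comp_of_edge)
  for (ci in unique(comp)) {
    members <- all_nodes[comp == ci]
    n <- length(members)
    if (n == 1L) { cluster_of[members] <- members; next }
    sub <- graph[sub_edges[[as.character(ci)]], , drop = FALSE]
    ii <- match(sub$from, members); jj <- match(sub$to, members)
    M <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii),
                              x = rep(sub$weight, 2), dims = c(n, n))
    trip0 <- Matrix::summary(M)
    loops <- rep(1, n)
    rm <- tapply(trip0$x, trip0$i, max)
    loops[as.integer(names(rm))] <- pmax(rm, 1e-12)
    Matrix::diag(M) <- loops
    res <- mclComponent(M, inflation, prune_threshold, tol, max_iter)
    if (!res$converged && !warned) {
      warning("MCL did not converge within ", max_iter,
              " iterations; returning current clustering")
      warned <- TRUE
    }
    Mc <- Matrix::drop0(res$M)
    # attractor nodes keep mass on their own row; attractor systems are the
    # connected groups of attractors sharing nonzero entries
    attract <- which(Matrix::diag(Mc) > prune_threshold)
    if (length(attract) == 0L) attract <- seq_len(n)
    Asub <- Mc[attract, attract, drop = FALSE]
    ga <- igraph::graph_from_adjacency_matrix(
      (Asub > 0) | Matrix::t(Asub > 0), mode = "undirected")
    amem <- igraph::components(ga)$membership
    # cluster label = lexicographically smallest attractor member
    sys_label <- vapply(split(members[attract], amem),
                        function(s) min(s), character(1))
    sys_of_row <- integer(n)
    sys_of_row[attract] <- amem
    trip <- Matrix::summary(Mc)
    trip <- trip[sys_of_row[trip$i] > 0, , drop = FALSE]
    assigned <- rep(NA_character_, n)
    if (nrow(trip)) {
      key <- split(seq_len(nrow(trip)), trip$j)
      for (jc in names(key)) {
        rows <- key[[jc]]
        wsum <- tapply(trip$x[rows], sys_of_row[trip$i[rows]], sum)
        best <- names(wsum)[wsum == max(wsum)]
        assigned[as.integer(jc)] <- min(sys_label[best])  # tie: smallest ID
      }
    }
    assigned[is.na(assigned)] <- members[is.na(assigned)]  # unattracted: own cluster
    cluster_of[members] <- assigned
  }
  ids <- sort(unique(cluster_of))
  setNames(match(cluster_of, ids), all_nodes)
}

#' Define protein families from a clustering
#'
#' Multi-member clusters become families; singletons are discarded. Families
#' are numbered by descending size, ties broken by the lexicographically
#' smallest member.
#'
#' @param clusters Named integer vector (node -> cluster), as from
#'   [mclCluster()].
#' @param species Optional named character vector mapping protein ID to
#'   species tag; when given, each family records its species set.
#' @return A data.frame with columns `family`, `protein` (and `species` when
#'   provided); attribute `members` holds the list of member vectors keyed by
#'   family ID.
#' @export
familiesFromClusters <- function(clusters, species = NULL) {
  memb <- split(names(clusters), clusters)
  memb <- memb[vapply(memb, length, 0L) >= 2L]
  if (length(memb) == 0L) {
    out <- data.frame(family = character(0), protein = character(0),
                      stringsAsFactors = FALSE)
    attr(out, "members") <- list()
    return(out)
  }
  memb <- lapply(memb, sort)
  ord <- order(-vapply(memb, length, 0L), vapply(memb, `[`, "", 1))
  memb <- memb[ord]
  ids <- sprintf("F%04d", seq_along(memb))
  names(memb) <- ids
  out <- data.frame(family = rep(ids, vapply(memb, length, 0L)),
                    protein = unlist(memb, use.names = FALSE),
                    stringsAsFactors = FALSE)
  if (!is.null(species)) {
    sp <- species[out$protein]
    if (anyNA(sp)) stop("protein(s) missing from species map: ",
                        paste(head(out$protein[is.na(sp)]), collapse = ", "))
    out$species <- unname(sp)
  }
  attr(out, "members") <- memb
  out
}
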