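# Family-level term enrichment: hypergeometric tails against a family
# background, with per-family term deduplication (a term counted once per
# family regardless of how many members carry it), ancestor propagation over
# the ontology DAG, elim-style refinement, and a permutation FDR.

#' Read a minimal OBO ontology
#'
#' Parses `[Term]` stanzas, keeping `id`, `name`, and `is_a` (and `part_of`
#' relationships) edges. Obsolete terms are skipped. The result must be
#' acyclic.
#'
#' @param path Path to an OBO 1.2 file.
#' @return List with `terms` (character vector of IDs), `name` (named
#'   vector), and `parents` (named list of parent IDs per term).
#' @export
readObo <- function(path) {
  ln <- readLines(path)
  terms <- character(0); nm <- character(0)
  parents <- list()
  cur <- NULL; cur_name <- NA_character_; cur_par <- character(0)
  obsolete <- FALSE; in_term <- FALSE
  flush <- function() {
    if (!is.null(cur) && !obsolete) {
      terms <<- c(terms, cur)
      nm[cur] <<- cur_name
      parents[[cur]] <<- cur_par
    }
  }
  for (l in ln) {
    l <- trimws(l)
    if (l == "[Term]") { flush(); cur <- NULL; cur_name <- NA; cur_par <- character(0)
                         obsolete <- FALSE; in_term <- TRUE; next }
    if (startsWith(l, "[")) { flush(); cur <- NULL; in_term <- FALSE; next }
    if (!in_term) next
    if (startsWith(l, "id:")) cur <- trimws(sub("^id:", "", l))
    else if (startsWith(l, "name:")) cur_name <- trimws(sub("^name:", "", l))
    else if (startsWith(l, "is_a:"))
      cur_par <- c(cur_par, trimws(sub("!.*$", "", sub("^is_a:", "", l))))
    else if (startsWith(l, "relationship: part_of"))
      cur_par <- c(cur_par, trimws(sub("!.*$", "",
                   sub("^relationship: part_of", "", l))))
    else if (l == "is_obsolete: true") obsolete <- TRUE
  }
  flush()
  dag <- list(terms = terms, name = nm, parents = parents)
  # acyclicity check via ancestor closure (errors on a cycle)
  invisible(termAncestors(dag))
  dag
}

#' Ancestor sets of every term
#'
#' @param dag Ontology as returned by [readObo()].
#' @return Named list: term -> character vector of strict ancestors.
#' @export
termAncestors <- function(dag) {
  memo <- new.env(parent = emptyenv())
  walking <- new.env(parent = emptyenv())
  anc <- function(t) {
    if (!is.null(memo[[t]])) return(memo[[t]])
    if (!is.null(walking[[t]])) stop("cycle in ontology at term ", t)
    walking[[t]] <- TRUE
    ps <- intersect(dag$parents[[t]], dag$terms)
    res <- unique(c(ps, unlist(lapply(ps, anc))))
    rm(list = t, envir = walking)
    memo[[t]] <- res
    res
  }
  setNames(lapply(dag$terms, anc), dag$terms)
}

#' Annotate families with deduplicated, ancestor-closed term sets
#'
#' Each family's annotation is the union of its members' terms (a term seen
#' in several members counts once), propagated to all ancestors in the DAG.
#'
#' @param protein_terms Data.frame with columns `protein`, `term`.
#' @param families Data.frame with columns `family`, `protein` (as from
#'   [familiesFromClusters()]).
#' @param dag Ontology from [readObo()].
#' @param strict Error on annotation terms absent from the DAG (default
#'   FALSE: warn and skip).
#' @return Named list: family ID -> sorted character vector of term IDs
#'   (ancestor-closed). Unannotated families get an empty vector.
#' @export
annotateFamilies <- function(protein_terms, families, dag, strict = FALSE) {
  unknown <- setdiff(unique(protein_terms$term), dag$terms)
  if (length(unknown)) {
    if (strict) stop("annotation terms not in ontology: ",
                     paste(unknown, collapse = ", "))
    warning("skipping ", length(unknown), " annotation term(s) not in ontology")
    protein_terms <- protein_terms[!protein_terms$term %in% unknown, , drop = FALSE]
  }
  anc <- termAncestors(dag)
  p2t <- split(protein_terms$term, protein_terms$protein)
  fams <- split(families$protein, families$family)
  lapply(fams, function(prots) {
    t0 <- unique(unlist(p2t[intersect(prots, names(p2t))]))
    as.character(sort(unique(c(t0, unlist(anc[t0])))))
  })
}

#' Exact hypergeometric tail probabilities
#'
#' For X ~ Hypergeometric(N, K, n): upper tail P(X >= k) (enrichment) and
#' lower tail P(X <= k) (depletion).
#'
#' @param k Observed annotated items in the target.
#' @param n Target size.
#' @param K Annotated items in the background.
#' @param N Background size.
#' @return Named numeric vector `c(p_enriched, p_depleted)`.
#' @export
hypergeomTest <- function(k, n, K, N) {
  if (!(k >= 0 && k <= n && n <= N && K <= N && k <= K))
    stop("inconsistent hypergeometric counts (need 0 <= k <= min(n, K), n, K <= N)")
  c(p_enriched = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
    p_depleted = phyper(k, K, N - K, n))
}

#' Test every term for enrichment/depletion of a target family set
#'
#' @param target Character vector of target family IDs.
#' @param annotations Named list family -> term set (from
#'   [annotateFamilies()]).
#' @param background Background family IDs; default: every family with at
#'   least one annotation.
#' @return Data.frame `term`, `k`, `n`, `K`, `N`, `p_enriched`,
#'   `p_depleted`, sorted by `p_enriched`.
#' @export
enrichFamilies <- function(target, annotations, background = NULL) {
  if (is.null(background))
    background <- names(annotations)[vapply(annotations, length, 0L) > 0]
  target <- intersect(target, background)
  N <- length(background); n <- length(target)
  terms <- sort(unique(unlist(annotations[background])))
  t2f <- invertAnnotations(annotations[background])
  out <- do.call(rbind, lapply(terms, function(t) {
    fams <- t2f[[t]]
    K <- length(fams)
    k <- length(intersect(fams, target))
    p <- hypergeomTest(k, n, K, N)
    data.frame(term = t, k = k, n = n, K = K, N = N,
               p_enriched = p[["p_enriched"]], p_depleted = p[["p_depleted"]],
               stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(term = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0),
                      p_enriched = numeric(0), p_depleted = numeric(0))
  out <- out[order(out$p_enriched, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

invertAnnotations <- function(annotations) {
  fam <- rep(names(annotations), vapply(annotations, length, 0L))
  trm <- unlist(annotations, use.names = FALSE)
  lapply(split(fam, trm), unique)
}

#' Elim-style refinement of enrichment results
#'
#' Terms are visited leaves-upward (decreasing DAG depth). When a term is
#' significant at `threshold`, its annotated families are removed from all
#' of its strict ancestors before those are re-tested, so a parent that was
#' significant only through a significant child loses its signal and is
#' flagged `refined_out`.
#'
#' @param results Data.frame from [enrichFamilies()].
#' @param dag Ontology from [readObo()].
#' @param annotations Named list family -> term set.
#' @param target Target family IDs used for `results`.
#' @param background Background family IDs (default as in
#'   [enrichFamilies()]).
#' @param threshold Significance threshold driving elimination
#'   (default 0.001).
#' @return `results` with columns `p_refined` and `refined_out` added.
#' @export
refineEnrichment <- function(results, dag, annotations, target,
                             background = NULL, threshold = 0.001) {
  if (is.null(background))
    background <- names(annotations)[vapply(annotations, length, 0L) > 0]
  target <- intersect(target, background)
  anc <- termAncestors(dag)
  depth <- vapply(anc, length, 0L)          # strict-ancestor count as depth
  t2f <- invertAnnotations(annotations[background])
  removed <- lapply(results$term, function(t) character(0))
  names(removed) <- results$term
  p_ref <- setNames(results$p_enriched, results$term)
  for (t in results$term[order(-depth[results$term])]) {
    fams <- setdiff(t2f[[t]], removed[[t]])
    k <- length(intersect(fams, target))
    K <- length(fams)
    p_ref[t] <- hypergeomTest(k, length(target), K, length(background))[["p_enriched"]]
    if (p_ref[t] < threshold) {
      for (a in intersect(anc[[t]], names(removed)))
        removed[[a]] <- union(removed[[a]], t2f[[t]])
    }
  }
  results$p_refined <- as.numeric(p_ref[results$term])
  results$refined_out <- results$p_enriched < threshold &
                         results$p_refined >= threshold
  results
}

#' Permutation-based false discovery rate
#'
#' Draws `reps` random target sets of the observed size from the background,
#' recomputes the minimum enrichment p-value of each draw, and estimates
#' `FDR(t)` as the fraction of draws whose minimum p-value is below the
#' observed term's p-value (a family-wise min-p null, deterministic given
#' the seed).
#'
#' @param results Data.frame from [enrichFamilies()] (optionally refined; the
#'   `p_refined` column is used when present).
#' @param annotations Named list family -> term set.
#' @param target_size Size of the observed target set.
#' @param background Background family IDs.
#' @param reps Number of permutations (default 1000; < 100 warns).
#' @param seed RNG seed (required for reproducibility).
#' @return `results` with an `FDR` column added.
#' @export
permutationFdr <- function(results, annotations, target_size,
                           background = NULL, reps = 1000L, seed = 1L) {
  if (reps < 100L) warning("reps < 100 gives an unstable FDR estimate")
  if (is.null(background))
    background <- names(annotations)[vapply(annotations, length, 0L) > 0]
  t2f <- invertAnnotations(annotations[background])
  terms <- names(t2f)
  K <- vapply(t2f, length, 0L)
  N <- length(background)
  set.seed(seed)
  minp <- vapply(seq_len(reps), function(rep) {
    draw <- sample(background, target_size)
    k <- vapply(t2f, function(f) length(intersect(f, draw)), 0L)
    min(phyper(k - 1, K, N - K, target_size, lower.tail = FALSE))
  }, 0)
  obs <- if ("p_refined" %in% names(results)) results$p_refined else results$p_enriched
  results$FDR <- vapply(obs, function(p) mean(minp <= p), 0)
  results
}

#' Apply the joint significance filter
#'
#' Retains terms passing both the (refined) p-value threshold and the FDR
#' threshold.
#'
#' @param results Data.frame with `p_refined` (or `p_enriched`) and `FDR`.
#' @param p_max P-value threshold (default 0.001).
#' @param fdr_max FDR threshold (default 0.1).
#' @return The filtered data.frame.
#' @export
filterSignificant <- function(results, p_max = 0.001, fdr_max = 0.1) {
  p <- if ("p_refined" %in% names(results)) results$p_refined else results$p_enriched
  out <- results[p < p_max & results$FDR < fdr_max, , drop = FALSE]
  rownames(out) <- NULL
  out
}
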