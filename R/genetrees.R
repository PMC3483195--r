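# Protein distance matrices and neighbor-joining gene trees. Downstream
# reconciliation uses topology only, so the shipped distance models are the
# uncorrected p-distance and the Kimura protein correction; externally
# computed matrices can be injected in PHYLIP square format.

#' Read an aligned protein FASTA
#'
#' @param path Path to an aligned FASTA file (equal-length gapped rows).
#' @return Character matrix, sequences x sites, rownames = sequence IDs.
#' @export
readAlignedFasta <- function(path) {
  aa <- ape::read.FASTA(path, type = "AA")
  m <- toupper(do.call(rbind, as.character(aa)))
  if (length(unique(vapply(as.character(aa), length, 0L))) != 1L)
    stop("alignment rows differ in length")
  rownames(m) <- names(aa)
  m
}

#' Pairwise protein distances from an alignment
#'
#' Gap columns are removed per pair (pairwise deletion). Model `"p"` is the
#' raw mismatch proportion; `"kimura"` applies d = -ln(1 - p - p^2/5), with
#' saturated pairs (p >= 0.85) mapped to a finite ceiling so NJ stays
#' defined.
#'
#' @param aln Character matrix (sequences x sites) as from
#'   [readAlignedFasta()]; `-` and `.` are gaps, `X` is treated as missing.
#' @param model `"p"` or `"kimura"`.
#' @param ceiling Distance assigned to saturated pairs under `"kimura"`
#'   (default 10.0).
#' @return Symmetric numeric distance matrix with zero diagonal.
#' @export
pairwiseDistance <- function(aln, model = c("p", "kimura"), ceiling = 10.0) {
  model <- match.arg(model)
  stopifnot(is.matrix(aln), nrow(aln) >= 2L)
  gap <- aln %in% c("-", ".", "X", "?") | is.na(aln)
  dim(gap) <- dim(aln)
  n <- nrow(aln)
  D <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !gap[i, ] & !gap[j, ]
    if (!any(ok))
      stop("no comparable sites between ", rownames(aln)[i], " and ",
           rownames(aln)[j])
    p <- mean(aln[i, ok] != aln[j, ok])
    d <- if (model == "p") p
         else if (p >= 0.85) ceiling
         else -log(1 - p - p^2 / 5)
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei NJ. The taxa are put in lexicographic order before joining so
#' that the output is invariant to input row order (ties in the Q criterion
#' then resolve to the lexicographically smallest pair). Negative estimated
#' branch lengths are clamped to zero with the deficit moved to the sibling
#' branch.
#'
#' @param D Symmetric distance matrix with >= 3 taxa.
#' @return An unrooted binary `phylo` tree (trifurcating root node).
#' @export
neighborJoining <- function(D) {
  stopifnot(is.matrix(D), nrow(D) >= 3L)
  if (max(abs(D - t(D))) > 1e-9) stop("distance matrix is not symmetric")
  ord <- order(rownames(D))
  D <- D[ord, ord]
  tr <- ape::nj(D)
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0)) {
    par <- nodeParents(tr)
    for (e in which(tr$edge.length < 0)) {
      deficit <- -tr$edge.length[e]
      tr$edge.length[e] <- 0
      sib <- which(tr$edge[, 1] == tr$edge[e, 1] & seq_len(nrow(tr$edge)) != e)
      if (length(sib)) tr$edge.length[sib[1]] <- tr$edge.length[sib[1]] + deficit
    }
  }
  tr
}

#' Read a PHYLIP square distance matrix
#'
#' Plain square (non-interleaved) layout: a count line, then one row per
#' taxon (`name d1 d2 ... dn`, whitespace-separated, names without spaces).
#'
#' @param path File path.
#' @return Symmetric numeric matrix with taxon dimnames.
#' @export
readPhylipDist <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln))]
  n <- as.integer(trimws(ln[1]))
  if (is.na(n) || length(ln) < n + 1L) stop("malformed PHYLIP distance file")
  rows <- strsplit(trimws(ln[2:(n + 1)]), "[[:space:]]+")
  nm <- vapply(rows, `[`, "", 1)
  D <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(n)))
  dimnames(D) <- list(nm, nm)
  if (any(!is.finite(D))) stop("non-numeric entries in PHYLIP distance file")
  D
}

#' Write a PHYLIP square distance matrix
#'
#' @param D Symmetric numeric matrix with taxon dimnames.
#' @param path File path.
#' @export
writePhylipDist <- function(D, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(nrow(D)), con)
  for (i in seq_len(nrow(D)))
    writeLines(paste(rownames(D)[i],
                     paste(sprintf("%.10g", D[i, ]), collapse = " ")), con)
  invisible(path)
}
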