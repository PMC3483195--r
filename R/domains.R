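# Per-protein domain hits, per-protein domain architectures, and domain
# groups (each domain accession's protein/species membership and copy counts).

#' Read and filter a per-protein domain hit table
#'
#' Two dialects: a simplified 6-column TSV
#' (`protein  domain  start  end  score  evalue`) and the HMMER3 per-domain
#' tabular layout (`domtblout`; whitespace-separated, `#` comments), from
#' which target name, query accession, envelope coordinates, bit score and
#' independent E-value are taken.
#'
#' @param path Path to the hit table.
#' @param evalue_cutoff Numeric independent-E-value cutoff, or `"precomputed"`
#'   to accept all rows as already thresholded (default).
#' @param dialect `"tsv6"` (default) or `"domtblout"`.
#' @return A data.frame of hits: `protein`, `domain`, `start`, `end`,
#'   `score`, `evalue`.
#' @export
readDomainHits <- function(path, evalue_cutoff = "precomputed",
                           dialect = c("tsv6", "domtblout")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv6") {
    d <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE,
                    col.names = c("protein", "domain", "start", "end",
                                  "score", "evalue"))
  } else {
    ln <- readLines(path)
    ln <- ln[!startsWith(ln, "#") & nzchar(trimws(ln))]
    f <- strsplit(trimws(ln), "[[:space:]]+")
    if (any(vapply(f, length, 0L) < 23))
      stop("domtblout row with fewer than 23 fields at line ",
           which(vapply(f, length, 0L) < 23)[1])
    d <- data.frame(protein = vapply(f, `[`, "", 1),
                    domain = vapply(f, `[`, "", 5),
                    start = as.numeric(vapply(f, `[`, "", 20)),
                    end = as.numeric(vapply(f, `[`, "", 21)),
                    score = as.numeric(vapply(f, `[`, "", 14)),
                    evalue = as.numeric(vapply(f, `[`, "", 13)),
                    stringsAsFactors = FALSE)
  }
  domainHits(d, evalue_cutoff)
}

#' Validate and threshold domain hits
#'
#' @param hits data.frame with columns `protein`, `domain`, `start`, `end`,
#'   `score`, `evalue` (1-based inclusive envelope coordinates).
#' @param evalue_cutoff Numeric cutoff or `"precomputed"`.
#' @return The filtered, validated hit data.frame.
#' @export
domainHits <- function(hits, evalue_cutoff = "precomputed") {
  need <- c("protein", "domain", "start", "end", "score", "evalue")
  stopifnot(all(need %in% names(hits)))
  bad <- which(!is.finite(hits$start) | !is.finite(hits$end) |
               hits$start < 1 | hits$start > hits$end)
  if (length(bad))
    stop("invalid envelope coordinates (need 1 <= start <= end) at row ", bad[1])
  if (any(!is.finite(hits$score))) stop("non-finite bit score")
  if (!identical(evalue_cutoff, "precomputed")) {
    stopifnot(is.numeric(evalue_cutoff), length(evalue_cutoff) == 1L)
    hits <- hits[hits$evalue <= evalue_cutoff, , drop = FALSE]
  }
  rownames(hits) <- NULL
  hits
}

# Resolve overlapping hits on one protein: overlap > 50% of the shorter
# envelope keeps the higher bit score, ties by lower E-value, then by
# lexicographic accession. Input order must not matter, so hits are put in a
# canonical order first.
resolveOverlaps <- function(h) {
  h <- h[order(h$start, h$end, -h$score, h$evalue, h$domain), , drop = FALSE]
  keep <- rep(TRUE, nrow(h))
  pref <- order(-h$score, h$evalue, h$domain, h$start)  # best hit first
  for (i in pref) {
    if (!keep[i]) next
    for (j in seq_len(nrow(h))) {
      if (j == i || !keep[j]) next
      ov <- min(h$end[i], h$end[j]) - max(h$start[i], h$start[j]) + 1
      shorter <- min(h$end[i] - h$start[i], h$end[j] - h$start[j]) + 1
      if (ov > 0.5 * shorter) keep[j] <- FALSE
    }
  }
  h[keep, , drop = FALSE]
}

#' Build per-protein domain architectures
#'
#' Hits are grouped by protein and sorted by envelope start; overlapping hits
#' (overlap > 50% of the shorter envelope) are resolved keeping the higher
#' bit score (ties: lower E-value, then lexicographic accession). A domain
#' hit twice in tandem appears twice in the architecture.
#'
#' @param hits Validated hit data.frame (see [domainHits()]).
#' @return A data.frame `protein`, `position`, `domain`; attribute `arch`
#'   holds the list of ordered accession vectors keyed by protein.
#' @export
buildArchitectures <- function(hits) {
  by_prot <- split(hits, hits$protein)
  arch <- lapply(by_prot, function(h) {
    h <- resolveOverlaps(h)
    h$domain[order(h$start, h$end, h$domain)]
  })
  arch <- arch[order(names(arch))]
  out <- data.frame(
    protein = rep(names(arch), vapply(arch, length, 0L)),
    position = unlist(lapply(arch, seq_along), use.names = FALSE),
    domain = unlist(arch, use.names = FALSE),
    stringsAsFactors = FALSE)
  attr(out, "arch") <- arch
  out
}

#' Define domain groups
#'
#' One group per distinct domain accession: its member proteins, species set,
#' and per-species copy count (one copy per retained hit).
#'
#' @param hits Validated hit data.frame.
#' @param species Named character vector mapping protein ID to species.
#' @return A data.frame `domain`, `species`, `copies`; attribute `proteins`
#'   holds the member protein list keyed by domain.
#' @export
domainGroups <- function(hits, species) {
  sp <- species[hits$protein]
  if (anyNA(sp))
    stop("protein(s) missing from species map: ",
         paste(unique(hits$protein[is.na(sp)]), collapse = ", "))
  key <- paste(hits$domain, sp, sep = "\t")
  counts <- table(key)
  parts <- strsplit(names(counts), "\t", fixed = TRUE)
  out <- data.frame(domain = vapply(parts, `[`, "", 1),
                    species = vapply(parts, `[`, "", 2),
                    copies = as.integer(counts),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$domain, out$species), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "proteins") <- lapply(split(hits$protein, hits$domain),
                                  function(p) sort(unique(p)))
  out
}
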