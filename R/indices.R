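# Branch-length-normalized event rates, the four lineage indices (family
# change, domain change, domain shuffling, adaptation), and Pearson
# correlations between event rates with Student-t significance. All
# logarithms are base 2: that base uniquely reproduces the three published
# shuffling indices (log2(177/39)=2.18, log2(106/27)=1.97, log2(60/24)=1.32).

#' Branch-length-normalized event rates
#'
#' Divides every event count by its lineage's branch length. Lineages with
#' non-positive or missing length are flagged and excluded.
#'
#' @param events Data.frame with a `branch_length` column and numeric event
#'   count columns (the packaged event-table schema, see [table2Events()]).
#' @param length_col Name of the branch length column.
#' @return Data.frame of the same shape with counts replaced by rates;
#'   attribute `excluded` lists dropped lineages.
#' @export
eventRates <- function(events, length_col = "branch_length") {
  stopifnot(length_col %in% names(events))
  l <- events[[length_col]]
  bad <- !is.finite(l) | l <= 0
  excluded <- if ("lineage" %in% names(events)) events$lineage[bad] else which(bad)
  out <- events[!bad, , drop = FALSE]
  num <- vapply(out, is.numeric, TRUE) & names(out) != length_col
  out[num] <- out[num] / out[[length_col]]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Complexity change index: log2 birth/death ratio
#'
#' Positive values mean net gain on the lineage, negative net loss. With a
#' zero birth or death count the index is undefined (`NA`) unless a
#' pseudocount is supplied.
#'
#' @param B,D Non-negative birth and death counts (vectorized).
#' @param pseudocount Added to both counts when > 0 (default 0 = off).
#' @return Numeric vector, `log2((B+c)/(D+c))`.
#' @export
changeIndex <- function(B, D, pseudocount = 0) {
  if (any(B < 0 | D < 0, na.rm = TRUE)) stop("negative event counts")
  B <- B + pseudocount; D <- D + pseudocount
  ifelse(B > 0 & D > 0, log2(B / D), NA_real_)
}

#' Domain shuffling index: log2 of family births over domain births
#'
#' Branch-length normalization cancels in the ratio, so raw counts and rates
#' give the identical index; it is computed on the counts as given.
#'
#' @param B_fam,B_dom Family and domain birth counts (vectorized).
#' @return Numeric vector, `NA` where `B_dom` (or `B_fam`) is zero.
#' @export
shufflingIndex <- function(B_fam, B_dom) {
  if (any(B_fam < 0 | B_dom < 0, na.rm = TRUE)) stop("negative event counts")
  ifelse(B_fam > 0 & B_dom > 0, log2(B_fam / B_dom), NA_real_)
}

#' Adaptation index: summed log rates of birth and death
#'
#' `AI = log2(B/l) + log2(D/l)`: large when a short branch carries many
#' birth and death events, i.e. fast turnover per unit of sequence
#' divergence.
#'
#' @param B,D Birth and death counts.
#' @param l Branch length (substitutions/site, > 0).
#' @return Numeric vector, `NA` where any input is non-positive.
#' @export
adaptationIndex <- function(B, D, l) {
  if (any(B < 0 | D < 0, na.rm = TRUE)) stop("negative event counts")
  ifelse(B > 0 & D > 0 & is.finite(l) & l > 0,
         log2(B / l) + log2(D / l), NA_real_)
}

#' Per-lineage index table
#'
#' @param events Event table in the packaged schema (see [table2Events()]).
#' @param pseudocount Passed to [changeIndex()].
#' @return Data.frame `lineage`, `fam_change`, `dom_change`, `shuffling`,
#'   `adaptation`.
#' @export
indexTable <- function(events, pseudocount = 0) {
  data.frame(
    lineage = events$lineage,
    fam_change = changeIndex(events$fam_birth, events$fam_death, pseudocount),
    dom_change = changeIndex(events$dom_birth, events$dom_death, pseudocount),
    shuffling = shufflingIndex(events$fam_birth, events$dom_birth),
    adaptation = adaptationIndex(events$fam_birth, events$fam_death,
                                 events$branch_length),
    stringsAsFactors = FALSE)
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length (>= 3 after pairwise removal
#'   of missing values); both must have nonzero variance.
#' @return The correlation coefficient r.
#' @export
pearsonR <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  cor(x, y)
}

#' Two-sided significance of a Pearson coefficient
#'
#' Student-t test: `t = r sqrt(n-2) / sqrt(1-r^2)` on `n - 2` degrees of
#' freedom. `|r| = 1` returns p = 0 with attribute `degenerate = TRUE`.
#'
#' @param r Correlation coefficient.
#' @param n Number of pairs (>= 3).
#' @return Two-sided p-value.
#' @export
pearsonP <- function(r, n) {
  stopifnot(n >= 3L, abs(r) <= 1 + 1e-12)
  if (abs(r) >= 1) {
    p <- 0
    attr(p, "degenerate") <- TRUE
    return(p)
  }
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * pt(-abs(t), df = n - 2)
}

#' All pairwise correlations between event rates
#'
#' Computes r and its t-distribution p-value for every unordered pair of the
#' eight event-rate vectors (family birth/death, domain birth/death,
#' universal-family duplication/deletion, universal-domain
#' duplication/deletion), on branch-length-normalized rates. Missing values
#' are removed pairwise.
#'
#' @param events Event table in the packaged schema; counts are normalized
#'   internally via [eventRates()].
#' @return Data.frame `var1`, `var2`, `r`, `n`, `p` (28 rows for the
#'   packaged fixture).
#' @export
correlationMatrix <- function(events) {
  rates <- eventRates(events)
  vars <- c("fam_birth", "fam_death", "dom_birth", "dom_death",
            "ufam_dup", "ufam_del", "udom_dup", "udom_del")
  vars <- intersect(vars, names(rates))
  pairs <- utils::combn(vars, 2)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    x <- rates[[pairs[1, k]]]; y <- rates[[pairs[2, k]]]
    ok <- is.finite(x) & is.finite(y)
    r <- pearsonR(x, y)
    data.frame(var1 = pairs[1, k], var2 = pairs[2, k],
               r = r, n = sum(ok), p = as.numeric(pearsonP(r, sum(ok))),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
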