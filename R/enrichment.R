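# Gene-set over-representation: hypergeometric upper-tail test,
# multiple-testing adjustment, and empirical resampling significance.

#' Upper-tail hypergeometric P value
#'
#' Probability of observing `x` or more query genes inside a set of
#' size `K`, when `n` genes are drawn from a universe of `N` genes:
#' \eqn{P = \sum_{i=x}^{\min(K,n)} \binom{K}{i}\binom{N-K}{n-i} /
#' \binom{N}{n}}.
#'
#' @param N Universe size.
#' @param K Gene-set size within the universe.
#' @param n Query size.
#' @param x Observed overlap.
#' @return The upper-tail P value (1 when `x = 0`).
#' @export
#' @examples
#' hypergeometric_p(N = 10, K = 5, n = 4, x = 4)  # 5/210
hypergeometric_p <- function(N, K, n, x) {
  ok <- x >= 0 & x <= pmin(K, n) & K <= N & n <= N &
    K >= 0 & n >= 0 & N >= 0
  if (any(!ok)) stop("inconsistent hypergeometric counts")
  stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
}

#' Multiple-testing adjustment
#'
#' Bonferroni (`min(1, m p)`) or Benjamini-Hochberg step-up with
#' monotonicity enforcement; output order matches input.
#'
#' @param pvalues Numeric vector of raw P values in (0, 1].
#' @param method `"bonferroni"` or `"BH"`.
#' @return Adjusted P values.
#' @export
adjust_p <- function(pvalues, method = c("bonferroni", "BH")) {
  method <- match.arg(method)
  if (!length(pvalues)) return(numeric(0))
  if (any(pvalues <= 0 | pvalues > 1)) stop("P values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = method)
}

#' Gene-set over-representation test
#'
#' Hypergeometric upper-tail test of every gene set against a query
#' gene list, within a fixed universe (by default the genes of the
#' weighted network).  Sets are restricted to the universe and
#' filtered by size before testing.
#'
#' @param query Character vector of query genes (e.g. consensus module
#'   genes); silently restricted to the universe.
#' @param gene_sets Named list of character vectors ([read_gmt()]).
#' @param universe Character vector of background genes.
#' @param min_size,max_size Within-universe set size bounds (defaults
#'   10 and 250).
#' @param method Adjustment method, `"bonferroni"` (default) or
#'   `"BH"`.
#' @return A data frame `set_name`, `set_size`, `overlap`, `p_hyper`,
#'   `p_adjusted`, sorted by adjusted then raw P.
#' @export
gene_set_enrichment <- function(query, gene_sets, universe,
                                min_size = 10, max_size = 250,
                                method = c("bonferroni", "BH")) {
  method <- match.arg(method)
  universe <- unique(universe)
  query <- intersect(unique(query), universe)
  sets <- lapply(gene_sets, function(s) intersect(unique(s), universe))
  sizes <- lengths(sets)
  keep <- sizes >= min_size & sizes <= max_size
  sets <- sets[keep]
  sizes <- sizes[keep]
  if (!length(sets))
    return(data.frame(set_name = character(0), set_size = integer(0),
                      overlap = integer(0), p_hyper = numeric(0),
                      p_adjusted = numeric(0), stringsAsFactors = FALSE))
  overlap <- vapply(sets, function(s) length(intersect(s, query)), 0L)
  p <- hypergeometric_p(length(universe), sizes, length(query), overlap)
  out <- data.frame(set_name = names(sets), set_size = sizes,
                    overlap = overlap, p_hyper = p,
                    p_adjusted = adjust_p(p, method),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$p_adjusted, out$p_hyper), , drop = FALSE]
}

#' Empirical resampling significance of gene-set enrichment
#'
#' Complements the analytic hypergeometric P: draws `B` random query
#' sets of the real query's size uniformly from the universe, runs the
#' full enrichment test (including size filtering and adjustment) on
#' each, and reports per gene set
#' `P = (1 + #(resample significant)) / (B + 1)` at the given adjusted
#' significance threshold.
#'
#' @param gene_sets Named list of gene sets.
#' @param query_size Size of the observed query.
#' @param universe Background genes.
#' @param B Number of resamples (default 1000).
#' @param threshold Adjusted-P significance threshold inside each
#'   resample (default 0.05); a resampled query counts as significant
#'   for a set when its adjusted P is at most the threshold.
#' @param min_size,max_size,method As in [gene_set_enrichment()].
#' @param seed Optional integer seed.
#' @return A data frame `set_name`, `n_significant`, `p_empirical`.
#' @export
empirical_set_p <- function(gene_sets, query_size, universe, B = 1000,
                            threshold = 0.05, min_size = 10,
                            max_size = 250,
                            method = c("bonferroni", "BH"),
                            seed = NULL) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  universe <- unique(universe)
  N <- length(universe)
  if (query_size > N) stop("query_size exceeds the universe")
  sets <- lapply(gene_sets, function(s) intersect(unique(s), universe))
  sizes <- lengths(sets)
  keep <- sizes >= min_size & sizes <= max_size
  sets <- sets[keep]
  sizes <- sizes[keep]
  if (!length(sets))
    return(data.frame(set_name = character(0), n_significant = integer(0),
                      p_empirical = numeric(0), stringsAsFactors = FALSE))
  # 0/1 incidence matrix: sets x universe
  inc <- matrix(FALSE, length(sets), N)
  uidx <- seq_len(N)
  names(uidx) <- universe
  for (i in seq_along(sets)) inc[i, uidx[sets[[i]]]] <- TRUE
  n_sig <- integer(length(sets))
  for (b in seq_len(B)) {
    draw <- sample.int(N, query_size)
    overlap <- rowSums(inc[, draw, drop = FALSE])
    p <- hypergeometric_p(N, sizes, query_size, overlap)
    n_sig <- n_sig + (adjust_p(p, method) <= threshold)
  }
  data.frame(set_name = names(sets), n_significant = n_sig,
             p_empirical = (1 + n_sig) / (B + 1),
             stringsAsFactors = FALSE, row.names = NULL)
}
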