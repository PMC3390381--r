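# SNP-level inverse-variance fixed-effects meta-analysis with genomic
# control, Cochran Q / I^2 heterogeneity, filtering, and SNP-set
# enrichment.

#' Genomic-control adjustment of study effects
#'
#' Inflated test statistics are deflated by scaling each study's
#' standard errors by \eqn{\sqrt{\lambda}} (equivalently dividing the
#' chi-square statistic by \eqn{\lambda}); effect sizes are untouched.
#'
#' @param se Numeric vector of standard errors.
#' @param lambda Genomic inflation factor (> 0; values below 1 are
#'   accepted with a warning, no deflation gain is implied).
#' @return Adjusted standard errors.
#' @export
#' @examples
#' gc_adjust(0.03, lambda = 1.04)
gc_adjust <- function(se, lambda = 1) {
  if (any(!is.finite(lambda)) || any(lambda <= 0))
    stop("lambda must be positive")
  if (any(lambda < 1))
    warning("lambda < 1 supplied; standard errors will shrink")
  se * sqrt(lambda)
}

#' Fixed-effects inverse-variance meta-analysis of one SNP
#'
#' Combines study effects with weights \eqn{w_i = 1/se_i^2}:
#' \eqn{\beta = \sum w_i \beta_i / \sum w_i},
#' \eqn{se = 1/\sqrt{\sum w_i}}, Wald \eqn{z = \beta/se} with
#' two-sided normal P.  Heterogeneity:
#' \eqn{Q = \sum w_i(\beta_i - \beta)^2},
#' \eqn{I^2 = \max(0, (Q - (k-1))/Q) \times 100},
#' and `p_het` from a chi-square with k-1 degrees of freedom
#' (`p_het = 1` for a single study).
#'
#' @param beta,se Numeric vectors of per-study effects and standard
#'   errors (same length, >= 1 study, se > 0).
#' @param lambda Optional per-study genomic inflation factors applied
#'   via [gc_adjust()] before combining.
#' @return A list with `k_studies`, `beta_meta`, `se_meta`, `z_meta`,
#'   `p_meta`, `Q`, `I2`, `p_het`.
#' @export
fixed_effects_meta <- function(beta, se, lambda = NULL) {
  if (!length(beta)) stop("at least one study is required")
  if (length(beta) != length(se)) stop("beta and se lengths differ")
  if (any(!is.finite(beta)) || any(!is.finite(se)) || any(se <= 0))
    stop("beta must be finite and se positive")
  if (!is.null(lambda)) se <- gc_adjust(se, lambda)
  w <- 1 / se^2
  beta_meta <- sum(w * beta) / sum(w)
  se_meta <- 1 / sqrt(sum(w))
  z <- beta_meta / se_meta
  k <- length(beta)
  Q <- sum(w * (beta - beta_meta)^2)
  I2 <- if (Q > 0) max(0, (Q - (k - 1)) / Q) * 100 else 0
  p_het <- if (k > 1) stats::pchisq(Q, df = k - 1, lower.tail = FALSE) else 1
  list(k_studies = k, beta_meta = beta_meta, se_meta = se_meta,
       z_meta = z, p_meta = 2 * stats::pnorm(-abs(z)),
       Q = Q, I2 = I2, p_het = p_het)
}

.AMBIGUOUS <- c("A\rT", "T\rA", "C\rG", "G\rC")

#' Align per-study allele coding for one SNP
#'
#' Takes the first study's ref/alt alleles as the consensus.  A study
#' reporting the same pair in swapped order has its effect sign
#' flipped; a study whose allele pair cannot be matched is dropped
#' with a report.  Strand-ambiguous SNPs (A/T or C/G) are flagged but
#' retained — same-platform studies resolve strand upstream.
#'
#' @param rows Data frame with one row per study: columns `beta`,
#'   `allele_ref`, `allele_alt` (other columns carried through).
#' @return `rows` with aligned `beta` signs, logical columns `flipped`
#'   and `ambiguous`, and unresolvable rows removed (their count in
#'   attribute `"dropped"`).
#' @export
align_alleles <- function(rows) {
  if (!nrow(rows)) stop("no study rows supplied")
  ref <- toupper(rows$allele_ref)
  alt <- toupper(rows$allele_alt)
  same <- ref == ref[1] & alt == alt[1]
  swap <- ref == alt[1] & alt == ref[1]
  keep <- same | swap
  out <- rows[keep, , drop = FALSE]
  out$beta <- ifelse(swap[keep], -out$beta, out$beta)
  out$flipped <- swap[keep]
  out$ambiguous <- paste(toupper(out$allele_ref), toupper(out$allele_alt),
                         sep = "\r") %in% .AMBIGUOUS
  attr(out, "dropped") <- sum(!keep)
  out
}

#' Meta-analysis table over the SNPs shared by all studies
#'
#' Runs the fixed-effects meta-analysis for every SNP genotyped in all
#' studies (no imputation: SNPs absent from any study are excluded).
#' Within each SNP, alleles are aligned to the first study's coding
#' (sign flips for swapped pairs; studies with unmatchable alleles are
#' dropped for that SNP, and SNPs retained by fewer than two studies
#' are excluded).  Genomic control is applied per study.
#'
#' @param study_tables Named list (>= 2) of SNP association data
#'   frames with `beta` and `se` columns.
#' @param lambdas Optional named or positional numeric vector of
#'   per-study inflation factors (default 1 for all).
#' @return A data frame of class `"meta_result"`: one row per shared
#'   SNP with columns snp_id, chrom, pos, allele_ref, allele_alt,
#'   k_studies, beta_meta, se_meta, z_meta, p_meta, Q, I2, p_het,
#'   ambiguous, plus per-study P columns `p_<study>`.
#' @export
meta_table <- function(study_tables, lambdas = NULL) {
  if (length(study_tables) < 2)
    stop("meta-analysis needs at least two studies")
  if (is.null(names(study_tables)))
    names(study_tables) <- paste0("study", seq_along(study_tables))
  nm <- names(study_tables)
  if (is.null(lambdas)) lambdas <- rep(1, length(study_tables))
  if (!is.null(names(lambdas))) lambdas <- lambdas[nm]
  if (anyNA(lambdas)) stop("lambdas must cover every study")
  for (s in nm) {
    tab <- study_tables[[s]]
    if (!all(c("beta", "se") %in% names(tab)) ||
        anyNA(tab$beta) || anyNA(tab$se))
      stop("study '", s, "' lacks complete beta/se columns")
  }
  shared <- Reduce(intersect, lapply(study_tables, `[[`, "snp_id"))
  if (!length(shared)) stop("no SNPs shared by all studies")
  first <- study_tables[[1]]
  f_idx <- match(shared, first$snp_id)
  has_alleles <- all(vapply(study_tables, function(tab)
    all(c("allele_ref", "allele_alt") %in% names(tab)), TRUE))
  S <- length(nm)
  n <- length(shared)
  betas <- ses <- pvals <- matrix(NA_real_, n, S,
                                  dimnames = list(NULL, nm))
  use <- matrix(TRUE, n, S)
  for (j in seq_len(S)) {
    tab <- study_tables[[j]]
    i <- match(shared, tab$snp_id)
    b <- tab$beta[i]
    if (has_alleles && j > 1) {
      same <- toupper(tab$allele_ref[i]) == toupper(first$allele_ref[f_idx]) &
        toupper(tab$allele_alt[i]) == toupper(first$allele_alt[f_idx])
      swap <- toupper(tab$allele_ref[i]) == toupper(first$allele_alt[f_idx]) &
        toupper(tab$allele_alt[i]) == toupper(first$allele_ref[f_idx])
      b[swap] <- -b[swap]
      use[, j] <- same | swap
    }
    betas[, j] <- b
    ses[, j] <- gc_adjust(tab$se[i], lambdas[j])
    pvals[, j] <- tab$p[i]
  }
  k <- rowSums(use)
  drop_few <- k < 2
  w <- 1 / ses^2
  w[!use] <- 0
  betas0 <- betas
  betas0[!use] <- 0
  sw <- rowSums(w)
  beta_meta <- rowSums(w * betas0) / sw
  se_meta <- 1 / sqrt(sw)
  z <- beta_meta / se_meta
  Q <- rowSums(w * (betas0 - beta_meta)^2 * use)
  I2 <- ifelse(Q > 0, pmax(0, (Q - (k - 1)) / Q) * 100, 0)
  p_het <- stats::pchisq(Q, df = pmax(k - 1, 1), lower.tail = FALSE)
  p_het[k <= 1] <- 1
  ambiguous <- if (has_alleles)
    paste(toupper(first$allele_ref[f_idx]),
          toupper(first$allele_alt[f_idx]), sep = "\r") %in% .AMBIGUOUS
  else rep(NA, n)
  out <- data.frame(
    snp_id = shared,
    chrom = first$chrom[f_idx],
    pos = first$pos[f_idx],
    allele_ref = if (has_alleles) first$allele_ref[f_idx] else NA,
    allele_alt = if (has_alleles) first$allele_alt[f_idx] else NA,
    k_studies = k,
    beta_meta = beta_meta, se_meta = se_meta, z_meta = z,
    p_meta = 2 * stats::pnorm(-abs(z)),
    Q = Q, I2 = I2, p_het = p_het, ambiguous = ambiguous,
    stringsAsFactors = FALSE)
  for (s in nm) out[[paste0("p_", s)]] <- pvals[, s]
  if (any(drop_few)) {
    warning(sum(drop_few),
            " SNP(s) excluded: allele coding unresolvable in all but ",
            "one study")
    out <- out[!drop_few, , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("meta_result", "data.frame")
  out
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("meta-analysis of %d SNPs across %d studies\n",
              nrow(x), max(x$k_studies)))
  cat(sprintf("  p_meta < 0.05: %d; p_meta < 1e-4: %d; p_het < 0.05: %d\n",
              sum(x$p_meta < 0.05), sum(x$p_meta < 1e-4),
              sum(x$p_het < 0.05)))
  invisible(x)
}

#' Filter meta-analysis results
#'
#' Keeps SNPs with `p_meta < p_max` and no substantial between-study
#' heterogeneity (`p_het >= het_min`).
#'
#' @param results A `"meta_result"` data frame (any data frame with
#'   `p_meta` and `p_het` columns works).
#' @param p_max Meta-analysis P threshold (default 1e-4).
#' @param het_min Minimum heterogeneity P to retain (default 0.05).
#' @return The filtered subset, same class.
#' @export
filter_meta <- function(results, p_max = 1e-4, het_min = 0.05) {
  keep <- results$p_meta < p_max & results$p_het >= het_min
  out <- results[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-gene bookkeeping of a (filtered) meta-analysis table
#'
#' Splits a comma- or semicolon-separated gene annotation column into
#' individual symbols and counts SNPs per gene.
#'
#' @param results Data frame with a gene column.
#' @param gene_col Name of the gene column (default `"genes"`).
#' @return A data frame `gene`, `n_snps`, sorted by descending count.
#' @export
meta_gene_summary <- function(results, gene_col = "genes") {
  if (!gene_col %in% names(results))
    stop("no '", gene_col, "' column in results")
  genes <- strsplit(as.character(results[[gene_col]]), "[,;] *")
  flat <- trimws(unlist(genes))
  flat <- flat[nzchar(flat)]
  counts <- sort(table(flat), decreasing = TRUE)
  data.frame(gene = names(counts), n_snps = as.integer(counts),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' SNP-set enrichment of meta-analysis signal
#'
#' Tests whether the SNPs mapped to a gene or module set contain more
#' nominally significant meta-analysis results (`p_meta < alpha`) than
#' equally sized random SNP sets drawn uniformly from all analysed
#' SNPs.  `P = (1 + #(K >= k)) / (B + 1)` where `k` is the observed
#' significant count and `K` the count in a random set.
#'
#' @param results A `"meta_result"` data frame.
#' @param module_snp_ids SNP ids of the set of interest (must all be
#'   in `results`).
#' @param B Number of resamples (default 1000).
#' @param alpha Nominal significance threshold (default 0.05).
#' @param seed Optional integer seed.
#' @return A list with `p`, `observed`, `n_snps`, `n_total`.
#' @export
meta_set_enrichment <- function(results, module_snp_ids, B = 1000,
                                alpha = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  idx <- match(unique(module_snp_ids), results$snp_id)
  if (anyNA(idx))
    stop("module SNP(s) absent from the meta-analysis results")
  n_total <- nrow(results)
  n_draw <- length(idx)
  if (n_draw > n_total) stop("module SNP set larger than the universe")
  sig <- results$p_meta < alpha
  observed <- sum(sig[idx])
  exceed <- 0L
  for (b in seq_len(B)) {
    if (sum(sig[sample.int(n_total, n_draw)]) >= observed)
      exceed <- exceed + 1L
  }
  list(p = (1 + exceed) / (B + 1), observed = observed,
       n_snps = n_draw, n_total = n_total)
}

#' Write a meta-analysis table to TSV
#' @param results A `"meta_result"`.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_meta_results <- function(results, path) {
  .write_tsv(as.data.frame(results), path)
}
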