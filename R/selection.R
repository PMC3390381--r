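# Module selection, bi-directional evaluation, consensus merging, and
# independent-dataset replication.

#' Selection thresholds for assessed modules
#'
#' All seven thresholds default to 0.05: the five discovery-side
#' criteria (score P, gene-length, SNP-density and topology resampling
#' Ps, permutation P) and the two evaluation-side criteria (score P
#' and permutation P recomputed under the second study's weights).
#'
#' @param alpha_zm,alpha_gl,alpha_nsnps,alpha_topo,alpha_emp Discovery
#'   thresholds.
#' @param alpha_zm_eval,alpha_emp_eval Evaluation thresholds.
#' @return A list of class `"selection_criteria"`.
#' @export
selection_criteria <- function(alpha_zm = 0.05, alpha_gl = 0.05,
                               alpha_nsnps = 0.05, alpha_topo = 0.05,
                               alpha_emp = 0.05, alpha_zm_eval = 0.05,
                               alpha_emp_eval = 0.05) {
  crit <- list(alpha_zm = alpha_zm, alpha_gl = alpha_gl,
               alpha_nsnps = alpha_nsnps, alpha_topo = alpha_topo,
               alpha_emp = alpha_emp, alpha_zm_eval = alpha_zm_eval,
               alpha_emp_eval = alpha_emp_eval)
  bad <- !vapply(crit, function(a)
    is.numeric(a) && length(a) == 1 && a > 0 && a < 1, TRUE)
  if (any(bad))
    stop("threshold(s) outside (0, 1): ",
         paste(names(crit)[bad], collapse = ", "))
  structure(crit, class = "selection_criteria")
}

#' Select modules by the combinatorial criteria
#'
#' A module is selected iff all five discovery-side P values lie
#' strictly below their thresholds: score P, both bias-matched
#' resampling Ps, the topology-matched P, and the permutation P.
#'
#' @param assessed A `"module_assessment"` with all five P columns
#'   populated.
#' @param criteria A [selection_criteria()] list.
#' @return The selected subset of `assessed` (same class, member lists
#'   in attribute `"modules"` subset accordingly).
#' @export
select_modules <- function(assessed, criteria = selection_criteria()) {
  need <- c("p_zm", "p_gl", "p_nsnps", "p_topo", "p_emp")
  missing <- setdiff(need, names(assessed))
  if (length(missing))
    stop("assessment is missing column(s): ",
         paste(missing, collapse = ", "))
  if (anyNA(assessed[need]))
    stop("assessment has unpopulated P values; run assess_modules ",
         "with a permutation matrix")
  keep <- assessed$p_zm < criteria$alpha_zm &
    assessed$p_gl < criteria$alpha_gl &
    assessed$p_nsnps < criteria$alpha_nsnps &
    assessed$p_topo < criteria$alpha_topo &
    assessed$p_emp < criteria$alpha_emp
  out <- assessed[keep, , drop = FALSE]
  rownames(out) <- NULL
  mods <- attr(assessed, "modules")
  if (!is.null(mods)) attr(out, "modules") <- mods[assessed$seed[keep]]
  attr(out, "null_fit") <- attr(assessed, "null_fit")
  class(out) <- class(assessed)
  out
}

#' Re-score modules under an evaluation study
#'
#' Each module's fixed gene set is re-scored with the evaluation
#' network's weights.  Module genes absent from the evaluation network
#' are dropped (with `k` reduced); a module losing more than
#' `max_missing` of its genes has its evaluation invalidated (eval Ps
#' set to `NA`, so it cannot pass).  The evaluation-side empirical
#' null is fitted on the evaluation scores of *all* candidate modules,
#' not only preselected ones, for a larger and less biased score pool.
#'
#' @param assessed A `"module_assessment"` (all candidate modules of
#'   the discovery direction).
#' @param eval_net The evaluation study's `"gwas_network"`.
#' @param eval_perm_p Optional permuted gene-wise P matrix of the
#'   evaluation study, for `p_emp_eval`.
#' @param max_missing Maximum tolerated fraction of module genes
#'   missing from the evaluation network (default 0.2).
#' @return `assessed` with added columns `k_eval`, `frac_missing`,
#'   `Zm_eval`, `p_zm_eval`, `p_emp_eval`.
#' @export
evaluate_modules <- function(assessed, eval_net, eval_perm_p = NULL,
                             max_missing = 0.2) {
  mods <- attr(assessed, "modules")
  if (is.null(mods)) stop("assessment carries no module member lists")
  n <- nrow(assessed)
  if (n < 50)
    stop("need at least 50 candidate modules to fit the evaluation null")
  kept <- lapply(mods[assessed$seed], function(g)
    g[g %in% eval_net$genes])
  k_eval <- lengths(kept)
  frac_missing <- 1 - k_eval / assessed$k
  valid <- frac_missing <= max_missing & k_eval > 0
  zm_eval <- rep(NA_real_, n)
  zm_eval[valid] <- vapply(kept[valid], function(g)
    module_score(eval_net, g)$Zm, 0)
  fit <- fit_empirical_null(zm_eval[valid])
  p_zm_eval <- rep(NA_real_, n)
  p_zm_eval[valid] <- score_p(zm_eval[valid], fit)
  p_emp_eval <- rep(NA_real_, n)
  if (!is.null(eval_perm_p) && any(valid))
    p_emp_eval[valid] <- permutation_p(kept[valid], eval_perm_p, eval_net)
  out <- assessed
  out$k_eval <- k_eval
  out$frac_missing <- frac_missing
  out$Zm_eval <- zm_eval
  out$p_zm_eval <- p_zm_eval
  out$p_emp_eval <- p_emp_eval
  attr(out, "eval_null_fit") <- fit
  attr(out, "eval_members") <- kept
  out
}

#' Merge selected modules from both directions into a consensus
#' subnetwork
#'
#' Takes the union of member genes of the modules selected in the two
#' discovery directions, induces the background-network edges on that
#' union, and records per gene which direction(s) and module(s)
#' contributed it.
#'
#' @param direction_a,direction_b Selected modules of each direction: a
#'   `"module_assessment"` subset (with attribute `"modules"`) or a
#'   named list of member-gene vectors.  Either may be empty.
#' @param net The background supplying induced edges: a
#'   `"gwas_network"`, or a raw edge data frame (`gene_a`, `gene_b`)
#'   covering both directions' genes.
#' @param labels Length-2 character vector naming the directions.
#' @return An object of class `"consensus_subnetwork"`: list with
#'   `genes`, `edges` (data frame), `provenance` (data frame gene /
#'   directions / modules).
#' @export
merge_selected <- function(direction_a, direction_b, net,
                           labels = c("a", "b")) {
  get_mods <- function(x) {
    if (is.null(x)) return(list())
    if (inherits(x, "module_assessment")) {
      m <- attr(x, "modules")
      if (is.null(m)) stop("assessment carries no module member lists")
      return(m)
    }
    if (is.list(x)) return(x)
    stop("selected modules must be a module_assessment or a list")
  }
  mods_a <- get_mods(direction_a)
  mods_b <- get_mods(direction_b)
  genes <- sort(unique(c(unlist(mods_a, use.names = FALSE),
                         unlist(mods_b, use.names = FALSE))))
  prov <- lapply(genes, function(g) {
    in_a <- names(mods_a)[vapply(mods_a, function(m) g %in% m, TRUE)]
    in_b <- names(mods_b)[vapply(mods_b, function(m) g %in% m, TRUE)]
    dirs <- c(if (length(in_a)) labels[1], if (length(in_b)) labels[2])
    list(directions = paste(dirs, collapse = ";"),
         modules = paste(c(in_a, in_b), collapse = ";"))
  })
  provenance <- data.frame(
    gene = genes,
    directions = vapply(prov, `[[`, "", "directions"),
    modules = vapply(prov, `[[`, "", "modules"),
    stringsAsFactors = FALSE)
  edges <- data.frame(gene_a = character(0), gene_b = character(0),
                      stringsAsFactors = FALSE)
  if (length(genes)) {
    if (inherits(net, "gwas_network")) {
      present <- intersect(genes, net$genes)
      sub <- igraph::induced_subgraph(net$graph, present)
      el <- igraph::as_edgelist(sub)
      if (nrow(el))
        edges <- data.frame(gene_a = el[, 1], gene_b = el[, 2],
                            stringsAsFactors = FALSE)
    } else if (is.data.frame(net)) {
      keep <- net$gene_a %in% genes & net$gene_b %in% genes
      edges <- net[keep, c("gene_a", "gene_b"), drop = FALSE]
      rownames(edges) <- NULL
    } else stop("net must be a gwas_network or an edge data frame")
  }
  structure(list(genes = genes, edges = edges, provenance = provenance),
            class = "consensus_subnetwork")
}

#' @export
print.consensus_subnetwork <- function(x, ...) {
  cat(sprintf("consensus subnetwork: %d genes, %d induced edges\n",
              length(x$genes), nrow(x$edges)))
  both <- grepl(";", x$provenance$directions)
  cat(sprintf("  genes supported by both directions: %d\n", sum(both)))
  invisible(x)
}

#' Write a consensus subnetwork to TSV
#' @param consensus A `"consensus_subnetwork"`.
#' @param node_path,edge_path Output TSV paths.
#' @param z_tables Optional named list of gene association data frames
#'   (one per study); each study's z weight for every consensus gene is
#'   added to the node table.
#' @return Invisibly, a list of the two paths.
#' @export
write_consensus <- function(consensus, node_path, edge_path,
                            z_tables = NULL) {
  nodes <- consensus$provenance
  if (!is.null(z_tables)) {
    for (nm in names(z_tables)) {
      tab <- z_tables[[nm]]
      p <- tab$p_gene[match(nodes$gene, tab$gene)]
      nodes[[paste0("z_", nm)]] <- ifelse(is.na(p), NA, z_weight(p))
    }
  }
  .write_tsv(nodes, node_path)
  .write_tsv(consensus$edges, edge_path)
  invisible(list(nodes = node_path, edges = edge_path))
}

#' Gene-level replication of consensus genes in an independent study
#'
#' The observed statistic is the number of consensus genes whose
#' gene-wise P in the replication study falls below `alpha`.  The null
#' distribution is built by `B` covariate-stratified resamples of the
#' same number of genes (deciles of gene length or SNP count, matching
#' the consensus set's profile), and the empirical P is the
#' +1-corrected exceedance fraction.
#'
#' @param consensus_genes Character vector of consensus genes.
#' @param replication_assoc Gene association data frame of the
#'   replication study (columns `gene`, `p_gene`, and the covariate).
#' @param covariate `"gene_length"` or `"n_snps"`.
#' @param B Number of resamples (default 10000).
#' @param alpha Nominal significance threshold (default 0.05).
#' @param n_bins Covariate strata (default 10).
#' @param seed Optional integer seed.
#' @return A list with `p` (empirical P), `observed` (significant
#'   consensus genes), `expected` (mean null count), `n_genes` (genes
#'   used), `n_excluded` (consensus genes absent from the replication
#'   table).
#' @export
replicate_gene_level <- function(consensus_genes, replication_assoc,
                                 covariate = c("gene_length", "n_snps"),
                                 B = 10000, alpha = 0.05, n_bins = 10,
                                 seed = NULL) {
  covariate <- match.arg(covariate)
  if (!is.null(seed)) set.seed(seed)
  v <- replication_assoc[[covariate]]
  if (is.null(v))
    stop("replication table has no '", covariate, "' column")
  ok <- !is.na(v) & !is.na(replication_assoc$p_gene)
  tab <- replication_assoc[ok, , drop = FALSE]
  idx <- match(consensus_genes, tab$gene)
  n_excluded <- sum(is.na(idx))
  if (n_excluded)
    warning(n_excluded, " consensus gene(s) absent from the ",
            "replication table were excluded")
  idx <- idx[!is.na(idx)]
  if (!length(idx)) stop("no consensus genes present in the replication table")
  sig <- as.numeric(tab$p_gene < alpha)
  bins <- .quantile_bins(tab[[covariate]], n_bins = n_bins)
  p <- .stratified_empirical_p(sig, bins, list(idx), B,
                               scale_sqrt_k = FALSE,
                               bin_label = paste(covariate, "decile"))
  list(p = unname(p), observed = sum(sig[idx]),
       expected = alpha * length(idx), n_genes = length(idx),
       n_excluded = n_excluded)
}

#' SNP-level replication of consensus genes in an independent study
#'
#' Counts the significant SNPs (replication P < `alpha`) among the
#' SNPs mapped to consensus genes, and compares against `B` uniform
#' draws of equally many SNPs from all genotyped SNPs of the
#' replication study.
#'
#' @param consensus_genes Character vector of consensus genes.
#' @param replication_snps SNP association data frame of the
#'   replication study.
#' @param mapping SNP-to-gene mapping over `replication_snps` (from
#'   [map_snps_to_genes()]).
#' @param B Number of resamples (default 10000).
#' @param alpha Nominal SNP significance threshold (default 0.05).
#' @param seed Optional integer seed.
#' @return A list with `p`, `observed`, `n_snps` (SNPs in consensus
#'   genes), `n_total` (all genotyped SNPs).
#' @export
replicate_snp_level <- function(consensus_genes, replication_snps,
                                mapping, B = 10000, alpha = 0.05,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  snp_ids <- unique(mapping$snp_id[mapping$gene %in% consensus_genes])
  idx <- match(snp_ids, replication_snps$snp_id)
  idx <- idx[!is.na(idx)]
  if (!length(idx)) stop("no SNPs map to the consensus genes")
  sig <- replication_snps$p < alpha
  n_total <- nrow(replication_snps)
  n_draw <- length(idx)
  observed <- sum(sig[idx])
  exceed <- 0L
  for (b in seq_len(B)) {
    if (sum(sig[sample.int(n_total, n_draw)]) >= observed)
      exceed <- exceed + 1L
  }
  list(p = (1 + exceed) / (B + 1), observed = observed,
       n_snps = n_draw, n_total = n_total)
}
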