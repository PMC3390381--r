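# GWAS-weighted interaction network and module scoring.
#
# Node weights are z_i = qnorm(1 - p_i) from the gene-wise P values;
# the module score is Zm = sum(z_i) / sqrt(k).  The network object keeps
# an integer adjacency list alongside the igraph so the greedy search
# and the resampling nulls stay fast.

#' Convert a P value to a z-score node weight
#'
#' `z_weight(p)` is the upper-tail standard-normal quantile of `p`,
#' i.e. the value z with `P(Z > z) = p`.  Small P values give large
#' positive weights; `p = 0.5` gives 0.  P values are clamped into
#' `[clamp_eps, 1 - clamp_eps]` before transformation so extreme inputs
#' stay finite; the clamp is far below any realistic GWAS minimum.
#'
#' @param p Numeric vector of P values in (0, 1].
#' @param clamp_eps Clamping bound (default `1e-15`).
#' @return Numeric vector of z weights, strictly decreasing in `p`.
#' @export
#' @examples
#' z_weight(c(0.5, 0.025, 0.975))
z_weight <- function(p, clamp_eps = 1e-15) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("P values must lie in (0, 1]")
  p <- pmin(pmax(p, clamp_eps), 1 - clamp_eps)
  stats::qnorm(p, lower.tail = FALSE)
}

#' Build a GWAS-weighted interaction network
#'
#' Retains only genes present in both the PPI edge list and the gene
#' association table, induces the PPI edges on that intersection, and
#' weights every node by [z_weight()] of its gene-wise P value.  Genes
#' left with no edge after induction are kept as isolated nodes (they
#' can only yield singleton modules downstream).
#'
#' @param edges Data frame of undirected edges (columns `gene_a`,
#'   `gene_b`), e.g. from [read_ppi_edges()] or [simulate_network()].
#' @param gene_assoc Gene association data frame from [gene_wise_p()]
#'   (columns `gene`, `p_gene`; `n_snps`/`gene_length` carried along
#'   when present).
#' @param clamp_eps Passed to [z_weight()].
#' @return An object of class `"gwas_network"`: a list with elements
#'   `graph` (igraph), `genes`, `z`, `degree` (named numeric vectors),
#'   `adj` (integer adjacency list) and `assoc` (per-node covariates).
#' @export
build_weighted_network <- function(edges, gene_assoc, clamp_eps = 1e-15) {
  if (!nrow(edges)) stop("empty edge list")
  if (!nrow(gene_assoc)) stop("empty gene association table")
  ppi_genes <- unique(c(edges$gene_a, edges$gene_b))
  common <- sort(intersect(ppi_genes, gene_assoc$gene))
  if (!length(common))
    stop("no genes shared between the PPI network and the GWAS table; ",
         "check that both use the same gene symbol namespace")
  keep <- edges$gene_a %in% common & edges$gene_b %in% common
  g <- igraph::graph_from_data_frame(edges[keep, c("gene_a", "gene_b")],
                                     directed = FALSE, vertices = common)
  g <- igraph::simplify(g)
  genes <- igraph::V(g)$name
  assoc <- gene_assoc[match(genes, gene_assoc$gene), , drop = FALSE]
  rownames(assoc) <- NULL
  z <- z_weight(assoc$p_gene, clamp_eps = clamp_eps)
  names(z) <- genes
  deg <- igraph::degree(g)
  adj <- lapply(igraph::as_adj_list(g), as.integer)
  names(adj) <- NULL
  structure(list(graph = g, genes = genes, z = z, degree = deg,
                 adj = adj, assoc = assoc),
            class = "gwas_network")
}

#' @export
print.gwas_network <- function(x, ...) {
  cat("GWAS-weighted interaction network\n")
  cat("  nodes:", length(x$genes),
      " edges:", igraph::ecount(x$graph), "\n")
  cat("  z range: [", sprintf("%.3f", min(x$z)), ",",
      sprintf("%.3f", max(x$z)), "]\n")
  invisible(x)
}

.check_members <- function(net, genes) {
  idx <- match(genes, net$genes)
  if (anyNA(idx))
    stop("gene(s) not in the network: ",
         paste(genes[is.na(idx)], collapse = ", "))
  idx
}

#' Score a gene module
#'
#' The module score is \eqn{Z_m = \sum_i z_i / \sqrt{k}} where the sum
#' runs over the k member genes' node weights.  It is independent of
#' member ordering.
#'
#' @param net A `"gwas_network"`.
#' @param genes Character vector of member genes (nonempty, all in the
#'   network).
#' @return An object of class `"module_score"`: list with `genes`,
#'   `k`, `z_sum`, `Zm`.
#' @export
module_score <- function(net, genes) {
  if (!length(genes)) stop("module must contain at least one gene")
  idx <- .check_members(net, genes)
  z_sum <- sum(net$z[idx])
  k <- length(idx)
  structure(list(genes = genes, k = k, z_sum = z_sum,
                 Zm = z_sum / sqrt(k)),
            class = "module_score")
}

#' @export
print.module_score <- function(x, ...) {
  cat(sprintf("module score Zm = %.4f (k = %d, sum z = %.4f)\n",
              x$Zm, x$k, x$z_sum))
  invisible(x)
}

# Integer-index neighborhood: all non-member nodes within d hops of the
# member set (BFS on the adjacency list).
.neighborhood_idx <- function(net, idx, d) {
  n <- length(net$genes)
  seen <- logical(n)
  seen[idx] <- TRUE
  frontier <- idx
  out <- integer(0)
  for (step in seq_len(d)) {
    nxt <- unlist(net$adj[frontier], use.names = FALSE)
    if (!length(nxt)) break
    nxt <- unique(nxt[!seen[nxt]])
    if (!length(nxt)) break
    seen[nxt] <- TRUE
    out <- c(out, nxt)
    frontier <- nxt
  }
  out
}

#' Candidate neighborhood of a module
#'
#' All non-member genes whose shortest-path distance (unweighted, BFS)
#' to the nearest module member is at most `d`.
#'
#' @param net A `"gwas_network"`.
#' @param genes Member genes.
#' @param d Hop distance (>= 1, default 2).
#' @return Character vector of candidate genes (possibly empty).
#' @export
neighborhood_genes <- function(net, genes, d = 2) {
  if (d < 1) stop("d must be >= 1")
  idx <- .check_members(net, genes)
  net$genes[.neighborhood_idx(net, idx, d)]
}

#' Serialize a weighted network to TSV
#'
#' Writes a node table (gene, z, degree) and an edge table.
#'
#' @param net A `"gwas_network"`.
#' @param node_path,edge_path Output TSV paths.
#' @return Invisibly, a list of the two paths.
#' @export
write_network <- function(net, node_path, edge_path) {
  nodes <- data.frame(gene = net$genes, z = unname(net$z),
                      degree = unname(net$degree),
                      stringsAsFactors = FALSE)
  el <- igraph::as_edgelist(net$graph)
  edges <- data.frame(gene_a = el[, 1], gene_b = el[, 2],
                      stringsAsFactors = FALSE)
  .write_tsv(nodes, node_path)
  .write_tsv(edges, edge_path)
  invisible(list(nodes = node_path, edges = edge_path))
}
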