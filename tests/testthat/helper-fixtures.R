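# Fixtures are built in code; nothing is read from disk except files a
# test writes itself.

# Tiny weighted network from an edge string like "A-B,B-C" and a named
# vector of gene-wise P values (genes absent from `p` get p = 0.5).
make_net <- function(edge_str, p, extra_genes = character(0),
                     gene_length = NULL, n_snps = NULL) {
  pairs <- strsplit(strsplit(edge_str, ",")[[1]], "-")
  edges <- data.frame(gene_a = vapply(pairs, `[[`, "", 1),
                      gene_b = vapply(pairs, `[[`, "", 2),
                      stringsAsFactors = FALSE)
  genes <- sort(unique(c(edges$gene_a, edges$gene_b, names(p),
                         extra_genes)))
  pv <- rep(0.5, length(genes))
  names(pv) <- genes
  pv[names(p)] <- p
  assoc <- data.frame(gene = genes, p_gene = unname(pv),
                      best_snp = paste0("rs", seq_along(genes)),
                      n_snps = if (is.null(n_snps)) rep(1L, length(genes))
                               else n_snps[genes],
                      gene_length = if (is.null(gene_length))
                        rep(1000L, length(genes)) else gene_length[genes],
                      stringsAsFactors = FALSE)
  build_weighted_network(edges, assoc)
}

# Network whose node weights are set directly from z scores (inverted
# through the normal CDF so build_weighted_network reproduces them).
make_net_z <- function(edge_str, z, ...) {
  make_net(edge_str, p = stats::pnorm(z, lower.tail = FALSE), ...)
}

# Random scale-free test network with uniform gene-wise P values and
# log-normal length / Poisson SNP covariates.
random_uniform_net <- function(n = 100, m = 2, seed = 1) {
  set.seed(seed)
  edges <- simulate_network(n = n, m = m, seed = seed)
  genes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  len <- pmax(200L, as.integer(round(stats::rlnorm(length(genes),
                                                   log(20000), 0.8))))
  assoc <- data.frame(gene = genes,
                      p_gene = stats::runif(length(genes)),
                      best_snp = paste0("rs", seq_along(genes)),
                      n_snps = 1L + stats::rpois(length(genes), 5),
                      gene_length = len,
                      stringsAsFactors = FALSE)
  build_weighted_network(edges, assoc)
}

# Brute-force d-hop neighborhood via igraph shortest paths (oracle).
bfs_neighborhood_oracle <- function(net, genes, d) {
  dist <- igraph::distances(net$graph,
                            v = setdiff(net$genes, genes),
                            to = genes)
  rownames(dist)[apply(dist, 1, min) <= d]
}

# Independent standard-normal upper quantile via root finding (oracle
# for z_weight, avoiding qnorm).
quantile_oracle <- function(p) {
  vapply(p, function(pp)
    stats::uniroot(function(z) stats::pnorm(z, lower.tail = FALSE) - pp,
                   c(-40, 40), tol = 1e-12)$root, 0)
}

# Write a data.frame as TSV into a temp file, return the path.
tsv_fixture <- function(df) {
  f <- tempfile(fileext = ".tsv")
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  f
}

`%||%` <- function(a, b) if (is.null(a)) b else a
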