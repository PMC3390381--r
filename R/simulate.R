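# Synthetic data with known ground truth: scale-free networks,
# multi-study GWAS summary statistics with a planted high-signal
# module, permutation matrices, and gene-set collections.  Effects are
# injected at the SNP level so the best-SNP gene summarisation and its
# gene-length/SNP-density biases are exercised honestly.

#' Specification of a synthetic study system
#'
#' Bundles every knob of the generator.  Defaults describe the
#' "default" preset: a 1000-gene scale-free network (3 attachments per
#' node), a planted connected 10-gene module whose SNP z-scores are
#' shifted by 3, two studies that both carry the planted signal,
#' log-normal gene lengths around 20 kb, and 0.3 array SNPs per kb.
#'
#' @param n_genes Number of genes/nodes (>= 10).
#' @param m Edges attached per new node in the preferential-attachment
#'   construction (total edges = `m * (n_genes - m)`).
#' @param planted_size Genes in the planted module (0 disables).
#' @param planted_effect Mean shift added to the planted genes' SNP
#'   z-scores.
#' @param n_studies Number of simulated studies.
#' @param shared_fraction Fraction of studies carrying the planted
#'   signal (1 = all; the first `ceil(shared_fraction * n_studies)`
#'   studies are causal).
#' @param length_meanlog,length_sdlog Log-normal parameters of gene
#'   length in base pairs.
#' @param snp_rate Expected genotyped SNPs per kb of gene length.
#' @param n_cases Nominal per-study sample size entering the standard
#'   error model \eqn{se = 1/\sqrt{2 N \cdot maf(1-maf)}} with
#'   \eqn{maf \sim U(0.05, 0.5)}.
#' @param n_permutations Columns of the permutation matrix.
#' @param seed Integer seed; every simulation step derives from it.
#' @return A list of class `"simulation_spec"`.
#' @export
simulation_spec <- function(n_genes = 1000, m = 3, planted_size = 10,
                            planted_effect = 3, n_studies = 2,
                            shared_fraction = 1,
                            length_meanlog = log(20000),
                            length_sdlog = 0.8, snp_rate = 0.3,
                            n_cases = 2000, n_permutations = 1000,
                            seed = 1) {
  spec <- list(n_genes = n_genes, m = m, planted_size = planted_size,
               planted_effect = planted_effect, n_studies = n_studies,
               shared_fraction = shared_fraction,
               length_meanlog = length_meanlog,
               length_sdlog = length_sdlog, snp_rate = snp_rate,
               n_cases = n_cases, n_permutations = n_permutations,
               seed = as.integer(seed))
  if (spec$n_genes < 10) stop("n_genes must be at least 10")
  if (spec$m < 1 || spec$m >= spec$n_genes)
    stop("m must lie in [1, n_genes)")
  if (spec$planted_size > spec$n_genes)
    stop("planted module larger than the gene universe")
  if (spec$shared_fraction < 0 || spec$shared_fraction > 1)
    stop("shared_fraction must lie in [0, 1]")
  counts <- c(spec$n_studies, spec$n_permutations, spec$n_cases,
              spec$snp_rate)
  if (any(counts <= 0)) stop("counts and rates must be positive")
  structure(spec, class = "simulation_spec")
}

#' Named simulation presets
#'
#' `"toy"` (50 genes, runs in well under a second), `"default"` (1000
#' genes), and `"paper-scale"` (10377 genes, 5 attachments per node,
#' approaching the size of an experimentally supported human
#' interactome).
#'
#' @param name Preset name.
#' @param ... Overrides passed on to [simulation_spec()].
#' @return A `"simulation_spec"`.
#' @export
simulation_preset <- function(name = c("toy", "default", "paper-scale"),
                              ...) {
  name <- match.arg(name)
  base <- switch(name,
    "toy" = list(n_genes = 50, m = 2, planted_size = 5,
                 n_permutations = 200),
    "default" = list(),
    "paper-scale" = list(n_genes = 10377, m = 5))
  do.call(simulation_spec, utils::modifyList(base, list(...)))
}

#' Simulate a scale-free interaction network
#'
#' Preferential attachment: `m` seed vertices start empty; each new
#' vertex attaches `m` distinct edges to existing vertices chosen with
#' probability proportional to degree + 1.  The first added vertex
#' connects to all seeds, so the graph is connected, has exactly
#' `m * (n - m)` edges, and a heavy-tailed degree distribution.
#'
#' @param spec A `"simulation_spec"` (only `n_genes`, `m`, `seed`
#'   used), or `NULL` to use `n`/`m`/`seed` directly.
#' @param n,m,seed Direct parameters when `spec` is `NULL`.
#' @return Edge data frame (`gene_a`, `gene_b`) over genes named
#'   `G0001, G0002, ...`.
#' @export
simulate_network <- function(spec = NULL, n = 1000, m = 3, seed = 1) {
  if (!is.null(spec)) {
    stopifnot(inherits(spec, "simulation_spec"))
    n <- spec$n_genes; m <- spec$m; seed <- spec$seed
  }
  if (n < 10) stop("need at least 10 nodes")
  if (m < 1 || m >= n) stop("m must lie in [1, n)")
  set.seed(seed)
  deg <- integer(n)
  from <- integer(m * (n - m))
  to <- integer(m * (n - m))
  e <- 0L
  for (v in (m + 1L):n) {
    existing <- seq_len(v - 1L)
    targets <- if (v - 1L <= m) existing
               else sample(existing, m, prob = deg[existing] + 1)
    for (t in targets) {
      e <- e + 1L
      from[e] <- v; to[e] <- t
      deg[v] <- deg[v] + 1L
      deg[t] <- deg[t] + 1L
    }
  }
  width <- max(4L, nchar(as.character(n)))
  nm <- sprintf(paste0("G%0", width, "d"), seq_len(n))
  data.frame(gene_a = pmin(nm[from[seq_len(e)]], nm[to[seq_len(e)]]),
             gene_b = pmax(nm[from[seq_len(e)]], nm[to[seq_len(e)]]),
             stringsAsFactors = FALSE)
}

# Random connected gene set: BFS from a random seed, visiting
# neighbors in random order, until `size` nodes are collected.
.connected_subset <- function(adj, size, seed_node = NULL) {
  n <- length(adj)
  start <- if (is.null(seed_node)) sample.int(n, 1) else seed_node
  seen <- logical(n)
  seen[start] <- TRUE
  members <- start
  frontier <- start
  while (length(members) < size && length(frontier)) {
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[!seen[nxt]]
    if (!length(nxt)) break
    nxt <- sample(nxt)
    take <- utils::head(nxt, size - length(members))
    seen[take] <- TRUE
    members <- c(members, take)
    frontier <- take
  }
  members
}

#' Simulate multi-study GWAS summary statistics over a network
#'
#' Gene lengths are log-normal; each gene carries
#' `1 + Poisson(length_kb * snp_rate)` SNPs placed inside its body;
#' genes are laid out on 22 chromosomes with gaps wider than twice the
#' default mapping flank, so each SNP belongs to exactly one gene.
#' Null SNP z-scores are standard normal (two-sided P); the planted
#' module is a random connected subgraph whose SNP z-scores are
#' shifted by `planted_effect` in every causal study.  Betas and
#' standard errors are emitted consistently with `z = beta/se` under
#' the nominal sample-size/MAF error model, so P values recompute
#' exactly from beta and se.
#'
#' @param spec A `"simulation_spec"`.
#' @param edges Network edge data frame from [simulate_network()]
#'   (generated from `spec` when omitted).
#' @return A list of class `"simulated_gwas"`: `annotation` (gene
#'   table), `studies` (named list of SNP association tables),
#'   `mapping` (snp_id/gene), `planted_genes`, `causal_studies`,
#'   `edges`, `spec`.
#' @export
simulate_gwas <- function(spec, edges = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (is.null(edges)) edges <- simulate_network(spec)
  set.seed(spec$seed + 1L)
  genes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  n <- length(genes)
  len <- pmax(200L, as.integer(round(stats::rlnorm(
    n, spec$length_meanlog, spec$length_sdlog))))
  chrom <- as.character(rep_len(1:22, n))
  start <- integer(n)
  gap <- 50000L
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    start[i] <- cumsum(c(1L, utils::head(len[i], -1) + gap))
  }
  annotation <- data.frame(gene = genes, chrom = chrom, start = start,
                           end = start + len - 1L, length = len,
                           stringsAsFactors = FALSE)
  n_snps <- 1L + stats::rpois(n, len / 1000 * spec$snp_rate)
  gene_of <- rep(seq_len(n), n_snps)
  total <- sum(n_snps)
  pos <- integer(total)
  off <- 0L
  for (i in seq_len(n)) {
    pos[off + seq_len(n_snps[i])] <-
      sort(sample.int(len[i], n_snps[i])) + start[i] - 1L
    off <- off + n_snps[i]
  }
  snp_id <- sprintf("rs%06d", seq_len(total))
  bases <- c("A", "C", "G", "T")
  allele_ref <- sample(bases, total, replace = TRUE)
  allele_alt <- vapply(allele_ref, function(a)
    sample(setdiff(bases, a), 1), "")
  maf <- stats::runif(total, 0.05, 0.5)
  se <- 1 / sqrt(2 * spec$n_cases * maf * (1 - maf))
  # planted connected module on the network
  adj <- lapply(igraph::as_adj_list(igraph::graph_from_data_frame(
    edges, directed = FALSE, vertices = genes)), as.integer)
  planted_idx <- if (spec$planted_size > 0)
    .connected_subset(adj, spec$planted_size) else integer(0)
  planted_genes <- sort(genes[planted_idx])
  n_causal <- ceiling(spec$shared_fraction * spec$n_studies)
  causal_studies <- paste0("study", seq_len(spec$n_studies))[
    seq_len(n_causal)]
  planted_snp <- gene_of %in% planted_idx
  studies <- vector("list", spec$n_studies)
  names(studies) <- paste0("study", seq_len(spec$n_studies))
  for (s in seq_len(spec$n_studies)) {
    z <- stats::rnorm(total)
    if (names(studies)[s] %in% causal_studies && any(planted_snp))
      z[planted_snp] <- z[planted_snp] + spec$planted_effect
    studies[[s]] <- data.frame(
      snp_id = snp_id, chrom = chrom[gene_of], pos = pos,
      allele_ref = allele_ref, allele_alt = allele_alt,
      beta = z * se, se = se,
      p = 2 * stats::pnorm(-abs(z)),
      stringsAsFactors = FALSE)
  }
  structure(list(annotation = annotation, studies = studies,
                 mapping = data.frame(snp_id = snp_id,
                                      gene = genes[gene_of],
                                      stringsAsFactors = FALSE),
                 planted_genes = planted_genes,
                 causal_studies = causal_studies,
                 edges = edges, spec = spec),
            class = "simulated_gwas")
}

#' @export
print.simulated_gwas <- function(x, ...) {
  cat(sprintf(
    "simulated GWAS system: %d genes, %d SNPs, %d studies (seed %d)\n",
    nrow(x$annotation), nrow(x$mapping), length(x$studies),
    x$spec$seed))
  if (length(x$planted_genes))
    cat("  planted module:", paste(x$planted_genes, collapse = ", "),
        sprintf("(effect %g in %s)\n", x$spec$planted_effect,
                paste(x$causal_studies, collapse = ", ")))
  invisible(x)
}

#' Simulate a permutation matrix of gene-wise P values
#'
#' Stand-in for case/control label shuffling when genotypes are not
#' available: each permutation column is a fresh draw under the global
#' null with the same per-gene SNP counts.  The minimum of `n`
#' independent uniform SNP P values is Beta(1, n), so columns are
#' sampled directly as `1 - (1 - U)^(1/n)`, preserving the best-SNP
#' min-P structure exactly.
#'
#' @param sim A `"simulated_gwas"` (supplies per-gene SNP counts), or
#'   `NULL` to use `n_snps_per_gene`.
#' @param n_permutations Number of columns (defaults to the spec's).
#' @param n_snps_per_gene Named integer vector of mapped-SNP counts
#'   when `sim` is `NULL`.
#' @param seed Integer seed (defaults to the spec's seed + 2).
#' @return Numeric matrix, genes in rows (rownames set), one column
#'   per permutation.
#' @export
simulate_permutations <- function(sim = NULL, n_permutations = NULL,
                                  n_snps_per_gene = NULL, seed = NULL) {
  if (!is.null(sim)) {
    stopifnot(inherits(sim, "simulated_gwas"))
    cnt <- table(sim$mapping$gene)
    n_snps_per_gene <- structure(as.integer(cnt), names = names(cnt))
    if (is.null(n_permutations))
      n_permutations <- sim$spec$n_permutations
    if (is.null(seed)) seed <- sim$spec$seed + 2L
  }
  if (is.null(n_snps_per_gene) || is.null(names(n_snps_per_gene)))
    stop("per-gene SNP counts (named) are required")
  if (is.null(n_permutations)) n_permutations <- 1000L
  if (is.null(seed)) seed <- 1L
  set.seed(seed)
  g <- length(n_snps_per_gene)
  u <- matrix(stats::runif(g * n_permutations), nrow = g)
  p <- 1 - (1 - u)^(1 / as.numeric(n_snps_per_gene))
  rownames(p) <- names(n_snps_per_gene)
  p
}

#' Simulate gene-set collections with one planted set
#'
#' Random sets of uniform sizes plus, when planted genes are given,
#' one set (`"PLANTED_SET"`) containing the requested fraction of the
#' planted genes topped up with random fillers.
#'
#' @param network_genes Universe of genes to draw from.
#' @param n_sets Number of random sets (default 50).
#' @param size_range Inclusive set-size bounds (default c(10, 50)).
#' @param planted_genes Optional character vector of planted genes.
#' @param planted_overlap Fraction of planted genes included in the
#'   planted set (default 0.8).
#' @param seed Integer seed.
#' @return Named list of gene sets (GMT-compatible, see
#'   [write_gmt()]).
#' @export
simulate_gene_sets <- function(network_genes, n_sets = 50,
                               size_range = c(10, 50),
                               planted_genes = NULL,
                               planted_overlap = 0.8, seed = 1) {
  set.seed(seed)
  sizes <- sample(size_range[1]:size_range[2], n_sets, replace = TRUE)
  sets <- lapply(sizes, function(k) sample(network_genes, k))
  names(sets) <- sprintf("SET_%03d", seq_len(n_sets))
  if (!is.null(planted_genes) && length(planted_genes)) {
    take <- max(1L, round(planted_overlap * length(planted_genes)))
    core <- sample(planted_genes, take)
    fill_n <- max(0L, size_range[1] - take)
    filler <- sample(setdiff(network_genes, core),
                     fill_n + 5L)
    sets$PLANTED_SET <- unique(c(core, filler))
  }
  sets
}

#' Write a complete ready-to-run synthetic study directory
#'
#' Emits the TSV/GMT dialects the rest of the package reads: network
#' edges, gene annotation, one SNP association table per study, a
#' permutation matrix per study, a gene-set GMT, and a JSON manifest
#' recording the spec, seeds, and the ground-truth planted genes.
#'
#' @param spec A `"simulation_spec"`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest as a list.
#' @export
simulate_study_set <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_gwas(spec)
  .write_tsv(sim$edges, file.path(dir, "ppi_edges.tsv"))
  .write_tsv(sim$annotation, file.path(dir, "gene_annotation.tsv"))
  for (s in names(sim$studies))
    .write_tsv(sim$studies[[s]], file.path(dir, paste0(s, "_snps.tsv")))
  for (i in seq_along(sim$studies)) {
    perm <- simulate_permutations(sim, seed = spec$seed + 2L + i)
    df <- data.frame(gene = rownames(perm), perm, check.names = FALSE)
    names(df) <- c("gene", sprintf("perm%04d", seq_len(ncol(perm))))
    .write_tsv(df, file.path(dir, paste0(names(sim$studies)[i],
                                         "_permutations.tsv")))
  }
  sets <- simulate_gene_sets(sort(unique(c(sim$edges$gene_a,
                                           sim$edges$gene_b))),
                             planted_genes = sim$planted_genes,
                             seed = spec$seed + 9L)
  write_gmt(sets, file.path(dir, "gene_sets.gmt"))
  manifest <- list(spec = unclass(spec),
                   planted_genes = sim$planted_genes,
                   causal_studies = sim$causal_studies,
                   files = list(
                     edges = "ppi_edges.tsv",
                     annotation = "gene_annotation.tsv",
                     studies = paste0(names(sim$studies), "_snps.tsv"),
                     permutations = paste0(names(sim$studies),
                                           "_permutations.tsv"),
                     gene_sets = "gene_sets.gmt"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a permutation matrix written by [simulate_study_set()]
#' @param path TSV with a `gene` column followed by permutation
#'   columns.
#' @return Numeric matrix with gene rownames.
#' @export
read_permutation_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"gene" %in% names(df)) stop("permutation table needs a 'gene' column")
  m <- as.matrix(df[setdiff(names(df), "gene")])
  rownames(m) <- df$gene
  storage.mode(m) <- "double"
  m
}
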