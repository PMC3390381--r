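# Bi-directional discovery/evaluation pipeline: each of two studies is
# used once to find modules and once to re-score the other's modules;
# only doubly supported modules enter the consensus subnetwork.

.as_gene_assoc <- function(x, edges, annotation, flank) {
  if ("p_gene" %in% names(x)) return(x)
  mapping <- map_snps_to_genes(x, annotation, flank = flank)
  gene_wise_p(x, mapping, annotation)
}

#' Run the full bi-directional module-discovery pipeline
#'
#' For each of the two studies: collapse SNP P values to gene-wise P
#' values (best SNP within the flank), build the GWAS-weighted
#' network, grow a module from every seed, assess all modules (score
#' P, gene-length/SNP-density resampling, degree-matched
#' randomization, permutation), select by the combinatorial criteria,
#' and re-score the candidates under the other study's weights.  A
#' module survives a direction iff it passes all five discovery
#' criteria and both evaluation criteria; the two surviving lists are
#' merged into the consensus subnetwork.
#'
#' @param studies Named list of exactly two SNP association tables
#'   (or gene association tables carrying `p_gene`, `n_snps`,
#'   `gene_length`).
#' @param edges PPI edge data frame.
#' @param annotation Gene annotation data frame (needed when SNP
#'   tables are given).
#' @param perm_p Named list of permuted gene-wise P matrices, same
#'   names as `studies`.
#' @param flank SNP-to-gene mapping flank in bp (default 20000).
#' @param r,d Greedy-search parameters (defaults 0.1 and 2).
#' @param B Resamples per assessment test (default 1000).
#' @param n_bins Covariate strata for weighted resampling.
#' @param criteria A [selection_criteria()] list.
#' @param max_missing Passed to [evaluate_modules()].
#' @param seed Optional integer seed; the two directions derive
#'   distinct sub-seeds from it.
#' @param verbose Print per-stage progress.
#' @return An object of class `"dms_pipeline"`: list with
#'   `directions` (per direction: the evaluated assessment table, the
#'   selected subset, and the funnel counts), `consensus`
#'   (a `"consensus_subnetwork"`), `gene_assoc`, `networks`, and the
#'   parameters.
#' @export
dms_pipeline <- function(studies, edges, annotation = NULL,
                         perm_p = NULL, flank = 20000, r = 0.1, d = 2,
                         B = 1000, n_bins = 10,
                         criteria = selection_criteria(),
                         max_missing = 0.2, seed = NULL,
                         verbose = FALSE) {
  if (length(studies) != 2)
    stop("the bi-directional pipeline needs exactly two studies")
  if (is.null(names(studies)))
    names(studies) <- c("study1", "study2")
  nm <- names(studies)
  say <- function(...) if (verbose) message(...)
  say("summarising gene-wise P values and building networks")
  assoc <- lapply(studies, .as_gene_assoc, edges = edges,
                  annotation = annotation, flank = flank)
  nets <- lapply(assoc, function(a) build_weighted_network(edges, a))
  run_direction <- function(disc, eval, dir_seed) {
    say("  direction ", disc, " -> ", eval)
    res <- dms_search(nets[[disc]], r = r, d = d)
    assessed <- assess_modules(res, nets[[disc]],
                               perm_p = perm_p[[disc]], B = B,
                               n_bins = n_bins, seed = dir_seed)
    evald <- evaluate_modules(assessed, nets[[eval]],
                              eval_perm_p = perm_p[[eval]],
                              max_missing = max_missing)
    pass5 <- evald$p_zm < criteria$alpha_zm &
      evald$p_gl < criteria$alpha_gl &
      evald$p_nsnps < criteria$alpha_nsnps &
      evald$p_topo < criteria$alpha_topo &
      evald$p_emp < criteria$alpha_emp
    pass_zm_eval <- pass5 & !is.na(evald$p_zm_eval) &
      evald$p_zm_eval < criteria$alpha_zm_eval
    pass_all <- pass_zm_eval & !is.na(evald$p_emp_eval) &
      evald$p_emp_eval < criteria$alpha_emp_eval
    selected <- evald[pass_all, , drop = FALSE]
    rownames(selected) <- NULL
    mods <- attr(evald, "modules")
    attr(selected, "modules") <- mods[selected$seed]
    class(selected) <- class(evald)
    funnel <- c(modules = nrow(evald),
                pass_combinatorial = sum(pass5),
                pass_score_eval = sum(pass_zm_eval),
                pass_all_eval = sum(pass_all))
    say(sprintf("    %d modules -> %d combinatorial -> %d + eval score -> %d final",
                funnel[1], funnel[2], funnel[3], funnel[4]))
    list(discovery = disc, evaluation = eval, assessed = evald,
         selected = selected, funnel = funnel)
  }
  seeds <- if (is.null(seed)) list(NULL, NULL)
           else list(seed, seed + 104729L)
  dir_a <- run_direction(nm[1], nm[2], seeds[[1]])
  dir_b <- run_direction(nm[2], nm[1], seeds[[2]])
  consensus <- merge_selected(dir_a$selected, dir_b$selected, edges,
                              labels = nm)
  say(sprintf("consensus subnetwork: %d genes", length(consensus$genes)))
  structure(list(
    directions = stats::setNames(list(dir_a, dir_b),
                                 paste(nm, c(nm[2], nm[1]), sep = "->")),
    consensus = consensus, gene_assoc = assoc, networks = nets,
    params = list(flank = flank, r = r, d = d, B = B, n_bins = n_bins,
                  criteria = unclass(criteria),
                  max_missing = max_missing, seed = seed)),
    class = "dms_pipeline")
}

#' @export
print.dms_pipeline <- function(x, ...) {
  cat("bi-directional dense module search pipeline\n")
  for (dn in names(x$directions)) {
    f <- x$directions[[dn]]$funnel
    cat(sprintf(
      "  %s: %d modules -> %d combinatorial -> %d eval score -> %d final\n",
      dn, f["modules"], f["pass_combinatorial"], f["pass_score_eval"],
      f["pass_all_eval"]))
  }
  print(x$consensus)
  invisible(x)
}

#' @export
summary.dms_pipeline <- function(object, ...) {
  print(object)
  cons <- object$consensus
  if (length(cons$genes)) {
    sig <- vapply(object$gene_assoc, function(a) {
      p <- a$p_gene[match(cons$genes, a$gene)]
      !is.na(p) & p < 0.05
    }, logical(length(cons$genes)))
    sig <- matrix(sig, nrow = length(cons$genes))
    cat(sprintf(
      "  consensus genes nominally significant in both studies: %d (%.2f%%)\n",
      sum(rowSums(sig) == ncol(sig)),
      100 * mean(rowSums(sig) == ncol(sig))))
    cat(sprintf(
      "  nominally significant in at least one study: %d (%.2f%%)\n",
      sum(rowSums(sig) > 0), 100 * mean(rowSums(sig) > 0)))
  }
  invisible(object)
}

#' Nominal-significance summary of a consensus gene set
#'
#' Given per-study gene association tables, reports how many of the
#' consensus genes are nominally significant (gene-wise P < `alpha`)
#' in every study, and in at least one, with percentages.
#'
#' @param genes Character vector of consensus genes.
#' @param gene_assoc Named list of gene association tables.
#' @param alpha Nominal threshold (default 0.05).
#' @return A list with `n_genes`, `per_study` (named counts), `both`
#'   (count significant in all studies), `either`, `pct_both`,
#'   `pct_either` (percentages rounded to 2 decimals).
#' @export
consensus_significance <- function(genes, gene_assoc, alpha = 0.05) {
  if (!length(genes)) stop("empty consensus gene set")
  sig <- vapply(gene_assoc, function(a) {
    p <- a$p_gene[match(genes, a$gene)]
    !is.na(p) & p < alpha
  }, logical(length(genes)))
  sig <- matrix(sig, nrow = length(genes),
                dimnames = list(genes, names(gene_assoc)))
  both <- sum(rowSums(sig) == ncol(sig))
  either <- sum(rowSums(sig) > 0)
  list(n_genes = length(genes),
       per_study = colSums(sig),
       both = both, either = either,
       pct_both = round(100 * both / length(genes), 2),
       pct_either = round(100 * either / length(genes), 2))
}

#' Write a JSON run manifest
#'
#' Records input file checksums, parameters, seeds and the package
#' version, so a run can be reproduced bit-identically.
#'
#' @param path Output JSON path.
#' @param params Named list of parameters.
#' @param inputs Optional character vector of input file paths to
#'   checksum (md5 via [tools::md5sum()]).
#' @param outputs Optional character vector of output paths.
#' @return Invisibly, the manifest list.
#' @export
write_run_manifest <- function(path, params, inputs = NULL,
                               outputs = NULL) {
  manifest <- list(
    package = "dmsnet",
    version = as.character(utils::packageVersion("dmsnet")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    params = params)
  if (!is.null(inputs))
    manifest$inputs <- lapply(stats::setNames(inputs, basename(inputs)),
                              function(f) list(
                                path = f,
                                md5 = unname(tools::md5sum(f))))
  if (!is.null(outputs)) manifest$outputs <- outputs
  jsonlite::write_json(manifest, path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a pipeline run configuration (YAML or JSON)
#'
#' Validates the configuration against the known parameter schema and
#' fills defaults: `flank = 20000`, `r = 0.1`, `d = 2`,
#' `B_assess = 1000`, `B_replication = 10000`, all selection
#' thresholds 0.05, `lambdas = 1`.  Unknown top-level keys are a
#' configuration error.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list of validated parameters.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::read_json(path,
                                                     simplifyVector = TRUE)
         else stop("config must be YAML or JSON")
  if (is.null(cfg)) cfg <- list()
  defaults <- list(flank = 20000, r = 0.1, d = 2, B_assess = 1000,
                   B_replication = 10000, n_bins = 10,
                   max_missing = 0.2, alpha = 0.05,
                   criteria = as.list(unclass(selection_criteria())),
                   lambdas = NULL, seed = NULL, inputs = NULL)
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ",
         paste(unknown, collapse = ", "))
  out <- utils::modifyList(defaults, cfg)
  numeric_keys <- c("flank", "r", "d", "B_assess", "B_replication",
                    "n_bins", "max_missing", "alpha")
  for (k in numeric_keys)
    if (!is.numeric(out[[k]]) || length(out[[k]]) != 1)
      stop("configuration key '", k, "' must be a single number")
  out$criteria <- do.call(selection_criteria, out$criteria)
  out
}
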