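# Greedy dense module search: grow a best-scoring module from a seed.
#
# At each iteration the candidate set is the d-hop neighborhood of the
# *current* module.  Because Zm+1 = (S + z_c)/sqrt(k+1), the candidate
# maximising the new score is simply the one with the largest node
# weight; ties break to the lexicographically smallest gene symbol so
# results are identical across runs and platforms.  The acceptance rule
# Zm+1 > Zm * (1 + r) is applied literally, also when Zm < 0 (where the
# multiplier lowers the bar).

#' Grow a dense module from a seed gene
#'
#' Starting from the singleton module `{seed}`, repeatedly consider all
#' genes within hop distance `d` of the current members, and add the
#' one giving the highest new score \eqn{Z_{m+1}} if
#' \eqn{Z_{m+1} > Z_m (1 + r)}; stop as soon as no candidate qualifies.
#' One gene is added per iteration; the procedure is deterministic.
#'
#' Note that a candidate reached at distance 2 need not share an edge
#' with the module once added, so member sets are close-knit by
#' construction but not guaranteed edge-connected.
#'
#' @param net A `"gwas_network"`.
#' @param seed Seed gene symbol (must be a network node).
#' @param r Expansion rate: proportional score improvement required to
#'   accept an addition (default 0.1).
#' @param d Neighborhood hop distance (default 2).
#' @return An object of class `"dms_module"`: list with `seed`,
#'   `members` (insertion order, seed first), `k`, `Zm` and `trace`, a
#'   data frame with one row per accepted addition (gene, score before,
#'   score after).
#' @export
grow_module <- function(net, seed, r = 0.1, d = 2) {
  if (length(seed) != 1) stop("exactly one seed gene expected")
  if (r <= -1) stop("r must be greater than -1")
  if (d < 1) stop("d must be >= 1")
  sidx <- .check_members(net, seed)
  members <- sidx
  z <- net$z
  s <- z[[sidx]]
  score <- s
  steps <- list()
  repeat {
    cand <- .neighborhood_idx(net, members, d)
    if (!length(cand)) break
    cz <- z[cand]
    best_z <- max(cz)
    ties <- cand[cz == best_z]
    if (length(ties) > 1)
      ties <- ties[order(net$genes[ties])]
    pick <- ties[1L]
    new_score <- (s + best_z) / sqrt(length(members) + 1)
    if (!(new_score > score * (1 + r))) break
    steps[[length(steps) + 1L]] <- data.frame(
      gene = net$genes[pick], score_before = score,
      score_after = new_score, stringsAsFactors = FALSE)
    members <- c(members, pick)
    s <- s + best_z
    score <- new_score
  }
  trace <- if (length(steps)) {
    tr <- do.call(rbind, steps)
    tr <- cbind(step = seq_len(nrow(tr)), tr)
    rownames(tr) <- NULL
    tr
  } else {
    data.frame(step = integer(0), gene = character(0),
               score_before = numeric(0), score_after = numeric(0))
  }
  structure(list(seed = net$genes[sidx], members = net$genes[members],
                 k = length(members), Zm = score, trace = trace),
            class = "dms_module")
}

#' @export
print.dms_module <- function(x, ...) {
  cat(sprintf("dense module from seed %s: k = %d, Zm = %.4f\n",
              x$seed, x$k, x$Zm))
  cat("  members:", paste(x$members, collapse = ", "), "\n")
  invisible(x)
}

#' Dense module search from every seed
#'
#' Runs [grow_module()] taking each network node in turn as the seed.
#' Seeds are processed independently in lexicographic order; distinct
#' seeds may converge to the same member set, and such duplicates are
#' retained.
#'
#' @param net A `"gwas_network"`.
#' @param r,d Passed to [grow_module()].
#' @return An object of class `"dms_result"`: list with `modules`
#'   (named list of member vectors, one per seed), `table` (data frame
#'   seed, k, Zm), and the parameters used.
#' @export
dms_search <- function(net, r = 0.1, d = 2) {
  seeds <- sort(net$genes)
  mods <- vector("list", length(seeds))
  k <- integer(length(seeds))
  zm <- numeric(length(seeds))
  for (i in seq_along(seeds)) {
    m <- grow_module(net, seeds[i], r = r, d = d)
    mods[[i]] <- m$members
    k[i] <- m$k
    zm[i] <- m$Zm
  }
  names(mods) <- seeds
  structure(list(modules = mods,
                 table = data.frame(seed = seeds, k = k, Zm = zm,
                                    stringsAsFactors = FALSE),
                 r = r, d = d),
            class = "dms_result")
}

#' @export
print.dms_result <- function(x, ...) {
  cat("dense module search result\n")
  cat(sprintf("  %d modules (r = %g, d = %g)\n",
              nrow(x$table), x$r, x$d))
  cat(sprintf("  module size: %d-%d (median %g); max Zm = %.4f\n",
              min(x$table$k), max(x$table$k),
              stats::median(x$table$k), max(x$table$Zm)))
  invisible(x)
}

#' @export
summary.dms_result <- function(object, ...) {
  print(object)
  cat("top modules by Zm:\n")
  top <- object$table[order(-object$table$Zm), ]
  print(utils::head(top, 5), row.names = FALSE)
  invisible(object$table)
}

#' Write a module table to TSV
#'
#' One row per module: seed, semicolon-joined members, k, Zm.
#'
#' @param result A `"dms_result"`.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_modules <- function(result, path) {
  tab <- result$table
  tab$members <- vapply(result$modules[tab$seed],
                        paste, "", collapse = ";")
  .write_tsv(tab[c("seed", "members", "k", "Zm")], path)
}
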