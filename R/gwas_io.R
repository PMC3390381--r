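#' @keywords internal
"_PACKAGE"

# Tabular IO and SNP-to-gene summarisation.
#
# All readers take plain TSV with a header row; coordinates are 1-based
# inclusive (a BED reader converts from 0-based half-open).  P values of
# exactly 0 or above 1 are rejected at the IO layer, never clamped --
# clamping happens only at the z-transformation.

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Normalize chromosome names
#'
#' Strips a leading `"chr"` prefix (any case) and upper-cases the
#' remainder, so that `"chr6"`, `"Chr6"` and `"6"` compare equal and
#' `"x"`/`"y"`/`"m"` become `"X"`/`"Y"`/`"MT"`.
#'
#' @param chrom Character vector of chromosome labels.
#' @return Character vector of normalized labels.
#' @export
#' @examples
#' normalize_chrom(c("chr6", "X", "chrMT", "m"))
normalize_chrom <- function(chrom) {
  x <- sub("^chr", "", as.character(chrom), ignore.case = TRUE)
  x <- toupper(x)
  x[x == "M"] <- "MT"
  x
}

.apply_dialect <- function(df, dialect) {
  if (is.null(dialect)) return(df)
  stopifnot(is.character(dialect), !is.null(names(dialect)))
  for (std in names(dialect)) {
    hit <- match(dialect[[std]], names(df))
    if (!is.na(hit)) names(df)[hit] <- std
  }
  df
}

#' Read a SNP association table
#'
#' Reads per-SNP GWAS summary statistics from a TSV file with a header.
#' Required columns: `snp_id`, `chrom`, `pos`, `p`; optional: `beta`,
#' `se`, `allele_ref`, `allele_alt`.  Effect columns may be absent
#' entirely (P-only tables are valid input for everything except
#' meta-analysis).
#'
#' Rows with an unparsable or out-of-range P value (`p <= 0`, `p > 1`),
#' a position below 1, or a non-positive standard error are dropped with
#' a warning; the dropped rows are attached as attribute `"rejected"`.
#' Input row order is preserved.
#'
#' @param path Path to the TSV file.
#' @param dialect Optional named character vector mapping standard
#'   column names to the names used in the file, e.g.
#'   `c(snp_id = "rsid", p = "P_VAL")`.
#' @return A `data.frame` with one row per retained SNP.
#' @export
read_snp_associations <- function(path, dialect = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  df <- .apply_dialect(df, dialect)
  required <- c("snp_id", "chrom", "pos", "p")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("SNP association table is missing required column(s): ",
         paste(missing, collapse = ", "))
  dup <- unique(df$snp_id[duplicated(df$snp_id)])
  if (length(dup))
    stop("duplicate snp_id values: ", paste(utils::head(dup, 10), collapse = ", "))
  df$chrom <- normalize_chrom(df$chrom)
  df$pos <- suppressWarnings(as.integer(df$pos))
  df$p <- suppressWarnings(as.numeric(df$p))
  if (!"beta" %in% names(df)) df$beta <- NA_real_
  if (!"se" %in% names(df)) df$se <- NA_real_
  df$beta <- suppressWarnings(as.numeric(df$beta))
  df$se <- suppressWarnings(as.numeric(df$se))
  bad <- !is.finite(df$p) | df$p <= 0 | df$p > 1 |
    is.na(df$pos) | df$pos < 1 |
    (!is.na(df$se) & df$se <= 0)
  if (any(bad)) {
    warning(sum(bad), " row(s) rejected (invalid p, pos or se): ",
            paste(utils::head(df$snp_id[bad], 5), collapse = ", "))
  }
  out <- df[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- df[bad, , drop = FALSE]
  out
}

#' Write a SNP association table
#'
#' @param snps Data frame as returned by [read_snp_associations()].
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_snp_associations <- function(snps, path) .write_tsv(snps, path)

#' Read a gene annotation table
#'
#' TSV format needs columns `gene`, `chrom`, `start`, `end` (1-based,
#' inclusive).  BED format has columns chrom, start, end, name with
#' 0-based half-open coordinates, converted on read.  A `length` column
#' (`end - start + 1`) is always computed from the annotation.
#'
#' @param path Path to the annotation file.
#' @param format `"tsv"` (default) or `"bed"`.
#' @return A `data.frame` with columns gene, chrom, start, end, length.
#' @export
read_gene_annotations <- function(path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene", "chrom", "start", "end")
    missing <- setdiff(need, names(df))
    if (length(missing))
      stop("gene annotation is missing column(s): ",
           paste(missing, collapse = ", "))
    df <- df[need]
  } else {
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 4) stop("BED annotation needs at least 4 columns")
    df <- data.frame(gene = df[[4]], chrom = df[[1]],
                     start = df[[2]] + 1L, end = df[[3]],
                     stringsAsFactors = FALSE)
  }
  df$chrom <- normalize_chrom(df$chrom)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (any(df$start > df$end)) stop("annotation rows with start > end")
  dup <- unique(df$gene[duplicated(df$gene)])
  if (length(dup))
    stop("duplicate gene symbols in annotation: ",
         paste(utils::head(dup, 10), collapse = ", "))
  df$length <- df$end - df$start + 1L
  rownames(df) <- NULL
  df
}

#' Map SNPs to genes by position
#'
#' A SNP is assigned to every gene on the same chromosome whose body,
#' extended by `flank` base pairs on both sides, contains it:
#' `start - flank <= pos <= end + flank`, boundaries inclusive.  A SNP
#' inside two genes' windows counts fully toward both (no fractional
#' assignment).
#'
#' @param snps SNP association data frame ([read_snp_associations()]).
#' @param genes Gene annotation data frame ([read_gene_annotations()]).
#' @param flank Flanking distance in base pairs (default 20000,
#'   i.e. 20 kb up- and downstream).
#' @return A `data.frame` with columns `snp_id`, `gene`, one row per
#'   (SNP, gene) assignment.  SNPs mapping to no gene are listed in
#'   attribute `"intergenic"`.
#' @export
map_snps_to_genes <- function(snps, genes, flank = 20000) {
  if (length(flank) != 1 || !is.finite(flank) || flank < 0)
    stop("flank must be a single non-negative number")
  snps$chrom <- normalize_chrom(snps$chrom)
  genes$chrom <- normalize_chrom(genes$chrom)
  pieces <- vector("list", 0L)
  for (ch in unique(genes$chrom)) {
    s <- snps[snps$chrom == ch, , drop = FALSE]
    if (!nrow(s)) next
    ord <- order(s$pos)
    pos <- s$pos[ord]
    ids <- s$snp_id[ord]
    g <- genes[genes$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(g))) {
      lo <- g$start[i] - flank
      hi <- g$end[i] + flank
      i0 <- findInterval(lo - 1, pos)   # last pos < lo
      i1 <- findInterval(hi, pos)      # last pos <= hi
      if (i1 > i0) {
        pieces[[length(pieces) + 1L]] <- data.frame(
          snp_id = ids[(i0 + 1L):i1], gene = g$gene[i],
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(pieces)) do.call(rbind, pieces)
         else data.frame(snp_id = character(0), gene = character(0),
                         stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "intergenic") <- setdiff(snps$snp_id, out$snp_id)
  out
}

#' Gene-wise P values from mapped SNPs
#'
#' Summarises each gene by the P value of its most significant mapped
#' SNP (the minimum over SNP P values).  Genes with no mapped SNP are
#' absent from the output.
#'
#' @param snps SNP association data frame.
#' @param mapping SNP-to-gene mapping from [map_snps_to_genes()] over
#'   the same SNPs.
#' @param genes Gene annotation data frame (supplies gene length).
#' @return A `data.frame` with columns `gene`, `p_gene`, `best_snp`,
#'   `n_snps`, `gene_length`, sorted by gene symbol.
#' @export
gene_wise_p <- function(snps, mapping, genes) {
  if (!nrow(mapping)) {
    warning("empty SNP-to-gene mapping; no gene-wise P values produced")
    return(data.frame(gene = character(0), p_gene = numeric(0),
                      best_snp = character(0), n_snps = integer(0),
                      gene_length = integer(0), stringsAsFactors = FALSE))
  }
  pidx <- match(mapping$snp_id, snps$snp_id)
  if (anyNA(pidx))
    stop("mapping refers to SNPs absent from the association table")
  m <- data.frame(gene = mapping$gene, snp_id = mapping$snp_id,
                  p = snps$p[pidx], stringsAsFactors = FALSE)
  ord <- order(m$gene, m$p, match(m$snp_id, snps$snp_id))
  m <- m[ord, , drop = FALSE]
  first <- !duplicated(m$gene)
  counts <- table(m$gene)
  out <- data.frame(
    gene = m$gene[first],
    p_gene = m$p[first],
    best_snp = m$snp_id[first],
    stringsAsFactors = FALSE)
  out$n_snps <- as.integer(counts[out$gene])
  out$gene_length <- genes$length[match(out$gene, genes$gene)]
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a gene association table
#' @param assoc Data frame from [gene_wise_p()].
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_gene_associations <- function(assoc, path) .write_tsv(assoc, path)

#' Read a gene association table written by [write_gene_associations()]
#' @param path TSV path with columns gene, p_gene, best_snp, n_snps,
#'   gene_length.
#' @return A `data.frame`.
#' @export
read_gene_associations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "p_gene")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("gene association table missing column(s): ",
         paste(missing, collapse = ", "))
  df
}

#' Read a protein-protein interaction edge list
#'
#' Two-column TSV of gene symbols with a header, optional third column
#' of evidence codes.  Self-loops are removed and duplicate or reversed
#' pairs collapsed to a single undirected edge.
#'
#' @param path Path to the edge TSV.
#' @param require_evidence If `TRUE`, rows with an empty or missing
#'   evidence field are dropped before deduplication (keeps only
#'   experimentally supported interactions).
#' @return A `data.frame` with columns `gene_a`, `gene_b`.
#' @export
read_ppi_edges <- function(path, require_evidence = FALSE) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2)
    stop("PPI edge list needs at least two columns (gene_a, gene_b)")
  if (!nrow(df)) {
    warning("empty PPI edge list")
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      stringsAsFactors = FALSE))
  }
  a <- as.character(df[[1]]); b <- as.character(df[[2]])
  if (require_evidence) {
    if (ncol(df) < 3)
      stop("require_evidence = TRUE but the edge list has no evidence column")
    ev <- as.character(df[[3]])
    keep <- !is.na(ev) & trimws(ev) != ""
    a <- a[keep]; b <- b[keep]
  }
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  dedup <- !duplicated(paste(lo, hi, sep = "\r"))
  out <- data.frame(gene_a = lo[dedup], gene_b = hi[dedup],
                    stringsAsFactors = FALSE)
  if (!nrow(out)) warning("PPI edge list contains no usable edges")
  rownames(out) <- NULL
  out
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors of member genes, with the
#'   per-set descriptions in attribute `"description"`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(fields, length, 1L) < 3L
  if (any(bad)) stop("malformed GMT line(s): fewer than 3 fields")
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  attr(sets, "description") <- vapply(fields, `[[`, "", 2L)
  sets
}

#' Write gene sets in GMT format
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Optional character vector of descriptions
#'   (defaults to `"na"`).
#' @return The path, invisibly.
#' @export
write_gmt <- function(sets, path, description = NULL) {
  if (is.null(description))
    description <- attr(sets, "description")
  if (is.null(description)) description <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
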