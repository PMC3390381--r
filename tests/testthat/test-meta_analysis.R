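test_that("genomic control scales standard errors by sqrt(lambda)", {
  expect_equal(gc_adjust(0.03, 1), 0.03)
  expect_equal(gc_adjust(0.03, 1.04), 0.03 * sqrt(1.04))
  expect_equal(gc_adjust(0.03, 1.04), 0.030594, tolerance = 1e-5)
  expect_equal(gc_adjust(0.05, 4), 0.1)
  expect_error(gc_adjust(0.03, 0), "positive")
  expect_warning(gc_adjust(0.03, 0.9), "shrink")
})

test_that("fixed-effects meta-analysis matches hand arithmetic and a
           WLS oracle", {
  # single study: identity
  r1 <- fixed_effects_meta(0.2, 0.1)
  expect_equal(r1$beta_meta, 0.2)
  expect_equal(r1$se_meta, 0.1)
  expect_equal(r1$Q, 0)
  expect_equal(r1$p_het, 1)
  # two identical studies: beta unchanged, se / sqrt(2)
  r2 <- fixed_effects_meta(c(0.2, 0.2), c(0.1, 0.1))
  expect_equal(r2$beta_meta, 0.2)
  expect_equal(r2$se_meta, 0.1 / sqrt(2))
  expect_equal(r2$se_meta, 0.070711, tolerance = 1e-5)
  expect_equal(r2$I2, 0)
  # hand case: w = {100, 25}
  r3 <- fixed_effects_meta(c(0.3, 0.1), c(0.1, 0.2))
  expect_equal(r3$beta_meta, 0.26)
  expect_equal(r3$se_meta, 1 / sqrt(125))
  expect_equal(r3$se_meta, 0.089443, tolerance = 1e-5)
  expect_equal(r3$Q, 0.8)
  expect_equal(r3$I2, 0)
  expect_equal(r3$p_het, pchisq(0.8, 1, lower.tail = FALSE))
  expect_equal(r3$p_het, 0.3711, tolerance = 1e-4)
  # WLS oracle on random fixtures: intercept-only weighted least
  # squares with weights 1/se^2 reproduces beta and se
  set.seed(2)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    beta <- rnorm(k, 0, 0.2)
    se <- runif(k, 0.02, 0.3)
    r <- fixed_effects_meta(beta, se)
    fit <- lm(beta ~ 1, weights = 1 / se^2)
    expect_equal(r$beta_meta, unname(coef(fit)[1]), tolerance = 1e-10)
    # se from the weight sum (dispersion fixed at 1)
    expect_equal(r$se_meta, 1 / sqrt(sum(1 / se^2)), tolerance = 1e-12)
    # pooled estimate within the study range; Q order-invariant
    expect_gte(r$beta_meta, min(beta))
    expect_lte(r$beta_meta, max(beta))
    perm <- sample(k)
    expect_equal(fixed_effects_meta(beta[perm], se[perm])$Q, r$Q)
  }
  # k copies of one study shrink se by exactly sqrt(k)
  r5 <- fixed_effects_meta(rep(0.15, 5), rep(0.08, 5))
  expect_equal(r5$se_meta, 0.08 / sqrt(5))
  expect_equal(r5$beta_meta, 0.15)
  expect_equal(r5$Q, 0)
  expect_error(fixed_effects_meta(numeric(0), numeric(0)), "one study")
})

test_that("allele alignment flips swapped codings and flags ambiguity", {
  rows <- data.frame(study = c("s1", "s2", "s3"),
                     allele_ref = c("T", "G", "A"),
                     allele_alt = c("G", "T", "C"),
                     beta = c(0.15, -0.15, 0.2),
                     stringsAsFactors = FALSE)
  al <- align_alleles(rows)
  expect_equal(nrow(al), 2)            # s3 alleles unmatchable
  expect_equal(attr(al, "dropped"), 1)
  expect_equal(al$beta, c(0.15, 0.15)) # swapped study sign-flipped
  expect_true(al$flipped[2])
  at <- align_alleles(data.frame(study = "s1", allele_ref = "A",
                                 allele_alt = "T", beta = 0.1))
  expect_true(at$ambiguous)
})

test_that("the meta table covers the SNP intersection and composes
           the per-SNP operation", {
  set.seed(6)
  mk <- function(ids, seed, flip = character(0)) {
    set.seed(seed)
    n <- length(ids)
    maf <- runif(n, 0.05, 0.5)
    se <- 1 / sqrt(2 * 2000 * maf * (1 - maf))
    z <- rnorm(n)
    ref <- rep("A", n); alt <- rep("G", n)
    beta <- z * se
    sw <- ids %in% flip
    data.frame(snp_id = ids, chrom = "1", pos = seq_len(n),
               allele_ref = ifelse(sw, alt, ref),
               allele_alt = ifelse(sw, ref, alt),
               beta = ifelse(sw, -beta, beta), se = se,
               p = 2 * pnorm(-abs(z)), stringsAsFactors = FALSE)
  }
  ids <- sprintf("rs%03d", 1:120)
  shared <- ids[1:100]
  tabs <- list(a = mk(ids, 1),
               b = mk(c(shared, sprintf("rx%02d", 1:5)), 2),
               c = mk(shared, 3, flip = shared[1:3]))
  res <- meta_table(tabs)
  expect_equal(nrow(res), 100)
  expect_s3_class(res, "meta_result")
  # row-wise equality with fixed_effects_meta (alleles aligned: study
  # c's first three SNPs are stored swapped and must flip back)
  for (i in c(1, 2, 50)) {
    id <- res$snp_id[i]
    beta <- c(tabs$a$beta[tabs$a$snp_id == id],
              tabs$b$beta[tabs$b$snp_id == id],
              tabs$c$beta[tabs$c$snp_id == id])
    if (id %in% shared[1:3]) beta[3] <- -beta[3]
    se <- c(tabs$a$se[tabs$a$snp_id == id],
            tabs$b$se[tabs$b$snp_id == id],
            tabs$c$se[tabs$c$snp_id == id])
    r <- fixed_effects_meta(beta, se)
    expect_equal(res$beta_meta[i], r$beta_meta, tolerance = 1e-12)
    expect_equal(res$p_meta[i], r$p_meta, tolerance = 1e-12)
    expect_equal(res$p_het[i], r$p_het, tolerance = 1e-12)
  }
  # genomic control propagates
  res_gc <- meta_table(tabs, lambdas = c(a = 1.04, b = 1, c = 1))
  expect_true(all(res_gc$se_meta > res$se_meta))
  expect_error(meta_table(tabs[1]), "two studies")
  expect_error(meta_table(list(a = mk(ids, 1), b = mk(paste0("zz", 1:5), 2))),
               "shared")
})

test_that("meta-analysis type-I error is nominal under the null", {
  set.seed(8)
  n <- 10000
  ids <- sprintf("rs%05d", 1:n)
  mk <- function(seed) {
    set.seed(seed)
    maf <- runif(n, 0.05, 0.5)
    se <- 1 / sqrt(2 * 2000 * maf * (1 - maf))
    z <- rnorm(n)
    data.frame(snp_id = ids, chrom = "1", pos = 1:n,
               allele_ref = "A", allele_alt = "G",
               beta = z * se, se = se, p = 2 * pnorm(-abs(z)),
               stringsAsFactors = FALSE)
  }
  res <- meta_table(list(a = mk(11), b = mk(12), c = mk(13)))
  rej <- mean(res$p_meta < 0.05)
  expect_gte(rej, 0.04)
  expect_lte(rej, 0.06)
})

test_that("heterogeneity filtering keeps low-P homogeneous SNPs", {
  f <- system.file("extdata", "meta_example.tsv", package = "dmsnet")
  tab <- utils::read.delim(f, stringsAsFactors = FALSE)
  expect_equal(nrow(filter_meta(tab, het_min = 0)), 21)
  expect_equal(nrow(filter_meta(tab, p_max = 0)), 0)
  kept <- filter_meta(tab)
  expect_true(all(kept$p_het >= 0.05))
  expect_true(all(kept$p_meta < 1e-4))
  gs <- meta_gene_summary(kept)
  expect_true(all(gs$n_snps >= 1))
})

test_that("SNP-set enrichment is exact in degenerate cases and finds
           planted signal", {
  set.seed(3)
  n <- 1000
  res <- data.frame(snp_id = sprintf("rs%04d", 1:n),
                    p_meta = runif(n), stringsAsFactors = FALSE)
  # set = entire universe: every resample ties
  expect_equal(meta_set_enrichment(res, res$snp_id, B = 100)$p, 1)
  # strongly enriched set
  res2 <- res
  res2$p_meta[1:100] <- res2$p_meta[1:100] / 50
  r <- meta_set_enrichment(res2, res2$snp_id[1:100], B = 999, seed = 5)
  expect_equal(r$p, 1 / 1000)
  expect_error(meta_set_enrichment(res, "nope"), "absent")
})
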