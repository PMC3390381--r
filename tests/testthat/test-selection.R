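# Build a module_assessment by hand (bypassing the search) so the
# selection logic can be tested against known labels.
fake_assessment <- function(p_tab, modules = NULL) {
  out <- cbind(data.frame(seed = paste0("S", seq_len(nrow(p_tab))),
                          k = 3L, Zm = rev(seq_len(nrow(p_tab))),
                          stringsAsFactors = FALSE),
               p_tab)
  if (is.null(modules))
    modules <- stats::setNames(
      replicate(nrow(out), paste0("G", sample(100, 3)),
                simplify = FALSE), out$seed)
  attr(out, "modules") <- modules
  class(out) <- c("module_assessment", "data.frame")
  out
}

test_that("combinatorial selection requires all five criteria strictly", {
  tab <- data.frame(p_zm = 0.01, p_gl = 0.01, p_nsnps = 0.01,
                    p_topo = 0.01, p_emp = 0.01)
  expect_equal(nrow(select_modules(fake_assessment(tab))), 1)
  tab$p_topo <- 0.06
  expect_equal(nrow(select_modules(fake_assessment(tab))), 0)
  tab$p_topo <- 0.05  # boundary: strict inequality rejects
  expect_equal(nrow(select_modules(fake_assessment(tab))), 0)
  # 100-module fixture with a known pass set of 7
  set.seed(1)
  big <- data.frame(p_zm = runif(100, 0.06, 1), p_gl = runif(100),
                    p_nsnps = runif(100), p_topo = runif(100),
                    p_emp = runif(100))
  winners <- sample(100, 7)
  big[winners, ] <- 0.01
  sel <- select_modules(fake_assessment(big))
  expect_setequal(sel$seed, paste0("S", winners))
  # member lists follow the selection
  expect_setequal(names(attr(sel, "modules")), sel$seed)
  # monotone: tightening any threshold never adds a module
  for (th in c("alpha_zm", "alpha_gl", "alpha_nsnps", "alpha_topo",
               "alpha_emp")) {
    crit <- selection_criteria()
    crit[[th]] <- 0.01
    tighter <- select_modules(fake_assessment(big), crit)
    expect_true(all(tighter$seed %in% sel$seed))
  }
  expect_error(select_modules(fake_assessment(big[-1])), "p_zm")
  expect_error(selection_criteria(alpha_zm = 0), "outside")
})

test_that("evaluation rescoring is exact under identical weights", {
  net <- random_uniform_net(n = 120, m = 2, seed = 55)
  res <- dms_search(net)
  assessed <- assess_modules(res, net, B = 200, seed = 1)
  ev <- evaluate_modules(assessed, net)
  expect_equal(ev$Zm_eval, ev$Zm, tolerance = 1e-12)
  expect_true(all(ev$frac_missing == 0))
})

test_that("null evaluation weights rarely pass both eval criteria", {
  set.seed(9)
  edges <- simulate_network(n = 400, m = 2, seed = 9)
  genes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  mk_assoc <- function(seed) {
    set.seed(seed)
    data.frame(gene = genes, p_gene = runif(length(genes)),
               n_snps = 1L + rpois(length(genes), 4),
               gene_length = 1000L, stringsAsFactors = FALSE)
  }
  net_eval <- build_weighted_network(edges, mk_assoc(101))
  # 2000 null candidate "modules"
  mods <- stats::setNames(
    replicate(2000, sample(genes, 8), simplify = FALSE),
    paste0("S", 1:2000))
  assessed <- fake_assessment(
    data.frame(p_zm = rep(0.01, 2000), p_gl = 0.01, p_nsnps = 0.01,
               p_topo = 0.01, p_emp = 0.01), modules = mods)
  assessed$k <- 8L
  perm_eval <- simulate_permutations(
    n_snps_per_gene = stats::setNames(rep(1L, length(genes)), genes),
    n_permutations = 199, seed = 77)
  ev <- evaluate_modules(assessed, net_eval, eval_perm_p = perm_eval)
  pass <- !is.na(ev$p_zm_eval) & ev$p_zm_eval < 0.05 &
    !is.na(ev$p_emp_eval) & ev$p_emp_eval < 0.05
  # the two evaluation criteria are strongly positively correlated
  # (both are monotone in the same evaluation score), so the joint
  # null pass rate sits between alpha^2 and alpha, close to the
  # conditional ceiling rather than the independence product
  expect_lt(mean(pass), 0.05)
  expect_gt(mean(pass), 0.05^2)
})

test_that("modules carrying genuine shared signal pass evaluation", {
  # two studies share 10 high-signal genes; candidate modules are 500
  # random null draws plus 10 planted-rich modules
  set.seed(21)
  edges <- simulate_network(n = 400, m = 2, seed = 21)
  genes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  planted <- sample(genes, 10)
  mk_assoc <- function(seed) {
    set.seed(seed)
    p <- runif(length(genes))
    p[match(planted, genes)] <- 10^-runif(10, 3, 6)
    data.frame(gene = genes, p_gene = p,
               n_snps = 1L + rpois(length(genes), 4),
               gene_length = 1000L, stringsAsFactors = FALSE)
  }
  net_eval <- build_weighted_network(edges, mk_assoc(202))
  mods <- c(replicate(500, sample(setdiff(genes, planted), 8),
                      simplify = FALSE),
            replicate(10, c(sample(planted, 6),
                            sample(setdiff(genes, planted), 2)),
                      simplify = FALSE))
  names(mods) <- paste0("S", seq_along(mods))
  assessed <- fake_assessment(
    data.frame(p_zm = rep(0.01, 510), p_gl = 0.01, p_nsnps = 0.01,
               p_topo = 0.01, p_emp = 0.01), modules = mods)
  assessed$k <- 8L
  perm_eval <- simulate_permutations(
    n_snps_per_gene = stats::setNames(rep(1L, length(genes)), genes),
    n_permutations = 199, seed = 99)
  ev <- evaluate_modules(assessed, net_eval, eval_perm_p = perm_eval)
  planted_rows <- 501:510
  pass <- ev$p_zm_eval[planted_rows] < 0.05 &
    ev$p_emp_eval[planted_rows] < 0.05
  expect_gte(mean(pass), 0.8)
  # and the null block stays mostly out
  null_pass <- ev$p_zm_eval[1:500] < 0.05 & ev$p_emp_eval[1:500] < 0.05
  expect_lte(mean(null_pass), 0.05)
})

test_that("modules losing too many genes have evaluation invalidated", {
  net <- random_uniform_net(n = 30, m = 2, seed = 66)
  g <- net$genes
  mods <- c(list(S1 = c(g[1], g[2], "X", "Y", "Z"),
                 S2 = g[1:3]),
            stats::setNames(replicate(58, sample(g, 3),
                                      simplify = FALSE),
                            paste0("S", 3:60)))
  assessed <- fake_assessment(
    data.frame(p_zm = rep(0.01, 60), p_gl = 0.01, p_nsnps = 0.01,
               p_topo = 0.01, p_emp = 0.01), modules = mods)
  assessed$k <- c(5L, 3L, rep(3L, 58))
  ev <- evaluate_modules(assessed, net, max_missing = 0.2)
  expect_true(is.na(ev$Zm_eval[1]))   # 3/5 of the genes missing
  expect_true(is.na(ev$p_zm_eval[1]))
  expect_false(is.na(ev$Zm_eval[2]))
  expect_equal(ev$frac_missing[1], 0.6)
  expect_equal(ev$Zm_eval[2], module_score(net, g[1:3])$Zm)
})

test_that("consensus merge unions genes with provenance", {
  net <- make_net("A-B,B-C,C-D,D-E", p = c(A = 0.5))
  a <- list(m1 = c("A", "B", "C"))
  b <- list(m2 = c("C", "D"))
  cons <- merge_selected(a, b, net, labels = c("x", "y"))
  expect_setequal(cons$genes, c("A", "B", "C", "D"))
  pc <- cons$provenance
  expect_equal(pc$directions[pc$gene == "C"], "x;y")
  expect_equal(pc$modules[pc$gene == "C"], "m1;m2")
  expect_equal(nrow(cons$edges), 3)  # A-B, B-C, C-D induced
  # one empty direction: consensus = the other side
  cons2 <- merge_selected(a, list(), net)
  expect_setequal(cons2$genes, c("A", "B", "C"))
  # union cardinality on an engineered-overlap fixture
  a2 <- lapply(1:68, function(i) paste0("G", i:(i + 2)))
  names(a2) <- paste0("a", 1:68)
  b2 <- list(b1 = paste0("G", 68:72))
  cons3 <- merge_selected(a2, b2, net)
  expect_equal(length(cons3$genes), length(unique(c(unlist(a2),
                                                    unlist(b2)))))
})

test_that("gene-level replication detects enrichment and stays exact
           in degenerate cases", {
  set.seed(4)
  genes <- sprintf("G%03d", 1:400)
  repl <- data.frame(gene = genes, p_gene = runif(400),
                     n_snps = 1L + rpois(400, 4),
                     gene_length = pmax(200, round(rlnorm(400, 9.9, 0.8))),
                     stringsAsFactors = FALSE)
  # consensus = the most significant genes: no resample can beat it
  top <- repl$gene[order(repl$p_gene)][1:20]
  r <- replicate_gene_level(top, repl, "gene_length", B = 999, seed = 1)
  expect_equal(r$p, 1 / 1000)
  expect_equal(r$observed, sum(repl$p_gene[match(top, repl$gene)] < 0.05))
  # null consensus: observed count near alpha * n
  null_set <- sample(genes, 205)
  r2 <- replicate_gene_level(null_set, repl, "n_snps", B = 499, seed = 2)
  expect_gt(r2$p, 0.05)
  expect_equal(r2$expected, 205 * 0.05)
  # absent genes are excluded with a warning
  expect_warning(
    r3 <- replicate_gene_level(c(top, "NOPE"), repl, "gene_length",
                               B = 499, seed = 3), "absent")
  expect_equal(r3$n_excluded, 1)
})

test_that("SNP-level replication counts significant SNPs against
           uniform draws", {
  set.seed(14)
  n <- 2000
  snps <- data.frame(snp_id = sprintf("rs%04d", 1:n), chrom = "1",
                     pos = 1:n, p = runif(n), stringsAsFactors = FALSE)
  genes <- sprintf("G%03d", 1:100)
  mapping <- data.frame(snp_id = snps$snp_id,
                        gene = rep(genes, each = 20),
                        stringsAsFactors = FALSE)
  # consensus covering all genes: every resample ties, P = 1
  r <- replicate_snp_level(genes, snps, mapping, B = 200, seed = 1)
  expect_equal(r$p, 1)
  expect_equal(r$observed, sum(snps$p < 0.05))
  # enriched consensus SNPs
  enr_genes <- genes[1:10]
  enr_idx <- mapping$snp_id[mapping$gene %in% enr_genes]
  snps2 <- snps
  snps2$p[snps2$snp_id %in% enr_idx] <-
    snps2$p[snps2$snp_id %in% enr_idx] / 20
  r2 <- replicate_snp_level(enr_genes, snps2, mapping, B = 499,
                            seed = 2)
  expect_lte(r2$p, 0.05)
  expect_error(replicate_snp_level("ABSENT", snps, mapping, B = 100),
               "no SNPs")
})
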