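---
title: "Network-assisted analysis of GWAS summary statistics with dmsnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-assisted analysis of GWAS summary statistics with dmsnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Genome-wide association studies of polygenic disorders rarely produce
single markers at genome-wide significance; the signal is spread over
many weakly associated genes.  `dmsnet` looks for that signal as
*modules* of interacting proteins: connected neighbourhoods of a
protein--protein interaction (PPI) network that are jointly enriched
for association.

Every SNP is mapped to the genes whose body, extended by a 20 kb flank
on either side, contains it (boundaries inclusive; a SNP inside two
overlapping windows counts fully toward both genes).  A gene's
association is summarised by its most significant mapped SNP,
$p_{\text{gene}} = \min_j p_j$, and converted to a node weight

$$ z_i = \Phi^{-1}(1 - p_{\text{gene},i}), $$

the upper-tail standard-normal quantile.  A candidate module with $k$
member genes is scored by

$$ Z_m = \frac{\sum_{i \in m} z_i}{\sqrt{k}} , $$

which is standard normal for any fixed gene set when gene-wise P
values are i.i.d. uniform.

### Greedy dense module search

For every network node taken as a seed, the module is grown greedily:
among all non-member genes within hop distance $d$ of the *current*
members, the gene with the largest weight (equivalently, the largest
$Z_{m+1}$) is added if and only if

$$ Z_{m+1} > Z_m \,(1 + r), $$

and the search stops at the first failure.  Defaults are $r = 0.1$ and
$d = 2$.  Two consequences of this rule are worth knowing:

* **Module size is bounded by the improvement rate.**  Inside a flat
  cluster of equal weights $z$, acceptance requires
  $\sqrt{k+1} > 1.1\sqrt{k}$, which fails for $k \ge 5$.  Modules
  therefore top out around 5--7 members unless the score climbs from a
  low-weight seed, and a 10-gene cluster of comparable weights is
  never absorbed whole by a single module.
* **The candidate set moves with the module.**  Because the $d$-hop
  neighbourhood is recomputed after every accepted addition, each
  step can extend the module's reach; on a small or highly connected
  network a strong cluster of high-weight genes attracts modules
  grown from distant seeds.  Members are close-knit by construction
  but not guaranteed edge-connected (a distance-2 candidate need not
  share an edge with the module after joining).

Ties between equal-weight candidates break to the lexicographically
smallest gene symbol, so results are identical across runs and
platforms.  The acceptance inequality is applied literally also when
$Z_m < 0$, where the multiplier *lowers* the bar; an addition can be
accepted if it makes a negative score sufficiently less negative
($z > (1.1\sqrt{2} - 1)\,z_0$ from a singleton seed).

### Module assessment

Four null models convert a module score into P values, each targeting
a different bias:

1. **Empirical null of module scores** (`fit_empirical_null`,
   `score_p`).  Scores of all grown modules are median-centered and a
   normal null $N(\delta, \sigma^2)$ is fitted by truncated-normal
   maximum likelihood on a central quantile window; each module gets
   $P(Z_m) = 1 - \Phi\!\left((Z_m - \text{med} - \delta)/\sigma\right)$.
   The transform is monotone, so P values rank modules exactly as the
   scores do.
2. **Bias-matched weighted resampling** (`weighted_resample_p`).
   Longer genes carry more SNPs, and a minimum over more SNPs is
   stochastically smaller, so long genes look associated for free.
   Network genes are binned into deciles of the covariate (gene
   length or mapped-SNP count) and each of $B$ resamples draws,
   without replacement, the module's per-decile gene counts; the
   resampled set is scored by $\sum z/\sqrt{k}$.
3. **Topology-matched randomization** (`topology_matched_p`).  Hub
   genes are recruited preferentially during expansion.  Nodes are
   categorized into four degree bins --- $[0,4]$, $(4,16]$,
   $(16,64]$, $(64,\infty)$, i.e. powers $2^2, 2^4, 2^6$ with
   lower-inclusive boundaries --- and resamples match the module's
   bin profile.
4. **Phenotype permutation** (`permutation_p`).  The module's fixed
   gene set is re-weighted with gene-wise P values obtained under
   shuffled case/control labels and re-scored per permutation.
   Because genotypes are outside this package's scope, the
   permutation columns are supplied externally or generated by
   `simulate_permutations`.

All empirical P values use the +1-corrected estimator
$(1 + \#\{\text{null} \ge \text{observed}\})/(B + 1)$, ties counting
toward the exceedance (both conservative choices; the raw exceedance
count is recoverable from $P$ and $B$).  Within one call all modules
are scored against a shared resample pool, which makes the estimator
monotone: against the same pool, a larger observed score can never
receive a larger P.

### Bi-directional selection and consensus

With two studies of the same phenotype, each serves once as discovery
and once as evaluation.  A module survives its direction if all five
discovery-side criteria hold strictly --- $P(Z_m) < 0.05$;
$P_{GL} < 0.05$, $P_{nSNPs} < 0.05$, $P_{topo} < 0.05$; and
$P_{emp} < 0.05$ --- and, re-scored with the evaluation study's
weights (the empirical null fitted on the evaluation scores of *all*
candidate modules), both $P(Z_{m(eval)}) < 0.05$ and
$P_{emp(eval)} < 0.05$.  Module genes absent from the evaluation
network are dropped with $k$ reduced; a module losing more than 20%
of its genes (configurable) has its evaluation invalidated.  The
selected modules of both directions are merged into a consensus
subnetwork: the gene union with induced PPI edges and per-gene
provenance.

Note that the two evaluation criteria are strongly positively
correlated --- both are monotone in the same evaluation score --- so
their joint null pass rate lies between $\alpha^2$ and $\alpha$,
much closer to $\alpha$ than the independence product.

### Replication and meta-analysis

Consensus genes are tested in an independent study at the gene level
(count of genes with replication $p_{\text{gene}} < 0.05$ against
covariate-stratified resamples of equal size) and at the SNP level
(count of significant SNPs in consensus genes against uniform draws
of equally many genotyped SNPs).

SNP-level fixed-effects meta-analysis combines per-study effects with
inverse-variance weights $w_i = 1/se_i^2$ after per-study genomic
control ($se \leftarrow se\sqrt{\lambda}$):
$\beta = \sum w_i\beta_i/\sum w_i$, $se = (\sum w_i)^{-1/2}$, Wald
$z$ with a two-sided normal P.  Heterogeneity is assessed by Cochran's
$Q = \sum w_i(\beta_i - \beta)^2$, $I^2 = \max(0, (Q - (k-1))/Q)$
(floored at zero, the standard convention), and a $\chi^2_{k-1}$ P
value; the conventional filter keeps $p_{\text{meta}} < 10^{-4}$ with
$p_{\text{het}} \ge 0.05$.  Only SNPs genotyped in all studies are
analysed (no imputation).  Within each SNP, allele codings are aligned
to the first study (sign flips for swapped ref/alt; unmatchable rows
dropped with a report); strand-ambiguous A/T and C/G SNPs are flagged
but retained, since same-platform studies resolve strand upstream.

Gene-set over-representation of the consensus genes uses the
upper-tail hypergeometric test within the network-gene universe
(configurable), set sizes restricted to 10--250 inside the universe,
with Bonferroni or Benjamini--Hochberg adjustment, plus an empirical
layer: random query sets of the same size are drawn from the universe
and each set's significant-resample count yields
$(1 + \#)/(B + 1)$.

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `flank` | 20000 | bp | SNP-to-gene window on each side of the gene body |
| `r` | 0.1 | -- | proportional score gain required per greedy addition |
| `d` | 2 | hops | candidate neighbourhood distance |
| `clamp_eps` | 1e-15 | -- | P clamp before the z transform; GWAS minima (~1e-8) unaffected, degenerate inputs stay finite |
| `window` | 0.8 | mass | central quantile window of the empirical-null fit |
| `n_bins` | 10 | -- | covariate strata (deciles) of the weighted resampling |
| `B` | 1000 / 10000 | -- | resamples for assessment / replication |
| thresholds | 0.05 | -- | all seven selection criteria |
| `lambda` | 1 | -- | per-study genomic inflation factor |

The empirical-null window deserves a note.  Narrow central windows
are maximally robust to the enriched upper tail that module search
creates, but the central half of a normal sample carries very little
curvature information about its scale: at a central-50% window the
sampling error of $\sigma$ on 5000 scores is around 20%, making
$P(Z_m)$ essentially unstable.  At the central-80% window the error
drops to 3--4% while a 5% enriched right tail still biases $\sigma$
by only about 2%, so 0.8 is the default; the window remains a
parameter for score distributions with heavier contamination.  The
likelihood is maximized under box constraints (location inside the
window, log-scale within a factor of 20 of the sample SD) because the
unconstrained truncated-normal likelihood has a degenerate uniform
limit along $|\mu|, \sigma \to \infty$ that dominates on small or
platykurtic samples.

## What the generator emulates --- and what it does not

`simulate_network` builds a connected scale-free graph by preferential
attachment: `m` seed vertices, each new vertex attaching `m` distinct
edges with probability proportional to degree + 1, giving exactly
`m (n - m)` edges and hub-dominated degrees.  `simulate_gwas` draws
log-normal gene lengths (median 20 kb), lays genes out on 22
chromosomes with gaps wider than twice the mapping flank, gives each
gene $1 + \text{Poisson}(\text{length}_{kb} \times 0.3)$ SNPs, and
emits per-SNP betas and standard errors from the error model
$se = 1/\sqrt{2N\,\text{maf}(1-\text{maf})}$ with
$\text{maf} \sim U(0.05, 0.5)$ and nominal $N = 2000$, consistent
with $z = \beta/se$ to machine precision.  The planted module is a
random connected subgraph whose SNP z-scores are shifted by the
effect in every causal study, so the best-SNP summarisation and its
gene-length/SNP-density biases act on the signal exactly as on real
data.  Permutation matrices exploit that the minimum of $n$ i.i.d.
uniform P values is Beta(1, *n*): columns are drawn as
$1 - (1-U)^{1/n}$ per gene, preserving the min-P structure without
re-simulating SNPs.

Deliberately not emulated: linkage disequilibrium (SNPs within a gene
are independent, so gene-wise minima are slightly more extreme than
on a real array with correlated SNPs); any polygenic background
shared between studies beyond the planted module (null genes are
independent across studies); genotype-level data of any kind.
Passing tests on this generator therefore demonstrate the machinery's
calibration and recovery mechanics, not performance on real cohorts.

## Known limitations

Two structural properties of the greedy rule, documented above, bound
what end-to-end recovery can achieve at desk scale.  First, the
module-size cap means a planted module of ten comparable weights is
recovered only as its top five or six members by any single module.
Second, on a 1000-gene network a planted cluster whose gene weights
(z about 4.5 after best-SNP summarisation of a 3.0 SNP-level shift)
dominate every null gene becomes globally absorbing: nearly all grown
modules contain it, the candidate modules' evaluation scores then
concentrate around the signal itself, and the *relative*
empirical-null selection loses its contrast --- when every module
replicates, none is significantly better than the bulk.  The
bi-directional design is at its best when signals are comparable to
the strongest null fluctuations and multi-focal, which is the regime
of real GWAS; the package reports the funnel counts at every stage so
this saturation is visible when it occurs.

## Problem sizes used by the tests

The suite exercises calibration on 300-gene networks (2000 module
evaluations per test, B = 499), search invariants on 100 random
50-gene networks, and end-to-end recovery on the 1000-gene "default"
preset over 20 seeded replicates --- sizes chosen so the full suite
documents the method's behaviour at desk scale.  The "paper-scale"
preset (10377 genes, 5 attachments per node) is provided for larger
experiments.
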