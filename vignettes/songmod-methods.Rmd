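---
title: "Co-expression module analysis of songbird vocal circuits: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-expression module analysis of songbird vocal circuits: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(songmod)
```

# The scientific setting

Songbirds learn their vocalizations with a dedicated telencephalic circuit of
four song nuclei — HVC, RA, LMAN, and Area X — each embedded in a surrounding
motor region (the dorsal nidopallium DN, lateral arcopallium LAI, anterior
nidopallium AN, and striatum Str) that serves as its non-vocal control. In
zebra finches only males sing, but chronic early estradiol (E2) treatment
masculinizes the female song system. Bulk RNA-seq of all eight regions from
males and females under vehicle or E2 treatment yields a structured design —
2 sexes x 2 treatments x 3 birds x 8 regions, 96 samples — in which
vocal-learning capability, sex, and treatment can be dissociated as binary
traits.

`songmod` implements the analysis chain this design calls for:

1. fragment counts are normalized to FPKM and filtered to well-expressed
   genes; outlier samples are removed by clustering of the sample space;
2. an unsigned weighted co-expression network is built, modules are detected
   from topological overlap, genes are iteratively reassigned, and module
   eigengenes summarize each module;
3. eigengenes and single genes are correlated against binarized design
   contrasts with Student-t p-values;
4. modules are tested for chromosome enrichment by a label-permutation
   bootstrap with BH-FDR;
5. sex-chromosome dosage is quantified as the male share of each gene's
   expression against copy-number predictions;
6. a four-contrast HVC procedure selects "core" vocal-learning genes and
   tests their Z-chromosome enrichment hypergeometrically.

A synthetic-data generator emulates the full design with known ground truth,
so every stage is testable by recovery.

# The network model

For genes $i,j$ with expression profiles across samples, the unsigned
adjacency is

$$a_{ij} = \lvert \mathrm{cor}(x_i, x_j) \rvert^{\beta},$$

with soft-threshold power $\beta = 6$ by default, chosen for approximate
scale-free connectivity (`pick_soft_threshold()` reports the fit of
$\log_{10} p(k)$ on $\log_{10} k$ over a candidate power grid and selects the
smallest power reaching $R^2 \ge 0.8$). The topological overlap blends direct
adjacency with shared neighbourhood:

$$\mathrm{TOM}_{ij} = \frac{\sum_{u \ne i,j} a_{iu}a_{uj} + a_{ij}}
{\min(k_i,k_j) + 1 - a_{ij}}, \qquad k_i = \sum_{u \ne i} a_{iu}.$$

Modules are branches of the average-linkage dendrogram of $1-\mathrm{TOM}$,
cut at a fixed height, with branches below `min_module_size` (default 100)
sent to the unassigned pool. Genes are then iteratively reassigned to the
module whose eigengene they correlate with best, when that correlation's
p-value beats `reassign_p` (default `1e-6`), until a fixed point. Module
eigengenes are the first principal component over samples of the z-scored
member expression, sign-oriented so that mean member correlation is positive;
kME is each gene's Pearson correlation with an eigengene.

All pipeline correlations (network, trait association, regional sex tests)
are computed on `log2(FPKM + 1)`; dosage fractions use raw FPKM because they
are expression shares. The log scale is standard practice for correlation
networks on RNA-seq abundances: it stabilizes variance across the dynamic
range so that a module's membership is not dominated by its most abundant
genes.

## Why the static cut height defaults to 0.90

A static branch cut is deterministic and fully documented, at the price of a
single global threshold. The operating point matters: with $\beta = 6$ a gene
merges with a formed module at height $1 - \overline{\mathrm{TOM}}$, and at
heights just below 1 the required overlap is so weak that sampling noise
qualifies — with ~100 samples, null correlations of $|r| \approx 0.2$ are
routine and give $\mathrm{TOM} \approx 0.02$ against a large module, i.e. a
merge at height 0.98. Planted-structure experiments show module-internal
merges complete below height ~0.8 while noise genes attach above ~0.93, so
the default cut of 0.90 demands a mean topological overlap of at least 0.1 —
genuine shared-neighbour structure. The cut height, minimum module size, and
reassignment threshold are all exposed in `network_params()`; a parameter
sweep simply maps `detect_modules()` over a grid.

## Overfit modules vs bird-marking modules

Two failure modes of module discovery on small designs are distinguished.
A *technically overfit* module tracks one or two individual samples: its
eigengene has one extreme value (default: $>4$ SD) concentrated in at most
two samples of a single bird, and `flag_overfit_modules()` excludes it. A
*bird-marking* module is elevated in all samples of one animal; it is real
structure (an individual's expression idiosyncrasy), so it is retained but
exposed by `attribute_modules_to_birds()`, which correlates each eigengene
against per-bird indicators and reports the best-matching bird with its
$r^2$. Downstream interpretation can then discount bird-attributed modules
without discarding them.

# Trait association

Contrasts are subset + trait rules over the sample table. The built-in
presets cover: song nucleus vs surround within each sex x treatment cell and
circuit node; E2-treated female song-system samples against all other female
samples at the node (vocal-capable = 1); and female vs male among
vehicle-treated birds per region (female = 1, so expressed W genes correlate
positively). Module-trait tests are two-sided; gene-level sex-chromosome
tests are one-tailed (upper for W, lower for Z). Significance is assessed at
raw $\alpha = 0.05$ by default, uncorrected — matching the analysis this
package reimplements — with a BH option available (`correct = TRUE` in
`regional_sex_tests()`, `bh_fdr()` elsewhere).

The test statistic throughout is the Student-t transform of the Pearson
correlation, $t = r\sqrt{n-2}/\sqrt{1-r^2}$ on $n - 2$ degrees of freedom.

# Chromosome and gene-set enrichment

`chromosome_module_enrichment()` computes, per (chromosome, module) pairing
among module-assigned genes, fold = observed / expected with expected =
module size x chromosome share of the assigned universe. The null is
generated by randomizing the gene-to-module mapping (module sizes preserved;
50,000 permutations by default), and the empirical p-value uses the add-one
estimator $(1 + b)/(B + 1)$ so it is never zero; q-values are BH over the
full grid. For a single pairing this permutation null is exactly
hypergeometric, which the test suite exploits as an analytic cross-check.

`gene_set_test()` is a deliberately simple set test: a one-tailed Welch t of
member vs non-member per-gene statistics (kME, or a contrast correlation).
It shares the inferential target of sample-permuting gene-set methods — is
the set's signal shifted against the background? — but is not a reimplementation
of them; treat its p-values as a screen, not parity with GAGE-style tests.

# Sex-chromosome dosage

In the avian ZW system males are ZZ and females ZW, so without compensation
copy number predicts a male share of expression of $2/3$ for Z genes, $0$ for
W genes, and $1/2$ for autosomes (`predicted_fraction()`, exact rationals).
`male_expression_fraction()` averages FPKM per region within each sex, then
averages the region means, then forms
$\mathrm{male\_avg}/(\mathrm{male\_avg}+\mathrm{female\_avg})$; region
averaging precedes the ratio, and zero-total genes are reported as missing
rather than 0/0. `summarize_dosage_by_module()` flags (module, class) cells
whose mean deviates from the prediction by more than a configurable margin
(default 0.1) as compensated. Per-region one-tailed sex tests and their
cross-region unions/intersections identify consistently dimorphic
transcripts.

# Core-gene selection

The four HVC vocal-learning contrasts are: all male HVC vs all male DN;
E2-treated female HVC vs all other female samples at the node; vehicle male
HVC vs vehicle female HVC; E2 female HVC vs vehicle female HVC — the
vocal-capable class coded 1 in each. A gene is *of interest* in a contrast
when its trait correlation satisfies $p \le 0.05$ and $r^2 \ge 0.5$ and its
squared membership in the focal module satisfies $\mathrm{kME}^2 \ge 0.5$;
*core genes* meet the criteria in all four contrasts. The $r^2$ thresholds
are sign-agnostic by default because the printed criterion is $r^2$-based;
`require_positive = TRUE` restricts to positive trait correlation for users
who read the selection regions as one-sided. Z-chromosome enrichment of the
core set is an upper-tailed hypergeometric draw-without-replacement test,
reported against both the module-assigned background and the focal module's
own members (core genes outside the focal module are not draws from it).

# The synthetic-data generator

`simulate_expression()` draws a lognormal-Poisson count matrix over the full
design. Key modeling choices, with rationale:

- **Planted modules.** Each module has a latent eigengene equal to its
  design pattern (e.g. "on in male HVC and E2-female HVC") plus sample-level
  Gaussian noise (`module_latent_sd`, default 0.05); members multiply their
  baseline by $\exp(\mathrm{effect} \times \mathrm{eigengene} + \varepsilon)$
  with $\varepsilon \sim N(0, \mathrm{noise\_sd}^2)$, `noise_sd` 0.2. The
  default plan emulates the emulated study's headline patterns: an Area
  X/striatum module (300 genes, effect 2), an RA module (250, 2), an LMAN
  module (200, 2), an HVC vocal-learning module (150, 3), and a male-biased
  module (120, 1.2) that the sex-chromosome genes attach to. Effects are
  natural-log on/off fold amplitudes (effect 2 is about 7.4-fold, roughly
  ten noise SDs — strong, as regional marker genes are).
- **Sex chromosomes.** 5% of genes are Z-linked, half simulated
  uncompensated (weights doubled in males), half sex-equal; 1% are W-linked
  and female-only, with an optional male paralog-leakage factor
  $\lambda$. Dose-only genes carry no latent module effect, so their male
  expression share stays at the copy-number prediction; their dosage-driven
  dimorphism makes them cluster with the male-biased module, whose truth
  label they share. The focal HVC module is autosomal, so the Z identity of
  core genes — a dataset-dependent feature of the real data — is not
  emulated.
- **Library composition.** Per-sample rates are normalized so each library's
  expected size is `library_size_mean` (default 3e7). The structured genes
  sit at moderate abundance (~3–5 FPKM, near the real module-assigned
  median) while the unstructured background pool carries ~97% of library
  mass, standing in for the large stable transcriptome outside the simulated
  catalog. This keeps FPKM compositional coupling — every gene dips when a
  planted module switches on — at the ~2% level it has in real libraries;
  with a small background pool that coupling becomes strong enough to pull
  background genes into modules, which is a generator artifact, not a
  property of the emulated study.
- **Counts.** Fragment weights multiply by exonic length (drawn log-uniform
  0.3–10 kb), so counts scale with length and FPKM normalization is
  genuinely exercised; counts are Poisson around the lognormal rates.
- **Artifacts.** `inject_artifacts()` replaces the counts of
  `outlier_samples` (default 2, as removed in the emulated study) with an
  independent lognormal-Poisson profile, and elevates reserved gene blocks
  ~7.4-fold in all samples of one bird (`bird_specific_modules`, default 1)
  to emulate bird-marking modules.

What passing recovery tests does and does not show: the generator produces
clean block-structured modules with known effect sizes, Poisson-level
technical noise, and no batch structure, GC/length bias beyond the explicit
length term, cross-hybridizing paralogs, or cell-composition gradients. Near-perfect
recovery here demonstrates that the pipeline's machinery is correct and
calibrated, not that real tissue yields modules this crisp.

# Numerical choices

- Eigengenes come from the SVD of z-scored member rows; constant member rows
  are dropped (a fully constant module yields a zero eigengene). Sign is
  fixed by positive mean member correlation; ties in reassignment break
  toward the current module, then lexicographic label order, so results are
  order-independent.
- Empirical enrichment p-values use the $(1+b)/(B+1)$ rule; the attainable
  minimum at $B$ permutations is $1/(B+1)$.
- The correlation test reports $p = 0$ when $|r| = 1$ (the t statistic is
  infinite); callers comparing tails should use the one-tailed forms, which
  satisfy $p_\mathrm{upper} + p_\mathrm{lower} = 1$.
- Outlier samples are flagged by the z-score of mean inter-sample
  $1 - r$ distance (default cut 2.5 SD), which is deterministic and
  order-invariant; a dendrogram-cut mode is available as an alternative.
- All randomness flows from one master seed through per-stage derived seeds,
  so a single integer reproduces a run; the bootstrap seed is recorded in
  the manifest.

# Problem sizes

The default simulated study is 2000 genes x 96 samples — large enough that
single-block TOM computation, 50,000-permutation enrichment, and the full
pipeline complete in seconds on one CPU, and small enough to iterate on.
All sizes scale upward through `sim_config()` and `network_params()`; the
single-block network computation is the only stage whose memory grows
quadratically in gene count.

# Known limitations

- Static tree cut and batch reassignment approximate, but do not replicate,
  dynamic tree-cut implementations; parity with them is a non-goal.
- The gene-set test is a per-gene-statistic screen, not a sample-level
  permutation method.
- Dosage fractions are means of region means; designs with very unbalanced
  region sampling should weight accordingly.
- The generator does not emulate read-level artifacts, alignment ambiguity
  between Z and W paralogs (it assumes uniquely attributed counts), or
  sex-linked core genes in the focal module.
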