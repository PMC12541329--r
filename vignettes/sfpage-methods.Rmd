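---
title: "Gene-age structured analysis of a seminal fluid proteome: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-age structured analysis of a seminal fluid proteome: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfpage)
```

## The scientific problem

Seminal fluid proteins (Sfps) are transferred to females during copulation and
drive post-mating physiology and behaviour. They are often treated as a
uniformly young, fast-evolving gene category. `sfpage` implements a pipeline
that asks whether that view survives stratifying an Sfp gene catalog by
*evolutionary gene age*: are ancient Sfp genes more pleiotropic (broader
expression, more interaction partners, wider functional annotation) and more
evolutionarily constrained than young ones, and do young genes concentrate in
a dense reproductive core of the protein-interaction network?

The pipeline consumes only tabular inputs — candidate gene lists, a
gene-to-age-class table, an expression matrix, a scored interaction edge
table, and per-gene polymorphism/divergence counts — and every input class can
be generated synthetically with known ground truth, so the full analysis runs
and is validated offline.

## Catalog and age classes

Two independent candidate lists are combined by union (`assemble_catalog()`),
with the intersection kept as a "conservative set". Gene identifiers are
opaque strings matched exactly and case-sensitively; we deliberately avoid
silent symbol/ID aliasing. Age classes A–E are phylostratigraphic strata from
oldest (present before the radiation of the genus) to youngest (restricted to
the focal species subgroup). Genes missing from the age table stay
`UNASSIGNED` — fatal only if they are not declared exceptions — and are
excluded from every age-stratified statistic, mirroring the exclusion of a
single unclassifiable pseudogene such catalogs typically contain.

Cross-validation (`cross_validate_ages()`) takes a set of genes with
independent deep-ortholog support: any such gene assigned a young class (D or
E) counts as a discrepancy, and the report is simply the discrepancy fraction.
Whether discrepant genes keep their original class downstream is configurable;
the default keeps them, because reassignment would presuppose which call is
wrong.

Paralog redundancy is handled by `collapse_paralogs()`: one representative per
group, chosen as the member with the most non-missing attributes, ties broken
lexicographically — deterministic and favouring data completeness. Groups that
mix age classes keep the oldest class (a gene family is at least as old as its
oldest member), with a warning.

## Composition tests

`age_composition_test()` compares a gene set's age-class counts with
expectations from genome-wide background proportions via a chi-square
goodness-of-fit test. Per-class post hoc tests use adjusted standardized
residuals,

$$ z_c = \frac{O_c - E_c}{\sqrt{E_c (1 - p_c)}}, $$

with two-sided normal p-values and Benjamini–Hochberg (BH) adjustment across
the $k = 5$ classes. We treat one composition test as one multiple-testing
family — the smallest defensible unit — rather than pooling families across
analyses. No continuity correction is applied; the intended use has
large-sample counts. A goodness-of-fit test is the default reading of
"observed vs expected composition"; the independence-test variant is available
through `chi_square_independence()` for contingency-table layouts.

## Tissue specificity (tau)

For a gene with expression $x_1, \dots, x_N$ over $N$ tissues,

$$ \tau = \frac{\sum_{i=1}^{N} (1 - x_i / \max_j x_j)}{N - 1}, $$

so $\tau = 0$ for uniform and $\tau = 1$ for single-tissue expression. A gene
is called tissue-specific at $\tau \ge 0.9$ (the threshold is a parameter) and
target-specific when additionally its maximum expression falls in a declared
target tissue set (e.g. the male reproductive glands). Which columns
constitute that target set is a required configuration item, because
delivered tissue panels differ in how they split reproductive tissues;
sex-shared tissues measured in both sexes are kept as distinct columns.

Expression is transformed with $\log_2(x + 1)$ by default before computing
tau. On FPKM-scale data the raw-scale index saturates: any gene with a
moderately dominant tissue scores near 1. On the log scale, $\tau \ge 0.9$
requires near-zero background expression, which is the biologically
interesting call. The transform is configurable (`transform = "identity"`),
and the scale-invariance property of tau holds on whichever scale it is
computed. Argmax ties resolve to the first tissue in column order and are
recorded. All-zero genes have undefined tau and are excluded from calls.

## Interaction network

Edge confidences arrive as per-channel scores (neighborhood, fusion,
co-occurrence, co-expression, experiments, database, text mining), either on
[0, 1] or the 0–999 integer export dialect (auto-detected; values above 2 are
treated as the integer dialect). `combine_scores()` follows the standard
prior-removal convention: with prior $p$ (default 0.041), each channel is
rescaled to $s_i' = \max(0, (s_i - p)/(1 - p))$, combined as
$1 - \prod_i (1 - s_i')$, and the prior is restored. Text mining is excluded
by default, so co-citation evidence cannot create edges. An edge with no
evidence above the prior reports 0 rather than the prior floor.

`build_network()` keeps edges at or above the high-confidence threshold 0.7
and retains isolated Sfp nodes, so degree-0 genes stay in the analysis.
Subnetworks (`extract_subnetworks()`) are connected components of the
*Sfp-induced* subgraph — paths through non-Sfp intermediates do not merge
components — with at least 4 members; the largest is the core.

**Monte Carlo enrichment.** For each subnetwork of size $k$ and each age
class, `mc_age_enrichment()` draws `n_resamples` subsets of size $k$ without
replacement from a universe (default: the genes belonging to reported
subnetworks, the universe per-subnetwork fractions are naturally quoted
against; an
all-networked-Sfps universe is available). Empirical p-values use the
pseudo-count estimator $p = (1 + r)/(n + 1)$, which never returns zero.
Enrichment and depletion are two one-sided tests with BH families per
direction across all subnetwork-by-class cells. With the universe held fixed
this resampling null is exactly hypergeometric, which the test suite exploits
as an independent oracle. Each subnetwork draws from a seed-keyed child
stream, so results do not depend on evaluation order.

**Reproductive association.** The subnetworks-by-{reproductive,
non-reproductive} table is tested with a Pearson chi-square whose p-value
comes from margin-preserving Monte Carlo simulation (default 2,000 tables),
plus per-cell adjusted standardized residuals with BH correction. A zero
margin (e.g. every gene flagged reproductive) is an error, not a degenerate
p-value.

## McDonald–Kreitman rates

Per gene, with polymorphism counts $P_n, P_s$, divergence counts $D_n, D_s$
and site counts $L_n, L_s$:

$$ \omega = \frac{D_n / L_n}{D_s / L_s}, \qquad
   \alpha = 1 - \frac{D_s \, P_n^{*}}{D_n \, P_s}, \qquad
   \omega_a = \alpha\,\omega, \qquad \omega_{na} = (1 - \alpha)\,\omega. $$

$\alpha$ may be negative under segregating deleterious variation and is
reported unclipped; $\omega_a + \omega_{na} = \omega$ holds identically.
Genes with $D_s = 0$ (no synonymous divergence) or $P_s = 0$ / $D_n = 0$ are
flagged unusable with a reason rather than silently dropped. Per-site
$\omega$ is the default; a raw-count mode exists because per-gene rate
tables are not always explicit about the normalisation.

**The 5% frequency threshold.** $P_n^{*}$ is an estimate of the *neutral*
nonsynonymous segregating sites. Deleterious amino-acid variants segregate at
low frequency, so sites with derived-allele frequency at or below the cutoff
(default 5%, strict inequality retained; a folded minor-allele-frequency mode
is available since SFS polarisation conventions vary) are removed from the
nonsynonymous SFS. Truncation alone, however, also removes genuinely neutral
low-frequency variants — under the standard neutral spectrum
($\mathbb{E}[\xi_i] \propto 1/i$) the bins at $\le 5\%$ hold a third to a half
of all neutral variants, which would bias $\alpha$ upward while $P_s$ stays
untouched. Because the threshold is an *estimation* step, the default
(`neutral_rescale = TRUE`) divides the retained count by the expected neutral
mass above the cutoff,

$$ P_n^{*} = \frac{\sum_{i/n > c} \xi_i}{\sum_{i/n > c} i^{-1} \Big/
             \sum_{i=1}^{n-1} i^{-1}}, $$

giving an estimator that is unbiased under pure neutrality and removes the
deleterious excess when present. The raw truncated count remains available
(`neutral_rescale = FALSE`). $\alpha$ is computed per gene (single-gene
estimates, as in threshold-corrected MKT practice), with a pooled
(summed-counts) mode for stability on small per-gene counts; no
asymptotic-MKT curve fitting is attempted, since the correction modelled here
is a single threshold.

## Synthetic data generators

Each generator is a pure function of its parameters and a seed, and emits a
ground-truth table sufficient to score recovery without inspecting generator
internals.

* `gen_catalog()` — two candidate lists with a fixed overlap and multinomial
  age classes. The study-scale default is 357 genes, a 228-gene intersection
  (the 129 single-study genes split 65/64) and class proportions
  (0.62, 0.10, 0.10, 0.08, 0.10).
* `gen_expression()` — planted tissue-specific genes at a foreground level on
  one target tissue over background, with multiplicative lognormal noise of
  a given CV (mean 1). It emulates a 31-tissue adult panel.
* `gen_network()` — planted-partition blocks over Sfp genes (default sizes
  64/13/6/5/5/5); a random spanning cycle guarantees each block is connected,
  Bernoulli($p_{in}$) adds density, and cross edges attach non-Sfp genes.
  Intended edges carry a high `experiments` channel score; optional decoy
  edges carry only text mining evidence and must vanish once that channel is
  excluded. Exact per-block class counts can be planted for composition
  experiments.
* `gen_mkt_counts()` — Poisson counts around a neutral scaling $\omega_0$,
  adaptive substitutions added to realise a chosen true $\alpha$, neutral SFS
  mass placed $\propto 1/i$ and a deleterious fraction confined to bins at or
  below a frequency ceiling. The $1/i$ shape is the standard neutral
  expectation, not a coalescent simulation: the generators exist to test
  estimator arithmetic and the threshold correction, not population-genetic
  realism (no linkage, no demography, no selection on synonymous sites).

What passing tests on these generators shows — and does not show — about real
data: recovery and calibration results validate the *estimators and tests*
under their stated assumptions. Real tissue panels have correlated tissues
and heavy-tailed expression; real interactomes have hubs and degree
heterogeneity; real SFS are distorted by demography. None of those features
are emulated, so the pipeline's statistical behaviour on real inputs should
be judged by the robustness of the underlying tests (rank-based comparisons,
resampling nulls with the universe held fixed), not by the synthetic recovery
rates.

## Genome background proportions

Genome-wide age-class proportions are an input, not something the package can
derive. The generator default, (A, B, C, D, E) = (0.83, 0.06, 0.04, 0.03,
0.04), encodes a genome dominated by ancient genes — the situation in which an
Sfp catalog with 62% class-A genes is still *under*-represented for ancient
genes, the qualitative pattern the pipeline is built to detect.

## Numerical and design choices

* **Empirical p-values** use $(1+r)/(n+1)$ everywhere; the smallest attainable
  value is $1/(n+1)$, so reported Monte Carlo p-values are floor-limited by
  the resample count (default 100,000 for enrichment, 2,000 for the
  association test).
* **Seeding.** A single master seed is mandatory for stochastic stages; every
  operation derives a child seed from a deterministic string hash of
  (operation, unit id), so a pipeline re-run — or a reordering of subnetworks
  — is bit-reproducible.
* **Two-group comparisons** are Wilcoxon rank-sum with a signed Z from the
  tie-corrected normal approximation (exact p for small tie-free samples).
  Some software reports these with a chi-square label; $z^2$
  equals that statistic asymptotically, and both are recoverable from the
  result object.
* **Degenerate inputs**: all-zero expression rows get undefined tau; empty
  groups are dropped with a warning; a subnetwork exceeding its resampling
  universe, a zero contingency margin, an expected count of zero, and an SFS
  that does not sum to $P_n$ are hard errors.
* **Calibration experiments** in the test suite use a null configuration
  (universe 500, subnetwork 100, class frequency 0.5, 999 resamples) chosen
  by exact hypergeometric analysis so the discrete count statistic is close
  enough to continuous for the empirical p-value to attain its nominal level;
  with small universes the estimator is conservative by construction, which
  is the expected behaviour of pseudo-count empirical p-values on discrete
  statistics.
* **Problem sizes** in tests and the acceptance script (e.g. 60–200 genes per
  MKT replicate, 200 replicates per recovery curve, 100,000 enrichment
  resamples on a 98-gene universe) were chosen as the smallest sizes at which
  the assertions are statistically meaningful.

## Known limitations

* Age classes are consumed, never inferred; orthology calls and paralog
  groups likewise arrive as inputs.
* The enrichment universe question (networked genes vs all genes with
  interaction data) is left configurable because reported fractions can be
  read either way; the default is the networked universe.
* Monte Carlo enrichment p-values below $1/(n+1)$ are unobservable; raise
  `n_resamples` if smaller p-values must be resolved.
* The neutral-mass rescaling of the SFS threshold assumes the $1/i$ neutral
  shape; under strong recent demography the retained-mass fraction differs,
  and the raw truncated count (with a matching synonymous treatment upstream)
  may be preferable.
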