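---
title: "Methods: family-based two-hit integration of variants and expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: family-based two-hit integration of variants and expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical procedures in `twohit`, the
assumptions behind them, the parameter choices that matter, and the
design of the synthetic family cohort that the test suite uses as ground
truth.

## The two-hit question

In families segregating a recurrent pathogenic deletion, the analysis
asks three connected questions: (i) which expression changes are
attributable to the deletion itself, (ii) whether rare deleterious
"second-hit" variants elsewhere in the genome associate with additional
expression changes, stratified by which parent transmitted them, and
(iii) whether second-hit genes and dysregulated genes are unusually close
in a tissue-relevant interaction network.  Each stage is an ordinary,
well-understood statistic; the contribution is the family-aware
integration, so the package keeps every stage inspectable and separately
testable.

## Variant taxonomy

Small variants pass quality filters (QUAL > 50, read depth > 8, allele
balance within [0.25, 0.75] or > 0.9 for homozygous calls) and rarity
filters (gnomAD allele frequency <= 0.001, fewer than 10 carriers in an
optional in-house panel).  CADD >= 10 is required for every class except
loss-of-function and splice-site variants, which are exempt.  One filter
needed a direction decision: the quality-depth statistic (QUAL per
alternate read) is listed among quality criteria without an explicit
keep/remove side; `twohit` *removes* calls with QD < 1.5, the
conventional low-QD exclusion.  This is a package decision and is
exposed in `variant_filter_config()`.

Classification is position- and annotation-driven, strand-aware, and
deliberately multi-label: a variant may receive labels for several genes
and several labels per gene (e.g. `upstream_snv` plus `enhancer_snv`).
The 25-class enumeration (11 SNV + 8 SV + 6 STR classes,
`variant_classes()`) is the package's reconstruction of the standard
coding / UTR / flanking / regulatory / structural split; the class list
is config-driven so an alternative partition can be swapped in.
Regulatory labels require a chromatin-state segment (promoter: states
1–3, enhancer: 4–7, silencer: 12) containing the position *and* a TSS
within 50 kbp; flanking labels use 1 kbp from the TSS/TES base,
inclusive.  Internally all intervals are 0-based half-open; VCF and GTF
are converted at the file boundary.

CNV calls of one type from one sample are merged transitively when they
overlap or are separated by a gap below both 20% of the CNV length and
50 kbp; after merging, SVs are classified per overlapped gene by
geometry (encapsulating / interstitial / 5′ or 3′ UTR overhang, with the
5′ end defined by strand).  STR expansion calls use the cohort
distribution at each locus: loci must be called in > 95% of samples with
non-zero variance, and a call is an expansion when its repeat length
exceeds the mean plus three sample (n−1) standard deviations, computed
over one call per individual.

Inheritance is genotype matching for SNVs (either parent carries the
alternate allele; both parents give `unresolved`, neither `de_novo`),
strict > 50% reciprocal overlap with a same-type parental call for SVs,
and exact repeat-length matching (configurable tolerance) for STRs.
Phase is not used; with deep short-read trios, genotype matching is the
robust default.

## The differential-expression engine

Cohort analyses of this kind usually reach for an off-the-shelf NB
quasi-likelihood engine; `twohit` re-implements the model rather than
wrapping one, so that its behaviour is fully specified by the code here:

* per-gene log-linear negative-binomial model fitted by IRLS
  (`glm.fit` with an NB family), log library-size offsets;
* gene-wise dispersion by matching the Pearson statistic to its residual
  degrees of freedom, i.e. solving
  `sum((y - mu)^2 / (mu + phi mu^2)) = n - p`.  The df-aware estimator
  matters: a naive method-of-moments estimate ignores the parameters
  spent on the mean model and inflates type-I error at replicate-level
  sample sizes;
* shrinkage of gene-wise dispersions toward a lowess mean–dispersion
  trend with prior weight `prior_df = 10` (between the heavy shrinkage
  appropriate for 3-vs-3 trio fits and none);
* a 1-df likelihood-ratio chi-square for the group coefficient, BH-FDR
  across tested genes.

Numerical identity with any external engine is *not* a goal; the engine
is accepted on its operating characteristics, which the test suite
measures: null type-I error within three binomial standard errors of
0.05 on 1000-gene NB null simulations, and near-complete power for a
4-fold shift at mean 100, dispersion 0.1, 6 vs 6 columns.  A separate
test cross-checks fold-change estimates against edgeR on one simulated
dataset (rank correlation, not equality).

Low-expression filtering is `count >= 10` in at least 70% of the
smallest group's columns for the global comparison (exposed as
`min_count` / `min_prop`), and the 25%-of-replicates expression rule for
trio tests, both strict as printed.

The global carrier-vs-noncarrier comparison includes family as a fixed
covariate and is robustified against single-sample leverage by
leave-one-out intersection: the test is repeated once per sample with
all of that sample's replicates removed, and only genes at FDR < 0.05 in
*every* iteration are kept.  Kinship-model alternatives are out of
scope; the intersection is the robustness mechanism.

## Outlier z-scores

Per individual: median TPM across replicates, `log2(x + 1)`, per-gene
z-score across individuals.  Because samples cluster by family, one
latent factor — the top singular component of the row-standardised z
matrix — is removed as a rank-one term, after which rows are
re-standardised and `|z| > 2` (strict) flags outliers.  Re-standardising
after factor removal is required for the threshold to keep its nominal
meaning; this is a deliberate choice where the source procedure is
ambiguous.  A single factor is the default because the planted (and the
observed) family structure is approximately rank one; `n_latent` is a
parameter.

## Splicing, ASE, patterns

Splicing calls are isoform-level DE (same NB engine) inside genes whose
gene-level test is not significant in the same offspring–parent
comparison; single-isoform genes are excluded because their isoform test
is identical to the gene test.  ASE uses the exact two-sided
(minimum-likelihood) binomial test at p = 0.5 on haplotype read counts
with total > 10, BH-corrected within each individual, and calls at
FDR < 0.05 — the source description prints an "FDR > 0.05" rule that can
only be a typo, and the package implements the conventional direction.
Called ASE genes are flagged when a classified coding variant (LOF,
missense, splice-site) is phased on the overexpressed haplotype.

Family patterns are set algebra on the two parental DE sets (`unique`,
`shared_carrier`, `shared_noncarrier` partition their union).  The
cohort-level comparison of shared-with-carrier versus
shared-with-noncarrier counts uses a paired two-sided Wilcoxon
signed-rank test — the paired analogue of the Mann-Whitney test named in
this literature.  Tied paired differences are common for count data, so
`signed_rank_test()` builds the exact null by convolution over sign
flips with midranks for n <= 20 (tie-aware exact p-values) and falls
back to the tie-corrected normal approximation above that.  Counts or
proportions of per-offspring totals are both supported; proportions are
the default when totals are supplied, since offspring differ strongly in
their total number of changes.

## Enrichment, burden, synergy

Enrichment uses gene–individual pairs as units: within each stratum
(all samples; carrier children / carrier parents / noncarrier parents;
carrier children restricted to variants inherited from the carrier or
noncarrier parent), a 2×2 table of variant presence against change
presence over the expressed-gene × sample background, Fisher's exact
two-sided p, a Wald 95% CI on the log odds ratio with Haldane–Anscombe
0.5 correction only when a cell is zero (the p-value is always exact),
and BH across the 25 classes within each (change type, stratum) family.
Gene–individual units (rather than pooled genes) match the per-person
nature of outlier and inheritance data; a per-gene analysis can be had
by collapsing the change table first.  Genes with several variants of
one class count once per (gene, individual, class) but appear in every
class they hit.

Synergy genes are the conjunction: in the global LOO-intersection DE
set, an outlier in a specific deletion carrier, and hit by a second-hit
variant inherited from the noncarrier parent in that carrier.

## Network proximity

Edges with interaction probability strictly above 2.0 are retained
(duplicates collapse to the maximum; self-loops dropped) and weighted by
inverse probability, so high-confidence interactions are short.  For
each carrier offspring, the observed quantity is the mean Dijkstra
distance over all connected ordered pairs between the offspring's
second-hit coding genes (LOF, missense, splice-site, exonic STR,
encapsulating DEL/DUP) and its expression-changed genes; disconnected
pairs are excluded and counted rather than given a sentinel distance.
The null relabels *all* nodes uniformly (topology untouched, so the
degree sequence is preserved exactly), 100 replicates by default;
`z = (permuted mean − observed) / permuted SD`, one-tailed `p = Φ(−z)`
for the "observed smaller" alternative, plus an add-one empirical p.
Both z and the empirical p are reported because the analytic p assumes
approximate normality of the permuted means.  Offspring-level p-values
are BH-corrected, and the cohort-level comparison of observed versus
permuted means is the same exact signed-rank test as above.

## The synthetic cohort

`simulate_cohort()` generates the study conditions the pipeline is
designed for: five families, 32 individuals (19 deletion carriers, 13
noncarriers; 10 carrier children; six discordant parent pairs, one
family with two; three grandparent pairs; four noncarrier siblings — 13
complete trios, because one carrier child has an unenrolled second
parent), three replicates per sample, and a 7-gene deletion region
modelled purely as 0.5× expected dosage.  Counts are negative binomial
with log2-mean = baseline + family effect + dosage + cis effects +
outlier shifts:

* baselines log-uniform on [100, 2000] counts/replicate and dispersions
  uniform on [0.02, 0.08] — the range typical of deeply sequenced LCL
  replicates;
* the family effect is a rank-one batch-like term (gene loadings
  ~N(0, 0.3) times a family score), reproducing the family clustering
  that the one-factor correction is designed to remove;
* per-individual biological noise SD 0.2 (log2);
* planted outlier shifts are expressed in z units (default 4) and
  converted per gene using the expected between-individual SD (biological
  plus replicate-median sampling noise), so the planted z-shift is
  calibrated regardless of the gene's depth;
* per-class cis effect sizes (LOF and encapsulating deletions −1,
  duplications +0.6, regulatory SNVs ±0.5 log2) are placeholders for
  power studies — no published per-class effect sizes exist to anchor
  them — and one strong loss-of-function wave (one per carrier child,
  inherited from the noncarrier parent) creates the conditions under
  which class-level enrichment is recoverable;
* planted synergy cases put noncarrier-inherited variants on
  deletion-region genes at −1.5 log2: the dosage split already inflates
  those genes' between-individual SD, so a second hit must move well
  past one dosage unit to stand out as an outlier — this is a property
  of the synergy definition itself, not a tuning artifact;
* isoforms (2–3 per gene, Dirichlet baseline usage) are multinomial
  splits of gene counts, so totals are conserved exactly; splice shifts
  move the target isoform to 90% usage in the affected child;
* haplotype counts are Binomial(n, 0.5) nulls at ~200 reads with
  planted fractions of 0.85, five of them phased with a coding variant
  on the major haplotype;
* the network is Erdős–Rényi with weights straddling the 2.0 threshold;
  "planted" mode adds high-weight edges between second-hit coding genes
  and expression-changed genes with probability 0.35 per pair, "null"
  mode wires independently of labels.

Decoy variants failing exactly one filter each (low CADD, common AF, low
QUAL, low depth, bad allele balance, low QD, in-house frequency) and
decoy STR loci (zero variance; low call rate) are planted so the filter
direction of every rule is observable.  Every planted effect is recorded
in a truth table, and all generator stages are deterministic given the
seed (byte-identical files).

What the generator does *not* emulate: read-level data (no FASTQ/BAM, no
sequence content), linkage between variants, chromatin-contact effects
on flanking genes (the deletion is pure dosage), eQTL architecture,
technical batch beyond the single family factor, and the long-tailed
outlier structure of real transcriptomes.  Passing recovery tests
therefore demonstrates that the *procedures* are correct and calibrated
under their stated model, not that real-cohort effect sizes would be
recovered at these rates.

### Problem sizes

Defaults are desk-scale: 260 genes (7 deletion, ~240 protein-coding),
96 expression columns, ~600 isoforms, ~8000 haplotype rows, a ~260-node
network, 100 permutations per offspring.  At these sizes the full
pipeline runs in about a minute on one CPU and the complete test suite —
including 1000-gene null calibrations at three seeds, 50 null network
cohorts, and a ten-seed enrichment-recovery study — in a few minutes.
All sizes scale through `cohort_spec()`.

### A note on the synthetic pattern comparison

In the synthetic cohort the paired shared-carrier vs shared-noncarrier
comparison tends to come out significant even though no parent-of-origin
bias is planted in the second-hit variants: the seven deletion-region
genes are differentially expressed against the noncarrier parent in
every carrier-offspring trio (hence "shared with the carrier parent"),
and at 260 genes they are not diluted by genome-scale background changes
the way they would be in real data.  This is a faithful consequence of
the planted dosage, and a useful reminder that the pattern test measures
the whole transcriptome's asymmetry, not only the second-hit signal.

## Known limitations

* The NB engine tests one group coefficient with categorical covariates;
  continuous covariates and interaction designs are out of scope.
* Inheritance assignment does not use phase and cannot separate
  identical parental genotypes (`unresolved`).
* The latent-factor correction removes exactly `n_latent` components;
  confounders that correlate with carrier status would be partially
  absorbed, as with any unsupervised correction.
* Network permutation relabels all nodes; an alternative restricted to
  labelled nodes is a documented variant (the choice matters only when
  labelled genes have atypical degree).
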