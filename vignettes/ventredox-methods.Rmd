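---
title: "Methods: proteome carbon oxidation state and community statistics for vent metagenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proteome carbon oxidation state and community statistics for vent metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ventredox)
```

## Scope and background

Serpentinization of mantle rocks produces H2-rich, alkaline, reducing
fluids.  Where such fluids discharge at the seafloor they build
carbonate–brucite chimneys whose microbial communities experience a
mixing gradient between reducing hydrothermal fluid and oxygenated
seawater.  One genomic proxy for the prevailing redox regime is the
average carbon oxidation state, $Z_\mathrm{C}$, of the proteins a
community encodes: proteomes evolved under reducing, alkaline conditions
tend to be built from more chemically reduced amino acids.

`ventredox` implements the downstream computational analysis such a
study requires, starting from assembled and annotated products (predicted
protein FASTA, featureCounts-style gene count tables, gene annotation
tables with KO ids and lineages, ASV tables): per-sample
abundance-weighted $Z_\mathrm{C}$ distributions with replicate
subsampling and statistical comparison; TMM and CSS count normalization;
Bray–Curtis distances with ANOSIM, PERMANOVA and Mantel permutation
tests; KEGG-module completeness with a half-missing detection rule;
marker-gene, hydrogenase and lineage profiling; and a synthetic-data
generator that reproduces the statistical structure these methods
assume, with exactly known ground truth.  Upstream steps (assembly,
mapping, gene calling, homology annotation, taxonomy assignment) are out
of scope: the package consumes their tabular outputs.

## Average carbon oxidation state of a protein

For a molecule with elemental formula
$\mathrm{C}_c\mathrm{H}_h\mathrm{N}_n\mathrm{O}_o\mathrm{S}_s$ and net
charge $z$, assigning the nominal oxidation states H $=+1$, N $=-3$,
O $=-2$, S $=-2$ and requiring the atomic oxidation states to sum to the
net charge gives the mean oxidation state of the carbon atoms:

$$Z_\mathrm{C} \;=\; \frac{z - h + 3n + 2o + 2s}{c}.$$

Protein formulas are sums of residue formulas (free amino acid minus one
water) plus one terminal water per chain, for the neutral species
($z = 0$).  Two conventions matter and are fixed here:

* **Terminal water** is included by default (`terminal_water = TRUE`).
  Because H2O contributes $-2 + 2 = 0$ to the numerator and no carbon,
  it never changes $Z_\mathrm{C}$ itself; it only matters if formulas
  are exported for other uses.  A flag disables it.
* **Net charge** is zero for all proteins.  Ionization modeling is out
  of scope.

Residue $Z_\mathrm{C}$ spans $[-1, +1]$: glycine (and asparagine,
aspartate) attain $+1$, leucine and isoleucine $-1$.  Non-standard
residue codes (including selenocysteine `U` and pyrrolysine `O`, whose
handling the upstream tools do not standardize) are dropped with a
warning by default; proteins with more than 10% non-standard residues
are excluded from a proteome.  Trailing `*` stop codons, a common gene
caller dialect, are stripped silently.

## Abundance weighting and the subsampling estimator

Complete predicted proteins are weighted by the abundance of their
encoding genes (per-sample weights normalized to sum to one), so that
the composite proteome reflects the community's gene abundance
structure, not just gene presence.  The analytic summary of one sample
is the pool $Z_\mathrm{C}$,

$$Z_\mathrm{C}^{\mathrm{pool}}
  = \frac{\sum_i w_i\, c_i\, Z_{\mathrm{C},i}}{\sum_i w_i\, c_i},$$

identical to the $Z_\mathrm{C}$ of the weighted sum of all elemental
formulas.

To expose intra-sample variability, `subsample_zc()` repeatedly draws a
composite proteome of about `target_aa` = 200,000 amino acids
(100 replicates by default): proteins are drawn **whole, with
replacement**, with probability proportional to their weight, until the
cumulative residue count first reaches the target; the last protein is
kept whole, so replicates reach the target *on average*.  Each
replicate's $Z_\mathrm{C}$ is the $Z_\mathrm{C}$ of the pooled formula
of the drawn proteins — the carbon-weighted mean of their per-protein
values — so a long protein contributes in proportion to its residues per
draw rather than dominating as a single observation
(length normalization).  An alternative mode
(`per_protein_mean = TRUE`) averages per-protein $Z_\mathrm{C}$
unweighted, for sensitivity analysis.  The replicate mean converges to
$Z_\mathrm{C}^{\mathrm{pool}}$ as `target_aa` grows; at 200,000 residues
the bias is far below one standard error for proteomes of up to
~10,000 proteins.  A seed is mandatory — there is no silent clock
seeding anywhere in the package.

Samples are compared pairwise: Welch's unequal-variance *t*-test on the
replicate values (means), and a Wilcoxon rank-sum test on the absolute
deviations of replicates from their sample mean (a Levene-type
dispersion comparison).  The dispersion proxy is a deliberate choice: a
rank-sum test on the raw replicate values tests location, not spread, so
it cannot serve as a variance comparison; a raw-values mode is exposed
for users who do want a rank-based location test.  Across all pairs in a
run, both p-value families receive a Holm adjustment by default.

## Count normalization

**TMM** (trimmed mean of M-values) corrects compositional bias in
gene-by-sample counts.  The reference sample is the one whose
upper-quartile/library-size ratio is closest to the mean of those
ratios.  For each sample, gene-wise log2 ratios $M$ (library-size-scaled,
against the reference) and average log abundances $A$ are computed over
genes positive in both samples, doubly trimmed (30% on $M$, 5% on $A$,
each side — the originating method's defaults, adjustable), and the
scaling factor is $2$ to the precision-weighted mean of the surviving
$M$, with binomial delta-method weights; factors are rescaled to
geometric mean one.  The implementation agrees with the canonical edgeR
implementation to machine precision on random tables (asserted in the
test suite).  One caveat worth stating precisely: because the precision
weights depend on absolute library sizes, the *weighted* estimator is
only asymptotically invariant to rescaling a single sample's depth
(edgeR behaves identically); `weighted = FALSE` gives the plain trimmed
mean, which is exactly invariant.  Proportional columns always get
factors of one in both modes.

**CSS** (cumulative sum scaling) serves the sparser ASV tables: each
sample's factor is the sum of its counts up to the chosen quantile of
its *positive* counts (default 0.5), under the nearest-rank quantile
convention — pinned explicitly because quantile conventions differ and
bit-exact tests require one.  The adaptive quantile selection of the
originating method is not applied by default; a fixed quantile keeps the
procedure deterministic.  Normalized values are counts divided by the
factor, rescaled by the median factor.

## Distance-based community statistics

ASV tables are first cleaned of commonly identified reagent
contaminants by case-insensitive exact genus matching against an
editable blocklist (a starter list ships with the package); unassigned
genera are never removed, and a removal report is attached to the
result.  Bray–Curtis dissimilarity,
$d(x,y) = 1 - 2\sum_k \min(x_k, y_k) / (\sum_k x_k + \sum_k y_k)$,
is computed on normalized tables via vegan.

Three permutation tests are implemented in-package (with vegan's
`anosim`, `adonis2` and `mantel` used as independent cross-checks in the
tests, agreeing on the statistics to ~1e-12):

* **ANOSIM**: $R = (\bar r_B - \bar r_W)/(N(N-1)/4)$ on rank-transformed
  distances (average ranks for ties).
* **PERMANOVA** (one factor, unbalanced forms):
  $SS_\mathrm{total} = \sum_{i<j} d_{ij}^2 / N$, within-group sums
  scaled by group size, pseudo-$F$ and $r^2$ from the partition.  On
  univariate Euclidean data the pseudo-$F$ reduces exactly to the
  classical one-way ANOVA $F$.
* **Mantel**: Pearson or Spearman correlation over the strictly lower
  triangles, permuting the second matrix's rows and columns jointly;
  one-sided (positive association) by default.  Environmental distance
  matrices are built from user-selected metadata columns, standardized
  to unit variance by default so variables on different scales
  contribute comparably.

All permutation p-values use the add-one convention,
$p = (1 + \#\{T^\pi \ge T\})/(n_\mathrm{perm} + 1)$, so $p \ge
1/(n_\mathrm{perm}+1)$ and a seed reproduces the exact value.  For small
designs an `exhaustive = TRUE` mode enumerates all label permutations
(identity included, so the add-one convention holds automatically) and
returns the exact permutation p-value.

A practical design note: with two groups of five samples only
$\binom{10}{5} = 252$ distinct label splits exist, so even perfect
separation cannot yield a PERMANOVA p much below ~0.008, with sampling
spread around it.  Validation scenarios in this package that claim
detection at $\alpha = 0.01$ therefore use six samples per group
(924 splits), a resolution requirement of the permutation null rather
than a statement about effect size.

## KEGG-module completeness

Module definitions are parsed from the KEGG grammar: space-separated
serial steps, commas for alternatives, `+` for complex subunits, a `-`
prefix for optional components, `--` for gap steps, parentheses for
grouping.  Decisions pinned by tests, where the grammar leaves room:

* Optional components and gap steps are excluded from the required-step
  denominator.
* A parenthesized serial list inside a step counts as **one** step that
  is satisfied only when all of its internal steps are.
* Completeness is the fraction of required top-level steps whose boolean
  expression is satisfied by the lineage's pooled KO set, and a module
  is **detected only when the fraction exceeds 0.5**: a pathway missing
  half of all required genes is considered undetected, so exactly half
  present is *not* a detection.  Completeness is monotone under KO
  addition.

Lineage-level scoring pools the KO annotations of all genes assigned to
a lineage at a chosen rank (semicolon-separated lineage strings,
coarse-to-fine; empty ranks become `"unclassified"`).

## Marker, hydrogenase and lineage profiles

Marker and hydrogenase abundance matrices sum normalized gene abundance
over configurable maps (KO ids first, gene symbols as fallback, each
gene counted once).  Rows with no matching genes are kept as explicit
zeros — the absence of a methanogenesis marker from every sample is
itself a finding.  The shipped maps are reconstructions from published
results text and are intended to be replaced or edited by the user; they
are configuration, not ground truth.  Lineage relative abundance sums
normalized abundance by lineage over all genes or over single-copy-gene
panels (12- or 40-gene, supplied as annotation flags — the package does
not identify single-copy genes itself) and reports percentages summing
to 100 per sample.

## The synthetic-data generator

The generator exists so that every pipeline stage can be validated
against known truth; its defaults are the study conditions the rest of
the package is tested under.

**Proteomes** (`simulate_proteome()`): residues are drawn from a mixture
of a fixed background composition (roughly natural residue frequencies,
weight `background_fraction`, default 0.5) and a glycine/leucine tuning
pair whose mixing fraction is solved in closed form from the
carbon-weighted $Z_\mathrm{C}$ balance; glycine ($+1$) and leucine
($-1$) span the residue range, so with no background any target in
$(-1, 1)$ is achievable, and with background the achievable hull is
reported in the error message.  Gene abundances are log-normal
(sdlog = 1).  After the random draw, a deterministic pass of
glycine–leucine swaps pins the *realized* abundance-weighted pool
$Z_\mathrm{C}$ to the target (tolerance 1e-6 by default), because
otherwise generation noise (~1e-3 for 5000 proteins) would exceed the
subsampler's standard error and blur estimator validation.  Defaults —
5000 proteins, length 300 ± 80 residues, targets near the field mean
$-0.168$ with between-sample shifts near 0.013 — mirror the scale of the
motivating observations.  What the generator does **not** emulate:
annotation error, length-composition covariance, strand or codon
structure, or any correlation between a protein's abundance and its
composition; conclusions from synthetic tests are about the estimator's
statistical behavior, not about biology.

**Gene counts** (`simulate_gene_counts()`): log-normal gene baselines
with negative-binomial sampling (dispersion 0.2), uniform depth factors,
and multiplicative fold-changes on a 10% gene subset per non-reference
group — the "most genes unchanged" structure TMM assumes.

**Annotations** (`simulate_annotations()`): realizes a programmed
per-lineage, per-module fraction of required steps *exactly* (erroring
with the nearest realizable fractions when a fraction is not an integer
number of steps), and emits single-copy-gene panels whose deterministic
per-gene abundances recover programmed lineage proportions exactly.

**ASV tables** (`simulate_asv_table()`): Dirichlet-multinomial counts
(concentration 200, depth 20,000) with a multiplicative effect of
programmed size on a subset of ASVs per non-reference group, optional
spiked contaminant genera at fixed counts, and metadata with
group-separated environmental covariates for Mantel demonstrations.

Every generator is a pure function of its parameters and seed.

## Numerical and validation choices

* Statistical machinery comes from R's own `t.test`, `wilcox.test`,
  `p.adjust`, `quantile`, `rank`; distances from vegan; FASTA parsing
  from Biostrings.  The quantities the package is *about* —
  $Z_\mathrm{C}$ arithmetic, the weighting and subsampling estimator,
  TMM/CSS factors, the three permutation tests, the module grammar and
  completeness rule, the generators — are implemented here and
  cross-checked in the test suite against independent oracles
  (per-atom oxidation accounting, a step-by-step TMM recomputation,
  exhaustive permutation enumeration, edgeR and vegan).
* Problem sizes used in the validation suite and the acceptance script:
  5000-protein proteomes at 100 replicates of 200,000 residues;
  200 simulated pairs for the null calibration of the Welch comparison;
  12-sample, 150-ASV communities with 999 permutations; 500 random
  module definitions for the monotonicity property.  These sizes give
  the Monte-Carlo assertions comfortable margins while keeping a full
  run in tens of seconds.
* Ties in rank transforms use average ranks.  Degenerate comparisons
  (zero variance in both samples with equal means) return $p = 1$ with a
  flag instead of failing.  Tables of identical samples give
  $r^2 = 0$ and a zero statistic rather than 0/0.

## Known limitations

* $Z_\mathrm{C}$ is computed from *encoded* proteins weighted by *gene*
  abundance; differences between gene, transcript and protein abundance
  are ignored by construction.
* PERMANOVA is restricted to the one-factor case (no strata, no
  continuous covariates); ordination and phylogenetic distances are out
  of scope.
* Whether the subsampler should draw proteins with or without
  replacement is not decidable from the description it follows;
  with-replacement is implemented (and documented) because it keeps
  replicates exchangeable regardless of proteome size.
* Reported per-sample spread is the standard deviation of replicate
  $Z_\mathrm{C}$ values, labeled as such (not a standard error).
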