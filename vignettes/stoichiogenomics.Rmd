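---
title: "Stoichiogenomic profiling of metagenomes: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stoichiogenomic profiling of metagenomes: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Nitrogen limitation leaves a signature in genomes. Synthesizing a
guanine–cytosine pair costs one more nitrogen atom than an
adenine–thymine pair, and amino acids differ in how much nitrogen their
side chains carry — arginine's guanidinium side chain holds three
nitrogen atoms, histidine's imidazole two, while methionine, like most
residues, carries none. Communities living under chronic nitrogen
scarcity therefore tend toward lower GC content, lower side-chain
nitrogen per residue (N-ARSC), and smaller genomes ("streamlining"),
while nutrient-replete niches relax that pressure. This package
quantifies those signatures in shotgun metagenomes sampled along an
environmental gradient (depth through a stratified water column) and
between two filter size fractions — particle-associated communities,
which sit on nutrient-rich microhabitats, and free-living cells in the
surrounding water.

## Per-gene chemistry

For every catalog gene we compute GC content (IUPAC ambiguity codes are
excluded from numerator *and* denominator, which is unbiased when
ambiguity is unrelated to base identity), and from its encoded protein:

* **N-ARSC / C-ARSC** — mean side-chain nitrogen / carbon atoms per
  residue, from a fixed 20-row atom table (side chain = residue minus
  the N–Cα–C(=O) backbone, hydrogens ignored). The table is checked in
  the test suite against an independent accounting that subtracts the
  backbone (2 C, 1 N) from the standard free-amino-acid molecular
  formulas.
* **Side-chain N:C** — the *aggregate* ratio ΣN/ΣC over all residues,
  not the mean of per-residue ratios, which would be undefined at every
  glycine. Poly-glycine-like proteins with zero side-chain carbon get
  `NA` and are excluded (with weight renormalization) from the weighted
  N:C average only.
* **Molecular weight** — the sum of free-amino-acid average masses,
  without subtracting one water per peptide bond. The summed-free-mass
  convention is stated in the documentation; switching conventions
  changes all values by `18.02 * (L - 1)` Da and none of the
  comparative statistics.
* **Codon diversity** — for each amino acid present, the fraction of
  its synonymous codons (translation table 11) actually used, averaged
  over amino acids. **Codon bias** is Wright's effective number of
  codons (ENC, 20–61), with families observed fewer than twice skipped
  and the isoleucine class falling back to the mean of the two- and
  fourfold estimates. Both definitions are deliberate, documented
  stand-ins: the upstream literature defers these two metrics to
  external scripts whose exact formulas are not published, so we fix
  explicit, testable definitions here.

Translation uses table 11; genes with internal stop codons, ambiguous
codons, frame problems, or selenocysteine are rejected rather than
patched, since a curated gene catalog should not contain them.

## Coverage weighting and genome size

Alignment summaries are filtered at identity ≥ 0.95 (identity defined
as 1 − mismatches/alignment length; the threshold is inclusive) and
alignment length strictly greater than 60 bp. Coverage of a gene is
mapped bases divided by gene length. Copy numbers divide each coverage
by the *arithmetic mean* coverage of ten single-copy marker genes
(zeros included, provided at least one marker is covered); genes per
genome is the sum of copy numbers, and average genome length the
copy-number-weighted sum of gene lengths. Because only cataloged genes
contribute, the genome length is a lower bound that ignores intergenic
DNA — a caveat worth remembering when comparing against assembly-based
estimates.

Sample profiles multiply each gene's properties by its weighted
coverage (coverage over summed coverage) and sum. Weights are
renormalized *within* each taxonomic domain, because profiles are
domain-specific and global weights would let an abundant domain bleed
into another's profile; genes labeled `other` are dropped. Every
profile is therefore a convex combination of gene properties and
inherits their range. The same machinery produces marker-gene profiles
(rpoZ for bacteria, ftsZ for archaea, Gp23 for T4-like phages): each
marker's gene clusters are averaged with their per-sample coverages as
weights.

## Statistical chain

**Ordination.** Property columns are standardized (they mix Daltons,
fractions and atom counts — without standardization molecular weight
would dominate every axis; the upstream literature is silent on this,
so standardization is this package's choice). The sequencing-depth
covariate is regressed out of every column, and the residuals are
ordinated by eigen-decomposition, so every retained axis has exactly
zero linear correlation with sequencing depth. Variance explained by
size fraction and by asinh-transformed depth is assessed with a
permutational R² = SS_fit/SS_total and `p = (1 + #(R²_perm ≥ R²_obs)) /
(1 + n_perm)`, default 999 permutations (p floor 1/1000). asinh
compresses depth because water-column chemistry changes much more
slowly below the oxycline than above it.

**Depth mixed models.** Each per-sample response (weighted GC, N-ARSC,
N:C) is modeled as intercept + fraction + log10 reads plus a per-depth
random effect with exponential correlation
`K_ij = exp(-|d_i - d_j|/rho)`, fitted by maximum likelihood. The
likelihood is profiled analytically over the fixed effects and residual
variance and maximized numerically over the variance ratio and
`log(rho)` with a 12-point multi-start grid (rho ∈ {1, 10, 100, 1000} m
× three variance ratios) to escape local optima; the boundary
`sigma_b² = 0` is admissible. Wald standard errors use the observed
information with t reference (n − 3 df). The null model for the
likelihood-ratio test keeps all fixed effects and adds asinh(depth) as
a *fixed* covariate — the models are then not strictly nested (a smooth
fixed trend can out-fit a stationary random effect), so the statistic
can be negative; we report the naive χ²(2) p-value and a halved
boundary-mixture version, both conservative under the null, which the
test suite verifies empirically (type-I rate ≤ 0.05 at α = 0.05). When
the random effect wins, its per-depth predictions (BLUPs) are rank-
correlated with depth to summarize the direction of the trend.

**Amino-acid drivers.** The weighted marker amino-acid profile (20
columns) predicts three simultaneous responses — binarized size
fraction, weighted N-ARSC and weighted N:C — via glmnet's multiresponse
Gaussian lasso. The grouped penalty λ Σ_j ||β_j·||₂ removes a residue
from all three responses at once, which matches how redundancy among
amino acids should be handled; a per-entry penalty is available via
`grouped = FALSE`. All three responses are standardized (population
sd), including the binary fraction: the penalty couples response
scales, so leaving one response unscaled would silently reweight the
loss. λ is chosen at the minimum mean CV error over 10 folds on a
100-point grid down to 1e-4 of the all-zero λ; fold assignment and the
70/30 train/test split are deterministic functions of the seed.
Rankings order residues by |coefficient| with alphabetical
tie-breaking.

**Functional enrichment.** KO coverages are divided by the coverage of
`sdhC` — a universally distributed TCA-cycle component — and
natural-logged (the log base only rescales coefficients). Only KOs
covered in *every* sample are kept, so the table is finite by
construction and invariant to per-sample total-coverage scaling. Each
KO's log-ratio is regressed on fraction, depth (untransformed here) and
their interaction; the three slope p-values of all KOs are pooled and
controlled by Benjamini–Hochberg at q = 0.10. Intercepts are excluded
from the pool: baseline abundance relative to `sdhC` is not an
enrichment hypothesis. Because "enriched" could mean any of the three
parameters, results are reported per parameter rather than as a single
count.

## The synthetic community generator

The generator emulates the study conditions: a catalog of a few hundred
genes (three domains, bacteria-dominated), 20–60 metagenomes spanning
two size fractions and a 15–500 m depth transect, ten single-copy
markers, and marker gene-cluster families per domain. Genes are drawn
from three pools differing in codon GC bias and side-chain nitrogen
richness; per sample and domain, pool mixing proportions are solved
from a 3×3 linear system so that the *expected* coverage-weighted GC
and N-ARSC equal `base + delta·fraction + trend(depth)` exactly —
ground truth is therefore analytic, and the test suite checks that the
pipeline reproduces it to machine precision on noiseless coverages.
Defaults are fixed at the scale of the study system: delta_gc = +0.05,
delta_narsc = +0.013 atoms/residue in the particle fraction; a
saturating depth trend `amp·(1 − exp(−depth/50 m))` that plateaus near
150 m (GC amplitude 0.02, N-ARSC 0.005), mirroring how nitrate rises
to a mid-water plateau; lognormal multiplicative coverage noise
(σ = 0.3, mean-one), since coverage is positive and heavy-tailed.
Marker families default to 24/18/18 clusters whose compositions differ
chiefly in arginine content, with cluster abundances tilted toward
arginine-rich clusters in the particle fraction and at depth; they
carry ~1% of domain coverage so they perturb the injected profile
deltas negligibly. Single-copy markers share one expected coverage per
sample (one copy per average genome). Alignment simulation emits
fixed-length reads with binomial mismatches, reproducing a target
coverage to within half a read per gene.

What the generator does *not* emulate: taxonomic structure within
domains, read-level errors and mapping ambiguity, assembly chimerism,
uneven gene lengths between domains, and compositional coupling between
KO families. Passing tests therefore demonstrate correctness of the
computations and calibration of the statistics under a plausible noise
model — not robustness to every artifact of real sequencing.

## Problem sizes and numerics

The test and acceptance suites run at deliberately desk-sized scales:
catalogs of 60–150 genes, 12–48 samples, 25–100 simulation replicates,
99–999 permutations — chosen so that each Monte Carlo check has enough
replication for its stated tolerance while the entire suite completes
in minutes. Mixed-model convergence uses L-BFGS-B on (log variance
ratio, log rho) with bounds log rho ∈ [log 0.01, log 1e6]; the residual
variance is floored at 1e-300 so that exactly-interpolating fits remain
finite. Eigenvalues below 1e-12 of the leading one are treated as null
axes. TSV output uses tab delimiters, `.` decimals and `NA` for
undefined N:C.

## Known limitations

* Genome length is genes-only (lower bound).
* The LRT null is not strictly nested (see above); AIC comparison is
  reported alongside for that reason.
* ENC and codon-diversity definitions are explicit stand-ins for
  unpublished upstream formulas.
* Lasso coefficients come without inference (no p-values or stability
  selection); rankings are descriptive.
* The permutation test permutes raw labels (no restricted permutation
  for the station structure).
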