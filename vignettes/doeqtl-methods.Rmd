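---
title: "Methods: eQTL mapping, hotspots and mediation in multiparent populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: eQTL mapping, hotspots and mediation in multiparent populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical models, the synthetic-data
generator, the numerical choices, and the known limitations of `doeqtl`.
It states no empirical result that the package's test suite or
`scripts/acceptance.R` does not itself compute.

# The mapping model

Each phenotype (a gene's processed expression) is scanned against 8-founder
haplotype dosages with a linear mixed model. Writing $P_m$ for the
samples-by-8 dosage slice at marker $m$, $X$ for the covariates
(intercept and sex by default), and $K_c$ for the kinship matrix of the
marker's chromosome:

$$y = P_m\beta + Xc + g + \varepsilon,\qquad
g \sim N(0, \sigma_g^2 K_c),\quad \varepsilon \sim N(0, \sigma_e^2 I).$$

**Kinship.** $K = \tfrac1M \sum_m P_m P_m^\top$ over the included markers.
In LOCO mode the scanned chromosome's markers are excluded so that the
polygenic term does not absorb the very signal being tested. The $1/M$
normalizer is a convention; heritabilities and LODs are invariant to it.

**Variance components.** For each phenotype and chromosome the null model
($\beta = 0$) is fit once by profiling the likelihood over
$h^2 = \sigma_g^2/(\sigma_g^2+\sigma_e^2)$ on the eigenbasis of $K_c$
(a one-dimensional `optimize` over $[0, 1)$), and the resulting weights are
reused at every marker of that chromosome — the standard genome-scan
approximation that keeps permutations tractable. Heritability reporting
(`est_herit`) uses REML; scan nulls use ML. Both are available via the
`reml` argument. When the likelihood is flat in $h^2$ (e.g. $K \propto I$,
where the model is unidentifiable) the fit is flagged and $h^2 = 0$
returned.

**LOD.** After rotating by the eigenvectors of $K_c$ and whitening, each
marker is fit by weighted least squares and
$\mathrm{LOD} = \tfrac n2\log_{10}(\mathrm{RSS}_0/\mathrm{RSS}_1)$. The
eight dosage columns sum to one, absorb the intercept, and are therefore
rank-deficient by construction; the fit uses the eigendecomposition of the
8×8 cross-product with a relative tolerance of $10^{-9}$, i.e. a
pseudoinverse. With `kinship = NULL` the scan reduces exactly to ordinary
least squares, which the tests exploit as an independent oracle (a naive
per-marker `lm()` implementation must agree to within $10^{-6}$).

**Permutations.** Genome-wide significance permutes the *genotypes'* sample
index while the phenotype–covariate pairing stays intact. Internally this
is implemented as the equivalent inverse permutation of phenotype and
covariates, which lets all genotype-side computation be reused; when the
covariates are permutation-invariant (intercept-only) all permutations are
evaluated in a single batched matrix product per chromosome. Null variance
components are reused from the unpermuted fits (re-estimating them per
permutation is a possible refinement the package does not take; the reuse
matches common practice). Null maxima are pooled across phenotypes;
thresholds are type-1 (inverse-ECDF) quantiles, so `alpha = 1` returns the
smallest null maximum. The default reported levels are `significant`
($\alpha = 0.05$) and `suggestive` ($\alpha = 0.25$); the suggestive level
is a package choice — the field convention is a LOD about 1.5 below the
significant threshold, which $\alpha = 0.25$ reproduces on the default
synthetic genome.

**q-values.** Permutation p-values feed a Storey procedure written in the
package: $\hat\pi_0(\lambda)$ on the grid $0.05, 0.10, \dots, 0.95$, with
$\lambda$ chosen by the bootstrap method (100 resamples, MSE against the
plug-in minimum), and the usual running-minimum q-values. All p-values
equal to zero is handled as $\pi_0 = 0$, $q = 0$.

**Peaks and classification.** One peak per gene per chromosome (the
maximum-LOD marker above threshold; no multi-peak dissection). A peak is
*local* if it lies on the gene's chromosome within ±10 Mbp of the gene
midpoint $(\mathrm{start}+\mathrm{end})/2$, *distant* otherwise. The 10 Mbp
boundary is inclusive.

**Founder effects.** At a peak the eight founder effects are BLUPs: effects
are treated as exchangeable random draws with a common variance, the
effect-to-residual variance ratio is estimated by ML on the whitened model
(profiled over $\log r$ on $[-12, 8]$ via Woodbury identities in the
8-dimensional space), and the predictors are shrunken toward zero relative
to the fixed-effect estimates. Reported effects are centered to sum to
zero.

# Hotspots and the eigengene

Distant eQTL are counted in 1 cM windows shifted by 0.25 cM (each interior
peak falls in exactly four bins). Bins are half-open $[s, s+1)$ cM, so a
peak on a boundary belongs to the later bin. The count threshold is the
$(1-0.005)$ quantile of all bin counts, ties included, with a floor of one;
selected bins that overlap or abut are merged (via `IRanges::reduce` on
quarter-cM integer coordinates), and merged intervals with at most 20
significant distant members are dropped. Whether the ">150 suggestive"
description seen in practice is a second gate is ambiguous; only the
significant-member gate is enforced.

The hotspot *eigengene* is the first principal component of the target
genes' rankZ expression (genes centered), with the sign oriented so scores
correlate positively with the mean target expression. Eigengenes are
computed on the rankZ stage; the processing stage is a package choice.

# Cross-cell-type sharing

An eQTL of the derived cell type B is *shared* with the progenitor cell
type A when A (scanned at a relaxed threshold, LOD > 5 by convention) has a
peak for the same gene on the same chromosome within ±5 Mbp, and the
Pearson correlation of the two 8-founder BLUP vectors is significant after
BH adjustment across all tested pairs (adjusted p < 0.1, two-sided with
n = 8). When several A-peaks qualify the closest wins, ties broken by
higher LOD. Negative correlations with small adjusted p count as shared
(opposing allele effects at a shared locus are a recognized phenomenon);
the sign is reported. Pearson on the 8 BLUPs and the BH adjustment are
package choices where the convention is loose.

# Mediation

`mediation_scan` regresses the target (e.g. a hotspot eigengene) on the
founder dosages at the QTL peak, with and without the candidate mediator's
expression as an additive covariate, on the sample subset complete in
*both* models — the double-LOD-difference device, which removes the
spurious drops that missing mediator values would otherwise create. With
no missing data it reduces exactly to the plain LOD difference. Models are
ordinary least squares at the single peak marker (mirroring the regression
formulation of mediation and keeping genome-wide scans fast); a
kinship-whitened variant is available via the `K` argument. Candidates
with fewer than 30 complete samples are skipped with a warning.

Significance uses the genome-wide null: all expressed genes of the cell
type are scanned as mediators, and each candidate's mediated LOD is
standardized by the moment estimates, $z = (\mathrm{LOD}_\mathrm{med} -
\bar{\mathrm{LOD}})/s$, flagged when $z < -4$. A rank-based inverse-normal
variant is available (`method = "ranknorm"`), but note an arithmetic
consequence: a rank-normal score over $m$ candidates cannot exceed
$|\Phi^{-1}(0.5/m)|$, which stays below 4 until $m$ is far above $10^4$ —
the moment-based default is the variant under which the $-4$ SD criterion
can actually fire. The positional filter (gene midpoint within ±10 Mbp of
the peak) is applied after standardization, to reporting only.

**Genotype classes and partial correlation.** Under a 4:4 founder split,
each sample's dosage summed over the Alt-side founders is cut at 0.25/0.75
into Ref/Het/Alt (the cutpoints are a package rule for probabilistic
ancestry; hard calls land exactly on 0, 0.5, 1). Partial correlation
residualizes both the mediator expression and the eigengene on the numeric
0/1/2 class coding (a two-indicator genotypic coding was considered;
dosage-additive is the default because the planted architecture is
additive), then reports the Pearson correlation of residuals with the
t-based p-value at $n-3$ degrees of freedom, BH-adjusted across candidates.
A true mediator stays correlated with its targets after genotype control;
a gene that merely shares the locus does not. Constant residuals are
flagged undefined rather than forced to a number.

Because transcript–transcript correlations are sensitive to shared
nuisance covariates, the partial-correlation analyses remove sex alongside
batch during preprocessing (the same practice as before differential
expression).

# Preprocessing

* **Filtering:** keep genes with median TPM-like abundance ≥ 0.5 that are
  nonzero in at least half the samples. In synthetic mode the TPM proxy is
  counts-per-million (no gene lengths exist).
* **Upper-quartile normalization:** each sample divided by the 75th
  percentile of its *nonzero* counts, rescaled by the geometric mean of
  those percentiles so values stay count-like. The reference scale is a
  package choice; the operation is exactly invariant to per-sample
  rescaling. All-zero samples are an error naming the sample.
* **Batch/sex correction:** per gene, within-level means are equalized to
  the grand mean and within-level SDs to the pooled SD. This is a
  location-scale adjustment, deliberately simpler than empirical-Bayes
  batch correction: it has the same contract on balanced designs but does
  not shrink gene-wise moment estimates across genes. Levels need ≥ 2
  samples; constant genes pass through unchanged.
* **rankZ:** per gene, $\Phi^{-1}((\mathrm{rank}-0.5)/n)$ with average
  ranks for ties (the $-0.5$ offset is a convention choice). Idempotent,
  invariant to monotone transforms; an all-tied gene maps to all zeros.
* **Sample matching:** genotype-correlation matrix between two datasets
  over shared markers (≥ 10 required); a labelled pair that is not the
  best-correlated pair is flagged as a mix-up.
* **Differential expression:** two-sided Wilcoxon rank-sum per gene (exact
  when both groups ≤ 25, normal approximation with tie correction
  otherwise), BH adjustment, $\log_2(\bar x_B/\bar x_A)$ fold changes;
  up/down labels need adjusted p < 0.05 *and* |log2FC| > 2. Non-positive
  group means make the fold change undefined and exclude the gene from
  labelling.

# The synthetic-data generator

`sim_study()` emulates the features downstream methods rely on, not the
breeding design:

* **Haplotype mosaics** are first-order Markov: uniform founder at the
  chromosome start, exponential inter-crossover distances at
  `recomb_rate` crossovers/cM, uniform among the other seven founders at
  each breakpoint. The default 0.1 crossovers/cM gives ~10 cM founder
  segments, comparable to a DO population after roughly 20 outbreeding
  generations; a much lower density would make founder segments span whole
  chromosomes and destroy within-chromosome localization.
* **Genotype probabilities** are haplotype counts/2 per marker, optionally
  blurred (`blur_sd = 0.02` by default, emulating inference uncertainty)
  then clipped and renormalized to sum to one.
* **Study design:** 186 donors; the derived cell type B (which carries the
  hotspot) is profiled in all donors, the progenitor cell type A in the
  127 shared donors. Same-cell mediation therefore runs at n = 186 and
  cross-cell mediation on the 127-donor intersection.
* **Expression:** a local eQTL contributes $P\beta$ rescaled so its
  realized variance fraction equals the specified heritability (default
  0.5), plus unit-variance noise. The mediator gene has a local eQTL at
  the hotspot marker whose effects take one value per side of the 4:4
  founder partition (default Alt side A/E/G/H, i.e. the AJ/NZO/PWK/WSB
  analog, heritability 0.6). Each hotspot target is
  `slope × mediator latent + noise` with *no* direct genotype term — the
  mediator's expression *is* the latent value the targets follow, so the
  causal chain is exactly the one mediation analysis assumes (this
  linear generative relationship is a modeling choice; the real mechanism
  is unknown). Decoy genes with their own local eQTL sit within 10 Mbp of
  the hotspot to exercise the positional filter. Sex (balanced binary)
  and batch (3 levels) act additively with SD 0.3 per gene.
* **Counts:** negative binomial with mean
  `exp(base + latent) × lib_size/10^6` (per-gene baseline log-mean around
  log 100) and size `dispersion = 10`, i.e. a biological CV of ~30% on
  top of Poisson noise; library sizes uniform in 0.8–1.2 million.

What the generator does **not** emulate: recombination hotspots and
map-position heterogeneity (the cM↔Mbp relation is a fixed 2 Mbp/cM),
X-chromosome dosage and inactivation, imprinting, polygenic backgrounds
beyond the planted QTL, gene-length effects, GC bias, and read-level
artifacts. Passing tests therefore demonstrate that the estimators recover
the planted architecture under idealized DO-like dosage structure — not
that they are robust to every artifact of real RNA-seq.

One consequence of the count layer worth knowing: per-sample normalization
estimates a scale factor from finitely many genes, and its error is a small
*common factor* shared by all genes of a sample. Processed expression of
truly independent genes is therefore very slightly positively dependent
(empirically a mean pairwise partial correlation of order 0.003 at 500
genes, with a corresponding small negative shift against an eigengene).
Null calibrations of transcript–transcript statistics in the acceptance
suite use decoys drawn independently of the study for exactly this reason,
and the effect shrinks with gene count.

# Problem sizes and determinism

The default synthetic genome is 5 chromosomes × 100 cM × 200 markers with
186 donors — large enough that permutation thresholds land in the
field-typical LOD 6–7.5 range while a full scan of 600 genes takes about a
minute. The test suite uses 20-seed replications for the recovery
properties (local-eQTL detection within 5 cM, eigengene 4:4 sign
consistency, same- and cross-cell mediator ranking) and 50 replicates per
point for heritability recovery at n = 400 over h² ∈ {0.2, 0.5, 0.8}. All
stages derive their randomness from a single master seed (kept within
32-bit range), and two pipeline runs with the same configuration write
byte-identical tables.

# Known limitations

* Single-peak-per-chromosome reporting; no conditional dissection of
  multiple linked signals within a hotspot.
* Mediation is regression-based; it cannot distinguish causal, reactive
  and confounded configurations, and misses mediators acting through
  anything other than their transcript abundance.
* The location-scale batch correction does not pool information across
  genes; with very small batches the per-gene moment estimates are noisy.
* The LMM reuses null variance components across markers and permutations;
  exact per-marker REML would be slower and typically indistinguishable.
* Genotype-probability output is TSV only (one file per chromosome).
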