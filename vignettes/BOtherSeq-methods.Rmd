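---
title: "Methods: transcriptome-based subtype assignment for B-other BCP-ALL"
author: "BOtherSeq authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcriptome-based subtype assignment for B-other BCP-ALL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and rationale

A substantial fraction of pediatric B-cell precursor acute lymphoblastic
leukemia (BCP-ALL) cases carry none of the classical risk-stratifying
lesions detectable by routine diagnostics ("B-other"). Bulk RNA sequencing
of the diagnostic sample can recover much of this missing information in a
single assay: fusion transcripts, hotspot driver mutations and the
expression signature of the leukemic clone. BOtherSeq implements the full
downstream workflow on top of upstream caller output (fusion-call tables,
annotated variant tables, count matrices):

1. **Fusion triage and assignment.** Calls are retained when a partner lies
   in a whitelist of ALL-relevant genes, or — for all other calls — when
   they carry strictly more than 10 supporting (split + spanning) reads and
   their unordered gene pair is a known recurrent fusion. Among a sample's
   retained, subtype-mapped calls, the winner is the call with the highest
   *support fraction* (its supporting reads over the sample's total
   retained supporting reads).
2. **Variant filter cascade and hotspot classification.** Caller-level
   rules (alternative-allele reads, tumor allele fraction, cohort
   recurrence, indel clustering) followed by annotation-level rules
   (variant class, population allele frequency, CADD, predictor consensus,
   impact), with a separate *spectrum* dataset in which only the
   population-frequency rule applies so that silent variants remain
   available for substitution-spectrum profiling. Samples carrying a known
   hotspot (e.g. *PAX5* p.P80R, *IKZF1* p.N159Y) after strict filtering
   are classified by that evidence.
3. **Expression subtyping.** GC normalization, variance stabilization,
   per-subgroup versus-rest negative-binomial differential expression, a
   MAD-ranked DEG-panel size sweep, and k-nearest-neighbour co-clustering
   classification of unknown samples, integrated with the fusion and
   hotspot tiers under the precedence fusion > hotspot > co-clustering.
4. **Isoform-usage concordance.** Overdispersed per-isoform usage tests and
   a direction-concordance comparison between result sets, the device used
   to corroborate co-clustering of unknown samples with a known subgroup.
5. **Paired tube comparison.** Patient-blocked differential expression
   between collection-tube technologies, nested effect-size tiers,
   rank-scored pre-ranked gene-set enrichment, decay-constant correlation,
   and clustering/PCA diagnostics.

Everything is driven and validated by a synthetic-cohort generator with
complete ground truth.

# The synthetic cohort

The generator emulates the statistical structure the workflow assumes, not
raw reads.

**Expression.** Counts are negative binomial with variance
$\mu + \alpha\mu^2$ and a single cohort-wide dispersion $\alpha$ (default
0.1, a typical bulk RNA-seq value). Each subgroup may plant an expression
signature: a set of genes (default 200) whose leukemic-profile means shift
by a common absolute log2 fold change (default 2), half up and half down.
The balanced up/down split mirrors real subtype signatures and keeps the
library composition comparable between subgroups. The observed profile of
a sample is the mixture
$\mathrm{bf}\cdot\text{leukemic} + (1-\mathrm{bf})\cdot\text{baseline}$,
where bf is the blast fraction (default 0.935, the typical tumor-cell
content of diagnostic marrow), so low-blast samples attenuate toward a
shared baseline. A per-sample GC bias multiplies expected counts by
$2^{s_j(\mathrm{gc}-\overline{\mathrm{gc}})}$ with a sample-specific slope
drawn around the configured value. Library sizes are drawn from 80–130
million read pairs and scaled by 1/1000 to a desk-scale count matrix;
signature genes are drawn from the moderately-to-highly expressed stratum,
where real subtype markers live.

**Fusion calls.** For each sample of a fusion-defined subgroup, total
supporting reads are Poisson with expectation
$r \cdot (\text{library size}/10^6) \cdot \mathrm{bf}$, with $r = 3$
reads per million read pairs at full blast content — a value that makes a
~100 M read-pair library yield tens of supporting reads even at 7% blasts,
matching the observation that standard depth suffices for low-blast
samples. Noise calls between non-whitelist genes with low support are
added at a configurable rate.

**Variants.** Four ground-truth classes: drivers (the subgroup's hotspot,
annotated to pass every rule), passengers (also cascade-passing),
artifacts (each violating *exactly one* named rule, including planted
cohort-recurrent variants shared by a configurable fraction of samples),
and an A-to-I editing excess — T>C or A>G substitutions with tumor AF in
[0.1, 0.6], so they survive caller-level filters but are largely removed
by the strict annotation rules, dominating the spectrum-mode dataset the
way RNA editing dominates RNA-derived variant calls.

**Paired tubes.** Two samples per patient share a per-gene log-normal
patient baseline (log2 sd = `patientSD`); a tube effect (default |log2FC|
= 3, half up/half down) is added to designated genes in the PAXgene
condition only.

**Isoforms.** Isoform counts are multinomial within the observed gene
totals, so conservation is exact by construction; usage shifts replace the
baseline proportions in designated samples.

What the generator does **not** emulate: read-level artifacts, alignment
and quantification uncertainty, fusion breakpoint structure, correlated
gene-gene noise, batch effects, and subtype-specific mutation burden.
Passing tests therefore demonstrate the correctness and calibration of the
downstream logic under the assumed model, not performance on real
sequencing data.

# Statistical choices

**Differential expression.** A deliberately transparent NB-Wald test:
median-of-ratios size factors (genes with any zero excluded from the
reference); per-gene moment dispersion around a Poisson fit, divided by
the residual degrees of freedom; a lowess mean-dispersion trend fitted to
the *raw* (possibly negative) moment estimates so their sampling noise
averages out rather than biasing the trend low; gene-wise shrinkage toward
the trend with weight $df/(df+20)$; and a fixed-theta NB GLM whose Wald
statistic is referred to a t distribution on the residual degrees of
freedom — the small-sample correction that keeps the paired six-patient
design calibrated. This is an approximation in the spirit of the standard
NB pipelines, validated by simulation (type-I error, BH false-discovery
proportion, effect recovery) rather than by equality with any package; a
cross-check against an independent DESeq2 fit on simulated data is part of
the test suite. The paired model uses free per-patient intercepts and a
single condition coefficient; genes with mean raw count of 10 or below are
excluded, and the reported effect is PAXgene over EDTA by default.

**Variant cascade conventions.** Cohort recurrence is computed on the raw
input (before the read-count and allele-fraction rules), which makes the
four caller-level rules order-independent. "Within 20 bp" is inclusive and
removes *both* members of a close indel pair — the rule targets alignment
artifacts, and keeping either member is unjustified. The population-AF
rule removes variants strictly above 0.01%. The predictor rule is read
predictor-wise: PolyPhen "benign" or SIFT "tolerated" or Condel "neutral"
each suffice for removal, and missing labels never count against a
variant. Variants are keyed on (chrom, pos, ref, alt) with 1-based
positions.

**Fusion rules.** The known-fusion and >10-read requirements apply only to
non-whitelist calls; whitelist calls are retained at any support (the
whitelist encodes prior relevance). The support-fraction denominator is
the sample's total retained supporting reads — computable from the call
table alone. Tie-breaks are fixed (fraction, then absolute support, then
lexicographic gene pair) for determinism. Pair keys in the subtype map may
be orientation-sensitive (`"P2RY8>CRLF2"`), unordered (`"ETV6+RUNX1"`) or
single-partner (`"ZNF384"` for any *ZNF384* fusion). The shipped whitelist
and known-fusion list are illustrative and user-overridable.

**Panel construction.** The DEG union takes each subgroup with at least
three labelled samples versus *all* other samples (including unknowns),
BH FDR < 0.05, and ranks the union by MAD of the variance-stabilized
values across all samples. Candidate sizes run 300 to 3000 in steps of 50
(55 sizes), truncated to the union when the union is smaller. Each size is
scored by the mean silhouette of the labelled samples under correlation
distance *in the panel expression space*. An earlier design scored the
silhouette of a 2-D t-SNE/UMAP projection at each size, but on a
well-separated cohort that projection saturates: every candidate size
scores ≈0.9 and the argmax is embedding noise, which made the selected
panel unstable and incomplete for the smaller subgroups. The panel-space
score is deterministic, cheap (no repeated embeddings), and sensitive to
whether a subgroup's markers are present at all. The 2-D embedding
(t-SNE with perplexity 20 and 50000 iterations, or UMAP with library
defaults) remains the visual validation step; t-SNE uses a deterministic
PCA initialization. Ties in the sweep resolve to the smallest panel.

**Co-clustering assignment.** Unknown samples vote among their k = 10
nearest labelled neighbours under correlation distance on the panel
matrix; a majority fraction of at least 0.5 (and a unique top label)
assigns, and the majority fraction is reported as confidence. Correlation
distance is scale-free across samples; Euclidean distance is used for
silhouettes in embedding space.

**Isoform usage.** Per isoform, a quasi-binomial logistic regression of
per-sample usage proportions on group membership, weighted by gene totals,
with BH correction over all tested isoforms. Genes need ≥2 isoforms and a
total of at least 10 in at least half the samples. Concordance between two
result sets counts isoforms present in both below a loose q threshold
(default 1.0, i.e. present in the reported output), tallies those below
the strict threshold (0.05) in both, and reports the fraction with equal
usage-change direction; an empty intersection yields an explicitly
undefined concordance, never 0.

**Pre-ranked enrichment.** Genes are ranked by
$\log_2(\text{FC})\times(-\log_{10} q)$, with q = 0 clamped to the
smallest positive double (the score would be infinite; the clamp is
warned about). The weighted Kolmogorov–Smirnov running sum (weight
exponent 1) with a gene-label permutation null is computed by
`fgsea::fgseaSimple`, which implements exactly this classic scheme,
including sign-conditional permutation p-values (so the 1/(nPerm+1) floor
holds) and BH FDR across sets. Sets are intersected with the ranking
universe before the 15–500 size filter.

**Variance stabilization.** Size-factor-normalized `log2(x + 1)`. Under
the median-of-ratios reference, doubling every count of one sample shifts
all size factors by $2^{1/n}$ (the doubled sample participates in the
reference), so the transform is invariant to per-sample depth only up to
that $1/n$ log2-unit shift; the test suite asserts exactly this bound.
GC normalization fits a per-sample lowess of log2(count + 0.5) on GC
fraction (span 2/3) and removes the fitted trend while preserving the
sample's mean log-signal exactly.

# Problem sizes and determinism

All simulations in tests and in `scripts/acceptance.R` run at desk scale,
chosen so a complete run takes a few minutes on one core: 2000 genes, 60
samples for cohort-level checks, 2000 genes × 6 patients for paired
checks, 100 replicate samples per blast-fraction level for the retention
property, and 1000 permutations for enrichment. Every stochastic step is
seeded; identical configurations and seeds give byte-identical outputs,
and each generator draws from its own seed offset so one output does not
depend on whether another was generated.

# Known limitations

* The NB-Wald test is an approximation: no LFC shrinkage, no outlier
  handling, moment rather than maximum-likelihood dispersion. It is
  calibrated for the cohort sizes used here; very small groups (n < 5)
  against large rests inherit the usual Wald liberality.
* Fusions involving non-transcribed partners (e.g. *IGH*
  enhancer-hijacking) produce no fusion transcript reads and are outside
  what call-table triage can recover.
* The co-clustering rule assumes the unknown sample's subtype is present
  among the labelled samples; novel subtypes can only end up unassigned.
* The whitelist, known-fusion list, subtype map and hotspot map shipped as
  defaults are small illustrative sets; diagnostic use requires curated,
  versioned lists.
* Real cohorts add layers the generator omits (batch, contamination,
  degraded RNA); calibration results transfer only to the extent the NB
  model holds.
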