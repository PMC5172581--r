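---
title: "Detecting foundation-parent IBD segments: models and methods"
author: "fpibd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting foundation-parent IBD segments: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpibd)
```

## The scientific setting

Maize foundation parents (FPs) — elite inbreds like B73, Mo17, PH207 and
Huangzaosi — were used so heavily in breeding that large panels of their
descendants exist. Chromosome segments transmitted intact from the FP to
its descendants are identical by descent (IBD) within the group: at SNPs
inside such a segment essentially one allele is observed among the
group's lines. `fpibd` operationalizes IBD discovery as *suppressed
within-group gene diversity around monomorphic anchor SNPs*, then asks
which segments are private to one FP group, which are shared, and what
trait loci and genes they carry.

This is a group-level definition. It does not phase haplotypes, model
recombination or compute pairwise IBD probabilities; it deliberately
mirrors how conserved regions are detected in inbred diversity panels,
where lines are near-fully homozygous and a shared ancestral block
manifests as a run of zero-diversity SNPs.

## The diversity scan

For a group of $n$ lines and a biallelic SNP with non-missing alt-allele
frequency $\hat p$ (a heterozygote contributes one copy of each allele),
Nei's gene diversity is

$$GD = 1 - \hat p^2 - (1-\hat p)^2,$$

the probability that two alleles drawn at random from the sample differ.
The scan proceeds per group:

1. **Tag loci.** SNPs with $GD$ exactly 0 and at least `minCalls`
   (default 4) non-missing lines. The call guard is ours: the source
   procedure has none, but with missing data a SNP observed in one line
   is trivially monomorphic, and such markers would seed spurious
   windows.
2. **Windows.** Around each tag SNP, all markers within ±25 kb
   (`halfWindowBp`, the stated window geometry; candidate intervals are
   clipped at the chromosome's marker extent). The window statistic is
   the arithmetic mean of defined GDs, tag included.
3. **Threshold.** Per chromosome and group,
   $\text{mean}(GD) - 0.5\,\text{SD}(GD)$ over that chromosome's
   per-marker GDs. We read "average GD of one chromosome" literally as
   per-marker GDs (not window means) and use the sample SD ($n-1$), the
   convention of common statistical software. Both comparisons are
   strict: tags need $GD = 0$, windows need mean $<$ threshold. A
   non-positive threshold (very uniform chromosome) is allowed and
   simply accepts nothing, with a warning.
4. **Merging.** Overlapping or bookended accepted windows merge into one
   segment; its `mean_window_gd` is the marker-count-weighted mean of
   member windows. Segment extent is the union of accepted windows, not
   the tag-to-tag span — the ±25 kb window is the only geometry the
   procedure defines, so a called segment can overhang a conserved block
   by up to 25 kb on each side.

### The Venn partition

Cross-group comparison builds the union interval set of all groups'
segments and labels each union interval with the set of groups owning a
segment that overlaps it (`any_overlap`, ≥1 bp, the default) or that
covers at least a fraction of it (`reciprocal`). Counting over union
intervals makes the arithmetic internally consistent: each group's total
equals its specific count plus its shared-class contributions, and
requiring one more group can never increase a commonality count (the
pairwise → triple → quadruple cascade). "Common" here is positional
overlap only; the data model cannot tell whether two groups carry the
*same* ancestral allele run, which would need haplotype comparison.

## Population structure and phenotypes

- **Distance**: $D = 1 - IBS$ with locus-level IBS the mean over the
  four ordered allele pairs of the identity indicator (identical
  homozygotes 1, opposite homozygotes 0, anything involving a
  heterozygote 0.5), averaged over loci non-missing in both lines. $D$
  is a semimetric; no triangle inequality is claimed.
- **UPGMA** is delegated to `phangorn::upgma` (average-linkage
  `hclust`); leaves at height 0, joins at half the joining distance, so
  cophenetic distances reproduce ultrametric inputs exactly.
- **PCA** mean-imputes missing dosages per marker and runs plain
  covariance PCA (no per-marker variance scaling — the source gives no
  standardization detail). Component signs are fixed by making the
  largest-magnitude score positive.
- **Subset selection** greedily removes the line whose removal maximizes
  retained *coverage*, defined as mean per-marker GD of the subset over
  that of the panel — GD being the pipeline's own diversity measure; the
  reported "fraction of diversity covered" statistic is otherwise
  undefined in the source. Note that removing low-diversity lines can
  push mean GD, hence coverage, marginally above 1; coverage is
  consequently not guaranteed monotone in the subset size.
- **BLUPs** come from the REML fit of
  $y_{ijk} = \mu + g_i + e_j + (ge)_{ij} + r_{jk} + \varepsilon_{ijk}$
  with all effects random (`lme4`); the reported value is
  $\mu + \hat g_i$, so environment main effects are excluded from the
  per-line value. Random terms that are inestimable on the data at hand
  (single replicate, non-identifiable G×E) are dropped in order. Group
  comparisons use one-way ANOVA with Tukey HSD letters at $\alpha=0.05$;
  a zero within-group-variance guard falls back to exact-separation
  letters.

## The mixed-model GWAS

Per trait, $y = \mu + Q\gamma + x_s\beta_s + u + \varepsilon$ with
$u \sim N(0, \sigma^2_g K)$. $K$ is VanRaden's centered cross-product
kinship (default) or IBS similarity; $Q$ is typically the first three PC
scores. The variance ratio $\lambda = \sigma^2_e/\sigma^2_g$ is
estimated once under the null by profiled REML over
$\log\lambda \in [-10, 10]$ via the eigendecomposition of $K$, then
fixed for every marker (P3D), which reduces each marker test to weighted
least squares in the whitened model.

The per-marker test is a **t test with per-marker residual variance**
(df $= n - q - 1$) rather than a large-sample Wald/normal approximation.
The choice is deliberate: with $K = I$ and no covariates the scan is
then *numerically identical* to `lm()`'s ordinary least squares t test
(verified to 1e−8 in the acceptance suite), and small-sample null
calibration is exact under normality. At the study's $n \geq 180$ the
two differ negligibly. Markers monomorphic in the analyzed lines or
collinear with covariates are flagged and skipped; missing dosages are
mean-imputed per marker, heterozygote dosage is 1.

QTNs are the markers with $p$ strictly below $\alpha/m$ — 0.05 divided
by the marker count, i.e. 1.156e−6 at 43,252 markers. The stricter
0.01/m line is available through `alpha`.

## Co-localization and expression

A QTN (point) supports a segment if its position lies inside the closed
interval; a QTL supports it on ≥1 bp intersection. Segments with both
kinds of support are the important candidate regions. A cluster is ≥3
QTN/QTL features in one segment (`minLoci`; the worked cases in the
source have three or more, "cluster" is otherwise undefined). Candidate
genes are annotation genes within 25 kb of an in-segment tag SNP
(distance 0 if the tag falls inside the gene body), reflecting the ~30
kb average LD of elite panels; a `radiusBp` of 50 kb reproduces the
wider screen used for GWAS peak SNPs.

Expression is normalized as $\log_2(\mathrm{FPKM} + 1)$: a pseudocount
is required because $\log_2$ of a zero FPKM is undefined, and 1 keeps
zero at zero. Group differences use per-gene one-way ANOVA on the log2
values, with the fold change defined as the **difference of group means
of log2 values** — consistent with the normalization, but not identical
to log2 of the ratio of mean FPKMs; the two differ and the choice is
documented here. No multiple-testing correction is applied by default
(the source reports raw significance); `fdr = TRUE` switches to
Benjamini–Hochberg. Co-expression edges keep gene pairs with
$|r| \geq 0.8$ Pearson correlation across organ samples; the threshold
is our choice, as the source never states its edge criterion.

## The simulator and what passing tests mean

`simulatePanel()` emulates the panel structure: one founder haplotype
per group (panel allele frequencies uniform on [0.1, 0.9]), descendants
copying the founder and resampling each background marker from the
panel allele distribution with probability $\rho = 0.4$, planted
conserved blocks where the listed group keeps the founder allele
exactly, 1% missing and 0.5% heterozygous calls (never inside a group's
own blocks, which therefore have GD exactly 0 before missingness).
Defaults mirror the study panel: four groups of 98/95/61/49 lines,
~43k SNPs on ten chromosomes, twelve 80–200 kb specific blocks per
group.

Two deliberate simplifications matter for interpretation. Background
diversity is created by *marker-wise* resampling, not recombination
blocks, so the simulator has no linkage disequilibrium structure; the
window scan only consumes marginal per-marker diversities, so this does
not favor the method, but passing tests say nothing about LD-driven
artifacts in real data. Second, planted QTN markers auto-picked by the
simulator are required to carry the same founder allele in every group,
i.e. they segregate within groups: a QTN fully confounded with group
membership is absorbed by the kinship/structure covariates of any MLM,
and its non-detection would measure the design, not the method.

### Test-scale study conditions

The recovery tests and the acceptance script run a reduced
configuration chosen once, by power analysis rather than tuning: 4 × 15
lines, 8,000 markers on four 1.7 Mb chromosomes (0.77 markers/kb),
twelve 40–80 kb specific blocks per group with 60 kb guard gaps. At 15
lines per group roughly a quarter of background markers are monomorphic
by drift alone, and the probability that a background window slips
under the threshold falls with the number of markers per window $k$
roughly as $\Phi(-0.5\sqrt k)$ — so ≥40 markers per 50 kb window keeps
drift-driven false calls near zero while the planted blocks (≥30
markers each) are always hit. Guard gaps exceed twice the 25 kb window
so called segments of different groups cannot merge across neighboring
blocks. Larger configurations only increase the margin (more lines per
group shrink drift monomorphism rapidly). "False-called length" is
accounted segment-wise — called segments intersecting no planted block
of the group — because the ±25 kb window overhang past every true block
edge is part of the method's stated geometry, not an error.

Other sizes used by the checks: mixed-model calibration on 5 × 1,000
markers at $n = 180$ under the generative null; QTN power over seeded
replicates of one planted QTN at 25% of variance, $m = 2{,}000$,
Bonferroni 0.05/m; expression shifts of ±2 log2 units at 9 lines per
group against ~1,000 null genes; co-expression blocks of 5 genes at
generative $r = 0.95$ over 27 organs.

## Numerical and degenerate-input choices

- p-values are clamped into (0, 1] (`.Machine$double.xmin`) so strict
  cutoffs and $-\log_{10}$ transforms stay defined for perfect signals.
- Eigenvalues of $K$ are floored at 1e−10 before whitening; REML uses
  `optimize` on $\log\lambda$ with tolerance 1e−6.
- Degenerate ANOVA inputs (zero variance everywhere, equal means) return
  $p = 1$; zero-variance genes are excluded from correlation networks
  with a warning.
- Missing dosages: mean imputation only inside PCA and kinship/GWAS;
  the diversity scan and IBS distance use complete pairs/calls.
- Duplicated lines across merged panels keep the first panel's calls;
  the discordant-call count is reported. Byte determinism of the
  simulator is part of the test suite (all outputs are written with
  fixed formatting; the GFF3 writer emits no timestamp).

## Known limitations

- Group-level diversity suppression cannot distinguish IBD from any
  other cause of monomorphism (strong selection, genotyping artifacts),
  and "shared" segments are positional only.
- At small group sizes drift monomorphism is substantial; the threshold
  is relative (mean − 0.5 SD per chromosome), so the scan's false-call
  behavior depends on marker density as analyzed above.
- The BLUP model folds replicate effects into the residual when they are
  inestimable; no spatial field-trial adjustment is attempted.
- The MLM is single-locus P3D; no multi-locus or Bayesian refinement.
- No admixture/ancestry model: group labels are inputs (membership file
  or tree cut), not estimated.
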