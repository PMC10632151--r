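---
title: "Methods: homoeolog expression bias, eQTL mapping and genomic design in polybias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homoeolog expression bias, eQTL mapping and genomic design in polybias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polybias)
```

## The problem

Allotetraploid species such as upland cotton carry two coresident
subgenomes (At and Dt), so most genes exist as duplicated homoeolog pairs.
The two copies are rarely expressed equally: expression is often *biased*
toward one subgenome, the bias can change across development, and it is
under genetic control by cis- and trans-acting variants. polybias
implements an integrated analysis of this phenomenon for a diversity
panel genotyped at SNP level and expression-profiled over developmental
timepoints: bias scoring and classification, eQTL and bias-eQTL mapping,
regulatory-network modules, a four-model classification of how favorably
each homoeolog pair is configured, and a genomic-design layer (favorable
allele library, ridge breeding values, donor-parent selection).

Because the package is validated entirely on synthetic cohorts, every
stage is exercised against a planted truth set, and this vignette states
explicitly what those tests do and do not show about real data.

## Bias scoring and calling

The bias score of a pair with expression levels At and Dt is

$$ s = \frac{\mathrm{At} - \mathrm{Dt}}{\mathrm{At} + \mathrm{Dt}} \in [-1, 1], $$

undefined when both copies are zero. Per accession and timepoint, a pair
is *callable* when at least one member exceeds `expr_min` (default 0.1,
FPKM-like units) and *biased* when one member is at least `fold` times
the other (default 2; a zero denominator counts as an infinite fold
change, so 0.5 vs 0 is a bias call — the limit-consistent reading of a
fold-change rule, avoiding pseudocount distortion).

At the population level a pair is labeled biased toward a subgenome at a
timepoint when (i) at least `min_frac` (default 5%) of accessions carry
that call, (ii) a paired two-sided Wilcoxon signed-rank test of At vs Dt
across accessions survives Benjamini–Hochberg correction at `fdr`
(default 0.05), and (iii) the opposite direction does not also reach
`min_frac` (that case is `bidirectional`). The Wilcoxon is paired across
accessions because the two members are measured in the same accession;
an unpaired variant would discard that structure. Both the FDR-gated
label and the fraction-only label are emitted, since either convention
is defensible for descriptive figures.

### Temporal classes and pair clusters

Over T = 6 timepoints, each accession's call vector maps to one of eight
classes: classes 1–6 hold a single bias direction at 6, 5, …, 1
timepoints (no bias elsewhere), class 7 is balanced throughout, class 8
contains both directions. The mapping is a total function on
{BiasA, BiasD, none}⁶; the test suite verifies it against an independent
per-definition oracle on all 729 vectors. `not_expressed` timepoints are
treated as "none" — the class definitions speak only of bias versus no
bias, and conflating "balanced" with "not expressed" in class 7 is the
one unavoidable ambiguity of that reading (logged per pair so users can
check sensitivity).

Pairs are then clustered on their per-class accession fractions by
Ward-linkage hierarchical clustering (Euclidean metric, k = 3) and each
cluster is named by its centroid's dominant mass: class 8 → *switched*,
class 1 → *dominant*, classes 2–7 → *time-dependent*. Linkage and metric
are package choices (no canonical convention exists for this step);
Ward/Euclidean on row-normalized fractions is the standard default for
profile clustering and recovers planted archetypes at > 95% accuracy in
the tests.

## Association scans

All scans use fixed-effect ordinary least squares with principal-
component covariates rather than a kinship mixed model. This is a
deliberate simplification: the synthetic cohorts have PC-capturable
structure by construction, and a REML mixed-model solver is outside the
package's scope. The scan engine residualizes the target and each SNP on
the covariates (Frisch–Waugh), which is algebraically identical to the
full OLS fit; the tests verify effect, standard error and p-value
against an explicit normal-equations oracle to 1e-8. Hidden expression
confounders are absorbed by expression PCs (default 5) instead of a
latent-factor model; the PC count is exposed so users can run the same
"maximize discoveries" tuning loop over it that latent-factor pipelines
use.

* **cis scan** (`scan_cis`): SNPs within ±1 Mb of the TSS (strand-aware:
  annotated start for +, end for −); per-gene expression is
  inverse-normal transformed (ranks to normal quantiles, (r − 0.5)/n,
  mid-ranked ties). Gene-level significance comes from min-p phenotype
  permutations (default 1,000, seeded; empirical p floored at
  1/(n_perm + 1)), then BH across genes at FDR < 0.05. Full permutations
  replace adaptive/beta-approximation schemes — exact at the scales the
  package targets.
* **trans/GWAS scans** (`scan_linear`, `run_gwas`): genome-wide SNPs at
  MAF > 0.05, thresholded at 1/n_snps (with n = 2,658,921 this prints
  3.76e-7). Trans is defined as outside the ±1 Mb TSS window or another
  chromosome.
* **bias-eQTL scan** (`scan_bias_eqtl`): the bias score is the phenotype.
  Pairs qualify at a timepoint only when their biased-accession fraction
  lies in [5%, 95%] — fully biased pairs carry no mappable variation.
  Effects are reported on the bias-score scale (positive = toward At);
  when compared against the Dt member's expression-eQTL effect they are
  multiplied by −1 (`dt_sign_flip`). Scaling both members by any c > 0
  leaves the score, and hence every statistic, unchanged (tested).

### Loci, merging and hotspots

Significant SNPs are clustered into loci by a single linear pass:
consecutive-SNP gap ≤ 10 kb for trans (clusters kept only with **more
than three** SNPs, read strictly as ≥ 4) and ≤ 20 kb for GWAS, where
adjacent loci additionally merge when their lead SNPs are in LD
(r² ≥ 0.6, consecutive pairs only — whether all pairs or consecutive
pairs were intended is ambiguous; consecutive is implemented). Stage-wise
loci for one target merge by single linkage when leads satisfy **both**
r² ≥ 0.6 and distance ≤ 100 kb (50 kb for the network build); the merge
is idempotent and order-invariant.

Hotspots are regions regulating more than three distinct eGenes,
detected by a fixed 100-kb window over trans-locus lead positions with
adjacent hotspots merged when closer than 20 kb. The window scan
replaces a dedicated scan-statistic program; the window width is a
parameter and the default is documented as a package choice.

## Network modules

The regulatory network is bipartite: locus/hotspot nodes connect to the
candidate genes they regulate, with loci whose lead falls inside a
hotspot absorbed into the hotspot node. Modules are found by Louvain
modularity maximization on the plain undirected, unweighted graph
(resolution 1.0, seeded) — matching how general-purpose network tools
treat such graphs, rather than a bipartite-specialized modularity. A
known consequence of the resolution limit: on very sparse strictly
bipartite blocks, resolution-1 modularity can prefer finer partitions
than the planted ones, so module counts on sparse graphs should be read
qualitatively. The reported Q is recomputable from the partition (tested
to 1e-9).

Module–trait profiles regress the trait on the module's gene expression
per timepoint; the normalized r² (share of the summed r² across
timepoints) localizes when the module tracks the trait. Profiles with
total r² < 0.01 are reported unnormalized — normalizing noise would
fabricate temporal structure. Modules enter this analysis only with
heritability ≥ 0.05 and ≥ 5 genes.

Module (and SNP-set) heritability uses Haseman–Elston regression: the
off-diagonal phenotypic cross-products of the centered trait are
regressed on the corresponding GRM entries from standardized dosages;
h² = slope/var(y), clamped to [0, 1]. HE is closed-form and unbiased,
with no convergence failures at small n — an LD-weighted REML estimator
is a possible extension point, not a dependency. Recovery error is
≤ 0.12 mean absolute across h² ∈ {0, 0.25, 0.5, 0.75} at n = 500.

Enrichment of a locus subset in modules is a one-sided Fisher exact test
per module, BH-corrected, verified against exhaustive hypergeometric
summation.

## Subgenome coordination models

For each trait-associated candidate gene (flagged by per-gene,
per-timepoint OLS of trait on expression — a transparent surrogate for
weighted transcriptome-association machinery; the downstream
classification logic is unchanged), its homoeolog pair is classified per
accession and timepoint by crossing two booleans:

* *genotype-favorable*: the accession carries ≥ 1 copy of the favorable
  allele at the candidate's variant. Dominant coding is the default
  because genotype-contrast analyses typically compare carrier classes;
  homozygous-only coding is an option.
* *expression-favorable*: for a positively acting candidate, the partner
  homoeolog is not more than `fold`-fold below the candidate ("higher or
  no difference", with "no difference" operationalized as within
  twofold — exact equality would be measure-zero); mirrored for negative
  candidates.

The cross yields favorable-pair / genotype-only / expression-only /
unfavorable-pair. Pair-level labels apply the priority rules: (1)
favorable pair when ≥ 50% of accessions are favorable at **every**
timepoint; (2) genotype-only when favorable-or-genotype-only reaches 50%
at every timepoint but (1) fails; (3) expression-only symmetrically; (4)
the remainder. "≥ 50% of accessions at all timepoints" is interpreted
per-timepoint (each timepoint independently reaches 50%), not as a fixed
accession set — the laxer and more natural reading; this is flagged as
an interpretation. Per-accession counts of pairs in each state recover a
positive correlation with the trait when favorable alleles are planted
as causal (r > 0.3 in the acceptance suite).

## Genomic design

The favorable allele at each trait-associated locus is the allele whose
dosage moves the trait in the beneficial direction. The *sharing ratio*
is the favorable-allele frequency among cultivars, binned into C1–C4 at
0.25/0.5/0.75 — quartile edges are a package choice (the source
convention is unstated) and configurable, as is carrier-frequency
binning. Selection status uses the strict rule: favorable-selected when
the cultivar–landrace favorable-frequency difference exceeds 0.6,
purifying when it falls below −0.6, else neutral.

Breeding values come from L2 ridge regression on favorable-allele
dosages (0/1/2), closed form with the penalty chosen by 5-fold CV
minimum MSE and the final model refit at λ\*. The method is implemented
as ridge (L2) as named, even though elastic-net tooling with mixing
parameter α = 1 denotes the lasso extreme — the two descriptions in the
method's lineage are internally inconsistent, so the package offers a
`glmnet` engine with a free α for users who want the other reading,
without presenting either as certified. Expression augmentation appends
standardized homoeolog-expression features that pass BH q < 0.05
trait-correlation at ≥ 1 timepoint; with causal expression planted, the
augmented model wins the paired CV comparison (sign test p < 0.05 over
100 replicate fits).

The predicted best value maximizes coefficient × dosage per locus over
{0, 1, 2}; distances to it are nonnegative by construction. The
improvement matrix counts, per target–donor pair, loci where the donor
carries more favorable copies, with ΔBV summed over those loci and the
percent gain taken relative to the target's current BV (the denominator
is a choice; trait-mean scaling is available by flag).

## The synthetic-data generator

`simulate_cohort()` emulates: biallelic SNPs (MAF ≥ 0.05) in LD blocks —
2·n haplotypes per block drawn from K = 20 founder haplotypes, a fast
block-copy model with tunable within-block r², not a coalescent;
homoeolog-pair expression over six stages simulated on the log2(x + 1)
scale as a smooth cubic per-pair baseline + planted cis/trans dosage
effects + an At-side bias offset + Gaussian noise (default sd 0.5 log2
units), reported on the linear scale; additive phenotypes at a target
heritability; and landrace/cultivar subpopulations with shifted
favorable-allele frequencies. Defaults (200 accessions, 2 chromosomes,
six stages) are a reduced-scale rendering of a few-hundred-accession
diversity panel.

What the generator does **not** emulate — and hence what green tests do
not establish about real data: read-level noise and mapping bias between
homoeologs, realistic recombination maps and long-range LD decay,
kinship structure beyond what PCs capture, batch effects richer than a
low-rank component, missing-data mechanisms other than missing slices,
and selection acting over generations. The pseudocount in
log2(x + 1) also means a planted 1-log2 bias offset yields a score
slightly above the asymptotic 1/3 at moderate baselines; tests account
for this analytically.

## Numerical and reproducibility choices

Every stochastic step takes an explicit seed and restores the caller's
RNG state. Ties in the inverse normal transform are mid-ranked; its
degenerate all-equal input returns zeros with a warning. Zero-variance
SNPs are undefined for LD and skipped in scans. Permutation p-values are
floored at 1/(n_perm + 1). The pipeline writes a manifest whose hash
covers thresholds and seed (not filesystem paths), so identical
configurations produce identical manifests. Problem sizes in the test
and acceptance suites (e.g. n = 300 with 50 replicates for scan power,
n = 1,000 with 200 loci for ridge accuracy, n = 500 for HE recovery)
were chosen as the smallest cohorts at which the corresponding
asymptotic properties are comfortably visible.

The spec-level command-line surface is fulfilled by the exported R
functions (`run_pipeline()`, `validate_config()`, and the per-stage
functions) plus `scripts/acceptance.R`; an analysis package's natural
interface is the R session, and a shell wrapper would add nothing the
functions do not already expose.

## Known limitations

* Fixed-effect scans with PCs under-correct confounding when relatedness
  is strong and not low-rank; a mixed-model engine is the natural
  extension.
* The transcriptome-association surrogate (expression-on-trait OLS) has
  no instrument structure; it flags association, not causality.
* Hotspot detection with a fixed window can split or fuse hotspots near
  the window scale; counts are reported per timepoint so users can
  inspect stability.
* Modularity at resolution 1 under-resolves or over-splits sparse
  bipartite graphs (resolution limit); module identities, not exact
  counts, are the robust output.
* C1–C4 bin edges and the ΔBV% denominator are conventions, exposed as
  parameters rather than fixed truths.
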