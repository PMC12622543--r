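---
title: "Marker-metabolite multi-omics QTL analysis: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker-metabolite multi-omics QTL analysis: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`mqtlnet` implements a complete marker-metabolite multi-omics analysis for a
replicated crop association panel: selecting trait-marker metabolites by
two-year consistent correlation, mapping metabolite and expression QTLs with
a kinship-corrected linear mixed model, associating metabolites with gene
expression by per-gene regression, collapsing signals into positional 100-kb
QTL blocks with hotspot calls, building soft-thresholded co-expression
modules with eigengenes, testing haplotype groups at lead variants, and
assembling the tripartite metabolite--QTL--gene colocalization network.
Because panels of this kind are rarely deposited in full, the package ships
a synthetic cohort generator with planted ground truth; every downstream
stage is exercised and validated against it.

# The synthetic cohort

The generator emulates a rapeseed inbred-line panel: by default 388
accessions phenotyped in 2 years with 6 replicates per accession-year, a
transcriptome subcohort of 274/388 of the panel sampled uniformly at random,
biallelic SNPs with generating MAF drawn from (0.08, 0.5), and metabolites
with broad-sense heritability targeted at 0.67.

**Genotypes.** Chromosomes are tiled into fixed 100-kb blocks. Each block
draws a founder binary haplotype at a frequency sampled from `maf_range`;
every variant in the block is a copy of the founder with a per-accession
flip probability (`mutation_rate`, default 0.06). Within-block correlation
is therefore high (about $(1-2\mu)^2 \approx 0.77$ between copies) and
between-block variants are independent. This is deliberately not a
coalescent: the downstream blocking step is purely positional, so a
distance-delimited LD mechanism is the simplest one that makes that step
meaningful. Accessions are inbred (dosages 0/2); a configurable 1% of calls
are set missing and mean-imputed downstream.

**Metabolites.** Each metabolite's accession-level genetic value is a
standardized mix of a planted causal-variant effect (variance fraction drawn
from `effect_size_range`, default 0.08--0.3, random sign) and an independent
polygenic accession effect, scaled to variance $H^2$. Observations add a
shared year shift (0.5% of the residual budget) and replicate noise
(99.5%), so the one-way ANOVA estimator recovers the target $H^2$.
The polygenic accession effect is drawn i.i.d. rather than from the
genotypes: this keeps non-planted metabolites exactly null with respect to
the variant panel, which is what makes the scan-calibration and
marker-specificity checks clean. The cost is that the generator does not
emulate confounding between polygenic background and causal variants; the
kinship correction is therefore exercised as a variance-component machinery
but not stress-tested against strong structure. Abundances are Gaussian on
a log-like scale; the raw-versus-log question is left to the user because
abundance distributions are instrument-specific.

**Expression.** Module genes share a latent accession factor plus noise
(within-module $r \approx 0.8$); planted cis genes load on a variant within
1 Mb of the gene; a trans hotspot is a single variant loading 120 genes.
Only the transcriptome subcohort receives observed values.

**Trait.** The trait's genetic value is a signed, equally weighted sum of
the designated marker metabolites' genetic values (one third negative by
default, echoing the mixed-sign marker sets seen in real panels), rescaled
to the same heritability, with the same year/replicate structure.

**Planted triples.** `simulate_cohort()` links one cis gene's latent
expression into a marker metabolite that also maps to the gene's causal
variant, so the full pipeline should close a metabolite--QTL--gene triangle
from raw matrices.

Determinism: a fixed `sim_config` (including `seed`) reproduces every
output byte for byte; each generator stage derives its stream from
`seed` plus a fixed offset so stages can also be re-run independently.

# Marker selection

Per year, the trait (accession means over replicates) is correlated with
every metabolite by Pearson correlation on pairwise-complete accessions,
with the two-sided p-value from $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$
degrees of freedom. A metabolite is a **marker** iff $p < \alpha$ (default
0.05) in *every* year and all years agree on a nonzero sign; the selected
set is partitioned into positive and negative markers and is monotone in
$\alpha$. Constant vectors are flagged, never silently zeroed. Spearman
correlation is available via `method =` for heavy-tailed abundances.

Broad-sense heritability is estimated per metabolite from the
replicate-level table by a one-way random-effects ANOVA across accessions
(years pooled as replicates):

$$H^2 = \frac{\hat\sigma^2_a}{\hat\sigma^2_a + \hat\sigma^2_e},\qquad
\hat\sigma^2_a = \frac{MS_B - MS_W}{k_0},$$

with $k_0$ the effective replicate count for unbalanced designs and
negative estimates truncated at zero. This treats year effects as part of
the residual, which biases $H^2$ down by well under 0.01 at the default
year-variance share; the estimator is affine-invariant.

# Association scans

**Mixed model (mGWAS/eGWAS).** For phenotype $y$ the null model is
$y = X\beta + g + \varepsilon$, $g \sim N(0,\sigma^2_g K)$,
$\varepsilon \sim N(0,\sigma^2_e I)$, with $K = ZZ^\top/m$ the
centered-and-scaled (VanRaden-style) genomic relationship matrix from
mean-imputed standardized dosages. $K$ is eigendecomposed once; the
restricted likelihood is profiled to a one-dimensional search over
$\log\delta$, $\delta = \sigma^2_e/\sigma^2_g$, on a 61-point grid spanning
$10^{\pm 5}$ refined by bounded scalar optimization (tolerance $10^{-8}$).
Per-variant tests are generalized least squares in the rotated coordinates
with $\hat\delta$ fixed from the null fit -- the standard
single-decomposition approximation used by fast mixed-model GWAS tools --
and a two-sided Wald $t$ test. With $K = I$ the scan reduces *exactly* to
per-variant OLS, which the test suite checks against a closed-form oracle
to $10^{-6}$ in $\log_{10} p$. When many phenotypes share a panel,
`lmm_scan_many()` reuses the eigendecomposition and the rotated dosage
matrix across phenotypes.

**Per-gene regression (mTWAS).** Simple linear regression of a metabolite
on each gene's expression over pairwise-complete accessions, two-sided $t$
test on $n-2$ df.

**Significance.** The genome-wide threshold convention is the reciprocal of
the number of tests, compared strictly: $1/8{,}274{,}830 = 1.2\times
10^{-7}$ and $1/70{,}781 = 1.41\times 10^{-5}$ at the panel sizes typical
of this design. An $\alpha$-scaled Bonferroni cut (0.05/$n$) is available
behind `threshold_mode = "bonferroni05"`.

Two-year handling: scans run per year on that year's accession means and
the significant-signal sets are unioned before blocking. No covariates or
principal components are included by default; the mixed model's kinship
term is the population-structure control, and a covariate matrix can be
supplied.

# QTL blocks and hotspots

Significant signals are chained per (trait, chromosome): sorted by
position, a signal joins the open block when its gap to the last member is
at most 100 kb, else a new block opens. Chaining is single-linkage, so a
block's span may exceed the window; the lead variant is the member with the
smallest p (ties to the smaller position). The blocking is order-invariant
and partitions the input signal set. Counting is per (trait, block): the
same interval hit by two metabolites yields two mQTLs.

Hotspots use fixed 1-based 100-kb bins, independent of chaining: an mQTL
hotspot bin holds strictly more than 30 significant signals across traits;
an eQTL hotspot bin associates with strictly more than 100 *distinct*
genes. An eQTL block is **cis** to its gene iff same chromosome and
interval gap at most 1 Mb (inclusive), else **trans**.

# Co-expression modules

The unsigned weighted network uses adjacency $a_{ij} = |r_{ij}|^\beta$ with
$\beta = 6$ and the standard topological overlap

$$\mathrm{TOM}_{ij} = \frac{\sum_{u\neq i,j} a_{iu}a_{uj} + a_{ij}}
{\min(k_i,k_j) + 1 - a_{ij}},$$

verified against a brute-force triple loop to $10^{-12}$. Modules come from
average-linkage clustering of $1-\mathrm{TOM}$ with a *static* cut at
dissimilarity 0.99 and a minimum size of 30; clusters below the minimum go
to an explicit "unassigned" pool. A static cut was chosen over dynamic
hybrid cutting because it is fully specifiable and deterministic; the cut
height and minimum size are exposed. Labels are assigned by decreasing
module size, so results are independent of gene order. Module merging by
eigengene similarity is deliberately not performed.

The module eigengene is the first principal component of the standardized
member submatrix, unit variance, oriented so its mean correlation with
members is non-negative; variance explained is $d_1^2/\sum d_k^2$.
Module--trait/metabolite relations are Pearson correlations flagged at
$p < 0.01$.

# Ternary network and candidates

An mQTL and an eQTL colocalize iff they share a chromosome and their
*interval gap* is at most 100 kb (zero when overlapping). Interval gap --
rather than lead-to-lead distance -- is the more inclusive reading of
"distance" between blocks and is applied symmetrically. Connected
components of the colocalization relation merge into single QTL nodes
spanning the union of member intervals, resolving chains like
$m_1\!-\!e_1\!-\!m_2$ into one node; consequently every QTL node touches at
least one metabolite edge and one gene edge by construction. Edges carry
their provenance (block ids, lead variants, p-values). Gene membership can
be restricted to modules significantly correlated with the trait.

A **candidate gene** closes at least one metabolite--QTL--gene triangle:
its eQTL shares a QTL node with an mQTL of a metabolite it is
mTWAS-associated with. Candidates are ranked by triangle count, then best
mTWAS p. The triangle rule is this package's operationalization of
multi-omics convergence; it is intentionally strict (all three edge types
must be present).

# Haplotype tests

At 1--k lead variants, each inbred accession's haplotype string
concatenates the allele letters of its homozygous calls (dosage 0 gives the
reference letter, 2 the alternate); heterozygous or missing calls drop the
accession, and groups below 10 accessions are excluded. Two groups are
compared by Welch's two-sided t-test (unequal variances -- the safer
default); more than two by one-way ANOVA. Welch p-values agree with an
exact permutation oracle within Monte-Carlo error in the test suite.

# Numerical choices and degenerate inputs

* Missing dosages are mean-imputed per variant for kinship and scans;
  variants constant after imputation are skipped with a log entry.
* MAF filtering is strict (`> 0.05`): a variant at exactly the threshold is
  removed.
* Kinship eigenvalues are clipped at zero below $10^{-8}$ of the maximum;
  matrices with materially negative eigenvalues are rejected with
  diagnostics.
* REML variance estimates are non-negative by construction; boundary
  estimates ($h^2 \to 0$ or $1$) are permitted and exercised.
* Tie-breaks are always deterministic (lead variant by smaller position,
  module labels by size then first gene id), making every stage
  reproducible under input permutation.
* Constant phenotypes, constant eigengenes, all-missing variants and
  single-replicate accessions raise or flag; nothing degrades silently.

# Problem sizes used in validation

The shipped validation suite exercises the generator at the panel scale the
design calls for where that matters statistically, and at reduced marker
densities where only the machinery is under test: null-calibration scans at
200 accessions by 2,000 variants over 50 phenotypes; planted-QTL recovery
and power at 400 accessions by 5,000 variants with 20 and 50 planted
effects; module recovery at 388 accessions (274 with expression) by 300
genes in 3 planted modules of 50; marker specificity at 388 accessions by
200 metabolites. These sizes give the Monte-Carlo checks enough resolution
(binomial standard errors of a few percent) while keeping the whole suite
runnable in minutes on a laptop.

# What passing tests do and do not show

The generator plants clean, additive, homoscedastic effects with Gaussian
noise and block-uniform LD. Passing recovery tests therefore demonstrates
the correctness of the estimators and the plumbing -- not robustness to
skewed abundance distributions, batch effects, genotype-by-environment
interaction, population stratification confounded with causal loci,
coalescent LD decay, or LC-MS artefacts, none of which are simulated.
Module counts, QTL counts and network sizes on real panels depend on panel
size, marker density and tuning, and are not reproduced by the synthetic
cohort.

# Known limitations

* Per-variant REML is approximated by the null-model variance ratio; for
  variants explaining a very large variance fraction the Wald p is
  slightly conservative.
* The static tree cut can split one true module at aggressive heights;
  the cut height is exposed and the default (0.99) was chosen for
  high-noise expression data.
* Haplotype analysis ignores heterozygotes entirely, which is appropriate
  for inbred panels only.
* The interfaces are R functions plus `run_pipeline()`; inter-stage
  products are plain TSV so any stage can be replaced by an external tool.
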