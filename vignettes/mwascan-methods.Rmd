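---
title: "Methods: summary-statistic methylome-wide association, fine-mapping and triangulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: summary-statistic methylome-wide association, fine-mapping and triangulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the statistical machinery:
the models, the assumptions they lean on, the tunable parameters and why
their defaults are what they are, what the synthetic-data generator does
and does not emulate, and the numerical and design choices made where more
than one convention was defensible.

## The pipeline in one paragraph

Blood DNA methylation at a CpG site is partly under local (cis) genetic
control. The package (1) trains per-CpG elastic-net models predicting
methylation from cis SNP dosages, (2) tests the *genetically predicted*
methylation against case-control GWAS summary statistics with a
summary-statistic Z, (3) fine-maps significant sites within LD blocks to
posterior inclusion probabilities and credible sets, (4) annotates CpGs
into functional categories and tests enrichment, and (5) asks whether
methylation, nearby gene expression, and disease risk have sign-consistent
effects (triangulation). Every stage consumes and produces plain tables, so
the stages compose with ordinary data-frame tooling.

## Cis prediction models

For CpG $j$ with normalized methylation $y_j$ and cis dosage matrix $X_j$,
we fit the elastic net ($\alpha = 0.5$ by default) with the penalty chosen
by $k$-fold cross-validation at the minimum-CV-error $\lambda$ (not the
1-SE rule — the minimum is the convention for prediction-oriented weight
databases, and the choice is recorded in the model metadata). Two
panel styles:

* **FHS-style**: all cis variants within 1 Mb on each side of the CpG, the
  boundary *inclusive* (a variant exactly 1,000,000 bp away is in).
* **BIOS-style**: a pre-filter first runs a simple linear regression for
  every SNP–CpG pair *strictly* closer than 250 kb and applies
  Benjamini–Hochberg across all tested pairs; a CpG is modelled only if at
  least one pair is significant at 5% FDR. The gate operates at CpG level:
  all cis variants of a gated CpG enter the elastic net
  (`restrict_to_meqtl = TRUE` restricts to the significant pairs instead).

The reported `cv_r2` is the squared correlation between *out-of-fold*
predictions and observations — an honest estimate, which a permutation test
(labels shuffled, 50 replicates) drives below 0.01 in median. Fold
assignment is seeded and recorded; training is deterministic given data and
seed.

**SNP QC.** Variants below 5% minor-allele frequency are excluded, as are
strand-ambiguous (A/T, C/G) pairs: their orientation against external
summary statistics cannot be resolved, so models containing them would
silently change at harmonization time. An arbitrary exclusion list
(`exclude_variants`) stands in for external QC such as imputation-quality
filters.

**Registry filters.** Models are retained when `cv_r2 >= 0.01` (inclusive)
and no model SNP lies inside the CpG's probe-binding interval — a SNP under
the hybridization probe can corrupt the measured signal itself. A CpG with
no probe interval on record is retained with a warning: exclusion requires
positive evidence. Per-panel and union counts follow inclusion–exclusion
and are exposed via `union_accounting()`.

## The association statistic

With harmonized GWAS effects $\beta_l$ (standard errors $se_l$), weights
$w_l$, per-variant dosage SDs $\sigma_l$ and predicted-level variance
$\sigma_g^2 = w^\top \Sigma w$ from an LD reference panel:

$$Z \;=\; \sum_l w_l \frac{\sigma_l}{\sigma_g}\,\frac{\beta_l}{se_l},
\qquad
b \;=\; \sum_l w_l \frac{\sigma_l^2}{\sigma_g^2}\,\beta_l ,$$

where $b$ is the log odds ratio per SD of genetically predicted
methylation. A single-variant model collapses to that variant's GWAS Z
exactly — a property the tests assert to machine precision. On simulated
cohorts where the LD reference *is* the GWAS cohort, the statistic agrees
with the Wald Z of an individual-level logistic regression of case status
on the predicted methylation to within 0.05 at $n = 5{,}000$ in the
moderate-signal regime ($|z| \approx 4$–$6$) where the test matters. The
agreement degrades mechanically at extreme $|z|$: the summary statistic
aggregates per-SNP Wald ratios (score-like behaviour), while the
individual-level Wald Z bends away cubically in the effect size. This is an
asymptotic property of the statistics, not an implementation artifact.

**Harmonization.** GWAS records are matched by variant id, falling back to
chrom+position; same-allele matches keep $\beta$, swapped effect/other
alleles negate it, any other pair is dropped and counted. Strand-ambiguous
variants are dropped under the default policy (`keep` is available for
fixtures with known strand). Flipping a model entry's alleles while
negating its weight leaves $Z$ unchanged to $10^{-12}$ — the invariance the
orientation logic must satisfy.

**Multiple testing.** BH runs jointly across *all* tests from both panels
(a CpG modelled twice contributes two records); significance is `q <= 0.05`
inclusive. The companion Bonferroni threshold divides $\alpha$ by the total
model count across panels. CpGs inside a user-supplied exclusion BED (e.g.
long-range LD regions) are removed *before* adjustment, so they never spend
multiple-testing budget. The exclusion list itself is an input: no
canonical list exists, so the mechanism is exposed rather than hard-coded.

**Novelty and concordance.** A significant CpG is *novel* iff its distance
to every known risk variant on the same chromosome is strictly greater
than 500 kb (different chromosome counts as infinite). Among CpGs
significant in both panels, the scan reports the fraction with agreeing Z
signs.

**Degeneracies.** $\sigma_g^2 \le 10^{-12}$ (e.g. perfectly anti-correlated
weighted variants) marks the feature untestable with reason
"variance collapse"; untestable features are always reported with a reason,
never silently dropped. The covariance gets an $\varepsilon I$ ridge
($\varepsilon = 10^{-6}$) only when its smallest eigenvalue is negative.

## Fine-mapping

Within an LD block, observed Z-scores of $k$ member records are modelled as

$$z \mid c \;\sim\; \mathcal N\!\big(0,\; \Omega + v\,\Omega\,
\mathrm{diag}(c)\,\Omega\big),$$

where $\Omega$ is the correlation of the models' predicted levels computed
sample-wise on the LD panel and $c \in \{0,1\}^k$ is a causal
configuration. Configurations up to `max_causal = 3` are enumerated along
with the null; the prior is i.i.d. Bernoulli(`prior_p = 1e-3`) and the
causal effect-variance scale is `v = 40` (so a causal site is expected to
carry $|z| \approx \sqrt{v} \approx 6$). These defaults are this package's
choices — exposed in `finemap_config()` and recorded in the result — since
"default" priors differ across fine-mapping tools. The per-site PIP is the
posterior mass of configurations containing the site; for $k \le 5$ the
implementation matches an exhaustive enumeration over all $2^k$
configurations to $10^{-9}$.

Conventions: blocks are 0-based half-open (a site at the start coordinate
belongs to the block, at the end coordinate it does not); a site in no
block gets a singleton pseudo-block with a warning; ties in PIP are broken
by genomic position so output is deterministic; the credible set is the
smallest PIP-ranked prefix whose *normalized* PIP mass reaches $\rho =
0.9$; the null configuration always participates in normalization, and the
result records whether the null's posterior exceeds $1 - \rho$ (the
credible mass cannot rule out "nothing causal here"). Records from the two
panels are fine-mapped as separate members, matching how dual-panel
associations are reported. The MVN log-density is computed via Cholesky
factorization with a $10^{-6}$ ridge applied when $\Omega$'s smallest
eigenvalue falls below $10^{-8}$.

## Annotation and enrichment

Gene models come from GFF3; each CpG receives exactly one of 13 categories
under a fixed precedence (exonic/splicing > splicing > exonic >
5'UTR/3'-UTR > 5'-UTR > 3'-UTR > ncRNA exonic > intronic > ncRNA intronic >
upstream/downstream > upstream > downstream > intergenic). The flank for
upstream/downstream is 1 kb (the common annotator default), splicing means
within 2 bp of an internal exon boundary, and both parameters are
arguments. Annotator suites differ in corner-case precedence; ours is
fixed, documented, and deliberately simple — the enrichment contract is the
13-label partition, not byte-compatibility with any particular tool.

Enrichment compares the associated set against *all tested* CpGs (a
superset), per category, with a two-proportion Pearson chi-square without
continuity correction (equal to the squared pooled two-proportion z — an
identity the tests verify numerically). An associated-vs-complement mode
exists. Categories with a zero expected cell are skipped with a note.

## Normalization and triangulation

`adjust_and_normalize()` applies, in order: quantile normalization mapping
every feature's across-sample distribution onto the mean sorted profile;
the rank-based inverse-normal transform
$z_i = \Phi^{-1}\!\big((r_i - 3/8)/(n + 1/4)\big)$ (Blom offset, average
ranks for ties); and least-squares residualization on covariates (age, sex,
cell-type fractions, genotype PCs) with an intercept. Because quantile
normalization preserves within-feature ranks, the INT that follows makes
the result invariant to the QN orientation except through tie structure —
we normalize feature-wise, which stays well-defined for matrices with few
features. Output features have $|\mathrm{mean}| < 10^{-8}$ and correlation
below $10^{-10}$ with every covariate column. Constant features cannot be
rank-transformed and are dropped with a warning; rank-deficient covariates
raise an error naming the collinear columns.

One consequence worth knowing: when a CpG's genetic signal comes from a
single low-frequency variant, its latent distribution is strongly bimodal,
and the INT — which forces marginal normality — compresses the gap between
modes. The achievable prediction $R^2$ on the INT scale then sits below
the latent-scale heritability. This is a property of rank-normalization
itself, shared by any pipeline that applies it, and is why the package's
heritability-recovery checks plant several common causal variants.

Pairs for correlation are CpG–gene combinations with the gene TSS within
±500 kb of the CpG (matching the 500-kb locus convention used for novelty;
configurable). Correlation is Pearson on the adjusted INT values — the
normalization makes Pearson and Spearman nearly identical — with BH across
all pairs. The expression side reuses the identical association engine on
gene weight models. A triad is *consistent* iff all three legs are
significant at their FDR thresholds and
$\mathrm{sign}(b_m) = \mathrm{sign}(r)\cdot\mathrm{sign}(b_e)$;
*inconsistent* if all significant but signs disagree; *incomplete*
otherwise. Requiring all three legs significant mirrors the sequential
filtering such analyses report. A curated table of 52 published CpG–gene–AD
triads ships with the package (`read_triad_table()`); all 52 satisfy the
sign rule, which the tests assert. Note this is a sign-consistency screen,
not formal mediation analysis: no indirect effect is estimated.

## The synthetic-data generator

`sim_config()` fixes the generative model:

* **Genotypes** — per LD block of `block_size` adjacent variants, a latent
  AR(1) Gaussian with parameter `ld_rho`, thresholded into Hardy–Weinberg
  genotype classes at a per-variant MAF drawn from `maf_range`. This gives
  tunable LD without external reference panels. Ref/alt pairs exclude
  strand-ambiguous combinations, emulating post-QC HapMap-style variant
  sets. A variant monomorphic in the realized sample receives one
  heterozygote so downstream regressions stay defined.
* **Methylation** — each CpG's latent value is a weighted sum of its
  `n_causal_per_cpg` nearest cis variants (standardized dosages), scaled so
  the genetic variance is exactly `cis_h2`, plus $\mathcal N(0, 1 -
  \texttt{cis\_h2})$ noise; beta values are the inverse logit of the latent
  plus a per-CpG baseline, keeping them in $[0,1]$.
* **Expression** — each gene is `mediation_beta` × its CpG's latent +
  $\mathcal N(0,1)$, with the TSS placed 1 kb from the CpG.
* **Disease** — liability = named CpG latents × `liability_effects` +
  standard-normal environment; cases are above the empirical
  $1-\texttt{prevalence}$ quantile; summary statistics come from
  per-variant logistic regressions (Wald), the way GWAS actually report.

One master seed drives everything; each stage uses the deterministic child
seed `seed + 1000 × stage_id`, so regenerating one stage never perturbs
another, and a fixed config yields byte-identical fixture files
(checksum-tested). `write_fixture_bundle()` writes VCF 4.2, feature-in-rows
TSV matrices, probe-interval BED (CpG ± 24 bp), GFF3 gene models (every
fifth gene non-coding), a GWAS sumstats TSV, LD-block BED, and the truth
table, all round-tripping through the package readers to $10^{-9}$.

What the generator does *not* emulate: population structure and admixture,
imputation uncertainty, X-chromosome dosage, batch effects, cell-type
heterogeneity beyond supplied covariates, by-proxy phenotypes, and any
realistic effect-size distribution for meQTLs (none is published; fixture
effects are chosen for testability). Passing tests therefore demonstrate
statistical correctness of the machinery under the stated model — not
robustness to the full messiness of cohort data.

## Problem sizes used by the test suite

The checks run at sizes chosen to make their statistical targets sharp while
keeping the suite quick to iterate on: calibration of the association test
uses 1,000 two-variant models over a 2,000-variant null cohort of 3,000
samples (type-I error within 0.05 ± 0.015); summary-vs-individual agreement
uses 20 cohorts of 5,000; credible-set coverage uses 500 simulated
ten-site blocks with one causal site at $|z| \approx 6$ (coverage ≥ 85%
at $\rho = 0.9$); the end-to-end triangulation recovery uses 20 cohorts of
5,000 with five planted CpG→gene→risk paths (≥ 4/5 recovered in ≥ 80% of
replicates, at most one false pair on average). `scripts/acceptance.R`
re-derives the headline quantities at the same scales.

## Known limitations

* The LD reference must carry the model variants with compatible alleles;
  variants absent from the panel make a feature untestable rather than
  being imputed.
* Fine-mapping enumerates configurations, so blocks are practical up to a
  few dozen members at `max_causal = 3`; larger blocks would need
  stochastic search, which is out of scope.
* The annotation precedence is a documented simplification, not a clone of
  any specific annotator.
* Sign-consistency triangulation cannot distinguish mediation from
  horizontal pleiotropy; it is a screen, not causal inference.
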