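---
title: "Methods and design of the dysbiome pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the dysbiome pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`dysbiome` implements the statistical core of a case/control shotgun-
metagenomic cohort study: given relative-abundance tables for species and
metabolic pathways, per-sample metadata, cytokine phenotypes, and a binary
gene-family matrix for one focal species, it runs compositional transforms,
covariate-adjusted differential abundance, log-ratio dysbiosis scoring,
diversity and permutational ANOVA, covariate-adjusted association scans
with heterogeneity testing, and strain typing. A synthetic-data generator
with planted ground truth makes every stage verifiable without access to
any real cohort.

# Compositional transforms

Relative abundances are compositions: only ratios carry information, and
zeros are detection limits rather than true absences. The pipeline order is
fixed: row closure, centered log-ratio (CLR) transform, prevalence filter,
then a per-feature rank-based inverse-normal transform (INT).

**Zero replacement.** The CLR is undefined at zero. We substitute a single
table-wide pseudocount, half the smallest nonzero value of the table, then
re-close rows. One global pseudocount (rather than per-sample values)
keeps the transform monotone in the original abundances across samples.
The same pseudocount policy is reused everywhere a log or a ratio needs
protection (fold changes, P/B ratio, dysbiosis scores), so all log-scale
quantities are comparable.

**INT.** We use the Blom variant, \(\Phi^{-1}((r - 3/8)/(n + 1/4))\),
with average ranks for ties. Any offset constant in \([0, 1/2]\) yields
nearly identical z-scores; 3/8 is the common default in genetic
association work. Constant vectors map to zero with a warning rather than
erroring, because all-constant features legitimately arise after heavy
filtering.

**Prevalence filter.** Two readings of "present in at least 20% of
samples" coexist in practice: require the threshold in *at least one*
cohort (`mode = "any"`, the default) or in *every* cohort
(`mode = "all"`). Both are implemented; the default is the inclusive
reading, which retains cohort-specific features whose absence elsewhere is
itself the signal of interest. The filter acts on presence (abundance
> 0), so it commutes with CLR and is idempotent.

# Diversity and PERMANOVA

Alpha diversity is the Shannon index with natural logarithm (the ecology
convention). Beta diversity is Bray–Curtis, which is bounded in [0, 1]
but not a metric; accordingly the principal-coordinates step reports
negative eigenvalues instead of silently truncating them, and explained-
variance fractions are taken over the positive part of the spectrum.

PERMANOVA partitions the Gower-centered squared-distance matrix by
sequential (Type I) sums of squares with covariates entered before the
group term. Significance of the group term comes from permuting the group
labels while covariates stay fixed — a pragmatic scheme that preserves the
covariate structure under the null hypothesis of no group effect. Whether
marginal or sequential attribution is "correct" is analysis policy, not
mathematics; sequential-with-group-last is the convention of the widely
used `adonis` family, and the implementation is verified against
`vegan::adonis2` on covariate-free designs where the two agree exactly.
The permutation count default is 9,999 and a seed is mandatory, making
every reported p-value exactly reproducible; the attainable minimum is
\(1/(n_{perm}+1)\).

# Differential abundance and scores

Per feature, ordinary least squares of the CLR+INT value on the group
indicator plus covariates (defaults: BMI, smoking, read count), with a
two-sided t test for the group coefficient and Benjamini–Hochberg
correction *within each feature family* — species and pathways are
corrected separately, matching the way such panels are reported. Betas are
in normalized-rank units, so arithmetic-mean fold changes of the raw
relative abundances are reported alongside for interpretability (a
geometric-mean variant is available by flag). Constant features are
flagged with p = 1 rather than dropped, keeping the output aligned with
the input panel.

The dysbiosis index (DI) is the per-sample log2 ratio of the geometric
mean abundance over case-enriched features to that over case-depleted
features; the function-imbalance (FI) score is the same statistic on
pathway sets. Feature sets come from the differential-abundance step
(q below threshold, split by coefficient sign) and are written as
two-column TSVs, so transferring case-derived sets onto an external
cohort's table is a file-level operation. The score is antisymmetric under
swapping the two sets, and the pseudocount policy is stated in the output
metadata because the geometric mean is undefined at zero.

# Association scans and heterogeneity

"Covariate-adjusted Spearman" is realized as residualized (partial)
Spearman: INT both variables, regress each on the covariates, correlate
the residuals with Spearman, and take p from the t approximation on
\(n - 2 - \#covariates\) degrees of freedom. With no covariates this
reduces to plain Spearman exactly. Missingness is handled pairwise per
(feature, phenotype) pair — never listwise across a scan — and BH runs
across the whole scan block (default FDR 0.1; cytokine case/control
comparisons use 0.05).

Cross-cohort heterogeneity uses Cochran's Q with inverse-variance weights
against \(\chi^2_{k-1}\). Effects enter as regression betas with standard
errors; correlations are first Fisher-z transformed with
\(se = 1/\sqrt{n-3}\).

# Strain typing

Strains are typed from binary gene-family repertoires: Jaccard distance on
presence sets (joint absences ignored), complete-linkage agglomeration,
and a fixed tree cut (default height 0.3 on the raw Jaccard scale).
Clusters smaller than `min_cluster_size` (default 20) are excluded from
downstream contrasts; the threshold is policy, chosen so that a cluster
supports covariate-adjusted regression, and is configurable.

Cluster–cohort enrichment uses the exact Fisher test (each cluster against
the rest, BH across clusters when there are more than two). Differential
gene families use logistic regression of presence on the cluster indicator
plus covariates. Near-archetypal strains routinely produce perfect
separation, where the Wald test collapses; such genes are detected (by the
fitted-probability warning or an exploding standard error) and assigned a
Fisher-exact fallback p with a `separation` flag, keeping p-value
semantics uniform rather than switching the whole analysis to penalized
likelihood. Pfam over-representation is the one-sided hypergeometric upper
tail with the universe defined as the annotated gene families of the
analyzed matrix.

Strain–phenotype association supports two exposure encodings, because
"strain abundance" is genuinely ambiguous: a cluster-membership indicator
across all retained samples (default), or the species abundance restricted
to carriers of each strain. Both feed the same INT-response least-squares
machinery and can be contrasted across strains with Cochran's Q.

# The synthetic world

The generator's defaults describe one fixed stated world, chosen once:

* **Cohorts:** 143 cases, 190 controls; case ages ~N(51.5, 10.7), control
  ages ~N(50.7, 11.1); male fractions 130/143 and 166/190; smoking 28% vs
  10%; BMI ~N(24.5, 3.5) vs N(25.5, 3.14); MSM 67% vs 0.5%; read depth
  log-normal around 26.8M vs 23.1M reads. Case-only clinical variables
  (CD4 count median 650, IQR 465–810; CD4 nadir 260, IQR 120–370;
  cell-associated viral DNA/RNA) are log-normal with sdlog matched to the
  quoted IQRs.
* **Species panel:** 123 features, 57 planted enriched and 19 depleted,
  default planted effect of 1 log2 unit on the mean; baseline log-means
  heavy-tailed (t with 3 df scaled by 2); log-normal noise with sd 1; the
  smallest 30% of entries zeroed before re-closure. The pathway panel
  scales the same proportions to 331 features (87 enriched / 76 depleted).
* **Gene families:** 4,998 families, two archetypes differing at 2,821,
  per-gene flip rate 0.02, strain membership switched across cohorts with
  probability 0.16.
* **Cytokines:** an 8-cytokine by 3-stimulus panel; target phenotypes get
  `sign * rho * INT(feature)` plus scaled noise (default rho 0.5) so the
  planted partial correlation given age and sex is approximately rho;
  every phenotype receives age/sex confounding with weight 0.5. Targets
  default to high-prevalence features, since a rank correlation cannot be
  carried by a feature that is almost always zero.

All randomness derives from one master seed through fixed per-module
offsets, so any stage can be regenerated independently and two runs with
the same configuration are bit-identical.

**What the generator does not emulate:** batch effects between cohorts,
phylogenetic correlation between features, longitudinal sampling,
count-level sequencing noise, or zero-inflation beyond the single
sparsity quantile. A green recovery test therefore establishes that the
estimators are correct and calibrated *under this stated world*, not that
they are robust to every real-data pathology.

# Numerical choices

* Fold-change and score pseudocounts equal the CLR pseudocount (half the
  table's smallest nonzero value).
* Tied ranks take average ranks everywhere; the Wilcoxon wrapper uses the
  exact enumeration null for small untied samples and the tie-corrected
  normal approximation otherwise.
* `fisher.test` can return p marginally above 1 in floating point; such
  values are capped at 1 before BH.
* Calibration tests are Monte Carlo experiments whose null rates sit
  exactly at the nominal boundary (e.g. a 5% family-wise call rate under a
  global null); those tests use large replicate counts and, where a rate
  is compared against its own nominal value, two binomial standard errors
  of slack. Planted-recovery thresholds are never widened.
* The strain-recovery check uses a planted geometry (1,000 genes, 520
  differential, flip rate 0.02) that satisfies the stated
  within-cluster (< 0.15) / between-cluster (> 0.5) Jaccard condition,
  and asserts the condition before asserting perfect recovery.

# Limitations

The differential-abundance model is a linear model on transformed data,
not a compositional-equilibrium test: when a large fraction of features is
planted in one direction, closure makes unaffected features drift the
other way, and the pipeline will report them — this is a property of
relative-abundance data, not a bug, and is why sensitivity (not
specificity) is the recovery criterion at the default planted fractions.
PERMANOVA's label-permutation scheme is approximate in the presence of
strong covariate effects. The hierarchical strain cut at a fixed height
assumes the chosen distance scale; it is exposed as a parameter rather
than inferred.
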