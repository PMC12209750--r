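---
title: "Aggregated trans-effect scores: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aggregated trans-effect scores: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gatescores)
```

## The scientific problem

Under the omnigenic sparse-effector model, most polygenic influence on a
complex trait is mediated by many weak *trans* effects of common variants
that converge on the expression of a relatively small set of "core" effector
genes. A conventional SNP-by-SNP GWAS is poorly suited to finding such
genes: each individual trans effect is tiny, and disease-relevant genes are
often depleted of large-effect cis-eQTLs. `gatescores` takes the opposite
route: for each gene it builds a genotypic predictor of expression (or of a
circulating protein level) by **aggregating trans effects genome-wide**, and
tests that predictor against a binary disease. A gene whose predicted
expression associates with disease through many independent trans loci is a
candidate core gene.

The pipeline has five stages, each an exported, tested function surface:

1. **Ingestion** — per-SNP univariate QTL summary statistics are filtered at
   `P < 1e-5`, the HLA region (chr6:25–34 Mb) is masked, alleles are
   harmonized to the reference panel, and SNPs are clumped per gene.
2. **LD weights** — within each clump the univariate betas are multiplied by
   the pseudoinverse of the panel genotype correlation matrix, turning
   marginal effects into joint, LD-corrected weights.
3. **Scoring** — each clump's weights times the cohort dosages give a
   per-individual locus score; trans-locus scores are summed genome-wide per
   gene; the Hill number of the locus-score variances gives the effective
   number of trans-QTLs.
4. **Association** — one covariate-only logistic null model (sex + 20 PCs)
   is fitted per cohort, and every score is tested by the efficient score
   test, reporting the log odds ratio per SD of the score.
5. **Filtering, MR and validation** — candidate core genes must have
   effective number > 5 and `P < 1e-5` (both strict); validation criteria
   include GWAS-hit proximity (200 kb), Mendelian randomization with
   pleiotropy marginalized (≥ 10 instruments, `P < 0.01`), and a measured
   protein association in the same direction with at least twice the
   magnitude.

## Clumping and LD-corrected weights

QTL studies publish *univariate* coefficients; SNPs in linkage
disequilibrium carry overlapping information. For each gene, associated SNPs
(`P < 1e-5`) are clumped greedily in order of ascending p-value: the best
unassigned SNP below the anchor threshold (`1e-6` by default) becomes a
lead, and unassigned SNPs within 1 Mb with panel r² ≥ 0.1 join it. The
anchor is relaxed to `1e-5` for designs that test only a preselected set of
trait-associated SNPs, where the prior probability of a true effect is
higher. There is no single canonical clumping rule in summary-statistic
scoring, so PLINK-style greedy p-ordered clumping — the field standard — is
adopted, with every threshold configurable via
`gate_config()`. Ties in p are broken toward the lower (chromosome,
position); a clump is flagged cis when its lead SNP lies within the cis
window (1 Mb, configurable; the literature gives no canonical numeric cis
definition) of the target gene's TSS. Coordinates are 1-based and all
intervals closed, following VCF convention.

Within a clump with correlation matrix \(R\) and univariate betas
\(\beta\), the multivariable weights are \(w = R^{+}\beta\), computed by
SVD with singular values below `1e-6` times the largest discarded. For a
full-rank clump this is the exact inverse solve (tested to 1e-8); for
collinear clumps the minimum-norm solution splits weight across duplicated
SNPs so the implied locus score is unchanged — the property that makes the
pseudoinverse the right tool for ill-conditioned clumps, not a shrinkage
substitute. No ridge regularization is applied by default. The
singular-value cutoff is a numerical-rank tolerance (dropping only
directions at machine-noise scale relative to the leading singular value),
not a statistical tuning parameter.

## Scores and the effective number of trans-QTLs

Locus scores are \(s = X_c w\) with dosages mean-imputed per SNP and
centered at twice the cohort allele frequency. Centering makes scores
mean-zero; with an intercept in the null model the association results are
invariant to it. The genome-wide trans score of a gene is the element-wise
sum of its trans-locus scores; cis loci are kept out and tested separately,
because cis effects on measured levels (e.g. through altered splicing) need
not reflect effects on function, and because a cis association is
vulnerable to confounding by a nearby direct disease locus.

The effective number of trans-QTLs is the Hill number of the locus-score
variances \(\sigma_1^2,\dots,\sigma_K^2\):
\[
N_\mathrm{eff} = 2^{-\sum_i p_i \log_2 p_i}, \qquad
p_i = \sigma_i^2 \Big/ \textstyle\sum_j \sigma_j^2 ,
\]
ranging from 1 when a single locus dominates to \(K\) when all variances
are equal (`diversity_index()`; \(0\log 0 = 0\)). Variances are computed in
the target cohort, not the reference panel: the Hill number should describe
the scores actually tested. Genes dominated by one locus are effectively
single-SNP associations; requiring \(N_\mathrm{eff} > 5\) (strict) keeps
only genes whose association rests on genuinely aggregated trans signal.

## The efficient score test

With outcome \(y\), covariate matrix \(X\) and fitted null probabilities
\(\hat\mu\) (logistic ML fit of \(y\) on \(X\) alone, convergence verified
by the gradient at the fit), a score \(s\) is tested by
\[
U = s^\top (y - \hat\mu), \qquad
V = s^\top W s - s^\top W X (X^\top W X)^{-1} X^\top W s, \qquad
W = \mathrm{diag}(\hat\mu(1-\hat\mu)),
\]
with \(U^2/V\) referred to \(\chi^2_1\). \(U\) is the gradient of the
log-likelihood in the score's coefficient at the null and \(V\) the
efficient information with the covariate directions projected out, so one
null fit serves thousands of scores. On a 2×2 layout with an
intercept-only null this statistic is algebraically the Pearson chi-square,
which the tests verify exactly.

Reported effects are **SD-standardized log odds ratios**: the one-step
estimator \(\hat\beta = U/V\) multiplied by the SD of the score — the log
odds ratio per one-SD increase. The one-step estimator is used rather than
a full refit because it is score-test-consistent and \(O(\text{genes})\)
cheaper; in the weak-effect regime where the pipeline operates it agrees
with the ML refit within 5% (tested). Tests of measured protein levels use
the same machinery on the level standardized to unit SD, with optional
restriction to incident cases (prevalent cases dropped). When a genotypic
score is derived from a proteomics substudy of the same cohort, substudy
members are excluded and the null refitted on the remainder.

### The attenuation law

If a measured level \(x\) causes disease with standardized log OR \(b\) and
a genotypic score has correlation \(r\) with \(x\), the score's
standardized log OR tends to \(r\,b\): the ratio of measured-to-score
effect sizes is \(1/\sqrt{r^2}\). At the typical \(r^2 \approx 2\%\) of
aggregated trans scores against measured protein levels this predicts a
ratio of about 7 — the calibration check reproduced by
`scripts/acceptance.R` and the acceptance suite (simulation at
\(n = 200{,}000\), 40 seeds, band 6.3–7.8).

## Mendelian randomization with pleiotropy marginalized

Each trans-QTL locus contributes one scalar instrument: its locus score.
\(\gamma_j\) is the coefficient of the exposure (measured
transcript/protein) on the locus score in exposure-study individuals;
\(\Gamma_j\) is the one-step log-odds coefficient of disease on the cohort
locus score with \(SE = 1/\sqrt{V}\). Direct (pleiotropic) effects
\(\alpha_j \sim N(0, \tau^2)\) are integrated analytically:
\[
\Gamma_j \sim N\!\big(\theta\,\gamma_j,\;
  se_{\Gamma_j}^2 + \theta^2 se_{\gamma_j}^2 + \tau^2\big),
\]
jointly maximized over \((\theta, \tau)\) by a bounded \(\tau\) grid with
per-\(\tau\) profile optimization and local refinement (deterministic; no
seeds). The p-value is the likelihood ratio for \(\theta = 0\) with
\(\tau\) free under both hypotheses; the 95% CI is the profile-likelihood
interval. With \(\tau = 0\) and negligible \(se_\gamma\) the MLE collapses
to the inverse-variance-weighted estimator exactly (closed-form oracle in
the tests). A zero-mean Gaussian is the transparent default for the
pleiotropy distribution; the likelihood is a small pluggable component
should a heavier-tailed choice be preferred. There is no Egger-style
intercept: a shared offset (directional pleiotropy) is absorbed into
\(\tau\), a deviation worth revisiting.

The criterion is evaluated only for genes with at least 10 trans-QTLs —
with fewer there is not enough information to learn the pleiotropy
distribution, and `fit_causal_effect()` flags such results advisory-only
rather than refusing to compute them. A null MR result does not exclude a
causal effect: with pleiotropy marginalized the test deliberately gives up
power for validity, which the calibration tests quantify (95% CI coverage
0.94 at \(\theta = 0.3\) with 20 instruments; type-I 1.3% at nominal 1%
over 1000 replicates — mild small-sample inflation of the LR test at 20
instruments).

## What the synthetic data emulates — and what it does not

`simulate_ld_panel()` generates dosages from a latent-Gaussian model: per
haplotype, an AR(1) chain of standard normals per block, thresholded at the
upper-tail quantile of each SNP's minor allele frequency; the two
haplotypes sum to a Hardy–Weinberg dosage. The latent correlation is
calibrated numerically (bivariate-normal orthant probability inverted by
root-finding) so that the **dosage** correlation, not the latent one, hits
the block's target. One consequence is worth knowing: thresholded variables
with unequal MAFs cannot reach arbitrarily high correlation (a
Fréchet-type bound), so e.g. a target of 0.9 requires closely matched MAFs;
unreachable targets raise an error rather than silently undershooting.

`simulate_qtl_study()` draws fresh individuals from the same generative
model (two-sample design: no overlap with the cohort), computes expression
as genetic signal plus Gaussian noise, and regresses it univariately on
every SNP — or only on a designated trait-associated subset, emulating
trans designs restricted to a preselected SNP panel. The QTL-study noise
model and effect-size distribution are not published quantities; the
defaults here (linear per-allele effects, unit Gaussian noise) are
documented choices, not inferences. `simulate_cohort()` assigns disease by
a logistic liability on the core genes' standardized expression plus any
direct SNP effects, with the intercept solved numerically for the target
prevalence; covariates (sex, 20 PCs) are independent of genotype by
default, since the PCs play the role of nuisance adjustments.

The reference design, `synthetic_architecture()`, fixes the study
conditions used throughout the tests, the analysis scripts and the
acceptance script: 50 genes, 3 core genes, 7 two-SNP trans blocks per gene
(adjacent dosage correlation 0.4, MAF 0.25–0.45), per-SNP effects 0.25 and
0.175 expression-SD per allele, unit expression noise, core coefficient 0.6
per expression SD, prevalence 1%. Problem sizes: a 2,000-individual LD
panel, a 20,000-sample QTL study and a 50,000-individual cohort. These were
chosen once, from power considerations: at 20,000 samples each trans anchor
has essentially unit power at `P < 1e-6` (`qtl_power()` gives
\(>0.999\)), the genetic signal explains roughly a quarter of expression
variance so the GATE score's standardized log OR is about
\(0.5 \times 0.6 \approx 0.3\), and at 50,000 individuals and 1%
prevalence the expected \(\chi^2\) for a core gene is about 45, far past
the \(P < 10^{-5}\) threshold, while null genes stay uniform. What passing
these simulations does **not** show: robustness to realistic human allele
frequency spectra, recombination maps, population stratification
(covariates here are unconfounded by construction), sample overlap between
QTL study and cohort, or mis-specified effect-size distributions.

## Numerical choices and degenerate inputs

- Thresholds live in `gate_config()` and are strict inequalities
  throughout (`effective_n = 5` exactly and `P = 1e-5` exactly fail).
- The null fit rejects separation and rank-deficient covariates with
  explicit errors; score tests reject constant scores and scores collinear
  with covariates (\(V\) at numerical zero).
- Monomorphic panel columns are an error (correlation undefined), as are
  all-zero locus-score variances in the Hill number.
- Missing dosages are mean-imputed per SNP (logged); SNPs absent from the
  cohort are dropped with a warning, and a score is refused only when every
  SNP is missing.
- Strand-ambiguous A/T and C/G SNPs are dropped during harmonization;
  swapped-allele rows get their beta re-signed to the panel's counted
  allele.
- The MR optimizer profiles \(\theta\) over a bounded interval seeded by
  the IVW estimate and \(\tau\) over \([0, 3\,\mathrm{sd}(\Gamma)]\);
  non-convergence is flagged on the result, never silent.

## Known limitations

Beyond the simulator's idealizations listed above: the clumping rule is a
reconstruction of an unpublished procedure; the cis window has no canonical
value; the Gaussian pleiotropy model is one defensible choice among
several; and the one-step log OR, while accurate in the weak-effect regime,
will understate very large effects (the measured-protein tests are the
place this matters, and the full ML refit remains available through
ordinary `glm` on the score).
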