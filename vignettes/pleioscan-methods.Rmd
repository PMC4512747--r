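---
title: "Methods: three-arm cross-trait polygenic analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: three-arm cross-trait polygenic analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

pleioscan asks whether two complex traits share genetic liability when one
is a quantitative biomarker measured in a modest population cohort (the
*discovery* trait — think a plasma coagulation factor) and the other is a
case-control disease study (the *target* — think ischemic stroke or one of
its subtypes). Because neither study is large enough for single-SNP
resolution, all three analysis arms aggregate evidence across many
sub-significant SNPs:

1. **Concordance**: do discovery and target effect *directions* agree (or
   disagree) more often than chance?
2. **Joint effect**: does a discovery-weighted combination of target
   effects — the summary-statistic equivalent of regressing the target
   outcome on a polygenic risk score (PRS) — depart from zero?
3. **GREML validation**: with individual-level genotypes, do the traits
   show non-zero genetic covariance under a two-trait mixed model?

A genetic correlation between the traits should register in all three arms
with a consistent direction; that triangulation, rather than any single
P value, is the design's core idea.

## Input model and allele harmonization

Summary tables carry one record per SNP: identifier, chromosome, 1-based
position, effect and other allele, effect-allele frequency, effect size
(log-odds for binary traits; odds ratios are logged at ingestion so
"direction" is uniformly `sign(beta)`), standard error, P value and sample
size. Records violating these constraints (`se <= 0`, P outside (0, 1],
invalid alleles, ...) are dropped and counted per reason rather than
failing the run.

Discovery and target tables are joined on SNP identifier (not position —
the two studies may be on different arrays or builds) and the target
effect is re-oriented to the discovery effect allele. Four orientations
are recognised: identical, swapped (effect negated), strand-complemented,
and complemented-plus-swapped (negated). For A/T and C/G SNPs a strand
complement is indistinguishable from an allele swap, and with
imputation-era data frequency-based disambiguation is unreliable, so these
strand-ambiguous SNPs are dropped by default (`drop_ambiguous = FALSE`
keeps them under the assumption of same-strand reporting).

## LD clumping and the effective number of SNPs

Aggregating over all SNPs would count dense LD regions many times, so the
discovery SNPs are thinned by greedy P-ranked clumping against a reference
dosage panel: the most significant unabsorbed SNP becomes an index and
absorbs every unabsorbed SNP within ±300 kb whose squared dosage
correlation with it exceeds 0.25 (composite, phase-free LD — appropriate
for imputed dosages). Ties on P are broken by (chromosome, position,
identifier) so results are order-independent. Retained index SNPs are
therefore pairwise in weak LD or physically distant.

Residual correlation among index SNPs is quantified by an eigenvalue
dispersion estimate: per chromosome block with correlation-matrix
eigenvalues $\lambda$ of $M$ SNPs,
$M_{eff} = 1 + (M-1)\,(1 - \mathrm{Var}(\lambda)/M)$ (variance with
denominator $M-1$), summed over blocks; blocks above 2000 SNPs are split
to bound the eigendecomposition. The *effective ratio* $M_{eff}/M$ close
to 1 confirms the clump set behaves as near-independent tests.

## Arm 1: concordance of effect directions

For each inclusion threshold $t$ in the grid
$\{0.01, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5\}$ (nested subsets of the
P-ranked clumped SNPs), `n` counts SNPs with discovery $P \le t$ and `k`
those whose harmonized effects share a sign; exact zero effects carry no
direction and are excluded (and reported). Under no shared genetic
influence each sign agreement is a fair coin, so `k` is tested against
Binomial(`n`, 1/2) with an exact two-sided P value by the
minimum-likelihood rule — the sum of outcome probabilities no larger than
that of `k`, which for a symmetric null equals the doubled smaller tail
capped at 1. Two-sided is the only defensible choice here: excess
concordance and excess discordance are both findings (a factor may be
protective). Each threshold is labelled `concordant`/`discordant` when
its P value passes the study-wide corrected level (below) with the
corresponding direction.

## Arm 2: polygenic joint effect from summary statistics

With discovery effects $\beta_i$, target effects $\omega_i$ and target
standard errors $s_i$, the coefficient of the target outcome on the
(unobserved) discovery-weighted allele score is estimated by the
precision-weighted mean of per-SNP effect ratios:
$$\hat a = \frac{\sum_i \beta_i\,\omega_i/s_i^2}{\sum_i \beta_i^2/s_i^2},
  \qquad se(\hat a) = \Big(\sum_i \beta_i^2/s_i^2\Big)^{-1/2},$$
with a normal two-sided P on $z = \hat a/se$. The point estimator is the
standard summary-statistic PRS coefficient; the SE is its usual companion
(derived by treating the $\omega_i$ as independent with variance $s_i^2$
given the weights), which makes $z$ well-defined. One SNP gives
$\hat a = \omega/\beta$ and $z = \omega/s$ exactly; rescaling all
$\beta_i$ by $c$ rescales $\hat a$ by $1/c$ and leaves $z$ unchanged.
Covariate adjustment is inherited from whatever covariates the
contributing GWASs used, so the summary path deliberately takes none.

The SE above ignores variance contributed by the *realized* effect
vectors themselves: with few, large causal effects, the chance alignment
of two effect vectors (order $1/\sqrt{n_{causal}}$) can exceed the
$s_i$-driven noise and inflate the null $z$. The estimator is therefore
calibrated only in the many-small-effects regime it assumes — each causal
SNP's target effect small relative to its standard error. The synthetic
generator's default architecture (below) respects that regime, and the
same caveat applies when interpreting the arm on real data for strongly
oligogenic traits.

When target genotypes are available the explicit route is also provided:
per-individual scores $\sum_i x_{ij}\beta_i$ (missing dosages mean-imputed)
enter a logistic regression on case status, reported with Nagelkerke's
pseudo-$R^2$, $\big(1 - e^{(D - D_0)/n}\big)\big/\big(1 - e^{-D_0/n}\big)$
(McFadden's $1 - D/D_0$ via option). Complete separation is flagged on the
result rather than raised. Across simulated cohorts the summary and
individual-level $z$ statistics correlate above 0.95, which is the
package's justification for trusting the summary path.

## Multiple testing

When several correlated discovery traits are scanned against several
target subtypes, the familywise level is controlled at
$\alpha/(M_{eff}^{traits} \times n_{subtypes})$, with $M_{eff}^{traits}$
the same eigenvalue-dispersion estimate applied to the correlation matrix
of the traits' PRS profiles scored on a shared cohort (a Li–Ji-style
eigenvalue floor is available but off by default, matching the plain
formula). A single trait pair gives $M_{eff} = 1$ and level 0.05.

Within one pipeline run the summary report applies two further Bonferroni
factors chosen conservatively at design time: the number of arms (3) for
every arm-level flag, and additionally the grid size (7) for the two
threshold-scan arms, whose nested thresholds are treated as separate
looks. Per-threshold labels inside a scan use the corrected level itself,
so a scan's labelled thresholds can be inspected even when the arm as a
whole is not flagged.

## Arm 3: GREML genetic correlation

The genomic relationship matrix over $m$ MAF-filtered SNPs is
$A_{jk} = \tfrac1m \sum_i (x_{ij} - 2\hat p_i)(x_{ik} - 2\hat p_i)
/ (2\hat p_i(1-\hat p_i))$ with sample allele frequencies and
mean-imputed missing dosages; under random mating its diagonal averages 1.
Close relatives violate the model's "distant relatedness" premise, so a
greedy pruner repeatedly drops the individual in the most pairs above a
relatedness cutoff (ties to the lexicographically first id). The
function default of 0.10 removes up to first-cousin pairs; the pipeline
default is 0.25 because at desk-scale SNP counts the GRM's sampling noise
(sd $1/\sqrt{m} \approx 0.026$ at $m = 1500$) would otherwise cause
spurious removals — with genome-wide panels the two coincide in effect.

The univariate model $y = Xb + g + e$, $g \sim N(0, \sigma^2_g A)$,
$e \sim N(0, \sigma^2_e I)$ is fitted by restricted maximum likelihood:
three EM warm-start iterations then average-information (AI) updates with
step-halving, components bounded below at $10^{-6}\,\mathrm{Var}(y)$,
convergence when the restricted log-likelihood moves under $10^{-4}$
(cap 100 iterations), SEs from the inverse AI matrix and a delta-method
SE for $h^2 = \sigma^2_g/(\sigma^2_g + \sigma^2_e)$. The univariate fit
runs in the GRM eigenbasis, making each iteration linear-time; its
likelihood is verified in the tests against an independent dense
evaluation and a grid search. An identity GRM makes the two components
unidentifiable; that case is detected and flagged.

The bivariate model stacks both traits over the union of individuals with
genetic covariance $\sigma_{g12} A_{12}$ linking the blocks — estimable
even when the cohorts are disjoint, which is exactly the two-study design
(a residual covariance is only estimable on doubly phenotyped individuals
and is fixed at 0 when fewer than 10 exist). The genetic correlation
$r_G = \sigma_{g12}/\sqrt{\sigma^2_{g1}\sigma^2_{g2}}$ is clamped to
$[-1, 1]$ with a boundary flag (no Fisher-z reparameterization; at small
$n$ the boundary is genuinely reachable and hiding it would mislead).
Because the constrained ($\sigma_{g12} = 0$) fit can out-climb an
early-converged full fit, the full optimization is resumed from the
constrained solution whenever that happens, guaranteeing a non-negative
likelihood-ratio statistic. Significance of $r_G$ uses the LRT,
$P = P\big(\chi^2_1 > 2(\ell_{full} - \ell_{rG=0})\big)$: at these sample
sizes the Wald ratio $r_G/se$ is badly calibrated (enormous SEs alongside
clearly non-zero covariance are routine and the tests reproduce that
divergence), while the LRT's null rejection rate stays near nominal.

A binary target is analysed on the observed 0/1 scale; `h2_liability()`
provides the prevalence-and-ascertainment conversion to the liability
scale but is off by default since the genetic *correlation*, the arm's
focus, is scale-invariant.

## The synthetic study generator

The generator produces the statistical structure the arms assume, with
known truth, so every pipeline claim is testable end to end:

* **Genotypes**: SNPs in LD blocks; per block each individual carries a
  latent standard normal that mixes into each SNP's liability at weight
  $\sqrt{r}$ (default $r = 0.7$), then cut at the Hardy–Weinberg genotype
  frequencies of the SNP's MAF (drawn uniformly on \[0.05, 0.5\]) to give
  dosages in {0, 1, 2}. Blocks of 3 SNPs spaced 5 kb apart, 1 Mb between
  blocks, round-robin over 22 chromosomes — so clumping's window and LD
  rules both bite.
* **Effects**: 30% of SNPs are causal for both traits; effect pairs are
  bivariate normal on the standardized-genotype scale with correlation
  `rG_true`, then each trait's vector is rescaled so its realized genetic
  variance equals the requested $h^2$ exactly (not merely in
  expectation). The dense architecture keeps every causal effect small —
  the regime the joint-effect arm assumes (see above); with few large
  effects its null is honestly not calibrated, and the generator does not
  pretend otherwise.
* **Cohorts**: the discovery phenotype adds $N(0, 1-h^2)$ noise; the
  target liability does likewise and is thresholded at
  $\Phi^{-1}(1 - K)$, with cases and controls sampled from a population
  pool. Default prevalence 0.2 (a lifetime-risk-scale figure for common
  late-life disease) keeps the pool, and hence runtime and memory, at
  desk scale.
* **GWAS**: per-SNP simple linear regression, or logistic regression via
  a Newton solver vectorized across SNPs (agreeing with `glm` to 5
  decimals in the tests). A quarter of target records are emitted with
  swapped allele orientation so harmonization is exercised end to end.

Defaults are one study design, fixed once: discovery $n = 2000$;
target 887 cases / 1493 controls (a 4× scale-down of a 3548/5972 study);
$h^2 = 0.13$ (discovery) and 0.34 (target liability); `rG_true` $= -0.8$.
The generator does **not** model population stratification, relatedness,
imputation error, MAF-dependent architecture, X-linked SNPs, or
long-range LD; passing tests therefore demonstrate correctness of the
statistical machinery under the stated model, not robustness to those
real-data complications (stratification in particular would require
covariate use throughout).

## Problem sizes in the tests

Validation simulations are sized for precision sufficient to detect real
errors while keeping a full serial run short: univariate recovery at
$n = 800$, $m = 1200$ (20 replicates per $h^2$, replicate SE ≈ 0.06);
bivariate recovery at $n = 500+500$, $m = 800$ (mean-of-20 SE ≈ 0.03 for
$r_G$); LRT null calibration over 200 replicates at $n = 200+200$;
clumping versus a brute-force oracle on 100 panels of 200 SNPs;
summary-versus-individual agreement over 50 studies spanning
`rG_true` $\in [-0.9, 0.9]$; and 25 end-to-end runs each at
`rG_true` $= -0.8$ and 0. The end-to-end GREML arm uses a genotyped
subsample of 450 per cohort, mirroring the common situation where only a
validation subset has individual-level data.

## Known limitations

* Per-SNP GWAS in the generator ignores covariates; the harmonizer
  handles biallelic autosomal SNPs only (no indels, no multi-allelics,
  no liftover).
* The joint-effect SE, as discussed, understates null variance for
  oligogenic architectures.
* AI-REML SEs are asymptotic; at a few hundred individuals per cohort
  they are large and the $r_G$ point estimate frequently sits on the
  ±1 boundary — the boundary flag and the LRT, not the Wald ratio, are
  the quantities to read.
* The greedy relatedness pruner is not guaranteed minimal on adversarial
  relatedness graphs (it is on cliques, the common case).
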