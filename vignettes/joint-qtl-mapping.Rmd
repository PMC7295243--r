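---
title: "Joint Bayesian mapping of molecular QTLs: model, inference and design choices"
author: "jqtl authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint Bayesian mapping of molecular QTLs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jqtl)
```

# The problem

Molecular QTL studies regress thousands of molecular trait levels (protein,
transcript or metabolite abundances) on hundreds of thousands of SNP
dosages. The standard practice tests every SNP-trait pair separately and
pays a severe multiplicity price, and it treats each trait as if it carried
no information about the others. In reality molecular traits are strongly
correlated, and single variants often control many traits at once
(pleiotropic "hotspots"). `jqtl` implements a fully multivariate
alternative: one hierarchical sparse regression over *all* SNPs and *all*
traits simultaneously, whose shared parameters let every trait borrow
strength from the rest, together with the calling, replication, annotation,
simulation and benchmarking machinery around it.

# The model

For samples $i = 1,\dots,n$, SNPs $s = 1,\dots,p$ and traits
$t = 1,\dots,q$, with $X$ the $n \times p$ matrix of centered minor-allele
dosages and $y_t$ the centered $t$-th trait,

$$y_t = X \beta_t + \varepsilon_t, \qquad
  \varepsilon_t \sim N_n(0, \tau_t^{-1} I),$$

with a spike-and-slab prior on every effect:

$$\beta_{st} \mid \gamma_{st}, \sigma^2, \tau_t \sim
  \gamma_{st}\, N(0, \sigma^2 \tau_t^{-1}) + (1 - \gamma_{st})\, \delta_0,
  \qquad \gamma_{st} \mid \omega_s \sim \mathrm{Bernoulli}(\omega_s),$$

$$\omega_s \sim \mathrm{Beta}(a_s, b_s), \qquad
  \tau_t \sim \mathrm{Gamma}(\eta_t, \kappa_t), \qquad
  \sigma^{-2} \sim \mathrm{Gamma}(\lambda, \nu).$$

Two parameters are shared across the whole matrix of effects and carry the
joint-modelling benefit:

* $\omega_s$ is the propensity of SNP $s$ to be associated with *any*
  trait. A SNP with several clear associations gets a large posterior
  $\omega_s$, which lowers the evidence threshold for its weaker
  associations; $E(\omega_s \mid y)$ is a direct hotspot score.
* $\sigma$ is the typical size of nonzero effects (modulated per trait by
  the residual scale $\tau_t^{-1/2}$), learned from all effects at once.

The quantity of interest is the posterior probability of inclusion (PPI)
$pr(\gamma_{st} = 1 \mid y)$ for every pair. Genotypes are centered but not
variance-standardized — effects stay on the per-minor-allele scale, which is
what makes the inverse relation between allele frequency and effect size
visible. Traits are centered per column over their observed entries.

## Covariates and missing data

Covariates (age, sex, BMI and similar) are removed from the traits by
least-squares residualization *before* fitting (`residualize_covariates()`);
the mapping model itself has no covariate term and genotypes are left
untouched. Missing trait values are kept as an explicit mask and handled
inside the inference — every inner product and every sample count is
restricted to the trait's observed samples. They are never imputed.
Missing genotypes, by contrast, are mean-imputed per SNP at load time;
dosage matrices are dense by construction after imputation-based
genotyping, and a mean-imputed dosage is the standard, essentially
information-free placeholder.

# Variational inference

The posterior is approximated by coordinate-ascent variational inference
(CAVI) under the factorization

$$q(\beta, \gamma)\, q(\omega)\, q(\tau)\, q(\sigma^{-2}), \qquad
  q(\beta_{st}, \gamma_{st}) =
  g_{st}\, N(\mu_{st}, s^2_{st}) \cdot [\gamma_{st} = 1] +
  (1 - g_{st})\, \delta_0 \cdot [\gamma_{st} = 0].$$

All updates are analytical. One sweep visits every $(\beta_{st},
\gamma_{st})$ block — traits in the outer loop, SNPs in the inner loop, with
running residual vectors — and then performs the conjugate Beta/Gamma
updates of $q(\omega)$, $q(\tau)$ and $q(\sigma^{-2})$. At temperature 1
each sweep provably does not decrease the evidence lower bound (ELBO); the
test suite checks this to $10^{-8}$ on 100 random instances, checks exact
agreement ($10^{-6}$) with the closed-form single-pair posterior, and checks
the fit against full $2^{pq}$ enumeration on tiny instances.

The inner loop is algebraically sequential but executed in SNP blocks of
64: the residual inner products of a block are taken in one BLAS
matrix-vector product and corrected within the block through its Gram
matrix, which reproduces the sequential updates to machine precision (a
pure-R reference sweep in the test suite pins this down to $10^{-9}$).

## Annealing

Strong linkage disequilibrium makes the posterior multimodal: two highly
correlated SNPs explain the same signal, and a greedy optimizer commits to
whichever it visits first. `jqtl` therefore anneals: sweeps follow a ladder
of `n_temperatures = 50` geometrically spaced temperatures from
`T_init = 20` down to exactly 1 (one sweep per hot rung, then
convergence-checked sweeps at temperature 1, stopping when the absolute
change of the objective falls below `tol = 1e-3`).

The tempered objective weights the *data* term:

$$F_T = \tfrac{1}{T}\, E_q[\log p(y \mid \cdot)] +
        E_q[\log p(\text{parameters})] + H(q),$$

so hot sweeps stay close to the sparse prior and associations switch on
strongest-first as the data weight grows. We also implemented the more
common entropy-weighted variant ($E_q[\log p] + T\,H(q)$, i.e. all updates
raised to $1/T$) and found it unusable at this temperature range: the
tempered Beta/Gamma feedback loop drives *every* pair's inclusion
probability to 1 during the hot rungs, and the state then collapses to the
all-null mode while cooling. Likelihood tempering has no such dense phase;
at $T = 1$ both variants coincide with the untempered ELBO, so convergence
behavior and all temperature-1 oracles are unaffected by this choice.

Annealing measurably improves LD discrimination: in the packaged test, a
causal SNP duplicated at $r^2 \approx 0.98$ and placed *after* its copy in
sweep order is identified correctly in 8/20 seeds by the annealed fit and
0/20 by the temperature-1 fit (which always credits the first-visited
copy).

## Initialization and numerical guards

* $g_{st}$ starts at the prior mean $a_s/(a_s + b_s)$, $\mu_{st}$ at 0.
* $q(\tau_t)$ starts at its null-model posterior
  $\mathrm{Gamma}(\eta_t + n_t/2,\ \kappa_t + \|y_t\|^2/2)$ and
  $q(\sigma^{-2})$ at $\mathrm{Gamma}(\lambda + 1, \nu + 1)$. Starting at
  the diffuse priors themselves would put
  $E[\log \tau_t] \approx \psi(0.01) \approx -100$ into the inclusion
  log-odds, which makes the all-null configuration absorbing. CAVI permits
  any valid starting factor, so we start at these data-informed values.
* Inclusion log-odds are clipped at $\pm 35$ before the logistic transform;
  Beta/Gamma expectations are computed in the log domain via `digamma`.
* Two SNPs with identical columns receive identical slab variances and are
  otherwise distinguished only by sweep order (the earlier column absorbs
  the shared signal); no extra symmetry breaking is performed.
* The optimizer is fully deterministic given its inputs.

## Hyperparameter defaults

* $\eta_t = \kappa_t = 10^{-2}$ and $\lambda = \nu = 10^{-2}$: diffuse on
  the residual precisions and on $\sigma^{-2}$.
* $a_s, b_s$ from `elicit_sparsity_prior()`: $a_s = 1$ and
  $b_s = 1/m - 1$ where
  $m = \frac{\text{expected active SNPs}}{p} \cdot
  \frac{\text{expected traits per active SNP}}{q}$ is the prior mean of
  $\omega_s$; the default expectation is `min(50, p/10)` active SNPs
  hitting one trait each. With $a_s = 1$ the prior is monotone decreasing,
  so $\omega_s$ rarely exceeds twice its mean; the exact elicitation
  convention is a documented package choice, and the fits are insensitive
  to it within an order of magnitude because the data term dominates.
* `tol = 1e-3` on the absolute change of the objective between consecutive
  temperature-1 sweeps.

# Calling, replication and annotation

`bayesian_fdr_select()` turns PPIs into discoveries: pairs are ranked by
PPI and the FDR of the top-$k$ set is estimated by the mean of $1 -
\text{PPI}$ over the set; the largest set with estimate at or below the
level (default 5%) is returned. The estimate is exact under the model, so
its calibration is a real test of the whole stack — on matched-prior
simulations the realized false-discovery proportion at nominal 5% averages
about 2% (the acceptance suite requires $\le$ 10%).

`replicate_hits()` implements the two-stage design: every discovered pair
is re-tested in an independent cohort by OLS with a two-sided Wald test,
Benjamini–Hochberg correction is applied across the discovered pairs only,
and pairs at adjusted $p \le 0.05$ are flagged validated. The comparator is
plain OLS because simulated cohorts are unrelated; a mixed-model
relatedness correction would be a no-op in expectation here.

`merge_loci()` chains, per trait and chromosome, position-sorted hits into
loci while consecutive hits are at most 1 Mb apart (inclusive at exactly
1 Mb, a documented convention); the sentinel is the member with the largest
PPI, ties broken by smaller position. `classify_cis_trans()` calls a locus
*cis* when the sentinel lies within $\pm$1 Mb (again inclusive) of the gene
body encoding the trait, *trans* otherwise. `resampling_enrichment()`
provides seeded add-one empirical p-values,
$(1 + \#\{\text{resamples} \ge \text{observed}\})/(B + 1)$.

# The synthetic-data generator

`simulate_qtl_study()` emulates a proteomic-QTL discovery cohort with full
ground truth. Defaults are the study conditions the package is benchmarked
under: $n = 376$ samples, $p = 20{,}900$ SNPs, $q = 133$ traits,
associations between 20 causal SNPs and 25 controlled traits.

* **Genotypes.** Per SNP a MAF is drawn uniformly on $[0.05, 0.5]$. Two
  independent latent haplotype layers come from a block-AR(1) Gaussian
  (blocks of 20 SNPs, autocorrelation 0.85 by default) and are thresholded
  at the MAF quantile; their sum is the dosage. Genotype frequencies
  satisfy Hardy–Weinberg equilibrium by construction, and adjacent-SNP
  $r^2$ increases with the autocorrelation. Note the thresholding
  attenuates correlation (the tetrachoric effect): latent 0.85 yields
  dosage $r^2$ around 0.3–0.5 depending on MAF, similar to a tag-SNP panel
  after light pruning. SNPs sit every 5 kb on one chromosome.
* **Causal pattern.** Each causal SNP's degree of pleiotropy is
  `max(1, round(25 * Beta(1, 4)))` — right-skewed, so only a few SNPs are
  hotspots; the skew parameters are configurable since only the shape is
  scientifically constrained. Traits left unassigned are repaired by
  giving them one random causal SNP.
* **Traits.** Per association the variance explained (PVE) is drawn from
  Beta(2, 5), favouring small effects; per trait the PVEs are rescaled
  proportionally if their sum exceeds the 35% cap (proportional rescaling
  preserves the Beta shape up to scale). Effects are
  $\beta_{st} = \pm\sqrt{\text{PVE}_{st} / \mathrm{Var}(x_s)}$ with
  independent Rademacher signs, which makes rarer alleles carry larger
  effects. Residuals are drawn with block-equicorrelated structure (blocks
  of 15 traits at correlation 0.4 by default, or any user correlation
  matrix) and variances that bring each trait's total variance to 1, so
  PVE keeps its literal meaning.

What the generator does *not* emulate: real LD fine structure (haplotype
blocks of variable length, allele-frequency-dependent LD), population
structure and relatedness, non-Gaussian trait distributions, batch and
assay effects, and genotype uncertainty. Passing benchmarks on these data
therefore demonstrate the statistical machinery under a correctly specified
model with realistic dimensions — not robustness to the full messiness of a
real cohort.

# Benchmarking

`univariate_scan()` is the single-pair comparator: per-pair OLS with Wald
p-values, vectorized but numerically identical to `lm()` per pair.
Selection performance is summarized by the truncated standardized partial
AUC (`standardized_pauc()`): the trapezoidal ROC area over false-positive
rates $[0, f]$, rescaled (McClish) to $[\tfrac12, 1]$ so chance is 0.5 and
perfection 1. The default truncation $f = 0.05$ reflects the
low-false-positive regime a QTL study operates in; benchmarks report
$f \in \{0.01, 0.05, 0.1\}$ since the choice is a convention. With
$f = 1$ the statistic is exactly the Mann–Whitney AUC (tested to
$10^{-10}$).

`run_power_benchmark()` holds the genotype panel fixed and redraws the
pattern, effects and traits each replicate; scores are PPIs for the joint
fit and $1 - p$ for the scan; means come with 95% normal-approximation
confidence intervals across replicates. `batch_split_experiment()`
partitions the traits into random batches of size $q_0$, fits each batch
independently, pools the PPIs and evaluates the full-range standardized
AUC: $q_0 = 1$ is a per-trait spike-and-slab with no sharing, $q_0 = q$
the fully joint fit, and the increase in between isolates the value of
joint modelling.

## Problem sizes used by the packaged checks

The acceptance-level tests and `scripts/acceptance.R` run, as the package's
own choice of desk-scale study: the power benchmark at $p = 2000$,
$q = 133$, $n = 376$ with 10 replicates; the batch-split study at the same
dimensions with 20 replicates over $q_0 \in \{1, 8, 33, 133\}$; pleiotropy
recovery at the full $p = 20{,}900$ design; and FDR calibration over 20
seeds at $p = 400$, $q = 20$. Typical outcomes: joint pAUC$_{0.05}$ about
0.99 vs univariate about 0.96 with non-overlapping CIs, a significant
batch-split gain, hotspot-degree Spearman (over causal SNPs) above 0.9, and
realized FDR near 2%.

On the pleiotropy figure: the Spearman correlation between
$E(\omega_s \mid y)$ and the true per-SNP association count is computed
over the causal SNPs. Across all $p$ SNPs the statistic is bounded near
$\sqrt{k/p}$ even for a perfect ranking, because the overwhelming majority
of SNPs are tied at degree zero; the restricted correlation is the
informative quantity.

# Known limitations

* No random-effect correction for population structure or relatedness;
  genotype principal components can be supplied as covariates.
* The Bayesian FDR estimate is exact only under the model; heavy-tailed
  traits or unmodelled confounding will erode its calibration.
* Variational posteriors underestimate uncertainty; PPIs are sharper than
  MCMC would give, which is acceptable for ranking and FDR selection but
  not for interval estimation of effects.
* Annealing is a heuristic against multimodality, not a guarantee: with
  $r^2 \to 1$ the data cannot distinguish duplicated SNPs and the model
  concentrates on one member of the pair by sweep order.
* The univariate comparator is OLS, appropriate for unrelated simulated
  cohorts but not a substitute for a mixed model on related samples.
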