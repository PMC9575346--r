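---
title: "Differential gene interaction networks from SNP data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential gene interaction networks from SNP data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jdinac)
```

# The problem

Case–control genetic studies usually ask whether individual variants shift
disease risk. This package asks a complementary question: which *pairs of
genes* change their statistical dependence between cases and controls? A
pair whose joint distribution of genetic burden differs between the two
groups — even when neither gene is marginally associated — marks a candidate
interaction, and genes that accumulate many such differential pairs
("hubs") are candidate drivers. The approach operates entirely on SNP
genotypes: no expression data are needed.

# From genotypes to gene scores

Genotypes are coded additively: 0, 1 or 2 copies of the minor (alternate)
allele per SNP and sample. Each gene's *risk score* for a sample is the
arithmetic mean of the additive codes over the SNPs mapped to that gene, so
scores lie in $[0, 2]$. Averaging borrows strength across the small number
of genotyped SNPs per gene and yields a quasi-continuous variable suitable
for density estimation. Two missing-data policies are offered:
`per_snp_mean_impute` (default) replaces a missing genotype by that SNP's
sample mean before averaging — this keeps the sample count constant, which
the downstream density estimation needs — while `drop_from_mean` averages
each sample over its observed SNPs only.

# The differential-network model

Let $S_i$ denote the score of gene $i$ and $Y \in \{0, 1\}$ case status.
For every unordered pair $(i, j)$ the group-conditional joint densities

$$ (S_i, S_j) \mid Y = 1 \sim f^1_{ij}, \qquad
   (S_i, S_j) \mid Y = 0 \sim f^0_{ij} $$

are estimated non-parametrically, and their log ratio becomes a feature in
a penalized logistic regression with covariate adjustment:

$$ \operatorname{logit} P(Y = 1)
   = \alpha_0 + \sum_t \alpha_t Z_t
   + \sum_{i < j} \beta_{ij}
     \ln \frac{f^1_{ij}(S_i, S_j)}{f^0_{ij}(S_i, S_j)},
   \qquad \sum_{i<j} |\beta_{ij}| \le c . $$

A non-zero $\beta_{ij}$ says that the pair's dependence structure carries
case/control information beyond all other pairs and the covariates. The
feature is on the log-likelihood-ratio scale: if the estimated densities
were exact, the Bayes-optimal coefficient of a truly differential pair
would be 1 and that of a null pair 0.

Because the same data cannot both estimate the densities and fit the
regression without optimism, each of $T$ rounds splits the samples into
stratified halves: densities are fitted per class on one half, features are
computed for the other half and the lasso-logistic model is fitted there;
the halves then swap roles. A pair counts as *selected* in a round if its
coefficient is non-zero in either direction, so the importance score

$$ \omega_{ij} = \sum_{t = 1}^{T} I(\hat\beta_{ij, t} \ne 0), \qquad
   0 \le \omega_{ij} \le T $$

counts the rounds that selected the pair. Edges with
$\omega_{ij} \ge$ `min_score` form the differential network; genes with at
least `min_hub_degree` (default 4) retained neighbours are hubs.

## Numerical and design choices

* **Density estimation.** Bivariate product-Gaussian kernels with
  per-dimension Silverman rule-of-thumb bandwidths (`stats::bw.nrd0`),
  fitted separately per class. A zero-variance dimension falls back to a
  small fixed bandwidth with a warning. Both densities are floored at
  `density_floor` ($10^{-10}$) before the log, so features are finite
  everywhere and exactly 0 far outside both supports.
* **Penalty selection.** The lasso path is cross-validated on binomial
  deviance with stratified folds (default 5). The penalty is chosen by the
  one-standard-error rule — the sparsest model within one SE of the CV
  minimum. We calibrated this choice on synthetic null cohorts: the CV
  *minimum* selects pure-noise pairs in roughly half of all splits, which
  floods $\omega$ with counts and manufactures spurious hubs, whereas the
  one-SE rule keeps null selection rare while planted edges at moderate
  effect sizes still accumulate high $\omega$.
* **No feature standardization.** `standardize = FALSE` in the lasso: all
  features already share the log-likelihood-ratio scale, and a larger
  feature variance is itself evidence of differential dependence.
  Standardizing would inflate near-constant noise features onto the same
  footing and measurably destabilizes selection.
* **Covariates are unpenalized** (default): they are adjustments, not
  selection candidates.
* **Defaults** $T = 20$, split fraction $0.5$, `min_score`
  $= \lceil T/4 \rceil$. The importance scale is only meaningful relative
  to $T$; both knobs are exposed everywhere.
* **Determinism.** All randomness (splits, folds, simulation draws) flows
  from one master seed through named sub-streams; split membership is tied
  to sample identifiers, so results are invariant to the order of samples
  in the input.
* **Tie-breaking.** Edge ranking uses $\omega$ descending, then
  lexicographic pair order.

# Per-SNP association and edge validation

Two lighter procedures complement the network. `snpLogistic` fits the
standard per-allele logistic model for a single SNP with covariates,
reporting the odds ratio with Wald 95% interval
($\exp(\hat\beta \pm 1.96\,\mathrm{SE})$) and Wald p-value — the
conventional presentation of hub-gene SNP association tables. On a
saturated binary predictor the OR reduces exactly to the cross-product
ratio $ad/bc$, which the test suite exploits as a closed-form oracle.

`validateEdge` tests one pair on an independent cohort without the lasso:
one stratified half estimates the two class densities, the other half
yields the single log density-ratio feature, and an unpenalized logistic
regression returns the Wald p-value of the feature coefficient. Simulation
shows the procedure is close to nominal under the null (type-I error
$\approx 0.05$, near-uniform p-values) and has high power for a dependence
difference of $\Delta\rho = 0.6$ at a few thousand samples per group.

# The synthetic cohort generator

Because the motivating cohort type (hospital-based breast-cancer
case–control genotyping of candidate obesity genes) is typically private,
the package ships a generator that plants known truth:

* **Marginals.** Each SNP's latent standard normal is discretized at the
  Hardy–Weinberg thresholds, giving genotype probabilities
  $(1-q)^2, 2q(1-q), q^2$ for minor allele frequency $q$. MAFs default to
  an even spread over $[0.1, 0.5]$.
* **Dependence.** A Gaussian copula: SNPs of one gene share latent
  correlation 0.3 (a stand-in for local LD), and the two genes of a planted
  edge are coupled through a uniform cross-block correlation *calibrated so
  that the latent gene-mean correlation equals the planted* $\rho$. The
  calibration matters: imposing $\rho$ directly on the SNP-level
  cross-block over-amplifies at the gene level by $m/(1 + (m-1)w)$ and
  renders moderate designs indefinite. The planted $\rho$ therefore
  describes gene-level dependence, which is what the truth network records
  and what the downstream method sees. Positive definiteness is verified by
  Cholesky and violations are reported with the offending edge set.
* **Hub designs.** A star of four leaves mutually independent at
  $\rho = 0.6$ is not a valid correlation structure (it needs
  $\sum \rho^2 < 1$), so the default hub design couples the leaves at a
  weak 0.2 in *both* groups. Those leaf–leaf pairs are recorded as
  non-differential — they carry no case/control signal and double as
  correlated-background decoys.
* **Covariates.** One BMI-like normal covariate (control mean 24.01, SD
  3.11; case 24.36, SD 3.46) and one menopause-like Bernoulli covariate
  (prevalence 0.281 vs 0.335), matching the baseline table of the
  motivating cohort type; cohort sizes default to 953 cases / 963 controls
  over 20 genes with 5 SNPs each.
* **Limitations.** No realistic LD maps, population structure, genotyping
  error or X-chromosome handling; observed genotype correlations are
  attenuated relative to the latent $\rho$ by the ordinal discretization
  (roughly 20–30% here). Passing tests on these cohorts demonstrates
  correct and calibrated machinery, not performance on any real
  population.

# Problem sizes used in the checks

The simulation-based checks run the full estimator at $p = 10$ genes
(45 pairs), 3 SNPs per gene, 400 cases / 400 controls and $T = 10$ splits
— five to six master seeds per scenario in the unit suite, twenty in the
reproduction script (planted-edge recovery, null control, hub recovery);
edge-validation calibration uses 200 null replicates at 500/500 and power
20 replicates at 2000/1750. These sizes give each
Monte-Carlo rate a resolution adequate for the pass bounds while keeping a
full run in the minutes range on a single core.

# Known limitations

* Only pairwise interactions are modelled; higher-order structure projects
  onto pairs.
* $\omega$ is a stability count, not a p-value; its null distribution
  depends on $T$, $n$ and $p$, which is why the package ships calibration
  machinery instead of universal thresholds. Because all $T$ splits reuse
  the same cohort, $\omega$ measures split-consistency *within* that
  cohort: a chance cohort-level dependence difference can hold a null
  pair's $\omega$ high, which is exactly why retained edges should be
  re-tested on independent data with `validateEdge`.
* Correlated differential edges shadow one another in the lasso: among the
  edges of a hub, the same strong subset tends to win in every split, so a
  weaker sibling edge can stay below the edge threshold and hub recovery
  is the most seed-variable property of the estimator.
* With very few samples per class (tens), CV-based penalty selection
  becomes erratic; the implementation refuses classes below 10 samples.
* KDE bandwidths assume roughly unimodal score distributions; genes whose
  scores concentrate on one or two values trigger the degenerate-bandwidth
  fallback.
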