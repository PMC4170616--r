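---
title: "Methods: DNA-repair prognostic signatures, interaction networks and ensemble ranking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DNA-repair prognostic signatures, interaction networks and ensemble ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliosig)
```

# Scope and model overview

`gliosig` implements a survival-genomics workflow for building a
DNA-repair prognostic gene signature from two independent high-grade
glioma expression cohorts, plus the two machine-learning analyses that
surround it: perceptron-based gene-interaction network inference and an
ensemble cross-validated gene ranking. Every stage operates on plain
probes-by-samples log2 expression matrices with matched clinical tables
(overall survival time in days, death indicator, treatment flags).

The pipeline's stages are:

1. **Optimal-cutpoint screening.** Each panel probe is dichotomized at
   the expression value maximizing the two-group log-rank statistic,
   scanned over every unique value between the 10th and 90th percentile.
   The per-probe p-values are corrected for the cutpoint optimization
   (Miller–Siegmund minimum-p correction) and then adjusted across the
   panel by Benjamini–Hochberg; probes significant in *both* cohorts
   with the *same* direction of association form the consensus set.
2. **Multivariate reduction.** The consensus probes, coded 0/1 at their
   cutpoints, enter a multivariable Cox model per cohort. All probes with
   Wald p above the threshold are removed in one batch and the model is
   refit, until only significant probes remain; the per-cohort survivors
   are intersected and both cohorts refit once on the common set.
3. **Prognostic index (PI).** For each retained gene,
   $\beta_{\text{combined}} = \tfrac{1}{2}(\beta_{\text{test}} +
   \beta_{\text{validation}})$, the mean of the two cohorts'
   log hazard ratios. A patient's score is
   $\mathrm{PI} = \sum_g \mathbf{1}(x_g > c_g)\,\beta_g$ over the model
   genes. Patients are cut into $k = 3$ score tertiles (ties kept
   together), relabelled 1..k by ascending median score, and the percent
   survival at 1, 2 and 3 years (from the per-group Kaplan–Meier life
   tables) is interpolated by the unique quadratic through the three
   (median score, percent survival) points — an exact fit, since three
   points determine three coefficients. Predictions are clamped to
   [0, 100] and flagged when the score lies outside the anchor range.
4. **Interaction networks.** A one-hidden-layer perceptron (2 hidden
   nodes, sigmoid transfer, batch backpropagation with momentum) first
   ranks candidate probes by single-input prediction of a target gene's
   median-split status over Monte-Carlo 60/20/20 resamples; the
   top-ranked probes then enter pairwise inference, where for each target
   the remaining probes are joint inputs and the influence of input $i$
   on target $j$ is the connection-weight product
   $\sum_h W_{hi} v_h$ averaged over resamples. Positive weights are
   excitatory, negative inhibitory. After keeping the strongest edges,
   nodes with at least 5 retained incident edges are hubs, ranked by the
   sum of |weight| over their incident edges.
5. **Ensemble gene ranking.** Within leave-one-out cross-validation,
   differentially expressed genes are selected on each training fold only
   (empirical-Bayes moderated t, p < 0.05), four learners (linear SVM,
   random forest, kNN, nearest shrunken centroid) are tuned by grid
   search in an inner CV, and the left-out sample is predicted by
   majority vote. Genes are ranked by how often they are selected across
   folds.
6. **IHC H-scores.** $H = 1\,p_1 + 2\,p_2 + 3\,p_3$ from the percentages
   of cells at weak/moderate/strong staining (range 0–300), replicate
   specimens averaged, and fixed published thresholds (APE1 160, NBN 85,
   nuclear PTEN 50, cytoplasmic PTEN 10, PMS2 120; strictly greater is
   "high") feeding the same survival comparisons.

The reference five-gene glioblastoma model (APE1, PMS2, NBN, MGMT, PTEN
with combined coefficients −0.524, 0.498, −0.620, 0.391, −0.439) ships
as `reference_pi_model()`; attainable scores under it lie in
[−1.583, 0.889], the sums of its negative and positive coefficients.

# Statistical building blocks and their defaults

**Survival primitives.** Kaplan–Meier estimation, the log-rank test and
Cox partial-likelihood fitting are delegated to the `survival` package
behind thin validated wrappers (`km_estimate()`, `logrank_test()`,
`cox_fit()`). Ties are handled by Efron's method by default — more
accurate than Breslow, which remains available as `ties = "breslow"` for
parity with older software defaults; the difference only matters with
heavily tied event times. Confidence intervals and tests are Wald
(`exp(beta ± 1.96 se)`), matching the HR (95% CI) reporting convention.
A hand-rolled $O(n)$ two-group log-rank statistic is used internally by
the cutpoint scan purely for speed; the test suite verifies it against
`survival::survdiff` on random data.

**Cutpoint scanning.** Candidates are the unique observed values inside
the `quantile_bounds` band (default 10th–90th percentile); "high" means
strictly above the cut. Ties among equally maximal candidates break
toward the value closest to the cohort median, favouring balanced
groups. Because the selected p-value is a minimum over candidates, the
uncorrected p is optimistic; `optimal_cutpoint()` therefore also reports
the Miller–Siegmund corrected p
$p_{\mathrm{cor}} = \varphi(z)\,(z - 1/z)\,
\log\!\frac{q_{hi}(1-q_{lo})}{(1-q_{hi})\,q_{lo}} + 4\varphi(z)/z$,
$z = \Phi^{-1}(1 - p_{\min}/2)$. The panel screen feeds the *corrected*
p into the BH adjustment by default (`p_source = "minp"`): in null
simulations, BH on the uncorrected minimum p declared roughly 10% of
null probes significant, violating the false-discovery guarantee the
screen is meant to provide, whereas the corrected p restores it. The
uncorrected route is kept behind `p_source = "raw"`.

**Moderated t.** Implemented in closed form: per-gene pooled variances
$s^2$ with $d = n - 2$ df are shrunk to
$\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)$, with $(d_0, s_0^2)$
estimated by moment-matching $\log s^2$ against a scaled-F prior
(Newton inversion of the trigamma function); the statistic has $d + d_0$
df. $d_0$ estimates are capped at $10^6$ ("effectively infinite"
shrinkage). The implementation agrees with `limma::eBayes` to machine
precision on shared inputs, which the test suite asserts; `d0 = 0`
recovers the ordinary pooled t exactly.

**Perceptron.** Architecture and training follow the screening protocol:
2 hidden nodes, sigmoid hidden and output activations, learning rate
0.5, momentum 0.1, weights updated once per epoch with the summed
(batch-accumulated) error gradient, uniform(−0.5, 0.5) seeded
initialization. Epoch budget and early stopping are implementation
choices: 500 epochs maximum, stopping after 25 epochs without test-split
improvement and restoring the best-epoch weights. Inputs are
standardized, which also makes rankings invariant to affine rescaling of
a candidate probe. The interaction stage predicts *continuous* targets:
each target probe is min-max rescaled into [0.1, 0.9] so the sigmoid
output node can represent it without saturating at the bounds (the 0/1
median coding is used only in the screening stage). Backpropagation
gradients are verified against central finite differences to below
1e−6 in the test suite. Gradient descent on batch error surfaces can
stall in local minima on contrived problems (the XOR check passes with
raised momentum); on the smooth single- and multi-probe regressions used
here the defaults converge reliably.

**Ensemble tuning grids.** Margin penalty ∈ {0.01, 0.1, 1, 10}; forest
sizes {100, 300}; k ∈ {1, 3, 5, 7}; nearest-shrunken-centroid shrinkage
over 10 quantiles of the unshrunken standardized centroid offsets; inner
CV 5-fold. These are deliberately small, standard grids; all are
adjustable through `learner_specs()`. The nearest-shrunken-centroid
learner is implemented in the package (soft-thresholded standardized
centroids, posterior classification) as no implementation is available
among the package's dependencies. Folds with no gene at p < 0.05 fall
back to the top 10 genes by |t|, and the fallback count is reported. A
2–2 vote tie goes to the class with higher mean predicted score, then
lexicographic — the rule is exposed as `majority_vote()` and tested
directly. Selection and tuning see only the training portion of each
fold; the suite asserts that flipping the left-out sample's label
changes neither that fold's gene list nor its prediction.

# The synthetic-cohort generator

`cohort_spec()`/`generate_cohort()` produce cohorts with exactly the
structure the analyses assume, so every stage can be validated with
known truth and no external downloads:

- **Expression marginals** are Gaussian on the log2 scale, mean 8, sd 1 —
  the familiar scale of RMA-summarized microarray intensities.
- **Planted prognostic effects** act through a proportional-hazards model
  on the probe's cohort-median high/low indicator: the linear predictor
  is $\sum \beta_p \mathbf{1}(x_p > \mathrm{med}_p)$, matching how the
  screening and index stages consume expression. Event times come from
  an exponential (default, rate 1/365 per day) or Weibull baseline
  scaled by $e^{\mathrm{lp}}$.
- **Censoring** is independent exponential; its rate is solved
  numerically (from the drawn death times) to achieve the requested
  censoring fraction, which lands within ±0.05 of the target at
  n ≥ 1000.
- **Hub blocks** wire target probes to a hub through linear, quadratic or
  sigmoid links plus Gaussian noise, with the signed coupling recorded as
  truth for network-inference validation.
- **The DE block** shifts a probe set by a constant in a Bernoulli-drawn
  class, for classifier validation.

Generation is fully deterministic given the spec (the seed is applied in
a local RNG scope, leaving the caller's stream untouched). What the
generator deliberately does *not* emulate: probe-level chemistry, batch
effects, normalization artefacts, correlated censoring, non-proportional
hazards, or the heavy-tailed dependence structure of real tumour
expression. Passing tests therefore demonstrate that the algorithms
recover the structures they target under their own model assumptions —
not that those assumptions hold in any particular real cohort.

# Numerical choices and degenerate inputs

- Cox convergence and step-halving follow `survival::coxph`; singular
  (collinear) fits raise a warning naming the offending covariates, and
  constant covariates or more covariates than events are rejected
  upfront.
- `optimal_cutpoint()` requires ≥ 10 samples, non-constant expression,
  at least one event, and a split leaving both groups nonempty;
  `screen_probes()` records per-probe failures and skips them with a
  warning rather than aborting the panel.
- Risk grouping requires ≥ k distinct scores; quantile bins that
  collapse under ties are an error rather than a silent regrouping. The
  alternative `mode = "logrank"` grouping exhaustively searches the two
  interior cut positions maximizing the ordered-group statistic — the
  default remains quantile tertiles, since the grouping rule used for
  the published index is not recorded and tertiles are the simplest
  reproducible choice.
- The year-survival quadratic refuses duplicate group medians (the
  interpolation matrix would be singular). Collinear anchors simply give
  a zero quadratic coefficient.
- H-score records must sum to 100 ± 0.5 (pathologist estimates are
  rounded); violations are errors, not silent renormalizations.
- All Monte-Carlo resampling (perceptron splits, forests, inner CV
  folds) is seeded from a single base seed through a deterministic
  stream-splitting helper, making every stage bit-reproducible.

# Problem sizes used by the tests and analysis scripts

The package's validation runs at "desk scale", chosen so the full suite
completes in a few minutes while leaving each property comfortably
detectable: screening cohorts of 80–500 samples and 20–300 probes with a
100-probe panel; Cox/log-rank calibration at n = 500 over 50 seeds and
2,000 null replicates; perceptron screening with 20 candidates and 10
resamples over 10 seeds; interaction inference over 6–13 probes;
ensemble LOOCV at n = 20–60 samples and 30–200 genes. Full-size runs
(tens of thousands of probes, hundreds of samples, 50 resamples, top-200
interaction panels) are configuration changes, not code changes — the
relevant knobs are `cohort_spec()`, `mlp_config()` and
`learner_specs()`.

# Known limitations

- The interaction-inference influence measure is the connection-weight
  product; it is isolated behind `infer_pairwise_interactions()` so a
  perturbation-based measure could be swapped in, but none is provided.
- No stratified or time-varying Cox models; treatment-stratified
  analyses re-use fixed cutpoints within strata rather than refitting.
- The multivariate models contain genes only — no adjustment for age or
  performance status.
- Probe-to-gene mapping is taken from the supplied panel table; no
  annotation service is consulted.
- The published year-survival curve equations for the reference model
  are not re-derivable without the original cohorts; the package fits
  such curves to whatever cohort it is given instead.
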