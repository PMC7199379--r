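---
title: "Trend-correlation screening for case-control genotype data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trend-correlation screening for case-control genotype data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trendscreen)
```

## The problem

A genome-wide association study yields a binary case-control status $Y$
and an enormous matrix of categorical features: for each of $p$ SNPs
(often $p$ in the hundreds of thousands) an additive genotype code
$X_j \in \{0, 1, 2\}$ counting copies of the minor allele, with
$p \gg n$. Joint models cannot be fit at this dimension, so the standard
strategy is *sure independence screening*: rank all features by a cheap
marginal utility, keep the top $d$, and only then fit a joint model.
A good screening utility for this data type must handle ordinal
categorical features and a binary response without assuming a regression
model, and must be fast enough to evaluate hundreds of thousands of
times.

## The trend correlation

`trendscreen`'s marginal utility is the **trend correlation**. Assign
each level $k$ of feature $X_j$ a numeric score $v_k^{(j)}$ that
respects the level order (by default the genotype code itself), and let
$p_{km}$ denote the joint probability of the cell $(X_j = k, Y = m)$,
$m \in \{0, 1\}$. Then

$$
\varrho_j \;=\;
\frac{\bigl|\sum_{k}\sum_{m}(v_k^{(j)} - \mathbb{E}X_j)(m - \mathbb{E}Y)\,p_{km}\bigr|}
     {\sigma_{X_j}\,\sigma_Y},
$$

the absolute correlation between the scored feature and the response
computed from the contingency distribution. It lies in $[0, 1]$, is
invariant to affine rescaling of the scores, and vanishes when feature
and response are independent. The sample version $\hat\varrho_j$
replaces the cells by sample proportions (`tc_sample()`); we use the
plug-in (divide-by-$n$) variance convention throughout, under which
$\hat\varrho_j$ is *exactly* the absolute sample Pearson correlation
between the scored feature vector and the 0/1 response. That algebraic
identity is both the fast computational route (one matrix product for a
whole genotype matrix in `tc_screen()`) and the independent oracle the
test-suite checks the contingency-table route against. Screening keeps
the top $d$ features (`select_top()`) or all features whose score
exceeds a threshold $c$ (`select_by_threshold()`).

Two caveats worth stating. First, for features with three or more
levels, a zero *trend* correlation does not logically force cell-level
independence (a distribution can have exactly cancelling monotone and
anti-monotone structure); what holds, and what the tests assert, is that
independence forces a zero statistic and that any genuine trend
component yields a positive one. Second, a constant feature has no
defined correlation: `tc_sample()` treats it as an error, while the
matrix-level `tc_screen()` assigns score 0 with a warning, so one
degenerate SNP cannot abort a genome scan.

### Choosing the budget d

`rule_of_thumb_d()` implements the conventional cutoff
$d = [\,n^{4/5}/\log(n^{4/5})\,]$ (natural logarithm, rounded half-up;
this rounding is what reproduces the standard worked values, e.g.
$d = 20$ at $n = 272$ and $3d = 351$ at $n = 4099$ — floor would give 19
and 348). Multipliers $2d$, $3d$ are commonly used when the screened set
feeds a joint model that can afford more candidates.

## Iterative screening and linkage disequilibrium

Marginal screening has two well-known failure modes under linkage
disequilibrium (LD): a locus whose effect is cancelled by correlated
loci with opposing effects becomes marginally invisible, and a null SNP
merely correlated with a causal one can outrank it. `itc_screen()`
addresses both by alternating screening with **residual projection**:

1. take the top $d_1$ features by trend correlation;
2. regress all remaining (scored) features on the selected ones plus an
   intercept and replace them by their residuals,
   $X_r = (I - P_{[1, X_{\hat S}]})\,X_{\hat S^c}$;
3. rank the residual columns and take the next $d_2$; repeat until
   $d = d_1 + \cdots + d_k$ features are selected.

Residual columns are continuous, so the step-2 utility is the
continuous-input limit of the trend correlation — the absolute Pearson
correlation (`residual_utility()`). This is a deliberate design choice:
the categorical statistic is undefined on residuals, and on scored data
the two coincide anyway. Two numerical choices matter here. An
intercept column is always appended before projection, so residualizing
always removes means. And the projector is built from a singular value
decomposition with singular values below $10^{-10}$ of the largest
treated as zero, so perfectly collinear selected SNPs — routine under
strong LD — cannot break the step; a feature exactly collinear with the
selected set has a zero residual and simply can never be selected again.
The default schedule is $d_1 = 6$, $k = 2$, $d_2 = d - d_1$, fully
configurable via `schedule=`.

## Comparator screeners

Three benchmark marginal utilities are included behind the same
interface, all computed from the per-feature level/class frequency
table rather than raw vectors:

* `dc_screen()` — sample distance correlation (V-statistic form).
  Because a scored genotype and a binary response take few distinct
  values, the V-statistic collapses to an $O(K^2)$ expression in the
  joint frequencies; the tests verify this fast path against the naive
  $O(n^2)$ double-centering computation to $10^{-10}$.
* `pc_screen()` — Pearson $\chi^2$ of the $K \times 2$ table normalized
  to Cramér's $V^2 = \chi^2 / (n(\min(K,2)-1))$, so features with
  different level counts are on a common $[0,1]$ scale. The literature
  this benchmark descends from does not fix one normalization; Cramér's
  $V^2$ is our documented choice, and reproductions of chi-squared
  screening numbers inherit that ambiguity.
* `mmle_screen()` — the absolute slope of the marginal logistic
  regression of $Y$ on the scored feature, fit by Newton iteration on
  the aggregated level counts (identical to the MLE on raw data, checked
  against `glm()`; max 25 iterations, tolerance $10^{-8}$). Completely
  separated features have an infinite MLE; they are detected from the
  level pattern, capped at $|\beta| = 25$ and flagged, as are
  non-converged fits. The additive (one-slope) coding is the default, in
  line with genotype convention; `coding = "dummy"` fits level dummies
  and scores the largest absolute level coefficient instead.

## Simulation designs and what they emulate

Four generators reproduce standard benchmark designs; each takes a
`seed` and is bit-reproducible given it. Their defaults are the study
conditions under which the published benchmark values were produced, and
the package's evaluation (`run_study()`) reports the three usual
criteria: average minimum model size $|\widehat{\mathcal M}|$ (the mean
over replicates of the smallest ranked prefix covering all causal
features), individual success rates $P_{X_i}$, and the simultaneous
success rate $P_a$, at one or more budgets $d$.

* `gen_sim2()` — response first ($p_y \sim U(0.05, 0.95)$ per
  replicate), ten causal features $\text{Bin}(2, \pi_{y j})$ with a
  fixed probability table, noise $\text{Bin}(2, \pi_j)$ with
  $\pi_j \sim U(0.05, 0.95)$ drawn per feature per replicate.
* `gen_sim3()` — causal features are discretizations of latent
  $N(y_i, 1)$ variables at fixed per-feature cutoffs: a pure trend
  association with no generating regression model.
* `gen_sim4()` — features uniform on $\{0,1,2\}$, response logistic in
  level-specific coefficients of five causal features: marginal
  likelihood screening's home turf.
* `gen_ld_gwas()` — the LD benchmark. Latent Gaussians thresholded at
  Hardy–Weinberg quantiles (MAF $\sim U(0.1, 0.5)$), AR(1) blocks of 40
  SNPs ($\rho = 0.6$) for the genome background, and a tight
  exchangeable bin (latent correlation 0.35) containing five consecutive
  causal SNPs with effects $\beta_i \sim N(5Z_i, 1)$, $Z_i = \pm 1$, and
  $N(0,1)$ noise added on the logit. The exchangeable causal bin (rather
  than an AR chain) is deliberate: with AR decay the chain's end loci
  decorrelate and are never masked, while in an exchangeable bin any
  minority-sign locus has its marginal association cancelled by the
  correlated majority — the regime real multi-locus LD traps create,
  where one-step screening needs thousands of features to cover the
  causal set and iterative screening covers it within tens. One term is
  centred relative to the literal textbook form: the genetic score is
  mean-centred on the logit scale so that random sign constellations do
  not drive the case prevalence to 0 or 1 (with random MAFs the
  uncentred form degenerates the response in a large share of
  replicates; the logit noise itself is kept exactly as specified).
  Defaults $n = 272$, $p = 10^4$ keep the confounder-to-budget ratio of
  a realistic scan at desk scale.

Sample sizes used by the shipped tests and the acceptance script are
n = 200, p = 5000 with 500 replicates for the cheap screeners and 100
for distance correlation and marginal likelihood, and 50 replicates of
the LD design; these reproduce the benchmark's bulk statistics (success
rates to about ±0.01) while keeping a full run in minutes.

What passing these tests shows — and what it does not. The generators
share the real data's *types* (ordinal features, binary response, LD
blocks, rare-ish alleles) but not its genuine haplotype structure,
population stratification, genotyping error, or missingness; results on
them validate the statistics and the iterative mechanism, not field
performance. One empirical caution surfaced by the Monte-Carlo work: the
covering model size is extremely heavy-tailed (replicates with a nearly
degenerate class split, which the designs deliberately keep, produce
covering sizes in the thousands), so its *average* is unstable across
master seeds even at 500 replicates, while success rates and
between-method orderings are very stable. Compare screeners on the
rates and the size *distribution*, not on a lone mean.

## The two-stage analysis pipeline

`run_pipeline()` chains the stages of a realistic SNP analysis:

1. **MAF filter** (`maf_filter()`, default threshold 0.1) removes rare
   variants whose contingency tables are too sparse to screen stably.
2. **First-step size selection** (`choose_d1_by_mspe()`): for each
   candidate $d_1$ up to $3\,[n^{4/5}/\log(n^{4/5})]$, repeatedly hold
   out 25% of samples, screen *within the training split only* (no
   selection leakage), fit a joint logistic model on the top $d_1$, and
   record the mean squared prediction error of predicted probabilities
   on the held-out quarter. MSPE is the Brier score — the natural
   squared-error risk for probabilistic binary prediction. The chosen
   $d_1$ is the smallest whose mean MSPE is within one standard
   deviation (across the default 10 repeats, taken at the minimizing
   grid point) of the minimum — the one-standard-error rule, favouring
   the most parsimonious statistically indistinguishable size.
3. **Iterative screening** with schedule $(d_1, d - d_1)$, $k = 2$.
4. **Joint multiple logistic regression** (`joint_logistic_report()`)
   on the selected SNPs: AIC, misclassification at the 0.5 cutoff
   (in-sample, with the out-of-sample analogue available through the CV
   stage), and per-SNP Wald $p$-values; an optional $p$-value cutoff
   refits a reduced model. Complete separation is flagged and, when
   glmnet is available, stabilized by a small ridge penalty.

Inputs can be a plain delimited matrix or PLINK `.raw` additive coding
(`read_genotype()`, with mode imputation or sample dropping for missing
calls — the screening statistics themselves do not accept missing
data). A thin command-line wrapper with `screen`, `itc`, `simulate`,
`evaluate` and `pipeline` subcommands is installed under
`inst/cli/trendscreen`.

## Reproducibility and numerical conventions

* All Monte-Carlo drivers spawn per-replicate seeds from one master
  seed (`run_study(..., seed = )`); the first $R$ replicates of a longer
  run coincide with a shorter run, and co-running additional methods
  never changes a method's results.
* Ties in every ranking break toward the lower feature index; the same
  rule is used by `select_top()`, `min_model_size()` and
  `success_indicators()`, keeping the three mutually consistent.
* Degenerate inputs: constant features score 0 (with a warning) in all
  matrix-level screeners; a constant response is an error everywhere; a
  replicate whose screening fails inside `run_study()` is excluded for
  that method and counted.
* The scored-feature variance obeys Popoviciu's bound
  $\sigma^2 \le (\max v - \min v)^2/4$, which the tests use as a cheap
  sanity invariant on random inputs.

## Known limitations

* Binary responses only; the trend correlation extends to multi-class
  ordinal responses, but that extension is not implemented.
* No data-driven stopping rule for the iterative process: $d$ is
  pre-specified, as in the screening literature this follows.
* No p-values on screening scores; screening is a ranking device, and
  inference happens in the joint-model stage.
* The LD generator emulates block correlation, not real haplotypes; see
  the simulation section for what that implies.
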