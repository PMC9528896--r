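---
title: "Scoring discourse coherence and mapping its cortical topography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring discourse coherence and mapping its cortical topography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glocoh)
library(dplyr)
```

## The problem

When people speak about a topic for an extended period, their speech
naturally fluctuates in *global coherence* — how closely each utterance
relates to the expected topic. Neuroimaging work links these fluctuations to
activity in default-mode regions (which appear to update mental models of
the discourse when it wanders) and to semantic-control regions. `glocoh`
implements the full analysis chain for this kind of study: quantifying
coherence from timed transcripts, turning it into fMRI parametric
modulators, estimating voxelwise coherence effects, and relating those
effects to a principal connectivity gradient and to networks of interest.
Because raw speech and scanner data cannot ship with a package, a
synthetic-data generator reproduces the statistical structure the analysis
assumes, with known ground truth at every stage.

## The coherence model

Words are embedded by latent semantic analysis: a term–document count
matrix from a training corpus is weighted (log-entropy by default: local
weight $\log_2(1+tf_{ij})$, global weight
$1 + \sum_j p_{ij}\log_2 p_{ij} / \log_2 n$), and a rank-$k$ truncated SVD
$(W \approx U_k D_k V_k^{\top})$ yields word vectors $U_k D_k$. A passage is
the unweighted mean of its word vectors; similarity is the cosine. The
default $k = 100$ follows common LSA practice; the sum and the mean give
identical cosines, and the mean is kept for scale stability. The SVD sign
ambiguity is fixed by making the largest-magnitude element of each right
singular vector positive, so rebuilt spaces are bitwise identical.

Global coherence of a response is computed against a *prototype*: the mean
of whole-response vectors for the same prompt, excluding the target response
(leave-one-out), or built from a separate reference cohort for comprehension
passages. A 20-word moving window (the current word plus the 19 preceding
it) is vectorized and compared with the prototype; the first 19 words carry
no value, since no growing-window variant is defined. Cosines are reported
raw in $[-1, 1]$; text cosines are empirically nonnegative in practice, and
a `clamp_negative` flag floors them at 0 for users who want the
conventional 0–1 range. Per-word values are averaged within 5-s bins of the
50-s speech period (half-open intervals, 10 bins); a bin with no scored
words is flagged missing rather than zeroed.

```{r coherence-demo}
model <- make_topic_model(n_topics = 3, vocab_size = 300, seed = 1)
space <- build_space(generate_corpus(model, seed = 2), k = 40)
cohort <- generate_cohort(model, n_participants = 4, n_prompts = 2, seed = 3)
scored <- score_transcripts(cohort$transcripts, space, mode = "leave_one_out")
bin_coherence(scored) |> head(5)
```

## From coherence to the BOLD model

Discourse periods are modelled as ten concatenated 5-s blocks. Each block
carries two parametric modulators: its mean coherence and its time index
(1–10). Both are mean-centered within each run *before* convolution, so a
modulator at the run mean contributes nothing; a missing bin imputes to the
run mean, i.e. exactly zero after centering, a neutral choice that cannot
drive the modulator effect. Modulators are *not* serially orthogonalized:
coherence and time are correlated in natural speech, and the GLM estimates
them jointly so each beta reflects unique variance. Regressors are boxcars
convolved with the canonical double-gamma HRF
($\mathrm{dgamma}(t; 6, 1) - \mathrm{dgamma}(t; 16, 1)/6$, the SPM
parameterization) at 0.1-s microtime resolution, sampled at the TR
(default 1.7 s). Each run contributes an intercept and a discrete-cosine
drift basis with a 128-s high-pass cutoff. Estimation is plain OLS per
voxel; no AR(1) prewhitening is applied — a documented simplification that
matters little here because inference happens across participants.

## Gradient topography

The principal connectivity gradient (a fixed per-voxel input, never derived
by this package) orders cortex from unimodal sensorimotor to multimodal
default-mode territory. Two analyses relate coherence betas to it:

* **Voxelwise correlation** of the group-mean coherence-beta map with
  gradient position (optionally within a semantic-region mask). The
  t-transform p-value is reported but labelled descriptive, because voxels
  are spatially autocorrelated.
* **Decile mixed models**: voxels are rank-split into 10 equal bins (ties
  broken by voxel id, sizes differing by at most one, lower bins taking the
  extra voxel), the per-participant mean beta per bin is modelled as
  `mean_beta ~ bin + bin²` with the bin index centered (mean 5.5 for 10
  bins; the quadratic uses the centered index, making the quadratic
  coefficient invariant to the centering constant). Random effects are a
  by-participant intercept and linear slope by default; a switch adds a
  random quadratic slope or drops to pooled OLS. Fits use REML via lme4;
  the linear-versus-quadratic comparison refits both fixed structures by ML
  and reports a likelihood-ratio test.

Fixed-effect p-values use the normal approximation to the t statistic
rather than Satterthwaite degrees of freedom. At cohort sizes of 20+
participants the two differ negligibly, and the likelihood-ratio comparison
carries the model-selection question; this is a deliberate, documented
divergence from analyses that report Satterthwaite-corrected p-values.

## Networks of interest

Raw default-mode (DMN), semantic-control (SCN), and multiple-demand (MDN)
masks overlap. They are resolved into disjoint sets by removing SCN voxels
from DMN and MDN, then removing remaining DMN–MDN overlap from the DMN; the
operation is idempotent and audited. Within each resolved mask, each
participant's analysis uses the top 20% of voxels (`ceiling` of the count;
ties broken by voxel id) on that participant's and task's
discourse-minus-baseline contrast, so the coherence effect is read from the
voxels most engaged by the task. Cell means enter a 2 × 3
(task × network) repeated-measures ANOVA with participant as the blocking
factor, plain degrees of freedom (no sphericity correction), and paired
post hoc t tests Holm-adjusted within each task's family of three
comparisons. The individual-differences analysis regresses per-participant
activation maps on mean-centered participant mean coherence and counts
suprathreshold voxels at uncorrected p < 0.001 (voxel counts only — no
random-field correction).

## What the generator emulates

The synthetic cohort is built to have the statistical signatures the
analysis relies on, at the study's conditions:

* **Topics**: each prompt's topic is a Dirichlet-derived word distribution
  with a dedicated high-weight word subset (concentration 0.02 keeps topics
  well separated).
* **Timing**: word onsets follow a homogeneous renewal process (exponential
  gaps). At 2.56 words/s over 50 s this yields ~128 words per response, and
  words per 5-s segment show no time trend by construction.
* **Topic drift**: each word is off-topic with probability
  $\pi(t) = \text{drift} + \text{ramp}\,t/T$ (defaults 0.1 and 1.2, clipped
  to [0, 1]). Off-topic words come from a *response-specific* sparse
  tangent distribution (symmetric Dirichlet, concentration 0.01, excluding
  the target topic's core words). The per-response tangent is the load-bearing
  design choice: real speakers wander onto idiosyncratic tangents, so
  off-topic content does not align across speakers and averages out of
  leave-one-out prototypes. With a single shared distractor distribution,
  off-topic content becomes part of the "typical response" and measured
  coherence stops declining. Under the defaults the mean per-response
  correlation between binned coherence and bin position is about −0.9.
* **Individual differences**: participants differ in baseline drift
  (heterogeneity 0.5, giving drifts of roughly 0.1–0.6), so true drift and
  measured participant mean coherence are strongly rank-correlated.
* **Comprehension**: passages come in a high- and a low-coherence tier
  (drift 0.1 versus 0.45) and are scored against fixed prototypes from a
  30-response reference cohort; the tier means preserve their ordering.
* **BOLD**: $Y = B X^{\top} + \varepsilon$ with optional AR(1) noise. The
  coherence sensitivity of voxel $v$ is
  $b(v) = a + b_{\text{lin}} g(v) + b_{\text{quad}} (g(v)-0.5)^2$ along the
  gradient $g$; defaults $a = 0.5$, $b_{\text{lin}} = -1.5$ make the
  sensorimotor end respond positively and the multimodal end negatively to
  coherence. Network masks are carved from gradient-ranked voxel pools
  (DMN high, SCN mid-high, MDN mid) with exactly realized overlap counts,
  so mask resolution is exercised.

What the generator does **not** emulate: real lexical statistics and syntax,
spatially smooth or physiological BOLD noise, head motion, and
preprocessing artifacts. Passing tests therefore demonstrate that the
estimators recover the structure they assume, not that the pipeline is
robust to everything real data contain.

## Numerical choices and degenerate inputs

* Ranks and ties: every rank-based operation (decile bins, top-voxel
  selection) breaks ties by voxel id, so results are permutation-stable.
* Out-of-vocabulary tokens are skipped and counted; a window with no usable
  tokens is missing with a warning; a response that is entirely
  out-of-vocabulary is an error distinct from numerical failure.
* Zero-norm vectors are errors, never NaN cosines.
* All-equal ANOVA tables report F = 0 and p = 1 (the 0/0 mean-square ratio
  is resolved by checking the effect sum of squares against the data
  scale); constant paired differences yield t = 0 or ±Inf explicitly.
* Singular random-effects fits warn with the boundary variance estimates
  rather than failing or staying silent.
* Problem sizes: the reference pipeline configuration simulates 8
  participants, 4 production prompts, 2 comprehension topics, 300 voxels,
  and one run per task; calibration checks use 25-participant bin tables
  with 200 replicates and 100-seed sign checks. These sizes were chosen so
  the full suite runs comfortably on a laptop while keeping every estimator
  in its asymptotically well-behaved regime.

## Worked example

```{r pipeline, warning = FALSE}
res <- run_pipeline(pipeline_config(seed = 1))
s <- summary(res)
s$gradient_correlations
s$network_anova
```

The production coherence-beta map correlates negatively with the gradient
(the multimodal end activates more when speech is less coherent), the mixed
model recovers a negative linear bin trend, and the network ANOVA separates
DMN, SCN, and MDN in the order fixed by the simulated truth.

## Known limitations

* The LSA space is built from the synthetic corpus; absolute coherence
  values depend on the space and are not comparable to values computed in
  any published space.
* OLS without prewhitening understates single-participant precision when
  noise is autocorrelated; group-level conclusions are unaffected in the
  simulated setting but the limitation matters for real single-subject use.
* Voxelwise correlation p-values ignore spatial autocorrelation and are
  descriptive only.
* The random-effects structure for the quadratic term is linear-slope-only
  by default; `random = "intercept_slope_quad"` exposes the alternative.
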