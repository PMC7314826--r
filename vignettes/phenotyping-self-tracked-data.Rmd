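---
title: "Mixed-membership phenotyping of self-tracked symptom data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed-membership phenotyping of self-tracked symptom data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endotype)
```

## The problem

Endometriosis is a chronic condition with no accepted clinical subtyping.
Self-tracking apps produce a different kind of evidence than clinic visits:
each participant accumulates, at their own pace, categorical answers to a
fixed set of questions ("Where is the pain?", "Describe your period flow.",
"Medications/hormones taken.", ...), each question with its own closed answer
vocabulary. The data are heterogeneous in two ways that matter: tracking
volume varies across participants by orders of magnitude, and the answer
spaces of different questions have very different sizes (3 to 64 in the
default 13-question schema shipped with the package, 202 answers in total).

`endotype` models such a corpus with a *multi-modal mixed-membership model*.
Each participant is a mixture over `K` latent phenotypes shared by the
cohort; each phenotype owns one categorical answer distribution **per
question**. Writing `theta_d` for participant `d`'s phenotype proportions
and `phi_k^q` for phenotype `k`'s answer distribution on question `q`, the
generative process is

* `theta_d ~ Dirichlet(alpha · 1_K)` per participant,
* for each tracked observation on question `q`:
  `z ~ Categorical(theta_d)`, `answer ~ Categorical(phi_z^q)`.

This is latent Dirichlet allocation with one emission vocabulary per
question. The per-question structure is the point: a vanilla LDA baseline
that concatenates all vocabularies into one 202-answer space (built with
`concatenate_view()`, fitted with `fit_baseline()`) must spend probability
mass deciding *which question* an observation answers, which the study
design already fixes. Held-out comparisons between the two quantify what
the multi-modal structure buys.

## Inference

`fit_phenotypes()` runs collapsed Gibbs sampling: `theta` and `phi` are
integrated out analytically and only the per-token phenotype labels are
sampled, each from

```
P(z = k | rest) ∝ (c_dk + alpha) · (c_kqv + beta) / (c_kq + V_q · beta)
```

with all counts excluding the current token and `V_q` the vocabulary size
of the token's own question. Collapsed Gibbs is the canonical sampler for
this model family, and — unlike variational approximations — admits exact
small-instance oracles: on corpora with a handful of tokens the full
posterior over assignment vectors can be enumerated, and the test suite
checks the sampler's empirical distribution against that enumeration to
total variation below 0.02.

Numerical and reproducibility choices:

* Token visit order is fixed (participant, then schema question order, then
  vocabulary order); the model is exchangeable over tokens, so any fixed
  order is valid and a fixed one makes runs reproducible from the seed.
* Posterior estimates average the count-ratio statistics
  `(c_kqv + beta)/(c_kq + V_q beta)` and `(c_dk + alpha)/(N_d + K alpha)`
  over retained post-burn-in sweeps (defaults: 2000 sweeps, 1000 burn-in,
  thinning 10) rather than using one final state — standard variance
  reduction.
* All argmax ties anywhere in the package break to the lowest index.
* Participants with zero observations are retained in the corpus but
  excluded from fits (they carry no likelihood); the exclusion is messaged.
* Only symmetric scalar `alpha`, `beta` are supported, matching the
  hyperparameter grid the evaluation harness searches.

The sampler and the held-out estimator are implemented in C++ (Rcpp), as
the topic-modelling packages this one resembles do; both draw exclusively
from R's RNG stream, so `set.seed()` governs every result.

## Held-out evaluation

Computing the marginal likelihood of an unseen participant under a fitted
model is intractable beyond small documents (it sums over `K^N` assignment
vectors — `exact_doc_loglik()` does exactly that, and serves as the test
oracle). `left_to_right_loglik()` implements the sequential particle
estimator: tokens are laid out in the canonical order; at each position
every particle resamples the earlier assignments in one pass, records the
predictive probability of the current token under its own question's
`phi^q` (phenotype-proportion counts are shared across questions within
the document), and samples the new assignment. The default is 20
particles; estimates are consistent as the particle count grows, and the
suite checks agreement with the enumeration oracle on short documents.

`cross_validate()` reproduces the evaluation design: hyperparameters
varied over `K ∈ {2, 3, 4, 5}` and `alpha, beta ∈ {0.1, 0.01, 0.001}` (36
cells), each scored by summed test-participant log-likelihood under
repeated seeded 80/20 participant-level splits. "10-fold cross-validation"
with an "80/20 ratio" cannot be one literal partition, so the harness runs
10 Monte-Carlo resplits, honouring both numbers; splits and scoring seeds
are shared across cells and between the proposed and baseline models, so
comparisons are paired. The result keeps one row per grid cell (both
models' means and standard deviations side by side); `write_eval_tsv()`
emits the long per-model layout.

## Phenotype summaries

* `hard_assign()` takes the argmax membership with a "clear" flag above
  0.9 — the threshold used when reporting how sharply participants separate.
* `top_answers()` ranks a phenotype's posterior answers for one question
  (default depth 10, the heatmap convention).
* `cloud_weights()` implements the answer-cloud rule: keep the minimal
  descending prefix of the posterior covering 80% of the mass
  (`>=` at the boundary), renormalise to 1. Conditioning on a fixed mass
  fraction makes weights comparable across questions whose vocabularies
  differ by an order of magnitude. Rendering is presentation-layer
  (`plot_answer_cloud()` draws the weights as bars); the tested artifact
  is the numeric table.
* `volume_correlation()` is the engagement diagnostic: would the learned
  memberships merely reflect how much someone tracks? It reports Spearman
  correlations (with permutation p-values) of each phenotype against days
  tracked, observations tracked, and observations per day (zero-day
  participants excluded from the ratio rather than imputed). Two
  correlations are reported per cell, and they answer different questions.
  The hard-membership indicator (`rho_membership`) tests the substantive
  claim of volume-independent assignments. The raw posterior probability
  (`rho_probability`) carries a smoothing artifact: for a participant whose
  tokens never visit phenotype `k`, the smoothed probability is exactly
  `alpha/(N_d + K alpha)` — strictly decreasing in tracking volume — so its
  rank correlation with observation counts is negative by arithmetic even
  under perfect decoupling. The membership statistic is the one the
  decoupling property is asserted on. Spearman with permutation p-values
  was chosen because the volume distributions are heavy-tailed.

## Validation layers

`select_review_panel()` reproduces the expert-review design: among
participants with at least 30 active days and more than 100 observations,
8 per phenotype with a membership probability above 0.95, plus 8 from the
pooled "uncertain" stratum, sampled without replacement — 40 in all at
`K = 4`. "Uncertain" is implemented as: top-two membership mass at least
0.80 while the maximum is at most 0.95 (the natural reading of "at least
80% of the assignment probability shared by more than one subtype" on a
worked case like `theta = (0.5, 0.4, 0.05, 0.05)`); the uncertain members
are drawn from the pooled stratum because no per-phenotype breakdown of
uncertain cases is defined.

`confusion()` and `purity()` compare model and expert groupings: purity is
the sum over model clusters of the largest overlap with any reference
class, divided by the number of participants. This definition — per-model-
row column maxima — reproduces all six published agreement values from the
shipped confusion-matrix fixtures (0.9/0.8 severe, 0.775/0.7 mild,
0.6/0.55 full four-way), which is what fixes it among the competing purity
conventions. `collapse_to_binary()` builds the severe/mild one-vs-rest
views from the four-way table, preserving the participant count.

`association_screen()` links phenotypes to survey covariates (WERF-EPHect
style): participants enter with their maximum-posterior phenotype;
categorical covariates get the uncorrected Pearson chi-square test of
independence (expected counts below 5 raise a flag, not an alternative
test), continuous covariates the tie-corrected Kruskal–Wallis H-test.
Missing cells are dropped per covariate; degenerate covariates are skipped
with a warning. No multiple-testing correction is applied by default —
matching how the associations are reported at the 0.05 level — and a
Benjamini–Hochberg option sits behind `adjust = "BH"`. Both tests delegate
to the base R implementations and are cross-checked in the suite against
hand-rolled formula oracles to 1e-10.

## The synthetic cohort generator

Every downstream stage is exercised on corpora drawn from the model's own
generative process by `sample_corpus()`, which returns the corpus together
with its ground truth (`phi_true`, `theta_true`, token labels, dominant
phenotypes). Choices, and what they emulate:

* **Volume.** Per-question observation counts are negative binomial with
  means set to the published per-question tracking averages (31 pain
  location, 42 difficult activities, 15 medications, ...) and a small
  dispersion (`size = 0.25`) so max/mean ratios reach the ~100x spread
  seen in real tracking data. Days tracked are drawn independently
  (negative binomial, mean 35). With `volume_phenotype_coupling = TRUE`
  the means double for participants dominated by phenotype 1 — the
  positive control for the engagement diagnostic.
* **Membership sparsity.** `alpha_true = 0.01` by default: about 94% of
  Dirichlet(0.01) draws at `K = 4` put over 0.9 of their mass on one
  phenotype, matching a cohort in which most participants express one
  dominant phenotype — the regime the sparse selected model
  (`alpha = beta = 0.001`) is meant for. The `alpha_true -> 0` limit
  degenerates cleanly to one-hot memberships.
* **Separation.** The default `beta_true = 0.1` draws moderately sparse
  answer distributions; the "well-separated" setting `beta_true = 0.01`
  gives nearly disjoint phenotypes and is what the parameter-recovery
  tests use, since recovery there is information-limited rather than
  identifiability-limited.
* **Surveys.** `sample_survey()` draws covariates whose distributions
  shift with the *dominant* phenotype — categorical levels tilted toward a
  phenotype-specific level by `effect_size`, continuous values shifted by
  `effect_size · sd` per phenotype step — with explicit missingness. Zero
  effect size yields exchangeable covariates for type-I-error checks.

What the generator deliberately does **not** emulate: real demographic or
questionnaire marginals, day-level clustering of observations within a
participant (tokens are exchangeable, matching the model's own
assumption), temporal or menstrual-cycle structure, and the real answer
strings (vocabularies are placeholders of the correct sizes; the true
vocabularies are not public). Passing tests therefore demonstrate that the
pipeline recovers the structure this model family can express — not that
real self-tracking data satisfies the model's assumptions.

## Problem sizes used by the test suite

The suite favours instances with known answers over large ones: sampler
exactness is checked on a 5-token corpus (32 enumerable assignment
vectors, 50,000 recorded sweeps); estimator agreement on 5-token documents
with 200 particles and 50 replicates; parameter recovery on a
well-separated cohort of 500 participants (~50,000 tokens); the
model-vs-baseline direction on five cohorts of 300 participants with
3-fold splits; the decoupling diagnostic at 1000 participants; test
calibration on 1500 null replicates. The review-panel check runs the full
pipeline at 800 participants.

## Known limitations

* Single-chain inference by default; label switching across restarts is
  handled by explicit alignment (`match_phenotypes()`, exact over the `K!`
  permutations) rather than by identifiability constraints.
* The left-to-right estimator is consistent but not unbiased on the log
  scale at finite particle counts; with very ambiguous documents the
  log-scale Jensen bias can exceed its Monte-Carlo error.
* No asymmetric priors, no hyperparameter optimisation, no variational or
  online inference, no temporal modelling.
* `corpus_summary()` attributes a participant's single `days_tracked`
  value to every question they answered at least once; the interchange
  format carries no per-question day counts.
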