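---
title: "Methods: models, protocols and design choices in eldermicro"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, protocols and design choices in eldermicro}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eldermicro)
```

eldermicro implements the statistical pipeline used to relate longitudinal
gut metagenomes of nursing-home elders to dementia status (no dementia /
Alzheimer's disease / other dementia) and to an intestinal epithelial
readout, normalized P-glycoprotein (P-gp) expression induced in T84
monolayers by stool supernatants. This vignette documents the models, the
protocols, the synthetic cohort generator that makes all of it testable
without patient data, and the design decisions taken where more than one
reasonable choice existed.

## The synthetic cohort generator

No public accession exists for the motivating cohort, so every analysis
stage is exercised on cohorts from `generate_cohort()`, which emulates the
study design rather than any particular dataset:

* **Design.** 108 subjects split 51/24/33 across NO/AD/OTHER by default,
  each contributing 1–4 monthly stool samples (drawn uniformly), for about
  300 samples.
* **Composition.** Species log-abundances are logistic-normal:
  `log a = baseline + class shift + subject intercept + sample noise`,
  closed by a softmax, then resampled multinomially at `read_depth` reads
  and renormalized. The multinomial stage is what creates sampling zeros,
  and the zero fraction falls as depth grows — the same mechanism the
  zero-inflated abundance model downstream assumes. `read_depth = Inf`
  gives exact proportions for degenerate-case tests. A Dirichlet
  alternative was rejected because it offers no subject-level covariance
  control. The subject intercept is drawn per subject × species: a scalar
  per subject would cancel in the softmax.
* **Defaults.** `subject_sd = 1.0`, `species_sd = 0.5` (log scale) give
  within-subject correlation of composition comparable to repeated stool
  samples; `baseline_sd = 1.5` produces the uneven rank-abundance curve
  typical of gut communities; `read_depth = 1e5` is a realistic
  species-level profile depth and leaves rare species with sampling zeros.
  These were fixed once when the generator was written.
* **Clinical covariates** are drawn with class-dependent means and clamped
  to their instrument ranges: frailty (CSHA 1–7) means 2.9/3.4/3.7 and
  malnutrition (MNA category 1–3) means 1.7/2.3/2.3 for NO/AD/OTHER,
  antipsychotic use concentrated in the dementia classes, proton-pump
  inhibitors more common in NO, and CDR centred near 0.25/2.12/1.88 —
  the directions and magnitudes of the motivating cohort's clinical table.
* **P-gp** is linear in log driver abundances:
  `pgp = b0 + sum_t w_t log(x_t + 1e-6) + noise`. The offset 1e-6 is about
  half the smallest nonzero proportion at default depth. Because the panel
  requires strictly positive values, rare negative draws are clamped at
  1e-6 with a warning; the default intercept keeps this from occurring.
* **Butyrate genes** are weighted sums of designated producer-taxon
  abundances with lognormal noise, grouped into the four major butyrate
  biosynthetic pathways. The shipped pathway labels are generic; real
  analyses supply their own gene → pathway map, whose membership the
  package deliberately does not assert.

What the generator does *not* emulate: taxonomic misassignment, read-level
artefacts, compositional correlation beyond what softmax closure induces,
longitudinal drift within subject (months are exchangeable), and any
relationship between clinical covariates and composition. Passing
recovery tests on these cohorts therefore demonstrates that the estimators
find what they are defined to find under the stated model — not that the
model captures every feature of real stool metagenomes.

## Beta diversity and PERMANOVA

`jaccard_matrix()` uses presence/absence with `presence_threshold = 0`
(any nonzero abundance counts as present); the threshold is exposed
because profilers differ in their noise floors. `permanova()` implements
the one-factor pseudo-F on squared distances with the add-one permutation
p-value. Free permutation of sample labels is the default; because the
cohort has repeated measures, a stricter subject-block scheme
(`strata = subject_id`) permutes class labels at the subject level and is
documented as the conservative option. Degenerate all-zero distance
matrices return F = 0, p = 1 with a warning instead of erroring so batch
simulation runs survive. The pseudo-F is cross-checked against
`vegan::adonis2` in the test suite; the permutation p-value is validated
against exhaustive enumeration on a 6-sample toy.

The t-SNE wrapper (`embed_tsne()`) is an exact (non-Barnes-Hut)
implementation with perplexity calibrated by bisection, early exaggeration
and momentum descent. No R t-SNE implementation ships in the package's
dependency set, and the embedding is visualization-only: no inferential
claim attaches to the coordinates, and tests only assert determinism,
finiteness and gross cluster separation. Default perplexity 30 is capped
at (n−1)/3; an explicitly supplied perplexity ≥ n−1 errors.

## The zero-inflated beta mixed model

`zib_glmm()` is the package's central model: per-sample genus proportion
`y` is zero with probability `pi0` (logit-linear, intercept-only by
default) and otherwise Beta-distributed with mean `mu` (logit link) and
precision `phi` (constant), with a subject random intercept in the mean
linear predictor only — the simplest structure consistent with "subject as
random effect". The marginal likelihood integrates the intercept per
subject by *adaptive* Gauss–Hermite quadrature (default order 15): the
integrand is recentred at its conditional mode (damped Newton) and scaled
by its curvature. Zero observations factor out of the integral because the
zero-inflation submodel does not involve the random effect.

Numerical choices:

* Gradients use Fisher's identity (posterior-expected complete-data
  score) on the same quadrature nodes; the observed information for Wald
  standard errors is obtained by central differences of that gradient.
  At low quadrature orders the objective and this gradient differ at the
  order of the quadrature error, which can make `nlminb` report false
  convergence; the fit is accepted when the scaled gradient norm is small,
  and `converged` additionally requires the final log-likelihood not to
  fall below its initialization.
* Initialization: logit-least-squares on the nonzero observations for
  `beta`, the empirical zero fraction for `pi0`, `sigma_u = 0.5`.
* Proportions exactly 1 (possible after genus aggregation) are squeezed by
  `y(N−1)/N + 0.5/N`; the beta support is open at 1 and zero inflation
  handles only the 0 boundary. An all-zero response leaves the mean model
  unidentified and is returned flagged rather than fitted.
* Rank-deficient designs are rejected up front.

The quadrature is validated against brute-force trapezoid integration
(1e5 nodes over ±10 sigma) to 1e-6, and whole fits are cross-checked
against an independent TMB-based implementation of the same model in the
test suite.

`screen_genera()` aggregates species to genera (summing proportions,
pooling unmapped species into "unclassified"), filters at 0.1% mean
relative abundance (computed across all samples before fitting), and fits
the model per genus with dementia class (NO reference), age category,
frailty, malnutrition and four medication flags as fixed effects. Raw
Wald p-values at 0.05 are reported — mirroring the screen this package
reimplements, which applied no multiplicity correction — with a
Benjamini–Hochberg column appended for users who want it. Non-converged
genera are listed in diagnostics and never enter the significant set.
Whether the original screen's precision was covariate-dependent is not
documented anywhere; constant precision was chosen.

## Random-forest stability selection

`stability_selection()` implements the repeated-measures consensus
protocol: for each seed, `n_trials` trials each draw one sample per
subject at random (removing within-subject dependence), fit a forest of
`n_trees` trees, and record unscaled permutation importance (mean decrease
in accuracy, the classic Breiman definition; the scaled variant is
deliberately not the default since the protocol averages importances).
Importance is averaged over the seed's trials, features are ranked (ties
broken lexicographically for determinism), and a feature's rank frequency
is the fraction of seeds placing it in the top `top_k`. Features at
rank frequency ≥ 0.90 form the consensus set. The field protocol is 100
seeds × 30 trials × 3000 trees with `top_k = 30`; tests and examples use a
reduced 20 × 10 × 500 preset, which the recovery experiments show is
already stable for planted effects of 1.0 on the log scale.

Two ambiguities were resolved explicitly: ranking uses the seed-averaged
importance (not per-trial ranks), and the out-of-bag error curve comes
from the all-sample forest of each trial, while leave-one-subject-out
accuracy is computed separately (optionally, once per seed) — running the
LOO loop inside every trial would cost one forest per subject per trial
and adds nothing to the consensus set. Clinical covariates can be offered
to the forest alongside species (`include_clinical`), as done for the
AD-vs-NO contrast.

## P-gp analyses

`compare_pgp_groups()` applies Kruskal–Wallis across classes with pairwise
Mann–Whitney (BH-corrected) — the expression ratios are small-sample and
non-normal, so rank tests were chosen; the specific test is not named in
the motivating work.

`compare_restricted_vs_full()` fits `rf_regress_pgp()` (per-seed OOB MSE,
permutation importance, MSE-vs-trees curves) on a restricted taxon set and
on all taxa with shared seeds, and applies a one-sample t test to the
per-seed paired MSE differences (restricted − full). Two points deserve
emphasis:

* The test is **one-sided by default** (alternative: restricted worse).
  The claim under test is sufficiency — the restricted, disease-
  discriminating taxa predict P-gp no worse than the full community. In
  practice the restricted model is often slightly *better*, because the
  dropped features are the uninformative ones whose presence dilutes the
  forest; a two-sided test rejects in that direction too, despite it
  supporting sufficiency. `alternative = "two.sided"` restores the
  symmetric test.
* With many paired seeds the t test is sensitive to any dataset-level
  difference between the two models, because per-seed differences are
  correlated through the single dataset. Its "p" should be read as a
  decision rule within the protocol, not a calibrated error rate over
  datasets.

`positive_importance_taxa()` flags taxa with strictly positive mean
permutation importance and assigns direction (induce/repress) from the
sign of the Spearman correlation with P-gp. Positive importance is a noisy
selector for truly null taxa — their importance is near zero with either
sign — so interpretation should lean on the magnitude gap between selected
drivers and the rest, which is orders of magnitude on planted data. MRP2
values, when present, are summarized descriptively only; no model is
attached to them.

## Butyrate gene statistics

Genes are analyzed on `log(x + pseudocount)` with the pseudocount set to
half the gene's smallest nonzero value (no transform is documented in the
motivating work; this one is standard for positive abundance data with
zeros). `lmm_gene_contrast()` fits, per gene, a linear mixed model with
the class contrast as fixed effect and a subject random intercept by
maximum likelihood (lme4), with Wald p-values; the ML log-likelihood is
checked against the closed-form marginal normal likelihood in the tests.
`correlate_genes_pgp()` uses Spearman correlation with average ranks for
ties, flagging constant genes. Pathway grouping is a plain sum of member
genes. Raw p-values are reported with a BH column, as in the genus screen.

## Problem sizes used in tests and the acceptance script

Simulation-based checks use cohort sizes chosen to make the planted
effects comfortably estimable while keeping the full suite quick to run:
differential-abundance recovery at 50 subjects/class × 3 samples with 36
species in 12 genera over 20 replicates; stability selection at 40
subjects/class with 60 species under the reduced 20 × 10 × 500 protocol;
sufficiency testing at 40 subjects/class, 40 species, 50 seeds × 500
trees over 20 replicates; PERMANOVA size at 200 null replicates. Wald
interval calibration is assessed at 30 subjects/class × 2 samples over 40
replicates (the wider acceptance band [0.85, 1] reflects the binomial
noise of 40 replicates). The quadrature order is reduced from 15 to 7 in
the large simulation loops; the adaptive recentring makes the order-7 rule
accurate to well below the simulation noise there.

## Known limitations

* Intercept-only zero inflation by default; covariate-dependent zero
  models are available (`zi_formula`) but untested against planted truth.
* The ZIB model treats precision as constant; heteroskedastic precision
  would need a different fitter.
* Compositional effects: planted log-scale shifts are recovered as
  logit-scale contrasts after softmax closure; single-taxon effect sizes
  are therefore not numerically equal to the planted deltas, and the
  package makes no compositional (log-ratio) correction, matching the
  analysis it reimplements.
* The t-SNE implementation is exact and O(n^2) per iteration; it is meant
  for cohort-sized inputs (hundreds of samples), not atlases.
* Free-permutation PERMANOVA treats repeated samples as exchangeable;
  use `strata` for the conservative subject-level test.
* Stability selection controls stability against *resampling* noise (which
  samples represent each subject, forest randomness), not dataset-level
  false consensus: on a single cohort with strong inter-individual
  variation, species that spuriously separate the realized subject groups
  do so in every seed, and a null cohort can yield a sizeable consensus
  set (observed: 17 of 60 species at chance-level OOB error). Consensus
  membership should therefore be read jointly with importance magnitudes
  and the OOB error, not as a false-discovery guarantee.
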