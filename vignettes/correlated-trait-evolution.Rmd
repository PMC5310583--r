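---
title: "Testing correlated evolution of two binary traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing correlated evolution of two binary traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corrtrait)
```

## The question and the model

Do two binary characters evolve together? The motivating application asks
whether conspicuous (bright) iris colour in passerine birds evolved in
concert with cavity nesting, or with coordinated parental care — traits
plausibly linked through gaze-based signalling. corrtrait implements the
standard maximum-likelihood machinery for this question: the trait pair is a
single four-state character `(0,0), (0,1), (1,0), (1,1)` evolving as a
continuous-time Markov chain along a rooted, fully resolved phylogeny.

Two generators are compared. The *dependent* model has eight free rates
`q12, q13, q21, q24, q31, q34, q42, q43` (1-based state indices): each
trait's gain and loss rates may differ with the current state of the other
trait. The entries connecting `(0,0)` with `(1,1)` and `(0,1)` with `(1,0)`
are structural zeros — the traits never change simultaneously; correlated
evolution appears as *sequential* substitutions whose rates depend on
context. The *independent* model is the nested four-rate special case with
`q13 = q24`, `q31 = q42`, `q12 = q34`, `q21 = q43`; its generator is exactly
the Kronecker sum of the two single-trait 2-state generators, so its paired
log-likelihood equals the sum of the two Mk2 log-likelihoods (a property the
test suite checks to 1e-8 — it exercises every index of the four-state
construction at once).

Likelihoods are computed by Felsenstein's pruning algorithm (post-order
partial likelihoods propagated through `exp(Q t)` per branch) in a small
compiled core, with per-node rescaling so trees of thousands of tips do not
underflow. Transition probabilities use scaling-and-squaring on the
generator, cached per unique branch length; an eigendecomposition serves
only as an independent oracle in the tests.

The comparison is a likelihood-ratio test: `2 * (LL_dep - LL_indep)`
referred to chi-squared with 4 degrees of freedom. Single-constraint
*restricted* models (one pair of dependent-model rates forced equal, 7 free
rates, 1 df against the unrestricted model) localize which context effect
carries the signal; `canonical_restrictions()` provides the four standard
contrasts (each trait-change type tied across the other trait's states).

## Tunable parameters

* **Branch lengths** (`branch_mode`): the default sets every branch to 1
  (`set_equal_branch_lengths()`), a punctuational-style transform under
  which rates are "per branch" rather than per unit time; the source
  analysis adopted it after finding it fit better than the ultrametric
  dated tree. `"as-is"` keeps the input lengths. The absolute value of the
  equal branch length is absorbed by the rate scale (doubling all rates and
  halving all branches leaves the likelihood unchanged), so 1 is canonical.
* **Root treatment** (`root_treatment()`): how per-state root likelihoods
  are combined — `uniform` (1/k, the default and the common convention for
  these analyses), `stationary`, `fitzjohn` (weights proportional to the
  root partials), or `fixed`. The choice shifts log-likelihoods by a bounded
  constant; it is recorded in every fit and report.
* **Optimization** (`attempts`, default 25): bounded quasi-Newton
  (`nlminb`) on log rates, bounds `[1e-8, 1e3]` per unit branch length,
  relative tolerance 1e-8, at most 2000 evaluations per attempt; starting
  log10-rates are uniform on [-3, 1]. Twenty-five random starts follow the
  source analysis; the per-attempt log-likelihoods are kept so multimodality
  is visible (`autoplot()` of a fit). If a restricted model ever beats its
  nesting model (optimizer slack), the full model is re-polished from the
  restricted solution before the test is formed.
* **alpha** (default 0.05) and degrees of freedom are fixed by the model
  structure: 4 for dependent-vs-independent, 1 per single restriction. No
  multiple-testing correction is applied across the restriction rows,
  matching standard practice for this design.

## Ancestral states and transition counts

`marginal_asr()` computes, per node, the marginal posterior of the state
given all tips under the supplied rates ("proportional likelihoods"), by the
inside-outside recursion; the root marginal under uniform weights equals the
normalized root partials of the pruning pass, a cross-module identity the
tests assert. Joint four-state reconstructions can be collapsed per trait
(`collapse_trait()`).

`count_transitions()` turns a reconstruction into per-direction change
counts. The default `argmax` rule assigns each node its most probable state
and counts edges whose endpoints differ. The `threshold` rule (p in
(0.5, 1]) counts only edges whose both endpoints are reconstructed with
proportional likelihood at least p — a conservative "at least this many"
reading. Edge-level counting has an intrinsic resolution limit: within-edge
flip-reverts and double hits are invisible to *any* assignment rule. In our
validation at moderate rates the argmax counts average about 0.9 of the true
number of edges on which the state changed, and about 0.8 of the raw event
count — which is precisely why such counts should be reported as lower
bounds.

## The MCC step

For posterior tree samples, `mcc_tree()` selects the sampled tree (never a
consensus) maximizing the aggregate of its clades' sample frequencies. The
default aggregate is the sum of clade frequencies, following the verbal
definition in the motivating study; `log-product` (the product of clade
posteriors, as in TreeAnnotator) is provided and agrees with
`phangorn::maxCladeCred` in the tests. The posterior-probability limit
(default 0.5) controls which nodes are *annotated* only — it never changes
which tree is selected; both readings of the ambiguous published wording are
therefore runnable (selection is limit-free; annotation honours the limit).
Node heights are not re-summarized: the selected tree keeps its own branch
lengths, which the default pipeline overrides with equal lengths anyway.

## What the synthetic generator emulates — and what it does not

The trait database and supertrees behind the motivating study are not
redistributable, so `make_study_like_dataset()` generates data with the
statistical structure the analysis assumes: a Yule (pure-birth) tree at the
study's scale (default 1582 species, the nesting-analysis sample size),
binary trait pairs evolved by exact Gillespie simulation under a
dependent-model truth, and per-trait missing-completely-at-random dropout
(defaults 5% and 15%) producing unequal per-analysis sample sizes. Every
change event is logged, and replaying the log reproduces the tip states
exactly — ground truth for the reconstruction and counting layers.

Default generating rates are 0.15 per unit branch length for all eight
transitions, with the bright-to-dark rate in non-cavity nesters (`q31`)
multiplied by 8 — the qualitative asymmetry the motivating study inferred
(selection away from bright eyes is much stronger outside cavities). On
these trees that is roughly one expected change per trait per root-to-tip
path, inside the 0.5–2 identifiability sweet spot; the Yule tree height has
the closed-form expectation `sum_{k=2..n} 1/(lambda k)` that the tests use
as an oracle.

What passing tests on these data do *not* show: real avian phylogenies are
not Yule trees; real missingness is not MCAR (rare, hard-to-photograph taxa
are preferentially missing); real traits have intraspecific variation,
scoring error and possible trait-dependent diversification, none of which
are modelled. The package validates the *inference machinery*, not the
biological conclusions of any particular dataset.

## Numerical and design choices

* Partial likelihoods are rescaled per node (log scalers accumulated), so
  likelihoods are exact in log space at any tree size.
* `exp(Qt)` entries are clamped at 0 and rows renormalized to absorb
  roundoff from the matrix exponential of non-symmetric generators.
* LRT statistics are clamped at zero; nesting violations beyond 1e-6 trigger
  a refit of the full model from the restricted optimum.
* Ties in `mcc_tree()` scores go to the lowest tree index; ties in argmax
  state assignments go to the lowest state index — both deterministic.
* Polytomies are rejected by default; optional random resolution inserts
  zero-length branches under a caller-supplied seed. Pruning to a single
  tip errors unless explicitly allowed (one tip carries no likelihood
  information).
* Species labels are matched after canonicalization (case folding,
  space/hyphen/underscore unification); fuzzy matching is deliberately
  absent to avoid silent mis-joins. Polymorphic or uncertain states are not
  supported; `?`, `NA` and empty cells are missing data, handled by
  complete-case pairing (the route implied by the per-analysis sample sizes
  of the motivating study).
* Simulation-scale choices in the test suite are the package's own: 500
  null replicates on 100-tip trees for type-I calibration (observed
  rejections compared with the exact binomial 95% interval of alpha), 50
  replicates of 400-tip trees at a 10-fold asymmetry for power, 50/30/30
  replicates at 200/100/400 tips for rate recovery, and 20,000 histories on
  a fixed 3-tip tree for the simulator-versus-likelihood master check
  (every tip-pattern frequency within 3 Monte-Carlo standard errors — the
  standard empirical-variance estimator, floored by the theoretical
  variance for near-empty cells — plus a global 64-cell goodness-of-fit).
  Simulation studies use 2 random starts per fit; at these sizes the
  surfaces are well behaved, and the full 25-start default is reserved for
  single-dataset analyses.
* Rate identifiability is assessed from the observed information
  (`fit_model(..., hessian = TRUE)`: the SE of a log rate is the relative
  SE of the rate). Under strong asymmetry a transition type can occur often
  in the true history yet be invisible at the tips (gains that revert
  almost immediately), so event counts are not a usable identifiability
  proxy — the recovery study labels a rate identifiable when its relative
  SE is below 50%.

## Known limitations

* Only binary traits (4-state pairs); no covarion, hidden-rate or
  multi-state extensions.
* Chi-squared reference distributions are used throughout, as in the
  source analysis; when ML estimates sit on the rate bounds the usual
  boundary caveats to the chi-squared approximation apply.
* The likelihood-ratio machinery is frequentist by design; no reversible-
  jump model averaging and no AIC/BIC selection.
* The MCC step summarizes topology support only; node-height
  summarization is out of scope.
* The care comparison of the motivating study prints a statistic (8.36)
  inconsistent with its printed log-likelihoods (which imply 10.36);
  `lrt()` is a pure function of log-likelihoods, and the acceptance script
  reports both numbers without resolving the discrepancy.

## A worked example

```{r example, eval = FALSE}
ds <- make_study_like_dataset(study_config(n_tips = 300, seed = 1),
                              dir = tempdir())
cfg <- run_config(tree_file = ds$files[["tree"]],
                  trait_file = ds$files[["traits"]],
                  attempts = 25, seed = 2)
bundle <- run_full_analysis(cfg)
print(bundle)
glance(bundle$comparison)
collapse_trait(bundle$asr, 1)   # per-node iris reconstruction
```
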