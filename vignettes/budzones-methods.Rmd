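---
title: "Segmenting shoot bud-fate sequences with hidden semi-Markov chains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting shoot bud-fate sequences with hidden semi-Markov chains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(budzones)
```

## The biological problem

In many temperate fruit trees, flowers — and hence fruit — are borne in
axillary position along one-year-old shoots. Walking a shoot from its base to
its tip and recording, at every node (metamer), the fate of the central
axillary bud — latent (`L`), vegetative (`V`) or floral (`F`) — together with
the number of associated flower buds flanking it (`0`, `1`, `2+`) yields a
bivariate categorical sequence indexed by node rank. These sequences are not
homogeneous: buds of like fate cluster into successive *zones* — typically a
basal zone of latent buds, a median flowering zone, and a distal vegetative
zone — and the lengths and presence of those zones carry the information
about a genotype's branching and bearing habit.

`budzones` models such sequences with a *left-right hidden semi-Markov
chain* (HSMC), estimates it from data, restores each shoot's most probable
zone decomposition, and compares the resulting zone statistics across
genotypes, years and shoot-length classes. Because real orchard datasets of
this kind are rarely public, the package also ships a synthetic generator
whose presets emulate the zone structure, so every stage of the analysis is
testable end to end.

## The model

A shoot is generated by an unobservable state process with `K` transient
states (default `K = 3`, one per zone) plus an absorbing *end* state:

* **Initial probabilities** `pi` select the first zone (in practice all mass
  starts in state 1, the basal zone, but `pi` is kept general and estimation
  decides).
* **Transition probabilities** `A[j, k]` move from state `j` to a strictly
  later state `k > j` or to the end state — the left-right constraint means
  every state is visited at most once, which is what gives zones their
  base-to-tip order and makes zones skippable (e.g. `A[1, 3] > 0` skips the
  median flowering zone).
* **Occupancy distributions** `d_j(u)` give the length of zone `j` in
  metamers, `u = 1..D_max`. This is the "semi-Markov" part: zone lengths are
  modelled explicitly instead of the geometric sojourns a Markov chain would
  imply.
* **Emission distributions**: each state carries one categorical
  distribution over bud fates and one over flower classes; the two observed
  variables are conditionally independent given the state. This mirrors how
  such models are reported per zone (one fate table and one flower table per
  state) and keeps every parameter interpretable.

The **end-state convention** matters: a sequence ends exactly when the chain
jumps to the absorbing end state, so the final zone's duration terminates at
the last observed node and is fully observed — there is no right-censoring
of the distal zone. The likelihood recursion, the EM estimator and the
Viterbi restoration all assert this convention.

The occupancy family is a **nonparametric pmf** on `1..D_max`
(default `D_max = 30`, comfortably above the longest shoots of 26 metamers
such data show). A nonparametric family is exact for the enumeration oracles
used in testing and puts no shape constraint on zone lengths; the synthetic
presets use truncated shifted negative binomials merely as a convenient way
to *construct* smooth pmfs.

## Estimation

`hsmc_fit()` runs expectation-maximization with explicit state durations.
The E-step is a forward-backward pass per shoot over *segment posteriors*
`P(state j occupies nodes s..e | shoot)`, from which expected counts of
initial states, transitions (including to end), durations, and per-state
emission categories accumulate; the M-step renormalizes those counts.
Implementation choices worth knowing:

* All recursions run in natural-log space with log-sum-exp; impossible
  observations yield `-Inf` likelihoods rather than underflow. The
  recursions are implemented in C++ (Rcpp), as is usual for
  duration-explicit HMM software, and cost `O(K^2 T D_max)` per sequence.
* **Initialization is deterministic**: every shoot is cut into `K` equal
  contiguous blocks; block-wise category frequencies (floored at `1e-3`)
  seed the emissions, a broad triangular pmf centred on the mean block
  length seeds each occupancy, `pi` starts at state 1, transitions start
  uniform over allowed successors. Identical data therefore always give
  identical fits. A seeded multi-start is easy to layer on top but is not
  the default.
* **Convergence** is declared when the relative log-likelihood change drops
  below `tol` (default `1e-6`, cap `max_iter = 500`). The trace is
  guaranteed nondecreasing (slack `1e-8` for floating point) and is stored
  on the fit object.
* **Smoothing**: occupancy entries below `1e-12` are truncated and the pmf
  renormalized, preventing denormalized tails; emission categories never
  seen may legitimately go to zero (the basal zone really is all-latent).
  States that lose all posterior mass keep their previous parameters rather
  than dividing by zero.
* **Pooling**: one model per genotype over all years and shoot types
  together is the default grouping (`hsmc_fit_by(group_by = "genotype")`),
  but any metadata grouping works.

Estimation settings (tolerance, cap, initializer) are engineering defaults —
reference analyses of this kind do not publish theirs — and are all exposed.

## Restoration and zone labels

`restore_states()` computes the globally most probable (state, duration)
path per shoot by a semi-Markov Viterbi dynamic program under the same
end-state convention, and asserts on every call that the result exactly
partitions the shoot. Ties between equal-probability paths are broken
deterministically: candidates at each cell are scanned by increasing
duration, then increasing predecessor state, and replaced only on strict
improvement — so the restoration prefers shorter current durations and
lower state indices. `label_zones()` then names states by their bud-fate
emission argmax (`L` → basal, `F` → median, `V` → distal); if two states
share an argmax the labelling refuses and asks for a manual mapping rather
than guessing. Posterior per-node state probabilities
(`posterior_states()`) are exposed for diagnostics, but all reported zone
statistics are computed from the restored ("optimal") segmentations, which
is how such studies tabulate zone occurrence and zone lengths.

On small pooled samples with a weakly expressed median zone, EM can settle
in a local optimum that splits the basal zone across two latent-dominated
states; the labelling error above is the designed response, and refitting
with more shoots (or merging groups) resolves it. This is a genuine
property of EM on semi-Markov models, not an artifact of this
implementation.

## Contextual statistics and group comparisons

`contextual_parameters()` extracts, per group (genotype, year, shoot type,
or any crossing), the frequency of occurrence of each zone, empirical
zone-to-zone transition frequencies (including to shoot end), zone-length
means/SDs, and per-shoot metamer and flower-bud counts. The comparison layer
mirrors standard practice for such data, which is firmly nonparametric:

* Kruskal-Wallis for omnibus genotype/year effects (`kruskal_wallis()`),
* pairwise Wilcoxon-Mann-Whitney tests summarised as compact letter
  displays (`pairwise_wilcoxon_letters()`); exact p-values for untied
  samples of up to 10 per group, the tie- and continuity-corrected normal
  approximation otherwise; **no multiple-testing correction by default**,
  mirroring letters-at-p<0.05 reporting, with a Holm option off by default,
* Pearson chi-squared without continuity correction for occurrence and
  survival proportions (`proportion_chi2()`, `proportion_table()`),
* Spearman rank correlations between zone lengths with the large-sample
  significance limit `z[1 - alpha/2] / sqrt(n - 1)` reported alongside rho
  (`spearman_with_limits()`); published tables of this kind print such
  limits without their formula, so the conventional normal bound was chosen
  and is documented rather than asserted against any source.

For the correlation tables a zone absent from a shoot contributes length 0
(the zone has no metamers); a zone absent from an entire group yields an
undefined rho, reported as missing rather than silently zero. The
shoot-level flower count scores the pooled `2+` class as 2 buds — its
observable lower bound — unless raw counts are available.

The omnibus tests, rank tests and chi-squared statistics are delegated to
R's `stats` primitives; the compact-letter insert-and-absorb construction
is implemented here and property-tested as a clique cover of the
non-significance graph.

## The synthetic generator

`make_preset()` returns three named genotype profiles — `"high-flowering"`,
`"low-flowering"`, `"median-skipping"` — that copy the *structure* real
fitted models show (state 1 strictly latent with no associated flowers;
state 2 floral-dominated carrying most flower mass; state 3
vegetative-dominated; median and distal zones skippable) with illustrative
numeric values chosen once: median-zone entry 0.85/0.45/0.25 across the
three presets, mean zone lengths of roughly 5/2–3/4–5 metamers, basal
occupancy support starting at 2 metamers so every generated shoot has at
least two nodes. The values are deliberately *not* transcriptions of any
published figure.

`generate_dataset()` stamps genotype/year metadata, derives shoot length by
the documented monotone map `length_cm = 0.45 × metamers × exp(N(0, 0.25))`
(spreading shoots across the SS/MS/LS classes: short ≤ 2 cm, medium 2.1–10,
long > 10), and applies a **year effect** in the second simulated year as a
single source of truth: occupancy means and the median-zone entry
probability are both multiplied by 0.8, emulating an "off" year with
shorter shoots and less flowering. Generation is byte-identical given the
same presets and seed.

What the generator does *not* emulate: branch-level architecture above the
shoot, weather covariates, fruit set, and any within-zone serial
correlation of emissions (emissions are i.i.d. given the state, exactly as
the model assumes). Passing tests on synthetic data therefore demonstrate
correctness of the machinery and recoverability of parameters under the
model's own assumptions — not that real shoots satisfy those assumptions.

## Verification strategy and problem sizes

The test suite checks every layer against an independent route:

* forward likelihood and Viterbi against exhaustive enumeration of all
  (state, duration) segmentations for 100 random small instances
  (`K ≤ 3`, `T ≤ 8`, `D_max ≤ 6`), at `1e-10`;
* the summed likelihood over every possible bounded-length observation
  sequence against the chain's analytic stopping probability;
* one EM step on a model's own exactly-enumerated expected counts, which
  must be a fixed point;
* parameter recovery from 500 simulated shoots (transitions within ±0.05,
  mean occupancies within 10%, emissions within ±0.05), and a consistency
  sweep over 50 → 500 → 5000 shoots with 10 replicates;
* rank statistics against from-scratch textbook formulas, the exact
  Wilcoxon branch against full enumeration of rank assignments, and the
  type-I error of the two-group comparison under the null (2,000
  replicates);
* byte-identical re-runs of the full pipeline.

These sizes keep the default suite to a few minutes on a single CPU while
leaving each property sharply falsifiable.

## A worked example

```{r example, eval = FALSE}
presets <- lapply(c("high-flowering", "low-flowering"), make_preset)
sim <- generate_dataset(presets, n_per_group = 150, seed = 11)

fits <- hsmc_fit_by(sim$sequences, group_by = "genotype")
seg <- dplyr::bind_rows(lapply(seq_len(nrow(fits)), function(i) {
  sub <- dplyr::filter(sim$sequences, genotype == fits$genotype[i])
  label_zones(restore_states(sub, fits$fit[[i]]$model), fits$fit[[i]]$model)
}))

contextual_parameters(seg, sim$sequences, group_by = c("genotype", "year"))
summary_tables(seg, sim$sequences, group_by = c("genotype", "year"))

autoplot(fits$fit[[1]]$model)
autoplot(seg)
```

Or in one call, writing every artifact (sequences, per-genotype model JSONs,
`segments.tsv`, comparison tables, a parseable run log) to a directory:

```{r pipeline, eval = FALSE}
run_pipeline(pipeline_config(presets = c("high-flowering", "low-flowering"),
                             n_per_group = 150, seed = 11,
                             out_dir = "run1"))
```

## Known limitations

* `K` is user-fixed; model selection over the number of zones (BIC or
  penalized likelihood) is out of scope.
* Emissions are conditionally independent given the state; dependence
  between bud fate and flower class within a zone is not modelled.
* The nonparametric occupancy pmf has `D_max` free parameters per state;
  on very small samples a parametric family would be more stable (a
  shifted negative-binomial smoothing hook exists in the generator but the
  estimator is nonparametric).
* Contextual statistics are computed from the single optimal segmentation;
  no uncertainty is propagated from the restoration step.
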