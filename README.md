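# budzones

Segmentation of axillary bud-fate sequences along one-year-old shoots with
hidden semi-Markov chains, and comparison of the resulting branching /
flowering zone structure across genotypes, years and shoot types.

## The problem

In temperate fruit trees, flowers — and therefore fruit — sit in axillary
position along one-year-old shoots. Recording each node (metamer) of a shoot
from base to tip gives a bivariate categorical sequence: the central bud fate
(`L` latent, `V` vegetative, `F` floral) and the associated flower-bud class
(`0`, `1`, `2+`). Shoots organize into successive homogeneous **zones** — a
basal zone of latent buds, a median flowering zone, a distal vegetative
zone — whose lengths and presence characterize a genotype's bearing habit.
`budzones` is for researchers in plant architecture and horticulture who
want to segment such sequences into zones, estimate the underlying model per
genotype, and run the standard nonparametric comparison battery over the
results.

## The model

A **left-right hidden semi-Markov chain** with `K` transient states plus an
absorbing end state:

- initial probabilities `π(j)` over transient states,
- transition probabilities `p(j → k)` restricted to `k > j` or to the end
  state (each zone visited at most once; zones may be skipped),
- explicit occupancy distributions `d_j(u)`, `u = 1..D_max`, for zone
  lengths in metamers,
- per-state categorical emission distributions for bud fate and flower
  class (conditionally independent given the state).

A sequence ends exactly when the chain enters the end state, so the last
zone's length is fully observed. The package provides exact forward
likelihood, EM estimation with explicit durations, semi-Markov Viterbi
restoration of the optimal segmentation, contextual zone statistics, and
group comparisons (Kruskal-Wallis, Wilcoxon-Mann-Whitney with compact
letter displays, Pearson χ², Spearman correlations with significance
limits). A synthetic shoot generator with named genotype presets and a
parameter-recovery harness make the whole analysis testable without field
data.

## Worked example

```r
library(budzones)

presets <- lapply(c("high-flowering", "low-flowering"), make_preset)
sim <- generate_dataset(presets, n_per_group = 150, seed = 11)

fits <- hsmc_fit_by(sim$sequences, group_by = "genotype")
glance(fits$fit[[1]])
#> # A tibble: 1 × 7
#>   logLik n_iter converged n_seq n_nodes     K D_max
#>    <dbl>  <dbl> <lgl>     <int>   <int> <int> <int>
#> 1 -3471.     14 TRUE        300    3092     3    30

seg <- dplyr::bind_rows(lapply(seq_len(nrow(fits)), function(i) {
  sub <- dplyr::filter(sim$sequences, genotype == fits$genotype[i])
  label_zones(restore_states(sub, fits$fit[[i]]$model), fits$fit[[i]]$model)
}))

cx <- contextual_parameters(seg, sim$sequences, group_by = c("genotype", "year"))
cx$occurrence
#> # A tibble: 12 × 5
#>    genotype       year  zone   n_shoots occurrence
#>  1 high-flowering Y1    basal       150      1
#>  2 high-flowering Y1    median      150      0.793
#>  3 high-flowering Y1    distal      150      0.727
#>  4 high-flowering Y2    basal       150      1
#>  5 high-flowering Y2    median      150      0.647
#>  ...
cx$shoots
#> # A tibble: 4 × 6
#>   genotype       year  n_shoots mean_metamers sd_metamers mean_assoc_flowers
#> 1 high-flowering Y1         150         11.4         4.21              1.78
#> 2 high-flowering Y2         150          9.26        3.68              1.35
#> 3 low-flowering  Y1         150          9.4         3.77              0.487
#> 4 low-flowering  Y2         150          7.81        2.96              0.2
```

Reading the output: the EM fit of the high-flowering genotype converged in
14 iterations on 300 pooled shoots (3,092 metamers). The basal latent zone
occurs on every shoot; the median flowering zone occurs on 79% of
first-year high-flowering shoots but only 65% in the simulated "off" second
year, and shoots are about two metamers shorter in that year — the injected
year effect, recovered by the analysis. `summary_tables(seg, sim$sequences)`
adds the letter-annotated comparison tables, and `autoplot()` methods
visualise models, segmentations and recovery reports.

The same workflow runs end to end with

```r
run_pipeline(pipeline_config(presets = c("high-flowering", "low-flowering"),
                             n_per_group = 150, seed = 11, out_dir = "run1"))
```

which writes `sequences.tsv`, one `model_<genotype>.json` per pool,
`segments.tsv`, `tables/*.tsv` and a machine-parseable `run.log`. A thin
command-line wrapper with `simulate` / `fit` / `segment` / `stats` /
`recover` / `run` subcommands lives at `inst/scripts/budzones-cli.R`.

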