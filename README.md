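# mnseg — metabolic network segmentation with Markov random fields

`mnseg` locates candidate sites of metabolic regulation from relative
metabolomics data (log2 fold-changes or z-scores between two conditions) and
a metabolic network of main reactant pairs. It is aimed at metabolomics and
systems-biology researchers who have a differential metabolite profile —
e.g. from an enzyme knockout, a drug treatment, or a time course — and want
an automatic, network-aware ranking of the reactions most likely to be
regulated, without fixed significance cutoffs or pathway definitions.

## The model

Every metabolite *i* carries a discrete hidden label *y*<sub>*i*</sub> ∈
{1..K}, its **module**: a group of neighboring metabolites changing
consistently. Three potential families tie the labels together:

- **Neighborhood** — for each maximal clique *c* of the reactant-pair graph,
  ψ<sub>N</sub>(c) = exp(−λ₁ · (unique(c) − 1)/size(c)), pulling connected
  metabolites toward one label with strength λ₁;
- **Observation** — for each measured metabolite,
  ψ<sub>O</sub>(x, y) = exp(−(x − μ(y))² / 2σ(y)²), a Gaussian kernel with
  state-dependent means and standard deviations (k-means centers, quantile
  spacing, or user-fixed values; unmeasured metabolites simply contribute no
  factor);
- **Sequence** (multi-frame data) — ψ<sub>S</sub> = exp(−λ₂·f) with f = −1
  when a metabolite keeps its label across consecutive frames, +1 when it
  switches.

The MAP labeling maximizes the product of all potentials (energy
minimization; exact enumeration on small problems, deterministic iterated
conditional modes with lazy-flipper-style subset flips and swap moves
otherwise). An edge whose endpoints disagree is a **fracture** — the
candidate regulation site. Scanning λ₁ from 0 up to the value where the
network collapses into one module yields two per-reaction statistics:
**max(λ₁)**, the strongest smoothing a fracture survives, and
**#fractures**, the number of grid points at which it appears. Significance
comes from rerunning the scan under permutations of the
observation-to-metabolite assignment; multiple parameterizations are
combined with rank products. For time courses, a (λ₁, λ₂) score surface is
swept with fracture-count weights (w_s, w_n) to extract stable fractures and
the frame at which each first appears — the sequential order of regulation
events. Reporter-reaction and mass-action-ratio rankings are included as
comparison baselines, and an evaluation layer classifies predictions as
exact / first-neighbor / not identifiable with reaction-label permutation
p-values and hypergeometric overlap tests.

## Worked example

```r
library(mnseg)

# a synthetic knockout: 30-metabolite pathway, a step of 2 log2 units
# planted across one edge, noise sd 0.5, 80% of the metabolome measured
sim <- simulate_dataset(n_metabolites = 30, effect_size = 2, noise_sd = 0.5,
                        fraction_measured = 0.8, seed = 42)
sim$truth$perturbed_edges
#> [1] "M15~M16"

model <- fit_observation_model(sim$obs, n_states = 3, mean_type = "kmeans",
                               std_type = "all_data", seed = 1)
tidy(model)
#> # A tibble: 3 × 3
#>   state   mean    sd
#>   <int>  <dbl> <dbl>
#> 1     1 -2.03   1.38
#> 2     2 -0.883  1.38
#> 3     3  1.28   1.38

seg <- mns_segment(sim$network, sim$obs, model,
                   mns_scan_config(grid_size = 100, n_permutations = 200,
                                   seed = 42))
seg |> dplyr::arrange(rank_max_lambda1) |> head(3) |>
  dplyr::select(edge_id, max_lambda1, n_fractures, p_max_lambda1)
#> # A tibble: 3 × 4
#>   edge_id max_lambda1 n_fractures p_max_lambda1
#>   <chr>         <dbl>       <int>         <dbl>
#> 1 M15~M16       32             50          0
#> 2 M19~M20        0.64           1          0.29
#> 3 M01~M02        0              0          1
```

The planted reaction M15~M16 survives smoothing up to λ₁ = 32 (half the
scan ceiling), fractures at 50 of the 100 grid values, and no permutation
reaches its statistic (p < 1/200 = 0.005); the runner-up is a noise
fracture that dies at λ₁ = 0.64 and is far from significant. The
evaluation layer confirms the exact identification:

```r
classify_prediction(sim$network, rank_reactions(seg, "max_lambda1"),
                    sim$truth$perturbed_edges)
#> # A tibble: 1 × 4
#>   true_edge predicted_rank_exact best_first_neighbor_rank class
#> 1 M15~M16                      1                       16 exact
```

`autoplot(seg)` draws the per-reaction statistics; `mns_segment_seq()` runs
the sequential mode on multi-frame data; `reporter_reaction_scores()` and
`mass_action_scores()` provide the baselines. A command-line wrapper with
subcommands `simulate`, `segment`, `segment-seq`, `baseline`, `evaluate`
and `params` is installed at
`system.file("cli", "mns.R", package = "mnseg")`.

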