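# fitland

Machine-learning-guided protein design on fitness landscapes, end to end:
supervised sequence→fitness predictors, ensemble uncertainty, a
fixed-distance simulated-annealing design engine, extrapolation metrics,
and sort-seq enrichment scoring — exercisable entirely on synthetic
landscapes, with generic loaders for real variant-fitness tables.

## The problem

Protein engineering searches the sequence–function landscape for variants
with improved fitness (e.g. binding of an immunoglobulin-binding domain to
IgG). Experiments only characterize a tiny local neighbourhood of the wild
type — typically single and double mutants — while useful designs may carry
5–50 mutations. A supervised model trained on the local data must therefore
*extrapolate*, and how far it can be trusted depends strongly on its
architecture's inductive biases. `fitland` provides the full toolchain for
studying and exploiting this:

* **Predictors** (`predictor_spec()`, `build_model()`,
  `train_predictor()`): linear (strictly additive), fully connected
  (epistasis-capable), 1-D sequence-convolutional (parameter sharing), and
  structure-based graph-convolutional models over a residue contact graph;
  trained with Adam + early stopping on MSE.
* **Ensembles** (`fitness_ensemble()`): aggregate ~100 models differing
  only in initialization; the median ensemble is an average predictor, the
  5th-percentile ensemble is a conservative one — 95% of members predict
  higher, i.e. fitness the ensemble largely agrees on.
* **Design engine** (`sa_design()`, `run_campaign()`,
  `select_representatives()`): simulated annealing at a fixed Hamming
  distance k from wild type. Exchange moves revert m ~ zero-truncated
  Poisson(1) substitutions and introduce m new ones, keeping distance
  exactly k; improving moves are always accepted, others with probability
  `exp(ΔF/T)` as T decays geometrically 1e3 → 1e-5. Hundreds of
  independent runs are clustered (K-means, one-hot encoding) and the
  fittest member of each cluster is kept — a synthesis-budget-sized,
  diverse design panel (41 clusters by default).
* **Extrapolation metrics** (`stratified_spearman()`,
  `recall_at_budget()`, `trajectory_divergence()`): mutation-count
  stratified rank correlation, recall of the true top-100 variants within
  a design budget N, and ensemble divergence along mutational pathways.
* **Sort-seq scoring** (`merge_read_pair()`, `count_exact_matches()`,
  `filter_min_count()`, `enrichment_scores()`): from sorted-population
  reads to display/binding enrichment,
  `e_bind = log10(p_b/p_d) − log10(p_b,wt/p_d,wt)` and
  `e_disp = log10((0.6·p_b + 0.4·p_d)/p_u) − (wt term)`, plus quadrant
  classification and Hill-equation titration fits (`fit_hill()`).
* **Synthetic landscapes** (`generate_landscape()`,
  `sample_local_dataset()`, `combinatorial_dataset()`,
  `simulate_sortseq_counts()`): additive + sparse pairwise-epistatic
  ground truth with local, combinatorial and count-level samplers — the
  oracle behind every test.

## Worked example

Train a model on local (≤ 2-mutant) data from a synthetic landscape, then
design diverse 4-mutants:

```r
library(fitland)
set.seed(0)
wt <- paste(sample(AA_ALPHABET, 12, replace = TRUE), collapse = "")  # "QEHACMQVWALQ"
land <- generate_landscape(wt, seed = 1)
dat <- assign_splits(sample_local_dataset(land, double_fraction = 0.2,
                                          noise_sd = 0.1, seed = 1), seed = 2)
spec <- predictor_spec("linear", L = 12, seed = 0, learning_rate = 0.05,
                       epochs = 60, batch_size = 256)
model <- train_predictor(build_model(spec), dat)

camp <- run_campaign(model, wt, anneal_config(k = 4, n_steps = 1000),
                     n_runs = 50, base_seed = 0)
reps <- select_representatives(camp, n_clusters = 5)
reps[, c("variant", "fitness", "cluster")]
#>           variant  fitness cluster
#>  Q1G,E2V,H3R,A10Q 7.658692       3
#>  Q1G,E2V,V8F,A10Q 7.522223       5
#>  Q1G,E2V,H3P,A10Q 7.491263       2
#>  Q1G,E2V,A4Q,A10G 7.202781       4
#>  E2V,H3R,V8F,A10G 7.084582       1
```

Each row is one design: its mutation string (1-based, wild-type residue /
position / new residue), the model's predicted fitness in the landscape's
arbitrary units (wild type = 0 baseline), and the cluster it represents.
The five designs agree on the strong beneficial substitutions (Q1G, E2V)
while sampling distinct local optima elsewhere — checking the first design
against the ground truth gives `true_fitness(land, reps$sequence[1])` ≈
7.41, close to the model's 7.66 despite the 4-mutant extrapolation.

The mutation-string convention everywhere is
`"<wt aa><1-based position><new aa>"`, comma-separated, `"WT"` for the
wild type.

A thin command-line wrapper for the design and scoring stages ships in
`inst/cli/fitland.R` (`design` and `score` subcommands); every other stage
is a documented function call (see the vignette
`vignettes/fitness-landscape-design.Rmd`).

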