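---
title: "Model-guided protein design on fitness landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-guided protein design on fitness landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`fitland` implements a complete machine-learning-guided protein design
workflow: supervised sequence-fitness predictors trained on local
mutational data, ensemble aggregation of many independently initialized
models, a fixed-mutation-distance simulated-annealing (SA) design engine
with clustering-based representative selection, extrapolation metrics, and
sort-seq enrichment scoring. This vignette explains the underlying models
and procedures, the parameters that matter, and the design decisions taken
where the methodology leaves room.

```{r setup}
library(fitland)
```

## The modeling problem

A fitness landscape maps a protein sequence to a quantitative functional
score (for a binding domain, typically a log-enrichment readout of ligand
binding). Experiments characterize only a minuscule, local neighbourhood of
the wild type — nearly all single mutants and a subset of double mutants is
a common design point. A supervised model trained on such data is then
asked to rank or propose variants carrying many more mutations. That is an
extrapolation task: the further a query is from the training regime, the
more the prediction depends on the model's inductive biases rather than
the data.

Four architectures spanning distinct biases are provided:

* **linear** — one weight per position/amino-acid pair. Exactly additive in
  mutations; cannot represent epistasis. `L*20 + 1` parameters.
* **fcn** — a fully connected network (two ReLU hidden layers of width 100
  by default) that can capture nonlinear, epistatic interactions between
  specific positions.
* **cnn** — 1-D convolutions along the sequence (two valid-convolution
  layers, kernel 5, 32 filters by default, dense head). Parameter sharing
  makes it learn position-independent patterns.
* **gcn** — graph convolutions over a residue contact graph (two layers, 32
  channels by default, dense head), propagating information between
  residues adjacent in the 3-D structure (adjacency from
  `contact_graph()` at an 8 Å alpha-carbon threshold by default).

All models consume the same one-hot encoding (`L x 20`, alphabetical
amino-acid order, frozen) and are trained with mini-batch Adam on mean
squared error with early stopping on a validation split (defaults:
learning rate 1e-3, batch 64, patience 10, 80/10/10 random split by
variant). These optimizer settings are conventional defaults, exposed in
`predictor_spec()`, and not tuned per dataset. Parameters returned are
those of the best validation epoch; epoch 0 of the recorded history is the
loss at initialization.

## Ensembles and conservative prediction

Neural networks carry many parameters unconstrained by local training
data, so models that agree near the wild type can diverge strongly deep in
sequence space. `fitness_ensemble()` aggregates many members trained from
different random initializations on identical data:

* the **median** ensemble is an "average" predictor;
* the **percentile** ensemble with p = 5 is a conservative predictor: 95%
  of members predict a fitness at least as high as its output.

The 5th percentile is computed with lower interpolation (inverse ECDF,
`quantile(..., type = 1)`); this convention is frozen and documented
because percentile definitions differ between libraries. By construction
the conservative ensemble never exceeds the median ensemble, and
`trajectory_divergence()` exposes the member spread along a mutational
pathway — near zero within the training regime, growing with mutation
count.

Members share training data and differ only in their initialization seed.
That choice (rather than also resampling the data) isolates the
initialization variance the ensembles are meant to marginalize.

## The synthetic landscape

`generate_landscape()` builds the ground truth every test runs against:

\[
f(s) = f_0 + \sum_{p} a_{p,s_p} + \sum_{(p,a),(q,b)} e_{(p,a),(q,b)}
       \, [s_p = a][s_q = b]
\]

additive effects `a` (Gaussian, default sd 1, mean −0.5 — most mutations
are deleterious, mirroring the strong destabilizing bias of real
mutational data) plus sparse specific pairwise epistasis (default: 2% of
all `C(L,2)·19²` candidate terms, effect sd 1, active only when **both**
substitutions are present). Measurement noise is additive Gaussian on this
scale; `simulate_sortseq_counts()` provides the count-level alternative
with multinomial sampling noise.

Two samplers emulate the canonical experimental designs: a **local**
dataset (wild type, all `L·19` singles, a uniform fraction of doubles) and
a **combinatorial** dataset (all `20^k` combinations at `k` fixed sites,
optionally subsampled). One structural point deserves emphasis because it
shapes the tests: a specific pairwise term is carried by exactly one
double mutant, so purely local double-mutant data cannot support
generalizing epistasis — each term is seen at most once. In a
combinatorial library every site-pair term recurs across hundreds of
variants, which is why the nonlinear-beats-linear property is asserted on
combinatorial data.

What the generator does **not** emulate: the heavy-tailed, bounded
enrichment distributions of real screens, correlations induced by protein
stability thresholds, position-dependent mutation biases, and any
biophysics of folding. Tests passing on this generator demonstrate the
machinery is correct, not that any architecture will win on a particular
real protein.

## The design engine

`sa_design()` maximizes predicted fitness over the set of sequences at a
**fixed Hamming distance k** from the wild type:

* **moves**: `m ~` zero-truncated Poisson(λ = 1) existing substitutions are
  reverted and `m` new ones introduced at positions currently wild type
  (just-reverted positions are eligible again, maximizing move-kernel
  connectivity; amino acids uniform over the 19 non-wild-type residues).
  Every chain state therefore has distance exactly `k`.
* **acceptance**: improving moves always; others with probability
  `exp(ΔFitness/T)`, ΔFitness = proposed − current.
* **schedule**: `T` decreases geometrically from 1e3 to 1e-5 over the run
  (`temperature_schedule()`); at the final temperatures acceptance reduces
  numerically to greedy hill climbing.
* **result**: the best-so-far variant, not the final state — a chain may
  end inside a late stochastic excursion, and returning the maximum is
  the natural choice when the schedule is the only stopping rule.

Model outputs are used as-is, without clamping extreme extrapolated
predictions; the conservative ensemble is the recommended mitigation when
extreme extrapolations are a concern.

`run_campaign()` executes many independent chains (run *r* seeded
`base_seed + r − 1`). Internally the chains advance in lockstep with
per-run RNG streams so predictions can be batched across runs — a large
speedup for ensemble members — while remaining bit-identical to serial
`sa_design()` calls (this equality is tested). Campaign-scale defaults
follow the field practice of 500 runs and 15,000–50,000 steps, with fewer
steps (10,000–25,000, `default_sa_steps()`) for smooth model–distance
combinations whose chains would otherwise all converge onto a handful of
sequences and leave fewer unique designs than clusters.

`select_representatives()` deduplicates the final designs, K-means
clusters their one-hot encodings (k-means++ seeding, 10 restarts, fixed
seed 0), and returns the fittest member of each cluster: a diverse panel
of high-predicted-fitness designs whose size matches a synthesis budget
(41 by default). If fewer unique designs than clusters exist the function
stops with advice to rerun with fewer SA steps. When the number of unique
designs equals the cluster count, clustering is the identity and the
unique designs are returned directly.

```{r design-demo}
wt <- paste(sample(AA_ALPHABET, 12, replace = TRUE), collapse = "")
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
```

## Evaluating extrapolation

* `stratified_spearman()` — rank correlation between predictions and
  observations within each mutation-count stratum; undersized strata are
  reported as missing rather than dropped.
* `recall_at_budget()` — given a design budget N, the fraction of the true
  top 100 variants present among the model's top N predictions. Ties are
  broken by a stable sort on (score decreasing, variant id increasing), so
  recall is deterministic; the curve over budgets is non-decreasing and a
  perfect predictor reaches recall 1 at N = 100.
* `trajectory_divergence()` / `ensemble_disagreement()` — member spread
  (population SD, IQR, min/max) along pathways or over arbitrary variant
  sets, quantifying where the ensemble stops being trustworthy.

## Sort-seq enrichment scoring

From sorted-population sequencing (unsorted u, display-only d, binding b),
with `p` the within-population proportions, the package computes

\[
e_{bind,i} = \log_{10}\frac{p_{b,i}}{p_{d,i}}
           - \log_{10}\frac{p_{b,wt}}{p_{d,wt}},\qquad
e_{disp,i} = \log_{10}\frac{w_b p_{b,i} + w_d p_{d,i}}{p_{u,i}}
           - \log_{10}\frac{w_b p_{b,wt} + w_d p_{d,wt}}{p_{u,wt}}
\]

and for quantitative sorts into populations x ∈ {l, w, h},
`e_x = log10(p_x/p_u) − log10(p_x,wt/p_u,wt)`. The weights
`(w_b, w_d) = (0.6, 0.4)` are the relative sizes of the binding and
display-only sorted populations in the FACS experiment — configuration
values on `sortseq_counts()`, not constants. Wild-type scores are
identically zero, scores are invariant to sequencing-depth rescaling of
any population, and designs with a zero count in b or d get a +1
pseudocount in both populations, flagged, so scores stay finite without
shifting the wild-type normalization (the pseudocount policy is the
package's choice; the convention is deliberately symmetric so the b/d
ratio is perturbed as little as possible).

Upstream, `merge_read_pair()` merges a forward/reverse Illumina pair at a
predetermined offset taking the higher-quality base in the overlap (ties
keep the forward base; qualities Phred+33; reverse reads are expected
reverse-complemented), and `count_exact_matches()` counts only exact
nucleotide matches to the designed sequences — no fuzzy matching, so
synonymous internal controls with distinct codon usage are tallied under
their own ids (`reverse_translate()` generates such controls).
`filter_min_count()` removes designs with fewer than 10 unsorted reads.

Titration curves are fit with `fit_hill()` as `s = Bmax·c/(KD + c)`: the
Hill coefficient is fixed at 1 since KD and the maximum signal are the two
parameters of interest for a simple binding isotherm.

KEX2 protease sites — Lys/Arg-Arg dipeptides cleaved in the yeast Golgi,
a known confounder of display measurements — are located with
`find_kex2_sites()`. The motif is operationalized purely as the dipeptide
`[KR]R`; whether a site is structurally exposed (a prerequisite for
cleavage) is outside the package's scope.

## Numerical choices and conventions

* Positions are 0-based internally; all user-facing mutation strings
  (`"A23Y,K31M"`) are 1-based.
* Entropy (`site_entropy()`) is reported in bits; the base is
  configurable.
* MDS (`mds_embed()`) uses classical (Torgerson) initialization followed
  by SMACOF metric stress majorization on the Hamming distance matrix;
  the stress trajectory is recorded and non-increasing by construction.
* Sequence length is always a property of the input wild type; no
  particular protein length is assumed anywhere.
* One acceptance draw is consumed per SA step whether or not the move is
  improving, which keeps serial and lockstep campaign execution on
  identical RNG streams.
* During SA the acceptance probability `exp(Δ/T)` underflows to exactly 0
  for ordinary downhill moves once T ≤ 1e-5, giving a clean greedy limit.

## Problem sizes used in the shipped checks

The package's end-to-end checks run a deliberately scaled-down study: a
random L = 30 wild type; a local training set of all 570 singles plus 2%
of doubles (≈3,100); a panel of eight predictors (linear, FCN, three CNNs
differing only in initialization, GCN, and median/conservative ensembles
of the three CNNs) with reduced widths (FCN 50+50, CNN 8 filters, GCN 8
channels, 25 epochs); and campaigns of 100 SA runs x 500 steps at six
distances {5, 10, 15, 20, 25, 30} (distances are capped by L, so the
upper distances of a full-length study are scaled into the L = 30 range).
With 41 clusters this yields the full 8 x 6 x 41 = 1,968-design grid.
The recall benchmark enumerates a complete 20^4 combinatorial library on
an L = 12 landscape. These sizes were chosen so a complete run finishes
in minutes on a laptop core while exercising every stage at full
fidelity; none of the package's defaults depend on them.

## Known limitations

* The neural networks are small, CPU-bound implementations intended for
  landscape-scale studies, not protein-language-model-scale training.
* Specific epistasis only: the landscape simulator has no higher-order
  terms and no global nonlinearity.
* No structural accessibility reasoning (KEX2 exposure, contact-graph
  quality) beyond what the user supplies.
* `classify_designs()` thresholds must come from calibration constructs or
  the user; no universal cutoffs are shipped.
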