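# abhumanize

Humanness scoring and computational humanization of antibody variable-domain
sequences.

Therapeutic monoclonal antibodies are frequently raised in mice, and murine
sequence content can provoke anti-drug antibody (ADA) responses in patients.
*Humanization* engineers a non-human precursor toward human sequence
character — keeping the antigen-binding CDR loops intact — to reduce
immunogenicity. This package provides, for researchers working on antibody
engineering:

- **Per-V-gene humanness classifiers.** Binary random forests over one-hot
  encoded, IMGT-numbered variable domains: human sequences of one V-gene
  family (e.g. heavy V1) against a pooled non-human repertoire. The score is
  the mean per-tree positive-class probability, s ∈ [0, 1]. A classification
  threshold τ is calibrated on a validation split as the cutpoint maximizing
  Youden's J statistic, J = sensitivity + specificity − 1; a sequence is
  called human when s > τ for any V-gene model of its chain, and a VH/VL
  pair is human when both chains are.
- **A greedy humanizer.** From a precursor sequence, every single-site
  framework substitution (CDRs and the conserved cysteines C23/C104 are
  masked) is scored, the best strictly improving mutation is accepted, and
  the loop repeats until a target score T is reached, no mutation improves
  the score, or an iteration cap is hit. Minimizing the number of accepted
  mutations limits the risk to affinity.
- **Evaluation metrics.** Framework mutation sets are compared by overlap
  ratio (OR = % of tool-suggested mutations also made experimentally, same
  position and target residue), adjusted overlap ratio (AOR, also counting
  same-similarity-group targets), and mutation ratio (tool count /
  experimental count), with panel aggregation, a random-humanization
  Monte-Carlo baseline, positional-category accounting and ADA-score R².
- **A repertoire simulator.** Synthetic germline templates (human heavy
  V1/V3/V4, kappa, lambda; mouse and rat counterparts differing at 12
  signature framework positions) with region-dependent somatic
  hypermutation, so the whole pipeline is testable end-to-end without
  repertoire downloads.

## Worked example

```r
library(abhumanize)

reps <- simulate_repertoire(sim_config(n_per_class = 500, seed = 42))
is_h <- vapply(reps, function(s) s$species == "human", TRUE)
vg   <- vapply(reps, function(s) s$v_gene, "")

dataset <- c(reps[is_h & vg == "V1"], reps[!is_h])
labels  <- c(rep(1L, sum(is_h & vg == "V1")), rep(0L, sum(!is_h)))
parts   <- split_dataset(labels, seed = 7)          # stratified 0.8/0.1/0.1

m <- train_model(dataset[parts$train][labels[parts$train] == 1],
                 dataset[parts$train][labels[parts$train] == 0],
                 n_estimators = 200, seed = 7)
m <- calibrate_threshold(m, dataset[parts$validation],
                         labels[parts$validation])
m
#> <humanness_model> chain=heavy v_gene=V1 trees=200 tau=0.4762198 (n+ 129, n- 397)

evaluate_model(m, dataset[parts$test], labels[parts$test])[c("auc", "yjs")]
#> test AUC = 1.000, test YJS = 1.000

mouse <- germline_as_sequence(make_default_germlines()$mouse_heavy_V1)
score_sequences(m, mouse)
#> [1] 0                      # murine germline: not human at all

tr <- humanize(mouse, m, humanization_config(target = 0.9))
tr
#> <humanization_trajectory> mouse_heavy_V1: 10 step(s), score 0.000 -> 0.924, target_reached
head(tr$steps, 4)
#>   step position from to score_before score_after
#> 1    1       40    I  A    0.0000000   0.1258333
#> 2    2        1    M  E    0.1258333   0.2213889
#> 3    3       72    E  T    0.2213889   0.3080556
#> 4    4       85    D  S    0.3080556   0.3868056
```

Ten accepted substitutions — all at signature framework positions, none in a
CDR — lift the murine germline from 0.000 to 0.924, past the 0.9 target.
Every step records the position (IMGT code), the substitution, and the score
before and after, so the trajectory doubles as a ranked back-mutation list.

A command-line interface wraps the same operations
(`simulate`, `train`, `score`, `humanize`, `evaluate`):

```sh
Rscript inst/cli/abhumanize.R simulate --n 200 --seed 7 --out repertoire.csv
```

## Layout

- `R/`, `src/` — implementation (IMGT domain model, simulator, forest in
  C++, calibration, humanizer, evaluation, CLI).
- `inst/extdata/therapeutic_overlap_panel.csv` — 25-therapeutic benchmark
  panel of per-chain overlap metrics used by the aggregate checks.
- `tests/testthat/` — unit, property and acceptance suites.
- `vignettes/humanization-methods.Rmd` — the methods vignette: model,
  assumptions, parameter choices, and what the synthetic benchmark does and
  does not establish.
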