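# mcfnet

Data-driven composite metabolic pathways for cancer classification and
survival prediction.

## The problem

Cancer rewires cellular metabolism through routes that cut across the
curated "canonical" pathway boundaries of genome-scale reconstructions,
which is why aggregating gene expression by canonical pathway often
fails to beat single-gene classifiers. `mcfnet` keeps the *structure* of
the metabolic network — metabolites, reactions, gene-protein-reaction
(GPR) rules — but learns its own pathway decomposition from data:

1. **Rank-transform** expression within each sample and evaluate every
   reaction's GPR rule on the ranks (`and` → `min`, `or` → `max`),
   giving each patient a personal edge-weighted metabolite digraph.
2. **Seed reporter metabolites**: substrates of at least *k* = 5
   differentially expressed reactions (two-sided Wilcoxon rank-sum,
   α = 0.05, Bonferroni).
3. **Heaviest distances**: for each seed *s*, the maximum over simple
   directed paths of the summed edge weights, budgeted at ≤ *D* = 6
   edges with the first reaction required to be differential.
4. **Composite pathways**: the *L* = 10 targets whose heaviest distance
   from *s* separates cancer from normal samples with the smallest
   rank-sum p-values; the distances are that seed's feature vector.
5. **Ensemble SVM**: one SVM per seed; majority vote classifies, and
   score(x) = Σᵢ fᵢ(x) (the summed decision values) drives ROC/AUC.

For survival, trained pathway definitions transfer to an unseen cohort
without re-selection. Pathways split into P꜀ (mean weight higher in
cancer) and Pₙ (higher in normal) on the labeled training cohort, and
each patient is scored by

    score(patient_i) = Σ_{p∈Pc} weight_i(p) / Σ_{p∈Pn} weight_i(p)

— evaluated by Kaplan-Meier curves of the score extremes (top vs bottom
10%), log-rank tests, per-pathway FDR screening, and the concordance
index.

Who it is for: computational biologists studying metabolic rewiring who
want network-informed expression features, and methods developers who
need a fully testable reference implementation with a synthetic-data
generator (planted differential chains, score-coupled survival) so every
stage runs without downloads.

## Worked example

```r
library(mcfnet)

spec  <- simulation_spec(seed = 0)     # 60 metabolites, 120 reactions,
model <- make_toy_model(spec)          # 10 planted chains, 50+50 samples
#> Metabolic model: 60 metabolites, 120 reactions, 98 genes, 8 pathway labels

sim <- simulate_expression(model, spec)
rxn <- reactions_from_genes(rank_transform(sim$expr), model)
de  <- differential_reactions(rxn, sim$labels)
head(find_seeds(de, model), 3)
#>   metabolite count selected
#> 1    seedM_c    11     TRUE
#> 2     bg01_c     6     TRUE
#> 3     bg06_c     6     TRUE

graph <- to_digraph(model)
ens   <- train_mcf(model, graph, rxn, sim$labels)
#> MCF ensemble: 3 per-seed SVMs (seeds: seedM_c, bg01_c, bg06_c)
head(ens$members[["seedM_c"]]$feature_set$targets, 3)
#>     target            p    direction
#> 1 sink02_c 1.097985e-17 up_in_cancer
#> 2 sink04_c 1.483564e-17 up_in_cancer
#> 3 ch04_2_c 2.514473e-17 up_in_cancer

cv <- cross_validate(mcf_trainer(model, graph, rxn, sim$labels),
                     sim$labels, eval_protocol(3, 5, seed = 1))
#> CV result: 3 repetitions x 5 folds; mean AUC 1.000, mean accuracy 1.000
```

The planted seed (`seedM_c`) tops the seed table with 11 differential
substrate reactions; its selected targets are the planted chain sinks,
all flagged `up_in_cancer` (the planted shift raises their formation in
cancer); and balanced repeated cross-validation — with seeds and targets
re-selected inside every training fold — separates the groups perfectly
at the default effect size (δ = 3σ₀). The two extra seeds are genuine
rank-displacement effects, not false positives of the test: pushing 30
planted genes up inevitably pushes other genes' within-sample ranks
down.

Coupling survival to the ensemble score and evaluating:

```r
sc   <- mcf_score(ens, mcf_features(ens, graph, rxn))
surv <- simulate_survival(sc, beta = 1, censor_rate = 0.2, seed = 2)
km   <- km_extremes(sc, surv, fraction = 0.10)
concordance_index(sc, surv)
#> log-rank p = 2.97e-06, delta-AUC = 0.715, C-index = 0.806
```

High-score (cancer-like) patients fail markedly earlier, as built into
the simulation.

A command-line wrapper covers the same pipeline:

```sh
exec/mcf simulate --out run/ --seed 0
exec/mcf train    --out run/ --model run/model.json \
                  --expression run/expression.tsv --labels run/labels.tsv
exec/mcf evaluate --out run/ --model run/model.json \
                  --expression run/expression.tsv --labels run/labels.tsv --reps 5
```

See `vignettes/composite-pathway-methods.Rmd` for the model, parameter
meanings, numerical choices, and what the synthetic generator does and
does not emulate.

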