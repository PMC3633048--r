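# ontoeval

An R package for evaluating ontology-based gene-function predictions.
It is aimed at people who run or study community assessments of function
prediction (CAFA-style): given an ontology (OBO), gold-standard and prior
annotations (GAF 2.x with evidence codes), and per-algorithm prediction
submissions (target / term / score triples), it computes the standard
assessment metrics, the null baselines those metrics must be compared
against, and ships a fully seeded synthetic-benchmark generator so the
whole pipeline is testable with known ground truth and no downloads.

## What it computes

All comparisons follow the true-path rule: annotated or predicted term
sets are replaced by their reflexive `is_a` ancestor closure before
scoring, and predicted scores propagate upward by the max rule (explicit
submissions keep their value).

- **Gene-centric score** — per-gene precision/recall over closed sets,
  swept across submitted score thresholds and summarized by step-wise
  average precision, AP = Σᵢ Pᵢ (Rᵢ − Rᵢ₋₁), then averaged across targets.
  The package also reproduces this metric's known degeneracy: predicting
  only the namespace root is always perfectly precise and scores
  1/|truth closure| per gene.
- **Term-centric AUROC** — for each gold term with 10–100 member genes,
  the Mann–Whitney AUROC of the gene ranking, mid-ranks for ties,
  non-predictions tied at the bottom. The prevalence null scores exactly
  0.5 on every term.
- **Informativeness** — IC(t) = −log₂ p(t) over a closed prior corpus;
  Resnik (IC of the most-informative common ancestor) or Lin similarity
  between a predictor's top-N terms and the truth; a prediction is
  informative only if it strictly beats τ, the best score the prevalence
  null ever achieves on the evaluation set.
- **Baselines** — prevalence (corpus term frequencies, identical for all
  genes), root-only, IEA carry-forward (pre-existing weak-evidence
  annotations at score 1.0), per-species term incidence.
- **Aggregation** — the naive average-normalized-rank combiner, along
  either axis (terms within gene, or genes within term).
- **Synthetic worlds** — layered random ontologies, heavy-tailed
  annotation corpora with evidence codes and species labels, a
  waiting-period gold-standard update with a tunable confirmation-bias
  upgrade mechanism, and simulated predictor families (noisy oracle,
  homology copy, prevalence mimic, binary oracle), all bit-reproducible
  from one integer seed.

See `vignettes/assessment-methods.Rmd` for the model, parameter and
design details.

## Worked example

```r
library(ontoeval)

world  <- generate_benchmark_world(seed = 42, n_terms = 100,
                                   n_genes = 400, n_targets = 60)
world
#> benchmark_world (seed 42): 200 terms, 400 genes, 60 evaluation targets,
#>   5 predictors [noisy_oracle_0.1, noisy_oracle_0.4, homology_copy,
#>   prevalence_mimic, binary_oracle]

report <- evaluate_world(world, namespace = "BP")
report
#> evaluation_report: 41 genes, 8 evaluable terms, tau = 1.264
#>         algorithm n_genes   mean_ap mean_auroc informativeness_rate      tau
#>  noisy_oracle_0.1      41 0.9503608  0.9783915            0.8048780 1.263881
#>  noisy_oracle_0.4      41 0.7209589  0.8399137            0.7317073 1.263881
#>     homology_copy      41 0.1339375  0.5453673            0.5365854 1.263881
#>  prevalence_mimic      41 0.5298129  0.5000000            0.0000000 1.263881
#>     binary_oracle      41 0.7849629  0.8850541            0.7073171 1.263881
#>        prevalence      41 0.5298129  0.5000000            0.0000000 1.263881
#>  iea_carryforward      41 0.3086504  0.6431608            0.5853659 1.263881
```

Reading the table: 41 of the 60 updated targets gained terms in the BP
namespace. `mean_ap` is the gene-centric score averaged across those
targets; the prevalence null reaches a respectable-looking 0.53 *by
construction* — which is exactly why the metric cannot be read in an
absolute sense. `mean_auroc` is averaged over the 8 evaluable terms, and
prevalence sits at exactly 0.5 there. `informativeness_rate` is the
fraction of genes whose best top-10 prediction strictly beats the
prevalence threshold τ = 1.26 bits; the oracles dominate, the prevalence
mimic is 0 by construction, and the carry-forward baseline is competitive
without using anything but the pre-existing weak annotations.

The same pipeline runs from the shell on serialized files:

```sh
Rscript inst/cli/ontoeval.R simulate --seed 42 --out-dir world/
Rscript inst/cli/ontoeval.R evaluate --obo world/ontology.obo \
    --gaf-before world/corpus_before.gaf --gaf-after world/gold_update.gaf \
    --namespace BP --out-dir report/ world/pred_*.tsv
Rscript inst/cli/ontoeval.R baseline --obo world/ontology.obo \
    --gaf world/corpus_before.gaf --kind prevalence --out prevalence.tsv
```

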