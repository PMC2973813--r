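# parabuffer

Genetic buffering between duplicate genes: a tested R pipeline for asking
whether yeast paralogs back each other up, why, and for how long.

## The problem

When one copy of a duplicated gene pair is deleted and the cell barely
notices, the usual suspect is the sister paralog quietly compensating. In a
quantitative double-mutant screen this *backup capacity* shows up as a
significant aggravating (negative) genetic-interaction score ε between the
two paralogs: the double mutant is much sicker than the single mutants
predict. `parabuffer` is for researchers in molecular evolution and systems
biology who have (or simulate) pair lists, interaction scores, GO
annotations, coding sequences, expression profiles and network data, and
want the full analysis chain:

* **Buffering calls and nulls** — a pair buffers iff ε < 0 and p < α
  (default 0.05); prevalence and mean strength are calibrated against two
  randomization protocols (random assayed pairs; randomly re-paired
  duplicate genes), with empirical p-values.
* **GO-div** — a best-match semantic divergence between two genes' GO
  Biological Process annotation sets. With p(x) the probability of sampling
  term x or any descendant from the corpus, term similarity is Lin's

      T(m, n) = 2 ln p(x*) / (ln p(m) + ln p(n)),

  x* the most informative common ancestor, and

      GO-div(A, B) = 1 - max_{i in A, j in B} T(i, j).

  One shared specific function drives GO-div to 0 no matter how much else
  has diverged — overlap, not global similarity.
* **Divergence** — Nei–Gojobori (1986) Ka/Ks with Jukes–Cantor correction
  (precomputed Ka/Ks columns take precedence when supplied), aligned
  protein identity, and expression divergence 1 − r.
* **Neutral decay** — Gaussian-KDE bimodality of Ks among buffering pairs,
  OLS of strength on Ks (Ks ≤ 2, saturation-filtered), and partial
  correlations r(Ks, strength | Ka) vs r(Ka, strength | Ks).
* **Prediction** — an RBF-kernel decision function over
  [Ka, identity, expression divergence, GO-div], stratified repeated 3-fold
  CV with inner hyperparameter search, rank-statistic ROC/AUC.
* **Structure & network** — secondary-structure transition vectors compared
  by Jensen–Shannon discrepancy D; shared-PPI-partner fractions with a 2×2
  chi-square test; protein-complex co-clustering fractions.
* **Synthetic world** — `synth_config()` / `generate_pairs()` /
  `write_fixture_bundle()` generate every input format (OBO, GAF, TSV,
  FASTA, 2-line secondary structure) with the statistical structure the
  analysis assumes planted at stated rates, so everything is testable
  offline.

## Worked example

```r
library(parabuffer)

cfg    <- synth_config(seed = 42)          # the stated synthetic world
report <- run_pipeline(config = cfg, n_controls = 1000,
                       cv_repeats = 10, seed = 42)
print(report)
#> <pipeline_report>
#>   SSD: 43/228 buffering (18.9%), mean strength -0.423, p(null) 0.000999
#>   WGD: 104/266 buffering (39.1%), mean strength -0.419, p(null) 0.000999
#>   random-pair null: 7.22% negative
#>   duplicate-shuffle null: 8.18% negative
#>   prediction: AUC 0.859 +/- 0.021 (GO-div alone 0.859)
#>   neutral mode: slope 0.425 (n = 13), r(Ks,strength|Ka) = 0.99 (p 4.49e-09), r(Ka,strength|Ks) = -0.41 (p 0.181)
```

Reading it: ~39% of WGD and ~19% of SSD pairs buffer, against a ~7% random
background (empirical p = 1/1001, the add-one floor at 1,000 controls) —
buffering is prevalent and strong. The classifier separates buffering from
non-buffering pairs well above chance, and GO-div alone carries essentially
all of the signal. Among unsaturated buffering SSD pairs, strength decays
with Ks at ~0.43 per Ks unit; the decay tracks synonymous (background)
divergence after controlling for Ka, while Ka given Ks shows nothing —
the neutral-decay signature. The duplicate-shuffle null sits slightly above
the 6.6% planted cross-duplicate rate because re-pairings that regenerate
true duplicate pairs are counted (see the methods vignette).

Individual stages are plain functions — e.g.

```r
dag    <- parse_obo("ontology.obo")
corpus <- parse_gaf("annotations.gaf", dag)   # aspect P, IEA excluded
go_div(dag, corpus, "YGL194C", "YNL330C")$go_div

est <- ka_ks_ng86(seq_a, seq_b)               # NG86 + Jukes-Cantor
partial_correlation(ks, strength, ka)
```

A command-line wrapper is installed as `exec/parabuffer`
(`parabuffer synth|godiv|buffering|predict|run ...`); see
`?parabuffer_cli`.

## Vignette

`vignettes/parabuffer-methods.Rmd` documents the model and its assumptions,
every tunable parameter with its default and rationale, what the synthetic
generator does and does not emulate, numerical edge cases, and known
limitations (notably the NG86 bias beyond Ks ≈ 1).
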