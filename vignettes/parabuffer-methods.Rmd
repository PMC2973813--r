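---
title: "Methods: genetic buffering between duplicate genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genetic buffering between duplicate genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The question

Budding yeast retains hundreds of paralogous gene pairs from a whole-genome
duplication (WGD) and from small-scale duplications (SSD). Deleting one copy
of such a pair often has little phenotypic consequence, which is commonly
attributed to *genetic buffering*: the sister paralog compensates. In a
quantitative double-mutant screen this buffering appears as a significant
*aggravating* (negative) genetic interaction ε between the two paralogs —
the double deletion grows much worse than expected from the two single
deletions. `parabuffer` implements the analysis chain that takes a pair
list, an interaction table, GO annotations, coding sequences, expression
profiles and network/structure data, and asks:

1. How prevalent and how strong is buffering among WGD and SSD pairs,
   relative to randomization nulls?
2. Is functional overlap (rather than global profile similarity) the
   determinant of buffering, and can buffering be predicted from divergence
   features?
3. Does buffering decay neutrally — in proportion to synonymous divergence
   Ks, a clock for background mutations — or is it stabilized by selection?
4. What structural and network properties mark pairs whose buffering
   survived long-term?

# Buffering calls and nulls

A pair buffers iff its interaction score is negative **and** its per-pair
p-value is below `alpha` (default 0.05). Strength is the score itself; more
negative means stronger backup. Two null protocols calibrate prevalence:

* **Random-pair null** — each of 1,000 control groups samples 1,000 assayed
  pairs uniformly without replacement; the percentage with negative score
  and the mean score among negative pairs form the null ensembles.
* **Duplicate-shuffle null** — all genes that belong to duplicate pairs are
  randomly re-paired (disjointly within a control); pairings present in the
  interaction table are scored the same way. A shuffle that regenerates a
  true duplicate pair is allowed and counted — no exclusion is applied, so
  in a dense table this null sits slightly above the cross-pair background
  rate.

Empirical p-values use the add-one rule `(k + 1) / (n + 1)`. Sampling is
without replacement within a control and controls are independent; the seed
is a mandatory argument everywhere randomness enters. The significance of
mean-strength differences is additionally available through a two-sample
rank test, which is the default because the underlying test behind such
comparisons is not standardized.

# GO-div: best-match semantic divergence

Only the Biological Process (BP) branch of the Gene Ontology is used
(Cellular Component is not a functional indicator; Molecular Function is
implicitly covered by BP), and electronically inferred annotations
(evidence code IEA) are excluded. The specificity of a term $x$ is the
probability $p(x)$ of drawing $x$ *or any of its recursive descendants*
from the annotation corpus; $p(\text{root}) = 1$ and the information
content is $-\ln p(x)$.

Term–term similarity uses the most informative common ancestor (MICA)
$x^*$, the shared ancestor (including the terms themselves when one
subsumes the other) with minimal $p$, under Lin's normalization:

$$T(m, n) = \frac{2 \ln p(x^*)}{\ln p(m) + \ln p(n)} \in [0, 1].$$

Three properties pin this choice down: the numerator is the information
content of the most specific shared parent, the denominator scales the
score to $[0, 1]$, and two terms meeting only at the root get $T = 0$. Both
Lin's and max-IC normalization satisfy these; Lin is the default because it
matches the Lord-style protocol this score family descends from, and the
max-IC alternative is available via `normalization = "max_ic"`. Logs are
natural; $T$ is base-invariant.

The pair score is computed over all cross pairs of the two genes'
annotation sets:

$$\mathrm{GO\text{-}div}(A, B) = 1 - \max_{i \in A,\, j \in B} T(i, j).$$

Only the best-matched term pair enters, so one shared *specific* function
drives GO-div to 0 no matter how many other functions have diverged — this
is what distinguishes functional *overlap* from global functional
*similarity*. Ties in the maximum are irrelevant by construction. A gene
without qualifying annotation excludes its pair with an explicit
`unannotated` status; it is never silently scored.

Two counting conventions exist for $p(x)$: de-duplicated annotation rows
(default; the corpus is a collection of annotations) or distinct genes per
term (`count_mode = "gene"`). Both propagate every direct annotation to all
ancestors, so counts are monotone from child to parent.

# Sequence and expression divergence

Ka and Ks (nonsynonymous / synonymous substitutions per site) are estimated
with the Nei–Gojobori (1986) pathway method: per-codon synonymous site
fractions (changes to stop codons count as nonsynonymous), equal-weight
averaging over mutational pathways for codons differing at 2–3 positions
(pathways through stops discarded), and Jukes–Cantor correction
$d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$. A proportion $p \ge 3/4$ leaves
the estimate undefined; `ks > 2` flags saturation, and the neutral-decay
regression discards such pairs. When a table already carries Ka/Ks columns
(e.g. from a maximum-likelihood tool), those take precedence over
re-estimation — the NG86 estimator exists so that the pipeline and its
tests need no external binary.

*Known limitation:* NG86 with JC correction overestimates divergence once
Ks approaches 1 — two-fold degenerate sites saturate faster than the JC
model assumes, and multi-hit codons mix difference classes across pathways.
Planted-recovery tests show median relative error of a few percent up to
Ks ≈ 0.5, rising to ~10–16% at Ks = 1. This is a property of the method,
shared by any faithful implementation, and is the reason the decay analysis
caps Ks at 2.

Protein identity is the fraction of aligned columns holding at least one
residue in which both sequences agree. Expression divergence is
$1 - r$, the Pearson correlation of the two expression profiles across
shared conditions (549 in the default synthetic world); a zero-variance
profile yields an explicit `zero_variance` status rather than a number.

# Neutral decay of buffering

If buffering erodes neutrally, its strength should scale with the amount of
background mutation — approximated by Ks — rather than with protein
divergence per se. Three instruments test this on buffering SSD pairs:

* **Ks density** — a Gaussian-kernel density estimate with Silverman's
  rule-of-thumb bandwidth (configurable; the method itself only requires a
  Gaussian window) on a 512-point grid spanning the data ± 3 bandwidths.
  Modes are strict local maxima filtered by topographic prominence of at
  least 1% of the density maximum, suppressing noise wiggles. A bimodal Ks
  density separates young transient pairs (left peak) from ancient,
  selectively stabilized ones (right peak, Ks > 2).
* **Regression** — OLS of strength on Ks over pairs with Ks ≤ 2; the slope
  is the strength lost per unit Ks.
* **Partial correlations** — $r_{xy\cdot z} = (r_{xy} - r_{xz} r_{yz}) /
  \sqrt{(1 - r_{xz}^2)(1 - r_{yz}^2)}$ with a two-sided t-test on $n - 3$
  degrees of freedom. Under neutral decay, Ks correlates with strength
  given Ka, while Ka given Ks does not. All p-values in the package are
  two-sided; sidedness is never assumed from the hypothesis.

# Predicting backup capacity

Each pair is a feature vector `[Ka, identity, expression_divergence,
GO-div]` with the buffering flag as label; WGD and SSD are pooled. The
classifier contract is a kernel decision function: higher score, more
likely buffering. It is implemented as regularized kernel least squares
(the least-squares formulation of the soft-margin kernel machine) with an
RBF kernel — no SVM library is assumed — and hyperparameters
$\gamma \in \{0.01, 0.1, 1, 10\}$, $C \in \{0.1, 1, 10, 100\}$ chosen by an
inner stratified 3-fold AUC search on the training folds only. Features are
z-standardized with training-fold statistics only; the test fold never
touches standardization or hyperparameter choice (a planted pure-noise
world yields chance AUC, which the tests assert). Outer CV is stratified
3-fold, repeated (default 10 draws) to give the AUC mean ± sd, since a
single 3-fold split yields only three AUC values. AUC is the rank
(Mann–Whitney) statistic with ties counted ½.

# Structure and network properties

Secondary structures (helix/strand/coil; extended codes mapped G,I→H, B→E,
T,S,'-'→C) are encoded as the nine first-order transition probabilities
among states. The dissimilarity $D$ between two such vectors — the cited
"information discrepancy" whose exact formula is not reproducible from the
source — is implemented as the Jensen–Shannon divergence of the
pseudocounted (1e-6), renormalized 9-vectors: symmetric, non-negative,
bounded by ln 2, zero iff equal. The formula choice is recorded in the
result's `method` attribute.

A pair *shares a partner* when its genes have a common network neighbor
other than themselves — the pair's own A–B edge does not count, since
physical interaction and shared partnership are different claims. Group
comparisons use a 2×2 chi-square test of independence without continuity
correction at these sample sizes (configurable). A pair *co-clusters* when
both genes belong to at least one common annotated complex; complexes need
≥ 2 members.

# The synthetic world

`synth_config()` fixes a stated world whose defaults are the conditions the
analysis targets: 266 WGD and 228 SSD assayed pairs; buffering rates 39.5%
and 18.4%; a 7% negative rate among random assayed pairs and 6.6% among
cross-duplicate pairings; WGD strength `N(-0.42, 0.15)` truncated negative
(WGD backup is stabilized, with no Ks dependence — its Ks is saturated,
`N(3.5, 0.5)` above 2); SSD buffering strength following
`0.41·Ks − 0.8 + N(0, 0.05)` below the Ks = 2 saturation point and a
stabilized `N(-0.33, 0.2)` beyond it; an SSD Ks mixture with a young peak
at 0.18 (sd 0.05, weight 10/42, with a 30% uniform tail toward 2 so the
decay regression has leverage across the unsaturated range) and an ancient
peak at 3.0 (sd 0.5); 549 expression conditions; shared-partner rates
0.62/0.40 and co-clustering rates 0.18/0.065 for buffering/non-buffering
pairs. Buffering p-values are Uniform(0, 0.05) and non-significant ones
Uniform(0.05, 1), since the analysis treats p only as a threshold.

GO annotations are planted over a layered random DAG (1–2 parents per term,
branch-preserving, so distinct top-level branches meet only at the root):
each pair shares an ancestor whose depth is drawn deep-biased for buffering
pairs and shallow-biased (or root-only) for non-buffering pairs, with the
two genes annotated to distinct deep descendants of that ancestor plus
private noise terms. GO-div then decreases stochastically with planted
overlap depth. Codon alignments are produced by drawing a sense-codon
ancestor and applying `round(Ks·S)` synonymous and `round(Ka·N)`
nonsynonymous point substitutions at uniformly random opportunities, split
between the two descendants — multiple hits arise naturally, so the JC
correction is exercised rather than assumed.

What the generator does **not** emulate: realistic yeast gene names or
codon usage, the SGA measurement process behind the scores, annotation
incompleteness bias, correlated measurement error between features, or a
genome-scale interaction matrix (the "genome" is a 20,000-pair background
plus 20,000 cross-duplicate pairs). A green end-to-end test therefore
establishes that the pipeline recovers planted statistical structure of the
stated shape and magnitude — not that it would reproduce any particular
empirical dataset.

One consequence of faithfulness worth noting: because the bundled
interaction table is small and duplicate-dense, and re-paired duplicates
that regenerate true pairs are counted, the duplicate-shuffle null on the
default bundle sits ~1–1.5 points above the planted 6.6% cross-duplicate
rate. The planted rate itself is recovered on a dedicated fixture with
complete cross coverage, which is what the acceptance suite checks.

# Numerical choices and degenerate inputs

* Ties in the MICA (equal minimal $p$) are broken arbitrarily; $T$ is
  tie-invariant. A term with $p = 1$ that is not the root is treated like
  the root (zero information).
* Duplicate unordered pairs in an interaction table collapse to the most
  significant record; out-of-range rows are rejected and counted.
* `empirical_p` never returns 0 (add-one rule).
* Zero-variance inputs: correlation and KDE raise classed errors;
  expression divergence returns a status.
* Constant feature columns are retained with a warning (they standardize to
  zero and carry no weight).
* KDE on fewer than 5 values, regression on fewer than 3 unsaturated pairs,
  partial correlation with a controlling correlation of ±1 — all classed
  errors naming the cause.
* All randomized procedures take explicit seeds and restore the caller's
  RNG state.

# Limitations

GO-div inherits annotation incompleteness: it measures overlap *within
current knowledge*. The NG86 stand-in should not be quoted beyond Ks ≈ 1
(see above); for publication-grade Ka/Ks use a codon-model tool and feed
the values in through the precomputed columns. The kernel classifier is a
contract-compliant stand-in for an SVM; decision values are not calibrated
probabilities. The pipeline consumes alignments and secondary-structure
strings as inputs — it aligns nothing and predicts no structures.
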