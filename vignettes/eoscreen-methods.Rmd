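---
title: "From docking score tables to essential-oil target profiles: methods and design notes"
author: "eoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From docking score tables to essential-oil target profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eoscreen)
```

## The problem

Essential oils (EOs) are mixtures of dozens to hundreds of volatile plant
metabolites — mostly mono- and sesquiterpenes — and many of them kill or
disrupt insects. Working out *which* insect proteins an oil hits
(acetylcholinesterase, GABA-A and octopamine receptors, the
methoprene-tolerant juvenile-hormone receptor, the juvenile-hormone binding
protein, the ecdysone nuclear receptor, ...) is hard precisely because an
oil is a mixture: the unit of evidence is a docking score for one compound
against one target, but the unit of interest is the whole oil.

`eoscreen` implements a consensus virtual-screening post-processing
protocol that bridges that gap. Its inputs are ordinary artifacts of a
docking campaign — long-form score tables over several scoring functions
and several homology models per target, compound structures/fingerprints,
molecular descriptor tables, actives/decoys validation labels — plus the
gas-chromatographic (GC) composition of each oil. Its outputs are (a)
archetypal chemical clusters of strong target binders, (b) a binary
compound-by-target likelihood matrix, and (c) a predicted target-action
profile for each whole oil. A separate module quantifies larval motility
from bioassay videos with a cosine-distance statistic, closing the loop
between prediction and experiment.

## The procedure, stage by stage

### Score aggregation as a block design

Each target is represented by several homology models built with different
tools; each ligand is docked to each model and rescored by several scoring
functions. We treat this like a randomized complete block design: the
model is a block, the ligand a treatment, the docked pose a repetition.
Per (ligand, target, function) the package takes, within each model,
either the best pose score or the mean of the three best poses, and then
averages across models. "Best" is always routed through the function's
declared orientation (`lower_is_better` for energy-like scores), so
functions with opposite sign conventions coexist. Ligands missing from
some models (an unbalanced block) are averaged over the models that have
them, with a warning — dropping them would silently bias the ranking
against compounds that failed in a single model.

A genuinely open reading here was whether the top-three mean pools poses
across models or averages poses within a model first; the block
interpretation (poses within model, then mean over models) is what the
design metaphor implies, and it is what `aggregate_scores()` does.

### Scoring-function validation

Not every scoring function ranks true binders of a given target well, so
each (function, aggregation mode) pair is validated against known actives
and property-matched decoys:

* **ROC AUC** — computed from midranks, so it equals the Mann–Whitney
  probability that a random active outranks a random decoy, ties counted
  one half.
* **Enrichment factor** — for a screened fraction $x$ of the ranked list
  of $N$ compounds with $A$ actives,
  $EF(x) = \frac{a(x) / n(x)}{A / N}$, where $n(x) = \lceil xN \rceil$ and
  $a(x)$ counts actives in that top slice. The ceiling rule is a
  deliberate choice (any rounding convention works; the ceiling keeps
  $EF(1) = 1$ exact and never evaluates an empty slice), and ranked lists
  are sorted by (goodness, ligand id) so cuts are deterministic under
  ties.

A function is retained when AUC $\ge 0.5$ **and** its EF maximum is first
attained within the first 5% of the database — i.e. it must both rank
globally better than chance and enrich early, where a prospective screen
actually looks. Both thresholds are arguments of `select_functions()`. A
`force_include` override exists because practitioners sometimes keep a
function that enriches early despite a poor global AUC (early enrichment
is the operationally relevant half of the rule); the rule itself is never
silently relaxed.

### Consensus hit selection by successive k-means

For one target, each ligand becomes an $N$-vector of standardized goodness
values over the $N$ selected functions. `iterative_kmeans_select()` then
repeatedly k-means-clusters the surviving ligands ($k = 3$ by default),
keeps the cluster whose centroid has the highest mean standardized
goodness, re-standardizes, and repeats until 8–12 unique ligands remain,
counting enantiomer pairs (same stereochemistry-stripped structure key) as
one ligand. Design choices worth recording:

* $k = 3$ because $k = 2$ shrinks the surviving set too slowly on
  heavy-tailed score distributions; $k$ is configurable.
* "Best combination of scores" is read as the highest centroid mean across
  dimensions; a `worst_dimension` strategy (max–min) is available behind a
  flag for users who want consensus in the strict sense.
* Re-standardizing each iteration matters: after the first cut every
  survivor is good, and without re-standardization the vectors lose
  discriminating power.
* If a step would overshoot below 8 unique ligands, the previous set is
  kept and trimmed to 12 unique ligands by mean rank — a deterministic,
  monotone fallback.
* k-means runs with seeded initialization and 10 restarts, so the whole
  selection is bit-reproducible given (inputs, seed).

A simpler selector, `top_fraction_hits()` (the top 1% by mean rank over
the selected functions), is provided alongside. The two selectors answer
the same question at different strictness, and sources describing this
kind of protocol do not always agree on which was used where; the package
exposes both and records which one produced each hit set rather than
pretending the choice away.

### Archetype clustering

Per-target hit sets are pooled (duplicates removed by canonical structure
key) and clustered hierarchically on the pairwise Tanimoto distance
$1 - |A \cap B| / |A \cup B|$ over fingerprint bits. Average linkage
(UPGMA) is the default — the common choice for Tanimoto distances, whose
ultrametric distortion under complete/single linkage is well known — and
the tree is cut at a distance cutoff. When no cutoff is given,
`choose_cutoff()` scans a grid and keeps the value maximizing the mean
silhouette width of the induced partition (ties to the smaller cutoff,
which by construction lands just above the within-cluster merge scale).
Silhouette maximization is our stand-in for a cutoff-selection step that
protocols of this kind usually tune by inspection; it is deterministic and
auditable, which inspection is not.

Clusters get stable ids `C01`, `C02`, ... in order of first member
appearance, so relabeling the input order permutes nothing.

### Similarity matrices: EPNMCS and BDSTFL

Two compound-by-cluster similarity matrices connect new compounds (the GC
compounds of the oils) to the archetypes:

* **EPNMCS** (Euclidean proximity, normalized, in cheminformatics space).
  Descriptors are z-scored per column ($z = (x - \bar{x}) / s$, sample sd,
  `ddof = 1`; constant columns are dropped with a warning). Each cluster's
  centroid is the mean of its members' z-vectors; compound-to-centroid
  Euclidean distances are divided by the largest distance in the batch and
  proximity is one minus that ratio, so values live in $[0, 1]$ with the
  farthest pair at exactly 0. The normalizing constant is recorded and can
  be frozen so later batches are scored on the same scale.
* **BDSTFL** (fuzzy Tanimoto degrees of belonging). The membership of
  compound $i$ in cluster $c$ is the mean (optionally max) Tanimoto
  similarity between $i$ and the members of $c$, with rows rescaled to sum
  to one. This matrix's exact construction is the least constrained part
  of the protocol we re-implement — the name promises fuzzy degrees of
  belonging over Tanimoto similarities but not the linkage statistic or
  normalization — so the package documents its choice (mean linkage, row
  normalization, uniform fallback for all-zero rows) and keeps the
  alternatives behind arguments rather than presenting one variant as
  canonical.

### Association matrices, validation, likelihood

Two cluster-by-target matrices summarize where each target's hits live:
Matrix 1 is the fraction of a cluster's members that are hits for the
target (the cluster's affinity signature); Matrix 2 is the fraction of a
target's hits falling in the cluster (the target's specificity), whose
columns sum to one by construction. Multiplying a similarity matrix by an
association matrix yields compound-by-target scores; all four products are
computed, and each is validated against mean docking rank by OLS: the
package reports $r^2$, $F = (n-2)\,r^2/(1-r^2)$, and the slope sign
(negative slope = higher similarity predicts better rank, the direction a
working protocol must show). The score axis is additionally split into 0.1
bins and a one-way ANOVA with Tukey HSD assigns compact letter groups, the
statistical justification for cutting the score into "signature" and
"no signature" classes. The binary likelihood matrix applies a strict
`score > 3.01` cut by default; the boundary is configurable, and the
half-open gap between "higher than 3.01" and "lower than 3.00" in the
protocol's stated rule is resolved as the strict inequality.

One scale caveat, flagged rather than resolved: EPNMCS entries are bounded
by 1, so a product score only exceeds 3 when a compound is proximate to
several clusters that all carry weight for the target. With few, clean,
well-separated clusters (as in our synthetic studies) product scores stay
far below 3 and the default cut yields an all-zero likelihood matrix —
which is the honest answer on such geometry, not a failure mode. Users
with small cluster counts should examine the binned ANOVA and set the
threshold on their own score scale.

### Essential-oil profiles

An oil's predicted action on a target is the composition-weighted sum
$\sum_i f_{s,i} \, W_{i,t}$ over its GC compounds, where $f_{s,i}$ are
area fractions (percent inputs are auto-detected and divided by 100) and
$W$ is the binary likelihood matrix (default) or the continuous product
score (both weightings are implemented because the bounded binary dot
product cannot exceed 1 while continuous product scores can — profiles on
the two scales answer slightly different questions, and the output records
which one was used). Compounds missing from $W$ reduce the reported
coverage instead of being silently imputed; a species with zero matched
coverage is an error, not a zero.

### Larval motility

Bioassay videos (stabilized, fixed fps — upstream concerns) become stacks
of binarized frames: Otsu's threshold is computed on the first frame and
frozen for the stack, so motility is not confounded by per-frame threshold
drift. Motility is the mean cosine distance
$1 - a \cdot b / (\lVert a \rVert \lVert b \rVert)$ between consecutive
flattened frames — scale-free, hence robust to larva size and pixel count,
unlike a Euclidean frame difference. Conventions for empty frames: both
empty → 0 (nothing observable moved), exactly one empty → 1 (appearance or
disappearance is maximal change). `windowed_pearson()` correlates motility
with other endpoints (pupation rate, pupae volume, deformed-and-dead
counts) inside closed concentration windows.

## The synthetic-data generators

Every input class has a seeded generator, so the full pipeline runs and is
tested with no external data:

* **Benchmarks** — decoy scores $\mathcal{N}(\mu_0, 1)$, active scores
  $\mathcal{N}(\mu_0 - \delta, 1)$ per (target, function, model, pose),
  lower better, defaults $\mu_0 = -6.5$ kcal/mol-like, $\delta = 2.5$,
  50 actives / 950 decoys. With one model and pose the theoretical AUC is
  $\Phi(\delta/\sqrt{2}) \approx 0.96$, which the tests verify empirically
  at 2000 per class.
* **Scaffold families** — each family has a base fingerprint (ones-density
  $2b/(1+b)$ so unrelated bases sit at the between-family Tanimoto target
  $b = 0.2$); members flip a bit count calibrated analytically so expected
  within-family similarity is 0.6. Family bases depend only on the seed,
  so hit compounds and EO compounds drawn separately still share scaffold
  identity. Descriptor vectors scatter (sd 0.3) around orthogonal
  centroids 3 units apart.
* **Planted score tables** — 651 ligands by default; each target's planted
  top ligands (one family's members) get all functions shifted 3 sd
  toward better scores.
* **Chromatograms** — Dirichlet(1) fractions over a random compound
  subset, summing to one.
* **Frame stacks** — a disc (diameter 9 px) jumping a configurable number
  of pixels per frame along a bouncing path that never touches the border;
  jump 0 gives motility exactly 0, jump ≥ diameter exactly 1, and motility
  increases monotonically in between.

What the generators deliberately do **not** emulate: real molecular
structures (families are statistical stand-ins, not valid chemistry),
correlated scoring-function errors, descriptor collinearity, multi-larva
videos, or chromatogram measurement error. Passing tests therefore
demonstrate that the machinery is correct and calibrated on known
structure — not that any particular real oil's predictions are right.

## Numerical and testing choices

* Tanimoto of two all-zero fingerprints is defined as 1 (identical absence
  of features) with a warning; the cosine-distance analogues at the frame
  level are 0/1 as above.
* Deduplication at similarity 1.0 keeps the first occurrence in input
  order; ties everywhere else break lexicographically (ligand id, target
  id, lowest cluster id), so every ordering in the package is total and
  reproducible.
* The cosine denominator is computed as $\sqrt{\lVert a\rVert^2 \lVert
  b\rVert^2}$ in one square root, keeping integer mask norms exact.
* Test problem sizes are chosen to make the suite sharp but quick: oracle
  equivalence uses 500 random instances up to $n = 200$; null
  calibrations use 100 replicates; planted-recovery checks use 10 seeds,
  500-ligand score tables, 2000-per-class benchmarks, and 5 families of 8;
  the end-to-end determinism check runs the full default configuration
  (651 ligands, 8 targets, 5 functions) twice and compares output file
  hashes, excluding only the manifest, which records wall-clock timings.

## Known limitations

* The descriptor set is configuration, not contract: EPNMCS values are
  only comparable across batches when the descriptor table and the frozen
  normalizing constant are shared.
* The silhouette-chosen cutoff requires non-trivial structure; a library
  that is one tight blob (or all singletons) raises a no-structure error
  by design.
* The likelihood threshold's absolute scale depends on the number and
  overlap of clusters, as discussed above.
* Fingerprint computation from structures is delegated to a pluggable
  backend; the package's own machinery starts at bitsets, and the identity
  canonicalization backend treats distinct SMILES strings of one molecule
  as distinct unless a chemistry toolkit backend is enabled.
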