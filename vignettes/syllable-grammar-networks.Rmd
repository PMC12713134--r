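---
title: "Syllable grammar and transition networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Syllable grammar and transition networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syllograph)
```

## The problem

Depth-video motion sequencing segments the spontaneous behavior of a freely
moving mouse into a sequence of sub-second stereotyped modules — *syllables*
— each an integer label ("scrunch", "rear up", "edge racing", ...). The
syllable *grammar*, the order in which syllables follow one another, carries
disease-relevant structure that per-syllable usage alone misses. In chronic
epilepsy models, affected animals repeat behaviors more (perseveration),
acquire disease-specific fast-locomotion ("racing") syllables, and their
behavioral networks become fragile and dispersed as disease progresses.
`syllograph` implements the full sequence-and-network analysis of such
data: alternation statistics, transition networks with six node-level
measures, racing binarization, and nonparametric group statistics, plus a
synthetic cohort generator used to validate every step.

## Repetitive alternations and perseveration bouts

For a sequence $S_1,\dots,S_T$, every overlapping three-syllable window is
classified by the indicator

$$b_t = \mathbb{1}[S_t \neq S_{t+2}], \qquad t = 1,\dots,T-2,$$

so an A–B–A window ($b_t = 0$) is a *repetitive alternation* and anything
else is non-repetitive. The session-level fraction of non-repetitive
alternations is $f = \frac{1}{T-2}\sum_t b_t$. Maximal constant runs in
$b$ quantify bout structure: 0-runs are perseveration bouts, 1-runs are
stretches of flexible behavior. Because motion-sequencing output never
contains immediate self-repeats ($S_t \neq S_{t+1}$, enforced by the
`SyllableSequence` validity method), a sequence drawn uniformly at random
over $n$ syllables has chance level $\Pr(S_t = S_{t+2}) = 1/(n-1)$, which
anchors the analytic checks below. Sequences shorter than 3 emissions are
rejected, not skipped.

Per-animal distributions (of run lengths, or of any node metric) are
summarized as empirical cumulative frequency curves in percent; group-level
curves evaluate each animal's right-continuous step CDF on the union grid of
observed values and average pointwise, so averaging identical curves is the
identity.

For the run-length group comparison the package pools run lengths across
animals within a group by default and applies the two-sample
Kolmogorov–Smirnov test to the pooled samples; a per-animal-median mode is
available through the profile tables since the pooling convention is a
genuine design choice (pooling mirrors how node-level distributions are
compared elsewhere in the pipeline, but mixes animals of unequal T).

## Transition matrices and networks

Transition counts are per-animal and non-normalized: cell $(a,b)$ counts
occurrences of $a \to b$; with no exclusions the grand total is $T-1$ and
the diagonal is zero. Analysis is restricted to the syllables explaining a
coverage fraction (default 0.99) of total usage: syllables are sorted by
descending usage (ties broken by ascending id) and the smallest prefix
reaching the coverage is kept. When excluded syllables are dropped, the
surviving emissions become adjacent by default; `breakAtGaps = TRUE`
instead splits the sequence at every gap, because either convention is
defensible and the choice measurably affects edge counts.

The directed weighted network has syllables as nodes and one edge per
observed ordered transition, weighted by its frequency. For edge-count
analysis the package also provides the *replicated* multigraph view, where
an edge of weight $w$ becomes $w$ parallel unit edges; node strength is
identical in the two representations (a property-tested invariant), so the
replicated form matters only when a downstream tool counts edges rather
than summing weights.

Nodes observed in at least one network of a group and in no network of any
other group are *group-specific*; the rest are shared. On synthetic cohorts
the partition recovers the generator's ground truth exactly.

## The six node-level measures

All distance-based measures run on an explicit all-pairs shortest-path
oracle (Dijkstra from every source with shortest-path counts
$\sigma_{s,t}$). Three weight-to-distance conventions are exposed:

* `raw` (default): edge length = transition frequency. This is the
  convention of the graph library in which these measures are conventionally
  defined when handed a `weight` attribute, and therefore reproduces
  numbers computed that way, although it is semantically counterintuitive
  (frequent transitions become *long*).
* `inverse`: length = 1/frequency, treating frequency as affinity.
* `unweighted`: every edge has length 1.

The measures, per node:

* **Strength (edge count)** $s_i$: summed incident edge weight (in, out, or
  total; total is the default since the directionality used in the original
  distributions is not determinate).
* **Average neighbor degree**
  $k^w_{nn,i} = \frac{1}{s_i}\sum_{j \in N_i} w_{ij} k_j$ with $N_i$ the
  union of predecessors and successors, $w_{ij}$ the summed weight of all
  edges between $i$ and $j$ in either direction, and $k_j$ the total
  unweighted degree of $j$. Undefined (NA) for isolated nodes.
* **Average degree connectivity**: the mean of the above over nodes grouped
  by total unweighted degree $k$ — a network-level dispersion profile.
* **Closeness vitality** $W(G) - W(G\setminus v)$, where
  $W(G) = \sum_{u \ne v} d(u,v)$ (Wiener index, ordered reachable pairs).
  If removing $v$ disconnects a previously connected pair the residual sum
  blows up; the package reports $-\infty$ for such removals so that every
  node keeps an entry in the distribution rather than silently dropping out.
* **Betweenness centrality**
  $c_B(v) = \sum_{s \ne v \ne t} \sigma_{s,t}(v)/\sigma_{s,t}$ with
  endpoints excluded and unreachable pairs contributing zero; unnormalized
  by default, with optional $(n-1)(n-2)$ normalization.
* **Closeness centrality** on incoming paths, with reachability scaling:
  with $r$ nodes able to reach $u$,
  $C(u) = \frac{r-1}{\sum_v d(v,u)}\cdot\frac{r-1}{n-1}$, which reduces to
  the plain reciprocal-mean form on strongly connected graphs and is 0 for
  a node nothing reaches. The scaling is needed because per-animal behavior
  networks are frequently not strongly connected.

Distribution summaries use the first quartile (linear interpolation) and
the *robust max*, read as the mean of the three largest values — the
max-of-top-three reading would equal the plain maximum and make the
qualifier vacuous.

Every one of these is verified against independent brute force in the test
suite: Floyd–Warshall distances and path counts, explicit simple-path
enumeration for betweenness on tiny graphs, and igraph as a third-party
cross-check. Random test graphs draw weights from powers of two so that
inverse-mode path lengths are exact in floating point and tie counting is
unambiguous; tie detection elsewhere uses a $10^{-9}$ relative tolerance.

## Racing syllables

Usage is occurrence-based (emissions of a syllable over total emissions;
duration weighting would require frame-level input) and normalized per
animal. Racing is an input label, not a detected property: the label map
flags which syllables show fast circular locomotion. Binarization marks a
racing syllable when usage **strictly** exceeds the threshold (default
0.025). Strictness matters: the threshold convention is "the highest
normalized racing usage among aged control animals", and only strict
exceedance makes those controls all-zero in the binarized heatmap.

## Group statistics

Mann–Whitney (exact for both $n \le 8$ without ties, normal approximation
with tie/continuity correction otherwise), two-sample Kolmogorov–Smirnov
with the D statistic, and Fisher's exact test, all two-tailed. Multiple
comparisons use the two-stage Benjamini–Krieger–Yekutieli step-up: stage 1
runs the linear step-up at $q' = q/(1+q)$ to estimate the number of true
nulls $m_0 = m - r_1$; stage 2 re-runs it at $q' m/m_0$. Reported q-values
are scaled so that rejection is exactly `q_value <= q`. The implementation
is a hand-rolled step-up; the test suite checks its rejection decisions
against an independent `p.adjust`-based reference on 500 simulated
p-value vectors, and checks the empirical dominance over plain
Benjamini–Hochberg when signals are present.

## The synthetic cohort generator

No recordings are distributed with the study this analysis emulates, so
validation runs on synthetic cohorts whose structure matches what the
analysis assumes. One sequence is generated as: first two emissions drawn
from the group vocabulary without immediate repeat; for $t \ge 3$, with
probability $\rho$ (the *return bias*) re-emit $S_{t-2}$ — by construction
never equal to $S_{t-1}$, though the implementation guards the impossible
case anyway — otherwise draw from the base distribution over the vocabulary
excluding $S_{t-1}$. This makes the repetitive-triplet fraction exactly
$\rho + (1-\rho)/(n_v-1)$ for a uniform base over $n_v$ syllables, an
analytic target the acceptance tests recover within Monte-Carlo error.

Default study conditions (all user-overridable):

* **37 syllables, 7 of them case-specific (ids 30–36)** — mirroring a
  30-shared / 7-specific chronic vocabulary split.
* **T = 1500 emissions** per 20-minute session: plausible for sub-second
  syllables at moderate occupancy; session lengths are not published, so
  this is a fixed choice, not a fit.
* **15 animals per group**, three timepoints (1.5, 12, 20 weeks).
* **Return bias** 0.05 (control; a small resting perseveration above the
  1/(n−1) chance floor) vs 0.35 (case at chronic timepoints), giving
  roughly 8% vs 37% repetitive windows — the right direction and order of
  magnitude for a strong perseverative phenotype.
* **Racing base mass 0.3** relative to 1 for ordinary syllables, boosted
  ×5 in the case group at chronic timepoints. Racing is rare in controls
  — that is precisely why a 0.025 usage threshold can separate the groups —
  so the resting mass is set low enough that control racing usage
  (≈0.0105 per racing syllable) sits several sampling standard deviations
  below the threshold at T = 1500, while boosted usage (≈0.036) sits
  clearly above. A fully uniform base would put control racing usage at
  1/30 ≈ 0.033 and make the binarized map meaningless. Configs with no
  racing ids keep an exactly uniform base, so analytic checks are
  unaffected.
* **Length factor 0.6** at the final timepoint for the case group only,
  emulating the sedentary shortening of total syllable output in late
  disease.

Per-animal seeds are `master seed + polynomial hash(group|timepoint|index)
mod (2^31 − 1)`, so a cohort is bit-reproducible while animals are
independent, and any single animal can be regenerated in isolation. The
generator's global-RNG state is saved and restored around every draw.

What the generator does **not** emulate: syllable duration distributions,
autoregressive state dynamics, non-stationarity within a session, and
realistic (long-tailed) usage distributions beyond the racing/non-racing
split. Passing tests therefore demonstrate correctness of the analysis
pipeline under the stated generative assumptions, not that real recordings
satisfy those assumptions.

## Worked example

```{r example}
cfg <- cohortConfig(nAnimalsPerGroup = 4, seqLength = 600,
                    timepoints = c("1.5w", "12w"), seed = 42)
cohort <- simulateCohort(cfg)
alt <- cohortAlternation(cohort)
aggregate(percent_repetitive ~ group + timepoint, alt$profiles, mean)

net <- buildNetwork(countTransitions(cohort[["epileptic_12w_01"]]))
head(nodeMetrics(net)$nodes)
```

## Numerical and degenerate-input conventions

* Shortest-path ties: relative tolerance $10^{-9}$; edge lengths must be
  strictly positive after the weight transform.
* Usage-coverage prefix: a $10^{-12}$ slack on the coverage comparison
  guards against accumulated floating error at exactly attainable
  coverages.
* Empty indicator vectors, sequences shorter than 3, empty samples, and
  vocabularies smaller than 2 raise errors; isolated nodes yield NA
  neighbor degree and are excluded from degree-connectivity tables;
  label-map misses resolve to `"unlabeled"`/non-racing.
* Problem sizes in the validation suite (up to 8-node graphs for
  brute-force equivalence, 1000 random trials, cohorts of 15 animals ×
  1000 emissions for the directional checks, 50,000 emissions per bias
  level for the analytic recovery) were chosen so the whole suite and the
  brute-force oracles stay exact and fast while keeping Monte-Carlo
  standard errors well below the effect sizes being checked.

## Known limitations

* The `raw` distance convention, while faithful to how the networks were
  originally measured, means high-frequency transitions *lengthen* paths;
  interpret vitality/closeness comparisons across weight modes, not as
  absolute quantities.
* Closeness vitality's $-\infty$ sentinel is meaningful for rankings and
  cumulative distributions but must be filtered before computing means.
* Pooled K-S tests across animals treat runs as exchangeable within group,
  ignoring per-animal correlation; the per-animal summary route is the
  conservative alternative.
* ANOVA-family analyses (two-way ANOVA, mixed-effects) are deliberately
  out of scope; the pipeline emits tidy long tables for use in any stats
  environment.
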