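---
title: "Qualitative analysis of signed signalling networks with signalflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Qualitative analysis of signed signalling networks with signalflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(signalflow)
```

## The modelling problem

Curated protein-signalling maps are often available only as signed,
directed interaction lists: gene A activates gene B, gene C inhibits
gene B. Such a map — for instance a two-layer network built around a
single disease gene such as *SORL1*, with a few dozen nodes and edges
curated from the literature — carries no kinetic parameters, yet two
qualitative questions can still be answered rigorously:

1. **Signal flow.** If an input node is held ON or OFF, which nodes end
   up active, inactive, or undetermined? Comparing a wild-type scenario
   (input ON) with a knockout scenario (input OFF) yields a per-node
   model prediction, `Emod` in $\{-1, 0, +1\}$, of how each gene should
   move when the input gene is lost.
2. **Path structure.** Independently of any particular input, what is
   the net qualitative effect of every node on every node, given all
   the signed paths between them and the feedback loops those paths
   cross? Deleting a node and recomputing this *dependency matrix*
   reveals which pairwise relationships a knockout rewires.

signalflow implements both analyses, the statistics used to score the
predictions against knockout RNA-seq experiments and stratified patient
cohorts, and synthetic-data generators so the full pipeline is testable
without any external downloads.

## Three-valued logical steady states

Each node takes a value in $\{1, 0, \mathrm{NaN}\}$ — ON, OFF, or
undetermined — with the activity order $1 > \mathrm{NaN} > 0$.
`compute_lss()` starts from all-NaN, clamps the scenario inputs, and
propagates synchronously until a fixpoint:

* an activating edge contributes its source's value to the target;
* an inhibiting edge contributes the Kleene negation of its source
  ($\lnot 1 = 0$, $\lnot 0 = 1$, $\lnot \mathrm{NaN} = \mathrm{NaN}$);
* a node with incoming edges takes the three-valued OR of its
  contributions (1 if any is 1; 0 if all are 0; NaN otherwise), and a
  node with no incoming edges stays NaN unless clamped.

Two design points deserve emphasis. First, **inhibiting edges act as
negated activators combined by OR**, not as vetoes that dominate
activators. Under this convention an OFF inhibitor *forces its target
ON* when it is the target's only determinant — which is exactly the
behaviour needed for a knockout scenario to up-regulate the genes that
the lost protein was suppressing. An inhibitor-dominant convention
could never produce those $0 \to 1$ flips. Second, updates are
**synchronous (Jacobi-style)**, which makes the result independent of
node ordering; convergence is guaranteed in at most $n+1$ sweeps
because a value can move from NaN to 0/1 but never back (the update is
monotone in the information order). Nodes inside cycles that are never
forced by the clamped inputs remain NaN — undetermined or potentially
oscillatory — and no attractor enumeration is attempted; this is a
deliberate restriction, not a limitation of the solver.

`emod()` compares two steady states on the activity order: a node
lower in the knockout scenario than in the wild type scores $-1$
(predicted down-regulation), higher scores $+1$, equal scores $0$.
Clamped nodes are excluded — they were set, not predicted. Two
knockout styles are exposed and both are legitimate: clamping the node
to 0 (used for steady-state scenarios) and structural deletion via
`knockout()` (used for dependency-matrix scenarios, where the deleted
node's row and column disappear and an $n$-node model drops from
$n^2$ to $(n-1)^2$ dependencies).

## The six-class dependency matrix

For an ordered pair $(A, B)$, `dependency_matrix()` considers every
*elementary* (node-distinct) directed path from $A$ to $B$; a path's
sign is the product of its edge signs. For $A = B$ the relevant
objects are the elementary circuits through $A$, so a node depends on
itself only via feedback, never trivially. A *negative feedback loop*
is an elementary circuit of negative sign; a loop is *present in* a
set of paths when it shares at least one node with at least one path
of that set. The classification:

| class | requirement |
|---|---|
| no effect | no paths |
| ambivalent factor | paths of both signs |
| weak inhibitor | only negative paths, some touched by a negative loop |
| strong inhibitor | only negative paths, none touched |
| weak activator | only positive paths, some touched by a negative loop |
| strong activator | only positive paths, none touched |

Loop contact is tested against paths of the classified sign only, and
a path "touches" a loop through any of its nodes, endpoints included.
Parallel opposite-sign edges between two nodes simply make both signs
available; whether an enumeration visits such a pair once or twice is
irrelevant because only sign existence matters.

Sign existence over *elementary* paths cannot be reduced to walk-based
signed reachability (a walk can pick up a sign flip from a cycle that
no simple path can use), so the production implementation is an exact
depth-first enumeration over simple paths with early termination: a
pair is ambivalent the moment one path of each sign has been seen,
which resolves the majority of pairs in dense networks almost
immediately. Negative-loop membership is precomputed once per network
by a rooted circuit enumeration (each circuit found exactly once from
its minimum-index node). An independent oracle,
`dependency_matrix_bruteforce()`, reaches the same classification by a
different route — literal enumeration of all simple paths and circuits
via igraph, with parallel-edge sign sets expanded afterwards — and the
test suite requires exact agreement between the two on hundreds of
randomized networks. On a 34-node, 92-edge hub network the full
$34 \times 34$ matrix computes in a few seconds.

`dm_delta()` compares two matrices over their common node set,
reporting the changed pairs, a $6 \times 6$ before/after transition
table, and the shortlist of changes that *end* in a strong class —
these are the relationship rewirings most likely to be observable in
vivo, and the natural starting points for experimental follow-up.
`ko_scenario_report()` wraps deletion, reclassification and delta for
a list of knockout scenarios.

## From expression data to Eexp, and scoring

Observed changes are reduced to the same three-valued scale as the
predictions. For replicate knockout experiments (`cellline_de()`),
replicates are averaged per condition and the fold change is
KO mean / WT mean; q-values travel with the source data set. For
stratified cohorts (`cohort_de()`), patients are split on a focal
gene (`split_cohort()`; mean, median, or a quartile with the
linear-interpolation convention, switchable) and the log10 fold change
is Low-group over High-group, so the focal gene itself always comes
out negative. The two-group q-value there is a Welch t-test on logged
values with Benjamini–Hochberg adjustment — a deliberately generic
surrogate for portal-specific comparison tools, and externally
computed tables can bypass it entirely.

`eexp_from_de()` applies two cuts: significance ($q < 0.05$, with
$q = 0.05$ exactly treated as not significant) and a biological
threshold $T \ge 1$ on the fold change, inclusive, with reciprocal
$1/T$ as the equivalent down-regulation bound. At $T = 1$ the rule
degenerates to the direction of the fold change. Raising $T$ can only
silence calls, never create them — a monotonicity property asserted in
the tests. One convention here is worth flagging: in the log10 rule the
up-regulation cut is the sign of the log fold change (symmetric with
the down cut at 0), since a cut at $+1$ log10 unit would leave the
interval $(0, 1]$ unclassifiable while down-regulation triggered at
any negative value.

Scoring (`score_predictions()`) compares `Emod` and `Eexp` per gene:
$|E_{mod} - E_{exp}|$ is 0 (correct), 1 (one-step, "small" error:
e.g. predicted unchanged, observed up) or 2 (two-step, "large" error:
predicted the opposite). The criterion gene is excluded from the
denominator — it was the input — after a directionality check that its
observed call is $-1$; genes absent from the data are excluded and
reported. Significance is the **binomial point probability**
$\binom{n}{k} (1/3)^k (2/3)^{n-k}$ of the observed number of correct
calls at the 1/3 random baseline (`binom_point_p()`), kept as a point
probability for parity with the established practice in this modelling
lineage; the conventional upper-tail sum is available behind a flag,
and for the reference value in this package's acceptance checks — 15
correct of 28, rate 53.57% — the point probability is 0.013407744.
`knockdown_correlation()` relates per-cell-type knockdown depth (the
perturbed gene's residual fold change) to the per-cell-type correct
rate: Pearson $r$, $r^2$, and a two-sided p-value from
$t = r\sqrt{(n-2)/(1-r^2)}$. The two-sided choice is deliberate;
published analyses of this kind do not always state their tail
convention, and no parity with any particular printed correlation
p-value is claimed.

## What the synthetic generators emulate

`gen_network()` (defaults: 34 nodes, 92 edges, hub mode) emulates the
star-plus-second-layer topology of a single-gene curated map: the
focal node reaches all 33 others and receives edges back from a third
of them, giving it degree $33 + 11 = 44$, strictly maximal by
construction; the remaining 48 edges are scattered over the periphery
under a degree cap. Edge signs are activating with probability 0.75 —
curated signalling maps skew towards activation, and the exact split
is not critical to any property tested. `gen_cellline_expr()` emulates
a 4×WT / 4×KO replicate design: per-gene baselines are log-normal
around 100 (arbitrary expression units), the planted KO/WT ratio
follows the gene's target direction with probability $\pi$ (the
*agreement rate*) and otherwise a uniformly chosen wrong direction,
effects default to 4-fold with replicate noise $\sigma_{\log} = 0.15$,
and q-values come from Welch tests with BH adjustment.
`gen_cohort()` draws a log-normal focal gene and gives each other gene
a signed log-linear response to the standardised log focal value.

Because the disagreement directions are uniform over the two wrong
options, the expected error mix is analytically known, and the
end-to-end property holds: scoring data generated at agreement $\pi$
returns a correct rate near $100\pi$, and $\pi = 1/3$ reproduces the
33.3% random-model baseline. What these generators deliberately do
**not** model: negative-binomial count dispersion, library-size or
batch effects, gene-gene correlation beyond the focal response, and
dropout. Passing tests on synthetic data therefore demonstrate the
correctness of the pipeline's logic and calibration, not robustness to
real RNA-seq pathologies.

## Numerical and design choices

* **Degree convention.** A self-edge counts 2 toward its node's degree
  (one incidence as source, one as target), making the degree sum
  exactly twice the edge count; `degree_distribution()` can count them
  once instead.
* **Duplicate records** (same source, target, sign) collapse to first
  occurrence with a warning; opposite-sign parallels and self-edges are
  preserved. Node names are matched exactly and case-sensitively — no
  gene-symbol aliasing, so near-duplicate symbols in a curated file
  (e.g. `GRFA1` vs `GFRA1`) surface as distinct nodes for a human to
  resolve rather than being merged silently.
* **Ties and boundaries.** Fold-change thresholds are inclusive;
  $q$ cut is strict; cohort "High" is strictly above the split
  threshold, "Low" at or below, so the groups always partition the
  cohort.
* **Degenerate inputs.** WT-mean-zero genes have an undefined fold
  change and are flagged, never coerced to 0; cohorts constant in the
  focal gene refuse to split; the brute-force oracle refuses networks
  above 12 nodes by default.
* **Problem sizes.** The randomized suites use 200 networks of up to 8
  nodes for oracle equivalence, 40 nine-node networks for the
  steady-state laws, and $3 \times 100$ simulated experiments of 33
  genes for agreement recovery — sizes chosen so the whole suite runs
  in well under a minute while still exercising cycles, parallel
  edges and self-edges densely.

## Worked example

```{r example}
net <- gen_network(seed = 1)
focal <- attr(net, "focal")
wt <- compute_lss(net, setNames(1, focal))
ko <- compute_lss(net, setNames(0, focal))
ev <- emod(wt, ko, focal)
emod_summary(ev)

dm <- dependency_matrix(net)
class_counts(dm)
delta <- dm_delta(dm, dependency_matrix(knockout(net, focal)))
delta
head(delta$strong_changes)
```

```{r score}
target <- c(setNames(-1L, focal), unclass(ev))
sim <- gen_cellline_expr(target, agreement = 0.9, seed = 1)
de <- cellline_de(sim$expr, "cellline")
score_predictions(ev, eexp_from_de(de), focal)
```

## Limitations

The Boolean abstraction ignores dosage: regulation is rarely on/off,
and semi-quantitative score-flow extensions are known to outperform
pure logical steady states on the same network structures; none is
implemented here. Dependency classification is purely topological — it
weights a single literature-curated edge the same as a well-quantified
one. Finally, elementary-path enumeration is exponential in the worst
case; the early-termination search is comfortable at the tens-of-nodes
scale these curated models occupy, but this package is not intended
for genome-scale graphs.
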