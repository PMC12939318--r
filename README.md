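# signalflow

Qualitative analysis of signed, directed protein-signalling networks:
three-valued logical steady states, six-class dependency matrices,
in-silico knockouts, and statistics for validating model predictions
against knockout RNA-seq experiments and stratified patient cohorts.

## Who this is for

Curated disease-gene networks — a few dozen genes/proteins connected
by literature-supported activation and inhibition edges — carry no
kinetic parameters, yet support two rigorous qualitative analyses.
signalflow is for modellers who build such maps (for instance around a
single risk gene like *SORL1*) and want to:

* predict how every node moves when an input gene is lost, and
* find which pairwise relationships a knockout rewires,

then score those predictions against real expression data.

## The methods in brief

**Logical steady states.** Node values live in {1, 0, NaN} (ON, OFF,
undetermined; activity order 1 > NaN > 0). From an all-NaN start with
scenario inputs clamped, values propagate synchronously: an activating
edge contributes its source value, an inhibiting edge the Kleene
negation of it (¬1 = 0, ¬0 = 1, ¬NaN = NaN), and each node takes the
three-valued OR of its incoming contributions. The comparison of a
wild-type and a knockout steady state yields the model prediction per
node, `Emod` ∈ {−1, 0, +1}.

**Dependency matrix.** The effect of node A on node B is classified
from the elementary signed paths A → B (elementary circuits through A
when A = B): *no effect* (no paths), *ambivalent* (both signs),
*strong activator / inhibitor* (single sign, no negative feedback loop
sharing a node with any such path), or *weak activator / inhibitor*
(single sign, some path touched by a negative loop). Deleting a node
and diffing the matrices (`dm_delta`) yields the knockout's
relationship changes, with changes ending in a strong class
highlighted as the most testable predictions.

**Validation.** Expression data become observed calls
`Eexp` ∈ {−1, 0, +1} via q-value and fold-change cuts with an optional
biological threshold (T, with reciprocal 1/T for down-regulation).
Predictions are scored by |Emod − Eexp| (0 correct, 1 small error, 2
large error); significance of the correct-call count is the binomial
point probability at the 1/3 random baseline. Cohorts are stratified
on a focal gene (mean / median / quartiles) before a Low-vs-High
comparison. Seed-deterministic generators simulate every input with
known ground truth.

## Worked example

```r
library(signalflow)

net <- gen_network(seed = 1)        # 34-node, 92-edge hub network
net
#> signed_network: 34 nodes, 92 edges (58 activating, 34 inhibiting)

focal <- attr(net, "focal")         # the hub gene, degree 44
wt <- compute_lss(net, setNames(1, focal))
ko <- compute_lss(net, setNames(0, focal))
ev <- emod(wt, ko, focal)
emod_summary(ev)
#>        up      down unchanged
#>         8         9        16

dm <- dependency_matrix(net)
class_counts(dm)
#>        NO_EFFECT       AMBIVALENT   WEAK_INHIBITOR   WEAK_ACTIVATOR
#>              332              765               27               25
#> STRONG_INHIBITOR STRONG_ACTIVATOR
#>                5                2

delta <- dm_delta(dm, dependency_matrix(knockout(net, focal)))
delta
#> dependency_delta: 524 of 1089 dependencies changed; 25 changes to strong classes

# simulate a 4xWT / 4xKO experiment agreeing with the model 90% of the
# time, and score the predictions
target <- c(setNames(-1L, focal), unclass(ev))
sim <- gen_cellline_expr(target, agreement = 0.9, seed = 1)
de <- cellline_de(sim$expr, "cellline")
score_predictions(ev, eexp_from_de(de), focal)
#> score_report: 33 genes evaluated; 29 correct (87.88%), 3 small / 1 large errors; p = 1.18e-10
```

Reading the output: of 33 predicted genes the simulated experiment
confirmed 29 (87.9%, against a 33.3% random baseline; the point
probability of 29/33 correct by chance is ~1e-10). Of the 1089
dependencies surviving the hub knockout, 524 changed class, 25 of them
into a strong (loop-free, single-sign) relationship — the shortlist an
experimentalist would take forward.

Real data enter the same way: `read_interactions()` for curated
SIF/evidence tables, `read_expression()` for replicate matrices with
q-values, `read_cohort()` + `split_cohort()` + `cohort_de()` for
patient tables, or any externally computed differential-expression
table fed straight into `eexp_from_de()`. A thin command-line
front-end with `lss`, `depmat`, `validate-cellline`,
`validate-clinical` and `simulate` subcommands is installed at
`inst/cli/signalflow`.

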