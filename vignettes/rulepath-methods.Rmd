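---
title: "Models and methods in rulepath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in rulepath}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`rulepath` predicts microbial biotransformation pathways of xenobiotic
compounds by iterative application of transformation rules, and provides
the statistical machinery around such predictions: a trainable
prioritization model, a pathway-level evaluation, an applicability
domain, and a rule-to-enzyme-class linkage derivation.  This vignette
explains the models, every tunable that matters, the numerical
conventions, and what the synthetic study design can and cannot show.

## Structures, rules and identity

Compound identity is the **stereo-stripped canonical SMILES**.
Transformation rules carry no stereochemistry, and observed pathways
frequently omit stereocenter annotations, so matching on stereo-aware
keys would produce spurious mismatches.  Canonicalization is idempotent
and delegated, like all chemistry, to RDKit via a bundled batch helper
(`inst/python/chem_backend.py`).  Fingerprints are Morgan, radius 2,
2048 bits; this is a declared default (standard, deterministic, adequate
for k-NN similarity), not a claim about any particular production
system.

A **rule** is a reaction SMARTS/SMIRKS with exactly one reactant
template.  `apply_rules()` yields one product multiset per distinct
match site, canonicalized and deduplicated, so a symmetric substrate
with two equivalent sites yields one product set.  Multi-product
outcomes are kept as multisets — an ester hydrolysis yields the acid
*and* the alcohol in one event — because exact multiset equality is what
reaction matching (training labels, single-generation evaluation, EC
linkage) tests.  Products failing valence sanitization are dropped with
a warning rather than an error: exhaustive rule application over a
corpus must not abort on one degenerate adduct.

The shipped `toy12` library covers twelve ubiquitous microbial
transformations (hydrolyses, hydroxylations, dealkylations, nitro
reduction, dehalogenation, oxidations, sulfoxidation, decarboxylation).
Each rule documents an example substrate and its hand-verified products;
the test suite pins them exactly.

## The relative-reasoning scorer

Structural triggering alone over-predicts badly: most compounds trigger
many rules of which few are realized.  The scorer estimates, per
(compound, rule), the probability that a triggered rule is actually
observed.  Training labels come from a data package: for every
single-substrate reaction substrate, `triggered` is the set of
structurally applicable rules and `observed` the subset whose
application reproduces the (substrate, product-multiset) of some package
reaction.

Two modes:

* `baseline`: per-rule global precision `n_observed / n_triggered`
  over training compounds; a rule never triggered defaults to the
  uninformed prior 0.5 (logged).
* `knn` (default, k = 5): the score of rule *r* on query *q* is the mean
  observed-label of the *k* nearest training compounds (Tanimoto on
  fingerprints) **among those that trigger r**; fewer than *k*
  candidates average over what exists; zero candidates fall back to the
  baseline.  Ties in similarity break by lexicographic canonical SMILES
  so scoring is deterministic.

This k-NN label average is this package's own default realization of
relative reasoning; the scorer is an ordinary R object, so alternative
models can be slotted in behind `score_transformations()`.

## Pathway prediction

`predict_pathway()` grows a DAG from the root by best-first expansion:
a priority queue of (compound, cumulative score) seeded with (root, 1),
always expanding the highest cumulative score, with ties broken by
lexicographic SMILES.  Re-encountered compounds gain in-edges but are
not re-expanded (this prevents exponential blow-up and keeps each
compound at its earliest generation); a product equal to an ancestor
creates no edge, preserving acyclicity; `max_depth` (4) and `max_nodes`
(50) bound the graph.

A design point worth spelling out: the score threshold is **not**
applied during expansion.  If it were, the node budget and threshold
monotonicity would conflict — raising the threshold frees budget slots
and can admit *new* compounds.  Instead the expansion runs once,
threshold-free, producing a threshold-independent candidate universe;
the predicted pathway at threshold *t* is the root-reachable subgraph of
universe edges with score ≥ *t*, minus any node whose recomputed
shortest-path depth exceeds `max_depth` (pruning can lengthen shortest
paths).  With this construction, raising *t* provably never adds a node,
budgets always hold, and a threshold sweep costs one expansion.
Node `cumulative_score` is the maximum product of edge scores over root
paths, recomputed on the pruned graph.

## Multi-generation evaluation

Observed environmental pathways under-report short-lived intermediates;
multi-step processes appear as single reactions.  Evaluating predictions
reaction-by-reaction therefore labels correct chemistry as false
positives.  The pathway-level evaluation addresses this with two
ingredients.

**Node categories.**  Predicted and observed pathways (same root —
root sets must match exactly; roots never score) are compared by
structure key.  Every predicted non-root node is `matched`,
`intermediate` (predicted-only with at least one matched proper
descendant in the predicted DAG), or `false_positive`; observed-only
nodes are `false_negative`.  The intermediate definition generalizes the
canonical three-compound situation — observed A→C, predicted A→B→C — to
branched DAGs: leniency is restricted to *connective* nodes because only
they are evidenced by a downstream observation; dead-end branches stay
false positives.

**Depth weights.**  A node at depth *d* (shortest edge-path from the
nearest root; the shortest path is each compound's earliest observable
generation, which also disambiguates diamond-shaped pathways) carries
weight `base^(d-1)`, base 0.5 by default.  The geometric family is the
simplest monotone decreasing one; the base is a parameter of
`eval_params()`.

With the adjustment **on** (default): matched nodes score at their
*observed* depth (unobserved intermediates must not deepen a match),
intermediates contribute nothing, false positives carry predicted depth
and false negatives observed depth.  With the adjustment **off**:
intermediates count as false positives at predicted depth, and a matched
node is credited `min(base^(d_pred-1), base^(d_obs-1))` with the
shortfall against its observed weight counted as false negative mass.
The clamp handles the corner where the predicted route is *shorter* than
the observed one; without it, recall could exceed 1, and the guarantee
that turning the adjustment on never lowers precision or recall would
fail.  Both worked-example scores (adjusted 1/1; unadjusted 1/3 and 0.5)
follow from these definitions, and the monotonicity guarantee is tested
against exhaustive small-DAG enumeration plus random pairs, with node
categorization checked against a path-enumeration oracle.

Precision `wTP/(wTP+wFP)` and recall `wTP/(wTP+wFN)` define 0/0 as 1,
keeping threshold sweeps total.  The evaluation depends only on the two
graphs — never on the scorer or rule vocabulary — so models trained on
different packages are comparable.

**Single-generation evaluation** is the per-reaction counterpart: per
test substrate, predicted positives are triggered rules scoring at or
above the threshold; a prediction is correct when applying the rule
reproduces an observed reaction of that substrate; counts are unweighted
and pooled over substrates (per-rule-on-substrate counting is the
declared convention).

**Holdout experiment.**  `holdout_experiment()` repeatedly splits the
package's pathways (default test fraction 0.25), trains on the remaining
reactions, predicts each test pathway from its root, and sweeps the
score threshold, pooling weighted tallies within a repeat and averaging
over repeats.  Repeat *i* draws its split with seed `seed + i - 1`, so a
20-repeat run with seed 1 uses split seeds 1–20 and is fully
reproducible.

On the default synthetic study (200 compounds, 30 pathways, collapse
probability 0.3, 20 repeats) the experiment shows multi-generation mean
*recall* below single-generation recall at every threshold — losing one
early reaction loses the whole weighted subtree — but multi-generation
mean *precision* above single-generation precision at most thresholds.
The direction of the precision gap follows from the study design: the
generator's observation probabilities (0.9 active / 0.05 inactive) make
the k-NN scorer nearly perfect (AUROC ≈ 0.97), so predictions contain
few wrong branches to penalize, while single-generation precision is
dragged down by collapsed multi-step reactions whose underlying rules
count as false positives — precisely the pathology that motivates
pathway-level evaluation.  With weaker scorers or sparser observed data
both gaps point the same way; the synthetic conditions are deliberately
high-signal and do not emulate that regime.

## Applicability domain

Four assessments, all in [0, 1], computed against a trained scorer's
index (`ad_params()` holds the knobs):

* **Compound applicability** = `(S_fp + S_rule) / 2` where `S_fp` is the
  mean Tanimoto similarity of the `k_structural` (5) nearest training
  compounds and `S_rule` the Jaccard similarity between the query's
  triggered rule set and the union of those neighbours' triggered sets
  (1 when both sides are empty).  The equal-weight mean is a declared
  choice: both ingredients are named, no combination is prescribed
  anywhere, and equal weighting adds no hidden tunable.
* **Functional-group coverage**: each hetero-atom group present in the
  query (from a fixed, versioned SMARTS library of 22 groups) is
  covered when at least `fg_min_support` (3) training compounds contain
  it.  Support 1 would make coverage trivial; 3 is conservative and
  configurable.
* **Reliability** of rule *r* on query *q*: mean similarity of the `n`
  (5) most similar training compounds on which *r* triggers, the query
  itself excluded (leave-one-out; duplicate structures never self-match).
  Fewer than `n` candidates average over what exists and set a
  low-support flag; zero candidates give 0.  Defined only when *r*
  triggers on *q* (error otherwise).  Adding less-similar neighbours can
  only lower the mean, so reliability is monotone non-increasing in `n`
  — asserted exactly in the tests.
* **Local goodness of fit**: over the same `n` neighbours, the fraction
  whose leave-one-out prediction is correct, where the predicted label
  is the scorer score for *r* on that neighbour (scored with the
  neighbour removed from the k-NN index) thresholded at `edge_threshold`,
  and the observed label is whether *r* is realized in one of its
  reactions.  "Correct" had to be pinned somewhere; thresholded LOO
  labels against observed labels is the declared definition.  Undefined
  (NA, flagged) when no candidate exists.

An edge passes (`edge_ok`) when reliability meets the threshold AND the
local fit is undefined or meets it — requiring both is the conservative
reading of "reliability or local compatibility above the threshold",
with undefined treated as non-disqualifying.  `export_dot()` renders
node borders green/red by domain membership and edges green/red by
`edge_ok`.

## Rule-to-EC linkage

`derive_linkages()` applies every rule to a compound corpus, compares
each generated (substrate, product multiset) against EC-annotated
corpora under exact canonical-multiset equality (forward direction
only), and aggregates matches into (rule, 3rd-level EC) links carrying
per-source support counts.  4th-level ECs are truncated to their
3rd-level class; 1st/2nd-level annotations are skipped, never guessed.
Cofactor handling is an explicit, empty-by-default ignore-list rather
than a heuristic.  `overlap_summary()` reports the fractions of links
found in both sources or one only; the three fractions sum to 1 exactly.

## The synthetic study design

`synthetic fixtures` are real chemistry, not abstract graphs, so every
downstream module exercises the SMIRKS engine.  The generator is fully
deterministic given its seed.

* **Compounds**: all para-, meta- and ortho-disubstituted benzenes over
  a 16-fragment substituent grid, canonicalized and deduplicated; the
  default corpus takes the first 200.  The grid guarantees every toy
  rule triggers on at least 10 corpus members.  The corpus is the
  deterministic frame of the study — identical across seeds — so only
  the biology (rule activity, observation, collapse) varies.
* **Observed pathways**: half the rules are drawn as *active*.  Ground
  truth grows from each of 30 root compounds to depth 3, realizing each
  triggered site with probability 0.9 (active) or 0.05 (inactive),
  capped at 15 nodes per pathway; a node expands fully or not at all so
  that no recorded reaction ever has a truncated product multiset.  Each
  internal truth node is then removed with probability 0.3, splicing its
  in/out edges into multi-step reactions — manufacturing, at a known
  rate, exactly the skipped-intermediate situation the evaluation is
  designed for.  The uncollapsed truth rides along as an attribute for
  oracle tests.  The sizes (30 pathways, 15-node cap, depth 3) are this
  package's standing choices for a desk-scale study: large enough that
  every rule class appears in training, small enough that the full
  20-repeat experiment runs in minutes.
* **EC corpora**: each rule is planted one or two 4th-level EC numbers;
  reactions generated by that rule (skipping any transformation a second
  rule could equally have produced, so every corpus reaction identifies
  its rule unambiguously) are annotated with them and distributed over
  two sources, with membership drawn once per (rule, EC) pair so the
  overlap parameter controls the overlap of derived *links*.  The
  generator returns the exact link set derivation must recover.

What passing tests on these fixtures show: the algorithms are correct
(exact planted recovery, oracle-matched categorization, invariant
bounds) and the pipeline is deterministic end to end.  What they do not
show: performance on real chemical space.  The grid chemistry is narrow,
there are no cofactors, no multi-substrate reactions, no kinetics, no
tautomers or protonation states, and observation noise is i.i.d. —
real reporting bias is anything but.

## Numerical conventions and determinism

* 0/0 precision and recall are 1; empty fingerprint pairs have Tanimoto 1.
* All neighbour selections break similarity ties by lexicographic
  canonical SMILES; expansion order ties break by (higher score, then
  SMILES).  No ordering depends on hash iteration.
* Every stochastic entry point takes an explicit integer seed; repeat
  *i* of the holdout uses `seed + i - 1`; the EC generator offsets its
  seed by 1 so pathway and corpus draws are independent streams.
* Serialization (`save_package()`) is byte-stable: identical inputs give
  identical files, which the determinism tests assert literally.

## Limitations

Rules with one reactant template only; multi-substrate reactions are
stored but never generated.  The scorer sees only structural
fingerprints — no reaction conditions, no kinetics (DT50 values are
carried as scenario metadata, not modelled).  Enzyme linkage stops at
3rd-level EC classes and does not rank candidate enzymes.  The
applicability domain reduces atom-level reactivity-centre rendering to
the functional-group coverage table plus DOT colouring.
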