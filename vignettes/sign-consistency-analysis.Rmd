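---
title: "Sign-consistency analysis of expression profiles on signed regulatory graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sign-consistency analysis of expression profiles on signed regulatory graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(signcon)
```

## The model

`signcon` treats a regulatory network as a signed directed graph
G(V, E, α): nodes are molecular entities (genes, proteins, complexes,
reaction events), edges carry α(e) ∈ {+, −} for activation or
inhibition. A *coloring model* μ : V → {+, −, 0} is one qualitative
state of the whole system — each node up, down or unchanged relative to
a reference condition. Transcriptomic measurements enter as a *partial
labeling* β over the observable gene nodes; everything else (protein
activities, complex formation) is unobserved and will be inferred.

A coloring is *consistent* when every node's sign is explained by its
direct predecessors:

* input nodes (by default the nodes without predecessors, overridable)
  are exempt;
* a variant node needs at least one predecessor whose transmitted
  influence (edge sign × predecessor sign) equals its own sign;
* an invariant node needs either all-invariant influences or two
  opposite variant influences that can cancel.

The rules are local constraints over a *total* coloring, so cycles —
ubiquitous in signalling networks — need no special treatment. The set
of consistent colorings extending β, and its per-node *projection* into
seven classes (`+`, `-`, `0`, `Not+`, `Not-`, `change`, `?`), is the
analysis currency: a strong class means the network forces that state in
every consistent scenario.

## Repairs

Real data and curated graphs conflict. Two exact repair modes restore
consistency, each reporting *all* minimal repairs:

* **MCOS** blames the graph: the smallest sets of nodes granted an
  *artificial influence*. An exempted node may take any sign, exactly as
  if a fresh unconstrained input pointed at it; the graph's node set is
  unchanged. Repairs may target any non-input node, observed or not —
  the mode corrects topology, not data — though a stricter policy can be
  emulated by passing explicit candidates to the brute-force oracle in
  the tests.
* **SCENFIT** blames the data: the cheapest sets of sign switches on
  observed nodes, where flipping a variant sign to its opposite costs 2
  and moving between variant and invariant costs 1. The all-zero
  coloring is always consistent, so a SCENFIT optimum always exists
  (unless an intervention is clamped, see below).

Projections are always computed over the *union* of consistent colorings
under all minimal repairs, never over a sampled witness: with several
tied repairs the union is what makes a node's class an invariant of the
instance rather than of a solver's tie-break.

## The exact engine

Both repair problems are solved exactly by evaluating the full candidate
coloring space: with k free nodes there are 3^k candidates, materialised
as an integer matrix and checked vectorised, rule by rule, per node. The
set of rule-violating nodes of each candidate is the key observation for
MCOS: exempting exactly those nodes makes that candidate consistent, and
every cardinality-minimal correction set arises as the violation set of
some candidate — so the optimum, all optimal repair sets and the pooled
colorings fall out of one pass. SCENFIT enumerates over all non-clamped
nodes (observed nodes may switch) and minimises the summed switch costs
over the fully consistent candidates.

We chose flat exhaustive evaluation over a branching search with
propagation because, at the problem sizes this package targets
(configurable bound of 12 free nodes, i.e. ≤ 3^12 ≈ 5.3 × 10^5
candidates), the vectorised scan is fast, trivially exact, and easy to
verify: the test suite cross-checks scores, complete repair sets and
projections against an independently written loop-and-subset brute-force
oracle on hundreds of random instances. Beyond the bound the engine
refuses rather than approximates; an external answer-set solver could be
plugged in behind the same interface, but exactness — not scale — is the
contract here.

## Discretization

Expression matrices (log2 scale, genes × profiles) are discretized
against the mean of the reference class: p = expression − reference
mean, then sign `+` if p > k2, `-` if p < −k2, `0` if |p| < k1. Values
in the gaps [k1, k2] and [−k2, −k1] yield *no* observation: the three
rules leave that band undefined, and an absent observation is exactly
what the partial-labeling semantics expects — forcing a call there would
manufacture certainty the data does not contain. Reference-class
profiles are discretized like any others (the reference mean includes
the profile itself; nothing suggests leave-one-out handling, and at
typical reference-class sizes the difference is a 1/N shrinkage).

Threshold pairs are chosen by grid search: pairs whose pooled variant
proportion exceeds 50% (strictly) are discarded, and surviving pairs are
ranked by repeated holdout precision — hide half of a profile's observed
genes, repair with MCOS, score the hidden genes that receive a strong
projection, report the mean with a ±1.96·sd/√n 95% interval. The default
grid crosses k1 ∈ {0.01, …, 0.10} with k2 ∈ {0.1, …, 1.5} (pruned to
k1 ≤ k2) and contains the reference pair (0.03, 0.2) used as the package
default throughout. Strict scoring (strong classes only, the mode whose
chance comparator is the 33% three-sign precision) is the default; a
lenient mode crediting any projection containing the hidden sign is
available and labelled as such in outputs.

## Graph construction

Large curated networks are cut down to the analysis scope in two steps.
*Extraction* keeps the union of all tied shortest directed paths from
the queried source pathways to each reachable target gene — all tied
paths, not one witness per target, because tie-breaking would make the
output depend on traversal order. Unreachable targets are dropped and
reported. *Compaction* then iteratively deletes unobserved non-input
nodes with exactly one predecessor or one successor, rewiring each
predecessor–successor pair with the sign product of the traversed edges
(two inhibitions compose to an activation); removals that would create a
self-loop are skipped, and sweeps visit nodes in sorted order so the
fixpoint is deterministic. Compaction preserves the coloring model on
retained nodes; rather than assume it, the test suite verifies on
random graphs that projection classes of retained observed nodes are
identical before and after (the guard covers the out-degree-1,
multi-predecessor case, where losslessness is least obvious). The
equivalence is asserted for consistent instances: under repairs, MCOS
sets may name nodes that compaction removed, so repair *sets* — unlike
projections of retained nodes — are not comparable across compaction.

## Signatures and perturbation

Per profile, MCOS projections of nodes never observed in any labeling
are decomposed into booleans M^s_ij (s ∈ {+, −}; invariant couples are
dropped to halve the variables). Frequency scores average M over the
profiles of a class, and assignments with FS higher in the case class
are ranked by a one-sided Fisher exact test — one-sided because the
direction filter has already fixed the hypothesis; the raw p-values are
reported (as is conventional for this ranking) with a clearly labelled
Benjamini–Hochberg column alongside, and sidedness is an explicit
option. Connectivity (observed genes reachable downstream of a node) is
annotated from the graph.

Perturbations clamp one unobserved node to a variant sign on top of a
profile's observations — the clamp is an intervention, never switchable
and never charged — and record the SCENFIT score SF^s_ij. Within each
profile and sign, the reference distribution is the SF of *all*
candidate nodes for that same sign, and a candidate is *top-ranked* when
its SF reaches the nearest-rank upper-q threshold (q = 0.10 by default):
sort decreasing, take the ⌈qK⌉-th value, count ties inclusively — a rank
statement, chosen because percentile interpolation would split ties
nondeterministically. TPS averages the top-ranked indicator over a
class; a one-sided Fisher test compares classes. Clamps that admit no
consistent coloring at all (possible only with hand-declared input sets)
score +Inf and are excluded from thresholds.

## The synthetic generator

Because the framework's published applications depend on cohort-scale
expression data and a retired pathway-database snapshot, the package
ships a generator that emulates the *statistical shape* of those inputs
at desk scale; its defaults are fixed once and double as the test-bed
conditions:

* graphs of 10 nodes at edge density 0.15 with 30% inhibitions, half
  the nodes observable genes on the sink side — sparse, cyclic,
  two-to-one case/reference class sizes (6 MC vs 3 NPC) mirroring a
  case-heavy cohort in miniature;
* planted-consistent labelings built by propagating random input signs
  through the condensation, cycles solved by bounded exhaustive search
  (≤ 3^8) — exactness over speed at this scale;
* corruptions flipping k variant observations (cost 2 each) or
  invalidating them (cost 1 each) with the switch list kept as ground
  truth;
* expression matrices with per-gene baselines from Normal(7, 1) log2
  units (cosmetic, configurable), case-class shifts of ±0.5 on 3 variant
  genes, Gaussian noise sd 0.1 — a shift comfortably above k2 = 0.2 and
  noise below it, so recovery is achievable but not trivial.

What passing tests on these inputs shows: the solver is exact, the
pipeline's bookkeeping is sound, and planted structure is recovered
under the stated noise. What it does not show: behaviour on real
pathway topology (hubs, motifs, dense reconvergence), on cohort-scale
profile counts, or under systematic measurement bias — none of which the
generator attempts to model.

## Numerical and design choices

* Problem sizes: tests and the acceptance script use graphs of 4–12
  nodes, 30–200 random instances per property, 10^5 draws for the
  random-precision comparators — sizes at which every optimum asserted
  is independently recomputable by brute force.
* Determinism: every stochastic function takes a seed; pipeline outputs
  are byte-identical across reruns and stamped with the seed and a
  configuration fingerprint.
* Ties and degenerate inputs: all tied shortest paths kept; all tied
  minimal repairs kept; nearest-rank quantile with inclusive ties;
  empty coloring sets make projection an error (not a silent default);
  holdout repetitions that score no node report `NA` and are excluded
  from means.
* Node ids are opaque strings; decorated names from curated databases
  (e.g. `"JUN/FOS[n]"`) pass through verbatim and are never parsed.
* Parallel opposite-sign edges are legal and contribute independent
  influences to the rules.

## Limitations

The exact engine is exponential in the free-node count and refuses past
its bound; compacting first, observing more nodes, or partitioning the
graph are the intended mitigations. Unsigned or unknown edge signs are
not supported. Multi-node (combinatorial) perturbations are out of
scope, as are supervised classification of the prediction matrix and
survival modelling downstream of the signatures — the prediction matrix
is exported in plain TSV precisely so such analyses can be run outside
the package.
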