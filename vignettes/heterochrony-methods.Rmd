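---
title: "Reconstructing sequence heterochrony on a phylogeny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing sequence heterochrony on a phylogeny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Developmental sequences can be compared across species by recording, for
each species, the rank at which each of a fixed set of developmental
events first appears (the onset of an appendage bud, a muscle precursor
group, a ganglion anlage, hatching, ...). Evolutionary changes in the
*relative order* of such events — sequence heterochrony — are then changes
in rank order between a species and its ancestors. This package
reconstructs ancestral ranked sequences on a rooted phylogeny, extracts
per-branch heterochronies with support values, and summarizes how
heterochrony is distributed over tissues, germ layers and body segments.
It ships the rank table of 33 events across seven crustacean species
(one branchiopod outgroup and six eumalacostracans) that motivated the
method, as `load_eumalacostraca_dataset()`.

Ranked sequences are integer vectors in *canonical dense form*: the
occupied ranks are exactly `1..k`, several events may share a rank
(simultaneity is first-class, and common in real tables), and `NA` marks
an event that is absent — unobservable or evolutionarily lost.
`canonicalize()` enforces this form at every module boundary, so rank
arithmetic is comparable across species with different numbers of
recorded stages.

## The edit cost: event-pair parsimony

The unit of comparison between two sequences is the *event pair*: for
events $i, j$ the relation is before, simultaneous, or after; it is
undefined if either event is absent. The edit cost between two sequences
is the minimal number of events whose movement explains every changed
pair relation. A set $S$ of events explains the changes iff every changed
pair has at least one endpoint in $S$, so the cost is exactly the minimum
vertex cover of the *conflict graph* whose edges are the changed pairs
(`parsimov_cost()`). We solve it exactly by branch and bound with a
pendant-vertex reduction and a greedy-matching lower bound; conflict
graphs here have at most 33 vertices, so exact solutions are instant.
Pairs involving absent events contribute nothing: absence is missing
data, never heterochrony, and gains/losses are reported separately
(`presence_diff()`).

`minimum_move_sets()` enumerates *all* minimum covers (capped) and labels
each moved event A (accelerated) or D (delayed) by comparing its
normalized position $(r-1)/(k-1)$ between the two sequences — normalized,
because the sequences may use different numbers of rank levels. An event
whose normalized position is unchanged (a pure tie change) is labelled
AMBIGUOUS; it still counts as a change in the rate statistics.

## Ancestral reconstruction: a GA over whole sequences

The whole sequence is treated as one complex character: an assignment of
a canonical sequence to every internal node is scored by the summed edit
cost over branches, and we search for minimum-cost assignments
(`optimize_tree()`). The defaults in `search_params()` are the study's
published settings: 100 cycles of selection per node, 200 candidate
sequences per cycle, up to 100 retained co-optimal sequences per node,
and up to 3,000 collected equal-score solutions.

Choices the original description leaves open are resolved as follows, as
this package's own design:

* **Presence at ancestors.** An event is present at every internal node
  iff it is present in at least one tip. An ancestor with an event marked
  absent would make all of that event's pairs undefined and spuriously
  cheap; treating tip absences as missing data (and separately as
  possible losses) avoids that degeneracy.
* **Initialization.** Post-order, each internal node starts from the
  rank-wise median of its children, re-canonicalized — a good, cheap
  incumbent.
* **Operators.** Mutation moves one uniformly chosen present event either
  by one rank level (joining the adjacent tie, or stepping out of its tie
  into a new level) or to a uniformly chosen existing level; mutations
  compound with probability 0.25 (up to three moves), which helps cross
  plateaus where no single move is improving. Crossover picks each
  event's rank uniformly from two retained parents and re-canonicalizes.
  The population is additionally seeded with the node's neighbours
  projected onto its presence pattern, so a node can adopt a neighbour's
  ordering wholesale.
* **Selection.** Each cycle evaluates the full population and retains all
  fitness-optimal candidates (up to the retention limit); offspring are
  generated from the retained set. Alongside the co-optimal set, each node
  archives the best distinct candidates it has seen (by local cost) across
  all sweeps — the recombination step searches over these, because a
  globally optimal assignment may pass through locally suboptimal node
  sequences. When a node's complete canonical-sequence space is no larger
  than the evaluations one GA pass would spend (up to six present events
  at the default parameters), the pass enumerates the space exactly
  instead of sampling it.
* **Schedule.** Alternating post-order and pre-order sweeps of the
  per-node GA run until a full sweep leaves the total cost unchanged.
  Then the retained per-node co-optimal sets are recombined *exactly*: a
  dynamic program over the tree computes the cheapest whole-tree
  combination of retained candidates and enumerates all minimum-cost
  combinations in deterministic order, up to the solution cap ("semi-
  exhaustive"). If recombination found a cheaper assignment than the
  sweeps did, it is adopted and sweeping resumes; the loop stops at a
  fixed point. On the built-in dataset this schedule reaches total costs
  at or below the worst of the original runs (the acceptance suite checks
  against that bound), typically in one to three minutes per run on one
  CPU.
* **Root and outgroup.** The root's local objective uses its children
  only. Following the study design, the outgroup row is added twice
  (`duplicate_outgroup = TRUE`), both copies attached at the root, so the
  outgroup's naupliar condition anchors the root sequence.
* **Randomness.** One seeded RNG per run; the pipeline's runs use seeds
  `seed, seed+1, seed+2`, so a manifest reproduces a run bit for bit.

`exhaustive_tree_search()` enumerates every canonical sequence at every
internal node (at most 5 present events and 4 internal nodes — 541
candidate sequences per node at 5 events) and serves as the independent
optimum oracle in the tests.

## Consensus and support

Within one solution, a branch's heterochronies are decided by a strict
majority over that branch's minimum move sets, so each solution casts one
vote per branch/event/direction. Across solutions, a record enters the
consensus iff it occurs in more than 50% of solutions; its percentage is
reported as support, in (50, 100]. A per-run consensus is built from that
run's pool (`pseudoconsensus()`); the cross-run summary pools all
solutions of all runs (`superconsensus()`) — pooling rather than
averaging per-run support tables keeps support interpretable as a
fraction of solutions. Ancestral sequences are mean-rank summaries over
the pooled solutions (`mean_rank_ancestors()`): per node and event the
rank is averaged (absent anywhere stays absent) and the means are
re-canonicalized, with ties only at exact mean equality. Because of this
averaging, reconstructed ancestral sequences can show slight positional
differences that are not reported as heterochronies.

The enumeration cap on move sets per branch defaults to 64, which bounds
memory in consensus pooling; raising it on the built-in dataset changes
supports only marginally (branch cover counts are small compared to the
cap in all solutions we examined).

## Heterochrony rates

The rate of an event is (number of consensus records for the event) ×
(mean support of those records, as a fraction); an event absent from all
records has rate 0, and direction never matters. Tissue rates are
unweighted means over the fixed event groups (6 epidermal, 18 myogenic, 7
neurogenic events; the segmentation-offset and hatching events belong to
no tissue). The ectoderm rate is the unweighted mean of the epidermis and
neural rates — the event-weighted mean would not reproduce the published
germ-layer table — and the mesoderm rate equals the muscle rate. Segment
rates exclude the four events with problematic segment affiliation
(segmentation offset, stomodeal muscles, nauplius eye, hatching); the two
composite events (the joint antennal buds, the naupliar ganglia) assign
their rate to each constituent segment, and segments with several
myogenic events take the mean.

## The synthetic generator

`simulate_sequences()` evolves a random canonical root sequence along a
tree: per branch, a Poisson number of uniformly chosen events relocate to
uniformly chosen rank levels, and events may be lost with a fixed
probability (inherited). Defaults (33 events, 10 levels, tie probability
0.35) mirror the built-in table's shape, so synthetic difficulty is
comparable. Every relocation is recorded together with its net normalized
displacement over the branch; shifts that cancel, and shifts of events
lost on the same branch, are unobservable in principle and are excluded
from the recall denominator of `recovery_score()`.

The generator plants *independent, uniform* shifts. It does not emulate
correlated or modular co-shifting of tissue-linked events, rate variation
across lineages, or observational rank compression near the end of a
sequence — so a green recovery test establishes that the pipeline can
find isolated planted reorderings at the simulated noise level, not that
it resolves every pattern real data may show.

## Numerical and degenerate cases

Non-positive ranks are rejected by validation; a sequence with a single
rank level has all normalized positions 0; identical sequences yield a
single empty move set; an empty solution pool is a validation error, as
is a consensus over pools from different trees. Vertex-cover enumeration
visits each cover exactly once (include/exclude branching on an endpoint
of the first uncovered edge), so support counts cannot double-count a
cover. Event universes are capped at 64 events (bitset adjacency); the
NEXUS dialect additionally caps ranks at 12 (`a`/`b`/`c` encode 10–12,
`z` absence).

## Known limitations

The GA is a stochastic heuristic: equal-cost attribution of changes to
events is genuinely ambiguous, and different optima can distribute
heterochronies differently over individual events even at identical tree
length (the event-level rates are correspondingly noisier than the
tissue-level means). The exhaustive oracle is limited to tiny instances;
for the 33-event dataset, optimality cannot be certified — only that the
search matches or improves on the published tree lengths. Branch lengths
and event weights are out of scope, and the NEXUS reader is deliberately
restricted to the dialect used here.
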