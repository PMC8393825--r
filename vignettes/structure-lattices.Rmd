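---
title: "Structure lattices for RA and BN models: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure lattices for RA and BN models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rabn)
```

## The two model families

Both model families describe a joint distribution over discrete variables
through a graph that encodes conditional independencies.

**RA structures** are antichains of relations (subsets of variables) whose
union covers the system, written `AD:BD:CD`.  The model associated with a
structure is the *maximum-entropy* distribution matching the data's margins
on every relation.  A structure is *loopless* when its hypergraph is
acyclic, decided by Graham reduction (repeatedly delete variables private to
one relation and relations embedded in another; loopless iff the reduction
empties the structure).  Loopless structures are decomposable: the maxent
solution is the classical clique/separator product and iterative
proportional fitting (IPF) reaches it in one sweep.  Loopy structures
genuinely iterate.  Independence semantics: (x ⊥ y | S) holds iff S
separates x and y in the co-occurrence graph (variables adjacent when they
share a relation).

**BN models** are DAGs; the fitted distribution is the product of empirical
conditionals p(node | parents), and (x ⊥ y | S) holds iff x and y are
d-separated given S.  We decide d-separation by the moral ancestral graph
(restrict to ancestors of {x, y} ∪ S, marry co-parents, drop directions,
delete S, test connectivity), which is equivalent to the active-trail
criterion and conveniently loop-free to implement.  Two DAGs are Markov
equivalent iff they share skeleton and V-structures; these classes are the
*specific graphs*, represented compactly by a CPDAG.  Grouping classes by
independence structure up to variable relabeling gives the *general
graphs*.

**Equivalence across families.**  A BN class without V-structures fits the
same distribution family as the loopless RA structure given by the maximal
cliques of its (moral) graph; conversely V-structured classes have no RA
counterpart and loopy RA structures no BN counterpart.  We therefore define
RA–BN equivalence as: identical labeled elementary independence sets *and*
loopless RA *and* V-structure-free BN.  Equality of independence sets alone
would spuriously pair every no-independence loopy structure with the
complete DAG; the restriction makes equivalence coincide with equality of
distribution families, and reproduces the published joint-lattice counts
(61 equivalent labeled pairs at n = 4 — exactly the labeled chordal graphs
on four vertices — and 10 equivalent unlabeled pairs).

## Notation

The grammar is `part (":" part)*` with `part = VARS [ "_" group (":"
group)* "_" ]`.  Canonical printing sorts variables within a relation in
system order and relations by descending size then lexicographically; the
notation itself is order-free, so published strings are compared by parsing
both sides (the source material itself alternates between e.g.
`BCD:ABD_A:B_` and size-then-lex order).

Subscript blocks encode the independencies that V-structures add inside a
moral clique.  Generation: within each maximal clique of the moral graph,
every pair of members non-adjacent in the skeleton gets its minimal
d-separating set S (smallest, ties broken lexicographically); pairs sharing
S are merged into groups (two members stay in one group unless some pair
separates them), and each group is printed with S appended — `(A ⊥ B | C)`
inside clique ABCD becomes `_AC:BC_`, mutual independence of A, B, C
becomes `_A:B:C_`.  Statements whose variables span cliques (or whose
minimal separator leaves the clique) are carried by the colon structure and
never subscripted.

## Compact independence lists

The full semantic currency is the set of elementary statements
(x ⊥ y | S); every compound statement is evaluated as a conjunction, valid
because graph separation satisfies composition.  For display we print an
*ordered local-Markov basis*: place vertices by repeatedly taking, among
those whose parents are all placed, the latest in system order; each vertex
contributes (x ⊥ predecessors \ parents | parents), empty statements are
dropped, and a contraction merge pools (X ⊥ R | S) with (Y ⊥ R | S ∪ X)
into (X, Y ⊥ R | S) — which is how two disconnected dyads print as
`(A, D ⊥ B, C)`.  This convention reproduces 19 of the 20 published
four-variable rows verbatim.  The remaining row (the graph `AD:BC:BD`)
admits two equally minimal bases — `(A ⊥ B | D), (C ⊥ A, D | B)` and
`(C ⊥ D | B), (A ⊥ B, C | D)` — with identical closures; no single
vertex-order rule generates the published choice for that row together
with the published choices for the star and collider rows, so we keep the
convention and document the difference rather than special-case it.  For a
loopless RA structure the display routes through its decomposable DAG
(maximum-cardinality search orders the chordal co-occurrence graph; edges
point from earlier to later, which creates no V-structures); loopy
structures fall back to deduplicated local-Markov statements
(x ⊥ non-neighbors | neighbors).

One enumeration convention deserves a note.  The published table of "all
possible independence statements" for four variables lists 46 forms with a
column-dependent treatment of symmetry (marginal pairs once per unordered
pair; compound right-hand sides once per left variable; a pair given one
variable once per unordered pair; a pair given both remaining variables
once per *ordered* pair).  `enumerate_independence_statements()` implements
exactly that convention, which yields 1 statement at n = 2 and 12 at n = 3;
no single convention can also produce the occasionally quoted 15 for
n = 3, and nothing downstream depends on the display enumeration — all
semantics use the elementary set.

## Lattices

*Neutral RA lattice.*  Children arise by deleting one non-singleton maximal
relation and re-exposing its embedded facets (the other relations plus all
(k−1)-subsets of the deleted relation, reduced to the maximal antichain).
Singleton relations are never deletable, so coverage is preserved and the
bottom is full independence.  Transitive closure from the saturated
structure yields 114 specific structures at n = 4; general classes are
unlabeled hypergraph-isomorphism classes (114 → 20).  We deliberately do
*not* define RA general classes by independence structure: loopy structures
(e.g. the four-triangle decomposition of the saturated relation) share
independence sets while being distinct models.

*Directed RA lattices.*  With IVs {A, B, C} and DV Z, the conventional
lattice consists of the IV relation plus every non-empty antichain of
Z-containing relations (19 structures).  The augmented lattice adds, for
each structure with at least two Z-relations, the variant with the IV
relation removed (singletons re-covering dropped IVs), plus the full
independence model — 31 structures.  The retention rule is structural
(with a single Z-relation the maxent prediction of Z is unchanged by
dropping the IV relation) and is audited numerically in the tests.
General classes of the directed lattices group by *unrestricted* unlabeled
isomorphism — the directed lattices label their general graphs by the
neutral general graph each structure belongs to, which yields the published
9 (conventional) and 12 (augmented); grouping with Z held fixed would give
15 for the augmented lattice.

*Joint lattice.*  Both families map onto the eleven unlabeled
variable-adjacency (Rho) graphs on four nodes (RA via co-occurrence, BN via
skeleton).  Per Rho graph we bucket RA-only structures (all loopy), BN-only
classes (all V-structured) and equivalent pairs; the four-cycle Rho graph
is the one whose RA and BN occupants are non-equivalent.  Totals: 30
general, 238 specific.

*BN directed lattice.*  A DV must not be a parent node within a
V-structure.  We read "within" operationally: every edge into a collision
node (a node with at least one non-adjacent parent pair) takes part in the
convergence, so *every* parent of such a node is excluded, not only the
members of non-adjacent pairs.  The narrow reading would admit three extra
n = 4 classes (e.g. `ABCZ_AZ:CZ_`, Z a parent of the collider child B) and
yield 21 retained classes instead of the published 18; those extra models
are exactly the collider-parent predictions deferred as BN-unique.
Eligible classes are partitioned by prediction equivalence — equality of
the fitted p(Z | A, B, C) as a function of the data, decided on two seeded
strictly-positive Dirichlet audit tables with values rounded to 1e-6
(distinct rational predictions on generic tables differ by orders of
magnitude more; float noise is ~1e-15) — and each partition retains its
least-df member, ties broken by canonical edge list.  Every retained class
maps to an augmented-RA structure with the same prediction; when both
`ABC:Z` and `A:B:C:Z` match (both predict the Z margin), the conventional
member is returned, matching the published table.

## Fitting, scores and search

IPF starts uniform, sweeps relations cyclically, and stops when the largest
absolute margin discrepancy falls below 1e-9 (cap 10,000 sweeps).  Zero
cells: empirical margins are used unsmoothed; conditionals on zero-mass
parent states default to uniform (they carry no likelihood weight).
Entropy and transmission are in bits; the likelihood-ratio statistic is
2·n·ln2·T between the fitted distributions, referred to χ² with the df
difference.  Degrees of freedom: RA structures count one u-term per
non-empty subset in the down-closure of the relations (∏(cardinality − 1)
each); DAGs count (card − 1)·∏ parent cards per node.  The two formulas
agree on every equivalent RA/BN pair, which is what makes least-df
selection meaningful across families.  Search is greedy (or beam) along
hierarchy edges, upward from full independence or downward from the
saturated model, under BIC, AIC, or a χ²-based rule (downward moves must
not lose significant information at α, upward moves must gain it).

## Synthetic data

`sample_from_model()` draws multinomial samples from an exactly known
generating distribution, returned with the draw.  For a DAG, conditional
tables are Dirichlet(1) per node and parent state.  For an RA structure the
generating distribution is the maxent projection (IPF) of a seed
distribution onto the structure, so the relation margins are the seed's and
the structure's independencies hold exactly; the seed is Dirichlet(1) over
the full table, optionally tilted toward the "all variables agree" states
by a mixture weight `effect_strength` (0.6 in the recovery experiments —
for binary variables this puts strong positive association inside every
relation while keeping all cells positive).  This emulates clean
categorical survey/assay data; it does not emulate structural zeros,
sampling bias, ordinal structure or measurement error, so a green recovery
test establishes correctness of the fitting/search machinery, not
robustness to real-data pathologies.

## Numerical and degenerate-input choices

Systems must have ≥ 2 states per variable; empty tables are rejected;
models over mismatched systems are rejected.  Transmission is +Inf when the
model has zero mass where the data has support.  Isomorphism and
signature computations permute labels exhaustively (n! with n ≤ ~6 by
construction — DAG enumeration refuses n > 6).  The elementary-set
signatures assume single-character variable names, which holds for every
enumerated lattice; parsing supports multi-character names with comma
delimiters for data work.

## Known limitations

Exhaustive enumeration only (no PC/GES-style scalable learning); no causal
semantics or interventions; no missing data, exact small-sample tests, or
Bayesian scores; state-based RA structures and continuous variables are out
of scope; hybrid graphs mixing loops and V-structures are not represented.
The display minimization is a convention — semantics never depend on it.
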