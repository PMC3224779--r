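---
title: "Validating logically defined ontologies by EL reasoning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating logically defined ontologies by EL reasoning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontodiff)
```

## The model

A cross-product logical definition declares a target term equivalent to an
intersection of named classes and existential restrictions:

$$D \equiv g_1 \sqcap \dots \sqcap g_m \sqcap \exists r_1.f_1 \sqcap \dots \sqcap \exists r_k.f_k$$

with genera $g_j$ (typically a PATO quality) and differentia $(r_i, f_i)$
over relations such as `inheres_in`, `towards` and `qualifier`, the fillers
$f_i$ drawn from building-block ontologies (GO, anatomy, ChEBI, ...). The
validation question is purely deductive: which subclass relations among the
defined target terms follow from the definitions together with the asserted
subsumptions of the building blocks, and how does that inferred hierarchy
compare with the hierarchy curators asserted in the target?

Three assumptions underpin the method. First, the building blocks supply
their knowledge as `is_a` axioms (optionally plus typed relationship edges);
they are trusted, not revised, by the run. Second, the definitions use only
conjunction and existential restriction — the $\mathcal{EL}$ fragment — so
classification is polynomial and incoherence is impossible (there is no
negation or disjointness to violate). Third, the comparison is advisory:
every disagreement is reported with its provenance, and nothing is repaired
automatically, because an asserted link the definitions cannot derive may
encode a legitimate different view rather than an error.

## Subset extraction

Only the terms a definition references, and their ancestors, can take part
in a derivation, so each building block is reduced to its *induced ancestral
graph*: the referenced terms plus every ancestor on every path to the
root(s), with **all** `is_a` and relationship edges between retained terms
carried over. Upward closure follows `is_a` by default; `closure_relations`
can add relations like `part_of` for ontologies where such paths matter,
since no published convention settles whether they should. Extraction is
idempotent and monotone in the seed set, and — the property the whole
optimization rests on — the pipeline output over subsets is byte-identical
to a full import. The test suite re-verifies that identity on fifty
generated corpora; `full_import = TRUE` remains available to force the
expensive route.

Terms referenced by a definition but absent from the supplied release are
not fabricated and do not abort the run: they are kept as fresh atomic
classes (subsuming only themselves), warned about, and counted. A stale
reference therefore suppresses inferences rather than inventing them, and
the warning is itself a curation signal. Obsolete terms are likewise
excluded from reasoning but retained in the model so findings can name
them; how a historical tool treated them is undocumented, so exclusion is
this package's own policy. `is_a` cycles in any input abort the run with a
typed error — breaking a cycle arbitrarily would corrupt the ancestral
closure, so no attempt is made.

## Reasoning

The composite ontology (subsets + definitions + bridges) is normalized into
the four EL normal forms ($A \sqsubseteq B$, $A \sqcap B \sqsubseteq C$,
$A \sqsubseteq \exists r.B$, $\exists r.A \sqsubseteq B$). Each definition
contributes both directions of its equivalence: the defined term is placed
under every conjunct, and the converse is encoded with deterministic fresh
names (one per differentium, plus a left-associated chain of binary
conjunctions), so runs are bit-reproducible regardless of input order.
Relationship edges are read as $S \sqsubseteq \exists r.O$, the standard
OBO-to-OWL interpretation; `translate_relationships = FALSE` turns this
off, since their effect on target inferences depends on whether any
definition quantifies over those relations. The fragment is deliberately
fixed — no role hierarchies, chains, inverses or nominals — because the
definition pattern uses none of them, and a smaller fragment keeps the
completion calculus exactly matched to its inputs.

Saturation applies the standard completion rules (transitivity,
conjunction introduction, existential propagation) to a fixpoint over
subsumer sets, implemented on logical matrices. The result is restricted
to original names; fresh names never escape. Bridge equivalences — derived
from a bridging ontology's cross-references and/or its cross-namespace
subclass axioms, both readings supported because the historical generator
is described only in one sentence — enter as paired inclusions and are kept
out of the graph itself so explanations can attribute an inference to
bridging. A generic class cross-referencing two classes of one namespace is
bridged to both; the resulting intra-namespace equivalence then surfaces in
the equivalence report for a curator to judge, rather than being silently
merged.

Correctness is not argued once; it is continuously cross-checked against an
independent implementation, `el_classify_canonical()`, which materializes
the least (canonical) model — one domain element per named class, class and
role extensions grown to fixpoint — and reads subsumption off as model
membership. The two routes share no code and disagree on nothing across
hundreds of random composites covering cyclic subclass graphs, multi-genus
definitions, bridges and relationship edges.

## Comparison semantics

The inferred hierarchy over defined target terms is reduced before
comparison: equivalence classes collapse onto their lexicographically
smallest member, and the strict order is cut to its transitive reduction,
so the reported edges are the *direct* ones a curator would actually add.
Each inferred edge is then **directly found** (asserted as an edge),
**indirectly found** (the parent is reachable from the child through two or
more asserted edges — the only reading of "indirect" consistent with
"direct" meaning edge membership), or **new**. In the opposite direction,
every asserted edge whose two endpoints both carry definitions is checked
for entailment against the closure — entailment, not mere presence among
direct inferred edges, so an asserted shortcut over a derivable chain is
not flagged spuriously. Asserted edges touching an undefined term are
excluded from that direction and counted separately, since absence of a
definition makes non-entailment vacuous. Equivalence classes of size two or
more are reported once per class, members sorted.

`trace_explanation()` reconstructs the *why* of an inferred edge: for each
conjunct of the parent's definition, the supporting conjunct of the child's
definition and the chain of building-block subsumptions and bridges
connecting them (shortest such chain; ties broken deterministically). When
both definitions are conjunct-for-conjunct identical the trace says exactly
that — the signature of a duplicated definition.

## The synthetic corpus generator

`generate_corpus()` emulates the data this tool meets in production: a
quality namespace (`PQ`) and `n_blocks` entity namespaces as random rooted
DAGs (rank-ordered parent sampling, acyclic by construction; default 15
terms per block at an expected 1.5 parents, with occasional `part_of`
edges), and entity-quality definitions — one quality genus plus one
existential filler per entity block, `inheres_in` for odd and `towards`
for even blocks. Roughly half the definitions specialize an earlier one in
a single coordinate, mirroring how real definition sets refine along one
axis at a time and guaranteeing a non-trivial true hierarchy; 12 defined
terms is the default, small enough that a corpus classifies in well under
a second and large enough to support the standard planting of three
missing links, two spurious links and one duplicate.

The target's asserted hierarchy starts as the *true* entailed hierarchy
(computed combinationally from per-block ancestor sets, independently of
the reasoner), then disagreements are planted with exact ground truth:
deleted edges are chosen so the parent becomes unreachable (hence must
return as `new`, not `indirect`); inserted edges are verified non-entailed
and acyclicity-preserving; duplicated definitions get fresh ids that sort
after all originals so representatives stay stable. A draw that admits no
valid planting is retried under derived sub-seeds a bounded number of
times before the requested configuration is declared infeasible; everything
is a deterministic
function of the seed.

What passing these tests shows — and what it does not: the generator
produces clean, prefix-disjoint, modestly sized corpora. Real ontologies
add scale (tens of thousands of classes), messier metadata, inter-ontology
references and versioning drift. The logic exercised is the same, but
performance at full MPO scale and robustness to malformed OBO files beyond
the parsed subset are not claims the test suite makes.

## Numerical and procedural choices

Fixpoint computations have no tolerances — saturation stops exactly when no
rule adds a fact. All orderings (stanza order, report line order, equivalence
members, tie-breaks among equally short explanation chains) use bytewise
(radix) sorting, never locale collation, so every output is byte-identical
across runs and platforms. Identifiers are accepted in both the colon and
underscore CURIE dialects and always rendered in the colon form. Duplicate
`[Term]` stanzas follow last-writer-wins with a warning; two *different*
definitions for one term across files are an error, since silently picking
one would change the logic. A definition needs at least two
`intersection_of` conjuncts — a single conjunct is not an intersection and
is ignored.

The problem sizes used by the verification suite — 200 random EL composites
of up to 40 names against the canonical-model oracle, 50 corpora for the
subset-invariance identity, 20 corpora for planted-disagreement recovery —
were chosen as the point where every implemented rule and category is
exercised many times over while the whole suite stays comfortably
interactive.

## Limitations

The reasoner covers exactly the EL fragment the definition pattern needs;
definitions using constructs outside it would require an external OWL
reasoner, for which the `backend` option is the designated integration
point (only the internal engine ships). OBO parsing covers the tags the
pipeline consumes (`id`, `name`, `is_a`, `relationship`,
`intersection_of`, `xref`, `is_obsolete`); other metadata passes through
unparsed and is not preserved on write. Explanations are rule-application
traces, not minimized justification sets. The tool deliberately never
edits either ontology.
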