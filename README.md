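# ontodiff

Reasoning-based quality control for logically defined biomedical
ontologies.

## The problem

Large application ontologies — the Mammalian Phenotype Ontology is the
motivating case — increasingly carry *cross-product logical definitions*:
each term is declared **equivalent to** the intersection of a genus class
and one or more existential restrictions over terms from building-block
ontologies (GO for processes, an anatomy ontology, PATO for qualities,
ChEBI for chemicals). In OBO syntax:

```
[Term]
id: HP:0001943 ! Hypoglycemia
intersection_of: PATO:0001163 ! decreased concentration
intersection_of: qualifier PATO:0000460 ! abnormal
intersection_of: towards CHEBI:17234 ! glucose
intersection_of: inheres_in FMA:9670 ! Portion of blood
```

which reads, in description-logic notation,

```
Hypoglycemia ≡ DecreasedConcentration ⊓ ∃qualifier.Abnormal
                ⊓ ∃towards.Glucose ⊓ ∃inheres_in.PortionOfBlood
```

If the definitions and the building blocks are right, the asserted `is_a`
hierarchy of the target ontology should follow logically from them. Where
it does not, either the target hierarchy or a definition needs curator
attention. `ontodiff` finds every such disagreement:

1. **implied but unasserted** subclass links (candidate additions to the
   target),
2. **asserted but unsupported** links (the definitions do not entail
   them),
3. **inferred equivalences** between distinct target terms (duplicates or
   copy-paste errors in the definitions).

Because only the terms a definition references — plus their ancestors on
all paths to the root, the *induced ancestral graph* — can influence these
inferences, `ontodiff` extracts exactly that subset from each building
block before reasoning. The reports are provably identical to a
full-import run; the composite ontology is just far smaller.

Classification is done by a built-in EL-fragment reasoner (conjunction +
existential restriction, the exact fragment the definition pattern uses):
axioms are normalized into the four EL normal forms and saturated with the
standard completion rules, which is sound, complete and polynomial for
this fragment. An independent canonical-model evaluator
(`el_classify_canonical()`) is shipped as a cross-check.

## A worked example

The classic finding: *abnormal copper homeostasis* and *abnormal ion
homeostasis* are unrelated in the target, but their definitions point at
GO terms that are related.

```r
library(ontodiff)

corpus <- example_corpus("copper_homeostasis")
report <- validate_corpus(corpus)
report
#> <comparison_report>
#>   inferred direct edges: 1 (found directly 0, indirectly 0, new 1)
#>   asserted edges between defined terms: 0 (entailed 0, not entailed 0; 2 excluded, endpoint undefined)
#>   inferred equivalence classes: 0

tidy(report)
#> # A tibble: 1 × 6
#>   direction          child      child_label                 parent     parent_label             category
#>   <chr>              <chr>      <chr>                       <chr>      <chr>                    <chr>
#> 1 reasoned_to_target MP:0003951 abnormal copper homeostasis MP:0001765 abnormal ion homeostasis new
```

The one inferred edge is classified `new`: the definitions imply it, the
target does not assert it — a priority item for curation. The trace shows
*why* the reasoner derived it:

```r
trace_explanation(report, "MP:0003951", "MP:0001765")
#> <axiom_trace> MP:0003951 [= MP:0001765
#>   MP:0003951 := PATO:0000001 and qualifier some PATO:0000460 and inheres_in some GO:0006878
#>   MP:0001765 := PATO:0000001 and qualifier some PATO:0000460 and inheres_in some GO:0050801
#>   PATO:0000001 supported by PATO:0000001
#>   PATO:0000460 supported by PATO:0000460
#>   GO:0050801 supported by GO:0006878 via GO:0006878 ->(is_a) GO:0050801
```

`glance(report)` gives the category counts as a one-row tibble and
`autoplot(report)` as a bar chart. On files instead of in-memory corpora,
`run_pipeline()` (or the `exec/ontodiff` command-line driver with the
`-t/-o/-d/-x/-s/-r` flags) reads OBO inputs and writes the five report
files — `inf_ax_found.txt`, `inf_ax_not_found.txt`, `assert_ax_found.txt`,
`assert_ax_not_found.txt`, `equivalence_ax.txt` — plus `composite.obo`,
`reasoned.obo` and a `summary.tsv`, all byte-stable across runs. The two
`*_not_found` files append the logical definitions of both terms of every
reported axiom, the hint a curator debugs from.

Synthetic corpora with known ground truth come from `generate_corpus()`:
random building-block DAGs, entity-quality definitions, and planted
disagreements of all three kinds that the pipeline must recover exactly.

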