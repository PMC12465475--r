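---
title: "Mapping a national drug terminology to RxNorm/RxNorm Extension: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a national drug terminology to RxNorm/RxNorm Extension: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxnemap)
```

## The mapping problem

A national drug register row describes a marketed product: a national code,
a product name, ingredients with strengths (usually in the national
language), ATC references, a dose-form text, sometimes an EU registration
number, and — possibly from a separate supplement — the box size and, for
liquids and inhalers, a total volume or actuation count. The OMOP side
offers RxNorm and RxNorm Extension (jointly RxN/E): a hierarchy of concept
classes ordered by information content, from `Ingredient` through
`Clinical Drug Component`, `Clinical Drug Form`, `Clinical Drug`,
quantified and boxed variants, up to packs, each clinical class shadowed by
a branded counterpart.

`rxnemap` maps each source product to the *finest attainable* class in that
order. The guiding principle is *gather, then refine*: at every level all
plausible candidates are kept as a set, and each further piece of evidence
(strength, brand, size, box) is used to climb one level while discarding
candidates that the evidence contradicts. Coarser candidates are never
deleted — if the climb stalls, the finalization falls back to the finest
populated level, ultimately to the ingredient baseline.

### Assumptions

* The vocabulary store behaves like the OMOP drug vocabulary: the upward
  links (is-a, consists-of, tradename-of, quantified-form-of, box-of,
  marketed-form-of, has-ingredient) form an almost-acyclic hierarchy.
  Cycles, which real vocabulary releases occasionally contain, are
  tolerated by visited-set traversal and reported.
* Ingredient semantics are carried by names, ATC references, CAS numbers
  and brands; no fuzzy or learned matching is attempted. A miss is
  preferred over a guessed hit, because every row is destined for human
  review in Usagi.
* Active-versus-excipient classification is taken from the source
  terminology as given.

## Concept-class granularity

The class order is a strict total order (`granularity_order()`): Ingredient
< Dose Form < Brand Name < components < drug forms < Clinical Drug <
Clinical Drug Box < Quantified Clinical Drug < Quantified Clinical Drug Box
< packs < Marketed Product, with every branded class at its clinical rank
plus 0.5. Dose Form and Brand Name carry ranks for ancestor comparisons but
are never final mapping targets; neither are components and drug forms,
which serve as refinement intermediates (`TARGET_CLASSES` in the pipeline).
Ties in candidate selection break first by this order, then by the smaller
concept id, making every output deterministic.

The ancestor closure used by `ancestors()` and
`finest_common_ancestors()` is computed from relationship edges at load
time rather than read from a precomputed ancestor table, so a fixture world
needs only relationships; which relationship ids count as hierarchy is a
`graph_config()` setting.

## Tunable parameters

| Parameter | Default | Unit/range | Why this default |
|---|---|---|---|
| `alpha` | 0.5 | fraction of max vote weight | accepts a form only if it gathered at least half the support of the best form; keeps genuine granularity splits (one source form, two RxN/E forms) while discarding noise. 1.0 would keep only the winner. |
| `strength_tol` | 1e-4 | relative | strengths in vocabularies are rounded prints of the same number; 0.01 % separates rounding from genuinely different strengths (59.4 vs 59.5 MG/ML differ by 0.17 %). |
| `brand_min_token_chars` | 3 | characters | single-token brands shorter than three characters ("AL") prefix-match half the register; multi-token brands are exempt because their full token sequence must match. |
| `second_pass_votes` | TRUE | — | once drug components exist they are far more specific anchors than ingredients; the second pass *recomputes* tallies from scratch rather than accumulating, so no drug votes twice. |
| `unit_table` | mg / mL canonical | — | RxN/E normalizes weights to milligrams and volumes to millilitres; the table is config so national unit spellings ("I.E.") can be added. |

Match scores are an explicit heuristic, not a probability: 0.3 for a mapped
ingredient, +0.2 dose form, +0.2 strength, +0.15 brand, +0.15
quantity/box, capped at 1. Usagi requires *some* score for sorting; this
one is monotone in evidence and flat within an evidence profile, which is
all a reviewer queue needs.

Equivalence hints follow the final class: ingredient-only rows are marked
`WIDER` (the target describes more products than the source code), rows at
a box class are `EQUAL` (the target pins down the marketed product
including its pack size), everything between is `RELATED`. The hints are
translated to the R4B `equivalence` and R5 `relationship` code systems on
ConceptMap export.

## Numerical and procedural choices

* **Name normalization** (shared by every module that compares names):
  lower-case, German umlaut/ß transliteration (ä→ae, ö→oe, ü→ue, ß→ss),
  Latin diacritic folding, non-alphanumeric runs collapsed to single
  spaces. Synonym expansion additionally generates surface variants
  (space↔hyphen, punctuation stripping) and closes the set under the rules,
  so applying it twice changes nothing.
* **Strength comparison** is symmetric and unit-gated: quantities only
  compare when their canonical units are identical; mg never matches UNT.
  Percent strengths convert only under an explicit weight-per-volume
  convention (`% w/v`, ×10 mg/mL); a bare `%` raises a unit error and the
  ingredient proceeds without strength. Actuation counts pass through
  unconverted.
* **Clinical drug derivation** enforces exact component-count equality: a
  two-component clinical drug never matches a one-ingredient product, and
  partial covers are rejected, preventing combination products from
  collapsing onto their single-ingredient neighbours.
* **Box sizes** compare as exact integers; total sizes use the same
  relative tolerance as strengths.
* **ATC precedence**: candidates from other strategies that contradict a
  nonempty ATC baseline are dropped unless they are hierarchy descendants
  of it — and every such conflict is logged rather than silently resolved,
  because disagreements frequently indicate vocabulary defects worth
  reporting upstream.
* **Degenerate inputs**: drugs without active ingredients, unparseable
  registration ranges, malformed strengths and unknown units degrade to
  warnings plus the coarsest mapping still supported, never to errors.

## Design decisions where the design was open

* *Merged candidate sets, not first-hit-wins.* The five ingredient
  strategies run in order but their outputs are unioned (under ATC
  precedence). Rationale: later refinement stages are better arbiters than
  strategy order.
* *Brand prefix semantics.* A brand matches only if its **complete** token
  sequence prefixes the product name's token sequence. The alternative —
  any common prefix — over-matches families of brands sharing a stem.
* *Vote splitting is equal (`1/k`).* Weighting by retrieval provenance was
  considered and rejected: without calibration data any unequal weighting
  is arbitrary, and equal splitting keeps the conservation invariant (tally
  sum = contributing drugs) exact.
* *Fallback to the finest populated class.* When a box size is known but no
  box concept exists, the mapping stops at the finest class that does exist
  rather than emitting nothing.
* *Packs are manual-only.* Pack content is not publicly distributed in the
  vocabulary; pack mappings enter through the override table and win
  unconditionally.
* *Translation matching spans all languages of a shared-identifier group*,
  not only the designated source language — the identifier, not the
  language tag, carries the synonymy.
* *Validation counts pairs.* When several source codes share a registration
  number, each (left, right) pair becomes one validation record.
* *Vocabulary persistence* uses a single-file serialized store
  (`save_graph()`/`load_graph()`), one file per vocabulary snapshot.

## What the synthetic worlds do and do not show

`generate_world()` plants, for every synthetic drug, exactly the concept
chain its attributes imply, and records the finest planted concept as
ground truth. The knobs mirror the difficulties of real registers:
ingredients reachable *only* via translation, CAS or brand; multi-ingredient
products; missing strengths; liquids with total sizes; boxed and branded
products; registration numbers present for only part of the register. The
defaults (40 ingredients, 40 % branded, 70 % boxed, 25 % of liquid-capable
forms quantified, 50 % registered, 20 % translation-only, 20 % CAS-only,
10 % brand-only, 15 % multi-ingredient, 5 % missing strength) are one
fixed, documented choice of a plausible register profile.

Recovery tests run at 200 drugs per world across seeds 1–20 — about 1,200
concepts per world, which exercises every refinement path while keeping a
full 20-seed sweep inside a few minutes on one CPU. Passing them shows the
machinery is sound: every planted chain is climbed to its top, and no drug
is mapped past what its evidence supports.

They do **not** show real-world mapping rates. Real registers contain
spelling noise, homonyms, brand families, vocabulary duplications and
concepts that simply do not exist in RxN/E; the generator plants none of
these (beyond route exclusivity and missing attributes), because a planted
world must have a well-defined truth. Real-world performance is a question
for expert review of the Usagi output, which is why review status
round-trips through `merge_previous()` are part of the contract.

## Known limitations

* No fuzzy or phonetic matching: a misspelled ingredient name that no
  synonym rule repairs stays unmapped at that route.
* Dose-form voting keys on the source dose-form *text*; registers that
  reuse one text across semantically different forms will blur tallies.
* Percent strengths without an explicit w/v convention, and actuation-based
  quantities, are not converted.
* Marketed Product, and the creation of new RxN/E concepts, are out of
  scope; packs require manual overrides.
* The FHIR ConceptMap validator checks the structural rules this package
  emits against (element/target shape, release code systems); it is not a
  full FHIR profile validator.
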