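# rxnemap

Semiautomated mapping of a national drug product terminology to standardized
OMOP **RxNorm / RxNorm Extension (RxN/E)** concepts at the finest attainable
concept class.

National drug registers identify marketed products by a national code (for
instance Austria's PZN) and describe them with German-language ingredient
names, strengths, ATC references, dose-form texts, brands and pack sizes.
OMOP analyses need those products expressed as standard RxN/E concepts —
ideally not just at the coarse ingredient level that ATC crosswalks provide,
but as the clinical drug, branded drug, quantified drug or drug **box**
concept that actually describes the marketed product. `rxnemap` is for
terminology teams and OMOP ETL engineers who need such mappings, want them
reviewable in OHDSI's Usagi tool, and want to publish them as HL7 FHIR
ConceptMaps.

## Method

The pipeline walks up the RxN/E concept hierarchy, gathering all plausible
candidates at each level and refining them with every piece of evidence the
source row offers:

1. **Ingredients** — five strategies produce candidate ingredient concepts
   with provenance: (i) monocomponent **ATC** classes followed over the
   lateral ATC→ingredient link; (ii) **exact name** matching of the
   ingredient's synonyms (case/diacritic/punctuation-normalized) against
   RxN/E ingredient names; (iii) **translation** of German names to English
   through a shared-identifier substance synonym table; (iv) the **CAS
   registry number** bridge (German name → CAS → chemical bridge concept →
   standard ingredient via maps-to); (v) a matched **brand** that is the
   tradename of exactly one ingredient. ATC-derived mappings act as a
   baseline that other strategies may refine but not contradict.
2. **Dose forms** — where an EU registration number is present, the dose
   form is taken from the registration's product-information extract via the
   EDQM→RxN/E dose-form alignment. Otherwise probabilistic **voting**: each
   drug retrieves the dose forms of all RxN/E drug concepts matching its
   anchors (ingredients, ATC targets, brand, later drug components) and
   casts one vote, split `1/k` over `k` retrieved forms; per source
   dose-form text, every form reaching `alpha` (default 0.5) of the maximum
   accumulated weight is accepted.
3. **Brands** — tokenized longest-common-prefix search of RxN/E brand names
   against the product name.
4. **Refinement** — strengths are normalized to canonical units (mg, mL) and
   matched against component strength rows within a relative tolerance
   (default 1e-4) to derive clinical drug components; brand evidence narrows
   them to branded components; components plus dose form yield clinical
   drugs (exact component-count cover required); total size selects
   quantified drugs; box size selects box concepts (exact integer match).
   The final mapping is the populated target class of maximal granularity,
   falling back to the ingredient baseline; pack products enter through a
   manual-override table.

Two independently produced mapping sets can be cross-validated by linking
them on EU registration numbers and computing the **finest common ancestor**
of their target concepts in the drug hierarchy — agreement at, say, the
clinical-drug-box level shows the two mappings describe the same product
even when one side adds brand information.

Everything is testable offline: a deterministic generator builds miniature
RxN/E-shaped worlds with planted ground-truth mappings.

## Worked example

```r
library(rxnemap)

w <- example_world()          # hand-built vocabulary + source drugs
res <- run_pipeline(w$graph, w$drugs, w$links)
res$rows[, c("source_code", "target_concept_id", "target_class",
             "match_score", "equivalence_hint")]
#>   source_code target_concept_id     target_class match_score equivalence_hint
#> 1     PZNB001             50004       Ingredient        0.30            WIDER
#> 2     PZND001             50008       Ingredient        0.45            WIDER
#> 3     PZNO001             50005       Ingredient        0.30            WIDER
#> 4     PZNP001          36888637    Clinical Drug        0.70          RELATED
#> 5     PZNR001             50024 Branded Drug Box        1.00            EQUAL
#> 6     PZNS001             50006       Ingredient        0.30            WIDER
#> 7     PZNZ001             50007       Ingredient        0.30            WIDER
```

Reading the rows: the benzocaine, digitoxin, olipudase, salicylic-acid and
zinc-sulfate products stop at the ingredient level (each reached by a
different strategy: ATC, brand, exact name, translation, CAS), so their
score is the 0.3 ingredient base (plus 0.15 brand evidence for the
Digimerck row) and the hint marks the target as wider than the product. The
penicillin G solution carries strength and a registration-derived dose
form, reaching its clinical drug (0.3 + 0.2 + 0.2 = 0.7). The entrectinib
capsule adds brand and box size and resolves to the branded drug box — a
complete product description, hence score 1.0 and hint `EQUAL`.

The common-ancestor comparator on the same world:

```r
fca <- finest_common_ancestors(w$graph, 36888637, 44123049)
fca$concept_id     #> 40072606  ("penicillin G Injectable Solution")
```

the two penicillin clinical drugs (59.4 MG/ML vs 1000000 UNT) agree at
their shared clinical drug form.

A larger synthetic study, end to end:

```r
world <- generate_world(fixture_spec(n_drugs = 200, seed = 1))
res <- run_pipeline(world$graph, world$drugs, world$links)
evaluate_recovery(res, world$truth, world$graph)[c("exact_rate", "ancestor_rate")]
#> $exact_rate   [1] 1
#> $ancestor_rate [1] 1
```

A command-line driver for shell use lives in `inst/cli/rxnemap.R`
(subcommands `load`, `map`, `convert`, `validate`, `demo`).

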