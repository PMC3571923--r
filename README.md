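# pkddi

Text mining of pharmacokinetic (PK) drug–drug interactions (DDI) from
biomedical abstracts, for pharmacologists and biomedical NLP researchers
who need the full chain from raw PubMed XML to classified interaction
pairs: controlled vocabularies, rule-based key-term tagging, a three-level
annotated-corpus model, a six-label relation classifier, inter-annotator
reliability, and an all-paths graph-kernel extraction pipeline — all
runnable offline on bundled or synthetic data.

## What it implements

**Key-term tagging.** Six term classes in sentence text: drug names (with
metabolites recognized through ten phase-I/II affixes such as *nor-*,
*hydroxyl-*, *O-dealkyl-*), CYP450 enzymes via a token-level pattern
`(?:cyp|CYP|P450|CYP450)?[0-9][A-Za-z][0-9]*(?:\*[0-9]+)?`, PK parameters
from a built-in ontology (AUC, CL, t½, C<sub>max</sub>, K<sub>i</sub>,
IC<sub>50</sub>, ...), numbers with units and p-values, mechanism stems
(inhibit-, induc-, metaboli-, ...), and change cues ("significantly",
"negligible", "doesn't interact").

**The relation classifier.** A candidate pair is labeled
`DDI / ADDI / NDDI` (in vivo) or additionally `DEI / ADEI / NDEI`
(drug–enzyme, in vitro) from four conditions — C1 ∧ C2 ∧ (C3 ∨ C4) —
where C1/C2 require the entities to be in the sentence or recoverable
from context, C3 applies numeric rules to the highest-priority PK
parameter (AUC > CL > t½ > C<sub>max</sub> in vivo; K<sub>i</sub> >
IC<sub>50</sub> in vitro):

| evidence (significant p) | label |
|---|---|
| FC ≥ 1.50 or FC < 0.67 | DDI (definite) |
| 0.67 < FC < 1.50 | ADDI (p < 0.05) / NDDI (p > 0.05) |
| K<sub>i</sub> or EC<sub>50</sub> < 10 µM | DEI |
| 10–100 µM | ADEI |
| > 100 µM, p > 0.05 | NDEI |

and C4 maps cue polarity (definite / ambiguous / negative, with negation
handling) to the same families. Thresholds and cue lists are configurable
through `ddi_rules()`.

**Reliability.** Nominal Krippendorff's alpha via the coincidence matrix,
for any number of annotators with missing data, plus extraction of
token-, sentence- and pair-level agreement units from parallel corpora.

**Extraction.** For every clear DDI sentence: metabolite removal, enzymes
pairable as drugs, C(n,2) candidate generation, six-label collapse to a
binary target (only DDI/DEI are true), a combined dependency +
part-of-speech graph per candidate (shortest-path edges 0.9, others 0.3,
linear chain 0.9, entities anonymized to `ENTITY1`/`ENTITY2`), the
all-paths graph kernel computed by the convergent series `(I − A)⁻¹ − I`,
and an SVM on the precomputed normalized kernel matrix with
document-level splitting and precision/recall/F reporting.

**Corpus I/O.** PubMed XML reading, abbreviation-aware sentence
splitting, a lossless three-level corpus XML dialect, conversion to the
unified DDI-extraction XML layout, colored HTML rendering, and corpus
statistics. A synthetic-corpus generator (`simulate_corpus()`) produces
fully ground-truthed fixtures so everything runs without downloads.

## A worked example

```r
library(pkddi)

sentence <- "Ketoconazole significantly increased the AUC of midazolam by 3.2 fold (P<0.01)."
tag_terms(sentence)
#> # A tibble: 7 × 8
#>   sentence_index start   end text          category     normal_form  unit  value
#>            <int> <int> <int> <chr>         <chr>        <chr>        <chr> <dbl>
#> 1              0     0    12 Ketoconazole  DRUG         ketoconazole <NA>  NA
#> 2              0    13    26 significantly CHANGE       significant  <NA>  NA
#> 3              0    27    36 increased     CHANGE       increase     <NA>  NA
#> 4              0    41    44 AUC           PK_PARAMETER AUC          <NA>  NA
#> 5              0    48    57 midazolam     DRUG         midazolam    <NA>  NA
#> 6              0    61    69 3.2 fold      NUMBER       3.2          fold   3.2
#> 7              0    71    77 P<0.01       NUMBER       p-value lt   <NA>   0.01
```

The tagger finds both drugs, the ranked parameter, the fold change with
its unit, and the p-value with its comparison operator. Feeding that
evidence to the rule classifier:

```r
classify_pairs(tibble::tibble(
  setting = "in_vivo", pair_type = "drug_drug", c1 = TRUE, c2 = TRUE,
  quant = list(quant_evidence("AUC", "fold_change", 3.2,
                              p_value = 0.01, p_relation = "lt")),
  cues = list(cue_evidence("significantly"))))$label
#> [1] "DDI"
```

A 3.2-fold AUC increase at p < 0.01 clears the definite thresholds, so
the pair is a DDI. The classifier reproduces all eight worked
classification examples shipped in `worked_examples()`
(`classify_pairs(worked_example_pairs())`).

End to end on synthetic data:

```r
synth <- simulate_corpus(20, seed = 1)
synth
#> <pk_synth> synthetic annotated corpus
#> <pk_corpus> 20 documents, 98 sentences, 395 key terms, 54 annotated pairs

inst  <- ddi_instances(synth$corpus)          # graphs for all C(n,2) pairs
model <- ddi_train_eval(inst, seed = 1)       # kernel SVM, document split
glance(model)                                 # held-out precision/recall/F
```

A thin command-line surface over the same functions ships in
`inst/cli/pkddi.R` (`tag`, `classify`, `convert`, `stats`, `agree`,
`synth`, `render`, `extract-eval`).

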