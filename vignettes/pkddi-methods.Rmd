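---
title: "Rule-based mining of pharmacokinetic drug-drug interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based mining of pharmacokinetic drug-drug interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pkddi)
library(dplyr)
```

## The problem

Pharmacokinetic (PK) drug–drug interaction (DDI) evidence is scattered
through abstracts as a mixture of numbers (fold changes of AUC or
clearance, inhibition constants, p-values) and language ("significantly
increased", "slightly induced", "doesn't interact"). pkddi implements the
machinery needed to mine that evidence: controlled vocabularies, a
rule-based key-term tagger, a three-level annotated-corpus model, a
six-label relation classifier, inter-annotator reliability, and a
graph-kernel extraction pipeline.

This vignette is the package's account of the methods: the models and
rules, the tunable parameters with their defaults and units, the numerical
and design choices made where the design was genuinely open, what the
synthetic-data generator does and does not emulate, and known limitations.

## The annotation scheme

Annotation is hierarchical, with three levels:

1. **Key terms** — seven categories: `DRUG`, `METABOLITE`, `ENZYME`,
   `PK_PARAMETER`, `NUMBER`, `MECHANISM`, `CHANGE`. Spans are 0-based,
   half-open character offsets local to the sentence; `text` always equals
   the sentence substring, and spans are pairwise non-overlapping after
   merging.
2. **DDI sentences** — `CDDIS` (both interacting entities in the sentence
   plus an interaction statement), `VDDIS` (one entity missing but
   inferable from context), or `NONE`.
3. **DDI pairs** — each annotated pair carries one of the relation labels
   below plus references to its evidence terms.

The in vivo label set has three members (`DDI`, `ADDI`, `NDDI`: definite,
ambiguous, and asserted-absent interaction); the in vitro set adds the
drug–enzyme triple (`DEI`, `ADEI`, `NDEI`) for six.

## Tagging rules

* **Enzymes.** The corpus definition's enzyme expression anchors a
  digit–letter–digit core with an optional `CYP`/`P450` prefix and one
  optional allele digit. Anchored literally, it cannot match `CYP2C19`
  (two trailing digits) or `CYP3A` (none) — names the scheme itself uses.
  The default is therefore an extended token-level pattern
  `(?:cyp|CYP|P450|CYP450)?[0-9][A-Za-z][0-9]*(?:\*[0-9]+)?`, with the
  verbatim pattern available behind `strict = TRUE`. End-of-string anchors
  in the printed patterns are interpreted as token anchors throughout.
  Enzyme family names without digits ("the CYP450 system") are not tagged.
* **Mechanisms.** Nine stem patterns (inhibit-, catalyz-, correlat-,
  metaboli-, induc-, form-, stimulat-, activ-, suppress-) with enumerated
  suffixes; suffixes outside the enumeration (e.g. "inhibitory") do not
  match, by design. The `form-` alternation accepts `formation` (the
  printed suffix list omits the linking "a", which we treat as a typo).
* **Change cues.** The printed cue list plus `decreas(e|es|ed|ing)`: the
  list contains increas- and reduc- but not decreas-, yet the worked
  examples use "decreased" as the change cue of a definite interaction, so
  the omission is treated as accidental. The multi-word cue "doesn't
  interact" is matched in both its typographic variants and as "does not
  interact".
* **Numbers.** Numerals with an attached unit when the unit belongs to the
  PK unit vocabulary (mg L^-1, ng/mL, microM, %, fold, h, ...), and
  p-value expressions in both dialects (`P=.26`, `p-value <0.05`), with
  the comparison operator retained because the relation rules need it.
* **PK parameters.** Longest match over symbols and spelled-out synonyms
  (clearance = CL, half-life = t1/2, area under the concentration curve =
  AUC), with parenthesized qualifiers (`AUC(0-48)`) mapping to the base
  symbol. Symbols shorter than two characters (E, F, V, Q, k) stay in the
  ontology but are not tagged — single letters are hopelessly ambiguous in
  running text. Two-character symbols are matched case-sensitively.
* **Drugs and metabolites.** Dictionary longest-match over the lexicon
  (case-insensitive; canonical forms lowercase). A token is a metabolite
  when one of the ten phase-I/II affixes (oxi, hydroxyl, methyl, acetyl,
  N-dealkyl, N-demethyl, nor, dihydroxy, O-dealkyl, sulfo) attached to a
  known drug name remains after stripping; the parent drug is recorded.
  This prevents false metabolite tags ("northern" is not nor+thern).
* **Merging.** Longer spans win; at equal length the precedence is DRUG >
  ENZYME > PK_PARAMETER > NUMBER > MECHANISM > CHANGE.

The bundled drug dictionary holds the probe inhibitors/inducers/substrates
of the CYP and transporter tables plus the drugs of the worked examples —
enough to run everything without downloads. Full dictionaries (DrugBank
scale) are loaded from pipe-delimited text with `load_drug_lexicon()`.

## The relation classifier

A candidate pair is labeled from four conditions: C1 (at least one entity
name in the sentence), C2 (the partner in the sentence or resolvable from
context), C3 (numeric rules), C4 (cue polarity). The combination is
**C1 AND C2 AND (C3 OR C4)**: the printed conjunction of C3 and C4 cannot
be meant literally, because several worked examples are labeled from words
alone. When both kinds of evidence are present, quantitative evidence
wins.

C3 operates on the highest-priority parameter — AUC > CL > t1/2 > Cmax in
vivo, Ki > IC50 in vitro; unranked parameters fall below ranked ones, and
ties break on the larger |log fold change|. The default thresholds
(`ddi_rules()`) are:

| parameter | default | meaning |
|---|---|---|
| `fc_upper` | 1.50 | definite fold-change threshold (increase) |
| `fc_lower` | 0.67 | definite fold-change threshold (decrease) |
| `p_sig` | 0.05 | significance threshold |
| `ki_definite` | 10 microM | definite Ki/IC50/EC50 bound |
| `ki_non` | 100 microM | non-interaction Ki/EC50 bound |

Three boundary/edge decisions were genuinely open and are fixed as
follows:

* **Threshold boundaries.** Values exactly at 0.67, 10 or 100 fall into
  the ambiguous band (the printed inequalities are strict on both sides).
  The upper fold-change boundary is the exception: 1.50 counts as
  definite, because the worked examples label a reported 1.5-fold AUC
  change with p ≤ 0.01 as a definite interaction. 0.67 is used verbatim,
  not as 1/1.5.
* **Missing p-values.** A missing p-value never blocks the definite band
  (the worked examples assign DDI from a 64% clearance decrease with no
  p-value at all) and never satisfies the non-interaction band, which
  requires an explicitly non-significant p. An explicit `p > x` assertion
  counts as non-significant only when x is at or above the threshold.
* **Conflicting measurements.** When several measurements of the
  top-priority parameter fall into different bands (e.g. Ki of 3.5 and
  24.9 microM for the same pair in two systems), the ambiguous band wins.

C4 assigns each cue phrase a polarity from three configurable lists —
definite (significantly, markedly, potently, ...), ambiguous (modestly,
may, might, ...), negative (slightly, negligible, minor, doesn't
interact, ...) — with negation handling: a negated definite cue ("not
significantly changed") is negative. A definite cue dominates, then
negative, then ambiguous. "Slightly induced" is negative, hence `NDEI`,
matching the worked examples; "potent" is definite (the example sentences
demand it, and the printed cue lists are explicitly open-ended).

In vitro, drug–enzyme pairs take the DEI family; drug–drug pairs keep the
DDI family. All thresholds and cue lists live in `ddi_rules()` so the
classifier is auditable and reconfigurable.

## Inter-annotator reliability

`krippendorff_alpha()` implements nominal-metric Krippendorff's alpha via
the coincidence matrix, with any number of annotators and missing labels;
units carrying fewer than two labels are excluded. When every pairable
value shares one label the expected disagreement is zero; the default
defines alpha = 1 there (a flag switches to an error). `agreement_units()`
derives the three unit sets from parallel corpora: one unit per token
(label = covering category or `O`, over the shared
whitespace-plus-punctuation tokenization), per sentence (NONE/CDDIS/VDDIS)
and per candidate entity pair in any sentence some annotator marked as a
DDI sentence, with unmarked annotators contributing `NONE`. These unit
definitions are a documented choice of this package — the annotation
scheme itself does not fix them.

## The all-paths graph kernel and extraction pipeline

Each candidate pair in a clear DDI sentence is represented as a weighted
directed graph with two disjoint components: the dependency graph of the
sentence (edges head → dependent) and a linear chain over the
part-of-speech tags. Edges on a shortest undirected path between the two
candidate entities carry weight 0.9, all other dependency edges 0.3, and
the linear chain 0.9 — the published defaults of the all-paths kernel
method, configurable in `build_graph()`. The two candidate entities are
anonymized to `ENTITY1`/`ENTITY2` and other candidate drugs to `ENTITY`,
so the classifier learns the relation pattern, not the drug identities.

The path-weight matrix is the convergent geometric series of the
adjacency matrix, `(I - A)^-1 - I`; for these acyclic graphs the series is
exact (spectral radius 0), and a non-convergent input is rejected with a
rescaling hint. The kernel between two graphs sums, over pairs of shared
vertex labels, the products of their path weights (each vertex also
matches itself through the identity path); it is normalized to
`k(a,b)/sqrt(k(a,a) k(b,b))` and is an explicit inner product, hence
positive semidefinite by construction.

Extraction mirrors the published pipeline: metabolite mentions are
removed (parent drugs and their metabolites rarely interact), enzymes are
pairable as drugs, synonym mentions collapse to the first mention, all
C(n,2) candidate pairs are generated with default "no interaction", and
gold labels collapse the six relation labels to a binary target — only
DDI and DEI are true. Only clear DDI sentences contribute candidates.
`ddi_train_eval()` trains a soft-margin SVM (kernlab) on the precomputed
normalized kernel matrix with a document-level split (all candidates of an
abstract stay together, preventing leakage), inverse-frequency class
weights (the usual guard against the heavy negative skew of candidate
pairs) and C = 10 by default.

Dependency parses are consumed from CoNLL-style files
(`read_conll_parses()`); no parser is bundled. The deterministic fallback
`chain_parse()` builds a right-branching chain with a crude closed-class
part-of-speech table — adequate for kernel computation and testing, far
cruder than a real parser.

## The synthetic-data generator

`simulate_corpus()` emits fully ground-truthed corpora from templates
modeled on the worked examples' phrasing: definite, ambiguous and
negative cue templates; numeric templates whose fold changes, inhibition
constants and p-values are drawn to land inside the intended rule bands
(e.g. definite fold changes in 1.8–3.2 with p < 0.01, ambiguous Ki in
15–90 microM, negative Ki in 150–400 microM with non-significant p);
distractor sentences with mechanism words but only one entity, to
exercise `NONE` labeling; and occasional vague-DDI sentences whose
partner lives in the preceding sentence. Annotations are correct by
construction, evidence stays adjacent to its parameter mention, and every
numeric pair's evidence reclassifies to its planted label.

Defaults: a class mix of 10/10/40/40% over clinical PK, pharmacogenetic,
in vivo DDI and in vitro DDI studies (matching the make-up of a PK
abstract corpus, which is dominated by interaction studies); 3–5 body
sentences per abstract; and `positive_rate = 0.25` — the target share of
candidate pairs that are definite interactions, on the order of the
positive rates seen in real DDI corpora. The per-sentence positive
probability is adjusted analytically for the three-entity templates,
which contribute two extra negative pairs each.

What the generator does **not** emulate: real syntactic variety (the
fallback parses are chains, so the kernel effectively sees weighted
lexical context rather than true syntax), coordination and anaphora,
abbreviation noise, OCR artifacts, or entity mentions absent from the
lexicon. Passing the pipeline test on synthetic data therefore shows the
machinery is correct and that planted lexical patterns are learnable; it
does not certify extraction performance on real abstracts, where
published systems of this family score far lower.

## Numerical choices and problem sizes

* Offsets are 0-based half-open everywhere; tie-breaks in span merging are
  by length, then category precedence, then position.
* Binary searches for rule boundaries run to 1e-6 on the evidence axis.
* Kernel PSD checks tolerate eigenvalues down to -1e-8; path-weight
  oracle comparisons use 1e-9.
* The test suite uses desk-scale problem sizes chosen to keep the default
  run fast: 200 randomized graphs (up to 6 vertices) for the kernel
  oracle, 20 randomized reliability cases plus one 10,000-unit null
  simulation, and a 45-document (about 230-sentence) synthetic corpus for
  the extraction criterion, trained once on true and once on shuffled
  labels. Shuffled-label extraction is compared against the prevalence
  baseline: a random classifier matching the positive rate has precision
  = recall = prevalence, so its F-measure is the prevalence itself.

## Known limitations

* The tagger is deliberately rule-based: no abbreviation expansion,
  coreference, or learned entity recognition; enzyme family names without
  digits are not tagged.
* The heuristic that links numbers to their parameters
  (nearest-preceding-parameter, used by the CLI glue) is exercised only on
  synthetic data, where adjacency is guaranteed by construction.
* Reported reliability coefficients for a real multi-annotator corpus
  require the annotators' raw files; this package implements and verifies
  the statistic, not those numbers.
* Corpus-scale extraction figures require the original hosted corpus; the
  pipeline is validated on synthetic data instead (see above for what
  that does and does not establish).

## A worked call

```{r example}
sentence <- paste("Ketoconazole significantly increased the AUC of",
                  "midazolam by 3.2 fold (P<0.01).")
tag_terms(sentence)

classify_pairs(tibble::tibble(
  setting = "in_vivo", pair_type = "drug_drug", c1 = TRUE, c2 = TRUE,
  quant = list(quant_evidence("AUC", "fold_change", 3.2,
                              p_value = 0.01, p_relation = "lt")),
  cues = list(cue_evidence("significantly"))))$label
```
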