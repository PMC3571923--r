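lex <- pk_lexicon()

test_that("enzyme tagging: extended pattern covers the CYP probe table", {
  probe_enzymes <- c("CYP1A2", "CYP2B6", "CYP2C8", "CYP2C9", "CYP2C19",
                     "CYP3A", "CYP2D6")
  for (e in probe_enzymes) {
    hit <- tag_enzymes(paste(e, "activity"))
    expect_equal(hit$normal_form, e, label = e)
  }
  # the strict printed pattern requires a digit-letter-digit core
  strict_hit <- function(e) nrow(tag_enzymes(e, strict = TRUE)) > 0
  expect_true(strict_hit("CYP1A2"))
  expect_true(strict_hit("CYP2C9"))
  expect_false(strict_hit("CYP2C19"))
  expect_false(strict_hit("CYP3A"))
  # normalization restores the CYP prefix, uppercased
  expect_equal(tag_enzymes("cyp3a4")$normal_form, "CYP3A4")
  expect_equal(tag_enzymes("P4502D6")$normal_form, "CYP2D6")
  expect_equal(tag_enzymes("2C19 was involved")$normal_form, "CYP2C19")
  # allele variants
  expect_equal(tag_enzymes("CYP2D6*4 carriers")$text, "CYP2D6*4")
  expect_equal(nrow(tag_enzymes("aspirin")), 0)
})

test_that("mechanism tagging matches the enumerated stem suffixes only", {
  expect_equal(tag_mechanisms("inhibited")$normal_form, "inhibit")
  expect_equal(tag_mechanisms("Inhibition was seen")$normal_form, "inhibit")
  expect_equal(nrow(tag_mechanisms("inhibitory")), 0)
  expect_equal(tag_mechanisms("formation")$normal_form, "form")
  expect_equal(tag_mechanisms("metabolized by")$normal_form, "metaboli")
  expect_equal(tag_mechanisms("induction")$normal_form, "induc")
  expect_equal(tag_mechanisms("activation")$normal_form, "activ")
  expect_equal(nrow(tag_mechanisms("performer")), 0)
})

test_that("change tagging covers single- and multi-word cues", {
  expect_equal(tag_changes("significantly")$normal_form, "significant")
  expect_equal(tag_changes("negligible")$normal_form, "negligible")
  expect_equal(nrow(tag_changes("blue")), 0)
  hit <- tag_changes("It doesn't interact with warfarin")
  expect_true("doesn't interact" %in% hit$normal_form)
  expect_equal(tag_changes("was reduced")$normal_form, "reduce")
  expect_equal(tag_changes("was decreased")$normal_form, "decrease")
})

test_that("number tagging parses values, units and p-value dialects", {
  hit <- tag_numbers("Ki values of 3.5 microM were seen")
  expect_equal(hit$value, 3.5)
  expect_equal(hit$unit, "microM")
  hit <- tag_numbers("the ratio was 0.014 (P=.26)")
  p <- hit[grepl("p-value", hit$normal_form), ]
  expect_equal(p$value, 0.26)
  expect_equal(p$normal_form, "p-value eq")
  hit <- tag_numbers("AUC rose (P≤0.01)")
  expect_equal(hit$normal_form[1], "p-value le")
  expect_equal(hit$value[1], 0.01)
  hit <- tag_numbers("a p-value <0.05 was required")
  expect_equal(hit$normal_form[1], "p-value lt")
  expect_equal(nrow(tag_numbers("no numbers here")), 0)
  hit <- tag_numbers("increased by 1.5 fold and 64%")
  expect_equal(hit$unit, c("fold", "%"))
  expect_equal(hit$value, c(1.5, 64))
})

test_that("parameter tagging is longest-match and maps qualifiers to base symbols", {
  expect_equal(tag_pk_parameters("renal clearance fell", lex)$normal_form,
               "CLR")
  expect_equal(tag_pk_parameters("the clearance fell", lex)$normal_form,
               "CL")
  expect_equal(tag_pk_parameters("terminal half-life", lex)$normal_form,
               "t1/2")
  expect_equal(tag_pk_parameters("AUC(0-infinity) rose", lex)$normal_form,
               "AUC")
  expect_equal(tag_pk_parameters("AUC(0-48) rose", lex)$text, "AUC(0-48)")
  expect_equal(tag_pk_parameters("the K(i) was high", lex)$normal_form,
               "Ki")
  # overlapping "half-life" yields one span
  hit <- tag_pk_parameters("half-life", lex)
  expect_equal(nrow(hit), 1)
})

test_that("drug tagging distinguishes drugs from affix-derived metabolites", {
  hit <- tag_drugs("verapamil was given", lex)
  expect_equal(hit$category, "DRUG")
  expect_equal(hit$normal_form, "verapamil")
  hit <- tag_drugs("norverapamil accumulated", lex)
  expect_equal(hit$category, "METABOLITE")
  expect_equal(hit$normal_form, "verapamil")
  # affix without a drug stem is not a metabolite
  expect_equal(nrow(tag_drugs("northern blot", lex)), 0)
  # multi-word names and case-insensitivity
  hit <- tag_drugs("St John's wort was co-administered", lex)
  expect_equal(hit$normal_form, "st john's wort")
  # O-/N- affixes with hyphens
  hit <- tag_drugs("N-demethyl-tamoxifen was measured", lex)
  expect_equal(hit$category, "METABOLITE")
  expect_equal(hit$normal_form, "tamoxifen")
})

test_that("tag_terms merges categories with precedence and no overlaps", {
  hit <- tag_terms("ketoconazole inhibited CYP3A4", lex)
  expect_equal(hit$category, c("DRUG", "MECHANISM", "ENZYME"))
  expect_equal(nrow(tag_terms("", lex)), 0)
  # spans are valid and pairwise non-overlapping on varied sentences
  sentences <- c(
    "Ketoconazole significantly inhibited CYP3A4 with a Ki of 0.1 microM (P<0.01).",
    "The AUC(0-48) of midazolam increased 3.2 fold vs. placebo.",
    "Norverapamil formation correlates with CYP3A activity.",
    "Verapamil doesn't interact with caffeine metabolism.")
  tt <- tag_terms(sentences, lex)
  for (i in seq_along(sentences) - 1L) {
    s <- tt[tt$sentence_index == i, ]
    expect_true(all(s$start >= 0 & s$start < s$end &
                      s$end <= nchar(sentences[i + 1])))
    expect_equal(s$text,
                 substring(sentences[i + 1], s$start + 1, s$end))
    if (nrow(s) > 1) {
      expect_true(all(s$start[-1] >= s$end[-nrow(s)]))
    }
  }
  # tagging sentences together equals tagging each alone (offsets local)
  solo <- dplyr::bind_rows(lapply(seq_along(sentences), function(i) {
    dplyr::mutate(tag_terms(sentences[i], lex), sentence_index = i - 1L)
  }))
  expect_equal(as.data.frame(tt), as.data.frame(solo))
})
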