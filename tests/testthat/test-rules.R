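empty_quant <- quant_evidence(character(), character(), double())
empty_cues <- cue_evidence(character())

cand <- function(quant = empty_quant, cues = empty_cues,
                 setting = "in_vivo", pair_type = "drug_drug", c1 = TRUE,
                 c2 = TRUE) {
  tibble::tibble(setting = setting, pair_type = pair_type, c1 = c1, c2 = c2,
                 quant = list(quant), cues = list(cues))
}

test_that("percent changes convert to fold changes", {
  expect_equal(percent_to_fold(64, "decrease"), 0.36)
  expect_equal(percent_to_fold(0, "increase"), 1.0)
  expect_equal(percent_to_fold(50, "increase"), 1.5)
  expect_error(percent_to_fold(-150, "increase"), "-100")
  expect_error(percent_to_fold(100, "decrease"), "fold")
})

test_that("parameter ranking follows the in vivo and in vitro priorities", {
  ev <- dplyr::bind_rows(
    quant_evidence("Cmax", "fold_change", 1.3, p_value = 0.05,
                   p_relation = "le"),
    quant_evidence("AUC", "fold_change", 1.5, p_value = 0.01,
                   p_relation = "le"))
  expect_equal(rank_parameter(ev, "in_vivo")$parameter, "AUC")
  ev2 <- dplyr::bind_rows(quant_evidence("Ki", "ki", 24.9),
                          quant_evidence("IC50", "ic50", 5))
  expect_equal(rank_parameter(ev2, "in_vitro")$parameter, "Ki")
  single <- quant_evidence("t1/2", "fold_change", 2)
  expect_equal(rank_parameter(single, "in_vivo"), single)
  # unranked parameters fall below ranked ones
  ev3 <- dplyr::bind_rows(quant_evidence("MR", "fold_change", 5),
                          quant_evidence("Cmax", "fold_change", 1.1))
  expect_equal(rank_parameter(ev3, "in_vivo")$parameter, "Cmax")
  expect_error(rank_parameter(empty_quant, "in_vivo"), "no quantitative")
})

test_that("quantitative classification follows the threshold bands", {
  expect_equal(classify_quant(
    quant_evidence("AUC", "fold_change", 1.5, p_value = 0.01,
                   p_relation = "le"), "in_vivo"), "DDI")
  expect_equal(classify_quant(
    quant_evidence("MR", "fold_change", 0.014 / 0.006, p_value = 0.26,
                   p_relation = "eq"), "in_vivo"), "ADDI")
  expect_equal(classify_quant(
    quant_evidence("Ki", "ki", 24.9), "in_vitro", "drug_enzyme"), "ADEI")
  expect_equal(classify_quant(
    quant_evidence("CL", "percent_change", 64, direction = "decrease"),
    "in_vivo"), "DDI")
  # in vitro drug-drug pairs use the DDI family
  expect_equal(classify_quant(
    quant_evidence("Ki", "ki", 2, p_value = 0.01, p_relation = "lt"),
    "in_vitro", "drug_drug"), "DDI")
  # wrong evidence kind for the setting errors
  expect_error(classify_quant(quant_evidence("Ki", "ki", 2), "in_vivo"),
               "fold")
  expect_error(classify_quant(quant_evidence("AUC", "fold_change", 2),
                              "in_vitro", "drug_enzyme"), "ki")
})

test_that("cue classification maps polarity to the label family", {
  expect_equal(classify_cues(cue_evidence("significantly altered")), "DDI")
  expect_equal(classify_cues(cue_evidence("did not significantly changed")),
               "NDDI")
  expect_equal(classify_cues(cue_evidence("potent inhibitor"), "in_vitro",
                             "drug_enzyme"), "DEI")
  expect_equal(classify_cues(cue_evidence("may moderately increase")),
               "ADDI")
  expect_equal(classify_cues(cue_evidence("slightly induced"), "in_vitro",
                             "drug_enzyme"), "NDEI")
  expect_equal(classify_cues(empty_cues), "NONE")
})

test_that("the full classifier requires C1 and C2 and prefers numbers", {
  # C1/C2 gate
  expect_equal(classify_pairs(cand(c1 = FALSE))$label, "NONE")
  expect_equal(classify_pairs(cand(c2 = FALSE))$label, "NONE")
  # quantitative evidence overrides a definite cue
  both <- cand(
    quant = quant_evidence("AUC", "fold_change", 1.1, p_value = 0.3,
                           p_relation = "eq"),
    cues = cue_evidence("significantly"))
  expect_equal(classify_pairs(both)$label, "NDDI")
  # conflicting measurements of the top parameter give the ambiguous band
  conflict <- cand(
    quant = dplyr::bind_rows(quant_evidence("Ki", "ki", 3.5),
                             quant_evidence("Ki", "ki", 24.9)),
    setting = "in_vitro", pair_type = "drug_enzyme")
  expect_equal(classify_pairs(conflict)$label, "ADEI")
  # no evidence at all
  expect_equal(classify_pairs(cand())$label, "NONE")
})

test_that("classification is deterministic and entity-order invariant", {
  # entity order is encoded only through pair_type, so swapping entities
  # (same evidence) cannot change the label; check across a grid
  for (fc in c(0.3, 1.0, 2.0)) {
    for (p in c(0.01, 0.2)) {
      q <- quant_evidence("AUC", "fold_change", fc, p_value = p,
                          p_relation = "eq")
      l1 <- classify_pairs(cand(q))$label
      l2 <- classify_pairs(cand(q))$label
      expect_equal(l1, l2)
    }
  }
})

test_that("in vivo labels are monotone in fold change at fixed significance", {
  # p significant: NDDI never occurs; DDI outside the band, ADDI inside
  fcs <- c(0.2, 0.5, 0.669, 0.671, 1.0, 1.49, 1.5, 2.0, 3.0)
  labs <- vapply(fcs, label_at_fc, character(1), p = 0.01)
  expect_false(any(labs == "NDDI"))
  expect_equal(labs[fcs < 0.67], rep("DDI", sum(fcs < 0.67)))
  expect_equal(labs[fcs >= 1.5], rep("DDI", sum(fcs >= 1.5)))
  expect_equal(labs[fcs > 0.67 & fcs < 1.5],
               rep("ADDI", sum(fcs > 0.67 & fcs < 1.5)))
  # in vitro definiteness is non-increasing over the Ki bands
  rank <- c(DEI = 3, ADEI = 2, NDEI = 1)
  labs_sig <- rank[vapply(c(1, 50, 700), label_at_ki, character(1),
                          p = 0.01)]
  expect_true(all(diff(labs_sig) <= 0))
  labs_ns <- rank[vapply(c(1, 50, 700), label_at_ki, character(1), p = 0.2)]
  expect_true(all(diff(labs_ns) <= 0))
})

test_that("exhaustive truth table over the fold-change/p grid", {
  truth <- tibble::tribble(
    ~fc, ~p, ~label,
    0.3, 0.01, "DDI", 0.3, 0.05, "DDI", 0.3, 0.2, "ADDI",
    0.67, 0.01, "ADDI", 0.67, 0.05, "ADDI", 0.67, 0.2, "ADDI",
    1.0, 0.01, "ADDI", 1.0, 0.05, "ADDI", 1.0, 0.2, "NDDI",
    1.5, 0.01, "DDI", 1.5, 0.05, "DDI", 1.5, 0.2, "ADDI",
    2.0, 0.01, "DDI", 2.0, 0.05, "DDI", 2.0, 0.2, "ADDI")
  got <- purrr::map2_chr(truth$fc, truth$p, label_at_fc)
  expect_equal(got, truth$label)
})

test_that("sentence labeling distinguishes NONE, CDDIS and VDDIS", {
  lex <- pk_lexicon()
  cddis <- tag_terms("verapamil significantly altered lovastatin", lex)
  expect_equal(label_sentence(cddis), "CDDIS")
  one <- tag_terms("verapamil exposure was significantly altered", lex)
  expect_equal(label_sentence(one, context_partner = TRUE), "VDDIS")
  expect_equal(label_sentence(one, context_partner = FALSE), "NONE")
  nostat <- tag_terms("verapamil and lovastatin were administered", lex)
  expect_equal(label_sentence(nostat), "NONE")
})
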