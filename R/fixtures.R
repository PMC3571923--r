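# Ground-truthed fixtures: the eight worked classification examples, and a
# synthetic corpus generator that emits template sentences with annotations
# that are correct by construction.

wx_row <- function(pmid, sentence, setting, pairs) {
  tibble::tibble(pmid = pmid, sentence = sentence, setting = setting,
                 pairs = list(pairs))
}

wx_pair <- function(entity_a, entity_b, pair_type, label, quant = NULL,
                    cues = NULL, corrected = FALSE) {
  tibble::tibble(
    entity_a = entity_a, entity_b = entity_b, pair_type = pair_type,
    label = label, corrected = corrected,
    quant = list(if (is.null(quant)) quant_evidence(character(), character(),
                                                    double()) else quant),
    cues = list(if (is.null(cues)) cue_evidence(character()) else cues))
}

#' The eight worked interaction-classification examples
#'
#' Structured encodings of the eight example sentences used to document the
#' interaction rules: sentence text, entity pair(s), the quantitative and
#' cue evidence stated in each sentence, and the assigned relation label.
#' The seventh example prints the pair (YM758, CYP1A2) twice; both printed
#' pairs are included as printed, plus a corrected (YM758, CYP3A4) variant
#' flagged `corrected = TRUE`, all NDEI.
#'
#' @return A tibble with one row per example: `pmid`, `sentence`, `setting`
#'   and a `pairs` list column of pair-level records.
#' @export
#' @examples
#' classify_pairs(worked_example_pairs())$label
worked_examples <- function() {
  dplyr::bind_rows(
    wx_row("20012601",
           paste("The pharmacokinetic parameters of verapamil were",
                 "significantly altered by the co-administration of",
                 "lovastatin compared to the control."),
           "in_vivo",
           wx_pair("verapamil", "lovastatin", "drug_drug", "DDI",
                   cues = cue_evidence("significantly"))),
    wx_row("20209646",
           paste("The clearance of mitoxantrone and etoposide was decreased",
                 "by 64% and 60%, respectively, when combined with",
                 "valspodar."),
           "in_vivo",
           dplyr::bind_rows(
             wx_pair("mitoxantrone", "valspodar", "drug_drug", "DDI",
                     quant = quant_evidence("CL", "percent_change", 64,
                                            direction = "decrease")),
             wx_pair("etoposide", "valspodar", "drug_drug", "DDI",
                     quant = quant_evidence("CL", "percent_change", 60,
                                            direction = "decrease")))),
    wx_row("20012601",
           paste("The AUC (0-infinity) of norverapamil and the terminal",
                 "half-life of verapamil did not significantly changed with",
                 "lovastatin coadministration."),
           "in_vivo",
           wx_pair("verapamil", "lovastatin", "drug_drug", "NDDI",
                   cues = cue_evidence("not significantly changed"))),
    wx_row("17304149",
           paste("Compared with placebo, itraconazole treatment",
                 "significantly increase the peak plasma concentration",
                 "(Cmax) of paroxetine by 1.3 fold (6.7 +/- 2.5 versus 9.0",
                 "+/- 3.3 ng/mL, P<=0.05) and the area under the plasma",
                 "concentration-time curve from zero to 48 hours [AUC(0-48)]",
                 "of paroxetine by 1.5 fold (137 +/- 73 versus 199 +/- 91",
                 "ng*h/mL, P<=0.01)."),
           "in_vivo",
           wx_pair("itraconazole", "paroxetine", "drug_drug", "DDI",
                   quant = dplyr::bind_rows(
                     quant_evidence("AUC", "fold_change", 1.5,
                                    p_value = 0.01, p_relation = "le"),
                     quant_evidence("Cmax", "fold_change", 1.3,
                                    p_value = 0.05, p_relation = "le")),
                   cues = cue_evidence("significantly"))),
    wx_row("13129991",
           paste("The mean (SD) urinary ratio of dextromethorphan to its",
                 "metabolite was 0.006 (0.010) at baseline and 0.014 (0.025)",
                 "after St John's wort administration (P=.26)."),
           "in_vivo",
           wx_pair("dextromethorphan", "st john's wort", "drug_drug", "ADDI",
                   quant = quant_evidence("MR", "fold_change", 0.014 / 0.006,
                                          p_value = 0.26,
                                          p_relation = "eq"))),
    wx_row("19904008",
           paste("The obtained results show that perazine at its",
                 "therapeutic concentrations is a potent inhibitor of human",
                 "CYP1A2."),
           "in_vitro",
           wx_pair("perazine", "CYP1A2", "drug_enzyme", "DEI",
                   cues = cue_evidence("potent inhibitor"))),
    wx_row("19230594",
           paste("After human hepatocytes were exposed to 10 microM YM758,",
                 "microsomal activity and mRNA level for CYP1A2 were not",
                 "induced while those for CYP3A4 were slightly induced."),
           "in_vitro",
           dplyr::bind_rows(
             wx_pair("ym758", "CYP1A2", "drug_enzyme", "NDEI",
                     cues = cue_evidence("not induced")),
             wx_pair("ym758", "CYP1A2", "drug_enzyme", "NDEI",
                     cues = cue_evidence("slightly induced")),
             wx_pair("ym758", "CYP3A4", "drug_enzyme", "NDEI",
                     cues = cue_evidence("slightly induced"),
                     corrected = TRUE))),
    wx_row("19960413",
           paste("From these results, DPT was characterized to be a",
                 "competitive inhibitor of CYP2C9 and CYP3A4, with K(i)",
                 "values of 3.5 and 10.8 microM in HLM and 24.9 and 3.5",
                 "microM in baculovirus-insect cell-expressed human CYPs,",
                 "respectively."),
           "in_vitro",
           dplyr::bind_rows(
             wx_pair("dpt", "CYP2C9", "drug_enzyme", "ADEI",
                     quant = dplyr::bind_rows(
                       quant_evidence("Ki", "ki", 3.5),
                       quant_evidence("Ki", "ki", 24.9))),
             wx_pair("dpt", "CYP3A4", "drug_enzyme", "ADEI",
                     quant = dplyr::bind_rows(
                       quant_evidence("Ki", "ki", 10.8),
                       quant_evidence("Ki", "ki", 3.5))))))
}

#' Flatten the worked examples into classification candidates
#'
#' @param corrected Include the corrected (YM758, CYP3A4) variant of the
#'   seventh example alongside the two pairs exactly as printed.
#' @return A candidate tibble ready for [classify_pairs()], with the printed
#'   label in `label_expected`.
#' @export
worked_example_pairs <- function(corrected = TRUE) {
  ex <- worked_examples()
  out <- purrr::pmap_dfr(ex, function(pmid, sentence, setting, pairs) {
    mutate(pairs, pmid = pmid, setting = setting, .before = 1)
  })
  if (!corrected) out <- filter(out, !.data$corrected)
  out %>%
    mutate(c1 = TRUE, c2 = TRUE) %>%
    rename(label_expected = "label")
}

# ---- synthetic corpus generation --------------------------------------

seg <- function(text, category = NA_character_, normal_form = NA_character_,
                unit = NA_character_, value = NA_real_, pre = "",
                post = "") {
  tibble::tibble(pre = pre, text = text, post = post, category = category,
                 normal_form = normal_form, unit = unit, value = value)
}

cap1 <- function(x) {
  paste0(toupper(substring(x, 1, 1)), substring(x, 2))
}

# Assemble segments into sentence text plus a 0-based offset term table.
compose_sentence <- function(segs) {
  full <- paste0(segs$pre, segs$text, segs$post)
  starts <- cumsum(c(0L, nchar(full[-length(full)]) + 1L))  # +1 for spaces
  text <- paste(full, collapse = " ")
  sel <- !is.na(segs$category)
  terms <- tibble::tibble(
    start = as.integer(starts[sel] + nchar(segs$pre[sel])),
    end = as.integer(starts[sel] + nchar(segs$pre[sel]) +
                       nchar(segs$text[sel])),
    text = segs$text[sel], category = segs$category[sel],
    normal_form = segs$normal_form[sel], unit = segs$unit[sel],
    value = segs$value[sel])
  list(text = text, terms = terms)
}

synth_drugs <- c(
  "verapamil", "ketoconazole", "itraconazole", "rifampin", "fluoxetine",
  "quinidine", "midazolam", "caffeine", "warfarin", "omeprazole",
  "theophylline", "diltiazem", "erythromycin", "fluconazole", "simvastatin",
  "lovastatin", "digoxin", "metformin", "probenecid", "cimetidine")
synth_enzymes <- c("CYP1A2", "CYP2B6", "CYP2C8", "CYP2C9", "CYP2C19",
                   "CYP3A4", "CYP2D6", "CYP3A5")

rnum <- function(lo, hi, digits = 1) {
  as.numeric(sprintf(paste0("%.", digits, "f"), stats::runif(1, lo, hi)))
}

# Each template returns list(segs, ddi_label, pairs) where pairs carries
# relation + evidence for every annotated pair (entities referenced by
# normal form; term ids are resolved by the assembler).
synth_templates <- list(
  pos_vivo = function(d) {
    fc <- rnum(1.8, 3.2); p <- 0.01
    list(
      segs = dplyr::bind_rows(
        seg(cap1(d[1]), "DRUG", d[1]),
        seg("significantly", "CHANGE", "significant"),
        seg("increased", "CHANGE", "increase"),
        seg("the"),
        seg("AUC", "PK_PARAMETER", "AUC"),
        seg("of"),
        seg(d[2], "DRUG", d[2]),
        seg("by"),
        seg(paste0(sprintf("%.1f", fc), " fold"), "NUMBER",
            sprintf("%.1f", fc), unit = "fold", value = fc),
        seg("P<0.01", "NUMBER", "p-value lt", value = 0.01, pre = "(",
            post = ").")),
      ddi_label = "CDDIS",
      pairs = tibble::tibble(
        a = d[1], b = d[2], relation = "DDI", pair_type = "drug_drug",
        quant = list(quant_evidence("AUC", "fold_change", fc, p_value = p,
                                    p_relation = "lt")),
        cues = list(cue_evidence("significantly"))))
  },
  pos_vivo_dec = function(d) {
    pct <- round(stats::runif(1, 50, 80))
    list(
      segs = dplyr::bind_rows(
        seg(cap1(d[1]), "DRUG", d[1]),
        seg("markedly", "CHANGE", "marked"),
        seg("reduced", "CHANGE", "reduce"),
        seg("the"),
        seg("clearance", "PK_PARAMETER", "CL"),
        seg("of"),
        seg(d[2], "DRUG", d[2]),
        seg("by"),
        seg(paste0(pct, "%"), "NUMBER", as.character(pct), unit = "%",
            value = pct),
        seg("P<0.05", "NUMBER", "p-value lt", value = 0.05, pre = "(",
            post = ").")),
      ddi_label = "CDDIS",
      pairs = tibble::tibble(
        a = d[1], b = d[2], relation = "DDI", pair_type = "drug_drug",
        quant = list(quant_evidence("CL", "percent_change", pct,
                                    direction = "decrease", p_value = 0.049,
                                    p_relation = "lt")),
        cues = list(cue_evidence("markedly"))))
  },
  pos_vivo_three = function(d) {
    fc <- rnum(1.8, 3.2)
    list(
      segs = dplyr::bind_rows(
        seg(cap1(d[1]), "DRUG", d[1]),
        seg("significantly", "CHANGE", "significant"),
        seg("increased", "CHANGE", "increase"),
        seg("the"),
        seg("AUC", "PK_PARAMETER", "AUC"),
        seg("of"),
        seg(d[2], "DRUG", d[2]),
        seg("by"),
        seg(paste0(sprintf("%.1f", fc), " fold"), "NUMBER",
            sprintf("%.1f", fc), unit = "fold", value = fc),
        seg("P<0.01", "NUMBER", "p-value lt", value = 0.01, pre = "(",
            post = "),"),
        seg("whereas"),
        seg(d[3], "DRUG", d[3]),
        seg("had no effect", post = ".")),
      ddi_label = "CDDIS",
      pairs = tibble::tibble(
        a = c(d[1], d[1]), b = c(d[2], d[3]),
        relation = c("DDI", "NDDI"), pair_type = "drug_drug",
        quant = list(
          quant_evidence("AUC", "fold_change", fc, p_value = 0.01,
                         p_relation = "lt"),
          quant_evidence(character(), character(), double())),
        cues = list(cue_evidence("significantly"),
                    cue_evidence("no effect"))))
  },
  neg_vivo = function(d) {
    fc <- rnum(0.8, 1.2, 2); p <- rnum(0.2, 0.9, 2)
    list(
      segs = dplyr::bind_rows(
        seg(cap1(d[1]), "DRUG", d[1]),
        seg("did not"),
        seg("significantly", "CHANGE", "significant"),
        seg("affect", "CHANGE", "affect"),
        seg("the"),
        seg("AUC", "PK_PARAMETER", "AUC"),
        seg("of"),
        seg(d[2], "DRUG", d[2]),
        seg(paste0("fold change ", sprintf("%.2f", fc)), pre = "(",
            post = ","),
        seg(paste0("P=", sprintf("%.2f", p)), "NUMBER", "p-value eq",
            value = p, post = ").")),
      ddi_label = "CDDIS",
      pairs = tibble::tibble(
        a = d[1], b = d[2], relation = "NDDI", pair_type = "drug_drug",
        quant = list(quant_evidence("AUC", "fold_change", fc, p_value = p,
                                    p_relation = "eq")),
        cues = list(cue_evidence("not significantly affect"))))
  },
  amb_vivo = function(d) {
    list(
      segs = dplyr::bind_rows(
        seg(cap1(d[1]), "DRUG", d[1]),
        seg("may", "CHANGE", "may"),
        seg("moderately", "CHANGE", "moderate"),
        seg("increase", "CHANGE", "increase"),
        seg("the"),
        seg("Cmax", "PK_PARAMETER", "Cmax"),
        seg("of"),
        seg(d[2], "DRUG", d[2], post = ".")),
      ddi_label = "CDDIS",
      pairs = tibble::tibble(
        a = d[1], b = d[2], relation = "ADDI", pair_type = "drug_drug",
        quant = list(quant_evidence(character(), character(), double())),
        cues = list(cue_evidence("may moderately increase"))))
  },
  pos_vitro = function(d, e) {
    ki <- rnum(0.5, 8)
    list(
      segs = dplyr::bind_rows(
        seg(cap1(d[1]), "DRUG", d[1]),
        seg("potently"),
        seg("inhibited", "MECHANISM", "inhibit"),
        seg(e[1], "ENZYME", e[1]),
        seg("with a"),
        seg("Ki", "PK_PARAMETER", "Ki"),
        seg("of"),
        seg(paste0(sprintf("%.1f", ki), " microM"), "NUMBER",
            sprintf("%.1f", ki), unit = "microM", value = ki),
        seg("P<0.01", "NUMBER", "p-value lt", value = 0.01, pre = "(",
            post = ").")),
      ddi_label = "CDDIS",
      pairs = tibble::tibble(
        a = d[1], b = e[1], relation = "DEI", pair_type = "drug_enzyme",
        quant = list(quant_evidence("Ki", "ki", ki, p_value = 0.01,
                                    p_relation = "lt")),
        cues = list(cue_evidence("potently inhibited"))))
  },
  amb_vitro = function(d, e) {
    ki <- rnum(15, 90)
    list(
      segs = dplyr::bind_rows(
        seg(cap1(d[1]), "DRUG", d[1]),
        seg("moderately", "CHANGE", "moderate"),
        seg("inhibited", "MECHANISM", "inhibit"),
        seg(e[1], "ENZYME", e[1]),
        seg("with a"),
        seg("Ki", "PK_PARAMETER", "Ki"),
        seg("of"),
        seg(paste0(sprintf("%.1f", ki), " microM"), "NUMBER",
            sprintf("%.1f", ki), unit = "microM", value = ki, post = ".")),
      ddi_label = "CDDIS",
      pairs = tibble::tibble(
        a = d[1], b = e[1], relation = "ADEI", pair_type = "drug_enzyme",
        quant = list(quant_evidence("Ki", "ki", ki)),
        cues = list(cue_evidence("moderately inhibited"))))
  },
  neg_vitro = function(d, e) {
    ki <- rnum(150, 400); p <- rnum(0.2, 0.8, 2)
    list(
      segs = dplyr::bind_rows(
        seg(cap1(d[1]), "DRUG", d[1]),
        seg("showed"),
        seg("negligible", "CHANGE", "negligible"),
        seg("inhibition", "MECHANISM", "inhibit"),
        seg("of"),
        seg(e[1], "ENZYME", e[1]),
        seg("Ki", "PK_PARAMETER", "Ki", pre = "("),
        seg(paste0(sprintf("%.1f", ki), " microM"), "NUMBER",
            sprintf("%.1f", ki), unit = "microM", value = ki, post = ","),
        seg(paste0("P=", sprintf("%.2f", p)), "NUMBER", "p-value eq",
            value = p, post = ").")),
      ddi_label = "CDDIS",
      pairs = tibble::tibble(
        a = d[1], b = e[1], relation = "NDEI", pair_type = "drug_enzyme",
        quant = list(quant_evidence("Ki", "ki", ki, p_value = p,
                                    p_relation = "eq")),
        cues = list(cue_evidence("negligible inhibition"))))
  },
  vddis = function(d) {
    fc <- rnum(1.8, 2.8)
    list(
      segs = dplyr::bind_rows(
        seg("Coadministration"),
        seg("significantly", "CHANGE", "significant"),
        seg("increased", "CHANGE", "increase"),
        seg("the"),
        seg("AUC", "PK_PARAMETER", "AUC"),
        seg("of"),
        seg(d[2], "DRUG", d[2]),
        seg("by"),
        seg(paste0(sprintf("%.1f", fc), " fold"), "NUMBER",
            sprintf("%.1f", fc), unit = "fold", value = fc, post = ".")),
      ddi_label = "VDDIS", context_entity = d[1],
      pairs = tibble::tibble(
        a = paste0("ctx:", d[1]), b = d[2], relation = "DDI",
        pair_type = "drug_drug",
        quant = list(quant_evidence("AUC", "fold_change", fc,
                                    p_value = 0.01, p_relation = "lt")),
        cues = list(cue_evidence("significantly"))))
  },
  vddis_neg = function(d) {
    p <- rnum(0.2, 0.8, 2)
    list(
      segs = dplyr::bind_rows(
        seg("Coadministration did not"),
        seg("significantly", "CHANGE", "significant"),
        seg("alter", "CHANGE", "affect"),
        seg("the"),
        seg("AUC", "PK_PARAMETER", "AUC"),
        seg("of"),
        seg(d[2], "DRUG", d[2]),
        seg(paste0("P=", sprintf("%.2f", p)), "NUMBER", "p-value eq",
            value = p, pre = "(", post = ").")),
      ddi_label = "VDDIS", context_entity = d[1],
      pairs = tibble::tibble(
        a = paste0("ctx:", d[1]), b = d[2], relation = "NDDI",
        pair_type = "drug_drug",
        quant = list(quant_evidence(character(), character(), double())),
        cues = list(cue_evidence("not significantly alter"))))
  },
  distractor = function(d) {
    list(
      segs = dplyr::bind_rows(
        seg("The"),
        seg("metabolism", "MECHANISM", "metaboli"),
        seg("of"),
        seg(d[1], "DRUG", d[1]),
        seg("was investigated in human liver microsomes", post = ".")),
      ddi_label = "NONE",
      pairs = NULL)
  },
  background = function(d) {
    list(
      segs = dplyr::bind_rows(
        seg("Plasma samples were collected over"),
        seg("24 h", "NUMBER", "24", unit = "h", value = 24, post = ".")),
      ddi_label = "NONE", pairs = NULL)
  }
)

#' Generate a synthetic annotated corpus
#'
#' Emits documents of template sentences modeled on the phrasing of the
#' worked examples (definite, ambiguous and negative cue templates, and
#' numeric templates whose fold changes, inhibition constants and p-values
#' are drawn to land in the intended rule bands), with key terms, sentence
#' labels and pair annotations that are correct by construction. Every
#' numeric pair's evidence reclassifies to its planted label. The returned
#' tally holds the planted counts, and `candidates` the evidence table used
#' by the rule classifier.
#'
#' @param n_documents Number of documents.
#' @param seed Integer seed; the output is identical across runs with the
#'   same seed.
#' @param class_mix Named proportions over the four study classes.
#' @param positive_rate Target proportion of candidate pairs (in DDI
#'   sentences) that are definite interactions (DDI/DEI).
#' @param sentences_per_doc Range of DDI-template sentences per interaction
#'   study document.
#' @return A list of class `pk_synth`: `corpus` (a `pk_corpus`), `tally`
#'   (tibble matching [corpus_stats()]), and `candidates` (tibble for
#'   [classify_pairs()] with the planted label in `label_expected`).
#' @export
#' @examples
#' synth <- simulate_corpus(5, seed = 1)
#' synth$corpus
simulate_corpus <- function(n_documents = 20, seed = 1,
                            class_mix = c(in_vivo_pk = 0.1, in_vivo_pg = 0.1,
                                          in_vivo_ddi = 0.4,
                                          in_vitro_ddi = 0.4),
                            positive_rate = 0.25,
                            sentences_per_doc = c(3L, 5L)) {
  stopifnot(abs(sum(class_mix) - 1) < 1e-8, n_documents >= 0,
            positive_rate >= 0, positive_rate < 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  three_frac <- 0.15
  # probability a DDI sentence is positive, so the expected share of
  # positive candidate pairs equals positive_rate (three-entity positive
  # sentences contribute two extra negative pairs each)
  q <- positive_rate / (1 - 2 * three_frac * positive_rate)
  docs <- list(); sents <- list(); terms <- list(); pairs <- list()
  cands <- list()
  # planted tallies, accumulated as sentences are emitted
  planted_cats <- character(); planted_slab <- character()
  planted_rel <- character(); planted_ws <- 0L; planted_tok <- 0L
  for (di in seq_len(n_documents)) {
    pmid <- sprintf("SYN%05d", di)
    cls <- sample(names(class_mix), 1, prob = class_mix)
    setting <- if (cls == "in_vitro_ddi") "in_vitro" else "in_vivo"
    n_body <- sample(seq(sentences_per_doc[1], sentences_per_doc[2]), 1)
    plan <- character(n_body)
    for (k in seq_len(n_body)) {
      if (!grepl("ddi", cls)) {
        plan[k] <- sample(c("distractor", "background"), 1)
      } else if (stats::runif(1) < 0.2) {
        # mechanism-word distractors exercise NONE labeling
        plan[k] <- "distractor"
      } else if (setting == "in_vitro") {
        plan[k] <- if (stats::runif(1) < positive_rate) "pos_vitro"
                   else sample(c("amb_vitro", "neg_vitro"), 1)
      } else if (stats::runif(1) < q) {
        plan[k] <- if (stats::runif(1) < three_frac) "pos_vivo_three"
                   else sample(c("pos_vivo", "pos_vivo_dec"), 1)
      } else {
        plan[k] <- sample(c("neg_vivo", "amb_vivo"), 1)
      }
    }
    # a vague-DDI sentence needs a preceding mention of the context drug
    if (grepl("ddi", cls) && setting == "in_vivo" && n_body >= 2 &&
        stats::runif(1) < 0.25) {
      plan[n_body] <- if (stats::runif(1) < q) "vddis" else "vddis_neg"
    }
    plan <- c("background", plan)
    doc_sents <- list(); doc_terms <- list(); doc_pairs <- list()
    prev_drug <- sample(synth_drugs, 1)
    for (si in seq_along(plan)) {
      d <- sample(synth_drugs, 3)
      if (plan[si] == "vddis") d[1] <- prev_drug
      e <- sample(synth_enzymes, 2)
      tpl <- synth_templates[[plan[si]]]
      made <- if (plan[si] %in% c("pos_vitro", "amb_vitro", "neg_vitro")) {
        tpl(d, e)
      } else {
        tpl(d)
      }
      comp <- compose_sentence(made$segs)
      sidx <- si - 1L
      tt <- comp$terms
      tt$term_id <- paste0("t", seq_len(nrow(tt)) - 1L)
      ctx <- if (!is.null(made$context_entity)) made$context_entity
             else NA_character_
      doc_sents[[si]] <- tibble::tibble(
        pmid = pmid, sentence_index = sidx, text = comp$text,
        ddi_label = made$ddi_label,
        context_entity = ctx,
        context_sentence = if (!is.na(ctx)) sidx - 1L else NA_integer_)
      doc_terms[[si]] <- mutate(tt, pmid = pmid, sentence_index = sidx,
                                .before = 1)
      planted_cats <- c(planted_cats, made$segs$category[
        !is.na(made$segs$category)])
      planted_slab <- c(planted_slab, made$ddi_label)
      planted_ws <- planted_ws +
        length(strsplit(comp$text, "\\s+")[[1]])
      planted_tok <- planted_tok + nrow(token_spans(comp$text))
      if (!is.null(made$pairs) && nrow(made$pairs)) {
        id_of <- function(nm) {
          if (grepl("^ctx:", nm)) return(paste0(nm, ":", sidx - 1L))
          tt$term_id[match(nm, tt$normal_form)]
        }
        pr <- made$pairs
        doc_pairs[[si]] <- tibble::tibble(
          pmid = pmid, sentence_index = sidx,
          pair_id = paste0("p", seq_len(nrow(pr)) - 1L),
          entity_a = vapply(pr$a, id_of, character(1)),
          entity_b = vapply(pr$b, id_of, character(1)),
          relation = pr$relation, setting = setting,
          evidence = NA_character_)
        cands[[length(cands) + 1L]] <- tibble::tibble(
          pmid = pmid, sentence_index = sidx,
          entity_a = pr$a, entity_b = pr$b, setting = setting,
          pair_type = pr$pair_type, c1 = TRUE, c2 = TRUE,
          quant = pr$quant, cues = pr$cues, label_expected = pr$relation)
        planted_rel <- c(planted_rel, pr$relation)
      }
      if (plan[si] %in% c("pos_vivo", "pos_vivo_dec", "neg_vivo",
                          "amb_vivo", "pos_vivo_three")) {
        prev_drug <- d[1]
      }
    }
    docs[[di]] <- tibble::tibble(
      pmid = pmid, title = paste("Synthetic PK study", di),
      study_class = cls)
    sents[[di]] <- dplyr::bind_rows(doc_sents)
    terms[[di]] <- dplyr::bind_rows(doc_terms)
    pairs[[di]] <- dplyr::bind_rows(doc_pairs)
  }
  corpus <- pk_corpus(dplyr::bind_rows(docs), dplyr::bind_rows(sents),
                      dplyr::bind_rows(terms),
                      if (length(pairs)) dplyr::bind_rows(pairs) else NULL)
  rel <- setdiff(relation_label_values, "NONE")
  tally <- dplyr::bind_rows(
    tibble::tibble(group = "key_terms", category = term_categories,
                   n = unname(vapply(term_categories,
                                     function(cc) sum(planted_cats == cc),
                                     integer(1)))),
    tibble::tibble(group = "sentences", category = sentence_label_values,
                   n = unname(vapply(sentence_label_values,
                                     function(l) sum(planted_slab == l),
                                     integer(1)))),
    tibble::tibble(group = "pairs", category = rel,
                   n = unname(vapply(rel, function(l) sum(planted_rel == l),
                                     integer(1)))),
    tibble::tibble(group = "totals",
                   category = c("words_whitespace", "words_tokenized",
                                "sentences", "pairs"),
                   n = c(planted_ws, planted_tok, length(planted_slab),
                         length(planted_rel))))
  structure(
    list(corpus = corpus, tally = tally,
         candidates = if (length(cands)) dplyr::bind_rows(cands) else
           tibble::tibble()),
    class = "pk_synth")
}

#' @export
print.pk_synth <- function(x, ...) {
  cat("<pk_synth> synthetic annotated corpus\n")
  print(x$corpus)
  invisible(x)
}
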