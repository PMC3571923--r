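# The rule-based six-label interaction classifier. A candidate pair is
# labeled from four conditions: C1 (an entity name in the sentence), C2 (the
# partner in the sentence or resolvable from context), C3 (numeric rules on
# the highest-priority PK parameter) and C4 (linguistic cue polarity); the
# combination is C1 AND C2 AND (C3 OR C4), with quantitative evidence taking
# precedence over cues when both are present.

#' Classifier thresholds and cue lists
#'
#' Bundles the numeric thresholds and cue word lists of the interaction
#' rules. In vivo, a definite interaction requires a significant p-value and
#' a fold change at or above `fc_upper` (1.50) or strictly below `fc_lower`
#' (0.67); the band between is a non-interaction when the p-value is
#' explicitly non-significant. In vitro, the inhibition/induction constant
#' (Ki, IC50 or EC50, microM) is definite below `ki_definite` (10),
#' non-interacting above `ki_non` (100) with a non-significant p-value, and
#' ambiguous between. Values exactly at 0.67, 10 or 100 fall into the
#' ambiguous band; 1.50 counts as definite, following the worked examples.
#'
#' @param fc_upper,fc_lower In vivo fold-change thresholds.
#' @param p_sig Significance threshold for p-values.
#' @param ki_definite,ki_non In vitro concentration thresholds (microM).
#' @param definite_cues,ambiguous_cues,negative_cues Regular expressions
#'   (matched case-insensitively against whole cue phrases) for the three
#'   cue polarities.
#' @param negation_pattern Regular expression detecting a negation adjacent
#'   to a cue ("not significantly" is a negative cue).
#' @return A list of class `ddi_rules`.
#' @export
ddi_rules <- function(fc_upper = 1.50, fc_lower = 0.67, p_sig = 0.05,
                      ki_definite = 10, ki_non = 100,
                      definite_cues = c("significant(ly)?", "obvious(ly)?",
                                        "marked(ly)?", "great(ly)?",
                                        "pronounced(ly)?", "potent(ly)?",
                                        "strong(ly)?"),
                      ambiguous_cues = c("modest(ly)?", "moderate(ly)?",
                                         "probably", "may", "might",
                                         "possib(le|ly)"),
                      negative_cues = c("minor( significance)?",
                                        "slight(ly)?", "little",
                                        "negligible", "no effect",
                                        "do(es)?n[’']?t interact",
                                        "does not interact"),
                      negation_pattern = "\\b(not?|n[’']t|without|neither|nor|fail(ed|s)? to|lack(ed|s)?( of)?)\\b") {
  stopifnot(fc_upper > 1, fc_lower > 0, fc_lower < 1, p_sig > 0,
            ki_definite > 0, ki_non > ki_definite)
  structure(
    list(fc_upper = fc_upper, fc_lower = fc_lower, p_sig = p_sig,
         ki_definite = ki_definite, ki_non = ki_non,
         definite_cues = definite_cues, ambiguous_cues = ambiguous_cues,
         negative_cues = negative_cues, negation_pattern = negation_pattern),
    class = "ddi_rules")
}

#' Convert a percent change to a fold change
#'
#' A decrease by x percent is a fold change of 1 - x/100; an increase by x
#' percent is 1 + x/100.
#'
#' @param percent Percent change (positive magnitude).
#' @param direction `"increase"` or `"decrease"`.
#' @return Fold change.
#' @export
#' @examples
#' percent_to_fold(64, "decrease")  # 0.36
percent_to_fold <- function(percent, direction = c("increase", "decrease")) {
  direction <- match.arg(direction)
  if (any(percent <= -100)) abort("percent change must exceed -100")
  if (direction == "decrease" && any(percent >= 100)) {
    abort("a decrease of 100% or more gives a non-positive fold change")
  }
  if (direction == "decrease") 1 - percent / 100 else 1 + percent / 100
}

#' Construct quantitative evidence rows
#'
#' @param parameter PK parameter symbol (e.g. `"AUC"`, `"CL"`, `"Ki"`).
#' @param kind One of `"fold_change"`, `"percent_change"`, `"ki"`,
#'   `"ic50"`, `"ec50"`.
#' @param value Numeric value (fold for fold changes, percent magnitude for
#'   percent changes, microM for in vitro constants).
#' @param direction `"increase"` or `"decrease"` (percent changes only).
#' @param p_value Associated p-value, or `NA`.
#' @param p_relation Comparison operator of the p-value as printed:
#'   `"lt"`, `"le"`, `"gt"`, `"ge"` or `"eq"`.
#' @return A quantitative-evidence tibble.
#' @export
quant_evidence <- function(parameter, kind, value, direction = NA_character_,
                           p_value = NA_real_, p_relation = NA_character_) {
  tibble::tibble(parameter = parameter, kind = kind, value = value,
                 direction = direction, p_value = p_value,
                 p_relation = p_relation)
}

#' Construct cue evidence rows
#'
#' @param phrase Cue surface string(s).
#' @param polarity `"definite"`, `"ambiguous"`, `"negative"` or `NA` to
#'   assign the polarity from the configured cue lists at classification
#'   time.
#' @return A cue-evidence tibble.
#' @export
cue_evidence <- function(phrase, polarity = NA_character_) {
  tibble::tibble(phrase = phrase, polarity = polarity)
}

in_vivo_ranks <- c(AUC = 1, CL = 2, "t1/2" = 3, Cmax = 4)
in_vitro_ranks <- c(Ki = 1, IC50 = 2)

param_rank <- function(parameter, setting) {
  ranks <- if (setting == "in_vitro") in_vitro_ranks else in_vivo_ranks
  r <- unname(ranks[parameter])
  ifelse(is.na(r), 99, r)
}

effective_fold <- function(ev) {
  dplyr::case_when(
    ev$kind == "fold_change" ~ ev$value,
    ev$kind == "percent_change" & ev$direction %in% "decrease" ~
      1 - ev$value / 100,
    ev$kind == "percent_change" ~ 1 + ev$value / 100,
    TRUE ~ NA_real_
  )
}

#' Select the highest-priority quantitative evidence
#'
#' In vivo the parameter priority is AUC > CL > t1/2 > Cmax; in vitro it is
#' Ki > IC50. Unranked parameters fall below all ranked ones; ties are broken
#' by the larger absolute log fold change, then input order.
#'
#' @param quant A quantitative-evidence tibble (columns `parameter`, `kind`,
#'   `value`, `direction`, `p_value`, `p_relation`).
#' @param setting `"in_vivo"` or `"in_vitro"`.
#' @return The single highest-priority row.
#' @export
rank_parameter <- function(quant, setting = c("in_vivo", "in_vitro")) {
  setting <- match.arg(setting)
  if (!nrow(quant)) abort("no quantitative evidence to rank")
  fc <- effective_fold(quant)
  ord <- order(param_rank(quant$parameter, setting),
               -abs(log(ifelse(is.na(fc) | fc <= 0, 1, fc))),
               seq_len(nrow(quant)))
  quant[ord[1], ]
}

# TRUE / FALSE / NA significance from a p-value and comparison operator.
# "p > x" asserts non-significance only when x is at or above the threshold.
p_significant <- function(p_value, p_relation, p_sig) {
  if (is.na(p_value)) return(NA)
  if (!is.na(p_relation) && p_relation %in% c("gt", "ge")) {
    return(if (p_value >= p_sig) FALSE else NA)
  }
  p_value <= p_sig
}

# Band of a single evidence row: "definite", "ambiguous" or "non".
quant_band <- function(ev, setting, rules) {
  sig <- p_significant(ev$p_value, ev$p_relation, rules$p_sig)
  if (setting == "in_vivo") {
    fc <- effective_fold(ev)
    if (is.na(fc)) abort("in vivo evidence requires a fold or percent change")
    outside <- fc >= rules$fc_upper | fc < rules$fc_lower
    inside <- fc > rules$fc_lower & fc < rules$fc_upper
    if (outside && !isFALSE(sig)) return("definite")
    if (inside && isFALSE(sig)) return("non")
    return("ambiguous")
  }
  if (!ev$kind %in% c("ki", "ic50", "ec50")) {
    abort("in vitro evidence requires a ki, ic50 or ec50 value")
  }
  if (ev$value <= 0) abort("ki/ic50/ec50 values must be positive")
  if (ev$value < rules$ki_definite && !isFALSE(sig)) return("definite")
  if (ev$value > rules$ki_non && isFALSE(sig)) return("non")
  "ambiguous"
}

band_to_label <- function(band, family) {
  base <- c(definite = "D", ambiguous = "AD", non = "ND")[band]
  if (family == "DEI") paste0(base, "EI") else paste0(base, "DI")
}

label_family <- function(setting, pair_type) {
  if (setting == "in_vitro" && pair_type == "drug_enzyme") "DEI" else "DDI"
}

#' Classify quantitative evidence
#'
#' Applies the numeric interaction rules to one evidence item. In vivo the
#' evidence must be a fold or percent change; in vitro a Ki, IC50 or EC50 in
#' microM. A missing p-value never blocks the definite band and never
#' satisfies the non-interaction band's requirement of an explicitly
#' non-significant p-value.
#'
#' @param quant A single-row quantitative-evidence tibble.
#' @param setting `"in_vivo"` or `"in_vitro"`.
#' @param pair_type `"drug_drug"` or `"drug_enzyme"`; drug-enzyme pairs in
#'   vitro take the DEI label family.
#' @param rules A [ddi_rules()] configuration.
#' @return A relation label.
#' @export
#' @examples
#' classify_quant(data.frame(parameter = "AUC", kind = "fold_change",
#'                           value = 2, direction = NA, p_value = 0.01,
#'                           p_relation = "le"))
classify_quant <- function(quant, setting = c("in_vivo", "in_vitro"),
                           pair_type = "drug_drug", rules = ddi_rules()) {
  setting <- match.arg(setting)
  quant <- as_tibble(quant)
  stopifnot(nrow(quant) == 1)
  if (setting == "in_vivo" &&
      !quant$kind %in% c("fold_change", "percent_change")) {
    abort("in vivo evidence must be a fold_change or percent_change")
  }
  band_to_label(quant_band(quant, setting, rules),
                label_family(setting, pair_type))
}

# Polarity of one cue phrase from the configured lists, with negation
# handling: a negated definite cue ("not significantly") is negative.
cue_polarity <- function(phrase, rules = ddi_rules()) {
  p <- tolower(phrase)
  negated <- grepl(rules$negation_pattern, p, perl = TRUE)
  has <- function(pats) {
    any(vapply(pats, function(x)
      grepl(paste0("(?i)\\b", x, "\\b"), p, perl = TRUE), logical(1)))
  }
  if (has(rules$negative_cues)) return("negative")
  if (has(rules$definite_cues)) {
    return(if (negated) "negative" else "definite")
  }
  if (has(rules$ambiguous_cues)) return("ambiguous")
  if (negated) return("negative")
  NA_character_
}

#' Classify linguistic-cue evidence
#'
#' Maps cue polarity to a label family member: an (un-negated) definite cue
#' gives the definite label; otherwise a negative cue gives the
#' non-interaction label; otherwise an ambiguous cue the ambiguous label.
#' Cues with missing polarity are assigned one from the configured lists.
#'
#' @param cues A cue-evidence tibble (columns `phrase`, `polarity`).
#' @inheritParams classify_quant
#' @return A relation label, or `"NONE"` for an empty cue list.
#' @export
#' @examples
#' classify_cues(data.frame(phrase = "not significantly changed",
#'                          polarity = NA))
classify_cues <- function(cues, setting = c("in_vivo", "in_vitro"),
                          pair_type = "drug_drug", rules = ddi_rules()) {
  setting <- match.arg(setting)
  cues <- as_tibble(cues)
  if (!nrow(cues)) return("NONE")
  pol <- ifelse(is.na(cues$polarity),
                vapply(cues$phrase, cue_polarity, character(1),
                       rules = rules),
                cues$polarity)
  pol <- pol[!is.na(pol)]
  if (!length(pol)) return("NONE")
  band <- if ("definite" %in% pol) "definite"
          else if ("negative" %in% pol) "non"
          else "ambiguous"
  band_to_label(band, label_family(setting, pair_type))
}

classify_one <- function(setting, pair_type, c1, c2, quant, cues, rules) {
  if (!isTRUE(c1) || !isTRUE(c2)) return("NONE")
  family <- label_family(setting, pair_type)
  quant <- as_tibble(quant)
  if (setting == "in_vivo") {
    quant <- quant[quant$kind %in% c("fold_change", "percent_change"), ,
                   drop = FALSE]
  } else {
    quant <- quant[quant$kind %in% c("ki", "ic50", "ec50"), , drop = FALSE]
  }
  if (nrow(quant)) {
    top <- rank_parameter(quant, setting)
    same <- quant[quant$parameter == top$parameter, , drop = FALSE]
    bands <- unique(vapply(seq_len(nrow(same)), function(i)
      quant_band(same[i, ], setting, rules), character(1)))
    band <- if (length(bands) > 1) "ambiguous" else bands
    return(band_to_label(band, family))
  }
  classify_cues(cues, setting, pair_type, rules)
}

#' Classify interaction candidates
#'
#' The full rule classifier: `NONE` unless both entity conditions hold (C1:
#' at least one entity name in the sentence; C2: the partner in the sentence
#' or resolvable from context); then the numeric rules applied to the
#' highest-priority PK parameter when quantitative evidence exists, and the
#' cue rules otherwise. When several measurements of the highest-priority
#' parameter fall into different bands, the ambiguous band wins. The result
#' does not depend on the order of the two entities.
#'
#' @param candidates A tibble with one row per candidate pair: columns
#'   `setting` (`"in_vivo"`/`"in_vitro"`), `pair_type`
#'   (`"drug_drug"`/`"drug_enzyme"`), `c1`, `c2` (logical), `quant` and
#'   `cues` (list columns of evidence tibbles; see [quant_evidence()] /
#'   [cue_evidence()] helpers used by the fixtures).
#' @param rules A [ddi_rules()] configuration.
#' @return `candidates` with a `label` column appended.
#' @export
#' @examples
#' classify_pairs(tibble::tibble(
#'   setting = "in_vivo", pair_type = "drug_drug", c1 = TRUE, c2 = TRUE,
#'   quant = list(data.frame(parameter = "AUC", kind = "fold_change",
#'                           value = 2, direction = NA, p_value = 0.01,
#'                           p_relation = "le")),
#'   cues = list(data.frame(phrase = character(), polarity = character()))
#' ))
classify_pairs <- function(candidates, rules = ddi_rules()) {
  candidates$label <- purrr::pmap_chr(
    list(candidates$setting, candidates$pair_type, candidates$c1,
         candidates$c2, candidates$quant, candidates$cues),
    classify_one, rules = rules)
  candidates
}

#' Label a tagged sentence as NONE, CDDIS or VDDIS
#'
#' A clear DDI sentence (CDDIS) holds at least two interaction entities
#' (drugs, or a drug-enzyme pair in vitro) together with an interaction
#' statement (a mechanism or change key term). A vague DDI sentence (VDDIS)
#' holds exactly one entity plus a statement, with the partner resolvable
#' from context.
#'
#' @param terms Key-term tibble for one sentence.
#' @param context_partner Logical: is a partner entity resolvable from the
#'   surrounding context?
#' @return `"NONE"`, `"CDDIS"` or `"VDDIS"`.
#' @export
label_sentence <- function(terms, context_partner = FALSE) {
  ents <- terms %>% filter(.data$category %in% c("DRUG", "ENZYME"))
  n_ent <- dplyr::n_distinct(ents$normal_form)
  statement <- any(terms$category %in% c("MECHANISM", "CHANGE"))
  if (n_ent >= 2 && statement) return("CDDIS")
  if (n_ent == 1 && statement && isTRUE(context_partner)) return("VDDIS")
  "NONE"
}
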