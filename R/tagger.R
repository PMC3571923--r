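# Rule-based tagging of the six key-term classes. All offsets are 0-based,
# half-open, local to the sentence; `text` always equals the sentence
# substring [start, end).

term_categories <- c("DRUG", "METABOLITE", "ENZYME", "PK_PARAMETER", "NUMBER",
                     "MECHANISM", "CHANGE")

empty_terms <- function() {
  tibble::tibble(
    sentence_index = integer(), start = integer(), end = integer(),
    text = character(), category = character(), normal_form = character(),
    unit = character(), value = double()
  )
}

term_row <- function(sentence_index, start, end, text, category, normal_form,
                     unit = NA_character_, value = NA_real_) {
  tibble::tibble(sentence_index = as.integer(sentence_index),
                 start = as.integer(start), end = as.integer(end),
                 text = text, category = category, normal_form = normal_form,
                 unit = unit, value = value)
}

# Tokens are maximal runs of word characters plus the in-token punctuation
# seen in enzyme and drug names. Offsets 0-based half-open.
token_spans <- function(sentence) {
  m <- gregexpr("[A-Za-z0-9*'’½-]+", sentence)[[1]]
  if (m[1] == -1) {
    return(tibble::tibble(token = character(), start = integer(),
                          end = integer()))
  }
  start <- as.integer(m) - 1L
  len <- attr(m, "match.length")
  tibble::tibble(token = substring(sentence, m, m + len - 1L),
                 start = start, end = start + as.integer(len))
}

#' Tokenize a sentence
#'
#' The shared tokenization used for agreement units and parse alignment:
#' maximal runs of alphanumerics plus in-token hyphen/apostrophe/asterisk.
#'
#' @param sentences Character vector of sentences.
#' @return A tibble with columns `sentence_index` (0-based), `token`,
#'   `start`, `end` (0-based half-open character offsets).
#' @export
pk_tokenize <- function(sentences) {
  purrr::imap_dfr(sentences, function(s, i) {
    dplyr::mutate(token_spans(s), sentence_index = i - 1L, .before = 1)
  })
}

# The printed enzyme pattern is anchored and requires a digit-letter-digit
# core, so it misses CYP2C19 (two trailing digits) and CYP3A (no trailing
# digit); the extended pattern fixes both and is the default.
enzyme_core_extended <- "(?:cyp|CYP|Cyp|P450|p450|CYP450)?[0-9][A-Za-z][0-9]*(?:\\*[0-9]+)?"
enzyme_core_strict <- "(?:cyp|CYP|P450|CYP450)?[0-9][a-zA-Z][0-9](?:\\*[0-9])?"

#' Tag CYP enzyme names
#'
#' @param sentences Character vector of sentences.
#' @param strict Use the verbatim corpus pattern (digit-letter-digit core,
#'   single optional allele digit) instead of the extended pattern. The
#'   strict pattern fails on `CYP2C19` and `CYP3A`.
#' @return A key-term tibble (see [tag_terms()]); `normal_form` is upper-cased
#'   with the `CYP` prefix restored.
#' @export
#' @examples
#' tag_enzymes("Ketoconazole inhibited CYP3A4 and cyp2c19.")
tag_enzymes <- function(sentences, strict = FALSE) {
  core <- if (strict) enzyme_core_strict else enzyme_core_extended
  pat <- paste0("^", core, "$")
  purrr::imap_dfr(sentences, function(s, i) {
    toks <- dplyr::filter(token_spans(s), grepl(pat, .data$token))
    if (!nrow(toks)) return(empty_terms())
    nf <- toupper(sub("^(?i:cyp450|cyp|p450)", "", toks$token, perl = TRUE))
    term_row(i - 1L, toks$start, toks$end, toks$token, "ENZYME",
             paste0("CYP", nf))
  })
}

mechanism_stems <- c(
  inhibit   = "inhibit(e(s|d)?|ing|ion(s)?|or(s)?)",
  catalyz   = "catalyz(e(s|d)?|ing)",
  correlat  = "correlat(e(s|d)?|ing|ion(s)?)",
  metaboli  = "metaboli(z(e(s|d)?|ing)|sm)",
  induc     = "induc(e(s|d)?|ing|tion(s)?|or(s)?)",
  form      = "form((s|ed)?|ing|a?tion(s)?|or(s)?)",
  stimulat  = "stimulat(e(s|d)?|ing|ion(s)?)",
  activ     = "activ(e(s)?|(at)(e(s|d)?|ing|ion(s)?))",
  suppress  = "suppress(e(s|d)?|ing|ion(s)?)"
)

#' Tag drug metabolism/interaction mechanism words
#'
#' Words matching the nine mechanism stem patterns (inhibit-, catalyz-,
#' correlat-, metaboli-, induc-, form-, stimulat-, activ-, suppress-) with
#' their enumerated suffixes. `normal_form` is the stem. Suffixes outside the
#' enumeration (e.g. "inhibitory") are deliberately not matched.
#'
#' @inheritParams tag_enzymes
#' @return A key-term tibble.
#' @export
tag_mechanisms <- function(sentences) {
  pats <- paste0("^(?i)", mechanism_stems, "$")
  purrr::imap_dfr(sentences, function(s, i) {
    toks <- token_spans(s)
    if (!nrow(toks)) return(empty_terms())
    hit <- purrr::map(pats, ~ grepl(.x, toks$token, perl = TRUE))
    idx <- purrr::map_int(purrr::transpose(hit), ~ {
      w <- which(unlist(.x)); if (length(w)) w[[1]] else NA_integer_
    })
    sel <- !is.na(idx)
    if (!any(sel)) return(empty_terms())
    term_row(i - 1L, toks$start[sel], toks$end[sel], toks$token[sel],
             "MECHANISM", names(mechanism_stems)[idx[sel]])
  })
}

# Change cues; decreas- supplements the printed increas-/reduc- pair (the
# worked examples use "decreased" as a change cue).
change_words <- c(
  strong = "strong(ly)?", moderate = "moderate(ly)?",
  high = "high(est|er)?", slight = "slight(ly)?",
  significant = "significant(ly)?", obvious = "obvious(ly)?",
  marked = "marked(ly)?", great = "great(ly)?",
  pronounced = "pronounced(ly)?", modest = "modest(ly)?",
  probably = "probably", may = "may", might = "might", minor = "minor",
  little = "little", negligible = "negligible",
  affect = "affect((s|ed)?|ing|ion(s)?)?",
  reduce = "reduc(e(s|d)?|ing|tion(s)?)",
  increase = "increas(e(s|d)?|ing)",
  decrease = "decreas(e(s|d)?|ing)"
)
change_multiword <- c("doesn't interact", "doesn’t interact",
                      "does not interact")

#' Tag change cues
#'
#' Single-word cues from the corpus change list (strongly, significantly,
#' slightly, negligible, may, might, ...) plus the multi-word cue
#' "doesn't interact".
#'
#' @inheritParams tag_enzymes
#' @return A key-term tibble; `normal_form` is the base form of the cue.
#' @export
tag_changes <- function(sentences) {
  pats <- paste0("^(?i)", change_words, "$")
  purrr::imap_dfr(sentences, function(s, i) {
    out <- empty_terms()
    for (mw in change_multiword) {
      loc <- stringr::str_locate_all(stringr::str_to_lower(s),
                                     stringr::fixed(tolower(mw)))[[1]]
      if (nrow(loc)) {
        out <- dplyr::bind_rows(out, term_row(
          i - 1L, loc[, 1] - 1L, loc[, 2],
          substring(s, loc[, 1], loc[, 2]), "CHANGE", "doesn't interact"))
      }
    }
    toks <- token_spans(s)
    if (nrow(toks)) {
      hit <- purrr::map(pats, ~ grepl(.x, toks$token, perl = TRUE))
      idx <- purrr::map_int(purrr::transpose(hit), ~ {
        w <- which(unlist(.x)); if (length(w)) w[[1]] else NA_integer_
      })
      sel <- !is.na(idx)
      if (any(sel)) {
        out <- dplyr::bind_rows(out, term_row(
          i - 1L, toks$start[sel], toks$end[sel], toks$token[sel], "CHANGE",
          names(change_words)[idx[sel]]))
      }
    }
    resolve_overlaps(out)
  })
}

number_units <- c(
  "ng\\*?h/mL", "mg h L\\^?-1", "mg/mL", "ng/mL", "ug/mL", "mg/kg", "mg/day",
  "mL/min", "ml/min", "cm/sec", "micromol/L", "microM", "micrograms?", "uM",
  "nM", "mM", "mg", "ng", "ug", "mL", "ml", "L", "fold", "%", "h(?:ours?|rs?)?",
  "min(?:utes?)?", "days?", "weeks?"
)

p_value_pattern <- paste0(
  "(?i)\\bp\\s*(?:-?\\s*values?)?\\s*",
  "(<=|>=|[<>=≤≥])\\s*(\\.?[0-9]+(?:\\.[0-9]+)?)"
)

p_relation_map <- c("<" = "lt", "<=" = "le", "≤" = "le",
                    ">" = "gt", ">=" = "ge", "≥" = "ge", "=" = "eq")

number_pattern <- paste0(
  "(?<![A-Za-z0-9.])[0-9]+(?:\\.[0-9]+)?(?:[eE][+-]?[0-9]+)?",
  "(?:\\s?(?:", paste(number_units, collapse = "|"), ")(?![A-Za-z]))?"
)

#' Tag numbers and p-value expressions
#'
#' Decimal and scientific numerals are captured together with a trailing unit
#' token when the unit belongs to the PK unit vocabulary (mg, ng/mL, microM,
#' fold, %, ...). P-value expressions such as `P=.26` or `p-value <0.05` are
#' captured with the comparison operator retained and `normal_form`
#' `"p-value"`.
#'
#' @inheritParams tag_enzymes
#' @return A key-term tibble; `value` holds the parsed numeral, `unit` the
#'   unit string if present. For p-values the operator is appended to
#'   `normal_form` as e.g. `"p-value le"`.
#' @export
#' @examples
#' tag_numbers("Ki values of 3.5 and 10.8 microM (P=.26)")
tag_numbers <- function(sentences) {
  purrr::imap_dfr(sentences, function(s, i) {
    out <- empty_terms()
    pm <- stringr::str_locate_all(s, p_value_pattern)[[1]]
    if (nrow(pm)) {
      txt <- substring(s, pm[, 1], pm[, 2])
      parsed <- stringr::str_match(txt, p_value_pattern)
      out <- dplyr::bind_rows(out, term_row(
        i - 1L, pm[, 1] - 1L, pm[, 2], txt, "NUMBER",
        paste("p-value", p_relation_map[parsed[, 2]]),
        unit = NA_character_, value = as.numeric(parsed[, 3])))
    }
    nm <- stringr::str_locate_all(s, number_pattern)[[1]]
    if (nrow(nm)) {
      txt <- substring(s, nm[, 1], nm[, 2])
      num <- stringr::str_extract(txt, "^[0-9]+(\\.[0-9]+)?([eE][+-]?[0-9]+)?")
      unit <- trimws(stringr::str_remove(
        txt, "^[0-9]+(\\.[0-9]+)?([eE][+-]?[0-9]+)?\\s?"))
      unit[!nzchar(unit)] <- NA_character_
      out <- dplyr::bind_rows(out, term_row(
        i - 1L, nm[, 1] - 1L, nm[, 2], txt, "NUMBER", num,
        unit = unit, value = as.numeric(num)))
    }
    resolve_overlaps(out)
  })
}

# Build the surface-form -> symbol table used by the parameter tagger.
param_surface_table <- function(lexicon) {
  par <- lexicon$parameters
  purrr::map2_dfr(par$symbol, par$synonyms, function(sym, syn) {
    forms <- unique(c(sym, syn))
    forms <- forms[nchar(forms) >= 2]
    tibble::tibble(form = forms, symbol = sym)
  })
}

regex_escape <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' Tag PK parameter mentions
#'
#' Longest-match tagging over parameter symbols and their spelled-out
#' synonyms ("clearance" -> `CL`, "half-life" -> `t1/2`). Parenthesized
#' qualifiers such as `AUC(0-48)` map to the base symbol. Symbols shorter
#' than two characters are not tagged (single letters are too ambiguous in
#' running text); two-character symbols are matched case-sensitively.
#'
#' @inheritParams tag_enzymes
#' @param lexicon A `pk_lexicon`.
#' @return A key-term tibble; `normal_form` is the parameter symbol.
#' @export
#' @examples
#' tag_pk_parameters("The AUC(0-infinity) and half-life were unchanged.")
tag_pk_parameters <- function(sentences, lexicon = pk_lexicon()) {
  surf <- param_surface_table(lexicon)
  surf <- surf[order(-nchar(surf$form)), ]
  pats <- purrr::map2_chr(surf$form, nchar(surf$form), function(f, n) {
    ci <- if (n > 2) "(?i)" else ""
    paste0(ci, "(?<![A-Za-z0-9])", regex_escape(f),
           # allow a parenthesized qualifier directly after the symbol
           "(\\([^()]*\\))?",
           "(?![A-Za-z0-9])")
  })
  purrr::imap_dfr(sentences, function(s, i) {
    hits <- purrr::map2_dfr(pats, surf$symbol, function(p, sym) {
      loc <- stringr::str_locate_all(s, p)[[1]]
      if (!nrow(loc)) return(NULL)
      tibble::tibble(start = loc[, 1] - 1L, end = loc[, 2],
                     symbol = sym)
    })
    if (is.null(hits) || !nrow(hits)) return(empty_terms())
    out <- term_row(i - 1L, hits$start, hits$end,
                    substring(s, hits$start + 1L, hits$end), "PK_PARAMETER",
                    hits$symbol)
    resolve_overlaps(out)
  })
}

metabolite_affixes <- c("oxi", "hydroxyl", "methyl", "acetyl", "n-dealkyl",
                        "n-demethyl", "nor", "dihydroxy", "o-dealkyl", "sulfo")

# Strip a metabolite affix (prefix or suffix, optional hyphen, optional
# leading position digits) and return the remainder, or NA.
strip_affix <- function(token) {
  t <- tolower(token)
  t <- sub("^[0-9]+[,']?[0-9]*-", "", t)  # positional prefix e.g. "4-"
  for (a in metabolite_affixes) {
    ae <- regex_escape(a)
    if (grepl(paste0("^", ae, "-?"), t)) {
      rem <- sub(paste0("^", ae, "-?"), "", t)
      if (nchar(rem) >= 3) return(rem)
    }
    if (grepl(paste0("-?", ae, "$"), t)) {
      rem <- sub(paste0("-?", ae, "$"), "", t)
      if (nchar(rem) >= 3) return(rem)
    }
  }
  NA_character_
}

#' Tag drug and metabolite mentions
#'
#' Dictionary longest-match over the lexicon surface forms yields `DRUG`
#' terms. A token formed by one of the ten metabolite affixes (oxi, hydroxyl,
#' methyl, acetyl, N-dealkyl, N-demethyl, nor, dihydroxy, O-dealkyl, sulfo)
#' attached to a known drug name yields a `METABOLITE` term whose
#' `normal_form` records the parent drug.
#'
#' @inheritParams tag_pk_parameters
#' @return A key-term tibble; for metabolites `normal_form` is the parent
#'   canonical name.
#' @export
#' @examples
#' tag_drugs("Norverapamil follows verapamil kinetics.")
tag_drugs <- function(sentences, lexicon = pk_lexicon()) {
  drugs <- lexicon$drugs
  forms <- tibble::tibble(
    form = unlist(drugs$surface_forms),
    canonical = rep(drugs$canonical, lengths(drugs$surface_forms)),
    is_metabolite = rep(drugs$is_metabolite, lengths(drugs$surface_forms)),
    parent = rep(drugs$parent, lengths(drugs$surface_forms))
  )
  forms <- forms[order(-nchar(forms$form)), ]
  form_set <- unique(tolower(forms$form))
  pats <- paste0("(?i)(?<![A-Za-z0-9])", regex_escape(forms$form),
                 "(?![A-Za-z0-9])")
  purrr::imap_dfr(sentences, function(s, i) {
    hits <- purrr::pmap_dfr(
      list(pats, forms$canonical, forms$is_metabolite, forms$parent),
      function(p, canon, is_met, parent) {
        loc <- stringr::str_locate_all(s, p)[[1]]
        if (!nrow(loc)) return(NULL)
        tibble::tibble(start = loc[, 1] - 1L, end = loc[, 2],
                       canonical = canon, is_metabolite = is_met,
                       parent = parent)
      })
    out <- empty_terms()
    if (!is.null(hits) && nrow(hits)) {
      out <- term_row(
        i - 1L, hits$start, hits$end,
        substring(s, hits$start + 1L, hits$end),
        ifelse(hits$is_metabolite, "METABOLITE", "DRUG"),
        ifelse(hits$is_metabolite,
               ifelse(is.na(hits$parent), hits$canonical, hits$parent),
               hits$canonical))
    }
    # affix-derived metabolites among tokens not already matched
    toks <- token_spans(s)
    if (nrow(toks)) {
      rem <- purrr::map_chr(toks$token, strip_affix)
      sel <- !is.na(rem) & tolower(rem) %in% form_set
      if (nrow(out)) {
        covered <- purrr::map_lgl(seq_len(nrow(toks)), function(j) {
          any(out$start <= toks$start[j] & out$end >= toks$end[j])
        })
        sel <- sel & !covered
      }
      if (any(sel)) {
        parent_canon <- forms$canonical[match(tolower(rem[sel]),
                                              tolower(forms$form))]
        out <- dplyr::bind_rows(out, term_row(
          i - 1L, toks$start[sel], toks$end[sel], toks$token[sel],
          "METABOLITE", parent_canon))
      }
    }
    resolve_overlaps(out)
  })
}

# Longer span wins; on equal length the category precedence is
# DRUG > ENZYME > PK_PARAMETER > NUMBER > MECHANISM > CHANGE.
category_precedence <- c(DRUG = 1, METABOLITE = 1, ENZYME = 2,
                         PK_PARAMETER = 3, NUMBER = 4, MECHANISM = 5,
                         CHANGE = 6)

resolve_overlaps <- function(terms) {
  if (!nrow(terms)) return(terms)
  terms <- terms %>%
    dplyr::mutate(.len = .data$end - .data$start,
                  .prec = category_precedence[.data$category]) %>%
    dplyr::arrange(.data$sentence_index, dplyr::desc(.data$.len),
                   .data$.prec, .data$start)
  keep <- logical(nrow(terms))
  for (i in seq_len(nrow(terms))) {
    prior <- which(keep & terms$sentence_index == terms$sentence_index[i])
    clash <- any(terms$start[prior] < terms$end[i] &
                   terms$end[prior] > terms$start[i])
    keep[i] <- !clash
  }
  terms[keep, ] %>%
    dplyr::select(-".len", -".prec") %>%
    dplyr::arrange(.data$sentence_index, .data$start)
}

#' Tag all six key-term classes
#'
#' Runs the drug, enzyme, PK-parameter, number, mechanism and change taggers
#' and merges their output. Overlaps are resolved by longest span first; on
#' equal length the precedence is DRUG > ENZYME > PK_PARAMETER > NUMBER >
#' MECHANISM > CHANGE. The result is sorted by offset and pairwise
#' non-overlapping.
#'
#' @inheritParams tag_pk_parameters
#' @param strict Use the strict printed enzyme pattern (see [tag_enzymes()]).
#' @return A key-term tibble with columns `sentence_index`, `start`, `end`,
#'   `text`, `category`, `normal_form`, `unit`, `value`.
#' @export
#' @examples
#' tag_terms("Ketoconazole significantly inhibited CYP3A4 (Ki 0.1 microM).")
tag_terms <- function(sentences, lexicon = pk_lexicon(), strict = FALSE) {
  all <- dplyr::bind_rows(
    tag_drugs(sentences, lexicon),
    tag_enzymes(sentences, strict = strict),
    tag_pk_parameters(sentences, lexicon),
    tag_numbers(sentences),
    tag_mechanisms(sentences),
    tag_changes(sentences)
  )
  resolve_overlaps(all)
}
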