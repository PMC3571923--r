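# Corpus XML serialization. The schema keeps the three-level structure
# (document -> sentence -> term/pair); offsets are 0-based half-open and
# local to the sentence. Version attribute guards future changes.

corpus_schema_version <- "1.0"

fmt_num <- function(x) {
  ifelse(is.na(x), NA_character_,
         vapply(x, function(v) format(v, digits = 15, scientific = FALSE),
                character(1)))
}

set_attr_if <- function(node, name, value) {
  if (!is.na(value)) xml2::xml_set_attr(node, name, as.character(value))
}

#' Write an annotated corpus to XML
#'
#' Lossless serialization of a [pk_corpus()]: `read_corpus_xml(write_corpus_xml(x))`
#' is structurally identical to `x`, including offsets, labels, pair
#' annotations and cross-sentence context references.
#'
#' @param corpus A `pk_corpus`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus_xml <- function(corpus, path) {
  root <- xml2::xml_new_root("pk_corpus", version = corpus_schema_version)
  for (d in seq_len(nrow(corpus$documents))) {
    drow <- corpus$documents[d, ]
    dnode <- xml2::xml_add_child(root, "document", pmid = drow$pmid,
                                 study_class = drow$study_class)
    tn <- xml2::xml_add_child(dnode, "title")
    xml2::xml_set_text(tn, drow$title)
    sents <- corpus$sentences %>% filter(.data$pmid == drow$pmid) %>%
      arrange(.data$sentence_index)
    for (s in seq_len(nrow(sents))) {
      srow <- sents[s, ]
      snode <- xml2::xml_add_child(dnode, "sentence",
                                   index = as.character(srow$sentence_index),
                                   ddi_label = srow$ddi_label)
      set_attr_if(snode, "context_entity", srow$context_entity)
      set_attr_if(snode, "context_sentence", srow$context_sentence)
      xn <- xml2::xml_add_child(snode, "text")
      xml2::xml_set_text(xn, srow$text)
      terms <- corpus$terms %>%
        filter(.data$pmid == drow$pmid,
               .data$sentence_index == srow$sentence_index) %>%
        arrange(.data$start)
      for (t in seq_len(nrow(terms))) {
        trow <- terms[t, ]
        tnode <- xml2::xml_add_child(snode, "term", id = trow$term_id,
                                     start = as.character(trow$start),
                                     end = as.character(trow$end),
                                     category = trow$category,
                                     normal_form = trow$normal_form)
        set_attr_if(tnode, "unit", trow$unit)
        set_attr_if(tnode, "value", fmt_num(trow$value))
        xml2::xml_set_text(tnode, trow$text)
      }
      pairs <- corpus$pairs %>%
        filter(.data$pmid == drow$pmid,
               .data$sentence_index == srow$sentence_index)
      for (p in seq_len(nrow(pairs))) {
        prow <- pairs[p, ]
        pnode <- xml2::xml_add_child(snode, "pair", id = prow$pair_id,
                                     entity_a = prow$entity_a,
                                     entity_b = prow$entity_b,
                                     relation = prow$relation,
                                     setting = prow$setting)
        set_attr_if(pnode, "evidence", prow$evidence)
      }
    }
  }
  xml2::write_xml(root, path)
  invisible(path)
}

xml_attr_or_na <- function(node, name, as = identity) {
  v <- xml2::xml_attr(node, name)
  as(v)
}

#' Read an annotated corpus from XML
#'
#' @param path Path to a file written by [write_corpus_xml()].
#' @return A `pk_corpus`. Schema violations (bad labels, overlapping or
#'   out-of-range spans) are rejected with an informative error.
#' @export
read_corpus_xml <- function(path) {
  doc <- xml2::read_xml(path)
  if (xml2::xml_name(doc) != "pk_corpus") {
    abort("not a pk_corpus file: root element must be <pk_corpus>")
  }
  docs <- list(); sents <- list(); terms <- list(); pairs <- list()
  for (dnode in xml2::xml_find_all(doc, "document")) {
    pmid <- xml2::xml_attr(dnode, "pmid")
    docs[[length(docs) + 1L]] <- tibble::tibble(
      pmid = pmid,
      title = xml2::xml_text(xml2::xml_find_first(dnode, "title")),
      study_class = xml2::xml_attr(dnode, "study_class"))
    for (snode in xml2::xml_find_all(dnode, "sentence")) {
      sidx <- as.integer(xml2::xml_attr(snode, "index"))
      sents[[length(sents) + 1L]] <- tibble::tibble(
        pmid = pmid, sentence_index = sidx,
        text = xml2::xml_text(xml2::xml_find_first(snode, "text")),
        ddi_label = xml2::xml_attr(snode, "ddi_label"),
        context_entity = xml_attr_or_na(snode, "context_entity"),
        context_sentence = as.integer(xml2::xml_attr(snode,
                                                     "context_sentence")))
      for (tnode in xml2::xml_find_all(snode, "term")) {
        terms[[length(terms) + 1L]] <- tibble::tibble(
          pmid = pmid, sentence_index = sidx,
          term_id = xml2::xml_attr(tnode, "id"),
          start = as.integer(xml2::xml_attr(tnode, "start")),
          end = as.integer(xml2::xml_attr(tnode, "end")),
          text = xml2::xml_text(tnode),
          category = xml2::xml_attr(tnode, "category"),
          normal_form = xml2::xml_attr(tnode, "normal_form"),
          unit = xml_attr_or_na(tnode, "unit"),
          value = as.numeric(xml2::xml_attr(tnode, "value")))
      }
      for (pnode in xml2::xml_find_all(snode, "pair")) {
        pairs[[length(pairs) + 1L]] <- tibble::tibble(
          pmid = pmid, sentence_index = sidx,
          pair_id = xml2::xml_attr(pnode, "id"),
          entity_a = xml2::xml_attr(pnode, "entity_a"),
          entity_b = xml2::xml_attr(pnode, "entity_b"),
          relation = xml2::xml_attr(pnode, "relation"),
          setting = xml2::xml_attr(pnode, "setting"),
          evidence = xml_attr_or_na(pnode, "evidence"))
      }
    }
  }
  pk_corpus(
    dplyr::bind_rows(docs),
    if (length(sents)) dplyr::bind_rows(sents) else empty_sentences(),
    if (length(terms)) dplyr::bind_rows(terms) else NULL,
    if (length(pairs)) dplyr::bind_rows(pairs) else NULL
  )
}

entity_categories <- c("DRUG", "ENZYME")

#' Convert a corpus to the unified relation-extraction XML
#'
#' Emits the flat document/sentence/entity/pair layout used by DDI
#' extraction systems: entities with character offsets and candidate pairs
#' with a binary `interaction` attribute. Entities are the pairable entities
#' after metabolite removal and synonym collapsing (see
#' [prepare_entities()]); only sentences with at least two entities emit
#' pairs, every candidate pair is emitted, and a pair is `interaction="true"`
#' only when an annotated relation collapses to true under `collapse`.
#'
#' @param corpus A `pk_corpus`.
#' @param path Output path.
#' @param collapse Function mapping a relation label to logical;
#'   default [collapse_labels()].
#' @return `path`, invisibly.
#' @export
to_unified_xml <- function(corpus, path, collapse = collapse_labels) {
  root <- xml2::xml_new_root("corpus", source = "pkddi")
  for (d in seq_len(nrow(corpus$documents))) {
    drow <- corpus$documents[d, ]
    did <- paste0("d", d - 1L)
    dnode <- xml2::xml_add_child(root, "document", id = did,
                                 origId = drow$pmid)
    sents <- corpus$sentences %>% filter(.data$pmid == drow$pmid) %>%
      arrange(.data$sentence_index)
    for (s in seq_len(nrow(sents))) {
      srow <- sents[s, ]
      sid <- paste0(did, ".s", srow$sentence_index)
      snode <- xml2::xml_add_child(dnode, "sentence", id = sid,
                                   text = srow$text)
      ents <- prepare_entities(
        corpus$terms %>% filter(.data$pmid == drow$pmid,
                                .data$sentence_index == srow$sentence_index))
      if (nrow(ents)) {
        ents$uid <- paste0(sid, ".e", seq_len(nrow(ents)) - 1L)
        for (e in seq_len(nrow(ents))) {
          xml2::xml_add_child(
            snode, "entity", id = ents$uid[e],
            charOffset = paste0(ents$start[e], "-", ents$end[e]),
            type = tolower(ents$category[e]), text = ents$text[e])
        }
      }
      if (nrow(ents) >= 2) {
        gold <- corpus$pairs %>%
          filter(.data$pmid == drow$pmid,
                 .data$sentence_index == srow$sentence_index)
        cmb <- utils::combn(seq_len(nrow(ents)), 2)
        for (k in seq_len(ncol(cmb))) {
          a <- cmb[1, k]; b <- cmb[2, k]
          ids <- sort(c(ents$term_id[a], ents$term_id[b]))
          hit <- gold %>% filter(
            pmin(.data$entity_a, .data$entity_b) == ids[1],
            pmax(.data$entity_a, .data$entity_b) == ids[2])
          interaction <- nrow(hit) > 0 && collapse(hit$relation[[1]])
          xml2::xml_add_child(
            snode, "pair", id = paste0(sid, ".p", k - 1L),
            e1 = ents$uid[a], e2 = ents$uid[b],
            interaction = tolower(as.character(interaction)))
        }
      }
    }
  }
  xml2::write_xml(root, path)
  invisible(path)
}

#' Corpus summary statistics
#'
#' Counts per key-term category, per sentence label and per relation label,
#' plus totals: words (both whitespace tokens and tokenizer tokens),
#' sentences and annotated pairs. Counts are additive over document
#' concatenation.
#'
#' @param corpus A `pk_corpus`.
#' @return A tibble with columns `group`, `category`, `n`.
#' @export
corpus_stats <- function(corpus) {
  term_counts <- tibble::tibble(
    group = "key_terms", category = term_categories,
    n = unname(vapply(term_categories,
               function(cc) sum(corpus$terms$category == cc), integer(1))))
  sent_counts <- tibble::tibble(
    group = "sentences", category = sentence_label_values,
    n = unname(vapply(sentence_label_values,
               function(l) sum(corpus$sentences$ddi_label == l),
               integer(1))))
  rel <- setdiff(relation_label_values, "NONE")
  pair_counts <- tibble::tibble(
    group = "pairs", category = rel,
    n = unname(vapply(rel, function(l) sum(corpus$pairs$relation == l),
                      integer(1))))
  totals <- tibble::tibble(
    group = "totals",
    category = c("words_whitespace", "words_tokenized", "sentences", "pairs"),
    n = c(sum(lengths(strsplit(corpus$sentences$text, "\\s+"))),
          nrow(pk_tokenize(corpus$sentences$text)),
          nrow(corpus$sentences), nrow(corpus$pairs)))
  dplyr::bind_rows(term_counts, sent_counts, pair_counts, totals)
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

term_css <- c(
  DRUG = "#1b9e77", METABOLITE = "#66c2a5", ENZYME = "#d95f02",
  PK_PARAMETER = "#7570b3", NUMBER = "#e7298a", MECHANISM = "#e6ab02",
  CHANGE = "#66a61e")

#' Render an annotated corpus as colored HTML
#'
#' One CSS class (and color) per key-term category; DDI sentences carry a
#' sentence-level highlight distinct from the term-level colors.
#'
#' @param corpus A `pk_corpus`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
render_corpus_html <- function(corpus, path) {
  css <- paste0(
    "body{font-family:sans-serif;max-width:60em;margin:2em auto}",
    ".sent-cddis{background:#fff3b0}.sent-vddis{background:#ffe0e0}",
    paste0(".term-", tolower(names(term_css)),
           "{color:", term_css, ";font-weight:bold}", collapse = ""))
  out <- c("<!DOCTYPE html>", "<html><head><meta charset=\"utf-8\"/>",
           paste0("<style>", css, "</style></head><body>"))
  for (d in seq_len(nrow(corpus$documents))) {
    drow <- corpus$documents[d, ]
    out <- c(out, paste0("<h2>PMID ", html_escape(drow$pmid), " &mdash; ",
                         html_escape(drow$title), "</h2>"))
    sents <- corpus$sentences %>% filter(.data$pmid == drow$pmid) %>%
      arrange(.data$sentence_index)
    for (s in seq_len(nrow(sents))) {
      srow <- sents[s, ]
      terms <- corpus$terms %>%
        filter(.data$pmid == drow$pmid,
               .data$sentence_index == srow$sentence_index) %>%
        arrange(.data$start)
      text <- srow$text
      pieces <- character(); pos <- 0L
      for (t in seq_len(nrow(terms))) {
        trow <- terms[t, ]
        pieces <- c(pieces,
                    html_escape(substring(text, pos + 1L, trow$start)),
                    paste0("<span class=\"term-", tolower(trow$category),
                           "\">", html_escape(trow$text), "</span>"))
        pos <- trow$end
      }
      pieces <- c(pieces, html_escape(substring(text, pos + 1L, nchar(text))))
      cls <- switch(srow$ddi_label, CDDIS = " class=\"sent-cddis\"",
                    VDDIS = " class=\"sent-vddis\"", "")
      out <- c(out, paste0("<p", cls, ">", paste(pieces, collapse = ""),
                           "</p>"))
    }
  }
  out <- c(out, "</body></html>")
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

#' @export
autoplot.pk_corpus <- function(object, ...) {
  df <- corpus_stats(object) %>% filter(.data$group == "key_terms")
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$category,
                                                      .data$n),
                                   y = .data$n)) +
    ggplot2::geom_col(fill = "#7570b3") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "mentions",
                  title = "Key-term frequencies")
}
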