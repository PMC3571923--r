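# The three-level annotated corpus: documents -> sentences -> key terms and
# DDI pair annotations, held as a relational bundle of tibbles.

relation_label_values <- c("DDI", "ADDI", "NDDI", "DEI", "ADEI", "NDEI", "NONE")
sentence_label_values <- c("NONE", "CDDIS", "VDDIS")
study_class_values <- c("in_vivo_pk", "in_vivo_pg", "in_vivo_ddi",
                        "in_vitro_ddi")

#' Relation label sets
#'
#' The in vivo annotation scheme has three pair labels (DDI, ADDI, NDDI); the
#' in vitro scheme adds the drug-enzyme triple (DEI, ADEI, NDEI) for six.
#'
#' @param setting `"in_vivo"` or `"in_vitro"`.
#' @return Character vector of relation labels (excluding `"NONE"`).
#' @export
ddi_label_set <- function(setting = c("in_vivo", "in_vitro")) {
  setting <- match.arg(setting)
  if (setting == "in_vivo") c("DDI", "ADDI", "NDDI")
  else c("DDI", "ADDI", "NDDI", "DEI", "ADEI", "NDEI")
}

empty_sentences <- function() {
  tibble::tibble(pmid = character(), sentence_index = integer(),
                 text = character(), ddi_label = character(),
                 context_entity = character(), context_sentence = integer())
}

empty_pairs <- function() {
  tibble::tibble(pmid = character(), sentence_index = integer(),
                 pair_id = character(), entity_a = character(),
                 entity_b = character(), relation = character(),
                 setting = character(), evidence = character())
}

#' Construct an annotated PK/DDI corpus
#'
#' @param documents Tibble with columns `pmid`, `title`, `study_class`.
#' @param sentences Tibble with `pmid`, `sentence_index` (0-based,
#'   consecutive per document), `text`, `ddi_label` (NONE/CDDIS/VDDIS),
#'   `context_entity`, `context_sentence` (cross-sentence partner for VDDIS).
#' @param terms Key-term tibble (see [tag_terms()]) plus `pmid` and `term_id`.
#' @param pairs Pair-annotation tibble: `pmid`, `sentence_index`, `pair_id`,
#'   `entity_a`/`entity_b` (term ids, or `ctx:<name>:<sentence>` context
#'   references), `relation`, `setting`, `evidence` (space-separated term
#'   ids or `NA`).
#' @return A `pk_corpus` object.
#' @export
pk_corpus <- function(documents, sentences, terms = NULL, pairs = NULL) {
  if (is.null(terms)) {
    terms <- dplyr::mutate(empty_terms(), pmid = character(),
                           term_id = character())
  }
  if (is.null(pairs)) pairs <- empty_pairs()
  documents <- dplyr::select(as_tibble(documents), "pmid", "title",
                             "study_class")
  sentences <- dplyr::select(as_tibble(sentences), "pmid", "sentence_index",
                             "text", "ddi_label", "context_entity",
                             "context_sentence")
  terms <- dplyr::select(as_tibble(terms), "pmid", "sentence_index",
                         "term_id", "start", "end", "text", "category",
                         "normal_form", "unit", "value")
  pairs <- dplyr::select(as_tibble(pairs), "pmid", "sentence_index",
                         "pair_id", "entity_a", "entity_b", "relation",
                         "setting", "evidence")
  x <- structure(
    list(documents = documents, sentences = sentences, terms = terms,
         pairs = pairs),
    class = "pk_corpus"
  )
  validate_pk_corpus(x)
}

validate_pk_corpus <- function(x) {
  stopifnot(all(nzchar(x$documents$pmid)))
  if (anyDuplicated(x$documents$pmid)) abort("duplicate pmid in corpus")
  bad <- setdiff(x$documents$study_class, study_class_values)
  if (length(bad)) abort(paste0("unknown study_class: ", bad[[1]]))
  # sentence indices consecutive from 0
  chk <- x$sentences %>% group_by(.data$pmid) %>%
    summarise(ok = all(sort(.data$sentence_index) ==
                         seq_len(dplyr::n()) - 1L), .groups = "drop")
  if (!all(chk$ok)) {
    abort(paste0("non-consecutive sentence indices in document ",
                 chk$pmid[!chk$ok][[1]]))
  }
  bad <- setdiff(x$sentences$ddi_label, sentence_label_values)
  if (length(bad)) abort(paste0("unknown sentence label: ", bad[[1]]))
  bad <- setdiff(x$pairs$relation, relation_label_values)
  if (length(bad)) abort(paste0("unknown relation label: ", bad[[1]]))
  # span invariants and non-overlap
  if (nrow(x$terms)) {
    tt <- dplyr::left_join(
      x$terms,
      dplyr::select(x$sentences, "pmid", "sentence_index", "text"),
      by = c("pmid", "sentence_index"), suffix = c("", ".sent"))
    ok <- tt$start >= 0 & tt$start < tt$end &
      tt$end <= nchar(tt$text.sent) &
      tt$text == substring(tt$text.sent, tt$start + 1L, tt$end)
    if (!all(ok)) abort("term span does not match sentence substring")
    ov <- x$terms %>% group_by(.data$pmid, .data$sentence_index) %>%
      arrange(.data$start, .by_group = TRUE) %>%
      summarise(ov = dplyr::n() > 1 &&
                  any(.data$start[-1] < .data$end[-dplyr::n()]),
                .groups = "drop")
    if (any(ov$ov)) abort("overlapping term spans")
    if (anyDuplicated(paste(x$terms$pmid, x$terms$sentence_index,
                            x$terms$term_id))) {
      abort("duplicate term ids within a sentence")
    }
  }
  # pairs only on labeled sentences
  if (nrow(x$pairs)) {
    lab <- dplyr::left_join(
      x$pairs, dplyr::select(x$sentences, "pmid", "sentence_index",
                             "ddi_label"),
      by = c("pmid", "sentence_index"))
    if (any(is.na(lab$ddi_label)) || any(lab$ddi_label == "NONE")) {
      abort("pair annotation on an unlabeled sentence")
    }
  }
  x
}

#' @export
print.pk_corpus <- function(x, ...) {
  cat("<pk_corpus> ", nrow(x$documents), " documents, ",
      nrow(x$sentences), " sentences, ", nrow(x$terms), " key terms, ",
      nrow(x$pairs), " annotated pairs\n", sep = "")
  invisible(x)
}

#' Combine corpora
#' @param ... `pk_corpus` objects.
#' @return A single `pk_corpus`.
#' @export
c.pk_corpus <- function(...) {
  xs <- list(...)
  pk_corpus(
    dplyr::bind_rows(purrr::map(xs, "documents")),
    dplyr::bind_rows(purrr::map(xs, "sentences")),
    dplyr::bind_rows(purrr::map(xs, "terms")),
    dplyr::bind_rows(purrr::map(xs, "pairs"))
  )
}

sentence_abbreviations <- c(
  "vs.", "e.g.", "i.e.", "i.p.", "i.v.", "p.o.", "b.i.d.", "t.i.d.", "Dr.",
  "Drs.", "Mr.", "Mrs.", "Prof.", "Fig.", "al.", "etc.", "approx.", "ca.",
  "cf.", "no.", "St.", "wk.", "hr.", "min.", "sec.", "resp.")

#' Split text into sentences
#'
#' Deterministic split on sentence-final punctuation followed by whitespace
#' and an upper-case/digit sentence opener, with an abbreviation guard list
#' (vs., e.g., i.p., Dr., St., ...). Decimal points never split. The
#' concatenation of the returned sentences, joined by single spaces, equals
#' the whitespace-normalized input.
#'
#' @param text A single character string.
#' @return Character vector of sentences.
#' @export
#' @examples
#' split_sentences("Cmax was 9.0 ng/mL (P<0.05) vs. control. AUC rose 1.5 fold.")
split_sentences <- function(text) {
  stopifnot(length(text) == 1)
  text <- stringr::str_squish(text)
  if (!nzchar(text)) return(character())
  locs <- stringr::str_locate_all(
    text, "(?<=[.!?])[\"')\\]]?\\s+(?=[\"'(\\[]?[A-Z0-9])")[[1]]
  if (nrow(locs)) {
    ok <- purrr::map_lgl(locs[, 1], function(pos) {
      before <- substring(text, max(1, pos - 12L), pos - 1L)
      last <- stringr::str_extract(before, "[A-Za-z.]+\\.$")
      if (is.na(last)) return(TRUE)
      !(tolower(last) %in% tolower(sentence_abbreviations))
    })
    locs <- locs[ok, , drop = FALSE]
  }
  if (!nrow(locs)) return(text)
  closer <- grepl("^[\"')\\]]", substring(text, locs[, 1], locs[, 1]))
  starts <- c(1L, locs[, 2] + 1L)
  ends <- c(locs[, 1] - 1L + ifelse(closer, 1L, 0L), nchar(text))
  trimws(substring(text, starts, ends))
}

#' Read PubMed abstracts from XML
#'
#' Reads a `PubmedArticleSet` file; each article's title and abstract are
#' concatenated and split into sentences. Records without an abstract are
#' skipped with a warning.
#'
#' @param path Path to a PubMed XML file.
#' @param study_class Study class assigned to all documents.
#' @return An unannotated `pk_corpus`.
#' @export
read_pubmed_xml <- function(path, study_class = "in_vivo_ddi") {
  doc <- xml2::read_xml(path)
  arts <- xml2::xml_find_all(doc, "//PubmedArticle")
  docs <- list(); sents <- list()
  for (a in arts) {
    pmid <- xml2::xml_text(xml2::xml_find_first(a, ".//PMID"))
    title <- xml2::xml_text(xml2::xml_find_first(a, ".//ArticleTitle"))
    abst <- xml2::xml_find_all(a, ".//Abstract/AbstractText")
    if (!length(abst)) {
      warn(paste0("record ", pmid, " has no abstract; skipped"))
      next
    }
    text <- paste(c(title, xml2::xml_text(abst)), collapse = " ")
    ss <- split_sentences(text)
    docs[[length(docs) + 1L]] <- tibble::tibble(
      pmid = pmid, title = title, study_class = study_class)
    sents[[length(sents) + 1L]] <- tibble::tibble(
      pmid = pmid, sentence_index = seq_along(ss) - 1L, text = ss,
      ddi_label = "NONE", context_entity = NA_character_,
      context_sentence = NA_integer_)
  }
  pk_corpus(dplyr::bind_rows(docs), dplyr::bind_rows(sents))
}
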