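test_that("sentence splitting respects decimals and abbreviation guards", {
  expect_equal(split_sentences("A is B. C is D."),
               c("A is B.", "C is D."))
  expect_equal(
    split_sentences("The dose (0.05 mg/kg) was given. Next day it rose."),
    c("The dose (0.05 mg/kg) was given.", "Next day it rose."))
  expect_equal(
    split_sentences("Cmax was 9.0 ng/mL (P<0.05) vs. Control values."),
    "Cmax was 9.0 ng/mL (P<0.05) vs. Control values.")
  expect_equal(split_sentences(""), character())
  # reconstruction: joining with single spaces recovers the squished input
  txt <- paste("Verapamil increased AUC 2.1 fold (P<0.01). The Cmax was",
               "unchanged. No effect on CYP2D6 was seen.")
  expect_equal(paste(split_sentences(txt), collapse = " "),
               stringr::str_squish(txt))
})

test_that("PubMed XML reading yields one document per abstract", {
  f <- system.file("extdata", "pubmed_sample.xml", package = "pkddi")
  expect_warning(corp <- read_pubmed_xml(f), "no abstract")
  expect_equal(nrow(corp$documents), 1)
  expect_equal(corp$documents$pmid, "90000001")
  # title + three abstract sentences
  expect_equal(nrow(corp$sentences), 4)
  expect_equal(corp$sentences$sentence_index, 0:3)
})

test_that("corpus XML round trip is lossless including VDDIS context pairs", {
  synth <- simulate_corpus(12, seed = 22)
  corp <- synth$corpus
  expect_true(any(corp$sentences$ddi_label == "VDDIS"))
  f <- withr::local_tempfile(fileext = ".xml")
  write_corpus_xml(corp, f)
  back <- read_corpus_xml(f)
  for (part in c("documents", "sentences", "terms", "pairs")) {
    expect_equal(as.data.frame(back[[part]]), as.data.frame(corp[[part]]),
                 label = part)
  }
})

test_that("corpus construction enforces the span and label invariants", {
  docs <- tibble::tibble(pmid = "X1", title = "t", study_class = "in_vivo_ddi")
  sents <- tibble::tibble(pmid = "X1", sentence_index = 0L,
                          text = "verapamil inhibits CYP3A4",
                          ddi_label = "NONE",
                          context_entity = NA_character_,
                          context_sentence = NA_integer_)
  term <- function(id, s, e, txt, cat) {
    tibble::tibble(pmid = "X1", sentence_index = 0L, term_id = id,
                   start = s, end = e, text = txt, category = cat,
                   normal_form = tolower(txt), unit = NA_character_,
                   value = NA_real_)
  }
  expect_s3_class(pk_corpus(docs, sents,
                            term("t0", 0L, 9L, "verapamil", "DRUG")),
                  "pk_corpus")
  # overlapping spans rejected
  expect_error(
    pk_corpus(docs, sents, dplyr::bind_rows(
      term("t0", 0L, 9L, "verapamil", "DRUG"),
      term("t1", 5L, 14L, "amil inhi", "DRUG"))),
    "overlapping")
  # span text must match the sentence substring
  expect_error(
    pk_corpus(docs, sents, term("t0", 0L, 9L, "verapamXX", "DRUG")),
    "substring")
  # pair on an unlabeled sentence rejected
  expect_error(
    pk_corpus(docs, sents, term("t0", 0L, 9L, "verapamil", "DRUG"),
              tibble::tibble(pmid = "X1", sentence_index = 0L,
                             pair_id = "p0", entity_a = "t0",
                             entity_b = "t1", relation = "DDI",
                             setting = "in_vivo",
                             evidence = NA_character_)),
    "unlabeled")
})

test_that("a hand-written minimal corpus file parses to the expected objects", {
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<pk_corpus version="1.0">',
    ' <document pmid="11111111" study_class="in_vivo_ddi">',
    '  <title>Minimal</title>',
    '  <sentence index="0" ddi_label="CDDIS">',
    '   <text>verapamil significantly altered lovastatin</text>',
    '   <term id="t0" start="0" end="9" category="DRUG" normal_form="verapamil">verapamil</term>',
    '   <term id="t1" start="10" end="23" category="CHANGE" normal_form="significant">significantly</term>',
    '   <term id="t2" start="32" end="42" category="DRUG" normal_form="lovastatin">lovastatin</term>',
    '   <pair id="p0" entity_a="t0" entity_b="t2" relation="DDI" setting="in_vivo"/>',
    '  </sentence>',
    ' </document>',
    '</pk_corpus>'), f)
  corp <- read_corpus_xml(f)
  expect_equal(corp$documents$pmid, "11111111")
  expect_equal(corp$sentences$ddi_label, "CDDIS")
  expect_equal(corp$terms$term_id, c("t0", "t1", "t2"))
  expect_equal(corp$pairs$relation, "DDI")
  expect_equal(corp$pairs$entity_a, "t0")
})

test_that("unified XML emits all candidate pairs with collapsed labels", {
  docs <- tibble::tibble(pmid = c("U1", "U2", "U3"), title = "t",
                         study_class = "in_vivo_ddi")
  sents <- tibble::tibble(
    pmid = c("U1", "U2", "U3"), sentence_index = 0L,
    text = c("verapamil significantly altered lovastatin",
             "verapamil was measured",
             "verapamil caffeine warfarin were given"),
    ddi_label = c("CDDIS", "NONE", "NONE"),
    context_entity = NA_character_, context_sentence = NA_integer_)
  term <- function(pmid, id, s, e, txt) {
    tibble::tibble(pmid = pmid, sentence_index = 0L, term_id = id,
                   start = s, end = e, text = txt, category = "DRUG",
                   normal_form = txt, unit = NA_character_,
                   value = NA_real_)
  }
  terms <- dplyr::bind_rows(
    term("U1", "t0", 0L, 9L, "verapamil"),
    term("U1", "t1", 32L, 42L, "lovastatin"),
    term("U2", "t0", 0L, 9L, "verapamil"),
    term("U3", "t0", 0L, 9L, "verapamil"),
    term("U3", "t1", 10L, 18L, "caffeine"),
    term("U3", "t2", 19L, 27L, "warfarin"))
  pairs <- tibble::tibble(pmid = "U1", sentence_index = 0L, pair_id = "p0",
                          entity_a = "t0", entity_b = "t1",
                          relation = "DDI", setting = "in_vivo",
                          evidence = NA_character_)
  corp <- pk_corpus(docs, sents, terms, pairs)
  f <- withr::local_tempfile(fileext = ".xml")
  to_unified_xml(corp, f)
  x <- xml2::read_xml(f)
  # annotated 2-drug sentence: one pair, interaction true
  s1 <- xml2::xml_find_all(x, "//document[@origId='U1']//pair")
  expect_equal(length(s1), 1)
  expect_equal(xml2::xml_attr(s1, "interaction"), "true")
  # single drug: no pairs
  expect_equal(length(xml2::xml_find_all(x, "//document[@origId='U2']//pair")),
               0)
  # three drugs, no annotations: three pairs, all false
  s3 <- xml2::xml_find_all(x, "//document[@origId='U3']//pair")
  expect_equal(length(s3), 3)
  expect_equal(unique(xml2::xml_attr(s3, "interaction")), "false")
})

test_that("corpus statistics count terms by category and are additive", {
  s1 <- simulate_corpus(4, seed = 31)$corpus
  s2 <- simulate_corpus(3, seed = 32)$corpus
  s2$documents$pmid <- sub("SYN", "ALT", s2$documents$pmid)
  s2$sentences$pmid <- sub("SYN", "ALT", s2$sentences$pmid)
  s2$terms$pmid <- sub("SYN", "ALT", s2$terms$pmid)
  s2$pairs$pmid <- sub("SYN", "ALT", s2$pairs$pmid)
  st1 <- corpus_stats(s1); st2 <- corpus_stats(s2)
  both <- corpus_stats(c(s1, s2))
  expect_equal(both$n, st1$n + st2$n)
  expect_equal(sum(st1$n[st1$group == "key_terms"]), nrow(s1$terms))
  drugs <- st1$n[st1$group == "key_terms" & st1$category == "DRUG"]
  expect_equal(drugs, sum(s1$terms$category == "DRUG"))
})

test_that("HTML rendering emits one style class per category present", {
  corp <- simulate_corpus(6, seed = 41)$corpus
  f <- withr::local_tempfile(fileext = ".html")
  render_corpus_html(corp, f)
  html <- paste(readLines(f), collapse = "\n")
  for (cat in unique(corp$terms$category)) {
    expect_true(grepl(paste0("term-", tolower(cat)), html), label = cat)
  }
  # DDI sentence highlight is distinct from term-level markup
  expect_true(grepl("sent-cddis", html))
  # empty corpus still renders a valid page
  f2 <- withr::local_tempfile(fileext = ".html")
  empty <- pk_corpus(
    tibble::tibble(pmid = "E1", title = "t", study_class = "in_vivo_pk"),
    tibble::tibble(pmid = "E1", sentence_index = 0L, text = "Nothing here.",
                   ddi_label = "NONE", context_entity = NA_character_,
                   context_sentence = NA_integer_))
  render_corpus_html(empty, f2)
  expect_true(grepl("</html>", paste(readLines(f2), collapse = "")))
})
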