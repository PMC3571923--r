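# Inter-annotator reliability: nominal Krippendorff's alpha via the
# coincidence-matrix formulation, plus extraction of the three unit sets
# (token, sentence, pair) from parallel annotated corpora.

#' Krippendorff's alpha for nominal annotations
#'
#' Chance-corrected agreement for any number of annotators with missing
#' data. Units carrying fewer than two labels are excluded from the pairable
#' set. Alpha is 1 - Do/De with Do and De the observed and expected
#' disagreement from the coincidence matrix.
#'
#' @param units A tibble with columns `unit_id`, `annotator_id`, `label`
#'   (rows with missing labels are dropped).
#' @param degenerate What to do when the expected disagreement is zero
#'   (every pairable value shares one label): `"one"` defines alpha = 1,
#'   `"error"` raises.
#' @return An object of class `krippendorff`: a list with `alpha`,
#'   `observed_disagreement`, `expected_disagreement`, `n_pairable` (number
#'   of pairable values) and `n_units`.
#' @export
#' @examples
#' u <- tibble::tibble(unit_id = rep(1:4, each = 2),
#'                     annotator_id = rep(c("a", "b"), 4),
#'                     label = c("A", "A", "A", "B", "B", "A", "B", "B"))
#' krippendorff_alpha(u)
krippendorff_alpha <- function(units, degenerate = c("one", "error")) {
  degenerate <- match.arg(degenerate)
  units <- as_tibble(units) %>% filter(!is.na(.data$label))
  if (anyDuplicated(paste(units$unit_id, units$annotator_id))) {
    abort("duplicate (unit_id, annotator_id) rows")
  }
  counts <- units %>% count(.data$unit_id, .data$label)
  m_u <- counts %>% group_by(.data$unit_id) %>%
    summarise(m = sum(.data$n), .groups = "drop")
  pairable <- m_u$unit_id[m_u$m >= 2]
  if (!length(pairable)) abort("insufficient overlap: no pairable units")
  counts <- counts %>% filter(.data$unit_id %in% pairable)
  labels <- sort(unique(counts$label))
  k <- length(labels)
  o <- matrix(0, k, k, dimnames = list(labels, labels))
  for (u in pairable) {
    cu <- counts[counts$unit_id == u, ]
    nvec <- setNames(numeric(k), labels)
    nvec[cu$label] <- cu$n
    m <- sum(nvec)
    o <- o + (outer(nvec, nvec) - diag(nvec, k)) / (m - 1)
  }
  n_c <- rowSums(o)
  n <- sum(n_c)
  d_obs <- sum(o) - sum(diag(o))
  d_exp_num <- sum(outer(n_c, n_c)) - sum(n_c^2)
  if (d_exp_num <= 0) {
    if (degenerate == "error") abort("expected disagreement is zero")
    alpha <- 1
    d_o <- 0; d_e <- 0
  } else {
    d_o <- d_obs / n
    d_e <- d_exp_num / (n * (n - 1))
    alpha <- 1 - d_o / d_e
  }
  structure(
    list(alpha = alpha, observed_disagreement = d_o,
         expected_disagreement = d_e, n_pairable = n,
         n_units = length(pairable), labels = labels),
    class = "krippendorff")
}

#' @export
print.krippendorff <- function(x, ...) {
  cat("Krippendorff's alpha (nominal): ", format(x$alpha, digits = 4),
      "\n  pairable values: ", x$n_pairable, " in ", x$n_units, " units, ",
      length(x$labels), " categories\n", sep = "")
  invisible(x)
}

#' @export
tidy.krippendorff <- function(x, ...) {
  tibble::tibble(alpha = x$alpha,
                 observed_disagreement = x$observed_disagreement,
                 expected_disagreement = x$expected_disagreement,
                 n_pairable = x$n_pairable, n_units = x$n_units)
}

#' @export
glance.krippendorff <- function(x, ...) tidy(x)

# Candidate entity pairs of a sentence, identified by canonical names.
sentence_entity_pairs <- function(terms) {
  ents <- prepare_entities(terms)
  if (nrow(ents) < 2) return(character())
  cmb <- utils::combn(sort(unique(ents$normal_form)), 2)
  paste(cmb[1, ], cmb[2, ], sep = "~")
}

#' Build agreement units from parallel annotated corpora
#'
#' Converts two or more annotator versions of the same corpus into the three
#' unit sets of the hierarchical scheme: one unit per token (label = key-term
#' category or `"O"`), one per sentence (NONE/CDDIS/VDDIS) and one per
#' candidate entity pair in any sentence some annotator marked as a DDI
#' sentence (annotators without a matching pair annotation contribute
#' `"NONE"`).
#'
#' @param corpora A named list of `pk_corpus` objects, one per annotator.
#'   All corpora must tokenize identically (same documents and sentence
#'   texts).
#' @return A list of three unit tibbles: `term`, `sentence`, `pair`.
#' @export
agreement_units <- function(corpora) {
  if (length(corpora) < 2) abort("need at least two annotators")
  if (is.null(names(corpora)) || any(!nzchar(names(corpora)))) {
    names(corpora) <- paste0("annotator", seq_along(corpora))
  }
  ref <- corpora[[1]]
  for (i in seq_along(corpora)[-1]) {
    a <- corpora[[i]]$sentences %>%
      dplyr::semi_join(ref$sentences, by = c("pmid", "sentence_index"))
    b <- ref$sentences %>%
      dplyr::semi_join(a, by = c("pmid", "sentence_index"))
    cmp <- dplyr::left_join(
      a, dplyr::select(b, "pmid", "sentence_index", ref_text = "text"),
      by = c("pmid", "sentence_index"))
    bad <- cmp$text != cmp$ref_text
    if (any(bad)) {
      abort(paste0("tokenization mismatch between annotators at ",
                   cmp$pmid[bad][1], " sentence ",
                   cmp$sentence_index[bad][1]))
    }
  }
  term_units <- purrr::imap_dfr(corpora, function(corp, ann) {
    toks <- corp$sentences %>%
      dplyr::group_split(.data$pmid) %>%
      purrr::map_dfr(function(sd) {
        pk_tokenize(sd$text[order(sd$sentence_index)]) %>%
          mutate(pmid = sd$pmid[[1]])
      })
    toks$label <- "O"
    if (nrow(corp$terms)) {
      for (j in seq_len(nrow(toks))) {
        hit <- corp$terms$pmid == toks$pmid[j] &
          corp$terms$sentence_index == toks$sentence_index[j] &
          corp$terms$start <= toks$start[j] & corp$terms$end >= toks$end[j]
        if (any(hit)) toks$label[j] <- corp$terms$category[which(hit)[1]]
      }
    }
    tibble::tibble(
      unit_id = paste0(toks$pmid, ":", toks$sentence_index, ":", toks$start),
      annotator_id = ann, label = toks$label)
  })
  sentence_units <- purrr::imap_dfr(corpora, function(corp, ann) {
    tibble::tibble(
      unit_id = paste0(corp$sentences$pmid, ":",
                       corp$sentences$sentence_index),
      annotator_id = ann, label = corp$sentences$ddi_label)
  })
  # pair universe: sentences any annotator marked CDDIS/VDDIS
  marked <- purrr::map_dfr(corpora, function(corp) {
    corp$sentences %>% filter(.data$ddi_label != "NONE") %>%
      dplyr::select("pmid", "sentence_index")
  }) %>% dplyr::distinct()
  pair_units <- purrr::imap_dfr(corpora, function(corp, ann) {
    purrr::pmap_dfr(marked, function(pmid, sentence_index) {
      terms <- corp$terms %>%
        filter(.data$pmid == .env$pmid,
               .data$sentence_index == .env$sentence_index)
      keys <- sentence_entity_pairs(terms)
      if (!length(keys)) return(NULL)
      anns <- corp$pairs %>%
        filter(.data$pmid == .env$pmid,
               .data$sentence_index == .env$sentence_index)
      lab <- setNames(rep("NONE", length(keys)), keys)
      if (nrow(anns)) {
        canon <- function(id) {
          t <- terms[match(id, terms$term_id), ]
          ifelse(is.na(t$normal_form), sub("^ctx:([^:]+):.*$", "\\1", id),
                 t$normal_form)
        }
        akey <- purrr::map2_chr(anns$entity_a, anns$entity_b, function(a, b) {
          nm <- sort(c(canon(a), canon(b)))
          paste(nm, collapse = "~")
        })
        ok <- akey %in% keys
        lab[akey[ok]] <- anns$relation[ok]
      }
      tibble::tibble(
        unit_id = paste0(pmid, ":", sentence_index, ":", keys),
        annotator_id = ann, label = unname(lab))
    })
  })
  list(term = term_units, sentence = sentence_units, pair = pair_units)
}

#' Three-level agreement summary
#'
#' @inheritParams agreement_units
#' @param degenerate Passed to [krippendorff_alpha()].
#' @return A tibble with one row per annotation level (term, sentence, pair)
#'   and the corresponding alpha.
#' @export
corpus_agreement <- function(corpora, degenerate = "one") {
  units <- agreement_units(corpora)
  purrr::imap_dfr(units, function(u, level) {
    r <- krippendorff_alpha(u, degenerate = degenerate)
    mutate(tidy(r), level = level, .before = 1)
  })
}
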