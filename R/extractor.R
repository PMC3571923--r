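# Sentence-level DDI extraction: candidate-pair generation over clear DDI
# sentences, label collapsing to a binary task, graph construction per
# candidate, and a maximum-margin classifier over the precomputed all-paths
# kernel matrix with precision/recall/F evaluation.

#' Prepare pairable entities of a sentence
#'
#' Metabolite mentions are dropped (parent drugs and their metabolites
#' rarely interact), enzyme mentions are kept as pairable entities (drug-
#' enzyme interactions are first-class), and repeated synonymous mentions of
#' one canonical entity collapse to the first mention.
#'
#' @param terms Key-term tibble of one sentence (needs `category`,
#'   `normal_form`, `start`; a `term_id` column is added if absent).
#' @return Tibble of pairable entity rows, one per canonical entity, in
#'   order of first mention.
#' @export
#' @examples
#' prepare_entities(tag_terms("Norverapamil and verapamil alter lovastatin."))
prepare_entities <- function(terms) {
  terms <- as_tibble(terms)
  if (!nrow(terms)) {
    terms$term_id <- character()
    return(terms[terms$category %in% entity_categories, , drop = FALSE])
  }
  if (!"term_id" %in% names(terms)) {
    terms <- terms %>% group_by(.data$sentence_index) %>%
      mutate(term_id = paste0("t", dplyr::row_number() - 1L)) %>% ungroup()
  }
  terms %>%
    filter(.data$category %in% entity_categories) %>%
    arrange(.data$start) %>%
    dplyr::distinct(.data$normal_form, .keep_all = TRUE)
}

#' Generate candidate pairs
#'
#' All unordered pairs of pairable entities: exactly n(n-1)/2 pairs, each
#' with default gold label `FALSE`. Sentences with fewer than two entities
#' yield no candidates.
#'
#' @param entities Entity tibble from [prepare_entities()].
#' @return Tibble with columns `entity_a`, `entity_b` (term ids), `a_name`,
#'   `b_name`, `gold`.
#' @export
generate_candidates <- function(entities) {
  n <- nrow(entities)
  if (n < 2) {
    return(tibble::tibble(entity_a = character(), entity_b = character(),
                          a_name = character(), b_name = character(),
                          gold = logical()))
  }
  cmb <- utils::combn(n, 2)
  tibble::tibble(
    entity_a = entities$term_id[cmb[1, ]],
    entity_b = entities$term_id[cmb[2, ]],
    a_name = entities$normal_form[cmb[1, ]],
    b_name = entities$normal_form[cmb[2, ]],
    gold = FALSE)
}

#' Collapse a relation label to the binary extraction target
#'
#' Only definite interactions (DDI, DEI) are true; ambiguous and negative
#' labels and NONE are all false. Total and idempotent over the label set.
#'
#' @param relation Character vector of relation labels.
#' @return Logical vector.
#' @export
collapse_labels <- function(relation) {
  relation %in% c("DDI", "DEI")
}

# Token span alignment: index of the parse token covering a term's start.
term_token_index <- function(term_start, token_starts, token_ends) {
  hit <- which(token_starts <= term_start & token_ends > term_start)
  if (length(hit)) hit[[1]] else NA_integer_
}

#' Build classification instances from an annotated corpus
#'
#' For every clear DDI sentence (CDDIS), forms all candidate entity pairs,
#' assigns the binary gold label by collapsing the annotated relation of a
#' matching pair (default no interaction), and builds the combined
#' dependency/PoS graph for each candidate. Parses are taken from `parses`
#' (named `pmid:sentence_index`) or built with the [chain_parse()] fallback.
#'
#' @param corpus A `pk_corpus`.
#' @param parses Optional named list of parse tibbles.
#' @param weights Graph edge weights, see [build_graph()].
#' @param collapse Label-collapsing function.
#' @return A tibble with one row per candidate: `pmid`, `sentence_index`,
#'   `entity_a`, `entity_b`, `gold` and a `graph` list column.
#' @export
ddi_instances <- function(corpus, parses = NULL,
                          weights = default_graph_weights(),
                          collapse = collapse_labels) {
  sents <- corpus$sentences %>% filter(.data$ddi_label == "CDDIS")
  purrr::pmap_dfr(
    dplyr::select(sents, "pmid", "sentence_index", "text"),
    function(pmid, sentence_index, text) {
      terms <- corpus$terms %>%
        filter(.data$pmid == .env$pmid,
               .data$sentence_index == .env$sentence_index)
      ents <- prepare_entities(terms)
      cand <- generate_candidates(ents)
      if (!nrow(cand)) return(NULL)
      gold <- corpus$pairs %>%
        filter(.data$pmid == .env$pmid,
               .data$sentence_index == .env$sentence_index)
      if (nrow(gold)) {
        gkey <- paste(pmin(gold$entity_a, gold$entity_b),
                      pmax(gold$entity_a, gold$entity_b))
        ckey <- paste(pmin(cand$entity_a, cand$entity_b),
                      pmax(cand$entity_a, cand$entity_b))
        hit <- match(ckey, gkey)
        cand$gold <- !is.na(hit) & collapse(gold$relation[ifelse(
          is.na(hit), 1L, hit)])
      }
      key <- paste0(pmid, ":", sentence_index)
      parse <- if (!is.null(parses) && key %in% names(parses)) {
        parses[[key]]
      } else {
        chain_parse(pk_tokenize(text)$token)
      }
      toks <- pk_tokenize(text)
      if (nrow(parse) != nrow(toks)) {
        abort(paste0("parse misaligned with sentence tokens at ", key))
      }
      tok_of <- function(id) {
        term_token_index(ents$start[match(id, ents$term_id)],
                         toks$start, toks$end)
      }
      all_tok <- vapply(ents$term_id, tok_of, integer(1))
      cand$graph <- purrr::map2(cand$entity_a, cand$entity_b, function(a, b) {
        ia <- tok_of(a); ib <- tok_of(b)
        build_graph(parse, c(ia, ib),
                    setdiff(all_tok[!is.na(all_tok)], c(ia, ib)),
                    weights = weights)
      })
      mutate(cand, pmid = pmid, sentence_index = sentence_index,
             .before = 1)
    })
}

eval_report <- function(gold, pred) {
  tp <- sum(gold & pred); fp <- sum(!gold & pred)
  fn <- sum(gold & !pred); tn <- sum(!gold & !pred)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  structure(
    list(tp = tp, fp = fp, fn = fn, tn = tn, precision = precision,
         recall = recall, f_measure = f, n = length(gold),
         prevalence = mean(gold)),
    class = "ddi_eval")
}

#' @export
print.ddi_eval <- function(x, ...) {
  cat("DDI extraction: P = ", format(x$precision, digits = 3),
      ", R = ", format(x$recall, digits = 3),
      ", F = ", format(x$f_measure, digits = 3),
      "  (tp ", x$tp, ", fp ", x$fp, ", fn ", x$fn, ", tn ", x$tn, ")\n",
      sep = "")
  invisible(x)
}

#' @export
tidy.ddi_eval <- function(x, ...) {
  tibble::tibble(metric = c("precision", "recall", "f_measure"),
                 value = c(x$precision, x$recall, x$f_measure))
}

#' @export
glance.ddi_eval <- function(x, ...) {
  tibble::tibble(precision = x$precision, recall = x$recall,
                 f_measure = x$f_measure, tp = x$tp, fp = x$fp, fn = x$fn,
                 tn = x$tn, n = x$n, prevalence = x$prevalence)
}

#' @export
autoplot.ddi_eval <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = NULL, title = "DDI extraction performance")
}

#' Train and evaluate the graph-kernel DDI extractor
#'
#' Splits instances at the document level (all candidates of an abstract
#' stay together), trains a support vector machine on the precomputed
#' normalized all-paths kernel matrix of the training instances, and reports
#' precision, recall and F-measure on the held-out documents. Class weights
#' are balanced (inverse class frequency) by default, the usual guard
#' against the heavy negative skew of candidate pairs.
#'
#' @param instances Instance tibble from [ddi_instances()].
#' @param test_fraction Fraction of documents held out.
#' @param seed Integer seed controlling the document split.
#' @param C Soft-margin regularization parameter.
#' @param balanced Use inverse-frequency class weights.
#' @return A list of class `ddi_model`: the fitted `ksvm`, the kernel
#'   matrix, split bookkeeping and `train`/`test` evaluation reports
#'   (`ddi_eval`).
#' @export
ddi_train_eval <- function(instances, test_fraction = 0.25, seed = 1,
                           C = 10, balanced = TRUE) {
  stopifnot(nrow(instances) >= 4)
  docs <- unique(instances$pmid)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n_test <- max(1L, round(length(docs) * test_fraction))
  test_docs <- sample(docs, n_test)
  is_test <- instances$pmid %in% test_docs
  y <- factor(ifelse(instances$gold, "yes", "no"), levels = c("no", "yes"))
  if (dplyr::n_distinct(y[!is_test]) < 2) {
    abort("degenerate class distribution in training set")
  }
  k <- kernel_matrix(instances$graph, normalize = TRUE)
  wts <- if (balanced) {
    tab <- table(y[!is_test])
    w <- sum(tab) / (2 * tab)
    setNames(as.numeric(w), names(tab))
  } else NULL
  fit <- kernlab::ksvm(kernlab::as.kernelMatrix(k[!is_test, !is_test]),
                       y[!is_test], kernel = "matrix", C = C,
                       class.weights = wts)
  sv <- kernlab::SVindex(fit)
  pred_tr <- kernlab::predict(fit, kernlab::as.kernelMatrix(
    k[!is_test, !is_test, drop = FALSE][, sv, drop = FALSE]))
  pred_te <- kernlab::predict(fit, kernlab::as.kernelMatrix(
    k[is_test, !is_test, drop = FALSE][, sv, drop = FALSE]))
  structure(
    list(fit = fit, kernel = k, test_docs = test_docs, is_test = is_test,
         y = y,
         train = eval_report(y[!is_test] == "yes", pred_tr == "yes"),
         test = eval_report(y[is_test] == "yes", pred_te == "yes")),
    class = "ddi_model")
}

#' @export
print.ddi_model <- function(x, ...) {
  cat("<ddi_model> graph-kernel SVM, ", sum(!x$is_test), " train / ",
      sum(x$is_test), " test candidates\n", sep = "")
  cat("train: "); print(x$train)
  cat("test:  "); print(x$test)
  invisible(x)
}

#' @export
tidy.ddi_model <- function(x, ...) {
  dplyr::bind_rows(
    mutate(glance(x$train), split = "train", .before = 1),
    mutate(glance(x$test), split = "test", .before = 1))
}

#' @export
glance.ddi_model <- function(x, ...) {
  mutate(glance(x$test), n_train = sum(!x$is_test),
         n_support = length(kernlab::SVindex(x$fit)))
}

#' @export
autoplot.ddi_model <- function(object, ...) {
  df <- tidy(object) %>%
    tidyr::pivot_longer(c("precision", "recall", "f_measure"),
                        names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value,
                                   fill = .data$split)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Graph-kernel DDI extraction performance")
}

# Save/restore the RNG state so seeded helpers do not disturb the caller.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
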