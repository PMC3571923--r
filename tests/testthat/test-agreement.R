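test_that("alpha is 1 under perfect agreement and matches a hand example", {
  perfect <- tibble::tibble(unit_id = rep(1:5, 2),
                            annotator_id = rep(c("a", "b"), each = 5),
                            label = rep(c("X", "Y", "X", "Y", "X"), 2))
  expect_equal(krippendorff_alpha(perfect)$alpha, 1.0)
  # 2 annotators, 4 units, labels (A,A),(A,B),(B,A),(B,B):
  # Do = 4/8, De = 32/56, alpha = 1 - (1/2)/(4/7) = 1/8
  u <- tibble::tibble(unit_id = rep(1:4, each = 2),
                      annotator_id = rep(c("a", "b"), 4),
                      label = c("A", "A", "A", "B", "B", "A", "B", "B"))
  r <- krippendorff_alpha(u)
  expect_equal(r$alpha, 1 / 8)
  expect_equal(r$observed_disagreement, 0.5)
  expect_equal(r$expected_disagreement, 4 / 7)
  expect_equal(r$n_pairable, 8)
})

test_that("alpha equals the brute-force pair-enumeration oracle", {
  withr::local_seed(2024)
  for (i in 1:25) {
    u <- random_units(n_units = sample(5:12, 1),
                      n_annotators = sample(2:4, 1),
                      n_labels = sample(2:4, 1),
                      missing = stats::runif(1, 0, 0.3))
    # ensure pairable overlap exists
    counts <- table(u$unit_id[!is.na(u$label)])
    if (!any(counts >= 2)) next
    got <- krippendorff_alpha(u, degenerate = "one")$alpha
    expect_equal(got, brute_alpha(u), tolerance = 1e-12)
  }
})

test_that("degenerate and error cases behave as documented", {
  same <- tibble::tibble(unit_id = rep(1:3, 2),
                         annotator_id = rep(c("a", "b"), each = 3),
                         label = "X")
  expect_equal(krippendorff_alpha(same, degenerate = "one")$alpha, 1.0)
  expect_error(krippendorff_alpha(same, degenerate = "error"),
               "expected disagreement")
  lone <- tibble::tibble(unit_id = 1:4, annotator_id = "a", label = "X")
  expect_error(krippendorff_alpha(lone), "insufficient overlap")
  dup <- tibble::tibble(unit_id = c(1, 1), annotator_id = c("a", "a"),
                        label = c("X", "Y"))
  expect_error(krippendorff_alpha(dup), "duplicate")
})

test_that("alpha is invariant under annotator and label renaming", {
  withr::local_seed(7)
  u <- random_units(n_units = 10, n_annotators = 3, n_labels = 3)
  a0 <- krippendorff_alpha(u)$alpha
  relabeled <- u
  relabeled$label <- c(A = "Q", B = "R", C = "S")[relabeled$label]
  relabeled$annotator_id <- paste0("x_", relabeled$annotator_id)
  expect_equal(krippendorff_alpha(relabeled)$alpha, a0)
  # adding disagreements to a perfect set lowers alpha
  perfect <- tibble::tibble(unit_id = rep(1:6, 2),
                            annotator_id = rep(c("a", "b"), each = 6),
                            label = rep(c("X", "Y"), 6))
  worse <- perfect
  worse$label[1] <- "Y"
  expect_lt(krippendorff_alpha(worse)$alpha,
            krippendorff_alpha(perfect)$alpha)
})

test_that("corpus-derived units give alpha 1 for identical annotators", {
  synth <- simulate_corpus(6, seed = 5)
  res <- corpus_agreement(list(a = synth$corpus, b = synth$corpus))
  expect_equal(res$level, c("term", "sentence", "pair"))
  expect_equal(res$alpha, rep(1, 3))
})

test_that("a single flipped sentence label lowers alpha to the brute value", {
  synth <- simulate_corpus(6, seed = 5)
  b <- synth$corpus
  i <- which(b$sentences$ddi_label == "NONE")[1]
  b$sentences$ddi_label[i] <- "CDDIS"
  units <- agreement_units(list(a = synth$corpus, b = b))
  r <- krippendorff_alpha(units$sentence)
  expect_lt(r$alpha, 1)
  expect_equal(r$alpha, brute_alpha(units$sentence), tolerance = 1e-12)
})

test_that("annotators missing a document still pair on the rest", {
  synth <- simulate_corpus(6, seed = 5)
  b <- synth$corpus
  drop <- b$documents$pmid[1]
  b$documents <- b$documents[b$documents$pmid != drop, ]
  b$sentences <- b$sentences[b$sentences$pmid != drop, ]
  b$terms <- b$terms[b$terms$pmid != drop, ]
  b$pairs <- b$pairs[b$pairs$pmid != drop, ]
  units <- agreement_units(list(a = synth$corpus, b = b))
  r <- krippendorff_alpha(units$sentence)
  expect_equal(r$alpha, 1.0)
  expect_lt(r$n_units, nrow(synth$corpus$sentences))
})

test_that("diverging sentence texts are reported as tokenization mismatch", {
  synth <- simulate_corpus(3, seed = 5)
  b <- synth$corpus
  b$sentences$text[2] <- paste(b$sentences$text[2], "extra")
  b$terms <- b$terms[0, ]
  expect_error(agreement_units(list(a = synth$corpus, b = b)),
               "tokenization mismatch")
})

test_that("alpha tends to zero for independent uniform annotators", {
  withr::local_seed(11)
  n <- 4000
  u <- tibble::tibble(unit_id = rep(seq_len(n), 2),
                      annotator_id = rep(c("a", "b"), each = n),
                      label = sample(LETTERS[1:3], 2 * n, replace = TRUE))
  expect_lt(abs(krippendorff_alpha(u)$alpha), 0.05)
})
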