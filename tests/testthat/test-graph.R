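test_that("all-paths weights follow the geometric series on simple graphs", {
  g <- dep_graph(list("a", "b"), rbind(c(0, 0.9), c(0, 0)))
  w <- all_paths_weights(g)
  expect_equal(w[1, 2], 0.9)
  expect_equal(w[2, 1], 0)
  chain <- dep_graph(list("a", "b", "c"),
                     rbind(c(0, 0.9, 0), c(0, 0, 0.9), c(0, 0, 0)))
  expect_equal(all_paths_weights(chain)[1, 3], 0.81)
  # a disconnected graph with no edges is valid
  iso <- dep_graph(list("a", "b"), matrix(0, 2, 2))
  expect_equal(all_paths_weights(iso), matrix(0, 2, 2))
  # non-convergent series errors with a rescale hint
  cyc <- dep_graph(list("a", "b"), rbind(c(0, 1), c(1, 0)))
  expect_error(all_paths_weights(cyc), "rescale")
  expect_error(dep_graph(list("a"), matrix(1.5, 1, 1)), "weights")
})

test_that("path weights match truncated brute-force enumeration", {
  withr::local_seed(99)
  for (i in 1:60) {
    g <- random_dep_graph(n_max = 6, w_max = 0.5)
    expect_equal(all_paths_weights(g), brute_path_weights(g$adj, 40),
                 tolerance = 1e-9)
  }
})

test_that("the kernel is normalized, symmetric and label-sensitive", {
  withr::local_seed(5)
  g1 <- random_dep_graph()
  g2 <- random_dep_graph()
  expect_equal(graph_kernel(g1, g1), 1.0)
  expect_equal(graph_kernel(g1, g2), graph_kernel(g2, g1))
  disjoint <- dep_graph(list("zz1", "zz2"), rbind(c(0, 0.5), c(0, 0)))
  expect_equal(graph_kernel(g1, disjoint), 0)
})

test_that("the kernel equals a brute-force double loop on small graphs", {
  withr::local_seed(17)
  for (i in 1:10) {
    g1 <- random_dep_graph(n_max = 4, w_max = 0.4)
    g2 <- random_dep_graph(n_max = 4, w_max = 0.4)
    expect_equal(graph_kernel(g1, g2, normalize = FALSE),
                 brute_kernel(g1, g2), tolerance = 1e-8)
  }
})

test_that("kernel matrices are symmetric and positive semidefinite", {
  withr::local_seed(23)
  graphs <- replicate(15, random_dep_graph(), simplify = FALSE)
  k <- kernel_matrix(graphs)
  expect_equal(k, t(k))
  expect_equal(diag(k), rep(1, 15))
  expect_gt(min(eigen(k, symmetric = TRUE, only.values = TRUE)$values),
            -1e-8)
})

test_that("build_graph marks entities and weights the shortest path", {
  parse <- chain_parse(c("A", "inhibits", "B"))
  g <- build_graph(parse, pair = c(1, 3))
  expect_equal(g$n, 6)  # 3 dependency vertices + 3 linear vertices
  expect_true("ENTITY1" %in% g$labels[[1]])
  expect_true("ENTITY2" %in% g$labels[[3]])
  expect_false("a" %in% g$labels[[1]])  # lemma anonymized
  expect_equal(g$labels[[2]], "inhibits")
  # chain parse: both dependency edges lie on the shortest path
  w <- default_graph_weights()
  expect_equal(g$adj[1, 2], w$w_shortest)
  expect_equal(g$adj[2, 3], w$w_shortest)
  # linear chain edges
  expect_equal(g$adj[4, 5], w$w_linear)
  expect_equal(g$adj[5, 6], w$w_linear)
  # other candidate entities get the generic marker
  g2 <- build_graph(chain_parse(c("A", "alters", "B", "and", "C")),
                    pair = c(1, 3), other_entities = 5L)
  expect_true("ENTITY" %in% g2$labels[[5]])
  # off-path edges get the lower weight
  expect_equal(g2$adj[3, 4], w$w_other)
  # misaligned parse errors
  bad <- chain_parse(c("A", "B")); bad$head <- c(5L, 0L)
  expect_error(build_graph(bad, pair = c(1, 2)), "misaligned")
})

test_that("CoNLL-style parse files read into aligned parse tables", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "# sentence_id token_index token lemma pos head rel",
    paste("s1", 1, "Verapamil", "verapamil", "NN", 2, "nsubj", sep = "\t"),
    paste("s1", 2, "inhibits", "inhibit", "VBZ", 0, "root", sep = "\t"),
    paste("s1", 3, "CYP3A4", "cyp3a4", "NN", 2, "dobj", sep = "\t"),
    paste("s2", 1, "Done", "done", "VBN", 0, "root", sep = "\t")), f)
  parses <- read_conll_parses(f)
  expect_equal(names(parses), c("s1", "s2"))
  expect_equal(nrow(parses$s1), 3)
  expect_equal(parses$s1$head, c(2L, 0L, 2L))
  g <- build_graph(parses$s1, pair = c(1, 3))
  expect_equal(g$n, 6)
  # real parse: path runs through the verb
  expect_equal(g$adj[2, 1], 0.9)
  expect_equal(g$adj[2, 3], 0.9)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("s1\tonly\tthree\tcols", f2)
  expect_error(read_conll_parses(f2), "malformed")
})
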