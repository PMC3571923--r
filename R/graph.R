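# Graph representation for the all-paths graph kernel: a weighted, directed
# graph combining the dependency parse of a sentence with a linearized chain
# of part-of-speech tags, plus the kernel computation itself.

#' Construct a dependency/PoS kernel graph
#'
#' @param labels List of character vectors, one label set per vertex
#'   (lemmas, part-of-speech tags, entity role markers).
#' @param adj Square numeric adjacency matrix; `adj[i, j]` is the weight of
#'   the directed edge i -> j, 0 for no edge. All weights must lie in (0, 1].
#' @return An object of class `dep_graph`.
#' @export
dep_graph <- function(labels, adj) {
  adj <- as.matrix(adj)
  stopifnot(length(labels) == nrow(adj), nrow(adj) == ncol(adj))
  w <- adj[adj != 0]
  if (length(w) && (any(w < 0) || any(w > 1))) {
    abort("edge weights must lie in (0, 1]")
  }
  structure(list(labels = labels, adj = adj, n = nrow(adj)),
            class = "dep_graph")
}

#' @export
print.dep_graph <- function(x, ...) {
  cat("<dep_graph> ", x$n, " vertices, ", sum(x$adj != 0), " edges\n",
      sep = "")
  invisible(x)
}

#' All-paths weight matrix
#'
#' Entry (i, j) is the sum over all directed paths from i to j (length >= 1)
#' of the product of edge weights along the path, computed by the convergent
#' geometric series of the adjacency matrix, `(I - A)^-1 - I`. The series
#' converges when the spectral radius of the adjacency matrix is below one
#' (always true for the acyclic graphs built by [build_graph()]).
#'
#' @param graph A `dep_graph`.
#' @return A numeric matrix of path-weight sums.
#' @export
#' @examples
#' g <- dep_graph(list("a", "b", "c"),
#'                rbind(c(0, .9, 0), c(0, 0, .9), c(0, 0, 0)))
#' all_paths_weights(g)  # chain: entry [1, 3] is 0.9 * 0.9 = 0.81
all_paths_weights <- function(graph) {
  a <- graph$adj
  if (nrow(a) == 0) return(a)
  rho <- max(Mod(eigen(a, only.values = TRUE)$values))
  if (rho >= 1) {
    abort(paste0("path series does not converge (spectral radius ",
                 format(rho, digits = 4),
                 " >= 1); rescale the edge weights"))
  }
  solve(diag(nrow(a)) - a) - diag(nrow(a))
}

# Per-graph feature table for the kernel: entries M[l1, l2] = sum over
# vertices u with label l1 and v with label l2 of (I + W)[u, v]. Keyed
# sparse representation: names "l1\rl2" -> weight.
graph_features <- function(graph) {
  wfull <- all_paths_weights(graph) + diag(graph$n)
  labs <- unique(unlist(graph$labels))
  memb <- matrix(0, length(labs), graph$n, dimnames = list(labs, NULL))
  for (v in seq_len(graph$n)) memb[graph$labels[[v]], v] <- 1
  m <- memb %*% wfull %*% t(memb)
  keys <- outer(labs, labs, function(a, b) paste(a, b, sep = "\r"))
  keep <- m != 0
  setNames(m[keep], keys[keep])
}

kernel_from_features <- function(f1, f2) {
  common <- intersect(names(f1), names(f2))
  if (!length(common)) return(0)
  sum(f1[common] * f2[common])
}

#' All-paths graph kernel
#'
#' Similarity of two labeled weighted graphs: the sum over pairs of vertex
#' pairs with shared labels of the products of their path-weight sums
#' (vertices match themselves through the identity path). With
#' `normalize = TRUE` returns k(a,b)/sqrt(k(a,a) k(b,b)), so identical
#' graphs score 1 and graphs with disjoint label sets 0.
#'
#' @param g1,g2 `dep_graph` objects.
#' @param normalize Return the normalized kernel value.
#' @return A numeric scalar.
#' @export
graph_kernel <- function(g1, g2, normalize = TRUE) {
  f1 <- graph_features(g1)
  f2 <- graph_features(g2)
  k <- kernel_from_features(f1, f2)
  if (!normalize) return(k)
  d <- sqrt(kernel_from_features(f1, f1) * kernel_from_features(f2, f2))
  if (d == 0) return(0)
  k / d
}

#' Kernel matrix of a list of graphs
#'
#' @param graphs List of `dep_graph` objects.
#' @param normalize Normalize so the diagonal is 1.
#' @return A symmetric positive semidefinite matrix.
#' @export
kernel_matrix <- function(graphs, normalize = TRUE) {
  feats <- purrr::map(graphs, graph_features)
  n <- length(feats)
  k <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      k[i, j] <- k[j, i] <- kernel_from_features(feats[[i]], feats[[j]])
    }
  }
  if (normalize) {
    d <- sqrt(diag(k))
    d[d == 0] <- 1
    k <- k / outer(d, d)
  }
  k
}

default_graph_weights <- function() {
  list(w_shortest = 0.9, w_other = 0.3, w_linear = 0.9)
}

#' Build the combined dependency + part-of-speech graph for a candidate pair
#'
#' The graph has two disjoint components: (i) the dependency graph of the
#' sentence, with edges directed head -> dependent, weighted `w_shortest`
#' when the edge lies on a shortest undirected path between the two candidate
#' entities and `w_other` elsewhere; (ii) a linear chain over the
#' part-of-speech tags with constant weight `w_linear`. Tokens of the two
#' candidate entities are anonymized to the role markers `ENTITY1`/`ENTITY2`
#' (their lemmas removed); tokens of other candidate entities become
#' `ENTITY`.
#'
#' @param parse A tibble with one row per token: columns `token`, `lemma`,
#'   `pos`, `head` (1-based index of the head token, 0 for the root).
#' @param pair Integer vector of length 2: token indices of the two
#'   candidate entities.
#' @param other_entities Integer vector of token indices of remaining
#'   candidate entities.
#' @param weights List with `w_shortest`, `w_other`, `w_linear`.
#' @return A `dep_graph` with `2 * nrow(parse)` vertices (dependency
#'   component first, then the linear chain).
#' @export
build_graph <- function(parse, pair, other_entities = integer(),
                        weights = default_graph_weights()) {
  parse <- as_tibble(parse)
  n <- nrow(parse)
  stopifnot(length(pair) == 2, all(pair >= 1), all(pair <= n))
  if (any(parse$head < 0 | parse$head > n)) {
    abort("parse is misaligned: head index out of range")
  }
  edges <- parse %>%
    mutate(dep = dplyr::row_number()) %>%
    filter(.data$head > 0)
  # shortest undirected path between the pair entities
  on_path <- rep(FALSE, nrow(edges))
  if (nrow(edges)) {
    g <- igraph::graph_from_edgelist(
      cbind(edges$head, edges$dep), directed = FALSE)
    if (igraph::vcount(g) < n) {
      g <- igraph::add_vertices(g, n - igraph::vcount(g))
    }
    d1 <- as.vector(igraph::distances(g, v = pair[1]))
    d2 <- as.vector(igraph::distances(g, v = pair[2]))
    dd <- d1[pair[2]]
    if (is.finite(dd)) {
      on_path <- (d1[edges$head] + 1 + d2[edges$dep] == dd) |
        (d1[edges$dep] + 1 + d2[edges$head] == dd)
    }
  }
  adj <- matrix(0, 2 * n, 2 * n)
  if (nrow(edges)) {
    w <- ifelse(on_path, weights$w_shortest, weights$w_other)
    adj[cbind(edges$head, edges$dep)] <- w
  }
  if (n > 1) {
    adj[cbind(n + seq_len(n - 1), n + seq_len(n - 1) + 1)] <- weights$w_linear
  }
  marker <- rep(NA_character_, n)
  marker[other_entities] <- "ENTITY"
  marker[pair[1]] <- "ENTITY1"
  marker[pair[2]] <- "ENTITY2"
  dep_labels <- purrr::map(seq_len(n), function(i) {
    if (!is.na(marker[i])) marker[i] else tolower(parse$lemma[i])
  })
  lin_labels <- purrr::map(seq_len(n), function(i) {
    base <- paste0("pos:", parse$pos[i])
    if (!is.na(marker[i])) c(base, paste0(marker[i], ":lin")) else base
  })
  dep_graph(c(dep_labels, lin_labels), adj)
}

#' Deterministic fallback parse
#'
#' A right-branching chain over the tokens of a sentence: token i is headed
#' by token i - 1, the first token is the root. Lemmas are lowercased
#' surface forms; part-of-speech tags come from a small closed-class table
#' and suffix heuristics. Used when no external dependency parser output is
#' supplied; adequate for kernel computation though far cruder than a real
#' parser.
#'
#' @param tokens Character vector of tokens.
#' @return A parse tibble (`token`, `lemma`, `pos`, `head`).
#' @export
chain_parse <- function(tokens) {
  n <- length(tokens)
  pos <- vapply(tokens, function(t) {
    lt <- tolower(t)
    if (grepl("^[0-9.]+$", t)) "CD"
    else if (lt %in% c("the", "a", "an")) "DT"
    else if (lt %in% c("of", "by", "with", "in", "on", "for", "to", "at",
                       "from")) "IN"
    else if (lt %in% c("and", "or", "but", "while", "whereas")) "CC"
    else if (lt %in% c("was", "were", "is", "are", "did", "had", "has")) "VBD"
    else if (lt %in% c("not", "no")) "RB"
    else if (grepl("ly$", lt)) "RB"
    else if (grepl("(ed|ing|ates?|izes?)$", lt)) "VB"
    else "NN"
  }, character(1))
  tibble::tibble(token = tokens, lemma = tolower(tokens), pos = pos,
                 head = c(0L, seq_len(max(n - 1, 0))))
}

#' Read dependency parses from CoNLL-style delimited text
#'
#' Tab-separated with columns `sentence_id`, `token_index`, `token`,
#' `lemma`, `pos`, `head`, `rel`; comment lines start with `#`. Sentences
#' are returned as a named list of parse tibbles.
#'
#' @param path Input file.
#' @return Named list of parse tibbles.
#' @export
read_conll_parses <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) != 7
  if (any(bad)) {
    abort(paste0("malformed parse row: ", lines[bad][1]))
  }
  df <- tibble::tibble(
    sentence_id = purrr::map_chr(parts, 1),
    token_index = as.integer(purrr::map_chr(parts, 2)),
    token = purrr::map_chr(parts, 3),
    lemma = purrr::map_chr(parts, 4),
    pos = purrr::map_chr(parts, 5),
    head = as.integer(purrr::map_chr(parts, 6)),
    rel = purrr::map_chr(parts, 7))
  df %>% dplyr::group_split(.data$sentence_id) %>%
    purrr::map(~ arrange(.x, .data$token_index)) %>%
    setNames(purrr::map_chr(., ~ .x$sentence_id[[1]])) %>%
    purrr::map(~ dplyr::select(.x, "token", "lemma", "pos", "head", "rel"))
}
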