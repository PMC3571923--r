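# Independent brute-force oracles used to cross-check the package's
# implementations: pair-enumeration Krippendorff alpha, truncated path-sum
# weights, and a 4-nested-loop graph kernel.

brute_alpha <- function(units) {
  units <- units[!is.na(units$label), ]
  sp <- split(units$label, units$unit_id)
  sp <- sp[lengths(sp) >= 2]
  vals <- unlist(sp)
  n <- length(vals)
  do_sum <- 0
  for (v in sp) {
    m <- length(v)
    for (i in seq_len(m)) {
      for (j in seq_len(m)) {
        if (i != j) do_sum <- do_sum + (v[i] != v[j]) / (m - 1)
      }
    }
  }
  de_sum <- 0
  for (i in seq_len(n)) {
    de_sum <- de_sum + sum(vals[i] != vals[-i])
  }
  d_o <- do_sum / n
  d_e <- de_sum / (n * (n - 1))
  if (d_e == 0) return(1)
  1 - d_o / d_e
}

# Sum of path-weight products over all walks of length 1..maxlen.
brute_path_weights <- function(adj, maxlen = 40) {
  w <- matrix(0, nrow(adj), ncol(adj))
  p <- diag(nrow(adj))
  for (k in seq_len(maxlen)) {
    p <- p %*% adj
    w <- w + p
  }
  w
}

# Unnormalized kernel by explicit enumeration of vertex 4-tuples, weighting
# each tuple by the number of shared label pairs.
brute_kernel <- function(g1, g2, maxlen = 60) {
  w1 <- brute_path_weights(g1$adj, maxlen) + diag(g1$n)
  w2 <- brute_path_weights(g2$adj, maxlen) + diag(g2$n)
  tot <- 0
  for (u1 in seq_len(g1$n)) for (v1 in seq_len(g1$n)) {
    for (u2 in seq_len(g2$n)) for (v2 in seq_len(g2$n)) {
      m_u <- length(intersect(g1$labels[[u1]], g2$labels[[u2]]))
      m_v <- length(intersect(g1$labels[[v1]], g2$labels[[v2]]))
      if (m_u > 0 && m_v > 0) {
        tot <- tot + m_u * m_v * w1[u1, v1] * w2[u2, v2]
      }
    }
  }
  tot
}

random_dep_graph <- function(n_max = 6, w_max = 0.5, labels = letters[1:8]) {
  n <- sample(2:n_max, 1)
  adj <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && stats::runif(1) < 0.4) {
        adj[i, j] <- round(stats::runif(1, 0.05, w_max), 3)
      }
    }
  }
  # keep the spectral radius small enough that a length-40 truncation of
  # the path series is accurate to well below 1e-9
  rho <- max(Mod(eigen(adj, only.values = TRUE)$values))
  if (rho > 0.55) adj <- adj * (0.55 / rho)
  labs <- lapply(seq_len(n), function(i) {
    sample(labels, sample(1:2, 1))
  })
  dep_graph(labs, adj)
}

random_units <- function(n_units = 8, n_annotators = 3, n_labels = 3,
                         missing = 0.2) {
  grid <- expand.grid(unit_id = seq_len(n_units),
                      annotator_id = paste0("a", seq_len(n_annotators)),
                      stringsAsFactors = FALSE)
  grid$label <- sample(LETTERS[seq_len(n_labels)], nrow(grid),
                       replace = TRUE)
  grid$label[stats::runif(nrow(grid)) < missing] <- NA
  tibble::as_tibble(grid)
}

# Binary search for a label transition along a numeric evidence axis.
rule_boundary <- function(label_at, lo, hi, tol = 1e-6) {
  lab_lo <- label_at(lo)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (label_at(mid) == lab_lo) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

label_at_fc <- function(fc, p = 0.01, rules = ddi_rules()) {
  classify_pairs(tibble::tibble(
    setting = "in_vivo", pair_type = "drug_drug", c1 = TRUE, c2 = TRUE,
    quant = list(quant_evidence("AUC", "fold_change", fc, p_value = p,
                                p_relation = "eq")),
    cues = list(cue_evidence(character()))), rules = rules)$label
}

label_at_ki <- function(ki, p = 0.01, rules = ddi_rules()) {
  classify_pairs(tibble::tibble(
    setting = "in_vitro", pair_type = "drug_enzyme", c1 = TRUE, c2 = TRUE,
    quant = list(quant_evidence("Ki", "ki", ki, p_value = p,
                                p_relation = "eq")),
    cues = list(cue_evidence(character()))), rules = rules)$label
}
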