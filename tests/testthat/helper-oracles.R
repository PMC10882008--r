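# Independent oracles used across the suite.  These deliberately use
# different code paths from the package implementation: utils::adist for
# edit distances, plain adjacency-matrix loops for graph metrics, and
# recursive permutation enumeration for the Mann-Kendall null.

random_aa_strings <- function(n, min_len = 8L, max_len = 20L) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  vapply(sample(min_len:max_len, n, replace = TRUE),
         function(L) paste(sample(aa, L, replace = TRUE), collapse = ""),
         character(1))
}

# Brute-force all-pairs Levenshtein distance-1 edge set (sorted pairs).
brute_force_edit1 <- function(seqs) {
  d <- utils::adist(seqs)
  idx <- which(d == 1 & upper.tri(d), arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(data.frame(from = character(0), to = character(0)))
  a <- seqs[idx[, 1L]]; b <- seqs[idx[, 2L]]
  out <- data.frame(from = pmin(a, b), to = pmax(a, b), stringsAsFactors = FALSE)
  out <- out[order(out$from, out$to), , drop = FALSE]
  rownames(out) <- NULL
  out
}

graph_edge_set <- function(g) {
  e <- igraph::as_data_frame(g, what = "edges")
  if (nrow(e) == 0L) return(data.frame(from = character(0), to = character(0)))
  out <- data.frame(from = pmin(e$from, e$to), to = pmax(e$from, e$to),
                    stringsAsFactors = FALSE)
  out <- out[order(out$from, out$to), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Direct-definition density / average clustering / S metric from an
# adjacency matrix.
oracle_metrics <- function(adj) {
  n <- nrow(adj)
  deg <- rowSums(adj)
  e <- sum(adj) / 2
  density <- 2 * e / (n * (n - 1))
  clus <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    sum(adj[nb, nb]) / (k * (k - 1))
  }, 0)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (j > i && adj[i, j] == 1) s <- s + deg[i] * deg[j]
  list(density = density, avg_clustering = mean(clus), s_metric = s)
}

# Exhaustive permutation enumeration of the Mann-Kendall S statistic;
# two-sided p = P(|S| >= |S_obs|) under uniform permutations.
oracle_mk_p <- function(x) {
  n <- length(x)
  s_of <- function(v) {
    s <- 0
    for (i in seq_len(n - 1L)) s <- s + sum(sign(v[(i + 1L):n] - v[i]))
    s
  }
  s_obs <- s_of(x)
  ss <- numeric(factorial(n))
  k <- 0L
  recurse <- function(prefix, rest) {
    if (length(rest) == 0L) {
      k <<- k + 1L
      ss[k] <<- s_of(prefix)
      return(invisible())
    }
    for (i in seq_along(rest)) recurse(c(prefix, rest[i]), rest[-i])
  }
  recurse(numeric(0), x)
  mean(abs(ss) >= abs(s_obs))
}

# Rank-based AUC of a score against a binary truth.
oracle_auc <- function(score, positive) {
  r <- rank(score)
  n1 <- sum(positive); n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

make_table <- function(cdr3, counts = 1L, sample_id = "S", day = 0L,
                       group = "sequential") {
  clonotype_table(sample_id, day, group, cdr3, counts)
}
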