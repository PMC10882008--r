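# Levenshtein distance-1 TCR similarity networks and connectivity metrics.
#
# Candidate edges come from a symmetric-deletion index (each sequence keyed
# by itself and all single-deletion variants); candidates are then verified
# by an exact edit-distance-1 check.  This yields O(n * L) candidate pairs
# instead of the O(n^2) all-pairs comparison, with output proven equal to
# the brute-force construction in the test suite.

deletion_keys <- function(seq) {
  L <- nchar(seq)
  c(seq, vapply(seq_len(L), function(i)
    paste0(substr(seq, 1L, i - 1L), substr(seq, i + 1L, L)), ""))
}

# Exact test for Levenshtein distance == 1 between two distinct strings
# whose lengths differ by at most 1 (guaranteed by the deletion index):
# equal lengths -> exactly one substitution; lengths off by one -> the
# shorter is the longer with one character deleted.
is_edit1 <- function(a, b) {
  la <- nchar(a); lb <- nchar(b)
  if (la == lb) {
    if (a == b) return(FALSE)
    return(sum(utf8ToInt(a) != utf8ToInt(b)) == 1L)
  }
  if (abs(la - lb) != 1L) return(FALSE)
  if (la > lb) { tmp <- a; a <- b; b <- tmp; la <- nchar(a); lb <- nchar(b) }
  ca <- utf8ToInt(a); cb <- utf8ToInt(b)
  diff <- which(ca != cb[seq_len(la)])
  i <- if (length(diff)) diff[1L] else la + 1L
  identical(ca[seq(i, length.out = la - i + 1L)], cb[seq(i + 1L, length.out = la - i + 1L)])
}

#' Build the Levenshtein distance-1 TCR similarity graph
#'
#' Nodes are the unique productive CDR3 amino-acid sequences across all
#' input samples; an undirected edge joins two sequences whose Levenshtein
#' distance (one substitution, insertion, or deletion) is exactly 1.  Each
#' node records the number of samples in which the sequence was detected
#' and the set of those samples.
#'
#' @param tables A [clonotype_table()] or list thereof.
#' @return An [igraph::igraph] of class `tcr_graph` with vertex attributes
#'   `name` (CDR3), `n_samples_detected` and `membership` (list of sample
#'   ids).
#' @export
build_edit1_graph <- function(tables) {
  if (inherits(tables, "clonotype_table")) tables <- list(tables)
  seq_lists <- lapply(tables, function(t) productive_records(t)$cdr3_aa)
  sample_ids <- vapply(tables, `[[`, "", "sample_id")
  seqs <- sort(unique(unlist(seq_lists)))
  if (length(seqs) == 0L) stop("no productive sequences in input tables")
  membership <- split(rep(sample_ids, lengths(seq_lists)),
                      factor(unlist(seq_lists), levels = seqs))

  keys <- lapply(seqs, deletion_keys)
  idx <- rep.int(seq_along(seqs), lengths(keys))
  buckets <- split(idx, unlist(keys))
  buckets <- buckets[lengths(buckets) > 1L]
  if (length(buckets)) {
    pairs <- do.call(cbind, lapply(buckets, function(b) {
      b <- unique(b)
      if (length(b) < 2L) return(matrix(integer(0), 2L)) else utils::combn(b, 2L)
    }))
    if (ncol(pairs)) {
      lo <- pmin(pairs[1L, ], pairs[2L, ]); hi <- pmax(pairs[1L, ], pairs[2L, ])
      keep <- !duplicated(lo * (length(seqs) + 1) + hi)
      lo <- lo[keep]; hi <- hi[keep]
      ok <- mapply(is_edit1, seqs[lo], seqs[hi], USE.NAMES = FALSE)
      edges <- data.frame(from = seqs[lo[ok]], to = seqs[hi[ok]],
                          stringsAsFactors = FALSE)
    } else edges <- data.frame(from = character(0), to = character(0))
  } else edges <- data.frame(from = character(0), to = character(0))

  vertices <- data.frame(name = seqs,
                         n_samples_detected = lengths(membership),
                         stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vertices)
  g <- igraph::set_vertex_attr(g, "membership", value = membership[igraph::V(g)$name])
  class(g) <- c("tcr_graph", class(g))
  g
}

#' Connectivity metrics of a TCR similarity graph
#'
#' Density is the fraction of potential connections realized,
#' `2E / (N (N - 1))`; the average clustering coefficient is the mean local
#' clustering coefficient over all nodes (nodes of degree < 2 contribute
#' 0); the S metric is the sum over edges of `degree(u) * degree(v)`.
#'
#' @param graph A `tcr_graph` (or any undirected igraph).
#' @return A list of class `network_metrics` with elements `density`,
#'   `avg_clustering`, `s_metric`, `n_nodes`, `n_edges`,
#'   `n_connected_nodes`.
#' @export
network_metrics <- function(graph) {
  n <- as.integer(igraph::vcount(graph))
  if (n < 2L) stop("density undefined: graph has fewer than 2 nodes")
  deg <- igraph::degree(graph)
  e <- as.integer(igraph::ecount(graph))
  s_metric <- if (e == 0L) 0 else {
    ends <- igraph::ends(graph, igraph::E(graph), names = FALSE)
    sum(deg[ends[, 1L]] * deg[ends[, 2L]])
  }
  structure(list(density = igraph::edge_density(graph),
                 avg_clustering = igraph::transitivity(graph, type = "localaverage",
                                                       isolates = "zero"),
                 s_metric = s_metric,
                 n_nodes = n, n_edges = e,
                 n_connected_nodes = as.integer(sum(deg > 0L))),
            class = "network_metrics")
}

#' @export
print.network_metrics <- function(x, ...) {
  cat(sprintf("TCR network: %d nodes (%d connected), %d edges\n",
              x$n_nodes, x$n_connected_nodes, x$n_edges))
  cat(sprintf("  density %.4g, average clustering %.4g, S metric %g\n",
              x$density, x$avg_clustering, x$s_metric))
  invisible(x)
}

#' Label a joined network by private/shared sample groups
#'
#' Each node of the joined network is labeled `private_a`, `private_b` or
#' `shared` from the groups of the samples in which its sequence was
#' detected; each connected component is summarized as `private_a`,
#' `private_b` or `mixed` from its node labels.
#'
#' @param graph A `tcr_graph` built by [build_edit1_graph()].
#' @param group_of_sample Named character vector mapping every sample id in
#'   the graph to one of exactly two group labels; the first label in sorted
#'   order plays the role of group a.
#' @return A list of class `labeled_tcr_graph`: the labeled `graph`, a
#'   `nodes` data frame (sequence, label, degree), a `components` data
#'   frame (component id, size, label) and `connected_by_label`, the counts
#'   of connected (degree >= 1) nodes per label.
#' @export
label_joined_network <- function(graph, group_of_sample) {
  membership <- igraph::vertex_attr(graph, "membership")
  samples <- unique(unlist(membership))
  missing <- setdiff(samples, names(group_of_sample))
  if (length(missing))
    stop("sample(s) without a group label: ", paste(missing, collapse = ", "))
  grp <- sort(unique(group_of_sample[samples]))
  if (length(grp) != 2L) stop("exactly two groups are required, got: ",
                              paste(grp, collapse = ", "))
  node_groups <- lapply(membership, function(m) unique(unname(group_of_sample[m])))
  label <- vapply(node_groups, function(gs) {
    if (length(gs) == 2L) "shared" else if (gs == grp[1L]) "private_a" else "private_b"
  }, "")
  graph <- igraph::set_vertex_attr(graph, "group_label", value = label)
  deg <- igraph::degree(graph)
  comps <- igraph::components(graph)
  comp_label <- vapply(seq_len(comps$no), function(k) {
    labs <- unique(label[comps$membership == k])
    if (length(labs) == 1L && labs != "shared") labs else "mixed"
  }, "")
  nodes <- data.frame(cdr3_aa = igraph::V(graph)$name, label = label,
                      degree = as.integer(deg),
                      component = comps$membership,
                      stringsAsFactors = FALSE)
  components <- data.frame(component = seq_len(comps$no),
                           size = as.integer(comps$csize),
                           label = comp_label, stringsAsFactors = FALSE)
  connected <- table(factor(label[deg > 0L],
                            levels = c("private_a", "private_b", "shared")))
  structure(list(graph = graph, nodes = nodes, components = components,
                 connected_by_label = connected,
                 groups = stats::setNames(grp, c("a", "b"))),
            class = "labeled_tcr_graph")
}

#' @export
print.labeled_tcr_graph <- function(x, ...) {
  cat(sprintf("Labeled TCR network (a = %s, b = %s): %d nodes, %d components\n",
              x$groups[["a"]], x$groups[["b"]], nrow(x$nodes), nrow(x$components)))
  print(x$connected_by_label)
  invisible(x)
}

#' Bootstrap stability of network metrics under downsampling
#'
#' Each replicate downsamples every input table to a common size (default:
#' the smallest table's clonotype count), rebuilds the distance-1 graph and
#' recomputes the connectivity metrics, verifying that the metrics do not
#' depend on sample size.
#'
#' @param tables List of [clonotype_table()] objects.
#' @param downsample_to Target clonotype count per table, or `"min"`.
#' @param reps Number of bootstrap replicates (default 10).
#' @param seed Integer seed; replicate subsamples are derived
#'   deterministically from it.
#' @return A list of class `bootstrap_metrics` with `replicates` (data
#'   frame of per-replicate metrics), `mean` and `sd` (named vectors) and
#'   the target `size`.
#' @export
bootstrap_metrics <- function(tables, downsample_to = "min", reps = 10L, seed = 1L) {
  if (inherits(tables, "clonotype_table")) tables <- list(tables)
  reps <- check_count(reps, "reps")
  sizes <- vapply(tables, function(t) nrow(productive_records(t)), 0L)
  if (identical(downsample_to, "min")) {
    target <- min(sizes)
  } else {
    target <- check_count(downsample_to, "downsample_to")
    if (target > min(sizes))
      stop(sprintf("target size %d exceeds the smallest table (%d clonotypes)",
                   target, min(sizes)))
  }
  seeds <- derive_seeds(seed, reps * length(tables))
  rows <- vector("list", reps)
  for (r in seq_len(reps)) {
    sub <- lapply(seq_along(tables), function(i)
      downsample_clonotypes(tables[[i]], target,
                            seed = seeds[(r - 1L) * length(tables) + i]))
    m <- network_metrics(build_edit1_graph(sub))
    rows[[r]] <- data.frame(replicate = r, density = m$density,
                            avg_clustering = m$avg_clustering,
                            s_metric = m$s_metric,
                            n_connected_nodes = m$n_connected_nodes)
  }
  replicates <- do.call(rbind, rows)
  metrics <- c("density", "avg_clustering", "s_metric", "n_connected_nodes")
  structure(list(replicates = replicates,
                 mean = vapply(replicates[metrics], mean, 0),
                 sd = vapply(replicates[metrics], stats::sd, 0),
                 size = target),
            class = "bootstrap_metrics")
}

#' @export
print.bootstrap_metrics <- function(x, ...) {
  cat(sprintf("Bootstrap (%d replicates, downsampled to %d clonotypes)\n",
              nrow(x$replicates), x$size))
  out <- rbind(mean = x$mean, sd = x$sd)
  print(out)
  invisible(x)
}

#' Write a TCR graph as GraphML and edge-list TSV
#'
#' @param graph A `tcr_graph`, labeled or not.
#' @param graphml,edge_list Output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_tcr_graph <- function(graph, graphml = NULL, edge_list = NULL) {
  if (inherits(graph, "labeled_tcr_graph")) graph <- graph$graph
  if (!is.null(graphml)) {
    g2 <- igraph::set_vertex_attr(graph, "membership",
      value = vapply(igraph::vertex_attr(graph, "membership"),
                     paste, "", collapse = ";"))
    igraph::write_graph(g2, graphml, format = "graphml")
  }
  if (!is.null(edge_list)) {
    e <- igraph::as_data_frame(graph, what = "edges")
    write_tsv(e, edge_list)
  }
  invisible(c(graphml = graphml, edge_list = edge_list))
}
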