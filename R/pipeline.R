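# End-to-end orchestration: simulate -> repertoire/network -> signatures ->
# clonal/clock -> integrate, as a configured, logged, reproducible run.

#' Build a pipeline run configuration
#'
#' One root seed is fanned out deterministically to every stage; rerunning
#' an identical configuration reproduces every output byte for byte.
#' Simulation configurations default to the generators' standard study
#' conditions; alternatively, `clonotype_paths` may point at existing AIRR
#' TSV files (validated before any stage runs).
#'
#' @param seed Root seed.
#' @param repertoire,expression,genome Stage simulation configs (see
#'   [repertoire_sim_config()], [expression_sim_config()],
#'   [genome_sim_config()]); their seeds are overridden from the root
#'   seed.
#' @param clonotype_paths Optional character vector of AIRR TSVs to use
#'   instead of simulated repertoires.
#' @param downsample_n Clonotype downsampling target before overlap
#'   statistics (default 1000).
#' @param bootstrap_reps Network bootstrap replicates (default 10).
#' @param exhaustion_logfc Planted log2 fold-change on the exhaustion panel
#'   in the expression simulation (default 1).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            repertoire = NULL,
                            expression = NULL,
                            genome = NULL,
                            clonotype_paths = NULL,
                            downsample_n = 1000L,
                            bootstrap_reps = 10L,
                            exhaustion_logfc = 1) {
  seed <- check_count(seed, "seed", min = 0L)
  seeds <- derive_seeds(seed, 4L)
  if (is.null(repertoire))
    repertoire <- repertoire_sim_config(n_clonotypes_per_sample = 1200L)
  if (is.null(expression)) {
    panel <- exhaustion_panel()
    sets <- default_gene_sets()
    sig <- c(sets, list(EXH_PANEL = panel))
    lfc <- stats::setNames(rep(exhaustion_logfc, length(panel)), panel)
    expression <- expression_sim_config(
      n_genes = 400L, n_samples = repertoire$n_samples,
      group_labels = repertoire$groups,
      signature_genes = sig, planted_logfc = lfc)
  }
  if (is.null(genome))
    genome <- genome_sim_config(n_samples = repertoire$n_samples)
  repertoire$seed <- seeds[1L]
  expression$seed <- seeds[2L]
  genome$seed <- seeds[3L]
  if (!is.null(clonotype_paths)) {
    missing <- clonotype_paths[!file.exists(clonotype_paths)]
    if (length(missing))
      stop("pre-flight validation: missing input path(s): ",
           paste(missing, collapse = ", "))
  }
  structure(list(seed = seed, stage_seeds = seeds,
                 repertoire = repertoire, expression = expression,
                 genome = genome, clonotype_paths = clonotype_paths,
                 downsample_n = check_count(downsample_n, "downsample_n"),
                 bootstrap_reps = check_count(bootstrap_reps, "bootstrap_reps")),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' @param path YAML file whose top-level keys mirror the arguments of
#'   [pipeline_config()] (stage sub-maps mirror the simulation config
#'   constructors).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML configs requires the 'yaml' package")
  raw <- yaml::read_yaml(path)
  args <- list()
  for (nm in c("seed", "clonotype_paths", "downsample_n", "bootstrap_reps",
               "exhaustion_logfc"))
    if (!is.null(raw[[nm]])) args[[nm]] <- raw[[nm]]
  if (!is.null(raw$repertoire))
    args$repertoire <- do.call(repertoire_sim_config, raw$repertoire)
  if (!is.null(raw$expression))
    args$expression <- do.call(expression_sim_config, raw$expression)
  if (!is.null(raw$genome))
    args$genome <- do.call(genome_sim_config, raw$genome)
  do.call(pipeline_config, args)
}

run_stage <- function(name, log, expr) {
  log(sprintf("stage %s: start", name))
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) all inputs, computes repertoire diversity and
#' overlap, builds and bootstraps the distance-1 TCR network, scores the
#' immune signatures and immunophenotypes, summarizes clonal architecture
#' (Shannon subclonality, TMB, neoantigen counts), fits the molecular
#' clock, and integrates per-sample features into a masked correlation
#' matrix plus a Mann-Kendall trend test of TCR diversity over time.
#' Every stage writes self-describing TSVs; a manifest with the seeds,
#' package version, per-stage record counts and output checksums is
#' written last.
#'
#' @param config A [pipeline_config()] or the path to a YAML file.
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress progress logging.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- if (quiet) function(...) invisible() else function(msg)
    message(sprintf("[immunoclock] %s", msg))
  counts <- list()
  outputs <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    write_tsv(df, path)
    outputs <<- c(outputs, path)
    path
  }

  # ---- simulate ----------------------------------------------------------
  sim <- run_stage("simulate", log, {
    rep_sim <- if (is.null(config$clonotype_paths)) {
      simulate_repertoires(config$repertoire)
    } else {
      list(tables = lapply(config$clonotype_paths, read_clonotypes), truth = NULL)
    }
    expr_sim <- simulate_expression(config$expression)
    gen_sim <- simulate_genomes(config$genome)
    list(rep = rep_sim, expr = expr_sim, gen = gen_sim)
  })
  tables <- sim$rep$tables
  sample_ids <- vapply(tables, `[[`, "", "sample_id")
  days <- vapply(tables, `[[`, 0L, "day")
  groups <- vapply(tables, `[[`, "", "group")
  sheet <- data.frame(sample_id = sample_ids, day = days, group = groups,
                      purity = rep_len(sim$gen$samples$purity, length(sample_ids)))
  emit(sheet, "samples.tsv")
  for (t in tables)
    outputs <- c(outputs, write_clonotypes(t, file.path(out_dir,
      sprintf("clonotypes_%s.tsv", t$sample_id))))
  expr_df <- data.frame(gene = rownames(sim$expr$matrix), sim$expr$matrix,
                        check.names = FALSE)
  emit(expr_df, "expression.tsv")
  emit(sim$gen$mutations, "mutations.tsv")
  emit(sim$gen$segments, "segments.tsv")
  counts$simulate <- c(samples = length(tables),
                       clonotypes = sum(vapply(tables, function(t) nrow(t$records), 0L)),
                       genes = nrow(sim$expr$matrix),
                       mutations = nrow(sim$gen$mutations))

  # ---- repertoire --------------------------------------------------------
  seeds <- derive_seeds(config$stage_seeds[4L], 2L + length(tables))
  repert <- run_stage("repertoire", log, {
    down <- lapply(seq_along(tables), function(i)
      downsample_clonotypes(tables[[i]], config$downsample_n, seed = seeds[i]))
    div <- data.frame(sample_id = sample_ids, day = days, group = groups,
                      richness = vapply(tables, function(t) nrow(productive_records(t)), 0L),
                      inverse_simpson = vapply(tables, inverse_simpson, 0))
    k <- length(down)
    overlap <- matrix(1, k, k, dimnames = list(sample_ids, sample_ids))
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k)
      overlap[i, j] <- overlap[j, i] <- morisita_overlap(down[[i]], down[[j]])
    part <- partition_sharing(tables[groups == "sequential"],
                              tables[groups == "parallel"])
    list(down = down, div = div, overlap = overlap, part = part)
  })
  emit(repert$div, "diversity.tsv")
  emit(data.frame(sample_id = sample_ids, round(repert$overlap, 6),
                  check.names = FALSE), "overlap_morisita.tsv")
  counts$repertoire <- c(private_sequential = length(repert$part$private_a),
                         private_parallel = length(repert$part$private_b),
                         shared = length(repert$part$shared))

  # ---- network -----------------------------------------------------------
  net <- run_stage("network", log, {
    g <- build_edit1_graph(tables)
    m <- network_metrics(g)
    lab <- label_joined_network(g, stats::setNames(groups, sample_ids))
    boot <- bootstrap_metrics(tables, reps = config$bootstrap_reps,
                              seed = seeds[length(tables) + 1L])
    list(graph = g, metrics = m, labeled = lab, boot = boot)
  })
  emit(data.frame(metric = c("density", "avg_clustering", "s_metric",
                             "n_nodes", "n_edges", "n_connected_nodes"),
                  value = c(net$metrics$density, net$metrics$avg_clustering,
                            net$metrics$s_metric, net$metrics$n_nodes,
                            net$metrics$n_edges, net$metrics$n_connected_nodes)),
       "network_metrics.tsv")
  emit(net$labeled$nodes, "network_nodes.tsv")
  emit(net$labeled$components, "network_components.tsv")
  emit(net$boot$replicates, "network_bootstrap.tsv")
  write_tcr_graph(net$labeled, edge_list = file.path(out_dir, "network_edges.tsv"))
  outputs <- c(outputs, file.path(out_dir, "network_edges.tsv"))
  counts$network <- c(nodes = net$metrics$n_nodes, edges = net$metrics$n_edges,
                      connected = net$metrics$n_connected_nodes)

  # ---- signatures --------------------------------------------------------
  sig <- run_stage("signatures", log, {
    expr <- sim$expr$matrix
    sets <- default_gene_sets()
    weights <- compute_logfc_weights(expr, sim$expr$samples$class)
    scores <- score_signatures(expr, sets, exhaustion_weights = weights)
    list(scores = scores, weights = weights)
  })
  emit(sig$scores, "signature_scores.tsv")
  emit(data.frame(gene = names(sig$weights), logfc = unname(sig$weights)),
       "exhaustion_weights.tsv")
  counts$signatures <- c(samples = nrow(sig$scores))

  # ---- clonal + clock ----------------------------------------------------
  clock <- run_stage("clock", log, {
    purity <- stats::setNames(sim$gen$samples$purity, sim$gen$samples$sample_id)
    muts <- sim$gen$mutations
    muts$neoantigen <- neoantigen_filter(muts)
    fit <- mutation_clock(muts, sim$gen$segments, purity)
    clonal <- do.call(rbind, lapply(split(fit$per_mutation,
                                          fit$per_mutation$sample_id), function(d) {
      data.frame(sample_id = d$sample_id[1L],
                 shannon_h = shannon_subclonality(cluster_proportions(d$cluster_id)),
                 tmb = tmb(d, config$genome$capture_mb),
                 n_neoantigens = sum(d$neoantigen),
                 prop_subclonal = mean(d$state == "subclonal"))
    }))
    rownames(clonal) <- NULL
    list(fit = fit, clonal = clonal)
  })
  emit(clock$clonal, "clonal_architecture.tsv")
  emit(clock$fit$per_sample, "clock_per_sample.tsv")
  emit(clock$fit$per_segment, "clock_segments.tsv")
  counts$clock <- c(timed_mutations = nrow(clock$fit$per_mutation),
                    untimeable_samples = length(clock$fit$untimeable))

  # ---- integrate ---------------------------------------------------------
  integ <- run_stage("integrate", log, {
    ord <- match(clock$fit$per_sample$sample_id, sample_ids)
    features <- data.frame(
      sample_id = clock$fit$per_sample$sample_id,
      day = days[ord],
      inverse_simpson = repert$div$inverse_simpson[ord],
      exhaustion = sig$scores$exhaustion[match(clock$fit$per_sample$sample_id,
                                               sig$scores$sample_id)],
      shannon_h = clock$clonal$shannon_h[match(clock$fit$per_sample$sample_id,
                                               clock$clonal$sample_id)],
      t1 = clock$fit$per_sample$t1,
      neo_late = clock$fit$per_sample$neo_late,
      stringsAsFactors = FALSE)
    cm <- correlation_matrix(features[, -1L])
    ord_t <- order(features$day)
    mk <- mann_kendall(features$inverse_simpson[ord_t])
    list(features = features, cm = cm, mk = mk)
  })
  emit(integ$features, "features.tsv")
  emit(data.frame(feature = rownames(integ$cm$r), round(integ$cm$r, 6),
                  check.names = FALSE), "correlation_r.tsv")
  emit(data.frame(feature = rownames(integ$cm$p), signif(integ$cm$p, 6),
                  check.names = FALSE), "correlation_p.tsv")
  jsonlite::write_json(
    list(r = integ$cm$r, p = integ$cm$p, method = integ$cm$method,
         significant = integ$cm$significant,
         mann_kendall = list(S = integ$mk$S, tau = integ$mk$tau, p = integ$mk$p)),
    file.path(out_dir, "correlations.json"), digits = NA, matrix = "rowmajor")
  outputs <- c(outputs, file.path(out_dir, "correlations.json"))
  counts$integrate <- c(features = ncol(integ$features) - 1L)

  # ---- manifest ----------------------------------------------------------
  manifest <- list(
    package = "immunoclock",
    version = as.character(utils::packageVersion("immunoclock")),
    seed = config$seed,
    stage_seeds = config$stage_seeds,
    counts = counts,
    checksums = as.list(tools::md5sum(sort(outputs))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log("pipeline complete")
  invisible(manifest)
}
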