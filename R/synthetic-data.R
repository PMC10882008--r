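# Seeded synthetic-data generators with planted ground truth.
#
# The raw patient data behind the analyses this package implements are under
# restricted access, so every downstream stage is exercised on synthetic
# inputs whose generating truth is recorded alongside the data.

random_cdr3 <- function(n, min_len = 8L, max_len = 20L) {
  lens <- sample(min_len:max_len, n, replace = TRUE)
  vapply(lens, function(L) paste(sample(AA20, L, replace = TRUE), collapse = ""),
         character(1))
}

random_unique_cdr3 <- function(n, exclude = character()) {
  out <- character(0)
  while (length(out) < n) {
    cand <- unique(random_cdr3(2L * (n - length(out)) + 10L))
    cand <- setdiff(cand, c(exclude, out))
    out <- c(out, cand)
  }
  out[seq_len(n)]
}

# One random single-edit (substitution / insertion / deletion) variant,
# kept within the 8-20 CDR3 length band.
single_edit_variant <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  op <- sample(c("sub", "ins", "del"), 1L, prob = c(0.6, 0.2, 0.2))
  if (op == "del" && L <= 8L) op <- "sub"
  if (op == "ins" && L >= 20L) op <- "sub"
  if (op == "sub") {
    i <- sample.int(L, 1L)
    chars[i] <- sample(setdiff(AA20, chars[i]), 1L)
  } else if (op == "del") {
    chars <- chars[-sample.int(L, 1L)]
  } else {
    i <- sample.int(L + 1L, 1L)
    chars <- append(chars, sample(AA20, 1L), after = i - 1L)
  }
  paste(chars, collapse = "")
}

#' Configuration for the repertoire simulator
#'
#' Defaults emulate the sampling layout of a closely monitored metastatic
#' patient: four sequential on-treatment chest-wall samples followed by five
#' parallel multiregion samples taken on the same terminal day.
#'
#' @param n_samples Number of samples (>= 2).
#' @param days Per-sample collection day (days since diagnosis).
#' @param groups Per-sample group label (`sequential`/`parallel`/`blood`).
#' @param n_families Number of single-edit CDR3 sequence families planted in
#'   the clonotype pool.
#' @param family_size Sequences per family (one ancestor plus single-edit
#'   variants of it).
#' @param zipf_exponent Power-law exponent of the ranked abundance
#'   distribution (> 0).
#' @param sharing_halflife Temporal lag (days) at which expected clonotype
#'   sharing between samples halves; `Inf` removes the temporal decay.
#' @param convergence_rate Fraction per day by which later samples
#'   concentrate on a fixed convergent clonotype pool (in `[0, 1]`).
#' @param n_clonotypes_per_sample Unique clonotypes per sample.
#' @param seed Root seed.
#' @return A validated config of class `repertoire_sim_config`.
#' @export
repertoire_sim_config <- function(n_samples = 9L,
                                  days = c(373L, 799L, 1687L, 1687L, rep(2033L, 5L)),
                                  groups = c(rep("sequential", 4L), rep("parallel", 5L)),
                                  n_families = 100L,
                                  family_size = 5L,
                                  zipf_exponent = 1,
                                  sharing_halflife = 500,
                                  convergence_rate = 2e-4,
                                  n_clonotypes_per_sample = 2000L,
                                  seed = 1L) {
  n_samples <- check_count(n_samples, "n_samples", min = 2L)
  if (length(days) != n_samples || anyNA(days) || any(days < 0))
    config_error("days", "must be non-negative, one per sample")
  if (length(groups) != n_samples || !all(groups %in% c("sequential", "parallel", "blood")))
    config_error("groups", "must be sequential/parallel/blood, one per sample")
  n_families <- check_count(n_families, "n_families", min = 0L)
  family_size <- check_count(family_size, "family_size", min = 1L)
  if (!is.numeric(zipf_exponent) || length(zipf_exponent) != 1L || zipf_exponent <= 0)
    config_error("zipf_exponent", "must be a positive number")
  if (!is.numeric(sharing_halflife) || length(sharing_halflife) != 1L || sharing_halflife <= 0)
    config_error("sharing_halflife", "must be a positive number (Inf allowed)")
  check_fraction(convergence_rate, "convergence_rate")
  n_clonotypes_per_sample <- check_count(n_clonotypes_per_sample, "n_clonotypes_per_sample")
  structure(list(n_samples = n_samples, days = as.integer(round(days)),
                 groups = groups, n_families = n_families,
                 family_size = family_size, zipf_exponent = zipf_exponent,
                 sharing_halflife = sharing_halflife,
                 convergence_rate = convergence_rate,
                 n_clonotypes_per_sample = n_clonotypes_per_sample,
                 seed = check_count(seed, "seed", min = 0L)),
            class = "repertoire_sim_config")
}

#' Simulate TCR repertoires with planted sharing structure
#'
#' Clonotypes are drawn from a global pool containing planted single-edit
#' sequence families.  A day-indexed "active pool" evolves by retaining each
#' member across a lag of `dt` days with probability
#' `2^(-dt / sharing_halflife)`, so the expected fraction of clonotypes two
#' samples share decays with their temporal lag at the configured half-life.
#' Later samples additionally draw a growing fraction of their clonotypes
#' from a fixed convergent subpool (`convergence_rate` per day), emulating
#' convergent repertoire evolution.  Abundances follow a Zipf law over
#' ranked clonotypes.
#'
#' @param config A [repertoire_sim_config()].
#' @return A list with `tables` (list of [clonotype_table()]) and `truth`
#'   (family membership per pool sequence, per-sample member sets, pairwise
#'   expected sharing decay factors).
#' @export
simulate_repertoires <- function(config) {
  stopifnot(inherits(config, "repertoire_sim_config"))
  with_seed(config$seed, {
    n <- config$n_clonotypes_per_sample
    # -- global pool: families first, then unrelated filler sequences
    fam_seqs <- character(0)
    fam_id <- integer(0)
    if (config$n_families > 0L) {
      ancestors <- random_unique_cdr3(config$n_families)
      for (f in seq_len(config$n_families)) {
        members <- ancestors[f]
        while (length(members) < config$family_size) {
          v <- single_edit_variant(ancestors[f])
          if (!v %in% c(members, fam_seqs)) members <- c(members, v)
        }
        fam_seqs <- c(fam_seqs, members)
        fam_id <- c(fam_id, rep.int(f, config$family_size))
      }
    }
    pool_size <- max(4L * n, length(fam_seqs))
    filler <- random_unique_cdr3(pool_size - length(fam_seqs), exclude = fam_seqs)
    pool <- c(fam_seqs, filler)
    family_of <- c(fam_id, rep(NA_integer_, length(filler)))
    n_active <- min(length(pool), 2L * n)

    conv_pool <- sample(pool, n)

    # -- active pool per distinct day, evolving by retention
    ord_days <- sort(unique(config$days))
    active <- vector("list", length(ord_days))
    names(active) <- as.character(ord_days)
    active[[1L]] <- sample(pool, n_active)
    if (length(ord_days) > 1L) {
      for (k in 2L:length(ord_days)) {
        dt <- ord_days[k] - ord_days[k - 1L]
        p_keep <- 2^(-dt / config$sharing_halflife)
        prev <- active[[k - 1L]]
        kept <- prev[stats::runif(length(prev)) < p_keep]
        fresh <- sample(setdiff(pool, kept), n_active - length(kept))
        active[[k]] <- c(kept, fresh)
      }
    }

    day_min <- min(config$days)
    counts_ranked <- pmax(1L, as.integer(round(1000 * seq_len(n)^(-config$zipf_exponent))))
    tables <- vector("list", config$n_samples)
    members_by_sample <- vector("list", config$n_samples)
    for (s in seq_len(config$n_samples)) {
      d <- config$days[s]
      A <- active[[as.character(d)]]
      w <- min(1, config$convergence_rate * (d - day_min))
      k_conv <- min(n, round(w * n))
      conv_draw <- if (k_conv > 0L) sample(conv_pool, k_conv) else character(0)
      rest <- sample(setdiff(A, conv_draw), n - k_conv)
      members <- sample(c(conv_draw, rest))  # random rank assignment
      tables[[s]] <- clonotype_table(sprintf("S%02d", s), d, config$groups[s],
                                     cdr3_aa = members, count = counts_ranked)
      members_by_sample[[s]] <- members
    }
    names(members_by_sample) <- vapply(tables, `[[`, "", "sample_id")

    lag <- abs(outer(config$days, config$days, "-"))
    expected_sharing <- 2^(-lag / config$sharing_halflife)
    dimnames(expected_sharing) <- list(names(members_by_sample), names(members_by_sample))

    truth <- list(pool = data.frame(cdr3_aa = pool, family = family_of,
                                    convergent = pool %in% conv_pool,
                                    stringsAsFactors = FALSE),
                  members = members_by_sample,
                  expected_sharing = expected_sharing)
    list(tables = tables, truth = truth)
  })
}

#' Configuration for the expression simulator
#'
#' @param n_genes Total genes in the simulated universe (housekeeping and
#'   signature genes included).
#' @param n_samples Number of samples.
#' @param group_labels Per-sample class label; the first distinct label is
#'   the reference class.
#' @param signature_genes Named list of gene sets (character vectors).
#' @param planted_logfc Either a named numeric vector of per-gene log2
#'   fold-changes applied to every non-reference class, or a gene-by-class
#'   matrix of effects (reference column zero).
#' @param noise_sd Residual standard deviation on the log2 scale (>= 0).
#' @param n_housekeeping Number of housekeeping genes (default 10); they
#'   always receive zero planted effect.
#' @param scale `"log2"` (normalized log2 values, default) or `"counts"`
#'   (raw counts, `round(2^value)`), for exercising normalization.
#' @param seed Root seed.
#' @return A validated config of class `expression_sim_config`.
#' @export
expression_sim_config <- function(n_genes = 300L,
                                  n_samples = 9L,
                                  group_labels = c(rep("sequential", 4L), rep("parallel", 5L)),
                                  signature_genes = list(),
                                  planted_logfc = numeric(0),
                                  noise_sd = 1,
                                  n_housekeeping = 10L,
                                  scale = c("log2", "counts"),
                                  seed = 1L) {
  n_genes <- check_count(n_genes, "n_genes")
  n_samples <- check_count(n_samples, "n_samples", min = 2L)
  if (length(group_labels) != n_samples)
    config_error("group_labels", "must supply one class per sample")
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0)
    config_error("noise_sd", "must be a non-negative number")
  n_housekeeping <- check_count(n_housekeeping, "n_housekeeping", min = 1L)
  sig_genes <- unique(unlist(signature_genes))
  hk <- sprintf("HK%02d", seq_len(n_housekeeping))
  if (any(sig_genes %in% hk))
    config_error("signature_genes", "must not overlap the housekeeping genes")
  if (n_genes < n_housekeeping + length(sig_genes))
    config_error("n_genes", "universe too small for the requested signature genes")
  if (is.matrix(planted_logfc)) {
    if (is.null(rownames(planted_logfc)) || is.null(colnames(planted_logfc)))
      config_error("planted_logfc", "matrix form needs gene rownames and class colnames")
    eff_genes <- rownames(planted_logfc)
  } else if (length(planted_logfc)) {
    if (is.null(names(planted_logfc)))
      config_error("planted_logfc", "vector form must be named by gene")
    eff_genes <- names(planted_logfc)
  } else eff_genes <- character(0)
  if (any(eff_genes %in% hk))
    config_error("planted_logfc", "housekeeping genes must receive zero planted effect")
  if (!all(eff_genes %in% sig_genes))
    config_error("planted_logfc", "names signature genes absent from signature_genes")
  structure(list(n_genes = n_genes, n_samples = n_samples,
                 group_labels = as.character(group_labels),
                 signature_genes = signature_genes,
                 planted_logfc = planted_logfc, noise_sd = noise_sd,
                 n_housekeeping = n_housekeeping,
                 scale = match.arg(scale),
                 seed = check_count(seed, "seed", min = 0L)),
            class = "expression_sim_config")
}

#' Simulate a two-or-more-class expression matrix with planted effects
#'
#' Log2 values are `baseline + class effect + Normal(0, noise_sd)`.
#' Housekeeping genes have a constant baseline and zero class effect, so
#' per-sample normalization against them is exact up to noise.
#'
#' @param config An [expression_sim_config()].
#' @return A list with `matrix` (genes x samples), `housekeeping` (gene
#'   names), `samples` (data frame of sample_id and class) and `truth`
#'   (per-gene true log2 fold-change by class, per-sample class).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "expression_sim_config"))
  with_seed(config$seed, {
    hk <- sprintf("HK%02d", seq_len(config$n_housekeeping))
    sig_genes <- unique(unlist(config$signature_genes))
    n_fill <- config$n_genes - length(hk) - length(sig_genes)
    genes <- c(hk, sig_genes, sprintf("G%05d", seq_len(n_fill)))
    classes <- unique(config$group_labels)
    effects <- matrix(0, length(genes), length(classes),
                      dimnames = list(genes, classes))
    if (is.matrix(config$planted_logfc)) {
      effects[rownames(config$planted_logfc), colnames(config$planted_logfc)] <-
        config$planted_logfc
    } else if (length(config$planted_logfc)) {
      for (cl in classes[-1L])
        effects[names(config$planted_logfc), cl] <- config$planted_logfc
    }
    baseline <- c(rep(10, length(hk)), stats::rnorm(length(genes) - length(hk), 6, 1.5))
    sample_ids <- sprintf("S%02d", seq_len(config$n_samples))
    vals <- baseline + effects[, config$group_labels, drop = FALSE] +
      matrix(stats::rnorm(length(genes) * config$n_samples, 0, config$noise_sd),
             length(genes), config$n_samples)
    dimnames(vals) <- list(genes, sample_ids)
    if (config$scale == "counts") vals <- round(2^vals)
    truth <- list(true_logfc = effects,
                  class = stats::setNames(config$group_labels, sample_ids))
    list(matrix = vals, housekeeping = hk,
         samples = data.frame(sample_id = sample_ids,
                              class = config$group_labels,
                              stringsAsFactors = FALSE),
         truth = truth)
  })
}

#' Configuration for the tumor-genome simulator
#'
#' @param n_samples Number of tumor samples.
#' @param purity Per-sample tumor purity in `(0, 1]` (recycled if scalar).
#' @param segments Data frame of copy-number segments with columns
#'   `length_mb`, `major`, `minor`, `gain_time`.  Gained states are limited
#'   to (major, minor) in {(2,1), (2,2), (2,0)} with `gain_time` in
#'   `[0, 1]`; the non-gained (1,1) state must carry `NA` gain time.
#' @param mutations_per_segment Somatic mutations simulated per segment and
#'   sample.
#' @param depth_mean Mean sequencing depth (Poisson).
#' @param subclonal_fraction Fraction of mutations drawn subclonal.
#' @param subclonal_ccf_range CCF interval for subclonal mutations, inside
#'   `(0, 1)`.
#' @param neoantigen_rate Bernoulli probability that a nonsynonymous
#'   mutation yields a predicted neoepitope.
#' @param capture_mb Interrogated footprint in megabases (for mutation
#'   burden).
#' @param seed Root seed.
#' @return A validated config of class `genome_sim_config`.
#' @export
genome_sim_config <- function(n_samples = 9L,
                              purity = 0.6,
                              segments = data.frame(
                                length_mb = c(50, 50, 50, 50),
                                major = c(1L, 2L, 2L, 2L),
                                minor = c(1L, 1L, 2L, 0L),
                                gain_time = c(NA, 0.3, 0.5, 0.7)),
                              mutations_per_segment = 100L,
                              depth_mean = 100,
                              subclonal_fraction = 0.3,
                              subclonal_ccf_range = c(0.1, 0.6),
                              neoantigen_rate = 0.15,
                              capture_mb = 65,
                              seed = 1L) {
  n_samples <- check_count(n_samples, "n_samples")
  purity <- rep_len(purity, n_samples)
  if (!is.numeric(purity) || anyNA(purity) || any(purity <= 0) || any(purity > 1))
    config_error("purity", "must lie in (0, 1]")
  segments <- as.data.frame(segments)
  need <- c("length_mb", "major", "minor", "gain_time")
  if (!all(need %in% names(segments)))
    config_error("segments", paste("must have columns", paste(need, collapse = ", ")))
  state <- paste(segments$major, segments$minor)
  gained <- segments$major >= 2L
  if (!all(state %in% c("1 1", "2 1", "2 2", "2 0")))
    config_error("segments", "unsupported CN state; gained states are limited to (2,1), (2,2), (2,0)")
  if (any(gained & (is.na(segments$gain_time) | segments$gain_time < 0 | segments$gain_time > 1)))
    config_error("segments", "gained segments need gain_time in [0, 1]")
  if (any(!gained & !is.na(segments$gain_time)))
    config_error("segments", "the non-gained (1,1) state carries no gain time")
  if (any(segments$length_mb <= 0))
    config_error("segments", "length_mb must be positive")
  mutations_per_segment <- check_count(mutations_per_segment, "mutations_per_segment")
  if (!is.numeric(depth_mean) || length(depth_mean) != 1L || depth_mean <= 0)
    config_error("depth_mean", "must be positive")
  check_fraction(subclonal_fraction, "subclonal_fraction")
  ccf_range <- check_fraction(subclonal_ccf_range, "subclonal_ccf_range", len = 2L)
  if (ccf_range[1] <= 0 || ccf_range[2] >= 1 || ccf_range[1] > ccf_range[2])
    config_error("subclonal_ccf_range", "must be an interval inside (0, 1)")
  check_fraction(neoantigen_rate, "neoantigen_rate")
  if (!is.numeric(capture_mb) || length(capture_mb) != 1L || capture_mb <= 0)
    config_error("capture_mb", "must be positive")
  structure(list(n_samples = n_samples, purity = purity, segments = segments,
                 mutations_per_segment = mutations_per_segment,
                 depth_mean = depth_mean,
                 subclonal_fraction = subclonal_fraction,
                 subclonal_ccf_range = ccf_range,
                 neoantigen_rate = neoantigen_rate, capture_mb = capture_mb,
                 seed = check_count(seed, "seed", min = 0L)),
            class = "genome_sim_config")
}

# Fraction of clonal mutations carrying multiplicity 2 on a gained segment
# whose gain occurred at molecular time t, under per-copy mutation
# accumulation (see the methods vignette for the derivation).
multiplicity2_fraction <- function(major, minor, t) {
  state <- paste(major, minor)
  switch(state,
         "2 1" = t / (3 - t),
         "2 2" = t / (2 - t),
         "2 0" = t / (2 - t),
         0)
}

#' Simulate somatic mutations and copy-number segments
#'
#' Clonal mutations on a gained segment acquire multiplicity 2 when they
#' precede the segment's gain time and multiplicity 1 otherwise, in the
#' proportions implied by per-copy mutation accumulation.  The expected
#' variant allele fraction is
#' `purity * multiplicity * CCF / (purity * CN_tumor + (1 - purity) * 2)`;
#' sequencing depth is Poisson and alternate reads are Binomial.
#' Neoantigen prediction columns (`affinity_nm`, `rank_pct`, `tpm`) are
#' generated so that the standard filter (affinity <= 500 nM, rank <= 2%,
#' expression >= 5 TPM) reproduces the planted neoantigen flag exactly.
#'
#' @param config A [genome_sim_config()].
#' @return A list with `mutations` (MAF-like data frame over all samples),
#'   `segments` (SEG-like data frame with 1-based inclusive coordinates),
#'   `samples` (sample sheet with purity) and `truth` (per-mutation
#'   multiplicity, CCF, timing state and neoantigen flag; per-segment gain
#'   time).
#' @export
simulate_genomes <- function(config) {
  stopifnot(inherits(config, "genome_sim_config"))
  with_seed(config$seed, {
    segs <- config$segments
    segs$chrom <- sprintf("seg%02d", seq_len(nrow(segs)))
    segs$start <- 1L
    segs$end <- as.integer(round(segs$length_mb * 1e6))
    seg_out <- segs[, c("chrom", "start", "end", "major", "minor")]

    res <- vector("list", config$n_samples)
    sample_ids <- sprintf("S%02d", seq_len(config$n_samples))
    for (s in seq_len(config$n_samples)) {
      pur <- config$purity[s]
      per_seg <- vector("list", nrow(segs))
      for (g in seq_len(nrow(segs))) {
        n <- config$mutations_per_segment
        major <- segs$major[g]; minor <- segs$minor[g]
        cn_t <- major + minor
        gained <- major >= 2L
        subcl <- stats::runif(n) < config$subclonal_fraction
        m <- rep(1L, n)
        if (gained && any(!subcl)) {
          p2 <- multiplicity2_fraction(major, minor, segs$gain_time[g])
          m[!subcl] <- 1L + stats::rbinom(sum(!subcl), 1L, p2)
        }
        ccf <- rep(1, n)
        ccf[subcl] <- stats::runif(sum(subcl), config$subclonal_ccf_range[1],
                                   config$subclonal_ccf_range[2])
        denom <- pur * cn_t + (1 - pur) * 2
        vaf <- pur * m * ccf / denom
        depth <- pmax(1L, stats::rpois(n, config$depth_mean))
        alt <- stats::rbinom(n, depth, vaf)
        pos <- sample.int(segs$end[g], n)
        ref_base <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
        alt_base <- vapply(ref_base, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
        neo <- stats::runif(n) < config$neoantigen_rate
        affinity <- stats::runif(n, 20, 500)
        rank <- stats::runif(n, 0.05, 2)
        tpm <- stats::runif(n, 5, 80)
        viol <- sample.int(3L, n, replace = TRUE)  # which criterion fails for non-neoantigens
        affinity[!neo & viol == 1L] <- stats::runif(sum(!neo & viol == 1L), 501, 5000)
        rank[!neo & viol == 2L] <- stats::runif(sum(!neo & viol == 2L), 2.05, 50)
        tpm[!neo & viol == 3L] <- stats::runif(sum(!neo & viol == 3L), 0, 4.9)
        state <- rep(if (gained) "clonal_late" else "clonal_not_specified", n)
        if (gained) state[m == 2L] <- "clonal_early"
        state[subcl] <- "subclonal"
        cluster <- ifelse(!subcl, "C1",
                          ifelse(ccf > mean(config$subclonal_ccf_range), "S1", "S2"))
        per_seg[[g]] <- data.frame(
          sample_id = sample_ids[s], chrom = segs$chrom[g], pos = pos,
          ref = ref_base, alt = alt_base,
          ref_count = depth - alt, alt_count = alt,
          nonsynonymous = TRUE,
          affinity_nm = affinity, rank_pct = rank, tpm = tpm,
          cluster_id = cluster,
          true_multiplicity = m, true_ccf = ccf, true_state = state,
          true_neoantigen = neo,
          stringsAsFactors = FALSE)
      }
      res[[s]] <- do.call(rbind, per_seg)
    }
    all <- do.call(rbind, res)
    rownames(all) <- NULL
    truth_cols <- c("true_multiplicity", "true_ccf", "true_state", "true_neoantigen")
    truth <- list(
      mutations = cbind(all[, c("sample_id", "chrom", "pos")],
                        all[, truth_cols]),
      segments = data.frame(chrom = segs$chrom, major = segs$major,
                            minor = segs$minor, gain_time = segs$gain_time,
                            stringsAsFactors = FALSE))
    mutations <- all[, setdiff(names(all), truth_cols)]
    list(mutations = mutations, segments = seg_out,
         samples = data.frame(sample_id = sample_ids, purity = config$purity,
                              stringsAsFactors = FALSE),
         truth = truth)
  })
}
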