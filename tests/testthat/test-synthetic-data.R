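# Generators: determinism, planted structure, truth completeness and the
# closed-form read-count model.

test_that("all three simulators are deterministic given config and seed", {
  rc <- repertoire_sim_config(n_clonotypes_per_sample = 150L, seed = 11L)
  expect_identical(simulate_repertoires(rc), simulate_repertoires(rc))
  ec <- expression_sim_config(n_genes = 60L, seed = 12L)
  expect_identical(simulate_expression(ec), simulate_expression(ec))
  gc <- genome_sim_config(n_samples = 2L, mutations_per_segment = 30L, seed = 13L)
  expect_identical(simulate_genomes(gc), simulate_genomes(gc))
})

test_that("configs reject out-of-domain values naming the offending field", {
  expect_error(repertoire_sim_config(n_samples = 1L), "n_samples")
  expect_error(repertoire_sim_config(zipf_exponent = -1), "zipf_exponent")
  expect_error(repertoire_sim_config(convergence_rate = 2), "convergence_rate")
  expect_error(expression_sim_config(noise_sd = -1), "noise_sd")
  expect_error(expression_sim_config(n_genes = 5L,
    signature_genes = list(A = sprintf("X%d", 1:20))), "n_genes")
  expect_error(genome_sim_config(segments = data.frame(
    length_mb = 10, major = 3L, minor = 1L, gain_time = 0.5)), "unsupported CN state")
  expect_error(genome_sim_config(segments = data.frame(
    length_mb = 10, major = 1L, minor = 1L, gain_time = 0.5)), "gain time")
})

test_that("repertoires have the requested size and planted family structure", {
  rc <- repertoire_sim_config(n_families = 100L, family_size = 5L,
                              n_clonotypes_per_sample = 600L, seed = 21L)
  sim <- simulate_repertoires(rc)
  for (t in sim$tables) {
    expect_identical(nrow(t$records), 600L)
    expect_identical(anyDuplicated(t$records$cdr3_aa), 0L)
  }
  # brute-force edit-distance oracle over one generated family
  fam <- sim$truth$pool
  for (f in c(1L, 50L, 100L)) {
    members <- fam$cdr3_aa[!is.na(fam$family) & fam$family == f]
    expect_length(members, 5L)
    d <- utils::adist(members)
    expect_true(all(d[upper.tri(d)] <= 2))          # all built from one ancestor
    expect_true(all(utils::adist(members[1L], members[-1L]) == 1))
  }
})

test_that("repertoire abundances follow the configured Zipf law", {
  sim <- simulate_repertoires(repertoire_sim_config(
    n_clonotypes_per_sample = 400L, zipf_exponent = 1.2, seed = 3L))
  counts <- sort(sim$tables[[1L]]$records$count, decreasing = TRUE)
  expected <- pmax(1L, as.integer(round(1000 * seq_len(400L)^(-1.2))))
  expect_identical(counts, sort(expected, decreasing = TRUE))
})

test_that("infinite sharing half-life removes the temporal decay", {
  rc <- repertoire_sim_config(sharing_halflife = Inf,
                              n_clonotypes_per_sample = 400L,
                              convergence_rate = 0, seed = 31L)
  sim <- simulate_repertoires(rc)
  expect_true(all(sim$truth$expected_sharing == 1))
  # empirical pairwise shared fraction shows no systematic trend in lag
  mem <- sim$truth$members
  days <- vapply(sim$tables, `[[`, 0L, "day")
  shared <- lag <- numeric(0)
  for (i in 1:8) for (j in (i + 1):9) {
    shared <- c(shared, length(intersect(mem[[i]], mem[[j]])) / 400)
    lag <- c(lag, abs(days[i] - days[j]))
  }
  expect_gt(min(shared), 0.5 * max(shared))
})

test_that("expected clonotype sharing is non-increasing in temporal lag", {
  lags <- shared <- NULL
  for (seed in 1:20) {
    sim <- simulate_repertoires(repertoire_sim_config(
      n_clonotypes_per_sample = 200L, convergence_rate = 0, seed = seed))
    mem <- sim$truth$members
    days <- vapply(sim$tables, `[[`, 0L, "day")
    for (i in 1:8) for (j in (i + 1):9) {
      shared <- c(shared, length(intersect(mem[[i]], mem[[j]])) / 200)
      lags <- c(lags, abs(days[i] - days[j]))
    }
  }
  m <- tapply(shared, lags, mean)
  lag_vals <- as.numeric(names(m))
  ord <- order(lag_vals)
  expect_true(all(diff(m[ord]) <= 0.02))  # non-increasing up to sampling noise
})

test_that("noiseless expression reproduces the planted log fold-changes exactly", {
  genes <- sprintf("SIG%d", 1:4)
  cfg <- expression_sim_config(n_genes = 30L, n_samples = 6L,
    group_labels = rep(c("primary", "metastasis"), each = 3L),
    signature_genes = list(S = genes),
    planted_logfc = stats::setNames(c(2, -1, 0.5, 0), genes),
    noise_sd = 0, seed = 5L)
  sim <- simulate_expression(cfg)
  diff <- rowMeans(sim$matrix[genes, 4:6]) - rowMeans(sim$matrix[genes, 1:3])
  expect_equal(unname(diff), c(2, -1, 0.5, 0), tolerance = 1e-12)
  hk <- sim$housekeeping
  expect_true(all(apply(sim$matrix[hk, ], 1L, stats::sd) == 0))
})

test_that("null expression simulation is calibrated (two-class t-test)", {
  # planted_logfc = 0 everywhere: |t| below the critical value in >= 94/100 seeds
  ok <- vapply(1:100, function(s) {
    sim <- simulate_expression(expression_sim_config(
      n_genes = 15L, n_samples = 20L,
      group_labels = rep(c("a", "b"), each = 10L),
      signature_genes = list(S = "SIG1"), noise_sd = 1, seed = s))
    stats::t.test(sim$matrix["SIG1", 1:10], sim$matrix["SIG1", 11:20])$p.value >= 0.05
  }, TRUE)
  expect_gte(sum(ok), 94L)
})

test_that("simulated VAFs match the closed-form expectation per CN state", {
  cfg <- genome_sim_config(n_samples = 1L, purity = 1,
    segments = data.frame(length_mb = 20, major = 1L, minor = 1L, gain_time = NA),
    mutations_per_segment = 1000L, depth_mean = 100, subclonal_fraction = 0,
    seed = 7L)
  sim <- simulate_genomes(cfg)
  vaf <- sim$mutations$alt_count / (sim$mutations$alt_count + sim$mutations$ref_count)
  se <- stats::sd(vaf) / sqrt(length(vaf))
  expect_lt(abs(mean(vaf) - 0.5), 3 * se)   # purity 1, (1,1), clonal: E[VAF] = 0.5

  cfg2 <- genome_sim_config(n_samples = 1L, purity = 0.6,
    segments = data.frame(length_mb = 20, major = 2L, minor = 1L, gain_time = 0.5),
    mutations_per_segment = 1500L, depth_mean = 100, subclonal_fraction = 0,
    seed = 8L)
  sim2 <- simulate_genomes(cfg2)
  tr <- sim2$truth$mutations
  vaf2 <- sim2$mutations$alt_count / (sim2$mutations$alt_count + sim2$mutations$ref_count)
  denom <- 0.6 * 3 + 0.4 * 2
  for (m in 1:2) {
    sel <- tr$true_multiplicity == m
    expect_gte(sum(sel), 200L)
    se_m <- stats::sd(vaf2[sel]) / sqrt(sum(sel))
    expect_lt(abs(mean(vaf2[sel]) - 0.6 * m / denom), 3 * se_m)
  }
})

test_that("genome simulator honors the timeline boundaries", {
  cfg <- genome_sim_config(n_samples = 1L,
    segments = data.frame(length_mb = 20, major = 2L, minor = 1L, gain_time = 0),
    mutations_per_segment = 400L, subclonal_fraction = 0, seed = 9L)
  sim <- simulate_genomes(cfg)
  expect_true(all(sim$truth$mutations$true_multiplicity == 1L))  # t = 0: nothing precedes the gain
  cfg2 <- genome_sim_config(n_samples = 2L, subclonal_fraction = 0,
                            mutations_per_segment = 50L, seed = 10L)
  sim2 <- simulate_genomes(cfg2)
  expect_true(all(sim2$truth$mutations$true_state != "subclonal"))
})

test_that("every emitted record maps to exactly one truth entry", {
  sim <- simulate_genomes(genome_sim_config(n_samples = 2L,
                                            mutations_per_segment = 40L, seed = 14L))
  key_m <- with(sim$mutations, paste(sample_id, chrom, pos))
  key_t <- with(sim$truth$mutations, paste(sample_id, chrom, pos))
  expect_identical(key_m, key_t)
  expect_identical(anyDuplicated(key_m), 0L)
  # planted neoantigen flags are reproduced exactly by the stated filter
  expect_identical(neoantigen_filter(sim$mutations),
                   sim$truth$mutations$true_neoantigen)

  rep_sim <- simulate_repertoires(repertoire_sim_config(
    n_clonotypes_per_sample = 150L, seed = 15L))
  expect_identical(anyDuplicated(rep_sim$truth$pool$cdr3_aa), 0L)
  for (t in rep_sim$tables)
    expect_true(all(t$records$cdr3_aa %in% rep_sim$truth$pool$cdr3_aa))

  expr_sim <- simulate_expression(expression_sim_config(n_genes = 40L, seed = 16L))
  expect_identical(rownames(expr_sim$matrix), rownames(expr_sim$truth$true_logfc))
})
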