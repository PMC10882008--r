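# Multiplicity algebra, timing states, gain times, T1, strata, ordering.

test_that("multiplicity formula matches hand evaluations", {
  expect_equal(mutation_multiplicity(0.5, 1, 2), 1)
  expect_equal(mutation_multiplicity(0.25, 0.5, 2, 2), 1)
  expect_equal(mutation_multiplicity(2 / 3, 1, 3), 2)
  expect_error(mutation_multiplicity(0.5, 0, 2), "purity")
  # inverse-consistency with the generator's expected VAFs (noiseless)
  for (purity in c(0.4, 0.7, 1)) for (m in 1:2) for (cn in 2:4) {
    v <- purity * m / (purity * cn + (1 - purity) * 2)
    expect_equal(mutation_multiplicity(v, purity, cn), m, tolerance = 1e-12)
  }
})

test_that("timing states follow the clonal/gained/multiplicity rules", {
  segs <- data.frame(chrom = c("s1", "s2"), start = 1L, end = 1000L,
                     major = c(2L, 1L), minor = 1L)
  muts <- data.frame(chrom = c("s1", "s1", "s2", "s1"),
                     pos = c(10L, 20L, 30L, 40L),
                     ref_count = c(34, 67, 50, 60),
                     alt_count = c(66, 33, 50, 40),
                     p_clonal = c(0.9, 0.9, 0.9, 0.2),
                     ccf_ci_lower = NA_real_)
  timed <- time_mutations(muts, segs, purity = 1)
  # multiplicity-2 evidence on a gained segment -> clonal_early
  expect_identical(timed$state,
                   c("clonal_early", "clonal_late", "clonal_not_specified",
                     "subclonal"))
  expect_error(time_mutations(data.frame(chrom = "s9", pos = 1L, ref_count = 10,
                                         alt_count = 10, p_clonal = 0.9,
                                         ccf_ci_lower = NA),
                              segs, 1), "outside")
})

test_that("gain-time estimator matches hand values and clips to [0, 1]", {
  expect_equal(gain_time(2, 1, n1 = 10, n2 = 0), 0)
  expect_equal(gain_time(2, 1, n1 = 10, n2 = 10), 1)
  expect_equal(gain_time(2, 2, n1 = 20, n2 = 10), 0.5)
  expect_equal(gain_time(2, 0, n1 = 20, n2 = 10), 0.5)
  expect_equal(gain_time(2, 1, n1 = 0, n2 = 10), 1)  # clipped from 1.5
  expect_error(gain_time(1, 1, 5, 5), "unsupported")
  expect_error(gain_time(2, 1, 0, 0), "informative")
})

test_that("T1 is the weighted histogram mode with earlier-bin ties", {
  gt <- data.frame(gain_time = c(0.3, 0.3, 0.3), n1 = c(5, 5, 5), n2 = c(5, 5, 5))
  expect_equal(sample_molecular_time(gt), 0.305)
  expect_equal(sample_molecular_time(data.frame(gain_time = 0.721, n1 = 9, n2 = 1)),
               0.725)
  # bimodal: the heavier mode wins
  gt2 <- data.frame(gain_time = c(0.2, 0.8), n1 = c(90, 9), n2 = c(10, 1))
  expect_equal(sample_molecular_time(gt2), 0.205)
  # exact tie breaks toward the earlier bin
  gt3 <- data.frame(gain_time = c(0.8, 0.2), n1 = c(50, 50), n2 = c(10, 10))
  expect_equal(sample_molecular_time(gt3), 0.205)
  expect_error(sample_molecular_time(data.frame(gain_time = NA_real_,
                                                n1 = 1, n2 = 1)), "untimeable")
})

test_that("quartile stratification follows the stated conventions", {
  t1 <- stats::setNames(1:8, paste0("s", 1:8))
  st <- stratify_quartiles(t1)
  expect_identical(as.vector(table(st)), c(2L, 4L, 2L))
  expect_identical(names(st)[st == "early"], c("s1", "s2"))
  expect_identical(names(st)[st == "late"], c("s7", "s8"))
  # degenerate all-equal input: all early under the tie rule
  st2 <- stratify_quartiles(stats::setNames(rep(0.4, 5), paste0("s", 1:5)))
  expect_true(all(st2 == "early"))
  expect_error(stratify_quartiles(c(a = 1, b = 2, c = 3)), "4 samples")
  # strata partition the cohort
  set.seed(3)
  st3 <- stratify_quartiles(stats::runif(17))
  expect_identical(sum(table(st3)), 17L)
})

test_that("Neoantigen Time maps states onto the three transitions", {
  nt <- neoantigen_time(rep("clonal_early", 5), rep(TRUE, 5))
  expect_equal(unname(nt$proportions), c(1, 0, 0))
  states <- c("clonal_early", "clonal_late", "clonal_not_specified", "subclonal")
  nt2 <- neoantigen_time(states, rep(TRUE, 4))
  expect_equal(unname(nt2$proportions), c(0.25, 0.5, 0.25))
  expect_equal(sum(nt2$proportions), 1)
  nt3 <- neoantigen_time(states, rep(FALSE, 4))
  expect_true(nt3$no_neoantigens)
  expect_true(all(is.na(nt3$proportions)))
})

test_that("timing-based clustering orders samples sensibly", {
  m <- rbind(a = c(0.1, 0.2, 0.1), b = c(0.1, 0.2, 0.1),
             c = c(0.8, 0.9, 0.85), d = c(0.82, 0.88, 0.9))
  cl <- cluster_by_timing(m)
  expect_equal(cl$hclust$height[1L], 0)            # identical samples merge first
  k2 <- stats::cutree(cl$hclust, 2L)
  expect_identical(k2[["a"]], k2[["b"]])           # first split separates groups
  expect_identical(k2[["c"]], k2[["d"]])
  expect_false(k2[["a"]] == k2[["c"]])
  expect_identical(cl$order, cluster_by_timing(m)$order)  # deterministic
  # mean imputation of untimed segments; all-missing sample errors
  m2 <- m; m2["a", 2L] <- NA
  expect_silent(cluster_by_timing(m2))
  m3 <- m; m3["a", ] <- NA
  expect_error(cluster_by_timing(m3), "no timed segments")
})

test_that("full clock fit recovers planted gain times and strata", {
  planted <- c(0.05, 0.08, 0.45, 0.5, 0.5, 0.55, 0.92, 0.95)
  segs <- data.frame(length_mb = rep(25, 3), major = 2L, minor = 1L, gain_time = NA)
  sims <- lapply(seq_along(planted), function(i) {
    s <- segs; s$gain_time <- planted[i]
    simulate_genomes(genome_sim_config(n_samples = 1L, purity = 0.6,
      segments = s, mutations_per_segment = 250L, depth_mean = 100,
      subclonal_fraction = 0.2, seed = 500L + i))
  })
  muts <- do.call(rbind, lapply(seq_along(sims), function(i) {
    m <- sims[[i]]$mutations; m$sample_id <- sprintf("P%02d", i); m
  }))
  fit <- mutation_clock(muts, sims[[1L]]$segments, purity = 0.6)
  expect_lt(max(abs(fit$per_sample$t1 - planted)), 0.1)
  st <- fit$per_sample$stratum
  expect_identical(as.character(st[1:2]), rep("early", 2L))
  expect_identical(as.character(st[7:8]), rep("late", 2L))
  expect_identical(as.character(st[3:6]), rep("inter", 4L))
  # neo proportions sum to 1 where defined
  ok <- !is.na(fit$per_sample$neo_early)
  expect_equal(rowSums(fit$per_sample[ok, c("neo_early", "neo_inter", "neo_late")]),
               rep(1, sum(ok)), ignore_attr = TRUE)
})

test_that("estimated multiplicity is close to truth at realistic depth", {
  sim <- simulate_genomes(genome_sim_config(n_samples = 1L, purity = 0.6,
    segments = data.frame(length_mb = 25, major = 2L, minor = 1L, gain_time = 0.5),
    mutations_per_segment = 600L, depth_mean = 80, subclonal_fraction = 0,
    seed = 77L))
  timed <- time_mutations(sim$mutations, sim$segments, 0.6)
  agree <- timed$multiplicity == sim$truth$mutations$true_multiplicity
  expect_gte(mean(agree), 0.95)
})
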