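# Mutation/neoantigen molecular-clock timing: multiplicity inference, four
# timing states, gain-time estimation, per-sample molecular time (T1),
# quartile stratification and timing-based sample ordering.

#' Mutation multiplicity from VAF, purity and copy number
#'
#' `m = vaf * (purity * cn_tumor + (1 - purity) * cn_normal) / purity`:
#' the expected number of mutated allele copies per tumor cell carried by a
#' clonal mutation observed at the given variant allele fraction.
#'
#' @param vaf Variant allele fraction in `[0, 1]`.
#' @param purity Tumor purity in `(0, 1]`.
#' @param cn_tumor Total tumor copy number at the locus (>= 1).
#' @param cn_normal Normal copy number (default 2).
#' @return Continuous multiplicity (>= 0).
#' @export
mutation_multiplicity <- function(vaf, purity, cn_tumor, cn_normal = 2) {
  if (any(purity <= 0)) stop("purity must be > 0")
  if (any(purity > 1)) stop("purity must be <= 1")
  if (any(cn_tumor < 1)) stop("cn_tumor must be >= 1")
  if (any(vaf < 0 | vaf > 1)) stop("vaf must lie in [0, 1]")
  vaf * (purity * cn_tumor + (1 - purity) * cn_normal) / purity
}

# Locate the (single) containing segment for each mutation; segments use
# 1-based inclusive coordinates on ingest.
locate_segments <- function(mutations, segments) {
  idx <- rep(NA_integer_, nrow(mutations))
  hits <- rep(0L, nrow(mutations))
  for (g in seq_len(nrow(segments))) {
    inside <- mutations$chrom == segments$chrom[g] &
      mutations$pos >= segments$start[g] & mutations$pos <= segments$end[g]
    hits <- hits + inside
    idx[inside] <- g
  }
  if (any(hits == 0L)) {
    bad <- mutations[hits == 0L, c("chrom", "pos")]
    stop("mutation(s) outside all segments: ",
         paste(utils::head(paste0(bad$chrom, ":", bad$pos), 5L), collapse = ", "),
         if (nrow(bad) > 5L) sprintf(" (and %d more)", nrow(bad) - 5L) else "")
  }
  if (any(hits > 1L)) {
    bad <- mutations[hits > 1L, c("chrom", "pos")]
    stop("mutation(s) overlapping multiple segments: ",
         paste(utils::head(paste0(bad$chrom, ":", bad$pos), 5L), collapse = ", "))
  }
  idx
}

#' Assign the four timing states to mutations
#'
#' Each mutation is first called clonal or subclonal ([classify_clonal()];
#' when the table lacks `p_clonal` / `ccf_ci_lower` columns, the evidence
#' is computed from read counts with [estimate_clonality()]).  Subclonal
#' mutations are state `subclonal` regardless of segment.  Clonal mutations
#' on a gained segment are assigned the integer multiplicity (1 or 2) that
#' maximizes the binomial read-count likelihood: multiplicity 2 (acquired
#' before the gain, then duplicated) is `clonal_early`, multiplicity 1 is
#' `clonal_late`.  Clonal mutations on a non-gained segment are
#' `clonal_not_specified`.
#'
#' @param mutations MAF-like data frame (one sample) with `chrom`, `pos`,
#'   `ref_count`, `alt_count`, optionally `p_clonal` / `ccf_ci_lower`.
#' @param segments SEG-like data frame with `chrom`, `start`, `end`,
#'   `major`, `minor` (1-based inclusive).
#' @param purity Tumor purity of the sample.
#' @return The mutation table with added columns `segment` (row index into
#'   `segments`), `multiplicity`, `clonality` and `state`.
#' @export
time_mutations <- function(mutations, segments, purity) {
  if (nrow(mutations) == 0L) stop("no mutations to time")
  idx <- locate_segments(mutations, segments)
  major <- segments$major[idx]; minor <- segments$minor[idx]
  depth <- mutations$ref_count + mutations$alt_count

  if (all(c("p_clonal", "ccf_ci_lower") %in% names(mutations)) &&
      !all(is.na(mutations$p_clonal) & is.na(mutations$ccf_ci_lower))) {
    clonality <- classify_clonal(mutations$p_clonal, mutations$ccf_ci_lower)
  } else if ("p_clonal" %in% names(mutations) && !all(is.na(mutations$p_clonal))) {
    clonality <- classify_clonal(p_clonal = mutations$p_clonal)
  } else {
    est <- estimate_clonality(mutations$alt_count, depth, purity, major, minor)
    clonality <- classify_clonal(est$p_clonal, est$ccf_lower)
  }

  cn_t <- major + minor
  denom <- purity * cn_t + (1 - purity) * 2
  v1 <- pmin(1, purity / denom)
  v2 <- pmin(1, purity * 2 / denom)
  m <- ifelse(stats::dbinom(mutations$alt_count, depth, v2, log = TRUE) >
                stats::dbinom(mutations$alt_count, depth, v1, log = TRUE), 2L, 1L)
  gained <- major >= 2L
  m[!gained | clonality == "subclonal"] <- 1L

  state <- ifelse(clonality == "subclonal", "subclonal",
                  ifelse(!gained, "clonal_not_specified",
                         ifelse(m == 2L, "clonal_early", "clonal_late")))
  out <- mutations
  out$segment <- idx
  out$multiplicity <- m
  out$clonality <- clonality
  out$state <- state
  out
}

#' Relative timing of a copy-number gain
#'
#' From the counts of clonal multiplicity-1 (`n1`) and multiplicity-2
#' (`n2`) mutations on a gained segment, the gain time on the 0-1 mutation
#' timeline is `3 n2 / (2 n2 + n1)` for (major, minor) = (2,1) and
#' `2 n2 / (2 n2 + n1)` for (2,2) and (2,0), clipped to `[0, 1]`.
#'
#' @param major,minor Allele-specific copy numbers; must be a gained state.
#' @param n1,n2 Informative clonal mutation counts (`n1 + n2 >= 1`).
#' @return Gain time `t` in `[0, 1]`.
#' @export
gain_time <- function(major, minor, n1, n2) {
  state <- paste(major, minor)
  if (!state %in% c("2 1", "2 2", "2 0"))
    stop("unsupported copy-number state for timing: (", major, ",", minor, ")")
  if (n1 + n2 < 1) stop("at least one informative mutation is required")
  coef <- if (state == "2 1") 3 else 2
  min(1, max(0, coef * n2 / (2 * n2 + n1)))
}

#' Gain times for all gained segments of a timed sample
#'
#' With `method = "mixture"` (the default when `purity` is supplied) the
#' multiplicity-2 fraction of each segment's clonal mutations is the
#' maximum-likelihood weight of a two-component binomial mixture (expected
#' VAFs of multiplicities 1 and 2), fitted by EM; the gain time is then
#' [gain_time()] applied to the effective counts.  This removes the
#' contamination bias that hard multiplicity assignment incurs when one
#' multiplicity class dominates.  `method = "counts"` (and the fallback
#' when `purity` is absent) instead counts the hard `clonal_early` /
#' `clonal_late` state calls.  The reported `n1`, `n2` are always the hard
#' informative-mutation counts.
#'
#' @param timed Output of [time_mutations()].
#' @param segments The segment table used for timing.
#' @param purity Tumor purity (enables the mixture method).
#' @param method `"mixture"` or `"counts"`.
#' @return Data frame with one row per gained segment: `segment`, `chrom`,
#'   `major`, `minor`, `n1`, `n2`, `gain_time` (NA when no informative
#'   clonal mutations).
#' @export
segment_gain_times <- function(timed, segments, purity = NULL,
                               method = c("mixture", "counts")) {
  method <- match.arg(method)
  if (is.null(purity)) method <- "counts"
  gained <- which(segments$major >= 2L)
  rows <- lapply(gained, function(g) {
    on_seg <- timed$segment == g
    n1 <- sum(on_seg & timed$state == "clonal_late")
    n2 <- sum(on_seg & timed$state == "clonal_early")
    t <- if (n1 + n2 < 1) NA_real_
    else if (method == "counts") {
      gain_time(segments$major[g], segments$minor[g], n1, n2)
    } else {
      cl <- on_seg & timed$clonality == "clonal"
      alt <- timed$alt_count[cl]
      depth <- timed$alt_count[cl] + timed$ref_count[cl]
      cn_t <- segments$major[g] + segments$minor[g]
      denom <- purity * cn_t + (1 - purity) * 2
      l1 <- stats::dbinom(alt, depth, min(1, purity / denom))
      l2 <- stats::dbinom(alt, depth, min(1, purity * 2 / denom))
      pi2 <- (n2 + 0.5) / (n1 + n2 + 1)  # smoothed start so EM can leave 0
      for (it in seq_len(200L)) {
        w <- pi2 * l2 / (pi2 * l2 + (1 - pi2) * l1)
        w[is.na(w)] <- pi2
        pi_new <- min(1, max(0, mean(w)))
        if (abs(pi_new - pi2) < 1e-9) { pi2 <- pi_new; break }
        pi2 <- pi_new
      }
      n_eff <- length(alt)
      gain_time(segments$major[g], segments$minor[g],
                (1 - pi2) * n_eff, pi2 * n_eff)
    }
    data.frame(segment = g, chrom = segments$chrom[g],
               major = segments$major[g], minor = segments$minor[g],
               n1 = n1, n2 = n2, gain_time = t, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-sample molecular time (T1) from the mode of first-gain times
#'
#' Builds a histogram over `[0, 1]` (default 100 bins) of the per-segment
#' gain times, weighted by each segment's informative-mutation count
#' (`n1 + n2`), and returns the midpoint of the maximal bin; ties break
#' toward the earlier bin.
#'
#' @param gain_times Data frame from [segment_gain_times()] (rows with `NA`
#'   gain time are ignored), or a numeric vector of gain times.
#' @param weights Optional weights when `gain_times` is a numeric vector.
#' @param bins Number of histogram bins (default 100).
#' @return T1 in `[0, 1]`.
#' @export
sample_molecular_time <- function(gain_times, weights = NULL, bins = 100L) {
  if (is.data.frame(gain_times)) {
    keep <- !is.na(gain_times$gain_time)
    t <- gain_times$gain_time[keep]
    w <- (gain_times$n1 + gain_times$n2)[keep]
  } else {
    t <- gain_times[!is.na(gain_times)]
    w <- rep_len(weights %||% 1, length(gain_times))[!is.na(gain_times)]
  }
  if (length(t) == 0L) stop("untimeable sample: no timed gained segments")
  idx <- pmin(floor(t * bins), bins - 1L) + 1L
  h <- vapply(seq_len(bins), function(b) sum(w[idx == b]), 0)
  top <- which.max(h)  # which.max takes the earliest maximal bin
  (top - 0.5) / bins
}

#' Stratify samples into early / inter / late molecular-time strata
#'
#' The cohort quartiles (linear-interpolation, type 7) of T1 define the
#' strata: T1 <= Q25 is early, T1 >= Q75 is late, anything else inter.
#' Boundaries are inclusive on both sides with early taking precedence
#' over late, so a degenerate all-equal cohort is all early.
#'
#' @param t1_by_sample Named numeric vector of per-sample T1 (>= 4
#'   samples).
#' @return Named factor with levels `early`, `inter`, `late`.
#' @export
stratify_quartiles <- function(t1_by_sample) {
  if (length(t1_by_sample) < 4L) stop("at least 4 samples are required")
  q <- stats::quantile(t1_by_sample, c(0.25, 0.75), type = 7, names = FALSE)
  s <- ifelse(t1_by_sample <= q[1L], "early",
              ifelse(t1_by_sample >= q[2L], "late", "inter"))
  factor(stats::setNames(s, names(t1_by_sample)),
         levels = c("early", "inter", "late"))
}

#' Neoantigen Time: early / inter / late proportions of neoantigens
#'
#' Restricts a sample's timed mutations to predicted neoantigens and maps
#' the four timing states onto the three time transitions: clonal_early
#' to neo-early; clonal_late and clonal_not_specified to neo-inter;
#' subclonal to neo-late.
#'
#' @param states Character vector of timing states (from
#'   [time_mutations()]).
#' @param neo_flags Logical vector marking predicted neoantigens (e.g.
#'   [neoantigen_filter()]).
#' @return A list of class `neoantigen_time`: `proportions` (named
#'   `neo_early`, `neo_inter`, `neo_late`, summing to 1), `n_neoantigens`,
#'   and `no_neoantigens` (flag; proportions are `NA` when set).
#' @export
neoantigen_time <- function(states, neo_flags) {
  stopifnot(length(states) == length(neo_flags))
  st <- states[neo_flags]
  if (length(st) == 0L)
    return(structure(list(proportions = c(neo_early = NA_real_,
                                          neo_inter = NA_real_,
                                          neo_late = NA_real_),
                          n_neoantigens = 0L, no_neoantigens = TRUE),
                     class = "neoantigen_time"))
  p <- c(neo_early = mean(st == "clonal_early"),
         neo_inter = mean(st %in% c("clonal_late", "clonal_not_specified")),
         neo_late = mean(st == "subclonal"))
  structure(list(proportions = p, n_neoantigens = length(st),
                 no_neoantigens = FALSE),
            class = "neoantigen_time")
}

#' @export
print.neoantigen_time <- function(x, ...) {
  if (x$no_neoantigens) cat("Neoantigen Time: no neoantigens in sample\n")
  else cat(sprintf("Neoantigen Time (%d neoantigens): early %.2f, inter %.2f, late %.2f\n",
                   x$n_neoantigens, x$proportions[1L], x$proportions[2L],
                   x$proportions[3L]))
  invisible(x)
}

#' Order samples by hierarchical clustering of timed segments
#'
#' Agglomerative clustering (Euclidean distance, average linkage) of the
#' samples-by-segments matrix of gain times.  Untimed segments enter as
#' missing values and are mean-imputed per segment; segments untimed in
#' every sample are dropped.
#'
#' @param timing_matrix Numeric matrix, samples in rows, segments in
#'   columns, `NA` for untimed entries.
#' @param method Linkage (default `"average"`).
#' @return A list with `order` (sample names in leaf order) and `hclust`
#'   (the [stats::hclust] object).
#' @export
cluster_by_timing <- function(timing_matrix, method = "average") {
  if (nrow(timing_matrix) < 2L) stop("at least 2 samples are required")
  all_missing <- rowSums(!is.na(timing_matrix)) == 0L
  if (any(all_missing))
    stop("sample(s) with no timed segments: ",
         paste(rownames(timing_matrix)[all_missing], collapse = ", "))
  keep <- colSums(!is.na(timing_matrix)) > 0L
  m <- timing_matrix[, keep, drop = FALSE]
  for (j in seq_len(ncol(m))) {
    mu <- mean(m[, j], na.rm = TRUE)
    m[is.na(m[, j]), j] <- mu
  }
  hc <- stats::hclust(stats::dist(m), method = method)
  list(order = rownames(m)[hc$order], hclust = hc)
}

#' Fit the molecular clock across samples
#'
#' Runs the full timing analysis: per-mutation timing states, per-segment
#' gain times, per-sample molecular time (T1) and quartile stratum,
#' Neoantigen Time proportions, and the timing-based hierarchical sample
#' ordering.
#'
#' @param mutations MAF-like data frame over all samples (column
#'   `sample_id`); neoantigen flags are taken from a logical `neoantigen`
#'   column if present, otherwise computed with [neoantigen_filter()] when
#'   the prediction columns exist.
#' @param segments SEG-like segment table (shared across samples) or a
#'   named list of per-sample tables.
#' @param purity Named per-sample purities (or a scalar).
#' @param bins Histogram bins for T1 (default 100).
#' @return An object of class `mutation_clock`: `per_mutation`,
#'   `per_segment`, `per_sample` (T1, stratum, neo proportions),
#'   `clustering` and `untimeable` (samples without timed gains).
#' @export
mutation_clock <- function(mutations, segments, purity, bins = 100L) {
  samples <- unique(mutations$sample_id)
  purity <- if (length(purity) == 1L && is.null(names(purity)))
    stats::setNames(rep(purity, length(samples)), samples) else purity
  missing_pur <- setdiff(samples, names(purity))
  if (length(missing_pur))
    stop("purity missing for sample(s): ", paste(missing_pur, collapse = ", "))
  seg_for <- function(s) if (is.data.frame(segments)) segments else segments[[s]]

  per_mut <- vector("list", length(samples))
  per_seg <- vector("list", length(samples))
  t1 <- stats::setNames(rep(NA_real_, length(samples)), samples)
  neo <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    s <- samples[i]
    mu <- mutations[mutations$sample_id == s, , drop = FALSE]
    sg <- seg_for(s)
    timed <- time_mutations(mu, sg, purity[[s]])
    gt <- segment_gain_times(timed, sg, purity = purity[[s]])
    t1[i] <- tryCatch(sample_molecular_time(gt, bins = bins),
                      error = function(e) NA_real_)
    flags <- if ("neoantigen" %in% names(timed)) timed$neoantigen
             else if (all(c("affinity_nm", "rank_pct", "tpm") %in% names(timed)))
               neoantigen_filter(timed)
             else rep(FALSE, nrow(timed))
    neo[[i]] <- neoantigen_time(timed$state, flags)
    gt$sample_id <- s
    per_mut[[i]] <- timed
    per_seg[[i]] <- gt
  }
  per_mutation <- do.call(rbind, per_mut)
  per_segment <- do.call(rbind, per_seg)

  timeable <- !is.na(t1)
  stratum <- factor(rep(NA_character_, length(samples)),
                    levels = c("early", "inter", "late"))
  names(stratum) <- samples
  if (sum(timeable) >= 4L)
    stratum[timeable] <- stratify_quartiles(t1[timeable])

  neo_mat <- t(vapply(neo, function(x) x$proportions, numeric(3L)))
  per_sample <- data.frame(sample_id = samples, t1 = unname(t1),
                           stratum = unname(stratum),
                           neo_early = neo_mat[, 1L], neo_inter = neo_mat[, 2L],
                           neo_late = neo_mat[, 3L],
                           n_neoantigens = vapply(neo, `[[`, 0L, "n_neoantigens"),
                           stringsAsFactors = FALSE)

  clustering <- NULL
  if (sum(timeable) >= 2L) {
    wide <- tapply(per_segment$gain_time,
                   list(per_segment$sample_id, per_segment$chrom),
                   function(x) x[1L])
    wide <- wide[samples[timeable], , drop = FALSE]
    clustering <- tryCatch(cluster_by_timing(wide), error = function(e) NULL)
  }
  structure(list(per_mutation = per_mutation, per_segment = per_segment,
                 per_sample = per_sample, clustering = clustering,
                 untimeable = samples[!timeable], bins = bins),
            class = "mutation_clock")
}

#' @export
print.mutation_clock <- function(x, ...) {
  cat(sprintf("Molecular clock fit: %d samples, %d mutations, %d timed segments\n",
              nrow(x$per_sample), nrow(x$per_mutation),
              sum(!is.na(x$per_segment$gain_time))))
  if (length(x$untimeable))
    cat("  untimeable sample(s): ", paste(x$untimeable, collapse = ", "), "\n")
  print(x$per_sample, digits = 3)
  invisible(x)
}

#' @export
summary.mutation_clock <- function(object, ...) {
  st <- table(object$per_mutation$state)
  cat("Timing states:\n"); print(st)
  cat("\nStrata:\n"); print(table(object$per_sample$stratum, useNA = "ifany"))
  cat("\nT1 distribution:\n"); print(summary(object$per_sample$t1))
  if (!is.null(object$clustering))
    cat("\nLeaf order: ", paste(object$clustering$order, collapse = " < "), "\n")
  invisible(object)
}
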