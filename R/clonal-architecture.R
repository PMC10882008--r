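# Clonality calls, subclonal diversity, mutation burden and neoantigen
# filtering.

#' Estimate cancer cell fraction and clonality probability from read counts
#'
#' For mutation callsets that do not carry external clonality annotations,
#' computes per mutation: the CCF point estimate and its 95% Clopper-Pearson
#' confidence interval (binomial interval on the VAF propagated through the
#' multiplicity algebra), and a clonality probability from a two-hypothesis
#' binomial model: the clonal hypothesis fixes CCF = 1 and maximizes the
#' binomial likelihood over integer multiplicities `1..major`; the
#' subclonal hypothesis has multiplicity 1 and CCF uniform on (0, 1),
#' integrated numerically.  By default the mixture weight of the two
#' hypotheses is estimated from the callset itself by
#' expectation-maximization (as cluster-based clonality callers do), so
#' that a mostly clonal sample does not over-call borderline mutations as
#' subclonal; `prior_clonal` fixes the weight instead.
#'
#' @param alt,depth Alternate read counts and total depths.
#' @param purity Tumor purity in (0, 1].
#' @param major,minor Allele-specific copy numbers of the containing
#'   segment (recycled).
#' @param grid Number of CCF grid points for the subclonal marginal.
#' @param prior_clonal `NULL` (default) to estimate the clonal mixture
#'   weight by EM across the supplied mutations, or a fixed prior
#'   probability in (0, 1).
#' @return Data frame with columns `ccf`, `ccf_lower`, `ccf_upper`,
#'   `p_clonal`, `multiplicity` (the likelihood-maximizing integer).
#' @export
estimate_clonality <- function(alt, depth, purity, major, minor, grid = 200L,
                               prior_clonal = NULL) {
  n <- length(alt)
  stopifnot(length(depth) == n, all(depth > 0), all(alt >= 0), all(alt <= depth))
  if (any(purity <= 0) || any(purity > 1)) stop("purity must lie in (0, 1]")
  purity <- rep_len(purity, n)
  major <- rep_len(major, n); minor <- rep_len(minor, n)
  cn_t <- major + minor
  denom <- purity * cn_t + (1 - purity) * 2

  m_max <- pmax(1L, major)
  lik_c <- rep(-Inf, n)
  m_hat <- rep(1L, n)
  for (m in seq_len(max(m_max))) {
    use <- m_max >= m
    v <- pmin(1, purity * m / denom)
    l <- ifelse(use, stats::dbinom(alt, depth, v, log = TRUE), -Inf)
    better <- l > lik_c
    m_hat[better] <- m
    lik_c[better] <- l[better]
  }
  cc <- (seq_len(grid) - 0.5) / grid
  vv <- pmin(1, (purity / denom) %o% cc)
  lik_s <- rowMeans(matrix(stats::dbinom(alt, depth, vv), n, grid))
  l_c <- exp(lik_c)
  if (is.null(prior_clonal)) {
    pi_c <- 0.5
    for (it in seq_len(200L)) {
      w <- pi_c * l_c / (pi_c * l_c + (1 - pi_c) * lik_s)
      pi_new <- min(0.99, max(0.01, mean(w)))
      if (abs(pi_new - pi_c) < 1e-8) { pi_c <- pi_new; break }
      pi_c <- pi_new
    }
  } else {
    if (prior_clonal <= 0 || prior_clonal >= 1) stop("prior_clonal must lie in (0, 1)")
    pi_c <- prior_clonal
  }
  p_clonal <- pi_c * l_c / (pi_c * l_c + (1 - pi_c) * lik_s)

  vaf <- alt / depth
  scale_ccf <- denom / (purity * m_hat)
  lo <- ifelse(alt == 0, 0, stats::qbeta(0.025, alt, depth - alt + 1))
  hi <- ifelse(alt == depth, 1, stats::qbeta(0.975, alt + 1, depth - alt))
  data.frame(ccf = pmin(2, vaf * scale_ccf),
             ccf_lower = pmin(2, lo * scale_ccf),
             ccf_upper = pmin(2, hi * scale_ccf),
             p_clonal = p_clonal,
             multiplicity = m_hat)
}

#' Classify mutations as clonal or subclonal
#'
#' A mutation is clonal when its probability of being clonal exceeds 50%,
#' or when the lower bound of the 95% confidence interval of its cancer
#' cell fraction exceeds 0.9; otherwise it is subclonal.  At least one of
#' the two pieces of evidence must be present per mutation.
#'
#' @param p_clonal Clonality probabilities (may contain `NA`).
#' @param ccf_ci_lower Lower 95% CI bounds of the CCF (may contain `NA`).
#' @return Character vector, `"clonal"` or `"subclonal"`.
#' @export
classify_clonal <- function(p_clonal = NULL, ccf_ci_lower = NULL) {
  n <- max(length(p_clonal), length(ccf_ci_lower))
  if (n == 0L) stop("neither p_clonal nor ccf_ci_lower present")
  p_clonal <- rep_len(p_clonal %||% NA_real_, n)
  ccf_ci_lower <- rep_len(ccf_ci_lower %||% NA_real_, n)
  both_missing <- is.na(p_clonal) & is.na(ccf_ci_lower)
  if (any(both_missing))
    stop("neither p_clonal nor ccf_ci_lower present for ", sum(both_missing),
         " mutation(s)")
  clonal <- (!is.na(p_clonal) & p_clonal > 0.5) |
    (!is.na(ccf_ci_lower) & ccf_ci_lower > 0.9)
  ifelse(clonal, "clonal", "subclonal")
}

#' Cluster proportions from mutation cluster assignments
#'
#' @param cluster_id Per-mutation cluster assignments, or a named numeric
#'   vector of cellular prevalences when `method = "prevalence"`.
#' @param method `"mutation_fraction"` (default: each cluster's share of
#'   mutations) or `"prevalence"` (normalized cellular prevalence).
#' @return Named proportions summing to 1.
#' @export
cluster_proportions <- function(cluster_id,
                                method = c("mutation_fraction", "prevalence")) {
  method <- match.arg(method)
  if (method == "mutation_fraction") {
    if (length(cluster_id) == 0L) stop("no cluster assignments")
    tab <- table(cluster_id)
    p <- as.numeric(tab) / sum(tab)
    names(p) <- names(tab)
  } else {
    if (length(cluster_id) == 0L || any(cluster_id < 0) || sum(cluster_id) == 0)
      stop("prevalences must be non-negative and not all zero")
    p <- cluster_id / sum(cluster_id)
  }
  structure(p, provenance = method)
}

#' Shannon-Wiener subclonal diversity index
#'
#' `H = -sum(p_i * log2(p_i))` over clonal-cluster proportions, in bits.
#' Zero-probability clusters are dropped (they do not change H); H is 0
#' for a single cluster and `log2(s)` at uniform proportions over `s`
#' clusters.
#'
#' @param props Proportions (or positive counts, normalized internally),
#'   e.g. from [cluster_proportions()].
#' @return H in bits (>= 0).
#' @export
shannon_subclonality <- function(props) {
  if (length(props) == 0L) stop("empty cluster proportions")
  if (any(props < 0) || anyNA(props)) stop("proportions must be non-negative")
  props <- props[props > 0]
  if (length(props) == 0L) stop("all proportions are zero")
  p <- props / sum(props)
  -sum(p * log2(p))
}

#' Tumor mutational burden
#'
#' Nonsynonymous somatic mutations per megabase of the interrogated
#' footprint (65 Mb for the Agilent exome capture, 37 Mb for Nextera).
#'
#' @param mutations Data frame with a logical `nonsynonymous` column, or a
#'   plain mutation count.
#' @param capture_mb Interrogated megabases (> 0).
#' @return Mutations per megabase.
#' @export
tmb <- function(mutations, capture_mb = 65) {
  if (!is.numeric(capture_mb) || length(capture_mb) != 1L || capture_mb <= 0)
    stop("capture_mb must be a positive number")
  n <- if (is.data.frame(mutations)) {
    if (!"nonsynonymous" %in% names(mutations))
      stop("mutation table lacks a 'nonsynonymous' column")
    sum(mutations$nonsynonymous)
  } else {
    if (length(mutations) != 1L || mutations < 0) stop("invalid mutation count")
    mutations
  }
  n / capture_mb
}

#' Filter mutations to predicted neoantigens
#'
#' A nonsynonymous mutation passes when its predicted MHC binding affinity
#' is <= 500 nM, its binding rank percentile is <= 2%, and the
#' corresponding gene is expressed at >= 5 TPM.  All thresholds are
#' inclusive.  The three criteria are combined with AND by default;
#' `require_both_binding = FALSE` relaxes the binding pair to affinity OR
#' rank.
#'
#' @param mutations Data frame with columns `affinity_nm`, `rank_pct`,
#'   `tpm` and `nonsynonymous`.
#' @param affinity_max,rank_max,tpm_min Thresholds (defaults 500 nM, 2%,
#'   5 TPM).
#' @param require_both_binding Combine affinity and rank with AND (default)
#'   or OR.
#' @return Logical vector: passes the neoantigen filter.
#' @export
neoantigen_filter <- function(mutations, affinity_max = 500, rank_max = 2,
                              tpm_min = 5, require_both_binding = TRUE) {
  need <- c("affinity_nm", "rank_pct", "tpm", "nonsynonymous")
  missing <- setdiff(need, names(mutations))
  if (length(missing))
    stop("missing prediction field(s): ", paste(missing, collapse = ", "))
  na_rows <- !stats::complete.cases(mutations[, need])
  if (any(na_rows))
    stop("missing prediction value(s) in ", sum(na_rows), " row(s)")
  binding <- if (require_both_binding)
    mutations$affinity_nm <= affinity_max & mutations$rank_pct <= rank_max
  else
    mutations$affinity_nm <= affinity_max | mutations$rank_pct <= rank_max
  mutations$nonsynonymous & binding & mutations$tpm >= tpm_min
}
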