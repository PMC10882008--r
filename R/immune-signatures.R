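# Expression normalization, immune signature scoring and
# inflamed/desert/excluded immunophenotype classification.

#' Default T-cell exhaustion gene panel
#'
#' The common immune-checkpoint inhibitory molecules used for the
#' exhaustion metagene: PDCD1 (PD-1), LAG3, HAVCR2 (TIM-3), KLRG1, TIGIT,
#' CD244, CD160, BTLA, CTLA4, ENTPD1 and ID2.
#'
#' @return Character vector of 11 gene symbols.
#' @export
exhaustion_panel <- function() {
  c("PDCD1", "LAG3", "HAVCR2", "KLRG1", "TIGIT", "CD244", "CD160",
    "BTLA", "CTLA4", "ENTPD1", "ID2")
}

#' Read gene sets from a GMT file
#'
#' @param path Path to a GMT file (one set per line: name, description,
#'   genes, tab-separated).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE))
    return(fgsea::gmtPathways(path))
  lines <- strsplit(readLines(path), "\t")
  stats::setNames(lapply(lines, function(x) x[-(1:2)]),
                  vapply(lines, `[[`, "", 1L))
}

#' Bundled immune gene sets
#'
#' Editable defaults for the IFN-gamma signaling, antigen-presentation
#' machinery (APM), proliferation, cytolytic and exhaustion signatures.
#' Memberships are conventional literature picks, not an authoritative
#' panel definition; replace them with platform gene sets where available.
#'
#' @return Named list of character vectors.
#' @export
default_gene_sets <- function() {
  read_gmt(system.file("extdata", "immune_signatures.gmt",
                       package = "immunoclock", mustWork = TRUE))
}

#' Normalize raw counts against housekeeping genes
#'
#' Per sample, `log2(count + 1)` minus the mean `log2(count + 1)` of the
#' housekeeping genes (geometric-mean scaling on the log scale), so the
#' housekeeping genes' normalized mean is exactly 0 in every sample.
#'
#' @param raw Genes x samples matrix of raw counts (>= 0), with gene
#'   rownames.
#' @param housekeeping Character vector of housekeeping gene names; all
#'   must be present.
#' @return Normalized log2 matrix with attribute `normalized = TRUE`.
#' @export
normalize_housekeeping <- function(raw, housekeeping) {
  if (length(housekeeping) == 0L) stop("housekeeping gene list is empty")
  if (is.null(rownames(raw))) stop("expression matrix needs gene rownames")
  missing <- setdiff(housekeeping, rownames(raw))
  if (length(missing))
    stop("housekeeping gene(s) missing from matrix: ", paste(missing, collapse = ", "))
  if (any(raw < 0, na.rm = TRUE)) stop("raw counts must be non-negative")
  l <- log2(raw + 1)
  offset <- colMeans(l[housekeeping, , drop = FALSE])
  out <- sweep(l, 2L, offset)
  attr(out, "normalized") <- TRUE
  out
}

# Cohort-wide per-gene z-scores; a zero-variance gene maps to 0.
cohort_zscore <- function(expr) {
  mu <- rowMeans(expr)
  sdv <- apply(expr, 1L, stats::sd)
  z <- sweep(expr, 1L, mu)
  z <- sweep(z, 1L, ifelse(sdv > 0, sdv, 1), "/")
  z[sdv == 0, ] <- 0
  z
}

#' Score a gene signature per sample
#'
#' With uniform weights, the arithmetic mean of the member genes' values.
#' With explicit weights, `sum(w_g * z_g) / sum(|w_g|)` on cohort-wide
#' per-gene z-scores.  Member genes absent from the matrix are dropped with
#' a warning.
#'
#' @param expr Normalized log2 genes x samples matrix.
#' @param gene_set Character vector of member genes.
#' @param weights `NULL` for uniform weights, or a named numeric vector of
#'   per-gene weights (log2 fold-changes).
#' @param zscore Use cohort z-scores with weights (default `TRUE`); when
#'   `FALSE`, raw normalized values are combined instead.
#' @return Named numeric vector of per-sample scores.
#' @export
signature_score <- function(expr, gene_set, weights = NULL, zscore = TRUE) {
  present <- intersect(gene_set, rownames(expr))
  if (length(present) == 0L)
    stop("none of the signature genes are present in the expression matrix")
  dropped <- setdiff(gene_set, present)
  if (length(dropped))
    warning("signature gene(s) absent and dropped: ", paste(dropped, collapse = ", "))
  if (is.null(weights))
    return(colMeans(expr[present, , drop = FALSE]))
  w <- weights[present]
  w <- w[!is.na(w)]
  if (sum(abs(w)) == 0) stop("sum of absolute weights is zero")
  vals <- if (zscore) cohort_zscore(expr[names(w), , drop = FALSE])
          else expr[names(w), , drop = FALSE]
  colSums(vals * w) / sum(abs(w))
}

#' Cytolytic activity score
#'
#' Geometric mean of GZMA and PRF1 expression on the linear scale.  When
#' either gene's value is 0 in a sample, a pseudocount of +1 is applied to
#' both terms inside the root for that sample, keeping the score finite and
#' monotone.
#'
#' @param expr Genes x samples matrix of linear-scale expression (>= 0,
#'   e.g. TPM), containing rows `GZMA` and `PRF1`.
#' @return Named numeric vector of per-sample scores.
#' @export
cytolytic_score <- function(expr) {
  missing <- setdiff(c("GZMA", "PRF1"), rownames(expr))
  if (length(missing)) stop("gene(s) absent: ", paste(missing, collapse = ", "))
  g <- expr["GZMA", ]; p <- expr["PRF1", ]
  if (any(g < 0) || any(p < 0)) stop("cytolytic score needs non-negative linear-scale values")
  zero <- g == 0 | p == 0
  out <- sqrt(g * p)
  out[zero] <- sqrt((g[zero] + 1) * (p[zero] + 1))
  out
}

#' Log fold-change weights from a two-group comparison
#'
#' Per-gene weight: mean log2 expression in the comparison group minus the
#' mean in the reference group, restricted to a gene panel (default: the
#' exhaustion checkpoint panel).  These weights serve as the coefficients
#' of the exhaustion metagene score.
#'
#' @param expr Normalized log2 genes x samples matrix.
#' @param groups Character vector (or factor) of group labels aligned with
#'   the matrix columns.
#' @param reference,comparison The two group labels; defaults to the first
#'   and second distinct label.
#' @param panel Genes to restrict to (default [exhaustion_panel()]).
#' @return Named numeric vector of per-gene log2 fold-changes.
#' @export
compute_logfc_weights <- function(expr, groups, reference = NULL,
                                  comparison = NULL, panel = exhaustion_panel()) {
  groups <- as.character(groups)
  if (length(groups) != ncol(expr)) stop("one group label per sample is required")
  lv <- unique(groups)
  reference <- reference %||% lv[1L]
  comparison <- comparison %||% setdiff(lv, reference)[1L]
  n_ref <- sum(groups == reference); n_cmp <- sum(groups == comparison)
  if (n_ref < 2L || n_cmp < 2L)
    stop("each group needs at least 2 samples (reference ", n_ref,
         ", comparison ", n_cmp, ")")
  present <- intersect(panel, rownames(expr))
  if (length(present) == 0L) stop("no panel genes present in the expression matrix")
  rowMeans(expr[present, groups == comparison, drop = FALSE]) -
    rowMeans(expr[present, groups == reference, drop = FALSE])
}

#' T-cell exhaustion metagene score
#'
#' Weighted arithmetic mean of the checkpoint panel on cohort z-scored
#' expression: `score_s = sum(w_g * z_gs) / sum(|w_g|)`.  The absolute-sum
#' normalizer keeps the score bounded and sign-interpretable when weights
#' have mixed signs: the group with higher panel expression in the
#' weight-defining comparison receives positive scores.
#'
#' @param expr Normalized log2 genes x samples matrix.
#' @param weights Named numeric vector of per-gene weights (see
#'   [compute_logfc_weights()]).
#' @param zscore Use cohort z-scores (default `TRUE`).
#' @return Named numeric vector of per-sample scores.
#' @export
exhaustion_score <- function(expr, weights, zscore = TRUE) {
  if (sum(abs(weights), na.rm = TRUE) == 0)
    stop("sum of absolute weights is zero")
  missing <- setdiff(names(weights), rownames(expr))
  if (length(missing)) stop("panel gene(s) absent: ", paste(missing, collapse = ", "))
  signature_score(expr, names(weights), weights = weights, zscore = zscore)
}

#' Classify samples into inflamed / desert / excluded immunophenotypes
#'
#' The cohort medians of the IFN-gamma signaling and antigen-presentation
#' machinery (APM) signature scores are the cutoffs: IFN >= median and
#' APM >= median is inflamed; IFN < median is desert (any APM); IFN >=
#' median with APM < median is excluded.  Ties at the median count as
#' "high".  Because only comparisons to the cohort median are used, the
#' classification is invariant under any strictly monotone transform
#' applied to both score vectors.
#'
#' @param ifng_scores,apm_scores Named numeric score vectors over the same
#'   samples (>= 2 samples).
#' @return Factor of classes (`inflamed`, `desert`, `excluded`) named by
#'   sample.
#' @export
classify_immunophenotype <- function(ifng_scores, apm_scores) {
  if (length(ifng_scores) < 2L) stop("at least 2 samples are required")
  if (!is.null(names(ifng_scores)) && !is.null(names(apm_scores))) {
    if (!setequal(names(ifng_scores), names(apm_scores)))
      stop("mismatched sample sets between the two score vectors")
    apm_scores <- apm_scores[names(ifng_scores)]
  } else if (length(ifng_scores) != length(apm_scores)) {
    stop("mismatched sample sets between the two score vectors")
  }
  mi <- stats::median(ifng_scores)
  ma <- stats::median(apm_scores)
  cls <- ifelse(ifng_scores < mi, "desert",
                ifelse(apm_scores >= ma, "inflamed", "excluded"))
  factor(stats::setNames(cls, names(ifng_scores)),
         levels = c("inflamed", "desert", "excluded"))
}

#' Score all bundled signatures and classify immunophenotypes
#'
#' Convenience wrapper: scores the IFN-gamma, APM, proliferation and
#' cytolytic signatures plus (optionally) an exhaustion metagene, and
#' assigns each sample an immunophenotype.
#'
#' @param expr Normalized log2 genes x samples matrix.
#' @param gene_sets Named list of gene sets (default [default_gene_sets()]).
#' @param exhaustion_weights Optional named weights for the exhaustion
#'   metagene.
#' @return Data frame with one row per sample: signature scores and the
#'   immunophenotype.
#' @export
score_signatures <- function(expr, gene_sets = default_gene_sets(),
                             exhaustion_weights = NULL) {
  ifng <- signature_score(expr, gene_sets$IFNG_SIGNALING)
  apm <- signature_score(expr, gene_sets$APM)
  out <- data.frame(sample_id = colnames(expr),
                    ifng = ifng, apm = apm,
                    proliferation = signature_score(expr, gene_sets$PROLIFERATION),
                    cytolytic = cytolytic_score(pmax(2^expr - 1, 0)),
                    stringsAsFactors = FALSE)
  if (!is.null(exhaustion_weights))
    out$exhaustion <- exhaustion_score(expr, exhaustion_weights)
  out$immunophenotype <- classify_immunophenotype(ifng, apm)
  rownames(out) <- NULL
  out
}
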