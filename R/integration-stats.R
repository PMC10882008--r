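# Correlation-method selection, masked correlation matrices and the
# Mann-Kendall trend test.

#' Choose and run the appropriate correlation test
#'
#' Pearson is used only when the assumptions of the parametric test hold
#' for the pair: both variables pass the Shapiro-Wilk normality test at
#' `alpha`, neither contains an outlier (|robust z| > 3.5, via median/MAD),
#' and the relationship is linear (the quadratic term of `y ~ x + x^2` is
#' non-significant at `alpha`).  Otherwise the rank-based Spearman test is
#' used.  The decision trail of the three sub-tests is returned.
#'
#' @param x,y Paired numeric vectors (missing pairs dropped; >= 5 complete
#'   pairs required).
#' @param alpha Significance level for the assumption checks (default
#'   0.05).
#' @param outlier_z Robust z threshold declaring an outlier (default 3.5).
#' @return A list of class `correlation_choice`: `method`, `r`, `p` and
#'   `trail` (named list of the sub-test results).
#' @export
choose_correlation <- function(x, y, alpha = 0.05, outlier_z = 3.5) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5L) stop("at least 5 complete pairs are required (got ", n, ")")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in one of the variables")

  sw_x <- stats::shapiro.test(x)$p.value
  sw_y <- stats::shapiro.test(y)$p.value
  normal <- sw_x >= alpha && sw_y >= alpha

  robust_z <- function(v) {
    m <- stats::mad(v)
    if (m == 0) return(rep(Inf, length(v)))
    abs(v - stats::median(v)) / m
  }
  has_outlier <- any(robust_z(x) > outlier_z) || any(robust_z(y) > outlier_z)

  quad_p <- tryCatch(suppressWarnings({
    fit <- stats::lm(y ~ x + I(x^2))
    co <- summary(fit)$coefficients
    if ("I(x^2)" %in% rownames(co)) co["I(x^2)", 4L] else 1
  }), error = function(e) 1)
  linear <- is.na(quad_p) || quad_p >= alpha

  method <- if (normal && !has_outlier && linear) "pearson" else "spearman"
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  structure(list(method = method, r = unname(ct$estimate), p = ct$p.value,
                 n = n,
                 trail = list(shapiro_x_p = sw_x, shapiro_y_p = sw_y,
                              normal = normal, has_outlier = has_outlier,
                              quadratic_p = quad_p, linear = linear)),
            class = "correlation_choice")
}

#' @export
print.correlation_choice <- function(x, ...) {
  cat(sprintf("%s correlation: r = %.3f, p = %.4g (n = %d)\n",
              x$method, x$r, x$p, x$n))
  cat(sprintf("  normality %s (SW p %.3g / %.3g), outliers %s, linearity %s\n",
              ifelse(x$trail$normal, "pass", "fail"),
              x$trail$shapiro_x_p, x$trail$shapiro_y_p,
              ifelse(x$trail$has_outlier, "present", "absent"),
              ifelse(x$trail$linear, "pass", "fail")))
  invisible(x)
}

#' Pairwise correlation matrix with significance masking
#'
#' Every feature pair is tested with [choose_correlation()] on
#' pairwise-complete observations.  Cells with p > `alpha` are flagged
#' non-significant (masked to `NA` in the `r_masked` matrix, mirroring
#' blanked cells in a correlation heat map).  No multiplicity adjustment is
#' applied by default; Benjamini-Hochberg is available via `adjust`.
#' Features with fewer than 5 complete pairs against every other feature
#' are excluded with a warning.
#'
#' @param table Data frame or matrix of numeric features (samples in
#'   rows).
#' @param alpha Significance cutoff for masking (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A list of class `cor_matrix`: matrices `r`, `p`, `r_masked`,
#'   `significant`, and a character matrix `method`.
#' @export
correlation_matrix <- function(table, alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  table <- as.data.frame(table)
  num <- vapply(table, is.numeric, TRUE)
  table <- table[num]
  if (ncol(table) < 2L) stop("at least 2 numeric features are required")
  k <- ncol(table)
  complete_pairs <- function(i, j) sum(stats::complete.cases(table[[i]], table[[j]]))
  usable <- vapply(seq_len(k), function(i)
    any(vapply(setdiff(seq_len(k), i), function(j) complete_pairs(i, j) >= 5L, TRUE)),
    TRUE)
  if (any(!usable)) {
    warning("feature(s) excluded (fewer than 5 complete pairs): ",
            paste(names(table)[!usable], collapse = ", "))
    table <- table[usable]
    k <- ncol(table)
    if (k < 2L) stop("fewer than 2 usable features remain")
  }
  nm <- names(table)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  method <- matrix(NA_character_, k, k, dimnames = list(nm, nm))
  diag(r) <- 1; diag(p) <- 0; diag(method) <- "identity"
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    res <- tryCatch(choose_correlation(table[[i]], table[[j]], alpha = alpha),
                    error = function(e) NULL)
    if (!is.null(res)) {
      r[i, j] <- r[j, i] <- res$r
      p[i, j] <- p[j, i] <- res$p
      method[i, j] <- method[j, i] <- res$method
    }
  }
  if (adjust == "BH") {
    up <- upper.tri(p)
    p[up] <- stats::p.adjust(p[up], method = "BH")
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
  }
  significant <- !is.na(p) & p <= alpha
  r_masked <- r
  r_masked[!significant] <- NA_real_
  structure(list(r = r, p = p, r_masked = r_masked,
                 significant = significant, method = method, alpha = alpha),
            class = "cor_matrix")
}

#' @export
print.cor_matrix <- function(x, ...) {
  cat(sprintf("Correlation matrix (%d features, alpha = %g; blank = non-significant)\n",
              ncol(x$r), x$alpha))
  print(round(x$r_masked, 2), na.print = ".")
  invisible(x)
}

# Mahonian numbers: distribution of the number of inversions of a random
# permutation of n distinct items, by convolution.
inversion_counts <- function(n) {
  counts <- 1
  for (k in 2:n) {
    newlen <- length(counts) + k - 1L
    cs <- cumsum(c(counts, rep(0, k - 1L)))
    counts <- cs - c(rep(0, k), utils::head(cs, newlen - k))
  }
  counts
}

# All permutations of seq_len(n), as an n! x n matrix (n <= 8).
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- i
    out[rows, -1L] <- sub + (sub >= i)
  }
  out
}

mk_s_statistic <- function(x) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n - 1L))
    s <- s + sum(sign(x[(i + 1L):n] - x[i]))
  as.integer(s)
}

#' Mann-Kendall trend test
#'
#' Tests for a monotone trend in a series ordered by time:
#' `S = sum_{i<j} sign(x_j - x_i)`, `tau = S / (n(n-1)/2)`.  The two-sided
#' p-value is exact for tie-free series with n <= 10 (from the permutation
#' null distribution of S, computed by the inversion-number recursion) and
#' for tied series with n <= 8 (full multiset enumeration); larger series
#' use the normal approximation with tie correction and continuity
#' correction.
#'
#' @param x Numeric series in temporal order (n >= 4).
#' @return A list of class `mann_kendall`: `tau`, `S`, `p`, `n`,
#'   `method`.
#' @export
mann_kendall <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 4L) stop("at least 4 observations are required")
  S <- mk_s_statistic(x)
  ties <- any(duplicated(x))
  if (S == 0L) {
    p <- 1
    method <- "degenerate"
  } else if (!ties && n <= 10L) {
    counts <- inversion_counts(n)  # index k+1 = permutations with k inversions
    total <- sum(counts)
    svals <- n * (n - 1L) / 2L - 2L * (seq_along(counts) - 1L)
    p <- min(1, 2 * min(sum(counts[svals >= S]), sum(counts[svals <= S])) / total)
    method <- "exact"
  } else if (ties && n <= 8L) {
    perms <- all_permutations(n)
    sgn <- sign(outer(x, x, "-"))
    sdist <- numeric(nrow(perms))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      sdist <- sdist + sgn[cbind(perms[, i], perms[, j])]
    p <- min(1, 2 * min(mean(sdist >= S), mean(sdist <= S)))
    method <- "exact"
  } else {
    tie_tab <- table(x)
    tie_tab <- tie_tab[tie_tab > 1L]
    var_s <- (n * (n - 1) * (2 * n + 5) -
                sum(tie_tab * (tie_tab - 1) * (2 * tie_tab + 5))) / 18
    z <- (S - sign(S)) / sqrt(var_s)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  structure(list(tau = S / (n * (n - 1) / 2), S = S, p = p, n = n,
                 method = method),
            class = "mann_kendall")
}

#' @export
print.mann_kendall <- function(x, ...) {
  cat(sprintf("Mann-Kendall trend test: S = %d, tau = %.3f, p = %.4g (n = %d, %s)\n",
              x$S, x$tau, x$p, x$n, x$method))
  invisible(x)
}
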