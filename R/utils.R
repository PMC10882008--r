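# Internal helpers shared across modules.

#: the 20 standard amino acids used for CDR3 strings
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

config_error <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

check_count <- function(x, field, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != round(x) || x < min)
    config_error(field, sprintf("must be a single integer >= %d", min))
  as.integer(x)
}

check_fraction <- function(x, field, lo = 0, hi = 1, len = 1L) {
  if (!is.numeric(x) || length(x) != len || anyNA(x) || any(x < lo) || any(x > hi))
    config_error(field, sprintf("must be numeric in [%g, %g] of length %d", lo, hi, len))
  as.numeric(x)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# One root seed fans out into reproducible child streams; adding a consumer
# at the end does not perturb earlier ones.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Atomic-ish TSV writer: write to a temporary sibling, then rename.
write_tsv <- function(df, path) {
  tmp <- paste0(path, ".tmp")
  utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, ...)
}
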