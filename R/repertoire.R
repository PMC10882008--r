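# Clonotype table I/O, rarefaction, diversity, overlap and sharing statistics.

#' Construct a clonotype table
#'
#' A clonotype table holds one sample's TCR beta-chain repertoire: unique
#' CDR3 amino-acid sequences with template counts, a productivity flag and
#' sample metadata.  Duplicate CDR3 rows are aggregated by summing their
#' counts; sequences are upper-cased and must use the 20 standard amino
#' acids.
#'
#' @param sample_id Sample identifier.
#' @param day Collection day (days since diagnosis, integer >= 0).
#' @param group Group label, one of `"sequential"`, `"parallel"`, `"blood"`.
#' @param cdr3_aa Character vector of CDR3 amino-acid sequences.
#' @param count Positive integer template counts, recycled if length 1.
#' @param productive Logical productivity flags, recycled if length 1.
#'   Non-productive records are retained but excluded from all statistics.
#' @return An object of class `clonotype_table`.
#' @export
clonotype_table <- function(sample_id, day, group, cdr3_aa, count = 1L,
                            productive = TRUE) {
  if (length(cdr3_aa) == 0L) stop("clonotype table must contain at least one record")
  cdr3_aa <- toupper(as.character(cdr3_aa))
  bad <- grepl(sprintf("[^%s]", paste(AA20, collapse = "")), cdr3_aa)
  if (any(bad))
    stop("non-amino-acid characters in CDR3 sequence(s): ",
         paste(utils::head(cdr3_aa[bad], 5L), collapse = ", "))
  count <- as.integer(rep_len(count, length(cdr3_aa)))
  if (anyNA(count) || any(count < 1L)) stop("counts must be positive integers")
  productive <- rep_len(as.logical(productive), length(cdr3_aa))
  day <- check_count(day, "day", min = 0L)
  group <- match.arg(group, c("sequential", "parallel", "blood"))

  if (anyDuplicated(cdr3_aa)) {
    key <- paste(cdr3_aa, productive)
    agg <- rowsum(count, key)
    first <- !duplicated(key)
    ord <- match(rownames(agg), key[first])
    records <- data.frame(cdr3_aa = cdr3_aa[first][ord],
                          count = as.integer(agg[, 1L]),
                          productive = productive[first][ord],
                          stringsAsFactors = FALSE)
  } else {
    records <- data.frame(cdr3_aa = cdr3_aa, count = count,
                          productive = productive, stringsAsFactors = FALSE)
  }
  rownames(records) <- NULL
  structure(list(sample_id = as.character(sample_id), day = day,
                 group = group, records = records),
            class = "clonotype_table")
}

#' @export
print.clonotype_table <- function(x, ...) {
  cat(sprintf("Clonotype table '%s' (day %d, %s): %d unique CDR3s, %d templates (%d productive records)\n",
              x$sample_id, x$day, x$group, nrow(x$records),
              sum(x$records$count), sum(x$records$productive)))
  invisible(x)
}

productive_records <- function(table) {
  stopifnot(inherits(table, "clonotype_table"))
  table$records[table$records$productive, , drop = FALSE]
}

#' Read a clonotype table from a rearrangement TSV
#'
#' Supports the AIRR rearrangement dialect (columns `junction_aa`,
#' `duplicate_count`, `productive`) and an immunoSEQ-style dialect
#' (`aminoAcid`, `templates`, `sequenceStatus` where `"In"` marks productive
#' records).  A custom column map can be supplied for other layouts.
#' Duplicate CDR3 rows are merged with summed counts; non-productive rows
#' are retained but flagged.
#'
#' @param path Path to a tab-separated file.
#' @param dialect `"airr"` (default) or `"immunoseq"`.
#' @param sample_id,day,group Sample metadata (see [clonotype_table()]).
#' @param col_map Optional named list overriding the dialect's column names;
#'   entries `cdr3`, `count`, `productive`.
#' @return A [clonotype_table()].
#' @export
read_clonotypes <- function(path, dialect = c("airr", "immunoseq"),
                            sample_id = basename(path), day = 0L,
                            group = "sequential", col_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  dialect <- match.arg(dialect)
  map <- switch(dialect,
    airr = list(cdr3 = "junction_aa", count = "duplicate_count", productive = "productive"),
    immunoseq = list(cdr3 = "aminoAcid", count = "templates", productive = "sequenceStatus"))
  map[names(col_map)] <- col_map
  df <- read_tsv(path)
  if (nrow(df) == 0L) stop("empty clonotype file: ", path)
  missing <- setdiff(unlist(map), names(df))
  if (length(missing))
    stop("missing mandatory column(s) in ", path, ": ", paste(missing, collapse = ", "))
  prod <- df[[map$productive]]
  prod <- if (is.logical(prod)) prod else toupper(as.character(prod)) %in% c("T", "TRUE", "IN")
  n_in <- nrow(df)
  tbl <- clonotype_table(sample_id, day, group,
                         cdr3_aa = df[[map$cdr3]],
                         count = df[[map$count]],
                         productive = prod)
  n_merged <- n_in - nrow(tbl$records)
  message(sprintf("read_clonotypes: %d rows read, %d duplicate rows merged", n_in, n_merged))
  tbl
}

#' Write a clonotype table as AIRR rearrangement TSV
#'
#' @param table A [clonotype_table()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_clonotypes <- function(table, path) {
  stopifnot(inherits(table, "clonotype_table"))
  out <- data.frame(junction_aa = table$records$cdr3_aa,
                    duplicate_count = table$records$count,
                    productive = ifelse(table$records$productive, "T", "F"))
  write_tsv(out, path)
}

#' Downsample a repertoire to a fixed number of clonotypes
#'
#' Repertoires of unequal depth are made comparable by downsampling every
#' sample to the same number of unique clonotypes (default 1000) before
#' diversity or overlap statistics are computed.  The default unit is unique
#' clonotypes drawn uniformly without replacement with their original counts
#' preserved; `unit = "templates"` instead rarefies at the template level.
#' Tables at or below the target size are returned unchanged (no randomness
#' is consumed).
#'
#' @param table A [clonotype_table()].
#' @param n Target size (default 1000).
#' @param seed Integer seed making the subsample deterministic.
#' @param unit `"clonotypes"` (default) or `"templates"`.
#' @return A [clonotype_table()].
#' @export
downsample_clonotypes <- function(table, n = 1000L, seed = 1L,
                                  unit = c("clonotypes", "templates")) {
  stopifnot(inherits(table, "clonotype_table"))
  n <- check_count(n, "n")
  unit <- match.arg(unit)
  rec <- table$records
  if (unit == "clonotypes") {
    if (nrow(rec) <= n) return(table)
    keep <- with_seed(seed, sample.int(nrow(rec), n))
    rec <- rec[sort(keep), , drop = FALSE]
  } else {
    total <- sum(rec$count)
    if (total <= n) return(table)
    drawn <- with_seed(seed, sample(rep.int(seq_len(nrow(rec)), rec$count), n))
    tab <- tabulate(drawn, nbins = nrow(rec))
    rec <- rec[tab > 0L, , drop = FALSE]
    rec$count <- tab[tab > 0L]
  }
  rownames(rec) <- NULL
  out <- table
  out$records <- rec
  out
}

#' Inverse Simpson diversity of a repertoire
#'
#' The effective number of equally abundant clonotypes, `1 / sum(p_i^2)`
#' with `p_i` the template-count proportions over productive clonotypes.
#' Values near 1 indicate strong clonal expansion; the maximum (the
#' richness) is attained at uniform abundances.
#'
#' @param table A [clonotype_table()] or a numeric vector of counts.
#' @return Diversity (dimensionless, >= 1).
#' @export
inverse_simpson <- function(table) {
  counts <- if (inherits(table, "clonotype_table")) productive_records(table)$count
            else table
  if (length(counts) == 0L || sum(counts) == 0) stop("empty repertoire")
  p <- counts / sum(counts)
  1 / sum(p^2)
}

#' Morisita-Horn overlap between two repertoires
#'
#' Abundance-weighted overlap of public clonotypes,
#' `C = 2 * sum(x_i * y_i) / ((d_x + d_y) * X * Y)` with
#' `d_x = sum(x_i^2) / X^2`, matching clonotypes on identical CDR3
#' amino-acid sequences.  Ranges from 0 (disjoint) to 1 (identical
#' composition); invariant under uniform scaling of either table's counts.
#'
#' @param a,b [clonotype_table()] objects.
#' @return Overlap index in `[0, 1]`.
#' @export
morisita_overlap <- function(a, b) {
  ra <- productive_records(a); rb <- productive_records(b)
  if (nrow(ra) == 0L || nrow(rb) == 0L) stop("empty repertoire")
  keys <- union(ra$cdr3_aa, rb$cdr3_aa)
  x <- numeric(length(keys)); names(x) <- keys
  y <- x
  x[ra$cdr3_aa] <- ra$count
  y[rb$cdr3_aa] <- rb$count
  X <- sum(x); Y <- sum(y)
  dx <- sum(x^2) / X^2
  dy <- sum(y^2) / Y^2
  as.numeric(2 * sum(x * y) / ((dx + dy) * X * Y))
}

#' Partition clonotypes into private and shared sets
#'
#' A sequence is shared when detected in at least one sample of each group;
#' private when detected in only one group.  The three sets are disjoint and
#' their union is the union of all productive sequences.
#'
#' @param group_a,group_b Non-empty lists of [clonotype_table()] objects.
#' @return A list with character-vector elements `private_a`, `private_b`,
#'   `shared`, of class `sharing_partition`.
#' @export
partition_sharing <- function(group_a, group_b) {
  if (inherits(group_a, "clonotype_table")) group_a <- list(group_a)
  if (inherits(group_b, "clonotype_table")) group_b <- list(group_b)
  if (length(group_a) == 0L || length(group_b) == 0L)
    stop("both groups must contain at least one sample")
  seqs <- function(tables) unique(unlist(lapply(tables, function(t) productive_records(t)$cdr3_aa)))
  sa <- seqs(group_a); sb <- seqs(group_b)
  structure(list(private_a = setdiff(sa, sb),
                 private_b = setdiff(sb, sa),
                 shared = intersect(sa, sb)),
            class = "sharing_partition")
}

#' @export
print.sharing_partition <- function(x, ...) {
  cat(sprintf("Sharing partition: %d private to group a, %d private to group b, %d shared\n",
              length(x$private_a), length(x$private_b), length(x$shared)))
  invisible(x)
}

#' T-cell fraction of the nucleated cell count
#'
#' The fraction of T cells within the total nucleated cell count, used as a
#' surrogate measure of T-cell infiltration from TCR beta-chain sequencing
#' of bulk tumor DNA.
#'
#' @param productive_templates Number of productive TCR templates.
#' @param total_nucleated Total nucleated cell count (> 0).
#' @return Fraction in `[0, 1]`.
#' @export
t_cell_fraction <- function(productive_templates, total_nucleated) {
  if (!is.numeric(productive_templates) || !is.numeric(total_nucleated) ||
      anyNA(productive_templates) || anyNA(total_nucleated))
    stop("counts must be numeric and non-missing")
  if (any(total_nucleated <= 0)) stop("total_nucleated must be > 0")
  if (any(productive_templates < 0) || any(productive_templates > total_nucleated))
    stop("requires 0 <= productive_templates <= total_nucleated")
  productive_templates / total_nucleated
}
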