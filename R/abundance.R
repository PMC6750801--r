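#' Construct an abundance table
#'
#' An `abundance_table` holds a samples-by-taxa matrix of relative abundances
#' (proportions; each row sums to 1) together with the per-sample total
#' classified read depth. It is the central compositional container used by
#' every analysis stage.
#'
#' @param values Numeric matrix, samples in rows, taxa in columns. Either raw
#'   read counts or proportions, controlled by `layout`.
#' @param read_depth Per-sample read depths. Required for `layout =
#'   "proportions"` if depths are to be retained; for counts it is derived as
#'   the row sum before normalization.
#' @param layout `"counts"` or `"proportions"`.
#' @return An object of class `abundance_table`: a list with `values`
#'   (proportions matrix with sample/taxon dimnames), `sample_ids`,
#'   `taxon_ids` and `read_depth`.
#' @details Proportion rows whose sum deviates from 1 by more than `1e-6` are
#'   rejected as non-compositional; smaller deviations are renormalized.
#'   Zero-depth samples (all-zero count rows) are rejected.
#' @seealso [read_abundance_table()], [filter_min_reads()]
#' @export
abundance_table <- function(values, read_depth = NULL,
                            layout = c("counts", "proportions")) {
  layout <- match.arg(layout)
  if (!is.matrix(values)) values <- as.matrix(values)
  if (length(values) == 0L || nrow(values) == 0L || ncol(values) == 0L)
    stopf("empty abundance table")
  if (!is.numeric(values)) stopf("abundance values must be numeric")
  if (anyNA(values)) stopf("abundance values contain NA")
  if (any(values < 0)) stopf("negative abundance values")
  sample_ids <- rownames(values)
  taxon_ids <- colnames(values)
  if (is.null(sample_ids) || is.null(taxon_ids))
    stopf("values must carry sample (row) and taxon (column) names")
  if (anyDuplicated(sample_ids)) stopf("duplicate sample IDs")
  if (anyDuplicated(taxon_ids)) stopf("duplicate taxon IDs")

  rs <- rowSums(values)
  if (layout == "counts") {
    if (any(abs(values - round(values)) > 1e-8))
      stopf("counts layout requires non-negative integers")
    if (any(rs == 0))
      stopf("zero-depth sample(s): %s",
            paste(sample_ids[rs == 0], collapse = ", "))
    read_depth <- rs
    values <- values / rs
  } else {
    bad <- abs(rs - 1) > 1e-6
    if (any(bad))
      stopf("not a composition: row sum(s) deviate from 1 (e.g. %s = %.6g)",
            sample_ids[which(bad)[1]], rs[which(bad)[1]])
    values <- values / rs
    if (is.null(read_depth)) read_depth <- rep(NA_real_, nrow(values))
  }
  read_depth <- as.numeric(read_depth)
  if (length(read_depth) != nrow(values))
    stopf("read_depth length does not match the number of samples")
  names(read_depth) <- sample_ids
  structure(list(values = values, sample_ids = sample_ids,
                 taxon_ids = taxon_ids, read_depth = read_depth),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d samples x %d taxa\n",
              length(x$sample_ids), length(x$taxon_ids)))
  if (!all(is.na(x$read_depth)))
    cat(sprintf("read depth: median %s [%s, %s]\n",
                format(stats::median(x$read_depth, na.rm = TRUE)),
                format(min(x$read_depth, na.rm = TRUE)),
                format(max(x$read_depth, na.rm = TRUE))))
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

#' Read an abundance table from tab-delimited text
#'
#' Expects a header row of taxon labels, a first column of sample identifiers,
#' and one row per sample. A `counts` layout holds non-negative integer read
#' counts which are normalized row-wise to proportions (the row sum is kept as
#' the sample's read depth); a `proportions` layout holds compositions whose
#' rows must sum to 1 within `1e-6`.
#'
#' @param path Path to a TSV file.
#' @param layout `"counts"` or `"proportions"`.
#' @param depth For `layout = "proportions"`, optional per-sample read depths
#'   (named numeric), since the file itself carries none.
#' @return An [abundance_table()].
#' @export
read_abundance_table <- function(path, layout = c("counts", "proportions"),
                                 depth = NULL) {
  layout <- match.arg(layout)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stopf("empty table: need a sample column plus taxa")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (!is.null(depth) && !is.null(names(depth))) depth <- depth[ids]
  abundance_table(m, read_depth = depth, layout = layout)
}

#' Write an abundance table (proportions) to tab-delimited text
#'
#' Writes the proportion matrix at full precision so that a
#' read-write-read round trip is bit-exact on the textual representation.
#'
#' @param table An [abundance_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(table, path) {
  stopifnot(inherits(table, "abundance_table"))
  m <- table$values
  header <- paste(c("sample_id", table$taxon_ids), collapse = "\t")
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(table$sample_ids[i], sprintf("%.17g", m[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Drop samples below a minimum read depth
#'
#' Samples whose total classified read count falls below `min_reads` are
#' removed; the study-standard quality floor is 1,000 reads, applied
#' inclusively (a sample with exactly `min_reads` reads is kept).
#'
#' @param table An [abundance_table()] with known read depths.
#' @param min_reads Minimum acceptable read depth (default 1000).
#' @return The filtered [abundance_table()]; sample order preserved. May be
#'   empty (with a warning).
#' @export
filter_min_reads <- function(table, min_reads = 1000) {
  stopifnot(inherits(table, "abundance_table"))
  if (all(is.na(table$read_depth)))
    stopf("read depths unknown; cannot apply a read-count filter")
  keep <- !is.na(table$read_depth) & table$read_depth >= min_reads
  if (!any(keep)) warnf("no sample reaches %d reads; returning empty table", min_reads)
  subset_samples(table, table$sample_ids[keep])
}

#' Subset an abundance table by sample or taxon
#'
#' @param table An [abundance_table()].
#' @param sample_ids Samples to keep (order respected).
#' @return The subset table. `subset_taxa` does not renormalize rows: retained
#'   proportions keep their original denominator, matching how proportional
#'   abundances are analyzed after taxon filtering.
#' @export
subset_samples <- function(table, sample_ids) {
  stopifnot(inherits(table, "abundance_table"))
  idx <- match(sample_ids, table$sample_ids)
  if (anyNA(idx)) stopf("unknown sample id(s): %s",
                        paste(sample_ids[is.na(idx)], collapse = ", "))
  out <- table
  out$values <- table$values[idx, , drop = FALSE]
  out$sample_ids <- table$sample_ids[idx]
  out$read_depth <- table$read_depth[idx]
  out
}

#' @param taxon_ids Taxa to keep.
#' @rdname subset_samples
#' @export
subset_taxa <- function(table, taxon_ids) {
  stopifnot(inherits(table, "abundance_table"))
  taxon_ids <- canonical_taxon(taxon_ids)
  idx <- match(taxon_ids, table$taxon_ids)
  if (anyNA(idx)) stopf("unknown taxon id(s): %s",
                        paste(taxon_ids[is.na(idx)], collapse = ", "))
  out <- table
  out$values <- table$values[, idx, drop = FALSE]
  out$taxon_ids <- table$taxon_ids[idx]
  out
}
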