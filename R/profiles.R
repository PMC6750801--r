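#' Soft-threshold log10 transform of relative abundances
#'
#' Subtracts 0.001 from the abundance, floors negatives at 0, and applies
#' `log10((x + 0.001)/0.001)`. This maps proportions in [0, 1] onto [0, 3]:
#' abundances at or below the 0.001 threshold map to 0, a monoculture (1.0)
#' maps to exactly 3, and the transform is continuous and monotone
#' non-decreasing, so relative sample positions above the threshold are
#' preserved while sub-threshold noise is flattened.
#'
#' @param abundance Numeric vector of proportions in [0, 1].
#' @param threshold Soft threshold (default 0.001).
#' @return Transformed values in `[0, log10(1/threshold)]`.
#' @export
soft_threshold_log <- function(abundance, threshold = 0.001) {
  if (anyNA(abundance) || any(abundance < 0 | abundance > 1))
    stopf("abundance must lie in [0, 1]")
  log10((pmax(abundance - threshold, 0) + threshold) / threshold)
}

#' Retain taxa passing the two-criterion abundance filter
#'
#' A taxon is kept when either (1) at least 5% of samples show abundance of
#' at least 1%, or (2) at least 15% of samples show abundance of at least
#' 0.1%. All four cutoffs are inclusive; fractions are computed over all
#' samples in the table. Taxa failing both criteria are removed from
#' downstream analyses.
#'
#' @param table An [abundance_table()].
#' @param prev1,abund1 Criterion 1: prevalence and abundance cutoffs
#'   (defaults 0.05, 0.01).
#' @param prev2,abund2 Criterion 2 (defaults 0.15, 0.001).
#' @return Character vector of retained taxon labels, in table order.
#' @export
filter_low_abundance <- function(table, prev1 = 0.05, abund1 = 0.01,
                                 prev2 = 0.15, abund2 = 0.001) {
  stopifnot(inherits(table, "abundance_table"))
  if (nrow(table$values) == 0L) stopf("empty table")
  f1 <- colMeans(table$values >= abund1)
  f2 <- colMeans(table$values >= abund2)
  table$taxon_ids[f1 >= prev1 | f2 >= prev2]
}

#' Assign vagitypes (community state types) by the predominant-taxon rule
#'
#' Each sample's vagitype is the taxon holding the largest proportion of
#' reads; samples whose largest proportion is below 30% are left
#' `"UNASSIGNED"`. Exact ties on the maximum are broken by the
#' lexicographically first taxon label (with a warning).
#'
#' @param table An [abundance_table()].
#' @param min_proportion Assignment cutoff on the maximum proportion
#'   (default 0.30).
#' @return Data.frame with `sample_id`, `vagitype`, `max_proportion`.
#' @export
assign_vagitype <- function(table, min_proportion = 0.30) {
  stopifnot(inherits(table, "abundance_table"))
  m <- table$values
  ord <- order(table$taxon_ids) # lexicographic tie-break
  m_ord <- m[, ord, drop = FALSE]
  labs <- table$taxon_ids[ord]
  mx <- apply(m, 1, max)
  arg <- labs[apply(m_ord, 1, which.max)]
  n_tie <- sum(apply(m, 1, function(r) sum(r == max(r)) > 1))
  if (n_tie > 0)
    warnf("%d sample(s) had tied maximum proportions; lexicographic tie-break applied", n_tie)
  vag <- ifelse(mx >= min_proportion, arg, "UNASSIGNED")
  data.frame(sample_id = table$sample_ids, vagitype = vag,
             max_proportion = as.numeric(mx), stringsAsFactors = FALSE)
}

#' Shannon diversity (natural log) of a composition
#'
#' @param p Numeric vector of proportions (a composition). Zeros contribute
#'   nothing.
#' @return Diversity in nats: `-sum(p_i * ln p_i)` over positive entries.
#' @export
shannon_diversity <- function(p) {
  if (any(p < 0)) stopf("proportions must be non-negative")
  p <- p[p > 0]
  -sum(p * log(p))
}
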