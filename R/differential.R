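#' Mann-Whitney U test with a zero-rounding floor
#'
#' Abundance values below `zero_floor` (default 1e-5) are rounded to zero
#' before ranking, suppressing spurious rank differences among trace
#' detections. The two-sided p-value is exact (enumeration) when the combined
#' sample size is at most 12 and there are no ties; otherwise the normal
#' approximation with tie-corrected variance and continuity correction is
#' used. When every value is tied the statistic carries no information and
#' p = 1 is returned.
#'
#' @param x,y Numeric vectors (the two groups), both non-empty.
#' @param zero_floor Values strictly below this are set to 0 (default 1e-5).
#' @return List with `u` (U statistic of `x`), `p` (two-sided), and `method`.
#' @export
mann_whitney <- function(x, y, zero_floor = 1e-5) {
  if (length(x) == 0L || length(y) == 0L) stopf("both groups must be non-empty")
  x <- ifelse(x < zero_floor, 0, x)
  y <- ifelse(y < zero_floor, 0, y)
  r <- rank(c(x, y))
  nx <- length(x); ny <- length(y)
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (nx + ny <= 12) && !ties
  if (!ties && stats::var(c(x, y)) == 0) # single value in both groups
    return(list(u = u, p = 1, method = "degenerate"))
  if (ties && length(unique(c(x, y))) == 1L)
    return(list(u = u, p = 1, method = "degenerate"))
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE,
                       alternative = "two.sided"))
  p <- ht$p.value
  if (is.na(p)) p <- 1
  list(u = u, p = min(p, 1), method = if (exact) "exact" else "normal")
}

## vectorized normal-approximation MW p-values for the columns of a feature
## matrix (used inside cross-validated feature filtering, where the per-call
## overhead of the scalar interface matters)
mw_pvals_matrix <- function(xmat, is_case, zero_floor = 1e-5) {
  n <- nrow(xmat); n1 <- sum(is_case); n0 <- n - n1
  xmat[xmat < zero_floor] <- 0
  vapply(seq_len(ncol(xmat)), function(j) {
    v <- xmat[, j]
    r <- rank(v)
    u <- sum(r[is_case]) - n1 * (n1 + 1) / 2
    tiecorr <- if (anyDuplicated(v)) {
      tt <- tabulate(match(v, v))
      tt <- tt[tt > 1]
      sum(tt^3 - tt)
    } else 0
    sigma2 <- n1 * n0 / 12 * ((n + 1) - tiecorr / (n * (n - 1)))
    if (sigma2 <= 0) return(1)
    z <- (abs(u - n1 * n0 / 2) - 0.5) / sqrt(sigma2)
    min(1, 2 * stats::pnorm(-max(z, 0)))
  }, numeric(1))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment: in sorted order
#' `q_(i) = min_{j >= i} m p_(j) / j`, capped at 1 and mapped back to the
#' input order.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' The two-sided p-value sums hypergeometric probabilities of all tables with
#' the observed margins that are at most as probable as the observed table
#' (the standard exact-test convention; doubling conventions differ).
#'
#' @param a,b,c,d Cell counts, row-wise: `rbind(c(a, b), c(c, d))`.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stopf("cell counts must be non-negative integers")
  if (sum(counts) == 0) stopf("all-zero table")
  stats::fisher.test(matrix(counts, 2, 2, byrow = TRUE))$p.value
}

#' Cross-sectional differential-abundance screen
#'
#' Runs a Mann-Whitney U test (with the 1e-5 zero floor) per taxon comparing
#' PTB against TB samples, adjusts p-values by Benjamini-Hochberg, and
#' attaches per-group medians and 75th percentiles computed on the floored
#' values (linear interpolation for the percentile). One result row is
#' returned per input taxon regardless of significance.
#'
#' @param table An [abundance_table()], typically restricted to the earliest
#'   sample per subject.
#' @param records Records data.frame supplying the outcome per sample.
#' @param taxa Taxa to screen; defaults to [filter_low_abundance()] applied
#'   to `table`.
#' @param alpha_fdr Significance cutoff on the q-value (default 0.05).
#' @param zero_floor Passed to [mann_whitney()].
#' @return Data.frame with columns `taxon`, `u_statistic`, `p_value`,
#'   `q_value`, `median_ptb`, `median_tb`, `p75_ptb`, `p75_tb`, `direction`
#'   (sign of the median difference) and `significant`.
#' @export
differential_screen <- function(table, records,
                                taxa = filter_low_abundance(table),
                                alpha_fdr = 0.05, zero_floor = 1e-5) {
  stopifnot(inherits(table, "abundance_table"))
  validate_records(records)
  oc <- records$outcome[match(table$sample_ids, records$sample_id)]
  if (anyNA(oc)) stopf("some samples lack metadata records")
  taxa <- canonical_taxon(taxa)
  m <- table$values[, taxa, drop = FALSE]
  res <- lapply(taxa, function(tx) {
    v <- m[, tx]
    v <- ifelse(v < zero_floor, 0, v)
    xp <- v[oc == "PTB"]; xt <- v[oc == "TB"]
    mw <- mann_whitney(xp, xt, zero_floor = zero_floor)
    data.frame(taxon = tx, u_statistic = mw$u, p_value = mw$p,
               median_ptb = stats::median(xp), median_tb = stats::median(xt),
               p75_ptb = unname(stats::quantile(xp, 0.75, type = 7)),
               p75_tb = unname(stats::quantile(xt, 0.75, type = 7)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_value <- bh_adjust(out$p_value)
  out$direction <- sign(out$median_ptb - out$median_tb)
  out$significant <- out$q_value < alpha_fdr
  rownames(out) <- NULL
  out[, c("taxon", "u_statistic", "p_value", "q_value", "median_ptb",
          "median_tb", "p75_ptb", "p75_tb", "direction", "significant")]
}

#' Fisher's exact contrast of L. crispatus vagitype frequency by outcome
#'
#' Builds the 2x2 table of (L. crispatus vagitype vs. any other assigned
#' vagitype) by (PTB vs. TB), counting one earliest assigned sample per
#' subject, and applies [fisher_exact_2x2()]. UNASSIGNED samples are excluded
#' from the contrast.
#'
#' @param assignments Output of [assign_vagitype()].
#' @param records Records data.frame.
#' @param taxon Vagitype of interest (default the L. crispatus cluster).
#' @return List with the 2x2 `table` and two-sided `p`.
#' @export
cst_outcome_test <- function(assignments, records,
                             taxon = "Lactobacillus_crispatus_cluster") {
  validate_records(records)
  taxon <- canonical_taxon(taxon)
  idx <- match(assignments$sample_id, records$sample_id)
  if (anyNA(idx)) stopf("assignments contain samples without records")
  df <- data.frame(subject_id = records$subject_id[idx],
                   gestational_age = records$gestational_age[idx],
                   outcome = records$outcome[idx],
                   vagitype = assignments$vagitype,
                   sample_id = assignments$sample_id,
                   stringsAsFactors = FALSE)
  df <- df[df$vagitype != "UNASSIGNED", , drop = FALSE]
  df <- df[order(df$subject_id, df$gestational_age, df$sample_id), , drop = FALSE]
  df <- df[!duplicated(df$subject_id), , drop = FALSE]
  tab <- matrix(c(sum(df$vagitype == taxon & df$outcome == "PTB"),
                  sum(df$vagitype != taxon & df$outcome == "PTB"),
                  sum(df$vagitype == taxon & df$outcome == "TB"),
                  sum(df$vagitype != taxon & df$outcome == "TB")),
                2, 2, byrow = TRUE,
                dimnames = list(c("PTB", "TB"), c(taxon, "other")))
  list(table = tab, p = fisher_exact_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]))
}
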