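#' Cohort description table
#'
#' Per-outcome-group summary in the conventional case-control layout: mean
#' (SD) age; counts and percentages for ancestry, household income bracket,
#' vaginal delivery, previous preterm birth and PPROM. Percentages are
#' `100 * count / non-missing group size`, rounded half-up to one decimal;
#' missing values are excluded from the denominator of their variable and
#' reported separately.
#'
#' @param records Records data.frame, one row per subject (e.g. earliest
#'   sample per subject, or subject-level metadata).
#' @return A `cohort_summary`: list of data.frames (`age`, `ancestry`,
#'   `income`, `flags`), each carrying counts, percentages, and per-variable
#'   missing counts.
#' @export
summarize_cohort <- function(records) {
  validate_records(records)
  if (anyDuplicated(records$subject_id))
    stopf("summarize_cohort expects one row per subject")
  groups <- c("PTB", "TB")
  if (nrow(records) == 0L) {
    warnf("empty cohort; empty summary returned")
    return(structure(list(), class = "cohort_summary"))
  }

  pct_rows <- function(var, levels_) {
    do.call(rbind, lapply(levels_, function(lv) {
      row <- data.frame(level = lv)
      for (g in groups) {
        v <- records[[var]][records$outcome == g]
        denom <- sum(!is.na(v))
        cnt <- sum(v == lv, na.rm = TRUE)
        row[[paste0("n_", g)]] <- cnt
        row[[paste0("pct_", g)]] <-
          if (denom > 0) round_half_up(100 * cnt / denom, 1) else NA_real_
      }
      row
    }))
  }
  miss_counts <- function(var) {
    vapply(groups, function(g)
      sum(is.na(records[[var]][records$outcome == g])), numeric(1))
  }

  age <- do.call(rbind, lapply(groups, function(g) {
    v <- records$age[records$outcome == g]
    data.frame(group = g, n = sum(records$outcome == g),
               mean_age = round_half_up(mean(v, na.rm = TRUE), 1),
               sd_age = round_half_up(stats::sd(v, na.rm = TRUE), 2))
  }))
  ancestry <- pct_rows("ancestry", c("African", "European", "Hispanic",
                                     "NativeAmerican"))
  income <- pct_rows("income_bracket", 1:3)
  flag_tab <- do.call(rbind, lapply(
    c("vaginal_delivery", "hist_ptb", "pprom"), function(var) {
      r <- pct_rows(var, 1)
      r$level <- var
      r
    }))
  structure(list(age = age, ancestry = ancestry, income = income,
                 flags = flag_tab,
                 missing = list(income = miss_counts("income_bracket"))),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  if (length(x) == 0L) { cat("cohort_summary: empty\n"); return(invisible(x)) }
  cat("Cohort description\n\nAge:\n")
  print(x$age, row.names = FALSE)
  cat("\nAncestry (n, %):\n")
  print(x$ancestry, row.names = FALSE)
  cat("\nIncome bracket (n, %; missing excluded):\n")
  print(x$income, row.names = FALSE)
  cat("\nClinical flags (n, %):\n")
  print(x$flags, row.names = FALSE)
  invisible(x)
}
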