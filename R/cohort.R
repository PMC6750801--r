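## Sample metadata ("records") travel as a plain data.frame with the columns
## below; clinical flags are 0/1 integers, missing values NA.

RECORD_COLUMNS <- c("sample_id", "subject_id", "gestational_age", "outcome",
                    "bmi", "vaginal_ph", "ethnicity", "ancestry", "age",
                    "income_bracket", "short_cervix", "cerclage",
                    "progesterone", "gravidity", "parity",
                    "hist_miscarriage", "hist_ptb", "antibiotics_6mo",
                    "vaginal_delivery", "pprom")

#' Validate a sample-record table
#'
#' Records are longitudinal per-sample metadata: `sample_id`, `subject_id`,
#' `gestational_age` (integer days since conception), `outcome` (`"PTB"` or
#' `"TB"`), `bmi` (kg/m^2), `vaginal_ph`, `ethnicity` (0 = African ancestry,
#' 1 = all other ancestries), `ancestry` (label), `age` (years),
#' `income_bracket` (ordinal 1..3), plus 0/1 clinical flags (`short_cervix`,
#' `cerclage`, `progesterone`, `gravidity`, `parity`, `hist_miscarriage`,
#' `hist_ptb`, `antibiotics_6mo`, `vaginal_delivery`, `pprom`).
#'
#' @param records A data.frame of per-sample metadata.
#' @return The validated data.frame (invisibly usable in pipelines).
#' @export
validate_records <- function(records) {
  need <- c("sample_id", "subject_id", "gestational_age", "outcome")
  miss <- setdiff(need, names(records))
  if (length(miss)) stopf("records missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(records$sample_id)) stopf("duplicate sample_id in records")
  ga <- records$gestational_age
  if (any(!is.na(ga) & (ga < 0 | ga > 315)))
    stopf("gestational_age outside [0, 315] days")
  if (!all(records$outcome %in% c("PTB", "TB")))
    stopf("outcome must be 'PTB' or 'TB'")
  if ("ethnicity" %in% names(records) &&
      !all(records$ethnicity %in% c(0, 1, NA)))
    stopf("ethnicity indicator must be 0 (African ancestry) or 1 (other)")
  records
}

#' Read / write sample metadata TSV
#'
#' Missing values are encoded as empty fields.
#'
#' @param path TSV path.
#' @return `read_records`: a validated records data.frame.
#' @export
read_records <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", na.strings = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  validate_records(df)
}

#' @param records Records data.frame.
#' @rdname read_records
#' @export
write_records <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}

#' Earliest sample per subject within a gestational-age window
#'
#' Selects, for each subject, the sample with the minimum gestational age
#' inside the inclusive window (the predictive-modeling default is days
#' 42-167 of gestation). Subjects with no sample in the window are excluded.
#' Ties on gestational age within a subject are broken by lexicographic
#' `sample_id` (logged as a message).
#'
#' @param records Records data.frame.
#' @param window Integer vector `c(day_lo, day_hi)`, inclusive.
#' @return One record row per retained subject.
#' @export
earliest_sample_in_window <- function(records, window = c(42, 167)) {
  validate_records(records)
  stopifnot(length(window) == 2L, window[1] <= window[2])
  inw <- records$gestational_age >= window[1] &
    records$gestational_age <= window[2] & !is.na(records$gestational_age)
  r <- records[inw, , drop = FALSE]
  if (nrow(r) == 0L) return(r)
  ## order by (subject, day, sample_id) and keep the first row per subject
  o <- order(r$subject_id, r$gestational_age, r$sample_id)
  r <- r[o, , drop = FALSE]
  first <- !duplicated(r$subject_id)
  ties <- tapply(r$gestational_age, r$subject_id,
                 function(g) sum(g == g[1]) > 1)
  if (any(ties))
    message(sprintf("earliest_sample_in_window: %d subject(s) had ties on gestational age; lexicographic sample_id tie-break applied", sum(ties)))
  out <- r[first, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match term controls to preterm cases
#'
#' Greedy multi-pass case-control matching on ethnicity, age and household
#' income, without replacement, blinded to everything else. Pass 0 requires
#' exact ethnicity, age within +/-2 years and the same income bracket; each
#' subsequent pass widens the age tolerance by 2 years (up to +/-10), then
#' income is dropped, then age, leaving ethnicity-only matching as the final
#' pass. Among equally eligible controls the closest in age is preferred,
#' with a seeded shuffle breaking exact ties.
#'
#' @param cases Data.frame of case subjects, one row each, with columns
#'   `subject_id`, `ethnicity`, `age`, `income_bracket`.
#' @param pool Data.frame of candidate control subjects (same columns),
#'   disjoint from `cases`.
#' @param ratio Controls per case (default 2).
#' @param seed Optional integer seed for the tie-break shuffle.
#' @return A `cohort_table`: list with `cases`, `controls` (subject ids) and
#'   `match_map` (named list, case id -> matched control ids).
#' @export
match_controls <- function(cases, pool, ratio = 2, seed = NULL) {
  stopifnot(ratio >= 1)
  if (anyDuplicated(c(cases$subject_id, pool$subject_id)))
    stopf("cases and pool must be disjoint with unique subject ids")
  with_seed(seed, {
    pool <- pool[sample.int(nrow(pool)), , drop = FALSE] # seeded tie-break order
    available <- rep(TRUE, nrow(pool))
    matched <- stats::setNames(vector("list", nrow(cases)), cases$subject_id)
    need <- stats::setNames(rep(ratio, nrow(cases)), cases$subject_id)

    passes <- c(lapply(seq(2, 10, by = 2), function(tol)
      list(age_tol = tol, use_income = TRUE)),
      list(list(age_tol = 10, use_income = FALSE),
           list(age_tol = Inf, use_income = FALSE)))
    for (p in passes) {
      for (ci in seq_len(nrow(cases))) {
        cid <- cases$subject_id[ci]
        while (need[cid] > 0) {
          ok <- available & pool$ethnicity == cases$ethnicity[ci]
          if (p$use_income) ok <- ok & pool$income_bracket == cases$income_bracket[ci]
          if (is.finite(p$age_tol)) ok <- ok & abs(pool$age - cases$age[ci]) <= p$age_tol
          ok[is.na(ok)] <- FALSE
          if (!any(ok)) break
          cand <- which(ok)
          best <- cand[which.min(abs(pool$age[cand] - cases$age[ci]))]
          matched[[cid]] <- c(matched[[cid]], pool$subject_id[best])
          available[best] <- FALSE
          need[cid] <- need[cid] - 1
        }
      }
      if (all(need == 0)) break
    }
    if (any(need > 0))
      stopf("control pool exhausted; unmatched case(s): %s",
            paste(names(need)[need > 0], collapse = ", "))
    structure(list(cases = cases$subject_id,
                   controls = unlist(matched, use.names = FALSE),
                   match_map = matched),
              class = "cohort_table")
  })
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("cohort_table: %d cases, %d matched controls (%d subjects)\n",
              length(x$cases), length(x$controls),
              length(x$cases) + length(x$controls)))
  invisible(x)
}
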