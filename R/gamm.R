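#' Response transform for longitudinal abundance models
#'
#' The shared soft-threshold log10 transform ([soft_threshold_log()]) is used
#' as the response for trajectory models, keeping the response scale
#' coherent with the predictive-model features.
#'
#' @param abundance Proportions in [0, 1].
#' @return Transformed response values in [0, 3].
#' @export
log_abundance_response <- function(abundance) soft_threshold_log(abundance)

gamm_frame <- function(table, records, taxon) {
  taxon <- canonical_taxon(taxon)
  if (!taxon %in% table$taxon_ids) stopf("taxon %s not in table", taxon)
  idx <- match(table$sample_ids, records$sample_id)
  if (anyNA(idx)) stopf("some samples lack metadata records")
  r <- records[idx, , drop = FALSE]
  data.frame(y = log_abundance_response(table$values[, taxon]),
             po = factor(r$outcome, levels = c("TB", "PTB")),
             bmi = r$bmi, ph = r$vaginal_ph,
             ethnicity = r$ethnicity,
             ga = r$gestational_age,
             subject = factor(r$subject_id),
             stringsAsFactors = FALSE)
}

#' Longitudinal penalized-spline mixed model of a taxon's abundance
#'
#' Fits `stl(abundance) ~ b0 + b1 PO + b2 BMI + b3 pH + b4 I_ethnicity +
#' f(ga) x PO + subject` where `f(ga) x PO` is a penalized cubic B-spline
#' smoother of gestational age per outcome level (second-difference penalty,
#' shared smoothing parameter across levels), the subject term is a random
#' intercept, and the smoothing parameter and variance components are
#' estimated by REML. Effect contributions are tested with ANOVA-style
#' approximate F/Wald tests.
#'
#' @param table An [abundance_table()] with longitudinal samples.
#' @param records Records data.frame (must cover all samples).
#' @param taxon Taxon label (canonical or abbreviation).
#' @param basis_dim Spline basis dimension per outcome level (default 10).
#' @param include Fixed effects to include besides the smoother; dropped
#'   automatically in stratified fits.
#' @param lambda Optional fixed smoothing parameter(s) for the gestational
#'   age smoother (e.g. `0` for an unpenalized regression-spline fit); the
#'   default estimates them by REML.
#' @param random_subject Include the random subject intercept
#'   (default TRUE).
#' @return A `gamm_fit`: list with the `mgcv` fit, fixed-effect table,
#'   `lambda` (smoothing parameters), `sigma_subject`, `sigma_resid`, the
#'   ANOVA effect tests, and predicted trajectories with 98% pointwise
#'   confidence bands per outcome level.
#' @export
fit_gamm <- function(table, records, taxon, basis_dim = 10,
                     include = c("po", "bmi", "ph", "ethnicity"),
                     lambda = NULL, random_subject = TRUE) {
  df <- gamm_frame(table, records, taxon)
  if (length(unique(df$ga)) > 1 && diff(range(df$ga)) < 60)
    warnf("gestational ages span under 60 days; smoother may be poorly identified")
  para <- intersect(include, c("po", "bmi", "ph", "ethnicity"))
  by_po <- "po" %in% para && nlevels(droplevels(df$po)) == 2
  ## a P-spline basis cannot exceed the number of distinct design points
  basis_dim <- min(basis_dim, max(length(unique(df$ga)) - 1, 4))
  sm <- if (by_po)
    sprintf("s(ga, by = po, bs = 'ps', k = %d, m = c(2, 2), id = 1)", basis_dim)
  else
    sprintf("s(ga, bs = 'ps', k = %d, m = c(2, 2))", basis_dim)
  terms <- c(para, sm, if (random_subject) "s(subject, bs = 're')")
  form <- stats::as.formula(paste("y ~", paste(terms, collapse = " + ")))
  sp <- NULL
  if (!is.null(lambda)) {
    n_sm <- if (by_po) 1L else 1L  # shared id => one sp for the ga smoother
    sp <- c(rep_len(lambda, n_sm), if (random_subject) -1)
  }
  fit <- mgcv::gam(form, data = df, method = "REML", sp = sp)
  if (!fit$converged) stopf("REML estimation did not converge")

  ## for a random-effect smooth, sigma_subject^2 = sig2 / sp(subject)
  sig_res <- sqrt(fit$sig2)
  sp_sub <- fit$sp[grepl("subject", names(fit$sp))]
  sig_sub <- if (length(sp_sub)) sqrt(fit$sig2 / sp_sub[[1]]) else NA_real_
  lambda <- fit$sp[!grepl("subject", names(fit$sp))]
  an <- stats::anova(fit)

  ## fitted trajectories with 98% pointwise bands, at covariate means
  ga_grid <- seq(min(df$ga), max(df$ga), length.out = 60)
  levs <- if (by_po) levels(df$po) else "all"
  traj <- do.call(rbind, lapply(levs, function(lv) {
    nd <- data.frame(ga = ga_grid,
                     po = factor(if (by_po) lv else df$po[1], levels = levels(df$po)),
                     bmi = mean(df$bmi, na.rm = TRUE),
                     ph = mean(df$ph, na.rm = TRUE),
                     ethnicity = stats::median(df$ethnicity, na.rm = TRUE),
                     subject = df$subject[1])
    pr <- mgcv::predict.gam(fit, nd, se.fit = TRUE,
                            exclude = if (random_subject) "s(subject)",
                            newdata.guaranteed = TRUE)
    crit <- stats::qnorm(0.99) # 98% pointwise band
    data.frame(outcome = lv, ga = ga_grid, fit = as.numeric(pr$fit),
               lo = as.numeric(pr$fit - crit * pr$se.fit),
               hi = as.numeric(pr$fit + crit * pr$se.fit))
  }))
  structure(list(fit = fit, taxon = canonical_taxon(taxon),
                 coefficients = stats::coef(fit)[seq_len(length(para) + 1)],
                 lambda = lambda, sigma_subject = sig_sub,
                 sigma_resid = sig_res, anova = an, trajectories = traj,
                 basis_dim = basis_dim),
            class = "gamm_fit")
}

#' @export
print.gamm_fit <- function(x, ...) {
  cat(sprintf("gamm_fit for %s: lambda = %s, sigma_subject = %.3g, sigma_resid = %.3g\n",
              x$taxon, paste(signif(x$lambda, 3), collapse = "/"),
              x$sigma_subject, x$sigma_resid))
  invisible(x)
}

#' Ancestry-by-outcome stratified trajectory fits
#'
#' Fits the trajectory model independently within each ancestry x outcome
#' stratum, dropping the ethnicity and outcome fixed effects (constant
#' within a stratum). Strata with fewer subjects than `min_subjects` are
#' flagged low-power; empty strata are skipped with a warning.
#'
#' @param table An [abundance_table()].
#' @param records Records data.frame.
#' @param taxon Taxon label.
#' @param basis_dim Spline basis dimension.
#' @param min_subjects Low-power flag threshold (default 5).
#' @return Named list of per-stratum results (`fit`, `n_subjects`,
#'   `low_power`), names `"<ancestry>.<outcome>"` with ancestry `"AA"`
#'   (African, indicator 0) or `"nonAA"`.
#' @export
stratified_fits <- function(table, records, taxon, basis_dim = 10,
                            min_subjects = 5) {
  validate_records(records)
  strata <- expand.grid(eth = c(0, 1), outcome = c("PTB", "TB"),
                        stringsAsFactors = FALSE)
  out <- list()
  for (i in seq_len(nrow(strata))) {
    keep <- records$ethnicity == strata$eth[i] &
      records$outcome == strata$outcome[i]
    name <- paste0(ifelse(strata$eth[i] == 0, "AA", "nonAA"), ".",
                   strata$outcome[i])
    if (!any(keep, na.rm = TRUE)) {
      warnf("stratum %s is empty; skipped", name)
      next
    }
    r <- records[which(keep), , drop = FALSE]
    tab <- subset_samples(table, intersect(table$sample_ids, r$sample_id))
    n_subj <- length(unique(r$subject_id))
    f <- fit_gamm(tab, r, taxon, basis_dim = basis_dim,
                  include = c("bmi", "ph"))
    out[[name]] <- list(fit = f, n_subjects = n_subj,
                        low_power = n_subj < min_subjects)
  }
  out
}
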