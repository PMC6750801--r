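## ---- L1-regularized logistic regression -----------------------------------

#' Fit L1-regularized logistic regression (penalty-multiplier form)
#'
#' Minimizes `sum_i ln(1 + exp(-y_i (w'x_i + b))) + C * ||w||_1` with an
#' unpenalized intercept `b`, by proximal gradient descent with FISTA
#' acceleration and exact soft-thresholding (so irrelevant weights are
#' exactly zero). Note the convention: `C` multiplies the PENALTY, so larger
#' `C` means more shrinkage — the reverse of the `C` used by some libraries
#' (and the reciprocal-times-n of glmnet's `lambda`: `lambda = C/n`).
#'
#' @param x Numeric feature matrix (n x p).
#' @param y Labels: +1 (PTB) / -1 (TB), or a factor/character with levels
#'   `"PTB"`/`"TB"`.
#' @param C Non-negative penalty multiplier.
#' @param tol Convergence tolerance on the objective decrease (default 1e-8).
#' @param max_iter Iteration cap (default 20000). Hitting the cap (e.g. with
#'   `C = 0` on separable data, where no finite minimizer exists) raises a
#'   warning carrying the final objective, and the current iterate is
#'   returned.
#' @return List with `w` (named weights), `intercept`, `objective`,
#'   `iterations`, `converged`.
#' @export
fit_l1_logistic <- function(x, y, C, tol = 1e-8, max_iter = 20000) {
  x <- as.matrix(x)
  y <- encode_labels(y)
  if (C < 0) stopf("C must be non-negative")
  if (length(unique(y)) < 2L) stopf("both classes must be present")
  n <- nrow(x); p <- ncol(x)
  if (p == 0L) {
    b <- log(sum(y > 0) / sum(y < 0))
    return(list(w = numeric(0), intercept = b,
                objective = sum(log1p(exp(-y * b))), iterations = 0L,
                converged = TRUE))
  }
  x1 <- cbind(x, 1)
  ## Lipschitz constant of the gradient of the smooth part
  L <- 0.25 * (svd(x1, nu = 0, nv = 0)$d[1])^2
  step <- 1 / L
  obj <- function(z) {
    f <- drop(x1 %*% z)
    sum(log1p(exp(-y * f))) + C * sum(abs(z[seq_len(p)]))
  }
  grad <- function(z) {
    f <- drop(x1 %*% z)
    drop(crossprod(x1, -y * stats::plogis(-y * f)))
  }
  z <- numeric(p + 1)        # (w, b)
  zv <- z                    # FISTA extrapolation point
  tk <- 1
  ob <- obj(z)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    g <- grad(zv)
    znew <- zv - step * g
    znew[seq_len(p)] <- sign(znew[seq_len(p)]) *
      pmax(abs(znew[seq_len(p)]) - step * C, 0)
    tnew <- (1 + sqrt(1 + 4 * tk^2)) / 2
    zv <- znew + ((tk - 1) / tnew) * (znew - z)
    obn <- obj(znew)
    if (obn > ob) { zv <- znew; tnew <- 1 }  # restart on non-monotone step
    if (abs(ob - obn) < tol * max(1, abs(obn)) && it > 1L) {
      z <- znew; ob <- obn; converged <- TRUE; break
    }
    z <- znew; ob <- obn; tk <- tnew
  }
  if (!converged)
    warnf("fit_l1_logistic: iteration cap %d reached (objective %.6g, C = %g); returning current iterate",
          max_iter, ob, C)
  w <- z[seq_len(p)]
  names(w) <- colnames(x)
  list(w = w, intercept = as.numeric(z[p + 1]), objective = ob,
       iterations = it, converged = converged)
}

encode_labels <- function(y) {
  if (is.numeric(y)) {
    if (!all(y %in% c(-1, 1))) stopf("numeric labels must be -1/+1")
    return(y)
  }
  y <- as.character(y)
  if (!all(y %in% c("PTB", "TB"))) stopf("labels must be 'PTB' or 'TB'")
  ifelse(y == "PTB", 1, -1)
}

#' Area under the ROC curve via the rank statistic
#'
#' Equals the probability that a random case outscores a random control,
#' counting ties as one half (midranks), i.e. the normalized Mann-Whitney U
#' of the case scores.
#'
#' @param scores Numeric decision values.
#' @param labels +1/-1 or `"PTB"`/`"TB"` per score.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, labels) {
  y <- encode_labels(labels)
  n1 <- sum(y > 0); n0 <- sum(y < 0)
  if (n1 == 0 || n0 == 0) stopf("both classes required for AUROC")
  r <- rank(scores)
  (sum(r[y > 0]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## ---- two-step training ----------------------------------------------------

#' Default classifier configuration
#'
#' @param p_cut Two-sided Mann-Whitney retention cutoff for step 1
#'   (default 0.05, inclusive).
#' @param C_grid Penalty-multiplier grid for the inner cross-validated search
#'   (default 13 log-spaced points over 1e-3..1e3). A length-1 grid skips the
#'   inner CV.
#' @param k Inner stratified fold count (default 5).
#' @param zero_floor Zero-rounding floor used by the step-1 filter.
#' @return List of settings consumed by [two_step_train()] and friends.
#' @export
classifier_config <- function(p_cut = 0.05,
                              C_grid = 10^seq(-3, 3, length.out = 13),
                              k = 5, zero_floor = 1e-5) {
  list(p_cut = p_cut, C_grid = C_grid, k = k, zero_floor = zero_floor)
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Two-step PTB model training
#'
#' Step 1 retains features whose two-sided Mann-Whitney p-value (cases vs.
#' controls, with the zero floor) is at most `p_cut`. Step 2 fits
#' [fit_l1_logistic()] on the retained features, with the penalty multiplier
#' `C` chosen by stratified k-fold grid search on the training data,
#' maximizing cross-validated AUROC (ties resolved toward the larger,
#' sparser, `C`). If no feature survives step 1 a flagged intercept-only
#' model is returned.
#'
#' @param x Feature matrix (n subjects x p features), e.g.
#'   [soft_threshold_log()]-transformed abundances in [0, 3] or min-max
#'   normalized clinical features in [0, 1].
#' @param y Labels (+1/-1 or "PTB"/"TB").
#' @param config A [classifier_config()].
#' @return A `ptb_model`: list with `selected_features`, `w`, `intercept`,
#'   `C`, `intercept_only` flag and `cv_auroc` per grid point.
#' @export
two_step_train <- function(x, y, config = classifier_config()) {
  x <- as.matrix(x)
  y <- encode_labels(y)
  p_filter <- mw_pvals_matrix(x, y > 0, zero_floor = config$zero_floor)
  keep <- which(p_filter <= config$p_cut)
  if (length(keep) == 0L) {
    fit <- fit_l1_logistic(x[, 0, drop = FALSE], y, C = 0)
    return(structure(list(selected_features = character(0), w = numeric(0),
                          intercept = fit$intercept, C = NA_real_,
                          intercept_only = TRUE, cv_auroc = NULL,
                          filter_p = p_filter),
                     class = "ptb_model"))
  }
  xs <- x[, keep, drop = FALSE]
  grid <- config$C_grid
  cv_auc <- NULL
  if (length(grid) > 1L) {
    fold <- stratified_folds(y, config$k)
    held <- matrix(NA_real_, nrow(xs), length(grid))
    for (f in seq_len(config$k)) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2L) next
      for (ci in seq_along(grid)) {
        m <- fit_l1_logistic(xs[tr, , drop = FALSE], y[tr], C = grid[ci])
        held[!tr, ci] <- drop(xs[!tr, , drop = FALSE] %*% m$w) + m$intercept
      }
    }
    cv_auc <- apply(held, 2, function(s) auroc(s[!is.na(s)], y[!is.na(s)]))
    best <- max(cv_auc)
    C <- grid[max(which(cv_auc >= best - 1e-12))] # sparser model on ties
  } else {
    C <- grid[1]
  }
  fit <- fit_l1_logistic(xs, y, C = C)
  structure(list(selected_features = colnames(xs), w = fit$w,
                 intercept = fit$intercept, C = C, intercept_only = FALSE,
                 cv_auroc = cv_auc, filter_p = p_filter),
            class = "ptb_model")
}

#' @export
print.ptb_model <- function(x, ...) {
  if (x$intercept_only) {
    cat("ptb_model: intercept-only (no feature passed the univariate filter)\n")
  } else {
    nz <- x$w[x$w != 0]
    cat(sprintf("ptb_model: %d selected features, %d nonzero weights, C = %g\n",
                length(x$selected_features), length(nz), x$C))
  }
  invisible(x)
}

#' Decision values from a fitted two-step model
#'
#' @param object A `ptb_model`.
#' @param newdata Feature matrix containing at least the selected features.
#' @param ... Unused.
#' @return Numeric decision values `w'x + b`; positive predicts PTB.
#' @export
predict.ptb_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (object$intercept_only || length(object$w) == 0L)
    return(rep(object$intercept, nrow(newdata)))
  drop(newdata[, object$selected_features, drop = FALSE] %*% object$w) +
    object$intercept
}

## ---- evaluation -----------------------------------------------------------

#' Leave-one-out evaluation of the two-step model
#'
#' For each subject the ENTIRE two-step procedure (univariate filter, grid
#' search, fit) is rerun on the remaining subjects and the held-out decision
#' value is recorded, so feature selection never sees the held-out subject.
#' Sensitivity and specificity are reported at decision threshold 0 (a score
#' strictly greater than 0 predicts PTB) and AUROC by the tie-corrected rank
#' statistic over the held-out scores.
#'
#' @param x Feature matrix, one row per subject.
#' @param y Labels.
#' @param config A [classifier_config()].
#' @param filter_mode `"in-fold"` (default; leakage-free) reruns the
#'   univariate filter inside every fold; `"whole-cohort"` performs it once
#'   on all subjects before the folds, for comparison with pipelines that
#'   filtered on the full cohort.
#' @param normalize If `TRUE`, min-max normalization of each feature is
#'   learned on each fold's training rows and applied to the held-out row
#'   (used for clinical features). Constant features map to 0 with a warning.
#' @param return_models Also return the per-fold trained models (for
#'   leakage diagnostics; default FALSE).
#' @return List with `loo_scores`, `sensitivity`, `specificity`, `auroc`
#'   (and `models` when requested).
#' @export
loo_evaluate <- function(x, y, config = classifier_config(),
                         filter_mode = c("in-fold", "whole-cohort"),
                         normalize = FALSE, return_models = FALSE) {
  filter_mode <- match.arg(filter_mode)
  x <- as.matrix(x)
  y <- encode_labels(y)
  n <- nrow(x)
  if (filter_mode == "whole-cohort") {
    xn <- if (normalize) minmax_fit_apply(x, x)$x else x
    p_all <- mw_pvals_matrix(xn, y > 0, zero_floor = config$zero_floor)
    pre_keep <- which(p_all <= config$p_cut)
    cfg <- config
    cfg$p_cut <- 1 # filter already applied; keep all passed-in features
  }
  scores <- numeric(n)
  models <- if (return_models) vector("list", n) else NULL
  for (i in seq_len(n)) {
    if (length(unique(y[-i])) < 2L)
      stopf("a leave-one-out fold contains a single class")
    xtr <- x[-i, , drop = FALSE]; xte <- x[i, , drop = FALSE]
    if (normalize) {
      mm <- minmax_fit_apply(xtr, xte)
      xtr <- mm$x; xte <- mm$newx
    }
    if (filter_mode == "whole-cohort") {
      m <- two_step_train(xtr[, pre_keep, drop = FALSE], y[-i], cfg)
    } else {
      m <- two_step_train(xtr, y[-i], config)
    }
    scores[i] <- predict(m, xte)
    if (return_models) models[[i]] <- m
  }
  out <- list(loo_scores = scores,
              sensitivity = mean(scores[y > 0] > 0),
              specificity = mean(scores[y < 0] <= 0),
              auroc = auroc(scores, y))
  if (return_models) out$models <- models
  out
}

minmax_fit_apply <- function(xtr, xte) {
  lo <- apply(xtr, 2, min); hi <- apply(xtr, 2, max)
  rng <- hi - lo
  const <- rng == 0
  if (any(const))
    warnf("constant feature(s) set to 0 under min-max normalization: %s",
          paste(colnames(xtr)[const], collapse = ", "))
  rng[const] <- 1
  sc <- function(m) {
    out <- sweep(sweep(m, 2, lo, "-"), 2, rng, "/")
    out[, const] <- 0
    out
  }
  list(x = sc(xtr), newx = sc(xte))
}

#' Permutation significance of the two-step model
#'
#' Repeatedly permutes the outcome labels, reruns the full two-step training
#' and evaluation, and records the null AUROC. The p-value uses the add-one
#' estimator `p = (1 + #\{null >= observed\}) / (1 + n_perm)`, so it is never
#' zero.
#'
#' @param x Feature matrix, one row per subject.
#' @param y Labels.
#' @param n_perm Number of permutations (the study-scale default is 10000;
#'   smaller values are appropriate for simulation studies).
#' @param config A [classifier_config()].
#' @param eval `"loo"` evaluates every (observed and permuted) model by full
#'   leave-one-out AUROC; `"apparent"` uses the in-sample AUROC of a single
#'   trained model, a cheaper statistic with the same exchangeability.
#' @param seed Optional integer seed.
#' @param filter_mode Passed to [loo_evaluate()].
#' @return List with `p`, `observed_auroc`, `null_aurocs`.
#' @export
permutation_test <- function(x, y, n_perm = 10000,
                             config = classifier_config(),
                             eval = c("loo", "apparent"), seed = NULL,
                             filter_mode = "in-fold") {
  eval <- match.arg(eval)
  stopifnot(n_perm >= 1)
  x <- as.matrix(x)
  y <- encode_labels(y)
  stat <- function(yy) {
    if (eval == "loo") {
      loo_evaluate(x, yy, config, filter_mode = filter_mode)$auroc
    } else {
      m <- two_step_train(x, yy, config)
      auroc(predict(m, x), yy)
    }
  }
  with_seed(seed, {
    observed <- stat(y)
    nulls <- vapply(seq_len(n_perm), function(i) stat(sample(y)), numeric(1))
    list(p = (1 + sum(nulls >= observed)) / (1 + n_perm),
         observed_auroc = observed, null_aurocs = nulls)
  })
}

## ---- the published 4-taxon score and the clinical comparator --------------

#' The frozen four-taxon PTB risk score
#'
#' `0.775 stl(Samn) + 0.751 stl(BVAB1) + 0.116 stl(TM7) + 0.011 stl(Pcl2)`,
#' where `stl` is [soft_threshold_log()] and the taxa are Sneathia amnii,
#' Lachnospiraceae BVAB1, TM7-H1 and Prevotella cluster 2. Coefficients are
#' shipped as a frozen scoring profile (they derive from a controlled-access
#' training cohort and are not re-estimated here). The score is monotone
#' non-decreasing in each abundance and ranges over [0, 4.959].
#'
#' @param abundances Named numeric vector of proportions; names may be
#'   canonical labels or the standard abbreviations (`Samn`, `BVAB1`, `TM7`,
#'   `Pcl2`). All four taxa must be present.
#' @return The scalar risk score.
#' @export
ptb_score <- function(abundances) {
  coefs <- c(Sneathia_amnii = 0.775, Lachnospiraceae_BVAB1 = 0.751,
             TM7_H1 = 0.116, Prevotella_cluster2 = 0.011)
  names(abundances) <- canonical_taxon(names(abundances))
  miss <- setdiff(names(coefs), names(abundances))
  if (length(miss)) stopf("missing taxon abundance(s): %s",
                          paste(miss, collapse = ", "))
  a <- abundances[names(coefs)]
  if (any(a < 0 | a > 1)) stopf("abundances must lie in [0, 1]")
  sum(coefs * soft_threshold_log(a))
}

#' Clinical-variable comparator model
#'
#' Builds the 11-variable clinical feature matrix (short cervix, cerclage,
#' vaginal pH, BMI, progesterone, gravidity, parity, gravidity minus parity,
#' history of miscarriage/stillbirth, history of PTB, antibiotics in the
#' prior 6 months; YES/NO flags coded 1/0) from one record per subject,
#' min-max normalizes continuous features to [0, 1] inside each training
#' fold, and runs the identical two-stage pipeline with leave-one-out
#' evaluation.
#'
#' @param records Records data.frame, one row per subject (e.g. the output
#'   of [earliest_sample_in_window()]).
#' @param config A [classifier_config()].
#' @param filter_mode Passed to [loo_evaluate()].
#' @return List with `model` (trained on all subjects) and `evaluation`
#'   (leave-one-out results).
#' @export
clinical_model <- function(records, config = classifier_config(),
                           filter_mode = "in-fold") {
  validate_records(records)
  if (anyDuplicated(records$subject_id))
    stopf("records must contain one row per subject")
  x <- clinical_features(records)
  y <- encode_labels(records$outcome)
  ev <- loo_evaluate(x, y, config, filter_mode = filter_mode, normalize = TRUE)
  xn <- minmax_fit_apply(x, x)$x
  list(model = two_step_train(xn, y, config), evaluation = ev)
}

#' @rdname clinical_model
#' @return `clinical_features`: the raw (un-normalized) 11-column matrix.
#' @export
clinical_features <- function(records) {
  need <- c("short_cervix", "cerclage", "vaginal_ph", "bmi", "progesterone",
            "gravidity", "parity", "hist_miscarriage", "hist_ptb",
            "antibiotics_6mo")
  miss <- setdiff(need, names(records))
  if (length(miss)) stopf("records missing clinical column(s): %s",
                          paste(miss, collapse = ", "))
  m <- cbind(short_cervix = records$short_cervix,
             cerclage = records$cerclage,
             vaginal_ph = records$vaginal_ph,
             bmi = records$bmi,
             progesterone = records$progesterone,
             gravidity = records$gravidity,
             parity = records$parity,
             gravidity_minus_parity = records$gravidity - records$parity,
             hist_miscarriage = records$hist_miscarriage,
             hist_ptb = records$hist_ptb,
             antibiotics_6mo = records$antibiotics_6mo)
  rownames(m) <- records$subject_id
  m
}
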