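make_toy_xy <- function(n = 40, p = 6, signal = 1.5, seed = 31) {
  set.seed(seed)
  y <- rep(c(1, -1), length.out = n)
  x <- matrix(runif(n * p, 0, 3), n, p,
              dimnames = list(paste0("s", 1:n), paste0("f", 1:p)))
  x[, 1] <- pmin(pmax(x[, 1] + signal * (y > 0), 0), 3)
  x[, 2] <- pmin(pmax(x[, 2] + 0.6 * signal * (y > 0), 0), 3)
  list(x = x, y = y)
}

test_that("a dominating penalty zeroes the weights and leaves the MLE intercept", {
  d <- make_toy_xy()
  fit <- fit_l1_logistic(d$x, d$y, C = 1e6)
  expect_true(all(fit$w == 0))
  expect_equal(fit$intercept, log(sum(d$y > 0) / sum(d$y < 0)),
               tolerance = 1e-5)
})

test_that("C = 0 on separable data stops at the iteration cap with a warning", {
  x <- matrix(c(0, 0.2, 2.8, 3), 4, 1, dimnames = list(NULL, "f"))
  y <- c(-1, -1, 1, 1)
  expect_warning(fit <- fit_l1_logistic(x, y, C = 0, max_iter = 300),
                 "iteration cap")
  expect_false(fit$converged)
})

test_that("the smooth-part gradient vanishes (to subgradient tolerance) at the solution", {
  set.seed(32)
  for (rep in 1:5) {
    n <- 25; p <- 4
    x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
    y <- sign(rnorm(n)); y[y == 0] <- 1
    if (length(unique(y)) < 2) next
    C <- 0.5
    fit <- fit_l1_logistic(x, y, C = C, tol = 1e-12)
    z <- c(fit$w, fit$intercept)
    smooth_loss <- function(z) {
      f <- drop(cbind(x, 1) %*% z)
      sum(log1p(exp(-y * f)))
    }
    ## central finite differences of the smooth part
    g_num <- vapply(seq_along(z), function(j) {
      h <- 1e-6; e <- numeric(length(z)); e[j] <- h
      (smooth_loss(z + e) - smooth_loss(z - e)) / (2 * h)
    }, numeric(1))
    ## optimality: |g_j| <= C where w_j = 0; g_j = -C sign(w_j) otherwise;
    ## intercept gradient = 0
    for (j in seq_len(p)) {
      if (fit$w[j] == 0) expect_lte(abs(g_num[j]), C + 1e-3)
      else expect_equal(unname(g_num[j]), unname(-C * sign(fit$w[j])),
                        tolerance = 1e-3)
    }
    expect_lt(abs(g_num[p + 1]), 1e-3)
  }
})

test_that("the l1 norm of the solution is non-increasing in C", {
  d <- make_toy_xy()
  grid <- 10^seq(-3, 3, length.out = 13)
  norms <- vapply(grid, function(C)
    sum(abs(fit_l1_logistic(d$x, d$y, C = C)$w)), numeric(1))
  expect_true(all(diff(norms) <= 1e-6))
})

test_that("the solver agrees with an independent coordinate-descent implementation", {
  skip_if_not_installed("glmnet")
  d <- make_toy_xy(n = 60, p = 5)
  n <- nrow(d$x)
  for (C in c(0.5, 2, 8)) {
    fit <- fit_l1_logistic(d$x, d$y, C = C, tol = 1e-12)
    g <- glmnet::glmnet(d$x, factor(d$y), family = "binomial",
                        lambda = C / n, standardize = FALSE,
                        thresh = 1e-14)
    expect_equal(unname(fit$w), unname(as.numeric(g$beta)), tolerance = 1e-4)
    expect_equal(fit$intercept, unname(as.numeric(g$a0)), tolerance = 1e-4)
  }
})

test_that("AUROC equals brute-force pair counting, including ties", {
  expect_equal(auroc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, -1, -1)), 1)
  set.seed(33)
  for (rep in 1:30) {
    n <- sample(4:30, 1)
    y <- c(1, -1, sign(rnorm(n - 2))); y[y == 0] <- 1
    s <- sample(round(rnorm(n), 1)) # coarse values induce ties
    expect_equal(auroc(s, y), auroc_pairs_oracle(s, y), tolerance = 1e-12)
  }
})

test_that("two-step training selects signal features and degrades gracefully", {
  d <- make_toy_xy(n = 60, signal = 2)
  set.seed(34)
  m <- two_step_train(d$x, d$y)
  expect_true(all(c("f1", "f2") %in% m$selected_features))
  ## p_cut = 0: no feature can pass -> flagged intercept-only model
  m0 <- two_step_train(d$x, d$y, classifier_config(p_cut = 0))
  expect_true(m0$intercept_only)
  expect_length(m0$w, 0)
})

test_that("under permuted labels the filter selects about alpha of the features", {
  set.seed(35)
  n <- 40; p <- 20
  x <- matrix(runif(n * p, 0, 3), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  frac <- replicate(100, {
    y <- sample(rep(c(1, -1), n / 2))
    m <- two_step_train(x, y, classifier_config(C_grid = 1))
    length(m$selected_features) / p
  })
  expect_gt(mean(frac), 0.01)
  expect_lt(mean(frac), 0.12) # ~0.05 expected under the null
})

test_that("the four-taxon score evaluates the printed coefficients exactly", {
  zero <- c(Samn = 0.001, BVAB1 = 0, TM7 = 0.0005, Pcl2 = 0.001)
  expect_equal(ptb_score(zero), 0)
  expect_equal(ptb_score(c(Samn = 1, BVAB1 = 0, TM7 = 0, Pcl2 = 0)),
               0.775 * 3, tolerance = 1e-12)
  expect_equal(ptb_score(c(Samn = 1, BVAB1 = 1, TM7 = 1, Pcl2 = 1)),
               4.959, tolerance = 1e-12)
  ## canonical names accepted; missing taxon named in the error
  expect_equal(ptb_score(c(Sneathia_amnii = 1, Lachnospiraceae_BVAB1 = 0,
                           TM7_H1 = 0, Prevotella_cluster2 = 0)),
               2.325, tolerance = 1e-12)
  expect_error(ptb_score(c(Samn = 1, BVAB1 = 0, TM7 = 0)), "Prevotella_cluster2")
})

test_that("the score is monotone non-decreasing in each taxon", {
  set.seed(36)
  for (rep in 1:50) {
    a <- runif(4); names(a) <- c("Samn", "BVAB1", "TM7", "Pcl2")
    j <- sample(4, 1)
    b <- a; b[j] <- min(1, a[j] + runif(1))
    expect_gte(ptb_score(b), ptb_score(a))
  }
})

test_that("leave-one-out evaluation has no feature-selection leakage", {
  d <- make_toy_xy(n = 24, p = 8)
  set.seed(37)
  ev1 <- loo_evaluate(d$x, d$y, classifier_config(C_grid = 1),
                      return_models = TRUE)
  ## perturb only subject i's features: fold i's model must be unchanged
  for (i in c(1, 12)) {
    x2 <- d$x
    x2[i, ] <- rev(x2[i, ])
    set.seed(37)
    ev2 <- loo_evaluate(x2, d$y, classifier_config(C_grid = 1),
                        return_models = TRUE)
    expect_equal(ev2$models[[i]]$w, ev1$models[[i]]$w)
    expect_equal(ev2$models[[i]]$selected_features,
                 ev1$models[[i]]$selected_features)
  }
})

test_that("LOO separates a strong-signal cohort and not a null cohort", {
  d <- make_toy_xy(n = 40, p = 6, signal = 3, seed = 38)
  set.seed(39)
  ev <- loo_evaluate(d$x, d$y, classifier_config(C_grid = c(0.1, 1, 10), k = 3))
  expect_gte(ev$auroc, 0.95)
  ## null: same features, labels shuffled. LOO shows no skill; values well
  ## below 0.5 are expected here because intercept-only folds score a
  ## held-out case slightly lower than a held-out control (the standard
  ## leave-one-out class-ratio artifact), which is conservative.
  set.seed(40)
  y0 <- sample(d$y)
  ev0 <- loo_evaluate(d$x, y0, classifier_config(C_grid = 1))
  expect_lt(ev0$auroc, 0.75)
  expect_error(loo_evaluate(d$x[c(1, 3, 5), ], rep(1, 3)), "single class")
})

test_that("the permutation p-value uses the add-one convention", {
  d <- make_toy_xy(n = 20, p = 4, signal = 6, seed = 41)
  pt <- permutation_test(d$x, d$y, n_perm = 19, seed = 42,
                         config = classifier_config(C_grid = 1),
                         eval = "apparent")
  expect_equal(pt$p, (1 + sum(pt$null_aurocs >= pt$observed_auroc)) / 20)
  expect_gt(pt$p, 0)
  expect_lte(pt$p, 1)
  ## perfectly separated: observed exceeds every null
  if (all(pt$null_aurocs < pt$observed_auroc)) expect_equal(pt$p, 1 / 20)
})

test_that("clinical features encode flags, derived terms and normalization", {
  rec <- toy_records(c("s1", "s2"), c("A", "B"), c(100, 100), c("PTB", "TB"),
                     bmi = c(30, 30), vaginal_ph = c(4.4, 5.0),
                     short_cervix = c(1, 0), cerclage = c(0, 0),
                     progesterone = c(1, 0), gravidity = c(3, 2),
                     parity = c(1, 2), hist_miscarriage = c(0, 0),
                     hist_ptb = c(1, 0), antibiotics_6mo = c(0, 1))
  f <- clinical_features(rec)
  expect_equal(ncol(f), 11L)
  expect_equal(unname(f[, "gravidity_minus_parity"]), c(2, 0))
  expect_true(all(f[, "short_cervix"] %in% c(0, 1)))
  ## constant column (cerclage) -> 0 with warning under min-max scaling
  expect_warning(mm <- ptbmicro:::minmax_fit_apply(f, f), "cerclage")
  expect_true(all(mm$x[, "cerclage"] == 0))
  expect_true(all(mm$x >= 0 & mm$x <= 1))
})

test_that("the clinical comparator pipeline runs end to end", {
  set.seed(43)
  coh <- simulate_cohort(cross_sectional_config(seed = 11, n_cases = 15,
                                                n_controls_pool = 90))
  subj <- earliest_sample_in_window(coh$records, c(42, 167))
  cm <- clinical_model(subj, classifier_config(C_grid = 1))
  expect_true(cm$evaluation$auroc >= 0 && cm$evaluation$auroc <= 1)
  expect_s3_class(cm$model, "ptb_model")
})
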