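two_state_Q <- function(a, b) {
  Q <- matrix(c(-a, a, b, -b), 2, 2, byrow = TRUE,
              dimnames = list(c("S1", "S2"), c("S1", "S2")))
  Q
}

test_that("transition probabilities satisfy the CTMC identities", {
  Q <- two_state_Q(0.03, 0.05)
  expect_equal(transition_probability(Q, 0), diag(2),
               ignore_attr = TRUE)
  ## closed-form off-diagonal for the 2-state chain
  for (t in c(1, 28, 91, 365)) {
    P <- transition_probability(Q, t)
    expect_equal(P[1, 2], p12_closed(0.03, 0.05, t), tolerance = 1e-10)
    expect_equal(P[2, 1], p12_closed(0.05, 0.03, t), tolerance = 1e-10)
  }
  ## semigroup property on random generators
  set.seed(51)
  for (rep in 1:10) {
    Qr <- random_generator(4)
    s <- runif(1, 1, 40); t <- runif(1, 1, 40)
    expect_equal(transition_probability(Qr, s + t),
                 transition_probability(Qr, s) %*% transition_probability(Qr, t),
                 tolerance = 1e-9)
  }
  expect_error(transition_probability(matrix(c(1, 2, 3, 4), 2), 1),
               "generator")
})

test_that("matrix exponential matches the eigendecomposition oracle", {
  set.seed(52)
  for (rep in 1:25) {
    Q <- random_generator(sample(3:6, 1))
    t <- runif(1, 1, 120)
    expect_equal(transition_probability(Q, t), expm_eigen_oracle(Q, t),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("simulated paths obey absorbing, stationary and determinism properties", {
  Q0 <- matrix(0, 2, 2, dimnames = list(c("S1", "S2"), c("S1", "S2")))
  path <- simulate_vagitype_path(Q0, c(1, 0), seq(0, 280, 28), seed = 1)
  expect_true(all(path == "S1"))

  ## long-horizon occupancy approaches the closed-form stationary law
  a <- 0.04; b <- 0.02
  path2 <- simulate_vagitype_path(two_state_Q(a, b), c(0.5, 0.5),
                                  seq(0, 150000, 10), seed = 2)
  occ <- mean(path2 == "S1")
  expect_lt(abs(occ - stationary_closed(a, b)[1]), 0.05) # Monte-Carlo margin

  expect_identical(
    simulate_vagitype_path(two_state_Q(a, b), c(0.5, 0.5), 1:50, seed = 9),
    simulate_vagitype_path(two_state_Q(a, b), c(0.5, 0.5), 1:50, seed = 9))
})

test_that("state sequences map non-focal vagitypes to Other and collapse duplicates", {
  va <- data.frame(
    sample_id = c("s1", "s2", "s3", "s4", "s5"),
    vagitype = c("Lactobacillus_crispatus_cluster", "Clostridiales_BVAB2",
                 "UNASSIGNED", "Lactobacillus_crispatus_cluster",
                 "Lactobacillus_iners"),
    max_proportion = c(.9, .5, .2, .8, .6))
  rec <- toy_records(c("s1", "s2", "s3", "s4", "s5"),
                     c("A", "A", "A", "A", "B"),
                     c(100, 128, 128, 156, 90),
                     rep(c("PTB", "TB"), c(4, 1)))
  expect_message(seqs <- build_state_sequences(va, rec), "duplicate-day")
  expect_equal(seqs$A$states, c("Lcrispatus", "Other", "Lcrispatus"))
  expect_equal(seqs$A$days, c(100, 128, 156))
  expect_equal(length(seqs$B$days), 1L) # single-visit subject retained
  cnt <- count_transitions(seqs)
  expect_equal(cnt["Lcrispatus", "Other"], 1L)
  expect_equal(cnt["Other", "Lcrispatus"], 1L)
  expect_equal(sum(cnt), 2L)
})

test_that("the >=4 observed-transition restriction masks rare transitions", {
  ## subjects alternating S1->S2 only; S2->S1 never observed
  seqs <- lapply(1:5, function(i)
    list(days = c(0, 28), states = c("S1", "S2"), outcome = "TB"))
  names(seqs) <- paste0("subj", 1:5)
  cnt <- count_transitions(seqs, states = c("S1", "S2"))
  expect_equal(cnt["S1", "S2"], 5L)
  fit <- fit_ctmc(seqs, states = c("S1", "S2"), with_covariate = FALSE,
                  seed = 1)
  expect_true(fit$allowed["S1", "S2"])
  expect_false(fit$allowed["S2", "S1"])
  expect_equal(fit$Q0["S2", "S1"], 0) # disallowed intensity exactly 0
  expect_error(fit_ctmc(seqs, states = c("S1", "S2"), min_transitions = 10),
               "mask")
})

test_that("the panel MLE recovers a known 3-state generator within 3 SE", {
  set.seed(53)
  states <- c("S1", "S2", "S3")
  Q <- matrix(c(-0.030, 0.020, 0.010,
                0.015, -0.025, 0.010,
                0.008, 0.012, -0.020), 3, 3, byrow = TRUE,
              dimnames = list(states, states))
  seqs <- lapply(1:200, function(i) {
    days <- seq(0, 28 * 7, 28)
    list(days = days,
         states = simulate_vagitype_path(Q, rep(1 / 3, 3), days),
         outcome = "TB")
  })
  names(seqs) <- paste0("subj", 1:200)
  fit <- fit_ctmc(seqs, states = states, with_covariate = FALSE, seed = 3)
  expect_true(fit$convergence)
  est <- fit$log_q0[fit$allowed]
  se <- fit$standard_errors[seq_len(sum(fit$allowed))]
  truth <- log(Q[fit$allowed])
  expect_true(all(abs(est - truth) <= 3 * se))
  ## MLE optimality: fitted likelihood at least that of the truth
  expect_gte(fit$loglik, ctmc_loglik(seqs, Q) - 1e-6)
})

test_that("recovery error shrinks with more subjects", {
  set.seed(54)
  states <- c("S1", "S2")
  Q <- two_state_Q(0.02, 0.03)
  med_err <- vapply(c(50, 400), function(n) {
    errs <- vapply(1:3, function(rep) {
      seqs <- lapply(1:n, function(i) {
        days <- seq(0, 28 * 7, 28)
        list(days = days,
             states = simulate_vagitype_path(Q, c(0.5, 0.5), days),
             outcome = "TB")
      })
      names(seqs) <- paste0("s", 1:n)
      fit <- fit_ctmc(seqs, states = states, with_covariate = FALSE,
                      min_transitions = 1, n_starts = 1, seed = rep)
      stats::median(abs(fit$log_q0[fit$allowed] - log(Q[fit$allowed])))
    }, numeric(1))
    stats::median(errs)
  }, numeric(1))
  expect_lt(med_err[2], med_err[1])
})

test_that("the covariate-free fit nests the covariate fit under pooled labels", {
  set.seed(55)
  Q <- two_state_Q(0.02, 0.05)
  seqs <- lapply(1:60, function(i) {
    days <- seq(0, 28 * 5, 28)
    list(days = days,
         states = simulate_vagitype_path(Q, c(0.5, 0.5), days),
         outcome = "TB") # single outcome: covariate carries no information
  })
  names(seqs) <- paste0("s", 1:60)
  f0 <- fit_ctmc(seqs, states = c("S1", "S2"), with_covariate = FALSE,
                 min_transitions = 1, n_starts = 1, seed = 1)
  f1 <- fit_ctmc(seqs, states = c("S1", "S2"), with_covariate = TRUE,
                 min_transitions = 1, n_starts = 1, seed = 1)
  expect_equal(f0$loglik, f1$loglik, tolerance = 1e-4)
})

test_that("stationary distributions match closed forms and solve pi Q = 0", {
  Q <- two_state_Q(1, 2)
  pi_hat <- stationary_distribution(Q)
  expect_equal(unname(pi_hat), c(2 / 3, 1 / 3), tolerance = 1e-9)
  set.seed(56)
  for (rep in 1:10) {
    Qr <- random_generator(4)
    p <- stationary_distribution(Qr)
    expect_lt(max(abs(p %*% Qr)), 1e-6)
    expect_equal(sum(p), 1, tolerance = 1e-9)
  }
  ## zero generator: degenerate, flagged as reducible
  Q0 <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_warning(out <- stationary_distribution(Q0), "reducible")
  expect_equal(out, diag(2), ignore_attr = TRUE)
})

test_that("dynamic balance vanishes for symmetric chains and matches the 2-state form", {
  Qs <- matrix(c(-0.02, 0.01, 0.01,
                 0.01, -0.02, 0.01,
                 0.01, 0.01, -0.02), 3, 3, byrow = TRUE,
               dimnames = list(paste0("S", 1:3), paste0("S", 1:3)))
  db <- dynamic_balance(Qs, t_trimester = 91)
  expect_true(all(abs(db$forward_minus_reverse) < 1e-10))
  expect_true(all(abs(db$detailed_balance_flux) < 1e-10))

  Q <- two_state_Q(1, 2)
  db2 <- dynamic_balance(Q, t_trimester = 91)
  expect_equal(db2$forward_minus_reverse,
               p12_closed(1, 2, 91) - p12_closed(2, 1, 91), tolerance = 1e-9)
  ## any 2-state chain is reversible: flux vanishes at stationarity
  expect_lt(abs(db2$detailed_balance_flux), 1e-9)
})
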