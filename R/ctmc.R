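#' Focal vagitype states of the transition model
#'
#' The five-state space used for vagitype dynamics: L. crispatus, L. iners,
#' BVAB1, G. vaginalis, and "Other" (every other vagitype, including
#' unassigned samples).
#'
#' @return Character vector of state names.
#' @export
ctmc_states <- function() {
  c("Lcrispatus", "Liners", "BVAB1", "Gvaginalis", "Other")
}

vagitype_to_state <- function(vagitype) {
  map <- c(Lactobacillus_crispatus_cluster = "Lcrispatus",
           Lactobacillus_iners = "Liners",
           Lachnospiraceae_BVAB1 = "BVAB1",
           Gardnerella_vaginalis = "Gvaginalis")
  out <- unname(map[vagitype])
  out[is.na(out)] <- "Other"
  out
}

#' Build per-subject (state, day) panel sequences
#'
#' Joins vagitype assignments to sample metadata, maps non-focal and
#' unassigned vagitypes to `"Other"`, sorts each subject's visits by
#' gestational day, and collapses duplicate days to the earlier sample
#' (lexicographic `sample_id`, logged). Single-visit subjects are retained
#' (they inform the initial distribution but contribute no transitions).
#'
#' @param assignments Output of [assign_vagitype()].
#' @param records Records data.frame.
#' @return List per subject: `days`, `states`, `outcome`.
#' @export
build_state_sequences <- function(assignments, records) {
  validate_records(records)
  idx <- match(assignments$sample_id, records$sample_id)
  if (anyNA(idx)) stopf("assignments contain samples without records")
  df <- data.frame(subject_id = records$subject_id[idx],
                   day = records$gestational_age[idx],
                   outcome = records$outcome[idx],
                   state = vagitype_to_state(assignments$vagitype),
                   sample_id = assignments$sample_id,
                   stringsAsFactors = FALSE)
  df <- df[order(df$subject_id, df$day, df$sample_id), , drop = FALSE]
  dup <- duplicated(df[, c("subject_id", "day")])
  if (any(dup)) {
    message(sprintf("build_state_sequences: %d duplicate-day sample(s) collapsed to the earlier sample", sum(dup)))
    df <- df[!dup, , drop = FALSE]
  }
  lapply(split(df, df$subject_id), function(s)
    list(days = s$day, states = s$state, outcome = s$outcome[1]))
}

validate_generator <- function(Q, tol = 1e-8) {
  if (!is.matrix(Q) || nrow(Q) != ncol(Q)) stopf("Q must be square")
  offd <- Q; diag(offd) <- 0
  if (any(offd < -tol)) stopf("invalid generator: negative off-diagonal intensity")
  if (any(abs(rowSums(Q)) > 1e-6)) stopf("invalid generator: rows must sum to 0")
  invisible(Q)
}

#' Transition-probability matrix of a CTMC
#'
#' `P(t) = expm(Q t)`, evaluated by scaling-and-squaring with a Pade
#' approximant. Rows are checked to sum to 1 within `1e-10` and entries are
#' clipped to [0, 1] afterwards.
#'
#' @param Q Intensity (generator) matrix: non-negative off-diagonals, zero
#'   row sums; units 1/day.
#' @param t Time in days, `t >= 0`.
#' @return The stochastic matrix `P(t)`.
#' @export
transition_probability <- function(Q, t) {
  validate_generator(Q)
  stopifnot(t >= 0)
  P <- as.matrix(Matrix::expm(Q * t))
  if (any(abs(rowSums(P) - 1) > 1e-10))
    stopf("matrix exponential rows deviate from 1 beyond tolerance")
  P[P < 0] <- 0
  P[P > 1] <- 1
  dimnames(P) <- dimnames(Q)
  P
}

## pack/unpack free parameters: log baseline intensities + covariate effects
## for each allowed off-diagonal transition
q_from_params <- function(par, allowed, z) {
  k <- nrow(allowed)
  n_free <- sum(allowed)
  has_beta <- length(par) >= 2 * n_free
  eta <- par[seq_len(n_free)]
  if (has_beta && z != 0) eta <- eta + z * par[n_free + seq_len(n_free)]
  Q <- matrix(0, k, k, dimnames = dimnames(allowed))
  Q[allowed] <- exp(eta)
  diag(Q) <- -rowSums(Q)
  Q
}

## flatten panel sequences into per-(covariate, interval-length) index
## triplets so the likelihood is a handful of matrix exponentials plus
## vectorized lookups
ctmc_interval_data <- function(seqs, states, z_map) {
  z_all <- unlist(z_map)
  rows <- lapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    nv <- length(s$days)
    if (nv < 2) return(NULL)
    si <- match(s$states, states)
    data.frame(z = unname(z_all[i]), dt = unname(diff(s$days)),
               from = unname(si[-nv]), to = unname(si[-1]))
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) stopf("no transition intervals in the data")
  split(df, interaction(df$z, df$dt, drop = TRUE))
}

ctmc_negloglik <- function(par, intervals, allowed) {
  total <- 0
  for (grp in intervals) {
    Q <- q_from_params(par, allowed, grp$z[1])
    P <- as.matrix(Matrix::expm(Q * grp$dt[1]))
    P[P < 1e-300] <- 1e-300
    total <- total - sum(log(P[cbind(grp$from, grp$to)]))
  }
  if (!is.finite(total)) return(1e10)
  total
}

#' Panel log-likelihood at given CTMC parameters
#'
#' Interval-censored panel likelihood of state observations at visit times
#' under `q_rs(z) = q0_rs * exp(beta_rs * z)`. Useful for comparing a fitted
#' model against the generating parameters.
#'
#' @param sequences Output of [build_state_sequences()].
#' @param Q0 Baseline generator (z = 0).
#' @param beta Optional matrix of covariate effects on the off-diagonals
#'   (NA/0 where absent).
#' @param states State space (default `rownames(Q0)`).
#' @return The log-likelihood.
#' @export
ctmc_loglik <- function(sequences, Q0, beta = NULL, states = rownames(Q0)) {
  validate_generator(Q0)
  z_map <- lapply(sequences, function(s)
    if (is.null(beta)) 0L else as.integer(s$outcome == "PTB"))
  intervals <- ctmc_interval_data(sequences, states, z_map)
  total <- 0
  for (grp in intervals) {
    Q <- Q0
    if (!is.null(beta) && grp$z[1] != 0) {
      off <- !is.na(beta) & row(Q) != col(Q)
      Q[off] <- Q[off] * exp(beta[off] * grp$z[1])
      diag(Q) <- 0
      diag(Q) <- -rowSums(Q)
    }
    P <- as.matrix(Matrix::expm(Q * grp$dt[1]))
    P[P < 1e-300] <- 1e-300
    total <- total + sum(log(P[cbind(grp$from, grp$to)]))
  }
  total
}

#' Count observed between-visit state changes
#'
#' @param sequences Output of [build_state_sequences()].
#' @param states State space (default [ctmc_states()]).
#' @return Integer matrix of counts of observed `r -> s` changes (`r != s`)
#'   between consecutive visits, pooled over subjects.
#' @export
count_transitions <- function(sequences, states = ctmc_states()) {
  k <- length(states)
  cnt <- matrix(0L, k, k, dimnames = list(states, states))
  for (s in sequences) {
    si <- match(s$states, states)
    for (j in seq_along(si)[-1]) {
      if (si[j - 1] != si[j]) cnt[si[j - 1], si[j]] <- cnt[si[j - 1], si[j]] + 1L
    }
  }
  cnt
}

#' Fit a panel-data CTMC of vagitype transitions with an outcome covariate
#'
#' Maximum-likelihood estimation from interval-censored panel observations
#' (states are only observed at visit times; exact transition times are not
#' assumed). Each allowed transition intensity is modeled log-linearly in the
#' outcome covariate, `q_rs(z) = q0_rs * exp(beta_rs * z)` with `z = 1` for
#' PTB subjects and `0` for TB. Following standard practice with sparse
#' panels, the transitions modeled are restricted to those with at least
#' `min_transitions` observed between-visit changes (pooled over outcome
#' groups by default); without such a restriction the MLE frequently fails
#' to converge. Optimization is quasi-Newton (BFGS) on log-intensities with
#' multiple seeded starts; standard errors come from the observed
#' information matrix.
#'
#' @param sequences Output of [build_state_sequences()], or compatible.
#' @param states State space (default [ctmc_states()]).
#' @param min_transitions Restriction threshold (default 4).
#' @param allowed Optional logical matrix overriding the observed-count
#'   restriction.
#' @param with_covariate Include the outcome effect (default TRUE). With
#'   `FALSE`, both groups are pooled under a common generator.
#' @param n_starts Seeded multi-starts for the optimizer (default 3).
#' @param seed Optional integer seed for the starts.
#' @return A `ctmc_model`: `states`, `Q0` (baseline, TB), `beta` (matrix of
#'   covariate effects on allowed transitions), `allowed`, `loglik`,
#'   `standard_errors` (per free parameter), `convergence`.
#' @export
fit_ctmc <- function(sequences, states = ctmc_states(), min_transitions = 4,
                     allowed = NULL, with_covariate = TRUE, n_starts = 3,
                     seed = NULL) {
  cnt <- count_transitions(sequences, states)
  if (is.null(allowed)) allowed <- cnt >= min_transitions
  diag(allowed) <- FALSE
  if (!any(allowed)) stopf("no allowed transitions (empty mask)")
  n_free <- sum(allowed)
  z_map <- lapply(sequences, function(s)
    if (with_covariate) as.integer(s$outcome == "PTB") else 0L)
  intervals <- ctmc_interval_data(sequences, states, z_map)

  ## crude start: observed changes per person-time at risk in the origin state
  time_at <- stats::setNames(numeric(length(states)), states)
  for (s in sequences) {
    if (length(s$days) < 2) next
    dt <- diff(s$days)
    for (j in seq_along(dt))
      time_at[s$states[j]] <- time_at[s$states[j]] + dt[j]
  }
  q_start <- (cnt + 0.5) / pmax(time_at[rownames(cnt)], 1)
  par0 <- c(log(q_start[allowed]), if (with_covariate) rep(0, n_free))

  negll <- function(par) ctmc_negloglik(par, intervals, allowed)
  with_seed(seed, {
    fits <- lapply(seq_len(n_starts), function(i) {
      p0 <- if (i == 1) par0 else par0 + stats::rnorm(length(par0), 0, 0.3)
      stats::optim(p0, negll, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-10))
    })
    best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
    hess <- stats::optimHess(best$par, negll)
    se <- rep(NA_real_, length(best$par))
    ih <- try(solve(hess), silent = TRUE)
    if (!inherits(ih, "try-error")) {
      d <- diag(ih)
      se[d > 0] <- sqrt(d[d > 0])
    }
    logq0 <- matrix(NA_real_, length(states), length(states),
                    dimnames = list(states, states))
    logq0[allowed] <- best$par[seq_len(n_free)]
    beta <- matrix(NA_real_, length(states), length(states),
                   dimnames = list(states, states))
    if (with_covariate) beta[allowed] <- best$par[n_free + seq_len(n_free)]
    Q0 <- q_from_params(best$par, allowed, 0)
    structure(list(states = states, Q0 = Q0, log_q0 = logq0, beta = beta,
                   allowed = allowed, transition_counts = cnt,
                   loglik = -best$value,
                   standard_errors = se, with_covariate = with_covariate,
                   convergence = best$convergence == 0),
              class = "ctmc_model")
  })
}

#' @export
print.ctmc_model <- function(x, ...) {
  cat(sprintf("ctmc_model: %d states, %d allowed transitions, loglik %.3f%s\n",
              length(x$states), sum(x$allowed), x$loglik,
              if (x$convergence) "" else " (NOT converged)"))
  invisible(x)
}

#' Generator at a covariate value
#'
#' @param model A `ctmc_model`.
#' @param z Covariate value: 1 = PTB, 0 = TB.
#' @return The intensity matrix `Q(z)`.
#' @export
ctmc_generator <- function(model, z = 0) {
  Q <- model$Q0
  if (model$with_covariate && z != 0) {
    off <- model$allowed
    Q[off] <- Q[off] * exp(model$beta[off] * z)
    diag(Q) <- 0
    diag(Q) <- -rowSums(Q)
  }
  Q
}

#' Stationary distribution of the fitted chain
#'
#' Estimated as a row of `P(t_large)` with `t_large = 100000` days, and
#' verified against the null-space solution `pi Q = 0` (residual below
#' `1e-6`) when the chain is irreducible; for reducible chains the rows of
#' `P(t_large)` differ and a warning reports the per-starting-state
#' distributions.
#'
#' @param model A `ctmc_model`, or a raw generator matrix.
#' @param z Covariate value (ignored for a raw matrix).
#' @param t_large Horizon in days (default 100000).
#' @return Named numeric simplex over states (irreducible case), or a matrix
#'   of per-starting-state rows with a warning (reducible case).
#' @export
stationary_distribution <- function(model, z = 0, t_large = 1e5) {
  Q <- if (inherits(model, "ctmc_model")) ctmc_generator(model, z) else model
  P <- transition_probability(Q, t_large)
  spread <- max(apply(P, 2, function(col) diff(range(col))))
  if (spread > 1e-6) {
    warnf("chain appears reducible at t = %g; returning per-starting-state distributions", t_large)
    return(P)
  }
  pi_hat <- colMeans(P)
  resid <- max(abs(pi_hat %*% Q))
  if (resid > 1e-6)
    warnf("stationary residual ||pi Q|| = %.3g exceeds 1e-6", resid)
  stats::setNames(pi_hat, colnames(Q))
}

#' Dynamic-balance diagnostic at the one-trimester horizon
#'
#' For each ordered state pair reports the difference between the forward
#' and reverse transition probabilities, `P_ij(t) - P_ji(t)`, at the
#' one-trimester horizon (91 days by the 13-week convention). A secondary
#' column reports the detailed-balance flux `pi_i P_ij - pi_j P_ji` at the
#' stationary distribution; both are emitted because either reading of
#' "forward minus reverse" is defensible.
#'
#' @param model A `ctmc_model` or generator matrix.
#' @param z Covariate value.
#' @param t_trimester Horizon in days (default 91).
#' @return Data.frame with `from`, `to`, `forward_minus_reverse`,
#'   `detailed_balance_flux` for each unordered pair (i < j).
#' @export
dynamic_balance <- function(model, z = 0, t_trimester = 91) {
  Q <- if (inherits(model, "ctmc_model")) ctmc_generator(model, z) else model
  P <- transition_probability(Q, t_trimester)
  pi_hat <- stationary_distribution(Q)
  if (is.matrix(pi_hat)) pi_hat <- colMeans(pi_hat) # reducible fallback
  k <- nrow(P)
  states <- rownames(P)
  rows <- list()
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    rows[[length(rows) + 1]] <- data.frame(
      from = states[i], to = states[j],
      forward_minus_reverse = P[i, j] - P[j, i],
      detailed_balance_flux = pi_hat[i] * P[i, j] - pi_hat[j] * P[j, i],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
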