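## Independent oracles used across the suite. These deliberately avoid the
## code paths they check: brute-force enumeration, closed forms, and direct
## textbook formulas.

## exhaustive-permutation two-sided Mann-Whitney p (tie-free inputs):
## enumerate every assignment of nx of the pooled values to group x
mw_permutation_oracle <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - nx * (nx + 1) / 2
  u_obs <- u_of(seq_len(nx))
  combos <- utils::combn(length(pooled), nx)
  u_all <- apply(combos, 2, u_of)
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

## direct step-up BH formula
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

## Fisher two-sided p by hypergeometric enumeration ("at most as probable")
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

## AUROC by explicit pair counting (ties count one half)
auroc_pairs_oracle <- function(scores, labels) {
  cs <- scores[labels == 1 | labels == "PTB"]
  ct <- scores[labels == -1 | labels == "TB"]
  tot <- 0
  for (a in cs) for (b in ct)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cs) * length(ct))
}

## 2-state CTMC closed forms for Q = [[-a, a], [b, -b]]
p12_closed <- function(a, b, t) a * (1 - exp(-(a + b) * t)) / (a + b)
stationary_closed <- function(a, b) c(b, a) / (a + b)

## random valid generator with the given states
random_generator <- function(k, rate = 0.05) {
  Q <- matrix(stats::runif(k * k, 0, rate), k, k)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  dimnames(Q) <- list(paste0("S", 1:k), paste0("S", 1:k))
  Q
}

## matrix exponential through an eigendecomposition (diagonalizable case)
expm_eigen_oracle <- function(Q, t) {
  e <- eigen(Q)
  Re(e$vectors %*% diag(exp(e$values * t)) %*% solve(e$vectors))
}

## tiny abundance-table fixture
toy_table <- function(counts = rbind(s1 = c(10, 30, 60), s2 = c(5, 5, 90)),
                      taxa = c("Lactobacillus_crispatus_cluster",
                               "Lactobacillus_iners",
                               "Gardnerella_vaginalis")) {
  colnames(counts) <- taxa
  abundance_table(counts, layout = "counts")
}

## subject-level covariate frame for matching tests
toy_subjects <- function(n, prefix, eth = 0, age = 30, income = 1) {
  data.frame(subject_id = paste0(prefix, seq_len(n)),
             ethnicity = rep_len(eth, n), age = rep_len(age, n),
             income_bracket = rep_len(income, n),
             stringsAsFactors = FALSE)
}

## minimal valid records frame
toy_records <- function(sample_id, subject_id, ga, outcome, ...) {
  data.frame(sample_id = sample_id, subject_id = subject_id,
             gestational_age = ga, outcome = outcome, ...,
             stringsAsFactors = FALSE)
}

## small cross-sectional synthetic cohort (single visit per subject): the
## full generator with a visit interval exceeding the horizon
cross_sectional_config <- function(seed, n_cases = 45, ...) {
  synthetic_config(n_cases = n_cases, visit_every = 400, seed = seed, ...)
}

## a global-null configuration: no abundance effect AND identical vagitype
## dynamics across outcomes, so PTB and TB profiles are exchangeable
null_config <- function(seed, ...) {
  cfg <- cross_sectional_config(seed, ptb_effect = numeric(0), ...)
  cfg$init_PTB <- cfg$init_TB
  cfg$Q_PTB <- cfg$Q_TB
  cfg
}
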