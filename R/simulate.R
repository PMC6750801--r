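#' Default taxon panel of the synthetic cohort
#'
#' A 27-taxon vaginal panel: the common Lactobacillus clusters, the major
#' dysbiosis-associated anaerobes (including the PTB-associated signature
#' taxa BVAB1, Sneathia amnii, Prevotella cluster 2 and TM7-H1), and
#' Megasphaera type 1.
#'
#' @return Character vector of canonical taxon labels.
#' @export
default_taxon_panel <- function() {
  c("Lactobacillus_crispatus_cluster", "Lactobacillus_iners",
    "Lactobacillus_jensenii", "Lactobacillus_gasseri_cluster",
    "Gardnerella_vaginalis", "Lachnospiraceae_BVAB1", "Sneathia_amnii",
    "Sneathia_sanguinegens", "Prevotella_cluster2", "TM7_H1",
    "Atopobium_vaginae", "Megasphaera_OTU70_type1", "Dialister_cluster51",
    "Dialister_micraerophilus", "Prevotella_amnii", "Clostridiales_BVAB2",
    "Coriobacteriaceae_OTU27", "Parvimonas_OTU142", "Mobiluncus_curtisii",
    "Anaerococcus_tetradius", "Peptoniphilus_lacrimalis", "Prevotella_bivia",
    "Ureaplasma_cluster23", "Mycoplasma_hominis", "Aerococcus_christensenii",
    "Finegoldia_magna", "Streptococcus_agalactiae")
}

dirichlet_templates <- function(taxa, precision = 40) {
  base <- stats::setNames(rep(0.004, length(taxa)), taxa)
  tpl <- list(
    Lcrispatus = c(Lactobacillus_crispatus_cluster = 0.78,
                   Lactobacillus_iners = 0.06, Lactobacillus_jensenii = 0.03),
    Liners     = c(Lactobacillus_iners = 0.78,
                   Lactobacillus_crispatus_cluster = 0.04,
                   Gardnerella_vaginalis = 0.05),
    BVAB1      = c(Lachnospiraceae_BVAB1 = 0.55, Gardnerella_vaginalis = 0.08,
                   Atopobium_vaginae = 0.07, Megasphaera_OTU70_type1 = 0.06,
                   Sneathia_amnii = 0.05, Prevotella_cluster2 = 0.04,
                   TM7_H1 = 0.03),
    Gvaginalis = c(Gardnerella_vaginalis = 0.62, Atopobium_vaginae = 0.08,
                   Lactobacillus_iners = 0.06, Prevotella_bivia = 0.04),
    Other      = c(Atopobium_vaginae = 0.50, Megasphaera_OTU70_type1 = 0.10,
                   Sneathia_sanguinegens = 0.05, Prevotella_cluster2 = 0.04,
                   Dialister_cluster51 = 0.04))
  out <- t(vapply(tpl, function(mass) {
    a <- base
    rest <- 1 - sum(base) - sum(mass)
    a[names(mass)] <- a[names(mass)] + mass
    a <- a + rest / length(a)       # spread leftover mass evenly
    a / sum(a) * precision
  }, numeric(length(taxa))))
  colnames(out) <- taxa
  out
}

default_generator <- function(states, rates_to) {
  k <- length(states)
  Q <- matrix(0, k, k, dimnames = list(states, states))
  for (r in states) for (s in states) {
    if (r != s) Q[r, s] <- rates_to[[s]]
  }
  diag(Q) <- -rowSums(Q)
  Q
}

#' Configuration of the synthetic longitudinal cohort generator
#'
#' Defaults define the study conditions the analyses assume: a 2:1
#' case-matched design, visits every 28 days from day 60 truncated at
#' delivery, overdispersed read depths around 50,000 (with a small
#' assay-failure rate producing sub-1,000-read samples for the QC rule to
#' catch), vagitype trajectories driven by outcome-specific continuous-time
#' Markov chains, Dirichlet-multinomial compositions concentrated on each
#' vagitype's dominant taxon with PTB enrichment of the four signature taxa
#' and TB enrichment of L. crispatus, proinflammatory cytokines loading
#' positively on dysbiotic taxa, and deliveries at 23w0d-36w6d (PTB) or
#' >= 39w (TB).
#'
#' @param n_cases Number of PTB subjects (default 45).
#' @param n_controls_pool Candidate TB pool for 2:1 matching (default 250).
#' @param visit_every,first_visit Visit schedule in days (default every 28
#'   from day 60).
#' @param depth_mean,depth_size Negative-binomial read-depth law (default
#'   mean 50000, size 12).
#' @param low_depth_rate Probability a sample is an assay failure with
#'   Poisson(500) depth (default 0.02).
#' @param precision Dirichlet precision of per-visit compositions
#'   (default 40).
#' @param ptb_effect Named log-fold concentration enrichments applied to PTB
#'   subjects' compositions (negative = TB-enriched).
#' @param cytokine_noise_sd Log10-scale Gaussian noise SD (default 0.4).
#' @param seed Integer seed.
#' @return A `synthetic_config` list; see fields in the implementation.
#' @export
synthetic_config <- function(n_cases = 45, n_controls_pool = 250,
                             visit_every = 28, first_visit = 60,
                             depth_mean = 50000, depth_size = 12,
                             low_depth_rate = 0.02, precision = 40,
                             ptb_effect = c(Lachnospiraceae_BVAB1 = 0.8,
                                            Sneathia_amnii = 0.8,
                                            Prevotella_cluster2 = 0.6,
                                            TM7_H1 = 0.6,
                                            Lactobacillus_crispatus_cluster = -0.5),
                             cytokine_noise_sd = 0.4, seed = 1L) {
  states <- ctmc_states()
  taxa <- default_taxon_panel()
  ## per-day intensities: mean holding times of a few weeks to months, with
  ## term trajectories drifting toward L. crispatus and preterm trajectories
  ## toward BVAB1/dysbiosis
  Q_TB <- default_generator(states, list(Lcrispatus = 0.006, Liners = 0.004,
                                         BVAB1 = 0.0008, Gvaginalis = 0.002,
                                         Other = 0.002))
  Q_PTB <- default_generator(states, list(Lcrispatus = 0.002, Liners = 0.004,
                                          BVAB1 = 0.004, Gvaginalis = 0.003,
                                          Other = 0.003))
  init_TB <- c(Lcrispatus = 0.40, Liners = 0.30, BVAB1 = 0.04,
               Gvaginalis = 0.14, Other = 0.12)
  init_PTB <- c(Lcrispatus = 0.16, Liners = 0.28, BVAB1 = 0.20,
                Gvaginalis = 0.20, Other = 0.16)

  cytokines <- cytokine_panel()
  dysbiotic <- c("Lachnospiraceae_BVAB1", "Sneathia_amnii",
                 "Prevotella_cluster2", "TM7_H1", "Gardnerella_vaginalis",
                 "Atopobium_vaginae", "Megasphaera_OTU70_type1")
  loadings <- matrix(0, length(cytokines), length(taxa),
                     dimnames = list(cytokines, taxa))
  proinflam <- c("eotaxin", "IL-1b", "IL-6", "MIP-1b")
  loadings[proinflam, dysbiotic] <- 0.18
  loadings[setdiff(cytokines, proinflam), dysbiotic] <- 0.06
  loadings["IP-10", "Lactobacillus_iners"] <- 0.15
  lod <- data.frame(lo = rep(0.5, length(cytokines)),
                    hi = rep(1e4, length(cytokines)),
                    row.names = cytokines)

  list(n_cases = n_cases, n_controls_pool = n_controls_pool,
       visit_every = visit_every, first_visit = first_visit,
       depth_mean = depth_mean, depth_size = depth_size,
       low_depth_rate = low_depth_rate,
       states = states, taxa = taxa,
       Q_PTB = Q_PTB, Q_TB = Q_TB, init_PTB = init_PTB, init_TB = init_TB,
       templates = dirichlet_templates(taxa, precision),
       precision = precision, ptb_effect = ptb_effect,
       cytokine_names = cytokines, cytokine_baseline =
         stats::setNames(rep(1.0, length(cytokines)), cytokines),
       cytokine_loadings = loadings, cytokine_noise_sd = cytokine_noise_sd,
       lod_bounds = lod,
       delivery_ptb = c(161, 258), delivery_tb = c(273, 294),
       seed = seed)
}

#' Simulate a vagitype path from a CTMC, reported at visit times
#'
#' Exact simulation: exponential holding times and the embedded jump chain.
#'
#' @param Q Generator matrix (states as dimnames).
#' @param initial_dist Probability vector over states at the first visit.
#' @param t_grid Strictly increasing visit times (days).
#' @param seed Optional integer seed.
#' @return Character vector of states, one per visit.
#' @export
simulate_vagitype_path <- function(Q, initial_dist, t_grid, seed = NULL) {
  validate_generator(Q)
  if (any(diff(t_grid) <= 0)) stopf("t_grid must be strictly increasing")
  states <- rownames(Q)
  with_seed(seed, {
    cur <- sample(states, 1, prob = initial_dist)
    t_cur <- t_grid[1]
    out <- character(length(t_grid))
    out[1] <- cur
    for (v in seq_along(t_grid)[-1]) {
      while (TRUE) {
        rate <- -Q[cur, cur]
        if (rate <= 0) { t_cur <- t_grid[v]; break }  # absorbing state
        hold <- stats::rexp(1, rate)
        if (t_cur + hold > t_grid[v]) { t_cur <- t_grid[v]; break }
        t_cur <- t_cur + hold
        probs <- Q[cur, ]; probs[cur] <- 0
        cur <- sample(states, 1, prob = probs)
      }
      out[v] <- cur
    }
    out
  })
}

## Dirichlet concentration for one visit: template row adjusted by the
## outcome effect, rescaled to the configured precision
composition_alpha <- function(state, config, outcome) {
  a <- config$templates[state, ]
  if (outcome == "PTB" && length(config$ptb_effect)) {
    a[names(config$ptb_effect)] <- a[names(config$ptb_effect)] *
      exp(config$ptb_effect)
  }
  a / sum(a) * config$precision
}

#' Simulate one sample's taxon counts
#'
#' Counts follow `Multinomial(depth, p)` with `p ~ Dirichlet(alpha)`, where
#' `alpha` is the vagitype's concentration template times the outcome-effect
#' multipliers, rescaled to the configured precision.
#'
#' @param state Vagitype state (one of `config$states`).
#' @param config A [synthetic_config()].
#' @param outcome `"PTB"` or `"TB"`.
#' @param depth Positive read depth.
#' @param seed Optional integer seed.
#' @return Named integer vector of counts over `config$taxa`.
#' @export
simulate_composition <- function(state, config, outcome, depth, seed = NULL) {
  if (depth <= 0) stopf("depth must be positive")
  if (!state %in% rownames(config$templates)) stopf("unknown state %s", state)
  a <- composition_alpha(state, config, outcome)
  with_seed(seed, {
    g <- stats::rgamma(length(a), shape = a)
    if (sum(g) == 0) g[which.max(a)] <- 1
    counts <- stats::rmultinom(1, size = depth, prob = g / sum(g))[, 1]
    stats::setNames(as.integer(counts), config$taxa)
  })
}

#' Simulate cytokine concentrations driven by taxon abundances
#'
#' Per sample, log10 concentration = baseline + loadings x transformed taxon
#' abundances + Gaussian noise; concentrations outside the limit-of-detection
#' bounds are censored at the bound and flagged.
#'
#' @param taxa_log_abundance Samples x taxa matrix of
#'   [soft_threshold_log()]-transformed abundances.
#' @param config A [synthetic_config()].
#' @param seed Optional integer seed.
#' @return List with `values` (pg/ml, censored), `flags` (`"in"`,
#'   `"below"`, `"above"`).
#' @export
simulate_cytokines <- function(taxa_log_abundance, config, seed = NULL) {
  m <- as.matrix(taxa_log_abundance)
  L <- config$cytokine_loadings[, colnames(m), drop = FALSE]
  with_seed(seed, {
    log10c <- matrix(rep(config$cytokine_baseline, each = nrow(m)),
                     nrow(m), nrow(L),
                     dimnames = list(rownames(m), rownames(L))) +
      m %*% t(L) +
      matrix(stats::rnorm(nrow(m) * nrow(L), 0, config$cytokine_noise_sd),
             nrow(m), nrow(L))
    conc <- 10^log10c
    flags <- matrix("in", nrow(conc), ncol(conc), dimnames = dimnames(conc))
    for (j in colnames(conc)) {
      lo <- config$lod_bounds[j, "lo"]; hi <- config$lod_bounds[j, "hi"]
      flags[conc[, j] < lo, j] <- "below"
      flags[conc[, j] > hi, j] <- "above"
      conc[conc[, j] < lo, j] <- lo
      conc[conc[, j] > hi, j] <- hi
    }
    list(values = conc, flags = flags)
  })
}

simulate_subject_covariates <- function(n, outcome, id_prefix) {
  ancestry <- sample(c("African", "European", "Hispanic", "NativeAmerican"),
                     n, replace = TRUE, prob = c(0.78, 0.14, 0.06, 0.02))
  is_ptb <- outcome == "PTB"
  gravidity <- 1 + stats::rpois(n, 1.2)
  parity <- stats::rbinom(n, pmax(gravidity - 1, 0), 0.6)
  data.frame(
    subject_id = sprintf("%s%03d", id_prefix, seq_len(n)),
    outcome = outcome,
    ancestry = ancestry,
    ethnicity = as.integer(ancestry != "African"),
    age = pmin(pmax(round(stats::rnorm(n, 26, 5.5)), 18), 45),
    income_bracket = sample(1:3, n, replace = TRUE, prob = c(0.75, 0.20, 0.05)),
    bmi = round(pmin(pmax(stats::rnorm(n, 28, 6), 16), 50), 1),
    short_cervix = stats::rbinom(n, 1, if (is_ptb) 0.15 else 0.03),
    cerclage = stats::rbinom(n, 1, if (is_ptb) 0.07 else 0.01),
    progesterone = stats::rbinom(n, 1, if (is_ptb) 0.20 else 0.08),
    gravidity = gravidity, parity = parity,
    hist_miscarriage = stats::rbinom(n, 1, if (is_ptb) 0.25 else 0.15),
    hist_ptb = stats::rbinom(n, 1, if (is_ptb) 0.31 else 0.10),
    antibiotics_6mo = stats::rbinom(n, 1, if (is_ptb) 0.30 else 0.25),
    vaginal_delivery = stats::rbinom(n, 1, if (is_ptb) 0.84 else 0.82),
    pprom = if (is_ptb) stats::rbinom(n, 1, 0.58) else integer(n),
    stringsAsFactors = FALSE)
}

#' Simulate a full longitudinal PTB/TB cohort with ground truth
#'
#' Generates case and candidate-control subjects, 2:1 case-matches controls
#' on ethnicity/age/income ([match_controls()]), draws a delivery day per
#' subject (PTB 161-258 d, TB 273-294 d), simulates each subject's latent
#' vagitype path over the visit schedule (truncated at delivery) from the
#' outcome-specific CTMC, draws per-visit Dirichlet-multinomial compositions
#' and overdispersed read depths, derives visit pH from the latent state,
#' and simulates LOD-censored cytokines from the realized transformed
#' abundances. All generating parameters and latent paths are retained for
#' recovery testing.
#'
#' @param config A [synthetic_config()].
#' @return A `synthetic_cohort`: list with `table` ([abundance_table()]),
#'   `records` (per-sample metadata), `cytokines` (`values`, `flags`),
#'   `cohort` (the matched `cohort_table`), and `truth` (config, latent
#'   states per sample, delivery days).
#' @export
simulate_cohort <- function(config = synthetic_config()) {
  with_seed(config$seed, {
    cases <- simulate_subject_covariates(config$n_cases, "PTB", "case")
    pool <- simulate_subject_covariates(config$n_controls_pool, "TB", "ctrl")
    cohort <- match_controls(cases, pool, ratio = 2)
    subjects <- rbind(cases, pool[pool$subject_id %in% cohort$controls, ])

    recs <- list(); counts <- list(); latent <- list()
    for (i in seq_len(nrow(subjects))) {
      s <- subjects[i, ]
      is_ptb <- s$outcome == "PTB"
      delivery <- round(stats::runif(1,
        if (is_ptb) config$delivery_ptb[1] else config$delivery_tb[1],
        if (is_ptb) config$delivery_ptb[2] else config$delivery_tb[2]))
      visits <- seq(config$first_visit, 315, by = config$visit_every)
      visits <- visits[visits < delivery]
      if (length(visits) == 0) next
      Q <- if (is_ptb) config$Q_PTB else config$Q_TB
      init <- if (is_ptb) config$init_PTB else config$init_TB
      path <- simulate_vagitype_path(Q, init, visits)
      for (v in seq_along(visits)) {
        depth <- if (stats::runif(1) < config$low_depth_rate)
          stats::rpois(1, 500) + 1L
        else
          stats::rnbinom(1, size = config$depth_size, mu = config$depth_mean) + 1L
        cnt <- simulate_composition(path[v], config, s$outcome, depth)
        sid <- sprintf("%s_v%02d", s$subject_id, v)
        counts[[sid]] <- cnt
        dysb <- path[v] %in% c("BVAB1", "Gvaginalis", "Other")
        recs[[sid]] <- data.frame(
          sample_id = sid, subject_id = s$subject_id,
          gestational_age = visits[v], outcome = s$outcome,
          bmi = s$bmi,
          vaginal_ph = round(4.0 + 0.8 * dysb + stats::rnorm(1, 0, 0.25), 2),
          ethnicity = s$ethnicity, ancestry = s$ancestry, age = s$age,
          income_bracket = s$income_bracket,
          short_cervix = s$short_cervix, cerclage = s$cerclage,
          progesterone = s$progesterone, gravidity = s$gravidity,
          parity = s$parity, hist_miscarriage = s$hist_miscarriage,
          hist_ptb = s$hist_ptb, antibiotics_6mo = s$antibiotics_6mo,
          vaginal_delivery = s$vaginal_delivery, pprom = s$pprom,
          delivery_day = delivery,
          stringsAsFactors = FALSE)
        latent[[sid]] <- path[v]
      }
    }
    cm <- do.call(rbind, counts)
    rownames(cm) <- names(counts)
    table <- abundance_table(cm, layout = "counts")
    records <- do.call(rbind, recs)
    rownames(records) <- NULL
    cyto <- simulate_cytokines(
      soft_threshold_log(table$values), config)
    structure(list(table = table, records = records, cytokines = cyto,
                   cohort = cohort,
                   truth = list(config = config,
                                latent_state = unlist(latent),
                                subjects = subjects)),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d subjects (%d PTB / %d TB), %d samples\n",
              length(unique(x$records$subject_id)),
              length(x$cohort$cases), length(x$cohort$controls),
              nrow(x$records)))
  invisible(x)
}
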