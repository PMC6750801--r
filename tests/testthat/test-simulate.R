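test_that("simulated compositions satisfy table invariants for any valid config", {
  cfg <- synthetic_config(seed = 81)
  for (st in rownames(cfg$templates)) {
    cnt <- simulate_composition(st, cfg, "PTB", depth = 20000, seed = 81)
    expect_equal(sum(cnt), 20000)
    expect_true(all(cnt >= 0))
    expect_length(cnt, length(cfg$taxa))
  }
  expect_error(simulate_composition("Lcrispatus", cfg, "TB", depth = 0),
               "positive")
})

test_that("the dominant taxon's mean proportion tracks its template mass", {
  cfg <- synthetic_config(seed = 82, precision = 200)
  ## with high precision the Dirichlet concentrates on the template mean
  tpl <- cfg$templates["Lcrispatus", ] / sum(cfg$templates["Lcrispatus", ])
  target <- tpl[["Lactobacillus_crispatus_cluster"]]
  set.seed(82)
  props <- replicate(100, {
    cnt <- simulate_composition("Lcrispatus", cfg, "TB", depth = 50000)
    cnt[["Lactobacillus_crispatus_cluster"]] / 50000
  })
  expect_equal(mean(props), target, tolerance = 0.02)
})

test_that("a zero outcome effect leaves PTB and TB draws identically distributed", {
  cfg <- synthetic_config(seed = 83, ptb_effect = numeric(0))
  set.seed(83)
  p_ptb <- replicate(500, {
    cnt <- simulate_composition("BVAB1", cfg, "PTB", 5000)
    cnt[["Lachnospiraceae_BVAB1"]] / 5000
  })
  p_tb <- replicate(500, {
    cnt <- simulate_composition("BVAB1", cfg, "TB", 5000)
    cnt[["Lachnospiraceae_BVAB1"]] / 5000
  })
  ## counts at finite depth tie occasionally; the approximate KS p suffices
  ks <- suppressWarnings(stats::ks.test(p_ptb, p_tb))
  expect_gt(ks$p.value, 0.01)
})

test_that("a near-degenerate template yields near-monoculture samples", {
  cfg <- synthetic_config(seed = 84, precision = 5000)
  cfg$templates["Lcrispatus", ] <- 1e-4
  cfg$templates["Lcrispatus", "Lactobacillus_crispatus_cluster"] <- 5000
  cnt <- simulate_composition("Lcrispatus", cfg, "TB", 50000, seed = 84)
  expect_gt(cnt[["Lactobacillus_crispatus_cluster"]] / 50000, 0.98)
})

test_that("cytokine simulation honors baseline, loadings and LOD censoring", {
  cfg <- synthetic_config(seed = 85)
  m <- matrix(runif(200 * length(cfg$taxa), 0, 3), 200,
              dimnames = list(paste0("s", 1:200), cfg$taxa))
  ## zero loadings, zero noise -> everything at baseline
  cfg0 <- cfg
  cfg0$cytokine_loadings[] <- 0
  cfg0$cytokine_noise_sd <- 0
  out0 <- simulate_cytokines(m, cfg0, seed = 85)
  expect_true(all(abs(out0$values - 10^1.0) < 1e-9))
  expect_true(all(out0$flags == "in"))

  ## positive IL-1b loading on BVAB1 -> positive sample correlation
  cfg1 <- cfg0
  cfg1$cytokine_loadings["IL-1b", "Lachnospiraceae_BVAB1"] <- 0.5
  cfg1$cytokine_noise_sd <- 0.3
  out1 <- simulate_cytokines(m, cfg1, seed = 86)
  ct <- stats::cor.test(log10(out1$values[, "IL-1b"]),
                        m[, "Lachnospiraceae_BVAB1"])
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)

  ## baseline below the lower LOD -> everything censored low
  cfg2 <- cfg0
  cfg2$cytokine_baseline[] <- -2
  out2 <- simulate_cytokines(m, cfg2, seed = 87)
  expect_true(all(out2$flags == "below"))
  expect_true(all(out2$values == cfg2$lod_bounds$lo[1]))
})

test_that("the default cohort realizes the 2:1 matched 135-subject design", {
  coh <- simulate_cohort(synthetic_config(seed = 88))
  expect_equal(length(coh$cohort$cases), 45L)
  expect_equal(length(coh$cohort$controls), 90L)
  expect_equal(length(unique(coh$records$subject_id)), 135L)
  ## every sample has a record; every record a sample
  expect_setequal(coh$table$sample_ids, coh$records$sample_id)
  ## delivery laws respected and visits truncated at delivery
  subj <- unique(coh$records[, c("subject_id", "outcome", "delivery_day")])
  expect_true(all(subj$delivery_day[subj$outcome == "PTB"] >= 161 &
                    subj$delivery_day[subj$outcome == "PTB"] <= 258))
  expect_true(all(subj$delivery_day[subj$outcome == "TB"] >= 273))
  expect_true(all(coh$records$gestational_age <
                    coh$records$delivery_day))
  ## compositional invariants
  expect_true(all(abs(rowSums(coh$table$values) - 1) < 1e-9))
  expect_true(all(coh$table$read_depth >= 1))
  ## a small fraction of sub-1000-read assay failures is present
  frac_low <- mean(coh$table$read_depth < 1000)
  expect_gt(frac_low, 0)
  expect_lt(frac_low, 0.1)
})

test_that("a fixed seed reproduces the cohort bitwise", {
  c1 <- simulate_cohort(synthetic_config(seed = 89, n_cases = 6,
                                         n_controls_pool = 40))
  c2 <- simulate_cohort(synthetic_config(seed = 89, n_cases = 6,
                                         n_controls_pool = 40))
  expect_identical(c1$table$values, c2$table$values)
  expect_identical(c1$records, c2$records)
  expect_identical(c1$cytokines$values, c2$cytokines$values)
})

test_that("latent truth is internally consistent with the drawn samples", {
  coh <- simulate_cohort(synthetic_config(seed = 90, n_cases = 6,
                                          n_controls_pool = 40))
  expect_setequal(names(coh$truth$latent_state), coh$table$sample_ids)
  expect_true(all(coh$truth$latent_state %in% rownames(coh$truth$config$templates)))
})

test_that("the signature taxa are recovered in at least 90% of simulated cohorts", {
  sig <- c("Lachnospiraceae_BVAB1", "Sneathia_amnii", "Prevotella_cluster2",
           "TM7_H1")
  hits <- vapply(1:50, function(rep) {
    coh <- simulate_cohort(cross_sectional_config(seed = 1000 + rep))
    tab <- filter_min_reads(coh$table)
    early <- earliest_sample_in_window(coh$records, c(42, 167))
    early <- early[early$sample_id %in% tab$sample_ids, ]
    res <- differential_screen(subset_samples(tab, early$sample_id), early)
    all(sig %in% res$taxon[res$significant])
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
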