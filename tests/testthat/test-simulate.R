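# Synthetic-data generators: composition, determinism, planted effects,
# and closed-form checks.

test_that("default screen generator emits the full hairpin library", {
  sim <- gen_screen_counts(screen_sim_config(seed = 1))
  expect_equal(nrow(sim$counts), 7296)
  expect_equal(ncol(sim$counts), 6)
  expect_equal(length(unique(sim$gene_id)), 912)
  expect_true(all(table(sim$gene_id) == 8))
  expect_true(all(sim$counts >= 0))
  expect_true(all(sim$counts == round(sim$counts)))
})

test_that("generators are deterministic given the seed", {
  a <- gen_screen_counts(screen_sim_config(n_genes = 25, seed = 6))
  b <- gen_screen_counts(screen_sim_config(n_genes = 25, seed = 6))
  expect_identical(a, b)
  expect_false(identical(
    a$counts, gen_screen_counts(screen_sim_config(n_genes = 25, seed = 7))$counts))

  s1 <- gen_slamseq_counts(slam_sim_config(n_genes = 15, seed = 2))
  s2 <- gen_slamseq_counts(slam_sim_config(n_genes = 15, seed = 2))
  expect_identical(s1, s2)

  p1 <- gen_protein_groups(proteome_sim_config(n_proteins = 50, seed = 3))
  p2 <- gen_protein_groups(proteome_sim_config(n_proteins = 50, seed = 3))
  expect_identical(p1, p2)

  d1 <- gen_dose_response(1, 1, c(0.5, 1, 2), noise_sd = 3, seed = 4)
  d2 <- gen_dose_response(1, 1, c(0.5, 1, 2), noise_sd = 3, seed = 4)
  expect_identical(d1, d2)
})

test_that("per-gene sub-streams keep existing genes stable when more are added", {
  small <- gen_screen_counts(screen_sim_config(n_genes = 10, frac_depleted = 0,
                                               frac_enriched = 0, seed = 5))
  large <- gen_screen_counts(screen_sim_config(n_genes = 40, frac_depleted = 0,
                                               frac_enriched = 0, seed = 5))
  expect_identical(small$counts, large$counts[1:80, ])
})

test_that("planted screen effects have the configured fold change", {
  cfg <- screen_sim_config(n_genes = 20, frac_depleted = 0.2,
                           frac_enriched = 0, effect_log2fc = 2,
                           frac_active_shrnas = 1, baseline_mean = 500,
                           seed = 10)
  sim <- gen_screen_counts(cfg)
  # independent recount on the emitted matrix
  dep <- sim$gene_id %in% sim$truth$gene_id[sim$truth$status == "depleted"]
  ctl <- rowMeans(sim$counts[, 1:3])
  trt <- rowMeans(sim$counts[, 4:6])
  ratio <- sum(trt[dep]) / sum(ctl[dep])
  expect_equal(ratio, 2^-2, tolerance = 0.1)
  ratio_null <- sum(trt[!dep]) / sum(ctl[!dep])
  expect_equal(ratio_null, 1, tolerance = 0.1)
})

test_that("null screens pass the trend rule at the binomial sign-pattern rate", {
  sim <- gen_screen_counts(screen_sim_config(n_genes = 500, effect_log2fc = 0,
                                             seed = 14))
  fcs <- shrna_log2fc(sim$counts, sim$condition, sim$gene_id)
  hits <- call_gene_hits(fcs)
  # oracle: exact binomial tail for >= 5 of 8 sharing a sign
  p_null <- 2 * sum(dbinom(5:8, 8, 0.5))
  se <- sqrt(p_null * (1 - p_null) / 500)
  expect_equal(mean(hits$passes_trend_rule), p_null, tolerance = 4 * se)
})

test_that("screen column sums scale linearly with baseline_mean", {
  lo <- gen_screen_counts(screen_sim_config(n_genes = 150, baseline_mean = 200,
                                            seed = 20))
  hi <- gen_screen_counts(screen_sim_config(n_genes = 150, baseline_mean = 800,
                                            seed = 20))
  expect_equal(unname(colSums(hi$counts) / colSums(lo$counts)), rep(4, 6),
               tolerance = 0.05)
})

test_that("screen config enforces its invariants", {
  expect_error(screen_sim_config(frac_depleted = 0.7, frac_enriched = 0.5),
               "<= 1")
  expect_error(screen_sim_config(baseline_mean = 0), "baseline_mean")
  expect_error(screen_sim_config(dispersion = -1), "dispersion")
})

test_that("noise-free dose-response tables follow the median-effect model", {
  tab <- gen_dose_response(1, 1, c(1, 3), n_replicates = 1, noise_sd = 0)
  expect_equal(tab$pct_live[tab$dose_um == 1], 50)  # D = Dm
  expect_equal(tab$pct_live[tab$dose_um == 3], 25)  # fa = 3/4 at m=1, Dm=1

  # round trip: generate then fit recovers (m, Dm) to tolerance
  doses <- c(0.2, 0.5, 1, 2, 5)
  tab2 <- gen_dose_response(1.7, 0.9, doses, n_replicates = 2, noise_sd = 0)
  fa <- 1 - tab2$pct_live / 100
  fit <- fit_median_effect(tab2$dose_um, fa)
  expect_equal(fit$m, 1.7, tolerance = 1e-9)
  expect_equal(fit$Dm, 0.9, tolerance = 1e-9)

  expect_error(gen_dose_response(0, 1, 1), "'m'")
  expect_error(gen_dose_response(1, -1, 1), "'Dm'")
  # noise is truncated to the physical bounds
  noisy <- gen_dose_response(1, 1, c(0.01, 100), n_replicates = 200,
                             noise_sd = 15, seed = 2)
  expect_true(all(noisy$pct_live >= 0 & noisy$pct_live <= 100))
})

test_that("gen_combination emits the fa solving the target CI", {
  f1 <- me_fit(1, 1)
  f2 <- me_fit(1, 2)
  # closed form: dA = dB = 0.5, DxA = 1, DxB = 2 at fa = 0.5 gives 0.75
  out <- gen_combination(f1, f2, data.frame(a = 0.5, b = 0.5),
                         target_ci = 0.75)
  expect_equal(out$fa, 0.5, tolerance = 1e-9)

  # sham: target 1 with identical fits at equal doses reproduces the
  # single-drug fa at the doubled dose
  f <- me_fit(2.2, 0.7)
  sham <- gen_combination(f, f, data.frame(a = 0.4, b = 0.4), target_ci = 1)
  expect_equal(sham$fa, me_fa(0.8, 2.2, 0.7), tolerance = 1e-9)

  # round trip through combination_index across random pairs
  set.seed(55)
  pairs <- data.frame(a = runif(20, 0.05, 3), b = runif(20, 0.05, 3))
  fits <- list(me_fit(runif(1, 0.5, 3), runif(1, 0.3, 3)),
               me_fit(runif(1, 0.5, 3), runif(1, 0.3, 3)))
  out2 <- gen_combination(fits[[1]], fits[[2]], pairs, target_ci = 0.8)
  for (i in which(out2$solved)) {
    ci <- combination_index(fits[[1]], fits[[2]], out2$dose_a_um[i],
                            out2$dose_b_um[i], out2$fa[i])$ci
    expect_equal(ci, 0.8, tolerance = 1e-6)
  }

  # an unattainably small target CI is flagged and skipped, not fatal
  expect_warning(
    miss <- gen_combination(f1, f2, data.frame(a = 5, b = 5),
                            target_ci = 1e-13),
    "no fa")
  expect_false(miss$solved)
})

test_that("slamseq generator reproduces the background conversion tail", {
  cfg <- slam_sim_config(n_genes = 60, utrs_per_gene = 1, n_replicates = 2,
                         reads_per_utr_mean = 400, n_t_sites = 25,
                         p_conversion_background = 0.004, frac_labeled = 0,
                         frac_repressed = 0, seed = 44)
  sim <- gen_slamseq_counts(cfg)
  n_total <- sum(sim$table$n_reads)
  n_nascent <- sum(sim$table$n_reads[sim$table$k >= 2])
  # binomial tail: 1 - (1-p)^n - n p (1-p)^(n-1)
  p <- 0.004
  n <- 25
  tail <- 1 - (1 - p)^n - n * p * (1 - p)^(n - 1)
  se <- sqrt(tail * (1 - tail) / n_total)
  expect_lt(abs(n_nascent / n_total - tail), 5 * se + 0.1 * tail)
})

test_that("degenerate conversion probabilities behave as limits", {
  cfg <- slam_sim_config(n_genes = 10, utrs_per_gene = 1, n_replicates = 2,
                         reads_per_utr_mean = 50, n_t_sites = 12,
                         p_conversion_labeled = 1,
                         p_conversion_background = 0, frac_labeled = 1,
                         frac_repressed = 0, seed = 3)
  sim <- gen_slamseq_counts(cfg)
  expect_true(all(sim$table$k == 12))
  expect_error(slam_sim_config(p_conversion_labeled = 0.01,
                               p_conversion_background = 0.02),
               "below p_conversion_labeled")
})

test_that("protein-group generator plants flags, background and reductions", {
  cfg <- proteome_sim_config(n_proteins = 800, frac_reverse = 0.1,
                             frac_background = 0.2, seed = 9)
  sim <- gen_protein_groups(cfg)
  expect_equal(nrow(sim$records), 800)
  expect_equal(mean(sim$records$reverse), 0.1, tolerance = 0.04)
  expect_equal(mean(sim$records$psm_background > 0), 0.2, tolerance = 0.05)
  # planted reduction shows up in raw PSM means
  aff <- sim$truth$affected
  trt <- rowMeans(sim$records[, grep("^psm_treated_", names(sim$records))])
  dmso <- rowMeans(sim$records[, grep("^psm_dmso_", names(sim$records))])
  expect_equal(sum(trt[aff]) / sum(dmso[aff]), 0.1, tolerance = 0.03)

  # total removal when everything is a decoy
  all_rev <- gen_protein_groups(proteome_sim_config(n_proteins = 40,
                                                    frac_reverse = 1,
                                                    seed = 2))
  expect_length(filter_protein_groups(all_rev$records)$retained, 0)
})
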