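# Pooled shRNA screen: normalization, fold changes, trend-rule hit
# calling, permutation significance, and coverage arithmetic.

test_that("normalize_rpm scales columns to one million", {
  m <- matrix(c(1, 1, 2), ncol = 1)
  expect_equal(drop(normalize_rpm(m)), c(250000, 250000, 500000))

  set.seed(11)
  r <- matrix(rpois(200, 40), 50, 4, dimnames = list(NULL, paste0("s", 1:4)))
  rpm <- normalize_rpm(r)
  expect_equal(unname(colSums(rpm)), rep(1e6, 4))
  # independent elementwise recomputation
  manual <- r
  for (j in 1:4) manual[, j] <- r[, j] * 1e6 / sum(r[, j])
  expect_equal(rpm, manual, tolerance = 1e-9)

  r[, 2] <- 0
  expect_error(normalize_rpm(r), "s2")
})

test_that("shrna_log2fc computes pseudocounted RPM fold changes", {
  set.seed(2)
  counts <- matrix(rpois(40, 100), 10, 4,
                   dimnames = list(paste0("sh", 1:10), NULL))
  cond <- c("control", "control", "treated", "treated")
  genes <- rep(c("g1", "g2"), each = 5)

  same <- cbind(counts[, 1:2], counts[, 1:2])
  fc0 <- shrna_log2fc(same, cond, genes)
  expect_equal(fc0$log2fc, rep(0, 10))

  # doubled relative abundance at RPM >> pseudocount: log2fc ~ 1.  The
  # doubling must survive depth normalization, so spike the treated
  # columns for half the rows against a fixed background.
  base <- matrix(1000, 10, 4)
  base[1:5, 3:4] <- 2000
  fc <- shrna_log2fc(base, cond, genes, pseudocount = 0.5)
  ratio <- (fc$mean_rpm_treated + 0.5) / (fc$mean_rpm_control + 0.5)
  expect_equal(fc$log2fc, log2(ratio), tolerance = 1e-12)
  expect_equal(fc$log2fc[1:5], rep(1, 5) + fc$log2fc[6], tolerance = 0.01,
               ignore_attr = TRUE)

  # independent recomputation on random data
  fcr <- shrna_log2fc(counts, cond, genes, pseudocount = 0.5)
  rpm <- normalize_rpm(counts)
  manual <- log2((rowMeans(rpm[, 3:4]) + 0.5) / (rowMeans(rpm[, 1:2]) + 0.5))
  expect_equal(fcr$log2fc, unname(manual), tolerance = 1e-9)

  expect_error(shrna_log2fc(counts, cond, genes, pseudocount = 0), "pseudocount")
})

test_that("call_gene_hits applies the 5-of-8 sign-consistency rule", {
  fc <- data.frame(gene_id = "g1",
                   log2fc = c(-1, -2, -0.5, -1.5, -3, 0.5, 1, 2))
  res <- call_gene_hits(fc)
  expect_equal(res$n_consistent, 5)
  expect_true(res$passes_trend_rule)
  expect_identical(res$direction, "depleted")
  expect_equal(res$avg_log2fc, mean(fc$log2fc))

  tie <- data.frame(gene_id = "g1", log2fc = c(-1, -1, -1, -1, 1, 1, 1, 1))
  res2 <- call_gene_hits(tie)
  expect_equal(res2$n_consistent, 4)
  expect_false(res2$passes_trend_rule)
  expect_identical(res2$direction, "none")

  # exact zeros count toward neither sign
  zeros <- data.frame(gene_id = "g1", log2fc = c(rep(-1, 5), 0, 0, 0))
  expect_true(call_gene_hits(zeros)$passes_trend_rule)
  expect_equal(call_gene_hits(zeros)$n_consistent, 5)
})

test_that("hit classification matches the exhaustive sign-count oracle", {
  set.seed(5)
  for (i in 1:200) {
    lfc <- round(rnorm(8), 2)
    if (i %% 7 == 0) lfc[sample(8, 2)] <- 0
    res <- call_gene_hits(data.frame(gene_id = "g", log2fc = lfc))
    oracle <- sign_rule_oracle(lfc)
    expect_equal(res$n_consistent, oracle$n_consistent)
    expect_equal(res$passes_trend_rule, oracle$passes)
    expect_identical(res$direction, oracle$direction)
  }
})

test_that("hit calling is invariant to shRNA order and flips with labels", {
  set.seed(9)
  counts <- matrix(rpois(8 * 40 * 6, 300), 8 * 40, 6)
  rownames(counts) <- paste0("sh", seq_len(nrow(counts)))
  genes <- rep(sprintf("g%02d", 1:40), each = 8)
  cond <- rep(c("control", "treated"), each = 3)

  fcs <- shrna_log2fc(counts, cond, genes)
  hits <- call_gene_hits(fcs)
  perm <- sample(nrow(fcs))
  hits_perm <- call_gene_hits(fcs[perm, ])
  expect_equal(hits, hits_perm)

  # swapping condition labels negates log2fc and swaps directions
  fcs_sw <- shrna_log2fc(counts, c("treated", "treated", "treated",
                                   "control", "control", "control"),
                         genes)
  expect_equal(fcs_sw$log2fc, -fcs$log2fc, tolerance = 1e-12)
  hits_sw <- call_gene_hits(fcs_sw)
  expect_equal(hits_sw$n_consistent, hits$n_consistent)
  flip <- c(depleted = "enriched", enriched = "depleted", none = "none")
  expect_identical(hits_sw$direction, unname(flip[hits$direction]))
})

test_that("permutation p-value matches exhaustive enumeration on a tiny library", {
  # library of 6 shRNAs, gene of 2: all C(6,2) = 15 subsets enumerable
  lfc <- c(-2.0, -1.5, 0.3, 0.8, 1.1, -0.2)
  fcs <- data.frame(gene_id = c("g1", "g1", "x", "x", "x", "x"),
                    log2fc = lfc)
  obs <- abs(mean(lfc[1:2]))
  combos <- combn(6, 2)
  exact <- mean(apply(combos, 2, function(ix) abs(mean(lfc[ix])) >= obs))
  p <- gene_permutation_pvalue(fcs, "g1", n_permutations = 20000, seed = 3)
  expect_equal(p, exact, tolerance = 0.02)
})

test_that("an extreme planted gene hits the permutation resolution floor", {
  set.seed(21)
  fcs <- data.frame(gene_id = c(rep("hit", 8), rep(sprintf("n%03d", 1:100),
                                                   each = 8)),
                    log2fc = c(rep(-3, 8), rnorm(800, 0, 0.3)))
  p <- gene_permutation_pvalue(fcs, "hit", n_permutations = 999, seed = 4)
  expect_equal(p, 1 / 1000)
  expect_warning(gene_permutation_pvalue(fcs, "hit", n_permutations = 99),
                 "coarse")
  expect_error(gene_permutation_pvalue(fcs[-(1:7), ], "hit"), "fewer than 2")
})

test_that("required_cells reproduces the screen coverage arithmetic", {
  des <- library_design()  # 912 x 8 at 1000x, 10% efficiency
  rc <- required_cells(des)
  expect_equal(rc$cells_to_transduce, 7296 * 1000 / 0.1)
  expect_equal(rc$cells_to_transduce_2sf, 7.3e7)
  expect_equal(rc$minimum_maintained_cells, 7296 * 1000)
  expect_equal(rc$minimum_maintained_cells_2sf, 7.3e6)

  full <- required_cells(library_design(infection_efficiency = 1))
  expect_equal(full$cells_to_transduce, full$minimum_maintained_cells)
})

test_that("analyze_screen chains fold changes, trend rule and permutation FDR", {
  sim <- gen_screen_counts(screen_sim_config(
    n_genes = 40, frac_depleted = 0.1, frac_enriched = 0.1,
    effect_log2fc = 2.5, frac_active_shrnas = 1, baseline_mean = 500,
    seed = 8))
  res <- analyze_screen(sim$counts, sim$condition, sim$gene_id,
                        n_permutations = 300, seed = 8)
  expect_equal(nrow(res), 40)
  expect_true(all(res$fdr >= res$p_value))
  truth <- sim$truth$status[match(res$gene_id, sim$truth$gene_id)]
  planted <- truth != "null"
  expect_true(all(res$passes_trend_rule[planted]))
  expect_identical(res$direction[planted], truth[planted])
  # planted genes dominate the small end of the permutation p distribution
  expect_lt(max(res$p_value[planted]), min(0.05, 1))
})
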