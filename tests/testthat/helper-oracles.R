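# Shared oracles and fixture builders, independent of the code paths they
# check.

# Evaluate expr under a throwaway RNG state.
with_seed_local <- function(seed, expr) {
  withr::with_seed(seed, expr)
}

# Median-effect forward model: fraction affected at dose D.
me_fa <- function(D, m, Dm) (D / Dm)^m / (1 + (D / Dm)^m)

# A median-effect fit object built directly from known parameters (for
# feeding CI routines without an OLS fit in the loop).
me_fit <- function(m, Dm, drug_id = NA_character_) {
  structure(list(drug_id = drug_id, m = m, Dm = Dm, r = 1, n_points = NA,
                 non_monotone = FALSE),
            class = "median_effect_fit")
}

# Exhaustive sign-count oracle for the gene trend rule.
sign_rule_oracle <- function(lfc, min_consistent = 5) {
  n_pos <- sum(lfc > 0)
  n_neg <- sum(lfc < 0)
  n_cons <- max(n_pos, n_neg)
  passes <- n_cons >= min_consistent && n_pos != n_neg
  direction <- if (!passes) "none" else if (n_neg > n_pos) "depleted" else "enriched"
  list(n_consistent = n_cons, passes = passes, direction = direction)
}

# Exact upper-tail hypergeometric probability by direct enumeration:
# P(overlap >= k) when drawing |A| genes from a universe of N containing
# |B| marked genes.
hyper_tail_oracle <- function(k, size_a, size_b, N) {
  ks <- k:min(size_a, size_b)
  sum(exp(lchoose(size_b, ks) + lchoose(N - size_b, size_a - ks) -
            lchoose(N, size_a)))
}

# Small protein-group table covering every cascade stage.
toy_protein_records <- function() {
  data.frame(
    protein_id = sprintf("P%d", 1:8),
    potential_contaminant = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    reverse = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    only_identified_by_site = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    psm_background = c(0L, 0L, 0L, 5L, 2L, 0L, 0L, 0L),
    psm_dmso_1 = c(10L, 10L, 10L, 10L, 25L, 5L, 12L, 30L),
    psm_dmso_2 = c(10L, 10L, 10L, 12L, 25L, 0L, 11L, 28L),
    psm_dmso_3 = c(10L, 10L, 10L, 11L, 25L, 7L, 13L, 32L),
    psm_treated_1 = c(5L, 5L, 5L, 5L, 20L, 2L, 0L, 6L),
    psm_treated_2 = c(5L, 5L, 5L, 6L, 22L, 3L, 0L, 8L),
    psm_treated_3 = c(5L, 5L, 5L, 5L, 21L, 2L, 0L, 7L),
    stringsAsFactors = FALSE
  )
  # Hand enumeration:
  #  stage 1 (qc flags) removes P1 (contaminant), P2 (reverse), P3 (site)
  #    -> 3 removed, 5 remain
  #  stage 2 (background) P4: mean DMSO 11, bg 5, ratio 2.2 < 10 -> removed;
  #    P5: mean DMSO 25, bg 2, ratio 12.5 >= 10 -> rescued
  #    -> 1 removed, 4 remain
  #  stage 3 (DMSO zero) removes P6 (psm_dmso_2 == 0) -> 1 removed, 3 remain
  #  retained: P5, P7, P8
}

# Long conversion-count fixture builder.
conv_row <- function(utr, gene, sample, cond, rep, k, n) {
  data.frame(utr_id = utr, gene_id = gene, sample_id = sample,
             condition = cond, replicate = rep, k = k, n_reads = n,
             stringsAsFactors = FALSE)
}
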