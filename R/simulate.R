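# Synthetic-data generators with planted ground truth for every input
# type of the pipeline: shRNA screen counts, single-agent and combination
# viability tables, SLAM-seq conversion-stratified read counts, and
# MaxQuant-style protein groups.  All generators are deterministic given
# their seed, with per-gene/protein sub-streams so enlarging a simulation
# never perturbs the units already present.

#' Configuration for the synthetic shRNA screen
#'
#' Defaults mirror a chromatin-focused hairpin library: 912 genes with 8
#' hairpins each (7296 constructs), sequenced in triplicate per condition.
#' Counts follow a negative-binomial model (the standard overdispersed
#' model for pooled-screen sequencing) around a per-hairpin baseline, and
#' planted genes carry an `effect_log2fc` shift in the treated condition
#' on `frac_active_shrnas` of their hairpins.
#'
#' @param n_genes,shrnas_per_gene Library composition (defaults 912 x 8).
#' @param n_replicates Replicates per condition (default 3).
#' @param baseline_mean Expected raw count per hairpin (default 1000,
#'   i.e. roughly 1000x sequencing coverage of the library).
#' @param dispersion Negative-binomial dispersion alpha, so
#'   `Var = mu + alpha * mu^2` (default 0.05).
#' @param frac_depleted,frac_enriched Fractions of genes planted as
#'   depleted / enriched (defaults 0.05 and 0.03); must sum to <= 1.
#' @param effect_log2fc Magnitude of the planted hairpin-level log2 fold
#'   change (default 2).
#' @param frac_active_shrnas Fraction of a planted gene's hairpins that
#'   carry the effect (default 0.75, i.e. 6 of 8).
#' @param seed Integer seed.
#' @return Validated list of class `screen_sim_config`.
#' @export
screen_sim_config <- function(n_genes = 912, shrnas_per_gene = 8,
                              n_replicates = 3, baseline_mean = 1000,
                              dispersion = 0.05, frac_depleted = 0.05,
                              frac_enriched = 0.03, effect_log2fc = 2,
                              frac_active_shrnas = 0.75, seed = 1) {
  cfg <- list(
    n_genes = check_count(n_genes, "n_genes"),
    shrnas_per_gene = check_count(shrnas_per_gene, "shrnas_per_gene"),
    n_replicates = check_count(n_replicates, "n_replicates"),
    baseline_mean = check_scalar(baseline_mean, "baseline_mean",
                                 lo = 0, strict_lo = TRUE),
    dispersion = check_scalar(dispersion, "dispersion",
                              lo = 0, strict_lo = TRUE),
    frac_depleted = check_scalar(frac_depleted, "frac_depleted", 0, 1),
    frac_enriched = check_scalar(frac_enriched, "frac_enriched", 0, 1),
    effect_log2fc = check_scalar(effect_log2fc, "effect_log2fc"),
    frac_active_shrnas = check_scalar(frac_active_shrnas,
                                      "frac_active_shrnas", 0, 1),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (cfg$frac_depleted + cfg$frac_enriched > 1) {
    stop_config("frac_depleted + frac_enriched must be <= 1")
  }
  if (!is.finite(cfg$baseline_mean) || cfg$baseline_mean <= 0) {
    stop_config("baseline_mean must be finite and positive")
  }
  structure(cfg, class = "screen_sim_config")
}

#' Generate synthetic pooled shRNA screen counts
#'
#' Emits a raw count matrix of `n_genes * shrnas_per_gene` hairpins by
#' `2 * n_replicates` samples (control then treated) and a truth table of
#' planted gene labels.  Per-hairpin baselines vary log-normally around
#' `baseline_mean` (sd 0.25 on the log2 scale) to emulate cloning and
#' representation noise; counts are negative binomial with the configured
#' dispersion; planted hairpins have their treated-condition mean
#' multiplied by `2^(+-effect_log2fc)`.
#'
#' @param config A [screen_sim_config()].
#' @return List with `counts` (integer matrix, rownames shRNA ids),
#'   `gene_id` (per-row gene), `condition` (per-column), and `truth`
#'   (data.frame: gene_id, status in depleted/enriched/null).
#' @export
gen_screen_counts <- function(config) {
  stopifnot(inherits(config, "screen_sim_config"))
  n_sh <- config$shrnas_per_gene
  n_rep <- config$n_replicates
  genes <- sprintf("gene_%04d", seq_len(config$n_genes))
  n_dep <- round(config$frac_depleted * config$n_genes)
  n_enr <- round(config$frac_enriched * config$n_genes)
  status <- with_seed(config$seed, {
    st <- rep("null", config$n_genes)
    planted <- sample.int(config$n_genes, n_dep + n_enr)
    st[planted[seq_len(n_dep)]] <- "depleted"
    if (n_enr > 0) st[planted[n_dep + seq_len(n_enr)]] <- "enriched"
    st
  })
  size <- 1 / config$dispersion
  n_active <- round(config$frac_active_shrnas * n_sh)
  per_gene <- lapply(seq_len(config$n_genes), function(g) {
    with_seed(substream_seed(config$seed, g), {
      base <- config$baseline_mean * 2^stats::rnorm(n_sh, 0, 0.25)
      shift <- rep(1, n_sh)
      if (status[g] != "null" && n_active > 0) {
        sgn <- if (status[g] == "depleted") -1 else 1
        shift[seq_len(n_active)] <- 2^(sgn * config$effect_log2fc)
      }
      ctl <- matrix(stats::rnbinom(n_sh * n_rep, size = size, mu = base),
                    n_sh, n_rep)
      trt <- matrix(stats::rnbinom(n_sh * n_rep, size = size,
                                   mu = base * shift),
                    n_sh, n_rep)
      cbind(ctl, trt)
    })
  })
  counts <- do.call(rbind, per_gene)
  rownames(counts) <- sprintf("%s.sh%d", rep(genes, each = n_sh),
                              rep(seq_len(n_sh), config$n_genes))
  colnames(counts) <- c(sprintf("control_%d", seq_len(n_rep)),
                        sprintf("treated_%d", seq_len(n_rep)))
  list(counts = counts,
       gene_id = rep(genes, each = n_sh),
       condition = rep(c("control", "treated"), each = n_rep),
       truth = data.frame(gene_id = genes, status = status,
                          stringsAsFactors = FALSE))
}

#' Generate a single-agent dose-response viability table
#'
#' Inverts the median-effect model: at dose D the fraction affected is
#' `fa = (D/Dm)^m / (1 + (D/Dm)^m)` and percent live is
#' `100 * (1 - fa)` plus Gaussian noise truncated to \[0, 100\] (the
#' physical bounds of a viability assay).
#'
#' @param m Median-effect slope, > 0.
#' @param Dm Median-effect dose (uM), > 0.
#' @param doses Positive dose vector (uM).
#' @param n_replicates Replicates per dose (default 4).
#' @param noise_sd Gaussian noise sd on the percent-live scale (default 0).
#' @param seed Integer seed.
#' @param drug_id Label carried into the table.
#' @return Data.frame: `drug_id`, `dose_um`, `replicate`, `pct_live`.
#' @export
gen_dose_response <- function(m, Dm, doses, n_replicates = 4, noise_sd = 0,
                              seed = 1, drug_id = "drugA") {
  check_scalar(m, "m", lo = 0, strict_lo = TRUE)
  check_scalar(Dm, "Dm", lo = 0, strict_lo = TRUE)
  if (any(doses <= 0)) stop_config("doses must be positive")
  n_replicates <- check_count(n_replicates, "n_replicates")
  check_scalar(noise_sd, "noise_sd", lo = 0)
  fa <- (doses / Dm)^m / (1 + (doses / Dm)^m)
  out <- data.frame(
    drug_id = drug_id,
    dose_um = rep(doses, each = n_replicates),
    replicate = rep(seq_len(n_replicates), length(doses)),
    pct_live = 100 * (1 - rep(fa, each = n_replicates)),
    stringsAsFactors = FALSE
  )
  if (noise_sd > 0) {
    out$pct_live <- with_seed(seed, {
      pmin(pmax(out$pct_live + stats::rnorm(nrow(out), 0, noise_sd), 0), 100)
    })
  }
  out
}

#' Generate a combination viability table with known combination index
#'
#' Inverse of the combination-index equation: for each dose pair
#' `(dA, dB)` the emitted fraction affected is the root of
#' `dA / DxA(fa) + dB / DxB(fa) = target_ci`.  The left side is strictly
#' decreasing in `fa` (for positive slopes), so the root on (0, 1) is
#' unique when it exists; pairs without a root are flagged and skipped.
#'
#' @param fit_a,fit_b Single-agent [fit_median_effect()] results (or lists
#'   with positive `m` and `Dm`).
#' @param dose_pairs Data.frame or 2-column matrix of positive doses
#'   (`dose_a_um`, `dose_b_um`).
#' @param target_ci Target combination index, > 0 (default 0.75,
#'   a synergistic pair).
#' @param tol Root-solver tolerance (default 1e-12).
#' @return Data.frame: `dose_a_um`, `dose_b_um`, `fa`, `pct_live`,
#'   `solved` (FALSE rows had no root and carry NA fa).
#' @export
gen_combination <- function(fit_a, fit_b, dose_pairs, target_ci = 0.75,
                            tol = 1e-12) {
  check_scalar(target_ci, "target_ci", lo = 0, strict_lo = TRUE)
  for (f in list(fit_a, fit_b)) {
    if (!is.finite(f$m) || f$m <= 0) stop_config("fit has non-positive slope")
  }
  dp <- as.data.frame(dose_pairs)
  names(dp)[1:2] <- c("dose_a_um", "dose_b_um")
  if (any(dp$dose_a_um <= 0) || any(dp$dose_b_um <= 0)) {
    stop_config("dose pairs must be positive")
  }
  eps <- 1e-12
  fa <- vapply(seq_len(nrow(dp)), function(i) {
    g <- function(f) {
      dp$dose_a_um[i] / dose_for_effect(fit_a, f) +
        dp$dose_b_um[i] / dose_for_effect(fit_b, f) - target_ci
    }
    lo <- g(eps)
    hi <- g(1 - eps)
    if (is.na(lo) || is.na(hi) || lo * hi > 0) return(NA_real_)
    stats::uniroot(g, c(eps, 1 - eps), tol = tol)$root
  }, numeric(1))
  if (any(is.na(fa))) {
    warning(sum(is.na(fa)), " dose pair(s) had no fa solving the target CI; ",
            "flagged and skipped", call. = FALSE)
  }
  data.frame(dose_a_um = dp$dose_a_um, dose_b_um = dp$dose_b_um, fa = fa,
             pct_live = 100 * (1 - fa), solved = !is.na(fa),
             stringsAsFactors = FALSE)
}

#' Configuration for the synthetic SLAM-seq experiment
#'
#' Models the read-level structure of metabolic-labelling sequencing: per
#' 3'UTR, reads are a mixture of nascent (4sU-labelled) and pre-existing
#' transcripts; every read covers `n_t_sites` T positions and each T
#' converts to C independently, at `p_conversion_labeled` in labelled
#' reads and at the sequencing-error rate `p_conversion_background`
#' otherwise.  Repressed genes have their labelled-read yield scaled by
#' `2^repression_log2fc` in treated samples only.  Conversion rates and
#' labelled fractions are simulator parameters chosen to represent an
#' efficient labelling chemistry, not measured values.
#'
#' @param n_genes Genes simulated (default 300).
#' @param utrs_per_gene 3'UTR annotations per gene (default 2).
#' @param n_replicates Replicates per condition (default 3).
#' @param reads_per_utr_mean Expected reads per UTR per sample
#'   (default 200).
#' @param n_t_sites T positions covered per read (default 25).
#' @param p_conversion_labeled Per-T conversion probability in labelled
#'   reads (default 0.1).
#' @param p_conversion_background Error conversion rate (default 0.001);
#'   must be below `p_conversion_labeled`.
#' @param frac_labeled Fraction of reads from nascent transcripts
#'   (default 0.2, a short labelling pulse).
#' @param frac_repressed Fraction of genes with planted nascent
#'   repression (default 0.1).
#' @param repression_log2fc Planted log2 change of nascent yield in
#'   treated samples (default -2, i.e. 4-fold repression).
#' @param seed Integer seed.
#' @return Validated list of class `slam_sim_config`.
#' @export
slam_sim_config <- function(n_genes = 300, utrs_per_gene = 2,
                            n_replicates = 3, reads_per_utr_mean = 200,
                            n_t_sites = 25, p_conversion_labeled = 0.1,
                            p_conversion_background = 0.001,
                            frac_labeled = 0.2, frac_repressed = 0.1,
                            repression_log2fc = -2, seed = 1) {
  cfg <- list(
    n_genes = check_count(n_genes, "n_genes"),
    utrs_per_gene = check_count(utrs_per_gene, "utrs_per_gene"),
    n_replicates = check_count(n_replicates, "n_replicates"),
    reads_per_utr_mean = check_scalar(reads_per_utr_mean,
                                      "reads_per_utr_mean", lo = 0,
                                      strict_lo = TRUE),
    n_t_sites = check_count(n_t_sites, "n_t_sites"),
    p_conversion_labeled = check_scalar(p_conversion_labeled,
                                        "p_conversion_labeled", 0, 1),
    p_conversion_background = check_scalar(p_conversion_background,
                                           "p_conversion_background", 0, 1),
    frac_labeled = check_scalar(frac_labeled, "frac_labeled", 0, 1),
    frac_repressed = check_scalar(frac_repressed, "frac_repressed", 0, 1),
    repression_log2fc = check_scalar(repression_log2fc, "repression_log2fc"),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (cfg$p_conversion_background >= cfg$p_conversion_labeled) {
    stop_config("p_conversion_background must be below p_conversion_labeled")
  }
  structure(cfg, class = "slam_sim_config")
}

#' Generate synthetic SLAM-seq conversion-stratified counts
#'
#' @param config A [slam_sim_config()].
#' @return List with `table` (long data.frame: utr_id, gene_id, sample_id,
#'   condition, replicate, k, n_reads), `condition` per sample, and
#'   `truth` (gene_id, status in repressed/null).
#' @export
gen_slamseq_counts <- function(config) {
  stopifnot(inherits(config, "slam_sim_config"))
  genes <- sprintf("gene_%04d", seq_len(config$n_genes))
  n_rep <- config$n_replicates
  samples <- data.frame(
    sample_id = c(sprintf("DMSO_%d", seq_len(n_rep)),
                  sprintf("treated_%d", seq_len(n_rep))),
    condition = rep(c("control", "treated"), each = n_rep),
    replicate = rep(seq_len(n_rep), 2L),
    stringsAsFactors = FALSE
  )
  n_repressed <- round(config$frac_repressed * config$n_genes)
  status <- with_seed(config$seed, {
    st <- rep("null", config$n_genes)
    if (n_repressed > 0) {
      st[sample.int(config$n_genes, n_repressed)] <- "repressed"
    }
    st
  })
  mu_lab <- config$reads_per_utr_mean * config$frac_labeled
  mu_unlab <- config$reads_per_utr_mean * (1 - config$frac_labeled)
  per_gene <- lapply(seq_len(config$n_genes), function(g) {
    with_seed(substream_seed(config$seed, g), {
      rows <- list()
      for (u in seq_len(config$utrs_per_gene)) {
        utr <- sprintf("%s.utr%d", genes[g], u)
        for (s in seq_len(nrow(samples))) {
          scale_lab <- if (status[g] == "repressed" &&
                           samples$condition[s] == "treated") {
            2^config$repression_log2fc
          } else 1
          n_lab <- stats::rpois(1, mu_lab * scale_lab)
          n_unlab <- stats::rpois(1, mu_unlab)
          k_lab <- stats::rbinom(n_lab, config$n_t_sites,
                                 config$p_conversion_labeled)
          k_bg <- stats::rbinom(n_unlab, config$n_t_sites,
                                config$p_conversion_background)
          tab <- tabulate(c(k_lab, k_bg) + 1L, config$n_t_sites + 1L)
          nz <- which(tab > 0L)
          if (length(nz)) {
            rows[[length(rows) + 1L]] <- data.frame(
              utr_id = utr, gene_id = genes[g],
              sample_id = samples$sample_id[s],
              condition = samples$condition[s],
              replicate = samples$replicate[s],
              k = nz - 1L, n_reads = tab[nz],
              stringsAsFactors = FALSE
            )
          }
        }
      }
      do.call(rbind, rows)
    })
  })
  list(table = do.call(rbind, per_gene),
       condition = samples$condition,
       truth = data.frame(gene_id = genes, status = status,
                          stringsAsFactors = FALSE))
}

#' Configuration for the synthetic nascent-proteome table
#'
#' Emulates a MaxQuant-style protein-group table from an AHA-enrichment
#' experiment: Poisson PSM counts per replicate, quality flags
#' (contaminant / decoy / only-by-site) set for configured fractions, a
#' no-AHA background channel populated for a background fraction (a
#' sub-fraction of which is high-abundance and would pass the 10-fold
#' rescue), and a planted fraction of proteins whose treated-condition
#' PSM mean is multiplied by `reduction_factor`.
#'
#' @param n_proteins Proteins simulated (default 1000).
#' @param frac_contaminant,frac_reverse,frac_onlysite Flag fractions
#'   (defaults 0.02, 0.02, 0.01).
#' @param frac_background Fraction present in the no-AHA channel
#'   (default 0.05).
#' @param frac_background_highratio Of the background proteins, fraction
#'   with DMSO/background ratio >= 10 (default 0.1).
#' @param psm_mean Mean PSM count per replicate in DMSO (default 30).
#' @param frac_affected Fraction with planted treatment reduction
#'   (default 0.6).
#' @param reduction_factor Multiplier on treated PSM means for affected
#'   proteins, in \[0, 1\] (default 0.1).
#' @param n_dmso_reps,n_treated_reps Replicates per condition
#'   (defaults 3, 3).
#' @param seed Integer seed.
#' @return Validated list of class `proteome_sim_config`.
#' @export
proteome_sim_config <- function(n_proteins = 1000, frac_contaminant = 0.02,
                                frac_reverse = 0.02, frac_onlysite = 0.01,
                                frac_background = 0.05,
                                frac_background_highratio = 0.1,
                                psm_mean = 30, frac_affected = 0.6,
                                reduction_factor = 0.1, n_dmso_reps = 3,
                                n_treated_reps = 3, seed = 1) {
  cfg <- list(
    n_proteins = check_count(n_proteins, "n_proteins"),
    frac_contaminant = check_scalar(frac_contaminant, "frac_contaminant", 0, 1),
    frac_reverse = check_scalar(frac_reverse, "frac_reverse", 0, 1),
    frac_onlysite = check_scalar(frac_onlysite, "frac_onlysite", 0, 1),
    frac_background = check_scalar(frac_background, "frac_background", 0, 1),
    frac_background_highratio = check_scalar(frac_background_highratio,
                                             "frac_background_highratio",
                                             0, 1),
    psm_mean = check_scalar(psm_mean, "psm_mean", lo = 0, strict_lo = TRUE),
    frac_affected = check_scalar(frac_affected, "frac_affected", 0, 1),
    reduction_factor = check_scalar(reduction_factor, "reduction_factor",
                                    0, 1),
    n_dmso_reps = check_count(n_dmso_reps, "n_dmso_reps"),
    n_treated_reps = check_count(n_treated_reps, "n_treated_reps"),
    seed = check_count(seed, "seed", min = 0L)
  )
  structure(cfg, class = "proteome_sim_config")
}

#' Generate a synthetic protein-group table
#'
#' @param config A [proteome_sim_config()].
#' @return List with `records` (data.frame matching the
#'   [filter_protein_groups()] / [call_affected()] schema, plus `gene_id`)
#'   and `truth` (protein_id, gene_id, affected flag, plus the planted
#'   flag/background assignments).
#' @export
gen_protein_groups <- function(config) {
  stopifnot(inherits(config, "proteome_sim_config"))
  n <- config$n_proteins
  ids <- sprintf("prot_%05d", seq_len(n))
  assign <- with_seed(config$seed, {
    list(contaminant = stats::runif(n) < config$frac_contaminant,
         reverse = stats::runif(n) < config$frac_reverse,
         onlysite = stats::runif(n) < config$frac_onlysite,
         background = stats::runif(n) < config$frac_background,
         bg_high = stats::runif(n) < config$frac_background_highratio,
         affected = stats::runif(n) < config$frac_affected)
  })
  per_prot <- lapply(seq_len(n), function(i) {
    with_seed(substream_seed(config$seed, i), {
      mu <- config$psm_mean
      dmso <- stats::rpois(config$n_dmso_reps, mu)
      mu_trt <- mu * if (assign$affected[i]) config$reduction_factor else 1
      trt <- stats::rpois(config$n_treated_reps, mu_trt)
      bg <- if (assign$background[i]) {
        # high-ratio background proteins sit ~1/20 of DMSO abundance so
        # the mean-DMSO / background ratio typically clears 10-fold;
        # ordinary background is comparable to DMSO abundance
        lam <- if (assign$bg_high[i]) mu / 20 else mu / 2
        stats::rpois(1, lam) + 1L
      } else 0L
      c(dmso, trt, bg)
    })
  })
  m <- do.call(rbind, per_prot)
  records <- data.frame(
    protein_id = ids, gene_id = sprintf("gene_%05d", seq_len(n)),
    potential_contaminant = assign$contaminant, reverse = assign$reverse,
    only_identified_by_site = assign$onlysite,
    stringsAsFactors = FALSE
  )
  for (j in seq_len(config$n_dmso_reps)) {
    records[[sprintf("psm_dmso_%d", j)]] <- m[, j]
  }
  for (j in seq_len(config$n_treated_reps)) {
    records[[sprintf("psm_treated_%d", j)]] <- m[, config$n_dmso_reps + j]
  }
  records$psm_background <- m[, ncol(m)]
  list(records = records,
       truth = data.frame(protein_id = ids, gene_id = records$gene_id,
                          affected = assign$affected,
                          contaminant = assign$contaminant,
                          reverse = assign$reverse,
                          onlysite = assign$onlysite,
                          background = assign$background,
                          stringsAsFactors = FALSE))
}
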