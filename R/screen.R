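# Pooled shRNA loss-of-function screen analysis: depth normalization,
# per-shRNA fold changes, gene-level trend-rule hit calling, and a
# permutation significance test.
#
# The hit-calling rule mirrors the screen design it was built for: each
# gene is covered by 8 independent hairpins, and a gene is a candidate hit
# only when at least 5 of its hairpins move in the same direction
# (depleted or enriched) under treatment; the gene score is the average
# fold change over its detected hairpins.

#' Describe a pooled shRNA library design
#'
#' @param n_genes Number of target genes (default 912).
#' @param shrnas_per_gene Hairpins per gene (default 8).
#' @param representation Fold coverage of the library to maintain during
#'   the screen (default 1000, i.e. 1000x).
#' @param infection_efficiency Fraction of cells receiving a single
#'   integration at the chosen titre, in (0, 1] (default 0.1).
#' @return A list of class `library_design` with the above fields plus
#'   `library_size = n_genes * shrnas_per_gene`.
#' @export
library_design <- function(n_genes = 912, shrnas_per_gene = 8,
                           representation = 1000,
                           infection_efficiency = 0.1) {
  n_genes <- check_count(n_genes, "n_genes")
  shrnas_per_gene <- check_count(shrnas_per_gene, "shrnas_per_gene")
  check_scalar(representation, "representation", lo = 0, strict_lo = TRUE)
  check_scalar(infection_efficiency, "infection_efficiency", lo = 0, hi = 1,
               strict_lo = TRUE)
  structure(
    list(n_genes = n_genes, shrnas_per_gene = shrnas_per_gene,
         library_size = n_genes * shrnas_per_gene,
         representation = representation,
         infection_efficiency = infection_efficiency),
    class = "library_design"
  )
}

#' Cell numbers required to run a pooled screen at coverage
#'
#' Coverage arithmetic for screen planning: to keep `representation`-fold
#' coverage of a library of `library_size` constructs when only a fraction
#' `infection_efficiency` of cells is transduced,
#' `cells_to_transduce = library_size * representation / infection_efficiency`,
#' and the population must never drop below
#' `minimum_maintained_cells = library_size * representation`.  Both are
#' also reported rounded to two significant figures, the precision at
#' which such numbers are conventionally quoted.
#'
#' @param design A [library_design()].
#' @return List with `cells_to_transduce`, `minimum_maintained_cells`, and
#'   their 2-significant-figure counterparts `cells_to_transduce_2sf`,
#'   `minimum_maintained_cells_2sf`.
#' @examples
#' required_cells(library_design())  # 7.3e7 to transduce, 7.3e6 floor
#' @export
required_cells <- function(design) {
  stopifnot(inherits(design, "library_design"))
  floor_cells <- design$library_size * design$representation
  transduce <- floor_cells / design$infection_efficiency
  list(
    cells_to_transduce = transduce,
    minimum_maintained_cells = floor_cells,
    cells_to_transduce_2sf = signif(transduce, 2),
    minimum_maintained_cells_2sf = signif(floor_cells, 2)
  )
}

#' Depth-normalize a count matrix to reads per million
#'
#' `rpm[i, j] = count[i, j] * 1e6 / colsum[j]`, so every column sums to
#' one million.
#'
#' @param counts Numeric matrix of non-negative raw counts, shRNAs in rows
#'   and samples in columns.
#' @return Matrix of the same shape containing RPM values.
#' @export
normalize_rpm <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop_config("counts must be non-negative")
  depth <- colSums(counts)
  zero <- depth <= 0
  if (any(zero)) {
    stop_config("zero-depth sample column(s): %s",
                paste(colnames(counts)[zero], collapse = ", "))
  }
  sweep(counts, 2, depth, "/") * 1e6
}

#' Per-shRNA log2 fold changes between conditions
#'
#' For each hairpin, `log2fc = log2((mean treated RPM + pseudocount) /
#' (mean control RPM + pseudocount))`.  The pseudocount (default 0.5 RPM)
#' keeps fold changes finite for hairpins that drop out entirely while
#' preserving rank among the rest.
#'
#' @param counts Raw count matrix (shRNA x sample); rownames are shRNA ids.
#' @param condition Character vector over columns, values `"control"` or
#'   `"treated"`.
#' @param gene_id Character vector over rows mapping each shRNA to its
#'   gene.
#' @param pseudocount Positive RPM pseudocount (default 0.5).
#' @return Data.frame with one row per shRNA: `shrna_id`, `gene_id`,
#'   `mean_rpm_control`, `mean_rpm_treated`, `log2fc`.
#' @export
shrna_log2fc <- function(counts, condition, gene_id, pseudocount = 0.5) {
  check_scalar(pseudocount, "pseudocount", lo = 0, strict_lo = TRUE)
  counts <- as.matrix(counts)
  if (length(condition) != ncol(counts)) {
    stop_config("'condition' must label every sample column")
  }
  if (!all(condition %in% c("control", "treated"))) {
    stop_config("'condition' values must be 'control' or 'treated'")
  }
  if (length(gene_id) != nrow(counts)) {
    stop_config("'gene_id' must label every shRNA row")
  }
  rpm <- normalize_rpm(counts)
  mc <- rowMeans(rpm[, condition == "control", drop = FALSE])
  mt <- rowMeans(rpm[, condition == "treated", drop = FALSE])
  ids <- rownames(counts)
  if (is.null(ids)) ids <- sprintf("shRNA_%d", seq_len(nrow(counts)))
  data.frame(
    shrna_id = ids, gene_id = as.character(gene_id),
    mean_rpm_control = mc, mean_rpm_treated = mt,
    log2fc = log2((mt + pseudocount) / (mc + pseudocount)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Gene-level screen hit calling by sign consistency
#'
#' Applies the trend rule: the candidate direction of a gene is the
#' majority sign of its hairpins' nonzero log2 fold changes, and the gene
#' passes when at least `min_consistent` hairpins share that sign
#' (default 5, built for libraries with 8 hairpins per gene).  Fold
#' changes of exactly zero count toward neither sign.  The gene score
#' `avg_log2fc` averages over all detected hairpins, not only the
#' consistent ones.  Genes detected with fewer than `expected_shrnas`
#' hairpins are still scored under the same `min_consistent` threshold and
#' flagged via `n_shrnas_detected`.
#'
#' @param fcs Data.frame from [shrna_log2fc()] (columns `gene_id`,
#'   `log2fc`).
#' @param min_consistent Minimum same-sign hairpins to pass (default 5).
#' @param expected_shrnas Nominal hairpins per gene in the library design
#'   (default 8); informational.
#' @return Data.frame with one row per gene: `gene_id`,
#'   `n_shrnas_detected`, `n_consistent`, `direction` (depleted /
#'   enriched / none), `avg_log2fc`, `passes_trend_rule`.  Ties in the
#'   sign tally give `direction = "none"`.
#' @examples
#' fc <- data.frame(gene_id = rep("g1", 8),
#'                  log2fc = c(-1, -2, -1, -3, -1, 0.5, 1, 2))
#' call_gene_hits(fc)  # 5 negative of 8: depleted, passes
#' @export
call_gene_hits <- function(fcs, min_consistent = 5, expected_shrnas = 8) {
  min_consistent <- check_count(min_consistent, "min_consistent")
  check_count(expected_shrnas, "expected_shrnas")
  if (!all(c("gene_id", "log2fc") %in% names(fcs))) {
    stop_config("'fcs' needs columns gene_id and log2fc")
  }
  keep <- !is.na(fcs$log2fc)
  if (!all(keep)) fcs <- fcs[keep, , drop = FALSE]
  genes <- split(fcs$log2fc, fcs$gene_id)
  empty <- vapply(genes, length, integer(1)) == 0L
  if (any(empty)) {
    warning("gene(s) with no detected shRNAs omitted: ",
            paste(names(genes)[empty], collapse = ", "), call. = FALSE)
    genes <- genes[!empty]
  }
  res <- lapply(names(genes), function(g) {
    lfc <- genes[[g]]
    n_pos <- sum(lfc > 0)
    n_neg <- sum(lfc < 0)
    n_cons <- max(n_pos, n_neg)
    passes <- n_cons >= min_consistent && n_pos != n_neg
    direction <- if (!passes) "none" else if (n_neg > n_pos) "depleted" else "enriched"
    data.frame(gene_id = g, n_shrnas_detected = length(lfc),
               n_consistent = n_cons, direction = direction,
               avg_log2fc = mean(lfc), passes_trend_rule = passes,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Permutation p-value for a gene's average fold change
#'
#' Resampling null for the gene score: the observed statistic is the
#' absolute mean log2 fold change of the gene's hairpins; the null draws
#' same-size hairpin sets from the whole library without replacement.
#' Two-sided p with the add-one correction:
#' `p = (1 + #{|mean(perm)| >= |observed|}) / (1 + n_permutations)`.
#'
#' @param fcs Data.frame from [shrna_log2fc()].
#' @param gene_id Gene to test (must have >= 2 hairpins).
#' @param n_permutations Number of resampled sets (default 1000; below 100
#'   a warning is issued).
#' @param seed Integer seed for the resampling stream.
#' @return Scalar p-value in (0, 1].
#' @export
gene_permutation_pvalue <- function(fcs, gene_id, n_permutations = 1000,
                                    seed = 1) {
  n_permutations <- check_count(n_permutations, "n_permutations")
  if (n_permutations < 100) {
    warning("n_permutations < 100 gives a coarse p-value resolution",
            call. = FALSE)
  }
  lfc_all <- fcs$log2fc[!is.na(fcs$log2fc)]
  lfc_gene <- fcs$log2fc[fcs$gene_id == gene_id & !is.na(fcs$log2fc)]
  k <- length(lfc_gene)
  if (k < 2L) stop_config("gene '%s' has fewer than 2 detected shRNAs", gene_id)
  obs <- abs(mean(lfc_gene))
  with_seed(seed, {
    perm <- vapply(seq_len(n_permutations), function(i) {
      abs(mean(lfc_all[sample.int(length(lfc_all), k)]))
    }, numeric(1))
    (1 + sum(perm >= obs)) / (1 + n_permutations)
  })
}

#' Full screen analysis: fold changes, trend rule, permutation p, BH FDR
#'
#' Convenience driver chaining [shrna_log2fc()], [call_gene_hits()] and
#' [gene_permutation_pvalue()] per gene, with Benjamini-Hochberg
#' adjustment across genes.
#'
#' @inheritParams shrna_log2fc
#' @inheritParams call_gene_hits
#' @param n_permutations Permutations per gene.
#' @param seed Base seed; per-gene sub-streams are derived from it so the
#'   p-value of a gene does not depend on how many other genes are tested.
#' @return [call_gene_hits()] output with `p_value` and `fdr` columns
#'   appended.
#' @export
analyze_screen <- function(counts, condition, gene_id, pseudocount = 0.5,
                           min_consistent = 5, expected_shrnas = 8,
                           n_permutations = 1000, seed = 1) {
  fcs <- shrna_log2fc(counts, condition, gene_id, pseudocount)
  hits <- call_gene_hits(fcs, min_consistent, expected_shrnas)
  hits$p_value <- vapply(seq_len(nrow(hits)), function(i) {
    gene_permutation_pvalue(fcs, hits$gene_id[i], n_permutations,
                            seed = substream_seed(seed, i))
  }, numeric(1))
  hits$fdr <- bh_fdr(hits$p_value)
  hits
}
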