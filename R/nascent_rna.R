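# Nascent transcription from SLAM-seq T>C-conversion read counts.
#
# Metabolic labelling with 4-thiouridine followed by alkylation leaves
# T>C mismatches in reads derived from nascent transcripts.  Reads with at
# least `min_conversions` (default 2) T>C conversions are counted as
# nascent; reads mapping to different 3'UTR annotations of one gene are
# collapsed; differential nascent expression is then called per gene with
# a negative-binomial score test and Benjamini-Hochberg adjustment.

#' Count nascent and total reads per UTR and sample
#'
#' Splits conversion-stratified read counts into a nascent matrix (reads
#' with `k >= min_conversions` T>C conversions) and a total matrix (all
#' reads).  Two conversions is the conventional threshold: a single
#' conversion is too easily produced by sequencing error or SNPs.
#'
#' @param table Data.frame with columns `utr_id`, `gene_id`, `sample_id`,
#'   `k` (integer conversion count per read, >= 0), `n_reads` (number of
#'   reads with exactly `k` conversions).
#' @param min_conversions Minimum conversions for a read to count as
#'   nascent (default 2).  With 0 the nascent matrix equals the total.
#' @return List of class `nascent_counts`: integer matrices `nascent` and
#'   `total` (UTR x sample, identical dimnames) and the `utr_gene` map.
#' @export
classify_nascent_reads <- function(table, min_conversions = 2) {
  min_conversions <- check_count(min_conversions, "min_conversions", min = 0L)
  need <- c("utr_id", "gene_id", "sample_id", "k", "n_reads")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop_config("conversion table lacks column(s): %s",
                paste(miss, collapse = ", "))
  }
  if (nrow(table) == 0L) {
    m <- matrix(0L, 0, 0)
    return(structure(list(nascent = m, total = m,
                          utr_gene = character(0)),
                     class = "nascent_counts"))
  }
  if (any(table$k < 0)) stop_config("negative conversion count k")
  if (any(table$n_reads < 0)) stop_config("negative read count")
  utr <- factor(table$utr_id)
  smp <- factor(table$sample_id)
  total <- tapply_sum(table$n_reads, utr, smp)
  nasc_rows <- table$k >= min_conversions
  nascent <- tapply_sum(table$n_reads[nasc_rows], utr[nasc_rows],
                        smp[nasc_rows], dims = dimnames(total))
  map <- tapply(as.character(table$gene_id), utr, function(g) unique(g))
  bad <- vapply(map, length, integer(1)) != 1L
  if (any(bad)) {
    stop_config("UTR(s) mapped to more than one gene: %s",
                paste(names(map)[bad], collapse = ", "))
  }
  structure(list(nascent = nascent, total = total,
                 utr_gene = vapply(map, identity, character(1))),
            class = "nascent_counts")
}

# Sum x into a complete (row factor) x (col factor) matrix of doubles.
#' @noRd
tapply_sum <- function(x, rows, cols, dims = NULL) {
  if (is.null(dims)) dims <- list(levels(rows), levels(cols))
  m <- matrix(0, length(dims[[1L]]), length(dims[[2L]]), dimnames = dims)
  if (length(x)) {
    agg <- tapply(x, list(rows, cols), sum, default = 0)
    m[rownames(agg), colnames(agg)] <- agg
  }
  m
}

#' Collapse UTR-level counts to gene level
#'
#' Reads mapping to different UTR annotations of the same gene are summed
#' per sample.  Requires a total UTR-to-gene mapping.
#'
#' @param counts A `nascent_counts` object from [classify_nascent_reads()],
#'   keyed by UTR.
#' @return A `nascent_counts` object keyed by gene.
#' @export
collapse_utrs <- function(counts) {
  stopifnot(inherits(counts, "nascent_counts"))
  utrs <- rownames(counts$nascent)
  if (is.null(utrs) || length(utrs) == 0L) return(counts)
  unmapped <- setdiff(utrs, names(counts$utr_gene))
  if (length(unmapped)) {
    stop_config("UTR(s) without gene mapping: %s",
                paste(unmapped, collapse = ", "))
  }
  gene <- factor(counts$utr_gene[utrs])
  collapse <- function(m) {
    out <- rowsum(m, gene)
    out[order(rownames(out)), , drop = FALSE]
  }
  structure(list(nascent = collapse(counts$nascent),
                 total = collapse(counts$total),
                 utr_gene = stats::setNames(levels(gene), levels(gene))),
            class = "nascent_counts")
}

#' Median-of-ratios size factors
#'
#' Per sample, the median over genes of the ratio of the gene's count to
#' its geometric mean across samples, computed on genes with all-positive
#' counts.  This is the standard depth-and-composition normalization for
#' count matrices.
#'
#' @param m Count matrix, genes x samples.
#' @return Numeric vector of positive size factors, one per sample.
#' @export
size_factors <- function(m) {
  m <- as.matrix(m)
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos)) stop_config("no gene has positive counts in every sample")
  logm <- log(m[pos, , drop = FALSE])
  logmeans <- rowMeans(logm)
  exp(apply(logm - logmeans, 2, stats::median))
}

#' Differential nascent expression by negative-binomial score test
#'
#' Per gene, nascent counts are normalized by median-of-ratios size
#' factors computed on the *total*-count matrix (labelling-efficiency
#' differences would distort factors computed on nascent counts alone).
#' The fold change is `log2((mean treated + 0.5) / (mean control + 0.5))`
#' on normalized means.  Significance comes from a two-sided
#' negative-binomial score test with per-gene moment dispersion estimates
#' shrunk toward a mean-dispersion trend, followed by Benjamini-Hochberg
#' adjustment.  Genes are classed `down` when `fdr <= fdr_cut` and
#' `log2fc <= -fc_cut`, `up` symmetrically, else `unchanged`.
#'
#' @param counts A gene-level `nascent_counts` object (see
#'   [collapse_utrs()]), or a list with `nascent` and `total` matrices.
#' @param condition Character vector over sample columns, `"control"` or
#'   `"treated"`; each condition needs >= 2 replicates.
#' @param fc_cut Absolute log2 fold-change cutoff (default 1).
#' @param fdr_cut FDR cutoff (default 0.01; overlap analyses
#'   conventionally relax this to 0.1).
#' @param prior_df Weight of the dispersion trend in the shrinkage
#'   (default 10 residual-df equivalents).
#' @return Data.frame with one row per gene: `gene_id`, `base_mean`,
#'   `log2fc`, `p_value`, `fdr`, `class`.
#' @export
differential_nascent <- function(counts, condition, fc_cut = 1,
                                 fdr_cut = 0.01, prior_df = 10) {
  check_scalar(fc_cut, "fc_cut", lo = 0)
  check_scalar(fdr_cut, "fdr_cut", lo = 0, hi = 1)
  nasc <- as.matrix(counts$nascent)
  tot <- as.matrix(counts$total)
  if (length(condition) != ncol(nasc)) {
    stop_config("'condition' must label every sample column")
  }
  if (!all(condition %in% c("control", "treated"))) {
    stop_config("'condition' values must be 'control' or 'treated'")
  }
  n_ctl <- sum(condition == "control")
  n_trt <- sum(condition == "treated")
  if (n_ctl < 2L || n_trt < 2L) {
    stop_config("each condition needs >= 2 replicates (control %d, treated %d)",
                n_ctl, n_trt)
  }
  sf <- size_factors(tot)
  norm <- sweep(nasc, 2, sf, "/")
  is_trt <- condition == "treated"
  mu_ctl <- rowMeans(norm[, !is_trt, drop = FALSE])
  mu_trt <- rowMeans(norm[, is_trt, drop = FALSE])
  log2fc <- log2((mu_trt + 0.5) / (mu_ctl + 0.5))
  base_mean <- rowMeans(norm)

  alpha <- shrunk_dispersions(nasc, sf, is_trt, prior_df)
  p <- nb_score_test(nasc, sf, is_trt, alpha)
  fdr <- bh_fdr(p)
  class <- rep("unchanged", nrow(nasc))
  class[fdr <= fdr_cut & log2fc <= -fc_cut] <- "down"
  class[fdr <= fdr_cut & log2fc >= fc_cut] <- "up"
  data.frame(gene_id = rownames(nasc), base_mean = base_mean,
             log2fc = log2fc, p_value = p, fdr = fdr, class = class,
             stringsAsFactors = FALSE, row.names = NULL)
}

# Method-of-moments per-gene NB dispersions, shrunk toward the fitted
# trend alpha(mu) = a0 + a1/mu.  Pooled within-condition variances keep
# real signal out of the dispersion estimate.
#' @noRd
shrunk_dispersions <- function(counts, sf, is_trt, prior_df = 10) {
  norm <- sweep(counts, 2, sf, "/")
  pooled_var <- function(m) {
    v1 <- apply(m[, !is_trt, drop = FALSE], 1, stats::var)
    v2 <- apply(m[, is_trt, drop = FALSE], 1, stats::var)
    d1 <- sum(!is_trt) - 1L
    d2 <- sum(is_trt) - 1L
    (v1 * d1 + v2 * d2) / (d1 + d2)
  }
  mu <- rowMeans(norm)
  s2 <- pooled_var(norm)
  # Var(y/s) ~ mu/s_eff + alpha*mu^2 under NB; use mean 1/s as the
  # effective inverse depth.
  inv_s <- mean(1 / sf)
  raw <- (s2 - mu * inv_s) / mu^2
  raw[!is.finite(raw) | raw < 1e-8] <- 1e-8
  use <- mu > 1 & is.finite(raw)
  if (sum(use) >= 10) {
    tr <- stats::lm.fit(cbind(1, 1 / mu[use]), raw[use])$coefficients
    trend <- tr[1L] + tr[2L] / mu
    trend[!is.finite(trend) | trend < 1e-8] <- 1e-8
  } else {
    trend <- rep(max(stats::median(raw), 1e-8), length(raw))
  }
  n_df <- length(is_trt) - 2L
  alpha <- (n_df * raw + prior_df * trend) / (n_df + prior_df)
  pmax(alpha, 1e-8)
}

# Two-sided NB score test of a condition effect on the log scale.
# Model: y_j ~ NB(mean = s_j * q * exp(beta * x_j), dispersion alpha);
# under H0 beta = 0 with q at its H0 maximum likelihood (the root of
# sum((y - s q)/(1 + alpha s q)) = 0, which also makes the statistic
# exactly antisymmetric under swapping condition labels).  The score
# statistic uses weights w_j = m_j / (1 + alpha * m_j):
#   U = sum x_j (y_j - m_j) / (1 + alpha m_j)
#   Var(U) = (sum_x w)(sum_(1-x) w) / sum w
#' @noRd
nb_score_test <- function(counts, sf, is_trt, alpha) {
  x <- as.numeric(is_trt)
  p <- vapply(seq_len(nrow(counts)), function(i) {
    y <- counts[i, ]
    if (sum(y) == 0) return(1)
    a <- alpha[i]
    score_q <- function(q) sum((y - sf * q) / (1 + a * sf * q))
    q0 <- stats::uniroot(score_q, c(1e-12, max(y / sf) + 1),
                         tol = 1e-12)$root
    if (q0 <= 0) return(1)
    m <- sf * q0
    w <- m / (1 + a * m)
    u <- sum(x * (y - m) / (1 + a * m))
    v <- sum(x * w) * sum((1 - x) * w) / sum(w)
    if (v <= 0) return(1)
    2 * stats::pnorm(-abs(u) / sqrt(v))
  }, numeric(1))
  pmin(p, 1)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with enforced monotonicity,
#' order-preserving on the input indexing.  Thin validating wrapper over
#' the standard step-up procedure.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, elementwise >= the input.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_fdr <- function(p_values) {
  if (!is.numeric(p_values) ||
      any(!is.na(p_values) & (p_values < 0 | p_values > 1))) {
    stop_config("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}
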