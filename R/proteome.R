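# Nascent-proteome (AHA pulse / click-chemistry enrichment) analysis:
# protein-group filter cascade, affected-protein calls by PSM reduction,
# and transcript-protein overlap statistics.

#' Filter nascent-proteome protein groups
#'
#' Applies the quality cascade used for AHA-enriched MaxQuant protein
#' groups, in order:
#' \enumerate{
#'   \item remove records flagged potential contaminant, reverse (decoy),
#'     or identified only by site;
#'   \item remove background proteins detected in the no-AHA negative
#'     control, except those whose mean DMSO PSM count is at least
#'     `background_ratio`-fold (default 10) the background channel;
#'   \item remove proteins with PSM = 0 in one or more DMSO control
#'     replicates (not reliably quantifiable at baseline).
#' }
#'
#' @param records Data.frame with one row per protein group: `protein_id`,
#'   logical flags `potential_contaminant`, `reverse`,
#'   `only_identified_by_site`, `psm_background` (no-AHA channel PSM
#'   count), and per-replicate DMSO PSM columns `psm_dmso_1`,
#'   `psm_dmso_2`, ... (at least one).
#' @param background_ratio Fold threshold rescuing high-abundance proteins
#'   from the background filter (default 10).
#' @return List of class `filter_cascade`: `retained` (protein ids),
#'   `stage_log` (data.frame of stage, n_removed, n_remaining) and the
#'   retained `records`.
#' @examples
#' rec <- data.frame(protein_id = c("P1", "P2"),
#'                   potential_contaminant = c(FALSE, FALSE),
#'                   reverse = c(TRUE, FALSE),
#'                   only_identified_by_site = FALSE,
#'                   psm_background = c(0, 2),
#'                   psm_dmso_1 = c(10, 25), psm_dmso_2 = c(12, 25))
#' filter_protein_groups(rec)  # P1 is a decoy; P2 rescued (25/2 >= 10)
#' @export
filter_protein_groups <- function(records, background_ratio = 10) {
  check_scalar(background_ratio, "background_ratio", lo = 0, strict_lo = TRUE)
  dmso_cols <- grep("^psm_dmso_", names(records), value = TRUE)
  if (nrow(records) == 0L) {
    return(structure(list(retained = character(0),
                          stage_log = data.frame(stage = character(0),
                                                 n_removed = integer(0),
                                                 n_remaining = integer(0)),
                          records = records),
                     class = "filter_cascade"))
  }
  need <- c("protein_id", "potential_contaminant", "reverse",
            "only_identified_by_site", "psm_background")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop_config("protein-group table lacks column(s): %s",
                paste(miss, collapse = ", "))
  }
  if (length(dmso_cols) < 1L) stop_config("need >= 1 psm_dmso_* column")

  cur <- records
  log_rows <- list()
  note <- function(stage, before, after) {
    data.frame(stage = stage, n_removed = before - after,
               n_remaining = after, stringsAsFactors = FALSE)
  }

  flagged <- cur$potential_contaminant | cur$reverse |
    cur$only_identified_by_site
  n0 <- nrow(cur)
  cur <- cur[!flagged, , drop = FALSE]
  log_rows$qc <- note("qc_flags", n0, nrow(cur))

  mean_dmso <- rowMeans(as.matrix(cur[, dmso_cols, drop = FALSE]))
  in_background <- cur$psm_background > 0
  rescued <- in_background & cur$psm_background > 0 &
    (mean_dmso / cur$psm_background) >= background_ratio
  n1 <- nrow(cur)
  cur <- cur[!in_background | rescued, , drop = FALSE]
  log_rows$bg <- note("background", n1, nrow(cur))

  any_zero <- apply(as.matrix(cur[, dmso_cols, drop = FALSE]) == 0, 1, any)
  n2 <- nrow(cur)
  cur <- cur[!any_zero, , drop = FALSE]
  log_rows$zero <- note("dmso_zero", n2, nrow(cur))

  structure(list(retained = as.character(cur$protein_id),
                 stage_log = do.call(rbind, unname(log_rows)),
                 records = cur),
            class = "filter_cascade")
}

#' Call proteins affected by treatment from PSM reduction
#'
#' For every retained protein, the relative PSM reduction is
#' `1 - mean(psm_treated) / mean(psm_dmso)` (arithmetic means over
#' replicates).  A protein is called affected when its reduction meets the
#' cutoff (default 0.75, inclusive: "a reduction of 75% or more") or when
#' it disappears entirely under treatment.  `strict = TRUE` switches to a
#' strict `> cutoff` comparison.
#'
#' @param cascade A [filter_protein_groups()] result.
#' @param records The full protein-group table; must contain the retained
#'   proteins with `psm_dmso_*` and `psm_treated_*` replicate columns.
#' @param reduction_cut Fractional reduction cutoff (default 0.75).
#' @param strict Use strict `>` instead of `>=` at the cutoff.
#' @return Data.frame with one row per retained protein: `protein_id`,
#'   `mean_psm_dmso`, `mean_psm_treated`, `reduction`, `affected`.
#' @export
call_affected <- function(cascade, records, reduction_cut = 0.75,
                          strict = FALSE) {
  stopifnot(inherits(cascade, "filter_cascade"))
  check_scalar(reduction_cut, "reduction_cut", lo = 0, hi = 1)
  dmso_cols <- grep("^psm_dmso_", names(records), value = TRUE)
  trt_cols <- grep("^psm_treated_", names(records), value = TRUE)
  if (!length(trt_cols)) stop_config("need >= 1 psm_treated_* column")
  rec <- records[records$protein_id %in% cascade$retained, , drop = FALSE]
  mean_dmso <- rowMeans(as.matrix(rec[, dmso_cols, drop = FALSE]))
  mean_trt <- rowMeans(as.matrix(rec[, trt_cols, drop = FALSE]))
  reduction <- 1 - mean_trt / mean_dmso
  reduction <- pmin(pmax(reduction, 0), 1)
  affected <- if (strict) reduction > reduction_cut else reduction >= reduction_cut
  affected <- affected | mean_trt == 0
  data.frame(protein_id = as.character(rec$protein_id),
             mean_psm_dmso = mean_dmso, mean_psm_treated = mean_trt,
             reduction = reduction, affected = affected,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Overlap between affected proteins and repressed nascent transcripts
#'
#' Reports the intersection of the two gene sets as a percentage of each
#' set, plus an upper-tail hypergeometric p-value for observing at least
#' the given overlap when sets of these sizes are drawn at random from a
#' universe of `universe_size` genes.  The p-value is supplementary
#' output; the percentages are the primary quantities.
#'
#' @param affected_genes Character vector: genes of affected proteins.
#' @param down_genes Character vector: downregulated nascent-transcript
#'   genes.
#' @param universe_size Number of genes in the common identifier space;
#'   must be at least `|union|`.
#' @return List: `n_intersection`, `pct_of_proteomics`
#'   (100 * |A intersect B| / |A|), `pct_of_slamseq`
#'   (100 * |A intersect B| / |B|), `p_value`.
#' @examples
#' overlap_stats(letters[1:10], letters[6:15], universe_size = 100)
#' @export
overlap_stats <- function(affected_genes, down_genes, universe_size) {
  universe_size <- check_count(universe_size, "universe_size", min = 0L)
  a <- unique(as.character(affected_genes))
  b <- unique(as.character(down_genes))
  if (universe_size < length(union(a, b))) {
    stop_config("universe_size %d smaller than |union| = %d",
                universe_size, length(union(a, b)))
  }
  n_int <- length(intersect(a, b))
  pct_a <- if (length(a)) 100 * n_int / length(a) else 0
  pct_b <- if (length(b)) 100 * n_int / length(b) else 0
  # P(X >= n_int), X ~ Hypergeometric(|A| draws from |B| successes in N)
  p <- stats::phyper(n_int - 1, length(b), universe_size - length(b),
                     length(a), lower.tail = FALSE)
  list(n_intersection = n_int, pct_of_proteomics = pct_a,
       pct_of_slamseq = pct_b, p_value = p)
}
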