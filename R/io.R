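# Table readers/writers for the pipeline's TSV schemas, a MaxQuant
# proteinGroups reader, and the umbrella pipeline driver with a run
# manifest.  All tables are UTF-8, tab-separated, '.' decimal.

# Column contracts per schema: `required` columns with types, and an
# optional `pattern` for families of per-sample columns.
.schemas <- list(
  dose_response = list(
    required = c(drug_id = "character", dose_um = "numeric",
                 replicate = "integer", pct_live = "numeric")
  ),
  combination = list(
    required = c(dose_a_um = "numeric", dose_b_um = "numeric",
                 replicate = "integer", pct_live = "numeric")
  ),
  slamseq = list(
    required = c(utr_id = "character", gene_id = "character",
                 sample_id = "character", condition = "character",
                 replicate = "integer", k = "count", n_reads = "count")
  ),
  protein_groups = list(
    required = c(protein_id = "character", potential_contaminant = "logical",
                 reverse = "logical", only_identified_by_site = "logical",
                 psm_background = "count"),
    pattern = c("^psm_dmso_[0-9]+$" = "count",
                "^psm_treated_[0-9]+$" = "count")
  ),
  screen_counts = list(
    required = c(shrna_id = "character", gene_id = "character"),
    pattern = c("^(control|treated)_[0-9]+$" = "count")
  ),
  gene_map = list(
    required = c(protein_id = "character", gene_id = "character")
  )
)

#' Names of the table schemas understood by [read_table()]
#' @return Character vector of schema names.
#' @export
table_schemas <- function() names(.schemas)

#' Read and validate a pipeline table
#'
#' Reads a UTF-8, tab-separated table and validates it against one of the
#' named column contracts (see [table_schemas()]).  Numeric columns are
#' parsed with '.' as the decimal mark; files with comma decimals or other
#' non-numeric content in numeric columns are rejected with the offending
#' row number, as are negative values in count columns.
#'
#' @param path File path.
#' @param schema_name One of [table_schemas()].
#' @return Validated data.frame.
#' @export
read_table <- function(path, schema_name) {
  if (!schema_name %in% names(.schemas)) {
    stop_config("unknown schema '%s'; known: %s", schema_name,
                paste(names(.schemas), collapse = ", "))
  }
  if (!file.exists(path)) stop_config("file not found: %s", path)
  schema <- .schemas[[schema_name]]
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, fileEncoding = "UTF-8")
  miss <- setdiff(names(schema$required), names(raw))
  if (length(miss)) {
    stop_config("schema '%s': missing column(s) %s in %s", schema_name,
                paste(miss, collapse = ", "), path)
  }
  types <- schema$required
  for (pat in names(schema$pattern)) {
    hit <- grep(pat, names(raw), value = TRUE)
    if (!length(hit)) {
      stop_config("schema '%s': no column matching %s in %s", schema_name,
                  pat, path)
    }
    types[hit] <- schema$pattern[[pat]]
  }
  out <- raw
  for (col in names(types)) {
    ty <- types[[col]]
    v <- raw[[col]]
    if (ty %in% c("numeric", "integer", "count")) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num) & !is.na(v) & nzchar(v))
      if (length(bad)) {
        stop_config("schema '%s': non-numeric value '%s' in column '%s', row %d",
                    schema_name, v[bad[1L]], col, bad[1L])
      }
      if (ty %in% c("integer", "count")) {
        notint <- which(is.finite(num) & num != round(num))
        if (length(notint)) {
          stop_config("schema '%s': non-integer value in column '%s', row %d",
                      schema_name, col, notint[1L])
        }
        if (ty == "count") {
          neg <- which(num < 0)
          if (length(neg)) {
            stop_config("schema '%s': negative count in column '%s', row %d",
                        schema_name, col, neg[1L])
          }
        }
        num <- as.integer(round(num))
      }
      out[[col]] <- num
    } else if (ty == "logical") {
      lg <- v %in% c("TRUE", "true", "1", "+")
      bad <- which(!v %in% c("TRUE", "true", "1", "+",
                             "FALSE", "false", "0", ""))
      if (length(bad)) {
        stop_config("schema '%s': non-logical value '%s' in column '%s', row %d",
                    schema_name, v[bad[1L]], col, bad[1L])
      }
      out[[col]] <- lg
    }
  }
  out
}

#' Write a pipeline table
#'
#' UTF-8, tab-separated, '.' decimal, no quoting, no row names.
#'
#' @param x Data.frame.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a MaxQuant-style proteinGroups table
#'
#' Parses the tab-separated `proteinGroups.txt` dialect: QC flags are
#' encoded as '+' in the columns `Potential contaminant`, `Reverse` and
#' `Only identified by site`; per-sample PSM counts are read from
#' `MS/MS count <sample>` columns.  The result uses the native
#' protein-group schema consumed by [filter_protein_groups()].
#'
#' @param path Path to the proteinGroups file.
#' @param dmso_samples,treated_samples Sample names as they appear after
#'   `MS/MS count ` in the header, in replicate order.
#' @param background_sample Sample name of the no-AHA control channel.
#' @param id_column Column holding protein identifiers (default
#'   `"Protein IDs"`).
#' @return Data.frame in the native protein-group schema.
#' @export
read_maxquant_protein_groups <- function(path, dmso_samples, treated_samples,
                                         background_sample,
                                         id_column = "Protein IDs") {
  raw <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character", fileEncoding = "UTF-8")
  need <- c(id_column, "Potential contaminant", "Reverse",
            "Only identified by site")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop_config("proteinGroups file lacks column(s): %s",
                paste(miss, collapse = ", "))
  }
  psm_col <- function(sample) {
    col <- paste0("MS/MS count ", sample)
    if (!col %in% names(raw)) {
      stop_config("proteinGroups file lacks column '%s'", col)
    }
    n <- suppressWarnings(as.numeric(raw[[col]]))
    n[is.na(n)] <- 0
    as.integer(round(n))
  }
  out <- data.frame(
    protein_id = raw[[id_column]],
    potential_contaminant = raw[["Potential contaminant"]] == "+",
    reverse = raw[["Reverse"]] == "+",
    only_identified_by_site = raw[["Only identified by site"]] == "+",
    stringsAsFactors = FALSE
  )
  for (j in seq_along(dmso_samples)) {
    out[[sprintf("psm_dmso_%d", j)]] <- psm_col(dmso_samples[j])
  }
  for (j in seq_along(treated_samples)) {
    out[[sprintf("psm_treated_%d", j)]] <- psm_col(treated_samples[j])
  }
  out$psm_background <- psm_col(background_sample)
  out
}

#' Default pipeline configuration
#'
#' All stage parameters with their conventional defaults: trend-rule and
#' fold-change settings for the screen, clipping and CI bands for the
#' synergy stage, conversion threshold and cutoffs for SLAM-seq, and the
#' filter-cascade settings for the proteome stage.
#'
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param out_dir Output directory for stage tables and the manifest.
#' @return Nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, out_dir = tempfile("azasynergy_run_")) {
  structure(list(
    seed = check_count(seed, "seed", min = 0L),
    out_dir = out_dir,
    screen = list(pseudocount = 0.5, min_consistent = 5,
                  expected_shrnas = 8, n_permutations = 200),
    synergy = list(eps = 1e-3),
    slamseq = list(min_conversions = 2, fc_cut = 1, fdr_cut = 0.01),
    proteome = list(reduction_cut = 0.75, background_ratio = 10,
                    strict = FALSE),
    overlap = list(fdr_cut = 0.1),
    sim = list(screen = list(n_genes = 120),
               slamseq = list(n_genes = 150),
               proteome = list(n_proteins = 400),
               dose = list(m = 1.2, Dm = 1, doses = c(0.25, 0.5, 1, 2, 4),
                           noise_sd = 2, target_ci = 0.75))
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the [pipeline_config()] defaults;
#' unknown keys are rejected.
#'
#' @param path YAML file.
#' @param out_dir Optional output-directory override.
#' @return `pipeline_config` list.
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  user <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  merge_into <- function(base, upd, prefix = "") {
    for (k in names(upd)) {
      if (!k %in% names(base)) {
        stop_config("unknown configuration key '%s%s'", prefix, k)
      }
      base[[k]] <- if (is.list(base[[k]]) && is.list(upd[[k]])) {
        merge_into(base[[k]], upd[[k]], paste0(prefix, k, "."))
      } else {
        upd[[k]]
      }
    }
    base
  }
  cfg <- merge_into(unclass(cfg), user)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  structure(cfg, class = "pipeline_config")
}

#' Run the full synthetic pipeline
#'
#' Executes the stages in dependency order: simulate all four input types,
#' then screen hit calling, synergy scoring, nascent-RNA differential
#' calling, the proteome filter cascade with affected-protein calls, and
#' finally the transcript-protein overlap.  Every stage table is written
#' to `config$out_dir` and a run manifest (tool version, configuration
#' hash, per-file checksums, seed registry, per-stage row counts) is
#' emitted alongside.  Identical configuration and seed reproduce
#' identical outputs byte for byte.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly; also written as `manifest.yaml`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- list(screen = substream_seed(config$seed, 101),
                dose = substream_seed(config$seed, 102),
                slamseq = substream_seed(config$seed, 103),
                proteome = substream_seed(config$seed, 104))
  rows <- list()
  paths <- character(0)
  emit <- function(x, name) {
    p <- file.path(config$out_dir, paste0(name, ".tsv"))
    write_table(x, p)
    paths[[name]] <<- p
    rows[[name]] <<- nrow(x)
  }

  # -- screen ---------------------------------------------------------
  sc_args <- config$sim$screen
  sc_args$seed <- seeds$screen
  sim <- gen_screen_counts(do.call(screen_sim_config, sc_args))
  screen_tab <- data.frame(shrna_id = rownames(sim$counts),
                           gene_id = sim$gene_id, sim$counts,
                           stringsAsFactors = FALSE, row.names = NULL)
  emit(screen_tab, "screen_counts")
  hits <- analyze_screen(sim$counts, sim$condition, sim$gene_id,
                         pseudocount = config$screen$pseudocount,
                         min_consistent = config$screen$min_consistent,
                         expected_shrnas = config$screen$expected_shrnas,
                         n_permutations = config$screen$n_permutations,
                         seed = seeds$screen)
  emit(hits, "screen_hits")

  # -- synergy --------------------------------------------------------
  dz <- config$sim$dose
  single_a <- gen_dose_response(dz$m, dz$Dm, dz$doses, noise_sd = dz$noise_sd,
                                seed = seeds$dose, drug_id = "AZA")
  single_b <- gen_dose_response(dz$m, dz$Dm * 2, dz$doses,
                                noise_sd = dz$noise_sd,
                                seed = substream_seed(seeds$dose, 2),
                                drug_id = "C646")
  emit(rbind(single_a, single_b), "dose_response")
  fit_a <- fit_single_table(single_a, eps = config$synergy$eps)
  fit_b <- fit_single_table(single_b, eps = config$synergy$eps)
  pairs <- expand.grid(dose_a_um = dz$doses[-1], dose_b_um = dz$Dm * 2)
  combo <- gen_combination(fit_a, fit_b, pairs, target_ci = dz$target_ci)
  combo <- combo[combo$solved, , drop = FALSE]
  combo_reps <- data.frame(dose_a_um = combo$dose_a_um,
                           dose_b_um = combo$dose_b_um, replicate = 1L,
                           pct_live = combo$pct_live,
                           stringsAsFactors = FALSE)
  emit(combo_reps, "combination")
  ci <- score_combinations(combo_reps, fit_a, fit_b,
                           eps = config$synergy$eps)
  emit(ci, "combination_index")

  # -- SLAM-seq -------------------------------------------------------
  sl_args <- config$sim$slamseq
  sl_args$seed <- seeds$slamseq
  slam <- gen_slamseq_counts(do.call(slam_sim_config, sl_args))
  emit(slam$table, "slamseq_counts")
  nc <- classify_nascent_reads(slam$table,
                               min_conversions = config$slamseq$min_conversions)
  gene_counts <- collapse_utrs(nc)
  cond <- sample_conditions(slam$table, colnames(gene_counts$nascent))
  de <- differential_nascent(gene_counts, cond,
                             fc_cut = config$slamseq$fc_cut,
                             fdr_cut = config$slamseq$fdr_cut)
  emit(de, "nascent_de")

  # -- proteome -------------------------------------------------------
  pr_args <- config$sim$proteome
  pr_args$seed <- seeds$proteome
  prot <- gen_protein_groups(do.call(proteome_sim_config, pr_args))
  # place proteins on the SLAM-seq gene universe so the overlap stage
  # compares like with like (proteins cycle through the gene space)
  slam_genes <- sort(unique(slam$truth$gene_id))
  prot$records$gene_id <- slam_genes[
    (seq_len(nrow(prot$records)) - 1L) %% length(slam_genes) + 1L]
  emit(prot$records, "protein_groups")
  cascade <- filter_protein_groups(prot$records,
                                   background_ratio =
                                     config$proteome$background_ratio)
  calls <- call_affected(cascade, prot$records,
                         reduction_cut = config$proteome$reduction_cut,
                         strict = config$proteome$strict)
  emit(cascade$stage_log, "proteome_filter_log")
  emit(calls, "proteome_affected")

  # -- overlap --------------------------------------------------------
  gene_of <- stats::setNames(prot$records$gene_id, prot$records$protein_id)
  affected_genes <- unname(gene_of[calls$protein_id[calls$affected]])
  down_genes <- de$gene_id[de$fdr <= config$overlap$fdr_cut &
                             de$log2fc <= -config$slamseq$fc_cut]
  universe <- length(unique(c(prot$records$gene_id, de$gene_id)))
  affected_genes <- unique(affected_genes)
  ov <- overlap_stats(affected_genes, down_genes, universe)
  emit(data.frame(n_intersection = ov$n_intersection,
                  pct_of_proteomics = ov$pct_of_proteomics,
                  pct_of_slamseq = ov$pct_of_slamseq,
                  p_value = ov$p_value), "overlap")

  manifest <- list(
    tool = "azasynergy",
    version = as.character(utils::packageVersion("azasynergy")),
    config_hash = hash_object(unclass(config)),
    seed = config$seed,
    seed_registry = seeds,
    row_counts = rows,
    checksums = as.list(tools::md5sum(unlist(paths)))
  )
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  invisible(manifest)
}

# Fit a median-effect model from a single-agent dose_response table.
#' @noRd
fit_single_table <- function(tab, eps = 1e-3) {
  fa <- viability_to_fa(tab$pct_live, 100, eps = eps)
  fit_median_effect(tab$dose_um, fa, drug_id = tab$drug_id[1L])
}

#' @noRd
sample_conditions <- function(table, sample_ids) {
  m <- unique(table[, c("sample_id", "condition")])
  stats::setNames(m$condition, m$sample_id)[sample_ids]
}

# md5 of the YAML serialization, via a temporary file.
#' @noRd
hash_object <- function(x) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(x, tmp)
  unname(tools::md5sum(tmp))
}
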