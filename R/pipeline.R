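# End-to-end orchestration: simulate/load -> filter -> fit -> call ->
# classify -> permutation FDR, with a run directory of TSV results and a
# JSON summary.

#' Build a run configuration
#'
#' @param counts Path to a counts TSV, or NULL to simulate.
#' @param simulate Named list of [sim_cohort_config()] arguments used when
#'   `counts` is NULL.
#' @param bias_table Optional path to a bias-filter TSV
#'   ([read_bias_table()]).
#' @param out_dir Output directory for result tables.
#' @param p_adj_threshold,min_abs_dlambda,min_abs_log2fc Calling
#'   thresholds.
#' @param n_boot Bootstrap resamples. Default 5000.
#' @param n_perm FDR permutations. Default 100.
#' @param fdr_grid |delta lambda| thresholds for the FDR curve.
#' @param seed Integer seed governing every random stage.
#' @return A `run_config` list.
#' @export
run_config <- function(counts = NULL, simulate = list(), bias_table = NULL,
                       out_dir = tempfile("asdecay_run_"),
                       p_adj_threshold = 0.05, min_abs_dlambda = 0.06,
                       min_abs_log2fc = 1.0, n_boot = 5000L, n_perm = 100L,
                       fdr_grid = seq(0, 0.2, by = 0.01), seed = 1L) {
  assert_that(p_adj_threshold > 0 && min_abs_dlambda > 0 &&
                min_abs_log2fc > 0, "thresholds must be positive")
  assert_that(length(fdr_grid) >= 1, "fdr_grid must be non-empty")
  structure(list(counts = counts, simulate = simulate,
                 bias_table = bias_table, out_dir = out_dir,
                 p_adj_threshold = p_adj_threshold,
                 min_abs_dlambda = min_abs_dlambda,
                 min_abs_log2fc = min_abs_log2fc,
                 n_boot = as.integer(n_boot), n_perm = as.integer(n_perm),
                 fdr_grid = fdr_grid, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [run_config()]; the `simulate`
#' section is passed to [sim_cohort_config()]. Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @param overrides Named list of values taking precedence over the file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path, overrides = list()) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(raw), known)
  assert_that(length(bad) == 0,
              paste0("unknown config key(s): ", paste(bad, collapse = ", ")))
  args <- modifyList(raw, overrides)
  if (!is.null(args$fdr_grid)) args$fdr_grid <- as.numeric(args$fdr_grid)
  do.call(run_config, args)
}

log_line <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " ", ...)
  writeLines(msg, con)
  inform(paste0("[asdecay] ", ...))
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load, SNP bias filtering, the read-sufficiency
#' filter, decay and abundance fitting with bootstrap, replicate-concordant
#' ASD/ASA calling, joint classification, and the permutation FDR curve.
#' Identical configuration and seed produce byte-identical result tables.
#'
#' @param config A `run_config` ([run_config()] / [read_run_config()]).
#' @return The output directory path, invisibly; result tables are
#'   `counts.tsv` (when simulated, plus `truth.tsv`), `bias_filter.tsv`
#'   (when a bias table was given), `gene_filter.tsv`, `decay_fits.tsv`,
#'   `asa_fits.tsv`, `asd_calls.tsv`, `asa_calls.tsv`, `decisions.tsv`,
#'   `fdr.tsv`, `summary.json` and `run.log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  log_con <- file(out("run.log"), open = "wt")
  on.exit(close(log_con))
  log_line(log_con, "asdecay ", as.character(utils::packageVersion("asdecay")),
           "; seed=", config$seed)

  if (is.null(config$counts)) {
    sim_args <- modifyList(list(seed = config$seed), config$simulate)
    sim <- simulate_cohort(do.call(sim_cohort_config, sim_args))
    counts <- sim$counts
    write_allelic_counts(counts, out("counts.tsv"))
    readr::write_tsv(sim$truth, out("truth.tsv"))
    log_line(log_con, "simulated cohort: ", nrow(sim$truth), " genes")
  } else {
    counts <- read_allelic_counts(config$counts)
    log_line(log_con, "loaded counts: ", config$counts, " md5=",
             unname(tools::md5sum(config$counts)))
  }

  remove_snps <- character(0)
  if (!is.null(config$bias_table)) {
    bias <- filter_biased_snps(read_bias_table(config$bias_table),
                               alpha = config$p_adj_threshold)
    remove_snps <- attr(bias, "removed")
    readr::write_tsv(bias, out("bias_filter.tsv"))
    log_line(log_con, "bias filter removed ", length(remove_snps), " SNPs")
  }

  filtered <- apply_filters(counts, remove_snps = remove_snps)
  gene_filter <- attr(filtered, "gene_filter")
  readr::write_tsv(gene_filter, out("gene_filter.tsv"))
  log_line(log_con, sum(gene_filter$retained), "/", nrow(gene_filter),
           " genes pass the sufficiency filter")
  assert_that(nrow(filtered) > 0, "no genes pass the sufficiency filter")

  fits <- fit_allelic_decay(filtered, n_boot = config$n_boot,
                            seed = config$seed)
  readr::write_tsv(fits, out("decay_fits.tsv"))
  asa_fits <- fit_allelic_abundance(filtered, n_boot = config$n_boot,
                                    seed = config$seed)
  readr::write_tsv(asa_fits, out("asa_fits.tsv"))
  log_line(log_con, "fitted ", dplyr::n_distinct(fits$gene_id), " genes")

  asd <- call_asd(fits, config$p_adj_threshold, config$min_abs_dlambda)
  asa <- call_asa(asa_fits, config$p_adj_threshold, config$min_abs_log2fc)
  readr::write_tsv(asd, out("asd_calls.tsv"))
  readr::write_tsv(asa, out("asa_calls.tsv"))
  decisions <- classify_joint(asd, asa)
  readr::write_tsv(decisions, out("decisions.tsv"))

  fdr <- permutation_fdr(fits, grid = config$fdr_grid,
                         n_perm = config$n_perm, seed = config$seed,
                         p_adj_threshold = config$p_adj_threshold)
  readr::write_tsv(fdr, out("fdr.tsv"))
  log_line(log_con, "ASD calls: ", sum(asd$asd_significant),
           "; ASA calls: ", sum(asa$asa_significant))

  summarize_run(config$out_dir, config = config)
  invisible(config$out_dir)
}

#' Summarise a completed run directory
#'
#' @param run_dir Directory produced by [run_pipeline()].
#' @param config Optional `run_config` used for threshold lookup; defaults
#'   to the standard thresholds when absent.
#' @return The summary as a list (also written to `summary.json` and
#'   echoed as a text report to `summary.txt`).
#' @export
summarize_run <- function(run_dir, config = NULL) {
  need <- c("decisions.tsv", "fdr.tsv", "decay_fits.tsv")
  missing <- need[!file.exists(file.path(run_dir, need))]
  assert_that(length(missing) == 0,
              paste0("incomplete run: missing ", paste(missing, collapse = ", ")))
  decisions <- readr::read_tsv(file.path(run_dir, "decisions.tsv"),
                               show_col_types = FALSE)
  fdr <- readr::read_tsv(file.path(run_dir, "fdr.tsv"),
                         show_col_types = FALSE)
  min_dl <- if (is.null(config)) 0.06 else config$min_abs_dlambda
  at <- which.min(abs(fdr$threshold - min_dl))
  n_asd <- sum(decisions$asd_significant)
  summary <- list(
    n_genes = nrow(decisions),
    n_asd = n_asd,
    n_asa = sum(decisions$asa_significant),
    n_both = sum(decisions$category == "both"),
    n_asd_only = sum(decisions$category == "ASD_only"),
    n_asa_only = sum(decisions$category == "ASA_only"),
    compensatory_fraction = if (n_asd > 0) {
      sum(decisions$compensatory) / n_asd
    } else NA,
    fdr_threshold = fdr$threshold[at],
    fdr_at_threshold = fdr$fdr[at]
  )
  jsonlite::write_json(summary, file.path(run_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report <- c(
    "asdecay run summary",
    sprintf("genes analysed: %d", summary$n_genes),
    sprintf("ASD calls: %d  ASA calls: %d  both: %d",
            summary$n_asd, summary$n_asa, summary$n_both),
    sprintf("compensatory fraction of ASD genes: %s",
            format(summary$compensatory_fraction)),
    sprintf("permutation FDR at |delta lambda| > %.3g: %s",
            summary$fdr_threshold, format(summary$fdr_at_threshold))
  )
  writeLines(report, file.path(run_dir, "summary.txt"))
  invisible(summary)
}
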