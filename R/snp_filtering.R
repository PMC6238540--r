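# SNP-locus bias filters and the gene/SNP read-sufficiency filter applied
# before model fitting.

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Classic conditional exact test: with margins fixed, the first cell is
#' hypergeometric; the two-sided p-value sums the probabilities of all
#' tables whose probability does not exceed the observed one. Ties are
#' resolved with a relative tolerance of 1e-12 on the observed probability.
#'
#' @param a,b,c,d Cell counts (row 1: a, b; row 2: c, d). Vectorised.
#' @return Two-sided p-value(s) in (0, 1].
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  assert_that(is_count_vector(c(a, b, c, d)),
              "cell counts must be non-negative integers")
  n <- length(a)
  assert_that(all(lengths(list(b, c, d)) == n), "cell vectors must align")
  tot <- a + b + c + d
  assert_that(all(tot > 0), "table must have at least one positive margin")
  vapply(seq_len(n), function(i) {
    r1 <- a[i] + b[i]
    k <- a[i] + c[i]          # first-column margin
    lo <- max(0L, k - (c[i] + d[i]))
    hi <- min(r1, k)
    support <- lo:hi
    probs <- dhyper(support, r1, c[i] + d[i], k)
    p_obs <- probs[match(a[i], support)]
    min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
  }, numeric(1))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values, capped at 1 and monotone in rank order.
#'
#' @param p Raw p-values in \[0, 1\].
#' @return Adjusted p-values, same order as input.
#' @export
adjust_pvalues_bh <- function(p) {
  assert_that(is.numeric(p) && all(is.finite(p)) && all(p >= 0 & p <= 1),
              "p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Flag and remove SNP loci with allelic mapping or assignment bias
#'
#' Each SNP is tested in up to two contexts: parental strains vs mock-hybrid
#' alleles (`"parental_mock"`), and uniquely-mapped vs all reads
#' (`"unique_multi"`). Raw Fisher p-values are BH-adjusted separately per
#' context (separate hypothesis families); a SNP is removed when flagged in
#' either context.
#'
#' @param records Tibble with columns snp_id, ctx, a, b, c, d (see
#'   [read_bias_table()]).
#' @param alpha Adjusted-p threshold for flagging. Default 0.05.
#' @return The records with p_raw, p_adj and flagged columns; attributes
#'   `"retained"` and `"removed"` carry the SNP id sets, and `"reasons"` a
#'   per-removed-SNP tibble of flagging contexts.
#' @export
filter_biased_snps <- function(records, alpha = 0.05) {
  if (nrow(records) == 0) {
    warn("filter_biased_snps: empty record list")
    out <- mutate(records, p_raw = numeric(0), p_adj = numeric(0),
                  flagged = logical(0))
    attr(out, "retained") <- character(0)
    attr(out, "removed") <- character(0)
    return(out)
  }
  out <- records |>
    mutate(p_raw = fisher_exact_2x2(.data$a, .data$b, .data$c, .data$d)) |>
    group_by(.data$ctx) |>
    mutate(p_adj = adjust_pvalues_bh(.data$p_raw)) |>
    ungroup() |>
    mutate(flagged = .data$p_adj < alpha)
  removed <- unique(out$snp_id[out$flagged])
  attr(out, "retained") <- setdiff(unique(out$snp_id), removed)
  attr(out, "removed") <- removed
  attr(out, "reasons") <- out |>
    filter(.data$flagged) |>
    select("snp_id", reason = "ctx", "p_adj")
  out
}

#' Read-sufficiency filter for genes and SNP loci
#'
#' A SNP locus passes in a replicate when the two alleles together provide
#' at least `min_tp_total` reads at every timepoint and each allele at least
#' `min_allele_total` reads summed over the timepoints. A gene is retained
#' when at least `min_snps` of its SNPs pass in every replicate.
#'
#' @param counts Counts tibble ([counts_schema()]).
#' @param min_snps Minimum number of passing SNPs per gene. Default 5.
#' @param min_tp_total Minimum two-allele total per timepoint. Default 10.
#' @param min_allele_total Minimum per-allele sum across timepoints,
#'   enforced per replicate. Default 15.
#' @return Tibble (gene_id, n_snps, n_passing_snps, retained); attribute
#'   `"snp_flags"` holds the per-(gene, snp, replicate) pass flags.
#' @export
sufficiency_filter <- function(counts, min_snps = 5, min_tp_total = 10,
                               min_allele_total = 15) {
  validate_counts(counts)
  grid <- counts |>
    dplyr::distinct(.data$gene_id, .data$snp_id, .data$replicate, .data$time_h)
  full <- counts |>
    group_by(.data$gene_id) |>
    summarise(complete = {
      tp <- unique(.data$time_h)
      reps <- unique(.data$replicate)
      cells <- dplyr::n_distinct(paste(.data$snp_id, .data$replicate, .data$time_h))
      cells == dplyr::n_distinct(.data$snp_id) * length(tp) * length(reps)
    })
  assert_that(all(full$complete),
              paste0("missing timepoint cells for gene(s): ",
                     paste(head(full$gene_id[!full$complete], 5), collapse = ", ")))

  snp_rep <- counts |>
    group_by(.data$gene_id, .data$snp_id, .data$replicate) |>
    summarise(pass = all(.data$n_allele1 + .data$n_allele2 >= min_tp_total) &&
                sum(.data$n_allele1) >= min_allele_total &&
                sum(.data$n_allele2) >= min_allele_total,
              .groups = "drop")
  snp_all <- snp_rep |>
    group_by(.data$gene_id, .data$snp_id) |>
    summarise(pass_all_reps = all(.data$pass), .groups = "drop")
  gene <- snp_all |>
    group_by(.data$gene_id) |>
    summarise(n_snps = dplyr::n(),
              n_passing_snps = sum(.data$pass_all_reps), .groups = "drop") |>
    mutate(retained = .data$n_passing_snps >= min_snps)
  attr(gene, "snp_flags") <- snp_rep
  attr(gene, "snp_pass") <- snp_all
  gene
}

#' Subset a counts table to sufficient SNPs of retained genes
#'
#' Convenience wrapper combining bias removal (optional) and
#' [sufficiency_filter()], returning the counts the decay model is fit on:
#' retained genes only, restricted to their passing SNP loci.
#'
#' @param counts Counts tibble.
#' @param remove_snps Character vector of SNP ids to drop first (e.g. from
#'   [filter_biased_snps()]).
#' @inheritParams sufficiency_filter
#' @return Filtered counts tibble; attribute `"gene_filter"` carries the
#'   per-gene summary.
#' @export
apply_filters <- function(counts, remove_snps = character(0), min_snps = 5,
                          min_tp_total = 10, min_allele_total = 15) {
  kept <- filter(counts, !.data$snp_id %in% remove_snps)
  summary_tbl <- sufficiency_filter(kept, min_snps, min_tp_total,
                                    min_allele_total)
  snp_pass <- attr(summary_tbl, "snp_pass")
  ok_genes <- summary_tbl$gene_id[summary_tbl$retained]
  out <- kept |>
    inner_join(filter(snp_pass, .data$pass_all_reps),
               by = c("gene_id", "snp_id")) |>
    filter(.data$gene_id %in% ok_genes) |>
    select(-"pass_all_reps")
  attr(out, "gene_filter") <- summary_tbl
  out
}
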