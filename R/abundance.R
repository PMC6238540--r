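# Steady-state allele-specific abundance (ASA) calling, joint ASD/ASA
# classification, and the targeted-validation decay formula.

#' Log2 allelic fold change
#'
#' `log2(n1 / n2)`, with a pseudocount added to both totals only when
#' either total is zero.
#'
#' @param n1_total,n2_total Allelic read totals (non-negative, vectorised).
#' @param pseudocount Continuity value used only for zero totals. Default 0.5.
#' @param strict Error when both totals are zero (default); otherwise NA.
#' @return Log2 fold change(s), allele 1 over allele 2.
#' @export
log2_allelic_fc <- function(n1_total, n2_total, pseudocount = 0.5,
                            strict = TRUE) {
  assert_that(all(n1_total >= 0) && all(n2_total >= 0),
              "totals must be non-negative")
  both_zero <- n1_total == 0 & n2_total == 0
  if (strict) assert_that(!any(both_zero), "both allelic totals are zero")
  delta <- ifelse(n1_total == 0 | n2_total == 0, pseudocount, 0)
  out <- log2((n1_total + delta) / (n2_total + delta))
  out[both_zero] <- NA_real_
  out
}

#' Fit allele-specific abundance at steady state
#'
#' Computes the per-gene log2 allelic fold change of the summed 0 h counts
#' and its SNP-bootstrap distribution (statistic `log2fc_t0`: counts are
#' summed across resampled SNP loci before forming the ratio), separately
#' per replicate, with BH adjustment across genes within each replicate.
#'
#' @inheritParams fit_allelic_decay
#' @return An `asa_fits` tibble: gene_id, replicate, n_snps, log2fc,
#'   boot_mean, boot_sd, z, p_raw, p_adj.
#' @export
fit_allelic_abundance <- function(counts, n_boot = 5000L, seed = 1L) {
  out <- fit_allelic_stat(counts, "log2fc_t0", n_boot, seed) |>
    mutate(log2fc = .data$estimate) |>
    select("gene_id", "replicate", "n_snps", "log2fc", "boot_mean",
           "boot_sd", "z", "p_raw", "p_adj", "n_boot", "n_dropped")
  class(out) <- c("asa_fits", class(out))
  attr(out, "seed") <- seed
  out
}

#' Call allele-specific abundance (ASA) per gene
#'
#' Significant when every replicate shows adjusted p below
#' `p_adj_threshold` and |log2 fold change| above `min_abs_log2fc`
#' (twofold), with one sign across replicates.
#'
#' @param fits An `asa_fits` tibble from [fit_allelic_abundance()].
#' @param p_adj_threshold Adjusted-p threshold. Default 0.05.
#' @param min_abs_log2fc Minimum |log2FC|. Default 1 (twofold).
#' @return An `asa_calls` tibble: gene_id, n_reps, log2fc (mean of
#'   replicate estimates), max_p_adj, min_abs_log2fc, sign_concordant,
#'   asa_significant, direction (`allele1_higher` / `allele2_higher` /
#'   `none`).
#' @export
call_asa <- function(fits, p_adj_threshold = 0.05, min_abs_log2fc = 1.0) {
  n_reps <- fits |> count(.data$gene_id)
  assert_that(all(n_reps$n >= 2), "call_asa needs >= 2 replicates per gene")
  out <- fits |>
    group_by(.data$gene_id) |>
    summarise(
      n_reps = dplyr::n(),
      max_p_adj = max(.data$p_adj),
      min_abs_log2fc = min(abs(.data$log2fc)),
      sign_concordant = dplyr::n_distinct(sign(.data$log2fc)) == 1 &&
        all(sign(.data$log2fc) != 0),
      log2fc = mean(.data$log2fc),
      .groups = "drop"
    ) |>
    mutate(
      asa_significant = .data$max_p_adj < p_adj_threshold &
        .data$min_abs_log2fc > .env$min_abs_log2fc &
        .data$sign_concordant,
      direction = dplyr::case_when(
        !.data$asa_significant ~ "none",
        .data$log2fc > 0 ~ "allele1_higher",
        TRUE ~ "allele2_higher"
      )
    )
  class(out) <- c("asa_calls", class(out))
  attr(out, "thresholds") <- c(p_adj = p_adj_threshold,
                               min_abs_log2fc = min_abs_log2fc)
  out
}

#' Classify genes jointly by decay and abundance divergence
#'
#' @param asd_calls An `asd_calls` tibble ([call_asd()]).
#' @param asa_calls An `asa_calls` tibble ([call_asa()]) over the same gene
#'   universe.
#' @return A `gene_decisions` tibble: gene_id, asd_significant,
#'   asa_significant, category (`ASD_only` / `ASA_only` / `both` /
#'   `neither`), asd_direction, asa_direction, delta_lambda, log2fc,
#'   compensatory (ASD without ASA where the faster-decaying allele is the
#'   transcriptionally favoured one; descriptive metadata). Attribute
#'   `"summary"` holds the headline tallies: n_genes, n_asd, n_asa, n_both,
#'   frac_asa_without_asd, frac_asd_without_asa, frac_compensatory (NA when
#'   a denominator is 0).
#' @export
classify_joint <- function(asd_calls, asa_calls) {
  assert_that(setequal(asd_calls$gene_id, asa_calls$gene_id),
              "ASD and ASA call sets cover different gene universes")
  joined <- inner_join(
    select(asd_calls, "gene_id", "asd_significant", "delta_lambda",
           asd_direction = "direction"),
    select(asa_calls, "gene_id", "asa_significant", "log2fc",
           asa_direction = "direction"),
    by = "gene_id"
  ) |>
    mutate(
      category = dplyr::case_when(
        .data$asd_significant & .data$asa_significant ~ "both",
        .data$asd_significant ~ "ASD_only",
        .data$asa_significant ~ "ASA_only",
        TRUE ~ "neither"
      ),
      # under compensation the steady-state ratio is flat because the
      # transcriptionally favoured allele is also the faster-decaying one
      compensatory = .data$asd_significant & !.data$asa_significant &
        sign(.data$delta_lambda) == sign(.data$log2fc) &
        sign(.data$delta_lambda) != 0
    ) |>
    arrange(.data$gene_id)
  n_asd <- sum(joined$asd_significant)
  n_asa <- sum(joined$asa_significant)
  n_both <- sum(joined$category == "both")
  attr(joined, "summary") <- tibble(
    n_genes = nrow(joined), n_asd = n_asd, n_asa = n_asa, n_both = n_both,
    frac_asa_without_asd = ifelse(n_asa > 0, (n_asa - n_both) / n_asa, NA),
    frac_asd_without_asa = ifelse(n_asd > 0, (n_asd - n_both) / n_asd, NA),
    frac_compensatory = ifelse(n_asd > 0,
                               sum(joined$compensatory) / n_asd, NA)
  )
  class(joined) <- c("gene_decisions", class(joined))
  joined
}

#' Sweep joint classification over a grid of significance thresholds
#'
#' Re-applies [call_asd()] and [call_asa()] at each adjusted-p threshold
#' and tabulates the joint category counts, mirroring a threshold-
#' robustness sweep.
#'
#' @param decay_fits,asa_fits Fit tibbles from [fit_allelic_decay()] and
#'   [fit_allelic_abundance()].
#' @param p_grid Adjusted-p thresholds.
#' @param min_abs_dlambda,min_abs_log2fc Effect-size thresholds.
#' @return Tibble: p_adj_threshold, n_asd, n_asa, n_both,
#'   frac_asa_without_asd, frac_asd_without_asa.
#' @export
classify_threshold_sweep <- function(decay_fits, asa_fits,
                                     p_grid = c(0.005, 0.0075, 0.01, 0.025,
                                                0.05, 0.075, 0.1),
                                     min_abs_dlambda = 0.06,
                                     min_abs_log2fc = 1.0) {
  list_rbind(map(p_grid, function(p) {
    dec <- classify_joint(
      call_asd(decay_fits, p, min_abs_dlambda),
      call_asa(asa_fits, p, min_abs_log2fc)
    )
    mutate(attr(dec, "summary"), p_adj_threshold = p, .before = 1) |>
      select("p_adj_threshold", "n_asd", "n_asa", "n_both",
             "frac_asa_without_asd", "frac_asd_without_asa")
  }))
}

#' Ratio-of-ratios decay estimate for targeted validation counts
#'
#' For deep targeted counts of both alleles at 0 h and a later timepoint,
#' the allelic decay difference is summarised as
#' `log2((m_t_allele1 / m_t_allele2) / (m_0_allele1 / m_0_allele2))`.
#' On noise-free exponential-decay data this equals
#' `-delta_lambda * t / ln 2` and is additive over time splits.
#'
#' @param m0_allele1,m0_allele2 Allelic counts at 0 h (positive).
#' @param mt_allele1,mt_allele2 Allelic counts at the later timepoint
#'   (positive).
#' @return Log2 ratio of ratios (vectorised).
#' @export
validation_asd <- function(m0_allele1, m0_allele2, mt_allele1, mt_allele2) {
  assert_that(all(c(m0_allele1, m0_allele2, mt_allele1, mt_allele2) > 0),
              "validation counts must all be positive")
  log2((mt_allele1 / mt_allele2) / (m0_allele1 / m0_allele2))
}

#' Correlate decay-difference estimates between two platforms
#'
#' @param dlambda_a,dlambda_b Paired per-gene estimates (finite, n >= 3).
#' @return Tibble: n, r (Pearson), p (two-sided t-based).
#' @export
compare_platforms <- function(dlambda_a, dlambda_b) {
  assert_that(length(dlambda_a) == length(dlambda_b),
              "vectors must be paired")
  assert_that(length(dlambda_a) >= 3, "need at least 3 pairs")
  assert_that(all(is.finite(dlambda_a)) && all(is.finite(dlambda_b)),
              "estimates must be finite")
  assert_that(sd(dlambda_a) > 0 && sd(dlambda_b) > 0,
              "zero variance in one platform's estimates")
  ct <- cor.test(dlambda_a, dlambda_b, method = "pearson")
  tibble(n = length(dlambda_a), r = unname(ct$estimate), p = ct$p.value)
}
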