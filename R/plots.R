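# ggplot2 visualisations for the result objects.

#' Volcano-style plot of allelic decay differences
#'
#' Delta lambda against -log10 adjusted p, one panel per replicate, with
#' the calling thresholds drawn as reference lines.
#'
#' @param object A `decay_fits` tibble.
#' @param p_adj_threshold,min_abs_dlambda Thresholds drawn as dashed lines.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.decay_fits <- function(object, p_adj_threshold = 0.05,
                                min_abs_dlambda = 0.06, ...) {
  df <- mutate(as_tibble(object),
               neglogp = -log10(pmax(.data$p_adj, 1e-300)))
  ggplot2::ggplot(df, ggplot2::aes(.data$delta_lambda, .data$neglogp)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * min_abs_dlambda,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_hline(yintercept = -log10(p_adj_threshold),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::facet_wrap(~replicate, labeller = ggplot2::label_both) +
    ggplot2::labs(x = expression(Delta * lambda ~ "(per hour)"),
                  y = expression(-log[10] ~ "adjusted p")) +
    ggplot2::theme_bw()
}

#' Replicate-concordance plot of ASD calls
#'
#' Scatter of replicate point estimates, coloured by the final call.
#'
#' @param object An `asd_calls` tibble.
#' @param fits The `decay_fits` tibble the calls were made from.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.asd_calls <- function(object, fits = NULL, ...) {
  if (is.null(fits)) {
    df <- as_tibble(object)
    return(
      ggplot2::ggplot(df, ggplot2::aes(.data$delta_lambda,
                                       fill = .data$asd_significant)) +
        ggplot2::geom_histogram(bins = 40, alpha = 0.8) +
        ggplot2::labs(x = expression(Delta * lambda ~ "(per hour)"),
                      fill = "ASD") +
        ggplot2::theme_bw()
    )
  }
  reps <- sort(unique(fits$replicate))[1:2]
  wide <- fits |>
    filter(.data$replicate %in% reps) |>
    select("gene_id", "replicate", "delta_lambda") |>
    tidyr::pivot_wider(names_from = "replicate",
                       values_from = "delta_lambda",
                       names_prefix = "rep") |>
    left_join(select(as_tibble(object), "gene_id", "asd_significant"),
              by = "gene_id")
  ggplot2::ggplot(wide, ggplot2::aes(.data[[paste0("rep", reps[1])]],
                                     .data[[paste0("rep", reps[2])]],
                                     colour = .data$asd_significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.9) +
    ggplot2::geom_abline(linetype = "dotted") +
    ggplot2::labs(x = sprintf("replicate %d Δλ", reps[1]),
                  y = sprintf("replicate %d Δλ", reps[2]),
                  colour = "ASD") +
    ggplot2::theme_bw()
}

#' Permutation FDR curve
#'
#' @param object An `fdr_curve` tibble from [permutation_fdr()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fdr_curve <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$threshold, .data$fdr)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.9) +
    ggplot2::labs(x = expression("|" * Delta * lambda * "| threshold"),
                  y = "permutation FDR") +
    ggplot2::theme_bw()
}

#' Joint ASD/ASA category counts
#'
#' @param object A `gene_decisions` tibble from [classify_joint()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gene_decisions <- function(object, ...) {
  df <- count(as_tibble(object), .data$category)
  ggplot2::ggplot(df, ggplot2::aes(.data$category, .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "genes") +
    ggplot2::theme_bw()
}

#' Allelic-fraction time course for one gene
#'
#' Per-SNP allele-1 read fractions over time with the fitted logit line,
#' one panel per replicate. Point size reflects the two-allele read total.
#'
#' @param counts Counts tibble.
#' @param gene_id Gene to plot.
#' @param fits Optional `decay_fits` tibble supplying the fitted lines.
#' @return A ggplot object.
#' @export
plot_gene_timecourse <- function(counts, gene_id, fits = NULL) {
  df <- filter(counts, .data$gene_id == !!gene_id) |>
    mutate(total = .data$n_allele1 + .data$n_allele2,
           frac = ifelse(.data$total > 0, .data$n_allele1 / .data$total, NA))
  assert_that(nrow(df) > 0, "gene not found in counts")
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_h, .data$frac)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$total), alpha = 0.5) +
    ggplot2::scale_size_area(max_size = 3) +
    ggplot2::facet_wrap(~replicate, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "hours after transcriptional arrest",
                  y = "allele-1 read fraction", size = "reads") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_bw()
  if (!is.null(fits)) {
    fsub <- filter(as_tibble(fits), .data$gene_id == !!gene_id)
    grid <- tidyr::crossing(
      replicate = unique(fsub$replicate),
      time_h = seq(min(df$time_h), max(df$time_h), length.out = 50)
    ) |>
      left_join(select(fsub, "replicate", "alpha", "beta"), by = "replicate") |>
      mutate(frac = plogis(.data$alpha + .data$beta * .data$time_h))
    p <- p + ggplot2::geom_line(data = grid, colour = "firebrick")
  }
  p
}
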