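# broom-style tidiers for the package's result objects.

#' Tidy decay fits
#'
#' @param x A `decay_fits` tibble.
#' @param conf_level Confidence level for the bootstrap normal interval.
#' @param ... Unused.
#' @return Tibble with one row per gene and replicate: estimate
#'   (delta lambda), std.error (bootstrap SD), statistic (z), p.value
#'   (raw), adj.p.value, conf.low, conf.high.
#' @export
tidy.decay_fits <- function(x, conf_level = 0.95, ...) {
  q <- qnorm(1 - (1 - conf_level) / 2)
  tibble(gene_id = x$gene_id, replicate = x$replicate,
         estimate = x$delta_lambda, std.error = x$boot_sd,
         statistic = x$z, p.value = x$p_raw, adj.p.value = x$p_adj,
         conf.low = x$boot_mean - q * x$boot_sd,
         conf.high = x$boot_mean + q * x$boot_sd)
}

#' Glance at decay fits
#'
#' @param x A `decay_fits` tibble.
#' @param ... Unused.
#' @return One-row tibble: n_genes, n_replicates, n_boot,
#'   median_boot_sd, prop_converged.
#' @export
glance.decay_fits <- function(x, ...) {
  tibble(n_genes = dplyr::n_distinct(x$gene_id),
         n_replicates = dplyr::n_distinct(x$replicate),
         n_boot = max(x$n_boot),
         median_boot_sd = median(x$boot_sd),
         prop_converged = mean(x$converged))
}

#' Tidy abundance fits
#'
#' @param x An `asa_fits` tibble.
#' @inheritParams tidy.decay_fits
#' @return Tibble with estimate (log2FC), std.error, statistic, p.value,
#'   adj.p.value, conf.low, conf.high per gene and replicate.
#' @export
tidy.asa_fits <- function(x, conf_level = 0.95, ...) {
  q <- qnorm(1 - (1 - conf_level) / 2)
  tibble(gene_id = x$gene_id, replicate = x$replicate,
         estimate = x$log2fc, std.error = x$boot_sd,
         statistic = x$z, p.value = x$p_raw, adj.p.value = x$p_adj,
         conf.low = x$boot_mean - q * x$boot_sd,
         conf.high = x$boot_mean + q * x$boot_sd)
}

#' Glance at joint gene decisions
#'
#' @param x A `gene_decisions` tibble from [classify_joint()].
#' @param ... Unused.
#' @return The one-row headline summary (counts and fractions).
#' @export
glance.gene_decisions <- function(x, ...) {
  attr(x, "summary")
}
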