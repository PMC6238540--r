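# Allelic decay-rate inference: binomial logit-linear model, SNP-level
# bootstrap, replicate-concordant calling, and permutation FDR.
#
# Model: with both alleles sharing the capture fraction f(t), the allele-1
# read fraction at time t after transcriptional arrest is
#   p(t) = R exp(-dl t) / (R exp(-dl t) + 1),  R = N1(0)/N2(0),
# so logit p(t) = alpha + beta t with alpha = log R and beta = -(lambda1 -
# lambda2). We report delta_lambda = -beta = lambda1 - lambda2, positive
# when allele 1 decays faster; exp(beta) is the per-hour odds change of
# observing an allele-1 read.

# Vectorised IRLS for the two-parameter binomial logit model. One row per
# fit; columns are timepoints. S1 = allele-1 successes, N = totals.
# Cells with N = 0 carry zero weight. Deviance tolerance and iteration cap
# mirror standard GLM practice; |beta| is clipped at beta_cap and the fit
# flagged as separated.
fit_logit_many <- function(S1, N, t, maxit = 50L, tol = 1e-10,
                           beta_cap = 50) {
  S1 <- as.matrix(S1); N <- as.matrix(N)
  B <- nrow(S1); K <- ncol(S1)
  y <- ifelse(N > 0, S1 / pmax(N, 1), 0.5)

  wls <- function(w, z) {
    Sw <- rowSums(w)
    Swt <- as.vector(w %*% t)
    Swtt <- as.vector(w %*% (t * t))
    Swz <- rowSums(w * z)
    Swtz <- as.vector((w * z) %*% t)
    det <- Sw * Swtt - Swt^2
    ok <- is.finite(det) & det > 1e-12 * pmax(Sw, 1)^2
    a <- ifelse(ok, (Swtt * Swz - Swt * Swtz) / det, 0)
    b <- ifelse(ok, (Sw * Swtz - Swt * Swz) / det, 0)
    list(a = a, b = b, ok = ok)
  }

  # init: weighted LS on the continuity-corrected empirical logit
  el <- log((S1 + 0.5) / (N - S1 + 0.5))
  init <- wls(N, el)
  a <- init$a; b <- init$b
  identifiable <- init$ok
  dev_old <- rep(Inf, B)
  converged <- rep(FALSE, B)
  iter <- 0L
  dev_of <- function(mu) {
    t1 <- ifelse(S1 > 0, S1 * log(S1 / (N * mu)), 0)
    S2 <- N - S1
    t2 <- ifelse(S2 > 0, S2 * log(S2 / (N * (1 - mu))), 0)
    2 * rowSums(ifelse(N > 0, t1 + t2, 0))
  }
  while (iter < maxit && !all(converged | !identifiable)) {
    iter <- iter + 1L
    eta <- pmin(pmax(matrix(a, B, K) + tcrossprod(b, t), -30), 30)
    mu <- plogis(eta)
    V <- pmax(mu * (1 - mu), 1e-12)
    w <- N * V
    z <- eta + (y - mu) / V
    step <- wls(w, z)
    identifiable <- identifiable & step$ok
    a <- ifelse(identifiable, step$a, a)
    b <- ifelse(identifiable, step$b, b)
    eta <- pmin(pmax(matrix(a, B, K) + tcrossprod(b, t), -30), 30)
    dev <- dev_of(plogis(eta))
    converged <- converged |
      (abs(dev - dev_old) / (abs(dev) + 0.1) < tol)
    dev_old <- dev
  }
  separated <- abs(b) > beta_cap
  b <- pmin(pmax(b, -beta_cap), beta_cap)
  list(alpha = a, beta = b,
       converged = converged & identifiable & !separated,
       separated = separated, identifiable = identifiable, n_iter = iter)
}

# Per-SNP x timepoint count matrices for one gene/replicate, ordered by
# snp_id then timepoint.
gene_count_matrices <- function(gene_counts, replicate) {
  sub <- filter(gene_counts, .data$replicate == !!replicate)
  assert_that(nrow(sub) > 0, "no counts for requested replicate")
  tps <- sort(unique(sub$time_h))
  snps <- sort(unique(sub$snp_id))
  sub <- arrange(sub, .data$snp_id, .data$time_h)
  assert_that(nrow(sub) == length(tps) * length(snps),
              "every SNP needs counts at every timepoint")
  list(
    c1 = matrix(sub$n_allele1, nrow = length(snps), byrow = TRUE,
                dimnames = list(snps, NULL)),
    c2 = matrix(sub$n_allele2, nrow = length(snps), byrow = TRUE,
                dimnames = list(snps, NULL)),
    timepoints = tps, snps = snps
  )
}

#' Fit the binomial logit-linear decay model for one gene
#'
#' Pools every (SNP, timepoint) cell of the chosen replicate as an
#' independent binomial observation (allele-1 reads out of the two-allele
#' total) and fits logit p = alpha + beta * time by maximum likelihood.
#'
#' @param gene_counts Counts tibble for a single gene ([counts_schema()]).
#' @param replicate Replicate to fit.
#' @param snp_subset Optional character vector of SNP ids (defaults to all;
#'   duplicates allowed, as used by the bootstrap).
#' @return One-row tibble: gene_id, replicate, n_snps, n_obs, alpha, beta,
#'   delta_lambda (= -beta = lambda1 - lambda2), converged, separated,
#'   n_iter.
#' @export
fit_logit_decay <- function(gene_counts, replicate = 1L, snp_subset = NULL) {
  validate_counts(gene_counts)
  gene <- unique(gene_counts$gene_id)
  assert_that(length(gene) == 1, "fit_logit_decay expects a single gene")
  m <- gene_count_matrices(gene_counts, replicate)
  if (!is.null(snp_subset)) {
    assert_that(length(snp_subset) > 0, "snp_subset must be non-empty")
    idx <- match(snp_subset, m$snps)
    assert_that(!anyNA(idx), "snp_subset contains unknown SNP ids")
  } else {
    idx <- seq_along(m$snps)
  }
  S1 <- matrix(colSums(m$c1[idx, , drop = FALSE]), nrow = 1)
  N <- S1 + matrix(colSums(m$c2[idx, , drop = FALSE]), nrow = 1)
  fit <- fit_logit_many(S1, N, m$timepoints)
  tibble(gene_id = gene, replicate = as.integer(replicate),
         n_snps = length(idx),
         n_obs = sum(m$c1[idx, , drop = FALSE] +
                       m$c2[idx, , drop = FALSE] > 0),
         alpha = fit$alpha, beta = fit$beta, delta_lambda = -fit$beta,
         converged = fit$converged, separated = fit$separated,
         n_iter = fit$n_iter)
}

boot_indices <- function(n, n_boot, seed) {
  with_seed(seed, matrix(sample.int(n, n * n_boot, replace = TRUE),
                         nrow = n_boot))
}

resample_sums <- function(counts_mat, idx) {
  # idx: n_boot x n matrix of SNP indices; returns n_boot x K sums
  K <- ncol(counts_mat)
  out <- matrix(0, nrow(idx), K)
  for (k in seq_len(K)) {
    col <- counts_mat[, k]
    out[, k] <- rowSums(matrix(col[idx], nrow(idx)))
  }
  out
}

#' Bootstrap a per-gene allelic statistic over SNP loci
#'
#' Draws `n_boot` resamples of the gene's n SNP loci (size n, with
#' replacement), recomputes the statistic on each resample, and summarises
#' the bootstrap distribution: mean, SD, z = mean/SD and the normal-theory
#' two-sided p-value `2 * (1 - pnorm(|z|))`.
#'
#' @param gene_counts Counts tibble for a single gene.
#' @param replicate Replicate to resample.
#' @param statistic `"delta_lambda"` (refits the logit model per resample)
#'   or `"log2fc_t0"` (log2 allelic ratio of summed 0 h counts).
#' @param n_boot Number of resamples. Default 5000.
#' @param seed Integer seed; resampling is deterministic given it.
#' @return One-row tibble: gene_id, replicate, statistic, estimate (point
#'   value on the full SNP set), n_boot, boot_mean, boot_sd, z, p_raw,
#'   n_dropped (non-converged resample fits, excluded with a warning when
#'   above 1%).
#' @export
bootstrap_statistic <- function(gene_counts, replicate = 1L,
                                statistic = c("delta_lambda", "log2fc_t0"),
                                n_boot = 5000L, seed = 1L) {
  statistic <- match.arg(statistic)
  validate_counts(gene_counts)
  gene <- unique(gene_counts$gene_id)
  assert_that(length(gene) == 1, "bootstrap_statistic expects a single gene")
  m <- gene_count_matrices(gene_counts, replicate)
  n <- length(m$snps)
  idx <- boot_indices(n, n_boot,
                      derive_seed(seed, gene, replicate, statistic, "boot"))
  if (statistic == "delta_lambda") {
    S1 <- resample_sums(m$c1, idx)
    N <- S1 + resample_sums(m$c2, idx)
    fits <- fit_logit_many(S1, N, m$timepoints)
    vals <- -fits$beta
    keep <- fits$converged
    point_fit <- fit_logit_many(matrix(colSums(m$c1), 1),
                                matrix(colSums(m$c1) + colSums(m$c2), 1),
                                m$timepoints)
    point <- -point_fit$beta
  } else {
    k0 <- which(m$timepoints == 0)
    assert_that(length(k0) == 1, "log2fc_t0 needs a 0 h timepoint")
    s1 <- resample_sums(m$c1[, k0, drop = FALSE], idx)[, 1]
    s2 <- resample_sums(m$c2[, k0, drop = FALSE], idx)[, 1]
    keep <- s1 + s2 > 0
    vals <- log2_allelic_fc(pmax(s1, 0), pmax(s2, 0), strict = FALSE)
    point <- log2_allelic_fc(sum(m$c1[, k0]), sum(m$c2[, k0]))
  }
  n_dropped <- sum(!keep)
  if (n_dropped > 0.01 * n_boot) {
    warn(sprintf("bootstrap_statistic(%s, rep %d): %d/%d resamples dropped",
                 gene, replicate, n_dropped, n_boot))
  }
  vals <- vals[keep]
  assert_that(length(vals) > 0, "all bootstrap resamples failed to fit")
  bm <- mean(vals)
  bs <- sd(vals)
  if (is.na(bs) || bs == 0) {
    z <- if (bm != 0) Inf * sign(bm) else 0
    p <- if (bm != 0) 0 else 1
    bs <- 0
  } else {
    z <- bm / bs
    p <- 2 * (1 - pnorm(abs(z)))
  }
  tibble(gene_id = gene, replicate = as.integer(replicate),
         statistic = statistic, estimate = point,
         n_boot = as.integer(n_boot), boot_mean = bm, boot_sd = bs,
         z = z, p_raw = p, n_dropped = as.integer(n_dropped))
}

# Shared driver: point fit + bootstrap for every gene x replicate, BH
# within replicate (one hypothesis family per replicate).
fit_allelic_stat <- function(counts, statistic, n_boot, seed) {
  validate_counts(counts)
  genes <- split(counts, counts$gene_id)
  reps <- sort(unique(counts$replicate))
  rows <- list_rbind(map(genes, function(g) {
    list_rbind(map(reps, function(r) {
      bs <- bootstrap_statistic(g, r, statistic, n_boot, seed)
      if (statistic == "delta_lambda") {
        pf <- fit_logit_decay(g, r)
        bs$alpha <- pf$alpha
        bs$beta <- pf$beta
        bs$converged <- pf$converged
        bs$n_snps <- pf$n_snps
      } else {
        bs$n_snps <- dplyr::n_distinct(g$snp_id)
        bs$converged <- TRUE
      }
      bs
    }))
  }))
  rows |>
    group_by(.data$replicate) |>
    mutate(p_adj = adjust_pvalues_bh(.data$p_raw)) |>
    ungroup()
}

#' Fit allelic decay differences for a cohort
#'
#' Runs [fit_logit_decay()] and [bootstrap_statistic()] (statistic
#' `delta_lambda`) for every gene and replicate, then BH-adjusts the
#' bootstrap p-values across genes within each replicate.
#'
#' @param counts Counts tibble, already filtered (see [apply_filters()]).
#' @param n_boot Bootstrap resamples per gene/replicate. Default 5000.
#' @param seed Integer seed.
#' @return A `decay_fits` tibble: gene_id, replicate, n_snps, alpha, beta,
#'   delta_lambda (point estimate, = `estimate`), boot_mean, boot_sd, z,
#'   p_raw, p_adj, converged, n_dropped.
#' @export
fit_allelic_decay <- function(counts, n_boot = 5000L, seed = 1L) {
  out <- fit_allelic_stat(counts, "delta_lambda", n_boot, seed) |>
    mutate(delta_lambda = .data$estimate) |>
    select("gene_id", "replicate", "n_snps", "alpha", "beta",
           "delta_lambda", "boot_mean", "boot_sd", "z", "p_raw", "p_adj",
           "converged", "n_boot", "n_dropped")
  class(out) <- c("decay_fits", class(out))
  attr(out, "seed") <- seed
  out
}

#' Call allele-specific decay (ASD) per gene
#'
#' A gene is called significant when, in every replicate, the BH-adjusted
#' bootstrap p-value is below `p_adj_threshold` and |delta lambda| exceeds
#' `min_abs_dlambda`, and all replicate estimates are biased toward the
#' same allele (one sign).
#'
#' @param fits A `decay_fits` tibble from [fit_allelic_decay()] with >= 2
#'   replicates per gene.
#' @param p_adj_threshold Adjusted-p threshold. Default 0.05.
#' @param min_abs_dlambda Minimum |delta lambda| per hour. Default 0.06.
#' @return An `asd_calls` tibble: gene_id, n_reps, delta_lambda (unweighted
#'   mean of replicate point estimates), max_p_adj, min_abs_delta_lambda,
#'   sign_concordant, all_converged, asd_significant, direction
#'   (`allele1_faster` / `allele2_faster` / `none`).
#' @export
call_asd <- function(fits, p_adj_threshold = 0.05, min_abs_dlambda = 0.06) {
  n_reps <- fits |> count(.data$gene_id)
  assert_that(all(n_reps$n >= 2), "call_asd needs >= 2 replicates per gene")
  out <- fits |>
    group_by(.data$gene_id) |>
    summarise(
      n_reps = dplyr::n(),
      max_p_adj = max(.data$p_adj),
      min_abs_delta_lambda = min(abs(.data$delta_lambda)),
      sign_concordant = dplyr::n_distinct(sign(.data$delta_lambda)) == 1 &&
        all(sign(.data$delta_lambda) != 0),
      all_converged = all(.data$converged),
      delta_lambda = mean(.data$delta_lambda),
      .groups = "drop"
    ) |>
    mutate(
      asd_significant = .data$max_p_adj < p_adj_threshold &
        .data$min_abs_delta_lambda > min_abs_dlambda &
        .data$sign_concordant & .data$all_converged,
      direction = dplyr::case_when(
        !.data$asd_significant ~ "none",
        .data$delta_lambda > 0 ~ "allele1_faster",
        TRUE ~ "allele2_faster"
      )
    )
  class(out) <- c("asd_calls", class(out))
  attr(out, "thresholds") <- c(p_adj = p_adj_threshold,
                               min_abs_dlambda = min_abs_dlambda)
  out
}

#' Permutation estimate of the ASD false discovery rate
#'
#' Shuffles the gene labels of replicate 2 (and any further replicates)
#' relative to replicate 1, preserving each replicate's marginal
#' distribution of (p_adj, delta lambda) while breaking cross-replicate
#' concordance; counts genes passing the dual thresholds with concordant
#' sign in each permuted set; FDR(x) = mean permuted count / real count.
#'
#' @param fits A `decay_fits` tibble (>= 2 replicates per gene).
#' @param grid Numeric vector of |delta lambda| thresholds x.
#' @param n_perm Number of permutations. Default 100.
#' @param seed Integer seed.
#' @param p_adj_threshold Adjusted-p threshold. Default 0.05.
#' @return An `fdr_curve` tibble: threshold, real_count, mean_perm_count,
#'   fdr (NA where real_count is 0).
#' @export
permutation_fdr <- function(fits, grid = seq(0, 0.2, by = 0.01),
                            n_perm = 100L, seed = 1L,
                            p_adj_threshold = 0.05) {
  assert_that(n_perm >= 1, "n_perm must be >= 1")
  assert_that(length(grid) >= 1, "threshold grid must be non-empty")
  reps <- sort(unique(fits$replicate))
  assert_that(length(reps) >= 2, "permutation_fdr needs >= 2 replicates")
  genes <- sort(unique(fits$gene_id))
  wide <- map(reps, function(r) {
    sub <- filter(fits, .data$replicate == r)
    i <- match(genes, sub$gene_id)
    list(p_adj = sub$p_adj[i], dl = sub$delta_lambda[i])
  })
  pass_mat <- function(rec, x) {
    rec$p_adj < p_adj_threshold & abs(rec$dl) > x & !is.na(rec$dl)
  }
  concordant <- function(recs, x) {
    ok <- Reduce(`&`, map(recs, pass_mat, x = x))
    sgn <- map(recs, function(r) sign(r$dl))
    same <- Reduce(`&`, map(sgn[-1], function(s) s == sgn[[1]]))
    sum(ok & same & sgn[[1]] != 0, na.rm = TRUE)
  }
  real <- map_dbl(grid, function(x) concordant(wide, x))
  perm_counts <- with_seed(derive_seed(seed, "perm_fdr"), {
    vapply(seq_len(n_perm), function(p) {
      permd <- c(wide[1], map(wide[-1], function(rec) {
        i <- sample.int(length(genes))
        list(p_adj = rec$p_adj[i], dl = rec$dl[i])
      }))
      map_dbl(grid, function(x) concordant(permd, x))
    }, numeric(length(grid)))
  })
  perm_counts <- matrix(perm_counts, nrow = length(grid))
  out <- tibble(threshold = grid, real_count = real,
                mean_perm_count = rowMeans(perm_counts),
                fdr = ifelse(real > 0, rowMeans(perm_counts) / real, NA_real_))
  class(out) <- c("fdr_curve", class(out))
  out
}

#' Select control genes without allelic decay differences
#'
#' Controls must show no hint of ASD in either replicate: raw bootstrap
#' p > 0.05, |delta lambda| < 0.03/h, and bootstrap SD below
#' `min(0.1, empirical 95% quantile of all bootstrap SDs)`.
#'
#' @param fits A `decay_fits` tibble.
#' @param max_p_raw,max_abs_dlambda,max_boot_sd The three criteria.
#' @return Tibble of selected genes with their combined delta lambda.
#' @export
select_control_genes <- function(fits, max_p_raw = 0.05,
                                 max_abs_dlambda = 0.03, max_boot_sd = 0.1) {
  sd_cap <- min(max_boot_sd,
                quantile(fits$boot_sd, 0.95, na.rm = TRUE, names = FALSE))
  fits |>
    group_by(.data$gene_id) |>
    summarise(ok = all(.data$p_raw > max_p_raw) &&
                all(abs(.data$delta_lambda) < max_abs_dlambda) &&
                all(.data$boot_sd < sd_cap),
              delta_lambda = mean(.data$delta_lambda),
              .groups = "drop") |>
    filter(.data$ok) |>
    select("gene_id", "delta_lambda")
}
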