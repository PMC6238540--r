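# helper: a minimal decay_fits-like tibble for the calling logic
fits_row <- function(gene, rep, dl, p_adj, p_raw = p_adj / 2, sd = 0.02) {
  tibble::tibble(gene_id = gene, replicate = as.integer(rep),
                 n_snps = 8L, alpha = 0, beta = -dl, delta_lambda = dl,
                 boot_mean = dl, boot_sd = sd, z = dl / sd,
                 p_raw = p_raw, p_adj = p_adj, converged = TRUE,
                 n_boot = 1000L, n_dropped = 0L)
}

test_that("logit fit recovers exact parameters from noise-free data", {
  # balanced counts at every timepoint: alpha = beta = 0
  eq <- make_counts("gEq", matrix(40, 5, 3), matrix(40, 5, 3))
  f <- fit_logit_decay(eq, replicate = 1)
  expect_equal(f$alpha, 0, tolerance = 1e-12)
  expect_equal(f$beta, 0, tolerance = 1e-12)

  # p(t) = exp(-0.3 t) / (exp(-0.3 t) + 1), totals 1e6: the logit line is
  # exactly linear, oracle = direct logit regression on exact proportions
  nf <- make_noise_free_gene("gNF", dl = 0.3, total = 1e6, replicates = 1)
  f2 <- fit_logit_decay(nf, replicate = 1)
  expect_lt(abs(f2$delta_lambda - 0.300), 1e-3)
  t <- c(0, 0.5, 1.5)
  p_exact <- round(1e6 * exp(-0.3 * t) / (exp(-0.3 * t) + 1)) / 1e6
  oracle <- coef(lm(qlogis(p_exact) ~ t))
  expect_equal(f2$beta, unname(oracle[2]), tolerance = 1e-3)
  expect_true(f2$converged)
})

test_that("logit fit agrees with glm and transforms correctly", {
  set.seed(99)
  c1 <- matrix(rpois(24, 80), 8); c2 <- matrix(rpois(24, 50), 8)
  counts <- make_counts("gG", c1, c2)
  f <- fit_logit_decay(counts, replicate = 1)
  t <- c(0, 0.5, 1.5)
  g <- glm(cbind(colSums(c1), colSums(c2)) ~ t, family = binomial)
  expect_equal(f$alpha, unname(coef(g)[1]), tolerance = 1e-8)
  expect_equal(f$beta, unname(coef(g)[2]), tolerance = 1e-8)

  # allele swap negates alpha and beta exactly
  sw <- fit_logit_decay(make_counts("gG", c2, c1), replicate = 1)
  expect_equal(sw$alpha, -f$alpha, tolerance = 1e-9)
  expect_equal(sw$beta, -f$beta, tolerance = 1e-9)

  # count-scaling invariance: c x counts leaves the MLE unchanged
  sc <- fit_logit_decay(make_counts("gG", 7L * c1, 7L * c2), replicate = 1)
  expect_equal(sc$beta, f$beta, tolerance = 1e-9)

  # exp(beta) is the fitted odds change per hour
  odds <- function(tt) {
    p <- plogis(f$alpha + f$beta * tt)
    p / (1 - p)
  }
  expect_equal(odds(1) / odds(0), exp(f$beta), tolerance = 1e-12)

  # SNP subsetting restricts the fit
  sub <- fit_logit_decay(counts, 1, snp_subset = c("gG_s01", "gG_s02"))
  gsub <- glm(cbind(colSums(c1[1:2, ]), colSums(c2[1:2, ])) ~ t,
              family = binomial)
  expect_equal(sub$beta, unname(coef(gsub)[2]), tolerance = 1e-8)
  expect_error(fit_logit_decay(counts, 1, snp_subset = character(0)),
               "non-empty")
})

test_that("degenerate fits are flagged rather than raised", {
  # allele 2 never observed: complete separation in alpha, not identifiable
  c1 <- matrix(50, 5, 3); c2 <- matrix(0, 5, 3)
  f <- fit_logit_decay(make_counts("gSep", c1, c2), 1)
  expect_false(f$converged)
  # a timepoint with zero totals for both alleles carries no weight
  c1b <- matrix(c(30, 0, 20), 5, 3, byrow = TRUE)
  c2b <- matrix(c(30, 0, 30), 5, 3, byrow = TRUE)
  fb <- fit_logit_decay(make_counts("gZ", c1b, c2b), 1)
  expect_true(is.finite(fb$delta_lambda))
})

test_that("bootstrap handles identical loci, is seeded, and drops failures", {
  # identical SNP count vectors: every resample refits the same data
  c1 <- matrix(30, 6, 3); c2 <- matrix(rep(c(40, 35, 25), each = 6), 6)
  counts <- make_counts("gI", c1, c2)
  bs <- bootstrap_statistic(counts, 1, "delta_lambda", n_boot = 200, seed = 3)
  expect_equal(bs$boot_sd, 0)
  expect_equal(bs$boot_mean, bs$estimate, tolerance = 1e-9)
  expect_equal(bs$p_raw, ifelse(bs$boot_mean != 0, 0, 1))

  set.seed(17)
  c1 <- matrix(rpois(18, 60), 6); c2 <- matrix(rpois(18, 60), 6)
  counts <- make_counts("gS", c1, c2)
  b1 <- bootstrap_statistic(counts, 1, "delta_lambda", 400, seed = 5)
  b2 <- bootstrap_statistic(counts, 1, "delta_lambda", 400, seed = 5)
  expect_identical(b1, b2)
  b3 <- bootstrap_statistic(counts, 1, "delta_lambda", 400, seed = 6)
  expect_false(identical(b1$boot_mean, b3$boot_mean))
  # Monte-Carlo error bound between independent seeds
  expect_lt(abs(b1$boot_mean - b3$boot_mean), 4 * b1$boot_sd / sqrt(400) +
              4 * b3$boot_sd / sqrt(400))
})

test_that("bootstrap z-test has the expected null behaviour (small-n tail inflation)", {
  # with 8 loci the bootstrap SD has ~7 df, so the normal-theory p is
  # anticonservative: raw rate sits between nominal 0.05 and P(|t7|>1.96)
  # plus sampling slack, well below what would survive BH + dual thresholds
  sim <- simulate_cohort(sim_cohort_config(n_genes = 120, fraction_asd = 0,
                                           depth_per_snp = 200,
                                           snps_per_gene = 8L, seed = 101))
  fits <- fit_allelic_decay(apply_filters(sim$counts), n_boot = 500,
                            seed = 5)
  rate <- mean(fits$p_raw < 0.05)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.16)
  # and no gene survives the replicate-concordant dual thresholds
  expect_lt(mean(call_asd(fits)$asd_significant), 0.01 + 1e-9)
})

test_that("ASD calling applies the dual thresholds and sign concordance", {
  thr <- list(p = 0.05, dl = 0.06)
  sig <- dplyr::bind_rows(fits_row("g1", 1, 0.08, 0.01),
                          fits_row("g1", 2, 0.07, 0.02))
  out <- call_asd(sig, thr$p, thr$dl)
  expect_true(out$asd_significant)
  expect_equal(out$direction, "allele1_faster")
  expect_equal(out$delta_lambda, 0.075)

  # |delta lambda| = 0.05 <= 0.06 in one replicate: not significant
  weak <- dplyr::bind_rows(fits_row("g1", 1, 0.08, 0.01),
                           fits_row("g1", 2, 0.05, 0.01))
  expect_false(call_asd(weak, thr$p, thr$dl)$asd_significant)

  # opposite signs: not significant even with strong p and effect
  disc <- dplyr::bind_rows(fits_row("g1", 1, 0.08, 0.01),
                           fits_row("g1", 2, -0.08, 0.01))
  expect_false(call_asd(disc, thr$p, thr$dl)$asd_significant)

  # negative concordant effects point at allele 2
  neg <- dplyr::bind_rows(fits_row("g1", 1, -0.1, 0.01),
                          fits_row("g1", 2, -0.09, 0.01))
  expect_equal(call_asd(neg, thr$p, thr$dl)$direction, "allele2_faster")

  # missing replicate rejected
  expect_error(call_asd(fits_row("g1", 1, 0.08, 0.01)), "2 replicates")
})

test_that("permutation FDR separates concordant signal from shuffled null", {
  # replicate 2 copies replicate 1 with strong planted effects: permuting
  # destroys concordance, FDR near 0
  # 12 strong concordant genes among 200: a permutation re-pairs a passing
  # rep-1 record with a passing rep-2 record only ~6% of the time
  set.seed(3)
  n <- 200
  dl <- c(rnorm(12, 0.25, 0.02), rnorm(n - 12, 0, 0.01))
  p_adj <- c(runif(12, 0, 0.01), runif(n - 12, 0.5, 1))
  fits <- dplyr::bind_rows(
    tibble::tibble(gene_id = sprintf("g%03d", 1:n), replicate = 1L,
                   delta_lambda = dl, p_adj = p_adj),
    tibble::tibble(gene_id = sprintf("g%03d", 1:n), replicate = 2L,
                   delta_lambda = dl, p_adj = p_adj)
  )
  res <- permutation_fdr(fits, grid = c(0, 0.06, 0.12), n_perm = 50, seed = 2)
  expect_equal(res$real_count, rep(12, 3))
  expect_true(all(res$fdr < 0.2))

  # all-null: real count 0 at high thresholds -> FDR NA by convention
  null_fits <- dplyr::bind_rows(
    tibble::tibble(gene_id = sprintf("g%03d", 1:50), replicate = 1L,
                   delta_lambda = rnorm(50, 0, 0.01), p_adj = runif(50, 0.3, 1)),
    tibble::tibble(gene_id = sprintf("g%03d", 1:50), replicate = 2L,
                   delta_lambda = rnorm(50, 0, 0.01), p_adj = runif(50, 0.3, 1))
  )
  rn <- permutation_fdr(null_fits, grid = 0.06, n_perm = 20, seed = 1)
  expect_equal(rn$real_count, 0)
  expect_true(is.na(rn$fdr))
  expect_error(permutation_fdr(fits, n_perm = 0), "n_perm")
})

test_that("control-gene selection applies all three criteria", {
  fits <- dplyr::bind_rows(
    fits_row("gNull", 1, 0.01, 0.9, p_raw = 0.8, sd = 0.02),
    fits_row("gNull", 2, -0.005, 0.9, p_raw = 0.7, sd = 0.02),
    fits_row("gBigDl", 1, 0.05, 0.9, p_raw = 0.6, sd = 0.02),
    fits_row("gBigDl", 2, 0.01, 0.9, p_raw = 0.6, sd = 0.02),
    fits_row("gNoisy", 1, 0.01, 0.9, p_raw = 0.6, sd = 0.2),
    fits_row("gNoisy", 2, 0.01, 0.9, p_raw = 0.6, sd = 0.02),
    fits_row("gSigP", 1, 0.01, 0.2, p_raw = 0.03, sd = 0.02),
    fits_row("gSigP", 2, 0.01, 0.9, p_raw = 0.6, sd = 0.02)
  )
  ctl <- select_control_genes(fits)
  expect_equal(ctl$gene_id, "gNull")  # 0.05 dl, 0.2 sd and p 0.03 all excluded
})

test_that("tidiers expose broom-style columns", {
  sim <- simulate_cohort(sim_cohort_config(n_genes = 4, seed = 2))
  fits <- fit_allelic_decay(apply_filters(sim$counts), n_boot = 100, seed = 1)
  td <- tidy(fits)
  expect_true(all(c("estimate", "std.error", "p.value", "conf.low",
                    "conf.high") %in% names(td)))
  gl <- glance(fits)
  expect_equal(gl$n_genes, 4)
  expect_equal(gl$n_replicates, 2)
})
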