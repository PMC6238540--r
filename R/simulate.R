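# Synthetic-data generator: allelic count time-courses with full ground
# truth, mock-hybrid bias datasets, and paired allele sequences.
#
# Model: each allele i of a gene starts at N_i(0) transcript copies and
# decays exponentially, N_i(t) = N_i(0) exp(-lambda_i t). The reads
# assignable to allele i at SNP locus s are Poisson with mean
# w_s f(t) N_i(t), where f(t) is the capture fraction shared by both
# alleles (it cancels from the allelic proportion) and w_s a per-SNP
# sampling weight reflecting uneven coverage along the transcript.

#' Ground truth for one simulated gene
#'
#' @param gene_id Gene identifier.
#' @param N1_0,N2_0 Initial transcript copies per allele (positive).
#' @param lambda1,lambda2 Decay rates per hour (non-negative).
#' @param capture_fractions Named numeric vector mapping timepoint (hours,
#'   as character or numeric names) to the capture fraction f(t) in (0, 1].
#'   A single unnamed value recycles to all timepoints. Default 1.
#' @param snp_weights Positive per-SNP relative sampling weights; length
#'   defines the number of SNP loci.
#' @param seed Integer seed for this gene's random stream.
#' @return A `sim_truth` list with fields as given plus `delta_lambda_true`
#'   and `n_snps`.
#' @export
sim_truth <- function(gene_id, N1_0, N2_0, lambda1, lambda2,
                      capture_fractions = 1, snp_weights = rep(1, 5),
                      seed = 1L) {
  assert_that(N1_0 > 0 && N2_0 > 0, "initial copy numbers must be positive")
  assert_that(lambda1 >= 0 && lambda2 >= 0, "decay rates must be non-negative")
  assert_that(all(capture_fractions > 0) && all(capture_fractions <= 1),
              "capture fractions must lie in (0, 1]")
  assert_that(all(snp_weights > 0), "SNP weights must be positive")
  dl <- lambda1 - lambda2
  assert_that(is.finite(dl), "delta lambda must be finite")
  structure(list(gene_id = as.character(gene_id), N1_0 = N1_0, N2_0 = N2_0,
                 lambda1 = lambda1, lambda2 = lambda2,
                 delta_lambda_true = dl,
                 capture_fractions = capture_fractions,
                 snp_weights = as.numeric(snp_weights),
                 n_snps = length(snp_weights), seed = as.integer(seed)),
            class = "sim_truth")
}

capture_at <- function(truth, timepoints) {
  f <- truth$capture_fractions
  if (is.null(names(f))) {
    assert_that(length(f) %in% c(1L, length(timepoints)),
                "capture_fractions must be scalar, per-timepoint, or named")
    return(rep_len(f, length(timepoints)))
  }
  idx <- match(format(timepoints), format(as.numeric(names(f))))
  assert_that(!anyNA(idx), "capture_fractions missing a timepoint")
  unname(f[idx])
}

# Allele stream key derived from the allele's own parameters so the
# generator is label-symmetric: swapping (N1_0, lambda1) with (N2_0,
# lambda2) swaps the count columns exactly. Slot index breaks the tie only
# when both alleles are identical (where a swap is the identity anyway).
allele_stream_key <- function(N0, lambda, other_N0, other_lambda, slot) {
  key <- paste(format(c(N0, lambda), digits = 17), collapse = ",")
  if (isTRUE(all.equal(c(N0, lambda), c(other_N0, other_lambda)))) {
    key <- paste0(key, "#", slot)
  }
  key
}

#' Simulate the allelic count time-course of one gene
#'
#' Draws, for every SNP locus, replicate and timepoint, independent Poisson
#' counts for each allele with mean `w_s f(t) N_i(0) exp(-lambda_i t)`.
#' Deterministic given `truth$seed`.
#'
#' @param truth A [sim_truth()] object.
#' @param timepoints Hours, strictly increasing, starting at 0.
#' @param n_replicates Number of independent replicates (re-draws from the
#'   same truth).
#' @return Counts tibble following [counts_schema()]; the truth is attached
#'   as attribute `"truth"`.
#' @export
simulate_gene_counts <- function(truth, timepoints = c(0, 0.5, 1.5),
                                 n_replicates = 2L) {
  stopifnot(inherits(truth, "sim_truth"))
  check_timepoints(timepoints)
  f <- capture_at(truth, timepoints)
  w <- truth$snp_weights
  mean1 <- outer(w, f * truth$N1_0 * exp(-truth$lambda1 * timepoints))
  mean2 <- outer(w, f * truth$N2_0 * exp(-truth$lambda2 * timepoints))
  assert_that(sum(mean1) + sum(mean2) > 0, "zero total expected reads")

  draw_allele <- function(mu, slot, N0, lambda, oN0, olambda, rep_i) {
    key <- allele_stream_key(N0, lambda, oN0, olambda, slot)
    with_seed(derive_seed(truth$seed, truth$gene_id, "counts", rep_i, key),
              matrix(rpois(length(mu), mu), nrow = nrow(mu)))
  }

  n_snps <- truth$n_snps
  per_rep <- map(seq_len(n_replicates), function(r) {
    c1 <- draw_allele(mean1, 1L, truth$N1_0, truth$lambda1,
                      truth$N2_0, truth$lambda2, r)
    c2 <- draw_allele(mean2, 2L, truth$N2_0, truth$lambda2,
                      truth$N1_0, truth$lambda1, r)
    tibble(
      gene_id = truth$gene_id,
      snp_id = rep(sprintf("%s_s%02d", truth$gene_id, seq_len(n_snps)),
                   times = length(timepoints)),
      chrom = truth$gene_id,
      pos = rep(100L * seq_len(n_snps), times = length(timepoints)),
      region = NA_character_,
      replicate = as.integer(r),
      time_h = rep(timepoints, each = n_snps),
      n_allele1 = as.integer(c1),
      n_allele2 = as.integer(c2)
    )
  })
  out <- list_rbind(per_rep)
  attr(out, "truth") <- truth
  out
}

#' Cohort simulation configuration
#'
#' Defaults mirror the study design this generator emulates: timepoints 0,
#' 0.5 and 1.5 h after transcriptional arrest, two replicates, and at least
#' five SNP loci per gene.
#'
#' @param n_genes Number of genes.
#' @param fraction_asd Fraction of genes with a planted decay-rate
#'   difference; planting is deterministic by count (see Details).
#' @param delta_lambda_values Values (per hour) from which each planted
#'   ASD gene's delta lambda is drawn uniformly; a single value is a point
#'   mass.
#' @param fraction_asa Fraction of genes with a planted initial-abundance
#'   offset.
#' @param asa_log2_offsets Values (log2 scale) from which each planted ASA
#'   gene's `log2(N1_0 / N2_0)` is drawn uniformly.
#' @param depth_per_snp Expected total reads (both alleles) per
#'   average-weight SNP at t = 0.
#' @param timepoints Hours, strictly increasing from 0.
#' @param n_replicates Replicates per timepoint.
#' @param snps_per_gene Integer (constant) or function(n) returning integer
#'   SNP counts per gene; minimum 1.
#' @param base_lambda Shared baseline decay rate per hour; allele rates are
#'   `base_lambda +/- delta_lambda / 2`.
#' @param snp_weight_sdlog SD (log scale) of the i.i.d. LogNormal per-SNP
#'   weights; weights are renormalised to mean 1 within each gene.
#' @param capture_fractions Capture fraction f(t); default 1 at all
#'   timepoints (it cancels from the allelic proportion).
#' @param seed Global integer seed; per-gene streams are derived by stable
#'   hashing of (seed, gene id).
#' @return A `sim_cohort_config` list.
#' @details Planted-gene selection is deterministic by count: after a seeded
#'   shuffle of gene ids, the first `floor(fraction * n_genes)` genes carry
#'   the effect, so the planted composition is exact. ASD and ASA planting
#'   use independent shuffles and may overlap.
#' @export
sim_cohort_config <- function(n_genes = 100, fraction_asd = 0,
                              delta_lambda_values = c(-0.3, 0.3),
                              fraction_asa = 0,
                              asa_log2_offsets = c(-1.5, 1.5),
                              depth_per_snp = 200,
                              timepoints = c(0, 0.5, 1.5),
                              n_replicates = 2L, snps_per_gene = 8L,
                              base_lambda = 0.3, snp_weight_sdlog = 0.5,
                              capture_fractions = 1, seed = 1L) {
  assert_that(fraction_asd >= 0 && fraction_asd <= 1 &&
                fraction_asa >= 0 && fraction_asa <= 1,
              "fractions must lie in [0, 1]")
  assert_that(depth_per_snp >= 1, "depth_per_snp must be >= 1")
  assert_that(length(delta_lambda_values) >= 1 &&
                all(is.finite(delta_lambda_values)),
              "delta_lambda_values must be finite")
  assert_that(all(abs(delta_lambda_values) / 2 <= base_lambda) ||
                fraction_asd == 0,
              "planted |delta lambda|/2 exceeds base_lambda (negative rate)")
  check_timepoints(timepoints)
  structure(list(n_genes = as.integer(n_genes), fraction_asd = fraction_asd,
                 delta_lambda_values = delta_lambda_values,
                 fraction_asa = fraction_asa,
                 asa_log2_offsets = asa_log2_offsets,
                 depth_per_snp = depth_per_snp, timepoints = timepoints,
                 n_replicates = as.integer(n_replicates),
                 snps_per_gene = snps_per_gene, base_lambda = base_lambda,
                 snp_weight_sdlog = snp_weight_sdlog,
                 capture_fractions = capture_fractions,
                 seed = as.integer(seed)),
            class = "sim_cohort_config")
}

#' Simulate a cohort of genes with planted effects
#'
#' @param config A [sim_cohort_config()].
#' @return List with `counts` (tibble, [counts_schema()]) and `truth`
#'   (tibble: gene_id, N1_0, N2_0, lambda1, lambda2, delta_lambda_true,
#'   asa_log2_offset, asd_planted, asa_planted, n_snps).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_cohort_config"))
  n <- config$n_genes
  gene_ids <- sprintf("g%05d", seq_len(n))

  n_asd <- floor(config$fraction_asd * n)
  n_asa <- floor(config$fraction_asa * n)
  asd_genes <- with_seed(derive_seed(config$seed, "plant_asd"),
                         head(sample(gene_ids), n_asd))
  asa_genes <- with_seed(derive_seed(config$seed, "plant_asa"),
                         head(sample(gene_ids), n_asa))

  dl <- setNames(rep(0, n), gene_ids)
  if (n_asd > 0) {
    vals <- config$delta_lambda_values
    dl[asd_genes] <- with_seed(
      derive_seed(config$seed, "dl_values"),
      vals[sample.int(length(vals), n_asd, replace = TRUE)])
  }
  off <- setNames(rep(0, n), gene_ids)
  if (n_asa > 0) {
    offs <- config$asa_log2_offsets
    off[asa_genes] <- with_seed(
      derive_seed(config$seed, "asa_values"),
      offs[sample.int(length(offs), n_asa, replace = TRUE)])
  }

  snp_n <- if (is.function(config$snps_per_gene)) {
    with_seed(derive_seed(config$seed, "snp_n"), config$snps_per_gene(n))
  } else rep(as.integer(config$snps_per_gene), n)
  assert_that(all(snp_n >= 1), "snps_per_gene must be >= 1")

  truths <- map(seq_len(n), function(i) {
    g <- gene_ids[i]
    w <- with_seed(derive_seed(config$seed, g, "weights"),
                   rlnorm(snp_n[i], 0, config$snp_weight_sdlog))
    w <- w / mean(w)
    ratio <- 2^off[g]
    N1 <- config$depth_per_snp * ratio / (1 + ratio)
    N2 <- config$depth_per_snp / (1 + ratio)
    sim_truth(g, N1_0 = N1, N2_0 = N2,
              lambda1 = config$base_lambda + dl[g] / 2,
              lambda2 = config$base_lambda - dl[g] / 2,
              capture_fractions = config$capture_fractions,
              snp_weights = w, seed = derive_seed(config$seed, g))
  })

  counts <- list_rbind(map(truths, simulate_gene_counts,
                           timepoints = config$timepoints,
                           n_replicates = config$n_replicates))
  truth_tbl <- list_rbind(map(truths, function(tr) {
    tibble(gene_id = tr$gene_id, N1_0 = tr$N1_0, N2_0 = tr$N2_0,
           lambda1 = tr$lambda1, lambda2 = tr$lambda2,
           delta_lambda_true = tr$delta_lambda_true,
           asa_log2_offset = log2(tr$N1_0 / tr$N2_0),
           asd_planted = tr$gene_id %in% asd_genes,
           asa_planted = tr$gene_id %in% asa_genes,
           n_snps = tr$n_snps)
  }))
  list(counts = counts, truth = truth_tbl, truths = truths)
}

#' Simulate a mock F1-hybrid bias dataset
#'
#' Emulates the mapping-bias diagnostic: for each SNP locus, counts of reads
#' assigned to the two parental strains in the original parental datasets
#' (columns a, b) and to the two alleles in the in-silico mock hybrid
#' (columns c, d). Unbiased loci share one binomial proportion between the
#' two tables; biased loci have the mock proportion shifted.
#'
#' @param n_loci Number of SNP loci.
#' @param biased_fraction Fraction of loci with a planted assignment bias.
#' @param depth Expected read depth per locus per dataset.
#' @param shift Additive shift of the mock allelic proportion at biased loci.
#' @param p0 Baseline allele-1 proportion.
#' @param seed Integer seed.
#' @return List with `bias_table` (snp_id, ctx = "parental_mock", a, b, c,
#'   d) and `truth` (snp_id, biased).
#' @export
simulate_mock_hybrid <- function(n_loci, biased_fraction = 0.1, depth = 200,
                                 shift = 0.2, p0 = 0.5, seed = 1L) {
  assert_that(biased_fraction >= 0 && biased_fraction <= 1,
              "biased_fraction must lie in [0, 1]")
  assert_that(depth >= 1, "depth must be >= 1")
  n_biased <- floor(biased_fraction * n_loci)
  ids <- sprintf("snp%05d", seq_len(n_loci))
  biased_ids <- with_seed(derive_seed(seed, "plant_bias"),
                          head(sample(ids), n_biased))
  biased <- ids %in% biased_ids
  p_mock <- pmin(pmax(p0 + shift * biased, 0), 1)
  tabs <- with_seed(derive_seed(seed, "mock_counts"), {
    tot_par <- rpois(n_loci, depth)
    a <- rbinom(n_loci, tot_par, p0)
    tot_mock <- rpois(n_loci, depth)
    cc <- rbinom(n_loci, tot_mock, p_mock)
    tibble(snp_id = ids, ctx = "parental_mock",
           a = a, b = tot_par - a, c = cc, d = tot_mock - cc)
  })
  list(bias_table = tabs, truth = tibble(snp_id = ids, biased = biased))
}

#' Simulate a pair of allele sequences differing only at given SNPs
#'
#' @param length Transcript length (nt).
#' @param snp_positions 1-based positions of substitutions; must be unique
#'   and within the transcript.
#' @param seed Integer seed.
#' @param region_map Optional tibble (region, start, end; 1-based inclusive)
#'   partitioning the transcript into UTR5/CDS/UTR3. Default: 20% UTR5, 50%
#'   CDS, 30% UTR3.
#' @param gene_id Gene identifier used in all outputs.
#' @return List with `pair` (gene_id, seq_allele1, seq_allele2), `variants`
#'   (gene_id, pos, ref, alt) and `regions` (gene_id, region, start, end).
#' @export
simulate_allele_sequences <- function(length, snp_positions, seed = 1L,
                                      region_map = NULL, gene_id = "gene1") {
  assert_that(all(snp_positions >= 1 & snp_positions <= length),
              "snp_positions must lie within [1, length]")
  assert_that(!anyDuplicated(snp_positions), "duplicate snp_positions")
  bases <- c("A", "C", "G", "T")
  seq1 <- with_seed(derive_seed(seed, gene_id, "seq"),
                    sample(bases, length, replace = TRUE))
  seq2 <- seq1
  if (length(snp_positions) > 0) {
    subs <- with_seed(derive_seed(seed, gene_id, "subs"), {
      vapply(seq1[snp_positions], function(b) sample(setdiff(bases, b), 1),
             character(1))
    })
    seq2[snp_positions] <- subs
  }
  if (is.null(region_map)) {
    b1 <- max(1L, floor(0.2 * length))
    b2 <- max(b1 + 1L, floor(0.7 * length))
    region_map <- tibble(region = c("UTR5", "CDS", "UTR3"),
                         start = c(1L, b1 + 1L, b2 + 1L),
                         end = c(b1, b2, as.integer(length)))
    region_map <- filter(region_map, .data$start <= .data$end)
  }
  list(
    pair = tibble(gene_id = gene_id,
                  seq_allele1 = paste(seq1, collapse = ""),
                  seq_allele2 = paste(seq2, collapse = "")),
    variants = tibble(gene_id = gene_id,
                      pos = as.integer(sort(snp_positions)),
                      ref = seq1[sort(snp_positions)],
                      alt = seq2[sort(snp_positions)]),
    regions = mutate(region_map, gene_id = gene_id, .before = 1)
  )
}
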