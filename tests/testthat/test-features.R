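test_that("SNP density counts per kb, whole transcript and per region", {
  expect_equal(snp_density(1:10, span_length = 2000), 5.0)
  expect_equal(snp_density(integer(0), span_length = 1000), 0.0)
  regions <- tibble::tibble(region = c("UTR5", "CDS", "UTR3"),
                            start = c(1L, 401L, 1001L),
                            end = c(400L, 1000L, 2000L))
  # 3 SNPs inside a 600 nt CDS within a 2 kb transcript
  expect_equal(snp_density(c(100, 450, 500, 999, 1500), regions = regions,
                           region = "CDS"), 5.0)
  expect_warning(d <- snp_density(1:3, regions = regions, region = "intron"),
                 "no intron")
  expect_true(is.na(d))
})

test_that("miRNA site counting matches the brute-force scan on random targets", {
  seeds <- tibble::tibble(mirna_id = "mir", sequence = "AGGAAUGUUUUAAUGCCCCUAG",
                          expression_rank = 1L)
  # positions 2-8 = GGAAUGU; an 8mer site counts once, with no extra 7mers
  hit8 <- count_mirna_sites("GGGACAUUCCAGG", seeds)
  expect_equal(unlist(hit8[, c("n_8mer", "n_7mer_m8", "n_7mer_1A")]),
               c(n_8mer = 1L, n_7mer_m8 = 0L, n_7mer_1A = 0L))
  # m8 match without the A: 7mer-m8
  hitm8 <- count_mirna_sites("GGGACAUUCCGGG", seeds)
  expect_equal(hitm8$n_7mer_m8, 1L)
  expect_equal(hitm8$n_8mer, 0L)
  # core match plus A but mismatched m8: 7mer-1A
  hit1a <- count_mirna_sites("GGGUCAUUCCAGG", seeds)
  expect_equal(hit1a$n_7mer_1A, 1L)
  # no 6mer complement anywhere: zero sites
  expect_equal(attr(count_mirna_sites("AAAAAAAAAAAAAAA", seeds), "total"), 0L)
  expect_error(count_mirna_sites("ACGU", tibble::tibble(
    mirna_id = "x", sequence = "ACGUACG", expression_rank = 1L)), "8 nt")

  set.seed(20)
  mirnas <- random_rna(5, 21)
  seeds5 <- tibble::tibble(mirna_id = paste0("m", 1:5), sequence = mirnas,
                           expression_rank = 1:5)
  for (target in random_rna(40, 200)) {
    got <- count_mirna_sites(target, seeds5)
    for (i in 1:5) {
      expect_equal(unlist(got[i, c("n_8mer", "n_7mer_m8", "n_7mer_1A")]),
                   oracle_mirna_counts(target, mirnas[i]),
                   info = paste(target, mirnas[i]))
    }
  }
  # top_k restricts to the most highly expressed seeds
  expect_equal(nrow(count_mirna_sites("ACGUACGUACGU", seeds5, top_k = 2)), 2)
})

test_that("stable/unstable site differences filter and test as specified", {
  # all-zero differences: median 0, symmetric
  flat <- tibble::tibble(gene_id = paste0("g", 1:10), group = "ASD",
                         stable_count = 6L, unstable_count = 6L)
  expect_warning(r0 <- site_difference_test(flat, min_diff = 0), "fewer")

  # planted destabilising sites on the unstable allele: negative median,
  # MWU against symmetric controls significant at n = 100
  set.seed(5)
  n <- 100
  base <- rpois(2 * n, 8)
  extra <- rpois(n, 3) + 1
  asd <- tibble::tibble(gene_id = paste0("a", 1:n), group = "ASD",
                        stable_count = base[1:n],
                        unstable_count = base[1:n] + extra)
  flip <- sample(c(-1L, 1L), n, replace = TRUE)
  ctl_diff <- (rpois(n, 2) + 1) * flip  # symmetric by construction
  ctl <- tibble::tibble(gene_id = paste0("c", 1:n), group = "control",
                        stable_count = base[n + 1:n] + pmax(ctl_diff, 0),
                        unstable_count = base[n + 1:n] - pmin(ctl_diff, 0))
  res <- site_difference_test(dplyr::bind_rows(asd, ctl),
                              min_total = 10, min_diff = 1)
  expect_lt(res$test$median_diff_asd, 0)
  expect_lt(res$test$mwu_p, 0.05)
  expect_gt(res$test$sign_p_control, 0.01)

  # the two filters drop low-information genes
  few <- tibble::tibble(gene_id = c("x", "y"), group = "ASD",
                        stable_count = c(3L, 20L), unstable_count = c(3L, 20L))
  expect_warning(rf <- site_difference_test(few), "fewer")
  expect_equal(nrow(rf$genes), 0)  # x fails min_total, y fails min_diff
})

test_that("nussinov_fold equals exhaustive structure enumeration", {
  expect_equal(nussinov_fold("AAAA"), 0)
  expect_equal(nussinov_fold("GGGAAACCC"), -3)
  expect_error(nussinov_fold("ACGX"), "alphabet")
  # all strings of length 6 and a seeded sample of longer ones
  bases <- c("A", "C", "G", "U")
  len6 <- apply(expand.grid(rep(list(bases), 6)), 1, paste, collapse = "")
  for (s in len6[seq(1, length(len6), by = 7)]) {
    expect_equal(nussinov_fold(s), -oracle_max_pairs(s), info = s)
  }
  set.seed(8)
  for (s in random_rna(60, 10)) {
    expect_equal(nussinov_fold(s), -oracle_max_pairs(s), info = s)
  }
  # anti-monotone under extension by a pairable closing base
  set.seed(9)
  for (s in random_rna(20, 8)) {
    first <- substr(s, 1, 1)
    closer <- c(A = "U", C = "G", G = "C", U = "A")[[first]]
    expect_lte(nussinov_fold(paste0(s, closer)), nussinov_fold(s))
  }
})

test_that("delta-MFE windows are centred, boundary-shifted and label-symmetric", {
  sim <- simulate_allele_sequences(600, c(5, 300, 590), seed = 3,
                                   gene_id = "gW")
  res <- mfe_windows(sim$pair, sim$variants, window = 41)
  # interior variant: centred with both flanks of 20 nt
  mid <- res[res$pos == 300, ]
  expect_equal(c(mid$start, mid$end), c(280L, 320L))
  # variant 5 nt from the start: window shifted to abut the end
  expect_equal(c(res$start[res$pos == 5], res$end[res$pos == 5]), c(1L, 41L))
  expect_equal(c(res$start[res$pos == 590], res$end[res$pos == 590]),
               c(560L, 600L))
  expect_true(all(res$end - res$start + 1 == 41))

  # allele-label swap: dmfe negates, max |dMFE| invariant
  swapped <- sim$pair
  names(swapped)[2:3] <- names(swapped)[3:2]
  res_sw <- mfe_windows(swapped, sim$variants, window = 41)
  expect_equal(res_sw$dmfe, -res$dmfe)
  expect_equal(attr(res_sw, "gene_summary")$max_abs_dmfe,
               attr(res, "gene_summary")$max_abs_dmfe)

  # identical windows in both alleles give exactly zero
  no_snp <- simulate_allele_sequences(200, integer(0), seed = 4, gene_id = "g0")
  vars <- tibble::tibble(gene_id = "g0", pos = 100L, ref = "A", alt = "A")
  expect_equal(mfe_windows(no_snp$pair, vars, window = 21)$dmfe, 0)

  # transcript shorter than the window: whole transcript used, flagged
  short <- simulate_allele_sequences(30, 15, seed = 5, gene_id = "gShort")
  expect_warning(rs <- mfe_windows(short$pair, short$variants, window = 41),
                 "shorter")
  expect_true(rs$truncated)
  expect_equal(c(rs$start, rs$end), c(1L, 30L))

  # per-region summary uses the region map
  resr <- mfe_windows(sim$pair, sim$variants, window = 41,
                      regions = sim$regions)
  expect_true(all(!is.na(resr$region)))
  expect_equal(max(abs(resr$dmfe)),
               max(attr(resr, "region_summary")$max_abs_dmfe))
})

test_that("CAI is the geometric mean over informative codons", {
  w <- c(GCT = 0.5, GCA = 1.0, AAA = 1.0, AAG = 0.25)
  expect_equal(cai("GCTGCA", w), sqrt(0.5))
  expect_equal(cai("GCAAAA", w), 1.0)              # maximal-weight codons
  expect_equal(cai("GCTGCAATGTGG", w), sqrt(0.5))  # Met/Trp excluded
  expect_warning(v <- cai("GCTTAAGCA", w), "stop")
  expect_equal(v, sqrt(0.5))
  # synonymous-order permutation invariance
  expect_equal(cai("GCTGCAAAG", w), cai("AAGGCAGCT", w))
  expect_error(cai("GCTG", w), "divisible")
  expect_error(cai("CCC", w), "lacks")
})

test_that("bundled synthetic seed and weight tables load and score", {
  seeds <- read_mirna_seeds(system.file("extdata", "mirna_seeds_synthetic.tsv",
                                        package = "asdecay"))
  expect_equal(nrow(seeds), 10)
  expect_true(all(nchar(seeds$sequence) >= 8))
  counts <- count_mirna_sites(paste(rep("ACGU", 50), collapse = ""), seeds,
                              top_k = 3)
  expect_equal(nrow(counts), 3)

  w <- read_cai_weights(system.file("extdata", "cai_weights_synthetic.tsv",
                                    package = "asdecay"))
  expect_equal(length(w), 64)
  v <- cai("GCTGCAGGT", w)
  expect_true(v > 0 && v <= 1)
  expect_equal(v, exp(mean(log(w[c("GCT", "GCA", "GGT")]))))
})

test_that("group comparisons wrap KS and exact/approximate MWU correctly", {
  x <- c(1.2, 3.4, 2.2, 0.1, 5.5)
  ks <- compare_groups(x, x, "KS_two_sided")
  expect_equal(ks$statistic, 0)
  expect_equal(ks$p, 1)
  # U = 0 with full enumeration: p = 2/6
  mwu <- compare_groups(c(1, 2), c(3, 4), "MWU_two_sided")
  expect_equal(mwu$statistic, 0)
  expect_equal(mwu$p, 1 / 3, tolerance = 1e-12)
  # location shift of 1 SD at n = 200 is overwhelmingly significant
  set.seed(2)
  a <- rnorm(200); b <- rnorm(200, 1)
  expect_lt(compare_groups(a, b, "KS_two_sided")$p, 1e-3)
  expect_lt(compare_groups(a, b, "MWU_two_sided")$p, 1e-3)
  expect_error(compare_groups(numeric(0), a), "n >= 2")
})

test_that("density matching reproduces the ASD distribution", {
  set.seed(14)
  asd <- rgamma(80, 2, 0.5)
  # pool = ASD set itself: a permutation of it
  perm <- select_matched_controls(asd, asd, seed = 3)
  expect_setequal(perm, seq_along(asd))
  # seeded determinism
  pool <- rgamma(800, 1.2, 0.3)
  s1 <- select_matched_controls(pool, asd, seed = 5)
  expect_identical(s1, select_matched_controls(pool, asd, seed = 5))
  expect_equal(length(s1), length(asd))
  expect_equal(anyDuplicated(s1), 0)
  # matched subset passes a KS test against the ASD densities in most runs
  ok <- vapply(1:20, function(s) {
    idx <- select_matched_controls(pool, asd, seed = s)
    suppressWarnings(ks.test(pool[idx], asd)$p.value) > 0.05
  }, logical(1))
  expect_gte(mean(ok), 0.95)
  # strict mode errors on an under-filled bin
  tiny_pool <- rep(median(asd), 80)
  expect_error(
    suppressWarnings(select_matched_controls(tiny_pool, asd, seed = 1,
                                             strict = TRUE)),
    "under-filled")
})
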