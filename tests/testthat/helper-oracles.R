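# Independent oracles and fixture builders used across the suite.

# --- Fisher exact: full hypergeometric enumeration via choose() ----------
# Probability of each table with the observed margins; two-sided p sums the
# probabilities not exceeding the observed table's.
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; k <- a + c; n <- r1 + r2
  support <- max(0, k - r2):min(r1, k)
  probs <- choose(r1, support) * choose(r2, k - support) / choose(n, k)
  p_obs <- probs[match(a, support)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

# --- BH: direct step-up formula ------------------------------------------
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# --- Nussinov: exhaustive enumeration of all nested structures -----------
# Recursively enumerates every nested set of AU/GC/GU pairs with hairpin
# loops >= min_loop and returns the maximum pair count (no memoisation).
oracle_max_pairs <- function(seq, min_loop = 3) {
  s <- strsplit(gsub("T", "U", toupper(seq)), "")[[1]]
  ok <- function(x, y) {
    paste0(x, y) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  }
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(0L)
    best <- rec(i + 1L, j)                      # i unpaired
    for (k in (i + min_loop + 1L):j) {
      if (ok(s[i], s[k])) {
        best <- max(best, 1L + rec(i + 1L, k - 1L) + rec(k + 1L, j))
      }
    }
    best
  }
  n <- length(s)
  if (n < min_loop + 2) 0L else rec(1L, n)
}

# --- miRNA sites: naive substring scan -----------------------------------
# Re-derives the three site types by direct string comparison at every
# target offset, independent of the package's regex-based scanner.
oracle_mirna_counts <- function(target, mirna) {
  comp <- function(x) chartr("ACGU", "UGCA", x)
  rc <- function(x) paste(rev(strsplit(comp(x), "")[[1]]), collapse = "")
  target <- gsub("T", "U", toupper(target))
  mirna <- gsub("T", "U", toupper(mirna))
  core6 <- rc(substr(mirna, 2, 7))
  m8 <- comp(substr(mirna, 8, 8))
  L <- nchar(target)
  n8 <- n7m8 <- n7a <- 0L
  if (L >= 6) {
    for (p in 1:(L - 5)) {
      if (substr(target, p, p + 5) != core6) next
      has_m8 <- p > 1 && substr(target, p - 1, p - 1) == m8
      has_a <- p + 6 <= L && substr(target, p + 6, p + 6) == "A"
      if (has_m8 && has_a) n8 <- n8 + 1L
      else if (has_m8) n7m8 <- n7m8 + 1L
      else if (has_a) n7a <- n7a + 1L
    }
  }
  c(n_8mer = n8, n_7mer_m8 = n7m8, n_7mer_1A = n7a)
}

# --- Count-table builders -------------------------------------------------
# Long-format counts tibble from per-replicate allele count matrices
# (SNPs x timepoints).
make_counts <- function(gene_id, c1, c2, timepoints = c(0, 0.5, 1.5),
                        replicate = 1L) {
  stopifnot(identical(dim(c1), dim(c2)))
  n <- nrow(c1)
  tibble::tibble(
    gene_id = gene_id,
    snp_id = rep(sprintf("%s_s%02d", gene_id, seq_len(n)),
                 times = length(timepoints)),
    chrom = gene_id,
    pos = rep(100L * seq_len(n), times = length(timepoints)),
    region = NA_character_,
    replicate = as.integer(replicate),
    time_h = rep(timepoints, each = n),
    n_allele1 = as.integer(c1),
    n_allele2 = as.integer(c2)
  )
}

# Noise-free counts realising exactly the binomial proportion
# p(t) = R exp(-dl t) / (R exp(-dl t) + 1), identical across SNPs.
make_noise_free_gene <- function(gene_id = "gX", dl = 0.3, R = 1,
                                 total = 1e6, n_snps = 5,
                                 timepoints = c(0, 0.5, 1.5),
                                 replicates = 1:2) {
  p <- R * exp(-dl * timepoints) / (R * exp(-dl * timepoints) + 1)
  c1 <- matrix(rep(round(total * p), each = n_snps), nrow = n_snps)
  c2 <- matrix(rep(total, n_snps * length(timepoints)), nrow = n_snps) - c1
  dplyr::bind_rows(lapply(replicates, function(r) {
    make_counts(gene_id, c1, c2, timepoints, replicate = r)
  }))
}

random_rna <- function(n, len) {
  len <- rep_len(len, n)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "U"), len[i], replace = TRUE), collapse = "")
  }, character(1))
}
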