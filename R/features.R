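# Allele-level sequence features: SNP density, miRNA seed-site counting,
# windowed secondary-structure differences (delta-MFE), codon adaptation
# index, and the stable-vs-unstable-allele comparison statistics.

RNA_BASES <- c("A", "C", "G", "U")

normalize_rna <- function(seq) {
  s <- gsub("T", "U", toupper(seq), fixed = TRUE)
  if (nchar(s) > 0) {
    assert_that(all(strsplit(s, "")[[1]] %in% RNA_BASES),
                "sequence contains characters outside the RNA alphabet")
  }
  s
}

rna_complement <- function(seq) {
  chartr("ACGU", "UGCA", seq)
}

rna_revcomp <- function(seq) {
  paste(rev(strsplit(rna_complement(seq), "")[[1]]), collapse = "")
}

#' SNP density in SNPs per kilobase
#'
#' @param positions 1-based variant positions (transcript coordinates).
#' @param span_length Length in nt of the whole transcript; required when
#'   `region = "whole"`.
#' @param regions Optional tibble (region, start, end; 1-based inclusive)
#'   used when `region` names a transcript region.
#' @param region `"whole"` (default), `"UTR5"`, `"CDS"` or `"UTR3"`.
#' @return SNPs per kb over the chosen span; `NA` (with a warning) when the
#'   span has zero length or the region is absent.
#' @export
snp_density <- function(positions, span_length = NULL, regions = NULL,
                        region = "whole") {
  if (region == "whole") {
    assert_that(!is.null(span_length) && span_length >= 0,
                "span_length required for whole-transcript density")
    if (span_length == 0) {
      warn("snp_density: zero-length span, returning NA")
      return(NA_real_)
    }
    return(1000 * length(positions) / span_length)
  }
  assert_that(!is.null(regions), "regions table required for region density")
  row <- filter(regions, .data$region == !!region)
  if (nrow(row) == 0) {
    warn(sprintf("snp_density: no %s annotation, returning NA", region))
    return(NA_real_)
  }
  span <- sum(row$end - row$start + 1)
  if (span <= 0) {
    warn("snp_density: zero-length region, returning NA")
    return(NA_real_)
  }
  n <- sum(vapply(positions, function(p) any(p >= row$start & p <= row$end),
                  logical(1)))
  1000 * n / span
}

#' Count canonical miRNA seed sites in a target sequence
#'
#' Scans the target (5'->3') for reverse-complement matches to each
#' miRNA's seed. Every match of the core 6mer (miRNA positions 2-7) is one
#' candidate site, typed by its flanks and counted once under its best
#' type: 8mer (positions 2-8 matched and an A opposite position 1),
#' 7mer-m8 (positions 2-8 matched), 7mer-1A (positions 2-7 matched plus
#' the A); plain 6mers are not counted.
#'
#' @param target_seq Target sequence (RNA or DNA alphabet; T and U are
#'   interchangeable).
#' @param seeds Tibble with columns mirna_id, sequence (the miRNA, 5'->3',
#'   length >= 8), expression_rank.
#' @param top_k Restrict to the `top_k` most highly expressed miRNAs
#'   (smallest expression_rank). Default: all.
#' @return Tibble: mirna_id, n_8mer, n_7mer_m8, n_7mer_1A, n_sites;
#'   attribute `"total"` holds the summed site count over all seeds.
#' @export
count_mirna_sites <- function(target_seq, seeds, top_k = NULL) {
  target <- normalize_rna(target_seq)
  assert_that(all(nchar(seeds$sequence) >= 8),
              "every miRNA sequence must be at least 8 nt")
  if (!is.null(top_k)) {
    seeds <- seeds |> arrange(.data$expression_rank) |> head(top_k)
  }
  L <- nchar(target)
  chars <- strsplit(target, "")[[1]]
  rows <- map(seq_len(nrow(seeds)), function(i) {
    mir <- normalize_rna(seeds$sequence[i])
    core6 <- rna_revcomp(substr(mir, 2, 7))
    m8_base <- rna_complement(substr(mir, 8, 8))
    starts <- if (L >= 6) {
      as.integer(gregexpr(paste0("(?=", core6, ")"), target,
                          perl = TRUE)[[1]])
    } else -1L
    starts <- starts[starts > 0]
    n8 <- n7m8 <- n7a <- 0L
    for (p in starts) {
      has_m8 <- p > 1 && chars[p - 1] == m8_base
      has_a <- p + 6 <= L && chars[p + 6] == "A"
      if (has_m8 && has_a) n8 <- n8 + 1L
      else if (has_m8) n7m8 <- n7m8 + 1L
      else if (has_a) n7a <- n7a + 1L
    }
    tibble(mirna_id = seeds$mirna_id[i], n_8mer = n8, n_7mer_m8 = n7m8,
           n_7mer_1A = n7a, n_sites = n8 + n7m8 + n7a)
  })
  out <- list_rbind(rows)
  attr(out, "total") <- sum(out$n_sites)
  out
}

#' Compare per-gene site counts between stable and unstable alleles
#'
#' Keeps genes with at least `min_total` sites over the two alleles
#' combined and at least `min_diff` differing sites, computes the per-gene
#' (stable - unstable) difference, and tests the ASD group against the
#' control group (whose "stable" labels are random) with a two-sided
#' Mann-Whitney U test; per-group sign tests are reported as diagnostics.
#'
#' @param site_counts Tibble with columns gene_id, group (`"ASD"` /
#'   `"control"`), stable_count, unstable_count.
#' @param min_total Minimum combined site count. Default 10.
#' @param min_diff Minimum absolute between-allele difference. Default 1.
#' @return List with `genes` (filtered per-gene differences) and `test`
#'   (one-row tibble: n_asd, n_control, median_diff_asd,
#'   median_diff_control, mwu_statistic, mwu_p, sign_p_asd,
#'   sign_p_control). `mwu_p` is NA (with a warning) when a post-filter
#'   group has fewer than 5 genes.
#' @export
site_difference_test <- function(site_counts, min_total = 10, min_diff = 1) {
  assert_that(all(site_counts$group %in% c("ASD", "control")),
              "group must be 'ASD' or 'control'")
  genes <- site_counts |>
    mutate(total = .data$stable_count + .data$unstable_count,
           diff = .data$stable_count - .data$unstable_count) |>
    filter(.data$total >= min_total, abs(.data$diff) >= min_diff)
  asd <- genes$diff[genes$group == "ASD"]
  ctl <- genes$diff[genes$group == "control"]
  sign_p <- function(d) {
    d <- d[d != 0]
    if (length(d) == 0) return(NA_real_)
    binom.test(sum(d > 0), length(d))$p.value
  }
  if (length(asd) < 5 || length(ctl) < 5) {
    warn("site_difference_test: fewer than 5 genes in a group, p set to NA")
    mwu <- list(statistic = NA_real_, p.value = NA_real_)
  } else {
    mwu <- suppressWarnings(wilcox.test(asd, ctl, alternative = "two.sided"))
  }
  list(
    genes = genes,
    test = tibble(n_asd = length(asd), n_control = length(ctl),
                  median_diff_asd = ifelse(length(asd), median(asd), NA),
                  median_diff_control = ifelse(length(ctl), median(ctl), NA),
                  mwu_statistic = unname(mwu$statistic),
                  mwu_p = mwu$p.value,
                  sign_p_asd = sign_p(asd), sign_p_control = sign_p(ctl))
  )
}

#' Maximum base-pairing fold score (Nussinov)
#'
#' Dynamic-programming maximum number of nested base pairs (AU, GC and GU
#' wobble) with hairpin loops of at least `min_loop` unpaired bases.
#' Returned as a proxy minimum free energy: minus the pair count, so more
#' structured sequences score lower. Deterministic; used as the default
#' folding engine for [mfe_windows()]. Real analyses can plug in an
#' external thermodynamic folder via [engine_rnafold()].
#'
#' @param seq RNA (or DNA) sequence.
#' @param min_loop Minimum hairpin loop length. Default 3.
#' @return Proxy MFE (non-positive number, = -max pairs).
#' @export
nussinov_fold <- function(seq, min_loop = 3L) {
  s <- normalize_rna(seq)
  n <- nchar(s)
  if (n < min_loop + 2) return(0)
  code <- match(strsplit(s, "")[[1]], RNA_BASES)
  P <- matrix(FALSE, 4, 4)  # A C G U
  P[1, 4] <- P[4, 1] <- TRUE   # A-U
  P[2, 3] <- P[3, 2] <- TRUE   # C-G
  P[3, 4] <- P[4, 3] <- TRUE   # G-U
  M <- matrix(0L, n + 1, n)
  for (span in (min_loop + 1):(n - 1)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      best <- M[i + 1, j]
      ks <- (i + min_loop + 1):j
      ks <- ks[P[code[i], code[ks]]]
      if (length(ks) > 0) {
        inner <- M[cbind(i + 1, ks - 1)]
        outer_ <- M[cbind(ks + 1, j)]
        best <- max(best, max(1L + inner + outer_))
      }
      M[i, j] <- best
    }
  }
  -as.numeric(M[1, n])
}

#' Folding-engine adapter for an external thermodynamic folder
#'
#' Returns a callable mapping a sequence to its minimum free energy as
#' computed by the `RNAfold` executable (ViennaRNA), when available on the
#' PATH.
#'
#' @param temperature Folding temperature in Celsius. Default 37.
#' @return A function(seq) -> numeric MFE (kcal/mol).
#' @export
engine_rnafold <- function(temperature = 37) {
  assert_that(nzchar(Sys.which("RNAfold")),
              "RNAfold executable not found on PATH")
  function(seq) {
    out <- system2("RNAfold", args = c("--noPS", "-T", format(temperature)),
                   input = normalize_rna(seq), stdout = TRUE)
    m <- regmatches(out[length(out)],
                    regexpr("\\(\\s*(-?[0-9.]+)\\s*\\)\\s*$",
                            out[length(out)]))
    as.numeric(gsub("[()\\s]", "", m, perl = TRUE))
  }
}

# Window bounds around a variant: centered when it fits, shifted to abut
# the transcript end otherwise; whole transcript when shorter than the
# window.
window_bounds <- function(pos, window, transcript_length) {
  assert_that(window %% 2 == 1, "window must be odd")
  if (transcript_length < window) {
    return(c(start = 1L, end = as.integer(transcript_length), short = 1L))
  }
  half <- (window - 1L) / 2L
  start <- pos - half
  if (start < 1L) start <- 1L
  end <- start + window - 1L
  if (end > transcript_length) {
    end <- as.integer(transcript_length)
    start <- end - window + 1L
  }
  c(start = as.integer(start), end = as.integer(end), short = 0L)
}

#' Windowed allelic secondary-structure differences
#'
#' For each variant, extracts the window of `window` nt centered on it
#' (shifted to the transcript boundary when the variant is closer than
#' `(window - 1)/2` to an end), folds both alleles with `engine`, and
#' reports the per-variant difference `dmfe = MFE_allele1 - MFE_allele2`.
#' The per-gene (and, when regions are given, per-region) summary is the
#' maximum |dMFE| over the gene's variants.
#'
#' @param pair Tibble with gene_id, seq_allele1, seq_allele2 (one gene).
#' @param variants Tibble with gene_id, pos (1-based transcript coords).
#' @param window Odd window size, one of the usual 21/41/61/81/101.
#' @param engine Folding callable (sequence -> scalar); default
#'   [nussinov_fold()].
#' @param regions Optional tibble (region, start, end) for per-region
#'   summaries.
#' @return Tibble per variant: gene_id, pos, start, end, truncated,
#'   mfe_allele1, mfe_allele2, dmfe, region (NA without annotation).
#'   Attributes `"gene_summary"` (gene_id, max_abs_dmfe) and, when regions
#'   are supplied, `"region_summary"`.
#' @export
mfe_windows <- function(pair, variants, window = 41L,
                        engine = nussinov_fold, regions = NULL) {
  assert_that(nrow(pair) == 1, "mfe_windows expects one gene at a time")
  assert_that(window %% 2 == 1, "window must be odd")
  s1 <- normalize_rna(pair$seq_allele1)
  s2 <- normalize_rna(pair$seq_allele2)
  assert_that(nchar(s1) == nchar(s2),
              "allele sequences must have equal length (substitutions only)")
  L <- nchar(s1)
  vars <- filter(variants, .data$gene_id == pair$gene_id)
  assert_that(all(vars$pos >= 1 & vars$pos <= L),
              "variant positions outside the transcript")
  if (L < window) {
    warn(sprintf("%s: transcript (%d nt) shorter than window (%d), using whole transcript",
                 pair$gene_id, L, window))
  }
  rows <- map(vars$pos, function(p) {
    b <- window_bounds(p, window, L)
    w1 <- substr(s1, b["start"], b["end"])
    w2 <- substr(s2, b["start"], b["end"])
    m1 <- engine(w1)
    m2 <- if (identical(w1, w2)) m1 else engine(w2)
    tibble(gene_id = pair$gene_id, pos = as.integer(p),
           start = b[["start"]], end = b[["end"]],
           truncated = b[["short"]] == 1,
           mfe_allele1 = m1, mfe_allele2 = m2, dmfe = m1 - m2)
  })
  out <- list_rbind(rows)
  if (nrow(out) == 0) {
    out <- tibble(gene_id = character(), pos = integer(), start = integer(),
                  end = integer(), truncated = logical(),
                  mfe_allele1 = numeric(), mfe_allele2 = numeric(),
                  dmfe = numeric())
  }
  out$region <- NA_character_
  if (!is.null(regions) && nrow(out) > 0) {
    for (i in seq_len(nrow(out))) {
      hit <- regions$region[out$pos[i] >= regions$start &
                              out$pos[i] <= regions$end]
      if (length(hit) > 0) out$region[i] <- hit[1]
    }
  }
  attr(out, "gene_summary") <- tibble(
    gene_id = pair$gene_id,
    max_abs_dmfe = if (nrow(out)) max(abs(out$dmfe)) else NA_real_)
  if (!is.null(regions)) {
    attr(out, "region_summary") <- out |>
      filter(!is.na(.data$region)) |>
      group_by(.data$region) |>
      summarise(max_abs_dmfe = max(abs(.data$dmfe)), .groups = "drop")
  }
  out
}

#' Codon adaptation index
#'
#' Geometric mean of per-codon relative adaptiveness weights over the CDS,
#' excluding stop codons and the single-codon amino acids Met and Trp.
#'
#' @param cds_seq Coding sequence, length divisible by 3 (RNA or DNA).
#' @param weight_table Named numeric vector of relative adaptiveness w in
#'   (0, 1], keyed by codon (DNA alphabet; see [read_cai_weights()]).
#' @return CAI in (0, 1].
#' @export
cai <- function(cds_seq, weight_table) {
  s <- gsub("U", "T", normalize_rna(cds_seq))
  assert_that(nchar(s) %% 3 == 0, "CDS length must be divisible by 3")
  assert_that(all(weight_table > 0 & weight_table <= 1),
              "weights must lie in (0, 1]")
  codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  stops <- c("TAA", "TAG", "TGA")
  if (any(codons[-length(codons)] %in% stops)) {
    warn("cai: internal stop codon(s) skipped")
  }
  keep <- !codons %in% c(stops, "ATG", "TGG")
  codons <- codons[keep]
  assert_that(length(codons) > 0, "no scorable codons in CDS")
  w <- weight_table[codons]
  assert_that(!anyNA(w), paste0("weight table lacks codon(s): ",
                                paste(unique(codons[is.na(w)]), collapse = ", ")))
  exp(mean(log(w)))
}

#' Two-group distribution comparison
#'
#' @param values_asd,values_control Numeric samples (each n >= 2).
#' @param test `"KS_two_sided"` (Kolmogorov-Smirnov D, asymptotic p) or
#'   `"MWU_two_sided"` (Mann-Whitney U; exact enumeration when both
#'   samples have n <= 8 and no ties, normal approximation with tie and
#'   continuity correction otherwise).
#' @return Tibble: test, statistic, p.
#' @export
compare_groups <- function(values_asd, values_control,
                           test = c("KS_two_sided", "MWU_two_sided")) {
  test <- match.arg(test)
  assert_that(length(values_asd) >= 2 && length(values_control) >= 2,
              "each sample needs n >= 2")
  if (test == "KS_two_sided") {
    res <- suppressWarnings(ks.test(values_asd, values_control,
                                    alternative = "two.sided"))
  } else {
    exact <- length(values_asd) <= 8 && length(values_control) <= 8
    res <- suppressWarnings(wilcox.test(values_asd, values_control,
                                        alternative = "two.sided",
                                        exact = exact, correct = TRUE))
  }
  tibble(test = test, statistic = unname(res$statistic), p = res$p.value)
}

#' Select density-matched control genes
#'
#' Bins the ASD genes' variant densities into `n_bins` quantile bins and
#' samples, without replacement, the same per-bin counts from the control
#' pool, so the matched controls share the ASD density distribution.
#'
#' @param control_pool_densities Densities of the candidate control genes.
#' @param asd_densities Densities of the ASD genes.
#' @param n_bins Number of quantile bins. Default 10.
#' @param seed Integer seed.
#' @param strict Error on an under-filled bin instead of borrowing from the
#'   nearest-density remaining controls (default borrows with a warning).
#' @return Integer indices into `control_pool_densities` of the matched
#'   subset (length = length(asd_densities)).
#' @export
select_matched_controls <- function(control_pool_densities, asd_densities,
                                    n_bins = 10, seed = 1L, strict = FALSE) {
  assert_that(length(control_pool_densities) >= length(asd_densities),
              "control pool smaller than the ASD set")
  breaks <- unique(quantile(asd_densities, probs = seq(0, 1, length.out = n_bins + 1),
                            names = FALSE))
  breaks[1] <- -Inf
  breaks[length(breaks)] <- Inf
  bin_asd <- cut(asd_densities, breaks, labels = FALSE)
  bin_pool <- cut(control_pool_densities, breaks, labels = FALSE)
  need <- tabulate(bin_asd, nbins = length(breaks) - 1)
  picked <- integer(0)
  with_seed(derive_seed(seed, "match_controls"), {
    for (b in seq_along(need)) {
      if (need[b] == 0) next
      avail <- setdiff(which(bin_pool == b), picked)
      take <- min(need[b], length(avail))
      if (take > 0) {
        picked <- c(picked, sample(avail, take))
      }
      short <- need[b] - take
      if (short > 0) {
        if (strict) {
          abort(sprintf("bin %d under-filled by %d control genes", b, short),
                class = "asdecay_error")
        }
        warn(sprintf("bin %d under-filled; borrowing %d nearest controls",
                     b, short))
        center <- median(asd_densities[bin_asd == b])
        rest <- setdiff(seq_along(control_pool_densities), picked)
        borrow <- rest[order(abs(control_pool_densities[rest] - center))][seq_len(short)]
        picked <- c(picked, borrow)
      }
    }
  })
  picked
}
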