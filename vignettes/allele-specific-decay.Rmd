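---
title: "Estimating allele-specific mRNA decay from hybrid time-course RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating allele-specific mRNA decay from hybrid time-course RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asdecay)
library(dplyr)
```

## The measurement problem

After transcription is arrested, the abundance of an mRNA species decays
approximately exponentially. In an F1 hybrid the two parental alleles of a
gene share one *trans* environment (the same ribonucleases, miRNAs and
RNA-binding proteins), so a reproducible difference in their decay rates
must be caused by the *cis*-acting sequence variants that distinguish them.
RNA-seq reads overlapping those variants can be assigned to an allele, and
the time course of the *allelic read fraction* carries the decay-rate
difference — without requiring absolute RNA quantification, spike-ins, or
knowledge of the library capture efficiency at each timepoint.

## Model and assumptions

For allele $i \in \{1, 2\}$ of one gene, let $N_i(t) = N_i(0)
e^{-\lambda_i t}$ (first-order decay with constant rate $\lambda_i$, in
h$^{-1}$). Reads assignable to allele $i$ at a SNP locus are Poisson with
mean $w_s f(t) N_i(t)$: $f(t)$ is the fraction of transcripts captured by
the library at timepoint $t$ and $w_s$ a locus-specific factor (coverage
profile, mappability). Because $f(t)$ and $w_s$ are shared by the two
alleles, the allele-1 count conditional on the locus total is binomial with

$$p(t) = \frac{R\,e^{-\Delta\lambda\,t}}{R\,e^{-\Delta\lambda\,t} + 1},
\qquad R = \frac{N_1(0)}{N_2(0)},\quad
\Delta\lambda = \lambda_1 - \lambda_2,$$

equivalently $\operatorname{logit} p(t) = \alpha + \beta t$ with $\alpha =
\log R$ and $\beta = -\Delta\lambda$. The model therefore identifies only
the *difference* of decay rates; absolute half-lives cancel with $f(t)$ and
are out of reach by design.

Assumptions worth stating explicitly:

* **Constant rates.** $\lambda_i$ does not change over the time course;
  with timepoints at 0, 0.5 and 1.5 h this is the usual short-horizon
  approximation.
* **Shared capture.** $f(t)$ is allele-independent. Locus-level mapping
  bias violates this, which is why biased SNPs are filtered out first.
* **Independent cells.** Each (SNP, timepoint) cell enters the likelihood
  as an independent binomial observation. Reads spanning two SNPs violate
  independence mildly; the SNP-level bootstrap (below) absorbs the
  resulting extra-binomial variation at the significance step.

### Sign convention

We report $\Delta\lambda \equiv -\beta = \lambda_1 - \lambda_2$, so
$\Delta\lambda > 0$ means allele 1 (the reference/maternal strain by
convention) decays faster; the raw $\beta$ is kept alongside, and
$e^{\beta}$ is the fitted per-hour change in the odds of observing an
allele-1 read. The targeted-validation statistic
`validation_asd()` ($\log_2$ ratio of allelic ratios between 0 h and a
later timepoint $t$) equals $-\Delta\lambda\, t / \ln 2$ on noise-free
data, which the test suite uses to pin the two conventions together.

## Inference pipeline

1. **Bias filters** (`filter_biased_snps()`). Two Fisher's-exact screens
   per SNP locus: parental-strain counts vs mock-hybrid allelic counts, and
   uniquely-mapped vs all reads. The two screens are separate hypothesis
   families, BH-adjusted separately; a locus flagged in either (adjusted
   p < 0.05) is removed. The exact test sums hypergeometric probabilities
   $\le$ the observed table's, with a relative tie tolerance of $10^{-12}$.
2. **Sufficiency filter** (`sufficiency_filter()`). A SNP "supports" a gene
   in a replicate when the two alleles together give $\ge 10$ reads at
   every timepoint and each allele $\ge 15$ reads summed over timepoints;
   a gene is analysed when $\ge 5$ SNPs pass in every replicate. The read
   thresholds are interpreted per SNP (a locus either is or is not
   sufficiently supported) and per replicate — the stricter of the
   available readings, chosen so that a gene's analysable locus set is the
   same in both replicates.
3. **Fit** (`fit_logit_decay()`). Maximum-likelihood fit of the
   two-parameter binomial logit model per gene and replicate. Since all
   cells sharing a timepoint have the same covariate, counts are aggregated
   per timepoint before fitting (the binomial MLE is identical); the fit is
   an iteratively reweighted least squares with at most 50 iterations and a
   relative deviance tolerance of $10^{-10}$, initialised from the
   continuity-corrected empirical logit. Complete separation is handled by
   clipping $|\beta|$ at 50 h$^{-1}$ and flagging the fit as
   non-converged; a timepoint with zero totals simply carries zero weight.
4. **Bootstrap** (`bootstrap_statistic()`). The gene's $n$ SNP loci are
   resampled with replacement ($n$ per resample, 5,000 resamples by
   default), the statistic refit on each resample, and the bootstrap mean
   and SD summarised as $z = \text{mean}/\text{SD}$ with a two-sided normal
   p-value. Non-converged resample fits are dropped and counted (a warning
   fires above 1%). A degenerate bootstrap SD of 0 maps to p = 0 when the
   mean is nonzero and p = 1 otherwise. All resampling is vectorised, so a
   5,000-resample bootstrap refits the GLM 5,000 times in a few tens of
   milliseconds.
5. **Calling** (`call_asd()`). BH adjustment is applied across genes
   *within* each replicate (each replicate is its own experiment; the
   dual-replicate requirement then multiplies the two error controls). A
   gene is ASD when every replicate has adjusted p < 0.05 and
   $|\Delta\lambda| > 0.06$ h$^{-1}$ with one sign across replicates. The
   reported per-gene $\Delta\lambda$ is the unweighted mean of replicate
   point estimates.
6. **Permutation FDR** (`permutation_fdr()`). The counted false positives
   are *cross-replicate concordant* calls, so the permutation null must
   break concordance while preserving each replicate's marginal
   distribution: the gene labels of replicate 2's (adjusted p,
   $\Delta\lambda$) records are shuffled against replicate 1 (100
   permutations), and FDR(x) is the mean permuted count of dual-threshold,
   sign-concordant passes divided by the real count (NA when the real
   count is 0).
7. **ASA and joint classes** (`fit_allelic_abundance()`, `call_asa()`,
   `classify_joint()`). The steady-state allelic ratio uses the 0 h samples
   only, per replicate, with the same bootstrap-over-loci machinery on the
   statistic $\log_2(\sum n_1 / \sum n_2)$ — counts are summed across the
   resampled loci *before* the ratio, which matches the read-level allelic
   ratio and is robust to low-count loci (a mean of per-locus ratios would
   be dominated by them). Thresholds: adjusted p < 0.05 and twofold
   ($|\log_2 FC| > 1$) in both replicates, concordant. Genes are then
   `ASD_only` / `ASA_only` / `both` / `neither`; a gene is annotated
   *compensatory* (descriptive metadata only) when it is ASD without ASA
   and the faster-decaying allele is also the transcriptionally favoured
   one — the configuration in which opposing transcription must be hiding
   the decay divergence at steady state.
8. **Control genes** (`select_control_genes()`). Genes with no hint of
   decay divergence: raw bootstrap p > 0.05, $|\Delta\lambda| < 0.03$
   h$^{-1}$ and bootstrap SD below $\min(0.1,$ the empirical 95% quantile
   of all bootstrap SDs$)$, in both replicates. For sequence-feature
   comparisons a density-matched subset is drawn
   (`select_matched_controls()`: quantile-bin the ASD genes' variant
   densities, sample the same per-bin counts from the control pool without
   replacement; an under-filled bin borrows the nearest-density remaining
   controls with a warning, or errors in strict mode).

### Key parameters

| parameter | default | units | rationale |
|---|---|---|---|
| timepoints | 0, 0.5, 1.5 | h | transcription-arrest design the package targets |
| `n_boot` | 5000 | resamples | bootstrap SD stable to ~1%; 1000 suffices for simulation studies |
| `p_adj_threshold` | 0.05 | — | BH-adjusted, per replicate |
| `min_abs_dlambda` | 0.06 | h⁻¹ | effect-size floor of the dual ASD rule |
| `min_abs_log2fc` | 1.0 | log2 | twofold ASA divergence |
| `n_perm` | 100 | permutations | FDR curve resolution ~1/real count |
| `min_snps` / `min_tp_total` / `min_allele_total` | 5 / 10 / 15 | loci / reads | sufficiency filter |
| MFE windows | 21–101 (odd) | nt | local structure around a variant |

## The synthetic generator

`simulate_cohort()` draws, for each gene, per-SNP weights (i.i.d.
LogNormal(0, 0.5²), renormalised to mean 1 — uneven SNP coverage that
deliberately stresses the bootstrap), allele copy numbers from the planted
$\log_2 R$ offset, and Poisson counts per (SNP, replicate, timepoint,
allele) with mean $w_s f(t) N_i(0) e^{-\lambda_i t}$. Defaults encode the
study design the package targets: timepoints 0/0.5/1.5 h, two replicates,
8 SNPs per gene, ~200 reads per average-weight SNP at 0 h, baseline decay
0.3 h⁻¹ (half-life ≈ 2.3 h, typical for fibroblast mRNA), planted decay
effects split symmetrically ($\lambda_i = 0.3 \mp \Delta\lambda/2$), and
$f(t) = 1$ (it cancels from the allelic proportion; it is configurable to
verify that robustness). Planting is deterministic by count — the first
$\lfloor \text{fraction} \cdot n \rfloor$ genes of a seeded shuffle — so
power studies have exact composition. Per-gene random streams are derived
by stable hashing of (seed, gene id), making any subset of genes exactly
reproducible, and the generator is label-symmetric: swapping the two
alleles' parameters swaps the count columns byte-for-byte.

What it does *not* emulate: read-level artifacts (FASTQ, alignment,
GC/length bias), replicate-level batch effects, overdispersion beyond
Poisson, correlated neighbouring SNPs (reads spanning two variants), or
indels. Passing tests therefore certify the statistical machinery under
the stated model, not robustness to alignment pathologies — those are
exactly what the mock-hybrid bias filter is for, and
`simulate_mock_hybrid()` plants assignment bias at the count level to
measure that filter's operating characteristics.

## Numerical and algorithmic choices

* **Fisher tie handling**: tables whose probability is within a factor
  $(1 + 10^{-12})$ of the observed probability count as ties (classic
  two-sided rule; no mid-p).
* **Pseudocount**: $\log_2$ allelic ratios add 0.5 to both totals only
  when one of them is 0.
* **miRNA site taxonomy**: a candidate site is a match of the reverse
  complement of miRNA positions 2–7; it is typed 8mer (m8 match + A
  opposite position 1), 7mer-m8, or 7mer-1A, and counted once under the
  best type. Anchoring on the core 6mer avoids double counting (every 8mer
  contains a 7mer-1A one base downstream); plain 6mers are not counted.
* **ΔMFE windows**: the window is centred on the variant; a variant closer
  than $(w-1)/2$ nt to a transcript end shifts the window to abut the end;
  transcripts shorter than the window are folded whole and flagged. The
  default engine is a Nussinov maximum base-pairing score (AU/GC/GU,
  hairpin $\ge 3$; proxy MFE = −pairs, deterministic and dependency-free);
  `engine_rnafold()` adapts an external thermodynamic folder when one is
  on the PATH. Only $|\Delta\text{MFE}|$ feeds the per-gene summary
  (maximum over variants); the signed value is available.
* **CAI**: geometric mean of relative-adaptiveness weights, excluding stop
  codons (skipped with a warning when internal) and the single-codon amino
  acids Met and Trp.
* **Stable/unstable labels**: the unstable allele is the faster-decaying
  one by the sign of the replicate-mean $\Delta\lambda$; exact ties are
  excluded; control genes get seeded random labels.

## Problem sizes used in the validation suite

The acceptance tests run cohorts of 200 genes per planted level
$\Delta\lambda \in \{0, \pm 0.1, \pm 0.3\}$ h⁻¹ (8 SNPs, ~200 reads/SNP,
2 replicates, 1,000 bootstrap resamples), a 500-gene null cohort, and a
500-gene 10%-planted cohort with 100 FDR permutations — sizes chosen so the
Monte-Carlo error of each checked quantity is several times smaller than
the band it is checked against, while a full run stays in the minutes
range on one core. Oracle-equivalence checks are exhaustive where
enumeration is proportionate (every 2×2 table with margins ≤ 30; every RNA
string to length 7) and seeded-random beyond (2,000 strings of length
8–10; 1,000 random 200-nt miRNA targets).

## Known limitations

* **Interval coverage at few loci.** With 8 SNPs per gene the bootstrap SD
  under-estimates the sampling SD by ~10% (small-$n$ resampling bias,
  aggravated by unequal locus weights), so nominal 95% z-intervals cover
  the truth for ~87–89% of genes in simulation, and raw bootstrap p-values
  are mildly anticonservative (null rate ~0.11 at nominal 0.05). The
  replicate-concordance requirement plus BH keeps the realized null *call*
  rate at ~0; single-replicate raw p-values should not be consumed as
  calibrated at small SNP counts.
* **Permutation FDR is a null-pairing rate.** The gene-label shuffle
  re-pairs strong replicate-1 records with strong replicate-2 records of
  *other* genes, so with a high planted effect fraction the estimate is
  conservative relative to the truth-based false-positive fraction (e.g.
  ~8% estimated vs 0 realized on a 10%-planted cohort). This is the
  method's intended behaviour — an upper-bound-flavoured estimate — not a
  bug.
* Only substitution variants are supported (equal-length allele
  sequences); indel harmonisation is upstream of this package.
* The Nussinov engine is a structural proxy, not a thermodynamic energy
  model; absolute ΔMFE magnitudes are not comparable across engines.
* Absolute per-allele half-lives are unidentifiable by design; only
  $\Delta\lambda$ is estimated.

## A compact end-to-end run

```{r pipeline, eval = FALSE}
cfg <- read_run_config(system.file("extdata", "demo_config.yaml",
                                   package = "asdecay"),
                       overrides = list(out_dir = tempfile()))
run_dir <- run_pipeline(cfg)
summarize_run(run_dir)
```

The run directory contains every stage's table (counts, truth, filters,
fits, calls, joint decisions, FDR curve), `summary.json`, and a log with
input hashes and seeds; rerunning the same configuration and seed yields
byte-identical tables.
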