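# Readers and writers for the package's plain-text interchange formats.

#' Read an allelic counts table
#'
#' Reads the tab-separated long-format counts table (one row per gene, SNP,
#' replicate, timepoint) and validates it against [counts_schema()].
#'
#' @param path Path to a TSV file with header.
#' @return A tibble with the schema columns, types coerced.
#' @export
read_allelic_counts <- function(path) {
  counts <- readr::read_tsv(
    path,
    col_types = readr::cols(
      gene_id = readr::col_character(), snp_id = readr::col_character(),
      chrom = readr::col_character(), pos = readr::col_integer(),
      region = readr::col_character(), replicate = readr::col_integer(),
      time_h = readr::col_double(), n_allele1 = readr::col_integer(),
      n_allele2 = readr::col_integer()
    )
  )
  prob <- readr::problems(counts)
  if (nrow(prob) > 0) {
    abort(paste0("malformed counts TSV: ", path, " (",
                 prob$expected[1], " expected in column beginning row ",
                 prob$row[1], ")"), class = "asdecay_error")
  }
  missing <- setdiff(names(counts_schema()), names(counts))
  assert_that(length(missing) == 0,
              paste0("counts TSV ", path, " lacks required column(s): ",
                     paste(missing, collapse = ", ")))
  validate_counts(counts, call_site = path)
}

#' Write an allelic counts table
#'
#' @param counts Counts tibble following [counts_schema()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_allelic_counts <- function(counts, path) {
  validate_counts(counts)
  readr::write_tsv(counts[, names(counts_schema())], path)
  invisible(path)
}

#' Read a SNP bias-filter table
#'
#' One row per (SNP, filter context) with the four cells of the 2x2 table:
#' `a`,`b` from context A (parental strain reads, or uniquely mapped reads)
#' and `c`,`d` from context B (mock-hybrid allelic reads, or all reads
#' including multi-mapped). `ctx` is `"parental_mock"` or `"unique_multi"`.
#'
#' @param path Path to a TSV file with header.
#' @return A tibble with columns snp_id, ctx, a, b, c, d.
#' @export
read_bias_table <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    snp_id = readr::col_character(), ctx = readr::col_character(),
    a = readr::col_integer(), b = readr::col_integer(),
    c = readr::col_integer(), d = readr::col_integer()
  ))
  assert_that(all(tbl$ctx %in% c("parental_mock", "unique_multi")),
              "ctx must be parental_mock or unique_multi")
  tbl
}

#' Write paired allele sequences as FASTA
#'
#' Record ids follow the `"<gene>|allele1"` / `"<gene>|allele2"` convention.
#'
#' @param pairs Tibble with columns gene_id, seq_allele1, seq_allele2.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_allele_fasta <- function(pairs, path) {
  seqs <- Biostrings::DNAStringSet(c(
    rbind(gsub("U", "T", toupper(pairs$seq_allele1)),
          gsub("U", "T", toupper(pairs$seq_allele2)))
  ))
  names(seqs) <- c(rbind(paste0(pairs$gene_id, "|allele1"),
                         paste0(pairs$gene_id, "|allele2")))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read paired allele sequences from FASTA
#'
#' @param path FASTA path with `"<gene>|allele1"`-style record ids.
#' @return Tibble with columns gene_id, seq_allele1, seq_allele2.
#' @export
read_allele_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- names(seqs)
  gene <- sub("\\|allele[12]$", "", ids)
  allele <- sub("^.*\\|", "", ids)
  tbl <- tibble(gene_id = gene, allele = allele,
                seq = unname(as.character(seqs)))
  wide <- tidyr::pivot_wider(tbl, names_from = "allele",
                             values_from = "seq")
  assert_that(all(c("allele1", "allele2") %in% names(wide)),
              "FASTA must contain |allele1 and |allele2 records per gene")
  dplyr::rename(wide, seq_allele1 = "allele1", seq_allele2 = "allele2")
}

#' Write variants as a minimal VCF v4.2
#'
#' CHROM is the gene id and POS the 1-based transcript coordinate, matching
#' the allele FASTA records. REF/ALT are the allele-1 and allele-2 bases.
#'
#' @param variants Tibble with columns gene_id, pos, ref, alt.
#' @param path Output VCF path.
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(variants, path) {
  header <- c("##fileformat=VCFv4.2",
              "##source=asdecay",
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.",
                  variants$gene_id, as.integer(variants$pos),
                  paste0(variants$gene_id, "_", variants$pos),
                  variants$ref, variants$alt)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read variants from VCF
#'
#' @param path VCF path (plain or bgzipped).
#' @return Tibble with columns gene_id, pos, ref, alt.
#' @export
read_variant_vcf <- function(path) {
  vcf <- suppressMessages(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  tibble(gene_id = fix$CHROM, pos = as.integer(fix$POS),
         ref = fix$REF, alt = fix$ALT)
}

#' Write transcript region spans as BED
#'
#' BED is 0-based half-open; the input spans are 1-based inclusive transcript
#' coordinates, converted on write.
#'
#' @param regions Tibble with columns gene_id, region, start, end (1-based
#'   inclusive).
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_region_bed <- function(regions, path) {
  lines <- sprintf("%s\t%d\t%d\t%s", regions$gene_id,
                   as.integer(regions$start) - 1L, as.integer(regions$end),
                   regions$region)
  writeLines(lines, path)
  invisible(path)
}

#' Read transcript region spans from BED
#'
#' @param path BED path (gene_id, 0-based start, end, region name).
#' @return Tibble with 1-based inclusive start/end.
#' @export
read_region_bed <- function(path) {
  bed <- readr::read_tsv(path, col_names = c("gene_id", "start0", "end", "region"),
                         col_types = "ciic")
  tibble(gene_id = bed$gene_id, region = bed$region,
         start = bed$start0 + 1L, end = bed$end)
}

#' Read a miRNA seed table
#'
#' @param path TSV with columns mirna_id, sequence (5'->3', RNA or DNA
#'   alphabet), expression_rank (1 = most highly expressed).
#' @return Tibble with those columns.
#' @export
read_mirna_seeds <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    mirna_id = readr::col_character(), sequence = readr::col_character(),
    expression_rank = readr::col_integer()
  ))
}

#' Read a codon relative-adaptiveness weight table
#'
#' @param path TSV with columns codon, w (relative adaptiveness in (0, 1]).
#' @return Named numeric vector of weights keyed by codon (DNA alphabet).
#' @export
read_cai_weights <- function(path) {
  tbl <- readr::read_tsv(path, col_types = "cd")
  setNames(tbl$w, gsub("U", "T", toupper(tbl$codon)))
}
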