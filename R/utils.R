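# Internal helpers: stable seeding, validation, small shared utilities.

# Deterministic 31-bit hash of a character key, used to derive independent
# random streams per (seed, gene) so that any subset of genes reproduces
# exactly. Polynomial rolling hash over UTF-8 code points, modulo the
# Mersenne prime 2^31 - 1; arithmetic stays < 2^52 so doubles are exact.
stable_hash <- function(key) {
  m <- 2147483647
  h <- 0
  for (code in utf8ToInt(key)) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h)
}

# Sub-seed for a named random stream. Always in [0, 2^31 - 2].
derive_seed <- function(seed, ...) {
  stable_hash(paste(c(format(seed), ...), collapse = "\r"))
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg, class = "asdecay_error")
  invisible(TRUE)
}

is_count_vector <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x == round(x))
}

#' Schema of the allelic counts table
#'
#' Column names and prototypes for the long-format allelic counts table used
#' throughout the package: one row per (gene, SNP, replicate, timepoint).
#' `pos` is 1-based in transcript coordinates; `region` is one of
#' `"UTR5"`, `"CDS"`, `"UTR3"` or `NA`; allele 1 is the reference/maternal
#' strain by convention.
#'
#' @return Named character vector mapping column name to type.
#' @export
counts_schema <- function() {
  c(gene_id = "character", snp_id = "character", chrom = "character",
    pos = "integer", region = "character", replicate = "integer",
    time_h = "numeric", n_allele1 = "integer", n_allele2 = "integer")
}

validate_counts <- function(counts, call_site = "counts") {
  schema <- counts_schema()
  missing <- setdiff(names(schema), names(counts))
  assert_that(length(missing) == 0,
              paste0(call_site, ": missing column(s): ",
                     paste(missing, collapse = ", ")))
  assert_that(is_count_vector(counts$n_allele1) &&
                is_count_vector(counts$n_allele2),
              paste0(call_site, ": allelic counts must be non-negative integers"))
  bad_region <- !counts$region %in% c("UTR5", "CDS", "UTR3") & !is.na(counts$region)
  assert_that(!any(bad_region),
              paste0(call_site, ": region must be UTR5/CDS/UTR3 or NA"))
  invisible(counts)
}

check_timepoints <- function(timepoints) {
  assert_that(is.numeric(timepoints) && length(timepoints) >= 2,
              "need at least two timepoints")
  assert_that(all(diff(timepoints) > 0),
              "timepoints must be strictly increasing")
  assert_that(timepoints[1] == 0, "first timepoint must be 0 h")
  invisible(timepoints)
}
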