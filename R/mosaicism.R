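#' Allelic ratio from reference and alternate read depths
#'
#' The fraction of reads supporting the alternate allele,
#' `alt / (ref + alt)`. A constitutional heterozygote is expected at ~0.5;
#' somatic mosaicism pulls the ratio below 0.5 in proportion to the fraction
#' of mutant cells.
#'
#' @param ref_reads,alt_reads Non-negative integer vectors of read counts.
#' @return Numeric vector of ratios in `[0, 1]`; `NA` where total depth is 0.
#' @examples
#' allelic_ratio(18, 19) # the balanced proband, ~0.51
#' allelic_ratio(22, 6)  # the mosaic grandmother, ~0.21
#' @export
allelic_ratio <- function(ref_reads, alt_reads) {
  if (any(ref_reads < 0, na.rm = TRUE) || any(alt_reads < 0, na.rm = TRUE)) {
    abort("read counts must be non-negative")
  }
  total <- ref_reads + alt_reads
  ifelse(total > 0, alt_reads / total, NA_real_)
}

#' Two-sided exact binomial p-value for allelic balance
#'
#' Tests the observed alternate read count against Binomial(n, `null_fraction`)
#' by the minimum-likelihood rule: the p-value sums `Pr(x)` over all outcomes
#' whose likelihood does not exceed the observed outcome's. For the symmetric
#' heterozygous null (0.5) this equals twice the smaller tail, capped at 1.
#'
#' @param alt_reads Observed alternate read counts (vectorized).
#' @param total_reads Total read counts, at least 1 (vectorized).
#' @param null_fraction Null alternate-read fraction, strictly inside (0, 1).
#' @return Numeric vector of two-sided p-values in (0, 1].
#' @examples
#' binom_balance_p(6, 28)   # ~0.0037: significant departure from 50/50
#' binom_balance_p(19, 37)  # 1: the observed count is the mode
#' @export
binom_balance_p <- function(alt_reads, total_reads, null_fraction = 0.5) {
  if (any(total_reads < 1)) abort("total_reads must be >= 1")
  if (any(alt_reads < 0) || any(alt_reads > total_reads)) {
    abort("alt_reads must lie in [0, total_reads]")
  }
  if (null_fraction <= 0 || null_fraction >= 1) {
    abort("null_fraction must be strictly between 0 and 1")
  }
  if (isTRUE(all.equal(null_fraction, 0.5))) {
    lo <- pbinom(alt_reads, total_reads, 0.5)
    hi <- pbinom(total_reads - alt_reads, total_reads, 0.5)
    return(pmin(1, 2 * pmin(lo, hi)))
  }
  mapply(function(k, n) {
    d <- dbinom(0:n, n, null_fraction)
    # relative tolerance guards against ties lost to floating point
    sum(d[d <= d[k + 1L] * (1 + 1e-07)])
  }, alt_reads, total_reads)
}

#' Allelic-balance test over a table of read depths
#'
#' @param depths Data frame with columns `individual`, `ref_reads`,
#'   `alt_reads` (one row per individual at the focal variant).
#' @param null_fraction Null alternate-read fraction (default 0.5).
#' @return A tibble of class `mh_balance` with added columns `ratio`, `n`
#'   and `p_two_sided`. `ratio` is kept at full precision; round only when
#'   reporting.
#' @examples
#' allelic_balance_test(tibble::tibble(
#'   individual = c("IV-4", "II-5"),
#'   ref_reads = c(18, 22), alt_reads = c(19, 6)
#' ))
#' @export
allelic_balance_test <- function(depths, null_fraction = 0.5) {
  need <- c("individual", "ref_reads", "alt_reads")
  missing <- setdiff(need, names(depths))
  if (length(missing)) {
    abort(paste0("depths is missing column(s): ", paste(missing, collapse = ", ")))
  }
  out <- as_tibble(depths) %>%
    mutate(
      n = .data$ref_reads + .data$alt_reads,
      ratio = allelic_ratio(.data$ref_reads, .data$alt_reads),
      p_two_sided = ifelse(
        .data$n > 0,
        binom_balance_p(pmin(.data$alt_reads, .data$n),
                        pmax(.data$n, 1L), null_fraction),
        NA_real_
      )
    )
  class(out) <- c("mh_balance", class(out))
  out
}

#' Classify per-individual carrier state at a focal variant
#'
#' Combines the called genotype, the read depths and the exact allelic-balance
#' test into one of four states: `non_carrier`, `heterozygous`,
#' `mosaic_candidate`, or `indeterminate`. A mosaic candidate must show the
#' variant (`alt_reads >= min_alt`), a significant departure from 50/50
#' (`p < alpha`) and a depleted ratio (`ratio < mosaic_ratio_max`).
#'
#' @param depths Data frame with `individual`, `ref_reads`, `alt_reads` and
#'   optionally `genotype` (VCF-style `"0/0"`, `"0/1"`, `"1/1"`; `NA` for
#'   untyped). Without a genotype column, individuals with fewer than
#'   `min_alt` alternate reads are treated as called homozygous reference.
#' @param alpha Significance level of the balance test (default 0.01).
#' @param min_alt Minimum alternate reads to accept that the variant is
#'   present (default 3).
#' @param min_depth Minimum total depth for a call (default 10).
#' @param mosaic_ratio_max Upper ratio bound for a mosaic call (default 0.35).
#' @return A tibble of class `mh_states`: the balance-test columns plus
#'   `state` (character).
#' @export
classify_carrier_state <- function(depths, alpha = 0.01, min_alt = 3,
                                   min_depth = 10, mosaic_ratio_max = 0.35) {
  tested <- allelic_balance_test(depths)
  if (!"genotype" %in% names(tested)) {
    tested$genotype <- ifelse(tested$alt_reads >= min_alt, "0/1", "0/0")
  }
  gt <- gsub("\\|", "/", as.character(tested$genotype))
  het_gt <- gt %in% c("0/1", "1/0")
  homref_gt <- gt %in% "0/0"

  conflict <- het_gt & tested$alt_reads == 0
  if (any(conflict, na.rm = TRUE)) {
    warn(paste0(
      "genotype called heterozygous but no alternate reads for: ",
      paste(tested$individual[which(conflict)], collapse = ", "),
      "; state set to indeterminate"
    ))
  }

  state <- rep("indeterminate", nrow(tested))
  has_alt <- tested$alt_reads >= min_alt
  ok <- !is.na(tested$n)
  state[ok & !has_alt & homref_gt] <- "non_carrier"
  deep <- ok & tested$n >= min_depth & !(ok & !has_alt & homref_gt)
  state[deep & has_alt & tested$p_two_sided < alpha &
          tested$ratio < mosaic_ratio_max] <- "mosaic_candidate"
  state[deep & has_alt & tested$p_two_sided >= alpha] <- "heterozygous"
  state[which(conflict)] <- "indeterminate"

  out <- mutate(tested, state = state)
  class(out) <- c("mh_states", setdiff(class(out), "mh_balance"))
  out
}

#' Read per-individual allele depths at one variant from a family VCF
#'
#' Extracts the `AD` FORMAT field (and `GT`) at a single site, as written by
#' standard germline callers.
#'
#' @param vcf_file Path to a VCF with `GT` and `AD` FORMAT fields.
#' @param variant Focal variant as `"chrom:pos:ref:alt"` (chromosome with or
#'   without the `chr` prefix).
#' @return Tibble with `individual`, `ref_reads`, `alt_reads`, `genotype`.
#' @export
read_allelic_depths <- function(vcf_file, variant) {
  key <- strsplit(variant, ":", fixed = TRUE)[[1]]
  if (length(key) != 4L) abort("variant must be 'chrom:pos:ref:alt'")
  vcf <- vcfR::read.vcfR(vcf_file, verbose = FALSE)
  fix <- vcf_fix_frame(vcf)
  hit <- which(normalize_chrom(fix$CHROM) == normalize_chrom(key[1]) &
                 as.integer(fix$POS) == as.integer(key[2]) &
                 toupper(fix$REF) == toupper(key[3]) &
                 toupper(fix$ALT) == toupper(key[4]))
  if (length(hit) != 1L) {
    abort(sprintf("variant %s matched %d VCF records", variant, length(hit)))
  }
  ad <- vcfR::extract.gt(vcf, element = "AD")[hit, , drop = TRUE]
  gt <- vcfR::extract.gt(vcf, element = "GT")[hit, , drop = TRUE]
  parts <- strsplit(ad, ",", fixed = TRUE)
  tibble(
    individual = names(ad),
    ref_reads = unname(vapply(parts, function(x) as.integer(x[1]),
                              integer(1))),
    alt_reads = unname(vapply(parts, function(x) as.integer(x[2]),
                              integer(1))),
    genotype = unname(gt)
  )
}
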