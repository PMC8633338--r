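#' Default classification-profile mix for synthetic cohorts
#'
#' Named submission-tally profiles assigned to planted variants, spanning
#' clean pathogenic, majority-kept conflict (10 pathogenic vs 1 likely
#' benign), uncertain-only, tied conflict, single likely pathogenic,
#' benign-only and drug-response-pathogenic patterns.
#'
#' @return Named list of named integer vectors (labels -> submission counts).
#' @export
default_classification_mix <- function() {
  list(
    clean_pathogenic = c(pathogenic = 2L),
    majority_kept = c(pathogenic = 10L, likely_benign = 1L),
    vus_only = c(uncertain = 3L),
    tied_conflict = c(pathogenic = 1L, benign = 1L),
    single_lp = c(likely_pathogenic = 1L),
    benign_only = c(benign = 2L),
    drug_response = c(drug_response_pathogenic = 2L)
  )
}

# Aggregate a tally profile with generator-side arithmetic (kept separate
# from aggregate_classification so the ledger is an independent oracle).
profile_verdict <- function(profile, rule) {
  g <- function(x) if (x %in% names(profile)) profile[[x]] else 0L
  p <- g("pathogenic") + g("likely_pathogenic") +
    g("drug_response_pathogenic")
  b <- g("benign") + g("likely_benign")
  u <- g("uncertain")
  if (rule == "majority") {
    if (p >= 1L && p > b) "actionable"
    else if (p >= 1L) "conflicting_excluded"
    else "not_actionable"
  } else {
    if (p >= 1L && b == 0L && u == 0L) "actionable"
    else if (p >= 1L) "conflicting_excluded"
    else "not_actionable"
  }
}

#' Generate a synthetic population cohort with classifications and ledger
#'
#' Plants `n_variants` single-nucleotide variants in an RYR1-like gene
#' region over `cohort_size` diploid individuals. Most variants are rare
#' (1 to a few carriers); a configurable fraction is common enough to fail
#' the 0.1% MAF screen, and some are synonymous, so both screening filters
#' have work to do. A sprinkle of missing genotypes exercises the
#' called-alleles-only denominator. Each variant may receive a
#' ClinVar-style submission-tally profile from `classification_mix`; every
#' profile in the mix is guaranteed to occur on at least one variant that
#' passes the screen. Two classification-only phantom variants absent from
#' the cohort are appended to exercise join behaviour.
#'
#' The returned ground-truth ledger records, per variant, the allele
#' counts, carrier sets and assigned profile, plus the derived screened /
#' actionable keys under both aggregation rules — enough to score every
#' pipeline output without re-simulation. The ledger never appears in the
#' generated files.
#'
#' @param config A [sim_config()].
#' @return List with `samples`, `variants` (tibble incl. `genotypes`
#'   list-column of per-sample GT strings), `annotations`, `regions`,
#'   `classifications` (long TSV-format tibble) and `ledger` (list:
#'   `variants`, `screened`, `actionable_majority`, `actionable_strict`,
#'   `carriers_merged_majority`).
#' @export
gen_cohort <- function(config = sim_config()) {
  mix <- config$classification_mix
  n <- config$n_variants
  N <- config$cohort_size
  region_start <- 38433691L
  region_end <- 38595273L

  withr::with_seed(op_seed(config$seed, "gen_cohort"), {
    samples <- sprintf("S%05d", seq_len(N))
    pos <- sort(sample(region_start:region_end, n))
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L),
                  character(1))
    kept <- default_kept_consequences()
    consequence <- ifelse(runif(n) < 0.75,
                          sample(kept, n, replace = TRUE),
                          "synonymous")

    is_rare <- runif(n) < config$maf_spectrum$rare_weight
    variants <- vector("list", n)
    for (i in seq_len(n)) {
      if (is_rare[i]) {
        n_car <- sample.int(config$maf_spectrum$rare_carriers_max, 1L)
        carriers <- sample(samples, n_car)
        hom <- if (n_car >= 2L && runif(1) < 0.2) carriers[1L] else
          character(0)
      } else {
        maf <- runif(1, config$maf_spectrum$common_maf_range[1],
                     config$maf_spectrum$common_maf_range[2])
        n_car <- max(1L, round(2 * N * maf))
        carriers <- sample(samples, n_car)
        hom <- character(0)
      }
      miss <- sample(setdiff(samples, carriers),
                     rbinom(1L, N - length(carriers), config$missing_rate))
      gt <- setNames(rep("0/0", N), samples)
      gt[carriers] <- "0/1"
      gt[hom] <- "1/1"
      gt[miss] <- "./."
      ac <- length(carriers) + length(hom)
      an <- 2L * (N - length(miss))
      variants[[i]] <- tibble(
        chrom = config$chrom, pos = pos[i], ref = ref[i], alt = alt[i],
        gene = "RYR1", consequence = consequence[i],
        allele_count = ac, allele_number = an,
        maf = min(ac, an - ac) / an,
        carriers = list(sort(carriers)),
        genotypes = list(gt)
      )
    }
    variants <- bind_rows(variants)

    screened_mask <- variants$maf < 0.001 & variants$consequence %in% kept
    profile_name <- rep(NA_character_, n)
    forced <- which(screened_mask)[seq_len(min(length(mix),
                                               sum(screened_mask)))]
    profile_name[forced] <- names(mix)
    rest <- setdiff(seq_len(n), forced)
    gets_profile <- rest[runif(length(rest)) < 0.7]
    profile_name[gets_profile] <- sample(names(mix), length(gets_profile),
                                         replace = TRUE)
    variants$profile <- profile_name

    # classification table rows (one per variant-label tally), plus two
    # phantom variants never observed in the cohort
    cls_variants <- variants %>% filter(!is.na(.data$profile))
    phantom <- tibble(
      chrom = config$chrom,
      pos = sort(sample(setdiff(region_start:region_end, pos), 2L)),
      ref = c("G", "C"), alt = c("A", "T"), gene = "RYR1",
      profile = c("clean_pathogenic", "single_lp")
    )
    cls_all <- bind_rows(
      cls_variants %>% select("chrom", "pos", "ref", "alt", "gene",
                              "profile"),
      phantom
    )
    long <- purrr::pmap_dfr(cls_all, function(chrom, pos, ref, alt, gene,
                                              profile) {
      tallies <- mix[[profile]]
      tibble(
        chrom = chrom, pos = pos, ref = ref, alt = alt, gene = gene,
        hgvs_c = sprintf("c.%d%s>%s", pos - region_start, ref, alt),
        hgvs_p = "p.?",
        label = gsub("_", " ", names(tallies)),
        n_submissions = as.integer(tallies),
        phenotype = "Malignant hyperthermia"
      )
    })

    key_cols <- c("chrom", "pos", "ref", "alt")
    screened <- variants[screened_mask, ]
    verdicts <- function(rule) {
      ok <- vapply(screened$profile, function(p) {
        !is.na(p) && profile_verdict(mix[[p]], rule) == "actionable"
      }, logical(1))
      screened[ok, ]
    }
    act_maj <- verdicts("majority")
    act_str <- verdicts("strict")

    ledger <- list(
      variants = variants %>% select(-"genotypes"),
      screened = screened %>% select(dplyr::all_of(key_cols)),
      actionable_majority = act_maj %>% select(dplyr::all_of(key_cols)),
      actionable_strict = act_str %>% select(dplyr::all_of(key_cols)),
      carriers_by_variant = setNames(
        act_maj$carriers,
        sprintf("%s:%d:%s:%s", act_maj$chrom, act_maj$pos, act_maj$ref,
                act_maj$alt)),
      carriers_merged_majority = sort(unique(unlist(act_maj$carriers)))
    )
    list(
      samples = samples,
      variants = variants,
      annotations = variants %>% select("chrom", "pos", "ref", "alt",
                                        "gene", "consequence"),
      regions = tibble(gene = "RYR1", chrom = config$chrom,
                       start = region_start, end = region_end),
      classifications = long,
      ledger = ledger,
      config = config
    )
  })
}

#' Write the synthetic cohort as a multi-sample VCF
#'
#' @param cohort Result of [gen_cohort()].
#' @param path Output VCF path.
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(cohort, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=mhtrace_synthetic_cohort",
    sprintf("##contig=<ID=%s,length=%d>", cohort$config$chrom,
            cohort$config$chrom_length),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cohort$samples), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(cohort$variants)), function(i) {
    v <- cohort$variants[i, ]
    paste(c(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", ".", "GT",
            unname(v$genotypes[[1]][cohort$samples])), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write gene regions as BED
#'
#' Converts the internal 1-based inclusive regions to BED 0-based half-open.
#'
#' @param regions Tibble with `gene`, `chrom`, `start`, `end`.
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s", regions$chrom, regions$start - 1L,
                     regions$end, regions$gene), path)
  invisible(path)
}

#' Write a variant annotation table
#'
#' @param annotations Tibble with `chrom`, `pos`, `ref`, `alt`, `gene`,
#'   `consequence`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  readr::write_tsv(annotations, path)
  invisible(path)
}

#' Write a single-site family VCF with GT and AD
#'
#' Emits one VCF record carrying per-sample genotypes and allele depths, the
#' shape consumed by [read_allelic_depths()].
#'
#' @param depths Tibble with `individual`, `ref_reads`, `alt_reads` and
#'   optionally `genotype` (defaults to `0/1` when alternate reads are
#'   present, else `0/0`).
#' @param variant Focal variant as `"chrom:pos:ref:alt"`.
#' @param path Output VCF path.
#' @return `path`, invisibly.
#' @export
write_family_vcf <- function(depths, variant, path) {
  key <- strsplit(variant, ":", fixed = TRUE)[[1]]
  if (length(key) != 4L) abort("variant must be 'chrom:pos:ref:alt'")
  gt <- if ("genotype" %in% names(depths)) depths$genotype else
    ifelse(depths$alt_reads > 0, "0/1", "0/0")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=mhtrace_family",
    sprintf("##contig=<ID=%s>", normalize_chrom(key[1])),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", depths$individual), collapse = "\t")
  )
  cells <- sprintf("%s:%d,%d", gt, depths$ref_reads, depths$alt_reads)
  body <- paste(c(normalize_chrom(key[1]), key[2], ".", toupper(key[3]),
                  toupper(key[4]), ".", "PASS", ".", "GT:AD", cells),
                collapse = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
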