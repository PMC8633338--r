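#' Read gene regions from a BED file
#'
#' BED intervals are 0-based half-open; they are converted to the 1-based
#' inclusive coordinates used internally. The BED `name` column carries the
#' gene symbol.
#'
#' @param path Path to a 4+ column BED file (chrom, start, end, name).
#' @return Tibble with `gene`, `chrom`, `start`, `end` (1-based inclusive).
#' @export
read_gene_regions <- function(path) {
  bed <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         comment = "#")
  if (ncol(bed) < 4L) abort("gene-region BED needs chrom, start, end, name")
  tibble(
    gene = as.character(bed[[4]]),
    chrom = normalize_chrom(bed[[1]]),
    start = as.integer(bed[[2]]) + 1L,
    end = as.integer(bed[[3]])
  )
}

#' Read a variant annotation table
#'
#' @param path TSV with columns `chrom`, `pos`, `ref`, `alt`, `gene`,
#'   `consequence` (one row per variant, consequence from the fixed
#'   vocabulary: missense, stop_gained, frameshift, inframe_deletion,
#'   splice_donor, splice_acceptor, synonymous, other).
#' @return Tibble keyed by normalized variant.
#' @export
read_annotations <- function(path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE)
  check_variant_key(ann, "annotation table")
  bad <- !ann$consequence %in% consequence_levels()
  if (any(bad)) {
    abort(paste0("unknown consequence value(s): ",
                 paste(unique(ann$consequence[bad]), collapse = ", ")))
  }
  norm <- normalize_variant(ann$pos, ann$ref, ann$alt)
  ann %>%
    mutate(chrom = normalize_chrom(.data$chrom),
           pos = norm$pos, ref = norm$ref, alt = norm$alt) %>%
    distinct(.data$chrom, .data$pos, .data$ref, .data$alt, .keep_all = TRUE)
}

#' Load per-variant cohort summaries from a multi-sample VCF
#'
#' Restricts to variants inside the supplied gene regions, decomposes
#' multiallelic sites into one biallelic record per alternate allele
#' (minimal representation), counts alleles over non-missing called genotypes
#' only, and attaches gene/consequence annotations. In-region variants absent
#' from the annotation table are kept with `consequence = "other"` and a
#' warning.
#'
#' @param vcf_file Path to a VCF (v4.2+) with per-sample GT.
#' @param gene_regions Tibble from [read_gene_regions()] (or with the same
#'   columns), non-overlapping per chromosome.
#' @param annotations Tibble from [read_annotations()].
#' @return A tibble of class `mh_cohort`, sorted by (chrom, pos, ref, alt),
#'   with columns `chrom`, `pos`, `ref`, `alt`, `gene`, `consequence`,
#'   `allele_count`, `allele_number`, `maf`, `n_carriers` and a list-column
#'   `carriers` of individual identifiers. The number of samples is stored in
#'   attribute `cohort_size`.
#' @export
load_cohort_variants <- function(vcf_file, gene_regions, annotations) {
  vcf <- vcfR::read.vcfR(vcf_file, verbose = FALSE)
  fix <- vcf_fix_frame(vcf)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) abort("VCF has no GT FORMAT field")
  samples <- colnames(gt)
  n_sites <- nrow(fix)

  records <- vector("list", 0L)
  for (i in seq_len(n_sites)) {
    chrom <- normalize_chrom(fix$CHROM[i])
    pos <- as.integer(fix$POS[i])
    ref <- toupper(fix$REF[i])
    alts <- strsplit(toupper(fix$ALT[i]), ",", fixed = TRUE)[[1]]

    in_region <- gene_regions$chrom == chrom &
      gene_regions$start <= pos & gene_regions$end >= pos
    if (!any(in_region)) next

    raw <- gsub("\\|", "/", gt[i, ])
    bad <- !is.na(raw) & !grepl("^[0-9.]+(/[0-9.]+)*$", raw)
    if (any(bad)) {
      abort(sprintf("malformed genotype at VCF site %d (%s:%d), sample %s",
                    i, chrom, pos, samples[which(bad)[1]]))
    }
    alleles <- strsplit(ifelse(is.na(raw), "./.", raw), "/", fixed = TRUE)
    allele_number <- sum(vapply(alleles, function(a) sum(a != "."), integer(1)))

    for (j in seq_along(alts)) {
      carries <- vapply(alleles, function(a) any(a == as.character(j)),
                        logical(1))
      allele_count <- sum(vapply(
        alleles, function(a) sum(a == as.character(j)), integer(1)))
      norm <- normalize_variant(pos, ref, alts[j])
      records[[length(records) + 1L]] <- tibble(
        chrom = chrom, pos = norm$pos, ref = norm$ref, alt = norm$alt,
        allele_count = allele_count, allele_number = allele_number,
        carriers = list(samples[carries])
      )
    }
  }
  out <- if (length(records)) bind_rows(records) else
    tibble(chrom = character(), pos = integer(), ref = character(),
           alt = character(), allele_count = integer(),
           allele_number = integer(), carriers = list())

  ann <- annotations %>%
    select("chrom", "pos", "ref", "alt", "gene", "consequence")
  out <- left_join(out, ann, by = c("chrom", "pos", "ref", "alt"))
  unannotated <- is.na(out$consequence)
  if (any(unannotated)) {
    warn(paste0("no annotation for ", sum(unannotated),
                " in-region variant(s); kept with consequence 'other'"))
    out$consequence[unannotated] <- "other"
    out$gene[unannotated] <- NA_character_
  }
  out <- out %>%
    mutate(
      maf = ifelse(.data$allele_number > 0,
                   compute_maf(.data$allele_count,
                               pmax(.data$allele_number, 1L)), NA_real_),
      n_carriers = vapply(.data$carriers, length, integer(1))
    ) %>%
    select("chrom", "pos", "ref", "alt", "gene", "consequence",
           "allele_count", "allele_number", "maf", "n_carriers",
           "carriers") %>%
    arrange(.data$chrom, .data$pos, .data$ref, .data$alt)
  attr(out, "cohort_size") <- length(samples)
  class(out) <- c("mh_cohort", class(out))
  out
}

#' Minor allele frequency
#'
#' `min(allele_count, allele_number - allele_count) / allele_number`: the
#' frequency of the rarer allele, so a near-fixed alternate allele is still
#' "rare" on the minor scale.
#'
#' @param allele_count Alternate allele count(s).
#' @param allele_number Total called alleles; must be positive.
#' @return Numeric vector of minor allele frequencies in `[0, 0.5]`.
#' @examples
#' compute_maf(6, 332000) # ~1.8e-05, i.e. 0.0018%
#' @export
compute_maf <- function(allele_count, allele_number) {
  if (any(allele_number <= 0)) {
    abort("allele_number must be positive: frequency undefined")
  }
  if (any(allele_count < 0) || any(allele_count > allele_number)) {
    abort("allele_count must lie in [0, allele_number]")
  }
  pmin(allele_count, allele_number - allele_count) / allele_number
}

#' Filter a cohort table to rare variants with kept consequence classes
#'
#' Keeps records with `maf < maf_threshold` (strict inequality) and a
#' consequence in `kept_consequences`. Row order is preserved.
#'
#' @param table A cohort variant tibble (see [load_cohort_variants()]).
#' @param maf_threshold Strict MAF upper bound, in (0, 0.5]; default 0.001
#'   (the "MAF < 0.1%" rare-variant rule).
#' @param kept_consequences Consequence classes to keep; defaults to all
#'   protein-altering/splice classes ([default_kept_consequences()]).
#' @return The filtered tibble, same class and `cohort_size` attribute.
#' @export
filter_rare_coding <- function(table, maf_threshold = 0.001,
                               kept_consequences = default_kept_consequences()) {
  if (maf_threshold <= 0 || maf_threshold > 0.5) {
    abort("maf_threshold must be in (0, 0.5]")
  }
  keep <- !is.na(table$maf) & table$maf < maf_threshold &
    table$consequence %in% kept_consequences
  out <- table[keep, , drop = FALSE]
  attr(out, "cohort_size") <- attr(table, "cohort_size")
  class(out) <- unique(c("mh_cohort", class(out)))
  out
}

#' Carrier counts and frequencies for screened variants
#'
#' Per-variant carrier reports, or (with `merge = TRUE`) a single merged
#' report over the union of carrier sets — an individual carrying two
#' variants counts once. `frequency` is carriers over individuals;
#' `one_in_n` is the reciprocal rounded to the nearest 10 and `percent` the
#' percentage at two significant figures (the reporting conventions that turn
#' 43/62,240 into "1 in 1450" and "0.069%").
#'
#' @param table Cohort variant tibble with a `carriers` list-column.
#' @param cohort_size Number of individuals in the cohort.
#' @param merge If `TRUE`, collapse all rows into one union report.
#' @return A tibble of class `mh_carrier_report` with `n_carriers`,
#'   `cohort_size`, `frequency`, `percent`, `one_in_n` and a `carriers`
#'   list-column.
#' @examples
#' tab <- tibble::tibble(chrom = "chr19", pos = 1L, ref = "A", alt = "G",
#'                       carriers = list(letters[1:3]))
#' carrier_report(tab, cohort_size = 1000)
#' @export
carrier_report <- function(table, cohort_size, merge = FALSE) {
  if (cohort_size <= 0) abort("cohort_size must be positive")
  if (merge) {
    all_carriers <- sort(unique(unlist(table$carriers)))
    out <- tibble(
      chrom = NA_character_, pos = NA_integer_,
      ref = NA_character_, alt = NA_character_,
      n_carriers = length(all_carriers),
      cohort_size = as.integer(cohort_size),
      carriers = list(all_carriers)
    )
  } else {
    out <- as_tibble(table) %>%
      mutate(carriers = lapply(.data$carriers, function(x) sort(unique(x))),
             n_carriers = vapply(.data$carriers, length, integer(1)),
             cohort_size = as.integer(cohort_size)) %>%
      select(dplyr::any_of(c("chrom", "pos", "ref", "alt", "gene")),
             "n_carriers", "cohort_size", "carriers")
  }
  out <- out %>%
    mutate(
      frequency = .data$n_carriers / .data$cohort_size,
      percent = percent_2sf(.data$frequency),
      one_in_n = one_in_n(.data$cohort_size, .data$n_carriers)
    ) %>%
    dplyr::relocate("carriers", .after = dplyr::last_col())
  class(out) <- c("mh_carrier_report", class(out))
  out
}

#' Write / read the per-variant screen report
#'
#' The TSV report carries one row per variant (carriers serialized as a
#' comma-joined list); reading it back reproduces keys, counts and MAFs
#' exactly (MAF is recomputed from the integer counts).
#'
#' @param table Cohort variant tibble.
#' @param path Output TSV path.
#' @return `write_cohort_table()` returns `path` invisibly;
#'   `read_cohort_table()` returns the tibble.
#' @export
write_cohort_table <- function(table, path) {
  flat <- as_tibble(table) %>%
    mutate(carriers = vapply(.data$carriers, paste, character(1),
                             collapse = ","))
  readr::write_tsv(flat, path)
  invisible(path)
}

#' @rdname write_cohort_table
#' @export
read_cohort_table <- function(path) {
  flat <- readr::read_tsv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            chrom = "c", ref = "c", alt = "c", gene = "c",
                            consequence = "c", carriers = "c",
                            .default = readr::col_guess()))
  out <- flat %>%
    mutate(
      carriers = lapply(strsplit(
        ifelse(is.na(.data$carriers), "", .data$carriers), ",", fixed = TRUE),
        function(x) x[nzchar(x)]),
      maf = ifelse(.data$allele_number > 0,
                   compute_maf(.data$allele_count,
                               pmax(.data$allele_number, 1L)), NA_real_)
    )
  class(out) <- c("mh_cohort", class(out))
  out
}
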