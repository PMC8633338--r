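# Classification labels recognised in ClinVar-style tables, mapped to the
# internal tally columns.
classification_labels <- function() {
  c("pathogenic" = "pathogenic",
    "likely pathogenic" = "likely_pathogenic",
    "drug response pathogenic" = "drug_response_pathogenic",
    "uncertain" = "uncertain",
    "uncertain significance" = "uncertain",
    "vus" = "uncertain",
    "likely benign" = "likely_benign",
    "benign" = "benign")
}

tally_cols <- function() {
  c("pathogenic", "likely_pathogenic", "drug_response_pathogenic",
    "uncertain", "likely_benign", "benign")
}

#' Parse a ClinVar-style classification table
#'
#' Reads a TSV with one row per (variant, label) submission tally and groups
#' rows by variant into per-label submission counts. Label strings are
#' matched case-insensitively (underscores and spaces interchangeable).
#'
#' @param path Path to a TSV with header `chrom, pos, ref, alt, gene, hgvs_c,
#'   hgvs_p, label, n_submissions, phenotype`, or a data frame with those
#'   columns.
#' @return A tibble of class `mh_classifications`, one row per variant:
#'   the normalized key columns, `gene`, `hgvs_c`, `hgvs_p`, `phenotype`,
#'   and one submission-count column per label
#'   (`pathogenic`, `likely_pathogenic`, `drug_response_pathogenic`,
#'   `uncertain`, `likely_benign`, `benign`).
#' @export
parse_classifications <- function(path) {
  raw <- if (is.data.frame(path)) as_tibble(path) else
    readr::read_tsv(path, show_col_types = FALSE,
                    col_types = readr::cols(.default = "c",
                                            pos = "i", n_submissions = "i"))
  need <- c("chrom", "pos", "ref", "alt", "gene", "hgvs_c", "hgvs_p",
            "label", "n_submissions", "phenotype")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    abort(paste0("classification table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(raw) == 0L) {
    out <- tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), gene = character(),
                  hgvs_c = character(), hgvs_p = character(),
                  phenotype = character())
    for (col in tally_cols()) out[[col]] <- integer()
    class(out) <- c("mh_classifications", class(out))
    return(out)
  }
  check_variant_key(raw, "classification table")

  label_key <- tolower(gsub("_", " ", trimws(raw$label)))
  known <- classification_labels()
  unknown <- !label_key %in% names(known)
  if (any(unknown)) {
    abort(sprintf("unknown classification label '%s' in row %d",
                  raw$label[which(unknown)[1]], which(unknown)[1]))
  }
  norm <- normalize_variant(raw$pos, raw$ref, raw$alt)
  rows <- raw %>%
    mutate(chrom = normalize_chrom(.data$chrom),
           pos = norm$pos, ref = norm$ref, alt = norm$alt,
           label = unname(known[label_key]),
           n_submissions = as.integer(.data$n_submissions))
  if (any(rows$n_submissions < 0)) abort("n_submissions must be >= 0")

  dup <- rows %>%
    dplyr::count(.data$chrom, .data$pos, .data$ref, .data$alt, .data$label) %>%
    filter(.data$n > 1L)
  if (nrow(dup)) {
    abort(sprintf("duplicate (variant, label) rows, e.g. %s:%d %s>%s '%s'",
                  dup$chrom[1], dup$pos[1], dup$ref[1], dup$alt[1],
                  dup$label[1]))
  }

  wide <- rows %>%
    select("chrom", "pos", "ref", "alt", "label", "n_submissions") %>%
    tidyr::pivot_wider(names_from = "label", values_from = "n_submissions",
                       values_fill = 0L)
  for (col in setdiff(tally_cols(), names(wide))) wide[[col]] <- 0L
  meta <- rows %>%
    group_by(.data$chrom, .data$pos, .data$ref, .data$alt) %>%
    summarise(gene = dplyr::first(.data$gene),
              hgvs_c = dplyr::first(.data$hgvs_c),
              hgvs_p = dplyr::first(.data$hgvs_p),
              phenotype = dplyr::first(.data$phenotype), .groups = "drop")
  out <- left_join(meta, wide, by = c("chrom", "pos", "ref", "alt")) %>%
    select("chrom", "pos", "ref", "alt", "gene", "hgvs_c", "hgvs_p",
           "phenotype", dplyr::all_of(tally_cols())) %>%
    arrange(.data$chrom, .data$pos, .data$ref, .data$alt)
  if (any(rowSums(out[tally_cols()]) == 0L)) {
    abort("every variant needs at least one submission with count > 0")
  }
  class(out) <- c("mh_classifications", class(out))
  out
}

#' Aggregate per-variant classification tallies into actionability calls
#'
#' Let P be the pathogenic-side submissions (pathogenic + likely pathogenic +
#' drug-response pathogenic) and B the benign side (benign + likely benign).
#'
#' * `majority` (default): `actionable` iff P >= 1 and P > B;
#'   `conflicting_excluded` iff P >= 1 and B >= P; otherwise
#'   `not_actionable`. Uncertain-significance tallies never create conflict.
#' * `strict`: `actionable` iff P >= 1 and B = 0 and uncertain = 0;
#'   `conflicting_excluded` iff P >= 1 otherwise; else `not_actionable`.
#'
#' The majority rule keeps a variant whose pathogenic assertions strictly
#' outnumber a stray benign-side submission (e.g. tallies P:10, LB:1).
#'
#' @param entries Tibble from [parse_classifications()].
#' @param rule `"majority"` or `"strict"`.
#' @return A tibble of class `mh_actionability`: key columns plus
#'   `aggregate` (one of `actionable`, `conflicting_excluded`,
#'   `not_actionable`) and a human-readable `rationale`.
#' @export
aggregate_classification <- function(entries, rule = c("majority", "strict")) {
  rule <- match.arg(rule)
  p_side <- entries$pathogenic + entries$likely_pathogenic +
    entries$drug_response_pathogenic
  b_side <- entries$benign + entries$likely_benign
  u <- entries$uncertain
  if (rule == "majority") {
    aggregate <- ifelse(p_side >= 1 & p_side > b_side, "actionable",
                 ifelse(p_side >= 1, "conflicting_excluded", "not_actionable"))
  } else {
    aggregate <- ifelse(p_side >= 1 & b_side == 0 & u == 0, "actionable",
                 ifelse(p_side >= 1, "conflicting_excluded", "not_actionable"))
  }
  out <- entries %>%
    select(dplyr::any_of(c("chrom", "pos", "ref", "alt", "gene",
                           "hgvs_c", "hgvs_p"))) %>%
    mutate(
      aggregate = aggregate,
      rationale = sprintf(
        "rule=%s P=%d B=%d VUS=%d -> %s", rule, p_side, b_side, u, aggregate)
    )
  class(out) <- c("mh_actionability", class(out))
  out
}

#' Join actionability calls against the screened cohort
#'
#' Inner-joins the actionable calls onto the already-filtered cohort table by
#' normalized variant key and reports per-variant and merged (union of
#' carriers) carrier frequencies. Calls for variants absent from the cohort
#' are ignored with a note, since classification databases cover variants the
#' cohort never observed.
#'
#' @param screened MAF/consequence-filtered cohort tibble
#'   ([filter_rare_coding()]).
#' @param calls Tibble from [aggregate_classification()].
#' @param cohort_size Number of individuals; defaults to the `cohort_size`
#'   attribute of `screened`.
#' @return List with `per_variant` (carrier report rows for each actionable
#'   screened variant) and `merged` (single union row), both
#'   `mh_carrier_report` tibbles.
#' @export
actionable_carrier_report <- function(screened, calls,
                                      cohort_size = attr(screened, "cohort_size")) {
  if (is.null(cohort_size)) abort("cohort_size is required")
  actionable <- calls %>%
    filter(.data$aggregate == "actionable") %>%
    select("chrom", "pos", "ref", "alt")
  n_unmatched <- nrow(dplyr::anti_join(
    actionable, as_tibble(screened), by = c("chrom", "pos", "ref", "alt")))
  if (n_unmatched > 0) {
    inform(sprintf(
      "%d actionable call(s) not present in the screened cohort; ignored",
      n_unmatched))
  }
  hits <- inner_join(as_tibble(screened), actionable,
                     by = c("chrom", "pos", "ref", "alt"))
  list(
    per_variant = carrier_report(hits, cohort_size),
    merged = carrier_report(hits, cohort_size, merge = TRUE)
  )
}

#' Extend a carrier report with imputed-genotype carriers
#'
#' Adds individuals whose imputed dosage for any reported variant reaches the
#' threshold to the carrier set, and recomputes the frequency against the
#' (larger) genotyped cohort — e.g. sequenced carriers complemented by
#' chip-imputation carriers.
#'
#' @param report A single-row merged `mh_carrier_report` (see
#'   [carrier_report()] with `merge = TRUE`).
#' @param imputed Data frame with columns `individual` and `dosage`
#'   (expected alternate allele count, in `[0, 2]`).
#' @param cohort_size Size of the extended (imputed) cohort.
#' @param dosage_threshold Minimum dosage to accept a carrier, in (0, 2);
#'   default 0.9.
#' @return An updated single-row `mh_carrier_report`.
#' @export
extend_with_imputed <- function(report, imputed, cohort_size,
                                dosage_threshold = 0.9) {
  if (dosage_threshold <= 0 || dosage_threshold >= 2) {
    abort("dosage_threshold must be in (0, 2)")
  }
  if (any(imputed$dosage < 0 | imputed$dosage > 2)) {
    abort("imputed dosages must lie in [0, 2]")
  }
  added <- unique(imputed$individual[imputed$dosage >= dosage_threshold])
  carriers <- sort(unique(c(unlist(report$carriers), added)))
  out <- tibble(
    n_carriers = length(carriers),
    cohort_size = as.integer(cohort_size),
    frequency = length(carriers) / cohort_size,
    percent = percent_2sf(length(carriers) / cohort_size),
    one_in_n = one_in_n(cohort_size, length(carriers)),
    carriers = list(carriers)
  )
  class(out) <- c("mh_carrier_report", class(out))
  out
}

#' Write / read the ClinVar-style classification table
#'
#' @param entries Long-format tibble with the columns listed in
#'   [parse_classifications()] (one row per variant-label tally).
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_classifications <- function(entries, path) {
  readr::write_tsv(entries, path)
  invisible(path)
}
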