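#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an allelic-balance table
#'
#' @param x An `mh_balance` tibble from [allelic_balance_test()].
#' @param ... Unused.
#' @return A plain tibble with `individual`, `ratio`, `n`, `p_two_sided`
#'   (ratio reported at two decimals, the reporting convention).
#' @export
tidy.mh_balance <- function(x, ...) {
  as_tibble(x) %>%
    mutate(ratio = round(.data$ratio, 2)) %>%
    select("individual", "ratio", "n", "p_two_sided")
}

#' @rdname tidy.mh_balance
#' @export
glance.mh_balance <- function(x, ...) {
  tibble(n_individuals = nrow(x),
         n_significant_01 = sum(x$p_two_sided < 0.01, na.rm = TRUE),
         min_p = suppressWarnings(min(x$p_two_sided, na.rm = TRUE)))
}

#' Tidy a carrier-state table
#'
#' @param x An `mh_states` tibble from [classify_carrier_state()].
#' @param ... Unused.
#' @return `tidy()`: per-individual rows with rounded ratios. `glance()`:
#'   one row of state counts.
#' @export
tidy.mh_states <- function(x, ...) {
  as_tibble(x) %>%
    mutate(ratio = round(.data$ratio, 2)) %>%
    select("individual", "ratio", "n", "p_two_sided", "state")
}

#' @rdname tidy.mh_states
#' @export
glance.mh_states <- function(x, ...) {
  counts <- table(factor(x$state, levels = c("non_carrier", "heterozygous",
                                             "mosaic_candidate",
                                             "indeterminate")))
  out <- as_tibble(as.list(counts))
  out$n <- nrow(x)
  out
}

#' Tidy a shared-segment object
#'
#' @param x An `mh_segment` from [shared_segment()].
#' @param ... Unused.
#' @return `tidy()`: one row per member haplotype. `glance()`: one row with
#'   the segment bounds, length and member count.
#' @export
tidy.mh_segment <- function(x, ...) {
  x$members %>%
    mutate(chrom = x$chrom, start_pos = x$start_pos, end_pos = x$end_pos)
}

#' @rdname tidy.mh_segment
#' @export
glance.mh_segment <- function(x, ...) {
  tibble(chrom = x$chrom, start_pos = x$start_pos, end_pos = x$end_pos,
         length_bp = x$end_pos - x$start_pos + 1L,
         n_markers = x$end_index - x$start_index + 1L,
         n_members = nrow(x$members))
}

#' Tidy an origin inference
#'
#' @param x An `mh_origin` from [infer_origin()].
#' @param ... Unused.
#' @return `tidy()`: the ordered evidence findings, one per row.
#'   `glance()`: one row with the mode and originating individual.
#' @export
tidy.mh_origin <- function(x, ...) {
  tibble(step = seq_along(x$evidence), finding = x$evidence)
}

#' @rdname tidy.mh_origin
#' @export
glance.mh_origin <- function(x, ...) {
  tibble(originating_individual = x$originating_individual,
         mode = x$mode, n_findings = length(x$evidence))
}

#' Tidy a clinical grading result
#'
#' @param x An `mh_grade` from [grade_case()].
#' @param ... Unused.
#' @return `tidy()`: the scored indicators. `glance()`: one row with
#'   `score` and `rank`.
#' @export
tidy.mh_grade <- function(x, ...) {
  x$breakdown
}

#' @rdname tidy.mh_grade
#' @export
glance.mh_grade <- function(x, ...) {
  tibble(score = x$score, rank = x$rank)
}
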