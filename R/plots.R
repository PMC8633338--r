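#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_segment geom_hline
#'   geom_col geom_vline labs theme_minimal scale_colour_manual
NULL

#' @export
ggplot2::autoplot

#' Plot per-individual allelic balance
#'
#' Read-depth scatter of alternate-read fraction per individual with the
#' heterozygous 50/50 expectation; points are coloured by carrier state when
#' available.
#'
#' @param object An `mh_balance` or `mh_states` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mh_balance <- function(object, ...) {
  df <- as_tibble(object)
  p <- ggplot(df, aes(x = .data$n, y = .data$ratio)) +
    geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey40") +
    labs(x = "Total reads", y = "Alternate-read fraction",
         title = "Allelic balance at the focal variant") +
    theme_minimal()
  if ("state" %in% names(df)) {
    p <- p + geom_point(aes(colour = .data$state), size = 3) +
      scale_colour_manual(values = c(
        non_carrier = "grey60", heterozygous = "#2166AC",
        mosaic_candidate = "#B2182B", indeterminate = "orange"))
  } else {
    p <- p + geom_point(size = 3)
  }
  p
}

#' @rdname autoplot.mh_balance
#' @export
autoplot.mh_states <- autoplot.mh_balance

#' Plot a shared haplotype segment
#'
#' Marker positions along the chromosome with the shared segment drawn per
#' member haplotype and the focal variant marked.
#'
#' @param object An `mh_segment` from [shared_segment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mh_segment <- function(object, ...) {
  members <- object$members %>%
    mutate(hap = paste0(.data$individual, " (slot ", .data$slot, ")"),
           y = dplyr::row_number())
  focal <- object$map$positions[object$map$focal_index]
  ggplot(members) +
    geom_segment(aes(x = object$start_pos, xend = object$end_pos,
                     y = .data$hap, yend = .data$hap),
                 linewidth = 3, colour = "#2166AC") +
    geom_vline(xintercept = focal, linetype = "dashed",
               colour = "#B2182B") +
    labs(x = sprintf("%s position (bp)", object$chrom), y = NULL,
         title = "Shared haplotype segment",
         subtitle = sprintf("%s:%s-%s; dashed line: focal variant",
                            object$chrom,
                            format(object$start_pos, big.mark = ","),
                            format(object$end_pos, big.mark = ","))) +
    theme_minimal()
}

#' Plot a clinical grading result
#'
#' Bar chart of the observed indicators' points with the total score and
#' rank in the title.
#'
#' @param object An `mh_grade` from [grade_case()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mh_grade <- function(object, ...) {
  ggplot(object$breakdown,
         aes(x = stats::reorder(.data$id, .data$points),
             y = .data$points)) +
    geom_col(fill = "#2166AC") +
    ggplot2::coord_flip() +
    labs(x = NULL, y = "Points",
         title = sprintf("Clinical grading: %s pts, \"%s\"",
                         format(object$score), object$rank)) +
    theme_minimal()
}

#' Plot carrier frequencies from a carrier report
#'
#' @param report An `mh_carrier_report` tibble.
#' @return A ggplot object (per-variant carrier counts).
#' @export
plot_carrier_report <- function(report) {
  df <- as_tibble(report) %>%
    mutate(variant = ifelse(is.na(.data$chrom), "merged",
                            sprintf("%s:%d %s>%s", .data$chrom, .data$pos,
                                    .data$ref, .data$alt)))
  ggplot(df, aes(x = stats::reorder(.data$variant, .data$n_carriers),
                 y = .data$n_carriers)) +
    geom_col(fill = "#2166AC") +
    ggplot2::coord_flip() +
    labs(x = NULL, y = "Carriers",
         title = sprintf("Carriers per variant (cohort n = %s)",
                         format(df$cohort_size[1], big.mark = ","))) +
    theme_minimal()
}
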