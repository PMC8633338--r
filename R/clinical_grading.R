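#' Construct a clinical grading scale
#'
#' The malignant hyperthermia clinical grading scale assigns points to
#' observed clinical indicators and maps the total score to a qualitative
#' likelihood rank. Both the indicator table and the rank boundaries are
#' configuration, not hard-coded truth.
#'
#' @param indicators Tibble with columns `id`, `category`, `points`
#'   (non-negative).
#' @param rank_boundaries Tibble with `min_score` (strictly increasing) and
#'   `rank`; a score maps to the highest boundary it reaches.
#' @param category_rule `"sum_all"` (sum every observed indicator's points)
#'   or `"max_per_category"` (sum, over process categories, the maximum
#'   observed indicator points — the published scale's double-counting
#'   guard).
#' @return An object of class `mh_scale`.
#' @export
grading_scale <- function(indicators, rank_boundaries,
                          category_rule = c("sum_all", "max_per_category")) {
  category_rule <- match.arg(category_rule)
  need <- c("id", "category", "points")
  if (length(setdiff(need, names(indicators)))) {
    abort("indicators needs columns id, category, points")
  }
  if (anyDuplicated(indicators$id)) abort("indicator ids must be unique")
  if (any(indicators$points < 0)) abort("indicator points must be >= 0")
  if (nrow(rank_boundaries) == 0L) abort("rank_boundaries must be nonempty")
  if (is.unsorted(rank_boundaries$min_score, strictly = TRUE)) {
    abort("rank boundaries must be strictly increasing in min_score")
  }
  structure(list(indicators = as_tibble(indicators),
                 rank_boundaries = as_tibble(rank_boundaries),
                 category_rule = category_rule),
            class = "mh_scale")
}

#' Default malignant hyperthermia grading scale
#'
#' Ships the five indicators with their points (15 each for masseter spasm,
#' CK elevation, respiratory acidosis and inappropriate temperature
#' increase; 10 for metabolic acidosis), each in its own process category,
#' summed over all observed indicators. Rank boundaries follow the published
#' six-rank ladder, with "almost certain" from 50 points. Supply your own
#' [grading_scale()] (or [read_grading_scale()] config) for the full
#' published indicator set.
#'
#' @return An `mh_scale` object.
#' @examples
#' grade_case(c("masseter_spasm", "ck_elevation", "respiratory_acidosis",
#'              "inappropriate_temperature_increase", "metabolic_acidosis"))
#' @export
default_grading_scale <- function() {
  grading_scale(
    indicators = tibble(
      id = c("masseter_spasm", "ck_elevation", "respiratory_acidosis",
             "inappropriate_temperature_increase", "metabolic_acidosis"),
      category = c("rigidity", "muscle_breakdown", "respiratory_acidosis",
                   "temperature", "metabolic_acidosis"),
      points = c(15, 15, 15, 15, 10)
    ),
    rank_boundaries = tibble(
      min_score = c(0, 3, 10, 20, 35, 50),
      rank = c("almost never", "unlikely", "somewhat less than likely",
               "somewhat greater than likely", "very likely",
               "almost certain")
    ),
    category_rule = "sum_all"
  )
}

#' @export
print.mh_scale <- function(x, ...) {
  cat(sprintf("<mh_scale> %d indicator(s), rule %s, %d rank(s)\n",
              nrow(x$indicators), x$category_rule,
              nrow(x$rank_boundaries)))
  invisible(x)
}

#' Read a grading scale from a YAML config file
#'
#' Expected structure: `indicators` (list of `id`/`category`/`points`
#' entries), `rank_boundaries` (list of `min_score`/`rank` entries) and
#' optional `category_rule`.
#'
#' @param path YAML file path.
#' @return An `mh_scale` object.
#' @export
read_grading_scale <- function(path) {
  cfg <- yaml::read_yaml(path)
  grading_scale(
    indicators = dplyr::bind_rows(lapply(cfg$indicators, as_tibble)),
    rank_boundaries = dplyr::bind_rows(lapply(cfg$rank_boundaries,
                                              as_tibble)),
    category_rule = cfg$category_rule %||% "sum_all"
  )
}

#' Score a case against a grading scale
#'
#' @param observed Character vector of observed indicator ids (a set; order
#'   and duplication are irrelevant).
#' @param scale An [grading_scale()] object; defaults to
#'   [default_grading_scale()].
#' @return An object of class `mh_grade`: list with `score`, `rank` and
#'   `breakdown` (tibble of the scored indicators).
#' @examples
#' grade_case(c("masseter_spasm", "metabolic_acidosis"))
#' @export
grade_case <- function(observed, scale = default_grading_scale()) {
  observed <- unique(as.character(observed))
  unknown <- setdiff(observed, scale$indicators$id)
  if (length(unknown)) {
    abort(paste0("unknown indicator id(s): ",
                 paste(unknown, collapse = ", ")))
  }
  hit <- scale$indicators %>% filter(.data$id %in% observed)
  score <- if (scale$category_rule == "sum_all") {
    sum(hit$points)
  } else {
    if (nrow(hit)) {
      sum((hit %>% group_by(.data$category) %>%
             summarise(pts = max(.data$points), .groups = "drop"))$pts)
    } else 0
  }
  reached <- scale$rank_boundaries %>% filter(.data$min_score <= score)
  if (nrow(reached) == 0L) {
    abort("score falls below every rank boundary; add a floor boundary")
  }
  structure(list(score = score, rank = tail(reached$rank, 1L),
                 breakdown = hit), class = "mh_grade")
}

#' @export
print.mh_grade <- function(x, ...) {
  cat(sprintf("<mh_grade> score %s -> \"%s\"\n", format(x$score), x$rank))
  invisible(x)
}
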