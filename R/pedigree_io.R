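#' Read / write a 6-column PED pedigree file
#'
#' Standard PED columns: family id, individual id, father id, mother id, sex
#' (1 male, 2 female, 0 unknown), phenotype. `0` parent ids become `NA`.
#'
#' @param path PED file path.
#' @return `read_ped()`: tibble with `family`, `id`, `father_id`,
#'   `mother_id`, `sex` (`"male"`, `"female"`, `"unknown"`), `phenotype`,
#'   `label` (copy of `id`). `write_ped()`: `path`, invisibly.
#' @export
read_ped <- function(path) {
  ped <- readr::read_tsv(path, col_names = c("family", "id", "father_id",
                                             "mother_id", "sex", "phenotype"),
                         show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  out <- ped %>%
    mutate(
      father_id = ifelse(.data$father_id == "0", NA_character_,
                         .data$father_id),
      mother_id = ifelse(.data$mother_id == "0", NA_character_,
                         .data$mother_id),
      sex = unname(c("0" = "unknown", "1" = "male",
                     "2" = "female")[.data$sex]),
      label = .data$id
    )
  check_pedigree(out)
  out
}

#' @param pedigree Pedigree tibble (`id`, `sex`, `father_id`, `mother_id`,
#'   optionally `family`, `phenotype`).
#' @rdname read_ped
#' @export
write_ped <- function(pedigree, path) {
  fam <- if ("family" %in% names(pedigree)) pedigree$family else "FAM1"
  phe <- if ("phenotype" %in% names(pedigree)) pedigree$phenotype else "0"
  sex_code <- c(male = "1", female = "2", unknown = "0")[pedigree$sex]
  lines <- sprintf("%s\t%s\t%s\t%s\t%s\t%s", fam, pedigree$id,
                   ifelse(is.na(pedigree$father_id), "0",
                          pedigree$father_id),
                   ifelse(is.na(pedigree$mother_id), "0",
                          pedigree$mother_id),
                   sex_code, phe)
  writeLines(lines, path)
  invisible(path)
}

# Structural validation: parents exist, sexes consistent, no cycles.
check_pedigree <- function(pedigree) {
  for (col in c("father_id", "mother_id")) {
    known <- pedigree[[col]][!is.na(pedigree[[col]])]
    missing <- setdiff(known, pedigree$id)
    if (length(missing)) {
      abort(paste0(col, " refers to unknown individual(s): ",
                   paste(missing, collapse = ", ")))
    }
  }
  fathers <- pedigree$father_id[!is.na(pedigree$father_id)]
  if (any(pedigree$sex[match(fathers, pedigree$id)] == "female")) {
    abort("a father is recorded as female")
  }
  mothers <- pedigree$mother_id[!is.na(pedigree$mother_id)]
  if (any(pedigree$sex[match(mothers, pedigree$id)] == "male")) {
    abort("a mother is recorded as male")
  }
  # cycle check by iterative ancestor climbing
  for (start in pedigree$id) {
    frontier <- start
    seen <- character(0)
    while (length(frontier)) {
      rows <- match(frontier, pedigree$id)
      nxt <- unique(c(pedigree$father_id[rows], pedigree$mother_id[rows]))
      nxt <- nxt[!is.na(nxt)]
      if (start %in% nxt) abort(sprintf("'%s' is its own ancestor", start))
      frontier <- setdiff(nxt, seen)
      seen <- c(seen, nxt)
    }
  }
  invisible(pedigree)
}

#' Write / read phased parent-of-origin haplotypes as TSV
#'
#' Wide format: `individual`, `haplotype_slot`, `parental_origin`, then one
#' column per marker named `m<position>` with alleles 0/1 and `NA` for
#' missing.
#'
#' @param phased Phased haplotype tibble (`individual`, `slot`, `origin`,
#'   list-column `alleles`).
#' @param map An [marker_map()] object.
#' @param path TSV path.
#' @return `write_haplotypes()`: `path` invisibly. `read_haplotypes()`:
#'   list with `phased` and `map`.
#' @export
write_haplotypes <- function(phased, map, path) {
  wide <- tibble(individual = phased$individual,
                 haplotype_slot = phased$slot,
                 parental_origin = phased$origin)
  allele_mat <- do.call(rbind, phased$alleles)
  colnames(allele_mat) <- paste0("m", map$positions)
  readr::write_tsv(dplyr::bind_cols(wide, as_tibble(allele_mat)), path)
  invisible(path)
}

#' @param chrom Chromosome of the marker panel.
#' @param focal_pos Focal variant position (must be a marker).
#' @rdname write_haplotypes
#' @export
read_haplotypes <- function(path, chrom, focal_pos) {
  wide <- readr::read_tsv(path, show_col_types = FALSE)
  marker_cols <- grep("^m[0-9]+$", names(wide), value = TRUE)
  positions <- as.integer(sub("^m", "", marker_cols))
  map <- marker_map(chrom, positions, focal_pos)
  mat <- as.matrix(wide[marker_cols])
  phased <- tibble(
    individual = as.character(wide$individual),
    slot = as.integer(wide$haplotype_slot),
    origin = as.character(wide$parental_origin),
    alleles = lapply(seq_len(nrow(mat)),
                     function(i) as.integer(mat[i, ]))
  )
  list(phased = phased, map = map)
}
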