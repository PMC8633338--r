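#' Construct a marker map
#'
#' A marker panel on one chromosome with a designated focal marker (the site
#' of the variant being traced). Positions are 1-based and strictly
#' increasing.
#'
#' @param chrom Chromosome name (normalized to the `chr` prefix).
#' @param positions Strictly increasing integer vector of marker positions.
#' @param focal_pos Position of the focal variant; must be one of
#'   `positions`.
#' @return An object of class `mh_marker_map`: list with `chrom`,
#'   `positions`, `focal_index`.
#' @export
marker_map <- function(chrom, positions, focal_pos) {
  positions <- as.integer(positions)
  if (any(diff(positions) <= 0)) {
    abort("marker positions must be strictly increasing")
  }
  focal_index <- match(as.integer(focal_pos), positions)
  if (is.na(focal_index)) {
    abort("focal_pos must be one of the marker positions")
  }
  structure(list(chrom = normalize_chrom(chrom), positions = positions,
                 focal_index = focal_index),
            class = "mh_marker_map")
}

#' @export
print.mh_marker_map <- function(x, ...) {
  cat(sprintf("<mh_marker_map> %s: %d markers %s-%s, focal %s (index %d)\n",
              x$chrom, length(x$positions), format(min(x$positions)),
              format(max(x$positions)), format(x$positions[x$focal_index]),
              x$focal_index))
  invisible(x)
}

# Accept carrier states as a named character vector or a tibble with
# individual/state columns.
as_states <- function(carrier_states) {
  if (is.data.frame(carrier_states)) {
    setNames(as.character(carrier_states$state), carrier_states$individual)
  } else {
    carrier_states
  }
}

# Rows of the phased table for one individual, with basic validation.
phased_rows <- function(phased, id) {
  rows <- phased[phased$individual == id, , drop = FALSE]
  if (nrow(rows) == 0L) abort(sprintf("no phased haplotypes for '%s'", id))
  rows
}

#' Shared haplotype segment among carriers around the focal variant
#'
#' For each carrier, the member haplotype is the phased haplotype carrying
#' the focal alternate allele. Starting from the focal marker the segment is
#' extended left and right marker-by-marker while all member haplotypes
#' agree. Missing alleles act as wildcards, but no more than
#' `max_missing_run` consecutive uninformative comparisons are crossed; the
#' reported bounds are the outermost markers with informative agreement.
#' With a single carrier the segment spans the whole map.
#'
#' @param phased Tibble with columns `individual`, `slot` (1/2), `origin`
#'   (`"paternal"`, `"maternal"`, `"unknown"`) and list-column `alleles`
#'   (integer 0/1/NA vectors over the marker map).
#' @param carriers Character vector of carrier individual ids (nonempty).
#' @param map An [marker_map()] object.
#' @param max_missing_run Maximum consecutive wildcard-only comparisons
#'   crossed during extension (default 10).
#' @return An object of class `mh_segment`: list with `chrom`, `start_pos`,
#'   `end_pos`, `start_index`, `end_index`, `members` (tibble of individual,
#'   slot), `consensus` (integer vector over the full map, NA outside the
#'   segment or where uninformative) and `map`.
#' @export
shared_segment <- function(phased, carriers, map, max_missing_run = 10) {
  if (length(carriers) == 0L) abort("carriers must be nonempty")
  f <- map$focal_index
  members <- list()
  for (id in carriers) {
    rows <- phased_rows(phased, id)
    hit <- vapply(rows$alleles,
                  function(a) !is.na(a[f]) && a[f] == 1L, logical(1))
    if (!any(hit)) {
      abort(sprintf(
        "individual '%s' is listed as a carrier but neither haplotype carries the focal alternate allele", id))
    }
    for (r in which(hit)) {
      members[[length(members) + 1L]] <- list(
        individual = id, slot = rows$slot[r], alleles = rows$alleles[[r]])
    }
  }
  H <- do.call(cbind, lapply(members, function(m) m$alleles))
  n_mark <- length(map$positions)
  n_mem <- ncol(H)

  if (length(carriers) == 1L) {
    lo <- 1L
    hi <- n_mark
  } else {
    step <- function(idx) {
      vals <- H[idx, ]
      nm <- vals[!is.na(vals)]
      if (length(nm) <= 1L) return("wildcard")
      if (all(nm == nm[1L])) return("agree")
      "disagree"
    }
    extend <- function(dir) {
      last <- f
      run <- 0L
      j <- f + dir
      while (j >= 1L && j <= n_mark) {
        s <- step(j)
        if (s == "disagree") break
        if (s == "wildcard") {
          run <- run + 1L
          if (run > max_missing_run) break
        } else {
          last <- j
          run <- 0L
        }
        j <- j + dir
      }
      last
    }
    lo <- extend(-1L)
    hi <- extend(1L)
  }

  consensus <- rep(NA_integer_, n_mark)
  for (j in lo:hi) {
    vals <- H[j, ]
    nm <- unique(vals[!is.na(vals)])
    if (length(nm) == 1L) consensus[j] <- nm
  }
  structure(list(
    chrom = map$chrom,
    start_pos = map$positions[lo], end_pos = map$positions[hi],
    start_index = lo, end_index = hi,
    members = tibble(
      individual = vapply(members, `[[`, character(1), "individual"),
      slot = vapply(members, function(m) as.integer(m$slot), integer(1))),
    consensus = consensus,
    map = map
  ), class = "mh_segment")
}

#' @export
print.mh_segment <- function(x, ...) {
  cat(sprintf("<mh_segment> %s:%s-%s (%d markers), %d member haplotype(s)\n",
              x$chrom, format(x$start_pos, big.mark = ","),
              format(x$end_pos, big.mark = ","),
              x$end_index - x$start_index + 1L, nrow(x$members)))
  invisible(x)
}

#' Export a shared segment as a BED interval
#'
#' Converts the internal 1-based inclusive bounds to BED's 0-based half-open
#' convention.
#'
#' @param segment An `mh_segment`.
#' @param path Output BED path.
#' @param name Interval name (default `"shared_segment"`).
#' @return `path`, invisibly.
#' @export
write_segment_bed <- function(segment, path, name = "shared_segment") {
  writeLines(sprintf("%s\t%d\t%d\t%s", segment$chrom,
                     segment$start_pos - 1L, segment$end_pos, name), path)
  invisible(path)
}

# Undirected pedigree connectivity (child-parent edges) among a set of ids.
pedigree_components <- function(pedigree, ids) {
  edges <- list()
  for (i in seq_len(nrow(pedigree))) {
    for (p in c(pedigree$father_id[i], pedigree$mother_id[i])) {
      if (!is.na(p)) edges[[length(edges) + 1L]] <- c(pedigree$id[i], p)
    }
  }
  adj <- split(
    c(vapply(edges, `[`, character(1), 2), vapply(edges, `[`, character(1), 1)),
    c(vapply(edges, `[`, character(1), 1), vapply(edges, `[`, character(1), 2))
  )
  comp <- setNames(rep(NA_integer_, length(ids)), ids)
  k <- 0L
  for (id in ids) {
    if (!is.na(comp[id])) next
    k <- k + 1L
    queue <- id
    seen <- character(0)
    while (length(queue)) {
      v <- queue[1L]
      queue <- queue[-1L]
      if (v %in% seen) next
      seen <- c(seen, v)
      queue <- c(queue, adj[[v]])
    }
    comp[ids %in% seen] <- k
  }
  split(ids, comp)
}

#' Trace the parental origin and transmission chain of the shared segment
#'
#' For every member haplotype of the segment, reports its parent-of-origin
#' label and the transmitting parent, and assembles the chain of
#' parent-to-child transmissions linking the carriers. The topmost member —
#' the carrier whose transmitting parent is not itself a carrier — anchors
#' the grandparental lineage: its haplotype label (maternal/paternal) says
#' which side of the family the variant-bearing background came from.
#'
#' @param segment An [shared_segment()] result.
#' @param pedigree Pedigree tibble (`id`, `sex`, `father_id`, `mother_id`,
#'   `label`), e.g. from [read_ped()] or [gen_pedigree()].
#' @param phased Phased haplotype tibble (see [shared_segment()]).
#' @return An object of class `mh_path`: list with `members` (tibble of
#'   individual, slot, origin, parent_id, parent_is_member), `chain`
#'   (tibble parent, child), `topmost` (character vector; length 1 when the
#'   seniority is unambiguous) and `topmost_origin`.
#' @export
trace_parental_origin <- function(segment, pedigree, phased) {
  mem <- segment$members %>% distinct(.data$individual, .keep_all = TRUE)
  ids <- mem$individual

  comps <- pedigree_components(pedigree, ids)
  if (length(comps) > 1L) {
    abort(paste0("segment members are not connected in the pedigree: ",
                 paste(vapply(comps, paste, character(1), collapse = ","),
                       collapse = " | ")))
  }

  origin <- character(nrow(mem))
  parent_id <- character(nrow(mem))
  for (i in seq_len(nrow(mem))) {
    rows <- phased_rows(phased, mem$individual[i])
    origin[i] <- rows$origin[match(mem$slot[i], rows$slot)]
    ped_row <- match(mem$individual[i], pedigree$id)
    if (is.na(ped_row)) abort(sprintf("'%s' absent from pedigree",
                                      mem$individual[i]))
    parent_id[i] <- switch(origin[i],
      paternal = pedigree$father_id[ped_row],
      maternal = pedigree$mother_id[ped_row],
      NA_character_)
  }
  members <- tibble(
    individual = ids, slot = mem$slot, origin = origin,
    parent_id = parent_id,
    parent_is_member = !is.na(parent_id) & parent_id %in% ids
  )
  chain <- members %>%
    filter(.data$parent_is_member) %>%
    select(parent = "parent_id", child = "individual")
  topmost <- members$individual[!members$parent_is_member]
  topmost_origin <- if (length(topmost) == 1L) {
    members$origin[members$individual == topmost]
  } else {
    NA_character_
  }
  structure(list(members = members, chain = chain, topmost = topmost,
                 topmost_origin = topmost_origin), class = "mh_path")
}

#' @export
print.mh_path <- function(x, ...) {
  cat(sprintf("<mh_path> %d member(s), topmost: %s (%s haplotype)\n",
              nrow(x$members), paste(x$topmost, collapse = ", "),
              x$topmost_origin %||% "unknown"))
  if (nrow(x$chain)) {
    cat(paste0("  ", x$chain$parent, " -> ", x$chain$child, collapse = "\n"),
        "\n")
  }
  invisible(x)
}

#' Detect relatives sharing the segment without carrying the variant
#'
#' A discordant sharer carries a haplotype identical (missing as wildcard) to
#' the segment consensus across the whole segment — the focal site itself
#' excluded, since that is exactly what they lack — yet is a confirmed
#' non-carrier of the focal variant. Such individuals delimit where on the
#' shared background the mutation arose.
#'
#' @param segment An [shared_segment()] result.
#' @param phased Phased haplotype tibble.
#' @param carrier_states Named character vector or tibble
#'   (`individual`, `state`) from [classify_carrier_state()].
#' @param relatives Ids to screen.
#' @return Character vector of discordant sharer ids (possibly empty).
#' @export
detect_discordant_sharers <- function(segment, phased, carrier_states,
                                      relatives) {
  states <- as_states(carrier_states)
  idx <- segment$start_index:segment$end_index
  # the focal variant itself is what a discordant sharer lacks; only the
  # surrounding background is compared
  idx <- setdiff(idx, segment$map$focal_index)
  cons <- segment$consensus[idx]
  out <- character(0)
  for (id in relatives) {
    if (is.na(states[id]) || states[id] != "non_carrier") next
    rows <- phased_rows(phased, id)
    shares <- any(vapply(rows$alleles, function(a) {
      v <- a[idx]
      all(is.na(v) | is.na(cons) | v == cons)
    }, logical(1)))
    if (shares) out <- c(out, id)
  }
  out
}

#' Infer the origin of the traced variant
#'
#' Combines the carrier states, the shared segment, the discordant sharers
#' and the transmission chain into an origin call. Decision rules, applied in
#' order to the topmost carrier T:
#'
#' 1. T is a mosaic candidate and a discordant relative shares T's
#'    segment-bearing lineage: `de_novo_germline_mosaic` in T — the mutation
#'    arose in T as an early embryo, after the shared background existed.
#' 2. T is a balanced heterozygote and a discordant sharer exists:
#'    `de_novo_full_heterozygote` in T.
#' 3. T is heterozygous, no discordant sharer, and T's parents are untyped:
#'    `inherited_unresolved` — the origin lies at or above T.
#' 4. Otherwise `ambiguous` (including ties for the topmost carrier).
#'
#' @param pedigree Pedigree tibble.
#' @param carrier_states Named vector or tibble of per-individual states.
#' @param segment An [shared_segment()] result.
#' @param discordant Character vector from [detect_discordant_sharers()].
#' @param path An [trace_parental_origin()] result.
#' @return An object of class `mh_origin`: list with
#'   `originating_individual` (id or `"unknown"`), `mode` and `evidence`
#'   (character vector recording each rule evaluated).
#' @export
infer_origin <- function(pedigree, carrier_states, segment, discordant,
                         path) {
  states <- as_states(carrier_states)
  evidence <- character(0)
  note <- function(...) evidence <<- c(evidence, sprintf(...))

  if (length(path$topmost) != 1L) {
    note("topmost carrier not unique (%s): carriers do not form a single traced lineage",
         paste(path$topmost, collapse = ", "))
    return(structure(list(originating_individual = "unknown",
                          mode = "ambiguous", evidence = evidence),
                     class = "mh_origin"))
  }
  tm <- path$topmost
  st <- if (tm %in% names(states)) states[[tm]] else "indeterminate"
  note("topmost carrier %s via %s haplotype; state %s", tm,
       path$topmost_origin %||% "unknown", st)
  note("discordant sharers: %s",
       if (length(discordant)) paste(discordant, collapse = ", ") else "none")

  if (st == "mosaic_candidate" && length(discordant) > 0L) {
    note("rule 1: mosaic topmost carrier with a non-carrier sharing its haplotype background -> de novo germline mosaicism in %s", tm)
    mode <- "de_novo_germline_mosaic"
    origin <- tm
  } else if (st == "heterozygous" && length(discordant) > 0L) {
    note("rule 2: heterozygous topmost carrier with a non-carrier sharer -> de novo full heterozygote in %s", tm)
    mode <- "de_novo_full_heterozygote"
    origin <- tm
  } else {
    ped_row <- match(tm, pedigree$id)
    parents <- c(pedigree$father_id[ped_row], pedigree$mother_id[ped_row])
    parents <- parents[!is.na(parents)]
    typed <- parents[parents %in% names(states) &
                       states[parents] != "indeterminate"]
    if (st == "heterozygous" && length(discordant) == 0L &&
        length(typed) == 0L) {
      note("rule 3: heterozygous topmost carrier, no discordant sharer, parents untyped -> inherited, origin unresolved at or above %s", tm)
      mode <- "inherited_unresolved"
      origin <- "unknown"
    } else {
      note("rule 4: no rule matched -> ambiguous")
      mode <- "ambiguous"
      origin <- "unknown"
    }
  }
  structure(list(originating_individual = origin, mode = mode,
                 evidence = evidence), class = "mh_origin")
}

#' @export
print.mh_origin <- function(x, ...) {
  cat(sprintf("<mh_origin> mode: %s; originating individual: %s\n",
              x$mode, x$originating_individual))
  cat(paste0("  - ", x$evidence, collapse = "\n"), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a)) b else a
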