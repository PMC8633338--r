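#' Simulation configuration for the synthetic-data generator
#'
#' One object carries every knob of the generator: pedigree shape, marker
#' panel, recombination and read-depth models, the mosaicism parameters and
#' the population-cohort parameters. Identical configurations (including the
#' seed) yield byte-identical outputs; each generator operation draws from
#' its own seed stream derived from `seed` plus an operation tag, so adding
#' one operation never perturbs another's draws.
#'
#' @param seed Integer master seed.
#' @param n_generations,children_per_couple Pedigree shape (default 4
#'   generations, 2 children per couple, matching a three-to-four-generation
#'   family study).
#' @param chrom,chrom_length Chromosome name and length in bp (defaults
#'   mirror chromosome 19).
#' @param focal_pos Position of the focal variant (default the RYR1 locus
#'   coordinate 38,496,455).
#' @param n_markers Number of phased markers on the panel (focal site
#'   included).
#' @param marker_freq Allele-1 frequency of founder haplotype markers
#'   (scalar; default 0.5, maximally informative chip-style markers).
#' @param recomb_rate Expected crossovers per meiosis for the chromosome
#'   (default 1.0).
#' @param depth_mean Mean sequencing depth (Poisson; default 30, standard
#'   short-read WGS).
#' @param error_rate Per-read miscall probability for non-carriers
#'   (default 0.002).
#' @param mosaic_cell_fraction Fraction of cells heterozygous in a mosaic
#'   founder (default 0.42, giving the index-case alternate-read fraction
#'   of ~0.21).
#' @param germline_transmission_fraction Probability that a transmitted copy
#'   of the mutant-background haplotype carries the variant when transmitted
#'   by the mosaic origin (default 0.5).
#' @param cohort_size,n_variants Population-screen cohort parameters
#'   (defaults 2000 individuals, 50 variants).
#' @param maf_spectrum List with `rare_weight` (fraction of variants that
#'   are rare), `rare_carriers_max` (rare variants get 1..max carriers) and
#'   `common_maf_range` (MAF range of the common remainder, above the 0.1%
#'   screening threshold).
#' @param missing_rate Per-genotype missingness in the synthetic cohort VCF.
#' @param classification_mix Named list of submission-tally profiles (named
#'   integer vectors over the classification labels) assigned to cohort
#'   variants; see [default_classification_mix()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_generations = 4L, children_per_couple = 2L,
                       chrom = "chr19", chrom_length = 58617616L,
                       focal_pos = 38496455L,
                       n_markers = 120L, marker_freq = 0.5,
                       recomb_rate = 1.0,
                       depth_mean = 30, error_rate = 0.002,
                       mosaic_cell_fraction = 0.42,
                       germline_transmission_fraction = 0.5,
                       cohort_size = 2000L, n_variants = 50L,
                       maf_spectrum = list(rare_weight = 0.8,
                                           rare_carriers_max = 4L,
                                           common_maf_range = c(0.002, 0.01)),
                       missing_rate = 0.005,
                       classification_mix = default_classification_mix()) {
  probs <- c(marker_freq, error_rate, mosaic_cell_fraction,
             germline_transmission_fraction, missing_rate,
             maf_spectrum$rare_weight)
  if (any(probs < 0 | probs > 1)) {
    abort("all probabilities must lie in [0, 1]")
  }
  if (n_generations < 2L) abort("n_generations must be >= 2")
  if (focal_pos < 1L || focal_pos > chrom_length) {
    abort("focal_pos must lie on the chromosome")
  }
  structure(list(
    seed = as.integer(seed), n_generations = as.integer(n_generations),
    children_per_couple = as.integer(children_per_couple),
    chrom = chrom, chrom_length = as.integer(chrom_length),
    focal_pos = as.integer(focal_pos), n_markers = as.integer(n_markers),
    marker_freq = marker_freq, recomb_rate = recomb_rate,
    depth_mean = depth_mean, error_rate = error_rate,
    mosaic_cell_fraction = mosaic_cell_fraction,
    germline_transmission_fraction = germline_transmission_fraction,
    cohort_size = as.integer(cohort_size),
    n_variants = as.integer(n_variants),
    maf_spectrum = maf_spectrum, missing_rate = missing_rate,
    classification_mix = classification_mix
  ), class = "sim_config")
}

roman_label <- function(generation, index) {
  paste0(as.character(utils::as.roman(generation)), "-", index)
}

#' Generate a synthetic pedigree
#'
#' Builds a connected multi-generation pedigree of monogamous couples with
#' assigned sexes and Roman-numeral generation labels ("II-5"). The
#' structure is deterministic given the configuration. The `"fig1"` preset
#' returns a fixed 16-member, four-generation family whose carrier topology
#' mirrors the index study: a grandmother (II-5) with a sister (II-2), a son
#' (III-5) with children by two partners (IV-4 the proband and IV-1 a
#' paternal half-sibling).
#'
#' @param config A [sim_config()].
#' @param preset Optional preset name; currently `"fig1"`.
#' @return A tibble with `id`, `sex`, `father_id`, `mother_id`,
#'   `generation`, `label` (same as `id`) and `founder`.
#' @export
gen_pedigree <- function(config = sim_config(), preset = NULL) {
  if (!is.null(preset)) {
    if (preset != "fig1") abort("unknown preset (available: 'fig1')")
    return(fig1_pedigree())
  }
  rows <- list()
  add <- function(id, sex, father = NA_character_, mother = NA_character_,
                  gen) {
    rows[[length(rows) + 1L]] <<- tibble(
      id = id, sex = sex, father_id = father, mother_id = mother,
      generation = gen, label = id, founder = is.na(father) & is.na(mother))
  }
  add("I-1", "male", gen = 1L)
  add("I-2", "female", gen = 1L)
  couples <- list(c("I-1", "I-2"))
  counter <- c(2L)
  for (g in 2L:config$n_generations) {
    nxt <- list()
    k <- 0L
    for (cp in couples) {
      for (ch in seq_len(config$children_per_couple)) {
        k <- k + 1L
        child_sex <- if (k %% 2L == 1L) "male" else "female"
        child <- roman_label(g, k)
        add(child, child_sex, father = cp[1], mother = cp[2], gen = g)
        if (g < config$n_generations) {
          k <- k + 1L
          spouse <- roman_label(g, k)
          spouse_sex <- if (child_sex == "male") "female" else "male"
          add(spouse, spouse_sex, gen = g)
          pair <- if (child_sex == "male") c(child, spouse) else
            c(spouse, child)
          nxt[[length(nxt) + 1L]] <- pair
        }
      }
    }
    couples <- nxt
  }
  out <- bind_rows(rows)
  check_pedigree(out)
  out
}

# Fixed 16-member family mirroring the index pedigree's carrier topology.
fig1_pedigree <- function() {
  ped <- tibble(
    id = c("I-1", "I-2",
           "II-1", "II-2", "II-3", "II-4", "II-5", "II-6",
           "III-1", "III-3", "III-4", "III-5", "III-6",
           "IV-1", "IV-2", "IV-4"),
    sex = c("male", "female",
            "male", "female", "male", "female", "female", "male",
            "male", "female", "female", "male", "female",
            "female", "female", "male"),
    father_id = c(NA, NA,
                  NA, "I-1", "I-1", NA, "I-1", NA,
                  "II-1", "II-3", NA, "II-6", NA,
                  "III-5", "III-5", "III-5"),
    mother_id = c(NA, NA,
                  NA, "I-2", "I-2", NA, "I-2", NA,
                  "II-2", "II-4", NA, "II-5", NA,
                  "III-6", "III-4", "III-4"),
    generation = c(1L, 1L, rep(2L, 6L), rep(3L, 5L), rep(4L, 3L))
  )
  ped$label <- ped$id
  ped$founder <- is.na(ped$father_id) & is.na(ped$mother_id)
  check_pedigree(ped)
  ped
}

# Which parental haplotype slot a meiosis transmits at a position: the start
# slot, switched once per crossover to the left of (or at) the position.
meiosis_slot_at <- function(start_slot, breakpoints, pos) {
  n_cross <- sum(breakpoints <= pos)
  if (n_cross %% 2L == 0L) start_slot else 3L - start_slot
}

#' Drop phased haplotypes through a pedigree
#'
#' Founder haplotypes are drawn marker-by-marker at the configured allele
#' frequency (the focal site starts ancestral in everyone). Every meiosis
#' draws a Poisson number of crossovers with uniform positions and copies
#' the recombined parental haplotype to the child; the child's two
#' haplotypes are labelled paternal/maternal by construction. All crossover
#' breakpoints are recorded in the returned meiosis ledger, which is
#' sufficient to reconstruct the true transmitted segments.
#'
#' @param pedigree A pedigree tibble ([gen_pedigree()]).
#' @param config A [sim_config()].
#' @return List with `phased` (tibble: `individual`, `slot`, `origin`,
#'   list-column `alleles`), `map` (an [marker_map()]) and `meioses`
#'   (tibble: `child`, `side`, `parent`, `start_slot`, list-column
#'   `breakpoints`).
#' @export
drop_haplotypes <- function(pedigree, config = sim_config()) {
  withr::with_seed(op_seed(config$seed, "drop_haplotypes"), {
    positions <- sort(sample.int(config$chrom_length,
                                 config$n_markers - 1L))
    positions <- sort(unique(c(positions, config$focal_pos)))
    map <- marker_map(config$chrom, positions, config$focal_pos)
    n_mark <- length(positions)
    freq <- rep(config$marker_freq, n_mark)
    freq[map$focal_index] <- 0

    phased <- list()
    meioses <- list()
    hap_of <- list() # id -> list(slot1 alleles, slot2 alleles)

    ord <- order(pedigree$generation)
    for (i in ord) {
      id <- pedigree$id[i]
      haps <- list()
      for (side in c("paternal", "maternal")) {
        parent <- if (side == "paternal") pedigree$father_id[i] else
          pedigree$mother_id[i]
        if (is.na(parent)) {
          hap <- rbinom(n_mark, 1L, freq)
        } else {
          start_slot <- sample(1:2, 1L)
          n_cross <- rpois(1L, config$recomb_rate)
          breakpoints <- sort(runif(n_cross, min = 1,
                                    max = config$chrom_length))
          slot_at <- vapply(positions, function(p)
            meiosis_slot_at(start_slot, breakpoints, p), integer(1))
          parent_haps <- hap_of[[parent]]
          hap <- ifelse(slot_at == 1L, parent_haps[[1]], parent_haps[[2]])
          meioses[[length(meioses) + 1L]] <- tibble(
            child = id, side = side, parent = parent,
            start_slot = start_slot, breakpoints = list(breakpoints))
        }
        haps[[side]] <- as.integer(hap)
      }
      hap_of[[id]] <- list(haps$paternal, haps$maternal)
      phased[[length(phased) + 1L]] <- tibble(
        individual = id, slot = 1:2,
        origin = c("paternal", "maternal"),
        alleles = list(haps$paternal, haps$maternal))
    }
    list(
      phased = bind_rows(phased),
      map = map,
      meioses = if (length(meioses)) bind_rows(meioses) else
        tibble(child = character(), side = character(),
               parent = character(), start_slot = integer(),
               breakpoints = list())
    )
  })
}

#' Plant a heterozygous or mosaic mutation on a founder haplotype
#'
#' Places the focal alternate allele on one named haplotype of the origin
#' individual and propagates it down the pedigree along the true transmitted
#' haplotypes recorded in the meiosis ledger. A descendant who inherited the
#' mutant-background haplotype at the focal position carries the variant
#' with probability `germline_transmission_fraction` per transmission out of
#' a mosaic origin (the fraction of mutant germ cells), and with probability
#' 1 otherwise. Descendants who inherited the background without the variant
#' are recorded as background sharers — the discordant relatives the tracing
#' module is designed to find.
#'
#' @param drop Result of [drop_haplotypes()].
#' @param pedigree The pedigree the haplotypes were dropped through.
#' @param origin Id of the originating individual.
#' @param mode `"heterozygous"` (constitutional) or `"mosaic"`.
#' @param config A [sim_config()].
#' @param origin_slot Which of the origin's haplotypes receives the
#'   mutation: `"maternal"` (default, as in the index family) or
#'   `"paternal"`.
#' @return List with updated `phased`, `map`, `states` (tibble:
#'   `individual`, `state` in non_carrier/heterozygous/mosaic,
#'   `cell_fraction`), `carriers`, `background_sharers`, `origin`, `mode`.
#' @export
plant_mutation <- function(drop, pedigree, origin,
                           mode = c("heterozygous", "mosaic"),
                           config = sim_config(),
                           origin_slot = c("maternal", "paternal")) {
  mode <- match.arg(mode)
  origin_slot <- match.arg(origin_slot)
  if (!origin %in% pedigree$id) abort("origin must be in the pedigree")
  phased <- drop$phased
  f <- drop$map$focal_index

  slot_of <- function(id, side) which(phased$individual == id &
                                        phased$origin == side)
  origin_row <- slot_of(origin, origin_slot)
  if (length(origin_row) != 1L) {
    abort(sprintf("origin '%s' lacks a %s haplotype", origin, origin_slot))
  }

  withr::with_seed(op_seed(config$seed, "plant_mutation"), {
    # id -> carrier slot side; variant presence; background presence
    background <- setNames(rep(NA_character_, nrow(pedigree)), pedigree$id)
    variant <- setNames(rep(FALSE, nrow(pedigree)), pedigree$id)
    background[origin] <- origin_slot
    variant[origin] <- TRUE

    ord <- order(pedigree$generation)
    for (i in ord) {
      id <- pedigree$id[i]
      if (id == origin) next
      for (side in c("paternal", "maternal")) {
        parent <- if (side == "paternal") pedigree$father_id[i] else
          pedigree$mother_id[i]
        if (is.na(parent) || is.na(background[parent])) next
        m <- drop$meioses %>%
          filter(.data$child == id, .data$side == !!side)
        parent_slot_sent <- meiosis_slot_at(
          m$start_slot[1], m$breakpoints[[1]], drop$map$positions[f])
        parent_carrier_slot <- if (background[parent] == "paternal") 1L else 2L
        if (parent_slot_sent == parent_carrier_slot) {
          background[id] <- side
          transmit <- if (!variant[parent]) {
            FALSE
          } else if (mode == "mosaic" && parent == origin) {
            runif(1) < config$germline_transmission_fraction
          } else {
            TRUE
          }
          variant[id] <- transmit
        }
      }
    }

    for (id in names(background)[!is.na(background)]) {
      if (variant[id]) {
        row <- slot_of(id, background[id])
        phased$alleles[[row]][f] <- 1L
      }
    }

    states <- tibble(
      individual = pedigree$id,
      state = ifelse(pedigree$id == origin & mode == "mosaic", "mosaic",
              ifelse(variant[pedigree$id], "heterozygous", "non_carrier")),
      cell_fraction = ifelse(
        pedigree$id == origin & mode == "mosaic",
        config$mosaic_cell_fraction,
        ifelse(variant[pedigree$id], 1, 0))
    )
    list(
      phased = phased, map = drop$map, states = states,
      carriers = pedigree$id[variant[pedigree$id]],
      background_sharers = pedigree$id[
        !is.na(background[pedigree$id]) & !variant[pedigree$id]],
      origin = origin, mode = mode
    )
  })
}

#' Simulate read depths at the focal variant
#'
#' Depth is Poisson with mean `depth_mean`; the alternate read count is
#' binomial with success probability `error_rate` for non-carriers, 0.5 for
#' constitutional heterozygotes and `cell_fraction / 2` for mosaics (a cell
#' fraction m puts the variant on one of two chromosomes in a fraction m of
#' cells).
#'
#' @param states Tibble with `individual`, `state`
#'   (`non_carrier`/`heterozygous`/`mosaic`) and `cell_fraction`
#'   (from [plant_mutation()]).
#' @param config A [sim_config()].
#' @return Tibble with `individual`, `ref_reads`, `alt_reads`.
#' @export
sim_reads <- function(states, config = sim_config()) {
  withr::with_seed(op_seed(config$seed, "sim_reads"), {
    q <- dplyr::case_when(
      states$state == "non_carrier" ~ config$error_rate,
      states$state == "heterozygous" ~ 0.5,
      states$state == "mosaic" ~ states$cell_fraction / 2
    )
    depth <- rpois(nrow(states), config$depth_mean)
    alt <- rbinom(nrow(states), depth, q)
    tibble(individual = states$individual,
           ref_reads = as.integer(depth - alt),
           alt_reads = as.integer(alt))
  })
}
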