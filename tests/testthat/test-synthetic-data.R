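test_that("pedigree generation is deterministic with the expected shapes", {
  trio <- gen_pedigree(sim_config(n_generations = 2, children_per_couple = 1))
  expect_equal(nrow(trio), 3L)
  expect_equal(sum(trio$founder), 2L)

  fig1 <- gen_pedigree(preset = "fig1")
  expect_equal(nrow(fig1), 16L)
  expect_true(all(c("II-2", "II-5", "III-5", "IV-1", "IV-4") %in% fig1$id))
  # proband and half-sibling share the father but not the mother
  expect_equal(fig1$father_id[fig1$id == "IV-4"],
               fig1$father_id[fig1$id == "IV-1"])
  expect_false(identical(fig1$mother_id[fig1$id == "IV-4"],
                         fig1$mother_id[fig1$id == "IV-1"]))
  expect_identical(gen_pedigree(sim_config(seed = 5)),
                   gen_pedigree(sim_config(seed = 5)))
})

test_that("haplotype dropping transmits intact copies when recombination is off", {
  cfg <- sim_config(seed = 31, recomb_rate = 0, n_markers = 40)
  ped <- gen_pedigree(preset = "fig1")
  dr <- drop_haplotypes(ped, cfg)
  expect_equal(nrow(dr$phased), 32L) # two haplotypes per individual, always
  for (i in seq_len(nrow(dr$meioses))) {
    m <- dr$meioses[i, ]
    child_hap <- dr$phased$alleles[[which(
      dr$phased$individual == m$child &
        dr$phased$origin == m$side)]]
    parent_rows <- dr$phased[dr$phased$individual == m$parent, ]
    expect_true(any(vapply(parent_rows$alleles,
                           function(a) identical(a, child_hap),
                           logical(1))))
  }
})

test_that("children's haplotypes are parental mosaics at the ledger breakpoints", {
  cfg <- sim_config(seed = 32, recomb_rate = 2, n_markers = 60)
  ped <- gen_pedigree(preset = "fig1")
  dr <- drop_haplotypes(ped, cfg)
  for (i in seq_len(nrow(dr$meioses))) {
    m <- dr$meioses[i, ]
    child_hap <- dr$phased$alleles[[which(
      dr$phased$individual == m$child & dr$phased$origin == m$side)]]
    parent_rows <- dr$phased[dr$phased$individual == m$parent, ]
    parent_haps <- list(parent_rows$alleles[[which(parent_rows$slot == 1)]],
                        parent_rows$alleles[[which(parent_rows$slot == 2)]])
    expected <- vapply(seq_along(dr$map$positions), function(j) {
      slot <- mhtrace:::meiosis_slot_at(m$start_slot, m$breakpoints[[1]],
                                        dr$map$positions[j])
      parent_haps[[slot]][j]
    }, integer(1))
    expect_equal(child_hap, expected)
  }
})

test_that("crossover counts follow the configured recombination rate", {
  n_meioses <- 0
  n_cross <- 0
  for (s in 1:40) {
    cfg <- sim_config(seed = 1000 + s, recomb_rate = 1.0, n_markers = 10)
    dr <- drop_haplotypes(gen_pedigree(cfg), cfg)
    n_meioses <- n_meioses + nrow(dr$meioses)
    n_cross <- n_cross + sum(vapply(dr$meioses$breakpoints, length,
                                    integer(1)))
  }
  expect_gt(n_meioses, 500)
  se <- sqrt(1.0 / n_meioses)
  expect_lt(abs(n_cross / n_meioses - 1.0), 3 * se)
})

test_that("planted mutations follow the recorded transmissions", {
  ped <- gen_pedigree(preset = "fig1")
  cfg <- sim_config(seed = 33)
  dr <- drop_haplotypes(ped, cfg)
  het <- plant_mutation(dr, ped, origin = "II-5", mode = "heterozygous",
                        config = cfg)
  # heterozygous mode: background inheritance and carriage coincide
  expect_equal(het$background_sharers, character(0))
  expect_true("II-5" %in% het$carriers)
  f <- dr$map$focal_index
  for (id in het$carriers) {
    rows <- het$phased[het$phased$individual == id, ]
    expect_equal(sum(vapply(rows$alleles, function(a) a[f], integer(1))), 1L)
  }
  # mosaic mode with no germline transmission: the origin carries alone
  cfg0 <- sim_config(seed = 33, germline_transmission_fraction = 0)
  solo <- plant_mutation(dr, ped, origin = "II-5", mode = "mosaic",
                         config = cfg0)
  expect_equal(solo$carriers, "II-5")
  expect_equal(solo$states$state[solo$states$individual == "II-5"],
               "mosaic")
})

test_that("germline transmission out of a mosaic origin matches its fraction", {
  # many independent replicates of the trio transmission II-5 -> III-5
  ped <- gen_pedigree(preset = "fig1")
  n_inherit <- 0
  n_carry <- 0
  for (s in 1:300) {
    cfg <- sim_config(seed = 2000 + s,
                      germline_transmission_fraction = 0.5)
    dr <- drop_haplotypes(ped, cfg)
    pm <- plant_mutation(dr, ped, origin = "II-5", mode = "mosaic",
                         config = cfg)
    inherited <- c(pm$carriers, pm$background_sharers)
    if ("III-5" %in% inherited) {
      n_inherit <- n_inherit + 1
      if ("III-5" %in% pm$carriers) n_carry <- n_carry + 1
    }
  }
  expect_gt(n_inherit, 80) # background passes ~half the time
  se <- sqrt(0.25 / n_inherit)
  expect_lt(abs(n_carry / n_inherit - 0.5), 3 * se)
})

test_that("read simulation hits the expected allelic ratios", {
  states <- tibble::tibble(
    individual = sprintf("H%05d", 1:10000),
    state = "heterozygous", cell_fraction = 1)
  rd <- sim_reads(states, sim_config(seed = 71, depth_mean = 30))
  ratio <- rd$alt_reads / (rd$ref_reads + rd$alt_reads)
  expect_lt(abs(mean(ratio, na.rm = TRUE) - 0.5),
            3 * sd(ratio, na.rm = TRUE) / sqrt(sum(!is.na(ratio))))

  mosaics <- tibble::tibble(
    individual = sprintf("M%05d", 1:10000),
    state = "mosaic", cell_fraction = 0.42)
  rdm <- sim_reads(mosaics, sim_config(seed = 72, depth_mean = 30))
  ratio_m <- rdm$alt_reads / (rdm$ref_reads + rdm$alt_reads)
  expect_lt(abs(mean(ratio_m, na.rm = TRUE) - 0.21),
            3 * sd(ratio_m, na.rm = TRUE) / sqrt(sum(!is.na(ratio_m))))

  empty <- sim_reads(states[1:50, ], sim_config(seed = 73, depth_mean = 0))
  expect_true(all(empty$ref_reads == 0 & empty$alt_reads == 0))
})

test_that("cohort generation is reproducible and internally consistent", {
  cfg <- sim_config(seed = 41, cohort_size = 120, n_variants = 20)
  c1 <- gen_cohort(cfg)
  c2 <- gen_cohort(cfg)
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "a.vcf"); f2 <- file.path(dir, "b.vcf")
  write_cohort_vcf(c1, f1); write_cohort_vcf(c2, f2)
  expect_identical(readLines(f1), readLines(f2)) # byte-identical

  # conservation: ledger allele counts equal the genotype matrix's
  for (i in seq_len(nrow(c1$variants))) {
    gt <- c1$variants$genotypes[[i]]
    ac <- sum(gt == "0/1") + 2L * sum(gt == "1/1")
    an <- 2L * sum(gt != "./.")
    expect_equal(ac, c1$variants$allele_count[i])
    expect_equal(an, c1$variants$allele_number[i])
  }
  # the generated files never carry the ledger's truth columns
  expect_false(any(grepl("profile|actionable|ledger", readLines(f1))))
})

test_that("classification profiles map to the ledgered verdicts", {
  cfg <- sim_config(seed = 42)
  cohort <- gen_cohort(cfg)
  v <- cohort$variants
  # the majority-kept conflict profile lands on a screened variant
  mk <- v[!is.na(v$profile) & v$profile == "majority_kept", ]
  expect_gte(nrow(mk), 1L)
  key <- paste(mk$chrom, mk$pos)
  expect_true(any(key %in% paste(cohort$ledger$actionable_majority$chrom,
                                 cohort$ledger$actionable_majority$pos)))
  expect_false(any(key %in% paste(cohort$ledger$actionable_strict$chrom,
                                  cohort$ledger$actionable_strict$pos)))

  # a mix of only uncertain profiles yields an empty actionable ledger
  cfg_vus <- sim_config(seed = 43, n_variants = 10,
                        classification_mix = list(
                          vus_only = c(uncertain = 3L)))
  vus <- gen_cohort(cfg_vus)
  expect_equal(nrow(vus$ledger$actionable_majority), 0L)
  expect_equal(nrow(vus$ledger$actionable_strict), 0L)
})
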