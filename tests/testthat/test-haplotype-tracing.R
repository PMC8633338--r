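test_that("fully identical member haplotypes span the whole map", {
  fx <- fixture_fig1()
  seg <- shared_segment(fx$phased, fx$carriers, fx$map)
  expect_equal(seg$start_pos, 3890643L)
  expect_equal(seg$end_pos, 53628382L)
  expect_equal(nrow(seg$members), 4L)
  expect_true(seg$start_pos <= 38496455 && seg$end_pos >= 38496455)
  # single carrier: full extent by definition
  solo <- shared_segment(fx$phased, "II-5", fx$map)
  expect_equal(c(solo$start_pos, solo$end_pos), c(3890643L, 53628382L))
})

test_that("disagreement at the flanking markers collapses the segment to the focal site", {
  map <- marker_map("chr19", c(100L, 200L, 300L), 200L)
  phased <- dplyr::bind_rows(
    tibble::tibble(individual = "a", slot = 1L, origin = "maternal",
                   alleles = list(c(0L, 1L, 0L))),
    tibble::tibble(individual = "b", slot = 1L, origin = "maternal",
                   alleles = list(c(1L, 1L, 1L)))
  )
  seg <- shared_segment(phased, c("a", "b"), map)
  expect_equal(c(seg$start_pos, seg$end_pos), c(200L, 200L))
})

test_that("a named non-carrier in the carrier list is an inconsistency error", {
  fx <- fixture_fig1()
  expect_error(shared_segment(fx$phased, c(fx$carriers, "II-2"), fx$map),
               "II-2")
})

test_that("missing alleles are wildcards bounded by the missing-run limit", {
  positions <- seq(100L, 1500L, by = 100L)
  map <- marker_map("chr1", positions, 800L)
  a <- rep(1L, 15)
  b <- rep(1L, 15)
  b[12:14] <- NA # wildcard run to the right of focal (index 8)
  phased <- dplyr::bind_rows(
    tibble::tibble(individual = "a", slot = 1L, origin = "maternal",
                   alleles = list(a)),
    tibble::tibble(individual = "b", slot = 1L, origin = "maternal",
                   alleles = list(b))
  )
  wide <- shared_segment(phased, c("a", "b"), map, max_missing_run = 10)
  expect_equal(wide$end_pos, 1500L) # crosses the run to the last marker
  tight <- shared_segment(phased, c("a", "b"), map, max_missing_run = 2)
  expect_equal(tight$end_pos, 1100L) # stops at the last informative marker
})

test_that("transmission tracing identifies the grandmother's maternal haplotype", {
  fx <- fixture_fig1()
  seg <- shared_segment(fx$phased, fx$carriers, fx$map)
  path <- trace_parental_origin(seg, fx$ped, fx$phased)
  expect_equal(path$topmost, "II-5")
  expect_equal(path$topmost_origin, "maternal")
  chain <- dplyr::arrange(path$chain, child)
  expect_equal(chain$parent, c("II-5", "III-5", "III-5"))
  expect_equal(chain$child, c("III-5", "IV-1", "IV-4"))
})

test_that("a single labelled carrier yields a zero-length path", {
  fx <- fixture_fig1()
  seg <- shared_segment(fx$phased, "II-5", fx$map)
  path <- trace_parental_origin(seg, fx$ped, fx$phased)
  expect_equal(nrow(path$chain), 0L)
  expect_equal(path$topmost, "II-5")
  expect_equal(path$topmost_origin, "maternal")
})

test_that("disconnected members raise an error naming the components", {
  fx <- fixture_fig1()
  lonely <- dplyr::bind_rows(
    fx$ped,
    tibble::tibble(id = "X-1", sex = "female", father_id = NA_character_,
                   mother_id = NA_character_, generation = 1L,
                   label = "X-1", founder = TRUE))
  phased <- dplyr::bind_rows(
    fx$phased,
    tibble::tibble(individual = "X-1", slot = 2L, origin = "maternal",
                   alleles = list(fx$background_variant)))
  seg <- shared_segment(phased, c(fx$carriers, "X-1"), fx$map)
  expect_error(trace_parental_origin(seg, lonely, phased),
               "not connected")
})

test_that("the non-carrier sister is a discordant sharer", {
  fx <- fixture_fig1()
  seg <- shared_segment(fx$phased, fx$carriers, fx$map)
  disc <- detect_discordant_sharers(seg, fx$phased, fx$states,
                                    c("II-2", "III-4"))
  expect_equal(disc, "II-2")
  none <- detect_discordant_sharers(seg, fx$phased, fx$states, "III-4")
  expect_equal(none, character(0))
})

test_that("the index family resolves to de novo germline mosaicism in II-5", {
  fx <- fixture_fig1()
  seg <- shared_segment(fx$phased, fx$carriers, fx$map)
  path <- trace_parental_origin(seg, fx$ped, fx$phased)
  disc <- detect_discordant_sharers(seg, fx$phased, fx$states,
                                    c("II-2", "III-4"))
  origin <- infer_origin(fx$ped, fx$states, seg, disc, path)
  expect_equal(origin$mode, "de_novo_germline_mosaic")
  expect_equal(origin$originating_individual, "II-5")
  expect_true(any(grepl("rule 1", origin$evidence)))
  # determinism / permutation invariance of the member order
  seg2 <- shared_segment(fx$phased, rev(fx$carriers), fx$map)
  origin2 <- infer_origin(fx$ped, fx$states, seg2, disc,
                          trace_parental_origin(seg2, fx$ped, fx$phased))
  expect_equal(origin2$mode, origin$mode)
  expect_equal(origin2$originating_individual,
               origin$originating_individual)
})

test_that("a balanced topmost carrier with untyped relatives is unresolved", {
  fx <- fixture_fig1()
  states <- fx$states
  states$state[states$individual == "II-5"] <- "heterozygous"
  states <- states[states$individual != "II-2", ]
  seg <- shared_segment(fx$phased, fx$carriers, fx$map)
  path <- trace_parental_origin(seg, fx$ped, fx$phased)
  disc <- detect_discordant_sharers(seg, fx$phased, states, "III-4")
  origin <- infer_origin(fx$ped, states, seg, disc, path)
  expect_equal(origin$mode, "inherited_unresolved")
  expect_equal(origin$originating_individual, "unknown")

  # heterozygous topmost with a discordant sharer: full de novo
  disc2 <- detect_discordant_sharers(seg, fx$phased, fx$states, "II-2")
  origin2 <- infer_origin(fx$ped, states, seg, disc2, path)
  expect_equal(origin2$mode, "de_novo_full_heterozygote")
  expect_equal(origin2$originating_individual, "II-5")
})

test_that("adding a member never lengthens the segment; bounds are maximal", {
  cfg <- sim_config(seed = 51, recomb_rate = 2, n_markers = 80)
  ped <- gen_pedigree(cfg)
  dr <- drop_haplotypes(ped, cfg)
  pm <- plant_mutation(dr, ped, origin = "I-2", mode = "heterozygous",
                       config = cfg)
  carriers <- pm$carriers
  if (length(carriers) >= 3L) {
    seg_all <- shared_segment(pm$phased, carriers, pm$map)
    seg_some <- shared_segment(pm$phased, carriers[1:2], pm$map)
    expect_true(seg_some$start_pos <= seg_all$start_pos)
    expect_true(seg_some$end_pos >= seg_all$end_pos)
  }
  # re-check agreement inside the reported segment and maximality outside
  seg <- shared_segment(pm$phased, carriers, pm$map)
  H <- do.call(cbind, lapply(seq_len(nrow(seg$members)), function(i) {
    rows <- pm$phased[pm$phased$individual == seg$members$individual[i] &
                        pm$phased$slot == seg$members$slot[i], ]
    rows$alleles[[1]]
  }))
  agrees <- function(j) {
    v <- H[j, ]
    v <- v[!is.na(v)]
    length(v) <= 1L || all(v == v[1L])
  }
  for (j in seg$start_index:seg$end_index) {
    expect_true(agrees(j))
  }
  if (seg$start_index > 1L) expect_false(agrees(seg$start_index - 1L))
  if (seg$end_index < length(pm$map$positions)) {
    expect_false(agrees(seg$end_index + 1L))
  }
})

test_that("segments export to BED half-open coordinates", {
  fx <- fixture_fig1()
  seg <- shared_segment(fx$phased, fx$carriers, fx$map)
  bed <- withr::local_tempfile(fileext = ".bed")
  write_segment_bed(seg, bed)
  fields <- strsplit(readLines(bed), "\t")[[1]]
  expect_equal(as.integer(fields[2]), seg$start_pos - 1L)
  expect_equal(as.integer(fields[3]), seg$end_pos)
})

test_that("haplotypes and pedigrees round-trip through their file formats", {
  fx <- fixture_fig1()
  dir <- withr::local_tempdir()
  hap <- file.path(dir, "haps.tsv")
  write_haplotypes(fx$phased, fx$map, hap)
  back <- read_haplotypes(hap, "chr19", 38496455)
  expect_equal(back$phased$individual, fx$phased$individual)
  expect_equal(back$phased$alleles, fx$phased$alleles)
  expect_equal(back$map$positions, fx$map$positions)
  expect_equal(back$map$focal_index, fx$map$focal_index)

  pedf <- file.path(dir, "fam.ped")
  write_ped(fx$ped, pedf)
  ped2 <- read_ped(pedf)
  expect_equal(ped2$id, fx$ped$id)
  expect_equal(ped2$father_id, fx$ped$father_id)
  expect_equal(ped2$sex, fx$ped$sex)
})

test_that("segment tidiers and plots report the inference", {
  fx <- fixture_fig1()
  seg <- shared_segment(fx$phased, fx$carriers, fx$map)
  gl <- glance(seg)
  expect_equal(gl$n_members, 4L)
  expect_s3_class(autoplot(seg), "ggplot")
  path <- trace_parental_origin(seg, fx$ped, fx$phased)
  disc <- detect_discordant_sharers(seg, fx$phased, fx$states, "II-2")
  origin <- infer_origin(fx$ped, fx$states, seg, disc, path)
  expect_equal(glance(origin)$mode, "de_novo_germline_mosaic")
  expect_equal(nrow(tidy(origin)), length(origin$evidence))
})
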