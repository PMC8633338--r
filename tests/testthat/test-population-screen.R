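make_screen_inputs <- function(dir) {
  samples <- c("S1", "S2", "S3")
  vcf <- file.path(dir, "cohort.vcf")
  write_test_vcf(vcf, list(
    list(chrom = "chr19", pos = 38445328, ref = "G", alt = "A",
         gt = c("0/1", "0/0", "./.")),
    list(chrom = "19", pos = 38464723, ref = "C", alt = "T",
         gt = c("1/1", "0/1", "0/0")),
    # multiallelic site: decomposed into two records
    list(chrom = "chr19", pos = 38500643, ref = "G", alt = "A,C",
         gt = c("0/1", "0/2", "0/0")),
    # outside every gene region: dropped
    list(chrom = "chr19", pos = 1000, ref = "A", alt = "T",
         gt = c("0/1", "0/0", "0/0"))
  ), samples)
  regions <- file.path(dir, "regions.bed")
  writeLines("chr19\t38433690\t38595273\tRYR1", regions)
  ann <- file.path(dir, "annotations.tsv")
  readr::write_tsv(tibble::tibble(
    chrom = "chr19",
    pos = c(38445328, 38464723, 38500643),
    ref = c("G", "C", "G"), alt = c("A", "T", "A"),
    gene = "RYR1",
    consequence = c("missense", "splice_donor", "missense")
  ), ann)
  list(vcf = vcf, regions = regions, ann = ann)
}

test_that("cohort loading counts alleles over called genotypes only", {
  dir <- withr::local_tempdir()
  paths <- make_screen_inputs(dir)
  expect_warning(
    tab <- load_cohort_variants(paths$vcf, read_gene_regions(paths$regions),
                                read_annotations(paths$ann)),
    "consequence 'other'")
  expect_equal(nrow(tab), 4L) # 2 biallelic + 2 from the multiallelic site
  expect_equal(attr(tab, "cohort_size"), 3L)

  site1 <- tab[tab$pos == 38445328, ]
  expect_equal(site1$allele_count, 1L)
  expect_equal(site1$allele_number, 4L) # one ./. drops two alleles
  expect_equal(site1$carriers[[1]], "S1")

  site2 <- tab[tab$pos == 38464723, ]
  expect_equal(site2$allele_count, 3L) # 1/1 + 0/1
  expect_equal(site2$allele_number, 6L)
  expect_equal(sort(site2$carriers[[1]]), c("S1", "S2"))

  multi <- tab[tab$pos == 38500643, ]
  expect_equal(nrow(multi), 2L)
  expect_equal(multi$alt[order(multi$alt)], c("A", "C"))
  expect_equal(multi$consequence[multi$alt == "A"], "missense")
  expect_equal(multi$consequence[multi$alt == "C"], "other") # unannotated
  expect_equal(multi$allele_number, c(6L, 6L))
  expect_false(any(tab$pos == 1000))
})

test_that("MAF is the minor-allele frequency with symmetry", {
  expect_equal(compute_maf(0, 1000), 0)
  expect_equal(compute_maf(6, 332000), 1.807e-05, tolerance = 1e-4)
  expect_equal(compute_maf(999, 1000), 0.001)
  k <- 0:40
  expect_equal(compute_maf(k, 40), compute_maf(40 - k, 40))
  expect_error(compute_maf(1, 0), "undefined")
})

test_that("rare-coding filter applies a strict MAF bound and kept classes", {
  tab <- tibble::tibble(
    chrom = "chr19", pos = 1:4 * 10L, ref = "A", alt = "G", gene = "RYR1",
    consequence = c("missense", "missense", "synonymous", "stop_gained"),
    allele_count = c(1L, 4L, 1L, 1L), allele_number = 4000L,
    maf = c(1, 4, 1, 1) / 4000,
    n_carriers = 1L, carriers = list("a", "b", "c", "d")
  )
  # maf 0.001 exactly is excluded (strict inequality)
  kept <- filter_rare_coding(tab, maf_threshold = 0.001)
  expect_equal(kept$pos, c(10L, 40L)) # drops maf==0.001 and synonymous
  # monotone in both the threshold and the consequence set
  tight <- filter_rare_coding(tab, maf_threshold = 0.0005)
  expect_true(all(tight$pos %in% kept$pos))
  fewer <- filter_rare_coding(tab, kept_consequences = "missense")
  expect_true(all(fewer$pos %in%
                    filter_rare_coding(tab)$pos))
})

test_that("carrier reports reproduce the 1-in-1450 reporting conventions", {
  tab <- tibble::tibble(chrom = "chr19", pos = 38496455L, ref = "G",
                        alt = "A", carriers = list(sprintf("C%02d", 1:43)))
  rep <- carrier_report(tab, cohort_size = 62240, merge = TRUE)
  expect_equal(rep$n_carriers, 43L)
  expect_equal(rep$percent, 0.069)
  expect_equal(rep$one_in_n, 1450)

  none <- carrier_report(tibble::tibble(chrom = character(), pos = integer(),
                                        ref = character(), alt = character(),
                                        carriers = list()),
                         cohort_size = 1000, merge = TRUE)
  expect_equal(none$frequency, 0)
  expect_true(is.na(none$one_in_n))

  # union semantics: an individual with two variants counts once
  two <- tibble::tibble(chrom = "chr1", pos = c(1L, 2L), ref = "A",
                        alt = "G", carriers = list(c("A", "B"), c("B", "C")))
  merged <- carrier_report(two, cohort_size = 10, merge = TRUE)
  expect_equal(merged$n_carriers, 3L)
  expect_equal(merged$percent, 30)
})

test_that("screen tables round-trip through the TSV report", {
  cohort <- gen_cohort(sim_config(seed = 11, cohort_size = 150,
                                  n_variants = 12))
  tab <- cohort$variants %>% dplyr::select(-"genotypes", -"profile")
  class(tab) <- c("mh_cohort", class(tab))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cohort_table(tab, path)
  back <- read_cohort_table(path)
  expect_equal(back$pos, tab$pos)
  expect_equal(back$allele_count, tab$allele_count)
  expect_equal(back$allele_number, tab$allele_number)
  expect_equal(back$maf, tab$maf)
  expect_equal(back$carriers, tab$carriers)
})

test_that("screen output equals the generator's planted-carrier ledger", {
  cfg <- sim_config(seed = 23, cohort_size = 200, n_variants = 50)
  cohort <- gen_cohort(cfg)
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "cohort.vcf")
  bed <- file.path(dir, "regions.bed")
  ann <- file.path(dir, "ann.tsv")
  write_cohort_vcf(cohort, vcf)
  write_regions_bed(cohort$regions, bed)
  write_annotations(cohort$annotations, ann)

  tab <- load_cohort_variants(vcf, read_gene_regions(bed),
                              read_annotations(ann))
  expect_equal(nrow(tab), 50L)
  truth <- cohort$ledger$variants
  expect_equal(tab$pos, truth$pos)
  expect_equal(tab$allele_count, truth$allele_count)
  expect_equal(tab$allele_number, truth$allele_number)
  expect_equal(tab$maf, truth$maf)
  expect_equal(lapply(tab$carriers, sort), truth$carriers)
})
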