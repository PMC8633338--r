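# Shared fixtures built in code. The index-family fixture reproduces the
# carrier topology of the case study: a mosaic grandmother (II-5) whose
# maternal haplotype background is shared with her non-carrier sister
# (II-2) and transmitted, with the variant, to III-5, IV-1 and IV-4.

fig1_map <- function() {
  marker_map(
    "chr19",
    c(3890643, 8e6, 12e6, 16e6, 20e6, 24e6, 28e6, 32e6, 36e6,
      38496455, 40e6, 44e6, 48e6, 52e6, 53628382),
    focal_pos = 38496455
  )
}

fixture_fig1 <- function() {
  ped <- gen_pedigree(preset = "fig1")
  map <- fig1_map()
  n <- length(map$positions)
  f <- map$focal_index

  # the shared grandmaternal background (focal site ancestral)
  A <- c(1L, 0L, 1L, 1L, 0L, 1L, 0L, 0L, 1L, 0L, 1L, 1L, 0L, 0L, 1L)
  stopifnot(length(A) == n, A[f] == 0L)
  Av <- replace(A, f, 1L)          # background carrying the variant
  B <- replace(1L - A, f, 0L)      # differs from A everywhere but the focal
  C <- c(0L, 0L, 1L, 0L, 1L, 1L, 1L, 0L, 0L, 0L, 0L, 1L, 1L, 1L, 0L)
  D <- c(1L, 1L, 0L, 0L, 1L, 0L, 1L, 1L, 0L, 0L, 1L, 0L, 1L, 0L, 0L)
  E <- c(0L, 1L, 1L, 0L, 0L, 0L, 1L, 0L, 1L, 0L, 0L, 0L, 1L, 1L, 1L)

  hap <- function(id, slot, origin, alleles) {
    tibble::tibble(individual = id, slot = slot, origin = origin,
                   alleles = list(alleles))
  }
  phased <- dplyr::bind_rows(
    hap("II-5", 1L, "paternal", B),
    hap("II-5", 2L, "maternal", Av),
    hap("II-2", 1L, "paternal", C),
    hap("II-2", 2L, "maternal", A),
    hap("III-5", 1L, "paternal", C),
    hap("III-5", 2L, "maternal", Av),
    hap("IV-4", 1L, "paternal", Av),
    hap("IV-4", 2L, "maternal", D),
    hap("IV-1", 1L, "paternal", Av),
    hap("IV-1", 2L, "maternal", E),
    hap("III-4", 1L, "paternal", D),
    hap("III-4", 2L, "maternal", E)
  )

  depths <- tibble::tibble(
    individual = c("IV-4", "II-5", "III-5", "IV-1", "II-2", "III-4"),
    ref_reads = c(18L, 22L, 15L, 14L, 25L, 28L),
    alt_reads = c(19L, 6L, 16L, 15L, 0L, 0L),
    genotype = c("0/1", "0/1", "0/1", "0/1", "0/0", "0/0")
  )
  states <- classify_carrier_state(depths)
  carriers <- c("II-5", "III-5", "IV-1", "IV-4")

  list(ped = ped, map = map, phased = phased, depths = depths,
       states = states, carriers = carriers,
       background = A, background_variant = Av)
}

# Small multi-sample VCF written from genotype strings, for screen tests.
write_test_vcf <- function(path, sites, samples) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr19>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- vapply(sites, function(s) {
    paste(c(s$chrom, s$pos, ".", s$ref, s$alt, ".", "PASS", ".", "GT",
            s$gt), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}

# Brute-force minimum-likelihood oracle for the two-sided exact binomial
# test, independent of the package's pbinom-based implementation.
oracle_binom_p <- function(k, n, p0 = 0.5) {
  d <- dbinom(0:n, n, p0)
  sum(d[d <= d[k + 1] * (1 + 1e-09)])
}
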