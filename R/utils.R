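# Internal helpers shared across modules.

# Normalize chromosome names to the "chr"-prefixed convention used throughout.
normalize_chrom <- function(chrom) {
  chrom <- as.character(chrom)
  ifelse(grepl("^chr", chrom), chrom, paste0("chr", chrom))
}

# Minimal representation of a variant: trim shared suffix, then shared prefix,
# adjusting pos for trimmed prefix bases. Vectorized over rows.
normalize_variant <- function(pos, ref, alt) {
  pos <- as.integer(pos)
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  for (i in seq_along(pos)) {
    r <- strsplit(ref[i], "")[[1]]
    a <- strsplit(alt[i], "")[[1]]
    while (length(r) > 1L && length(a) > 1L && r[length(r)] == a[length(a)]) {
      r <- r[-length(r)]
      a <- a[-length(a)]
    }
    while (length(r) > 1L && length(a) > 1L && r[1L] == a[1L]) {
      r <- r[-1L]
      a <- a[-1L]
      pos[i] <- pos[i] + 1L
    }
    ref[i] <- paste(r, collapse = "")
    alt[i] <- paste(a, collapse = "")
  }
  list(pos = pos, ref = ref, alt = alt)
}

# Validate a variant key tibble (chrom/pos/ref/alt columns).
check_variant_key <- function(df, where = "input") {
  need <- c("chrom", "pos", "ref", "alt")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort(sprintf("%s is missing variant key column(s): %s",
                  where, paste(missing, collapse = ", ")))
  }
  bad <- !grepl("^[ACGT]+$", df$ref) | !grepl("^[ACGT]+$", df$alt)
  if (any(bad)) {
    abort(sprintf("%s has non-ACGT alleles in row(s): %s",
                  where, paste(which(bad), collapse = ", ")))
  }
  if (any(df$ref == df$alt)) {
    abort(sprintf("%s has ref == alt in row(s): %s",
                  where, paste(which(df$ref == df$alt), collapse = ", ")))
  }
  invisible(df)
}

# Deterministic per-operation seed stream: the same SimConfig seed gives every
# generator operation its own independent, reproducible stream, so adding an
# operation never perturbs another's draws. Kept below 2^31 - 1.
op_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  (as.integer(seed) %% 97777L) * 20011L + (h %% 99991L) * 101L + 7L
}

# "1 in N" reciprocal, rounded to the nearest 10 (62,240/43 = 1447.4 -> 1450).
one_in_n <- function(cohort_size, n_carriers) {
  ifelse(n_carriers > 0, round(cohort_size / n_carriers / 10) * 10, NA_real_)
}

# Percentage at two significant figures, as a number (0.00069087 -> 0.069).
percent_2sf <- function(frequency) {
  ifelse(frequency > 0, signif(100 * frequency, 2), 0)
}

# vcfR::getFIX drops to a bare named vector when the VCF has one record;
# always hand back a one-row-per-record data frame.
vcf_fix_frame <- function(vcf) {
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(fix)
  as.data.frame(fix, stringsAsFactors = FALSE)
}
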