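test_that("canonical_genotype sorts, uppercases and rejects junk", {
  expect_equal(canonical_genotype("G", "A"), "AG")
  expect_equal(canonical_genotype("C", "C"), "CC")
  expect_equal(canonical_genotype("t", "a"), "AT")
  expect_equal(canonical_genotype("A", "G"), canonical_genotype("G", "A"))
  expect_error(canonical_genotype("A", "N"), class = "pgx_allele_error")
  expect_error(canonical_genotype("-", "A"), class = "pgx_allele_error")

  # all 16 ordered pairs collapse to the 10 unordered diploid genotypes
  pairs <- expand.grid(a1 = c("A", "C", "G", "T"),
                       a2 = c("A", "C", "G", "T"),
                       stringsAsFactors = FALSE)
  canon <- canonical_genotype(pairs$a1, pairs$a2)
  expect_equal(length(unique(canon)), 10L)
})

test_that("resolve_vcf_genotype maps GT indexes and handles missing/haploid", {
  expect_equal(resolve_vcf_genotype("G", "A", "0/1"), "AG")
  expect_equal(resolve_vcf_genotype("G", "A", "1|0"), "AG")
  expect_equal(resolve_vcf_genotype("C", "T", "./."), NA_character_)
  expect_equal(resolve_vcf_genotype("C", "T", "."), NA_character_)
  expect_equal(resolve_vcf_genotype("C", "T", "1"), "TT") # haploid chrX/Y
  expect_error(resolve_vcf_genotype("C", "T", "0/2"),
               class = "pgx_record_error")
})

test_that("resolve_vcf_genotype agrees with a naive character mapper on fuzz", {
  set.seed(99)
  for (i in 1:200) {
    ref <- sample(c("A", "C", "G", "T"), 1)
    alts <- sample(setdiff(c("A", "C", "G", "T"), ref),
                   sample(1:2, 1))
    n_all <- 1 + length(alts)
    gt <- paste(sample(0:(n_all - 1), 2, replace = TRUE),
                collapse = sample(c("/", "|"), 1))
    expect_equal(resolve_vcf_genotype(ref, alts, gt),
                 naive_gt_mapper(ref, alts, gt), info = gt)
  }
})

write_test_vcf <- function(records,
                           samples = c("S1", "S2"),
                           path = tempfile(fileext = ".vcf")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records
  ), path)
  path
}

test_that("VCF records resolve per sample with phase ignored", {
  p <- write_test_vcf("1\t100\trs11615\tG\tA\t.\tPASS\t.\tGT\t0/1\t1|1")
  calls <- read_vcf_genotypes(p)
  expect_equal(calls$genotype[calls$sample_id == "S1"], "AG")
  expect_equal(calls$genotype[calls$sample_id == "S2"], "AA")
  expect_equal(calls$rsid, c("rs11615", "rs11615"))
  expect_equal(attr(calls, "samples"), c("S1", "S2"))
})

test_that("header-only VCFs yield every sample with zero calls", {
  p <- write_test_vcf(character(0), samples = c("A", "B", "C"))
  calls <- read_vcf_genotypes(p)
  expect_equal(nrow(calls), 0L)
  expect_equal(attr(calls, "samples"), c("A", "B", "C"))
})

test_that("filtered, multi-allelic and non-SNV records are skipped and counted", {
  p <- write_test_vcf(c(
    "1\t100\trs1\tG\tA\t.\tPASS\t.\tGT\t0/1\t1/1",
    "1\t200\trs2\tC\tT\t.\tq10\t.\tGT\t0/1\t0/0",     # failed filter
    "1\t300\trs3\tC\tT,G\t.\tPASS\t.\tGT\t1/2\t0/0",  # multi-allelic
    "1\t400\trs4\tCT\tC\t.\tPASS\t.\tGT\t0/1\t0/0",   # indel
    "1\t500\trs5\tA\tG\t.\t.\t.\tGT\t./.\t1/1"        # '.' filter accepted
  ))
  expect_message(calls <- read_vcf_genotypes(p), "skipped 3 record")
  sk <- attr(calls, "skipped")
  expect_equal(unname(sk[c("filtered", "multiallelic", "non_snv")]),
               c(1L, 1L, 1L))
  expect_equal(sort(unique(calls$rsid)), c("rs1", "rs5"))
  expect_equal(calls$genotype[calls$rsid == "rs5" &
                                calls$sample_id == "S1"], NA_character_)
})

test_that("a missing #CHROM header is a format error", {
  p <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2", "##no body"), p)
  expect_error(read_vcf_genotypes(p), class = "pgx_format_error")
  writeLines(c("not a vcf"), p)
  expect_error(read_vcf_genotypes(p), class = "pgx_format_error")
})

test_that("per-sample call counts match an independent record count", {
  set.seed(7)
  n <- 400
  keep_filter <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(.9, .1))
  recs <- vapply(seq_len(n), function(i) {
    ref <- sample(c("A", "C", "G", "T"), 1)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    sprintf("1\t%d\trs%d\t%s\t%s\t.\t%s\t.\tGT\t%s\t%s",
            i * 10, i, ref, alt,
            if (keep_filter[i]) "PASS" else "lowqual",
            sample(c("0/0", "0/1", "1/1"), 1),
            sample(c("0/0", "0/1", "1/1"), 1))
  }, "")
  p <- write_test_vcf(recs)
  suppressMessages(calls <- read_vcf_genotypes(p))
  # oracle: count PASS data lines in the raw file
  raw <- readLines(p)
  pass_lines <- sum(grepl("\tPASS\t", raw, fixed = TRUE))
  expect_equal(sum(calls$sample_id == "S1"), pass_lines)
  expect_equal(sum(calls$sample_id == "S2"), pass_lines)
})

test_that("23andMe lines map directly and no-calls become missing", {
  p <- tempfile()
  writeLines(c("# rsid\tchromosome\tposition\tgenotype",
               "rs1042522\t17\t7579472\tCC",
               "rs11615\t19\t45923653\t--",
               "rs555\tX\t123\tA"), p)
  calls <- read_array_genotypes(p, "23andme", sample_id = "P1")
  expect_equal(calls$genotype[calls$rsid == "rs1042522"], "CC")
  expect_equal(calls$genotype[calls$rsid == "rs11615"], NA_character_)
  # hemizygous X call duplicated to diploid representation
  expect_equal(calls$genotype[calls$rsid == "rs555"], "AA")
  expect_equal(unique(calls$sample_id), "P1")
})

test_that("unknown dialects and malformed lines are rejected", {
  p <- tempfile()
  writeLines(c("# rsid\tchromosome\tposition\tgenotype",
               "rs1\t1\tnot_a_position\tAA"), p)
  expect_error(read_array_genotypes(p, "mystery"), class = "pgx_usage_error")
  expect_error(read_array_genotypes(p, "23andme"),
               class = "pgx_format_error")
})

test_that("the same genotypes round-trip identically through all dialects", {
  set.seed(5)
  rsids <- paste0("rs", 1:20)
  geno <- replicate(20, paste(sort(sample(c("A", "C", "G", "T"), 2,
                                          replace = TRUE)), collapse = ""))
  geno[7] <- NA_character_ # one no-call
  calls0 <- make_calls("S1", rsids, geno, chrom = "1", pos = 1:20 * 100)

  parsed <- lapply(c("23andme", "affymetrix", "decodeme", "ftdna"),
                   function(d) {
                     p <- tempfile()
                     write_array_genotypes(calls0, p, dialect = d)
                     out <- read_array_genotypes(p, d, sample_id = "S1")
                     out$source <- NULL
                     out
                   })
  for (i in 2:4) expect_equal(parsed[[i]], parsed[[1]])
  expect_equal(parsed[[1]]$genotype, calls0$genotype)

  # and through VCF
  pv <- tempfile(fileext = ".vcf")
  write_vcf_genotypes(calls0, pv)
  vcf_calls <- read_vcf_genotypes(pv)
  expect_equal(
    vcf_calls[order(vcf_calls$rsid), c("rsid", "genotype")],
    calls0[order(calls0$rsid), c("rsid", "genotype")],
    ignore_attr = TRUE
  )
})

test_that("no parser emits an unsorted or non-canonical genotype", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 30
    calls0 <- make_calls(
      "S1", paste0("rs", sample(1e5, n)),
      replicate(n, paste(sample(c("A", "C", "G", "T"), 2, replace = TRUE),
                         collapse = "")), # deliberately unsorted input
      pos = sample(1e6, n)
    )
    calls0$genotype <- ifelse(runif(n) < .1, NA, calls0$genotype)
    canon <- sort_genotypes_oracle(calls0$genotype)
    p <- tempfile()
    write_array_genotypes(
      dplyr::mutate(calls0, genotype = canon), p, "ftdna")
    out <- read_array_genotypes(p, "ftdna", sample_id = "S1")
    ok <- is.na(out$genotype) |
      out$genotype == sort_genotypes_oracle(out$genotype)
    expect_true(all(ok))
  }
})

test_that("gzip-compressed inputs are detected and parsed", {
  p <- tempfile(fileext = ".txt.gz")
  con <- gzfile(p, "wt")
  writeLines(c("# rsid\tchromosome\tposition\tgenotype",
               "rs1042522\tchr17\t7579472\tCC"), con)
  close(con)
  calls <- read_array_genotypes(p, "23andme", sample_id = "Z")
  expect_equal(calls$genotype, "CC")
  expect_equal(calls$chrom, "17") # chr prefix normalized
})
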