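test_that("count tables tally distinct matched rsids per gene and drug", {
  kb <- mini_kb()
  calls <- make_calls("S1", c("rs1042522", "rs11615"), c("CC", "GG"),
                      chrom = c("17", "19"), pos = c(7579472L, 45923653L))
  attr(calls, "samples") <- "S1"
  m <- annotate_cohort(calls, kb)

  g <- sample_gene_counts(m)
  expect_equal(g$GENE_CIS1, 1L)
  expect_equal(g$GENE_CIS3, 1L)
  d <- sample_drug_counts(m)
  expect_equal(d$cisplatin, 2L) # two SNPs, one drug

  # one rsid annotated to two drugs contributes once per drug column
  calls2 <- make_calls("S2", "rs2108622", "TT", chrom = "19",
                       pos = 15990431L)
  m2 <- annotate_cohort(calls2, kb)
  d2 <- sample_drug_counts(m2)
  expect_equal(d2$warfarin, 1L)
  expect_equal(d2$phenprocoumon, 1L)
})

test_that("an empty cohort yields an empty count table", {
  m <- annotate_cohort(make_calls(character(0), character(0), character(0)),
                       mini_kb())
  tab <- sample_gene_counts(m)
  expect_equal(nrow(tab), 0L)
  expect_equal(names(tab), "sample_id")
})

test_that("count tables equal an independent group-by over the matches", {
  kb <- mini_kb()
  sim <- simulate_cohort(kb, default_population_specs(kb, n = 15), seed = 8)
  m <- annotate_cohort(sim$calls, kb)

  for (col in c("gene", "drug")) {
    tab <- if (col == "gene") sample_gene_counts(m) else
      sample_drug_counts(m)
    # oracle: base-R xtabs over the distinct (sample, rsid, col) triples
    dd <- unique(as.data.frame(m)[, c("sample_id", "rsid", col)])
    xt <- as.data.frame(table(dd$sample_id, dd[[col]]),
                        stringsAsFactors = FALSE)
    for (k in seq_len(nrow(xt))) {
      s <- xt$Var1[k]; cc <- xt$Var2[k]
      got <- if (cc %in% names(tab)) tab[[cc]][tab$sample_id == s] else 0L
      expect_equal(as.integer(got), xt$Freq[k],
                   info = paste(col, s, cc))
    }
    # row sums equal distinct matched (rsid, col) pairs per sample
    for (s in tab$sample_id) {
      expect_equal(sum(as.integer(tab[tab$sample_id == s, -1])),
                   nrow(unique(as.data.frame(
                     m[m$sample_id == s, c("rsid", col)]))))
    }
  }
})

test_that("genotype distributions are direct fractions over observed calls", {
  calls <- make_calls(paste0("S", 1:4), rep("rs11615", 4),
                      c("AG", "AG", "GG", "GG"))
  calls$sample_id <- paste0("S", 1:4)
  attr(calls, "samples") <- paste0("S", 1:4)
  groups <- tibble::tibble(sample_id = paste0("S", 1:4), population = "EUR")
  gd <- genotype_distribution(calls, "rs11615", groups)
  expect_equal(gd$frequency[gd$genotype == "AG"], 0.5)
  expect_equal(gd$frequency[gd$genotype == "GG"], 0.5)
  expect_equal(gd$count[gd$genotype == "AG"], 2L)
})

test_that("an all-missing locus reports MISSING fraction 1 and nothing else", {
  calls <- make_calls(paste0("S", 1:3), rep("rs11615", 3),
                      rep(NA_character_, 3))
  calls$sample_id <- paste0("S", 1:3)
  attr(calls, "samples") <- paste0("S", 1:3)
  groups <- tibble::tibble(sample_id = paste0("S", 1:3), population = "P")
  gd <- genotype_distribution(calls, "rs11615", groups)
  expect_equal(nrow(gd), 1L)
  expect_equal(gd$genotype, "MISSING")
  expect_equal(gd$frequency, 1)
})

test_that("unassigned samples are named in the error", {
  calls <- make_calls(c("S1", "S2"), c("rs1", "rs1"), c("AA", "AA"))
  calls$sample_id <- c("S1", "S2")
  attr(calls, "samples") <- c("S1", "S2")
  groups <- tibble::tibble(sample_id = "S1", population = "P")
  err <- expect_error(genotype_distribution(calls, "rs1", groups),
                      class = "pgx_input_error")
  expect_match(conditionMessage(err), "S2")
})

test_that("observed genotype frequencies sum to one per cell", {
  kb <- mini_kb()
  sim <- simulate_cohort(kb, default_population_specs(kb, n = 40),
                         seed = 19, missing_rate = 0.1)
  gd <- genotype_distribution(sim$calls, unique(sim$calls$rsid),
                              sim$groups)
  sums <- gd |>
    dplyr::filter(genotype != "MISSING") |>
    dplyr::group_by(rsid, population) |>
    dplyr::summarise(s = sum(frequency), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-9))

  af <- allele_frequencies(sim$calls, unique(sim$calls$rsid), sim$groups)
  asums <- af |>
    dplyr::group_by(rsid, population) |>
    dplyr::summarise(s = sum(frequency), .groups = "drop")
  expect_true(all(abs(asums$s - 1) < 1e-9))
})

test_that("group_summary does hand-checkable arithmetic", {
  # sample A matches 2 distinct rsids, sample B 4 -> mean 3, sd sqrt(2)
  kb4 <- random_kb(16, 2, seed = 55)
  ann <- kb4$annotations[!duplicated(kb4$annotations$rsid), ]
  callsA <- make_calls("A", ann$rsid[1:2], ann$genotype[1:2])
  callsB <- make_calls("B", ann$rsid[3:6], ann$genotype[3:6])
  calls <- dplyr::bind_rows(callsA, callsB)
  attr(calls, "samples") <- c("A", "B")
  m <- annotate_cohort(calls, kb4)
  groups <- tibble::tibble(sample_id = c("A", "B"), population = "P")
  gs <- group_summary(m, groups)
  expect_equal(gs$n, 2L)
  expect_equal(gs$mean_all, 3)
  expect_equal(gs$sd_all, sqrt(2))

  # identical samples -> SD 0; single sample -> SD undefined (NA)
  calls_same <- dplyr::bind_rows(
    make_calls("X", ann$rsid[1:2], ann$genotype[1:2]),
    make_calls("Y", ann$rsid[1:2], ann$genotype[1:2])
  )
  attr(calls_same, "samples") <- c("X", "Y")
  gs2 <- group_summary(annotate_cohort(calls_same, kb4),
                       tibble::tibble(sample_id = c("X", "Y"),
                                      population = "P"))
  expect_equal(gs2$sd_all, 0)
  gs3 <- group_summary(annotate_cohort(callsA, kb4),
                       tibble::tibble(sample_id = "A", population = "P"))
  expect_true(is.na(gs3$sd_all))
})

test_that("group_summary equals a spreadsheet-style recomputation", {
  kb <- mini_kb()
  sim <- simulate_cohort(kb, default_population_specs(kb, n = 30),
                         seed = 23)
  m <- annotate_cohort(sim$calls, kb)
  gs <- group_summary(m, sim$groups)

  # oracle: flat tapply over per-sample distinct counts incl zeros
  md <- as.data.frame(m)
  per <- sapply(sim$groups$sample_id, function(s) {
    length(unique(md$rsid[md$sample_id == s]))
  })
  per_fda <- sapply(sim$groups$sample_id, function(s) {
    length(unique(md$rsid[md$sample_id == s & md$fda_labeled]))
  })
  pop <- sim$groups$population
  for (p in unique(pop)) {
    expect_equal(gs$mean_all[gs$population == p], mean(per[pop == p]))
    expect_equal(gs$sd_all[gs$population == p], sd(per[pop == p]))
    expect_equal(gs$mean_fda[gs$population == p], mean(per_fda[pop == p]))
    expect_equal(gs$sd_fda[gs$population == p], sd(per_fda[pop == p]))
  }
})

test_that("FDA-subset counts are contained in the totals", {
  kb <- mini_kb()
  sim <- simulate_cohort(kb, default_population_specs(kb, n = 25),
                         seed = 29)
  m <- annotate_cohort(sim$calls, kb)
  gs <- group_summary(m, sim$groups)
  expect_true(all(gs$mean_fda <= gs$mean_all))
  # per-sample containment
  md <- as.data.frame(m)
  for (s in unique(md$sample_id)) {
    expect_lte(length(unique(md$rsid[md$sample_id == s & md$fda_labeled])),
               length(unique(md$rsid[md$sample_id == s])))
  }
})

test_that("permuting sample order permutes rows and leaves summaries unchanged", {
  kb <- mini_kb()
  sim <- simulate_cohort(kb, default_population_specs(kb, n = 10),
                         seed = 31)
  m <- annotate_cohort(sim$calls, kb)
  tab <- sample_drug_counts(m)

  set.seed(1)
  perm <- sample(attr(m, "samples"))
  tab_p <- sample_drug_counts(m, samples = perm)
  expect_equal(tab_p[match(tab$sample_id, tab_p$sample_id), ], tab,
               ignore_attr = TRUE)

  gs <- group_summary(m, sim$groups)
  gs_p <- group_summary(m, sim$groups[sample(nrow(sim$groups)), ],
                        samples = perm)
  expect_equal(gs_p, gs)
})

test_that("compare_to_group flags exactly the planted rare genotypes", {
  kb <- mini_kb()
  sim <- simulate_cohort(kb, default_population_specs(kb, n = 50),
                         seed = 37)

  # index sample whose genotype equals each group's majority -> 0 flagged
  gd <- genotype_distribution(sim$calls, unique(sim$calls$rsid),
                              sim$groups)
  eur_major <- gd |>
    dplyr::filter(population == "EUR", genotype != "MISSING") |>
    dplyr::group_by(rsid) |>
    dplyr::slice_max(frequency, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  majority_ok <- eur_major |> dplyr::filter(frequency >= 0.5)
  idx_calls <- make_calls("IDX", majority_ok$rsid, majority_ok$genotype)
  idx_m <- annotate_sample(idx_calls, kb)
  cmp <- compare_to_group(idx_m, sim$calls, sim$groups, "EUR")
  expect_equal(cmp$n_flagged, 0L)

  # plant a genotype that is rare in the comparison group: rs9923231 AA is
  # nearly absent where the G allele runs at frequency 0.95 (AFR spec)
  rare <- make_calls("IDX2", "rs9923231", "AA")
  rare_m <- annotate_sample(rare, kb)
  expect_equal(nrow(rare_m), 1L)
  cmp2 <- compare_to_group(rare_m, sim$calls, sim$groups, "AFR")
  expect_equal(cmp2$n_flagged, 1L)
  expect_true(tidy(cmp2)$flagged[tidy(cmp2)$rsid == "rs9923231"])

  g <- glance(cmp2)
  expect_equal(g$n_matched, 1L)
  expect_equal(g$population, "AFR")

  expect_error(compare_to_group(rare_m, sim$calls, sim$groups, "MARS"),
               class = "pgx_input_error")
})

test_that("group plots build without error", {
  kb <- mini_kb()
  sim <- simulate_cohort(kb, default_population_specs(kb, n = 10),
                         seed = 41)
  m <- annotate_cohort(sim$calls, kb)
  gd <- genotype_distribution(sim$calls, unique(sim$calls$rsid),
                              sim$groups)
  expect_s3_class(plot_genotype_distribution(gd), "ggplot")
  expect_s3_class(plot_group_summary(group_summary(m, sim$groups)),
                  "ggplot")
})
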