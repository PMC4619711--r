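# Reference allele pairs for the built-in mini KB loci. A KB row only
# carries a genotype, so a locus annotated for one homozygote (e.g.
# rs1042522 CC) does not reveal its second allele; this table supplies it.
MINI_KB_ALLELES <- list(
  rs1042522 = c("C", "G"), rs316019 = c("A", "C"), rs11615 = c("A", "G"),
  rs3957357 = c("C", "T"), rs9923231 = c("A", "G"), rs1799853 = c("C", "T"),
  rs2108622 = c("C", "T"), rs2292566 = c("A", "G"), rs4244285 = c("A", "G")
)

#' Allele pairs for the loci of a knowledge base
#'
#' Derives, per rsid, the biallelic allele pair a simulated cohort segregates
#' at: the union of alleles across the KB's genotype rows, completed from the
#' built-in reference table (or, failing that, with the alphabetically first
#' other base) when only one allele is observed.
#'
#' @param kb A [pgx_kb] object.
#' @return Named list: rsid -> sorted pair of allele characters.
#' @export
kb_alleles <- function(kb) {
  stopifnot(inherits(kb, "pgx_kb"))
  ann <- kb$annotations
  split(ann$genotype, ann$rsid) |>
    purrr::imap(function(gts, rs) {
      alleles <- sort(unique(unlist(strsplit(gts, ""))))
      if (length(alleles) > 2L) {
        stop_pgx(paste0(rs, " has >2 alleles in the KB; cannot simulate"),
                 class = "pgx_spec_error")
      }
      if (length(alleles) == 1L) {
        partner <- MINI_KB_ALLELES[[rs]] %||%
          c(alleles, setdiff(BASES, alleles)[1])
        alleles <- sort(unique(c(alleles, partner)))[1:2]
      }
      alleles
    })
}

# per-population frequencies of the alphabetically later allele at the mini
# KB loci, chosen once to emulate the qualitative population patterns of the
# five 1000 Genomes super-populations (see the methods vignette)
MINI_KB_FREQS <- tibble::tribble(
  ~rsid,        ~AFR, ~AMR, ~SAS, ~EAS, ~EUR,
  "rs1042522",  0.70, 0.30, 0.50, 0.55, 0.28,
  "rs316019",   0.80, 0.50, 0.50, 0.85, 0.50,
  "rs11615",    0.80, 0.80, 0.80, 0.80, 0.50,
  "rs3957357",  0.70, 0.70, 0.70, 0.70, 0.70,
  "rs9923231",  0.95, 0.55, 0.85, 0.10, 0.60,
  "rs1799853",  0.02, 0.08, 0.04, 0.01, 0.12,
  "rs2108622",  0.08, 0.25, 0.40, 0.22, 0.29,
  "rs2292566",  0.85, 0.80, 0.75, 0.65, 0.80,
  "rs4244285",  0.83, 0.88, 0.65, 0.70, 0.85
)

#' Default population specifications for a simulated cohort
#'
#' Five populations named after the 1000 Genomes super-populations (AFR,
#' AMR, SAS, EAS, EUR), each of `n` samples. Allele frequencies at the mini
#' KB loci follow a fixed, field-realistic table reproducing the qualitative
#' between-population patterns of those pharmacogenomic variants; any other
#' KB locus defaults to frequency 0.5.
#'
#' @param kb A [pgx_kb] object (its rsids define the simulated loci).
#' @param n Samples per population (default 500).
#' @param labels Population labels.
#' @return List of population specs, each a list with `label`, `n_samples`
#'   and `allele_freqs` (named vector: rsid -> frequency of the
#'   alphabetically later allele).
#' @examples
#' str(default_population_specs(mini_kb(), n = 10)[[1]])
#' @export
default_population_specs <- function(kb, n = 500,
                                     labels = c("AFR", "AMR", "SAS", "EAS",
                                                "EUR")) {
  rsids <- sort(unique(kb$annotations$rsid))
  lapply(labels, function(lab) {
    freqs <- vapply(rsids, function(rs) {
      row <- MINI_KB_FREQS[MINI_KB_FREQS$rsid == rs, ]
      if (nrow(row) == 1L && lab %in% names(row)) row[[lab]] else 0.5
    }, numeric(1))
    list(label = lab, n_samples = as.integer(n),
         allele_freqs = freqs)
  })
}

#' Simulate a diploid genotype cohort with exhaustive ground truth
#'
#' Draws, per sample and per knowledge-base locus, a diploid genotype under
#' Hardy-Weinberg proportions (p^2, 2pq, q^2) from the sample's population
#' allele frequency, and computes the exact expected results alongside: the
#' truth match table (by an exhaustive pair scan of planted genotypes
#' against KB rows, independent of the annotation engine's join) and the
#' closed-form Hardy-Weinberg genotype frequencies.
#'
#' @param kb A [pgx_kb] object.
#' @param specs List of population specs (see
#'   [default_population_specs()]); each needs `label`, `n_samples` and
#'   `allele_freqs` (frequency of the alphabetically later allele, in
#'   `[0, 1]`).
#' @param seed Integer seed; the whole cohort is drawn from one stream.
#' @param missing_rate Per-call probability of a no-call (default 0).
#' @return A `pgx_cohort_sim` list: `$calls` (cohort call tibble),
#'   `$groups` (sample -> population manifest), `$truth_matches` (expected
#'   matched annotations), `$expected_freqs` (per rsid and population, the
#'   Hardy-Weinberg genotype probabilities), `$seed`.
#' @examples
#' sim <- simulate_cohort(mini_kb(), default_population_specs(mini_kb(), n = 5),
#'                        seed = 42)
#' dplyr::count(sim$calls, sample_id)
#' @export
simulate_cohort <- function(kb, specs, seed, missing_rate = 0) {
  stopifnot(inherits(kb, "pgx_kb"), length(specs) >= 1L)
  alleles <- kb_alleles(kb)
  rsids <- names(alleles)
  sites <- kb$annotations |>
    dplyr::distinct(.data$rsid, .data$chrom, .data$pos) |>
    dplyr::group_by(.data$rsid) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()

  for (sp in specs) {
    if (any(sp$allele_freqs < 0 | sp$allele_freqs > 1)) {
      stop_pgx(paste0("allele frequencies must lie in [0, 1] (population ",
                      sp$label, ")"), class = "pgx_spec_error")
    }
  }

  set.seed(as.integer(seed))
  groups <- dplyr::bind_rows(lapply(specs, function(sp) {
    tibble::tibble(
      sample_id = sprintf("%s_%04d", sp$label, seq_len(sp$n_samples)),
      population = sp$label
    )
  }))

  calls <- dplyr::bind_rows(lapply(specs, function(sp) {
    dplyr::bind_rows(lapply(rsids, function(rs) {
      p <- unname(sp$allele_freqs[rs])
      if (is.na(p)) p <- 0.5
      a <- alleles[[rs]] # sorted; p is the frequency of a[2]
      k <- rbinom(sp$n_samples, 2L, p)
      geno <- c(paste0(a[1], a[1]), paste0(a[1], a[2]),
                paste0(a[2], a[2]))[k + 1L]
      if (missing_rate > 0) {
        geno[stats::runif(sp$n_samples) < missing_rate] <- NA_character_
      }
      site <- sites[sites$rsid == rs, ]
      tibble::tibble(
        sample_id = sprintf("%s_%04d", sp$label, seq_len(sp$n_samples)),
        rsid = rs, chrom = site$chrom, pos = site$pos,
        genotype = geno, source = "simulated"
      )
    }))
  })) |>
    dplyr::arrange(match(.data$sample_id, groups$sample_id), .data$rsid)
  attr(calls, "samples") <- groups$sample_id

  # ground truth by exhaustive pair scan (every annotation row against
  # every planted call), deliberately not a join
  ann <- kb$annotations
  call_idx <- integer(0)
  ann_idx <- integer(0)
  for (j in seq_len(nrow(ann))) {
    hits <- which(!is.na(calls$genotype) & calls$rsid == ann$rsid[j] &
                    calls$genotype == ann$genotype[j])
    call_idx <- c(call_idx, hits)
    ann_idx <- c(ann_idx, rep(j, length(hits)))
  }
  truth <- tibble::tibble(
    sample_id = calls$sample_id[call_idx],
    ann[ann_idx, c("rsid", "gene", "genotype", "drug", "aspect",
                   "direction", "evidence", "fda_labeled", "description")]
  )
  truth_matches <- dplyr::bind_rows(empty_matches(), truth) |>
    dplyr::mutate(.rank = evidence_rank(.data$evidence)) |>
    dplyr::arrange(match(.data$sample_id, groups$sample_id), .data$drug,
                   .data$.rank, .data$rsid, .data$aspect) |>
    dplyr::select(dplyr::all_of(MATCH_COLS))
  attr(truth_matches, "samples") <- groups$sample_id

  expected_freqs <- dplyr::bind_rows(lapply(specs, function(sp) {
    dplyr::bind_rows(lapply(rsids, function(rs) {
      p <- unname(sp$allele_freqs[rs])
      if (is.na(p)) p <- 0.5
      a <- alleles[[rs]]
      tibble::tibble(
        rsid = rs, population = sp$label,
        genotype = c(paste0(a[1], a[1]), paste0(a[1], a[2]),
                     paste0(a[2], a[2])),
        expected = c((1 - p)^2, 2 * p * (1 - p), p^2)
      )
    }))
  }))

  structure(
    list(calls = calls, groups = groups, truth_matches = truth_matches,
         expected_freqs = expected_freqs, seed = as.integer(seed)),
    class = "pgx_cohort_sim"
  )
}

#' @export
print.pgx_cohort_sim <- function(x, ...) {
  cat(sprintf(
    "<pgx_cohort_sim> %d samples, %d populations, %d loci (seed %d)\n",
    length(unique(x$groups$sample_id)),
    length(unique(x$groups$population)),
    length(unique(x$calls$rsid)), x$seed))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Emits the standard file bundle: a multi-sample VCF, one 23andMe-dialect
#' file per sample, the population manifest, the truth tables, and a JSON
#' metadata record carrying the seed.
#'
#' @param sim A `pgx_cohort_sim` from [simulate_cohort()].
#' @param dir Output directory (created if absent).
#' @param dialect_files Write the per-sample array-dialect files (default
#'   TRUE; can be turned off for large cohorts).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir, dialect_files = TRUE) {
  stopifnot(inherits(sim, "pgx_cohort_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_vcf_genotypes(sim$calls, file.path(dir, "cohort.vcf"))
  if (dialect_files) {
    sample_dir <- file.path(dir, "samples")
    if (!dir.exists(sample_dir)) dir.create(sample_dir)
    for (s in unique(sim$groups$sample_id)) {
      write_array_genotypes(sim$calls[sim$calls$sample_id == s, ],
                            file.path(sample_dir, paste0(s, ".txt")),
                            dialect = "23andme")
    }
  }
  readr::write_tsv(sim$groups, file.path(dir, "manifest.tsv"),
                   progress = FALSE)
  readr::write_tsv(sim$truth_matches, file.path(dir, "truth_matches.tsv"),
                   progress = FALSE)
  readr::write_tsv(sim$expected_freqs, file.path(dir, "expected_freqs.tsv"),
                   progress = FALSE)
  jsonlite::write_json(list(seed = sim$seed,
                            n_samples = nrow(sim$groups)),
                       file.path(dir, "simulation.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Generate a random schema-valid knowledge base
#'
#' Builds a knowledge base of exactly `n_rows` distinct annotation rows over
#' exactly `n_drugs` drugs, with random rsids, placeholder genes, biallelic
#' genotypes, aspects, directions, evidence levels and per-drug FDA flags.
#' Construction guarantees a clean [validate_kb()]: each rsid keeps one
#' fixed allele pair and no (rsid, genotype, drug, aspect) key recurs, so no
#' conflicting directions can arise. Identical seeds give identical KBs.
#'
#' @param n_rows Number of annotation rows (>= 1).
#' @param n_drugs Number of drugs (>= 1).
#' @param seed Integer seed.
#' @return A [pgx_kb] object.
#' @examples
#' glance(random_kb(20, 5, seed = 7))
#' @export
random_kb <- function(n_rows, n_drugs, seed) {
  stopifnot(n_rows >= 1L, n_drugs >= 1L)
  set.seed(as.integer(seed))

  n_sites <- max(n_drugs, ceiling(n_rows / 2))
  sites <- tibble::tibble(
    rsid = paste0("rs", sample(1e6:9e6, n_sites)),
    gene = sprintf("GENE_%03d", seq_len(n_sites)),
    chrom = as.character(sample(1:22, n_sites, replace = TRUE)),
    pos = sample(1e4:1e8, n_sites),
    a1 = character(n_sites), a2 = character(n_sites)
  )
  pair <- t(vapply(seq_len(n_sites),
                   function(i) sort(sample(BASES, 2L)), character(2)))
  sites$a1 <- pair[, 1]
  sites$a2 <- pair[, 2]

  site_idx <- rep(seq_len(n_sites), length.out = n_rows)
  gt_idx <- stats::ave(site_idx, site_idx, FUN = seq_along) # 1..3 per site
  gt_options <- cbind(paste0(sites$a1, sites$a1),
                      paste0(sites$a1, sites$a2),
                      paste0(sites$a2, sites$a2))
  drugs <- sprintf("DRUG_%03d", seq_len(n_drugs))
  fda_drug <- setNames(stats::runif(n_drugs) < 0.3, drugs)

  ann <- tibble::tibble(
    rsid = sites$rsid[site_idx],
    gene = sites$gene[site_idx],
    chrom = sites$chrom[site_idx],
    pos = sites$pos[site_idx],
    genotype = gt_options[cbind(site_idx, gt_idx)],
    drug = rep(drugs, length.out = n_rows),
    aspect = sample(KB_ASPECTS, n_rows, replace = TRUE),
    direction = sample(KB_DIRECTIONS, n_rows, replace = TRUE),
    evidence = sample(evidence_levels(), n_rows, replace = TRUE),
    description = sprintf("Synthetic association %d.", seq_len(n_rows))
  )
  ann$fda_labeled <- unname(fda_drug[ann$drug])
  ann <- ann[sample(n_rows), ]

  category_pool <- c("Anticoagulants", "Antineoplastic Agents",
                     "Analgesics", "Antidepressants", "Antihypertensives",
                     "Platelet Aggregation Inhibitors")
  drug_tbl <- tibble::tibble(
    drug = drugs,
    external_id = sprintf("DBX%05d", sample(1e4:99999, n_drugs)),
    categories = vapply(seq_len(n_drugs), function(i) {
      paste(sample(category_pool, sample(1:2, 1)), collapse = ";")
    }, ""),
    description = sprintf("Synthetic drug %d.", seq_len(n_drugs))
  )

  pgx_kb(ann, drug_tbl)
}
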