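check_groups <- function(groups) {
  groups <- tibble::as_tibble(groups)
  need <- c("sample_id", "population")
  miss <- setdiff(need, names(groups))
  if (length(miss)) {
    stop_pgx(paste0("group assignment is missing column(s): ",
                    paste(miss, collapse = ", ")),
             class = "pgx_schema_error")
  }
  dup <- duplicated(groups$sample_id)
  if (any(dup)) {
    stop_pgx(paste0("sample(s) assigned to more than one population: ",
                    paste(unique(groups$sample_id[dup]), collapse = ", ")),
             class = "pgx_input_error")
  }
  groups
}

assert_assigned <- function(sample_ids, groups) {
  unassigned <- setdiff(sample_ids, groups$sample_id)
  if (length(unassigned)) {
    stop_pgx(paste0("sample(s) missing from the population manifest: ",
                    paste(unassigned, collapse = ", ")),
             class = "pgx_input_error")
  }
}

count_table <- function(matches, col, samples = NULL) {
  samples <- samples %||% attr(matches, "samples") %||%
    unique(matches$sample_id)
  long <- matches |>
    dplyr::distinct(.data$sample_id, .data$rsid, .data[[col]]) |>
    dplyr::count(.data$sample_id, .data[[col]])
  cols <- sort(unique(long[[col]]))
  wide <- long |>
    tidyr::pivot_wider(names_from = dplyr::all_of(col), values_from = "n",
                       values_fill = 0L)
  out <- tibble::tibble(sample_id = samples) |>
    dplyr::left_join(wide, by = "sample_id")
  out[is.na(out)] <- 0L
  out[, c("sample_id", cols), drop = FALSE]
}

#' Sample-by-gene and sample-by-drug variant count tables
#'
#' Cohort-level count tables for data mining: entry (sample, gene) is the
#' number of distinct matched rsids of that gene in that sample, and entry
#' (sample, drug) the number of distinct matched rsids annotated to that
#' drug. Samples with zero matches keep an all-zero row; columns are sorted
#' lexicographically.
#'
#' @param matches Matched annotations from [annotate_cohort()].
#' @param samples Optional character vector fixing the row set and order;
#'   defaults to the `"samples"` attribute of `matches`.
#' @return Tibble with a `sample_id` column followed by one non-negative
#'   integer column per gene (or drug).
#' @examples
#' sim <- simulate_cohort(mini_kb(), default_population_specs(mini_kb(), n = 4),
#'                        seed = 1)
#' m <- annotate_cohort(sim$calls, mini_kb())
#' sample_gene_counts(m)
#' sample_drug_counts(m)
#' @export
sample_gene_counts <- function(matches, samples = NULL) {
  count_table(matches, "gene", samples)
}

#' @rdname sample_gene_counts
#' @export
sample_drug_counts <- function(matches, samples = NULL) {
  count_table(matches, "drug", samples)
}

#' Per-population genotype frequency distributions
#'
#' For each requested rsid and each population, tabulates the observed
#' canonical genotypes of that population's samples. Missing genotypes (a
#' no-call, or no call at all at that site) are tracked as the `MISSING`
#' category and excluded from the frequency denominator, so the observed
#' genotype frequencies of each (rsid, population) cell sum to 1.
#'
#' @param calls Multi-sample call tibble.
#' @param rsids Character vector of rsids to tabulate.
#' @param groups Population manifest: tibble with `sample_id`, `population`.
#' @return Tibble with columns `rsid`, `population`, `genotype` (canonical
#'   string or `"MISSING"`), `count` and `frequency`. For observed genotypes
#'   `frequency` is relative to the population's non-missing calls at that
#'   rsid; for the `MISSING` row it is the missing fraction of all samples.
#' @examples
#' sim <- simulate_cohort(mini_kb(), default_population_specs(mini_kb(), n = 20),
#'                        seed = 1)
#' genotype_distribution(sim$calls, "rs11615", sim$groups)
#' @export
genotype_distribution <- function(calls, rsids, groups) {
  groups <- check_groups(groups)
  samples <- attr(calls, "samples") %||% unique(calls$sample_id)
  assert_assigned(samples, groups)
  groups <- groups[groups$sample_id %in% samples, ]

  grid <- tidyr::expand_grid(rsid = rsids,
                             sample_id = groups$sample_id) |>
    dplyr::left_join(groups, by = "sample_id") |>
    dplyr::left_join(
      calls |> dplyr::filter(.data$rsid %in% rsids) |>
        dplyr::select("sample_id", "rsid", "genotype"),
      by = c("sample_id", "rsid")
    ) |>
    dplyr::mutate(genotype = ifelse(is.na(.data$genotype), "MISSING",
                                    .data$genotype))

  counts <- grid |>
    dplyr::count(.data$rsid, .data$population, .data$genotype,
                 name = "count")
  totals <- counts |>
    dplyr::group_by(.data$rsid, .data$population) |>
    dplyr::summarise(
      n_total = sum(.data$count),
      n_obs = sum(.data$count[.data$genotype != "MISSING"]),
      .groups = "drop"
    )
  counts |>
    dplyr::left_join(totals, by = c("rsid", "population")) |>
    dplyr::mutate(frequency = ifelse(
      .data$genotype == "MISSING",
      .data$count / .data$n_total,
      .data$count / .data$n_obs
    )) |>
    dplyr::select("rsid", "population", "genotype", "count", "frequency") |>
    dplyr::arrange(.data$rsid, .data$population, .data$genotype)
}

#' Per-population allele frequencies
#'
#' Counts the two allele copies of every non-missing diploid call, by rsid
#' and population.
#'
#' @inheritParams genotype_distribution
#' @return Tibble with `rsid`, `population`, `allele`, `count`, `frequency`
#'   (summing to 1 per rsid and population).
#' @export
allele_frequencies <- function(calls, rsids, groups) {
  groups <- check_groups(groups)
  samples <- attr(calls, "samples") %||% unique(calls$sample_id)
  assert_assigned(samples, groups)

  obs <- calls |>
    dplyr::filter(.data$rsid %in% rsids, !is.na(.data$genotype)) |>
    dplyr::left_join(groups, by = "sample_id")
  if (nrow(obs) == 0L) {
    return(tibble::tibble(rsid = character(), population = character(),
                          allele = character(), count = integer(),
                          frequency = double()))
  }
  obs |>
    dplyr::mutate(allele = strsplit(.data$genotype, "")) |>
    tidyr::unnest_longer("allele") |>
    dplyr::count(.data$rsid, .data$population, .data$allele,
                 name = "count") |>
    dplyr::group_by(.data$rsid, .data$population) |>
    dplyr::mutate(frequency = .data$count / sum(.data$count)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$rsid, .data$population, .data$allele)
}

#' Population burden summary of drug-related SNPs
#'
#' Per population: the mean and sample standard deviation (n-1 denominator)
#' of the number of distinct drug-response SNPs matched per individual,
#' computed over all matched annotations and again over the subset carrying
#' the FDA biomarker-label flag. Samples with zero matches count as zeros.
#'
#' @param matches Matched annotations from [annotate_cohort()].
#' @param groups Population manifest (`sample_id`, `population`).
#' @param samples Optional explicit sample set (defaults to the `"samples"`
#'   attribute of `matches`).
#' @return Tibble with one row per population: `population`, `n`,
#'   `mean_all`, `sd_all`, `mean_fda`, `sd_fda`. The SD of a single-sample
#'   population is `NA`.
#' @examples
#' sim <- simulate_cohort(mini_kb(), default_population_specs(mini_kb(), n = 10),
#'                        seed = 1)
#' m <- annotate_cohort(sim$calls, mini_kb())
#' group_summary(m, sim$groups)
#' @export
group_summary <- function(matches, groups, samples = NULL) {
  groups <- check_groups(groups)
  samples <- samples %||% attr(matches, "samples") %||%
    unique(matches$sample_id)
  assert_assigned(samples, groups)

  per_sample <- tibble::tibble(sample_id = samples) |>
    dplyr::left_join(
      matches |>
        dplyr::group_by(.data$sample_id) |>
        dplyr::summarise(
          n_all = dplyr::n_distinct(.data$rsid),
          n_fda = dplyr::n_distinct(.data$rsid[.data$fda_labeled]),
          .groups = "drop"
        ),
      by = "sample_id"
    ) |>
    dplyr::mutate(n_all = dplyr::coalesce(.data$n_all, 0L),
                  n_fda = dplyr::coalesce(.data$n_fda, 0L)) |>
    dplyr::left_join(groups, by = "sample_id")

  per_sample |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_all = mean(.data$n_all),
      sd_all = stats::sd(.data$n_all),
      mean_fda = mean(.data$n_fda),
      sd_fda = stats::sd(.data$n_fda),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$population)
}

#' Compare one sample's matched genotypes with a population
#'
#' For every matched (rsid, genotype) of an index sample, reports how common
#' that genotype is within a chosen population of the cohort, and flags loci
#' where the index genotype is carried by less than `threshold` of the
#' group's genotyped samples — i.e. where the individual differs from the
#' group majority. Frequencies are over the group's non-missing calls.
#'
#' @param sample_matches Matched annotations of the index sample
#'   ([annotate_sample()]).
#' @param cohort_calls Call tibble of the comparison cohort.
#' @param groups Population manifest for `cohort_calls`.
#' @param label Population to compare against.
#' @param threshold Flagging threshold on the within-group genotype
#'   frequency (default 0.5).
#' @return A `pgx_divergence` object: `tidy()` gives the per-locus detail
#'   (`rsid`, `genotype`, `group_frequency`, `flagged`), `glance()` the
#'   counts (`n_matched`, `n_flagged`).
#' @examples
#' sim <- simulate_cohort(mini_kb(), default_population_specs(mini_kb(), n = 10),
#'                        seed = 1)
#' idx <- annotate_sample(sim$calls[sim$calls$sample_id ==
#'                                    sim$calls$sample_id[1], ], mini_kb())
#' cmp <- compare_to_group(idx, sim$calls, sim$groups,
#'                         label = sim$groups$population[1])
#' glance(cmp)
#' @export
compare_to_group <- function(sample_matches, cohort_calls, groups, label,
                             threshold = 0.5) {
  groups <- check_groups(groups)
  if (!label %in% groups$population) {
    stop_pgx(paste0("population label not present in manifest: ", label),
             class = "pgx_input_error")
  }
  group_samples <- groups$sample_id[groups$population == label]

  loci <- sample_matches |>
    dplyr::distinct(.data$rsid, .data$genotype)
  group_calls <- cohort_calls |>
    dplyr::filter(.data$sample_id %in% group_samples,
                  .data$rsid %in% loci$rsid,
                  !is.na(.data$genotype))
  freq <- group_calls |>
    dplyr::count(.data$rsid, .data$genotype, name = "k") |>
    dplyr::group_by(.data$rsid) |>
    dplyr::mutate(group_frequency = .data$k / sum(.data$k)) |>
    dplyr::ungroup()

  details <- loci |>
    dplyr::left_join(freq |> dplyr::select(-"k"),
                     by = c("rsid", "genotype")) |>
    dplyr::mutate(
      group_frequency = dplyr::coalesce(.data$group_frequency, 0),
      flagged = .data$group_frequency < threshold
    ) |>
    dplyr::arrange(.data$rsid)

  structure(
    list(details = details, label = label, threshold = threshold,
         n_matched = nrow(details), n_flagged = sum(details$flagged)),
    class = "pgx_divergence"
  )
}

#' @export
print.pgx_divergence <- function(x, ...) {
  cat(sprintf(
    "<pgx_divergence> vs %s: %d matched locus/loci, %d flagged (< %.2f group frequency)\n",
    x$label, x$n_matched, x$n_flagged, x$threshold))
  print(x$details, n = 5)
  invisible(x)
}

#' @method tidy pgx_divergence
#' @export
tidy.pgx_divergence <- function(x, ...) x$details

#' @method glance pgx_divergence
#' @export
glance.pgx_divergence <- function(x, ...) {
  tibble::tibble(population = x$label, threshold = x$threshold,
                 n_matched = x$n_matched, n_flagged = x$n_flagged)
}
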