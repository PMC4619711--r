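#' Test two canonical genotypes for an exact match
#'
#' Matching is exact string equality after canonicalization: a knowledge-base
#' row for `AG` never matches an observed `GG`, because drug-response
#' phenotypes are reported per genotype, not per allele. A missing observed
#' genotype never matches.
#'
#' @param observed,kb_genotype Canonical genotype strings ([canonical
#'   genotypes][canonical_genotype] — sorted, two A/C/G/T characters).
#'   `observed` may be `NA` (missing).
#' @return Logical vector.
#' @examples
#' match_genotype("AG", "AG") # TRUE
#' match_genotype("AG", "GG") # FALSE
#' @export
match_genotype <- function(observed, kb_genotype) {
  chk <- !is.na(observed) & !is_canonical_genotype(observed)
  if (any(chk) || any(!is_canonical_genotype(kb_genotype))) {
    stop_pgx("match_genotype() requires canonical genotypes (sorted, 2 chars)",
             class = "pgx_contract_error")
  }
  !is.na(observed) & observed == kb_genotype
}

MATCH_COLS <- c("sample_id", "rsid", "gene", "genotype", "drug", "aspect",
                "direction", "evidence", "fda_labeled", "description")

empty_matches <- function() {
  tibble::tibble(
    sample_id = character(), rsid = character(), gene = character(),
    genotype = character(), drug = character(), aspect = character(),
    direction = character(), evidence = character(),
    fda_labeled = logical(), description = character()
  )
}

#' Annotate a sample's genotypes against the knowledge base
#'
#' The clinical-annotation step: every call whose rsid and exact canonical
#' genotype equal a knowledge-base row is emitted as a matched annotation,
#' one output row per matching KB row (a SNP associated with several drugs
#' or aspects yields several rows). Matching is keyed on rsid; calls lacking
#' an rsid fall back to chromosome/position matching with a warning. Output
#' is deterministically sorted by drug, evidence strength, rsid, aspect.
#'
#' @param calls Call tibble for one sample (from [read_vcf_genotypes()] or
#'   [read_array_genotypes()]).
#' @param kb A [pgx_kb] object.
#' @param min_evidence Optional minimum evidence level (e.g. `"2B"`); rows
#'   with weaker evidence are dropped. Default `NULL` reports all levels.
#' @return Tibble of matched annotations: `sample_id`, `rsid`, `gene`,
#'   `genotype`, `drug`, `aspect`, `direction`, `evidence`, `fda_labeled`,
#'   `description`.
#' @examples
#' calls <- tibble::tibble(
#'   sample_id = "S1", rsid = c("rs1042522", "rs11615"),
#'   chrom = c("17", "19"), pos = c(7579472L, 45923653L),
#'   genotype = c("CC", "GG"), source = "23andme"
#' )
#' annotate_sample(calls, mini_kb())
#' @export
annotate_sample <- function(calls, kb, min_evidence = NULL) {
  stopifnot(inherits(kb, "pgx_kb"))
  if (length(unique(calls$sample_id)) > 1L) {
    stop_pgx("annotate_sample() expects calls from a single sample; use annotate_cohort()",
             class = "pgx_input_error")
  }
  annotate_calls(calls, kb, min_evidence)
}

# shared indexed join used by annotate_sample()/annotate_cohort();
# the brute-force pair loop in the test suite is the independent oracle
annotate_calls <- function(calls, kb, min_evidence = NULL) {
  ann <- kb$annotations
  if (!is.null(min_evidence)) {
    ann <- ann[evidence_at_least(ann$evidence, min_evidence), ]
  }
  usable <- calls[!is.na(calls$genotype), , drop = FALSE]

  by_rsid <- usable[!is.na(usable$rsid), ] |>
    dplyr::inner_join(
      ann |> dplyr::select(-"chrom", -"pos"),
      by = c("rsid", "genotype"), relationship = "many-to-many"
    )

  no_rsid <- usable[is.na(usable$rsid), ]
  by_pos <- NULL
  if (nrow(no_rsid) > 0L && nrow(ann) > 0L) {
    by_pos <- no_rsid |>
      dplyr::select(-"rsid") |>
      dplyr::inner_join(ann, by = c("chrom", "pos", "genotype"),
                        relationship = "many-to-many")
    if (nrow(by_pos) > 0L) {
      rlang::warn(sprintf(
        "%d call(s) without rsid matched by chromosome/position",
        length(unique(paste(by_pos$chrom, by_pos$pos)))))
    }
  }

  out <- dplyr::bind_rows(empty_matches(), by_rsid, by_pos)
  out |>
    dplyr::mutate(.rank = evidence_rank(.data$evidence)) |>
    dplyr::arrange(.data$sample_id, .data$drug, .data$.rank, .data$rsid,
                   .data$aspect) |>
    dplyr::select(dplyr::all_of(MATCH_COLS))
}

#' Annotate a cohort of samples
#'
#' Applies [annotate_sample()] to every sample of a long multi-sample call
#' table; equivalent to annotating each sample independently and binding the
#' results, with the input's sample order preserved. Samples with zero
#' matches contribute no rows but stay listed in the `"samples"` attribute,
#' which downstream count tables and summaries use to keep their all-zero
#' rows.
#'
#' @param calls Multi-sample call tibble. At most one call per (sample,
#'   rsid) — and per (sample, chrom, pos) for rsid-less calls — is allowed.
#' @inheritParams annotate_sample
#' @return Tibble of matched annotations (see [annotate_sample()]), samples
#'   in input order; attribute `"samples"` lists every input sample.
#' @examples
#' sim <- simulate_cohort(mini_kb(), default_population_specs(mini_kb(), n = 3),
#'                        seed = 1)
#' annotate_cohort(sim$calls, mini_kb())
#' @export
annotate_cohort <- function(calls, kb, min_evidence = NULL) {
  stopifnot(inherits(kb, "pgx_kb"))
  samples <- attr(calls, "samples") %||% unique(calls$sample_id)
  key <- ifelse(is.na(calls$rsid),
                paste0("pos:", calls$chrom, ":", calls$pos),
                calls$rsid)
  dup <- duplicated(paste(calls$sample_id, key))
  if (any(dup)) {
    stop_pgx(paste0("duplicate call key(s) within a sample: ",
                    paste(unique(paste(calls$sample_id[dup], key[dup],
                                       sep = "/")), collapse = ", ")),
             class = "pgx_input_error")
  }
  out <- annotate_calls(calls, kb, min_evidence)
  out <- out[order(match(out$sample_id, samples)), , drop = FALSE]
  attr(out, "samples") <- samples
  out
}
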