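read_genotype_input <- function(path, format, sample_id = NULL) {
  if (format == "vcf") {
    read_vcf_genotypes(path)
  } else {
    read_array_genotypes(path, dialect = format, sample_id = sample_id)
  }
}

bind_cohort_calls <- function(call_list) {
  samples <- unlist(lapply(call_list, function(x) {
    attr(x, "samples") %||% unique(x$sample_id)
  }))
  if (anyDuplicated(samples)) {
    stop_pgx(paste0("duplicate sample id(s) across inputs: ",
                    paste(unique(samples[duplicated(samples)]),
                          collapse = ", ")),
             class = "pgx_input_error")
  }
  out <- dplyr::bind_rows(call_list)
  attr(out, "samples") <- samples
  out
}

#' Run the full annotation pipeline from a configuration
#'
#' Wires the stages end to end: load and validate the knowledge base, parse
#' every genotype input, annotate the cohort, and write the requested
#' outputs (matched-annotation TSV, per-sample HTML reports, GraphML
#' network, group-analysis tables). A JSON run manifest recording the
#' configuration and output files is written beside the outputs. Running
#' twice with the same configuration overwrites the outputs with identical
#' content.
#'
#' @param config Named list (or path of a YAML file holding one) with
#'   elements:
#'   * `kb`: knowledge-base directory (omit to use the built-in [mini_kb()])
#'   * `inputs`: list of `list(path=, format=, sample_id=)` entries, format
#'     one of `vcf`, `23andme`, `affymetrix`, `decodeme`, `ftdna`
#'   * `out`: output directory
#'   * `min_evidence`: optional evidence floor (e.g. `"2B"`)
#'   * `manifest`: optional population manifest TSV (`sample_id`,
#'     `population`) switching on the group analysis
#'   * `reports`, `network`: logicals (default `TRUE`) selecting outputs
#' @return Invisibly, a list with the loaded `kb`, the `calls`, the
#'   `matches` and the vector of written `files`.
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' sim <- simulate_cohort(mini_kb(), default_population_specs(mini_kb(), n = 2),
#'                        seed = 1)
#' write_cohort(sim, file.path(dir, "cohort"))
#' res <- run_pipeline(list(
#'   inputs = list(list(path = file.path(dir, "cohort", "cohort.vcf"),
#'                      format = "vcf")),
#'   out = file.path(dir, "results"),
#'   manifest = file.path(dir, "cohort", "manifest.tsv")
#' ))
#' basename(res$files)
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  out_dir <- config$out %||% stop_pgx("config$out (output directory) is required",
                                      class = "pgx_config_error")
  if (is.null(config$inputs) || length(config$inputs) == 0L) {
    stop_pgx("config$inputs must list at least one genotype input",
             class = "pgx_config_error")
  }
  # fail fast on unreadable paths before any stage runs
  if (!is.null(config$kb) && !dir.exists(config$kb) &&
        !file.exists(config$kb)) {
    stop_pgx(paste0("knowledge base path does not exist: ", config$kb),
             class = "pgx_config_error")
  }
  for (inp in config$inputs) {
    if (is.null(inp$path) || !file.exists(inp$path)) {
      stop_pgx(paste0("input file does not exist: ",
                      inp$path %||% "(missing path)"),
               class = "pgx_config_error")
    }
  }
  if (!is.null(config$manifest) && !file.exists(config$manifest)) {
    stop_pgx(paste0("population manifest does not exist: ", config$manifest),
             class = "pgx_config_error")
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  kb <- if (is.null(config$kb)) mini_kb() else read_kb(config$kb)
  issues <- validate_kb(kb)
  if (nrow(issues)) {
    rlang::warn(sprintf("knowledge base has %d validation issue(s)",
                        nrow(issues)))
  }

  calls <- bind_cohort_calls(lapply(config$inputs, function(inp) {
    read_genotype_input(inp$path, inp$format %||% "vcf", inp$sample_id)
  }))
  matches <- annotate_cohort(calls, kb,
                             min_evidence = config$min_evidence)

  files <- character(0)
  matches_path <- file.path(out_dir, "matches.tsv")
  readr::write_tsv(matches, matches_path, progress = FALSE)
  files <- c(files, matches_path)

  if (isTRUE(config$reports %||% TRUE)) {
    for (s in attr(matches, "samples")) {
      rep <- build_report(matches[matches$sample_id == s, , drop = FALSE],
                          kb)
      p <- file.path(out_dir, paste0("report_", s, ".html"))
      render_report(rep, p, format = "html")
      files <- c(files, p)
    }
  }
  if (isTRUE(config$network %||% TRUE)) {
    net <- build_network(kb, matches = if (nrow(matches)) matches)
    p <- file.path(out_dir, "network.graphml")
    export_network(net, p, format = "graphml")
    files <- c(files, p)
  }
  if (!is.null(config$manifest)) {
    groups <- readr::read_tsv(config$manifest,
                              col_types = readr::cols(.default = "c"),
                              progress = FALSE)
    gene_p <- file.path(out_dir, "gene_counts.tsv")
    drug_p <- file.path(out_dir, "drug_counts.tsv")
    freq_p <- file.path(out_dir, "genotype_freq.tsv")
    sum_p <- file.path(out_dir, "group_summary.tsv")
    readr::write_tsv(sample_gene_counts(matches), gene_p, progress = FALSE)
    readr::write_tsv(sample_drug_counts(matches), drug_p, progress = FALSE)
    readr::write_tsv(
      genotype_distribution(calls, sort(unique(kb$annotations$rsid)),
                            groups),
      freq_p, progress = FALSE)
    readr::write_tsv(group_summary(matches, groups), sum_p,
                     progress = FALSE)
    files <- c(files, gene_p, drug_p, freq_p, sum_p)
  }

  manifest <- list(
    config = config[setdiff(names(config), "inputs")],
    inputs = lapply(config$inputs, function(i) i$path),
    n_samples = length(attr(matches, "samples")),
    n_matches = nrow(matches),
    files = basename(files)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(kb = kb, calls = calls, matches = matches,
                 files = c(files, file.path(out_dir, "run_manifest.json"))))
}
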