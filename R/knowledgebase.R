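KB_ANNOTATION_COLS <- c(
  "rsid", "gene", "chrom", "pos", "genotype", "drug", "aspect",
  "direction", "evidence", "fda_labeled", "description"
)
KB_DRUG_COLS <- c("drug", "external_id", "categories", "description")

KB_ASPECTS <- c("efficacy", "dosage", "toxicity")
KB_DIRECTIONS <- c("increase", "decrease")

#' Construct a drug-response knowledge base
#'
#' A knowledge base pairs an annotation table — one row per
#' (rsid, genotype, drug, aspect, direction) association — with a drug table
#' carrying DrugBank-style descriptions and functional categories. Genotypes
#' are canonicalized (uppercased, alleles sorted) on construction, exact
#' duplicate rows are collapsed, and rsid/gene/drug indexes are built.
#'
#' @param annotations Data frame with columns `rsid`, `gene`, `chrom`, `pos`,
#'   `genotype`, `drug`, `aspect` (efficacy/dosage/toxicity), `direction`
#'   (increase/decrease), `evidence` (see [evidence_levels()]), `fda_labeled`
#'   (logical), `description`.
#' @param drugs Data frame with columns `drug`, `external_id`, `categories`
#'   (list column of character vectors, or `";"`-separated strings),
#'   `description`.
#' @return An object of class `pgx_kb`: a list with tibbles `$annotations`
#'   and `$drugs` plus row-number indexes `$index` by rsid, gene and drug.
#' @seealso [read_kb()], [mini_kb()], [validate_kb()]
#' @examples
#' kb <- mini_kb()
#' kb
#' @export
pgx_kb <- function(annotations, drugs) {
  ann <- tibble::as_tibble(annotations)
  drg <- tibble::as_tibble(drugs)

  missing_ann <- setdiff(KB_ANNOTATION_COLS, names(ann))
  if (length(missing_ann)) {
    stop_pgx(paste0("annotation table is missing required column(s): ",
                    paste(missing_ann, collapse = ", ")),
             class = "pgx_schema_error")
  }
  missing_drg <- setdiff(KB_DRUG_COLS, names(drg))
  if (length(missing_drg)) {
    stop_pgx(paste0("drug table is missing required column(s): ",
                    paste(missing_drg, collapse = ", ")),
             class = "pgx_schema_error")
  }

  if (!is.list(drg$categories)) {
    drg$categories <- lapply(drg$categories, function(x) {
      if (is.na(x) || !nzchar(x)) character(0)
      else strsplit(x, ";", fixed = TRUE)[[1]]
    })
  }
  if (any(is.na(drg$drug) | !nzchar(drg$drug))) {
    stop_pgx("drug table has empty drug names", class = "pgx_schema_error")
  }

  ann <- check_annotation_rows(ann)

  orphan <- setdiff(unique(ann$drug), drg$drug)
  if (length(orphan)) {
    stop_pgx(paste0("annotation rows reference drug(s) absent from the ",
                    "drug table: ", paste(orphan, collapse = ", ")),
             class = "pgx_referential_error")
  }

  ann <- dplyr::distinct(ann) |>
    dplyr::arrange(.data$drug, .data$rsid, .data$genotype, .data$aspect)
  drg <- drg[!duplicated(drg$drug), , drop = FALSE]

  structure(
    list(
      annotations = ann,
      drugs = drg,
      index = list(
        rsid = split(seq_len(nrow(ann)), ann$rsid),
        gene = split(seq_len(nrow(ann)), ann$gene),
        drug = split(seq_len(nrow(ann)), ann$drug)
      )
    ),
    class = "pgx_kb"
  )
}

# row-level validation shared by pgx_kb() and read_kb(); `line` gives the
# source line number for error messages when reading from file
check_annotation_rows <- function(ann, line = NULL) {
  if (nrow(ann) == 0L) {
    ann$genotype <- character(0)
    return(ann)
  }
  line <- line %||% seq_len(nrow(ann))
  where <- function(bad) paste(paste0("row ", line[bad]), collapse = ", ")

  bad <- !grepl("^rs[0-9]+$", ann$rsid)
  if (any(bad)) {
    stop_pgx(paste0("invalid rsid (must match rs[0-9]+) at ", where(bad)),
             class = "pgx_row_error")
  }
  ann$genotype <- sort_genotype(ann$genotype)
  bad <- !is_canonical_genotype(ann$genotype)
  if (any(bad)) {
    stop_pgx(paste0("invalid genotype (need two A/C/G/T alleles) at ",
                    where(bad)), class = "pgx_row_error")
  }
  bad <- !(ann$aspect %in% KB_ASPECTS)
  if (any(bad)) {
    stop_pgx(paste0("unknown aspect token at ", where(bad),
                    " (expected efficacy, dosage or toxicity)"),
             class = "pgx_row_error")
  }
  bad <- !(ann$direction %in% KB_DIRECTIONS)
  if (any(bad)) {
    stop_pgx(paste0("unknown direction token at ", where(bad),
                    " (expected increase or decrease)"),
             class = "pgx_row_error")
  }
  bad <- !(ann$evidence %in% evidence_levels())
  if (any(bad)) {
    stop_pgx(paste0("unknown evidence level at ", where(bad)),
             class = "pgx_row_error")
  }
  if (!is.logical(ann$fda_labeled) || anyNA(ann$fda_labeled)) {
    stop_pgx("fda_labeled must be true/false with no missing values",
             class = "pgx_row_error")
  }
  ann$chrom <- normalize_chrom(ann$chrom)
  ann$pos <- as.integer(ann$pos)
  bad <- is.na(ann$pos) | ann$pos < 1L
  if (any(bad)) {
    stop_pgx(paste0("position must be a 1-based integer at ", where(bad)),
             class = "pgx_row_error")
  }
  ann
}

#' Read a knowledge base from its two-file TSV serialization
#'
#' The on-disk form is a directory (or file pair) holding
#' `kb_annotations.tsv` and `kb_drugs.tsv`. See [pgx_kb()] for the column
#' schema; `categories` is `";"`-separated and `fda_labeled` is
#' `true`/`false`.
#'
#' @param path Directory containing `kb_annotations.tsv` and `kb_drugs.tsv`,
#'   or the path of the annotations file itself (the drug table is then
#'   looked up next to it).
#' @param drugs_path Optional explicit path of the drug table.
#' @return A [pgx_kb] object.
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' write_kb(mini_kb(), dir)
#' kb <- read_kb(dir)
#' glance(kb)
#' @export
read_kb <- function(path, drugs_path = NULL) {
  if (dir.exists(path)) {
    ann_path <- file.path(path, "kb_annotations.tsv")
    drugs_path <- drugs_path %||% file.path(path, "kb_drugs.tsv")
  } else {
    ann_path <- path
    drugs_path <- drugs_path %||% file.path(dirname(path), "kb_drugs.tsv")
  }
  for (p in c(ann_path, drugs_path)) {
    if (!file.exists(p)) {
      stop_pgx(paste0("knowledge base file not found: ", p),
               class = "pgx_io_error")
    }
  }

  ann <- readr::read_tsv(ann_path, col_types = readr::cols(
    rsid = "c", gene = "c", chrom = "c", pos = "i", genotype = "c",
    drug = "c", aspect = "c", direction = "c", evidence = "c",
    fda_labeled = "c", description = "c"
  ), na = character(), progress = FALSE)
  missing_ann <- setdiff(KB_ANNOTATION_COLS, names(ann))
  if (length(missing_ann)) {
    stop_pgx(paste0(ann_path, " is missing required column(s): ",
                    paste(missing_ann, collapse = ", ")),
             class = "pgx_schema_error")
  }
  fda <- tolower(ann$fda_labeled)
  if (!all(fda %in% c("true", "false"))) {
    bad <- which(!(fda %in% c("true", "false")))
    stop_pgx(paste0("fda_labeled must be true/false; bad value on line ",
                    paste(bad + 1L, collapse = ", "), " of ", ann_path),
             class = "pgx_row_error")
  }
  ann$fda_labeled <- fda == "true"
  # +1: header line
  ann <- tryCatch(
    check_annotation_rows(ann, line = seq_len(nrow(ann)) + 1L),
    pgx_row_error = function(e) {
      stop_pgx(paste0(ann_path, ": ", conditionMessage(e)),
               class = "pgx_row_error")
    }
  )

  drg <- readr::read_tsv(drugs_path, col_types = readr::cols(
    drug = "c", external_id = "c", categories = "c", description = "c"
  ), na = character(), progress = FALSE)
  missing_drg <- setdiff(KB_DRUG_COLS, names(drg))
  if (length(missing_drg)) {
    stop_pgx(paste0(drugs_path, " is missing required column(s): ",
                    paste(missing_drg, collapse = ", ")),
             class = "pgx_schema_error")
  }
  pgx_kb(ann, drg)
}

#' Write a knowledge base to its two-file TSV serialization
#'
#' @param kb A [pgx_kb] object.
#' @param path Output directory (created if absent); `kb_annotations.tsv` and
#'   `kb_drugs.tsv` are written inside it.
#' @return `path`, invisibly.
#' @export
write_kb <- function(kb, path) {
  stopifnot(inherits(kb, "pgx_kb"))
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  ann <- kb$annotations
  ann$fda_labeled <- ifelse(ann$fda_labeled, "true", "false")
  readr::write_tsv(ann, file.path(path, "kb_annotations.tsv"),
                   progress = FALSE)
  drg <- kb$drugs
  drg$categories <- vapply(drg$categories, paste, "", collapse = ";")
  readr::write_tsv(drg, file.path(path, "kb_drugs.tsv"), progress = FALSE)
  invisible(path)
}

#' Report internal consistency issues in a knowledge base
#'
#' Validation reports, it never raises: a clean knowledge base yields a
#' zero-row tibble. Two classes of issue are checked:
#' * `conflicting_direction`: rows sharing (rsid, genotype, drug, aspect)
#'   but disagreeing on increase vs decrease;
#' * `multi_allelic`: an rsid whose genotypes involve more than two distinct
#'   alleles (the schema is biallelic-SNV).
#'
#' @param kb A [pgx_kb] object.
#' @return Tibble with columns `issue`, `rsid`, `detail`; zero rows if clean.
#' @examples
#' nrow(validate_kb(mini_kb())) # 0
#' @export
validate_kb <- function(kb) {
  stopifnot(inherits(kb, "pgx_kb"))
  ann <- kb$annotations
  empty <- tibble::tibble(issue = character(), rsid = character(),
                          detail = character())
  if (nrow(ann) == 0L) return(empty)

  conflicts <- ann |>
    dplyr::distinct(.data$rsid, .data$genotype, .data$drug, .data$aspect,
                    .data$direction) |>
    dplyr::count(.data$rsid, .data$genotype, .data$drug, .data$aspect) |>
    dplyr::filter(.data$n > 1L) |>
    dplyr::mutate(
      issue = "conflicting_direction",
      detail = sprintf("%s %s/%s: both directions asserted",
                       .data$drug, .data$genotype, .data$aspect)
    ) |>
    dplyr::select("issue", "rsid", "detail")

  multi <- ann |>
    dplyr::group_by(.data$rsid) |>
    dplyr::summarise(
      n_alleles = length(unique(unlist(strsplit(.data$genotype, "")))),
      alleles = paste(sort(unique(unlist(strsplit(.data$genotype, "")))),
                      collapse = "/"),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_alleles > 2L) |>
    dplyr::mutate(
      issue = "multi_allelic",
      detail = sprintf("%d distinct alleles observed (%s)",
                       .data$n_alleles, .data$alleles)
    ) |>
    dplyr::select("issue", "rsid", "detail")

  dplyr::bind_rows(empty, conflicts, multi)
}

#' Look up annotation rows by rsid, gene or drug
#'
#' @param kb A [pgx_kb] object.
#' @param rsid,gene,drug Optional filters; rows must satisfy all that are
#'   given.
#' @return Tibble of matching annotation rows.
#' @examples
#' kb_lookup(mini_kb(), rsid = "rs11615")
#' @export
kb_lookup <- function(kb, rsid = NULL, gene = NULL, drug = NULL) {
  stopifnot(inherits(kb, "pgx_kb"))
  rows <- seq_len(nrow(kb$annotations))
  if (!is.null(rsid)) rows <- intersect(rows, unlist(kb$index$rsid[rsid]))
  if (!is.null(gene)) rows <- intersect(rows, unlist(kb$index$gene[gene]))
  if (!is.null(drug)) rows <- intersect(rows, unlist(kb$index$drug[drug]))
  kb$annotations[sort(rows), ]
}

#' @export
print.pgx_kb <- function(x, ...) {
  cat(sprintf(
    "<pgx_kb> %d annotation row(s), %d rsid(s), %d gene(s), %d drug(s)\n",
    nrow(x$annotations), length(x$index$rsid), length(x$index$gene),
    nrow(x$drugs)
  ))
  print(x$annotations, n = 5)
  invisible(x)
}

#' @method tidy pgx_kb
#' @export
tidy.pgx_kb <- function(x, ...) x$annotations

#' @method glance pgx_kb
#' @export
glance.pgx_kb <- function(x, ...) {
  tibble::tibble(
    n_annotations = nrow(x$annotations),
    n_rsids = length(x$index$rsid),
    n_genes = length(x$index$gene),
    n_drugs = nrow(x$drugs),
    n_fda_labeled = sum(x$annotations$fda_labeled)
  )
}
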