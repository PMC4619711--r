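SUMMARY_COLS <- c("rsid", "evidence", "gene", "genotype", "aspect",
                  "direction", "description")

#' Assemble an individual drug-response report
#'
#' Organizes one sample's matched annotations into the report structure: a
#' drug index (the navigation list), one section per drug — the drug's
#' DrugBank-style description followed by the sample's matched variant rows
#' — and a flat summary table. Drugs with at least one FDA
#' pharmacogenomic-biomarker-labeled match are flagged for highlighting.
#'
#' @param matches Matched annotations of a single sample
#'   ([annotate_sample()]).
#' @param kb The [pgx_kb] the matches came from (supplies drug
#'   descriptions and categories).
#' @param index_by `"drug"` (default) indexes sections by drug name;
#'   `"category"` groups the index entries under drug functional categories.
#' @return A `pgx_report` object with fields `sample_id`, `drug_index`,
#'   `sections` (named list of `list(drug_info, rows)`), `summary_table`,
#'   `fda_flags`, `index_by`.
#' @examples
#' calls <- tibble::tibble(sample_id = "S1", rsid = "rs11615", chrom = "19",
#'                         pos = 45923653L, genotype = "GG", source = "vcf")
#' rep <- build_report(annotate_sample(calls, mini_kb()), mini_kb())
#' rep$drug_index
#' @export
build_report <- function(matches, kb, index_by = c("drug", "category")) {
  stopifnot(inherits(kb, "pgx_kb"))
  index_by <- match.arg(index_by)
  sample_ids <- unique(matches$sample_id)
  if (length(sample_ids) > 1L) {
    stop_pgx("build_report() expects matches from exactly one sample",
             class = "pgx_input_error")
  }
  sample_id <- if (length(sample_ids)) sample_ids else "(no sample)"

  drug_index <- sort(unique(matches$drug))
  sections <- lapply(drug_index, function(d) {
    rows <- matches[matches$drug == d, , drop = FALSE]
    rows <- rows[order(evidence_rank(rows$evidence), rows$rsid,
                       rows$aspect), , drop = FALSE]
    list(
      drug_info = kb$drugs[kb$drugs$drug == d, , drop = FALSE],
      rows = rows
    )
  })
  names(sections) <- drug_index

  summary_table <- dplyr::bind_rows(lapply(sections, `[[`, "rows"))
  summary_table <- if (nrow(summary_table)) {
    summary_table[, c("drug", SUMMARY_COLS, "fda_labeled"), drop = FALSE]
  } else {
    empty_matches()[, c("drug", SUMMARY_COLS, "fda_labeled")]
  }

  fda_flags <- sort(unique(matches$drug[matches$fda_labeled]))

  structure(
    list(sample_id = sample_id, drug_index = drug_index,
         sections = sections, summary_table = tibble::as_tibble(summary_table),
         fda_flags = fda_flags, index_by = index_by),
    class = "pgx_report"
  )
}

#' @export
print.pgx_report <- function(x, ...) {
  cat(sprintf("<pgx_report> sample %s: %d drug(s), %d matched row(s), %d FDA-flagged\n",
              x$sample_id, length(x$drug_index), nrow(x$summary_table),
              length(x$fda_flags)))
  invisible(x)
}

#' @method tidy pgx_report
#' @export
tidy.pgx_report <- function(x, ...) x$summary_table

#' @method glance pgx_report
#' @export
glance.pgx_report <- function(x, ...) {
  tibble::tibble(
    sample_id = x$sample_id,
    n_drugs = length(x$drug_index),
    n_matches = nrow(x$summary_table),
    n_fda_drugs = length(x$fda_flags)
  )
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

drug_anchor <- function(drug) {
  paste0("drug-", gsub("[^a-z0-9]+", "-", tolower(drug)))
}

# the summary/section table in either narrow (aspect, direction) or wide
# (efficacy/dosage/toxicity) layout
report_table <- function(rows, wide) {
  tab <- rows[, c(SUMMARY_COLS), drop = FALSE]
  if (!wide) return(tab)
  base <- tab |>
    dplyr::select("rsid", "evidence", "gene", "genotype", "description")
  eff <- tab |>
    dplyr::mutate(value = .data$direction) |>
    dplyr::select("rsid", "evidence", "gene", "genotype", "description",
                  "aspect", "value") |>
    tidyr::pivot_wider(names_from = "aspect", values_from = "value",
                       values_fill = "")
  for (a in KB_ASPECTS) if (!a %in% names(eff)) eff[[a]] <- ""
  eff[, c("rsid", "evidence", "gene", "genotype", KB_ASPECTS,
          "description"), drop = FALSE]
}

#' Render an individual report to HTML or Markdown
#'
#' The HTML report reproduces the navigable structure of the on-screen
#' original: every index entry is an intra-document link to its drug
#' section, FDA biomarker-labeled drugs carry a highlight marker, and the
#' flat summary table closes the document. Rendering is deterministic:
#' identical reports yield byte-identical files.
#'
#' @param report A `pgx_report` from [build_report()].
#' @param path Output file path.
#' @param format `"html"` or `"markdown"`.
#' @param wide Use the three sparse efficacy/dosage/toxicity columns instead
#'   of the compact aspect/direction pair (default `FALSE`).
#' @return `path`, invisibly.
#' @export
render_report <- function(report, path, format = c("html", "markdown"),
                          wide = FALSE) {
  stopifnot(inherits(report, "pgx_report"))
  format <- match.arg(format)
  lines <- if (format == "html") {
    render_report_html(report, wide)
  } else {
    render_report_markdown(report, wide)
  }
  writeLines(lines, path)
  invisible(path)
}

html_table <- function(tab) {
  header <- paste0("<tr>", paste0("<th>", html_escape(names(tab)), "</th>",
                                  collapse = ""), "</tr>")
  body <- apply(tab, 1L, function(r) {
    paste0("<tr>", paste0("<td>", html_escape(as.character(r)), "</td>",
                          collapse = ""), "</tr>")
  })
  c('<table border="1">', header, body, "</table>")
}

render_report_html <- function(report, wide) {
  fda_mark <- function(d) if (d %in% report$fda_flags)
    ' <span class="fda" title="FDA pharmacogenomic biomarker label">[FDA]</span>' else ""

  index <- unlist(lapply(report$drug_index, function(d) {
    sprintf('<li><a href="#%s">%s</a>%s</li>',
            drug_anchor(d), html_escape(d), fda_mark(d))
  }))
  if (report$index_by == "category") {
    cats <- lapply(report$drug_index, function(d) {
      cc <- unlist(report$sections[[d]]$drug_info$categories)
      if (length(cc) == 0L) cc <- "(uncategorized)"
      tibble::tibble(category = cc, drug = d)
    })
    cats <- dplyr::bind_rows(cats) |> dplyr::arrange(.data$category,
                                                     .data$drug)
    index <- unlist(lapply(split(cats, cats$category), function(g) {
      c(sprintf("<li>%s<ul>", html_escape(g$category[1])),
        sprintf('<li><a href="#%s">%s</a>%s</li>',
                drug_anchor(g$drug), html_escape(g$drug),
                vapply(g$drug, fda_mark, "")),
        "</ul></li>")
    }))
  }

  sections <- unlist(lapply(report$drug_index, function(d) {
    sec <- report$sections[[d]]
    info <- sec$drug_info
    c(sprintf('<h2 id="%s">%s%s</h2>', drug_anchor(d), html_escape(d),
              fda_mark(d)),
      sprintf("<p><em>%s</em></p>",
              html_escape(paste(unlist(info$categories), collapse = "; "))),
      sprintf("<p>%s</p>", html_escape(info$description)),
      html_table(report_table(sec$rows, wide)))
  }))

  no_findings <- if (length(report$drug_index) == 0L) {
    "<p>No drug-response variants matched the knowledge base.</p>"
  }

  c("<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\">",
    sprintf("<title>Drug-response report: %s</title>",
            html_escape(report$sample_id)),
    "<style>.fda{background:#ffe08a;font-weight:bold;}</style>",
    "</head><body>",
    sprintf("<h1>Drug-response report: %s</h1>",
            html_escape(report$sample_id)),
    "<h2>Drug index</h2>",
    "<ul>", index, "</ul>",
    no_findings,
    sections,
    '<h2 id="summary">Summary table</h2>',
    if (nrow(report$summary_table))
      html_table(report_table(report$summary_table, wide))
    else "<p>No findings.</p>",
    "</body></html>")
}

md_table <- function(tab) {
  esc <- function(x) gsub("|", "\\|", x, fixed = TRUE)
  c(paste0("| ", paste(esc(names(tab)), collapse = " | "), " |"),
    paste0("|", paste(rep("---", ncol(tab)), collapse = "|"), "|"),
    apply(tab, 1L, function(r) {
      paste0("| ", paste(esc(as.character(r)), collapse = " | "), " |")
    }))
}

render_report_markdown <- function(report, wide) {
  fda_mark <- function(d) if (d %in% report$fda_flags) " **[FDA]**" else ""
  index <- vapply(report$drug_index, function(d) {
    sprintf("- [%s](#%s)%s", d, drug_anchor(d), fda_mark(d))
  }, "")
  sections <- unlist(lapply(report$drug_index, function(d) {
    sec <- report$sections[[d]]
    c(sprintf('## %s%s {#%s}', d, fda_mark(d), drug_anchor(d)),
      "",
      paste0("*", paste(unlist(sec$drug_info$categories), collapse = "; "),
             "*"),
      "",
      sec$drug_info$description,
      "",
      md_table(report_table(sec$rows, wide)),
      "")
  }))
  c(sprintf("# Drug-response report: %s", report$sample_id),
    "",
    "## Drug index",
    "",
    if (length(index)) index else "No drug-response variants matched the knowledge base.",
    "",
    sections,
    "## Summary table",
    "",
    if (nrow(report$summary_table))
      md_table(report_table(report$summary_table, wide))
    else "No findings.")
}
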