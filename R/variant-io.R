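#' Canonicalize a diploid genotype
#'
#' Diploid genotypes are unordered allele pairs; the canonical string form is
#' uppercase and lexicographically sorted, so `("G","A")`, `("A","G")` and a
#' VCF `1|0` against REF=G/ALT=A all compare equal as `"AG"`.
#'
#' @param a1,a2 Allele characters (`A`, `C`, `G` or `T`; case-insensitive).
#'   Vectors are recycled to common length.
#' @return Character vector of sorted 2-character genotype strings.
#' @examples
#' canonical_genotype("G", "A") # "AG"
#' canonical_genotype("c", "C") # "CC"
#' @export
canonical_genotype <- function(a1, a2) {
  a1 <- toupper(as.character(a1))
  a2 <- toupper(as.character(a2))
  bad <- !(a1 %in% BASES) | !(a2 %in% BASES)
  if (any(bad)) {
    stop_pgx(paste0("alleles must be one of A, C, G, T; got: ",
                    paste(unique(c(a1[bad], a2[bad])), collapse = ", ")),
             class = "pgx_allele_error")
  }
  ifelse(a1 <= a2, paste0(a1, a2), paste0(a2, a1))
}

#' Resolve a VCF GT field to a canonical genotype
#'
#' Maps the numeric allele indexes of a VCF `GT` value onto the record's REF
#' and ALT alleles and canonicalizes the result. The phase separator (`/` or
#' `|`) is ignored; haploid calls (e.g. chrX in males) are duplicated to a
#' homozygous diploid representation; `.`, `./.` and `.|.` give `NA`
#' (missing).
#'
#' @param ref Single REF allele.
#' @param alts Character vector of ALT alleles (possibly empty).
#' @param gt_field GT string such as `"0/1"`, `"1|1"`, `"."` or `"0"`.
#' @return A canonical genotype string, or `NA_character_` for a no-call.
#' @examples
#' resolve_vcf_genotype("G", "A", "0/1") # "AG"
#' resolve_vcf_genotype("C", "T", "./.") # NA
#' @export
resolve_vcf_genotype <- function(ref, alts, gt_field) {
  if (is.na(gt_field)) return(NA_character_)
  gt <- strsplit(gt_field, ":", fixed = TRUE)[[1]][1]
  idx <- strsplit(gt, "[/|]")[[1]]
  if (length(idx) == 0L || all(idx == ".")) return(NA_character_)
  if (any(idx == ".")) return(NA_character_) # half-missing treated as no-call
  idx <- suppressWarnings(as.integer(idx))
  if (anyNA(idx)) {
    stop_pgx(paste0("malformed GT field: ", gt_field),
             class = "pgx_record_error")
  }
  if (length(idx) == 1L) idx <- c(idx, idx)
  if (length(idx) != 2L) {
    stop_pgx(paste0("GT field is not diploid: ", gt_field),
             class = "pgx_record_error")
  }
  alleles <- c(ref, alts)
  if (any(idx + 1L > length(alleles)) || any(idx < 0L)) {
    stop_pgx(sprintf("GT index out of allele range: %s (REF=%s ALT=%s)",
                     gt_field, ref, paste(alts, collapse = ",")),
             class = "pgx_record_error")
  }
  canonical_genotype(alleles[idx[1] + 1L], alleles[idx[2] + 1L])
}

new_calls <- function(sample_id = character(), rsid = character(),
                      chrom = character(), pos = integer(),
                      genotype = character(), source = character()) {
  tibble::tibble(sample_id = sample_id, rsid = rsid, chrom = chrom,
                 pos = as.integer(pos), genotype = genotype, source = source)
}

#' Read per-sample genotype calls from a VCF v4.2 file
#'
#' Converts the biallelic SNV records of a (possibly multi-sample,
#' optionally gzip-compressed) VCF into a normalized long call table: one row
#' per sample per usable record. Records are skipped — with a summarizing
#' message — when they fail FILTER (anything other than `PASS` or `.`), are
#' multi-allelic, or are not simple A/C/G/T SNVs; the per-category skip
#' counts are attached as the `"skipped"` attribute.
#'
#' @param path Path to a VCF file (plain or gzipped).
#' @return Tibble with columns `sample_id`, `rsid` (`NA` when the ID column
#'   is `.`), `chrom` (normalized), `pos`, `genotype` (canonical or `NA` for
#'   no-calls) and `source` (`"vcf"`). Samples with zero usable records are
#'   recorded in the `"samples"` attribute.
#' @examples
#' vcf <- system.file("extdata", "example.vcf", package = "pgxkit")
#' read_vcf_genotypes(vcf)
#' @export
read_vcf_genotypes <- function(path) {
  if (!file.exists(path)) {
    stop_pgx(paste0("VCF file not found: ", path), class = "pgx_io_error")
  }
  header <- read_text_lines(path, n = 1000L)
  if (!any(grepl("^##fileformat=VCF", header))) {
    stop_pgx(paste0(path, ": missing ##fileformat=VCF header"),
             class = "pgx_format_error")
  }
  chrom_line <- grep("^#CHROM\t", header, value = TRUE)
  if (length(chrom_line) == 0L) {
    # header may extend past the probe window; scan the whole file
    chrom_line <- grep("^#CHROM\t", read_text_lines(path), value = TRUE)
  }
  if (length(chrom_line) == 0L) {
    stop_pgx(paste0(path, ": missing #CHROM header line"),
             class = "pgx_format_error")
  }
  cols <- strsplit(chrom_line[1], "\t", fixed = TRUE)[[1]]
  if (length(cols) < 10L) {
    stop_pgx(paste0(path, ": #CHROM line lists no sample columns"),
             class = "pgx_format_error")
  }
  samples <- cols[-(1:9)]

  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- v@fix
  gt <- v@gt
  skipped <- c(filtered = 0L, multiallelic = 0L, non_snv = 0L)

  calls <- new_calls()
  if (nrow(fix) > 0L) {
    filt <- fix[, "FILTER"]
    keep_filter <- is.na(filt) | filt == "PASS" | filt == "."
    skipped["filtered"] <- sum(!keep_filter)
    alt <- fix[, "ALT"]
    multi <- !is.na(alt) & grepl(",", alt, fixed = TRUE)
    skipped["multiallelic"] <- sum(multi & keep_filter)
    snv <- !is.na(alt) & fix[, "REF"] %in% BASES & alt %in% BASES
    skipped["non_snv"] <- sum(!snv & !multi & keep_filter)
    keep <- keep_filter & !multi & snv
    if (any(keep)) {
      fixk <- fix[keep, , drop = FALSE]
      gtk <- gt[keep, -1, drop = FALSE] # drop FORMAT column
      line_no <- which(keep)
      per_sample <- lapply(samples, function(s) {
        geno <- vapply(seq_len(nrow(fixk)), function(i) {
          tryCatch(
            resolve_vcf_genotype(fixk[i, "REF"], fixk[i, "ALT"], gtk[i, s]),
            pgx_record_error = function(e) {
              stop_pgx(sprintf("%s, record %d (sample %s): %s",
                               path, line_no[i], s, conditionMessage(e)),
                       class = "pgx_record_error")
            }
          )
        }, character(1))
        new_calls(
          sample_id = rep(s, nrow(fixk)),
          rsid = unname(ifelse(is.na(fixk[, "ID"]) | fixk[, "ID"] == ".",
                               NA_character_, fixk[, "ID"])),
          chrom = unname(normalize_chrom(fixk[, "CHROM"])),
          pos = unname(as.integer(fixk[, "POS"])),
          genotype = unname(geno),
          source = "vcf"
        )
      })
      calls <- dplyr::bind_rows(per_sample)
    }
  }
  if (sum(skipped) > 0L) {
    rlang::inform(sprintf(
      "%s: skipped %d record(s) (%d failed FILTER, %d multi-allelic, %d non-SNV)",
      basename(path), sum(skipped), skipped[["filtered"]],
      skipped[["multiallelic"]], skipped[["non_snv"]]))
  }
  attr(calls, "samples") <- samples
  attr(calls, "skipped") <- skipped
  calls
}

# readLines that transparently handles gzip (by magic bytes, not extension)
read_text_lines <- function(path, n = -1L) {
  con <- gzfile(path, "rt") # gzfile reads plain text files unchanged
  on.exit(close(con))
  readLines(con, n = n, warn = FALSE)
}

ARRAY_NO_CALLS <- c("--", "00", "NN", "", "??", "-")

#' Consumer-array dialect definitions
#'
#' Column layouts for the four supported consumer-genotyping export
#' dialects. Each entry gives the delimiter, whether a header line is
#' expected, the comment prefix, and which columns carry rsid, chromosome,
#' position and genotype. The returned list can be modified and passed to
#' [read_array_genotypes()] via `config` to accommodate vendor layout
#' revisions.
#'
#' @return Named list of dialect definitions for `23andme`, `affymetrix`,
#'   `decodeme` and `ftdna`.
#' @export
array_dialects <- function() {
  list(
    `23andme` = list(
      delim = "\t", comment = "#", header = FALSE,
      col_names = c("rsid", "chromosome", "position", "genotype"),
      fields = c(rsid = "rsid", chrom = "chromosome", pos = "position",
                 genotype = "genotype")
    ),
    affymetrix = list(
      delim = "\t", comment = "#", header = TRUE,
      col_names = c("probeset_id", "chromosome", "position", "call"),
      fields = c(rsid = "probeset_id", chrom = "chromosome",
                 pos = "position", genotype = "call")
    ),
    decodeme = list(
      delim = ",", comment = "#", header = TRUE,
      col_names = c("Name", "Variation", "Chromosome", "Position", "Strand",
                    "YourCode"),
      fields = c(rsid = "Name", chrom = "Chromosome", pos = "Position",
                 genotype = "YourCode")
    ),
    ftdna = list(
      delim = ",", comment = "#", header = TRUE,
      col_names = c("RSID", "CHROMOSOME", "POSITION", "RESULT"),
      fields = c(rsid = "RSID", chrom = "CHROMOSOME", pos = "POSITION",
                 genotype = "RESULT")
    )
  )
}

#' Read genotype calls from a consumer-array export file
#'
#' Parses one of the four supported vendor dialects into the same normalized
#' call table as [read_vcf_genotypes()]. No-call tokens (`--`, `00`, `NN`,
#' empty) become missing genotypes; single-character hemizygous calls on
#' X/Y/MT are duplicated to a homozygous diploid representation; genotypes
#' containing non-ACGT characters (e.g. indel codes) are treated as missing.
#'
#' @param path Path to the export file (plain or gzipped).
#' @param dialect One of `"23andme"`, `"affymetrix"`, `"decodeme"`,
#'   `"ftdna"`.
#' @param sample_id Sample name; defaults to the file name without
#'   extension.
#' @param config Dialect definition list, defaulting to [array_dialects()];
#'   override to accept a vendor's revised column layout.
#' @return Tibble of calls (see [read_vcf_genotypes()] for columns), with the
#'   `"samples"` attribute set to `sample_id`.
#' @examples
#' f <- tempfile()
#' writeLines(c("# comment", "rs1042522\t17\t7579472\tCC"), f)
#' read_array_genotypes(f, "23andme", sample_id = "S1")
#' @export
read_array_genotypes <- function(path, dialect, sample_id = NULL,
                                 config = array_dialects()) {
  if (!dialect %in% names(config)) {
    stop_pgx(paste0("unknown dialect: ", dialect, " (expected one of ",
                    paste(names(config), collapse = ", "), ")"),
             class = "pgx_usage_error")
  }
  if (!file.exists(path)) {
    stop_pgx(paste0("genotype file not found: ", path),
             class = "pgx_io_error")
  }
  d <- config[[dialect]]
  sample_id <- sample_id %||% sub("\\.(txt|csv|tsv)(\\.gz)?$", "",
                                  basename(path))

  raw <- readr::read_delim(
    path, delim = d$delim, comment = d$comment,
    col_names = if (d$header) TRUE else d$col_names,
    col_types = readr::cols(.default = "c"),
    na = character(), progress = FALSE, trim_ws = TRUE
  )
  missing_cols <- setdiff(unname(d$fields), names(raw))
  if (length(missing_cols)) {
    stop_pgx(paste0(path, ": ", dialect, " layout expects column(s) ",
                    paste(missing_cols, collapse = ", "),
                    "; found: ", paste(names(raw), collapse = ", ")),
             class = "pgx_format_error")
  }
  if (nrow(raw) == 0L) {
    out <- new_calls()
    attr(out, "samples") <- sample_id
    return(out)
  }

  geno_raw <- toupper(raw[[d$fields[["genotype"]]]])
  geno <- ifelse(geno_raw %in% ARRAY_NO_CALLS, NA_character_, geno_raw)
  # hemizygous single-letter calls (X/Y/MT) -> homozygous diploid
  one <- !is.na(geno) & nchar(geno) == 1L
  geno[one] <- paste0(geno[one], geno[one])
  valid <- is.na(geno) | grepl("^[ACGT]{2}$", geno)
  geno[!valid] <- NA_character_ # indel and other non-SNV codes
  geno <- sort_genotype(geno)

  pos <- suppressWarnings(as.integer(raw[[d$fields[["pos"]]]]))
  bad <- which(is.na(pos))
  if (length(bad)) {
    stop_pgx(sprintf("%s: malformed position on data line %d", path, bad[1]),
             class = "pgx_format_error")
  }

  out <- new_calls(
    sample_id = rep(sample_id, nrow(raw)),
    rsid = ifelse(grepl("^rs[0-9]+$", raw[[d$fields[["rsid"]]]]),
                  raw[[d$fields[["rsid"]]]], NA_character_),
    chrom = normalize_chrom(raw[[d$fields[["chrom"]]]]),
    pos = pos,
    genotype = geno,
    source = dialect
  )
  attr(out, "samples") <- sample_id
  out
}

#' Write genotype calls as a consumer-array export file
#'
#' Inverse of [read_array_genotypes()] for a single sample; used by the
#' cohort simulator and the cross-dialect equivalence tests.
#'
#' @param calls Call tibble for one sample.
#' @param path Output path.
#' @inheritParams read_array_genotypes
#' @return `path`, invisibly.
#' @export
write_array_genotypes <- function(calls, path, dialect,
                                  config = array_dialects()) {
  if (!dialect %in% names(config)) {
    stop_pgx(paste0("unknown dialect: ", dialect), class = "pgx_usage_error")
  }
  if (length(unique(calls$sample_id)) > 1L) {
    stop_pgx("array files hold one sample; got several sample_ids",
             class = "pgx_usage_error")
  }
  d <- config[[dialect]]
  tab <- as.data.frame(
    setNames(rep(list(rep("", nrow(calls))), length(d$col_names)),
             d$col_names),
    check.names = FALSE
  )
  tab[[d$fields[["rsid"]]]] <- ifelse(is.na(calls$rsid), "", calls$rsid)
  tab[[d$fields[["chrom"]]]] <- calls$chrom
  tab[[d$fields[["pos"]]]] <- as.character(calls$pos)
  tab[[d$fields[["genotype"]]]] <-
    ifelse(is.na(calls$genotype), "--", calls$genotype)
  if ("Strand" %in% d$col_names) tab[["Strand"]] <- "+"
  lines <- c(
    if (!d$header) paste0("# ", paste(d$col_names, collapse = d$delim)),
    if (d$header) paste(d$col_names, collapse = d$delim),
    apply(tab, 1L, paste, collapse = d$delim)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write genotype calls as a multi-sample VCF v4.2 file
#'
#' Inverse of [read_vcf_genotypes()]: pivots a long call table into one VCF
#' record per site with a GT column per sample. REF is the alphabetically
#' first allele observed at the site; for a monomorphic site a placeholder
#' ALT allele (never referenced by any GT) is emitted so the record remains
#' a well-formed biallelic SNV.
#'
#' @param calls Call tibble (one or more samples).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf_genotypes <- function(calls, path) {
  samples <- attr(calls, "samples") %||% unique(calls$sample_id)
  sites <- calls |>
    dplyr::distinct(.data$rsid, .data$chrom, .data$pos) |>
    dplyr::arrange(.data$chrom, .data$pos)

  gt_of <- function(geno, ref, alt) {
    if (is.na(geno)) return("./.")
    idx <- match(strsplit(geno, "")[[1]], c(ref, alt)) - 1L
    paste(sort(idx), collapse = "/")
  }

  records <- vapply(seq_len(nrow(sites)), function(i) {
    site_calls <- calls[!is.na(calls$pos) & calls$pos == sites$pos[i] &
                          calls$chrom == sites$chrom[i], ]
    alleles <- sort(unique(unlist(strsplit(
      site_calls$genotype[!is.na(site_calls$genotype)], ""))))
    if (length(alleles) > 2L) {
      stop_pgx(sprintf("site %s:%d has >2 alleles; VCF writer is biallelic",
                       sites$chrom[i], sites$pos[i]),
               class = "pgx_usage_error")
    }
    if (length(alleles) == 0L) alleles <- c("A") # all-missing site
    ref <- alleles[1]
    alt <- if (length(alleles) >= 2L) alleles[2] else setdiff(BASES, ref)[1]
    geno <- site_calls$genotype[match(samples, site_calls$sample_id)]
    paste(c(sites$chrom[i], sites$pos[i],
            ifelse(is.na(sites$rsid[i]), ".", sites$rsid[i]),
            ref, alt, ".", "PASS", ".", "GT",
            vapply(geno, gt_of, "", ref = ref, alt = alt)),
          collapse = "\t")
  }, character(1))

  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=pgxkit",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records
  ), path)
  invisible(path)
}
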