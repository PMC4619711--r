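# Independent oracles used across the suite. These deliberately avoid the
# code paths of the functions they check: the annotation oracle is an
# exhaustive per-call scan over every annotation row (no join, no index),
# and the GT mapper resolves VCF genotype fields character by character.

# brute-force (call x annotation) exhaustive scan
oracle_annotate <- function(calls, kb, min_evidence = NULL) {
  ann <- as.data.frame(kb$annotations)
  keep_rank <- if (is.null(min_evidence)) 6L else
    match(min_evidence, c("1A", "1B", "2A", "2B", "3", "4"))
  ann_rank <- match(ann$evidence, c("1A", "1B", "2A", "2B", "3", "4"))
  ci <- integer(0)
  aj <- integer(0)
  for (i in seq_len(nrow(calls))) {
    g <- calls$genotype[i]
    if (is.na(g)) next
    if (is.na(calls$rsid[i])) {
      hits <- which(ann$chrom == calls$chrom[i] & ann$pos == calls$pos[i] &
                      ann$genotype == g & ann_rank <= keep_rank)
    } else {
      hits <- which(ann$rsid == calls$rsid[i] & ann$genotype == g &
                      ann_rank <= keep_rank)
    }
    ci <- c(ci, rep(i, length(hits)))
    aj <- c(aj, hits)
  }
  if (length(ci) == 0L) {
    out <- data.frame(sample_id = character(), rsid = character(),
                      gene = character(), genotype = character(),
                      drug = character(), aspect = character(),
                      direction = character(), evidence = character(),
                      fda_labeled = logical(), description = character())
    return(out)
  }
  out <- data.frame(
    sample_id = calls$sample_id[ci], rsid = ann$rsid[aj],
    gene = ann$gene[aj], genotype = ann$genotype[aj], drug = ann$drug[aj],
    aspect = ann$aspect[aj], direction = ann$direction[aj],
    evidence = ann$evidence[aj], fda_labeled = ann$fda_labeled[aj],
    description = ann$description[aj]
  )
  sample_order <- unique(calls$sample_id)
  rank <- match(out$evidence, c("1A", "1B", "2A", "2B", "3", "4"))
  out <- out[order(match(out$sample_id, sample_order), out$drug, rank,
                   out$rsid, out$aspect), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# character-by-character GT resolver, independent of resolve_vcf_genotype()
naive_gt_mapper <- function(ref, alts, gt) {
  parts <- character(0)
  cur <- ""
  for (ch in strsplit(gt, "")[[1]]) {
    if (ch %in% c("/", "|")) {
      parts <- c(parts, cur); cur <- ""
    } else cur <- paste0(cur, ch)
  }
  parts <- c(parts, cur)
  if (any(parts == ".")) return(NA_character_)
  idx <- as.integer(parts)
  if (length(idx) == 1L) idx <- rep(idx, 2L)
  pool <- c(ref, alts)
  a <- pool[idx + 1L]
  paste(sort(a), collapse = "")
}

# matches tibble -> comparable plain data frame (drops attributes)
as_plain <- function(x) {
  out <- as.data.frame(x)
  attr(out, "samples") <- NULL
  rownames(out) <- NULL
  out
}

make_calls <- function(sample_id, rsid, genotype, chrom = "1",
                       pos = seq_along(rsid), source = "test") {
  tibble::tibble(sample_id = sample_id, rsid = rsid,
                 chrom = rep_len(chrom, length(rsid)),
                 pos = as.integer(rep_len(pos, length(rsid))),
                 genotype = genotype,
                 source = rep_len(source, length(rsid)))
}

# a tiny valid KB built directly (not via mini_kb) for edge-case tests
toy_kb <- function(ann_extra = NULL) {
  ann <- tibble::tibble(
    rsid = c("rs1", "rs1", "rs2"),
    gene = c("G1", "G1", "G2"),
    chrom = c("1", "1", "2"),
    pos = c(100L, 100L, 200L),
    genotype = c("AA", "AG", "CC"),
    drug = c("drugA", "drugA", "drugB"),
    aspect = c("toxicity", "efficacy", "dosage"),
    direction = c("increase", "decrease", "decrease"),
    evidence = c("1A", "2B", "3"),
    fda_labeled = c(TRUE, FALSE, FALSE),
    description = "toy"
  )
  if (!is.null(ann_extra)) ann <- dplyr::bind_rows(ann, ann_extra)
  drugs <- tibble::tibble(
    drug = c("drugA", "drugB"),
    external_id = c("X1", "X2"),
    categories = c("CatA;CatB", "CatB"),
    description = c("Drug A.", "Drug B.")
  )
  pgx_kb(ann, drugs)
}

# canonical form of genotype strings, independent of package internals
sort_genotypes_oracle <- function(g) {
  vapply(g, function(x) {
    if (is.na(x)) return(NA_character_)
    paste(sort(strsplit(x, "")[[1]]), collapse = "")
  }, "", USE.NAMES = FALSE)
}

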