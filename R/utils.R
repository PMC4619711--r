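BASES <- c("A", "C", "G", "T")

#' Normalize a chromosome name
#'
#' Strips a leading `"chr"` prefix and unifies the mitochondrial names `"M"`
#' and `"MT"` to `"MT"`, so that inputs mixing UCSC- and Ensembl-style names
#' compare equal.
#'
#' @param chrom Character vector of chromosome names.
#' @return Character vector of normalized names.
#' @examples
#' normalize_chrom(c("chr17", "M", "MT", "X"))
#' @export
normalize_chrom <- function(chrom) {
  out <- sub("^chr", "", as.character(chrom), ignore.case = TRUE)
  out[out %in% c("M", "m")] <- "MT"
  toupper(out)
}

is_canonical_genotype <- function(g) {
  ok <- !is.na(g) & nchar(g) == 2L
  a1 <- substr(g, 1L, 1L)
  a2 <- substr(g, 2L, 2L)
  ok & a1 %in% BASES & a2 %in% BASES & a1 <= a2
}

# sort the two characters of each diploid genotype string; NA passes through
sort_genotype <- function(g) {
  out <- toupper(as.character(g))
  idx <- which(!is.na(out))
  if (length(idx)) {
    a1 <- substr(out[idx], 1L, 1L)
    a2 <- substr(out[idx], 2L, 2L)
    swap <- a1 > a2
    out[idx][swap] <- paste0(a2[swap], a1[swap])
  }
  out
}

stop_pgx <- function(msg, class = "pgx_error") {
  rlang::abort(msg, class = class)
}
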