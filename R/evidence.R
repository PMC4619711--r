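#' PharmGKB-style clinical evidence levels
#'
#' Variant-drug associations are graded on the six-tier clinical-annotation
#' scale used by PharmGKB: `1A` (strongest; variant-specific prescribing
#' guidance) down to `4` (weakest; case reports or in-vitro only). The total
#' order by decreasing strength is `1A < 1B < 2A < 2B < 3 < 4`.
#'
#' @return Character vector of the six level codes, strongest first.
#' @examples
#' evidence_levels()
#' evidence_rank(c("1A", "4"))
#' @export
evidence_levels <- function() c("1A", "1B", "2A", "2B", "3", "4")

#' @rdname evidence_levels
#' @param code Character vector of evidence level codes.
#' @return `evidence_rank()`: integer rank 1..6, 1 = strongest (`1A`).
#'   Any code outside the six-tier scale is an error.
#' @export
evidence_rank <- function(code) {
  rank <- match(as.character(code), evidence_levels())
  bad <- is.na(rank) & !is.na(code)
  if (any(bad)) {
    stop_pgx(sprintf(
      "invalid evidence level(s): %s (must be one of %s)",
      paste(unique(code[bad]), collapse = ", "),
      paste(evidence_levels(), collapse = ", ")
    ), class = "pgx_evidence_error")
  }
  if (any(is.na(code))) {
    stop_pgx("evidence level may not be NA", class = "pgx_evidence_error")
  }
  rank
}

#' Test whether evidence meets a minimum strength
#'
#' @param code Character vector of evidence codes to test.
#' @param min_evidence Single evidence code; `NULL` accepts every level.
#' @return Logical vector: `TRUE` where `code` is at least as strong
#'   (equal or lower rank) as `min_evidence`.
#' @examples
#' evidence_at_least(c("1A", "3"), "2B")
#' @export
evidence_at_least <- function(code, min_evidence = NULL) {
  if (is.null(min_evidence)) {
    return(rep(TRUE, length(code)))
  }
  evidence_rank(code) <= evidence_rank(min_evidence)
}
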