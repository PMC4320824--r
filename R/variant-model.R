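#' Classify a variant by its REF/ALT lengths
#'
#' SNP when both alleles are single bases; insertion when ALT is longer than
#' REF; deletion when REF is longer. Equal-length multi-base substitutions
#' (which the upstream short-variant caller does not emit) are labelled
#' `COMPLEX`; they are carried through the table but excluded from SNP/Ins/Del
#' tallies and from the substitution spectrum.
#'
#' @param ref,alt Character vectors of REF and ALT alleles (non-empty, not
#'   identical element-wise).
#' @return Character vector with elements in
#'   `c("SNP", "INS", "DEL", "COMPLEX")`.
#' @examples
#' classify_variant_type(c("A", "A", "AT"), c("G", "AT", "A"))
#' @export
classify_variant_type <- function(ref, alt) {
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  if (any(!nzchar(ref)) || any(!nzchar(alt))) {
    abort("ref and alt must be non-empty")
  }
  if (any(ref == alt)) {
    abort("ref == alt is not a variant")
  }
  if (any(grepl("[^ACGTN]", c(ref, alt)))) {
    abort("ref/alt must be DNA strings (A/C/G/T/N)")
  }
  lr <- nchar(ref)
  la <- nchar(alt)
  dplyr::case_when(
    lr == 1 & la == 1 ~ "SNP",
    la > lr ~ "INS",
    lr > la ~ "DEL",
    .default = "COMPLEX"
  )
}

#' Build the multi-line variant table
#'
#' Lists all variants from all lines according to their genomic positions:
#' the union of sites keyed by (chrom, pos, ref, alt), with per-line presence
#' recorded as one row per carrying line. This long table is the substrate
#' for filtration and sharing classification.
#'
#' @param calls A call tibble covering one or more lines (rows as returned by
#'   [read_vcf_calls()], with a `line_id` column), or a list of such tibbles.
#' @param line_ids Optional canonical line order (e.g. transgenic lines first).
#'   Defaults to order of first appearance.
#' @return The combined call tibble, sorted by position, with attribute
#'   `line_ids`. Duplicate (line, chrom, pos, ref, alt) rows are an input
#'   error.
#' @seealso [cohort_lines()], [n_sites()]
#' @export
build_multiline_table <- function(calls, line_ids = NULL) {
  if (is.list(calls) && !is.data.frame(calls)) {
    calls <- bind_rows(calls)
  }
  calls <- as_tibble(calls)
  if (is.null(line_ids)) {
    line_ids <- unique(calls$line_id)
  } else if (nrow(calls) > 0 && !all(calls$line_id %in% line_ids)) {
    abort("calls contain line_id values not listed in line_ids")
  }
  if (anyDuplicated(line_ids)) {
    abort("line_ids must be unique")
  }
  key <- paste(calls$line_id, calls$chrom, calls$pos, calls$ref, calls$alt)
  if (anyDuplicated(key)) {
    abort("duplicate (line, chrom, pos, ref, alt) call in input")
  }
  calls <- arrange(calls, .data$chrom, .data$pos, .data$ref, .data$alt,
                   match(.data$line_id, line_ids))
  attr(calls, "line_ids") <- line_ids
  calls
}

#' Line identifiers of a multi-line table
#'
#' @param calls A table built by [build_multiline_table()] (falls back to the
#'   distinct `line_id` values for plain call tibbles).
#' @return Character vector of line ids in canonical order.
#' @export
cohort_lines <- function(calls) {
  ids <- attr(calls, "line_ids")
  if (is.null(ids)) unique(calls$line_id) else ids
}

#' Number of distinct variant sites in a call table
#'
#' A site is a distinct (chrom, pos, ref, alt) tuple, regardless of how many
#' lines carry it.
#'
#' @param calls A call tibble.
#' @return Integer site count.
#' @export
n_sites <- function(calls) {
  nrow(distinct(as_tibble(calls)[, c("chrom", "pos", "ref", "alt")]))
}
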