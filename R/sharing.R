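#' Classify variants by line-sharing pattern
#'
#' Every surviving site is assigned to exactly one of the `2^n - 1` presence
#' patterns over the cohort's lines: line-specific, shared by a particular
#' subset of lines, or common to all lines. "Shared" requires identity of the
#' full (chrom, pos, ref, alt) tuple — same position and same alteration;
#' different ALT alleles at one position are distinct, unshared sites.
#'
#' @param calls A filtered call tibble (all lines).
#' @param line_ids Canonical line order used for the pattern encoding
#'   (defaults to [cohort_lines()]).
#' @return A tibble of class `sharing_profile` with one row per observed
#'   pattern: `pattern` (a 0/1 string over `line_ids`), `lines`
#'   (`"+"`-separated carrier ids), `n_lines` (carrier count) and
#'   `n_variants`. Counts sum to [n_sites()] of the input.
#' @examples
#' calls <- build_multiline_table(tibble::tibble(
#'   line_id = c("A", "B", "B"), chrom = "chr1", pos = c(10, 10, 20),
#'   ref = "A", alt = "G", var_type = "SNP", qual = 60, depth = 20))
#' classify_sharing(calls)
#' @export
classify_sharing <- function(calls, line_ids = cohort_lines(calls)) {
  calls <- as_tibble(calls)
  if (nrow(calls) == 0) {
    out <- tibble(pattern = character(0), lines = character(0),
                  n_lines = integer(0), n_variants = integer(0))
  } else {
    if (!all(calls$line_id %in% line_ids)) {
      abort("calls contain line_id values not listed in line_ids")
    }
    out <- calls |>
      group_by(.data$chrom, .data$pos, .data$ref, .data$alt) |>
      summarise(pattern = paste(as.integer(line_ids %in% .data$line_id),
                                collapse = ""),
                n_lines = dplyr::n_distinct(.data$line_id),
                .groups = "drop") |>
      count(.data$pattern, .data$n_lines, name = "n_variants") |>
      mutate(lines = purrr::map_chr(strsplit(.data$pattern, ""), function(b) {
        paste(line_ids[b == "1"], collapse = "+")
      })) |>
      select("pattern", "lines", "n_lines", "n_variants") |>
      arrange(dplyr::desc(.data$n_lines == 1), .data$n_lines, .data$pattern)
  }
  attr(out, "line_ids") <- line_ids
  class(out) <- c("sharing_profile", class(out))
  out
}

#' Extract a line's line-specific (private) variants
#'
#' A line-specific variant is present in exactly one line of the cohort —
#' i.e. not shared by any other line at the same position with the same
#' alteration.
#'
#' @param calls A filtered call tibble (all lines).
#' @param line_id The line of interest; `NULL` returns the line-specific
#'   variants of every line.
#' @param line_ids Cohort lines (defaults to [cohort_lines()]).
#' @return A tibble of the private calls (same columns as the input).
#' @export
line_specific_variants <- function(calls, line_id = NULL,
                                   line_ids = cohort_lines(calls)) {
  calls <- as_tibble(calls)
  if (!is.null(line_id) && !(line_id %in% line_ids)) {
    abort(paste0("unknown line_id: ", line_id))
  }
  if (nrow(calls) == 0) {
    return(calls)
  }
  private <- calls |>
    group_by(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    filter(dplyr::n_distinct(.data$line_id) == 1) |>
    ungroup()
  if (!is.null(line_id)) {
    private <- filter(private, .data$line_id == .env$line_id)
  }
  private
}

#' Per-line tally of line-specific variants
#'
#' Counts each line's private insertions, deletions and SNPs (complex records
#' are excluded from the three type tallies but reported), and, when per-line
#' covered lengths are supplied, the per-site mutation rate
#' `n_line_specific / covered_length`.
#'
#' @param calls A filtered call tibble (all lines).
#' @param line_ids Cohort lines (defaults to [cohort_lines()]).
#' @param covered_lengths Optional named numeric vector (bp covered by at
#'   least one read, per line).
#' @return A tibble with one row per line: `line_id`, `n_line_specific`,
#'   `n_ins`, `n_del`, `n_snp`, `n_complex`, and `covered_length` +
#'   `mutation_rate` when covered lengths are given.
#' @export
summarize_line_specific <- function(calls, line_ids = cohort_lines(calls),
                                    covered_lengths = NULL) {
  private <- line_specific_variants(calls, line_ids = line_ids)
  out <- tibble(line_id = line_ids) |>
    left_join(
      private |>
        group_by(.data$line_id) |>
        summarise(n_ins = sum(.data$var_type == "INS"),
                  n_del = sum(.data$var_type == "DEL"),
                  n_snp = sum(.data$var_type == "SNP"),
                  n_complex = sum(.data$var_type == "COMPLEX"),
                  .groups = "drop"),
      by = "line_id") |>
    mutate(across(c("n_ins", "n_del", "n_snp", "n_complex"),
                  ~ dplyr::coalesce(.x, 0L)),
           n_line_specific = .data$n_ins + .data$n_del + .data$n_snp) |>
    select("line_id", "n_line_specific", "n_ins", "n_del", "n_snp", "n_complex")
  if (!is.null(covered_lengths)) {
    missing_len <- setdiff(line_ids, names(covered_lengths))
    if (length(missing_len) > 0) {
      abort(paste0("no covered_length for line(s): ",
                   paste(missing_len, collapse = ", ")))
    }
    out$covered_length <- unname(covered_lengths[out$line_id])
    out$mutation_rate <- mutation_rate(out$n_line_specific, out$covered_length)
  }
  out
}
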