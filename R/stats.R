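# Per-line divergence and substitution-spectrum summaries.

#' Per-site mutation rate
#'
#' The number of line-specific variants divided by the line's covered length
#' (bases covered by at least one read) — a per-site divergence measure, not
#' a per-generation rate.
#'
#' @param n_line_specific Count(s) of line-specific variants (>= 0).
#' @param covered_length Covered length(s) in bp (> 0).
#' @return Numeric rate(s) per site, at full precision (display at 3
#'   significant digits is conventional).
#' @examples
#' mutation_rate(798, 371762264)  # ~2.15e-06
#' @export
mutation_rate <- function(n_line_specific, covered_length) {
  if (any(covered_length <= 0)) abort("covered_length must be > 0")
  if (any(n_line_specific < 0)) abort("n_line_specific must be >= 0")
  n_line_specific / covered_length
}

TS_PAIRS <- c("A>G", "G>A", "C>T", "T>C")
ALL_SUBS <- c("A>C", "A>G", "A>T", "C>A", "C>G", "C>T",
              "G>A", "G>C", "G>T", "T>A", "T>C", "T>G")

#' Classify single-base substitutions as transitions or transversions
#'
#' Purine-to-purine (A<->G) and pyrimidine-to-pyrimidine (C<->T) changes are
#' transitions; the other eight directed changes are transversions.
#'
#' @param ref,alt Single-base character vectors (A/C/G/T, `ref != alt`).
#' @return A tibble with columns `ref`, `alt`, `substitution` (e.g. `"G>T"`)
#'   and `class` (`"transition"` or `"transversion"`).
#' @examples
#' classify_substitution(c("G", "G"), c("A", "T"))
#' @export
classify_substitution <- function(ref, alt) {
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  if (any(!ref %in% c("A", "C", "G", "T")) || any(!alt %in% c("A", "C", "G", "T"))) {
    abort("ref and alt must be single bases in {A, C, G, T}")
  }
  if (any(ref == alt)) abort("ref == alt is not a substitution")
  sub <- paste0(ref, ">", alt)
  tibble(ref = ref, alt = alt, substitution = sub,
         class = if_else(sub %in% TS_PAIRS, "transition", "transversion"))
}

#' Substitution spectrum of a set of calls
#'
#' Tallies SNPs into the 12 directed substitution bins. Non-SNP calls
#' (insertions, deletions, complex records) are ignored with a single counted
#' warning.
#'
#' @param calls A call tibble (typically one line's line-specific variants,
#'   or a group's pooled variants).
#' @return A 12-row tibble of class `substitution_spectrum` with columns
#'   `substitution`, `class` and `n` (zero-filled), ordered A>C ... T>G.
#' @seealso [ts_tv_ratio()]
#' @export
substitution_spectrum <- function(calls) {
  calls <- as_tibble(calls)
  n_other <- sum(calls$var_type != "SNP")
  if (n_other > 0) {
    warn(paste0(n_other, " non-SNP call(s) ignored in substitution spectrum"))
  }
  snps <- filter(calls, .data$var_type == "SNP")
  base <- classify_substitution(c("A", "A", "A", "C", "C", "C",
                                  "G", "G", "G", "T", "T", "T"),
                                c("C", "G", "T", "A", "G", "T",
                                  "A", "C", "T", "A", "C", "G"))
  counts <- if (nrow(snps) == 0) {
    tibble(substitution = character(0), n = integer(0))
  } else {
    snps |>
      mutate(substitution = paste0(.data$ref, ">", .data$alt)) |>
      count(.data$substitution, name = "n")
  }
  out <- base |>
    select("substitution", "class") |>
    left_join(counts, by = "substitution") |>
    mutate(n = dplyr::coalesce(.data$n, 0L))
  class(out) <- c("substitution_spectrum", class(out))
  out
}

#' Transition/transversion ratio
#'
#' @param spectrum A `substitution_spectrum` tibble (or any tibble with
#'   `class` and `n` columns).
#' @return `ts / tv` as a single number; `NA` with a warning when the
#'   transversion count is zero (undefined ratio).
#' @examples
#' calls <- tibble::tibble(line_id = "A", chrom = "c", pos = 1:4,
#'                         ref = "G", alt = c("A", "A", "T", "T"),
#'                         var_type = "SNP", qual = 60, depth = 20)
#' ts_tv_ratio(substitution_spectrum(calls))
#' @export
ts_tv_ratio <- function(spectrum) {
  ts <- sum(spectrum$n[spectrum$class == "transition"])
  tv <- sum(spectrum$n[spectrum$class == "transversion"])
  if (tv == 0) {
    warn("transversion count is zero; Ts/Tv ratio undefined")
    return(NA_real_)
  }
  ts / tv
}

#' Alignment summary statistics
#'
#' Computes, per line, the mapping rate (mapped / total reads, as a
#' percentage), coverage rate (covered length / total genome length, as a
#' percentage) and mean depth (mapped reads x read length / covered length).
#'
#' @param summaries A tibble with columns `line_id`, `total_reads`,
#'   `mapped_reads`, `read_length` and `covered_length`.
#' @param genome A `genome_index` giving the total reference length.
#' @return The input tibble with `mapping_rate`, `coverage_rate` and `depth`
#'   columns appended (full precision; 1-decimal display is conventional).
#' @export
alignment_summary_stats <- function(summaries, genome) {
  summaries <- as_tibble(summaries)
  total_len <- genome_total_length(genome)
  if (any(summaries$total_reads <= 0) || any(summaries$covered_length <= 0) ||
      total_len <= 0) {
    abort("total_reads, covered_length and genome length must be positive")
  }
  if (any(summaries$mapped_reads > summaries$total_reads) ||
      any(summaries$mapped_reads < 0)) {
    abort("mapped_reads must lie in [0, total_reads]")
  }
  if (any(summaries$read_length <= 0)) abort("read_length must be positive")
  mutate(summaries,
         mapping_rate = .data$mapped_reads / .data$total_reads * 100,
         coverage_rate = .data$covered_length / total_len * 100,
         depth = .data$mapped_reads * .data$read_length / .data$covered_length)
}
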