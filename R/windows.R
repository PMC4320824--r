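# Windowed variant-density profiles: non-overlapping, consecutive windows
# anchored at position 1 of each chromosome; the final window may be partial
# and is reported as-is (no length normalization).

#' Per-line variant counts in consecutive genomic windows
#'
#' A variant at 1-based position `p` falls in window `floor((p - 1) / w)`
#' (reported 1-based as `window = floor((p - 1) / w) + 1`). The full window
#' grid is emitted for every line and chromosome, including empty windows, so
#' profiles from different lines always share the same grid.
#'
#' @param calls A call tibble.
#' @param genome A `genome_index`.
#' @param window_size Window width in bp (default 500 kbp).
#' @param line_ids Lines to profile (defaults to [cohort_lines()]).
#' @return A tibble with columns `line_id`, `chrom`, `window`, `start`,
#'   `end` and `n`.
#' @export
window_counts <- function(calls, genome, window_size = 500000,
                          line_ids = cohort_lines(calls)) {
  if (window_size < 1) abort("window_size must be >= 1")
  calls <- as_tibble(calls)
  grid <- window_grid(genome, window_size)
  full <- tidyr::expand_grid(line_id = line_ids, grid)
  if (nrow(calls) == 0) {
    return(mutate(full, n = 0L))
  }
  counted <- calls |>
    mutate(window = floor((.data$pos - 1) / window_size) + 1) |>
    count(.data$line_id, .data$chrom, .data$window, name = "n")
  full |>
    left_join(counted, by = c("line_id", "chrom", "window")) |>
    mutate(n = dplyr::coalesce(.data$n, 0L))
}

window_grid <- function(genome, window_size) {
  purrr::map2(genome$chrom, genome$length, function(ch, len) {
    k <- ceiling(len / window_size)
    tibble(chrom = ch, window = seq_len(k),
           start = (seq_len(k) - 1) * window_size + 1,
           end = pmin(seq_len(k) * window_size, len))
  }) |>
    bind_rows()
}

#' Group-averaged window profiles
#'
#' Element-wise arithmetic mean of the per-line window counts within each
#' group (e.g. transgenic lines vs wild-type lines).
#'
#' @param counts Output of [window_counts()].
#' @param groups Named list mapping group label to character vector of line
#'   ids; empty groups or groups naming unprofiled lines are an error.
#' @return A tibble with columns `group`, `chrom`, `window`, `start`, `end`,
#'   `mean_n`.
#' @export
group_mean_profile <- function(counts, groups) {
  if (length(groups) == 0 || is.null(names(groups))) {
    abort("groups must be a non-empty named list")
  }
  have <- unique(counts$line_id)
  purrr::imap(groups, function(lines, label) {
    if (length(lines) == 0) abort(paste0("group '", label, "' is empty"))
    missing_lines <- setdiff(lines, have)
    if (length(missing_lines) > 0) {
      abort(paste0("group '", label, "' names unprofiled line(s): ",
                   paste(missing_lines, collapse = ", ")))
    }
    counts |>
      filter(.data$line_id %in% lines) |>
      group_by(.data$chrom, .data$window, .data$start, .data$end) |>
      summarise(mean_n = mean(.data$n), .groups = "drop") |>
      mutate(group = label)
  }) |>
    bind_rows() |>
    select("group", "chrom", "window", "start", "end", "mean_n")
}

#' Maximum per-window group difference per chromosome
#'
#' For each chromosome, the maximum over windows of the absolute difference
#' between two groups' mean per-window variant counts.
#'
#' @param means Output of [group_mean_profile()] covering both groups.
#' @param group_a,group_b Group labels to contrast (symmetric).
#' @return A tibble with one row per chromosome: `chrom`, `max_diff`, and the
#'   `window`/`start`/`end` where the maximum is attained (first window on
#'   ties).
#' @export
max_window_difference <- function(means, group_a, group_b) {
  a <- filter(means, .data$group == group_a)
  b <- filter(means, .data$group == group_b)
  if (nrow(a) == 0 || nrow(b) == 0) {
    abort("both groups must be present in `means`")
  }
  j <- inner_join(a, b, by = c("chrom", "window", "start", "end"),
                  suffix = c("_a", "_b"))
  if (nrow(j) != nrow(a) || nrow(j) != nrow(b)) {
    abort("window grids of the two groups do not match")
  }
  j |>
    mutate(diff = abs(.data$mean_n_a - .data$mean_n_b)) |>
    group_by(.data$chrom) |>
    arrange(dplyr::desc(.data$diff), .data$window, .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup() |>
    select("chrom", max_diff = "diff", "window", "start", "end")
}
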