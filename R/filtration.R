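#' Filtration settings for a multi-line variant table
#'
#' Defaults follow the three-criterion scheme used for multi-line call-set
#' comparison: phred-scaled site quality of at least 30 (false-positive
#' probability <= 0.001), every position covered by at least four reads in
#' every line regardless of carrier status, cross-line alteration-type
#' consistency, plus the upstream exclusion of sites covered by an excessive
#' number of reads (more than 10,000; strictly greater).
#'
#' @param min_quality Minimum phred-scaled quality (inclusive).
#' @param min_reads_all_lines Minimum read depth required at the site in every
#'   line (inclusive).
#' @param max_site_depth Maximum site depth; calls with depth strictly greater
#'   are excluded.
#' @param require_type_consistency Apply the cross-line type-consistency
#'   criterion?
#' @param del_span_coverage For deletions, require the coverage criterion at
#'   every deleted base (strictest reading); `FALSE` tests the anchor base
#'   only.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_quality = 30, min_reads_all_lines = 4,
                          max_site_depth = 10000,
                          require_type_consistency = TRUE,
                          del_span_coverage = TRUE) {
  if (min_quality < 0) abort("min_quality must be >= 0")
  if (min_reads_all_lines < 1) abort("min_reads_all_lines must be >= 1")
  if (max_site_depth <= min_reads_all_lines) {
    abort("max_site_depth must exceed min_reads_all_lines")
  }
  structure(list(min_quality = min_quality,
                 min_reads_all_lines = min_reads_all_lines,
                 max_site_depth = max_site_depth,
                 require_type_consistency = isTRUE(require_type_consistency),
                 del_span_coverage = isTRUE(del_span_coverage)),
            class = "filter_config")
}

#' Remove calls covered by an excessive number of reads
#'
#' @param calls A call tibble.
#' @param config A [filter_config()]; calls with `depth > max_site_depth`
#'   (strict inequality) are removed.
#' @return The kept calls, with attribute `n_removed`.
#' @export
filter_excessive_depth <- function(calls, config = filter_config()) {
  keep <- calls$depth <= config$max_site_depth
  out <- calls[keep, , drop = FALSE]
  attr(out, "line_ids") <- attr(calls, "line_ids")
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Remove calls below the quality threshold
#'
#' Quality `>= min_quality` is retained (the threshold is inclusive); sites
#' left with no carrying line disappear from the table.
#'
#' @inheritParams filter_excessive_depth
#' @return The kept calls, with attribute `n_removed`.
#' @export
filter_quality <- function(calls, config = filter_config()) {
  keep <- calls$qual >= config$min_quality
  out <- calls[keep, , drop = FALSE]
  attr(out, "line_ids") <- attr(calls, "line_ids")
  attr(out, "n_removed") <- sum(!keep)
  out
}

# depth of one line's track at 1-based positions (0 where uncovered)
track_depth_at <- function(track, chrom, pos) {
  out <- numeric(length(pos))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    iv <- track[track$chrom == ch, , drop = FALSE]
    if (nrow(iv) == 0) next
    idx <- findInterval(pos[sel], iv$start)
    hit <- idx >= 1
    hit[hit] <- pos[sel][hit] <= iv$end[idx[hit]]
    d <- numeric(sum(sel))
    d[hit] <- iv$depth[idx[hit]]
    out[sel] <- d
  }
  out
}

#' Keep only sites covered in every line
#'
#' A site survives only if the read depth at its position is at least
#' `min_reads_all_lines` in every line of the cohort, including lines that do
#' not carry the variant. For deletions, every deleted base must meet the
#' threshold when `del_span_coverage` is set.
#'
#' @param calls A call tibble (all lines).
#' @param tracks A single tibble of coverage intervals for all lines (rows as
#'   from [read_coverage_track()]) or a list of per-line tracks.
#' @param config A [filter_config()].
#' @param line_ids Lines that make up the cohort; defaults to
#'   [cohort_lines()] of `calls`. A listed line without a track is a
#'   configuration error.
#' @return The kept calls, with attributes `n_removed` (calls) and
#'   `n_sites_removed`.
#' @export
filter_min_coverage_all_lines <- function(calls, tracks,
                                          config = filter_config(),
                                          line_ids = cohort_lines(calls)) {
  if (is.list(tracks) && !is.data.frame(tracks)) tracks <- bind_rows(tracks)
  missing_tracks <- setdiff(line_ids, unique(tracks$line_id))
  if (length(missing_tracks) > 0) {
    abort(paste0("no coverage track for line(s): ",
                 paste(missing_tracks, collapse = ", ")))
  }
  if (nrow(calls) == 0) {
    attr(calls, "n_removed") <- 0L
    attr(calls, "n_sites_removed") <- 0L
    return(calls)
  }
  sites <- distinct(as_tibble(calls)[, c("chrom", "pos", "ref", "alt", "var_type")])
  width <- ifelse(sites$var_type == "DEL" & config$del_span_coverage,
                  nchar(sites$ref), 1L)
  probe <- tibble(site = rep(seq_len(nrow(sites)), width),
                  chrom = rep(sites$chrom, width),
                  pos = sequence(width, from = sites$pos, by = 1))
  ok <- rep(TRUE, nrow(sites))
  for (ln in line_ids) {
    tr <- tracks[tracks$line_id == ln, , drop = FALSE]
    d <- track_depth_at(tr, probe$chrom, probe$pos)
    site_min <- tapply(d, probe$site, min)
    ok <- ok & (site_min >= config$min_reads_all_lines)
  }
  kept_sites <- sites[ok, c("chrom", "pos", "ref", "alt"), drop = FALSE]
  out <- semi_join(as_tibble(calls), kept_sites,
                   by = c("chrom", "pos", "ref", "alt"))
  attr(out, "line_ids") <- attr(calls, "line_ids")
  attr(out, "n_removed") <- nrow(calls) - nrow(out)
  attr(out, "n_sites_removed") <- sum(!ok)
  out
}

#' Remove positions with conflicting alteration types across lines
#'
#' If a variant of one type (say an SNP) is called at a position in one line
#' while a variant of a different type (say an insertion) is called at the
#' same position in another line, all calls at that position are excluded.
#' Two SNPs with different ALT alleles at one position are the same
#' alteration type and are retained (as distinct, unshared sites).
#'
#' @param calls A call tibble (all lines).
#' @return The kept calls, with attributes `n_removed` (calls) and
#'   `excluded_positions` (a tibble of chrom/pos).
#' @export
filter_type_consistency <- function(calls) {
  if (nrow(calls) == 0) {
    attr(calls, "n_removed") <- 0L
    attr(calls, "excluded_positions") <- tibble(chrom = character(0), pos = numeric(0))
    return(calls)
  }
  conflict <- as_tibble(calls) |>
    group_by(.data$chrom, .data$pos) |>
    summarise(n_types = dplyr::n_distinct(.data$var_type), .groups = "drop") |>
    filter(.data$n_types > 1) |>
    select("chrom", "pos")
  out <- anti_join(as_tibble(calls), conflict, by = c("chrom", "pos"))
  attr(out, "line_ids") <- attr(calls, "line_ids")
  attr(out, "n_removed") <- nrow(calls) - nrow(out)
  attr(out, "excluded_positions") <- conflict
  out
}

#' Apply the full filtration cascade
#'
#' Filters are applied in a fixed order: excessive-depth exclusion, then the
#' quality criterion, then the all-lines coverage criterion, then cross-line
#' type consistency. Per-call filters run before the cross-line filter so
#' that a call already removed for quality cannot create a type conflict.
#'
#' @inheritParams filter_min_coverage_all_lines
#' @return An object of class `filter_result` with elements `calls` (the
#'   surviving table), `report` (per-stage input/removed/output counts),
#'   `excluded_positions` and `config`. Use [generics::tidy()] for the
#'   surviving calls and [generics::glance()] for a one-row count summary.
#' @examples
#' sim <- simulate_cohort(sim_config(seed = 7))
#' res <- apply_variant_filters(sim$calls, sim$tracks)
#' glance(res)
#' @export
apply_variant_filters <- function(calls, tracks, config = filter_config(),
                                  line_ids = cohort_lines(calls)) {
  calls <- build_multiline_table(as_tibble(calls), line_ids = line_ids)
  stages <- character(0); n_in <- integer(0); n_rm <- integer(0)
  note <- function(stage, before, after) {
    stages <<- c(stages, stage)
    n_in <<- c(n_in, nrow(before))
    n_rm <<- c(n_rm, nrow(before) - nrow(after))
  }
  s1 <- filter_excessive_depth(calls, config)
  note("excessive_depth", calls, s1)
  s2 <- filter_quality(s1, config)
  note("quality", s1, s2)
  s3 <- filter_min_coverage_all_lines(s2, tracks, config, line_ids)
  note("coverage_all_lines", s2, s3)
  if (config$require_type_consistency) {
    s4 <- filter_type_consistency(s3)
    excluded <- attr(s4, "excluded_positions")
  } else {
    s4 <- s3
    excluded <- tibble(chrom = character(0), pos = numeric(0))
  }
  note("type_consistency", s3, s4)
  report <- tibble(stage = stages, n_calls_in = n_in, n_calls_removed = n_rm,
                   n_calls_out = n_in - n_rm)
  s4 <- as_tibble(s4)
  for (a in c("n_removed", "n_sites_removed", "excluded_positions")) {
    attr(s4, a) <- NULL
  }
  out <- build_multiline_table(s4, line_ids = line_ids)
  structure(list(calls = out, report = report,
                 excluded_positions = excluded, config = config),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat("<filter_result>\n")
  cat("  lines:", paste(cohort_lines(x$calls), collapse = ", "), "\n")
  cat("  surviving calls:", nrow(x$calls), " sites:", n_sites(x$calls), "\n")
  print(x$report)
  invisible(x)
}

#' @rdname apply_variant_filters
#' @param x A `filter_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.filter_result <- function(x, ...) {
  as_tibble(x$calls)
}

#' @rdname apply_variant_filters
#' @exportS3Method generics::glance
glance.filter_result <- function(x, ...) {
  rm <- setNames(x$report$n_calls_removed, paste0("removed_", x$report$stage))
  tibble(n_calls_in = x$report$n_calls_in[1],
         !!!rm,
         n_calls_out = nrow(x$calls),
         n_sites_out = n_sites(x$calls),
         n_positions_type_conflict = nrow(x$excluded_positions))
}
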