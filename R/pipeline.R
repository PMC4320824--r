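# End-to-end orchestration: reads the per-line inputs, runs filtration,
# sharing, spectra, windows and (optionally) effect classification, and
# writes a machine-readable report bundle. Fully deterministic on fixed
# inputs; every summary number in the reports is recomputable from the
# emitted per-variant tables.

#' Pipeline configuration
#'
#' @param vcf Named character vector: line id -> VCF path. The name order is
#'   the canonical line order.
#' @param coverage Named character vector: line id -> bedgraph path (one per
#'   line in `vcf`).
#' @param genome_index Path to the genome index table.
#' @param groups Named list partitioning the lines into groups (e.g.
#'   transgenic vs wild-type).
#' @param filter A [filter_config()].
#' @param window_size Window width for the density profiles (bp).
#' @param windows_use_filtered Profile the fully filtered variant set instead
#'   of the default all-detected (post depth-exclusion) set.
#' @param gff,fasta Optional gene models + chromosome sequences enabling the
#'   built-in effect classifier.
#' @param annotations Optional precomputed effect annotations (TSV or
#'   ANN-style VCF); takes precedence over `gff`/`fasta`.
#' @param alignment_summary Optional TSV with columns `line_id`,
#'   `total_reads`, `mapped_reads`, `read_length` for read-mapping
#'   statistics (covered lengths come from the coverage tracks).
#' @param out_dir Optional output directory for the report bundle.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(vcf, coverage, genome_index, groups,
                            filter = filter_config(), window_size = 500000,
                            windows_use_filtered = FALSE,
                            gff = NULL, fasta = NULL, annotations = NULL,
                            alignment_summary = NULL, out_dir = NULL) {
  lines <- names(vcf)
  if (is.null(lines) || anyDuplicated(lines)) {
    abort("`vcf` must be uniquely named by line id")
  }
  if (!setequal(names(coverage), lines)) {
    abort("`coverage` must be named by the same line ids as `vcf`")
  }
  if (!setequal(unlist(groups), lines)) {
    abort("`groups` must partition the line list")
  }
  paths <- c(vcf, coverage, genome_index, gff, fasta, annotations,
             alignment_summary)
  missing_files <- paths[!file.exists(paths)]
  if (length(missing_files) > 0) {
    abort(paste0("input file(s) not found: ",
                 paste(missing_files, collapse = ", ")))
  }
  structure(list(vcf = vcf, coverage = coverage, genome_index = genome_index,
                 lines = lines, groups = groups, filter = filter,
                 window_size = window_size,
                 windows_use_filtered = windows_use_filtered,
                 gff = gff, fasta = fasta, annotations = annotations,
                 alignment_summary = alignment_summary, out_dir = out_dir),
            class = "pipeline_config")
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", stage, "' failed: ", conditionMessage(e)))
  })
}

#' Run the whole comparison pipeline
#'
#' Stages: read inputs; apply the filtration cascade; classify sharing and
#' extract line-specific variants; per-line and per-group substitution
#' spectra with Ts/Tv ratios; windowed density profiles with group means and
#' maximum per-window group differences; and, when gene models or
#' precomputed annotations are supplied, the effect classification rollup.
#' When `out_dir` is set, writes tab-separated reports plus a JSON summary.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list with elements `genome`, `filter_result`,
#'   `line_summary`, `sharing`, `line_specific`, `spectra`, `ts_tv`,
#'   `window_means`, `max_window_diff`, `alignment`, `effects` (NULL when
#'   not computed) and `files` (paths written).
#' @export
run_pipeline <- function(config) {
  cfg <- config
  genome <- pipeline_stage("genome_index", read_genome_index(cfg$genome_index))
  calls <- pipeline_stage("read_vcf", {
    build_multiline_table(
      purrr::imap(as.list(cfg$vcf), function(p, ln) read_vcf_calls(p, ln, genome)),
      line_ids = cfg$lines)
  })
  tracks <- pipeline_stage("read_coverage", {
    bind_rows(purrr::imap(as.list(cfg$coverage),
                          function(p, ln) read_coverage_track(p, genome, ln)))
  })
  covered <- pipeline_stage("covered_length", {
    v <- purrr::map_dbl(cfg$lines, function(ln) {
      covered_length(tracks[tracks$line_id == ln, , drop = FALSE])
    })
    setNames(v, cfg$lines)
  })
  res <- pipeline_stage("filtration",
                        apply_variant_filters(calls, tracks, cfg$filter,
                                              line_ids = cfg$lines))
  line_summary <- pipeline_stage("line_summary",
    summarize_line_specific(res$calls, cfg$lines, covered_lengths = covered))
  sharing <- pipeline_stage("sharing", classify_sharing(res$calls, cfg$lines))
  private <- pipeline_stage("line_specific",
                            line_specific_variants(res$calls, line_ids = cfg$lines))

  spectra <- pipeline_stage("spectra", {
    per_line <- purrr::map(cfg$lines, function(ln) {
      suppressWarnings(
        substitution_spectrum(filter(private, .data$line_id == ln))) |>
        mutate(unit = ln, level = "line")
    })
    per_group <- purrr::imap(cfg$groups, function(lns, g) {
      suppressWarnings(
        substitution_spectrum(filter(private, .data$line_id %in% lns))) |>
        mutate(unit = g, level = "group")
    })
    bind_rows(bind_rows(per_line), bind_rows(per_group)) |>
      select("level", "unit", "substitution", "class", "n")
  })
  ts_tv <- spectra |>
    group_by(.data$level, .data$unit) |>
    summarise(n_ts = sum(.data$n[.data$class == "transition"]),
              n_tv = sum(.data$n[.data$class == "transversion"]),
              .groups = "drop") |>
    mutate(ts_tv = if_else(.data$n_tv > 0, .data$n_ts / .data$n_tv, NA_real_))

  window_input <- if (cfg$windows_use_filtered) {
    res$calls
  } else {
    filter_excessive_depth(calls, cfg$filter)
  }
  wcounts <- pipeline_stage("windows",
    window_counts(window_input, genome, cfg$window_size, line_ids = cfg$lines))
  wmeans <- pipeline_stage("window_means", group_mean_profile(wcounts, cfg$groups))
  wdiff <- if (length(cfg$groups) >= 2) {
    pipeline_stage("max_window_diff",
      max_window_difference(wmeans, names(cfg$groups)[1], names(cfg$groups)[2]))
  } else NULL

  alignment <- NULL
  if (!is.null(cfg$alignment_summary)) {
    alignment <- pipeline_stage("alignment_summary", {
      readr::read_tsv(cfg$alignment_summary, col_types = readr::cols(),
                      progress = FALSE) |>
        mutate(covered_length = unname(covered[.data$line_id])) |>
        alignment_summary_stats(genome)
    })
  }

  effects <- NULL
  if (!is.null(cfg$annotations)) {
    effects <- pipeline_stage("effects", {
      ann <- parse_effect_annotations(cfg$annotations)
      assignments <- inner_join(
        private, ann, by = c("chrom", "pos", "ref", "alt"))
      effect_rollup(assignments, cfg$groups)
    })
  } else if (!is.null(cfg$gff) && !is.null(cfg$fasta)) {
    effects <- pipeline_stage("effects", {
      models <- read_gene_models(cfg$gff)
      seqs <- Biostrings::readDNAStringSet(cfg$fasta)
      names(seqs) <- sub("\\s.*$", "", names(seqs))
      effect_rollup(annotate_effects(private, models, seqs), cfg$groups)
    })
  }

  files <- character(0)
  if (!is.null(cfg$out_dir)) {
    files <- pipeline_stage("write_reports",
      write_report_bundle(cfg$out_dir, res, line_summary, sharing, private,
                          spectra, ts_tv, wmeans, wdiff, alignment, effects))
  }
  invisible(list(genome = genome, filter_result = res,
                 line_summary = line_summary, sharing = sharing,
                 line_specific = private, spectra = spectra, ts_tv = ts_tv,
                 window_counts = wcounts, window_means = wmeans,
                 max_window_diff = wdiff, alignment = alignment,
                 effects = effects, files = files))
}

write_report_bundle <- function(dir, res, line_summary, sharing, private,
                                spectra, ts_tv, wmeans, wdiff, alignment,
                                effects) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(x, name) {
    p <- file.path(dir, name)
    readr::write_tsv(x, p, progress = FALSE)
    p
  }
  files <- c(
    emit(res$report, "filter_report.tsv"),
    emit(as_tibble(res$calls), "filtered_variants.tsv"),
    emit(line_summary, "table2_sharing.tsv"),
    emit(as_tibble(sharing), "sharing_profile.tsv"),
    emit(private, "line_specific_variants.tsv"),
    emit(spectra, "figure2_spectra.tsv"),
    emit(ts_tv, "figure2_tstv.tsv"),
    emit(wmeans, "figure1_windows.tsv"))
  if (!is.null(wdiff)) files <- c(files, emit(wdiff, "figure1_maxdiff.tsv"))
  if (!is.null(alignment)) files <- c(files, emit(alignment, "table1_summary.tsv"))
  if (!is.null(effects)) {
    files <- c(files,
               emit(tidy(effects), "table3_effects.tsv"),
               emit(effects$impact_pct, "table3_impact.tsv"))
  }
  summary <- list(
    filter = as.list(glance(res)),
    line_specific = setNames(as.list(line_summary$n_line_specific),
                             line_summary$line_id),
    mutation_rate = if ("mutation_rate" %in% names(line_summary)) {
      setNames(as.list(line_summary$mutation_rate), line_summary$line_id)
    },
    ts_tv = setNames(as.list(ts_tv$ts_tv), ts_tv$unit))
  p <- file.path(dir, "summary.json")
  jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  c(files, p)
}
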