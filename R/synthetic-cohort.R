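# Seeded generator of multi-line variant cohorts with a known truth table.
# Violations of each filtration criterion are planted by explicit assignment
# (never by sampling), so planted counts are exact.

#' Substitution-spectrum weights targeting a Ts/Tv ratio
#'
#' Builds a 12-bin directed-substitution weight vector with the G>A / C>T
#' transition bias typical of spontaneous plant mutation spectra and, when
#' `gt_ca_weight` is set, an excess of G>T / C>A transversions (the
#' oxidative-damage signature).
#'
#' @param ts_tv Target transition/transversion ratio.
#' @param ag_tc_weight Weight given to each of A>G and T>C (the remaining
#'   transition mass goes to G>A and C>T equally).
#' @param gt_ca_weight Weight given to each of G>T and C>A; `NULL` spreads
#'   the transversion mass evenly over all eight transversions.
#' @return A named numeric 12-vector summing to 1.
#' @export
spectrum_weights <- function(ts_tv, ag_tc_weight = 0.06, gt_ca_weight = NULL) {
  ts_mass <- ts_tv / (1 + ts_tv)
  tv_mass <- 1 / (1 + ts_tv)
  w <- setNames(numeric(12), ALL_SUBS)
  w[c("A>G", "T>C")] <- ag_tc_weight
  w[c("G>A", "C>T")] <- (ts_mass - 2 * ag_tc_weight) / 2
  tv_bins <- setdiff(ALL_SUBS, TS_PAIRS)
  if (is.null(gt_ca_weight)) {
    w[tv_bins] <- tv_mass / 8
  } else {
    w[c("G>T", "C>A")] <- gt_ca_weight
    w[setdiff(tv_bins, c("G>T", "C>A"))] <- (tv_mass - 2 * gt_ca_weight) / 6
  }
  if (any(w < 0)) abort("infeasible spectrum weights (negative bin)")
  w
}

#' Configuration for the synthetic cohort generator
#'
#' The defaults emulate, at roughly one-tenth scale, a five-line resequencing
#' comparison of three transgenic and two wild-type lines of one cultivar: a
#' large block of variants common to all lines, a modest number of partially
#' shared variants, per-line private variants in the published proportions
#' (80/62/84/52/83 at this scale), SNP:Ins:Del fractions of 0.58:0.10:0.32,
#' group substitution spectra targeting Ts/Tv 1.12 (transgenic, with excess
#' G>T/C>A) and 1.65 (wild-type), ~100x coverage, and a small number of
#' planted violations of each filtration criterion.
#'
#' @param seed Integer seed; the whole simulation is deterministic given the
#'   seed and configuration.
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param lines Line identifiers, in canonical display order.
#' @param groups Named list partitioning `lines` into groups.
#' @param n_common Number of variants common to all lines.
#' @param pattern_counts Named vector: `"+"`-separated carrier subsets (2 to
#'   n-1 lines) -> variant counts.
#' @param private_counts Named vector: line -> private variant count.
#' @param snp_fraction,ins_fraction,del_fraction Variant-type mix (sum to 1).
#' @param spectrum_by_group Named list of 12-bin weight vectors (one per
#'   group) used for private SNPs; shared/common SNPs use the mean weights.
#' @param quality_mean,quality_sd,quality_floor Phred quality model for
#'   passing calls (normal, truncated below at `quality_floor`).
#' @param baseline_depth Coverage depth of the covered genome.
#' @param covered_fraction Fraction of each chromosome covered by reads; the
#'   remainder is emitted as zero-depth bedgraph rows.
#' @param low_coverage_depth Depth planted at low-coverage violation sites.
#' @param n_low_quality,n_low_coverage_sites,n_type_conflicts,n_over_depth
#'   Planted violations of each filter (type conflicts are positions; each
#'   contributes two sites).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       chrom_lengths = c(chr1 = 12e6, chr2 = 10e6, chr3 = 8e6),
                       lines = c("TG1", "TG2", "TG3", "WT1", "WT2"),
                       groups = list(TG = c("TG1", "TG2", "TG3"),
                                     WT = c("WT1", "WT2")),
                       n_common = 1037,
                       pattern_counts = c("TG1+TG2" = 40, "TG1+TG2+TG3" = 60,
                                          "WT1+WT2" = 50,
                                          "TG1+TG2+TG3+WT1" = 30,
                                          "TG2+WT2" = 20),
                       private_counts = c(TG1 = 80, TG2 = 62, TG3 = 84,
                                          WT1 = 52, WT2 = 83),
                       snp_fraction = 0.58, ins_fraction = 0.10,
                       del_fraction = 0.32,
                       spectrum_by_group = list(
                         TG = spectrum_weights(1.12, gt_ca_weight = 0.12),
                         WT = spectrum_weights(1.65)),
                       quality_mean = 180, quality_sd = 40, quality_floor = 30,
                       baseline_depth = 100, covered_fraction = 0.996,
                       low_coverage_depth = 3,
                       n_low_quality = 25, n_low_coverage_sites = 25,
                       n_type_conflicts = 10, n_over_depth = 10) {
  cfg <- as.list(environment())
  stopifnot(length(lines) >= 2)
  if (abs(snp_fraction + ins_fraction + del_fraction - 1) > 1e-8) {
    abort("snp/ins/del fractions must sum to 1")
  }
  if (!setequal(unlist(groups), lines)) {
    abort("groups must partition `lines`")
  }
  if (!setequal(names(private_counts), lines)) {
    abort("private_counts must be named by the cohort lines")
  }
  for (g in names(spectrum_by_group)) {
    w <- spectrum_by_group[[g]]
    if (!setequal(names(w), ALL_SUBS) || abs(sum(w) - 1) > 1e-8) {
      abort("each spectrum weight vector must cover the 12 substitutions and sum to 1")
    }
  }
  if (length(pattern_counts) > 0) {
    carriers <- strsplit(names(pattern_counts), "+", fixed = TRUE)
    sizes <- lengths(carriers)
    if (any(!unlist(carriers) %in% lines) ||
        any(sizes < 2 | sizes >= length(lines))) {
      abort("pattern_counts names must be '+'-joined subsets of 2..n-1 lines")
    }
  }
  counts <- c(n_common, pattern_counts, private_counts, n_low_quality,
              n_low_coverage_sites, n_type_conflicts, n_over_depth)
  if (any(counts < 0)) abort("all counts must be >= 0")
  structure(cfg, class = "sim_config")
}

rand_bases <- function(n, len = 1) {
  purrr::map_chr(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  })
}

# draw ref/alt/type for n sites given a 12-bin SNP weight vector
draw_alleles <- function(n, types, snp_weights) {
  ref <- character(n); alt <- character(n)
  is_snp <- types == "SNP"
  if (any(is_snp)) {
    pair <- sample(ALL_SUBS, sum(is_snp), replace = TRUE,
                   prob = snp_weights[ALL_SUBS])
    ref[is_snp] <- substr(pair, 1, 1)
    alt[is_snp] <- substr(pair, 3, 3)
  }
  is_ins <- types == "INS"
  if (any(is_ins)) {
    anchor <- rand_bases(sum(is_ins))
    ref[is_ins] <- anchor
    alt[is_ins] <- paste0(anchor, rand_bases(sum(is_ins), len = 2))
  }
  is_del <- types == "DEL"
  if (any(is_del)) {
    anchor <- rand_bases(sum(is_del))
    ref[is_del] <- paste0(anchor, rand_bases(sum(is_del), len = 2))
    alt[is_del] <- anchor
  }
  tibble(ref = ref, alt = alt)
}

#' Simulate a multi-line variant cohort with known truth
#'
#' Draws variant positions uniformly without replacement within the covered
#' span of each chromosome (allocated proportionally to length), assigns
#' them to the configured sharing patterns, draws alleles from the
#' type mix and group substitution spectra, plants the configured filter
#' violations by explicit assignment, and builds per-line coverage tracks.
#' Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_cohort` with elements `calls` (multi-line
#'   table), `tracks`, `genome`, `truth` (one row per site with its intended
#'   pattern and filter fate), `covered_lengths`, `groups` and `config`.
#' @seealso [write_cohort()] to materialize the cohort as VCF/bedgraph/index
#'   files.
#' @export
simulate_cohort <- function(config = sim_config()) {
  cfg <- config
  set.seed(cfg$seed)
  genome <- genome_index(names(cfg$chrom_lengths), unname(cfg$chrom_lengths))
  lines <- cfg$lines
  n_lines <- length(lines)
  line_group <- setNames(rep(names(cfg$groups), lengths(cfg$groups)),
                         unlist(cfg$groups))
  mean_weights <- purrr::reduce(cfg$spectrum_by_group, `+`) /
    length(cfg$spectrum_by_group)

  # --- site plan -----------------------------------------------------------
  plan <- bind_rows(
    tibble(category = "common",
           carriers = rep(list(lines), cfg$n_common)),
    purrr::imap(cfg$pattern_counts, function(k, pat) {
      tibble(category = "shared",
             carriers = rep(list(strsplit(pat, "+", fixed = TRUE)[[1]]), k))
    }) |> bind_rows(),
    purrr::imap(cfg$private_counts, function(k, ln) {
      tibble(category = "private", carriers = rep(list(ln), k))
    }) |> bind_rows(),
    tibble(category = "low_quality",
           carriers = as.list(rep_len(lines, cfg$n_low_quality))),
    tibble(category = "low_coverage",
           carriers = as.list(rep_len(lines, cfg$n_low_coverage_sites))),
    tibble(category = "over_depth",
           carriers = as.list(rep_len(lines, cfg$n_over_depth)))
  )
  n_conflict_pos <- cfg$n_type_conflicts

  # --- positions (distinct; margin away from covered-span edges) -----------
  cov_end <- floor(cfg$covered_fraction * genome$length)
  usable <- pmax(cov_end - 20, 0)
  n_pos <- nrow(plan) + n_conflict_pos
  if (n_pos > sum(usable)) abort("more variants requested than genome positions")
  n_per_chrom <- as.vector(stats::rmultinom(1, n_pos, usable / sum(usable)))
  while (any(n_per_chrom > usable)) {  # guard tiny chromosomes
    excess <- pmax(n_per_chrom - usable, 0)
    n_per_chrom <- pmin(n_per_chrom, usable)
    room <- which(n_per_chrom < usable)
    n_per_chrom[room[1]] <- n_per_chrom[room[1]] + sum(excess)
  }
  pos_tbl <- purrr::map(seq_len(nrow(genome)), function(i) {
    tibble(chrom = genome$chrom[i],
           pos = sample.int(usable[i] - 10, n_per_chrom[i]) + 10)
  }) |> bind_rows()
  pos_tbl <- pos_tbl[sample.int(nrow(pos_tbl)), ]

  plan$chrom <- pos_tbl$chrom[seq_len(nrow(plan))]
  plan$pos <- pos_tbl$pos[seq_len(nrow(plan))]
  conflict_pos <- pos_tbl[nrow(plan) + seq_len(n_conflict_pos), , drop = FALSE]

  # --- alleles -------------------------------------------------------------
  plan$var_type <- sample(c("SNP", "INS", "DEL"), nrow(plan), replace = TRUE,
                          prob = c(cfg$snp_fraction, cfg$ins_fraction,
                                   cfg$del_fraction))
  single <- lengths(plan$carriers) == 1
  first_carrier <- purrr::map_chr(plan$carriers, 1)
  plan$ref <- NA_character_
  plan$alt <- NA_character_
  for (g in names(cfg$spectrum_by_group)) {
    sel <- which(single & line_group[first_carrier] == g)
    if (length(sel)) {
      al <- draw_alleles(length(sel), plan$var_type[sel],
                         cfg$spectrum_by_group[[g]])
      plan$ref[sel] <- al$ref
      plan$alt[sel] <- al$alt
    }
  }
  sel <- which(!single)
  if (length(sel)) {
    al <- draw_alleles(length(sel), plan$var_type[sel], mean_weights)
    plan$ref[sel] <- al$ref
    plan$alt[sel] <- al$alt
  }

  # --- type-conflict sites: SNP in one line, INS in another ----------------
  if (n_conflict_pos > 0) {
    pair_idx <- purrr::map(seq_len(n_conflict_pos), function(i) {
      k <- ((i - 1) %% n_lines) + 1
      c(k, (k %% n_lines) + 1)
    })
    anchor <- rand_bases(n_conflict_pos)
    snp_alt <- purrr::map_chr(anchor, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1))
    conflict <- bind_rows(
      tibble(category = "type_conflict",
             carriers = purrr::map(pair_idx, ~ lines[.x[1]]),
             chrom = conflict_pos$chrom, pos = conflict_pos$pos,
             var_type = "SNP", ref = anchor, alt = snp_alt),
      tibble(category = "type_conflict",
             carriers = purrr::map(pair_idx, ~ lines[.x[2]]),
             chrom = conflict_pos$chrom, pos = conflict_pos$pos,
             var_type = "INS", ref = anchor,
             alt = paste0(anchor, rand_bases(n_conflict_pos, len = 2)))
    )
    plan <- bind_rows(plan, conflict)
  }

  plan$fate <- dplyr::case_match(plan$category,
    "low_quality" ~ "removed_quality",
    "low_coverage" ~ "removed_coverage",
    "over_depth" ~ "removed_depth",
    "type_conflict" ~ "removed_type_conflict",
    .default = "pass")
  plan$pattern <- purrr::map_chr(plan$carriers, function(cs) {
    paste(as.integer(lines %in% cs), collapse = "")
  })

  # --- per-call table ------------------------------------------------------
  calls <- plan |>
    mutate(site = row_number()) |>
    tidyr::unnest_longer("carriers", values_to = "line_id") |>
    mutate(qual = round(pmax(cfg$quality_floor,
                             rnorm(n(), cfg$quality_mean, cfg$quality_sd)), 1),
           depth = rpois(n(), cfg$baseline_depth))
  lq <- calls$category == "low_quality"
  calls$qual[lq] <- round(runif(sum(lq), 5, 29.4), 1)
  od <- calls$category == "over_depth"
  calls$depth[od] <- 10001 + rpois(sum(od), 50)

  # --- coverage tracks -----------------------------------------------------
  low_cov <- plan |>
    filter(.data$category == "low_coverage") |>
    mutate(hole_line = purrr::map_chr(.data$carriers, function(cs) {
      sample(setdiff(lines, cs), 1)  # a non-carrier line lacks coverage
    }))
  tracks <- purrr::map(lines, function(ln) {
    purrr::map(seq_len(nrow(genome)), function(i) {
      ch <- genome$chrom[i]
      holes <- low_cov |> filter(.data$hole_line == ln, .data$chrom == ch)
      bounds <- sort(unique(holes$pos))
      starts <- c(1, bounds, bounds + 1)
      starts <- sort(unique(starts[starts <= cov_end[i]]))
      ends <- c(starts[-1] - 1, cov_end[i])
      depth <- ifelse(starts %in% bounds, cfg$low_coverage_depth,
                      cfg$baseline_depth)
      iv <- tibble(chrom = ch, start = starts, end = ends, depth = depth)
      iv <- iv[iv$end >= iv$start, ]
      if (cov_end[i] < genome$length[i]) {
        iv <- bind_rows(iv, tibble(chrom = ch, start = cov_end[i] + 1,
                                   end = genome$length[i], depth = 0))
      }
      iv
    }) |>
      bind_rows() |>
      mutate(line_id = ln, .before = 1)
  }) |> bind_rows()
  class(tracks) <- c("coverage_track", class(tracks))

  covered_lengths <- setNames(rep(sum(cov_end), n_lines), lines)
  truth <- plan |>
    mutate(carriers = purrr::map_chr(.data$carriers, paste, collapse = "+"),
           n_carriers = nchar(gsub("0", "", .data$pattern))) |>
    select("chrom", "pos", "ref", "alt", "var_type", "category", "carriers",
           "n_carriers", "pattern", "fate")
  calls_out <- build_multiline_table(
    calls[, c("line_id", "chrom", "pos", "ref", "alt", "var_type",
              "qual", "depth")],
    line_ids = lines)
  structure(list(calls = calls_out, tracks = tracks, genome = genome,
                 truth = truth, covered_lengths = covered_lengths,
                 groups = cfg$groups, config = cfg),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("<sim_cohort>", nrow(x$truth), "sites,", nrow(x$calls), "calls,",
      length(x$config$lines), "lines\n")
  print(count(x$truth, .data$category, .data$fate))
  invisible(x)
}

#' @rdname simulate_cohort
#' @param x A `sim_cohort`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.sim_cohort <- function(x, ...) {
  tibble(n_sites = nrow(x$truth), n_calls = nrow(x$calls),
         n_lines = length(x$config$lines),
         n_pass_sites = sum(x$truth$fate == "pass"),
         n_planted_violations = sum(x$truth$fate != "pass"))
}

#' Write a simulated cohort to disk
#'
#' Materializes the cohort as one VCF and one bedgraph per line plus a
#' genome-index table, all plain text, so the files can be fed back through
#' the package's readers (or any external tool).
#'
#' @param sim A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of file paths (`genome`, `vcf`,
#'   `coverage`, `truth`).
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(genome = file.path(dir, "genome_index.tsv"),
                vcf = setNames(file.path(dir, paste0(sim$config$lines, ".vcf")),
                               sim$config$lines),
                coverage = setNames(
                  file.path(dir, paste0(sim$config$lines, ".bedgraph")),
                  sim$config$lines),
                truth = file.path(dir, "truth.tsv"))
  write_genome_index(sim$genome, paths$genome)
  for (ln in sim$config$lines) {
    write_vcf_calls(filter(as_tibble(sim$calls), .data$line_id == ln),
                    paths$vcf[[ln]], genome = sim$genome)
    write_coverage_track(filter(sim$tracks, .data$line_id == ln),
                         paths$coverage[[ln]])
  }
  readr::write_tsv(sim$truth, paths$truth, progress = FALSE)
  invisible(paths)
}
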