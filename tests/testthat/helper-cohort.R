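# Shared fixture builders and independent oracles.

# quick per-call row constructor
make_calls <- function(line_id, chrom, pos, ref = "A", alt = "G",
                       qual = 60, depth = 30) {
  d <- tibble::tibble(line_id = line_id, chrom = chrom, pos = pos,
                      ref = ref, alt = alt, qual = qual, depth = depth)
  d$var_type <- classify_variant_type(d$ref, d$alt)
  d[, c("line_id", "chrom", "pos", "ref", "alt", "var_type", "qual", "depth")]
}

# uniform-depth coverage for every line over whole chromosomes
full_tracks <- function(line_ids, genome, depth = 50) {
  purrr::map(line_ids, function(ln) {
    tibble::tibble(line_id = ln, chrom = genome$chrom, start = 1,
                   end = genome$length, depth = depth)
  }) |> dplyr::bind_rows()
}

# independent brute-force sharing oracle: per-site scan over all lines
oracle_sharing <- function(calls, line_ids) {
  sites <- unique(calls[, c("chrom", "pos", "ref", "alt")])
  pats <- vapply(seq_len(nrow(sites)), function(i) {
    carriers <- calls$line_id[calls$chrom == sites$chrom[i] &
                                calls$pos == sites$pos[i] &
                                calls$ref == sites$ref[i] &
                                calls$alt == sites$alt[i]]
    paste(as.integer(line_ids %in% carriers), collapse = "")
  }, character(1))
  tab <- table(pats)
  tibble::tibble(pattern = names(tab), n_variants = as.integer(tab))
}

# random toy cohort over `n_lines` lines and <= max_sites sites
random_toy_cohort <- function(n_lines = 5, max_sites = 50) {
  line_ids <- paste0("L", seq_len(n_lines))
  n <- sample.int(max_sites, 1)
  sites <- tibble::tibble(
    chrom = "chr1",
    pos = sample.int(10000, n),
    ref = sample(c("A", "C", "G", "T"), n, replace = TRUE))
  sites$alt <- vapply(sites$ref, function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }, character(1))
  calls <- purrr::map(seq_len(n), function(i) {
    carriers <- sample(line_ids, sample.int(n_lines, 1))
    make_calls(carriers, sites$chrom[i], sites$pos[i], sites$ref[i],
               sites$alt[i])
  }) |> dplyr::bind_rows()
  build_multiline_table(calls, line_ids = line_ids)
}

# small, fast simulation settings used where full scale is unnecessary
small_sim_config <- function(seed = 1, ...) {
  defaults <- list(
    seed = seed,
    chrom_lengths = c(chr1 = 2e6, chr2 = 1e6),
    n_common = 100,
    pattern_counts = c("TG1+TG2" = 10, "WT1+WT2" = 8, "TG1+TG2+TG3+WT1" = 5),
    private_counts = c(TG1 = 12, TG2 = 9, TG3 = 14, WT1 = 7, WT2 = 11),
    n_low_quality = 5, n_low_coverage_sites = 4,
    n_type_conflicts = 3, n_over_depth = 2)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}
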