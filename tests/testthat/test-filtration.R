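test_that("excessive-depth exclusion uses a strict > 10,000 boundary", {
  calls <- make_calls("A", "chr1", c(10, 20, 30), depth = c(10000, 10001, 50))
  kept <- filter_excessive_depth(calls)
  expect_equal(kept$pos, c(10, 30))
  expect_equal(attr(kept, "n_removed"), 1L)

  empty <- filter_excessive_depth(make_calls(character(0), character(0), numeric(0)))
  expect_equal(nrow(empty), 0)
  expect_equal(attr(empty, "n_removed"), 0L)
})

test_that("quality threshold is inclusive at 30", {
  calls <- make_calls("A", "chr1", c(1, 2, 3), qual = c(30, 29.99, 45))
  kept <- filter_quality(calls)
  expect_equal(kept$pos, c(1, 3))
  expect_equal(attr(kept, "n_removed"), 1L)
})

test_that("coverage criterion requires min depth in every line, carriers or not", {
  g <- genome_index("chr1", 10000)
  lines <- c("A", "B")
  calls <- build_multiline_table(make_calls("A", "chr1", c(100, 200)),
                                 line_ids = lines)
  # line B (non-carrier) has depth 3 at pos 100, depth 4 at pos 200
  tracks <- dplyr::bind_rows(
    tibble::tibble(line_id = "A", chrom = "chr1", start = 1, end = 10000,
                   depth = 50),
    tibble::tibble(line_id = "B", chrom = "chr1",
                   start = c(1, 100, 101), end = c(99, 100, 10000),
                   depth = c(50, 3, 4)))
  kept <- filter_min_coverage_all_lines(calls, tracks, line_ids = lines)
  expect_equal(kept$pos, 200)
  expect_equal(attr(kept, "n_sites_removed"), 1L)

  # vacuous when everyone is well covered
  kept2 <- filter_min_coverage_all_lines(calls, full_tracks(lines, g),
                                         line_ids = lines)
  expect_equal(nrow(kept2), nrow(calls))

  expect_error(filter_min_coverage_all_lines(calls, tracks[tracks$line_id == "A", ],
                                             line_ids = lines),
               "no coverage track")
})

test_that("deletions test every deleted base unless configured anchor-only", {
  lines <- c("A", "B")
  del <- build_multiline_table(
    make_calls("A", "chr1", 100, ref = "ACGT", alt = "A"), line_ids = lines)
  # line B drops below threshold at position 103 (the last deleted base)
  tracks <- dplyr::bind_rows(
    tibble::tibble(line_id = "A", chrom = "chr1", start = 1, end = 10000, depth = 50),
    tibble::tibble(line_id = "B", chrom = "chr1",
                   start = c(1, 103, 104), end = c(102, 103, 10000),
                   depth = c(50, 2, 50)))
  expect_equal(nrow(filter_min_coverage_all_lines(del, tracks, line_ids = lines)), 0)
  anchor_only <- filter_config(del_span_coverage = FALSE)
  expect_equal(nrow(filter_min_coverage_all_lines(del, tracks, anchor_only,
                                                  line_ids = lines)), 1)
})

test_that("type conflicts at a position remove all calls there", {
  conflict <- dplyr::bind_rows(
    make_calls("A", "chr1", 500),                      # SNP
    make_calls("B", "chr1", 500, ref = "A", alt = "AT"),  # INS, same pos
    make_calls("A", "chr1", 900))
  out <- filter_type_consistency(build_multiline_table(conflict))
  expect_equal(out$pos, 900)
  expect_equal(attr(out, "excluded_positions")$pos, 500)

  # same-type different ALT alleles at one position are retained
  two_snps <- dplyr::bind_rows(
    make_calls("A", "chr1", 500, alt = "G"),
    make_calls("B", "chr1", 500, alt = "T"))
  out2 <- filter_type_consistency(build_multiline_table(two_snps))
  expect_equal(nrow(out2), 2)

  single <- filter_type_consistency(build_multiline_table(make_calls("A", "chr1", 7)))
  expect_equal(nrow(single), 1)
})

test_that("the cascade recovers planted violation counts exactly", {
  sim <- simulate_cohort(small_sim_config(seed = 31))
  cfg <- sim$config
  res <- apply_variant_filters(sim$calls, sim$tracks)
  g <- glance(res)
  expect_equal(g$removed_excessive_depth, cfg$n_over_depth)
  expect_equal(g$removed_quality, cfg$n_low_quality)
  expect_equal(g$removed_coverage_all_lines, cfg$n_low_coverage_sites)
  expect_equal(g$n_positions_type_conflict, cfg$n_type_conflicts)
  expect_equal(g$removed_type_consistency, 2 * cfg$n_type_conflicts)
  expect_equal(n_sites(res$calls), sum(sim$truth$fate == "pass"))

  # an all-pass cohort is untouched
  clean <- simulate_cohort(small_sim_config(seed = 8, n_low_quality = 0,
                                            n_low_coverage_sites = 0,
                                            n_type_conflicts = 0,
                                            n_over_depth = 0))
  res2 <- apply_variant_filters(clean$calls, clean$tracks)
  expect_equal(as.data.frame(res2$calls), as.data.frame(clean$calls),
               ignore_attr = TRUE)
})

test_that("filtration is idempotent, monotone and line-order invariant", {
  sim <- simulate_cohort(small_sim_config(seed = 13))
  res1 <- apply_variant_filters(sim$calls, sim$tracks)
  res2 <- apply_variant_filters(res1$calls, sim$tracks)
  expect_equal(as.data.frame(res2$calls), as.data.frame(res1$calls),
               ignore_attr = TRUE)

  # stricter thresholds can only shrink the surviving set
  for (cfg in list(filter_config(min_quality = 100),
                   filter_config(min_reads_all_lines = 10))) {
    strict <- apply_variant_filters(sim$calls, sim$tracks, cfg)
    expect_lte(nrow(strict$calls), nrow(res1$calls))
    expect_equal(nrow(dplyr::anti_join(
      tidy(strict), tidy(res1),
      by = c("line_id", "chrom", "pos", "ref", "alt"))), 0)
  }

  # permuting the line order leaves the surviving site set unchanged
  rev_lines <- rev(sim$config$lines)
  res_rev <- apply_variant_filters(sim$calls, sim$tracks,
                                   line_ids = rev_lines)
  key <- c("line_id", "chrom", "pos", "ref", "alt")
  expect_equal(dplyr::arrange(tidy(res_rev)[, key], chrom, pos, line_id),
               dplyr::arrange(tidy(res1)[, key], chrom, pos, line_id),
               ignore_attr = TRUE)
})
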