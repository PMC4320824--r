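test_that("mutation rates reproduce the published per-line values", {
  # line-specific counts over covered lengths, at 3 significant digits
  expect_equal(signif(mutation_rate(798, 371762264), 3), 2.15e-6)
  expect_equal(signif(mutation_rate(842, 369691614), 3), 2.28e-6)
  expect_equal(signif(mutation_rate(524, 371589770), 3), 1.41e-6)
  expect_equal(mutation_rate(0, 12345), 0)
  expect_error(mutation_rate(10, 0), "covered_length")
  expect_error(mutation_rate(-1, 10), ">= 0")
  # homogeneity: doubling count and length leaves the rate unchanged
  expect_equal(mutation_rate(2 * 798, 2 * 371762264),
               mutation_rate(798, 371762264))
})

test_that("exactly 4 of the 12 directed substitutions are transitions", {
  all12 <- classify_substitution(
    rep(c("A", "C", "G", "T"), each = 3),
    c("C", "G", "T", "A", "G", "T", "A", "C", "T", "A", "C", "G"))
  expect_equal(sum(all12$class == "transition"), 4)
  expect_setequal(all12$substitution[all12$class == "transition"],
                  c("A>G", "G>A", "C>T", "T>C"))
  expect_equal(classify_substitution("G", "A")$class, "transition")
  expect_equal(classify_substitution("G", "T")$class, "transversion")
  expect_error(classify_substitution("N", "A"), "single bases")
  expect_error(classify_substitution("A", "A"), "not a substitution")
})

test_that("spectra count the 12 bins and the Ts/Tv ratio follows", {
  empty <- substitution_spectrum(make_calls(character(0), character(0), numeric(0)))
  expect_equal(nrow(empty), 12)
  expect_true(all(empty$n == 0))

  planted <- make_calls("A", "chr1", 1:10,
                        ref = c(rep("G", 4), rep("C", 4), rep("G", 2)),
                        alt = c(rep("T", 4), rep("A", 4), rep("A", 2)))
  spec <- substitution_spectrum(planted)
  expect_equal(sum(spec$n[spec$class == "transversion"]), 8)
  expect_equal(sum(spec$n[spec$class == "transition"]), 2)
  expect_equal(sum(spec$n), nrow(planted))
  expect_equal(ts_tv_ratio(spec), 0.25)

  with_indel <- dplyr::bind_rows(planted, make_calls("A", "chr1", 99,
                                                     ref = "A", alt = "AT"))
  expect_warning(spec2 <- substitution_spectrum(with_indel), "non-SNP")
  expect_equal(sum(spec2$n), 10)

  even <- substitution_spectrum(make_calls("A", "chr1", 1:8,
                                           ref = "G", alt = rep(c("A", "T"), 4)))
  expect_equal(ts_tv_ratio(even), 1)
  none_ts <- substitution_spectrum(make_calls("A", "chr1", 1:5, ref = "G", alt = "T"))
  expect_equal(ts_tv_ratio(none_ts), 0)
  all_ts <- substitution_spectrum(make_calls("A", "chr1", 1:5, ref = "G", alt = "A"))
  expect_warning(expect_true(is.na(ts_tv_ratio(all_ts))), "undefined")
})

test_that("simulated spectra recover the configured Ts/Tv ratio at n = 10,000", {
  cfg <- sim_config(seed = 17,
                    chrom_lengths = c(chr1 = 3e7, chr2 = 3e7),
                    lines = c("A", "B"),
                    groups = list(GA = "A", GB = "B"),
                    n_common = 0, pattern_counts = c(),
                    private_counts = c(A = 10000, B = 10000),
                    snp_fraction = 1, ins_fraction = 0, del_fraction = 0,
                    spectrum_by_group = list(GA = spectrum_weights(1.12, gt_ca_weight = 0.12),
                                             GB = spectrum_weights(1.65)),
                    n_low_quality = 0, n_low_coverage_sites = 0,
                    n_type_conflicts = 0, n_over_depth = 0)
  sim <- simulate_cohort(cfg)
  for (spec in list(list(line = "A", target = 1.12),
                    list(line = "B", target = 1.65))) {
    s <- substitution_spectrum(
      dplyr::filter(tibble::as_tibble(sim$calls), line_id == spec$line))
    n <- sum(s$n)
    p0 <- spec$target / (1 + spec$target)
    phat <- sum(s$n[s$class == "transition"]) / n
    expect_lt(abs(phat - p0), 3 * sqrt(p0 * (1 - p0) / n))
  }
})

test_that("alignment statistics reproduce the published mapping and coverage rates", {
  genome <- read_genome_index(cohort_example("rice_genome_index.tsv"))
  summaries <- readr::read_tsv(cohort_example("rice_alignment_summary.tsv"),
                               show_col_types = FALSE)
  stats <- alignment_summary_stats(summaries, genome)
  r50A <- stats[stats$line_id == "50A", ]
  expect_equal(round(r50A$mapping_rate, 1), 97.8)
  expect_equal(round(r50A$coverage_rate, 1), 99.6)
  # depth by the stated formula (mapped reads x read length / covered length)
  expect_equal(round(r50A$depth, 1), 101.1)
  expect_equal(round(stats$mapping_rate, 1), c(97.8, 97.3, 98.1, 97.1, 97.2))

  expect_error(alignment_summary_stats(
    dplyr::mutate(summaries, total_reads = 0), genome), "positive")
  expect_error(alignment_summary_stats(
    dplyr::mutate(summaries, mapped_reads = total_reads + 1), genome),
    "mapped_reads")
})
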