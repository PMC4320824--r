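test_that("genome index reading sums chromosome lengths and validates input", {
  g <- read_genome_index(cohort_example("rice_genome_index.tsv"))
  expect_equal(nrow(g), 12)
  expect_equal(genome_total_length(g), 373245519)

  p <- withr::local_tempfile(lines = "chr1\t1000")
  g1 <- read_genome_index(p)
  expect_equal(genome_total_length(g1), 1000)

  # FAI dialect: extra columns ignored
  p2 <- withr::local_tempfile(lines = c("chr1\t500\t6\t60\t61",
                                        "chr2\t300\t520\t60\t61"))
  expect_equal(genome_total_length(read_genome_index(p2)), 800)

  expect_error(genome_index(c("a", "a"), c(10, 20)), "duplicate")
  expect_error(genome_index("a", 0), "positive")
  expect_error(genome_index("a", 100, centromere_mid = c(a = 200)),
               "centromere")
})

test_that("synthetic genome index round-trips with its configured total", {
  cfg <- small_sim_config(seed = 5)
  sim <- simulate_cohort(cfg)
  p <- withr::local_tempfile()
  write_genome_index(sim$genome, p)
  g <- read_genome_index(p)
  expect_equal(genome_total_length(g), sum(cfg$chrom_lengths))
  expect_equal(g$chrom, names(cfg$chrom_lengths))
})

test_that("coverage tracks are normalized and covered_length computed", {
  g <- genome_index("chr1", 1000)
  p <- withr::local_tempfile(lines = "chr1\t0\t1000\t5")
  tr <- read_coverage_track(p, g, "A")
  expect_equal(covered_length(tr), 1000)
  expect_equal(tr$start, 1)  # 0-based half-open -> 1-based inclusive

  p2 <- withr::local_tempfile(lines = c("chr1\t0\t400\t4", "chr1\t600\t1000\t1"))
  expect_equal(covered_length(read_coverage_track(p2, g, "A")), 800)

  # zero-depth rows are accepted but do not count as covered
  p3 <- withr::local_tempfile(lines = c("chr1\t0\t400\t4", "chr1\t400\t1000\t0"))
  expect_equal(covered_length(read_coverage_track(p3, g, "A")), 400)

  p4 <- withr::local_tempfile(lines = "chr1\t0\t1001\t2")
  expect_error(read_coverage_track(p4, g, "A"), "beyond chromosome end")
  p5 <- withr::local_tempfile(lines = c("chr1\t0\t500\t2", "chr1\t400\t800\t3"))
  expect_error(read_coverage_track(p5, g, "A"), "overlapping")
})

test_that("covered_length is invariant under splitting intervals of equal depth", {
  g <- genome_index("chr1", 10000)
  whole <- coverage_track("A", "chr1", 101, 900, 7, g)
  parts <- coverage_track("A", c("chr1", "chr1", "chr1"),
                          c(101, 301, 601), c(300, 600, 900), 7, g)
  expect_equal(covered_length(whole), covered_length(parts))
})

test_that("VCF reading maps records, splits multi-allelics and rejects bad rows", {
  g <- genome_index("chr1", 100000)
  p <- withr::local_tempfile(lines = c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t100\t.\tA\tG\t45\t.\tDP=30",
    "chr1\t200\t.\tA\tG,T\t50\t.\tDP=22",
    "chr1\t300\t.\tAT\tA\t.\t.\tDP=10"))
  expect_warning(calls <- read_vcf_calls(p, "L1", g), "rejected")
  expect_equal(nrow(calls), 3)  # missing-QUAL record dropped, multiallelic split
  expect_equal(attr(calls, "n_rejected"), 1L)
  expect_equal(calls$var_type, c("SNP", "SNP", "SNP"))
  expect_equal(calls$alt[calls$pos == 200], c("G", "T"))
  expect_equal(calls$depth, c(30, 22, 22))

  p2 <- withr::local_tempfile(lines = c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chrX\t10\t.\tA\tG\t45\t.\tDP=30"))
  expect_error(read_vcf_calls(p2, "L1", g), "unknown chromosome")
  # alias table maps names explicitly; no fuzzy matching
  expect_equal(read_vcf_calls(p2, "L1", g, aliases = c(chrX = "chr1"))$chrom,
               "chr1")
})

test_that("writing then re-reading variant calls is the identity", {
  g <- genome_index(c("chr1", "chr2"), c(5e5, 3e5))
  set.seed(42)
  calls <- make_calls(line_id = "L1", chrom = sample(g$chrom, 40, TRUE),
                      pos = sample.int(2e5, 40),
                      qual = round(runif(40, 0, 250), 1),
                      depth = sample.int(200, 40))
  # add indels and make keys unique
  calls$ref[1:5] <- paste0(calls$ref[1:5], "TT")
  calls$alt[6:10] <- paste0(calls$alt[6:10], "ACA")
  calls$var_type <- classify_variant_type(calls$ref, calls$alt)
  calls <- calls[!duplicated(calls[, c("chrom", "pos")]), ]
  p <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_calls(calls, p, genome = g)
  back <- read_vcf_calls(p, "L1", g)
  key <- c("chrom", "pos", "ref", "alt", "qual", "depth")
  expect_equal(dplyr::arrange(back[, key], chrom, pos),
               dplyr::arrange(calls[, key], chrom, pos), ignore_attr = TRUE)
})
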