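test_that("the impact mapping is total and partitions the 23 effect types", {
  cat23 <- effect_catalog()
  expect_equal(nrow(cat23), 23)
  expect_equal(as.vector(table(cat23$impact)[c("HIGH", "MODERATE", "LOW", "MODIFIER")]),
               c(6L, 5L, 5L, 7L))
  expect_equal(impact_category("FRAME_SHIFT"), "HIGH")
  expect_equal(impact_category("INTRON"), "MODIFIER")
  expect_equal(impact_category(c("SYNONYMOUS_CODING", "CODON_DELETION")),
               c("LOW", "MODERATE"))
  expect_error(impact_category("NOT_AN_EFFECT"), "unknown effect")
})

test_that("codon-level calls agree with hand-translated codons on a mini gene", {
  # chrom 'c': CCCCCCCCCC ATGGATTAA CCC... ; CDS = ATG GAT TAA at 11..19
  seqs <- Biostrings::DNAStringSet(c(c = paste0(strrep("C", 10), "ATGGATTAA",
                                                strrep("C", 21))))
  models <- gene_models(
    genes = tibble::tibble(gene_id = "g", chrom = "c", start = 11, end = 19,
                           strand = "+"),
    transcripts = tibble::tibble(transcript_id = "t", gene_id = "g",
                                 chrom = "c", start = 11, end = 19,
                                 strand = "+"),
    features = tibble::tibble(transcript_id = "t",
                              feature = c("exon", "CDS"),
                              start = 11, end = 19, phase = c(NA, 0L)))
  cases <- tibble::tribble(
    ~pos, ~ref, ~alt, ~expected,
    16, "T", "A", "NON_SYNONYMOUS_CODING",  # GAT (Asp) -> GAA (Glu)
    16, "T", "C", "SYNONYMOUS_CODING",      # GAT (Asp) -> GAC (Asp)
    12, "T", "C", "START_LOST",             # ATG -> ACG
    11, "A", "G", "NON_SYNONYMOUS_START",   # ATG -> GTG
    18, "A", "G", "SYNONYMOUS_STOP",        # TAA -> TGA
    15, "A", "AC", "FRAME_SHIFT")
  calls <- make_calls("L", "c", cases$pos, ref = cases$ref, alt = cases$alt)
  ann <- annotate_effects(calls, models, seqs)
  expect_equal(ann$effect_type, cases$expected)
})

test_that("planted toy-gene variants reproduce all 23 effect labels", {
  sg <- simulate_gene_models(seed = 3)
  fwd <- dplyr::filter(sg$planted, gene_copy == "forward")
  ann <- annotate_effects(make_calls("L", fwd$chrom, fwd$pos, fwd$ref, fwd$alt),
                          sg$models, sg$seq)
  expect_equal(ann$effect_type, fwd$expected_effect)
  expect_setequal(ann$effect_type, effect_catalog()$effect_type)
})

test_that("the classifier is strand-symmetric on the mirrored gene copy", {
  sg <- simulate_gene_models(seed = 3)
  rev <- dplyr::filter(sg$planted, gene_copy == "reverse")
  ann <- annotate_effects(make_calls("L", rev$chrom, rev$pos, rev$ref, rev$alt),
                          sg$models, sg$seq)
  expect_equal(ann$effect_type, rev$expected_effect)
})

test_that("non-exonic assignment agrees with a brute-force positional oracle", {
  sg <- simulate_gene_models(seed = 6)
  # independent rule table for gene1 (+ strand; tx 2001..3500; introns
  # 2301..2500 and 2801..3000; splice sites = 2 intronic bp at each junction,
  # splice region = intronic bp 3..8 from a junction)
  oracle <- function(p) {
    donor <- c(2301, 2302, 2801, 2802)
    acceptor <- c(2499, 2500, 2999, 3000)
    region <- c(2303:2308, 2493:2498, 2803:2808, 2993:2998)
    if (p %in% donor) return("SPLICE_SITE_DONOR")
    if (p %in% acceptor) return("SPLICE_SITE_ACCEPTOR")
    if (p %in% region) return("SPLICE_SITE_REGION")
    if ((p >= 2301 && p <= 2500) || (p >= 2801 && p <= 3000)) return("INTRON")
    if (p >= 2001 - 5000 && p < 2001) return("UPSTREAM")
    if (p > 3500 && p <= 3500 + 5000) return("DOWNSTREAM")
    "INTERGENIC"
  }
  pos <- c(2301:2500, 2801:3000,            # every intronic base
           seq(1501, 2000, by = 25),        # upstream flank
           seq(3501, 4000, by = 25),        # downstream flank
           seq(9000, 9500, by = 25))        # far from every gene
  S <- as.character(sg$seq[["chrT"]])
  ref <- substring(S, pos, pos)
  alt <- c(A = "C", C = "G", G = "T", T = "A")[ref]
  ann <- annotate_effects(make_calls("L", "chrT", pos, ref, unname(alt)),
                          sg$models, sg$seq)
  expect_equal(ann$effect_type, vapply(pos, oracle, character(1)))
})

test_that("precomputed annotations are parsed, aliased and reduced to one effect", {
  p <- withr::local_tempfile(lines = c(
    "chrom\tpos\tref\talt\teffect",
    "chr1\t100\tA\tG\tsynonymous_variant",
    "chr1\t200\tA\tG\tmissense_variant&intron_variant",
    "chr1\t300\tA\tG\tFRAME_SHIFT"))
  ann <- parse_effect_annotations(p)
  expect_equal(ann$effect_type,
               c("SYNONYMOUS_CODING", "NON_SYNONYMOUS_CODING", "FRAME_SHIFT"))
  expect_equal(ann$impact, c("LOW", "MODERATE", "HIGH"))

  bad <- withr::local_tempfile(lines = c(
    "chrom\tpos\tref\talt\teffect", "chr1\t1\tA\tG\tmystery_effect"))
  expect_error(parse_effect_annotations(bad), "mystery_effect")

  vcf <- withr::local_tempfile(lines = c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=ANN,Number=.,Type=String,Description=\"ann\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    paste0("chr1\t50\t.\tA\tG\t60\t.\t",
           "ANN=G|intron_variant|MODIFIER|g1,G|missense_variant|MODERATE|g1")))
  ann2 <- parse_effect_annotations(vcf)
  expect_equal(ann2$effect_type, "NON_SYNONYMOUS_CODING")
})

test_that("rolling up parsed classifier output equals the direct rollup", {
  sg <- simulate_gene_models(seed = 3)
  fwd <- dplyr::filter(sg$planted, gene_copy == "forward")
  ann <- annotate_effects(make_calls("L1", fwd$chrom, fwd$pos, fwd$ref, fwd$alt),
                          sg$models, sg$seq)
  p <- withr::local_tempfile()
  readr::write_tsv(dplyr::transmute(ann, chrom, pos, ref, alt,
                                    effect = effect_type), p)
  reparsed <- parse_effect_annotations(p)
  groups <- list(G = "L1")
  direct <- effect_rollup(ann, groups)
  via_file <- effect_rollup(dplyr::mutate(reparsed, line_id = "L1"), groups)
  expect_equal(direct$counts, via_file$counts)
  expect_equal(direct$impact_pct, via_file$impact_pct)
})

test_that("rollup percentages are per-group shares of line-specific totals", {
  one <- effect_rollup(tibble::tibble(line_id = "A", effect_type = "INTRON"),
                       groups = list(G = "A"))
  expect_equal(one$impact_pct$pct[one$impact_pct$impact == "MODIFIER"], 100)

  sim <- tibble::tibble(
    line_id = rep(c("A", "B"), each = 100),
    effect_type = rep(c("INTERGENIC", "SYNONYMOUS_CODING", "FRAME_SHIFT",
                        "NON_SYNONYMOUS_CODING"), each = 25, times = 2))
  ru <- effect_rollup(sim, groups = list(G1 = "A", G2 = "B"))
  pct <- dplyr::summarise(dplyr::group_by(ru$impact_pct, group),
                          total = sum(pct))
  expect_true(all(abs(pct$total - 100) < 0.1))
  expect_equal(ru$line_totals$n_total, c(100, 100))
  expect_true(all(ru$impact_pct$pct == 25))
})
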