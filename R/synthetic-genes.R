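# Deterministic toy locus set for exercising the effect classifier: one
# fully featured forward-strand gene, an exact reverse-complement copy of it
# on the minus strand (for strand-symmetry checks), and a bare gene record
# with no transcript (INTRAGENIC). Planted variants cover all 23 effect
# types; their expected labels are fixed by construction of the sequence,
# not by running the classifier.

# gene1 layout on chrT (1-based; local coordinate = genomic - 2000)
G1_START <- 2001
G1_END <- 3500
G2_START <- 20001
G2_END <- 21500
CHRT_LEN <- 30000
mirror_pos <- function(p) G2_START + (G1_END - p)  # 23501 - p

cycle_base <- function(b) {
  c(A = "C", C = "G", G = "T", T = "A")[b]
}

build_chrT <- function(seed) {
  set.seed(seed)
  s <- sample(c("A", "C", "G", "T"), CHRT_LEN, replace = TRUE)
  region <- s[G1_START:G1_END]
  ct <- rep(c("C", "T"), length.out = 500)
  region[1:200] <- ct[1:200]                      # 5'UTR, no A/G -> no ATG
  region[100:102] <- c("T", "T", "G")             # START_GAINED site (T>A)
  # designed CDS: ATG + 165 x GCT (codon 20 = TAT) + TAA
  codons <- c("ATG", rep("GCT", 165), "TAA")
  codons[20] <- "TAT"
  cds <- strsplit(paste(codons, collapse = ""), "")[[1]]  # 501 bases
  region[201:300] <- cds[1:100]                   # CDS exon 1
  region[501:800] <- cds[101:400]                 # CDS exon 2
  region[1001:1101] <- cds[401:501]               # CDS exon 3
  region[1102:1500] <- rep(c("C", "T"), length.out = 399)  # 3'UTR
  region[301:302] <- c("G", "T"); region[499:500] <- c("A", "G")  # intron 1
  region[801:802] <- c("G", "T"); region[999:1000] <- c("A", "G") # intron 2
  s[G1_START:G1_END] <- region
  s[G2_START:G2_END] <- rev(chartr("ACGT", "TGCA", region))
  paste(s, collapse = "")
}

toy_gene_features <- function() {
  # forward gene1: exons, CDS pieces, UTRs (1-based inclusive, genomic)
  f1 <- tibble(
    transcript_id = "t1",
    feature = c("exon", "exon", "exon",
                "five_prime_UTR", "CDS", "CDS", "CDS", "three_prime_UTR"),
    start = c(2001, 2501, 3001, 2001, 2201, 2501, 3001, 3102),
    end = c(2300, 2800, 3500, 2200, 2300, 2800, 3101, 3500),
    phase = c(NA, NA, NA, NA, 0L, 2L, 2L, NA))
  # mirrored gene2: same features reflected into [G2_START, G2_END]
  f2 <- f1 |>
    mutate(transcript_id = "t2",
           new_start = mirror_pos(.data$end),
           new_end = mirror_pos(.data$start)) |>
    mutate(start = .data$new_start, end = .data$new_end) |>
    select(-"new_start", -"new_end")
  bind_rows(f1, f2)
}

toy_gene_models <- function() {
  genes <- tibble(gene_id = c("g1", "g2", "g3"),
                  chrom = "chrT",
                  start = c(G1_START, G2_START, 27001),
                  end = c(G1_END, G2_END, 28000),
                  strand = c("+", "-", "+"))
  tx <- tibble(transcript_id = c("t1", "t2"),
               gene_id = c("g1", "g2"),
               chrom = "chrT",
               start = c(G1_START, G2_START),
               end = c(G1_END, G2_END),
               strand = c("+", "-"))
  gene_models(genes, tx, toy_gene_features())
}

# planted forward-strand variants (gene1) with construction-fixed labels
plant_forward <- function(S) {
  base_at <- function(p) substr(S, p, p)
  seg <- function(a, b) substr(S, a, b)
  snp <- function(pos, alt, effect) {
    tibble(pos = pos, ref = base_at(pos), alt = alt, var_type = "SNP",
           expected_effect = effect)
  }
  snp_any <- function(pos, effect) snp(pos, unname(cycle_base(base_at(pos))), effect)
  ins <- function(pos, insert, effect) {
    tibble(pos = pos, ref = base_at(pos), alt = paste0(base_at(pos), insert),
           var_type = "INS", expected_effect = effect)
  }
  del <- function(pos, len, effect) {  # deletes len bases after anchor `pos`
    tibble(pos = pos, ref = seg(pos, pos + len), alt = base_at(pos),
           var_type = "DEL", expected_effect = effect)
  }
  bind_rows(
    ins(2650, "A", "FRAME_SHIFT"),
    snp_any(2499, "SPLICE_SITE_ACCEPTOR"),
    snp_any(2301, "SPLICE_SITE_DONOR"),
    snp(2202, "C", "START_LOST"),                 # ATG -> ACG
    snp(2260, "A", "STOP_GAINED"),                # TAT -> TAA
    snp(3101, "C", "STOP_LOST"),                  # TAA -> TAC
    del(2549, 3, "CODON_CHANGE_PLUS_CODON_DELETION"),
    ins(2560, "AAA", "CODON_CHANGE_PLUS_CODON_INSERTION"),
    del(2601, 3, "CODON_DELETION"),
    ins(2610, "GGG", "CODON_INSERTION"),
    snp(2758, "C", "NON_SYNONYMOUS_CODING"),      # GCT -> CCT (Ala -> Pro)
    snp(2201, "G", "NON_SYNONYMOUS_START"),       # ATG -> GTG
    snp_any(2305, "SPLICE_SITE_REGION"),
    snp(2100, "A", "START_GAINED"),               # TTG -> ATG in 5'UTR
    snp(2790, "C", "SYNONYMOUS_CODING"),          # GCT -> GCC (Ala)
    snp(3101, "G", "SYNONYMOUS_STOP"),            # TAA -> TAG
    snp_any(3601, "DOWNSTREAM"),
    snp_any(10000, "INTERGENIC"),
    snp_any(27500, "INTRAGENIC"),
    snp_any(2900, "INTRON"),
    snp_any(1001, "UPSTREAM"),
    snp_any(3300, "UTR_3_PRIME"),
    snp(2050, "C", "UTR_5_PRIME")
  ) |>
    mutate(chrom = "chrT", gene_copy = "forward")
}

# reflect an in-region planted variant onto the minus-strand gene copy
mirror_variant <- function(v, S) {
  base_at <- function(p) substr(S, p, p)
  rc <- function(x) revcomp(x)
  if (v$var_type == "SNP") {
    p2 <- mirror_pos(v$pos)
    tibble(pos = p2, ref = base_at(p2), alt = rc(v$alt), var_type = "SNP")
  } else if (v$var_type == "INS") {
    p2 <- mirror_pos(v$pos + 1)
    insert <- substr(v$alt, 2, nchar(v$alt))
    tibble(pos = p2, ref = base_at(p2),
           alt = paste0(base_at(p2), rc(insert)), var_type = "INS")
  } else {
    L <- nchar(v$ref)
    a2 <- mirror_pos(v$pos + L - 1) - 1
    e2 <- mirror_pos(v$pos + 1)
    tibble(pos = a2, ref = substr(S, a2, e2), alt = base_at(a2),
           var_type = "DEL")
  }
}

#' Simulate toy gene models with planted variants for every effect type
#'
#' Builds a small deterministic locus set: a three-exon coding gene with
#' UTRs and introns, an exact reverse-complement copy of it on the minus
#' strand, and a transcript-less gene record. Plants one variant per effect
#' type on the forward gene (plus flanking and intergenic variants), with
#' the expected label fixed by construction of the designed sequence, and a
#' mirrored copy of each sequence-dependent variant on the minus-strand gene
#' so that strand symmetry of the classifier can be checked.
#'
#' @param seed Seed for the background sequence.
#' @param dir Optional directory; when given, writes `genes.gff3`,
#'   `genome.fasta` and `genome_index.tsv` there.
#' @return A list of class `sim_genes` with elements `genome`
#'   (a [genome_index()]), `seq` (a `DNAStringSet`), `models`
#'   (a [gene_models()] set) and `planted` (variants with columns
#'   `chrom`, `pos`, `ref`, `alt`, `var_type`, `expected_effect`,
#'   `gene_copy`).
#' @export
simulate_gene_models <- function(seed = 1, dir = NULL) {
  S <- build_chrT(seed)
  genome <- genome_index("chrT", CHRT_LEN)
  models <- toy_gene_models()
  fwd <- plant_forward(S)
  in_region <- fwd$pos >= G1_START & fwd$pos <= G1_END
  rev_rows <- purrr::map(which(in_region), function(i) {
    v <- fwd[i, ]
    mirror_variant(v, S) |>
      mutate(chrom = "chrT", expected_effect = v$expected_effect,
             gene_copy = "reverse")
  }) |> bind_rows()
  flank_rev <- bind_rows(
    tibble(pos = 22500, var_type = "SNP", expected_effect = "UPSTREAM"),
    tibble(pos = 19901, var_type = "SNP", expected_effect = "DOWNSTREAM")
  ) |>
    mutate(chrom = "chrT", ref = substr(S, .data$pos, .data$pos),
           alt = unname(cycle_base(.data$ref)), gene_copy = "reverse")
  planted <- bind_rows(fwd, rev_rows, flank_rev) |>
    select("chrom", "pos", "ref", "alt", "var_type", "expected_effect",
           "gene_copy")
  seq <- Biostrings::DNAStringSet(setNames(S, "chrT"))
  out <- structure(list(genome = genome, seq = seq, models = models,
                        planted = planted, seed = seed),
                   class = "sim_genes")
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_gene_models(models, file.path(dir, "genes.gff3"))
    Biostrings::writeXStringSet(seq, file.path(dir, "genome.fasta"))
    write_genome_index(genome, file.path(dir, "genome_index.tsv"))
  }
  out
}
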