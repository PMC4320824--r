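# Single-effect coding-consequence classifier. Each variant receives exactly
# one effect (the most severe applicable under the fixed catalogue order),
# so per-line effect counts sum exactly to the line-specific totals.

#' Settings for the effect classifier
#'
#' Distance parameters follow the SNPEff defaults: 5,000 bp up/downstream of
#' the gene span; the 2 intronic bases flanking each exon junction are splice
#' donor/acceptor sites; intronic bases 3-8 from a junction and the first or
#' last 3 exonic bases of an internal exon edge are the splice region.
#'
#' @param upstream_distance,downstream_distance Distances in bp from the gene
#'   span within which a variant is UPSTREAM/DOWNSTREAM.
#' @param splice_site_size Intronic bases at each junction treated as splice
#'   acceptor/donor sites.
#' @param splice_region_intron Two integers: the intronic base range (from
#'   the junction) counted as splice region.
#' @param splice_region_exon Exonic bases at an internal exon edge counted as
#'   splice region.
#' @return A list of class `effect_config`.
#' @export
effect_config <- function(upstream_distance = 5000, downstream_distance = 5000,
                          splice_site_size = 2,
                          splice_region_intron = c(3, 8),
                          splice_region_exon = 3) {
  structure(list(upstream_distance = upstream_distance,
                 downstream_distance = downstream_distance,
                 splice_site_size = splice_site_size,
                 splice_region_intron = splice_region_intron,
                 splice_region_exon = splice_region_exon),
            class = "effect_config")
}

#' Assemble a gene-model set
#'
#' @param genes Tibble with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @param transcripts Tibble with columns `transcript_id`, `gene_id`,
#'   `chrom`, `start`, `end`, `strand`.
#' @param features Tibble with columns `transcript_id`, `feature` (one of
#'   `exon`, `CDS`, `five_prime_UTR`, `three_prime_UTR`), `start`, `end`,
#'   `phase` (NA except CDS). All coordinates 1-based inclusive.
#' @return A list of class `gene_models`.
#' @export
gene_models <- function(genes, transcripts, features) {
  out <- list(genes = as_tibble(genes), transcripts = as_tibble(transcripts),
              features = as_tibble(features))
  cds_len <- out$features |>
    filter(.data$feature == "CDS") |>
    group_by(.data$transcript_id) |>
    summarise(len = sum(.data$end - .data$start + 1), .groups = "drop")
  bad <- cds_len$transcript_id[cds_len$len %% 3 != 0]
  if (length(bad) > 0) {
    warn(paste0("CDS length not divisible by 3 (classified best-effort): ",
                paste(bad, collapse = ", ")))
  }
  structure(out, class = "gene_models")
}

#' Read gene models from GFF3
#'
#' Uses \pkg{rtracklayer} to parse GFF3 and normalizes gene / mRNA / exon /
#' CDS / UTR records into a [gene_models()] set.
#'
#' @param path Path to a GFF3 file.
#' @return A `gene_models` list.
#' @export
read_gene_models <- function(path) {
  g <- rtracklayer::import(path, format = "gff3")
  d <- as_tibble(as.data.frame(g))
  d$type <- as.character(d$type)
  d$seqnames <- as.character(d$seqnames)
  d$strand <- as.character(d$strand)
  d$parent <- purrr::map_chr(as.list(d$Parent), function(p) {
    if (length(p) == 0) NA_character_ else as.character(p[[1]])
  })
  genes <- d |>
    filter(.data$type == "gene") |>
    transmute(gene_id = .data$ID, chrom = .data$seqnames,
              start = as.numeric(.data$start), end = as.numeric(.data$end),
              strand = .data$strand)
  tx <- d |>
    filter(.data$type %in% c("mRNA", "transcript")) |>
    transmute(transcript_id = .data$ID, gene_id = .data$parent,
              chrom = .data$seqnames,
              start = as.numeric(.data$start), end = as.numeric(.data$end),
              strand = .data$strand)
  feat_types <- c(exon = "exon", CDS = "CDS",
                  five_prime_UTR = "five_prime_UTR",
                  three_prime_UTR = "three_prime_UTR")
  sel <- d$type %in% names(feat_types)
  features <- tibble(transcript_id = d$parent[sel],
                     feature = unname(feat_types[d$type[sel]]),
                     start = as.numeric(d$start[sel]),
                     end = as.numeric(d$end[sel]),
                     phase = suppressWarnings(as.integer(d$phase[sel])))
  gene_models(genes, tx, features)
}

#' Write gene models as GFF3
#'
#' @param models A `gene_models` list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  rows <- function(type, id, parent, chrom, start, end, strand, phase = NA) {
    n <- length(start)
    id <- rep_len(id, n)
    parent <- rep_len(parent, n)
    phase <- rep_len(phase, n)
    attr_col <- dplyr::case_when(
      is.na(parent) ~ paste0("ID=", id),
      is.na(id) ~ paste0("Parent=", parent),
      .default = paste0("ID=", id, ";Parent=", parent))
    tibble(chrom = chrom, source = "varcohort", type = type,
           start = start, end = end, score = ".", strand = strand,
           phase = ifelse(is.na(phase), ".", as.character(phase)),
           attributes = attr_col)
  }
  g <- models$genes
  t <- models$transcripts
  f <- t |>
    select("transcript_id", tx_strand = "strand", tx_chrom = "chrom") |>
    right_join(models$features, by = "transcript_id")
  gff_type <- c(exon = "exon", CDS = "CDS",
                five_prime_UTR = "five_prime_UTR",
                three_prime_UTR = "three_prime_UTR")
  out <- bind_rows(
    rows("gene", g$gene_id, NA, g$chrom, g$start, g$end, g$strand),
    rows("mRNA", t$transcript_id, t$gene_id, t$chrom, t$start, t$end, t$strand),
    rows(unname(gff_type[f$feature]),
         NA, f$transcript_id, f$tx_chrom, f$start, f$end, f$tx_strand, f$phase)
  ) |>
    arrange(.data$chrom, .data$start,
            match(.data$type, c("gene", "mRNA", "exon", "five_prime_UTR",
                                "CDS", "three_prime_UTR")))
  body <- do.call(paste, c(as.list(out), sep = "\t"))
  writeLines(c("##gff-version 3", body), path)
  invisible(path)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

codon_aa <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

# Precompute per-transcript structures used by the classifier.
build_tx_data <- function(models, seq) {
  chrom_seq <- purrr::map(setNames(names(seq), names(seq)),
                          function(ch) as.character(seq[[ch]]))
  purrr::pmap(models$transcripts, function(transcript_id, gene_id, chrom,
                                           start, end, strand, ...) {
    feats <- models$features[models$features$transcript_id == transcript_id, ]
    exons <- feats |> filter(.data$feature == "exon") |> arrange(.data$start)
    cds <- feats |> filter(.data$feature == "CDS") |> arrange(.data$start)
    cds_pos <- if (nrow(cds) > 0) {
      p <- unlist(purrr::map2(cds$start, cds$end, base::seq))
      if (strand == "-") rev(p) else p
    } else numeric(0)
    cds_seq <- if (nrow(cds) > 0) {
      s <- paste(purrr::map2_chr(cds$start, cds$end, function(a, b) {
        substr(chrom_seq[[chrom]], a, b)
      }), collapse = "")
      if (strand == "-") revcomp(s) else s
    } else ""
    # introns between consecutive exons (genomic order)
    introns <- if (nrow(exons) > 1) {
      tibble(start = exons$end[-nrow(exons)] + 1, end = exons$start[-1] - 1)
    } else tibble(start = numeric(0), end = numeric(0))
    list(transcript_id = transcript_id, gene_id = gene_id, chrom = chrom,
         tx_start = start, tx_end = end, strand = strand,
         exons = exons, cds = cds, introns = introns,
         cds_pos = cds_pos, cds_seq = cds_seq,
         chrom_seq = chrom_seq[[chrom]])
  })
}

span_hits <- function(s, e, starts, ends) {
  any(s <= ends & e >= starts)
}

# all applicable effects of one variant against one transcript
tx_effects <- function(tx, pos, ref, alt, var_type, cfg) {
  s <- pos; e <- pos
  if (var_type == "DEL") {
    s <- pos + nchar(alt)
    e <- pos + nchar(ref) - 1
  }
  eff <- character(0)
  if (e < tx$tx_start || s > tx$tx_end) {
    # flanking regions, strand-aware
    if (s > tx$tx_end && s - tx$tx_end <= ifelse(tx$strand == "+",
                                                 cfg$downstream_distance,
                                                 cfg$upstream_distance)) {
      eff <- c(eff, if (tx$strand == "+") "DOWNSTREAM" else "UPSTREAM")
    }
    if (e < tx$tx_start && tx$tx_start - e <= ifelse(tx$strand == "+",
                                                     cfg$upstream_distance,
                                                     cfg$downstream_distance)) {
      eff <- c(eff, if (tx$strand == "+") "UPSTREAM" else "DOWNSTREAM")
    }
    return(eff)
  }
  # splice donor/acceptor: first/last `splice_site_size` bases of each intron
  k <- cfg$splice_site_size
  if (nrow(tx$introns) > 0) {
    for (i in seq_len(nrow(tx$introns))) {
      is <- tx$introns$start[i]; ie <- tx$introns$end[i]
      left <- c(is, min(is + k - 1, ie))    # intron 5' (genomic) edge
      right <- c(max(ie - k + 1, is), ie)   # intron 3' (genomic) edge
      left_eff <- if (tx$strand == "+") "SPLICE_SITE_DONOR" else "SPLICE_SITE_ACCEPTOR"
      right_eff <- if (tx$strand == "+") "SPLICE_SITE_ACCEPTOR" else "SPLICE_SITE_DONOR"
      if (span_hits(s, e, left[1], left[2])) eff <- c(eff, left_eff)
      if (span_hits(s, e, right[1], right[2])) eff <- c(eff, right_eff)
      # splice region: intronic bases splice_region_intron[1]..[2] from edges
      ri <- cfg$splice_region_intron
      if (span_hits(s, e, min(is + ri[1] - 1, ie), min(is + ri[2] - 1, ie)) ||
          span_hits(s, e, max(ie - ri[2] + 1, is), max(ie - ri[1] + 1, is))) {
        eff <- c(eff, "SPLICE_SITE_REGION")
      }
    }
    # splice region: first/last `splice_region_exon` exonic bases at internal edges
    rx <- cfg$splice_region_exon
    for (i in seq_len(nrow(tx$exons))) {
      es <- tx$exons$start[i]; ee <- tx$exons$end[i]
      if (i > 1 && span_hits(s, e, es, min(es + rx - 1, ee))) {
        eff <- c(eff, "SPLICE_SITE_REGION")
      }
      if (i < nrow(tx$exons) && span_hits(s, e, max(ee - rx + 1, es), ee)) {
        eff <- c(eff, "SPLICE_SITE_REGION")
      }
    }
  }
  in_exon <- nrow(tx$exons) > 0 && span_hits(s, e, tx$exons$start, tx$exons$end)
  in_cds <- nrow(tx$cds) > 0 && span_hits(s, e, tx$cds$start, tx$cds$end)
  if (in_cds) {
    eff <- c(eff, coding_effects(tx, pos, ref, alt, var_type))
  } else if (in_exon) {
    if (nrow(tx$cds) > 0) {
      cds_min <- min(tx$cds$start); cds_max <- max(tx$cds$end)
      five <- if (tx$strand == "+") e < cds_min else s > cds_max
      eff <- c(eff, if (five) "UTR_5_PRIME" else "UTR_3_PRIME")
      if (five && var_type == "SNP" && start_gained(tx, pos, ref, alt)) {
        eff <- c(eff, "START_GAINED")
      }
    } else {
      eff <- c(eff, "INTRAGENIC")
    }
  } else if (nrow(tx$introns) > 0 &&
             span_hits(s, e, tx$introns$start, tx$introns$end)) {
    eff <- c(eff, "INTRON")
  }
  eff
}

# does a 5'UTR SNP create a new ATG (coding strand)?
start_gained <- function(tx, pos, ref, alt) {
  cs <- tx$chrom_seq
  for (off in 0:2) {
    a <- pos - off; b <- a + 2
    if (a < 1 || b > nchar(cs)) next
    win_ref <- substr(cs, a, b)
    win_alt <- win_ref
    substr(win_alt, off + 1, off + 1) <- alt
    if (tx$strand == "-") {
      win_ref <- revcomp(win_ref)
      win_alt <- revcomp(win_alt)
    }
    if (win_alt == "ATG" && win_ref != "ATG") return(TRUE)
  }
  FALSE
}

coding_effects <- function(tx, pos, ref, alt, var_type) {
  cds_len <- length(tx$cds_pos)
  cds_index <- function(p) match(p, tx$cds_pos)
  if (var_type == "SNP") {
    ci <- cds_index(pos)
    if (is.na(ci)) return(character(0))
    codon_i <- (ci - 1) %/% 3
    off <- (ci - 1) %% 3 + 1
    codon <- substr(tx$cds_seq, 3 * codon_i + 1, 3 * codon_i + 3)
    if (nchar(codon) < 3) return("NON_SYNONYMOUS_CODING")  # truncated model
    alt_c <- if (tx$strand == "-") revcomp(alt) else alt
    alt_codon <- codon
    substr(alt_codon, off, off) <- alt_c
    if (codon_i == 0) {
      if (codon_aa(codon) == "M" || codon == "ATG") {
        if (alt_codon %in% c("GTG", "TTG")) return("NON_SYNONYMOUS_START")
        return("START_LOST")
      }
    }
    ref_aa <- codon_aa(codon)
    alt_aa <- codon_aa(alt_codon)
    if (ref_aa == "*") {
      if (alt_aa == "*") return("SYNONYMOUS_STOP")
      return("STOP_LOST")
    }
    if (alt_aa == "*") return("STOP_GAINED")
    if (alt_aa == ref_aa) return("SYNONYMOUS_CODING")
    return("NON_SYNONYMOUS_CODING")
  }
  if (var_type == "INS") {
    ilen <- nchar(alt) - nchar(ref)
    if (ilen %% 3 != 0) return("FRAME_SHIFT")
    i1 <- cds_index(pos); i2 <- cds_index(pos + 1)
    b <- if (!is.na(i1) && !is.na(i2)) {
      min(i1, i2)
    } else if (!is.na(i1)) {
      if (tx$strand == "+") i1 else i1 - 1
    } else if (!is.na(i2)) {
      if (tx$strand == "+") i2 - 1 else i2
    } else {
      return(character(0))
    }
    if (b %% 3 == 0) return("CODON_INSERTION")
    return("CODON_CHANGE_PLUS_CODON_INSERTION")
  }
  if (var_type == "DEL") {
    dpos <- seq(pos + nchar(alt), pos + nchar(ref) - 1)
    cind <- cds_index(dpos)
    cind <- cind[!is.na(cind)]
    if (length(cind) == 0) return(character(0))
    if (length(cind) %% 3 != 0) return("FRAME_SHIFT")
    eff <- character(0)
    if (any(cind <= 3)) eff <- c(eff, "START_LOST")
    if (any(cind > cds_len - 3)) eff <- c(eff, "STOP_LOST")
    eff <- c(eff, if ((min(cind) - 1) %% 3 == 0) "CODON_DELETION"
                  else "CODON_CHANGE_PLUS_CODON_DELETION")
    return(eff)
  }
  character(0)  # COMPLEX: no coding classification
}

#' Assign one effect type per variant
#'
#' Classifies each variant against all overlapping (or nearby) gene models
#' and keeps the single most severe applicable effect under the fixed
#' [effect_catalog()] ordering. Variants inside a gene span but in no
#' transcript feature are INTRAGENIC; variants overlapping no gene and beyond
#' the up/downstream distances are INTERGENIC.
#'
#' @param calls A call tibble (typically line-specific variants).
#' @param models A [gene_models()] set.
#' @param seq A [Biostrings::DNAStringSet] of chromosome sequences (needed
#'   for codon-level classification).
#' @param config An [effect_config()].
#' @return The input rows with `effect_type`, `impact` and `gene_id` columns
#'   appended.
#' @export
annotate_effects <- function(calls, models, seq, config = effect_config()) {
  calls <- as_tibble(calls)
  if (nrow(calls) == 0) {
    return(mutate(calls, effect_type = character(0), impact = character(0),
                  gene_id = character(0)))
  }
  bad_chrom <- setdiff(unique(calls$chrom), names(seq))
  if (length(bad_chrom) > 0) {
    abort(paste0("variant on unknown chromosome: ",
                 paste(bad_chrom, collapse = ", ")))
  }
  txs <- build_tx_data(models, seq)
  genes <- models$genes
  buffer <- max(config$upstream_distance, config$downstream_distance)
  res <- purrr::pmap(calls[, c("chrom", "pos", "ref", "alt", "var_type")],
                     function(chrom, pos, ref, alt, var_type) {
    cand <- character(0); cand_gene <- character(0)
    for (tx in txs) {
      if (tx$chrom != chrom) next
      if (pos + nchar(ref) < tx$tx_start - buffer || pos > tx$tx_end + buffer) next
      eff <- tx_effects(tx, pos, ref, alt, var_type, config)
      if (length(eff) > 0) {
        cand <- c(cand, eff)
        cand_gene <- c(cand_gene, rep(tx$gene_id, length(eff)))
      }
    }
    # inside a gene span but no transcript-level effect -> INTRAGENIC
    if (length(cand) == 0 && nrow(genes) > 0) {
      g <- genes[genes$chrom == chrom & genes$start <= pos &
                   genes$end >= pos, , drop = FALSE]
      if (nrow(g) > 0) {
        cand <- "INTRAGENIC"
        cand_gene <- g$gene_id[1]
      }
    }
    if (length(cand) == 0) {
      return(list(effect_type = "INTERGENIC", gene_id = NA_character_))
    }
    i <- which.min(effect_severity(cand))
    list(effect_type = cand[i], gene_id = cand_gene[i])
  })
  calls$effect_type <- purrr::map_chr(res, "effect_type")
  calls$impact <- impact_category(calls$effect_type)
  calls$gene_id <- purrr::map_chr(res, "gene_id")
  calls
}

#' Parse precomputed effect annotations
#'
#' Alternate input path so the pipeline can consume an external annotator's
#' output instead of the built-in classifier. Accepts either a tab-separated
#' table with columns `chrom`, `pos`, `ref`, `alt`, `effect` (effects
#' possibly `&`- or `,`-separated), or a VCF whose INFO field carries
#' `ANN=allele|effect|...` entries. When several effects are listed for one
#' variant, the single most severe is retained. Both classic effect names and
#' their Sequence-Ontology aliases (e.g. `synonymous_variant`) are accepted;
#' unknown effect strings raise an error listing the offenders.
#'
#' @param path Path to the TSV or VCF file.
#' @param format `"auto"` (by extension/content), `"tsv"` or `"vcf"`.
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt`, `effect_type`,
#'   `impact`.
#' @export
parse_effect_annotations <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1)
    format <- if (startsWith(first, "##fileformat=VCF")) "vcf" else "tsv"
  }
  if (format == "tsv") {
    d <- readr::read_tsv(path, col_types = readr::cols(
      chrom = "c", pos = "d", ref = "c", alt = "c", effect = "c"),
      progress = FALSE)
    eff_strings <- d$effect
  } else {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
    ann <- vcfR::extract.info(v, "ANN")
    eff_strings <- purrr::map_chr(strsplit(ann, ",", fixed = TRUE), function(entries) {
      paste(purrr::map_chr(strsplit(entries, "|", fixed = TRUE), function(f) {
        if (length(f) >= 2) f[2] else f[1]
      }), collapse = "&")
    })
    d <- tibble(chrom = fix$CHROM, pos = as.numeric(fix$POS),
                ref = fix$REF, alt = fix$ALT)
  }
  tokens <- strsplit(eff_strings, "[&,]")
  canon <- purrr::map(tokens, function(tk) {
    tk <- trimws(tk)
    out <- ifelse(tk %in% EFFECT_CATALOG$effect_type, tk,
                  unname(EFFECT_ALIASES[tk]))
    out
  })
  unknown <- unique(unlist(purrr::map2(tokens, canon, ~ .x[is.na(.y)])))
  if (length(unknown) > 0) {
    abort(paste0("unknown effect string(s): ", paste(unknown, collapse = ", ")))
  }
  d$effect_type <- unname(purrr::map_chr(canon, most_severe_effect))
  d$impact <- impact_category(d$effect_type)
  d[, c("chrom", "pos", "ref", "alt", "effect_type", "impact")]
}

#' Roll up per-line effect assignments into a classification table
#'
#' Produces the per-line counts of each effect type and, per group, the
#' percentage of line-specific variants in each impact category
#' (group category count / group line-specific total x 100).
#'
#' @param assignments Either per-variant rows with `line_id` and
#'   `effect_type` columns, or pre-tabulated counts with `line_id`,
#'   `effect_type`, `n`.
#' @param groups Named list mapping group label to line ids.
#' @return An object of class `effect_rollup` with elements `counts` (23
#'   effect types x lines, zero-filled, with impact), `line_totals` and
#'   `impact_pct` (group x impact percentages). [generics::tidy()] returns
#'   the counts; [generics::glance()] the group percentages in wide form.
#' @export
effect_rollup <- function(assignments, groups) {
  assignments <- as_tibble(assignments)
  if (!"n" %in% names(assignments)) {
    assignments <- count(assignments, .data$line_id, .data$effect_type, name = "n")
  }
  bad <- setdiff(unique(assignments$effect_type), EFFECT_CATALOG$effect_type)
  if (length(bad) > 0) {
    abort(paste0("unknown effect type(s): ", paste(bad, collapse = ", ")))
  }
  line_ids <- unique(c(unlist(groups), unique(assignments$line_id)))
  counts <- tidyr::expand_grid(effect_type = EFFECT_CATALOG$effect_type,
                               line_id = line_ids) |>
    left_join(assignments, by = c("effect_type", "line_id")) |>
    mutate(n = dplyr::coalesce(.data$n, 0L),
           impact = impact_category(.data$effect_type)) |>
    select("impact", "effect_type", "line_id", "n")
  line_totals <- counts |>
    group_by(.data$line_id) |>
    summarise(n_total = sum(.data$n), .groups = "drop")
  impact_pct <- purrr::imap(groups, function(lines, label) {
    gc <- filter(counts, .data$line_id %in% lines)
    total <- sum(gc$n)
    gc |>
      group_by(.data$impact) |>
      summarise(n = sum(.data$n), .groups = "drop") |>
      mutate(group = label,
             pct = if (total > 0) .data$n / total * 100 else NA_real_)
  }) |>
    bind_rows() |>
    mutate(impact = factor(.data$impact,
                           levels = c("HIGH", "MODERATE", "LOW", "MODIFIER"))) |>
    arrange(.data$group, .data$impact) |>
    select("group", "impact", "n", "pct")
  structure(list(counts = counts, line_totals = line_totals,
                 impact_pct = impact_pct, groups = groups),
            class = "effect_rollup")
}

#' @export
print.effect_rollup <- function(x, ...) {
  cat("<effect_rollup>\n")
  print(x$line_totals)
  print(x$impact_pct)
  invisible(x)
}

#' @rdname effect_rollup
#' @param x An `effect_rollup`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.effect_rollup <- function(x, ...) {
  x$counts
}

#' @rdname effect_rollup
#' @exportS3Method generics::glance
glance.effect_rollup <- function(x, ...) {
  x$impact_pct |>
    select("group", "impact", "pct") |>
    tidyr::pivot_wider(names_from = "impact", values_from = "pct")
}
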