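# I/O boundary: every external coordinate convention (1-based VCF, 0-based
# half-open bedgraph) is converted here; everything internal is 1-based
# inclusive.

#' Build a genome index
#'
#' The genome index is the coordinate authority for the whole pipeline: an
#' ordered chromosome catalogue with lengths and, optionally, centromere
#' midpoints.
#'
#' @param chrom Character vector of unique chromosome names, in display order.
#' @param length Positive integer chromosome lengths in bp.
#' @param centromere_mid Optional named numeric vector of centromere midpoint
#'   positions (bp, 1-based), named by chromosome.
#' @return A tibble of class `genome_index` with columns `chrom`, `length`
#'   and `centromere_mid` (`NA` where unknown).
#' @seealso [read_genome_index()], [genome_total_length()]
#' @export
genome_index <- function(chrom, length, centromere_mid = NULL) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (anyDuplicated(chrom)) {
    abort(paste0("duplicate chromosome name(s): ",
                 paste(unique(chrom[duplicated(chrom)]), collapse = ", ")))
  }
  if (any(!is.finite(length)) || any(length <= 0)) {
    abort("chromosome lengths must be positive")
  }
  cen <- rep(NA_real_, base::length(chrom))
  if (!is.null(centromere_mid) && base::length(centromere_mid) > 0) {
    if (is.null(names(centromere_mid))) {
      abort("centromere_mid must be named by chromosome")
    }
    bad <- setdiff(names(centromere_mid), chrom)
    if (base::length(bad) > 0) {
      abort(paste0("centromere position for unknown chromosome: ",
                   paste(bad, collapse = ", ")))
    }
    idx <- match(names(centromere_mid), chrom)
    if (any(centromere_mid < 1 | centromere_mid > length[idx])) {
      abort("centromere_mid outside [1, chromosome length]")
    }
    cen[idx] <- as.numeric(centromere_mid)
  }
  out <- tibble(chrom = chrom, length = length, centromere_mid = cen)
  class(out) <- c("genome_index", class(out))
  out
}

#' Total genome length of an index
#'
#' @param genome A `genome_index` tibble.
#' @return Sum of chromosome lengths in bp.
#' @export
genome_total_length <- function(genome) {
  sum(genome$length)
}

#' Read a genome index file
#'
#' Accepts a tab-separated name/length table; the `samtools faidx` `.fai`
#' dialect (extra columns after the first two) is accepted and the extra
#' columns are ignored. An optional companion centromere table
#' (chromosome, position) adds centromere midpoints.
#'
#' @param path Path to the tab-separated index (no header).
#' @param centromere_path Optional path to a 2-column tab-separated
#'   chromosome/position table (no header).
#' @return A `genome_index` tibble.
#' @examples
#' g <- read_genome_index(cohort_example("rice_genome_index.tsv"))
#' genome_total_length(g)
#' @export
read_genome_index <- function(path, centromere_path = NULL) {
  raw <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (ncol(raw) < 2) {
    abort(paste0("genome index needs >= 2 tab-separated columns: ", path))
  }
  len <- suppressWarnings(as.numeric(raw[[2]]))
  if (anyNA(len)) {
    abort(paste0("non-numeric chromosome length in ", path))
  }
  cen <- NULL
  if (!is.null(centromere_path)) {
    cen_raw <- readr::read_tsv(centromere_path, col_names = FALSE,
                               col_types = readr::cols(.default = "c"), progress = FALSE)
    cen <- setNames(as.numeric(cen_raw[[2]]), cen_raw[[1]])
  }
  genome_index(raw[[1]], len, centromere_mid = cen)
}

#' Write a genome index file
#'
#' @param genome A `genome_index` tibble.
#' @param path Output path (tab-separated name/length, no header).
#' @return `path`, invisibly.
#' @export
write_genome_index <- function(genome, path) {
  readr::write_tsv(genome[, c("chrom", "length")], path, col_names = FALSE,
                   progress = FALSE)
  invisible(path)
}

resolve_chrom <- function(chrom, genome, aliases = NULL, context = "record") {
  if (!is.null(aliases)) {
    hit <- match(chrom, names(aliases))
    chrom[!is.na(hit)] <- unname(aliases[hit[!is.na(hit)]])
  }
  unknown <- !(chrom %in% genome$chrom)
  if (any(unknown)) {
    abort(paste0("unknown chromosome in ", context, ": ",
                 paste(unique(chrom[unknown]), collapse = ", ")))
  }
  chrom
}

#' Read a per-line coverage track (bedgraph)
#'
#' Reads a `genomeCoverageBed`-style bedgraph (chrom, start, end, depth;
#' 0-based half-open) and normalizes it to 1-based inclusive intervals.
#' Intervals must be sorted and non-overlapping within each chromosome and
#' must lie within the chromosome bounds; zero-depth rows (as produced with
#' the `-bga` option) are accepted and count as uncovered.
#'
#' @param path Path to the bedgraph file.
#' @param genome A `genome_index` tibble used to validate coordinates.
#' @param line_id Identifier of the sequenced line the track belongs to.
#' @param aliases Optional named character vector mapping file chromosome
#'   names to index names (e.g. `c(chr01 = "chr1")`). No fuzzy matching is
#'   ever applied.
#' @return A tibble of class `coverage_track` with columns `line_id`,
#'   `chrom`, `start`, `end` (1-based inclusive) and `depth`.
#' @seealso [covered_length()]
#' @export
read_coverage_track <- function(path, genome, line_id, aliases = NULL) {
  raw <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "depth"),
                         col_types = "ciid", progress = FALSE)
  coverage_track(line_id = line_id, chrom = raw$chrom, start = raw$start + 1,
                 end = raw$end, depth = raw$depth, genome = genome,
                 aliases = aliases, context = path)
}

#' Assemble and validate a coverage track
#'
#' @param line_id Line identifier.
#' @param chrom,start,end,depth Parallel vectors of 1-based inclusive
#'   intervals and their read depth.
#' @param genome A `genome_index` tibble.
#' @param aliases Optional chromosome-name alias map (see
#'   [read_coverage_track()]).
#' @param context Label used in error messages.
#' @return A `coverage_track` tibble.
#' @export
coverage_track <- function(line_id, chrom, start, end, depth, genome,
                           aliases = NULL, context = "coverage track") {
  chrom <- resolve_chrom(chrom, genome, aliases, context)
  out <- tibble(line_id = line_id, chrom = chrom,
                start = as.numeric(start), end = as.numeric(end),
                depth = as.numeric(depth))
  if (any(out$start < 1) || any(out$end < out$start)) {
    abort(paste0("malformed interval in ", context))
  }
  chrom_len <- genome$length[match(out$chrom, genome$chrom)]
  if (any(out$end > chrom_len)) {
    abort(paste0("interval beyond chromosome end in ", context))
  }
  out <- arrange(out, match(.data$chrom, genome$chrom), .data$start)
  ov <- out |>
    group_by(.data$chrom) |>
    summarise(overlap = any(.data$start[-1] <= .data$end[-base::length(.data$end)]),
              .groups = "drop")
  if (any(ov$overlap, na.rm = TRUE)) {
    abort(paste0("overlapping intervals in ", context))
  }
  class(out) <- c("coverage_track", class(out))
  out
}

#' Covered length of a coverage track
#'
#' The number of genome bases covered by at least one read, i.e. the total
#' length of intervals with depth >= 1.
#'
#' @param track A `coverage_track` tibble.
#' @return Covered length in bp.
#' @export
covered_length <- function(track) {
  keep <- track$depth >= 1
  sum(track$end[keep] - track$start[keep] + 1)
}

#' Write a coverage track as bedgraph
#'
#' @param track A `coverage_track` tibble (1-based inclusive internally).
#' @param path Output path; written as 0-based half-open bedgraph.
#' @return `path`, invisibly.
#' @export
write_coverage_track <- function(track, path) {
  out <- tibble(chrom = track$chrom,
                start = format(track$start - 1, scientific = FALSE, trim = TRUE),
                end = format(track$end, scientific = FALSE, trim = TRUE),
                depth = format(track$depth, scientific = FALSE, trim = TRUE))
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read one line's variant calls from a VCF file
#'
#' Parses a VCF v4.x file (via \pkg{vcfR}) into a normalized call table.
#' Multi-allelic records are split into one call per ALT allele; the variant
#' type (SNP/INS/DEL/COMPLEX) is derived from the REF/ALT lengths rather than
#' trusted from INFO. Records with a missing QUAL or missing site depth
#' (`DP` INFO field) are rejected with a single warning carrying the count.
#'
#' @param path Path to the VCF file (plain or gzipped).
#' @param line_id Identifier of the line the calls belong to.
#' @param genome A `genome_index`; records on unknown chromosomes or with
#'   positions beyond the chromosome end raise an error naming the record.
#' @param aliases Optional chromosome-name alias map.
#' @return A tibble with columns `line_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `var_type`, `qual`, `depth`, with attribute `n_rejected` giving the
#'   number of records dropped for missing QUAL/DP.
#' @export
read_vcf_calls <- function(path, line_id, genome, aliases = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    out <- empty_calls(line_id = character(0))
    attr(out, "n_rejected") <- 0L
    return(out)
  }
  dp <- suppressWarnings(as.numeric(vcfR::extract.info(v, "DP")))
  qual <- suppressWarnings(as.numeric(fix$QUAL))
  bad <- is.na(qual) | is.na(dp)
  if (any(bad)) {
    warn(paste0(sum(bad), " record(s) in ", path,
                " rejected for missing QUAL or DP"))
  }
  fix <- fix[!bad, , drop = FALSE]
  qual <- qual[!bad]
  dp <- dp[!bad]
  chrom <- resolve_chrom(fix$CHROM, genome, aliases, context = path)
  pos <- as.numeric(fix$POS)
  chrom_len <- genome$length[match(chrom, genome$chrom)]
  over <- pos > chrom_len | pos < 1
  if (any(over)) {
    i <- which(over)[1]
    abort(paste0("record ", chrom[i], ":", pos[i], " in ", path,
                 " lies beyond the chromosome end"))
  }
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  nalt <- lengths(alts)
  idx <- rep(seq_along(nalt), nalt)
  out <- tibble(line_id = line_id,
                chrom = chrom[idx],
                pos = pos[idx],
                ref = toupper(fix$REF[idx]),
                alt = toupper(unlist(alts)),
                qual = qual[idx],
                depth = dp[idx])
  out$var_type <- classify_variant_type(out$ref, out$alt)
  out <- out[, c("line_id", "chrom", "pos", "ref", "alt", "var_type",
                 "qual", "depth")]
  attr(out, "n_rejected") <- sum(bad)
  out
}

empty_calls <- function(line_id = character(0)) {
  tibble(line_id = line_id, chrom = character(0), pos = numeric(0),
         ref = character(0), alt = character(0), var_type = character(0),
         qual = numeric(0), depth = numeric(0))
}

#' Write variant calls as a VCF v4.2 file
#'
#' Minimal plain-text emitter (one record per call; QUAL and `DP` carried
#' through at full precision) so that writing then re-reading with
#' [read_vcf_calls()] is the identity on (chrom, pos, ref, alt, qual, depth).
#'
#' @param calls A call tibble as returned by [read_vcf_calls()].
#' @param path Output path.
#' @param genome Optional `genome_index`; when given, `##contig` header lines
#'   are written and records are sorted in index order.
#' @return `path`, invisibly.
#' @export
write_vcf_calls <- function(calls, path, genome = NULL) {
  header <- c("##fileformat=VCFv4.2",
              "##source=varcohort",
              "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Raw read depth\">")
  if (!is.null(genome)) {
    header <- c(header,
                sprintf("##contig=<ID=%s,length=%d>", genome$chrom,
                        as.integer(genome$length)))
    calls <- arrange(calls, match(.data$chrom, genome$chrom), .data$pos)
  } else {
    calls <- arrange(calls, .data$chrom, .data$pos)
  }
  header <- c(header,
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%s\t.\t%s\t%s\t%s\t.\tDP=%s",
                  calls$chrom,
                  format(calls$pos, scientific = FALSE, trim = TRUE),
                  calls$ref, calls$alt,
                  format(calls$qual, scientific = FALSE, trim = TRUE, digits = 10),
                  format(calls$depth, scientific = FALSE, trim = TRUE))
  writeLines(c(header, body), path)
  invisible(path)
}
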