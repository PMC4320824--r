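# Fixed catalogue of the 23 classic effect types and their impact category.
# The row order IS the severity order used for most-severe-effect selection
# (impact blocks HIGH > MODERATE > LOW > MODIFIER; within a block, the listed
# order breaks ties).

EFFECT_CATALOG <- tibble::tibble(
  effect_type = c(
    # HIGH
    "FRAME_SHIFT", "SPLICE_SITE_ACCEPTOR", "SPLICE_SITE_DONOR",
    "START_LOST", "STOP_GAINED", "STOP_LOST",
    # MODERATE
    "CODON_CHANGE_PLUS_CODON_DELETION", "CODON_CHANGE_PLUS_CODON_INSERTION",
    "CODON_DELETION", "CODON_INSERTION", "NON_SYNONYMOUS_CODING",
    # LOW
    "NON_SYNONYMOUS_START", "SPLICE_SITE_REGION", "START_GAINED",
    "SYNONYMOUS_CODING", "SYNONYMOUS_STOP",
    # MODIFIER
    "DOWNSTREAM", "INTERGENIC", "INTRAGENIC", "INTRON", "UPSTREAM",
    "UTR_3_PRIME", "UTR_5_PRIME"),
  impact = rep(c("HIGH", "MODERATE", "LOW", "MODIFIER"), c(6, 5, 5, 7))
)
EFFECT_CATALOG$severity <- seq_len(nrow(EFFECT_CATALOG))

# Sequence-Ontology (VCF ANN field) aliases -> classic effect names.
EFFECT_ALIASES <- c(
  frameshift_variant = "FRAME_SHIFT",
  splice_acceptor_variant = "SPLICE_SITE_ACCEPTOR",
  splice_donor_variant = "SPLICE_SITE_DONOR",
  start_lost = "START_LOST",
  stop_gained = "STOP_GAINED",
  stop_lost = "STOP_LOST",
  disruptive_inframe_deletion = "CODON_CHANGE_PLUS_CODON_DELETION",
  disruptive_inframe_insertion = "CODON_CHANGE_PLUS_CODON_INSERTION",
  inframe_deletion = "CODON_DELETION",
  conservative_inframe_deletion = "CODON_DELETION",
  inframe_insertion = "CODON_INSERTION",
  conservative_inframe_insertion = "CODON_INSERTION",
  missense_variant = "NON_SYNONYMOUS_CODING",
  initiator_codon_variant = "NON_SYNONYMOUS_START",
  splice_region_variant = "SPLICE_SITE_REGION",
  `5_prime_UTR_premature_start_codon_gain_variant` = "START_GAINED",
  synonymous_variant = "SYNONYMOUS_CODING",
  stop_retained_variant = "SYNONYMOUS_STOP",
  downstream_gene_variant = "DOWNSTREAM",
  intergenic_region = "INTERGENIC",
  intergenic_variant = "INTERGENIC",
  intragenic_variant = "INTRAGENIC",
  intron_variant = "INTRON",
  upstream_gene_variant = "UPSTREAM",
  `3_prime_UTR_variant` = "UTR_3_PRIME",
  `5_prime_UTR_variant` = "UTR_5_PRIME"
)

#' The effect-type catalogue
#'
#' The 23 recognized effect types with their impact category and the fixed
#' severity rank used when a single most-severe effect must be chosen per
#' variant.
#'
#' @return A 23-row tibble with columns `effect_type`, `impact` and
#'   `severity` (1 = most severe).
#' @export
effect_catalog <- function() {
  EFFECT_CATALOG
}

#' Impact category of an effect type
#'
#' Fixed mapping of the 23 effect types into the four severity categories
#' HIGH (6 types), MODERATE (5), LOW (5) and MODIFIER (7).
#'
#' @param effect_type Character vector of effect types.
#' @return Character vector in `c("HIGH", "MODERATE", "LOW", "MODIFIER")`.
#' @examples
#' impact_category(c("FRAME_SHIFT", "INTRON"))
#' @export
impact_category <- function(effect_type) {
  idx <- match(effect_type, EFFECT_CATALOG$effect_type)
  if (anyNA(idx)) {
    abort(paste0("unknown effect type(s): ",
                 paste(unique(effect_type[is.na(idx)]), collapse = ", ")))
  }
  EFFECT_CATALOG$impact[idx]
}

effect_severity <- function(effect_type) {
  EFFECT_CATALOG$severity[match(effect_type, EFFECT_CATALOG$effect_type)]
}

most_severe_effect <- function(effect_types) {
  effect_types[which.min(effect_severity(effect_types))]
}
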