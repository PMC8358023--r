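#' Canonical functional classes
#'
#' The pipeline collects possibly functional mutations only: missense,
#' stop-gain, stop-loss, in-frame deletion and frameshift. Everything else
#' (synonymous, intronic, UTR, ...) is mapped to `"other"` and removed by
#' the class filter.
#' @export
FUNCTIONAL_CLASSES <- c("missense", "stop_gain", "stop_loss",
                        "inframe_deletion", "frameshift", "other")

#' Sample material types and timepoint labels
#' @export
MATERIALS <- c("cfDNA", "tissue_FFPE", "tissue_frozen", "PBMC")

# SnpEff-style annotation strings -> canonical class
.functional_map <- c(
  missense_variant = "missense", missense = "missense",
  stop_gained = "stop_gain", stop_gain = "stop_gain",
  stop_lost = "stop_loss", stop_loss = "stop_loss",
  inframe_deletion = "inframe_deletion",
  disruptive_inframe_deletion = "inframe_deletion",
  conservative_inframe_deletion = "inframe_deletion",
  frameshift_variant = "frameshift", frameshift = "frameshift",
  other = "other"
)

#' Map annotation functional strings to the canonical class enum
#'
#' Unknown strings map to `"other"` with a warning, so an unrecognised
#' annotation is dropped by the class filter rather than silently kept.
#'
#' @param x Character vector of functional-effect strings.
#' @return Character vector over [FUNCTIONAL_CLASSES].
#' @export
map_functional_class <- function(x) {
  out <- unname(.functional_map[x])
  unknown <- is.na(out) & !is.na(x)
  if (any(unknown)) {
    warning("unknown functional class string(s) mapped to 'other': ",
            paste(unique(x[unknown]), collapse = ", "), call. = FALSE)
    out[unknown] <- "other"
  }
  out[is.na(x)] <- "other"
  out
}

#' Build a variant-call tibble
#'
#' The package's working container for observed alleles: one row per allele
#' per sample, VAF stored as a fraction in [0, 1]. Invariants are checked:
#' `ref != alt`, `pos >= 1`, `0 <= alt_reads <= depth`, and when both depth
#' and VAF are supplied, `vaf == alt_reads / depth` to 1e-9.
#'
#' @param chrom,pos,ref,alt Variant key fields (1-based position; chromosome
#'   labels are compared as exact strings).
#' @param gene Gene symbol from the panel.
#' @param functional_class One of [FUNCTIONAL_CLASSES].
#' @param depth,alt_reads Deduplicated total / variant-supporting read counts.
#' @param vaf Variant allele fraction in [0, 1]; computed from
#'   `alt_reads / depth` when missing.
#' @param sample_id,base_change,aa_change Optional identity and HGVS fields.
#' @return A tibble of class `variant_calls`.
#' @export
variant_calls <- function(chrom, pos, ref, alt, gene,
                          functional_class = "missense",
                          depth = NA_integer_, alt_reads = NA_integer_,
                          vaf = NULL, sample_id = NA_character_,
                          base_change = NA_character_,
                          aa_change = NA_character_) {
  n <- length(pos)
  calls <- tibble(
    sample_id = rep_len(as.character(sample_id), n),
    chrom = rep_len(as.character(chrom), n),
    pos = as.integer(pos),
    ref = rep_len(as.character(ref), n),
    alt = rep_len(as.character(alt), n),
    gene = rep_len(as.character(gene), n),
    functional_class = rep_len(functional_class, n),
    depth = rep_len(as.integer(depth), n),
    alt_reads = rep_len(as.integer(alt_reads), n),
    base_change = rep_len(as.character(base_change), n),
    aa_change = rep_len(as.character(aa_change), n)
  )
  calls$vaf <- if (is.null(vaf)) calls$alt_reads / calls$depth else rep_len(as.numeric(vaf), n)
  validate_calls(calls)
}

#' Validate a variant-call tibble
#'
#' @param calls Tibble with at least the columns produced by
#'   [variant_calls()].
#' @return `calls`, invisibly classed, after invariant checks.
#' @export
validate_calls <- function(calls) {
  req <- c("chrom", "pos", "ref", "alt", "gene", "functional_class",
           "depth", "alt_reads", "vaf")
  miss <- setdiff(req, names(calls))
  if (length(miss) > 0)
    stop("variant-call table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(calls) == 0) return(calls)
  if (any(calls$pos < 1)) stop("variant position must be >= 1", call. = FALSE)
  if (any(!nzchar(calls$ref) | !nzchar(calls$alt)))
    stop("ref and alt alleles must be non-empty", call. = FALSE)
  if (any(calls$ref == calls$alt))
    stop("ref and alt alleles must differ", call. = FALSE)
  bad_class <- setdiff(unique(calls$functional_class), FUNCTIONAL_CLASSES)
  if (length(bad_class) > 0)
    stop("unknown functional class: ", paste(bad_class, collapse = ", "),
         call. = FALSE)
  has_counts <- !is.na(calls$depth) & !is.na(calls$alt_reads)
  if (any(has_counts & (calls$alt_reads < 0 | calls$alt_reads > calls$depth)))
    stop("alt_reads must satisfy 0 <= alt_reads <= depth", call. = FALSE)
  chk <- has_counts & calls$depth > 0 & !is.na(calls$vaf)
  if (any(abs(calls$vaf[chk] - calls$alt_reads[chk] / calls$depth[chk]) > 1e-9))
    stop("vaf inconsistent with alt_reads / depth (tolerance 1e-9)",
         call. = FALSE)
  if (any(!is.na(calls$vaf) & (calls$vaf < 0 | calls$vaf > 1)))
    stop("vaf must lie in [0, 1]", call. = FALSE)
  calls
}

#' Exact variant keys
#'
#' A variant key is the tuple (chrom, pos, ref, alt), encoded as
#' `"chrom:pos:ref>alt"`. Equality is exact tuple equality; no reference
#' genome is consulted. `positional = TRUE` drops the alleles (chrom:pos
#' only), a looser mode for indel-representation drift.
#'
#' @param calls Variant-call tibble.
#' @param positional Match on position only.
#' @return Character vector of keys, one per row.
#' @export
variant_keys <- function(calls, positional = FALSE) {
  if (nrow(calls) == 0) return(character(0))
  if (positional) paste0(calls$chrom, ":", calls$pos)
  else paste0(calls$chrom, ":", calls$pos, ":", calls$ref, ">", calls$alt)
}

#' Strip "chr" prefixes from chromosome labels
#'
#' Chromosome labels are otherwise compared as exact strings
#' (`"12" != "chr12"`); this normalization toggle reconciles the two
#' conventions before any matching.
#'
#' @param calls Variant-call tibble.
#' @return The tibble with normalized `chrom`.
#' @export
normalize_chrom <- function(calls) {
  calls$chrom <- sub("^chr", "", calls$chrom)
  calls
}

empty_calls <- function() {
  validate_calls(tibble(
    sample_id = character(0), chrom = character(0), pos = integer(0),
    ref = character(0), alt = character(0), gene = character(0),
    functional_class = character(0), depth = integer(0),
    alt_reads = integer(0), base_change = character(0),
    aa_change = character(0), vaf = numeric(0)
  ))
}
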