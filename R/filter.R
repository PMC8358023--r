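#' Filter-cascade configuration
#'
#' Thresholds are expressed in percent, matching how they are quoted in
#' clinical reports; conversion to fractions happens inside the filters.
#' Defaults encode the study design this package implements:
#' cfDNA calls are kept at >= 1% VAF with >= 10 variant reads (the small
#' ctDNA fraction of plasma cfDNA demands a permissive VAF cutoff), tissue
#' calls at >= 10% VAF with >= 10 variant reads, and PBMC calls at >= 20%
#' VAF are treated as germline while PBMC calls below 20% feed the
#' cohort-wide noise/clonal-hematopoiesis blacklist.
#'
#' @param cfdna_min_vaf_pct,cfdna_min_alt_reads cfDNA keep thresholds
#'   (inclusive).
#' @param tissue_min_vaf_pct,tissue_min_alt_reads Tissue keep thresholds
#'   (inclusive).
#' @param germline_min_vaf_pct PBMC germline boundary: VAF >= this is
#'   germline, below it blacklist candidate (the boundary itself is
#'   assigned to germline so the two sets partition PBMC calls).
#' @param allowed_classes Functional classes retained by the class filter.
#' @return A `filter_config` list.
#' @export
filter_config <- function(cfdna_min_vaf_pct = 1.0,
                          cfdna_min_alt_reads = 10L,
                          tissue_min_vaf_pct = 10.0,
                          tissue_min_alt_reads = 10L,
                          germline_min_vaf_pct = 20.0,
                          allowed_classes = setdiff(FUNCTIONAL_CLASSES,
                                                    "other")) {
  stopifnot(cfdna_min_vaf_pct > 0, tissue_min_vaf_pct > 0,
            germline_min_vaf_pct > 0, cfdna_min_alt_reads > 0,
            tissue_min_alt_reads > 0, length(allowed_classes) > 0)
  structure(list(
    cfdna_min_vaf_pct = cfdna_min_vaf_pct,
    cfdna_min_alt_reads = as.integer(cfdna_min_alt_reads),
    tissue_min_vaf_pct = tissue_min_vaf_pct,
    tissue_min_alt_reads = as.integer(tissue_min_alt_reads),
    germline_min_vaf_pct = germline_min_vaf_pct,
    allowed_classes = allowed_classes
  ), class = "filter_config")
}

.EPS <- 1e-12  # guards >=/< comparisons on percent-to-fraction conversions

#' Functional-class filter
#'
#' Keeps only possibly functional mutation classes (missense, stop-gain,
#' stop-loss, in-frame deletion, frameshift by default); order preserved.
#'
#' @param calls Variant-call tibble.
#' @param config A [filter_config()].
#' @return The retained calls.
#' @export
filter_functional <- function(calls, config = filter_config()) {
  calls[calls$functional_class %in% config$allowed_classes, , drop = FALSE]
}

#' VAF and read-support thresholds by material
#'
#' cfDNA: keep iff VAF >= 1% and alt reads >= 10. Tissue: keep iff
#' VAF >= 10% and alt reads >= 10. Boundaries are inclusive. PBMC calls
#' must not pass through here — they take the germline/blacklist path.
#'
#' @param calls Variant-call tibble.
#' @param material One of `cfDNA`, `tissue_FFPE`, `tissue_frozen`.
#' @param config A [filter_config()].
#' @return The retained calls.
#' @export
filter_thresholds <- function(calls, material, config = filter_config()) {
  if (identical(material, "PBMC"))
    stop("PBMC samples take the germline/blacklist path, ",
         "not the somatic threshold filter", call. = FALSE)
  if (!material %in% MATERIALS)
    stop("unknown material: ", material, call. = FALSE)
  keep <- threshold_keep(calls, material, config)
  calls[keep, , drop = FALSE]
}

threshold_keep <- function(calls, material, config) {
  if (material == "cfDNA") {
    min_vaf <- config$cfdna_min_vaf_pct / 100
    min_alt <- config$cfdna_min_alt_reads
  } else {
    min_vaf <- config$tissue_min_vaf_pct / 100
    min_alt <- config$tissue_min_alt_reads
  }
  calls$vaf >= min_vaf - .EPS & calls$alt_reads >= min_alt
}

#' Extract a patient's germline variant set from PBMC calls
#'
#' PBMC variants at VAF >= 20% are taken as germline (heterozygous and
#' homozygous variants cluster near 50% and 100% VAF); they are later
#' removed from the cfDNA and tissue results of the same patient only.
#'
#' @param pbmc_calls PBMC variant-call tibble from one patient. When a
#'   `material` column is present it must be all-PBMC.
#' @param config A [filter_config()].
#' @param patient_id Patient the PBMC sample belongs to.
#' @return A `germline_set`: character vector of variant keys with a
#'   `patient_id` attribute.
#' @export
extract_germline <- function(pbmc_calls, config = filter_config(),
                             patient_id = NA_character_) {
  if ("material" %in% names(pbmc_calls) &&
      any(pbmc_calls$material != "PBMC"))
    stop("extract_germline() expects PBMC calls only", call. = FALSE)
  if ("patient_id" %in% names(pbmc_calls) && nrow(pbmc_calls) > 0) {
    pats <- unique(pbmc_calls$patient_id)
    if (length(pats) > 1)
      stop("PBMC calls from more than one patient", call. = FALSE)
    if (is.na(patient_id)) patient_id <- pats
  }
  thr <- config$germline_min_vaf_pct / 100
  keys <- unique(variant_keys(
    pbmc_calls[pbmc_calls$vaf >= thr - .EPS, , drop = FALSE]))
  structure(keys, patient_id = patient_id, class = "germline_set")
}

#' Build the cohort-wide noise / clonal-hematopoiesis blacklist
#'
#' PBMC variant calls below the germline boundary (20% VAF), pooled across
#' every PBMC sample in the cohort, form a blacklist of recurrent
#' sequencing errors and clonal-hematopoiesis variants. The blacklist is
#' applied cohort-wide. By the boundary rule every PBMC call is either
#' germline or a blacklist candidate — never both, never neither.
#'
#' @param pbmc_calls PBMC calls pooled across the cohort (needs a
#'   `sample_id` column for provenance).
#' @param config A [filter_config()].
#' @param min_recurrence Minimum number of distinct PBMC samples a key must
#'   appear in to enter the blacklist. The default (1) admits singletons;
#'   raise it to require recurrence.
#' @return A `ctdna_blacklist`: list with `entries` (character keys) and
#'   `provenance` (key, sample_id, vaf).
#' @export
build_blacklist <- function(pbmc_calls, config = filter_config(),
                            min_recurrence = 1L) {
  if ("material" %in% names(pbmc_calls) &&
      any(pbmc_calls$material != "PBMC"))
    stop("build_blacklist() expects PBMC calls only", call. = FALSE)
  thr <- config$germline_min_vaf_pct / 100
  cand <- pbmc_calls[pbmc_calls$vaf < thr - .EPS, , drop = FALSE]
  prov <- tibble(key = variant_keys(cand),
                 sample_id = if (nrow(cand)) cand$sample_id else character(0),
                 vaf = cand$vaf)
  counts <- prov %>% group_by(.data$key) %>%
    summarise(n_samples = n_distinct(.data$sample_id), .groups = "drop")
  keep <- counts$key[counts$n_samples >= min_recurrence]
  structure(list(entries = sort(keep),
                 provenance = prov[prov$key %in% keep, , drop = FALSE]),
            class = "ctdna_blacklist")
}

#' @export
print.ctdna_blacklist <- function(x, ...) {
  cat("<ctdna_blacklist> ", length(x$entries), " variant key(s) from ",
      n_distinct(x$provenance$sample_id), " PBMC sample(s)\n", sep = "")
  invisible(x)
}

#' Serialize / read a blacklist as TSV
#'
#' Columns: `chrom, pos, ref, alt, n_samples, max_vaf`.
#'
#' @param blacklist A `ctdna_blacklist`.
#' @param path Output path.
#' @return `path` (write) or a `ctdna_blacklist` (read).
#' @export
write_blacklist <- function(blacklist, path) {
  prov <- blacklist$provenance %>% group_by(.data$key) %>%
    summarise(n_samples = n_distinct(.data$sample_id),
              max_vaf = max(.data$vaf), .groups = "drop")
  parts <- key_parts(prov$key)
  readr::write_tsv(
    tibble(chrom = parts$chrom, pos = parts$pos, ref = parts$ref,
           alt = parts$alt, n_samples = prov$n_samples,
           max_vaf = prov$max_vaf),
    path, progress = FALSE)
  invisible(path)
}

#' @rdname write_blacklist
#' @export
read_blacklist <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    chrom = "c", pos = "i", ref = "c", alt = "c", n_samples = "i",
    max_vaf = "d"), progress = FALSE)
  keys <- paste0(tab$chrom, ":", tab$pos, ":", tab$ref, ">", tab$alt)
  structure(list(entries = sort(keys),
                 provenance = tibble(key = keys, sample_id = NA_character_,
                                     vaf = tab$max_vaf)),
            class = "ctdna_blacklist")
}

key_parts <- function(keys) {
  m <- regmatches(keys, regexec("^(.*):([0-9]+):(.*)>(.*)$", keys))
  tibble(chrom = vapply(m, `[`, "", 2),
         pos = as.integer(vapply(m, `[`, "", 3)),
         ref = vapply(m, `[`, "", 4),
         alt = vapply(m, `[`, "", 5))
}

#' Finalize a somatic set: germline and blacklist subtraction
#'
#' Removes calls whose key is in the patient's germline set (patient
#' scope) or in the cohort blacklist (cohort scope). Germline removal is
#' applied before blacklist removal; the logged disposition reflects the
#' first matching rule. An optional manual exclusion list stands in for
#' browser-based visual inspection of pileups, which cannot be automated
#' but must be representable.
#'
#' @param calls Class- and threshold-filtered calls for one sample.
#' @param germline A `germline_set` from [extract_germline()], same
#'   patient (checked when both carry a patient id).
#' @param blacklist A `ctdna_blacklist`, or `NULL`.
#' @param patient_id Patient the calls belong to.
#' @param manual_exclude Optional character vector of keys to drop
#'   (disposition `dropped:manual`).
#' @return A `somatic_set`.
#' @export
finalize_somatic <- function(calls, germline = NULL, blacklist = NULL,
                             patient_id = NA_character_,
                             manual_exclude = NULL) {
  if (!is.null(germline)) {
    gpat <- attr(germline, "patient_id")
    if (!is.na(patient_id) && !is.na(gpat) && !identical(gpat, patient_id))
      stop("germline set belongs to patient '", gpat,
           "', not '", patient_id, "'", call. = FALSE)
  }
  keys <- variant_keys(calls)
  disp <- rep("kept", nrow(calls))
  if (!is.null(germline))
    disp[keys %in% as.character(germline)] <- "dropped:germline"
  if (!is.null(blacklist))
    disp[disp == "kept" & keys %in% blacklist$entries] <- "dropped:blacklist"
  if (!is.null(manual_exclude))
    disp[disp == "kept" & keys %in% manual_exclude] <- "dropped:manual"
  new_somatic_set(calls, disp, patient_id)
}

new_somatic_set <- function(calls, disposition, patient_id,
                            material = NA_character_,
                            sample_id = NA_character_) {
  if ("material" %in% names(calls) && nrow(calls) > 0)
    material <- unique(calls$material)[1]
  if ("sample_id" %in% names(calls) && nrow(calls) > 0 &&
      !all(is.na(calls$sample_id)))
    sample_id <- unique(calls$sample_id)[1]
  log <- tibble(key = variant_keys(calls), gene = calls$gene,
                vaf = calls$vaf, disposition = disposition)
  structure(list(
    sample_id = sample_id, patient_id = patient_id, material = material,
    calls = calls[disposition == "kept", , drop = FALSE],
    cascade_log = log
  ), class = "somatic_set")
}

#' @export
print.somatic_set <- function(x, ...) {
  cat("<somatic_set> sample ", x$sample_id, " (", x$material, "): ",
      nrow(x$calls), " somatic call(s) kept of ",
      nrow(x$cascade_log), " input\n", sep = "")
  invisible(x)
}

#' Run the full somatic filter cascade on one sample
#'
#' Canonical stage order: panel gate, functional-class filter, material
#' thresholds, germline subtraction, blacklist subtraction (then any
#' manual exclusions). Every input call receives exactly one disposition
#' in the cascade log (`kept`, `dropped:panel`, `dropped:class`,
#' `dropped:threshold`, `dropped:germline`, `dropped:blacklist`,
#' `dropped:manual`); re-running the cascade on its own kept output is a
#' no-op.
#'
#' @param calls All parsed calls for one cfDNA or tissue sample.
#' @param material `cfDNA`, `tissue_FFPE` or `tissue_frozen`.
#' @param config A [filter_config()].
#' @param germline The patient's `germline_set` (or `NULL`, e.g. for a
#'   patient without a PBMC sample — subtraction is skipped with a
#'   warning).
#' @param blacklist The cohort `ctdna_blacklist` (or `NULL`).
#' @param panel_version When given, calls outside the panel's gene list
#'   are excluded first.
#' @param patient_id Patient identifier for scope checks.
#' @param manual_exclude Optional keys to drop at the end.
#' @param warn_no_germline Warn when `germline` is `NULL`.
#' @return A `somatic_set` with a complete cascade log.
#' @export
somatic_cascade <- function(calls, material, config = filter_config(),
                            germline = NULL, blacklist = NULL,
                            panel_version = NULL,
                            patient_id = NA_character_,
                            manual_exclude = NULL,
                            warn_no_germline = TRUE) {
  if (identical(material, "PBMC"))
    stop("PBMC samples are inputs to the germline/blacklist path; ",
         "the somatic cascade applies to cfDNA and tissue", call. = FALSE)
  if (is.null(germline) && warn_no_germline)
    warning("no PBMC germline set for patient '", patient_id,
            "'; germline subtraction skipped", call. = FALSE)
  calls <- validate_calls(calls)
  keys <- variant_keys(calls)
  disp <- rep("kept", nrow(calls))
  if (!is.null(panel_version))
    disp[!calls$gene %in% panel_genes(panel_version)] <- "dropped:panel"
  ok <- disp == "kept"
  disp[ok & !calls$functional_class %in% config$allowed_classes] <-
    "dropped:class"
  ok <- disp == "kept"
  disp[ok & !threshold_keep(calls, material, config)] <- "dropped:threshold"
  ok <- disp == "kept"
  if (!is.null(germline)) {
    gpat <- attr(germline, "patient_id")
    if (!is.na(patient_id) && !is.na(gpat %||% NA_character_) &&
        !identical(gpat, patient_id))
      stop("germline set belongs to patient '", gpat, "', not '",
           patient_id, "'", call. = FALSE)
    disp[ok & keys %in% as.character(germline)] <- "dropped:germline"
    ok <- disp == "kept"
  }
  if (!is.null(blacklist)) {
    disp[ok & keys %in% blacklist$entries] <- "dropped:blacklist"
    ok <- disp == "kept"
  }
  if (!is.null(manual_exclude))
    disp[ok & keys %in% manual_exclude] <- "dropped:manual"
  new_somatic_set(calls, disp, patient_id)
}
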