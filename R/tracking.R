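#' Average VAF of a finalized cfDNA somatic set
#'
#' The per-sample ctDNA burden summary: the unweighted arithmetic mean of
#' the VAFs of all somatic mutations detected at that timepoint, in
#' percent. Averaging over all detected mutations (rather than tracking a
#' fixed baseline clone) is deliberate: under combined cytotoxic and
#' targeted therapy the dominant clone can change, and a detection-based
#' denominator lets the summary fall to 0 when nothing is detectable.
#'
#' @param somatic A `somatic_set` from the cascade, cfDNA material.
#' @return Mean VAF in percent; 0 for an empty set.
#' @export
average_vaf <- function(somatic) {
  if (!inherits(somatic, "somatic_set"))
    stop("average_vaf() expects a somatic_set", call. = FALSE)
  if (!is.na(somatic$material) && somatic$material != "cfDNA")
    stop("average VAF is defined for cfDNA sets; got material '",
         somatic$material, "'", call. = FALSE)
  if (nrow(somatic$calls) == 0) return(0)
  mean(somatic$calls$vaf) * 100
}

#' Per-patient average-VAF trajectory
#'
#' One point per cfDNA timepoint: average VAF (percent), mutation count,
#' matched target-lesion size when supplied, the average-VAF delta against
#' baseline (percentage points) and the tumor-size change (percent).
#' Optional cfDNA-concentration columns support the comparator metrics
#' (concentration alone, and average VAF times concentration).
#'
#' @param somatic_sets Named list of cfDNA `somatic_set`s, names are
#'   timepoint labels; must include `baseline`.
#' @param sizes_mm Optional named numeric vector of target-lesion sizes by
#'   timepoint.
#' @param cfdna_conc Optional named numeric vector (or scalar) of cfDNA
#'   concentrations by timepoint.
#' @param patient_id Patient identifier for the output.
#' @return Tibble of trajectory points ordered by timepoint.
#' @export
vaf_trajectory <- function(somatic_sets, sizes_mm = NULL, cfdna_conc = NULL,
                           patient_id = NA_character_) {
  tps <- names(somatic_sets)
  if (is.null(tps) || !"baseline" %in% tps)
    stop("trajectory requires a named list of timepoints including ",
         "'baseline'", call. = FALSE)
  ord <- order(timepoint_rank(tps))
  tps <- tps[ord]
  avg <- vapply(somatic_sets[tps], average_vaf, numeric(1))
  nmut <- vapply(somatic_sets[tps],
                 function(s) nrow(s$calls), integer(1))
  size <- if (is.null(sizes_mm)) rep(NA_real_, length(tps))
          else as.numeric(sizes_mm[tps])
  traj <- tibble(
    patient_id = patient_id, timepoint = tps,
    average_vaf_pct = unname(avg), n_mutations = unname(nmut),
    tumor_size_mm = size,
    delta_vaf_pct = unname(avg) - avg[["baseline"]],
    tumor_size_change_pct =
      if (!is.na(size[1]) && size[1] > 0) (size / size[1] - 1) * 100
      else rep(NA_real_, length(tps))
  )
  if (!is.null(cfdna_conc)) {
    conc <- if (length(cfdna_conc) == 1 && is.null(names(cfdna_conc)))
      rep(cfdna_conc, length(tps)) else as.numeric(cfdna_conc[tps])
    traj$cfdna_conc <- conc
    traj$vaf_x_conc <- traj$average_vaf_pct * conc
  }
  traj
}

#' Classify ctDNA clearance at the first response evaluation
#'
#' Cleared means the average VAF fell strictly below the cutoff (1% by
#' default) at the first evaluation timepoint; exactly 1% is not cleared.
#' Patients without a first-evaluation sample are `"unknown"` and excluded
#' from downstream survival comparisons.
#'
#' @param trajectory Tibble from [vaf_trajectory()].
#' @param cutoff_pct Clearance cutoff in percent.
#' @return List with `label` (`cleared`/`not_cleared`/`unknown`),
#'   `timepoint` and `average_vaf_pct` at that point.
#' @export
classify_clearance <- function(trajectory, cutoff_pct = 1.0) {
  ev <- trajectory[grepl("^eval[0-9]+$", trajectory$timepoint), ,
                   drop = FALSE]
  if (nrow(ev) == 0)
    return(list(label = "unknown", timepoint = NA_character_,
                average_vaf_pct = NA_real_))
  first <- ev[which.min(timepoint_rank(ev$timepoint)), ]
  list(label = if (first$average_vaf_pct < cutoff_pct) "cleared"
               else "not_cleared",
       timepoint = first$timepoint,
       average_vaf_pct = first$average_vaf_pct)
}

#' Emergent mutations at disease progression
#'
#' Variants present in the finalized PD cfDNA somatic set but absent from
#' every earlier cfDNA somatic set of the patient and from the tissue
#' somatic set — candidate resistance mechanisms selected during therapy.
#'
#' @param pd_set Finalized cfDNA `somatic_set` at PD.
#' @param earlier_sets List of the patient's earlier cfDNA `somatic_set`s
#'   (may be empty).
#' @param tissue_set Tissue `somatic_set`, or `NULL` when no tissue was
#'   sequenced.
#' @return Variant-call tibble of the emergent calls.
#' @export
detect_emergent <- function(pd_set, earlier_sets = list(),
                            tissue_set = NULL) {
  if (is.null(pd_set) || !inherits(pd_set, "somatic_set"))
    stop("PD cfDNA somatic set is required", call. = FALSE)
  seen <- unlist(lapply(earlier_sets,
                        function(s) variant_keys(s$calls)))
  if (!is.null(tissue_set))
    seen <- c(seen, variant_keys(tissue_set$calls))
  keys <- variant_keys(pd_set$calls)
  pd_set$calls[!keys %in% seen, , drop = FALSE]
}

#' Tissue-plasma concordance with sub-threshold rescue
#'
#' Matches a patient's tissue somatic variants against the ctDNA somatic
#' set by exact variant key (or chromosome+position with
#' `match = "positional"`). Unmatched tissue variants are "rescued" when
#' they appear in the unfiltered (post-class, pre-threshold) cfDNA calls
#' with non-zero VAF below the cfDNA cutoff — real tumor signal lost to
#' the restrictive VAF filter, not absent from plasma. The symmetric check
#' flags ctDNA-only variants present sub-threshold in unfiltered tissue
#' calls.
#'
#' @param tissue_somatic Tissue `somatic_set`.
#' @param cfdna_somatic Baseline cfDNA `somatic_set`, same patient.
#' @param cfdna_unfiltered Variant-call tibble of the cfDNA sample after
#'   the class filter but before thresholds.
#' @param tissue_unfiltered Optional analogous tibble for tissue.
#' @param match `"exact"` (default) or `"positional"`.
#' @return A `concordance_report` (one-row tibble of counts plus
#'   `patient_covered`).
#' @export
concordance <- function(tissue_somatic, cfdna_somatic, cfdna_unfiltered,
                        tissue_unfiltered = NULL,
                        match = c("exact", "positional")) {
  match <- match.arg(match)
  pos <- match == "positional"
  pats <- stats::na.omit(c(tissue_somatic$patient_id,
                           cfdna_somatic$patient_id))
  if (n_distinct(pats) > 1)
    stop("tissue and cfDNA sets belong to different patients", call. = FALSE)
  t_keys <- unique(variant_keys(tissue_somatic$calls, positional = pos))
  c_keys <- unique(variant_keys(cfdna_somatic$calls, positional = pos))
  u_keys <- unique(variant_keys(cfdna_unfiltered, positional = pos))
  matched <- intersect(t_keys, c_keys)
  unmatched <- setdiff(t_keys, c_keys)
  rescued <- intersect(unmatched, u_keys)
  ctdna_only <- setdiff(c_keys, t_keys)
  rescued_tissue <- if (!is.null(tissue_unfiltered))
    intersect(ctdna_only,
              unique(variant_keys(tissue_unfiltered, positional = pos)))
  else character(0)
  out <- tibble(
    patient_id = if (length(pats)) pats[1] else NA_character_,
    n_tissue = length(t_keys),
    n_matched = length(matched),
    n_unmatched = length(unmatched),
    n_rescued_subthreshold = length(rescued),
    n_ctdna_only = length(ctdna_only),
    n_ctdna_only_subthreshold_in_tissue = length(rescued_tissue),
    patient_covered = length(unmatched) == 0
  )
  class(out) <- c("concordance_report", class(out))
  out
}

#' Load the bundled hotspot and pathogenicity lookup tables
#'
#' Both lookups are total functions: any variant absent from the table
#' maps to `"none"`. The bundled catalogues cover the recurrent RAS/RAF
#' and MAP2K1 activating codons and the ClinVar-style classifications of
#' the resistance variants the panel targets.
#'
#' @return Tibbles keyed by `(gene, aa_change)` (hotspots) or
#'   `(gene, base_change)` / variant key (pathogenicity).
#' @export
load_hotspots <- function() {
  readr::read_tsv(cf_extdata("hotspots.tsv"), show_col_types = FALSE,
                  progress = FALSE)
}

#' @rdname load_hotspots
#' @export
load_pathogenicity <- function() {
  readr::read_tsv(cf_extdata("pathogenicity.tsv"), show_col_types = FALSE,
                  progress = FALSE)
}

#' Annotate calls with hotspot labels and pathogenicity classes
#'
#' @param calls Variant-call tibble.
#' @param hotspots,pathogenicity Lookup tibbles (defaults: bundled
#'   catalogues).
#' @return `calls` with `hotspot` and `pathogenicity` columns
#'   (`"none"` when not listed).
#' @export
annotate_calls <- function(calls, hotspots = load_hotspots(),
                           pathogenicity = load_pathogenicity()) {
  hs <- hotspots %>% select(gene = "gene", aa_change = "aa_change",
                            hotspot = "label")
  out <- left_join(calls, hs, by = c("gene", "aa_change"))
  pg <- pathogenicity %>%
    select(gene = "gene", base_change = "base_change",
           pathogenicity = "pathogenicity") %>%
    distinct(.data$gene, .data$base_change, .keep_all = TRUE)
  out <- left_join(out, pg, by = c("gene", "base_change"))
  # fallback: exact variant-key lookup for rows without an HGVS c. string
  pk <- paste0(pathogenicity$chrom, ":", pathogenicity$pos, ":",
               pathogenicity$ref, ">", pathogenicity$alt)
  missing <- is.na(out$pathogenicity)
  if (any(missing)) {
    idx <- match(variant_keys(out)[missing], pk)
    out$pathogenicity[missing] <-
      ifelse(is.na(idx), NA, pathogenicity$pathogenicity[idx])
  }
  out$hotspot[is.na(out$hotspot)] <- "none"
  out$pathogenicity[is.na(out$pathogenicity)] <- "none"
  out
}
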