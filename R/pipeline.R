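#' Pipeline run configuration
#'
#' A single declarative configuration drives the whole analysis; all
#' thresholds appear here with the study defaults, so the canonical
#' analysis is the zero-argument invocation. Round-trips losslessly
#' through YAML.
#'
#' @param input_dir Directory with `variants/<sample_id>.tsv`,
#'   `sample_sheet.csv` and `clinical.csv` (the layout [write_cohort()]
#'   emits).
#' @param out_dir Optional output directory for artifacts.
#' @param filter A [filter_config()].
#' @param clearance_cutoff_pct Average-VAF clearance cutoff (percent).
#' @param min_recurrence Blacklist recurrence requirement (see
#'   [build_blacklist()]).
#' @param blacklist_scope `"cohort"` (default) or `"patient"` for
#'   sensitivity analysis.
#' @param match Concordance matching mode, `"exact"` or `"positional"`.
#' @return A `run_config` list.
#' @export
run_config <- function(input_dir, out_dir = NULL,
                       filter = filter_config(),
                       clearance_cutoff_pct = 1.0,
                       min_recurrence = 1L,
                       blacklist_scope = c("cohort", "patient"),
                       match = c("exact", "positional")) {
  structure(list(
    input_dir = input_dir, out_dir = out_dir, filter = filter,
    clearance_cutoff_pct = clearance_cutoff_pct,
    min_recurrence = as.integer(min_recurrence),
    blacklist_scope = match.arg(blacklist_scope),
    match = match.arg(match)
  ), class = "run_config")
}

#' Read / write a run configuration as YAML
#' @param path YAML path.
#' @param config A `run_config`.
#' @return A `run_config` (read) or `path` (write).
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(
    input_dir = y$input_dir, out_dir = y$out_dir,
    filter = do.call(filter_config, y$filter %||% list()),
    clearance_cutoff_pct = y$clearance_cutoff_pct %||% 1.0,
    min_recurrence = y$min_recurrence %||% 1L,
    blacklist_scope = y$blacklist_scope %||% "cohort",
    match = y$match %||% "exact"
  )
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  y <- unclass(config)
  y$filter <- unclass(y$filter)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Orchestrates reading, the filter cascade (class, thresholds, PBMC
#' germline subtraction, cohort blacklist), per-patient average-VAF
#' trajectories with clearance classification, tissue-plasma concordance,
#' emergent-mutation detection at PD, and the cohort statistics. When
#' `config$out_dir` is set, per-stage artifacts (TSV/JSON) are written
#' with a manifest. The run is deterministic: no stage draws random
#' numbers.
#'
#' @param config A [run_config()], or a path to its YAML form.
#' @return A `ctdna_report` list (see Details).
#' @details The report contains `cohort_summary`, `frequency_baseline`,
#'   `frequency_emergent`, `trajectories`, `clearance`, `concordance`
#'   (per patient and totals), `emergent` (annotated calls),
#'   `survival_by_clearance`, `correlations`, `blacklist_size` and
#'   `cascade` (per-sample disposition counts).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  samples <- read_sample_sheet(file.path(config$input_dir,
                                         "sample_sheet.csv"))
  clinical <- read_clinical(file.path(config$input_dir, "clinical.csv"),
                            samples)
  calls <- purrr::map_dfr(samples$sample_id, function(sid) {
    path <- file.path(config$input_dir, "variants", paste0(sid, ".tsv"))
    if (!file.exists(path))
      stop("stage read: variant table missing for sample '", sid, "'",
           call. = FALSE)
    read_variant_table(path, sample_id = sid)
  })
  calls <- left_join(calls, samples, by = "sample_id")
  analyze_cohort(calls, samples, clinical, config)
}

#' Analyse an in-memory cohort
#'
#' The computational core of [run_pipeline()], usable directly on the
#' tibbles [simulate_cohort()] returns.
#'
#' @param calls All variant calls with sample metadata columns attached
#'   (`patient_id`, `material`, `timepoint`, `panel_version`).
#' @param samples Sample sheet tibble.
#' @param clinical Clinical tibble.
#' @param config A [run_config()] (its `input_dir` may be empty).
#' @return A `ctdna_report` list.
#' @export
analyze_cohort <- function(calls, samples, clinical,
                           config = run_config(input_dir = ".")) {
  fc <- config$filter
  need <- c("patient_id", "material", "timepoint", "panel_version")
  miss <- setdiff(need, names(calls))
  if (length(miss))
    stop("calls lack metadata column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)

  pbmc <- calls[calls$material == "PBMC", , drop = FALSE]
  germline_by_patient <- lapply(
    split(pbmc, pbmc$patient_id),
    function(g) extract_germline(g, fc, patient_id = g$patient_id[1]))
  blacklist <- build_blacklist(pbmc, fc,
                               min_recurrence = config$min_recurrence)

  non_pbmc <- samples[samples$material != "PBMC", , drop = FALSE]
  sets <- vector("list", nrow(non_pbmc))
  names(sets) <- non_pbmc$sample_id
  unfiltered <- vector("list", nrow(non_pbmc))
  names(unfiltered) <- non_pbmc$sample_id
  for (i in seq_len(nrow(non_pbmc))) {
    s <- non_pbmc[i, ]
    sc <- calls[calls$sample_id == s$sample_id, , drop = FALSE]
    bl <- if (config$blacklist_scope == "cohort") blacklist else
      build_blacklist(pbmc[pbmc$patient_id == s$patient_id, , drop = FALSE],
                      fc, min_recurrence = config$min_recurrence)
    gl <- germline_by_patient[[s$patient_id]]
    sets[[s$sample_id]] <- somatic_cascade(
      sc, material = s$material, config = fc, germline = gl,
      blacklist = bl, panel_version = s$panel_version,
      patient_id = s$patient_id, warn_no_germline = FALSE)
    # post-class, pre-threshold calls: input to sub-threshold rescue
    unfiltered[[s$sample_id]] <-
      filter_functional(apply_panel(sc, s$panel_version), fc)
  }

  patients <- unique(samples$patient_id)
  baseline_sets <- pd_sets <- tissue_sets <- list()
  traj <- clearance <- list()
  conc <- emergent <- list()
  for (pid in patients) {
    ps <- non_pbmc[non_pbmc$patient_id == pid, , drop = FALSE]
    cf <- ps[ps$material == "cfDNA", , drop = FALSE]
    cf <- cf[order(timepoint_rank(cf$timepoint)), , drop = FALSE]
    tis <- ps[ps$material %in% c("tissue_FFPE", "tissue_frozen"), ,
              drop = FALSE]
    cf_sets <- setNames(sets[cf$sample_id], cf$timepoint)
    if (!"baseline" %in% names(cf_sets)) next
    baseline_sets[[pid]] <- cf_sets[["baseline"]]
    sizes <- vapply(cf$timepoint,
                    function(tp) tumor_size(clinical, pid, tp), numeric(1))
    traj[[pid]] <- vaf_trajectory(cf_sets, sizes_mm = sizes,
                                  patient_id = pid)
    clearance[[pid]] <- c(patient_id = pid,
                          classify_clearance(traj[[pid]],
                                             config$clearance_cutoff_pct))
    if (nrow(tis) > 0) {
      tset <- sets[[tis$sample_id[1]]]
      tissue_sets[[pid]] <- tset
      conc[[pid]] <- concordance(
        tset, cf_sets[["baseline"]],
        cfdna_unfiltered = unfiltered[[cf$sample_id[cf$timepoint ==
                                                      "baseline"][1]]],
        tissue_unfiltered = unfiltered[[tis$sample_id[1]]],
        match = config$match)
    }
    if ("PD" %in% names(cf_sets)) {
      pd_sets[[pid]] <- cf_sets[["PD"]]
      earlier <- cf_sets[names(cf_sets) != "PD"]
      emergent[[pid]] <- detect_emergent(cf_sets[["PD"]], earlier,
                                         tissue_sets[[pid]])
    }
  }

  panel_by_patient <- distinct(samples[, c("patient_id", "panel_version")])
  base_calls <- bind_rows(lapply(baseline_sets, function(s)
    mutate(s$calls, patient_id = s$patient_id)))
  freq_base <- summarize_frequencies(base_calls, panel_by_patient)
  em_calls <- bind_rows(purrr::imap(emergent, function(e, pid)
    mutate(e, patient_id = pid)))
  pd_patients <- panel_by_patient[panel_by_patient$patient_id %in%
                                    names(pd_sets), , drop = FALSE]
  freq_em <- if (nrow(em_calls) > 0)
    summarize_frequencies(em_calls, pd_patients) else NULL

  trajectories <- bind_rows(traj)
  clearance_tbl <- bind_rows(lapply(clearance, as_tibble))
  conc_tbl <- bind_rows(conc)
  conc_totals <- if (nrow(conc_tbl) > 0) list(
    n_patients = nrow(conc_tbl),
    n_tissue = sum(conc_tbl$n_tissue),
    n_matched = sum(conc_tbl$n_matched),
    pct_matched = pct(sum(conc_tbl$n_matched), sum(conc_tbl$n_tissue)),
    n_unmatched = sum(conc_tbl$n_unmatched),
    n_rescued_subthreshold = sum(conc_tbl$n_rescued_subthreshold),
    pct_rescued = pct(sum(conc_tbl$n_rescued_subthreshold),
                      sum(conc_tbl$n_unmatched)),
    n_ctdna_only = sum(conc_tbl$n_ctdna_only),
    n_ctdna_only_subthreshold_in_tissue =
      sum(conc_tbl$n_ctdna_only_subthreshold_in_tissue),
    pct_ctdna_only_rescued =
      pct(sum(conc_tbl$n_ctdna_only_subthreshold_in_tissue),
          sum(conc_tbl$n_ctdna_only)),
    n_patients_covered = sum(conc_tbl$patient_covered),
    pct_patients_covered = pct(sum(conc_tbl$patient_covered),
                               nrow(conc_tbl))
  ) else NULL

  # survival split by clearance
  surv <- NULL
  known <- clearance_tbl[clearance_tbl$label != "unknown", , drop = FALSE]
  if (nrow(known) > 0 && n_distinct(known$label) == 2) {
    cl <- left_join(known, clinical, by = "patient_id")
    km <- km_estimate(cl$pfs_months, cl$pfs_event, cl$label)
    lr <- tryCatch(logrank_test(cl$pfs_months, cl$pfs_event, cl$label),
                   error = function(e) NULL)
    surv <- list(median_pfs = as.list(km$median),
                 logrank_p = if (!is.null(lr)) lr$p.value else NA_real_,
                 n = as.list(table(cl$label)))
  }

  # correlations: baseline burden vs size; delta VAF vs size change
  correlations <- list()
  base_tr <- trajectories[trajectories$timepoint == "baseline", ,
                          drop = FALSE]
  ok <- complete.cases(base_tr$average_vaf_pct, base_tr$tumor_size_mm)
  if (sum(ok) >= 3 && stats::sd(base_tr$average_vaf_pct[ok]) > 0)
    correlations$baseline_vaf_vs_size <-
      correlate(base_tr$average_vaf_pct[ok], base_tr$tumor_size_mm[ok])
  ev <- trajectories[grepl("^eval", trajectories$timepoint), , drop = FALSE]
  ev <- ev[!duplicated(ev$patient_id), , drop = FALSE]
  ok <- complete.cases(ev$delta_vaf_pct, ev$tumor_size_change_pct)
  if (sum(ok) >= 3 && stats::sd(ev$delta_vaf_pct[ok]) > 0)
    correlations$delta_vaf_vs_size_change <-
      correlate(ev$delta_vaf_pct[ok], ev$tumor_size_change_pct[ok])

  cascade_tbl <- purrr::map_dfr(sets, function(s)
    mutate(as_tibble(table(disposition = s$cascade_log$disposition)),
           sample_id = s$sample_id))

  report <- structure(list(
    cohort_summary = list(
      n_patients = length(patients),
      n_baseline_positive = sum(vapply(baseline_sets, function(s)
        nrow(s$calls) > 0, logical(1))),
      pct_positive = pct(sum(vapply(baseline_sets, function(s)
        nrow(s$calls) > 0, logical(1))), length(baseline_sets)),
      total_baseline_mutations = freq_base$total_mutations,
      mean_mutations_per_positive = freq_base$mean_mutations_per_positive,
      mean_avg_vaf_baseline_pct = mean(base_tr$average_vaf_pct),
      pct_cleared = pct(sum(known$label == "cleared"), nrow(known)),
      n_emergent = if (!is.null(freq_em)) freq_em$total_mutations else 0L
    ),
    frequency_baseline = freq_base,
    frequency_emergent = freq_em,
    trajectories = trajectories,
    clearance = clearance_tbl,
    concordance = list(per_patient = conc_tbl, totals = conc_totals),
    emergent = if (nrow(em_calls) > 0) annotate_calls(em_calls) else
      em_calls,
    survival_by_clearance = surv,
    correlations = correlations,
    blacklist_size = length(blacklist$entries),
    cascade = cascade_tbl,
    somatic_sets = sets
  ), class = "ctdna_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

pct <- function(num, den) if (den > 0) round(100 * num / den, 1) else NA_real_

#' @export
print.ctdna_report <- function(x, ...) {
  cs <- x$cohort_summary
  cat("<ctdna_report> ", cs$n_patients, " patients; ",
      cs$n_baseline_positive, " (", cs$pct_positive,
      "%) mutation-positive at baseline; ", cs$total_baseline_mutations,
      " baseline mutations; ", cs$n_emergent,
      " emergent at PD\n", sep = "")
  invisible(x)
}

#' Write pipeline artifacts and a manifest
#'
#' @param report A `ctdna_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) {
    readr::write_tsv(x, file.path(dir, name), progress = FALSE)
    name
  }
  files <- c(
    w(report$frequency_baseline$table, "frequency_baseline.tsv"),
    if (!is.null(report$frequency_emergent))
      w(report$frequency_emergent$table, "frequency_emergent.tsv"),
    w(report$trajectories, "trajectories.tsv"),
    w(report$clearance, "clearance.tsv"),
    if (nrow(report$concordance$per_patient) > 0)
      w(report$concordance$per_patient, "concordance.tsv"),
    if (nrow(report$emergent) > 0) w(report$emergent, "emergent.tsv"),
    w(report$cascade, "cascade_log_counts.tsv")
  )
  summary <- report[c("cohort_summary", "survival_by_clearance",
                      "correlations", "blacklist_size")]
  summary$concordance_totals <- report$concordance$totals
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       null = "null")
  files <- c(files, "report.json")
  writeLines(files, file.path(dir, "manifest.txt"))
  invisible(dir)
}
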