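#' Order of longitudinal timepoint labels
#'
#' Samples are labelled `baseline`, then `eval1`, `eval2`, ... at successive
#' response evaluations, then `PD` at confirmed progression. `baseline`
#' precedes every eval label, which precede `PD`.
#'
#' @param timepoint Character vector of labels.
#' @return Numeric rank (baseline = 0, evalK = K, PD = Inf).
#' @export
timepoint_rank <- function(timepoint) {
  rk <- rep(NA_real_, length(timepoint))
  rk[timepoint == "baseline"] <- 0
  rk[timepoint == "PD"] <- Inf
  ev <- grepl("^eval[0-9]+$", timepoint)
  rk[ev] <- as.numeric(sub("^eval", "", timepoint[ev]))
  if (anyNA(rk))
    stop("unknown timepoint label(s): ",
         paste(unique(timepoint[is.na(rk)]), collapse = ", "), call. = FALSE)
  rk
}

#' Read variant calls from a VCF file
#'
#' Expects a VCF 4.2 with per-sample `DP` (total depth) and `AD`
#' (ref,alt allele depths) FORMAT fields; multi-allelic records are split
#' into one call per ALT allele and the VAF is recomputed as
#' `AD[alt] / DP`. Gene, functional class and HGVS strings are taken from
#' the INFO fields `GENE`, `FUNC`, `BC`, `AAC` when present.
#'
#' @param path Path to the VCF.
#' @param sample_id Sample identifier attached to the calls.
#' @param normalize_chr Strip `"chr"` prefixes from chromosome labels.
#' @return A variant-call tibble (see [variant_calls()]).
#' @export
read_vcf <- function(path, sample_id = NA_character_, normalize_chr = FALSE) {
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("malformed VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  fix <- as.data.frame(vcfR::getFIX(vcf, getINFO = TRUE),
                       stringsAsFactors = FALSE)
  if (nrow(fix) == 0) return(empty_calls())
  fmt_keys <- unique(unlist(strsplit(vcf@gt[, "FORMAT"], ":", fixed = TRUE)))
  if (!all(c("DP", "AD") %in% fmt_keys))
    stop("VCF '", path, "' lacks per-sample DP/AD depth fields; ",
         "VAF cannot be computed", call. = FALSE)
  dp <- suppressWarnings(as.integer(vcfR::extract.gt(vcf, "DP")[, 1]))
  ad <- vcfR::extract.gt(vcf, "AD")[, 1]
  if (anyNA(dp) || anyNA(ad))
    stop("VCF '", path, "' has records without DP/AD annotations; ",
         "refusing to assume a VAF", call. = FALSE)
  info_field <- function(info, key) {
    m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]*)"), info))
    vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, "")
  }
  rows <- lapply(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    ads <- as.integer(strsplit(ad[i], ",", fixed = TRUE)[[1]])
    if (length(ads) != length(alts) + 1)
      stop("VCF '", path, "' record ", fix$CHROM[i], ":", fix$POS[i],
           ": AD has ", length(ads), " values for ", length(alts),
           " ALT allele(s)", call. = FALSE)
    tibble(
      chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
      ref = fix$REF[i], alt = alts,
      gene = info_field(fix$INFO[i], "GENE"),
      functional_raw = info_field(fix$INFO[i], "FUNC"),
      base_change = info_field(fix$INFO[i], "BC"),
      aa_change = info_field(fix$INFO[i], "AAC"),
      depth = dp[i], alt_reads = ads[-1]
    )
  })
  calls <- bind_rows(rows)
  calls$functional_class <- map_functional_class(calls$functional_raw)
  calls$functional_raw <- NULL
  calls$vaf <- ifelse(calls$depth > 0, calls$alt_reads / calls$depth, NA_real_)
  calls$sample_id <- as.character(sample_id)
  calls$base_change <- decode_hgvs(calls$base_change)
  calls$aa_change <- decode_hgvs(calls$aa_change)
  if (normalize_chr) calls <- normalize_chrom(calls)
  validate_calls(calls)
}

# spaces/angle brackets are not legal inside INFO values; percent-encode
encode_hgvs <- function(x) {
  x <- gsub(" ", "%20", x, fixed = TRUE)
  gsub(";", "%3B", x, fixed = TRUE)
}
decode_hgvs <- function(x) {
  x <- gsub("%20", " ", x, fixed = TRUE)
  gsub("%3B", ";", x, fixed = TRUE)
}

#' Write variant calls as a minimal VCF 4.2
#'
#' One record per call (no multi-allelic merging on write), with
#' `GT:DP:AD` genotype columns and the gene / functional-class / HGVS
#' annotations in INFO. Round-trips through [read_vcf()].
#'
#' @param calls Variant-call tibble with depth and alt_reads.
#' @param path Output path.
#' @param sample_name Column header for the genotype column.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, sample_name = NULL) {
  calls <- validate_calls(calls)
  sample_name <- sample_name %||%
    (if (nrow(calls) > 0 && !is.na(calls$sample_id[1])) calls$sample_id[1] else "SAMPLE")
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Panel gene symbol\">",
    "##INFO=<ID=FUNC,Number=1,Type=String,Description=\"Functional class\">",
    "##INFO=<ID=BC,Number=1,Type=String,Description=\"HGVS c. change\">",
    "##INFO=<ID=AAC,Number=1,Type=String,Description=\"HGVS p. change\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Deduplicated read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t")
  )
  if (nrow(calls) > 0) {
    ord <- order(calls$chrom, calls$pos, calls$ref, calls$alt)
    calls <- calls[ord, , drop = FALSE]
    info <- paste0(
      "GENE=", calls$gene, ";FUNC=", calls$functional_class,
      ifelse(is.na(calls$base_change), "",
             paste0(";BC=", encode_hgvs(calls$base_change))),
      ifelse(is.na(calls$aa_change), "",
             paste0(";AAC=", encode_hgvs(calls$aa_change)))
    )
    gt <- paste0("0/1:", calls$depth, ":",
                 calls$depth - calls$alt_reads, ",", calls$alt_reads)
    body <- paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt, ".",
                  "PASS", info, "GT:DP:AD", gt, sep = "\t")
  } else body <- character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

# Table-style TSV dialect: Chr Start End Ref Alt Functional Gene
# "Base change" "AA change" "VAF (%)" [Depth AltReads Sample]
.table_cols <- c("Chr", "Start", "End", "Ref", "Alt", "Functional", "Gene",
                 "Base change", "AA change", "VAF (%)")

#' Read variant calls from a tabular (TSV) variant list
#'
#' Reads the tab-separated dialect used for reporting panel variants:
#' columns `Chr Start End Ref Alt Functional Gene "Base change" "AA change"
#' "VAF (%)"`, plus optional `Depth`, `AltReads` and `Sample` columns. VAF
#' is given in percent and converted to a fraction; when read counts are
#' present the VAF is recomputed from `AltReads / Depth` so that write/read
#' round-trips are lossless. Functional strings are mapped through
#' [map_functional_class()] (unknown strings become `"other"` with a
#' warning).
#'
#' @param path Path to the TSV.
#' @param sample_id Sample identifier to attach when no `Sample` column
#'   exists.
#' @param normalize_chr Strip `"chr"` prefixes.
#' @return A variant-call tibble.
#' @export
read_variant_table <- function(path, sample_id = NA_character_,
                               normalize_chr = FALSE) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  miss <- setdiff(setdiff(.table_cols, "End"), names(tab))
  if (length(miss) > 0)
    stop("variant table '", path, "' is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(tab) == 0) return(empty_calls())
  vaf_pct <- suppressWarnings(as.numeric(tab$`VAF (%)`))
  if (anyNA(vaf_pct))
    stop("non-numeric VAF (%) value(s) in '", path, "'", call. = FALSE)
  calls <- tibble(
    sample_id = if ("Sample" %in% names(tab)) tab$Sample
                else rep(as.character(sample_id), nrow(tab)),
    chrom = tab$Chr,
    pos = as.integer(tab$Start),
    ref = tab$Ref, alt = tab$Alt, gene = tab$Gene,
    functional_class = map_functional_class(tab$Functional),
    depth = if ("Depth" %in% names(tab))
      suppressWarnings(as.integer(tab$Depth)) else NA_integer_,
    alt_reads = if ("AltReads" %in% names(tab))
      suppressWarnings(as.integer(tab$AltReads)) else NA_integer_,
    base_change = tab$`Base change`,
    aa_change = tab$`AA change`
  )
  have <- !is.na(calls$depth) & !is.na(calls$alt_reads) & calls$depth > 0
  calls$vaf <- ifelse(have, calls$alt_reads / calls$depth, vaf_pct / 100)
  if (normalize_chr) calls <- normalize_chrom(calls)
  validate_calls(calls)
}

#' Write variant calls to the tabular dialect
#'
#' @param calls Variant-call tibble.
#' @param path Output path.
#' @param digits Decimal places for the VAF percent column.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(calls, path, digits = 6) {
  calls <- validate_calls(calls)
  out <- tibble(
    Chr = calls$chrom, Start = calls$pos,
    End = calls$pos + nchar(calls$ref) - 1L,
    Ref = calls$ref, Alt = calls$alt,
    Functional = calls$functional_class, Gene = calls$gene,
    `Base change` = calls$base_change, `AA change` = calls$aa_change,
    `VAF (%)` = round(calls$vaf * 100, digits),
    Depth = calls$depth, AltReads = calls$alt_reads,
    Sample = calls$sample_id
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' CSV with columns `sample_id, patient_id, material, timepoint,
#' panel_version` mapping each sequenced library to its patient, material
#' (`cfDNA`, `tissue_FFPE`, `tissue_frozen`, `PBMC`) and timepoint label.
#'
#' @param path Path to the CSV.
#' @return Tibble of sample metadata.
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  req <- c("sample_id", "patient_id", "material", "timepoint", "panel_version")
  miss <- setdiff(req, names(sheet))
  if (length(miss) > 0)
    stop("sample sheet is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  dup <- sheet$sample_id[duplicated(sheet$sample_id)]
  if (length(dup) > 0)
    stop("duplicate sample_id in sample sheet: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(sheet$material), MATERIALS)
  if (length(bad) > 0)
    stop("unknown material token(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  timepoint_rank(sheet$timepoint) # validates labels
  badp <- setdiff(unique(sheet$panel_version), c("v2", "v3"))
  if (length(badp) > 0)
    stop("unknown panel_version token(s): ", paste(badp, collapse = ", "),
         call. = FALSE)
  sheet
}

#' Read a clinical table
#'
#' CSV with columns `patient_id, best_response, pfs_months, pfs_event,
#' cea_ng_ml, cfdna_conc, met_sites` plus any number of `size_<timepoint>`
#' columns holding target-lesion sizes in mm. `met_sites` is a
#' semicolon-separated subset of liver/lung/peritoneum/lymph_node/other.
#'
#' @param path Path to the CSV.
#' @param samples Optional sample sheet; when supplied, every sample's
#'   patient must appear in the clinical table (referential integrity).
#' @return Tibble of clinical records.
#' @export
read_clinical <- function(path, samples = NULL) {
  clin <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("patient_id", "best_response", "pfs_months", "pfs_event")
  miss <- setdiff(req, names(clin))
  if (length(miss) > 0)
    stop("clinical table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(clin$patient_id))
    stop("duplicate patient_id in clinical table", call. = FALSE)
  badr <- setdiff(unique(clin$best_response), c("PR", "SD", "PD", "NE"))
  if (length(badr) > 0)
    stop("unknown best_response token(s): ", paste(badr, collapse = ", "),
         call. = FALSE)
  if (any(clin$pfs_months < 0, na.rm = TRUE))
    stop("pfs_months must be non-negative", call. = FALSE)
  size_cols <- grep("^size_", names(clin), value = TRUE)
  for (sc in size_cols)
    if (any(clin[[sc]] < 0, na.rm = TRUE))
      stop("tumor sizes must be non-negative (", sc, ")", call. = FALSE)
  clin$pfs_event <- as.logical(clin$pfs_event)
  if (!is.null(samples)) {
    orphan <- setdiff(unique(samples$patient_id), clin$patient_id)
    if (length(orphan) > 0)
      stop("sample sheet references patient(s) absent from clinical table: ",
           paste(orphan, collapse = ", "), call. = FALSE)
  }
  clin
}

#' Target-lesion size at a timepoint
#'
#' @param clinical Clinical tibble from [read_clinical()].
#' @param patient_id Patient.
#' @param timepoint Timepoint label; looked up in the `size_<timepoint>`
#'   column.
#' @return Size in mm, or `NA` when unmeasured.
#' @export
tumor_size <- function(clinical, patient_id, timepoint) {
  col <- paste0("size_", timepoint)
  if (!col %in% names(clinical)) return(NA_real_)
  i <- match(patient_id, clinical$patient_id)
  if (is.na(i)) return(NA_real_)
  as.numeric(clinical[[col]][i])
}
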