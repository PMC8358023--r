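# shared fixtures, built in code at test time

# random variant calls spanning both sides of every filter boundary
random_calls <- function(n, seed, sample_id = "S1") {
  set.seed(seed)
  genes <- panel_genes("v3")
  depth <- sample(200:4000, n, replace = TRUE)
  vaf <- stats::runif(n, 0, 0.6)
  # plant a few calls exactly on the 1% / 10% / 20% boundaries
  planted <- sample(n, min(n, 6))
  vaf[planted] <- rep(c(0.01, 0.10, 0.20), length.out = length(planted))
  alt_n <- pmin(depth, pmax(0L, as.integer(round(vaf * depth))))
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  validate_calls(tibble::tibble(
    sample_id = sample_id,
    chrom = as.character(sample(1:22, n, replace = TRUE)),
    pos = sample.int(1e8, n),
    ref = ref,
    alt = ifelse(ref == "A", "G", "A"),
    gene = sample(genes, n, replace = TRUE),
    functional_class = sample(FUNCTIONAL_CLASSES, n, replace = TRUE),
    depth = depth, alt_reads = alt_n,
    base_change = NA_character_, aa_change = NA_character_,
    vaf = alt_n / depth
  ))
}

# one-pass brute-force reference filter, independent of the cascade code
brute_force_filter <- function(calls, material, cfg = filter_config(),
                               germline_keys = character(0),
                               blacklist_keys = character(0)) {
  kept <- logical(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    cl <- calls[i, ]
    if (!cl$functional_class %in% cfg$allowed_classes) next
    if (material == "cfDNA") {
      if (cl$vaf * 100 < cfg$cfdna_min_vaf_pct - 1e-9) next
      if (cl$alt_reads < cfg$cfdna_min_alt_reads) next
    } else {
      if (cl$vaf * 100 < cfg$tissue_min_vaf_pct - 1e-9) next
      if (cl$alt_reads < cfg$tissue_min_alt_reads) next
    }
    key <- paste0(cl$chrom, ":", cl$pos, ":", cl$ref, ">", cl$alt)
    if (key %in% germline_keys) next
    if (key %in% blacklist_keys) next
    kept[i] <- TRUE
  }
  calls[kept, , drop = FALSE]
}

# a somatic_set wrapper around plain VAF percentages, for trajectory tests
set_from_vafs <- function(vaf_pct, material = "cfDNA", patient = "P1",
                          sample_id = "S") {
  n <- length(vaf_pct)
  calls <- if (n == 0) {
    variant_calls(chrom = character(0), pos = integer(0),
                  ref = character(0), alt = character(0),
                  gene = character(0), functional_class = character(0),
                  depth = integer(0), alt_reads = integer(0),
                  vaf = numeric(0))
  } else {
    variant_calls(chrom = "1", pos = seq_len(n) * 1000L, ref = "A",
                  alt = "T", gene = "APC", functional_class = "missense",
                  depth = 100000L,
                  alt_reads = as.integer(round(vaf_pct * 1000)),
                  sample_id = sample_id)
  }
  calls$material <- rep("cfDNA", nrow(calls))
  finalize_somatic(calls, patient_id = patient) |>
    (\(s) { s$material <- material; s })()
}

# memoized small cohort shared across test files
shared_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_cohort(sim_params(n_patients = 40, seed = 2024))
    cache
  }
})

# expected kept somatic keys for one sample, derived from planted truth
# plus the emitted observed counts (thresholds applied by hand)
expected_somatic_keys <- function(cohort, sample_id,
                                  cfg = filter_config()) {
  s <- cohort$samples[cohort$samples$sample_id == sample_id, ]
  tv <- cohort$truth$variants
  som_keys <- tv$key[tv$patient_id == s$patient_id &
                       tv$role %in% c("somatic_core", "somatic_low_shed",
                                      "emergent")]
  emitted <- cohort$calls[cohort$calls$sample_id == sample_id, ]
  keys <- variant_keys(emitted)
  if (s$material == "cfDNA") {
    pass <- emitted$vaf >= cfg$cfdna_min_vaf_pct / 100 - 1e-9 &
      emitted$alt_reads >= cfg$cfdna_min_alt_reads
  } else {
    pass <- emitted$vaf >= cfg$tissue_min_vaf_pct / 100 - 1e-9 &
      emitted$alt_reads >= cfg$tissue_min_alt_reads
  }
  sort(keys[pass & keys %in% som_keys])
}
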