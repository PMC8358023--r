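# 200-patient cohort + its analysis, shared by the recovery tests
big_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_cohort(sim_params(n_patients = 200, seed = 424))
    cache
  }
})

big_report <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- big_cohort()
      cache <<- analyze_cohort(co$calls, co$samples, co$clinical)
    }
    cache
  }
})

# per-patient baseline average VAF derived directly from the emitted calls
# and the planted truth (cheap stand-in for a full pipeline run when only
# the generator's statistical structure is under test)
truth_side_avg_vaf <- function(cohort) {
  base <- cohort$calls[cohort$calls$material == "cfDNA" &
                         cohort$calls$timepoint == "baseline", ]
  tv <- cohort$truth$variants
  som <- tv[tv$role == "somatic_core", c("patient_id", "key")]
  vapply(split(base, base$patient_id), function(b) {
    keys <- variant_keys(b)
    is_som <- keys %in% som$key[som$patient_id == b$patient_id[1]]
    det <- is_som & b$vaf >= 0.01 & b$alt_reads >= 10
    if (any(det)) mean(b$vaf[det]) * 100 else 0
  }, numeric(1))
}
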