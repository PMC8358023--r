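{
  "n_patients": 93,
  "n_baseline_positive": 84,
  "n_baseline_mutations": 230,
  "n_ras_carrier_patients": 7,
  "n_response_evaluable": 92,
  "n_pr": 69,
  "n_sd": 19,
  "n_pd": 4,
  "n_tissue_patients": 66,
  "n_tissue_variants": 137,
  "n_tissue_matched": 97,
  "n_tissue_unmatched_rescued": 34,
  "n_ctdna_only": 44,
  "n_ctdna_only_subthreshold": 31,
  "n_patients_tissue_covered": 50,
  "n_pd_blood_patients": 54,
  "n_emergent_mutations": 54,
  "n_emergent_pathogenic": 11,
  "n_emergent_uncertain": 5,
  "mean_avg_vaf_baseline_pct": 23.34,
  "clearance_rate_pct": 76.2,
  "liver_met_detected": [68, 71],
  "no_liver_met_detected": [16, 22],
  "power_n": 78,
  "power_p0": 0.7,
  "power_p1": 0.9,
  "power_alpha": 0.05
}
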