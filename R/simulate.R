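#' Simulation parameters for a synthetic ctDNA cohort
#'
#' Defaults encode the cohort structure the analysis assumes: 93 patients
#' sequenced at ~2000x deduplicated depth, ~9.7% of patients with no
#' detectable ctDNA, a mean of 2.74 somatic mutations among
#' mutation-positive patients, per-patient baseline tumor burden drawn
#' log-normal and calibrated so the cohort mean of per-patient average VAF
#' is ~23.3%, germline heterozygous/homozygous variants near 50%/100% VAF
#' shared between PBMC, plasma and tissue, low-VAF clonal-hematopoiesis
#' variants shared between PBMC and plasma, response mix PR/SD/PD of
#' roughly 75/21/4%, a 76.2% clearance rate at the first evaluation coupled
#' to response, and progression-free survival exponential with a
#' clearance-group hazard ratio.
#'
#' The burden distribution is truncated to \[3%, 90%\] and planted VAFs keep
#' a guard band away from the 1% clearance/detection cutoff and the 20%
#' germline boundary, so that binomial read noise at the default depth
#' cannot flip a planted truth label across a decision boundary.
#'
#' @param n_patients Cohort size.
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @param depth_mean Mean deduplicated depth per locus.
#' @param somatic_mean Mean somatic mutations per mutation-positive patient.
#' @param dropout_rate Fraction of patients with no detectable ctDNA.
#' @param burden_meanlog,burden_sdlog,burden_range Log-normal baseline
#'   burden (fraction) and its truncation range.
#' @param germline_het,germline_hom Germline variant counts per patient.
#' @param germline_pool_size Cohort pool of germline keys patients draw
#'   from (shared polymorphisms).
#' @param ch_pool_size,ch_carrier_prob,ch_private_mean,ch_vaf_range
#'   Clonal-hematopoiesis structure: shared pool size, per-patient carrier
#'   probability per pool variant, mean private CH variants, VAF range
#'   (kept below the 20% germline boundary).
#' @param shedding_coef Link from burden to baseline target-lesion size
#'   (mm of lesion per VAF percentage point); 0 decouples them.
#' @param size_base_mm,size_noise_sd Baseline size intercept and noise.
#' @param response_probs Named PR/SD/PD probabilities.
#' @param clearance_by_response Named P(cleared | response).
#' @param tissue_rate,pd_sample_rate Availability of archival tissue and of
#'   a PD blood sample.
#' @param emergent_mean Mean resistance mutations emerging at PD per
#'   PD-sampled patient.
#' @param hr_clearance PFS hazard ratio, not-cleared vs cleared.
#' @param median_pfs_cleared Median PFS (months) of the cleared group.
#' @param followup_months Administrative censoring horizon.
#' @param panel_version Panel for v3 patients; `v3_fraction` of patients
#'   get v3, the rest v2.
#' @param v3_fraction Fraction of patients sequenced on panel v3.
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_patients = 93, seed = 1, depth_mean = 2000,
                       somatic_mean = 2.74, dropout_rate = 0.097,
                       burden_meanlog = -1.74, burden_sdlog = 1,
                       burden_range = c(0.03, 0.9),
                       germline_het = 12L, germline_hom = 4L,
                       germline_pool_size = 80L,
                       ch_pool_size = 15L, ch_carrier_prob = 0.12,
                       ch_private_mean = 0.3,
                       ch_vaf_range = c(0.01, 0.12),
                       shedding_coef = 1.0,
                       size_base_mm = 12, size_noise_sd = 22,
                       response_probs = c(PR = 0.750, SD = 0.207, PD = 0.043),
                       clearance_by_response = c(PR = 0.88, SD = 0.48,
                                                 PD = 0.10),
                       tissue_rate = 0.71, pd_sample_rate = 0.58,
                       emergent_mean = 1.0,
                       hr_clearance = 2.16, median_pfs_cleared = 11.9,
                       followup_months = 30,
                       panel_version = "v3", v3_fraction = 69 / 93) {
  p <- as.list(environment())
  stopifnot(p$n_patients >= 1, p$dropout_rate >= 0, p$dropout_rate <= 1,
            p$tissue_rate >= 0, p$tissue_rate <= 1,
            p$pd_sample_rate >= 0, p$pd_sample_rate <= 1,
            p$ch_carrier_prob >= 0, p$ch_carrier_prob <= 1,
            all(p$ch_vaf_range > 0), all(p$ch_vaf_range < 0.2),
            abs(sum(p$response_probs) - 1) < 1e-6,
            p$burden_range[1] > 0.01, p$burden_range[2] <= 0.95,
            p$somatic_mean >= 1, p$hr_clearance > 0,
            p$seed == as.integer(p$seed))
  structure(p, class = "sim_params")
}

# approximate relative baseline mutation rates of the panel genes
.gene_weights <- c(APC = 0.44, TP53 = 0.29, ERBB2 = 0.055, PTEN = 0.026,
                   KRAS = 0.028, PIK3CA = 0.026, MET = 0.017,
                   PDGFRB = 0.013, BRAF = 0.013, NRAS = 0.009,
                   ERBB3 = 0.009, MAP2K1 = 0.006, EGFR = 0.005,
                   FGFR1 = 0.005, HRAS = 0.004, IRS1 = 0.019)

.emergent_gene_weights <- c(KRAS = 0.25, MAP2K1 = 0.15, APC = 0.18,
                            TP53 = 0.16, ERBB2 = 0.12, PIK3CA = 0.05,
                            ERBB3 = 0.04, NRAS = 0.03, HRAS = 0.02)

.allowed_class_weights <- c(missense = 0.70, stop_gain = 0.12,
                            frameshift = 0.10, inframe_deletion = 0.05,
                            stop_loss = 0.03)

#' Simulate a full synthetic cohort
#'
#' Generates, per patient, PBMC / baseline cfDNA / first-evaluation cfDNA
#' samples (plus tissue and PD cfDNA where available), with germline,
#' clonal-hematopoiesis, somatic, sub-threshold and synonymous variant
#' calls; read counts are binomial draws at targeted-panel depth. Returns
#' the emitted call tables together with the ground truth needed to verify
#' every downstream stage. Patient `i` is generated from a substream
#' derived deterministically from `seed` and `i`, so it is reproducible
#' independent of cohort size.
#'
#' @param params A [sim_params()] list.
#' @return List with `calls` (all emitted variant calls), `samples`
#'   (sample sheet), `clinical` (clinical table) and `truth` (planted
#'   variant roles and patient-level labels).
#' @export
simulate_cohort <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  iv <- gene_intervals()
  registry <- new.env(parent = emptyenv())
  catalog <- resistance_catalog()
  for (k in paste0(catalog$chrom, ":", catalog$pos))
    assign(k, TRUE, envir = registry)

  germ_pool <- draw_variants(params$germline_pool_size, iv, registry,
                             genes = panel_genes("v2"))
  ch_pool <- draw_variants(params$ch_pool_size, iv, registry,
                           genes = panel_genes("v2"))
  patient_seeds <- (as.integer(params$seed) %% 100000L) * 10007L +
    7919L * seq_len(params$n_patients)

  pats <- vector("list", params$n_patients)
  for (i in seq_len(params$n_patients)) {
    set.seed(patient_seeds[i])
    pats[[i]] <- simulate_patient(sprintf("P%03d", i), params, iv,
                                  registry, germ_pool, ch_pool, catalog)
  }
  calls <- bind_rows(lapply(pats, `[[`, "calls"))
  samples <- bind_rows(lapply(pats, `[[`, "samples"))
  clinical <- bind_rows(lapply(pats, `[[`, "clinical"))
  truth <- list(
    variants = bind_rows(lapply(pats, `[[`, "truth_variants")),
    patients = bind_rows(lapply(pats, `[[`, "truth_patient")),
    ch_pool_keys = paste0(ch_pool$chrom, ":", ch_pool$pos, ":",
                          ch_pool$ref, ">", ch_pool$alt),
    params_seed = params$seed
  )
  list(calls = calls, samples = samples, clinical = clinical, truth = truth)
}

# known anti-EGFR resistance alterations used for emergent RAS/MAPK draws
resistance_catalog <- function() {
  tibble(
    gene = c("KRAS", "KRAS", "KRAS", "KRAS", "NRAS", "MAP2K1", "MAP2K1"),
    chrom = c("12", "12", "12", "12", "1", "15", "15"),
    pos = c(25398284L, 25398285L, 25380275L, 25398281L, 115256529L,
            66727454L, 66727455L),
    ref = c("C", "C", "T", "C", "T", "A", "G"),
    alt = c("A", "A", "G", "T", "C", "C", "T"),
    base_change = c("c.35G > T", "c.34G > T", "c.183A > C", "c.38G > A",
                    "c.182A > G", "c.170A > C", "c.171G > T"),
    aa_change = c("p.Gly12Val", "p.Gly12Cys", "p.Gln61His", "p.Gly13Asp",
                  "p.Gln61Arg", "p.Lys57Thr", "p.Lys57Asn"),
    functional_class = "missense"
  )
}

# draw n novel variant keys; positions unique cohort-wide via the registry
draw_variants <- function(n, intervals, registry, genes = NULL,
                          weights = NULL, classes = NULL) {
  if (n == 0)
    return(tibble(gene = character(0), chrom = character(0),
                  pos = integer(0), ref = character(0), alt = character(0),
                  functional_class = character(0)))
  if (is.null(genes)) genes <- intervals$gene
  w <- if (is.null(weights)) rep(1, length(genes))
       else { w0 <- weights[genes]; w0[is.na(w0)] <- 0.005; unname(w0) }
  bases <- c("A", "C", "G", "T")
  out <- vector("list", n)
  for (j in seq_len(n)) {
    repeat {
      g <- sample(genes, 1, prob = w)
      row <- intervals[intervals$gene == g, ]
      pos <- sample.int(row$end - row$start, 1) + row$start
      pk <- paste0(row$chrom, ":", pos)
      if (!exists(pk, envir = registry, inherits = FALSE)) {
        assign(pk, TRUE, envir = registry)
        ref <- sample(bases, 1)
        alt <- sample(setdiff(bases, ref), 1)
        cls <- if (is.null(classes))
          sample(names(.allowed_class_weights), 1,
                 prob = .allowed_class_weights)
        else classes
        out[[j]] <- tibble(gene = g, chrom = row$chrom, pos = as.integer(pos),
                           ref = ref, alt = alt, functional_class = cls)
        break
      }
    }
  }
  bind_rows(out)
}

rtrunc_lnorm <- function(meanlog, sdlog, range) {
  repeat {
    x <- rlnorm(1, meanlog, sdlog)
    if (x >= range[1] && x <= range[2]) return(x)
  }
}

simulate_patient <- function(patient_id, p, iv, registry, germ_pool,
                             ch_pool, catalog) {
  dropout <- runif(1) < p$dropout_rate
  tissue_avail <- runif(1) < p$tissue_rate
  pd_avail <- runif(1) < p$pd_sample_rate
  panel <- if (runif(1) < p$v3_fraction) p$panel_version else "v2"
  pgenes <- panel_genes(panel)
  response <- sample(names(p$response_probs), 1, prob = p$response_probs)
  cleared <- if (dropout) NA else
    runif(1) < p$clearance_by_response[[response]]
  burden <- rtrunc_lnorm(p$burden_meanlog, p$burden_sdlog, p$burden_range)

  # --- germline: draw shared pool variants; het near 50%, hom near 100%
  gidx <- sample.int(nrow(germ_pool), p$germline_het + p$germline_hom)
  germ <- germ_pool[gidx, ]
  germ$true_vaf <- c(pmin(0.65, pmax(0.35, rnorm(p$germline_het, 0.5, 0.02))),
                     runif(p$germline_hom, 0.985, 1.0))
  germ$role <- "germline"

  # --- clonal hematopoiesis: shared pool carriers + private variants
  carried <- ch_pool[runif(nrow(ch_pool)) < p$ch_carrier_prob, ]
  n_priv <- rpois(1, p$ch_private_mean)
  priv <- draw_variants(n_priv, iv, registry, genes = pgenes)
  ch <- bind_rows(carried, priv)
  ch$true_vaf <- if (nrow(ch)) runif(nrow(ch), p$ch_vaf_range[1],
                                     p$ch_vaf_range[2]) else numeric(0)
  ch$role <- if (nrow(ch)) c(rep("ch_shared", nrow(carried)),
                             rep("ch_private", nrow(priv))) else character(0)

  # --- somatic truth
  n_core <- if (dropout) 0L else 1L + rpois(1, p$somatic_mean - 1)
  core <- draw_variants(n_core, iv, registry, genes = pgenes,
                        weights = .gene_weights)
  if (n_core > 0) {
    core$true_vaf <- pmin(0.95, pmax(0.03, burden * runif(n_core, 0.6, 1.4)))
    core$in_tissue <- runif(n_core) < 0.75
    # plasma-only variants shed well; tissue misses them (heterogeneity)
    core$tissue_vaf <- ifelse(core$in_tissue, runif(n_core, 0.15, 0.6),
                              ifelse(runif(n_core) < 0.5,
                                     runif(n_core, 0.01, 0.08), 0))
    core$role <- "somatic_core"
  }
  # tissue variants shedding too little ctDNA to pass the 1% cutoff
  n_low <- if (dropout || !tissue_avail) 0L else rpois(1, 0.6)
  low <- draw_variants(n_low, iv, registry, genes = pgenes,
                       weights = .gene_weights)
  if (n_low > 0) {
    low$true_vaf <- runif(n_low, 0.001, 0.003)
    low$in_tissue <- TRUE
    low$tissue_vaf <- runif(n_low, 0.15, 0.6)
    low$role <- "somatic_low_shed"
  }
  som <- bind_rows(core, low)

  # --- first-evaluation burden (guard band around the 1% cutoff)
  t1 <- if (is.na(cleared)) NA_real_
        else if (cleared) runif(1, 0.0002, 0.003)
        else runif(1, 0.03, 0.03 + 0.5 * burden)
  if (nrow(som)) {
    som$eval1_vaf <- ifelse(som$role == "somatic_core",
                            pmin(0.95, t1 * runif(nrow(som), 0.9, 1.1)), 0)
    som$pd_vaf <- ifelse(som$role == "somatic_core",
                         pmin(0.95, pmax(0.03, burden *
                                           runif(nrow(som), 0.5, 1.2))), 0)
  }

  # --- emergent resistance mutations at PD
  n_em <- if (pd_avail) rpois(1, p$emergent_mean) else 0L
  em_wts <- .emergent_gene_weights[names(.emergent_gene_weights) %in% pgenes]
  em <- if (n_em > 0) {
    picks <- lapply(seq_len(n_em), function(j) {
      g <- sample(names(em_wts), 1, prob = em_wts)
      hot <- catalog[catalog$gene == g, ]
      if (nrow(hot) > 0 && runif(1) < 0.7) hot[sample.int(nrow(hot), 1), ]
      else draw_variants(1, iv, registry, genes = g)
    })
    e <- bind_rows(picks)
    # an emergent key must be new for this patient
    prior <- paste0(c(germ$chrom, ch$chrom, som$chrom),
                    ":", c(germ$pos, ch$pos, som$pos))
    e <- e[!duplicated(paste0(e$chrom, ":", e$pos)) &
             !paste0(e$chrom, ":", e$pos) %in% prior, , drop = FALSE]
    if (nrow(e)) {
      e$true_vaf <- runif(nrow(e), 0.03, 0.15)
      e$role <- "emergent"
    }
    e
  } else draw_variants(0, iv, registry)

  # --- synonymous + low-level noise calls exercise class/threshold filters
  syn_mk <- function(n_syn, vmin, vmax) {
    s <- draw_variants(n_syn, iv, registry, genes = pgenes)
    if (n_syn > 0) {
      s$functional_class <- "other"
      s$true_vaf <- runif(n_syn, vmin, vmax)
    }
    s
  }

  # --- tumor size trajectory
  size0 <- max(6, p$size_base_mm + p$shedding_coef * 100 * burden +
                 rnorm(1, 0, p$size_noise_sd))
  size1 <- size0 * switch(response, PR = runif(1, 0.35, 0.65),
                          SD = runif(1, 0.75, 1.15),
                          PD = runif(1, 1.25, 1.7))
  size_pd <- size0 * runif(1, 1.2, 1.8)

  # --- PFS linked to clearance
  rate0 <- log(2) / p$median_pfs_cleared
  rate <- if (isTRUE(cleared) || is.na(cleared)) rate0
          else rate0 * p$hr_clearance
  t_ev <- rexp(1, rate)
  cens <- runif(1, 6, p$followup_months)
  pfs <- min(t_ev, cens)
  event <- t_ev <= cens

  # --- clinical covariates
  cea <- rlnorm(1, log(if (dropout) 4.6 else 35.8), 1.1)
  conc <- rlnorm(1, log(10), 0.8)
  p_liver <- if (dropout) 0.35 else 0.82
  sites <- c(if (runif(1) < p_liver) "liver",
             if (runif(1) < 0.23) "lung",
             if (runif(1) < 0.21) "peritoneum",
             if (runif(1) < 0.29) "lymph_node",
             if (runif(1) < 0.10) "other")

  # --- emit observed calls per sample
  dp <- function(n) pmax(200L, as.integer(round(
    rnorm(n, p$depth_mean, 0.1 * p$depth_mean))))
  observe <- function(v, sample_id, material, timepoint, vaf_col) {
    if (nrow(v) == 0) return(empty_calls())
    dpv <- dp(nrow(v))
    altv <- rbinom(nrow(v), dpv, v[[vaf_col]])
    keep <- altv > 0
    obs_vaf <- altv[keep] / dpv[keep]
    obs_dp <- dpv[keep]
    obs_alt <- altv[keep]
    validate_calls(tibble(
      sample_id = sample_id, chrom = v$chrom[keep], pos = v$pos[keep],
      ref = v$ref[keep], alt = v$alt[keep], gene = v$gene[keep],
      functional_class = v$functional_class[keep],
      depth = obs_dp, alt_reads = obs_alt,
      base_change = if ("base_change" %in% names(v)) v$base_change[keep]
                    else NA_character_,
      aa_change = if ("aa_change" %in% names(v)) v$aa_change[keep]
                  else NA_character_,
      vaf = obs_vaf
    )) %>% mutate(patient_id = patient_id, material = material,
                  timepoint = timepoint, panel_version = panel)
  }

  sid <- function(tag) paste0(patient_id, "_", tag)
  base_cols <- c("gene", "chrom", "pos", "ref", "alt", "functional_class")
  # subset to the emission columns, tolerating 0-row pieces
  sel <- function(v, vaf_col = "true_vaf", extra = character(0)) {
    if (is.null(v) || nrow(v) == 0) return(NULL)
    out <- v[, c(base_cols, vaf_col, intersect(extra, names(v)))]
    names(out)[names(out) == vaf_col] <- "true_vaf"
    out
  }
  plasma_truth <- bind_rows(sel(germ), sel(ch))
  calls <- list(
    observe(plasma_truth, sid("PBMC"), "PBMC", "baseline", "true_vaf"),
    observe(bind_rows(plasma_truth, sel(som),
                      sel(syn_mk(rpois(1, 0.7), 0.01, 0.3))),
            sid("B"), "cfDNA", "baseline", "true_vaf")
  )
  ev_som <- if (nrow(som)) som[som$eval1_vaf > 0, ] else som
  ev_truth <- bind_rows(sel(germ), sel(ch), sel(ev_som, "eval1_vaf"))
  calls <- c(calls, list(
    observe(ev_truth, sid("E1"), "cfDNA", "eval1", "true_vaf")))
  if (pd_avail) {
    pd_som <- if (nrow(som)) som[som$pd_vaf > 0, ] else som
    pd_truth <- bind_rows(
      sel(germ), sel(ch), sel(pd_som, "pd_vaf"),
      sel(em, extra = c("base_change", "aa_change")))
    calls <- c(calls, list(
      observe(pd_truth, sid("PD"), "cfDNA", "PD", "true_vaf")))
  }
  tissue_mat <- if (runif(1) < 0.7) "tissue_FFPE" else "tissue_frozen"
  if (tissue_avail) {
    tis_som <- if (nrow(som)) som[som$tissue_vaf > 0, ] else som
    tis_truth <- bind_rows(sel(germ), sel(tis_som, "tissue_vaf"))
    calls <- c(calls, list(
      observe(tis_truth, sid("T"), tissue_mat, "baseline", "true_vaf")))
  }
  calls <- bind_rows(calls)

  tps <- c("PBMC", "B", "E1", if (pd_avail) "PD", if (tissue_avail) "T")
  samples <- tibble(
    sample_id = vapply(tps, sid, ""),
    patient_id = patient_id,
    material = c("PBMC", "cfDNA", "cfDNA", if (pd_avail) "cfDNA",
                 if (tissue_avail) tissue_mat),
    timepoint = c("baseline", "baseline", "eval1", if (pd_avail) "PD",
                  if (tissue_avail) "baseline"),
    panel_version = panel
  )
  clinical <- tibble(
    patient_id = patient_id, best_response = response,
    pfs_months = round(pfs, 3), pfs_event = event,
    cea_ng_ml = round(cea, 2), cfdna_conc = round(conc, 2),
    met_sites = paste(sites, collapse = ";"),
    size_baseline = round(size0, 1), size_eval1 = round(size1, 1),
    size_PD = round(size_pd, 1)
  )
  tv <- bind_rows(
    germ %>% mutate(in_tissue = tissue_avail, tissue_vaf = .data$true_vaf,
                    eval1_vaf = .data$true_vaf, pd_vaf = .data$true_vaf),
    if (nrow(ch)) ch %>% mutate(in_tissue = FALSE, tissue_vaf = 0,
                                eval1_vaf = .data$true_vaf,
                                pd_vaf = .data$true_vaf),
    if (nrow(som)) som,
    if (nrow(em)) em %>% mutate(in_tissue = FALSE, tissue_vaf = 0,
                                eval1_vaf = 0, pd_vaf = .data$true_vaf)
  ) %>% mutate(patient_id = patient_id,
               key = paste0(.data$chrom, ":", .data$pos, ":", .data$ref,
                            ">", .data$alt))
  list(
    calls = calls, samples = samples, clinical = clinical,
    truth_variants = tv,
    truth_patient = tibble(
      patient_id = patient_id, dropout = dropout, burden = burden,
      response = response, cleared = cleared, eval1_target_vaf = t1,
      tissue_avail = tissue_avail, pd_avail = pd_avail,
      panel_version = panel, pfs_months = round(pfs, 3), pfs_event = event,
      n_core = n_core, n_emergent = if (nrow(em)) nrow(em) else 0L
    )
  )
}

#' Write a simulated cohort to disk
#'
#' Emits exactly the formats the readers consume: one variant table per
#' sample under `variants/`, `sample_sheet.csv`, `clinical.csv`, and the
#' ground truth as `truth.json`.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  vd <- file.path(dir, "variants")
  dir.create(vd, recursive = TRUE, showWarnings = FALSE)
  for (sid in cohort$samples$sample_id) {
    sc <- cohort$calls[cohort$calls$sample_id == sid,
                       c("sample_id", "chrom", "pos", "ref", "alt", "gene",
                         "functional_class", "depth", "alt_reads",
                         "base_change", "aa_change", "vaf")]
    write_variant_table(sc, file.path(vd, paste0(sid, ".tsv")))
  }
  readr::write_csv(cohort$samples, file.path(dir, "sample_sheet.csv"),
                   progress = FALSE)
  readr::write_csv(cohort$clinical, file.path(dir, "clinical.csv"),
                   progress = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(dir)
}

#' Simulate UMI-tagged reads at one locus
#'
#' Generates reads with a known family structure and planted per-read
#' errors, for testing duplicate collapsing. `dup_rate` is the fraction of
#' reads that are PCR copies of an earlier molecule: 0 means every read is
#' its own molecule, 1 means all reads descend from a single molecule (a
#' duplication factor f maps to `dup_rate = 1 - 1/f`).
#'
#' @param true_vaf Fraction of original molecules carrying the alternate
#'   allele.
#' @param n_reads Total reads to emit.
#' @param dup_rate Duplicate fraction in \[0, 1\].
#' @param error_rate Per-read probability of flipping the observed allele.
#' @param ref,alt Alleles at the locus.
#' @param chrom,pos Locus coordinates.
#' @param seed Optional seed.
#' @return List with `reads` (tagged-read tibble), `molecules` (per-family
#'   truth) and `true_vaf`.
#' @export
simulate_umi_reads <- function(true_vaf, n_reads, dup_rate = 0,
                               error_rate = 0, ref = "C", alt = "T",
                               chrom = "12", pos = 25398284L, seed = NULL) {
  stopifnot(true_vaf >= 0, true_vaf <= 1, dup_rate >= 0, dup_rate <= 1,
            error_rate >= 0, error_rate < 0.5, n_reads >= 1)
  if (!is.null(seed)) set.seed(seed)
  n_mol <- max(1L, as.integer(round((1 - dup_rate) * n_reads)))
  umis <- make_umis(n_mol)
  mol <- tibble(
    umi = umis,
    start = as.integer(pos - sample.int(120L, n_mol, replace = TRUE)),
    strand = sample(c("+", "-"), n_mol, replace = TRUE),
    allele = ifelse(runif(n_mol) < true_vaf, alt, ref)
  )
  origin <- c(seq_len(n_mol),
              if (n_reads > n_mol)
                sample.int(n_mol, n_reads - n_mol, replace = TRUE))
  reads <- mol[origin, ]
  flip <- runif(n_reads) < error_rate
  reads$allele <- ifelse(flip, ifelse(reads$allele == ref, alt, ref),
                         reads$allele)
  reads <- tibble(umi = reads$umi, chrom = chrom, start = reads$start,
                  strand = reads$strand, allele = reads$allele)
  list(reads = reads, molecules = mol, true_vaf = true_vaf)
}

make_umis <- function(n, width = 8) {
  pool <- character(0)
  while (length(pool) < n) {
    more <- vapply(seq_len(n - length(pool) + 10), function(i)
      paste(sample(c("A", "C", "G", "T"), width, replace = TRUE),
            collapse = ""), "")
    pool <- unique(c(pool, more))
  }
  pool[seq_len(n)]
}

#' Simulate two-group exponential survival data
#'
#' Helper for power experiments: exponential event times with a given
#' hazard ratio, uniform administrative censoring.
#'
#' @param n_per_group Patients per group.
#' @param hazard_ratio Group B vs group A.
#' @param median_a Median survival of group A (months).
#' @param censor_range Uniform censoring window (months).
#' @return Tibble with `time`, `event`, `group`.
#' @export
simulate_survival <- function(n_per_group, hazard_ratio, median_a = 12,
                              censor_range = c(6, 36)) {
  rate_a <- log(2) / median_a
  t <- c(rexp(n_per_group, rate_a),
         rexp(n_per_group, rate_a * hazard_ratio))
  cens <- runif(2 * n_per_group, censor_range[1], censor_range[2])
  tibble(time = pmin(t, cens), event = t <= cens,
         group = rep(c("A", "B"), each = n_per_group))
}
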