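mk_call <- function(vaf_pct, alt_reads = 50L, depth = NULL,
                    class = "missense", chrom = "1", pos = 1000L,
                    gene = "APC", sample_id = "S1") {
  if (is.null(depth)) depth <- as.integer(round(alt_reads / (vaf_pct / 100)))
  variant_calls(chrom = chrom, pos = pos, ref = "A", alt = "T",
                gene = gene, functional_class = class, depth = depth,
                alt_reads = as.integer(alt_reads), sample_id = sample_id)
}

test_that("functional-class filter keeps only possibly functional classes", {
  calls <- dplyr::bind_rows(
    mk_call(5, class = "missense", pos = 1L),
    mk_call(5, class = "other", pos = 2L),
    mk_call(5, class = "stop_gain", pos = 3L),
    mk_call(5, class = "frameshift", pos = 4L),
    mk_call(5, class = "other", pos = 5L)
  )
  kept <- filter_functional(calls)
  expect_equal(kept$pos, c(1L, 3L, 4L))
})

test_that("cfDNA and tissue thresholds are inclusive at the boundary", {
  cfg <- filter_config()
  # vaf 1.74%, 35 alt reads: a reportable cfDNA call
  expect_equal(nrow(filter_thresholds(
    mk_call(1.74, alt_reads = 35, depth = 2011L), "cfDNA", cfg)), 1)
  # exactly 1% and exactly 10 reads: kept ("at least")
  expect_equal(nrow(filter_thresholds(
    mk_call(1, alt_reads = 10, depth = 1000L), "cfDNA", cfg)), 1)
  # below either bound: dropped
  expect_equal(nrow(filter_thresholds(
    mk_call(0.9, alt_reads = 50, depth = 5556L), "cfDNA", cfg)), 0)
  expect_equal(nrow(filter_thresholds(
    mk_call(2, alt_reads = 9, depth = 450L), "cfDNA", cfg)), 0)
  # tissue: 9.9% dropped, 10% kept
  expect_equal(nrow(filter_thresholds(
    mk_call(9.9, alt_reads = 200, depth = 2020L), "tissue_FFPE", cfg)), 0)
  expect_equal(nrow(filter_thresholds(
    mk_call(10, alt_reads = 200, depth = 2000L), "tissue_frozen", cfg)), 1)
  expect_error(filter_thresholds(mk_call(50), "PBMC", cfg), "PBMC")
})

test_that("PBMC calls split into germline (>=20%) and blacklist (<20%)", {
  pbmc <- dplyr::bind_rows(
    mk_call(99.9, alt_reads = 999, depth = 1000L, pos = 1L),
    mk_call(50.1, alt_reads = 501, depth = 1000L, pos = 2L),
    mk_call(19.0, alt_reads = 190, depth = 1000L, pos = 3L),
    mk_call(3.0, alt_reads = 30, depth = 1000L, pos = 4L),
    mk_call(20.0, alt_reads = 200, depth = 1000L, pos = 5L)
  )
  germ <- extract_germline(pbmc, patient_id = "P1")
  expect_setequal(as.character(germ), c("1:1:A>T", "1:2:A>T", "1:5:A>T"))
  bl <- build_blacklist(pbmc)
  expect_setequal(bl$entries, c("1:3:A>T", "1:4:A>T"))
  # partition: germline XOR blacklist, never both, never neither
  expect_length(intersect(as.character(germ), bl$entries), 0)
  expect_equal(length(germ) + length(bl$entries), nrow(pbmc))
})

test_that("partition property holds on random PBMC calls", {
  pbmc <- random_calls(80, seed = 12, sample_id = "P_PBMC")
  germ <- extract_germline(pbmc, patient_id = "P1")
  bl <- build_blacklist(pbmc)
  keys <- unique(variant_keys(pbmc))
  expect_setequal(union(as.character(germ), bl$entries), keys)
  expect_length(intersect(as.character(germ), bl$entries), 0)
})

test_that("blacklist provenance tracks contributing samples and recurrence", {
  shared <- dplyr::bind_rows(lapply(c("A_PBMC", "B_PBMC", "C_PBMC"),
    function(s) mk_call(2, alt_reads = 20, depth = 1000L, pos = 7L,
                        sample_id = s)))
  private <- mk_call(5, alt_reads = 50, depth = 1000L, pos = 8L,
                     sample_id = "A_PBMC")
  bl <- build_blacklist(dplyr::bind_rows(shared, private))
  expect_setequal(bl$entries, c("1:7:A>T", "1:8:A>T"))
  expect_equal(sum(bl$provenance$key == "1:7:A>T"), 3)
  # recurrence requirement drops the singleton
  bl2 <- build_blacklist(dplyr::bind_rows(shared, private),
                         min_recurrence = 2)
  expect_equal(bl2$entries, "1:7:A>T")
  # a 30% PBMC call never enters the blacklist
  bl3 <- build_blacklist(mk_call(30, alt_reads = 300, depth = 1000L))
  expect_length(bl3$entries, 0)
  # TSV round trip
  f <- withr::local_tempfile(fileext = ".tsv")
  write_blacklist(bl, f)
  expect_setequal(read_blacklist(f)$entries, bl$entries)
})

test_that("finalization drops germline before blacklist and logs it", {
  calls <- dplyr::bind_rows(
    mk_call(30, alt_reads = 300, depth = 1000L, pos = 1L),
    mk_call(30, alt_reads = 300, depth = 1000L, pos = 2L),
    mk_call(30, alt_reads = 300, depth = 1000L, pos = 3L)
  )
  germ <- structure("1:1:A>T", patient_id = "P1", class = "germline_set")
  bl <- structure(list(entries = c("1:1:A>T", "1:2:A>T"),
                       provenance = tibble::tibble()),
                  class = "ctdna_blacklist")
  s <- finalize_somatic(calls, germ, bl, patient_id = "P1")
  expect_equal(s$cascade_log$disposition,
               c("dropped:germline", "dropped:blacklist", "kept"))
  expect_equal(variant_keys(s$calls), "1:3:A>T")
  germB <- structure("1:1:A>T", patient_id = "P2", class = "germline_set")
  expect_error(finalize_somatic(calls, germB, patient_id = "P1"),
               "patient")
})

test_that("cascade equals an independent brute-force filter", {
  cfg <- filter_config()
  for (seed in c(1, 22, 333)) {
    calls <- random_calls(100, seed = seed)
    keys <- unique(variant_keys(calls))
    set.seed(seed + 1)
    germ_keys <- sample(keys, 5)
    bl_keys <- sample(setdiff(keys, germ_keys), 5)
    germ <- structure(germ_keys, patient_id = "P1",
                      class = "germline_set")
    bl <- structure(list(entries = bl_keys, provenance = tibble::tibble()),
                    class = "ctdna_blacklist")
    for (mat in c("cfDNA", "tissue_FFPE")) {
      got <- somatic_cascade(calls, mat, cfg, germ, bl,
                             patient_id = "P1",
                             warn_no_germline = FALSE)$calls
      want <- brute_force_filter(calls, mat, cfg, germ_keys, bl_keys)
      expect_equal(as.data.frame(got), as.data.frame(want))
    }
  }
})

test_that("cascade is idempotent and kept calls satisfy the thresholds", {
  cfg <- filter_config()
  calls <- random_calls(100, seed = 77)
  s1 <- somatic_cascade(calls, "cfDNA", cfg, warn_no_germline = FALSE)
  s2 <- somatic_cascade(s1$calls, "cfDNA", cfg, warn_no_germline = FALSE)
  expect_equal(as.data.frame(s2$calls), as.data.frame(s1$calls))
  expect_true(all(s1$calls$vaf >= 0.01 - 1e-12))
  expect_true(all(s1$calls$alt_reads >= 10))
  # every input call gets exactly one disposition
  expect_equal(nrow(s1$cascade_log), nrow(calls))
  expect_equal(sum(s1$cascade_log$disposition == "kept"), nrow(s1$calls))
  # cascade warns when a patient has no PBMC sample
  expect_warning(somatic_cascade(calls[0, ], "cfDNA", cfg), "germline")
})

test_that("planted cohort roles are routed to the right cascade branch", {
  co <- shared_cohort()
  tv <- co$truth$variants
  pbmc <- co$calls[co$calls$material == "PBMC", ]
  cfg <- filter_config()
  # germline keys observed >= 20%, CH keys < 20%, for every patient
  bl <- build_blacklist(pbmc, cfg)
  ch_keys <- unique(tv$key[tv$role %in% c("ch_shared", "ch_private")])
  expect_setequal(bl$entries, ch_keys)
  for (pid in unique(pbmc$patient_id)[1:5]) {
    g <- extract_germline(pbmc[pbmc$patient_id == pid, ], cfg,
                          patient_id = pid)
    expect_setequal(as.character(g),
                    unique(tv$key[tv$patient_id == pid &
                                    tv$role == "germline"]))
  }
})
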