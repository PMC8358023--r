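test_that("VCF records yield one call per ALT allele with recomputed VAF", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"a\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "12\t25398284\t.\tC\tA\t.\tPASS\tGENE=KRAS;FUNC=missense\tGT:DP:AD\t0/1:1000:990,10",
    "17\t7577548\t.\tC\tT,G\t.\tPASS\tGENE=TP53;FUNC=missense\tGT:DP:AD\t0/1:2000:1900,60,40"
  ), f)
  calls <- read_vcf(f, sample_id = "S1")
  expect_equal(nrow(calls), 3)
  expect_equal(calls$depth[1], 1000L)
  expect_equal(calls$alt_reads[1], 10L)
  expect_equal(calls$vaf[1], 0.01)
  # multi-allelic record split into two calls sharing chrom/pos/ref
  multi <- calls[calls$pos == 7577548, ]
  expect_equal(nrow(multi), 2)
  expect_equal(unique(multi$ref), "C")
  expect_setequal(multi$alt, c("T", "G"))
  expect_equal(sort(multi$alt_reads), c(40L, 60L))
})

test_that("VCFs without depth annotations are rejected, not guessed", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "12\t100\t.\tC\tA\t.\tPASS\t.\tGT\t0/1"
  ), f)
  expect_error(read_vcf(f), "DP/AD")
})

test_that("synthetic VCF written from calls round-trips identically", {
  calls <- random_calls(20, seed = 41)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(calls, f)
  back <- read_vcf(f, sample_id = "S1")
  cols <- c("chrom", "pos", "ref", "alt", "gene", "functional_class",
            "depth", "alt_reads", "vaf")
  ord <- function(x) x[order(x$chrom, x$pos, x$ref, x$alt), cols]
  expect_equal(as.data.frame(ord(back)), as.data.frame(ord(calls)))
})

test_that("tabular variant lists parse VAF percent and functional strings", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste("Chr", "Start", "End", "Ref", "Alt", "Functional", "Gene",
          "Base change", "AA change", "VAF (%)", sep = "\t"),
    paste("12", "25398284", "25398284", "C", "A", "missense_variant",
          "KRAS", "c.35G > T", "p.Gly12Val", "1.74", sep = "\t"),
    paste("5", "112175639", "112175639", "C", "T", "stop_gained", "APC",
          "c.4348C > T", "p.Arg1450*", "38.41", sep = "\t")
  ), f)
  calls <- read_variant_table(f)
  expect_equal(calls$gene, c("KRAS", "APC"))
  expect_equal(calls$aa_change[1], "p.Gly12Val")
  expect_equal(calls$vaf, c(0.0174, 0.3841))
  expect_equal(calls$functional_class, c("missense", "stop_gain"))
})

test_that("header-only tables, unknown classes and bad VAFs behave", {
  hdr <- paste("Chr", "Start", "End", "Ref", "Alt", "Functional", "Gene",
               "Base change", "AA change", "VAF (%)", sep = "\t")
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(hdr, f)
  expect_equal(nrow(read_variant_table(f)), 0)

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(hdr, paste("1", "5", "5", "A", "T", "weird_effect", "APC",
                          "NA", "NA", "12.0", sep = "\t")), f2)
  expect_warning(calls <- read_variant_table(f2), "weird_effect")
  expect_equal(calls$functional_class, "other")

  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(hdr, paste("1", "5", "5", "A", "T", "missense", "APC",
                          "NA", "NA", "oops", sep = "\t")), f3)
  expect_error(read_variant_table(f3), "non-numeric VAF")
})

test_that("variant table write/read round-trips a 50-call list", {
  calls <- random_calls(50, seed = 7)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_variant_table(calls, f)
  back <- read_variant_table(f)
  cols <- c("sample_id", "chrom", "pos", "ref", "alt", "gene",
            "functional_class", "depth", "alt_reads", "vaf")
  expect_equal(as.data.frame(back[, cols]), as.data.frame(calls[, cols]))
  # parsed VAF always agrees with the read counts
  expect_true(all(abs(back$vaf - back$alt_reads / back$depth) <= 1e-9))
})

test_that("sample sheets are validated", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,patient_id,material,timepoint,panel_version",
               "P1_PBMC,P1,PBMC,baseline,v3",
               "P1_B,P1,cfDNA,baseline,v3"), f)
  sheet <- read_sample_sheet(f)
  expect_equal(nrow(sheet), 2)
  expect_equal(unique(sheet$patient_id), "P1")

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,patient_id,material,timepoint,panel_version",
               "S1,P1,PBMC,baseline,v3", "S1,P1,cfDNA,baseline,v3"), f2)
  expect_error(read_sample_sheet(f2), "duplicate sample_id")

  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,patient_id,material,timepoint,panel_version",
               "S1,P1,plasma,baseline,v3"), f3)
  expect_error(read_sample_sheet(f3), "unknown material")

  f4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,patient_id,material,timepoint,panel_version",
               "S1,P1,cfDNA,week3,v3"), f4)
  expect_error(read_sample_sheet(f4), "timepoint")
})

test_that("clinical tables enforce referential integrity", {
  fs <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,patient_id,material,timepoint,panel_version",
               "S1,P9,cfDNA,baseline,v3"), fs)
  samples <- read_sample_sheet(fs)
  fc <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,best_response,pfs_months,pfs_event",
               "P1,PR,10.5,TRUE"), fc)
  expect_error(read_clinical(fc, samples), "P9")
  clin <- read_clinical(fc)
  expect_equal(clin$pfs_months, 10.5)
  expect_true(clin$pfs_event)
})

test_that("panel gating and chromosome normalization work", {
  expect_length(panel_genes("v2"), 11)
  expect_length(panel_genes("v3"), 16)
  expect_true(all(panel_genes("v2") %in% panel_genes("v3")))
  calls <- variant_calls(chrom = c("15", "12"), pos = c(66727454L, 100L),
                         ref = "A", alt = "C",
                         gene = c("MAP2K1", "KRAS"),
                         depth = 1000L, alt_reads = 100L)
  expect_equal(apply_panel(calls, "v2")$gene, "KRAS")
  expect_equal(nrow(apply_panel(calls, "v3")), 2)
  chr <- variant_calls(chrom = "chr12", pos = 5L, ref = "A", alt = "T",
                       gene = "KRAS", depth = 100L, alt_reads = 50L)
  expect_equal(normalize_chrom(chr)$chrom, "12")
})

test_that("timepoint ordering puts baseline before evals before PD", {
  rk <- timepoint_rank(c("PD", "baseline", "eval2", "eval1"))
  expect_equal(order(rk), c(2, 4, 3, 1))
  expect_error(timepoint_rank("week3"), "unknown timepoint")
})

test_that("call validation rejects inconsistent records", {
  expect_error(variant_calls(chrom = "1", pos = 5L, ref = "A", alt = "A",
                             gene = "APC", depth = 10L, alt_reads = 1L),
               "must differ")
  expect_error(variant_calls(chrom = "1", pos = 5L, ref = "A", alt = "T",
                             gene = "APC", depth = 10L, alt_reads = 11L),
               "alt_reads")
  expect_error(variant_calls(chrom = "1", pos = 5L, ref = "A", alt = "T",
                             gene = "APC", depth = 100L, alt_reads = 10L,
                             vaf = 0.5), "inconsistent")
})
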