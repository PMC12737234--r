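test_that("VCF dosage parsing follows the GT field", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tA\tB",
    "1\t100\tv1\tA\tT\t.\t.\t.\tGT\t0/0\t0|1",
    "1\t200\tv2\tG\tC\t.\t.\t.\tGT\t0/1\t./.",
    "1\t300\tv3\tT\tA\t.\t.\t.\tGT\t1/1\t0/."
  ), vcf)
  gm <- read_vcf(vcf)
  expect_equal(gm$sample_ids, c("A", "B"))
  expect_equal(unname(gm$dosages["A", ]), c(0L, 1L, 2L))
  # phased het counted, "./.": missing, half-call "0/.": missing
  expect_equal(unname(gm$dosages["B", ]), c(1L, NA_integer_, NA_integer_))
})

test_that("multi-allelic records are skipped with a warning and counted", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tA",
    "1\t100\tv1\tA\tT\t.\t.\t.\tGT\t0/1",
    "1\t200\tv2\tG\tC,T\t.\t.\t.\tGT\t1/2"
  ), vcf)
  expect_warning(gm <- read_vcf(vcf), "multi-allelic")
  expect_equal(n_variants(gm), 1L)
  expect_equal(attr(gm, "n_multiallelic_skipped"), 1L)
})

test_that("a file without a VCF header is a format error", {
  f <- tempfile()
  writeLines("not a vcf", f)
  expect_error(read_vcf(f), class = "apd_format_error")
})

test_that("VCF round-trip reproduces dosages, sample IDs and variant IDs", {
  gm <- random_gm(5, 10, missing_rate = 0.2, seed = 11)
  path <- tempfile(fileext = ".vcf")
  write_vcf(gm, path)
  back <- read_vcf(path)
  expect_identical(back$dosages, gm$dosages)
  expect_identical(back$sample_ids, gm$sample_ids)
  expect_identical(back$variants$vid, gm$variants$vid)
})

test_that("empty-variant genotype matrix writes a valid header-only VCF", {
  gm <- genotype_matrix(matrix(integer(0), nrow = 2, ncol = 0,
                               dimnames = list(c("A", "B"), NULL)))
  path <- tempfile(fileext = ".vcf")
  write_vcf(gm, path)
  back <- read_vcf(path)
  expect_equal(back$sample_ids, c("A", "B"))
  expect_equal(n_variants(back), 0L)
})

test_that("PLINK round-trip reproduces dosages for awkward sample counts", {
  # n mod 4 in {0,1,2,3} exercises .bed byte padding
  for (n in 3:6) {
    gm <- random_gm(n, 7, missing_rate = 0.3, seed = 20 + n)
    prefix <- tempfile()
    write_plink(gm, prefix)
    back <- read_plink(prefix)
    expect_identical(back$dosages, gm$dosages)
    expect_identical(back$sample_ids, gm$sample_ids)
    expect_identical(back$variants$vid, gm$variants$vid)
  }
})

test_that("bad .bed magic bytes are a format error", {
  gm <- random_gm(4, 3, seed = 1)
  prefix <- tempfile()
  write_plink(gm, prefix)
  raw <- readBin(paste0(prefix, ".bed"), "raw", n = file.size(paste0(prefix, ".bed")))
  raw[1] <- as.raw(0x00)
  writeBin(raw, paste0(prefix, ".bed"))
  expect_error(read_plink(prefix), class = "apd_format_error")
})

test_that("an all-missing variant survives a PLINK round trip as all NA", {
  d <- matrix(c(0L, 1L, 2L, NA, NA, NA), nrow = 3)
  gm <- genotype_matrix(d, sample_ids = c("A", "B", "C"))
  prefix <- tempfile()
  write_plink(gm, prefix)
  back <- read_plink(prefix)
  expect_true(all(is.na(back$dosages[, 2])))
})

test_that("subset_samples keeps requested rows in order and flags unknowns", {
  gm <- random_gm(6, 8, seed = 5)
  expect_identical(subset_samples(gm, gm$sample_ids)$dosages, gm$dosages)
  one <- subset_samples(gm, gm$sample_ids[4])
  expect_equal(n_samples(one), 1L)
  rev2 <- subset_samples(gm, rev(gm$sample_ids[1:3]))
  expect_equal(rev2$sample_ids, rev(gm$sample_ids[1:3]))
  expect_error(subset_samples(gm, c("S001", "nope", "also_nope")),
               "nope.*also_nope", class = "apd_lookup_error")
})

test_that("filter_variants applies MAF, missingness and monomorphism rules", {
  # columns: monomorphic-0; singleton het in 100; 6/100 missing; clean common
  n <- 100
  d <- cbind(rep(0L, n),
             c(1L, rep(0L, n - 1)),
             c(rep(NA_integer_, 6), rep(1L, 4), rep(0L, 45), rep(2L, 45)),
             c(rep(0L, 50), rep(2L, 50)))
  gm <- genotype_matrix(d, sample_ids = sprintf("S%03d", 1:n))
  fl <- filter_variants(gm, filter_spec(maf_min = 0.01, miss_max = 0.05))
  expect_equal(fl$gm$variants$vid, gm$variants$vid[4])
  expect_equal(fl$report$n_fail_monomorphic, 1L)
  expect_equal(fl$report$n_fail_maf, 2L)  # p = 0.005 and the monomorphic col
  expect_equal(fl$report$n_fail_missing, 1L)  # 0.06 > 0.05
  # relaxing the missing threshold to 0.2 keeps the 6%-missing column
  fl2 <- filter_variants(gm, filter_spec(maf_min = 0.01, miss_max = 0.2))
  expect_true("v3" %in% fl2$gm$variants$vid)
  # boundary kept: a variant at exactly MAF 0.01 survives
  d5 <- cbind(c(rep(1L, 2), rep(0L, 98)))
  gm5 <- genotype_matrix(d5, sample_ids = sprintf("S%03d", 1:100))
  expect_equal(n_variants(filter_variants(gm5, filter_spec(maf_min = 0.01,
                                                           miss_max = 1))$gm), 1L)
})

test_that("a variant with zero non-missing calls is removed and counted separately", {
  d <- cbind(c(NA_integer_, NA_integer_, NA_integer_), c(0L, 1L, 2L))
  gm <- genotype_matrix(d, sample_ids = c("A", "B", "C"))
  fl <- filter_variants(gm, filter_spec(maf_min = 0, miss_max = 1,
                                        drop_monomorphic = FALSE))
  expect_equal(fl$report$n_no_calls, 1L)
  expect_equal(n_variants(fl$gm), 1L)
})

test_that("filtering is idempotent and never alters surviving dosages", {
  gm <- random_gm(30, 60, missing_rate = 0.1, seed = 33)
  spec <- filter_spec(maf_min = 0.05, miss_max = 0.1)
  once <- filter_variants(gm, spec)$gm
  twice <- filter_variants(once, spec)$gm
  expect_identical(twice$dosages, once$dosages)
  expect_identical(gm$dosages[, once$variants$vid], once$dosages)
})

test_that("subsetting before monomorphic filtering can only lose variants", {
  for (seed in 1:5) {
    gm <- random_gm(12, 40, missing_rate = 0.05, seed = seed)
    keep <- gm$sample_ids[1:4]
    spec <- filter_spec(maf_min = 0, miss_max = 1, drop_monomorphic = TRUE)
    sub_then_filter <- filter_variants(subset_samples(gm, keep), spec)$gm
    filter_then_sub <- subset_samples(filter_variants(gm, spec)$gm, keep)
    expect_lte(n_variants(sub_then_filter), n_variants(filter_then_sub))
  }
})

test_that("allele_frequency_table computes MAF from non-missing calls", {
  gm <- toy_gm(rbind(c(0L, 1L), c(0L, 1L), c(0L, NA), c(2L, NA)))
  aft <- allele_frequency_table(gm)
  expect_equal(aft$maf, c(0.25, 0.5))
  expect_equal(aft$missing_rate, c(0, 0.5))
})
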