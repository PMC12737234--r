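#' Read biallelic genotypes from a VCF file
#'
#' Parses the GT subfield into ALT-allele dosages (0/1/2). Any call
#' containing a missing allele (including half-calls such as `0/.`) becomes
#' `NA`. Phased (`|`) and unphased (`/`) separators are treated identically.
#' Multi-allelic records are skipped with a warning (the analyses here are
#' defined for biallelic variants only); the number skipped is available as
#' `attr(gm, "n_multiallelic_skipped")`.
#'
#' @param path VCF file (plain or gzipped).
#' @return a [genotype_matrix()], samples in header order.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop_format("VCF not found: %s", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0 || !startsWith(first, "##fileformat=VCF")) {
    stop_format("malformed VCF header in %s: first line must be ##fileformat=VCF...",
                path)
  }
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop_format("failed to parse VCF %s: %s",
                                                path, conditionMessage(e)))
  fix <- v@fix
  if (nrow(fix) == 0) {
    samples <- colnames(v@gt)
    samples <- samples[samples != "FORMAT"]
    return(genotype_matrix(
      matrix(integer(0), nrow = length(samples), ncol = 0,
             dimnames = list(samples, NULL)),
      variants = data.frame(chrom = character(), pos = integer(),
                            vid = character(), allele_ref = character(),
                            allele_alt = character())))
  }
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  n_multi <- sum(multi)
  if (n_multi > 0) {
    warning(sprintf("skipped %d multi-allelic record(s) in %s", n_multi, path))
    v <- v[!multi, ]
    fix <- v@fix
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  # fast dosage conversion via lookup over the distinct GT strings
  codes <- unique(as.vector(gt))
  dose_of <- vapply(codes, gt_to_dosage, integer(1))
  d <- matrix(dose_of[match(gt, codes)], nrow = nrow(gt))
  vid <- fix[, "ID"]
  vid[is.na(vid) | vid == "."] <-
    paste0(fix[is.na(vid) | vid == ".", "CHROM"], "_",
           fix[is.na(vid) | vid == ".", "POS"])
  variants <- data.frame(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]), vid = vid,
    allele_ref = fix[, "REF"], allele_alt = fix[, "ALT"],
    stringsAsFactors = FALSE)
  gm <- genotype_matrix(t(d), variants = variants, sample_ids = colnames(gt))
  attr(gm, "n_multiallelic_skipped") <- n_multi
  gm
}

# GT string -> ALT dosage; NA for anything containing ".", non-diploid or
# non-GT content. Allele indices > 1 should not occur post multi-allelic
# filtering but map to NA defensively.
gt_to_dosage <- function(gt) {
  if (is.na(gt)) return(NA_integer_)
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (length(alleles) != 2 || any(alleles == ".")) return(NA_integer_)
  a <- suppressWarnings(as.integer(alleles))
  if (any(is.na(a)) || any(a > 1L) || any(a < 0L)) return(NA_integer_)
  sum(a)
}

#' Write a genotype matrix as a VCF file
#'
#' Emits a minimal VCF v4.2 with a GT-only FORMAT column; re-reading with
#' [read_vcf()] reproduces the dosages exactly (0 -> `0/0`, 1 -> `0/1`,
#' 2 -> `1/1`, `NA` -> `./.`).
#'
#' @param gm a `genotype_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop_format("cannot write %s: %s", path,
                                                  conditionMessage(e)))
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=apdtools",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$sample_ids), collapse = "\t")
  ), con)
  if (n_variants(gm) == 0) return(invisible(path))
  gt_code <- c("0/0", "0/1", "1/1")
  g <- matrix(gt_code[gm$dosages + 1L], nrow = n_samples(gm))
  g[is.na(gm$dosages)] <- "./."
  lines <- paste(gm$variants$chrom, gm$variants$pos, gm$variants$vid,
                 gm$variants$allele_ref, gm$variants$allele_alt,
                 ".", ".", ".", "GT",
                 apply(g, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

# 256 x 4 lookup: PLINK 1 .bed byte -> four A1 dosages.
# 2-bit codes (low bits = first sample): 00 hom A1 (2), 01 missing (NA),
# 10 het (1), 11 hom A2 (0).
plink_byte_lut <- function() {
  code_dose <- c(2L, NA_integer_, 1L, 0L)
  b <- 0:255
  cbind(code_dose[b %% 4L + 1L],
        code_dose[(b %/% 4L) %% 4L + 1L],
        code_dose[(b %/% 16L) %% 4L + 1L],
        code_dose[(b %/% 64L) %% 4L + 1L])
}

#' Read genotypes from a PLINK 1 binary fileset
#'
#' Reads `prefix.bed` / `prefix.bim` / `prefix.fam` (SNP-major .bed). Dosage
#' is the A1-allele count, so the .bim A1 allele plays the role of ALT.
#' Sample IDs are the .fam IID column.
#'
#' @param prefix path prefix of the fileset.
#' @return a [genotype_matrix()].
#' @export
read_plink <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  missing_f <- paths[!file.exists(paths)]
  if (length(missing_f) > 0) {
    stop_format("PLINK file(s) not found: %s", paste(missing_f, collapse = ", "))
  }
  fam <- utils::read.table(paths[3], header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  bim <- utils::read.table(paths[2], header = FALSE, stringsAsFactors = FALSE,
                           colClasses = c("character", "character", "character",
                                          "integer", "character", "character"))
  n <- nrow(fam)
  l <- nrow(bim)
  raw <- readBin(paths[1], "raw", n = file.size(paths[1]))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop_format("%s: bad PLINK .bed magic bytes", paths[1])
  }
  if (raw[3] != as.raw(0x01)) {
    stop_format("%s: only SNP-major .bed files are supported", paths[1])
  }
  bytes_per_variant <- ceiling(n / 4)
  if (length(raw) - 3L != bytes_per_variant * l) {
    stop_format(".bed size (%d data bytes) inconsistent with %d samples x %d variants",
                length(raw) - 3L, n, l)
  }
  lut <- plink_byte_lut()
  body <- as.integer(raw[-(1:3)])
  # decode all bytes at once, then drop per-variant padding samples
  dec <- matrix(t(lut[body + 1L, , drop = FALSE]), nrow = 4L * bytes_per_variant)
  d <- dec[seq_len(n), , drop = FALSE]  # samples x variants
  variants <- data.frame(chrom = bim[[1]], pos = bim[[4]], vid = bim[[2]],
                         allele_ref = bim[[6]], allele_alt = bim[[5]],
                         stringsAsFactors = FALSE)
  genotype_matrix(d, variants = variants, sample_ids = fam[[2]])
}

#' Write a genotype matrix as a PLINK 1 binary fileset
#'
#' Emits SNP-major `prefix.bed` plus `.bim`/`.fam`. The ALT allele is written
#' as A1 so that [read_plink()] reproduces the dosages exactly.
#'
#' @param gm a `genotype_matrix`.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(gm, prefix) {
  n <- n_samples(gm)
  l <- n_variants(gm)
  fam <- data.frame(gm$sample_ids, gm$sample_ids, 0L, 0L, 0L, -9L)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  bim <- data.frame(gm$variants$chrom, gm$variants$vid, 0L, gm$variants$pos,
                    gm$variants$allele_alt, gm$variants$allele_ref)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  # dosage -> 2-bit code: 2 -> 00, NA -> 01, 1 -> 10, 0 -> 11
  code <- matrix(3L, nrow = n, ncol = l)
  code[!is.na(gm$dosages) & gm$dosages == 2L] <- 0L
  code[!is.na(gm$dosages) & gm$dosages == 1L] <- 2L
  code[is.na(gm$dosages)] <- 1L
  bytes_per_variant <- ceiling(n / 4)
  pad <- bytes_per_variant * 4L - n
  if (pad > 0) code <- rbind(code, matrix(0L, nrow = pad, ncol = l))
  # pack 4 samples per byte, low bits first
  i4 <- matrix(seq_len(nrow(code)), nrow = 4L)
  packed <- code[i4[1, ], , drop = FALSE] +
    4L * code[i4[2, ], , drop = FALSE] +
    16L * code[i4[3, ], , drop = FALSE] +
    64L * code[i4[4, ], , drop = FALSE]
  con <- tryCatch(file(paste0(prefix, ".bed"), "wb"),
                  error = function(e) stop_format("cannot write %s.bed: %s",
                                                  prefix, conditionMessage(e)))
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  if (length(packed)) writeBin(as.raw(as.vector(packed)), con)
  invisible(prefix)
}
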