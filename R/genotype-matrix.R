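#' Genotype matrix container
#'
#' A `genotype_matrix` holds biallelic diploid genotypes as an ALT-allele
#' dosage matrix (samples x variants, entries 0/1/2 with `NA` for missing
#' calls) together with variant metadata. It is the substrate of every
#' computation in the package.
#'
#' @param dosages integer or numeric matrix, samples in rows, variants in
#'   columns; entries must be 0, 1, 2 or `NA`.
#' @param variants `data.frame` with columns `chrom`, `pos`, `vid`,
#'   `allele_ref`, `allele_alt` (one row per variant), or `NULL` to
#'   autogenerate placeholder records.
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to `rownames(dosages)`.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `sample_ids`, `variants` and `dosages` (the dosage matrix carries the
#'   sample IDs as rownames and variant IDs as colnames).
#' @export
genotype_matrix <- function(dosages, variants = NULL, sample_ids = NULL) {
  if (!is.matrix(dosages)) {
    stop_domain("'dosages' must be a matrix (samples x variants)")
  }
  storage.mode(dosages) <- "integer"
  if (is.null(sample_ids)) sample_ids <- rownames(dosages)
  if (is.null(sample_ids)) {
    stop_domain("sample IDs are required (rownames(dosages) or 'sample_ids')")
  }
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(dosages)) {
    stop_domain("length(sample_ids) [%d] != nrow(dosages) [%d]",
                length(sample_ids), nrow(dosages))
  }
  if (anyDuplicated(sample_ids)) {
    stop_domain("duplicate sample IDs: %s",
                paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (is.null(variants)) {
    variants <- data.frame(
      chrom = rep("1", ncol(dosages)),
      pos = seq_len(ncol(dosages)),
      vid = if (!is.null(colnames(dosages))) colnames(dosages) else
        sprintf("v%d", seq_len(ncol(dosages))),
      allele_ref = rep("A", ncol(dosages)),
      allele_alt = rep("T", ncol(dosages)),
      stringsAsFactors = FALSE
    )
  }
  required <- c("chrom", "pos", "vid", "allele_ref", "allele_alt")
  if (!all(required %in% names(variants))) {
    stop_domain("variant table lacks columns: %s",
                paste(setdiff(required, names(variants)), collapse = ", "))
  }
  variants <- as.data.frame(variants)[, required]
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  variants$vid <- as.character(variants$vid)
  rownames(variants) <- NULL
  if (nrow(variants) != ncol(dosages)) {
    stop_domain("nrow(variants) [%d] != ncol(dosages) [%d]",
                nrow(variants), ncol(dosages))
  }
  if (nrow(variants) > 0 && anyDuplicated(variants$vid)) {
    stop_domain("duplicate variant IDs: %s",
                paste(utils::head(unique(variants$vid[duplicated(variants$vid)]), 5),
                      collapse = ", "))
  }
  if (nrow(variants) > 0 && any(variants$pos < 1L, na.rm = TRUE)) {
    stop_domain("variant positions must be >= 1 (1-based coordinates)")
  }
  bad <- !(dosages %in% c(0L, 1L, 2L) | is.na(dosages))
  if (any(bad)) {
    stop_domain("dosages must be 0, 1, 2 or NA; found %s",
                paste(utils::head(unique(dosages[bad]), 5), collapse = ", "))
  }
  dimnames(dosages) <- list(sample_ids, variants$vid)
  structure(
    list(sample_ids = sample_ids, variants = variants, dosages = dosages),
    class = "genotype_matrix"
  )
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Number of samples / variants in a genotype matrix
#' @param gm a `genotype_matrix`.
#' @return integer count.
#' @export
n_samples <- function(gm) length(gm$sample_ids)

#' @rdname n_samples
#' @export
n_variants <- function(gm) nrow(gm$variants)

#' @export
print.genotype_matrix <- function(x, ...) {
  miss <- if (length(x$dosages)) mean(is.na(x$dosages)) else 0
  cat(sprintf("genotype_matrix: %d samples x %d variants (%.2f%% missing)\n",
              n_samples(x), n_variants(x), 100 * miss))
  invisible(x)
}

#' Restrict a genotype matrix to a set of samples
#'
#' Keeps the requested samples, in the requested order; variants are
#' untouched. The typical use is splitting a panel into varietal groups
#' (e.g. indica vs japonica) from a plain-text ID list before group-wise
#' analysis.
#'
#' @param gm a `genotype_matrix`.
#' @param keep character vector of sample IDs to retain (must all exist).
#' @return A `genotype_matrix` with rows restricted to `keep`, in that order.
#' @export
subset_samples <- function(gm, keep) {
  keep <- as.character(keep)
  missing_ids <- setdiff(keep, gm$sample_ids)
  if (length(missing_ids) > 0) {
    stop_lookup("unknown sample IDs: %s", paste(missing_ids, collapse = ", "))
  }
  genotype_matrix(gm$dosages[keep, , drop = FALSE],
                  variants = gm$variants, sample_ids = keep)
}

#' Read a sample-group list
#'
#' One sample ID per line; blank lines and leading/trailing whitespace are
#' ignored.
#'
#' @param path file path.
#' @return character vector of IDs.
#' @export
read_sample_list <- function(path) {
  if (!file.exists(path)) stop_format("sample list not found: %s", path)
  ids <- trimws(readLines(path, warn = FALSE))
  ids[nzchar(ids)]
}

#' Variant filter specification
#'
#' Thresholds applied per variant. A variant is kept iff its missing-call
#' rate is `<= miss_max` AND its minor allele frequency (computed from
#' non-missing calls) is `>= maf_min` AND, when `drop_monomorphic`, its MAF
#' is strictly positive. Both boundaries are inclusive keeps. The defaults
#' are the thresholds used for dense SNP panels (MAF 0.01, missingness 0.05);
#' sparser presence/absence SV panels typically relax `miss_max` to 0.2.
#'
#' @param maf_min minimum minor allele frequency in \[0, 0.5\].
#' @param miss_max maximum per-variant missing rate in \[0, 1\].
#' @param drop_monomorphic drop variants with zero minor-allele count.
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(maf_min = 0.01, miss_max = 0.05, drop_monomorphic = TRUE) {
  if (!is.numeric(maf_min) || length(maf_min) != 1 || maf_min < 0 || maf_min > 0.5) {
    stop_domain("maf_min must be a single value in [0, 0.5]")
  }
  if (!is.numeric(miss_max) || length(miss_max) != 1 || miss_max < 0 || miss_max > 1) {
    stop_domain("miss_max must be a single value in [0, 1]")
  }
  structure(list(maf_min = maf_min, miss_max = miss_max,
                 drop_monomorphic = isTRUE(drop_monomorphic)),
            class = "filter_spec")
}

#' Per-variant allele frequency and missingness table
#'
#' @param gm a `genotype_matrix`.
#' @return `data.frame` with one row per variant: `vid`, `chrom`, `maf`
#'   (minor allele frequency from non-missing calls; `NA` if no calls) and
#'   `missing_rate`.
#' @export
allele_frequency_table <- function(gm) {
  d <- gm$dosages
  n <- nrow(d)
  n_miss <- colSums(is.na(d))
  n_obs <- n - n_miss
  p <- ifelse(n_obs > 0, colSums(d, na.rm = TRUE) / (2 * n_obs), NA_real_)
  data.frame(
    vid = gm$variants$vid,
    chrom = gm$variants$chrom,
    maf = pmin(p, 1 - p),
    missing_rate = if (n > 0) n_miss / n else rep(NA_real_, ncol(d)),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Filter variants by missingness, MAF and monomorphism
#'
#' @param gm a `genotype_matrix`.
#' @param spec a [filter_spec()].
#' @return list with `gm` (the filtered matrix; dosage values of surviving
#'   variants are untouched) and `report` (a `filter_report`: totals, counts
#'   failing each criterion, and removals per chromosome).
#' @export
filter_variants <- function(gm, spec = filter_spec()) {
  if (!inherits(spec, "filter_spec")) spec <- do.call(filter_spec, as.list(spec))
  aft <- allele_frequency_table(gm)
  no_calls <- is.na(aft$maf)
  fail_miss <- !no_calls & aft$missing_rate > spec$miss_max
  fail_maf <- !no_calls & aft$maf < spec$maf_min
  fail_mono <- !no_calls & spec$drop_monomorphic & aft$maf <= 0
  keep <- !(no_calls | fail_miss | fail_maf | fail_mono)

  removed_by_chrom <- table(factor(aft$chrom[!keep],
                                   levels = unique(aft$chrom)))
  report <- structure(list(
    n_input = nrow(aft),
    n_kept = sum(keep),
    n_removed = sum(!keep),
    n_no_calls = sum(no_calls),
    n_fail_missing = sum(fail_miss),
    n_fail_maf = sum(fail_maf),
    n_fail_monomorphic = sum(fail_mono),
    removed_by_chrom = as.data.frame(removed_by_chrom,
                                     responseName = "n_removed",
                                     stringsAsFactors = FALSE),
    spec = spec
  ), class = "filter_report")
  names(report$removed_by_chrom)[1] <- "chrom"

  out <- genotype_matrix(gm$dosages[, keep, drop = FALSE],
                         variants = gm$variants[keep, , drop = FALSE],
                         sample_ids = gm$sample_ids)
  list(gm = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(paste0(
    "variant filter: %d in -> %d kept (%d removed)\n",
    "  no non-missing calls: %d\n",
    "  missing rate > %g:    %d\n",
    "  MAF < %g:             %d\n",
    "  monomorphic:          %d\n"),
    x$n_input, x$n_kept, x$n_removed, x$n_no_calls,
    x$spec$miss_max, x$n_fail_missing,
    x$spec$maf_min, x$n_fail_maf, x$n_fail_monomorphic))
  invisible(x)
}

#' Write a filter report as TSV
#'
#' @param report a `filter_report` from [filter_variants()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  df <- data.frame(
    criterion = c("input", "kept", "removed", "no_calls",
                  "missing_rate", "maf", "monomorphic"),
    n = c(report$n_input, report$n_kept, report$n_removed, report$n_no_calls,
          report$n_fail_missing, report$n_fail_maf, report$n_fail_monomorphic)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(report$removed_by_chrom) > 0) {
    suppressWarnings(utils::write.table(
      cbind(criterion = paste0("removed_chrom_", report$removed_by_chrom$chrom),
            n = report$removed_by_chrom$n_removed),
      path, sep = "\t", quote = FALSE, row.names = FALSE,
      col.names = FALSE, append = TRUE))
  }
  invisible(path)
}
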