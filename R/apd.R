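#' Pairwise dissimilarity between two genotype vectors
#'
#' Loci with a missing call in either vector are excluded
#' (pairwise-complete). Two metrics are available:
#' \describe{
#'   \item{`smc`}{one minus the simple matching coefficient on genotype
#'     calls: the fraction of compared loci where the two calls differ.
#'     The default, and the classical definition of the measure.}
#'   \item{`ibs`}{identity-by-state distance: mean of |a - b| / 2 over the
#'     compared loci, i.e. one minus the allele-sharing proportion.}
#' }
#' On fully homozygous data (no heterozygotes) the two coincide exactly, and
#' in highly selfing panels they are nearly identical; they differ in how a
#' heterozygous call is scored against a homozygous one (full mismatch under
#' `smc`, half under `ibs`), which matters for inbreeding-related contrasts
#' (see the methods vignette).
#'
#' @param a,b dosage vectors of equal length (0/1/2/`NA`).
#' @param metric `"smc"` (default) or `"ibs"`.
#' @return dissimilarity in \[0, 1\].
#' @export
pair_dissimilarity <- function(a, b, metric = c("smc", "ibs")) {
  metric <- match.arg(metric)
  if (length(a) != length(b)) {
    stop_domain("vectors differ in length (%d vs %d)", length(a), length(b))
  }
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) {
    stop_domain("no locus with non-missing calls in both samples")
  }
  if (metric == "ibs") mean(abs(a[ok] - b[ok]) / 2) else mean(a[ok] != b[ok])
}

# All-pairs dissimilarity and complete-locus-count matrices, via indicator
# cross-products (O(N^2 L) through BLAS). Returns list(d = NxN dissimilarity
# with NA where no locus overlaps, n_complete = NxN counts).
pairwise_dissimilarity_matrix <- function(dosages, metric = c("smc", "ibs")) {
  metric <- match.arg(metric)
  m <- !is.na(dosages)
  storage.mode(m) <- "double"
  i0 <- (dosages == 0L) & !is.na(dosages); storage.mode(i0) <- "double"
  i1 <- (dosages == 1L) & !is.na(dosages); storage.mode(i1) <- "double"
  i2 <- (dosages == 2L) & !is.na(dosages); storage.mode(i2) <- "double"
  n_complete <- tcrossprod(m)
  if (metric == "ibs") {
    c01 <- tcrossprod(i0, i1)
    c12 <- tcrossprod(i1, i2)
    c02 <- tcrossprod(i0, i2)
    half_diff_sum <- (c01 + t(c01) + c12 + t(c12)) / 2 + (c02 + t(c02))
    d <- half_diff_sum / n_complete
  } else {
    same <- tcrossprod(i0) + tcrossprod(i1) + tcrossprod(i2)
    d <- (n_complete - same) / n_complete
  }
  d[n_complete == 0] <- NA_real_
  diag(d) <- 0
  list(d = d, n_complete = n_complete)
}

#' Average pairwise dissimilarity (APD) of every sample
#'
#' For each sample, computes the mean of its N - 1 pairwise dissimilarities
#' against the remaining samples, together with the standard deviation of
#' those N - 1 values. High APD marks genomically distinct samples; low APD
#' marks redundant ones.
#'
#' Pairs with no commonly observed locus are excluded from both samples'
#' averages (with a warning); a sample with no defined pair gets `NA` APD.
#' With N = 2 there is a single pair, whose standard deviation is recorded
#' as 0.
#'
#' @param gm a `genotype_matrix` with at least 2 samples and 1 variant.
#' @param metric see [pair_dissimilarity()].
#' @return An `apd_result`: list with `sample_ids`, `apd`, `sd`, `n_samples`
#'   and `metric`.
#' @export
apd_all <- function(gm, metric = c("smc", "ibs")) {
  metric <- match.arg(metric)
  n <- n_samples(gm)
  if (n < 2) stop_domain("APD requires at least 2 samples (got %d)", n)
  if (n_variants(gm) < 1) stop_domain("APD requires at least 1 variant")
  pd <- pairwise_dissimilarity_matrix(gm$dosages, metric)
  d <- pd$d
  diag(d) <- NA_real_  # self-pairs are not part of any average
  undefined_pairs <- sum(pd$n_complete == 0 & upper.tri(pd$n_complete))
  if (undefined_pairs > 0) {
    warning(sprintf("%d sample pair(s) share no non-missing locus; excluded from APD averages",
                    undefined_pairs))
  }
  k <- rowSums(!is.na(d))           # defined pairs per sample
  s1 <- rowSums(d, na.rm = TRUE)
  s2 <- rowSums(d^2, na.rm = TRUE)
  apd <- unname(ifelse(k > 0, s1 / k, NA_real_))
  sdv <- unname(ifelse(k > 1, sqrt(pmax(0, (s2 - s1^2 / k) / (k - 1))), 0))
  sdv[k == 0] <- NA_real_
  if (any(k == 0)) {
    warning(sprintf("%d sample(s) have no defined pair; APD recorded as NA",
                    sum(k == 0)))
  }
  structure(list(sample_ids = gm$sample_ids, apd = apd, sd = sdv,
                 n_samples = n, metric = metric),
            class = "apd_result")
}

#' @export
print.apd_result <- function(x, ...) {
  ok <- !is.na(x$apd)
  cat(sprintf("apd_result: %d samples, metric '%s'\n", x$n_samples, x$metric))
  if (any(ok)) {
    cat(sprintf("  APD range %.4f - %.4f, mean %.4f\n",
                min(x$apd[ok]), max(x$apd[ok]), mean(x$apd[ok])))
  }
  invisible(x)
}

#' @export
as.data.frame.apd_result <- function(x, ...) {
  data.frame(sample_id = x$sample_ids, APD = x$apd, SD = x$sd,
             stringsAsFactors = FALSE)
}

#' Summarise an APD result
#'
#' @param res an `apd_result`.
#' @param bin_width histogram bin width on the APD scale.
#' @return list with `min`, `max`, `mean`, `n` (defined values) and
#'   `histogram` (`data.frame` of `bin_start`, `bin_end`, `count`; counts sum
#'   to the number of defined APD values).
#' @export
apd_summary <- function(res, bin_width = 0.01) {
  if (!is.numeric(bin_width) || bin_width <= 0) {
    stop_domain("bin_width must be positive")
  }
  v <- res$apd[!is.na(res$apd)]
  if (length(v) == 0) stop_domain("no defined APD values to summarise")
  lo <- floor(min(v) / bin_width) * bin_width
  hi <- ceiling(max(v) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  if (max(breaks) <= max(v)) breaks <- c(breaks, max(breaks) + bin_width)
  counts <- tabulate(findInterval(v, breaks), nbins = length(breaks) - 1)
  list(min = min(v), max = max(v), mean = mean(v), n = length(v),
       histogram = data.frame(bin_start = utils::head(breaks, -1),
                              bin_end = breaks[-1], count = counts))
}

#' Write APD estimates as TSV
#'
#' Columns `sample_id`, `APD`, `SD`.
#' @param res an `apd_result`.
#' @param path output file.
#' @param header_comment optional `#`-prefixed provenance line(s).
#' @return `path`, invisibly.
#' @export
write_apd <- function(res, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  utils::write.table(as.data.frame(res), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
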