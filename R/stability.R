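#' Correlation between subsampled and full-data APD
#'
#' Draws `m` distinct variants uniformly at random (seeded), recomputes APD
#' on the reduced matrix, and returns the Pearson correlation with the
#' full-data APD vector over samples with defined APD in both.
#'
#' @param gm a `genotype_matrix` (post-filter).
#' @param full the `apd_result` computed from `gm` with the same metric.
#' @param m number of variants to draw (`1 <= m <= n_variants(gm)`).
#' @param seed integer RNG seed for the draw.
#' @param metric see [pair_dissimilarity()].
#' @return Pearson r.
#' @export
subsample_apd_correlation <- function(gm, full, m, seed,
                                      metric = c("smc", "ibs")) {
  metric <- match.arg(metric)
  l <- n_variants(gm)
  if (m < 1 || m > l) {
    stop_domain("m = %d outside [1, %d] available variants", m, l)
  }
  set.seed(seed)
  cols <- sample.int(l, m)
  sub <- genotype_matrix(gm$dosages[, cols, drop = FALSE],
                         variants = gm$variants[cols, , drop = FALSE],
                         sample_ids = gm$sample_ids)
  res <- apd_all(sub, metric)
  ok <- !is.na(res$apd) & !is.na(full$apd)
  if (sum(ok) < 3) stop_domain("fewer than 3 samples with defined APD in both vectors")
  stats::cor(res$apd[ok], full$apd[ok])
}

#' Variant-subsampling stability of APD estimates
#'
#' For each subsample size, repeats [subsample_apd_correlation()] over
#' independent replicate draws (replicate i uses seed `base_seed + i`) and
#' summarises the replicate correlations by mean, standard deviation and
#' coefficient of variation. The attribute `"m_reliable"` records the
#' smallest size whose mean correlation reaches `threshold` (`NA` if none
#' does) — the operational answer to "how many random variants does a
#' reliable APD estimate need?".
#'
#' @param gm a `genotype_matrix` (post-filter).
#' @param sizes subsample sizes; default 1000, 3000, 5000, 10000, 15000.
#' @param reps replicate draws per size (>= 2; default 10).
#' @param base_seed integer seed; replicate i of every size uses
#'   `base_seed + i`.
#' @param metric see [pair_dissimilarity()].
#' @param threshold reliability threshold on the mean correlation
#'   (default 0.98).
#' @param full optionally, a precomputed full-data `apd_result` for `gm`.
#' @return A `stability_table`: `data.frame` with columns `m`, `mean_r`,
#'   `sd_r`, `cv_r`, ordered by `m`, with attributes `m_reliable`,
#'   `threshold`, `reps` and `base_seed`.
#' @export
stability_table <- function(gm, sizes = c(1000, 3000, 5000, 10000, 15000),
                            reps = 10, base_seed = 1,
                            metric = c("smc", "ibs"), threshold = 0.98,
                            full = NULL) {
  metric <- match.arg(metric)
  if (reps < 2) stop_domain("reps must be >= 2")
  l <- n_variants(gm)
  too_big <- sizes[sizes > l]
  if (length(too_big) > 0) {
    stop_domain("subsample size(s) exceed the %d available variants: %s",
                l, paste(too_big, collapse = ", "))
  }
  if (any(sizes < 1)) stop_domain("subsample sizes must be >= 1")
  sizes <- sort(sizes)
  if (is.null(full)) full <- apd_all(gm, metric)
  rows <- lapply(sizes, function(m) {
    r <- vapply(seq_len(reps), function(i) {
      subsample_apd_correlation(gm, full, m, seed = base_seed + i,
                                metric = metric)
    }, numeric(1))
    mr <- mean(r)
    sr <- stats::sd(r)
    data.frame(m = m, mean_r = mr, sd_r = sr,
               cv_r = if (mr != 0) sr / mr else NA_real_)
  })
  out <- do.call(rbind, rows)
  reliable <- out$m[out$mean_r >= threshold]
  structure(out,
            class = c("stability_table", "data.frame"),
            m_reliable = if (length(reliable)) min(reliable) else NA_integer_,
            threshold = threshold, reps = reps, base_seed = base_seed)
}

#' @export
print.stability_table <- function(x, ...) {
  cat(sprintf("APD subsampling stability (%d replicates, threshold %.2f):\n",
              attr(x, "reps"), attr(x, "threshold")))
  print.data.frame(x, row.names = FALSE, digits = 5)
  mr <- attr(x, "m_reliable")
  cat(if (is.na(mr)) "no size reached the threshold\n"
      else sprintf("smallest reliable size: %d variants\n", mr))
  invisible(x)
}

#' Write a stability table as TSV
#'
#' Columns `m`, `mean_r`, `sd_r`, `cv_r`.
#' @param tab a `stability_table`.
#' @param path output file.
#' @param header_comment optional `#`-prefixed provenance line(s).
#' @return `path`, invisibly.
#' @export
write_stability <- function(tab, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  mr <- attr(tab, "m_reliable")
  writeLines(sprintf("# smallest m with mean_r >= %g: %s",
                     attr(tab, "threshold"),
                     if (is.na(mr)) "none" else as.character(mr)), con)
  utils::write.table(as.data.frame(tab), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
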