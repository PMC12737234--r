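# Orchestration of the end-to-end analysis: ingest -> subset -> filter ->
# APD -> ranking -> PCA/HAP -> IBC/correlation (-> stability), with TSV
# outputs, a machine-readable manifest, and timestamped logging.

log_msg <- function(...) {
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), sprintf(...))
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(cfg, f)
  unname(tools::md5sum(f))
}

load_genotypes <- function(input, format = c("auto", "vcf", "plink")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", input)) "vcf" else "plink"
  }
  if (format == "vcf") read_vcf(input) else read_plink(input)
}

#' Run the APD analysis end to end
#'
#' Reads genotypes, optionally restricts to a sample group, filters variants
#' by missingness/MAF/monomorphism, computes per-sample APD, the top-rank
#' lists, genotype PCA with convex-hull area percentages for the
#' APD-selected subsets, individual inbreeding coefficients and the APD-IBC
#' correlation. All tables are written as TSV into `out_dir`, each with a
#' provenance header (config hash and seed), plus a `manifest.json`.
#'
#' @param input VCF path or PLINK prefix.
#' @param out_dir output directory (created if needed).
#' @param format `"auto"` (by extension), `"vcf"` or `"plink"`.
#' @param keep optional sample IDs to retain: a character vector or the path
#'   of a one-ID-per-line file.
#' @param spec a [filter_spec()].
#' @param metric see [pair_dissimilarity()].
#' @param rank_pcts percentage levels for the ranking table.
#' @param hap_pcts APD percentage levels whose subsets are measured against
#'   the PCA space.
#' @param pca_k number of principal components to store.
#' @param seed integer seed recorded in the provenance headers (the APD
#'   computation itself is deterministic).
#' @return invisibly, a list with the in-memory results (`gm`, `apd`, `pca`,
#'   `ibc`, `hap`, `correlation`, `filter_report`, `paths`).
#' @export
run_apd <- function(input, out_dir, format = "auto", keep = NULL,
                    spec = filter_spec(), metric = c("smc", "ibs"),
                    rank_pcts = c(1, 5, 10, 15, 20, 25, 30),
                    hap_pcts = c(10, 20, 30), pca_k = 2, seed = 1) {
  metric <- match.arg(metric)
  if (any(rank_pcts <= 0 | rank_pcts > 100) || any(hap_pcts <= 0 | hap_pcts > 100)) {
    stop_domain("percentage levels must lie in (0, 100]")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- list(input = input, format = format, keep = keep, spec = spec,
              metric = metric, rank_pcts = rank_pcts, hap_pcts = hap_pcts,
              pca_k = pca_k, seed = seed)
  hash <- config_hash(cfg)
  prov <- sprintf("config_hash=%s seed=%d", hash, as.integer(seed))

  gm <- load_genotypes(input, format)
  log_msg("loaded %d samples x %d variants from %s", n_samples(gm),
          n_variants(gm), input)
  if (!is.null(keep)) {
    ids <- if (length(keep) == 1 && file.exists(keep)) read_sample_list(keep) else keep
    gm <- subset_samples(gm, ids)
    log_msg("restricted to %d samples", n_samples(gm))
  }
  fl <- filter_variants(gm, spec)
  log_msg("filter: %d -> %d variants (missing>%g: %d, MAF<%g: %d, monomorphic: %d, no calls: %d)",
          fl$report$n_input, fl$report$n_kept, spec$miss_max,
          fl$report$n_fail_missing, spec$maf_min, fl$report$n_fail_maf,
          fl$report$n_fail_monomorphic, fl$report$n_no_calls)
  gm <- fl$gm
  if (n_variants(gm) == 0) {
    stop_contract("no variants survive filtering (miss_max=%g, maf_min=%g)",
                  spec$miss_max, spec$maf_min)
  }

  res <- apd_all(gm, metric)
  s <- apd_summary(res)
  log_msg("APD range %.4f-%.4f, mean %.4f", s$min, s$max, s$mean)

  paths <- list(apd = file.path(out_dir, "apd_estimates.tsv"))
  write_apd(res, paths$apd, header_comment = prov)
  paths$summary <- file.path(out_dir, "apd_summary.tsv")
  con <- file(paths$summary, "w")
  writeLines(c(paste0("# ", prov),
               sprintf("# min=%.6f max=%.6f mean=%.6f n=%d", s$min, s$max,
                       s$mean, s$n)), con)
  utils::write.table(s$histogram, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  paths$filter <- file.path(out_dir, "filter_report.tsv")
  write_filter_report(fl$report, paths$filter)

  top_lists <- lapply(rank_pcts, function(p) top_samples(res, p))
  names(top_lists) <- as.character(rank_pcts)
  paths$top <- file.path(out_dir, "top_samples.tsv")
  top_df <- do.call(rbind, lapply(rank_pcts, function(p) {
    data.frame(pct = p, rank = seq_along(top_lists[[as.character(p)]]),
               sample_id = top_lists[[as.character(p)]])
  }))
  con <- file(paths$top, "w")
  writeLines(paste0("# ", prov), con)
  utils::write.table(top_df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)

  pca <- genotype_pca(gm, k = pca_k)
  paths$pca <- file.path(out_dir, "pca_coords.tsv")
  con <- file(paths$pca, "w")
  writeLines(paste0("# ", prov), con)
  utils::write.table(data.frame(sample_id = pca$sample_ids, pca$coords),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)

  hap_ok <- vapply(hap_pcts,
                   function(p) length(top_samples(res, p)) >= 3, logical(1))
  if (!all(hap_ok)) {
    warning(sprintf("HAP level(s) %s select fewer than 3 samples; skipped",
                    paste(hap_pcts[!hap_ok], collapse = ", ")))
  }
  haps <- lapply(hap_pcts[hap_ok],
                 function(p) hap(pca, top_samples(res, p), pct = p))
  paths$hap <- file.path(out_dir, "hap.tsv")
  hap_df <- do.call(rbind, c(list(data.frame(pct = numeric(0),
                                             area_full = numeric(0),
                                             area_subset = numeric(0),
                                             hap = numeric(0))),
                             lapply(haps, function(h) {
    data.frame(pct = h$pct, area_full = h$area_full,
               area_subset = h$area_subset, hap = h$hap)
  })))
  con <- file(paths$hap, "w")
  writeLines(paste0("# ", prov), con)
  utils::write.table(hap_df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)

  ibc <- individual_inbreeding(gm)
  paths$ibc <- file.path(out_dir, "ibc.tsv")
  con <- file(paths$ibc, "w")
  writeLines(paste0("# ", prov), con)
  utils::write.table(data.frame(sample_id = ibc$sample_ids, Fhat = ibc$fhat),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)

  corr <- correlate(res$apd, ibc$fhat)
  log_msg("APD-IBC correlation r = %.4f (p = %.3g)", corr$r, corr$p_value)
  paths$correlations <- file.path(out_dir, "correlations.tsv")
  con <- file(paths$correlations, "w")
  writeLines(paste0("# ", prov), con)
  utils::write.table(
    data.frame(x = "IBC", y = "APD", r = corr$r, r_squared = corr$r_squared,
               slope = corr$slope, intercept = corr$intercept,
               p_value = corr$p_value, n = corr$n),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)

  manifest <- list(config_hash = hash, seed = as.integer(seed),
                   input = input, metric = metric,
                   n_samples = n_samples(gm),
                   n_variants_input = fl$report$n_input,
                   n_variants_kept = fl$report$n_kept,
                   apd_min = s$min, apd_max = s$max, apd_mean = s$mean,
                   apd_ibc_r = corr$r,
                   outputs = lapply(paths, normalizePath))
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(gm = gm, apd = res, pca = pca, ibc = ibc, hap = haps,
                 correlation = corr, filter_report = fl$report, paths = paths))
}

#' Compare two APD analyses of the same samples
#'
#' Takes the results of two [run_apd()] calls (the returned lists, or the
#' output directories, whose `apd_estimates.tsv` is then read back) over the
#' identical sample set — typically the SNP-based and SV-based channels of
#' one panel — and writes the top-rank overlap table plus the correlation
#' between the two APD vectors.
#'
#' @param a,b [run_apd()] result lists or output directories.
#' @param out_dir output directory.
#' @param pcts percentage levels for the overlap table.
#' @return invisibly, list with `overlap` (`data.frame`) and `correlation`
#'   (a `correlation_report`).
#' @export
run_compare <- function(a, b, out_dir, pcts = c(1, 5, 10, 15, 20, 25, 30)) {
  res_a <- as_apd_result(a)
  res_b <- as_apd_result(b)
  if (!setequal(res_a$sample_ids, res_b$sample_ids)) {
    stop_contract("sample sets differ: %d only in A (%s...), %d only in B",
                  length(setdiff(res_a$sample_ids, res_b$sample_ids)),
                  paste(utils::head(setdiff(res_a$sample_ids, res_b$sample_ids), 3),
                        collapse = ","),
                  length(setdiff(res_b$sample_ids, res_a$sample_ids)))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ov <- rank_overlap(res_a, res_b, pcts)
  write_rank_overlap(ov, file.path(out_dir, "rank_overlap.tsv"))
  corr <- correlate(res_a$apd, res_b$apd[match(res_a$sample_ids,
                                               res_b$sample_ids)])
  utils::write.table(
    data.frame(x = "APD_a", y = "APD_b", r = corr$r,
               r_squared = corr$r_squared, slope = corr$slope,
               intercept = corr$intercept, p_value = corr$p_value, n = corr$n),
    file.path(out_dir, "apd_cross_correlation.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  log_msg("cross-channel APD correlation r = %.4f", corr$r)
  invisible(list(overlap = ov, correlation = corr))
}

as_apd_result <- function(x) {
  if (inherits(x, "apd_result")) return(x)
  if (is.list(x) && inherits(x$apd, "apd_result")) return(x$apd)
  if (is.character(x) && length(x) == 1) {
    f <- if (dir.exists(x)) file.path(x, "apd_estimates.tsv") else x
    if (!file.exists(f)) stop_format("no APD table found at %s", f)
    df <- utils::read.table(f, header = TRUE, sep = "\t", comment.char = "#",
                            stringsAsFactors = FALSE)
    return(structure(list(sample_ids = df$sample_id, apd = df$APD,
                          sd = df$SD, n_samples = nrow(df), metric = NA),
                     class = "apd_result"))
  }
  stop_contract("cannot interpret input as an APD result")
}

#' Run the variant-subsampling stability analysis
#'
#' Loads and filters genotypes as in [run_apd()], then evaluates
#' [stability_table()] and writes it as TSV with the smallest reliable
#' subsample size recorded in the header.
#'
#' @inheritParams run_apd
#' @param sizes,reps,threshold see [stability_table()].
#' @return invisibly, the `stability_table`.
#' @export
run_stability <- function(input, out_dir, format = "auto", keep = NULL,
                          spec = filter_spec(), metric = c("smc", "ibs"),
                          sizes = c(1000, 3000, 5000, 10000, 15000),
                          reps = 10, seed = 1, threshold = 0.98) {
  metric <- match.arg(metric)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gm <- load_genotypes(input, format)
  if (!is.null(keep)) {
    ids <- if (length(keep) == 1 && file.exists(keep)) read_sample_list(keep) else keep
    gm <- subset_samples(gm, ids)
  }
  gm <- filter_variants(gm, spec)$gm
  if (any(sizes > n_variants(gm))) {
    stop_domain("subsample size(s) %s exceed the %d post-filter variants",
                paste(sizes[sizes > n_variants(gm)], collapse = ","),
                n_variants(gm))
  }
  cfg <- list(input = input, keep = keep, spec = spec, metric = metric,
              sizes = sizes, reps = reps, seed = seed, threshold = threshold)
  tab <- stability_table(gm, sizes = sizes, reps = reps, base_seed = seed,
                         metric = metric, threshold = threshold)
  write_stability(tab, file.path(out_dir, "stability.tsv"),
                  header_comment = sprintf("config_hash=%s seed=%d",
                                           config_hash(cfg), as.integer(seed)))
  invisible(tab)
}
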