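# Round-half-up helpers. base round() uses round-half-even, which does not
# reproduce published top-k set sizes (e.g. 854 x 25% = 213.5 must give 214).
round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}

#' Number of samples in a top percentage
#'
#' Converts a percentage level into a set size: round-half-up of
#' `n * pct / 100`, never less than 1.
#'
#' @param n total sample count (>= 1).
#' @param pct percentage in (0, 100].
#' @return integer set size.
#' @export
top_fraction_count <- function(n, pct) {
  if (!is.numeric(n) || n < 1) stop_domain("n must be >= 1")
  if (!is.numeric(pct) || pct <= 0 || pct > 100) {
    stop_domain("pct must be in (0, 100]")
  }
  max(1L, as.integer(round_half_up(n * pct / 100)))
}

#' Samples with the highest APD at a percentage level
#'
#' Returns the `top_fraction_count(N, pct)` samples with the largest APD,
#' ordered by descending APD; ties are broken by ascending sample ID so the
#' selection is deterministic. Samples with undefined APD are excluded (with
#' a warning) before ranking.
#'
#' @param res an `apd_result`.
#' @param pct percentage in (0, 100].
#' @return character vector of sample IDs.
#' @export
top_samples <- function(res, pct) {
  defined <- !is.na(res$apd)
  if (!all(defined)) {
    warning(sprintf("%d sample(s) with undefined APD excluded from ranking",
                    sum(!defined)))
  }
  ids <- res$sample_ids[defined]
  apd <- res$apd[defined]
  if (length(ids) == 0) stop_domain("no samples with defined APD")
  k <- top_fraction_count(length(ids), pct)
  ord <- order(-apd, ids)
  ids[ord][seq_len(k)]
}

#' Overlap between two APD rankings across percentage levels
#'
#' For each level, takes the top sets from both rankings and counts the
#' samples present in both, reporting the shared percentage
#' (100 x shared / |set A|, rounded half-up to 1 decimal). Both results must
#' cover the identical sample set.
#'
#' @param res_a,res_b `apd_result` objects over the same samples (e.g.
#'   SNP-based and SV-based APD of one panel).
#' @param pcts percentage levels; default the ladder 1, 5, 10, ..., 30.
#' @return `data.frame` with columns `pct`, `count_a`, `count_b`, `shared`,
#'   `shared_pct`.
#' @export
rank_overlap <- function(res_a, res_b, pcts = c(1, 5, 10, 15, 20, 25, 30)) {
  if (!setequal(res_a$sample_ids, res_b$sample_ids)) {
    only_a <- setdiff(res_a$sample_ids, res_b$sample_ids)
    only_b <- setdiff(res_b$sample_ids, res_a$sample_ids)
    stop_contract("rankings cover different sample sets (%d only in A, %d only in B)",
                  length(only_a), length(only_b))
  }
  rows <- lapply(pcts, function(p) {
    a <- top_samples(res_a, p)
    b <- top_samples(res_b, p)
    shared <- length(intersect(a, b))
    data.frame(pct = p, count_a = length(a), count_b = length(b),
               shared = shared,
               shared_pct = round_half_up(100 * shared / length(a), 1))
  })
  do.call(rbind, rows)
}

#' Write a ranking-overlap table as TSV
#'
#' @param tab output of [rank_overlap()].
#' @param path output file.
#' @param header_comment optional `#`-prefixed provenance line(s).
#' @return `path`, invisibly.
#' @export
write_rank_overlap <- function(tab, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  names(tab)[names(tab) == "pct"] <- "top_rank_pct"
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
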