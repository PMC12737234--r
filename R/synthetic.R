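#' Configuration for the synthetic panel generator
#'
#' The generator emulates the statistical structure of a selfing-crop
#' diversity panel genotyped at genome-wide biallelic variants: an L-shaped
#' minor-allele-frequency spectrum (Beta-distributed ancestral frequencies
#' with shape < 1), optional subpopulation structure (Balding-Nichols
#' divergence), per-individual inbreeding induced by generations of selfing,
#' and uniform missing calls. Defaults describe a panel of 200 individuals
#' spanning a selfing gradient from outbred to near-fully inbred
#' (`selfing_gens` 0..8, expected F from 0 to 0.996), with SNP-like 5%
#' missingness.
#'
#' @param n_samples number of individuals (>= 2).
#' @param n_variants number of variants (>= 1).
#' @param n_subpops number of subpopulations (>= 1).
#' @param fst Balding-Nichols divergence of subpopulation frequencies from
#'   the ancestral frequency, in \[0, 1).
#' @param maf_shape length-2 Beta shape pair for ancestral ALT frequencies;
#'   values < 1 give the L-shaped spectrum typical of resequencing panels.
#' @param selfing_gens nonnegative integer generations of selfing per
#'   individual (recycled); expected inbreeding is `1 - (1/2)^s`.
#' @param missing_rate fraction of calls set missing, in \[0, 1).
#' @param seed integer RNG seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_samples = 200, n_variants = 5000, n_subpops = 1,
                         fst = 0, maf_shape = c(0.3, 0.3),
                         selfing_gens = rep(0:8, length.out = n_samples),
                         missing_rate = 0.05, seed = 1) {
  if (n_samples < 2) stop_domain("n_samples must be >= 2")
  if (n_variants < 1) stop_domain("n_variants must be >= 1")
  if (n_subpops < 1) stop_domain("n_subpops must be >= 1")
  if (fst < 0 || fst >= 1) stop_domain("fst must be in [0, 1)")
  if (length(maf_shape) != 2 || any(!is.finite(maf_shape)) || any(maf_shape <= 0)) {
    stop_domain("maf_shape must be two positive Beta shape parameters")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop_domain("missing_rate must be in [0, 1)")
  }
  if (any(selfing_gens < 0)) stop_domain("selfing_gens must be nonnegative")
  structure(list(n_samples = as.integer(n_samples),
                 n_variants = as.integer(n_variants),
                 n_subpops = as.integer(n_subpops), fst = fst,
                 maf_shape = maf_shape,
                 selfing_gens = rep_len(as.integer(selfing_gens), n_samples),
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "synth_config")
}

# Genotypes under the inbreeding mixture law: at a locus with ALT frequency
# p and individual inbreeding f,
#   P(2) = p^2 + f p q,  P(1) = 2 p q (1 - f),  P(0) = q^2 + f p q.
# p_mat: n x L per-individual frequencies; f: length-n vector.
draw_inbred_genotypes <- function(p_mat, f) {
  q_mat <- 1 - p_mat
  p2 <- p_mat^2 + f * p_mat * q_mat
  p1 <- 2 * p_mat * q_mat * (1 - f)
  u <- matrix(stats::runif(length(p_mat)), nrow = nrow(p_mat))
  g <- matrix(0L, nrow = nrow(p_mat), ncol = ncol(p_mat))
  g[u < p2 + p1] <- 1L
  g[u < p2] <- 2L
  g
}

# Per-individual frequency matrix (n x L): ancestral freqs optionally
# diverged per subpopulation via Balding-Nichols Beta draws.
subpop_frequencies <- function(anc, subpop, n_subpops, fst) {
  l <- length(anc)
  if (n_subpops == 1 || fst == 0) {
    return(matrix(anc, nrow = length(subpop), ncol = l, byrow = TRUE))
  }
  ratio <- (1 - fst) / fst
  pk <- vapply(seq_len(n_subpops), function(k) {
    pmin(pmax(stats::rbeta(l, anc * ratio, (1 - anc) * ratio), 1e-9), 1 - 1e-9)
  }, numeric(l))
  t(pk)[subpop, , drop = FALSE]
}

#' Generate a synthetic genotype panel with known ground truth
#'
#' See [synth_config()] for the generative model. The returned truth carries
#' each individual's expected inbreeding `f_true = 1 - (1/2)^s`, its
#' subpopulation label and the ancestral variant frequencies, enabling
#' parameter-recovery tests (e.g. of the inbreeding estimator or of the
#' negative APD-inbreeding relationship).
#'
#' @param cfg a [synth_config()].
#' @return list with `gm` (a `genotype_matrix`) and `truth` (list with
#'   `samples` — `data.frame(sample_id, subpop, f_true, selfing_gens)` —,
#'   `ancestral_freqs`, and the generating `cfg`).
#' @export
generate_panel <- function(cfg = synth_config()) {
  if (!inherits(cfg, "synth_config")) cfg <- do.call(synth_config, as.list(cfg))
  set.seed(cfg$seed)
  n <- cfg$n_samples
  l <- cfg$n_variants
  anc <- pmin(pmax(stats::rbeta(l, cfg$maf_shape[1], cfg$maf_shape[2]),
                   1e-9), 1 - 1e-9)
  subpop <- rep_len(seq_len(cfg$n_subpops), n)
  p_mat <- subpop_frequencies(anc, subpop, cfg$n_subpops, cfg$fst)
  f <- 1 - 0.5^cfg$selfing_gens
  g <- draw_inbred_genotypes(p_mat, f)
  if (cfg$missing_rate > 0) {
    g[matrix(stats::runif(n * l) < cfg$missing_rate, nrow = n)] <- NA_integer_
  }
  ids <- sprintf("S%04d", seq_len(n))
  variants <- data.frame(
    chrom = as.character(rep_len(1:12, l)[order(rep_len(1:12, l))]),
    pos = integer(l), vid = sprintf("v%06d", seq_len(l)),
    allele_ref = "A", allele_alt = "T", stringsAsFactors = FALSE)
  variants$pos <- stats::ave(seq_len(l), variants$chrom, FUN = seq_along) * 100L
  gm <- genotype_matrix(g, variants = variants, sample_ids = ids)
  truth <- list(samples = data.frame(sample_id = ids, subpop = subpop,
                                     f_true = f,
                                     selfing_gens = cfg$selfing_gens,
                                     stringsAsFactors = FALSE),
                ancestral_freqs = anc, cfg = cfg)
  list(gm = gm, truth = truth)
}

#' Derive a noisy companion variant channel on the same individuals
#'
#' Emulates a second, noisier variant type (e.g. structural variants called
#' by cluster overlap) assayed on the same panel: an independent variant set
#' is generated for the same individuals (same inbreeding, same
#' subpopulation labels), then each call is corrupted with probability
#' `error_rate` (replaced by one of the other two genotype states, chosen
#' uniformly) and missing calls are added at `missing_rate`. Because the two
#' channels share individuals but not variants, their APD vectors are
#' positively but imperfectly correlated, and the correlation degrades as
#' `error_rate` grows.
#'
#' @param gm the primary-channel `genotype_matrix` (used only for its size
#'   default).
#' @param truth the truth list from [generate_panel()].
#' @param error_rate symmetric per-call genotyping error probability,
#'   in \[0, 0.5).
#' @param missing_rate missing-call rate for this channel, in \[0, 1)
#'   (default 0.2, typical of presence/absence SV panels).
#' @param seed integer RNG seed.
#' @param n_variants number of variants in this channel; defaults to
#'   `n_variants(gm)`.
#' @return a `genotype_matrix` over the same sample IDs.
#' @export
derive_sv_channel <- function(gm, truth, error_rate = 0.1, missing_rate = 0.2,
                              seed = 1, n_variants = NULL) {
  if (error_rate < 0 || error_rate >= 0.5) {
    stop_domain("error_rate must be in [0, 0.5)")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop_domain("missing_rate must be in [0, 1)")
  }
  cfg <- truth$cfg
  n <- nrow(truth$samples)
  l <- if (is.null(n_variants)) ncol(gm$dosages) else as.integer(n_variants)
  set.seed(seed)
  anc <- pmin(pmax(stats::rbeta(l, cfg$maf_shape[1], cfg$maf_shape[2]),
                   1e-9), 1 - 1e-9)
  p_mat <- subpop_frequencies(anc, truth$samples$subpop, cfg$n_subpops, cfg$fst)
  g <- draw_inbred_genotypes(p_mat, truth$samples$f_true)
  if (error_rate > 0) {
    flip <- matrix(stats::runif(n * l) < error_rate, nrow = n)
    # replace with one of the two other states, uniformly
    shift <- matrix(sample(1:2, n * l, replace = TRUE), nrow = n)
    g[flip] <- (g[flip] + shift[flip]) %% 3L
  }
  if (missing_rate > 0) {
    g[matrix(stats::runif(n * l) < missing_rate, nrow = n)] <- NA_integer_
  }
  variants <- data.frame(
    chrom = as.character(rep_len(1:12, l)[order(rep_len(1:12, l))]),
    pos = integer(l), vid = sprintf("sv%06d", seq_len(l)),
    allele_ref = "N", allele_alt = "<DEL>", stringsAsFactors = FALSE)
  variants$pos <- stats::ave(seq_len(l), variants$chrom, FUN = seq_along) * 500L
  genotype_matrix(g, variants = variants, sample_ids = truth$samples$sample_id)
}

#' Write a paired SNP-like / SV-like fixture suite
#'
#' Generates a panel from `cfg`, writes the primary channel as VCF
#' (`snp.vcf`), a noisy companion channel as a PLINK fileset (`sv.bed/.bim/
#' .fam`), and the ground truth as `truth.tsv` (`sample_id`, `subpop`,
#' `f_true`). All files are re-readable by [read_vcf()] / [read_plink()].
#'
#' @param dir output directory (created if needed).
#' @param cfg a [synth_config()].
#' @param sv_error_rate,sv_missing_rate noise parameters of the companion
#'   channel (see [derive_sv_channel()]).
#' @return named list of the written paths, invisibly.
#' @export
write_fixture_suite <- function(dir, cfg = synth_config(),
                                sv_error_rate = 0.1, sv_missing_rate = 0.2) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  panel <- generate_panel(cfg)
  vcf <- file.path(dir, "snp.vcf")
  write_vcf(panel$gm, vcf)
  sv <- derive_sv_channel(panel$gm, panel$truth, error_rate = sv_error_rate,
                          missing_rate = sv_missing_rate, seed = cfg$seed + 1L)
  plink_prefix <- file.path(dir, "sv")
  write_plink(sv, plink_prefix)
  truth_path <- file.path(dir, "truth.tsv")
  utils::write.table(panel$truth$samples[, c("sample_id", "subpop", "f_true")],
                     truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(vcf = vcf, plink_prefix = plink_prefix, truth = truth_path))
}
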