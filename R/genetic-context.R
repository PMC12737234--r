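#' Genotype principal component analysis
#'
#' Standard population-genetic PCA of the dosage matrix: each variant is
#' centred by twice its estimated ALT-allele frequency and (by default)
#' scaled by `sqrt(p(1-p))`; missing cells contribute 0 after centring.
#' Scores are the eigenvectors of the sample cross-product matrix scaled by
#' the singular values. Variants that are monomorphic among the analysed
#' samples carry no variance and are dropped with a warning. The sign of
#' each axis is fixed deterministically by making its largest-magnitude
#' variant loading positive.
#'
#' @param gm a post-filter `genotype_matrix` with at least 3 samples.
#' @param k number of components to return (>= 2).
#' @param scale divide by `sqrt(p(1-p))` (set `FALSE` for unscaled,
#'   centred-only PCA).
#' @return A `pca_coordinates` object: list with `sample_ids`, `coords`
#'   (samples x k score matrix, columns `PC1..PCk`), `eigenvalues`
#'   (non-increasing) and `n_variants_used`.
#' @export
genotype_pca <- function(gm, k = 2, scale = TRUE) {
  n <- n_samples(gm)
  if (n < 3) stop_domain("PCA requires at least 3 samples (got %d)", n)
  if (k < 2) stop_domain("k must be >= 2")
  k <- min(k, n - 1L)
  d <- gm$dosages
  n_obs <- colSums(!is.na(d))
  p <- ifelse(n_obs > 0, colSums(d, na.rm = TRUE) / (2 * n_obs), NA_real_)
  usable <- !is.na(p) & p > 0 & p < 1
  if (!all(usable)) {
    warning(sprintf("dropping %d zero-variance variant(s) before PCA",
                    sum(!usable)))
  }
  if (sum(usable) < 1) stop_domain("no polymorphic variants for PCA")
  d <- d[, usable, drop = FALSE]
  p <- p[usable]
  x <- sweep(d, 2, 2 * p)
  if (scale) x <- sweep(x, 2, sqrt(p * (1 - p)), "/")
  x[is.na(x)] <- 0
  sv <- svd(x, nu = k, nv = k)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], nrow = k)
  # deterministic orientation: largest-|loading| entry of each axis positive
  for (j in seq_len(k)) {
    i_max <- which.max(abs(sv$v[, j]))
    if (sv$v[i_max, j] < 0) {
      scores[, j] <- -scores[, j]
    }
  }
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- gm$sample_ids
  structure(list(sample_ids = gm$sample_ids, coords = scores,
                 eigenvalues = (sv$d[seq_len(k)]^2) / (n - 1),
                 n_variants_used = sum(usable)),
            class = "pca_coordinates")
}

#' @export
print.pca_coordinates <- function(x, ...) {
  cat(sprintf("pca_coordinates: %d samples x %d components (from %d variants)\n",
              length(x$sample_ids), ncol(x$coords), x$n_variants_used))
  invisible(x)
}

#' Area of the convex hull of 2-D points
#'
#' Hull vertices from [grDevices::chull()], area by the shoelace formula.
#' Collinear (or coincident) point sets have area 0.
#'
#' @param points numeric matrix or data.frame with >= 3 rows and 2 columns.
#' @return hull area (>= 0).
#' @export
convex_hull_area <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3 || ncol(points) != 2) {
    stop_domain("convex_hull_area needs >= 3 points in 2 dimensions")
  }
  idx <- grDevices::chull(points[, 1], points[, 2])
  if (length(idx) < 3) return(0)
  x <- points[idx, 1]
  y <- points[idx, 2]
  abs(sum(x * (c(y[-1], y[1])) - c(x[-1], x[1]) * y)) / 2
}

#' Convex-hull area percentage (HAP) of a sample subset in PC1-PC2
#'
#' Quantifies how much of the PCA sample space an APD-selected subset
#' covers: 100 x (hull area of the subset) / (hull area of all samples),
#' computed in the PC1-PC2 plane. The percentage is reported rounded
#' half-up to 1 decimal; the areas are returned at full precision.
#'
#' @param pcs a `pca_coordinates` object.
#' @param subset character vector of >= 3 sample IDs, all present in `pcs`.
#' @param pct optional label recording the APD percentage level the subset
#'   came from.
#' @return A `hap_report`: list with `pct`, `area_full`, `area_subset`,
#'   `hap`, `n_subset`.
#' @export
hap <- function(pcs, subset, pct = NA_real_) {
  unknown <- setdiff(subset, pcs$sample_ids)
  if (length(unknown) > 0) {
    stop_lookup("subset IDs not in PCA coordinates: %s",
                paste(unknown, collapse = ", "))
  }
  if (length(subset) < 3) stop_domain("subset must contain >= 3 samples")
  xy_all <- pcs$coords[, 1:2, drop = FALSE]
  area_full <- convex_hull_area(xy_all)
  if (area_full <= 0) {
    stop_domain("full PCA sample space is degenerate (hull area 0)")
  }
  area_subset <- convex_hull_area(xy_all[match(subset, pcs$sample_ids), ,
                                         drop = FALSE])
  structure(list(pct = pct, area_full = area_full, area_subset = area_subset,
                 hap = round_half_up(100 * area_subset / area_full, 1),
                 n_subset = length(subset)),
            class = "hap_report")
}

#' @export
print.hap_report <- function(x, ...) {
  cat(sprintf("HAP: %.1f%% (subset of %d samples%s)\n", x$hap, x$n_subset,
              if (is.na(x$pct)) "" else sprintf(", top %g%% APD", x$pct)))
  invisible(x)
}

#' Individual inbreeding coefficients (method of moments)
#'
#' Per-sample excess-homozygosity estimator. With dosage g at a locus of
#' ALT frequency p, each locus contributes
#' \deqn{(g^2 - (1+2p) g + 2p^2) / (2 p (1-p))}
#' and the estimate is the mean contribution over the sample's non-missing
#' loci with 0 < p < 1. Allele frequencies are estimated from all
#' non-missing calls. Values are not clamped: finite-data estimates can fall
#' outside \[-1, 1\].
#'
#' @param gm a post-filter `genotype_matrix`.
#' @return An `ibc_result`: list with `sample_ids`, `fhat` (`NA` for a
#'   sample with no usable locus) and `n_loci_used` per sample.
#' @export
individual_inbreeding <- function(gm) {
  d <- gm$dosages
  n_obs <- colSums(!is.na(d))
  p <- ifelse(n_obs > 0, colSums(d, na.rm = TRUE) / (2 * n_obs), NA_real_)
  usable <- !is.na(p) & p > 0 & p < 1
  if (sum(usable) < 1) stop_domain("no locus with estimable 0 < p < 1")
  d <- d[, usable, drop = FALSE]
  p <- p[usable]
  g <- d
  storage.mode(g) <- "double"
  # contribution matrix: (g^2 - (1+2p) g + 2 p^2) / (2 p (1-p))
  num <- g^2 - sweep(g, 2, 1 + 2 * p, "*")
  num <- sweep(num, 2, 2 * p^2, "+")
  contrib <- sweep(num, 2, 2 * p * (1 - p), "/")
  l_i <- unname(rowSums(!is.na(contrib)))
  fhat <- unname(ifelse(l_i > 0, rowMeans(contrib, na.rm = TRUE), NA_real_))
  if (any(l_i == 0)) {
    warning(sprintf("%d sample(s) have no usable locus; IBC recorded as NA",
                    sum(l_i == 0)))
  }
  structure(list(sample_ids = gm$sample_ids, fhat = fhat, n_loci_used = l_i),
            class = "ibc_result")
}

#' @export
print.ibc_result <- function(x, ...) {
  ok <- !is.na(x$fhat)
  cat(sprintf("ibc_result: %d samples", length(x$sample_ids)))
  if (any(ok)) {
    cat(sprintf(", Fhat range %.3f - %.3f, mean %.3f",
                min(x$fhat[ok]), max(x$fhat[ok]), mean(x$fhat[ok])))
  }
  cat("\n")
  invisible(x)
}

#' Pearson correlation and simple linear regression
#'
#' Correlates two per-sample quantities (e.g. APD against inbreeding
#' coefficient): Pearson r, r-squared, OLS slope/intercept of `y` on `x`,
#' and the two-sided p-value of r from the t statistic on n - 2 degrees of
#' freedom. Pairs with a missing value in either variable are dropped.
#'
#' @param x,y numeric vectors of equal length (>= 3 complete pairs).
#' @return A `correlation_report`: list with `r`, `r_squared`, `slope`,
#'   `intercept`, `p_value`, `n`.
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y)) {
    stop_contract("x and y differ in length (%d vs %d)", length(x), length(y))
  }
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3) stop_domain("need at least 3 complete pairs (got %d)",
                                 length(x))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_domain("zero variance in x or y; correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  r <- unname(ct$estimate)
  slope <- r * stats::sd(y) / stats::sd(x)
  structure(list(r = r, r_squared = r^2, slope = slope,
                 intercept = mean(y) - slope * mean(x),
                 p_value = ct$p.value, n = length(x)),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("r = %.4f (r^2 = %.4f), y = %.4g + %.4g x, p = %.3g, n = %d\n",
              x$r, x$r_squared, x$intercept, x$slope, x$p_value, x$n))
  invisible(x)
}
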