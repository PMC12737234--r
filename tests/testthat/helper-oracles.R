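# Independent oracles and fixture builders. These deliberately avoid the
# package's fast computational paths: the APD oracle is a literal double
# loop over the definition, the hull oracle is a monotone-chain
# implementation distinct from grDevices::chull, and the correlation oracle
# is the textbook sum formula.

random_gm <- function(n, l, missing_rate = 0.05, seed = 1,
                      p = NULL) {
  set.seed(seed)
  if (is.null(p)) p <- stats::runif(l, 0.05, 0.95)
  g <- sapply(p, function(pp) stats::rbinom(n, 2, pp))
  if (missing_rate > 0) {
    g[matrix(stats::runif(n * l) < missing_rate, nrow = n)] <- NA_integer_
  }
  g <- matrix(as.integer(g), nrow = n)
  genotype_matrix(g, sample_ids = sprintf("S%03d", seq_len(n)))
}

# APD by definition: per sample, loop over the other samples, compute the
# pairwise dissimilarity over pairwise-complete loci, average and take the
# sample SD of the N-1 values.
brute_apd <- function(gm, metric = "smc") {
  d <- gm$dosages
  n <- nrow(d)
  apd <- sd_out <- numeric(n)
  for (i in seq_len(n)) {
    vals <- numeric(0)
    for (j in seq_len(n)) {
      if (j == i) next
      ok <- !is.na(d[i, ]) & !is.na(d[j, ])
      if (!any(ok)) next
      vals <- c(vals, if (metric == "ibs") {
        mean(abs(d[i, ok] - d[j, ok]) / 2)
      } else {
        mean(d[i, ok] != d[j, ok])
      })
    }
    apd[i] <- if (length(vals)) mean(vals) else NA_real_
    sd_out[i] <- if (length(vals) > 1) stats::sd(vals) else 0
  }
  list(apd = apd, sd = sd_out)
}

# Andrew's monotone chain convex hull + shoelace, independent of chull().
hull_area_monotone_chain <- function(pts) {
  pts <- unique(as.matrix(pts))
  pts <- pts[order(pts[, 1], pts[, 2]), , drop = FALSE]
  n <- nrow(pts)
  if (n < 3) return(0)
  cross <- function(o, a, b) {
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  }
  build <- function(idx) {
    h <- integer(0)
    for (i in idx) {
      while (length(h) >= 2 &&
             cross(pts[h[length(h) - 1], ], pts[h[length(h)], ], pts[i, ]) <= 0) {
        h <- h[-length(h)]
      }
      h <- c(h, i)
    }
    h
  }
  lower <- build(seq_len(n))
  upper <- build(rev(seq_len(n)))
  hull <- c(lower[-length(lower)], upper[-length(upper)])
  if (length(hull) < 3) return(0)
  x <- pts[hull, 1]
  y <- pts[hull, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

pearson_oracle <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

# tiny deterministic matrix for hand-computed examples
toy_gm <- function(dosages, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("T%d", seq_len(nrow(dosages)))
  genotype_matrix(matrix(as.integer(dosages), nrow = nrow(dosages)),
                  sample_ids = ids)
}
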