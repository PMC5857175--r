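# Independent oracles and small fixture builders shared across the suite.

suppressPackageStartupMessages(library(dplyr))

# OLS by the normal equations, independent of stats::lm.
ols_oracle <- function(x, y, through_origin = FALSE) {
  X <- if (through_origin) cbind(x) else cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  list(
    intercept = if (through_origin) 0 else beta[1L],
    slope = beta[length(beta)],
    r2_centered = 1 - sum(res^2) / sum((y - mean(y))^2),
    r2_uncentered = 1 - sum(res^2) / sum(y^2)
  )
}

# Naive O(n^3) agglomerative clustering; returns merge heights in order.
agglomerative_heights_oracle <- function(m, linkage = "complete") {
  d <- as.matrix(dist(m))
  clusters <- as.list(seq_len(nrow(m)))
  heights <- numeric(0)
  link <- function(a, b) {
    v <- d[a, b, drop = FALSE]
    if (linkage == "complete") max(v) else min(v)
  }
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        h <- link(clusters[[i]], clusters[[j]])
        if (h < best_h) { best_h <- h; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_h)
    clusters[[best[1L]]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters[[best[2L]]] <- NULL
  }
  heights
}

# Small long-format feature table with a parseable lineage per taxon.
make_feature_table <- function(counts, samples = NULL, lineages = NULL) {
  counts <- as.matrix(counts) # taxa x samples
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(counts)))
  if (is.null(lineages)) {
    lineages <- sprintf("Bacteria;Phylum%02d;Genus%03d",
                        (seq_len(nrow(counts)) - 1L) %% 3L + 1L,
                        seq_len(nrow(counts)))
  }
  absquant:::build_feature_table(lineages, samples, counts)
}

# Noise-free qPCR dilution series following a known line.
make_standards <- function(slope = -3.3219, intercept = 37, logs = 1:9) {
  tibble::tibble(
    assay = "total_16s",
    copies_per_ul = 10^logs,
    ct = intercept + slope * logs
  )
}

expect_tbl_equal_counts <- function(a, b) {
  key <- c("sample", "lineage")
  a <- dplyr::arrange(a, dplyr::across(dplyr::all_of(key)))
  b <- dplyr::arrange(b, dplyr::across(dplyr::all_of(key)))
  expect_equal(a$count, b$count)
  expect_equal(a$sample, b$sample)
}
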