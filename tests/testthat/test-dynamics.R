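rel_tbl <- function(sample, taxa, p) {
  tibble::tibble(sample = sample, lineage = taxa, taxon = taxa, proportion = p)
}
abs_tbl <- function(sample, taxa, a) {
  tibble::tibble(sample = sample, lineage = taxa, taxon = taxa, abundance = a)
}

test_that("percent change reproduces the worked share and quantity examples", {
  # genus share dropping by almost three quarters
  expect_equal(percent_change(10.71, 2.71), -74.70, tolerance = 5e-5)
  # absolute abundances in the two 16S regions
  expect_equal(percent_change(5.13e8, 2.47e8), -51.85, tolerance = 1e-2)
  expect_equal(percent_change(3.86e8, 1.40e8), -63.73, tolerance = 1e-2)
  expect_equal(percent_change(7, 7), 0)
  # exact relation for relative increase f
  withr::local_seed(3)
  a <- runif(10, 1, 100); f <- runif(10, -0.9, 2)
  expect_equal(percent_change(a, a * (1 + f)), 100 * f, tolerance = 1e-9)
  expect_error(percent_change(0, 5), "positive")
})

test_that("trend classification follows the sign pattern", {
  expect_equal(classify_trend_pair(9.44, -20.8), "discordant")
  expect_equal(classify_trend_pair(-8.00, -63.7), "concordant")
  expect_equal(classify_trend_pair(0, 0), "unchanged")
  expect_equal(classify_trend_pair(0, 12), "unchanged")
  expect_equal(classify_trend_pair(5, 0), "unchanged")
  # deltas within eps count as zero
  expect_equal(classify_trend_pair(0.5, -30, eps = 1), "unchanged")
  # flipping both signs preserves the class
  withr::local_seed(6)
  r <- rnorm(50); a <- rnorm(50)
  expect_equal(classify_trend_pair(-r, -a), classify_trend_pair(r, a))
})

test_that("discordance counts equal brute-force enumeration", {
  withr::local_seed(14)
  n <- 50
  taxa <- sprintf("t%02d", 1:n)
  p0 <- rgamma(n, 1); p0 <- p0 / sum(p0)
  p1 <- rgamma(n, 1); p1 <- p1 / sum(p1)
  a0 <- runif(n, 1e4, 1e9)
  a1 <- a0 * exp(rnorm(n, 0, 1))
  d <- count_discordant(
    rel_tbl("x0", taxa, p0), rel_tbl("x1", taxa, p1),
    abs_tbl("x0", taxa, a0), abs_tbl("x1", taxa, a1)
  )
  brute <- vapply(seq_len(n), function(i) {
    r <- sign(p1[i] - p0[i]); a <- sign(a1[i] - a0[i])
    if (r == 0 || a == 0) "unchanged" else if (r == a) "concordant" else "discordant"
  }, character(1))
  expect_equal(d$n_discordant, sum(brute == "discordant"))
  expect_equal(d$n_concordant, sum(brute == "concordant"))
  expect_equal(d$n_unchanged, sum(brute == "unchanged"))
  expect_equal(d$n_taxa, n)
  expect_equal(d$n_taxa, d$n_discordant + d$n_concordant + d$n_unchanged)
  # records are ordered by taxon
  expect_equal(d$records$taxon, sort(taxa))
})

test_that("identical time points produce no discordance", {
  taxa <- c("a", "b")
  d <- count_discordant(
    rel_tbl("s", taxa, c(0.4, 0.6)), rel_tbl("s", taxa, c(0.4, 0.6)),
    abs_tbl("s", taxa, c(4e8, 6e8)), abs_tbl("s", taxa, c(4e8, 6e8))
  )
  expect_equal(d$n_discordant, 0L)
  expect_equal(d$n_unchanged, 2L)
})

test_that("a pure total-load shift leaves all taxa unchanged", {
  taxa <- c("a", "b", "c")
  p <- c(0.2, 0.3, 0.5)
  d <- count_discordant(
    rel_tbl("s", taxa, p), rel_tbl("s", taxa, p),
    abs_tbl("s", taxa, p * 1e9), abs_tbl("s", taxa, p * 2e9)
  )
  expect_equal(d$n_unchanged, 3L)
  expect_equal(d$n_discordant, 0L)
})

test_that("taxa appearing from zero are flagged, classed by sign", {
  d <- count_discordant(
    rel_tbl("s", c("a", "b"), c(1, 0)), rel_tbl("s", c("a", "b"), c(0.9, 0.1)),
    abs_tbl("s", c("a", "b"), c(1e9, 0)), abs_tbl("s", c("a", "b"), c(9e8, 1e8))
  )
  rec <- d$records[d$records$taxon == "b", ]
  expect_true(rec$undefined_pct)
  expect_true(is.na(rec$abs_change_pct))
  expect_equal(rec$trend_class, "concordant") # both rise
})

test_that("clustering matches a naive agglomerative oracle", {
  withr::local_seed(25)
  m <- matrix(runif(5 * 8, 0, 100), nrow = 5,
              dimnames = list(paste0("s", 1:5), paste0("t", 1:8)))
  tbl <- tidyr::pivot_longer(
    dplyr::mutate(tibble::as_tibble(m), sample = rownames(m)),
    -sample, names_to = "taxon", values_to = "abundance"
  )
  hc <- cluster_samples(tbl, transform = "none")
  expect_equal(hc$height, agglomerative_heights_oracle(m), tolerance = 1e-9)

  # identical samples merge at height zero
  two <- tbl[tbl$sample %in% c("s1", "s2"), ]
  two$abundance[two$sample == "s2"] <- two$abundance[two$sample == "s1"]
  expect_equal(cluster_samples(two, transform = "none")$height, 0)

  # the close pair merges first under a forced topology
  tri <- tibble::tibble(
    sample = rep(c("a", "b", "c"), each = 1),
    taxon = "t", abundance = c(0, 1, 10)
  )
  hc3 <- cluster_samples(tri, transform = "none")
  expect_equal(hc3$merge[1, ], c(-1, -2))
  expect_error(cluster_samples(tri[1, ]), "2 samples")
})

test_that("uniform scaling preserves merge topology without transform", {
  withr::local_seed(26)
  m <- matrix(runif(4 * 6), nrow = 4,
              dimnames = list(paste0("s", 1:4), paste0("t", 1:6)))
  long <- function(mm) tidyr::pivot_longer(
    dplyr::mutate(tibble::as_tibble(mm), sample = rownames(mm)),
    -sample, names_to = "taxon", values_to = "abundance"
  )
  h1 <- cluster_samples(long(m), transform = "none")
  h2 <- cluster_samples(long(m * 50), transform = "none")
  expect_equal(h1$merge, h2$merge)
  expect_equal(h1$order, h2$order)
  expect_equal(h2$height, 50 * h1$height, tolerance = 1e-9)
})

test_that("dendrograms export as newick readable by ape", {
  tbl <- tibble::tibble(
    sample = rep(c("a", "b", "c"), each = 2),
    taxon = rep(c("t1", "t2"), 3),
    abundance = c(1, 2, 1.1, 2.1, 8, 9)
  )
  hc <- cluster_samples(tbl)
  nwk <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram(hc, nwk)
  tree <- ape::read.tree(nwk)
  expect_setequal(tree$tip.label, c("a", "b", "c"))
})
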