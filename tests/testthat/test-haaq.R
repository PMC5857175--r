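totals_fixture <- function(samples, totals, region = "V4") {
  tibble::tibble(sample = samples, region = region, total_copies = totals)
}

test_that("integration multiplies proportions by the sample total", {
  # one genus at 10.71% of a community whose V4 total is back-computed from
  # its published absolute abundance of 5.13e8 copies/g
  total <- 5.13e8 / 0.1071
  rel <- tibble::tibble(sample = "W0", lineage = c("Massilia", "rest"),
                        taxon = c("Massilia", "rest"),
                        proportion = c(0.1071, 0.8929))
  abs_tbl <- integrate_abundance(rel, totals_fixture("W0", total), region = "V4")
  expect_equal(abs_tbl$abundance[1L], 5.13e8, tolerance = 1e-9)
  expect_equal(abs_tbl$region, c("V4", "V4"))
  # conservation: per-sample abundances sum to T
  expect_equal(sum(abs_tbl$abundance), total, tolerance = 1e-6 * total)
  # p = 0 gives A = 0
  rel0 <- dplyr::mutate(rel, proportion = c(0, 1))
  expect_equal(integrate_abundance(rel0, totals_fixture("W0", total))$abundance[1L], 0)
})

test_that("integration conserves totals and scales linearly for random tables", {
  withr::local_seed(21)
  for (i in 1:5) {
    k <- sample(3:12, 1)
    p <- rgamma(k, 1); p <- p / sum(p)
    t1 <- runif(1, 1e8, 1e10)
    rel <- tibble::tibble(sample = "s", lineage = paste0("t", 1:k),
                          taxon = paste0("t", 1:k), proportion = p)
    a1 <- integrate_abundance(rel, totals_fixture("s", t1))
    expect_equal(sum(a1$abundance), t1, tolerance = 1e-6)
    # scale equivariance
    a2 <- integrate_abundance(rel, totals_fixture("s", 3 * t1))
    expect_equal(a2$abundance, 3 * a1$abundance, tolerance = 1e-12)
    # monotone in p within a sample
    expect_equal(order(a1$abundance), order(p))
  }
})

test_that("missing totals are reported by sample and region", {
  rel <- tibble::tibble(sample = "s2", lineage = "t", taxon = "t", proportion = 1)
  expect_error(integrate_abundance(rel, totals_fixture("s1", 1e9), region = "V4"),
               "s2.*V4")
})

test_that("replicate totals for a pooled sequencing sample are averaged", {
  rel <- tibble::tibble(sample = "s", lineage = "t", taxon = "t", proportion = 1)
  totals <- tibble::tibble(sample = "s", region = "V4",
                           total_copies = c(1e9, 2e9, 3e9))
  expect_equal(integrate_abundance(rel, totals, "V4")$abundance, 2e9)
})

test_that("marker expectation scales by the 16S:marker copy ratio", {
  expect_equal(signif(expected_marker_copies(4.79e9, 7), 3), 3.35e10)
  expect_equal(signif(expected_marker_copies(8.11e4, 7), 3), 5.68e5)
  expect_equal(expected_marker_copies(123.4, 1), 123.4)
  expect_error(expected_marker_copies(1, 0), "positive")
})

test_that("genome equivalents divide by 16S copies per genome", {
  abs_tbl <- tibble::tibble(sample = "W0", lineage = "Massilia",
                            taxon = "Massilia", abundance = 9.0e7)
  cn <- tibble::tibble(taxon = "Massilia", copies_per_genome = 9)
  ge <- to_genome_equivalents(abs_tbl, cn)
  expect_equal(ge$abundance, 1.0e7)

  # c = 1 everywhere is the identity
  cn1 <- tibble::tibble(taxon = "Massilia", copies_per_genome = 1)
  expect_equal(to_genome_equivalents(abs_tbl, cn1)$abundance, 9.0e7)

  # inverse relation G * c = A on a random table
  withr::local_seed(33)
  k <- 10
  tbl <- tibble::tibble(sample = "s", lineage = paste0("t", 1:k),
                        taxon = paste0("t", 1:k),
                        abundance = runif(k, 1e3, 1e9))
  cn2 <- tibble::tibble(taxon = paste0("t", 1:k),
                        copies_per_genome = sample(1:15, k, replace = TRUE))
  ge2 <- to_genome_equivalents(tbl, cn2)
  expect_equal(ge2$abundance * ge2$copies_per_genome, tbl$abundance,
               tolerance = 1e-12)

  # unmatched taxa fall back to the default with a warning
  expect_warning(
    to_genome_equivalents(tbl, cn2[1:3, ]),
    "without a 16S copy number"
  )
  expect_error(to_genome_equivalents(tbl, dplyr::mutate(cn2, copies_per_genome = 0)),
               ">= 1")
})

test_that("detection limit scales reads-to-total and linearly in T", {
  dl <- detection_limit(5, 66460, 1e8)
  expect_equal(dl$limit, 5 / 66460 * 1e8, tolerance = 1e-12)
  expect_equal(signif(dl$limit, 3), 7.52e3)
  expect_true(dl$limit <= 1e8)
  expect_equal(detection_limit(100, 100, 1e9)$limit, 1e9)
  expect_equal(detection_limit(5, 1000, 2e8)$limit,
               2 * detection_limit(5, 1000, 1e8)$limit)
  expect_error(detection_limit(5, 0, 1e8), "positive")
  expect_error(detection_limit(0, 10, 1e8), "1..depth")
})
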