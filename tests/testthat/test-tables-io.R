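test_that("TSV round-trip preserves counts exactly and parses lineages", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "#OTU ID\tA\tB",
    "Bacteria;Proteobacteria;Gammaproteobacteria\t2\t3",
    "Bacteria;Firmicutes\t5\t0",
    "d__Bacteria;p__Bacteroidetes;c__Flavobacteriia\t1\t7"
  ), tf)
  ft <- read_feature_table(tf)
  expect_equal(sort(unique(ft$sample)), c("A", "B"))
  expect_equal(ft$count[ft$sample == "A"], c(2L, 5L, 1L))
  expect_equal(ft$count[ft$sample == "B"], c(3L, 0L, 7L))
  # rank prefixes like d__/p__ are stripped during parsing
  expect_identical(ft$phylum[ft$lineage ==
    "d__Bacteria;p__Bacteroidetes;c__Flavobacteriia"][1L], "Bacteroidetes")
  expect_identical(
    ft$phylum[ft$lineage == "Bacteria;Firmicutes"], rep("Firmicutes", 2L)
  )

  out <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(ft, out)
  expect_tbl_equal_counts(read_feature_table(out), ft)
})

test_that("a named rank below a missing one is rejected", {
  expect_error(parse_lineage("Bacteria;;Gammaproteobacteria"), "missing rank")
})

test_that("BIOM v1 input equals the same matrix read from TSV", {
  skip_if_not_installed("biomformat")
  counts <- matrix(c(2L, 5L, 1L, 3L, 0L, 7L), nrow = 3)
  lineages <- c("Bacteria;P1;G1", "Bacteria;P1;G2", "Bacteria;P2;G3")
  ft_tsv <- make_feature_table(counts, samples = c("A", "B"), lineages = lineages)

  m <- counts
  rownames(m) <- lineages
  colnames(m) <- c("A", "B")
  b <- biomformat::make_biom(m)
  bf <- withr::local_tempfile(fileext = ".biom")
  biomformat::write_biom(b, bf)
  ft_biom <- read_feature_table(bf, format = "biom")
  expect_tbl_equal_counts(ft_biom, ft_tsv)
})

test_that("malformed tables are rejected with informative errors", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#OTU ID\ts1", "Bacteria;P;G\t-1"), tf)
  expect_error(read_feature_table(tf), "negative")
  writeLines(c("#OTU ID\ts1", "Bacteria;P;G\t1.5"), tf)
  expect_error(read_feature_table(tf), "non-integer")
  writeLines(c("#OTU ID\ts1", "Bacteria;P;G\t1\t2"), tf)
  expect_error(read_feature_table(tf), "line 2")
  writeLines(c("#OTU ID\ts1\ts1", "Bacteria;P;G\t1\t2"), tf)
  expect_error(read_feature_table(tf), "duplicated sample")
})

test_that("to_relative divides by the sample total and sums to one", {
  ft <- make_feature_table(matrix(c(2L, 3L, 5L), ncol = 1))
  rel <- to_relative(ft)
  expect_equal(rel$proportion, c(0.2, 0.3, 0.5))

  single <- make_feature_table(matrix(17L, ncol = 1))
  expect_equal(to_relative(single)$proportion, 1)

  # a rare taxon: 5 reads out of a deep sample
  deep <- make_feature_table(matrix(c(5L, 66455L), ncol = 1))
  expect_equal(to_relative(deep)$proportion[1L], 5 / 66460, tolerance = 1e-12)
  expect_equal(to_relative(deep)$proportion[1L], 7.523e-5, tolerance = 1e-3)

  zero <- make_feature_table(matrix(c(0L, 0L), ncol = 1))
  expect_error(to_relative(zero), "zero total")
})

test_that("row sums after to_relative are 1 for random tables", {
  withr::local_seed(11)
  for (rep in 1:5) {
    counts <- matrix(rpois(8 * 4, 30) + 1L, nrow = 8)
    rel <- to_relative(make_feature_table(counts))
    sums <- tapply(rel$proportion, rel$sample, sum)
    expect_true(all(abs(sums - 1) < 1e-9))
  }
})

test_that("aggregate_by_rank matches brute-force group sums and is idempotent", {
  withr::local_seed(42)
  counts <- matrix(rpois(20 * 3, 50), nrow = 20)
  ft <- make_feature_table(counts)
  agg <- aggregate_by_rank(ft, "phylum")

  manual <- ft %>%
    dplyr::group_by(sample, phylum) %>%
    dplyr::summarise(count = sum(count), .groups = "drop") %>%
    dplyr::arrange(sample, phylum)
  expect_equal(
    dplyr::arrange(agg, sample, phylum)$count,
    manual$count
  )
  # conservation of per-sample totals
  expect_equal(
    tapply(agg$count, agg$sample, sum),
    tapply(ft$count, ft$sample, sum)
  )
  # genus-level aggregation of a genus-level table changes nothing
  agg2 <- aggregate_by_rank(ft, "genus")
  expect_tbl_equal_counts(agg2, ft)
  expect_error(aggregate_by_rank(ft, "species"), "unknown rank")
})

test_that("unclassified-at-rank taxa aggregate under a sentinel label", {
  ft <- make_feature_table(
    matrix(c(4L, 6L), ncol = 1),
    lineages = c("Bacteria;Firmicutes;Bacillus", "Bacteria")
  )
  agg <- aggregate_by_rank(ft, "phylum")
  expect_setequal(agg$taxon, c("Firmicutes", "Unclassified"))
  expect_equal(sum(agg$count), 10L)
})

test_that("pool_minor pools only taxa below threshold in every sample", {
  rel <- to_relative(make_feature_table(
    matrix(c(9990L, 5L, 5L,
             9000L, 500L, 500L), ncol = 2),
    samples = c("x", "y")
  ))
  # taxa 2 and 3 are 0.0005 in x but 0.05 in y: retained
  pooled <- pool_minor(rel, 0.001)
  expect_false("Minor" %in% pooled$taxon)

  rel2 <- to_relative(make_feature_table(
    matrix(c(9990L, 5L, 5L, 9990L, 5L, 5L), ncol = 2),
    samples = c("x", "y")
  ))
  pooled2 <- pool_minor(rel2, 0.001)
  expect_true("Minor" %in% pooled2$taxon)
  expect_equal(nrow(pooled2), 4L) # one kept taxon + Minor, per sample
  # per-sample sums unchanged
  expect_equal(as.numeric(tapply(pooled2$proportion, pooled2$sample, sum)),
               c(1, 1), tolerance = 1e-12)
  # boundary: exactly at threshold is retained (strict <)
  rel3 <- to_relative(make_feature_table(matrix(c(1L, 999L), ncol = 1)))
  expect_false("Minor" %in% pool_minor(rel3, 0.001)$taxon)
  expect_error(pool_minor(rel3, 1.5), "fraction")
})
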