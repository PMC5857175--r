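#' Percent change between two measurements
#'
#' `(after - before) / before * 100`; negative values are decreases. Used
#' for absolute abundances, where changes are naturally expressed relative
#' to the baseline quantity. (Relative-abundance changes are instead
#' reported in percentage points, the difference of two percentages.)
#'
#' @param before Baseline value(s), strictly positive.
#' @param after New value(s), non-negative.
#' @return Percent change, vectorised.
#' @export
#' @examples
#' percent_change(10.71, 2.71) # -74.70: dropped almost three quarters
percent_change <- function(before, after) {
  if (any(!is.finite(before) | before <= 0)) {
    abort("`before` must be positive; percent change from 0 is undefined")
  }
  if (any(after < 0, na.rm = TRUE)) abort("`after` must be non-negative")
  (after - before) / before * 100
}

#' Classify agreement between relative and absolute abundance trends
#'
#' Given a taxon's change in relative abundance and in absolute abundance
#' between two time points, classifies the pair as `"concordant"` (both move
#' the same way), `"discordant"` (opposite directions — the situations where
#' relative abundance alone misleads), or `"unchanged"` (either change
#' within `eps` of zero). Deltas with magnitude at most `eps` are treated as
#' zero; the default `eps = 0` is a strict sign test.
#'
#' @param rel_delta Change in relative abundance (percentage points).
#' @param abs_delta Change in absolute abundance (any consistent scale,
#'   e.g. percent of baseline).
#' @param eps Half-width of the "no change" band, on each delta's own scale.
#' @return Character vector of classes, vectorised over the deltas.
#' @export
#' @examples
#' classify_trend_pair(9.44, -20.8) # rises in share, falls in quantity
classify_trend_pair <- function(rel_delta, abs_delta, eps = 0) {
  if (eps < 0) abort("`eps` must be non-negative")
  r <- ifelse(abs(rel_delta) <= eps, 0, sign(rel_delta))
  a <- ifelse(abs(abs_delta) <= eps, 0, sign(abs_delta))
  dplyr::case_when(
    r == 0 | a == 0 ~ "unchanged",
    r == a ~ "concordant",
    .default = "discordant"
  )
}

#' Count trend discordances between relative and absolute abundances
#'
#' Joins per-taxon relative and absolute abundances at two time points and
#' classifies every taxon with [classify_trend_pair()], producing the
#' discordance summary that quantifies how often relative abundance alone
#' would have called the direction of change wrong. Taxa absent at a time
#' point are treated as zeros; a taxon appearing from zero has a positive
#' absolute trend but an undefined percent change (`abs_change_pct` is `NA`
#' and the record is flagged).
#'
#' @param rel0,rel1 Relative-abundance tibbles (single sample each) at the
#'   two time points.
#' @param abs0,abs1 Matching absolute-abundance tibbles.
#' @param eps No-change band passed to [classify_trend_pair()], in
#'   percentage points for the relative delta and percent for the absolute
#'   delta.
#' @param treatment,region Optional labels carried into the summary.
#' @return A `discordance_summary` object: counts `n_taxa`, `n_concordant`,
#'   `n_discordant`, `n_unchanged`, and `records`, a tibble sorted by taxon
#'   name with columns `taxon`, `rel_before`, `rel_after`, `abs_before`,
#'   `abs_after`, `rel_change_pp`, `abs_change_pct`, `undefined_pct`,
#'   `trend_class`. Supports [tidy()], [glance()] and [ggplot2::autoplot()].
#' @export
count_discordant <- function(rel0, rel1, abs0, abs1, eps = 0,
                             treatment = NA_character_, region = NA_character_) {
  one <- function(tbl, col, nm) {
    if (!col %in% names(tbl)) abort(sprintf("`%s` must have a `%s` column", nm, col))
    if (length(unique(tbl$sample)) > 1L) {
      abort(sprintf("`%s` must contain a single sample; got %d", nm,
                    length(unique(tbl$sample))))
    }
    key <- if ("lineage" %in% names(tbl)) "lineage" else "taxon"
    tibble(taxon = tbl[[key]], value = tbl[[col]])
  }
  r0 <- one(rel0, "proportion", "rel0"); r1 <- one(rel1, "proportion", "rel1")
  a0 <- one(abs0, "abundance", "abs0"); a1 <- one(abs1, "abundance", "abs1")
  if (!setequal(union(r0$taxon, r1$taxon), union(a0$taxon, a1$taxon))) {
    abort("relative and absolute tables cover different taxa")
  }
  rec <- tibble(taxon = sort(unique(c(r0$taxon, r1$taxon)))) %>%
    mutate(
      rel_before = lookup0(.data$taxon, r0),
      rel_after = lookup0(.data$taxon, r1),
      abs_before = lookup0(.data$taxon, a0),
      abs_after = lookup0(.data$taxon, a1),
      rel_change_pp = (.data$rel_after - .data$rel_before) * 100,
      undefined_pct = .data$abs_before == 0,
      abs_change_pct = dplyr::if_else(
        .data$undefined_pct, NA_real_,
        (.data$abs_after - .data$abs_before) / dplyr::if_else(.data$abs_before == 0, NA_real_, .data$abs_before) * 100
      ),
      trend_class = classify_trend_pair(
        .data$rel_change_pp,
        # appearing-from-zero taxa count as increases; percent change itself
        # stays undefined
        dplyr::if_else(.data$undefined_pct & .data$abs_after > 0, 1,
                       dplyr::coalesce(.data$abs_change_pct, 0)),
        eps = eps
      )
    )
  structure(
    list(
      treatment = treatment, region = region,
      n_taxa = nrow(rec),
      n_concordant = sum(rec$trend_class == "concordant"),
      n_discordant = sum(rec$trend_class == "discordant"),
      n_unchanged = sum(rec$trend_class == "unchanged"),
      eps = eps, records = rec
    ),
    class = "discordance_summary"
  )
}

lookup0 <- function(taxa, tbl) {
  v <- tbl$value[match(taxa, tbl$taxon)]
  dplyr::coalesce(v, 0)
}

#' @export
print.discordance_summary <- function(x, ...) {
  cat(sprintf(
    "relative vs absolute trend agreement%s%s\n  %d taxa: %d concordant, %d discordant, %d unchanged (eps = %s)\n",
    if (is.na(x$treatment)) "" else paste0(" [", x$treatment, "]"),
    if (is.na(x$region)) "" else paste0(" (", x$region, ")"),
    x$n_taxa, x$n_concordant, x$n_discordant, x$n_unchanged, format(x$eps)
  ))
  invisible(x)
}

#' Hierarchically cluster samples of an abundance table
#'
#' Agglomerative clustering of samples for heatmap ordering: the table is
#' cast to a sample-by-taxon matrix, optionally log10(x+1)-transformed (the
#' usual choice for copies-per-gram values spanning orders of magnitude),
#' and clustered on Euclidean distances with complete linkage. Ties are
#' broken deterministically by input sample order.
#'
#' @param table A long abundance tibble (count, proportion or abundance
#'   column).
#' @param transform `"log10p1"` (default for absolute abundances) or
#'   `"none"`.
#' @param metric Distance metric passed to [stats::dist()].
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return An object of class `hclust`; leaf order in `$order`, merge
#'   heights in `$height`. Export with [write_dendrogram()].
#' @export
cluster_samples <- function(table, transform = c("log10p1", "none"),
                            metric = "euclidean", linkage = "complete") {
  transform <- arg_match(transform)
  value <- table_value_col(table)
  key <- if ("lineage" %in% names(table)) "lineage" else "taxon"
  wide <- tidyr::pivot_wider(
    table[c("sample", key, value)],
    names_from = all_of(key), values_from = all_of(value), values_fill = 0
  )
  m <- as.matrix(wide[-1L])
  rownames(m) <- wide$sample
  if (nrow(m) < 2L) abort("need at least 2 samples to cluster")
  if (transform == "log10p1") m <- log10(m + 1)
  hclust(dist(m, method = metric), method = linkage)
}

#' Write a sample dendrogram as newick
#'
#' @param hc An `hclust` object from [cluster_samples()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram <- function(hc, path) {
  stopifnot(inherits(hc, "hclust"))
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
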