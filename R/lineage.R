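#' Taxonomic rank names used throughout the package
#'
#' The fixed rank ladder, domain through genus, in aggregation order.
#' Lineage strings are parsed into these columns; [aggregate_by_rank()]
#' accepts any of them.
#'
#' @return Character vector of the six rank names.
#' @export
#' @examples
#' taxonomic_ranks()
taxonomic_ranks <- function() {
  c("domain", "phylum", "class", "order", "family", "genus")
}

#' Parse taxonomy lineage strings
#'
#' Splits SILVA/Greengenes-style lineage strings (segments separated by ";",
#' with optional "k__"/"p__"-style rank prefixes) into one column per rank,
#' domain through genus. Empty or missing segments are recorded as `NA`;
#' missing ranks are only permitted as a suffix of the lineage, so a taxon
#' classified to genus must carry every higher rank.
#'
#' @param lineage Character vector of lineage strings, e.g.
#'   `"Bacteria;Proteobacteria;Gammaproteobacteria"`.
#' @return A tibble with columns `lineage` (the input, verbatim), one column
#'   per rank in [taxonomic_ranks()], and `taxon`, the most specific
#'   classified name (used as the display label).
#' @export
#' @examples
#' parse_lineage("d__Bacteria;p__Firmicutes;c__Bacilli")
parse_lineage <- function(lineage) {
  ranks <- taxonomic_ranks()
  parts <- stringr::str_split(lineage, ";")
  seg <- purrr::map(parts, function(p) {
    p <- stringr::str_trim(p)
    p <- stringr::str_remove(p, "^[a-zA-Z]__")
    p[p == "" | tolower(p) %in% c("unclassified", "unknown", "na")] <- NA_character_
    length(p) <- length(ranks)
    p
  })
  mat <- do.call(rbind, seg)
  colnames(mat) <- ranks
  out <- as_tibble(mat)
  # classified names must form a prefix: a named genus under an unnamed family
  # breaks the rank ladder
  bad <- apply(!is.na(mat), 1L, function(x) {
    any(diff(which(c(TRUE, x))) > 1L)
  })
  if (any(bad)) {
    abort(sprintf(
      "lineage %d ('%s') has a missing rank followed by a named one; missing ranks are only allowed as a suffix",
      which(bad)[1L], lineage[which(bad)[1L]]
    ))
  }
  deepest <- apply(mat, 1L, function(x) {
    x <- x[!is.na(x)]
    if (length(x)) x[[length(x)]] else "Unclassified"
  })
  dplyr::bind_cols(tibble(lineage = as.character(lineage)), out, tibble(taxon = deepest))
}

format_lineage <- function(tbl, upto = "genus") {
  ranks <- taxonomic_ranks()
  ranks <- ranks[seq_len(match(upto, ranks))]
  apply(as.matrix(tbl[ranks]), 1L, function(x) {
    if (!any(!is.na(x))) return("Unclassified")
    paste(x[seq_len(max(which(!is.na(x))))], collapse = ";")
  })
}
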