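#' Read a per-sample taxon count table
#'
#' Reads a feature (OTU/ASV) count table from a tab-separated file or a BIOM
#' v1 (JSON) file into a long tibble of integer read counts with the taxonomy
#' lineage parsed into rank columns.
#'
#' The TSV dialect is the common QIIME-style export: the first column holds
#' the taxonomy lineage string (its header may be `#OTU ID`, `taxonomy`, or
#' anything else), the remaining column headers are sample identifiers, and
#' cells are non-negative integer read counts. BIOM input must be version 1
#' (JSON) with an observation-by-sample matrix; per-observation `taxonomy`
#' metadata is used as the lineage when present, the observation id otherwise.
#'
#' @param path Path to the table file.
#' @param format `"tsv"` or `"biom"`. Defaults to a guess from the file
#'   extension.
#' @return A tibble with one row per (sample, taxon): columns `sample`,
#'   `lineage` (verbatim string), the six rank columns of
#'   [taxonomic_ranks()], `taxon` (display name) and integer `count`.
#'   Sample order and taxon order follow the file.
#' @seealso [write_feature_table()], [to_relative()]
#' @export
read_feature_table <- function(path, format = c("auto", "tsv", "biom")) {
  format <- arg_match(format)
  if (format == "auto") {
    format <- if (grepl("\\.biom$", path, ignore.case = TRUE)) "biom" else "tsv"
  }
  if (!file.exists(path)) abort(sprintf("no such file: '%s'", path))
  if (format == "tsv") read_feature_tsv(path) else read_feature_biom(path)
}

read_feature_tsv <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^# ", lines)] # comment lines, but keep '#OTU ID' header
  if (!length(lines)) abort(sprintf("'%s': empty table", path))
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 2L) {
    abort(sprintf("'%s' line 1: header needs a lineage column plus at least one sample", path))
  }
  samples <- header[-1L]
  if (anyDuplicated(samples)) abort(sprintf("'%s' line 1: duplicated sample id", path))
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  nfield <- lengths(rows)
  if (any(nfield != length(header))) {
    abort(sprintf(
      "'%s' line %d: %d fields, expected %d",
      path, which(nfield != length(header))[1L] + 1L,
      nfield[which(nfield != length(header))[1L]], length(header)
    ))
  }
  lineage <- purrr::map_chr(rows, 1L)
  counts <- matrix(
    suppressWarnings(as.numeric(unlist(purrr::map(rows, ~ .x[-1L])))),
    nrow = length(rows), byrow = TRUE
  )
  build_feature_table(lineage, samples, counts, path)
}

read_feature_biom <- function(path) {
  check_installed("biomformat", reason = "to read BIOM files")
  b <- biomformat::read_biom(path)
  counts <- t(as.matrix(biomformat::biom_data(b))) # sample x observation -> transpose below
  obs_ids <- colnames(counts)
  md <- tryCatch(biomformat::observation_metadata(b), error = function(e) NULL)
  lineage <- obs_ids
  if (!is.null(md) && length(md)) {
    tax <- if (is.data.frame(md)) {
      apply(md, 1L, function(x) paste(x[!is.na(x) & x != ""], collapse = ";"))
    } else {
      purrr::map_chr(md, function(x) paste(unlist(x), collapse = ";"))
    }
    if (length(tax) == length(obs_ids) && any(nzchar(tax))) lineage <- unname(tax)
  }
  build_feature_table(lineage, rownames(counts), t(counts), path)
}

build_feature_table <- function(lineage, samples, counts, path = "<matrix>") {
  if (anyNA(counts)) abort(sprintf("'%s': non-numeric count", path))
  if (any(counts < 0)) abort(sprintf("'%s': negative count", path))
  if (any(counts != round(counts))) abort(sprintf("'%s': non-integer count", path))
  if (anyDuplicated(lineage)) abort(sprintf("'%s': duplicated taxon lineage", path))
  tax <- parse_lineage(lineage)
  idx <- tidyr::expand_grid(.s = seq_along(samples), .t = seq_along(lineage))
  out <- dplyr::bind_cols(tibble(sample = samples[idx$.s]), tax[idx$.t, ])
  out$count <- as.integer(counts[cbind(idx$.t, idx$.s)])
  as_tibble(out)
}

#' Write a feature table to TSV
#'
#' Writes the wide, QIIME-style counterpart of [read_feature_table()]:
#' first column `#OTU ID` with the verbatim lineage string, one column per
#' sample, integer counts. A read-back with [read_feature_table()] reproduces
#' the counts exactly.
#'
#' @param table A long feature-table tibble (see [read_feature_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  check_count_table(table)
  wide <- tidyr::pivot_wider(
    table[c("sample", "lineage", "count")],
    names_from = "sample", values_from = "count", values_fill = 0L
  )
  names(wide)[1L] <- "#OTU ID"
  readr::write_tsv(wide, path, escape = "none")
  invisible(path)
}

#' Convert read counts to relative abundances
#'
#' Divides each taxon's read count by its sample's total, giving the
#' per-sample proportions that the absolute-quantification step multiplies by
#' the qPCR total bacterial quantity.
#'
#' @param table A long feature-table tibble with a `count` column.
#' @return The same tibble with `count` replaced by `proportion`; proportions
#'   within a sample sum to 1.
#' @export
#' @examples
#' ft <- tibble::tibble(
#'   sample = "s1", lineage = c("a", "b", "c"),
#'   taxon = c("a", "b", "c"), count = c(2L, 3L, 5L)
#' )
#' to_relative(ft)$proportion
to_relative <- function(table) {
  check_count_table(table)
  totals <- table %>%
    group_by(.data$sample) %>%
    summarise(.total = sum(.data$count), .groups = "drop")
  zero <- totals$sample[totals$.total <= 0]
  if (length(zero)) {
    abort(sprintf("sample '%s' has zero total reads; cannot form proportions", zero[1L]))
  }
  table %>%
    left_join(totals, by = "sample") %>%
    mutate(proportion = .data$count / .data$.total) %>%
    select(-"count", -".total")
}

#' Aggregate a table at a taxonomic rank
#'
#' Sums counts or proportions over all taxa sharing the same classification
#' down to `rank`. Grouping uses the full rank path (domain through `rank`),
#' so two genera with the same name in different families stay distinct.
#' Taxa unclassified at `rank` are grouped per their deepest classified
#' prefix under the label `"Unclassified"`.
#'
#' @param table A long feature or relative-abundance tibble.
#' @param rank One of [taxonomic_ranks()].
#' @return A tibble of the same kind with one row per (sample, rank-level
#'   taxon); rank columns below `rank` are dropped.
#' @export
aggregate_by_rank <- function(table, rank) {
  ranks <- taxonomic_ranks()
  if (!is.character(rank) || length(rank) != 1L || !rank %in% ranks) {
    abort(sprintf("unknown rank '%s'; expected one of %s",
                  paste(rank, collapse = ","), paste(ranks, collapse = ", ")))
  }
  value <- table_value_col(table)
  keep <- ranks[seq_len(match(rank, ranks))]
  out <- table %>%
    mutate(.label = dplyr::if_else(is.na(.data[[rank]]), "Unclassified",
                                   .data[[rank]])) %>%
    group_by(.data$sample, across(all_of(keep)), .label = .data$.label) %>%
    summarise(across(all_of(value), sum), .groups = "drop")
  out$taxon <- out$.label
  out$lineage <- format_lineage(out, upto = rank)
  out %>%
    select("sample", "lineage", all_of(keep), "taxon", all_of(value)) %>%
    arrange(.data$sample, .data$lineage)
}

#' Pool rare taxa into a "Minor" category
#'
#' Taxa whose relative abundance is strictly below `threshold` in every
#' sample of the table are summed into a single taxon labelled `"Minor"`,
#' the convention used for community composition displays (default 0.1%).
#' A taxon above the threshold in any one sample is kept everywhere, so it
#' is never split between its own label and Minor across samples.
#'
#' @param table A relative-abundance tibble (`proportion` column).
#' @param threshold Pooling threshold as a fraction, in (0, 1). Comparison is
#'   strict (`<`); a taxon sitting exactly at the threshold is retained.
#' @return The table with pooled taxa replaced by one `"Minor"` row per
#'   sample. Per-sample sums are unchanged.
#' @export
pool_minor <- function(table, threshold = 0.001) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1) {
    abort("`threshold` must be a single fraction in (0, 1)")
  }
  if (!"proportion" %in% names(table)) {
    abort("`table` must be a relative-abundance table (column `proportion`); see to_relative()")
  }
  peak <- table %>%
    group_by(.data$lineage) %>%
    summarise(.peak = max(.data$proportion), .groups = "drop")
  minor <- peak$lineage[peak$.peak < threshold]
  if (!length(minor)) return(table)
  kept <- filter(table, !.data$lineage %in% minor)
  pooled <- table %>%
    filter(.data$lineage %in% minor) %>%
    group_by(.data$sample) %>%
    summarise(proportion = sum(.data$proportion), .groups = "drop") %>%
    mutate(lineage = "Minor", taxon = "Minor")
  for (r in intersect(taxonomic_ranks(), names(table))) pooled[[r]] <- NA_character_
  bind_rows(kept, pooled)[names(kept)]
}

check_count_table <- function(table) {
  if (!is.data.frame(table)) abort("`table` must be a data frame")
  need <- c("sample", "lineage", "count")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    abort(sprintf("`table` is missing column(s): %s", paste(miss, collapse = ", ")))
  }
  if (any(table$count < 0)) abort("counts must be non-negative")
  if (any(table$count != round(table$count))) abort("counts must be integers")
  invisible(table)
}

table_value_col <- function(table) {
  if ("count" %in% names(table)) return("count")
  if ("proportion" %in% names(table)) return("proportion")
  if ("abundance" %in% names(table)) return("abundance")
  abort("`table` must have a `count`, `proportion` or `abundance` column")
}
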