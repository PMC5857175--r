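#' Integrate relative abundances with qPCR totals into absolute abundances
#'
#' The core absolute-quantification step: each taxon's absolute abundance is
#' its sequencing relative abundance multiplied by the sample's total 16S
#' rRNA gene quantity from qPCR, `A_i = p_i * T`, in copies per gram dry
#' soil. Totals measured on different 16S variable regions (V3, V4) are kept
#' separate; pass one region per call.
#'
#' @param rel A relative-abundance tibble from [to_relative()] (or an
#'   aggregated/pooled version of one).
#' @param totals Data frame of total bacterial quantities with columns
#'   `sample`, `total_copies` and optionally `region` and `sd`. When a sample
#'   has replicate totals (e.g. triplicate qPCR extractions pooled for
#'   sequencing), they are averaged.
#' @param region Which region's totals to use when `totals` has a `region`
#'   column (e.g. `"V4"`).
#' @return The `rel` tibble with an added `abundance` column (copies per g
#'   dry soil) and, when selected, a `region` column. Per-sample abundances
#'   sum to the sample's total.
#' @export
integrate_abundance <- function(rel, totals, region = NULL) {
  if (!"proportion" %in% names(rel)) {
    abort("`rel` must be a relative-abundance table (column `proportion`)")
  }
  if (!is.data.frame(totals) || !all(c("sample", "total_copies") %in% names(totals))) {
    abort("`totals` needs columns `sample` and `total_copies`")
  }
  if (!is.null(region)) {
    if (!"region" %in% names(totals)) abort("`totals` has no `region` column")
    totals <- filter(totals, .data$region == !!region)
  }
  if (any(totals$total_copies <= 0)) abort("total copies must be positive")
  totals <- totals %>%
    group_by(.data$sample) %>%
    summarise(total_copies = mean(.data$total_copies), .groups = "drop")
  missing <- setdiff(unique(rel$sample), totals$sample)
  if (length(missing)) {
    abort(sprintf(
      "no total bacterial quantity for sample '%s'%s",
      missing[1L], if (is.null(region)) "" else sprintf(" (region %s)", region)
    ))
  }
  out <- rel %>%
    left_join(totals, by = "sample") %>%
    mutate(abundance = .data$proportion * .data$total_copies) %>%
    select(-"total_copies")
  if (!is.null(region)) out$region <- region
  out
}

#' Expected 16S-equivalent copies from a single-copy marker measurement
#'
#' Scales a marker-gene qPCR quantity by the strain's 16S-to-marker copy
#' ratio, giving the 16S copy number the spike-in strain is expected to
#' contribute. For a strain carrying 7 16S rRNA operons and a single-copy
#' marker, the ratio is 7.
#'
#' @param marker_quant Marker-gene copies per gram (vectorised).
#' @param ratio_16s_to_marker 16S copies per genome divided by marker copies
#'   per genome; must be positive.
#' @return `marker_quant * ratio_16s_to_marker`.
#' @export
#' @examples
#' expected_marker_copies(4.79e9, 7)
expected_marker_copies <- function(marker_quant, ratio_16s_to_marker) {
  if (!is.numeric(ratio_16s_to_marker) || any(ratio_16s_to_marker <= 0)) {
    abort("`ratio_16s_to_marker` must be positive")
  }
  marker_quant * ratio_16s_to_marker
}

#' Convert 16S copies to genome equivalents
#'
#' Divides each taxon's absolute abundance by its 16S rRNA gene copies per
#' genome, `G_i = A_i / c_i`, converting gene copies per gram into genome
#' (approximately cell) equivalents per gram. rRNA operon multiplicity
#' varies widely between bacteria (1 to ~15), so uncorrected 16S copy
#' numbers overstate multi-operon taxa.
#'
#' Only taxa present in `copy_numbers` are corrected; others use `default_c`
#' (1 by default, i.e. left as copies) with a warning, since community-wide
#' copy numbers are rarely known.
#'
#' @param abs_table An absolute-abundance tibble from
#'   [integrate_abundance()].
#' @param copy_numbers Data frame with columns `taxon` and
#'   `copies_per_genome` (integers >= 1).
#' @param default_c Copy number for unmatched taxa.
#' @return `abs_table` with `abundance` replaced by genome equivalents per
#'   gram and an added `copies_per_genome` column.
#' @export
to_genome_equivalents <- function(abs_table, copy_numbers, default_c = 1L) {
  if (!"abundance" %in% names(abs_table)) {
    abort("`abs_table` must have an `abundance` column; see integrate_abundance()")
  }
  if (!is.data.frame(copy_numbers) ||
      !all(c("taxon", "copies_per_genome") %in% names(copy_numbers))) {
    abort("`copy_numbers` needs columns `taxon` and `copies_per_genome`")
  }
  if (any(copy_numbers$copies_per_genome < 1)) {
    abort("16S copies per genome must be >= 1")
  }
  if (default_c <= 0) abort("`default_c` must be positive")
  out <- abs_table %>%
    left_join(copy_numbers[c("taxon", "copies_per_genome")], by = "taxon")
  unmatched <- unique(out$taxon[is.na(out$copies_per_genome)])
  if (length(unmatched)) {
    warn(sprintf(
      "%d taxa without a 16S copy number use the default of %s (first: '%s')",
      length(unmatched), format(default_c), unmatched[1L]
    ))
  }
  out %>%
    mutate(
      copies_per_genome = dplyr::coalesce(.data$copies_per_genome, as.numeric(default_c)),
      abundance = .data$abundance / .data$copies_per_genome
    )
}

#' Detection limit of the integrated quantification
#'
#' The smallest absolute abundance observable at a given sequencing depth:
#' with a minimum detectable read count `min_reads` (commonly the smallest
#' read count actually observed for an indigenous taxon) out of `depth`
#' reads, a taxon must exceed `L = (min_reads / depth) * T` copies per gram
#' to appear in the table at all. Deeper sequencing lowers the limit
#' proportionally.
#'
#' @param min_reads Minimum detectable read count (positive integer).
#' @param depth Reads per sample.
#' @param totals Data frame with columns `sample`, `total_copies` and
#'   optionally `region` (as for [integrate_abundance()]), or a single
#'   numeric total.
#' @return A tibble with columns `sample`, `region` (if given), `min_reads`,
#'   `depth` and `limit` (copies per g dry soil).
#' @export
#' @examples
#' detection_limit(5, 66460, 1e8)
detection_limit <- function(min_reads, depth, totals) {
  if (depth <= 0) abort("`depth` must be positive")
  if (min_reads <= 0 || min_reads > depth) {
    abort("`min_reads` must be in 1..depth")
  }
  if (is.numeric(totals)) {
    totals <- tibble(sample = NA_character_, total_copies = totals)
  }
  totals %>%
    mutate(
      min_reads = min_reads, depth = depth,
      limit = min_reads / depth * .data$total_copies
    ) %>%
    select(any_of(c("sample", "region")), "min_reads", "depth", "limit",
           "total_copies")
}
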