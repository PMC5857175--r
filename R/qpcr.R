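#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Ct on log10(template copies) over a dilution
#' series, the calibration line used to convert cycle-threshold values into
#' copy numbers. Amplification efficiency is derived from the slope as
#' `10^(-1/slope) - 1` (1.0 means perfect doubling each cycle); the
#' limit-of-quantification Ct (`loq_ct`) is the mean Ct of the most dilute
#' standard, the point beyond which a sample is treated as a non-detect.
#'
#' @param standards Data frame with columns `copies_per_ul` (positive
#'   template concentration) and `ct`; replicate rows per concentration are
#'   allowed. An optional `assay` column names the assay.
#' @param assay Assay label; defaults to the `assay` column if present.
#' @return A `standard_curve` object with elements `slope`, `intercept`,
#'   `r2`, `efficiency`, `loq_ct`, `range` (min/max copies) and `n`.
#'   Supports [tidy()], [glance()], `print()` and [ggplot2::autoplot()].
#' @export
#' @examples
#' std <- tibble::tibble(copies_per_ul = 10^(1:6),
#'                       ct = 37 - 3.3219 * (1:6))
#' fit_standard_curve(std)
fit_standard_curve <- function(standards, assay = NULL) {
  if (!is.data.frame(standards)) abort("`standards` must be a data frame")
  if (!all(c("copies_per_ul", "ct") %in% names(standards))) {
    abort("`standards` needs columns `copies_per_ul` and `ct`")
  }
  conc <- standards$copies_per_ul
  if (any(!is.finite(conc)) || any(conc <= 0)) {
    abort("standard concentrations must be positive")
  }
  if (length(unique(conc)) < 3L) {
    abort("need at least 3 distinct standard concentrations")
  }
  if (diff(log10(range(conc))) < 2) {
    abort("standard series must span at least 2 log10 units of concentration")
  }
  if (is.null(assay)) {
    assay <- if ("assay" %in% names(standards)) as.character(standards$assay[1L]) else NA_character_
  }
  fit <- lm(ct ~ log10(copies_per_ul), data = standards)
  slope <- unname(coef(fit)[2L])
  # centered R2 computed directly; summary.lm() warns on noise-free series
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((standards$ct - mean(standards$ct))^2)
  by_conc <- standards %>%
    group_by(.data$copies_per_ul) %>%
    summarise(ct = mean(.data$ct), .groups = "drop")
  structure(
    list(
      assay = assay,
      slope = slope,
      intercept = unname(coef(fit)[1L]),
      r2 = r2,
      efficiency = 10^(-1 / slope) - 1,
      loq_ct = by_conc$ct[which.min(by_conc$copies_per_ul)],
      range = range(conc),
      n = nrow(standards),
      standards = as_tibble(standards)
    ),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "qPCR standard curve%s\n  Ct = %.4f * log10(copies) + %.4f\n  R2 = %.4f, efficiency = %.1f%%, LoQ Ct = %.2f\n  range: %.3g to %.3g copies/uL (%d standards)\n",
    if (is.na(x$assay)) "" else paste0(" [", x$assay, "]"),
    x$slope, x$intercept, x$r2, 100 * x$efficiency, x$loq_ct,
    x$range[1L], x$range[2L], x$n
  ))
  invisible(x)
}

#' Convert Ct values to template copy numbers
#'
#' Inverts the standard curve: `copies = 10^((ct - intercept) / slope)`.
#' No quality flags are applied here; see [qc_quantify()].
#'
#' @param ct Numeric vector of cycle-threshold values.
#' @param curve A [fit_standard_curve()] result.
#' @return Copies per microlitre of template, same length as `ct`.
#' @export
ct_to_copies <- function(ct, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  10^((ct - curve$intercept) / curve$slope)
}

#' Quantify samples from replicate Ct values with quality control
#'
#' Summarises replicate Ct values per sample, interpolates the mean Ct on the
#' standard curve, and applies the three quality-control rules used for
#' spike-in detection calls:
#'
#' * `high_replicate_sd` — replicate Ct standard deviation above `sd_limit`
#'   (default 0.5 cycles);
#' * `below_loq` — mean Ct strictly greater than the most dilute standard's
#'   Ct, i.e. the target is not reliably detected (the rule that classifies
#'   an unspiked control as negative for a marker gene);
#' * `out_of_range` — implied concentration outside the standard series.
#'
#' Quantification uses the mean Ct (not the mean of per-replicate copies),
#' the conventional reading of the delta-Ct interpolation method. A single
#' replicate has its SD treated as 0.
#'
#' @param cts Data frame with columns `sample`, `ct` and optionally `assay`
#'   and `replicate`; one row per replicate reaction.
#' @param curve A [fit_standard_curve()] result.
#' @param sd_limit Maximum acceptable replicate Ct standard deviation.
#' @return A tibble with one row per sample (and assay, if given): `mean_ct`,
#'   `sd_ct`, `n_replicates`, `copies_per_rxn`, and logical flag columns
#'   `high_replicate_sd`, `below_loq`, `out_of_range`.
#' @export
qc_quantify <- function(cts, curve, sd_limit = 0.5) {
  stopifnot(inherits(curve, "standard_curve"))
  if (!is.data.frame(cts) || !all(c("sample", "ct") %in% names(cts))) {
    abort("`cts` needs columns `sample` and `ct`")
  }
  if (!nrow(cts)) abort("`cts` has no replicate measurements")
  keys <- intersect(c("sample", "assay"), names(cts))
  out <- cts %>%
    group_by(across(all_of(keys))) %>%
    summarise(
      mean_ct = mean(.data$ct),
      sd_ct = dplyr::if_else(dplyr::n() > 1L, sd(.data$ct), 0),
      n_replicates = dplyr::n(),
      .groups = "drop"
    ) %>%
    mutate(
      copies_per_rxn = ct_to_copies(.data$mean_ct, curve),
      high_replicate_sd = .data$sd_ct > sd_limit,
      below_loq = .data$mean_ct > curve$loq_ct,
      out_of_range = .data$copies_per_rxn < curve$range[1L] |
        .data$copies_per_rxn > curve$range[2L]
    )
  out
}

#' Scale a per-reaction concentration to copies per gram of soil
#'
#' Converts the copies-per-microlitre template concentration from
#' [qc_quantify()] into copies per gram of dry soil, given the DNA extraction
#' geometry: `copies_per_g = copies_per_rxn / template_volume *
#' elution_volume / soil_mass`.
#'
#' @param copies_per_rxn Copies per microlitre of template in the reaction.
#' @param template_volume Microlitres of template per reaction (default 1).
#' @param elution_volume Microlitres of DNA eluate from the extraction.
#' @param soil_mass Grams (dry weight) of soil extracted.
#' @return Copies per gram dry soil.
#' @export
#' @examples
#' copies_per_gram(100, elution_volume = 100, soil_mass = 0.2)
copies_per_gram <- function(copies_per_rxn, template_volume = 1,
                            elution_volume, soil_mass) {
  if (any(template_volume <= 0) || any(elution_volume <= 0) || any(soil_mass <= 0)) {
    abort("volumes and soil mass must be positive")
  }
  if (any(copies_per_rxn < 0, na.rm = TRUE)) abort("`copies_per_rxn` must be non-negative")
  copies_per_rxn / template_volume * elution_volume / soil_mass
}
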