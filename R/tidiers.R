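#' Tidy a qPCR standard curve
#'
#' @param x A [fit_standard_curve()] result.
#' @param ... Unused.
#' @return One row per coefficient (`term`, `estimate`).
#' @method tidy standard_curve
#' @export
tidy.standard_curve <- function(x, ...) {
  tibble(term = c("intercept", "slope"), estimate = c(x$intercept, x$slope))
}

#' @rdname tidy.standard_curve
#' @return For `glance()`: a one-row tibble with `r2`, `efficiency`,
#'   `loq_ct`, `range_min`, `range_max`, `n`.
#' @method glance standard_curve
#' @export
glance.standard_curve <- function(x, ...) {
  tibble(
    r2 = x$r2, efficiency = x$efficiency, loq_ct = x$loq_ct,
    range_min = x$range[1L], range_max = x$range[2L], n = x$n
  )
}

#' Tidy a validation regression
#'
#' @param x A [fit_validation_regression()] result.
#' @param ... Unused.
#' @return One row per coefficient for `tidy()`; a one-row fit summary
#'   (`slope`, `intercept`, `r2_centered`, `r2_uncentered`, `n`,
#'   `through_origin`) for `glance()`.
#' @method tidy validation_fit
#' @export
tidy.validation_fit <- function(x, ...) {
  if (x$through_origin) {
    tibble(term = "slope", estimate = x$slope)
  } else {
    tibble(term = c("intercept", "slope"), estimate = c(x$intercept, x$slope))
  }
}

#' @rdname tidy.validation_fit
#' @method glance validation_fit
#' @export
glance.validation_fit <- function(x, ...) {
  tibble(
    slope = x$slope, intercept = x$intercept,
    r2_centered = x$r2_centered, r2_uncentered = x$r2_uncentered,
    n = x$n, through_origin = x$through_origin
  )
}

#' Tidy a spike-in validation report
#'
#' @param x A [validate_spikein()] result.
#' @param ... Unused.
#' @return `tidy()`: one row per fitted regression; `glance()`: a one-row
#'   verdict summary.
#' @method tidy spike_validation
#' @export
tidy.spike_validation <- function(x, ...) {
  select(x$fits, -"result")
}

#' @rdname tidy.spike_validation
#' @method glance spike_validation
#' @export
glance.spike_validation <- function(x, ...) {
  cal <- filter(x$fits, .data$fit == "marker_vs_nominal")
  tibble(
    pass = x$pass, copy_ratio = x$copy_ratio,
    min_calibration_r2 = min(cal$r2_centered),
    slope_low = min(cal$slope), slope_high = max(cal$slope),
    n_fits = nrow(x$fits)
  )
}

#' Tidy a method-comparison ANOVA
#'
#' @param x A [compare_methods_anova()] result.
#' @param ... Unused.
#' @return `tidy()`: the pairwise comparisons; `glance()`: Levene p-value,
#'   post hoc method and group count.
#' @method tidy method_comparison
#' @export
tidy.method_comparison <- function(x, ...) {
  x$pairwise
}

#' @rdname tidy.method_comparison
#' @method glance method_comparison
#' @export
glance.method_comparison <- function(x, ...) {
  tibble(levene_p = x$levene_p, method = x$method, alpha = x$alpha,
         n_groups = nrow(x$letters))
}

#' Tidy a discordance summary
#'
#' @param x A [count_discordant()] result.
#' @param ... Unused.
#' @return `tidy()`: the per-taxon change records; `glance()`: the counts.
#' @method tidy discordance_summary
#' @export
tidy.discordance_summary <- function(x, ...) {
  x$records
}

#' @rdname tidy.discordance_summary
#' @method glance discordance_summary
#' @export
glance.discordance_summary <- function(x, ...) {
  tibble(
    treatment = x$treatment, region = x$region, n_taxa = x$n_taxa,
    n_concordant = x$n_concordant, n_discordant = x$n_discordant,
    n_unchanged = x$n_unchanged, eps = x$eps
  )
}
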