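#' Base-10 logarithm with input validation
#'
#' Quantities spanning several orders of magnitude (copies per gram across a
#' 10-fold spike dilution series) are log10-transformed before linear
#' regression. Non-positive values have no logarithm and indicate an
#' upstream problem, so they raise an error naming the offending position.
#'
#' @param values Numeric vector of positive values.
#' @return `log10(values)`.
#' @export
#' @examples
#' log10_transform(c(1e6, 1))
log10_transform <- function(values) {
  bad <- which(!is.finite(values) | values <= 0)
  if (length(bad)) {
    abort(sprintf("value at position %d (%s) is not positive; cannot log10-transform",
                  bad[1L], format(values[bad[1L]])))
  }
  log10(values)
}

#' Linear regression for spike-in validation
#'
#' Ordinary least squares of `y` on `x`, optionally constrained through the
#' origin (the convention for log-log agreement plots between two
#' quantification methods, where a slope of 1 and intercept 0 mean perfect
#' agreement). Both R-squared conventions are reported, because they differ
#' for through-origin fits: `r2_centered` compares residuals to the
#' variance around the mean, `r2_uncentered` to the raw sum of squares.
#'
#' @param x,y Numeric vectors of equal length (typically log10 quantities).
#' @param through_origin Fix the intercept at 0?
#' @param subset Optional logical or integer index of points to use; the
#'   remaining points are ignored (e.g. dropping a treatment at the
#'   detection limit).
#' @param labels Optional point labels carried into the result.
#' @return A `validation_fit` object with `slope`, `intercept`,
#'   `r2_centered`, `r2_uncentered`, `n`, `through_origin`, `subset` (labels
#'   of the points used) and the data. Supports [tidy()], [glance()] and
#'   [ggplot2::autoplot()].
#' @export
#' @examples
#' fit_validation_regression(1:5, 2 * (1:5), through_origin = TRUE)
fit_validation_regression <- function(x, y, through_origin = FALSE,
                                      subset = NULL, labels = NULL) {
  if (length(x) != length(y)) abort("`x` and `y` must have the same length")
  if (is.null(labels)) labels <- as.character(seq_along(x))
  if (!is.null(subset)) {
    x <- x[subset]; y <- y[subset]; labels <- labels[subset]
  }
  n <- length(x)
  if (n < if (through_origin) 1L else 2L) {
    abort("too few points for regression")
  }
  if (!through_origin && length(unique(x)) == 1L) {
    abort("all x values identical; slope is undefined")
  }
  if (through_origin) {
    slope <- sum(x * y) / sum(x^2)
    intercept <- 0
  } else {
    b <- coef(lm(y ~ x))
    intercept <- unname(b[1L]); slope <- unname(b[2L])
  }
  res <- y - (intercept + slope * x)
  ss_res <- sum(res^2)
  ss_cen <- sum((y - mean(y))^2)
  ss_unc <- sum(y^2)
  structure(
    list(
      slope = slope, intercept = intercept,
      r2_centered = if (ss_cen > 0) 1 - ss_res / ss_cen else NA_real_,
      r2_uncentered = if (ss_unc > 0) 1 - ss_res / ss_unc else NA_real_,
      n = n, through_origin = through_origin, subset = labels,
      data = tibble(label = labels, x = x, y = y)
    ),
    class = "validation_fit"
  )
}

#' @export
print.validation_fit <- function(x, ...) {
  cat(sprintf(
    "validation regression (%s, n = %d)\n  y = %.4f x %s %.4f\n  R2 centered = %.4f, uncentered = %.4f\n",
    if (x$through_origin) "through origin" else "with intercept", x$n,
    x$slope, ifelse(x$intercept < 0, "-", "+"), abs(x$intercept),
    x$r2_centered, x$r2_uncentered
  ))
  invisible(x)
}

#' Validate absolute quantification against a spike-in reference strain
#'
#' Runs the full internal-reference validation for a spike-in experiment in
#' which a strain of known addition carries a single-copy (or known-copy)
#' marker gene. Three regressions are produced per 16S region, all on
#' log10-transformed copies per gram:
#'
#' 1. expected 16S-equivalent copies (marker qPCR × copy ratio) against the
#'    sequencing-derived estimate, through the origin, using all treatments;
#' 2. the same fit excluding the lowest addition (the treatment nearest the
#'    sequencing detection limit, where classification carry-over inflates
#'    the estimate);
#' 3. marker qPCR copies against the nominal addition, with intercept — the
#'    calibration check that the marker assay tracks what was added.
#'
#' The verdict passes when fit 3 has slope within `slope_range` and centered
#' R-squared at least `r2_min`.
#'
#' @param spike Data frame with one row per treatment and region: columns
#'   `treatment`, `nominal_added` (copies or CFU per g), `marker_quant`
#'   (marker copies per g), `ihaaq` (sequencing-derived copies per g) and
#'   optionally `region`.
#' @param copy_ratio 16S copies per genome divided by marker copies per
#'   genome for the spike strain.
#' @param slope_range,r2_min Pass thresholds for the verdict.
#' @return A `spike_validation` object: tibble `fits` (one row per
#'   regression: `region`, `fit`, `subset`, `slope`, `intercept`,
#'   `r2_centered`, `r2_uncentered`, `n`), logical `pass`, and the inputs.
#' @export
validate_spikein <- function(spike, copy_ratio, slope_range = c(0.9, 1.1),
                             r2_min = 0.99) {
  need <- c("treatment", "nominal_added", "marker_quant", "ihaaq")
  if (!is.data.frame(spike) || !all(need %in% names(spike))) {
    abort(sprintf("`spike` needs columns %s", paste(need, collapse = ", ")))
  }
  if (anyNA(spike[need])) abort("`spike` has missing treatment entries")
  if (!"region" %in% names(spike)) spike$region <- NA_character_
  fit_region <- function(d) {
    if (nrow(d) < 3L) abort("need at least 3 treatments per region")
    expected <- log10_transform(expected_marker_copies(d$marker_quant, copy_ratio))
    est <- log10_transform(d$ihaaq)
    nominal <- log10_transform(d$nominal_added)
    marker <- log10_transform(d$marker_quant)
    lowest <- which.min(d$nominal_added)
    f_all <- fit_validation_regression(est, expected, through_origin = TRUE,
                                       labels = d$treatment)
    f_trim <- fit_validation_regression(est, expected, through_origin = TRUE,
                                        subset = seq_len(nrow(d))[-lowest],
                                        labels = d$treatment)
    f_cal <- fit_validation_regression(nominal, marker, labels = d$treatment)
    tibble(
      fit = c("expected_vs_estimate", "expected_vs_estimate", "marker_vs_nominal"),
      subset = c("all", "drop_lowest", "all"),
      result = list(f_all, f_trim, f_cal)
    )
  }
  fits <- spike %>%
    group_by(.data$region) %>%
    dplyr::group_modify(~ fit_region(.x)) %>%
    ungroup()
  fits <- fits %>%
    mutate(
      slope = purrr::map_dbl(.data$result, "slope"),
      intercept = purrr::map_dbl(.data$result, "intercept"),
      r2_centered = purrr::map_dbl(.data$result, "r2_centered"),
      r2_uncentered = purrr::map_dbl(.data$result, "r2_uncentered"),
      n = purrr::map_int(.data$result, "n")
    )
  cal <- filter(fits, .data$fit == "marker_vs_nominal")
  pass <- all(cal$slope >= slope_range[1L] & cal$slope <= slope_range[2L] &
                cal$r2_centered >= r2_min)
  structure(
    list(fits = fits, pass = pass, copy_ratio = copy_ratio,
         slope_range = slope_range, r2_min = r2_min, spike = as_tibble(spike)),
    class = "spike_validation"
  )
}

#' @export
print.spike_validation <- function(x, ...) {
  cat(sprintf("spike-in validation (copy ratio %s): %s\n",
              format(x$copy_ratio), if (x$pass) "PASS" else "FAIL"))
  print(select(x$fits, -"result"), ...)
  invisible(x)
}

#' Spike-in validation measurements for E. coli O157:H7 strain EDL933
#'
#' The bundled validation dataset for a soil spike-in experiment: strain
#' EDL933 (7 16S rRNA operons, single-copy *fliC* marker) added to 30 g soil
#' at six levels, 7.0e9 down to 7.0e4 copies per gram (1 mL of 2.1e11 to
#' 2.1e6 CFU/mL suspensions; one CFU counted as one genome). Columns:
#' `treatment` (E9..E4), `nominal_added` (genomes per g dry soil),
#' `marker_quant` and `marker_sd` (*fliC* copies per g by qPCR),
#' `ihaaq` and `ihaaq_sd` (the strain's genus-level absolute abundance from
#' relative abundance × total 16S copies), and `region` (the 16S variable
#' region, V3 or V4, used for both the total qPCR and sequencing).
#'
#' @return A tibble with 12 rows (6 treatments × 2 regions).
#' @export
#' @examples
#' validate_spikein(edl933_spikein(), copy_ratio = 7)
edl933_spikein <- function() {
  path <- system.file("extdata", "edl933_spikein.csv", package = "absquant",
                      mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, comment = "#")
}
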