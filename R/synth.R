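#' Configuration for a synthetic spike-in experiment
#'
#' Describes a simulated soil spike-in study with known ground truth: a
#' fixed background community, lognormal total bacterial loads, a reference
#' strain added at a gradient of levels, multinomial amplicon sequencing,
#' and qPCR with Gaussian Ct noise. Defaults mirror a realistic soil
#' experiment: 66,460 reads per sample; background total 16S load with
#' median 5.82e9 copies/g and ~6% coefficient of variation; spike levels
#' 7e9 down to 7e4 genomes/g for a strain with 7 16S operons and a
#' single-copy marker gene; replicate Ct noise of 0.05 cycles; a standard
#' curve at 100% amplification efficiency (slope -3.3219).
#'
#' @param n_taxa Number of background taxa.
#' @param base_proportions Explicit background proportions (summing to 1),
#'   or `NULL` to draw them once from a symmetric Dirichlet.
#' @param dirichlet_alpha Concentration for the Dirichlet draw; values below
#'   1 give the long-tailed, few-dominants shape typical of soil.
#' @param total_median,total_log10_sd Lognormal background total 16S load
#'   (copies/g): median and SD on the log10 scale.
#' @param spike_levels Spike additions, genomes per g dry soil (one sample
#'   per level; a level of 0 is an unspiked control).
#' @param spike_16s_copies,spike_marker_copies 16S and marker-gene copies
#'   per genome of the spike strain.
#' @param depth Sequencing reads per sample.
#' @param ct_noise_sd Gaussian SD added to every simulated Ct.
#' @param n_ct_replicates qPCR replicates per measurement.
#' @param curve_slope,curve_intercept Generating standard-curve parameters.
#' @param elution_volume,soil_mass,template_volume DNA extraction geometry
#'   (µL eluate, g soil, µL template per reaction) linking copies/g to
#'   copies/reaction.
#' @return A `synth_config` list, validated.
#' @seealso [synth_experiment()], [recovery_report()]
#' @export
synth_config <- function(n_taxa = 50L,
                         base_proportions = NULL,
                         dirichlet_alpha = 0.5,
                         total_median = 5.82e9,
                         total_log10_sd = 0.0246,
                         spike_levels = 7 * 10^(9:4),
                         spike_16s_copies = 7L,
                         spike_marker_copies = 1L,
                         depth = 66460L,
                         ct_noise_sd = 0.05,
                         n_ct_replicates = 3L,
                         curve_slope = -log10(2)^-1,
                         curve_intercept = 37,
                         elution_volume = 100,
                         soil_mass = 0.21,
                         template_volume = 1) {
  cfg <- list(
    n_taxa = as.integer(n_taxa), base_proportions = base_proportions,
    dirichlet_alpha = dirichlet_alpha, total_median = total_median,
    total_log10_sd = total_log10_sd, spike_levels = spike_levels,
    spike_16s_copies = spike_16s_copies,
    spike_marker_copies = spike_marker_copies,
    depth = as.integer(depth), ct_noise_sd = ct_noise_sd,
    n_ct_replicates = as.integer(n_ct_replicates),
    curve_slope = curve_slope, curve_intercept = curve_intercept,
    elution_volume = elution_volume, soil_mass = soil_mass,
    template_volume = template_volume
  )
  if (cfg$n_taxa < 1L) abort("`n_taxa` must be at least 1")
  if (!is.null(cfg$base_proportions)) {
    p <- cfg$base_proportions
    if (length(p) != cfg$n_taxa || any(p < 0) ||
        abs(sum(p) - 1) > 1e-8) {
      abort("`base_proportions` must be `n_taxa` non-negative values summing to 1")
    }
  }
  if (cfg$dirichlet_alpha <= 0) abort("`dirichlet_alpha` must be positive")
  if (cfg$total_median <= 0 || cfg$total_log10_sd < 0) {
    abort("total load parameters must be positive")
  }
  if (any(cfg$spike_levels < 0)) abort("`spike_levels` must be non-negative")
  if (cfg$spike_16s_copies < 1 || cfg$spike_marker_copies < 1) {
    abort("copy numbers must be >= 1")
  }
  if (cfg$depth < 1L) abort("`depth` must be positive")
  if (cfg$ct_noise_sd < 0) abort("`ct_noise_sd` must be non-negative")
  if (cfg$curve_slope >= 0) abort("`curve_slope` must be negative")
  structure(cfg, class = "synth_config")
}

#' Simulate a spike-in experiment with known ground truth
#'
#' Generates, deterministically given `seed`, everything the analysis
#' pipeline consumes plus the truth it should recover:
#'
#' * a fixed background community (one Dirichlet draw shared by all
#'   samples, as for aliquots of one homogenised soil);
#' * per-sample background total loads, lognormal around the configured
#'   median; sample totals are background + spike 16S copies;
#' * the spike strain's true 16S contribution, `genomes × 16S copies per
#'   genome`, renormalised into the community proportions;
#' * read counts as one multinomial draw of `depth` reads per sample;
#' * qPCR standard series (10-fold, 3.6e1..3.6e9 copies/µL) and sample Ct
#'   values for the total-16S and marker assays, from the generating curve
#'   plus Gaussian noise.
#'
#' Sub-seeds for community, totals, sequencing and qPCR noise are derived
#' from `seed`, so e.g. changing `n_taxa` does not perturb the qPCR noise.
#'
#' @param config A [synth_config()].
#' @param seed Integer seed governing all randomness.
#' @return A `synth_experiment` list with elements `truth` (tibbles
#'   `proportions`, `totals`, `spike`), `observed` (`feature_table`,
#'   `standards`, `total_cts`, `marker_cts`), and `config`.
#' @export
synth_experiment <- function(config = synth_config(), seed = 1L) {
  stopifnot(inherits(config, "synth_config"))
  sub_seed <- function(k) (as.integer(seed) * 7L + k * 1009L) %% .Machine$integer.max

  # background community, drawn once
  withr::with_seed(sub_seed(1L), {
    p_bg <- config$base_proportions
    if (is.null(p_bg)) {
      gam <- rgamma(config$n_taxa, shape = config$dirichlet_alpha)
      while (sum(gam) == 0) gam <- rgamma(config$n_taxa, shape = config$dirichlet_alpha)
      p_bg <- gam / sum(gam)
    }
  })
  taxa <- c(sprintf("Bacteria;BgPhylum%02d;BgGenus%03d",
                    (seq_len(config$n_taxa) - 1L) %% 8L + 1L,
                    seq_len(config$n_taxa)),
            "Bacteria;Proteobacteria;SpikeStrain")

  samples <- if (length(config$spike_levels)) {
    sprintf("S%02d", seq_along(config$spike_levels))
  } else "S01"
  levels <- if (length(config$spike_levels)) config$spike_levels else 0

  withr::with_seed(sub_seed(2L), {
    t_bg <- config$total_median *
      10^rnorm(length(samples), 0, config$total_log10_sd)
  })
  spike_16s <- levels * config$spike_16s_copies
  spike_marker <- levels * config$spike_marker_copies
  totals <- t_bg + spike_16s
  p_true <- vapply(seq_along(samples), function(i) {
    c(p_bg * t_bg[i], spike_16s[i]) / totals[i]
  }, numeric(config$n_taxa + 1L))

  withr::with_seed(sub_seed(3L), {
    counts <- vapply(seq_along(samples), function(i) {
      drop(rmultinom(1L, config$depth, p_true[, i]))
    }, integer(config$n_taxa + 1L))
  })

  scale_g_to_rxn <- config$template_volume / config$elution_volume * config$soil_mass
  true_ct <- function(copies_per_g) {
    copies_rxn <- pmax(copies_per_g * scale_g_to_rxn, .Machine$double.xmin)
    config$curve_slope * log10(copies_rxn) + config$curve_intercept
  }
  std_conc <- 3.6 * 10^(1:9)
  withr::with_seed(sub_seed(4L), {
    noisy <- function(ct0, n) ct0 + rnorm(n, 0, config$ct_noise_sd)
    standards <- purrr::map_dfr(c("total_16s", "marker"), function(a) {
      tidyr::expand_grid(assay = a, copies_per_ul = std_conc,
                         replicate = seq_len(config$n_ct_replicates)) %>%
        mutate(ct = noisy(config$curve_slope * log10(.data$copies_per_ul) +
                            config$curve_intercept, dplyr::n()))
    })
    total_cts <- tidyr::expand_grid(sample = samples,
                                    replicate = seq_len(config$n_ct_replicates)) %>%
      mutate(assay = "total_16s",
             ct = noisy(true_ct(totals)[match(.data$sample, samples)], dplyr::n()))
    marker_cts <- tidyr::expand_grid(sample = samples,
                                     replicate = seq_len(config$n_ct_replicates)) %>%
      mutate(assay = "marker",
             ct = noisy(true_ct(spike_marker)[match(.data$sample, samples)], dplyr::n()))
  })

  ft <- build_feature_table(taxa, samples, counts)
  structure(
    list(
      truth = list(
        proportions = tibble(
          sample = rep(samples, each = config$n_taxa + 1L),
          lineage = rep(taxa, times = length(samples)),
          proportion = as.numeric(p_true)
        ),
        totals = tibble(sample = samples, background = t_bg,
                        total_copies = totals),
        spike = tibble(sample = samples, nominal_added = levels,
                       spike_16s_copies = spike_16s,
                       spike_marker_copies = spike_marker)
      ),
      observed = list(feature_table = ft, standards = standards,
                      total_cts = total_cts, marker_cts = marker_cts),
      config = config, seed = as.integer(seed)
    ),
    class = "synth_experiment"
  )
}

#' Run the full pipeline on a synthetic experiment and score recovery
#'
#' Exercises every stage on simulated data with known truth: fits standard
#' curves from the simulated dilution series, quantifies total and marker
#' copies per gram from the noisy Ct values, converts read counts to
#' relative abundances, integrates them into absolute abundances, and
#' compares the result to the generating truth. The spike strain's
#' estimates are additionally regressed (log-log, through origin) against
#' its true 16S contribution across samples.
#'
#' @param exp A [synth_experiment()].
#' @return A list: `taxon_errors` (per sample and taxon, estimated vs true
#'   absolute abundance and relative error), `total_errors`, `spike_fit`
#'   (a `validation_fit` of log10 estimate on log10 truth across spiked
#'   samples, or `NULL` when fewer than 2), `median_abs_rel_error`, and the
#'   intermediate objects.
#' @export
recovery_report <- function(exp) {
  stopifnot(inherits(exp, "synth_experiment"))
  cfg <- exp$config
  curve_total <- fit_standard_curve(
    filter(exp$observed$standards, .data$assay == "total_16s"))
  quant <- qc_quantify(exp$observed$total_cts, curve_total)
  totals <- quant %>%
    mutate(total_copies = copies_per_gram(
      .data$copies_per_rxn, template_volume = cfg$template_volume,
      elution_volume = cfg$elution_volume, soil_mass = cfg$soil_mass
    )) %>%
    select("sample", "total_copies")
  rel <- to_relative(exp$observed$feature_table)
  abs_tbl <- integrate_abundance(rel, totals)
  truth_abs <- exp$truth$proportions %>%
    left_join(exp$truth$totals[c("sample", "total_copies")], by = "sample") %>%
    mutate(true_abundance = .data$proportion * .data$total_copies) %>%
    select("sample", "lineage", "true_abundance")
  taxon_errors <- abs_tbl %>%
    select("sample", "lineage", "abundance") %>%
    left_join(truth_abs, by = c("sample", "lineage")) %>%
    mutate(rel_error = dplyr::if_else(
      .data$true_abundance > 0,
      (.data$abundance - .data$true_abundance) / .data$true_abundance,
      NA_real_
    ))
  total_errors <- totals %>%
    left_join(exp$truth$totals, by = "sample", suffix = c("_est", "_true")) %>%
    mutate(rel_error = .data$total_copies_est / .data$total_copies_true - 1)
  spike_est <- abs_tbl %>%
    filter(.data$taxon == "SpikeStrain") %>%
    left_join(exp$truth$spike, by = "sample") %>%
    filter(.data$spike_16s_copies > 0, .data$abundance > 0)
  spike_fit <- NULL
  if (nrow(spike_est) >= 2L) {
    spike_fit <- fit_validation_regression(
      log10_transform(spike_est$spike_16s_copies),
      log10_transform(spike_est$abundance),
      through_origin = TRUE, labels = spike_est$sample
    )
  }
  list(
    taxon_errors = taxon_errors,
    total_errors = total_errors,
    spike_fit = spike_fit,
    median_abs_rel_error = stats::median(abs(taxon_errors$rel_error), na.rm = TRUE),
    curve = curve_total, totals = totals, relative = rel, absolute = abs_tbl
  )
}
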