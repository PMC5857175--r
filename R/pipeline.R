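#' Run the full absolute-quantification workflow
#'
#' Ties the stages together in the order a spike-in study is analysed:
#' calibrate the qPCR assays, quantify total bacterial copies per gram,
#' convert the feature table to relative abundances, integrate the two into
#' per-taxon absolute abundances, and optionally validate against a
#' spike-in table and compare two time points. All numeric outputs are
#' written as plain text (TSV/JSON), plus a machine-readable run log
#' recording inputs, parameters, package version and seed.
#'
#' @param config A named list (or path to a YAML file) with elements:
#'   `feature_table` (path), `standards` (path; CSV with `assay`,
#'   `copies_per_ul`, `ct`), `total_cts` (path; CSV with `sample`, `assay`,
#'   `replicate`, `ct`), `total_assay` (assay name of the total-16S runs),
#'   `elution_volume`, `soil_mass`, `template_volume`, and optionally
#'   `region`, `rank`, `minor_threshold`, `sd_limit`, `spike` (path to a
#'   spike CSV with `treatment`, `nominal_added`, `marker_quant`, `ihaaq`
#'   and optionally `region`), `copy_ratio`, `before`/`after` (sample ids
#'   for a two-time-point discordance comparison), `eps`, `seed`.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with the in-memory results (`curve`, `totals`,
#'   `relative`, `absolute`, and when configured `validation`,
#'   `discordance`) and `files`, the paths written.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    check_installed("yaml", reason = "to read YAML pipeline configs")
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("`config` must be a list or a YAML file path")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  get <- function(key, default = NULL) {
    if (!is.null(config[[key]])) config[[key]] else default
  }
  need <- function(key) {
    v <- config[[key]]
    if (is.null(v)) abort(sprintf("stage 'config' failed: missing entry '%s'", key))
    v
  }
  files <- character()
  emit <- function(x, name) {
    path <- file.path(out_dir, name)
    readr::write_tsv(x, path)
    files <<- c(files, path)
  }

  curve <- stage("calibrate", {
    std <- readr::read_csv(need("standards"), show_col_types = FALSE)
    assay <- get("total_assay", "total_16s")
    fit_standard_curve(filter(std, .data$assay == !!assay))
  })
  totals <- stage("quantify_totals", {
    cts <- readr::read_csv(need("total_cts"), show_col_types = FALSE)
    if ("assay" %in% names(cts)) {
      cts <- filter(cts, .data$assay == !!get("total_assay", "total_16s"))
    }
    qc_quantify(cts, curve, sd_limit = get("sd_limit", 0.5)) %>%
      mutate(total_copies = copies_per_gram(
        .data$copies_per_rxn,
        template_volume = get("template_volume", 1),
        elution_volume = need("elution_volume"),
        soil_mass = need("soil_mass")
      ))
  })
  absolute <- NULL
  relative <- stage("relative_abundance", {
    ft <- read_feature_table(need("feature_table"))
    rank <- get("rank")
    if (!is.null(rank)) ft <- aggregate_by_rank(ft, rank)
    rel <- to_relative(ft)
    thr <- get("minor_threshold")
    if (!is.null(thr)) rel <- pool_minor(rel, thr)
    rel
  })
  absolute <- stage("integrate", {
    integrate_abundance(relative, totals, region = get("region"))
  })
  emit(select(totals, -any_of("result")), "totals.tsv")
  emit(relative, "relative_abundance.tsv")
  emit(absolute, "absolute_abundance.tsv")

  results <- list(curve = curve, totals = totals, relative = relative,
                  absolute = absolute)

  if (!is.null(get("spike"))) {
    results$validation <- stage("validate", {
      spike <- readr::read_csv(need("spike"), show_col_types = FALSE)
      v <- validate_spikein(spike, copy_ratio = get("copy_ratio", 1))
      emit(tidy(v), "spikein_validation.tsv")
      v
    })
  }
  if (!is.null(get("before")) && !is.null(get("after"))) {
    results$discordance <- stage("dynamics", {
      pick <- function(tbl, s) filter(tbl, .data$sample == !!s)
      d <- count_discordant(
        pick(relative, need("before")), pick(relative, need("after")),
        pick(absolute, need("before")), pick(absolute, need("after")),
        eps = get("eps", 0)
      )
      emit(tidy(d), "discordance_records.tsv")
      counts_path <- file.path(out_dir, "discordance_counts.json")
      jsonlite::write_json(glance(d), counts_path, auto_unbox = TRUE,
                           digits = NA)
      files <- c(files, counts_path)
      d
    })
  }

  log_path <- file.path(out_dir, "run_log.json")
  jsonlite::write_json(
    list(
      package = "absquant",
      version = as.character(utils::packageVersion("absquant")),
      timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
      parameters = config[!purrr::map_lgl(config, is.null)],
      outputs = basename(files)
    ),
    log_path, auto_unbox = TRUE, digits = NA
  )
  results$files <- c(files, log_path)
  invisible(results)
}
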