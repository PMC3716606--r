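#' Characteristics summary table (per land use and depth interval)
#'
#' Means and standard errors of soil texture, bulk density, C:N, pH, ECEC
#' and base saturation by land use and depth interval.
#'
#' @param study A `soc_study` bundle.
#' @return A tibble, one row per land use and interval.
#' @export
characteristics_summary <- function(study) {
  h <- dplyr::left_join(study$horizons,
                        study$plots[, c("plot_id", "land_use")],
                        by = "plot_id")
  h$interval <- interval_label(h$top_m, h$bottom_m)
  h$cn <- ifelse(h$n_pct > 0, h$c_pct / h$n_pct, NA_real_)
  se <- function(x) {
    n <- sum(!is.na(x))
    if (n < 2) NA_real_ else stats::sd(x, na.rm = TRUE) / sqrt(n)
  }
  vars <- c("sand_pct", "silt_clay_pct", "bd_g_cm3", "cn", "ph_h2o",
            "ph_kcl", "ecec_mmolc_kg", "base_sat_pct")
  dplyr::summarise(
    dplyr::group_by(h, .data$land_use, .data$interval, .data$top_m),
    n = dplyr::n(),
    dplyr::across(dplyr::all_of(vars),
                  list(mean = ~ mean(.x, na.rm = TRUE), se = ~ se(.x))),
    .groups = "drop"
  ) |>
    dplyr::arrange(.data$top_m, .data$land_use) |>
    dplyr::select(-"top_m")
}

#' Litter and tree summary table (per land use)
#'
#' Means and standard errors over plots of litter carbon concentration,
#' litter C:N, litter carbon stock, tree basal area and total basal area.
#'
#' @param study A `soc_study` bundle.
#' @return A tibble, one row per land use.
#' @export
litter_tree_summary <- function(study) {
  s <- plot_summaries(study)
  se <- function(x) stats::sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x)))
  vars <- c("litter_c_pct", "litter_cn", "litter_c_mg_ha", "tree_ba_m2_ha",
            "total_ba_m2_ha")
  dplyr::summarise(
    dplyr::group_by(s, .data$land_use),
    n = dplyr::n(),
    dplyr::across(dplyr::all_of(vars),
                  list(mean = ~ mean(.x, na.rm = TRUE), se = ~ se(.x))),
    .groups = "drop"
  )
}

pipeline_log <- function(lines, path, quiet) {
  if (!quiet) message(paste(lines, collapse = "\n"))
  cat(lines, file = path, sep = "\n", append = TRUE)
}

#' Run the full SOC change analysis pipeline
#'
#' Orchestrates validation, stock accounting with the equal-bulk-density
#' correction, cluster-paired change statistics, the mixed-model land-use by
#' depth analysis with Holm-adjusted per-depth contrasts, the covariate
#' correlation screen, and per-depth decay fitting with model selection.
#' Writes the report tables as CSV plus a JSON run manifest.
#'
#' @param study A `soc_study` bundle, or `NULL` to read from `input_dir`.
#' @param input_dir Directory with the four input CSVs (used when `study`
#'   is `NULL`).
#' @param output_dir Directory for output tables (created if absent).
#' @param seed Root seed for all randomness (decay-fit multi-start jitter).
#' @param bd_correction Apply the equal-bulk-density correction.
#' @param variance_by_landuse Passed to [fit_landuse_model()].
#' @param pairing_level Passed to [correlation_screen()].
#' @param fit_intervals Depth intervals to fit decay models for.
#' @param curve_threshold Passed to [select_model()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with all result tables and `manifest`.
#' @export
run_pipeline <- function(study = NULL, input_dir = NULL, output_dir = ".",
                         seed = 1L, bd_correction = TRUE,
                         variance_by_landuse = FALSE,
                         pairing_level = "plot",
                         fit_intervals = c("0-0.15", "0.15-0.3", "0.3-0.6"),
                         curve_threshold = 0.5, quiet = FALSE) {
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  log_path <- file.path(output_dir, "run_log.txt")
  if (file.exists(log_path)) unlink(log_path)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("pipeline stage '%s' failed: %s", name,
                           conditionMessage(e)),
                   class = "socchrono_pipeline_error", parent = e)
    })
  }

  input_digests <- NULL
  if (is.null(study)) {
    if (is.null(input_dir)) {
      abort_schema("run_pipeline: provide a study bundle or an input_dir",
                   "socchrono_config_error")
    }
    paths <- file.path(input_dir, c("plots.csv", "horizons.csv", "litter.csv",
                                    "trees.csv"))
    input_digests <- tools::md5sum(paths[file.exists(paths)])
    study <- stage("read", read_study(input_dir))
  }
  pipeline_log(sprintf("stage read: %d plots in %d clusters",
                       nrow(study$plots),
                       length(unique(study$plots$cluster_id))),
               log_path, quiet)

  stocks <- stage("stocks", compute_stocks(study, bd_correction = bd_correction))
  changes <- stage("changes", cluster_changes(stocks))
  change_summary <- stage("changes", summarize_changes(changes))
  bd_cmp <- stage("bd_comparison", bd_correction_comparison(study))
  pipeline_log(sprintf(
    "stage stocks: bd_correction=%s; mean total change %.1f Mg C ha-1 (%.1f%%)",
    bd_correction,
    change_summary$abs_mean[change_summary$interval == "total"],
    change_summary$rel_mean[change_summary$interval == "total"]),
    log_path, quiet)

  lme_fit <- stage("landuse_model", fit_landuse_model(
    stocks, response = "stock_mg_ha",
    variance_by_landuse = variance_by_landuse))
  contrasts <- stage("landuse_model", depth_contrasts(lme_fit))
  pipeline_log(sprintf(
    "stage landuse_model: variance function %s; %d/%d contrasts significant at 0.05 after Holm",
    if (variance_by_landuse) "per land use" else "off",
    sum(contrasts$p_holm <= 0.05), nrow(contrasts)), log_path, quiet)

  correlations <- stage("correlations", correlation_screen(
    study, stocks = stocks, pairing_level = pairing_level))

  chron <- stage("chronosequence", chronosequence_fits(
    stocks, intervals = fit_intervals, curve_threshold = curve_threshold,
    seed = seed))
  for (iv in fit_intervals) {
    sel <- chron$fits[[iv]]$selection
    pipeline_log(sprintf("stage chronosequence [%s]: selected %s model (%s)",
                         iv, sel$model, sel$rationale), log_path, quiet)
  }

  t_grid <- seq(0, max(study$plots$age_years, na.rm = TRUE) + 10, by = 0.5)
  curves <- purrr::map_dfr(fit_intervals, function(iv) {
    f <- chron$fits[[iv]]$mono
    if (!f$converged) return(NULL)
    tibble::tibble(interval = iv, t = t_grid, y_pct = predict(f, t_grid))
  })

  # Table-3-style report: plot-level stock means, cluster-level differences
  stock_means <- dplyr::summarise(
    dplyr::group_by(stocks, .data$land_use, .data$interval, .data$top_m),
    stock_mean = mean(.data$stock_mg_ha),
    stock_se = stats::sd(.data$stock_mg_ha) / sqrt(dplyr::n()),
    .groups = "drop"
  )
  totals <- profile_totals(stocks)
  totals_means <- dplyr::summarise(
    dplyr::group_by(totals, .data$land_use),
    interval = "total", top_m = Inf,
    stock_mean = mean(.data$total_mg_ha),
    stock_se = stats::sd(.data$total_mg_ha) / sqrt(dplyr::n()),
    .groups = "drop"
  )
  stock_means <- dplyr::bind_rows(stock_means, totals_means)
  wide <- tidyr::pivot_wider(
    stock_means, names_from = "land_use",
    values_from = c("stock_mean", "stock_se")
  )
  stocks_changes <- dplyr::left_join(
    wide,
    change_summary[, c("interval", "abs_mean", "abs_se", "rel_mean", "rel_se")],
    by = "interval"
  )
  stocks_changes <- dplyr::left_join(
    stocks_changes, contrasts[, c("interval", "p_holm", "flag")],
    by = "interval"
  )
  stocks_changes <- dplyr::arrange(stocks_changes, .data$top_m)
  stocks_changes$top_m <- NULL

  tables <- list(
    summary_characteristics = characteristics_summary(study),
    litter_trees = litter_tree_summary(study),
    stocks_out = stocks,
    changes_out = changes,
    stocks_changes = stocks_changes,
    contrasts_out = contrasts,
    correlations = correlations,
    decay_fits = chron$table,
    decay_curves = curves,
    bd_correction_comparison = bd_cmp
  )
  artifacts <- character(0)
  for (nm in names(tables)) {
    path <- file.path(output_dir, paste0(nm, ".csv"))
    readr::write_csv(tables[[nm]], path, na = "")
    artifacts <- c(artifacts, basename(path))
  }

  cfg <- list(seed = seed, bd_correction = bd_correction,
              variance_by_landuse = variance_by_landuse,
              pairing_level = pairing_level, fit_intervals = fit_intervals,
              curve_threshold = curve_threshold)
  manifest <- list(
    package_version = as.character(utils::packageVersion("socchrono")),
    config = cfg,
    config_hash = rlang::hash(cfg),
    input_digests = as.list(input_digests),
    seed = seed,
    artifacts = c(artifacts, "run_log.txt", "manifest.json")
  )
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  } else {
    yaml::write_yaml(manifest, file.path(output_dir, "manifest.yaml"))
  }
  pipeline_log(sprintf("pipeline complete: %d artifacts emitted",
                       length(manifest$artifacts)),
               log_path, quiet)
  invisible(c(tables, list(chronosequence = chron, model = lme_fit,
                           manifest = manifest)))
}
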