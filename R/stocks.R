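#' Soil carbon stock of one depth interval
#'
#' Converts a carbon concentration and bulk density to an areal SOC stock:
#' `stock = c_pct/100 * bd * thickness_m * 10000` Mg C ha^-1, treating bulk
#' density in g cm^-3 as Mg m^-3 over one hectare. No gravel correction is
#' applied.
#'
#' @param c_pct Carbon concentration, mass percent (>= 0).
#' @param bd_g_cm3 Bulk density, g cm^-3 (> 0).
#' @param top_m,bottom_m Interval bounds in meters, `top_m < bottom_m`.
#' @return SOC stock in Mg C ha^-1 (vectorized).
#' @export
#' @examples
#' interval_stock(2, 1, 0, 0.15) # 30 Mg C ha^-1
interval_stock <- function(c_pct, bd_g_cm3, top_m, bottom_m) {
  if (any(c_pct < 0, na.rm = TRUE)) {
    abort_schema("interval_stock: c_pct must be >= 0", "socchrono_domain_error")
  }
  if (any(bd_g_cm3 <= 0, na.rm = TRUE)) {
    abort_schema("interval_stock: bd_g_cm3 must be > 0", "socchrono_domain_error")
  }
  if (any(top_m < 0 | top_m >= bottom_m)) {
    abort_schema("interval_stock: need 0 <= top_m < bottom_m",
                 "socchrono_domain_error")
  }
  (c_pct / 100) * bd_g_cm3 * (bottom_m - top_m) * 1e4
}

#' Per-interval and total SOC stocks for one plot
#'
#' Computes the stock of every depth interval of a plot and the profile
#' total. For converted (rubber) plots, supplying the same-cluster reference
#' forest's bulk-density profile evaluates the plot's carbon concentrations
#' at the reference bulk density (equal-bulk-density correction), so that
#' the same soil mass is compared across land uses; the plot's own carbon
#' concentrations are always used.
#'
#' @param plot_horizons Horizon rows of a single plot (columns `plot_id`,
#'   `top_m`, `bottom_m`, `c_pct`, `bd_g_cm3`).
#' @param reference_bd Optional reference bulk-density profile: a data frame
#'   with `top_m`, `bottom_m`, `bd_g_cm3` covering the same intervals.
#'   `NULL` uses the plot's own bulk density.
#' @return A tibble of class `soc_stock_profile` with one row per interval
#'   (`plot_id`, `top_m`, `bottom_m`, `interval`, `stock_mg_ha`, `bd_source`)
#'   and the profile total in attribute `total`.
#' @export
#' @examples
#' h <- data.frame(plot_id = "p", top_m = canonical_depths()$top_m,
#'                 bottom_m = canonical_depths()$bottom_m, c_pct = 1,
#'                 bd_g_cm3 = 1)
#' profile_stocks(h) # 120 Mg C ha^-1 over 1.2 m
profile_stocks <- function(plot_horizons, reference_bd = NULL) {
  h <- plot_horizons[order(plot_horizons$top_m), ]
  if (length(unique(h$plot_id)) != 1) {
    abort_schema("profile_stocks: expects horizons of a single plot",
                 "socchrono_domain_error")
  }
  bd_source <- "own"
  bd <- h$bd_g_cm3
  if (!is.null(reference_bd)) {
    ref <- reference_bd[order(reference_bd$top_m), ]
    if (nrow(ref) != nrow(h) ||
        !isTRUE(all.equal(ref$top_m, h$top_m, tolerance = 1e-9))) {
      abort_schema("profile_stocks: reference BD profile does not match the plot's depth set",
                   "socchrono_config_error")
    }
    bd <- ref$bd_g_cm3
    bd_source <- "reference"
  }
  out <- tibble::tibble(
    plot_id = h$plot_id,
    top_m = h$top_m,
    bottom_m = h$bottom_m,
    interval = interval_label(h$top_m, h$bottom_m),
    stock_mg_ha = interval_stock(h$c_pct, bd, h$top_m, h$bottom_m),
    bd_source = bd_source
  )
  attr(out, "total") <- sum(out$stock_mg_ha)
  class(out) <- c("soc_stock_profile", class(out))
  out
}

#' SOC stocks for every plot in a study
#'
#' Applies [profile_stocks()] to all plots. With `bd_correction = TRUE`
#' (the default) each rubber plot's stocks are computed with the
#' bulk-density profile of its cluster's forest plot; forest plots always
#' use their own bulk density. `bd_correction = FALSE` reproduces the
#' uncorrected variant in which every plot uses its own bulk density.
#'
#' @param study A `soc_study` bundle.
#' @param bd_correction Apply the equal-bulk-density correction to rubber
#'   plots.
#' @return A tibble with one row per plot and interval: `plot_id`,
#'   `cluster_id`, `land_use`, `age_years`, `top_m`, `bottom_m`, `interval`,
#'   `stock_mg_ha`, `bd_source`.
#' @export
compute_stocks <- function(study, bd_correction = TRUE) {
  stopifnot(inherits(study, "soc_study"))
  plots <- study$plots
  res <- purrr::map_dfr(plots$plot_id, function(pid) {
    meta <- plots[plots$plot_id == pid, ]
    h <- study$horizons[study$horizons$plot_id == pid, ]
    ref <- NULL
    if (bd_correction && meta$land_use == "rubber") {
      fid <- plots$plot_id[plots$cluster_id == meta$cluster_id &
                             plots$land_use == "forest"]
      if (length(fid) != 1) {
        abort_schema(
          sprintf("plot '%s': no reference forest BD profile in cluster '%s'",
                  pid, meta$cluster_id),
          "socchrono_config_error"
        )
      }
      ref <- study$horizons[study$horizons$plot_id == fid,
                            c("top_m", "bottom_m", "bd_g_cm3")]
    }
    p <- profile_stocks(h, reference_bd = ref)
    p$cluster_id <- meta$cluster_id
    p$land_use <- meta$land_use
    p$age_years <- meta$age_years
    p
  })
  res[, c("plot_id", "cluster_id", "land_use", "age_years", "top_m",
          "bottom_m", "interval", "stock_mg_ha", "bd_source")]
}

#' Profile totals from a per-interval stock table
#'
#' @param stocks Output of [compute_stocks()].
#' @return One row per plot with `total_mg_ha`.
#' @export
profile_totals <- function(stocks) {
  dplyr::summarise(
    dplyr::group_by(stocks, .data$plot_id, .data$cluster_id, .data$land_use,
                    .data$age_years),
    total_mg_ha = sum(.data$stock_mg_ha), .groups = "drop"
  )
}

#' Cluster-paired stock differences
#'
#' For each cluster, the absolute difference is the mean over that cluster's
#' rubber plots minus the reference forest plot, per depth interval and for
#' the profile total; the relative difference divides by the forest stock
#' and multiplies by 100.
#'
#' @param stocks Per-interval stock table from [compute_stocks()].
#' @return A tibble with one row per cluster and interval (plus an
#'   `interval = "total"` row): `cluster_id`, `interval`, `top_m`,
#'   `forest_mg_ha`, `rubber_mean_mg_ha`, `abs_mg_ha`, `rel_pct`. When a
#'   forest stock is zero the relative difference is `NA`.
#' @export
cluster_changes <- function(stocks) {
  totals <- profile_totals(stocks)
  totals$interval <- "total"
  totals$top_m <- Inf
  totals$stock_mg_ha <- totals$total_mg_ha
  long <- dplyr::bind_rows(
    stocks[, c("cluster_id", "plot_id", "land_use", "interval", "top_m",
               "stock_mg_ha")],
    totals[, c("cluster_id", "plot_id", "land_use", "interval", "top_m",
               "stock_mg_ha")]
  )
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$cluster_id, .data$interval, .data$top_m),
    forest_mg_ha = .data$stock_mg_ha[.data$land_use == "forest"][1],
    rubber_mean_mg_ha = mean(.data$stock_mg_ha[.data$land_use == "rubber"]),
    .groups = "drop"
  )
  out$abs_mg_ha <- out$rubber_mean_mg_ha - out$forest_mg_ha
  out$rel_pct <- ifelse(out$forest_mg_ha == 0, NA_real_,
                        100 * out$abs_mg_ha / out$forest_mg_ha)
  if (any(out$forest_mg_ha == 0)) {
    rlang::warn("cluster_changes: forest stock of 0; relative difference set to NA")
  }
  out[order(out$cluster_id, out$top_m), ]
}

#' Across-cluster summary of stock changes
#'
#' Arithmetic mean and standard error of the mean (n = clusters) of the
#' absolute and relative cluster-paired differences, per depth interval and
#' for the profile total.
#'
#' @param changes Output of [cluster_changes()].
#' @return A tibble per interval with `n`, means and SEs of forest stock,
#'   rubber stock, absolute and relative differences.
#' @export
summarize_changes <- function(changes) {
  if (length(unique(changes$cluster_id)) < 2) {
    abort_schema("summarize_changes: needs >= 2 clusters",
                 "socchrono_domain_error")
  }
  se <- function(x) stats::sd(x) / sqrt(sum(!is.na(x)))
  out <- dplyr::summarise(
    dplyr::group_by(changes, .data$interval, .data$top_m),
    n = dplyr::n(),
    forest_mean = mean(.data$forest_mg_ha),
    forest_se = se(.data$forest_mg_ha),
    rubber_mean = mean(.data$rubber_mean_mg_ha),
    rubber_se = se(.data$rubber_mean_mg_ha),
    abs_mean = mean(.data$abs_mg_ha),
    abs_se = se(.data$abs_mg_ha),
    rel_mean = mean(.data$rel_pct, na.rm = TRUE),
    rel_se = se(.data$rel_pct),
    .groups = "drop"
  )
  out <- out[order(out$top_m), ]
  out$top_m <- NULL
  out
}

#' Litter-layer carbon stock of a plot
#'
#' Each frame sample contributes `c_pct/100 * mass_g` grams of carbon over
#' its frame area; samples are scaled to Mg C ha^-1 and averaged over the
#' plot's frames.
#'
#' @param plot_litter Litter rows of one plot (`mass_g`, `frame_area_m2`,
#'   `c_pct`, `n_pct`).
#' @return A one-row tibble: `litter_c_mg_ha`, `litter_c_se`,
#'   `litter_c_pct` (mean concentration), `litter_cn` (mean C:N ratio),
#'   `n_samples`.
#' @export
#' @examples
#' litter_stock(data.frame(mass_g = 10, frame_area_m2 = 0.04,
#'                         c_pct = 40, n_pct = 1)) # 1 Mg C ha^-1
litter_stock <- function(plot_litter) {
  if (nrow(plot_litter) < 1) {
    abort_schema("litter_stock: needs >= 1 litter record",
                 "socchrono_domain_error")
  }
  if (any(plot_litter$frame_area_m2 <= 0)) {
    abort_schema("litter_stock: frame_area_m2 must be > 0",
                 "socchrono_domain_error")
  }
  # g C m^-2 -> Mg C ha^-1 is a factor of 0.01
  per_sample <- (plot_litter$c_pct / 100) * plot_litter$mass_g /
    plot_litter$frame_area_m2 * 0.01
  cn <- ifelse(plot_litter$n_pct > 0, plot_litter$c_pct / plot_litter$n_pct,
               NA_real_)
  tibble::tibble(
    litter_c_mg_ha = mean(per_sample),
    litter_c_se = stats::sd(per_sample) / sqrt(length(per_sample)),
    litter_c_pct = mean(plot_litter$c_pct),
    litter_cn = mean(cn, na.rm = TRUE),
    n_samples = nrow(plot_litter)
  )
}

#' Tree and total basal area of a plot
#'
#' Basal area of each stem is `pi * (dbh/200)^2` m^2; a bamboo clump
#' contributes its measured stem's basal area times the clump's stem count.
#' Tree basal area excludes bamboo; total basal area includes it. Both are
#' scaled to m^2 ha^-1 by `10000 / plot_area_m2`.
#'
#' @param plot_trees Tree rows of one plot (`stem_kind`, `dbh_cm`,
#'   `stems_in_clump`).
#' @param plot_area_m2 Horizontal (slope-corrected) plot area in m^2.
#' @return A one-row tibble: `tree_ba_m2_ha`, `total_ba_m2_ha`.
#' @export
#' @examples
#' basal_areas(data.frame(stem_kind = "tree", dbh_cm = 20,
#'                        stems_in_clump = 1), 400)
basal_areas <- function(plot_trees, plot_area_m2) {
  if (plot_area_m2 <= 0) {
    abort_schema("basal_areas: plot_area_m2 must be > 0",
                 "socchrono_domain_error")
  }
  scale <- 1e4 / plot_area_m2
  if (nrow(plot_trees) == 0) {
    return(tibble::tibble(tree_ba_m2_ha = 0, total_ba_m2_ha = 0))
  }
  ba_stem <- pi * (plot_trees$dbh_cm / 200)^2 * plot_trees$stems_in_clump
  is_tree <- plot_trees$stem_kind == "tree"
  tibble::tibble(
    tree_ba_m2_ha = sum(ba_stem[is_tree]) * scale,
    total_ba_m2_ha = sum(ba_stem) * scale
  )
}

#' Plot-level site summary table
#'
#' Combines litter stocks, basal areas and plot metadata into one row per
#' plot, for covariate screening and reporting.
#'
#' @param study A `soc_study` bundle.
#' @return A tibble with one row per plot: metadata, `litter_c_mg_ha`,
#'   `litter_c_pct`, `litter_cn`, `tree_ba_m2_ha`, `total_ba_m2_ha`, and the
#'   topsoil `silt_clay_pct`.
#' @export
plot_summaries <- function(study) {
  stopifnot(inherits(study, "soc_study"))
  purrr::map_dfr(study$plots$plot_id, function(pid) {
    meta <- study$plots[study$plots$plot_id == pid, ]
    lit <- litter_stock(study$litter[study$litter$plot_id == pid, ])
    ba <- basal_areas(study$trees[study$trees$plot_id == pid, ],
                      meta$plot_area_m2)
    top <- study$horizons[study$horizons$plot_id == pid &
                            study$horizons$top_m == 0, ]
    dplyr::bind_cols(meta, lit, ba,
                     tibble::tibble(silt_clay_top_pct = top$silt_clay_pct[1]))
  })
}

#' Corrected versus uncorrected stock-change comparison
#'
#' Recomputes cluster-paired differences with and without the
#' equal-bulk-density correction, quantifying the error made when
#' bulk-density change with land use is ignored.
#'
#' @param study A `soc_study` bundle.
#' @return A tibble per cluster and interval with corrected and uncorrected
#'   absolute and relative differences and their gap
#'   (`rel_error_pct = rel_uncorrected - rel_corrected`).
#' @export
bd_correction_comparison <- function(study) {
  corr <- cluster_changes(compute_stocks(study, bd_correction = TRUE))
  unc <- cluster_changes(compute_stocks(study, bd_correction = FALSE))
  out <- dplyr::inner_join(
    dplyr::rename(corr, abs_corrected = "abs_mg_ha", rel_corrected = "rel_pct",
                  rubber_corrected = "rubber_mean_mg_ha"),
    dplyr::rename(unc, abs_uncorrected = "abs_mg_ha",
                  rel_uncorrected = "rel_pct",
                  rubber_uncorrected = "rubber_mean_mg_ha")[,
      c("cluster_id", "interval", "rubber_uncorrected", "abs_uncorrected",
        "rel_uncorrected")],
    by = c("cluster_id", "interval")
  )
  out$rel_error_pct <- out$rel_uncorrected - out$rel_corrected
  out
}
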