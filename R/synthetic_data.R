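#' Configuration for the synthetic study generator
#'
#' Defaults emulate the clustered chronosequence design that motivates the
#' package: 7 clusters, one reference forest plot each plus 1--3 rubber
#' plots totalling 11, plantation ages spread over 5--46 years, five depth
#' intervals to 1.2 m, forest baseline stocks at the magnitudes observed in
#' the field study that anchors the defaults, and a depth-specific
#' mono-exponential decline of rubber stocks toward an equilibrium fraction.
#'
#' @param n_clusters Number of clusters.
#' @param rubber_per_cluster Integer vector (length `n_clusters`) of rubber
#'   plots per cluster, each in 1--3.
#' @param ages Pool of plantation ages (years) sampled without replacement;
#'   must be at least as long as `sum(rubber_per_cluster)`.
#' @param forest_baseline_mg_ha Forest stock means per depth interval,
#'   Mg C ha^-1 (top to bottom).
#' @param cluster_sd_frac Between-cluster SD of baselines as a fraction of
#'   the mean (log-normal cluster intercepts).
#' @param Xe_pct Equilibrium proportion of forest stock per interval, %.
#' @param k_per_yr Decay rate per interval, yr^-1.
#' @param proportion_noise_cv Multiplicative noise CV on the decay
#'   proportion of each rubber plot (about 5 percentage points near 100%).
#' @param stock_noise_cv Multiplicative measurement-noise CV applied to
#'   every plot's stocks.
#' @param bd_forest,bd_rubber Bulk-density means per interval and land use,
#'   g cm^-3.
#' @param bd_rubber_shift Additional systematic shift added to rubber bulk
#'   density (g cm^-3), for stress-testing the equal-bulk-density
#'   correction.
#' @param bd_match_forest If `TRUE`, every rubber plot inherits its cluster
#'   forest plot's bulk-density draws exactly (no bulk-density change with
#'   land use), so corrected and uncorrected stocks coincide.
#' @param bd_sd Bulk-density SD per interval.
#' @param silt_clay_mean,silt_clay_sd Texture distribution, %.
#' @param texture_altitude_slope Increase of silt+clay (%) per m altitude.
#' @param altitude_range Plot altitude range, m a.s.l.
#' @param slope_range Plot slope range, %.
#' @param plot_area_m2 Horizontal plot area.
#' @param litter_mass_mean_g,litter_mass_sd_g Oven-dry litter mass per
#'   0.04 m^2 frame (land-use neutral).
#' @param litter_c_pct_mean,litter_c_pct_sd Litter carbon concentration, %.
#' @param n_litter_samples Frames per plot.
#' @param ba_age_intercept,ba_age_slope,ba_noise_sd Rubber basal-area growth
#'   with age (m^2 ha^-1 and m^2 ha^-1 yr^-1).
#' @param cn_topsoil,cn_subsoil Soil C:N means used to back out nitrogen.
#' @return A list of class `soc_synth_config`.
#' @export
synthetic_config <- function(
    n_clusters = 7,
    rubber_per_cluster = c(2, 2, 2, 2, 1, 1, 1),
    ages = c(5, 7, 9, 12, 15, 18, 22, 25, 30, 38, 46),
    forest_baseline_mg_ha = c(43.9, 38.9, 52, 35.2, 26.0),
    cluster_sd_frac = 0.10,
    Xe_pct = c(68, 75, 85, 90, 95),
    k_per_yr = rep(0.2, 5),
    proportion_noise_cv = 0.05,
    stock_noise_cv = 0.02,
    bd_forest = c(1.0, 1.2, 1.3, 1.3, 1.3),
    bd_rubber = c(1.1, 1.1, 1.3, 1.3, 1.3),
    bd_rubber_shift = 0,
    bd_match_forest = FALSE,
    bd_sd = c(0.08, 0.05, 0.05, 0.05, 0.05),
    silt_clay_mean = 68,
    silt_clay_sd = 3,
    texture_altitude_slope = 0.1,
    altitude_range = c(700, 830),
    slope_range = c(10, 60),
    plot_area_m2 = 400,
    litter_mass_mean_g = 24,
    litter_mass_sd_g = 8,
    litter_c_pct_mean = 40.5,
    litter_c_pct_sd = 2,
    n_litter_samples = 10,
    ba_age_intercept = -1.6,
    ba_age_slope = 0.96,
    ba_noise_sd = 3.5,
    cn_topsoil = 12.3,
    cn_subsoil = 9.6) {
  cfg <- as.list(environment())
  n_int <- nrow(canonical_depths())
  stopifnot(
    length(cfg$rubber_per_cluster) == cfg$n_clusters,
    length(cfg$forest_baseline_mg_ha) == n_int,
    length(cfg$Xe_pct) == n_int, length(cfg$k_per_yr) == n_int,
    length(cfg$bd_forest) == n_int, length(cfg$bd_rubber) == n_int,
    length(cfg$bd_sd) == n_int
  )
  if (any(cfg$rubber_per_cluster < 1 | cfg$rubber_per_cluster > 3)) {
    abort_schema("synthetic_config: rubber_per_cluster entries must be 1-3",
                 "socchrono_config_error")
  }
  if (any(cfg$Xe_pct <= 0 | cfg$Xe_pct > 100)) {
    abort_schema("synthetic_config: Xe_pct must lie in (0, 100]",
                 "socchrono_config_error")
  }
  if (any(c(cfg$cluster_sd_frac, cfg$proportion_noise_cv, cfg$stock_noise_cv,
            cfg$bd_sd, cfg$silt_clay_sd, cfg$litter_mass_sd_g,
            cfg$ba_noise_sd) < 0)) {
    abort_schema("synthetic_config: SDs must be >= 0",
                 "socchrono_config_error")
  }
  if (length(cfg$ages) < sum(cfg$rubber_per_cluster)) {
    abort_schema("synthetic_config: age pool smaller than the number of rubber plots",
                 "socchrono_config_error")
  }
  structure(cfg, class = "soc_synth_config")
}

trunc_norm <- function(rng, n, mean, sd, lower, upper) {
  pmin(pmax(rng$rnorm(n, mean, sd), lower), upper)
}

#' Generate a complete synthetic study
#'
#' Draws a full input bundle (plots, horizons, litter, trees) with the
#' statistical structure the analysis assumes. Forest plots receive
#' cluster-level baseline stocks; rubber plots receive the baseline scaled
#' by the one-pool decay curve at their age, times multiplicative noise.
#' Horizon carbon concentrations are back-computed from the generated
#' stocks, the reference (forest) bulk density and the interval thickness,
#' so re-running the stock calculation on the bundle reproduces the
#' generated stocks exactly. Tree inventories make basal area grow with
#' plantation age; litter stocks are land-use neutral.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed; the same seed yields an identical bundle.
#' @return A list with `study` (a validated `soc_study`) and `truth`, a
#'   record of every generating parameter plus the per-plot true corrected
#'   stocks (`truth$stocks`), cluster baselines (`truth$baselines`) and the
#'   per-interval decay truth (`truth$decay`).
#' @export
#' @examples
#' gs <- generate_study(synthetic_config(), seed = 42)
#' gs$study
generate_study <- function(config = synthetic_config(), seed = 1L) {
  stopifnot(inherits(config, "soc_synth_config"))
  rng <- local_rng(seed)
  depths <- canonical_depths()
  n_int <- nrow(depths)
  cl_ids <- sprintf("C%d", seq_len(config$n_clusters))

  n_rubber <- sum(config$rubber_per_cluster)
  ages <- rng$sample(config$ages, n_rubber)

  plots <- list(); horizons <- list(); litter <- list(); trees <- list()
  truth_stocks <- list()
  baselines <- list()
  age_i <- 0

  for (ci in seq_len(config$n_clusters)) {
    cl <- cl_ids[ci]
    # cluster-level random intercept on the baseline profile (log-normal)
    base <- config$forest_baseline_mg_ha *
      exp(rng$rnorm(n_int, 0, config$cluster_sd_frac))
    baselines[[cl]] <- tibble::tibble(cluster_id = cl,
                                      interval = depths$interval,
                                      baseline_mg_ha = base)
    alt_cl <- rng$runif(1, config$altitude_range[1], config$altitude_range[2])
    slope_cl <- rng$runif(1, config$slope_range[1], config$slope_range[2])

    # texture shared across the cluster (matched-site assumption)
    silt_clay_cl <- config$silt_clay_mean +
      config$texture_altitude_slope *
      (alt_cl - mean(config$altitude_range)) +
      rng$rnorm(1, 0, config$silt_clay_sd)

    make_plot <- function(pid, land_use, age) {
      alt <- alt_cl + rng$runif(1, -10, 10)
      slope <- pmax(1, slope_cl + rng$runif(1, -5, 5))
      plots[[pid]] <<- tibble::tibble(
        plot_id = pid, cluster_id = cl, land_use = land_use,
        age_years = age, altitude_m = alt, slope_pct = slope,
        plot_area_m2 = config$plot_area_m2
      )
    }

    fid <- sprintf("%s_F", cl)
    make_plot(fid, "forest", NA_real_)
    bd_f <- trunc_norm(rng, n_int, config$bd_forest, config$bd_sd, 0.5, 2.0)
    f_meas <- base * exp(rng$rnorm(n_int, 0, config$stock_noise_cv))
    f_cpct <- f_meas / (bd_f * depths$thickness_m * 100)
    # recompute so the recorded truth round-trips through the stock formula
    f_meas <- f_cpct * bd_f * depths$thickness_m * 100

    make_horizons <- function(pid, c_pct, bd) {
      cn <- ifelse(depths$top_m < 0.3,
                   rng$rnorm(n_int, config$cn_topsoil, 0.5),
                   rng$rnorm(n_int, config$cn_subsoil, 0.5))
      sc <- pmin(95, pmax(5,
        silt_clay_cl + rng$rnorm(n_int, 0, 1.5) + 2 * (depths$top_m >= 0.3)))
      horizons[[pid]] <<- tibble::tibble(
        plot_id = pid, top_m = depths$top_m, bottom_m = depths$bottom_m,
        c_pct = c_pct, n_pct = c_pct / cn, bd_g_cm3 = bd,
        sand_pct = 100 - sc, silt_clay_pct = sc,
        ph_h2o = rng$rnorm(n_int, 4.85, 0.15),
        ph_kcl = rng$rnorm(n_int, 3.9, 0.1),
        ecec_mmolc_kg = ifelse(depths$interval %in% c("0-0.15", "0.6-0.9"),
                               rng$rnorm(n_int, c(50, 45, 40, 33, 30), 4),
                               NA_real_),
        base_sat_pct = ifelse(depths$interval %in% c("0-0.15", "0.6-0.9"),
                              pmax(2, rng$rnorm(n_int, c(24, 20, 15, 11, 10), 4)),
                              NA_real_)
      )
    }
    make_horizons(fid, f_cpct, bd_f)
    truth_stocks[[fid]] <- tibble::tibble(
      plot_id = fid, cluster_id = cl, land_use = "forest",
      age_years = NA_real_, interval = depths$interval,
      true_stock_mg_ha = f_meas
    )

    make_litter <- function(pid) {
      mass <- pmax(0, rng$rnorm(config$n_litter_samples,
                                config$litter_mass_mean_g,
                                config$litter_mass_sd_g))
      litter[[pid]] <<- tibble::tibble(
        plot_id = pid, sample_id = seq_len(config$n_litter_samples),
        mass_g = mass, frame_area_m2 = 0.04,
        c_pct = rng$rnorm(config$n_litter_samples, config$litter_c_pct_mean,
                          config$litter_c_pct_sd),
        n_pct = rng$rnorm(config$n_litter_samples, 0.9, 0.1)
      )
    }
    make_litter(fid)

    # forest stand: broadleaf trees above the DBH threshold plus bamboo
    n_tree <- max(5, round(rng$rnorm(1, 30, 5)))
    n_bamboo <- max(1, rng$rpois(1, 4))
    trees[[fid]] <- dplyr::bind_rows(
      tibble::tibble(
        plot_id = fid, stem_kind = "tree",
        dbh_cm = pmax(4.1, rng$rlnorm(n_tree, log(12), 0.35)),
        stems_in_clump = 1L
      ),
      tibble::tibble(
        plot_id = fid, stem_kind = "bamboo_clump",
        dbh_cm = pmax(2, rng$rnorm(n_bamboo, 6, 1)),
        stems_in_clump = pmax(1L, as.integer(round(rng$rnorm(n_bamboo, 18, 4))))
      )
    )

    for (ri in seq_len(config$rubber_per_cluster[ci])) {
      age_i <- age_i + 1
      age <- ages[age_i]
      pid <- sprintf("%s_R%d", cl, ri)
      make_plot(pid, "rubber", age)

      decay <- mono_exp(age, config$Xe_pct, config$k_per_yr) / 100
      r_true <- base * decay *
        exp(rng$rnorm(n_int, 0, config$proportion_noise_cv))
      r_meas <- r_true * exp(rng$rnorm(n_int, 0, config$stock_noise_cv))
      # corrected stocks are defined at the reference (forest) bulk density
      r_cpct <- r_meas / (bd_f * depths$thickness_m * 100)
      r_meas <- r_cpct * bd_f * depths$thickness_m * 100
      bd_r <- if (config$bd_match_forest) bd_f else {
        trunc_norm(rng, n_int, config$bd_rubber + config$bd_rubber_shift,
                   config$bd_sd, 0.5, 2.0)
      }
      make_horizons(pid, r_cpct, bd_r)
      truth_stocks[[pid]] <- tibble::tibble(
        plot_id = pid, cluster_id = cl, land_use = "rubber",
        age_years = age, interval = depths$interval,
        true_stock_mg_ha = r_meas
      )
      make_litter(pid)

      # plantation: ~450 stems/ha sized to hit the age-driven basal area
      ba_target <- pmax(1, config$ba_age_intercept +
                          config$ba_age_slope * age +
                          rng$rnorm(1, 0, config$ba_noise_sd))
      n_stem <- max(4, as.integer(round(config$plot_area_m2 * 450 / 1e4)))
      ba_per_stem_m2 <- ba_target * config$plot_area_m2 / 1e4 / n_stem
      dbh <- 200 * sqrt(ba_per_stem_m2 / pi)
      trees[[pid]] <- tibble::tibble(
        plot_id = pid, stem_kind = "tree",
        dbh_cm = pmax(1, dbh * rng$rnorm(n_stem, 1, 0.05)),
        stems_in_clump = 1L
      )
    }
  }

  study <- read_study(list(
    plots = dplyr::bind_rows(plots),
    horizons = dplyr::bind_rows(horizons),
    litter = dplyr::bind_rows(litter),
    trees = dplyr::bind_rows(trees)
  ))
  truth <- list(
    seed = seed,
    config = config,
    decay = tibble::tibble(interval = depths$interval,
                           Xe_pct = config$Xe_pct, k_per_yr = config$k_per_yr),
    baselines = dplyr::bind_rows(baselines),
    stocks = dplyr::bind_rows(truth_stocks)
  )
  list(study = study, truth = truth)
}

#' Score pipeline outputs against the generating truth
#'
#' Compares recovered quantities with the parameters that generated a
#' synthetic bundle: per-plot corrected stocks, per-cluster per-depth mean
#' losses, and (when decay fits are supplied) the equilibrium proportion and
#' decay rate with Wald 95% interval coverage indicators.
#'
#' @param truth The `truth` record from [generate_study()].
#' @param stocks Corrected stock table from [compute_stocks()] on the same
#'   bundle.
#' @param decay_fits Optional result of [chronosequence_fits()].
#' @return A list with `stock_recovery` (per plot-interval bias), `losses`
#'   (per interval: true and estimated mean relative loss, bias), and
#'   `decay` (per fitted interval: true and estimated Xe and k, absolute
#'   and relative error, CI coverage flags).
#' @export
truth_report <- function(truth, stocks, decay_fits = NULL) {
  key <- c("plot_id", "interval")
  k_truth <- paste(truth$stocks$plot_id, truth$stocks$interval)
  k_stocks <- paste(stocks$plot_id, stocks$interval)
  if (!identical(sort(k_truth), sort(k_stocks))) {
    abort_schema("truth_report: plot/interval ids do not match the truth record",
                 "socchrono_domain_error")
  }
  merged <- dplyr::inner_join(truth$stocks, stocks, by = key)
  merged$bias_mg_ha <- merged$stock_mg_ha - merged$true_stock_mg_ha

  # true mean relative loss per interval: cluster-paired, like the estimator
  tr <- truth$stocks
  tr_wide <- dplyr::summarise(
    dplyr::group_by(tr, .data$cluster_id, .data$interval),
    forest = .data$true_stock_mg_ha[.data$land_use == "forest"][1],
    rubber = mean(.data$true_stock_mg_ha[.data$land_use == "rubber"]),
    .groups = "drop"
  )
  tr_wide$rel_pct <- 100 * (tr_wide$rubber - tr_wide$forest) / tr_wide$forest
  true_loss <- dplyr::summarise(dplyr::group_by(tr_wide, .data$interval),
                                true_rel_pct = mean(.data$rel_pct),
                                .groups = "drop")
  est <- summarize_changes(cluster_changes(stocks))
  losses <- dplyr::inner_join(
    true_loss, est[, c("interval", "rel_mean", "rel_se")], by = "interval"
  )
  losses$bias_pct_points <- losses$rel_mean - losses$true_rel_pct

  decay <- NULL
  if (!is.null(decay_fits)) {
    decay <- dplyr::inner_join(decay_fits$table, truth$decay, by = "interval")
    decay$Xe_error <- decay$Xe - decay$Xe_pct
    decay$k_error <- decay$k - decay$k_per_yr
    decay$Xe_covered <- abs(decay$Xe_error) <= 1.96 * decay$Xe_se
    decay$k_covered <- abs(decay$k_error) <= 1.96 * decay$k_se
  }
  list(stock_recovery = merged[, c(key, "true_stock_mg_ha", "stock_mg_ha",
                                   "bias_mg_ha")],
       losses = losses, decay = decay)
}

#' Reference stock magnitudes anchoring the generator defaults
#'
#' Per-interval mean SOC stocks (Mg C ha^-1) and cluster-paired absolute
#' (Mg C ha^-1) and relative (%) differences from the published field study
#' of secondary-forest-to-rubber conversion whose design the synthetic
#' generator emulates. These published means parameterise
#' [synthetic_config()] and provide arithmetic consistency checks (interval
#' stocks summing to profile totals, loss partitioning across depths).
#'
#' @return A tibble with columns `interval`, `rubber_mg_ha`, `forest_mg_ha`,
#'   `abs_diff_mg_ha`, `rel_diff_pct`, including a `"total"` row.
#' @export
reference_stock_table <- function() {
  tibble::tibble(
    interval = c(canonical_depths()$interval, "total"),
    rubber_mg_ha = c(30.3, 29.8, 43.6, 28.0, 23.2, 154.9),
    forest_mg_ha = c(43.9, 38.9, 52, 35.2, 26.0, 196.0),
    abs_diff_mg_ha = c(-11.8, -8.2, -8.0, -6.5, -2.9, -37.4),
    rel_diff_pct = c(-26.9, -21.4, -15.4, -16.0, -11.2, -19.3)
  )
}
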