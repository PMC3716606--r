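#' Canonical depth intervals of the sampling design
#'
#' The study design samples five fixed depth intervals down to 1.2 m:
#' 0--0.15, 0.15--0.3, 0.3--0.6, 0.6--0.9 and 0.9--1.2 m. Intervals are
#' encoded as two numeric columns (`top_m`, `bottom_m`), half-open
#' `[top, bottom)`, in meters below the mineral soil surface.
#'
#' @return A tibble with columns `top_m`, `bottom_m`, `interval`
#'   (a label such as `"0-0.15"`) and `thickness_m`.
#' @export
#' @examples
#' canonical_depths()
canonical_depths <- function() {
  tops <- c(0, 0.15, 0.3, 0.6, 0.9)
  bottoms <- c(0.15, 0.3, 0.6, 0.9, 1.2)
  tibble::tibble(
    top_m = tops,
    bottom_m = bottoms,
    interval = interval_label(tops, bottoms),
    thickness_m = bottoms - tops
  )
}

#' @keywords internal
interval_label <- function(top_m, bottom_m) {
  fmt <- function(x) sub("\\.?0+$", "", formatC(x, format = "f", digits = 2))
  paste0(fmt(top_m), "-", fmt(bottom_m))
}

abort_schema <- function(msg, class) {
  rlang::abort(msg, class = c(class, "socchrono_error"))
}

`%||%` <- rlang::`%||%`

# ---- per-table validators ---------------------------------------------------

req_cols <- function(df, cols, table) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort_schema(
      sprintf("%s: missing column(s): %s", table, paste(missing, collapse = ", ")),
      "socchrono_schema_error"
    )
  }
}

validate_plots <- function(plots, age_range = c(1, 60)) {
  req_cols(plots, c("plot_id", "cluster_id", "land_use", "age_years",
                    "altitude_m", "slope_pct", "plot_area_m2"), "plots")
  if (nrow(plots) == 0) {
    abort_schema("plots: table is empty", "socchrono_schema_error")
  }
  plots <- tibble::as_tibble(plots)
  plots$plot_id <- as.character(plots$plot_id)
  plots$cluster_id <- as.character(plots$cluster_id)
  if (anyDuplicated(plots$plot_id)) {
    abort_schema("plots: duplicated plot_id", "socchrono_schema_error")
  }
  if (!all(plots$land_use %in% c("forest", "rubber"))) {
    abort_schema("plots: land_use must be 'forest' or 'rubber'",
                 "socchrono_invariant_error")
  }
  is_rubber <- plots$land_use == "rubber"
  if (any(is_rubber & is.na(plots$age_years))) {
    abort_schema("plots: age_years required for rubber plots",
                 "socchrono_invariant_error")
  }
  age <- plots$age_years[is_rubber]
  if (any(age < age_range[1] | age > age_range[2])) {
    abort_schema(
      sprintf("plots: rubber age_years outside plausible range [%g, %g]",
              age_range[1], age_range[2]),
      "socchrono_invariant_error"
    )
  }
  if (any(plots$plot_area_m2 <= 0, na.rm = TRUE)) {
    abort_schema("plots: plot_area_m2 must be positive",
                 "socchrono_invariant_error")
  }
  # design: each cluster has exactly one forest plot and 1-3 rubber plots
  by_cl <- split(plots$land_use, plots$cluster_id)
  for (cl in names(by_cl)) {
    n_forest <- sum(by_cl[[cl]] == "forest")
    n_rubber <- sum(by_cl[[cl]] == "rubber")
    if (n_forest != 1) {
      abort_schema(
        sprintf("cluster '%s': needs exactly one forest plot (found %d)",
                cl, n_forest),
        "socchrono_design_error"
      )
    }
    if (n_rubber < 1 || n_rubber > 3) {
      abort_schema(
        sprintf("cluster '%s': needs 1-3 rubber plots (found %d)", cl, n_rubber),
        "socchrono_design_error"
      )
    }
  }
  plots[order(plots$cluster_id, plots$land_use, plots$plot_id), ]
}

validate_horizons <- function(horizons, plots, depths = canonical_depths()) {
  horizons <- tibble::as_tibble(horizons)
  # accept separate silt/clay columns and sum them on load
  if (all(c("silt_pct", "clay_pct") %in% names(horizons)) &&
      !"silt_clay_pct" %in% names(horizons)) {
    horizons$silt_clay_pct <- horizons$silt_pct + horizons$clay_pct
  }
  req_cols(horizons, c("plot_id", "top_m", "bottom_m", "c_pct", "n_pct",
                       "bd_g_cm3", "sand_pct", "silt_clay_pct"), "horizons")
  if (nrow(horizons) == 0) {
    abort_schema("horizons: table is empty", "socchrono_schema_error")
  }
  horizons$plot_id <- as.character(horizons$plot_id)
  for (opt in c("ph_h2o", "ph_kcl", "ecec_mmolc_kg", "base_sat_pct")) {
    if (!opt %in% names(horizons)) horizons[[opt]] <- NA_real_
  }
  orphan <- setdiff(horizons$plot_id, plots$plot_id)
  if (length(orphan) > 0) {
    abort_schema(
      sprintf("horizons: plot_id without PlotRecord: %s",
              paste(orphan, collapse = ", ")),
      "socchrono_schema_error"
    )
  }
  bad_c <- !is.na(horizons$c_pct) & (horizons$c_pct < 0 | horizons$c_pct > 60)
  if (any(bad_c)) {
    abort_schema("horizons: c_pct outside [0, 60]", "socchrono_invariant_error")
  }
  bad_bd <- is.na(horizons$bd_g_cm3) | horizons$bd_g_cm3 < 0.2 |
    horizons$bd_g_cm3 > 2.2
  if (any(bad_bd)) {
    abort_schema("horizons: bd_g_cm3 outside [0.2, 2.2]",
                 "socchrono_invariant_error")
  }
  tex <- horizons$sand_pct + horizons$silt_clay_pct
  if (any(abs(tex - 100) > 0.5, na.rm = TRUE)) {
    abort_schema("horizons: sand_pct + silt_clay_pct must equal 100 within 0.5",
                 "socchrono_invariant_error")
  }
  # each plot must carry the canonical depth set with no gaps or overlaps
  for (pid in unique(horizons$plot_id)) {
    h <- horizons[horizons$plot_id == pid, ]
    h <- h[order(h$top_m), ]
    if (any(h$top_m >= h$bottom_m) || any(h$top_m < 0)) {
      abort_schema(sprintf("plot '%s': invalid depth interval", pid),
                   "socchrono_profile_error")
    }
    if (nrow(h) != nrow(depths) ||
        !isTRUE(all.equal(h$top_m, depths$top_m, tolerance = 1e-9)) ||
        !isTRUE(all.equal(h$bottom_m, depths$bottom_m, tolerance = 1e-9))) {
      abort_schema(
        sprintf("plot '%s': profile does not match the canonical depth set (gaps, overlaps or missing intervals)", pid),
        "socchrono_profile_error"
      )
    }
  }
  horizons[order(horizons$plot_id, horizons$top_m), ]
}

validate_litter <- function(litter, plots) {
  req_cols(litter, c("plot_id", "sample_id", "mass_g", "frame_area_m2",
                     "c_pct", "n_pct"), "litter")
  litter <- tibble::as_tibble(litter)
  litter$plot_id <- as.character(litter$plot_id)
  orphan <- setdiff(litter$plot_id, plots$plot_id)
  if (length(orphan) > 0) {
    abort_schema(
      sprintf("litter: plot_id without PlotRecord: %s",
              paste(orphan, collapse = ", ")),
      "socchrono_schema_error"
    )
  }
  if (any(litter$mass_g < 0, na.rm = TRUE)) {
    abort_schema("litter: mass_g must be >= 0", "socchrono_invariant_error")
  }
  if (any(litter$frame_area_m2 <= 0, na.rm = TRUE)) {
    abort_schema("litter: frame_area_m2 must be > 0",
                 "socchrono_invariant_error")
  }
  litter[order(litter$plot_id, litter$sample_id), ]
}

validate_trees <- function(trees, plots, forest_dbh_min_cm = 4) {
  req_cols(trees, c("plot_id", "stem_kind", "dbh_cm", "stems_in_clump"),
           "trees")
  trees <- tibble::as_tibble(trees)
  trees$plot_id <- as.character(trees$plot_id)
  orphan <- setdiff(trees$plot_id, plots$plot_id)
  if (length(orphan) > 0) {
    abort_schema(
      sprintf("trees: plot_id without PlotRecord: %s",
              paste(orphan, collapse = ", ")),
      "socchrono_schema_error"
    )
  }
  if (!all(trees$stem_kind %in% c("tree", "bamboo_clump"))) {
    abort_schema("trees: stem_kind must be 'tree' or 'bamboo_clump'",
                 "socchrono_invariant_error")
  }
  if (any(trees$dbh_cm <= 0, na.rm = TRUE)) {
    abort_schema("trees: dbh_cm must be > 0", "socchrono_invariant_error")
  }
  if (any(trees$stems_in_clump < 1, na.rm = TRUE)) {
    abort_schema("trees: stems_in_clump must be >= 1",
                 "socchrono_invariant_error")
  }
  # forest inventories only record trees above the DBH threshold
  forest_ids <- plots$plot_id[plots$land_use == "forest"]
  drop <- trees$plot_id %in% forest_ids & trees$stem_kind == "tree" &
    trees$dbh_cm <= forest_dbh_min_cm
  if (any(drop)) {
    rlang::warn(sprintf(
      "trees: dropping %d forest tree(s) at or below the %g cm DBH threshold",
      sum(drop), forest_dbh_min_cm
    ))
    trees <- trees[!drop, ]
  }
  trees[order(trees$plot_id, trees$stem_kind, trees$dbh_cm), ]
}

# ---- study bundle -----------------------------------------------------------

#' Read and validate a paired-plot SOC study
#'
#' Assembles the four input tables (plots, soil horizons, litter samples,
#' tree inventory) into a validated study bundle. All downstream functions
#' consume this bundle. Validation enforces the clustered design (each
#' cluster has exactly one reference forest plot and one to three rubber
#' plots), the canonical depth set without gaps or overlaps, physical bounds
#' on measurements, and cross-table referential integrity.
#'
#' @param x Either a named list of data frames
#'   (`plots`, `horizons`, `litter`, `trees`), a directory containing
#'   `plots.csv`, `horizons.csv`, `litter.csv` and `trees.csv`, or a named
#'   list/vector of file paths with those four names.
#' @param age_range Plausible plantation-age range in years used to validate
#'   rubber plot ages.
#' @param forest_dbh_min_cm Minimum DBH (cm) retained for trees on forest
#'   plots; smaller stems are dropped with a warning.
#'
#' @return An object of class `soc_study`: a list with validated tibbles
#'   `plots`, `horizons`, `litter`, `trees` and the `depths` table.
#' @export
#' @examples
#' study <- generate_study(synthetic_config(), seed = 1)$study
#' dir <- tempfile(); write_study(study, dir)
#' study2 <- read_study(dir)
read_study <- function(x, age_range = c(1, 60), forest_dbh_min_cm = 4) {
  if (is.character(x) && length(x) == 1 && dir.exists(x)) {
    x <- file.path(x, c(plots = "plots.csv", horizons = "horizons.csv",
                        litter = "litter.csv", trees = "trees.csv"))
    names(x) <- c("plots", "horizons", "litter", "trees")
  }
  if (is.character(x)) {
    req <- c("plots", "horizons", "litter", "trees")
    if (!all(req %in% names(x))) {
      abort_schema("read_study: paths must be named plots, horizons, litter, trees",
                   "socchrono_schema_error")
    }
    missing <- x[!file.exists(x)]
    if (length(missing) > 0) {
      abort_schema(sprintf("read_study: file not found: %s",
                           paste(missing, collapse = ", ")),
                   "socchrono_schema_error")
    }
    x <- lapply(x[req], function(p) {
      readr::read_csv(p, show_col_types = FALSE, progress = FALSE)
    })
  }
  plots <- validate_plots(x$plots, age_range = age_range)
  horizons <- validate_horizons(x$horizons, plots)
  litter <- validate_litter(x$litter, plots)
  trees <- validate_trees(x$trees, plots, forest_dbh_min_cm = forest_dbh_min_cm)
  structure(
    list(plots = plots, horizons = horizons, litter = litter, trees = trees,
         depths = canonical_depths()),
    class = "soc_study"
  )
}

#' Write a study bundle to CSV files
#'
#' Writes `plots.csv`, `horizons.csv`, `litter.csv` and `trees.csv` into
#' `dir`. `read_study(dir)` re-reads them to an identical bundle.
#'
#' @param study A `soc_study` bundle.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths of the written files.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "soc_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("plots.csv", "horizons.csv", "litter.csv",
                            "trees.csv"))
  names(paths) <- c("plots", "horizons", "litter", "trees")
  for (nm in names(paths)) {
    readr::write_csv(study[[nm]], paths[[nm]], na = "")
  }
  invisible(paths)
}

#' @export
print.soc_study <- function(x, ...) {
  n_cl <- length(unique(x$plots$cluster_id))
  cat(sprintf(
    "<soc_study> %d clusters, %d plots (%d forest, %d rubber), %d horizon rows\n",
    n_cl, nrow(x$plots), sum(x$plots$land_use == "forest"),
    sum(x$plots$land_use == "rubber"), nrow(x$horizons)
  ))
  invisible(x)
}

#' Read a run configuration file
#'
#' Reads a YAML run configuration with input paths, analysis options and the
#' random seed, filling defaults for missing entries.
#'
#' @param path Path to a YAML file.
#' @return A named list with elements `inputs`, `output_dir`, `seed`,
#'   `bd_correction`, `variance_by_landuse`, `pairing_level`,
#'   `fit_intervals`, `curve_threshold`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(
    inputs = NULL,
    output_dir = ".",
    seed = 1L,
    bd_correction = TRUE,
    variance_by_landuse = FALSE,
    pairing_level = "plot",
    fit_intervals = c("0-0.15", "0.15-0.3", "0.3-0.6"),
    curve_threshold = 0.5
  )
  utils::modifyList(defaults, cfg)
}
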