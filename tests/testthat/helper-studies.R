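# Small fixture builders used across the suite. Everything is generated in
# code; no data files are read.

depths_tbl <- canonical_depths()

# a minimal valid study: `n_clusters` clusters, each with one forest plot and
# `n_rubber` rubber plots, constant measurements unless overridden
tiny_study_tables <- function(n_clusters = 2, n_rubber = 1,
                              forest_c = 2, rubber_c = 1.5,
                              forest_bd = 1.0, rubber_bd = 1.0,
                              ages = NULL) {
  plots <- list(); horizons <- list(); litter <- list(); trees <- list()
  age_seq <- ages %||% rep(10, n_clusters * n_rubber)
  i <- 0
  for (ci in seq_len(n_clusters)) {
    cl <- paste0("C", ci)
    ids <- c(paste0(cl, "_F"), paste0(cl, "_R", seq_len(n_rubber)))
    lus <- c("forest", rep("rubber", n_rubber))
    for (j in seq_along(ids)) {
      pid <- ids[j]
      is_f <- lus[j] == "forest"
      if (!is_f) i <- i + 1
      plots[[pid]] <- data.frame(
        plot_id = pid, cluster_id = cl, land_use = lus[j],
        age_years = if (is_f) NA_real_ else age_seq[i],
        altitude_m = 760, slope_pct = 30, plot_area_m2 = 400
      )
      horizons[[pid]] <- data.frame(
        plot_id = pid, top_m = depths_tbl$top_m, bottom_m = depths_tbl$bottom_m,
        c_pct = if (is_f) forest_c else rubber_c,
        n_pct = 0.15, bd_g_cm3 = if (is_f) forest_bd else rubber_bd,
        sand_pct = 32, silt_clay_pct = 68,
        ph_h2o = 4.8, ph_kcl = 3.9, ecec_mmolc_kg = NA_real_,
        base_sat_pct = NA_real_
      )
      litter[[pid]] <- data.frame(
        plot_id = pid, sample_id = 1:3, mass_g = 20, frame_area_m2 = 0.04,
        c_pct = 40, n_pct = 0.9
      )
      trees[[pid]] <- data.frame(
        plot_id = pid, stem_kind = "tree", dbh_cm = 20, stems_in_clump = 1
      )
    }
  }
  list(plots = do.call(rbind, plots), horizons = do.call(rbind, horizons),
       litter = do.call(rbind, litter), trees = do.call(rbind, trees))
}

tiny_study <- function(...) read_study(tiny_study_tables(...))

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent Holm oracle: sort, cumulative max of scaled p, cap at 1
holm_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- cummax(pmin((n - seq_len(n) + 1) * p[o], 1))
  out <- numeric(n)
  out[o] <- adj
  out
}
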