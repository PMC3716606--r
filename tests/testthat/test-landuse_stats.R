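test_that("Holm adjustment matches the hand example and a brute-force oracle", {
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.20), "holm"),
               c(0.03, 0.04, 0.20))
  expect_equal(stats::p.adjust(rep(1, 5), "holm"), rep(1, 5))
  expect_equal(stats::p.adjust(0.037, "holm"), 0.037)
  set.seed(31)
  for (i in 1:50) {
    p <- runif(sample(1:10, 1))
    expect_equal(stats::p.adjust(p, "holm"), holm_brute(p))
  }
})

test_that("spearman_test uses mid-ranks and sensible p-values", {
  st <- spearman_test(1:6, (1:6)^3)
  expect_equal(st$rho, 1)
  expect_equal(spearman_test(c(1, 2, 3, 4), c(2, 1, 4, 3))$rho, 0.6)
  # rho equals the Pearson correlation of mid-ranks, ties included
  set.seed(8)
  for (i in 1:30) {
    x <- sample(1:6, 12, replace = TRUE)
    y <- sample(1:6, 12, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(spearman_test(x, y)$rho, cor(rank(x), rank(y)),
                 tolerance = 1e-12)
  }
  # constant column: rho undefined, reported missing
  st0 <- spearman_test(rep(1, 5), 1:5)
  expect_true(is.na(st0$rho) && is.na(st0$p_value))
  # too few complete cases: no p-value
  expect_true(is.na(spearman_test(c(1, 2, NA), c(2, NA, 1))$p_value))
})

test_that("the mixed model recovers a uniform land-use effect", {
  # balanced design, homoscedastic noise: contrasts match paired cluster means
  tabs <- tiny_study_tables(n_clusters = 6, n_rubber = 1)
  set.seed(20)
  noise <- rnorm(nrow(tabs$horizons), 0, 0.02)
  tabs$horizons$c_pct <- tabs$horizons$c_pct + noise
  study <- read_study(tabs)
  st <- compute_stocks(study)
  fit <- fit_landuse_model(st)
  ctr <- depth_contrasts(fit)
  expect_equal(nrow(ctr), 5)
  expect_true(all(ctr$p_holm >= ctr$p_raw - 1e-15))

  paired <- sapply(split(st, st$interval), function(d) {
    mean(sapply(split(d, d$cluster_id), function(cl) {
      mean(cl$stock_mg_ha[cl$land_use == "rubber"]) -
        cl$stock_mg_ha[cl$land_use == "forest"]
    }))
  })
  expect_equal(ctr$estimate, unname(paired[ctr$interval]), tolerance = 1e-6)
})

test_that("a constant response yields zero effect estimates", {
  study <- tiny_study(n_clusters = 4, forest_c = 2, rubber_c = 2)
  st <- compute_stocks(study)
  fit <- fit_landuse_model(st)
  ctr <- depth_contrasts(fit)
  expect_equal(ctr$estimate, rep(0, 5), tolerance = 1e-8)
})

test_that("depth-dependent losses produce a significant interaction", {
  hits <- 0
  for (s in 1:10) {
    cfg <- synthetic_config(Xe_pct = c(60, 70, 95, 100, 100))
    gs <- generate_study(cfg, seed = 100 + s)
    st <- compute_stocks(gs$study)
    fit <- fit_landuse_model(st)
    an <- stats::anova(fit$model)
    p_int <- an[["p-value"]][rownames(an) == "land_use:interval"]
    if (p_int <= 0.05) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("single-cluster data advises a fixed-effects fallback", {
  st <- data.frame(cluster_id = "C1",
                   land_use = rep(c("forest", "rubber"), each = 5),
                   interval = rep(depths_tbl$interval, 2),
                   stock_mg_ha = rnorm(10, 30))
  expect_error(fit_landuse_model(st), "fixed-effects",
               class = "socchrono_design_error")
})

test_that("requesting a contrast for an absent interval errors", {
  gs <- generate_study(synthetic_config(), seed = 15)
  fit <- fit_landuse_model(compute_stocks(gs$study))
  expect_error(depth_contrasts(fit, intervals = "1.2-1.5"),
               class = "socchrono_domain_error")
})

test_that("the variance function changes the residual model, not the design", {
  gs <- generate_study(synthetic_config(), seed = 2)
  st <- compute_stocks(gs$study)
  f1 <- fit_landuse_model(st, variance_by_landuse = FALSE)
  f2 <- fit_landuse_model(st, variance_by_landuse = TRUE)
  c1 <- depth_contrasts(f1)
  c2 <- depth_contrasts(f2)
  # same contrasts tested, broadly similar estimates, different SEs allowed
  expect_equal(c1$interval, c2$interval)
  expect_equal(c1$estimate, c2$estimate, tolerance = 0.2)
})

test_that("correlation screen reproduces the designed age-basal-area link", {
  gs <- generate_study(synthetic_config(), seed = 6)
  summ <- plot_summaries(gs$study)
  rub <- summ[summ$land_use == "rubber", ]
  st <- spearman_test(rub$age_years, rub$total_ba_m2_ha)
  expect_gt(st$rho, 0.85)
  expect_lt(st$p_value, 0.001)

  scr <- correlation_screen(gs$study)
  expect_setequal(unique(scr$stratum),
                  c("rubber_c_pct", "forest_c_pct", "relative_difference"))
  expect_true(all(abs(scr$rho) <= 1, na.rm = TRUE))
  expect_true(all(scr$n[scr$stratum == "rubber_c_pct"] == 11))
  expect_true(all(scr$n[scr$stratum == "forest_c_pct"] == 7))
  # forest stratum never sees plantation age
  expect_false("age_years" %in%
                 scr$covariate[scr$stratum == "forest_c_pct"])
  # pairing level controls the n of the difference rows
  scr_cl <- correlation_screen(gs$study, pairing_level = "cluster")
  expect_true(all(scr_cl$n[scr_cl$stratum == "relative_difference"] == 7))
})
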