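test_that("interval_stock matches hand arithmetic and rejects bad inputs", {
  expect_equal(interval_stock(0, 1.3, 0.3, 0.6), 0)
  expect_equal(interval_stock(2.0, 1.0, 0, 0.15), 30.0)
  expect_equal(interval_stock(1.0, 1.5, 0.3, 0.6), 45.0)
  expect_error(interval_stock(-1, 1, 0, 0.15), class = "socchrono_domain_error")
  expect_error(interval_stock(1, 0, 0, 0.15), class = "socchrono_domain_error")
  expect_error(interval_stock(1, 1, 0.3, 0.2), class = "socchrono_domain_error")
})

test_that("interval_stock is linear in concentration and bulk density", {
  set.seed(42)
  for (i in 1:20) {
    c0 <- runif(1, 0.1, 5); bd <- runif(1, 0.8, 1.6); a <- runif(1, 0.1, 4)
    base <- interval_stock(c0, bd, 0.15, 0.3)
    expect_equal(interval_stock(a * c0, bd, 0.15, 0.3), a * base)
    expect_equal(interval_stock(c0, a * bd, 0.15, 0.3), a * base)
  }
})

test_that("profile_stocks sums intervals and honours the BD source", {
  h <- data.frame(plot_id = "p", top_m = depths_tbl$top_m,
                  bottom_m = depths_tbl$bottom_m, c_pct = 1, bd_g_cm3 = 1)
  p <- profile_stocks(h)
  expect_equal(attr(p, "total"), 120)
  expect_equal(p$stock_mg_ha, depths_tbl$thickness_m * 100)
  expect_equal(sum(p$stock_mg_ha), attr(p, "total"), tolerance = 1e-9)
  expect_true(all(p$bd_source == "own"))

  # reference BD +10% in topsoil scales the corrected topsoil stock by 1.1
  ref <- data.frame(top_m = depths_tbl$top_m, bottom_m = depths_tbl$bottom_m,
                    bd_g_cm3 = c(1.1, 1, 1, 1, 1))
  pc <- profile_stocks(h, reference_bd = ref)
  expect_true(all(pc$bd_source == "reference"))
  expect_equal(pc$stock_mg_ha[1], p$stock_mg_ha[1] * 1.1)
  expect_equal(pc$stock_mg_ha[-1], p$stock_mg_ha[-1])

  # mismatched reference profile is a configuration error
  expect_error(profile_stocks(h, reference_bd = ref[-1, ]),
               class = "socchrono_config_error")
})

test_that("correction equals identity when rubber BD equals forest BD", {
  study <- tiny_study(forest_bd = 1.2, rubber_bd = 1.2)
  corr <- compute_stocks(study, bd_correction = TRUE)
  unc <- compute_stocks(study, bd_correction = FALSE)
  expect_identical(corr$stock_mg_ha, unc$stock_mg_ha)
})

test_that("rubber with forest C and forest BD reproduces the forest profile", {
  study <- tiny_study(forest_c = 2, rubber_c = 2, forest_bd = 1.1,
                      rubber_bd = 1.4)
  st <- compute_stocks(study, bd_correction = TRUE)
  f <- st$stock_mg_ha[st$plot_id == "C1_F"]
  r <- st$stock_mg_ha[st$plot_id == "C1_R1"]
  expect_equal(r, f)
})

test_that("profile totals agree with a brute-force fine re-partition", {
  gs <- generate_study(synthetic_config(), seed = 5)
  st <- compute_stocks(gs$study, bd_correction = FALSE)
  h <- gs$study$horizons
  set.seed(99)
  for (pid in sample(unique(h$plot_id), 4)) {
    hp <- h[h$plot_id == pid, ]
    brute <- 0
    for (i in seq_len(nrow(hp))) {
      # split each interval at random internal points; C and BD constant within
      cuts <- sort(c(hp$top_m[i], runif(5, hp$top_m[i], hp$bottom_m[i]),
                     hp$bottom_m[i]))
      brute <- brute + sum(interval_stock(hp$c_pct[i], hp$bd_g_cm3[i],
                                          head(cuts, -1), tail(cuts, -1)))
    }
    tot <- sum(st$stock_mg_ha[st$plot_id == pid])
    expect_equal(tot, brute, tolerance = 1e-9)
  }
})

test_that("cluster_changes pairs rubber means against the forest plot", {
  # forest c=2 (total 240 over 1.2 m at bd 1), rubber c=1.5 -> -25% everywhere
  study <- tiny_study(n_clusters = 2, n_rubber = 2)
  st <- compute_stocks(study)
  ch <- cluster_changes(st)
  expect_equal(nrow(ch), 2 * 6)
  expect_equal(ch$rel_pct, rep(-25, nrow(ch)))
  tot <- ch[ch$interval == "total", ]
  expect_equal(tot$abs_mg_ha, rep(-60, 2)) # 240 * 25%

  # rubber identical to forest -> all zero
  null_study <- tiny_study(rubber_c = 2)
  ch0 <- cluster_changes(compute_stocks(null_study))
  expect_true(all(ch0$abs_mg_ha == 0) && all(ch0$rel_pct == 0))
})

test_that("cluster_changes averages rubber plots before differencing", {
  tabs <- tiny_study_tables(n_clusters = 2, n_rubber = 2)
  # cluster C1: forest total 200, rubber totals 150 and 170 -> -40, -20%
  tabs$horizons$c_pct[tabs$horizons$plot_id == "C1_F"] <- 200 / 120
  tabs$horizons$c_pct[tabs$horizons$plot_id == "C1_R1"] <- 150 / 120
  tabs$horizons$c_pct[tabs$horizons$plot_id == "C1_R2"] <- 170 / 120
  st <- compute_stocks(read_study(tabs))
  ch <- cluster_changes(st)
  tot1 <- ch[ch$cluster_id == "C1" & ch$interval == "total", ]
  expect_equal(tot1$abs_mg_ha, -40)
  expect_equal(tot1$rel_pct, -20)

  # invariant to rubber plot order
  st_rev <- st[rev(seq_len(nrow(st))), ]
  ch_rev <- cluster_changes(st_rev)
  expect_equal(as.data.frame(ch_rev), as.data.frame(ch), ignore_attr = TRUE)
})

test_that("summarize_changes computes means and SEs over clusters", {
  study <- tiny_study(n_clusters = 3)
  st <- compute_stocks(study)
  ch <- cluster_changes(st)
  # identical clusters -> SE 0
  s <- summarize_changes(ch)
  expect_true(all(s$abs_se == 0))
  expect_equal(s$rel_mean, rep(-25, 6))

  # hand SE: totals {-30, -40, -50} -> mean -40, SE 5.7735
  ch2 <- ch
  tot_rows <- which(ch2$interval == "total")
  ch2$abs_mg_ha[tot_rows] <- c(-30, -40, -50)
  s2 <- summarize_changes(ch2)
  expect_equal(s2$abs_mean[s2$interval == "total"], -40)
  expect_equal(s2$abs_se[s2$interval == "total"], 10 / sqrt(3),
               tolerance = 1e-9)

  expect_error(summarize_changes(ch[ch$cluster_id == "C1", ]),
               class = "socchrono_domain_error")
})

test_that("litter_stock scales frames to the hectare", {
  expect_equal(litter_stock(data.frame(mass_g = 0, frame_area_m2 = 0.04,
                                       c_pct = 40, n_pct = 1))$litter_c_mg_ha,
               0)
  # 10 g dry mass at 40% C on 0.04 m2 -> 100 g C m-2 -> 1 Mg C ha-1
  one <- litter_stock(data.frame(mass_g = 10, frame_area_m2 = 0.04,
                                 c_pct = 40, n_pct = 1))
  expect_equal(one$litter_c_mg_ha, 1.0)
  ten <- litter_stock(data.frame(mass_g = rep(10, 10), frame_area_m2 = 0.04,
                                 c_pct = 40, n_pct = 1))
  expect_equal(ten$litter_c_mg_ha, 1.0)
  expect_equal(ten$litter_c_se, 0)
  expect_equal(ten$litter_cn, 40)
  expect_error(litter_stock(data.frame(mass_g = 1, frame_area_m2 = 0,
                                       c_pct = 40, n_pct = 1)),
               class = "socchrono_domain_error")
})

test_that("basal_areas separates trees from bamboo and scales by area", {
  none <- basal_areas(data.frame(stem_kind = character(0),
                                 dbh_cm = numeric(0),
                                 stems_in_clump = integer(0)), 400)
  expect_equal(unlist(none), c(tree_ba_m2_ha = 0, total_ba_m2_ha = 0))

  one <- basal_areas(data.frame(stem_kind = "tree", dbh_cm = 20,
                                stems_in_clump = 1), 400)
  expect_equal(one$tree_ba_m2_ha, pi * 0.01 * 25, tolerance = 1e-12)
  expect_equal(one$total_ba_m2_ha, one$tree_ba_m2_ha)

  clump <- basal_areas(data.frame(stem_kind = "bamboo_clump", dbh_cm = 5,
                                  stems_in_clump = 10), 400)
  expect_equal(clump$tree_ba_m2_ha, 0)
  expect_equal(clump$total_ba_m2_ha, 10 * pi * 6.25e-4 * 25, tolerance = 1e-12)
})

test_that("uncorrected stocks understate losses when rubber soil is denser", {
  study <- tiny_study(forest_bd = 1.0, rubber_bd = 1.1)
  cmp <- bd_correction_comparison(study)
  expect_true(all(cmp$rel_uncorrected > cmp$rel_corrected))
  # zero shift -> exact agreement
  study0 <- tiny_study(forest_bd = 1.0, rubber_bd = 1.0)
  cmp0 <- bd_correction_comparison(study0)
  expect_identical(cmp0$rel_uncorrected, cmp0$rel_corrected)
})
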