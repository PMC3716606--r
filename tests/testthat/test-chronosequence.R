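test_that("decay curves honour their anchors and limits", {
  expect_equal(mono_exp(0, 68, 0.2), 100)
  expect_equal(mono_exp(0, 50, 3), 100)
  expect_equal(mono_exp(1e6, 68, 0.2), 68)
  expect_equal(mono_exp(5, 68, 0.2), 68 + 32 * exp(-1))
  expect_equal(bi_exp(0, 30, 1, 0.01), 100)
  # equal pool rates collapse to a single exponential
  tt <- seq(0, 50, by = 5)
  expect_equal(bi_exp(tt, 30, 0.2, 0.2), 100 * exp(-0.2 * tt))
  expect_equal(bi_exp(tt, 100, 0.5, 0.01), 100 * exp(-0.5 * tt))
})

test_that("mono_exp is monotone decreasing iff k > 0 and Xe < 100", {
  tt <- seq(0, 60, by = 0.5)
  set.seed(7)
  for (i in 1:25) {
    Xe <- runif(1, 10, 130)
    k <- runif(1, 0.01, 2)
    y <- mono_exp(tt, Xe, k)
    if (Xe < 100) {
      expect_true(all(diff(y) <= 0) && y[2] < y[1])
    } else if (Xe > 100) {
      expect_true(all(diff(y) >= 0) && y[2] > y[1])
    }
  }
})

test_that("proportions express rubber stocks relative to the paired forest", {
  study <- tiny_study(n_clusters = 2, n_rubber = 2, forest_c = 2,
                      rubber_c = 1.5, ages = c(12, 20, 30, 40))
  st <- compute_stocks(study)
  pts <- proportions(st, "0-0.15")
  expect_equal(nrow(pts), 4)
  expect_equal(unique(pts$y), 75)
  expect_setequal(pts$t, c(12, 20, 30, 40))
  # rubber equal to forest -> y = 100
  pts0 <- proportions(compute_stocks(tiny_study(rubber_c = 2)), "0-0.15")
  expect_equal(unique(pts0$y), 100)
  expect_error(proportions(st, "5-6"), class = "socchrono_domain_error")
})

test_that("noiseless model-generated data is recovered exactly", {
  tt <- c(0, 5, 10, 20, 30, 46)
  fm <- fit_decay(data.frame(t = tt, y = mono_exp(tt, 68, 0.2)), "mono")
  expect_true(fm$converged)
  expect_equal(unname(fm$params["Xe"]), 68, tolerance = 1e-6)
  expect_equal(unname(fm$params["k"]), 0.2, tolerance = 1e-6)
  expect_equal(fm$r, 1, tolerance = 1e-9)

  tb <- c(0:10, 15, 20, 30, 46)
  fb <- fit_decay(data.frame(t = tb, y = bi_exp(tb, 30, 1.0, 0.01)), "bi")
  expect_true(fb$converged)
  expect_equal(unname(fb$params), c(30, 1.0, 0.01), tolerance = 1e-6)
})

test_that("a mono fit to two-pool data is systematically biased", {
  tb <- c(0:10, 15, 20, 30, 46)
  y <- bi_exp(tb, 40, 1.5, 0.005)
  fm <- fit_decay(data.frame(t = tb, y = y), "mono")
  fb <- fit_decay(data.frame(t = tb, y = y), "bi")
  expect_gt(fm$sse, fb$sse + 1)
  expect_gt(fm$sse, 1) # residuals are nonzero
})

test_that("too few points raise a fit error; non-convergence is a flag", {
  expect_error(fit_decay(data.frame(t = c(0, 5), y = c(100, 80)), "mono"),
               class = "socchrono_fit_error")
  expect_error(fit_decay(data.frame(t = c(0, 5, 9), y = c(100, 80, 70)), "bi"),
               class = "socchrono_fit_error")
})

test_that("steady_state_time closed form agrees with a grid scan", {
  # anchored example: Xe = 68, k = 0.2 -> about 19.3 yr
  ss <- steady_state_time(68, 0.2)
  expect_equal(ss$t_years, log(32 / 0.68) / 0.2, tolerance = 1e-12)
  expect_equal(ss$t_years, 19.26, tolerance = 1e-3)
  expect_equal(ss$y_at_t, 1.01 * 68)

  set.seed(123)
  grid_step <- 0.001
  for (i in 1:1000) {
    Xe <- runif(1, 5, 99)
    k <- runif(1, 0.02, 2)
    t_closed <- steady_state_time(Xe, k)$t_years
    tt <- seq(0, 400, by = grid_step)
    t_scan <- tt[which(mono_exp(tt, Xe, k) - Xe <= 0.01 * Xe)[1]]
    expect_lt(abs(t_closed - t_scan), grid_step + 1e-9)
  }

  # scaling law: doubling k halves t*
  expect_equal(steady_state_time(50, 0.4)$t_years,
               steady_state_time(50, 0.2)$t_years / 2)
  # no steady state without decay toward Xe < 100
  expect_false(steady_state_time(100, 0.2)$reachable)
  expect_false(steady_state_time(68, 0)$reachable)
})

test_that("model selection prefers parsimony unless two pools are needed", {
  tt <- c(0, 2, 4, 6, 9, 12, 15, 18, 22, 25, 30, 38, 46)
  set.seed(4)
  y_mono <- mono_exp(tt, 68, 0.2) + rnorm(length(tt), 0, 1)
  fm <- fit_decay(data.frame(t = tt, y = y_mono), "mono")
  fb <- fit_decay(data.frame(t = tt, y = y_mono), "bi")
  sel <- select_model(fm, fb)
  expect_equal(sel$model, "mono")

  # well-separated pools, many low-noise points -> bi wins
  t2 <- seq(0, 60, length.out = 40)
  set.seed(5)
  y_bi <- bi_exp(t2, 50, 1.0, 0.01) + rnorm(40, 0, 0.3)
  fm2 <- fit_decay(data.frame(t = t2, y = y_bi), "mono")
  fb2 <- fit_decay(data.frame(t = t2, y = y_bi), "bi")
  sel2 <- select_model(fm2, fb2)
  expect_equal(sel2$model, "bi")

  # indistinguishable curves -> mono by parsimony
  y_eq <- 100 * exp(-0.2 * tt)
  fm3 <- fit_decay(data.frame(t = tt, y = y_eq), "mono")
  fb3 <- fit_decay(data.frame(t = tt, y = y_eq), "bi")
  expect_equal(select_model(fm3, fb3)$model, "mono")
})

test_that("fit_decay leaves the caller's RNG state untouched", {
  tt <- c(0, 5, 10, 20, 30, 46)
  set.seed(1)
  before <- .Random.seed
  fit_decay(data.frame(t = tt, y = mono_exp(tt, 68, 0.2) + c(1, -1, 0, 1, -1, 0)),
            "mono", seed = 9)
  expect_identical(.Random.seed, before)
})
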