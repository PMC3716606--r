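#' One-pool exponential decay toward equilibrium
#'
#' Proportion of the initial carbon stock remaining `t` years after
#' conversion under a single-pool model that decays toward a new
#' equilibrium: `Xe + (X0 - Xe) * exp(-k * t)`, with the initial proportion
#' `X0` fixed at 100%.
#'
#' @param t Years since land-use change (vectorized).
#' @param Xe Equilibrium proportion, %.
#' @param k Decay rate, yr^-1.
#' @param X0 Initial proportion, % (default 100).
#' @return Proportion remaining, %.
#' @export
#' @examples
#' mono_exp(0, 68, 0.2)  # 100
#' mono_exp(5, 68, 0.2)  # 79.77
mono_exp <- function(t, Xe, k, X0 = 100) {
  Xe + (X0 - Xe) * exp(-k * t)
}

#' Two-pool (labile + stable) exponential decay
#'
#' `X1 * exp(-k1 * t) + (100 - X1) * exp(-k2 * t)`: a labile pool of size
#' `X1` % decaying at `k1` and a stable pool of size `100 - X1` % decaying
#' at `k2`. At `t = 0` the curve equals 100 by construction.
#'
#' @param t Years since land-use change (vectorized).
#' @param X1 Labile-pool proportion, % in `[0, 100]`.
#' @param k1,k2 Decay rates of the labile and stable pools, yr^-1.
#' @return Proportion remaining, %.
#' @export
bi_exp <- function(t, X1, k1, k2) {
  X1 * exp(-k1 * t) + (100 - X1) * exp(-k2 * t)
}

#' Proportion-of-forest-carbon points for decay fitting
#'
#' Expresses each rubber plot's stock in an interval as a percentage of its
#' cluster's reference forest stock in that interval, paired with the
#' plantation age. These (t, y) points are the input to [fit_decay()].
#'
#' @param stocks Per-interval stock table from [compute_stocks()]
#'   (bulk-density-corrected stocks are expected).
#' @param interval Interval label (e.g. `"0-0.15"`) or `"total"`.
#' @return A tibble with `plot_id`, `cluster_id`, `interval`, `t` (years)
#'   and `y` (% of forest stock). Points whose forest stock is zero are
#'   dropped with a warning.
#' @export
proportions <- function(stocks, interval = "0-0.15") {
  if (identical(interval, "total")) {
    long <- profile_totals(stocks)
    long$stock_mg_ha <- long$total_mg_ha
    long$interval <- "total"
  } else {
    long <- stocks[stocks$interval == interval, ]
    if (nrow(long) == 0) {
      abort_schema(sprintf("proportions: interval '%s' not present", interval),
                   "socchrono_domain_error")
    }
  }
  out <- purrr::map_dfr(split(long, long$cluster_id), function(cl) {
    f <- cl$stock_mg_ha[cl$land_use == "forest"][1]
    r <- cl[cl$land_use == "rubber", ]
    tibble::tibble(
      plot_id = r$plot_id, cluster_id = r$cluster_id, interval = interval,
      t = r$age_years, y = if (f == 0) NA_real_ else 100 * r$stock_mg_ha / f
    )
  })
  if (anyNA(out$y)) {
    rlang::warn("proportions: dropping points with zero forest stock")
    out <- out[!is.na(out$y), ]
  }
  out[order(out$t, out$plot_id), ]
}

# one Levenberg-Marquardt attempt; returns NULL on failure
try_nls <- function(pred_fun, pts, start, lower, upper) {
  par0 <- unlist(start)
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = par0, lower = lower[names(par0)], upper = upper[names(par0)],
      fn = function(p) pts$y - pred_fun(pts$t, p),
      control = minpack.lm::nls.lm.control(
        maxiter = 1000, ftol = 1e-15, ptol = 1e-15
      )
    ),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(fit) || !fit$info %in% 1:4) return(NULL)
  fit
}

# asymptotic (Gauss-Newton) standard errors from a nls.lm fit
wald_stats <- function(fit, n) {
  est <- fit$par
  p <- length(est)
  sse <- sum(fit$fvec^2)
  df <- n - p
  se <- rep(NA_real_, p)
  names(se) <- names(est)
  if (df > 0) {
    cv <- tryCatch(solve(fit$hessian) * sse / df, error = function(e) NULL)
    if (!is.null(cv)) {
      d <- diag(cv)
      se[d >= 0] <- sqrt(d[d >= 0])
    }
  }
  tval <- est / se
  pv <- 2 * stats::pt(-abs(tval), df = max(df, 1))
  list(est = est, se = se, p = pv, sse = sse)
}

#' Fit an exponential decay model to proportion points
#'
#' Nonlinear least-squares fit of the one-pool ([mono_exp()]) or two-pool
#' ([bi_exp()]) decay model to (t, y) proportion points, with the initial
#' proportion fixed at 100% by default. A small seeded multi-start (jittered
#' restarts around the start values) guards against local minima; the
#' converged fit with the lowest residual sum of squares is kept. Goodness
#' of fit is the Pearson correlation between observed and fitted values.
#'
#' @param points Data frame with columns `t` (years, >= 0) and `y`
#'   (proportion remaining, %), e.g. from [proportions()].
#' @param model `"mono"` or `"bi"`.
#' @param start Optional named list of start values (`Xe`, `k` for mono;
#'   `X1`, `k1`, `k2` for bi). Defaults: mono `Xe = min(y)`, `k = 0.1`;
#'   bi `X1 = 30`, `k1 = 0.3`, `k2 = 0.01`.
#' @param n_starts Number of jittered restarts (default 5).
#' @param fix_x0 Keep the initial proportion fixed at 100% (default `TRUE`);
#'   `FALSE` adds `X0` as a free parameter (mono only).
#' @param seed Integer seed for the restart jitter.
#' @return An object of class `soc_decay_fit`: a list with `model`,
#'   `params` (named estimates), `se`, `p_values` (Wald), `r`, `r_pvalue`,
#'   `steady_state_t` and `y_at_steady_state` (mono only), `converged`,
#'   `sse`, `n`, `fitted`, and the input `points`. Non-convergence is
#'   reported via `converged = FALSE`, not an error.
#' @export
#' @examples
#' pts <- data.frame(t = c(0, 5, 10, 20, 30, 46),
#'                   y = mono_exp(c(0, 5, 10, 20, 30, 46), 68, 0.2))
#' fit_decay(pts, "mono")
fit_decay <- function(points, model = c("mono", "bi"), start = NULL,
                      n_starts = 5, fix_x0 = TRUE, seed = 1L) {
  model <- match.arg(model)
  pts <- tibble::as_tibble(points)[, c("t", "y")]
  pts <- pts[stats::complete.cases(pts), ]
  n_par <- switch(model, mono = if (fix_x0) 2L else 3L, bi = 3L)
  if (nrow(pts) <= n_par) {
    abort_schema(sprintf(
      "fit_decay: %d points are too few for the %s model (%d free parameters)",
      nrow(pts), model, n_par
    ), "socchrono_fit_error")
  }

  if (model == "mono") {
    if (fix_x0) {
      pred_fun <- function(t, p) mono_exp(t, p[["Xe"]], p[["k"]])
      start0 <- list(Xe = min(pts$y), k = 0.1)
      lower <- c(Xe = 1e-8, k = 1e-8)
      upper <- c(Xe = 120, k = 5)
    } else {
      pred_fun <- function(t, p) mono_exp(t, p[["Xe"]], p[["k"]], p[["X0"]])
      start0 <- list(Xe = min(pts$y), k = 0.1, X0 = 100)
      lower <- c(Xe = 1e-8, k = 1e-8, X0 = 1e-8)
      upper <- c(Xe = 120, k = 5, X0 = 200)
    }
  } else {
    pred_fun <- function(t, p) bi_exp(t, p[["X1"]], p[["k1"]], p[["k2"]])
    start0 <- list(X1 = 30, k1 = 0.3, k2 = 0.01)
    lower <- c(X1 = 0, k1 = 1e-8, k2 = 1e-8)
    upper <- c(X1 = 100, k1 = 5, k2 = 5)
  }
  if (!is.null(start)) start0 <- utils::modifyList(start0, as.list(start))

  # multi-start: the plain start plus jittered restarts, best SSE wins
  starts <- list(start0)
  if (n_starts > 1) {
    jitter_rng <- local_rng(seed)
    for (i in seq_len(n_starts - 1)) {
      s <- lapply(start0, function(v) v * jitter_rng$runif(1, 0.5, 1.5))
      for (nm in names(s)) {
        s[[nm]] <- min(max(s[[nm]], lower[[nm]] * 1.01), upper[[nm]] * 0.99)
      }
      starts[[i + 1]] <- s
    }
  }
  fits <- lapply(starts, function(s) try_nls(pred_fun, pts, s, lower, upper))
  fits <- fits[!vapply(fits, is.null, logical(1))]

  if (length(fits) == 0) {
    return(structure(list(
      model = model, params = NULL, se = NULL, p_values = NULL,
      r = NA_real_, r_pvalue = NA_real_, steady_state_t = NA_real_,
      y_at_steady_state = NA_real_, converged = FALSE, sse = NA_real_,
      n = nrow(pts), fitted = NULL, points = pts
    ), class = "soc_decay_fit"))
  }
  sses <- vapply(fits, function(f) sum(f$fvec^2), numeric(1))
  best <- fits[[which.min(sses)]]
  ws <- wald_stats(best, nrow(pts))
  est <- ws$est
  se <- ws$se
  pv <- ws$p
  if (model == "bi" && est[["k2"]] > est[["k1"]]) {
    # canonical labelling: the labile pool is the faster one
    est <- c(X1 = 100 - est[["X1"]], k1 = est[["k2"]], k2 = est[["k1"]])
    se <- c(X1 = se[["X1"]], k1 = se[["k2"]], k2 = se[["k1"]])
    pv <- c(X1 = pv[["X1"]], k1 = pv[["k2"]], k2 = pv[["k1"]])
  }
  fitted_y <- pred_fun(pts$t, est)
  r <- NA_real_
  r_p <- NA_real_
  if (stats::sd(fitted_y) > 0 && stats::sd(pts$y) > 0) {
    ct <- stats::cor.test(pts$y, as.numeric(fitted_y))
    r <- unname(ct$estimate)
    r_p <- ct$p.value
  }
  ss_t <- NA_real_
  ss_y <- NA_real_
  if (model == "mono") {
    ss <- steady_state_time(est[["Xe"]], est[["k"]],
                            X0 = if (fix_x0) 100 else est[["X0"]])
    ss_t <- ss$t_years
    ss_y <- ss$y_at_t
  }
  structure(list(
    model = model, params = est, se = se, p_values = pv,
    r = r, r_pvalue = r_p, steady_state_t = ss_t, y_at_steady_state = ss_y,
    converged = TRUE, sse = ws$sse, n = nrow(pts),
    fitted = as.numeric(fitted_y), points = pts
  ), class = "soc_decay_fit")
}

#' @export
print.soc_decay_fit <- function(x, ...) {
  cat(sprintf("<soc_decay_fit> %s-exponential, n = %d, converged: %s\n",
              x$model, x$n, x$converged))
  if (x$converged) {
    for (nm in names(x$params)) {
      cat(sprintf("  %s = %.4g (SE %.3g, p = %.3g)\n",
                  nm, x$params[[nm]], x$se[[nm]], x$p_values[[nm]]))
    }
    cat(sprintf("  r = %.4f (p = %.3g)", x$r, x$r_pvalue))
    if (!is.na(x$steady_state_t)) {
      cat(sprintf("; steady state at %.1f yr (%.1f%% remaining)",
                  x$steady_state_t, x$y_at_steady_state))
    }
    cat("\n")
  }
  invisible(x)
}

#' Predict from a decay fit
#'
#' @param object A `soc_decay_fit`.
#' @param t Years at which to evaluate the fitted curve.
#' @param ... Unused.
#' @return Predicted proportion remaining, %.
#' @export
predict.soc_decay_fit <- function(object, t, ...) {
  if (!object$converged) {
    abort_schema("predict: fit did not converge", "socchrono_fit_error")
  }
  p <- as.list(object$params)
  if (object$model == "mono") {
    mono_exp(t, p$Xe, p$k, X0 = p$X0 %||% 100)
  } else {
    bi_exp(t, p$X1, p$k1, p$k2)
  }
}

#' Time to steady state of the one-pool model
#'
#' The steady-state time is the smallest `t` at which the remaining
#' proportion is within 1% of the equilibrium value `Xe`, i.e.
#' `X_t - Xe <= 0.01 * Xe`. For the one-pool model this has the closed form
#' `t* = ln((X0 - Xe) / (0.01 * Xe)) / k`, clamped at 0 when the criterion
#' already holds at `t = 0`.
#'
#' @param Xe Equilibrium proportion, % (0 < Xe < X0 required for a finite
#'   steady state).
#' @param k Decay rate, yr^-1 (> 0 required).
#' @param X0 Initial proportion, % (default 100).
#' @return A list with `t_years` (NA with `reachable = FALSE` when `k <= 0`
#'   or `Xe >= X0`), `y_at_t` (the proportion remaining at `t*`, equal to
#'   `1.01 * Xe` unless clamped), and `reachable`.
#' @export
#' @examples
#' steady_state_time(68, 0.2) # about 19.3 yr
steady_state_time <- function(Xe, k, X0 = 100) {
  if (!is.finite(Xe) || !is.finite(k) || k <= 0 || Xe >= X0 || Xe <= 0) {
    return(list(t_years = NA_real_, y_at_t = NA_real_, reachable = FALSE))
  }
  t_star <- log((X0 - Xe) / (0.01 * Xe)) / k
  t_star <- max(0, t_star)
  list(t_years = t_star, y_at_t = mono_exp(t_star, Xe, k, X0),
       reachable = TRUE)
}

#' Choose between the one-pool and two-pool fits
#'
#' Applies a parsimony rule: the one-pool model is preferred when any
#' two-pool decay rate is not significant at the 5% level, or when the two
#' fitted curves are practically indistinguishable (maximum absolute
#' difference over the observed ages below `curve_threshold` percentage
#' points). Otherwise the two-pool model is preferred.
#'
#' @param fit_mono,fit_bi `soc_decay_fit` objects fitted to the same points.
#' @param curve_threshold Curve-indistinguishability threshold in percentage
#'   points (default 0.5).
#' @param alpha Significance level for the two-pool decay rates.
#' @return A list with `chosen` (the selected `soc_decay_fit`), `model`, and
#'   `rationale` (a character explanation).
#' @export
select_model <- function(fit_mono, fit_bi, curve_threshold = 0.5,
                         alpha = 0.05) {
  if (!fit_mono$converged && !fit_bi$converged) {
    abort_schema("select_model: both fits failed to converge",
                 "socchrono_fit_error")
  }
  if (!fit_bi$converged) {
    return(list(chosen = fit_mono, model = "mono",
                rationale = "two-pool fit did not converge"))
  }
  if (!fit_mono$converged) {
    return(list(chosen = fit_bi, model = "bi",
                rationale = "one-pool fit did not converge"))
  }
  k_p <- fit_bi$p_values[c("k1", "k2")]
  if (any(is.na(k_p)) || any(k_p > alpha)) {
    return(list(chosen = fit_mono, model = "mono",
                rationale = sprintf(
                  "two-pool decay rate(s) not significant at %g", alpha)))
  }
  tt <- sort(unique(fit_mono$points$t))
  gap <- max(abs(predict(fit_mono, tt) - predict(fit_bi, tt)))
  if (gap < curve_threshold) {
    return(list(chosen = fit_mono, model = "mono",
                rationale = sprintf(
                  "fitted curves indistinguishable (max gap %.3g < %g points)",
                  gap, curve_threshold)))
  }
  list(chosen = fit_bi, model = "bi",
       rationale = "two-pool rates significant and curves distinct")
}

#' Fit decay models per depth interval and select one
#'
#' Runs [proportions()], [fit_decay()] for both models and [select_model()]
#' for each requested interval.
#'
#' @param stocks Per-interval stock table from [compute_stocks()].
#' @param intervals Interval labels to fit (default the three upper
#'   intervals, where decline is expected).
#' @param curve_threshold Passed to [select_model()].
#' @param seed Seed for the fitting multi-start.
#' @return A list with `fits` (per-interval list of `mono`, `bi`,
#'   `selection`) and `table`, a tidy tibble of mono-fit parameters per
#'   interval (`Xe`, `k`, SEs, Wald p, `r`, `r_pvalue`, `steady_state_t`,
#'   `model_selected`).
#' @export
chronosequence_fits <- function(stocks,
                                intervals = c("0-0.15", "0.15-0.3", "0.3-0.6"),
                                curve_threshold = 0.5, seed = 1L) {
  fits <- lapply(intervals, function(iv) {
    pts <- proportions(stocks, iv)
    m <- fit_decay(pts, "mono", seed = seed)
    b <- fit_decay(pts, "bi", seed = seed)
    list(points = pts, mono = m, bi = b,
         selection = select_model(m, b, curve_threshold = curve_threshold))
  })
  names(fits) <- intervals
  table <- purrr::map_dfr(intervals, function(iv) {
    f <- fits[[iv]]$mono
    tibble::tibble(
      interval = iv,
      model_selected = fits[[iv]]$selection$model,
      Xe = if (f$converged) f$params[["Xe"]] else NA_real_,
      Xe_se = if (f$converged) f$se[["Xe"]] else NA_real_,
      Xe_p = if (f$converged) f$p_values[["Xe"]] else NA_real_,
      k = if (f$converged) f$params[["k"]] else NA_real_,
      k_se = if (f$converged) f$se[["k"]] else NA_real_,
      k_p = if (f$converged) f$p_values[["k"]] else NA_real_,
      r = f$r, r_pvalue = f$r_pvalue,
      steady_state_t = f$steady_state_t,
      converged = f$converged
    )
  })
  list(fits = fits, table = table)
}
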