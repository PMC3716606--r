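#' Significance flags used in report tables
#'
#' `***` for p <= 0.001, `**` for p <= 0.01, `*` for p <= 0.05 and a dagger
#' for marginal significance at p <= 0.1.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of flags (empty string when p > 0.1 or `NA`).
#' @export
significance_flags <- function(p) {
  out <- character(length(p))
  out[!is.na(p) & p <= 0.1] <- "†"
  out[!is.na(p) & p <= 0.05] <- "*"
  out[!is.na(p) & p <= 0.01] <- "**"
  out[!is.na(p) & p <= 0.001] <- "***"
  out
}

#' Linear mixed-effects model of a response across land uses and depths
#'
#' Fits `response ~ land_use * interval` with a random intercept per cluster
#' by REML, the standard model for clustered paired-plot designs. An
#' optional variance function allows the residual variance to differ
#' between land uses when inspection of the residuals suggests
#' heteroscedasticity.
#'
#' @param data Long table with one row per plot and depth interval, columns
#'   `cluster_id`, `land_use` (`"forest"`/`"rubber"`), `interval`, and the
#'   response.
#' @param response Name of the response column (default `"stock_mg_ha"`).
#' @param variance_by_landuse Allow land-use-specific residual variances
#'   (`nlme::varIdent`).
#' @return A list of class `soc_lme`: `model` (the `nlme::lme` fit),
#'   `response`, `intervals` (ordered labels), `data`.
#' @export
fit_landuse_model <- function(data, response = "stock_mg_ha",
                              variance_by_landuse = FALSE) {
  req_cols(data, c("cluster_id", "land_use", "interval", response),
           "landuse model data")
  d <- tibble::as_tibble(data)
  if (length(unique(d$cluster_id)) < 2) {
    abort_schema(
      "fit_landuse_model: a single cluster cannot support a cluster random intercept; fit a fixed-effects model instead",
      "socchrono_design_error"
    )
  }
  if (length(unique(d$land_use)) < 2) {
    abort_schema("fit_landuse_model: both land uses must be present",
                 "socchrono_design_error")
  }
  ord <- unique(d$interval[order(match(d$interval,
                                       canonical_depths()$interval))])
  d$land_use <- factor(d$land_use, levels = c("forest", "rubber"))
  d$interval <- factor(d$interval, levels = ord)
  d$cluster_id <- factor(d$cluster_id)
  d$.resp <- d[[response]]
  weights <- if (variance_by_landuse) nlme::varIdent(form = ~ 1 | land_use)
             else NULL
  model <- nlme::lme(
    fixed = .resp ~ land_use * interval,
    random = ~ 1 | cluster_id,
    weights = weights,
    data = d,
    method = "REML",
    na.action = stats::na.omit
  )
  structure(list(model = model, response = response, intervals = ord,
                 data = d, variance_by_landuse = variance_by_landuse),
            class = "soc_lme")
}

#' @export
print.soc_lme <- function(x, ...) {
  cat(sprintf("<soc_lme> %s ~ land_use * interval, random ~1|cluster (%s)\n",
              x$response,
              if (x$variance_by_landuse) "per-land-use variances"
              else "homoscedastic"))
  print(summary(x$model))
  invisible(x)
}

#' Per-depth land-use contrasts with Holm adjustment
#'
#' Tests the rubber-minus-forest difference at each depth interval via
#' general linear hypotheses (Wald tests) on the fitted mixed model, then
#' adjusts the family of per-depth p-values with Holm's step-down
#' correction.
#'
#' @param fit A `soc_lme` from [fit_landuse_model()].
#' @param intervals Interval labels to test (default: all in the model).
#' @return A tibble with `response`, `interval`, `estimate`, `se`, `p_raw`,
#'   `p_holm`, `flag`.
#' @export
depth_contrasts <- function(fit, intervals = NULL) {
  stopifnot(inherits(fit, "soc_lme"))
  intervals <- intervals %||% fit$intervals
  missing_iv <- setdiff(intervals, fit$intervals)
  if (length(missing_iv) > 0) {
    abort_schema(sprintf("depth_contrasts: interval(s) absent from model: %s",
                         paste(missing_iv, collapse = ", ")),
                 "socchrono_domain_error")
  }
  fe <- nlme::fixef(fit$model)
  ref <- fit$intervals[1]
  K <- matrix(0, nrow = length(intervals), ncol = length(fe),
              dimnames = list(intervals, names(fe)))
  K[, "land_userubber"] <- 1
  for (iv in intervals) {
    if (iv != ref) {
      K[iv, sprintf("land_userubber:interval%s", iv)] <- 1
    }
  }
  g <- multcomp::glht(fit$model, linfct = K)
  s <- summary(g, test = multcomp::univariate())
  p_raw <- as.numeric(s$test$pvalues)
  p_holm <- stats::p.adjust(p_raw, method = "holm")
  tibble::tibble(
    response = fit$response,
    interval = intervals,
    estimate = as.numeric(s$test$coefficients),
    se = as.numeric(s$test$sigma),
    p_raw = p_raw,
    p_holm = p_holm,
    flag = significance_flags(p_holm)
  )
}

#' Spearman rank correlation with tie-aware ranks
#'
#' Mid-ranks are used for ties, making rho identical to the Pearson
#' correlation of the ranks. P-values use the exact permutation
#' distribution for n <= 9 without ties, and the t approximation otherwise.
#'
#' @param x,y Numeric vectors; incomplete pairs are dropped.
#' @return A list with `rho`, `p_value`, `n`.
#' @export
spearman_test <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    rho <- if (n >= 2 && stats::sd(x) > 0 && stats::sd(y) > 0) {
      stats::cor(rank(x), rank(y))
    } else NA_real_
    return(list(rho = rho, p_value = NA_real_, n = n))
  }
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = (n <= 9 && !ties))
  )
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = n)
}

#' Covariate correlation screen
#'
#' Runs Spearman rank correlations of each response column against each
#' covariate column, one row per pair.
#'
#' @param data A data frame.
#' @param responses,covariates Column names.
#' @return A tibble `response`, `covariate`, `rho`, `p_value`, `n`, `flag`.
#' @export
spearman_screen <- function(data, responses, covariates) {
  req_cols(data, c(responses, covariates), "spearman_screen data")
  grid <- expand.grid(response = responses, covariate = covariates,
                      stringsAsFactors = FALSE)
  purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    st <- spearman_test(data[[grid$covariate[i]]], data[[grid$response[i]]])
    tibble::tibble(
      response = grid$response[i], covariate = grid$covariate[i],
      rho = st$rho, p_value = st$p_value, n = st$n,
      flag = significance_flags(st$p_value)
    )
  })
}

# per-plot relative stock difference against the cluster's forest plot
plot_relative_differences <- function(stocks, interval) {
  pts <- proportions(stocks, interval)
  pts$rel_pct <- pts$y - 100
  pts
}

#' Correlation screen of carbon responses against site covariates
#'
#' For each depth interval, correlates (i) carbon concentrations within each
#' land-use stratum and (ii) relative stock differences of rubber versus the
#' cluster's reference forest against the site covariates: litter carbon
#' stock, litter C:N, total basal area, silt+clay content of the interval,
#' plantation age (rubber only), slope and altitude.
#'
#' @param study A `soc_study` bundle.
#' @param stocks Corrected per-interval stock table from [compute_stocks()];
#'   computed if `NULL`.
#' @param intervals Interval labels to screen.
#' @param pairing_level `"plot"` (one relative difference per rubber plot)
#'   or `"cluster"` (cluster means of rubber plots first). The reporting
#'   level of the published analogue is ambiguous, so it is an explicit
#'   option.
#' @return A tibble `stratum`, `interval`, `response`, `covariate`, `rho`,
#'   `p_value`, `n`, `flag`.
#' @export
correlation_screen <- function(study, stocks = NULL,
                               intervals = c("0-0.15", "0.15-0.3", "0.3-0.6"),
                               pairing_level = c("plot", "cluster")) {
  pairing_level <- match.arg(pairing_level)
  stocks <- stocks %||% compute_stocks(study, bd_correction = TRUE)
  summ <- plot_summaries(study)
  covars <- c("litter_c_mg_ha", "litter_cn", "total_ba_m2_ha",
              "silt_clay_pct", "age_years", "slope_pct", "altitude_m")

  purrr::map_dfr(intervals, function(iv) {
    hz <- study$horizons[study$horizons$plot_id %in% summ$plot_id, ]
    hz <- hz[interval_label(hz$top_m, hz$bottom_m) == iv,
             c("plot_id", "c_pct", "silt_clay_pct")]
    base <- dplyr::left_join(summ, hz, by = "plot_id")

    conc <- purrr::map_dfr(c("rubber", "forest"), function(lu) {
      d <- base[base$land_use == lu, ]
      cv <- if (lu == "rubber") covars else setdiff(covars, "age_years")
      out <- spearman_screen(d, "c_pct", cv)
      out$stratum <- paste0(lu, "_c_pct")
      out
    })

    rel <- plot_relative_differences(stocks, iv)
    if (pairing_level == "cluster") {
      rel <- dplyr::summarise(dplyr::group_by(rel, .data$cluster_id),
                              rel_pct = mean(.data$rel_pct),
                              .groups = "drop")
      # cluster-level covariates: means over the cluster's rubber plots
      rub <- base[base$land_use == "rubber", ]
      cv_cl <- dplyr::summarise(
        dplyr::group_by(rub, .data$cluster_id),
        dplyr::across(dplyr::all_of(covars), ~ mean(.x, na.rm = TRUE)),
        .groups = "drop"
      )
      d <- dplyr::left_join(rel, cv_cl, by = "cluster_id")
    } else {
      d <- dplyr::left_join(rel[, c("plot_id", "rel_pct")],
                            base[base$land_use == "rubber", ],
                            by = "plot_id")
    }
    diff <- spearman_screen(d, "rel_pct", covars)
    diff$stratum <- "relative_difference"

    out <- dplyr::bind_rows(conc, diff)
    out$interval <- iv
    out[, c("stratum", "interval", "response", "covariate", "rho",
            "p_value", "n", "flag")]
  })
}
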