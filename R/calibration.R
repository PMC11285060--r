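new_calibration <- function(fit, data, outliers, excluded, threshold, iterations) {
  co <- stats::coef(fit)
  # vcov warns on an exactly collinear (perfect) fit; that case is legitimate
  # here (noiseless oracle data) and the SEs are simply ~0
  se <- sqrt(diag(suppressWarnings(stats::vcov(fit))))
  resid <- data$pka_exp - (co[2] * data$delta_g_min + co[1])
  r <- if (stats::sd(data$pka_exp) > 0) {
    stats::cor(data$delta_g_min, data$pka_exp)
  } else NA_real_
  rho <- if (stats::sd(data$pka_exp) > 0) {
    stats::cor(data$delta_g_min, data$pka_exp, method = "spearman")
  } else NA_real_
  structure(
    list(
      a = unname(co[2]), b = unname(co[1]),
      se_a = unname(se[2]), se_b = unname(se[1]),
      n_used = nrow(data),
      mae = mean(abs(resid)), rmse = sqrt(mean(resid^2)),
      pearson_r = r, spearman_rho = rho,
      outliers = outliers, excluded = excluded,
      data = data, threshold = threshold, iterations = iterations,
      lm_fit = fit
    ),
    class = "chpka_calibration"
  )
}

check_calibration_input <- function(delta_g_min, pka_exp) {
  if (length(delta_g_min) != length(pka_exp)) {
    abort("delta_g_min and pka_exp must have equal length",
          class = "chpka_fit_error")
  }
  if (!all(is.finite(delta_g_min)) || !all(is.finite(pka_exp))) {
    abort("Calibration inputs must be finite", class = "chpka_fit_error")
  }
  if (length(unique(delta_g_min)) < 2L) {
    abort("Degenerate calibration: fewer than two distinct delta_g values",
          class = "chpka_fit_error")
  }
}

#' Linear free-energy calibration: pKa = a * deltaG + b
#'
#' Ordinary least squares of experimental pKa on the per-molecule minimum
#' deprotonation energy. The slope `a` (pKa units per kcal/mol) and intercept
#' `b` absorb the systematic error of whatever energy backend produced the
#' deltaG values.
#'
#' @param delta_g_min Numeric vector, kcal/mol.
#' @param pka_exp Experimental pKa values, same length.
#' @param ids Optional point identifiers (used in outlier reports).
#' @return A `chpka_calibration` with slope/intercept, their standard errors,
#'   MAE, RMSE, Pearson r and Spearman rho on the fitted points.
#' @export
fit_linear <- function(delta_g_min, pka_exp, ids = NULL) {
  check_calibration_input(delta_g_min, pka_exp)
  data <- tibble(
    id = as.character(ids %||% seq_along(delta_g_min)),
    delta_g_min = as.numeric(delta_g_min), pka_exp = as.numeric(pka_exp)
  )
  fit <- stats::lm(pka_exp ~ delta_g_min, data = data)
  empty <- tibble(id = character(), delta_g_min = numeric(),
                  pka_exp = numeric(), residual = numeric(),
                  iteration = integer())
  new_calibration(fit, data, outliers = empty, excluded = empty[0, 1:3],
                  threshold = NA_real_, iterations = 0L)
}

#' Calibration with iterative outlier rejection
#'
#' Fits, converts each deltaG to a predicted pKa with the current (a, b),
#' removes every point whose |predicted - experimental| exceeds `threshold`
#' pKa units, and refits, until no point is removed or `max_iter` passes.
#' Points with experimental pKa at or beyond `exclude_pka_ge` (the DMSO
#' autoprotolysis limit, where experimental values are extrapolated) can be
#' excluded up front; they are reported separately from residual outliers.
#'
#' @inheritParams fit_linear
#' @param threshold Absolute pKa-unit residual above which a point is an
#'   outlier (default 5).
#' @param max_iter Safety cap on refit rounds (default 10).
#' @param exclude_pka_ge Exclude points with `pka_exp >=` this value before
#'   fitting; `Inf` disables (default 35).
#' @return A `chpka_calibration`; `outliers` records each removed point with
#'   its residual and the iteration of removal.
#' @export
fit_with_outlier_rejection <- function(delta_g_min, pka_exp, threshold = 5.0,
                                       max_iter = 10L, ids = NULL,
                                       exclude_pka_ge = 35) {
  check_calibration_input(delta_g_min, pka_exp)
  data <- tibble(
    id = as.character(ids %||% seq_along(delta_g_min)),
    delta_g_min = as.numeric(delta_g_min), pka_exp = as.numeric(pka_exp)
  )
  excluded <- filter(data, .data$pka_exp >= exclude_pka_ge)
  data <- filter(data, .data$pka_exp < exclude_pka_ge)

  outliers <- tibble(id = character(), delta_g_min = numeric(),
                     pka_exp = numeric(), residual = numeric(),
                     iteration = integer())
  iter <- 0L
  repeat {
    if (nrow(data) < 2L || length(unique(data$delta_g_min)) < 2L) {
      abort("Outlier rejection removed too many points for a fit",
            class = "chpka_fit_error")
    }
    fit <- stats::lm(pka_exp ~ delta_g_min, data = data)
    iter <- iter + 1L
    pred <- stats::predict(fit, data)
    resid <- pred - data$pka_exp
    bad <- abs(resid) > threshold
    if (!any(bad) || iter > max_iter) break
    outliers <- bind_rows(outliers,
                          mutate(data[bad, ], residual = resid[bad],
                                 iteration = iter))
    data <- data[!bad, ]
  }
  new_calibration(fit, data, outliers, excluded, threshold, iter)
}

#' Data-frame interface to the calibration fit
#'
#' @param data Tibble with columns `id`, `delta_g_min`, `pka_exp`.
#' @param threshold,max_iter,exclude_pka_ge See [fit_with_outlier_rejection()].
#' @return A `chpka_calibration`.
#' @export
fit_pka_calibration <- function(data, threshold = 5.0, max_iter = 10L,
                                exclude_pka_ge = 35) {
  fit_with_outlier_rejection(data$delta_g_min, data$pka_exp,
                             threshold = threshold, max_iter = max_iter,
                             ids = data$id, exclude_pka_ge = exclude_pka_ge)
}

#' Predict pKa from a deprotonation energy
#'
#' @param delta_g Energies in kcal/mol.
#' @param fit A `chpka_calibration`.
#' @return `a * delta_g + b` in pKa units.
#' @export
predict_pka <- function(delta_g, fit) {
  stopifnot(inherits(fit, "chpka_calibration"))
  fit$a * delta_g + fit$b
}

#' @export
predict.chpka_calibration <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) newdata <- newdata$delta_g
  predict_pka(newdata, object)
}

#' @export
print.chpka_calibration <- function(x, ...) {
  cat(sprintf(
    "<chpka_calibration> pKa = %.6g * dG + %.6g\n  n = %d, MAE = %.3f, RMSE = %.3f, r = %.3f, rho = %.3f\n",
    x$a, x$b, x$n_used, x$mae, x$rmse, x$pearson_r, x$spearman_rho))
  if (nrow(x$outliers)) {
    cat("  outliers removed:", nrow(x$outliers), "\n")
  }
  if (nrow(x$excluded)) {
    cat("  excluded (extrapolated pKa):", nrow(x$excluded), "\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.chpka_calibration <- function(x, ...) {
  tibble(
    term = c("intercept_b", "slope_a"),
    estimate = c(x$b, x$a),
    std.error = c(x$se_b, x$se_a)
  )
}

#' @export
glance.chpka_calibration <- function(x, ...) {
  tibble(
    a = x$a, b = x$b, n_used = x$n_used, mae = x$mae, rmse = x$rmse,
    pearson_r = x$pearson_r, spearman_rho = x$spearman_rho,
    n_outliers = nrow(x$outliers), n_excluded = nrow(x$excluded),
    iterations = x$iterations
  )
}

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_abline labs
#'   theme_minimal
#' @export
ggplot2::autoplot

#' Calibration scatter plot
#'
#' Retained points, the fitted line, and removed outliers (crosses).
#'
#' @param object A `chpka_calibration`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.chpka_calibration <- function(object, ...) {
  pts <- mutate(object$data, kind = "retained")
  out <- if (nrow(object$outliers)) {
    mutate(select(object$outliers, "id", "delta_g_min", "pka_exp"),
           kind = "outlier")
  } else NULL
  df <- bind_rows(pts, out)
  ggplot(df, aes(x = .data$delta_g_min, y = .data$pka_exp,
                 shape = .data$kind, colour = .data$kind)) +
    geom_point(alpha = 0.7) +
    geom_abline(slope = object$a, intercept = object$b, colour = "grey30") +
    labs(
      x = expression(Delta * G * degree ~ "(kcal/mol)"),
      y = expression(pK[a] ~ "(experimental)"),
      title = sprintf("pKa = %.3f dG %+.1f  (n = %d, MAE = %.2f)",
                      object$a, object$b, object$n_used, object$mae)
    ) +
    theme_minimal()
}

#' Write a calibration fit report
#'
#' JSON report (constants and statistics) plus a CSV of per-point residuals.
#'
#' @param fit A `chpka_calibration`.
#' @param json_path,csv_path Output paths (NULL to skip either).
#' @return The fit, invisibly.
#' @export
write_calibration_report <- function(fit, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    rep <- list(
      a = fit$a, b = fit$b, se_a = fit$se_a, se_b = fit$se_b,
      n_used = fit$n_used, mae = fit$mae, rmse = fit$rmse,
      pearson_r = fit$pearson_r, spearman_rho = fit$spearman_rho,
      threshold = fit$threshold, iterations = fit$iterations,
      outliers = fit$outliers, excluded = fit$excluded
    )
    jsonlite::write_json(rep, json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  if (!is.null(csv_path)) {
    resid <- mutate(fit$data,
                    pka_pred = predict_pka(.data$delta_g_min, fit),
                    residual = .data$pka_pred - .data$pka_exp)
    utils::write.csv(as.data.frame(resid), csv_path, row.names = FALSE)
  }
  invisible(fit)
}
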