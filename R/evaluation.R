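#' Regression metric suite
#'
#' MAE, RMSE, Pearson r and Spearman rho (average ranks on ties). When either
#' vector has zero variance the correlations are reported as `NA` (undefined),
#' never as an error.
#'
#' @param y_true,y_pred Equal-length numeric vectors.
#' @return One-row tibble: `mae`, `rmse`, `pearson_r`, `spearman_rho`, `n`.
#' @export
regression_metrics <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) > 0)
  err <- y_pred - y_true
  safe_cor <- function(method) {
    if (stats::sd(y_true) == 0 || stats::sd(y_pred) == 0) return(NA_real_)
    stats::cor(y_true, y_pred, method = method)
  }
  tibble(
    mae = mean(abs(err)), rmse = sqrt(mean(err^2)),
    pearson_r = safe_cor("pearson"), spearman_rho = safe_cor("spearman"),
    n = length(y_true)
  )
}

#' Classification metric suite from binary vectors
#'
#' Accuracy, Matthews correlation coefficient, precision (PPV), recall (TPR),
#' specificity (TNR) and negative predictive value from the pooled confusion
#' matrix. Conventions for empty denominators: MCC = 0, PPV = 0, NPV = 0 --
#' these make the all-negative null model on an imbalanced set report
#' TPR = PPV = 0, TNR = 1 and MCC = 0.
#'
#' @param labels,preds Equal-length 0/1 vectors.
#' @return One-row tibble with the metrics and `tp`, `fp`, `tn`, `fn`.
#' @export
classification_metrics <- function(labels, preds) {
  stopifnot(length(labels) == length(preds))
  if (!all(labels %in% c(0, 1)) || !all(preds %in% c(0, 1))) {
    abort("labels and preds must be binary 0/1", class = "chpka_input_error")
  }
  tp <- sum(labels == 1 & preds == 1)
  fp <- sum(labels == 0 & preds == 1)
  tn <- sum(labels == 0 & preds == 0)
  fn <- sum(labels == 1 & preds == 0)
  rate <- function(num, den) if (den == 0) 0 else num / den
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  tibble(
    acc = (tp + tn) / length(labels),
    mcc = if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den,
    ppv = rate(tp, tp + fp),
    tpr = rate(tp, tp + fn),
    tnr = rate(tn, tn + fp),
    npv = rate(tn, tn + fn),
    tp = tp, fp = fp, tn = tn, fn = fn
  )
}

#' The all-negative null model
#'
#' Predicts every site as 0; its accuracy equals the negative-class fraction,
#' exposing the class imbalance of lowest-site labeling.
#'
#' @param labels 0/1 vector.
#' @return [classification_metrics()] of the all-zero prediction.
#' @export
null_model <- function(labels) {
  stopifnot(length(labels) >= 1)
  classification_metrics(labels, rep(0, length(labels)))
}

#' Flag sites within a pKa window of the per-molecule minimum
#'
#' For each parent, flag = 1 for sites whose predicted pKa lies within
#' `window` units of the parent's lowest predicted pKa. With a site mask
#' (e.g. aromatic C-H only for borylation candidates) the minimum is computed
#' over masked sites and unmasked sites are never flagged.
#'
#' @param data Tibble with `parent_id`, `pka_pred`, optionally a logical
#'   `mask` column.
#' @param window Non-negative window in pKa units; 0 flags only minima.
#' @return `data` with a `flag` column (0/1).
#' @export
site_window <- function(data, window = 1.5) {
  stopifnot(window >= 0)
  if (!nrow(data)) abort("Empty site table", class = "chpka_empty_error")
  has_mask <- "mask" %in% names(data)
  data %>%
    group_by(.data$parent_id) %>%
    mutate(flag = {
      m <- if (has_mask) .data$mask else rep(TRUE, dplyr::n())
      if (!any(m)) {
        rep(0L, dplyr::n())
      } else {
        thr <- min(.data$pka_pred[m]) + window
        as.integer(m & .data$pka_pred <= thr)
      }
    }) %>%
    ungroup()
}

#' Pooled reaction-site evaluation
#'
#' Each reaction contributes its candidate C-H sites; the experimentally
#' observed site is the positive, every other candidate a negative. Counts
#' are pooled (micro-averaged) across reactions into one confusion table.
#'
#' @param data Tibble with `reaction_id`, `label` (1 = experimental site),
#'   and `predicted` (0/1 flags).
#' @return [classification_metrics()] on the pooled sites.
#' @export
reaction_site_eval <- function(data) {
  stopifnot(all(c("reaction_id", "label", "predicted") %in% names(data)))
  missing_exp <- data %>%
    group_by(.data$reaction_id) %>%
    summarise(has = any(.data$label == 1), .groups = "drop") %>%
    filter(!.data$has)
  if (nrow(missing_exp)) {
    abort(paste0("Experimental site missing among candidates for reaction(s): ",
                 paste(missing_exp$reaction_id, collapse = ", ")),
          class = "chpka_data_error")
  }
  classification_metrics(data$label, data$predicted)
}

#' Write an evaluation report
#'
#' @param report One-row metrics tibble.
#' @param json_path,csv_path Output paths (NULL skips).
#' @export
write_eval_report <- function(report, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(as.list(report), json_path, auto_unbox = TRUE,
                         digits = NA)
  }
  if (!is.null(csv_path)) {
    utils::write.csv(as.data.frame(report), csv_path, row.names = FALSE)
  }
  invisible(report)
}
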