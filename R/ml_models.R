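#' Binary lowest-site labels from per-site pKa values
#'
#' Within each parent, the site(s) with the lowest pKa get label 1; a site
#' within `tolerance` pKa units of the minimum is also accepted as 1 to
#' absorb small variations between near-degenerate sites. Ties at the
#' minimum are all labeled 1, so every parent has at least one positive.
#'
#' @param data Tibble with `parent_id` and `pka` (plus any other columns,
#'   preserved).
#' @param tolerance Non-negative window in pKa units (0, 1 or 2 in practice).
#' @return `data` with a `binary` column and a `tolerance` column.
#' @export
build_labels <- function(data, tolerance = 1) {
  stopifnot(tolerance >= 0)
  if (!nrow(data)) abort("Empty site table", class = "chpka_empty_error")
  data %>%
    group_by(.data$parent_id) %>%
    mutate(binary = as.integer(.data$pka <= min(.data$pka) + tolerance),
           tolerance = tolerance) %>%
    ungroup()
}

#' Compound-level train/test split with shuffled cross-validation folds
#'
#' Splits by compound so no molecule contributes sites to both sides of any
#' split: an 80/20 outer split (test size `round(test_frac * n)`), then
#' `n_folds` folds, each re-splitting the original training set into 90%
#' inner-train and 10% validation compounds with an independent shuffle.
#'
#' @param compound_ids Character vector of unique compound ids.
#' @param seed Integer seed; the whole plan is a deterministic function of it.
#' @param test_frac,val_frac Outer test and inner validation fractions.
#' @param n_folds Number of shuffled folds (default 5).
#' @return A `chpka_split`: `train_ids`, `test_ids`, `cv_folds` (list of
#'   `inner_train_ids` / `val_ids`), `seed`.
#' @export
make_split <- function(compound_ids, seed = 1L, test_frac = 0.2,
                       val_frac = 0.1, n_folds = 5L) {
  ids <- unique(as.character(compound_ids))
  if (length(ids) < 10L) {
    abort("Need at least 10 compounds to split", class = "chpka_split_error")
  }
  with_seed(seed, {
    n <- length(ids)
    n_test <- round(test_frac * n)
    test_ids <- sort(sample(ids, n_test))
    train_ids <- sort(setdiff(ids, test_ids))
    n_val <- round(val_frac * length(train_ids))
    cv_folds <- lapply(seq_len(n_folds), function(k) {
      val <- sort(sample(train_ids, n_val))
      list(inner_train_ids = sort(setdiff(train_ids, val)), val_ids = val)
    })
    structure(list(train_ids = train_ids, test_ids = test_ids,
                   cv_folds = cv_folds, seed = seed),
              class = "chpka_split")
  })
}

#' @export
print.chpka_split <- function(x, ...) {
  cat("<chpka_split> ", length(x$train_ids), " train / ", length(x$test_ids),
      " test compounds, ", length(x$cv_folds), " folds (seed ", x$seed, ")\n",
      sep = "")
  invisible(x)
}

#' Default hyperparameter search space
#'
#' A named list of sampler functions defining the random-search space for the
#' gradient-boosted models: tree count, learning rate, depth, minimum child
#' weight, row/column subsampling, L1/L2 regularization, and (classifier
#' only) the positive-class weight that counteracts the heavy 0/1 imbalance
#' of lowest-site labels.
#'
#' @param kind `"regression"` or `"classification"`.
#' @return Named list of zero-argument sampler functions.
#' @export
default_search_space <- function(kind = c("regression", "classification")) {
  kind <- match.arg(kind)
  space <- list(
    nrounds = function() sample(60:300, 1),
    eta = function() exp(stats::runif(1, log(0.03), log(0.3))),
    max_depth = function() sample(3:8, 1),
    min_child_weight = function() stats::runif(1, 1, 10),
    subsample = function() stats::runif(1, 0.6, 1),
    colsample_bytree = function() stats::runif(1, 0.6, 1),
    lambda = function() exp(stats::runif(1, log(1e-3), log(10))),
    alpha = function() exp(stats::runif(1, log(1e-4), log(1)))
  )
  if (kind == "classification") {
    space$scale_pos_weight <- function() exp(stats::runif(1, log(1), log(20)))
  }
  space
}

feature_matrix_of <- function(features, feature_names) {
  missing <- setdiff(feature_names, names(features))
  if (length(missing)) {
    abort(paste0("Features lack columns: ", paste(missing, collapse = ", ")),
          class = "chpka_schema_error")
  }
  m <- as.matrix(features[, feature_names, drop = FALSE])
  if (!all(is.finite(m))) {
    bad <- which(!stats::complete.cases(m) | rowSums(!is.finite(m)) > 0)
    abort(paste0("Non-finite features in rows: ",
                 paste(utils::head(bad, 10), collapse = ", ")),
          class = "chpka_input_error")
  }
  m
}

fit_booster <- function(kind, x, y, config, seed) {
  params <- list(
    objective = if (kind == "regression") "reg:squarederror" else "binary:logistic",
    eta = config$eta, max_depth = config$max_depth,
    min_child_weight = config$min_child_weight,
    subsample = config$subsample, colsample_bytree = config$colsample_bytree,
    lambda = config$lambda, alpha = config$alpha,
    nthread = 1, seed = seed
  )
  if (!is.null(config$scale_pos_weight)) {
    params$scale_pos_weight <- config$scale_pos_weight
  }
  dtrain <- xgboost::xgb.DMatrix(x, label = y)
  xgboost::xgb.train(params = params, data = dtrain,
                     nrounds = config$nrounds, verbose = 0)
}

#' Random-search hyperparameter tuning and final training
#'
#' Draws `search_budget` configurations from the search space, scores each by
#' shuffled cross-validation on the split plan (regression: mean validation
#' RMSE, lower better; classification: mean validation MCC, higher better),
#' then refits the best configuration on the full original training set.
#' Everything is a deterministic function of `seed`.
#'
#' @param kind `"regression"` or `"classification"`.
#' @param features Feature tibble from [build_feature_matrix()] (must carry
#'   `parent_id`).
#' @param outcome Numeric vector aligned with `features` rows: pKa values for
#'   regression, 0/1 labels for classification.
#' @param split_plan A [make_split()] plan over the `parent_id` compounds.
#' @param search_budget Number of sampled configurations (>= 1).
#' @param seed Integer seed for sampling and boosting.
#' @param space Search space (default [default_search_space()]).
#' @param schema Optional feature schema stored with the model.
#' @return A `chpka_model` bundle.
#' @export
tune_and_train <- function(kind = c("regression", "classification"), features,
                           outcome, split_plan, search_budget = 20L, seed = 1L,
                           space = NULL, schema = NULL) {
  kind <- match.arg(kind)
  if (search_budget < 1L) {
    abort("search_budget must be >= 1", class = "chpka_input_error")
  }
  stopifnot(inherits(split_plan, "chpka_split"),
            nrow(features) == length(outcome))
  space <- space %||% default_search_space(kind)
  feature_names <- setdiff(names(features), c("parent_id", "atom_index"))
  x_all <- feature_matrix_of(features, feature_names)
  pid <- features$parent_id

  configs <- with_seed(seed, {
    lapply(seq_len(search_budget), function(i) lapply(space, function(f) f()))
  })

  score_config <- function(config) {
    fold_scores <- vapply(split_plan$cv_folds, function(fold) {
      tr <- pid %in% fold$inner_train_ids
      va <- pid %in% fold$val_ids
      bst <- fit_booster(kind, x_all[tr, , drop = FALSE], outcome[tr],
                         config, seed)
      pred <- stats::predict(bst, xgboost::xgb.DMatrix(x_all[va, , drop = FALSE]))
      if (kind == "regression") {
        sqrt(mean((pred - outcome[va])^2))
      } else {
        lab <- outcome[va]
        bin <- as.integer(pred > 0.5)
        # a one-class validation fold makes MCC undefined; score it by
        # accuracy rescaled to [-1, 1] so a perfect fit still counts as 1
        if (length(unique(lab)) < 2L) {
          2 * mean(bin == lab) - 1
        } else {
          classification_metrics(lab, bin)$mcc
        }
      }
    }, numeric(1))
    mean(fold_scores)
  }

  scores <- vapply(configs, score_config, numeric(1))
  best_i <- if (kind == "regression") which.min(scores) else which.max(scores)
  best <- configs[[best_i]]

  tr <- pid %in% split_plan$train_ids
  booster <- fit_booster(kind, x_all[tr, , drop = FALSE], outcome[tr], best, seed)

  structure(
    list(
      kind = if (kind == "regression") "regressor" else "classifier",
      booster = booster, hyperparameters = best,
      feature_names = feature_names,
      cv = tibble(trial = seq_along(scores), score = scores,
                  metric = if (kind == "regression") "rmse" else "mcc"),
      best_trial = best_i, seed = seed,
      split_hash = rlang::hash(split_plan[c("train_ids", "test_ids", "seed")]),
      schema = schema,
      schema_hash = if (is.null(schema)) NA_character_ else rlang::hash(schema)
    ),
    class = "chpka_model"
  )
}

#' @export
print.chpka_model <- function(x, ...) {
  cat("<chpka_model> ", x$kind, ", ", length(x$feature_names),
      " features, best CV ", x$cv$metric[1], " = ",
      signif(x$cv$score[x$best_trial], 4), " (", nrow(x$cv), " trials)\n",
      sep = "")
  invisible(x)
}

#' @export
predict.chpka_model <- function(object, newdata, type = c("response", "class"), ...) {
  type <- match.arg(type)
  x <- feature_matrix_of(newdata, object$feature_names)
  p <- stats::predict(object$booster, xgboost::xgb.DMatrix(x))
  if (object$kind == "classifier" && type == "class") {
    return(as.integer(p > 0.5))
  }
  p
}

#' @export
glance.chpka_model <- function(x, ...) {
  tibble(kind = x$kind, n_features = length(x$feature_names),
         trials = nrow(x$cv), best_trial = x$best_trial,
         cv_metric = x$cv$metric[1], cv_score = x$cv$score[x$best_trial],
         seed = x$seed)
}

#' @export
tidy.chpka_model <- function(x, ...) {
  tibble(term = names(x$hyperparameters),
         value = as.numeric(unlist(x$hyperparameters)))
}

#' Use a pKa regressor as a lowest-site classifier
#'
#' Predicts per-site pKa values, then labels 1 every site within `tolerance`
#' pKa units of its parent's lowest *predicted* pKa. This is the construction
#' under which a regression model competes directly with a binary classifier
#' on the site-identification task.
#'
#' @param model A regressor `chpka_model`.
#' @param features Feature tibble carrying `parent_id`.
#' @param tolerance Window in pKa units.
#' @return Integer 0/1 vector aligned with `features` rows.
#' @export
regressor_as_classifier <- function(model, features, tolerance = 1) {
  stopifnot(inherits(model, "chpka_model"))
  if (model$kind != "regressor") {
    abort("regressor_as_classifier needs a regression model",
          class = "chpka_input_error")
  }
  if (is.null(features$parent_id)) {
    abort("features must carry parent_id for per-molecule grouping",
          class = "chpka_input_error")
  }
  pred <- stats::predict(model, features)
  df <- tibble(parent_id = features$parent_id, pka = pred)
  build_labels(df, tolerance)$binary
}

#' Persist / restore a model bundle
#'
#' The bundle is a directory: the serialized booster plus a JSON metadata
#' file (hyperparameters, feature schema and hashes, seeds). Loading restores
#' a model whose predictions match the in-memory model exactly.
#'
#' @param model A `chpka_model`.
#' @param dir Bundle directory (created if needed).
#' @return `save_model_bundle` the directory, `load_model_bundle` the model.
#' @export
save_model_bundle <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  xgboost::xgb.save(model$booster, file.path(dir, "model.ubj"))
  meta <- model[setdiff(names(model), "booster")]
  meta$cv <- as.data.frame(meta$cv)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns",
                       null = "null")
  invisible(dir)
}

#' @rdname save_model_bundle
#' @param dir Bundle directory.
#' @export
load_model_bundle <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  model <- list(
    kind = meta$kind,
    booster = xgboost::xgb.load(file.path(dir, "model.ubj")),
    hyperparameters = as.list(meta$hyperparameters),
    feature_names = meta$feature_names,
    cv = as_tibble(meta$cv), best_trial = meta$best_trial,
    seed = meta$seed, split_hash = meta$split_hash,
    schema = meta$schema, schema_hash = meta$schema_hash
  )
  structure(model, class = "chpka_model")
}
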