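test_that("lowest-site labels honor the tolerance window and minimum ties", {
  df <- tibble::tibble(parent_id = "m", pka = c(10, 10.5, 13))
  expect_identical(build_labels(df, tolerance = 1)$binary, c(1L, 1L, 0L))
  expect_identical(build_labels(df, tolerance = 0)$binary, c(1L, 0L, 0L))
  tie <- tibble::tibble(parent_id = "m", pka = c(12, 12, 20))
  expect_identical(build_labels(tie, tolerance = 0)$binary, c(1L, 1L, 0L))
  # every parent keeps at least one positive
  set.seed(2)
  many <- tibble::tibble(parent_id = rep(letters[1:6], each = 4),
                         pka = stats::runif(24, 5, 50))
  lab <- build_labels(many, tolerance = 1)
  pos <- tapply(lab$binary, lab$parent_id, max)
  expect_true(all(pos == 1))
  expect_error(build_labels(many[0, ]), class = "chpka_empty_error")
})

test_that("compound splits reproduce the 620/155 arithmetic and never leak", {
  ids <- sprintf("cmp%04d", 1:775)
  plan <- make_split(ids, seed = 42)
  expect_length(plan$train_ids, 620L)
  expect_length(plan$test_ids, 155L)
  expect_length(intersect(plan$train_ids, plan$test_ids), 0L)
  expect_identical(make_split(ids, seed = 42), plan)
  expect_false(identical(make_split(ids, seed = 43), plan))
  for (fold in plan$cv_folds) {
    expect_length(intersect(fold$inner_train_ids, fold$val_ids), 0L)
    expect_setequal(c(fold$inner_train_ids, fold$val_ids), plan$train_ids)
    expect_length(fold$val_ids, round(0.1 * 620))
    expect_length(intersect(fold$val_ids, plan$test_ids), 0L)
  }
  expect_error(make_split(letters[1:5]), class = "chpka_split_error")
})

ml_fixture <- function() {
  cached("ml_fixture", {
    w <- make_world(seed = 5, noise_sigma = 0, n_molecules = 40)
    fm <- build_feature_matrix(w$sites, w$molecules, surrogate_charge_provider())
    x <- as.matrix(fm$features[, fm$schema$columns])
    signal <- 25 + 40 * x[, "d0_s01"] + 15 * x[, "d1_s01"] - 8 * x[, "d1_s02"] +
      1.5 * x[, "occ_d1"]
    list(world = w, fm = fm, signal = signal)
  })
}

test_that("tuning is deterministic and fits separable classes perfectly", {
  fx <- ml_fixture()
  split <- make_split(unique(fx$fm$features$parent_id), seed = 11)
  # separable by a single integer-valued feature (second-shell occupancy),
  # and imbalanced enough to exercise the positive-class weighting
  occ <- fx$fm$features$occ_d2
  labels <- as.integer(occ >= 5)
  m1 <- tune_and_train("classification", fx$fm$features, labels, split,
                       search_budget = 3, seed = 9)
  m2 <- tune_and_train("classification", fx$fm$features, labels, split,
                       search_budget = 3, seed = 9)
  expect_identical(m1$hyperparameters, m2$hyperparameters)
  expect_identical(m1$cv$score, m2$cv$score)
  expect_equal(max(m1$cv$score), 1) # separable -> perfect CV MCC
  expect_error(tune_and_train("classification", fx$fm$features, labels, split,
                              search_budget = 0), class = "chpka_input_error")
})

test_that("the tuned regressor learns a synthetic target above the null", {
  fx <- ml_fixture()
  set.seed(31)
  sigma <- stats::sd(fx$signal) / 2
  y <- fx$signal + stats::rnorm(length(fx$signal), 0, sigma)
  split <- make_split(unique(fx$fm$features$parent_id), seed = 11)
  model <- tune_and_train("regression", fx$fm$features, y, split,
                          search_budget = 5, seed = 3, schema = fx$fm$schema)
  te <- fx$fm$features$parent_id %in% split$test_ids
  pred <- predict(model, fx$fm$features[te, ])
  mae <- mean(abs(pred - y[te]))
  expect_lt(mae, 1.5 * sigma * sqrt(2 / pi))
  expect_s3_class(glance(model), "tbl_df")
  expect_identical(glance(model)$kind, "regressor")
})

test_that("non-finite features are refused with row information", {
  fx <- ml_fixture()
  feats <- fx$fm$features
  feats[[fx$fm$schema$columns[1]]][3] <- NaN
  split <- make_split(unique(feats$parent_id), seed = 11)
  expect_error(tune_and_train("regression", feats, fx$signal, split,
                              search_budget = 1), class = "chpka_input_error")
})

test_that("a regressor used as classifier reproduces the label construction", {
  fx <- ml_fixture()
  # oracle predictor: returns the known pKa values exactly
  oracle <- structure(list(kind = "regressor", feature_names = character()),
                      class = c("oracle_model", "chpka_model"))
  pka <- fx$world$sites$pka_true
  assign("predict.oracle_model",
         function(object, newdata, ...) pka[seq_len(nrow(newdata))],
         envir = globalenv())
  withr::defer(rm("predict.oracle_model", envir = globalenv()))
  feats <- fx$fm$features
  for (tol in c(0, 1, 2)) {
    want <- build_labels(tibble::tibble(parent_id = fx$world$sites$parent_id,
                                        pka = pka), tolerance = tol)$binary
    got <- regressor_as_classifier(oracle, feats, tolerance = tol)
    expect_identical(got, want, info = paste("tolerance", tol))
  }
  # threshold behaviour on explicit predictions
  p <- tibble::tibble(parent_id = c("r", "r", "r"))
  oracle2 <- structure(list(kind = "regressor"), class = c("o2", "chpka_model"))
  assign("predict.o2", function(object, newdata, ...) c(8, 8.9, 14),
         envir = globalenv())
  withr::defer(rm("predict.o2", envir = globalenv()))
  expect_identical(regressor_as_classifier(oracle2, p, tolerance = 0),
                   c(1L, 0L, 0L))
  expect_identical(regressor_as_classifier(oracle2, p, tolerance = 1),
                   c(1L, 1L, 0L))
  single <- tibble::tibble(parent_id = "s")
  oracle3 <- structure(list(kind = "regressor"), class = c("o3", "chpka_model"))
  assign("predict.o3", function(object, newdata, ...) 12.3, envir = globalenv())
  withr::defer(rm("predict.o3", envir = globalenv()))
  expect_identical(regressor_as_classifier(oracle3, single), 1L)
})

test_that("model bundles round-trip through disk with identical predictions", {
  fx <- ml_fixture()
  split <- make_split(unique(fx$fm$features$parent_id), seed = 11)
  model <- tune_and_train("regression", fx$fm$features, fx$signal, split,
                          search_budget = 2, seed = 8, schema = fx$fm$schema)
  dir <- withr::local_tempdir()
  save_model_bundle(model, dir)
  back <- load_model_bundle(dir)
  expect_identical(predict(back, fx$fm$features),
                   predict(model, fx$fm$features))
  expect_equal(back$hyperparameters[order(names(back$hyperparameters))],
               model$hyperparameters[order(names(model$hyperparameters))],
               tolerance = 1e-12) # JSON decimal round-trip
  expect_identical(back$schema_hash, model$schema_hash)
})
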