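test_that("regression metrics match hand-rolled textbook formulas", {
  expect_equal(regression_metrics(1:5, 1:5)$mae, 0)
  expect_equal(regression_metrics(1:5, 1:5)$pearson_r, 1)
  shifted <- regression_metrics(1:5, 1:5 + 2)
  expect_equal(shifted$mae, 2)
  expect_equal(shifted$rmse, 2)
  expect_equal(shifted$pearson_r, 1)
  set.seed(17)
  y <- stats::rnorm(1000)
  p <- 0.6 * y + stats::rnorm(1000, 0, 0.5)
  got <- regression_metrics(y, p)
  # independent implementation from the raw definitions
  e <- p - y
  mae <- sum(abs(e)) / 1000
  rmse <- sqrt(sum(e^2) / 1000)
  r <- sum((y - mean(y)) * (p - mean(p))) /
    sqrt(sum((y - mean(y))^2) * sum((p - mean(p))^2))
  ry <- rank(y); rp <- rank(p)
  rho <- sum((ry - mean(ry)) * (rp - mean(rp))) /
    sqrt(sum((ry - mean(ry))^2) * sum((rp - mean(rp))^2))
  expect_equal(got$mae, mae, tolerance = 1e-10)
  expect_equal(got$rmse, rmse, tolerance = 1e-10)
  expect_equal(got$pearson_r, r, tolerance = 1e-10)
  expect_equal(got$spearman_rho, rho, tolerance = 1e-10)
  # zero variance: undefined correlation, not a crash
  flat <- regression_metrics(c(1, 1, 1), c(1, 2, 3))
  expect_true(is.na(flat$pearson_r))
  expect_false(is.na(flat$mae))
})

test_that("classification metrics recompute exactly from the confusion counts", {
  lab <- c(1, 1, 0, 0, 1, 0)
  perfect <- classification_metrics(lab, lab)
  expect_equal(perfect$acc, 1)
  expect_equal(perfect$mcc, 1)
  hand <- classification_metrics(c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0),
                                 c(1, 1, 0, 0, 1, 0, 0, 0, 0, 0))
  # TP=2 FP=1 TN=5 FN=2
  expect_identical(unlist(hand[c("tp", "fp", "tn", "fn")]),
                   c(tp = 2L, fp = 1L, tn = 5L, fn = 2L))
  expect_equal(hand$acc, 7 / 10)
  expect_equal(hand$ppv, 2 / 3)
  expect_equal(hand$tpr, 2 / 4)
  expect_equal(hand$tnr, 5 / 6)
  expect_equal(hand$npv, 5 / 7)
  expect_equal(hand$mcc, (2 * 5 - 1 * 2) / sqrt(3) / sqrt(4) / sqrt(6) / sqrt(7))
  expect_error(classification_metrics(c(0, 2), c(0, 1)),
               class = "chpka_input_error")
})

test_that("the all-negative null model exposes the class imbalance", {
  lab <- c(rep(1, 2), rep(0, 8)) # 20% positives
  nm <- null_model(lab)
  expect_equal(nm$acc, 0.80)
  expect_equal(nm$mcc, 0)
  expect_equal(nm$tpr, 0)
  expect_equal(nm$ppv, 0)
  expect_equal(nm$tnr, 1)
  expect_equal(nm$acc + mean(lab), 1)
  expect_equal(null_model(rep(0, 5))$acc, 1)
  expect_equal(null_model(rep(1, 5))$acc, 0)
})

test_that("site windows flag near-minimum sites, with and without masks", {
  df <- tibble::tibble(parent_id = "m", pka_pred = c(20, 21, 25))
  expect_identical(site_window(df, 1.5)$flag, c(1L, 1L, 0L))
  expect_identical(site_window(df, 0)$flag, c(1L, 0L, 0L))
  # masking away the minimum recomputes it over the remaining sites
  masked <- tibble::tibble(parent_id = "m", pka_pred = c(20, 21, 25),
                           mask = c(FALSE, TRUE, TRUE))
  expect_identical(site_window(masked, 1.5)$flag, c(0L, 1L, 0L))
  expect_error(site_window(df[0, ], 1), class = "chpka_empty_error")
  # window 0 without mask equals tolerance-0 labeling
  set.seed(23)
  many <- tibble::tibble(parent_id = rep(letters[1:5], each = 3),
                         pka_pred = stats::runif(15, 10, 40))
  sw <- site_window(many, 0)$flag
  bl <- build_labels(dplyr::rename(many, pka = "pka_pred"), tolerance = 0)$binary
  expect_identical(sw, bl)
})

test_that("reaction-site evaluation pools confusion counts across reactions", {
  one <- tibble::tibble(reaction_id = "r1", label = c(1, 0, 0),
                        predicted = c(1, 0, 0))
  m <- reaction_site_eval(one)
  expect_identical(c(m$tp, m$tn), c(1L, 2L))
  expect_equal(m$mcc, 1)
  wrong <- tibble::tibble(reaction_id = "r1", label = c(1, 0, 0),
                          predicted = c(0, 1, 0))
  mw <- reaction_site_eval(wrong)
  expect_identical(unlist(mw[c("tp", "fp", "tn", "fn")]),
                   c(tp = 0L, fp = 1L, tn = 1L, fn = 1L))
  # ten synthetic reactions against a brute-force tally
  set.seed(29)
  rows <- do.call(rbind, lapply(1:10, function(r) {
    k <- sample(2:5, 1)
    lab <- integer(k)
    lab[sample(k, 1)] <- 1L
    data.frame(reaction_id = paste0("r", r), label = lab,
               predicted = stats::rbinom(k, 1, 0.4))
  }))
  got <- reaction_site_eval(tibble::as_tibble(rows))
  expect_identical(got$tp, sum(rows$label == 1 & rows$predicted == 1))
  expect_identical(got$fp, sum(rows$label == 0 & rows$predicted == 1))
  expect_identical(got$tn, sum(rows$label == 0 & rows$predicted == 0))
  expect_identical(got$fn, sum(rows$label == 1 & rows$predicted == 0))
  # a reaction whose experimental site is missing is a data error
  bad <- tibble::tibble(reaction_id = c("r1", "r1", "r2"),
                        label = c(1, 0, 0), predicted = c(1, 0, 0))
  expect_error(reaction_site_eval(bad), "r2", class = "chpka_data_error")
})
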