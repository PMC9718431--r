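make_gaussian_toy <- function(n = 200, sep = 4, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n / 2 * 5), ncol = 5),
             matrix(rnorm(n / 2 * 5, mean = sep / sqrt(5)), ncol = 5))
  list(x = x, y = rep(c("non_ad", "ad"), each = n / 2))
}

test_that("stratified split is an exact seeded 70/15/15 partition", {
  y <- rep(c("ad", "non_ad"), each = 100)
  cfg <- train_config(seed = 3)
  sp <- split_stratified(y, cfg)
  expect_equal(lengths(sp), c(train = 140L, val = 30L, test = 30L))
  for (cl in c("ad", "non_ad")) {
    expect_equal(sum(y[sp$train] == cl), 70)
    expect_equal(sum(y[sp$val] == cl), 15)
    expect_equal(sum(y[sp$test] == cl), 15)
  }
  expect_identical(sp, split_stratified(y, cfg))
  all_idx <- sort(unlist(sp, use.names = FALSE))
  expect_equal(all_idx, seq_along(y))
  expect_error(split_stratified(c("a", "a", "a", "b", "b"),
                                cfg), "< 3 windows")
})

test_that("uneven class counts stay within one window of exact stratification", {
  set.seed(8)
  y <- sample(c("ad", "none", "startle", "tail_pinch"), 487, replace = TRUE,
              prob = c(0.2, 0.6, 0.1, 0.1))
  cfg <- train_config(seed = 2)
  sp <- split_stratified(y, cfg)
  expect_equal(sort(unlist(sp, use.names = FALSE)), seq_along(y))
  expect_equal(length(sp$train), round(0.7 * length(y)))
  expect_equal(length(sp$val), round(0.15 * length(y)))
  for (cl in unique(y)) {
    n_c <- sum(y == cl)
    expect_lte(abs(sum(y[sp$train] == cl) - 0.7 * n_c), 1)
    expect_lte(abs(sum(y[sp$val] == cl) - 0.15 * n_c), 1)
  }
})

test_that("the network learns a separable toy and is seed-stable", {
  toy <- make_gaussian_toy(200, sep = 6)
  cfg <- train_config(seed = 5, max_epochs = 200)
  m <- train_model(toy$x, toy$y, cfg)
  acc <- mean(predict(m, toy$x, type = "class") == toy$y)
  expect_gte(acc, 0.99)

  m2 <- train_model(toy$x, toy$y, cfg)
  r1 <- evaluate(m, toy$x, toy$y)
  r2 <- evaluate(m2, toy$x, toy$y)
  expect_identical(r1, r2)
})

test_that("non-finite features are rejected with the offending windows", {
  toy <- make_gaussian_toy(40)
  toy$x[7, 2] <- NA
  expect_error(train_model(toy$x, toy$y, train_config()), "7")
})

test_that("shuffled labels give chance-level cross-validation accuracy", {
  toy <- make_gaussian_toy(200, sep = 6, seed = 11)
  set.seed(21)
  y_shuf <- sample(toy$y)
  cfg <- train_config(seed = 7, cv_folds = 5, max_epochs = 120)
  cv <- cross_validate(toy$x, y_shuf, cfg, positive = "ad")
  p0 <- max(table(y_shuf)) / length(y_shuf)
  se <- sqrt(p0 * (1 - p0) / length(y_shuf))
  expect_lt(abs(cv$cv_mean - p0), 3 * se + 0.05)
})

test_that("confusion-matrix metrics match direct arithmetic", {
  m1 <- metrics_from_confusion(matrix(c(50, 0, 0, 50), 2, byrow = TRUE,
                                      dimnames = list(c("non_ad", "ad"),
                                                      c("non_ad", "ad"))),
                               positive = "ad")
  expect_equal(m1$accuracy, 1)
  expect_equal(m1$sensitivity, 1)
  expect_equal(m1$specificity, 1)
  expect_equal(m1$f1, 1)

  m2 <- metrics_from_confusion(matrix(c(45, 5, 5, 45), 2, byrow = TRUE,
                                      dimnames = list(c("non_ad", "ad"),
                                                      c("non_ad", "ad"))),
                               positive = "ad")
  expect_equal(m2$accuracy, 0.90)
  expect_equal(m2$sensitivity, 0.90)
  expect_equal(m2$specificity, 0.90)
})

test_that("reported accuracy equals the confusion-matrix recomputation", {
  toy <- make_gaussian_toy(300, sep = 2, seed = 13)
  cfg <- train_config(seed = 1, max_epochs = 120)
  sp <- split_stratified(toy$y, cfg)
  m <- train_model(toy$x[sp$train, ], toy$y[sp$train], cfg)
  r <- evaluate(m, toy$x[sp$test, ], toy$y[sp$test])
  expect_equal(r$accuracy, sum(diag(r$confusion)) / sum(r$confusion),
               tolerance = 1e-12)
  expect_equal(sum(r$confusion), r$n)
  expect_equal(rowSums(r$confusion),
               c(non_ad = sum(toy$y[sp$test] == "non_ad"),
                 ad = sum(toy$y[sp$test] == "ad")))
})

test_that("AUC matches the pairwise oracle and flips under score negation", {
  toy <- make_gaussian_toy(120, sep = 2, seed = 17)
  cfg <- train_config(seed = 9, max_epochs = 120)
  m <- train_model(toy$x, toy$y, cfg)
  score <- predict(m, toy$x, type = "prob")[, "ad"]
  r <- suppressMessages(pROC::roc(toy$y, score, levels = c("non_ad", "ad"),
                                  direction = "<", quiet = TRUE))
  auc <- as.numeric(pROC::auc(r))
  expect_equal(auc, brute_auc(score, toy$y == "ad"), tolerance = 1e-9)
  r_flip <- pROC::roc(toy$y, -score, levels = c("non_ad", "ad"),
                      direction = "<", quiet = TRUE)
  expect_equal(as.numeric(pROC::auc(r_flip)), 1 - auc, tolerance = 1e-9)
})

test_that("single-class test sets flag undefined sensitivity", {
  toy <- make_gaussian_toy(60, sep = 4, seed = 3)
  m <- train_model(toy$x, toy$y, train_config(seed = 2, max_epochs = 60))
  expect_warning(r <- evaluate(m, toy$x[1:30, ], toy$y[1:30]),
                 "single-class")
  expect_true(is.na(r$sensitivity) || is.na(r$specificity))
})

test_that("cross-validation folds partition the data per class", {
  toy <- make_gaussian_toy(100, sep = 8, seed = 4)
  cfg <- train_config(seed = 6, cv_folds = 5, max_epochs = 100)
  cv <- cross_validate(toy$x, toy$y, cfg)
  expect_length(cv$fold_assignment, 100)
  expect_equal(sort(unique(cv$fold_assignment)), 1:5)
  for (f in 1:5) for (cl in c("ad", "non_ad"))
    expect_equal(sum(cv$fold_assignment == f & toy$y == cl), 10)
  expect_gte(cv$cv_mean, 0.95)
})

test_that("the JSON weight bundle round-trips exactly", {
  toy <- make_gaussian_toy(80, sep = 3, seed = 5)
  m <- train_model(toy$x, toy$y, train_config(seed = 8, max_epochs = 60))
  path <- tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  expect_equal(predict(m2, toy$x), predict(m, toy$x), tolerance = 1e-12)
  expect_equal(m2$layer_sizes, m$layer_sizes)
})

test_that("stronger simulated effects never lower CV accuracy", {
  accs <- vapply(c(0.6, 1.0, 1.6), function(mult) {
    cfg <- sim_config(seed = 19, n_animals = 4, trial_days = c(7L, 9L),
                      burst_rate_ad = 20 * mult,
                      ad_bradycardia_frac = min(0.15 * mult, 0.4))
    recs <- simulate_cohort(cfg)
    w <- suppressWarnings(cohort_windows(recs, cfg))
    fm <- suppressWarnings(feature_matrix(w))
    tcfg <- train_config(seed = 23, cv_folds = 5, max_epochs = 150,
                         task = "multiclass")
    cross_validate(fm$x, w$label, tcfg)$cv_mean
  }, numeric(1))
  cv_sd <- 0.03
  expect_true(all(diff(accs) >= -cv_sd))
})
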