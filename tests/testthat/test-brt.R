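# synthetic calibration-sample builder with explicit X and labels
make_sample <- function(X, y, lon = NULL, lat = NULL) {
  n <- nrow(X)
  structure(list(cells = seq_len(n), label = as.integer(y), X = X,
                 lon = lon %||% runif(n, -5, 5),
                 lat = lat %||% runif(n, 35, 45),
                 method = "synthetic", seed = 0,
                 n_presence = sum(y == 1), n_absence = sum(y == 0)),
            class = "calibration_sample")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("null-model deviance matches the closed-form Bernoulli deviance", {
  set.seed(4)
  n <- 300
  X <- cbind(a = rnorm(n), b = rnorm(n))
  y <- rbinom(n, 1, 0.3)
  b <- brtsdm:::booster_create(X, y, 0.01, 3L, 0.5, 10L, 1L, X, y)
  brtsdm:::booster_grow(b, 1L)
  pbar <- mean(y)
  dev0 <- -2 * mean(y * log(pbar) + (1 - y) * log(1 - pbar))
  # after one tiny tree the deviance is within a whisker of the null value
  expect_equal(brtsdm:::booster_valid_dev(b)[1], dev0, tolerance = 0.02)
})

test_that("separable predictor gives perfect training discrimination", {
  set.seed(7)
  n <- 400
  x1 <- c(rnorm(n / 2, -3), rnorm(n / 2, 3))
  X <- cbind(sep = x1, noise = rnorm(n))
  y <- rep(c(0L, 1L), each = n / 2)
  smp <- make_sample(X, y)
  m <- fit_with_cv(smp, config = brt_config(learning_rate = 0.1,
                                            max_trees = 500, n_folds = 5,
                                            seed = 2))
  expect_equal(auc(y, predict(m, X)), 1.0)
  expect_gt(contributions(m)["sep"], 95)
})

test_that("pure-noise labels: flat deviance curve, small selected tree count", {
  set.seed(9)
  n <- 400
  X <- cbind(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- rbinom(n, 1, 0.5)
  smp <- make_sample(X, y)
  cfg <- brt_config(learning_rate = 0.05, tree_step = 25, max_trees = 1500,
                    patience_steps = 60, n_folds = 5, seed = 3)
  m <- fit_with_cv(smp, config = cfg)
  curve <- m$cv_deviance
  i_sel <- which(curve$trees == m$n_trees)
  i_3x <- which.min(abs(curve$trees - 3 * m$n_trees))
  expect_lte(curve$deviance[i_sel], curve$deviance[i_3x])
  expect_lt(m$n_trees, 500) # no signal to learn
})

test_that("fit_with_cv input validation", {
  set.seed(1)
  X <- cbind(a = rnorm(50), b = rnorm(50))
  expect_error(fit_with_cv(make_sample(X, rep(1, 50))), "both labels")
  expect_error(fit_with_cv(make_sample(X, rbinom(50, 1, 0.5)),
                           predictors = "a"), "2 predictors")
  Xbad <- X; Xbad[3, 1] <- NA
  expect_error(fit_with_cv(make_sample(Xbad, rbinom(50, 1, 0.5)),
                           config = brt_config(n_folds = 5)),
               "non-finite")
})

test_that("tuning loop: window contract, tc bounds, documented start", {
  w <- small_world()
  smp <- select_background(w$map, w$stacks[["2000"]], "random", 150, 150,
                           seed = 31)
  preds <- c(names(w$truth$responses), "BIO4", "BIO5", "AHUM", "EXV01")
  m <- tune(smp, preds, brt_config(seed = 17))
  expect_false(m$flagged)
  expect_gte(m$n_trees, 1200)
  expect_lte(m$n_trees, 2000)
  expect_gte(m$tree_complexity, 3)
  expect_lte(m$tree_complexity, 10)
  expect_equal(m$tuning[[1]]$learning_rate, 0.15)
  expect_equal(m$tuning[[1]]$tree_complexity, 5)
})

test_that("contributions normalize to 100 and ignore unused predictors", {
  f <- small_fit()
  co <- contributions(f$model)
  expect_equal(sum(co), 100, tolerance = 1e-6)
  expect_true(all(co >= 0))
  expect_true(any(co == 0)) # 52 predictors, many never split on
})

test_that("response curves: bounds, flatness, monotone truth recovery", {
  f <- small_fit()
  co <- contributions(f$model)
  flat_pred <- names(co)[co == 0][1]
  rc <- response_curve(f$model, flat_pred)
  expect_lt(max(rc$y) - min(rc$y), 1e-6)
  expect_true(all(rc$y >= 0 & rc$y <= 1))
  expect_true(all(diff(rc$x) > 0))
  # monotone generative response (BIO12 ramp in the default truth); a
  # dedicated fit on decorrelated predictors so the marginal is identified
  w <- f$world
  smp <- suppressWarnings(
    select_background(w$map, f$stack, "random", 150, 150, seed = 55))
  m2 <- fit_with_cv(smp, c("BIO1", "BIO12", "urban", "BIO2", "bare_soil"),
                    brt_config(learning_rate = 0.05, max_trees = 600,
                               n_folds = 5, seed = 56))
  rc12 <- response_curve(m2, "BIO12")
  truth_resp <- plogis((rc12$x - 500) / 150)
  expect_gte(cor(rc12$y, truth_resp, method = "spearman"), 0.9)
  expect_error(response_curve(f$model, "not_a_predictor"), "not in model")
})

test_that("interactions: symmetry, sums, additive vs product generative", {
  set.seed(12)
  n <- 500
  X <- cbind(x1 = runif(n, -2, 2), x2 = runif(n, -2, 2), x3 = rnorm(n))
  y_add <- rbinom(n, 1, plogis(1.2 * X[, "x1"] + 1.2 * X[, "x2"]))
  y_int <- rbinom(n, 1, plogis(2 * X[, "x1"] * X[, "x2"]))
  cfg <- brt_config(learning_rate = 0.05, max_trees = 600, n_folds = 5,
                    seed = 5)
  m_add <- fit_with_cv(make_sample(X, y_add), config = cfg)
  m_int <- fit_with_cv(make_sample(X, y_int), config = cfg)
  i_add <- interactions(m_add)
  i_int <- interactions(m_int)
  expect_equal(i_add$matrix, t(i_add$matrix))
  expect_true(all(diag(i_add$matrix) == 0))
  expect_equal(i_add$sums, rowSums(i_add$matrix))
  expect_lte(i_add$matrix["x1", "x2"], 0.1 * i_int$matrix["x1", "x2"])
})

test_that("simplify: drops noise, keeps strong independent predictors", {
  set.seed(21)
  cfg <- brt_config(learning_rate = 0.05, max_trees = 500, n_folds = 5,
                    seed = 13)
  drops <- vapply(1:10, function(s) {
    set.seed(100 + s)
    n <- 300
    X <- cbind(s1 = rnorm(n), s2 = rnorm(n), s3 = rnorm(n),
               junk = rnorm(n))
    y <- rbinom(n, 1, plogis(1.5 * X[, "s1"] - 1.5 * X[, "s2"] +
                               1.5 * X[, "s3"]))
    m <- fit_with_cv(make_sample(X, y), config = cfg)
    keep <- simplify(m)
    expect_true(all(keep %in% colnames(X))) # subset property
    !("junk" %in% keep)
  }, logical(1))
  expect_gte(sum(drops), 8)
  # all-strong case: nothing dropped
  set.seed(33)
  n <- 400
  X <- cbind(s1 = rnorm(n), s2 = rnorm(n), s3 = rnorm(n))
  y <- rbinom(n, 1, plogis(2 * X[, "s1"] - 2 * X[, "s2"] + 2 * X[, "s3"]))
  m <- fit_with_cv(make_sample(X, y), config = cfg)
  expect_setequal(simplify(m), colnames(X))
})

test_that("predict_map: consistency, masks, missing predictors", {
  f <- small_fit()
  m <- f$model
  pm <- predict_map(m, f$stack, mask = f$world$mask)
  expect_true(all(is.na(pm$prob[f$world$mask])))
  expect_true(all(pm$prob >= 0 & pm$prob <= 1, na.rm = TRUE))
  # prediction on the training cells equals the model's fitted values
  expect_equal(unname(predict(m, m$sample$X)), unname(m$fitted),
               tolerance = 1e-12)
  # constant stack -> constant map
  stc <- f$stack
  stc$values <- matrix(rep(colMeans(stc$values), each = nrow(stc$values)),
                       nrow(stc$values),
                       dimnames = dimnames(stc$values))
  expect_equal(var(predict_map(m, stc)$prob), 0)
  badstack <- f$stack
  keep <- setdiff(colnames(badstack$values), "BIO1")
  badstack$values <- badstack$values[, keep]
  expect_error(predict(m, badstack$values), "BIO1")
})

test_that("refits under the same seed are bit-identical", {
  set.seed(3)
  n <- 200
  X <- cbind(a = rnorm(n), b = rnorm(n))
  y <- rbinom(n, 1, plogis(X[, 1]))
  cfg <- brt_config(learning_rate = 0.05, max_trees = 300, n_folds = 5,
                    seed = 77)
  m1 <- fit_with_cv(make_sample(X, y), config = cfg)
  m2 <- fit_with_cv(make_sample(X, y), config = cfg)
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$cv_deviance, m2$cv_deviance)
})
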