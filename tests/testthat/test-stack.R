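test_that("cluster folds form a balanced seeded partition", {
  f <- make_cv_folds(100, 5, seed = 3)
  expect_equal(as.vector(table(f)), rep(20L, 5))
  expect_identical(f, make_cv_folds(100, 5, seed = 3))
  expect_false(identical(f, make_cv_folds(100, 5, seed = 4)))
  expect_error(make_cv_folds(10, 1), "k")
  expect_error(make_cv_folds(3, 5), "at least")
})

test_that("lasso with a vanishing penalty recovers a noiseless linear map", {
  set.seed(5)
  X <- matrix(rnorm(200 * 3), 200, 3)
  y <- 1.5 + X %*% c(2, -1, 0.5)
  fit <- fit_submodel("l1_linear", X, y, control = list(lambda = 1e-10))
  ols <- lm.fit(cbind(1, X), y)$coefficients
  expect_equal(predict(fit, X), as.numeric(y), tolerance = 1e-6)
  expect_equal(predict(fit, X), as.numeric(cbind(1, X) %*% ols),
               tolerance = 1e-6)
})

test_that("additive splines reproduce a linear signal on its range", {
  set.seed(6)
  X <- matrix(runif(300, -2, 2), ncol = 2)
  colnames(X) <- c("a", "b")
  y <- 0.5 + 1.2 * X[, 1] - 0.7 * X[, 2]
  fit <- fit_submodel("additive_splines", X, y)
  lsq <- as.numeric(cbind(1, X) %*% lm.fit(cbind(1, X), y)$coefficients)
  expect_equal(predict(fit, X), lsq, tolerance = 0.02)
})

test_that("shallow boosting fits a one-dimensional step function", {
  set.seed(7)
  x <- matrix(runif(400), ncol = 1)
  y <- ifelse(x[, 1] > 0.5, 2, -1)
  fit <- fit_submodel("boosted_trees", x, y,
                      control = list(max_depth = 1, eta = 0.3,
                                     nrounds = 400))
  pred <- predict(fit, x)
  r2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  expect_gte(r2, 0.95)
})

test_that("constant outcomes yield constant predictors, not errors", {
  X <- matrix(rnorm(60), 20, 3)
  fit <- fit_submodel("l1_linear", X, rep(2.5, 20))
  expect_equal(predict(fit, X), rep(2.5, 20))
})

test_that("stack features exist for every observation and pixel-time", {
  st <- small_study()
  feats <- generate_stack_features(st$lvl1, st$world, "binomial", seed = 2)
  expect_equal(nrow(feats$oos), nrow(st$lvl1))
  expect_equal(nrow(feats$grid), st$world$n_pix * st$world$n_time)
  expect_true(all(is.finite(feats$oos)))
  expect_true(all(is.finite(feats$grid)))
  expect_equal(ncol(feats$oos), 3L)
})

test_that("out-of-sample features never see their own fold's outcomes", {
  st <- small_study()
  obs <- st$lvl1
  folds <- make_cv_folds(nrow(obs), 5, seed = 9)
  f1 <- generate_stack_features(obs, st$world, "binomial", folds = folds,
                                kinds = "l1_linear", seed = 2)
  # corrupt the outcome of one fold-3 observation: fold-3 OOS predictions of
  # the OTHER fold-3 rows come from a fit that excluded fold 3, so they and
  # every other fold's rows trained without it must only change where that
  # observation entered training
  j <- which(folds == 3)[1]
  obs2 <- obs
  obs2$successes[j] <- max(0, obs2$trials[j] - obs2$successes[j])
  f2 <- generate_stack_features(obs2, st$world, "binomial", folds = folds,
                                kinds = "l1_linear", seed = 2)
  keep3 <- setdiff(which(folds == 3), j)
  expect_equal(f1$oos[keep3, 1], f2$oos[keep3, 1], tolerance = 1e-12)
  expect_equal(f1$oos[j, 1], f2$oos[j, 1], tolerance = 1e-12)
})

test_that("an informative submodel outperforms pure noise out of sample", {
  st <- small_study()
  obs <- st$lvl1
  w <- st$world
  folds <- make_cv_folds(nrow(obs), 5, seed = 4)
  # hand one model the true linear predictor as its only feature
  truth_feat <- st$truth$eta1[cbind(obs$pixel, obs$t)]
  set.seed(8)
  noise_feat <- rnorm(nrow(obs))
  oos_for <- function(feat) {
    out <- numeric(nrow(obs))
    y <- qlogis(pmin(pmax(obs$successes / obs$trials,
                          0.5 / (obs$trials + 1)),
                     1 - 0.5 / (obs$trials + 1)))
    X <- cbind(f1 = feat, f2 = feat^2)
    for (f in 1:5) {
      fit <- fit_submodel("l1_linear", X[folds != f, ],
                          y[folds != f], obs$trials[folds != f],
                          control = list(lambda = 1e-8))
      out[folds == f] <- predict(fit, X[folds == f, ])
    }
    out
  }
  y_obs <- obs$successes / obs$trials
  expect_gt(cor(oos_for(truth_feat), y_obs),
            cor(oos_for(noise_feat), y_obs) + 0.2)
})
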