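test_that("the binomial data term matches direct pmf evaluation", {
  # C = 3 of N = 10 at p = 0.5: -log[ choose(10,3) * 0.5^10 ]
  expect_equal(neg_log_posterior(0, successes = 3, trials = 10),
               10 * log(2) - log(choose(10, 3)), tolerance = 1e-12)
  # zero-trial records contribute exactly nothing
  expect_identical(neg_log_posterior(1.3, successes = 0, trials = 0), 0)
  # doubling every count doubles the data term at fixed p
  eta <- c(-0.4, 1.1)
  a <- neg_log_posterior(eta, successes = c(3, 7), trials = c(10, 12))
  b <- neg_log_posterior(eta, successes = c(6, 14), trials = c(20, 24))
  brute <- function(C, N, p) -sum(lchoose(N, C) + C * log(p) +
                                    (N - C) * log(1 - p))
  expect_equal(a, brute(c(3, 7), c(10, 12), plogis(eta)), tolerance = 1e-10)
  # the pmf normalization differs between the two scales; the kernel doubles
  ka <- a + sum(lchoose(c(10, 12), c(3, 7)))
  kb <- b + sum(lchoose(c(20, 24), c(6, 14)))
  expect_equal(kb, 2 * ka, tolerance = 1e-10)
})

test_that("Laplace inference is exact for the conjugate Gaussian model", {
  w <- build_world(world_config(grid_rows = 4, grid_cols = 4,
                                n_countries = 1, n_admin1 = 2, n_admin2 = 2,
                                years = 2000:2001), seed = 5)
  params <- list(omega2 = 0.5, delta = 2.5, rho = 0.6, gamma2 = 0.3,
                 sigma2 = 0.1, tau = 0.05, nu = 2)
  set.seed(6)
  n <- 12
  obs <- data.frame(pixel = sample(w$n_pix, n), t = sample(1:2, n, TRUE),
                    country = 1, design = "point",
                    mean_years = rnorm(n, 6, 2), N = sample(20:60, n, TRUE),
                    source_id = "s")
  fit <- edu_geostat(obs, w, indicator = "mean_years", params = params,
                     fixed = params[c("omega2", "delta", "rho", "gamma2",
                                      "sigma2", "tau")])
  # conjugate closed form assembled independently: posterior precision
  # P = Q + A' W A, mean = P^{-1} A' W y
  nz <- w$n_pix * 2
  Ss <- matern_covariance(w$D, params$omega2, params$delta, jitter = 1e-8)
  St <- ar1_covariance(params$rho, 2)
  Q <- matrix(0, nz + 1 + n + 1, nz + 1 + n + 1)
  Q[1:nz, 1:nz] <- solve(kronecker(St, Ss))
  Q[nz + 1, nz + 1] <- 1 / params$gamma2
  # nugget latents appear in first-occurrence order of unique pixel-times
  key <- paste0(obs$pixel, "_", obs$t)
  stopifnot(!anyDuplicated(key))
  diag(Q)[nz + 1 + seq_len(n)] <- 1 / params$sigma2
  b0 <- nz + 1 + n + 1
  Q[b0, b0] <- 1 / 100
  A <- matrix(0, n, b0)
  A[cbind(1:n, (obs$t - 1) * w$n_pix + obs$pixel)] <- 1
  A[, nz + 1] <- 1
  A[cbind(1:n, nz + 1 + 1:n)] <- 1
  A[, b0] <- 1
  W <- diag(params$tau * obs$N)
  P <- Q + t(A) %*% W %*% A
  mean_post <- solve(P, t(A) %*% W %*% obs$mean_years)
  expect_equal(fit$u, as.vector(mean_post), tolerance = 1e-6)
  expect_equal(fit$beta0_se, sqrt(diag(solve(P))[b0]), tolerance = 1e-6)
})

test_that("fitted stacking weights lie on the simplex", {
  fit <- small_fit()
  expect_equal(sum(fit$weights), 1, tolerance = 1e-12)
  expect_true(all(fit$weights >= 0))
  expect_length(fit$weights, 3)
})

test_that("posterior candidate maps have the requested count and range", {
  fit <- small_fit()
  dr <- draw_posterior_fields(fit, n_draws = 200, seed = 3)
  expect_equal(dim(dr$values), c(fit$model$np, fit$model$nt, 200))
  expect_true(all(dr$values > 0 & dr$values < 1))
  # identical seed reproduces the draws
  dr2 <- draw_posterior_fields(fit, n_draws = 200, seed = 3)
  expect_identical(dr$values, dr2$values)
})

test_that("draw means concentrate on the Laplace mode on the link scale", {
  fit <- small_fit()
  dr <- draw_posterior_fields(fit, n_draws = 400, seed = 9)
  eta_draws <- qlogis(dr$values)
  eta_mean <- apply(eta_draws, c(1, 2), mean)
  eta_mode <- predict(fit, type = "link")
  eta_sd <- apply(eta_draws, c(1, 2), sd)
  # elementwise MC error bound: 4 posterior SDs / sqrt(n_draws)
  expect_true(all(abs(eta_mean - eta_mode) < 4 * eta_sd / sqrt(400) + 1e-6))
})

test_that("regional blocks make disjoint countries independent", {
  w <- build_world(world_config(grid_rows = 6, grid_cols = 6,
                                n_countries = 2, n_admin1 = 1, n_admin2 = 1,
                                years = 2000:2001), seed = 8)
  params <- list(omega2 = 0.4, delta = 2, rho = 0.5, gamma2 = 0.2,
                 sigma2 = 0.05, nu = 2)
  fx <- params[c("omega2", "delta", "rho", "gamma2", "sigma2")]
  set.seed(10)
  mk_obs <- function(ctr, n) {
    pix <- sample(which(w$country == ctr), n, replace = TRUE)
    data.frame(pixel = pix, t = sample(1:2, n, TRUE), country = ctr,
               design = "point", successes = rbinom(n, 40, 0.4),
               trials = 40, source_id = paste0("s", ctr))
  }
  o1 <- mk_obs(1, 15); o2 <- mk_obs(2, 15)
  # with a region-blocked prior and a pinned intercept, adding country-2
  # data must leave the country-1 posterior untouched
  f_joint <- edu_geostat(rbind(o1, o2), w, fixed = fx, region = w$country,
                         beta0_prior_var = 1e-10)
  f_c1 <- edu_geostat(o1, w, fixed = fx, region = w$country,
                      beta0_prior_var = 1e-10)
  pix1 <- which(w$country == 1)
  expect_equal(f_joint$Z[pix1, ], f_c1$Z[pix1, ], tolerance = 1e-5)
  expect_equal(f_joint$ctr[["1"]], f_c1$ctr[["1"]], tolerance = 1e-5)
})

test_that("fit methods expose coherent summaries", {
  fit <- small_fit()
  co <- coef(fit)
  expect_true(all(c("beta0", "omega2", "delta", "rho") %in% names(co)))
  s <- summary(fit)
  expect_s3_class(s, "summary.edu_geostat")
  expect_output(print(fit), "geostatistical")
  r <- residuals(fit)
  expect_length(r, nrow(fit$model$obs))
  expect_lt(abs(mean(r)), 0.2)
  surf <- predict(fit)
  expect_true(all(surf > 0 & surf < 1))
  sims <- simulate(fit, nsim = 30, seed = 1)
  expect_identical(dim(sims), c(nrow(fit$model$obs), 30L))
  expect_true(all(sims >= 0 & sims <= fit$model$obs$trials))
})

test_that("polygon observations enter the likelihood and fit converges", {
  st <- small_study()
  srcs <- default_sources(st$world, clusters_per_source = 6,
                          with_polygon = TRUE)
  obs <- simulate_surveys(st$world, st$truth, srcs, seed = 4)
  cr <- cr_prepare_observations(obs)
  lvl1 <- cr[cr$level == 1, ]
  fx <- default_model_params()[c("omega2", "delta", "rho", "gamma2",
                                 "sigma2")]
  fit <- edu_geostat(lvl1, st$world, fixed = fx)
  expect_true(fit$converged)
  expect_true(is.finite(fit$objective))
  expect_gt(length(fit$model$poly), 0)
})
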