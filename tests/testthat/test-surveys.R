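test_that("simulated surveys conserve persons and honour impossible events", {
  st <- small_study()
  obs <- st$obs
  expect_equal(obs$count_zero + obs$count_1to5 + obs$count_6to11 +
                 obs$count_12plus, obs$N)
  # single-year counts agree with the bin counts
  y <- as.matrix(obs[paste0("y", 0:18)])
  expect_equal(unname(rowSums(y)), obs$N)
  expect_equal(unname(rowSums(y[, 2:6])), obs$count_1to5)
  # determinism
  obs2 <- simulate_surveys(st$world, st$truth,
                           default_sources(st$world,
                                           clusters_per_source = 10),
                           seed = 13)
  expect_identical(obs, obs2)
})

test_that("a zero-probability bin never produces observations", {
  w <- small_world()
  lat0 <- sample_latent_field(w, default_model_params(omega2 = 1e-12,
                                                      gamma2 = 1e-12,
                                                      sigma2 = 1e-12),
                              seed = 3)
  coefs <- truth_coefficients()
  coefs$eta1$b0 <- -40    # p(zero years) ~ 0 everywhere
  coefs$eta1$beta <- c(year = 0)
  truth <- compute_true_surfaces(w, list(eta1 = lat0, eta2 = lat0,
                                         eta3 = lat0, mu = lat0), coefs)
  src <- list(survey_source("s1", country = 1, year = w$years[1],
                            n_clusters = 20))
  obs <- simulate_surveys(w, truth, src, seed = 5)
  expect_true(all(obs$count_zero == 0))
})

test_that("large-cluster bin frequencies sit within binomial error of truth", {
  w <- build_world(world_config(grid_rows = 2, grid_cols = 2,
                                n_countries = 1, n_admin1 = 1, n_admin2 = 1,
                                years = 2000), seed = 2)
  lat0 <- sample_latent_field(w, default_model_params(omega2 = 1e-12,
                                                      gamma2 = 1e-12,
                                                      sigma2 = 1e-12),
                              seed = 1)
  # pin the bin probabilities at (0.1, 0.2, 0.3, 0.4) via the CR inverse
  coefs <- truth_coefficients()
  q <- c(0.1, 0.2 / 0.9, 0.3 / 0.7)
  coefs$eta1 <- list(b0 = qlogis(q[1]), beta = c(year = 0))
  coefs$eta2 <- list(b0 = qlogis(q[2]), beta = c(year = 0))
  coefs$eta3 <- list(b0 = qlogis(q[3]), beta = c(year = 0))
  truth <- compute_true_surfaces(w, list(eta1 = lat0, eta2 = lat0,
                                         eta3 = lat0, mu = lat0), coefs)
  expect_equal(unname(truth$bin_probs[1, 1, ]), c(0.1, 0.2, 0.3, 0.4),
               tolerance = 1e-4)
  src <- list(survey_source("big", country = 1, year = 2000, n_clusters = 1,
                            mean_cluster_size = 10000))
  obs <- simulate_surveys(w, truth, src, seed = 8)
  N <- obs$N[1]
  freq <- c(obs$count_zero, obs$count_1to5, obs$count_6to11,
            obs$count_12plus) / N
  p <- c(0.1, 0.2, 0.3, 0.4)
  expect_true(all(abs(freq - p) < 3 * sqrt(p * (1 - p) / N)))
})

test_that("clusters land on pixels proportional to population", {
  w <- small_world()
  src <- list(survey_source("dense", country = 2, year = w$years[1],
                            n_clusters = 3000, mean_cluster_size = 5))
  lat0 <- sample_latent_field(w, default_model_params(), seed = 1)
  truth <- compute_true_surfaces(w, list(eta1 = lat0, eta2 = lat0,
                                         eta3 = lat0, mu = lat0))
  obs <- simulate_surveys(w, truth, src, seed = 21)
  pix <- which(w$country == 2)
  p <- w$population[pix, 1] / sum(w$population[pix, 1])
  emp <- tabulate(match(obs$pixel, pix), length(pix)) / nrow(obs)
  se <- sqrt(p * (1 - p) / nrow(obs))
  expect_true(all(abs(emp - p) < 4 * se + 1e-9))
})

test_that("polygon observations carry valid design-effect metadata", {
  st <- small_study()
  srcs <- default_sources(st$world, clusters_per_source = 5,
                          with_polygon = TRUE)
  obs <- simulate_surveys(st$world, st$truth, srcs, seed = 4)
  pg <- obs[obs$design == "polygon", ]
  expect_gt(nrow(pg), 0)
  expect_true(all(pg$deff >= 1))
  expect_true(all(pg$N <= pg$n_raw + 1e-9))
  expect_true(is.na(pg$y0[1]))
})

test_that("requesting a year outside the world errors", {
  st <- small_study()
  src <- list(survey_source("bad", country = 1, year = 1990, n_clusters = 2))
  expect_error(simulate_surveys(st$world, st$truth, src, seed = 1),
               "outside")
})
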