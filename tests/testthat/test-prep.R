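test_that("top-coding caps at 18 and rejects negatives", {
  expect_equal(top_code_years(c(22, 5, 18, 0)), c(18, 5, 18, 0))
  expect_error(top_code_years(-1), "negative")
})

test_that("bin assignment follows the stated edges", {
  expect_equal(as.character(assign_bin(c(0, 1, 5, 6, 11, 12, 18))),
               c("zero", "1-5", "1-5", "6-11", "6-11", "12+", "12+"))
  ind <- compute_indicators(c(0, 3, 6, 12))
  expect_equal(unname(c(ind$counts)), c(1, 1, 1, 1))
  expect_equal(ind$mean, 5.25)
  expect_error(compute_indicators(numeric(0)), "empty")
})

test_that("Kish design effect and effective sample size", {
  eq <- aggregate_polygon_obs(c(0, 3, 7), rep(2, 3))
  expect_equal(eq$deff, 1)
  expect_equal(eq$n_eff, 3)
  kk <- aggregate_polygon_obs(c(0, 3, 7), c(1, 1, 2))
  expect_equal(kk$deff, 1.125)
  expect_equal(kk$n_eff, 3 / 1.125)
  expect_equal(sum(kk$proportions), 1)
  expect_error(aggregate_polygon_obs(c(0, 1), c(0, 0)), "weights")
})

test_that("DEFF is always >= 1 with equality only at equal weights", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(3:40, 1)
    w <- rgamma(n, shape = 0.7)
    d <- aggregate_polygon_obs(sample(0:18, n, replace = TRUE), w)
    expect_gte(d$deff, 1 - 1e-12)
  }
})

test_that("continuation-ratio transform conditions counts as stated", {
  tr <- cr_transform_counts(c(2, 3, 4, 1))
  expect_equal(tr$successes, c(2, 3, 4))
  expect_equal(tr$trials, c(10, 8, 5))
  dg <- cr_transform_counts(c(10, 0, 0, 0))
  expect_equal(dg$trials, c(10, 0, 0))
  expect_equal(dg$successes, c(10, 0, 0))
})

test_that("CR transform and composition are mutually inverse", {
  set.seed(17)
  for (i in 1:25) {
    p <- runif(3)
    bins <- compose_cr_probabilities(p[1], p[2], p[3])
    expect_equal(sum(bins), 1, tolerance = 1e-14)
    tr <- cr_transform_counts(unname(bins), N = 1)
    back <- tr$successes / pmax(tr$trials, .Machine$double.eps)
    expect_equal(back, p, tolerance = 1e-12)
    # and composing the recovered conditionals restores the bins
    expect_equal(unname(compose_cr_probabilities(back[1], back[2], back[3])),
                 unname(bins), tolerance = 1e-12)
  }
})

test_that("bin splitting follows the pooled training distribution", {
  mk_pool <- function(ycounts) {
    df <- data.frame(country = 1, year = 2001)
    df[paste0("y", 0:18)] <- as.list(ycounts)
    df
  }
  obs <- list(country = 1, year = 2000, count_zero = 0, count_1to5 = 50,
              count_6to11 = 0, count_12plus = 0)
  unif <- numeric(19); unif[2:6] <- 7          # uniform over years 1..5
  sp <- split_binned_counts(obs, mk_pool(unif))
  expect_equal(unname(sp$year_counts[paste0("y", 1:5)]), rep(10, 5))
  degen <- numeric(19); degen[6] <- 11         # all mass at year 5
  sp2 <- split_binned_counts(obs, mk_pool(degen))
  expect_equal(unname(sp2$year_counts[["y5"]]), 50)
  expect_equal(sp2$mean_years, 5)
  # conservation of totals
  expect_equal(sum(sp$year_counts), 50)
  # empty training mass for the bin -> uniform fallback with a warning
  empty <- numeric(19); empty[10] <- 3
  expect_warning(sp3 <- split_binned_counts(obs, mk_pool(empty)),
                 "uniform")
  expect_equal(sum(sp3$year_counts), 50)
})

test_that("observation tables expand to valid conditional records", {
  st <- small_study()
  cr <- st$cr
  expect_equal(nrow(cr), 3 * nrow(st$obs))
  expect_true(all(cr$successes <= cr$trials + 1e-9))
  expect_true(all(cr$trials >= 0))
  # level-k trials equal N minus lower-level successes
  l <- split(cr, cr$cluster_id)
  one <- l[[1]]
  expect_equal(one$trials[2], one$trials[1] - one$successes[1])
  expect_equal(one$trials[3], one$trials[2] - one$successes[2])
})
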