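# shared small fixtures, built once per test run

small_world <- local({
  w <- NULL
  function() {
    if (is.null(w)) w <<- build_world(world_config(grid_rows = 8,
                                                   grid_cols = 9,
                                                   years = 2000:2003),
                                      seed = 42)
    w
  }
})

# a compact simulated study: world + truth + point-cluster observations and
# their level-1 (zero-years) conditional-binomial rows
small_study <- local({
  s <- NULL
  function() {
    if (!is.null(s)) return(s)
    sim <- simulate_truth(world_config(grid_rows = 8, grid_cols = 9,
                                       years = 2000:2003), seed = 7)
    srcs <- default_sources(sim$world, clusters_per_source = 10)
    obs <- simulate_surveys(sim$world, sim$truth, srcs, seed = 13)
    cr <- cr_prepare_observations(obs)
    s <<- list(sim = sim, world = sim$world, truth = sim$truth, obs = obs,
               cr = cr, lvl1 = cr[cr$level == 1, ])
    s
  }
})

# one shared full model fit on the small study (three stacked features)
small_fit <- local({
  f <- NULL
  function() {
    if (!is.null(f)) return(f)
    st <- small_study()
    feats <- generate_stack_features(st$lvl1, st$world, "binomial",
                                     seed = 2)
    f <<- edu_geostat(st$lvl1, st$world, features = feats)
    f
  }
})

# dense multivariate-normal log-density, the brute-force oracle for the
# factored Kronecker computation
dense_mvn_logdens <- function(x, Sigma) {
  n <- length(x)
  ch <- chol(Sigma)
  -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ch))) +
            sum(backsolve(ch, x, transpose = TRUE)^2))
}
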