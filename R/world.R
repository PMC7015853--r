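#' Default configuration for a synthetic study region
#'
#' The default world is a 15x15 pixel grid over 6 years with 3 countries
#' (contiguous column blocks), 1 first-level and 3 second-level admin units
#' per country level as requested, and the nine covariate layers used for
#' educational-attainment mapping (access to roads, nighttime lights,
#' population, growing season, aridity, elevation, urbanicity, irrigation,
#' year), some time-varying. Distances are abstract: 1 unit = 1 pixel width.
#'
#' @param grid_rows,grid_cols grid dimensions in pixels.
#' @param n_countries number of countries (contiguous column blocks).
#' @param n_admin1 first-level admin units per country (row bands).
#' @param n_admin2 second-level admin units per admin1 (column slivers within
#'   the country block).
#' @param years calendar years covered (time indices follow their order).
#' @param covariates character vector of covariate layer names.
#' @param time_varying names of covariates that vary over time.
#' @param cov_range Matern range (pixel units) of the smooth covariate fields.
#' @param pop_sd log-scale standard deviation of the population surface.
#' @param n_hotspots number of urban population hotspots.
#' @param barren_frac fraction of pixels labelled "barren or sparsely
#'   vegetated" in the land-cover layer.
#' @return named list usable as \code{config} in [build_world()].
#' @export
world_config <- function(grid_rows = 15, grid_cols = 15,
                         n_countries = 3, n_admin1 = 3, n_admin2 = 3,
                         years = 2000:2005,
                         covariates = c("access", "nightlights", "population",
                                        "growing_season", "aridity",
                                        "elevation", "urbanicity",
                                        "irrigation", "year"),
                         time_varying = c("nightlights", "population",
                                          "aridity", "urbanicity", "year"),
                         cov_range = 6, pop_sd = 0.8, n_hotspots = 3,
                         barren_frac = 0.04) {
  list(grid_rows = grid_rows, grid_cols = grid_cols,
       n_countries = n_countries, n_admin1 = n_admin1, n_admin2 = n_admin2,
       years = years, covariates = covariates, time_varying = time_varying,
       cov_range = cov_range, pop_sd = pop_sd, n_hotspots = n_hotspots,
       barren_frac = barren_frac)
}

#' Build a synthetic study region
#'
#' Generates the raster-like scaffolding the attainment model consumes: pixel
#' centres, a nested country/admin1/admin2 hierarchy (countries are contiguous
#' column blocks, admin1 row bands within countries, admin2 column slivers
#' within admin1), smooth random covariate fields (Matern-correlated spatial
#' signal plus white noise; time-varying layers evolve as an AR1 in time),
#' a log-normal population surface with urban hotspots, and a land-cover
#' class layer. Deterministic given \code{seed}.
#'
#' @param config list from [world_config()].
#' @param seed integer seed.
#' @return object of class \code{"edu_world"}: list with \code{grid_rows},
#'   \code{grid_cols}, \code{n_pix}, \code{coords} (n_pix x 2 matrix of pixel
#'   centres), \code{years}, \code{n_time}, \code{country}, \code{admin1},
#'   \code{admin2} (integer labels per pixel; admin ids are globally unique
#'   and nested), \code{covariates} (array n_pix x n_time x n_cov, dimnames
#'   on the third margin), \code{time_varying}, \code{population}
#'   (n_pix x n_time), \code{landcover} (character per pixel), \code{D}
#'   (pairwise pixel distances).
#' @export
build_world <- function(config = world_config(), seed = 1) {
  gr <- config$grid_rows; gc <- config$grid_cols
  if (gr < 2 || gc < config$n_countries)
    stop("grid too small for the requested admin units")
  if (config$n_admin1 > gr)
    stop("grid too small for the requested admin units")
  np <- gr * gc
  # pixel (row, col) centres; column-major like R matrices
  coords <- cbind(row = rep(seq_len(gr), times = gc),
                  col = rep(seq_len(gc), each = gr))
  D <- as.matrix(stats::dist(coords))
  years <- config$years
  nt <- length(years)

  # countries: contiguous column blocks
  col_country <- as.integer(cut(coords[, "col"],
                                breaks = seq(0.5, gc + 0.5,
                                             length.out = config$n_countries + 1),
                                labels = FALSE))
  # admin1: row bands within country; admin2: column slivers within admin1
  row_band <- as.integer(cut(coords[, "row"],
                             breaks = seq(0.5, gr + 0.5,
                                          length.out = config$n_admin1 + 1),
                             labels = FALSE))
  admin1 <- (col_country - 1L) * config$n_admin1 + row_band
  # sliver index within the country's column block
  cc_width <- tapply(coords[, "col"], col_country, function(x) range(x))
  sliver <- integer(np)
  for (ctr in seq_len(config$n_countries)) {
    idx <- col_country == ctr
    rng <- cc_width[[ctr]]
    sliver[idx] <- as.integer(cut(coords[idx, "col"],
                                  breaks = seq(rng[1] - 0.5, rng[2] + 0.5,
                                               length.out = config$n_admin2 + 1),
                                  labels = FALSE))
  }
  admin2 <- (admin1 - 1L) * config$n_admin2 + sliver

  set.seed(seed %% .Machine$integer.max)
  Sigma_cov <- matern_covariance(D, omega2 = 1, delta = config$cov_range,
                                 jitter = 1e-8)
  Ls <- t(chol(Sigma_cov))
  n_cov <- length(config$covariates)
  covs <- array(0, c(np, nt, n_cov),
                dimnames = list(NULL, NULL, config$covariates))
  for (j in seq_len(n_cov)) {
    nm <- config$covariates[j]
    if (nm == "year") {
      # linear time trend layer, shared by all pixels
      tr <- if (nt > 1) scale(seq_len(nt))[, 1] else 0
      covs[, , j] <- matrix(rep(tr, each = np), np, nt)
      next
    }
    base <- as.vector(Ls %*% stats::rnorm(np)) + 0.25 * stats::rnorm(np)
    if (nm %in% config$time_varying) {
      phi <- 0.9
      f <- base
      for (t in seq_len(nt)) {
        covs[, t, j] <- f
        innov <- as.vector(Ls %*% stats::rnorm(np))
        f <- phi * f + sqrt(1 - phi^2) * 0.5 * innov
      }
    } else {
      covs[, , j] <- matrix(rep(base, nt), np, nt)
    }
  }

  # population: log-normal smooth field plus urban hotspots, mild growth
  logpop <- config$pop_sd * as.vector(Ls %*% stats::rnorm(np)) + log(100)
  hot <- sample.int(np, config$n_hotspots)
  for (h in hot) {
    d2 <- (coords[, 1] - coords[h, 1])^2 + (coords[, 2] - coords[h, 2])^2
    logpop <- logpop + 2.5 * exp(-d2 / 4)
  }
  growth <- 0.01 * (seq_len(nt) - 1)
  population <- exp(outer(logpop, growth, "+"))

  # land cover: barren pixels concentrated where population is lowest
  landcover <- rep("vegetated", np)
  n_barren <- round(config$barren_frac * np)
  if (n_barren > 0)
    landcover[order(logpop)[seq_len(n_barren)]] <- "barren or sparsely vegetated"

  structure(list(grid_rows = gr, grid_cols = gc, n_pix = np, coords = coords,
                 years = years, n_time = nt,
                 country = col_country, admin1 = admin1, admin2 = admin2,
                 covariates = covs, time_varying = config$time_varying,
                 population = population, landcover = landcover, D = D,
                 config = config, seed = seed),
            class = "edu_world")
}

#' @export
print.edu_world <- function(x, ...) {
  cat("Synthetic study region:", x$grid_rows, "x", x$grid_cols, "pixels,",
      x$n_time, "years (", min(x$years), "-", max(x$years), ")\n")
  cat("  countries:", length(unique(x$country)),
      " admin1:", length(unique(x$admin1)),
      " admin2:", length(unique(x$admin2)), "\n")
  cat("  covariate layers:", paste(dimnames(x$covariates)[[3]], collapse = ", "), "\n")
  invisible(x)
}

#' Sample the space-time latent structure of the attainment model
#'
#' Draws the residual components the geostatistical model assumes: a
#' Matern-by-AR1 Kronecker Gaussian-process field \code{Z}, iid country
#' effects with variance \code{gamma2}, and an iid pixel-time nugget with
#' variance \code{sigma2}. Used as simulation ground truth.
#'
#' @param world an \code{edu_world}.
#' @param params list with \code{omega2}, \code{delta}, \code{rho},
#'   \code{gamma2}, \code{sigma2} (and optionally \code{nu}, default 2).
#' @param seed integer seed.
#' @return list with \code{Z} (n_pix x n_time), \code{ctr} (per-country
#'   effect), \code{nugget} (n_pix x n_time).
#' @export
sample_latent_field <- function(world, params, seed = 1) {
  nu <- if (is.null(params$nu)) 2 else params$nu
  set.seed(seed %% .Machine$integer.max)
  n_ctr <- length(unique(world$country))
  if (params$omega2 <= 0) {
    Z <- matrix(0, world$n_pix, world$n_time)
  } else {
    Ss <- matern_covariance(world$D, params$omega2, params$delta, nu,
                            jitter = 1e-8)
    St <- ar1_covariance(params$rho, world$n_time)
    Z <- sample_kronecker_field(Ss, St)
    if (world$n_time == 1) Z <- matrix(Z, ncol = 1)
  }
  ctr <- stats::rnorm(n_ctr, 0, sqrt(params$gamma2))
  nugget <- matrix(stats::rnorm(world$n_pix * world$n_time, 0,
                                sqrt(params$sigma2)),
                   world$n_pix, world$n_time)
  list(Z = Z, ctr = ctr, nugget = nugget)
}
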