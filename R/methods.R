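#' @export
print.edu_geostat <- function(x, ...) {
  cat("Space-time geostatistical attainment model (",
      if (x$family == "binomial") "conditional binomial, logit link"
      else "mean years, identity link", ")\n", sep = "")
  m <- x$model
  cat(sprintf("  grid %d pixels x %d years, %d observations\n",
              m$np, m$nt, nrow(m$obs)))
  cat(sprintf("  intercept beta0 = %.3f (Laplace SE %.3f)\n",
              x$beta0, x$beta0_se))
  if (length(x$weights) > 1)
    cat("  stacking weights:",
        paste(sprintf("%.3f", x$weights), collapse = ", "),
        "(sum", format(sum(x$weights)), ")\n")
  h <- x$params
  cat(sprintf("  omega2 = %.3g  delta = %.3g  rho = %.3g  gamma2 = %.3g  sigma2 = %.3g%s\n",
              h$omega2, h$delta, h$rho, h$gamma2, h$sigma2,
              if (!is.null(h$tau)) sprintf("  tau = %.3g", h$tau) else ""))
  cat("  converged:", x$converged, "\n")
  invisible(x)
}

#' @export
summary.edu_geostat <- function(object, ...) {
  out <- list(
    indicator = object$indicator,
    n_obs = nrow(object$model$obs),
    beta0 = object$beta0, beta0_se = object$beta0_se,
    weights = object$weights,
    hyperparameters = object$params[c("omega2", "delta", "rho", "gamma2",
                                      "sigma2", "tau")],
    objective = object$objective,
    converged = object$converged,
    country_effects = object$ctr)
  class(out) <- "summary.edu_geostat"
  out
}

#' @export
print.summary.edu_geostat <- function(x, ...) {
  cat("Indicator:", x$indicator, " (", x$n_obs, "observations )\n")
  cat(sprintf("Intercept: %.4f (SE %.4f)\n", x$beta0, x$beta0_se))
  if (length(x$weights) > 1) {
    cat("Stacking weights (sum to 1):\n")
    print(round(x$weights, 4))
  }
  cat("Hyperparameters:\n")
  print(unlist(x$hyperparameters))
  cat("Country effects:\n")
  print(round(x$country_effects, 4))
  cat("Negative log marginal posterior:", format(x$objective), "\n")
  invisible(x)
}

#' @export
coef.edu_geostat <- function(object, ...) {
  w <- object$weights
  names(w) <- if (!is.null(object$model$features))
    paste0("w_", colnames(object$model$features$oos))
  else "w_1"
  c(beta0 = object$beta0, w,
    unlist(object$params[c("omega2", "delta", "rho", "gamma2", "sigma2",
                           "tau")]))
}

#' Predicted attainment surfaces
#'
#' Posterior surfaces over all pixel-times, either at the Laplace mode
#' (pushed through the link, with the in-sample feature grids as mean
#' function) or summarized from posterior candidate maps.
#'
#' @param object an \code{edu_geostat}.
#' @param type \code{"response"} (probability / years) or \code{"link"}.
#' @param draws optional \code{edu_draws} from [draw_posterior_fields()];
#'   when supplied, the posterior mean of the draws is returned instead of
#'   the plug-in mode surface.
#' @param ... unused.
#' @return matrix n_pix x n_time.
#' @export
predict.edu_geostat <- function(object, type = c("response", "link"),
                                draws = NULL, ...) {
  type <- match.arg(type)
  if (!is.null(draws)) {
    stopifnot(inherits(draws, "edu_draws"))
    mean_surf <- apply(draws$values, c(1, 2), mean)
    if (type == "response") return(mean_surf)
    return(stats::qlogis(pmin(pmax(mean_surf, 1e-12), 1 - 1e-12)))
  }
  m <- object$model
  ctr_of_pix <- match(m$world$country, m$ctr_levels)
  eta <- matrix(object$offset$grid, m$np, m$nt) + object$Z +
    object$ctr[ctr_of_pix] + object$beta0
  if (type == "link") return(eta)
  if (object$family == "binomial")
    stats::plogis(pmin(pmax(eta, -30), 30))
  else pmin(pmax(eta, 0), 18)
}

#' Working residuals at observed clusters
#'
#' Observed cluster proportions (or means) minus the mode-surface prediction
#' at the cluster's pixel-time; \code{type = "pearson"} scales by the
#' binomial (or Gaussian) standard deviation.
#'
#' @param object an \code{edu_geostat}.
#' @param type \code{"response"} or \code{"pearson"}.
#' @param ... unused.
#' @return numeric vector, one value per point observation.
#' @export
residuals.edu_geostat <- function(object, type = c("response", "pearson"),
                                  ...) {
  type <- match.arg(type)
  m <- object$model
  pt <- m$point
  if (is.null(pt)) return(numeric(0))
  obs <- m$obs
  eta <- object$offset$obs[pt$rows] + object$u[pt$zi] + object$u[pt$ci] +
    object$u[pt$ni] + object$u[m$b0i]
  if (object$family == "binomial") {
    p <- stats::plogis(pmin(pmax(eta, -30), 30))
    yhat <- obs$successes[pt$rows] / pmax(obs$trials[pt$rows], 1)
    r <- yhat - p
    if (type == "pearson")
      r <- r / sqrt(pmax(p * (1 - p) / pmax(obs$trials[pt$rows], 1), 1e-12))
  } else {
    r <- obs$mean_years[pt$rows] - eta
    if (type == "pearson")
      r <- r * sqrt(object$params$tau * obs$N[pt$rows])
  }
  r
}

#' Posterior-predictive simulation of observed clusters
#'
#' Simulates new observations at the observed clusters from the posterior:
#' each replicate pushes one joint Laplace draw of the latent field through
#' the link at every point observation's pixel-time (adding fresh nugget
#' noise) and then through the observation model (binomial sampling at the
#' cluster's N, or Gaussian noise at precision tau N). This is the
#' machinery behind predictive-interval coverage checks.
#'
#' @param object an \code{edu_geostat}.
#' @param nsim number of replicates.
#' @param seed integer seed.
#' @param newdata optional data.frame of point observations (\code{pixel},
#'   \code{t}, \code{country}, \code{trials} or \code{N}, and optionally
#'   stack-feature rows via attribute or \code{features} argument) — by
#'   default the fitted observations are used.
#' @param features optional OOS feature matrix for \code{newdata} rows; when
#'   missing, predictions use the in-sample feature grids at the new
#'   pixel-times.
#' @param ... unused.
#' @return matrix n_obs x nsim of simulated successes (binomial) or means
#'   (Gaussian).
#' @export
simulate.edu_geostat <- function(object, nsim = 1000, seed = 1,
                                 newdata = NULL, features = NULL, ...) {
  set.seed(seed %% .Machine$integer.max)
  m <- object$model
  if (is.null(newdata)) {
    pt <- m$point
    if (is.null(pt)) stop("no point observations to simulate")
    obs <- m$obs[pt$rows, ]
    off <- object$offset$obs[pt$rows]
    zi <- pt$zi; ci <- pt$ci; ni <- pt$ni
  } else {
    ni <- NULL
    obs <- newdata
    zi <- (obs$t - 1L) * m$np + obs$pixel
    ci <- m$nz + match(obs$country, m$ctr_levels)
    if (is.null(features)) {
      off <- object$offset$grid[zi]
    } else {
      off <- as.vector(as.matrix(features) %*% object$params$beta)
    }
  }
  nobs <- nrow(obs)
  U <- object$cholH
  out <- matrix(0, nobs, nsim)
  ntr <- if (object$family == "binomial") obs$trials else obs$N
  for (r in seq_len(nsim)) {
    u <- object$u + backsolve(U, stats::rnorm(m$n_lat))
    # in-sample rows use their posterior nugget; new rows get fresh noise
    nug <- if (is.null(ni))
      stats::rnorm(nobs, 0, sqrt(object$params$sigma2)) else u[ni]
    # countries unseen in training get a fresh effect from N(0, gamma2)
    ctr_term <- numeric(nobs)
    seen <- !is.na(ci)
    ctr_term[seen] <- u[ci[seen]]
    if (any(!seen))
      ctr_term[!seen] <- stats::rnorm(sum(!seen), 0,
                                      sqrt(object$params$gamma2))
    eta <- off + u[zi] + ctr_term + u[m$b0i] + nug
    if (object$family == "binomial") {
      p <- stats::plogis(pmin(pmax(eta, -30), 30))
      out[, r] <- stats::rbinom(nobs, round(ntr), p)
    } else {
      out[, r] <- stats::rnorm(nobs, eta,
                               1 / sqrt(object$params$tau * ntr))
    }
  }
  out
}

#' Map a fitted attainment surface
#'
#' Images the posterior (mode or draw-mean) surface of one year on the pixel
#' grid, with country borders overlaid.
#'
#' @param x an \code{edu_geostat}.
#' @param year calendar year to map (default last).
#' @param draws optional \code{edu_draws} for a draw-mean map.
#' @param ... passed to [graphics::image()].
#' @return invisibly, the matrix that was imaged.
#' @export
plot.edu_geostat <- function(x, year = NULL, draws = NULL, ...) {
  w <- x$model$world
  if (is.null(year)) year <- w$years[w$n_time]
  t_idx <- match(year, w$years)
  if (is.na(t_idx)) stop("year outside the fitted world")
  surf <- predict(x, draws = draws)[, t_idx]
  mat <- matrix(surf, w$grid_rows, w$grid_cols)
  graphics::image(seq_len(w$grid_cols), seq_len(w$grid_rows), t(mat),
                  xlab = "pixel column", ylab = "pixel row",
                  main = paste0(x$indicator, " surface, ", year), ...)
  invisible(mat)
}
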