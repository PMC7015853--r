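#' Negative log-likelihood of attainment observations
#'
#' The data term of the model's posterior: binomial count likelihood with
#' success probability \code{plogis(eta)} (linear predictor clamped at
#' \eqn{\pm 30} before the inverse logit as an overflow guard), or Gaussian
#' likelihood with mean \code{eta} and precision \code{tau * s} (the
#' precision-scaling reading: the variance of a cluster mean is
#' \code{1/(tau * s)} with \code{s} the cluster sample size).
#' Zero-trial records contribute exactly zero. During fitting this data term
#' is combined with Gaussian penalties for the Kronecker space-time field,
#' the country effects, the nugget, and weak priors on the intercept and
#' hyperparameters; \code{penalty} lets callers add such terms explicitly.
#'
#' @param eta linear predictor per observation.
#' @param successes,trials binomial data (fractional trials allowed).
#' @param y,s Gaussian data: observed means and precision scalings.
#' @param tau Gaussian observation precision.
#' @param family \code{"binomial"} or \code{"gaussian"}.
#' @param penalty additional penalty value added to the data term.
#' @return scalar negative log posterior contribution.
#' @examples
#' neg_log_posterior(0, successes = 3, trials = 10)  # 10*log(2) - log(120)
#' @export
neg_log_posterior <- function(eta, successes = NULL, trials = NULL,
                              y = NULL, s = NULL, tau = 1,
                              family = c("binomial", "gaussian"),
                              penalty = 0) {
  family <- match.arg(family)
  if (family == "binomial") {
    if (is.null(successes) || is.null(trials))
      stop("binomial family needs successes and trials")
    eta <- pmin(pmax(eta, -30), 30)
    p <- stats::plogis(eta)
    ll <- ifelse(trials > 0,
                 lgamma(trials + 1) - lgamma(successes + 1) -
                   lgamma(trials - successes + 1) +
                   successes * log(p) + (trials - successes) * log1p(-p),
                 0)
    if (any(!is.finite(ll))) stop("non-finite likelihood value")
    -sum(ll) + penalty
  } else {
    if (is.null(y) || is.null(s)) stop("gaussian family needs y and s")
    prec <- tau * s
    ll <- 0.5 * log(prec) - 0.5 * log(2 * pi) - 0.5 * prec * (y - eta)^2
    if (any(!is.finite(ll))) stop("non-finite likelihood value")
    -sum(ll) + penalty
  }
}

# transformed-scale hyperparameter helpers ---------------------------------

theta_names_for <- function(family, n_weights, fixed) {
  base <- c("log_omega2", "log_delta", "rho_t", "log_gamma2", "log_sigma2")
  if (family == "gaussian") base <- c(base, "log_tau")
  base <- setdiff(base, paste0("log_", names(fixed)))
  if ("rho" %in% names(fixed)) base <- setdiff(base, "rho_t")
  if (n_weights > 1 && !"beta" %in% names(fixed))
    base <- c(base, paste0("a", seq_len(n_weights - 1)))
  base
}

theta_to_params <- function(theta, family, n_weights, fixed, nu = 2) {
  gv <- function(nm, fx, tr) {
    if (fx %in% names(fixed)) fixed[[fx]] else tr(theta[[nm]])
  }
  p <- list(
    omega2 = gv("log_omega2", "omega2", exp),
    delta = gv("log_delta", "delta", exp),
    rho = if ("rho" %in% names(fixed)) fixed$rho
          else 2 * stats::plogis(theta[["rho_t"]]) - 1,
    gamma2 = gv("log_gamma2", "gamma2", exp),
    sigma2 = gv("log_sigma2", "sigma2", exp),
    nu = nu)
  if (family == "gaussian") p$tau <- gv("log_tau", "tau", exp)
  if ("beta" %in% names(fixed)) {
    p$beta <- fixed$beta
  } else if (n_weights > 1) {
    a <- c(vapply(seq_len(n_weights - 1),
                  function(i) theta[[paste0("a", i)]], 0), 0)
    p$beta <- exp(a - max(a)); p$beta <- p$beta / sum(p$beta)
  } else p$beta <- 1
  p
}

params_to_theta <- function(params, family, n_weights, fixed) {
  nm <- theta_names_for(family, n_weights, fixed)
  th <- stats::setNames(numeric(length(nm)), nm)
  if ("log_omega2" %in% nm) th["log_omega2"] <- log(params$omega2)
  if ("log_delta" %in% nm) th["log_delta"] <- log(params$delta)
  if ("rho_t" %in% nm) th["rho_t"] <- stats::qlogis((params$rho + 1) / 2)
  if ("log_gamma2" %in% nm) th["log_gamma2"] <- log(params$gamma2)
  if ("log_sigma2" %in% nm) th["log_sigma2"] <- log(params$sigma2)
  if ("log_tau" %in% nm) th["log_tau"] <- log(params$tau)
  for (i in seq_len(n_weights - 1))
    if (paste0("a", i) %in% nm) th[paste0("a", i)] <- 0
  th
}

# weakly informative hyperpriors on the transformed scale; negative log
neg_log_hyperprior <- function(theta) {
  pen <- 0
  pr <- list(log_omega2 = c(0, 3), log_delta = c(log(4), 1.5),
             rho_t = c(0, 2), log_gamma2 = c(0, 3), log_sigma2 = c(0, 3),
             log_tau = c(0, 3))
  for (nm in names(theta)) {
    p <- if (nm %in% names(pr)) pr[[nm]] else c(0, 2)  # softmax weights
    pen <- pen + 0.5 * ((theta[[nm]] - p[1]) / p[2])^2
  }
  pen
}

# model structure shared by the objective, the fitter and the draw engine
build_geostat_model <- function(obs, world, features, family, region,
                                beta0_prior_var) {
  np <- world$n_pix; nt <- world$n_time
  ctr_levels <- sort(unique(world$country))
  n_ctr <- length(ctr_levels)
  pt_rows <- which(obs$design != "polygon")
  pg_rows <- which(obs$design == "polygon")
  # nugget latents: one per unique observed pixel-time, one per polygon row
  ptk <- paste0(obs$pixel[pt_rows], "_", obs$t[pt_rows])
  upt <- unique(ptk)
  n_nug <- length(upt) + length(pg_rows)
  nz <- np * nt
  n_lat <- nz + n_ctr + n_nug + 1L
  b0i <- n_lat
  point <- NULL
  if (length(pt_rows)) {
    point <- list(
      rows = pt_rows,
      zi = (obs$t[pt_rows] - 1L) * np + obs$pixel[pt_rows],
      ci = nz + match(obs$country[pt_rows], ctr_levels),
      ni = nz + n_ctr + match(ptk, upt))
  }
  poly <- list()
  for (j in seq_along(pg_rows)) {
    r <- pg_rows[j]
    upix <- which(world$admin2 == obs$admin2_id[r])
    w <- world$population[upix, obs$t[r]]
    if (sum(w) <= 0) stop("polygon unit with zero population")
    poly[[j]] <- list(
      row = r, pix = upix, w = w / sum(w),
      zi = (obs$t[r] - 1L) * np + upix,
      ci = nz + match(obs$country[r], ctr_levels),
      ni = nz + n_ctr + length(upt) + j)
  }
  if (is.null(region)) region <- rep(1L, np)
  list(obs = obs, world = world, features = features, family = family,
       np = np, nt = nt, nz = nz, n_ctr = n_ctr, ctr_levels = ctr_levels,
       n_nug = n_nug, n_lat = n_lat, b0i = b0i, point = point, poly = poly,
       region = region, beta0_prior_var = beta0_prior_var)
}

# prior precision and its log-determinant for given hyperparameters
build_prior <- function(model, params) {
  w <- model$world
  Ss <- matern_covariance(w$D, params$omega2, params$delta, params$nu,
                          jitter = 1e-8)
  if (length(unique(model$region)) > 1) {
    same <- outer(model$region, model$region, "==")
    Ss[!same] <- 0
  }
  St <- ar1_covariance(params$rho, w$n_time)
  cs <- chol(Ss); ct <- chol(St)
  Qz <- kronecker(chol2inv(ct), chol2inv(cs))
  logdetQ <- -(2 * w$n_time * sum(log(diag(cs))) +
                 2 * w$n_pix * sum(log(diag(ct))))
  qdiag <- c(rep(0, model$nz), rep(1 / params$gamma2, model$n_ctr),
             rep(1 / params$sigma2, model$n_nug), 1 / model$beta0_prior_var)
  logdetQ <- logdetQ - model$n_ctr * log(params$gamma2) -
    model$n_nug * log(params$sigma2) - log(model$beta0_prior_var)
  Q <- diag(qdiag)
  Q[seq_len(model$nz), seq_len(model$nz)] <- Qz
  list(Q = Q, logdetQ = logdetQ)
}

# per-observation stack offset F beta (zero-trial rows keep an offset too)
stack_offset <- function(model, params) {
  if (is.null(model$features)) {
    list(obs = rep(0, nrow(model$obs)),
         grid = rep(0, model$nz))
  } else {
    list(obs = as.vector(model$features$oos %*% params$beta),
         grid = as.vector(model$features$grid %*% params$beta))
  }
}

# data term, gradient and curvature pieces at latent vector u
data_terms <- function(model, params, off, u, want_curv = FALSE) {
  obs <- model$obs
  grad <- numeric(model$n_lat)
  nll <- 0
  Glist <- list(); lam <- numeric(0)
  clamp <- function(x) pmin(pmax(x, -30), 30)
  if (!is.null(model$point)) {
    pt <- model$point
    eta <- off$obs[pt$rows] + u[pt$zi] + u[pt$ci] + u[pt$ni] + u[model$b0i]
    if (model$family == "binomial") {
      C <- obs$successes[pt$rows]; N <- obs$trials[pt$rows]
      eta <- clamp(eta)
      p <- stats::plogis(eta)
      live <- N > 0
      nll <- nll + neg_log_posterior(eta[live], successes = C[live],
                                     trials = N[live])
      d1 <- ifelse(live, N * p - C, 0)
      d2 <- ifelse(live, N * p * (1 - p), 0)
    } else {
      yv <- obs$mean_years[pt$rows]; s <- obs$N[pt$rows]
      nll <- nll + neg_log_posterior(eta, y = yv, s = s, tau = params$tau,
                                     family = "gaussian")
      d1 <- params$tau * s * (eta - yv)
      d2 <- params$tau * s
      d2 <- rep(d2, length.out = length(eta))
    }
    for (idx in list(pt$zi, pt$ci, pt$ni)) {
      sm <- rowsum(d1, idx)
      grad[as.integer(rownames(sm))] <-
        grad[as.integer(rownames(sm))] + sm[, 1]
    }
    grad[model$b0i] <- grad[model$b0i] + sum(d1)
    if (want_curv) {
      A <- matrix(0, length(pt$rows), model$n_lat)
      rows <- seq_along(pt$rows)
      A[cbind(rows, pt$zi)] <- 1
      A[cbind(rows, pt$ci)] <- A[cbind(rows, pt$ci)] + 1
      A[cbind(rows, pt$ni)] <- A[cbind(rows, pt$ni)] + 1
      A[, model$b0i] <- A[, model$b0i] + 1
      Glist[[length(Glist) + 1L]] <- A
      lam <- c(lam, d2)
    }
  }
  for (pg in model$poly) {
    r <- pg$row
    etas <- clamp(off$obs[r] + u[pg$zi] + u[pg$ci] + u[pg$ni] + u[model$b0i])
    if (model$family == "binomial") {
      C <- obs$successes[r]; N <- obs$trials[r]
      ps <- stats::plogis(etas)
      pd <- sum(pg$w * ps)
      pd <- min(max(pd, 1e-12), 1 - 1e-12)
      if (N > 0) {
        nll <- nll - (lgamma(N + 1) - lgamma(C + 1) - lgamma(N - C + 1) +
                        C * log(pd) + (N - C) * log1p(-pd))
        dldp <- -(C / pd - (N - C) / (1 - pd))
        gp <- pg$w * ps * (1 - ps)          # dp/deta_i
        g <- numeric(model$n_lat)
        g[pg$zi] <- gp
        g[pg$ci] <- sum(gp); g[pg$ni] <- sum(gp); g[model$b0i] <- sum(gp)
        grad <- grad + dldp * g
        if (want_curv) {
          Glist[[length(Glist) + 1L]] <- matrix(g, 1)
          lam <- c(lam, N / (pd * (1 - pd)))
        }
      }
    } else {
      yv <- obs$mean_years[r]; s <- obs$N[r]
      mud <- sum(pg$w * etas)
      prec <- params$tau * s
      nll <- nll + 0.5 * prec * (yv - mud)^2 - 0.5 * log(prec) +
        0.5 * log(2 * pi)
      g <- numeric(model$n_lat)
      g[pg$zi] <- pg$w
      g[pg$ci] <- 1; g[pg$ni] <- 1; g[model$b0i] <- 1
      grad <- grad + prec * (mud - yv) * g
      if (want_curv) {
        Glist[[length(Glist) + 1L]] <- matrix(g, 1)
        lam <- c(lam, prec)
      }
    }
  }
  list(nll = nll, grad = grad, Glist = Glist, lam = lam)
}

# inner Newton / Fisher-scoring MAP over latents given hyperparameters
inner_map <- function(model, params, prior, off, u0 = NULL,
                      tol = 1e-5, max_iter = 200) {
  n <- model$n_lat
  u <- if (is.null(u0)) numeric(n) else u0
  fval <- function(u) {
    dt <- data_terms(model, params, off, u)
    list(f = dt$nll + 0.5 * sum(u * (prior$Q %*% u)), dt = dt)
  }
  cur <- fval(u)
  cholH <- NULL
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    grad <- cur$dt$grad + as.vector(prior$Q %*% u)
    if (sqrt(sum(grad^2)) < tol * sqrt(n)) { converged <- TRUE; break }
    dtc <- data_terms(model, params, off, u, want_curv = TRUE)
    H <- prior$Q
    for (j in seq_along(dtc$Glist)) {
      G <- dtc$Glist[[j]]
      l <- dtc$lam[seq_len(nrow(G)) + if (j > 1)
        sum(vapply(dtc$Glist[seq_len(j - 1)], nrow, 0L)) else 0L]
      H <- H + crossprod(G * sqrt(pmax(l, 0)))
    }
    cholH <- tryCatch(chol(H), error = function(e) {
      chol(H + diag(1e-6, n))
    })
    step <- backsolve(cholH, backsolve(cholH, grad, transpose = TRUE))
    t_ls <- 1
    repeat {
      unew <- u - t_ls * step
      new <- tryCatch(fval(unew), error = function(e) list(f = Inf))
      if (is.finite(new$f) && new$f <= cur$f - 1e-4 * t_ls * sum(grad * step))
        break
      t_ls <- t_ls / 2
      if (t_ls < 1e-8) { new <- cur; unew <- u; break }
    }
    if (abs(new$f - cur$f) < 1e-10 * (1 + abs(cur$f)) && it > 1) {
      u <- unew; cur <- new; converged <- TRUE; break
    }
    u <- unew; cur <- new
  }
  # final curvature at the mode
  dtc <- data_terms(model, params, off, u, want_curv = TRUE)
  H <- prior$Q
  off_n <- 0L
  for (j in seq_along(dtc$Glist)) {
    G <- dtc$Glist[[j]]
    l <- dtc$lam[off_n + seq_len(nrow(G))]
    off_n <- off_n + nrow(G)
    H <- H + crossprod(G * sqrt(pmax(l, 0)))
  }
  cholH <- tryCatch(chol(H), error = function(e) chol(H + diag(1e-6, n)))
  list(u = u, f = cur$f, cholH = cholH, converged = converged,
       grad_norm = sqrt(sum((cur$dt$grad + as.vector(prior$Q %*% u))^2)))
}

#' Fit the space-time geostatistical attainment model
#'
#' Fits one indicator (a conditional binomial of the continuation-ratio
#' chain, or mean years) on a pixel grid over time. The linear predictor is
#' \deqn{\eta_{i,t} = \beta_0 + X_{i,t}\beta + Z_{i,t} + \epsilon_{ctr(i)}
#'   + \epsilon_{i,t},}
#' with stacked-ensemble features \code{X} whose weights \eqn{\beta} are a
#' convex combination (softmax-parameterized, summing to 1), a
#' Matern(nu = 2) x AR1 Kronecker Gaussian process \code{Z}, iid country
#' effects, and an iid pixel-time nugget. Estimation is nested: an inner
#' Newton (Fisher-scoring) pass finds the joint mode of all latent effects
#' and the intercept given hyperparameters; an outer Nelder-Mead pass
#' maximizes the Laplace-approximate marginal posterior of the
#' hyperparameters (and stacking weights) on an unconstrained transformed
#' scale, with weakly informative hyperpriors. The returned object carries
#' the mode, the Cholesky factor of the curvature (the Laplace Gaussian),
#' and the hyperparameter estimates; posterior candidate maps are generated
#' by [draw_posterior_fields()].
#'
#' @param obs observation data.frame: columns \code{pixel}, \code{t},
#'   \code{country}, \code{design} plus \code{successes}/\code{trials}
#'   (binomial) or \code{mean_years}/\code{N} (Gaussian); polygon rows need
#'   \code{admin2_id}.
#' @param world an \code{edu_world}.
#' @param features an \code{edu_stack} (or list with \code{oos} and
#'   \code{grid} matrices), or \code{NULL} for an intercept-only mean
#'   function.
#' @param indicator \code{"binomial"} or \code{"mean_years"}.
#' @param params initial hyperparameters, see [default_model_params()].
#' @param fixed named list of hyperparameters to hold fixed (any of
#'   \code{omega2}, \code{delta}, \code{rho}, \code{gamma2}, \code{sigma2},
#'   \code{tau}, or \code{beta} for the full weight vector).
#' @param region optional per-pixel integer labels; spatial covariance is
#'   zeroed across regions, emulating independent regional models fit
#'   jointly.
#' @param beta0_prior_var prior variance of the intercept (default 100).
#' @param control list: \code{inner_tol} (1e-5), \code{inner_max} (200),
#'   \code{outer_max} (60), \code{outer_reltol} (1e-6); \code{se_hyper}
#'   (default TRUE) propagates hyperparameter uncertainty into the
#'   intercept's standard error by mixing over a Gaussian approximation to
#'   the hyperparameter posterior (\code{se_hyper_draws}, default 20,
#'   mixture points), at the cost of extra inner solves.
#' @return object of class \code{"edu_geostat"}.
#' @seealso [draw_posterior_fields()], [predict.edu_geostat()],
#'   [simulate.edu_geostat()]
#' @export
edu_geostat <- function(obs, world, features = NULL,
                        indicator = c("binomial", "mean_years"),
                        params = default_model_params(),
                        fixed = NULL, region = NULL,
                        beta0_prior_var = 100, control = list()) {
  indicator <- match.arg(indicator)
  family <- if (indicator == "binomial") "binomial" else "gaussian"
  ctl <- utils::modifyList(list(inner_tol = 1e-5, inner_max = 200,
                                outer_max = 60, outer_reltol = 1e-6,
                                se_hyper = TRUE, se_hyper_draws = 20,
                                se_seed = 1), control)
  if (is.null(fixed)) fixed <- list()
  n_weights <- if (is.null(features)) 1L else ncol(features$oos)
  if (n_weights == 1L && !is.null(features) && !"beta" %in% names(fixed))
    fixed$beta <- 1
  model <- build_geostat_model(obs, world, features, family, region,
                               beta0_prior_var)
  theta0 <- params_to_theta(params, family, n_weights, fixed)
  env <- new.env()
  env$u <- NULL; env$trace <- numeric(0); env$best <- NULL
  outer_obj <- function(th) {
    names(th) <- names(theta0)
    pr <- tryCatch({
      pars <- theta_to_params(th, family, n_weights, fixed)
      prior <- build_prior(model, pars)
      off <- stack_offset(model, pars)
      fit <- inner_map(model, pars, prior, off, u0 = env$u,
                       tol = ctl$inner_tol, max_iter = ctl$inner_max)
      env$u <- fit$u
      obj <- fit$f - 0.5 * prior$logdetQ +
        sum(log(diag(fit$cholH))) + neg_log_hyperprior(th)
      if (is.null(env$best) || obj < env$best$obj)
        env$best <- list(obj = obj, th = th, pars = pars, fit = fit,
                         prior = prior, off = off)
      obj
    }, error = function(e) Inf)
    env$trace <- c(env$trace, pr)
    pr
  }
  if (length(theta0) > 0) {
    opt <- stats::optim(theta0, outer_obj, method = "Nelder-Mead",
                        control = list(maxit = ctl$outer_max,
                                       reltol = ctl$outer_reltol))
    # Nelder-Mead reports 1 when the iteration cap binds; accept the fit if
    # the objective had flattened by then
    tr <- env$trace[is.finite(env$trace)]
    flat <- length(tr) > 10 &&
      (min(tr[seq_len(length(tr) - 10)]) - min(tr)) <
        2e-3 * (1 + abs(min(tr)))
    outer_converged <- opt$convergence == 0 || flat
  } else {
    outer_obj(theta0)
    outer_converged <- TRUE
  }
  best <- env$best
  if (is.null(best)) stop("model fitting failed: no finite objective")
  # refit the mode at the selected hyperparameters from the stored latents
  fit <- inner_map(model, best$pars, best$prior, best$off, u0 = best$fit$u,
                   tol = ctl$inner_tol, max_iter = ctl$inner_max)
  u <- fit$u
  nz <- model$nz
  se_of <- function(cholH, i) {
    e <- numeric(model$n_lat); e[i] <- 1
    v <- backsolve(cholH, backsolve(cholH, e, transpose = TRUE))
    sqrt(v[i])
  }
  beta0_se_cond <- se_of(fit$cholH, model$b0i)
  beta0_se <- beta0_se_cond
  # mix the intercept over the hyperparameter posterior (Gaussian
  # approximation at the mode): total variance = E[Var(b0|theta)] +
  # Var(E[b0|theta]) over mixture points theta_k
  if (ctl$se_hyper && length(theta0) > 0) {
    th_hat <- best$th
    p <- length(th_hat)
    eval_at <- function(th) {
      pars <- theta_to_params(stats::setNames(th, names(th_hat)), family,
                              n_weights, fixed)
      prior <- build_prior(model, pars)
      off <- stack_offset(model, pars)
      im <- inner_map(model, pars, prior, off, u0 = fit$u,
                      tol = ctl$inner_tol, max_iter = ctl$inner_max)
      obj <- im$f - 0.5 * prior$logdetQ + sum(log(diag(im$cholH))) +
        neg_log_hyperprior(stats::setNames(th, names(th_hat)))
      list(obj = obj, b0 = im$u[model$b0i],
           se = se_of(im$cholH, model$b0i))
    }
    h <- 0.2
    Hth <- matrix(0, p, p)
    f0 <- best$obj
    fp <- fm <- numeric(p)
    ok <- TRUE
    cache <- tryCatch({
      for (i in seq_len(p)) {
        ei <- numeric(p); ei[i] <- h
        fp[i] <- eval_at(th_hat + ei)$obj
        fm[i] <- eval_at(th_hat - ei)$obj
        Hth[i, i] <- (fp[i] - 2 * f0 + fm[i]) / h^2
      }
      if (p > 1) for (i in 1:(p - 1)) for (j in (i + 1):p) {
        ei <- numeric(p); ei[i] <- h
        ej <- numeric(p); ej[j] <- h
        fpp <- eval_at(th_hat + ei + ej)$obj
        fmm <- eval_at(th_hat - ei - ej)$obj
        Hth[i, j] <- Hth[j, i] <-
          (fpp - fp[i] - fp[j] + 2 * f0 - fm[i] - fm[j] + fmm) / (2 * h^2)
      }
      TRUE
    }, error = function(e) FALSE)
    if (isTRUE(cache)) {
      eg <- eigen(Hth, symmetric = TRUE)
      ev <- pmax(eg$values, 1e-2)
      cov_th <- eg$vectors %*% diag(1 / ev, p) %*% t(eg$vectors)
      Lth <- t(chol((cov_th + t(cov_th)) / 2))
      set.seed(ctl$se_seed %% .Machine$integer.max)
      K <- ctl$se_hyper_draws
      b0s <- ses <- numeric(0)
      for (k in seq_len(K)) {
        thk <- th_hat + as.vector(Lth %*% stats::rnorm(p))
        ek <- tryCatch(eval_at(thk), error = function(e) NULL)
        if (!is.null(ek)) { b0s <- c(b0s, ek$b0); ses <- c(ses, ek$se) }
      }
      b0s <- c(b0s, u[model$b0i]); ses <- c(ses, beta0_se_cond)
      beta0_se <- sqrt(mean(ses^2) + stats::var(b0s))
    }
  }
  structure(list(
    call = match.call(), indicator = indicator, family = family,
    model = model, params = best$pars, theta = best$th,
    beta0 = u[model$b0i], beta0_se = beta0_se,
    beta0_se_cond = beta0_se_cond,
    weights = best$pars$beta,
    Z = matrix(u[seq_len(nz)], model$np, model$nt),
    ctr = stats::setNames(u[nz + seq_len(model$n_ctr)],
                          model$ctr_levels),
    u = u, cholH = fit$cholH, offset = best$off,
    objective = best$obj, trace = env$trace,
    converged = fit$converged && outer_converged,
    inner_grad_norm = fit$grad_norm, control = ctl),
    class = "edu_geostat")
}

#' Posterior candidate maps from a fitted model
#'
#' Draws joint Gaussian samples of all latent effects and the intercept from
#' the Laplace approximation at the mode, assembles the linear predictor
#' over every pixel-time using the in-sample stacked-feature grids, adds
#' fresh nugget noise for unobserved micro-scale variation, and pushes the
#' result through the link: each draw is one statistically plausible
#' candidate map.
#'
#' @param fit an \code{edu_geostat}.
#' @param n_draws number of candidate maps (default 1000).
#' @param seed integer seed.
#' @return object of class \code{"edu_draws"}: list with \code{values}
#'   (array n_pix x n_time x n_draws of probabilities or mean years),
#'   \code{beta0}, \code{ctr} (draw matrices), \code{indicator},
#'   \code{years}.
#' @export
draw_posterior_fields <- function(fit, n_draws = 1000, seed = 1) {
  stopifnot(inherits(fit, "edu_geostat"))
  if (!fit$converged)
    warning("drawing from a fit that did not fully converge")
  set.seed(seed %% .Machine$integer.max)
  m <- fit$model
  U <- fit$cholH
  n <- m$n_lat
  vals <- array(0, c(m$np, m$nt, n_draws))
  b0d <- numeric(n_draws)
  ctrd <- matrix(0, n_draws, m$n_ctr)
  off_grid <- fit$offset$grid
  ctr_of_pix <- match(fit$model$world$country, m$ctr_levels)
  for (r in seq_len(n_draws)) {
    z <- stats::rnorm(n)
    u <- fit$u + backsolve(U, z)
    Z <- matrix(u[seq_len(m$nz)], m$np, m$nt)
    ctr <- u[m$nz + seq_len(m$n_ctr)]
    b0 <- u[m$b0i]
    nug <- matrix(stats::rnorm(m$np * m$nt, 0, sqrt(fit$params$sigma2)),
                  m$np, m$nt)
    eta <- matrix(off_grid, m$np, m$nt) + Z + ctr[ctr_of_pix] + b0 + nug
    if (fit$family == "binomial") {
      vals[, , r] <- stats::plogis(pmin(pmax(eta, -30), 30))
    } else {
      vals[, , r] <- pmin(pmax(eta, 0), 18)
    }
    b0d[r] <- b0; ctrd[r, ] <- ctr
  }
  structure(list(values = vals, beta0 = b0d, ctr = ctrd,
                 indicator = fit$indicator,
                 years = fit$model$world$years),
            class = "edu_draws")
}
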