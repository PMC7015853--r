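#' Random cross-validation folds at the cluster level
#'
#' Seeded random partition of observations into \code{k} folds whose sizes
#' differ by at most one. The fold unit here is the observation (cluster);
#' source-stratified folds for validation holdouts are built separately by
#' [source_stratified_folds()].
#'
#' @param n number of observations (or a data.frame, whose rows are
#'   counted).
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return integer vector of fold ids in \code{1..k}.
#' @export
make_cv_folds <- function(n, k = 5, seed = 1) {
  if (is.data.frame(n)) n <- nrow(n)
  if (k < 2) stop("k must be >= 2")
  if (n < k) stop("need at least k observations")
  set.seed(seed %% .Machine$integer.max)
  sample(rep(seq_len(k), length.out = n))
}

# clamp empirical proportions away from 0/1 before the logit
adjust_proportion <- function(p, n) {
  eps <- 0.5 / (n + 1)
  pmin(pmax(p, eps), 1 - eps)
}

#' Fit one covariate submodel
#'
#' The three submodel families feeding the stacked ensemble:
#' \code{"additive_splines"} (penalized thin-plate additive model via
#' \pkg{mgcv}), \code{"boosted_trees"} (depth-limited gradient boosting via
#' \pkg{xgboost} with early stopping on an internal validation split), and
#' \code{"l1_linear"} (lasso via \pkg{glmnet} with its own internal
#' cross-validation for the penalty). All are fit to a continuous link-scale
#' outcome (logit-transformed empirical proportions with a continuity
#' correction, or mean years on the identity scale) with observation
#' weights, and return a predictor on that link scale.
#'
#' @param kind one of \code{"additive_splines"}, \code{"boosted_trees"},
#'   \code{"l1_linear"}.
#' @param features numeric matrix (observations x covariates).
#' @param outcome link-scale outcome vector.
#' @param weights nonnegative observation weights (e.g. trials).
#' @param seed integer seed (used by the tree booster's validation split).
#' @param control optional tuning overrides: \code{lambda} (fixed lasso
#'   penalty, bypassing the internal CV), \code{max_depth}, \code{eta},
#'   \code{nrounds} (booster), \code{k} (spline basis size cap).
#' @return object of class \code{"edu_submodel"} with a \code{predict}
#'   method taking a new feature matrix.
#' @export
fit_submodel <- function(kind = c("additive_splines", "boosted_trees",
                                  "l1_linear"),
                         features, outcome, weights = NULL, seed = 1,
                         control = list()) {
  kind <- match.arg(kind)
  features <- as.matrix(features)
  if (any(!is.finite(features)) || any(!is.finite(outcome)))
    stop("features and outcome must be finite")
  if (is.null(weights)) weights <- rep(1, length(outcome))
  n <- length(outcome)
  const <- stats::var(outcome) < 1e-12 || nrow(unique(features)) < 3
  fitted_obj <- NULL
  if (const) {
    fitted_obj <- list(type = "constant",
                       value = sum(weights * outcome) / sum(weights))
  } else if (kind == "additive_splines") {
    df <- data.frame(.y = outcome, features)
    vn <- colnames(df)[-1]
    keep <- vn[apply(features, 2, function(x) length(unique(x)) > 3)]
    kmax <- if (is.null(control$k)) 8 else control$k
    rhs <- if (length(keep))
      paste(sprintf("s(%s, k = %d)", keep,
                    pmin(kmax, vapply(keep, function(v)
                      length(unique(df[[v]])) - 1, 0))), collapse = " + ")
    else "1"
    lin <- setdiff(vn, keep)
    if (length(lin)) rhs <- paste(c(rhs, lin), collapse = " + ")
    fit <- mgcv::gam(stats::as.formula(paste(".y ~", rhs)), data = df,
                     weights = weights, method = "REML")
    fitted_obj <- list(type = "gam", fit = fit, vars = vn)
  } else if (kind == "l1_linear") {
    set.seed(seed %% .Machine$integer.max)
    if (!is.null(control$lambda)) {
      fit <- glmnet::glmnet(features, outcome, weights = weights,
                            alpha = 1, lambda = control$lambda)
      fitted_obj <- list(type = "glmnet_fixed", fit = fit)
    } else {
      fit <- glmnet::cv.glmnet(features, outcome, weights = weights,
                               nfolds = min(5, n), alpha = 1)
      fitted_obj <- list(type = "glmnet", fit = fit)
    }
  } else {
    set.seed(seed %% .Machine$integer.max)
    val <- sample.int(n, max(2, round(0.2 * n)))
    dtrain <- xgboost::xgb.DMatrix(features[-val, , drop = FALSE],
                                   label = outcome[-val],
                                   weight = weights[-val])
    dval <- xgboost::xgb.DMatrix(features[val, , drop = FALSE],
                                 label = outcome[val],
                                 weight = weights[val])
    fit <- xgboost::xgb.train(
      params = list(max_depth = if (is.null(control$max_depth)) 3
                    else control$max_depth,
                    eta = if (is.null(control$eta)) 0.1 else control$eta,
                    subsample = 0.8, nthread = 1,
                    objective = "reg:squarederror"),
      data = dtrain,
      nrounds = if (is.null(control$nrounds)) 300 else control$nrounds,
      evals = list(val = dval), early_stopping_rounds = 20,
      verbose = 0)
    fitted_obj <- list(type = "xgb", fit = fit)
  }
  structure(c(fitted_obj, list(kind = kind)), class = "edu_submodel")
}

#' @export
predict.edu_submodel <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  switch(object$type,
    constant = rep(object$value, nrow(newdata)),
    gam = as.numeric(mgcv::predict.gam(object$fit,
                                       newdata = as.data.frame(newdata))),
    glmnet = as.numeric(predict(object$fit, newx = newdata,
                                s = "lambda.min")),
    glmnet_fixed = as.numeric(predict(object$fit, newx = newdata)),
    xgb = as.numeric(predict(object$fit, xgboost::xgb.DMatrix(newdata))))
}

# covariate matrix at each observation's pixel-time
obs_features <- function(world, obs) {
  nms <- dimnames(world$covariates)[[3]]
  out <- vapply(nms, function(nm)
    world$covariates[, , nm][cbind(obs$pixel, obs$t)], numeric(nrow(obs)))
  colnames(out) <- nms
  as.matrix(out)
}

# covariate matrix over the whole pixel-time grid (pixels fastest)
grid_features <- function(world) {
  nms <- dimnames(world$covariates)[[3]]
  out <- vapply(nms, function(nm) as.vector(world$covariates[, , nm]),
                numeric(world$n_pix * world$n_time))
  colnames(out) <- nms
  as.matrix(out)
}

#' Out-of-sample and in-sample stacked-ensemble features
#'
#' Fits the three submodels with fivefold cross-validation: each
#' observation's out-of-sample (OOS) feature comes from the fit that
#' excluded its fold, and the five folds' predictions are compiled into one
#' complete OOS column per submodel (these enter the geostatistical linear
#' predictor at fit time). The same submodels are also refit on all
#' observations and evaluated over every pixel-time to give the in-sample
#' prediction grids used at prediction time. Everything is on the link
#' scale: logit of continuity-corrected empirical proportions (binomial
#' indicators, weighted by trials) or identity (mean years, weighted by N).
#'
#' @param obs observation rows with \code{pixel}, \code{t}, and either
#'   \code{successes}/\code{trials} (binomial) or \code{mean_years}/\code{N}
#'   (Gaussian).
#' @param world an \code{edu_world}.
#' @param indicator \code{"binomial"} or \code{"mean_years"}.
#' @param folds fold ids from [make_cv_folds()] (built internally when
#'   \code{NULL}).
#' @param kinds submodel kinds to include.
#' @param seed integer seed.
#' @return list of class \code{"edu_stack"}: \code{oos} (n_obs x H matrix of
#'   OOS link-scale features), \code{grid} (n_pix*n_time x H in-sample
#'   grids, pixels fastest), \code{folds}, \code{kinds}.
#' @export
generate_stack_features <- function(obs, world,
                                    indicator = c("binomial", "mean_years"),
                                    folds = NULL,
                                    kinds = c("additive_splines",
                                              "boosted_trees", "l1_linear"),
                                    seed = 1) {
  indicator <- match.arg(indicator)
  if (is.null(folds)) folds <- make_cv_folds(nrow(obs), 5, seed)
  if (any(table(factor(folds, levels = unique(folds))) == 0) ||
      length(folds) != nrow(obs))
    stop("invalid folds")
  X <- obs_features(world, obs)
  Xg <- grid_features(world)
  if (indicator == "binomial") {
    w <- obs$trials
    keep <- w > 0
    y <- rep(0, nrow(obs))
    y[keep] <- stats::qlogis(adjust_proportion(
      obs$successes[keep] / obs$trials[keep], obs$trials[keep]))
  } else {
    w <- obs$N
    keep <- rep(TRUE, nrow(obs))
    y <- obs$mean_years
  }
  H <- length(kinds)
  oos <- matrix(NA_real_, nrow(obs), H, dimnames = list(NULL, kinds))
  grid <- matrix(NA_real_, nrow(Xg), H, dimnames = list(NULL, kinds))
  for (h in seq_len(H)) {
    for (f in sort(unique(folds))) {
      tr <- keep & folds != f
      if (!any(tr)) stop("fold ", f, " has no training data")
      fit <- fit_submodel(kinds[h], X[tr, , drop = FALSE], y[tr], w[tr],
                          seed = seed + h)
      oos[folds == f, h] <- predict(fit, X[folds == f, , drop = FALSE])
    }
    full <- fit_submodel(kinds[h], X[keep, , drop = FALSE], y[keep], w[keep],
                         seed = seed + 100 + h)
    grid[, h] <- predict(full, Xg)
  }
  if (any(!is.finite(oos)) || any(!is.finite(grid)))
    stop("non-finite submodel predictions")
  structure(list(oos = oos, grid = grid, folds = folds, kinds = kinds,
                 indicator = indicator),
            class = "edu_stack")
}
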