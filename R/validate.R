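#' Source-stratified cross-validation folds
#'
#' Holdout folds built from whole data sources (survey-years), respecting
#' within-source correlation: every observation of a source lands in the
#' same fold, and fold source-counts differ by at most one.
#'
#' @param sources character vector of source ids, one per observation (or a
#'   data.frame with a \code{source_id} column).
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer fold id per observation.
#' @export
source_stratified_folds <- function(sources, k = 5, seed = 1) {
  if (is.data.frame(sources)) sources <- sources$source_id
  usrc <- unique(sources)
  if (k > length(usrc)) stop("k exceeds the number of sources")
  set.seed(seed %% .Machine$integer.max)
  fold_of_src <- stats::setNames(sample(rep(seq_len(k),
                                            length.out = length(usrc))),
                                 usrc)
  unname(fold_of_src[sources])
}

#' Out-of-sample validation metrics
#'
#' The four holdout summaries: mean error (bias), root-mean-square error,
#' empirical coverage of nominal 95% posterior-predictive intervals, and
#' Pearson correlation between observed values and posterior-mean
#' predictions. Coverage uses the full predictive distribution of the
#' observation (latent draws pushed through binomial sampling at the
#' cluster's N, or Gaussian noise), not just the latent interval.
#'
#' @param observed observed values per held-out cluster (proportions or
#'   means).
#' @param pred_mean posterior-mean prediction per cluster, same scale.
#' @param pred_samples matrix n_obs x n_draws of posterior-predictive
#'   replicates of the observed value (e.g. simulated counts / N).
#' @param level interval level (default 0.95).
#' @return list with \code{me}, \code{rmse}, \code{coverage}, \code{cor},
#'   \code{n}.
#' @export
oos_metrics <- function(observed, pred_mean, pred_samples, level = 0.95) {
  n <- length(observed)
  stopifnot(length(pred_mean) == n, nrow(pred_samples) == n)
  err <- pred_mean - observed
  a <- (1 - level) / 2
  lo <- apply(pred_samples, 1, stats::quantile, probs = a, type = 7)
  hi <- apply(pred_samples, 1, stats::quantile, probs = 1 - a, type = 7)
  list(me = mean(err), rmse = sqrt(mean(err^2)),
       coverage = mean(observed >= lo & observed <= hi),
       cor = if (stats::sd(observed) > 0 && stats::sd(pred_mean) > 0)
         stats::cor(observed, pred_mean) else NA_real_,
       n = n)
}

#' Empirical semivariogram of residuals
#'
#' Method-of-moments semivariance by spatial distance bin,
#' \eqn{\gamma(h) = \frac{1}{2}\,\mathrm{mean}[(r_a - r_b)^2]} over pixel
#' pairs whose distance falls in bin \eqn{h}; optionally the temporal
#' analogue by integer lag. Used to compare residual autocorrelation before
#' (stacked features only) and after (full geostatistical) modelling.
#'
#' @param residuals vector of residuals, one per location (or a matrix
#'   locations x times for the temporal analogue).
#' @param coords matrix of coordinates for the locations.
#' @param n_bins number of equal-width distance bins up to half the maximum
#'   pairwise distance (default 10).
#' @param temporal if \code{TRUE} and \code{residuals} is a matrix, also
#'   return semivariance by time lag.
#' @return data.frame with \code{dist} (bin midpoint), \code{gamma},
#'   \code{n_pairs} (empty bins dropped with a warning); when
#'   \code{temporal}, a list with \code{spatial} and \code{temporal}.
#' @export
empirical_semivariogram <- function(residuals, coords, n_bins = 10,
                                    temporal = FALSE) {
  rmat <- if (is.matrix(residuals)) residuals else cbind(residuals)
  D <- as.matrix(stats::dist(coords))
  maxd <- max(D) / 2
  edges <- seq(0, maxd, length.out = n_bins + 1)
  pair <- which(upper.tri(D), arr.ind = TRUE)
  d <- D[pair]
  # average squared half-differences over all time columns
  sq <- rowMeans((rmat[pair[, 1], , drop = FALSE] -
                    rmat[pair[, 2], , drop = FALSE])^2) / 2
  bin <- cut(d, edges, labels = FALSE, include.lowest = TRUE)
  keep <- !is.na(bin)
  gamma <- tapply(sq[keep], bin[keep], mean)
  npair <- tapply(sq[keep], bin[keep], length)
  got <- as.integer(names(gamma))
  if (length(got) < n_bins)
    warning("empty distance bins dropped")
  spatial <- data.frame(dist = (edges[got] + edges[got + 1]) / 2,
                        gamma = as.numeric(gamma),
                        n_pairs = as.integer(npair))
  if (!temporal || ncol(rmat) < 2) return(spatial)
  lags <- 0:(ncol(rmat) - 1)
  tg <- vapply(lags, function(l) {
    if (l == 0) return(0)
    mean((rmat[, seq_len(ncol(rmat) - l)] -
            rmat[, seq_len(ncol(rmat) - l) + l])^2) / 2
  }, 0)
  list(spatial = spatial,
       temporal = data.frame(lag = lags, gamma = tg))
}

#' Source-stratified cross-validation of the geostatistical model
#'
#' The full validation loop for one conditional indicator: splits sources
#' into folds, and for each fold regenerates stacked-ensemble features from
#' the training clusters only, fits the space-time model, and simulates the
#' posterior-predictive distribution of every held-out cluster (latent
#' draws pushed through binomial sampling at the cluster's N). Pooled and
#' per-fold metrics follow [oos_metrics()].
#'
#' @param obs conditional-binomial observation rows (one level), with
#'   \code{source_id}, \code{pixel}, \code{t}, \code{country},
#'   \code{design}, \code{successes}, \code{trials}.
#' @param world an \code{edu_world}.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @param n_draws posterior-predictive replicates per held-out cluster.
#' @param params,fixed,control passed to [edu_geostat()].
#' @param stack_kinds submodel kinds for the per-fold stacking.
#' @return list with \code{pooled} (metrics over all held-out clusters),
#'   \code{by_fold}, \code{folds}.
#' @export
cv_edu_geostat <- function(obs, world, k = 5, seed = 1, n_draws = 250,
                           params = default_model_params(), fixed = NULL,
                           control = list(),
                           stack_kinds = c("additive_splines",
                                           "boosted_trees", "l1_linear")) {
  folds <- source_stratified_folds(obs$source_id, k, seed)
  observed <- numeric(0); pm <- numeric(0)
  sim_all <- NULL
  by_fold <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- obs[folds != f, , drop = FALSE]
    te <- obs[folds == f & obs$design != "polygon", , drop = FALSE]
    if (nrow(te) == 0) next
    st <- generate_stack_features(tr, world, "binomial",
                                  kinds = stack_kinds, seed = seed + f)
    ctl <- utils::modifyList(list(se_hyper = FALSE), control)
    fit <- edu_geostat(tr, world, features = st, indicator = "binomial",
                       params = params, fixed = fixed, control = ctl)
    sims <- simulate(fit, nsim = n_draws, seed = seed + 1000 + f,
                     newdata = te)
    prop <- sweep(sims, 1, pmax(te$trials, 1), "/")
    obs_prop <- te$successes / pmax(te$trials, 1)
    mu <- rowMeans(prop)
    by_fold[[f]] <- oos_metrics(obs_prop, mu, prop)
    observed <- c(observed, obs_prop); pm <- c(pm, mu)
    sim_all <- rbind(sim_all, prop)
  }
  pooled <- oos_metrics(observed, pm, sim_all)
  list(pooled = pooled, by_fold = by_fold, folds = folds)
}
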