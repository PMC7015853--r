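#' Compose continuation-ratio conditional probabilities into bin probabilities
#'
#' The four ordinal attainment bins (zero years; 1-5; 6-11; 12+) are modelled
#' as a chain of conditional binomials: \code{p0} is the probability of zero
#' years, \code{q1} the probability of 1-5 years given more than zero, and
#' \code{q2} the probability of 6-11 years given more than five. The bin
#' probabilities are the telescoping products
#' \deqn{(p_0,\; (1-p_0)q_1,\; (1-p_0)(1-q_1)q_2,\; (1-p_0)(1-q_1)(1-q_2)),}
#' so the top bin is the complement of the three modelled levels and the
#' vector always sums to 1. Inputs may be vectors/arrays of equal shape;
#' applied draw-wise this aligns the three indicators' posterior draws by
#' draw index.
#'
#' @param p_zero probability of zero years.
#' @param q_lessprimary conditional probability of 1-5 years given > 0.
#' @param q_primary conditional probability of 6-11 years given > 5.
#' @return matrix with 4 columns (\code{zero}, \code{1-5}, \code{6-11},
#'   \code{12+}); a plain named vector for scalar input.
#' @examples
#' compose_cr_probabilities(0.2, 0.5, 0.5)  # c(0.2, 0.4, 0.2, 0.2)
#' @export
compose_cr_probabilities <- function(p_zero, q_lessprimary, q_primary) {
  if (any(c(p_zero, q_lessprimary, q_primary) < 0) ||
      any(c(p_zero, q_lessprimary, q_primary) > 1))
    stop("conditional probabilities must lie in [0, 1]")
  b1 <- p_zero
  b2 <- (1 - p_zero) * q_lessprimary
  b3 <- (1 - p_zero) * (1 - q_lessprimary) * q_primary
  b4 <- (1 - p_zero) * (1 - q_lessprimary) * (1 - q_primary)
  out <- cbind(zero = b1, `1-5` = b2, `6-11` = b3, `12+` = b4)
  if (length(p_zero) == 1) out[1, ] else out
}

#' Default generative coefficients for the synthetic truth
#'
#' Fixed-effect coefficients of the three conditional logit surfaces and the
#' mean-years surface used when simulating ground truth. Chosen once to give
#' attainment that improves over time, favours urban/accessible pixels, and
#' spans realistic ranges (zero-years proportions mostly 0.1-0.6, mean years
#' mostly 2-12).
#'
#' @return nested list of intercepts and named covariate coefficients.
#' @export
truth_coefficients <- function() {
  list(
    eta1 = list(b0 = -0.5, beta = c(year = -0.5, access = -0.4, urbanicity = -0.3)),
    eta2 = list(b0 = 0.2,  beta = c(year = -0.3, nightlights = -0.3)),
    eta3 = list(b0 = 0.3,  beta = c(year = -0.2, urbanicity = -0.3)),
    mu   = list(b0 = 6.0,  beta = c(year = 0.8, access = 0.8, urbanicity = 0.6))
  )
}

#' Default model hyperparameters
#'
#' Space-time hyperparameters shared by the generative truth and the
#' fitting defaults: GP marginal variance \code{omega2}, Matern range
#' \code{delta} (pixel units), smoothness \code{nu = 2}, AR1 autocorrelation
#' \code{rho}, country-effect variance \code{gamma2}, nugget variance
#' \code{sigma2}, and the Gaussian observation precision \code{tau}
#' (cluster-mean variance is \code{1 / (tau * N)}; the default corresponds
#' to a person-level standard deviation of about 4.5 years).
#'
#' @param ... overrides by name.
#' @return named list.
#' @export
default_model_params <- function(...) {
  p <- list(omega2 = 0.25, delta = 4, nu = 2, rho = 0.7,
            gamma2 = 0.2, sigma2 = 0.05, tau = 0.05)
  over <- list(...)
  p[names(over)] <- over
  p
}

# geometric-decay profile over the single years inside each bin; most
# attainers of a bin stop in its early years
default_within_bin_profile <- function(decay = 0.65) {
  bins <- list(zero = 0, `1-5` = 1:5, `6-11` = 6:11, `12+` = 12:18)
  lapply(bins, function(yrs) {
    w <- decay^(seq_along(yrs) - 1)
    stats::setNames(w / sum(w), yrs)
  })
}

#' Assemble true attainment surfaces from latent fields
#'
#' Builds the logit-scale linear predictors of the three conditional
#' indicators additively from fixed effects and their (independent) latent
#' fields, composes them into bin probabilities via the continuation-ratio
#' chain, and assembles the true mean-years surface on the identity link,
#' clamped to [0, 18].
#'
#' @param world an \code{edu_world}.
#' @param latents list of four latent structures (from
#'   [sample_latent_field()]) named \code{eta1}, \code{eta2}, \code{eta3},
#'   \code{mu}.
#' @param coefs coefficients as from [truth_coefficients()].
#' @param profile within-bin single-year profiles (default geometric decay).
#' @return object of class \code{"edu_truth"}: list with \code{eta1..eta3}
#'   (n_pix x n_time), \code{mu}, \code{bin_probs}
#'   (n_pix x n_time x 4), \code{within_bin_profile}.
#' @export
compute_true_surfaces <- function(world, latents,
                                  coefs = truth_coefficients(),
                                  profile = default_within_bin_profile()) {
  lin <- function(cf) {
    out <- matrix(cf$b0, world$n_pix, world$n_time)
    for (nm in names(cf$beta)) {
      if (!nm %in% dimnames(world$covariates)[[3]])
        stop("unknown covariate in truth coefficients: ", nm)
      out <- out + cf$beta[[nm]] * world$covariates[, , nm]
    }
    out
  }
  add_lat <- function(eta, lat)
    eta + lat$Z + lat$ctr[world$country] + lat$nugget
  eta1 <- add_lat(lin(coefs$eta1), latents$eta1)
  eta2 <- add_lat(lin(coefs$eta2), latents$eta2)
  eta3 <- add_lat(lin(coefs$eta3), latents$eta3)
  mu <- pmin(pmax(add_lat(lin(coefs$mu), latents$mu), 0), 18)
  p0 <- stats::plogis(eta1); q1 <- stats::plogis(eta2); q2 <- stats::plogis(eta3)
  bp <- array(0, c(world$n_pix, world$n_time, 4),
              dimnames = list(NULL, NULL, c("zero", "1-5", "6-11", "12+")))
  bp[, , 1] <- p0
  bp[, , 2] <- (1 - p0) * q1
  bp[, , 3] <- (1 - p0) * (1 - q1) * q2
  bp[, , 4] <- (1 - p0) * (1 - q1) * (1 - q2)
  structure(list(eta1 = eta1, eta2 = eta2, eta3 = eta3, mu = mu,
                 bin_probs = bp, within_bin_profile = profile),
            class = "edu_truth")
}

#' Convenience: simulate a full synthetic truth
#'
#' Builds the world, samples four independent latent structures (one per
#' conditional indicator and one for mean years), and assembles the true
#' surfaces. Deterministic given \code{seed}.
#'
#' @inheritParams build_world
#' @param params hyperparameters, see [default_model_params()].
#' @param coefs fixed-effect coefficients, see [truth_coefficients()].
#' @return list with \code{world}, \code{latents}, \code{truth}.
#' @export
simulate_truth <- function(config = world_config(), seed = 1,
                           params = default_model_params(),
                           coefs = truth_coefficients()) {
  world <- build_world(config, seed = seed)
  latents <- list(eta1 = sample_latent_field(world, params, seed + 101L),
                  eta2 = sample_latent_field(world, params, seed + 102L),
                  eta3 = sample_latent_field(world, params, seed + 103L),
                  mu = sample_latent_field(world, params, seed + 104L))
  truth <- compute_true_surfaces(world, latents, coefs)
  list(world = world, latents = latents, truth = truth)
}
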