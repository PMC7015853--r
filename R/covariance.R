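#' Matern spatial covariance matrix
#'
#' Isotropic stationary Matern covariance evaluated on a pairwise distance
#' matrix,
#' \deqn{C(d) = \frac{\omega^2}{\Gamma(\nu) 2^{\nu-1}} (\kappa d)^\nu
#'   K_\nu(\kappa d), \qquad \kappa = \sqrt{8\nu}/\delta,}
#' where \eqn{K_\nu} is the modified Bessel function of the second kind.
#' The smoothness \eqn{\nu} is fixed at 2 by default; with
#' \eqn{\kappa = \sqrt{8\nu}/\delta} the correlation at distance
#' \eqn{d = \delta} is approximately 0.1, so \code{delta} is interpretable
#' as the practical range. Distances are in abstract pixel units
#' (1 = one pixel width).
#'
#' @param D symmetric matrix of pairwise Euclidean distances (zero diagonal).
#' @param omega2 marginal variance \eqn{\omega^2 > 0}.
#' @param delta range parameter \eqn{\delta > 0}, the distance at which the
#'   correlation has decayed to roughly 0.1.
#' @param nu smoothness, fixed at 2 unless overridden.
#' @param jitter nonnegative relative diagonal jitter (default 0, so
#'   \code{C(0) = omega2} exactly); factorization-bound callers pass a small
#'   positive value, giving a diagonal of \code{omega2 * (1 + jitter)}.
#' @return symmetric covariance matrix, same dimension as \code{D}.
#' @examples
#' D <- as.matrix(dist(expand.grid(1:3, 1:3)))
#' S <- matern_covariance(D, omega2 = 1, delta = 2)
#' @export
matern_covariance <- function(D, omega2, delta, nu = 2, jitter = 0) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  if (omega2 <= 0 || delta <= 0 || nu <= 0)
    stop("omega2, delta and nu must be positive")
  if (max(abs(D - t(D))) > 1e-10 || any(diag(D) != 0))
    stop("D must be symmetric with zero diagonal")
  kappa <- sqrt(8 * nu) / delta
  x <- kappa * D
  C <- matrix(omega2, nrow(D), ncol(D))
  pos <- x > 0
  # Matern form; the d -> 0 limit is omega^2.
  C[pos] <- omega2 / (gamma(nu) * 2^(nu - 1)) * x[pos]^nu * besselK(x[pos], nu)
  C <- (C + t(C)) / 2
  diag(C) <- omega2 * (1 + jitter)
  C
}

#' AR1 temporal correlation matrix
#'
#' First-order autoregressive correlation over \code{T} annual time points:
#' entry \eqn{(j,k)} is \eqn{\rho^{|k-j|}}, unit diagonal.
#'
#' @param rho autocorrelation, \eqn{|\rho| < 1}.
#' @param T_len number of time points.
#' @return \code{T_len x T_len} correlation matrix.
#' @examples
#' ar1_covariance(0.9, 5)
#' @export
ar1_covariance <- function(rho, T_len) {
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  if (T_len < 1) stop("T_len must be >= 1")
  lag <- abs(outer(seq_len(T_len), seq_len(T_len), "-"))
  rho^lag
}

# Cholesky factors (lower) of the two Kronecker factors, reused by both the
# sampler and the log-density; errors out on indefinite inputs.
kron_chol_factors <- function(Sigma_s, Sigma_t) {
  Ls <- tryCatch(t(chol(Sigma_s)), error = function(e)
    stop("spatial covariance is not positive definite: ", conditionMessage(e)))
  Lt <- tryCatch(t(chol(Sigma_t)), error = function(e)
    stop("temporal covariance is not positive definite: ", conditionMessage(e)))
  list(Ls = Ls, Lt = Lt)
}

#' Sample a matrix-normal field with Kronecker covariance
#'
#' Draws \code{Z} (pixels x times) such that
#' \code{cov(Z[i,t], Z[j,s]) = Sigma_s[i,j] * Sigma_t[t,s]}, i.e. the
#' vectorized field is \eqn{N(0, \Sigma^{space} \otimes \Sigma^{time})},
#' without ever materializing the Kronecker product: if
#' \eqn{\Sigma_s = L_s L_s'} and \eqn{\Sigma_t = L_t L_t'} then
#' \eqn{Z = L_s E L_t'} with iid standard-normal \code{E} has the target law.
#'
#' @param Sigma_s spatial covariance matrix (pixels).
#' @param Sigma_t temporal covariance matrix (times).
#' @param n_draws number of independent fields to draw.
#' @return array \code{c(n_pix, n_time, n_draws)} (dropped to a matrix when
#'   \code{n_draws = 1}).
#' @export
sample_kronecker_field <- function(Sigma_s, Sigma_t, n_draws = 1) {
  f <- kron_chol_factors(Sigma_s, Sigma_t)
  np <- nrow(Sigma_s); nt <- nrow(Sigma_t)
  out <- array(0, c(np, nt, n_draws))
  for (r in seq_len(n_draws)) {
    E <- matrix(stats::rnorm(np * nt), np, nt)
    out[, , r] <- f$Ls %*% E %*% t(f$Lt)
  }
  if (n_draws == 1) out[, , 1] else out
}

#' Log-density of a Kronecker-covariance Gaussian field
#'
#' Evaluates the \eqn{N(0, \Sigma^{space} \otimes \Sigma^{time})} log-density
#' of a pixels-by-times field using only the two factors:
#' the quadratic form is \eqn{\mathrm{tr}(\Sigma_t^{-1} Z' \Sigma_s^{-1} Z)}
#' and \eqn{\log|\Sigma_s \otimes \Sigma_t| =
#' T \log|\Sigma_s| + n \log|\Sigma_t|}.
#'
#' @param Z matrix (pixels x times).
#' @inheritParams sample_kronecker_field
#' @return scalar log-density.
#' @export
dkronecker_field <- function(Z, Sigma_s, Sigma_t) {
  stopifnot(nrow(Z) == nrow(Sigma_s), ncol(Z) == nrow(Sigma_t))
  f <- kron_chol_factors(Sigma_s, Sigma_t)
  np <- nrow(Sigma_s); nt <- nrow(Sigma_t)
  # W = Ls^{-1} Z Lt^{-T}; quadratic form = sum(W^2)
  W <- forwardsolve(f$Ls, Z)
  W <- t(forwardsolve(f$Lt, t(W)))
  logdet <- 2 * nt * sum(log(diag(f$Ls))) + 2 * np * sum(log(diag(f$Lt)))
  -0.5 * (np * nt * log(2 * pi) + logdet + sum(W^2))
}

# Kronecker precision (dense) from the two covariance factors, ordered so the
# latent vector stacks pixels fastest: vec index = (t-1)*np + i.
kron_precision <- function(Sigma_s, Sigma_t) {
  Qs <- chol2inv(chol(Sigma_s))
  Qt <- chol2inv(chol(Sigma_t))
  kronecker(Qt, Qs)
}
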