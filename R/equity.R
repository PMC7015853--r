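#' Index of dissimilarity across admin units
#'
#' Classical two-group index of evenness between attainers and
#' non-attainers: with unit populations \eqn{pop_i} and rates \eqn{r_i},
#' let \eqn{a_i = pop_i r_i} (attainers) and \eqn{b_i = pop_i (1 - r_i)};
#' then \deqn{D = \tfrac12 \sum_i | a_i/A - b_i/B |,} with \eqn{A, B} the
#' group totals. D is the fraction of attainers who would have to move to
#' equalize rates across all units: 0 under equal rates, 1 under complete
#' segregation, invariant to scaling all populations.
#'
#' @param unit_rates attainment rates in [0, 1] per unit (vector), or a
#'   units x draws matrix for draw-wise computation.
#' @param unit_populations positive populations per unit.
#' @return scalar D (or vector over draws for matrix input).
#' @export
dissimilarity_index <- function(unit_rates, unit_populations) {
  if (is.matrix(unit_rates))
    return(apply(unit_rates, 2, dissimilarity_index,
                 unit_populations = unit_populations))
  if (any(unit_rates < 0 | unit_rates > 1)) stop("rates must lie in [0, 1]")
  if (any(unit_populations <= 0)) stop("populations must be positive")
  a <- unit_populations * unit_rates
  b <- unit_populations * (1 - unit_rates)
  A <- sum(a); B <- sum(b)
  if (A == 0 || B == 0)
    stop("dissimilarity index undefined: one group is empty")
  0.5 * sum(abs(a / A - b / B))
}

#' Additive decomposition of national rate change
#'
#' Decomposes the change in a national rate between two years into exact
#' additive contributions of its admin units:
#' \deqn{C = \sum_i (c_{i,t_1} r_{i,t_1} - c_{i,t_0} r_{i,t_0}),}
#' where \eqn{c_i} is the unit's population share and \eqn{r_i} its rate;
#' \code{contribution_i = c_{i,t1} r_{i,t1} - c_{i,t0} r_{i,t0}} and the
#' contributions sum to \code{C} by construction (asserted).
#'
#' @param rates_t0,rates_t1 unit rates in the base and final year.
#' @param popshare_t0,popshare_t1 unit population shares (each summing
#'   to 1 within 1e-9).
#' @return list with \code{C} (national change) and \code{contributions}.
#' @examples
#' decompose_national_change(c(0.1, 0.2), c(0.3, 0.6), c(0.5, 0.5),
#'                           c(0.5, 0.5))  # C = 0.30
#' @export
decompose_national_change <- function(rates_t0, rates_t1,
                                      popshare_t0, popshare_t1) {
  if (abs(sum(popshare_t0) - 1) > 1e-9 || abs(sum(popshare_t1) - 1) > 1e-9)
    stop("population shares must sum to 1")
  contrib <- popshare_t1 * rates_t1 - popshare_t0 * rates_t0
  C <- sum(popshare_t1 * rates_t1) - sum(popshare_t0 * rates_t0)
  stopifnot(abs(sum(contrib) - C) < 1e-12 * max(1, abs(C)))
  list(C = C, contributions = contrib)
}

#' Gender-parity exceedance probabilities
#'
#' Draw-wise male:female rate ratio per unit, the posterior probability that
#' the ratio exceeds 1 (male advantage), and whether the ratio is credibly
#' different from parity at the 95% level (exceedance probability at or
#' beyond 0.975 / 0.025). Draws are aligned by index; draws with a zero
#' female rate are excluded with a warning and counted.
#'
#' @param draws_female,draws_male aligned draw vectors of the two rates.
#' @return list with \code{ratio} (summary of ratio draws: mean and 95%
#'   interval), \code{p_exceed} = P(ratio > 1), \code{credibly_different},
#'   \code{n_dropped}.
#' @export
parity_probability <- function(draws_female, draws_male) {
  if (length(draws_female) != length(draws_male))
    stop("draw vectors must be aligned")
  bad <- draws_female == 0
  n_dropped <- sum(bad)
  if (n_dropped > 0) {
    warning(n_dropped, " draws with zero female rate excluded")
    draws_female <- draws_female[!bad]
    draws_male <- draws_male[!bad]
  }
  if (length(draws_female) == 0) stop("no usable draws")
  ratio <- draws_male / draws_female
  p <- mean(ratio > 1)
  list(ratio = summarize_draws(ratio), p_exceed = p,
       credibly_different = p >= 0.975 || p <= 0.025,
       n_dropped = n_dropped)
}
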