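#' Population-weighted aggregation of candidate maps to admin units
#'
#' For every posterior draw and year, the admin-unit value is the
#' population-weighted mean of its unmasked pixels,
#' \eqn{\sum_i pop_i x_i / \sum_i pop_i}. Draw count is preserved, so
#' re-aggregating second-level estimates with unit populations reproduces
#' first-level and national estimates exactly.
#'
#' @param draws \code{edu_draws} or a plain array n_pix x n_time x n_draws.
#' @param world an \code{edu_world} (provides population and admin labels).
#' @param level \code{"admin2"}, \code{"admin1"} or \code{"national"}.
#' @param mask optional logical per pixel; masked pixels are excluded from
#'   values and weights (see [apply_mask()]).
#' @return object of class \code{"edu_admin"}: list with \code{values}
#'   (array n_units x n_time x n_draws), \code{units}, \code{level},
#'   \code{population} (n_units x n_time of the weights used),
#'   \code{years}.
#' @export
aggregate_to_admin <- function(draws, world,
                               level = c("admin2", "admin1", "national"),
                               mask = NULL) {
  level <- match.arg(level)
  vals <- if (inherits(draws, "edu_draws")) draws$values else draws
  lab <- switch(level, admin2 = world$admin2, admin1 = world$admin1,
                national = world$country)
  keep <- if (is.null(mask)) rep(TRUE, world$n_pix) else !mask
  units <- sort(unique(lab))
  nd <- dim(vals)[3]
  out <- array(0, c(length(units), world$n_time, nd))
  popu <- matrix(0, length(units), world$n_time)
  for (k in seq_along(units)) {
    pix <- which(lab == units[k] & keep)
    if (length(pix) == 0 || all(world$population[pix, ] == 0))
      stop("admin unit ", units[k], " has zero unmasked population")
    for (t in seq_len(world$n_time)) {
      w <- world$population[pix, t]
      popu[k, t] <- sum(w)
      out[k, t, ] <- crossprod(w, matrix(vals[pix, t, ],
                                         length(pix), nd))[1, ] / sum(w)
    }
  }
  structure(list(values = out, units = units, level = level,
                 population = popu, years = world$years),
            class = "edu_admin")
}

#' Rake candidate maps to national reference estimates
#'
#' For each draw and country-year, computes the ratio of the reference
#' national estimate to that draw's population-weighted national aggregate
#' and multiplies every cell of the country-year by the ratio, so each
#' raked draw's national aggregate matches the reference exactly.
#' Proportions are clipped to [0, 1] after scaling (clipping breaks
#' exactness only where it binds). \code{per_draw = FALSE} instead rakes
#' all draws by the single ratio of the posterior-mean national estimate to
#' the reference.
#'
#' @param draws \code{edu_draws} (or plain array n_pix x n_time x n_draws).
#' @param world an \code{edu_world}.
#' @param reference data.frame with columns \code{country}, \code{year},
#'   \code{value}: the national reference series.
#' @param is_proportion clip results to [0, 1] (default TRUE for binomial
#'   indicators when \code{draws} is an \code{edu_draws}).
#' @param per_draw match each draw to the reference (default) or use one
#'   posterior-mean ratio for all draws.
#' @param mask optional logical per pixel, excluded from the national
#'   aggregates and left untouched by raking.
#' @return same shape as \code{draws}, raked.
#' @export
rake_draws <- function(draws, world, reference, is_proportion = NULL,
                       per_draw = TRUE, mask = NULL) {
  is_edu <- inherits(draws, "edu_draws")
  vals <- if (is_edu) draws$values else draws
  if (is.null(is_proportion))
    is_proportion <- is_edu && draws$indicator != "mean_years"
  keep <- if (is.null(mask)) rep(TRUE, world$n_pix) else !mask
  nd <- dim(vals)[3]
  for (ctr in sort(unique(world$country))) {
    pix <- which(world$country == ctr & keep)
    allpix <- which(world$country == ctr)
    for (t in seq_len(world$n_time)) {
      ref <- reference$value[reference$country == ctr &
                               reference$year == world$years[t]]
      if (length(ref) != 1) next
      w <- world$population[pix, t]
      nat <- crossprod(w, matrix(vals[pix, t, ], length(pix), nd))[1, ] /
        sum(w)
      if (per_draw) {
        if (any(nat == 0) && ref != 0)
          stop("draw national aggregate of 0 with nonzero reference")
        fac <- ref / nat
      } else {
        if (mean(nat) == 0 && ref != 0)
          stop("national aggregate of 0 with nonzero reference")
        fac <- rep(ref / mean(nat), nd)
      }
      vals[allpix, t, ] <- sweep(vals[allpix, t, , drop = FALSE], 3, fac,
                                 "*")
    }
  }
  if (is_proportion) vals <- pmin(pmax(vals, 0), 1)
  if (is_edu) { draws$values <- vals; draws } else vals
}

#' Mask barren and near-empty pixels
#'
#' Pixels whose land-cover class is "barren or sparsely vegetated", or whose
#' population density falls strictly below the threshold in the reference
#' year, are flagged for exclusion from outputs and aggregation weights
#' (density exactly at the threshold is retained).
#'
#' @param world an \code{edu_world}.
#' @param min_density density threshold (persons per pixel; default 10).
#' @param ref_year calendar year whose population defines density (default
#'   last year).
#' @return logical vector per pixel; \code{TRUE} = masked.
#' @export
apply_mask <- function(world, min_density = 10, ref_year = NULL) {
  if (is.null(ref_year)) ref_year <- world$years[world$n_time]
  t_idx <- match(ref_year, world$years)
  if (is.na(t_idx)) stop("ref_year outside the world")
  world$landcover == "barren or sparsely vegetated" |
    world$population[, t_idx] < min_density
}

#' Summarize posterior draws
#'
#' Posterior mean and central 95% uncertainty interval (2.5th and 97.5th
#' percentiles, linear interpolation between order statistics).
#'
#' @param x numeric vector of draws (or matrix: rows summarized
#'   independently).
#' @return for a vector, named vector \code{mean}, \code{lower},
#'   \code{upper}; for a matrix, a data.frame with those columns.
#' @export
summarize_draws <- function(x) {
  if (is.matrix(x)) {
    out <- t(apply(x, 1, summarize_draws))
    return(as.data.frame(out))
  }
  if (length(x) < 2) stop("need at least 2 draws")
  q <- stats::quantile(x, c(0.025, 0.975), names = FALSE, type = 7)
  c(mean = mean(x), lower = q[1], upper = q[2])
}

#' Admin-level summary table
#'
#' Convenience wrapper: aggregates candidate maps to an admin level and
#' returns one row per unit-year with the posterior mean and 95%
#' uncertainty interval.
#'
#' @inheritParams aggregate_to_admin
#' @return data.frame with columns \code{unit}, \code{year}, \code{mean},
#'   \code{lower}, \code{upper}.
#' @export
admin_summary <- function(draws, world, level = "admin2", mask = NULL) {
  agg <- aggregate_to_admin(draws, world, level, mask)
  rows <- list()
  for (k in seq_along(agg$units)) for (t in seq_len(length(agg$years))) {
    s <- summarize_draws(agg$values[k, t, ])
    rows[[length(rows) + 1L]] <- data.frame(
      unit = agg$units[k], year = agg$years[t],
      mean = s["mean"], lower = s["lower"], upper = s["upper"],
      row.names = NULL)
  }
  do.call(rbind, rows)
}
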