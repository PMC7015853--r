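#' Top-code years of attainment at 18
#'
#' @param years nonnegative numeric vector of single years of attainment.
#' @param cap top-coding threshold (default 18).
#' @return \code{pmin(years, cap)}.
#' @export
top_code_years <- function(years, cap = 18) {
  if (any(years < 0)) stop("years of attainment cannot be negative")
  pmin(years, cap)
}

#' Assign attainment bins
#'
#' Bins on top-coded years: zero years; 1-5 (less than primary); 6-11 (at
#' least primary); 12-18 (secondary or higher). Closed integer intervals.
#'
#' @param years top-coded years.
#' @return factor with levels \code{zero}, \code{1-5}, \code{6-11},
#'   \code{12+}.
#' @export
assign_bin <- function(years) {
  years <- top_code_years(years)
  cut(years, breaks = c(-0.5, 0.5, 5.5, 11.5, 18.5),
      labels = c("zero", "1-5", "6-11", "12+"))
}

#' Summarize person years into model indicators
#'
#' @param person_years vector of single years of attainment (top-coded
#'   internally).
#' @return list with \code{mean} (arithmetic mean of top-coded years) and
#'   \code{counts} (named 4-vector of bin counts).
#' @export
compute_indicators <- function(person_years) {
  if (length(person_years) == 0) stop("empty person list")
  y <- top_code_years(person_years)
  list(mean = mean(y), counts = table(assign_bin(y)))
}

#' Aggregate weighted person records into a polygon observation
#'
#' Computes design-weighted bin proportions and mean years, the Kish design
#' effect \eqn{DEFF = n \sum w^2 / (\sum w)^2}, and the effective sample
#' size \eqn{n_{eff} = n / DEFF}.
#'
#' @param person_years single years of attainment per person.
#' @param weights positive sampling weights per person.
#' @return list with \code{proportions} (4-vector summing to 1),
#'   \code{mean_years}, \code{n}, \code{deff}, \code{n_eff}.
#' @export
aggregate_polygon_obs <- function(person_years, weights) {
  n <- length(person_years)
  if (n == 0) stop("empty person list")
  if (length(weights) != n || any(weights < 0) || sum(weights) == 0)
    stop("weights must be positive with the same length as person_years")
  y <- top_code_years(person_years)
  b <- assign_bin(y)
  w <- weights / sum(weights)
  prop <- vapply(levels(b), function(l) sum(w[b == l]), 0)
  deff <- n * sum(weights^2) / sum(weights)^2
  list(proportions = prop, mean_years = sum(w * y), n = n,
       deff = deff, n_eff = n / deff)
}

#' Continuation-ratio transform of bin counts
#'
#' Turns a 4-vector of ordinal bin counts into the three conditional
#' binomial records the model consumes: level 1 is zero-years successes out
#' of all \code{N}; level 2 is 1-5-years successes out of those with more
#' than zero years; level 3 is 6-11-years successes out of those with more
#' than five years. The level-3 complement implies the 12+ count, so person
#' totals are conserved. Degenerate levels with zero trials are retained
#' (they contribute zero likelihood).
#'
#' @param bin_counts numeric 4-vector (zero, 1-5, 6-11, 12+), or a matrix
#'   with 4 columns for row-wise transformation; fractional counts
#'   (effective sample sizes) are allowed.
#' @param N total count(s); defaults to the (row) sums of
#'   \code{bin_counts}.
#' @return for a vector, a data.frame with columns \code{level},
#'   \code{successes}, \code{trials}; for a matrix, a list with
#'   \code{successes} and \code{trials} matrices (3 columns, one per
#'   level).
#' @examples
#' cr_transform_counts(c(2, 3, 4, 1))  # (2,10), (3,8), (4,5)
#' @export
cr_transform_counts <- function(bin_counts, N = NULL) {
  if (is.matrix(bin_counts)) {
    if (ncol(bin_counts) != 4 || any(bin_counts < 0))
      stop("bin_counts must have 4 nonnegative columns")
    if (is.null(N)) N <- rowSums(bin_counts)
    if (any(abs(rowSums(bin_counts) - N) > 1e-8))
      stop("bin counts must sum to N")
    tr <- cbind(N, N - bin_counts[, 1], N - bin_counts[, 1] - bin_counts[, 2])
    return(list(successes = unname(bin_counts[, 1:3, drop = FALSE]),
                trials = unname(tr)))
  }
  if (length(bin_counts) != 4 || any(bin_counts < 0))
    stop("bin_counts must be a nonnegative 4-vector")
  if (is.null(N)) N <- sum(bin_counts)
  if (abs(sum(bin_counts) - N) > 1e-8)
    stop("bin counts must sum to N")
  tr <- c(N, N - bin_counts[1], N - bin_counts[1] - bin_counts[2])
  data.frame(level = 1:3, successes = unname(bin_counts[1:3]),
             trials = unname(tr))
}

# inverse of compose_cr_probabilities on a valid 4-vector of proportions
cr_conditional_from_bins <- function(bins) {
  p0 <- bins[1]
  q1 <- if (1 - p0 > 0) bins[2] / (1 - p0) else 0
  rest <- 1 - p0 - bins[2]
  q2 <- if (rest > 0) bins[3] / rest else 0
  c(p_zero = unname(p0), q_lessprimary = unname(q1), q_primary = unname(q2))
}

#' Redistribute binned counts over single years using similar surveys
#'
#' For sources whose attainment coding is binned, each bin's count is spread
#' over its constituent single years proportionally to the pooled empirical
#' within-bin distribution of single-year-coded training observations from
#' similar surveys: same country first, matched within \code{year_window}
#' years, widening to all years of that country and then to the whole pool;
#' a bin with no training mass anywhere falls back to a uniform split with a
#' warning. Totals are conserved exactly per bin; fractional counts result.
#'
#' @param binned_obs one observation row (list/data.frame row) with
#'   \code{country}, \code{year} and bin counts \code{count_zero},
#'   \code{count_1to5}, \code{count_6to11}, \code{count_12plus}.
#' @param training_pool data.frame of single-year-coded observations with
#'   columns \code{country}, \code{year} and single-year counts
#'   \code{y0..y18} (as produced by [simulate_surveys()]).
#' @param year_window half-width of the survey-year match (default 5).
#' @return list with \code{year_counts} (named length-19 vector over years
#'   0..18 summing to the total person count) and \code{mean_years} (the
#'   implied mean).
#' @export
split_binned_counts <- function(binned_obs, training_pool, year_window = 5) {
  ycols <- paste0("y", 0:18)
  if (!all(ycols %in% names(training_pool)))
    stop("training pool lacks single-year count columns y0..y18")
  pool <- training_pool[stats::complete.cases(training_pool[ycols]), ,
                        drop = FALSE]
  if (nrow(pool) == 0) stop("empty training pool")
  bins <- list(zero = "y0", `1-5` = paste0("y", 1:5),
               `6-11` = paste0("y", 6:11), `12+` = paste0("y", 12:18))
  counts <- c(binned_obs$count_zero, binned_obs$count_1to5,
              binned_obs$count_6to11, binned_obs$count_12plus)
  out <- stats::setNames(numeric(19), ycols)
  subsets <- list(
    pool[pool$country == binned_obs$country &
           abs(pool$year - binned_obs$year) <= year_window, , drop = FALSE],
    pool[pool$country == binned_obs$country, , drop = FALSE],
    pool)
  for (b in seq_along(bins)) {
    cols <- bins[[b]]
    if (counts[b] == 0) next
    if (length(cols) == 1) { out[cols] <- counts[b]; next }
    dist <- NULL
    for (s in subsets) {
      if (nrow(s) == 0) next
      m <- colSums(s[, cols, drop = FALSE])
      if (sum(m) > 0) { dist <- m / sum(m); break }
    }
    if (is.null(dist)) {
      warning("no training mass for bin ", names(bins)[b],
              "; falling back to a uniform within-bin split")
      dist <- rep(1 / length(cols), length(cols))
    }
    out[cols] <- counts[b] * dist
  }
  yrs <- 0:18
  list(year_counts = out,
       mean_years = sum(yrs * out) / sum(out))
}

#' Mean years under midpoint imputation of binned counts
#'
#' The comparator heuristic: every person in a bin is assigned the bin's
#' midpoint year (0, 3, 8.5, 15) and the mean is taken. Used to benchmark
#' [split_binned_counts()].
#'
#' @inheritParams split_binned_counts
#' @return implied mean years.
#' @export
midpoint_mean_years <- function(binned_obs) {
  counts <- c(binned_obs$count_zero, binned_obs$count_1to5,
              binned_obs$count_6to11, binned_obs$count_12plus)
  mid <- c(0, 3, 8.5, 15)
  sum(mid * counts) / sum(counts)
}

#' Expand an observation table into conditional-binomial records
#'
#' Applies [cr_transform_counts()] to every row and returns the long table
#' of (level, successes, trials) records joined to the row's location/time
#' fields; trials of polygon rows are the Kish effective sample sizes.
#'
#' @param obs observation data.frame from [simulate_surveys()].
#' @return data.frame with the original location columns plus \code{level},
#'   \code{successes}, \code{trials}.
#' @export
cr_prepare_observations <- function(obs) {
  keep <- c("source_id", "design", "cluster_id", "pixel", "country",
            "admin1_id", "admin2_id", "year", "t")
  out <- lapply(seq_len(nrow(obs)), function(r) {
    cc <- c(obs$count_zero[r], obs$count_1to5[r], obs$count_6to11[r],
            obs$count_12plus[r])
    cr <- cr_transform_counts(cc)
    cbind(obs[rep(r, 3), keep, drop = FALSE], cr)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
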