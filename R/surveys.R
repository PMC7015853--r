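#' Describe a survey source
#'
#' A source is one survey- or census-year: a set of clusters (point design,
#' GPS-located) or admin-referenced samples (polygon design) with either
#' single-year attainment coding or binned coding (only bin counts retained).
#'
#' @param source_id character id.
#' @param design \code{"point"} or \code{"polygon"}.
#' @param coding \code{"single_year"} or \code{"binned"}.
#' @param country country id the source samples from.
#' @param year calendar year of the survey.
#' @param n_clusters number of clusters (point) or sampled admin2 units
#'   (polygon).
#' @param mean_cluster_size expected persons per cluster (Poisson, min 5).
#' @param weight_dispersion gamma-shape dispersion of person weights for
#'   polygon designs (weights ~ Gamma(1/disp, 1/disp), mean 1); larger
#'   values give more unequal weights and DEFF further above 1.
#' @param bin_edges lower cut points of the upper three bins on the
#'   top-coded year scale (fixed at c(1, 6, 12) for the standard bins).
#' @return list of class \code{"edu_source"}.
#' @export
survey_source <- function(source_id, design = c("point", "polygon"),
                          coding = c("single_year", "binned"),
                          country = 1L, year, n_clusters = 30,
                          mean_cluster_size = 50, weight_dispersion = 0.3,
                          bin_edges = c(1, 6, 12)) {
  design <- match.arg(design); coding <- match.arg(coding)
  if (n_clusters < 1) stop("n_clusters must be >= 1")
  if (is.unsorted(bin_edges, strictly = TRUE) || any(bin_edges < 0) ||
      any(bin_edges > 18))
    stop("bin_edges must be strictly increasing within [0, 18]")
  structure(list(source_id = source_id, design = design, coding = coding,
                 country = country, year = year, n_clusters = n_clusters,
                 mean_cluster_size = mean_cluster_size,
                 weight_dispersion = weight_dispersion,
                 bin_edges = bin_edges),
            class = "edu_source")
}

#' Default survey-source battery for a synthetic world
#'
#' One point source per country in each of a spread of survey years (about
#' 400 clusters in total on the default world), plus optionally a binned
#' point source and a polygon source per country to exercise the
#' preparation steps.
#'
#' @param world an \code{edu_world}.
#' @param clusters_per_source clusters per point source.
#' @param with_binned,with_polygon include binned-coding / polygon sources.
#' @return list of \code{edu_source}.
#' @export
default_sources <- function(world, clusters_per_source = 34,
                            with_binned = FALSE, with_polygon = FALSE) {
  countries <- sort(unique(world$country))
  yrs <- world$years[unique(round(seq(1, world$n_time, length.out = 4)))]
  out <- list()
  for (ctr in countries) for (y in yrs) {
    out[[length(out) + 1L]] <- survey_source(
      sprintf("src_c%d_y%d", ctr, y), design = "point",
      coding = "single_year", country = ctr, year = y,
      n_clusters = clusters_per_source)
  }
  if (with_binned) for (ctr in countries) {
    out[[length(out) + 1L]] <- survey_source(
      sprintf("src_binned_c%d", ctr), design = "point", coding = "binned",
      country = ctr, year = yrs[2], n_clusters = clusters_per_source)
  }
  if (with_polygon) for (ctr in countries) {
    out[[length(out) + 1L]] <- survey_source(
      sprintf("src_poly_c%d", ctr), design = "polygon",
      coding = "single_year", country = ctr, year = yrs[3], n_clusters = 3)
  }
  out
}

# draw one person's single-year attainment given the 4 bin probabilities and
# the within-bin profiles; returns integer years 0..18
draw_person_years <- function(n, bin_probs, profile) {
  bins <- sample.int(4, n, replace = TRUE, prob = bin_probs)
  yrs <- integer(n)
  for (b in 1:4) {
    k <- bins == b
    if (!any(k)) next
    pr <- profile[[b]]
    yrs[k] <- as.integer(names(pr))[sample.int(length(pr), sum(k),
                                               replace = TRUE, prob = pr)]
  }
  yrs
}

#' Simulate survey observations from the synthetic truth
#'
#' For point sources, clusters are placed at population-weighted random
#' pixels of the source's country and each person's single-year attainment
#' is drawn from the true bin probabilities and within-bin profiles; the
#' cluster is summarized by its bin counts and mean years (simple random
#' sample). Binned-coding sources retain only the bin counts (single-year
#' columns and mean years are \code{NA}). For polygon sources, persons are
#' sampled across the pixels of sampled admin2 units proportional to
#' population, receive unequal gamma-distributed sampling weights, and are
#' aggregated with the Kish design-effect correction
#' (see [aggregate_polygon_obs()]).
#'
#' @param world an \code{edu_world}.
#' @param truth an \code{edu_truth}.
#' @param sources list of [survey_source()] objects.
#' @param seed integer seed; the observation table is deterministic given it.
#' @return data.frame with one row per cluster (point) or admin2 sample
#'   (polygon): source_id, design, coding, cluster_id, pixel, pixel_row,
#'   pixel_col, country, admin1_id, admin2_id, year, t, N (for polygon rows
#'   the Kish effective sample size), n_raw, deff, count_zero, count_1to5,
#'   count_6to11, count_12plus, mean_years, and single-year counts y0..y18
#'   (NA where coding is binned).
#' @export
simulate_surveys <- function(world, truth, sources, seed = 1) {
  set.seed(seed %% .Machine$integer.max)
  rows <- list()
  ycols <- paste0("y", 0:18)
  for (src in sources) {
    t_idx <- match(src$year, world$years)
    if (is.na(t_idx)) stop("source year outside world: ", src$year)
    in_ctr <- which(world$country == src$country)
    pop <- world$population[in_ctr, t_idx]
    if (sum(pop) <= 0) stop("source country has zero population")
    if (src$design == "point") {
      pix <- in_ctr[sample.int(length(in_ctr), src$n_clusters, replace = TRUE,
                               prob = pop)]
      sizes <- pmax(5L, stats::rpois(src$n_clusters, src$mean_cluster_size))
      for (cl in seq_len(src$n_clusters)) {
        i <- pix[cl]
        yrs <- draw_person_years(sizes[cl], truth$bin_probs[i, t_idx, ],
                                 truth$within_bin_profile)
        cnt <- tabulate(yrs + 1L, nbins = 19L)
        bin <- c(cnt[1], sum(cnt[2:6]), sum(cnt[7:12]), sum(cnt[13:19]))
        r <- data.frame(source_id = src$source_id, design = "point",
                        coding = src$coding,
                        cluster_id = sprintf("%s_cl%03d", src$source_id, cl),
                        pixel = i, pixel_row = world$coords[i, 1],
                        pixel_col = world$coords[i, 2],
                        country = src$country, admin1_id = world$admin1[i],
                        admin2_id = world$admin2[i], year = src$year,
                        t = t_idx, N = sizes[cl], n_raw = sizes[cl], deff = 1,
                        count_zero = bin[1], count_1to5 = bin[2],
                        count_6to11 = bin[3], count_12plus = bin[4],
                        mean_years = if (src$coding == "single_year")
                          mean(yrs) else NA_real_,
                        stringsAsFactors = FALSE)
        r[ycols] <- if (src$coding == "single_year") as.list(cnt)
                    else as.list(rep(NA_real_, 19))
        rows[[length(rows) + 1L]] <- r
      }
    } else {
      units <- sort(unique(world$admin2[in_ctr]))
      units <- units[sample.int(length(units),
                                min(src$n_clusters, length(units)))]
      for (ad in units) {
        upix <- which(world$admin2 == ad)
        upop <- world$population[upix, t_idx]
        if (sum(upop) <= 0) stop("polygon unit has zero population")
        n <- max(5L, stats::rpois(1, src$mean_cluster_size * 3))
        person_pix <- upix[sample.int(length(upix), n, replace = TRUE,
                                      prob = upop)]
        yrs <- integer(n)
        for (i in unique(person_pix)) {
          k <- person_pix == i
          yrs[k] <- draw_person_years(sum(k), truth$bin_probs[i, t_idx, ],
                                      truth$within_bin_profile)
        }
        w <- stats::rgamma(n, shape = 1 / src$weight_dispersion,
                           rate = 1 / src$weight_dispersion)
        agg <- aggregate_polygon_obs(yrs, w)
        r <- data.frame(source_id = src$source_id, design = "polygon",
                        coding = src$coding,
                        cluster_id = sprintf("%s_ad%03d", src$source_id, ad),
                        pixel = NA_integer_, pixel_row = NA_integer_,
                        pixel_col = NA_integer_,
                        country = src$country,
                        admin1_id = world$admin1[upix[1]],
                        admin2_id = ad, year = src$year, t = t_idx,
                        N = agg$n_eff, n_raw = n, deff = agg$deff,
                        count_zero = agg$proportions[1] * agg$n_eff,
                        count_1to5 = agg$proportions[2] * agg$n_eff,
                        count_6to11 = agg$proportions[3] * agg$n_eff,
                        count_12plus = agg$proportions[4] * agg$n_eff,
                        mean_years = agg$mean_years,
                        stringsAsFactors = FALSE)
        r[ycols] <- as.list(rep(NA_real_, 19))
        rows[[length(rows) + 1L]] <- r
      }
    }
  }
  do.call(rbind, rows)
}

#' Write world layers and observations as plain-text files
#'
#' Emits CSV representations of the admin hierarchy / population / land
#' cover, the covariate stack, and an observation table, for interchange
#' with other tools.
#'
#' @param world an \code{edu_world}.
#' @param obs observation data.frame from [simulate_surveys()].
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_world_csv <- function(world, obs = NULL, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  base <- data.frame(pixel = seq_len(world$n_pix),
                     row = world$coords[, 1], col = world$coords[, 2],
                     country = world$country, admin1 = world$admin1,
                     admin2 = world$admin2, landcover = world$landcover)
  paths <- file.path(dir, "pixels.csv")
  utils::write.csv(base, paths[1], row.names = FALSE)
  pop <- data.frame(pixel = rep(seq_len(world$n_pix), world$n_time),
                    year = rep(world$years, each = world$n_pix),
                    population = as.vector(world$population))
  paths <- c(paths, file.path(dir, "population.csv"))
  utils::write.csv(pop, paths[2], row.names = FALSE)
  cv <- do.call(rbind, lapply(dimnames(world$covariates)[[3]], function(nm)
    data.frame(covariate = nm,
               pixel = rep(seq_len(world$n_pix), world$n_time),
               year = rep(world$years, each = world$n_pix),
               value = as.vector(world$covariates[, , nm]))))
  paths <- c(paths, file.path(dir, "covariates.csv"))
  utils::write.csv(cv, paths[3], row.names = FALSE)
  if (!is.null(obs)) {
    paths <- c(paths, file.path(dir, "observations.csv"))
    utils::write.csv(obs, paths[length(paths)], row.names = FALSE)
  }
  invisible(paths)
}
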