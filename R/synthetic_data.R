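#' Define a planar study grid
#'
#' The study domain is a rectangular grid of square cells on a planar
#' (easting/northing, meter) coordinate system, mimicking a national
#' 10 x 10 km recording grid. Cells are half-open intervals
#' \code{[x, x + cell_size) x [y, y + cell_size)} and are indexed row-major
#' from the lower-left origin.
#'
#' @param x_min,y_min,x_max,y_max grid extent in meters.
#' @param cell_size cell edge length in meters (default 10,000 = 10 km).
#' @return an object of class \code{grid_spec}.
#' @examples
#' spec <- grid_spec(0, 0, 2e5, 1.1e6)
#' spec$n_cells  # 20 x 110 = 2200
#' @export
grid_spec <- function(x_min, y_min, x_max, y_max, cell_size = 10000) {
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("invalid grid: cell_size must be a positive number", call. = FALSE)
  if (x_max <= x_min || y_max <= y_min)
    stop("invalid grid: extent must satisfy x_max > x_min and y_max > y_min",
         call. = FALSE)
  nx <- (x_max - x_min) / cell_size
  ny <- (y_max - y_min) / cell_size
  if (abs(nx - round(nx)) > 1e-8 || abs(ny - round(ny)) > 1e-8)
    stop("invalid grid: extent must be an integer multiple of cell_size",
         call. = FALSE)
  out <- list(x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max,
              cell_size = cell_size,
              nx = as.integer(round(nx)), ny = as.integer(round(ny)))
  out$n_cells <- out$nx * out$ny
  class(out) <- "grid_spec"
  out
}

#' Default study grid for the synthetic world
#'
#' A 200 km x 1,100 km domain of 10-km cells whose northings span the
#' latitudinal band of a Fennoscandian-style study region (the 7,000,000 m
#' northing used to delimit southern species falls inside it).
#'
#' @return a [grid_spec()].
#' @export
default_grid_spec <- function() {
  grid_spec(x_min = 2e5, y_min = 6.6e6, x_max = 4e5, y_max = 7.7e6,
            cell_size = 10000)
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells of %g m (easting %g..%g, northing %g..%g)\n",
              x$nx, x$ny, x$cell_size, x$x_min, x$x_max, x$y_min, x$y_max))
  invisible(x)
}

#' Cell centroids of a grid
#'
#' @param spec a [grid_spec()].
#' @return data frame with \code{cell_id}, \code{easting_m}, \code{northing_m};
#'   one row per cell, row-major from the lower-left origin.
#' @export
cell_centroids <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  cx <- spec$x_min + (seq_len(spec$nx) - 0.5) * spec$cell_size
  cy <- spec$y_min + (seq_len(spec$ny) - 0.5) * spec$cell_size
  data.frame(cell_id = seq_len(spec$n_cells),
             easting_m  = rep(cx, times = spec$ny),
             northing_m = rep(cy, each = spec$nx))
}

#' Map point coordinates to grid cell ids
#'
#' Points on a cell boundary belong to the cell whose half-open interval
#' contains them. Points outside the grid extent map to \code{NA}.
#'
#' @param spec a [grid_spec()].
#' @param easting,northing coordinate vectors in meters.
#' @return integer vector of cell ids (row-major from lower-left), \code{NA}
#'   for points outside the extent.
#' @export
cell_index <- function(spec, easting, northing) {
  stopifnot(inherits(spec, "grid_spec"))
  ix <- floor((easting - spec$x_min) / spec$cell_size)
  iy <- floor((northing - spec$y_min) / spec$cell_size)
  ok <- ix >= 0 & ix < spec$nx & iy >= 0 & iy < spec$ny
  out <- rep(NA_integer_, length(easting))
  out[ok] <- as.integer(iy[ok]) * spec$nx + as.integer(ix[ok]) + 1L
  out
}

#' Simulate a climate grid with latitudinal gradients
#'
#' Generates cell-level climate for a grid: mean annual temperature (MAT,
#' degrees C) declines linearly with northing at a fixed lapse; growing degree
#' days (GDD5) are a monotone function of MAT, \code{max(0, a * MAT + b)};
#' annual precipitation (PREC, mm) and soil water content (SWC, fraction)
#' follow linear latitudinal gradients plus independent Gaussian noise.
#'
#' Defaults: lapse -1 degree C per 100 km; GDD5 = max(0, 200 * MAT + 300);
#' PREC 700 mm at the southern edge declining 100 mm per 1,000 km with 50 mm
#' noise; SWC 0.35 rising 0.05 per 1,000 km with 0.03 noise.
#'
#' @param spec a [grid_spec()].
#' @param gradient named list of gradient parameters; any subset of
#'   \code{mat_south} (MAT at \code{y_min}), \code{lapse} (degree C per m),
#'   \code{gdd_a}, \code{gdd_b}, \code{prec_south}, \code{prec_slope} (mm/m),
#'   \code{swc_south}, \code{swc_slope} (1/m).
#' @param noise_sd named list of Gaussian noise SDs for \code{MAT} (degree C),
#'   \code{PREC} (mm), \code{SWC} (fraction).
#' @param seed integer seed; the grid is reproduced bit-identically from it.
#' @return data frame (\code{climate_grid}): \code{cell_id}, \code{easting_m},
#'   \code{northing_m}, \code{MAT}, \code{GDD5}, \code{PREC}, \code{SWC}.
#' @export
simulate_climate_grid <- function(spec,
                                  gradient = list(),
                                  noise_sd = list(),
                                  seed = 1L) {
  stopifnot(inherits(spec, "grid_spec"))
  g <- utils::modifyList(list(mat_south = 6, lapse = -1e-5,
                              gdd_a = 200, gdd_b = 300,
                              prec_south = 700, prec_slope = -1e-4,
                              swc_south = 0.35, swc_slope = 5e-8),
                         gradient)
  ns <- utils::modifyList(list(MAT = 0.3, PREC = 50, SWC = 0.03), noise_sd)
  if (any(unlist(ns) < 0)) stop("noise_sd values must be >= 0", call. = FALSE)

  cells <- cell_centroids(spec)
  dy <- cells$northing_m - spec$y_min
  set.seed(as.integer(seed))
  n <- nrow(cells)
  cells$MAT  <- g$mat_south + g$lapse * dy + stats::rnorm(n, 0, ns$MAT)
  cells$GDD5 <- pmax(0, g$gdd_a * cells$MAT + g$gdd_b)
  cells$PREC <- pmax(0, g$prec_south + g$prec_slope * dy +
                       stats::rnorm(n, 0, ns$PREC))
  cells$SWC  <- pmin(1, pmax(0, g$swc_south + g$swc_slope * dy +
                               stats::rnorm(n, 0, ns$SWC)))
  cells
}

#' Simulate a species pool with known ground truth
#'
#' Draws, for each species, climatic niche parameters (mean and SD of MAT,
#' GDD5, PREC and SWC over its continental range), categorical traits
#' (overwintering mode, generations per season), body size and European range
#' size, a true northern-edge position in the first period, and a true edge
#' shift generated by a linear model on scaled covariates:
#' \deqn{shift = \beta_0 + \sum_j \beta_j z_j + \epsilon,\quad
#'       \epsilon \sim N(0, \sigma^2)}
#' where \eqn{z_j} are the within-pool scaled (mean 0, SD 1) continuous
#' covariates. Trait levels may add fixed offsets. The returned table is the
#' ground truth against which parameter-recovery tests run.
#'
#' GDD5 niche parameters are derived from the MAT ones through the same
#' monotone link used by the climate generator, so GDD5 acts as a correlated
#' alternative thermal variable; PREC is drawn correlated with SWC in the
#' same spirit for the moisture axis.
#'
#' @param n_species number of species (>= 1).
#' @param niche named list overriding niche hyper-parameters: \code{mat_mean},
#'   \code{mat_mean_sd}, \code{mat_sd_range}, \code{swc_mean},
#'   \code{swc_mean_sd}, \code{swc_sd_range}, \code{prec_mean_sd},
#'   \code{prec_sd_range}, \code{range_size_range}.
#' @param trait_freq named list of trait level frequencies:
#'   \code{wintering} (named, sums to 1) and \code{n_gen} (named, sums to 1).
#' @param effect named list of generating coefficients on scaled covariates:
#'   \code{intercept} plus any of \code{Tmean} (mean MAT), \code{Tbreadth}
#'   (SD MAT), \code{Mmean} (mean SWC), \code{Mbreadth} (SD SWC), \code{size},
#'   \code{range_size}, and optional named numeric vectors \code{wintering}
#'   and \code{n_gen} giving per-level offsets (km).
#' @param shift_noise_sd SD of the Gaussian shift noise, km (>= 0).
#' @param edge_range two northings (m) between which true first-period edges
#'   are drawn uniformly.
#' @param effort_ratio nominal second-to-first period recording-effort ratio,
#'   stored in the truth table.
#' @param seed integer seed.
#' @return data frame (\code{synthetic_truth}), one row per species, with the
#'   niche parameters, traits, \code{true_edge_T1_m} and \code{true_shift_km}.
#' @export
simulate_species_pool <- function(n_species,
                                  niche = list(),
                                  trait_freq = list(),
                                  effect = list(),
                                  shift_noise_sd = 15,
                                  edge_range = c(6.8e6, 7.5e6),
                                  effort_ratio = 3,
                                  seed = 1L) {
  stopifnot(n_species >= 1, shift_noise_sd >= 0, effort_ratio > 0)
  np <- utils::modifyList(list(mat_mean = 7, mat_mean_sd = 2,
                               mat_sd_range = c(0.8, 4),
                               swc_mean = 0.32, swc_mean_sd = 0.04,
                               swc_sd_range = c(0.01, 0.08),
                               prec_mean = 650, prec_mean_sd = 80,
                               prec_sd_range = c(30, 120),
                               size_mean = 30, size_sd = 8,
                               range_size_range = c(100, 2500)),
                          niche)
  tf <- utils::modifyList(
    list(wintering = c(adult = 0.2, egg = 0.2, larva = 0.4, pupa = 0.2),
         n_gen = c(one = 0.7, two_plus = 0.3)),
    trait_freq)
  for (nm in c("wintering", "n_gen")) {
    if (abs(sum(tf[[nm]]) - 1) > 1e-8)
      stop(sprintf("trait frequencies for '%s' must sum to 1", nm),
           call. = FALSE)
  }
  ef <- utils::modifyList(list(intercept = 25, Tmean = 0, Tbreadth = 0,
                               Mmean = 0, Mbreadth = 0, size = 0,
                               range_size = 0),
                          effect)

  set.seed(as.integer(seed))
  n <- as.integer(n_species)
  mean_MAT <- stats::rnorm(n, np$mat_mean, np$mat_mean_sd)
  sd_MAT   <- stats::runif(n, np$mat_sd_range[1], np$mat_sd_range[2])
  mean_SWC <- pmin(0.95, pmax(0.02, stats::rnorm(n, np$swc_mean, np$swc_mean_sd)))
  sd_SWC   <- stats::runif(n, np$swc_sd_range[1], np$swc_sd_range[2])
  mean_PREC <- pmax(50, stats::rnorm(n, np$prec_mean, np$prec_mean_sd) +
                      2000 * (mean_SWC - np$swc_mean))
  sd_PREC  <- stats::runif(n, np$prec_sd_range[1], np$prec_sd_range[2])
  # GDD5 niche via the monotone climate link GDD5 = 200 * MAT + 300
  mean_GDD5 <- pmax(0, 200 * mean_MAT + 300)
  sd_GDD5   <- 200 * sd_MAT
  wintering <- sample(names(tf$wintering), n, replace = TRUE,
                      prob = tf$wintering)
  n_gen <- sample(names(tf$n_gen), n, replace = TRUE, prob = tf$n_gen)
  body_size <- pmax(2, stats::rnorm(n, np$size_mean, np$size_sd))
  range_size <- as.integer(round(stats::runif(n, np$range_size_range[1],
                                              np$range_size_range[2])))
  true_edge <- stats::runif(n, edge_range[1], edge_range[2])

  zscale <- function(x) if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x)
    else x * 0
  shift <- ef$intercept +
    ef$Tmean * zscale(mean_MAT) + ef$Tbreadth * zscale(sd_MAT) +
    ef$Mmean * zscale(mean_SWC) + ef$Mbreadth * zscale(sd_SWC) +
    ef$size * zscale(body_size) + ef$range_size * zscale(range_size)
  if (!is.null(ef$wintering)) shift <- shift + ef$wintering[wintering]
  if (!is.null(ef$n_gen)) shift <- shift + ef$n_gen[n_gen]
  shift <- shift + stats::rnorm(n, 0, shift_noise_sd)

  data.frame(species_id = sprintf("sp%03d", seq_len(n)),
             mean_MAT = mean_MAT, sd_MAT = sd_MAT,
             mean_GDD5 = mean_GDD5, sd_GDD5 = sd_GDD5,
             mean_PREC = mean_PREC, sd_PREC = sd_PREC,
             mean_SWC = mean_SWC, sd_SWC = sd_SWC,
             wintering = wintering, n_gen = n_gen,
             body_size = body_size, range_size = range_size,
             true_edge_T1_m = true_edge,
             true_shift_km = as.numeric(shift),
             effort_ratio = effort_ratio,
             stringsAsFactors = FALSE)
}

#' Simulate a continent-scale occupancy atlas
#'
#' For each species, occupies \code{range_size} distinct cells of a
#' continental climate grid, sampled without replacement with probability
#' proportional to a Gaussian kernel on the cell's MAT centred at the
#' species' thermal niche mean with its niche SD. The resulting occupancy
#' table is the input from which empirical niche metrics are recomputed.
#'
#' @param truth a species pool from [simulate_species_pool()].
#' @param climate a continental climate grid (e.g. from
#'   [simulate_climate_grid()] on a wide-extent [grid_spec()]).
#' @param seed integer seed.
#' @return data frame with columns \code{cell_id}, \code{species_id}.
#' @export
simulate_euro_atlas <- function(truth, climate, seed = 1L) {
  .require_cols(truth, c("species_id", "mean_MAT", "sd_MAT", "range_size"),
                "truth")
  .require_cols(climate, c("cell_id", "MAT"), "climate")
  set.seed(as.integer(seed))
  out <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    w <- stats::dnorm(climate$MAT, truth$mean_MAT[i], truth$sd_MAT[i]) + 1e-12
    k <- min(truth$range_size[i], nrow(climate))
    cells <- sample(climate$cell_id, k, replace = FALSE, prob = w)
    out[[i]] <- data.frame(cell_id = cells,
                           species_id = truth$species_id[i],
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simulate occurrence records under period-specific recording effort
#'
#' Occupancy is uniform south of the species' true edge: every cell whose
#' centroid northing lies below the edge is occupied independently with a
#' fixed probability. The true edge sits at \code{true_edge_T1_m} in the first
#' period and at \code{true_edge_T1_m + 1000 * true_shift_km} in the second.
#' Recording effort acts as independent Poisson thinning per occupied cell:
#' the number of records in a cell is Poisson with mean
#' \code{intensity * (1 + gradient * ((y - y_mid) / y_range))}, allowing a
#' configurable latitudinal effort gradient (gradient 0 = spatially uniform).
#' Setting \code{intensity = Inf} reports every occupied cell exactly once
#' (complete census). Record coordinates are cell centroids; years are drawn
#' uniformly within the period window.
#'
#' Species whose edge (in either period) falls outside the grid's northing
#' extent are skipped with a warning and listed in the \code{"skipped"}
#' attribute of the result.
#'
#' @param truth a species pool from [simulate_species_pool()].
#' @param spec the study [grid_spec()].
#' @param period_windows named list of two disjoint year ranges, e.g.
#'   \code{list(T1 = c(1992, 1996), T2 = c(2013, 2017))}.
#' @param effort named list per period, each with \code{intensity} (expected
#'   records per occupied cell, > 0 or \code{Inf}) and \code{gradient}
#'   (dimensionless latitudinal tilt, 0 = uniform).
#' @param occupancy list with \code{p}, the occupancy probability of a cell
#'   south of the edge (default 0.4).
#' @param seed integer seed.
#' @return data frame of occurrence records: \code{species_id},
#'   \code{easting_m}, \code{northing_m}, \code{year}; attribute
#'   \code{"skipped"} lists species whose edges fell off-grid.
#' @export
simulate_occurrences <- function(truth, spec,
                                 period_windows = list(T1 = c(1992, 1996),
                                                       T2 = c(2013, 2017)),
                                 effort = list(T1 = list(intensity = 0.3,
                                                         gradient = 0),
                                               T2 = list(intensity = 0.9,
                                                         gradient = 0)),
                                 occupancy = list(p = 0.4),
                                 seed = 1L) {
  stopifnot(inherits(spec, "grid_spec"))
  .require_cols(truth, c("species_id", "true_edge_T1_m", "true_shift_km"),
                "truth")
  if (length(period_windows) != 2L)
    stop("exactly two period windows are required", call. = FALSE)
  w1 <- period_windows[[1]]; w2 <- period_windows[[2]]
  if (max(w1) >= min(w2) && max(w2) >= min(w1))
    stop("period windows must be disjoint", call. = FALSE)
  for (p in names(effort))
    if (!is.infinite(effort[[p]]$intensity) && effort[[p]]$intensity <= 0)
      stop("effort intensities must be > 0", call. = FALSE)

  cells <- cell_centroids(spec)
  y_range <- spec$y_max - spec$y_min
  y_mid <- (spec$y_max + spec$y_min) / 2
  set.seed(as.integer(seed))

  skipped <- character(0)
  res <- list()
  for (i in seq_len(nrow(truth))) {
    e1 <- truth$true_edge_T1_m[i]
    e2 <- e1 + 1000 * truth$true_shift_km[i]
    if (e1 <= spec$y_min || e1 > spec$y_max ||
        e2 <= spec$y_min || e2 > spec$y_max) {
      skipped <- c(skipped, truth$species_id[i])
      next
    }
    for (p in names(period_windows)) {
      edge <- if (p == names(period_windows)[1]) e1 else e2
      south <- cells[cells$northing_m < edge, , drop = FALSE]
      occ <- south[stats::runif(nrow(south)) < occupancy$p, , drop = FALSE]
      if (!nrow(occ)) next
      ep <- effort[[p]]
      if (is.infinite(ep$intensity)) {
        k <- rep(1L, nrow(occ))
      } else {
        lam <- ep$intensity *
          pmax(0, 1 + ep$gradient * (occ$northing_m - y_mid) / y_range)
        k <- stats::rpois(nrow(occ), lam)
      }
      keep <- k > 0
      if (!any(keep)) next
      occ <- occ[keep, , drop = FALSE]; k <- k[keep]
      win <- period_windows[[p]]
      rows <- data.frame(
        species_id = truth$species_id[i],
        easting_m = rep(occ$easting_m, k),
        northing_m = rep(occ$northing_m, k),
        year = sample(seq(win[1], win[2]), sum(k), replace = TRUE),
        stringsAsFactors = FALSE)
      res[[length(res) + 1L]] <- rows
    }
  }
  if (length(skipped))
    warning(sprintf("%d species skipped: true edge outside grid extent (%s)",
                    length(skipped),
                    paste(utils::head(skipped, 5), collapse = ", ")),
            call. = FALSE)
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(species_id = character(0), easting_m = numeric(0),
               northing_m = numeric(0), year = integer(0))
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
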