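#' tau-quantile range-edge position of a set of northings
#'
#' Returns the minimizer of the check (pinball) loss
#' \deqn{\sum_i \rho_\tau(y_i - q), \quad \rho_\tau(u) = u(\tau - 1[u < 0]).}
#' With a two-level period factor, quantile regression of northings on period
#' reduces to this per-period quantile. When \code{n * tau} is an integer the
#' minimizer is a flat interval between two order statistics and the lower
#' endpoint is returned, matching the vertex solutions of linear-programming
#' quantile fits; otherwise the \code{ceiling(n * tau)}-th order statistic is
#' the unique minimizer.
#'
#' @param northings non-empty numeric vector (m).
#' @param tau quantile level in (0, 1); default 0.9 (the leading-edge
#'   definition).
#' @return the edge northing (m).
#' @examples
#' quantile_edge(1:10, 0.75)  # 8
#' quantile_edge(1:10, 0.9)   # 9 (lower endpoint of the flat interval [9,10])
#' @export
quantile_edge <- function(northings, tau = 0.9) {
  if (!length(northings)) stop("empty input: no northings", call. = FALSE)
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0 || tau >= 1)
    stop("tau must lie strictly between 0 and 1", call. = FALSE)
  n <- length(northings)
  nt <- n * tau
  k <- if (abs(nt - round(nt)) < 1e-9) as.integer(round(nt))
       else as.integer(ceiling(nt))
  sort(northings, partial = k)[k]
}

# row-wise quantile_edge for a bootstrap matrix (same tie convention)
.row_quantile_edge <- function(m, tau) {
  n <- ncol(m)
  nt <- n * tau
  k <- if (abs(nt - round(nt)) < 1e-9) as.integer(round(nt))
       else as.integer(ceiling(nt))
  apply(m, 1L, function(r) sort(r, partial = k)[k])
}

#' Estimate the shift of a species' range edge between two periods
#'
#' The edge in each period is the tau-quantile of presence northings; the
#' shift is their difference in km (positive = northward). The 95% confidence
#' interval comes from a stratified percentile bootstrap: presences are
#' resampled with replacement within each period, the shift recomputed, and
#' the 2.5% and 97.5% percentiles of the \code{B} bootstrap shifts taken.
#'
#' @param northings_T1,northings_T2 presence northings (m) in the two periods.
#' @param tau quantile level in (0, 1).
#' @param ci \code{"bootstrap"} (default) or \code{"none"} (CIs reported as
#'   \code{NA}; useful when only point estimates are needed).
#' @param B number of bootstrap resamples (default 1000).
#' @param seed integer seed for the bootstrap.
#' @param min_support minimum presence count per period (default 5); below
#'   it the species cannot support a high quantile and an error of class
#'   \code{"insufficient_support"} is thrown (callers catch it and report
#'   the species as skipped).
#' @return one-row data frame: \code{tau}, \code{edge_T1_m}, \code{edge_T2_m},
#'   \code{shift_km}, \code{ci_low_km}, \code{ci_high_km}, \code{n_T1},
#'   \code{n_T2}, \code{n_replicates} (1).
#' @export
estimate_shift <- function(northings_T1, northings_T2, tau = 0.9,
                           ci = c("bootstrap", "none"), B = 1000,
                           seed = 1L, min_support = 5) {
  ci <- match.arg(ci)
  n1 <- length(northings_T1); n2 <- length(northings_T2)
  if (n1 < min_support || n2 < min_support) {
    e <- simpleError(sprintf(
      "insufficient support: n_T1 = %d, n_T2 = %d (minimum %d per period)",
      n1, n2, min_support))
    class(e) <- c("insufficient_support", class(e))
    stop(e)
  }
  e1 <- quantile_edge(northings_T1, tau)
  e2 <- quantile_edge(northings_T2, tau)
  shift <- (e2 - e1) / 1000
  lo <- hi <- NA_real_
  if (ci == "bootstrap") {
    stopifnot(B >= 1)
    set.seed(as.integer(seed))
    b1 <- matrix(northings_T1[sample.int(n1, n1 * B, replace = TRUE)], B, n1)
    b2 <- matrix(northings_T2[sample.int(n2, n2 * B, replace = TRUE)], B, n2)
    shifts <- (.row_quantile_edge(b2, tau) - .row_quantile_edge(b1, tau)) / 1000
    qs <- unname(stats::quantile(shifts, c(0.025, 0.975)))
    lo <- qs[1]; hi <- qs[2]
  }
  data.frame(tau = tau, edge_T1_m = e1, edge_T2_m = e2, shift_km = shift,
             ci_low_km = lo, ci_high_km = hi, n_T1 = n1, n_T2 = n2,
             n_replicates = 1L)
}

#' Average edge estimates over subsampling replicates
#'
#' For taxa whose second-period data were balanced by repeated subsampling,
#' the per-replicate point estimates and the endpoints of their 95% CIs are
#' each replaced by their arithmetic means, producing the final estimate.
#'
#' @param estimates data frame of one-row estimates from [estimate_shift()]
#'   (stacked), all for the same species and tau.
#' @return one-row data frame in the same layout, with \code{n_replicates}
#'   set to the number of rows averaged.
#' @export
average_replicates <- function(estimates) {
  if (!nrow(estimates)) stop("no estimates to average", call. = FALSE)
  if (length(unique(estimates$tau)) != 1L)
    stop("estimates mix tau levels", call. = FALSE)
  out <- estimates[1, , drop = FALSE]
  for (col in c("edge_T1_m", "edge_T2_m", "shift_km",
                "ci_low_km", "ci_high_km", "n_T1", "n_T2"))
    out[[col]] <- mean(estimates[[col]])
  out$n_replicates <- nrow(estimates)
  rownames(out) <- NULL
  out
}

#' Classify a shift by whether its 95% CI covers zero
#'
#' Northward if the whole CI is above zero, southward if below, otherwise
#' "none" (poor evidence for a shift). Estimates without a CI give \code{NA}.
#'
#' @param estimates data frame with \code{ci_low_km} and \code{ci_high_km}.
#' @return character vector: \code{"northward"}, \code{"southward"},
#'   \code{"none"} or \code{NA}.
#' @export
classify_shift <- function(estimates) {
  lo <- estimates$ci_low_km; hi <- estimates$ci_high_km
  ifelse(is.na(lo) | is.na(hi), NA_character_,
         ifelse(lo > 0, "northward", ifelse(hi < 0, "southward", "none")))
}

#' Estimate edge shifts for all species across balancing replicates
#'
#' Runs [estimate_shift()] per species on each replicate presence table and
#' averages the replicates with [average_replicates()]. Species below the
#' support threshold in any replicate are skipped and reported.
#'
#' @param replicates list of presence tables (from [balance_effort()], or a
#'   single-element list for unbalanced data).
#' @param tau quantile level.
#' @param ci,B,seed,min_support passed to [estimate_shift()]; each
#'   species x replicate bootstrap derives its own sub-seed from \code{seed}.
#' @param t1_label,t2_label period labels.
#' @return data frame of averaged estimates, one row per retained species,
#'   with a \code{class} column from [classify_shift()] and a
#'   \code{"skipped"} attribute naming species below support.
#' @export
estimate_edges <- function(replicates, tau = 0.9, ci = "bootstrap", B = 1000,
                           seed = 1L, min_support = 5,
                           t1_label = "T1", t2_label = "T2") {
  stopifnot(is.list(replicates), length(replicates) >= 1)
  species <- sort(unique(unlist(lapply(replicates, function(d) d$species_id))))
  out <- vector("list", length(species))
  skipped <- character(0)
  for (si in seq_along(species)) {
    sp <- species[si]
    ests <- vector("list", length(replicates))
    ok <- TRUE
    for (r in seq_along(replicates)) {
      d <- replicates[[r]]
      y1 <- d$northing_m[d$species_id == sp & d$period == t1_label]
      y2 <- d$northing_m[d$species_id == sp & d$period == t2_label]
      est <- tryCatch(
        estimate_shift(y1, y2, tau = tau, ci = ci, B = B,
                       seed = derive_seed(seed, paste0(sp, "_rep", r)),
                       min_support = min_support),
        insufficient_support = function(e) NULL)
      if (is.null(est)) { ok <- FALSE; break }
      ests[[r]] <- est
    }
    if (!ok) { skipped <- c(skipped, sp); next }
    avg <- average_replicates(do.call(rbind, ests))
    avg <- cbind(species_id = sp, avg, stringsAsFactors = FALSE)
    out[[si]] <- avg
  }
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(species_id = character(0), tau = numeric(0),
                      edge_T1_m = numeric(0), edge_T2_m = numeric(0),
                      shift_km = numeric(0), ci_low_km = numeric(0),
                      ci_high_km = numeric(0), n_T1 = numeric(0),
                      n_T2 = numeric(0), n_replicates = integer(0))
  }
  rownames(out) <- NULL
  out$class <- classify_shift(out)
  attr(out, "skipped") <- skipped
  out
}

#' Summarize edge shifts by species group
#'
#' Reports, per group, the species count, mean shift (km) and northward speed
#' (km/yr). Two speed conventions are reported because they differ when
#' shifts vary across species relative to a common mid-year span: the group
#' mean shift divided by the span of the group's period mid-years
#' (\code{speed_from_mean_km_yr}) and the mean of per-species speeds
#' (\code{mean_species_speed_km_yr}; identical here since the span is shared
#' within a group, but kept explicit). The overall mean shift is the
#' species-count-weighted mean of the group means.
#'
#' @param estimates estimates table with \code{species_id} and
#'   \code{shift_km}.
#' @param groups named character vector mapping species id to group label.
#' @param midyears named list mapping group label to a numeric pair
#'   \code{c(midyear_T1, midyear_T2)} with \code{midyear_T2 > midyear_T1}.
#' @return list with \code{by_group} (data frame: group, n, mean_shift_km,
#'   speed_from_mean_km_yr, mean_species_speed_km_yr) and
#'   \code{overall_mean_shift_km}.
#' @export
summarize_shifts <- function(estimates, groups, midyears) {
  .require_cols(estimates, c("species_id", "shift_km"), "estimates")
  g <- unname(groups[estimates$species_id])
  if (anyNA(g)) stop("every species must be assigned to a group",
                     call. = FALSE)
  labels <- unique(unname(groups))
  rows <- list()
  for (lab in labels) {
    sel <- g == lab
    if (!any(sel)) { warning(sprintf("group '%s' has no species; omitted",
                                     lab), call. = FALSE); next }
    my <- midyears[[lab]]
    if (is.null(my) || my[2] <= my[1])
      stop(sprintf("midyears for group '%s' must be a pair with T2 > T1",
                   lab), call. = FALSE)
    span <- my[2] - my[1]
    sh <- estimates$shift_km[sel]
    rows[[lab]] <- data.frame(group = lab, n = sum(sel),
                              mean_shift_km = mean(sh),
                              speed_from_mean_km_yr = mean(sh) / span,
                              mean_species_speed_km_yr = mean(sh / span))
  }
  by_group <- do.call(rbind, rows)
  rownames(by_group) <- NULL
  overall <- sum(by_group$n * by_group$mean_shift_km) / sum(by_group$n)
  list(by_group = by_group, overall_mean_shift_km = overall)
}
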