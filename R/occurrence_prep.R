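#' Convert occurrence records to period-labelled grid-cell presences
#'
#' Records are assigned a period by their year (records outside both windows
#' are dropped), snapped to the grid cell containing their coordinates
#' (half-open cells, so boundary points belong to the cell to the north-east
#' of the boundary), and deduplicated to one presence per
#' (species, cell, period). Presence coordinates are cell centroids.
#'
#' @param records data frame with \code{species_id}, \code{easting_m},
#'   \code{northing_m}, \code{year}.
#' @param spec the study [grid_spec()].
#' @param period_windows named list of two disjoint year ranges
#'   (\code{list(T1 = c(1992, 1996), T2 = c(2013, 2017))} by default).
#' @return data frame of presences: \code{species_id}, \code{cell_id},
#'   \code{easting_m}, \code{northing_m} (centroids), \code{period}.
#'   Attribute \code{"report"}: counts of records dropped for falling outside
#'   the grid extent or outside both period windows.
#' @export
grid_presences <- function(records, spec,
                           period_windows = list(T1 = c(1992, 1996),
                                                 T2 = c(2013, 2017))) {
  stopifnot(inherits(spec, "grid_spec"))
  .require_cols(records, c("species_id", "easting_m", "northing_m", "year"),
                "records")
  stopifnot(length(period_windows) == 2L)

  period <- rep(NA_character_, nrow(records))
  for (p in names(period_windows)) {
    w <- period_windows[[p]]
    period[records$year >= w[1] & records$year <= w[2]] <- p
  }
  out_window <- sum(is.na(period))

  cid <- cell_index(spec, records$easting_m, records$northing_m)
  out_extent <- sum(!is.na(period) & is.na(cid))
  keep <- !is.na(period) & !is.na(cid)

  cents <- cell_centroids(spec)
  df <- data.frame(species_id = records$species_id[keep],
                   cell_id = cid[keep],
                   period = period[keep],
                   stringsAsFactors = FALSE)
  df <- unique(df)
  df$easting_m <- cents$easting_m[df$cell_id]
  df$northing_m <- cents$northing_m[df$cell_id]
  df <- df[order(df$species_id, df$period, df$cell_id),
           c("species_id", "cell_id", "easting_m", "northing_m", "period")]
  rownames(df) <- NULL
  attr(df, "report") <- list(n_records = nrow(records),
                             dropped_outside_extent = out_extent,
                             dropped_outside_windows = out_window,
                             n_presences = nrow(df))
  df
}

#' Retain species with a southern first-period distribution centre
#'
#' Species are kept only if the centre point of their first-period
#' distribution lies south of a northing threshold, which restricts the
#' analysis to predominantly southern species whose leading (northern) range
#' edge falls inside the study domain. The centre is the unweighted mean
#' (optionally median) of first-period presence-cell northings; species at or
#' north of the threshold, and species with no first-period presences, are
#' removed.
#'
#' @param presences presence table from [grid_presences()].
#' @param northing_threshold northing in meters (default 7,000,000).
#' @param t1_label period label of the first period (default \code{"T1"}).
#' @param center \code{"mean"} (default) or \code{"median"}.
#' @return character vector of retained species ids; attribute
#'   \code{"report"} lists species removed as northern and species lacking
#'   first-period presences.
#' @export
filter_southern_species <- function(presences, northing_threshold = 7e6,
                                    t1_label = "T1", center = "mean") {
  .require_cols(presences, c("species_id", "northing_m", "period"),
                "presences")
  center <- match.arg(center, c("mean", "median"))
  if (!nrow(presences)) {
    warning("empty presence table: no species retained", call. = FALSE)
    out <- character(0)
    attr(out, "report") <- list(removed_northern = character(0),
                                removed_no_t1 = character(0))
    return(out)
  }
  all_sp <- unique(presences$species_id)
  t1 <- presences[presences$period == t1_label, , drop = FALSE]
  cfun <- if (center == "mean") mean else stats::median
  centres <- tapply(t1$northing_m, t1$species_id, cfun)
  no_t1 <- setdiff(all_sp, names(centres))
  retained <- names(centres)[centres < northing_threshold]
  removed_north <- setdiff(names(centres), retained)
  out <- sort(retained)
  attr(out, "report") <- list(removed_northern = sort(removed_north),
                              removed_no_t1 = sort(no_t1))
  out
}

#' Partition the study extent into latitudinal zones
#'
#' @param y_min,y_max northing extent in meters.
#' @param n_zones number of contiguous equal-width zones (default 5).
#' @param breaks optional explicit strictly increasing break vector spanning
#'   the extent (overrides \code{n_zones}).
#' @return numeric vector of \code{n_zones + 1} strictly increasing break
#'   northings covering \code{[y_min, y_max]}.
#' @export
zone_partition <- function(y_min, y_max, n_zones = 5, breaks = NULL) {
  if (is.null(breaks)) {
    stopifnot(y_max > y_min, n_zones >= 1)
    breaks <- seq(y_min, y_max, length.out = n_zones + 1)
  }
  if (any(diff(breaks) <= 0))
    stop("zone breaks must be strictly increasing", call. = FALSE)
  breaks
}

#' Equalize recording effort between periods by zone-stratified subsampling
#'
#' Within each latitudinal zone, the pooled-across-species second-period
#' presences are randomly subsampled without replacement down to the zone's
#' pooled first-period presence count, so that the total number of presences
#' of all species combined is equal between the periods in every zone. The
#' first period is never modified. The procedure is repeated
#' \code{n_replicates} times (default 5) with distinct sub-seeds, yielding
#' replicate data sets over which downstream edge estimates are averaged.
#' If a zone has fewer second-period than first-period presences, all its
#' second-period presences are kept and a warning is emitted (no upsampling).
#'
#' @param presences presence table from [grid_presences()].
#' @param breaks zone breaks from [zone_partition()].
#' @param n_replicates number of independent subsampling replicates (>= 1).
#' @param seed integer seed; replicate \code{r} uses a sub-seed derived from
#'   it, so the whole replicate set is reproducible.
#' @param t1_label,t2_label period labels (defaults \code{"T1"}, \code{"T2"}).
#' @return list of \code{n_replicates} presence tables (all first-period rows
#'   plus the zone-balanced second-period subsample), each carrying a
#'   \code{"zone_counts"} attribute (per-zone T1 count, available T2 count,
#'   kept T2 count) and a \code{"seed"} attribute.
#' @export
balance_effort <- function(presences, breaks, n_replicates = 5, seed = 1L,
                           t1_label = "T1", t2_label = "T2") {
  .require_cols(presences, c("species_id", "cell_id", "northing_m", "period"),
                "presences")
  stopifnot(n_replicates >= 1)
  if (any(presences$northing_m < breaks[1] |
          presences$northing_m > breaks[length(breaks)]))
    stop("zone breaks do not cover all presences", call. = FALSE)

  zone <- findInterval(presences$northing_m, breaks, rightmost.closed = TRUE)
  t1 <- presences[presences$period == t1_label, , drop = FALSE]
  t2 <- presences[presences$period == t2_label, , drop = FALSE]
  z1 <- zone[presences$period == t1_label]
  z2 <- zone[presences$period == t2_label]
  n_zones <- length(breaks) - 1L
  n1 <- tabulate(z1, n_zones)
  n2 <- tabulate(z2, n_zones)
  if (any(n2 < n1))
    warning(sprintf(
      "zone(s) %s have fewer %s than %s presences; keeping all %s there",
      paste(which(n2 < n1), collapse = ", "), t2_label, t1_label, t2_label),
      call. = FALSE)

  reps <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    sub_seed <- derive_seed(seed, paste0("balance_replicate_", r))
    set.seed(sub_seed)
    keep_idx <- integer(0)
    kept <- integer(n_zones)
    for (z in seq_len(n_zones)) {
      idx <- which(z2 == z)
      k <- min(n1[z], length(idx))
      kept[z] <- k
      if (k > 0) keep_idx <- c(keep_idx, sample(idx, k, replace = FALSE))
    }
    rep_df <- rbind(t1, t2[sort(keep_idx), , drop = FALSE])
    rownames(rep_df) <- NULL
    attr(rep_df, "zone_counts") <- data.frame(zone = seq_len(n_zones),
                                              n_T1 = n1, n_T2_avail = n2,
                                              n_T2_kept = kept)
    attr(rep_df, "seed") <- sub_seed
    attr(rep_df, "replicate") <- r
    reps[[r]] <- rep_df
  }
  reps
}
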