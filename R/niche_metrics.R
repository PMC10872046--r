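#' European range size of a species
#'
#' Number of distinct occupied grid cells in the continental occupancy atlas.
#'
#' @param atlas occupancy table with \code{cell_id}, \code{species_id}.
#' @param species_id species identifier (must be present in the atlas).
#' @return integer count of distinct occupied cells.
#' @export
range_size <- function(atlas, species_id) {
  .require_cols(atlas, c("cell_id", "species_id"), "atlas")
  cells <- atlas$cell_id[atlas$species_id == species_id]
  if (!length(cells))
    stop(sprintf("species '%s' is absent from the atlas", species_id),
         call. = FALSE)
  length(unique(cells))
}

#' Climatic niche statistics of a species for one climate variable
#'
#' Mean, SD and coefficient of variation of a climate variable over the
#' cells the species occupies. The mean describes the average conditions the
#' species experiences (for MAT this is the species temperature index, STI);
#' the SD is the absolute niche breadth; CV = SD / mean is the relative
#' breadth. For MAT the CV denominator is converted to Kelvin
#' (mean + 273.15) so that the ratio is taken on an absolute temperature
#' scale. SD is the sample SD (n - 1 denominator) by default.
#'
#' Occupied cells lacking a climate value for the variable are dropped (and
#' counted in the result); with fewer than two valued cells, SD and CV are
#' reported missing with a warning.
#'
#' @param atlas occupancy table (\code{cell_id}, \code{species_id}).
#' @param climate climate grid with \code{cell_id} and the variable column.
#' @param species_id species identifier.
#' @param variable one of \code{"MAT"}, \code{"GDD5"}, \code{"PREC"},
#'   \code{"SWC"} (any numeric column of \code{climate} is accepted).
#' @param sd_type \code{"sample"} (default, n - 1) or \code{"population"}.
#' @return list: \code{mean}, \code{sd}, \code{cv}, \code{n_cells} (cells
#'   with values), \code{n_dropped} (occupied cells without a value).
#' @export
niche_stats <- function(atlas, climate, species_id, variable,
                        sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  .require_cols(climate, c("cell_id", variable), "climate")
  n_occ <- range_size(atlas, species_id)  # errors on unknown species
  cells <- unique(atlas$cell_id[atlas$species_id == species_id])
  vals <- climate[[variable]][match(cells, climate$cell_id)]
  vals <- vals[!is.na(vals)]
  n <- length(vals)
  if (n == 0)
    stop(sprintf("species '%s' has no occupied cell with a %s value",
                 species_id, variable), call. = FALSE)
  m <- mean(vals)
  if (n < 2) {
    warning(sprintf(
      "species '%s': single cell with a %s value; SD and CV are missing",
      species_id, variable), call. = FALSE)
    s <- cv <- NA_real_
  } else {
    s <- if (sd_type == "sample") stats::sd(vals)
         else sqrt(mean((vals - m)^2))
    denom <- if (variable == "MAT") m + 273.15 else m
    cv <- s / denom
  }
  list(mean = m, sd = s, cv = cv, n_cells = n, n_dropped = n_occ - n)
}

#' Niche metric table for all species
#'
#' Computes [niche_stats()] for every species and variable plus the European
#' range size, in one wide table.
#'
#' @param atlas occupancy table.
#' @param climate climate grid.
#' @param variables climate variables to summarize (default the four used by
#'   the analysis).
#' @param sd_type passed to [niche_stats()].
#' @return data frame with one row per species: \code{species_id}, then
#'   \code{mean_v}, \code{sd_v}, \code{cv_v} per variable, and
#'   \code{range_size}.
#' @export
niche_metrics_table <- function(atlas, climate,
                                variables = c("MAT", "GDD5", "PREC", "SWC"),
                                sd_type = "sample") {
  species <- sort(unique(atlas$species_id))
  rows <- lapply(species, function(sp) {
    row <- list(species_id = sp)
    for (v in variables) {
      st <- niche_stats(atlas, climate, sp, v, sd_type = sd_type)
      row[[paste0("mean_", v)]] <- st$mean
      row[[paste0("sd_", v)]] <- st$sd
      row[[paste0("cv_", v)]] <- st$cv
    }
    row$range_size <- range_size(atlas, sp)
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assemble the species-level regression table
#'
#' Joins edge-shift estimates, niche metrics and traits into the table the
#' weighted regression consumes: response \code{shift_km}; regression weight
#' = inverse of the 95% CI width of the shift; four climatic covariates
#' (mean and breadth of the chosen thermal and moisture variables), three
#' traits and European range size. Breadth is either the SD (absolute) or CV
#' (relative) column of the chosen variables. Species missing any covariate,
#' or with a non-positive CI width (undefined weight), are dropped and
#' reported.
#'
#' @param edges estimates table from [estimate_edges()].
#' @param niches table from [niche_metrics_table()].
#' @param traits data frame with \code{species_id}, \code{wintering},
#'   \code{n_gen}, \code{body_size}.
#' @param thermal_var \code{"MAT"} (default) or \code{"GDD5"}.
#' @param moisture_var \code{"SWC"} (default) or \code{"PREC"}.
#' @param breadth_kind \code{"SD"} (default) or \code{"CV"}.
#' @param weight_kind \code{"width"} (default; weight = 1 / CI width) or
#'   \code{"half_width"} (1 / half-width).
#' @return data frame: \code{species_id}, \code{shift_km}, \code{weight},
#'   \code{Tmean}, \code{Tbreadth}, \code{Mmean}, \code{Mbreadth},
#'   \code{wintering}, \code{n_gen}, \code{size}, \code{range_size};
#'   attribute \code{"report"} names species dropped and why.
#' @export
assemble_model_table <- function(edges, niches, traits,
                                 thermal_var = c("MAT", "GDD5"),
                                 moisture_var = c("SWC", "PREC"),
                                 breadth_kind = c("SD", "CV"),
                                 weight_kind = c("width", "half_width")) {
  thermal_var <- match.arg(thermal_var)
  moisture_var <- match.arg(moisture_var)
  breadth_kind <- match.arg(breadth_kind)
  weight_kind <- match.arg(weight_kind)
  .require_cols(edges, c("species_id", "shift_km", "ci_low_km", "ci_high_km"),
                "edges")
  .require_cols(traits, c("species_id", "wintering", "n_gen", "body_size"),
                "traits")
  bcol <- if (breadth_kind == "SD") "sd_" else "cv_"

  df <- merge(edges[, c("species_id", "shift_km", "ci_low_km", "ci_high_km")],
              niches, by = "species_id")
  df <- merge(df, traits[, c("species_id", "wintering", "n_gen", "body_size")],
              by = "species_id")
  width <- df$ci_high_km - df$ci_low_km
  bad_w <- !is.na(width) & width <= 0
  if (any(bad_w))
    warning(sprintf("dropping %d species with non-positive CI width: %s",
                    sum(bad_w),
                    paste(utils::head(df$species_id[bad_w], 5),
                          collapse = ", ")), call. = FALSE)
  denom <- if (weight_kind == "width") width else width / 2
  out <- data.frame(species_id = df$species_id,
                    shift_km = df$shift_km,
                    weight = 1 / denom,
                    Tmean = df[[paste0("mean_", thermal_var)]],
                    Tbreadth = df[[paste0(tolower(bcol), thermal_var)]],
                    Mmean = df[[paste0("mean_", moisture_var)]],
                    Mbreadth = df[[paste0(tolower(bcol), moisture_var)]],
                    wintering = df$wintering,
                    n_gen = df$n_gen,
                    size = df$body_size,
                    range_size = df$range_size,
                    stringsAsFactors = FALSE)
  complete <- stats::complete.cases(out) & !bad_w & !is.infinite(out$weight)
  dropped <- out$species_id[!complete]
  out <- out[complete, , drop = FALSE]
  rownames(out) <- NULL
  all_sp <- unique(edges$species_id)
  attr(out, "report") <- list(
    dropped_incomplete = sort(dropped),
    dropped_unmatched = sort(setdiff(all_sp, c(out$species_id, dropped))))
  out
}
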