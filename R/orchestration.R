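#' Build and validate a pipeline run configuration
#'
#' Collects every tunable of the pipeline into one validated list. Unknown
#' keys are rejected; every randomized stage later derives its own sub-seed
#' from \code{seed} and the stage name via [derive_seed()], so a single
#' master seed reproduces the whole run bit-identically.
#'
#' Presets mirror the study's main and alternative analysis variants:
#' \code{"main"} models the 0.9-quantile shift on MAT/SWC with SD breadths;
#' \code{"alt_a"} switches the quantile to 0.75; \code{"alt_b"} switches the
#' breadths to CV; \code{"alt_c"} switches the climate variables to
#' GDD5/PREC.
#'
#' @param ... configuration overrides; see Defaults.
#' @param preset one of \code{"main"}, \code{"alt_a"}, \code{"alt_b"},
#'   \code{"alt_c"}.
#' @section Defaults:
#' \describe{
#'   \item{grid}{[default_grid_spec()]}
#'   \item{period_windows}{\code{list(T1 = c(1992, 1996), T2 = c(2013, 2017))}}
#'   \item{n_zones}{5 equal-width latitudinal zones}
#'   \item{n_replicates}{5 subsampling replicates}
#'   \item{tau}{0.9}
#'   \item{ci}{\code{"bootstrap"}}, \item{B}{1000 resamples}
#'   \item{min_support}{5 presences per period}
#'   \item{northing_threshold}{7e6 m southern-species delimitation}
#'   \item{thermal_var/moisture_var/breadth_kind}{\code{"MAT"}, \code{"SWC"},
#'     \code{"SD"}}
#'   \item{candidates}{the eight standard predictors}
#'   \item{delta_aic}{2}
#'   \item{n_species}{200}, \item{effect}{generator coefficients},
#'   \item{shift_noise_sd}{15}, \item{effort}{per-period intensities},
#'   \item{occupancy_p}{0.4}, \item{seed}{1}
#' }
#' @return validated list of class \code{run_config}.
#' @export
run_config <- function(..., preset = c("main", "alt_a", "alt_b", "alt_c")) {
  preset <- match.arg(preset)
  defaults <- list(
    grid = default_grid_spec(),
    continent_grid = grid_spec(0, 4.2e6, 2e6, 7.7e6, cell_size = 50000),
    period_windows = list(T1 = c(1992, 1996), T2 = c(2013, 2017)),
    n_zones = 5,
    n_replicates = 5,
    tau = 0.9,
    ci = "bootstrap",
    B = 1000,
    min_support = 5,
    northing_threshold = 7e6,
    thermal_var = "MAT",
    moisture_var = "SWC",
    breadth_kind = "SD",
    candidates = c("Tmean", "Tbreadth", "Mmean", "Mbreadth",
                   "wintering", "n_gen", "size", "range_size"),
    delta_aic = 2,
    n_species = 200,
    effect = list(intercept = 25, Tbreadth = -30),
    shift_noise_sd = 15,
    effort = list(T1 = list(intensity = 0.3, gradient = 0),
                  T2 = list(intensity = 0.9, gradient = 0)),
    occupancy_p = 0.4,
    out_dir = NULL,
    seed = 1L)
  if (preset == "alt_a") defaults$tau <- 0.75
  if (preset == "alt_b") defaults$breadth_kind <- "CV"
  if (preset == "alt_c") {
    defaults$thermal_var <- "GDD5"; defaults$moisture_var <- "PREC"
  }
  overrides <- list(...)
  validate_config(utils::modifyList(defaults, overrides,
                                    keep.null = TRUE),
                  known = names(defaults))
}

#' Validate a raw configuration list
#'
#' Type- and cross-field-checks a configuration; unknown keys are rejected
#' and every violated constraint is reported naming the offending field.
#'
#' @param config named list.
#' @param known character vector of permitted keys (defaults to the keys of
#'   [run_config()]).
#' @return the config, classed \code{run_config}.
#' @export
validate_config <- function(config, known = NULL) {
  if (is.null(known)) known <- names(unclass(run_config()))
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  fail <- function(field, msg)
    stop(sprintf("invalid config field '%s': %s", field, msg), call. = FALSE)
  if (!inherits(config$grid, "grid_spec")) fail("grid", "must be a grid_spec")
  if (any(config$tau <= 0) || any(config$tau >= 1))
    fail("tau", "must lie strictly between 0 and 1")
  if (config$B < 1) fail("B", "must be a positive integer")
  if (config$n_replicates < 1) fail("n_replicates", "must be >= 1")
  if (config$n_zones < 1) fail("n_zones", "must be >= 1")
  if (!config$breadth_kind %in% c("SD", "CV"))
    fail("breadth_kind", "must be 'SD' or 'CV'")
  if (!config$thermal_var %in% c("MAT", "GDD5"))
    fail("thermal_var", "must be 'MAT' or 'GDD5'")
  if (!config$moisture_var %in% c("SWC", "PREC"))
    fail("moisture_var", "must be 'SWC' or 'PREC'")
  if (!config$ci %in% c("bootstrap", "none"))
    fail("ci", "must be 'bootstrap' or 'none'")
  if (config$delta_aic < 0) fail("delta_aic", "must be >= 0")
  if (config$occupancy_p <= 0 || config$occupancy_p > 1)
    fail("occupancy_p", "must lie in (0, 1]")
  if (config$min_support < 1) fail("min_support", "must be >= 1")
  class(config) <- "run_config"
  config
}

#' Run the full synthetic pipeline end to end
#'
#' Simulate (species pool, climate grids, continental atlas, occurrence
#' records) then prepare (grid presences, southern-species delimitation,
#' zone-stratified effort balancing), estimate edge shifts, compute niche
#' metrics, assemble the regression table, enumerate all predictor subsets
#' and select the final model by the AIC parsimony rule. Every random stage
#' derives its sub-seed from the master seed, so rerunning the same config
#' reproduces all outputs bit-identically.
#'
#' @param config a [run_config()].
#' @return list of class \code{run_report}: \code{truth}, \code{edges},
#'   \code{niches}, \code{model_table}, \code{subsets}, \code{selection},
#'   \code{summary} (per-stage row counts, seeds and warnings). If
#'   \code{config$out_dir} is set, TSV outputs and a JSON run report are
#'   written there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seeds <- list(
    pool = derive_seed(config$seed, "species_pool"),
    climate = derive_seed(config$seed, "climate_grid"),
    continent = derive_seed(config$seed, "continent_climate"),
    atlas = derive_seed(config$seed, "euro_atlas"),
    occurrences = derive_seed(config$seed, "occurrences"),
    balance = derive_seed(config$seed, "balance"),
    edges = derive_seed(config$seed, "edges"))

  truth <- simulate_species_pool(config$n_species, effect = config$effect,
                                 shift_noise_sd = config$shift_noise_sd,
                                 seed = seeds$pool)
  continent <- simulate_climate_grid(config$continent_grid,
                                     gradient = list(mat_south = 17,
                                                     lapse = -7e-6),
                                     seed = seeds$continent)
  atlas <- simulate_euro_atlas(truth, continent, seed = seeds$atlas)
  occ <- simulate_occurrences(truth, config$grid,
                              period_windows = config$period_windows,
                              effort = config$effort,
                              occupancy = list(p = config$occupancy_p),
                              seed = seeds$occurrences)

  presences <- grid_presences(occ, config$grid,
                              period_windows = config$period_windows)
  keep <- filter_southern_species(presences, config$northing_threshold)
  presences <- presences[presences$species_id %in% keep, , drop = FALSE]
  breaks <- zone_partition(config$grid$y_min, config$grid$y_max,
                           config$n_zones)
  replicates <- balance_effort(presences, breaks,
                               n_replicates = config$n_replicates,
                               seed = seeds$balance)

  edges <- estimate_edges(replicates, tau = config$tau, ci = config$ci,
                          B = config$B, seed = seeds$edges,
                          min_support = config$min_support)

  niches <- niche_metrics_table(atlas, continent)
  traits <- truth[, c("species_id", "wintering", "n_gen", "body_size")]
  model_table <- assemble_model_table(edges, niches, traits,
                                      thermal_var = config$thermal_var,
                                      moisture_var = config$moisture_var,
                                      breadth_kind = config$breadth_kind)

  subsets <- NULL; selection <- NULL
  if (nrow(model_table) > 2 * length(config$candidates)) {
    subsets <- best_subsets(model_table, config$candidates)
    selection <- select_final(subsets, delta = config$delta_aic)
  }

  report <- list(
    seeds = seeds,
    n_species = nrow(truth),
    n_records = nrow(occ),
    n_presences = nrow(presences),
    n_species_retained = length(keep),
    n_species_estimated = nrow(edges),
    n_model_rows = nrow(model_table),
    chosen_size = if (!is.null(selection)) selection$chosen_size else NA,
    chosen_predictors = if (!is.null(selection))
      selection$chosen_predictors else NA)

  out <- list(truth = truth, edges = edges, niches = niches,
              model_table = model_table, subsets = subsets,
              selection = selection, summary = report, config = config)
  class(out) <- "run_report"

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv_table(truth, file.path(config$out_dir, "truth.tsv"))
    write_tsv_table(occ, file.path(config$out_dir, "occurrences.tsv"))
    write_tsv_table(presences, file.path(config$out_dir, "presences.tsv"))
    write_tsv_table(edges, file.path(config$out_dir, "edges.tsv"))
    write_tsv_table(niches, file.path(config$out_dir, "niche_metrics.tsv"))
    write_tsv_table(model_table,
                    file.path(config$out_dir, "model_table.tsv"))
    if (!is.null(subsets))
      write_tsv_table(subsets$summary,
                      file.path(config$out_dir, "candidates.tsv"))
    jsonlite::write_json(report,
                         file.path(config$out_dir, "run_report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}

#' @export
print.run_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "pipeline run: %d species -> %d records -> %d presences -> %d estimated\n",
    s$n_species, s$n_records, s$n_presences, s$n_species_estimated))
  if (!is.na(s$chosen_size))
    cat(sprintf("final model: size %d (%s)\n", s$chosen_size,
                s$chosen_predictors))
  invisible(x)
}
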