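#' Build a complete synthetic world with known ground truth
#'
#' Convenience orchestrator for tests, examples and the command line: daily
#' climate, annual land-use, climatological predictor stacks for each
#' analysis year, a sea mask, a calibrated ground-truth suitability model
#' and the resulting reference-year species probability map.
#'
#' The default domain is 5W-5E, 35N-45N at 0.25 degrees (40 x 40 = 1600
#' cells) with years 1970-2020 and analysis years 2000/2010/2020 — a
#' desk-scale stand-in for the full 0.1-degree Euro-Mediterranean domain,
#' which remains a configuration choice.
#'
#' @param seed master seed; every stochastic component derives from it.
#' @param grid a [grid_spec()].
#' @param years climate years (must cover every analysis year's window).
#' @param analysis_years years to build predictor stacks for; the first is
#'   the reference year.
#' @param window climatological window length.
#' @param trend warming trend, degrees C per decade.
#' @param drift_rate annual land-use drift bound; 0 freezes land-use.
#' @param noise_sd daily temperature noise.
#' @param map_noise_sd link-scale noise of the species map.
#' @param registry extreme-variable registry.
#' @param truth a [truth_spec()]; default [default_truth()], intercept
#'   calibrated to a 0.4 presence fraction on the reference stack.
#' @param sea_fraction sea-mask coverage.
#' @param keep_cube retain the (large) daily cube in the result.
#' @return list with `grid`, `mask`, `landuse`, `stacks` (named by year),
#'   `truth`, `map`, `reference_year`, and optionally `cube`.
#' @export
synthetic_world <- function(seed = 1,
                            grid = grid_spec(-5, 5, 35, 45, 0.25),
                            years = 1970:2020,
                            analysis_years = c(2000, 2010, 2020),
                            window = 31, trend = 0.4, drift_rate = 0.01,
                            noise_sd = 2, map_noise_sd = 0,
                            registry = default_threshold_registry(),
                            truth = NULL, sea_fraction = 0.2,
                            keep_cube = FALSE) {
  cube <- generate_climate(grid, years, trend = trend, seed = seed,
                           noise_sd = noise_sd, min_window = window)
  lu_years <- min(analysis_years):max(analysis_years)
  landuse <- generate_landuse(grid, lu_years, drift_rate = drift_rate,
                              seed = seed)
  stacks <- lapply(analysis_years, function(y)
    climatological_stack(cube, landuse, y, registry, window))
  names(stacks) <- analysis_years
  mask <- sea_mask(grid, seed, sea_fraction)
  ref <- as.character(analysis_years[1])
  if (is.null(truth))
    truth <- calibrate_truth(default_truth(), stacks[[ref]], mask)
  map <- generate_species_map(stacks[[ref]], truth, noise_sd = map_noise_sd,
                              seed = seed, mask = mask)
  out <- list(grid = grid, mask = mask, landuse = landuse, stacks = stacks,
              truth = truth, map = map,
              reference_year = analysis_years[1])
  if (keep_cube) out$cube <- cube
  out
}
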