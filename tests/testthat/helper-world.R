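# Shared fixtures, built once per test run. The "small world" is a 20x20,
# 0.5-degree domain with a 5-year climatological window: large enough for the
# statistical properties under test, small enough to keep the suite fast.

.fixtures <- new.env(parent = emptyenv())

small_world <- function() {
  if (is.null(.fixtures$world))
    .fixtures$world <- synthetic_world(
      seed = 11, grid = grid_spec(-5, 5, 35, 45, 0.5),
      years = 1996:2020, analysis_years = c(2000, 2010, 2020), window = 5)
  .fixtures$world
}

small_cube <- function() {
  if (is.null(.fixtures$cube))
    .fixtures$cube <- generate_climate(grid_spec(0, 5, 40, 45, 0.5),
                                       1996:2002, trend = 0, seed = 5,
                                       min_window = 5)
  .fixtures$cube
}

# a modest calibration sample plus fitted model on the small world
small_fit <- function() {
  if (is.null(.fixtures$fit)) {
    w <- small_world()
    st <- w$stacks[["2000"]]
    smp <- select_background(w$map, st, "random", 150, 150, seed = 21)
    cfg <- brt_config(learning_rate = 0.05, max_trees = 800,
                      n_folds = 5, seed = 9)
    model <- fit_with_cv(smp, config = cfg)
    .fixtures$fit <- list(world = w, stack = st, sample = smp, model = model)
  }
  .fixtures$fit
}

# hand-rolled climate cube with prescribed daily fields (one year)
toy_cube <- function(tmean, tmin = tmean, tmax = tmean, precip = 0,
                     dewpoint = tmean, n_cells = 1, year = 2000) {
  expand_field <- function(x) {
    m <- matrix(x, n_cells, 365, byrow = length(x) == 365)
    array(m, c(n_cells, 365, 1))
  }
  structure(list(grid = NULL, years = year,
                 tmean = expand_field(tmean), tmin = expand_field(tmin),
                 tmax = expand_field(tmax), precip = expand_field(precip),
                 dewpoint = expand_field(dewpoint)),
            class = "climate_cube")
}

# species map built directly from a probability vector on a given grid
toy_map <- function(prob, grid) {
  structure(list(grid = grid, prob = prob), class = "species_map")
}
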