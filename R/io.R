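grid_to_list <- function(grid)
  grid[c("lon_min", "lon_max", "lat_min", "lat_max", "cell_size")]

grid_from_list <- function(l)
  grid_spec(l$lon_min, l$lon_max, l$lat_min, l$lat_max, l$cell_size)

sidecar_path <- function(path) paste0(path, ".json")

write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

read_sidecar <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) stop("missing metadata sidecar: ", sc)
  jsonlite::read_json(sc, simplifyVector = TRUE)
}

#' Write / read a species probability map as CSV
#'
#' Long-format CSV (`cell`, `lon`, `lat`, `prob`; masked cells carry empty
#' `prob`) plus a JSON sidecar holding the grid geometry. Round trips are
#' value-exact.
#'
#' @param map a `species_map`.
#' @param path CSV file path.
#' @export
write_species_map <- function(map, path) {
  cc <- cell_centers(map$grid)
  cc$prob <- map$prob
  write.csv(cc, path, row.names = FALSE)
  write_sidecar(path, list(kind = "species_map",
                           grid = grid_to_list(map$grid)))
}

#' @rdname write_species_map
#' @export
read_species_map <- function(path) {
  meta <- read_sidecar(path)
  if (!identical(meta$kind, "species_map"))
    stop(path, " is not a species_map artifact")
  grid <- grid_from_list(meta$grid)
  d <- read.csv(path)
  if (nrow(d) != grid$n_cells)
    stop("cell count mismatch in ", path, ": ", nrow(d), " rows vs ",
         grid$n_cells, " grid cells")
  structure(list(grid = grid, prob = d$prob), class = "species_map")
}

#' Write / read a predictor stack as CSV
#'
#' Wide CSV (one column per predictor, one row per cell) with the grid and
#' per-predictor metadata in a JSON sidecar. Round trips reproduce values to
#' full double precision and metadata exactly.
#'
#' @param stack a [predictor_stack()].
#' @param path CSV file path.
#' @export
write_predictor_stack <- function(stack, path) {
  d <- as.data.frame(stack$values)
  write.csv(d, path, row.names = FALSE)
  write_sidecar(path, list(kind = "predictor_stack",
                           grid = grid_to_list(stack$grid),
                           meta = stack$meta))
}

#' @rdname write_predictor_stack
#' @export
read_predictor_stack <- function(path) {
  meta <- read_sidecar(path)
  if (!identical(meta$kind, "predictor_stack"))
    stop(path, " is not a predictor_stack artifact")
  grid <- grid_from_list(meta$grid)
  v <- as.matrix(read.csv(path, check.names = FALSE))
  if (nrow(v) != grid$n_cells)
    stop("cell count mismatch in ", path)
  m <- as.data.frame(meta$meta)
  m$window_length <- suppressWarnings(as.integer(m$window_length))
  predictor_stack(grid, v, m)
}

#' Write a calibration sample as CSV plus JSON sidecar
#'
#' @param sample a [select_background()] sample.
#' @param path CSV file path.
#' @export
write_sample <- function(sample, path) {
  d <- data.frame(cell = sample$cells, lon = sample$lon, lat = sample$lat,
                  label = sample$label)
  d <- cbind(d, as.data.frame(sample$X))
  write.csv(d, path, row.names = FALSE)
  write_sidecar(path, list(kind = "calibration_sample",
                           method = sample$method, seed = sample$seed,
                           n_presence = sample$n_presence,
                           n_absence = sample$n_absence))
}

#' Write the collated ensemble report files
#'
#' Emits the per-setup skill table (best-model table analog), the ensemble
#' quantile HSA series (time-series figure analog), the per-setup attribution
#' summary for the final year (attribution figure analog) and, when a `mip`
#' table is supplied, the MIP summary (importance table analog).
#'
#' @param result an `ensemble_result`.
#' @param dir output directory (created if needed).
#' @param mip optional [mip_summary()] table.
#' @return invisibly, the paths written.
#' @export
write_ensemble_report <- function(result, dir, mip = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ok <- vapply(result$members, function(m) isTRUE(m$ok), logical(1))
  skills <- do.call(rbind, lapply(result$members[ok], function(m)
    cbind(data.frame(setup = m$id, background = m$background,
                     selection = m$predictor_selection,
                     n_predictors = length(m$predictors),
                     n_trees = m$model$n_trees,
                     learning_rate = m$model$learning_rate,
                     tree_complexity = m$model$tree_complexity,
                     flagged = m$model$flagged,
                     best = m$id == result$best),
          as.data.frame(m$skill))))
  paths <- character(0)
  p <- file.path(dir, "skills.csv")
  write.csv(skills, p, row.names = FALSE); paths <- c(paths, p)
  if (!is.null(result$quantiles)) {
    p <- file.path(dir, "hsa_quantiles.csv")
    write.csv(result$quantiles, p, row.names = FALSE); paths <- c(paths, p)
  }
  series <- do.call(rbind, lapply(result$members[ok], function(m)
    cbind(setup = m$id, m$hsa)))
  p <- file.path(dir, "hsa_series.csv")
  write.csv(series, p, row.names = FALSE); paths <- c(paths, p)
  final_year <- max(result$years)
  attr_tab <- do.call(rbind, lapply(result$members[ok], function(m) {
    ch <- classify_change(m$run, final_year)
    cbind(setup = m$id, year = final_year,
          attribution_summary(ch, sum(m$run$ref, na.rm = TRUE)))
  }))
  p <- file.path(dir, "attribution.csv")
  write.csv(attr_tab, p, row.names = FALSE); paths <- c(paths, p)
  if (!is.null(mip)) {
    p <- file.path(dir, "mip_summary.csv")
    write.csv(mip, p, row.names = FALSE); paths <- c(paths, p)
  }
  invisible(paths)
}
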