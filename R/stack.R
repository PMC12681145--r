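#' Predictor stack: named per-cell grids with metadata
#'
#' The common currency between the predictor-construction and modelling
#' stages: one column per predictor, one row per grid cell, plus per-predictor
#' metadata (group climate/landuse, subgroup BIO/EXV/AHUM or land-use class,
#' units, target year, and the climatological window length for climate
#' predictors).
#'
#' @param grid a [grid_spec()].
#' @param values numeric matrix `n_cells x n_predictors` with unique column
#'   names.
#' @param meta data.frame with columns `name`, `group`, `subgroup`, `units`,
#'   `target_year`, `window_length` aligned to the columns of `values`.
#' @return object of class `predictor_stack`.
#' @export
predictor_stack <- function(grid, values, meta) {
  stopifnot(inherits(grid, "grid_spec"),
            is.matrix(values), nrow(values) == grid$n_cells,
            !is.null(colnames(values)),
            !anyDuplicated(colnames(values)),
            identical(meta$name, colnames(values)),
            all(meta$group %in% c("climate", "landuse")))
  structure(list(grid = grid, values = values, meta = meta),
            class = "predictor_stack")
}

#' Predictor names of a stack
#' @param stack a [predictor_stack()].
#' @param group optionally restrict to `"climate"` or `"landuse"`.
#' @export
stack_predictors <- function(stack, group = NULL) {
  nm <- stack$meta$name
  if (!is.null(group)) nm <- nm[stack$meta$group %in% group]
  nm
}

#' @export
print.predictor_stack <- function(x, ...) {
  cat(sprintf(
    "predictor_stack: %d cells, %d predictors (%d climate, %d landuse), target year %s\n",
    nrow(x$values), ncol(x$values), sum(x$meta$group == "climate"),
    sum(x$meta$group == "landuse"),
    paste(unique(x$meta$target_year), collapse = ",")))
  invisible(x)
}

stack_meta_row <- function(name, group, subgroup, units, target_year,
                           window_length) {
  data.frame(name = name, group = group, subgroup = subgroup, units = units,
             target_year = target_year, window_length = window_length,
             stringsAsFactors = FALSE)
}
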