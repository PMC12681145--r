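#' The 14 land-use classes of the study domain
#'
#' Class-fraction rasters carry one layer per class; fractions sum to 1 in
#' every cell-year. Names follow the LUCAS-style classes occurring in the
#' Euro-Mediterranean domain (tropical classes excluded).
#'
#' @return character vector of 14 class names.
#' @export
landuse_classes <- function() {
  c("urban", "non_irrigated_crops", "irrigated_crops", "c3_grass", "c4_grass",
    "deciduous_shrubs", "coniferous_shrubs", "temperate_deciduous_trees",
    "temperate_broadleaf_evergreen_trees", "coniferous_trees", "mixed_forest",
    "wetlands", "bare_soil", "inland_water")
}

#' Synthetic annual land-use class fractions
#'
#' Per-cell baseline compositions come from spatially smoothed log-abundance
#' fields (a Dirichlet-style draw with spatial coherence). Year-on-year the
#' composition moves a fraction `drift_rate` of the way towards a fixed
#' per-cell target composition, which bounds the per-year total-variation
#' change by `drift_rate` and yields slow, monotone drift.
#'
#' @param grid a [grid_spec()].
#' @param years integer vector of years.
#' @param drift_rate maximal per-year total-variation drift; must be >= 0.
#' @param seed master seed.
#' @param classes class names (14 by default).
#' @return object of class `landuse_stack`: list with `grid`, `years`,
#'   `classes` and array `frac` of dimension `c(n_cells, n_classes, n_years)`.
#' @export
generate_landuse <- function(grid, years, drift_rate = 0.01, seed = 1,
                             classes = landuse_classes()) {
  stopifnot(inherits(grid, "grid_spec"))
  if (drift_rate < 0) stop("drift_rate must be non-negative")
  years <- as.integer(years)
  nc <- grid$n_cells; nk <- length(classes); ny <- length(years)
  compo <- function(tag, offsets) {
    logab <- with_seed(derive_seed(seed, "landuse", tag), {
      vapply(seq_len(nk),
             function(k) offsets[k] + 1.5 * smooth_field(grid, passes = 6),
             numeric(nc))
    })
    e <- exp(logab)
    e / rowSums(e)
  }
  offsets <- c(-1, 0.5, -0.5, 0.3, -1.5, -0.7, -0.9, 0, -1.2, -0.4, -0.8,
               -2, -1, -2.2)[seq_len(nk)]
  base <- compo("base", offsets)
  target <- compo("target", offsets + rnorm_fixed(seed, nk))
  frac <- array(NA_real_, c(nc, nk, ny))
  f <- base
  for (t in seq_len(ny)) {
    if (t > 1) f <- (1 - drift_rate) * f + drift_rate * target
    frac[, , t] <- f
  }
  structure(list(grid = grid, years = years, classes = classes, frac = frac),
            class = "landuse_stack")
}

rnorm_fixed <- function(seed, n) with_seed(derive_seed(seed, "lu-off"),
                                           rnorm(n, 0, 0.5))

#' @export
print.landuse_stack <- function(x, ...) {
  cat(sprintf("landuse_stack: %d cells, %d classes, years %d-%d\n",
              x$grid$n_cells, length(x$classes), min(x$years), max(x$years)))
  invisible(x)
}

#' Total-variation distance between two compositions per cell
#'
#' @param a,b matrices `n_cells x n_classes` of fractions.
#' @return numeric vector of per-cell TV distances in `[0, 1]`.
#' @export
tv_distance <- function(a, b) 0.5 * rowSums(abs(a - b))
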