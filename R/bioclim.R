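MONTH_LEN <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
MONTH_OF_DAY <- rep.int(seq_len(12L), MONTH_LEN)

year_index <- function(cube, year) {
  ti <- match(year, cube$years)
  if (is.na(ti)) stop("year ", year, " not covered by the climate cube")
  ti
}

# n_cells x 365 matrix for one variable-year, robust to single-cell cubes
slice_year <- function(cube, var, ti) {
  m <- cube[[var]][, , ti, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  m
}

monthly_stat <- function(daily, fun = rowMeans) {
  # daily: n_cells x 365 -> n_cells x 12 (kept a matrix even for one cell)
  matrix(vapply(seq_len(12L),
                function(m) fun(daily[, MONTH_OF_DAY == m, drop = FALSE]),
                numeric(nrow(daily))), nrow(daily), 12L)
}

# all 12 wrap-around consecutive 3-month windows, as index matrix 12 x 3
quarter_months <- function()
  t(vapply(1:12, function(s) as.integer(((s - 1):(s + 1)) %% 12 + 1),
           integer(3)))

#' Compute the 19 BIOCLIM bioclimatic variables for one calendar year
#'
#' Standard BIOCLIM definitions from monthly aggregates (monthly means of
#' daily tmean/tmin/tmax; monthly precipitation sums). Quarters are all 12
#' consecutive 3-month windows with calendar wrap (Jan-Mar, ..., Dec-Feb,
#' months taken from the same year). Ties among quarters resolve to the
#' earliest start month. Temperatures are in degrees C (not degrees C x 10);
#' BIO4 is 100 x the standard deviation of monthly mean temperature; BIO15 is
#' the precipitation coefficient of variation 100 x sd / (1 + BIO12/12).
#' Where BIO7 is zero (degenerate constant climate) BIO3 is set to 0 with a
#' warning.
#'
#' @param cube a [generate_climate()] cube (or same-shaped object).
#' @param year calendar year, fully covered by the cube.
#' @return numeric matrix `n_cells x 19`, columns `BIO1`..`BIO19`.
#' @export
compute_bios <- function(cube, year) {
  ti <- year_index(cube, year)
  tavg <- monthly_stat(slice_year(cube, "tmean", ti))
  tmin <- monthly_stat(slice_year(cube, "tmin", ti))
  tmax <- monthly_stat(slice_year(cube, "tmax", ti))
  prec <- monthly_stat(slice_year(cube, "precip", ti), fun = rowSums)
  qm <- quarter_months()
  n <- nrow(tavg)
  qtemp <- matrix(vapply(seq_len(12),
                         function(q) rowMeans(tavg[, qm[q, ], drop = FALSE]),
                         numeric(n)), n, 12L)
  qprec <- matrix(vapply(seq_len(12),
                         function(q) rowSums(prec[, qm[q, ], drop = FALSE]),
                         numeric(n)), n, 12L)
  pick <- function(values, by, which = c("max", "min")) {
    which <- match.arg(which)
    idx <- if (which == "max") max.col(by, ties.method = "first")
    else max.col(-by, ties.method = "first")
    values[cbind(seq_len(nrow(values)), idx)]
  }
  b <- matrix(NA_real_, n, 19, dimnames = list(NULL, paste0("BIO", 1:19)))
  b[, "BIO1"] <- rowMeans(tavg)
  b[, "BIO2"] <- rowMeans(tmax - tmin)
  b[, "BIO4"] <- 100 * apply(tavg, 1, sd)
  b[, "BIO5"] <- apply(tmax, 1, max)
  b[, "BIO6"] <- apply(tmin, 1, min)
  b[, "BIO7"] <- b[, "BIO5"] - b[, "BIO6"]
  zero7 <- b[, "BIO7"] <= 0
  b[, "BIO3"] <- ifelse(zero7, 0, 100 * b[, "BIO2"] / b[, "BIO7"])
  if (any(zero7))
    warning("BIO7 = 0 in ", sum(zero7), " cells; BIO3 set to 0 there")
  b[, "BIO8"] <- pick(qtemp, qprec, "max")
  b[, "BIO9"] <- pick(qtemp, qprec, "min")
  b[, "BIO10"] <- apply(qtemp, 1, max)
  b[, "BIO11"] <- apply(qtemp, 1, min)
  b[, "BIO12"] <- rowSums(prec)
  b[, "BIO13"] <- apply(prec, 1, max)
  b[, "BIO14"] <- apply(prec, 1, min)
  b[, "BIO15"] <- 100 * apply(prec, 1, sd) / (1 + b[, "BIO12"] / 12)
  b[, "BIO16"] <- apply(qprec, 1, max)
  b[, "BIO17"] <- apply(qprec, 1, min)
  b[, "BIO18"] <- pick(qprec, qtemp, "max")
  b[, "BIO19"] <- pick(qprec, qtemp, "min")
  b
}

#' Default extreme-variable threshold registry
#'
#' 18 extreme variables: the number of days (ND) and the longest consecutive
#' run (LP) per year for which a daily variable satisfies a threshold. Covers
#' cold thresholds (mean/max/min temperature below 0 degrees C), heat
#' thresholds (tmax above 30/35, tmin above 20), dry days (precip below 1 mm)
#' and wet days (precip above 20 and 10 mm). `EXV15` is the longest period of
#' precipitation > 20 mm. Fully user-overridable: supply any data.frame with
#' the same columns.
#'
#' @return data.frame with columns `name`, `variable`, `comparator`,
#'   `threshold`, `statistic`.
#' @export
default_threshold_registry <- function() {
  reg <- rbind(
    data.frame(variable = "tmean", comparator = "<", threshold = 0, statistic = c("ND", "LP")),
    data.frame(variable = "tmax", comparator = "<", threshold = 0, statistic = c("ND", "LP")),
    data.frame(variable = "tmin", comparator = "<", threshold = 0, statistic = c("ND", "LP")),
    data.frame(variable = "tmax", comparator = ">", threshold = 30, statistic = c("ND", "LP")),
    data.frame(variable = "tmax", comparator = ">", threshold = 35, statistic = c("ND", "LP")),
    data.frame(variable = "tmin", comparator = ">", threshold = 20, statistic = c("ND", "LP")),
    data.frame(variable = "precip", comparator = "<", threshold = 1, statistic = c("ND", "LP")),
    data.frame(variable = "precip", comparator = ">", threshold = 20, statistic = c("LP", "ND")),
    data.frame(variable = "precip", comparator = ">", threshold = 10, statistic = c("ND", "LP"))
  )
  reg$name <- sprintf("EXV%02d", seq_len(nrow(reg)))
  reg[, c("name", "variable", "comparator", "threshold", "statistic")]
}

#' Compute extreme-threshold variables for one calendar year
#'
#' Per cell and registry entry: `ND` counts qualifying days within the year,
#' `LP` is the length of the longest consecutive qualifying run. Runs never
#' wrap across calendar years.
#'
#' @param cube a climate cube.
#' @param year calendar year.
#' @param registry threshold registry, see [default_threshold_registry()].
#' @return numeric matrix `n_cells x nrow(registry)` named by registry entry.
#' @export
compute_exvs <- function(cube, year, registry = default_threshold_registry()) {
  ti <- year_index(cube, year)
  if (anyDuplicated(registry$name)) stop("registry names must be unique")
  out <- matrix(NA_real_, dim(cube$tmean)[1], nrow(registry),
                dimnames = list(NULL, registry$name))
  for (i in seq_len(nrow(registry))) {
    v <- registry$variable[i]
    if (!v %in% c("tmean", "tmin", "tmax", "precip"))
      stop("unknown variable in registry: ", v)
    daily <- slice_year(cube, v, ti)
    q <- switch(registry$comparator[i],
                "<" = daily < registry$threshold[i],
                ">" = daily > registry$threshold[i],
                stop("unknown comparator: ", registry$comparator[i]))
    out[, i] <- switch(registry$statistic[i],
                       ND = rowSums(q),
                       LP = longest_run_rows(q),
                       stop("unknown statistic: ", registry$statistic[i]))
  }
  out
}

#' Annual-mean absolute humidity from dewpoint
#'
#' Daily absolute humidity (g/m3) from the Magnus saturation vapour pressure
#' at the dewpoint and the ideal gas law at the air temperature,
#' `AH = 216.7 * e(Td) / (tmean + 273.15)` with
#' `e = 6.112 * exp(17.67 Td / (Td + 243.5))` hPa, averaged over the year.
#'
#' @param cube a climate cube with a `dewpoint` component.
#' @param year calendar year.
#' @return numeric vector of length `n_cells`.
#' @export
compute_ahum <- function(cube, year) {
  if (is.null(cube$dewpoint)) stop("cube has no dewpoint field")
  ti <- year_index(cube, year)
  td <- slice_year(cube, "dewpoint", ti)
  e <- 6.112 * exp(17.67 * td / (td + 243.5))
  ah <- 216.7 * e / (slice_year(cube, "tmean", ti) + 273.15)
  rowMeans(ah)
}

annual_climate_predictors <- function(cube, year, registry) {
  cbind(compute_bios(cube, year),
        compute_exvs(cube, year, registry),
        AHUM = compute_ahum(cube, year))
}

#' Assemble the climatological predictor stack for a target year
#'
#' Climate predictors (BIOs, EXVs, AHUM) are computed per year and averaged
#' arithmetically over the 31-year window ending at the target year (e.g. a
#' 2020 stack uses 1990-2020). Land-use class fractions enter for the target
#' year only.
#'
#' @param cube a climate cube covering `(target_year - window + 1):target_year`.
#' @param landuse a [generate_landuse()] stack covering `target_year`.
#' @param target_year the year of interest (last year of the window).
#' @param registry extreme-variable registry.
#' @param window climatological window length in years (default 31).
#' @return a [predictor_stack()].
#' @export
climatological_stack <- function(cube, landuse, target_year,
                                 registry = default_threshold_registry(),
                                 window = 31) {
  win_years <- (target_year - window + 1):target_year
  missing_y <- setdiff(win_years, cube$years)
  if (length(missing_y))
    stop("climate cube does not cover window years: ",
         paste(range(missing_y), collapse = "-"))
  if (!target_year %in% landuse$years)
    stop("land-use stack does not cover target year ", target_year)
  acc <- NULL
  for (y in win_years) {
    a <- annual_climate_predictors(cube, y, registry)
    acc <- if (is.null(acc)) a else acc + a
  }
  clim <- acc / length(win_years)
  lu <- landuse$frac[, , match(target_year, landuse$years)]
  colnames(lu) <- landuse$classes
  values <- cbind(clim, lu)
  subgroup <- c(rep("BIO", 19), rep("EXV", nrow(registry)), "AHUM",
                landuse$classes)
  units <- c(rep("degC/mm", 19), rep("days", nrow(registry)), "g/m3",
             rep("fraction", length(landuse$classes)))
  meta <- stack_meta_row(
    name = colnames(values),
    group = c(rep("climate", ncol(clim)), rep("landuse", ncol(lu))),
    subgroup = subgroup, units = units, target_year = target_year,
    window_length = c(rep(window, ncol(clim)), rep(NA_integer_, ncol(lu))))
  predictor_stack(cube$grid, values, meta)
}
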