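#' Project constant- and varying-land-use scenarios
#'
#' REF is the binarized prediction on the reference-year stack. For every
#' year, VLU uses the full year stack while CLU combines the year's climate
#' predictors with the reference year's land-use predictors, isolating the
#' climate effect. Predictions are binarized at `threshold` (typically the
#' model's max-TSS threshold).
#'
#' @param model a `brt_model`.
#' @param stacks named list of per-year [predictor_stack()]s (names years).
#' @param reference_year reference year present in `stacks`.
#' @param threshold binarization threshold for predictions.
#' @param mask optional sea mask.
#' @return object of class `scenario_run` with binary matrices `clu`, `vlu`
#'   (`n_cells x n_years`), vector `ref`, `years`, `threshold`.
#' @export
project_scenarios <- function(model, stacks, reference_year, threshold,
                              mask = NULL) {
  years <- as.integer(names(stacks))
  if (!reference_year %in% years)
    stop("reference year ", reference_year, " missing from stacks")
  ref_stack <- stacks[[as.character(reference_year)]]
  binp <- function(stack_values) {
    p <- predict(model, stack_values)
    b <- as.integer(p >= threshold)
    if (!is.null(mask)) b[mask] <- NA_integer_
    b
  }
  lu_cols <- stack_predictors(ref_stack, "landuse")
  ref <- binp(ref_stack$values)
  n <- length(ref)
  clu <- matrix(NA_integer_, n, length(years))
  vlu <- matrix(NA_integer_, n, length(years))
  for (t in seq_along(years)) {
    sv <- stacks[[t]]$values
    vlu[, t] <- binp(sv)
    hybrid <- sv
    hybrid[, lu_cols] <- ref_stack$values[, lu_cols]
    clu[, t] <- binp(hybrid)
  }
  structure(list(ref = ref, clu = clu, vlu = vlu, years = years,
                 reference_year = reference_year, threshold = threshold,
                 grid = ref_stack$grid),
            class = "scenario_run")
}

#' The eight change categories
#'
#' Mapping of (REF, CLU, VLU) presence triples to categories: `P` present
#' throughout, `A` absent throughout, `PCC`/`ACC` change to present/absent
#' due to climate change, `PLUC`/`ALUC` change to present/absent due to
#' land-use change, `RPLUC`/`RALUC` remaining present/absent due to land-use
#' change (land-use offsets a climate-driven flip).
#'
#' @return character vector of the 8 category codes.
#' @export
change_categories <- function()
  c("P", "A", "PCC", "ACC", "PLUC", "ALUC", "RPLUC", "RALUC")

category_lookup <- function() {
  # index by 1 + 4*REF + 2*CLU + VLU
  lut <- character(8)
  lut[1 + 4 * 1 + 2 * 1 + 1] <- "P"     # (1,1,1)
  lut[1 + 4 * 0 + 2 * 0 + 0] <- "A"     # (0,0,0)
  lut[1 + 4 * 0 + 2 * 1 + 1] <- "PCC"   # (0,1,1)
  lut[1 + 4 * 1 + 2 * 0 + 0] <- "ACC"   # (1,0,0)
  lut[1 + 4 * 0 + 2 * 0 + 1] <- "PLUC"  # (0,0,1)
  lut[1 + 4 * 1 + 2 * 1 + 0] <- "ALUC"  # (1,1,0)
  lut[1 + 4 * 1 + 2 * 0 + 1] <- "RPLUC" # (1,0,1)
  lut[1 + 4 * 0 + 2 * 1 + 0] <- "RALUC" # (0,1,0)
  lut
}

#' Classify per-cell habitat changes for one year
#'
#' @param run a [project_scenarios()] result.
#' @param year a year contained in the run.
#' @return factor vector over [change_categories()], `NA` on masked cells.
#' @export
classify_change <- function(run, year) {
  t <- match(year, run$years)
  if (is.na(t)) stop("year ", year, " not in scenario run")
  code <- 1 + 4 * run$ref + 2 * run$clu[, t] + run$vlu[, t]
  factor(category_lookup()[code], levels = change_categories())
}

#' Habitat suitability area time series
#'
#' HSA is the count of suitable cells; percent change is computed against
#' the reference-year HSA of the (varying-land-use) run, which always
#' represents 100%.
#'
#' @param run a [project_scenarios()] result.
#' @return data.frame of class `hsa_series` with `year`, `hsa`,
#'   `pct_change`.
#' @export
hsa_timeseries <- function(run) {
  ref_hsa <- sum(run$ref, na.rm = TRUE)
  if (ref_hsa == 0) stop("empty reference HSA")
  hsa <- colSums(run$vlu, na.rm = TRUE)
  out <- data.frame(year = run$years, hsa = hsa,
                    pct_change = 100 * (hsa - ref_hsa) / ref_hsa)
  class(out) <- c("hsa_series", class(out))
  out
}

#' Climate- versus land-use-change attribution summary
#'
#' Category counts as percentages of the reference HSA: climate gain (PCC)
#' and loss (ACC), land-use gain (PLUC) and loss (ALUC), their nets, and the
#' overall net change. Retention effects (RPLUC/RALUC) leave the net change
#' unchanged (status equals REF) and are reported separately.
#'
#' @param change a [classify_change()] factor.
#' @param ref_hsa reference-year HSA (cell count).
#' @return one-row data.frame with percent fields.
#' @export
attribution_summary <- function(change, ref_hsa) {
  stopifnot(ref_hsa > 0)
  cnt <- table(change)
  pct <- function(k) 100 * as.numeric(cnt[k]) / ref_hsa
  out <- data.frame(
    climate_gain = pct("PCC"), climate_loss = pct("ACC"),
    landuse_gain = pct("PLUC"), landuse_loss = pct("ALUC"),
    retained_present = pct("RPLUC"), retained_absent = pct("RALUC"))
  out$net_climate <- out$climate_gain - out$climate_loss
  out$net_landuse <- out$landuse_gain - out$landuse_loss
  out$overall <- out$net_climate + out$net_landuse
  out
}
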