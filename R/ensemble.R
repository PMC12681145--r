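#' The four within-model predictor selection methods
#' @return character vector `c("I", "II", "III", "IV")`.
#' @export
predictor_methods <- function() c("I", "II", "III", "IV")

#' Apply a predictor selection method to a fitted full model
#'
#' \describe{
#'   \item{I}{all predictors (identity).}
#'   \item{II}{[simplify()]'s survivors.}
#'   \item{III}{climate predictors kept when contribution > 1 OR their
#'     interaction sum exceeds twice the median of the climate predictors'
#'     interaction sums; land-use predictors pass through untouched.}
#'   \item{IV}{method III, then correlated climate pairs
#'     (`|Pearson r| > 0.7` on the calibration sample) pruned keeping the
#'     higher-contribution member.}
#' }
#'
#' @param method one of [predictor_methods()].
#' @param model tuned full-predictor `brt_model` (required for II-IV).
#' @param sample calibration sample (for method IV's correlations).
#' @param stack a [predictor_stack()] supplying the climate/landuse grouping.
#' @param inter optional precomputed [interactions()] result.
#' @param assess_folds,n_candidates passed to [simplify()] for method II.
#' @return character vector of surviving predictor names.
#' @export
select_predictors <- function(method, model, sample = model$sample,
                              stack = NULL, inter = NULL,
                              assess_folds = NULL, n_candidates = 2) {
  method <- match.arg(method, predictor_methods())
  preds <- model$predictors
  if (method == "I") return(preds)
  if (method == "II") return(simplify(model, assess_folds = assess_folds,
                                      n_candidates = n_candidates))
  if (is.null(stack)) stop("methods III/IV need the stack for grouping")
  climate <- intersect(preds, stack_predictors(stack, "climate"))
  landuse <- intersect(preds, stack_predictors(stack, "landuse"))
  contr <- contributions(model)
  if (is.null(inter)) inter <- interactions(model)
  isum <- inter$sums[climate]
  keep_cl <- climate[contr[climate] > 1 | isum > 2 * median(isum)]
  if (method == "IV" && length(keep_cl) > 1) {
    X <- sample$X[, keep_cl, drop = FALSE]
    repeat {
      r <- cor(X)
      diag(r) <- 0
      if (all(abs(r) <= 0.7)) break
      ij <- which(abs(r) == max(abs(r)), arr.ind = TRUE)[1, ]
      pair <- colnames(r)[ij]
      drop <- pair[which.min(contr[pair])]
      keep_cl <- setdiff(keep_cl, drop)
      X <- X[, keep_cl, drop = FALSE]
      if (length(keep_cl) < 2) break
    }
  }
  out <- c(keep_cl, landuse)
  if (length(out) < 2)
    stop("predictor selection method ", method,
         " left fewer than 2 predictors; model would be unfittable")
  out
}

#' Ensemble run configuration
#'
#' @param n_presence,n_absence nominal sample sizes per background method.
#' @param brt a [brt_config()].
#' @param seed master seed; per-setup seeds are derived from it.
#' @param background subset of [background_methods()].
#' @param predictor_selection subset of [predictor_methods()].
#' @param oms_variant see [oms()].
#' @param simplify_assess_folds fold indices used by [simplify()]'s drop
#'   assessment inside the ensemble (a runtime lever; reduced models are
#'   re-tuned on the full fold set).
#' @param warm_start start re-tunes of reduced predictor sets from the full
#'   model's tuned learning rate and tree complexity instead of the
#'   configured initial values (the tuning loop still enforces the tree
#'   window).
#' @export
ensemble_config <- function(n_presence = 10000, n_absence = 10000,
                            brt = brt_config(), seed = 1,
                            background = background_methods(),
                            predictor_selection = predictor_methods(),
                            oms_variant = "four",
                            simplify_assess_folds = c(1, 4, 7, 10),
                            warm_start = TRUE) {
  list(n_presence = n_presence, n_absence = n_absence, brt = brt,
       seed = seed, background = background,
       predictor_selection = predictor_selection,
       oms_variant = oms_variant,
       simplify_assess_folds = simplify_assess_folds,
       warm_start = warm_start)
}

#' Run the background x predictor-selection model ensemble
#'
#' For every background method: draw a calibration sample, split 50/50 into
#' calibration and held-out evaluation halves, tune a full-predictor model,
#' then for each predictor-selection method reduce the predictor set,
#' re-tune, evaluate skills, and project constant-land-use (CLU) and
#' varying-land-use (VLU) scenarios over all years, binarized at the
#' member's max-TSS threshold. With the default four methods each way this
#' yields the 16 model setups. Failed setups are flagged and logged;
#' ensemble quantiles are computed over the survivors.
#'
#' @param map reference-year species probability map (carries the sea mask
#'   as `NA` cells).
#' @param stacks named list of [predictor_stack()]s, names are years; must
#'   include the reference year.
#' @param reference_year the reference (first) year.
#' @param config an [ensemble_config()].
#' @return object of class `ensemble_result`: `members` (per-setup list with
#'   model, skill, scenario run, HSA series), `quantiles` (per-year 5/25/50/
#'   75/95 percentiles of HSA percent change), `best` (setup id), `setups`.
#' @export
run_ensemble <- function(map, stacks, reference_year, config = ensemble_config()) {
  years <- as.integer(names(stacks))
  stopifnot(reference_year %in% years)
  ref_stack <- stacks[[as.character(reference_year)]]
  mask <- is.na(map$prob)
  setups <- expand.grid(background = config$background,
                        predictor_selection = config$predictor_selection,
                        stringsAsFactors = FALSE)
  setups$id <- seq_len(nrow(setups))
  members <- vector("list", nrow(setups))
  for (bg in config$background) {
    res <- try({
      smp <- select_background(map, ref_stack, bg, config$n_presence,
                               config$n_absence,
                               derive_seed(config$seed, "sample", bg))
      halves <- split_sample(smp, derive_seed(config$seed, "split", bg))
      cfg_bg <- config$brt
      cfg_bg$seed <- derive_seed(config$seed, "tune", bg)
      full <- tune(halves$calib, colnames(smp$X), cfg_bg)
      inter_full <- interactions(full)
      list(halves = halves, full = full, inter = inter_full)
    }, silent = TRUE)
    for (pm in config$predictor_selection) {
      sid <- setups$id[setups$background == bg &
                         setups$predictor_selection == pm]
      if (inherits(res, "try-error")) {
        members[[sid]] <- list(ok = FALSE, error = as.character(res))
        next
      }
      members[[sid]] <- try({
        preds <- select_predictors(pm, res$full, res$halves$calib,
                                   ref_stack, res$inter,
                                   assess_folds =
                                     intersect(config$simplify_assess_folds,
                                               seq_len(max(res$full$folds))),
                                   n_candidates = 1)
        model <- if (pm == "I") res$full else {
          cfg_pm <- config$brt
          cfg_pm$seed <- derive_seed(config$seed, "tune", bg, pm)
          if (isTRUE(config$warm_start)) {
            cfg_pm$learning_rate <- res$full$learning_rate
            cfg_pm$tree_complexity <- res$full$tree_complexity
          }
          tune(res$halves$calib, preds, cfg_pm)
        }
        skill <- skill_report(model, res$halves$eval, ref_stack, mask = mask,
                              oms_variant = config$oms_variant)
        run <- project_scenarios(model, stacks, reference_year,
                                 skill$tss_max_threshold, mask = mask)
        list(ok = TRUE, id = sid, background = bg, predictor_selection = pm,
             predictors = preds, model = model, skill = skill, run = run,
             hsa = hsa_timeseries(run))
      }, silent = TRUE)
      if (inherits(members[[sid]], "try-error")) {
        members[[sid]] <- list(ok = FALSE,
                               error = as.character(members[[sid]]))
        warning("setup ", sid, " (", bg, "/", pm, ") failed: ",
                members[[sid]]$error)
      }
    }
  }
  ok <- vapply(members, function(m) isTRUE(m$ok), logical(1))
  qs <- NULL
  if (any(ok)) {
    series <- vapply(members[ok], function(m) m$hsa$pct_change,
                     numeric(length(years)))
    qs <- data.frame(year = years,
                     t(apply(series, 1, quantile,
                             probs = c(0.05, 0.25, 0.5, 0.75, 0.95))))
    names(qs) <- c("year", "q05", "q25", "q50", "q75", "q95")
  }
  out <- structure(list(members = members, setups = setups, quantiles = qs,
                        years = years, reference_year = reference_year),
                   class = "ensemble_result")
  out$best <- if (any(ok)) pick_best(out) else NA_integer_
  out
}

#' Pick the best ensemble member by composite SCORE
#'
#' Ties break by higher AoA, then by lower setup id. Errors if every member
#' is flagged.
#'
#' @param result an `ensemble_result`, or a list of skill reports.
#' @return the winning setup id.
#' @export
pick_best <- function(result) {
  members <- if (inherits(result, "ensemble_result")) result$members
  else result
  ok <- vapply(members, function(m) isTRUE(m$ok %||% TRUE) &&
                 !is.null(m$skill), logical(1))
  if (!any(ok)) stop("all ensemble members failed")
  score <- vapply(members, function(m) if (is.null(m$skill)) -Inf
                  else m$skill$SCORE, numeric(1))
  aoa_v <- vapply(members, function(m) if (is.null(m$skill)) -Inf
                  else m$skill$AoA, numeric(1))
  ids <- vapply(seq_along(members),
                function(i) members[[i]]$id %||% i, numeric(1))
  ord <- order(-score, -aoa_v, ids)
  ids[ord[1]]
}

#' @export
print.ensemble_result <- function(x, ...) {
  ok <- sum(vapply(x$members, function(m) isTRUE(m$ok), logical(1)))
  cat(sprintf("ensemble_result: %d/%d setups ok, best setup %s\n",
              ok, length(x$members), x$best))
  invisible(x)
}
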