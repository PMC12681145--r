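#' Ground-truth suitability specification
#'
#' Defines the generative logistic suitability model behind a synthetic
#' species probability map: a set of predictor response functions (bounded
#' unimodal "gaussian" bumps or "logistic" ramps) combined additively on the
#' link scale with an intercept. Used both to generate maps and as the known
#' truth for parameter-recovery tests.
#'
#' @param responses named list; each element is a list with `type`
#'   (`"gaussian"` or `"logistic"`) and parameters: `a` (amplitude on the link
#'   scale), `mu` (centre/location), `s` (width/scale). Names are predictor
#'   names and must include at least 2 climate and 1 land-use predictor for
#'   the default world.
#' @param intercept link-scale intercept.
#' @return object of class `truth_spec`.
#' @export
truth_spec <- function(responses, intercept = 0) {
  stopifnot(length(responses) >= 1, !is.null(names(responses)))
  for (r in responses)
    stopifnot(r$type %in% c("gaussian", "logistic"),
              is.finite(r$a), is.finite(r$mu), is.finite(r$s), r$s > 0)
  structure(list(responses = responses, intercept = intercept),
            class = "truth_spec")
}

#' Default ground truth for the synthetic world
#'
#' Mean annual temperature (BIO1) acts through a unimodal optimum near a
#' warm-temperate 15 degrees C, annual precipitation (BIO12) through a
#' saturating increasing ramp, and the urban land-use fraction through an
#' increasing ramp (anthropophilic species). Amplitudes are on the logit
#' scale.
#'
#' @return a [truth_spec()].
#' @export
default_truth <- function() {
  truth_spec(
    responses = list(
      BIO1 = list(type = "gaussian", a = 6, mu = 15, s = 4),
      BIO12 = list(type = "logistic", a = 4, mu = 500, s = 150),
      urban = list(type = "logistic", a = 2, mu = 0.08, s = 0.04)
    ),
    intercept = -6
  )
}

# link-scale contribution of each truth predictor, n_cells x n_pred
truth_response_matrix <- function(truth, stack) {
  miss <- setdiff(names(truth$responses), colnames(stack$values))
  if (length(miss))
    stop("truth predictors missing from stack: ", paste(miss, collapse = ", "))
  vapply(names(truth$responses), function(nm) {
    r <- truth$responses[[nm]]
    x <- stack$values[, nm]
    switch(r$type,
           gaussian = r$a * exp(-(x - r$mu)^2 / (2 * r$s^2)),
           logistic = r$a * plogis((x - r$mu) / r$s))
  }, numeric(nrow(stack$values)))
}

#' Generate a species presence-probability map from a known truth
#'
#' `probability = plogis(intercept + sum of responses + noise)`. Values below
#' `zero_floor` are truncated to exactly 0 (outside-range areas of real
#' probability-of-presence rasters are exact zeros, which the buffered
#' background selection relies on). Sea cells become `NA`.
#'
#' @param stack a [predictor_stack()] holding all truth predictors.
#' @param truth a [truth_spec()].
#' @param noise_sd link-scale Gaussian noise standard deviation.
#' @param seed master seed (used only when `noise_sd > 0`).
#' @param mask logical sea mask (length `n_cells`) or `NULL` for none.
#' @param zero_floor probabilities strictly below this are set to 0.
#' @return object of class `species_map`: list with `grid` and `prob`.
#' @export
generate_species_map <- function(stack, truth, noise_sd = 0, seed = 1,
                                 mask = NULL, zero_floor = 0.05) {
  eta <- truth$intercept + rowSums(truth_response_matrix(truth, stack))
  if (noise_sd > 0)
    eta <- eta + with_seed(derive_seed(seed, "speciesmap"),
                           rnorm(length(eta), 0, noise_sd))
  p <- plogis(eta)
  p[p < zero_floor] <- 0
  if (!is.null(mask)) {
    stopifnot(length(mask) == length(p))
    p[mask] <- NA_real_
  }
  structure(list(grid = stack$grid, prob = p), class = "species_map")
}

#' @export
print.species_map <- function(x, ...) {
  cat(sprintf("species_map: %d cells (%d masked), presence fraction %.2f\n",
              length(x$prob), sum(is.na(x$prob)),
              mean(x$prob >= 0.5, na.rm = TRUE)))
  invisible(x)
}

#' Calibrate the truth intercept so both classes are populous
#'
#' Bisects the intercept until the fraction of unmasked cells with
#' probability >= 0.5 lands at `target` (default 0.4, comfortably inside the
#' 0.2-0.6 band the generator promises).
#'
#' @param truth a [truth_spec()].
#' @param stack a [predictor_stack()].
#' @param mask optional sea mask.
#' @param target desired presence fraction.
#' @return the truth with an adjusted intercept.
#' @export
calibrate_truth <- function(truth, stack, mask = NULL, target = 0.4) {
  resp <- rowSums(truth_response_matrix(truth, stack))
  if (!is.null(mask)) resp <- resp[!mask]
  frac <- function(b) mean(plogis(b + resp) >= 0.5)
  lo <- -50; hi <- 50
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (frac(mid) < target) lo <- mid else hi <- mid
  }
  truth$intercept <- (lo + hi) / 2
  truth
}
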