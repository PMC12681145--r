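#' Response difference between two predictor values on a response curve
#'
#' Linearly interpolates the curve at the year-of-interest and reference
#' values and returns `f(x_now) - f(x_ref)`; values outside the curve's grid
#' clamp to the end responses.
#'
#' @param curve a [response_curve()].
#' @param x_ref,x_now predictor values at the reference year and the year of
#'   interest.
#' @return signed response delta (probability scale).
#' @export
response_range <- function(curve, x_ref, x_now) {
  f <- curve_interp(curve)
  f(x_now) - f(x_ref)
}

# interpolator that tolerates degenerate (constant-x) curves
curve_interp <- function(curve) {
  ux <- unique(curve$x)
  if (length(ux) < 2) {
    y0 <- mean(curve$y)
    return(function(x) rep(y0, length(x)))
  }
  function(x) approx(curve$x, curve$y, xout = x, rule = 2)$y
}

feature_scale <- function(x, degenerate = 1) {
  rng <- range(x)
  if (diff(rng) < 1e-300) return(rep(degenerate, length(x)))
  (x - rng[1]) / diff(rng)
}

mip_scores <- function(contr, int_sums, r_n) {
  con_n <- feature_scale(contr, degenerate = 1)
  int_n <- feature_scale(int_sums, degenerate = 0)
  weight <- con_n + con_n * int_n
  sweep(r_n, 2, weight, "*")
}

pick_winners <- function(scores, con_n, preds) {
  n <- nrow(scores)
  winner <- rep(NA_character_, n)
  importance <- rep(NA_real_, n)
  pos <- scores > 0
  any_pos <- rowSums(pos) > 0
  if (any(any_pos)) {
    # argmax with ties broken by higher CON_N then lexicographic name
    ord <- order(-con_n, preds)
    sc <- scores[, ord, drop = FALSE]
    wi <- max.col(sc, ties.method = "first")
    tot <- rowSums(sc * (sc > 0))
    winner[any_pos] <- preds[ord][wi[any_pos]]
    best <- sc[cbind(seq_len(n), wi)]
    importance[any_pos] <- 100 * best[any_pos] / tot[any_pos]
  }
  list(winner = winner, importance = importance)
}

#' Most important predictor per grid cell
#'
#' Per-predictor score at each cell: `(CON_N + CON_N * INT_N) * R_N`, where
#' CON_N and INT_N are the model's contributions and interaction sums
#' feature-scaled across the supplied predictors (per model scalars) and
#' R_N is the absolute response delta feature-scaled jointly across all
#' cells and predictors. The winner is the argmax (ties: higher CON_N, then
#' name); the importance percent divides the winning score by the sum of all
#' strictly positive scores at that cell. Cells whose scores are all zero
#' (no observed change, or no important predictor) carry `NA` ("no MIP").
#' Analyze climate-related and land-use-related predictors separately by
#' restricting the inputs to one group.
#'
#' @param contr named contributions (percent) of the group's predictors.
#' @param int_sums named per-predictor interaction sums (same names).
#' @param resp_delta matrix `n_cells x n_predictors` of signed response
#'   deltas (year-of-interest minus reference on the response curves).
#' @return list of class `mip_record`: `winner` (character, `NA` = no MIP),
#'   `importance` (percent), and the normalized terms.
#' @export
compute_mip <- function(contr, int_sums, resp_delta) {
  preds <- names(contr)
  if (!length(preds)) stop("empty predictor group")
  stopifnot(identical(preds, names(int_sums)),
            identical(preds, colnames(resp_delta)))
  # joint scaling across cells x predictors, anchored at zero so that a
  # zero response change scores exactly zero (and only then)
  dmax <- max(abs(resp_delta))
  r_n <- if (dmax > 0) abs(resp_delta) / dmax else resp_delta * 0
  scores <- mip_scores(contr, int_sums, r_n)
  con_n <- feature_scale(contr, degenerate = 1)
  w <- pick_winners(scores, con_n, preds)
  structure(list(winner = w$winner, importance = w$importance,
                 scores = scores, con_n = con_n,
                 int_n = feature_scale(int_sums, degenerate = 0),
                 resp_delta = resp_delta),
            class = "mip_record")
}

#' Most important predictor for change, sign-filtered by category
#'
#' As [compute_mip()], but at cells in presence-gaining categories (PCC,
#' PLUC, RPLUC) only predictors with a positive response delta compete, and
#' in absence-gaining categories (ACC, ALUC, RALUC) only negative ones;
#' stable cells (P, A) rank unsigned exactly as the MIP does. Cells whose
#' candidate set is empty carry `NA` ("no MIPC").
#'
#' @inheritParams compute_mip
#' @param change a [classify_change()] factor aligned to the rows.
#' @return a `mip_record`.
#' @export
compute_mipc <- function(contr, int_sums, resp_delta, change) {
  rec <- compute_mip(contr, int_sums, resp_delta)
  gain <- change %in% c("PCC", "PLUC", "RPLUC")
  loss <- change %in% c("ACC", "ALUC", "RALUC")
  scores <- rec$scores
  if (any(gain)) {
    sg <- scores[gain, , drop = FALSE]
    sg[resp_delta[gain, , drop = FALSE] <= 0] <- 0
    scores[gain, ] <- sg
  }
  if (any(loss)) {
    sl <- scores[loss, , drop = FALSE]
    sl[resp_delta[loss, , drop = FALSE] >= 0] <- 0
    scores[loss, ] <- sl
  }
  w <- pick_winners(scores, rec$con_n, names(contr))
  rec$winner <- w$winner
  rec$importance <- w$importance
  rec$scores <- scores
  rec
}

#' Category-level MIP(C) summary table
#'
#' For each change category: the modal winning predictor, the percentage of
#' the category's cells it wins, and the mean raw predictor change and mean
#' response delta of that predictor over those cells. Empty categories are
#' omitted (with a message).
#'
#' @param record a [compute_mip()] / [compute_mipc()] record.
#' @param change a [classify_change()] factor.
#' @param pred_delta matrix `n_cells x n_predictors` of raw predictor
#'   changes (year of interest minus reference).
#' @return data.frame with one row per non-empty category.
#' @export
mip_summary <- function(record, change, pred_delta) {
  rows <- list()
  for (cat in change_categories()) {
    in_cat <- which(!is.na(change) & change == cat)
    if (!length(in_cat)) {
      message("mip_summary: category ", cat, " empty; row omitted")
      next
    }
    wn <- record$winner[in_cat]
    if (all(is.na(wn))) {
      message("mip_summary: no MIP winners in category ", cat,
              "; row omitted")
      next
    }
    tab <- sort(table(wn), decreasing = TRUE)
    modal <- names(tab)[1]
    cells <- in_cat[!is.na(wn) & wn == modal]
    rows[[cat]] <- data.frame(
      category = cat, mip = modal,
      fraction_pct = 100 * length(cells) / length(in_cat),
      mean_delta = mean(pred_delta[cells, modal]),
      mean_delta_res = mean(record$resp_delta[cells, modal]))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Per-cell response deltas of a model between two stacks
#'
#' Convenience builder for [compute_mip()]: evaluates each predictor's
#' response curve at the reference and year-of-interest values per cell.
#'
#' @param model a `brt_model`.
#' @param stack_ref,stack_now reference and year-of-interest stacks.
#' @param predictors predictors to evaluate (default: model predictors).
#' @param n_points response-curve resolution.
#' @return list with matrices `resp_delta` and `pred_delta`
#'   (`n_cells x n_predictors`).
#' @export
response_deltas <- function(model, stack_ref, stack_now,
                            predictors = model$predictors, n_points = 100) {
  n <- nrow(stack_ref$values)
  rd <- matrix(0, n, length(predictors),
               dimnames = list(NULL, predictors))
  pd <- rd
  for (p in predictors) {
    curve <- response_curve(model, p, n_points)
    x0 <- stack_ref$values[, p]
    x1 <- stack_now$values[, p]
    f <- curve_interp(curve)
    rd[, p] <- f(x1) - f(x0)
    pd[, p] <- x1 - x0
  }
  list(resp_delta = rd, pred_delta = pd)
}
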