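check_two_classes <- function(labels) {
  if (length(unique(labels)) < 2)
    stop("both classes must be present in the evaluation set")
}

#' Threshold maximizing the True Skill Statistic
#'
#' Scans all unique prediction values as candidate thresholds (presence iff
#' prediction >= threshold) and returns the one maximizing
#' sensitivity + specificity - 1; ties resolve to the lowest threshold.
#'
#' @param labels 0/1 vector.
#' @param predictions probabilities.
#' @return the threshold value.
#' @export
max_tss_threshold <- function(labels, predictions) {
  check_two_classes(labels)
  np <- sum(labels == 1); nn <- sum(labels == 0)
  ord <- order(predictions)
  ys <- labels[ord]; ps <- predictions[ord]
  first <- which(!duplicated(ps)) # first index of each unique value, ascending
  cum1 <- cumsum(ys == 1); cum0 <- cumsum(ys == 0)
  below1 <- ifelse(first == 1, 0, cum1[pmax(first - 1, 1)]) # y=1, pred < thr
  below0 <- ifelse(first == 1, 0, cum0[pmax(first - 1, 1)])
  sens <- (np - below1) / np
  spec <- below0 / nn
  tssv <- sens + spec - 1
  best <- max(tssv)
  min(ps[first][tssv >= best - 1e-12])
}

#' True Skill Statistic at a threshold
#' @param labels 0/1 vector.
#' @param predictions probabilities.
#' @param threshold binarization threshold (prediction >= threshold is
#'   presence).
#' @return sensitivity + specificity - 1.
#' @export
tss <- function(labels, predictions, threshold) {
  check_two_classes(labels)
  pred <- predictions >= threshold
  sens <- mean(pred[labels == 1])
  spec <- mean(!pred[labels == 0])
  sens + spec - 1
}

#' Cohen's kappa at a threshold
#' @inheritParams tss
#' @export
cohen_kappa <- function(labels, predictions, threshold) {
  check_two_classes(labels)
  pred <- as.integer(predictions >= threshold)
  n <- length(labels)
  po <- mean(pred == labels)
  pe <- mean(pred == 1) * mean(labels == 1) + mean(pred == 0) * mean(labels == 0)
  (po - pe) / (1 - pe)
}

#' Area under the ROC curve (rank-based)
#' @param labels 0/1 vector.
#' @param predictions probabilities.
#' @return probability that a random presence outranks a random absence.
#' @export
auc <- function(labels, predictions) {
  check_two_classes(labels)
  r <- rank(predictions)
  np <- sum(labels == 1); nn <- sum(labels == 0)
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Brier skill score against the base-rate reference
#'
#' `1 - BS / BS_ref` where `BS` is the mean squared error of the predicted
#' probabilities and `BS_ref` that of the constant base-rate prediction,
#' floored at 0.
#'
#' @inheritParams auc
#' @export
brier_skill <- function(labels, predictions) {
  check_two_classes(labels)
  bs <- mean((predictions - labels)^2)
  base <- mean(labels)
  bs_ref <- mean((base - labels)^2)
  max(0, 1 - bs / bs_ref)
}

#' Remove spatial sorting bias by point-wise distance sampling
#'
#' For every test presence (processed in order of its distance to the
#' nearest calibration presence) the test absence with the most similar
#' such distance is paired with it, provided the two distances agree within
#' the tolerance factor (`|d_a - d_p| <= tol * d_p`). Unmatched points are
#' dropped. The SSB ratio (mean presence distance / mean absence distance)
#' of the kept pairs is closer to 1 than before.
#'
#' @param test_pres,test_abs data.frames with `lon`, `lat` for the held-out
#'   presences and absences.
#' @param calib_pres data.frame with `lon`, `lat` of calibration presences.
#' @param tol tolerance factor (default 0.33).
#' @return list with kept index vectors `pres_idx`, `abs_idx` (equal
#'   length) and `ssb_before`, `ssb_after`.
#' @export
remove_ssb <- function(test_pres, test_abs, calib_pres, tol = 0.33) {
  ndist <- function(pts) {
    vapply(seq_len(nrow(pts)), function(i) {
      min(gc_distance(pts$lon[i], pts$lat[i], calib_pres$lon,
                      calib_pres$lat))
    }, numeric(1))
  }
  dp <- ndist(test_pres)
  da <- ndist(test_abs)
  ssb_before <- mean(dp) / mean(da)
  avail <- rep(TRUE, length(da))
  pres_idx <- integer(0); abs_idx <- integer(0)
  for (i in order(dp)) {
    cand <- which(avail & abs(da - dp[i]) <= tol * pmax(dp[i], 1e-9))
    if (!length(cand)) next
    j <- cand[which.min(abs(da[cand] - dp[i]))]
    avail[j] <- FALSE
    pres_idx <- c(pres_idx, i)
    abs_idx <- c(abs_idx, j)
  }
  if (!length(pres_idx))
    stop("no presence/absence pairs matchable; increase the tolerance factor")
  list(pres_idx = pres_idx, abs_idx = abs_idx,
       ssb_before = ssb_before,
       ssb_after = mean(dp[pres_idx]) / mean(da[abs_idx]))
}

#' Overall model skill
#'
#' Average of TSS, feature-scaled SSB-corrected AUC, SSB-corrected kappa and
#' the Brier skill score. The AUC is rescaled from its chance floor of 0.5 to
#' `[0, 1]` (`(AUC - 0.5) / 0.5`, floored at 0). A three-metric variant
#' (without BSS) is available via `variant = "three"`.
#'
#' @param tss,auc_ssb_raw,ck_ssb,bss component skills.
#' @param variant `"four"` (default) or `"three"`.
#' @export
oms <- function(tss, auc_ssb_raw, ck_ssb, bss, variant = c("four", "three")) {
  variant <- match.arg(variant)
  auc_scaled <- pmax(0, (auc_ssb_raw - 0.5) / 0.5)
  if (variant == "four") (tss + auc_scaled + ck_ssb + bss) / 4
  else (tss + auc_scaled + ck_ssb) / 3
}

#' Composite model score from skill and transferability
#'
#' Euclidean distance of (OMS, AoA) from the origin, divided by sqrt(2) so a
#' perfect model scores 1. Symmetric and monotone increasing in both
#' arguments.
#'
#' @param oms_value overall model skill in `[0, 1]`.
#' @param aoa_value area of applicability in `[0, 1]`.
#' @export
composite_score <- function(oms_value, aoa_value) {
  sqrt(oms_value^2 + aoa_value^2) / sqrt(2)
}

weighted_std_coords <- function(X, center, scale, w) {
  sweep(sweep(X, 2, center), 2, scale / sqrt(pmax(w, 0)), "/")
}

min_cross_dist <- function(A, B, chunk = 2048L) {
  # per row of A, min Euclidean distance to rows of B
  nb2 <- rowSums(B^2)
  out <- numeric(nrow(A))
  for (s in seq(1, nrow(A), by = chunk)) {
    idx <- s:min(s + chunk - 1, nrow(A))
    d2 <- outer(rowSums(A[idx, , drop = FALSE]^2), nb2, "+") -
      2 * A[idx, , drop = FALSE] %*% t(B)
    out[idx] <- sqrt(pmax(0, apply(d2, 1, min)))
  }
  out
}

#' Area of applicability of a model over a prediction domain
#'
#' Dissimilarity index (DI) per cell: contribution-weighted, standardized
#' Euclidean distance in predictor space to the nearest calibration point,
#' divided by the mean pairwise distance among calibration points. The DI
#' threshold is Q3 + 1.5 IQR of cross-validated calibration DIs (each
#' calibration point against the points outside its fold). The AoA is the
#' fraction of (unmasked) cells with DI at or below the threshold.
#'
#' @param sample calibration sample (predictor matrix `X`).
#' @param stack prediction-domain [predictor_stack()].
#' @param contributions named percent contributions (weights are
#'   `contributions / 100`); predictors with zero weight drop out.
#' @param folds fold assignment for the threshold cross-validation; default
#'   10 pseudo-folds assigned round-robin.
#' @param mask optional logical sea mask on the stack's cells.
#' @return list with `aoa`, `di`, `threshold`, `inside`.
#' @export
aoa <- function(sample, stack, contributions, folds = NULL, mask = NULL) {
  preds <- names(contributions)[contributions > 0]
  if (length(preds) < 1) stop("no predictors with positive contribution")
  Xc <- sample$X[, preds, drop = FALSE]
  if (nrow(Xc) < 10) stop("need at least 10 calibration points")
  if (is.null(folds)) folds <- rep_len(1:10, nrow(Xc))
  w <- contributions[preds] / 100
  ctr <- colMeans(Xc)
  scl <- apply(Xc, 2, sd)
  scl[scl < 1e-12] <- 1
  A <- weighted_std_coords(Xc, ctr, scl, w)
  P <- weighted_std_coords(stack$values[, preds, drop = FALSE], ctr, scl, w)
  # mean pairwise calibration distance (subsampled above 1000 points)
  idx <- if (nrow(A) > 1000) round(seq(1, nrow(A), length.out = 1000)) else
    seq_len(nrow(A))
  dbar <- mean(dist(A[idx, , drop = FALSE]))
  if (dbar <= 0) stop("degenerate calibration sample (zero mean distance)")
  di_cell <- min_cross_dist(P, A) / dbar
  di_cv <- vapply(seq_len(nrow(A)), function(i) {
    other <- folds != folds[i]
    min_cross_dist(A[i, , drop = FALSE], A[other, , drop = FALSE])
  }, numeric(1)) / dbar
  thr <- quantile(di_cv, 0.75) + 1.5 * IQR(di_cv)
  keep <- if (is.null(mask)) rep(TRUE, length(di_cell)) else !mask
  inside <- di_cell <= thr
  list(aoa = mean(inside[keep]), di = di_cell, threshold = unname(thr),
       inside = inside)
}

#' Full skill report for one fitted model
#'
#' Evaluates a model on a held-out sample: max-TSS threshold, TSS, AUC and
#' kappa after spatial-sorting-bias removal, Brier skill score, OMS, AoA
#' over the prediction stack and the composite SCORE.
#'
#' @param model a `brt_model` (calibrated on its `sample`).
#' @param eval_sample held-out [split_sample()] half.
#' @param stack prediction-domain stack for the AoA.
#' @param mask optional sea mask.
#' @param oms_variant `"four"` or `"three"`; see [oms()].
#' @return one-row data.frame of class `skill_report`.
#' @export
skill_report <- function(model, eval_sample, stack, mask = NULL,
                         oms_variant = "four") {
  p <- predict(model, eval_sample$X)
  y <- eval_sample$label
  thr <- max_tss_threshold(y, p)
  tss_v <- tss(y, p, thr)
  bss_v <- brier_skill(y, p)
  calib_pres <- data.frame(lon = model$sample$lon[model$sample$label == 1],
                           lat = model$sample$lat[model$sample$label == 1])
  tp <- which(y == 1); ta <- which(y == 0)
  ssb <- remove_ssb(data.frame(lon = eval_sample$lon[tp],
                               lat = eval_sample$lat[tp]),
                    data.frame(lon = eval_sample$lon[ta],
                               lat = eval_sample$lat[ta]),
                    calib_pres)
  keep <- c(tp[ssb$pres_idx], ta[ssb$abs_idx])
  auc_ssb <- auc(y[keep], p[keep])
  ck_ssb <- cohen_kappa(y[keep], p[keep], thr) # kappa shares the max-TSS threshold
  contr <- contributions(model)
  aoa_v <- aoa(model$sample, stack, contr, folds = model$folds, mask = mask)
  oms_v <- oms(tss_v, auc_ssb, ck_ssb, bss_v, variant = oms_variant)
  out <- data.frame(
    TSS = tss_v, AUC_SSB_raw = auc_ssb,
    AUC_SSB_scaled = max(0, (auc_ssb - 0.5) / 0.5),
    CK_SSB = ck_ssb, BSS = bss_v, OMS = oms_v, AoA = aoa_v$aoa,
    SCORE = composite_score(oms_v, aoa_v$aoa),
    tss_max_threshold = thr, n_eval_points = length(y),
    n_ssb_pairs = length(ssb$pres_idx))
  class(out) <- c("skill_report", class(out))
  out
}
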