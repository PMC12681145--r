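#' Boosted regression tree configuration
#'
#' Hyperparameters of the boosting engine and of the cross-validated
#' tree-count search. The tuning loop starts from `learning_rate = 0.15` and
#' `tree_complexity = 5` and adjusts both until the cross-validated tree
#' count falls inside `tree_window`; tree complexity is bounded to `[3, 10]`.
#'
#' @param learning_rate shrinkage applied to every tree (initial value for
#'   the tuning loop).
#' @param tree_complexity number of splits per tree (interaction depth),
#'   integer in `[3, 10]`.
#' @param bag_fraction stochastic subsampling fraction per tree.
#' @param n_folds folds of the cross-validated tree-count search.
#' @param tree_step trees added between deviance assessments.
#' @param tree_window acceptable range for the selected tree count.
#' @param max_loop_iterations cap on tuning-loop iterations.
#' @param max_trees hard cap on trees grown during one CV search.
#' @param patience_steps stop growing once the deviance minimum is this many
#'   steps old.
#' @param min_obs minimum observations per terminal node.
#' @param seed seed for fold assignment and bagging.
#' @return list of class `brt_config`.
#' @export
brt_config <- function(learning_rate = 0.15, tree_complexity = 5,
                       bag_fraction = 0.5, n_folds = 10, tree_step = 50,
                       tree_window = c(1200, 2000), max_loop_iterations = 12,
                       max_trees = 2600, patience_steps = 6, min_obs = 10,
                       seed = 1) {
  stopifnot(learning_rate > 0, tree_complexity >= 1,
            tree_window[1] < tree_window[2], bag_fraction > 0,
            bag_fraction <= 1, n_folds >= 2)
  structure(list(learning_rate = learning_rate,
                 tree_complexity = as.integer(tree_complexity),
                 bag_fraction = bag_fraction, n_folds = n_folds,
                 tree_step = tree_step, tree_window = tree_window,
                 max_loop_iterations = max_loop_iterations,
                 max_trees = max_trees, patience_steps = patience_steps,
                 min_obs = min_obs, seed = seed),
            class = "brt_config")
}

stratified_folds <- function(y, n_folds, seed) {
  if (min(table(y)) < n_folds) {
    warning("fewer minority-class points than folds; re-stratifying with ",
            "fewer folds")
    n_folds <- max(2, min(table(y)))
  }
  with_seed(seed, {
    f <- integer(length(y))
    for (cls in unique(y)) {
      i <- which(y == cls)
      f[i] <- sample(rep_len(seq_len(n_folds), length(i)))
    }
    f
  })
}

sample_xy <- function(sample, predictors) {
  X <- sample$X[, predictors, drop = FALSE]
  if (!all(is.finite(X))) stop("non-finite predictor values in sample")
  list(X = X, y = as.integer(sample$label))
}

#' Fit a BRT with cross-validated tree-count selection
#'
#' Grows trees in increments of `tree_step` across `n_folds` stratified
#' folds in lockstep, tracking mean held-out Bernoulli deviance after each
#' increment; growth stops once the deviance minimum is `patience_steps`
#' increments old (or at `max_trees`). The selected tree count is the
#' deviance-minimizing increment, and the returned model is refit on the
#' full sample at that count.
#'
#' @param sample a [select_background()] (or [split_sample()]) sample.
#' @param predictors character vector of at least 2 predictor names.
#' @param config a [brt_config()].
#' @return object of class `brt_model`: exported trees, selected `n_trees`,
#'   the CV deviance curve, per-predictor split-gain totals, training data
#'   reference and fitted probabilities.
#' @export
fit_with_cv <- function(sample, predictors = colnames(sample$X),
                        config = brt_config()) {
  if (length(predictors) < 2) stop("at least 2 predictors required")
  d <- sample_xy(sample, predictors)
  if (length(unique(d$y)) < 2) stop("both labels must be present")
  folds <- stratified_folds(d$y, config$n_folds,
                            derive_seed(config$seed, "folds"))
  n_folds <- max(folds)
  boosters <- lapply(seq_len(n_folds), function(k) {
    tr <- folds != k
    booster_create(d$X[tr, , drop = FALSE], d$y[tr], config$learning_rate,
                   config$tree_complexity, config$bag_fraction,
                   config$min_obs, derive_seed(config$seed, "fold", k),
                   d$X[!tr, , drop = FALSE], d$y[!tr])
  })
  step <- config$tree_step
  mean_dev <- numeric(0)
  repeat {
    for (b in boosters) booster_grow(b, step)
    nt <- booster_n_trees(boosters[[1]])
    mean_dev <- c(mean_dev,
                  mean(vapply(boosters,
                              function(b) booster_valid_dev(b)[nt],
                              numeric(1))))
    best <- which.min(mean_dev)
    if ((length(mean_dev) - best) >= config$patience_steps ||
        nt >= config$max_trees) break
  }
  best <- which.min(mean_dev)
  n_trees <- best * step
  fold_dev <- vapply(boosters, function(b) booster_valid_dev(b)[n_trees],
                     numeric(1))
  final <- booster_create(d$X, d$y, config$learning_rate,
                          config$tree_complexity, config$bag_fraction,
                          config$min_obs, derive_seed(config$seed, "final"),
                          matrix(0, 0, ncol(d$X)), integer(0))
  booster_grow(final, n_trees)
  exp <- booster_export(final, n_trees)
  fit_link <- booster_train_fit(final)
  structure(list(
    nodes = exp$nodes, tree_start = exp$tree_start, init_f = exp$init_f,
    var_gain = setNames(exp$var_gain, predictors),
    n_trees = n_trees, learning_rate = config$learning_rate,
    tree_complexity = config$tree_complexity,
    cv_deviance = data.frame(trees = step * seq_along(mean_dev),
                             deviance = mean_dev),
    cv_dev_min = mean_dev[best],
    cv_dev_se = sd(fold_dev) / sqrt(length(fold_dev)),
    predictors = predictors, folds = folds, config = config,
    sample = sample, fitted = plogis(fit_link), flagged = FALSE,
    tuning = NULL), class = "brt_model")
}

#' @export
print.brt_model <- function(x, ...) {
  cat(sprintf(
    "brt_model: %d trees (lr %.4g, tc %d), %d predictors, CV deviance %.4f%s\n",
    x$n_trees, x$learning_rate, x$tree_complexity, length(x$predictors),
    x$cv_dev_min, if (x$flagged) " [FLAGGED: tuning not converged]" else ""))
  invisible(x)
}

#' Predict presence probabilities from a fitted BRT
#'
#' @param object a `brt_model`.
#' @param newdata numeric matrix containing the model's predictor columns.
#' @param type `"response"` (probability) or `"link"`.
#' @param ... unused.
#' @export
predict.brt_model <- function(object, newdata, type = c("response", "link"),
                              ...) {
  type <- match.arg(type)
  miss <- setdiff(object$predictors, colnames(newdata))
  if (length(miss)) stop("missing predictors: ", paste(miss, collapse = ", "))
  f <- boost_predict_link(object$nodes, object$tree_start, object$init_f,
                          newdata[, object$predictors, drop = FALSE], 0L)
  if (type == "link") f else plogis(f)
}

#' Adaptive hyperparameter tuning loop
#'
#' Repeats [fit_with_cv()] from the configured starting point
#' (learning rate 0.15, tree complexity 5 by default). When the selected
#' tree count falls below the window the learning rate is halved (trees too
#' few means learning too fast); above the window it is multiplied by 1.5.
#' Tree complexity moves by one step, clamped to `[3, 10]`, only after 3
#' consecutive learning-rate-only moves in the same direction have failed.
#' Stops when the tree count lands inside `tree_window`; if
#' `max_loop_iterations` is exhausted the best model so far is returned with
#' `flagged = TRUE` (never an exception).
#'
#' @inheritParams fit_with_cv
#' @return a `brt_model` with a `tuning` history; `flagged` marks
#'   non-convergence.
#' @export
tune <- function(sample, predictors = colnames(sample$X),
                 config = brt_config()) {
  lr <- config$learning_rate
  tc <- config$tree_complexity
  window <- config$tree_window
  consec <- 0; last_dir <- 0
  best <- NULL; best_gap <- Inf
  history <- list()
  for (it in seq_len(config$max_loop_iterations)) {
    cfg <- config
    cfg$learning_rate <- lr
    cfg$tree_complexity <- as.integer(tc)
    cfg$seed <- derive_seed(config$seed, "tune", it)
    # growing past the window only needs to establish "too many trees";
    # patience still confirms any in-window minimum
    cfg$max_trees <- min(config$max_trees,
                         window[2] + (config$patience_steps + 1) *
                           config$tree_step)
    m <- fit_with_cv(sample, predictors, cfg)
    history[[it]] <- list(iteration = it, learning_rate = lr,
                          tree_complexity = tc, n_trees = m$n_trees)
    if (m$n_trees >= window[1] && m$n_trees <= window[2]) {
      m$tuning <- history
      return(m)
    }
    gap <- if (m$n_trees < window[1]) window[1] - m$n_trees
    else m$n_trees - window[2]
    if (gap < best_gap) { best <- m; best_gap <- gap }
    dir <- if (m$n_trees < window[1]) -1 else 1
    consec <- if (dir == last_dir) consec + 1 else 1
    last_dir <- dir
    if (dir < 0) lr <- lr * 0.5 else lr <- lr * 1.5
    if (consec >= 3) {
      tc <- max(3, min(10, tc + dir))
      consec <- 0
    }
  }
  best$flagged <- TRUE
  best$tuning <- history
  warning("tuning loop exhausted after ", config$max_loop_iterations,
          " iterations; returning best model so far (flagged)")
  best
}

#' Relative predictor contributions (percent)
#'
#' Split-improvement totals accumulated during boosting, normalized to sum
#' to 100. A predictor never split on contributes 0.
#'
#' @param model a `brt_model`.
#' @return named numeric vector summing to 100.
#' @export
contributions <- function(model) {
  g <- model$var_gain
  if (sum(g) <= 0) return(setNames(rep(0, length(g)), names(g)))
  100 * g / sum(g)
}

#' Pairwise interaction strengths
#'
#' For every predictor pair, the model is evaluated on a 20 x 20 quantile
#' grid of the pair (all other predictors fixed at training medians, link
#' scale) and a main-effects-only two-way surface (factor main effects) is
#' fitted; the interaction size is 1000 x the residual variance, which is
#' exactly zero for an additive pair. Sizes are assigned symmetrically and
#' summed per predictor.
#'
#' @param model a `brt_model`.
#' @param grid_n quantile grid resolution per axis.
#' @return list of class `interaction_matrix` with `matrix` (symmetric,
#'   zero diagonal) and `sums` (per-predictor totals).
#' @export
interactions <- function(model, grid_n = 20) {
  preds <- model$predictors
  if (length(preds) < 2) stop("need at least 2 predictors")
  X <- model$sample$X[, preds, drop = FALSE]
  med <- apply(X, 2, median)
  qgrid <- lapply(preds, function(p) {
    q <- unique(quantile(X[, p], probs = seq(0.02, 0.98,
                                             length.out = grid_n)))
    q
  })
  names(qgrid) <- preds
  const <- vapply(qgrid, function(q) length(q) < 2, logical(1))
  if (any(const))
    warning("constant predictors get zero interaction rows: ",
            paste(preds[const], collapse = ", "))
  m <- matrix(0, length(preds), length(preds),
              dimnames = list(preds, preds))
  for (i in seq_along(preds)[-length(preds)]) {
    for (j in (i + 1):length(preds)) {
      if (const[i] || const[j]) next
      g <- expand.grid(a = qgrid[[i]], b = qgrid[[j]])
      nd <- matrix(rep(med, each = nrow(g)), nrow(g),
                   dimnames = list(NULL, preds))
      nd[, preds[i]] <- g$a
      nd[, preds[j]] <- g$b
      f <- predict(model, nd, type = "link")
      # complete balanced grid: the main-effects-only least-squares fit is
      # the additive decomposition row mean + column mean - grand mean
      fm <- matrix(f, length(qgrid[[i]]), length(qgrid[[j]]))
      fit <- outer(rowMeans(fm), colMeans(fm), "+") - mean(fm)
      m[i, j] <- m[j, i] <- 1000 * mean((fm - fit)^2)
    }
  }
  structure(list(matrix = m, sums = rowSums(m)),
            class = "interaction_matrix")
}

#' Partial-dependence response curve of one predictor
#'
#' Evaluated on an equally spaced grid spanning the training 1st to 99th
#' percentile, with all other predictors fixed at training medians, mapped
#' to the probability scale.
#'
#' @param model a `brt_model`.
#' @param predictor predictor name.
#' @param n_points grid resolution.
#' @return list of class `response_curve` with `predictor`, `x`, `y`.
#' @export
response_curve <- function(model, predictor, n_points = 100) {
  if (!predictor %in% model$predictors)
    stop("predictor not in model: ", predictor)
  X <- model$sample$X[, model$predictors, drop = FALSE]
  q <- quantile(X[, predictor], c(0.01, 0.99))
  x <- if (q[1] < q[2]) seq(q[1], q[2], length.out = n_points) else q[1]
  med <- apply(X, 2, median)
  nd <- matrix(rep(med, each = n_points), n_points,
               dimnames = list(NULL, model$predictors))
  nd[, predictor] <- x
  structure(list(predictor = predictor, x = x,
                 y = predict(model, nd, type = "response")),
            class = "response_curve")
}

# mean held-out deviance of a fixed-hyperparameter refit on a predictor subset
cv_deviance_fixed <- function(model, predictors, assess_folds = NULL) {
  d <- sample_xy(model$sample, predictors)
  cfg <- model$config
  folds <- model$folds
  ks <- assess_folds %||% seq_len(max(folds))
  dev <- vapply(ks, function(k) {
    tr <- folds != k
    b <- booster_create(d$X[tr, , drop = FALSE], d$y[tr],
                        model$learning_rate, model$tree_complexity,
                        cfg$bag_fraction, cfg$min_obs,
                        derive_seed(cfg$seed, "simplify", k,
                                    paste(predictors, collapse = ",")),
                        d$X[!tr, , drop = FALSE], d$y[!tr])
    booster_grow(b, model$n_trees)
    booster_valid_dev(b)[model$n_trees]
  }, numeric(1))
  mean(dev)
}

#' Drop uninformative predictors (model simplification)
#'
#' Iteratively removes predictors whose removal barely changes the
#' cross-validated deviance: each round the lowest-contribution candidates
#' (shortlist of 2) are assessed by a fixed-hyperparameter CV refit at the
#' model's selected tree count, and the cheaper removal is applied; the
#' process stops when the deviance increase over the original model exceeds
#' one standard error of the original CV deviance, or after `max_drops`
#' rounds. Returns the surviving predictor list (possibly the full list).
#'
#' @param model a `brt_model`.
#' @param max_drops cap on removals (default `min(p - 2, 8)`).
#' @param assess_folds optional subset of fold indices used for the drop
#'   assessment (a runtime lever for large ensembles; the reduced model is
#'   re-tuned with the full fold set downstream regardless).
#' @param n_candidates lowest-contribution candidates assessed per round
#'   (1 reproduces the classic contribution-ordered drop sequence).
#' @return character vector, subset of `model$predictors`.
#' @export
simplify <- function(model, max_drops = NULL, assess_folds = NULL,
                     n_candidates = 2) {
  preds <- model$predictors
  if (is.null(max_drops)) max_drops <- max(0, min(length(preds) - 2, 8))
  baseline <- model$cv_dev_min
  se <- model$cv_dev_se
  contr <- contributions(model)
  for (drop_i in seq_len(max_drops)) {
    if (length(preds) <= 2) break
    shortlist <- names(sort(contr[preds]))[
      seq_len(min(n_candidates, length(preds) - 2))]
    devs <- vapply(shortlist,
                   function(cand) cv_deviance_fixed(model,
                                                    setdiff(preds, cand),
                                                    assess_folds),
                   numeric(1))
    cand <- shortlist[which.min(devs)]
    if (min(devs) - baseline > se) break
    preds <- setdiff(preds, cand)
  }
  preds
}

#' Project a fitted model onto a predictor stack
#'
#' @param model a `brt_model`.
#' @param stack a [predictor_stack()] holding all model predictors.
#' @param mask optional logical sea mask; masked cells become `NA`.
#' @return a `species_map` of predicted probabilities.
#' @export
predict_map <- function(model, stack, mask = NULL) {
  p <- predict(model, stack$values)
  if (!is.null(mask)) p[mask] <- NA_real_
  structure(list(grid = stack$grid, prob = p), class = "species_map")
}
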