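#' Binarize a probability-of-presence map
#'
#' Presence iff probability >= threshold (the boundary value is a presence);
#' masked (`NA`) cells are preserved.
#'
#' @param map a [generate_species_map()] map.
#' @param threshold in the open interval (0, 1); default 0.5.
#' @return integer vector of length `n_cells` with 1/0/NA.
#' @export
binarize <- function(map, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must be strictly inside (0, 1)")
  ifelse(is.na(map$prob), NA_integer_, as.integer(map$prob >= threshold))
}

#' The four background (pseudo-absence) selection methods
#' @return character vector of method names.
#' @export
background_methods <- function()
  c("random", "sampled", "buffered", "sampled_buffered")

#' Draw a presence / pseudo-absence calibration sample
#'
#' Presences are drawn uniformly without replacement from cells with
#' probability >= 0.5. Pseudo-absences are drawn according to `method`:
#' \describe{
#'   \item{random}{uniformly from cells with probability < 0.5.}
#'   \item{sampled}{stratified by each cell's dominant land-use class so the
#'     absence sample's dominant-class composition matches the domain-wide
#'     composition (proportional allocation; exhausted strata reallocate
#'     proportionally with a message).}
#'   \item{buffered}{only from cells with probability exactly 0; cells with
#'     0 < p < 0.5 form the excluded buffer.}
#'   \item{sampled_buffered}{both constraints.}
#' }
#' If fewer than `n_presence` presence cells exist, 75% of the available
#' presence cells are used and absences are topped up towards a total of
#' `2 * n_presence` (capped by the number of eligible absence cells, with a
#' warning, since sampling is without replacement).
#'
#' @param map a [generate_species_map()] map.
#' @param stack a [predictor_stack()] for the reference year; supplies the
#'   predictor table and the land-use fractions used for stratification.
#' @param method one of [background_methods()].
#' @param n_presence,n_absence nominal sample sizes (production-scale default
#'   10,000 each).
#' @param seed sampling seed.
#' @return object of class `calibration_sample`: cells, labels, predictor
#'   matrix `X`, coordinates, method tag, seed and achieved counts.
#' @export
select_background <- function(map, stack, method = background_methods(),
                              n_presence = 10000, n_absence = 10000,
                              seed = 1) {
  method <- match.arg(method)
  stopifnot(same_grid(map$grid, stack$grid))
  p <- map$prob
  pres_cells <- which(!is.na(p) & p >= 0.5)
  abs_pool <- switch(method,
    random = , sampled = which(!is.na(p) & p < 0.5),
    buffered = , sampled_buffered = which(!is.na(p) & p == 0))
  if (!length(abs_pool))
    stop("no eligible pseudo-absence cells under the '", method,
         "' constraint (e.g. no probability-0 cells outside the buffer)")
  if (!length(pres_cells)) stop("no presence cells (probability >= 0.5)")

  if (length(pres_cells) < n_presence) {
    np <- floor(0.75 * length(pres_cells))
    na_target <- 2 * n_presence - np
  } else {
    np <- n_presence
    na_target <- n_absence
  }
  if (na_target > length(abs_pool)) {
    warning("only ", length(abs_pool), " eligible absence cells for a target ",
            "of ", na_target, "; sample capped (without replacement)")
    na_target <- length(abs_pool)
  }

  pres <- with_seed(derive_seed(seed, "bg", method, "pres"),
                    sample(pres_cells, np))
  absn <- if (method %in% c("sampled", "sampled_buffered")) {
    draw_stratified_absences(stack, abs_pool, na_target,
                             derive_seed(seed, "bg", method, "abs"),
                             domain_cells = which(!is.na(p)))
  } else {
    with_seed(derive_seed(seed, "bg", method, "abs"),
              sample(abs_pool, na_target))
  }
  cells <- c(pres, absn)
  label <- c(rep(1L, length(pres)), rep(0L, length(absn)))
  cc <- cell_centers(map$grid)
  structure(list(cells = cells, label = label,
                 X = stack$values[cells, , drop = FALSE],
                 lon = cc$lon[cells], lat = cc$lat[cells],
                 method = method, seed = seed,
                 n_presence = length(pres), n_absence = length(absn)),
            class = "calibration_sample")
}

#' @export
print.calibration_sample <- function(x, ...) {
  cat(sprintf("calibration_sample (%s): %d presences + %d absences, %d predictors\n",
              x$method, x$n_presence, x$n_absence, ncol(x$X)))
  invisible(x)
}

#' Dominant land-use class per cell
#'
#' @param stack a [predictor_stack()] containing land-use fraction columns.
#' @return character vector of class names, length `n_cells`.
#' @export
dominant_landuse <- function(stack) {
  lu_cols <- stack_predictors(stack, "landuse")
  if (!length(lu_cols)) stop("stack has no land-use predictors")
  lu <- stack$values[, lu_cols, drop = FALSE]
  lu_cols[max.col(lu, ties.method = "first")]
}

draw_stratified_absences <- function(stack, abs_pool, n_target, seed,
                                     domain_cells) {
  dom <- dominant_landuse(stack)
  target_prop <- table(dom[domain_cells]) / length(domain_cells)
  pool_by_class <- split(abs_pool, dom[abs_pool])
  alloc <- floor(n_target * as.numeric(target_prop))
  names(alloc) <- names(target_prop)
  # give remainder to the largest strata, then reallocate deficits
  rem <- n_target - sum(alloc)
  if (rem > 0) {
    ord <- order(-as.numeric(target_prop))
    alloc[ord[seq_len(rem)]] <- alloc[ord[seq_len(rem)]] + 1
  }
  avail <- vapply(names(alloc), function(k) length(pool_by_class[[k]] %||%
                                                    integer(0)), integer(1))
  deficit <- sum(pmax(0, alloc - avail))
  if (deficit > 0) {
    message("stratified absence sampling: ", deficit,
            " points reallocated from exhausted land-use strata")
    alloc <- pmin(alloc, avail)
    while (sum(alloc) < n_target) {
      room <- avail - alloc
      if (all(room <= 0)) break
      w <- pmax(0, room) * as.numeric(target_prop)
      k <- which.max(w)
      alloc[k] <- alloc[k] + 1
    }
  }
  with_seed(seed, {
    out <- integer(0)
    for (k in names(alloc)) {
      if (alloc[[k]] == 0) next
      pool_k <- pool_by_class[[k]]
      out <- c(out, if (length(pool_k) == 1) pool_k
               else sample(pool_k, alloc[[k]]))
    }
    sample(out) # shuffle
  })
}

#' Stratified 50/50 split of a calibration sample
#'
#' The held-out half is used for skill evaluation; the other half calibrates
#' the model (the boosting itself additionally bags half of the calibration
#' rows per tree).
#'
#' @param sample a [select_background()] sample.
#' @param seed split seed.
#' @param eval_fraction held-out fraction (default 0.5).
#' @return list with `calib` and `eval` calibration_sample objects.
#' @export
split_sample <- function(sample, seed = 1, eval_fraction = 0.5) {
  idx <- with_seed(derive_seed(seed, "split"), {
    pres <- which(sample$label == 1)
    absn <- which(sample$label == 0)
    c(sample(pres, floor(eval_fraction * length(pres))),
      sample(absn, floor(eval_fraction * length(absn))))
  })
  take <- function(s, i) {
    s$cells <- s$cells[i]; s$label <- s$label[i]
    s$X <- s$X[i, , drop = FALSE]
    s$lon <- s$lon[i]; s$lat <- s$lat[i]
    s$n_presence <- sum(s$label == 1); s$n_absence <- sum(s$label == 0)
    s
  }
  list(calib = take(sample, setdiff(seq_along(sample$label), idx)),
       eval = take(sample, idx))
}
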