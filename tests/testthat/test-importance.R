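# independent brute-force evaluation of the per-cell importance rule
mip_oracle <- function(contr, int_sums, resp_delta, sign_filter = NULL) {
  fs <- function(x, dg) {
    r <- range(x)
    if (diff(r) < 1e-300) rep(dg, length(x)) else (x - r[1]) / diff(r)
  }
  con_n <- fs(contr, 1)
  int_n <- fs(int_sums, 0)
  dmax <- max(abs(resp_delta))
  r_n <- if (dmax > 0) abs(resp_delta) / dmax else resp_delta * 0
  preds <- names(contr)
  winner <- rep(NA_character_, nrow(resp_delta))
  imp <- rep(NA_real_, nrow(resp_delta))
  for (cell in seq_len(nrow(resp_delta))) {
    sc <- vapply(seq_along(preds), function(j) {
      s <- (con_n[j] + con_n[j] * int_n[j]) * r_n[cell, j]
      if (!is.null(sign_filter)) {
        dir <- sign_filter[cell]
        if (dir > 0 && resp_delta[cell, j] <= 0) s <- 0
        if (dir < 0 && resp_delta[cell, j] >= 0) s <- 0
      }
      s
    }, numeric(1))
    if (all(sc <= 0)) next
    # ties: higher CON_N then lexicographic name
    best <- which(sc == max(sc))
    if (length(best) > 1) best <- best[order(-con_n[best],
                                             preds[best])][1]
    winner[cell] <- preds[best]
    imp[cell] <- 100 * sc[best] / sum(sc[sc > 0])
  }
  list(winner = winner, importance = imp)
}

rand_terms <- function(n_cells, preds, seed) {
  set.seed(seed)
  list(contr = setNames(runif(length(preds), 0, 50), preds),
       int = setNames(runif(length(preds), 0, 10), preds),
       delta = matrix(rnorm(n_cells * length(preds), 0, 0.3), n_cells,
                      dimnames = list(NULL, preds)))
}

test_that("response_range: identity, flat curve, hand interpolation", {
  curve <- structure(list(predictor = "x", x = c(0, 1, 2),
                          y = c(0.2, 0.8, 0.4)),
                     class = "response_curve")
  expect_equal(response_range(curve, 1.3, 1.3), 0)
  # hand: f(1.5) = 0.8 + 0.5*(0.4-0.8) = 0.6; f(0.5) = 0.5
  expect_equal(response_range(curve, 0.5, 1.5), 0.6 - 0.5,
               tolerance = 1e-12)
  # clamp outside the grid
  expect_equal(response_range(curve, -5, 10), 0.4 - 0.2, tolerance = 1e-12)
  flat <- structure(list(predictor = "x", x = 0:3, y = rep(0.5, 4)),
                    class = "response_curve")
  expect_equal(response_range(flat, 0.1, 2.9), 0)
})

test_that("compute_mip: degenerate cases and the zero-product rule", {
  d <- matrix(c(0.3, 0, -0.2), 3, 1, dimnames = list(NULL, "only"))
  r <- compute_mip(setNames(40, "only"), setNames(2, "only"), d)
  expect_equal(r$winner, c("only", NA, "only"))
  expect_equal(r$importance, c(100, NA, 100))
  # all deltas zero at a cell -> no MIP flag
  t2 <- rand_terms(4, c("a", "b"), 1)
  t2$delta[2, ] <- 0
  r2 <- compute_mip(t2$contr, t2$int, t2$delta)
  expect_true(is.na(r2$winner[2]))
})

test_that("compute_mip matches the brute-force oracle", {
  for (s in 1:5) {
    t <- rand_terms(50, c("a", "b", "c"), 100 + s)
    got <- compute_mip(t$contr, t$int, t$delta)
    want <- mip_oracle(t$contr, t$int, t$delta)
    expect_identical(got$winner, want$winner)
    expect_equal(got$importance, want$importance, tolerance = 1e-9)
  }
})

test_that("importance percentages sum to 100 over winners per cell", {
  t <- rand_terms(30, c("a", "b", "c", "d"), 7)
  r <- compute_mip(t$contr, t$int, t$delta)
  # per cell: sum over predictors of score/total = 1, winner share <= 100
  tot <- rowSums(r$scores * (r$scores > 0))
  share_sums <- rowSums(100 * r$scores * (r$scores > 0) / tot)
  expect_equal(share_sums, rep(100, 30), tolerance = 1e-9)
  expect_true(all(r$importance <= 100 + 1e-9, na.rm = TRUE))
})

test_that("scale invariance: rescaling contributions keeps winners", {
  t <- rand_terms(40, c("a", "b", "c"), 9)
  r1 <- compute_mip(t$contr, t$int, t$delta)
  r2 <- compute_mip(t$contr * 7.3, t$int, t$delta)
  expect_identical(r1$winner, r2$winner)
  expect_equal(r1$importance, r2$importance, tolerance = 1e-9)
})

test_that("MIPC sign filter per change category", {
  preds <- c("X", "Y")
  contr <- setNames(c(30, 30), preds)
  ints <- setNames(c(1, 1), preds)
  delta <- matrix(c(0.2, -0.5,   # cell 1: PCC
                    -0.1, 0.4,   # cell 2: ACC (no negative? X is negative)
                    0.3, 0.6),   # cell 3: P (unsigned)
                  3, 2, byrow = TRUE, dimnames = list(NULL, preds))
  change <- factor(c("PCC", "ACC", "P"), levels = change_categories())
  r <- compute_mipc(contr, ints, delta, change)
  # PCC: only positive deltas compete -> X despite |delta Y| larger
  expect_equal(r$winner[1], "X")
  # ACC: only negative deltas -> X
  expect_equal(r$winner[2], "X")
  # P: unsigned, equals the plain MIP ranking
  plain <- compute_mip(contr, ints, delta)
  expect_equal(r$winner[3], plain$winner[3])
  # ACC cell with no negative-delta predictor -> no MIPC
  delta2 <- delta; delta2[2, ] <- c(0.1, 0.4)
  r2 <- compute_mipc(contr, ints, delta2, change)
  expect_true(is.na(r2$winner[2]))
})

test_that("MIPC equals brute-force oracle with sign filtering", {
  t <- rand_terms(60, c("a", "b", "c"), 17)
  change <- factor(sample(change_categories(), 60, replace = TRUE),
                   levels = change_categories())
  dirs <- ifelse(change %in% c("PCC", "PLUC", "RPLUC"), 1,
                 ifelse(change %in% c("ACC", "ALUC", "RALUC"), -1, 0))
  got <- compute_mipc(t$contr, t$int, t$delta, change)
  want <- mip_oracle(t$contr, t$int, t$delta, sign_filter = dirs)
  expect_identical(got$winner, want$winner)
  expect_equal(got$importance, want$importance, tolerance = 1e-9)
})

test_that("mip_summary: hand-tabulated toy map", {
  preds <- c("a", "b")
  rec <- structure(list(
    winner = c("a", "a", "b", NA),
    importance = c(60, 80, 100, NA),
    resp_delta = matrix(c(0.2, 0.4, 0, 0, 0, 0, -0.3, 0), 4, 2,
                        dimnames = list(NULL, preds))),
    class = "mip_record")
  change <- factor(c("PCC", "PCC", "ACC", "ACC"),
                   levels = change_categories())
  pred_delta <- matrix(c(1, 3, 0, 0, 0, 0, -2, 0), 4, 2,
                       dimnames = list(NULL, preds))
  suppressMessages(s <- mip_summary(rec, change, pred_delta))
  pcc <- s[s$category == "PCC", ]
  expect_equal(pcc$mip, "a")
  expect_equal(pcc$fraction_pct, 100)
  expect_equal(pcc$mean_delta, 2)      # mean of 1, 3
  expect_equal(pcc$mean_delta_res, 0.3)
  acc <- s[s$category == "ACC", ]
  expect_equal(acc$mip, "b")
  expect_equal(acc$fraction_pct, 50)   # one NA winner of two cells
  expect_equal(acc$mean_delta, -2)
  # empty categories omitted
  expect_false("PLUC" %in% s$category)
})
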