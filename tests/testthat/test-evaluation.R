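test_that("max-TSS threshold agrees with a brute-force scan", {
  set.seed(5)
  for (rep in 1:5) {
    n <- 200
    p <- runif(n)
    y <- rbinom(n, 1, p)
    thr <- max_tss_threshold(y, p)
    # oracle: evaluate TSS at every unique prediction value
    cand <- sort(unique(p))
    tssv <- vapply(cand, function(t) tss(y, p, t), numeric(1))
    best <- max(tssv)
    expect_equal(tss(y, p, thr), best, tolerance = 1e-12)
    # lowest threshold among ties
    expect_equal(thr, min(cand[tssv >= best - 1e-12]))
  }
  # perfectly separated -> TSS 1
  y <- rep(c(0, 1), each = 20)
  p <- c(runif(20, 0, 0.4), runif(20, 0.6, 1))
  expect_equal(tss(y, p, max_tss_threshold(y, p)), 1)
  # independent labels, large n -> max TSS near 0
  set.seed(6)
  y <- rbinom(10000, 1, 0.5)
  p <- runif(10000)
  expect_lt(tss(y, p, max_tss_threshold(y, p)), 0.1)
  expect_error(max_tss_threshold(rep(1, 5), runif(5)), "both classes")
})

test_that("TSS / kappa / AUC / BSS closed forms", {
  # sensitivity 0.9, specificity 0.8 -> TSS 0.7
  y <- rep(c(1, 0), each = 10)
  p <- c(rep(0.9, 9), 0.1, rep(0.1, 8), 0.9, 0.9)
  expect_equal(tss(y, p, 0.5), 0.7)
  # 2x2 table (TP, FP, FN, TN) = (40, 10, 10, 40) -> kappa 0.6
  # hand: po = 0.8, pe = 0.5, kappa = (0.8 - 0.5) / 0.5 = 0.6
  y2 <- c(rep(1, 50), rep(0, 50))
  p2 <- c(rep(1, 40), rep(0, 10), rep(1, 10), rep(0, 40))
  expect_equal(cohen_kappa(y2, p2, 0.5), 0.6)
  # random predictions: AUC ~ 0.5
  set.seed(8)
  y3 <- rbinom(10000, 1, 0.4)
  expect_equal(auc(y3, runif(10000)), 0.5, tolerance = 0.04)
  # BSS toy: BS = mean((.8,.2,.6,.4) - (1,0,1,0))^2 = 0.1, BS_ref = 0.25
  expect_equal(brier_skill(c(1, 0, 1, 0), c(0.8, 0.2, 0.6, 0.4)),
               1 - 0.1 / 0.25)
  expect_equal(brier_skill(c(1, 0, 1), c(1, 0, 1)), 1)
  expect_equal(brier_skill(c(1, 0, 1, 0), rep(0.5, 4)), 0)
})

test_that("OMS: arithmetic, chance floor, monotonicity", {
  expect_equal(oms(1, 1, 1, 1), 1)
  expect_equal(oms(0.8, 0.75, 0.6, 0.7), 0.65)
  expect_equal(oms(0.8, 0.5, 0.6, 0.7), (0.8 + 0 + 0.6 + 0.7) / 4)
  expect_equal(oms(0.8, 0.4, 0.6, 0.7), oms(0.8, 0.5, 0.6, 0.7)) # floored
  expect_equal(oms(0.9, 0.8, 0.7, 0.6, variant = "three"),
               (0.9 + 0.6 + 0.7) / 3)
  # monotone increasing in each component
  set.seed(2)
  for (i in 1:20) {
    v <- runif(4, 0.5, 0.9)
    eps <- 0.05
    base <- oms(v[1], v[2], v[3], v[4])
    expect_gt(oms(v[1] + eps, v[2], v[3], v[4]), base)
    expect_gt(oms(v[1], v[2] + eps, v[3], v[4]), base)
    expect_gt(oms(v[1], v[2], v[3] + eps, v[4]), base)
    expect_gt(oms(v[1], v[2], v[3], v[4] + eps), base)
  }
})

test_that("composite score: bounds, symmetry, monotonicity", {
  expect_equal(composite_score(1, 1), 1)
  expect_equal(composite_score(0, 0), 0)
  set.seed(3)
  a <- runif(50); b <- runif(50)
  expect_equal(composite_score(a, b), composite_score(b, a))
  expect_true(all(composite_score(pmin(a + 0.01, 1), b) >=
                    composite_score(a, b)))
  expect_true(all(composite_score(a, b) >= 0 & composite_score(a, b) <= 1))
})

test_that("spatial sorting bias removal", {
  calib <- data.frame(lon = 0, lat = 40)
  # symmetric layout: presences and absences at identical distances
  tp <- data.frame(lon = c(1, 2, 3), lat = 40)
  ta <- data.frame(lon = -c(1, 2, 3), lat = 40)
  r <- remove_ssb(tp, ta, calib)
  expect_equal(length(r$pres_idx), 3)
  expect_equal(length(r$pres_idx), length(r$abs_idx))
  expect_equal(r$ssb_after, 1)
  # absences systematically 10x farther: matched subset or error
  ta10 <- data.frame(lon = -c(10, 20, 30), lat = 40)
  expect_error(remove_ssb(tp, ta10, calib), "tolerance")
  # mixed case: removal moves the ratio towards 1
  set.seed(4)
  tp2 <- data.frame(lon = runif(40, 0.5, 2), lat = runif(40, 39, 41))
  ta2 <- data.frame(lon = runif(40, 1, 6), lat = runif(40, 39, 41))
  r2 <- remove_ssb(tp2, ta2, calib)
  expect_lt(abs(r2$ssb_after - 1), abs(r2$ssb_before - 1))
  expect_equal(length(r2$pres_idx), length(r2$abs_idx))
})

test_that("ssb removal improves systematically biased layouts", {
  # absences drawn systematically farther from the calibration presences
  # than the presences are: the defining spatial-sorting-bias situation
  calib <- data.frame(lon = c(0, 1), lat = c(40, 41))
  set.seed(10)
  for (i in 1:10) {
    tp <- data.frame(lon = runif(40, 0.2, 2), lat = runif(40, 39.5, 41.5))
    ta <- data.frame(lon = runif(40, 0.2, 2) * (1.3 + 0.15 * i),
                     lat = runif(40, 39.5, 41.5))
    r <- try(remove_ssb(tp, ta, calib), silent = TRUE)
    if (inherits(r, "try-error")) next
    expect_lte(abs(r$ssb_after - 1), abs(r$ssb_before - 1) + 1e-9)
  }
})

test_that("area of applicability: identity, extrapolation, coverage", {
  set.seed(15)
  w <- small_world()
  st <- w$stacks[["2000"]]
  smp <- select_background(w$map, st, "random", 100, 100, seed = 2)
  contr <- setNames(rep(100 / 4, 4), c("BIO1", "BIO12", "urban", "BIO4"))
  # prediction domain identical to the calibration cells -> DI = 0, AoA = 1
  st_cal <- st
  st_cal$values <- st$values[smp$cells, , drop = FALSE]
  expect_equal(aoa(smp, st_cal, contr)$aoa, 1)
  # full domain: most cells resemble some calibration point
  a1 <- aoa(smp, st, contr)
  expect_gt(a1$aoa, 0.5)
  expect_lte(a1$aoa, 1)
  # displaced domain: 100 SDs away in predictor space -> nothing applicable
  far <- st
  sds <- apply(smp$X[, names(contr)], 2, sd)
  far$values[, names(contr)] <-
    sweep(far$values[, names(contr)], 2, 100 * sds, "+")
  expect_equal(aoa(smp, far, contr)$aoa, 0)
  # shrinking calibration to one spatial corner decreases coverage
  corner <- which(smp$lon < quantile(smp$lon, 0.3))
  smp_c <- smp
  for (f in c("cells", "label", "lon", "lat")) smp_c[[f]] <- smp_c[[f]][corner]
  smp_c$X <- smp_c$X[corner, , drop = FALSE]
  a2 <- aoa(smp_c, st, contr)
  expect_lt(a2$aoa, a1$aoa)
  expect_error(aoa(list(X = smp$X[1:5, ]), st, contr), "10 calibration")
})

test_that("skill_report assembles a coherent row", {
  f <- small_fit()
  w <- f$world
  smp <- select_background(w$map, f$stack, "random", 150, 150, seed = 22)
  h <- split_sample(smp, seed = 4)
  cfg <- brt_config(learning_rate = 0.05, max_trees = 500, n_folds = 5,
                    seed = 6)
  m <- fit_with_cv(h$calib, config = cfg)
  rep <- skill_report(m, h$eval, f$stack, mask = w$mask)
  expect_s3_class(rep, "skill_report")
  expect_true(rep$TSS > 0.5)          # strong synthetic signal
  expect_true(rep$AoA > 0 && rep$AoA <= 1)
  expect_equal(rep$SCORE, composite_score(rep$OMS, rep$AoA))
  expect_equal(rep$AUC_SSB_scaled,
               max(0, (rep$AUC_SSB_raw - 0.5) / 0.5))
  expect_equal(rep$OMS, oms(rep$TSS, rep$AUC_SSB_raw, rep$CK_SSB, rep$BSS))
})
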