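test_that("wls_fit reproduces a perfect linear relationship", {
  set.seed(1)
  d <- data.frame(shift_km = 0, weight = 1, x = rnorm(30, 0, 3))
  d$shift_km <- 2 * d$x
  # summary.lm warns about an essentially perfect fit; that is the point here
  fit <- suppressWarnings(wls_fit(d, "x"))
  # standardized slope = 2 * SD(x); intercept = mean(y)
  expect_equal(unname(coef(fit$lm)["x"]), 2 * sd(d$x))
  expect_equal(unname(coef(fit$lm)["(Intercept)"]), mean(d$shift_km))
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$adj_r_squared, 1)
  expect_equal(fit$pred_r_squared, 1)
})

test_that("the intercept-only model fits the weighted mean with R2 = 0", {
  set.seed(2)
  d <- data.frame(shift_km = rnorm(25, 10, 5), weight = runif(25, 0.5, 2))
  fit <- wls_fit(d, character(0))
  expect_equal(unname(coef(fit$lm)),
               sum(d$weight * d$shift_km) / sum(d$weight))
  expect_equal(fit$r_squared, 0)
  expect_equal(fit$k, 1L)
})

test_that("AIC follows the k + 1 convention and the weight-scaling identity", {
  d <- make_toy_table(50)
  fit <- wls_fit(d, c("Tmean", "Tbreadth"))
  expect_equal(fit$AIC, -2 * fit$logLik + 2 * (fit$k + 1))
  expect_gte(fit$r_squared, fit$adj_r_squared)
  # rescaling all weights: coefficients and R2 unchanged, and the
  # sum(log w) term of the likelihood cancels exactly against the
  # n*log(RSSw/n) term, leaving logLik (and hence AIC) invariant
  d2 <- d; d2$weight <- 2 * d$weight
  fit2 <- wls_fit(d2, c("Tmean", "Tbreadth"))
  expect_equal(coef(fit2$lm), coef(fit$lm))
  expect_equal(fit2$r_squared, fit$r_squared)
  expect_equal(fit2$logLik, fit$logLik)
  expect_equal(fit2$AIC, fit$AIC)
  # the stated likelihood formula holds as written
  ll <- 0.5 * (sum(log(d$weight)) -
                 fit$n * (log(2 * pi) + 1 + log(fit$rss_w / fit$n)))
  expect_equal(fit$logLik, ll)
})

test_that("wls_fit agrees with direct numerical loss minimization", {
  set.seed(3)
  for (i in 1:20) {
    n <- sample(15:30, 1)
    X <- cbind(1, matrix(rnorm(n * 3), n, 3))
    y <- rnorm(n, 5, 3)
    w <- runif(n, 0.2, 3)
    d <- data.frame(shift_km = y, weight = w,
                    a = X[, 2], b = X[, 3], c = X[, 4])
    fit <- wls_fit(d, c("a", "b", "c"))
    # refit the oracle on the standardized design the package uses
    Z <- cbind(1, scale(X[, 2:4]))
    oracle <- wls_optim_oracle(Z, y, w)
    expect_lt(max(abs(unname(coef(fit$lm)) - oracle)), 1e-8)
  }
})

test_that("degenerate designs raise precise errors", {
  d <- make_toy_table(30)
  d$flat <- 1
  expect_error(wls_fit(d, "flat"), "zero variance")
  d$dup <- d$Tmean
  expect_error(wls_fit(d, c("Tmean", "dup")), "aliased")
  d$w0 <- 0
  expect_error(wls_fit(d, "Tmean", weight_col = "w0"), "positive")
  expect_error(wls_fit(d[1:2, ], c("Tmean", "Tbreadth")), "exceed")
})

test_that("factors are treatment-coded against the declared reference", {
  d <- make_toy_table(80)
  fit <- wls_fit(d, "wintering",
                 reference_levels = list(wintering = "adult"))
  expect_equal(fit$k, 4L)  # intercept + 3 contrasts
  expect_false("winteringadult" %in% rownames(fit$coefficients))
  fit2 <- wls_fit(d, "wintering",
                  reference_levels = list(wintering = "larva"))
  expect_false("winteringlarva" %in% rownames(fit2$coefficients))
  expect_equal(fit$r_squared, fit2$r_squared)  # reparameterization only
  expect_error(wls_fit(d, "wintering",
                       reference_levels = list(wintering = "nope")),
               "reference level")
})

test_that("best_subsets enumerates the full powerset with per-size bests", {
  d <- make_toy_table(60)
  bs2 <- best_subsets(d, c("Tmean", "Tbreadth"))
  expect_equal(nrow(bs2$summary), 4L)
  expect_setequal(bs2$summary$predictors,
                  c("", "Tmean", "Tbreadth", "Tmean + Tbreadth"))
  # per-size best flags match brute-force recomputation over 3 candidates
  cand <- c("Tmean", "Tbreadth", "wintering")
  bs3 <- best_subsets(d, cand)
  expect_equal(nrow(bs3$summary), 8L)
  for (s in 1:3) {
    idx <- which(bs3$summary$size == s)
    best_flagged <- bs3$summary$predictors[idx][bs3$summary$best_of_size[idx]]
    r2 <- vapply(idx, function(i) {
      vars <- strsplit(bs3$summary$predictors[i], " \\+ ")[[1]]
      wls_fit(d, vars)$r_squared
    }, numeric(1))
    expect_equal(best_flagged, bs3$summary$predictors[idx][which.max(r2)])
  }
  # a multi-level factor enters as a block: its models gain 3 df at once
  win_model <- bs3$models[[which(bs3$summary$predictors == "wintering")]]
  expect_equal(win_model$k, 4L)
})

test_that("the AIC parsimony rule picks the smallest qualifying size", {
  # less parsimonious models must be at least delta units better
  sel <- select_final(c(100, 99.5, 95, 94.9), delta = 2)
  expect_equal(sel$chosen_size, 3L)  # size 4 is only 0.1 lower
  sel2 <- select_final(c(100, 101, 102), delta = 2)
  expect_equal(sel2$chosen_size, 1L)
  # works from a best_subsets object and returns the fitted model
  d <- make_toy_table(120, seed = 99)
  d$shift_km <- d$shift_km + 12 * scale(d$Tbreadth)[, 1]
  bs <- best_subsets(d, c("Tmean", "Tbreadth", "size"))
  sel3 <- select_final(bs)
  expect_s3_class(sel3$chosen_model, "wls_fit")
  expect_true(grepl("Tbreadth", sel3$chosen_predictors))
  expect_error(select_final(numeric(0)), "non-empty")
})

test_that("drop1 tables account for factor blocks and reduce to the null", {
  d <- make_toy_table(100)
  fit <- wls_fit(d, c("Tmean", "wintering"))
  tab <- drop1_table(fit)
  expect_identical(tab$dropped[1], "<none>")
  expect_equal(tab$df[tab$dropped == "wintering"], 3)  # 4-level factor
  expect_equal(tab$df[tab$dropped == "Tmean"], 1)
  # RSS of the reduced models: dropping the only predictor gives the null RSS
  fit1 <- wls_fit(d, "Tmean")
  t1 <- drop1_table(fit1)
  null_fit <- wls_fit(d, character(0))
  expect_equal(t1$rss[t1$dropped == "Tmean"], null_fit$rss_w)
  expect_error(drop1_table(null_fit), "no predictor")
})

test_that("dropping a pure-noise predictor lowers drop1 AIC in expectation", {
  set.seed(11)
  deltas <- replicate(500, {
    n <- 100
    d <- data.frame(shift_km = rnorm(n), weight = 1,
                    signal = rnorm(n), noise = rnorm(n))
    d$shift_km <- d$shift_km + 0.8 * d$signal
    tab <- drop1_table(wls_fit(d, c("signal", "noise")))
    tab$aic[tab$dropped == "noise"] - tab$aic[tab$dropped == "<none>"]
  })
  expect_lt(mean(deltas), 0)
  expect_lt(abs(mean(deltas) - (-2 + 1)), 0.6)  # E[chisq_1] - 2 = -1
})

test_that("diagnostics report normality, heteroscedasticity, VIF and Cook", {
  set.seed(12)
  n <- 60
  # orthogonal mean-centred design: all VIFs are 1
  q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n, 3))))[, 2:4]
  d <- data.frame(shift_km = rnorm(n), weight = 1,
                  a = q[, 1], b = q[, 2], c = q[, 3])
  diag <- model_diagnostics(wls_fit(d, c("a", "b", "c")))
  expect_equal(unname(diag$vif), rep(1, 3), tolerance = 1e-6)
  expect_true(diag$shapiro$p_value > 0 && diag$shapiro$p_value <= 1)
  expect_true(diag$breusch_pagan$df == 3)
  # a gross outlier dominates Cook's distance and is flagged
  d2 <- data.frame(shift_km = rnorm(n, 0, 1), weight = 1,
                   x = rnorm(n))
  d2$shift_km <- 0.5 * d2$x + rnorm(n, 0, 0.3)
  d2$x[1] <- 4; d2$shift_km[1] <- -20
  dg2 <- model_diagnostics(wls_fit(d2, "x"))
  expect_equal(which.max(dg2$cooks), 1L)
  expect_true(1L %in% dg2$influential)
  expect_gt(max(dg2$cooks), 4 / n)
})

test_that("prediction profiles respect standardization and factor levels", {
  d <- make_toy_table(90)
  beta <- 9
  d$shift_km <- 5 + beta * scale(d$Tbreadth)[, 1] + rnorm(90, 0, 2)
  fit <- wls_fit(d, c("Tbreadth", "Tmean", "wintering"))
  prof <- predict_profile(fit, "Tbreadth", n_grid = 50)
  expect_equal(nrow(prof), 50 * 4)  # one curve per wintering level
  expect_true(all(c("Tbreadth", "wintering", "predicted") %in% names(prof)))
  expect_equal(range(prof$Tbreadth), range(d$Tbreadth))
  # the curve's slope in original units is the coefficient / SD(focus)
  one <- prof[prof$wintering == "adult", ]
  slope <- coef(lm(predicted ~ Tbreadth, data = one))[2]
  expect_equal(unname(slope),
               unname(coef(fit$lm)["Tbreadth"]) / sd(d$Tbreadth))
  # at the focus mean (standardized 0) the prediction matches the
  # all-means point prediction
  nd <- data.frame(Tbreadth = 0, Tmean = 0,
                   wintering = factor("adult",
                                      levels = levels(fit$lm$model$wintering)))
  at_mean <- predict(fit$lm, nd)
  mid <- approx(one$Tbreadth, one$predicted, xout = mean(d$Tbreadth))$y
  expect_equal(mid, unname(at_mean))
  expect_error(predict_profile(fit, "size"), "not a continuous predictor")
})
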