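# synthetic patch table with known generative structure: fire intercepts
# N(mu, tau^2), aspen slope per proportion unit, residual sd
simPatchTable <- function(nFires = 40, perFire = 20, slope = -0.8,
                          tau = 0.3, sigma = 0.3, mu = 3, seed = 1) {
  set.seed(seed)
  fid <- rep(sprintf("f%02d", seq_len(nFires)), each = perFire)
  b0 <- rep(rnorm(nFires, mu, tau), each = perFire)
  aspen <- runif(nFires * perFire, 0, 0.6)
  y <- b0 + slope * aspen + rnorm(nFires * perFire, 0, sigma)
  data.frame(fire_id = fid, aspen = aspen,
             area_ha = 10^y, max_linear_spread_m = 10^(y - 1),
             stringsAsFactors = FALSE)
}

test_that("prepareResponse adds logs, the zero floor, and subset flags", {
  tab <- data.frame(fire_id = c("a", "a", "b"),
                    area_ha = c(100, 9, 0.09),
                    max_linear_spread_m = c(1000, 0, 270),
                    aspen = c(0.07, 0.2, 0.0005))
  pr <- prepareResponse(tab, pixelSize = 30)
  expect_equal(pr$log10_area_ha[1], 2)
  expect_equal(pr$log10_linear_m[2], log10(15))  # floored at half a pixel
  expect_equal(pr$aspen_present, c(TRUE, TRUE, FALSE))
  expect_equal(pr$gt5, c(TRUE, TRUE, FALSE))
  expect_equal(pr$gt10, c(FALSE, TRUE, FALSE))
  expect_error(prepareResponse(tab[0, ]), "empty")
})

test_that("the mixed model recovers a known negative aspen slope", {
  tab <- prepareResponse(simPatchTable(slope = -0.8, seed = 11))
  fit <- fitMixed(tab, "log10_area_ha", "aspen")
  est <- fit$fixedEffects[fit$fixedEffects$term == "aspen", ]
  expect_lt(abs(est$estimate - (-0.8)), 2 * est$se)
  expect_lt(est$estimate, 0)
  expect_gt(fit$randomVar, 0)
  expect_gt(fit$r2[["conditional"]], fit$r2[["marginal"]])
})

test_that("estimates reduce to least squares without fire-level variance", {
  tab <- prepareResponse(simPatchTable(nFires = 12, perFire = 15, tau = 0,
                                       sigma = 0.25, seed = 3))
  fit <- suppressWarnings(fitMixed(tab, "log10_area_ha", "aspen"))
  ols <- lm(log10_area_ha ~ aspen, data = tab)
  expect_equal(
    unname(fit$fixedEffects$estimate[fit$fixedEffects$term == "aspen"]),
    unname(coef(ols)[["aspen"]]), tolerance = 0.05)
})

test_that("cover contrasts flag inestimable types and recover signs", {
  tab <- prepareResponse(simPatchTable(slope = -0.8, seed = 5))
  tab$warm_conifer <- 1 - tab$aspen  # complement: positive association
  tab$wetland <- 0.25                # constant: no usable variation
  fits <- suppressMessages(
    fitCoverContrasts(tab, "log10_area_ha",
                      c("aspen", "warm_conifer", "wetland")))
  expect_equal(attr(fits, "skipped"), "wetland")
  aspenEst <- fits$aspen$fixedEffects
  expect_lt(aspenEst$estimate[aspenEst$term == "aspen"], 0)
  wcEst <- fits$warm_conifer$fixedEffects
  expect_gt(wcEst$estimate[wcEst$term == "warm_conifer"], 0)
  # a duplicated column under two names gives identical coefficients
  tab$aspen_copy <- tab$aspen
  fits2 <- fitCoverContrasts(tab, "log10_area_ha", c("aspen", "aspen_copy"))
  expect_equal(
    fits2$aspen$fixedEffects$estimate[2],
    fits2$aspen_copy$fixedEffects$estimate[2])
})

test_that("selection prunes perfectly collinear copies and noise terms", {
  tab <- prepareResponse(simPatchTable(nFires = 30, perFire = 15,
                                       slope = -0.8, seed = 7))
  set.seed(8)
  tab$FWI <- 0.6 * (tab$log10_area_ha - mean(tab$log10_area_ha)) +
    rnorm(nrow(tab), 0, 0.3)       # a real predictor
  tab$FWI_copy <- tab$FWI           # r = 1 duplicate
  tab$noise <- rnorm(nrow(tab))     # pure noise
  sel <- selectModel(tab, "log10_area_ha", c("FWI", "FWI_copy", "noise"))
  terms <- sel$model$fixedEffects$term
  expect_true("aspen" %in% terms)
  expect_true(xor("FWI" %in% terms, "FWI_copy" %in% terms))
  expect_true("drop_collinear" %in% sel$trace$action ||
                "drop_nonsignificant" %in% sel$trace$action)
  # selected model never has a worse AIC than the all-terms initial fit
  full <- fitMixed(tab, "log10_area_ha",
                   c("aspen", "FWI", "FWI_copy", "noise"))
  expect_lte(sel$model$aic, full$aic + 1e-9)
})

test_that("null interactions are rarely retained", {
  keepers <- vapply(1:25, function(r) {
    tab <- prepareResponse(simPatchTable(nFires = 20, perFire = 10,
                                         slope = -0.5, seed = 100 + r))
    set.seed(200 + r)
    tab$FWI <- 0.5 * (tab$log10_area_ha - mean(tab$log10_area_ha)) +
      rnorm(nrow(tab), 0, 0.4)
    sel <- selectModel(tab, "log10_area_ha", "FWI")
    any(grepl(":", sel$model$fixedEffects$term))
  }, logical(1))
  expect_lte(mean(keepers), 0.2)
})

test_that("FPE covariate models recover slopes and need 10 fires", {
  set.seed(12)
  n <- 60
  cov <- data.frame(FWI = rnorm(n), Tmax = rnorm(n))
  f <- 0.5 * cov$FWI + rnorm(n, 0, 0.3)
  res <- fitFpeCovariateLm(f, cov)
  fw <- res[res$covariate == "FWI", ]
  expect_lt(abs(fw$slope - 0.5), 2 * fw$se)
  expect_lt(fw$p, 0.01)
  expect_error(fitFpeCovariateLm(f[1:5], cov[1:5, ]), "10 fires")
  cov$flat <- 1
  expect_false("flat" %in% fitFpeCovariateLm(f, cov)$covariate)
})

test_that("the DOY smooth finds a seasonal signal but not a flat one", {
  set.seed(14)
  doy <- sample(100:280, 300, replace = TRUE)
  flat <- rnorm(300, 0.2, 0.1)
  g0 <- fitFpeDoySmooth(flat, doy)
  expect_lt(g0$edf, 3)
  expect_gt(g0$pValue, 0.05)
  wavy <- 0.3 * sin(2 * pi * doy / 365) + rnorm(300, 0, 0.15)
  g1 <- fitFpeDoySmooth(wavy, doy)
  expect_lt(g1$pValue, 0.05)
  truth <- 0.3 * sin(2 * pi * g1$curve$doy / 365)
  # compare shapes after centering (the smooth absorbs the intercept)
  dev <- (g1$curve$fit - mean(g1$curve$fit)) - (truth - mean(truth))
  cover <- mean(abs(dev) <= 1.96 * g1$curve$se)
  expect_gt(cover, 0.8)
  expect_error(fitFpeDoySmooth(wavy[1:10], doy[1:10]), "20 fires")
  expect_error(fitFpeDoySmooth(wavy, rep(150:170, length.out = 300)),
               "60-day")
})
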