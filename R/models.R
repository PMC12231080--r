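# Statistical models of fire spread: Gaussian linear mixed models of
# log10 spread metrics on cover proportions (random intercept per fire),
# top-down covariate selection, and the FPE weather / day-of-year models.

#' Prepare a patch table for modelling
#'
#' Adds log10-transformed responses (both spread metrics are log-normally
#' distributed) and the aspen-cover subset flags. Patches with zero linear
#' spread (no-advance days) are floored at half a pixel before the log
#' transform.
#'
#' @param table patch data.frame with columns area_ha,
#'   max_linear_spread_m, aspen, fire_id
#' @param pixelSize cell size in meters used for the zero-spread floor
#'   (default 30)
#' @return The table with columns log10_area_ha, log10_linear_m and
#'   logical flags aspen_present (>= 0.1 percent), gt5 (> 5 percent),
#'   gt10 (> 10 percent).
#' @export
prepareResponse <- function(table, pixelSize = 30) {
  if (!nrow(table)) stop("patch table is empty")
  need <- c("area_ha", "max_linear_spread_m", "aspen", "fire_id")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  table$log10_area_ha <- log10(table$area_ha)
  table$log10_linear_m <-
    log10(pmax(table$max_linear_spread_m, pixelSize / 2))
  table$aspen_present <- table$aspen >= 0.001
  table$gt5 <- table$aspen > 0.05
  table$gt10 <- table$aspen > 0.10
  table
}

#' Fit a Gaussian linear mixed model of a spread metric
#'
#' Response (a log10 spread metric) on the given fixed-effect terms with a
#' random intercept per fire event to absorb between-fire differences.
#' When the random-effect fit is singular or fails to converge, the model
#' falls back to a fixed-effects-only least-squares fit with a warning.
#'
#' @param table modelling data.frame (see [prepareResponse()])
#' @param response response column name ("log10_area_ha" or
#'   "log10_linear_m")
#' @param fixedTerms character vector of fixed-effect column names
#' @param subset optional label recorded on the result (e.g. "gt5")
#' @return An object of class "SpreadModelResult": list with
#'   fixedEffects (term/estimate/se/statistic/p), randomVar, residualVar,
#'   aic, r2 (marginal, conditional), nPatches, nFires, subset, singular,
#'   and the underlying fit.
#' @export
fitMixed <- function(table, response, fixedTerms, subset = NA_character_) {
  if (length(unique(table$fire_id)) < 2) stop("need at least 2 fires")
  if (nrow(table) < 10) stop("need at least 10 patches")
  baseVars <- unique(unlist(strsplit(fixedTerms, ":", fixed = TRUE)))
  miss <- setdiff(c(response, baseVars, "fire_id"), names(table))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  fml <- stats::reformulate(c(fixedTerms, "(1 | fire_id)"), response)
  fit <- tryCatch(
    glmmTMB::glmmTMB(fml, data = table, family = stats::gaussian()),
    error = function(e) NULL, warning = function(w) NULL)
  singular <- is.null(fit) || !isTRUE(fit$sdr$pdHess)
  if (!singular) {
    co <- summary(fit)$coefficients$cond
    vc <- glmmTMB::VarCorr(fit)$cond
    randVar <- as.numeric(vc$fire_id[1, 1])
    residVar <- attr(vc, "sc")^2
    aic <- stats::AIC(fit)
    muF <- stats::predict(fit, re.form = NA)
  } else {
    warning("singular or non-converged mixed fit; ",
            "falling back to fixed effects only")
    fml2 <- stats::reformulate(fixedTerms, response)
    fit <- stats::lm(fml2, data = table)
    co <- summary(fit)$coefficients
    randVar <- 0
    residVar <- summary(fit)$sigma^2
    aic <- stats::AIC(fit)
    muF <- stats::fitted(fit)
  }
  varF <- stats::var(muF)
  r2m <- varF / (varF + randVar + residVar)
  r2c <- (varF + randVar) / (varF + randVar + residVar)
  structure(list(
    response = response,
    fixedEffects = data.frame(term = rownames(co), estimate = co[, 1],
                              se = co[, 2], statistic = co[, 3], p = co[, 4],
                              row.names = NULL, stringsAsFactors = FALSE),
    randomVar = randVar, residualVar = residVar, aic = aic,
    r2 = c(marginal = r2m, conditional = r2c),
    nPatches = nrow(table), nFires = length(unique(table$fire_id)),
    subset = subset, singular = singular, fit = fit),
    class = "SpreadModelResult")
}

#' @export
print.SpreadModelResult <- function(x, ...) {
  cat(sprintf("Spread model: %s ~ %s + (1 | fire_id)%s\n", x$response,
              paste(setdiff(x$fixedEffects$term, "(Intercept)"),
                    collapse = " + "),
              if (x$singular) " [singular: fixed-effects fallback]" else ""))
  cat(sprintf("  %d patches, %d fires%s; AIC %.1f; R2 marginal %.3f / conditional %.3f\n",
              x$nPatches, x$nFires,
              if (!is.na(x$subset)) paste0(" (subset ", x$subset, ")") else "",
              x$aic, x$r2[["marginal"]], x$r2[["conditional"]]))
  print(x$fixedEffects, digits = 3)
  invisible(x)
}

#' Per-cover-type contrast models
#'
#' One mixed model per cover type with that type's patch proportion as the
#' single fixed effect; used to contrast the aspen effect with the other
#' ten groups. Types absent from the table or with (near-)constant
#' proportions are skipped with a notice.
#'
#' @param table modelling data.frame
#' @param response response column name
#' @param types cover types to model (default all 11)
#' @return Named list of "SpreadModelResult"; skipped types in
#'   \code{attr(, "skipped")}.
#' @export
fitCoverContrasts <- function(table, response, types = coverTypes()) {
  out <- list(); skipped <- character()
  for (tp in types) {
    if (!tp %in% names(table) || stats::var(table[[tp]]) < 1e-12) {
      skipped <- c(skipped, tp)
      next
    }
    out[[tp]] <- fitMixed(table, response, tp)
  }
  if (length(skipped))
    message("skipped type(s) with no usable variation: ",
            paste(skipped, collapse = ", "))
  attr(out, "skipped") <- skipped
  out
}

#' Top-down covariate selection around the aspen effect
#'
#' Starting from a model with all candidate covariates as first-order
#' terms (aspen cover always retained): (1) drop covariates that are not
#' significant at \code{alpha}; (2) among surviving pairs with Pearson
#' |r| > \code{rThreshold}, keep the individually more predictive term
#' (lower single-term-model AIC); (3) test second-order interactions of
#' aspen cover with each survivor, retaining an interaction only if it is
#' significant and lowers AIC. If the resulting model has a higher AIC
#' than the initial all-terms model, the initial model is kept (AIC is the
#' fit criterion throughout).
#'
#' @param table modelling data.frame
#' @param response response column name
#' @param candidateTerms covariate column names entering selection
#' @param alpha significance level for dropping terms (default 0.05)
#' @param rThreshold collinearity cutoff on Pearson r (default 0.3)
#' @param protect term(s) never dropped (default "aspen")
#' @return List with \code{model} (a "SpreadModelResult") and \code{trace}
#'   (data.frame of actions: action, term, metric).
#' @export
selectModel <- function(table, response, candidateTerms, alpha = 0.05,
                        rThreshold = 0.3, protect = "aspen") {
  miss <- setdiff(candidateTerms, names(table))
  if (length(miss)) stop("missing candidate(s): ", paste(miss, collapse = ", "))
  trace <- data.frame(action = character(), term = character(),
                      metric = numeric(), stringsAsFactors = FALSE)
  note <- function(action, term, metric = NA_real_) {
    trace <<- rbind(trace, data.frame(action = action, term = term,
                                      metric = metric,
                                      stringsAsFactors = FALSE))
  }
  cands <- setdiff(candidateTerms, protect)
  initial <- fitMixed(table, response, c(protect, cands))
  # 1: drop non-significant covariates (Wald p >= alpha)
  fe <- initial$fixedEffects
  survivors <- character()
  for (tm in cands) {
    p <- fe$p[fe$term == tm]
    if (length(p) && !is.na(p) && p < alpha) survivors <- c(survivors, tm)
    else note("drop_nonsignificant", tm, if (length(p)) p else NA_real_)
  }
  # 2: collinearity pruning by single-term AIC
  singleAic <- function(tm) fitMixed(table, response, tm)$aic
  aics <- vapply(c(protect, survivors), singleAic, numeric(1))
  repeat {
    terms <- c(protect, survivors)
    if (length(terms) < 2) break
    cm <- stats::cor(table[, terms, drop = FALSE])
    diag(cm) <- 0
    worst <- which(abs(cm) == max(abs(cm)), arr.ind = TRUE)[1, ]
    if (max(abs(cm)) <= rThreshold) break
    a <- terms[worst[1]]; b <- terms[worst[2]]
    dropTerm <- if (a %in% protect) b
      else if (b %in% protect) a
      else if (aics[[a]] <= aics[[b]]) b else a
    survivors <- setdiff(survivors, dropTerm)
    note("drop_collinear", dropTerm, max(abs(cm)))
  }
  model <- fitMixed(table, response, c(protect, survivors))
  # 3: aspen x covariate interactions, kept only when significant and
  # AIC-improving
  kept <- character()
  for (tm in survivors) {
    ia <- paste0(protect[1], ":", tm)
    cand <- fitMixed(table, response, c(protect, survivors, kept, ia))
    pIa <- cand$fixedEffects$p[cand$fixedEffects$term == ia]
    if (length(pIa) && !is.na(pIa) && pIa < alpha && cand$aic < model$aic) {
      kept <- c(kept, ia)
      model <- cand
      note("add_interaction", ia, cand$aic)
    }
  }
  if (!length(survivors) && !length(kept))
    note("all_covariates_dropped", paste(protect, collapse = "+"))
  if (model$aic > initial$aic) {
    note("keep_initial_by_aic", "initial", initial$aic)
    model <- initial
  }
  list(model = model, trace = trace)
}

#' Simple linear models of per-fire FPE on covariate means
#'
#' One ordinary least-squares model per covariate of a cover type's
#' per-fire FPE on the fire's mean covariate value.
#'
#' @param fpeValues numeric per-fire FPE values
#' @param covariates data.frame of per-fire covariate means (rows aligned
#'   with \code{fpeValues})
#' @return data.frame with covariate, slope, se, p, r2; constant
#'   covariates are skipped.
#' @export
fitFpeCovariateLm <- function(fpeValues, covariates) {
  ok <- !is.na(fpeValues)
  if (sum(ok) < 10) stop("need at least 10 fires with defined FPE")
  rows <- list()
  for (nm in names(covariates)) {
    x <- covariates[[nm]][ok]
    if (stats::var(x) < 1e-12) next
    m <- stats::lm(fpeValues[ok] ~ x)
    sm <- summary(m)
    rows[[nm]] <- data.frame(covariate = nm,
                             slope = sm$coefficients[2, 1],
                             se = sm$coefficients[2, 2],
                             p = sm$coefficients[2, 4],
                             r2 = sm$r.squared, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Penalized smooth of FPE on day of year
#'
#' Univariate GAM testing for a nonlinear seasonal relationship between a
#' cover type's per-fire FPE and the fire's day of year, with a
#' thin-plate smooth (basis dimension k, default 10, selected by
#' penalization).
#'
#' @param fpeValues numeric per-fire FPE values
#' @param doy day-of-year per fire (1..366)
#' @param k smooth basis dimension (default 10)
#' @return List with edf, pValue, r2, and \code{curve}: a data.frame of
#'   the fitted smooth (doy, fit, se) on a 100-point grid.
#' @export
fitFpeDoySmooth <- function(fpeValues, doy, k = 10) {
  ok <- !is.na(fpeValues) & !is.na(doy)
  if (sum(ok) < 20) stop("need at least 20 fires with defined FPE")
  if (diff(range(doy[ok])) < 60)
    stop("need at least a 60-day span of day-of-year values")
  df <- data.frame(fpe = fpeValues[ok], doy = doy[ok])
  g <- mgcv::gam(fpe ~ s(doy, k = k), data = df)
  sm <- summary(g)
  grid <- data.frame(doy = seq(min(df$doy), max(df$doy), length.out = 100))
  pr <- mgcv::predict.gam(g, newdata = grid, se.fit = TRUE)
  list(edf = unname(sm$s.table[1, "edf"]),
       pValue = unname(sm$s.table[1, "p-value"]),
       r2 = sm$r.sq,
       curve = data.frame(doy = grid$doy, fit = as.numeric(pr$fit),
                          se = as.numeric(pr$se.fit)),
       fit = g)
}
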