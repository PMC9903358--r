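#' Random-forest permutation-importance filter with decorrelation
#'
#' Stage one of the variable-selection pipeline: fits a permutation-
#' importance random forest of the response on a (potentially large)
#' covariate table, ranks predictors by mean increase in MSE after
#' permutation, keeps the `top_k` most important, then greedily removes
#' correlated pairs -- for any retained pair with `|Pearson r| >=`
#' `cor_threshold`, the lower-importance member is dropped so each retained
#' predictor contributes unique information.
#'
#' @param x data.frame of numeric predictors.
#' @param y numeric response (e.g. site mean B-IBI).
#' @param n_trees number of trees (default 3000).
#' @param top_k number of top-ranked predictors kept before decorrelation
#'   (default 15; capped at the number of predictors).
#' @param cor_threshold absolute-correlation cut (default 0.70).
#' @param seed integer seed; the ranking is deterministic given the seed.
#' @return List of class `selection_result`: `importance` (named, sorted
#'   decreasing), `top` (names before decorrelation), `retained` (names
#'   after), and `decisions` (data.frame of kept/dropped pairs with r).
#' @export
rf_importance_filter <- function(x, y, n_trees = 3000, top_k = 15,
                                 cor_threshold = 0.70, seed = NULL) {
  if (ncol(x) < 2L) stop("need at least 2 predictors")
  if (!all(vapply(x, is.numeric, logical(1)))) {
    stop("all predictors must be numeric")
  }
  if (!is.null(seed)) set.seed(seed)
  rf <- randomForest::randomForest(x = x, y = y, ntree = n_trees,
                                   importance = TRUE)
  imp <- randomForest::importance(rf, type = 1)[, 1]
  imp <- sort(imp, decreasing = TRUE)
  top <- names(imp)[seq_len(min(top_k, length(imp)))]

  retained <- character(0)
  decisions <- data.frame(kept = character(0), dropped = character(0),
                          r = numeric(0))
  for (v in top) { # in decreasing importance order
    r_with <- if (length(retained) > 0L) {
      vapply(retained, function(u) stats::cor(x[[u]], x[[v]]), numeric(1))
    } else numeric(0)
    clash <- which(abs(r_with) >= cor_threshold)
    if (length(clash) == 0L) {
      retained <- c(retained, v)
    } else {
      decisions <- rbind(decisions, data.frame(
        kept = retained[clash[1]], dropped = v, r = r_with[clash[1]]))
    }
  }
  structure(list(importance = imp, top = top, retained = retained,
                 decisions = decisions),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result> ", length(x$importance), " predictors ranked; ",
      length(x$retained), " retained after decorrelation\n", sep = "")
  cat("retained:", paste(x$retained, collapse = ", "), "\n")
  invisible(x)
}

#' Centre and scale predictors
#'
#' Standardizes every column to sample mean 0 and sample standard deviation
#' 1 (n-1 denominator) so coefficients are comparable across predictors
#' with different units. Zero-variance columns are dropped with a warning.
#'
#' @param data data.frame of numeric predictors.
#' @return Standardized data.frame with attributes `center` and `scale`.
#' @export
center_scale <- function(data) {
  sds <- vapply(data, stats::sd, numeric(1))
  drop <- names(sds)[is.na(sds) | sds == 0]
  if (length(drop) > 0L) {
    warning("dropping zero-variance predictor(s): ",
            paste(drop, collapse = ", "))
    data <- data[setdiff(names(data), drop)]
    sds <- sds[setdiff(names(sds), drop)]
  }
  mus <- vapply(data, mean, numeric(1))
  out <- as.data.frame(mapply(function(col, m, s) (col - m) / s,
                              data, mus, sds, SIMPLIFY = FALSE))
  attr(out, "center") <- mus
  attr(out, "scale") <- sds
  out
}

#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R2_j), where R2_j comes from regressing predictor j on
#' all the others; values near 1 mean the predictor is nearly orthogonal to
#' the rest, and exact collinearity gives `Inf`.
#'
#' @param data data.frame of numeric predictors (>= 2 columns).
#' @return Named numeric vector of VIFs.
#' @export
vif_values <- function(data) {
  if (ncol(data) < 2L) stop("VIF needs at least 2 predictors")
  vapply(names(data), function(j) {
    fit <- stats::lm(stats::reformulate(setdiff(names(data), j), j),
                     data = data)
    # exact collinearity is expected here and surfaces as an infinite VIF;
    # silence the "essentially perfect fit" chatter from summary.lm
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Iterative VIF screening
#'
#' Repeatedly removes the predictor with the largest VIF until every
#' remaining VIF is at or below `threshold` (or one predictor remains);
#' exactly collinear members surface as infinite VIFs and are dropped
#' first.
#'
#' @param data data.frame of numeric predictors.
#' @param threshold VIF cut (default 2.5).
#' @return List: `data` (screened table), `dropped` (data.frame of removed
#'   predictors with the VIF at removal), `vif` (final VIFs).
#' @export
vif_screen <- function(data, threshold = 2.5) {
  dropped <- data.frame(predictor = character(0), vif = numeric(0))
  while (ncol(data) >= 2L) {
    v <- vif_values(data)
    if (max(v) <= threshold) break
    worst <- names(v)[which.max(v)]
    dropped <- rbind(dropped,
                     data.frame(predictor = worst, vif = max(v)))
    data <- data[setdiff(names(data), worst)]
  }
  final_vif <- if (ncol(data) >= 2L) vif_values(data) else
    stats::setNames(rep(1, ncol(data)), names(data))
  list(data = data, dropped = dropped, vif = final_vif)
}

#' Backward-forward stepwise-AIC regression with a significance filter
#'
#' Starts from the full linear model and performs a backward-forward
#' stepwise search minimizing AIC (Gaussian log-likelihood form); at the
#' AIC optimum, terms whose coefficients are not significant at `alpha` are
#' removed one at a time (worst p first, refitting each time) until every
#' remaining term has `p < alpha`. If nothing survives, the intercept-only
#' model is returned with `no_significant = TRUE`.
#'
#' @param data data.frame holding the response and (screened, standardized)
#'   predictors.
#' @param response name of the response column.
#' @param predictors predictor names (default: all other columns).
#' @param alpha significance level for the post-AIC filter (default 0.05).
#' @return List of class `landscape_model`: `fit` (the final `lm`),
#'   `predictors`, `coefficients` (term, estimate, std_error, t, p),
#'   `adj_r2`, `f_statistic`, `f_p` (overall model test), `aic_trace`
#'   (data.frame of the stepwise moves), `sig_dropped` (terms removed by
#'   the significance filter) and `no_significant`.
#' @export
stepwise_aic <- function(data, response, predictors = NULL, alpha = 0.05) {
  if (is.null(predictors)) predictors <- setdiff(names(data), response)
  if (length(predictors) == 0L) stop("no predictors supplied")
  full <- stats::lm(stats::reformulate(predictors, response), data = data)
  scope <- list(lower = stats::reformulate("1", response),
                upper = stats::formula(full))
  step_fit <- stats::step(full, scope = scope, direction = "both", trace = 0)
  trace <- step_fit$anova
  aic_trace <- data.frame(step = trimws(as.character(trace$Step)),
                          aic = trace$AIC)
  aic_trace$step[aic_trace$step == ""] <- "<start>"

  fit <- step_fit
  sig_dropped <- character(0)
  repeat {
    terms_now <- attr(stats::terms(fit), "term.labels")
    if (length(terms_now) == 0L) break
    ct <- summary(fit)$coefficients
    ct <- ct[setdiff(rownames(ct), "(Intercept)"), , drop = FALSE]
    p <- stats::setNames(ct[, 4], rownames(ct))
    if (all(p < alpha)) break
    worst <- names(p)[which.max(p)]
    sig_dropped <- c(sig_dropped, worst)
    terms_now <- setdiff(terms_now, worst)
    fit <- if (length(terms_now) == 0L) {
      stats::lm(stats::reformulate("1", response), data = data)
    } else {
      stats::lm(stats::reformulate(terms_now, response), data = data)
    }
  }
  final_terms <- attr(stats::terms(fit), "term.labels")
  sm <- summary(fit)
  coefs <- as.data.frame(sm$coefficients)
  names(coefs) <- c("estimate", "std_error", "t", "p")
  coefs <- cbind(term = rownames(coefs), coefs)
  rownames(coefs) <- NULL
  fstat <- sm$fstatistic
  f_p <- if (is.null(fstat)) NA_real_ else
    unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  structure(list(
    fit = fit, predictors = final_terms, coefficients = coefs,
    adj_r2 = sm$adj.r.squared,
    f_statistic = if (is.null(fstat)) NA_real_ else unname(fstat[1]),
    f_p = f_p, aic_trace = aic_trace, sig_dropped = sig_dropped,
    no_significant = length(final_terms) == 0L),
    class = "landscape_model")
}

#' @export
print.landscape_model <- function(x, ...) {
  if (x$no_significant) {
    cat("<landscape_model> intercept-only: no significant predictors\n")
  } else {
    cat("<landscape_model> ", length(x$predictors), " predictor(s), adj R2 = ",
        round(x$adj_r2, 3), "\n", sep = "")
    print(x$coefficients, digits = 3)
  }
  invisible(x)
}

#' Residual diagnostics for a fitted model
#'
#' Breusch-Pagan test for heteroscedasticity (studentized form), a
#' Shapiro-Wilk normality test plus residual skewness and excess kurtosis,
#' and a binned residual-versus-fitted summary table for plotting. An
#' exact-fit model (all residuals zero) returns a Breusch-Pagan statistic
#' of 0.
#'
#' @param model a `landscape_model` or an `lm` fit.
#' @param bins number of fitted-value bins for the residual table
#'   (default 5).
#' @return List of class `model_diagnostics`: `bp_statistic`, `bp_p`,
#'   `shapiro_statistic`, `shapiro_p`, `skewness`, `kurtosis_excess`,
#'   `residual_table`.
#' @export
model_diagnostics <- function(model, bins = 5L) {
  fit <- if (inherits(model, "landscape_model")) model$fit else model
  r <- stats::residuals(fit)
  f <- stats::fitted(fit)
  n <- length(r)
  if (stats::sd(r) < 1e-12 ||
      length(attr(stats::terms(fit), "term.labels")) == 0L) {
    bp_stat <- 0
    bp_p <- 1
  } else {
    bp <- lmtest::bptest(fit)
    bp_stat <- unname(bp$statistic)
    bp_p <- unname(bp$p.value)
  }
  sw_stat <- NA_real_
  sw_p <- NA_real_
  if (n >= 3L && n <= 5000L && stats::sd(r) > 1e-12) {
    sw <- stats::shapiro.test(r)
    sw_stat <- unname(sw$statistic)
    sw_p <- unname(sw$p.value)
  }
  m2 <- mean((r - mean(r))^2)
  skew <- if (m2 > 0) mean((r - mean(r))^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((r - mean(r))^4) / m2^2 - 3 else 0
  brk <- unique(stats::quantile(f, probs = seq(0, 1, length.out = bins + 1),
                                type = 7, names = FALSE))
  bin <- cut(f, breaks = brk, include.lowest = TRUE)
  tab <- data.frame(
    bin = levels(bin),
    n = as.integer(table(bin)),
    mean_fitted = as.numeric(tapply(f, bin, mean)),
    mean_residual = as.numeric(tapply(r, bin, mean)),
    sd_residual = as.numeric(tapply(r, bin, stats::sd)))
  structure(list(bp_statistic = bp_stat, bp_p = bp_p,
                 shapiro_statistic = sw_stat, shapiro_p = sw_p,
                 skewness = skew, kurtosis_excess = kurt,
                 residual_table = tab),
            class = "model_diagnostics")
}

#' @export
print.model_diagnostics <- function(x, ...) {
  cat("<model_diagnostics> BP = ", round(x$bp_statistic, 3), " (p = ",
      signif(x$bp_p, 3), "); Shapiro-Wilk p = ", signif(x$shapiro_p, 3),
      "; skew = ", round(x$skewness, 3), "; excess kurtosis = ",
      round(x$kurtosis_excess, 3), "\n", sep = "")
  invisible(x)
}

#' Per-predictor variance decomposition of a final model
#'
#' For each predictor in the final model, reports the adjusted R2 of the
#' simple one-predictor regression of the response on it (the variation in
#' the response explained by that predictor alone), the sign of its
#' coefficient in the full model, and -- as an alternative view -- a
#' sequential (order-of-entry) R2 decomposition from the fitted model's
#' ANOVA. Univariate R2 values over correlated predictors need not sum to
#' the model fit.
#'
#' @param data the data.frame the model was fitted on.
#' @param response name of the response column.
#' @param model a `landscape_model` (or `lm`) whose terms are columns of
#'   `data`.
#' @return data.frame (term, direction, univariate_adj_r2, sequential_r2)
#'   with the full-model adjusted R2 as attribute `model_adj_r2`.
#' @export
univariate_r2_decomposition <- function(data, response, model) {
  fit <- if (inherits(model, "landscape_model")) model$fit else model
  terms_ <- attr(stats::terms(fit), "term.labels")
  if (length(terms_) == 0L) {
    out <- data.frame(term = character(0), direction = character(0),
                      univariate_adj_r2 = numeric(0),
                      sequential_r2 = numeric(0))
    attr(out, "model_adj_r2") <- summary(fit)$adj.r.squared
    return(out)
  }
  coefs <- stats::coef(fit)[terms_]
  uni <- vapply(terms_, function(v) {
    summary(stats::lm(stats::reformulate(v, response),
                      data = data))$adj.r.squared
  }, numeric(1))
  an <- stats::anova(fit)
  ss <- an[["Sum Sq"]]
  seq_r2 <- stats::setNames(ss[seq_along(terms_)] / sum(ss), terms_)
  out <- data.frame(term = terms_,
                    direction = ifelse(coefs > 0, "positive", "negative"),
                    univariate_adj_r2 = unname(uni),
                    sequential_r2 = unname(seq_r2[terms_]))
  rownames(out) <- NULL
  attr(out, "model_adj_r2") <- summary(fit)$adj.r.squared
  out
}

#' Fit the full landscape regression pipeline
#'
#' Convenience wrapper running the regression stage end to end: centre and
#' scale the predictors, screen them iteratively by VIF, run the
#' backward-forward stepwise-AIC search with the significance filter, and
#' attach diagnostics and the per-predictor variance decomposition.
#'
#' @param data data.frame with the response and raw predictor columns.
#' @param response name of the response column.
#' @param predictors predictor names (default: all other numeric columns).
#' @param vif_threshold VIF cut (default 2.5).
#' @param alpha significance level (default 0.05).
#' @return List of class `landscape_fit`: `model` ([stepwise_aic()]
#'   result), `diagnostics`, `decomposition`, `vif` (final VIFs),
#'   `vif_dropped`, `scaled` (the standardized analysis table).
#' @export
fit_landscape_model <- function(data, response, predictors = NULL,
                                vif_threshold = 2.5, alpha = 0.05) {
  if (is.null(predictors)) {
    predictors <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                          response)
  }
  z <- center_scale(data[predictors])
  scr <- if (ncol(z) >= 2L) vif_screen(z, vif_threshold) else
    list(data = z, dropped = data.frame(predictor = character(0),
                                        vif = numeric(0)),
         vif = stats::setNames(rep(1, ncol(z)), names(z)))
  tab <- cbind(scr$data, stats::setNames(data.frame(data[[response]]),
                                         response))
  model <- stepwise_aic(tab, response, names(scr$data), alpha)
  structure(list(model = model,
                 diagnostics = model_diagnostics(model),
                 decomposition = univariate_r2_decomposition(tab, response,
                                                             model),
                 vif = scr$vif, vif_dropped = scr$dropped, scaled = tab),
            class = "landscape_fit")
}

#' @export
print.landscape_fit <- function(x, ...) {
  print(x$model)
  print(x$diagnostics)
  invisible(x)
}
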