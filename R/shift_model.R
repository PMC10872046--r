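#' Weighted least-squares fit of shift on niche metrics and traits
#'
#' Fits \eqn{\min_\beta \sum_i w_i (y_i - x_i'\beta)^2} with the species'
#' inverse-CI-width weights. Continuous covariates are scaled and centred
#' (mean 0, SD 1) before fitting, so coefficients are km per SD of the
#' covariate; categorical covariates enter with treatment coding against a
#' declared reference level. The Gaussian log-likelihood is
#' \deqn{\ell = \tfrac12\left[\sum_i \log w_i - n(\log 2\pi + 1 +
#'   \log(RSS_w/n))\right]}
#' and AIC = -2 l + 2 (k + 1), counting the error variance as an estimated
#' parameter. R-squared values use weighted sums of squares about the
#' weighted mean; predicted R-squared uses the leverage-based weighted PRESS
#' \eqn{\sum_i w_i (e_i / (1 - h_{ii}))^2} and may be negative.
#'
#' @param data regression table (e.g. from [assemble_model_table()]).
#' @param predictors character vector of predictor column names (possibly
#'   empty for the intercept-only model). A factor counts as one predictor.
#' @param response response column name (default \code{"shift_km"}).
#' @param weight_col weight column name, or \code{NULL} for unit weights.
#' @param reference_levels optional named list giving the reference level of
#'   each categorical predictor (default: first level in sort order).
#' @return object of class \code{wls_fit}: the underlying \code{lm}, the
#'   standardization constants, \code{n}, \code{k}, \code{logLik},
#'   \code{AIC}, \code{r_squared}, \code{adj_r_squared}, \code{pred_r_squared},
#'   \code{rss_w}, a coefficient table, leverages and weighted residuals.
#' @export
wls_fit <- function(data, predictors, response = "shift_km",
                    weight_col = "weight", reference_levels = NULL) {
  .require_cols(data, c(response, predictors), "data")
  w <- if (is.null(weight_col)) rep(1, nrow(data)) else data[[weight_col]]
  if (any(!is.finite(w)) || any(w <= 0))
    stop("weights must be strictly positive and finite", call. = FALSE)

  df <- data.frame(.y = data[[response]])
  centers <- scales <- numeric(0)
  for (p in predictors) {
    v <- data[[p]]
    if (is.numeric(v)) {
      s <- stats::sd(v)
      if (!is.finite(s) || s == 0)
        stop(sprintf("continuous predictor '%s' has zero variance", p),
             call. = FALSE)
      centers[p] <- mean(v); scales[p] <- s
      df[[p]] <- (v - mean(v)) / s
    } else {
      f <- factor(v)
      ref <- reference_levels[[p]]
      if (!is.null(ref)) {
        if (!ref %in% levels(f))
          stop(sprintf("reference level '%s' not found in '%s'", ref, p),
               call. = FALSE)
        f <- stats::relevel(f, ref)
      }
      df[[p]] <- f
    }
  }
  form <- if (length(predictors))
    stats::reformulate(predictors, response = ".y") else .y ~ 1
  fit <- stats::lm(form, data = df, weights = w)
  if (nrow(df) <= fit$rank)
    stop("n must exceed the number of estimated coefficients", call. = FALSE)
  if (anyNA(stats::coef(fit)))
    stop(sprintf("rank-deficient design; aliased: %s",
                 paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                       collapse = ", ")), call. = FALSE)

  sm <- summary(fit)
  e <- stats::residuals(fit)
  h <- stats::hatvalues(fit)
  rss_w <- sum(w * e^2)
  ybar_w <- sum(w * df$.y) / sum(w)
  tss_w <- sum(w * (df$.y - ybar_w)^2)
  press_w <- sum(w * (e / (1 - h))^2)
  k <- fit$rank
  n <- nrow(df)
  r2 <- if (tss_w > 0) 1 - rss_w / tss_w else 1
  out <- list(
    lm = fit,
    predictors = predictors,
    response = response,
    centers = centers, scales = scales,
    weights = w,
    n = n, k = k,
    logLik = as.numeric(stats::logLik(fit)),
    AIC = stats::AIC(fit),
    r_squared = r2,
    adj_r_squared = 1 - (1 - r2) * (n - 1) / (n - k),
    pred_r_squared = if (tss_w > 0) 1 - press_w / tss_w else NA_real_,
    rss_w = rss_w, tss_w = tss_w, press_w = press_w,
    coefficients = sm$coefficients,
    leverage = h,
    weighted_residuals = sqrt(w) * e)
  class(out) <- "wls_fit"
  out
}

#' @export
print.wls_fit <- function(x, ...) {
  cat(sprintf("Weighted LS fit: %s ~ %s\n", x$response,
              if (length(x$predictors)) paste(x$predictors, collapse = " + ")
              else "1"))
  cat(sprintf("n = %d, k = %d, AIC = %.4f, R2 = %.4f (adj %.4f, pred %.4f)\n",
              x$n, x$k, x$AIC, x$r_squared, x$adj_r_squared,
              x$pred_r_squared))
  stats::printCoefmat(x$coefficients, ...)
  invisible(x)
}

#' Exhaustive best-subsets enumeration of weighted regressions
#'
#' Fits one weighted regression per subset of the candidate predictors
#' (including the intercept-only model), \code{2^p} models in total, and
#' flags the best model of each subset size by R-squared (equivalently,
#' lowest weighted RSS). Multi-level factors enter or leave as a block.
#' Subsets whose fit fails (e.g. rank deficiency) are recorded as failed and
#' enumeration continues.
#'
#' @param data regression table.
#' @param candidates character vector of candidate predictor columns.
#' @param ... passed to [wls_fit()].
#' @return object of class \code{best_subsets}: \code{summary} (data frame
#'   with subset id, predictor list, size, R2, adjusted R2, predicted R2,
#'   AIC, per-size-best flag), \code{models} (list of \code{wls_fit} or
#'   \code{NULL} for failures), \code{candidates}.
#' @export
best_subsets <- function(data, candidates, ...) {
  p <- length(candidates)
  stopifnot(p >= 1)
  n_sub <- 2^p
  rows <- vector("list", n_sub)
  models <- vector("list", n_sub)
  for (i in seq_len(n_sub) - 1L) {
    sel <- candidates[bitwAnd(i, bitwShiftL(1L, seq_len(p) - 1L)) != 0L]
    fit <- tryCatch(wls_fit(data, sel, ...), error = function(e) e)
    if (inherits(fit, "error")) {
      rows[[i + 1L]] <- data.frame(
        subset = i, predictors = paste(sel, collapse = " + "),
        size = length(sel), r_squared = NA_real_,
        adj_r_squared = NA_real_, pred_r_squared = NA_real_,
        AIC = NA_real_, failed = TRUE)
    } else {
      models[[i + 1L]] <- fit
      rows[[i + 1L]] <- data.frame(
        subset = i, predictors = paste(sel, collapse = " + "),
        size = length(sel), r_squared = fit$r_squared,
        adj_r_squared = fit$adj_r_squared,
        pred_r_squared = fit$pred_r_squared,
        AIC = fit$AIC, failed = FALSE)
    }
  }
  summ <- do.call(rbind, rows)
  summ$best_of_size <- FALSE
  for (s in unique(summ$size)) {
    idx <- which(summ$size == s & !summ$failed)
    if (length(idx))
      summ$best_of_size[idx[which.max(summ$r_squared[idx])]] <- TRUE
  }
  out <- list(summary = summ, models = models, candidates = candidates)
  class(out) <- "best_subsets"
  out
}

#' @export
print.best_subsets <- function(x, ...) {
  cat(sprintf("best_subsets: %d models over %d candidates\n",
              nrow(x$summary), length(x$candidates)))
  print(x$summary[x$summary$best_of_size,
                  c("predictors", "size", "adj_r_squared", "pred_r_squared",
                    "r_squared", "AIC")],
        row.names = FALSE, ...)
  invisible(x)
}

#' Choose the final model by the AIC parsimony rule
#'
#' From the per-size best models, the chosen model is the one with the
#' smallest number of predictors whose AIC is within \code{delta} (default 2)
#' units of the global minimum AIC: a less parsimonious model is accepted
#' only when its AIC is at least \code{delta} units lower, since models
#' within \code{delta} units carry the same information value. Ties in size
#' go to the lower AIC.
#'
#' @param x a \code{best_subsets} object, a data frame with \code{size} and
#'   \code{AIC} columns (one row per per-size best), or a bare numeric vector
#'   of AICs taken to correspond to sizes 1, 2, ... in order.
#' @param delta AIC tolerance (default 2).
#' @return list of class \code{selection_result}: \code{chosen_size},
#'   \code{chosen_predictors} (when available), \code{chosen_model} (the
#'   \code{wls_fit}, when available), \code{per_size} (data frame with size,
#'   AIC, delta to the minimum and the qualifying flag), \code{delta}.
#' @export
select_final <- function(x, delta = 2) {
  if (inherits(x, "best_subsets")) {
    ps <- x$summary[x$summary$best_of_size & x$summary$size > 0, , drop = FALSE]
    ps <- ps[order(ps$size), ]
    tab <- data.frame(size = ps$size, AIC = ps$AIC,
                      predictors = ps$predictors,
                      stringsAsFactors = FALSE)
    model_idx <- ps$subset + 1L
  } else if (is.data.frame(x)) {
    .require_cols(x, c("size", "AIC"), "per-size table")
    tab <- x[order(x$size), , drop = FALSE]
    model_idx <- NULL
  } else {
    tab <- data.frame(size = seq_along(x), AIC = as.numeric(x))
    model_idx <- NULL
  }
  if (!nrow(tab) || any(!is.finite(tab$AIC)))
    stop("per-size AICs must be non-empty and finite", call. = FALSE)
  amin <- min(tab$AIC)
  tab$delta_aic <- tab$AIC - amin
  tab$qualifies <- tab$delta_aic <= delta
  cand <- which(tab$qualifies)
  # smallest size; among ties in size, lowest AIC
  sizes <- tab$size[cand]
  best <- cand[order(sizes, tab$AIC[cand])][1]
  out <- list(chosen_size = tab$size[best],
              chosen_predictors = if ("predictors" %in% names(tab))
                tab$predictors[best] else NULL,
              chosen_model = if (!is.null(model_idx) &&
                                 inherits(x, "best_subsets"))
                x$models[[model_idx[best]]] else NULL,
              per_size = tab, delta = delta)
  class(out) <- "selection_result"
  out
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selected size %d (delta AIC rule, delta = %g)\n",
              x$chosen_size, x$delta))
  if (!is.null(x$chosen_predictors))
    cat("predictors:", x$chosen_predictors, "\n")
  print(x$per_size, row.names = FALSE)
  invisible(x)
}

#' Single-term deletion table for a weighted fit
#'
#' Removes each predictor (a factor as a block) in turn and reports the
#' change in degrees of freedom, the increase in weighted residual sum of
#' squares, the reduced model's RSS and its AIC, on the same rows as the full
#' model. AIC here is on the deviance scale used by single-term-deletion
#' tables (\code{n log(RSS/n) + 2 k}, additive constants dropped), computed
#' via [stats::drop1()].
#'
#' @param fit a \code{wls_fit} with at least one predictor.
#' @return data frame: \code{dropped}, \code{df}, \code{delta_ss},
#'   \code{rss}, \code{aic}; first row \code{<none>} is the full model.
#' @export
drop1_table <- function(fit) {
  stopifnot(inherits(fit, "wls_fit"))
  if (!length(fit$predictors))
    stop("model has no predictor to drop", call. = FALSE)
  d1 <- stats::drop1(fit$lm, test = "none")
  out <- data.frame(dropped = rownames(d1),
                    df = d1$Df,
                    delta_ss = d1$`Sum of Sq`,
                    rss = d1$RSS,
                    aic = d1$AIC,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Diagnostics for a weighted fit
#'
#' Normality of weighted residuals (Shapiro-Wilk), heteroscedasticity
#' (studentized Breusch-Pagan: n times the R-squared of the squared weighted
#' residuals regressed on the design, chi-squared with k - 1 df),
#' collinearity (generalized variance inflation factors per predictor block,
#' computed from the correlation matrix of the weighted design), and
#' influential observations (Cook's distance, flagged above 4 / n).
#'
#' @param fit a \code{wls_fit}.
#' @return list: \code{shapiro} (statistic, p), \code{breusch_pagan}
#'   (statistic, df, p), \code{vif} (named vector of GVIF per predictor, or
#'   \code{NULL} for models with < 2 predictors where collinearity is
#'   undefined), \code{cooks} (distances), \code{influential} (row indices
#'   with Cook's distance > 4/n), \code{n}.
#' @export
model_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "wls_fit"))
  if (fit$n < 3) {
    warning("fewer than 3 observations: diagnostics skipped", call. = FALSE)
    return(NULL)
  }
  r <- fit$weighted_residuals
  sw <- stats::shapiro.test(r)

  mm <- stats::model.matrix(fit$lm)
  X <- sqrt(fit$weights) * mm
  bp <- NULL
  if (fit$k > 1) {
    u <- r^2
    aux <- stats::lm.fit(X, u)
    r2_aux <- 1 - sum(aux$residuals^2) / sum((u - mean(u))^2)
    stat <- fit$n * r2_aux
    df <- fit$k - 1
    bp <- list(statistic = stat, df = df,
               p_value = stats::pchisq(stat, df, lower.tail = FALSE))
  }

  vif <- NULL
  terms_assign <- attr(mm, "assign")
  blocks <- unique(terms_assign[terms_assign > 0])
  if (length(blocks) >= 2) {
    Xc <- X[, terms_assign > 0, drop = FALSE]
    R <- stats::cor(Xc)
    detR <- det(R)
    asg <- terms_assign[terms_assign > 0]
    vif <- vapply(blocks, function(b) {
      i <- asg == b
      det(R[i, i, drop = FALSE]) * det(R[!i, !i, drop = FALSE]) / detR
    }, numeric(1))
    names(vif) <- attr(stats::terms(fit$lm), "term.labels")[blocks]
  }

  cd <- stats::cooks.distance(fit$lm)
  list(shapiro = list(statistic = unname(sw$statistic),
                      p_value = sw$p.value),
       breusch_pagan = bp,
       vif = vif,
       cooks = unname(cd),
       influential = which(unname(cd) > 4 / fit$n),
       n = fit$n)
}

#' Prediction profile over one continuous covariate
#'
#' Predicted shifts over a grid from the minimum to the maximum of the focus
#' covariate (in its original units), holding all other continuous covariates
#' at their means, with one curve per combination of levels of any
#' categorical predictors in the model.
#'
#' @param fit a \code{wls_fit}.
#' @param focus name of a continuous predictor in the model.
#' @param n_grid grid resolution (default 100).
#' @return data frame: \code{focus} value column (original units), one column
#'   per categorical predictor in the model, and \code{predicted}.
#' @export
predict_profile <- function(fit, focus, n_grid = 100) {
  stopifnot(inherits(fit, "wls_fit"))
  if (!focus %in% names(fit$centers))
    stop(sprintf("'%s' is not a continuous predictor of the model", focus),
         call. = FALSE)
  # original-unit range of the focus variable, back-transformed
  z <- fit$lm$model[[focus]]
  orig <- z * fit$scales[focus] + fit$centers[focus]
  grid_orig <- seq(min(orig), max(orig), length.out = n_grid)

  cont <- setdiff(names(fit$centers), focus)
  cats <- fit$predictors[!fit$predictors %in% names(fit$centers)]
  base <- list()
  base[[focus]] <- (grid_orig - fit$centers[focus]) / fit$scales[focus]
  for (p in cont) base[[p]] <- 0  # standardized mean
  if (length(cats)) {
    combos <- expand.grid(lapply(cats, function(p)
      levels(fit$lm$model[[p]])), stringsAsFactors = FALSE)
    names(combos) <- cats
  } else {
    combos <- data.frame(row.names = 1)
  }
  out <- list()
  for (ci in seq_len(max(1L, nrow(combos)))) {
    nd <- as.data.frame(base)
    for (p in cats)
      nd[[p]] <- factor(combos[ci, p], levels = levels(fit$lm$model[[p]]))
    pred <- stats::predict(fit$lm, newdata = nd)
    row <- data.frame(grid_orig, stringsAsFactors = FALSE)
    names(row) <- focus
    for (p in cats) row[[p]] <- combos[ci, p]
    row$predicted <- as.numeric(pred)
    out[[ci]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
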