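#' Fit the error-response regression
#'
#' Ordinary least squares of `error_abs` (kcal/mol) on a chosen set of
#' predictor columns, with the bookkeeping the rest of the pipeline needs:
#' Gaussian maximum log-likelihood, the BIC convention used for model search,
#' adjusted R-squared, and the factorization required for exact out-of-sample
#' prediction intervals. Exactly aliased (collinear or constant) columns are
#' dropped with a warning and recorded, so that held-out rows carrying a
#' predictor level unseen in training fall back to the reference-level
#' contribution.
#'
#' A perfect fit (RSS = 0) is allowed — intervals then have zero width — but
#' its log-likelihood is undefined; `rss_floor = TRUE` substitutes
#' `1e-12 * n * var(y)` so BIC stays finite in degenerate synthetic cases.
#'
#' @param table Data frame containing `response` and the predictor columns
#'   (typically from [build_predictor_table()]).
#' @param predictors Character vector of predictor column names; `character(0)`
#'   fits the intercept-only model.
#' @param response Response column name (default `"error_abs"`).
#' @param rss_floor Apply the epsilon floor to RSS when computing the
#'   log-likelihood (default `FALSE`).
#' @return An object of class `error_model`.
#' @examples
#' d <- generate_dataset(synthetic_config(n_systems = 3, n_per_system = 20, seed = 1))
#' pt <- build_predictor_table(d, "model3")
#' fit_ols(pt, c("vdw_mean", "total_mean"))
#' @export
fit_ols <- function(table, predictors, response = "error_abs",
                    rss_floor = FALSE) {
  table <- tibble::as_tibble(table)
  if (!response %in% names(table)) stop("response column not found: ", response)
  missing <- setdiff(predictors, names(table))
  if (length(missing) > 0) {
    stop("predictor column(s) not found: ", paste(missing, collapse = ", "))
  }
  n <- nrow(table)
  if (n <= length(predictors) + 1) {
    stop("need n > p: n = ", n, ", predictors = ", length(predictors))
  }

  dat <- table[c(response, predictors)]
  fml <- if (length(predictors) == 0) {
    as.formula(paste(response, "~ 1"))
  } else {
    as.formula(paste(response, "~", paste0("`", predictors, "`", collapse = " + ")))
  }
  fit <- lm(fml, data = dat)

  dropped <- character(0)
  if (anyNA(coef(fit))) {
    dropped <- predictors[paste0("`", predictors, "`") %in%
                            names(coef(fit))[is.na(coef(fit))] |
                          predictors %in% names(coef(fit))[is.na(coef(fit))]]
    warning("dropping aliased predictor(s): ", paste(dropped, collapse = ", "))
    kept <- setdiff(predictors, dropped)
    fml <- if (length(kept) == 0) {
      as.formula(paste(response, "~ 1"))
    } else {
      as.formula(paste(response, "~", paste0("`", kept, "`", collapse = " + ")))
    }
    fit <- lm(fml, data = dat)
    predictors_kept <- kept
  } else {
    predictors_kept <- predictors
  }

  rss <- sum(fit$residuals^2)
  d <- length(coef(fit)) - 1L          # slope coefficients, dummies counted singly
  df_resid <- fit$df.residual
  if (df_resid < 1) stop("no residual degrees of freedom")
  y <- dat[[response]]
  degenerate <- rss <= 1e-12 * n * max(var(y), .Machine$double.eps)
  loglik <- if (degenerate && !rss_floor) {
    NA_real_                              # RSS ~ 0: likelihood unbounded
  } else {
    rss_eff <- max(rss, if (rss_floor) 1e-12 * n * max(var(y), .Machine$double.eps) else 0)
    -n / 2 * (log(2 * pi) + log(rss_eff / n) + 1)
  }
  tss <- sum((y - mean(y))^2)
  adj_r2 <- if (tss > 0) 1 - (rss / df_resid) / (tss / (n - 1)) else NA_real_

  structure(
    list(
      fit = fit,
      response = response,
      predictors = predictors_kept,
      dropped = dropped,
      coefficients = coef(fit),
      n = n,
      d = d,
      df_resid = df_resid,
      rss = rss,
      sigma2 = rss / df_resid,
      loglik = loglik,
      bic_value = if (is.na(loglik)) NA_real_ else -2 * loglik + log(n) * d,
      adj_r2 = adj_r2,
      degenerate_rss = degenerate && !rss_floor
    ),
    class = "error_model"
  )
}

#' BIC of a fitted error model
#'
#' `-2 loglike + log(n) * d`, where `loglike` is the Gaussian maximum
#' log-likelihood. Under the default convention `d` counts the fitted slope
#' coefficients (dummy columns individually), excluding the intercept;
#' `"plus_intercept"` adds 1. The two conventions differ by a constant at
#' fixed `n` and never reorder candidate models.
#'
#' @param model An `error_model` from [fit_ols()].
#' @param d_convention `"paper"` (default, slopes only) or `"plus_intercept"`.
#' @return BIC value (nats scale).
#' @export
bic <- function(model, d_convention = c("paper", "plus_intercept")) {
  d_convention <- match.arg(d_convention)
  stopifnot(inherits(model, "error_model"))
  if (is.na(model$loglik)) {
    stop("log-likelihood undefined (RSS = 0); refit with rss_floor = TRUE")
  }
  d <- model$d + if (d_convention == "plus_intercept") 1L else 0L
  -2 * model$loglik + log(model$n) * d
}

#' Out-of-sample prediction interval (the per-mutation error bound)
#'
#' The exact t-based prediction interval for a new observation, with
#' half-width `t(q, df) * s * sqrt(1 + x0' (X'X)^{-1} x0)` around the point
#' prediction `x0' beta_hat`. Its upper limit is the per-mutation error
#' bound: the true stability change then lies within `ddg_foldx +/- upper`
#' with the bound's capture probability.
#'
#' Because the Error is an unsigned magnitude, only the upper limit is used
#' downstream, and the calibrated construction is one-sided:
#' `side = "upper"` (default) places the upper limit at the level-quantile of
#' the predictive t distribution (`q = level`), so
#' `P(Error < upper) = level` when the model is correct.
#' `side = "two_sided"` is the central interval (`q = (1 + level)/2`), whose
#' upper limit sits at the `(1 + level)/2` predictive quantile; its capture
#' rate matches `level` only for responses with no mass at the lower tail.
#' The lower limit is reported raw in both cases (no clamping at zero).
#'
#' Rows in which a predictor dropped as aliased during training takes a
#' nonzero value are predicted with the reference-level (zero) contribution
#' and flagged in `flag_unmodeled`.
#'
#' @param model An `error_model`.
#' @param newdata Data frame holding the model's predictor columns.
#' @param level Interval level in (0, 1); default 0.95.
#' @param side `"upper"` (one-sided calibrated bound, default) or
#'   `"two_sided"`.
#' @return A tibble with columns `point`, `lower`, `upper` (kcal/mol),
#'   `level`, `flag_unmodeled`.
#' @export
predict_interval <- function(model, newdata, level = 0.95,
                             side = c("upper", "two_sided")) {
  stopifnot(inherits(model, "error_model"))
  side <- match.arg(side)
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1) {
    stop("level must be a single number in (0, 1)")
  }
  newdata <- tibble::as_tibble(newdata)
  missing <- setdiff(model$predictors, names(newdata))
  if (length(missing) > 0) {
    stop("newdata lacks predictor column(s): ", paste(missing, collapse = ", "))
  }
  pred <- predict(model$fit, newdata = newdata, se.fit = TRUE)
  q <- if (side == "upper") level else (1 + level) / 2
  # se of a new observation: leverage term plus residual variance
  se_new <- sqrt(pred$se.fit^2 + model$sigma2)
  half <- qt(q, df = model$df_resid) * se_new
  flag <- rep(FALSE, nrow(newdata))
  for (cl in intersect(model$dropped, names(newdata))) {
    flag <- flag | (newdata[[cl]] != 0)
  }
  tibble::tibble(
    point = unname(pred$fit),
    lower = unname(pred$fit - half),
    upper = unname(pred$fit + half),
    level = level,
    flag_unmodeled = flag
  )
}

#' Effect of one predictor on the interval width
#'
#' Rescales a coefficient into kcal/mol of bound width: constructs two
#' hypothetical mutations whose target predictor equals the mean of its values
#' within the upper versus the lower `quantile` tail (for a binary flag such
#' as the proline indicator: 1 versus 0), holds every other predictor at its
#' dataset-wide mean, and returns the difference between the two predicted
#' upper bounds.
#'
#' @param model An `error_model`.
#' @param table The data the model was fitted to (supplies the empirical
#'   quantiles and means).
#' @param predictor Name of one fitted predictor.
#' @param quantile Tail fraction defining the contrast (default 0.10).
#' @param level Interval level for the bounds (default 0.95).
#' @param side Bound construction (see [predict_interval()]).
#' @return Difference in upper bounds, kcal/mol.
#' @export
effect_on_interval_width <- function(model, table, predictor, quantile = 0.10,
                                     level = 0.95,
                                     side = c("upper", "two_sided")) {
  side <- match.arg(side)
  stopifnot(inherits(model, "error_model"))
  if (!predictor %in% model$predictors) {
    stop("predictor not in model: ", predictor)
  }
  v <- table[[predictor]]
  if (length(unique(v)) == 1) {
    stop("predictor is constant in the data; contrast undefined: ", predictor)
  }
  if (all(v %in% c(0, 1))) {
    hi <- 1; lo <- 0
  } else {
    hi <- mean(v[v >= stats::quantile(v, 1 - quantile)])
    lo <- mean(v[v <= stats::quantile(v, quantile)])
  }
  base <- lapply(table[model$predictors], mean)
  row_hi <- tibble::as_tibble(base); row_hi[[predictor]] <- hi
  row_lo <- tibble::as_tibble(base); row_lo[[predictor]] <- lo
  bounds <- predict_interval(model, dplyr::bind_rows(row_hi, row_lo),
                             level = level, side = side)
  bounds$upper[1] - bounds$upper[2]
}

#' @export
print.error_model <- function(x, ...) {
  cat("<error_model> n =", x$n, " predictors =", x$d,
      " s =", signif(sqrt(x$sigma2), 4), "kcal/mol\n")
  cat("  adj R2 =", signif(x$adj_r2, 3),
      " BIC =", if (is.na(x$bic_value)) "NA (RSS = 0)" else signif(x$bic_value, 6),
      "\n")
  if (length(x$predictors) > 0) {
    cat("  terms:", paste(x$predictors, collapse = ", "), "\n")
  } else {
    cat("  intercept-only model\n")
  }
  invisible(x)
}

#' Broom-style tidiers for fitted error models
#'
#' `tidy()` returns the coefficient table (estimate, standard error,
#' t statistic, p-value); `glance()` returns one-row model-level summaries
#' including the package's BIC convention.
#'
#' @param x An `error_model`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy error_model
#' @export
tidy.error_model <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(
    term = gsub("`", "", rownames(sm)),
    estimate = sm[, "Estimate"],
    std.error = sm[, "Std. Error"],
    statistic = sm[, "t value"],
    p.value = sm[, "Pr(>|t|)"]
  )
}

#' @rdname tidy.error_model
#' @method glance error_model
#' @export
glance.error_model <- function(x, ...) {
  tibble::tibble(
    n = x$n, d = x$d, adj.r.squared = x$adj_r2,
    sigma = sqrt(x$sigma2), logLik = x$loglik, BIC = x$bic_value,
    df.residual = x$df_resid, rss = x$rss
  )
}
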