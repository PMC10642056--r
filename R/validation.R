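#' Coverage of error bounds
#'
#' Fraction of observations whose Error falls strictly below its bound:
#' `mean(I(error < bound))`. Ties (error exactly equal to the bound) count as
#' not captured.
#'
#' @param errors,bounds Numeric vectors of equal, positive length (kcal/mol).
#' @return Coverage fraction in \[0, 1\].
#' @export
coverage <- function(errors, bounds) {
  if (length(errors) == 0) stop("empty input")
  if (length(errors) != length(bounds)) stop("length mismatch")
  mean(errors < bounds)
}

#' Leave-one-system-out cross-validation of the error model
#'
#' For each protein system in turn, the model is trained on all other systems
#' — including re-running predictor selection on the training fold only, so no
#' information leaks from the held-out system — and each held-out mutation
#' receives an out-of-sample prediction interval. A mutation is captured when
#' its Error lies strictly below the interval's upper bound; overall coverage
#' is the pooled fraction captured, and the median of the upper bounds is the
#' headline precision metric (`width_kind = "full"` switches to
#' upper-minus-lower for sensitivity checks).
#'
#' @param table Design table from [build_predictor_table()].
#' @param selector Either a character vector of predictor column names (a
#'   fixed formula evaluated in every fold), or a list with `method`
#'   (`"best_subset"` or `"stepwise"`) and optional `blocks`, `max_size`,
#'   `start`, in which case selection is re-run inside each fold.
#' @param level Bound level (default 0.95).
#' @param side Bound construction passed to [predict_interval()]: `"upper"`
#'   (one-sided calibrated bound, default) or `"two_sided"` (the upper limit
#'   of the central interval, the construction used with real magnitude
#'   data in the source workflow).
#' @param width_kind `"upper"` (default: the bound itself) or `"full"`.
#' @return A `loso_result` with elements `predictions` (one row per held-out
#'   mutation: system, Error, bound, captured, flag), `per_system`,
#'   `overall` (coverage, median width, n), and `models` (per-fold fits with
#'   the fold's chosen blocks).
#' @export
loso_cv <- function(table, selector = list(method = "best_subset", max_size = 8),
                    level = 0.95, side = c("upper", "two_sided"),
                    width_kind = c("upper", "full")) {
  width_kind <- match.arg(width_kind)
  side <- match.arg(side)
  table <- tibble::as_tibble(table)
  systems <- unique(table$system_id)
  if (length(systems) < 2) stop("leave-one-system-out needs >= 2 systems")
  keys <- attr(table, "mutation_keys")
  if (is.null(keys)) keys <- as.character(seq_len(nrow(table)))

  fit_fold <- function(train) {
    if (is.character(selector)) {
      list(model = fit_ols(train, selector), blocks = selector)
    } else {
      sel <- switch(
        selector$method %||% "best_subset",
        best_subset = best_subset_select(train, blocks = selector$blocks,
                                         max_size = selector$max_size %||% 8),
        stepwise = stepwise_select(train, blocks = selector$blocks,
                                   start = selector$start %||% "null"),
        stop("unknown selection method: ", selector$method)
      )
      list(model = sel$chosen, blocks = sel$chosen_blocks)
    }
  }

  models <- list()
  preds <- vector("list", length(systems))
  for (i in seq_along(systems)) {
    sys <- systems[i]
    train <- table[table$system_id != sys, , drop = FALSE]
    test <- table[table$system_id == sys, , drop = FALSE]
    fold <- fit_fold(train)
    pi <- predict_interval(fold$model, test, level = level, side = side)
    width <- if (width_kind == "upper") pi$upper else pi$upper - pi$lower
    preds[[i]] <- tibble::tibble(
      system_id = sys,
      key = keys[table$system_id == sys],
      error_abs = test$error_abs,
      bound = pi$upper,
      width = width,
      captured = test$error_abs < pi$upper,
      flag_unmodeled = pi$flag_unmodeled
    )
    models[[sys]] <- fold
  }
  predictions <- dplyr::bind_rows(preds)
  per_system <- predictions |>
    dplyr::group_by(.data$system_id) |>
    dplyr::summarise(
      n = dplyr::n(),
      median_error = median(.data$error_abs),
      coverage = mean(.data$captured),
      median_width = median(.data$width),
      n_outliers = sum(!.data$captured),
      outlier_keys = list(.data$key[!.data$captured]),
      .groups = "drop"
    )
  structure(
    list(
      predictions = predictions,
      per_system = per_system,
      overall = list(
        n = nrow(predictions),
        coverage = mean(predictions$captured),
        median_width = median(predictions$width),
        median_error = median(predictions$error_abs),
        level = level,
        side = side,
        width_kind = width_kind
      ),
      models = models
    ),
    class = "loso_result"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' System-by-system performance breakdown
#'
#' Per-system counts, median Error, coverage (percent) and median bound width
#' from a leave-one-system-out run, with a pooled `Total` row.
#'
#' @param result A `loso_result` from [loso_cv()].
#' @return A tibble with columns `system_id`, `n`, `median_error`,
#'   `coverage_pct`, `median_width`.
#' @export
summarize_by_system <- function(result) {
  stopifnot(inherits(result, "loso_result"))
  per <- result$per_system |>
    dplyr::transmute(
      .data$system_id, .data$n, .data$median_error,
      coverage_pct = 100 * .data$coverage,
      .data$median_width
    )
  dplyr::bind_rows(per, tibble::tibble(
    system_id = "Total",
    n = result$overall$n,
    median_error = result$overall$median_error,
    coverage_pct = 100 * result$overall$coverage,
    median_width = result$overall$median_width
  ))
}

#' @export
print.loso_result <- function(x, ...) {
  cat("<loso_result>", x$overall$n, "mutations,",
      nrow(x$per_system), "systems\n")
  cat("  coverage =", sprintf("%.1f%%", 100 * x$overall$coverage),
      " median width =", signif(x$overall$median_width, 4), "kcal/mol",
      sprintf("(level %.2f)\n", x$overall$level))
  invisible(x)
}

#' @rdname summarize_by_system
#' @param x A `loso_result`.
#' @param ... Unused.
#' @method tidy loso_result
#' @export
tidy.loso_result <- function(x, ...) summarize_by_system(x)

#' @rdname summarize_by_system
#' @method glance loso_result
#' @export
glance.loso_result <- function(x, ...) {
  tibble::tibble(
    n = x$overall$n,
    n_systems = nrow(x$per_system),
    coverage = x$overall$coverage,
    median_width = x$overall$median_width,
    median_error = x$overall$median_error,
    level = x$overall$level
  )
}

#' Goodness-of-fit test for the distribution of outliers across systems
#'
#' Tests whether uncaptured mutations (outliers) are spread across protein
#' systems in proportion to system size. Expected counts are
#' `total_outliers * n_i / N`; the statistic is the usual
#' `sum((O - E)^2 / E)`. The Monte-Carlo p-value simulates multinomial outlier
#' allocations and reports `(b + 1) / (reps + 1)`, where `b` counts
#' simulations with a statistic at least as large as observed; with the
#' default 2000 replicates, a statistic exceeded by no simulation yields
#' p = 1/2001, about 0.00050. The asymptotic alternative refers the statistic
#' to a chi-squared distribution with `k - 1` degrees of freedom.
#'
#' @param observed Integer vector of outlier counts per system.
#' @param n_i System sizes (same length/order as `observed`).
#' @param method `"monte_carlo"` (default) or `"asymptotic"`.
#' @param reps Monte-Carlo replicates (default 2000).
#' @param seed Optional seed for the Monte-Carlo draw.
#' @return A `gof_result` with `observed`, `expected`, `statistic`,
#'   `p_value`, `method`, `df`, `reps`.
#' @export
outlier_gof_test <- function(observed, n_i,
                             method = c("monte_carlo", "asymptotic"),
                             reps = 2000, seed = NULL) {
  method <- match.arg(method)
  if (length(observed) != length(n_i)) stop("length mismatch")
  total <- sum(observed)
  if (total < 1) stop("need at least one outlier")
  expected <- total * n_i / sum(n_i)
  if (any(expected == 0)) stop("expected count of zero (empty system?)")
  statistic <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  if (method == "asymptotic") {
    p <- pchisq(statistic, df = df, lower.tail = FALSE)
  } else {
    if (!is.null(seed)) set.seed(seed)
    sims <- rmultinom(reps, total, prob = n_i / sum(n_i))
    stat_sim <- colSums((sims - expected)^2 / expected)
    p <- (sum(stat_sim >= statistic - 1e-12) + 1) / (reps + 1)
  }
  structure(
    list(observed = observed, expected = expected, n_i = n_i,
         statistic = statistic, p_value = p, method = method,
         df = df, reps = if (method == "monte_carlo") reps else NA_integer_),
    class = "gof_result"
  )
}

#' @export
print.gof_result <- function(x, ...) {
  cat("<gof_result> chi-squared =", signif(x$statistic, 4),
      " p =", signif(x$p_value, 3), paste0("(", x$method, ")\n"))
  invisible(x)
}
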