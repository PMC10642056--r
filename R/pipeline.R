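#' Run the five-model ladder on one or two datasets
#'
#' Orchestrates the whole analysis across the model ladder: Models 1-2 use the
#' single-structure FoldX run (energy terms, then + biochemical properties);
#' Models 3-5 use the MD-snapshot means (terms, + biochemistry, + per-term
#' SDs). For each rung it assembles the predictor pool, selects predictors
#' under BIC on the full data (for the reported coefficients, adjusted
#' R-squared and BIC), and scores the rung by leave-one-system-out
#' cross-validation with selection re-run inside each fold. The report
#' mirrors the standard comparison layout: a model-comparison table, a
#' per-system breakdown of the full model, its coefficient/effect table, and
#' the outlier goodness-of-fit test.
#'
#' @param folding_table Tidy mutation table for folding stability (see
#'   [read_tidy_table()] / [generate_dataset()]).
#' @param binding_table Optional second table (binding stability).
#' @param selector Selection configuration passed to [loso_cv()] (default
#'   best-subset, `max_size` blocks).
#' @param level Prediction-interval level (default 0.95).
#' @param compare_methods Also run stepwise selection on the full data and
#'   record its chosen blocks and BIC alongside the headline method.
#' @param gof_seed Seed for the Monte-Carlo goodness-of-fit p-value (fixed so
#'   the report is a pure function of its inputs).
#' @return A `ladder_report`: per dataset, `comparison` (one row per model:
#'   coverage %, median width, adjusted R-squared, BIC, selected blocks),
#'   `per_system`, `coefficients` (with the interval-width effect per scalar
#'   predictor), `gof`, and the full-model `loso_result`.
#' @export
run_model_ladder <- function(folding_table, binding_table = NULL,
                             selector = list(method = "best_subset",
                                             max_size = 8),
                             level = 0.95, compare_methods = FALSE,
                             gof_seed = 1) {
  datasets <- list(folding = folding_table)
  if (!is.null(binding_table)) datasets$binding <- binding_table
  pools <- paste0("model", 1:5)

  run_one <- function(records, label) {
    rows <- list(); losos <- list(); selections <- list()
    for (pool in pools) {
      needs_single <- pool %in% c("model1", "model2")
      if (needs_single && !"total_single" %in% names(records)) {
        rows[[pool]] <- tibble::tibble(
          model = pool, status = "not run (no single-structure columns)",
          n = NA_integer_, predictors = NA_character_,
          coverage_pct = NA_real_, median_width = NA_real_,
          adj_r2 = NA_real_, bic = NA_real_
        )
        next
      }
      pt <- build_predictor_table(records, pool)
      sel <- if ((selector$method %||% "best_subset") == "stepwise") {
        stepwise_select(pt, blocks = selector$blocks,
                        start = selector$start %||% "null")
      } else {
        best_subset_select(pt, blocks = selector$blocks,
                           max_size = selector$max_size %||% 8)
      }
      lo <- loso_cv(pt, selector = selector, level = level)
      message(sprintf("[%s/%s] n = %d; selected: %s", label, pool, nrow(pt),
                      paste(sel$chosen_blocks, collapse = ", ")))
      rows[[pool]] <- tibble::tibble(
        model = pool, status = "ok", n = nrow(pt),
        predictors = paste(sel$chosen_blocks, collapse = "+"),
        coverage_pct = 100 * lo$overall$coverage,
        median_width = lo$overall$median_width,
        adj_r2 = sel$chosen$adj_r2,
        bic = bic(sel$chosen)
      )
      if (compare_methods) {
        alt <- if ((selector$method %||% "best_subset") == "stepwise") {
          best_subset_select(pt, blocks = selector$blocks,
                             max_size = selector$max_size %||% 8)
        } else {
          stepwise_select(pt, blocks = selector$blocks)
        }
        rows[[pool]]$alt_predictors <- paste(alt$chosen_blocks, collapse = "+")
        rows[[pool]]$alt_bic <- bic(alt$chosen)
      }
      losos[[pool]] <- lo
      selections[[pool]] <- sel
    }
    full <- selections$model5
    full_pt <- build_predictor_table(records, "model5")
    coef_tab <- NULL
    gof <- NULL
    if (!is.null(full)) {
      coef_tab <- tidy(full$chosen)
      coef_tab$effect_on_width <- vapply(coef_tab$term, function(tm) {
        if (tm == "(Intercept)" || tm %in% ss_dummy_cols()) return(NA_real_)
        if (length(unique(full_pt[[tm]])) == 1) return(NA_real_)
        effect_on_interval_width(full$chosen, full_pt, tm, level = level)
      }, numeric(1))
      per <- losos$model5$per_system
      if (sum(per$n_outliers) >= 1) {
        gof <- outlier_gof_test(per$n_outliers, per$n, seed = gof_seed)
      }
    }
    list(
      comparison = dplyr::bind_rows(rows),
      per_system = if (!is.null(losos$model5)) {
        summarize_by_system(losos$model5)
      },
      coefficients = coef_tab,
      gof = gof,
      loso_full = losos$model5
    )
  }

  out <- lapply(names(datasets), function(nm) run_one(datasets[[nm]], nm))
  names(out) <- names(datasets)
  structure(list(datasets = out, level = level, selector = selector),
            class = "ladder_report")
}

#' @export
print.ladder_report <- function(x, ...) {
  for (nm in names(x$datasets)) {
    cat("==", nm, "dataset ==\n")
    print(x$datasets[[nm]]$comparison)
  }
  invisible(x)
}
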