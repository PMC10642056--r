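# Model search over predictor blocks. A block is a set of columns that enters
# or leaves the model as a unit: scalar predictors are their own block and the
# secondary-structure dummies form one block, since the categorical predictor
# is kept or removed whole.

# RSS of the least-squares fit on an index set of columns (intercept always
# included). Rank-deficient subsets are handled by the pivoted QR inside
# .lm.fit, so collinear candidates are evaluated, not skipped.
rss_for <- function(X, y, cols) {
  Z <- cbind(1, X[, cols, drop = FALSE])
  sum(.lm.fit(Z, y)$residuals^2)
}

resolve_blocks <- function(table, blocks) {
  if (is.null(blocks)) blocks <- predictor_blocks(table)
  if (is.null(names(blocks)) || any(!nzchar(names(blocks)))) {
    stop("blocks must be a named list of column vectors")
  }
  cols <- unlist(blocks, use.names = FALSE)
  if (anyDuplicated(cols)) stop("blocks must partition the candidate columns")
  missing <- setdiff(cols, names(table))
  if (length(missing) > 0) {
    stop("block column(s) not in table: ", paste(missing, collapse = ", "))
  }
  blocks[order(names(blocks))]   # deterministic branching and tie-breaking
}

finish_selection <- function(table, blocks, best_sets, best_rss, method,
                             extra = list()) {
  sizes <- seq_along(best_sets) - 1L
  # candidate fits are internal: aliased-column warnings are recorded in the
  # chosen model's `dropped` field rather than raised once per candidate
  candidates <- lapply(seq_along(best_sets), function(i) {
    cols <- unlist(blocks[best_sets[[i]]], use.names = FALSE)
    suppressWarnings(fit_ols(table, cols))
  })
  bics <- vapply(candidates, bic, numeric(1))
  # ties broken toward fewer predictors (sizes ascend; strict improvement only)
  chosen_idx <- 1L
  for (i in seq_along(bics)) {
    if (bics[i] < bics[chosen_idx] - 1e-9) chosen_idx <- i
  }
  structure(
    c(list(
      method = method,
      best_per_size = tibble::tibble(
        size = sizes,
        rss = best_rss,
        blocks = lapply(best_sets, function(s) sort(names(blocks)[s])),
        bic = bics
      ),
      chosen = candidates[[chosen_idx]],
      chosen_blocks = sort(names(blocks)[best_sets[[chosen_idx]]]),
      blocks = blocks
    ), extra),
    class = "selection_result"
  )
}

#' Best-subset predictor search under BIC
#'
#' Finds, for every subset size `k <= max_size`, the minimum-RSS set of
#' predictor blocks, then picks the BIC-minimizing size (the intercept-only
#' model is always a candidate). The search is branch-and-bound: because
#' adding predictors can only decrease RSS, the RSS of the relaxed model
#' containing all still-free blocks lower-bounds every completion of a branch,
#' which prunes the `2^p` tree; with few blocks it is exhaustive. Ties in BIC
#' go to fewer predictors, then to lexicographic block order.
#'
#' @param table Design table from [build_predictor_table()] (columns
#'   `system_id`, `error_abs`, predictors).
#' @param blocks Named list mapping block name to its column names; by default
#'   every predictor is its own block and the `ss_*` dummies form one
#'   `ss_class` block.
#' @param max_size Largest number of blocks considered (default 8), bounding runtime
#'   on wide pools: exact search among many near-equivalent noise blocks is
#'   combinatorial in `max_size`, and fitted error models in this domain use
#'   fewer than eight predictor blocks.
#' @return A `selection_result`: `best_per_size` (size, RSS, blocks, BIC),
#'   `chosen` (the fitted `error_model`), `chosen_blocks`, `n_evaluations`.
#' @export
best_subset_select <- function(table, blocks = NULL, max_size = 8) {
  blocks <- resolve_blocks(table, blocks)
  y <- table[["error_abs"]]
  all_cols <- unlist(blocks, use.names = FALSE)
  X <- as.matrix(table[all_cols])
  col_of_block <- lapply(blocks, function(b) match(b, all_cols))

  nb <- length(blocks)
  kmax <- min(max_size, nb)
  if (nrow(table) <= length(all_cols) + 1 && kmax == nb) {
    # full model would be unidentifiable; sizes are still capped below by n
    kmax <- min(kmax, nrow(table) - 2L)
  }
  best_rss <- rep(Inf, kmax + 1)
  best_sets <- rep(list(integer(0)), kmax + 1)
  n_evals <- 0L

  # cross-products computed once; per-subset RSS is then a small Cholesky
  # solve, rss = y'y - g_S' (G_SS)^{-1} g_S, with a pivoted-QR fallback for
  # singular candidate subsets
  Z <- cbind(`(int)` = 1, X)
  G <- crossprod(Z)
  g <- drop(crossprod(Z, y))
  yty <- sum(y * y)
  rss_cols <- function(cols) {
    idx <- c(1L, cols + 1L)
    ch <- tryCatch(chol(G[idx, idx, drop = FALSE]), error = function(e) NULL)
    if (is.null(ch)) return(rss_for(X, y, cols))
    z <- forwardsolve(ch, g[idx], upper.tri = TRUE, transpose = TRUE)
    max(yty - sum(z * z), 0)
  }

  score <- function(set) {
    n_evals <<- n_evals + 1L
    if (length(set) == 0) return(sum((y - mean(y))^2))
    rss_cols(unlist(col_of_block[set], use.names = FALSE))
  }
  consider <- function(set, rss) {
    k <- length(set)
    if (k > kmax) return(invisible())
    if (rss < best_rss[k + 1] - 1e-9) {
      best_rss[k + 1] <<- rss
      best_sets[[k + 1]] <<- set
    } else if (rss <= best_rss[k + 1] + 1e-9) {
      # exact tie: keep the lexicographically earlier block set
      cur_names <- paste(sort(names(blocks)[best_sets[[k + 1]]]), collapse = "|")
      new_names <- paste(sort(names(blocks)[set]), collapse = "|")
      if (new_names < cur_names) best_sets[[k + 1]] <<- set
    }
    invisible()
  }

  # greedy forward pass seeds the incumbents, tightening pruning early
  cur <- integer(0)
  consider(cur, score(cur))
  while (length(cur) < kmax) {
    cand <- setdiff(seq_len(nb), cur)
    rs <- vapply(cand, function(b) score(sort(c(cur, b))), numeric(1))
    cur <- sort(c(cur, cand[which.min(rs)]))
    consider(cur, min(rs))
  }

  # branch on the most predictive blocks first: deciding strong predictors
  # early makes the relaxed-model bound bite almost immediately
  single_rss <- vapply(seq_len(nb), function(b) score(b), numeric(1))
  branch_order <- order(single_rss, names(blocks))

  score_relax <- function(in_set, free) {
    n_evals <<- n_evals + 1L
    rss_cols(unlist(col_of_block[c(in_set, free)], use.names = FALSE))
  }
  recurse <- function(in_set, free) {
    consider(in_set, score(in_set))
    if (length(free) == 0 || length(in_set) >= kmax) return(invisible())
    reach <- seq(length(in_set) + 1L, min(length(in_set) + length(free), kmax))
    # RSS of the relaxed model (everything still free included) lower-bounds
    # every completion of this branch
    relax_rss <- score_relax(in_set, free)
    if (all(best_rss[reach + 1] <= relax_rss + 1e-9)) return(invisible())
    recurse(sort(c(in_set, free[1])), free[-1])
    recurse(in_set, free[-1])
  }
  recurse(integer(0), branch_order)

  finish_selection(table, blocks, best_sets, best_rss, "best_subset",
                   extra = list(n_evaluations = n_evals, max_size = kmax))
}

#' Stepwise predictor search under BIC
#'
#' Greedy search that, from a null or full start, repeatedly applies the
#' single block addition or removal producing the largest BIC decrease, and
#' stops when every further step gives a poorer (or equal) fit. Deterministic
#' given the table and start.
#'
#' @inheritParams best_subset_select
#' @param start `"null"` (intercept-only, default) or `"full"`.
#' @return A `selection_result` with a `steps` trace (step, action, block,
#'   BIC).
#' @export
stepwise_select <- function(table, blocks = NULL, start = c("null", "full")) {
  start <- match.arg(start)
  blocks <- resolve_blocks(table, blocks)
  nb <- length(blocks)

  fit_set <- function(set) {
    suppressWarnings(fit_ols(table, unlist(blocks[set], use.names = FALSE)))
  }
  cur <- if (start == "null") integer(0) else seq_len(nb)
  cur_fit <- fit_set(cur)
  cur_bic <- bic(cur_fit)
  trace <- tibble::tibble(step = 0L, action = "start",
                          block = NA_character_, bic = cur_bic)
  step <- 0L
  repeat {
    moves <- c(
      lapply(setdiff(seq_len(nb), cur), function(b) list(action = "add", b = b)),
      lapply(cur, function(b) list(action = "remove", b = b))
    )
    if (length(moves) == 0) break
    bics <- vapply(moves, function(m) {
      set <- if (m$action == "add") sort(c(cur, m$b)) else setdiff(cur, m$b)
      if (nrow(table) <= length(unlist(blocks[set])) + 1) return(Inf)
      bic(fit_set(set))
    }, numeric(1))
    best <- which.min(bics)
    if (bics[best] >= cur_bic - 1e-9) break
    m <- moves[[best]]
    cur <- if (m$action == "add") sort(c(cur, m$b)) else setdiff(cur, m$b)
    cur_bic <- bics[best]
    step <- step + 1L
    trace <- dplyr::bind_rows(trace, tibble::tibble(
      step = step, action = m$action, block = names(blocks)[m$b], bic = cur_bic
    ))
  }
  cur_fit <- fit_set(cur)
  structure(
    list(
      method = "stepwise",
      best_per_size = tibble::tibble(
        size = length(cur), rss = cur_fit$rss,
        blocks = list(sort(names(blocks)[cur])), bic = cur_bic
      ),
      chosen = cur_fit,
      chosen_blocks = sort(names(blocks)[cur]),
      blocks = blocks,
      steps = trace,
      start = start
    ),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result>", x$method, "— chosen blocks:",
      if (length(x$chosen_blocks) == 0) "(intercept only)"
      else paste(x$chosen_blocks, collapse = ", "), "\n")
  cat("  BIC =", signif(bic(x$chosen), 6), " n =", x$chosen$n, "\n")
  invisible(x)
}
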