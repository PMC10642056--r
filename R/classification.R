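stability_labels <- function() c("stabilizing", "neutral", "destabilizing")

#' Point classification of a stability change
#'
#' Thresholds a ddG value (kcal/mol) into the three conventional classes:
#' stabilizing below -0.5, destabilizing above 0.5, neutral in between
#' (boundary values +/-0.5 are neutral).
#'
#' @param ddg Numeric vector (kcal/mol), finite.
#' @return Factor with levels stabilizing, neutral, destabilizing.
#' @examples
#' classify_exp(c(-0.7, 0.5, 0.6))
#' @export
classify_exp <- function(ddg) {
  if (!all(is.finite(ddg))) stop("classify_exp requires finite values")
  out <- ifelse(ddg < -0.5, "stabilizing",
                ifelse(ddg > 0.5, "destabilizing", "neutral"))
  factor(out, levels = stability_labels())
}

#' Classification with error bounds
#'
#' Widens each prediction into the interval
#' `[ddg_foldx - bound, ddg_foldx + bound]` and reports every stability class
#' whose ddG range that interval intersects (neutral owns the closed band
#' \[-0.5, 0.5\]). A mutation is classified unambiguously only when a single
#' class is overlapped; with `bound = 0` this reduces to the point
#' classification of `ddg_foldx`.
#'
#' @param ddg_foldx Predicted ddG values (kcal/mol).
#' @param bound Non-negative error bounds (kcal/mol), recycled if scalar.
#' @return A tibble with columns `ddg_foldx`, `bound`, `lower`, `upper`,
#'   logical columns `stabilizing`, `neutral`, `destabilizing`,
#'   `labels_overlapped` (collapsed with `+`), `unambiguous`, and `label`
#'   (the single class, or `"ambiguous"`).
#' @examples
#' classify_with_bounds(c(4, 0, 2.6), c(1, 1, 2))
#' @export
classify_with_bounds <- function(ddg_foldx, bound) {
  if (any(bound < 0)) stop("bound must be non-negative")
  if (length(bound) == 1) bound <- rep(bound, length(ddg_foldx))
  if (length(bound) != length(ddg_foldx)) stop("length mismatch")
  lower <- ddg_foldx - bound
  upper <- ddg_foldx + bound
  stab <- lower < -0.5
  neut <- upper >= -0.5 & lower <= 0.5
  dest <- upper > 0.5
  n_lab <- stab + neut + dest
  label <- dplyr::case_when(
    n_lab > 1 ~ "ambiguous",
    stab ~ "stabilizing",
    neut ~ "neutral",
    TRUE ~ "destabilizing"
  )
  collapse <- function(s, ne, d) {
    paste(stability_labels()[c(s, ne, d)], collapse = "+")
  }
  tibble::tibble(
    ddg_foldx = ddg_foldx, bound = bound, lower = lower, upper = upper,
    stabilizing = stab, neutral = neut, destabilizing = dest,
    labels_overlapped = mapply(collapse, stab, neut, dest),
    unambiguous = n_lab == 1,
    label = factor(label, levels = c(stability_labels(), "ambiguous"))
  )
}

#' Bin specification along a ddG axis
#'
#' Defines left-open, right-closed bins along `ddg_exp` or `ddg_foldx`. The
#' default edge generator uses 1 kcal/mol bins aligned to the +/-0.5
#' classification thresholds (..., -1.5, -0.5, 0.5, 1.5, ...) extended to
#' cover the data.
#'
#' @param axis `"ddg_exp"` or `"ddg_foldx"`.
#' @param edges Strictly increasing numeric vector of bin edges.
#' @return A `bin_spec` list.
#' @export
bin_spec <- function(axis = c("ddg_exp", "ddg_foldx"), edges) {
  axis <- match.arg(axis)
  if (length(edges) < 2 || any(diff(edges) <= 0)) {
    stop("edges must be strictly increasing with length >= 2")
  }
  structure(list(axis = axis, edges = edges), class = "bin_spec")
}

#' @rdname bin_spec
#' @param x Data values the bins must cover.
#' @param width Bin width (default 1 kcal/mol).
#' @param align An edge the grid must pass through (default 0.5, so bins line
#'   up with the classification thresholds).
#' @export
default_bin_edges <- function(x, width = 1, align = 0.5) {
  stopifnot(width > 0, all(is.finite(x)))
  k_lo <- ceiling((min(x) - align) / width) - 1
  k_hi <- ceiling((max(x) - align) / width)   # right-closed: max lands inside
  align + seq(k_lo, k_hi) * width
}

assign_bins <- function(x, spec) {
  edges <- spec$edges
  if (any(x <= edges[1]) || any(x > edges[length(edges)])) {
    stop("data outside bin range; extend the edges (open outer bins)")
  }
  cut(x, breaks = edges, right = TRUE, include.lowest = FALSE)
}

#' Per-bin class frequencies
#'
#' Splits the data into ddG bins and reports the relative frequency of each
#' stability class per bin. In mode `"exp_truth_vs_foldx"` the classes are the
#' experimental truth ([classify_exp()] on `ddg_exp`), typically binned along
#' `ddg_foldx`, exposing where predictions misclassify. In mode `"bounded"`
#' each mutation is classified by its interval `ddg_foldx +/- bound`
#' ([classify_with_bounds()]) and the outcomes include `"ambiguous"`.
#' Frequencies sum to 1 within every nonempty bin; empty bins are reported
#' with `n_bin = 0` and zero frequencies.
#'
#' @param data Data frame with `ddg_exp`, `ddg_foldx` and (for the bounded
#'   mode) a bound column.
#' @param bins A [bin_spec()]; default: 1 kcal/mol bins along `ddg_foldx`
#'   aligned to the thresholds.
#' @param classifier `"exp_truth_vs_foldx"` or `"bounded"`.
#' @param bound_col Name of the bound column (default `"bound"`).
#' @return Tibble with `bin`, `bin_lower`, `bin_upper`, `n_bin`, `class`,
#'   `count`, `freq`.
#' @export
bin_frequencies <- function(data, bins = NULL,
                            classifier = c("exp_truth_vs_foldx", "bounded"),
                            bound_col = "bound") {
  classifier <- match.arg(classifier)
  if (nrow(data) == 0) stop("empty dataset")
  if (is.null(bins)) {
    bins <- bin_spec("ddg_foldx", default_bin_edges(data$ddg_foldx))
  }
  x <- data[[bins$axis]]
  bin <- assign_bins(x, bins)
  cls <- if (classifier == "exp_truth_vs_foldx") {
    classify_exp(data$ddg_exp)
  } else {
    classify_with_bounds(data$ddg_foldx, data[[bound_col]])$label
  }
  counts <- as.data.frame(table(bin = bin, class = cls), stringsAsFactors = FALSE)
  lev <- levels(bin)
  edges <- bins$edges
  out <- tibble::as_tibble(counts) |>
    dplyr::rename(count = "Freq") |>
    dplyr::group_by(.data$bin) |>
    dplyr::mutate(n_bin = sum(.data$count),
                  freq = ifelse(.data$n_bin > 0, .data$count / .data$n_bin, 0)) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      bin_lower = edges[match(.data$bin, lev)],
      bin_upper = edges[match(.data$bin, lev) + 1]
    ) |>
    dplyr::select("bin", "bin_lower", "bin_upper", "n_bin", "class",
                  "count", "freq")
  out
}

#' Resample mutations uniformly across ddG bins
#'
#' Draws, with replacement, `n_per_bin` rows from every nonempty bin along
#' `ddg_exp`, simulating a study in which experimental stability changes are
#' sampled uniformly instead of with the destabilizing skew typical of
#' mutation databases. One master seed drives the draw; per-bin child seeds
#' are derived from it by a single `sample.int` call, so results are
#' bit-reproducible and bins are decoupled.
#'
#' @param data Data frame with a `ddg_exp` column.
#' @param bins A [bin_spec()] over `ddg_exp`; default 1 kcal/mol threshold-
#'   aligned bins covering the data.
#' @param n_per_bin Draws per nonempty bin (default 1000).
#' @param seed Optional master seed.
#' @param on_empty `"skip"` (default; empty bins are skipped with a warning
#'   when explicitly requested edges leave them empty) or `"error"`.
#' @return Tibble of resampled rows with a `.bin` column appended; output has
#'   `n_per_bin * (number of nonempty bins)` rows.
#' @export
resample_uniform_bins <- function(data, bins = NULL, n_per_bin = 1000,
                                  seed = NULL, on_empty = c("skip", "error")) {
  on_empty <- match.arg(on_empty)
  stopifnot(n_per_bin >= 1)
  if (nrow(data) == 0) stop("empty dataset")
  if (is.null(bins)) {
    bins <- bin_spec("ddg_exp", default_bin_edges(data$ddg_exp))
  }
  if (bins$axis != "ddg_exp") stop("resampling bins must run along ddg_exp")
  bin <- assign_bins(data$ddg_exp, bins)
  tab <- table(bin)
  empty <- names(tab)[tab == 0]
  if (length(empty) > 0) {
    if (on_empty == "error") stop("empty bin(s): ", paste(empty, collapse = ", "))
    warning("skipping empty bin(s): ", paste(empty, collapse = ", "))
  }
  nonempty <- names(tab)[tab > 0]
  if (!is.null(seed)) set.seed(seed)
  child_seeds <- sample.int(.Machine$integer.max, length(nonempty))
  pieces <- lapply(seq_along(nonempty), function(i) {
    rows <- which(bin == nonempty[i])
    set.seed(child_seeds[i])
    take <- rows[sample.int(length(rows), n_per_bin, replace = TRUE)]
    out <- tibble::as_tibble(data[take, , drop = FALSE])
    out$.bin <- nonempty[i]
    out
  })
  dplyr::bind_rows(pieces)
}
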