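#' Absolute prediction error of a stability change
#'
#' The response variable of the whole framework: the unsigned discrepancy
#' between the FoldX-predicted and the experimentally measured stability
#' change, `|ddg_foldx - ddg_exp|`, in kcal/mol.
#'
#' @param ddg_foldx,ddg_exp Numeric vectors (kcal/mol), recycled to a common
#'   length.
#' @return Numeric vector of absolute errors (kcal/mol).
#' @examples
#' compute_error(c(2, -1.3), c(2, 0.4))
#' @export
compute_error <- function(ddg_foldx, ddg_exp) {
  if (!all(is.finite(ddg_foldx)) || !all(is.finite(ddg_exp))) {
    stop("compute_error requires finite inputs")
  }
  abs(ddg_foldx - ddg_exp)
}

#' Biochemical properties of a mutation
#'
#' Derives the residue-level predictors for each mutation: a proline flag
#' (wild-type or substituting residue is proline), absolute changes in van der
#' Waals volume, hydrophobicity index and side-chain charge (all symmetric in
#' wt/mut), the DSSP secondary-structure class, and relative solvent
#' accessibility RSA = ACC / maxASA(wt), clipped to \[0, 1\].
#'
#' @param mutations Data frame with columns `chain`, `position`, `wt_aa`,
#'   `mut_aa` (and optionally `system_id`, carried through).
#' @param dssp Data frame from [read_dssp()] for the corresponding structure.
#' @param props Property tables from [aa_properties()].
#' @param max_asa_kind `"theoretical"` (default) or `"empirical"` maximum ASA
#'   normalization.
#' @param strict If `TRUE`, a mismatch between `wt_aa` and the DSSP residue is
#'   an error; otherwise a warning.
#' @return The input mutations with columns `is_proline`, `volume_change`,
#'   `hydrophobicity_change`, `charge_change`, `ss_class`, `rsa` appended.
#' @export
compute_biochem_props <- function(mutations, dssp,
                                  props = aa_properties(),
                                  max_asa_kind = c("theoretical", "empirical"),
                                  strict = FALSE) {
  max_asa_kind <- match.arg(max_asa_kind)
  mutations <- tibble::as_tibble(mutations)
  bad <- !(mutations$wt_aa %in% amino_acids() & mutations$mut_aa %in% amino_acids())
  if (any(bad)) stop("unknown residue code in row ", which(bad)[1])

  vol <- aa_property_vector(props, "volume")
  hyd <- aa_property_vector(props, "hydrophobicity")
  chg <- aa_property_vector(props, "charge")
  masa <- aa_property_vector(props, paste0("max_asa_", max_asa_kind))

  idx <- match(paste(mutations$chain, mutations$position),
               paste(dssp$chain, dssp$position))
  if (anyNA(idx)) {
    stop("no DSSP record for chain/position of row ", which(is.na(idx))[1])
  }
  dssp_aa <- dssp$aa[idx]
  mismatch <- toupper(dssp_aa) != mutations$wt_aa
  if (any(mismatch)) {
    msg <- paste0("DSSP residue differs from wt_aa in ", sum(mismatch), " row(s)")
    if (strict) stop(msg) else warning(msg)
  }

  rsa_raw <- dssp$acc[idx] / masa[mutations$wt_aa]
  if (any(rsa_raw > 1)) {
    warning("RSA > 1 in ", sum(rsa_raw > 1), " row(s); clipped to 1")
  }
  mutations$is_proline <- as.integer(mutations$wt_aa == "P" | mutations$mut_aa == "P")
  mutations$volume_change <- unname(abs(vol[mutations$wt_aa] - vol[mutations$mut_aa]))
  mutations$hydrophobicity_change <- unname(abs(hyd[mutations$wt_aa] - hyd[mutations$mut_aa]))
  mutations$charge_change <- unname(abs(chg[mutations$wt_aa] - chg[mutations$mut_aa]))
  mutations$ss_class <- dssp$ss_class[idx]
  mutations$rsa <- unname(pmin(pmax(rsa_raw, 0), 1))
  mutations
}

# Expand ss_class to 0/1 dummies against reference level B. All non-reference
# levels always get a column so the design is reproducible across subsets of
# the data; absent levels yield all-zero columns, which the fitter drops as
# aliased.
ss_dummy_cols <- function() paste0("ss_", setdiff(ss_levels(), "B"))

expand_ss_dummies <- function(ss_class) {
  lv <- setdiff(ss_levels(), "B")
  out <- lapply(lv, function(l) as.integer(ss_class == l))
  tibble::as_tibble(setNames(out, paste0("ss_", lv)))
}

#' Predictor-pool manifest
#'
#' The candidate predictor columns made available to model selection for each
#' rung of the model ladder: `model1`/`model3` use the 17 energy terms;
#' `model2`/`model4` add the biochemical properties (proline flag, volume,
#' hydrophobicity and charge changes, secondary-structure dummies against
#' reference B, RSA); `model5` further adds the 17 per-term MD-snapshot SDs.
#'
#' @param pool One of `"model1"` to `"model5"`.
#' @param term_source `"single"` or `"mean"`: which structure source supplies
#'   the energy-term columns (defaults to single-structure for models 1-2 and
#'   MD means for models 3-5).
#' @return Character vector of column names, in deterministic order.
#' @export
pool_columns <- function(pool = c("model1", "model2", "model3", "model4", "model5"),
                         term_source = NULL) {
  pool <- match.arg(pool)
  if (is.null(term_source)) {
    term_source <- if (pool %in% c("model1", "model2")) "single" else "mean"
  }
  term_source <- match.arg(term_source, c("single", "mean"))
  terms <- paste0(foldx_term_names(), "_", term_source)
  biochem <- c("is_proline", "volume_change", "hydrophobicity_change",
               "charge_change", ss_dummy_cols(), "rsa")
  switch(pool,
    model1 = terms,
    model2 = c(terms, biochem),
    model3 = terms,
    model4 = c(terms, biochem),
    model5 = c(terms, biochem, paste0(foldx_term_names(), "_sd"))
  )
}

#' Assemble the design table for one predictor pool
#'
#' Builds the analysis-ready table for a model rung: computes the response
#' `error_abs = |ddg_foldx - ddg_exp|` from the designated FoldX value
#' (single-structure total or MD-mean total), expands `ss_class` into dummies
#' against reference level B, and keeps the pool's candidate columns plus
#' `system_id` for grouping. Column order is deterministic.
#'
#' @param records Validated tidy mutation table (see [read_tidy_table()]).
#' @param pool One of `"model1"` to `"model5"` (see [pool_columns()]).
#' @param response_source `"single_structure"` or `"md_mean"`: which FoldX
#'   total feeds the Error response. Defaults by pool (single-structure for
#'   models 1-2, MD mean for models 3-5).
#' @param term_source Optional override for the energy-term column source
#'   (`"single"` or `"mean"`); defaults to the same source as the response.
#' @return A tibble with columns `system_id`, `error_abs`, then the pool's
#'   predictors; attributes `pool`, `response_source` and `mutation_keys` are
#'   attached.
#' @export
build_predictor_table <- function(records,
                                  pool = c("model1", "model2", "model3",
                                           "model4", "model5"),
                                  response_source = NULL, term_source = NULL) {
  pool <- match.arg(pool)
  records <- tibble::as_tibble(records)
  if (is.null(response_source)) {
    response_source <- if (pool %in% c("model1", "model2")) {
      "single_structure"
    } else {
      "md_mean"
    }
  }
  response_source <- match.arg(response_source, c("single_structure", "md_mean"))
  if (is.null(term_source)) {
    term_source <- if (response_source == "single_structure") "single" else "mean"
  }

  total_col <- if (response_source == "single_structure") "total_single" else "total_mean"
  if (!total_col %in% names(records)) {
    stop("records lack the ", total_col, " column needed for response_source = ",
         response_source)
  }
  if (!"ddg_exp" %in% names(records) || !all(is.finite(records$ddg_exp))) {
    stop("records need finite ddg_exp to form the Error response")
  }

  work <- records
  if (pool %in% c("model2", "model4", "model5")) {
    missing_bio <- setdiff(setdiff(biochem_cols(), "ss_class"), names(work))
    if (length(missing_bio) > 0 || !"ss_class" %in% names(work)) {
      stop("pool ", pool, " needs biochemical columns: ",
           paste(c(missing_bio, setdiff("ss_class", names(work))), collapse = ", "))
    }
    work <- dplyr::bind_cols(work, expand_ss_dummies(work$ss_class))
  }

  cols <- pool_columns(pool, term_source = term_source)
  missing <- setdiff(cols, names(work))
  if (length(missing) > 0) {
    stop("records lack pool column(s): ", paste(missing, collapse = ", "))
  }
  if (length(unique(work$system_id)) < 2) {
    stop("need at least 2 systems (leave-one-system-out requires groups)")
  }

  out <- dplyr::bind_cols(
    tibble::tibble(
      system_id = work$system_id,
      error_abs = compute_error(work[[total_col]], work$ddg_exp)
    ),
    work[cols]
  )
  if (anyNA(out)) stop("missing values in selected pool columns")
  attr(out, "pool") <- pool
  attr(out, "response_source") <- response_source
  attr(out, "mutation_keys") <-
    do.call(paste, c(records[intersect(mutation_key_cols(), names(records))],
                     sep = "/"))
  out
}

# Candidate blocks for selection: each scalar predictor is its own block; the
# secondary-structure dummies enter and leave as one unit.
predictor_blocks <- function(table) {
  cols <- setdiff(names(table), c("system_id", "error_abs"))
  ss <- intersect(ss_dummy_cols(), cols)
  scalars <- setdiff(cols, ss)
  blocks <- as.list(setNames(scalars, scalars))
  if (length(ss) > 0) blocks$ss_class <- ss
  blocks
}
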