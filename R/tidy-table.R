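# Flat per-mutation table: the package's interchange format. One row per
# mutation in one system, carrying identifiers, experimental ddG, aggregated
# FoldX energies and (optionally) single-structure energies and biochemical
# properties.

mutation_key_cols <- function() c("system_id", "chain", "position", "wt_aa", "mut_aa")

biochem_cols <- function() {
  c("is_proline", "volume_change", "hydrophobicity_change", "charge_change",
    "ss_class", "rsa")
}

tidy_table_cols <- function() {
  c(mutation_key_cols(), "ddg_exp",
    paste0(foldx_term_names(), "_mean"),
    paste0(foldx_term_names(), "_sd"))
}

#' Validate a per-mutation table
#'
#' Checks the record invariants of the flat mutation table: standard 1-letter
#' codes, `wt_aa != mut_aa`, positive positions, unique
#' (system, chain, position, wt, mut) keys, finite energies, `rsa` in
#' \[0, 1\] and non-negative SD and change columns.
#'
#' @param records Data frame in the tidy per-mutation layout (see
#'   [read_tidy_table()]).
#' @param require_ddg_exp If `TRUE` (default) every row must carry a finite
#'   `ddg_exp`; set `FALSE` for prediction-only tables.
#' @return The validated records, invisibly as a tibble.
#' @export
validate_mutation_table <- function(records, require_ddg_exp = TRUE) {
  records <- tibble::as_tibble(records)
  needed <- c(mutation_key_cols(), paste0(foldx_term_names(), "_mean"))
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0) {
    stop("mutation table lacks column(s): ", paste(missing, collapse = ", "))
  }
  aa_ok <- records$wt_aa %in% amino_acids() & records$mut_aa %in% amino_acids()
  if (!all(aa_ok)) stop("non-standard amino-acid code in row ", which(!aa_ok)[1])
  if (any(records$wt_aa == records$mut_aa)) {
    stop("wt_aa equals mut_aa in row ", which(records$wt_aa == records$mut_aa)[1])
  }
  if (any(records$position < 1)) stop("position must be >= 1")
  key <- do.call(paste, c(records[mutation_key_cols()], sep = "/"))
  if (anyDuplicated(key)) {
    stop("duplicate mutation key: ", key[duplicated(key)][1])
  }
  if (require_ddg_exp) {
    if (!"ddg_exp" %in% names(records) || !all(is.finite(records$ddg_exp))) {
      stop("ddg_exp must be present and finite (or pass require_ddg_exp = FALSE)")
    }
  }
  num_cols <- intersect(
    c(paste0(foldx_term_names(), "_mean"), paste0(foldx_term_names(), "_sd"),
      paste0(foldx_term_names(), "_single")),
    names(records)
  )
  for (cl in num_cols) {
    if (!is.numeric(records[[cl]])) stop("non-numeric energy column: ", cl)
  }
  sd_cols <- grep("_sd$", num_cols, value = TRUE)
  for (cl in sd_cols) {
    if (any(records[[cl]] < 0, na.rm = TRUE)) stop("negative SD in column ", cl)
  }
  if ("rsa" %in% names(records) &&
      any(records$rsa < 0 | records$rsa > 1, na.rm = TRUE)) {
    stop("rsa outside [0, 1]")
  }
  if ("ss_class" %in% names(records) &&
      !all(records$ss_class %in% ss_levels())) {
    stop("unknown ss_class level")
  }
  invisible(records)
}

#' Read a tidy per-mutation table
#'
#' Reads the package's flat CSV/TSV interchange format: columns `system_id`,
#' `chain`, `position`, `wt_aa`, `mut_aa`, `ddg_exp`, the 17 `{term}_mean`
#' and 17 `{term}_sd` columns, optionally 17 `{term}_single` columns
#' (single-structure FoldX run) and the biochemical property columns
#' `is_proline`, `volume_change`, `hydrophobicity_change`, `charge_change`,
#' `ss_class`, `rsa`. Records are validated on the way in.
#'
#' @param path File path (delimiter inferred from extension: `.tsv`/`.tab`
#'   read as tab-separated, otherwise comma).
#' @param require_ddg_exp Passed to [validate_mutation_table()]; set `FALSE`
#'   to admit prediction-only rows with missing `ddg_exp`.
#' @param strict If `TRUE`, unknown columns are an error.
#' @return A validated tibble.
#' @export
read_tidy_table <- function(path, require_ddg_exp = TRUE, strict = FALSE) {
  delim <- if (grepl("\\.(tsv|tab)$", path)) "\t" else ","
  records <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                               progress = FALSE)
  if (strict) {
    known <- c(tidy_table_cols(), paste0(foldx_term_names(), "_single"),
               biochem_cols(), "n_snapshots")
    unknown <- setdiff(names(records), known)
    if (length(unknown) > 0) {
      stop("unknown column(s) in strict mode: ", paste(unknown, collapse = ", "))
    }
  }
  validate_mutation_table(records, require_ddg_exp = require_ddg_exp)
  tibble::as_tibble(records)
}

#' Write a tidy per-mutation table
#'
#' Counterpart of [read_tidy_table()]; a read-write-read round trip is the
#' identity on records.
#'
#' @param records Data frame in the tidy layout.
#' @param path Output path (`.tsv`/`.tab` writes tab-separated, else CSV).
#' @return `path`, invisibly.
#' @export
write_tidy_table <- function(records, path) {
  delim <- if (grepl("\\.(tsv|tab)$", path)) "\t" else ","
  readr::write_delim(tibble::as_tibble(records), path, delim = delim,
                     progress = FALSE)
  invisible(path)
}
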