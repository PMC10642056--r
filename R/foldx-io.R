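#' Read a FoldX "Dif" energy-difference table
#'
#' Parses the tab-separated per-mutation energy table that FoldX 4 writes
#' (`Dif_*.fxout`): banner and comment lines are skipped until the header row,
#' recognized by its first field `Pdb`; each subsequent row holds one mutant
#' structure's ddG decomposition. FoldX headers are mapped to the canonical
#' term names of [foldx_term_names()] via [foldx_column_map()]; extra FoldX
#' columns are kept under sanitized raw names.
#'
#' @param path Path to a `Dif_*.fxout` file.
#' @param dialect Output dialect; only `"foldx4"` is supported.
#' @return A tibble with one row per data row: `structure` (the `Pdb` tag),
#'   the 17 canonical term columns, then any extra columns.
#' @examples
#' dir <- tempfile(); make_fixture_suite(dir)
#' read_foldx_dif(file.path(dir, "dif_fixture.fxout"))
#' @export
read_foldx_dif <- function(path, dialect = "foldx4") {
  dialect <- match.arg(dialect, "foldx4")
  if (!file.exists(path)) stop("cannot read FoldX file: ", path)
  lines <- readLines(path, warn = FALSE)
  first_field <- sub("\t.*$", "", lines)
  header_at <- which(first_field == "Pdb")[1]
  if (is.na(header_at)) {
    stop("no FoldX header row (first field 'Pdb') found in ", path)
  }
  header <- strsplit(lines[header_at], "\t", fixed = TRUE)[[1]]
  body <- lines[-seq_len(header_at)]
  body <- body[nzchar(trimws(body))]

  map <- foldx_column_map()
  missing <- setdiff(map$foldx_header, header)
  if (length(missing) > 0) {
    stop("missing canonical term column(s) in ", path, ": ",
         paste(missing, collapse = ", "))
  }

  rows <- strsplit(body, "\t", fixed = TRUE)
  bad <- lengths(rows) != length(header)
  if (any(bad)) stop("malformed FoldX data row(s): ", which(bad)[1])
  mat <- do.call(rbind, rows)
  out <- tibble::tibble(structure = mat[, 1])
  canonical_idx <- match(map$foldx_header, header)
  for (i in seq_len(nrow(map))) {
    out[[map$canonical[i]]] <- as.numeric(mat[, canonical_idx[i]])
  }
  extra_idx <- setdiff(seq_along(header)[-1], canonical_idx)
  for (i in extra_idx) {
    nm <- gsub("[^A-Za-z0-9]+", "_", trimws(header[i]))
    nm <- gsub("^_|_$", "", nm)
    out[[paste0("raw_", tolower(nm))]] <- as.numeric(mat[, i])
  }
  if (anyNA(out[foldx_term_names()])) {
    stop("non-numeric value in canonical energy column of ", path)
  }
  out
}

#' Aggregate per-snapshot FoldX energies over an MD ensemble
#'
#' FoldX is run on each snapshot of a molecular-dynamics trajectory (the
#' study design uses 100 snapshots, 1 ns apart); per-term ddG values are then
#' averaged into the final prediction, and their spread across snapshots
#' becomes the SD predictor pool. Input is tabular: one row per snapshot, one
#' column per canonical term (extra columns are ignored).
#'
#' @param snapshots Data frame of per-snapshot energies containing all 17
#'   canonical term columns ([foldx_term_names()]).
#' @param sd_kind `"sample"` (divisor n-1, default) or `"population"`
#'   (divisor n).
#' @return A one-row tibble with `{term}_mean` and `{term}_sd` columns,
#'   `n_snapshots`, and `ddg_foldx` (alias of `total_mean`). SD columns are
#'   `NA` when only one snapshot is supplied.
#' @examples
#' snaps <- as.data.frame(matrix(rnorm(5 * 17), 5, 17,
#'   dimnames = list(NULL, foldx_term_names())))
#' aggregate_snapshots(snaps)
#' @export
aggregate_snapshots <- function(snapshots, sd_kind = c("sample", "population")) {
  sd_kind <- match.arg(sd_kind)
  terms <- foldx_term_names()
  missing <- setdiff(terms, names(snapshots))
  if (length(missing) > 0) {
    stop("snapshot table lacks term column(s): ", paste(missing, collapse = ", "))
  }
  n <- nrow(snapshots)
  if (n < 1) stop("empty snapshot series")
  means <- vapply(snapshots[terms], mean, numeric(1))
  if (n >= 2) {
    sds <- vapply(snapshots[terms], sd, numeric(1))
    if (sd_kind == "population") sds <- sds * sqrt((n - 1) / n)
  } else {
    sds <- rep(NA_real_, length(terms))
  }
  out <- tibble::as_tibble(as.list(setNames(means, paste0(terms, "_mean"))))
  out <- dplyr::bind_cols(
    out, tibble::as_tibble(as.list(setNames(sds, paste0(terms, "_sd"))))
  )
  out$n_snapshots <- n
  out$ddg_foldx <- out$total_mean
  out
}
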