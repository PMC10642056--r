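#' Read a classic DSSP output file
#'
#' Parses the fixed-width per-residue block of a DSSP text file (the section
#' following the `  #  RESIDUE AA STRUCTURE` header): PDB residue number with
#' insertion code, chain, amino acid, 8-state secondary-structure code and
#' absolute solvent accessibility (ACC, \eqn{\mathrm{\AA}^2}). A blank
#' structure code becomes class `"none"`; chain-break rows (`!`) are skipped.
#'
#' @param path Path to a DSSP text file.
#' @return A tibble with columns `chain`, `position` (integer, author
#'   numbering), `ins_code` (empty string when absent), `aa`, `ss_class`
#'   (one of [ss_levels]), `acc`.
#' @examples
#' dir <- tempfile(); make_fixture_suite(dir)
#' read_dssp(file.path(dir, "fixture.dssp"))
#' @export
read_dssp <- function(path) {
  if (!file.exists(path)) stop("cannot read DSSP file: ", path)
  lines <- readLines(path, warn = FALSE)
  header_at <- grep("^  #  RESIDUE AA STRUCTURE", lines)[1]
  if (is.na(header_at)) {
    stop("malformed DSSP file (no '  #  RESIDUE AA STRUCTURE' header): ", path)
  }
  body <- lines[-seq_len(header_at)]
  body <- body[nzchar(body)]
  if (length(body) == 0) {
    return(tibble::tibble(chain = character(), position = integer(),
                          ins_code = character(), aa = character(),
                          ss_class = character(), acc = integer()))
  }
  if (any(nchar(body) < 38)) {
    stop("DSSP residue line too short (need >= 38 columns): line ",
         which(nchar(body) < 38)[1])
  }
  aa <- substr(body, 14, 14)
  keep <- aa != "!"
  body <- body[keep]
  aa <- aa[keep]
  ss <- substr(body, 17, 17)
  ss[ss == " "] <- "none"
  bad_ss <- !ss %in% ss_levels()
  if (any(bad_ss)) {
    stop("unrecognized DSSP structure code: '", ss[bad_ss][1], "'")
  }
  tibble::tibble(
    chain = trimws(substr(body, 12, 12)),
    position = as.integer(trimws(substr(body, 6, 10))),
    ins_code = trimws(substr(body, 11, 11)),
    aa = aa,
    ss_class = ss,
    acc = as.integer(trimws(substr(body, 35, 38)))
  )
}
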