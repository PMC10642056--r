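#' Amino-acid property tables
#'
#' Loads the frozen per-residue property tables used to derive biochemical
#' predictors: van der Waals residue volume (\eqn{\mathrm{\AA}^3}),
#' hydrophobicity index at pH 7, formal side-chain charge at pH 7, and
#' residue-specific maximum accessible surface area (\eqn{\mathrm{\AA}^2},
#' theoretical and empirical normalizations). Tables ship as a versioned CSV
#' under `inst/extdata` with source citations in its header.
#'
#' Histidine is near its pKa at physiological pH; its charge defaults to 0 and
#' can be overridden (e.g. `his_charge = 0.1`) if a fractional-protonation
#' convention is preferred.
#'
#' @param his_charge Side-chain charge assigned to histidine (default 0).
#' @return A tibble with one row per standard amino acid (column `aa`,
#'   1-letter code) and columns `volume`, `hydrophobicity`, `charge`,
#'   `max_asa_theoretical`, `max_asa_empirical`.
#' @examples
#' aa_properties()
#' @export
aa_properties <- function(his_charge = 0) {
  path <- system.file("extdata", "aa_properties.csv", package = "ddgbounds",
                      mustWork = TRUE)
  props <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                           progress = FALSE)
  stopifnot(nrow(props) == 20L, setequal(props$aa, amino_acids()))
  props$charge[props$aa == "H"] <- his_charge
  props
}

# fast named lookup used by the feature builder and the generator
aa_property_vector <- function(props, column) {
  setNames(props[[column]], props$aa)
}
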