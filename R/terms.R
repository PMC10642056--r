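# Canonical FoldX energy-term vocabulary shared by the readers, the predictor
# pools and the synthetic generator. 16 constituent terms plus the total.

#' Canonical FoldX energy-term names
#'
#' The 16 constituent free-energy terms reported by FoldX plus the total
#' energy, under the fixed canonical names used throughout the package
#' (column suffixes `_mean`, `_sd` and `_single` are appended to these by the
#' tidy-table layout).
#'
#' @param include_total If `FALSE`, drop `"total"` and return only the 16
#'   constituent terms.
#' @return Character vector of canonical term names, in the package's fixed
#'   order.
#' @examples
#' foldx_term_names()
#' @export
foldx_term_names <- function(include_total = TRUE) {
  terms <- c(
    "backbone_vdw_clash", "cis_bond", "disulfide", "electrostatic",
    "electrostatic_kon", "entropy_mainchain", "entropy_sidechain",
    "helix_dipole", "hbond_backbone", "hbond_sidechain", "ionization",
    "solvation_hydrophobic", "solvation_polar", "torsional_clash",
    "vdw", "vdw_clash", "total"
  )
  if (!include_total) terms <- setdiff(terms, "total")
  terms
}

#' Mapping from FoldX 4 "Dif" column headers to canonical term names
#'
#' FoldX 4 writes one column per energy term using free-text headers; this
#' frozen table maps each header to the package's canonical name. Headers not
#' listed here (water bridge, partial covalent bonds, sloop/mloop entropy,
#' complex entropy) are retained by [read_foldx_dif()] under sanitized raw
#' names but are not part of the canonical 17.
#'
#' @return A tibble with columns `foldx_header` and `canonical`.
#' @export
foldx_column_map <- function() {
  tibble::tribble(
    ~foldx_header,            ~canonical,
    "total energy",           "total",
    "Backbone Hbond",         "hbond_backbone",
    "Sidechain Hbond",        "hbond_sidechain",
    "Van der Waals",          "vdw",
    "Electrostatics",         "electrostatic",
    "Solvation Polar",        "solvation_polar",
    "Solvation Hydrophobic",  "solvation_hydrophobic",
    "Van der Waals clashes",  "vdw_clash",
    "entropy sidechain",      "entropy_sidechain",
    "entropy mainchain",      "entropy_mainchain",
    "cis_bond",               "cis_bond",
    "torsional clash",        "torsional_clash",
    "backbone clash",         "backbone_vdw_clash",
    "helix dipole",           "helix_dipole",
    "disulfide",              "disulfide",
    "electrostatic kon",      "electrostatic_kon",
    "energy Ionisation",      "ionization"
  )
}

# DSSP secondary-structure levels; B is the dummy-coding reference. I (pi
# helix) is a valid level but absent from the datasets this framework targets.
ss_levels <- function() c("B", "E", "G", "H", "I", "S", "T", "none")

amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}
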