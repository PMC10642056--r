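# Synthetic datasets with the statistical structure the analysis assumes:
# per-system groups of mutations, 17 energy-term means and SDs, biochemical
# properties from the real residue tables, and an Error response that is
# linear in a known set of predictors with Gaussian noise. Ground truth is
# attached so selection, interval calibration and parameter recovery can be
# tested end to end.

default_term_params <- function() {
  terms <- foldx_term_names(include_total = FALSE)
  clash <- c("backbone_vdw_clash", "vdw_clash", "torsional_clash")
  small <- c("cis_bond", "disulfide", "electrostatic_kon", "ionization")
  tibble::tibble(
    term = terms,
    dist = ifelse(terms %in% clash, "lognormal", "normal"),
    location = ifelse(terms %in% clash, -0.5, 0),
    scale = ifelse(terms %in% clash, 0.6, ifelse(terms %in% small, 0.1, 0.8)),
    sd_base = ifelse(terms %in% clash, 0.4, 0.3)
  )
}

#' Configuration for the synthetic-data generator
#'
#' Collects every knob of the generator with defaults emulating the study
#' conditions: 10 protein systems of 19-190 mutations each, 17 FoldX term
#' means with per-term SDs arising from a 100-snapshot MD ensemble,
#' biochemical properties drawn from the real residue tables, a
#' destabilizing-skewed experimental ddG, and an Error response
#' `intercept + X beta + u_system + eps` with Gaussian noise. The default
#' true coefficients act on van der Waals, van der Waals clash, side-chain
#' entropy, the SD of the total energy and the proline flag — the predictor
#' profile the folding error model recovers — with magnitudes around
#' 0.35-0.7 kcal/mol per unit and an intercept keeping the linear predictor
#' well above zero, so the non-negativity resampling of Error is rare and the
#' Gaussian model remains essentially correctly specified.
#'
#' @param n_systems Number of protein systems (default 10).
#' @param n_per_system Mutations per system: a scalar, a vector of length
#'   `n_systems`, or a range `c(lo, hi)` sampled uniformly (default
#'   `c(19, 190)`).
#' @param beta Named vector of true coefficients (kcal/mol per unit) over
#'   generated columns.
#' @param intercept Intercept of the Error model (kcal/mol, default 1.5).
#' @param noise_sd Residual SD of the Error model (kcal/mol, default 0.6).
#' @param system_effect_sd SD of the Gaussian per-system intercept shift
#'   (default 0: no between-system heterogeneity).
#' @param proline_prob Probability a mutation involves proline (default 0.1).
#' @param ss_probs Named probabilities over secondary-structure classes; the
#'   rare pi-helix class I defaults to probability 0.
#' @param rsa_shape Beta-distribution shape parameters for RSA (default
#'   `c(1.2, 2.5)`, skewed toward buried residues).
#' @param destab_sign_prob Probability that the experimental ddG lies on the
#'   destabilizing side of the prediction (default 0.7).
#' @param term_params Per-term distribution table (see
#'   `ddgbounds:::default_term_params`).
#' @param snapshot_count Nominal MD ensemble size recorded in the output
#'   (default 100).
#' @param variability_sdlog Log-SD of the per-row conformational-variability
#'   factor scaling all SD columns (default 0.4).
#' @param single_structure Also emit `{term}_single` columns emulating a
#'   FoldX run on one structure (default `TRUE`).
#' @param clamp_negative_error If `TRUE`, negative Error draws are clamped to
#'   0 instead of resampled (a deliberate misspecification switch).
#' @param seed Optional integer seed; the dataset is bit-reproducible given
#'   the seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_systems = 10,
                             n_per_system = c(19, 190),
                             beta = c(vdw_mean = 0.4,
                                      entropy_sidechain_mean = 0.35,
                                      vdw_clash_mean = 0.45,
                                      total_sd = 0.55,
                                      is_proline = 0.7),
                             intercept = 1.5,
                             noise_sd = 0.6,
                             system_effect_sd = 0,
                             proline_prob = 0.1,
                             ss_probs = c(B = 0.05, E = 0.20, G = 0.05,
                                          H = 0.35, I = 0, S = 0.10,
                                          T = 0.10, none = 0.15),
                             rsa_shape = c(1.2, 2.5),
                             destab_sign_prob = 0.7,
                             term_params = default_term_params(),
                             snapshot_count = 100,
                             variability_sdlog = 0.4,
                             single_structure = TRUE,
                             clamp_negative_error = FALSE,
                             seed = NULL) {
  stopifnot(noise_sd >= 0, system_effect_sd >= 0, snapshot_count >= 2,
            proline_prob >= 0, proline_prob <= 1,
            destab_sign_prob >= 0, destab_sign_prob <= 1)
  ss_probs <- ss_probs[ss_levels()[ss_levels() %in% names(ss_probs)]]
  if (abs(sum(ss_probs) - 1) > 1e-8) stop("ss_probs must sum to 1")
  if (!all(names(ss_probs) %in% ss_levels())) stop("unknown ss_probs level")
  structure(
    list(n_systems = n_systems, n_per_system = n_per_system, beta = beta,
         intercept = intercept, noise_sd = noise_sd,
         system_effect_sd = system_effect_sd, proline_prob = proline_prob,
         ss_probs = ss_probs, rsa_shape = rsa_shape,
         destab_sign_prob = destab_sign_prob, term_params = term_params,
         snapshot_count = snapshot_count,
         variability_sdlog = variability_sdlog,
         single_structure = single_structure,
         clamp_negative_error = clamp_negative_error, seed = seed),
    class = "synthetic_config"
  )
}

#' Draw synthetic mutation feature rows
#'
#' Samples predictor columns only (no response): wild-type/mutant pairs drawn
#' over distinct residues with a configurable proline rate, biochemical
#' changes derived from the real property tables, secondary structure and RSA
#' from their configured distributions, per-term energy means (clash terms
#' log-normal, signed terms Gaussian, total = sum of constituents plus noise)
#' and per-term SDs scaled by a per-row conformational-variability factor.
#' Uses the current RNG state; seed control lives in [generate_dataset()].
#'
#' @param config A [synthetic_config()].
#' @param n Number of rows.
#' @return Tibble of feature columns.
#' @export
sample_mutation_features <- function(config, n = 1) {
  stopifnot(inherits(config, "synthetic_config"))
  props <- aa_properties()
  aas <- amino_acids()
  non_p <- setdiff(aas, "P")

  with_p <- runif(n) < config$proline_prob
  wt <- character(n); mut <- character(n)
  # proline-involving pairs get P on a uniformly chosen side
  p_side_wt <- runif(n) < 0.5
  wt[with_p & p_side_wt] <- "P"
  mut[with_p & p_side_wt] <- sample(non_p, sum(with_p & p_side_wt), replace = TRUE)
  mut[with_p & !p_side_wt] <- "P"
  wt[with_p & !p_side_wt] <- sample(non_p, sum(with_p & !p_side_wt), replace = TRUE)
  wt[!with_p] <- sample(non_p, sum(!with_p), replace = TRUE)
  mut[!with_p] <- vapply(wt[!with_p],
                         function(w) sample(setdiff(non_p, w), 1), character(1))

  vol <- aa_property_vector(props, "volume")
  hyd <- aa_property_vector(props, "hydrophobicity")
  chg <- aa_property_vector(props, "charge")

  out <- tibble::tibble(
    wt_aa = wt, mut_aa = mut,
    is_proline = as.integer(wt == "P" | mut == "P"),
    volume_change = unname(abs(vol[wt] - vol[mut])),
    hydrophobicity_change = unname(abs(hyd[wt] - hyd[mut])),
    charge_change = unname(abs(chg[wt] - chg[mut])),
    ss_class = sample(names(config$ss_probs), n, replace = TRUE,
                      prob = config$ss_probs),
    rsa = rbeta(n, config$rsa_shape[1], config$rsa_shape[2])
  )

  tp <- config$term_params
  variability <- rlnorm(n, 0, config$variability_sdlog)
  constituents <- matrix(0, n, nrow(tp), dimnames = list(NULL, tp$term))
  for (i in seq_len(nrow(tp))) {
    constituents[, i] <- if (tp$dist[i] == "lognormal") {
      rlnorm(n, tp$location[i], tp$scale[i])
    } else {
      rnorm(n, tp$location[i], tp$scale[i])
    }
    out[[paste0(tp$term[i], "_mean")]] <- constituents[, i]
    out[[paste0(tp$term[i], "_sd")]] <-
      tp$sd_base[i] * variability * exp(rnorm(n, 0, 0.25))
  }
  out$total_mean <- rowSums(constituents) + rnorm(n, 0, 0.3)
  out$total_sd <- 0.4 * variability * exp(rnorm(n, 0, 0.25))

  if (config$single_structure) {
    singles <- matrix(0, n, nrow(tp), dimnames = list(NULL, tp$term))
    for (i in seq_len(nrow(tp))) {
      sd_col <- out[[paste0(tp$term[i], "_sd")]]
      singles[, i] <- constituents[, i] + rnorm(n, 0, sd_col)
      out[[paste0(tp$term[i], "_single")]] <- singles[, i]
    }
    out$total_single <- rowSums(singles) + rnorm(n, 0, 0.3)
  }
  out
}

#' Generate a synthetic mutation dataset with known ground truth
#'
#' Builds a full per-mutation table in the tidy layout: systems of configured
#' sizes, feature columns from [sample_mutation_features()], and the response
#' mechanism `Error = intercept + X beta + u_system + eps`,
#' `eps ~ N(0, noise_sd^2)`, `u ~ N(0, system_effect_sd^2)`. Negative Error
#' draws (rare under the defaults) are resampled so the magnitude response
#' stays non-negative, unless `clamp_negative_error` clamps them at 0. The
#' experimental ddG is reconstructed as
#' `ddg_exp = ddg_foldx - s * Error` with the sign `s` drawn with the
#' configured destabilizing skew, so the stored Error is exactly
#' `|ddg_foldx - ddg_exp|`.
#'
#' @param config A [synthetic_config()].
#' @return A tibble in the tidy mutation layout with `ddg_exp`, `ddg_foldx`
#'   and all term/biochem columns; attribute `truth` holds the generating
#'   `beta`, `intercept`, `noise_sd`, per-system effects, per-row `error` and
#'   the config.
#' @examples
#' d <- generate_dataset(synthetic_config(n_systems = 3, n_per_system = 25, seed = 7))
#' dplyr::count(d, system_id)
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.null(config$seed)) set.seed(config$seed)

  nps <- config$n_per_system
  sizes <- if (length(nps) == config$n_systems) {
    as.integer(nps)
  } else if (length(nps) == 1) {
    rep(as.integer(nps), config$n_systems)
  } else if (length(nps) == 2) {
    sample(seq(nps[1], nps[2]), config$n_systems, replace = TRUE)
  } else {
    stop("n_per_system must be scalar, a range, or one size per system")
  }
  n <- sum(sizes)
  system_id <- rep(sprintf("SYS%02d", seq_len(config$n_systems)), sizes)

  feats <- sample_mutation_features(config, n)
  dat <- dplyr::bind_cols(
    tibble::tibble(
      system_id = system_id,
      chain = "A",
      position = unlist(lapply(sizes, seq_len), use.names = FALSE)
    ),
    feats
  )

  beta <- config$beta
  missing <- setdiff(names(beta), names(dat))
  if (length(missing) > 0) {
    stop("beta names not among generated columns: ", paste(missing, collapse = ", "))
  }
  eta <- config$intercept +
    as.vector(as.matrix(dat[names(beta)]) %*% unname(beta))
  u <- rnorm(config$n_systems, 0, config$system_effect_sd)
  eta <- eta + rep(u, sizes)

  err <- eta + rnorm(n, 0, config$noise_sd)
  if (config$clamp_negative_error) {
    err <- pmax(err, 0)
  } else if (config$noise_sd > 0) {
    for (round in seq_len(100)) {          # resample rare negative draws
      neg <- which(err < 0)
      if (length(neg) == 0) break
      err[neg] <- eta[neg] + rnorm(length(neg), 0, config$noise_sd)
    }
    err <- pmax(err, 0)
  } else {
    err <- pmax(err, 0)
  }

  s <- ifelse(runif(n) < config$destab_sign_prob, -1, 1)
  dat$ddg_foldx <- dat$total_mean
  dat$ddg_exp <- dat$ddg_foldx - s * err
  dat$n_snapshots <- config$snapshot_count

  attr(dat, "truth") <- list(
    beta = beta, intercept = config$intercept, noise_sd = config$noise_sd,
    system_effects = setNames(u, unique(system_id)),
    error = err, sign = s, config = config
  )
  dat
}

#' Write the fixture suite
#'
#' Writes small plain-text fixtures exercising every reader plus three
#' canonical synthetic datasets — `calibration.csv` (defaults at reduced
#' size), `misspecified.csv` (a true predictor, the SD of the total energy,
#' removed from the observable columns, for under-coverage demonstrations)
#' and `degenerate.csv` (zero noise and coefficients: Error equals the
#' intercept everywhere) — together with an MD5 manifest. Reruns reproduce
#' the checksums bit-for-bit.
#'
#' @param out_dir Output directory (created if needed).
#' @return Tibble manifest (file, md5), invisibly; also written as
#'   `manifest.json`.
#' @export
make_fixture_suite <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # FoldX Dif fixture: banner, header with canonical + extra columns, 3 rows
  map <- foldx_column_map()
  extra <- c("Water bridge", "sloop_entropy", "mloop_entropy",
             "partial covalent bonds", "Entropy Complex")
  header <- c("Pdb", map$foldx_header, extra)
  set.seed(20231112)
  rows <- lapply(1:3, function(i) {
    vals <- round(rnorm(length(header) - 1, 0, 1), 3)
    vals[match("Van der Waals clashes", header) - 1] <- 0.50
    paste(c(sprintf("snap_%d.pdb", i), format(vals, trim = TRUE)),
          collapse = "\t")
  })
  fx <- file.path(out_dir, "dif_fixture.fxout")
  writeLines(c("FoldX fixture banner line", "generated for testing",
               paste(header, collapse = "\t"), unlist(rows)), fx)

  # DSSP fixture: header block, 10 residues across a chain break
  aa <- c("M", "K", "L", "V", "P", "G", "A", "S", "T", "W")
  ss <- c("H", "H", "E", "E", " ", "T", "G", "S", "B", " ")
  acc <- c(120, 45, 3, 0, 88, 60, 15, 75, 10, 140)
  res_line <- function(serial, resnum, chain, aa, ss, acc) {
    sprintf("%5d%5d %1s %1s  %1s%17s%4d", serial, resnum, chain, aa, ss, "", acc)
  }
  lines <- c(
    "==== Secondary Structure Definition, fixture ====",
    "REFERENCE fixture",
    "  10  1  0  0  0  TOTAL NUMBER OF RESIDUES",
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC     N-H-->O    O-->H-N",
    mapply(res_line, 1:5, 1:5, "A", aa[1:5], ss[1:5], acc[1:5]),
    sprintf("%5d%5s %1s %1s%24s", 6L, "", "", "!", ""),
    mapply(res_line, 7:11, 1:5, "B", aa[6:10], ss[6:10], acc[6:10])
  )
  ds <- file.path(out_dir, "fixture.dssp")
  writeLines(lines, ds)

  # tidy 5-row fixture and the three canonical synthetic datasets
  small <- generate_dataset(synthetic_config(n_systems = 2, n_per_system = 3,
                                             seed = 11))
  tidy_path <- file.path(out_dir, "tidy_fixture.csv")
  write_tidy_table(head(small, 5), tidy_path)

  calib <- generate_dataset(synthetic_config(n_systems = 4, n_per_system = 15,
                                             seed = 101))
  calib_path <- file.path(out_dir, "calibration.csv")
  write_tidy_table(calib, calib_path)

  miss <- generate_dataset(synthetic_config(n_systems = 4, n_per_system = 15,
                                            seed = 102))
  miss$total_sd <- NULL                     # hide a true predictor
  miss_path <- file.path(out_dir, "misspecified.csv")
  write_tidy_table(miss, miss_path)

  degen <- generate_dataset(synthetic_config(
    n_systems = 2, n_per_system = 10, seed = 103,
    beta = setNames(numeric(0), character(0)), noise_sd = 0
  ))
  degen_path <- file.path(out_dir, "degenerate.csv")
  write_tidy_table(degen, degen_path)

  files <- c(fx, ds, tidy_path, calib_path, miss_path, degen_path)
  manifest <- tibble::tibble(
    file = basename(files),
    md5 = unname(tools::md5sum(files))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       pretty = TRUE)
  invisible(manifest)
}
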