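test_that("the Error response is the absolute ddG difference", {
  expect_equal(compute_error(2.0, 2.0), 0.0)
  expect_equal(compute_error(-1.3, 0.4), 1.7)
  expect_error(compute_error(NA_real_, 1), "finite")
  # symmetry and triangle-style bound, over random triples
  set.seed(1)
  for (i in 1:50) {
    abc <- rnorm(3, 0, 3)
    expect_equal(compute_error(abc[1], abc[2]), compute_error(abc[2], abc[1]))
    expect_lte(compute_error(abc[1], abc[3]),
               compute_error(abc[1], abc[2]) + compute_error(abc[2], abc[3]))
  }
})

test_that("biochemical properties derive from the frozen residue tables", {
  props <- aa_properties()
  dssp <- tibble::tibble(chain = "A", position = 1:4,
                         ins_code = "", aa = c("L", "A", "G", "K"),
                         ss_class = c("H", "E", "none", "T"),
                         acc = c(10L, 50L, 104L, 500L))
  muts <- tibble::tibble(chain = "A", position = 1:4,
                         wt_aa = c("L", "A", "G", "K"),
                         mut_aa = c("L", "P", "W", "E"))
  expect_warning(out <- compute_biochem_props(muts, dssp, props),
                 "RSA > 1")

  # hypothetical identity substitution: all change fields vanish
  expect_equal(out$volume_change[1], 0)
  expect_equal(out$hydrophobicity_change[1], 0)
  expect_equal(out$charge_change[1], 0)
  expect_equal(out$is_proline[1], 0L)
  # proline on either side sets the flag
  expect_equal(out$is_proline[2], 1L)
  # G -> W volume change against an independent table lookup
  vol <- setNames(props$volume, props$aa)
  expect_equal(out$volume_change[3], abs(vol["G"] - vol["W"]),
               ignore_attr = TRUE)
  # K -> E crosses the charge scale: |+1 - (-1)| = 2
  expect_equal(out$charge_change[4], 2)
  # RSA = ACC / maxASA(wt), clipped into [0, 1]
  masa <- setNames(props$max_asa_theoretical, props$aa)
  expect_equal(out$rsa[1], 10 / masa[["L"]])
  expect_equal(out$rsa[3], 1)           # ACC equals glycine's max
  expect_equal(out$rsa[4], 1)           # over-max ACC clipped
  expect_equal(out$ss_class, c("H", "E", "none", "T"))
  # change fields are symmetric under wt/mut swap
  swapped <- suppressWarnings(compute_biochem_props(
    dplyr::mutate(muts, wt = wt_aa, wt_aa = mut_aa, mut_aa = wt),
    dplyr::mutate(dssp, aa = muts$mut_aa), props
  ))
  expect_equal(swapped$volume_change, out$volume_change)
  expect_equal(swapped$charge_change, out$charge_change)
})

test_that("predictor pools carry the documented column manifests", {
  d <- generate_dataset(synthetic_config(n_systems = 3, n_per_system = 15,
                                         seed = 5))
  pt5 <- build_predictor_table(d, "model5")
  # 17 means + 17 SDs + 4 scalar biochem + 7 SS dummies + rsa
  expect_equal(length(pool_columns("model5")), 17 + 17 + 4 + 7 + 1)
  expect_named(pt5, c("system_id", "error_abs", pool_columns("model5")))
  expect_equal(length(pool_columns("model1")), 17)
  expect_equal(length(pool_columns("model2")), 17 + 4 + 7 + 1)

  # models 1 and 3 differ in which FoldX run feeds both terms and response
  pt1 <- build_predictor_table(d, "model1")
  pt3 <- build_predictor_table(d, "model3")
  expect_true(all(grepl("_single$", setdiff(names(pt1), c("system_id", "error_abs")))))
  expect_equal(pt1$error_abs, compute_error(d$total_single, d$ddg_exp))
  expect_equal(pt3$error_abs, compute_error(d$total_mean, d$ddg_exp))
  # response is a magnitude
  expect_true(all(pt5$error_abs >= 0))
})

test_that("secondary-structure dummies sum to 1 unless the class is B", {
  d <- generate_dataset(synthetic_config(n_systems = 4, n_per_system = 40,
                                         seed = 9))
  pt <- build_predictor_table(d, "model4")
  dummy_sum <- rowSums(pt[intersect(names(pt), paste0("ss_", c("E","G","H","I","S","T","none")))])
  expect_equal(dummy_sum, as.numeric(d$ss_class != "B"))
})

test_that("pool construction fails without its required columns", {
  d <- generate_dataset(synthetic_config(n_systems = 3, n_per_system = 10,
                                         seed = 2, single_structure = FALSE))
  expect_error(build_predictor_table(d, "model1"), "total_single")
  d2 <- d
  d2$rsa <- NULL
  expect_error(build_predictor_table(d2, "model5"), "biochemical")
  d3 <- d[d$system_id == d$system_id[1], ]
  expect_error(build_predictor_table(d3, "model3"), "2 systems")
})
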