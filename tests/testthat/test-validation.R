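truth_cols <- c("vdw_mean", "entropy_sidechain_mean", "vdw_clash_mean",
                "total_sd", "is_proline")

test_that("coverage uses the strict indicator", {
  expect_equal(coverage(c(1, 2, 3), c(2, 3, 4)), 1.0)
  expect_equal(coverage(c(1, 2), c(1, 3)), 0.5)   # tie counts as a miss
  set.seed(3)
  e <- runif(200); b <- runif(200)
  expect_equal(coverage(e, b), sum(e < b) / 200)
  expect_error(coverage(numeric(0), numeric(0)), "empty")
  expect_error(coverage(1:3, 1:2), "mismatch")
})

test_that("LOSO coverage identity: overall equals size-weighted per-system mean", {
  d <- generate_dataset(synthetic_config(n_systems = 6,
                                         n_per_system = c(20, 60), seed = 51))
  pt <- build_predictor_table(d, "model5")
  lo <- loso_cv(pt, selector = truth_cols)
  per <- lo$per_system
  expect_equal(lo$overall$coverage,
               sum(per$coverage * per$n) / sum(per$n))
  expect_equal(sum(per$n), lo$overall$n)
  expect_equal(sum(per$n_outliers),
               sum(!lo$predictions$captured))
})

test_that("LOSO is deterministic and invariant to row order", {
  d <- generate_dataset(synthetic_config(n_systems = 4, n_per_system = 25,
                                         seed = 53))
  pt <- build_predictor_table(d, "model3")
  lo1 <- loso_cv(pt, selector = truth_cols[1:3])
  lo2 <- loso_cv(pt, selector = truth_cols[1:3])
  expect_equal(lo1$predictions, lo2$predictions)
  set.seed(1)
  perm <- sample(nrow(pt))
  pt_shuf <- pt[perm, ]
  attr(pt_shuf, "mutation_keys") <- attr(pt, "mutation_keys")[perm]
  lo3 <- loso_cv(pt_shuf, selector = truth_cols[1:3])
  expect_equal(lo3$overall$coverage, lo1$overall$coverage)
  expect_equal(lo3$overall$median_width, lo1$overall$median_width)
  expect_equal(
    dplyr::arrange(lo3$per_system, system_id)$coverage,
    dplyr::arrange(lo1$per_system, system_id)$coverage
  )
})

test_that("selection re-runs per fold without leaking the held-out system", {
  d <- generate_dataset(synthetic_config(n_systems = 5, n_per_system = 30,
                                         seed = 57))
  pt <- build_predictor_table(d, "model3")
  sub <- pt[c("system_id", "error_abs", "vdw_mean", "entropy_sidechain_mean",
              "vdw_clash_mean")]
  sel_cfg <- list(method = "best_subset", max_size = 3)
  base <- loso_cv(sub, selector = sel_cfg)
  # inject a response-leaking column in the held-out system only; elsewhere noise
  held <- "SYS01"
  leak <- sub
  set.seed(99)
  leak$leaky <- ifelse(leak$system_id == held, leak$error_abs,
                       rnorm(nrow(leak)))
  with_leak <- loso_cv(leak, selector = sel_cfg)
  expect_equal(with_leak$models[[held]]$blocks, base$models[[held]]$blocks)
  expect_equal(
    with_leak$predictions$bound[with_leak$predictions$system_id == held],
    base$predictions$bound[base$predictions$system_id == held]
  )
  # per-fold chosen subsets are exposed and may differ across folds
  expect_named(base$models, unique(sub$system_id))
})

test_that("system heterogeneity widens the between-system coverage spread", {
  var_between <- function(effect_sd) {
    vapply(1:5, function(seed) {
      d <- generate_dataset(synthetic_config(
        n_systems = 8, n_per_system = 40, seed = 1000 + seed,
        system_effect_sd = effect_sd
      ))
      pt <- build_predictor_table(d, "model5")
      var(loso_cv(pt, selector = truth_cols)$per_system$coverage)
    }, numeric(1))
  }
  expect_gt(mean(var_between(1.0)), mean(var_between(0)))
})

test_that("per-system summary mirrors brute-force group medians", {
  d <- generate_dataset(synthetic_config(n_systems = 5, n_per_system = 25,
                                         seed = 61))
  pt <- build_predictor_table(d, "model5")
  lo <- loso_cv(pt, selector = truth_cols)
  tab <- summarize_by_system(lo)
  expect_equal(nrow(tab), 6)            # 5 systems + Total
  for (sys in unique(pt$system_id)) {
    rows <- lo$predictions[lo$predictions$system_id == sys, ]
    expect_equal(tab$median_error[tab$system_id == sys], median(rows$error_abs))
    expect_equal(tab$median_width[tab$system_id == sys], median(rows$bound))
    expect_equal(tab$coverage_pct[tab$system_id == sys],
                 100 * mean(rows$error_abs < rows$bound))
  }
  expect_equal(tab$n[tab$system_id == "Total"], nrow(pt))
  expect_equal(tidy(lo), tab)
  expect_equal(glance(lo)$coverage, lo$overall$coverage)
})

test_that("outlier goodness-of-fit arithmetic and p-values", {
  # proportional outliers: zero statistic, Monte-Carlo p of 1
  g0 <- outlier_gof_test(c(2, 4, 6), c(10, 20, 30), seed = 1)
  expect_equal(g0$statistic, 0)
  expect_equal(g0$p_value, 1.0)
  # hand-computed two-system toy: E = (2.5, 2.5), stat = 2.5 + 2.5 = 5
  g1 <- outlier_gof_test(c(5, 0), c(50, 50), method = "asymptotic")
  expect_equal(g1$statistic, 5)
  expect_equal(g1$p_value, pchisq(5, df = 1, lower.tail = FALSE))
  # asymptotic route agrees with the standard chi-squared test
  ref <- suppressWarnings(stats::chisq.test(c(5, 0), p = c(0.5, 0.5)))
  expect_equal(g1$statistic, unname(ref$statistic))
  expect_equal(g1$p_value, ref$p.value)
  # extreme departure with 2000 replicates: no exceedances, p = 1/2001
  g2 <- outlier_gof_test(c(40, 0, 0, 0), c(25, 25, 25, 25),
                         reps = 2000, seed = 7)
  expect_equal(g2$p_value, 1 / 2001)
  expect_equal(round(g2$p_value, 5), 0.00050)
  expect_error(outlier_gof_test(c(0, 0), c(5, 5)), "at least one")
})
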