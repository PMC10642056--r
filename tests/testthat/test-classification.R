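test_that("point classification follows the +/-0.5 kcal/mol thresholds", {
  expect_equal(as.character(classify_exp(-0.7)), "stabilizing")
  expect_equal(as.character(classify_exp(0.5)), "neutral")   # boundary inclusive
  expect_equal(as.character(classify_exp(-0.5)), "neutral")
  expect_equal(as.character(classify_exp(0.6)), "destabilizing")
  expect_error(classify_exp(Inf), "finite")
})

test_that("interval classification reports every overlapped class", {
  out <- classify_with_bounds(c(4.0, 0.0, 2.6), c(1.0, 1.0, 2.0))
  expect_equal(as.character(out$label), c("destabilizing", "ambiguous",
                                          "destabilizing"))
  expect_equal(out$labels_overlapped[2],
               "stabilizing+neutral+destabilizing")
  expect_true(out$unambiguous[3])      # lower end 0.6 stays above 0.5
  expect_equal(out$lower[3], 0.6)
  expect_error(classify_with_bounds(1, -0.1), "non-negative")
})

test_that("zero bound degenerates to the point classification", {
  set.seed(71)
  x <- runif(1e4, -6, 6)
  b0 <- classify_with_bounds(x, 0)
  expect_true(all(b0$unambiguous))
  expect_equal(as.character(b0$label), as.character(classify_exp(x)))
})

test_that("the overlapped label set grows with the bound", {
  set.seed(73)
  x <- runif(200, -4, 4)
  small <- classify_with_bounds(x, 0.3)
  big <- classify_with_bounds(x, 1.7)
  for (cls in c("stabilizing", "neutral", "destabilizing")) {
    expect_true(all(big[[cls]] >= small[[cls]]))
  }
})

test_that("bin frequencies sum to one and match brute-force counts", {
  set.seed(79)
  d <- tibble::tibble(ddg_foldx = runif(20, -3, 3),
                      ddg_exp = runif(20, -3, 3))
  fr <- bin_frequencies(d)
  sums <- fr |>
    dplyr::filter(n_bin > 0) |>
    dplyr::group_by(bin) |>
    dplyr::summarise(s = sum(freq))
  expect_true(all(abs(sums$s - 1) < 1e-12))
  # brute force a single bin
  edges <- default_bin_edges(d$ddg_foldx)
  in_bin <- d$ddg_foldx > edges[1] & d$ddg_foldx <= edges[2]
  lab <- levels(cut(d$ddg_foldx, edges))[1]
  for (cls in c("stabilizing", "neutral", "destabilizing")) {
    want <- sum(classify_exp(d$ddg_exp[in_bin]) == cls)
    got <- fr$count[fr$bin == lab & fr$class == cls]
    expect_equal(got, want)
  }
  # single-bin degenerate case: all destabilizing mass in one bin
  d2 <- tibble::tibble(ddg_foldx = rep(1.2, 5), ddg_exp = rep(3, 5))
  fr2 <- bin_frequencies(d2, bins = bin_spec("ddg_foldx", c(0.5, 1.5)))
  expect_equal(fr2$freq[fr2$class == "destabilizing"], 1)
  # bounded mode includes the ambiguous outcome and still sums to 1
  d$bound <- 1.5
  frb <- bin_frequencies(d, classifier = "bounded")
  sumsb <- frb |>
    dplyr::filter(n_bin > 0) |>
    dplyr::group_by(bin) |>
    dplyr::summarise(s = sum(freq))
  expect_true(all(abs(sumsb$s - 1) < 1e-12))
  expect_error(bin_frequencies(d[0, ]), "empty")
})

test_that("uniform-bin resampling is exact in size and seed-reproducible", {
  set.seed(83)
  d <- tibble::tibble(ddg_exp = c(runif(120, -2.4, 2.4), 6.0),
                      id = 1:121)
  expect_warning(r1 <- resample_uniform_bins(d, n_per_bin = 1000, seed = 7),
                 "empty bin")   # the gap below the outlier row
  n_bins <- length(unique(r1$.bin))
  expect_equal(nrow(r1), 1000 * n_bins)
  expect_equal(unname(table(r1$.bin))[1], 1000L, ignore_attr = TRUE)
  r2 <- suppressWarnings(resample_uniform_bins(d, n_per_bin = 1000, seed = 7))
  expect_identical(r1, r2)
  r3 <- suppressWarnings(resample_uniform_bins(d, n_per_bin = 1000, seed = 8))
  expect_false(identical(r1, r3))
  # a single-row bin resamples only itself
  lone_bin <- r1$.bin[r1$id == 121][1]
  expect_true(all(r1$id[r1$.bin == lone_bin] == 121))
})

test_that("resampled class frequencies converge to the source bin frequencies", {
  set.seed(89)
  d <- tibble::tibble(ddg_exp = runif(400, -3, 3))
  d$class <- classify_exp(d$ddg_exp)
  spec <- bin_spec("ddg_exp", c(-3.5, -0.5, 0.5, 3.5))
  r <- resample_uniform_bins(d, bins = spec, n_per_bin = 1e5, seed = 11)
  bin_of <- cut(d$ddg_exp, spec$edges)
  for (b in unique(r$.bin)) {
    src <- d$class[as.character(bin_of) == b]
    p_src <- mean(src == "neutral")
    p_res <- mean(r$class[r$.bin == b] == "neutral")
    se <- sqrt(max(p_src * (1 - p_src), 1e-12) / 1e5)
    expect_lt(abs(p_res - p_src), max(3 * se, 1e-6))
  }
})
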