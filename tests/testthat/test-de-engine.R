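test_that("size factors reproduce hand-computed median-of-ratios values", {
  eq <- make_counts(matrix(c(5, 9, 5, 9), 2))
  expect_equal(estimate_size_factors(eq)$size_factor, c(1, 1))

  two <- make_counts(matrix(c(10, 30, 20, 60), 2))
  expect_equal(estimate_size_factors(two)$size_factor,
               c(1 / sqrt(2), sqrt(2)), tolerance = 1e-4)
})

test_that("size factors equal an independent brute-force oracle on random matrices", {
  set.seed(99)
  for (rep in 1:5) {
    m <- matrix(rpois(20 * 4, 50), nrow = 20)
    cm <- make_counts(m)
    expect_equal(estimate_size_factors(cm)$size_factor, size_factor_oracle(m),
                 tolerance = 1e-12)
  }
})

test_that("size factors recover proportional columns up to a common scale", {
  set.seed(7)
  base <- rpois(50, 80) + 1
  scale <- c(0.5, 1, 2, 4)
  m <- outer(base, scale)
  cm <- make_counts(m)
  s <- estimate_size_factors(cm)$size_factor
  expect_equal(s / s[2], scale / scale[2], tolerance = 1e-10)
})

test_that("size factors match DESeq2's median-of-ratios implementation", {
  set.seed(11)
  m <- matrix(rnbinom(200 * 6, mu = 150, size = 8), nrow = 200)
  m[m == 0] <- 1
  cm <- make_counts(m)
  ours <- estimate_size_factors(cm)$size_factor
  theirs <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(ours, unname(theirs), tolerance = 1e-5)
})

test_that("all-zero-free reference absent triggers the total-count fallback", {
  m <- matrix(c(0, 5, 8, 0), 2)  # every gene has a zero somewhere
  cm <- make_counts(m)
  expect_warning(sf <- estimate_size_factors(cm), "total-count")
  tot <- colSums(m)
  expect_equal(sf$size_factor, tot / exp(mean(log(tot))))
})

test_that("dispersion estimates floor at alpha_min for constant and Poisson genes", {
  sheet <- study_sheet()
  const <- make_counts(matrix(100, 1, 15), sample_ids = sheet$sample_id)
  sf <- unit_size_factors(sheet$sample_id)
  expect_equal(estimate_dispersions(const, sf, sheet)$dispersion, 1e-8)

  set.seed(21)
  pois <- make_counts(matrix(rpois(5000 * 15, 100), 5000),
                      sample_ids = sheet$sample_id)
  d <- estimate_dispersions(pois, sf, sheet)
  expect_lt(median(d$dispersion), 0.02)
})

test_that("dispersion estimates are calibrated for NB counts", {
  sheet <- study_sheet()
  set.seed(22)
  nb <- make_counts(matrix(rnbinom(5000 * 15, mu = 200, size = 5), 5000),
                    sample_ids = sheet$sample_id)
  d <- estimate_dispersions(nb, unit_size_factors(sheet$sample_id), sheet)
  expect_gt(median(d$dispersion), 0.1)
  expect_lt(median(d$dispersion), 0.3)
})

test_that("within-line centering keeps between-line signal out of the dispersion", {
  sheet <- study_sheet()
  # strong fibroblast-vs-rest difference, no within-line noise beyond Poisson
  set.seed(23)
  mu <- ifelse(sheet$cell_class == "fibroblast", 1000, 50)
  m <- t(vapply(1:2000, function(i) rpois(15, mu), numeric(15)))
  d <- estimate_dispersions(make_counts(m, sample_ids = sheet$sample_id),
                            unit_size_factors(sheet$sample_id), sheet)
  expect_lt(median(d$dispersion), 0.02)
})

test_that("the Wald test matches closed forms on symmetric and shifted groups", {
  sheet <- study_sheet()
  m <- rbind(rep(100, 6), c(100, 100, 100, 400, 400, 400))
  cm <- make_counts(m, gene_ids = c("null", "shift"), sample_ids = sheet$sample_id[1:6])
  sf <- unit_size_factors(sheet$sample_id[1:6])
  disp <- tibble::tibble(gene_id = c("null", "shift"), dispersion = 0.1)
  de <- nb_wald_test(cm, sf, disp, sheet$sample_id[1:3], sheet$sample_id[4:6])
  expect_equal(de$log2fc[1], 0)
  expect_equal(de$wald_z[1], 0)
  expect_equal(de$pvalue[1], 1)
  # with unit size factors the group MLE is the sample mean: log2(400/100)
  expect_equal(de$log2fc[2], 2, tolerance = 1e-8)
  expect_equal(de$base_mean_a[2], 100, tolerance = 1e-8)
  expect_equal(de$base_mean_b[2], 400, tolerance = 1e-8)
  expect_equal(sign(de$log2fc), sign(de$base_mean_b - de$base_mean_a))
})

test_that("group MLE equals the normalized group mean under equal size factors", {
  set.seed(31)
  sheet <- study_sheet()
  m <- matrix(rnbinom(50 * 6, mu = 80, size = 5), 50)
  cm <- make_counts(m, sample_ids = sheet$sample_id[1:6])
  sf <- tibble::tibble(sample_id = sheet$sample_id[1:6], size_factor = 2)
  disp <- tibble::tibble(gene_id = cm$gene_id, dispersion = runif(50, 0.01, 1))
  de <- nb_wald_test(cm, sf, disp, sheet$sample_id[1:3], sheet$sample_id[4:6])
  expect_equal(de$base_mean_a, rowMeans(m[, 1:3]) / 2, tolerance = 1e-8)
  expect_equal(de$base_mean_b, rowMeans(m[, 4:6]) / 2, tolerance = 1e-8)
  expect_equal(de$log2fc, log2(de$base_mean_b / de$base_mean_a), tolerance = 1e-10)
})

test_that("all-zero genes are flagged untestable or extreme, never infinite", {
  sheet <- study_sheet()
  m <- rbind(rep(0, 6), c(0, 0, 0, 50, 60, 70))
  cm <- make_counts(m, gene_ids = c("dead", "onesided"),
                    sample_ids = sheet$sample_id[1:6])
  sf <- unit_size_factors(sheet$sample_id[1:6])
  disp <- tibble::tibble(gene_id = cm$gene_id, dispersion = 0.1)
  de <- nb_wald_test(cm, sf, disp, sheet$sample_id[1:3], sheet$sample_id[4:6])
  expect_equal(de$flag, c("untestable", "extreme"))
  expect_equal(de$pvalue[1], 1)
  expect_equal(de$log2fc[1], 0)
  expect_true(is.finite(de$log2fc[2]))
  expect_equal(de$qvalue[1], 1)  # excluded from the BH denominator
})

test_that("null p-values are calibrated: type-I error and coarse uniformity", {
  ne <- null_experiment(10000, mu = 100, alpha = 0.1, seed = 101)
  sf <- estimate_size_factors(ne$counts)
  disp <- estimate_dispersions(ne$counts, sf, ne$sheet)
  de <- nb_wald_test(ne$counts, sf, disp,
                     group_a = ne$sheet$sample_id[1:3],
                     group_b = ne$sheet$sample_id[4:6])
  expect_gt(mean(de$pvalue < 0.05), 0.02)
  expect_lt(mean(de$pvalue < 0.05), 0.10)
  D <- suppressWarnings(stats::ks.test(de$pvalue, "punif")$statistic)
  expect_lt(D, 0.05)
})

test_that("BH adjustment follows the step-up definition", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(5)
  for (rep in 1:20) {
    p <- runif(sample(1:50, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-12))
    expect_true(all(q <= 1))
    # monotone in p and invariant to input order
    o <- sample(length(p))
    expect_equal(bh_adjust(p[o]), q[o], tolerance = 1e-12)
    expect_true(all(diff(q[order(p)]) > -1e-12))
  }
})
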