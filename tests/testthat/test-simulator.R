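test_that("the exponent threshold is strict at 1", {
  expect_equal(bloom_threshold(0.5), 0)
  expect_equal(bloom_threshold(1.5), 1.5)
  expect_equal(bloom_threshold(1.0), 0)
  expect_equal(bloom_threshold(c(-2, 1.2)), c(0, 1.2))
})

test_that("noiseless baseline is flat at one and blooms recur as expected", {
  # sin(x) never exceeds 1, so with b = 0 the threshold gates everything
  flat <- simulate_series(n = 93, b = 0, snr = Inf)
  expect_true(all(flat == 1))
  # with a strong recurrent bloom, maxima recur once per slow cycle
  s <- simulate_series(n = 400, b = 10, p = 10, snr = Inf)
  expect_true(all(s > 0))
  period <- 2 * pi * 10
  # count bloom episodes as runs of strong elevation, one per slow cycle
  runs <- rle(s > exp(5))
  n_blooms <- sum(runs$values)
  expect_true(n_blooms %in% (floor(400 / period) + 0:1))
})

test_that("series are reproducible under a fixed seed and strictly positive", {
  set.seed(41); a <- simulate_series()
  set.seed(41); b <- simulate_series()
  expect_identical(a, b)
  expect_true(all(a > 0))
  set.seed(42)
  tr1 <- simulate_trial(); set.seed(42); tr2 <- simulate_trial()
  expect_identical(tr1$series, tr2$series)
})

test_that("single-bloom mode confines the bloom to one window", {
  set.seed(43)
  s <- simulate_series(n = 93, b = 10, p = 20, snr = Inf, recurrent = FALSE,
                       bloom_start = 30)
  expect_true(all(s[1:25] <= exp(1) + 1e-9))   # outside window: basal only
  expect_gt(max(s[30:49]), exp(2))
})

test_that("planted truth layout marks one pair of each type", {
  tr <- simulate_trial()
  ut <- upper.tri(tr$truth)
  expect_equal(sum(tr$truth[ut] == 1), 1)
  expect_equal(sum(tr$truth[ut] == 2), 1)
  expect_equal(sum(tr$truth[ut] == 3), 1)
  expect_equal(sum(tr$truth[ut] == 0), 25)
})

test_that("noiseless type-2 pair shows the planted frequency signature", {
  set.seed(44)
  found <- replicate(10, {
    tr <- simulate_trial(b = 10, p = 20, snr = Inf)
    da <- wavelet_decompose(tr$series["S3", ])
    db <- wavelet_decompose(tr$series["S4", ])
    fine <- min(level_similarity(da, db, 1), level_similarity(da, db, 2))
    coarse <- max(level_similarity(da, db, 3), level_similarity(da, db, 4))
    pear <- cor(tr$series["S3", ], tr$series["S4", ])
    c(fine, coarse, pear)
  })
  expect_lt(mean(found[1, ]), -0.8)   # strong anti-similarity, fine levels
  expect_gt(mean(found[2, ]), 0.5)    # positive similarity, coarse levels
  # Pearson sees far less of the coupling than the level-wise similarity
  expect_lt(mean(abs(found[3, ])), 0.6)
  expect_lt(mean(abs(found[3, ])), mean(abs(found[1, ])) - 0.2)
})

test_that("trial averaging separates planted pairs from unrelated ones", {
  ve <- validation_experiment(n_trials = 40, seed = 45)
  ut <- upper.tri(ve$truth)
  expect_gt(mean(ve$mean_pospos[ut & ve$truth == 1]),
            3 * mean(ve$mean_pospos[ut & ve$truth == 0]))
  expect_gt(mean(ve$mean_negpos[ut & ve$truth == 2]),
            3 * mean(ve$mean_negpos[ut & ve$truth == 0]))
  # single-trial mode returns raw matrices
  one <- validation_experiment(n_trials = 1, seed = 46)
  expect_equal(dim(one$mean_pospos), c(8L, 8L))
})

test_that("sensitivity grid reports both modes over the parameter grid", {
  sg <- sensitivity_grid(b_grid = c(5, 10), p_grid = 20, n_trials = 5,
                         seed = 47)
  expect_setequal(unique(sg$mode), c("pospos", "negpos"))
  expect_equal(nrow(sg), 2 * 2 * 4)
  expect_true(all(is.finite(sg$mean_score)))
})
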