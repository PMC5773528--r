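test_that("mutual information matches the double-sum oracle and its bounds", {
  # MI of a partition with itself is its entropy
  u <- rep(1:2, each = 5)
  expect_equal(mutual_information(u, u), log(2), tolerance = 1e-12)
  # a single cluster carries no information
  expect_equal(mutual_information(u, rep(1, 10)), 0)
  set.seed(21)
  for (rep in 1:5) {
    a <- sample(1:4, 20, TRUE); b <- sample(1:3, 20, TRUE)
    mi <- mutual_information(a, b)
    expect_equal(mi, oracle_mi(a, b), tolerance = 1e-12)
    expect_equal(mi, mutual_information(b, a), tolerance = 1e-12)
    n <- 20
    expect_lte(mi, min(entropy_of_labels(a), entropy_of_labels(b)) + 1e-12)
  }
  # base-2 reporting
  expect_equal(mutual_information(u, u, base = 2), 1, tolerance = 1e-12)
})

test_that("expected MI matches exhaustive enumeration on a tiny case", {
  u <- c(1, 1, 1, 2, 2)
  v <- c(1, 2, 1, 2, 2)
  emi_exact <- oracle_expected_mi(u, v)   # mean over all 120 permutations
  emi_impl <- waveclust:::expected_mutual_information(
    tabulate(u), tabulate(v), 5)
  expect_equal(emi_impl, emi_exact, tolerance = 1e-12)
})

test_that("AMI is 1 for identical partitions and label-permutation invariant", {
  set.seed(22)
  u <- sample(1:5, 40, TRUE)
  expect_equal(adjusted_mutual_information(u, u), 1, tolerance = 1e-9)
  relab <- c(3, 5, 1, 2, 4)[u]
  expect_equal(adjusted_mutual_information(u, relab), 1, tolerance = 1e-9)
  v <- sample(1:4, 40, TRUE)
  expect_equal(adjusted_mutual_information(u, v),
               adjusted_mutual_information(c(9, 2, 7, 5, 1)[u], v),
               tolerance = 1e-12)
})

test_that("AMI against random same-size partitions centres on zero", {
  set.seed(23)
  fixed <- stats::setNames(rep(1:10, each = 10), paste0("i", 1:100))
  amis <- replicate(200, adjusted_mutual_information(
    fixed, stats::setNames(sample(rep(1:10, each = 10)), names(fixed))))
  expect_lt(abs(mean(amis)), 0.02)
})

test_that("co-membership split is tested against the size-preserving null", {
  set.seed(24)
  # all pairs in one community: everything lands in "same"
  memb1 <- stats::setNames(rep(1L, 10), paste0("o", 1:10))
  prs <- data.frame(otu_a = paste0("o", 1:5), otu_b = paste0("o", 6:10),
                    distance = runif(5, 0, 0.06))
  one <- comembership_analysis(prs, memb1)
  expect_equal(unname(one$observed["same"]), 5)
  # two equal communities: null co-membership probability has closed form
  memb2 <- stats::setNames(rep(1:2, each = 10), paste0("o", 1:20))
  ids <- names(memb2)
  all_pairs <- t(combn(ids, 2))
  prs2 <- data.frame(otu_a = all_pairs[, 1], otu_b = all_pairs[, 2],
                     distance = runif(nrow(all_pairs), 0, 0.06))
  res <- comembership_analysis(prs2, memb2)
  expect_equal(res$p_same_null, 2 * 10 * 9 / (20 * 19), tolerance = 1e-12)
  # observed equals the complete enumeration, so expected == observed here
  expect_equal(unname(res$observed["same"]), 2 * choose(10, 2))
  expect_lt(res$statistic, 1e-9)
  expect_error(comembership_analysis(
    data.frame(otu_a = "o1", otu_b = "zz", distance = 0.01), memb2),
    "missing")
})

test_that("planted avoidance of co-membership is detected by the chi-square", {
  set.seed(25)
  n <- 40
  memb <- stats::setNames(rep(1:4, each = 10), paste0("o", 1:n))
  # plant: close pairs always straddle communities
  a <- paste0("o", 1:10); b <- paste0("o", 11:20)
  prs <- data.frame(otu_a = rep(a, 4), otu_b = rep(b, 4),
                    distance = runif(40, 0, 0.03))
  res <- comembership_analysis(prs, memb)
  expect_lt(unname(res$observed["same"]), unname(res$expected["same"]))
  expect_gt(res$statistic, qchisq(0.95, df = 1))
})
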