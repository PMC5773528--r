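test_that("raw scores implement the thresholded geometric means", {
  p <- score_params()
  expect_equal(raw_score_pospos(0.8, 0.9, p), sqrt(0.72), tolerance = 1e-12)
  expect_equal(raw_score_pospos(0.6, 0.9, p), 0)   # high side fails > 0.7
  expect_equal(raw_score_pospos(1.0, 1.0, p), 1)
  expect_equal(raw_score_negpos(-0.8, 0.9, p), sqrt(0.72), tolerance = 1e-12)
  expect_equal(raw_score_negpos(-0.4, 0.9, p), 0)  # high side fails < -0.5
  expect_equal(raw_score_negpos(-1.0, 1.0, p), 1)
  # thresholds are strict at the boundary
  expect_equal(raw_score_pospos(0.7, 0.9, p), 0)
  expect_equal(raw_score_negpos(-0.5, 0.9, p), 0)
})

test_that("period-separation weights reproduce the printed calibration", {
  expect_equal(weight_pospos(0, 0.25), 1)
  expect_equal(weight_pospos(2, 0.25), 1.5)
  expect_equal(weight_pospos(14, 0.25), 4.5)
  expect_equal(weight_negpos(4, 0.25), 0.5)        # the k = 0.25 calibration
  expect_equal(weight_negpos(2, 0.25), 2 / 3, tolerance = 1e-12)
  expect_equal(weight_negpos(6, 1e-9), 1, tolerance = 1e-6)  # k -> 0 limit
  expect_error(weight_negpos(0, 0.25), "distinct")
})

make_stack <- function(sims_list, periods = 2^seq_along(sims_list)) {
  n <- nrow(sims_list[[1]])
  ids <- paste0("O", seq_len(n))
  sims_list <- lapply(sims_list, function(s) {
    dimnames(s) <- list(ids, ids); s
  })
  structure(list(sims = sims_list, period_days = periods, otu_ids = ids),
            class = "level_similarity_stack")
}

test_that("maximum over level combinations picks the weighted best", {
  # pair similar at periods 2 and 16 only: best +/+ combo is (2,16), w = 4.5
  s <- lapply(1:4, function(j) diag(2))
  s[[1]][1, 2] <- s[[1]][2, 1] <- 0.9
  s[[4]][1, 2] <- s[[4]][2, 1] <- 0.9
  sc <- interaction_scores(make_stack(s), "pospos")
  expect_equal(sc$scores[1, 2], 4.5 * 0.9, tolerance = 1e-12)
  expect_equal(sc$high_period[1, 2], 2)
  expect_equal(sc$low_period[1, 2], 16)
  # similarity at a single level only scores 0 in both modes
  s1 <- lapply(1:4, function(j) diag(2))
  s1[[2]][1, 2] <- s1[[2]][2, 1] <- 0.95
  expect_equal(interaction_scores(make_stack(s1), "pospos")$scores[1, 2], 0)
  expect_equal(interaction_scores(make_stack(s1), "negpos")$scores[1, 2], 0)
})

test_that("score matrices match the brute-force enumeration oracle", {
  set.seed(11)
  tab <- make_fixture_table(n_otus = 8, n_days = 93, seed = 12)
  stack <- pairwise_level_similarities(decompose_table(tab))
  for (mode in c("pospos", "negpos")) {
    sc <- interaction_scores(stack, mode)
    expect_lt(max(abs(sc$scores - t(sc$scores))), 1e-12)
    expect_true(all(diag(sc$scores) == 0))
    for (a in 1:7) for (b in (a + 1):8) {
      sims <- vapply(stack$sims, function(m) m[a, b], numeric(1))
      expect_equal(sc$scores[a, b],
                   oracle_pair_score(sims, stack$period_days, mode),
                   tolerance = 1e-9)
    }
  }
})

test_that("scores are invariant to OTU order and positive rescaling", {
  tab <- make_fixture_table(n_otus = 6, n_days = 93, seed = 13)
  sc <- score_table(tab, "pospos")$scores
  perm <- c(4, 1, 6, 2, 5, 3)
  tabp <- otu_table(tab$values[perm, ], tab$otu_ids[perm], tab$sample_days)
  scp <- score_table(tabp, "pospos")$scores
  expect_equal(scp[tab$otu_ids, tab$otu_ids], sc, tolerance = 1e-10)
  scale <- otu_table(tab$values * rep(c(3, 0.2), 3), tab$otu_ids,
                     tab$sample_days)
  expect_equal(score_table(scale, "pospos")$scores, sc, tolerance = 1e-10)
})

test_that("raising the positive threshold never increases any score", {
  tab <- make_fixture_table(n_otus = 6, n_days = 93, seed = 14)
  lo <- score_table(tab, "pospos", score_params(pos_threshold = 0.5))$scores
  hi <- score_table(tab, "pospos", score_params(pos_threshold = 0.8))$scores
  expect_true(all(hi <= lo + 1e-12))
})

test_that("a level pair feeds at most one mode (sign conditions exclusive)", {
  set.seed(15)
  tab <- make_fixture_table(n_otus = 6, n_days = 93, seed = 15)
  stack <- pairwise_level_similarities(decompose_table(tab))
  pp <- interaction_scores(stack, "pospos")
  np <- interaction_scores(stack, "negpos")
  both <- pp$scores > 0 & np$scores > 0
  if (any(both)) {
    idx <- which(both, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      expect_false(
        pp$high_period[idx[r, 1], idx[r, 2]] ==
          np$high_period[idx[r, 1], idx[r, 2]] &&
        pp$low_period[idx[r, 1], idx[r, 2]] ==
          np$low_period[idx[r, 1], idx[r, 2]])
    }
  }
  expect_true(TRUE)
})

test_that("edge list contains exactly the positive upper-triangle scores", {
  tab <- make_fixture_table(n_otus = 6, n_days = 93, seed = 16)
  sc <- score_table(tab, "pospos")
  ed <- score_edges(sc)
  expect_equal(nrow(ed), sum(sc$scores[upper.tri(sc$scores)] > 0))
  for (r in seq_len(nrow(ed)))
    expect_equal(ed$score[r], sc$scores[ed$otu_a[r], ed$otu_b[r]])
})
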