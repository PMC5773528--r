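test_that("TSV round trip preserves the table, including replicate days", {
  tab <- make_fixture_table(n_otus = 3, n_days = 4, replicates = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_otu_table(tab, path)
  back <- read_otu_table(path)
  expect_equal(back$values, tab$values, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(back$otu_ids, tab$otu_ids)
  expect_identical(back$sample_days, tab$sample_days)
})

test_that("constructor enforces the table invariants", {
  v <- matrix(1:6, 2, 3)
  expect_error(otu_table(rbind(v, v), c("a", "b", "a", "b"), 1:3),
               "duplicate")
  v2 <- v; v2[1, 2] <- -1
  expect_error(otu_table(v2, c("a", "b"), 1:3), "negative")
  rel <- matrix(c(0.5, 0.5, 0.9, 0.2), 2, 2)
  expect_error(otu_table(rel, c("a", "b"), 1:2, is_relative = TRUE),
               "sum to 1")
})

test_that("replicate averaging equals the brute-force per-day mean", {
  tab <- make_fixture_table(n_otus = 5, n_days = 7, replicates = 3)
  avg <- average_replicates(tab)
  expect_identical(avg$sample_days, 1:7)
  for (d in unique(tab$sample_days)) {
    expect_equal(avg$values[, d],
                 rowMeans(tab$values[, tab$sample_days == d, drop = FALSE]),
                 tolerance = 1e-12)
  }
  # singleton groups pass through
  single <- make_fixture_table(n_otus = 2, n_days = 5, replicates = 1)
  expect_equal(average_replicates(single)$values, single$values)
})

test_that("relative-abundance conversion normalises columns and is idempotent", {
  tab <- otu_table(matrix(c(1, 1, 2, 2, 3, 5), 3, 2), c("a", "b", "c"), 1:2)
  rel <- to_relative_abundance(tab)
  expect_equal(rel$values[, 1], c(a = 0.25, b = 0.25, c = 0.5))
  expect_equal(colSums(rel$values), c(1, 1), ignore_attr = TRUE)
  expect_true(rel$is_relative)
  expect_equal(to_relative_abundance(rel)$values, rel$values)
  zero <- otu_table(matrix(c(1, 0, 0, 0), 2, 2), c("a", "b"), 1:2)
  expect_error(to_relative_abundance(zero), "all-zero")
})

test_that("recurrence filter keeps OTUs on strictly more than min_days days", {
  n_days <- 30
  present <- c(A = 11, B = 10, C = 25, D = 1)
  v <- t(vapply(present, function(k)
    c(rep(1, k), rep(0, n_days - k)), numeric(n_days)))
  tab <- otu_table(v, names(present), seq_len(n_days))
  kept <- filter_recurrent(tab, min_days = 10)
  expect_identical(kept$otu_ids, c("A", "C"))
  # brute-force agreement on a random presence pattern
  set.seed(7)
  vr <- matrix(rbinom(8 * n_days, 1, 0.3), 8) * runif(8 * n_days)
  tabr <- otu_table(vr, paste0("O", 1:8), seq_len(n_days))
  for (md in c(0, 5, 10)) {
    expect_identical(filter_recurrent(tabr, md)$otu_ids,
                     tabr$otu_ids[rowSums(vr > 0) > md])
  }
  # monotone: raising min_days never adds OTUs
  expect_true(all(filter_recurrent(tabr, 8)$otu_ids %in%
                    filter_recurrent(tabr, 4)$otu_ids))
})

test_that("prep order commutes with column reordering", {
  tab <- make_fixture_table(n_otus = 4, n_days = 6, replicates = 2)
  perm <- sample(ncol(tab$values))
  o <- order(tab$sample_days[perm])
  shuffled <- otu_table(tab$values[, perm][, o],
                        tab$otu_ids, tab$sample_days[perm][o])
  a <- to_relative_abundance(average_replicates(tab))
  b <- to_relative_abundance(average_replicates(shuffled))
  expect_equal(a$values, b$values, tolerance = 1e-12)
})

test_that("metadata reader aligns days and keeps missing values explicit", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("day\ttemp\tsalinity", "3\t12.5\tNA", "1\t11.0\t31.2"), path)
  md <- read_metadata(path)
  expect_identical(md$day, c(1L, 3L))
  expect_true(is.na(md$salinity[2]))
})
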