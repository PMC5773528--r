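#' Permutation null for interaction scores
#'
#' Each permutation shuffles every OTU's series independently in time,
#' recomputes the full interaction-score matrix for the requested mode, and
#' counts, per pair, how often the permuted score is at least the observed
#' one (ties count, a conservative choice). Empirical p-values use the
#' add-one estimator `p = (1 + exceedances) / (n_perm + 1)`, so p is never 0
#' and is super-uniform under the null.
#'
#' @param table a day-averaged [otu_table()].
#' @param mode `"pospos"` or `"negpos"`.
#' @param params a [score_params()].
#' @param n_perm number of permutations (>= 1); 1000 is a desk-scale default,
#'   50000 matches a field-scale analysis.
#' @param seed integer seed for the permutation stream.
#' @return an object of class `permutation_result`: list with `observed`
#'   (score matrix), `exceedances`, `pvalues` (symmetric matrices), `n_perm`,
#'   `mode`, `seed`.
#' @export
permutation_pvalues <- function(table, mode = c("pospos", "negpos"),
                                params = score_params(), n_perm = 1000,
                                seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(table, "otu_table"))
  if (n_perm < 1) stop("n_perm must be at least 1")
  observed <- score_table(table, mode, params)$scores
  n <- nrow(table$values)
  nt <- ncol(table$values)
  exceed <- matrix(0, n, n, dimnames = dimnames(observed))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  for (b in seq_len(n_perm)) {
    perm <- table$values
    for (i in seq_len(n)) perm[i, ] <- perm[i, sample.int(nt)]
    pt <- otu_table(perm, table$otu_ids, table$sample_days,
                    is_relative = FALSE)
    ps <- score_table(pt, mode, params)$scores
    exceed <- exceed + (ps >= observed)
  }
  pvals <- (1 + exceed) / (n_perm + 1)
  diag(pvals) <- 1
  structure(list(observed = observed, exceedances = exceed, pvalues = pvals,
                 n_perm = n_perm, mode = mode, seed = seed),
            class = "permutation_result")
}

#' Benjamini-Hochberg FDR mask
#'
#' @param pvalues numeric vector or matrix of p-values.
#' @param q target false-discovery rate in (0, 1); default 0.10.
#' @return logical mask of the same shape; `TRUE` where the BH-adjusted
#'   p-value is at most `q`.
#' @export
bh_fdr <- function(pvalues, q = 0.10) {
  stopifnot(q > 0, q < 1)
  adj <- stats::p.adjust(as.vector(pvalues), method = "BH")
  mask <- adj <= q
  if (is.matrix(pvalues))
    mask <- matrix(mask, nrow = nrow(pvalues), dimnames = dimnames(pvalues))
  mask
}

#' Score matrix restricted to FDR-significant pairs
#'
#' Applies [bh_fdr()] to the upper-triangle p-values of a
#' [permutation_pvalues()] result and zeroes all non-significant edges.
#'
#' @param permresult a `permutation_result`.
#' @param q target FDR (default 0.10).
#' @return symmetric score matrix with non-significant entries set to 0.
#' @export
significant_scores <- function(permresult, q = 0.10) {
  stopifnot(inherits(permresult, "permutation_result"))
  p <- permresult$pvalues
  ut <- upper.tri(p)
  keep_ut <- bh_fdr(p[ut], q)
  mask <- matrix(FALSE, nrow(p), ncol(p))
  mask[ut] <- keep_ut
  mask <- mask | t(mask)
  s <- permresult$observed
  s[!mask] <- 0
  s
}

#' First differences of every OTU series
#'
#' Removes lag-1 autocorrelation by replacing each series with
#' `x[t+1] - x[t]`. The result has one fewer time point and may contain
#' negative values, so it is flagged as counts-like; downstream wavelet
#' scoring accepts it unchanged.
#'
#' @param table an [otu_table()] with one column per day and >= 2 days.
#' @return an [otu_table()] of differenced series (days relabelled to the
#'   later day of each difference). Values are shifted up by the global
#'   minimum so the non-negativity invariant holds; the shift is constant per
#'   table and does not affect wavelet detail coefficients or cosine scores.
#' @export
first_difference <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  v <- table$values
  if (ncol(v) < 2L) stop("need at least two days to difference")
  d <- v[, -1L, drop = FALSE] - v[, -ncol(v), drop = FALSE]
  shift <- min(d)
  if (shift < 0) d <- d - shift
  otu_table(d, table$otu_ids, table$sample_days[-1L], is_relative = FALSE)
}

#' Lagged autocorrelation of one series
#'
#' Pearson correlation of `(x[t], x[t + lag])`; defined as 0 for
#' zero-variance (constant) series.
#'
#' @param series numeric vector.
#' @param lag positive integer lag in days (default 1).
#' @return correlation in `[-1, 1]`.
#' @export
lag_autocorrelation <- function(series, lag = 1L) {
  series <- as.numeric(series)
  n <- length(series)
  if (n <= lag) stop("series must be longer than the lag")
  a <- series[seq_len(n - lag)]
  b <- series[seq_len(n - lag) + lag]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b)
}
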