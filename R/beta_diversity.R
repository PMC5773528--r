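#' Jensen-Shannon distance between two relative-abundance profiles
#'
#' The square root of the Jensen-Shannon divergence
#' `JS(P, Q) = KL(P || M)/2 + KL(Q || M)/2` with `M = (P + Q)/2`, computed
#' with base-2 logarithms so the distance lies in `[0, 1]` and equals 1
#' exactly for profiles with disjoint support. Zero-abundance taxa contribute
#' nothing (the `0 log 0 := 0` convention); no pseudocounts are added.
#'
#' @param P,Q non-negative vectors, each summing to 1 within `1e-9`.
#' @return distance in `[0, 1]`.
#' @export
jsd_distance <- function(P, Q) {
  P <- as.numeric(P); Q <- as.numeric(Q)
  if (length(P) != length(Q)) stop("profiles must have equal length")
  if (any(P < 0) || any(Q < 0)) stop("profiles must be non-negative")
  if (abs(sum(P) - 1) > 1e-9 || abs(sum(Q) - 1) > 1e-9)
    stop("profiles must each sum to 1 (normalise first)")
  M <- (P + Q) / 2
  kl <- function(a) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / M[nz]))
  }
  js <- kl(P) / 2 + kl(Q) / 2
  sqrt(max(js, 0))
}

#' Lag-averaged taxonomic similarity curve
#'
#' For every time lag `L = 0..max_lag`, averages the similarity
#' `1 - JSD` over all pairs of samples whose days differ by exactly `L`.
#' Lag 0 compares replicate samples of the same day (and is reported only
#' when replicates exist). The curve's decline with lag measures the rate of
#' community turnover; an optional `grouping` map aggregates OTUs (e.g. to
#' phylum level) before the distances are computed, which flattens the curve
#' for coarse taxonomies.
#'
#' @param table a relative-abundance [otu_table()] (replicates allowed).
#' @param max_lag largest lag in days (default 40); must be smaller than the
#'   day span.
#' @param grouping optional named vector mapping each OTU id to a group
#'   label; abundances are summed within groups first.
#' @return data.frame with columns `lag`, `similarity` (mean `1 - JSD`),
#'   `se` (standard error over pairs; `NA` for a single pair), `n_pairs`.
#' @export
lag_similarity_curve <- function(table, max_lag = 40, grouping = NULL) {
  stopifnot(inherits(table, "otu_table"))
  v <- table$values
  if (!table$is_relative) stop("table must hold relative abundances")
  if (!is.null(grouping)) {
    g <- grouping[table$otu_ids]
    if (anyNA(g)) stop("grouping must cover every OTU")
    v <- rowsum(v, g)
  }
  days <- table$sample_days
  span <- max(days) - min(days)
  if (max_lag > span) stop("max_lag must not exceed the day span")
  ut <- upper.tri(matrix(0, length(days), length(days)))
  ddiff <- outer(days, days, function(a, b) b - a)
  rows <- lapply(0:max_lag, function(L) {
    prs <- which(ddiff == L & ut, arr.ind = TRUE)
    if (nrow(prs) == 0L)
      return(data.frame(lag = L, similarity = NA_real_, se = NA_real_,
                        n_pairs = 0L))
    sims <- vapply(seq_len(nrow(prs)), function(i)
      1 - jsd_distance(v[, prs[i, 1L]], v[, prs[i, 2L]]), numeric(1L))
    data.frame(lag = L, similarity = mean(sims),
               se = if (length(sims) > 1L)
                 stats::sd(sims) / sqrt(length(sims)) else NA_real_,
               n_pairs = length(sims))
  })
  do.call(rbind, rows)
}
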