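# Partition-comparison metrics. Memberships are vectors of cluster labels
# over a shared item set; names, when present, are used to align the two
# partitions (items unclustered/absent in either are dropped).

align_partitions <- function(u, v) {
  if (inherits(u, "mcl_partition")) u <- u$membership
  if (inherits(v, "mcl_partition")) v <- v$membership
  if (!is.null(names(u)) && !is.null(names(v))) {
    shared <- intersect(names(u)[!is.na(u)], names(v)[!is.na(v)])
    if (length(shared) == 0L) stop("partitions share no clustered items")
    u <- u[shared]; v <- v[shared]
  } else {
    if (length(u) != length(v))
      stop("unnamed partitions must have equal length")
    keep <- !is.na(u) & !is.na(v)
    u <- u[keep]; v <- v[keep]
  }
  list(u = as.integer(factor(u)), v = as.integer(factor(v)))
}

entropy_of <- function(sizes, n) {
  p <- sizes[sizes > 0] / n
  -sum(p * log(p))
}

#' Mutual information between two partitions
#'
#' `MI(U, V) = sum_ij P(i,j) log(P(i,j) / (P(i) P'(j)))` over the contingency
#' table of the two clusterings, with the `0 log 0 := 0` convention. Natural
#' logarithm by default.
#'
#' @param u,v cluster memberships over the same items (named vectors or
#'   `mcl_partition` objects; `NA` = unclustered, dropped from both).
#' @param base logarithm base (default `exp(1)`; use 2 for bits).
#' @return non-negative mutual information.
#' @export
mutual_information <- function(u, v, base = exp(1)) {
  al <- align_partitions(u, v)
  ct <- table(al$u, al$v)
  n <- sum(ct)
  pij <- ct / n
  pi_ <- rowSums(pij); pj_ <- colSums(pij)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi_, pj_)[nz]))
  mi / log(base)
}

# Exact expectation of MI under the fixed-margins permutation
# (generalized hypergeometric) model, Vinh, Epps & Bailey (2010).
expected_mutual_information <- function(a, b, n) {
  emi <- 0
  lgn <- lgamma(n + 1)
  for (ai in a) {
    for (bj in b) {
      lo <- max(1L, ai + bj - n)
      hi <- min(ai, bj)
      if (lo > hi) next
      nij <- lo:hi
      lp <- lgamma(ai + 1) + lgamma(bj + 1) + lgamma(n - ai + 1) +
        lgamma(n - bj + 1) - lgn - lgamma(nij + 1) - lgamma(ai - nij + 1) -
        lgamma(bj - nij + 1) - lgamma(n - ai - bj + nij + 1)
      emi <- emi + sum(exp(lp) * (nij / n) * log(n * nij / (ai * bj)))
    }
  }
  emi
}

#' Adjusted mutual information between two partitions
#'
#' MI corrected for chance agreement at fixed cluster sizes:
#' `AMI = (MI - E[MI]) / (norm(H(U), H(V)) - E[MI])`, with `E[MI]` the exact
#' expectation under the permutation model and the normaliser the maximum
#' (default) or arithmetic mean of the two entropies. Identical partitions
#' score 1; random same-size partitions score about 0.
#'
#' @inheritParams mutual_information
#' @param normalizer `"max"` (default) or `"mean"`.
#' @return AMI, at most 1 (can be slightly negative by chance).
#' @export
adjusted_mutual_information <- function(u, v,
                                        normalizer = c("max", "mean")) {
  normalizer <- match.arg(normalizer)
  al <- align_partitions(u, v)
  n <- length(al$u)
  a <- tabulate(al$u); b <- tabulate(al$v)
  hu <- entropy_of(a, n); hv <- entropy_of(b, n)
  mi <- mutual_information(al$u, al$v)
  if (hu == 0 && hv == 0)  # both trivial
    return(if (identical(al$u, al$v)) 1 else 0)
  emi <- expected_mutual_information(a, b, n)
  norm <- if (normalizer == "max") max(hu, hv) else mean(c(hu, hv))
  denom <- norm - emi
  if (abs(denom) < .Machine$double.eps) {
    return(if (identical(tabulate(al$u), tabulate(al$v)) && mi >= norm - 1e-12)
      1 else 0)
  }
  (mi - emi) / denom
}

#' Same- vs different-community analysis of closely related OTU pairs
#'
#' Given pairwise genetic distances between OTU representatives and a
#' community partition, counts in each distance bin how many pairs fall in
#' the same vs different communities, and tests by a chi-squared goodness of
#' fit (df = 1 on the pooled same/different totals) whether the observed
#' split departs from random membership assignment preserving the observed
#' community sizes, under which a pair is co-member with probability
#' `sum_c n_c (n_c - 1) / (N (N - 1))`.
#'
#' @param pair_distances data.frame with columns `otu_a`, `otu_b`,
#'   `distance`.
#' @param partition named membership vector or `mcl_partition` covering every
#'   OTU referenced by the pairs.
#' @param breaks distance-bin breakpoints (default 0 to 0.06 in 0.01 steps).
#' @return list with `histogram` (data.frame: bin, n_same, n_different),
#'   `p_same_null`, `statistic` (chi-squared, df = 1), `p.value`,
#'   `observed`/`expected` same/different totals.
#' @export
comembership_analysis <- function(pair_distances, partition,
                                  breaks = seq(0, 0.06, by = 0.01)) {
  membership <- if (inherits(partition, "mcl_partition"))
    partition$membership else partition
  membership <- membership[!is.na(membership)]
  need <- unique(c(pair_distances$otu_a, pair_distances$otu_b))
  missing <- setdiff(need, names(membership))
  if (length(missing))
    stop("pair references OTU(s) missing from partition: ",
         paste(missing, collapse = ", "))
  same <- membership[pair_distances$otu_a] == membership[pair_distances$otu_b]
  bin <- cut(pair_distances$distance, breaks = breaks, include.lowest = TRUE)
  hist_df <- data.frame(
    bin = levels(bin),
    n_same = as.vector(table(bin[same])),
    n_different = as.vector(table(bin[!same])))

  sizes <- table(membership)
  N <- length(membership)
  p_same <- sum(sizes * (sizes - 1)) / (N * (N - 1))
  m <- length(same)
  obs <- c(same = sum(same), different = sum(!same))
  expd <- c(same = m * p_same, different = m * (1 - p_same))
  stat <- sum((obs - expd)^2 / expd)
  list(histogram = hist_df, p_same_null = p_same, statistic = stat,
       p.value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       observed = obs, expected = expd)
}
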