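#' Parameters for interaction scoring
#'
#' @param pos_threshold minimum cosine similarity a positive correlation must
#'   exceed (strictly) to count; default 0.7.
#' @param neg_threshold value the high-frequency similarity must lie strictly
#'   below for a negative (-/+) interaction; default -0.5.
#' @param k weighting sensitivity in the period-separation weights; default
#'   0.25, which gives a -/+ weight of 1/2 when the two periods differ by
#'   4 days.
#' @return a `score_params` list.
#' @export
score_params <- function(pos_threshold = 0.7, neg_threshold = -0.5,
                         k = 0.25) {
  stopifnot(pos_threshold > 0, pos_threshold < 1,
            neg_threshold > -1, neg_threshold < 0, k > 0)
  structure(list(pos_threshold = pos_threshold,
                 neg_threshold = neg_threshold, k = k),
            class = "score_params")
}

#' Raw +/+ score for one frequency combination
#'
#' Geometric mean of the two similarities when both strictly exceed the
#' positive threshold, else 0.
#'
#' @param sim_high,sim_low cosine similarities at the high (finer) and low
#'   (coarser) frequency level; vectorised.
#' @param params a [score_params()].
#' @return non-negative score(s).
#' @export
raw_score_pospos <- function(sim_high, sim_low, params = score_params()) {
  ok <- sim_high > params$pos_threshold & sim_low > params$pos_threshold
  out <- sim_high * 0
  out[ok] <- sqrt(sim_high[ok] * sim_low[ok])
  out
}

#' Raw -/+ score for one frequency combination
#'
#' Geometric mean of `-sim_high` and `sim_low` when the high-frequency
#' similarity is strictly below the negative threshold and the low-frequency
#' similarity strictly above the positive threshold, else 0.
#'
#' @inheritParams raw_score_pospos
#' @return non-negative score(s).
#' @export
raw_score_negpos <- function(sim_high, sim_low, params = score_params()) {
  ok <- sim_high < params$neg_threshold & sim_low > params$pos_threshold
  out <- sim_high * 0
  out[ok] <- sqrt(-sim_high[ok] * sim_low[ok])
  out
}

#' Period-separation weight for +/+ scores
#'
#' Positive co-fluctuation at two nearby periods is likely discretisation of
#' one underlying frequency, so widely separated levels are up-weighted:
#' `k * delta + 1`, with `delta` the difference of characteristic periods in
#' days.
#'
#' @param delta_period_days non-negative period difference in days.
#' @param k weighting sensitivity (default 0.25).
#' @return weight `>= 1`.
#' @export
weight_pospos <- function(delta_period_days, k = 0.25) {
  stopifnot(all(delta_period_days >= 0))
  k * delta_period_days + 1
}

#' Period-separation weight for -/+ scores
#'
#' Opposite signs at neighbouring levels cannot be discretisation noise, so
#' close levels are up-weighted: `(1/delta) / (k + 1/delta)`. At k = 0.25 the
#' weight is exactly 1/2 for a 4-day period difference.
#'
#' @param delta_period_days strictly positive period difference in days.
#' @param k weighting sensitivity (default 0.25).
#' @return weight in `(0, 1]`.
#' @export
weight_negpos <- function(delta_period_days, k = 0.25) {
  if (any(delta_period_days <= 0))
    stop("-/+ weighting requires distinct frequency levels (delta > 0)")
  (1 / delta_period_days) / (k + 1 / delta_period_days)
}

#' Interaction-score matrix over all OTU pairs
#'
#' For every pair the thresholded raw score is computed for every ordered
#' (high, low) level combination with the high level strictly finer than the
#' low one, multiplied by the mode's period-separation weight, and maximised
#' over combinations. Ties in the maximum are broken towards the smallest
#' period difference, then the finest high level, so output is deterministic.
#'
#' @param stack a `level_similarity_stack` from
#'   [pairwise_level_similarities()] with at least 2 levels.
#' @param mode `"pospos"` (+/+) or `"negpos"` (-/+).
#' @param params a [score_params()].
#' @return an object of class `interaction_scores`: list with `scores`
#'   (symmetric matrix, zero diagonal), `high_period`/`low_period` (matrices
#'   of the argmax combination's periods in days, `NA` where the score is 0),
#'   `mode`, `params`.
#' @export
interaction_scores <- function(stack, mode = c("pospos", "negpos"),
                               params = score_params()) {
  mode <- match.arg(mode)
  stopifnot(inherits(stack, "level_similarity_stack"))
  L <- length(stack$sims)
  if (L < 2L) stop("need at least 2 frequency levels")
  n <- nrow(stack$sims[[1L]])
  periods <- stack$period_days

  combos <- expand.grid(high = seq_len(L), low = seq_len(L))
  combos <- combos[combos$high < combos$low, , drop = FALSE]  # finer = smaller period
  combos$delta <- periods[combos$low] - periods[combos$high]
  # tie-break order: smallest delta first, then finest high level
  combos <- combos[order(combos$delta, combos$high), , drop = FALSE]

  scores <- matrix(0, n, n)
  hi_p <- lo_p <- matrix(NA_real_, n, n)
  for (r in seq_len(nrow(combos))) {
    sh <- stack$sims[[combos$high[r]]]
    sl <- stack$sims[[combos$low[r]]]
    raw <- if (mode == "pospos") raw_score_pospos(sh, sl, params)
           else raw_score_negpos(sh, sl, params)
    w <- if (mode == "pospos") weight_pospos(combos$delta[r], params$k)
         else weight_negpos(combos$delta[r], params$k)
    ws <- w * raw
    better <- ws > scores  # strict: earlier (preferred) combos win ties
    scores[better] <- ws[better]
    hi_p[better] <- periods[combos$high[r]]
    lo_p[better] <- periods[combos$low[r]]
  }
  diag(scores) <- 0
  diag(hi_p) <- diag(lo_p) <- NA_real_
  dimnames(scores) <- dimnames(hi_p) <- dimnames(lo_p) <-
    dimnames(stack$sims[[1L]])
  structure(list(scores = scores, high_period = hi_p, low_period = lo_p,
                 mode = mode, params = params),
            class = "interaction_scores")
}

#' Convenience wrapper: scores straight from an OTU table
#'
#' Decomposes every series, builds the per-level similarity stack, and scores
#' the requested mode.
#'
#' @param table a day-averaged [otu_table()].
#' @param mode `"pospos"` or `"negpos"`.
#' @param params a [score_params()].
#' @param include_approx include the coarsest approximation band as an extra
#'   level (default `FALSE`).
#' @return an `interaction_scores` object.
#' @export
score_table <- function(table, mode = c("pospos", "negpos"),
                        params = score_params(), include_approx = FALSE) {
  mode <- match.arg(mode)
  stack <- pairwise_level_similarities(decompose_table(table),
                                       include_approx = include_approx)
  interaction_scores(stack, mode, params)
}

#' Edge list of positive interaction scores
#'
#' @param iscores an `interaction_scores` object.
#' @return data.frame with columns `otu_a`, `otu_b`, `score`, `high_period`,
#'   `low_period`, one row per unordered pair with score > 0.
#' @export
score_edges <- function(iscores) {
  stopifnot(inherits(iscores, "interaction_scores"))
  s <- iscores$scores
  ut <- upper.tri(s)
  idx <- which(ut & s > 0, arr.ind = TRUE)
  data.frame(otu_a = rownames(s)[idx[, 1L]],
             otu_b = colnames(s)[idx[, 2L]],
             score = s[idx],
             high_period = iscores$high_period[idx],
             low_period = iscores$low_period[idx],
             stringsAsFactors = FALSE)
}
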