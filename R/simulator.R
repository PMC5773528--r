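# Synthetic bloom-dynamics generator used to validate the frequency-coupling
# detector. Series follow f(x) = exp(T(sin(x) + b sin(x/p) + eps)): a fast
# basal oscillation (period 2*pi days), a slow bloom term of amplitude b and
# period 2*pi*p days, and Gaussian noise, passed through a threshold T
# (T(y) = y if y > 1, else 0) so that taxa sit at a flat baseline of 1 and
# expand episodically — the seed-bank pattern seen in real plankton series.

#' Threshold applied inside the simulator's exponent
#'
#' `T(y) = y` if `y > 1`, else 0 (strict inequality at the boundary).
#'
#' @param y numeric vector.
#' @return thresholded vector.
#' @export
bloom_threshold <- function(y) ifelse(y > 1, y, 0)

# noiseless exponent components at x = 1..n
sim_components <- function(n, b, p, phase_base = 0, phase_bloom = 0,
                           base_sign = 1, recurrent = TRUE,
                           bloom_start = NULL) {
  x <- seq_len(n)
  base <- base_sign * sin(x + phase_base)
  bloom <- b * sin(x / p + phase_bloom)  # phase in radians of the slow cycle
  if (!recurrent) {
    if (is.null(bloom_start)) bloom_start <- 1L
    win <- seq(bloom_start, min(n, bloom_start + ceiling(p) - 1L))
    mask <- rep(0, n); mask[win] <- 1
    bloom <- bloom * mask
  }
  list(base = base, bloom = bloom)
}

#' Simulate one abundance series with bloom dynamics
#'
#' Evaluates `f(x) = exp(T(sin(x + phase_base) + b sin(x/p + phase_bloom)
#' + eps))` at `x = 1..n`. The noise vector `eps` is i.i.d. Gaussian,
#' rescaled so that the signal-to-noise ratio `||s|| / ||eps||` equals
#' `snr`, where `s` is the unit-amplitude basal oscillation inside the
#' exponent (two-pass generation: the noiseless components are realised
#' first, then the noise vector is scaled against them). Calibrating in the
#' exponent domain keeps the noise commensurate with the signal it corrupts;
#' at `snr = 1` the per-day noise standard deviation is about 0.71, the RMS
#' amplitude of the basal term. With `recurrent = FALSE` the bloom term acts
#' only in a single window of length `p` starting at `bloom_start`
#' (uniformly random when `NULL`).
#'
#' @param n series length in days (default 93).
#' @param b bloom amplitude (default 10).
#' @param p bloom period scale in samples (default 20; the bloom's sinusoidal
#'   period is `2*pi*p` days).
#' @param snr target signal-to-noise ratio (default 1); `Inf` for noiseless.
#' @param phase_base,phase_bloom phase offsets of the fast and slow terms.
#' @param base_sign +1 or -1; -1 negates the fast basal term (used to plant
#'   high-frequency anti-correlation).
#' @param recurrent multiple blooms (`TRUE`, default) or one random-position
#'   bloom window.
#' @param bloom_start start of the single-bloom window (days); ignored when
#'   `recurrent = TRUE`.
#' @return numeric vector of strictly positive abundances.
#' @export
simulate_series <- function(n = 93, b = 10, p = 20, snr = 1,
                            phase_base = 0, phase_bloom = 0, base_sign = 1,
                            recurrent = TRUE, bloom_start = NULL) {
  if (!recurrent && is.null(bloom_start))
    bloom_start <- sample.int(max(1L, n - ceiling(p) + 1L), 1L)
  comp <- sim_components(n, b, p, phase_base, phase_bloom, base_sign,
                         recurrent, bloom_start)
  y0 <- comp$base + comp$bloom
  if (is.infinite(snr)) return(exp(bloom_threshold(y0)))
  eps <- stats::rnorm(n)
  eps <- eps * sqrt(sum(comp$base^2)) / (snr * sqrt(sum(eps^2)))
  exp(bloom_threshold(y0 + eps))
}

#' Simulate one validation trial of 8 series with planted associations
#'
#' The default layout plants one pair of each association type among 8
#' series: type 1 (pair 1-2) shares both the fast and the slow component
#' (positive correlation at high and low frequency); type 2 (pair 3-4) shares
#' the slow bloom but the second partner's fast term is negated (negative at
#' high, positive at low frequency); type 3 (pair 5-6) shares the fast term
#' but has independent blooms (positive at high frequency, none at low);
#' series 7 and 8 are fully independent. All phases are drawn uniformly per
#' trial; partners share the phases of their shared components.
#'
#' @param b,p,snr,n,recurrent as in [simulate_series()].
#' @return list with `series` (8 x n matrix, rows `S1..S8`), `truth` (8 x 8
#'   matrix of planted types: 1, 2, 3, or 0 for unrelated), and `params`.
#' @export
simulate_trial <- function(b = 10, p = 20, snr = 1, n = 93,
                           recurrent = TRUE) {
  ph <- function() stats::runif(1, 0, 2 * pi)
  mk <- function(phb, phl, sgn = 1) simulate_series(
    n = n, b = b, p = p, snr = snr, phase_base = phb, phase_bloom = phl,
    base_sign = sgn, recurrent = recurrent)
  s <- matrix(0, 8L, n)
  ph12b <- ph(); ph12l <- ph()
  s[1L, ] <- mk(ph12b, ph12l); s[2L, ] <- mk(ph12b, ph12l)      # type 1
  ph34b <- ph(); ph34l <- ph()
  s[3L, ] <- mk(ph34b, ph34l); s[4L, ] <- mk(ph34b, ph34l, -1)  # type 2
  ph56b <- ph()
  s[5L, ] <- mk(ph56b, ph()); s[6L, ] <- mk(ph56b, ph())        # type 3
  s[7L, ] <- mk(ph(), ph()); s[8L, ] <- mk(ph(), ph())          # unrelated
  rownames(s) <- paste0("S", 1:8)
  truth <- matrix(0L, 8L, 8L, dimnames = list(rownames(s), rownames(s)))
  truth[1L, 2L] <- truth[2L, 1L] <- 1L
  truth[3L, 4L] <- truth[4L, 3L] <- 2L
  truth[5L, 6L] <- truth[6L, 5L] <- 3L
  list(series = s, truth = truth,
       params = list(b = b, p = p, snr = snr, n = n, recurrent = recurrent))
}

#' Average pairwise score matrices over many simulated trials
#'
#' For each trial the 8 x 8 matrices of Pearson correlation, +/+ interaction
#' scores and -/+ interaction scores are computed and averaged across trials,
#' alongside the (fixed) planted-truth matrix.
#'
#' @param n_trials number of trials (default 100; 500 matches a full-scale
#'   validation run).
#' @param b,p,snr,n,recurrent passed to [simulate_trial()].
#' @param params a [score_params()].
#' @param seed integer seed.
#' @return list with `mean_pearson`, `mean_abs_pearson`, `mean_pospos`,
#'   `mean_negpos` (8 x 8 matrices), `truth`, `n_trials`.
#' @export
validation_experiment <- function(n_trials = 100, b = 10, p = 20, snr = 1,
                                  n = 93, recurrent = TRUE,
                                  params = score_params(), seed = 1L) {
  stopifnot(n_trials >= 1)
  set.seed(seed)
  acc <- list(pearson = 0, abs_pearson = 0, pospos = 0, negpos = 0)
  truth <- NULL
  for (tr in seq_len(n_trials)) {
    trial <- simulate_trial(b = b, p = p, snr = snr, n = n,
                            recurrent = recurrent)
    truth <- trial$truth
    tab <- otu_table(trial$series, rownames(trial$series),
                     sample_days = seq_len(n))
    pear <- stats::cor(t(trial$series))
    acc$pearson <- acc$pearson + pear
    acc$abs_pearson <- acc$abs_pearson + abs(pear)
    acc$pospos <- acc$pospos + score_table(tab, "pospos", params)$scores
    acc$negpos <- acc$negpos + score_table(tab, "negpos", params)$scores
  }
  list(mean_pearson = acc$pearson / n_trials,
       mean_abs_pearson = acc$abs_pearson / n_trials,
       mean_pospos = acc$pospos / n_trials,
       mean_negpos = acc$negpos / n_trials,
       truth = truth, n_trials = n_trials)
}

#' Sensitivity of detection to bloom amplitude and period
#'
#' Runs [validation_experiment()] over a grid of bloom amplitudes `b` and
#' period scales `p`, reporting the mean planted-pair score per association
#' type and the mean score among unrelated pairs.
#'
#' @param b_grid,p_grid parameter grids (defaults 2-20 and 10-50, coarse).
#' @param n_trials trials per grid cell (default 25).
#' @param seed integer seed.
#' @param ... passed to [validation_experiment()].
#' @return data.frame with columns `b`, `p`, `mode`, `type`, `mean_score`.
#' @export
sensitivity_grid <- function(b_grid = c(2, 5, 10, 20),
                             p_grid = c(10, 20, 50), n_trials = 25,
                             seed = 1L, ...) {
  grid <- expand.grid(b = b_grid, p = p_grid)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    ve <- validation_experiment(n_trials = n_trials, b = grid$b[g],
                                p = grid$p[g],
                                seed = seed + g, ...)
    ut <- upper.tri(ve$truth)
    per_type <- function(m, type) {
      sel <- ut & ve$truth == type
      if (!any(sel)) return(NA_real_)
      mean(m[sel])
    }
    do.call(rbind, lapply(c(pospos = "mean_pospos", negpos = "mean_negpos"),
                          function(nm) {
      data.frame(b = grid$b[g], p = grid$p[g],
                 mode = sub("mean_", "", nm),
                 type = c("type1", "type2", "type3", "unrelated"),
                 mean_score = c(per_type(ve[[nm]], 1L), per_type(ve[[nm]], 2L),
                                per_type(ve[[nm]], 3L),
                                per_type(ve[[nm]], 0L)))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a full OTU table of independent bloom series
#'
#' A convenience generator for pipeline demonstrations and null controls:
#' `n_otus` mutually independent series (random phases per OTU) with the
#' given bloom parameters.
#'
#' @param n_otus number of OTUs (default 40).
#' @param n number of days (default 93).
#' @param b,p,snr as in [simulate_series()].
#' @param seed integer seed.
#' @return a counts-like [otu_table()] with days `1..n`.
#' @export
simulate_otu_table <- function(n_otus = 40, n = 93, b = 10, p = 20, snr = 1,
                               seed = 1L) {
  set.seed(seed)
  v <- t(vapply(seq_len(n_otus), function(i)
    simulate_series(n = n, b = b, p = p, snr = snr,
                    phase_base = stats::runif(1, 0, 2 * pi),
                    phase_bloom = stats::runif(1, 0, 2 * pi)),
    numeric(n)))
  rownames(v) <- sprintf("OTU%03d", seq_len(n_otus))
  otu_table(v, rownames(v), seq_len(n))
}
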