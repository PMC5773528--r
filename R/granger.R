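# Toda-Yamamoto lag-augmented Granger causality. Ordinary Granger Wald tests
# lose their chi-squared reference distribution when a series is integrated;
# the lag-augmented form fits p_lag + d_max lags of both series but tests
# only the first p_lag coefficients of the putative cause, which restores
# the chi-squared limit.

# Augmented Dickey-Fuller regression: t-statistic on rho in
# diff(x)_t = const + rho * x_{t-1} + sum_j gamma_j diff(x)_{t-j} + e_t
adf_statistic <- function(x, k = NULL) {
  x <- as.numeric(x)
  n <- length(x)
  if (is.null(k)) k <- trunc((n - 1)^(1/3))  # Said-Dickey rule
  dx <- diff(x)
  m <- length(dx)
  if (m - k < k + 3L) stop("series too short for unit-root testing")
  rows <- (k + 1L):m
  y <- dx[rows]
  X <- cbind(1, x[rows])  # x_{t-1} aligned with dx_t
  if (k > 0) for (j in seq_len(k)) X <- cbind(X, dx[rows - j])
  fit <- stats::lm.fit(X, y)
  res <- fit$residuals
  s2 <- sum(res^2) / (length(y) - ncol(X))
  xtxi <- chol2inv(chol(crossprod(X)))
  fit$coefficients[2L] / sqrt(s2 * xtxi[2L, 2L])
}

# Dickey-Fuller critical values, constant-only case (no trend), for the
# tau statistic; asymptotic row (Fuller 1976 / MacKinnon).
df_critical <- function(alpha) {
  cv <- c(`0.01` = -3.43, `0.025` = -3.12, `0.05` = -2.86, `0.10` = -2.57)
  key <- as.character(alpha)
  if (!key %in% names(cv))
    stop("alpha must be one of ", paste(names(cv), collapse = ", "))
  cv[[key]]
}

#' Order of integration of a series
#'
#' The smallest number of differencing steps `d <= max_d` after which an
#' augmented Dickey-Fuller test (constant, Said-Dickey lag rule) rejects a
#' unit root at level `alpha`; `max_d` when no differencing ever rejects.
#' Constant (zero-variance) series are degenerate and return `d = 0`.
#'
#' @param series numeric vector.
#' @param max_d maximum differencing order considered (default 2).
#' @param alpha test level, one of 0.01, 0.025, 0.05, 0.10 (default 0.05).
#' @return integer order of integration.
#' @export
order_of_integration <- function(series, max_d = 2L, alpha = 0.05) {
  x <- as.numeric(series)
  if (stats::sd(x) == 0) return(0L)
  crit <- df_critical(alpha)
  for (d in 0:max_d) {
    y <- if (d == 0) x else diff(x, differences = d)
    if (stats::sd(y) == 0) return(as.integer(d))
    if (adf_statistic(y) < crit) return(as.integer(d))
  }
  as.integer(max_d)
}

#' Toda-Yamamoto lag-augmented Granger causality test (x -> y)
#'
#' Fits `y_t` on a constant, `p_lag + d_max` lags of `y` and of `x` by least
#' squares, then Wald-tests that the first `p_lag` coefficients on `x` are
#' jointly zero, referring the statistic to a chi-squared distribution with
#' `p_lag` degrees of freedom. The `d_max` augmentation lags are never part
#' of the restriction.
#'
#' @param x putative cause series.
#' @param y response series (same length, aligned).
#' @param p_lag number of tested lags (>= 1).
#' @param d_max number of augmentation lags (the maximum order of integration
#'   of the two series); default 0 gives the standard Granger Wald test.
#' @return list of class `ty_test`: `statistic`, `df`, `p.value`, `p_lag`,
#'   `d_max`, `n_used`.
#' @export
toda_yamamoto <- function(x, y, p_lag = 1L, d_max = 0L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("series must have equal length")
  if (p_lag < 1L) stop("p_lag must be at least 1")
  ptot <- p_lag + d_max
  n <- length(y)
  if (n - ptot < 2L * ptot + 3L) stop("series too short for the model")
  rows <- (ptot + 1L):n
  X <- matrix(1, length(rows), 1L)
  for (j in seq_len(ptot)) X <- cbind(X, y[rows - j])
  for (j in seq_len(ptot)) X <- cbind(X, x[rows - j])
  yy <- y[rows]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("near-singular regressor matrix")
  beta <- qr.coef(qrX, yy)
  res <- yy - X %*% beta
  dfres <- length(yy) - ncol(X)
  s2 <- sum(res^2) / dfres
  if (s2 < .Machine$double.eps) stop("degenerate (perfect) fit")
  xtxi <- chol2inv(qr.R(qrX))
  test_idx <- 1L + ptot + seq_len(p_lag)  # first p_lag x-lags
  b <- beta[test_idx]
  V <- s2 * xtxi[test_idx, test_idx, drop = FALSE]
  stat <- drop(t(b) %*% solve(V, b))
  structure(list(statistic = stat, df = p_lag,
                 p.value = stats::pchisq(stat, df = p_lag,
                                         lower.tail = FALSE),
                 p_lag = p_lag, d_max = d_max, n_used = length(yy)),
            class = "ty_test")
}

# AIC-minimising common lag order for the bivariate model, over 1..max_lag
select_lag <- function(x, y, max_lag = 5L) {
  n <- length(y)
  max_lag <- min(max_lag, max(1L, (n - 10L) %/% 4L))
  best <- 1L; best_aic <- Inf
  start <- max_lag + 1L  # common estimation window across candidate orders
  for (p in seq_len(max_lag)) {
    rows <- start:n
    X <- matrix(1, length(rows), 1L)
    for (j in seq_len(p)) X <- cbind(X, y[rows - j], x[rows - j])
    fit <- stats::lm.fit(X, y[rows])
    rss <- sum(fit$residuals^2)
    aic <- length(rows) * log(rss / length(rows)) + 2 * ncol(X)
    if (aic < best_aic) { best_aic <- aic; best <- p }
  }
  best
}

#' Causal network over community profiles and environmental variables
#'
#' Tests every directed environment -> community and community -> community
#' pair with the Toda-Yamamoto procedure: the lag order is chosen per pair by
#' AIC over `1..max_lag`, the augmentation order is the maximum estimated
#' order of integration of the two series, and the Benjamini-Hochberg mask at
#' rate `q` is applied across all tests. Days present in only one of the two
#' series are dropped pairwise; nothing is imputed. Pairs with too few
#' overlapping days are skipped (flagged in the output).
#'
#' @param profiles matrix from [community_profiles()] (rows = communities,
#'   columns named by day).
#' @param metadata optional data.frame from [read_metadata()]; when `NULL`,
#'   only community -> community edges are tested.
#' @param q FDR level (default 0.10).
#' @param max_lag largest candidate lag order (default 5).
#' @param max_d maximum integration order considered (default 2).
#' @param alpha level of the unit-root test (default 0.05).
#' @return data.frame with one row per directed test: `source`, `target`,
#'   `p_lag`, `d_max`, `statistic`, `p.value`, `q_pass`, `skipped`.
#' @export
causal_network <- function(profiles, metadata = NULL, q = 0.10, max_lag = 5L,
                           max_d = 2L, alpha = 0.05) {
  prof_days <- as.integer(colnames(profiles))
  series <- stats::setNames(
    lapply(seq_len(nrow(profiles)), function(i)
      stats::setNames(profiles[i, ], prof_days)),
    rownames(profiles))
  kinds <- stats::setNames(rep("community", length(series)), names(series))
  if (!is.null(metadata)) {
    for (v in setdiff(names(metadata), "day")) {
      series[[v]] <- stats::setNames(metadata[[v]], metadata$day)
      kinds[[v]] <- "environment"
    }
  }
  pairs <- expand.grid(source = names(series), target = names(series),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, , drop = FALSE]
  # tested directions: env -> community, community -> community
  pairs <- pairs[kinds[pairs$target] == "community", , drop = FALSE]

  rows <- lapply(seq_len(nrow(pairs)), function(r) {
    sx <- series[[pairs$source[r]]]
    sy <- series[[pairs$target[r]]]
    days <- intersect(names(sx)[!is.na(sx)], names(sy)[!is.na(sy)])
    out <- data.frame(source = pairs$source[r], target = pairs$target[r],
                      p_lag = NA_integer_, d_max = NA_integer_,
                      statistic = NA_real_, p.value = NA_real_,
                      q_pass = FALSE, skipped = TRUE,
                      stringsAsFactors = FALSE)
    if (length(days) < 4L * max_lag + 10L) return(out)
    xx <- as.numeric(sx[days]); yy <- as.numeric(sy[days])
    p_lag <- select_lag(xx, yy, max_lag)
    d_max <- max(order_of_integration(xx, max_d, alpha),
                 order_of_integration(yy, max_d, alpha))
    tt <- tryCatch(toda_yamamoto(xx, yy, p_lag, d_max),
                   error = function(e) NULL)
    if (is.null(tt)) return(out)
    out$p_lag <- p_lag; out$d_max <- d_max
    out$statistic <- tt$statistic; out$p.value <- tt$p.value
    out$skipped <- FALSE
    out
  })
  edges <- do.call(rbind, rows)
  tested <- !edges$skipped
  if (any(tested)) edges$q_pass[tested] <- bh_fdr(edges$p.value[tested], q)
  edges
}
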