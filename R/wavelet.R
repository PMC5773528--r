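# Multilevel discrete wavelet transform with the sym2 mother wavelet and
# half-sample symmetric boundary extension. Conventions (extension width,
# convolution offset, output length floor((n + L - 1)/2)) follow the standard
# pyramid DWT so that coefficient vectors agree with common reference
# implementations (e.g. PyWavelets' wavedec with mode = "symmetric").

sym2_filters <- function() {
  s3 <- sqrt(3)
  lo <- c(1 - s3, 3 - s3, 3 + s3, 1 + s3) / (4 * sqrt(2))
  hi <- rev(lo) * c(-1, 1, -1, 1)  # quadrature mirror highpass
  list(lo = lo, hi = hi)
}

# single-level analysis step; returns approximation and detail coefficients
dwt_step <- function(x, filters = sym2_filters()) {
  fl <- length(filters$lo)
  n <- length(x)
  if (n < fl) stop("series shorter than the wavelet filter (need >= ", fl, ")")
  pad <- fl - 1L
  ext <- c(x[pad:1], x, x[n:(n - pad + 1L)])
  out_len <- (n + fl - 1L) %/% 2L
  idx <- fl + 2L * (seq_len(out_len) - 1L) + 1L  # 1-based into full convolution
  conv_lo <- stats::convolve(ext, rev(filters$lo), type = "open")
  conv_hi <- stats::convolve(ext, rev(filters$hi), type = "open")
  list(approx = conv_lo[idx], detail = conv_hi[idx])
}

#' Maximum admissible number of decomposition levels
#'
#' The deepest level at which the approximation is still at least as long as
#' the analysis filter: `floor(log2(n / (filter_len - 1)))`.
#'
#' @param n series length.
#' @param filter_len analysis filter length (4 for sym2).
#' @return integer number of levels (0 if the series is too short for one).
#' @export
max_dwt_levels <- function(n, filter_len = 4L) {
  if (n < filter_len) return(0L)
  as.integer(floor(log2(n / (filter_len - 1))))
}

#' Multilevel wavelet decomposition of one abundance series
#'
#' Decomposes a regularly sampled (daily) series into detail-coefficient
#' vectors at dyadic frequency levels, finest first. Level `j` captures
#' fluctuations with a characteristic period of about `2^j` days, so a
#' 93-point daily series yields 4 levels with periods 2, 4, 8 and 16 days.
#' The coarsest approximation band is kept in the result but excluded from
#' similarity scoring by default (see [pairwise_level_similarities()]).
#'
#' @param series numeric vector, one value per day.
#' @param n_levels number of levels; default the maximum admissible for the
#'   series length.
#' @param otu_id optional identifier stored with the result.
#' @return an object of class `wavelet_decomposition`: list with `levels`
#'   (list of detail vectors, finest to coarsest), `approx` (coarsest
#'   approximation vector), `period_days` (`2^(1:L)`), `otu_id`.
#' @export
wavelet_decompose <- function(series, n_levels = NULL, otu_id = NULL) {
  series <- as.numeric(series)
  lmax <- max_dwt_levels(length(series))
  if (lmax < 1L) stop("series too short for one decomposition level")
  if (is.null(n_levels)) n_levels <- lmax
  if (n_levels < 1L || n_levels > lmax)
    stop("n_levels must be in 1..", lmax, " for a series of length ",
         length(series))
  filters <- sym2_filters()
  details <- vector("list", n_levels)
  a <- series
  for (j in seq_len(n_levels)) {
    s <- dwt_step(a, filters)
    details[[j]] <- s$detail
    a <- s$approx
  }
  # a level whose energy is pure floating-point residue (e.g. the details of
  # a constant series) carries no frequency information; zero it so cosine
  # similarities between silent levels are 0, not numerical noise
  floor_norm <- 1e-9 * sqrt(sum(series^2))
  details <- lapply(details, function(v)
    if (sqrt(sum(v^2)) <= floor_norm) v * 0 else v)
  structure(list(levels = details, approx = a,
                 period_days = 2^seq_len(n_levels), otu_id = otu_id),
            class = "wavelet_decomposition")
}

cosine_sim <- function(u, v) {
  nu <- sqrt(sum(u * u)); nv <- sqrt(sum(v * v))
  if (nu == 0 || nv == 0) return(0)
  sum(u * v) / (nu * nv)
}

#' Cosine similarity between two decompositions at one frequency level
#'
#' Returns 0 when either coefficient vector is all zero (an OTU silent at a
#' level carries no information at that frequency).
#'
#' @param a,b `wavelet_decomposition` objects with identical level structure.
#' @param level level index (1 = finest, period 2 days).
#' @return a number in `[-1, 1]`.
#' @export
level_similarity <- function(a, b, level) {
  stopifnot(inherits(a, "wavelet_decomposition"),
            inherits(b, "wavelet_decomposition"))
  if (length(a$levels) != length(b$levels) ||
      any(lengths(a$levels) != lengths(b$levels)))
    stop("decompositions have mismatched level structure")
  if (level < 1L || level > length(a$levels)) stop("no such level: ", level)
  cosine_sim(a$levels[[level]], b$levels[[level]])
}

#' Decompose every row of an OTU table
#'
#' @param table an [otu_table()] with one column per day.
#' @param n_levels passed to [wavelet_decompose()].
#' @return named list of `wavelet_decomposition` objects, one per OTU.
#' @export
decompose_table <- function(table, n_levels = NULL) {
  stopifnot(inherits(table, "otu_table"))
  if (anyDuplicated(table$sample_days))
    stop("average replicates before decomposition (duplicate days present)")
  out <- lapply(seq_len(nrow(table$values)), function(i)
    wavelet_decompose(table$values[i, ], n_levels, otu_id = table$otu_ids[i]))
  names(out) <- table$otu_ids
  out
}

#' Per-level pairwise cosine-similarity matrices
#'
#' Builds one symmetric OTU-by-OTU cosine-similarity matrix per frequency
#' level. Rows whose coefficient vector is all zero at a level get similarity
#' 0 against everything (including themselves) at that level.
#'
#' @param decomps list of `wavelet_decomposition` objects sharing one level
#'   structure (as from [decompose_table()]).
#' @param include_approx if `TRUE`, append the coarsest approximation band as
#'   an extra (coarsest) pseudo-level with period `2^(L+1)` days.
#' @return an object of class `level_similarity_stack`: list with `sims`
#'   (list of matrices, finest level first) and `period_days`.
#' @export
pairwise_level_similarities <- function(decomps, include_approx = FALSE) {
  if (length(decomps) < 2L) stop("need at least two decompositions")
  L <- length(decomps[[1L]]$levels)
  ids <- vapply(seq_along(decomps), function(i) {
    id <- decomps[[i]]$otu_id
    if (is.null(id)) paste0("OTU", i) else id
  }, character(1L))
  periods <- decomps[[1L]]$period_days
  bands <- lapply(seq_len(L), function(j)
    t(vapply(decomps, function(d) d$levels[[j]],
             numeric(length(decomps[[1L]]$levels[[j]])))))
  if (include_approx) {
    bands <- c(bands, list(t(vapply(decomps, function(d) d$approx,
                                    numeric(length(decomps[[1L]]$approx))))))
    periods <- c(periods, 2^(L + 1L))
  }
  sims <- lapply(bands, function(m) {
    nr <- sqrt(rowSums(m * m))
    mn <- m / ifelse(nr > 0, nr, 1)  # zero rows stay zero -> similarity 0
    s <- tcrossprod(mn)
    s <- pmin(pmax(s, -1), 1)
    dimnames(s) <- list(ids, ids)
    s
  })
  structure(list(sims = sims, period_days = periods, otu_ids = ids),
            class = "level_similarity_stack")
}
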