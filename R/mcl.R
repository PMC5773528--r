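#' Markov clustering (MCL) of a weighted interaction graph
#'
#' Iterates expansion (matrix squaring of the column-stochastic transition
#' matrix) and inflation (element-wise power followed by column
#' renormalisation) until the matrix is stable, then reads clusters off the
#' attractor structure. Before the first normalisation every node receives a
#' self-loop equal to its maximum incident edge weight (a standard
#' regularisation that guarantees convergence; isolated nodes get weight 1).
#' Entries below `prune` are zeroed after each inflation to keep the matrix
#' sparse in spirit.
#'
#' Nodes not attracted to any attractor system (possible only in degenerate
#' inputs) are reported unclustered; nodes attracted to several systems go to
#' the one receiving the larger total flow, ties to the lexicographically
#' smallest attractor label.
#'
#' @param adjacency symmetric non-negative weight matrix with dimnames, or an
#'   `interaction_scores` object (its `scores` matrix is used).
#' @param inflation inflation exponent, > 1 (default 2.4).
#' @param max_iter maximum expansion/inflation rounds (default 200).
#' @param tol convergence threshold on the max absolute change between
#'   successive matrices (default 1e-6).
#' @param prune transition probabilities below this are zeroed after each
#'   inflation (default 1e-5).
#' @return an object of class `mcl_partition`: list with `membership` (named
#'   integer vector over all nodes; `NA` = unclustered), `n_clusters`,
#'   `inflation`, `iterations`.
#' @export
mcl <- function(adjacency, inflation = 2.4, max_iter = 200, tol = 1e-6,
                prune = 1e-5) {
  if (inherits(adjacency, "interaction_scores")) adjacency <- adjacency$scores
  a <- as.matrix(adjacency)
  n <- nrow(a)
  if (n == 0L) stop("empty graph")
  if (is.null(rownames(a))) dimnames(a) <- list(paste0("n", seq_len(n)),
                                                paste0("n", seq_len(n)))
  if (any(a < 0)) stop("edge weights must be non-negative")
  if (max(abs(a - t(a))) > 1e-9) stop("adjacency must be symmetric")
  if (inflation <= 1) stop("inflation must exceed 1")
  ids <- rownames(a)
  diag(a) <- 0
  loop <- apply(a, 2L, max)
  loop[loop == 0] <- 1
  diag(a) <- loop

  m <- sweep(a, 2L, colSums(a), "/")
  iter <- 0L
  repeat {
    iter <- iter + 1L
    m2 <- m %*% m                      # expansion
    m2 <- m2^inflation                 # inflation
    m2[m2 < prune] <- 0
    cs <- colSums(m2)
    dead <- cs == 0                    # fully pruned column: park on itself
    if (any(dead)) { m2[cbind(which(dead), which(dead))] <- 1; cs[dead] <- 1 }
    m2 <- sweep(m2, 2L, cs, "/")
    delta <- max(abs(m2 - m))
    m <- m2
    if (delta < tol) break
    if (iter >= max_iter)
      stop(sprintf("MCL did not converge in %d iterations (residual %.3g)",
                   max_iter, delta))
  }

  attractors <- which(diag(m) > tol)
  if (length(attractors) == 0L) attractors <- which.max(diag(m))
  # attractor systems: connected groups of attractors (they share columns)
  sys_of <- integer(0)
  sys_id <- rep(NA_integer_, n)
  next_sys <- 0L
  for (att in attractors) {
    linked <- sys_id[attractors][!is.na(sys_id[attractors]) &
                                   m[att, attractors] > tol]
    linked <- unique(c(linked,
                       sys_id[attractors][!is.na(sys_id[attractors]) &
                                            m[attractors, att] > tol]))
    if (length(linked) == 0L) {
      next_sys <- next_sys + 1L
      sys_id[att] <- next_sys
    } else {
      keep <- min(linked)
      sys_id[att] <- keep
      sys_id[sys_id %in% linked] <- keep
    }
  }
  systems <- sort(unique(sys_id[attractors]))
  membership <- rep(NA_integer_, n)
  flow <- vapply(systems, function(s) {
    rows <- attractors[sys_id[attractors] == s]
    colSums(m[rows, , drop = FALSE])
  }, numeric(n))
  flow <- matrix(flow, nrow = n)
  has_flow <- rowSums(flow) > tol
  membership[has_flow] <- max.col(flow[has_flow, , drop = FALSE],
                                  ties.method = "first")
  # relabel 1..K by first appearance for determinism
  membership <- match(membership, unique(stats::na.omit(membership)))
  names(membership) <- ids
  structure(list(membership = membership,
                 n_clusters = length(unique(stats::na.omit(membership))),
                 inflation = inflation, iterations = iter),
            class = "mcl_partition")
}

#' @export
print.mcl_partition <- function(x, ...) {
  cat(sprintf("mcl_partition: %d clusters over %d nodes (inflation %.2f, %d iterations)\n",
              x$n_clusters, length(x$membership), x$inflation, x$iterations))
  invisible(x)
}

#' Cluster granularity across a range of inflation values
#'
#' Small inflation values produce fewer, larger clusters; large values more,
#' smaller ones. For each value the number of clusters and the fraction of
#' nodes in clusters of size >= 2 are reported.
#'
#' @param adjacency as in [mcl()].
#' @param inflations numeric vector of inflation values (default the sweep
#'   1.6, 2.0, 2.4, 2.8, 3.2, 3.6, 4.2).
#' @param ... passed to [mcl()].
#' @return data.frame with columns `inflation`, `n_clusters`,
#'   `fraction_clustered`.
#' @export
inflation_sweep <- function(adjacency,
                            inflations = c(1.6, 2.0, 2.4, 2.8, 3.2, 3.6, 4.2),
                            ...) {
  rows <- lapply(inflations, function(i) {
    p <- mcl(adjacency, inflation = i, ...)
    sizes <- table(p$membership)
    in_big <- sum(sizes[sizes >= 2])
    data.frame(inflation = i, n_clusters = p$n_clusters,
               fraction_clustered = in_big / length(p$membership))
  })
  do.call(rbind, rows)
}

#' Mean relative-abundance profile of each community
#'
#' @param partition an `mcl_partition` (or named membership vector).
#' @param table a relative-abundance [otu_table()] (one column per day)
#'   covering every clustered OTU.
#' @return matrix, one row per community (rownames `C1`, `C2`, ...), one
#'   column per day.
#' @export
community_profiles <- function(partition, table) {
  membership <- if (inherits(partition, "mcl_partition"))
    partition$membership else partition
  stopifnot(inherits(table, "otu_table"))
  membership <- membership[!is.na(membership)]
  missing <- setdiff(names(membership), table$otu_ids)
  if (length(missing))
    stop("clustered OTU(s) missing from table: ",
         paste(missing, collapse = ", "))
  labs <- sort(unique(membership))
  prof <- t(vapply(labs, function(l) {
    members <- names(membership)[membership == l]
    colMeans(table$values[members, , drop = FALSE])
  }, numeric(ncol(table$values))))
  rownames(prof) <- paste0("C", labs)
  colnames(prof) <- table$sample_days
  prof
}
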