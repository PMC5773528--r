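# Independent brute-force oracles used across the suite. These deliberately
# re-derive quantities with the most literal formula available, never by
# calling the implementation under test.

oracle_cosine <- function(u, v) {
  if (sqrt(sum(u^2)) == 0 || sqrt(sum(v^2)) == 0) return(0)
  sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
}

# exhaustive weighted-score maximum over every (high, low) level combination
oracle_pair_score <- function(sims_by_level, periods, mode,
                              pos_thr = 0.7, neg_thr = -0.5, k = 0.25) {
  best <- 0
  L <- length(sims_by_level)
  for (hi in seq_len(L)) for (lo in seq_len(L)) {
    if (periods[hi] >= periods[lo]) next
    sh <- sims_by_level[hi]; sl <- sims_by_level[lo]
    delta <- periods[lo] - periods[hi]
    if (mode == "pospos") {
      raw <- if (sh > pos_thr && sl > pos_thr) sqrt(sh * sl) else 0
      w <- k * delta + 1
    } else {
      raw <- if (sh < neg_thr && sl > pos_thr) sqrt(-sh * sl) else 0
      w <- (1 / delta) / (k + 1 / delta)
    }
    best <- max(best, w * raw)
  }
  best
}

oracle_mi <- function(u, v) {
  ct <- table(u, v)
  n <- sum(ct)
  mi <- 0
  for (i in seq_len(nrow(ct))) for (j in seq_len(ncol(ct))) {
    pij <- ct[i, j] / n
    if (pij == 0) next
    mi <- mi + pij * log(pij / ((sum(ct[i, ]) / n) * (sum(ct[, j]) / n)))
  }
  mi
}

# exact expected MI at fixed margins by full enumeration of permutations of
# one labelling (feasible only for tiny n)
oracle_expected_mi <- function(u, v) {
  n <- length(u)
  perms <- all_permutations(seq_len(n))
  mean(vapply(perms, function(p) oracle_mi(u, v[p]), numeric(1L)))
}

all_permutations <- function(x) {
  if (length(x) == 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    rest <- all_permutations(x[-i])
    out <- c(out, lapply(rest, function(r) c(x[i], r)))
  }
  out
}

entropy_of_labels <- function(x) {
  p <- table(x) / length(x)
  -sum(p * log(p))
}

oracle_jsd <- function(P, Q) {
  M <- (P + Q) / 2
  kl <- function(a, b) {
    s <- 0
    for (i in seq_along(a)) if (a[i] > 0) s <- s + a[i] * log2(a[i] / b[i])
    s
  }
  sqrt(0.5 * kl(P, M) + 0.5 * kl(Q, M))
}

# deterministic small OTU fixture: smooth positive series, optional replicates
make_fixture_table <- function(n_otus = 5, n_days = 32, replicates = 1,
                               seed = 101) {
  set.seed(seed)
  days <- rep(seq_len(n_days), each = replicates)
  v <- t(vapply(seq_len(n_otus), function(i) {
    base <- abs(sin(seq_along(days) / i + i)) + 0.1
    base * stats::runif(length(days), 0.8, 1.2)
  }, numeric(length(days))))
  rownames(v) <- paste0("OTU", seq_len(n_otus))
  otu_table(v, rownames(v), days)
}

# sym2 multilevel DWT of sin(x) + 0.5 sin(x/8), x = 1..93, frozen from
# PyWavelets (pywt.wavedec, mode = "symmetric") as an external reference.
pywt_reference <- function() {
  list(
    input = sin(1:93) + 0.5 * sin((1:93) / 8),
    cD4 = c(0.216518694730904, -0.462589758178742, 0.383273679395173,
            -0.933767342335974, 0.616961099214607, 0.11832232832674,
            0.872081900833599, -1.38987767721333),
    cD3 = c(0.08444482269821, -1.04009265784593, 1.21485201008223,
            0.340587475866396, -1.19535177057357, -0.065544083741751,
            1.01714148891978, -0.370825687971143, -0.863644502545644,
            0.811789009503913, 0.78675594992499, -1.12091123894808,
            -0.724171219677942, 1.61591471347647),
    cD1_head = c(-0.0791130409913069, 0.172478929157901, -0.513149241510533,
                 0.262060397477479, 0.304956534645401),
    cA4 = c(3.63275386534586, 3.31680506923912, 1.54289998912197,
            -0.699146158996837, -1.25025240362957, 1.97755988151143,
            -0.246829903194581, -3.78416255075118))
}
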