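# Shared fixtures and independent oracles for the test suite.

# random weight matrix with labelled concepts
rand_map <- function(n, scale = 0.5) {
  fcm_weights(matrix(runif(n * n, -scale, scale), n, n),
              paste0("C", seq_len(n)))
}

# noise-free trajectory generated by rolling a known map forward
rollout_traj <- function(W, init = NULL, steps = 3,
                         control = fcm_sim_control()) {
  if (is.null(init)) {
    init <- runif(nrow(W), 0.2, 0.8)
    names(init) <- rownames(W)
  }
  fcm_trajectory(fcm_rollout(init, W, control, steps))
}

# independent bisection root-finder for x = 1 / (1 + exp(-x)); deliberately
# avoids the package's own simulation path
bisect_sigmoid_fixed_point <- function(lo = 0, hi = 1, tol = 1e-12) {
  g <- function(x) 1 / (1 + exp(-x)) - x
  stopifnot(g(lo) > 0, g(hi) < 0)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# independent fine-grid centroid oracle for the fuzzy pipeline: its own
# triangle evaluation, activation bookkeeping and integration, sharing no
# code with the package implementation
oracle_tri <- function(x, a, b, c) {
  up <- if (b > a) (x - a) / (b - a) else as.numeric(x >= b)
  dn <- if (c > b) (c - x) / (c - b) else as.numeric(x <= b)
  pmax(0, pmin(up, dn, 1))
}

oracle_centroid <- function(terms, vocab, n_grid = 1e6 + 1) {
  x <- seq(0, 1, length.out = n_grid)
  counts <- table(terms)
  curve <- numeric(n_grid)
  for (term in names(counts)) {
    if (term == "non-existent") next
    mf <- vocab$mfs[[term]]
    lev <- as.numeric(counts[[term]]) / length(terms)
    curve <- pmax(curve, pmin(oracle_tri(x, mf$a, mf$b, mf$c), lev))
  }
  s <- sum(curve)
  if (s == 0) 0 else sum(x * curve) / s
}

# all multisets of `size` linguistic terms (as a list of character vectors)
term_multisets <- function(terms, size = 3) {
  idx <- utils::combn(length(terms) + size - 1, size)
  lapply(seq_len(ncol(idx)), function(j) {
    terms[idx[, j] - seq_len(size) + 1]
  })
}
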