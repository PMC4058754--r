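# Test helpers: independent oracles and small fixtures.

# Exhaustive minimum-cost injective assignment of rows to columns
# (enumeration over all injections; the independent oracle for Munkres).
brute_force_assignment <- function(cost) {
  n <- nrow(cost)
  m <- ncol(cost)
  stopifnot(n <= m)
  best <- Inf
  rec <- function(i, used, acc) {
    if (i > n) {
      if (acc < best) best <<- acc
      return(invisible())
    }
    for (j in seq_len(m)) {
      if (!used[j]) {
        used[j] <- TRUE
        rec(i + 1L, used, acc + cost[i, j])
        used[j] <- FALSE
      }
    }
  }
  rec(1L, rep(FALSE, m), 0)
  best
}

# Small attributed graph from a weight matrix, with simple default powers
# and well-separated coordinates.
tg <- function(W, powers = NULL, coords = NULL, id = "g") {
  N <- nrow(W)
  if (is.null(powers)) powers <- seq(0.2, 0.9, length.out = N)
  if (is.null(coords)) {
    coords <- cbind(30 * seq_len(N), 10 * (seq_len(N) %% 3), 0)
  }
  graph_from_adjacency(W, powers, coords, subject_id = id)
}

# Complete graph on n nodes with constant edge weight.
complete_graph <- function(n, w = 1, ...) {
  W <- matrix(w, n, n)
  diag(W) <- 0
  tg(W, ...)
}

# Random attributed graph (for property-style checks).
random_graph <- function(n, p_edge = 0.5, id = "rg") {
  W <- matrix(0, n, n)
  up <- which(upper.tri(W))
  on <- up[stats::runif(length(up)) < p_edge]
  W[on] <- round(stats::runif(length(on), 0.3, 1), 3)
  W <- W + t(W)
  tg(W, powers = round(stats::runif(n), 3),
     coords = matrix(stats::runif(n * 3, 0, 60), n, 3), id = id)
}

# One small simulated cohort shared across tests (built once per session).
.fixture_env <- new.env(parent = emptyenv())

small_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    cfg <- cohort_config(n_per_group = 8, n_test_per_group = 4,
                         n_timepoints = 80, seed = 42)
    .fixture_env$cohort <- simulate_cohort(cfg)
  }
  .fixture_env$cohort
}

small_cohort_graphs <- function() {
  if (is.null(.fixture_env$graphs)) {
    .fixture_env$graphs <- cohort_graphs(small_cohort(),
                                         network_config(corr_threshold = 0))
  }
  .fixture_env$graphs
}
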