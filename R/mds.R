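# Metric multidimensional scaling by stress majorization (SMACOF),
# initialized from the classical (eigendecomposition) solution.

#' Embedding configuration
#'
#' @param n_dims Dimension of the embedding space (default 2; two
#'   dimensions gave the method its best classification performance).
#' @param max_iter Iteration cap for the majorization loop (default 1e5).
#' @param seed RNG seed; only consumed when the classical initialization is
#'   rank-deficient and missing coordinates must be jittered.
#' @param tol Relative stress-change convergence tolerance (default 1e-8).
#' @return An `embedding_config` list.
#' @export
embedding_config <- function(n_dims = 2, max_iter = 100000, seed = 1,
                             tol = 1e-8) {
  stopifnot(n_dims >= 1, max_iter >= 1, tol > 0)
  structure(list(n_dims = as.integer(n_dims),
                 max_iter = as.integer(max_iter),
                 seed = seed, tol = tol,
                 criterion = "metric_stress"),
            class = "embedding_config")
}

check_distance_matrix <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) stop("distance matrix must be square", call. = FALSE)
  if (max(abs(D - t(D))) > 1e-8) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  if (any(D < 0)) stop("distances must be nonnegative", call. = FALSE)
  if (any(abs(diag(D)) > 1e-12)) {
    stop("distance matrix must have a zero diagonal", call. = FALSE)
  }
  D
}

#' Metric stress of a configuration against target distances
#'
#' `stress = sqrt( sum_{i<j} (D_ij - ||x_i - x_j||)^2 / sum_{i<j} D_ij^2 )`.
#' Zero for a configuration that reproduces the distances exactly; 1 when
#' all points collapse to a single location.
#'
#' @param D Symmetric nonnegative distance matrix with zero diagonal.
#' @param coords n x k coordinate matrix.
#' @return Nonnegative scalar.
#' @export
metric_stress <- function(D, coords) {
  D <- check_distance_matrix(D)
  coords <- as.matrix(coords)
  if (nrow(coords) != nrow(D)) stop("shapes disagree", call. = FALSE)
  up <- upper.tri(D)
  denom <- sum(D[up]^2)
  if (denom == 0) stop("all-zero distance matrix", call. = FALSE)
  Dp <- as.matrix(stats::dist(coords))
  sqrt(sum((D[up] - Dp[up])^2) / denom)
}

#' Embed subjects by metric-stress MDS
#'
#' Starts from the classical scaling solution (`stats::cmdscale`) and
#' refines it by SMACOF majorization, which decreases the metric stress
#' monotonically. Iteration stops when the relative stress change falls
#' below `cfg$tol` or `cfg$max_iter` is reached. The procedure is
#' deterministic for a given seed (randomness only enters when the
#' classical start is rank-deficient and columns must be jittered).
#'
#' @param D Symmetric nonnegative distance matrix, zero diagonal, >= 2
#'   subjects.
#' @param cfg An [embedding_config()].
#' @return An `mds_embedding`: `coords` (n x n_dims), `stress` (final
#'   metric stress), `stress_trace`, `n_iter`, `converged`.
#' @export
mds_embed <- function(D, cfg = embedding_config()) {
  D <- check_distance_matrix(D)
  n <- nrow(D)
  if (n < 2L) stop("need at least 2 subjects", call. = FALSE)
  up <- upper.tri(D)
  if (sum(D[up]^2) == 0) stop("all-zero distance matrix", call. = FALSE)
  k <- cfg$n_dims

  X <- suppressWarnings(stats::cmdscale(D, k = min(k, n - 1L)))
  if (ncol(X) < k) {
    # rank-deficient classical start: pad with tiny seeded jitter
    set.seed(cfg$seed)
    X <- cbind(X, matrix(stats::rnorm(n * (k - ncol(X)), sd = 1e-8),
                         n, k - ncol(X)))
  }

  s <- metric_stress(D, X)
  trace <- s
  iter <- 0L
  converged <- FALSE
  while (iter < cfg$max_iter) {
    iter <- iter + 1L
    Dp <- as.matrix(stats::dist(X))
    ratio <- ifelse(Dp > 0, D / Dp, 0)
    B <- -ratio
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    X <- B %*% X / n        # Guttman transform
    s_new <- metric_stress(D, X)
    trace <- c(trace, s_new)
    # relative criterion, with an absolute floor so that configurations at
    # (numerically) zero stress terminate
    if (abs(s - s_new) <= max(cfg$tol * s, 1e-12)) {
      s <- s_new
      converged <- TRUE
      break
    }
    s <- s_new
  }
  dimnames(X) <- list(rownames(D), paste0("dim", seq_len(k)))
  structure(list(coords = X, stress = s, stress_trace = trace,
                 n_iter = iter, converged = converged, config = cfg),
            class = "mds_embedding")
}

#' @export
print.mds_embedding <- function(x, ...) {
  cat(sprintf("<mds_embedding> %d subjects in %d dims; stress %.3g (%d iterations%s)\n",
              nrow(x$coords), ncol(x$coords), x$stress, x$n_iter,
              if (x$converged) "" else ", not converged"))
  invisible(x)
}
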