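# Standard graph-feature baselines computed on the binarized networks
# (edge present iff correlation >= corrTh), plus the global features used
# to interpret the embedding axes. Per-node features need equal node counts
# across subjects, i.e. graphs built with per-ROI voxel selection
# (`network_config(roiwise_selection = TRUE)`).

#' Baseline feature configuration
#'
#' @param gtom_steps Neighborhood depth m of the generalized topological
#'   overlap (default 5).
#' @param rich_club_k Degree level at which the scalar rich-club feature is
#'   evaluated (default 1).
#' @param pow_threshold Power threshold for the high-power node fraction
#'   (default 0.85).
#' @param binarize Features are computed on the binarized adjacency
#'   (fixed TRUE; weighted variants are out of scope).
#' @return A `baseline_config` list.
#' @export
baseline_config <- function(gtom_steps = 5, rich_club_k = 1,
                            pow_threshold = 0.85, binarize = TRUE) {
  stopifnot(gtom_steps >= 1, rich_club_k >= 0,
            pow_threshold >= 0, pow_threshold <= 1)
  structure(list(gtom_steps = as.integer(gtom_steps),
                 rich_club_k = as.integer(rich_club_k),
                 pow_threshold = pow_threshold,
                 binarize = TRUE),
            class = "baseline_config")
}

# Binary adjacency matrix of an attributed graph.
graph_adjacency <- function(g) {
  N <- nrow(g$nodes)
  A <- matrix(0L, N, N)
  if (nrow(g$edges) > 0L) {
    A[cbind(g$edges$from, g$edges$to)] <- 1L
    A[cbind(g$edges$to, g$edges$from)] <- 1L
  }
  A
}

graph_igraph <- function(g) {
  igraph::graph_from_adjacency_matrix(graph_adjacency(g), mode = "undirected")
}

#' Per-node degree (unweighted neighbor count)
#'
#' Distinct from the weighted degree in the node signature: here degree is
#' the number of nodes a node is connected to in the binarized network.
#'
#' @param g An `attributed_graph`.
#' @return Integer vector, one count per node.
#' @export
degree_feature <- function(g) {
  as.integer(colSums(graph_adjacency(g)))
}

#' Generalized topological overlap (GTOM-m), per node
#'
#' Pairwise overlap of m-step neighborhoods: with `N_m(i)` the set of nodes
#' reachable from i by a path of length at most m (excluding i itself), the
#' overlap of i and j is
#' `(|N_m(i) inter N_m(j)| + a_ij) / (min(|N_m(i)|, |N_m(j)|) + 1 - a_ij)`.
#' The per-node feature is the mean overlap of the node with all others.
#'
#' @param g An `attributed_graph`.
#' @param m Neighborhood depth (default 5).
#' @return Numeric vector, one score per node.
#' @export
gtom <- function(g, m = 5) {
  A <- graph_adjacency(g)
  N <- nrow(A)
  if (N == 1L) return(0)
  M <- A
  if (m >= 2) {
    for (s in 2:m) M <- (M + M %*% A > 0) * 1L
  }
  diag(M) <- 0L
  k <- rowSums(M)
  inter <- M %*% t(M)          # |N_m(i) inter N_m(j)|
  denom <- outer(k, k, pmin) + 1 - A
  Tov <- (inter + A) / denom
  diag(Tov) <- 0
  rowSums(Tov) / (N - 1)
}

#' Clustering coefficient, per node
#'
#' Fraction of triangles around a node: connected neighbor pairs over all
#' neighbor pairs; nodes with fewer than 2 neighbors score 0.
#'
#' @param g An `attributed_graph`.
#' @return Numeric vector in `[0, 1]`.
#' @export
clustering_coefficient <- function(g) {
  cc <- igraph::transitivity(graph_igraph(g), type = "local", isolates = "zero")
  cc[is.nan(cc)] <- 0
  cc
}

#' Local efficiency, per node
#'
#' Global efficiency (mean inverse shortest-path length) of the subgraph
#' induced by a node's neighbors; nodes with fewer than 2 neighbors score 0.
#'
#' @param g An `attributed_graph`.
#' @return Numeric vector in `[0, 1]`.
#' @export
local_efficiency <- function(g) {
  ig <- graph_igraph(g)
  if (igraph::ecount(ig) == 0L) return(rep(0, nrow(g$nodes)))
  igraph::local_efficiency(ig, weights = NA)
}

#' Rich-club curve phi(k), k = 0..K
#'
#' `phi(k) = 2 E_k / (N_k (N_k - 1))` where `N_k` counts nodes of degree
#' greater than k and `E_k` the edges among them; levels with fewer than 2
#' such nodes are encoded 0.
#'
#' @param g An `attributed_graph`.
#' @param K Maximum degree level (typically the maximum degree over the
#'   training data).
#' @return Numeric vector of length `K + 1`, named by k.
#' @export
rich_club_curve <- function(g, K) {
  A <- graph_adjacency(g)
  deg <- colSums(A)
  phi <- vapply(0:K, function(k) {
    idx <- deg > k
    nk <- sum(idx)
    if (nk < 2L) return(0)
    sum(A[idx, idx]) / (nk * (nk - 1))
  }, numeric(1))
  names(phi) <- 0:K
  phi
}

#' Global network features of one subject
#'
#' Density (present edges over possible edges), global efficiency (mean
#' inverse shortest-path length), the rich-club coefficient at
#' `cfg$rich_club_k`, and the fraction of nodes with power above
#' `cfg$pow_threshold`.
#'
#' @param g An `attributed_graph` with node powers.
#' @param cfg A [baseline_config()].
#' @return Named numeric vector of 4 scalars.
#' @export
global_features <- function(g, cfg = baseline_config()) {
  ig <- graph_igraph(g)
  N <- nrow(g$nodes)
  dens <- if (N < 2L) 0 else igraph::edge_density(ig)
  geff <- if (igraph::ecount(ig) == 0L) 0 else
    igraph::global_efficiency(ig, weights = NA)
  rc <- rich_club_curve(g, cfg$rich_club_k)[[cfg$rich_club_k + 1L]]
  c(density = dens,
    global_efficiency = geff,
    rich_club_at_k = rc,
    high_power_node_fraction = mean(g$nodes$power > cfg$pow_threshold))
}

#' Correlation of a per-subject feature with an embedding axis
#'
#' @param features Per-subject scalars.
#' @param axis Matching embedding coordinates (one axis).
#' @return Pearson correlation.
#' @export
feature_axis_correlation <- function(features, axis) {
  if (length(features) != length(axis)) {
    stop("features and axis lengths differ", call. = FALSE)
  }
  if (length(features) < 3L) stop("need at least 3 subjects", call. = FALSE)
  pearson_corr(features, axis)
}

#' Per-subject feature matrix for a named feature
#'
#' Stacks one per-node (or per-k) feature vector per subject. Requires
#' identical node counts across subjects (graphs built with per-ROI
#' selection); the rich-club feature spans k = 0..K.
#'
#' @param graphs List of `attributed_graph`s with equal node counts.
#' @param feature One of `"degree"`, `"gtom"`, `"clustering"`,
#'   `"local_efficiency"`, `"rich_club"`.
#' @param cfg A [baseline_config()].
#' @param K Rich-club range; default the maximum degree over `graphs`.
#' @return Subjects x features numeric matrix with subject-id rownames.
#' @export
subject_features <- function(graphs, feature = c("degree", "gtom", "clustering",
                                                 "local_efficiency", "rich_club"),
                             cfg = baseline_config(), K = NULL) {
  feature <- match.arg(feature)
  if (feature == "rich_club" && is.null(K)) {
    K <- max(unlist(lapply(graphs, function(g) max(c(0, degree_feature(g))))))
  }
  rows <- lapply(graphs, function(g) {
    switch(feature,
           degree = degree_feature(g),
           gtom = gtom(g, cfg$gtom_steps),
           clustering = clustering_coefficient(g),
           local_efficiency = local_efficiency(g),
           rich_club = rich_club_curve(g, K))
  })
  lens <- lengths(rows)
  if (length(unique(lens)) != 1L) {
    stop("ragged feature vectors: node counts differ across subjects ",
         "(build graphs with roiwise_selection = TRUE)", call. = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- vapply(graphs, `[[`, character(1), "subject_id")
  out
}

#' Classify subjects from baseline feature vectors
#'
#' Same SVM protocol as the attributed-graph pipeline, applied directly to
#' fixed-length feature vectors instead of embedded coordinates.
#'
#' @param features Subjects x features matrix (see [subject_features()]).
#' @param labels Labels in `{control, case}`.
#' @param protocol `"loocv"` or `"train_test"`.
#' @param train_idx,test_idx Split indices for `"train_test"`.
#' @param ccfg A [classifier_config()].
#' @return List with `metrics` and `predicted`.
#' @export
baseline_classify <- function(features, labels,
                              protocol = c("loocv", "train_test"),
                              train_idx = NULL, test_idx = NULL,
                              ccfg = classifier_config()) {
  protocol <- match.arg(protocol)
  X <- as.matrix(features)
  y <- as_class_factor(labels)
  if (nrow(X) != length(y)) stop("features and labels disagree", call. = FALSE)
  if (protocol == "loocv") {
    if (any(table(y) < 2L)) {
      stop("need at least 2 subjects per class", call. = FALSE)
    }
    pred <- factor(rep(NA_character_, nrow(X)), levels = CLASS_LEVELS)
    for (i in seq_len(nrow(X))) {
      fit <- fit_svm(X[-i, , drop = FALSE], y[-i], ccfg)
      pred[i] <- stats::predict(fit, X[i, , drop = FALSE])
    }
    list(metrics = detection_metrics(pred, y), predicted = pred)
  } else {
    stopifnot(!is.null(train_idx), !is.null(test_idx))
    fit <- fit_svm(X[train_idx, , drop = FALSE], y[train_idx], ccfg)
    pred <- stats::predict(fit, X[test_idx, , drop = FALSE])
    list(metrics = detection_metrics(pred, y[test_idx]), predicted = pred)
  }
}
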