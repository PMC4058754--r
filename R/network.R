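# Attributed functional connectivity network construction.
#
# One subject's in-mask voxel time series become a graph: voxels are scored
# by time-series power, the most active ones are kept, survivors are grouped
# by ROI label into nodes, nodes are linked by positive Pearson correlation
# of their mean series above a threshold, and every node carries a signature
# <weighted degree, sorted neighbor degrees, power, sorted neighbor powers,
# mean world coordinate>.

#' Network construction configuration
#'
#' @param power_percentile Voxel power percentile cutoff in (0, 100); voxels
#'   "ranked at this percentile or more" (the top `100 - power_percentile`
#'   percent, ties included) survive selection. Default 98.
#' @param corr_threshold Correlation threshold `corrTh` in `[0, 1]`; edges
#'   with Pearson correlation below it are removed. Only positive
#'   correlations ever form edges. Default 0.5 (midpoint of the usual
#'   0.30-0.90 sweep grid).
#' @param roiwise_selection If TRUE, the power percentile is applied within
#'   each ROI instead of over the whole brain, so every ROI containing at
#'   least one in-mask voxel yields a node and node counts are equal across
#'   subjects (required by fixed-length feature baselines).
#' @return A `network_config` list.
#' @export
network_config <- function(power_percentile = 98, corr_threshold = 0.5,
                           roiwise_selection = FALSE) {
  stopifnot(power_percentile > 0, power_percentile < 100,
            corr_threshold >= 0, corr_threshold <= 1)
  structure(list(power_percentile = power_percentile,
                 corr_threshold = corr_threshold,
                 edge_sign = "positive",
                 roiwise_selection = isTRUE(roiwise_selection)),
            class = "network_config")
}

#' Power of a time series
#'
#' Mean squared amplitude, `P(T) = (1/n) sum t_i^2`. Series are used as-is
#' (no demeaning): bandpass-filtered BOLD inputs are near zero-mean, so
#' power reflects fluctuation amplitude.
#'
#' @param series Numeric vector of length >= 1.
#' @return Nonnegative scalar; zero iff the series is identically zero.
#' @export
voxel_power <- function(series) {
  if (length(series) == 0L) stop("empty series", call. = FALSE)
  mean(series^2)
}

# Row-wise power of a voxel-by-time matrix.
voxel_powers <- function(series_matrix) {
  rowMeans(series_matrix^2)
}

#' Min-max normalize voxel powers to [0, 1]
#'
#' @param powers Numeric vector (>= 1 value).
#' @return Vector with min 0 and max 1; constant input maps to all zeros.
#' @export
normalize_powers <- function(powers) {
  if (length(powers) == 0L) stop("no voxels", call. = FALSE)
  rng <- range(powers)
  if (rng[1] == rng[2]) return(rep(0, length(powers)))
  (powers - rng[1]) / (rng[2] - rng[1])
}

#' Select high-power voxels at a percentile cutoff
#'
#' Keeps the top `ceil((100 - percentile)/100 * n)` voxels by power; ties at
#' the cutoff value are all included (so an all-equal input selects every
#' voxel).
#'
#' @param norm_powers Per-voxel (normalized) powers.
#' @param percentile Percent in (0, 100).
#' @return Integer indices of selected voxels.
#' @export
select_active_voxels <- function(norm_powers, percentile) {
  stopifnot(percentile > 0, percentile < 100)
  n <- length(norm_powers)
  if (n == 0L) return(integer(0))
  m <- max(1L, ceiling((100 - percentile) / 100 * n))
  cutoff <- sort(norm_powers, decreasing = TRUE)[m]
  which(norm_powers >= cutoff)
}

#' Pearson product-moment correlation with a zero-variance guard
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return Correlation in `[-1, 1]`; if either series has zero variance the
#'   correlation is undefined and 0 is returned with a warning.
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) {
    stop("series lengths differ (", length(x), " vs ", length(y), ")",
         call. = FALSE)
  }
  if (length(x) < 2L) stop("need at least 2 timepoints", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero-variance series; correlation set to 0", call. = FALSE)
    return(0)
  }
  stats::cor(x, y)
}

# Correlation matrix over rows of a node-by-time matrix; zero-variance rows
# give 0 (with one warning) instead of NA.
node_corr_matrix <- function(mean_series) {
  n <- nrow(mean_series)
  if (n == 1L) return(matrix(1, 1, 1))
  sds <- apply(mean_series, 1L, stats::sd)
  C <- suppressWarnings(stats::cor(t(mean_series)))
  if (any(sds == 0)) {
    warning("zero-variance node series; correlations set to 0", call. = FALSE)
    C[sds == 0, ] <- 0
    C[, sds == 0] <- 0
  }
  diag(C) <- 1
  C
}

# ---- graph construction -----------------------------------------------------

new_attributed_graph <- function(subject_id, nodes, coords, mean_series,
                                 corr, edges, corr_threshold) {
  g <- structure(list(subject_id = subject_id,
                      nodes = nodes,
                      coords = coords,
                      mean_series = mean_series,
                      corr = corr,
                      edges = edges,
                      corr_threshold = corr_threshold,
                      signatures = NULL),
                 class = "attributed_graph")
  g$signatures <- all_signatures(g)
  g
}

#' Build a subject's attributed connectivity graph
#'
#' Pipeline: (1) per-voxel power (mean squared amplitude), min-max
#' normalized over the in-mask voxels; (2) percentile selection of active
#' voxels, whole-brain by default or per-ROI with
#' `cfg$roiwise_selection`; (3) one node per ROI that received at least one
#' selected voxel (so node counts vary across subjects in whole-brain
#' mode); (4) node mean series = unweighted average of member voxel series;
#' (5) edges between node pairs whose mean-series Pearson correlation is
#' positive and at least `cfg$corr_threshold`; (6) per-node signatures.
#'
#' @param vs A `voxel_series` from [extract_voxel_series()].
#' @param atlas A `roi_atlas`; voxels with label 0 never enter a node.
#' @param cfg A [network_config()].
#' @param subject_id Identifier stored in the graph.
#' @return An `attributed_graph`.
#' @export
build_graph <- function(vs, atlas, cfg = network_config(), subject_id = "subject") {
  stopifnot(inherits(vs, "voxel_series"), inherits(atlas, "roi_atlas"))
  n <- nrow(vs$series)
  if (n == 0L) stop("empty network: no voxels", call. = FALSE)
  vox1 <- vs$coords_voxel + 1L
  labels <- atlas$data[vox1]
  norm_p <- normalize_powers(voxel_powers(vs$series))

  if (cfg$roiwise_selection) {
    sel <- integer(0)
    for (lab in atlas$labels) {
      in_roi <- which(labels == lab)
      if (length(in_roi) == 0L) next
      keep <- select_active_voxels(norm_p[in_roi], cfg$power_percentile)
      sel <- c(sel, in_roi[keep])
    }
  } else {
    sel <- select_active_voxels(norm_p, cfg$power_percentile)
  }
  sel <- sel[labels[sel] > 0]
  if (length(sel) == 0L) {
    stop("empty network: no selected voxel falls inside a labeled ROI",
         call. = FALSE)
  }

  roi <- sort(unique(labels[sel]))
  N <- length(roi)
  nt <- ncol(vs$series)
  mean_series <- matrix(0, N, nt)
  coords <- matrix(0, N, 3)
  power <- numeric(N)
  n_vox <- integer(N)
  for (k in seq_len(N)) {
    members <- sel[labels[sel] == roi[k]]
    mean_series[k, ] <- colMeans(vs$series[members, , drop = FALSE])
    coords[k, ] <- colMeans(vs$coords_world[members, , drop = FALSE])
    power[k] <- mean(norm_p[members])
    n_vox[k] <- length(members)
  }
  nodes <- data.frame(node_id = seq_len(N), roi_label = roi,
                      n_voxels = n_vox, power = power)
  C <- node_corr_matrix(mean_series)
  edges <- edges_from_corr(C, cfg$corr_threshold)
  new_attributed_graph(subject_id, nodes, coords, mean_series, C, edges,
                       cfg$corr_threshold)
}

edges_from_corr <- function(C, corr_threshold) {
  N <- nrow(C)
  th <- max(corr_threshold, 0)  # positive correlations only
  keep <- which(upper.tri(C) & C >= th, arr.ind = TRUE)
  data.frame(from = keep[, 1], to = keep[, 2],
             weight = C[keep])
}

#' Re-threshold a graph's edges at a new correlation threshold
#'
#' Node attributes and the stored node correlation matrix are unchanged;
#' edges and signatures are recomputed. Used by the threshold sweep to avoid
#' rebuilding graphs from voxel data for every `corrTh`.
#'
#' @param g An `attributed_graph` (must carry its correlation matrix).
#' @param corr_threshold New threshold in `[0, 1]`.
#' @return An `attributed_graph`.
#' @export
rethreshold_graph <- function(g, corr_threshold) {
  stopifnot(inherits(g, "attributed_graph"), !is.null(g$corr))
  new_attributed_graph(g$subject_id, g$nodes, g$coords, g$mean_series,
                       g$corr, edges_from_corr(g$corr, corr_threshold),
                       corr_threshold)
}

#' @export
print.attributed_graph <- function(x, ...) {
  cat(sprintf("<attributed_graph> '%s': %d nodes, %d edges (corrTh = %.2f)\n",
              x$subject_id, nrow(x$nodes), nrow(x$edges), x$corr_threshold))
  invisible(x)
}

# ---- signatures -------------------------------------------------------------

# Weighted degree of every node: sum of incident edge weights.
weighted_degrees <- function(g) {
  N <- nrow(g$nodes)
  deg <- numeric(N)
  if (nrow(g$edges) > 0L) {
    for (e in seq_len(nrow(g$edges))) {
      deg[g$edges$from[e]] <- deg[g$edges$from[e]] + g$edges$weight[e]
      deg[g$edges$to[e]] <- deg[g$edges$to[e]] + g$edges$weight[e]
    }
  }
  deg
}

neighbor_lists <- function(g) {
  N <- nrow(g$nodes)
  ngh <- rep(list(integer(0)), N)
  if (nrow(g$edges) > 0L) {
    for (e in seq_len(nrow(g$edges))) {
      i <- g$edges$from[e]; j <- g$edges$to[e]
      ngh[[i]] <- c(ngh[[i]], j)
      ngh[[j]] <- c(ngh[[j]], i)
    }
  }
  ngh
}

all_signatures <- function(g) {
  deg <- weighted_degrees(g)
  ngh <- neighbor_lists(g)
  lapply(seq_len(nrow(g$nodes)), function(i) {
    nb <- ngh[[i]]
    structure(list(degree = deg[i],
                   neighbor_degrees = sort(deg[nb], decreasing = TRUE),
                   power = g$nodes$power[i],
                   neighbor_powers = sort(g$nodes$power[nb], decreasing = TRUE),
                   coord = g$coords[i, ]),
              class = "node_signature")
  })
}

#' Signature of one node
#'
#' The signature is the attribute tuple used for node-to-node matching:
#' weighted degree (sum of incident edge weights), descending-sorted
#' neighbor degrees, node power, descending-sorted neighbor powers, and the
#' node's mean world coordinate in mm.
#'
#' @param g An `attributed_graph`.
#' @param node_id Node identifier (row in `g$nodes`).
#' @return A `node_signature`.
#' @export
compute_signature <- function(g, node_id) {
  stopifnot(inherits(g, "attributed_graph"))
  if (!node_id %in% g$nodes$node_id) {
    stop("unknown node: ", node_id, call. = FALSE)
  }
  g$signatures[[match(node_id, g$nodes$node_id)]]
}

# ---- direct construction (fixtures, baselines on arbitrary graphs) ----------

#' Build an attributed graph from a weighted adjacency matrix
#'
#' Mainly for constructing small test graphs and for running the baseline
#' features on arbitrary networks.
#'
#' @param W Symmetric nonnegative weight matrix (0 = no edge).
#' @param powers Per-node powers in `[0, 1]`.
#' @param coords N x 3 matrix of node world coordinates (mm).
#' @param roi_labels Optional integer labels (default `1:N`).
#' @param subject_id Identifier.
#' @param corr_threshold Threshold recorded on the graph (default the
#'   smallest positive weight, so all given edges survive).
#' @return An `attributed_graph`.
#' @export
graph_from_adjacency <- function(W, powers, coords, roi_labels = NULL,
                                 subject_id = "graph",
                                 corr_threshold = NULL) {
  N <- nrow(W)
  stopifnot(ncol(W) == N, length(powers) == N, nrow(coords) == N,
            max(abs(W - t(W))) < 1e-12, all(diag(W) == 0))
  if (is.null(roi_labels)) roi_labels <- seq_len(N)
  if (is.null(corr_threshold)) {
    pos <- W[W > 0]
    corr_threshold <- if (length(pos)) min(pos) else 0
  }
  keep <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  edges <- data.frame(from = keep[, 1], to = keep[, 2], weight = W[keep])
  nodes <- data.frame(node_id = seq_len(N), roi_label = roi_labels,
                      n_voxels = 1L, power = powers)
  new_attributed_graph(subject_id, nodes, coords, NULL, NULL, edges,
                       corr_threshold)
}

# ---- serialization ----------------------------------------------------------

GRAPH_SCHEMA_VERSION <- "1.0"

#' Write an attributed graph as a JSON document
#' @param g An `attributed_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graph_json <- function(g, path) {
  doc <- list(schema_version = GRAPH_SCHEMA_VERSION,
              subject_id = g$subject_id,
              corr_threshold = g$corr_threshold,
              nodes = data.frame(g$nodes,
                                 x = g$coords[, 1], y = g$coords[, 2],
                                 z = g$coords[, 3]),
              edges = g$edges)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an attributed graph from JSON
#' @param path Path written by [write_graph_json()].
#' @return An `attributed_graph` (without voxel-level or correlation data).
#' @export
read_graph_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- doc$nodes
  coords <- as.matrix(nodes[, c("x", "y", "z")])
  dimnames(coords) <- NULL
  edges <- if (length(doc$edges)) {
    data.frame(from = as.integer(doc$edges$from),
               to = as.integer(doc$edges$to),
               weight = as.numeric(doc$edges$weight))
  } else {
    data.frame(from = integer(0), to = integer(0), weight = numeric(0))
  }
  new_attributed_graph(doc$subject_id,
                       data.frame(node_id = as.integer(nodes$node_id),
                                  roi_label = as.integer(nodes$roi_label),
                                  n_voxels = as.integer(nodes$n_voxels),
                                  power = as.numeric(nodes$power)),
                       coords, NULL, NULL, edges,
                       as.numeric(doc$corr_threshold))
}

#' Export a graph's edge list as 3-column TSV
#' @param g An `attributed_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_tsv <- function(g, path) {
  utils::write.table(g$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
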