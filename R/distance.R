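# Assignment-based distance between attributed graphs.
#
# A node pair's distance is a weighted sum of five normalized components:
# d1 |degree difference| / max training degree, d2 sorted-neighbor-degree
# profile distance, d3 |power difference| / max training power, d4
# sorted-neighbor-power profile distance, d5 a sigmoid of the Euclidean
# distance between node coordinates. The graph distance is the minimum-cost
# injective assignment of the smaller graph's nodes onto the larger's
# (Munkres algorithm); the optimal total cost is the distance.

#' Signature component weights
#'
#' Order: node degree, neighbor degrees, node power, neighbor powers,
#' spatial. The spatial term carries the largest weight so that nodes far
#' apart in the brain are discouraged from matching; node-level terms weigh
#' more than neighborhood profiles.
#'
#' @return Named numeric vector of length 5 summing to 1.
#' @export
signature_weights <- function() {
  c(degree = 0.2, neighbor_degrees = 0.1, power = 0.2,
    neighbor_powers = 0.1, spatial = 0.4)
}

#' Distance configuration
#'
#' @param weights 5-vector of nonnegative component weights
#'   (default [signature_weights()]).
#' @param sigmoid_scale,sigmoid_decay Constants of the spatial sigmoid
#'   `1 / (1 + scale * exp(-dist/decay))` (defaults 300 and 4 mm).
#' @param printed_sigmoid Use the decreasing variant
#'   `1 / (1 + scale * exp(+dist/decay))` instead of the increasing one.
#'   Only useful for archaeology; the increasing form is the one matching
#'   the method's description (spatially distant nodes should be expensive
#'   to match).
#' @param normalize_by_size Divide the total assignment cost by the smaller
#'   node count. Off by default: the raw assignment cost is the distance.
#' @return A `distance_config` list.
#' @export
distance_config <- function(weights = signature_weights(),
                            sigmoid_scale = 300, sigmoid_decay = 4,
                            printed_sigmoid = FALSE,
                            normalize_by_size = FALSE) {
  stopifnot(length(weights) == 5L, all(weights >= 0),
            sigmoid_scale > 0, sigmoid_decay > 0)
  structure(list(weights = unname(weights),
                 sigmoid_scale = sigmoid_scale,
                 sigmoid_decay = sigmoid_decay,
                 printed_sigmoid = isTRUE(printed_sigmoid),
                 normalize_by_size = isTRUE(normalize_by_size)),
            class = "distance_config")
}

#' Normalization constants from a training set of graphs
#'
#' The maximum weighted degree and maximum node power over every node of
#' every training graph; they normalize the degree and power components of
#' the node distance to `[0, 1]`. Test-set values exceeding a maximum are
#' clamped downstream so components stay at most 1.
#'
#' @param graphs List of `attributed_graph`s (>= 1, each with >= 1 node).
#' @return A `normalization_constants` list with `max_degree`, `max_power`.
#' @export
training_constants <- function(graphs) {
  stopifnot(length(graphs) >= 1L)
  degs <- unlist(lapply(graphs, function(g)
    vapply(g$signatures, `[[`, numeric(1), "degree")))
  pows <- unlist(lapply(graphs, function(g) g$nodes$power))
  if (length(degs) == 0L) stop("no nodes in training graphs", call. = FALSE)
  max_degree <- max(degs)
  max_power <- max(pows)
  if (max_degree <= 0 && max_power <= 0) {
    stop("degenerate training set: all degrees and powers are zero",
         call. = FALSE)
  }
  if (max_degree <= 0) {
    warning("all training degrees are zero; max_degree guarded to 1",
            call. = FALSE)
    max_degree <- 1
  }
  if (max_power <= 0) {
    warning("all training powers are zero; max_power guarded to 1",
            call. = FALSE)
    max_power <- 1
  }
  structure(list(max_degree = max_degree, max_power = max_power),
            class = "normalization_constants")
}

#' Spatial distance component (sigmoid of inter-node distance)
#'
#' `d5 = 1 / (1 + scale * exp(-||c1 - c2|| / decay))`: near zero for
#' coincident nodes (1/301 at distance 0 with defaults), strictly
#' increasing with distance, approaching 1 for distant nodes.
#'
#' @param c1,c2 mm coordinate triples.
#' @param cfg A [distance_config()].
#' @return Value in `(0, 1)`.
#' @export
spatial_component <- function(c1, c2, cfg = distance_config()) {
  d <- sqrt(sum((c1 - c2)^2))
  s <- if (cfg$printed_sigmoid) 1 else -1
  1 / (1 + cfg$sigmoid_scale * exp(s * d / cfg$sigmoid_decay))
}

#' Distance between two descending-sorted attribute profiles
#'
#' The shorter profile is zero-padded at the end to the longer's length L;
#' the distance is the sum of absolute elementwise differences divided by
#' `max_val * L` (clamped to `[0, 1]`). Two empty profiles have distance 0.
#'
#' @param a1,a2 Descending-sorted numeric vectors (possibly empty).
#' @param max_val Positive normalizer (maximum attribute over training).
#' @return Value in `[0, 1]`.
#' @export
profile_distance <- function(a1, a2, max_val) {
  stopifnot(max_val > 0)
  L <- max(length(a1), length(a2))
  if (L == 0L) return(0)
  p1 <- c(a1, rep(0, L - length(a1)))
  p2 <- c(a2, rep(0, L - length(a2)))
  min(sum(abs(p1 - p2)) / (max_val * L), 1)
}

#' Distance between two node signatures
#'
#' Weighted sum of the five normalized components (each clamped to
#' `[0, 1]`).
#'
#' @param s1,s2 `node_signature`s.
#' @param nc [training_constants()] of the training set.
#' @param cfg A [distance_config()].
#' @return Cost in `[0, sum(weights)]`.
#' @export
node_distance <- function(s1, s2, nc, cfg = distance_config()) {
  w <- cfg$weights
  d1 <- min(abs(s1$degree - s2$degree) / nc$max_degree, 1)
  d2 <- profile_distance(s1$neighbor_degrees, s2$neighbor_degrees, nc$max_degree)
  d3 <- min(abs(s1$power - s2$power) / nc$max_power, 1)
  d4 <- profile_distance(s1$neighbor_powers, s2$neighbor_powers, nc$max_power)
  d5 <- spatial_component(s1$coord, s2$coord, cfg)
  w[1] * d1 + w[2] * d2 + w[3] * d3 + w[4] * d4 + w[5] * d5
}

#' Node-to-node cost matrix for a graph pair
#'
#' Rows are indexed by the graph with fewer nodes (ties favor `g1`);
#' columns by the other. Entry (i, j) is [node_distance()] of the i-th row
#' node and j-th column node.
#'
#' @param g1,g2 Nonempty `attributed_graph`s.
#' @param nc [training_constants()].
#' @param cfg A [distance_config()].
#' @return Matrix with attribute `row_graph` (1 or 2).
#' @export
node_cost_matrix <- function(g1, g2, nc, cfg = distance_config()) {
  n1 <- nrow(g1$nodes); n2 <- nrow(g2$nodes)
  if (n1 == 0L || n2 == 0L) stop("empty graph", call. = FALSE)
  if (n1 <= n2) { gr <- g1; gc <- g2; row_graph <- 1L }
  else { gr <- g2; gc <- g1; row_graph <- 2L }
  nr <- nrow(gr$nodes); nc_ <- nrow(gc$nodes)
  cost <- matrix(0, nr, nc_)
  for (i in seq_len(nr)) {
    si <- gr$signatures[[i]]
    for (j in seq_len(nc_)) {
      cost[i, j] <- node_distance(si, gc$signatures[[j]], nc, cfg)
    }
  }
  attr(cost, "row_graph") <- row_graph
  cost
}

#' Minimum-cost assignment of rows to columns (Munkres)
#'
#' Solves the rectangular linear assignment problem for a cost matrix with
#' `rows <= cols`: every row is matched to a distinct column so that the
#' total cost is minimized; unmatched columns contribute nothing.
#' Implemented with the O(n^2 m) shortest-augmenting-path form of the
#' Hungarian method (dual potentials).
#'
#' @param cost Numeric matrix, `nrow(cost) <= ncol(cost)`.
#' @return List with `total_cost` and `assignment` (matrix with columns
#'   `row`, `col`, one row per matched pair, ordered by row).
#' @export
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost); m <- ncol(cost)
  if (n > m) stop("cost matrix must have rows <= cols", call. = FALSE)
  if (n == 0L) stop("empty cost matrix", call. = FALSE)
  u <- numeric(n + 1L)       # row potentials (index i+1)
  v <- numeric(m + 1L)       # column potentials (index j+1; j = 0 virtual)
  p <- integer(m + 1L)       # p[j+1]: row matched to column j (0 = free)
  way <- integer(m + 1L)     # predecessor column on the alternating path
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, m)
    used <- rep(FALSE, m + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(m)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j]) { minv[j] <- cur; way[j + 1L] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in 0:m) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  rows <- p[-1L]
  sel <- which(rows > 0L)
  assignment <- cbind(row = rows[sel], col = sel)
  assignment <- assignment[order(assignment[, 1L]), , drop = FALSE]
  list(total_cost = sum(cost[assignment]), assignment = assignment)
}

#' Distance between two attributed graphs
#'
#' The minimum total cost of assigning every node of the smaller graph to a
#' distinct node of the larger one, with node-pair costs from
#' [node_distance()]. Symmetric by construction.
#'
#' @inheritParams node_cost_matrix
#' @return Nonnegative scalar.
#' @export
graph_distance <- function(g1, g2, nc, cfg = distance_config()) {
  cost <- node_cost_matrix(g1, g2, nc, cfg)
  total <- solve_assignment(cost)$total_cost
  if (cfg$normalize_by_size) total <- total / nrow(cost)
  total
}

#' Pairwise graph distance matrix
#'
#' Full symmetric matrix of [graph_distance()] over all graph pairs. The
#' diagonal is set to 0 by convention: metric MDS requires zero
#' self-dissimilarity, whereas the raw self-assignment cost of an N-node
#' graph is N times the zero-distance spatial sigmoid (reported via the
#' `raw_self_cost` attribute).
#'
#' @param graphs List of >= 2 `attributed_graph`s.
#' @param nc [training_constants()].
#' @param cfg A [distance_config()].
#' @return Symmetric matrix with subject ids as dimnames.
#' @export
pairwise_distances <- function(graphs, nc, cfg = distance_config()) {
  n <- length(graphs)
  stopifnot(n >= 2L)
  ids <- vapply(graphs, `[[`, character(1), "subject_id")
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      D[i, j] <- D[j, i] <- graph_distance(graphs[[i]], graphs[[j]], nc, cfg)
    }
  }
  attr(D, "raw_self_cost") <- vapply(graphs, function(g)
    graph_distance(g, g, nc, cfg), numeric(1))
  D
}

# ---- serialization ----------------------------------------------------------

#' Write a distance matrix as square TSV with a JSON provenance sidecar
#'
#' @param D Symmetric matrix with subject-id dimnames.
#' @param path Output TSV path; `<path>.json` records weights and constants.
#' @param nc,cfg Optional provenance ([training_constants()],
#'   [distance_config()]).
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(D, path, nc = NULL, cfg = NULL) {
  utils::write.table(as.data.frame(D), path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  meta <- list(n_subjects = nrow(D))
  if (!is.null(nc)) meta$normalization <- unclass(nc)
  if (!is.null(cfg)) meta$distance_config <- unclass(cfg)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a distance matrix written by [write_distance_matrix()]
#' @param path TSV path.
#' @return Symmetric numeric matrix with subject-id dimnames.
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE)
  as.matrix(df)
}
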