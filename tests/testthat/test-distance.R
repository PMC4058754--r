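test_that("training constants are maxima over all training nodes", {
  W1 <- matrix(0, 2, 2); W1[1, 2] <- W1[2, 1] <- 0.4
  g1 <- tg(W1, powers = c(0.3, 0.7))
  W2 <- matrix(0, 3, 3); W2[1, 2] <- W2[2, 1] <- 0.8; W2[2, 3] <- W2[3, 2] <- 0.4
  g2 <- tg(W2, powers = c(0.1, 0.9, 0.5))
  nc <- training_constants(list(g1, g2))
  expect_equal(nc$max_degree, 1.2)
  expect_equal(nc$max_power, 0.9)

  # edgeless training graph: degree maximum is guarded
  g0 <- tg(matrix(0, 1, 1), powers = 0.3)
  expect_warning(nc0 <- training_constants(list(g0)), "guarded")
  expect_equal(nc0$max_degree, 1)
  expect_equal(nc0$max_power, 0.3)

  gz <- tg(matrix(0, 1, 1), powers = 0)
  expect_error(training_constants(list(gz)), "degenerate")
})

test_that("the spatial sigmoid has its closed-form values and is increasing", {
  expect_equal(spatial_component(c(1, 2, 3), c(1, 2, 3)), 1 / 301)
  expect_equal(spatial_component(c(0, 0, 0), c(4 * log(300), 0, 0)), 0.5)
  expect_equal(spatial_component(c(0, 0, 0), c(1e6, 0, 0)), 1)
  d5 <- sapply(seq(0, 100, by = 0.5),
               function(d) spatial_component(c(0, 0, 0), c(d, 0, 0)))
  expect_true(all(diff(d5) > 0))   # strictly increasing in distance
  # the printed (uncorrected) variant decreases instead
  cfg_p <- distance_config(printed_sigmoid = TRUE)
  d5p <- sapply(c(0, 10, 50),
                function(d) spatial_component(c(0, 0, 0), c(d, 0, 0), cfg_p))
  expect_true(all(diff(d5p) < 0))
})

test_that("profile distance pads with zeros and normalizes by padded length", {
  expect_equal(profile_distance(c(3, 2, 1), c(3, 2, 1), 5), 0)
  expect_equal(profile_distance(c(2, 1), numeric(0), 2), 0.75)
  expect_equal(profile_distance(5, 0, 5), 1)
  expect_equal(profile_distance(numeric(0), numeric(0), 2), 0)
})

test_that("node distance weights its five components", {
  g <- complete_graph(3, w = 0.5)
  nc <- training_constants(list(g))
  s <- g$signatures[[1]]
  expect_equal(node_distance(s, s, nc), 0.4 / 301)

  # components d1..d4 at 1 with coincident coordinates: 0.6 + 0.4/301
  s1 <- structure(list(degree = 0, neighbor_degrees = numeric(0),
                       power = 0, neighbor_powers = numeric(0),
                       coord = c(0, 0, 0)), class = "node_signature")
  s2 <- structure(list(degree = 1, neighbor_degrees = 1,
                       power = 1, neighbor_powers = 1,
                       coord = c(0, 0, 0)), class = "node_signature")
  nc1 <- structure(list(max_degree = 1, max_power = 1),
                   class = "normalization_constants")
  expect_equal(node_distance(s1, s2, nc1), 0.6 + 0.4 / 301)

  # out-of-training degree/power are clamped, so the cost stays bounded
  s_big <- structure(list(degree = 50, neighbor_degrees = c(50, 50),
                          power = 1, neighbor_powers = c(1, 1),
                          coord = c(1e4, 0, 0)), class = "node_signature")
  expect_lte(node_distance(s1, s_big, nc1), 1)
})

test_that("cost matrices are oriented smaller-by-larger", {
  tp <- toy_graph_pair()
  cm <- node_cost_matrix(tp$g1, tp$g2, tp$nc)
  expect_equal(dim(cm), c(3, 4))
  cm_swapped <- node_cost_matrix(tp$g2, tp$g1, tp$nc)
  expect_equal(dim(cm_swapped), c(3, 4))
  expect_equal(attr(cm, "row_graph"), 1)
  expect_equal(attr(cm_swapped, "row_graph"), 2)

  g <- complete_graph(3)
  nc <- training_constants(list(g))
  self_cm <- node_cost_matrix(g, g, nc)
  expect_equal(diag(self_cm), rep(0.4 / 301, 3))
})

test_that("the toy pair's cost matrix matches its embedded arithmetic oracle", {
  tp <- toy_graph_pair()
  cm <- node_cost_matrix(tp$g1, tp$g2, tp$nc, tp$cfg)
  expect_equal(unclass(cm)[, ], tp$expected_cost_matrix, tolerance = 1e-12,
               ignore_attr = TRUE)
  res <- solve_assignment(cm)
  expect_equal(res$total_cost, brute_force_assignment(tp$expected_cost_matrix))
})

test_that("solve_assignment finds the optimum on hand-checkable matrices", {
  r <- solve_assignment(matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE))
  expect_equal(r$total_cost, 0)
  expect_equal(r$assignment[, "col"], c(1, 2))

  r2 <- solve_assignment(matrix(c(4, 1, 2, 3), 2, 2, byrow = TRUE))
  expect_equal(r2$total_cost, 3)   # 1 -> col 2, 2 -> col 1
  expect_equal(r2$assignment[, "col"], c(2, 1))

  r3 <- solve_assignment(matrix(c(1, 2, 3), 1, 3))
  expect_equal(r3$total_cost, 1)
  expect_equal(nrow(r3$assignment), 1)

  expect_error(solve_assignment(matrix(0, 3, 2)), "rows <= cols")
})

test_that("assignments are injective and match brute force on random matrices", {
  set.seed(11)
  for (rep in 1:60) {
    n <- sample(1:6, 1)
    mm <- n:6
    m <- mm[sample.int(length(mm), 1)]
    cost <- matrix(runif(n * m), n, m)
    res <- solve_assignment(cost)
    expect_equal(res$total_cost, brute_force_assignment(cost),
                 tolerance = 1e-12)
    expect_equal(anyDuplicated(res$assignment[, "col"]), 0)
    expect_equal(nrow(res$assignment), n)
  }
})

test_that("self-distance is N times the zero-distance sigmoid", {
  set.seed(3)
  for (n in c(2, 4, 6)) {
    g <- random_graph(n)
    # a small random graph may be edgeless; the guarded normalizer warns
    nc <- suppressWarnings(training_constants(list(g)))
    cm <- node_cost_matrix(g, g, nc)
    expect_equal(graph_distance(g, g, nc), n * 0.4 / 301)
    expect_equal(brute_force_assignment(cm), n * 0.4 / 301)
  }
})

test_that("graph distance is symmetric and bounded", {
  set.seed(21)
  gs <- lapply(1:4, function(i) random_graph(sample(2:6, 1), id = paste0("s", i)))
  nc <- training_constants(gs)
  for (i in 1:3) {
    for (j in (i + 1):4) {
      dij <- graph_distance(gs[[i]], gs[[j]], nc)
      dji <- graph_distance(gs[[j]], gs[[i]], nc)
      expect_equal(dij, dji)
      nmin <- min(nrow(gs[[i]]$nodes), nrow(gs[[j]]$nodes))
      expect_lte(dij, nmin * 1.0)  # sum of weights = 1
      expect_gte(dij, 0)
    }
  }
})

test_that("distances are legal across differing series lengths", {
  # signatures are length-free: only degrees, powers, coords enter
  fxa <- complete_graph(3)
  fxb <- complete_graph(4)
  fxb$mean_series <- matrix(rnorm(4 * 99), 4)   # pretend other site length
  nc <- training_constants(list(fxa, fxb))
  expect_gte(graph_distance(fxa, fxb, nc), 0)
})

test_that("the pairwise matrix is symmetric, zero-diagonal and consistent", {
  set.seed(31)
  gs <- lapply(1:5, function(i) random_graph(sample(3:6, 1), id = paste0("s", i)))
  nc <- training_constants(gs)
  D <- pairwise_distances(gs, nc)
  expect_equal(D, t(D))
  expect_equal(diag(D), setNames(rep(0, 5), rownames(D)))
  expect_equal(D[2, 4], graph_distance(gs[[2]], gs[[4]], nc))
  expect_equal(D[1, 5], graph_distance(gs[[5]], gs[[1]], nc))
  # identical graphs are equidistant from each other
  g <- random_graph(4)
  D3 <- pairwise_distances(list(g, g, g), nc)
  off <- D3[upper.tri(D3)]
  expect_equal(off, rep(off[1], 3))
  # the raw self-cost is recorded alongside the zeroed diagonal
  expect_equal(attr(D, "raw_self_cost"),
               vapply(gs, function(g) nrow(g$nodes) * 0.4 / 301, numeric(1)))
})

test_that("distance matrices round-trip through TSV", {
  set.seed(41)
  gs <- lapply(1:3, function(i) random_graph(4, id = paste0("sub", i)))
  nc <- training_constants(gs)
  D <- pairwise_distances(gs, nc)
  path <- tempfile(fileext = ".tsv")
  write_distance_matrix(D, path, nc = nc, cfg = distance_config())
  D2 <- read_distance_matrix(path)
  expect_equal(unclass(D2), unclass(D)[, ], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(rownames(D2), c("sub1", "sub2", "sub3"))
  expect_true(file.exists(paste0(path, ".json")))
})
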