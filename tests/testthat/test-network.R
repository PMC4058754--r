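test_that("voxel power is the mean squared amplitude", {
  expect_equal(voxel_power(c(0, 0, 0)), 0)
  expect_equal(voxel_power(c(1, 1, 1, 1)), 1)
  expect_equal(voxel_power(c(1, 2, 3)), 14 / 3)
  expect_error(voxel_power(numeric(0)), "empty")
})

test_that("power normalization is min-max with a degenerate convention", {
  expect_equal(normalize_powers(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(normalize_powers(c(5, 5, 5)), c(0, 0, 0))
  expect_equal(normalize_powers(c(0, 1)), c(0, 1))
})

test_that("percentile selection keeps the top tail with ties included", {
  p <- sample(seq(0.001, 1, length.out = 100))   # 100 distinct powers
  sel <- select_active_voxels(p, 98)
  expect_length(sel, 2)
  expect_setequal(sel, order(p, decreasing = TRUE)[1:2])
  # near-zero percentile keeps everything
  expect_length(select_active_voxels(p, 1e-6), 100)
  # all-equal powers: every voxel ties at the cutoff
  expect_length(select_active_voxels(rep(0.4, 50), 98), 50)
})

test_that("pearson_corr matches hand values and guards zero variance", {
  expect_equal(pearson_corr(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(pearson_corr(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(pearson_corr(c(1, 2, 3), c(1, 2, 4)), 9 / sqrt(84))
  expect_warning(r <- pearson_corr(c(1, 1, 1), c(1, 2, 3)), "zero-variance")
  expect_equal(r, 0)
  expect_error(pearson_corr(1:3, 1:4), "lengths differ")
})

# Two-ROI fixture: each ROI has voxels sharing one latent series.
two_roi_fixture <- function(r_latent = NULL, nt = 40, amp = 5) {
  set.seed(99)
  atlas_data <- array(0L, c(4, 4, 1))
  atlas_data[1:2, 1:2, 1] <- 1L
  atlas_data[3:4, 3:4, 1] <- 2L
  atlas <- agnet:::new_roi_atlas(atlas_data, diag(4))
  lat <- if (is.null(r_latent)) {
    z <- rnorm(nt)
    list(z, z + rnorm(nt, sd = 0.01))  # near-identical latents
  } else {
    r_latent
  }
  n <- 16
  series <- matrix(rnorm(n * nt, sd = 0.2), n, nt)
  idx <- which(atlas_data > 0, arr.ind = FALSE)
  coords <- which(array(TRUE, c(4, 4, 1)), arr.ind = TRUE) - 1L
  for (i in seq_len(n)) {
    lin <- i
    lab <- atlas_data[lin]
    if (lab > 0) series[i, ] <- series[i, ] + amp * lat[[lab]]
  }
  vs <- structure(list(coords_voxel = coords,
                       coords_world = coords,
                       series = series),
                  class = "voxel_series")
  list(vs = vs, atlas = atlas)
}

test_that("build_graph clusters selected voxels by ROI and thresholds edges", {
  fx <- two_roi_fixture()
  g <- build_graph(fx$vs, fx$atlas,
                   network_config(power_percentile = 60, corr_threshold = 0.3))
  expect_equal(nrow(g$nodes), 2)
  expect_equal(nrow(g$edges), 1)
  expect_gt(g$edges$weight[1], 0.95)
  expect_s3_class(g, "attributed_graph")

  # no node pair reaches an extreme threshold: nodes kept, no edges
  g2 <- build_graph(fx$vs, fx$atlas,
                    network_config(power_percentile = 60, corr_threshold = 1))
  expect_equal(nrow(g2$nodes), 2)
  expect_equal(nrow(g2$edges), 0)
  expect_length(g2$signatures[[1]]$neighbor_degrees, 0)
  expect_length(g2$signatures[[1]]$neighbor_powers, 0)
})

test_that("graph construction is invariant to voxel input order", {
  fx <- two_roi_fixture()
  cfg <- network_config(power_percentile = 60, corr_threshold = 0.3)
  g <- build_graph(fx$vs, fx$atlas, cfg)
  perm <- sample(nrow(fx$vs$series))
  vs2 <- structure(list(coords_voxel = fx$vs$coords_voxel[perm, ],
                        coords_world = fx$vs$coords_world[perm, ],
                        series = fx$vs$series[perm, ]),
                   class = "voxel_series")
  g2 <- build_graph(vs2, fx$atlas, cfg)
  expect_equal(g2$nodes, g$nodes)
  expect_equal(g2$edges, g$edges)
  expect_equal(g2$coords, g$coords)
})

test_that("empty selection fails loudly", {
  fx <- two_roi_fixture()
  # atlas with a single labeled voxel, which we force to the lowest power:
  # the one selected voxel is then background
  a <- array(0L, c(4, 4, 1))
  a[1, 1, 1] <- 1L
  bare <- agnet:::new_roi_atlas(a, diag(4))
  vs <- fx$vs
  vs$series[1, ] <- 0  # the only labeled voxel has zero power
  expect_error(
    build_graph(vs, bare, network_config(power_percentile = 98)),
    "empty network")
})

test_that("signatures carry weighted degree and sorted neighbor profiles", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.5
  W[2, 3] <- W[3, 2] <- 0.7
  g <- tg(W)
  s2 <- compute_signature(g, 2)
  expect_equal(s2$degree, 1.2)
  expect_equal(s2$neighbor_degrees, c(0.7, 0.5))   # sorted descending
  s1 <- compute_signature(g, 1)
  expect_equal(s1$degree, 0.5)
  expect_equal(s1$neighbor_degrees, 1.2)
  expect_error(compute_signature(g, 99), "unknown node")

  # isolated node
  g0 <- tg(matrix(0, 2, 2))
  expect_equal(compute_signature(g0, 1)$degree, 0)
  expect_length(compute_signature(g0, 1)$neighbor_powers, 0)

  # triangle with equal weights: every neighbor-degree list is [2w, 2w]
  gt <- complete_graph(3, w = 0.6)
  for (i in 1:3) {
    expect_equal(compute_signature(gt, i)$neighbor_degrees, c(1.2, 1.2))
  }
})

test_that("degree sum equals twice the edge weight sum", {
  set.seed(5)
  for (rep in 1:10) {
    g <- random_graph(sample(2:8, 1))
    degs <- vapply(g$signatures, `[[`, numeric(1), "degree")
    expect_equal(sum(degs), 2 * sum(g$edges$weight))
  }
})

test_that("edge weights never fall below the threshold and are symmetric", {
  fx <- two_roi_fixture(r_latent = list(rnorm(40), rnorm(40)))
  for (th in c(0.3, 0.6, 0.9)) {
    g <- build_graph(fx$vs, fx$atlas,
                     network_config(power_percentile = 50, corr_threshold = th))
    if (nrow(g$edges) > 0) expect_true(all(g$edges$weight >= th))
    expect_equal(g$corr, t(g$corr))
  }
})

test_that("per-ROI selection yields a node for every populated ROI", {
  fx <- two_roi_fixture()
  # whole-brain at 98: only the very top voxels survive; per-ROI keeps both
  g_roi <- build_graph(fx$vs, fx$atlas,
                       network_config(power_percentile = 98,
                                      roiwise_selection = TRUE))
  expect_equal(nrow(g_roi$nodes), 2)
  expect_equal(g_roi$nodes$roi_label, 1:2)
})

test_that("rethresholding matches building at the new threshold", {
  fx <- two_roi_fixture(r_latent = list(rnorm(40), rnorm(40)))
  g0 <- build_graph(fx$vs, fx$atlas,
                    network_config(power_percentile = 50, corr_threshold = 0))
  g_re <- rethreshold_graph(g0, 0.4)
  g_direct <- build_graph(fx$vs, fx$atlas,
                          network_config(power_percentile = 50,
                                         corr_threshold = 0.4))
  expect_equal(g_re$edges, g_direct$edges)
  expect_equal(g_re$signatures, g_direct$signatures)
})

test_that("graph JSON round-trip preserves structure", {
  g <- random_graph(5, id = "subjX")
  path <- tempfile(fileext = ".json")
  write_graph_json(g, path)
  g2 <- read_graph_json(path)
  expect_equal(g2$subject_id, "subjX")
  expect_equal(g2$nodes$power, g$nodes$power)
  expect_equal(g2$edges$weight, g$edges$weight)
  expect_equal(g2$coords, g$coords)
  expect_equal(g2$signatures, g$signatures)
})
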