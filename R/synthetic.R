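# Synthetic cohort generator. Emulates the statistical structure the
# pipeline assumes: a labeled atlas of compact ROIs on a small 3D grid,
# per-ROI latent BOLD-like series with group-dependent correlation
# structure, a minority of high-power "active" voxels riding on those
# latents (so the percentile power selection is exercised), and low-power
# noise voxels elsewhere in the mask.

#' Synthetic cohort configuration
#'
#' Defaults describe the standard validation cohort: a 12x12x12 grid at
#' 4 mm, 8 ROIs of 20 voxels, 120 timepoints, 20 subjects per group, and a
#' planted between-group drop of 0.6 in the latent correlation of coupled
#' ROI pairs.
#'
#' @param grid_shape 3D voxel grid (default `c(12, 12, 12)`).
#' @param n_rois Number of ROIs (default 8).
#' @param voxels_per_roi Voxels per ROI (default 20).
#' @param n_timepoints Series length (default 120).
#' @param n_per_group Training subjects per class (default 20).
#' @param n_test_per_group Test subjects per class (default 0).
#' @param effect_size Between-group difference in the latent correlation of
#'   coupled ROI pairs, in `[0, 1]`; 0 plants no signal (default 0.6).
#' @param active_fraction Fraction of each ROI's voxels given high-power
#'   latents (default 0.1, i.e. 2 of 20).
#' @param noise_sd Voxel noise standard deviation (default 0.5).
#' @param active_amplitude Scale of the latent in active voxels (default 3;
#'   active-voxel power then dominates noise power by more than an order of
#'   magnitude, so percentile selection is near-deterministic).
#' @param baseline_corr Latent correlation between non-coupled ROI pairs
#'   (default 0.15).
#' @param coupled_corr Latent correlation of coupled pairs in the control
#'   group (default 0.8).
#' @param sex_effect Extra correlation drop applied to male cases (default
#'   0; set > 0 to give the sex-stratified protocol something to find).
#' @param dilate Chebyshev radius of the unlabeled in-mask margin around
#'   the ROIs (default 2).
#' @param voxel_size Voxel edge in mm (default 4).
#' @param seed RNG seed; all randomness funnels through it.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(grid_shape = c(12, 12, 12), n_rois = 8,
                          voxels_per_roi = 20, n_timepoints = 120,
                          n_per_group = 20, n_test_per_group = 0,
                          effect_size = 0.6, active_fraction = 0.1,
                          noise_sd = 0.5, active_amplitude = 3,
                          baseline_corr = 0.15, coupled_corr = 0.8,
                          sex_effect = 0, dilate = 2, voxel_size = 4,
                          seed = 1) {
  stopifnot(length(grid_shape) == 3L, n_rois >= 1, voxels_per_roi >= 1,
            n_timepoints >= 2, n_per_group >= 1,
            effect_size >= 0, effect_size <= 1,
            active_fraction > 0, active_fraction <= 1, noise_sd >= 0)
  structure(as.list(environment()), class = "cohort_config")
}

#' Build the synthetic atlas and brain mask
#'
#' Places `n_rois` spatially compact, disjoint labeled blobs on the grid
#' (nearest unclaimed voxels around lattice-cell centers) and defines the
#' mask as the labeled voxels plus a dilated margin of unlabeled in-mask
#' voxels. Deterministic (no RNG).
#'
#' @param cfg A [cohort_config()].
#' @return List with `atlas` (`roi_atlas`) and `mask` (`brain_mask`).
#' @export
make_atlas <- function(cfg = cohort_config()) {
  gs <- cfg$grid_shape
  if (cfg$n_rois * cfg$voxels_per_roi > prod(gs)) {
    stop("ROIs do not fit in the grid", call. = FALSE)
  }
  affine <- diag(c(rep(cfg$voxel_size, 3), 1))
  # lattice of ROI centers
  nside <- ceiling(cfg$n_rois^(1 / 3))
  cell <- gs / nside
  centers <- as.matrix(expand.grid(x = seq_len(nside), y = seq_len(nside),
                                   z = seq_len(nside)))
  centers <- (centers - 0.5) * matrix(cell, nrow(centers), 3, byrow = TRUE)
  centers <- centers[seq_len(cfg$n_rois), , drop = FALSE]

  vox <- as.matrix(expand.grid(x = seq_len(gs[1]), y = seq_len(gs[2]),
                               z = seq_len(gs[3]))) - 0.5
  labels <- array(0L, gs)
  taken <- rep(FALSE, nrow(vox))
  for (r in seq_len(cfg$n_rois)) {
    d2 <- rowSums((vox - matrix(centers[r, ], nrow(vox), 3, byrow = TRUE))^2)
    ord <- order(d2, seq_along(d2))
    pick <- ord[!taken[ord]][seq_len(cfg$voxels_per_roi)]
    taken[pick] <- TRUE
    labels[pick] <- r
  }
  # mask: labeled voxels plus a Chebyshev-dilated margin
  inmask <- labels > 0
  if (cfg$dilate > 0) {
    lab <- labels > 0
    for (dx in -cfg$dilate:cfg$dilate)
      for (dy in -cfg$dilate:cfg$dilate)
        for (dz in -cfg$dilate:cfg$dilate) {
          if (dx == 0 && dy == 0 && dz == 0) next
          sx <- pmin(pmax(seq_len(gs[1]) + dx, 1L), gs[1])
          sy <- pmin(pmax(seq_len(gs[2]) + dy, 1L), gs[2])
          sz <- pmin(pmax(seq_len(gs[3]) + dz, 1L), gs[3])
          inmask <- inmask | lab[sx, sy, sz]
        }
  }
  list(atlas = new_roi_atlas(labels, affine),
       mask = new_brain_mask(inmask * 1L, affine))
}

coupled_pairs <- function(n_rois) {
  np <- floor(n_rois / 2)
  cbind(2 * seq_len(np) - 1, 2 * seq_len(np))
}

latent_sigma <- function(cfg, shift) {
  R <- cfg$n_rois
  S <- matrix(cfg$baseline_corr, R, R)
  diag(S) <- 1
  pr <- coupled_pairs(R)
  rho <- cfg$coupled_corr - shift
  for (k in seq_len(nrow(pr))) {
    S[pr[k, 1], pr[k, 2]] <- S[pr[k, 2], pr[k, 1]] <- rho
  }
  ev <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < 1e-8) {
    stop("latent covariance not positive definite; lower effect_size or ",
         "baseline_corr", call. = FALSE)
  }
  S
}

#' Simulate a synthetic rs-fMRI cohort
#'
#' Per group, a latent ROI correlation matrix (control: coupled pairs at
#' `coupled_corr`; case: the same pairs lowered by `effect_size`); per
#' subject, zero-mean latent ROI series drawn from it (matching the
#' bandpassed, near-zero-mean character of preprocessed BOLD); each active
#' voxel carries its ROI's latent at high amplitude plus noise, every other
#' in-mask voxel is low-amplitude noise. Sexes alternate within groups; the
#' same seed reproduces the cohort bit-exactly.
#'
#' @param cfg A [cohort_config()].
#' @return A `synthetic_cohort`: `volumes` (named list of `fmri_volume`),
#'   `records` (subject data.frame), `atlas`, `mask`, `active_voxels`
#'   (named list of planted active linear voxel indices), `config`.
#' @export
simulate_cohort <- function(cfg = cohort_config()) {
  set.seed(cfg$seed)
  am <- make_atlas(cfg)
  gs <- cfg$grid_shape
  nt <- cfg$n_timepoints
  nvox <- prod(gs)
  mask_lin <- which(am$mask$data != 0)
  members <- lapply(seq_len(cfg$n_rois), function(r) which(am$atlas$data == r))
  n_active <- max(1L, round(cfg$active_fraction * cfg$voxels_per_roi))

  chol_ctrl <- chol(latent_sigma(cfg, 0))
  chol_case <- chol(latent_sigma(cfg, cfg$effect_size))
  chol_case_m <- if (cfg$sex_effect != 0) {
    chol(latent_sigma(cfg, min(cfg$effect_size + cfg$sex_effect, 1)))
  } else {
    chol_case
  }

  plan <- expand.grid(i = seq_len(cfg$n_per_group + cfg$n_test_per_group),
                      label = c("control", "case"),
                      stringsAsFactors = FALSE)
  plan$split <- ifelse(plan$i <= cfg$n_per_group, "train", "test")
  plan <- plan[order(plan$split == "test", plan$label), ]
  plan$sex <- rep_len(c("male", "female"), nrow(plan))
  plan$subject_id <- sprintf("S%03d", seq_len(nrow(plan)))

  volumes <- list()
  actives <- list()
  for (s in seq_len(nrow(plan))) {
    ch <- if (plan$label[s] == "control") chol_ctrl
          else if (plan$sex[s] == "male") chol_case_m
          else chol_case
    latent <- matrix(stats::rnorm(nt * cfg$n_rois), nt) %*% ch
    dat <- numeric(nvox * nt)
    noise <- matrix(stats::rnorm(length(mask_lin) * nt, sd = cfg$noise_sd),
                    length(mask_lin), nt)
    act <- integer(0)
    for (r in seq_len(cfg$n_rois)) {
      av <- sample(members[[r]], n_active)
      act <- c(act, av)
      rows <- match(av, mask_lin)
      noise[rows, ] <- noise[rows, ] +
        matrix(cfg$active_amplitude * latent[, r], length(av), nt, byrow = TRUE)
    }
    idx <- rep(mask_lin, nt) + rep((seq_len(nt) - 1L) * nvox, each = length(mask_lin))
    dat[idx] <- as.vector(noise)
    volumes[[plan$subject_id[s]]] <-
      new_fmri_volume(array(dat, c(gs, nt)), am$atlas$affine,
                      rep(cfg$voxel_size, 3))
    actives[[plan$subject_id[s]]] <- sort(act)
  }
  records <- data.frame(subject_id = plan$subject_id, site = "SiteA",
                        sex = plan$sex, label = plan$label,
                        qc_pass = TRUE, split = plan$split,
                        stringsAsFactors = FALSE)
  structure(list(volumes = volumes, records = records,
                 atlas = am$atlas, mask = am$mask,
                 active_voxels = actives, config = cfg),
            class = "synthetic_cohort")
}

#' Build attributed graphs for every subject of a cohort
#'
#' @param cohort A `synthetic_cohort` (or any list with `volumes`, `mask`,
#'   `atlas`, `records`).
#' @param net_cfg A [network_config()].
#' @return Named list of `attributed_graph`s, one per subject.
#' @export
cohort_graphs <- function(cohort, net_cfg = network_config()) {
  out <- lapply(cohort$records$subject_id, function(id) {
    vs <- extract_voxel_series(cohort$volumes[[id]], cohort$mask)
    build_graph(vs, cohort$atlas, net_cfg, subject_id = id)
  })
  names(out) <- cohort$records$subject_id
  out
}

#' Write a synthetic cohort to disk in standard formats
#'
#' NIfTI volumes, mask and atlas plus a phenotype CSV, in exactly the
#' formats the reading functions accept.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(cohort$mask, file.path(dir, "mask.nii.gz"))
  write_volume(cohort$atlas, file.path(dir, "atlas.nii.gz"))
  for (id in names(cohort$volumes)) {
    write_volume(cohort$volumes[[id]], file.path(dir, paste0(id, ".nii.gz")))
  }
  utils::write.csv(cohort$records, file.path(dir, "phenotype.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Hand-checkable pair of small attributed graphs with an embedded oracle
#'
#' Two fixed graphs (3 and 4 nodes) whose signature components are simple
#' numbers, together with the expected 3x4 node cost matrix computed here
#' by direct scalar arithmetic (sorting, zero-padding and the sigmoid
#' written out inline, no calls into the distance code), for use as a test
#' oracle.
#'
#' @return List with `g1`, `g2`, `nc`, `cfg` and `expected_cost_matrix`.
#' @export
toy_graph_pair <- function() {
  g1 <- graph_from_adjacency(
    W = matrix(c(0, 0.8, 0,
                 0.8, 0, 0.4,
                 0, 0.4, 0), 3, 3, byrow = TRUE),
    powers = c(0.9, 0.5, 0.2),
    coords = matrix(c(0, 0, 0,
                      10, 0, 0,
                      0, 20, 0), 3, 3, byrow = TRUE),
    subject_id = "toy1")
  g2 <- graph_from_adjacency(
    W = matrix(c(0, 0.9, 0.5, 0,
                 0.9, 0, 0, 0,
                 0.5, 0, 0, 0.35,
                 0, 0, 0.35, 0), 4, 4, byrow = TRUE),
    powers = c(1.0, 0.6, 0.3, 0.1),
    coords = matrix(c(0, 0, 0,
                      12, 0, 0,
                      0, 18, 0,
                      30, 30, 30), 4, 3, byrow = TRUE),
    subject_id = "toy2")
  nc <- structure(list(max_degree = 1.4, max_power = 1.0),
                  class = "normalization_constants")

  # independent arithmetic oracle ------------------------------------------
  deg1 <- c(0.8, 0.8 + 0.4, 0.4)
  deg2 <- c(0.9 + 0.5, 0.9, 0.5 + 0.35, 0.35)
  ngh1 <- list(2L, c(1L, 3L), 2L)
  ngh2 <- list(c(2L, 3L), 1L, c(1L, 4L), 3L)
  pow1 <- c(0.9, 0.5, 0.2)
  pow2 <- c(1.0, 0.6, 0.3, 0.1)
  xyz1 <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 20, 0))
  xyz2 <- rbind(c(0, 0, 0), c(12, 0, 0), c(0, 18, 0), c(30, 30, 30))
  prof <- function(a, b, mx) {
    L <- max(length(a), length(b))
    if (L == 0) return(0)
    a <- c(sort(a, decreasing = TRUE), rep(0, L - length(a)))
    b <- c(sort(b, decreasing = TRUE), rep(0, L - length(b)))
    min(sum(abs(a - b)) / (mx * L), 1)
  }
  expected <- matrix(0, 3, 4)
  for (i in 1:3) {
    for (j in 1:4) {
      d1 <- min(abs(deg1[i] - deg2[j]) / 1.4, 1)
      d2 <- prof(deg1[ngh1[[i]]], deg2[ngh2[[j]]], 1.4)
      d3 <- min(abs(pow1[i] - pow2[j]) / 1.0, 1)
      d4 <- prof(pow1[ngh1[[i]]], pow2[ngh2[[j]]], 1.0)
      d5 <- 1 / (1 + 300 * exp(-sqrt(sum((xyz1[i, ] - xyz2[j, ])^2)) / 4))
      expected[i, j] <- 0.2 * d1 + 0.1 * d2 + 0.2 * d3 + 0.1 * d4 + 0.4 * d5
    }
  }
  list(g1 = g1, g2 = g2, nc = nc, cfg = distance_config(),
       expected_cost_matrix = expected)
}
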