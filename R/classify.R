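# Classification protocol: polynomial-kernel SVM on the MDS-embedded
# subjects, leave-one-out and train/test evaluation, correlation-threshold
# sweep, and the detection-rate arithmetic used in reporting.

#' Classifier configuration
#'
#' Polynomial kernel `(gamma * <u, v> + coef0)^degree` with defaults
#' matching the classic cubic polynomial kernel `(<u, v> + 1)^3` and unit
#' regularization.
#'
#' @param degree Polynomial degree (default 3).
#' @param cost Regularization parameter C (default 1).
#' @param gamma,coef0 Kernel constants (defaults 1 and 1).
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(degree = 3, cost = 1, gamma = 1, coef0 = 1) {
  stopifnot(degree >= 1, cost > 0)
  structure(list(kernel = "polynomial", degree = as.integer(degree),
                 cost = cost, gamma = gamma, coef0 = coef0),
            class = "classifier_config")
}

CLASS_LEVELS <- c("control", "case")

as_class_factor <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), CLASS_LEVELS)
  if (length(bad)) {
    stop("labels must be 'control' or 'case'; got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  factor(labels, levels = CLASS_LEVELS)
}

fit_svm <- function(x, y, ccfg) {
  e1071::svm(x = as.matrix(x), y = y, type = "C-classification",
             kernel = "polynomial", degree = ccfg$degree, cost = ccfg$cost,
             gamma = ccfg$gamma, coef0 = ccfg$coef0, scale = FALSE)
}

#' Detection rate, specificity and sensitivity
#'
#' Detection rate = overall fraction correct; specificity = fraction of
#' controls classified as controls; sensitivity = fraction of cases
#' classified as cases. All in percent.
#'
#' @param predicted,truth Equal-length label vectors in
#'   `{control, case}`.
#' @return Named numeric vector `(detection_rate, specificity,
#'   sensitivity)` in `[0, 100]` (NaN for an absent class).
#' @export
detection_metrics <- function(predicted, truth) {
  if (length(predicted) == 0L) stop("empty input", call. = FALSE)
  if (length(predicted) != length(truth)) {
    stop("predicted and truth lengths differ", call. = FALSE)
  }
  p <- as_class_factor(predicted)
  t <- as_class_factor(truth)
  c(detection_rate = 100 * mean(p == t),
    specificity = 100 * sum(p == "control" & t == "control") / sum(t == "control"),
    sensitivity = 100 * sum(p == "case" & t == "case") / sum(t == "case"))
}

#' Detection metrics implied by confusion counts
#'
#' Convenience for reconstructing reported rates from cohort arithmetic:
#' expands the confusion counts into label vectors and delegates to
#' [detection_metrics()].
#'
#' @param tp,tn,fp,fn Confusion counts (cases correct, controls correct,
#'   controls misclassified, cases misclassified).
#' @return As [detection_metrics()].
#' @export
confusion_metrics <- function(tp, tn, fp, fn) {
  truth <- c(rep("case", tp + fn), rep("control", tn + fp))
  predicted <- c(rep("case", tp), rep("control", fn),
                 rep("control", tn), rep("case", fp))
  detection_metrics(predicted, truth)
}

#' Leave-one-out cross-validated classification
#'
#' The embedding is computed once on the full (label-free) distance matrix;
#' for each held-out subject an SVM is fit on the remaining embedded points
#' and the held-out point is predicted. Since neither the distances nor the
#' embedding see any label, holding the embedding fixed across folds leaks
#' no label information.
#'
#' @param D Symmetric distance matrix over the cohort.
#' @param labels Labels in `{control, case}`, one per subject.
#' @param ecfg An [embedding_config()].
#' @param ccfg A [classifier_config()].
#' @return List with `metrics` (detection/specificity/sensitivity),
#'   `predicted`, `embedding`.
#' @export
classify_loocv <- function(D, labels, ecfg = embedding_config(),
                           ccfg = classifier_config()) {
  y <- as_class_factor(labels)
  n <- length(y)
  if (nrow(as.matrix(D)) != n) stop("D and labels disagree", call. = FALSE)
  if (any(table(factor(y, levels = CLASS_LEVELS)) < 2L)) {
    stop("need at least 2 subjects per class", call. = FALSE)
  }
  emb <- mds_embed(D, ecfg)
  X <- emb$coords
  pred <- factor(rep(NA_character_, n), levels = CLASS_LEVELS)
  for (i in seq_len(n)) {
    fit <- fit_svm(X[-i, , drop = FALSE], y[-i], ccfg)
    pred[i] <- stats::predict(fit, X[i, , drop = FALSE])
  }
  list(metrics = detection_metrics(pred, y), predicted = pred,
       embedding = emb)
}

#' Train/test classification with a joint transductive embedding
#'
#' Train and test subjects are embedded together from their joint distance
#' matrix (labels untouched); the SVM is fit on the training coordinates
#' only and evaluated on the test coordinates.
#'
#' @param D_joint Distance matrix over train and test subjects together.
#' @param train_idx,test_idx Disjoint index sets covering `D_joint`.
#' @param labels_train,labels_test Labels for each split.
#' @param ecfg An [embedding_config()].
#' @param ccfg A [classifier_config()].
#' @return List with `metrics`, `predicted` (test predictions),
#'   `embedding`.
#' @export
classify_train_test <- function(D_joint, train_idx, test_idx,
                                labels_train, labels_test,
                                ecfg = embedding_config(),
                                ccfg = classifier_config()) {
  n <- nrow(as.matrix(D_joint))
  if (length(intersect(train_idx, test_idx)) > 0L) {
    stop("train and test index sets overlap", call. = FALSE)
  }
  if (!setequal(c(train_idx, test_idx), seq_len(n))) {
    stop("train and test indices must cover the joint matrix", call. = FALSE)
  }
  y_train <- as_class_factor(labels_train)
  y_test <- as_class_factor(labels_test)
  stopifnot(length(y_train) == length(train_idx),
            length(y_test) == length(test_idx))
  emb <- mds_embed(D_joint, ecfg)
  X <- emb$coords
  fit <- fit_svm(X[train_idx, , drop = FALSE], y_train, ccfg)
  pred <- stats::predict(fit, X[test_idx, , drop = FALSE])
  list(metrics = detection_metrics(pred, y_test), predicted = pred,
       embedding = emb)
}

#' Subject-count-weighted average of per-site rates
#'
#' @param rates Per-site rates (percent).
#' @param counts Per-site subject counts (> 0).
#' @return `sum(rates * counts) / sum(counts)`.
#' @export
weighted_average_rates <- function(rates, counts) {
  if (length(rates) != length(counts)) {
    stop("rates and counts lengths differ", call. = FALSE)
  }
  if (any(counts <= 0)) stop("counts must be positive", call. = FALSE)
  sum(rates * counts) / sum(counts)
}

# ---- correlation-threshold sweep -------------------------------------------

#' Sweep the correlation threshold over the full evaluation protocol
#'
#' For each site and subject group (all subjects, or male/female separately
#' when `stratify_by_sex`), networks are re-thresholded at every `corrTh`
#' of the grid and training detection rates are measured by leave-one-out
#' cross-validation. Cells where specificity or sensitivity is zero (the
#' classifier voted one class for everyone) are flagged degenerate and
#' excluded from model selection. The best non-degenerate training `corrTh`
#' per site x group is then applied to that site's test split via a joint
#' transductive embedding. Normalization constants are recomputed from the
#' training graphs at each threshold.
#'
#' @param graphs Named list of `attributed_graph`s carrying their node
#'   correlation matrices (built by [build_graph()]), names = subject ids.
#' @param records Data.frame of subject records (`subject_id`, `site`,
#'   `sex`, `label`, `split`), as from [read_phenotype_table()].
#' @param grid Thresholds to scan (default `seq(0.30, 0.90, by = 0.10)`).
#' @param stratify_by_sex Run male and female groups separately and pool
#'   their rates subject-weighted (default FALSE).
#' @param ecfg,ccfg,dist_cfg Stage configurations.
#' @param min_group Smallest usable group (default 4); smaller groups are
#'   skipped with a warning.
#' @return A `sweep_report`: `results` (one row per site x group x corrTh x
#'   split), `chosen` (selected corrTh per site x group), `site_rates`
#'   (per-site rates at the chosen threshold, sex groups pooled), and
#'   `averages` (subject-weighted across sites).
#' @export
threshold_sweep <- function(graphs, records, grid = seq(0.30, 0.90, by = 0.10),
                            stratify_by_sex = FALSE,
                            ecfg = embedding_config(),
                            ccfg = classifier_config(),
                            dist_cfg = distance_config(),
                            min_group = 4) {
  stopifnot(length(grid) >= 1L, is.data.frame(records))
  ids <- vapply(graphs, `[[`, character(1), "subject_id")
  names(graphs) <- ids
  if (!all(records$subject_id %in% ids)) {
    stop("records contain subjects without graphs", call. = FALSE)
  }
  groups <- if (stratify_by_sex) c("male", "female") else "all"
  results <- list()
  chosen <- list()
  site_rates <- list()

  for (site in unique(records$site)) {
    for (grp in groups) {
      rec <- records[records$site == site, , drop = FALSE]
      if (grp != "all") rec <- rec[rec$sex == grp, , drop = FALSE]
      tr <- rec[rec$split == "train", , drop = FALSE]
      te <- rec[rec$split == "test", , drop = FALSE]
      if (nrow(tr) < min_group || length(unique(tr$label)) < 2L ||
          any(table(as_class_factor(tr$label)) < 2L)) {
        warning("skipping ", site, "/", grp,
                ": too few training subjects or single-class", call. = FALSE)
        next
      }
      train_rows <- data.frame()
      for (th in grid) {
        gs <- lapply(graphs[tr$subject_id], rethreshold_graph, corr_threshold = th)
        nc <- training_constants(gs)
        D <- pairwise_distances(gs, nc, dist_cfg)
        m <- classify_loocv(D, tr$label, ecfg, ccfg)$metrics
        train_rows <- rbind(train_rows, data.frame(
          site = site, group = grp, corrTh = th, split = "train",
          n = nrow(tr), detection_rate = m[["detection_rate"]],
          specificity = m[["specificity"]], sensitivity = m[["sensitivity"]],
          degenerate = m[["specificity"]] == 0 || m[["sensitivity"]] == 0))
      }
      results[[length(results) + 1L]] <- train_rows

      ok <- which(!train_rows$degenerate)
      if (length(ok) == 0L) {
        warning("all thresholds degenerate for ", site, "/", grp, call. = FALSE)
        next
      }
      best <- ok[which.max(train_rows$detection_rate[ok])]
      best_th <- train_rows$corrTh[best]
      chosen[[length(chosen) + 1L]] <- data.frame(
        site = site, group = grp, corrTh = best_th,
        train_detection_rate = train_rows$detection_rate[best])
      rate_row <- data.frame(site = site, group = grp,
                             split = "train", n = nrow(tr),
                             detection_rate = train_rows$detection_rate[best])

      if (nrow(te) >= 1L) {
        all_ids <- c(tr$subject_id, te$subject_id)
        gs <- lapply(graphs[all_ids], rethreshold_graph, corr_threshold = best_th)
        nc <- training_constants(gs[seq_len(nrow(tr))])
        D <- pairwise_distances(gs, nc, dist_cfg)
        m <- classify_train_test(D, seq_len(nrow(tr)),
                                 nrow(tr) + seq_len(nrow(te)),
                                 tr$label, te$label, ecfg, ccfg)$metrics
        results[[length(results) + 1L]] <- data.frame(
          site = site, group = grp, corrTh = best_th, split = "test",
          n = nrow(te), detection_rate = m[["detection_rate"]],
          specificity = m[["specificity"]], sensitivity = m[["sensitivity"]],
          degenerate = isTRUE(m[["specificity"]] == 0) ||
            isTRUE(m[["sensitivity"]] == 0))
        rate_row <- rbind(rate_row, data.frame(
          site = site, group = grp, split = "test", n = nrow(te),
          detection_rate = m[["detection_rate"]]))
      }
      site_rates[[length(site_rates) + 1L]] <- rate_row
    }
  }
  results <- do.call(rbind, results)
  chosen <- if (length(chosen)) do.call(rbind, chosen) else NULL
  site_rates <- if (length(site_rates)) do.call(rbind, site_rates) else NULL

  averages <- NULL
  if (!is.null(site_rates)) {
    # pool sex groups within site (subject-weighted), then across sites
    pooled <- stats::aggregate(cbind(w = n, wr = n * detection_rate) ~ site + split,
                               data = site_rates, FUN = sum)
    pooled$detection_rate <- pooled$wr / pooled$w
    averages <- do.call(rbind, lapply(split(pooled, pooled$split), function(d)
      data.frame(split = d$split[1],
                 detection_rate = weighted_average_rates(d$detection_rate, d$w),
                 n = sum(d$w))))
    rownames(averages) <- NULL
  }
  structure(list(results = results, chosen = chosen,
                 site_rates = site_rates, averages = averages,
                 grid = grid, stratify_by_sex = stratify_by_sex),
            class = "sweep_report")
}

#' @export
print.sweep_report <- function(x, ...) {
  cat("<sweep_report> grid:", paste(format(x$grid), collapse = " "), "\n")
  if (!is.null(x$chosen)) {
    cat("chosen thresholds:\n")
    print(x$chosen, row.names = FALSE)
  }
  if (!is.null(x$averages)) {
    cat("subject-weighted average detection rates:\n")
    print(x$averages, row.names = FALSE)
  }
  invisible(x)
}
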