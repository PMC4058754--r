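#' @keywords internal
"_PACKAGE"

# ---- constructors -----------------------------------------------------------

new_fmri_volume <- function(data, affine, voxel_size) {
  structure(list(data = data, affine = affine, voxel_size = voxel_size),
            class = "fmri_volume")
}

new_brain_mask <- function(data, affine) {
  structure(list(data = data, affine = affine), class = "brain_mask")
}

new_roi_atlas <- function(data, affine) {
  labels <- sort(unique(as.integer(data[data != 0])))
  structure(list(data = data, affine = affine,
                 labels = labels, n_labels = length(labels)),
            class = "roi_atlas")
}

#' Number of timepoints in a 4D fMRI volume
#' @param vol An `fmri_volume`.
#' @return Integer length of the time axis.
#' @export
n_timepoints <- function(vol) {
  stopifnot(inherits(vol, "fmri_volume"))
  dim(vol$data)[4L]
}

#' @export
print.fmri_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<fmri_volume> %d x %d x %d voxels, %d timepoints, voxel size %s mm\n",
              d[1], d[2], d[3], d[4],
              paste(signif(x$voxel_size, 4), collapse = " x ")))
  invisible(x)
}

#' @export
print.roi_atlas <- function(x, ...) {
  cat(sprintf("<roi_atlas> %s grid, %d labels\n",
              paste(dim(x$data), collapse = " x "), x$n_labels))
  invisible(x)
}

voxel_size_from_affine <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

# ---- NIfTI read/write -------------------------------------------------------

read_nifti_array <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  img <- RNifti::readNifti(path)
  affine <- matrix(as.numeric(RNifti::xform(img)), 4L, 4L)
  data <- as.array(img)
  attributes(data) <- list(dim = dim(data))  # drop RNifti header attributes
  list(data = data, affine = affine)
}

#' Read a 4D fMRI volume from a NIfTI-1 file
#'
#' Accepts plain or gzip-compressed NIfTI-1. The voxel-index to world-mm
#' affine is taken from the image xform (0-based voxel indices).
#'
#' @param path Path to a `.nii` or `.nii.gz` file with 4 dimensions.
#' @return An `fmri_volume` with fields `data` (4D array), `affine` (4x4)
#'   and `voxel_size` (mm triple).
#' @export
read_volume <- function(path) {
  x <- read_nifti_array(path)
  nd <- length(dim(x$data))
  if (nd != 4L) {
    stop("expected 4D image, got ", nd, "D: ", path, call. = FALSE)
  }
  if (dim(x$data)[4L] < 2L) {
    stop("expected at least 2 timepoints: ", path, call. = FALSE)
  }
  new_fmri_volume(x$data, x$affine, voxel_size_from_affine(x$affine))
}

#' Read a 3D mask or ROI atlas from a NIfTI-1 file
#'
#' @param path Path to a 3D integer-valued NIfTI-1 file.
#' @param kind `"mask"` (binarized, nonzero -> 1) or `"atlas"` (integer
#'   labels preserved, 0 = background).
#' @return A `brain_mask` or `roi_atlas`.
#' @export
read_label_volume <- function(path, kind = c("mask", "atlas")) {
  kind <- match.arg(kind)
  x <- read_nifti_array(path)
  nd <- length(dim(x$data))
  if (nd != 3L) {
    stop("expected 3D image, got ", nd, "D: ", path, call. = FALSE)
  }
  if (max(abs(x$data - round(x$data))) > 1e-6) {
    stop("expected integer-valued labels in ", path, call. = FALSE)
  }
  data <- round(x$data)
  if (kind == "mask") {
    if (!any(data != 0)) stop("empty mask: ", path, call. = FALSE)
    new_brain_mask((data != 0) * 1L, x$affine)
  } else {
    if (!any(data > 0)) stop("atlas has no positive labels: ", path, call. = FALSE)
    if (any(data < 0)) stop("atlas labels must be nonnegative: ", path, call. = FALSE)
    new_roi_atlas(data, x$affine)
  }
}

#' Write a volume, mask or atlas as NIfTI-1
#'
#' @param x An `fmri_volume`, `brain_mask`, `roi_atlas`, or a plain 3D/4D
#'   array (in which case `affine` must be given).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param affine 4x4 affine, only used for plain arrays.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, affine = NULL) {
  if (is.list(x)) {
    affine <- x$affine
    data <- x$data
  } else {
    data <- x
    if (is.null(affine)) stop("affine required for plain arrays", call. = FALSE)
  }
  img <- RNifti::asNifti(data)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# ---- voxel series extraction ------------------------------------------------

#' Extract per-voxel time series inside a brain mask
#'
#' @param vol An `fmri_volume`.
#' @param mask A `brain_mask` with matching spatial dimensions and affine.
#' @return A `voxel_series` object: `coords_voxel` (n x 3, 0-based integer
#'   indices), `coords_world` (n x 3, mm), `series` (n x T matrix).
#' @export
extract_voxel_series <- function(vol, mask) {
  stopifnot(inherits(vol, "fmri_volume"), inherits(mask, "brain_mask"))
  dv <- dim(vol$data)[1:3]
  dm <- dim(mask$data)
  if (!identical(as.integer(dv), as.integer(dm))) {
    stop("volume and mask spatial dimensions differ (",
         paste(dv, collapse = "x"), " vs ", paste(dm, collapse = "x"), ")",
         call. = FALSE)
  }
  if (max(abs(vol$affine - mask$affine)) > 1e-4) {
    stop("volume and mask affines differ", call. = FALSE)
  }
  idx <- which(mask$data != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask", call. = FALSE)
  coords_voxel <- idx - 1L  # 0-based
  coords_world <- apply_affine(vol$affine, coords_voxel)
  nt <- dim(vol$data)[4L]
  flat <- matrix(vol$data, prod(dv), nt)
  lin <- (idx[, 1] - 1L) + dv[1] * (idx[, 2] - 1L) + dv[1] * dv[2] * (idx[, 3] - 1L) + 1L
  series <- flat[lin, , drop = FALSE]
  structure(list(coords_voxel = coords_voxel,
                 coords_world = coords_world,
                 series = series),
            class = "voxel_series")
}

apply_affine <- function(affine, coords0) {
  # coords0: n x 3 matrix of 0-based voxel indices
  h <- cbind(coords0, 1)
  t(affine %*% t(h))[, 1:3, drop = FALSE]
}

# ---- phenotype tables -------------------------------------------------------

#' Default phenotype column aliases
#'
#' Phenotype sheets name their columns differently across sites; each entry
#' lists accepted header names (case-insensitive) for the corresponding
#' field. Override entries to point at nonstandard columns.
#'
#' @return Named list of character vectors of accepted column names.
#' @export
pheno_columns <- function() {
  list(id    = c("subject_id", "scandir id", "scandirid", "id", "subject"),
       site  = c("site", "center"),
       sex   = c("sex", "gender"),
       dx    = c("dx", "label", "diagnosis", "group"),
       qc    = c("qc", "qc_rest_1", "qc_pass"),
       split = c("split", "set"))
}

parse_sex <- function(x) {
  v <- tolower(trimws(as.character(x)))
  out <- ifelse(v %in% c("male", "m", "1"), "male",
         ifelse(v %in% c("female", "f", "0"), "female", NA))
  if (anyNA(out)) {
    stop("unknown sex code(s): ", paste(unique(v[is.na(out)]), collapse = ", "),
         call. = FALSE)
  }
  out
}

parse_dx <- function(x) {
  v <- tolower(trimws(as.character(x)))
  out <- ifelse(v %in% c("control", "td", "typically developing", "0"), "control",
         ifelse(v %in% c("case", "adhd", "1", "2", "3"), "case", NA))
  if (anyNA(out)) {
    stop("unknown diagnosis code(s): ", paste(unique(v[is.na(out)]), collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Read a phenotype table of subject records
#'
#' Reads a delimited text file (comma or tab separated, header row) and
#' returns one record per subject: id, site, sex, diagnosis label, QC flag
#' and train/test split. Subjects whose QC flag is 0/false are dropped when
#' `exclude_qc_failures` is on, mirroring the usual exclusion of scans with
#' questionable image quality.
#'
#' @param path Path to a CSV/TSV file.
#' @param columns Column alias map, see [pheno_columns()].
#' @param exclude_qc_failures Drop records whose QC flag is false (default TRUE).
#' @param default_split Split assigned when no split column is present.
#' @return A data.frame with columns `subject_id`, `site`, `sex`, `label`,
#'   `qc_pass`, `split`.
#' @export
read_phenotype_table <- function(path, columns = pheno_columns(),
                                 exclude_qc_failures = TRUE,
                                 default_split = "train") {
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  hdr <- tolower(trimws(names(df)))
  find_col <- function(field, required = TRUE) {
    hit <- which(hdr %in% tolower(columns[[field]]))
    if (length(hit) == 0L) {
      if (required) {
        stop("phenotype table is missing a '", field, "' column (accepted: ",
             paste(columns[[field]], collapse = ", "), ")", call. = FALSE)
      }
      return(NA_integer_)
    }
    hit[1L]
  }
  id_c <- find_col("id"); site_c <- find_col("site")
  sex_c <- find_col("sex"); dx_c <- find_col("dx")
  qc_c <- find_col("qc", required = FALSE)
  split_c <- find_col("split", required = FALSE)

  qc <- if (is.na(qc_c)) rep(TRUE, nrow(df)) else {
    v <- tolower(trimws(as.character(df[[qc_c]])))
    v %in% c("1", "true", "pass", "yes")
  }
  split <- if (is.na(split_c)) rep(default_split, nrow(df)) else {
    tolower(trimws(as.character(df[[split_c]])))
  }
  rec <- data.frame(subject_id = as.character(df[[id_c]]),
                    site = as.character(df[[site_c]]),
                    sex = parse_sex(df[[sex_c]]),
                    label = parse_dx(df[[dx_c]]),
                    qc_pass = qc,
                    split = split,
                    stringsAsFactors = FALSE)
  if (anyDuplicated(rec$subject_id)) {
    stop("duplicate subject ids in phenotype table", call. = FALSE)
  }
  if (exclude_qc_failures) rec <- rec[rec$qc_pass, , drop = FALSE]
  rownames(rec) <- NULL
  rec
}
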