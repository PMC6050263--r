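#' ROI time-series container
#'
#' @param data numeric matrix, timepoints x ROIs.
#' @param roi_names unique ROI identifiers (column order fixes the edge
#'   ordering downstream).
#' @param subject_id subject identifier.
#' @return A `roi_timeseries` object.
#' @export
roi_timeseries <- function(data, roi_names = colnames(data),
                           subject_id = "subject") {
  data <- as.matrix(data)
  if (is.null(roi_names)) roi_names <- paste0("R", seq_len(ncol(data)))
  if (nrow(data) < 2L) stop("time-series must have at least 2 timepoints")
  if (anyNA(data)) stop("time-series contains missing values")
  if (anyDuplicated(roi_names)) stop("ROI names must be unique")
  if (length(roi_names) != ncol(data)) stop("roi_names length mismatch")
  colnames(data) <- roi_names
  structure(list(data = data, roi_names = roi_names,
                 subject_id = subject_id),
            class = "roi_timeseries")
}

#' Extract mean ROI time-series from a 4D image
#'
#' Per ROI, the unweighted mean over in-mask voxels at each timepoint.
#' Probability masks are thresholded at 0.5; label images take one ROI per
#' integer label.
#'
#' @param image4d 4D numeric array (x, y, z, time) or path to a NIfTI file
#'   (read with the RNifti package).
#' @param roi_masks either a 3D integer label array (one ROI per non-zero
#'   label), a named list of 3D binary/probability masks, or paths to NIfTI
#'   files of the same.
#' @param roi_names optional names overriding those derived from labels.
#' @param subject_id subject identifier.
#' @return A [roi_timeseries()].
#' @export
extract_roi_timeseries <- function(image4d, roi_masks, roi_names = NULL,
                                   subject_id = "subject") {
  read_nii <- function(x) {
    if (is.character(x)) {
      if (!requireNamespace("RNifti", quietly = TRUE)) {
        stop("reading NIfTI files requires the RNifti package")
      }
      x <- as.array(RNifti::readNifti(x))
    }
    x
  }
  image4d <- read_nii(image4d)
  if (length(dim(image4d)) != 4L) stop("image must be 4-dimensional")
  grid <- dim(image4d)[1:3]
  n_t <- dim(image4d)[4]
  vox <- matrix(image4d, prod(grid), n_t)

  if (!is.list(roi_masks)) {
    lab <- read_nii(roi_masks)
    if (!identical(dim(lab)[1:3], grid)) {
      stop("ROI label image grid does not match the 4D image grid")
    }
    labels <- sort(unique(as.vector(lab)))
    labels <- labels[labels != 0]
    roi_masks <- lapply(labels, function(l) lab == l)
    names(roi_masks) <- paste0("ROI", labels)
  } else {
    roi_masks <- lapply(roi_masks, read_nii)
  }
  if (!is.null(roi_names)) names(roi_masks) <- roi_names
  if (is.null(names(roi_masks))) {
    names(roi_masks) <- paste0("ROI", seq_along(roi_masks))
  }

  ts <- matrix(0, n_t, length(roi_masks))
  for (i in seq_along(roi_masks)) {
    m <- roi_masks[[i]]
    if (!identical(dim(m)[1:3], grid)) {
      stop(sprintf("mask grid mismatch for ROI '%s'", names(roi_masks)[i]))
    }
    sel <- which(as.vector(m) > 0.5)
    if (length(sel) == 0L) {
      stop(sprintf("ROI '%s' has an empty mask", names(roi_masks)[i]))
    }
    ts[, i] <- colMeans(vox[sel, , drop = FALSE])
  }
  roi_timeseries(ts, roi_names = names(roi_masks), subject_id = subject_id)
}

detrend_linear <- function(y) {
  t <- seq_along(y)
  stats::lm.fit(cbind(1, t), y)$residuals
}

#' Compute a connectivity fingerprint from ROI time-series
#'
#' Each ROI series is linearly detrended (first-order polynomial removed)
#' and standardized to zero mean and unit variance; Pearson correlations are
#' then computed between every unordered ROI pair and vectorized in
#' row-major upper-triangle order of the fixed ROI ordering. For the
#' 21-node DMN/DAN/SN network this yields 210 edges.
#'
#' @param ts a [roi_timeseries()].
#' @param fisher_z apply Fisher z-transform to the correlations (default
#'   `FALSE`: raw Pearson r).
#' @return A `connectivity_fingerprint`: list with `values` (length
#'   `n(n-1)/2`), `edge_names` and `roi_order`.
#' @export
compute_fingerprint <- function(ts, fisher_z = FALSE) {
  stopifnot(inherits(ts, "roi_timeseries"))
  d <- apply(ts$data, 2, detrend_linear)
  sds <- apply(d, 2, stats::sd)
  scale_ref <- pmax(apply(abs(ts$data), 2, max), 1)
  degenerate <- sds < 1e-10 * scale_ref
  if (any(degenerate)) {
    stop(sprintf("zero-variance series after detrending for ROI '%s'",
                 ts$roi_names[which(degenerate)[1]]))
  }
  z <- scale(d)
  r <- stats::cor(z)
  v <- vectorize_upper_cor(r)
  if (fisher_z) v <- atanh(pmin(1 - 1e-12, pmax(-1 + 1e-12, v)))
  structure(list(values = v, edge_names = edge_names(ts$roi_names),
                 roi_order = ts$roi_names, fisher_z = fisher_z),
            class = "connectivity_fingerprint")
}

# upper-triangle extraction without the unit-diagonal check (correlation
# diagonals are exactly 1 but guard against tiny fp wobble)
vectorize_upper_cor <- function(r) {
  t(r)[lower.tri(r)]
}

#' Cohort fingerprint matrix
#'
#' @param X numeric matrix, subjects x edges.
#' @param subject_ids subject identifiers (defaults to rownames or
#'   `sub-0001`...).
#' @param edge_names_ edge names (defaults to colnames).
#' @param site_labels optional integer site labels, one per subject.
#' @return A `cohort_matrix` object.
#' @export
cohort_matrix <- function(X, subject_ids = NULL, edge_names_ = NULL,
                          site_labels = NULL) {
  X <- as.matrix(X)
  if (is.null(subject_ids)) {
    subject_ids <- rownames(X)
    if (is.null(subject_ids)) subject_ids <- sprintf("sub-%04d", seq_len(nrow(X)))
  }
  if (is.null(edge_names_)) {
    edge_names_ <- colnames(X)
    if (is.null(edge_names_)) edge_names_ <- paste0("edge_", seq_len(ncol(X)))
  }
  if (!is.null(site_labels) && length(site_labels) != nrow(X)) {
    stop("site_labels length must match the number of subjects")
  }
  structure(list(X = X, subject_ids = subject_ids, edge_names = edge_names_,
                 site_labels = site_labels),
            class = "cohort_matrix")
}

#' Remove additive site effects from a cohort matrix
#'
#' Per edge, ordinary least squares on site indicator variables; the output
#' is the residuals plus the grand mean of that edge, so residualized
#' fingerprints stay on an interpretable scale. With indicator regressors
#' this equals subtracting each site's mean and re-adding the grand mean.
#' A single-site cohort is returned unchanged.
#'
#' @param cohort a [cohort_matrix()] with `site_labels`.
#' @return A `cohort_matrix` with site effects removed.
#' @export
remove_site_effects <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_matrix"))
  site <- cohort$site_labels
  if (is.null(site)) stop("cohort has no site labels")
  sizes <- table(site)
  if (any(sizes == 1)) {
    warning(sprintf("site(s) with a single subject retained: %s",
                    paste(names(sizes)[sizes == 1], collapse = ", ")))
  }
  if (length(sizes) == 1L) return(cohort)
  X <- cohort$X
  grand <- colMeans(X)
  for (s in unique(site)) {
    idx <- which(site == s)
    X[idx, ] <- sweep(X[idx, , drop = FALSE], 2,
                      colMeans(X[idx, , drop = FALSE]) - grand)
  }
  out <- cohort
  out$X <- X
  out
}

#' Read / write cohort fingerprints as TSV
#'
#' The TSV has a `subject_id` column followed by one column per edge named
#' `"ROIa__ROIb"`.
#'
#' @param cohort a [cohort_matrix()].
#' @param path file path.
#' @return `write_fingerprints` returns `path` invisibly;
#'   `read_fingerprints` returns a [cohort_matrix()].
#' @export
write_fingerprints <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_matrix"))
  df <- data.frame(subject_id = cohort$subject_ids, cohort$X,
                   check.names = FALSE)
  colnames(df)[-1] <- cohort$edge_names
  write_tsv(df, path)
}

#' @rdname write_fingerprints
#' @param metadata optional data frame with `subject_id` and `site` columns
#'   used to attach site labels.
#' @export
read_fingerprints <- function(path, metadata = NULL) {
  df <- utils::read.delim(path, check.names = FALSE)
  X <- as.matrix(df[, -1, drop = FALSE])
  site <- NULL
  if (!is.null(metadata)) {
    site <- metadata$site[match(df$subject_id, metadata$subject_id)]
  }
  cohort_matrix(X, subject_ids = df$subject_id,
                edge_names_ = colnames(df)[-1], site_labels = site)
}
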