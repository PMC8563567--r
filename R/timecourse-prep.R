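# Per-subject network time-course container and postprocessing:
# polynomial detrending and running-median/MAD despiking with cubic-spline
# interpolation of flagged samples.

#' Network time-course container
#'
#' One subject's T x N matrix of network (or region) signals with sampling
#' metadata. T is the number of volumes, N the number of networks.
#'
#' @param data numeric T x N matrix (rows = volumes, columns = networks).
#' @param subject_id subject identifier string.
#' @param tr_seconds repetition time (sampling interval) in seconds.
#' @param labels optional character vector of N network names.
#' @return an object of class `network_timecourses`.
#' @export
network_timecourses <- function(data, subject_id = "subject",
                                tr_seconds = 2.072, labels = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stopf("time-course data must be numeric")
  if (any(!is.finite(data))) stopf("time-course data contains non-finite values")
  check_scalar(tr_seconds, "tr_seconds", positive = TRUE)
  if (is.null(labels)) labels <- paste0("net", seq_len(ncol(data)))
  if (length(labels) != ncol(data))
    stopf("need %d labels, got %d", ncol(data), length(labels))
  colnames(data) <- labels
  structure(list(data = data, subject_id = as.character(subject_id),
                 tr_seconds = tr_seconds, labels = labels),
            class = "network_timecourses")
}

#' @export
print.network_timecourses <- function(x, ...) {
  cat(sprintf("<network_timecourses> subject %s: %d volumes x %d networks, TR = %.3f s\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$tr_seconds))
  invisible(x)
}

as_timecourses <- function(x) {
  if (inherits(x, "network_timecourses")) return(x)
  network_timecourses(x)
}

#' Polynomial detrending of network time courses
#'
#' Removes, per column, the least-squares polynomial fit in time up to
#' `max_order` (including the intercept). The default cubic order removes
#' linear, quadratic and cubic trends alongside the mean, the standard
#' time-course postprocessing before sliding-window connectivity.
#'
#' @param tc a `network_timecourses` object (or bare T x N matrix).
#' @param max_order highest polynomial order removed (default 3).
#' @return a `network_timecourses` with detrended data; each column has zero
#'   mean and zero projection on the polynomial basis.
#' @export
detrend_polynomial <- function(tc, max_order = 3) {
  tc <- as_timecourses(tc)
  check_scalar(max_order, "max_order", positive = TRUE, integer = TRUE)
  T <- nrow(tc$data)
  if (T <= max_order + 1)
    stopf("need more than %d volumes to remove order-%d trends (got %d)",
          max_order + 1, max_order, T)
  tt <- seq_len(T)
  basis <- cbind(1, stats::poly(tt, degree = max_order))  # orthogonal basis
  qrb <- qr(basis)
  resid <- tc$data - basis %*% qr.coef(qrb, tc$data)
  tc$data <- resid
  tc
}

#' Despike network time courses
#'
#' Flags isolated outliers by comparing each sample to a running-median
#' reference: points deviating by more than `spike_threshold_mad` robust
#' standard deviations (MAD of the residual, scaled to the Gaussian SD) are
#' flagged, then replaced by a natural cubic spline fitted to the unflagged
#' samples. Columns are processed independently.
#'
#' @param tc a `network_timecourses` object (or bare matrix).
#' @param spike_threshold_mad robust-SD threshold (default 5).
#' @param median_window running-median window length, odd (default 11).
#' @return list with `timecourses` (despiked) and `mask` (T x N logical,
#'   TRUE where a sample was flagged and interpolated).
#' @export
despike <- function(tc, spike_threshold_mad = 5, median_window = 11) {
  tc <- as_timecourses(tc)
  check_scalar(spike_threshold_mad, "spike_threshold_mad", positive = TRUE)
  T <- nrow(tc$data)
  if (T < 8) stopf("need at least 8 volumes to despike (got %d)", T)
  win <- min(median_window, if (T %% 2 == 1) T else T - 1)
  mask <- matrix(FALSE, T, ncol(tc$data), dimnames = dimnames(tc$data))
  out <- tc$data
  for (j in seq_len(ncol(out))) {
    x <- out[, j]
    ref <- stats::runmed(x, k = win, endrule = "median")
    resid <- x - ref
    s <- stats::mad(resid)
    # a running median tracks smooth signals exactly at most samples, which
    # can zero the MAD; fall back to the scale of the nonzero residuals
    if (s == 0) s <- stats::mad(resid[resid != 0], center = 0)
    if (!is.finite(s) || s == 0) next  # constant column: nothing to flag
    bad <- abs(resid) > spike_threshold_mad * s
    if (!any(bad)) next
    if (mean(bad) > 0.5)
      stopf("column %d: %.0f%% of samples flagged as spikes; signal unusable",
            j, 100 * mean(bad))
    good <- which(!bad)
    sf <- stats::splinefun(good, x[good], method = "natural")
    out[bad, j] <- sf(which(bad))
    mask[, j] <- bad
  }
  tc$data <- out
  list(timecourses = tc, mask = mask)
}

#' Write a TSV outlier report from a despike mask
#'
#' One row per flagged sample: subject, network column, 1-based volume index.
#'
#' @param mask logical matrix from [despike()].
#' @param subject_id subject identifier.
#' @param path output file path.
#' @export
write_outlier_report <- function(mask, subject_id, path) {
  idx <- which(mask, arr.ind = TRUE)
  rep <- data.frame(subject = rep(subject_id, nrow(idx)),
                    column = idx[, 2], volume = idx[, 1])
  rep <- rep[order(rep$column, rep$volume), , drop = FALSE]
  write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
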