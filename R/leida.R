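# Window-free dynamic connectivity via leading eigenvector dynamics:
# Hilbert phases, instantaneous phase-coherence matrices
# dFC(n,p,t) = cos(theta_n(t) - theta_p(t)), their leading eigenvectors,
# the time-by-time FCD cosine-similarity matrix, and eigenvector-based
# state clustering.

#' Instantaneous phases via the Hilbert transform
#'
#' Columns are mean-centered, the analytic signal is formed by FFT (positive
#' frequencies doubled, negative zeroed) and the instantaneous phase is its
#' argument, wrapped to (-pi, pi]. The first and last `drop_edges` volumes
#' are discarded to blunt transform edge effects.
#'
#' @param tc a `network_timecourses` (or T x N matrix).
#' @param drop_edges volumes discarded at each end (default 1).
#' @return object of class `phase_series`: list with `theta` (T' x N),
#'   `dropped_edges`, `tr_seconds`, `subject_id`.
#' @export
hilbert_phase <- function(tc, drop_edges = 1) {
  tc <- as_timecourses(tc)
  T <- nrow(tc$data)
  if (T < 2 * drop_edges + 2)
    stopf("need at least %d volumes with drop_edges = %d (got %d)",
          2 * drop_edges + 2, drop_edges, T)
  theta <- apply(tc$data, 2, function(x) {
    if (var(x) == 0) stopf("constant column: instantaneous phase undefined")
    Arg(analytic_signal(x - mean(x)))
  })
  if (drop_edges > 0)
    theta <- theta[(drop_edges + 1):(T - drop_edges), , drop = FALSE]
  structure(list(theta = theta, dropped_edges = as.integer(drop_edges),
                 tr_seconds = tc$tr_seconds, subject_id = tc$subject_id),
            class = "phase_series")
}

# analytic signal x + i H(x) by the FFT method
analytic_signal <- function(x) {
  n <- length(x)
  f <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1          # DC and Nyquist
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(f * h, inverse = TRUE) / n
}

#' Instantaneous phase-coherence matrix
#'
#' `dFC(n, p) = cos(theta_n - theta_p)`: 1 for aligned phases, 0 for
#' orthogonal (quadrature) phases, -1 in antiphase. Symmetric with unit
#' diagonal.
#'
#' @param theta_t numeric N-vector of phases (radians) at one timepoint.
#' @return symmetric N x N matrix with entries in `[-1, 1]` and diagonal 1.
#' @export
phase_coherence_matrix <- function(theta_t) {
  if (any(!is.finite(theta_t))) stopf("non-finite phase")
  c_ <- cos(theta_t); s_ <- sin(theta_t)
  m <- outer(c_, c_) + outer(s_, s_)   # cos(a - b) expanded
  diag(m) <- 1
  m
}

#' Leading eigenvector of a phase-coherence matrix
#'
#' Unit-norm eigenvector of the algebraically largest eigenvalue, with the
#' sign fixed so that the majority of components are negative (for an exact
#' balance, the first nonzero component is made negative). A degenerate top
#' eigenvalue triggers a warning and a deterministic lexicographic
#' tie-break.
#'
#' @param m symmetric N x N matrix.
#' @param tol relative tolerance for eigenvalue degeneracy (default 1e-10).
#' @return unit-norm numeric vector of length N.
#' @export
leading_eigenvector <- function(m, tol = 1e-10) {
  if (!is_symmetric_matrix(m)) stopf("matrix must be symmetric")
  e <- eigen(m, symmetric = TRUE)
  top <- e$values[1]
  cand <- which(e$values >= top - tol * max(1, abs(top)))
  vs <- lapply(cand, function(i) fix_eigvec_sign(e$vectors[, i]))
  if (length(cand) > 1) {
    warnf("degenerate leading eigenvalue (multiplicity %d); using lexicographic tie-break",
          length(cand))
    ord <- order(vapply(vs, function(v) paste(sprintf("%.12e", v), collapse = ","), ""))
    vs <- vs[ord]
  }
  v <- vs[[1]]
  v / sqrt(sum(v^2))
}

fix_eigvec_sign <- function(v) {
  n_neg <- sum(v < 0); n_pos <- sum(v > 0)
  if (n_neg < n_pos) return(-v)
  if (n_neg == n_pos) {
    first <- v[v != 0][1]
    if (!is.na(first) && first > 0) return(-v)
  }
  v
}

#' Outer-product connectivity pattern of an eigenvector
#'
#' `V V^T`: the rank-1, trace-1 N x N pattern showing each area's
#' contribution to the dominant coherence mode.
#'
#' @param v unit-norm numeric vector.
#' @return symmetric N x N matrix.
#' @export
outer_pattern <- function(v) {
  if (abs(sum(v^2) - 1) > 1e-8) stopf("v must have unit Euclidean norm")
  tcrossprod(v)
}

#' Leading-eigenvector series for one subject
#'
#' Hilbert phases, per-timepoint phase-coherence matrices and their leading
#' eigenvectors.
#'
#' @param tc a `network_timecourses`.
#' @param drop_edges volumes discarded at each end (default 1).
#' @return object of class `eigenvector_series`: list with `V1` (T' x N,
#'   unit-norm sign-fixed rows), `dropped_edges`, `subject_id`.
#' @export
eigenvector_series <- function(tc, drop_edges = 1) {
  ph <- hilbert_phase(tc, drop_edges = drop_edges)
  V1 <- t(apply(ph$theta, 1, function(th)
    leading_eigenvector(phase_coherence_matrix(th))))
  structure(list(V1 = V1, dropped_edges = ph$dropped_edges,
                 subject_id = ph$subject_id),
            class = "eigenvector_series")
}

#' Functional connectivity dynamics (FCD) matrix
#'
#' Time-by-time cosine similarity between leading eigenvectors; with
#' unit-norm rows this is the Gram matrix `V1 V1^T`, entries in `[-1, 1]`,
#' unit diagonal. The mean over the strict upper triangle summarises how
#' strongly connectivity patterns recur.
#'
#' @param series an `eigenvector_series` (or T' x N matrix of unit rows).
#' @return object of class `fcd_matrix`: list with `fcd` (T' x T') and
#'   `mean_similarity`.
#' @export
fcd_matrix <- function(series) {
  V <- if (inherits(series, "eigenvector_series")) series$V1 else as.matrix(series)
  if (nrow(V) < 2) stopf("need at least 2 timepoints")
  f <- tcrossprod(V)
  f <- pmin(pmax(f, -1), 1)            # clip numerical overshoot
  diag(f) <- 1
  structure(list(fcd = f, mean_similarity = mean(f[upper.tri(f)])),
            class = "fcd_matrix")
}

#' Cohort-level LEiDA state analysis
#'
#' Computes each subject's leading-eigenvector series, pools the
#' eigenvectors across all timepoints and subjects, clusters them with
#' Manhattan k-means (elbow-selected k unless `k` is given) and computes the
#' four state metrics per subject, plus each subject's mean FCD similarity
#' for group comparison.
#'
#' @param timecourses list of `network_timecourses` (consistent N).
#' @param k_range candidate numbers of states (default 2:6).
#' @param k fixed number of states (default NULL: elbow).
#' @param n_restarts k-means restarts (default 500).
#' @param seed integer seed.
#' @param drop_edges Hilbert edge trim (default 1).
#' @return list as in [cohort_state_analysis()], plus `fcd_mean_similarity`
#'   (named per-subject vector) and `eigenvectors` (per-subject series).
#' @export
leida_cohort_analysis <- function(timecourses, k_range = 2:6, k = NULL,
                                  n_restarts = 500, seed = 1, drop_edges = 1) {
  if (length(timecourses) < 2) stopf("need at least 2 subjects")
  Ns <- vapply(timecourses, function(tc) ncol(tc$data), 1L)
  if (length(unique(Ns)) != 1)
    stopf("subjects have differing network counts: %s",
          paste(unique(Ns), collapse = ", "))
  series <- lapply(timecourses, eigenvector_series, drop_edges = drop_edges)
  names(series) <- vapply(timecourses, function(tc) tc$subject_id, "")
  rows <- lapply(series, function(s) s$V1)
  fit <- fit_state_model(rows, k_range = k_range, k = k,
                         n_restarts = n_restarts, seed = seed)
  fit$fcd_mean_similarity <- vapply(series, function(s)
    fcd_matrix(s)$mean_similarity, 0)
  fit$eigenvectors <- series
  fit
}
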