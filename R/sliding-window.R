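# Tapered sliding-window dynamic connectivity: taper construction, window
# enumeration, weighted covariance, graphical-LASSO precision with
# cross-validated L1 weight, Fisher-z conversion, covariate residualisation
# and connectivity-variability metrics.

#' Tapered sliding-window specification
#'
#' The taper is a rectangular window of `window_length_tr` TRs convolved
#' with a Gaussian of SD `gaussian_sigma_tr` TRs, stepped by `step_tr`.
#' Defaults follow the common choice of a 22-TR (~44 s at TR ~2 s) window
#' with a sigma-3 Gaussian moved in steps of 1 TR.
#'
#' @param window_length_tr window length L in TRs (default 22).
#' @param gaussian_sigma_tr Gaussian sigma in TRs (default 3).
#' @param step_tr step between window starts in TRs (default 1).
#' @return an object of class `taper_spec`.
#' @export
taper_spec <- function(window_length_tr = 22, gaussian_sigma_tr = 3,
                       step_tr = 1) {
  check_scalar(window_length_tr, "window_length_tr", positive = TRUE, integer = TRUE)
  if (window_length_tr < 2) stopf("window length must be >= 2 TR")
  check_scalar(gaussian_sigma_tr, "gaussian_sigma_tr", positive = TRUE)
  check_scalar(step_tr, "step_tr", positive = TRUE, integer = TRUE)
  structure(list(window_length_tr = as.integer(window_length_tr),
                 gaussian_sigma_tr = gaussian_sigma_tr,
                 step_tr = as.integer(step_tr)),
            class = "taper_spec")
}

#' Build the tapered window weights
#'
#' Discrete convolution of a length-L rectangle of ones with a Gaussian
#' kernel discretised at integer TR offsets, cropped symmetrically to length
#' L about the convolution peak and normalised to sum 1.
#'
#' @param spec a `taper_spec`.
#' @return numeric vector of L nonnegative weights summing to 1, symmetric
#'   and unimodal.
#' @export
build_taper <- function(spec) {
  stopifnot(inherits(spec, "taper_spec"))
  L <- spec$window_length_tr
  sigma <- spec$gaussian_sigma_tr
  R <- max(1L, ceiling(4 * sigma))
  kern <- exp(-((-R):R)^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  rect <- rep(1, L)
  full <- numeric(L + 2 * R)            # direct double-sum convolution
  for (i in seq_len(L))
    full[i:(i + 2 * R)] <- full[i:(i + 2 * R)] + rect[i] * kern
  w <- full[(R + 1):(R + L)]            # symmetric crop about the peak
  w / sum(w)
}

#' Enumerate sliding windows
#'
#' Windows of length L stepped by `step_tr`; the count is
#' floor((T - L) / step) + 1, e.g. 269 windows for 290 volumes at L = 22,
#' step 1. Indices are 1-based inclusive.
#'
#' @param n_volumes total number of volumes T.
#' @param spec a `taper_spec`.
#' @return data.frame with columns `start`, `end` (1-based inclusive) and
#'   `center` (mean of start and end).
#' @export
enumerate_windows <- function(n_volumes, spec) {
  stopifnot(inherits(spec, "taper_spec"))
  L <- spec$window_length_tr
  step <- spec$step_tr
  if (n_volumes < L)
    stopf("need at least %d volumes for a window of length %d (got %d)",
          L, L, n_volumes)
  starts <- seq(1L, n_volumes - L + 1L, by = step)
  data.frame(start = starts, end = starts + L - 1L,
             center = starts + (L - 1) / 2)
}

#' Taper-weighted windowed covariance
#'
#' Weighted sample covariance of the rows in one window: columns are
#' centered by their taper-weighted mean and cross-products weighted by the
#' taper, normalised by the weight sum. With a uniform taper this reduces to
#' the ordinary (biased) sample covariance.
#'
#' @param tc a `network_timecourses` (or T x N matrix).
#' @param window length-2 integer vector (start, end), 1-based inclusive.
#' @param taper weight vector of length `end - start + 1`.
#' @return symmetric positive semi-definite N x N covariance matrix.
#' @export
windowed_covariance <- function(tc, window, taper) {
  tc <- as_timecourses(tc)
  start <- window[1]; end <- window[2]
  if (start < 1 || end > nrow(tc$data) || end < start)
    stopf("window [%d, %d] outside the series (T = %d)", start, end, nrow(tc$data))
  X <- tc$data[start:end, , drop = FALSE]
  if (length(taper) != nrow(X))
    stopf("taper length %d does not match window length %d",
          length(taper), nrow(X))
  w <- taper / sum(taper)
  mu <- colSums(X * w)
  Xc <- sweep(X, 2, mu)
  S <- crossprod(Xc * w, Xc)            # sum_t w_t (x_t - mu)(x_t - mu)'
  S <- (S + t(S)) / 2
  if (any(diag(S) <= 0))
    stopf("zero-variance column in window [%d, %d]: correlation undefined",
          start, end)
  S
}

#' Default L1 regularisation grid
#'
#' 20 log-spaced values in `[1e-3, 1]`.
#'
#' @param n grid size (default 20).
#' @param range lower/upper bounds (default `c(1e-3, 1)`).
#' @return increasing numeric vector.
#' @export
lambda_grid_default <- function(n = 20, range = c(1e-3, 1)) {
  exp(seq(log(range[1]), log(range[2]), length.out = n))
}

#' Graphical-LASSO precision estimate
#'
#' Maximises the L1-penalised Gaussian log-likelihood
#' `log det(Theta) - tr(S Theta) - lambda * sum_(i != j) |Theta_ij|`
#' (off-diagonal penalty only) by block coordinate descent. At `lambda = 0`
#' the estimate is the unpenalised maximum likelihood `solve(S)`.
#'
#' @param S symmetric positive semi-definite sample covariance.
#' @param lambda nonnegative L1 weight.
#' @param tol convergence tolerance on the working covariance
#'   (max successive change, default 1e-6).
#' @param max_iter maximum outer iterations (default 200).
#' @return object of class `precision_estimate`: list with `S`, `theta`
#'   (precision), `w` (estimated covariance), `lambda`, `iterations`.
#' @export
glasso_precision <- function(S, lambda, tol = 1e-6, max_iter = 200) {
  if (!is_symmetric_matrix(S, tol = 1e-6)) stopf("S must be symmetric")
  S <- (S + t(S)) / 2
  if (lambda < 0) stopf("lambda must be >= 0")
  if (lambda == 0) {
    theta <- tryCatch(solve(S), error = function(e)
      stopf("S is singular at lambda = 0; use lambda > 0 for regularisation"))
    theta <- (theta + t(theta)) / 2
    est <- list(S = S, theta = theta, w = S, lambda = 0, iterations = 0L)
  } else {
    fit <- .glasso_cd(S, lambda, tol, as.integer(max_iter))
    if (!fit$converged)
      stopf("graphical LASSO did not converge at lambda = %g after %d iterations (max change %g)",
            lambda, fit$iterations, fit$max_change)
    est <- list(S = S, theta = fit$theta, w = fit$w, lambda = lambda,
                iterations = fit$iterations)
  }
  class(est) <- "precision_estimate"
  est
}

#' Cross-validated selection of the L1 weight
#'
#' Windows are split into `n_folds` contiguous-in-time folds (contiguity
#' respects the strong dependence of overlapping windows). For each lambda
#' and fold, the precision is fitted on the mean covariance of the training
#' windows and scored by the mean Gaussian log-likelihood
#' `log det(Theta) - tr(S_test Theta)` over held-out windows. Returns the
#' lambda maximising the mean held-out score; ties break toward the larger
#' (sparser) lambda.
#'
#' @param window_covs list of per-window N x N covariance matrices.
#' @param grid candidate lambdas (default [lambda_grid_default()]).
#' @param n_folds number of folds (default 20).
#' @param seed kept for interface stability; the contiguous fold scheme is
#'   deterministic and ignores it.
#' @return the selected lambda (scalar).
#' @export
select_lambda_cv <- function(window_covs, grid = lambda_grid_default(),
                             n_folds = 20, seed = NULL) {
  W <- length(window_covs)
  if (W < n_folds)
    stopf("need at least %d windows for %d-fold CV (got %d)", n_folds, n_folds, W)
  if (!length(grid)) stopf("empty lambda grid")
  fold_id <- cut(seq_len(W), breaks = n_folds, labels = FALSE)
  scores <- matrix(NA_real_, length(grid), n_folds)
  for (f in seq_len(n_folds)) {
    test <- which(fold_id == f)
    train <- which(fold_id != f)
    S_train <- Reduce(`+`, window_covs[train]) / length(train)
    for (g in seq_along(grid)) {
      est <- glasso_precision(S_train, grid[g])
      ld <- determinant(est$theta, logarithm = TRUE)$modulus
      scores[g, f] <- mean(vapply(window_covs[test], function(S_test)
        as.numeric(ld) - sum(S_test * est$theta), 0))
    }
  }
  mean_score <- rowMeans(scores)
  best <- max(mean_score)
  candidates <- grid[mean_score >= best - 1e-12]
  max(candidates)
}

#' Precision matrix to Fisher-z correlations
#'
#' Inverts the precision to a covariance, normalises to correlations and
#' applies the Fisher r-to-z transform. The diagonal (self-connection) is
#' stored as 0 by convention.
#'
#' @param est a `precision_estimate`.
#' @return N x N symmetric Fisher-z matrix with zero diagonal.
#' @export
precision_to_z <- function(est) {
  stopifnot(inherits(est, "precision_estimate"))
  C <- solve(est$theta)
  r <- stats::cov2cor((C + t(C)) / 2)
  diag(r) <- 0
  if (any(abs(r) >= 1 - 1e-12))
    stopf("correlation of magnitude 1 off the diagonal: Fisher z infinite")
  z <- atanh(r)
  diag(z) <- 0
  z
}

#' Windowed Fisher-z connectivity stack for one subject
#'
#' Runs the full sliding-window chain: taper, window enumeration, weighted
#' covariance per window, graphical LASSO (with a subject-level lambda,
#' either given or selected by cross-validation on this subject's windows)
#' and Fisher-z conversion.
#'
#' @param tc a `network_timecourses`.
#' @param spec a `taper_spec`.
#' @param lambda numeric L1 weight, or `"cv"` to select per subject.
#' @param grid lambda grid for CV.
#' @param n_folds CV folds (default 20).
#' @return object of class `window_stack`: list with `z` (W x N x N array),
#'   `window_centers`, `windows`, `lambda`, `subject_id`.
#' @export
subject_window_stack <- function(tc, spec = taper_spec(), lambda = "cv",
                                 grid = lambda_grid_default(), n_folds = 20) {
  tc <- as_timecourses(tc)
  taper <- build_taper(spec)
  win <- enumerate_windows(nrow(tc$data), spec)
  covs <- lapply(seq_len(nrow(win)), function(i)
    windowed_covariance(tc, c(win$start[i], win$end[i]), taper))
  lam <- if (identical(lambda, "cv"))
    select_lambda_cv(covs, grid = grid, n_folds = n_folds)
  else lambda
  N <- ncol(tc$data)
  z <- array(0, dim = c(length(covs), N, N),
             dimnames = list(NULL, tc$labels, tc$labels))
  for (i in seq_along(covs))
    z[i, , ] <- precision_to_z(glasso_precision(covs[[i]], lam))
  structure(list(z = z, window_centers = win$center, windows = win,
                 lambda = lam, subject_id = tc$subject_id),
            class = "window_stack")
}

#' @export
print.window_stack <- function(x, ...) {
  cat(sprintf("<window_stack> subject %s: %d windows x %d networks, lambda = %g\n",
              x$subject_id, dim(x$z)[1], dim(x$z)[2], x$lambda))
  invisible(x)
}

#' Residualise edge values for age and sex
#'
#' Ordinary least squares of each edge value on intercept, age and sex
#' across subjects; returns residuals plus the column (grand) mean so that
#' values stay on their original scale. Group membership is deliberately not
#' in the model. Rank-deficient covariate columns (e.g. a constant sex) are
#' dropped with a warning.
#'
#' @param values subjects x D numeric matrix of edge values.
#' @param design data.frame with columns `age` and `sex`, one row per
#'   subject in the same order.
#' @return residualised matrix of the same shape.
#' @export
residualize_edges <- function(values, design) {
  values <- as.matrix(values)
  if (nrow(values) != nrow(design))
    stopf("values have %d rows but design has %d", nrow(values), nrow(design))
  if (nrow(values) < 3)
    stopf("need at least 3 subjects to residualise on age and sex (got %d)",
          nrow(values))
  if (anyNA(design$age) || anyNA(design$sex)) stopf("missing covariates")
  X <- cbind(intercept = 1, age = design$age,
             sex = as.numeric(factor(design$sex)) - 1)
  keep <- c(TRUE, apply(X[, -1, drop = FALSE], 2, function(col) var(col) > 0))
  if (!all(keep)) {
    warnf("dropping constant covariate column(s): %s",
          paste(colnames(X)[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  fit <- lm.fit(X, values)
  res <- as.matrix(fit$residuals)
  sweep(res, 2, colMeans(values), `+`)
}

#' Connectivity-variability metrics
#'
#' Per-edge sample standard deviation (denominator W - 1) of the Fisher-z
#' values across windows; per-network mean SD over that network's row
#' (diagonal excluded); global mean SD over the strict upper triangle.
#'
#' @param stack a `window_stack` (or W x N x N array).
#' @return object of class `variability_metrics`: list with `per_edge_sd`
#'   (N x N), `per_network_mean_sd` (length N), `global_mean_sd` (scalar).
#' @export
connectivity_variability <- function(stack) {
  z <- if (inherits(stack, "window_stack")) stack$z else stack
  W <- dim(z)[1]; N <- dim(z)[2]
  if (W < 2) stopf("need at least 2 windows to compute variability (got %d)", W)
  flat <- matrix(z, nrow = W)           # W x N^2
  sds <- matrix(apply(flat, 2, sd), N, N, dimnames = dimnames(z)[2:3])
  diag(sds) <- 0
  per_network <- rowSums(sds) / (N - 1)
  global <- mean(sds[upper.tri(sds)])
  structure(list(per_edge_sd = sds, per_network_mean_sd = per_network,
                 global_mean_sd = global),
            class = "variability_metrics")
}
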