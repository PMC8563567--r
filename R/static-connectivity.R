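# Static between-network connectivity: full and partial correlations per
# subject on the Fisher-z scale, and max-statistic permutation inference
# (Freedman-Lane) with family-wise error control across edges, correlation
# types and group contrasts.

#' Full-correlation netmat on the Fisher-z scale
#'
#' Pearson correlation over the full time series, Fisher r-to-z transformed,
#' diagonal stored as 0.
#'
#' @param tc a `network_timecourses` (or T x N matrix).
#' @return symmetric N x N Fisher-z matrix.
#' @export
full_correlation_z <- function(tc) {
  tc <- as_timecourses(tc)
  X <- tc$data
  v <- apply(X, 2, var)
  if (any(v == 0))
    stopf("zero-variance column(s): %s",
          paste(tc$labels[v == 0], collapse = ", "))
  if (nrow(X) <= ncol(X))
    warnf("T = %d <= N = %d: full correlations will be poorly conditioned",
          nrow(X), ncol(X))
  r <- cor(X)
  diag(r) <- 0
  if (any(abs(r) >= 1 - 1e-12))
    stopf("perfectly correlated column pair: Fisher z infinite")
  z <- atanh(r)
  diag(z) <- 0
  z
}

#' Partial correlations from a covariance matrix (Fisher z)
#'
#' Analytic path: inverts `S + ridge * I` to the precision P and forms
#' `partial_r(i, j) = -P_ij / sqrt(P_ii P_jj)`, Fisher-z transformed with a
#' zero diagonal.
#'
#' @param S symmetric covariance matrix.
#' @param ridge nonnegative L2 regulariser added to the diagonal (default 0).
#' @return symmetric N x N Fisher-z partial-correlation matrix.
#' @export
partial_z_from_cov <- function(S, ridge = 0) {
  if (!is_symmetric_matrix(S, tol = 1e-6)) stopf("S must be symmetric")
  P <- tryCatch(solve(S + ridge * diag(nrow(S))), error = function(e)
    stopf("covariance singular even after ridge %g", ridge))
  d <- 1 / sqrt(diag(P))
  r <- -P * outer(d, d)
  diag(r) <- 0
  if (any(abs(r) >= 1 - 1e-12))
    stopf("partial correlation of magnitude 1: Fisher z infinite")
  z <- atanh(r)
  diag(z) <- 0
  z
}

#' Partial-correlation netmat on the Fisher-z scale
#'
#' Sample covariance of the series, optionally ridge-regularised, inverted
#' to partial correlations. The default ridge is `0.1 * mean(diag(S))` when
#' T < 5N (short series), else 0.
#'
#' @param tc a `network_timecourses` (or T x N matrix).
#' @param ridge L2 regulariser; `NULL` (default) applies the rule above.
#' @return symmetric N x N Fisher-z matrix.
#' @export
partial_correlation_z <- function(tc, ridge = NULL) {
  tc <- as_timecourses(tc)
  S <- cov(tc$data)
  if (is.null(ridge))
    ridge <- if (nrow(tc$data) < 5 * ncol(tc$data)) 0.1 * mean(diag(S)) else 0
  partial_z_from_cov(S, ridge)
}

#' Static netmats (full and partial) for one subject
#'
#' @param tc a `network_timecourses`.
#' @param ridge passed to [partial_correlation_z()].
#' @return object of class `static_netmat`: list with `full_z`, `partial_z`,
#'   `subject_id`.
#' @export
static_netmat <- function(tc, ridge = NULL) {
  tc <- as_timecourses(tc)
  structure(list(full_z = full_correlation_z(tc),
                 partial_z = partial_correlation_z(tc, ridge = ridge),
                 subject_id = tc$subject_id),
            class = "static_netmat")
}

# pairwise signed group contrasts on the coefficient vector of
# X = [intercept, covariates, dummies for groups 2..G]
pairwise_contrasts <- function(group_levels, p_total, dummy_cols) {
  G <- length(group_levels)
  pairs <- utils::combn(G, 2)
  out <- list()
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    cvec <- numeric(p_total)
    if (a > 1) cvec[dummy_cols[a - 1]] <- 1
    if (b > 1) cvec[dummy_cols[b - 1]] <- -1
    out[[paste0(group_levels[a], ">", group_levels[b])]] <- cvec
    out[[paste0(group_levels[b], ">", group_levels[a])]] <- -cvec
  }
  out
}

#' Max-statistic permutation test of group differences in netmats
#'
#' Per edge and contrast, the statistic is the t-value of the pairwise group
#' contrast in a linear model with age and sex covariates. The null is
#' built with the Freedman-Lane scheme: covariate-only residuals are
#' permuted, the covariate fit added back, and the model refitted. The FWE-
#' corrected p-value is the proportion of permutations (the unpermuted
#' labelling included, so the smallest attainable p is 1/n_permutations)
#' whose maximum |t| across all edges, both correlation types and all
#' contrasts exceeds the observed |t|.
#'
#' @param netmats list of `static_netmat` objects, one per subject, in
#'   design order.
#' @param design data.frame with `subject_id`, `group`, `age`, `sex`.
#' @param n_permutations number of permutations (default 500).
#' @param seed integer seed.
#' @return list with `results` (data.frame: edge_i, edge_j,
#'   correlation_type, contrast, t, p_uncorrected, p_fwe) and `null_max_t`
#'   (the permutation distribution of the family maximum |t|).
#' @export
permutation_group_test <- function(netmats, design, n_permutations = 500,
                                   seed = 1) {
  n <- length(netmats)
  if (n != nrow(design))
    stopf("%d netmats but %d design rows", n, nrow(design))
  grp <- factor(design$group)
  if (nlevels(grp) < 2) stopf("need at least 2 groups")
  if (any(table(grp) < 2)) stopf("every group needs at least 2 subjects")
  if (anyNA(design$age) || anyNA(design$sex)) stopf("missing covariates")

  N <- nrow(netmats[[1]]$full_z)
  idx <- upper_tri_index(N)
  Y <- cbind(
    t(vapply(netmats, function(m) vec_upper_tri(m$full_z), numeric(nrow(idx)))),
    t(vapply(netmats, function(m) vec_upper_tri(m$partial_z), numeric(nrow(idx)))))
  V <- ncol(Y)

  sex_num <- as.numeric(factor(design$sex)) - 1
  Z <- cbind(1, age = design$age, sex = sex_num)           # nuisance
  dummies <- stats::model.matrix(~grp)[, -1, drop = FALSE] # groups 2..G
  X <- cbind(Z, dummies)
  p <- ncol(X)
  dummy_cols <- seq(ncol(Z) + 1, p)
  contrasts <- pairwise_contrasts(levels(grp), p, dummy_cols)
  # two directions of a pair share |t|; compute once per unordered pair
  pair_names <- names(contrasts)[seq(1, length(contrasts), by = 2)]
  C <- do.call(rbind, contrasts[pair_names])               # n_pairs x p

  XtXi <- solve(crossprod(X))
  pinv <- XtXi %*% t(X)
  cc <- rowSums((C %*% XtXi) * C)                          # c' (X'X)^-1 c
  dof <- n - p

  t_stats <- function(Ymat) {
    B <- pinv %*% Ymat
    rss <- colSums((Ymat - X %*% B)^2)
    s2 <- rss / dof
    TT <- (C %*% B) / sqrt(outer(cc, s2))                  # n_pairs x V
    TT
  }

  Hz <- Z %*% solve(crossprod(Z)) %*% t(Z)
  fitted_nuis <- Hz %*% Y
  resid_nuis <- Y - fitted_nuis

  t_obs <- t_stats(Y)
  set.seed(seed)
  perms <- vector("list", n_permutations)
  perms[[1]] <- seq_len(n)                                 # unpermuted included
  for (b in 2:n_permutations) perms[[b]] <- sample.int(n)

  abs_obs <- abs(t_obs)
  count_fwe <- matrix(0, nrow(t_obs), V)
  count_unc <- matrix(0, nrow(t_obs), V)
  null_max <- numeric(n_permutations)
  for (b in seq_len(n_permutations)) {
    Yb <- fitted_nuis + resid_nuis[perms[[b]], , drop = FALSE]
    tb <- abs(t_stats(Yb))
    null_max[b] <- max(tb)
    count_fwe <- count_fwe + (null_max[b] >= abs_obs)
    count_unc <- count_unc + (tb >= abs_obs)
  }
  p_fwe <- count_fwe / n_permutations
  p_unc <- count_unc / n_permutations

  E <- nrow(idx)
  rows <- list()
  for (ct in seq_along(pair_names)) {
    for (type in c("full", "partial")) {
      cols <- if (type == "full") seq_len(E) else E + seq_len(E)
      for (dir_sign in c(1, -1)) {
        nm <- if (dir_sign == 1) pair_names[ct] else {
          parts <- strsplit(pair_names[ct], ">", fixed = TRUE)[[1]]
          paste0(parts[2], ">", parts[1])
        }
        rows[[length(rows) + 1]] <- data.frame(
          edge_i = idx[, 1], edge_j = idx[, 2],
          correlation_type = type, contrast = nm,
          t = dir_sign * t_obs[ct, cols],
          p_uncorrected = p_unc[ct, cols],
          p_fwe = p_fwe[ct, cols])
      }
    }
  }
  list(results = do.call(rbind, rows), null_max_t = null_max)
}
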