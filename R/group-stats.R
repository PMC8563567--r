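# Nonparametric group comparisons: Kruskal-Wallis, Mann-Whitney U with
# exact enumeration for small samples, rank-based permutation MANOVA
# (Pillai trace on column ranks), and the medication subgroup comparison.

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H with a chi-squared reference on (#groups - 1) degrees of
#' freedom (via `stats::kruskal.test`). When all values are identical the
#' test is degenerate and H = 0, p = 1 is returned.
#'
#' @param values numeric vector of per-subject scalars.
#' @param groups group membership, same length.
#' @return list with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stopf("need at least 2 groups")
  if (any(table(groups) == 0)) stopf("empty group")
  if (length(unique(values)) == 1)
    return(list(H = 0, df = nlevels(groups) - 1L, p = 1))
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = unname(kt$p.value))
}

#' Mann-Whitney U test
#'
#' U computed from rank sums (midranks for ties). The two-sided p-value is
#' obtained by exact enumeration of all group assignments when the
#' enumeration is small enough (at most `max_enumeration` subsets), else by
#' the tie-corrected normal approximation with continuity correction. Exact
#' enumeration handles ties symmetrically, so identical samples give p = 1.
#'
#' @param values_a,values_b numeric samples.
#' @param max_enumeration largest number of subsets enumerated exactly
#'   (default 20000).
#' @return list with `U` (for the first sample), `p` (two-sided) and
#'   `method`.
#' @export
mann_whitney_u <- function(values_a, values_b, max_enumeration = 20000) {
  na <- length(values_a); nb <- length(values_b)
  if (na == 0 || nb == 0) stopf("both samples must be nonempty")
  pooled <- c(values_a, values_b)
  rk <- rank(pooled)
  U <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  n <- na + nb
  if (choose(n, na) <= max_enumeration) {
    subsets <- utils::combn(n, na)
    dev_obs <- abs(U - mu)
    devs <- apply(subsets, 2, function(ix)
      abs(sum(rk[ix]) - na * (na + 1) / 2 - mu))
    p <- mean(devs >= dev_obs - 1e-9)
    method <- "exact enumeration"
  } else {
    ties <- table(rk)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma <- sqrt(na * nb / 12 * (n + 1 - tie_term))
    if (sigma == 0) {
      p <- 1                       # all values tied: no evidence either way
    } else {
      zstat <- (abs(U - mu) - 0.5) / sigma
      p <- min(1, 2 * stats::pnorm(zstat, lower.tail = FALSE))
    }
    method <- "normal approximation"
  }
  list(U = U, p = p, method = method)
}

#' Rank-based permutation MANOVA
#'
#' Responses are rank-transformed per column; the statistic is the Pillai
#' trace `tr(H (H + E)^-1)` of the between-group (H) and within-group (E)
#' scatter of the ranks. Significance comes from permuting group labels
#' (the observed labelling is included, so p >= 1/n_permutations).
#'
#' @param responses subjects x D numeric matrix.
#' @param groups group membership, length = subjects.
#' @param n_permutations permutations (default 5000).
#' @param seed integer seed.
#' @return list with `pillai`, `p`, `n_permutations`.
#' @export
nonparametric_manova <- function(responses, groups, n_permutations = 5000,
                                 seed = 1) {
  responses <- as.matrix(responses)
  groups <- factor(groups)
  if (nlevels(groups) < 2) stopf("need at least 2 groups")
  if (ncol(responses) < 1) stopf("need at least one response column")
  if (n_permutations < 100)
    warnf("fewer than 100 permutations gives a very coarse p-value")
  R <- apply(responses, 2, rank)
  # compositional or otherwise collinear responses make H + E singular;
  # work in a full-rank column basis of the centered ranks
  Rc <- sweep(R, 2, colMeans(R))
  qrd <- qr(Rc)
  if (qrd$rank < ncol(R))
    R <- R[, qrd$pivot[seq_len(qrd$rank)], drop = FALSE]
  pillai <- function(g) {
    gm <- rowsum(R, g) / as.vector(table(g))
    grand <- colMeans(R)
    H <- crossprod(sweep(gm, 2, grand) * sqrt(as.vector(table(g))))
    Rc <- R - gm[as.integer(g), , drop = FALSE]
    E <- crossprod(Rc)
    sum(diag(H %*% solve(H + E)))
  }
  obs <- pillai(groups)
  set.seed(seed)
  count <- 1L                                   # observed labelling included
  for (b in seq_len(n_permutations - 1)) {
    if (pillai(sample(groups)) >= obs - 1e-12) count <- count + 1L
  }
  list(pillai = obs, p = count / n_permutations,
       n_permutations = n_permutations)
}

#' Medication subgroup comparison of dynamic connectivity metrics
#'
#' Compares every metric column between flagged and unflagged subjects
#' (e.g. cholinesterase-inhibitor users versus non-users) with Mann-Whitney
#' U tests. Metrics whose subgroup is empty are skipped with a note.
#'
#' @param metrics data.frame with a `subject` column and numeric metric
#'   columns.
#' @param design data.frame with `subject_id` and a logical/0-1 flag column.
#' @param flag_column name of the flag column in `design` (default
#'   `"medication"`).
#' @return data.frame with columns metric, n_flagged, n_unflagged, U, p.
#' @export
medication_subgroup_compare <- function(metrics, design,
                                        flag_column = "medication") {
  if (!flag_column %in% names(design))
    stopf("design has no column `%s`", flag_column)
  flag <- as.logical(design[[flag_column]])[match(metrics$subject,
                                                  design$subject_id)]
  if (anyNA(flag)) stopf("flag missing for some analysed subjects")
  num_cols <- names(metrics)[vapply(metrics, is.numeric, TRUE)]
  out <- list()
  for (mcol in num_cols) {
    a <- metrics[[mcol]][flag]
    b <- metrics[[mcol]][!flag]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (!length(a) || !length(b)) {
      message(sprintf("metric `%s` skipped: empty subgroup", mcol))
      next
    }
    mw <- mann_whitney_u(a, b)
    out[[length(out) + 1]] <- data.frame(metric = mcol,
                                         n_flagged = length(a),
                                         n_unflagged = length(b),
                                         U = mw$U, p = mw$p)
  }
  if (!length(out)) return(data.frame(metric = character(0),
                                      n_flagged = integer(0),
                                      n_unflagged = integer(0),
                                      U = numeric(0), p = numeric(0)))
  do.call(rbind, out)
}
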