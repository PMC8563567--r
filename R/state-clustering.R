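# Brain-state clustering: k-means with Manhattan distance (median centroid
# updates), the within/between validity index, elbow-based selection of k,
# and the four per-subject state metrics (frequency, mean dwell time,
# number of transitions, mean intertransition time).

#' k-means clustering with Manhattan distance
#'
#' Lloyd-style alternation with L1 assignment and coordinate-wise median
#' centroid updates (the median minimises the L1 objective per coordinate).
#' The best (lowest-objective) of `n_restarts` seeded random initialisations
#' is returned; an emptied cluster is re-seeded with the farthest point.
#' Clusters are reported in descending frequency order.
#'
#' @param X M x D data matrix (rows are patterns).
#' @param k number of clusters (>= 2).
#' @param n_restarts random restarts (default 500).
#' @param seed integer seed.
#' @param max_iter Lloyd iteration cap per restart (default 100).
#' @return object of class `state_model`: list with `k`, `centroids`
#'   (k x D), `labels` (length M, in 1..k), `objective` (total within-
#'   cluster L1 distance), `objective_trace` (per-iteration objective of the
#'   winning restart) and `validity_index`.
#' @export
kmeans_manhattan <- function(X, k, n_restarts = 500, seed = 1, max_iter = 100) {
  X <- as.matrix(X)
  M <- nrow(X)
  check_scalar(k, "k", positive = TRUE, integer = TRUE)
  if (k < 2) stopf("k must be >= 2 (got %d)", k)
  if (M < k) stopf("cannot form %d clusters from %d points", k, M)
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- X[sample.int(M, k), , drop = FALSE]
    run <- .kmeans_l1_run(X, init, as.integer(max_iter))
    if (is.null(best) || run$objective < best$objective - 1e-12) best <- run
  }
  labels <- best$labels + 1L            # 0-based from C++
  # relabel in descending frequency (ties keep the original order)
  counts <- tabulate(labels, nbins = k)
  ord <- order(-counts, seq_len(k))
  relab <- integer(k); relab[ord] <- seq_len(k)
  model <- structure(list(k = as.integer(k),
                          centroids = best$centroids[ord, , drop = FALSE],
                          labels = relab[labels],
                          objective = best$objective,
                          objective_trace = best$objective_trace,
                          validity_index = NA_real_),
                     class = "state_model")
  model$validity_index <- tryCatch(cluster_validity_index(X, model),
                                   error = function(e) {
                                     warnf("validity index non-informative: %s",
                                           conditionMessage(e))
                                     NA_real_
                                   })
  model
}

#' @export
print.state_model <- function(x, ...) {
  cat(sprintf("<state_model> k = %d, %d patterns, objective = %.4g, validity index = %.4g\n",
              x$k, length(x$labels), x$objective, x$validity_index))
  invisible(x)
}

#' Cluster validity index (within / between)
#'
#' Sum over points of the L1 distance to their own centroid, divided by the
#' sum over points of the L1 distances to all other centroids. Small values
#' indicate tight, well-separated clusters.
#'
#' @param X the clustered data matrix.
#' @param model a `state_model`.
#' @return nonnegative scalar.
#' @export
cluster_validity_index <- function(X, model) {
  stopifnot(inherits(model, "state_model"))
  X <- as.matrix(X)
  if (anyDuplicated(model$centroids))
    stopf("coincident centroids: validity index undefined")
  D <- .l1_dist_to_centroids(X, model$centroids)
  own <- D[cbind(seq_len(nrow(X)), model$labels)]
  between <- sum(D) - sum(own)
  if (between <= 0)
    stopf("coincident centroids: between-cluster distance is zero, validity index undefined")
  sum(own) / between
}

#' Elbow selection of the number of states
#'
#' Picks the k with the greatest curvature of the validity index, i.e. the
#' interior k maximising the discrete second difference
#' `index(k-1) - 2 index(k) + index(k+1)`. Ties break toward the smallest k.
#'
#' @param index_by_k named numeric vector of validity indices over
#'   consecutive k (names are the k values, e.g. `"2"` to `"6"`).
#' @return the selected k (integer).
#' @export
choose_k_elbow <- function(index_by_k) {
  ks <- as.integer(names(index_by_k))
  if (anyNA(index_by_k))
    stopf("validity index non-informative for some k: no k >= 2 cluster structure found")
  if (length(ks) < 3) stopf("need at least 3 consecutive k values")
  if (any(diff(ks) != 1)) stopf("k values must be consecutive")
  v <- as.numeric(index_by_k)
  curv <- v[seq_len(length(v) - 2)] - 2 * v[seq(2, length(v) - 1)] +
    v[seq(3, length(v))]
  interior <- ks[seq(2, length(ks) - 1)]
  # ties (within numerical noise) break toward the smallest interior k
  best <- max(curv)
  interior[which(curv >= best - 1e-9 * max(1, abs(best)))[1]]
}

#' Per-subject state metrics from a label sequence
#'
#' The four occupancy/transition statistics: (1) frequency — fraction of
#' windows per state; (2) mean dwell time — mean length (in windows) of
#' maximal runs per state, boundary-censored first/last runs included by
#' default; (3) number of transitions — number of runs minus 1; (4) mean
#' intertransition time — mean gap between consecutive transition positions
#' (a transition sits at the 1-based first window of each new run), defined
#' when there are at least 2 transitions, NA otherwise.
#'
#' @param labels integer state sequence (values in 1..k).
#' @param k number of states.
#' @param include_censored include boundary-censored first/last runs in the
#'   dwell-time average (default TRUE).
#' @return object of class `state_metrics`: list with `frequency` (length
#'   k), `mean_dwell_time` (length k, windows), `n_transitions`,
#'   `mean_intertransition_time` (windows; NA when fewer than 2
#'   transitions).
#' @export
state_metrics <- function(labels, k, include_censored = TRUE) {
  if (!length(labels)) stopf("empty label sequence")
  labels <- as.integer(labels)
  if (min(labels) < 1 || max(labels) > k)
    stopf("label %d outside 1..%d", labels[which.max(labels < 1 | labels > k)], k)
  runs <- rle(labels)
  freq <- tabulate(labels, nbins = k) / length(labels)
  run_values <- runs$values
  run_lengths <- runs$lengths
  if (!include_censored && length(run_lengths) > 2) {
    run_values <- run_values[-c(1, length(run_values))]
    run_lengths <- run_lengths[-c(1, length(run_lengths))]
  }
  dwell <- vapply(seq_len(k), function(s) {
    ls <- run_lengths[run_values == s]
    if (length(ls)) mean(ls) else NA_real_
  }, 0)
  n_trans <- length(runs$lengths) - 1L
  positions <- cumsum(runs$lengths[-length(runs$lengths)]) + 1L
  iti <- if (n_trans >= 2) mean(diff(positions)) else NA_real_
  structure(list(frequency = freq, mean_dwell_time = dwell,
                 n_transitions = n_trans, mean_intertransition_time = iti),
            class = "state_metrics")
}

# shared core: pool per-subject row matrices, cluster over a k range,
# pick k by elbow, split labels back per subject and compute metrics
fit_state_model <- function(rows_by_subject, k_range = 2:6, k = NULL,
                            n_restarts = 500, seed = 1,
                            include_censored = TRUE) {
  if (length(rows_by_subject) < 2) stopf("need at least 2 subjects")
  Ds <- vapply(rows_by_subject, ncol, 1L)
  if (length(unique(Ds)) != 1)
    stopf("subjects have differing pattern dimension: %s",
          paste(unique(Ds), collapse = ", "))
  X <- do.call(rbind, rows_by_subject)
  sizes <- vapply(rows_by_subject, nrow, 1L)
  subj <- rep(names(rows_by_subject), sizes)

  models <- list()
  validity <- numeric(0)
  for (kk in k_range) {
    models[[as.character(kk)]] <- kmeans_manhattan(X, kk, n_restarts = n_restarts,
                                                   seed = seed + kk)
    validity[as.character(kk)] <- models[[as.character(kk)]]$validity_index
  }
  chosen_k <- if (is.null(k)) choose_k_elbow(validity) else as.integer(k)
  model <- models[[as.character(chosen_k)]]

  idx_end <- cumsum(sizes)
  idx_start <- idx_end - sizes + 1
  labels_by_subject <- stats::setNames(
    lapply(seq_along(sizes), function(i) model$labels[idx_start[i]:idx_end[i]]),
    names(rows_by_subject))
  metrics_list <- lapply(labels_by_subject, state_metrics, k = chosen_k,
                         include_censored = include_censored)
  metrics <- do.call(rbind, lapply(names(metrics_list), function(id) {
    m <- metrics_list[[id]]
    data.frame(subject = id, state = seq_len(chosen_k),
               frequency = m$frequency, mean_dwell_time = m$mean_dwell_time)
  }))
  subject_summary <- do.call(rbind, lapply(names(metrics_list), function(id) {
    m <- metrics_list[[id]]
    data.frame(subject = id, n_transitions = m$n_transitions,
               mean_intertransition_time = m$mean_intertransition_time)
  }))
  list(model = model, k = chosen_k, validity_by_k = validity,
       labels_by_subject = labels_by_subject, metrics = metrics,
       subject_summary = subject_summary)
}

#' Cohort-level brain-state analysis of windowed connectivity
#'
#' Pools the vectorised strict-upper-triangle Fisher-z patterns of all
#' subjects' windows, clusters them with Manhattan k-means over `k_range`,
#' selects k by the elbow criterion (unless `k` is given), splits the labels
#' back per subject in temporal order and computes the four state metrics.
#'
#' @param stacks list of `window_stack` objects (one per subject; same N).
#' @param k_range candidate numbers of states (default 2:6).
#' @param k fixed number of states, bypassing the elbow (default NULL).
#' @param n_restarts k-means restarts (default 500).
#' @param seed integer seed.
#' @param include_censored dwell-time convention, see [state_metrics()].
#' @return list with `model` (`state_model` at the chosen k), `k`,
#'   `validity_by_k`, `labels_by_subject`, `metrics` (subject x state
#'   frequency/dwell table) and `subject_summary` (transition counts and
#'   intertransition times).
#' @export
cohort_state_analysis <- function(stacks, k_range = 2:6, k = NULL,
                                  n_restarts = 500, seed = 1,
                                  include_censored = TRUE) {
  Ns <- vapply(stacks, function(s) dim(s$z)[2], 1L)
  if (length(unique(Ns)) != 1)
    stopf("subjects have differing network counts: %s",
          paste(unique(Ns), collapse = ", "))
  rows <- lapply(stacks, function(s) {
    W <- dim(s$z)[1]
    t(vapply(seq_len(W), function(w) vec_upper_tri(s$z[w, , ]),
             numeric(Ns[1] * (Ns[1] - 1) / 2)))
  })
  names(rows) <- vapply(stacks, function(s) s$subject_id, "")
  fit_state_model(rows, k_range = k_range, k = k, n_restarts = n_restarts,
                  seed = seed, include_censored = include_censored)
}

#' Fold a state centroid back into a connectivity matrix
#'
#' @param model a `state_model` fitted on vectorised upper-triangle patterns.
#' @param state state index.
#' @param n_networks matrix dimension N.
#' @return symmetric N x N matrix with zero diagonal.
#' @export
state_centroid_matrix <- function(model, state, n_networks) {
  unfold_upper_tri(model$centroids[state, ], n_networks)
}

#' Align estimated state labels to a reference labelling
#'
#' Searches all permutations of 1..k for the one maximising agreement with
#' the reference sequence; used to score planted-state recovery.
#'
#' @param reference integer reference sequence.
#' @param estimated integer estimated sequence, same length.
#' @param k number of states.
#' @return list with `agreement` (fraction matched under the best
#'   permutation) and `permutation` (estimated label -> reference label map).
#' @export
match_state_labels <- function(reference, estimated, k) {
  if (length(reference) != length(estimated))
    stopf("sequences differ in length")
  perms <- permutations_of(k)
  best <- 0; best_p <- perms[[1]]
  for (p in perms) {
    agree <- mean(p[estimated] == reference)
    if (agree > best) { best <- agree; best_p <- p }
  }
  list(agreement = best, permutation = best_p)
}

permutations_of <- function(k) {
  if (k == 1) return(list(1L))
  sub <- permutations_of(k - 1)
  out <- list()
  for (p in sub)
    for (pos in seq_len(k))
      out[[length(out) + 1]] <- append(p, k, after = pos - 1)
  out
}
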