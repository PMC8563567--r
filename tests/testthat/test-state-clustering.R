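test_that("Manhattan k-means separates well-separated clouds", {
  set.seed(1)
  X <- rbind(matrix(rnorm(40, 0, 0.05), 20, 2),
             matrix(rnorm(40, 10, 0.05), 20, 2))
  km <- kmeans_manhattan(X, 2, n_restarts = 20, seed = 3)
  expect_length(unique(km$labels[1:20]), 1)
  expect_length(unique(km$labels[21:40]), 1)
  # centroids within 0.1 (L1) of the cloud medians
  med1 <- apply(X[1:20, ], 2, median); med2 <- apply(X[21:40, ], 2, median)
  d <- min(sum(abs(km$centroids[1, ] - med1)) + sum(abs(km$centroids[2, ] - med2)),
           sum(abs(km$centroids[1, ] - med2)) + sum(abs(km$centroids[2, ] - med1)))
  expect_lt(d, 0.2)
  # clusters reported in descending frequency order
  expect_true(all(diff(tabulate(km$labels, km$k)) <= 0))
})

test_that("k-means attains the exhaustive-partition optimum at small M", {
  # brute force over all 2-partitions with coordinate-wise median centroids
  l1_partition_objective <- function(X, assign) {
    obj <- 0
    for (g in unique(assign)) {
      rows <- X[assign == g, , drop = FALSE]
      ctr <- apply(rows, 2, median)
      obj <- obj + sum(abs(sweep(rows, 2, ctr)))
    }
    obj
  }
  for (seed in 1:3) {
    set.seed(seed)
    X <- matrix(rnorm(16), 8, 2)
    best <- Inf
    for (code in 1:(2^8 - 2)) {
      assign <- as.integer(intToBits(code))[1:8]
      if (length(unique(assign)) < 2) next
      best <- min(best, l1_partition_objective(X, assign))
    }
    km <- kmeans_manhattan(X, 2, n_restarts = 50, seed = seed)
    expect_equal(km$objective, best, tolerance = 1e-9)
  }
})

test_that("k-means is invariant to duplicating the dataset", {
  set.seed(4)
  X <- rbind(matrix(rnorm(30, 0, 0.2), 15, 2),
             matrix(rnorm(30, 5, 0.2), 15, 2))
  km1 <- kmeans_manhattan(X, 2, n_restarts = 30, seed = 1)
  km2 <- kmeans_manhattan(rbind(X, X), 2, n_restarts = 30, seed = 2)
  expect_equal(km1$centroids[order(km1$centroids[, 1]), ],
               km2$centroids[order(km2$centroids[, 1]), ], tolerance = 1e-10)
})

test_that("the Lloyd objective never increases within a run", {
  set.seed(9)
  X <- matrix(rnorm(600), 200, 3)
  km <- kmeans_manhattan(X, 3, n_restarts = 5, seed = 7)
  expect_true(all(diff(km$objective_trace) <= 1e-9))
})

test_that("the validity index is within over between distance", {
  model <- structure(list(k = 2L, centroids = matrix(c(0.5, 10.5), 2, 1),
                          labels = c(1L, 1L, 2L, 2L), objective = 2,
                          objective_trace = 2, validity_index = NA_real_),
                     class = "state_model")
  X <- matrix(c(0, 1, 10, 11), 4, 1)
  expect_equal(cluster_validity_index(X, model), 2 / 40)

  # index decreases when clusters move farther apart
  model_far <- model
  model_far$centroids <- matrix(c(0.5, 100.5), 2, 1)
  X_far <- matrix(c(0, 1, 100, 101), 4, 1)
  expect_lt(cluster_validity_index(X_far, model_far),
            cluster_validity_index(X, model))

  # two infinitely tight clusters far apart: index tends to 0
  model_tight <- model
  model_tight$centroids <- matrix(c(0, 1000), 2, 1)
  expect_lt(cluster_validity_index(matrix(c(0, 0, 1000, 1000), 4, 1),
                                   model_tight), 1e-12)

  model_bad <- model
  model_bad$centroids <- matrix(c(1, 1), 2, 1)
  expect_error(cluster_validity_index(X, model_bad), "coincident")
})

test_that("elbow selection maximises discrete curvature", {
  expect_equal(choose_k_elbow(c(`2` = 1.0, `3` = 0.3, `4` = 0.28, `5` = 0.27)), 3)
  # linear decline: curvature ties, smallest interior k wins
  expect_equal(choose_k_elbow(c(`2` = 1.0, `3` = 0.8, `4` = 0.6, `5` = 0.4)), 3)
  expect_error(choose_k_elbow(c(`2` = 1, `3` = 0.5)), "at least 3")
})

test_that("state metrics match hand counts", {
  m <- state_metrics(c(1, 1, 2, 2, 2, 1), 2)
  expect_equal(m$frequency, c(0.5, 0.5))
  expect_equal(m$n_transitions, 2)
  expect_equal(m$mean_dwell_time, c(1.5, 3))

  m0 <- state_metrics(rep(3L, 4), 3)
  expect_equal(m0$n_transitions, 0)
  expect_equal(m0$frequency[3], 1)
  expect_true(is.na(m0$mean_intertransition_time))

  m2 <- state_metrics(c(1, 2, 1, 2, 1), 2)
  expect_equal(m2$n_transitions, 4)
  expect_equal(m2$mean_intertransition_time, 1)

  expect_error(state_metrics(c(1, 5), 3), "outside")
})

test_that("state metrics are equivariant under relabelling", {
  set.seed(11)
  labels <- sample(1:3, 60, replace = TRUE)
  perm <- c(3, 1, 2)
  m <- state_metrics(labels, 3)
  mp <- state_metrics(perm[labels], 3)
  expect_equal(mp$frequency[perm], m$frequency)
  expect_equal(mp$mean_dwell_time[perm], m$mean_dwell_time)
  expect_equal(mp$n_transitions, m$n_transitions)
  expect_equal(mp$mean_intertransition_time, m$mean_intertransition_time)
  # run/transition identity
  expect_equal(length(rle(labels)$lengths) - 1, m$n_transitions)
})

test_that("boundary-censored runs can be excluded from dwell times", {
  lbl <- c(1, 1, 2, 2, 2, 1, 1, 1, 1)
  inc <- state_metrics(lbl, 2, include_censored = TRUE)
  exc <- state_metrics(lbl, 2, include_censored = FALSE)
  expect_equal(inc$mean_dwell_time, c(3, 3))   # runs 2,4 and 3
  expect_equal(exc$mean_dwell_time, c(NA_real_, 3))
})

test_that("cohort state analysis keeps per-subject bookkeeping straight", {
  coh <- tiny_cohort(seed = 2, n_per_group = 2, n_networks = 5, n_volumes = 80)
  stacks <- lapply(coh$timecourses, subject_window_stack,
                   spec = taper_spec(12, 3, 1), lambda = 0.05)
  fit <- cohort_state_analysis(stacks, k = 3, n_restarts = 5, seed = 1)
  # frequencies per subject sum to 1
  sums <- tapply(fit$metrics$frequency, fit$metrics$subject, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  # labels split back in original length and order
  expect_equal(lengths(fit$labels_by_subject),
               setNames(rep(69L, 4), names(fit$labels_by_subject)))

  # degenerate: identical patterns everywhere cannot support k >= 2 structure
  z <- stacks[[1]]$z
  for (w in seq_len(dim(z)[1])) z[w, , ] <- z[1, , ]
  const_stack <- stacks[[1]]; const_stack$z <- z
  s2 <- const_stack; s2$subject_id <- "other"
  expect_error(suppressWarnings(
    cohort_state_analysis(list(const_stack, s2), k_range = 2:4,
                          n_restarts = 3, seed = 1)),
    "non-informative|structure")
})
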