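test_that("the taper is the rectangle-Gaussian convolution", {
  w <- build_taper(taper_spec(22, 3, 1))
  expect_length(w, 22)
  expect_true(all(w >= 0))
  expect_equal(sum(w), 1)
  expect_lt(max(abs(w - rev(w))), 1e-12)          # symmetric
  expect_true(all(diff(w[1:11]) >= -1e-12))       # unimodal rise to the middle

  # sigma -> 0: the Gaussian is a delta, weights become uniform
  w0 <- build_taper(taper_spec(10, 1e-8, 1))
  expect_equal(w0, rep(1 / 10, 10))

  # L = 4, sigma = 1: brute-force double-sum convolution oracle
  L <- 4; sigma <- 1; R <- ceiling(4 * sigma)
  kern <- exp(-((-R):R)^2 / (2 * sigma^2)); kern <- kern / sum(kern)
  full <- rep(0, L + 2 * R)
  for (i in seq_len(L))
    for (j in seq_along(kern))
      full[i + j - 1] <- full[i + j - 1] + kern[j]
  oracle <- full[(R + 1):(R + L)]; oracle <- oracle / sum(oracle)
  expect_equal(build_taper(taper_spec(4, 1, 1)), oracle, tolerance = 1e-12)
})

test_that("window enumeration matches the closed-form count", {
  expect_equal(nrow(enumerate_windows(290, taper_spec(22, 3, 1))), 269)
  expect_equal(nrow(enumerate_windows(22, taper_spec(22, 3, 1))), 1)
  expect_equal(nrow(enumerate_windows(10, taper_spec(3, 1, 2))), 4)
  expect_error(enumerate_windows(10, taper_spec(22, 3, 1)), "at least")

  # property: floor((T - L)/step) + 1 over random triples vs enumeration
  set.seed(5)
  for (i in 1:25) {
    L <- sample(2:30, 1); step <- sample(1:5, 1); T <- L + sample(0:100, 1)
    win <- enumerate_windows(T, taper_spec(L, 2, step))
    expect_equal(nrow(win), floor((T - L) / step) + 1)
    expect_true(all(win$end - win$start + 1 == L))
    expect_true(all(win$end <= T))
  }
})

test_that("windowed covariance equals the brute-force weighted sums", {
  set.seed(6)
  X <- matrix(rnorm(22 * 5), 22, 5)
  taper <- build_taper(taper_spec(22, 3, 1))
  S <- windowed_covariance(X, c(1, 22), taper)
  # element-wise direct computation
  w <- taper / sum(taper)
  mu <- colSums(X * w)
  oracle <- matrix(0, 5, 5)
  for (a in 1:5) for (b in 1:5)
    oracle[a, b] <- sum(w * (X[, a] - mu[a]) * (X[, b] - mu[b]))
  expect_equal(S, oracle, tolerance = 1e-12, ignore_attr = TRUE)

  # uniform taper reduces to the ordinary biased sample covariance
  Su <- windowed_covariance(X, c(1, 22), rep(1, 22))
  expect_equal(Su, cov(X) * 21 / 22, tolerance = 1e-12, ignore_attr = TRUE)

  # two identical columns give correlation 1 after normalisation
  Y <- cbind(X[, 1], X[, 1], X[, 2])
  Sy <- windowed_covariance(Y, c(1, 22), taper)
  expect_equal(stats::cov2cor(Sy)[1, 2], 1)
})

test_that("graphical LASSO satisfies its optimality conditions", {
  # lambda = 0: unpenalised maximum likelihood, Theta = solve(S)
  for (n in c(3, 6, 10)) {
    S <- random_spd(n, seed = n)
    est <- glasso_precision(S, 0)
    expect_lt(max(abs(est$theta - solve(S))) / max(abs(solve(S))), 1e-6)
  }

  # diagonal S: Theta diagonal with 1/S_ii, any lambda
  ed <- glasso_precision(diag(c(2, 3, 4)), 0.7)
  expect_equal(diag(ed$theta), 1 / c(2, 3, 4))
  expect_equal(max(abs(ed$theta[upper.tri(ed$theta)])), 0)

  # heavy penalty saturates all off-diagonal entries to exactly 0
  S <- diag(3); S[1, 2] <- S[2, 1] <- 0.3; S[1, 3] <- S[3, 1] <- 0.2
  es <- glasso_precision(S, 10 * 0.3)
  expect_true(all(es$theta[upper.tri(es$theta)] == 0))

  # KKT stationarity on random problems: |Theta^-1 - S| <= lambda off the
  # diagonal (equality with the right sign where Theta_ij != 0), and
  # Theta^-1 matching S on the diagonal; Theta positive-definite
  for (seed in 1:5) {
    S <- random_spd(6, seed = 100 + seed)
    lam <- 0.1
    est <- glasso_precision(S, lam)
    G <- solve(est$theta) - S
    expect_lt(max(abs(diag(G))), 1e-4)
    off <- upper.tri(G)
    expect_lt(max(abs(G[off])), lam + 1e-4)
    active <- off & est$theta != 0
    if (any(active))
      expect_lt(max(abs(abs(G[active]) - lam)), 1e-4)
    expect_gt(min(eigen(est$theta, only.values = TRUE)$values), 0)
  }

  expect_error(glasso_precision(matrix(1, 3, 3), 0), "singular")
})

test_that("cross-validated lambda selection favours sparsity under a sparse truth", {
  # chain precision: sparse truth; lambda = 0 overfits per-window covariances
  chosen <- vapply(1:10, function(rep) {
    set.seed(400 + rep)
    Theta <- diag(6)
    for (i in 1:5) Theta[i, i + 1] <- Theta[i + 1, i] <- 0.4
    Sigma <- solve(Theta)
    covs <- lapply(1:20, function(i) {
      X <- matrix(rnorm(15 * 6), 15, 6) %*% chol(Sigma)
      crossprod(scale(X, scale = FALSE)) / 15
    })
    select_lambda_cv(covs, grid = c(0, 0.02, 0.05, 0.1, 0.2), n_folds = 20)
  }, 0)
  expect_gte(mean(chosen > 0), 0.9)

  covs <- lapply(1:20, function(i) random_spd(3, seed = i))
  expect_equal(select_lambda_cv(covs, grid = 0.3), 0.3)
  # duplicate grid entries tie; the tie rule returns the larger lambda
  expect_equal(select_lambda_cv(covs, grid = c(0.2, 0.2)), 0.2)
  expect_error(select_lambda_cv(covs[1:5], grid = 0.1, n_folds = 20), "fold")
})

test_that("precision converts to Fisher-z correlations", {
  # r = 0.5 gives z = atanh(0.5) = log(3)/2
  S <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  z <- precision_to_z(glasso_precision(S, 0))
  expect_equal(z[1, 2], log(3) / 2, tolerance = 1e-10)
  expect_equal(diag(z), c(0, 0))

  # odd function: z(-r) = -z(r)
  Sm <- matrix(c(1, -0.5, -0.5, 1), 2, 2)
  expect_equal(precision_to_z(glasso_precision(Sm, 0))[1, 2], -z[1, 2])

  # oracle equivalence at lambda = 0: Fisher z of the plain correlation
  S6 <- random_spd(6, seed = 12)
  z6 <- precision_to_z(glasso_precision(S6, 0))
  ref <- atanh(stats::cov2cor(S6)); diag(ref) <- 0
  expect_lt(max(abs(z6 - ref)), 1e-5)
})

test_that("windowed correlations recover a planted single-state correlation", {
  # mean windowed correlation approaches the planted value (small bias at L=22)
  Sig <- diag(3); Sig[1, 2] <- Sig[2, 1] <- 0.6
  biases <- vapply(1:10, function(seed) {
    set.seed(seed)
    X <- matrix(rnorm(290 * 3), 290, 3) %*% chol(Sig)
    st <- subject_window_stack(network_timecourses(X), lambda = 0.01)
    mean(tanh(st$z[, 1, 2])) - 0.6
  }, 0)
  expect_lt(abs(mean(biases)), 0.05)
})

test_that("edge residualisation removes covariate effects only", {
  set.seed(20)
  n <- 40
  design <- data.frame(age = runif(n, 65, 85),
                       sex = sample(c("F", "M"), n, TRUE))
  # values exactly linear in age: residual variance collapses
  v <- cbind(3 + 0.5 * design$age, 1 - 0.2 * design$age)
  res <- residualize_edges(v, design)
  expect_lt(var(res[, 1]) / var(v[, 1]), 1e-12)
  # scale preserved: the grand mean survives
  expect_equal(colMeans(res), colMeans(v))

  # covariates unrelated to the values: residuals ~ centered inputs
  set.seed(21)
  n <- 200
  design2 <- data.frame(age = runif(n, 65, 85), sex = sample(c("F", "M"), n, TRUE))
  v2 <- cbind(rnorm(n))
  res2 <- residualize_edges(v2, design2)
  expect_gt(cor(res2[, 1], v2[, 1] - mean(v2[, 1])), 0.99)

  expect_error(residualize_edges(matrix(1, 1, 2),
                                 data.frame(age = 70, sex = "F")), "at least 3")
  expect_warning(residualize_edges(v2, transform(design2, sex = "F")),
                 "constant covariate")
})

test_that("variability metrics follow their definitions", {
  set.seed(29)
  z0 <- array(0, dim = c(5, 4, 4))
  m <- matrix(rnorm(16), 4, 4); m <- m + t(m); diag(m) <- 0
  for (w in 1:5) z0[w, , ] <- m
  v0 <- connectivity_variability(z0)
  expect_equal(v0$global_mean_sd, 0)
  expect_true(all(v0$per_edge_sd == 0))

  # one alternating edge, others constant
  a <- 0.7
  z1 <- array(0, dim = c(4, 4, 4))
  for (w in 1:4) {
    z1[w, 1, 2] <- z1[w, 2, 1] <- a * (-1)^w
  }
  v1 <- connectivity_variability(z1)
  expect_equal(v1$per_edge_sd[1, 2], a * sqrt(4 / 3))
  expect_equal(v1$global_mean_sd, a * sqrt(4 / 3) / 6)  # 6 upper-tri edges

  # definitional identity and permutation equivariance on random stacks
  set.seed(30)
  z2 <- array(rnorm(10 * 5 * 5), dim = c(10, 5, 5))
  for (w in 1:10) {
    z2[w, , ] <- z2[w, , ] + t(z2[w, , ]); diag(z2[w, , ]) <- 0
  }
  v2 <- connectivity_variability(z2)
  expect_equal(v2$global_mean_sd, mean(v2$per_edge_sd[upper.tri(v2$per_edge_sd)]),
               tolerance = 1e-12)
  perm <- c(3, 1, 5, 2, 4)
  v2p <- connectivity_variability(z2[, perm, perm])
  expect_equal(v2p$per_edge_sd, v2$per_edge_sd[perm, perm], ignore_attr = TRUE)
  expect_equal(v2p$global_mean_sd, v2$global_mean_sd)

  expect_error(connectivity_variability(z2[1, , , drop = FALSE]), "at least 2")
})

test_that("upper-triangle vectorisation round-trips", {
  m <- matrix(1:25, 5, 5); m <- m + t(m); diag(m) <- 0
  v <- vec_upper_tri(m)
  expect_equal(v[1:4], m[1, 2:5])       # row-major order
  expect_equal(unfold_upper_tri(v, 5), m)
})
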