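test_that("full-correlation netmats behave at scale", {
  set.seed(1)
  # duplicated column: |r| = 1, Fisher z infinite
  x <- rnorm(100)
  expect_error(full_correlation_z(cbind(x, x)), "infinite|perfectly")

  # independent white noise at T = 50000: all |z| small
  X <- matrix(rnorm(50000 * 4), ncol = 4)
  z <- full_correlation_z(X)
  expect_lt(max(abs(z)), 0.03)

  # planted r = 0.6 recovered on the z scale
  Sig <- diag(3); Sig[1, 2] <- Sig[2, 1] <- 0.6
  Y <- matrix(rnorm(50000 * 3), ncol = 3) %*% chol(Sig)
  expect_lt(abs(full_correlation_z(Y)[1, 2] - atanh(0.6)), 0.05)

  expect_error(full_correlation_z(cbind(rnorm(50), rep(1, 50))), "zero-variance")
})

test_that("partial correlations remove indirect chain links", {
  # X -> Y -> Z: conditionally independent given Y
  set.seed(2)
  T <- 50000
  x <- rnorm(T); y <- 0.8 * x + rnorm(T, sd = 0.6); z <- 0.8 * y + rnorm(T, sd = 0.6)
  tc <- cbind(x, y, z)
  pz <- partial_correlation_z(tc, ridge = 0)
  fz <- full_correlation_z(tc)
  expect_lt(abs(pz[1, 3]), 0.03)
  expect_gt(abs(fz[1, 3]), 0.3)

  # N = 2: partial equals full
  tc2 <- cbind(x, y)
  expect_equal(partial_correlation_z(tc2, ridge = 0)[1, 2],
               full_correlation_z(tc2)[1, 2], tolerance = 1e-10)

  # analytic identity covariance: all partials 0
  expect_equal(partial_z_from_cov(diag(3)), matrix(0, 3, 3))
})

test_that("the permutation group test is deterministic and coherent", {
  set.seed(3)
  tcs <- lapply(1:12, function(i)
    network_timecourses(matrix(rnorm(80 * 4), 80, 4), subject_id = paste0("s", i)))
  design <- data.frame(subject_id = paste0("s", 1:12),
                       group = rep(c("A", "B"), each = 6),
                       age = runif(12, 65, 85),
                       sex = rep(c("F", "M"), 6))
  nm <- lapply(tcs, static_netmat)
  r1 <- permutation_group_test(nm, design, n_permutations = 100, seed = 5)
  r2 <- permutation_group_test(nm, design, n_permutations = 100, seed = 5)
  expect_identical(r1$results, r2$results)

  # corrected p-values never undercut uncorrected ones, and never reach 0
  expect_true(all(r1$results$p_fwe >= r1$results$p_uncorrected))
  expect_true(all(r1$results$p_fwe >= 1 / 100))
  # six contrasts for three groups, both correlation types
  design3 <- design; design3$group <- rep(c("A", "B", "C"), each = 4)
  r3 <- permutation_group_test(nm, design3, n_permutations = 50, seed = 1)
  expect_setequal(unique(r3$results$contrast),
                  c("A>B", "B>A", "A>C", "C>A", "B>C", "C>B"))
  expect_setequal(unique(r3$results$correlation_type), c("full", "partial"))
  # signed pairs carry opposite t but the same two-sided p
  ab <- subset(r3$results, contrast == "A>B" & correlation_type == "full")
  ba <- subset(r3$results, contrast == "B>A" & correlation_type == "full")
  expect_equal(ab$t, -ba$t)
  expect_equal(ab$p_fwe, ba$p_fwe)

  expect_error(permutation_group_test(nm[1:3],
                                      data.frame(subject_id = paste0("s", 1:3),
                                                 group = c("A", "A", "B"),
                                                 age = c(70, 71, 72),
                                                 sex = c("F", "M", "F")),
                                      n_permutations = 10),
               "at least 2 subjects")
})

test_that("the test statistic ignores affine covariate rescaling", {
  set.seed(6)
  tcs <- lapply(1:12, function(i)
    network_timecourses(matrix(rnorm(60 * 3), 60, 3), subject_id = paste0("s", i)))
  nm <- lapply(tcs, static_netmat)
  design <- data.frame(subject_id = paste0("s", 1:12),
                       group = rep(c("A", "B"), each = 6),
                       age = runif(12, 65, 85), sex = rep(c("F", "M"), 6))
  design_scaled <- design
  design_scaled$age <- (design$age - 70) / 10
  r1 <- permutation_group_test(nm, design, n_permutations = 50, seed = 2)
  r2 <- permutation_group_test(nm, design_scaled, n_permutations = 50, seed = 2)
  expect_equal(r1$results$t, r2$results$t, tolerance = 1e-10)
})

test_that("a strong planted group shift is detected after FWE correction", {
  set.seed(7)
  detections <- vapply(1:10, function(rep) {
    Sg <- diag(5); Sg[1, 2] <- Sg[2, 1] <- 0.6
    tcs <- lapply(1:40, function(i) {
      Sig <- if (i > 20) Sg else diag(5)
      network_timecourses(matrix(rnorm(200 * 5), 200, 5) %*% chol(Sig),
                          subject_id = paste0("s", i))
    })
    design <- data.frame(subject_id = paste0("s", 1:40),
                         group = rep(c("A", "B"), each = 20),
                         age = runif(40, 65, 85),
                         sex = sample(c("F", "M"), 40, TRUE))
    res <- permutation_group_test(lapply(tcs, static_netmat), design,
                                  n_permutations = 200,
                                  seed = sample.int(1e6, 1))
    r <- res$results
    min(r$p_fwe[r$edge_i == 1 & r$edge_j == 2 &
                  r$correlation_type == "full"]) < 0.05
  }, TRUE)
  expect_gte(mean(detections), 0.9)
})
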