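test_that("identical group means give T2 = 0 and P = 1", {
  set.seed(1)
  a <- matrix(rnorm(30), 15, 2)
  b <- a[rev(seq_len(nrow(a))), ]  # same rows, so identical mean vector
  fit <- hotelling_t2(a, b)
  expect_equal(fit$t2, 0)
  expect_equal(fit$p_value, 1)
})

test_that("for p = 1, T2 equals the squared pooled-variance t statistic", {
  set.seed(42)
  for (i in 1:100) {
    n1 <- sample(3:40, 1); n2 <- sample(3:40, 1)
    x <- rnorm(n1, mean = runif(1, -2, 2), sd = runif(1, 0.5, 2))
    y <- rnorm(n2, mean = runif(1, -2, 2), sd = runif(1, 0.5, 2))
    fit <- hotelling_t2(matrix(x), matrix(y))
    tt <- t.test(x, y, var.equal = TRUE)
    expect_equal(fit$t2, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(fit$p_value, tt$p.value, tolerance = 1e-10)
  }
})

test_that("a fixed 2-D dataset matches the long-form formula", {
  # deterministic data; oracle written out with the explicit 2x2 inverse
  x <- cbind(c(1.2, 0.8, 1.5, 0.9, 1.1, 1.3, 0.7, 1.0, 1.4, 0.6),
             c(2.1, 1.9, 2.4, 1.8, 2.0, 2.2, 1.7, 2.0, 2.3, 1.6))
  y <- cbind(c(0.9, 0.5, 1.1, 0.7, 0.8, 1.0, 0.4, 0.6, 1.2, 0.3),
             c(1.5, 1.2, 1.8, 1.4, 1.3, 1.6, 1.1, 1.3, 1.9, 1.0))
  n1 <- nrow(x); n2 <- nrow(y); p <- 2
  m1 <- colMeans(x); m2 <- colMeans(y); dm <- m1 - m2
  A <- crossprod(sweep(x, 2, m1)) + crossprod(sweep(y, 2, m2))
  S <- A / (n1 + n2 - 2)
  det_s <- S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1]
  Sinv <- matrix(c(S[2, 2], -S[2, 1], -S[1, 2], S[1, 1]), 2, 2) / det_s
  quad <- dm[1]^2 * Sinv[1, 1] + 2 * dm[1] * dm[2] * Sinv[1, 2] +
    dm[2]^2 * Sinv[2, 2]
  t2_oracle <- n1 * n2 / (n1 + n2) * quad
  f_oracle <- t2_oracle * (n1 + n2 - p - 1) / (p * (n1 + n2 - 2))
  p_oracle <- pf(f_oracle, p, n1 + n2 - p - 1, lower.tail = FALSE)
  fit <- hotelling_t2(x, y)
  expect_equal(fit$t2, t2_oracle, tolerance = 1e-12)
  expect_equal(fit$f_stat, f_oracle, tolerance = 1e-12)
  expect_equal(fit$p_value, p_oracle, tolerance = 1e-12)
  expect_equal(fit$df1, 2L)
  expect_equal(fit$df2, n1 + n2 - 3L)
})

test_that("T2 is invariant under common affine maps and label swaps", {
  set.seed(7)
  for (i in 1:10) {
    x <- matrix(rnorm(60), 20, 3)
    y <- matrix(rnorm(45, mean = 0.4), 15, 3)
    base <- hotelling_t2(x, y)
    A <- matrix(rnorm(9), 3, 3) + diag(3)     # invertible w.h.p.
    b <- rnorm(3)
    tx <- sweep(x %*% A, 2, b, "+"); ty <- sweep(y %*% A, 2, b, "+")
    expect_equal(hotelling_t2(tx, ty)$t2, base$t2, tolerance = 1e-8)
    swapped <- hotelling_t2(y, x)
    expect_equal(swapped$t2, base$t2, tolerance = 1e-12)
    expect_equal(swapped$p_value, base$p_value, tolerance = 1e-12)
  }
})

test_that("the F transform and its degrees of freedom are consistent", {
  set.seed(3)
  x <- matrix(rnorm(80), 40, 2); y <- matrix(rnorm(60, 1), 30, 2)
  fit <- hotelling_t2(x, y)
  expect_equal(fit$f_stat,
               fit$t2 * (fit$n1 + fit$n2 - fit$p - 1) /
                 (fit$p * (fit$n1 + fit$n2 - 2)), tolerance = 1e-12)
  # p_value decreases as t2 increases, all else equal
  y2 <- sweep(y, 2, c(2, 2), "+")
  fit2 <- hotelling_t2(x, y2)
  expect_gt(fit2$t2, fit$t2)
  expect_lt(fit2$p_value, fit$p_value)
})

test_that("degenerate inputs are rejected with guidance", {
  x <- matrix(rnorm(20), 10, 2)
  expect_error(hotelling_t2(x[1, , drop = FALSE], x), "at least 2")
  # duplicated coordinate column -> singular pooled covariance
  xs <- cbind(x, x[, 1]); ys <- cbind(x + 1, x[, 1] + 1)
  expect_error(hotelling_t2(xs, ys), "singular")
  expect_error(hotelling_t2(matrix(rnorm(4), 2), matrix(rnorm(6), 2, 3)),
               "same dimension")
  expect_error(hotelling_t2(matrix(rnorm(6), 2, 3), matrix(rnorm(6), 2, 3)),
               "too few")
})

test_that("separation_report splits MDS coordinates by phenotype", {
  # planted common-variant divergence: strong, detectable separation
  sim <- simulate_cohort(n_cases = 40, n_controls = 40, n_common = 400,
                         n_low_freq = 0, n_rare = 0,
                         affected_fraction = c(common = 1), effect_size = 1.4,
                         seed = 99)
  d <- pairwise_distances(sim$genotypes, metric = "hamming")
  mds <- classical_mds(d, k = 2, input = "squared")
  fit <- suppressMessages(separation_report(mds, sim$phenotypes, dims = 2))
  expect_s3_class(fit, "hotelling_test")
  expect_lt(fit$p_value, 0.05)
  expect_equal(fit$n1, 40L); expect_equal(fit$n2, 40L)

  # permuted labels kill the separation signal (fixed permutation)
  set.seed(123)
  perm <- phenotype_table(sim$phenotypes$sample_id,
                          sample(as.character(sim$phenotypes$status)))
  null_fit <- suppressMessages(separation_report(mds, perm, dims = 2))
  expect_gt(null_fit$p_value, 1e-4)

  # a class with < 2 members errors
  tiny <- phenotype_table(sim$phenotypes$sample_id,
                          c("case", rep("control", 79)))
  expect_error(suppressMessages(separation_report(mds, tiny, dims = 2)),
               "at least 2")
  expect_error(separation_report(mds, sim$phenotypes[-1, ], dims = 2),
               "phenotype missing")
})

test_that("permuted-label P-values are uniform under the null", {
  # calibration on one fixed cohort across independent permutations
  sim <- simulate_cohort(n_cases = 30, n_controls = 30, n_common = 200,
                         n_low_freq = 0, n_rare = 0, seed = 55)
  d <- pairwise_distances(sim$genotypes, metric = "hamming")
  mds <- classical_mds(d, k = 2, input = "squared")
  set.seed(808)
  pvals <- replicate(200, {
    perm <- phenotype_table(sim$phenotypes$sample_id,
                            sample(as.character(sim$phenotypes$status)))
    suppressMessages(separation_report(mds, perm, dims = 2))$p_value
  })
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.001)
  expect_gt(mean(pvals > 0.5), 0.35)
  expect_lt(mean(pvals > 0.5), 0.65)
})
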