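test_that("analytic radius and outlier formulas evaluate correctly", {
  expect_equal(theory_gaussian_radius(1, 0), 1)
  expect_equal(theory_gaussian_radius(1, 1), 0)
  expect_equal(theory_gaussian_radius(1, 0.5), sqrt(0.5))
  expect_error(theory_gaussian_radius(1, 1.5))

  expect_equal(theory_rank_one_outlier(4, s = 0), 4)
  expect_equal(theory_rank_one_outlier(4, s = 0.5), 2)
  expect_equal(theory_rank_one_outlier(0.04, C = 200, rescaled = TRUE), 8)
  # fixed-degree parameterisation of the scaled branch
  expect_equal(theory_rank_one_outlier(4, C = 250, N = 1000),
               theory_rank_one_outlier(4, s = 0.75))
  expect_error(theory_rank_one_outlier(0.04, rescaled = TRUE), "requires `C`")

  expect_equal(theory_rank_one_bulk_radius(16, s = 0, N = 1000), 0)
  expect_equal(theory_rank_one_bulk_radius(0.09, N = 2000, C = 200,
                                           rescaled = TRUE),
               0.09 * sqrt(200 * 1800 / 2000))
  # high-sparsity limit: radius tends to sigma2 * sqrt(C) at fixed C
  lim <- theory_rank_one_bulk_radius(0.09, N = 10000000, C = 200,
                                     rescaled = TRUE)
  expect_equal(lim, 0.09 * sqrt(200), tolerance = 1e-4)
})

test_that("scaled bulk radius is symmetric in s and maximal at s = 0.5", {
  f <- function(s) theory_rank_one_bulk_radius(1, s = s, N = 1000)
  s_vals <- seq(0.05, 0.95, by = 0.05)
  expect_equal(vapply(s_vals, f, 0), vapply(1 - s_vals, f, 0))
  opt <- optimize(f, c(0, 1), maximum = TRUE)
  expect_equal(opt$maximum, 0.5, tolerance = 1e-5)
  expect_equal(f(0), 0)
  expect_equal(f(1), 0)
})

test_that("compute_spectrum returns the full closed spectrum", {
  expect_equal(compute_spectrum(matrix(0, 5, 5)), rep(0 + 0i, 5))
  rot <- matrix(c(0, -1, 1, 0), 2, 2)
  expect_equal(sort(Im(compute_spectrum(rot))), c(-1, 1), tolerance = 1e-12)
  # conjugate closure for a real random matrix
  set.seed(2)
  ev <- compute_spectrum(gaussian_matrix(60, 1))
  cplx <- ev[Im(ev) > 1e-10]
  for (z in cplx)
    expect_true(any(Mod(ev - Conj(z)) < 1e-8 * max(Mod(ev))))
  expect_error(compute_spectrum(matrix(c(1, NA, 0, 1), 2)), "finite")
  expect_error(compute_spectrum(matrix(1, 2, 3)), "square")
})

test_that("outlier/bulk separation follows the declared rule", {
  est <- estimate_outlier_and_bulk(c(2 + 0i, 0 + 0.1i, 0 - 0.1i, 0.05 + 0i))
  expect_true(est$outlier_measurable)
  expect_equal(est$outlier_hat, 2)
  expect_equal(est$bulk_radius_hat, 0.1)

  zero <- estimate_outlier_and_bulk(rep(0 + 0i, 10))
  expect_false(zero$outlier_measurable)
  expect_equal(zero$bulk_radius_hat, 0)
  expect_true(is.na(zero$outlier_hat))

  # theory outlier below the bulk: location not empirically measurable
  set.seed(31)
  cv <- connectivity_vectors(500, 0.09, 0.0005)
  W <- sparsify(rank_one_matrix(cv, rescaled = TRUE),
                sparsity_mask(500, "fixed_in_degree", C = 200))
  th <- spectral_theory("rank_one_rescaled", sigma2 = 0.09,
                        sigma_mn = 0.0005, C = 200, N = 500)
  expect_lt(th$outlier, th$bulk_radius)
  est2 <- estimate_outlier_and_bulk(compute_spectrum(W), th)
  expect_false(est2$outlier_measurable)
  expect_error(estimate_outlier_and_bulk(complex(0)), "empty")
})

test_that("the rank-one outlier persists under sparsity", {
  # empirical outlier tracks (1 - s) * overlap while separable; the
  # eigenvector residual shrinks with N
  set.seed(41)
  for (s in c(0.2, 0.5)) {
    cv <- connectivity_vectors(800, 16, 4)
    P <- sparsify(rank_one_matrix(cv), sparsity_mask(800, "bernoulli", s = s))
    est <- estimate_outlier_and_bulk(compute_spectrum(P))
    expect_true(est$outlier_measurable)
    expect_equal(est$outlier_hat, (1 - s) * overlap(cv), tolerance = 0.1)
  }
  res <- vapply(c(500, 2000), function(N) {
    cv <- connectivity_vectors(N, 16, 4)
    P <- sparsify(rank_one_matrix(cv), sparsity_mask(N, "bernoulli", s = 0.5))
    lam <- 0.5 * overlap(cv)
    sqrt(sum((as.numeric(P$W %*% cv$m) - lam * cv$m)^2)) /
      (sqrt(sum(cv$m^2)) * abs(lam))
  }, 0)
  expect_lt(res[2], res[1])
})

test_that("deflation removes the outlier and leaves the predicted bulk", {
  set.seed(51)
  cv <- connectivity_vectors(600, 16, 4)
  P <- rank_one_matrix(cv)
  # s = 0: nothing was removed, the deflated matrix vanishes
  expect_equal(deflate_outlier(P, P, 0)$W, matrix(0, 600, 600))

  # entrywise variance sigma^4 s(1-s)/N^2 within 3 SE over instances
  v <- replicate(10, {
    cv_i <- connectivity_vectors(600, 16, 4)
    P_i <- rank_one_matrix(cv_i)
    Ps <- sparsify(P_i, sparsity_mask(600, "bernoulli", s = 0.5))
    var(as.numeric(deflate_outlier(Ps, P_i, 0.5)$W))
  })
  expect_lt(abs(mean(v) - 16^2 * 0.25 / 600^2), 3 * sd(v) / sqrt(10))

  # m becomes a near-null eigenvector, residual shrinking as N doubles
  res <- vapply(c(400, 800, 1600), function(N) {
    cv_i <- connectivity_vectors(N, 16, 4)
    P_i <- rank_one_matrix(cv_i)
    Ps <- sparsify(P_i, sparsity_mask(N, "bernoulli", s = 0.5))
    D <- deflate_outlier(Ps, P_i, 0.5)
    sqrt(sum(as.numeric(D$W %*% cv_i$m)^2) / sum(cv_i$m^2))
  }, 0)
  expect_true(all(diff(res) < 0))
})

test_that("empirical radii track the circular law across branches", {
  set.seed(61)
  # iid Gaussian branch: tight agreement already at moderate N
  r <- mean(replicate(3, {
    W <- sparsify(gaussian_matrix(800, 1),
                  sparsity_mask(800, "bernoulli", s = 0.5))
    estimate_outlier_and_bulk(compute_spectrum(W))$bulk_radius_hat
  }))
  expect_equal(r, theory_gaussian_radius(1, 0.5), tolerance = 0.08)

  # rank-one bulk: the law captures scale and shape; the max-modulus
  # estimator sits above the asymptotic edge at finite N (documented), so
  # the band here is wider
  bulk <- vapply(c(0.2, 0.5, 0.8), function(s) {
    mean(replicate(3, {
      cv <- connectivity_vectors(800, 16, 1.44)
      W <- sparsify(rank_one_matrix(cv),
                    sparsity_mask(800, "bernoulli", s = s))
      estimate_outlier_and_bulk(compute_spectrum(W))$bulk_radius_hat
    }))
  }, 0)
  th <- vapply(c(0.2, 0.5, 0.8),
               function(s) theory_rank_one_bulk_radius(16, s = s, N = 800), 0)
  expect_true(all(bulk / th > 0.95 & bulk / th < 1.3))
  # non-monotonic in s with the maximum at s = 0.5
  expect_gt(bulk[2], bulk[1])
  expect_gt(bulk[2], bulk[3])
})
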