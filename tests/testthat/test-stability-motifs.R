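test_that("the competition Jacobian has the required zero structure", {
  sp <- competition_spec(b1 = 1, b2 = 2, a1 = 1, a2 = 1, C_block = matrix(-1))
  J <- competition_jacobian(sp)
  expect_identical(dim(J), c(3L, 3L))
  expect_equal(J[1:2, 1:2], matrix(0, 2, 2)) # consumers: no self-interaction
  expect_equal(J[3, 1:2], c(1, 2))
  expect_equal(J[1:2, 3], c(1, 1))

  sp5 <- competition_spec(1, 2, 1, 1, C_block = random_symmetric(3))
  J5 <- competition_jacobian(sp5)
  expect_identical(dim(J5), c(5L, 5L))
  # consumer columns: only the resource row may be nonzero
  expect_true(all(J5[-3, 1:2] == 0))
})

test_that("the zero mode (b2, -b1, 0, ...) annihilates the Jacobian exactly", {
  sp <- competition_spec(1, 2, 1, 1, matrix(-1))
  zm <- localized_zero_mode(sp)
  expect_equal(zm$vector, c(2, -1, 0))
  expect_identical(zm$value, 0)
  expect_lte(zm$residual, 1e-12)

  set.seed(41)
  for (q in 1:50) {
    spq <- competition_spec(
      b1 = rnorm(1), b2 = rnorm(1), a1 = rnorm(1), a2 = rnorm(1),
      C_block = matrix(rnorm(16), 4)
    )
    expect_lte(localized_zero_mode(spq)$residual, 1e-12)
  }
})

test_that("a one-sided consumer impact still yields a localized zero mode", {
  sp <- competition_spec(b1 = 0, b2 = 5, a1 = 1, a2 = -1, matrix(-2))
  zm <- localized_zero_mode(sp)
  expect_equal(zm$vector, c(5, 0, 0))
  expect_lte(zm$residual, 1e-12)
  expect_false(zm$degenerate)
})

test_that("zero is always in the spectrum of the competition Jacobian", {
  set.seed(42)
  for (q in 1:30) {
    k <- sample(1:5, 1)
    sp <- competition_spec(rnorm(1), rnorm(1), rnorm(1), rnorm(1),
                           matrix(rnorm(k^2), k))
    ev <- eigen(competition_jacobian(sp), only.values = TRUE)$values
    expect_lt(min(Mod(ev)), 1e-10)
  }
})

test_that("the symmetric pair mode has eigenvalue d = -m p x*^p", {
  m1 <- symmetric_pair_mode(symmetric_pair_spec(1, -1, -1, m = 1, p = -1, x_star = 2))
  expect_equal(m1$value, 0.5)
  expect_true(m1$destabilizing)

  m2 <- symmetric_pair_mode(symmetric_pair_spec(1, -1, -1, m = 1, p = 1, x_star = 1))
  expect_equal(m2$value, -1)
  expect_false(m2$destabilizing)

  m0 <- symmetric_pair_mode(symmetric_pair_spec(1, -1, -1, m = 2, p = 0, x_star = 3))
  expect_equal(m0$value, 0)
  expect_true(m0$destabilizing) # boundary case p = 0
})

test_that("the pair eigenvalue matches a direct eigendecomposition", {
  set.seed(43)
  for (q in 1:50) {
    sp <- symmetric_pair_spec(
      a = rnorm(1), b = rnorm(1), c_ = rnorm(1),
      m = runif(1, 0.1, 3), p = runif(1, -2, 2), x_star = runif(1, 0.1, 3)
    )
    md <- symmetric_pair_mode(sp)
    expect_lte(md$residual, 1e-10)
    ev <- eigen(symmetric_pair_jacobian(sp), only.values = TRUE)$values
    expect_lt(min(Mod(ev - md$value)), 1e-10)
    expect_identical(md$destabilizing, sp$p <= 0)
  }
})

test_that("the pair matrix is invariant under swapping the two consumers", {
  sp <- symmetric_pair_spec(1.3, -0.7, -0.2, d = -0.9)
  J <- symmetric_pair_jacobian(sp)
  perm <- c(2, 1, 3)
  expect_identical(J[perm, perm], J)
  # the (1, -1, 0) mode is orthogonal to the symmetric subspace
  expect_identical(sum(symmetric_pair_mode(sp)$vector * c(1, 1, 0)), 0)
})

test_that("participation ratio separates localized from delocalized vectors", {
  expect_equal(localization_score(c(1, 0, 0, 0))$participation_ratio, 1)
  expect_identical(localization_score(c(1, 0, 0, 0))$support, 1L)
  n <- 8
  expect_equal(localization_score(rep(1 / sqrt(n), n))$participation_ratio, n)
  expect_error(localization_score(rep(0, 4)), "nonzero")
})

test_that("the competition zero mode is localized on the two consumers", {
  set.seed(44)
  sp <- competition_spec(1.5, -0.5, 0.3, 1.1, C_block = matrix(rnorm(64), 8))
  zm <- localized_zero_mode(sp) # 10-node system
  sc <- localization_score(zm$vector)
  expect_true(all(sc$support %in% 1:2))
  expect_true(sc$exact)
  expect_lte(sc$participation_ratio, 2)
})

test_that("the demo prints verification residuals as JSON", {
  set.seed(45)
  out <- expect_output(demo_stability_motifs(), "residual")
  expect_lte(out$exploitative_competition$residual, 1e-12)
  expect_lte(out$symmetric_pair$residual, 1e-10)
})
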