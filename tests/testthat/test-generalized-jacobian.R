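test_that("sampled parameters respect role-forced zeros and normalizations", {
  for (s in 1:20) {
    set.seed(s)
    web <- niche_web(15)
    p <- sample_parameters(web)
    roles <- trophic_roles(web)
    basal <- roles$role == "basal"
    expect_identical(p$rho == 0, basal)
    expect_identical(p$sigma == 0, roles$n_predators == 0L)
    for (k in which(!basal)) {
      expect_lt(abs(sum(p$chi[k, ]) - 1), 1e-12)
      expect_identical(which(p$chi[k, ] > 0), roles$prey[[k]])
    }
    for (m in which(roles$n_predators > 0L)) {
      expect_lt(abs(sum(p$beta[m, ]) - 1), 1e-12)
      expect_identical(which(p$beta[m, ] > 0), roles$predators[[m]])
    }
    expect_true(all(p$gamma >= 0.5 & p$gamma <= 1.5))
    expect_true(all(p$mu >= 1 & p$mu <= 2))
    expect_true(all(p$psi >= 0.5 & p$psi <= 1.5))
    expect_true(all(p$phi >= 0 & p$phi <= 1))
    expect_true(all(p$lam == 1))
  }
})

test_that("a single predator forces unit diet and loss weights", {
  set.seed(1)
  p <- sample_parameters(ac_triad_web())
  expect_equal(p$chi[3, 1] + p$chi[3, 2], 1)
  expect_equal(p$beta[1, 3], 1)
  expect_equal(p$beta[2, 3], 1)
})

test_that("invalid range configuration errors", {
  expect_error(param_ranges(gamma = c(2, 1)), "gamma")
})

test_that("an unconsumed producer reduces to production minus mortality", {
  producer <- list(n_species = 1L)
  params <- list(
    alpha = 1, rho = 0, sigma = 0, phi = 0.5, gamma = 1, mu = 1.5, psi = 1,
    chi = matrix(0, 1, 1), beta = matrix(0, 1, 1), lam = matrix(1, 1, 1),
    prey = list(integer()), predators = list(integer())
  )
  expect_equal(build_jacobian(producer, params), matrix(-1))
})

test_that("a two-species chain has the predator-prey sign pattern", {
  web <- chain_web(2)
  set.seed(3)
  p <- sample_parameters(web)
  p$sigma[1] <- 0.5 # ensure the prey actually loses biomass to predation
  J <- build_jacobian(web, p)
  expect_gt(J[2, 1], 0) # consumer gains from prey
  expect_lt(J[1, 2], 0) # prey loses to predator
})

test_that("shared-predator coupling appears exactly when gamma != 1", {
  web <- ac_triad_web()
  set.seed(4)
  p <- sample_parameters(web)
  p$sigma[1:2] <- c(0.6, 0.7)
  p$gamma[3] <- 1
  J <- build_jacobian(web, p)
  expect_identical(J[1, 2], 0)
  expect_identical(J[2, 1], 0)
  p$gamma[3] <- 1.4
  J2 <- build_jacobian(web, p)
  expect_true(J2[1, 2] != 0 && J2[2, 1] != 0)
})

test_that("the Jacobian matches a finite-difference oracle on random webs", {
  set.seed(7)
  for (q in 1:25) {
    web <- niche_web(10)
    p <- sample_parameters(web)
    expect_lt(max(abs(build_jacobian(web, p) - fd_jacobian(web, p))), 1e-6)
  }
})

test_that("the Jacobian support is the predicted set of couplings", {
  set.seed(8)
  for (q in 1:10) {
    web <- niche_web(12)
    p <- sample_parameters(web)
    J <- build_jacobian(web, p)
    A <- web$adjacency
    shared_pred <- (A %*% t(A)) > 0 # prey pairs with a common predator
    allowed <- diag(TRUE, 12) | A | t(A) | shared_pred
    expect_true(all(J[!allowed] == 0))
  }
})

test_that("stability and reactivity classification matches closed forms", {
  st <- classify_state(diag(c(-1, -2)))
  expect_true(st$stable)
  expect_false(st$reactive)

  rot <- matrix(c(0, -1, 1, 0), 2, 2) # pure rotation
  st2 <- classify_state(rot)
  expect_false(st2$stable)
  expect_false(st2$reactive) # symmetric part is zero

  shear <- matrix(c(-1, 0, 3, -1), 2, 2)
  st3 <- classify_state(shear)
  expect_true(st3$stable)
  expect_true(st3$reactive)
  expect_equal(st3$reactivity, 0.5)
})

test_that("spectral abscissa never exceeds reactivity (numerical abscissa bound)", {
  set.seed(9)
  for (q in 1:30) {
    J <- matrix(rnorm(100), 10)
    st <- classify_state(J)
    expect_lte(st$abscissa, st$reactivity + 1e-10)
  }
})

test_that("accepted realizations are stable and reactive, and seeded runs repeat", {
  set.seed(21)
  rea <- sample_stable_reactive(n = 15)
  expect_true(rea$stable && rea$reactive)
  st <- classify_state(rea$J)
  expect_true(st$stable && st$reactive)

  set.seed(21)
  rea2 <- sample_stable_reactive(n = 15)
  expect_identical(rea$J, rea2$J)
  expect_identical(rea$web$adjacency, rea2$web$adjacency)
})

test_that("Jacobian CSV round-trips bit-exactly", {
  set.seed(10)
  J <- matrix(rnorm(25), 5)
  f <- withr::local_tempfile(fileext = ".csv")
  write_jacobian(J, f)
  expect_identical(read_jacobian(f), J)
})
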