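#' Parameter ranges for the generalized food-web model
#'
#' Configuration of the random draws in [sample_parameters()]. All elasticity
#' ranges are uniform `[lower, upper]`. The per-species turnover rate is tied
#' to trophic position through the niche value,
#' `alpha_i = alpha_base^(alpha_exponent_scale * n_i)` (default `10^(-2 n_i)`:
#' turnover slows by two decades from the bottom to the top of the niche
#' axis). `lam` is the prey-switching exponent, constant 1 by default
#' (passive switching).
#'
#' @param gamma range of the predation elasticity w.r.t. total prey
#'   availability (saturation of the functional response; 1 is linear).
#' @param mu range of the elasticity of non-predation mortality
#'   (1 linear, 2 quadratic closure).
#' @param psi range of the predation elasticity w.r.t. the predator's own
#'   density.
#' @param phi range of the elasticity of primary production.
#' @param sigma range of the fraction of biomass loss due to predation, for
#'   species that have predators.
#' @param lam prey-switching exponent applied to every trophic link.
#' @param alpha_base,alpha_exponent_scale turnover scaling (see above).
#' @param tol eigenvalue tolerance used when classifying stability and
#'   reactivity.
#' @return A list of class `param_ranges`.
#' @export
param_ranges <- function(gamma = c(0.5, 1.5),
                         mu = c(1, 2),
                         psi = c(0.5, 1.5),
                         phi = c(0, 1),
                         sigma = c(0, 1),
                         lam = 1,
                         alpha_base = 10,
                         alpha_exponent_scale = -2,
                         tol = 1e-9) {
  ranges <- list(gamma = gamma, mu = mu, psi = psi, phi = phi, sigma = sigma)
  for (nm in names(ranges)) {
    rg <- ranges[[nm]]
    if (length(rg) != 2 || !is.numeric(rg) || rg[1] > rg[2]) {
      abort(sprintf("Range `%s` must be numeric c(lower, upper) with lower <= upper.", nm))
    }
  }
  structure(
    c(ranges, list(lam = lam, alpha_base = alpha_base,
                   alpha_exponent_scale = alpha_exponent_scale, tol = tol)),
    class = "param_ranges"
  )
}

#' Draw generalized-model parameters for a topology
#'
#' Samples the scale and elasticity parameters of the generalized food-web
#' model for a given topology. Role-forced values: `rho = 1` for consumers and
#' `0` for basal species (no mixotrophy); `sigma = 0` for species without
#' predators; the diet weights `chi` (one per link, consumer rows) and loss
#' weights `beta` (one per link, prey rows) are independent `U(0, 1)` draws
#' normalized to sum to 1 over each consumer's prey and each prey's
#' predators, respectively.
#'
#' The draw order is fixed (`phi`, `gamma`, `psi`, `mu`, `sigma`, each a
#' length-`n` vector drawn for all species before role masking, then one
#' variate per link for `chi` and `beta` in column order), so a given seed and
#' topology always yield the same parameters.
#'
#' @param web a [web_topology()].
#' @param ranges a [param_ranges()] configuration.
#' @return A list of class `generalized_params` with per-species vectors
#'   `alpha`, `rho`, `sigma`, `phi`, `gamma`, `mu`, `psi` and per-link
#'   matrices `chi`, `beta`, `lam` (consumer/prey orientation as documented
#'   for each).
#' @export
sample_parameters <- function(web, ranges = param_ranges()) {
  validate_web_topology(web)
  n <- web$n_species
  adj <- web$adjacency
  prey <- purrr::map(seq_len(n), ~ which(adj[, .x]))
  pred <- purrr::map(seq_len(n), ~ which(adj[.x, ]))
  runif_rg <- function(rg) runif(n, rg[1], rg[2])
  phi <- runif_rg(ranges$phi)
  gamma <- runif_rg(ranges$gamma)
  psi <- runif_rg(ranges$psi)
  mu <- runif_rg(ranges$mu)
  sigma <- runif_rg(ranges$sigma)
  sigma[lengths(pred) == 0L] <- 0
  rho <- as.double(lengths(prey) > 0L)
  alpha <- ranges$alpha_base^(ranges$alpha_exponent_scale * web$niche_values)
  chi <- matrix(0, n, n) # chi[k, m]: weight of prey m in consumer k's diet
  beta <- matrix(0, n, n) # beta[m, k]: share of prey m's predation loss to k
  for (k in seq_len(n)) {
    if (length(prey[[k]])) {
      w <- runif(length(prey[[k]]))
      chi[k, prey[[k]]] <- w / sum(w)
    }
  }
  for (m in seq_len(n)) {
    if (length(pred[[m]])) {
      w <- runif(length(pred[[m]]))
      beta[m, pred[[m]]] <- w / sum(w)
    }
  }
  lam <- matrix(ranges$lam, n, n)
  structure(
    list(alpha = alpha, rho = rho, sigma = sigma, phi = phi, gamma = gamma,
         mu = mu, psi = psi, chi = chi, beta = beta, lam = lam,
         prey = prey, predators = pred),
    class = "generalized_params"
  )
}

#' Assemble the generalized-model Jacobian
#'
#' Builds the community Jacobian of the normalized generalized food-web model
#' at its steady state. Entry `J[n, m] = alpha_n` times
#' `delta_nm ((1 - rho_n) phi_n + rho_n psi_n - (1 - sigma_n) mu_n)
#'  + rho_n gamma_n lam[n, m] chi[n, m]
#'  - sigma_n sum_k beta[n, k] (delta_nm lam[k, n]
#'      + (gamma_k - 1) lam[k, m] chi[k, m] + psi_k delta_km)`,
#' with the sum over predators `k` of `n`. Nonzero entries occur only on the
#' diagonal, on prey and predator partners, and on prey that share a predator
#' with `n` (through the saturation term `gamma_k - 1`).
#'
#' @param web a [web_topology()].
#' @param params a `generalized_params` object from [sample_parameters()].
#' @return An `n x n` numeric Jacobian matrix (units: 1/time).
#' @export
build_jacobian <- function(web, params) {
  n <- web$n_species
  if (length(params$alpha) != n) abort("Parameter/topology dimension mismatch.")
  for (nm in c("alpha", "rho", "sigma", "phi", "gamma", "mu", "psi")) {
    if (anyNA(params[[nm]])) abort(sprintf("NaN/NA in parameter `%s`.", nm))
  }
  p <- params
  J <- matrix(0, n, n)
  for (i in seq_len(n)) {
    J[i, i] <- (1 - p$rho[i]) * p$phi[i] + p$rho[i] * p$psi[i] -
      (1 - p$sigma[i]) * p$mu[i]
    J[i, ] <- J[i, ] + p$rho[i] * p$gamma[i] * p$lam[i, ] * p$chi[i, ]
    for (k in p$predators[[i]]) {
      bk <- p$sigma[i] * p$beta[i, k]
      J[i, i] <- J[i, i] - bk * p$lam[k, i]
      J[i, ] <- J[i, ] - bk * (p$gamma[k] - 1) * p$lam[k, ] * p$chi[k, ]
      J[i, k] <- J[i, k] - bk * p$psi[k]
    }
  }
  J * p$alpha
}

#' Classify stability and reactivity of a Jacobian
#'
#' A steady state is stable when the spectral abscissa (largest eigenvalue
#' real part) of `J` is below `-tol`, and reactive when the leading eigenvalue
#' of the symmetric part `S = (J + J')/2` exceeds `+tol`. The tolerance
#' separates genuinely marginal cases from floating-point noise.
#'
#' @param J square numeric Jacobian.
#' @param tol eigenvalue tolerance.
#' @return A list with `stable`, `reactive` (logicals), `abscissa` and
#'   `reactivity` (the two leading eigenvalues).
#' @export
classify_state <- function(J, tol = 1e-9) {
  check_square(J)
  abscissa <- max(Re(eigen(J, only.values = TRUE)$values))
  r <- reactivity(J)$r
  list(
    stable = abscissa < -tol,
    reactive = r > tol,
    abscissa = abscissa,
    reactivity = r
  )
}

#' Rejection-sample a stable-but-reactive realization
#'
#' Draws (topology, parameters) pairs until the resulting Jacobian is both
#' stable and reactive. With `web = NULL` a fresh niche-model topology is
#' drawn on every attempt (the "random topologies" mode); with a fixed `web`
#' only the parameters are redrawn.
#'
#' @param web a fixed [web_topology()], or `NULL` to draw a fresh topology per
#'   attempt.
#' @param n,connectance niche-model settings used when `web` is `NULL`.
#' @param ranges a [param_ranges()].
#' @param max_tries rejection budget.
#' @return A list of class `jacobian_realization`: `J`, `web`, `params`,
#'   `stable`, `reactive`, `abscissa`, `reactivity`, `attempts`.
#' @examples
#' set.seed(42)
#' rea <- sample_stable_reactive(n = 15)
#' rea$reactivity
#' @export
sample_stable_reactive <- function(web = NULL, n = 15, connectance = 0.15,
                                   ranges = param_ranges(), max_tries = 1e5) {
  for (i in seq_len(max_tries)) {
    w <- if (is.null(web)) niche_web(n, connectance) else web
    params <- sample_parameters(w, ranges)
    J <- build_jacobian(w, params)
    st <- classify_state(J, tol = ranges$tol)
    if (st$stable && st$reactive) {
      return(structure(
        list(J = J, web = w, params = params, stable = TRUE, reactive = TRUE,
             abscissa = st$abscissa, reactivity = st$reactivity, attempts = i),
        class = "jacobian_realization"
      ))
    }
  }
  abort(sprintf(
    "No stable-reactive realization in %d tries (acceptance rate so far: 0/%d).",
    max_tries, max_tries
  ))
}

#' @export
print.jacobian_realization <- function(x, ...) {
  cat(sprintf(
    "<jacobian_realization> %d species, stable = %s, reactivity = %.4g (attempts: %d)\n",
    nrow(x$J), x$stable, x$reactivity, x$attempts
  ))
  invisible(x)
}

#' @method tidy jacobian_realization
#' @export
tidy.jacobian_realization <- function(x, ...) {
  ev <- eigen(x$J, only.values = TRUE)$values
  tibble::tibble(
    eigenvalue = seq_along(ev),
    real = Re(ev),
    imaginary = Im(ev)
  )
}

#' @method glance jacobian_realization
#' @export
glance.jacobian_realization <- function(x, ...) {
  tibble::tibble(
    n_species = nrow(x$J),
    n_links = n_links(x$web),
    stable = x$stable,
    reactive = x$reactive,
    abscissa = x$abscissa,
    reactivity = x$reactivity,
    attempts = x$attempts
  )
}

#' Read and write Jacobian matrices as CSV
#'
#' Plain `n x n` comma-separated reals, row-major, no header, written at 17
#' significant digits so that a write/read round trip is bit-exact.
#'
#' @param J square numeric matrix.
#' @param path file path.
#' @return `read_jacobian()` returns a matrix; `write_jacobian()` returns
#'   `path` invisibly.
#' @export
read_jacobian <- function(path) {
  J <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(J) <- NULL
  check_square(J, "Jacobian CSV")
  J
}

#' @rdname read_jacobian
#' @export
write_jacobian <- function(J, path) {
  check_square(J)
  writeLines(apply(J, 1, function(row) {
    paste(sprintf("%.17g", row), collapse = ",")
  }), path)
  invisible(path)
}
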