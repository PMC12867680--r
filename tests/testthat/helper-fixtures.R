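# Fixtures and independent oracles used across the test files.

# A linear chain 1 -> 2 -> ... -> n (prey -> predator).
chain_web <- function(n) {
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) adj[i, i + 1] <- TRUE
  web_topology(n, (seq_len(n) - 0.5) / n, adj)
}

# Apparent-competition triad: 1 -> 3 and 2 -> 3 (one predator, two prey).
ac_triad_web <- function() {
  adj <- matrix(FALSE, 3, 3)
  adj[1, 3] <- TRUE
  adj[2, 3] <- TRUE
  web_topology(3, c(0.2, 0.5, 0.8), adj)
}

# Star: species 1 consumes all others (n - 1 basal species).
star_web <- function(n) {
  adj <- matrix(FALSE, n, n)
  adj[2:n, 1] <- TRUE
  web_topology(n, (seq_len(n) - 0.5) / n, adj)
}

# Random dense symmetric matrix.
random_symmetric <- function(n) {
  M <- matrix(rnorm(n * n), n)
  (M + t(M)) / 2
}

# Independent finite-difference oracle for the generalized-model Jacobian.
# Instantiates the normalized model with concrete power-law rate functions:
#   dx_n/dt = alpha_n [ rho_n t_n(x)^gamma_n x_n^psi_n
#                       + (1 - rho_n) x_n^phi_n
#                       - sigma_n sum_k beta[n,k] x_n^lam[k,n] t_k(x)^(gamma_k - 1) x_k^psi_k
#                       - (1 - sigma_n) x_n^mu_n ]
# with prey availability t_k(x) = sum_m chi[k,m] x_m^lam[k,m], and
# differentiates numerically at the normalized steady state x = 1.
fd_jacobian <- function(web, params, h = 1e-5) {
  n <- web$n_species
  p <- params
  t_of <- function(x, k) {
    m <- p$prey[[k]]
    if (length(m) == 0) return(1)
    sum(p$chi[k, m] * x[m]^p$lam[k, m])
  }
  rhs <- function(x) {
    vapply(seq_len(n), function(i) {
      gain <- if (p$rho[i] > 0) t_of(x, i)^p$gamma[i] * x[i]^p$psi[i] else 0
      loss <- 0
      for (k in p$predators[[i]]) {
        loss <- loss + p$beta[i, k] * x[i]^p$lam[k, i] *
          t_of(x, k)^(p$gamma[k] - 1) * x[k]^p$psi[k]
      }
      p$alpha[i] * (p$rho[i] * gain + (1 - p$rho[i]) * x[i]^p$phi[i] -
                      p$sigma[i] * loss - (1 - p$sigma[i]) * x[i]^p$mu[i])
    }, numeric(1))
  }
  J <- matrix(0, n, n)
  x0 <- rep(1, n)
  for (m in seq_len(n)) {
    xp <- x0; xp[m] <- 1 + h
    xm <- x0; xm[m] <- 1 - h
    J[, m] <- (rhs(xp) - rhs(xm)) / (2 * h)
  }
  J
}

# Brute-force most reactive instance over explicit node subsets, using a
# dense eigensolver only (independent of the scan's closed forms).
brute_force_best <- function(J, node_sets) {
  S <- (J + t(J)) / 2
  r <- vapply(node_sets, function(nd) {
    max(eigen(S[nd, nd, drop = FALSE], symmetric = TRUE, only.values = TRUE)$values)
  }, numeric(1))
  best <- which.max(r)
  list(nodes = node_sets[[best]], r = r[best], all_r = r)
}
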