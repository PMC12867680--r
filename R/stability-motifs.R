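#' Exploitative-competition system specification
#'
#' Two unregulated specialist consumers exploiting a single shared resource,
#' embedded in an arbitrary rest-of-network. With linear gain and loss rates
#' the consumers have no self-interaction and interact with everything else
#' only through the resource, so the Jacobian's first two columns contain
#' only the consumers' impacts on the resource, `b1` and `b2`.
#'
#' @param b1,b2 the consumers' impacts on the resource (row 3 entries).
#' @param a1,a2 the resource's impacts on the consumers (column 3 entries).
#' @param C_block square numeric matrix (size >= 1): coupling of the resource
#'   and the rest of the network, `c_ij`; its first row/column is the
#'   resource.
#' @return A list of class `competition_spec`. If `b1 = b2 = 0` the localized
#'   direction is degenerate (any consumer-plane vector is an eigenvector);
#'   the returned object is flagged with `degenerate = TRUE`.
#' @export
competition_spec <- function(b1, b2, a1, a2, C_block) {
  C_block <- as.matrix(C_block)
  check_square(C_block, "C_block")
  structure(
    list(b1 = b1, b2 = b2, a1 = a1, a2 = a2, C_block = C_block,
         degenerate = (b1 == 0 && b2 == 0)),
    class = "competition_spec"
  )
}

#' Jacobian of the exploitative-competition motif in a network
#'
#' Builds the `(2 + k) x (2 + k)` Jacobian with a zero 2x2 top-left block
#' (the two consumers), `a1, a2` in the resource column, `b1, b2` in the
#' resource row, and the rest-of-network block elsewhere. Columns 1-2 are
#' zero outside the resource row, which is what localizes the zero mode.
#'
#' @param spec a [competition_spec()].
#' @return A square numeric matrix.
#' @export
competition_jacobian <- function(spec) {
  k <- nrow(spec$C_block)
  n <- 2L + k
  J <- matrix(0, n, n)
  J[1, 3] <- spec$a1
  J[2, 3] <- spec$a2
  J[3, 1] <- spec$b1
  J[3, 2] <- spec$b2
  J[3:n, 3:n] <- spec$C_block
  J
}

#' Localized zero mode of exploitative competition
#'
#' The vector `(b2, -b1, 0, ..., 0)` annihilates the competition Jacobian
#' regardless of the rest-of-network block: the motif forces a zero
#' eigenvalue, precluding asymptotic stability of the whole network. The
#' residual `||J v||` is computed and must vanish to floating-point accuracy.
#'
#' @param spec a [competition_spec()].
#' @return A list: `vector` (the localized eigenvector, unnormalized),
#'   `value` (0), `residual` (`||J v||`), `degenerate` (TRUE when
#'   `b1 = b2 = 0`, in which case the direction is arbitrary in the consumer
#'   plane).
#' @examples
#' sp <- competition_spec(b1 = 1, b2 = 2, a1 = 1, a2 = 1, C_block = matrix(-1))
#' localized_zero_mode(sp)$vector # (2, -1, 0)
#' @export
localized_zero_mode <- function(spec) {
  J <- competition_jacobian(spec)
  v <- c(spec$b2, -spec$b1, rep(0, nrow(J) - 2L))
  if (spec$degenerate) v <- c(1, 0, rep(0, nrow(J) - 2L))
  list(
    vector = v,
    value = 0,
    residual = sqrt(sum((J %*% v)^2)),
    degenerate = spec$degenerate
  )
}

#' Symmetric consumer-pair specification
#'
#' Two species with identical dynamics (`F(R) X - m X^(1+p)` for both)
#' sharing a resource, with a stationary state at equal abundances
#' `X* = Y* > 0`. The isolated-motif Jacobian is
#' `rbind(c(d, 0, a), c(0, d, a), c(b, b, c))`; the permutation symmetry of
#' the first two species localizes the antisymmetric mode `(1, -1, 0)` with
#' eigenvalue `d = -m p (X*)^p`.
#'
#' Either supply `d` directly or supply `(m, p, x_star)` and let the
#' constructor derive it.
#'
#' @param a resource impact on each consumer.
#' @param b each consumer's impact on the resource.
#' @param c_ resource self-interaction.
#' @param m mortality coefficient (> 0).
#' @param p mortality exponent (density dependence of mortality; `p = 0` is
#'   purely linear mortality).
#' @param x_star steady-state abundance (> 0).
#' @param d diagonal entry; computed as `-m p x_star^p` when omitted.
#' @return A list of class `symmetric_pair_spec`.
#' @export
symmetric_pair_spec <- function(a, b, c_, m = NULL, p = NULL, x_star = NULL,
                                d = NULL) {
  if (is.null(d)) {
    if (is.null(m) || is.null(p) || is.null(x_star)) {
      abort("Supply either `d` or all of `m`, `p`, `x_star`.")
    }
    if (m <= 0) abort("`m` must be positive.")
    if (x_star <= 0) abort("`x_star` must be positive.")
    d <- -m * p * x_star^p
  }
  structure(
    list(a = a, b = b, c_ = c_, d = d, m = m, p = p, x_star = x_star),
    class = "symmetric_pair_spec"
  )
}

#' Jacobian of the symmetric consumer pair
#' @param spec a [symmetric_pair_spec()].
#' @return The 3x3 motif Jacobian (consumers first, resource third).
#' @export
symmetric_pair_jacobian <- function(spec) {
  matrix(c(
    spec$d, 0, spec$a,
    0, spec$d, spec$a,
    spec$b, spec$b, spec$c_
  ), 3, 3, byrow = TRUE)
}

#' Localized eigenpair of the symmetric consumer pair
#'
#' Returns the antisymmetric mode `(1, -1, 0)` and its eigenvalue `d`. The
#' third component being zero is what allows the rest of a network to attach
#' at the resource without perturbing this eigenvalue. When the specification was
#' built from `(m, p, x_star)`, `d = -m p (X*)^p`, which is nonnegative —
#' destabilizing — exactly when `p <= 0`.
#'
#' @param spec a [symmetric_pair_spec()].
#' @return A list: `vector` (`c(1, -1, 0)`), `value` (`d`), `residual`
#'   (`||J v - d v||`), `destabilizing` (`value >= 0`).
#' @examples
#' sp <- symmetric_pair_spec(a = 1, b = -1, c_ = -1, m = 1, p = -1, x_star = 2)
#' symmetric_pair_mode(sp)$value # 0.5: destabilizing
#' @export
symmetric_pair_mode <- function(spec) {
  J <- symmetric_pair_jacobian(spec)
  v <- c(1, -1, 0)
  list(
    vector = v,
    value = spec$d,
    residual = sqrt(sum((J %*% v - spec$d * v)^2)),
    destabilizing = spec$d >= 0
  )
}

#' Eigenvector localization diagnostics
#'
#' For a unit vector `v`, the participation ratio `PR = 1 / sum(v_i^4)`
#' estimates the number of nodes the vector effectively occupies: 1 for a
#' vector concentrated on one node, `n` for a uniformly spread one. The
#' support set collects indices with `|v_i| > eps`; the vector is declared
#' exactly localized when the Euclidean mass outside the support is below
#' `1e-10`. A separate relative threshold (default 5% of the largest
#' component) gives an approximate-localization support for reporting.
#'
#' @param v numeric vector (normalized internally; the zero vector errors).
#' @param eps absolute threshold for the exact support set.
#' @param rel relative threshold (fraction of `max |v_i|`) for the
#'   approximate support.
#' @return A list: `participation_ratio`, `support`, `approx_support`,
#'   `exact` (logical), `off_support_mass`.
#' @export
localization_score <- function(v, eps = 1e-8, rel = 0.05) {
  if (!is.numeric(v) || length(v) == 0) abort("`v` must be a numeric vector.")
  nrm <- sqrt(sum(v^2))
  if (nrm == 0) abort("`v` must be nonzero.")
  v <- v / nrm
  support <- which(abs(v) > eps)
  off_mass <- sqrt(sum(v[-support]^2))
  if (length(support) == length(v)) off_mass <- 0
  list(
    participation_ratio = 1 / sum(v^4),
    support = support,
    approx_support = which(abs(v) > rel * max(abs(v))),
    exact = off_mass < 1e-10,
    off_support_mass = off_mass
  )
}

#' Print the analytic stability-motif constructions
#'
#' Builds one random exploitative-competition system and one symmetric
#' consumer pair, verifies the localized modes, and returns (and optionally
#' prints) the constructions with their residuals.
#'
#' @param rest_size size of the random rest-of-network block.
#' @param quiet suppress printing.
#' @return (Invisibly) a list with both constructions, residuals, and
#'   localization scores.
#' @export
demo_stability_motifs <- function(rest_size = 4, quiet = FALSE) {
  cb <- matrix(stats::rnorm(rest_size^2), rest_size)
  comp <- competition_spec(
    b1 = runif(1, -2, 2), b2 = runif(1, -2, 2),
    a1 = runif(1, -2, 2), a2 = runif(1, -2, 2),
    C_block = cb
  )
  zm <- localized_zero_mode(comp)
  pair <- symmetric_pair_spec(
    a = runif(1, -2, 2), b = runif(1, -2, 2), c_ = runif(1, -2, 0),
    m = runif(1, 0.5, 2), p = runif(1, -1, 1), x_star = runif(1, 0.5, 2)
  )
  pm <- symmetric_pair_mode(pair)
  out <- list(
    exploitative_competition = list(
      jacobian = competition_jacobian(comp),
      vector = zm$vector, eigenvalue = zm$value, residual = zm$residual,
      localization = localization_score(zm$vector)
    ),
    symmetric_pair = list(
      jacobian = symmetric_pair_jacobian(pair),
      vector = pm$vector, eigenvalue = pm$value, residual = pm$residual,
      destabilizing = pm$destabilizing,
      localization = localization_score(pm$vector)
    )
  )
  if (!quiet) {
    cat(jsonlite::toJSON(
      list(
        exploitative_competition = list(
          eigenvalue = zm$value, residual = zm$residual,
          participation_ratio = out$exploitative_competition$localization$participation_ratio
        ),
        symmetric_pair = list(
          eigenvalue = pm$value, residual = pm$residual,
          destabilizing = pm$destabilizing
        )
      ),
      auto_unbox = TRUE, digits = 12, pretty = TRUE
    ), "\n")
  }
  invisible(out)
}
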