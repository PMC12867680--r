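#' Symmetric part of a matrix
#'
#' `S = (J + J') / 2`, symmetrized explicitly so the result is bit-exactly
#' symmetric. Reactivity is the leading eigenvalue of `S`.
#'
#' @param J square numeric matrix.
#' @return A symmetric matrix of the same dimension.
#' @export
symmetric_part <- function(J) {
  check_square(J)
  (J + t(J)) / 2
}

#' Reactivity of a steady state
#'
#' Reactivity is the initial growth rate of the worst-case infinitesimal
#' perturbation of a steady state, `r = max (d|delta|/dt) / |delta|` over
#' perturbation directions. It equals the leading eigenvalue of the symmetric
#' part of the Jacobian; the maximizing direction is the corresponding unit
#' eigenvector. A positive `r` means some perturbations are transiently
#' amplified even if the state is asymptotically stable.
#'
#' @param J square numeric Jacobian (finite entries).
#' @return A list of class `reactivity_result`: `r` (1/time) and
#'   `worst_case_direction`, a unit vector with its largest-magnitude
#'   component made positive (deterministic sign convention).
#' @examples
#' reactivity(matrix(c(-1, 0, 3, -1), 2, 2))$r # 0.5
#' @export
reactivity <- function(J) {
  check_square(J)
  check_finite(J)
  S <- symmetric_part(J)
  es <- eigen(S, symmetric = TRUE)
  v <- es$vectors[, 1]
  if (v[which.max(abs(v))] < 0) v <- -v
  structure(
    list(r = es$values[1], worst_case_direction = v),
    class = "reactivity_result"
  )
}

#' @export
print.reactivity_result <- function(x, ...) {
  cat(sprintf("<reactivity_result> r = %.6g\n", x$r))
  invisible(x)
}

#' @method tidy reactivity_result
#' @export
tidy.reactivity_result <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$worst_case_direction),
    direction = x$worst_case_direction
  )
}

#' @method glance reactivity_result
#' @export
glance.reactivity_result <- function(x, ...) {
  tibble::tibble(r = x$r, n = length(x$worst_case_direction))
}

# Leading eigenvalue of a symmetric matrix, with closed forms for orders
# 1-3 (quadratic formula; trigonometric solution of the characteristic
# cubic). The motif scan calls this millions of times, so the small cases
# avoid eigen()'s overhead; both forms are property-tested against eigen().
sym_top_eig <- function(S) {
  n <- nrow(S)
  if (n == 1L) return(S[1, 1])
  if (n == 2L) return(sym_top_eig2(S[1, 1], S[2, 2], S[1, 2]))
  if (n == 3L) {
    return(sym_top_eig3(S[1, 1], S[2, 2], S[3, 3], S[1, 2], S[1, 3], S[2, 3]))
  }
  eigen(S, symmetric = TRUE, only.values = TRUE)$values[1]
}

# Vectorized closed forms: each argument a vector over instances.
sym_top_eig2 <- function(a11, a22, a12) {
  (a11 + a22) / 2 + sqrt(((a11 - a22) / 2)^2 + a12^2)
}

sym_top_eig3 <- function(a11, a22, a33, a12, a13, a23) {
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * (a12^2 + a13^2 + a23^2)
  p <- sqrt(p2 / 6)
  out <- q
  nz <- p > 0
  ps <- ifelse(nz, p, 1) # avoid 0/0; masked below
  b11 <- (a11 - q) / ps; b22 <- (a22 - q) / ps; b33 <- (a33 - q) / ps
  c12 <- a12 / ps; c13 <- a13 / ps; c23 <- a23 / ps
  det_b <- b11 * (b22 * b33 - c23^2) - c12 * (c12 * b33 - c23 * c13) +
    c13 * (c12 * c23 - b22 * c13)
  phi <- acos(pmin(pmax(det_b / 2, -1), 1)) / 3
  ifelse(nz, q + 2 * p * cos(phi), out)
}

#' Reactivity of a principal submatrix
#'
#' Leading eigenvalue of the principal submatrix of `S = (J + J')/2` on the
#' given node set — the reactivity attributable to that motif inside the full
#' system (including any shared-predator couplings within the block). Taking
#' the symmetric part before or after extracting the principal submatrix
#' gives the same result. By Cauchy interlacing this value never exceeds the
#' full system's reactivity.
#'
#' @param J square numeric matrix.
#' @param nodes nonempty vector of distinct node indices.
#' @return Scalar reactivity of the motif block.
#' @export
submatrix_reactivity <- function(J, nodes) {
  check_square(J)
  nodes <- as.integer(nodes)
  if (length(nodes) == 0) abort("`nodes` must be nonempty.")
  if (anyDuplicated(nodes)) abort("`nodes` must be distinct.")
  if (any(nodes < 1 | nodes > nrow(J))) abort("`nodes` out of range.")
  S <- symmetric_part(J)
  sym_top_eig(S[nodes, nodes, drop = FALSE])
}

#' Certify Cauchy eigenvalue interlacing
#'
#' For a symmetric matrix with eigenvalues `lambda_1 >= ... >= lambda_N` and a
#' principal submatrix obtained by deleting one row/column, with eigenvalues
#' `kappa_1 >= ... >= kappa_{N-1}`, Cauchy's interlacing theorem guarantees
#' `lambda_{i+1} <= kappa_i <= lambda_i`. For multi-index removal the check is
#' applied recursively, one deletion at a time, and the largest violation over
#' all steps is reported. Any violation beyond numerical tolerance indicates
#' an eigensolver or bookkeeping bug, since the theorem is exact.
#'
#' @param S symmetric numeric matrix.
#' @param nodes_removed indices to delete (one or several).
#' @param tol asymmetry / violation tolerance.
#' @return A list of class `interlacing_report`: `lambda` (full spectrum,
#'   descending), `kappa` (submatrix spectrum after all removals, descending),
#'   `satisfied`, `max_violation`.
#' @export
verify_interlacing <- function(S, nodes_removed, tol = 1e-8) {
  check_square(S)
  if (max(abs(S - t(S))) > tol) {
    abort("`S` must be symmetric: interlacing is only guaranteed for symmetric matrices.")
  }
  nodes_removed <- as.integer(nodes_removed)
  if (anyDuplicated(nodes_removed)) abort("`nodes_removed` must be distinct.")
  if (any(nodes_removed < 1 | nodes_removed > nrow(S))) {
    abort("`nodes_removed` out of range.")
  }
  if (length(nodes_removed) >= nrow(S)) {
    abort("Cannot remove every row of `S`.")
  }
  S <- (S + t(S)) / 2
  lambda_full <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  max_violation <- 0
  cur <- S
  remaining <- sort(nodes_removed, decreasing = TRUE) # delete high first
  lam <- lambda_full
  for (idx in remaining) {
    cur <- cur[-idx, -idx, drop = FALSE]
    kap <- eigen(cur, symmetric = TRUE, only.values = TRUE)$values
    m <- length(kap)
    viol <- max(c(kap - lam[seq_len(m)], lam[seq_len(m) + 1] - kap))
    max_violation <- max(max_violation, viol)
    lam <- kap
  }
  structure(
    list(lambda = lambda_full, kappa = lam,
         satisfied = max_violation <= tol, max_violation = max_violation),
    class = "interlacing_report"
  )
}

#' @export
print.interlacing_report <- function(x, ...) {
  cat(sprintf("<interlacing_report> satisfied = %s (max violation %.3g)\n",
              x$satisfied, x$max_violation))
  invisible(x)
}

#' @method tidy interlacing_report
#' @export
tidy.interlacing_report <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(spectrum = "full", rank = seq_along(x$lambda), value = x$lambda),
    tibble::tibble(spectrum = "submatrix", rank = seq_along(x$kappa), value = x$kappa)
  )
}
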