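# Riemannian geometry of symmetric positive-definite (SPD) matrices.
# Covariance features of ERP super-trials live on the SPD manifold; the
# affine-invariant metric and the Karcher mean below are the numerical core
# of the MDM classifier.

sym <- function(m) (m + t(m)) / 2

# spectral matrix function f(M) for symmetric M; re-symmetrise first so that
# eigen() takes the stable symmetric path
fun_sym <- function(m, f) {
  e <- eigen(sym(m), symmetric = TRUE)
  sym(e$vectors %*% (f(e$values) * t(e$vectors)))
}

logm_sym <- function(m) fun_sym(m, log)
expm_sym <- function(m) fun_sym(m, exp)
sqrtm_sym <- function(m) fun_sym(m, sqrt)
isqrtm_sym <- function(m) fun_sym(m, function(v) 1 / sqrt(v))

new_spd <- function(values, loaded = FALSE, converged = NA,
                    iterations = NA_integer_) {
  structure(
    list(values = values, dim = nrow(values), loaded = loaded,
         converged = converged, iterations = iterations),
    class = "spd"
  )
}

#' Extract the matrix of values from an SPD object
#'
#' @param x An object of class `spd` or a plain square matrix.
#' @return The underlying numeric matrix.
#' @export
spd_values <- function(x) {
  if (inherits(x, "spd")) return(x$values)
  if (is.matrix(x)) return(x)
  stop("expected an 'spd' object or a numeric matrix")
}

# validate and return the plain matrix; errors name the violated invariant
check_spd <- function(x, sym_tol = 1e-10, arg = "matrix") {
  m <- spd_values(x)
  if (nrow(m) != ncol(m)) {
    stop(sprintf("%s is not square (%d x %d)", arg, nrow(m), ncol(m)))
  }
  scale <- max(1, max(abs(m)))
  if (max(abs(m - t(m))) > sym_tol * scale) {
    stop(sprintf("%s is not symmetric within tolerance %g", arg, sym_tol))
  }
  ev <- eigen(sym(m), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop(sprintf(
      "%s is not positive definite (minimum eigenvalue %.3e <= 0)",
      arg, min(ev)
    ))
  }
  sym(m)
}

#' Eigenvalue spectrum of an SPD matrix
#'
#' @param x An `spd` object or square symmetric matrix.
#' @return Numeric vector of eigenvalues, decreasing.
#' @export
spd_spectrum <- function(x) {
  eigen(sym(spd_values(x)), symmetric = TRUE, only.values = TRUE)$values
}

#' Validate a matrix as symmetric positive definite
#'
#' Checks symmetry (to a relative tolerance) and strict positivity of the
#' spectrum, and wraps the matrix as an `spd` object.
#'
#' @param m Square numeric matrix.
#' @param sym_tol Relative symmetry tolerance.
#' @return An object of class `spd`.
#' @export
as_spd <- function(m, sym_tol = 1e-10) {
  new_spd(check_spd(m, sym_tol))
}

#' Affine-invariant Riemannian distance between SPD matrices
#'
#' Computes the geodesic distance
#' \deqn{\delta_R(A, B) = \|\log(A^{-1}B)\|_F = \sqrt{\sum_n [\ln w_n]^2},}
#' where \eqn{w_n} are the eigenvalues of \eqn{A^{-1}B}.  The distance is
#' symmetric in its arguments, zero iff the matrices are equal, and invariant
#' under congruence transforms \eqn{A \mapsto W^\top A W} for any invertible
#' \eqn{W} — the property that makes covariance-based EEG decoding robust to
#' linear spatial mixing.
#'
#' Numerically the eigenvalues of \eqn{A^{-1}B} are obtained as the spectrum
#' of the whitened matrix \eqn{A^{-1/2} B A^{-1/2}}, which is symmetric.
#'
#' @param a,b SPD matrices (class `spd` or plain symmetric matrices) of equal
#'   dimension.
#' @return A non-negative scalar distance.
#' @export
riemannian_distance <- function(a, b) {
  A <- check_spd(a, arg = "first argument")
  B <- check_spd(b, arg = "second argument")
  if (nrow(A) != nrow(B)) {
    stop(sprintf("dimension mismatch: %d x %d vs %d x %d",
                 nrow(A), ncol(A), nrow(B), ncol(B)))
  }
  E <- isqrtm_sym(A)
  w <- eigen(sym(E %*% B %*% E), symmetric = TRUE, only.values = TRUE)$values
  sqrt(sum(log(w)^2))
}

#' Geometric (Karcher) mean of SPD matrices
#'
#' Returns the SPD matrix minimising the sum of squared Riemannian distances
#' to the inputs,
#' \deqn{\mathfrak{G}(C_1, \dots, C_J) = \arg\min_C \sum_j \delta_R^2(C, C_j).}
#'
#' The minimiser is found by fixed-point iteration in the tangent space at
#' the current estimate: starting from the arithmetic mean, the update is
#' \deqn{C \leftarrow C^{1/2} \exp\Big(\tfrac1J \sum_j
#'   \log\big(C^{-1/2} C_j C^{-1/2}\big)\Big) C^{1/2},}
#' stopping when the Frobenius norm of the tangent-space mean falls below
#' `tolerance` (the tangent norm is a log of eigenvalue ratios, hence
#' scale-free) or after `max_iterations` sweeps.  Non-convergence yields a
#' warning and a result flagged `converged = FALSE`, never an error: a
#' slightly unconverged mean is still a usable class centroid.
#'
#' @param matrices List of SPD matrices (class `spd` or plain) of equal
#'   dimension; a single matrix is also accepted.
#' @param tolerance Convergence threshold on the tangent-space Frobenius
#'   norm.
#' @param max_iterations Maximum number of fixed-point sweeps.
#' @return An `spd` object with fields `converged` and `iterations`.
#' @export
geometric_mean <- function(matrices, tolerance = 1e-8, max_iterations = 50L) {
  if (is.matrix(matrices) || inherits(matrices, "spd")) {
    matrices <- list(matrices)
  }
  J <- length(matrices)
  if (J < 1) stop("geometric mean of an empty set of matrices")
  stopifnot(tolerance > 0, max_iterations >= 1)
  mats <- lapply(seq_len(J), function(j) {
    check_spd(matrices[[j]], arg = sprintf("matrix %d", j))
  })
  d <- nrow(mats[[1]])
  if (!all(vapply(mats, nrow, 1L) == d)) {
    stop("all matrices must share the same dimension")
  }

  C <- Reduce(`+`, mats) / J
  converged <- FALSE
  it <- 0L
  while (it < max_iterations) {
    it <- it + 1L
    S <- sqrtm_sym(C)
    Si <- isqrtm_sym(C)
    Tm <- matrix(0, d, d)
    for (Mj in mats) Tm <- Tm + logm_sym(Si %*% Mj %*% Si)
    Tm <- Tm / J
    C <- sym(S %*% expm_sym(Tm) %*% S)
    if (norm(Tm, "F") < tolerance) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning(sprintf(
      "geometric mean did not converge in %d iterations (tangent norm %.3e)",
      max_iterations, norm(Tm, "F")
    ))
  }
  new_spd(C, converged = converged, iterations = it)
}

#' Symmetrise and regularise a matrix into SPD form
#'
#' Symmetrises `(m + t(m))/2` and, when the minimum eigenvalue is
#' non-positive or falls below `loading * trace/d`, adds diagonal loading
#' until that floor is reached.  Short epochs can yield rank-deficient
#' sample covariances; the floor keeps them on the SPD manifold without
#' materially perturbing well-conditioned matrices.  For a matrix with
#' non-positive trace (e.g. the zero matrix) the absolute floor `loading`
#' is used instead.
#'
#' @param m Square numeric matrix.
#' @param loading Relative eigenvalue floor (fraction of the mean diagonal).
#' @return An `spd` object; field `loaded` records whether regularisation
#'   was applied.
#' @export
ensure_spd <- function(m, loading = 1e-10) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop("ensure_spd() expects a square matrix")
  }
  stopifnot(loading > 0)
  s <- sym(m)
  d <- nrow(s)
  floor_ev <- loading * sum(diag(s)) / d
  if (floor_ev <= 0) floor_ev <- loading
  min_ev <- min(eigen(s, symmetric = TRUE, only.values = TRUE)$values)
  loaded <- FALSE
  if (min_ev < floor_ev) {
    s <- s + diag(floor_ev - min_ev, d)
    loaded <- TRUE
  }
  new_spd(s, loaded = loaded)
}

#' @export
print.spd <- function(x, ...) {
  cat(sprintf("<spd matrix %d x %d%s>\n", x$dim, x$dim,
              if (isTRUE(x$loaded)) ", diagonally loaded" else ""))
  ev <- spd_spectrum(x)
  cat(sprintf("  eigenvalues: [%.4g, %.4g], condition %.3g\n",
              min(ev), max(ev), max(ev) / min(ev)))
  invisible(x)
}
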