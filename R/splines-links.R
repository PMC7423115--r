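#' Monotone I-spline link specification
#'
#' Defines the monotone transformation H(y) = eta0 + sum_k w_k^2 I_k(y) used
#' to map observed annual exposure intensities onto the latent-process scale.
#' The I-spline basis functions I_k are running integrals of an M-spline
#' basis of the given order, so H is non-decreasing by construction
#' (coefficients enter squared) and has the analytic derivative
#' H'(y) = sum_k w_k^2 M_k(y).
#'
#' The three conventional knots are interpreted as boundary, interior,
#' boundary: e.g. `c(0, 20, 100)` for daily cigarette counts or
#' `c(0, 0.05, 12.6)` for asbestos intensity in equivalent f/mL. Intensities
#' outside the boundary knots are clamped (with a warning at transform time).
#'
#' @param knots strictly increasing numeric vector of at least 3 values on
#'   the intensity scale; first and last are boundary knots.
#' @param w unconstrained spline coefficients (used squared); length must be
#'   `length(knots) - 2 + order`. May be `NULL` before fitting.
#' @param eta0 link intercept, fixed at 0 for identifiability with the
#'   latent-process location.
#' @param order spline order of the M-spline basis (3 = quadratic pieces,
#'   giving a continuously differentiable H).
#' @return an object of class `"link_spline"`.
#' @export
link_spline <- function(knots, w = NULL, eta0 = 0, order = 3) {
  knots <- as.numeric(knots)
  if (length(knots) < 3 || is.unsorted(knots, strictly = TRUE))
    stop("'knots' must be at least 3 strictly increasing values")
  n_basis <- length(knots) - 2L + as.integer(order)
  if (!is.null(w) && length(w) != n_basis)
    stop(sprintf("'w' must have length %d for these knots", n_basis))
  structure(list(knots = knots, w = w, eta0 = eta0, order = as.integer(order),
                 n_basis = n_basis),
            class = "link_spline")
}

#' @export
print.link_spline <- function(x, ...) {
  cat("Monotone I-spline link: order", x$order, "\n")
  cat("  knots:", paste(format(x$knots), collapse = ", "), "\n")
  if (is.null(x$w)) cat("  coefficients: not yet estimated\n")
  else cat("  w^2:", paste(format(x$w^2, digits = 4), collapse = ", "), "\n")
  invisible(x)
}

# extended knot sequence for B-splines of order `order + 1`; the I-spline
# basis is the upper partial sum of those B-splines (Ramsay 1988).
.link_ext_knots <- function(link) {
  k <- link$knots
  ord <- link$order + 1L
  c(rep(k[1], ord), k[-c(1, length(k))], rep(k[length(k)], ord))
}

.clamp <- function(y, lo, hi) pmin(pmax(y, lo), hi)

#' I-spline basis evaluation
#'
#' Each column is one I-spline basis function: 0 at and below the lower
#' boundary knot, 1 at and above the upper, non-decreasing in between.
#'
#' @param y numeric vector of intensities (clamped to the knot span).
#' @param link a [link_spline()] object (coefficients not required).
#' @return numeric matrix, `length(y)` rows by `link$n_basis` columns.
#' @export
ispline_basis <- function(y, link) {
  stopifnot(inherits(link, "link_spline"))
  yc <- .clamp(as.numeric(y), link$knots[1], link$knots[length(link$knots)])
  B <- splines::splineDesign(.link_ext_knots(link), yc, ord = link$order + 1L)
  K <- ncol(B) - 1L
  out <- matrix(0, length(yc), K)
  for (k in seq_len(K)) out[, k] <- rowSums(B[, (k + 1L):ncol(B), drop = FALSE])
  out
}

#' M-spline basis evaluation (derivative of the I-spline basis)
#'
#' @inheritParams ispline_basis
#' @return numeric matrix of the same shape as [ispline_basis()].
#' @export
mspline_basis <- function(y, link) {
  stopifnot(inherits(link, "link_spline"))
  yc <- .clamp(as.numeric(y), link$knots[1], link$knots[length(link$knots)])
  dB <- splines::splineDesign(.link_ext_knots(link), yc, ord = link$order + 1L,
                              derivs = rep(1L, length(yc)))
  K <- ncol(dB) - 1L
  out <- matrix(0, length(yc), K)
  for (k in seq_len(K)) out[, k] <- rowSums(dB[, (k + 1L):ncol(dB), drop = FALSE])
  out
}

.link_check_fitted <- function(link) {
  if (is.null(link$w)) stop("link has no coefficients; fit or supply 'w'")
}

#' Apply, differentiate, and invert the monotone link
#'
#' `link_transform()` evaluates H(y); `link_derivative()` evaluates H'(y);
#' `link_inverse()` maps latent-scale values back to the intensity scale by
#' monotone root-finding, clamping values outside `[H(min), H(max)]` to the
#' boundary intensities.
#'
#' @param y intensities; values outside the knot span are clamped with a
#'   warning.
#' @param link fitted [link_spline()] (non-`NULL` `w`).
#' @return numeric vector.
#' @export
link_transform <- function(y, link) {
  .link_check_fitted(link)
  rng <- range(link$knots)
  if (any(y < rng[1] - 1e-12 | y > rng[2] + 1e-12, na.rm = TRUE))
    warning("intensities outside the link knot span were clamped")
  drop(link$eta0 + ispline_basis(y, link) %*% (link$w^2))
}

#' @rdname link_transform
#' @export
link_derivative <- function(y, link) {
  .link_check_fitted(link)
  drop(mspline_basis(y, link) %*% (link$w^2))
}

#' @rdname link_transform
#' @param x latent-scale values.
#' @param tol absolute tolerance of the root-finder on the latent scale.
#' @export
link_inverse <- function(x, link, tol = 1e-10) {
  .link_check_fitted(link)
  if (sum(link$w^2) <= 0)
    stop("degenerate flat link (all coefficients zero) cannot be inverted")
  lo <- link$knots[1]; hi <- link$knots[length(link$knots)]
  Hlo <- link_transform(lo, link); Hhi <- link_transform(hi, link)
  vapply(as.numeric(x), function(xi) {
    if (xi <= Hlo) return(lo)
    if (xi >= Hhi) return(hi)
    stats::uniroot(function(y) link_transform(y, link) - xi,
                   lower = lo, upper = hi, tol = tol)$root
  }, numeric(1))
}

#' Natural cubic spline basis for the backward time axis
#'
#' Time is measured in whole years before the index date (0 at the index
#' date, increasing into the past). The design matrix is an intercept column
#' plus a natural cubic spline basis with the given inner knots; beyond the
#' boundary knots the basis extrapolates linearly (natural constraints).
#'
#' @param inner_knots inner knot positions in years before index
#'   (default 12, 24, 36 — the quartiles of exposure time in the motivating
#'   study design).
#' @param boundary_knots length-2 vector; defaults are set from the data at
#'   design time when `NULL`.
#' @return an object of class `"time_basis"`.
#' @export
time_basis <- function(inner_knots = c(12, 24, 36), boundary_knots = NULL) {
  inner_knots <- sort(as.numeric(inner_knots))
  if (!is.null(boundary_knots)) {
    boundary_knots <- as.numeric(boundary_knots)
    stopifnot(length(boundary_knots) == 2, boundary_knots[1] < boundary_knots[2])
  }
  structure(list(inner_knots = inner_knots, boundary_knots = boundary_knots,
                 n_basis = length(inner_knots) + 2L),
            class = "time_basis")
}

#' Time design matrix
#'
#' @param times numeric vector of years before the index date (>= 0).
#' @param basis a [time_basis()] object. When its boundary knots are `NULL`
#'   they are taken from `range(times)`.
#' @return matrix with `basis$n_basis` columns (intercept first).
#' @export
ncs_design <- function(times, basis = time_basis()) {
  stopifnot(inherits(basis, "time_basis"), all(times >= 0))
  bk <- basis$boundary_knots
  if (is.null(bk)) bk <- range(times)
  S <- splines::ns(times, knots = basis$inner_knots, Boundary.knots = bk)
  X <- cbind(1, unclass(S)[, , drop = FALSE])
  dimnames(X) <- list(NULL, c("(Intercept)",
                              paste0("ns", seq_len(ncol(X) - 1L))))
  X
}
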