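#' Contracted Cartesian Gaussian orbitals
#'
#' A molecular orbital is represented as a linear combination of primitive
#' Cartesian Gaussians
#' \deqn{g(r) = c \, (x-X)^{l_x}(y-Y)^{l_y}(z-Z)^{l_z}
#'       \exp(-\alpha |r-R|^2)}
#' with center \eqn{R} in bohr, exponent \eqn{\alpha > 0} and angular-momentum
#' triple \eqn{(l_x, l_y, l_z)}. This is the form in which quantum-chemistry
#' programs export orbitals (e.g. through Molden files), and it is flexible
#' enough to express the analytic toy systems used for testing.
#'
#' @param centers numeric matrix (n x 3) of primitive centers in bohr, or a
#'   length-3 vector recycled to all primitives.
#' @param exponents positive numeric vector of primitive exponents.
#' @param coefficients numeric vector of contraction coefficients (applied to
#'   primitives *after* primitive normalization when `normalize_primitives`
#'   is `TRUE`).
#' @param angular integer matrix (n x 3) of Cartesian powers (lx, ly, lz), or
#'   a length-3 vector recycled.
#' @param normalize_primitives logical; multiply each primitive by its
#'   self-overlap normalization constant (the Molden convention for raw
#'   contraction coefficients).
#' @param normalize logical; rescale the contracted orbital to unit
#'   self-overlap.
#' @return an object of class `gaussian_orbital`.
#' @examples
#' # a normalized 1s Gaussian with exponent 0.5 at the origin
#' g <- gaussian_orbital(c(0, 0, 0), 0.5, 1, c(0, 0, 0))
#' orbital_self_overlap(g)  # 1
#' @export
gaussian_orbital <- function(centers, exponents, coefficients,
                             angular = c(0L, 0L, 0L),
                             normalize_primitives = TRUE,
                             normalize = TRUE) {
  if (is.null(dim(centers))) centers <- matrix(centers, nrow = 1)
  n <- max(nrow(centers), length(exponents), length(coefficients))
  if (nrow(centers) == 1 && n > 1)
    centers <- centers[rep(1, n), , drop = FALSE]
  if (is.null(dim(angular))) angular <- matrix(as.integer(angular), nrow = 1)
  if (nrow(angular) == 1 && n > 1)
    angular <- angular[rep(1, n), , drop = FALSE]
  exponents <- rep_len(exponents, n)
  coefficients <- rep_len(coefficients, n)
  stopifnot(ncol(centers) == 3, ncol(angular) == 3)
  if (!all(is.finite(exponents)) || any(exponents <= 0))
    stop("orbital exponents must be finite and positive")
  if (!all(is.finite(coefficients)))
    stop("orbital coefficients must be finite")
  if (any(angular < 0)) stop("angular-momentum powers must be >= 0")

  if (normalize_primitives)
    coefficients <- coefficients * primitive_norm(exponents, angular)

  orb <- structure(
    list(centers = centers, exponents = exponents,
         coefficients = coefficients, angular = angular),
    class = "gaussian_orbital")
  if (normalize) {
    s <- orbital_self_overlap(orb)
    if (!is.finite(s) || s <= 0) stop("orbital self-overlap is not positive")
    orb$coefficients <- orb$coefficients / sqrt(s)
  }
  orb
}

# (2l-1)!! for integer l >= 0
double_factorial_odd <- function(l) {
  vapply(l, function(li) if (li <= 0) 1 else prod(seq(1, 2 * li - 1, by = 2)),
         numeric(1))
}

# self-overlap normalization constant of a primitive Cartesian Gaussian
primitive_norm <- function(alpha, angular) {
  l <- angular[, 1]; m <- angular[, 2]; n <- angular[, 3]
  L <- l + m + n
  (2 * alpha / pi)^0.75 * (4 * alpha)^(L / 2) /
    sqrt(double_factorial_odd(l) * double_factorial_odd(m) *
           double_factorial_odd(n))
}

# analytic overlap of two primitive Cartesian Gaussians on the SAME center
# (sufficient for contraction normalization; general centers not needed here)
same_center_primitive_overlap <- function(a, la, b, lb) {
  l <- la + lb
  if (any(l %% 2 == 1)) return(0)
  p <- a + b
  prod(double_factorial_odd(l / 2) / (2 * p)^(l / 2) * sqrt(pi / p))
}

#' Analytic self-overlap of a contracted Gaussian orbital
#'
#' Exact for orbitals whose primitives share a center; falls back to a dense
#' numerical quadrature when primitives sit on different centers.
#' @param orbital a `gaussian_orbital`
#' @return numeric scalar, \eqn{\int \phi^2 dr}
#' @export
orbital_self_overlap <- function(orbital) {
  ctr <- orbital$centers
  same <- all(abs(sweep(ctr, 2, ctr[1, ])) < 1e-12)
  n <- length(orbital$exponents)
  if (same) {
    s <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (!all(orbital$angular[i, ] %% 2 == orbital$angular[j, ] %% 2)) next
      s <- s + orbital$coefficients[i] * orbital$coefficients[j] *
        same_center_primitive_overlap(orbital$exponents[i],
                                      orbital$angular[i, ],
                                      orbital$exponents[j],
                                      orbital$angular[j, ])
    }
    return(s)
  }
  # multi-center contraction: numerical quadrature on a fitted box
  g <- uniform_grid(orbital_bbox(orbital), spacing = 0.15)
  integrate_field(evaluate_orbital(orbital, g)^2, g)
}

# bounding box generously covering the orbital's support
orbital_bbox <- function(orbital, nsigma = 7) {
  ext <- nsigma / sqrt(2 * min(orbital$exponents))
  lo <- apply(orbital$centers, 2, min) - ext
  hi <- apply(orbital$centers, 2, max) + ext
  rbind(lo, hi)
}

#' Evaluate a Gaussian orbital on a quadrature grid
#'
#' @param orbital a `gaussian_orbital`
#' @param grid a `quadrature_grid` (see [uniform_grid()], [becke_grid()])
#' @return numeric vector of orbital values at every grid point
#' @export
evaluate_orbital <- function(orbital, grid) {
  stopifnot(inherits(orbital, "gaussian_orbital"),
            inherits(grid, "quadrature_grid"))
  pts <- grid$points
  if (nrow(pts) == 0) stop("grid is empty")
  val <- numeric(nrow(pts))
  for (k in seq_along(orbital$exponents)) {
    dx <- pts[, 1] - orbital$centers[k, 1]
    dy <- pts[, 2] - orbital$centers[k, 2]
    dz <- pts[, 3] - orbital$centers[k, 3]
    r2 <- dx * dx + dy * dy + dz * dz
    ang <- orbital$angular[k, ]
    poly <- 1
    if (ang[1] > 0) poly <- poly * dx^ang[1]
    if (ang[2] > 0) poly <- poly * dy^ang[2]
    if (ang[3] > 0) poly <- poly * dz^ang[3]
    val <- val + orbital$coefficients[k] * poly *
      exp(-orbital$exponents[k] * r2)
  }
  val
}

#' Shift an orbital rigidly by a translation vector
#' @param orbital a `gaussian_orbital`
#' @param shift length-3 numeric, bohr
#' @return translated `gaussian_orbital`
#' @export
translate_orbital <- function(orbital, shift) {
  orbital$centers <- sweep(orbital$centers, 2, shift, "+")
  orbital
}
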