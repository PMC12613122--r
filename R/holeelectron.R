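#' Excited-state configuration sets
#'
#' In linear-response TD-DFT the excited-state wave function is a linear
#' combination of singly excited (coefficients `w`, occupied i -> virtual a)
#' and de-excited (coefficients `w'`, virtual a -> occupied i) configuration
#' functions. Under the Tamm-Dancoff approximation the de-excitation block is
#' empty; full TD input carries both.
#'
#' @param excitations data frame (or matrix) with columns `i`, `a`, `w`
#' @param deexcitations optional data frame with columns `i`, `a`, `w`;
#'   empty by default (TDA-like input)
#' @return a `configuration_set`
#' @export
configuration_set <- function(excitations,
                              deexcitations = data.frame(i = integer(),
                                                         a = integer(),
                                                         w = numeric())) {
  norm_cfg <- function(x, what) {
    x <- as.data.frame(x)
    names(x) <- c("i", "a", "w")[seq_len(ncol(x))]
    if (!all(c("i", "a", "w") %in% names(x)))
      stop(sprintf("%s need columns i, a, w", what))
    x$i <- as.integer(x$i); x$a <- as.integer(x$a); x$w <- as.numeric(x$w)
    if (anyDuplicated(x[c("i", "a")]))
      stop(sprintf("duplicate (i, a) pair in %s", what))
    if (any(!is.finite(x$w))) stop("configuration coefficients must be finite")
    x
  }
  exc <- norm_cfg(excitations, "excitations")
  dex <- norm_cfg(deexcitations, "deexcitations")
  nrm <- sum(exc$w^2) - sum(dex$w^2)
  if (nrm <= 0)
    stop("configuration norm sum(w^2) - sum(w'^2) must be positive")
  structure(list(excitations = exc, deexcitations = dex, norm = nrm),
            class = "configuration_set")
}

#' @export
print.configuration_set <- function(x, ...) {
  cat(sprintf("<configuration_set> %d excitations, %d de-excitations, norm %.4f\n",
              nrow(x$excitations), nrow(x$deexcitations), x$norm))
  invisible(x)
}

# evaluate the orbitals referenced by a configuration set; returns a named
# list mapping orbital index -> value vector
evaluate_referenced_orbitals <- function(configs, orbitals, grid) {
  idx <- sort(unique(c(configs$excitations$i, configs$excitations$a,
                       configs$deexcitations$i, configs$deexcitations$a)))
  vals <- list()
  for (k in idx) {
    key <- as.character(k)
    if (is.null(orbitals[[key]]) && (k > length(orbitals) ||
                                     is.null(orbitals[[k]])))
      stop(sprintf("configuration references orbital %d, which is not present",
                   k))
    orb <- if (!is.null(orbitals[[key]])) orbitals[[key]] else orbitals[[k]]
    vals[[key]] <- evaluate_orbital(orb, grid)
  }
  vals
}

# local + cross terms for one block (hole: key by occupied i, shared index a;
# electron: key by occupied i shared, orbitals are the virtuals)
hole_ele_block <- function(cfg, orbvals, side, sign = +1) {
  # side "hole": density built from occupied orbitals, cross terms couple
  #   configurations sharing the same virtual a (Eq 3)
  # side "ele": density from virtual orbitals, cross terms couple
  #   configurations sharing the same occupied i (Eq 6)
  np <- length(orbvals[[1]])
  local <- numeric(np); cross <- numeric(np)
  dens_idx <- if (side == "hole") cfg$i else cfg$a
  share_idx <- if (side == "hole") cfg$a else cfg$i
  phi <- function(k) orbvals[[as.character(k)]]
  for (r in seq_len(nrow(cfg)))
    local <- local + cfg$w[r]^2 * phi(dens_idx[r])^2
  # grouped evaluation of the ordered-pair double sum:
  # sum_{p != q, share equal} w_p w_q phi_p phi_q
  #   = sum_groups [ (sum w phi)^2 - sum (w phi)^2 ]
  for (s in unique(share_idx)) {
    rows <- which(share_idx == s)
    if (length(rows) < 2) next
    acc <- numeric(np); acc2 <- numeric(np)
    for (r in rows) {
      t <- cfg$w[r] * phi(dens_idx[r])
      acc <- acc + t
      acc2 <- acc2 + t * t
    }
    cross <- cross + (acc * acc - acc2)
  }
  list(local = sign * local, cross = sign * cross)
}

#' Build hole and electron distributions from configuration coefficients
#'
#' Constructs \eqn{\rho^{hole}} and \eqn{\rho^{ele}} on a quadrature grid as
#' local plus cross terms. The local terms are the diagonal
#' \eqn{\sum w^2 \phi^2} contributions of each configuration; the cross terms
#' couple pairs of configurations that share the virtual orbital (hole) or
#' the occupied orbital (electron). De-excitation coefficients enter every
#' term with a negative sign, so both densities integrate to
#' \eqn{\sum w^2 - \sum w'^2} when the orbitals are orthonormal.
#'
#' @param configs a [configuration_set()]
#' @param orbitals list of `gaussian_orbital`s indexed by the orbital numbers
#'   that the configurations reference (names or positions)
#' @param grid a `quadrature_grid`
#' @param include_cross logical; `FALSE` zeroes the cross terms only
#' @return a `hole_electron_fields` object with components `grid`,
#'   `rho_hole`, `rho_ele` and the four local/cross vectors
#' @export
build_hole_electron <- function(configs, orbitals, grid,
                                include_cross = TRUE) {
  stopifnot(inherits(configs, "configuration_set"),
            inherits(grid, "quadrature_grid"))
  orbvals <- evaluate_referenced_orbitals(configs, orbitals, grid)
  np <- nrow(grid$points)
  zero <- numeric(np)
  hole_l <- zero; hole_c <- zero; ele_l <- zero; ele_c <- zero
  if (nrow(configs$excitations) > 0) {
    h <- hole_ele_block(configs$excitations, orbvals, "hole", +1)
    e <- hole_ele_block(configs$excitations, orbvals, "ele", +1)
    hole_l <- hole_l + h$local; hole_c <- hole_c + h$cross
    ele_l <- ele_l + e$local; ele_c <- ele_c + e$cross
  }
  if (nrow(configs$deexcitations) > 0) {
    h <- hole_ele_block(configs$deexcitations, orbvals, "hole", -1)
    e <- hole_ele_block(configs$deexcitations, orbvals, "ele", -1)
    hole_l <- hole_l + h$local; hole_c <- hole_c + h$cross
    ele_l <- ele_l + e$local; ele_c <- ele_c + e$cross
  }
  if (!include_cross) {
    hole_c <- zero; ele_c <- zero
  }
  structure(
    list(grid = grid,
         rho_hole = hole_l + hole_c, rho_ele = ele_l + ele_c,
         hole_local = hole_l, hole_cross = hole_c,
         ele_local = ele_l, ele_cross = ele_c,
         norm = configs$norm),
    class = "hole_electron_fields")
}

#' @export
print.hole_electron_fields <- function(x, ...) {
  cat(sprintf("<hole_electron_fields> %d grid points; int(hole) = %.5f, int(ele) = %.5f\n",
              nrow(x$grid$points),
              integrate_field(x$rho_hole, x$grid),
              integrate_field(x$rho_ele, x$grid)))
  invisible(x)
}

#' Hole/electron population shares per molecular fragment
#'
#' Attributes each grid point's hole and electron density to atoms (Becke
#' fuzzy weights by default, or hard nearest-nucleus assignment), then sums
#' atoms into user-defined fragments. Shares are normalized by the total
#' hole/electron integrals, so they sum to one over fragments.
#'
#' @param fields a `hole_electron_fields`
#' @param atom_centers natoms x 3 matrix, bohr
#' @param fragments integer or character vector, length natoms, naming the
#'   fragment of each atom; every atom must be assigned
#' @param method `"becke"` (default) or `"nearest"`
#' @return data frame with columns `fragment`, `hole`, `ele` (shares)
#' @export
fragment_populations <- function(fields, atom_centers, fragments,
                                 method = c("becke", "nearest")) {
  method <- match.arg(method)
  if (is.null(dim(atom_centers))) atom_centers <- matrix(atom_centers, nrow = 1)
  atom_centers <- as.matrix(atom_centers)
  if (length(fragments) != nrow(atom_centers))
    stop("every atom must be assigned to exactly one fragment")
  if (any(is.na(fragments))) stop("unassigned atom in fragment map")
  pts <- fields$grid$points
  w <- fields$grid$weights
  if (method == "becke") {
    aw <- becke_weights(pts, atom_centers)
  } else {
    dist <- sapply(seq_len(nrow(atom_centers)), function(a) {
      d <- sweep(pts, 2, atom_centers[a, ]); rowSums(d * d)
    })
    dist <- matrix(dist, nrow = nrow(pts))
    nearest <- max.col(-dist, ties.method = "first")
    aw <- matrix(0, nrow(pts), nrow(atom_centers))
    aw[cbind(seq_len(nrow(pts)), nearest)] <- 1
  }
  frg <- unique(fragments)
  tot_h <- integrate_field(fields$rho_hole, fields$grid)
  tot_e <- integrate_field(fields$rho_ele, fields$grid)
  res <- data.frame(fragment = frg,
                    hole = NA_real_, ele = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(frg)) {
    fw <- rowSums(aw[, fragments == frg[k], drop = FALSE])
    res$hole[k] <- sum(fields$rho_hole * w * fw) / tot_h
    res$ele[k] <- sum(fields$rho_ele * w * fw) / tot_e
  }
  res
}
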