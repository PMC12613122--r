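# Independent oracles used across the suite. These deliberately avoid the
# package's vectorized code paths: orbital values come from a literal
# primitive-by-primitive evaluator, and hole/electron densities from a
# literal double loop over configuration pairs written term by term.

# literal evaluator for a contracted Cartesian Gaussian at a point matrix
ref_eval_orbital <- function(orb, pts) {
  out <- numeric(nrow(pts))
  for (k in seq_along(orb$exponents)) {
    for (p in seq_len(nrow(pts))) {
      d <- pts[p, ] - orb$centers[k, ]
      out[p] <- out[p] + orb$coefficients[k] *
        prod(d^orb$angular[k, ]) * exp(-orb$exponents[k] * sum(d^2))
    }
  }
  out
}

# literal term-by-term hole/electron densities: local terms as written, the
# cross sums as explicit ordered-pair double loops (hole couples pairs that
# share the virtual orbital, electron pairs that share the occupied one)
ref_hole_electron <- function(configs, orbitals, grid) {
  pts <- grid$points
  phi <- lapply(orbitals, ref_eval_orbital, pts = pts)
  np <- nrow(pts)
  block <- function(cfg, sgn) {
    hole_l <- numeric(np); hole_c <- numeric(np)
    ele_l <- numeric(np); ele_c <- numeric(np)
    m <- nrow(cfg)
    for (p in seq_len(m)) {
      hole_l <- hole_l + cfg$w[p]^2 * phi[[cfg$i[p]]]^2
      ele_l <- ele_l + cfg$w[p]^2 * phi[[cfg$a[p]]]^2
      for (q in seq_len(m)) {
        if (q == p) next
        if (cfg$a[q] == cfg$a[p] && cfg$i[q] != cfg$i[p])
          hole_c <- hole_c + cfg$w[p] * cfg$w[q] *
            phi[[cfg$i[p]]] * phi[[cfg$i[q]]]
        if (cfg$i[q] == cfg$i[p] && cfg$a[q] != cfg$a[p])
          ele_c <- ele_c + cfg$w[p] * cfg$w[q] *
            phi[[cfg$a[p]]] * phi[[cfg$a[q]]]
      }
    }
    lapply(list(hole_l = hole_l, hole_c = hole_c,
                ele_l = ele_l, ele_c = ele_c), function(v) sgn * v)
  }
  acc <- block(configs$excitations, +1)
  if (nrow(configs$deexcitations) > 0) {
    d <- block(configs$deexcitations, -1)
    acc <- Map(`+`, acc, d)
  }
  list(rho_hole = acc$hole_l + acc$hole_c,
       rho_ele = acc$ele_l + acc$ele_c)
}

# small deterministic rotation matrix (rotation about a fixed axis)
ref_rotation <- function(angle = 0.7, axis = c(1, 2, 2) / 3) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

rotate_orbital <- function(orb, R) {
  # s-type primitives only (angular all zero): rotating the centers suffices
  stopifnot(all(orb$angular == 0))
  orb$centers <- orb$centers %*% t(R)
  orb
}

# random valid configuration set over a given orbital count; resamples until
# the net norm is comfortably positive
random_configuration_set <- function(n_occ, n_vir, n_exc, n_dex = 0) {
  pairs <- expand.grid(i = seq_len(n_occ), a = n_occ + seq_len(n_vir))
  repeat {
    exc <- pairs[sample.int(nrow(pairs), n_exc), ]
    exc$w <- runif(n_exc, -1, 1)
    dex <- NULL
    if (n_dex > 0) {
      dex <- pairs[sample.int(nrow(pairs), n_dex), ]
      dex$w <- runif(n_dex, -0.2, 0.2)
    }
    if (sum(exc$w^2) - sum(if (is.null(dex)) 0 else dex$w^2) > 0.1) break
  }
  if (is.null(dex)) configuration_set(exc) else configuration_set(exc, dex)
}

# random set of s-Gaussian orbitals with well-spread centers; orthonormality
# is NOT implied (tests that need it use far-separated centers)
random_s_orbitals <- function(n, spread = 6, alpha_range = c(0.4, 1.2)) {
  lapply(seq_len(n), function(k)
    gaussian_orbital(runif(3, -spread, spread),
                     runif(1, alpha_range[1], alpha_range[2]), 1))
}

# far-separated (numerically orthonormal) s orbitals on a line
separated_s_orbitals <- function(n, gap = 12, alpha = 0.7) {
  lapply(seq_len(n), function(k)
    gaussian_orbital(c((k - 1) * gap, 0, 0), alpha, 1))
}

with_seed_runif <- function(seed, n) {
  set.seed(seed)
  runif(n)
}

grid_for_orbitals <- function(orbitals, level = 3) {
  centers <- do.call(rbind, lapply(orbitals, function(o) o$centers))
  becke_grid(unique(centers), level = level)
}
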