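#' Excitation bundles: serialized TD-DFT results for one complex
#'
#' A bundle is a JSON document (schema id `phidelta-bundle/1`) carrying the
#' molecular geometry (Angstrom), the orbital source (inline Gaussian
#' contractions or a Molden file reference), per-state blocks (label,
#' excitation energy in eV, configuration and de-excitation triples
#' `[i, a, w]`, transition electric/velocity/magnetic dipoles in a.u.), the
#' S1-T1 spin-orbit coupling matrix element in cm^-1, and free-text
#' provenance for the upstream electronic-structure calculation. The bundle
#' insulates the descriptor engine from version-brittle quantum-chemistry
#' output formats.
#'
#' @param path path to a bundle JSON file
#' @return an `excitation_bundle`: list with `geometry` (elements,
#'   `coords_bohr`), `orbitals` (list of [gaussian_orbital()]s, or `NULL`
#'   with `molden` set), `states` (named by label), `soc` (cm^-1 or `NA`),
#'   `provenance`
#' @export
read_excitation_bundle <- function(path) {
  if (!file.exists(path)) stop(sprintf("bundle file not found: %s", path))
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  problems <- character(0)
  if (is.null(doc$schema)) problems <- c(problems, "missing 'schema' id")
  else if (!identical(doc$schema, "phidelta-bundle/1"))
    stop(sprintf(
      "bundle schema '%s' is not supported; this reader handles phidelta-bundle/1 (re-export or migrate the bundle)",
      doc$schema))
  if (is.null(doc$geometry$elements)) problems <- c(problems, "missing geometry.elements")
  if (is.null(doc$geometry$coords_angstrom)) problems <- c(problems, "missing geometry.coords_angstrom")
  if (is.null(doc$states) || length(doc$states) == 0)
    problems <- c(problems, "missing states")
  labels <- vapply(doc$states, function(s)
    if (is.null(s$label)) NA_character_ else s$label, character(1))
  if (anyNA(labels)) problems <- c(problems, "state without a label")
  if (anyDuplicated(stats::na.omit(labels)))
    problems <- c(problems, "duplicate state labels")
  for (s in doc$states) {
    for (fld in c("configurations", "deexcitations")) {
      cf <- s[[fld]]
      if (is.null(cf)) next
      cf <- if (is.list(cf)) cf else asplit(cf, 1)
      for (k in seq_along(cf))
        if (length(cf[[k]]) != 3 || any(!is.finite(as.numeric(cf[[k]]))))
          problems <- c(problems, sprintf(
            "state '%s': malformed %s triple at index %d", s$label, fld, k))
    }
    if (is.null(s$energy_ev) || !is.finite(as.numeric(s$energy_ev)))
      problems <- c(problems, sprintf("state '%s': missing energy_ev", s$label))
  }
  if (length(problems) > 0)
    stop(paste(c("invalid excitation bundle:", problems), collapse = "\n  "))

  to_mat3 <- function(x) {
    if (is.matrix(x)) matrix(as.numeric(x), ncol = 3)
    else matrix(as.numeric(unlist(x)), ncol = 3, byrow = TRUE)
  }
  coords <- to_mat3(doc$geometry$coords_angstrom)
  orbitals <- NULL
  if (!is.null(doc$orbitals$inline)) {
    orbitals <- lapply(doc$orbitals$inline, function(o)
      gaussian_orbital(
        centers = to_mat3(o$centers),
        exponents = as.numeric(o$exponents),
        coefficients = as.numeric(o$coefficients),
        angular = to_mat3(o$angular),
        normalize_primitives = isTRUE(o$normalize_primitives),
        normalize = !isTRUE(o$raw)))
  } else if (!is.null(doc$orbitals$molden)) {
    mp <- doc$orbitals$molden
    if (!file.exists(mp))
      mp <- file.path(dirname(path), doc$orbitals$molden)
    orbitals <- read_molden(mp)$orbitals
  }
  states <- lapply(doc$states, function(s) {
    to_cfg <- function(x) {
      if (is.null(x) || length(x) == 0)
        return(data.frame(i = integer(), a = integer(), w = numeric()))
      m <- matrix(unlist(x), ncol = 3, byrow = TRUE)
      data.frame(i = as.integer(m[, 1]), a = as.integer(m[, 2]), w = m[, 3])
    }
    vec_or_null <- function(v) if (is.null(v)) NULL else as.numeric(v)
    list(label = s$label, energy_ev = as.numeric(s$energy_ev),
         configs = configuration_set(to_cfg(s$configurations),
                                     to_cfg(s$deexcitations)),
         tedm = vec_or_null(s$tedm), tvdm = vec_or_null(s$tvdm),
         tmdm = vec_or_null(s$tmdm))
  })
  names(states) <- labels
  structure(list(
    geometry = list(elements = doc$geometry$elements,
                    coords_bohr = ang2bohr(coords)),
    orbitals = orbitals,
    states = states,
    soc = if (is.null(doc$soc_cm1)) NA_real_ else as.numeric(doc$soc_cm1),
    provenance = doc$provenance),
    class = "excitation_bundle")
}

#' Write an excitation bundle to JSON
#' @param bundle list in the shape produced by [read_excitation_bundle()],
#'   or a raw document list with `geometry`, `states`, etc.
#' @param path output path
#' @return `path`, invisibly
#' @export
write_excitation_bundle <- function(bundle, path) {
  doc <- list(schema = "phidelta-bundle/1",
              geometry = list(
                elements = bundle$geometry$elements,
                coords_angstrom = bohr2ang(bundle$geometry$coords_bohr)),
              soc_cm1 = if (is.na(bundle$soc)) NULL else bundle$soc,
              provenance = bundle$provenance)
  doc$orbitals <- if (!is.null(bundle$orbitals)) list(
    inline = lapply(bundle$orbitals, function(o) list(
      centers = o$centers, exponents = o$exponents,
      coefficients = o$coefficients, angular = o$angular,
      normalize_primitives = FALSE, raw = TRUE)))
  doc$states <- lapply(bundle$states, function(s) list(
    label = s$label, energy_ev = s$energy_ev,
    configurations = unname(as.matrix(s$configs$excitations)),
    deexcitations = if (nrow(s$configs$deexcitations) > 0)
      unname(as.matrix(s$configs$deexcitations)),
    tedm = s$tedm, tvdm = s$tvdm, tmdm = s$tmdm))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Compute the quantum-chemistry descriptor record of a bundle
#'
#' End-to-end driver: builds the hole/electron fields of the S1 and T1
#' states on an atom-centered Becke grid, computes the per-state descriptor
#' blocks and assembles the 40-column record.
#'
#' @param bundle an `excitation_bundle` (with orbitals resolved)
#' @param fragments fragment label per atom (with one label equal to
#'   `metal_fragment`) or `NULL` to skip MLCT
#' @param metal_fragment fragment label of the metal center
#' @param grid_level Becke grid resolution (1-5)
#' @param mode Sr/HDI/EDI convention ([overlap_indices()])
#' @param hct_variant see [geometry_indices()]
#' @return a `qcd_record`
#' @export
qcd_from_bundle <- function(bundle, fragments = NULL, metal_fragment = NULL,
                            grid_level = 3, mode = "as-printed",
                            hct_variant = "dot") {
  stopifnot(inherits(bundle, "excitation_bundle"))
  need <- c("S1", "T1")
  missing <- setdiff(need, names(bundle$states))
  if (length(missing) > 0)
    stop(sprintf("bundle lacks state(s): %s", paste(missing, collapse = ", ")))
  if (is.null(bundle$orbitals)) stop("bundle carries no orbitals")
  grid <- becke_grid(bundle$geometry$coords_bohr, level = grid_level)
  one <- function(label) {
    st <- bundle$states[[label]]
    fields <- build_hole_electron(st$configs, bundle$orbitals, grid)
    sp <- spectroscopic_descriptors(st$energy_ev, tedm = st$tedm,
                                    tvdm = st$tvdm, tmdm = st$tmdm,
                                    soc = bundle$soc)
    list(block = state_descriptors(
      fields, sp, atom_centers = bundle$geometry$coords_bohr,
      fragments = fragments, metal_fragment = metal_fragment,
      mode = mode, hct_variant = hct_variant),
      spectro = sp)
  }
  s1 <- one("S1"); t1 <- one("T1")
  assemble_qcd_record(s1$block, t1$block, s1$spectro, soc = bundle$soc)
}

# ---------------------------------------------------------------------------
# Molden, XYZ, cube

MOLDEN_SHELLS <- list(
  s = matrix(c(0L, 0L, 0L), 1, 3, byrow = TRUE),
  p = matrix(c(1L, 0L, 0L, 0L, 1L, 0L, 0L, 0L, 1L), 3, 3, byrow = TRUE),
  # Cartesian 6d in Molden order: xx, yy, zz, xy, xz, yz
  d = matrix(c(2L, 0L, 0L, 0L, 2L, 0L, 0L, 0L, 2L,
               1L, 1L, 0L, 1L, 0L, 1L, 0L, 1L, 1L), 6, 3, byrow = TRUE))

#' Read a Molden orbital file
#'
#' Parses the `[Atoms]`, `[GTO]` and `[MO]` sections. Supported shells: s,
#' p and Cartesian d (files flagged `[5D]` spherical are rejected).
#' Contraction coefficients are taken in the Molden convention of
#' unnormalized primitives and renormalized on load; each molecular orbital
#' becomes one [gaussian_orbital()] whose primitives carry the MO
#' coefficients.
#'
#' @param path Molden file path
#' @return list `atoms` (data frame element, x, y, z in bohr) and
#'   `orbitals` (list of `gaussian_orbital`s in file order)
#' @export
read_molden <- function(path) {
  if (!file.exists(path)) stop(sprintf("Molden file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (any(grepl("^\\s*\\[5D", lines, ignore.case = TRUE)))
    stop("spherical-harmonic d shells ([5D]) are not supported; re-export with Cartesian (6d) functions")
  sect <- function(name) {
    st <- grep(sprintf("^\\s*\\[%s\\]", name), lines, ignore.case = TRUE)
    if (length(st) == 0) return(NULL)
    en <- grep("^\\s*\\[", lines)
    en <- en[en > st[1]]
    lines[(st[1] + 1):(if (length(en)) en[1] - 1 else length(lines))]
  }
  hdr <- grep("^\\s*\\[Atoms\\]", lines, ignore.case = TRUE, value = TRUE)
  if (length(hdr) == 0) stop("Molden file has no [Atoms] section")
  unit_ang <- grepl("Angs", hdr[1], ignore.case = TRUE)
  at <- sect("Atoms")
  at <- at[nzchar(trimws(at))]
  tok <- strsplit(trimws(at), "\\s+")
  atoms <- data.frame(
    element = vapply(tok, `[`, character(1), 1),
    x = as.numeric(vapply(tok, `[`, character(1), 4)),
    y = as.numeric(vapply(tok, `[`, character(1), 5)),
    z = as.numeric(vapply(tok, `[`, character(1), 6)),
    stringsAsFactors = FALSE)
  if (unit_ang) atoms[c("x", "y", "z")] <- ang2bohr(atoms[c("x", "y", "z")])

  gto <- sect("GTO")
  if (is.null(gto)) stop("Molden file has no [GTO] section")
  gto <- gto[nzchar(trimws(gto))]
  # basis functions in file order: center, angular row, exponents, coeffs
  basis <- list()
  i <- 1
  while (i <= length(gto)) {
    head <- strsplit(trimws(gto[i]), "\\s+")[[1]]
    atom_idx <- suppressWarnings(as.integer(head[1]))
    if (is.na(atom_idx)) stop(sprintf("malformed [GTO] atom header: '%s'", gto[i]))
    i <- i + 1
    repeat {
      if (i > length(gto)) break
      ln <- trimws(gto[i])
      tk <- strsplit(ln, "\\s+")[[1]]
      if (!tolower(tk[1]) %in% c("s", "p", "d", "f", "sp")) break
      shell <- tolower(tk[1])
      nprim <- as.integer(tk[2])
      if (shell == "f") stop("f shells are not supported by this reader")
      prim <- do.call(rbind, lapply(gto[(i + 1):(i + nprim)], function(l)
        as.numeric(strsplit(trimws(gsub("[DdEe]([+-])", "e\\1", l)),
                            "\\s+")[[1]])))
      i <- i + nprim + 1
      ang <- MOLDEN_SHELLS[[shell]]
      for (r in seq_len(nrow(ang)))
        basis[[length(basis) + 1]] <- list(
          atom = atom_idx, angular = ang[r, ],
          exponents = prim[, 1], coefficients = prim[, 2])
    }
  }
  mo <- sect("MO")
  if (is.null(mo)) stop("Molden file has no [MO] section")
  mo <- mo[nzchar(trimws(mo))]
  orbitals <- list()
  coef <- NULL
  flush <- function() {
    if (is.null(coef)) return()
    centers <- NULL; expo <- NULL; co <- NULL; ang <- NULL
    for (b in seq_along(basis)) {
      if (b > length(coef) || coef[b] == 0) next
      bf <- basis[[b]]
      np <- length(bf$exponents)
      ctr <- as.numeric(atoms[bf$atom, c("x", "y", "z")])
      centers <- rbind(centers, matrix(rep(ctr, np), ncol = 3, byrow = TRUE))
      expo <- c(expo, bf$exponents)
      # normalize primitives within the contraction, then scale the
      # contracted (unit-norm) basis function by the MO coefficient
      cf <- bf$coefficients * primitive_norm(bf$exponents,
                                             matrix(bf$angular, np, 3,
                                                    byrow = TRUE))
      tmp <- structure(list(centers = matrix(rep(ctr, np), ncol = 3,
                                             byrow = TRUE),
                            exponents = bf$exponents, coefficients = cf,
                            angular = matrix(bf$angular, np, 3, byrow = TRUE)),
                       class = "gaussian_orbital")
      s <- orbital_self_overlap(tmp)
      co <- c(co, coef[b] * cf / sqrt(s))
      ang <- rbind(ang, matrix(bf$angular, np, 3, byrow = TRUE))
    }
    orbitals[[length(orbitals) + 1]] <<- structure(
      list(centers = centers, exponents = expo, coefficients = co,
           angular = ang),
      class = "gaussian_orbital")
  }
  seen_coef <- FALSE
  for (ln in mo) {
    t <- trimws(ln)
    if (grepl("^(Sym|Ene|Spin|Occup)", t, ignore.case = TRUE)) {
      # header line: starts a new orbital once coefficients have been read
      if (seen_coef) { flush(); coef <- NULL; seen_coef <- FALSE }
      next
    }
    tk <- strsplit(t, "\\s+")[[1]]
    if (length(tk) == 2 && !is.na(suppressWarnings(as.integer(tk[1])))) {
      if (is.null(coef)) coef <- numeric(length(basis))
      coef[as.integer(tk[1])] <- as.numeric(tk[2])
      seen_coef <- TRUE
    }
  }
  flush()
  list(atoms = atoms, orbitals = orbitals)
}

#' Read an XYZ geometry file
#' @param path XYZ file (coordinates in Angstrom)
#' @return list `elements`, `coords_bohr` (n x 3 matrix)
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- as.integer(trimws(lines[1]))
  if (is.na(n) || length(lines) < n + 2) stop("malformed XYZ file")
  tok <- strsplit(trimws(lines[3:(n + 2)]), "\\s+")
  list(elements = vapply(tok, `[`, character(1), 1),
       coords_bohr = ang2bohr(matrix(
         as.numeric(unlist(lapply(tok, `[`, 2:4))), ncol = 3, byrow = TRUE)))
}

#' Write a scalar field as a Gaussian cube file
#'
#' Standard cube layout: two comment lines, atom count and origin, three
#' voxel-axis records, atom records, then the field in z-fastest order. The
#' grid must be a rectilinear [uniform_grid()].
#'
#' @param field numeric field values on the grid (in grid point order)
#' @param grid a `quadrature_grid` produced by [uniform_grid()]
#' @param path output path
#' @param elements,coords_bohr atoms to embed (optional)
#' @param comment first header line
#' @return `path`, invisibly
#' @export
write_cube <- function(field, grid, path, elements = character(0),
                       coords_bohr = NULL, comment = "phidelta field") {
  if (is.null(grid$dims)) stop("cube export needs a uniform rectilinear grid")
  dims <- grid$dims; h <- grid$voxel; org <- grid$origin
  z_an <- function(el) {
    common <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, P = 15, S = 16,
                Cl = 17, Br = 35, I = 53, Fe = 26, Ru = 44, Rh = 45,
                Pd = 46, Re = 75, Os = 76, Ir = 77, Pt = 78, Au = 79)
    if (el %in% names(common)) common[[el]] else 0
  }
  con <- file(path, "w")
  on.exit(close(con))
  nat <- length(elements)
  writeLines(c(comment, "generated by phidelta"), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", nat, org[1], org[2], org[3]),
             con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", dims[1], h[1], 0, 0), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", dims[2], 0, h[2], 0), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", dims[3], 0, 0, h[3]), con)
  if (nat > 0)
    for (k in seq_len(nat))
      writeLines(sprintf("%5d %11.6f %11.6f %11.6f %11.6f", z_an(elements[k]),
                         0, coords_bohr[k, 1], coords_bohr[k, 2],
                         coords_bohr[k, 3]), con)
  # expand.grid order is x-fastest; cube wants z-fastest
  arr <- array(field, dim = dims)
  vals <- as.numeric(aperm(arr, c(3, 2, 1)))  # now x slow ... z fast
  idx <- seq_along(vals)
  writeLines(vapply(split(vals, ceiling(idx / 6)), function(v)
    paste(sprintf("%13.5e", v), collapse = " "), character(1)), con)
  invisible(path)
}

#' Write / read a feature table as CSV plus JSON column manifest
#'
#' @param table a `feature_table`
#' @param path CSV path; the manifest is written alongside as
#'   `<path>.manifest.json`
#' @return `path`, invisibly
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(as.data.frame(table, check.names = FALSE), path,
                   row.names = FALSE)
  jsonlite::write_json(attr(table, "manifest"),
                       paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  mpath <- paste0(path, ".manifest.json")
  if (file.exists(mpath))
    attr(tab, "manifest") <- jsonlite::fromJSON(mpath, simplifyVector = TRUE)
  class(tab) <- c("feature_table", "data.frame")
  tab
}
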