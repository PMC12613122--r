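#' Hole/electron centroids, spreads and the H vector
#'
#' The centroid of each density is its density-weighted mean position (the
#' density is first normalized to unit integral). The per-axis spread is
#' \deqn{\sigma_\lambda^s = \sqrt{\int (\lambda - \Gamma_s)^2 \rho_s(r) dr}}
#' for \eqn{\lambda \in \{x, y, z\}} and the H vector averages the hole and
#' electron spreads axis by axis,
#' \eqn{H_\lambda = (\sigma_\lambda^{ele} + \sigma_\lambda^{hole}) / 2}.
#' `u_ct` is the unit vector pointing from the hole centroid toward the
#' electron centroid (undefined, and flagged, when they coincide).
#'
#' For full-TD inputs the densities may be negative in places; moments are
#' then taken on the signed density normalized by its (positive) integral,
#' and the result is flagged when more than 5 percent of the total absolute
#' weight is negative.
#'
#' @param fields a `hole_electron_fields`
#' @return a `descriptor_intermediates` list: `centroid_hole`, `centroid_ele`
#'   (bohr), `sigma_hole`, `sigma_ele`, `h_vec` (bohr), `u_ct`,
#'   `negative_flag`
#' @export
centroid_and_sigma <- function(fields) {
  g <- fields$grid
  one_state <- function(rho, label) {
    tot <- integrate_field(rho, g)
    if (tot <= 0)
      stop(sprintf("%s density integrates to %.3g; cannot form moments",
                   label, tot))
    p <- rho * g$weights / tot
    ctr <- as.numeric(crossprod(p, g$points))
    dev <- unname(sweep(g$points, 2, ctr))
    cov <- crossprod(dev, dev * p)              # full second-moment matrix
    # signed densities can give slightly negative variances; clamp at zero
    list(centroid = ctr, sigma = sqrt(pmax(diag(cov), 0)), cov = cov,
         neg_share = sum(abs(pmin(rho, 0)) * g$weights) /
           sum(abs(rho) * g$weights))
  }
  h <- one_state(fields$rho_hole, "hole")
  e <- one_state(fields$rho_ele, "electron")
  d <- e$centroid - h$centroid
  dn <- sqrt(sum(d^2))
  structure(list(
    centroid_hole = h$centroid, centroid_ele = e$centroid,
    sigma_hole = h$sigma, sigma_ele = e$sigma,
    cov_hole = h$cov, cov_ele = e$cov,
    h_vec = (e$sigma + h$sigma) / 2,
    u_ct = if (dn > 1e-10) d / dn else c(NA_real_, NA_real_, NA_real_),
    coincident = dn <= 1e-10,
    negative_flag = max(h$neg_share, e$neg_share) > 0.05),
    class = "descriptor_intermediates")
}

#' Overlap and delocalization indices (Sr, HDI, EDI)
#'
#' Two conventions are supported and recorded in the result. In the default
#' `"as-printed"` mode \eqn{S_r = \int \rho^{hole}\rho^{ele} dr},
#' \eqn{HDI = 100 \int (\rho^{hole})^2 dr} and
#' \eqn{EDI = 100 \int (\rho^{ele})^2 dr}. The `"compat"` mode applies the
#' square roots used in the wider hole-electron analysis literature:
#' \eqn{S_r = \int \sqrt{\rho^{hole}\rho^{ele}} dr} (over the nonnegative
#' part) and \eqn{HDI/EDI = 100\sqrt{\int \rho^2 dr}}; compat-mode Sr lies in
#' [0, 1] for normalized nonnegative densities.
#'
#' @param fields a `hole_electron_fields`
#' @param mode `"as-printed"` or `"compat"`
#' @return list with `sr`, `hdi`, `edi`, `mode`
#' @export
overlap_indices <- function(fields, mode = c("as-printed", "compat")) {
  mode <- match.arg(mode)
  g <- fields$grid
  h <- fields$rho_hole; e <- fields$rho_ele
  if (mode == "as-printed") {
    list(sr = integrate_field(h * e, g),
         hdi = 100 * integrate_field(h^2, g),
         edi = 100 * integrate_field(e^2, g),
         mode = mode)
  } else {
    list(sr = integrate_field(sqrt(pmax(h * e, 0)), g),
         hdi = 100 * sqrt(integrate_field(h^2, g)),
         edi = 100 * sqrt(integrate_field(e^2, g)),
         mode = mode)
  }
}

#' Charge-transfer geometry indices (D, delta-sigma, H_CT, H, t)
#'
#' \itemize{
#'   \item `d`: Euclidean distance between hole and electron centroids.
#'   \item `delta_sigma`: \eqn{|\sigma^{ele}| - |\sigma^{hole}|} (difference
#'     of the Euclidean norms of the spread vectors).
#'   \item `hct`: spread of the pair along the charge-transfer direction. The
#'     default projects the per-axis H vector on the CT unit vector,
#'     \eqn{|H \cdot u_{CT}|}, exactly as the index is conventionally
#'     printed; because the per-axis spreads are coordinate-frame
#'     quantities, this form (and hence `t`) changes under rigid rotation
#'     of the molecule. `hct_variant = "covariance"` instead evaluates the
#'     true spread along the CT direction from the full second-moment
#'     matrices, \eqn{(\sqrt{u^T\Sigma^{ele}u} + \sqrt{u^T\Sigma^{hole}u})/2},
#'     which is rotation invariant. `hct_variant = "cross"` takes the
#'     magnitude of the vector product \eqn{|H \times u_{CT}|} for audit.
#'   \item `h_index`: \eqn{(|\sigma^{ele}| + |\sigma^{hole}|)/2}.
#'   \item `t`: \eqn{D - H_{CT}}, the net hole-electron separation.
#' }
#' When the centroids coincide the CT direction is undefined; `hct` is then
#' defined as 0 and `ct_undefined` is set.
#'
#' @param inter a `descriptor_intermediates` from [centroid_and_sigma()]
#' @param hct_variant `"dot"` (default), `"covariance"` or `"cross"`
#' @return list `d`, `delta_sigma`, `hct`, `h_index`, `t`, `ct_undefined`
#' @export
geometry_indices <- function(inter,
                             hct_variant = c("dot", "covariance", "cross")) {
  hct_variant <- match.arg(hct_variant)
  stopifnot(inherits(inter, "descriptor_intermediates"))
  d <- sqrt(sum((inter$centroid_ele - inter$centroid_hole)^2))
  ns_e <- sqrt(sum(inter$sigma_ele^2))
  ns_h <- sqrt(sum(inter$sigma_hole^2))
  if (inter$coincident) {
    hct <- 0
  } else if (hct_variant == "dot") {
    hct <- abs(sum(inter$h_vec * inter$u_ct))
  } else if (hct_variant == "covariance") {
    u <- inter$u_ct
    hct <- as.numeric(sqrt(max(0, u %*% inter$cov_ele %*% u)) +
                        sqrt(max(0, u %*% inter$cov_hole %*% u))) / 2
  } else {
    u <- inter$u_ct; H <- inter$h_vec
    cr <- c(H[2] * u[3] - H[3] * u[2],
            H[3] * u[1] - H[1] * u[3],
            H[1] * u[2] - H[2] * u[1])
    hct <- sqrt(sum(cr^2))
  }
  list(d = d, delta_sigma = ns_e - ns_h, hct = hct,
       h_index = (ns_e + ns_h) / 2, t = d - hct,
       ct_undefined = inter$coincident)
}

#' Metal-to-ligand charge-transfer fraction
#'
#' The fraction of the excitation with MLCT character, computed from
#' fragment populations under an independent-fragment approximation:
#' (hole share on the metal fragment) times (electron share on all ligand
#' fragments). The definition name is recorded so downstream tables carry
#' their provenance.
#'
#' @param fields a `hole_electron_fields`
#' @param atom_centers natoms x 3 matrix (bohr)
#' @param fragments fragment label per atom
#' @param metal_fragment the single fragment label that is the metal center
#' @param method population scheme passed to [fragment_populations()]
#' @return list `mlct` (in [0, 1] up to quadrature error), `definition`
#' @export
mlct_fraction <- function(fields, atom_centers, fragments, metal_fragment,
                          method = "becke") {
  if (!metal_fragment %in% fragments)
    stop(sprintf("no fragment labelled '%s' in the partition", metal_fragment))
  if (sum(unique(fragments) == metal_fragment) != 1)
    stop("exactly one fragment must be tagged as the metal")
  pops <- fragment_populations(fields, atom_centers, fragments, method = method)
  hole_metal <- pops$hole[pops$fragment == metal_fragment]
  ele_ligand <- sum(pops$ele[pops$fragment != metal_fragment])
  list(mlct = hole_metal * ele_ligand,
       definition = "hole(metal) x electron(ligands), independent fragments")
}

#' Spectroscopic descriptors from bundle-level data
#'
#' Converts the excitation energy and transition dipoles of a state into the
#' scalar descriptors used by the QSPR table: absorption wavelength
#' \eqn{\lambda(nm) = 1239.841984 / E(eV)}, oscillator strengths in length
#' gauge \eqn{f_1 = (2/3) E(a.u.) |\mu_{len}|^2} and velocity gauge
#' \eqn{f_2 = (2/3) |\mu_{vel}|^2 / E(a.u.)}, and the magnitudes of the
#' transition electric and magnetic dipole moments (a.u.). The spin-orbit
#' coupling matrix element is parsed from upstream relativistic TD-DFT
#' output, never computed here.
#'
#' @param energy_ev excitation energy in eV (> 0)
#' @param tedm,tvdm,tmdm length-3 transition electric / velocity / magnetic
#'   dipole vectors in atomic units; `NULL` marks the quantity absent
#' @param soc S1-T1 spin-orbit coupling matrix element, cm^-1 (`NULL` if
#'   absent)
#' @return list `ee`, `wavelength_nm`, `fosc1`, `fosc2`, `tedm`, `tmdm`,
#'   `soc` (absent quantities are `NA`, never silently zero)
#' @export
spectroscopic_descriptors <- function(energy_ev, tedm = NULL, tvdm = NULL,
                                      tmdm = NULL, soc = NULL) {
  if (!is.finite(energy_ev) || energy_ev <= 0)
    stop("excitation energy must be positive")
  e_au <- energy_ev / HARTREE_EV
  mag <- function(v) if (is.null(v)) NA_real_ else sqrt(sum(v^2))
  m_len <- mag(tedm); m_vel <- mag(tvdm); m_mag <- mag(tmdm)
  list(ee = energy_ev,
       wavelength_nm = EV_NM / energy_ev,
       fosc1 = if (is.na(m_len)) NA_real_ else (2 / 3) * e_au * m_len^2,
       fosc2 = if (is.na(m_vel)) NA_real_ else (2 / 3) * m_vel^2 / e_au,
       tedm = m_len, tmdm = m_mag,
       soc = if (is.null(soc)) NA_real_ else as.numeric(soc))
}

# the twelve per-state descriptors, in canonical order
STATE_DESCRIPTORS <- c("sr", "d", "sigma", "hct", "h", "t", "hdi", "edi",
                       "ee", "mlct", "tedm", "tmdm")

#' Per-state descriptor block
#'
#' Convenience driver: computes the twelve per-state descriptors of one
#' excited state from its fields, fragment partition and spectroscopic data.
#' Spatial descriptors are reported in Angstrom (converted from bohr).
#'
#' @param fields a `hole_electron_fields`
#' @param spectro result of [spectroscopic_descriptors()]
#' @param atom_centers,fragments,metal_fragment passed to [mlct_fraction()];
#'   all `NULL` to skip MLCT (reported `NA`)
#' @param mode Sr/HDI/EDI convention, see [overlap_indices()]
#' @param hct_variant see [geometry_indices()]
#' @return named list of the twelve descriptors plus `mode`
#' @export
state_descriptors <- function(fields, spectro,
                              atom_centers = NULL, fragments = NULL,
                              metal_fragment = NULL,
                              mode = "as-printed", hct_variant = "dot") {
  inter <- centroid_and_sigma(fields)
  ov <- overlap_indices(fields, mode = mode)
  ge <- geometry_indices(inter, hct_variant = hct_variant)
  mlct <- if (is.null(atom_centers) || is.null(metal_fragment)) NA_real_
          else mlct_fraction(fields, atom_centers, fragments,
                             metal_fragment)$mlct
  list(sr = ov$sr,
       d = bohr2ang(ge$d),
       sigma = bohr2ang(ge$delta_sigma),
       hct = bohr2ang(ge$hct),
       h = bohr2ang(ge$h_index),
       t = bohr2ang(ge$t),
       hdi = ov$hdi, edi = ov$edi,
       ee = spectro$ee, mlct = mlct,
       tedm = spectro$tedm, tmdm = spectro$tmdm,
       mode = mode)
}

#' Assemble the 40-descriptor quantum-chemistry record
#'
#' Combines the S1 and T1 per-state blocks with their differences (D-block:
#' S value minus T value for each of the twelve descriptors) and the four
#' state-independent quantities: `soc` (cm^-1), `S1` (absorption wavelength,
#' nm) and the two S1 oscillator strengths.
#'
#' @param s1 per-state block of the S1 state ([state_descriptors()])
#' @param t1 per-state block of the T1 state
#' @param s1_spectro spectroscopic data of S1 (for wavelength and fosc)
#' @param soc S1-T1 spin-orbit coupling, cm^-1 (`NA` if absent)
#' @return a `qcd_record`: named numeric vector of the 40 descriptors in
#'   canonical column order, with the Sr/HDI/EDI mode in attribute `mode`
#' @export
assemble_qcd_record <- function(s1, t1, s1_spectro, soc = NA_real_) {
  if (!identical(s1$mode, t1$mode))
    stop("S1 and T1 blocks were computed with different Sr/HDI/EDI modes")
  sv <- unlist(s1[STATE_DESCRIPTORS])
  tv <- unlist(t1[STATE_DESCRIPTORS])
  rec <- c(stats::setNames(sv, paste0("S-", STATE_DESCRIPTORS)),
           stats::setNames(tv, paste0("T-", STATE_DESCRIPTORS)),
           stats::setNames(sv - tv, paste0("D-", STATE_DESCRIPTORS)),
           soc = as.numeric(soc),
           S1 = s1_spectro$wavelength_nm,
           fosc1 = s1_spectro$fosc1,
           fosc2 = s1_spectro$fosc2)
  structure(rec, mode = s1$mode, class = c("qcd_record", "numeric"))
}

#' Canonical QCD column names
#' @return character vector of the 40 quantum-chemistry descriptor names
#' @export
qcd_column_names <- function() {
  c(paste0("S-", STATE_DESCRIPTORS), paste0("T-", STATE_DESCRIPTORS),
    paste0("D-", STATE_DESCRIPTORS), "soc", "S1", "fosc1", "fosc2")
}
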