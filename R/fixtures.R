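#' Analytic two-Gaussian excitation fixture
#'
#' A toy excited state with closed-form descriptor values: the hole sits in
#' a normalized s-type Gaussian at the origin and the electron in an
#' identical Gaussian displaced by `separation` along +z (single excitation
#' 1 -> 2, w = 1). For exponent \eqn{\alpha} the density
#' \eqn{\phi^2 \propto e^{-2\alpha r^2}} has per-axis spread
#' \eqn{\sigma = 1/(2\sqrt{\alpha})}, the centroid distance is exactly the
#' separation, and for zero separation Sr and the delocalization integrals
#' have the closed forms of a Gaussian self-overlap. Expected values carry
#' their provenance (closed form) so tests never compare the engine against
#' itself.
#'
#' @param separation hole-electron displacement along z, bohr (>= 0)
#' @param alpha_hole,alpha_ele Gaussian exponents
#' @return list with `orbitals`, `configs`, `centers` (the two Gaussian
#'   centers), `spectro` (nominal S1-like energy/dipoles), `expected`
#'   (closed-form centroids, sigma, d in bohr) and `provenance`
#' @export
gaussian_excitation_fixture <- function(separation = 4, alpha_hole = 0.5,
                                        alpha_ele = alpha_hole) {
  if (separation < 0) stop("separation must be >= 0")
  c1 <- c(0, 0, 0); c2 <- c(0, 0, separation)
  orbitals <- list(
    gaussian_orbital(c1, alpha_hole, 1, c(0, 0, 0)),
    gaussian_orbital(c2, alpha_ele, 1, c(0, 0, 0)))
  configs <- configuration_set(data.frame(i = 1, a = 2, w = 1))
  expected <- list(
    centroid_hole = c1, centroid_ele = c2,
    sigma_hole = rep(1 / (2 * sqrt(alpha_hole)), 3),
    sigma_ele = rep(1 / (2 * sqrt(alpha_ele)), 3),
    d = separation)
  list(orbitals = orbitals, configs = configs,
       centers = rbind(c1, c2),
       spectro = spectroscopic_descriptors(
         2.4, tedm = c(0.5, 0, 0), tvdm = c(0.45, 0, 0),
         tmdm = c(0, 0, 0.1), soc = 150),
       expected = expected,
       provenance = "closed form: sigma = 1/(2 sqrt(alpha)), D = separation")
}

# canonical descriptor manifest reused by the synthetic table so pipeline
# tests exercise exactly the production schema
full_descriptor_manifest <- function() {
  c(qcd_column_names(), structure_column_names(),
    "cn", "cp", "mc", "cf", "cd", "cs", "eps", "epsinf", "wl")
}

#' Synthetic QSPR table
#'
#' Generates a feature table with the full production descriptor manifest
#' (40 quantum-chemistry, 24 structure, 6 metal, 3 condition columns) and a
#' target in (0, 1] that is a stated smooth function of a small signal
#' descriptor set plus Gaussian noise. Descriptor marginals are drawn from
#' block-appropriate distributions (overlap indices in [0, 1], counts as
#' small integers, SOC log-normal); no attempt is made to mimic the
#' correlation structure of real transition-metal-complex data beyond the
#' block layout. The raw signal is squashed into (0, 1] by the logistic
#' function, and the generation is byte-identical under a fixed seed.
#'
#' @param n number of rows (>= 10)
#' @param noise_sd Gaussian noise, as a fraction of the raw signal's SD
#' @param seed integer seed
#' @param signal named numeric vector of signal weights on standardized
#'   descriptors; default five descriptors spanning the four blocks
#' @return a `feature_table` with extra attribute `signal` naming the
#'   planted descriptors and weights
#' @export
synthetic_qspr_table <- function(n = 136, noise_sd = 0.05, seed = 1,
                                 signal = c(`S-ee` = 1.0, `T-ee` = -0.8,
                                            soc = 0.7, mw = 0.5,
                                            eps = -0.4)) {
  if (n < 10) stop("need at least 10 rows")
  cols <- full_descriptor_manifest()
  if (!all(names(signal) %in% cols))
    stop("signal descriptors must belong to the descriptor manifest")
  tab <- with_local_seed(seed, {
    draw <- function(col) {
      base <- sub("^[STD]-", "", col)
      switch(base,
        sr = , mlct = stats::runif(n, 0, 1),
        d = , hct = , h = , t = abs(stats::rnorm(n, 2, 1)),
        sigma = stats::rnorm(n, 0, 0.5),
        hdi = , edi = stats::runif(n, 2, 30),
        ee = stats::runif(n, 1.2, 3.2),
        tedm = , tmdm = abs(stats::rnorm(n, 1, 0.6)),
        soc = stats::rlnorm(n, log(100), 1),
        S1 = stats::runif(n, 380, 900),
        fosc1 = , fosc2 = abs(stats::rnorm(n, 0.1, 0.08)),
        nc = sample(0:3, n, replace = TRUE),
        lc = sample(-2:0, n, replace = TRUE),
        cc = sample(-2:0, n, replace = TRUE),
        an = sample(30:160, n, replace = TRUE),
        mw = stats::runif(n, 300, 1600),
        cn = sample(1:2, n, replace = TRUE, prob = c(0.9, 0.1)),
        cp = sample(4:6, n, replace = TRUE),
        mc = sample(1:3, n, replace = TRUE),
        cf = sample(c(0, 14), n, replace = TRUE),
        cd = sample(5:10, n, replace = TRUE),
        cs = sample(0:2, n, replace = TRUE),
        eps = stats::runif(n, 2, 80),
        epsinf = stats::runif(n, 1.7, 2.3),
        wl = stats::runif(n, 380, 800),
        stats::rpois(n, 1.5))  # functional-group counts
    }
    M <- as.data.frame(lapply(stats::setNames(cols, cols), draw),
                       check.names = FALSE)
    # the signal is planted on the modeling scale: SOC enters through its
    # logarithm, mirroring the normalizer's log transform
    Msig <- M[names(signal)]
    if ("soc" %in% names(Msig)) Msig$soc <- log10(Msig$soc)
    z <- scale(as.matrix(Msig))
    raw <- as.numeric(z %*% signal)
    raw <- raw + 0.3 * sin(z[, 1])  # mild smooth nonlinearity
    # gentle logistic squash (gain 0.6) keeps targets spread over the
    # mid-range of (0, 1), as measured quantum yields are, instead of
    # piling them into the saturated tails
    y <- stats::plogis(0.6 * (raw + stats::rnorm(n, 0, noise_sd * stats::sd(raw))))
    metals <- sample(c("Ru", "Ir", "Re"), n, replace = TRUE,
                     prob = c(0.55, 0.35, 0.1))
    cbind(data.frame(id = sprintf("syn-%03d", seq_len(n)),
                     metal = metals, source = "internal",
                     phi_delta = pmin(pmax(y, 1e-6), 1),
                     stringsAsFactors = FALSE),
          M)
  })
  attr(tab, "manifest") <- list(
    meta = c("id", "metal", "source", "phi_delta"),
    blocks = list(qcd = qcd_column_names(),
                  structure = structure_column_names(),
                  metal_desc = c("cn", "cp", "mc", "cf", "cd", "cs"),
                  condition = c("eps", "epsinf", "wl")))
  attr(tab, "signal") <- signal
  class(tab) <- c("feature_table", "data.frame")
  tab
}
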