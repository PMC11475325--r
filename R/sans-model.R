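#' Triaxial core-shell ("lozenge") model parameters
#'
#' Parameter container for the scattering model: a triaxial ellipsoidal
#' hydrophobic core with semi-axes `core_polar <= core_minor <= core_major`
#' (polar, minor equatorial and major equatorial radii), wrapped in a
#' uniform head-group shell of fixed thickness, so the outer semi-axes are
#' the core semi-axes plus `shell_thickness`. Scattering length densities
#' (SLDs) are in 1e-6 / Angstrom^2 (D2O is 6.35, H2O is -0.56). Inter-micelle
#' interference is described by a Percus-Yevick hard-sphere structure factor
#' with radius `hs_radius` (default: the volume-equivalent sphere radius of
#' the outer ellipsoid) and the given volume fraction.
#'
#' @param core_minor,core_major,core_polar Core semi-axes, Angstrom.
#' @param shell_thickness Uniform shell thickness, Angstrom (default 5).
#' @param sld_core,sld_shell,sld_solvent SLDs, 1e-6 / Angstrom^2.
#' @param volume_fraction Hard-sphere volume fraction in [0, 0.74).
#' @param hs_radius Hard-sphere interaction radius, Angstrom, or `NULL` for
#'   the volume-equivalent default.
#' @param scale Overall scale (volume fraction of scatterers under the
#'   absolute-intensity convention).
#' @param background Flat incoherent background, 1/cm.
#' @return Object of class `triaxial_params`.
#' @export
triaxial_params <- function(core_minor, core_major, core_polar,
                            shell_thickness = 5,
                            sld_core = -0.37, sld_shell = 1.98,
                            sld_solvent = 6.35,
                            volume_fraction = 0.05, hs_radius = NULL,
                            scale = 1, background = 0) {
  if (any(c(core_minor, core_major, core_polar, shell_thickness) <= 0))
    mk_stop("radii and shell thickness must be positive", "mk_parameter_error")
  if (!(core_polar <= core_minor && core_minor <= core_major))
    mk_stop("lozenge ordering requires core_polar <= core_minor <= core_major",
            "mk_parameter_error")
  if (volume_fraction < 0 || volume_fraction >= 0.74)
    mk_stop("volume_fraction must lie in [0, 0.74)", "mk_parameter_error")
  outer_axes <- c(core_major, core_minor, core_polar) + shell_thickness
  hs_radius <- hs_radius %||% (prod(outer_axes))^(1 / 3)
  structure(list(core_minor = core_minor, core_major = core_major,
                 core_polar = core_polar, shell_thickness = shell_thickness,
                 sld_core = sld_core, sld_shell = sld_shell,
                 sld_solvent = sld_solvent,
                 volume_fraction = volume_fraction, hs_radius = hs_radius,
                 scale = scale, background = background),
            class = "triaxial_params")
}

#' @export
print.triaxial_params <- function(x, ...) {
  cat(sprintf(paste0("<triaxial_params> core %.2f/%.2f/%.2f + shell %.2f Angstrom\n",
                     "  SLD core/shell/solvent %.3g/%.3g/%.3g x 1e-6/A^2; ",
                     "phi=%.3g, R_hs=%.2f, scale=%.3g, bkg=%.3g\n"),
              x$core_major, x$core_minor, x$core_polar, x$shell_thickness,
              x$sld_core, x$sld_shell, x$sld_solvent,
              x$volume_fraction, x$hs_radius, x$scale, x$background))
  invisible(x)
}

core_axes <- function(p) c(p$core_major, p$core_minor, p$core_polar)
outer_axes <- function(p) core_axes(p) + p$shell_thickness

# 3 (sin u - u cos u) / u^3, the sphere amplitude kernel, stable at small u
sphere_kernel <- function(u) {
  out <- numeric(length(u))
  small <- abs(u) < 1e-4
  out[small] <- 1 - u[small]^2 / 10
  ub <- u[!small]
  out[!small] <- 3 * (sin(ub) - ub * cos(ub)) / ub^3
  out
}

#' Orientation-averaged triaxial core-shell form factor
#'
#' Single-particle scattering of the lozenge model:
#' `F(q, theta, phi) = dr_cs V_core K(q r_core) + dr_ss V_total K(q r_out)`
#' with `K` the sphere kernel, `dr_cs = sld_core - sld_shell`,
#' `dr_ss = sld_shell - sld_solvent`, and
#' `r(theta, phi) = sqrt((a^2 cos^2 phi + b^2 sin^2 phi) sin^2 theta + c^2
#' cos^2 theta)` the effective radius of the ellipsoid with semi-axes
#' (a, b, c) along the scattering vector. `<|F|^2>` is averaged over the
#' symmetry octant by a fixed-order Gauss-Legendre product rule in
#' (cos theta, phi) and normalised per unit particle volume on the absolute
#' scale: `P(q) = 1e-4 <|F|^2> / V_total` (1/cm for SLDs given in 1e-6 /
#' Angstrom^2).
#'
#' @param params A [triaxial_params()].
#' @param q Momentum-transfer values, 1/Angstrom.
#' @param n_quad Gauss-Legendre order per dimension (>= 16).
#' @return P(q), 1/cm, same length as `q`.
#' @export
triaxial_core_shell_form_factor <- function(params, q, n_quad = 76) {
  if (n_quad < 16) mk_stop("quadrature order must be >= 16", "mk_parameter_error")
  ff_kernel(params, q, n_quad)
}

# quadrature core shared with the exported wrapper; takes the axes exactly as
# given (the orientation average itself is permutation-symmetric)
ff_kernel <- function(params, q, n_quad) {
  ca <- c(params$core_major, params$core_minor, params$core_polar)
  oa <- ca + params$shell_thickness
  v_core <- ellipsoid_volume(ca[1], ca[2], ca[3])
  v_total <- ellipsoid_volume(oa[1], oa[2], oa[3])
  dr_cs <- params$sld_core - params$sld_shell
  dr_ss <- params$sld_shell - params$sld_solvent
  gu <- pracma::gaussLegendre(n_quad, 0, 1)        # u = cos(theta)
  gp <- pracma::gaussLegendre(n_quad, 0, pi / 2)   # phi
  s2 <- 1 - gu$x^2                                 # sin^2(theta)
  eff_r <- function(ax) {
    eq <- ax[1]^2 * cos(gp$x)^2 + ax[2]^2 * sin(gp$x)^2  # length n_quad (phi)
    sqrt(outer(s2, eq) + ax[3]^2 * gu$x^2)               # u x phi grid
  }
  rc <- eff_r(ca)
  ro <- eff_r(oa)
  w <- (2 / pi) * (gu$w %o% gp$w)
  vapply(q, function(qi) {
    f <- dr_cs * v_core * sphere_kernel(qi * rc) +
      dr_ss * v_total * sphere_kernel(qi * ro)
    1e-4 * sum(w * f * f) / v_total
  }, numeric(1))
}

#' Percus-Yevick hard-sphere structure factor
#'
#' Closed-form S(q) for monodisperse hard spheres of radius `hs_radius` at
#' the given volume fraction, from the analytic Percus-Yevick direct
#' correlation function. `volume_fraction = 0` gives S(q) = 1, and
#' `S(0) = (1 - phi)^4 / (1 + 2 phi)^2` (the PY compressibility limit).
#'
#' @param q Momentum transfer, 1/Angstrom.
#' @param hs_radius Hard-sphere radius, Angstrom.
#' @param volume_fraction Volume fraction in [0, 0.74).
#' @return S(q), same length as `q`.
#' @export
hard_sphere_structure_factor <- function(q, hs_radius, volume_fraction) {
  phi <- volume_fraction
  if (phi < 0 || phi >= 0.74)
    mk_stop("volume_fraction must lie in [0, 0.74)", "mk_parameter_error")
  if (phi == 0) return(rep(1, length(q)))
  al <- (1 + 2 * phi)^2 / (1 - phi)^4
  be <- -6 * phi * (1 + phi / 2)^2 / (1 - phi)^4
  ga <- phi * al / 2
  A <- 2 * q * hs_radius
  gA_over_A <- numeric(length(A))
  small <- A < 1e-3
  gA_over_A[small] <- al / 3 + be / 4 + ga / 6
  Ab <- A[!small]
  sA <- sin(Ab); cA <- cos(Ab)
  t1 <- al * (sA - Ab * cA) / Ab^3
  t2 <- be * (2 * Ab * sA + (2 - Ab^2) * cA - 2) / Ab^4
  t3 <- ga * (-Ab^4 * cA + 4 * ((3 * Ab^2 - 6) * cA + (Ab^3 - 6 * Ab) * sA + 6)) / Ab^6
  gA_over_A[!small] <- t1 + t2 + t3
  1 / (1 + 24 * phi * gA_over_A)
}

#' Model intensity: scaled form factor, structure factor and background
#'
#' `I(q) = scale * P(q) * S(q) + background` in the scalar decoupling
#' approximation (the structure factor multiplies the orientation-averaged
#' form factor).
#'
#' @param params A [triaxial_params()].
#' @param q Momentum transfer grid, 1/Angstrom.
#' @param n_quad Quadrature order for the form factor.
#' @return I(q), 1/cm.
#' @export
model_intensity <- function(params, q, n_quad = 76) {
  p <- if (params$scale == 0) rep(0, length(q))
       else triaxial_core_shell_form_factor(params, q, n_quad)
  s <- hard_sphere_structure_factor(q, params$hs_radius, params$volume_fraction)
  params$scale * p * s + params$background
}
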