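#' Guinier analysis of a SANS curve
#'
#' Weighted linear fit of `ln(I - background)` against `q^2` in a low-q
#' window chosen iteratively so that `q * Rg <= qr_max`: starting from the
#' lowest points, the slope-derived `Rg = sqrt(-3 * slope)` shrinks or grows
#' the window until it is self-consistent. Points with non-positive
#' background-subtracted intensity are masked with a warning.
#'
#' @param curve A [sans_curve()].
#' @param qr_max Upper limit on `q * Rg` for the fit window (default 1.3).
#' @param background Flat background to subtract, 1/cm.
#' @return List with `rg`, `rg_se` (Angstrom), `i0`, `i0_se` (1/cm),
#'   `n_points`, `q_window`.
#' @export
guinier_rg <- function(curve, qr_max = 1.3, background = 0) {
  ii <- curve$intensity - background
  valid <- ii > 0
  if (any(!valid)) {
    warning(sprintf("masking %d point(s) with I - background <= 0", sum(!valid)))
  }
  q <- curve$q[valid]; ii <- ii[valid]; sig <- curve$sigma[valid]
  if (length(q) < 5) mk_stop("fewer than 5 usable points", "mk_fit_error")
  y <- log(ii)
  w <- if (all(sig == 0)) rep(1, length(q)) else (ii / pmax(sig, 1e-300))^2
  # start from the whole curve and shrink to the self-consistent low-q window
  sel <- seq_along(q)
  fit <- NULL
  for (it in 1:50) {
    d <- data.frame(y = y[sel], q2 = q[sel]^2, w = w[sel])
    fit <- stats::lm(y ~ q2, data = d, weights = w)
    slope <- stats::coef(fit)[["q2"]]
    if (slope >= 0)
      mk_stop("non-negative Guinier slope; no size information in the window",
              "mk_fit_error")
    rg <- sqrt(-3 * slope)
    new_sel <- which(q * rg <= qr_max)
    if (length(new_sel) < 5) mk_stop("Guinier window collapsed", "mk_fit_error")
    if (identical(new_sel, sel)) break
    sel <- new_sel
  }
  sm <- summary(fit)$coefficients
  rg <- sqrt(-3 * stats::coef(fit)[["q2"]])
  list(rg = rg,
       rg_se = 3 * sm["q2", "Std. Error"] / (2 * rg),
       i0 = exp(stats::coef(fit)[["(Intercept)"]]),
       i0_se = exp(stats::coef(fit)[["(Intercept)"]]) * sm["(Intercept)", "Std. Error"],
       n_points = length(sel),
       q_window = range(q[sel]))
}

fit_parameter_names <- c("core_minor", "core_major", "core_polar",
                         "shell_thickness", "sld_core", "sld_shell",
                         "sld_solvent", "volume_fraction", "hs_radius",
                         "scale", "background")

default_fit_bounds <- function() {
  list(lower = c(core_minor = 1, core_major = 1, core_polar = 1,
                 shell_thickness = 0.5, sld_core = -1, sld_shell = -1,
                 sld_solvent = -1, volume_fraction = 0, hs_radius = 1,
                 scale = 0, background = 0),
       upper = c(core_minor = 200, core_major = 200, core_polar = 200,
                 shell_thickness = 50, sld_core = 10, sld_shell = 10,
                 sld_solvent = 10, volume_fraction = 0.7, hs_radius = 500,
                 scale = 1e6, background = 1e3))
}

# update a triaxial_params list without re-validating the lozenge ordering
# (optimizer iterates may transiently violate it)
params_with <- function(params, values) {
  params[names(values)] <- as.list(values)
  params
}

#' Fit the triaxial core-shell model to a SANS curve
#'
#' Weighted least squares `sum(((I_model - I_obs) / sigma)^2)` over the
#' selected free parameters, via bounded Levenberg-Marquardt
#' ([minpack.lm::nls.lm()]). The shell thickness stays fixed at its initial
#' value unless explicitly freed (5 Angstrom by convention). The fit is
#' deterministic given the initial parameters. Standard errors come from the
#' residual-variance-scaled covariance at the optimum; the reduced
#' chi-squared is `deviance / (n - p)`.
#'
#' @param curve A [sans_curve()] (all sigmas must be positive).
#' @param init A [triaxial_params()] with the starting values.
#' @param free Character vector of parameter names to optimise.
#' @param lower,upper Named bounds (defaults cover all parameters).
#' @param n_quad Form-factor quadrature order.
#' @return Object of class `mk_fit`: list with `params`, `uncertainties`,
#'   `chi2_reduced`, `n_points`, `free_param_names`, `converged`, `message`.
#' @export
fit_model <- function(curve, init,
                      free = c("core_minor", "core_major", "core_polar",
                               "scale", "background"),
                      lower = NULL, upper = NULL, n_quad = 76) {
  bad <- setdiff(free, fit_parameter_names)
  if (length(bad))
    mk_stop(paste("unknown free parameter(s):", paste(bad, collapse = ", ")),
            "mk_parameter_error")
  if (any(curve$sigma <= 0))
    mk_stop("all sigma must be positive for weighted fitting", "mk_weighting_error")
  resid_fn <- function(p) {
    m <- model_intensity(params_with(init, p), curve$q, n_quad = n_quad)
    (m - curve$intensity) / curve$sigma
  }
  n <- length(curve$q)
  if (!length(free)) {
    chi2 <- sum(resid_fn(numeric(0))^2)
    return(structure(list(params = init, uncertainties = numeric(0),
                          chi2_reduced = chi2 / n, n_points = n,
                          free_param_names = character(0), converged = TRUE,
                          message = "no free parameters; evaluated only"),
                     class = "mk_fit"))
  }
  bounds <- default_fit_bounds()
  lo <- bounds$lower[free]; hi <- bounds$upper[free]
  if (!is.null(lower)) lo[names(lower)[names(lower) %in% free]] <- lower[names(lower) %in% free]
  if (!is.null(upper)) hi[names(upper)[names(upper) %in% free]] <- upper[names(upper) %in% free]
  start <- unlist(init[free])
  res <- minpack.lm::nls.lm(par = start, lower = lo, upper = hi, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 300))
  if (res$info %in% c(0, 9))
    mk_stop(paste("fit did not converge:", res$message), "mk_fit_error")
  p_hat <- res$par
  dof <- max(1L, n - length(free))
  chi2_red <- res$deviance / dof
  se <- tryCatch({
    covar <- chi2_red * solve(res$hessian)
    sqrt(pmax(0, diag(covar)))
  }, error = function(e) rep(NA_real_, length(free)))
  names(se) <- free
  out_params <- params_with(init, p_hat)
  structure(list(params = out_params, uncertainties = se,
                 chi2_reduced = chi2_red, n_points = n,
                 free_param_names = free,
                 converged = TRUE, message = res$message),
            class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, ...) {
  cat(sprintf("<mk_fit> %d points, chi2_red = %.4g\n", x$n_points, x$chi2_reduced))
  if (length(x$free_param_names)) {
    v <- unlist(x$params[x$free_param_names])
    for (i in seq_along(v))
      cat(sprintf("  %-15s %10.4g +/- %.3g\n", x$free_param_names[i], v[i],
                  x$uncertainties[i]))
  }
  invisible(x)
}

#' Sequential fits of a time-sliced curve series
#'
#' Fits each curve in order, warm-starting from the previous optimum -- the
#' workflow for stopped-flow time slices where the micelle evolves gradually.
#'
#' @param curves List of [sans_curve()] objects, in time order.
#' @inheritParams fit_model
#' @return List of `mk_fit` objects.
#' @export
fit_series <- function(curves, init,
                       free = c("core_minor", "core_major", "core_polar",
                                "scale", "background"),
                       lower = NULL, upper = NULL, n_quad = 76) {
  fits <- vector("list", length(curves))
  current <- init
  for (i in seq_along(curves)) {
    fits[[i]] <- fit_model(curves[[i]], current, free = free,
                           lower = lower, upper = upper, n_quad = n_quad)
    current <- fits[[i]]$params
  }
  names(fits) <- vapply(curves, function(cu) cu$label, character(1))
  fits
}

#' Micelle quantities derived from fitted core-shell geometry
#'
#' Tanford-based derived parameters: the aggregation number is the core
#' volume divided by the per-lipid tail volume
#' (`N = round(V_core / V_tails)`, rounded half up); per-lipid areas are the
#' core and outer ellipsoid surface areas divided by N; and the head-group
#' hydration is a volume balance over the shell,
#' `H2O = (V_shell - N V_head) / (N V_water)`. The head-group and water
#' volumes are configurable approximations (defaults 319 and 30 Angstrom^3),
#' so the hydration column is method-dependent.
#'
#' @param params A [triaxial_params()] fit result.
#' @param n_core_carbons Carbons per chain in the hydrophobic core
#'   (default 5: the ester groups count as part of the head group).
#' @param n_chains Chains per lipid (default 2).
#' @param v_head Head-group volume, Angstrom^3.
#' @param v_water Water molecule volume, Angstrom^3.
#' @return Object of class `mk_derived`: list with `aggregation_number`,
#'   `h2o_per_headgroup`, `area_per_lipid_core`, `area_per_lipid_shell`,
#'   `tail_length_used`, `tail_volume_used`, `v_core`, `v_total`.
#' @export
derived_quantities <- function(params, n_core_carbons = 5, n_chains = 2,
                               v_head = 319, v_water = 30) {
  ca <- core_axes(params)
  oa <- outer_axes(params)
  v_core <- ellipsoid_volume(ca[1], ca[2], ca[3])
  v_total <- ellipsoid_volume(oa[1], oa[2], oa[3])
  v_tails <- tanford_tail_volume(n_core_carbons, n_chains)
  n_agg <- round_half_away(v_core / v_tails)
  if (n_agg < 1) mk_stop("degenerate core: aggregation number rounds to 0",
                         "mk_degenerate_core")
  s_core <- ellipsoid_surface_area(ca[1], ca[2], ca[3])
  s_out <- ellipsoid_surface_area(oa[1], oa[2], oa[3])
  structure(list(
    aggregation_number = as.integer(n_agg),
    h2o_per_headgroup = (v_total - v_core - n_agg * v_head) / (n_agg * v_water),
    area_per_lipid_core = s_core / n_agg,
    area_per_lipid_shell = s_out / n_agg,
    tail_length_used = tanford_tail_length(n_core_carbons),
    tail_volume_used = v_tails,
    v_core = v_core, v_total = v_total),
    class = "mk_derived")
}

#' @export
print.mk_derived <- function(x, ...) {
  cat(sprintf(paste0("<mk_derived> N = %d, H2O per head group = %.1f ",
                     "(method-dependent),\n  area per lipid %.3g (core) / %.3g (shell) Angstrom^2\n"),
              x$aggregation_number, x$h2o_per_headgroup,
              x$area_per_lipid_core, x$area_per_lipid_shell))
  invisible(x)
}
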