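# Monte-Carlo Debye-sum oracle for the core-shell scattering model:
# stratified uniform points in the two ellipsoidal domains, pair-distance
# histogram, and I(q) = sum_ij w_i w_j sinc(q r_ij) / V (absolute scale).
# Entirely independent of the orientation-average quadrature it checks.

debye_stratified_points <- function(axes, h) {
  gx <- seq(-axes[1] - h, axes[1] + h, by = h)
  gy <- seq(-axes[2] - h, axes[2] + h, by = h)
  gz <- seq(-axes[3] - h, axes[3] + h, by = h)
  pts <- as.matrix(expand.grid(gx, gy, gz))
  pts <- pts + matrix(stats::runif(length(pts), -h / 2, h / 2), ncol = 3)
  pts[rowSums(sweep(pts, 2, axes, "/")^2) < 1, , drop = FALSE]
}

debye_pair_hist <- function(A, B, dbin, nb) {
  H <- numeric(nb)
  sA <- rowSums(A^2); sB <- rowSums(B^2)
  for (s in seq(1, nrow(A), by = 1200L)) {
    e <- min(s + 1199L, nrow(A))
    d2 <- outer(sA[s:e], sB, "+") - 2 * A[s:e, , drop = FALSE] %*% t(B)
    bins <- pmax(ceiling(sqrt(pmax(d2, 0)) / dbin), 1)
    H <- H + tabulate(bins, nbins = nb)
  }
  H
}

debye_oracle_curve <- function(params, q, n_core = 8000, n_outer = 26000,
                               dbin = 0.05) {
  ca <- c(params$core_major, params$core_minor, params$core_polar)
  oa <- ca + params$shell_thickness
  vc <- 4 / 3 * pi * prod(ca)
  vt <- 4 / 3 * pi * prod(oa)
  pc <- debye_stratified_points(ca, (vc / n_core)^(1 / 3))
  po <- debye_stratified_points(oa, (vt / n_outer)^(1 / 3))
  w1 <- (params$sld_core - params$sld_shell) * vc / nrow(pc)
  w2 <- (params$sld_shell - params$sld_solvent) * vt / nrow(po)
  maxd <- 2 * max(oa) + 1
  nb <- ceiling(maxd / dbin)
  Hcc <- debye_pair_hist(pc, pc, dbin, nb)
  Hco <- debye_pair_hist(pc, po, dbin, nb)
  Hoo <- debye_pair_hist(po, po, dbin, nb)
  rc <- (seq_len(nb) - 0.5) * dbin
  vapply(q, function(qi) {
    sinc <- sin(qi * rc) / (qi * rc)
    s <- w1^2 * sum(Hcc * sinc) + 2 * w1 * w2 * sum(Hco * sinc) +
      w2^2 * sum(Hoo * sinc)
    1e-4 * s / vt
  }, numeric(1))
}
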