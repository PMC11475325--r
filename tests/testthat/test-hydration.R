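test_that("an ideal gas gives g = 1 and the analytic coordination integral", {
  box <- 30
  n_b <- 10000
  cfg <- ideal_gas_config(20, n_b, box, n_frames = 50)
  r <- rdf(cfg, sel_a = 1:20, sel_b = 20 + seq_len(n_b), dr = 0.25)
  inside <- r$r >= 3 & r$r <= max(r$r)
  expect_lt(max(abs(r$g[inside] - 1)), 0.05)
  rho <- n_b / box^3
  expect_lt(abs(coordination_number(r, 3.5) / (4 / 3 * pi * rho * 3.5^3) - 1), 0.02)
  # running integral over the whole histogram matches the ideal-gas volume term
  r_max <- max(r$r_edges)
  expect_lt(abs(coordination_number(r, r_max) / (4 / 3 * pi * rho * r_max^3) - 1),
            0.02)
})

test_that("a clamped pair produces a delta RDF with unit coordination", {
  atoms <- data.frame(name = c("C", "OW"), resname = c("FA6", "SOL"),
                      element = c("C", "O"), molecule_id = 1:2,
                      species = c("FA", "WATER"), role = c("OTHER", "WATER_O"),
                      mass = 1)
  cfg <- mk_configuration(rbind(c(10, 10, 10), c(15, 10, 10)), rep(40, 3), atoms)
  r <- rdf(cfg, 1, 2, dr = 0.1, r_max = 10)
  expect_equal(sum(r$g > 0), 1L)
  expect_equal(r$r[r$g > 0], 4.95, tolerance = 0.11)  # the bin holding 5 A
  expect_equal(coordination_number(r, 6), 1)
  expect_equal(coordination_number(r, 3), 0)
})

test_that("the running coordination number equals brute-force neighbour counts", {
  cfg <- ideal_gas_config(3, 50, box = 20, n_frames = 5, seed = 23)
  r <- rdf(cfg, 1:3, 3 + 1:50, dr = 0.25)
  for (edge_i in c(5, 10, 20, length(r$r_edges))) {
    re <- r$r_edges[edge_i]
    counts <- vapply(1:5, function(fi) {
      d <- micellekit:::pair_dist_pbc(cfg$frames[[fi]][1:3, ],
                                      cfg$frames[[fi]][3 + 1:50, ], rep(20, 3))
      sum(d <= re) / 3
    }, numeric(1))
    expect_equal(r$n_of_r[edge_i], mean(counts), tolerance = 1e-6)
  }
})

test_that("the first RDF minimum is located after the first peak", {
  r_grid <- seq(0.05, 6, by = 0.05)
  # designed trough: peak at 2.8, locally symmetric parabolic minimum at 3.2
  g <- 2 * exp(-((r_grid - 2.8) / 0.18)^2) +
    1 - 0.6 * exp(-((r_grid - 3.2) / 0.35)^2)
  fake <- structure(list(r = r_grid, g = g, rho_b = 0.0334,
                         r_edges = c(0, r_grid + 0.025),
                         n_of_r = cumsum(c(0, g))), class = "mk_rdf")
  fm <- first_minimum(fake)
  # oracle: direct argmin of the smoothed curve after the peak
  sm <- stats::filter(g, rep(1 / 3, 3), sides = 2)
  pk <- which.max(sm)
  oracle <- r_grid[pk + which.min(sm[(pk + 1):(length(sm) - 1)])]
  expect_equal(fm, oracle)
  expect_lt(abs(fm - 3.2), 0.1)

  mono <- structure(list(r = r_grid, g = exp(-r_grid), rho_b = 1,
                         r_edges = c(0, r_grid + 0.025),
                         n_of_r = cumsum(c(0, g))), class = "mk_rdf")
  expect_warning(fm2 <- first_minimum(mono), "window end")
  expect_equal(fm2, 6)

  # noise-free parabolic trough: exact vertex bin
  g3 <- 3 * exp(-((r_grid - 2.2) / 0.1)^2) + 1 + pmin((r_grid - 3.0)^2, 0.8)
  fake3 <- structure(list(r = r_grid, g = g3, rho_b = 1,
                          r_edges = c(0, r_grid + 0.025),
                          n_of_r = cumsum(c(0, g3))), class = "mk_rdf")
  expect_equal(first_minimum(fake3), 3.0)
})

test_that("rdf input contracts are enforced", {
  cfg <- ideal_gas_config(2, 20, box = 20, n_frames = 1)
  expect_error(rdf(cfg, 1:2, 2 + 1:20, r_max = 15), class = "mk_box_error")
  expect_error(rdf(cfg, integer(0), 1:3), class = "mk_selection_error")
})

test_that("water contacts split by state reproduce planted counts", {
  water_at <- function(center, n, rmax) {
    d <- micellekit:::runif_sphere(n) * runif(n, 0.5, rmax)
    sweep(d, 2, center, "+")
  }
  set.seed(41)
  # molecules A and B form a dimer (micelle under min_micelle_size = 2);
  # C is a monomer. Planted: 4 waters in the terminal-carbon shells of A and
  # B, 17 around C's terminal.
  A <- list(species = "FA", roles = c("TAIL_C", "TERMINAL_C"),
            coords = rbind(c(20, 20, 20), c(20, 20, 23)))
  B <- list(species = "FA", roles = c("TAIL_C", "TERMINAL_C"),
            coords = rbind(c(24, 20, 20), c(24, 20, 17)))
  C <- list(species = "FA", roles = c("TAIL_C", "TERMINAL_C"),
            coords = rbind(c(45, 45, 45), c(45, 45, 48)))
  wat <- rbind(water_at(c(20, 20, 25), 4, 1.8),   # within 5.0 of A terminal
               water_at(c(24, 20, 15), 4, 1.8),   # within 5.0 of B terminal
               water_at(c(45, 45, 50), 17, 2.5))  # within 5.0 of C terminal
  mols <- list(A, B, C)
  for (i in seq_len(nrow(wat)))
    mols[[3 + i]] <- list(species = "WATER", roles = "WATER_O",
                          coords = wat[i, , drop = FALSE])
  cfg <- toy_config(mols, box = c(60, 60, 60))
  cl <- cluster_molecules(cfg)
  tab <- water_contact_table(cfg, list(cl), roles = "TERMINAL_C",
                             min_micelle_size = 2)
  expect_equal(tab$micelle, 4)
  expect_equal(tab$monomer, 17)
  expect_equal(tab$n_micelle_obs, 2L)
  expect_equal(tab$n_monomer_obs, 1L)
})

test_that("contact counts vanish without water and are rigid-motion invariant", {
  dry <- toy_config(list(bead_mol("FA", c(10, 10, 10))), box = c(30, 30, 30))
  tab <- water_contact_table(dry, list(cluster_molecules(dry)),
                             roles = "TERMINAL_C")
  expect_equal(tab$monomer, 0)

  set.seed(51)
  mols <- list(bead_mol("FA", c(20, 20, 20)))
  wat <- sweep(micellekit:::runif_sphere(30) * runif(30, 1, 8), 2,
               c(21.9, 20, 20), "+")
  for (i in 1:30)
    mols[[1 + i]] <- list(species = "WATER", roles = "WATER_O",
                          coords = wat[i, , drop = FALSE])
  cfg <- toy_config(mols, box = c(60, 60, 60))
  t1 <- water_contact_table(cfg, list(cluster_molecules(cfg)), roles = "TERMINAL_C")
  rot <- micellekit:::rotate_matrix(c(0.3, 1, -2), 0.9)
  xyz2 <- sweep(cfg$frames[[1]] %*% t(rot), 2, c(5, 8, -3), "+")
  xyz2 <- xyz2 - floor(xyz2 / 60) * 60  # wrap back into the box
  cfg2 <- mk_configuration(xyz2, cfg$box, cfg$atoms)
  t2 <- water_contact_table(cfg2, list(cluster_molecules(cfg2)), roles = "TERMINAL_C")
  expect_equal(t1$monomer_mean, t2$monomer_mean)
})

test_that("micelle tails are shielded from water relative to monomers", {
  spec <- micelle_spec(composition = c(FA = 8), n_monomers = c(FA = 2),
                       core_semi_axes = c(10, 8, 6), water_density = 0.0334,
                       seed = 13)
  b <- build_micelle_configuration(spec)
  cl <- cluster_molecules(b$configuration)
  tab <- water_contact_table(b$configuration, list(cl), roles = "TERMINAL_C")
  expect_lt(tab$micelle_mean, tab$monomer_mean)
})
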