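test_that("tail-contact clustering separates an aggregate from a distant molecule", {
  cfg <- toy_config(list(
    bead_mol("FA", c(10, 10, 10)),
    bead_mol("FA", c(13, 10, 10)),
    bead_mol("FA", c(10, 13, 10)),
    bead_mol("FA", c(45, 10, 10))), box = c(60, 60, 60))
  cl <- cluster_molecules(cfg)
  expect_equal(sort(cl$sizes, decreasing = TRUE), c(3L, 1L))
  expect_setequal(micellekit:::largest_cluster_members(cl), 1:3)
})

test_that("molecules link through the periodic boundary", {
  cfg <- toy_config(list(
    bead_mol("FA", c(1, 10, 10)),
    bead_mol("FA", c(54.2, 10, 10), spread = 1.9)), box = c(60, 60, 60))
  # terminal of molecule 2 at x = 56.1: distance to x = 1 through the wall is
  # 4.9 > cutoff; move closer
  cfg2 <- toy_config(list(
    bead_mol("FA", c(1, 10, 10)),
    bead_mol("FA", c(56, 10, 10))), box = c(60, 60, 60))
  # molecule 2 terminal at 57.9 -> 3.1 A from x=1 through the boundary
  cl <- cluster_molecules(cfg2)
  expect_equal(max(cl$sizes), 2L)
  expect_equal(max(cluster_molecules(cfg)$sizes), 1L)
})

test_that("cluster membership is invariant to atom order", {
  set.seed(21)
  spec <- micelle_spec(composition = c(FA = 6), n_monomers = c(FA = 2),
                       core_semi_axes = c(9, 8, 6), water_density = 0, seed = 9)
  cfg <- build_micelle_configuration(spec)$configuration
  perm <- sample(nrow(cfg$atoms))
  shuffled <- mk_configuration(cfg$frames[[1]][perm, ], cfg$box,
                               cfg$atoms[perm, ], cfg$time_per_frame)
  cl1 <- cluster_molecules(cfg)
  cl2 <- cluster_molecules(shuffled)
  sets <- function(cl) {
    s <- split(cl$molecule_id, cl$cluster_id)
    sort(vapply(s, function(x) paste(sort(x), collapse = ","), character(1)))
  }
  expect_identical(sets(cl1), sets(cl2))
})

test_that("largest-cluster size is monotone in the cutoff", {
  set.seed(5)
  for (rep in 1:5) {
    mols <- lapply(seq_len(10), function(i)
      bead_mol("FA", runif(3, 5, 35)))
    cfg <- toy_config(mols, box = c(40, 40, 40))
    sizes <- vapply(c(2, 4, 6, 10, 20), function(cut)
      max(cluster_molecules(cfg, cutoff = cut)$sizes), integer(1))
    expect_true(all(diff(sizes) >= 0))
  }
})

test_that("single-linkage components match the brute-force transitive closure", {
  set.seed(8)
  for (rep in 1:10) {
    n <- sample(4:12, 1)
    mols <- lapply(seq_len(n), function(i) bead_mol("FA", runif(3, 2, 28)))
    cfg <- toy_config(mols, box = c(30, 30, 30))
    cl <- cluster_molecules(cfg)
    ours <- vapply(cl$molecule_id, function(m) {
      members <- cl$molecule_id[cl$cluster_id == cl$cluster_id[cl$molecule_id == m]]
      paste(sort(members), collapse = ",")
    }, character(1))
    expect_identical(ours, brute_force_clusters(cfg))
  }
})

test_that("the aggregation time series is constant on a frozen planted micelle", {
  tr <- build_trajectory(micelle_spec(composition = c(FA = 8),
                                      core_semi_axes = c(10, 8, 6),
                                      n_frames = 6, jitter_sigma = 0,
                                      water_density = 0, seed = 2))
  series <- aggregation_timeseries(tr$configuration)
  expect_equal(nrow(series), 6L)
  expect_equal(series$largest_size, rep(8L, 6))
  expect_equal(series$FA, rep(8L, 6))
  expect_equal(series$time_ns, 0:5)
})

test_that("an all-monomer system gives a constant series of 1", {
  tr <- build_trajectory(micelle_spec(composition = c(PC2C6 = 0),
                                      n_monomers = c(FA = 4),
                                      core_semi_axes = c(8, 7, 5),
                                      n_frames = 3, water_density = 0, seed = 6))
  series <- aggregation_timeseries(tr$configuration)
  expect_equal(series$largest_size, rep(1L, 3))
})

test_that("composition summaries reproduce the planted occupancy arithmetic", {
  tr <- build_trajectory(micelle_preset("C6-50", seed = 4, water_density = 0,
                                        n_frames = 4, jitter_sigma = 0.3))
  series <- aggregation_timeseries(tr$configuration)
  comp <- micelle_composition(series, window = 1:4)
  lyso <- comp[comp$species == "LYSO", ]
  # 15 of 18 LYSO planted in the micelle
  expect_equal(lyso$mean_count, 15)
  expect_equal(lyso$percent, 83)
  expect_equal(comp[comp$species == "PC2C6", "percent"], round(16 / 17 * 100))
  expect_equal(comp$sd_count, rep(0, 3))
})

test_that("degenerate composition windows are handled", {
  tr <- build_trajectory(micelle_spec(composition = c(FA = 6),
                                      core_semi_axes = c(9, 8, 6),
                                      n_frames = 2, water_density = 0, seed = 3))
  series <- aggregation_timeseries(tr$configuration)
  expect_warning(comp <- micelle_composition(series, window = 2), "single frame")
  expect_equal(comp[comp$species == "FA", "sd_count"], 0)
  # species absent from the system reported as NA
  expect_true(is.na(comp[comp$species == "LYSO", "percent"]))
  expect_error(micelle_composition(series, window = 5:9), class = "mk_parameter_error")
})

test_that("monomer/micelle state assignment follows the size threshold", {
  mols <- c(lapply(1:35, function(i)
    bead_mol("FA", c(20 + (i %% 6) * 2.2, 20 + (i %/% 6) * 2.2, 20), spread = 1.9)),
    list(bead_mol("FA", c(70, 70, 70)), bead_mol("FA", c(5, 70, 20))))
  cfg <- toy_config(mols, box = c(90, 90, 90))
  cl <- cluster_molecules(cfg)
  expect_equal(sort(cl$sizes, decreasing = TRUE)[1], 35L)
  st <- assign_monomer_state(cl)
  expect_equal(sum(st == "MICELLE"), 35L)
  expect_equal(sum(st == "MONOMER"), 2L)
  # a 4-mer is below the default threshold of 5
  four <- toy_config(lapply(1:4, function(i)
    bead_mol("FA", c(10 + i * 2.5, 10, 10))), box = c(40, 40, 40))
  st4 <- assign_monomer_state(cluster_molecules(four))
  expect_true(all(st4 == "MONOMER"))
  st4b <- assign_monomer_state(cluster_molecules(four), min_micelle_size = 4)
  expect_true(all(st4b == "MICELLE"))
})

test_that("the pure-LYSO preset stays monomeric under the default criterion", {
  b <- build_micelle_configuration(micelle_preset("LYSO", seed = 5,
                                                  water_density = 0))
  cl <- cluster_molecules(b$configuration)
  expect_true(all(assign_monomer_state(cl) == "MONOMER"))
})

test_that("empty solute sets and bad cutoffs are rejected", {
  cfg <- toy_config(list(bead_mol("FA", c(5, 5, 5))), box = c(20, 20, 20))
  expect_error(cluster_molecules(cfg, cutoff = -1), class = "mk_parameter_error")
  watery <- toy_config(list(list(species = "WATER", roles = "WATER_O",
                                 coords = matrix(c(5, 5, 5), 1))),
                       box = c(20, 20, 20))
  expect_error(cluster_molecules(watery), class = "mk_empty_solute")
})
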