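test_that("symmetric double well is sampled with equal occupancy", {
  # low barrier => fast mixing, so the 0.5 +/- 0.02 check is well powered
  ws <- well_spec(centers = c(-1.5, 1.5), depths = 1.2, widths = 1,
                  temperature = 300, friction = 1, timestep = 0.005)
  p <- sample_overdamped_dynamics(ws, 1.2e6, seed = 11)
  occ <- mean(p[, 1] < 0)
  expect_lt(abs(occ - 0.5), 0.02)
  # reproducibility: same seed, same path
  p2 <- sample_overdamped_dynamics(ws, 1e3, seed = 11)
  expect_identical(p[1:1e3, , drop = FALSE], p2)
})

test_that("zero-temperature dynamics never leaves the starting well", {
  ws <- well_spec(centers = c(-2, 2), depths = c(2, 4), widths = 1,
                  temperature = 0, friction = 1, timestep = 0.005)
  p <- sample_overdamped_dynamics(ws, 5e3, seed = 1, x0 = -2)
  expect_true(all(assign_wells(ws, p) == 1L))
})

test_that("asymmetric well occupancy matches the Boltzmann quadrature oracle", {
  wa <- well_spec(centers = c(-2, 2), depths = c(2, 4), widths = 1,
                  temperature = 300, friction = 1, timestep = 0.005)
  beta <- 1 / (kB * 300)
  dens <- function(x) exp(-beta * well_potential(wa, x))
  z_shallow <- stats::integrate(dens, -Inf, 0)$value
  z_deep <- stats::integrate(dens, 0, Inf)$value
  p_shallow <- z_shallow / (z_shallow + z_deep)

  p <- sample_overdamped_dynamics(wa, 2e6, seed = 13)
  occ <- mean(p[, 1] < 0)
  # ~1000 barrier crossings at these parameters: 3 sigma ~ 0.007, plus a
  # small Euler-Maruyama discretisation bias
  expect_lt(abs(occ - p_shallow), 0.015)
})

test_that("timestep stability bound is enforced", {
  expect_error(
    sample_overdamped_dynamics(
      well_spec(centers = c(-1, 1), depths = 10, widths = 0.1,
                timestep = 0.01), 10, seed = 1),
    "stability bound")
})

test_that("loop protein geometry plants the open/closed contrast", {
  sys <- make_loop_protein(n_residues = 50, loop_span = 10:17, seed = 1)
  non_loop <- setdiff(seq_len(50), sys$loop_span)
  expect_equal(sys$open_frame[non_loop, ], sys$closed_frame[non_loop, ])

  lig <- sys$open_frame[sys$ligand_atom, ]
  d_open <- min(sqrt(rowSums(sweep(
    sys$open_frame[sys$loop_span, , drop = FALSE], 2, lig)^2)))
  d_closed <- min(sqrt(rowSums(sweep(
    sys$closed_frame[sys$loop_span, , drop = FALSE], 2, lig)^2)))
  expect_lt(d_closed, d_open)

  # loop RMSD between the frames equals the planted displacement norm
  disp <- sys$loop_displacement
  expected <- sqrt(sum(disp^2) / nrow(disp))
  got <- coord_rmsd(sys$open_frame[sys$loop_span, ],
                    sys$closed_frame[sys$loop_span, ])
  expect_equal(got, expected, tolerance = 1e-12)

  expect_error(make_loop_protein(n_residues = 40, loop_span = 39:45),
               "outside")
})

test_that("state-path interpolation hits its endpoints and plants RMSF", {
  sys <- make_loop_protein(seed = 2)
  tr0 <- interpolate_trajectory(sys$open_frame, sys$closed_frame,
                                rep(0, 4), sys$topology)
  for (m in 1:4)
    expect_equal(frame_coords(tr0, m), unname(sys$open_frame),
                 tolerance = 1e-12, ignore_attr = TRUE)
  tr <- interpolate_trajectory(sys$open_frame, sys$closed_frame, c(0, 1),
                               sys$topology)
  expect_equal(frame_coords(tr, 2), unname(sys$closed_frame),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(interpolate_trajectory(sys$open_frame, sys$closed_frame,
                                      c(0, 1.2), sys$topology), "\\[0, 1\\]")

  # isotropic jitter sigma per coordinate => RMSF = sigma * sqrt(3)
  sigma <- 0.1
  trj <- interpolate_trajectory(sys$open_frame, sys$closed_frame,
                                rep(0, 600), sys$topology,
                                jitter_sd = sigma, seed = 5)
  non_loop_ca <- which(!(sys$topology$resid %in% sys$loop_span) &
                         sys$topology$name == "CA")
  fl <- rmsf(trj, selection = non_loop_ca, fit_selection = non_loop_ca)
  expect_equal(mean(fl), sigma * sqrt(3), tolerance = 0.05)
})

test_that("markov chain sampler respects degenerate and planted matrices", {
  expect_identical(sample_markov_chain(diag(2), 50, seed = 1, start = 2L),
                   rep(2L, 50))
  alt <- sample_markov_chain(rbind(c(0, 1), c(1, 0)), 40, seed = 1)
  expect_identical(alt, rep(c(2L, 1L), 20))

  Tm <- rbind(c(0.9, 0.1), c(0.2, 0.8))   # stationary (2/3, 1/3)
  s <- sample_markov_chain(Tm, 1e5, seed = 7)
  expect_lt(abs(mean(s == 1) - 2 / 3), 0.01)

  expect_error(sample_markov_chain(rbind(c(0.5, 0.6), c(0.5, 0.5)), 5, 1),
               "sum to 1")
  expect_error(sample_markov_chain(rbind(c(1.2, -0.2), c(0.5, 0.5)), 5, 1),
               "negative")
})

test_that("planted covariance generator reproduces its correlations", {
  expect_error(planted_covariance(list(1:2, 3:4, 5:6), intra = 0.9,
                                  inter = -0.8),
               "positive semi-definite")

  # three planted parameter sets, each recovered from the sample
  cases <- list(list(intra = 0.9, inter = -0.8),
                list(intra = 0.7, inter = 0.0),
                list(intra = 0.5, inter = 0.3))
  for (cs in cases) {
    pc <- planted_covariance(list(1:15, 16:30), intra = cs$intra,
                             inter = cs$inter, amplitude = 0.5)
    sim <- sample_correlated_displacements(pc, 4000, seed = 42)
    C <- dccm(sim$trajectory, selection = sim$residue_atoms,
              fit_selection = sim$anchor_atoms)
    intra_hat <- region_correlation_summary(
      C, as.character(1:15), as.character(1:15))$mean
    inter_hat <- region_correlation_summary(
      C, as.character(1:15), as.character(16:30))$mean
    expect_lt(abs(intra_hat - cs$intra), 0.05)
    expect_lt(abs(inter_hat - cs$inter), 0.05)
  }
})

test_that("perfectly correlated residues move proportionally frame by frame", {
  pc <- planted_covariance(list(1:2), intra = 1, inter = 0, amplitude = 0.5)
  sim <- sample_correlated_displacements(pc, 50, seed = 3, n_anchors = 3)
  d1 <- sweep(sim$trajectory$coords[, 1, ], 2,
              colMeans(sim$trajectory$coords[, 1, ]))
  d2 <- sweep(sim$trajectory$coords[, 2, ], 2,
              colMeans(sim$trajectory$coords[, 2, ]))
  expect_equal(d1, d2, tolerance = 1e-8)
})

test_that("energy table generator recovers planted means and is exact at sd 0", {
  means <- list(
    complex = c(E_internal = 10, E_elec = -60, E_vdw = -30, G_pol = 50, G_np = -6),
    receptor = c(E_internal = 10, E_elec = -10, E_vdw = -8, G_pol = 7, G_np = -0.5),
    ligand = c(E_internal = 0, E_elec = -2.28, E_vdw = -3.4, G_pol = 1.72, G_np = 0.32))
  zeros <- lapply(means, function(x) x * 0)

  tabs <- make_energy_tables(means, zeros, n_frames = 10, seed = 1)
  res <- mmgbsa_combine(tabs$complex, tabs$receptor, tabs$ligand)
  planted_dG <- sum(means$complex) - sum(means$receptor) - sum(means$ligand)
  expect_equal(res$dG_mean, planted_dG, tolerance = 1e-10)
  expect_equal(res$dG_sd, 0)

  sds <- lapply(means, function(x) abs(x) * 0 + 2)
  for (seed in c(1, 2, 3)) {
    tabs <- make_energy_tables(means, sds, n_frames = 1000, seed = seed)
    for (sp in names(tabs)) {
      err <- abs(colMeans(as.matrix(tabs[[sp]])) - means[[sp]])
      expect_true(all(err < 4 * 2 / sqrt(1000)))
    }
  }
  expect_error(make_energy_tables(means, zeros, n_frames = 1, seed = 1),
               "at least 2")
})

test_that("generators are pure functions of parameters and seed", {
  sys1 <- make_loop_protein(seed = 9)
  sys2 <- make_loop_protein(seed = 9)
  expect_identical(sys1$open_frame, sys2$open_frame)

  s1 <- sample_markov_chain(rbind(c(0.7, 0.3), c(0.4, 0.6)), 500, seed = 4)
  s2 <- sample_markov_chain(rbind(c(0.7, 0.3), c(0.4, 0.6)), 500, seed = 4)
  expect_identical(s1, s2)

  pc <- planted_covariance(list(1:4, 5:8), intra = 0.8, inter = -0.5)
  a <- sample_correlated_displacements(pc, 20, seed = 6)
  b <- sample_correlated_displacements(pc, 20, seed = 6)
  expect_identical(a$trajectory$coords, b$trajectory$coords)

  # the global RNG stream is untouched by seeded generators
  set.seed(123); before <- .Random.seed
  invisible(sample_markov_chain(diag(2), 10, seed = 99))
  expect_identical(.Random.seed, before)
})
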