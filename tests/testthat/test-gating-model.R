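# independent oracle: reduce the coupled-spring graph by solving the
# force balance at the contact-site node with a linear solve
network_stiffness_oracle <- function(ka, n_pulled, n_AR = 29, split_N = 9,
                                     split_C = 20, n_subunits = 4) {
  k_seg_N <- n_AR * ka / split_N
  k_seg_C <- n_AR * ka / split_C
  # unit displacement applied at the pulled ends; CS1 displacement u solves
  # sum_pulled k_seg_N (1 - u) = n_subunits k_seg_C u
  K <- matrix(n_pulled * k_seg_N + n_subunits * k_seg_C, 1, 1)
  u <- solve(K, n_pulled * k_seg_N)[1]
  n_pulled * k_seg_N * (1 - u)
}

test_that("coupled-spring stiffness matches the brute-force reduction", {
  net <- spring_network(ka = 0.5)
  for (N in 1:4) {
    expect_equal(effective_stiffness(net, N),
                 network_stiffness_oracle(0.5, N), tolerance = 1e-12)
  }
  # asymmetric split and odd subunit counts reduce identically
  net2 <- spring_network(ka = 1.3, n_AR = 24, split_N = 7, split_C = 17,
                         n_subunits = 3)
  for (N in 1:3) {
    expect_equal(effective_stiffness(net2, N),
                 network_stiffness_oracle(1.3, N, 24, 7, 17, 3),
                 tolerance = 1e-12)
  }
  expect_error(effective_stiffness(net, 0), "1..4")
  expect_error(effective_stiffness(net, 5), "1..4")
  expect_error(spring_network(1, split_N = 10), "must equal n_AR")
})

test_that("calibrating from the single-subunit measurement gives the tetramer stiffness", {
  net <- calibrate_spring_network(0.7, n_pulled = 1)
  expect_equal(net$ka, 0.7 * 14 / 29, tolerance = 1e-12)
  expect_equal(effective_stiffness(net, 1), 0.7, tolerance = 1e-12)
  expect_equal(effective_stiffness(net, 2), 58 / 19 * net$ka,
               tolerance = 1e-12)
  expect_equal(effective_stiffness(net, 4), 4 * net$ka, tolerance = 1e-12)
  expect_equal(round(effective_stiffness(net, 4), 1), 1.4)
})

test_that("state energy is thermodynamically consistent (dE/dx = F)", {
  cfg <- gating_config()
  h <- 1e-4
  for (open in c(FALSE, TRUE)) {
    for (partial in c(FALSE, TRUE)) {
      rest <- if (partial) cfg$x0_closed_partial else cfg$x0_closed_folded
      if (open) rest <- rest + cfg$gating_swing
      for (x in rest + c(2, 5, 10, 20)) {
        se <- state_energy(x, open, partial, cfg)
        dEdx <- (state_energy(x + h, open, partial, cfg)$energy_pNnm -
                   state_energy(x - h, open, partial, cfg)$energy_pNnm) / (2 * h)
        expect_equal(dEdx, se$tension_pN, tolerance = 1e-5)
      }
    }
  }
  # zero-force reference: closed state at its rest length has E = 0, F = 0
  se0 <- state_energy(cfg$x0_closed_folded, FALSE, FALSE, cfg)
  expect_equal(se0$energy_pNnm, 0)
  expect_equal(se0$tension_pN, 0)
  expect_error(state_energy(cfg$x0_closed_folded - 5, FALSE, FALSE, cfg),
               "below the zero-force")
})

test_that("opening probability follows the Boltzmann closed forms", {
  # chain-free configuration: dE(x) = V kBT - k s (x - x0 - s/2) exactly
  cfg <- gating_config(disordered_residues_folded = 0,
                       disordered_residues_partial = 0)
  k <- cfg$k_fold; s <- cfg$gating_swing; V <- cfg$V_open * 4.1
  x_half <- cfg$x0_closed_folded + s / 2 + V / (k * s)
  expect_equal(open_probability(x_half, cfg = cfg), 0.5, tolerance = 1e-9)
  # dE = +1 kBT -> P = 1/(1+e)
  x_1kBT <- cfg$x0_closed_folded + s / 2 + (V - 4.1) / (k * s)
  expect_equal(open_probability(x_1kBT, cfg = cfg), 1 / (1 + exp(1)),
               tolerance = 1e-9)
  # a vanishing swing leaves only the gate energy
  cfg0 <- gating_config(disordered_residues_folded = 0,
                        disordered_residues_partial = 0,
                        gating_swing = 0)
  expect_equal(open_probability(40, cfg = cfg0), 1 / (1 + exp(8)),
               tolerance = 1e-9)
  # nondecreasing in extension (default config, with chains)
  xg <- seq(26, 70, by = 0.5)
  expect_true(all(diff(open_probability(xg)) >= 0))
})

test_that("midpoint force matches the chain-free identity and the model value", {
  # without disordered chains the average branch tension at P = 0.5 is
  # exactly V kBT / swing, independent of the rod stiffness
  for (k in c(1.4, 2.5)) {
    cfg <- gating_config(k_fold = k, disordered_residues_folded = 0,
                         disordered_residues_partial = 0)
    mp <- midpoint_force(cfg)
    expect_equal(mp$F_gating_pN, 8 * 4.1 / 4.6, tolerance = 1e-9)
    expect_equal(mp$p_open, 0.5, tolerance = 1e-9)
  }
  # full model: gating force lands near 7 pN
  mp <- midpoint_force(gating_config())
  expect_gt(mp$F_gating_pN, 6.5)
  expect_lt(mp$F_gating_pN, 7.5)
  # raising the gate energy raises the midpoint
  mp9 <- midpoint_force(gating_config(V_open = 9))
  expect_gt(mp9$F_gating_pN, mp$F_gating_pN)
})

test_that("gating curves have the expected ordering and bounds", {
  cfg <- gating_config()
  xg <- seq(30, 70, by = 1)
  cur <- gating_curves(xg, cfg)
  fol <- cur[cur$arrangement == "folded", ]
  par_ <- cur[cur$arrangement == "partial", ]
  # longer intrinsic length (open state) carries lower tension at equal x
  expect_true(all(fol$F_closed_pN > fol$F_open_pN))
  # partial unfolding reduces tension at equal extension
  expect_true(all(par_$F_avg_pN < fol$F_avg_pN))
  # stiffness stays below the folded rod stiffness
  expect_true(all(cur$stiffness_pN_per_nm < cfg$k_fold))
  # average tension lies between the branch tensions
  expect_true(all(fol$F_avg_pN <= fol$F_closed_pN + 1e-12 &
                    fol$F_avg_pN >= fol$F_open_pN - 1e-12))
  # opening probability is nondecreasing along the grid
  expect_true(all(diff(fol$p_open) >= 0))
})

test_that("stimulus loading rate follows the half-period convention", {
  expect_equal(loading_rate(1000, 1, 1.4), 2800)
  expect_equal(loading_rate(1000, 1, 1.4, signif_digits = 1), 3000)
  expect_equal(loading_rate(2000, 1, 1.4), 2 * 2800)
  expect_equal(loading_rate(1000, 0, 1.4), 0)
  expect_equal(loading_rate(1000, 1, 1.4, convention = "peak"),
               1.4 * 2 * pi * 1000)
})

test_that("Bell-Evans rupture distribution matches its closed forms", {
  bd <- bell_rupture_distribution(k0 = 1e-3, x_dagger = 2, r = 3000)
  # normalization
  expect_equal(stats::integrate(bd$density, 0, Inf, rel.tol = 1e-10)$value,
               1, tolerance = 1e-8)
  # analytic mode equals the numeric argmax
  opt <- stats::optimize(bd$density, c(0, 60), maximum = TRUE)$maximum
  expect_equal(bd$mode_pN, opt, tolerance = 0.05)
  # mean rupture force grows with loading rate
  means <- vapply(c(10, 100, 1000, 10000), function(r)
    bell_rupture_distribution(1e-3, 2, r)$mean_pN, numeric(1))
  expect_true(all(diff(means) > 0))
})
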