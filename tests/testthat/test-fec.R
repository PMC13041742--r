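test_that("boxcar filter has the expected impulse and noise response", {
  n <- 2000; rate <- 100
  tt <- seq_len(n) / rate
  # constant trace passes through unchanged
  con <- fec_trace(tt, rep(100, n), rep(5, n), rep(50, n),
                   sampling_rate = rate)
  out <- boxcar_filter(con, 0.1)
  expect_true(all(abs(out$data$force_pN - 5) < 1e-12))
  expect_true(all(abs(out$data$extension_nm - 50) < 1e-12))
  expect_lt(nrow(out$data), n)
  # white noise of sd sigma -> sd sigma/sqrt(m) within 10%
  set.seed(7)
  m <- 10
  noisy <- fec_trace(tt, rep(100, n), rep(5, n), rnorm(n, 50, 2),
                     sampling_rate = rate)
  filt <- boxcar_filter(noisy, m / rate)
  # thin to independent (non-overlapping) windows before taking the SD
  idx <- seq(1, nrow(filt$data), by = m)
  expect_equal(sd(filt$data$extension_nm[idx]), 2 / sqrt(m),
               tolerance = 0.1)
  # single spike of height h -> plateau of height h/m
  spike <- rep(0, n); spike[1000] <- 8
  sp <- fec_trace(tt, rep(100, n), rep(5, n), spike, sampling_rate = rate)
  fsp <- boxcar_filter(sp, m / rate)
  expect_equal(max(fsp$data$extension_nm), 8 / m, tolerance = 1e-12)
  expect_equal(sum(fsp$data$extension_nm > 1e-12), m)
  expect_error(boxcar_filter(con, 0.001), "at least 2 samples")
  expect_error(boxcar_filter(con, 1000), "duration")
})

test_that("force binning reproduces exact curves and keeps bookkeeping", {
  rod <- elastic_rod(20, 0.7)
  centers <- seq(1.2, 6.8, by = 0.2)   # true bin centers for lo=0.5, w=0.2
  tr <- trace_from_model(tether(rod), centers, dwell = 7)
  b <- bin_by_force(tr, 0.2, c(0.5, 20))
  expect_equal(b$bins$force_pN, centers)
  expect_equal(b$bins$mean_ext_nm, 20 + centers / 0.7, tolerance = 1e-9)
  expect_true(all(b$bins$n == 7))
  expect_true(all(b$bins$sd_nm < 1e-9))
  # all samples at one force -> a single bin holding the sample mean
  one <- fec_trace(1:50 / 100, rep(1, 50), rep(3.05, 50),
                   c(rep(10, 25), rep(12, 25)))
  b1 <- bin_by_force(one, 0.2, c(0.5, 20))
  expect_equal(nrow(b1$bins), 1)
  expect_equal(b1$bins$mean_ext_nm, 11)
  # pooling two interleaved ramps doubles the per-bin counts
  b2 <- pool_molecules(list(b, b))
  expect_true(all(b2$bins$n == 14))
  expect_equal(b2$bins$mean_ext_nm, b$bins$mean_ext_nm)
  expect_error(bin_by_force(tr, 0.2, c(5, 5)), "empty force range")
  expect_error(bin_by_force(one, 0.2, c(15, 20)), "no samples")
})

test_that("differential subtraction recovers the rod law exactly", {
  centers <- seq(0.7, 7.9, by = 0.2)
  dna <- wlc(1527.8, 40)
  rod <- elastic_rod(20, 0.7)
  chain <- wlc(residues_to_contour(123), 0.6)
  prot <- binned_from_model(tether(dna, rod, parallel_bundle(chain, 1),
                                   rigid_offset(5)), centers)
  dna_fec <- binned_from_model(tether(dna), centers)
  diff <- differential_structured_extension(prot, dna_fec,
                                            n_disordered = 123, nanodisc = 5)
  expect_equal(diff$bins$mean_ext_nm, 20 + centers / 0.7, tolerance = 1e-6)
  # identical inputs with nothing to subtract -> all-zero differential
  zero <- differential_structured_extension(dna_fec, dna_fec)
  expect_true(all(abs(zero$bins$mean_ext_nm) < 1e-12))
  # plain difference when no chain and no disc
  plain <- differential_structured_extension(prot, dna_fec)
  expect_equal(plain$bins$mean_ext_nm,
               prot$bins$mean_ext_nm - dna_fec$bins$mean_ext_nm)
  shifted <- binned_fec(centers + 100, prot$bins$mean_ext_nm,
                        prot$bins$sd_nm, prot$bins$n)
  expect_error(differential_structured_extension(shifted, dna_fec),
               "share no bins")
})

test_that("pooling across molecules uses exact population moments", {
  centers <- c(1.1, 1.3)
  a <- binned_fec(centers, c(10, 20), c(0, 0), c(4, 4))
  expect_identical(pool_molecules(list(a)), a)
  same <- pool_molecules(list(a, a))
  expect_equal(same$bins$mean_ext_nm, c(10, 20))
  expect_equal(same$bins$sd_nm, c(0, 0))
  # two molecules offset by +/- d -> mean at midpoint, population SD d
  up <- binned_fec(centers, c(13, 23), c(0, 0), c(4, 4))
  dn <- binned_fec(centers, c(7, 17), c(0, 0), c(4, 4))
  mix <- pool_molecules(list(up, dn))
  expect_equal(mix$bins$mean_ext_nm, c(10, 20))
  expect_equal(mix$bins$sd_nm, c(3, 3))
  expect_equal(mix$n_molecules, 2L)
})

test_that("linear stiffness fit recovers exact rod data and flags failures", {
  centers <- seq(1.1, 6.9, by = 0.2)
  exact <- binned_fec(centers, 20 + centers / 0.7,
                      rep(0, length(centers)), rep(10, length(centers)))
  fit <- fit_stiffness_linear(exact, c(1, 7))
  expect_true(fit$converged)
  expect_equal(fit$k, 0.7, tolerance = 1e-9)
  expect_equal(fit$x0, 20, tolerance = 1e-9)
  # too few bins
  few <- binned_fec(centers[1:2], 20 + centers[1:2] / 0.7, c(0, 0), c(1, 1))
  f2 <- fit_stiffness_linear(few, c(1, 7))
  expect_false(f2$converged)
  expect_match(f2$reason, "fewer than 3")
  # extension decreasing with force -> flagged, not clamped
  bad <- binned_fec(centers, 40 - centers, rep(0, length(centers)),
                    rep(1, length(centers)))
  f3 <- fit_stiffness_linear(bad, c(1, 7))
  expect_false(f3$converged)
  expect_match(f3$reason, "non-positive")
})

test_that("global FEC fit recovers noiseless truth and branch contours", {
  centers <- seq(0.7, 14.9, by = 0.2)
  dna <- wlc(1527.8, 40)
  rod <- elastic_rod(20, 0.7)
  dna_fec <- binned_from_model(tether(dna), centers)
  mk_branch <- function(L_unf) {
    binned_from_model(tether(dna, rod, wlc(L_unf, 0.6), rigid_offset(5)),
                      centers)
  }
  L1 <- residues_to_contour(123)        # 44.895 nm
  L2 <- L1 + residues_to_contour(957)   # + 349.305 nm fully unfolded
  fit <- fit_fec_global(dna_fec, list(mk_branch(L1), mk_branch(L2)),
                        start = list(P_dna = 35, P_chain = 0.8, x0 = 15,
                                     k = 1, L_unf = c(50, 420)),
                        fixed = list(L_dna = 1527.8, offset_nm = 5))
  expect_true(fit$converged)
  expect_equal(fit$par$P_dna, 40, tolerance = 1e-5)
  expect_equal(fit$par$P_chain, 0.6, tolerance = 1e-5)
  expect_equal(fit$par$x0, 20, tolerance = 1e-5)
  expect_equal(fit$par$k, 0.7, tolerance = 1e-5)
  expect_equal(fit$contour_gain_nm[2], 349.305, tolerance = 1e-3)
  # contour gain converts back to the released residue count
  expect_equal(round(fit$contour_gain_nm[2] / cst$aa_rise), 957)
})

test_that("global FEC fit errors are calibrated on noisy data", {
  centers <- seq(0.7, 14.9, by = 0.2)
  dna <- wlc(1527.8, 40)
  rod <- elastic_rod(20, 0.7)
  truth_tether <- tether(dna, rod, wlc(44.895, 0.6), rigid_offset(5))
  set.seed(31)
  hits <- 0
  n_rep <- 25
  for (r in seq_len(n_rep)) {
    dna_fec <- binned_fec(centers,
                          tether_extension(centers, tether(dna)) +
                            rnorm(length(centers), 0, 2),
                          rep(2, length(centers)), rep(1, length(centers)))
    tet_fec <- binned_fec(centers,
                          tether_extension(centers, truth_tether) +
                            rnorm(length(centers), 0, 2),
                          rep(2, length(centers)), rep(1, length(centers)))
    fit <- fit_fec_global(dna_fec, tet_fec,
                          start = list(P_dna = 40, P_chain = 0.6, x0 = 18,
                                       k = 0.8, L_unf = 50),
                          fixed = list(L_dna = 1527.8, offset_nm = 5))
    if (abs(fit$par$k - 0.7) <= 3 * fit$se$k) hits <- hits + 1
  }
  expect_gte(hits, round(0.85 * n_rep))
})

# residues whose release produces a target extension jump in the recorded
# trace: the constant-force contour gain DL*u(f) is shared between the
# tether and the trap compliance, so the observable jump is scaled by
# C_trap / (C_trap + C_tether)
residues_for_observed_jump <- function(target_nm, f, prior_residues = 123,
                                       k_trap = 0.3) {
  C_trap <- 2 / k_trap
  th <- tether(wlc(1527.8, 40), elastic_rod(20, 0.7),
               wlc(residues_to_contour(prior_residues), 0.6),
               rigid_offset(5))
  C_t <- 1 / tether_stiffness(f, th)
  u <- wlc_extension(f, wlc(1, 0.6))
  target_nm * (C_trap + C_t) / (C_trap * u * cst$aa_rise)
}

test_that("rip detection finds programmed jumps and nothing else", {
  # noiseless ramp without rips -> no events
  quiet <- simulate_pull(wt_truth(noise_ext = 0, noise_force = 0), seed = 1)
  expect_equal(nrow(detect_transitions(boxcar_filter(quiet, 0.1))), 0)
  # three programmed rips sized to show 8, 12 and 20 nm jumps in the trace
  jumps <- c(8, 12, 20); trig <- c(6, 8, 10)
  res <- numeric(3); prior <- 123
  for (i in 1:3) {
    res[i] <- residues_for_observed_jump(jumps[i], trig[i], prior)
    prior <- prior + res[i]
  }
  truth <- wt_truth(rip_plan = list(
    list(at_force = 6, residues = res[1]),
    list(at_force = 8, residues = res[2]),
    list(at_force = 10, residues = res[3])))
  tr <- simulate_pull(truth, seed = 21)
  truth_rips <- attr(tr, "rips")
  expect_equal(truth_rips$ext_jump_nm, jumps, tolerance = 0.5)
  ev <- detect_transitions(boxcar_filter(tr, 0.1))
  ev <- ev[ev$direction == "unfolding", ]
  expect_equal(nrow(ev), 3)
  expect_equal(ev$extension_jump_nm, jumps, tolerance = 1)
  expect_equal(ev$force_at_rip_pN, trig, tolerance = 0.2)
  expect_equal(ev$time_s, truth_rips$time_s, tolerance = 0.3)
})

test_that("a programmed extension drop at constant force is an insertion", {
  set.seed(5)
  n <- 3000; rate <- 100
  ext <- c(rep(1250, 1500), rep(1240, 1500)) + rnorm(n, 0, 2)
  tr <- fec_trace(seq_len(n) / rate, rep(1283, n),
                  rnorm(n, 5, 0.2), ext, sampling_rate = rate)
  ev <- detect_transitions(boxcar_filter(tr, 0.1))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$direction, "insertion")
  expect_equal(ev$extension_jump_nm, -10, tolerance = 1)
})

test_that("rip detection has no false positives and full recall", {
  # no-rip traces: zero events across 100 seeds at default thresholds
  total <- 0
  proto <- pull_protocol(force_range = c(0.5, 8))
  for (s in 1:100) {
    tr <- simulate_pull(wt_truth(), protocol = proto, seed = 3000 + s)
    total <- total + nrow(detect_transitions(boxcar_filter(tr, 0.1)))
  }
  expect_equal(total, 0)
  # rips showing twice the threshold (6 nm) are always recovered
  res6 <- residues_for_observed_jump(6, 6)
  truth <- wt_truth(rip_plan = list(list(at_force = 6, residues = res6)),
                    noise_ext = 1)
  found <- vapply(1:20, function(s) {
    tr <- simulate_pull(truth, protocol = proto, seed = 5000 + s)
    ev <- detect_transitions(boxcar_filter(tr, 0.1))
    sum(ev$direction == "unfolding")
  }, numeric(1))
  expect_true(all(found == 1))
})

test_that("contour gains map to residue and ankyrin-repeat counts", {
  st <- assign_states(c(0, 120.5, 349.3))
  expect_equal(st$state_label, c("F_A", "I1", "I3"))
  expect_equal(st$unfolded_residues, c(0, 330, 957))
  expect_equal(st$unfolded_ARs, c(0, 10, 29))
  # identity on integer residue counts through the gain transform
  res <- c(33, 100, 330, 660, 957)
  back <- assign_states(residues_to_contour(res))
  expect_equal(back$unfolded_residues, res)
  expect_error(assign_states(-5), ">= 0")
})

test_that("unfolding force statistics follow the sample conventions", {
  mk <- function(f) data.frame(time_s = seq_along(f),
                               force_at_rip_pN = f,
                               extension_jump_nm = 10,
                               direction = "unfolding")
  st <- unfolding_force_stats(list(mk(5), mk(7), mk(9)))
  expect_equal(st$mean_pN, 7)
  expect_equal(st$sd_pN, 2)
  one <- unfolding_force_stats(mk(6.5))
  expect_true(one$single_event)
  expect_true(is.na(one$sd_pN))
  expect_error(unfolding_force_stats(list()), "no unfolding")
  # first-vs-all selection
  two <- mk(c(6, 9))
  expect_equal(unfolding_force_stats(two, "first")$mean_pN, 6)
  expect_equal(unfolding_force_stats(two, "all")$mean_pN, 7.5)
})

test_that("Bell-triggered rupture forces match the analytic distribution", {
  # rod-only tether gives a constant loading rate r = v / (1/k_eff + 1/k)
  proto <- pull_protocol(force_range = c(0.5, 20))
  r <- proto$speed / (2 / proto$trap_stiffness + 1 / 1.4)
  kin <- list(k0 = 1e-3, x_dagger = 2)
  truth <- sim_truth(dna = NULL, rod = elastic_rod(20, 1.4),
                     unfolded_residues = 0, nanodisc = 0,
                     rip_plan = list(list(bell = kin, residues = 300)))
  forces <- vapply(1:200, function(s) {
    tr <- simulate_pull(truth, proto, seed = 40000 + s)
    ev <- detect_transitions(boxcar_filter(tr, 0.1))
    ev <- ev[ev$direction == "unfolding", ]
    if (nrow(ev) == 0) NA_real_ else ev$force_at_rip_pN[1]
  }, numeric(1))
  expect_gt(mean(!is.na(forces)), 0.95)
  st <- unfolding_force_stats(
    data.frame(time_s = seq_along(forces[!is.na(forces)]),
               force_at_rip_pN = forces[!is.na(forces)],
               extension_jump_nm = 10, direction = "unfolding"), "all")
  ref <- bell_rupture_distribution(kin$k0, kin$x_dagger, r)
  se <- st$sd_pN / sqrt(length(st$forces_pN))
  expect_lt(abs(st$mean_pN - ref$mean_pN), 3 * se + 0.2)
})

test_that("state occurrence profiles peak at the programmed intermediates", {
  gains_true <- c(I1 = residues_to_contour(330),
                  I2 = residues_to_contour(660),
                  I3 = residues_to_contour(957))
  truth <- wt_truth(rip_plan = list(
    list(at_force = 7, residues = 330),
    list(at_force = 9, residues = 330),
    list(at_force = 11, residues = 297)))
  gains <- lapply(1:5, function(m) {
    prot <- simulate_pull(truth, seed = 600 + 2 * m)
    dna <- simulate_dna_only(seed = 601 + 2 * m)
    res <- analyze_pull_fec(prot, dna)
    res$states$contour_gain_nm[res$states$contour_gain_nm > 10]
  })
  prof <- state_occurrence_profile(gains, grid_width = 40)
  expect_equal(sum(prof$probability), 1)
  peaks <- prof$contour_gain_nm[order(-prof$probability)][1:3]
  for (g in gains_true) expect_lte(min(abs(peaks - g)), 40)
  # single-state cohort -> all mass in one cell
  single <- state_occurrence_profile(list(349.3, 349.3, 349.3),
                                     grid_width = 40)
  expect_equal(max(single$probability), 1)
  expect_error(state_occurrence_profile(list()), "non-empty")
})

test_that("refolding classification matches the programmed success rate", {
  proto <- pull_protocol(force_range = c(0.5, 8))
  folded <- wt_truth()
  trapped <- wt_truth(unfolded_residues = 123 + 200)
  bin_of <- function(tr) bin_by_force(boxcar_filter(tr, 0.1), 0.2, c(0.5, 8))
  # identical curves are refolded; a +20 nm shift is misfolded
  base <- bin_of(simulate_pull(folded, proto, seed = 900))
  expect_equal(classify_refolding(base, base)$classification, "refolded")
  shifted <- binned_fec(base$bins$force_pN, base$bins$mean_ext_nm + 20,
                        base$bins$sd_nm, base$bins$n)
  expect_equal(classify_refolding(base, shifted)$classification, "misfolded")
  # cohort with 30% programmed refolding probability
  set.seed(77)
  n_mol <- 40
  success <- rbinom(n_mol, 1, 0.3) == 1
  calls <- vapply(seq_len(n_mol), function(m) {
    first <- bin_of(simulate_pull(folded, proto, seed = 7000 + 2 * m))
    re_truth <- if (success[m]) folded else trapped
    re <- bin_of(simulate_pull(re_truth, proto, seed = 7001 + 2 * m))
    classify_refolding(first, re)$classification
  }, character(1))
  expect_equal(calls == "refolded", success)
  frac <- mean(calls == "refolded")
  expect_lt(abs(frac - 0.3), 1.96 * sqrt(0.3 * 0.7 / n_mol))
})
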