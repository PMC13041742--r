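#' Pulling protocol for simulated dual-trap experiments
#'
#' @param speed Trap speed, nm/s (default 10, one trap moving).
#' @param trap_stiffness Stiffness of each trap, pN/nm (default 0.3; the
#'   experimental range is 0.1-0.3). The two traps act in series, so the
#'   bead-displacement compliance is 2/trap_stiffness.
#' @param sampling_rate Hz (default 100).
#' @param force_range Forces spanned by the ramp, pN.
#' @return An object of class `pull_protocol`.
#' @export
pull_protocol <- function(speed = 10, trap_stiffness = 0.3,
                          sampling_rate = 100, force_range = c(0.5, 20)) {
  stopifnot(speed > 0, trap_stiffness > 0, sampling_rate > 0,
            force_range[2] > force_range[1], force_range[1] > 0)
  structure(list(speed = speed, trap_stiffness = trap_stiffness,
                 sampling_rate = sampling_rate, force_range = force_range),
            class = "pull_protocol")
}

#' Ground truth for a simulated tether
#'
#' Describes the mechanical truth behind a simulated trace: handle, rod,
#' disordered chain, rigid offset, unfolding rip plan and noise. The seed
#' passed to the simulators fully determines the output.
#'
#' @param dna A [wlc()] for the DNA handles, or `NULL`.
#' @param rod An [elastic_rod()] for the structured protein, or `NULL`.
#' @param unfolded_residues Initially unfolded residues (e.g. the
#'   disordered N-terminal tail).
#' @param chain_P Persistence length of unfolded polypeptide, nm.
#' @param nanodisc Rigid offset, nm.
#' @param rip_plan List of rip events, in order; each a list with
#'   `residues` (released on unfolding) and either `at_force` (pN,
#'   deterministic trigger) or `bell = list(k0, x_dagger)` (stochastic
#'   Bell-rate trigger, Gillespie-drawn per time step).
#' @param ard_capacity Total foldable residues; the summed released
#'   residues may not exceed it (NULL skips the check).
#' @param noise_ext,noise_force I.i.d. Gaussian noise SDs added to each
#'   raw extension (nm) and force (pN) sample.
#' @return An object of class `sim_truth`.
#' @export
sim_truth <- function(dna = wlc(1527.8, 40), rod = NULL,
                      unfolded_residues = 0, chain_P = 0.6, nanodisc = 0,
                      rip_plan = list(), ard_capacity = NULL,
                      noise_ext = 2, noise_force = 0.2) {
  if (!is.null(dna)) stopifnot(inherits(dna, "wlc"))
  if (!is.null(rod)) stopifnot(inherits(rod, "elastic_rod"))
  stopifnot(unfolded_residues >= 0, nanodisc >= 0,
            noise_ext >= 0, noise_force >= 0)
  released <- sum(vapply(rip_plan, function(r) r$residues, numeric(1)))
  if (!is.null(ard_capacity) && released > ard_capacity) {
    stop("sim_truth: rip plan releases ", released,
         " residues, exceeding the ARD content of ", ard_capacity)
  }
  structure(list(dna = dna, rod = rod,
                 unfolded_residues = unfolded_residues, chain_P = chain_P,
                 nanodisc = nanodisc, rip_plan = rip_plan,
                 ard_capacity = ard_capacity,
                 noise_ext = noise_ext, noise_force = noise_force),
            class = "sim_truth")
}

# tether for a given number of unfolded residues
.truth_tether <- function(truth, unfolded_residues, c) {
  els <- list()
  if (!is.null(truth$dna)) els <- c(els, list(truth$dna))
  if (!is.null(truth$rod)) els <- c(els, list(truth$rod))
  if (unfolded_residues > 0) {
    els <- c(els, list(wlc(residues_to_contour(unfolded_residues, c),
                           truth$chain_P)))
  }
  if (truth$nanodisc > 0) els <- c(els, list(rigid_offset(truth$nanodisc)))
  tether(els)
}

#' Simulate a quasi-static pulling ramp
#'
#' One trap moves at constant speed; at every trap separation the common
#' tension of the two traps (in series) and the tether is solved, rips
#' switch the unfolded-residue count when their trigger fires (fixed
#' force, or a Bell-rate event drawn per time step), and i.i.d. Gaussian
#' noise is added to the recorded force and extension. Deterministic for
#' a given seed.
#'
#' @param truth A [sim_truth()].
#' @param protocol A [pull_protocol()].
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param label Trace label.
#' @param c A [constants()] object.
#' @return A [fec_trace()] carrying attributes `truth` (the input truth)
#'   and `rips` (data frame of realized rip times, forces and released
#'   residues).
#' @export
simulate_pull <- function(truth, protocol = pull_protocol(), seed = NULL,
                          label = "sim", c = constants()) {
  stopifnot(inherits(truth, "sim_truth"), inherits(protocol, "pull_protocol"))
  if (!is.null(seed)) set.seed(seed)
  k_eff <- protocol$trap_stiffness / 2
  F_lo <- protocol$force_range[1]; F_hi <- protocol$force_range[2]
  F_grid <- seq(min(0.01, F_lo / 2), F_hi * 1.05, length.out = 2000)
  sep_of <- function(th) tether_extension(F_grid, th, c) + F_grid / k_eff
  unf0 <- truth$unfolded_residues
  th0 <- .truth_tether(truth, unf0, c)
  unf_final <- unf0 + sum(vapply(truth$rip_plan, function(r) r$residues,
                                 numeric(1)))
  th_final <- .truth_tether(truth, unf_final, c)
  D_start <- stats::approx(F_grid, sep_of(th0), xout = F_lo)$y
  D_end <- stats::approx(F_grid, sep_of(th_final), xout = F_hi)$y
  dt <- 1 / protocol$sampling_rate
  times <- seq(0, (D_end - D_start) / protocol$speed, by = dt)
  D <- D_start + protocol$speed * times
  n <- length(times)
  F_out <- numeric(n)
  i0 <- 1L
  unf <- unf0
  plan <- truth$rip_plan
  rips <- list()
  while (i0 <= n) {
    th <- .truth_tether(truth, unf, c)
    sep_grid <- sep_of(th)
    F_seg <- stats::approx(sep_grid, F_grid, xout = D[i0:n], rule = 2)$y
    if (length(plan) == 0) {
      F_out[i0:n] <- F_seg
      break
    }
    rp <- plan[[1]]
    if (!is.null(rp$at_force)) {
      trig <- which(F_seg >= rp$at_force)
    } else {
      haz <- rp$bell$k0 * exp(F_seg * rp$bell$x_dagger / c$kBT) * dt
      trig <- which(cumsum(haz) >= stats::rexp(1))
    }
    if (length(trig) == 0) {            # trigger never fires in this ramp
      F_out[i0:n] <- F_seg
      break
    }
    cut <- trig[1]
    F_out[i0:(i0 + cut - 1)] <- F_seg[seq_len(cut)]
    rips[[length(rips) + 1]] <- data.frame(
      time_s = times[i0 + cut - 1], force_pN = F_seg[cut],
      residues = rp$residues, idx = i0 + cut - 1)
    unf <- unf + rp$residues
    plan <- plan[-1]
    i0 <- i0 + cut
  }
  x <- D - F_out / k_eff
  F_rec <- F_out + stats::rnorm(n, 0, truth$noise_force)
  x_rec <- x + stats::rnorm(n, 0, truth$noise_ext)
  tr <- fec_trace(times, D, F_rec, x_rec, label = label, phase = "pull",
                  sampling_rate = protocol$sampling_rate)
  attr(tr, "truth") <- truth
  rips_df <- if (length(rips)) do.call(rbind, rips) else
    data.frame(time_s = numeric(0), force_pN = numeric(0),
               residues = numeric(0), idx = integer(0))
  # realized extension jump at constant trap separation (the observable):
  # the released contour is shared between the tether and the trap
  # compliance, so this is smaller than the constant-force contour gain
  rips_df$ext_jump_nm <- if (nrow(rips_df)) {
    vapply(rips_df$idx, function(i) {
      if (i < n) x[i + 1] - x[i] else NA_real_
    }, numeric(1))
  } else numeric(0)
  rips_df$idx <- NULL
  attr(tr, "rips") <- rips_df
  tr
}

#' Simulate a DNA-only pulling ramp
#'
#' Convenience wrapper: [simulate_pull()] with a handle-only tether
#' sharing the protein truth's noise model.
#'
#' @param dna A [wlc()] for the handles.
#' @param protocol A [pull_protocol()].
#' @param noise_ext,noise_force Gaussian noise SDs.
#' @param seed Integer seed (use a seed distinct from the paired protein
#'   trace: each call consumes its own stream).
#' @param label Trace label.
#' @param c A [constants()] object.
#' @return A [fec_trace()].
#' @export
simulate_dna_only <- function(dna = wlc(1527.8, 40),
                              protocol = pull_protocol(), noise_ext = 2,
                              noise_force = 0.2, seed = NULL,
                              label = "dna", c = constants()) {
  truth <- sim_truth(dna = dna, rod = NULL, unfolded_residues = 0,
                     nanodisc = 0, rip_plan = list(),
                     noise_ext = noise_ext, noise_force = noise_force)
  simulate_pull(truth, protocol, seed = seed, label = label, c = c)
}

#' Simulate a constant-force two-state trace
#'
#' Continuous-time two-state Markov chain with exact exponential dwell
#' sampling whose stationary occupancy follows the Boltzmann relation
#' P_high = 1 / (1 + exp((F_eq - F) delta_x / kBT)), overlaid with
#' Gaussian measurement noise.
#'
#' @param force Clamp force, pN.
#' @param F_eq Equilibrium force of the transition, pN (default 6.9).
#' @param delta_x Extension change between the states, nm (default 4.7).
#' @param duration Trace length, s (default 60).
#' @param noise_sd Gaussian noise SD, nm (default 1.5).
#' @param rate_scale Transition attempt rate at equilibrium, 1/s per
#'   direction (default 2, giving on the order of 100 transitions per
#'   minute at the equilibrium force).
#' @param sampling_rate Hz (default 200).
#' @param baseline Extension of the low state, nm.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param c A [constants()] object.
#' @return A [clamp_trace()] with attribute `truth` (parameters and the
#'   number of simulated transitions).
#' @export
simulate_clamp <- function(force, F_eq = 6.9, delta_x = 4.7, duration = 60,
                           noise_sd = 1.5, rate_scale = 2,
                           sampling_rate = 200, baseline = 0, seed = NULL,
                           c = constants()) {
  stopifnot(force > 0, delta_x > 0, duration > 0, rate_scale > 0)
  if (!is.null(seed)) set.seed(seed)
  dG <- (F_eq - force) * delta_x          # high minus low, pN nm
  k_up <- rate_scale * exp(-dG / (2 * c$kBT))
  k_down <- rate_scale * exp(dG / (2 * c$kBT))
  p_high <- 1 / (1 + exp(dG / c$kBT))
  state <- as.integer(stats::runif(1) < p_high)
  t_now <- 0
  sw_t <- numeric(0); sw_s <- integer(0)
  sw_t[1] <- 0; sw_s[1] <- state
  while (t_now < duration) {
    rate <- if (state == 1L) k_down else k_up
    t_now <- t_now + stats::rexp(1, rate)
    state <- 1L - state
    sw_t <- c(sw_t, t_now); sw_s <- c(sw_s, state)
  }
  tt <- seq(0, duration, by = 1 / sampling_rate)
  st <- sw_s[findInterval(tt, sw_t)]
  ext <- baseline + st * delta_x + stats::rnorm(length(tt), 0, noise_sd)
  tr <- clamp_trace(tt, ext, mean_force = force,
                    sampling_rate = sampling_rate)
  attr(tr, "truth") <- list(force = force, F_eq = F_eq, delta_x = delta_x,
                            noise_sd = noise_sd, rate_scale = rate_scale,
                            p_high = p_high,
                            n_transitions = length(sw_t) - 2L)
  tr
}

#' Simulate a paired cohort and run the differential stiffness pipeline
#'
#' For each molecule, simulates a protein-DNA pull and an independent
#' DNA-only pull, box-filters and force-bins both, forms the differential
#' structured extension, pools across molecules, and fits the linear
#' stiffness over the requested force range.
#'
#' @param k,x0 Truth rod stiffness (pN/nm) and intrinsic length (nm).
#' @param n_disordered Disordered residues (simulated and subtracted).
#' @param nanodisc Rigid offset, nm (simulated and subtracted).
#' @param n_molecules Number of molecules (default 10).
#' @param seed Base seed; molecule m uses seeds `seed + 2m` (protein) and
#'   `seed + 2m + 1` (DNA) so the noise streams are independent.
#' @param protocol A [pull_protocol()].
#' @param noise_ext,noise_force Gaussian noise SDs.
#' @param window Boxcar window, s.
#' @param bin_width,bin_range Force binning parameters, pN.
#' @param fit_range Force range of the linear stiffness fit, pN.
#' @param rip_plan Optional rip plan applied to every protein molecule.
#' @param c A [constants()] object.
#' @return A list: `fit` (the [fit_stiffness_linear()] result),
#'   `structured` (pooled differential [binned_fec()]), `truth`.
#' @export
simulate_stiffness_cohort <- function(k, x0 = 20, n_disordered = 123,
                                      nanodisc = 5, n_molecules = 10,
                                      seed = 1, protocol = pull_protocol(),
                                      noise_ext = 2, noise_force = 0.2,
                                      window = 0.1, bin_width = 0.2,
                                      bin_range = c(0.5, 20),
                                      fit_range = c(1, 7),
                                      rip_plan = list(), c = constants()) {
  truth <- sim_truth(dna = wlc(1527.8, 40), rod = elastic_rod(x0, k),
                     unfolded_residues = n_disordered, nanodisc = nanodisc,
                     rip_plan = rip_plan, noise_ext = noise_ext,
                     noise_force = noise_force)
  diffs <- vector("list", n_molecules)
  for (m in seq_len(n_molecules)) {
    prot <- simulate_pull(truth, protocol, seed = seed + 2 * m,
                          label = paste0("mol", m))
    dna <- simulate_dna_only(truth$dna, protocol, noise_ext, noise_force,
                             seed = seed + 2 * m + 1)
    pb <- bin_by_force(boxcar_filter(prot, window), bin_width, bin_range)
    db <- bin_by_force(boxcar_filter(dna, window), bin_width, bin_range)
    diffs[[m]] <- differential_structured_extension(
      pb, db, n_disordered = n_disordered, nanodisc = nanodisc,
      chain_P = truth$chain_P, c = c)
  }
  pooled <- pool_molecules(diffs)
  list(fit = fit_stiffness_linear(pooled, fit_range), structured = pooled,
       truth = truth)
}

#' Write the canonical synthetic test cohort to disk
#'
#' Generates the study-like file set: per-molecule DNA-only and
#' protein-DNA pulls for wild-type NompC (truth 0.7 pN/nm), the
#' 12-repeat truncation (0.26 pN/nm) and the isolated AnkB ARD
#' (0.12 pN/nm), plus a constant-force clamp ladder; every trace gets a
#' `.truth.json` sidecar. Idempotent for a given seed.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Base seed.
#' @param n_molecules Molecules per construct (default 5).
#' @param clamp_forces Clamp ladder forces, pN.
#' @param c A [constants()] object.
#' @return Invisibly, the character vector of files written.
#' @export
fixture_suite <- function(out_dir, seed = 1, n_molecules = 5,
                          clamp_forces = c(5.5, 6.2, 6.9, 7.6, 8.5),
                          c = constants()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  constructs <- list(
    wt = list(k = 0.7, x0 = 20, n_disordered = 123, nanodisc = 5),
    d12 = list(k = 0.26, x0 = 15, n_disordered = 123, nanodisc = 5),
    ankb = list(k = 0.12, x0 = 15, n_disordered = 20, nanodisc = 0))
  files <- character(0)
  put <- function(obj, path, truth) {
    write_trace(obj, path)
    tj <- sub("\\.tsv$", ".truth.json", path)
    jsonlite::write_json(truth, tj, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    c(path, tj)
  }
  off <- 0
  for (nmc in names(constructs)) {
    cs <- constructs[[nmc]]
    truth <- sim_truth(dna = wlc(1527.8, 40),
                       rod = elastic_rod(cs$x0, cs$k),
                       unfolded_residues = cs$n_disordered,
                       nanodisc = cs$nanodisc)
    for (m in seq_len(n_molecules)) {
      sp <- seed + off; off <- off + 2
      prot <- simulate_pull(truth, seed = sp,
                            label = sprintf("%s_m%02d", nmc, m))
      dna <- simulate_dna_only(truth$dna, seed = sp + 1,
                               label = sprintf("dna_%s_m%02d", nmc, m))
      truth_rec <- list(construct = nmc, k = cs$k, x0 = cs$x0,
                        n_disordered = cs$n_disordered,
                        nanodisc = cs$nanodisc, L_dna = 1527.8,
                        P_dna = 40, chain_P = 0.6, seed = sp)
      files <- c(files,
                 put(prot, file.path(out_dir,
                                     sprintf("%s_m%02d.tsv", nmc, m)),
                     truth_rec),
                 put(dna, file.path(out_dir,
                                    sprintf("dna_%s_m%02d.tsv", nmc, m)),
                     c(truth_rec[c("L_dna", "P_dna")], seed = sp + 1)))
    }
  }
  for (i in seq_along(clamp_forces)) {
    f <- clamp_forces[i]
    tr <- simulate_clamp(f, seed = seed + 1000 + i)
    path <- file.path(out_dir, sprintf("clamp_%04.1fpN.tsv", f))
    files <- c(files, put(tr, path, attr(tr, "truth")))
  }
  invisible(files)
}
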