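#' Coupled ankyrin-repeat spring network
#'
#' Four ARDs of `n_AR` repeats each, joined at a contact site that splits
#' every ARD into an N-terminal segment of `split_N` repeats and a
#' C-terminal segment of `split_C` repeats. Each ARD has uniform
#' elasticity, so a segment of m repeats has stiffness `n_AR * ka / m`
#' (compliance proportional to length). The C-terminal segments of all
#' subunits act in parallel; the N-terminal segments of the pulled
#' subunits act in parallel; the two groups are in series.
#'
#' @param ka Stiffness of one isolated full-length ARD, pN/nm.
#' @param n_AR Repeats per ARD (default 29).
#' @param split_N Repeats N-terminal of the contact site (default 9).
#' @param split_C Repeats C-terminal of the contact site (default 20).
#' @param n_subunits Subunits in the complex (default 4).
#' @return An object of class `spring_network`.
#' @export
spring_network <- function(ka, n_AR = 29, split_N = 9, split_C = 20,
                           n_subunits = 4) {
  stopifnot(ka > 0, n_AR >= 1, split_N >= 1, split_C >= 1, n_subunits >= 1)
  if (split_N + split_C != n_AR) {
    stop("spring_network: split_N + split_C must equal n_AR")
  }
  structure(list(ka = ka, n_AR = n_AR, split_N = split_N,
                 split_C = split_C, n_subunits = n_subunits),
            class = "spring_network")
}

#' Effective stiffness when N subunits are pulled
#'
#' Series combination of the parallel pulled N-terminal segments with the
#' parallel C-terminal segments of all subunits, derived from the
#' segment-stiffness rule (never a hard-coded closed form). With the
#' default 29-repeat ARDs split 9/20 this reduces to
#' 29 N / (9 + 5 N) * ka.
#'
#' @param net A [spring_network()].
#' @param n_pulled Number of subunits being pulled (1..n_subunits).
#' @return Stiffness in pN/nm.
#' @export
effective_stiffness <- function(net, n_pulled) {
  stopifnot(inherits(net, "spring_network"))
  if (any(n_pulled < 1 | n_pulled > net$n_subunits |
          n_pulled != round(n_pulled))) {
    stop("effective_stiffness: n_pulled must be an integer in 1..",
         net$n_subunits)
  }
  k_seg_N <- net$n_AR * net$ka / net$split_N
  k_seg_C <- net$n_AR * net$ka / net$split_C
  kN <- n_pulled * k_seg_N
  kC <- net$n_subunits * k_seg_C
  kN * kC / (kN + kC)
}

#' Calibrate the isolated-ARD stiffness from a measured complex stiffness
#'
#' Solves for `ka` such that the network stiffness with `n_pulled`
#' subunits equals the measured value (e.g. the single-subunit pulling
#' measurement of 0.7 pN/nm).
#'
#' @param k_measured Measured complex stiffness, pN/nm.
#' @param n_pulled Subunits pulled in the measurement.
#' @inheritParams spring_network
#' @return The calibrated [spring_network()].
#' @export
calibrate_spring_network <- function(k_measured, n_pulled = 1, n_AR = 29,
                                     split_N = 9, split_C = 20,
                                     n_subunits = 4) {
  stopifnot(k_measured > 0)
  net1 <- spring_network(1, n_AR, split_N, split_C, n_subunits)
  ka <- k_measured / effective_stiffness(net1, n_pulled)
  spring_network(ka, n_AR, split_N, split_C, n_subunits)
}

#' Gating model configuration
#'
#' Parameters of the two-state (open/closed) Boltzmann gating model of a
#' stretched NompC complex, for fully folded or partially unfolded ARDs.
#' The structured portion is an elastic rod; the disordered N-terminal
#' chains of the tethered subunits load in parallel as worm-like chains;
#' opening adds the gating swing to the rod intrinsic length and the gate
#' energy to the state energy.
#'
#' @param k_fold Folded-spring (rod) stiffness, pN/nm (default 1.4, the
#'   four-subunit network value).
#' @param x0_closed_folded Rod intrinsic length, closed channel, folded
#'   ARDs, nm (default 20).
#' @param x0_closed_partial Same for partially unfolded ARDs (default
#'   14.5).
#' @param gating_swing Extension added on opening, nm (default 4.6).
#' @param V_open Gate energy of the open state, kBT (default 8).
#' @param disordered_residues_folded Disordered residues per subunit,
#'   folded state (default 123, the N-terminal tail).
#' @param disordered_residues_partial Disordered residues per pulled
#'   subunit, partially unfolded state (default 442 = 123 tail + 319 from
#'   the unfolded N-terminal ARs).
#' @param n_tethered Subunits tethered to the cytoskeleton (default 4).
#' @param chain_P Persistence length of disordered polypeptide, nm.
#' @return An object of class `gating_config`.
#' @export
gating_config <- function(k_fold = 1.4, x0_closed_folded = 20,
                          x0_closed_partial = 14.5, gating_swing = 4.6,
                          V_open = 8, disordered_residues_folded = 123,
                          disordered_residues_partial = 442,
                          n_tethered = 4, chain_P = 0.6) {
  stopifnot(k_fold > 0, x0_closed_folded >= 0, x0_closed_partial >= 0,
            gating_swing >= 0, disordered_residues_folded >= 0,
            disordered_residues_partial >= 0, n_tethered >= 1, chain_P > 0)
  structure(list(k_fold = k_fold, x0_closed_folded = x0_closed_folded,
                 x0_closed_partial = x0_closed_partial,
                 gating_swing = gating_swing, V_open = V_open,
                 disordered_residues_folded = disordered_residues_folded,
                 disordered_residues_partial = disordered_residues_partial,
                 n_tethered = n_tethered, chain_P = chain_P),
            class = "gating_config")
}

# tether of one model state
.state_tether <- function(open, partial, cfg, c) {
  x0 <- if (partial) cfg$x0_closed_partial else cfg$x0_closed_folded
  if (open) x0 <- x0 + cfg$gating_swing
  n_dis <- if (partial) cfg$disordered_residues_partial
           else cfg$disordered_residues_folded
  els <- list(elastic_rod(x0, cfg$k_fold))
  if (n_dis > 0) {
    els <- c(els, list(parallel_bundle(
      wlc(residues_to_contour(n_dis, c), cfg$chain_P), cfg$n_tethered)))
  }
  tether(els)
}

#' Energy and tension of a stretched NompC state
#'
#' Solves the tension F at total protein extension `x` for the given
#' channel/ARD state, then returns the state energy
#' E = F^2 / (2 k) + Eu + V: elastic energy of the folded rod, entropic
#' energy of the disordered chains, and the gate energy (V = 0 closed,
#' V = V_open kBT open). Satisfies dE/dx = F.
#'
#' @param x Protein extension, nm; vectorized; must be at or above the
#'   state's zero-force length.
#' @param open Channel open? (logical)
#' @param partial Partially unfolded ARDs? (logical)
#' @param cfg A [gating_config()].
#' @param c A [constants()] object.
#' @return A list of vectors: `energy_pNnm`, `tension_pN`.
#' @export
state_energy <- function(x, open = FALSE, partial = FALSE,
                         cfg = gating_config(), c = constants()) {
  th <- .state_tether(open, partial, cfg, c)
  F <- tether_force(x, th, c)
  n_dis <- if (partial) cfg$disordered_residues_partial
           else cfg$disordered_residues_folded
  Eu <- 0
  if (n_dis > 0) {
    chain <- wlc(residues_to_contour(n_dis, c), cfg$chain_P)
    xu <- wlc_extension(F / cfg$n_tethered, chain, c)
    Eu <- cfg$n_tethered * wlc_energy(xu, chain, c)
  }
  V <- if (open) cfg$V_open * c$kBT else 0
  list(energy_pNnm = F^2 / (2 * cfg$k_fold) + Eu + V, tension_pN = F)
}

#' Boltzmann channel-opening probability at a given extension
#'
#' P = 1 / (1 + exp(dE / kBT)) with dE the open-minus-closed state energy
#' difference at the same extension; nondecreasing in x.
#'
#' @inheritParams state_energy
#' @return Opening probability in (0, 1); vectorized over `x`.
#' @export
open_probability <- function(x, partial = FALSE, cfg = gating_config(),
                             c = constants()) {
  dE <- state_energy(x, TRUE, partial, cfg, c)$energy_pNnm -
    state_energy(x, FALSE, partial, cfg, c)$energy_pNnm
  1 / (1 + exp(dE / c$kBT))
}

#' Tension, stiffness and opening probability versus extension
#'
#' Evaluates, for the fully folded and (optionally) partially unfolded
#' arrangements, the closed- and open-state tensions, the
#' occupancy-averaged tension P F_open + (1 - P) F_closed, the
#' occupancy-averaged tether stiffness, and the opening probability on an
#' extension grid.
#'
#' @param x_grid Extensions, nm; each must be inside both states' domains
#'   for the arrangement evaluated.
#' @param cfg A [gating_config()].
#' @param c A [constants()] object.
#' @param arrangements Character subset of `c("folded", "partial")`.
#' @return A data frame: `arrangement`, `ext_nm`, `F_closed_pN`,
#'   `F_open_pN`, `F_avg_pN`, `stiffness_pN_per_nm`, `p_open`.
#' @export
gating_curves <- function(x_grid, cfg = gating_config(), c = constants(),
                          arrangements = c("folded", "partial")) {
  arrangements <- match.arg(arrangements, several.ok = TRUE)
  out <- lapply(arrangements, function(arr) {
    partial <- arr == "partial"
    closed <- state_energy(x_grid, FALSE, partial, cfg, c)
    open <- state_energy(x_grid, TRUE, partial, cfg, c)
    p <- 1 / (1 + exp((open$energy_pNnm - closed$energy_pNnm) / c$kBT))
    k_closed <- tether_stiffness(closed$tension_pN,
                                 .state_tether(FALSE, partial, cfg, c), c)
    k_open <- tether_stiffness(open$tension_pN,
                               .state_tether(TRUE, partial, cfg, c), c)
    data.frame(arrangement = arr, ext_nm = x_grid,
               F_closed_pN = closed$tension_pN,
               F_open_pN = open$tension_pN,
               F_avg_pN = p * open$tension_pN + (1 - p) * closed$tension_pN,
               stiffness_pN_per_nm = p * k_open + (1 - p) * k_closed,
               p_open = p)
  })
  do.call(rbind, out)
}

#' Midpoint (gating) force of the Boltzmann model
#'
#' Root-solves dE(x*) = 0 so that the opening probability is exactly 0.5,
#' and reports the average of the two branch tensions there (the gating
#' force), along with both branch tensions. In the chain-free limit this
#' equals V_open kBT / gating_swing analytically.
#'
#' @param cfg A [gating_config()].
#' @param c A [constants()] object.
#' @param partial Partially unfolded arrangement? (default FALSE)
#' @return A list: `x_star_nm`, `F_gating_pN` (average tension),
#'   `F_closed_pN`, `F_open_pN`, `p_open` (0.5 by construction).
#' @export
midpoint_force <- function(cfg = gating_config(), c = constants(),
                           partial = FALSE) {
  dE <- function(x) {
    state_energy(x, TRUE, partial, cfg, c)$energy_pNnm -
      state_energy(x, FALSE, partial, cfg, c)$energy_pNnm
  }
  rest_open <- tether_rest_length(.state_tether(TRUE, partial, cfg, c), c)
  lo <- rest_open + 1e-9
  if (dE(lo) <= 0) stop("midpoint_force: no root in domain (dE <= 0 at rest)")
  hi <- rest_open + 10
  for (i in 1:60) {
    if (dE(hi) < 0) break
    hi <- rest_open + (hi - rest_open) * 2
    if (hi - rest_open > 1e6) stop("midpoint_force: no root in domain")
  }
  x_star <- stats::uniroot(dE, c(lo, hi), tol = 1e-12)$root
  Fc <- state_energy(x_star, FALSE, partial, cfg, c)$tension_pN
  Fo <- state_energy(x_star, TRUE, partial, cfg, c)$tension_pN
  list(x_star_nm = x_star, F_gating_pN = (Fc + Fo) / 2,
       F_closed_pN = Fc, F_open_pN = Fo,
       p_open = open_probability(x_star, partial, cfg, c))
}

#' Force loading rate produced by an oscillatory stimulus
#'
#' A sinusoidal stimulus of the given frequency traverses the amplitude
#' once per half-period, so the average loading rate on a spring of the
#' given stiffness is stiffness * amplitude * 2 * frequency. The
#' instantaneous-peak convention 2 pi f A k is available via
#' `convention = "peak"`.
#'
#' @param frequency Stimulus frequency, Hz (> 0).
#' @param amplitude Peak extension change of the gating spring, nm (>= 0).
#' @param stiffness Spring stiffness, pN/nm (> 0).
#' @param convention `"half_period"` (default) or `"peak"`.
#' @param signif_digits If given, round the result to this many
#'   significant figures (e.g. 1 reproduces order-of-magnitude reporting).
#' @return Loading rate, pN/s.
#' @examples
#' loading_rate(1000, 1, 1.4)                    # 2800 pN/s
#' loading_rate(1000, 1, 1.4, signif_digits = 1) # 3000 pN/s (~3e3)
#' @export
loading_rate <- function(frequency, amplitude, stiffness,
                         convention = c("half_period", "peak"),
                         signif_digits = NULL) {
  convention <- match.arg(convention)
  stopifnot(frequency > 0, amplitude >= 0, stiffness > 0)
  r <- switch(convention,
              half_period = stiffness * amplitude * 2 * frequency,
              peak = stiffness * amplitude * 2 * pi * frequency)
  if (!is.null(signif_digits)) r <- signif(r, signif_digits)
  r
}

#' Bell-Evans rupture-force distribution at constant loading rate
#'
#' For a single barrier with zero-force rate `k0` and distance to the
#' transition state `x_dagger`, loaded at rate `r`, the survival
#' probability is
#' S(F) = exp\[-(k0 kBT)/(r x_dagger) (exp(F x_dagger / kBT) - 1)\];
#' the rupture-force density is -dS/dF and the analytic mode is
#' (kBT/x_dagger) log(r x_dagger / (k0 kBT)).
#'
#' @param k0 Zero-force rupture rate, 1/s (> 0).
#' @param x_dagger Distance to the barrier, nm (> 0).
#' @param r Loading rate, pN/s (> 0).
#' @param c A [constants()] object.
#' @return A list: `survival(F)`, `density(F)` (both vectorized
#'   functions of force in pN), `mean_pN` (by quadrature), `mode_pN`
#'   (closed form; `NA` when the most probable rupture force is at 0).
#' @export
bell_rupture_distribution <- function(k0, x_dagger, r, c = constants()) {
  stopifnot(k0 > 0, x_dagger > 0, r > 0)
  beta <- x_dagger / c$kBT
  a <- k0 / (r * beta)   # dimensionless rate/loading ratio
  survival <- function(F) exp(-a * (exp(pmin(beta * F, 700)) - 1))
  # evaluated in log space so extreme forces underflow to 0, not NaN
  density <- function(F) {
    exp(log(k0 / r) + beta * F - a * (exp(pmin(beta * F, 700)) - 1))
  }
  mode_arg <- 1 / a
  mode_pN <- if (mode_arg > 1) log(mode_arg) / beta else NA_real_
  upper <- (if (is.na(mode_pN)) 0 else mode_pN) + 30 / beta
  mean_pN <- stats::integrate(function(F) F * density(F), 0, upper,
                              rel.tol = 1e-10)$value
  list(survival = survival, density = density,
       mean_pN = mean_pN, mode_pN = mode_pN)
}
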