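#' Detect discrete extension transitions (rips) in a filtered trajectory
#'
#' Scans a box-filtered trace for abrupt extension changes: the jump is
#' measured between linear-drift-corrected baseline windows before and
#' after each candidate point, so the slow ramp of a pulling experiment
#' does not trigger detections. Events are classified by sign and phase:
#' positive jumps are unfolding; negative jumps are insertions during a
#' pull (e.g. strand displacement) and refolding during relaxation.
#'
#' @param trace A filtered [fec_trace()].
#' @param jump_threshold Minimum extension change, nm (default 3 nm; the
#'   smallest reported discrete features are ~5 nm and the post-filter
#'   noise floor ~1-2 nm).
#' @param max_dwell Maximum transition duration, s (default 20 ms).
#' @param baseline Baseline window used on each side of a candidate, s
#'   (default 0.2 s; long baselines keep the jump statistic's noise floor
#'   several-fold below the threshold).
#' @param settle Extra guard time around the transition so that the box
#'   filter's smearing of the step does not bias the measured jump, s.
#' @return A data frame of events (possibly 0 rows): `time_s`,
#'   `force_at_rip_pN` (pre-jump force), `extension_jump_nm` (signed),
#'   `direction` (unfolding/refolding/insertion), ordered by time.
#' @export
detect_transitions <- function(trace, jump_threshold = 3, max_dwell = 0.02,
                               baseline = 0.2, settle = 0.08) {
  stopifnot(inherits(trace, "fec_trace"), jump_threshold > 0)
  d <- trace$data
  rate <- trace$sampling_rate
  m_b <- max(2L, round(baseline * rate))
  m_g <- max(1L, round((max_dwell + settle) * rate))
  n <- nrow(d)
  empty <- data.frame(time_s = numeric(0), force_at_rip_pN = numeric(0),
                      extension_jump_nm = numeric(0),
                      direction = character(0))
  m_s <- max(2L, round(2 * rate))    # secant span for local drift slopes
  if (n < 2 * m_b + m_g + 2 * m_s + 2) return(empty)
  cx <- cumsum(c(0, d$extension_nm))
  cf <- cumsum(c(0, d$force_pN))
  # candidate anchors i: pre window (i-m_b, i], post window (i+m_g, i+m_g+m_b];
  # anchors too close to the edges for a full drift-slope support are skipped
  i <- seq.int(m_b + m_s, n - m_g - m_b - m_s)
  pre_x <- (cx[i + 1] - cx[i + 1 - m_b]) / m_b
  post_x <- (cx[i + 1 + m_g + m_b] - cx[i + 1 + m_g]) / m_b
  pre_f <- (cf[i + 1] - cf[i + 1 - m_b]) / m_b
  # local drift from 2-s secant slopes on either side of the candidate;
  # the smaller-magnitude side is used, so one nearby rip cannot bias the
  # correction while the noise stays far below the jump threshold
  xv <- d$extension_nm
  sL <- (xv[i] - xv[i - m_s]) / (m_s / rate)
  sR <- (xv[i + m_g + m_b + m_s] - xv[i + m_g + m_b]) / (m_s / rate)
  slope_i <- ifelse(abs(sL) < abs(sR), sL, sR)
  span_s <- (m_g + m_b) / rate                          # window-centre gap
  J <- post_x - pre_x - slope_i * span_s
  hit <- abs(J) >= jump_threshold
  if (!any(hit)) return(empty)
  # group contiguous hits (gaps <= m_b samples) into single events
  hidx <- which(hit)
  brk <- c(0, which(diff(hidx) > m_b), length(hidx))
  ev <- lapply(seq_len(length(brk) - 1), function(g) {
    run <- hidx[(brk[g] + 1):brk[g + 1]]
    best <- run[which.max(abs(J[run]))]
    anchor <- i[best]
    data.frame(time_s = d$time_s[anchor + round(m_g / 2)],
               force_at_rip_pN = pre_f[best],
               extension_jump_nm = J[best])
  })
  ev <- do.call(rbind, ev)
  ev$direction <- ifelse(ev$extension_jump_nm > 0, "unfolding",
                         if (trace$phase == "relax") "refolding" else "insertion")
  ev[order(ev$time_s), , drop = FALSE]
}

#' Map contour-length gains to unfolded residue and ankyrin-repeat counts
#'
#' Residue counts are the gains divided by the per-residue contour rise
#' (0.365 nm), rounded (half to even); repeat counts divide by 33
#' residues per AR. Gains matching the three long-lived intermediates
#' (about 10, 20 and 29 ARs) within `tol_AR` repeats get labels I1/I2/I3;
#' zero gain is the folded state F_A.
#'
#' @param contour_gains Non-negative contour-length gains, nm.
#' @param c A [constants()] object (supplies `aa_rise` and
#'   `residues_per_AR`).
#' @param targets Named AR counts for the labelled states.
#' @param tol_AR Label tolerance in repeats (default 2).
#' @return A data frame: `state_label`, `contour_gain_nm`,
#'   `unfolded_residues`, `unfolded_ARs`.
#' @export
assign_states <- function(contour_gains, c = constants(),
                          targets = c(I1 = 10, I2 = 20, I3 = 29),
                          tol_AR = 2) {
  if (any(contour_gains < 0)) {
    stop("assign_states: contour gains must be >= 0")
  }
  residues <- round(contour_gains / c$aa_rise)
  ars <- round(residues / c$residues_per_AR)
  label <- rep("custom", length(ars))
  label[ars == 0] <- "F_A"
  for (nmt in names(targets)) {
    label[abs(ars - targets[[nmt]]) <= tol_AR & ars > 0] <- nmt
  }
  data.frame(state_label = label, contour_gain_nm = contour_gains,
             unfolded_residues = residues, unfolded_ARs = ars)
}

#' Rupture-force statistics over molecules
#'
#' @param events A list with one event data frame (as returned by
#'   [detect_transitions()]) per molecule, or a single data frame for one
#'   molecule.
#' @param which `"first"` keeps only each molecule's earliest unfolding
#'   event (the initial ARD unfolding); `"all"` keeps every unfolding
#'   event.
#' @param bin_width Histogram bin width, pN.
#' @return A list: `mean_pN`, `sd_pN` (sample SD over the selected
#'   forces; `NA` with `single_event = TRUE` when only one force is
#'   available), `forces_pN`, and `histogram` (breaks/counts).
#' @export
unfolding_force_stats <- function(events, which = c("first", "all"),
                                  bin_width = 0.5) {
  which <- match.arg(which)
  if (is.data.frame(events)) events <- list(events)
  forces <- unlist(lapply(events, function(ev) {
    ev <- ev[ev$direction == "unfolding", , drop = FALSE]
    if (nrow(ev) == 0) {
      if (which == "first") {
        stop("unfolding_force_stats: a molecule has no unfolding event")
      }
      return(numeric(0))
    }
    if (which == "first") ev$force_at_rip_pN[which.min(ev$time_s)]
    else ev$force_at_rip_pN
  }))
  if (length(forces) == 0) {
    stop("unfolding_force_stats: no unfolding events supplied")
  }
  breaks <- seq(floor(min(forces) / bin_width) * bin_width,
                ceiling(max(forces) / bin_width) * bin_width + bin_width,
                by = bin_width)
  h <- graphics::hist(forces, breaks = breaks, plot = FALSE)
  list(mean_pN = mean(forces),
       sd_pN = if (length(forces) > 1) stats::sd(forces) else NA_real_,
       single_event = length(forces) == 1,
       forces_pN = forces,
       histogram = list(breaks = h$breaks, counts = h$counts))
}

#' State occurrence profile over a cohort of analyzed FECs
#'
#' Normalized frequency with which contour-gain values (states) are
#' visited across molecules, on a uniform contour-gain grid; the profile
#' sums to 1.
#'
#' @param gains_per_molecule List with one numeric vector of visited
#'   contour gains (nm) per molecule.
#' @param grid_width Grid cell width in nm.
#' @return A data frame `contour_gain_nm` (cell centers), `probability`.
#' @export
state_occurrence_profile <- function(gains_per_molecule, grid_width = 10) {
  if (!is.list(gains_per_molecule) || length(gains_per_molecule) == 0) {
    stop("state_occurrence_profile: need a non-empty list of gain vectors")
  }
  all_gains <- unlist(gains_per_molecule)
  stopifnot(all(all_gains >= 0))
  nmax <- ceiling((max(all_gains) + grid_width) / grid_width)
  counts <- numeric(nmax)
  for (g in gains_per_molecule) {
    cells <- unique(pmin(floor(g / grid_width), nmax - 1))  # once per molecule
    counts[cells + 1] <- counts[cells + 1] + 1
  }
  data.frame(contour_gain_nm = (seq_len(nmax) - 0.5) * grid_width,
             probability = counts / sum(counts))
}

#' Classify a repull as refolded or misfolded
#'
#' A repulled molecule is called refolded when its binned FEC overlaps the
#' initial pull: RMS extension deviation over the criterion force range at
#' most `tol` (default 2 nm over 2-6 pN, below the smallest inter-state
#' extension difference there).
#'
#' @param first_pull,repull [binned_fec()] curves binned identically.
#' @param criterion_range Force range `c(lo, hi)` in pN.
#' @param tol RMS tolerance in nm.
#' @return A list: `classification` ("refolded"/"misfolded"),
#'   `rms_deviation_nm`, `n_bins`.
#' @export
classify_refolding <- function(first_pull, repull,
                               criterion_range = c(2, 6), tol = 2) {
  stopifnot(inherits(first_pull, "binned_fec"), inherits(repull, "binned_fec"))
  m <- .match_bins(first_pull, repull)
  keep <- m$centers >= criterion_range[1] & m$centers <= criterion_range[2]
  if (!any(keep)) {
    stop("classify_refolding: no shared bins in the criterion force range")
  }
  dev <- first_pull$bins$mean_ext_nm[m$ia][keep] -
    repull$bins$mean_ext_nm[m$ib][keep]
  rms <- sqrt(mean(dev^2))
  list(classification = if (rms <= tol) "refolded" else "misfolded",
       rms_deviation_nm = rms, n_bins = sum(keep))
}
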