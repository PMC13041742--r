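#' Analyze a pulling FEC: rips, branches, contour gains, state labels
#'
#' The full single-trace analysis behind the unfolding-intermediate
#' assignment: box-filters the protein-DNA and DNA-only traces, detects
#' rips, splits the protein trace into branches between rips, force-bins
#' every branch, fits all branches and the DNA curve simultaneously with
#' the series tether model (shared handle and rod parameters, one free
#' unfolded contour length per branch), and converts the per-branch
#' contour gains into unfolded-residue and ankyrin-repeat counts.
#'
#' @param protein_trace,dna_trace Raw [fec_trace()]s of the protein-DNA
#'   and DNA-only tethers.
#' @param n_disordered_init Disordered residues already unfolded in the
#'   first branch (the N-terminal tail).
#' @param nanodisc Rigid offset, nm (held fixed in the fit).
#' @param L_dna DNA handle contour length, nm (held fixed).
#' @param window Boxcar window, s.
#' @param bin_width,bin_range Force-binning parameters, pN.
#' @param guard Time excluded on each side of a rip when forming
#'   branches, s.
#' @param min_bins Branches with fewer occupied bins are dropped.
#' @param jump_threshold,max_dwell Passed to [detect_transitions()].
#' @param c A [constants()] object.
#' @return A list: `events` (rip table), `fit` (the [fit_fec_global()]
#'   result), `states` (the [assign_states()] table, one row per kept
#'   branch), `branches` (list of [binned_fec()]).
#' @export
analyze_pull_fec <- function(protein_trace, dna_trace,
                             n_disordered_init = 123, nanodisc = 5,
                             L_dna = 1527.8, window = 0.1, bin_width = 0.2,
                             bin_range = c(0.5, 20), guard = 0.4,
                             min_bins = 5, jump_threshold = 3,
                             max_dwell = 0.02, c = constants()) {
  pf <- boxcar_filter(protein_trace, window)
  df <- boxcar_filter(dna_trace, window)
  events <- detect_transitions(pf, jump_threshold, max_dwell)
  dna_fec <- bin_by_force(df, bin_width, bin_range)
  tt <- pf$data$time_s
  cuts <- c(min(tt) - 1, events$time_s, max(tt) + 1)
  branches <- list()
  jumps <- c(0, cumsum(events$extension_jump_nm))
  kept_jump <- numeric(0)
  for (b in seq_len(length(cuts) - 1)) {
    keep <- tt > cuts[b] + guard & tt < cuts[b + 1] - guard
    if (sum(keep) < 10) next
    seg <- fec_trace(pf$data$time_s[keep], pf$data$trap_sep_nm[keep],
                     pf$data$force_pN[keep], pf$data$extension_nm[keep],
                     label = paste0(pf$label, "_b", b), phase = pf$phase,
                     sampling_rate = pf$sampling_rate)
    fec <- tryCatch(bin_by_force(seg, bin_width, bin_range),
                    error = function(e) NULL)
    if (is.null(fec) || nrow(fec$bins) < min_bins) next
    branches[[length(branches) + 1]] <- fec
    kept_jump <- c(kept_jump, jumps[b])
  }
  if (length(branches) == 0) {
    stop("analyze_pull_fec: no branch has enough bins to fit")
  }
  L0 <- residues_to_contour(n_disordered_init, c)
  # initial contour guess from the cumulative extension jumps: at the
  # unfolding forces (~7 pN) an unfolded chain is roughly half extended
  u7 <- wlc_extension(7, wlc(1, 0.6), c)
  L_init <- pmax(L0 + kept_jump / u7, 1)
  fit <- fit_fec_global(
    dna_fec, branches,
    start = list(P_dna = 40, P_chain = 0.6, x0 = 15, k = 0.5,
                 L_unf = L_init),
    fixed = list(L_dna = L_dna, offset_nm = nanodisc), c = c)
  # gains are referenced to the first (least-unfolded) branch's fitted
  # contour: correlated errors in the shared rod/persistence parameters
  # cancel between branches, unlike a reference to the nominal tail length
  gains <- pmax(fit$contour_gain_nm, 0)
  list(events = events, fit = fit,
       states = assign_states(gains, c), branches = branches)
}
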