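# Shared fixture builders: everything is generated in code at test time.

cst <- constants()

# A trace whose force ladder sits exactly on the given values (held for
# `dwell` samples each) with extensions on the model curve; binning such a
# trace reproduces the model exactly, isolating pipeline arithmetic from
# binning/smearing effects.
trace_from_model <- function(tether_obj, forces, dwell = 5, rate = 100,
                             noise_ext = 0, label = "model", c = cst) {
  F <- rep(forces, each = dwell)
  x <- tether_extension(F, tether_obj, c)
  if (noise_ext > 0) x <- x + stats::rnorm(length(x), 0, noise_ext)
  tt <- seq_along(F) / rate
  fec_trace(tt, x + F / 0.15, F, x, label = label, sampling_rate = rate)
}

# Binned FEC evaluated exactly on the model at given bin centers.
binned_from_model <- function(tether_obj, centers, sd = 0, n = 100, c = cst) {
  x <- tether_extension(centers, tether_obj, c)
  if (sd > 0) x <- x + stats::rnorm(length(x), 0, sd)
  binned_fec(centers, x, rep(sd, length(centers)), rep(n, length(centers)))
}

# Default WT-like truth used by several pipeline tests.
wt_truth <- function(unfolded_residues = 123, ...) {
  sim_truth(dna = wlc(1527.8, 40), rod = elastic_rod(20, 0.7),
            unfolded_residues = unfolded_residues, nanodisc = 5, ...)
}

# Independent brute-force series solver: per-element extensions computed
# from each element's own law with scalar uniroot, never through the
# package's vectorized composition path.
brute_extension <- function(elements, F, c = cst) {
  one <- function(el, f) {
    if (inherits(el, "wlc")) {
      if (f == 0) return(0)
      g <- function(x) (c$kBT / el$P) *
        (1 / (4 * (1 - x / el$L)^2) + x / el$L - 0.25) - f
      stats::uniroot(g, c(0, el$L * (1 - 1e-12)), tol = 1e-12)$root
    } else if (inherits(el, "elastic_rod")) {
      el$x0 + f / el$k
    } else if (inherits(el, "rigid_offset")) {
      el$length
    } else if (inherits(el, "parallel_bundle")) {
      one(el$element, f / el$n)
    } else stop("unknown element")
  }
  sum(vapply(elements, one, numeric(1), f = F))
}
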