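#' Force-binned force-extension curve
#'
#' @param force_pN Bin centers, pN, strictly increasing on a uniform grid.
#' @param mean_ext_nm Per-bin mean extension, nm.
#' @param sd_nm Per-bin spread of extension (population SD convention).
#' @param n Per-bin sample count (>= 1).
#' @param n_molecules Number of molecules pooled into the bins.
#' @return An object of class `binned_fec`.
#' @export
binned_fec <- function(force_pN, mean_ext_nm, sd_nm, n, n_molecules = 1L) {
  stopifnot(length(force_pN) >= 1,
            length(mean_ext_nm) == length(force_pN),
            length(sd_nm) == length(force_pN),
            length(n) == length(force_pN))
  if (any(diff(force_pN) <= 0)) {
    stop("binned_fec: bin centers must be strictly increasing")
  }
  if (any(n < 1)) stop("binned_fec: every reported bin needs n >= 1")
  structure(list(
    bins = data.frame(force_pN = force_pN, mean_ext_nm = mean_ext_nm,
                      sd_nm = sd_nm, n = as.integer(n)),
    n_molecules = as.integer(n_molecules),
    sd_convention = "population"
  ), class = "binned_fec")
}

#' @export
print.binned_fec <- function(x, ...) {
  cat("binned_fec: ", nrow(x$bins), " bins, force ",
      min(x$bins$force_pN), "-", max(x$bins$force_pN), " pN, ",
      x$n_molecules, " molecule(s)\n", sep = "")
  invisible(x)
}

#' Boxcar (moving-average) filter of a trajectory
#'
#' Centered moving average of force, extension and trap separation over a
#' time window; the edges without full support are dropped, so the trace
#' shrinks by roughly one window.
#'
#' @param trace A [fec_trace()].
#' @param window Averaging window in seconds (default 0.1 s; the
#'   experimental range is 50-200 ms). Must cover at least 2 samples and at
#'   most the trace duration.
#' @return A filtered [fec_trace()].
#' @export
boxcar_filter <- function(trace, window = 0.1) {
  stopifnot(inherits(trace, "fec_trace"))
  m <- round(window * trace$sampling_rate)
  dur <- max(trace$data$time_s) - min(trace$data$time_s)
  if (m < 2) stop("boxcar_filter: window must span at least 2 samples")
  if (window > dur) stop("boxcar_filter: window exceeds trace duration")
  kern <- rep(1 / m, m)
  sm <- function(v) as.numeric(stats::filter(v, kern, sides = 2))
  d <- trace$data
  f <- sm(d$force_pN); x <- sm(d$extension_nm); s <- sm(d$trap_sep_nm)
  keep <- which(!is.na(f) & !is.na(x))
  fec_trace(d$time_s[keep], s[keep], f[keep], x[keep],
            label = trace$label, phase = trace$phase,
            sampling_rate = trace$sampling_rate)
}

#' Discretize a trajectory into uniform force bins
#'
#' Per-bin mean, population SD and count of extension over the samples
#' whose (filtered) force falls in \[lo, hi) of each bin; empty bins are
#' omitted.
#'
#' @param trace A [fec_trace()] (typically after [boxcar_filter()]).
#' @param bin_width Bin size, pN (> 0). Default 0.2 pN.
#' @param range Force range `c(lo, hi)` covered by the bins,
#'   default 0.5-20 pN.
#' @return A [binned_fec()].
#' @export
bin_by_force <- function(trace, bin_width = 0.2, range = c(0.5, 20)) {
  stopifnot(inherits(trace, "fec_trace"), bin_width > 0)
  if (range[2] <= range[1]) stop("bin_by_force: empty force range")
  f <- trace$data$force_pN
  x <- trace$data$extension_nm
  idx <- floor((f - range[1]) / bin_width + 1e-9)
  nbin <- ceiling((range[2] - range[1]) / bin_width - 1e-9)
  ok <- idx >= 0 & idx < nbin
  if (!any(ok)) stop("bin_by_force: no samples fall inside the force range")
  idx <- idx[ok]; x <- x[ok]
  n <- tabulate(idx + 1L, nbins = nbin)
  sx <- rowsum(x, idx)[, 1]
  occupied <- sort(unique(idx))
  nn <- n[occupied + 1L]
  mean_x <- sx / nn
  # centered second pass: numerically exact population variance
  dev <- x - mean_x[match(idx, occupied)]
  var_x <- rowsum(dev^2, idx)[, 1] / nn
  binned_fec(force_pN = range[1] + (occupied + 0.5) * bin_width,
             mean_ext_nm = mean_x, sd_nm = sqrt(var_x), n = nn)
}

.match_bins <- function(a, b) {
  # shared centers (bitwise-comparable after rounding to sub-pico pN)
  ka <- round(a$bins$force_pN, 9); kb <- round(b$bins$force_pN, 9)
  shared <- intersect(ka, kb)
  list(ia = match(shared, ka), ib = match(shared, kb), centers = shared)
}

#' Differential structured extension (toehold subtraction)
#'
#' Per shared force bin, subtracts from the protein-DNA tether extension
#' the DNA-only extension, the worm-like-chain extension of the disordered
#' polypeptide, and the rigid nanodisc offset, leaving the extension of the
#' structured protein portion. SDs are propagated in quadrature.
#'
#' @param protein_fec,dna_fec [binned_fec()] curves of the protein-DNA and
#'   DNA-only tethers (intersection of bin centers is used).
#' @param n_disordered Disordered residues whose WLC extension is
#'   subtracted (0 for none).
#' @param nanodisc A [rigid_offset()] or a length in nm (0 for none).
#' @param chain_P Persistence length of the disordered chain, nm.
#' @param c A [constants()] object.
#' @return A [binned_fec()] of the structured-portion extension.
#' @export
differential_structured_extension <- function(protein_fec, dna_fec,
                                              n_disordered = 0,
                                              nanodisc = 0,
                                              chain_P = 0.6,
                                              c = constants()) {
  stopifnot(inherits(protein_fec, "binned_fec"),
            inherits(dna_fec, "binned_fec"))
  m <- .match_bins(protein_fec, dna_fec)
  if (length(m$centers) == 0) {
    stop("differential_structured_extension: the two curves share no bins")
  }
  off <- if (inherits(nanodisc, "rigid_offset")) nanodisc$length else nanodisc
  Fb <- m$centers
  chain_ext <- if (n_disordered > 0) {
    wlc_extension(Fb, wlc(residues_to_contour(n_disordered, c), chain_P), c)
  } else 0
  pa <- protein_fec$bins[m$ia, ]; db <- dna_fec$bins[m$ib, ]
  binned_fec(force_pN = Fb,
             mean_ext_nm = pa$mean_ext_nm - db$mean_ext_nm - chain_ext - off,
             sd_nm = sqrt(pa$sd_nm^2 + db$sd_nm^2),
             n = pmin(pa$n, db$n),
             n_molecules = protein_fec$n_molecules)
}

#' Pool binned curves from several molecules
#'
#' Per-bin pooled mean and population SD over all samples of all
#' molecules, computed exactly from the per-molecule moments.
#'
#' @param fecs A list of [binned_fec()] objects (>= 1).
#' @return A [binned_fec()] with `n_molecules` set to the number pooled.
#' @export
pool_molecules <- function(fecs) {
  stopifnot(is.list(fecs), length(fecs) >= 1)
  for (f in fecs) stopifnot(inherits(f, "binned_fec"))
  if (length(fecs) == 1) return(fecs[[1]])
  all_centers <- sort(unique(unlist(lapply(fecs, function(f)
    round(f$bins$force_pN, 9)))))
  k <- length(all_centers)
  n <- s1 <- s2 <- numeric(k)
  for (f in fecs) {
    i <- match(round(f$bins$force_pN, 9), all_centers)
    n[i] <- n[i] + f$bins$n
    s1[i] <- s1[i] + f$bins$n * f$bins$mean_ext_nm
    s2[i] <- s2[i] + f$bins$n * (f$bins$sd_nm^2 + f$bins$mean_ext_nm^2)
  }
  mean_x <- s1 / n
  var_x <- pmax(s2 / n - mean_x^2, 0)
  binned_fec(all_centers, mean_x, sqrt(var_x), n,
             n_molecules = sum(vapply(fecs, function(f) f$n_molecules,
                                      integer(1))))
}

#' Linear stiffness fit of a structured-extension curve
#'
#' Fits the linear force-extension law F = k (x - x0) over a stated force
#' range (default 1-7 pN, the folded-state region below the first
#' unfolding force). Because the curve is binned by force, force is the
#' (nearly noise-free) predictor and extension the noisy response, so the
#' regression is x = x0 + F / k, weighted by the per-bin sample counts;
#' k is the reciprocal slope (regressing F on x instead would attenuate
#' stiff springs whose extension change is comparable to the bin noise).
#'
#' @param fec A [binned_fec()] of the structured protein extension.
#' @param force_range `c(lo, hi)` in pN; only bins inside are fit.
#' @return An object of class `stiffness_fit` with fields `k` (pN/nm),
#'   `x0` (nm), `k_sem` (delta-method SE of k), `force_range`,
#'   `n_molecules`, `converged`. A fit with fewer than 3 bins or a
#'   non-positive slope is flagged (`converged = FALSE`), never silently
#'   clamped.
#' @export
fit_stiffness_linear <- function(fec, force_range = c(1, 7)) {
  stopifnot(inherits(fec, "binned_fec"), length(force_range) == 2)
  sel <- fec$bins$force_pN >= force_range[1] &
         fec$bins$force_pN <= force_range[2]
  out <- structure(list(k = NA_real_, x0 = NA_real_, k_sem = NA_real_,
                        force_range = force_range,
                        n_molecules = fec$n_molecules, converged = FALSE),
                   class = "stiffness_fit")
  if (sum(sel) < 3) {
    out$reason <- "fewer than 3 bins in the force range"
    return(out)
  }
  fit <- stats::lm(mean_ext_nm ~ force_pN, data = fec$bins[sel, ],
                   weights = fec$bins$n[sel])
  b <- unname(stats::coef(fit)[2])     # compliance, nm/pN
  if (!is.finite(b) || b <= 0) {
    out$reason <- "non-positive fitted compliance"
    return(out)
  }
  out$k <- 1 / b
  out$x0 <- unname(stats::coef(fit)[1])
  out$k_sem <- suppressWarnings(summary(fit)$coefficients[2, 2]) / b^2
  out$converged <- TRUE
  out
}

#' @export
print.stiffness_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("stiffness_fit: k = %.3g +/- %.2g pN/nm, x0 = %.3g nm (%g-%g pN, N = %d)\n",
                x$k, x$k_sem, x$x0, x$force_range[1], x$force_range[2],
                x$n_molecules))
  } else {
    cat("stiffness_fit: failed (", x$reason, ")\n", sep = "")
  }
  invisible(x)
}

#' Simultaneous fit of DNA-only and protein-DNA force-extension curves
#'
#' Weighted least squares jointly fitting the DNA handle WLC and the
#' series tether (DNA + elastic rod + unfolded chain + rigid offset) to
#' force-binned curves. Free parameters are any subset of the DNA
#' persistence length `P_dna`, the polypeptide persistence length
#' `P_chain`, the rod intrinsic length `x0` and stiffness `k`, and one
#' unfolded contour length `L_unf<j>` per tether branch; everything in
#' `fixed` is held.
#'
#' @param dna_fec [binned_fec()] of the DNA-only tether.
#' @param tether_fecs A [binned_fec()] or list of them, one per FEC branch
#'   (states differing in unfolded contour length).
#' @param start Named list of starting values for the free parameters;
#'   `L_unf` may be a vector with one entry per branch.
#' @param fixed Named list of fixed quantities; must include the DNA
#'   contour length `L_dna` (nm) and may fix `offset_nm` (rigid offset,
#'   default 0) and any parameter omitted from `start`.
#' @param c A [constants()] object.
#' @return A list with `par` (estimates), `se` (standard errors),
#'   `unfolded_residues` (per branch, from `L_unf / aa_rise`),
#'   `contour_gain_nm` (per branch, relative to the first branch),
#'   `converged`, and `rss`. Non-convergence raises an error carrying the
#'   last residual norm.
#' @export
fit_fec_global <- function(dna_fec, tether_fecs = NULL,
                           start = list(P_dna = 40, P_chain = 0.6,
                                        x0 = 20, k = 0.7, L_unf = 45),
                           fixed = list(L_dna = 1527.8, offset_nm = 0),
                           c = constants()) {
  stopifnot(inherits(dna_fec, "binned_fec"))
  if (inherits(tether_fecs, "binned_fec")) tether_fecs <- list(tether_fecs)
  if (is.null(tether_fecs)) tether_fecs <- list()
  nb <- length(tether_fecs)
  if (is.null(fixed$offset_nm)) fixed$offset_nm <- 0
  if (is.null(fixed$L_dna) && is.null(start$L_dna)) {
    stop("fit_fec_global: DNA contour length L_dna must be given")
  }
  # flatten L_unf vector into per-branch parameters
  par0 <- list()
  for (nmp in names(start)) {
    if (nmp == "L_unf") {
      lu <- rep_len(start$L_unf, nb)
      for (j in seq_len(nb)) par0[[paste0("L_unf", j)]] <- lu[j]
    } else par0[[nmp]] <- start[[nmp]]
  }
  par0 <- unlist(par0)
  getp <- function(p, nmq, j = NULL) {
    if (!is.null(j)) {
      key <- paste0(nmq, j)
      if (key %in% names(p)) return(p[[key]])
      lu <- fixed$L_unf
      if (!is.null(lu)) return(rep_len(lu, nb)[j])
      stop("fit_fec_global: no value for ", key)
    }
    if (nmq %in% names(p)) p[[nmq]] else fixed[[nmq]]
  }
  wts <- function(fec) {
    s <- fec$bins$sd_nm / sqrt(fec$bins$n)
    pos <- is.finite(s) & s > 0
    if (!any(pos)) return(rep(1, length(s)))
    s[!pos] <- stats::median(s[pos])
    1 / s
  }
  w_dna <- wts(dna_fec); w_br <- lapply(tether_fecs, wts)
  resid_fn <- function(p) {
    p <- abs(p)  # all mechanical parameters are positive
    P_dna <- getp(p, "P_dna"); P_chain <- getp(p, "P_chain")
    x0 <- getp(p, "x0"); k <- getp(p, "k"); L_dna <- getp(p, "L_dna")
    dna_chain <- wlc(L_dna, P_dna)
    r <- w_dna * (dna_fec$bins$mean_ext_nm -
                  wlc_extension(dna_fec$bins$force_pN, dna_chain, c))
    for (j in seq_len(nb)) {
      fec <- tether_fecs[[j]]
      Fb <- fec$bins$force_pN
      L_unf <- getp(p, "L_unf", j)
      xu <- if (L_unf > 0) wlc_extension(Fb, wlc(L_unf, P_chain), c) else 0
      pred <- wlc_extension(Fb, dna_chain, c) + x0 + Fb / k + xu +
        fixed$offset_nm
      r <- c(r, w_br[[j]] * (fec$bins$mean_ext_nm - pred))
    }
    r
  }
  fit <- minpack.lm::nls.lm(par = par0, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-12, ptol = 1e-12))
  if (fit$info %in% c(0, 5, 9)) {
    stop("fit_fec_global: did not converge (", fit$message,
         "); last residual norm ", sqrt(sum(fit$fvec^2)))
  }
  est <- abs(fit$par)
  sm <- summary(fit)
  se <- sm$coefficients[, "Std. Error"]
  names(se) <- names(est)
  L_unf <- vapply(seq_len(nb), function(j) getp(as.list(est), "L_unf", j),
                  numeric(1))
  list(par = as.list(est), se = as.list(se),
       unfolded_residues = L_unf / c$aa_rise,
       contour_gain_nm = L_unf - L_unf[1],
       converged = TRUE, rss = sum(fit$fvec^2))
}
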