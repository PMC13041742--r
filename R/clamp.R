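#' Probability density of extension in a force-clamp trace
#'
#' Normalized histogram density over extension (integrates to 1).
#'
#' @param trace A [clamp_trace()].
#' @param bin_width Histogram bin width, nm (> 0).
#' @return A data frame `extension_nm` (bin centers), `density` (1/nm),
#'   with attribute `bin_width`.
#' @export
extension_density <- function(trace, bin_width = 0.25) {
  stopifnot(inherits(trace, "clamp_trace"), bin_width > 0)
  x <- trace$data$extension_nm
  if (length(x) == 0) stop("extension_density: empty trace")
  breaks <- seq(floor(min(x) / bin_width) * bin_width,
                ceiling(max(x) / bin_width) * bin_width + bin_width,
                by = bin_width)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  out <- data.frame(extension_nm = h$mids, density = h$density)
  attr(out, "bin_width") <- bin_width
  out
}

#' Fit a sum of two Gaussians to an extension density
#'
#' Weighted least squares of the mixture
#' w N(mu_high, sigma_high) + (1 - w) N(mu_low, sigma_low) against a
#' binned density, initialized from the two most prominent well-separated
#' modes. The result is canonicalized so `mu_high > mu_low`; a density
#' whose two candidate modes are closer than one bin is flagged as
#' degenerate.
#'
#' @param density A data frame from [extension_density()] (columns
#'   `extension_nm`, `density`) with at least 10 occupied bins.
#' @return An object of class `two_gaussian_fit`: `mu_low`, `mu_high`,
#'   `sigma_low`, `sigma_high`, `weight_high`, `separation_nm`,
#'   `converged`, `degenerate`.
#' @export
fit_two_gaussians <- function(density) {
  stopifnot(is.data.frame(density),
            all(c("extension_nm", "density") %in% names(density)))
  occ <- density$density > 0
  if (sum(occ) < 10) {
    stop("fit_two_gaussians: need at least 10 occupied bins")
  }
  x <- density$extension_nm
  y <- density$density
  bw <- if (!is.null(attr(density, "bin_width"))) attr(density, "bin_width")
        else stats::median(diff(x))
  out <- structure(list(mu_low = NA_real_, mu_high = NA_real_,
                        sigma_low = NA_real_, sigma_high = NA_real_,
                        weight_high = NA_real_, separation_nm = NA_real_,
                        converged = FALSE, degenerate = FALSE),
                   class = "two_gaussian_fit")
  # candidate initializations: (a) the two most prominent local maxima,
  # (b) mass quantiles of the distribution; the lower-RSS fit wins, so a
  # shoulder mistaken for a mode cannot trap the optimizer
  inits <- list()
  ys <- stats::filter(y, rep(1 / 3, 3), sides = 2)
  ys[is.na(ys)] <- y[is.na(ys)]
  lm_i <- which(diff(sign(diff(ys))) < 0) + 1
  lm_i <- lm_i[ys[lm_i] > 0.05 * max(ys)]
  lm_i <- lm_i[order(-ys[lm_i])]
  if (length(lm_i) >= 2) {
    i2 <- lm_i[-1][abs(x[lm_i[-1]] - x[lm_i[1]]) > 2 * bw]
    if (length(i2)) {
      inits[[length(inits) + 1]] <- sort(c(x[lm_i[1]], x[i2[1]]))
    }
  }
  cdf <- cumsum(y) / sum(y)
  q_at <- function(p) x[which.max(cdf >= p)]
  q_init <- c(q_at(0.2), q_at(0.8))
  if (diff(q_init) > bw) inits[[length(inits) + 1]] <- q_init
  if (length(inits) == 0) {
    out$degenerate <- TRUE
    return(out)
  }
  mix <- function(p) {
    p[["w"]] * stats::dnorm(x, p[["mu_b"]], p[["sig_b"]]) +
      (1 - p[["w"]]) * stats::dnorm(x, p[["mu_a"]], p[["sig_a"]])
  }
  fits <- lapply(inits, function(ini) {
    sig0 <- max((ini[2] - ini[1]) / 4, bw)
    minpack.lm::nls.lm(
      par = c(mu_a = ini[1], mu_b = ini[2], sig_a = sig0, sig_b = sig0,
              w = 0.5),
      fn = function(p) y - mix(p),
      lower = c(-Inf, -Inf, bw / 20, bw / 20, 1e-6),
      upper = c(Inf, Inf, Inf, Inf, 1 - 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14))
  })
  fit <- fits[[which.min(vapply(fits, function(f) sum(f$fvec^2),
                                numeric(1)))]]
  p <- fit$par
  mus <- c(p[["mu_a"]], p[["mu_b"]])
  sigs <- c(p[["sig_a"]], p[["sig_b"]])
  w_b <- p[["w"]]
  wts <- c(1 - w_b, w_b)
  hi <- which.max(mus); lo <- 3 - hi
  out$mu_low <- mus[lo]; out$mu_high <- mus[hi]
  out$sigma_low <- sigs[lo]; out$sigma_high <- sigs[hi]
  out$weight_high <- wts[hi]
  out$separation_nm <- out$mu_high - out$mu_low
  out$converged <- !(fit$info %in% c(0, 5, 9))
  # a separation below one bin or a vanishing component means the density
  # is effectively unimodal
  if (out$separation_nm <= bw || out$weight_high < 0.01 ||
      out$weight_high > 0.99) {
    out$degenerate <- TRUE
  }
  out
}

#' @export
print.two_gaussian_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("two_gaussian_fit: degenerate (modes unresolved)\n")
  } else {
    cat(sprintf(
      "two_gaussian_fit: mu = %.2f / %.2f nm (sep %.2f), sigma = %.2f / %.2f, w_high = %.2f\n",
      x$mu_low, x$mu_high, x$separation_nm, x$sigma_low, x$sigma_high,
      x$weight_high))
  }
  invisible(x)
}

#' Equilibrium force from a ladder of clamp occupancies
#'
#' The force at which the two states are equally occupied, found where the
#' log-odds of the high-extension state crosses zero, by linear
#' interpolation in force (exact for a two-state system with a constant
#' extension change).
#'
#' @param clamps A data frame (or list coercible to one) with columns
#'   `force_pN` and `occupancy_high` in (0, 1); at least two points
#'   straddling occupancy 0.5.
#' @return Equilibrium force, pN.
#' @export
equilibrium_force <- function(clamps) {
  clamps <- as.data.frame(clamps)
  stopifnot(all(c("force_pN", "occupancy_high") %in% names(clamps)),
            nrow(clamps) >= 1)
  p <- clamps$occupancy_high
  if (any(p <= 0 | p >= 1)) {
    stop("equilibrium_force: occupancies must lie strictly in (0, 1)")
  }
  o <- order(clamps$force_pN)
  f <- clamps$force_pN[o]
  lo <- log(p[o] / (1 - p[o]))
  exact <- which(lo == 0)
  if (length(exact)) return(f[exact[1]])
  cross <- which(lo[-length(lo)] * lo[-1] < 0)
  if (length(cross) == 0) {
    stop("equilibrium_force: clamp ladder does not straddle occupancy 0.5")
  }
  i <- cross[1]
  f[i] + (0 - lo[i]) * (f[i + 1] - f[i]) / (lo[i + 1] - lo[i])
}

#' Gating energy as mechanical work
#'
#' The free energy of the gating transition estimated as the reversible
#' work F_eq * delta_x, reported in pN nm, kBT and kcal/mol.
#'
#' @param F_eq Equilibrium force, pN (> 0).
#' @param delta_x Gating extension change, nm (>= 0).
#' @param c A [constants()] object.
#' @param transitions Optional data frame with per-transition columns
#'   `force_pN` and `delta_x_nm`; when given, the per-transition work
#'   values are averaged instead of multiplying the means, and `F_eq` /
#'   `delta_x` default to the transition means.
#' @return An object of class `gating_estimate`: `F_eq_pN`,
#'   `delta_x_nm`, `energy_pNnm`, `energy_kBT`, `energy_kcal_per_mol`,
#'   `n_transitions`, `mode` ("means" or "per_transition").
#' @export
gating_energy <- function(F_eq = NULL, delta_x = NULL, c = constants(),
                          transitions = NULL) {
  if (!is.null(transitions)) {
    transitions <- as.data.frame(transitions)
    stopifnot(all(c("force_pN", "delta_x_nm") %in% names(transitions)),
              nrow(transitions) >= 1)
    work <- mean(transitions$force_pN * transitions$delta_x_nm)
    if (is.null(F_eq)) F_eq <- mean(transitions$force_pN)
    if (is.null(delta_x)) delta_x <- mean(transitions$delta_x_nm)
    n <- nrow(transitions); mode <- "per_transition"
  } else {
    stopifnot(F_eq > 0, delta_x >= 0)
    work <- F_eq * delta_x
    n <- NA_integer_; mode <- "means"
  }
  structure(list(F_eq_pN = F_eq, delta_x_nm = delta_x,
                 energy_pNnm = work, energy_kBT = work / c$kBT,
                 energy_kcal_per_mol = work / c$kcal_per_mol_pNnm,
                 n_transitions = n, mode = mode),
            class = "gating_estimate")
}

#' @export
print.gating_estimate <- function(x, ...) {
  cat(sprintf(
    "gating_estimate (%s): %.1f pN x %.1f nm = %.1f pN nm = %.1f kBT = %.1f kcal/mol\n",
    x$mode, x$F_eq_pN, x$delta_x_nm, x$energy_pNnm, x$energy_kBT,
    x$energy_kcal_per_mol))
  invisible(x)
}

#' Two-state Gaussian mixture by expectation-maximization
#'
#' Fits a two-component Gaussian mixture with a shared variance
#' (measurement noise dominates both states equally) to raw extension
#' samples. The means are initialized at the 15% and 85% sample
#' quantiles, which keeps the components anchored to the two states even
#' when they overlap strongly or the occupancy is skewed.
#'
#' @param x Numeric samples.
#' @param max_iter,tol EM iteration controls (log-likelihood change).
#' @return A list: `mu` (length 2, sorted), `sigma` (shared), `pro`
#'   (component weights matching `mu`), `loglik`, `iterations`,
#'   `converged`.
#' @export
two_state_em <- function(x, max_iter = 500, tol = 1e-10) {
  stopifnot(length(x) >= 10)
  mu <- unname(stats::quantile(x, c(0.15, 0.85)))
  if (diff(mu) < 1e-12) mu <- mu + c(-1, 1) * stats::sd(x) / 2
  sigma <- max(stats::sd(x) / 2, 1e-6)
  w <- c(0.5, 0.5)
  ll_old <- -Inf
  iter <- 0
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(x, mu[1], sigma)
    d2 <- w[2] * stats::dnorm(x, mu[2], sigma)
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    r2 <- d2 / tot
    ll <- sum(log(tot))
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    n2 <- sum(r2); n1 <- length(x) - n2
    mu <- c(sum((1 - r2) * x) / n1, sum(r2 * x) / n2)
    sigma <- sqrt((sum((1 - r2) * (x - mu[1])^2) +
                     sum(r2 * (x - mu[2])^2)) / length(x))
    sigma <- max(sigma, 1e-9)
    w <- c(n1, n2) / length(x)
  }
  o <- order(mu)
  list(mu = mu[o], sigma = sigma, pro = w[o], loglik = ll_old,
       iterations = iter, converged = converged)
}

#' Occupancy of the high-extension state from a clamp trace
#'
#' The occupancy is the fitted mass of the high-extension component of a
#' two-Gaussian mixture. `method = "em"` (default) fits the mixture to
#' the raw extension samples with [two_state_em()], which stays well
#' conditioned when the states overlap strongly or the occupancy is
#' skewed; `method = "density"` uses the binned-density curve fit of
#' [fit_two_gaussians()].
#'
#' @param trace A [clamp_trace()].
#' @param method `"em"` or `"density"`.
#' @param bin_width Density bin width, nm (density method).
#' @return A list: `occupancy_high`, `fit` (the mixture fit object),
#'   `force_pN`.
#' @export
clamp_occupancy <- function(trace, method = c("em", "density"),
                            bin_width = 0.25) {
  method <- match.arg(method)
  if (method == "em") {
    m <- two_state_em(trace$data$extension_nm)
    return(list(occupancy_high = m$pro[2], fit = m,
                force_pN = trace$mean_force))
  }
  fit <- fit_two_gaussians(extension_density(trace, bin_width))
  list(occupancy_high = fit$weight_high, fit = fit,
       force_pN = trace$mean_force)
}
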