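#' Worm-like chain segment
#'
#' A semi-flexible polymer described by its contour length and persistence
#' length (Marko-Siggia interpolation). Used for the DNA handles
#' (P = 40 nm) and for unfolded polypeptide (P = 0.6 nm).
#'
#' @param L Contour length, nm (> 0).
#' @param P Persistence length, nm (> 0).
#' @return An object of class `wlc` (also a `tether_element`).
#' @export
wlc <- function(L, P) {
  stopifnot(is.numeric(L), is.numeric(P), length(L) == 1, length(P) == 1)
  if (!(L > 0)) stop("wlc: contour length L must be > 0, got ", L)
  if (!(P > 0)) stop("wlc: persistence length P must be > 0, got ", P)
  structure(list(L = L, P = P), class = c("wlc", "tether_element"))
}

#' Elastic rod (structured protein portion)
#'
#' Linear spring with an intrinsic (zero-force) length: x(F) = x0 + F/k.
#' Compression (F < 0) follows the same linear law.
#'
#' @param x0 Intrinsic length at zero force, nm (>= 0).
#' @param k Stiffness, pN/nm (> 0).
#' @return An object of class `elastic_rod`.
#' @export
elastic_rod <- function(x0, k) {
  if (!(k > 0)) stop("elastic_rod: stiffness k must be > 0, got ", k)
  if (x0 < 0) stop("elastic_rod: intrinsic length x0 must be >= 0, got ", x0)
  structure(list(x0 = x0, k = k), class = c("elastic_rod", "tether_element"))
}

#' Rigid (force-independent) offset
#'
#' Fixed-length element, e.g. the lipid nanodisc whose extension stays
#' constant (~5 nm) over the experimental force range.
#'
#' @param length Length in nm (>= 0).
#' @return An object of class `rigid_offset`.
#' @export
rigid_offset <- function(length) {
  if (length < 0) stop("rigid_offset: length must be >= 0, got ", length)
  structure(list(length = length),
            class = c("rigid_offset", "tether_element"))
}

#' Bundle of identical elements in parallel
#'
#' `n` copies of one element sharing a common extension; the tension is
#' split equally so each member carries F/n and the bundle compliance is
#' the member compliance divided by n. Realizes e.g. four disordered
#' N-terminal chains, one per subunit, loaded in parallel.
#'
#' @param element A `tether_element`.
#' @param n Multiplicity (integer >= 1).
#' @return An object of class `parallel_bundle`.
#' @export
parallel_bundle <- function(element, n) {
  stopifnot(inherits(element, "tether_element"))
  if (n < 1 || n != round(n)) stop("parallel_bundle: n must be an integer >= 1, got ", n)
  structure(list(element = element, n = as.integer(n)),
            class = c("parallel_bundle", "tether_element"))
}

#' Series tether of mechanical elements
#'
#' Ordered series composition (WLC handles, elastic rod, rigid offsets,
#' parallel bundles) sharing one tension; the total extension is the sum of
#' element extensions.
#'
#' @param ... `tether_element` objects, in series.
#' @return An object of class `tether`.
#' @export
tether <- function(...) {
  elements <- list(...)
  if (length(elements) == 1 && is.list(elements[[1]]) &&
      !inherits(elements[[1]], "tether_element")) {
    elements <- elements[[1]]
  }
  stopifnot(length(elements) >= 1)
  for (el in elements) stopifnot(inherits(el, "tether_element"))
  structure(list(elements = elements), class = "tether")
}

# ---- worm-like chain closed forms -------------------------------------

#' Worm-like chain force at a given extension
#'
#' Marko-Siggia interpolation:
#' F = (kBT/P) \[ 1/(4 (1 - x/L)^2) + x/L - 1/4 \].
#' Strictly increasing in x, diverging as x approaches L.
#'
#' @param x Extension, nm; vectorized; must satisfy 0 <= x < L.
#' @param chain A [wlc()] segment.
#' @param c A [constants()] object.
#' @return Force in pN.
#' @examples
#' wlc_force(22.45, wlc(44.9, 0.6))   # ~8.54 pN
#' @export
wlc_force <- function(x, chain, c = constants()) {
  stopifnot(inherits(chain, "wlc"))
  bad <- x < 0 | x >= chain$L
  if (any(bad)) {
    stop("wlc_force: extension out of domain [0, L=", chain$L, "): ",
         paste(utils::head(x[bad], 3), collapse = ", "))
  }
  u <- x / chain$L
  (c$kBT / chain$P) * (1 / (4 * (1 - u)^2) + u - 0.25)
}

# Solve the Marko-Siggia relation for relative extension u given
# cc = F*P/kBT; vectorized bisection on [0, 1), 64 iterations
# (absolute precision ~5e-20 in u, far below the 1e-9 contract).
.wlc_inv_u <- function(cc) {
  stopifnot(all(cc >= 0))
  lo <- rep(0, length(cc))
  hi <- rep(1 - 1e-14, length(cc))
  f <- function(u) 1 / (4 * (1 - u)^2) + u - 0.25
  for (i in 1:64) {
    mid <- 0.5 * (lo + hi)
    high <- f(mid) > cc
    hi[high] <- mid[high]
    lo[!high] <- mid[!high]
  }
  0.5 * (lo + hi)
}

#' Worm-like chain extension at a given force (inverse of [wlc_force()])
#'
#' @param F Force, pN; vectorized; must be >= 0.
#' @param chain A [wlc()] segment.
#' @param c A [constants()] object.
#' @return The unique extension x in \[0, L) with `wlc_force(x) == F`,
#'   solved by safeguarded bisection to relative tolerance well below 1e-9.
#' @export
wlc_extension <- function(F, chain, c = constants()) {
  stopifnot(inherits(chain, "wlc"))
  if (any(F < 0)) {
    stop("wlc_extension: force must be >= 0, got ",
         paste(utils::head(F[F < 0], 3), collapse = ", "))
  }
  chain$L * .wlc_inv_u(F * chain$P / c$kBT)
}

#' Entropic stretching energy of a worm-like chain
#'
#' E = (kBT/P) (L/4) \[ 3 (x/L)^2 - 2 (x/L)^3 \] / (1 - x/L), the exact
#' integral of the Marko-Siggia force from 0 to x.
#'
#' @inheritParams wlc_force
#' @return Energy in pN nm.
#' @export
wlc_energy <- function(x, chain, c = constants()) {
  stopifnot(inherits(chain, "wlc"))
  bad <- x < 0 | x >= chain$L
  if (any(bad)) {
    stop("wlc_energy: extension out of domain [0, L=", chain$L, "): ",
         paste(utils::head(x[bad], 3), collapse = ", "))
  }
  u <- x / chain$L
  (c$kBT / chain$P) * (chain$L / 4) * (3 * u^2 - 2 * u^3) / (1 - u)
}

#' Extension of an elastic rod at a given force
#'
#' @param F Force, pN (any real; negative compresses).
#' @param rod An [elastic_rod()].
#' @return Extension x0 + F/k in nm.
#' @export
rod_extension <- function(F, rod) {
  stopifnot(inherits(rod, "elastic_rod"))
  rod$x0 + F / rod$k
}

# ---- element generics --------------------------------------------------

el_extension <- function(el, F, c) UseMethod("el_extension")
#' @export
el_extension.wlc <- function(el, F, c) wlc_extension(F, el, c)
#' @export
el_extension.elastic_rod <- function(el, F, c) rod_extension(F, el)
#' @export
el_extension.rigid_offset <- function(el, F, c) rep(el$length, length(F))
#' @export
el_extension.parallel_bundle <- function(el, F, c) {
  el_extension(el$element, F / el$n, c)
}

el_compliance <- function(el, F, c) UseMethod("el_compliance")
#' @export
el_compliance.wlc <- function(el, F, c) {
  # dx/dF = L / f'(u) with f(u) the Marko-Siggia force
  u <- .wlc_inv_u(F * el$P / c$kBT)
  el$L / ((c$kBT / el$P) * (1 / (2 * (1 - u)^3) + 1))
}
#' @export
el_compliance.elastic_rod <- function(el, F, c) rep(1 / el$k, length(F))
#' @export
el_compliance.rigid_offset <- function(el, F, c) rep(0, length(F))
#' @export
el_compliance.parallel_bundle <- function(el, F, c) {
  el_compliance(el$element, F / el$n, c) / el$n
}

# zero-force length of an element / tether (rigid floor of the domain)
el_rest_length <- function(el, c) UseMethod("el_rest_length")
#' @export
el_rest_length.wlc <- function(el, c) 0
#' @export
el_rest_length.elastic_rod <- function(el, c) el$x0
#' @export
el_rest_length.rigid_offset <- function(el, c) el$length
#' @export
el_rest_length.parallel_bundle <- function(el, c) el_rest_length(el$element, c)

# ---- tether-level operations ------------------------------------------

#' Extension of a series tether at a common tension
#'
#' Sums the element extensions at shared tension F; members of a
#' [parallel_bundle()] are evaluated at the per-member force F/n.
#'
#' @param F Tension, pN; vectorized; must be >= 0.
#' @param tether A [tether()].
#' @param c A [constants()] object.
#' @return Extension in nm; strictly increasing in F.
#' @export
tether_extension <- function(F, tether, c = constants()) {
  stopifnot(inherits(tether, "tether"))
  if (any(F < 0)) stop("tether_extension: force must be >= 0")
  out <- rep(0, length(F))
  for (el in tether$elements) out <- out + el_extension(el, F, c)
  out
}

#' Zero-force (rest) extension of a tether
#'
#' @inheritParams tether_extension
#' @return Sum of rigid lengths and rod intrinsic lengths, nm.
#' @export
tether_rest_length <- function(tether, c = constants()) {
  sum(vapply(tether$elements, el_rest_length, numeric(1), c = c))
}

#' Tension of a series tether at a given total extension
#'
#' Numerically inverts [tether_extension()] by bracketed bisection
#' (relative tolerance ~1e-12); round-trips with `tether_extension`.
#'
#' @param X Total extension, nm; vectorized.
#' @param tether A [tether()].
#' @param c A [constants()] object.
#' @return Tension in pN.
#' @export
tether_force <- function(X, tether, c = constants()) {
  stopifnot(inherits(tether, "tether"))
  rest <- tether_rest_length(tether, c)
  if (any(X < rest - 1e-9)) {
    stop("tether_force: extension ", paste(utils::head(X[X < rest - 1e-9], 3),
         collapse = ", "), " below the zero-force tether length ", rest)
  }
  X <- pmax(X, rest)
  # expand a common bracket
  hi <- 1
  for (i in 1:80) {
    ext <- tether_extension(hi, tether, c)
    if (all(ext >= X)) break
    hi <- hi * 2
    if (hi > 1e12) {
      stop("tether_force: extension unreachable (at or beyond total contour ",
           "length of a rod-free tether)")
    }
  }
  if (any(tether_extension(hi, tether, c) < X)) {
    stop("tether_force: extension unreachable (at or beyond total contour ",
         "length of a rod-free tether)")
  }
  lo <- rep(0, length(X))
  hi <- rep(hi, length(X))
  for (i in 1:100) {
    mid <- 0.5 * (lo + hi)
    high <- tether_extension(mid, tether, c) > X
    hi[high] <- mid[high]
    lo[!high] <- mid[!high]
  }
  out <- 0.5 * (lo + hi)
  out[abs(X - rest) < 1e-12] <- 0
  out
}

#' Stiffness of a series tether at a given tension
#'
#' Reciprocal of the summed element compliances (compliances add in
#' series; a parallel bundle contributes its member compliance / n,
#' evaluated at the per-member force).
#'
#' @param F Tension, pN; vectorized; must be > 0 for WLC elements (the
#'   zero-force WLC compliance limit 2PL/(3 kBT) is used at F = 0).
#' @param tether A [tether()].
#' @param c A [constants()] object.
#' @return Stiffness in pN/nm.
#' @export
tether_stiffness <- function(F, tether, c = constants()) {
  stopifnot(inherits(tether, "tether"))
  compliance <- rep(0, length(F))
  for (el in tether$elements) compliance <- compliance + el_compliance(el, F, c)
  1 / compliance
}
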