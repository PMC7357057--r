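#' Physical parameters of a matrix release system
#'
#' Collects the dimensional parameters of a spherical matrix loaded with
#' dispersed solid drug. All quantities must be expressed in one consistent
#' unit system; no unit inference is attempted.
#'
#' @param D drug diffusion coefficient in the matrix (length^2/time).
#' @param k dissolution rate constant (area^-1 time^-1); `k * A0` acts as a
#'   first-order rate constant (1/time).
#' @param A0 initial solid drug surface area per unit matrix volume
#'   (area/volume).
#' @param r0 radius of the spherical matrix (length).
#' @param Cs drug solubility in the matrix phase (mass/volume).
#' @param Ca0 initial dispersed (un-dissolved) drug concentration
#'   (mass/volume).
#' @param n particle shape factor in `[0, 1)`; see [particle_shapes].
#'
#' @return An object of class `physical_params`.
#' @seealso [nondimensionalize()], [dimensionless_params()]
#' @examples
#' p <- physical_params(D = 1e-6, k = 10, A0 = 50, r0 = 0.1,
#'                      Cs = 1, Ca0 = 100, n = particle_shapes$spherical)
#' nondimensionalize(p)
#' @export
physical_params <- function(D, k, A0, r0, Cs, Ca0, n = 0) {
  vals <- list(D = D, k = k, A0 = A0, r0 = r0, Cs = Cs, Ca0 = Ca0)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("'%s' must be a single positive finite number", nm),
           call. = FALSE)
    }
  }
  check_shape_factor(n)
  structure(c(vals, list(n = n)), class = "physical_params")
}

#' Dimensionless parameters of a matrix release system
#'
#' The release problem is governed by three dimensionless groups: `K`, the
#' solubility-to-total-loading ratio \eqn{C_s/(C_s + C_{a0})}; `G`, the
#' dissolution-to-diffusion rate ratio \eqn{k A_0 r_0^2 / D}; and the
#' particle shape factor `n`. Time is measured as \eqn{\tau = D t / r_0^2}
#' and radius as \eqn{\eta = r/r_0}.
#'
#' `K` is restricted to the open interval (0, 1): `K = 0` (insoluble drug)
#' and `K = 1` (no dispersed solid) are degenerate for the governing
#' equations and are rejected.
#'
#' @param K solubility/loading ratio, in (0, 1).
#' @param G dissolution/diffusion rate ratio, > 0. Large `G` approaches the
#'   instantaneous-dissolution (Higuchi) limit.
#' @param n particle shape factor in `[0, 1)`; see [particle_shapes].
#'
#' @return An object of class `dimensionless_params`.
#' @examples
#' dimensionless_params(K = 1 / 101, G = 0.1, n = 0)
#' @export
dimensionless_params <- function(K, G, n = 0) {
  if (!is.numeric(K) || length(K) != 1L || !is.finite(K)) {
    stop("'K' must be a single finite number", call. = FALSE)
  }
  if (K <= 0 || K >= 1) {
    stop("'K' must lie strictly between 0 and 1 (K = ", K,
         " is degenerate: K = 0 means insoluble drug, K = 1 means no ",
         "dispersed solid)", call. = FALSE)
  }
  if (!is.numeric(G) || length(G) != 1L || !is.finite(G) || G <= 0) {
    stop("'G' must be a single positive finite number", call. = FALSE)
  }
  check_shape_factor(n)
  structure(list(K = K, G = G, n = n), class = "dimensionless_params")
}

check_shape_factor <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 0 || n >= 1) {
    stop("shape factor 'n' must be a single number in [0, 1)", call. = FALSE)
  }
  invisible(n)
}

#' @export
print.dimensionless_params <- function(x, ...) {
  shape <- shape_label(x$n)
  cat(sprintf("Dimensionless release parameters: K = %g, G = %g, n = %g%s\n",
              x$K, x$G, x$n, if (nzchar(shape)) paste0(" (", shape, ")") else ""))
  invisible(x)
}

#' @export
print.physical_params <- function(x, ...) {
  cat("Physical release parameters:\n")
  cat(sprintf("  D = %g, k = %g, A0 = %g, r0 = %g, Cs = %g, Ca0 = %g, n = %g\n",
              x$D, x$k, x$A0, x$r0, x$Cs, x$Ca0, x$n))
  d <- nondimensionalize(x)
  cat(sprintf("  (K = %g, G = %g)\n", d$K, d$G))
  invisible(x)
}

shape_label <- function(n) {
  lbl <- names(particle_shapes)[vapply(particle_shapes, function(v)
    isTRUE(all.equal(v, n, tolerance = 1e-12)), logical(1))]
  if (length(lbl)) lbl[[1]] else ""
}

#' Convert physical parameters to the dimensionless groups
#'
#' Computes `K = Cs / (Cs + Ca0)` and `G = k * A0 * r0^2 / D`; the shape
#' factor is passed through unchanged.
#'
#' @param p a [physical_params()] object.
#' @return A [dimensionless_params()] object.
#' @examples
#' nondimensionalize(physical_params(D = 1, k = 10, A0 = 10, r0 = 1,
#'                                   Cs = 1, Ca0 = 100))
#' @export
nondimensionalize <- function(p) {
  stopifnot(inherits(p, "physical_params"))
  dimensionless_params(K = p$Cs / (p$Cs + p$Ca0),
                       G = p$k * p$A0 * p$r0^2 / p$D,
                       n = p$n)
}

#' Convert between clock time and dimensionless time
#'
#' Dimensionless time is \eqn{\tau = D t / r_0^2}. `tau_of_time()` and
#' `time_of_tau()` are exact inverses.
#'
#' @param t time (same units as implied by `D` and `r0`); must be >= 0.
#' @param tau dimensionless time; must be >= 0.
#' @param p a [physical_params()] object.
#' @return A numeric vector.
#' @examples
#' p <- physical_params(D = 2, k = 1, A0 = 1, r0 = 4, Cs = 1, Ca0 = 1)
#' tau_of_time(8, p)      # 8 * 2 / 16 = 1
#' time_of_tau(tau_of_time(8, p), p)
#' @export
tau_of_time <- function(t, p) {
  stopifnot(inherits(p, "physical_params"))
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("'t' must be nonnegative and finite", call. = FALSE)
  }
  p$D * t / p$r0^2
}

#' @rdname tau_of_time
#' @export
time_of_tau <- function(tau, p) {
  stopifnot(inherits(p, "physical_params"))
  if (any(!is.finite(tau)) || any(tau < 0)) {
    stop("'tau' must be nonnegative and finite", call. = FALSE)
  }
  tau * p$r0^2 / p$D
}
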