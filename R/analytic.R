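#' Critical time for depletion-zone formation
#'
#' Before any depletion zone exists the solid concentration at the matrix
#' surface decays according to a local dissolution balance, reaching zero at
#' the critical time
#' \deqn{\tau_c = \frac{1 - K}{G K (1 - n)},}
#' i.e. \eqn{(1-K)/GK}, \eqn{2(1-K)/GK} and \eqn{3(1-K)/GK} for planar,
#' cylindrical and spherical particles. For \eqn{\tau > \tau_c} the problem
#' becomes a moving-boundary one, with the depletion front receding inward.
#'
#' @param params a [dimensionless_params()] object.
#' @return The dimensionless critical time (scalar).
#' @examples
#' critical_time(dimensionless_params(K = 1 / 2, G = 0.1, n = 0))  # 10
#' @export
critical_time <- function(params) {
  stopifnot(inherits(params, "dimensionless_params"))
  (1 - params$K) / (params$G * params$K * (1 - params$n))
}

#' Surface solid concentration before depletion
#'
#' Closed-form fraction of un-dissolved drug at the matrix surface. The
#' sink condition pins the dissolved concentration at zero there, so the
#' solid balance reduces to the separable ODE
#' \eqn{d\phi_a/d\tau = -GK(\phi_a/(1-K))^n} with solution
#' \deqn{\phi_a(\tau, 1) = \left[(1-K)^{1-n} -
#'       \frac{G (1-n) K \tau}{(1-K)^{n}}\right]^{1/(1-n)},}
#' valid for \eqn{\tau \le \tau_c} and identically zero afterwards (the
#' expression is continuous at \eqn{\tau_c}).
#'
#' @param tau dimensionless time(s), >= 0.
#' @param params a [dimensionless_params()] object.
#' @return Numeric vector of surface solid concentration fractions.
#' @examples
#' p <- dimensionless_params(K = 1 / 2, G = 1, n = 0)
#' surface_undissolved(0, p)                 # 1 - K
#' surface_undissolved(critical_time(p), p)  # 0
#' @export
surface_undissolved <- function(tau, params) {
  stopifnot(inherits(params, "dimensionless_params"))
  if (any(!is.finite(tau)) || any(tau < 0)) {
    stop("'tau' must be nonnegative and finite", call. = FALSE)
  }
  K <- params$K; G <- params$G; n <- params$n
  base <- (1 - K)^(1 - n) - G * (1 - n) * K * tau / (1 - K)^n
  pmax(base, 0)^(1 / (1 - n))
}

#' Truncation options for the planar-particle series solution
#'
#' @param max_terms maximum number of series terms (default 10000).
#' @param term_tolerance stop once the magnitude of the last added term
#'   falls below this value (default 1e-4).
#' @return An object of class `series_options`.
#' @export
series_options <- function(max_terms = 10000L, term_tolerance = 1e-4) {
  if (!is.numeric(max_terms) || length(max_terms) != 1L || max_terms < 1) {
    stop("'max_terms' must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(term_tolerance) || length(term_tolerance) != 1L ||
      term_tolerance <= 0) {
    stop("'term_tolerance' must be positive", call. = FALSE)
  }
  structure(list(max_terms = as.integer(max_terms),
                 term_tolerance = term_tolerance),
            class = "series_options")
}

#' Series solution for planar particles before depletion
#'
#' For planar dispersed particles (`n = 0`) the governing equations are
#' linear while no depletion zone exists (\eqn{\tau \le \tau_c}), and admit
#' an eigenfunction-expansion solution. With
#' \eqn{s_m = \sin(m\pi\eta)/(m\pi\eta)}, \eqn{\mu_m = G + (m\pi)^2},
#' \eqn{a_m = G/\mu_m} and \eqn{b_m = (m\pi)^2/\mu_m}, the dissolved and
#' solid fractions are
#' \deqn{\varphi(\tau,\eta) = 2K \sum_{m\ge1} (-1)^{m+1} s_m
#'       \left[a_m + b_m e^{-\mu_m \tau}\right],}
#' \deqn{\phi_a(\tau,\eta) = (1-K) - GK\left[\tau - 2\sum_{m\ge1}
#'       (-1)^{m+1} s_m \left(a_m \tau +
#'       \frac{b_m}{\mu_m}(1 - e^{-\mu_m\tau})\right)\right].}
#' This is the exact solution of the linear pre-depletion problem: it
#' satisfies the initial conditions (\eqn{\varphi = K},
#' \eqn{\phi_a = 1 - K}), the sink and symmetry boundary conditions, and
#' reduces at \eqn{\eta = 1} to the closed-form surface result of
#' [surface_undissolved()]. (Commonly cited printed forms of this series
#' differ by normalization constants and a time rescaling; see the package
#' vignette.) Terms are summed in increasing `m` until the last term's
#' magnitude drops below `opts$term_tolerance` at every requested radius, or
#' `opts$max_terms` is reached. The removable singularity at the center is
#' evaluated by its limit \eqn{s_m \to 1}.
#'
#' @param tau a single dimensionless time in `[0, critical_time(params)]`.
#' @param eta radial fractions in (0, 1] (values below 1e-12 use the
#'   symmetric-center limit).
#' @param params a [dimensionless_params()] object with `n = 0`.
#' @param opts a [series_options()] object.
#' @return A list with elements `tau`, `eta`, `phi` (dissolved fraction),
#'   `phi_a` (solid fraction) and `terms` (number of terms used).
#' @examples
#' p <- dimensionless_params(K = 1 / 2, G = 10, n = 0)
#' series_state(0.01, c(0.25, 0.5, 0.75, 1), p)
#' @export
series_state <- function(tau, eta, params, opts = series_options()) {
  stopifnot(inherits(params, "dimensionless_params"),
            inherits(opts, "series_options"))
  if (params$n != 0) {
    stop("the series solution exists only for planar particles (n = 0)",
         call. = FALSE)
  }
  if (length(tau) != 1L || !is.finite(tau) || tau < 0) {
    stop("'tau' must be a single nonnegative time", call. = FALSE)
  }
  tau_c <- critical_time(params)
  if (tau > tau_c * (1 + 1e-12)) {
    stop(sprintf(paste0("'tau' = %g exceeds the critical time %g; the series",
                        " is valid only before depletion-zone formation"),
         tau, tau_c), call. = FALSE)
  }
  if (any(!is.finite(eta)) || any(eta < 0) || any(eta > 1)) {
    stop("'eta' must lie in [0, 1]", call. = FALSE)
  }
  K <- params$K; G <- params$G

  phi_sum <- numeric(length(eta))   # sum of (-1)^(m+1) s_m [a_m + b_m e^-mu tau]
  int_sum <- numeric(length(eta))   # sum of (-1)^(m+1) s_m [a_m tau + b_m/mu (1-e^-mu tau)]
  m <- 0L
  repeat {
    m <- m + 1L
    mp <- m * pi
    mu <- G + mp^2
    a <- G / mu
    b <- mp^2 / mu
    sm <- sinc_eta(mp, eta)
    sgn <- if (m %% 2L == 1L) 1 else -1
    em <- exp(-mu * tau)
    t_phi <- sgn * sm * (a + b * em)
    t_int <- sgn * sm * (a * tau + b / mu * (1 - em))
    phi_sum <- phi_sum + t_phi
    int_sum <- int_sum + t_int
    # termination uses the eta-independent envelope |s_m| <= 1: the raw
    # last term would stop prematurely wherever sin(m pi eta) hits a zero
    envelope <- max(2 * K * (a + b * em),
                    2 * G * K * (a * tau + b / mu * (1 - em)))
    if (envelope < opts$term_tolerance || m >= opts$max_terms) break
  }
  phi <- 2 * K * phi_sum
  phi_a <- (1 - K) - G * K * (tau - 2 * int_sum)
  list(tau = tau, eta = eta, phi = phi, phi_a = phi_a, terms = m)
}

# sin(mp*eta)/(mp*eta) with the eta -> 0 limit
sinc_eta <- function(mp, eta) {
  out <- numeric(length(eta))
  tiny <- eta < 1e-12
  out[tiny] <- 1
  out[!tiny] <- sin(mp * eta[!tiny]) / (mp * eta[!tiny])
  out
}

#' Released fraction from the planar-particle series solution
#'
#' Integrates the release complement of the series profiles,
#' \eqn{F(\tau) = \int_0^1 (1 - \varphi - \phi_a)\, 3\eta^2\, d\eta},
#' by adaptive quadrature.
#'
#' @inheritParams series_state
#' @param tau dimensionless time(s) in `[0, critical_time(params)]`.
#' @param quad_rel_tol relative quadrature tolerance (default 1e-6).
#' @return Numeric vector of released fractions.
#' @examples
#' p <- dimensionless_params(K = 1 / 2, G = 10, n = 0)
#' series_release_fraction(c(0, 0.05, 0.1), p)
#' @export
series_release_fraction <- function(tau, params, opts = series_options(),
                                    quad_rel_tol = 1e-6) {
  vapply(tau, function(t1) {
    if (t1 == 0) return(0)   # initial condition; the series itself is only
                             # conditionally convergent at tau = 0
    f <- function(x) {
      st <- series_state(t1, x, params, opts)
      (1 - st$phi - st$phi_a) * 3 * x^2
    }
    stats::integrate(f, 0, 1, rel.tol = quad_rel_tol,
                     subdivisions = 500L)$value
  }, numeric(1))
}
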