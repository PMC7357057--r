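#' Depletion-front position in the spherical Higuchi model
#'
#' Under instantaneous dissolution and a pseudo-steady-state depletion-zone
#' profile, the front radius \eqn{\eta^*} of a spherical matrix in a perfect
#' sink satisfies the implicit equation
#' \deqn{1 + 2(\eta^*)^3 - 3(\eta^*)^2 +
#'       K\left[4(\eta^*)^2 + \ln\frac{1}{\eta^*} - 1 - \eta^* -
#'       2(\eta^*)^3\right] = 6 K \tau.}
#' The unique root in `(0, 1]` is found by bracketed root-finding to an
#' absolute tolerance of 1e-12; at `tau = 0` the front is exactly at the
#' surface (`eta_star = 1`). At very late times, when the root falls below
#' 1e-12 (the logarithmic term makes this an exponentially small radius),
#' the front is reported as 0: the matrix is exhausted and the released
#' fraction is 1.
#'
#' @param tau dimensionless time(s), >= 0.
#' @param K solubility/loading ratio in (0, 1).
#' @return Numeric vector of front positions in `(0, 1]`.
#' @examples
#' higuchi_front(c(0, 0.1, 1), K = 1 / 2)
#' @export
higuchi_front <- function(tau, K) {
  if (!is.numeric(K) || length(K) != 1L || K <= 0 || K >= 1) {
    stop("'K' must lie strictly between 0 and 1", call. = FALSE)
  }
  if (any(!is.finite(tau)) || any(tau < 0)) {
    stop("'tau' must be nonnegative and finite", call. = FALSE)
  }
  vapply(tau, function(t1) {
    if (t1 == 0) return(1)
    rhs <- 6 * K * t1
    f <- function(x) higuchi_lhs(x, K) - rhs
    lo <- 1e-3
    while (f(lo) < 0) {
      lo <- lo / 10
      if (lo < 1e-12) {
        # the logarithmic term only reaches 6*K*tau at an eta* below any
        # meaningful resolution: the matrix is exhausted, front at center
        return(0)
      }
    }
    if (!is.finite(f(lo))) {
      stop(sprintf("front not bracketed for K = %g, tau = %g", K, t1),
           call. = FALSE)
    }
    stats::uniroot(f, c(lo, 1), tol = 1e-13)$root
  }, numeric(1))
}

higuchi_lhs <- function(x, K) {
  1 + 2 * x^3 - 3 * x^2 + K * (4 * x^2 + log(1 / x) - 1 - x - 2 * x^3)
}

#' Pseudo-steady-state profile in the depletion zone
#'
#' The quasi-static dissolved-drug profile in the depleted spherical shell
#' solves the Laplace equation with saturation at the front
#' (\eqn{\varphi(\eta^*) = K}) and a sink at the surface
#' (\eqn{\varphi(1) = 0}):
#' \deqn{\varphi(\eta) = K\,\frac{1/\eta - 1}{1/\eta^* - 1}.}
#'
#' @param eta radial fraction(s) with `eta_star < eta <= 1`.
#' @param eta_star front position in (0, 1).
#' @param K solubility/loading ratio in (0, 1).
#' @return Numeric vector of dissolved concentration fractions.
#' @examples
#' pss_profile(3 / 4, eta_star = 1 / 2, K = 1 / 2)  # 1/6
#' @export
pss_profile <- function(eta, eta_star, K) {
  if (!is.numeric(eta_star) || length(eta_star) != 1L ||
      eta_star <= 0 || eta_star >= 1) {
    stop("'eta_star' must lie strictly between 0 and 1", call. = FALSE)
  }
  if (any(eta <= eta_star) || any(eta > 1)) {
    stop("'eta' must lie in (eta_star, 1]", call. = FALSE)
  }
  K * (1 / eta - 1) / (1 / eta_star - 1)
}

#' Released fraction in the spherical Higuchi model
#'
#' With the front at \eqn{\eta^*} from [higuchi_front()], the released
#' fraction is the total load minus the (saturated, concentration 1)
#' un-depleted core and the dissolved drug still in the depletion shell:
#' \deqn{F = 1 - (\eta^*)^3 - \int_{\eta^*}^{1} \varphi\, 3\eta^2\, d\eta.}
#' With the pseudo-steady-state profile the shell integral has the closed
#' form \eqn{K\,\eta^*(1-\eta^*)(\eta^* + 1/2)}, which is used by default;
#' `method = "quadrature"` evaluates it numerically instead (the two agree
#' to 1e-10, see the test suite).
#'
#' @inheritParams higuchi_front
#' @param method `"closed_form"` (default) or `"quadrature"`.
#' @return Numeric vector of released fractions.
#' @examples
#' higuchi_fraction(c(0, 0.05, 0.5), K = 1 / 2)
#' @export
higuchi_fraction <- function(tau, K, method = c("closed_form", "quadrature")) {
  method <- match.arg(method)
  x <- higuchi_front(tau, K)
  shell <- if (method == "closed_form") {
    K * x * (1 - x) * (x + 1 / 2)
  } else {
    vapply(x, function(xs) {
      if (xs >= 1 || xs <= 0) return(0)
      stats::integrate(function(e) pss_profile(e, xs, K) * 3 * e^2, xs, 1,
                       rel.tol = 1e-12, abs.tol = 1e-14,
                       subdivisions = 1000L)$value
    }, numeric(1))
  }
  1 - x^3 - shell
}

#' Tabulate the spherical Higuchi solution
#'
#' @inheritParams higuchi_front
#' @param tau strictly increasing dimensionless times.
#' @return A data frame of class `higuchi_solution` with columns `tau`,
#'   `eta_star` and `fraction_released`.
#' @export
higuchi_solution <- function(tau, K) {
  if (is.unsorted(tau, strictly = TRUE)) {
    stop("'tau' must be strictly increasing", call. = FALSE)
  }
  x <- higuchi_front(tau, K)
  out <- data.frame(tau = tau, eta_star = x,
                    fraction_released = 1 - x^3 - K * x * (1 - x) * (x + 1 / 2))
  class(out) <- c("higuchi_solution", "data.frame")
  out
}
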