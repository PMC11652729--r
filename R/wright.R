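#' Wright's two-argument exponential integral function
#'
#' Evaluates
#' \deqn{\psi(x, y) = \tfrac12 \int_{-1}^{1} e^{\,x t + y(1/2 - t^2)}\,dt,}
#' the special function appearing in the flux-equilibrium allele-frequency
#' density and decay rate. Two closed special cases pin the definition:
#' `psi(x, 0) = sinh(x)/x` and the series
#' `psi(0, y) = 1 + y/3! + 7 y^2/5! + 27 y^3/7! + ...`; both are enforced by
#' the test suite. `psi` is even in `x`.
#'
#' @param x,y Real arguments.
#' @param rel_tol Relative accuracy requested from the adaptive quadrature.
#' @param method `"quadrature"` (adaptive, any argument size within the
#'   overflow guard) or `"series"` (double Taylor series, accurate for
#'   moderate arguments, used as an independent cross-check).
#' @return The value of `psi(x, y)`.
#' @examples
#' psi_wright(2, 0)            # sinh(2)/2
#' psi_wright(0, 1)
#' @export
psi_wright <- function(x, y, rel_tol = 1e-12,
                       method = c("quadrature", "series")) {
  stopifnot(is.finite(x), is.finite(y))
  method <- match.arg(method)
  if (method == "series") return(.psi_series(x, y))
  # peak of the exponent over [-1, 1] for overflow-safe scaling
  h <- function(t) x * t + y * (0.5 - t^2)
  cand <- c(-1, 1)
  if (y > 0) {
    tstar <- x / (2 * y)
    if (tstar > -1 && tstar < 1) cand <- c(cand, tstar)
  }
  M <- max(h(cand))
  if (M > 700)
    stop("psi overflow: |x| = ", abs(x), ", y = ", y,
         " exceed the representable range", call. = FALSE)
  val <- stats::integrate(function(t) 0.5 * exp(h(t) - M), -1, 1,
                          rel.tol = rel_tol, abs.tol = 0)$value * exp(M)
  if (!is.finite(val))
    stop("psi returned a non-finite value for x = ", x, ", y = ", y,
         call. = FALSE)
  val
}

# Double Taylor series: psi = sum_{j even, k} x^j y^k / (j! k!) * m_{jk},
# m_{jk} = (1/2) int_{-1}^{1} t^j (1/2 - t^2)^k dt.
.psi_series <- function(x, y, jmax = 60L, kmax = 60L, tol = 1e-16) {
  m_jk <- function(j, k) {
    mm <- 0:k
    sum(choose(k, mm) * 0.5^(k - mm) * (-1)^mm / (j + 2 * mm + 1))
  }
  total <- 0
  for (j in seq(0L, jmax, by = 2L)) {
    xj <- x^j / factorial(j)
    if (j > 0 && abs(xj) < tol && abs(x) <= j) next
    row <- 0
    for (k in 0:kmax) {
      term <- xj * y^k / factorial(k) * m_jk(j, k)
      row <- row + term
      if (k > 4 && abs(term) < tol * max(1, abs(total))) break
    }
    total <- total + row
    if (j > 4 && abs(row) < tol * max(1, abs(total))) break
  }
  total
}

# int_{lo}^{hi} exp(-(a x + b x^2)) dx by adaptive quadrature with
# overflow-safe scaling. a = 4*Ne*S, b = 2*Ne*T in all uses.
.int_exp_neg_A <- function(lo, hi, a, b, rel_tol = 1e-12) {
  if (abs(a) > 200 || abs(b) > 200)
    stop("selection intensity out of the supported range: |4NeS| = ",
         abs(a), ", |2NeT| = ", abs(b), " (must be <= 200)", call. = FALSE)
  h <- function(x) -(a * x + b * x^2)
  cand <- c(lo, hi)
  if (b < 0) {                       # -(a x + b x^2) concave max interior
    xstar <- -a / (2 * b)
    if (xstar > lo && xstar < hi) cand <- c(cand, xstar)
  }
  M <- max(h(cand))
  stats::integrate(function(x) exp(h(x) - M), lo, hi,
                   rel.tol = rel_tol, abs.tol = 0)$value * exp(M)
}

# A(q) = 4*Ne*S*q + 2*Ne*T*q^2, the integrated scaled drift exponent.
.drift_exponent <- function(q, Ne, S, T) 4 * Ne * S * q + 2 * Ne * T * q^2

#' Flux-equilibrium density of the mutant allele frequency
#'
#' The steady-state density of the mutant allele frequency under a constant
#' flux of irreversible mutation into fixation. It solves the constant-flux
#' steady state of the forward equation with drift `M(q) = (S + Tq)q(1-q)`
#' and drift variance `V(q) = q(1-q)/(2Ne)`:
#' \deqn{\phi(q) = \frac{4 N_e \mu}{q(1-q)}\, e^{A(q)}
#'   \frac{\int_q^1 e^{-A(x)}dx}{\int_0^1 e^{-A(x)}dx},
#'   \quad A(q) = 4N_eSq + 2N_eTq^2,}
#' which reduces to `4*Ne*mu/q` in the neutral case. The class frequencies
#' are `f(q) = phi(q)/(2Ne)` on the heteroallelic grid
#' `q = 1/2Ne, ..., 1 - 1/2Ne`, and the decay (gene-fixation) rate is
#' `K = mu / int_0^1 exp(-A)` (see [decay_rate_K()]); the subterminal class
#' satisfies `f(1 - 1/2Ne) ~= 2K`.
#'
#' @param params A [selfix_params] with `Ne >= 2` and `mu > 0`.
#' @return An object of class `"flux_distribution"`: list with `q_grid`,
#'   `phi`, `f` (= `phi/2Ne`), `f_sub_low`, `f_sub_high`, `K`, and the
#'   composite coefficients `S`, `T`.
#' @examples
#' phi_flux(selfix_params(alpha = 0, mu = 1e-4, Ne = 30))
#' @export
phi_flux <- function(params) {
  stopifnot(inherits(params, "selfix_params"))
  if (is.null(params$Ne)) stop("'params' must carry Ne", call. = FALSE)
  if (params$mu <= 0) stop("phi_flux requires mu > 0", call. = FALSE)
  Ne <- params$Ne
  cs <- composite_selection(params)
  a <- 4 * Ne * cs$S; b <- 2 * Ne * cs$T
  q <- (1:(2 * Ne - 1)) / (2 * Ne)
  I0 <- .int_exp_neg_A(0, 1, a, b)
  Iq <- vapply(q, function(qi) .int_exp_neg_A(qi, 1, a, b), numeric(1))
  phi <- 4 * Ne * params$mu / (q * (1 - q)) *
    exp(.drift_exponent(q, Ne, cs$S, cs$T)) * Iq / I0
  f <- phi / (2 * Ne)
  structure(list(q_grid = q, phi = phi, f = f,
                 f_sub_low = f[1L], f_sub_high = f[length(f)],
                 K = params$mu / I0, S = cs$S, T = cs$T,
                 Ne = Ne, params = params),
            class = "flux_distribution")
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat(sprintf("flux-equilibrium density on %d heteroallelic classes (Ne = %d)\n",
              length(x$q_grid), x$Ne))
  cat(sprintf("  S = %.6g, T = %.6g; K = %.6g (K/mu = %.6g)\n",
              x$S, x$T, x$K, x$K / x$params$mu))
  cat(sprintf("  f(1/2Ne) = %.6g, f(1-1/2Ne) = %.6g (~ 2K = %.6g)\n",
              x$f_sub_low, x$f_sub_high, 2 * x$K))
  invisible(x)
}

#' Fixation probability from the flux-equilibrium density
#'
#' Wright's fixation probability of a mutant allele present at initial
#' frequency `1/2Ne`: the ratio of the subterminal class frequencies,
#' `u(1/2Ne) = f(1 - 1/2Ne) / f(1/2Ne)`. Because the two subterminal classes
#' satisfy `q(1-q)` symmetry, the mutation rate cancels exactly and
#' \deqn{u = e^{A(1-1/2N_e) - A(1/2N_e)}
#'   \frac{\int_{1-1/2N_e}^1 e^{-A}}{\int_{1/2N_e}^1 e^{-A}},}
#' equal to `(1/2Ne)/(1 - 1/2Ne)` in the neutral case.
#'
#' @param params A [selfix_params] with `Ne >= 2` (`mu` is irrelevant: it
#'   cancels).
#' @return The fixation probability (scalar).
#' @examples
#' fixation_prob_wright(selfix_params(alpha = 0, Ne = 30))  # 1/59
#' @export
fixation_prob_wright <- function(params) {
  stopifnot(inherits(params, "selfix_params"))
  if (is.null(params$Ne)) stop("'params' must carry Ne", call. = FALSE)
  Ne <- params$Ne
  cs <- composite_selection(params)
  a <- 4 * Ne * cs$S; b <- 2 * Ne * cs$T
  qL <- 1 / (2 * Ne); qH <- 1 - qL
  exp(.drift_exponent(qH, Ne, cs$S, cs$T) - .drift_exponent(qL, Ne, cs$S, cs$T)) *
    .int_exp_neg_A(qH, 1, a, b) / .int_exp_neg_A(qL, 1, a, b)
}

#' Gene-fixation (decay) rate K under flux equilibrium
#'
#' The constant per-generation rate at which the heteroallelic class
#' frequencies decay as genes drift irreversibly into fixation:
#' `K = mu / int_0^1 exp(-A(x)) dx` with `A(q) = 4NeSq + 2NeTq^2`. `K = mu`
#' for a neutral allele; for small `2NeS`, `2NeT` it expands as
#' `mu (1 + 2NeS + ...)`. The `"psi"` route evaluates the integral through
#' the identity `int_0^1 exp(-A) = psi(2NeS + NeT, NeT/2) *
#' exp(-2NeS - 3NeT/4)`; `"quadrature"` integrates directly.
#'
#' @param params A [selfix_params] with `Ne` and `mu > 0`.
#' @param method `"psi"` (default) or `"quadrature"`.
#' @return The decay rate per generation.
#' @examples
#' decay_rate_K(selfix_params(alpha = 0, mu = 1e-4, Ne = 30))  # mu, neutral
#' @export
decay_rate_K <- function(params, method = c("psi", "quadrature")) {
  stopifnot(inherits(params, "selfix_params"))
  method <- match.arg(method)
  if (is.null(params$Ne)) stop("'params' must carry Ne", call. = FALSE)
  if (params$mu <= 0) stop("decay_rate_K requires mu > 0", call. = FALSE)
  Ne <- params$Ne
  cs <- composite_selection(params)
  if (method == "quadrature")
    return(params$mu / .int_exp_neg_A(0, 1, 4 * Ne * cs$S, 2 * Ne * cs$T))
  x <- 2 * Ne * cs$S + Ne * cs$T
  y <- Ne * cs$T / 2
  I0 <- psi_wright(x, y) * exp(-2 * Ne * cs$S - 0.75 * Ne * cs$T)
  params$mu / I0
}

#' Ratio K/mu under the linear additive sporophytic model
#'
#' Closed form of the fixation-rate-to-mutation-rate ratio when
#' `shom = 2 shet` (so the frequency-dependent composite coefficient `T`
#' vanishes): with `X = -(1/2)(1 - Fis) shap + (1 + Fis) shet`,
#' \deqn{K/\mu = \frac{4 N_e X}{1 - e^{-4 N_e X}}.}
#' The ratio equals 1 for a neutral allele, exceeds 1 for a net-favourable
#' allele (`X > 0`) and falls below 1 for a net-deleterious one.
#'
#' @param params A [selfix_params] with `Ne` and `shom = 2 shet` (enforced).
#' @return The dimensionless ratio `K/mu`.
#' @examples
#' k_over_mu_additive(selfix_params(alpha = 0.5, shet = -0.01, shom = -0.02,
#'                                  Ne = 30))
#' @export
k_over_mu_additive <- function(params) {
  stopifnot(inherits(params, "selfix_params"))
  if (is.null(params$Ne)) stop("'params' must carry Ne", call. = FALSE)
  if (abs(params$shom - 2 * params$shet) > 1e-12)
    stop("k_over_mu_additive requires the additive sporophytic model shom = 2*shet",
         call. = FALSE)
  Fis <- params$Fis
  X <- -0.5 * (1 - Fis) * params$shap + (1 + Fis) * params$shet
  z <- 4 * params$Ne * X
  if (abs(z) < 1e-10) return(1)
  z / (-expm1(-z))
}

#' Genetic load of the mutant allele
#'
#' `load_infinite()` gives the reduction of mean population fitness (product
#' of gametophyte- and sporophyte-phase mean fitnesses, minus one) in an
#' infinitely large population at mutant frequency `q`:
#' \deqn{L(q) = q\left(-s_{hap} + 2p(1-F_{is})s_{het}
#'   + (q + pF_{is})s_{hom}\right),}
#' which equals `-shap + shom` at fixation (`q = 1`). `load_finite_mean()`
#' integrates `L(q)` against the flux-equilibrium density over the
#' heteroallelic band `[1/2Ne, 1 - 1/2Ne]` (the density diverges like `1/q`
#' at 0); by default the raw (unnormalised) density is used, matching the
#' definition of the mean load as an expectation over class occupancies;
#' `normalize = TRUE` instead rescales the density to unit mass on the band.
#'
#' @param q Mutant allele frequency (vectorised).
#' @param params A [selfix_params] object (finite-size version requires `Ne`
#'   and `mu > 0`).
#' @param normalize Normalise the density to total mass one on the
#'   heteroallelic band before integrating?
#' @return Load value(s); negative values mean reduced fitness for
#'   deleterious parameters under this sign convention.
#' @examples
#' load_infinite(1, selfix_params(sO = 0.01, sP = 0, shom = -0.03))
#' @export
load_infinite <- function(q, params) {
  stopifnot(inherits(params, "selfix_params"))
  if (any(q < 0 | q > 1)) stop("'q' must lie in [0, 1]", call. = FALSE)
  p <- 1 - q
  Fis <- params$Fis
  q * (-params$shap + 2 * p * (1 - Fis) * params$shet +
         (q + p * Fis) * params$shom)
}

#' @rdname load_infinite
#' @export
load_finite_mean <- function(params, normalize = FALSE) {
  stopifnot(inherits(params, "selfix_params"))
  if (is.null(params$Ne)) stop("'params' must carry Ne", call. = FALSE)
  if (params$mu <= 0) stop("load_finite_mean requires mu > 0", call. = FALSE)
  Ne <- params$Ne
  cs <- composite_selection(params)
  a <- 4 * Ne * cs$S; b <- 2 * Ne * cs$T
  I0 <- .int_exp_neg_A(0, 1, a, b)
  phi_fun <- function(q) {
    Iq <- vapply(q, function(qi) .int_exp_neg_A(qi, 1, a, b), numeric(1))
    4 * Ne * params$mu / (q * (1 - q)) *
      exp(.drift_exponent(q, Ne, cs$S, cs$T)) * Iq / I0
  }
  qL <- 1 / (2 * Ne); qH <- 1 - qL
  num <- stats::integrate(function(q) load_infinite(q, params) * phi_fun(q),
                          qL, qH, rel.tol = 1e-10, abs.tol = 0)$value
  if (!normalize) return(num)
  den <- stats::integrate(phi_fun, qL, qH, rel.tol = 1e-10, abs.tol = 0)$value
  num / den
}
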