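#' Diffusion (Kimura) fixation probability under selection and drift
#'
#' The classical diffusion fixation probability for the life-cycle drift
#' term `M(q) = (S + Tq)q(1-q)` and variance `V(q) = q(1-q)/(2Ne)`, without
#' the irreversible mutation term:
#' \deqn{u(p_0) = \frac{\int_0^{p_0} G(x)\,dx}{\int_0^1 G(x)\,dx}, \qquad
#'   G(x) = e^{-4N_eSx - 2N_eTx^2}.}
#' Neutrality gives `u(p0) = p0` exactly; for `T = 0` the closed form
#' `u = (1 - exp(-4NeS p0)) / (1 - exp(-4NeS))` applies.
#'
#' @param params A [selfix_params] with `Ne`.
#' @param p0 Initial mutant frequency in `(0, 1)`; default `1/(2Ne)`.
#' @param Ne Optional override of the effective size used in the scaled
#'   intensities (a real value is accepted; useful for exact
#'   census/effective-size algebra).
#' @return The fixation probability (vectorised over `p0`).
#' @examples
#' fixation_prob_diffusion(selfix_params(alpha = 0, Ne = 30))  # 1/60
#' @export
fixation_prob_diffusion <- function(params, p0 = NULL, Ne = NULL) {
  stopifnot(inherits(params, "selfix_params"))
  if (is.null(Ne)) Ne <- params$Ne
  if (is.null(Ne)) stop("'params' must carry Ne (or pass Ne)", call. = FALSE)
  if (is.null(p0)) p0 <- 1 / (2 * Ne)
  if (any(p0 <= 0 | p0 >= 1)) stop("'p0' must lie in (0, 1)", call. = FALSE)
  cs <- composite_selection(params)
  a <- 4 * Ne * cs$S; b <- 2 * Ne * cs$T
  den <- .int_exp_neg_A(0, 1, a, b)
  vapply(p0, function(x) .int_exp_neg_A(0, x, a, b) / den, numeric(1))
}

#' Census- vs effective-size scaling of the diffusion fixation probability
#'
#' A new mutation arises as one copy among `2N` gene copies (frequency
#' `1/2N`), while the drift intensity is governed by `Ne = N/(1 + Fis)`.
#' This check evaluates `u(1/2Ne)` and `u(1/2N)` from the same diffusion and
#' reports the relative deviation from the two first-order scaling
#' relations: `u(1/2Ne) = (1 + Fis) u(1/2N)` (exact up to the curvature of
#' `u` in `p0`; the natural regime is the additive sporophytic model where
#' `u(1/2N)` is selfing-independent) and the reverse reading
#' `u(1/2N) = (1 - Fis) u(1/2Ne)` (first order in `Fis` only: the two
#' deviations differ by a term of order `Fis^2`). At `Fis = 0` the two
#' initialisations coincide and both relations are exact.
#'
#' @param params A [selfix_params] carrying `Ne` or `N`.
#' @return List with `u_half_Ne`, `u_half_N`, `Fis`, and the relative
#'   deviations `dev_forward` (`|u(1/2Ne) - (1+Fis)u(1/2N)| / u(1/2Ne)`) and
#'   `dev_reverse` (`|u(1/2N) - (1-Fis)u(1/2Ne)| / u(1/2N)`).
#' @examples
#' p <- selfix_params(alpha = 0.5, shet = -0.01, shom = -0.02, N = 40)
#' scaling_relations_check(p)
#' @export
scaling_relations_check <- function(params) {
  stopifnot(inherits(params, "selfix_params"))
  if (is.null(params$N)) stop("'params' must carry N or Ne", call. = FALSE)
  Fis <- params$Fis
  Ne_real <- params$N / (1 + Fis)   # exact, unrounded
  u_Ne <- fixation_prob_diffusion(params, p0 = 1 / (2 * Ne_real), Ne = Ne_real)
  u_N <- fixation_prob_diffusion(params, p0 = 1 / (2 * params$N), Ne = Ne_real)
  list(u_half_Ne = u_Ne, u_half_N = u_N, Fis = Fis,
       dev_forward = abs(u_Ne - (1 + Fis) * u_N) / u_Ne,
       dev_reverse = abs(u_N - (1 - Fis) * u_Ne) / u_N)
}

#' Selfing-independence of u(1/2N) under additive sporophytic selection
#'
#' For genes expressed in the sporophyte phase only with linear additive
#' selection (`shap = 0`, `shom = 2 shet`), the scaled intensity satisfies
#' `4NeS = 4N shet` for every selfing rate, so the diffusion fixation
#' probability of a new mutation (`p0 = 1/2N`, census size fixed) is
#' independent of `alpha`. Dominance (`shom != 2 shet`) breaks the
#' independence.
#'
#' @param params A [selfix_params] carrying `N` (its `alpha` is ignored);
#'   `sO = sP = 0` is required, `shom = 2 shet` is *not* enforced so the
#'   broken case can be quantified.
#' @param alpha_grid Selfing rates to evaluate.
#' @return List with the data frame `u` (columns `alpha`, `u_half_N`) and
#'   `relative_spread` (`(max - min)/mean`).
#' @examples
#' p <- selfix_params(shet = -0.01, shom = -0.02, N = 60)
#' additivity_independence_check(p)$relative_spread   # ~0
#' @export
additivity_independence_check <- function(params,
                                          alpha_grid = c(0, 0.25, 0.5, 0.75, 1)) {
  stopifnot(inherits(params, "selfix_params"))
  if (is.null(params$N)) stop("'params' must carry N or Ne", call. = FALSE)
  if (params$sO != 0 || params$sP != 0)
    stop("sporophyte-only check: sO and sP must be 0", call. = FALSE)
  N <- params$N
  u <- vapply(alpha_grid, function(a) {
    p <- selfix_params(alpha = a, shet = params$shet, shom = params$shom,
                       mu = params$mu)
    Ne_real <- N / (1 + p$Fis)
    fixation_prob_diffusion(p, p0 = 1 / (2 * N), Ne = Ne_real)
  }, numeric(1))
  list(u = data.frame(alpha = alpha_grid, u_half_N = u),
       relative_spread = (max(u) - min(u)) / mean(u))
}
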