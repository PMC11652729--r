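#' Exact allele-count Markov chain for small populations
#'
#' The Wright-Fisher chain underlying both analytic approximations: the
#' population is collapsed to the count `i` of mutant gene copies among
#' `2Ne` (`q = i/2Ne`), and the next generation count is binomial,
#' `i' ~ Binomial(2Ne, q + Delta q(q))`, with `Delta q` the weak-selection
#' systematic change at mating-system-equilibrium inbreeding
#' ([delta_q_weak()]). With mutation off both boundary states are absorbing;
#' with one-way mutation on, only fixation (`i = 2Ne`) absorbs. Expected
#' frequencies falling outside `[0, 1]` are clamped; clamping events are
#' counted and reported (the supported parameter ranges produce none).
#'
#' @param params A [selfix_params]; `Ne` may be overridden.
#' @param Ne Effective size (defaults to `params$Ne`).
#' @param mutation Include one-way mutation in the expected-frequency map
#'   (and make only fixation absorbing)?
#' @return An object of class `"allele_count_chain"`: list with the
#'   `(2Ne+1) x (2Ne+1)` transition matrix `P` (rows sum to one), `Ne`,
#'   `mutation` flag, `clamped` count and `params`.
#' @examples
#' ch <- allele_count_chain(selfix_params(alpha = 0, sO = 0.02, sP = 0.02),
#'                          Ne = 12)
#' absorption_probability(ch, 1)
#' @export
allele_count_chain <- function(params, Ne = NULL, mutation = FALSE) {
  stopifnot(inherits(params, "selfix_params"))
  if (is.null(Ne)) Ne <- params$Ne
  if (is.null(Ne)) stop("'params' must carry Ne (or pass Ne)", call. = FALSE)
  if (mutation && params$mu <= 0)
    stop("mutation = TRUE requires mu > 0", call. = FALSE)
  n <- 2 * Ne
  q <- (0:n) / n
  m <- q + delta_q_weak(q, params, include_mutation = mutation)
  clamped <- sum(m < 0 | m > 1)
  if (clamped > 0) {
    warning(clamped, " expected frequencies clamped to [0, 1]", call. = FALSE)
    m <- pmin(pmax(m, 0), 1)
  }
  P <- t(vapply(m, function(mi) stats::dbinom(0:n, n, mi), numeric(n + 1)))
  P[n + 1, ] <- 0; P[n + 1, n + 1] <- 1           # fixation absorbs
  if (!mutation) { P[1, ] <- 0; P[1, 1] <- 1 }    # loss absorbs without mutation
  structure(list(P = P, Ne = Ne, mutation = mutation, clamped = clamped,
                 params = params),
            class = "allele_count_chain")
}

#' @export
print.allele_count_chain <- function(x, ...) {
  cat(sprintf("allele-count chain: 2Ne = %d (%d states), mutation %s\n",
              2 * x$Ne, 2 * x$Ne + 1, if (x$mutation) "on" else "off"))
  invisible(x)
}

#' Exact fixation probability of the allele-count chain
#'
#' Solves the first-step linear system for the probability that the chain
#' is absorbed at fixation (`i = 2Ne`) rather than loss, starting from `i0`
#' mutant copies. Requires the mutation-off chain (with one-way mutation
#' every trajectory fixes eventually and the probability is trivially 1).
#'
#' @param chain An [allele_count_chain()] built with `mutation = FALSE`.
#' @param i0 Initial copy number(s), `0 < i0 < 2Ne` (vectorised).
#' @return Fixation probability for each `i0`.
#' @export
absorption_probability <- function(chain, i0) {
  stopifnot(inherits(chain, "allele_count_chain"))
  if (chain$mutation)
    stop("absorption_probability requires a mutation-off chain", call. = FALSE)
  n <- 2 * chain$Ne
  if (any(i0 <= 0 | i0 >= n | i0 != round(i0)))
    stop("'i0' must be an integer strictly between 0 and 2Ne", call. = FALSE)
  trans <- 2:n                 # transient states 1..(2Ne-1), 1-based rows 2..n
  Q <- chain$P[trans, trans, drop = FALSE]
  r <- chain$P[trans, n + 1]   # one-step probability of hitting fixation
  u <- solve(diag(length(trans)) - Q, r)
  u[i0]
}

#' Quasi-stationary distribution and decay rate of the mutation-flux chain
#'
#' With one-way mutation on, fixation is the only absorbing state and the
#' transient states (`i = 0, ..., 2Ne - 1`) lose mass at an asymptotically
#' constant rate: the decay rate is `1 - lambda`, with `lambda` the dominant
#' eigenvalue of the transient sub-kernel, and the quasi-stationary
#' distribution is the associated (left) eigenvector. This is the exact
#' finite-`Ne` counterpart of the flux-equilibrium decay rate `K` and
#' density `phi`.
#'
#' @param chain An [allele_count_chain()] built with `mutation = TRUE`.
#' @param power_iteration Force power iteration instead of a dense eigen
#'   decomposition (automatic for `Ne > 50`).
#' @param tol,max_iter Convergence controls for the power iteration.
#' @return List with `decay_rate`, `lambda`, `distribution` (probabilities
#'   over the transient states, summing to one) and `q` (their allele
#'   frequencies `i/2Ne`).
#' @export
quasi_stationary <- function(chain, power_iteration = NULL,
                             tol = 1e-13, max_iter = 1e5) {
  stopifnot(inherits(chain, "allele_count_chain"))
  if (!chain$mutation)
    stop("quasi_stationary requires a mutation-on chain", call. = FALSE)
  n <- 2 * chain$Ne
  Q <- chain$P[1:n, 1:n, drop = FALSE]   # transient states 0..(2Ne-1)
  if (is.null(power_iteration)) power_iteration <- chain$Ne > 50
  if (!power_iteration) {
    e <- eigen(t(Q))
    k <- which.max(Re(e$values))
    lambda <- Re(e$values[k])
    v <- Re(e$vectors[, k])
    if (max(abs(Im(e$values[k]))) > 1e-10)
      stop("dominant eigenvalue is not real; eigen solve failed", call. = FALSE)
  } else {
    v <- rep(1 / n, n); lambda <- NA_real_
    for (it in seq_len(max_iter)) {
      w <- as.vector(v %*% Q)
      lam_new <- sum(w)
      w <- w / lam_new
      if (max(abs(w - v)) < tol) { v <- w; lambda <- lam_new; break }
      v <- w
    }
    if (is.na(lambda))
      stop("power iteration did not converge in ", max_iter, " iterations",
           call. = FALSE)
  }
  if (all(v <= 0)) v <- -v
  if (any(v < -1e-8 * max(abs(v))))
    stop("quasi-stationary eigenvector has mixed signs", call. = FALSE)
  v <- pmax(v, 0); v <- v / sum(v)
  list(decay_rate = 1 - lambda, lambda = lambda,
       distribution = v, q = (0:(n - 1)) / n)
}
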