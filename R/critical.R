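#' Critical selfing rates for deterministic fixation of a mutant allele
#'
#' In an infinitely large population the mutant allele reaches fixation
#' (rather than an interior mutation-selection equilibrium) only on one side
#' of a critical selfing rate `alpha*`. The boundary is obtained by setting
#' the systematic frequency change to zero in the limit `q -> 1`: writing
#' `Delta q / p` at `q = 1` gives the condition
#' \deqn{\mu + s_{hom} \ge (1 - F_{is})\,(s_{het} + s_{hap}/2)}
#' with `Fis = alpha/(2 - alpha)`. Solving for the boundary with
#' `r = (mu + shom) / (shet + shap/2)` yields
#' \deqn{\alpha^{*} = \frac{2(1 - r)}{2 - r}, \qquad 0 \le r \le 1,}
#' which specialises to the gametophyte-only (`shet = shom = 0`, so
#' `r = 2 mu / shap`), sporophyte-only (`shap = 0`, `r = (mu+shom)/shet`) and
#' biphasic regimes. When `shet + shap/2 > 0` fixation occurs *above*
#' `alpha*`; when negative (e.g. a sporophyte-deleterious allele) fixation
#' occurs *below* it, i.e. selfing impedes fixation.
#'
#' The `q -> 1` condition is necessary but not always sufficient: for
#' synergistic deleterious alleles (and sporophytic-deleterious alleles at
#' low selfing) the frequency change can dip negative at low `q`, trapping
#' the allele at a low interior equilibrium. [critical_alpha_biphasic()]
#' applies the synergistic existence condition
#' `shet + shap/2 > mu + shom > 0`; [critical_alpha_numeric()] detects every
#' actual boundary by iterating the exact recursion.
#'
#' @param mu One-way mutation rate (`>= 0`).
#' @param shap Composite gametophytic coefficient `sO + sP` (deleterious
#'   when positive).
#' @param shet,shom Sporophytic selection coefficients (deleterious when
#'   negative).
#' @return An object of class `"critical_rate"`: list with
#'   \describe{
#'     \item{alpha_star}{the boundary selfing rate, or `NA` for the
#'       sentinel statuses;}
#'     \item{status}{`"boundary"`, `"always-fixes"` or `"never-fixes"`;}
#'     \item{direction}{`"above"` or `"below"`: the side of `alpha_star`
#'       on which fixation occurs;}
#'     \item{regime}{which expression regime applies;}
#'     \item{validity}{list with the ratio `r` and whether the classical
#'       condition `0 <= r <= 1` holds.}
#'   }
#' @examples
#' critical_alpha_gametophytic(mu = 1e-4, shap = 1e-3)
#' critical_alpha_sporophytic(mu = 1e-4, shet = -1e-3, shom = -2e-4)
#' @name critical_alpha
NULL

# q -> 1 boundary analysis shared by the three regimes.
.critical_core <- function(mu, shap, shet, shom, regime) {
  numer <- mu + shom
  D <- shet + shap / 2
  res <- list(alpha_star = NA_real_, status = NA_character_,
              direction = NA_character_, regime = regime,
              validity = list(ratio = NA_real_, holds = NA))
  if (D == 0) {
    res$status <- if (numer >= 0) "always-fixes" else "never-fixes"
    class(res) <- "critical_rate"
    return(res)
  }
  r <- numer / D
  res$validity <- list(ratio = r, holds = r >= 0 && r <= 1)
  res$direction <- if (D > 0) "above" else "below"
  if (r >= 0 && r <= 1) {
    res$alpha_star <- 2 * (1 - r) / (2 - r)
    res$status <- "boundary"
  } else if (D > 0) {
    # condition mu + shom >= (1-Fis) D: monotone increasing in alpha
    res$status <- if (r > 1) "always-fixes" else "never-fixes"
  } else {
    # D < 0: condition monotone decreasing in alpha
    res$status <- if (r < 0) "always-fixes" else "never-fixes"
  }
  class(res) <- "critical_rate"
  res
}

#' @export
print.critical_rate <- function(x, ...) {
  cat(sprintf("critical selfing rate (%s regime): ", x$regime))
  if (x$status == "boundary")
    cat(sprintf("alpha* = %.6g, fixation %s alpha*\n", x$alpha_star, x$direction))
  else cat(x$status, "\n")
  if (!is.na(x$validity$holds) && !x$validity$holds)
    cat(sprintf("  note: validity ratio r = %.4g lies outside [0, 1]\n",
                x$validity$ratio))
  invisible(x)
}

#' @describeIn critical_alpha genes expressed in the gametophyte phase only
#'   (`shet = shom = 0`); `r = 2 mu / shap`, fixation above `alpha*` for a
#'   deleterious allele, `always-fixes` for a favourable one.
#' @export
critical_alpha_gametophytic <- function(mu, shap) {
  stopifnot(mu >= 0, shap != 0)
  .critical_core(mu, shap, 0, 0, regime = "gametophyte-only")
}

#' @describeIn critical_alpha genes expressed in the sporophyte phase only
#'   (`shap = 0`); `r = (mu + shom)/shet` with validity `0 <= r <= 1`. For a
#'   deleterious allele fixation occurs *below* `alpha*` (selfing impedes
#'   fixation).
#' @export
critical_alpha_sporophytic <- function(mu, shet, shom) {
  stopifnot(mu >= 0, shet != 0)
  .critical_core(mu, 0, shet, shom, regime = "sporophyte-only")
}

#' @describeIn critical_alpha genes expressed in both phases. Antagonistic
#'   regimes use the generic boundary; the synergistic deleterious regime
#'   (`shap > 0`, `shet <= 0`, `shom <= 0`) additionally requires the
#'   existence condition `shet + shap/2 > mu + shom > 0`, failing which the
#'   allele is held at a low interior equilibrium (`never-fixes`); an allele
#'   favourable in both phases `always-fixes`.
#' @export
critical_alpha_biphasic <- function(mu, shap, shet, shom) {
  stopifnot(mu >= 0)
  if (shet + shap / 2 == 0)
    return(.critical_core(mu, shap, shet, shom, regime = "biphasic"))
  syn_del <- shap > 0 && shet <= 0 && shom <= 0
  syn_fav <- shap < 0 && shet >= 0 && shom >= 0
  if (syn_fav) {
    res <- .critical_core(mu, shap, shet, shom, regime = "biphasic synergistic (favourable)")
    res$status <- "always-fixes"; res$alpha_star <- NA_real_
    res$direction <- NA_character_
    return(res)
  }
  if (syn_del) {
    res <- .critical_core(mu, shap, shet, shom, regime = "biphasic synergistic (deleterious)")
    D <- shet + shap / 2; numer <- mu + shom
    if (!(D > 0 && numer > 0 && numer < D)) {
      # existence condition shet + shap/2 > mu + shom > 0 fails: the mutant
      # is trapped at a low mutation-selection equilibrium
      res$status <- "never-fixes"; res$alpha_star <- NA_real_
      res$direction <- NA_character_
    }
    return(res)
  }
  .critical_core(mu, shap, shet, shom, regime = "biphasic antagonistic")
}

# Aitken delta-squared on three equally spaced sequence values.
.aitken3 <- function(x0, x1, x2) {
  if (anyNA(c(x0, x1, x2)) || any(!is.finite(c(x0, x1, x2)))) return(NA_real_)
  d1 <- x1 - x0; d2 <- x2 - x1
  den <- d2 - d1
  if (!is.finite(den) || abs(den) < 1e-300) return(x2)
  res <- x2 - d2^2 / den
  if (!is.finite(res)) x2 else res
}

# Classify the deterministic fate at one selfing rate by iterating the exact
# life-cycle recursion from a low frequency. Near a critical selfing rate
# the approach to the limit suffers critical slowing-down and the q
# trajectory is Moebius-like (a ratio of geometric terms), so a single
# Aitken extrapolation converges too slowly; an iterated (two-level) Aitken
# on widely spaced block samples estimates the limit, and a classification
# is accepted only when the estimate is stable, close to the current
# frequency relative to the remaining distance, and (for an interior call)
# the motion has genuinely stalled. The inner recursion is inlined for
# speed (it is the hot loop of the bisection oracle).
.classify_fate <- function(alpha, params, q0 = 0.01, block = 400L,
                           max_gen = 2e6) {
  Fis <- inbreeding_equilibrium(alpha)
  st <- equilibrium_state(q0, Fis)
  pAA <- st[["pAA"]]; pAa <- st[["pAa"]]; paa <- st[["paa"]]
  sO <- params$sO; sP <- params$sP
  shet <- params$shet; shom <- params$shom; mu <- params$mu
  oa <- (1 - sO) / (2 - sO); pa <- (1 - sP) / (2 - sP)
  whet <- 1 + shet; whom <- 1 + shom
  m2 <- (1 - mu)^2; m11 <- 2 * mu * (1 - mu); m1 <- 1 - mu
  onema <- 1 - alpha
  qs <- numeric(0)
  last_final <- NA_real_
  gen <- 0L
  repeat {
    for (i in seq_len(block)) {
      q <- paa + pAa / 2
      sAA <- pAA + pAa * (1 - oa) * (1 - pa)
      saa <- paa + pAa * oa * pa
      sAa <- pAa * (oa * (1 - pa) + (1 - oa) * pa)
      qo <- q * (1 - sO) / (1 - sO * q)
      qp <- q * (1 - sP) / (1 - sP * q)
      zAA <- alpha * sAA + onema * (1 - qo) * (1 - qp)
      zAa <- alpha * sAa + onema * (qo * (1 - qp) + (1 - qo) * qp)
      zaa <- alpha * saa + onema * qo * qp
      mAA <- zAA * m2
      mAa <- zAA * m11 + zAa * m1
      maa <- zAA * mu * mu + zAa * mu + zaa
      wbar <- mAA + mAa * whet + maa * whom
      pAA <- mAA / wbar; pAa <- mAa * whet / wbar; paa <- maa * whom / wbar
    }
    gen <- gen + block
    q <- paa + pAa / 2
    qs[length(qs) + 1L] <- q
    if (q >= 1 - 1e-9) return("fixed")
    k <- length(qs)
    d2 <- if (k >= 2L) qs[k] - qs[k - 1L] else NA_real_
    if (k >= 2L && abs(d2) < 1e-15)
      return(if (q >= 1 - 3e-4) "fixed" else "interior")
    if (k >= 9L) {
      s <- max(1L, (k - 1L) %/% 4L)
      idx <- k - (4:0) * s          # five samples with growing spacing
      a1 <- .aitken3(qs[idx[1]], qs[idx[2]], qs[idx[3]])
      a2 <- .aitken3(qs[idx[2]], qs[idx[3]], qs[idx[4]])
      a3 <- .aitken3(qs[idx[3]], qs[idx[4]], qs[idx[5]])
      final <- .aitken3(a1, a2, a3)
      ok <- !is.na(final) && is.finite(final) && !is.na(last_final) &&
        abs(final - last_final) < 2e-5 &&
        final >= q - 1e-6 && (final - q) < 0.25 * (1 - q) + 1e-5
      if (ok) {
        if (final >= 1 - 2e-4) return("fixed")
        if (final < 1 - 4e-4 && abs(d2) < 1e-6) return("interior")
      }
      last_final <- if (!is.na(final) && is.finite(final)) final else NA_real_
    }
    if (gen >= max_gen) {
      if (q >= 1 - 3e-4) return("fixed")
      if (!is.na(last_final) && last_final >= 1 - 3e-4) return("fixed")
      # trend of the log-distance slope: constant slope = steady exponential
      # escape towards fixation; decaying slope = stalling at an interior
      # equilibrium
      if (k >= 8L) {
        m <- max(2L, k %/% 4L)
        z <- log1p(-qs[c(k - 2L * m, k - m, k)])
        s_prev <- z[2] - z[1]; s_rec <- z[3] - z[2]
        if (s_rec < 0 && s_prev < 0 && s_rec / s_prev > 0.8) return("fixed")
      }
      return("interior")
    }
  }
}

#' Numerical critical selfing rates from the exact recursion
#'
#' Verification oracle for the analytic critical rates: classifies the
#' deterministic fate (fixation vs interior equilibrium) of the mutant
#' allele on a grid of selfing rates by iterating the exact life-cycle
#' recursion from a low initial frequency, then bisects every
#' fixed/interior boundary to `alpha_tol`. The outcome over `alpha` can be
#' non-monotone (sporophytic-deleterious alleles have, besides the upper
#' `q -> 1` boundary, a lower boundary below which heterozygote selection
#' traps the rare allele at a low interior equilibrium), so *all* boundaries
#' are returned, each with its empirically probed direction.
#'
#' @param params A [selfix_params] object with `mu > 0`; its `alpha` slot is
#'   ignored (swept).
#' @param alpha_tol Bisection half-width on the boundary.
#' @param q0 Initial mutant frequency for the recursion.
#' @param grid_n Number of grid points used for the initial outcome scan.
#' @param max_gen Generation cap per classification.
#' @return List with `outcomes` (data frame: `alpha`, `fate` on the scan
#'   grid) and `boundaries` (data frame: `alpha_star`, `direction`
#'   (`"above"`/`"below"`, side on which fixation occurs)); zero rows means
#'   the fate is uniform in `alpha` (`always-fixes` / `never-fixes`,
#'   reported in `uniform`).
#' @examples
#' \donttest{
#' p <- selfix_params(alpha = 0, sO = 5e-4, sP = 5e-4, mu = 1e-4)
#' critical_alpha_numeric(p, alpha_tol = 1e-3, grid_n = 11)$boundaries
#' }
#' @export
critical_alpha_numeric <- function(params, alpha_tol = 1e-3, q0 = 0.01,
                                   grid_n = 21L, max_gen = 2e6) {
  stopifnot(inherits(params, "selfix_params"), alpha_tol > 0, params$mu > 0)
  grid <- seq(0, 1, length.out = grid_n)
  fate <- vapply(grid, .classify_fate, character(1),
                 params = params, q0 = q0, max_gen = max_gen)
  boundaries <- NULL
  for (k in seq_len(grid_n - 1L)) {
    if (fate[k] == fate[k + 1L]) next
    lo <- grid[k]; hi <- grid[k + 1L]
    f_lo <- fate[k]
    while (hi - lo > alpha_tol) {
      mid <- (lo + hi) / 2
      if (.classify_fate(mid, params, q0 = q0, max_gen = max_gen) == f_lo)
        lo <- mid else hi <- mid
    }
    direction <- if (f_lo == "interior") "above" else "below"
    boundaries <- rbind(boundaries,
                       data.frame(alpha_star = (lo + hi) / 2, direction = direction))
  }
  uniform <- if (is.null(boundaries)) {
    if (all(fate == "fixed")) "always-fixes" else "never-fixes"
  } else NA_character_
  list(outcomes = data.frame(alpha = grid, fate = fate),
       boundaries = if (is.null(boundaries))
         data.frame(alpha_star = numeric(0), direction = character(0))
       else boundaries,
       uniform = uniform)
}
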