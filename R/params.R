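#' Model parameters for a biallelic locus under partial selfing
#'
#' Bundles and validates the parameters of the mixed-mating life-cycle model:
#' a single nuclear locus with ancestral allele `A` and mutant allele `a` in a
#' hermaphroditic plant population that selfs with probability `alpha` and
#' outcrosses with probability `1 - alpha`.
#'
#' Sign conventions differ between the two phases and are enforced here only
#' through the positivity of fitnesses, never by restricting signs:
#' \describe{
#'   \item{gametophyte}{mutant ovule fitness `1 - sO`, mutant pollen fitness
#'     `1 - sP`; the mutant is *deleterious* in the gametophyte phase when
#'     `sO > 0`, `sP > 0` and favourable when negative.}
#'   \item{sporophyte}{genotype fitnesses `W_AA = 1`, `W_Aa = 1 + shet`,
#'     `W_aa = 1 + shom`; the mutant is *deleterious* in the sporophyte phase
#'     when `shet < 0`, `shom < 0` and favourable when positive.}
#' }
#'
#' Either the effective size `Ne` or the census size `N` (or both) may be
#' supplied for finite-population computations; the other is derived through
#' `Ne = N / (1 + Fis)` with `Fis = alpha / (2 - alpha)`. Infinite-population
#' operations ignore both.
#'
#' @param alpha Selfing probability per seed, in `[0, 1]`.
#' @param sO Ovule (female gamete) selection coefficient; mutant ovule fitness
#'   is `1 - sO` (must stay positive).
#' @param sP Pollen (male gamete) selection coefficient; mutant pollen fitness
#'   is `1 - sP` (must stay positive).
#' @param shet Heterozygote sporophytic coefficient; `W_Aa = 1 + shet > 0`.
#' @param shom Mutant-homozygote sporophytic coefficient; `W_aa = 1 + shom > 0`.
#' @param mu One-way mutation rate from `A` to `a` per generation
#'   (irreversible mutation), `mu >= 0`.
#' @param Ne Effective population size (finite-population modules only).
#' @param N Census population size; used when `Ne` is not given.
#'
#' @return An object of class `"selfix_params"`: a list with the validated
#'   fields plus derived `Fis`, `shap = sO + sP`, and (when a size was given)
#'   integer `Ne` and `N` with a `"rounding"` attribute recording the rounding
#'   mode used in the `Ne`/`N` conversion.
#'
#' @examples
#' p <- selfix_params(alpha = 0.5, sO = 0.02, sP = 0.02, shet = 0.02,
#'                    shom = 0.03, mu = 1e-4, Ne = 30)
#' p$Fis            # 1/3 at alpha = 0.5
#' classify_selection(p)
#' @export
selfix_params <- function(alpha = 0, sO = 0, sP = 0, shet = 0, shom = 0,
                          mu = 0, Ne = NULL, N = NULL) {
  chk_num <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
    as.numeric(x)
  }
  alpha <- chk_num(alpha, "alpha")
  sO <- chk_num(sO, "sO"); sP <- chk_num(sP, "sP")
  shet <- chk_num(shet, "shet"); shom <- chk_num(shom, "shom")
  mu <- chk_num(mu, "mu")
  if (alpha < 0 || alpha > 1)
    stop("'alpha' must lie in [0, 1]", call. = FALSE)
  if (mu < 0) stop("'mu' must be non-negative", call. = FALSE)
  if (1 - sO <= 0) stop("mutant ovule fitness 1 - sO must be positive", call. = FALSE)
  if (1 - sP <= 0) stop("mutant pollen fitness 1 - sP must be positive", call. = FALSE)
  if (1 + shet <= 0) stop("heterozygote fitness 1 + shet must be positive", call. = FALSE)
  if (1 + shom <= 0) stop("mutant homozygote fitness 1 + shom must be positive", call. = FALSE)

  Fis <- inbreeding_equilibrium(alpha)
  out <- list(alpha = alpha, sO = sO, sP = sP, shet = shet, shom = shom,
              mu = mu, Fis = Fis, shap = sO + sP, Ne = NULL, N = NULL)

  if (!is.null(Ne)) {
    Ne <- chk_num(Ne, "Ne")
    if (Ne < 2 || Ne != round(Ne))
      stop("'Ne' must be an integer >= 2", call. = FALSE)
    out$Ne <- as.integer(Ne)
    out$N <- as.integer(census_size(Ne, Fis))
  } else if (!is.null(N)) {
    N <- chk_num(N, "N")
    if (N < 2 || N != round(N))
      stop("'N' must be an integer >= 2", call. = FALSE)
    out$N <- as.integer(N)
    out$Ne <- as.integer(effective_size(N, Fis))
  }
  if (!is.null(out$Ne) && 2 * out$Ne * mu >= 1)
    warning("2*Ne*mu >= 1: the flux-equilibrium approximations assume 2*Ne*mu < 1",
            call. = FALSE)
  class(out) <- "selfix_params"
  out
}

#' @export
print.selfix_params <- function(x, ...) {
  cat("Mixed-mating selection model parameters\n")
  cat(sprintf("  selfing rate alpha = %g (Fis = %g at mating-system equilibrium)\n",
              x$alpha, x$Fis))
  cat(sprintf("  gametophyte: sO = %g, sP = %g (shap = %g)\n", x$sO, x$sP, x$shap))
  cat(sprintf("  sporophyte:  shet = %g, shom = %g\n", x$shet, x$shom))
  cat(sprintf("  mutation:    mu = %g (A -> a, one-way)\n", x$mu))
  if (!is.null(x$Ne))
    cat(sprintf("  sizes:       Ne = %d, N = %d\n", x$Ne, x$N))
  cls <- classify_selection(x)
  cat(sprintf("  regime:      %s\n", cls))
  invisible(x)
}

#' Equilibrium inbreeding coefficient under partial selfing
#'
#' The fixed point of the heterozygosity recursion under a constant selfing
#' rate: a fraction `alpha` of seeds derive from selfing (halving
#' heterozygosity) and `1 - alpha` from random outcrossing, giving the
#' mating-system equilibrium `Fis = alpha / (2 - alpha)`.
#'
#' @param alpha Selfing rate(s) in `[0, 1]`; vectorised.
#' @return Equilibrium inbreeding coefficient(s) in `[0, 1]`.
#' @examples
#' inbreeding_equilibrium(c(0, 2/3, 1))  # 0, 0.5, 1
#' @export
inbreeding_equilibrium <- function(alpha) {
  if (!is.numeric(alpha) || any(!is.finite(alpha)) || any(alpha < 0 | alpha > 1))
    stop("'alpha' must be in [0, 1]", call. = FALSE)
  alpha / (2 - alpha)
}

#' Composite selection coefficients of the weak-selection frequency change
#'
#' Reparameterises the per-generation change of the mutant allele frequency
#' (mutation aside) as `(S + T q) q (1 - q)`, with
#' `S = -(1/2)(1 - Fis) shap + (1 - Fis) shet + Fis shom` and
#' `T = (1 - Fis)(shom - 2 shet)`. Under the linear additive sporophytic model
#' (`shom = 2 shet`) the frequency-dependent part vanishes (`T = 0`).
#'
#' @param params A [selfix_params] object.
#' @return An object of class `"composite_selection"`: list with `Fis`,
#'   `shap`, `S` and `T`.
#' @examples
#' composite_selection(selfix_params(alpha = 0, sO = 0.01, sP = 0.01,
#'                                   shet = 0.02, shom = 0.03))
#' @export
composite_selection <- function(params) {
  stopifnot(inherits(params, "selfix_params"))
  Fis <- params$Fis
  S <- -0.5 * (1 - Fis) * params$shap + (1 - Fis) * params$shet + Fis * params$shom
  T <- (1 - Fis) * (params$shom - 2 * params$shet)
  structure(list(Fis = Fis, shap = params$shap, S = S, T = T),
            class = "composite_selection")
}

#' @export
print.composite_selection <- function(x, ...) {
  cat(sprintf("Composite selection: S = %g, T = %g (Fis = %g, shap = %g)\n",
              x$S, x$T, x$Fis, x$shap))
  invisible(x)
}

#' Convert between census and effective population size
#'
#' Under partial selfing the effective size is reduced relative to the census
#' size: `Ne = N / (1 + Fis)`. The inverse conversion rounds to the nearest
#' integer with ties away from zero; the rounding mode is recorded as an
#' attribute so downstream outputs can report it.
#'
#' @param N Census population size (`>= 2`).
#' @param Ne Effective population size.
#' @param Fis Inbreeding coefficient in `[0, 1]`.
#' @return Integer population size with attribute `rounding`.
#' @examples
#' effective_size(60, Fis = 1)                          # 30
#' census_size(30, inbreeding_equilibrium(0.5))         # 40
#' @export
effective_size <- function(N, Fis) {
  stopifnot(is.numeric(N), N >= 2, is.numeric(Fis), Fis >= 0, Fis <= 1)
  x <- N / (1 + Fis)
  structure(as.integer(sign(x) * floor(abs(x) + 0.5)),
            rounding = "nearest, ties away from zero")
}

#' @rdname effective_size
#' @export
census_size <- function(Ne, Fis) {
  stopifnot(is.numeric(Ne), Ne >= 2, is.numeric(Fis), Fis >= 0, Fis <= 1)
  x <- Ne * (1 + Fis)
  structure(as.integer(sign(x) * floor(abs(x) + 0.5)),
            rounding = "nearest, ties away from zero")
}

#' Classify a parameter set by the sign of selection in each phase
#'
#' Applies the phase-specific sign conventions (gametophyte: deleterious when
#' `shap > 0`; sporophyte: deleterious when `shet < 0`, `shom < 0`) and labels
#' the joint regime. Mixed-sign biphasic selection is "antagonistic",
#' same-direction biphasic selection "synergistic".
#'
#' @param params A [selfix_params] object.
#' @return A single character string, e.g. `"gametophyte-only (deleterious)"`.
#' @export
classify_selection <- function(params) {
  stopifnot(inherits(params, "selfix_params"))
  gam <- if (params$shap > 0) "deleterious" else if (params$shap < 0) "favourable" else "neutral"
  sp_sign <- sign(params$shet) + sign(params$shom)
  spo <- if (params$shet == 0 && params$shom == 0) "neutral"
         else if (params$shet <= 0 && params$shom <= 0) "deleterious"
         else if (params$shet >= 0 && params$shom >= 0) "favourable"
         else "mixed"
  if (gam == "neutral" && spo == "neutral") return("neutral")
  if (spo == "neutral") return(paste0("gametophyte-only (", gam, ")"))
  if (gam == "neutral") return(paste0("sporophyte-only (", spo, ")"))
  if ((gam == "deleterious" && spo == "favourable") ||
      (gam == "favourable" && spo == "deleterious"))
    return(sprintf("biphasic antagonistic (gametophyte %s, sporophyte %s)", gam, spo))
  if (gam == spo)
    return(sprintf("biphasic synergistic (%s in both phases)", gam))
  sprintf("biphasic (gametophyte %s, sporophyte %s)", gam, spo)
}

#' Read model parameters from a YAML or JSON configuration file
#'
#' Accepted keys: `alpha`, `sO`, `sP`, `shet`, `shom`, `mu`, and one of `Ne`
#' or `N`. Unknown keys are an error (typo guard). The format is chosen from
#' the file extension (`.yml`/`.yaml` vs `.json`).
#'
#' @param path Path to the configuration file.
#' @return A validated [selfix_params] object.
#' @export
read_params_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext == "json") jsonlite::fromJSON(path) else yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a mapping of parameter names to values", call. = FALSE)
  allowed <- c("alpha", "sO", "sP", "shet", "shom", "mu", "Ne", "N")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         " (allowed: ", paste(allowed, collapse = ", "), ")", call. = FALSE)
  do.call(selfix_params, cfg)
}
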