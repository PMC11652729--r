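#' Genotype-frequency state
#'
#' A simplex of the three genotype frequencies at the biallelic locus, with
#' derived mutant allele frequency `q = paa + pAa/2` and, when off the
#' Hardy-Weinberg manifold, the observed heterozygote deficit.
#'
#' @param pAA,pAa,paa Genotype frequencies; must be non-negative and sum to 1
#'   within `1e-9` (renormalised exactly on construction).
#' @return An object of class `"genotype_state"`: named numeric vector with
#'   components `pAA`, `pAa`, `paa` and attributes `q` (mutant allele
#'   frequency) and `Fis_obs` (observed inbreeding coefficient, `NA` when `q`
#'   is 0 or 1).
#' @examples
#' genotype_state(0.81, 0.18, 0.01)
#' equilibrium_state(0.1, Fis = 0.5)
#' @export
genotype_state <- function(pAA, pAa, paa) {
  v <- c(pAA = pAA, pAa = pAa, paa = paa)
  if (any(!is.finite(v)) || any(v < -1e-12))
    stop("genotype frequencies must be finite and non-negative", call. = FALSE)
  v[v < 0] <- 0
  s <- sum(v)
  if (abs(s - 1) > 1e-9)
    stop("genotype frequencies must sum to 1 (got ", format(s), ")", call. = FALSE)
  v <- v / s
  q <- v[["paa"]] + v[["pAa"]] / 2
  p <- 1 - q
  Fis_obs <- if (q <= 0 || q >= 1) NA_real_ else 1 - v[["pAa"]] / (2 * p * q)
  structure(v, q = q, Fis_obs = Fis_obs, class = "genotype_state")
}

#' @export
print.genotype_state <- function(x, ...) {
  cat(sprintf("genotype state: pAA = %.6g, pAa = %.6g, paa = %.6g  (q = %.6g)\n",
              x[["pAA"]], x[["pAa"]], x[["paa"]], attr(x, "q")))
  invisible(x)
}

#' @describeIn genotype_state genotype frequencies at inbreeding equilibrium:
#'   `pAA = p^2 + p*q*Fis`, `pAa = 2*p*q*(1 - Fis)`, `paa = q^2 + p*q*Fis`.
#' @param q Mutant allele frequency in `[0, 1]`.
#' @param Fis Inbreeding coefficient in `[0, 1]`.
#' @export
equilibrium_state <- function(q, Fis) {
  stopifnot(q >= 0, q <= 1, Fis >= 0, Fis <= 1)
  p <- 1 - q
  genotype_state(p^2 + p * q * Fis, 2 * p * q * (1 - Fis), q^2 + p * q * Fis)
}

# Vectorised core of the one-generation recursion: operates on plain numeric
# vectors of genotype frequencies so that the Monte Carlo simulator can step
# thousands of replicate populations at once. Order of events: gametophytic
# selection within the mating system (selfing part with within-plant gamete
# pools, outcrossing part with mass-action population pools), seed formation,
# one-way mutation A -> a, then sporophytic selection.
#
# mutation_phase = "sporophyte": mu applied to zygote genotype frequencies,
# exactly (including the mu^2 class). "gametophyte": mu applied to the gamete
# pools after gametophytic selection, before union.
.lifecycle_step <- function(pAA, pAa, paa, alpha, sO, sP, shet, shom,
                            mu = 0, mutation_phase = "sporophyte") {
  gam_mut <- mu > 0 && mutation_phase == "gametophyte"
  # within-plant gamete shares from a heterozygote after gametophytic selection
  oa_het <- (1 - sO) / (2 - sO)   # mutant ovule share from Aa
  pa_het <- (1 - sP) / (2 - sP)   # mutant pollen share from Aa
  oa_AA <- 0; pa_AA <- 0; oa_aa <- 1; pa_aa <- 1
  if (gam_mut) {
    oa_AA <- mu; pa_AA <- mu
    oa_het <- oa_het + (1 - oa_het) * mu
    pa_het <- pa_het + (1 - pa_het) * mu
  }
  # selfing part: gametes united within each parental plant
  self_AA <- pAA * (1 - oa_AA) * (1 - pa_AA) +
             pAa * (1 - oa_het) * (1 - pa_het)
  self_aa <- pAA * oa_AA * pa_AA +
             pAa * oa_het * pa_het +
             paa * oa_aa * pa_aa
  self_Aa <- pAA * (oa_AA + pa_AA - 2 * oa_AA * pa_AA) +
             pAa * (oa_het * (1 - pa_het) + (1 - oa_het) * pa_het) +
             paa * (oa_aa * (1 - pa_aa) + (1 - oa_aa) * pa_aa)
  # outcrossing part: mass-action gamete pools over the whole population
  q <- paa + pAa / 2
  qo <- q * (1 - sO) / (1 - sO * q)   # mutant frequency in the ovule pool
  qp <- q * (1 - sP) / (1 - sP * q)   # mutant frequency in the pollen pool
  if (gam_mut) {
    qo <- qo + (1 - qo) * mu
    qp <- qp + (1 - qp) * mu
  }
  out_AA <- (1 - qo) * (1 - qp)
  out_Aa <- qo * (1 - qp) + (1 - qo) * qp
  out_aa <- qo * qp
  zAA <- alpha * self_AA + (1 - alpha) * out_AA
  zAa <- alpha * self_Aa + (1 - alpha) * out_Aa
  zaa <- alpha * self_aa + (1 - alpha) * out_aa
  # one-way mutation applied to zygotes (default placement), exact in mu
  if (mu > 0 && !gam_mut) {
    mAA <- zAA * (1 - mu)^2
    mAa <- zAA * 2 * mu * (1 - mu) + zAa * (1 - mu)
    maa <- zAA * mu^2 + zAa * mu + zaa
    zAA <- mAA; zAa <- mAa; zaa <- maa
  }
  # sporophytic selection
  wbar <- zAA + zAa * (1 + shet) + zaa * (1 + shom)
  if (any(wbar <= 0))
    stop("mean sporophytic fitness is non-positive; invalid fitness parameters",
         call. = FALSE)
  list(pAA = zAA / wbar,
       pAa = zAa * (1 + shet) / wbar,
       paa = zaa * (1 + shom) / wbar)
}

#' One generation of the deterministic life cycle
#'
#' Advances adult genotype frequencies through one full generation:
#' gametophytic selection inside the mixed mating system (the selfing part
#' uses within-plant gamete pools, the outcrossing part mass-action
#' population pools of ovules and pollen), seed formation, one-way mutation
#' `A -> a`, and sporophytic selection with renormalisation by the mean
#' fitness.
#'
#' From a heterozygous plant the mutant gamete shares after within-plant
#' gametophytic selection are `(1 - sO)/(2 - sO)` in ovules and
#' `(1 - sP)/(2 - sP)` in pollen; the outcross pools carry mutant frequencies
#' `q(1 - sO)/(1 - sO q)` and `q(1 - sP)/(1 - sP q)`.
#'
#' @param state A [genotype_state].
#' @param params A [selfix_params] object.
#' @param include_mutation Apply the one-way mutation step? (Fixation
#'   probability experiments switch it off.)
#' @param mutation_phase Where mutation acts: `"sporophyte"` (default; applied
#'   to zygote genotype frequencies, exactly to order `mu^2`) or
#'   `"gametophyte"` (applied to the gamete pools before union). The
#'   placement is immaterial to first order in `mu`.
#' @return The next-generation adult [genotype_state].
#' @examples
#' st <- equilibrium_state(0.1, Fis = 0)
#' step_generation(st, selfix_params(alpha = 0, mu = 1e-4))
#' @export
step_generation <- function(state, params, include_mutation = TRUE,
                            mutation_phase = c("sporophyte", "gametophyte")) {
  stopifnot(inherits(state, "genotype_state"), inherits(params, "selfix_params"))
  mutation_phase <- match.arg(mutation_phase)
  nxt <- .lifecycle_step(state[["pAA"]], state[["pAa"]], state[["paa"]],
                         params$alpha, params$sO, params$sP,
                         params$shet, params$shom,
                         mu = if (include_mutation) params$mu else 0,
                         mutation_phase = mutation_phase)
  genotype_state(nxt$pAA, nxt$pAa, nxt$paa)
}

#' Weak-selection change of the mutant allele frequency per generation
#'
#' The first-order systematic change with the inbreeding coefficient at its
#' mating-system equilibrium `Fis = alpha/(2 - alpha)`:
#' \deqn{\Delta q = p\mu - \tfrac12 p q (1-F_{is}) s_{hap}
#'       - p q (q-p)(1-F_{is}) s_{het} + p q (q + p F_{is}) s_{hom}}
#' with `p = 1 - q` and `shap = sO + sP`. Mutation aside, this is identical to
#' `(S + T q) q (1 - q)` with `S`, `T` from [composite_selection()].
#'
#' @param q Mutant allele frequency (vectorised).
#' @param params A [selfix_params] object.
#' @param include_mutation Include the `p*mu` mutation influx term?
#' @return The signed frequency change `Delta q` (same length as `q`).
#' @examples
#' delta_q_weak(0.5, selfix_params(alpha = 0, sO = 0.01, sP = 0.01, mu = 1e-5))
#' @export
delta_q_weak <- function(q, params, include_mutation = TRUE) {
  stopifnot(inherits(params, "selfix_params"))
  if (any(q < 0 | q > 1)) stop("'q' must lie in [0, 1]", call. = FALSE)
  p <- 1 - q
  Fis <- params$Fis
  dq <- -0.5 * p * q * (1 - Fis) * params$shap -
    p * q * (q - p) * (1 - Fis) * params$shet +
    p * q * (q + p * Fis) * params$shom
  if (include_mutation) dq <- dq + p * params$mu
  dq
}

#' Iterate the life-cycle recursion to equilibrium
#'
#' Repeats [step_generation()] until the per-generation change of the mutant
#' allele frequency falls below `tol`, the frequency reaches a boundary, or
#' `max_gen` generations have elapsed, and classifies the terminal state.
#'
#' @param state Initial [genotype_state] (or a scalar `q0`, expanded to the
#'   inbreeding-equilibrium genotype frequencies at the parameter's `Fis`).
#' @param params A [selfix_params] object.
#' @param tol Convergence tolerance on `|Delta q|` per generation.
#' @param boundary_tol Distance from 0/1 at which `q` is declared absorbed.
#' @param max_gen Generation cap.
#' @param include_mutation Passed to [step_generation()].
#' @param record_every Store every k-th generation in the trajectory (the
#'   first and last generations are always stored).
#' @return An object of class `"lifecycle_trajectory"`: list with
#'   `classification` (one of `"interior equilibrium"`, `"fixed"`, `"lost"`,
#'   `"not converged"`), the terminal `state`, number of `generations`, and a
#'   `trajectory` data frame with columns `generation`, `pAA`, `pAa`, `paa`,
#'   `q`, `delta_q` (exportable with [utils::write.csv()]).
#' @examples
#' eq <- iterate_to_equilibrium(0.01, selfix_params(alpha = 0, shet = -0.01,
#'                                                  shom = -0.02, mu = 1e-4))
#' eq$classification
#' @export
iterate_to_equilibrium <- function(state, params, tol = 1e-12,
                                   boundary_tol = 1e-9, max_gen = 1e6,
                                   include_mutation = TRUE,
                                   record_every = 1L) {
  stopifnot(inherits(params, "selfix_params"), tol > 0)
  if (is.numeric(state) && length(state) == 1L)
    state <- equilibrium_state(state, params$Fis)
  stopifnot(inherits(state, "genotype_state"))
  mu <- if (include_mutation) params$mu else 0

  pAA <- state[["pAA"]]; pAa <- state[["pAa"]]; paa <- state[["paa"]]
  q <- paa + pAa / 2
  keep_gen <- integer(0); keep_st <- list(); keep_dq <- numeric(0)
  push <- function(g, st, dq) {
    keep_gen[[length(keep_gen) + 1L]] <<- g
    keep_st[[length(keep_st) + 1L]] <<- st
    keep_dq[[length(keep_dq) + 1L]] <<- dq
  }
  classification <- "not converged"
  gen <- 0L
  dq <- NA_real_
  repeat {
    if (gen >= max_gen) break
    nxt <- .lifecycle_step(pAA, pAa, paa, params$alpha, params$sO, params$sP,
                           params$shet, params$shom, mu = mu)
    qn <- nxt$paa + nxt$pAa / 2
    dq <- qn - q
    if (gen %% record_every == 0L) push(gen, c(pAA, pAa, paa, q), dq)
    pAA <- nxt$pAA; pAa <- nxt$pAa; paa <- nxt$paa; q <- qn
    gen <- gen + 1L
    if (q >= 1 - boundary_tol) { classification <- "fixed"; break }
    if (q <= boundary_tol)     { classification <- "lost";  break }
    if (abs(dq) < tol)         { classification <- "interior equilibrium"; break }
  }
  push(gen, c(pAA, pAa, paa, q), dq)
  tr <- do.call(rbind, keep_st)
  trajectory <- data.frame(generation = keep_gen,
                           pAA = tr[, 1], pAa = tr[, 2], paa = tr[, 3],
                           q = tr[, 4], delta_q = keep_dq)
  structure(list(classification = classification,
                 state = genotype_state(pAA, pAa, paa),
                 generations = gen,
                 q = q,
                 trajectory = trajectory,
                 params = params),
            class = "lifecycle_trajectory")
}

#' @export
print.lifecycle_trajectory <- function(x, ...) {
  cat(sprintf("life-cycle iteration: %s after %d generations (q = %.8g)\n",
              x$classification, x$generations, x$q))
  invisible(x)
}
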