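# Vectorised one-generation update of many replicate populations: applies the
# deterministic life-cycle expectation to each replicate's genotype counts and
# draws the next generation of N individuals from the implied trinomial
# (sequential binomials, which R vectorises over replicates).
.sample_generation <- function(nAA, nAa, naa, N, alpha, sO, sP, shet, shom, mu) {
  tot <- nAA + nAa + naa
  nxt <- .lifecycle_step(nAA / tot, nAa / tot, naa / tot,
                         alpha, sO, sP, shet, shom, mu = mu)
  k <- length(nAA)
  fAA <- nxt$pAA; fAa <- nxt$pAa
  nAA2 <- stats::rbinom(k, N, fAA)
  rem <- N - nAA2
  pr <- fAa / (1 - fAA)
  pr[!is.finite(pr)] <- 0
  pr <- pmin(pmax(pr, 0), 1)
  nAa2 <- stats::rbinom(k, rem, pr)
  list(nAA = nAA2, nAa = nAa2, naa = rem - nAa2)
}

# Initial mutant copy numbers per replicate. "one_het": a single heterozygote
# (frequency 1/2N). "freq_ne": expected frequency 1/2Ne, realised as a mixture
# over the two integer heterozygote counts bracketing 2N/(2Ne) = 1 + Fis.
.init_copies <- function(n_runs, N, Ne, init) {
  if (init == "one_het") return(rep.int(1L, n_runs))
  target <- N / Ne                       # heterozygotes carrying one copy each
  k <- floor(target)
  k + stats::rbinom(n_runs, 1L, target - k)
}

#' Monte Carlo estimate of the fixation probability
#'
#' Forward stochastic simulation of the full genotype-resolved life cycle:
#' each replicate population starts with the mutant present in
#' heterozygotes, advances by the deterministic life-cycle expectation
#' ([step_generation()] semantics, mutation off) followed by multinomial
#' sampling of `N` individuals, and runs to loss or fixation. The fixation
#' fraction is estimated per dataset and aggregated over replicate datasets
#' to give a mean, a standard deviation, and a 95% interval
#' (`u_hat +/- 1.96 sd`, the normal-approximation range of single-dataset
#' estimates).
#'
#' Recurrent mutation is excluded: the analytic fixation probability is
#' mutation-free (with one-way mutation every run would fix trivially). Use
#' [simulate_flux_histogram()] for the mutation-on flux experiment.
#'
#' @param params A [selfix_params] object.
#' @param n_runs Replicate runs per dataset.
#' @param n_datasets Independent datasets (for the mean/SD structure).
#' @param seed Integer master seed; the RNG state is seeded once and the
#'   datasets consume sequential substreams, so results are reproducible
#'   bit-for-bit.
#' @param init `"one_het"` (one heterozygous individual, frequency `1/2N`)
#'   or `"freq_ne"` (expected frequency `1/2Ne`, a mixture over the integer
#'   heterozygote counts bracketing `1 + Fis`).
#' @param size `"effective"`: interpret the model's `Ne` as effective size
#'   and simulate `N = round(Ne (1 + Fis))` individuals; `"census"`:
#'   simulate `params$N` individuals as given.
#' @param max_generations Safety cap per run; runs still segregating at the
#'   cap are counted as unresolved (warned about when they exceed 0.1% of
#'   runs) and treated as not fixed.
#' @param rng_kind Optional RNG kind passed to [set.seed()] (used by the
#'   generator-substitution checks).
#' @return An object of class `"fixation_estimate"`: list with `u_hat`,
#'   `sd`, `ci95`, `per_dataset`, `n_runs`, `n_datasets`, `seed`, `N`,
#'   `Ne`, `init` and `n_unresolved`.
#' @examples
#' \donttest{
#' p <- selfix_params(alpha = 0, Ne = 30)
#' simulate_fixation(p, n_runs = 1000, n_datasets = 5, seed = 1)
#' }
#' @export
simulate_fixation <- function(params, n_runs = 10000, n_datasets = 100,
                              seed = NULL,
                              init = c("one_het", "freq_ne"),
                              size = c("effective", "census"),
                              max_generations = 1e5, rng_kind = NULL) {
  stopifnot(inherits(params, "selfix_params"), n_runs >= 1, n_datasets >= 1)
  init <- match.arg(init); size <- match.arg(size)
  if (size == "effective") {
    if (is.null(params$Ne)) stop("'params' must carry Ne", call. = FALSE)
    Ne <- params$Ne
    N <- as.integer(census_size(Ne, params$Fis))
  } else {
    if (is.null(params$N)) stop("'params' must carry N", call. = FALSE)
    N <- params$N
    Ne <- params$Ne
  }
  if (!is.null(seed)) {
    if (is.null(rng_kind)) set.seed(seed) else set.seed(seed, kind = rng_kind)
  }
  per_dataset <- numeric(n_datasets)
  n_unresolved <- 0L
  for (d in seq_len(n_datasets)) {
    copies <- .init_copies(n_runs, N, Ne, init)
    nAa <- pmin(copies, N)
    nAA <- N - nAa
    naa <- integer(n_runs)
    fixed <- 0L
    gen <- 0L
    while (length(nAa) && gen < max_generations) {
      s <- .sample_generation(nAA, nAa, naa, N, params$alpha, params$sO,
                              params$sP, params$shet, params$shom, mu = 0)
      mut_copies <- s$nAa + 2L * s$naa
      fix <- mut_copies == 2L * N
      lost <- mut_copies == 0L
      fixed <- fixed + sum(fix)
      keep <- !(fix | lost)
      nAA <- s$nAA[keep]; nAa <- s$nAa[keep]; naa <- s$naa[keep]
      gen <- gen + 1L
    }
    n_unresolved <- n_unresolved + length(nAa)
    per_dataset[d] <- fixed / n_runs
  }
  if (n_unresolved > 0.001 * n_runs * n_datasets)
    warning(n_unresolved, " runs still segregating at max_generations = ",
            max_generations, call. = FALSE)
  u_hat <- mean(per_dataset)
  sdv <- stats::sd(per_dataset)
  structure(list(u_hat = u_hat, sd = sdv,
                 ci95 = c(lower = max(0, u_hat - 1.96 * sdv),
                          upper = min(1, u_hat + 1.96 * sdv)),
                 per_dataset = per_dataset,
                 n_runs = n_runs, n_datasets = n_datasets, seed = seed,
                 N = N, Ne = Ne, init = init,
                 n_unresolved = n_unresolved, params = params),
            class = "fixation_estimate")
}

#' @export
print.fixation_estimate <- function(x, ...) {
  cat(sprintf("MC fixation probability: u_hat = %.6g (sd = %.3g over %d datasets of %d runs)\n",
              x$u_hat, x$sd, x$n_datasets, x$n_runs))
  cat(sprintf("  95%% interval [%.6g, %.6g]; N = %d, init = %s, seed = %s\n",
              x$ci95[1], x$ci95[2], x$N, x$init,
              if (is.null(x$seed)) "<inherited>" else format(x$seed)))
  invisible(x)
}

#' Monte Carlo flux experiment: segregating-class histogram and decay rate
#'
#' Forward simulation with one-way mutation switched on: replicate
#' populations start from the all-ancestral state, mutation feeds mutant
#' copies in, and each run ends when the mutant fixes. After a burn-in the
#' routine records (i) the histogram of mutant copy numbers among
#' non-fixed runs, pooled over snapshots -- the empirical counterpart of the
#' flux-equilibrium density -- and (ii) the exponential decay of the
#' non-fixed fraction, whose fitted rate estimates the gene-fixation rate
#' `K`.
#'
#' @param params A [selfix_params] with `mu > 0`.
#' @param n_runs Number of replicate populations.
#' @param burn_in Generations discarded before recording.
#' @param n_snapshots Number of recorded snapshots.
#' @param snap_every Generations between snapshots.
#' @param seed,size,rng_kind As in [simulate_fixation()].
#' @return An object of class `"flux_histogram"`: list with `q` (frequency
#'   classes `0, 1/2N, ...`), `density` (normalised over non-fixed runs),
#'   `counts`, `decay_rate` (fixation events per surviving run-generation),
#'   `decay_se` (Poisson standard error of that rate),
#'   `surviving` (data frame `generation`, `n_alive`),
#'   and bookkeeping fields. Errors if fewer than 100 runs survive to the
#'   end of recording.
#' @export
simulate_flux_histogram <- function(params, n_runs = 5000, burn_in = 200,
                                    n_snapshots = 50, snap_every = 5,
                                    seed = NULL, size = c("effective", "census"),
                                    rng_kind = NULL) {
  stopifnot(inherits(params, "selfix_params"))
  if (params$mu <= 0) stop("flux experiment requires mu > 0", call. = FALSE)
  size <- match.arg(size)
  if (size == "effective") {
    if (is.null(params$Ne)) stop("'params' must carry Ne", call. = FALSE)
    N <- as.integer(census_size(params$Ne, params$Fis))
  } else N <- params$N
  if (!is.null(seed)) {
    if (is.null(rng_kind)) set.seed(seed) else set.seed(seed, kind = rng_kind)
  }
  nAA <- rep.int(N, n_runs); nAa <- integer(n_runs); naa <- integer(n_runs)
  step_all <- function() {
    s <- .sample_generation(nAA, nAa, naa, N, params$alpha, params$sO,
                            params$sP, params$shet, params$shom, mu = params$mu)
    keep <- (s$nAa + 2L * s$naa) != 2L * N   # drop runs fixed for the mutant
    nAA <<- s$nAA[keep]; nAa <<- s$nAa[keep]; naa <<- s$naa[keep]
    sum(!keep)
  }
  for (g in seq_len(burn_in)) step_all()
  counts <- integer(2L * N)                  # copy classes 0 .. 2N-1
  gens <- integer(n_snapshots); alive <- integer(n_snapshots)
  gen <- burn_in
  alive_prev <- length(nAa)
  deaths <- 0; exposure <- 0
  for (s in seq_len(n_snapshots)) {
    for (g in seq_len(snap_every)) step_all()
    gen <- gen + snap_every
    copies <- nAa + 2L * naa
    tab <- tabulate(copies + 1L, nbins = 2L * N)
    counts <- counts + tab
    gens[s] <- gen; alive[s] <- length(nAa)
    deaths <- deaths + (alive_prev - alive[s])
    exposure <- exposure + snap_every * (alive_prev + alive[s]) / 2
    alive_prev <- alive[s]
  }
  if (alive[n_snapshots] < 100)
    stop("fewer than 100 runs survived to the last snapshot; ",
         "increase n_runs", call. = FALSE)
  # fixation-event rate per run-generation, with a Poisson standard error
  # (a log-linear fit of the survival curve underestimates the error: the
  # counts share their randomness cumulatively)
  structure(list(q = (0:(2L * N - 1L)) / (2 * N),
                 density = counts / sum(counts),
                 counts = counts,
                 decay_rate = deaths / exposure,
                 decay_se = sqrt(max(deaths, 1)) / exposure,
                 surviving = data.frame(generation = gens, n_alive = alive),
                 N = N, n_runs = n_runs, burn_in = burn_in,
                 seed = seed, params = params),
            class = "flux_histogram")
}

#' @export
print.flux_histogram <- function(x, ...) {
  cat(sprintf("MC flux experiment: N = %d, %d runs, decay rate %.4g (se %.2g)\n",
              x$N, x$n_runs, x$decay_rate, x$decay_se))
  invisible(x)
}
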