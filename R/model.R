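#' Fit-free model object for mutant-allele fixation under partial selfing
#'
#' The package's central object: bundles a parameter set with every derived
#' quantity of the theory -- the composite selection coefficients, the
#' flux-equilibrium fixation probability and gene-fixation rate, the
#' diffusion fixation probability, and the genetic loads -- behind the
#' usual modelling verbs (`print`, `summary`, `coef`, `predict`, `simulate`,
#' `plot`).
#'
#' @param ... Either a single [selfix_params] object, or the arguments of
#'   [selfix_params()] (`alpha`, `sO`, `sP`, `shet`, `shom`, `mu`, `Ne`,
#'   `N`).
#' @return An object of class `"fixation_model"`: list with `params`,
#'   `composite` (`S`, `T`, `Fis`, `shap`), and -- when the parameter set
#'   carries a population size -- `u_wright`, `u_diffusion`
#'   (both at initial frequency `1/2Ne`), `K`, `K_over_mu`, `load_fixed`
#'   (`L(1)`), and `load_mean` (finite-population mean load; requires
#'   `mu > 0`).
#' @examples
#' m <- fixation_model(alpha = 0.5, sO = 0.02, sP = 0.02, mu = 1e-4, Ne = 30)
#' m
#' coef(m)
#' predict(m, alpha = c(0, 0.5, 1))
#' @export
fixation_model <- function(...) {
  args <- list(...)
  params <- if (length(args) == 1L && inherits(args[[1L]], "selfix_params"))
    args[[1L]] else do.call(selfix_params, args)
  obj <- list(params = params, composite = composite_selection(params),
              u_wright = NA_real_, u_diffusion = NA_real_,
              K = NA_real_, K_over_mu = NA_real_,
              load_fixed = load_infinite(1, params),
              load_mean = NA_real_)
  if (!is.null(params$Ne)) {
    obj$u_wright <- fixation_prob_wright(params)
    obj$u_diffusion <- fixation_prob_diffusion(params)
    if (params$mu > 0) {
      obj$K <- decay_rate_K(params)
      obj$K_over_mu <- obj$K / params$mu
      obj$load_mean <- load_finite_mean(params)
    }
  }
  class(obj) <- "fixation_model"
  obj
}

#' @export
print.fixation_model <- function(x, ...) {
  p <- x$params
  cat("Mutant-allele fixation model under partial selfing\n")
  cat(sprintf("  %s; alpha = %g, mu = %g%s\n", classify_selection(p),
              p$alpha, p$mu,
              if (!is.null(p$Ne)) sprintf(", Ne = %d (N = %d)", p$Ne, p$N) else ""))
  cat(sprintf("  composite: Fis = %.4g, S = %.4g, T = %.4g\n",
              x$composite$Fis, x$composite$S, x$composite$T))
  if (!is.null(p$Ne)) {
    cat(sprintf("  u(1/2Ne): %.6g (flux equilibrium), %.6g (diffusion); neutral 1/2Ne = %.6g\n",
                x$u_wright, x$u_diffusion, 1 / (2 * p$Ne)))
    if (p$mu > 0)
      cat(sprintf("  K = %.6g (K/mu = %.5g); mean load = %.6g\n",
                  x$K, x$K_over_mu, x$load_mean))
  }
  invisible(x)
}

#' @export
summary.fixation_model <- function(object, ...) {
  p <- object$params
  crit <- if (p$shap == 0 && (p$shet != 0))
    critical_alpha_sporophytic(p$mu, p$shet, p$shom)
  else if (p$shap != 0 && p$shet == 0 && p$shom == 0)
    critical_alpha_gametophytic(p$mu, p$shap)
  else if (p$shap != 0)
    critical_alpha_biphasic(p$mu, p$shap, p$shet, p$shom)
  else NULL
  out <- list(model = object, critical = crit,
              load_fixed = object$load_fixed)
  class(out) <- "summary.fixation_model"
  out
}

#' @export
print.summary.fixation_model <- function(x, ...) {
  print(x$model)
  if (!is.null(x$critical)) {
    cat("deterministic (infinite-population) fate:\n  ")
    print(x$critical)
  }
  cat(sprintf("load at fixation L(1) = -shap + shom = %.6g\n", x$load_fixed))
  invisible(x)
}

#' @export
coef.fixation_model <- function(object, ...) {
  p <- object$params
  c(alpha = p$alpha, sO = p$sO, sP = p$sP, shet = p$shet, shom = p$shom,
    mu = p$mu, Fis = p$Fis, shap = p$shap,
    S = object$composite$S, T = object$composite$T)
}

#' Predict fixation probabilities over selfing rates or initial frequencies
#'
#' @param object A [fixation_model].
#' @param alpha Selfing rate(s) at which to evaluate (default: the model's
#'   own).
#' @param p0 Initial frequency for the diffusion method (default `1/2Ne`;
#'   ignored by the flux-equilibrium method, which is defined at `1/2Ne`).
#' @param method `"wright"` (flux equilibrium) or `"diffusion"`.
#' @param ... Unused.
#' @return A data frame with columns `alpha` and `u`.
#' @export
predict.fixation_model <- function(object, alpha = NULL, p0 = NULL,
                                   method = c("wright", "diffusion"), ...) {
  method <- match.arg(method)
  p <- object$params
  if (is.null(p$Ne)) stop("prediction requires a population size", call. = FALSE)
  if (is.null(alpha)) alpha <- p$alpha
  u <- vapply(alpha, function(a) {
    pa <- selfix_params(alpha = a, sO = p$sO, sP = p$sP, shet = p$shet,
                        shom = p$shom, mu = p$mu, Ne = p$Ne)
    if (method == "wright") fixation_prob_wright(pa)
    else fixation_prob_diffusion(pa, p0 = p0)
  }, numeric(1))
  data.frame(alpha = alpha, u = u)
}

#' Simulate fixation experiments from a model
#'
#' `simulate()` method wrapping [simulate_fixation()]: `nsim` is the number
#' of replicate datasets (each of `n_runs` runs).
#'
#' @param object A [fixation_model] with a population size.
#' @param nsim Number of datasets.
#' @param seed Integer seed.
#' @param n_runs Runs per dataset.
#' @param ... Passed to [simulate_fixation()].
#' @return A [simulate_fixation()] estimate.
#' @export
simulate.fixation_model <- function(object, nsim = 1, seed = NULL,
                                    n_runs = 10000, ...) {
  simulate_fixation(object$params, n_runs = n_runs, n_datasets = nsim,
                    seed = seed, ...)
}

#' Plot a fixation model
#'
#' Left panel: the flux-equilibrium density `phi(q)` over the heteroallelic
#' classes (requires `mu > 0`). Right panel: fixation probability against
#' the selfing rate for both methods.
#'
#' @param x A [fixation_model] with a population size.
#' @param alpha_grid Selfing rates for the right panel.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.fixation_model <- function(x, alpha_grid = seq(0, 1, by = 0.05), ...) {
  p <- x$params
  if (is.null(p$Ne)) stop("plotting requires a population size", call. = FALSE)
  op <- graphics::par(mfrow = c(1, if (p$mu > 0) 2 else 1))
  on.exit(graphics::par(op))
  if (p$mu > 0) {
    fd <- phi_flux(p)
    graphics::plot(fd$q_grid, fd$phi, type = "l", xlab = "mutant frequency q",
                   ylab = expression(phi(q)),
                   main = "flux-equilibrium density", ...)
  }
  uw <- predict(x, alpha = alpha_grid, method = "wright")$u
  ud <- predict(x, alpha = alpha_grid, method = "diffusion")$u
  graphics::plot(alpha_grid, uw, type = "l", ylim = range(uw, ud),
                 xlab = expression(alpha), ylab = "fixation probability",
                 main = "u(1/2Ne) vs selfing rate", ...)
  graphics::lines(alpha_grid, ud, lty = 2)
  graphics::abline(h = 1 / (2 * p$Ne), col = "grey")
  graphics::legend("topleft", c("flux equilibrium", "diffusion", "neutral"),
                   lty = c(1, 2, 1), col = c("black", "black", "grey"),
                   bty = "n", cex = 0.8)
  invisible(x)
}
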