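#' Canonical biphasic selection cases
#'
#' The eight selection parameter sets used throughout the numerical
#' comparisons: gametophyte-only and sporophyte-only selection, each for a
#' deleterious and a favourable mutant allele, plus the two antagonistic
#' and two synergistic biphasic combinations (|sO| = |sP| = 0.02,
#' |shom| = 0.03, |shet| = 0.02).
#'
#' @return A data frame with columns `case`, `sO`, `sP`, `shet`, `shom` and
#'   `expected_trend` (the direction in which the fixation probability
#'   moves as the selfing rate increases).
#' @export
selection_cases <- function() {
  data.frame(
    case = c("gametophytic deleterious", "gametophytic favourable",
             "sporophytic deleterious", "sporophytic favourable",
             "antagonistic (gam fav, spo del)", "antagonistic (gam del, spo fav)",
             "synergistic deleterious", "synergistic favourable"),
    sO   = c( 0.02, -0.02,  0.00, 0.00, -0.02, 0.02,  0.02, -0.02),
    sP   = c( 0.02, -0.02,  0.00, 0.00, -0.02, 0.02,  0.02, -0.02),
    shet = c( 0.00,  0.00, -0.02, 0.02, -0.02, 0.02, -0.02,  0.02),
    shom = c( 0.00,  0.00, -0.03, 0.03, -0.03, 0.03, -0.03,  0.03),
    expected_trend = c("increasing", "decreasing", "decreasing", "increasing",
                       "decreasing", "increasing", "increasing", "decreasing"),
    stringsAsFactors = FALSE
  )
}

# '#'-prefixed metadata header so a written table is self-describing and
# reproducible from its own header.
.write_sweep_csv <- function(df, out, meta) {
  con <- file(out, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# selfix %s",
                       as.character(utils::packageVersion("selfix"))),
               paste0("# ", names(meta), " = ", unlist(lapply(meta, format)))),
             con)
  utils::write.table(df, con, sep = ",", dec = ".", row.names = FALSE,
                     quote = FALSE)
}

#' Parameter-sweep tables for the standard numerical comparisons
#'
#' Generates, as plain data frames, the tables behind the package's standard
#' figures:
#' \describe{
#'   \item{`critical_gam`}{critical selfing rate against the composite
#'     gametophytic coefficient (log sweep 2e-5 .. 1e-3) at `mu` 1e-5 and
#'     1e-4.}
#'   \item{`critical_spo`}{critical selfing rate against `shom` (at
#'     `shet = -0.001`) and against `shet` (at `shom = -0.0002`).}
#'   \item{`critical_biphasic`}{critical selfing rate with all three
#'     coefficients swept together, antagonistic (positive sweep) and the
#'     reversed-sign sweep.}
#'   \item{`fixation_alpha`}{fixation probability (flux-equilibrium and
#'     diffusion, optionally Monte Carlo) against the selfing rate for the
#'     eight [selection_cases()], `Ne = 30`.}
#'   \item{`k_ratio_alpha`}{the ratio `K/mu` against the selfing rate for
#'     the eight cases, `Ne = 30`.}
#'   \item{`fixation_alpha_small`}{as `fixation_alpha` with `Ne = 15`.}
#' }
#'
#' @param sweep Which table to build (see Details).
#' @param Ne Effective size for the finite-population sweeps (overridden to
#'   15 by `fixation_alpha_small`).
#' @param mu Mutation rate(s); the critical-rate sweeps use both standard
#'   values `c(1e-5, 1e-4)` by default.
#' @param alpha_grid Selfing-rate grid for the finite-population sweeps.
#' @param include_mc Add Monte Carlo estimate columns (slow).
#' @param n_runs,n_datasets,seed Monte Carlo controls.
#' @param out Optional path; the table is written as CSV with `#`-prefixed
#'   metadata header lines (package version, parameters, seed).
#' @return The table, invisibly when `out` is given.
#' @examples
#' head(figure_table("critical_gam"))
#' @export
figure_table <- function(sweep = c("critical_gam", "critical_spo",
                                   "critical_biphasic", "fixation_alpha",
                                   "k_ratio_alpha", "fixation_alpha_small"),
                         Ne = 30, mu = NULL,
                         alpha_grid = seq(0, 1, by = 0.05),
                         include_mc = FALSE, n_runs = 10000,
                         n_datasets = 100, seed = NULL, out = NULL) {
  sweep <- match.arg(sweep)
  if (sweep == "fixation_alpha_small") { Ne <- 15; sweep <- "fixation_alpha" }

  df <- switch(sweep,
    critical_gam = {
      mus <- if (is.null(mu)) c(1e-5, 1e-4) else mu
      shap <- exp(seq(log(2e-5), log(1e-3), length.out = 25))
      g <- expand.grid(mu = mus, shap = shap)
      g$alpha_star <- mapply(function(m, s)
        critical_alpha_gametophytic(m, s)$alpha_star, g$mu, g$shap)
      g
    },
    critical_spo = {
      mus <- if (is.null(mu)) c(1e-5, 1e-4) else mu
      g1 <- expand.grid(mu = mus, shet = -0.001,
                        shom = -exp(seq(log(1.5e-4), log(9e-4), length.out = 25)))
      g1$swept <- "shom"
      g2 <- expand.grid(mu = mus, shet = -exp(seq(log(3e-4), log(2e-3),
                                                  length.out = 25)),
                        shom = -0.0002)
      g2$swept <- "shet"
      g <- rbind(g1, g2)
      cr <- mapply(function(m, he, ho) {
        r <- critical_alpha_sporophytic(m, he, ho)
        c(r$alpha_star, r$validity$holds)
      }, g$mu, g$shet, g$shom)
      g$alpha_star <- cr[1, ]; g$valid <- as.logical(cr[2, ])
      g
    },
    critical_biphasic = {
      mus <- if (is.null(mu)) c(1e-5, 1e-4) else mu
      cc <- exp(seq(log(2e-5), log(2e-3), length.out = 25))
      g <- rbind(
        data.frame(expand.grid(mu = mus, coef = cc), sign = "positive"),
        data.frame(expand.grid(mu = mus, coef = -cc), sign = "negative"))
      g$alpha_star <- mapply(function(m, co)
        critical_alpha_biphasic(m, co, co, co)$alpha_star, g$mu, g$coef)
      g
    },
    fixation_alpha = {
      cases <- selection_cases()
      g <- merge(cases, expand.grid(case = cases$case, alpha = alpha_grid),
                 by = "case")
      g <- g[order(g$case, g$alpha), ]
      g$u_wright <- NA_real_; g$u_diffusion <- NA_real_
      for (i in seq_len(nrow(g))) {
        p <- selfix_params(alpha = g$alpha[i], sO = g$sO[i], sP = g$sP[i],
                           shet = g$shet[i], shom = g$shom[i], Ne = Ne)
        g$u_wright[i] <- fixation_prob_wright(p)
        g$u_diffusion[i] <- fixation_prob_diffusion(p)
      }
      if (include_mc) {
        g$u_mc <- NA_real_; g$u_mc_sd <- NA_real_
        g$ci_lo <- NA_real_; g$ci_hi <- NA_real_
        for (i in seq_len(nrow(g))) {
          p <- selfix_params(alpha = g$alpha[i], sO = g$sO[i], sP = g$sP[i],
                             shet = g$shet[i], shom = g$shom[i], Ne = Ne)
          est <- simulate_fixation(p, n_runs = n_runs, n_datasets = n_datasets,
                                   seed = seed, init = "freq_ne")
          g$u_mc[i] <- est$u_hat; g$u_mc_sd[i] <- est$sd
          g$ci_lo[i] <- est$ci95[1]; g$ci_hi[i] <- est$ci95[2]
          if (!is.null(seed)) seed <- seed + 1L
        }
      }
      rownames(g) <- NULL
      g
    },
    k_ratio_alpha = {
      m <- if (is.null(mu)) 1e-4 else mu[1]  # K/mu is independent of mu
      cases <- selection_cases()
      g <- merge(cases, expand.grid(case = cases$case, alpha = alpha_grid),
                 by = "case")
      g <- g[order(g$case, g$alpha), ]
      g$K_over_mu <- NA_real_
      for (i in seq_len(nrow(g))) {
        p <- selfix_params(alpha = g$alpha[i], sO = g$sO[i], sP = g$sP[i],
                           shet = g$shet[i], shom = g$shom[i], mu = m, Ne = Ne)
        g$K_over_mu[i] <- decay_rate_K(p) / m
      }
      rownames(g) <- NULL
      g
    })

  if (!is.null(out)) {
    .write_sweep_csv(df, out, list(sweep = sweep, Ne = Ne,
                                   seed = if (is.null(seed)) NA else seed))
    return(invisible(df))
  }
  df
}
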