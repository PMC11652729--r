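test_that("psi reproduces both classical special cases", {
  expect_equal(psi_wright(0, 0), 1, tolerance = 1e-12)
  expect_equal(psi_wright(2, 0), sinh(2) / 2, tolerance = 1e-11)
  # sinh(x)/x across a wide range, and evenness in x
  for (x in c(0.1, 1, 5, 12, 20)) {
    expect_equal(psi_wright(x, 0), sinh(x) / x, tolerance = 1e-10)
    expect_equal(psi_wright(-x, 0.7), psi_wright(x, 0.7), tolerance = 1e-11)
  }
  # series coefficients of psi(0, y): 1, 1/3!, 7/5!, 27/7!
  h <- 1e-2
  ys <- h * c(-3, -2, -1, 0, 1, 2, 3)
  vals <- vapply(ys, function(y) psi_wright(0, y), numeric(1))
  fit <- lm(vals ~ poly(ys, 3, raw = TRUE))
  cf <- unname(coef(fit))
  expect_equal(cf[1], 1, tolerance = 1e-9)
  expect_equal(cf[2], 1 / factorial(3), tolerance = 1e-6)
  expect_equal(cf[3], 7 / factorial(5), tolerance = 1e-4)
  expect_equal(cf[4], 27 / factorial(7), tolerance = 1e-2)
  # quadrature and independent double series agree
  for (x in c(0, 0.5, 2)) for (y in c(-1, 0, 1, 3))
    expect_equal(psi_wright(x, y), psi_wright(x, y, method = "series"),
                 tolerance = 1e-10)
  expect_error(psi_wright(1000, 0), "overflow")
})

test_that("flux density: neutral limit, selection response, and subterminal classes", {
  pn <- selfix_params(alpha = 0, mu = 1e-4, Ne = 30)
  fd <- phi_flux(pn)
  # neutral phi(q) = 4 Ne mu / q, so phi * q is constant
  expect_equal(fd$phi * fd$q_grid, rep(4 * 30 * 1e-4, 59), tolerance = 0.01)
  expect_equal(fd$K, 1e-4, tolerance = 1e-12)

  # net-favourable selection tilts mass towards fixation
  pf <- selfix_params(alpha = 0, shet = 0.01, shom = 0.02, mu = 1e-4, Ne = 30)
  ff <- phi_flux(pf)
  neutral_ratio <- fd$phi[59] / fd$phi[1]
  expect_gt(ff$phi[59] / ff$phi[1], neutral_ratio)

  # f(1 - 1/2Ne) ~ 2K across the canonical cases
  for (i in 1:8) {
    p <- case_params(i, alpha = 0.5, mu = 1e-4)
    f <- phi_flux(p)
    expect_equal(f$f_sub_high / (2 * f$K), 1, tolerance = 0.05)
  }

  # quasi-stationary oracle agreement away from the boundaries (Ne = 12,
  # antagonistic case)
  p12 <- case_params(6, alpha = 0.5, Ne = 12, mu = 1e-3)
  f12 <- phi_flux(p12)
  qsd <- quasi_stationary(allele_count_chain(p12, mutation = TRUE))
  band <- 3:20
  a <- f12$f[band] / sum(f12$f[band])
  b <- qsd$distribution[-1][band] / sum(qsd$distribution[-1][band])
  expect_lt(max(abs(a / b - 1)), 0.05)
})

test_that("Wright fixation probability: neutral value, bound, and monotonicity", {
  expect_equal(fixation_prob_wright(selfix_params(alpha = 0, Ne = 30)),
               (1 / 60) / (1 - 1 / 60), tolerance = 1e-12)

  # gametophyte-deleterious: below the neutral drift value 1/2Ne
  p <- selfix_params(alpha = 0, sO = 0.02, sP = 0.02, Ne = 30)
  expect_lt(fixation_prob_wright(p), 1 / 60)

  ag <- seq(0, 1, by = 0.1)
  u_gam <- vapply(ag, function(a)
    fixation_prob_wright(selfix_params(alpha = a, sO = 0.02, sP = 0.02,
                                       Ne = 30)), numeric(1))
  expect_true(all(diff(u_gam) > 0))       # selfing facilitates fixation
  u_spo <- vapply(ag, function(a)
    fixation_prob_wright(selfix_params(alpha = a, shet = -0.02, shom = -0.03,
                                       Ne = 30)), numeric(1))
  expect_true(all(diff(u_spo) < 0))       # selfing impedes fixation

  # mu never enters u
  u_mu <- vapply(c(1e-6, 1e-5, 1e-4), function(m)
    fixation_prob_wright(selfix_params(alpha = 0.3, sO = 0.01, sP = 0.01,
                                       shet = -0.01, shom = -0.005, mu = m,
                                       Ne = 30)), numeric(1))
  expect_equal(u_mu[1], u_mu[2], tolerance = 1e-12)
  expect_equal(u_mu[1], u_mu[3], tolerance = 1e-12)
})

test_that("decay rate K: neutral value, psi/quadrature routes, additive form", {
  pn <- selfix_params(alpha = 0.4, mu = 2e-4, Ne = 30)
  expect_equal(decay_rate_K(pn), 2e-4, tolerance = 1e-12)

  for (i in 1:8) for (a in c(0, 0.5, 1)) {
    p <- case_params(i, alpha = a, mu = 1e-4)
    expect_equal(decay_rate_K(p, method = "psi"),
                 decay_rate_K(p, method = "quadrature"), tolerance = 1e-10)
    # subterminal-class link between K and the flux density
    f <- phi_flux(p)
    expect_equal(f$phi[59] / (4 * 30) / f$K, 1, tolerance = 0.05)
  }

  # additive sporophytic closed form: exact agreement, plus its signed limits
  for (a in c(0, 0.3, 0.8)) {
    p <- selfix_params(alpha = a, sO = 0.01, sP = 0.01, shet = -0.01,
                       shom = -0.02, mu = 1e-4, Ne = 30)
    expect_equal(decay_rate_K(p) / p$mu, k_over_mu_additive(p),
                 tolerance = 1e-8)
  }
  expect_equal(k_over_mu_additive(selfix_params(alpha = 0.7, mu = 1e-4,
                                                Ne = 30)), 1)
  # 4 Ne X = 1 evaluates the closed form directly: X = (1+Fis) shet
  p1 <- selfix_params(alpha = 0, shet = 1 / 120, shom = 1 / 60, Ne = 30)
  expect_equal(k_over_mu_additive(p1), 1 / (1 - exp(-1)), tolerance = 1e-10)
  expect_lt(k_over_mu_additive(selfix_params(alpha = 0, shet = -0.01,
                                             shom = -0.02, Ne = 30)), 1)
  expect_gt(k_over_mu_additive(selfix_params(alpha = 0, shet = 0.01,
                                             shom = 0.02, Ne = 30)), 1)
  expect_error(k_over_mu_additive(selfix_params(shet = -0.01, shom = -0.015,
                                                Ne = 30)), "additive")

  # quasi-stationary decay eigenvalue cross-check at small Ne
  p12 <- case_params(6, alpha = 0.5, Ne = 12, mu = 1e-3)
  qs <- quasi_stationary(allele_count_chain(p12, mutation = TRUE))
  expect_equal(qs$decay_rate / decay_rate_K(p12), 1, tolerance = 0.1)
})

test_that("K/mu sits on the correct side of 1 given the net selection", {
  # Jensen: S + T/3 < 0 forces K/mu < 1; the favourable side holds at the
  # canonical parameter magnitudes
  for (i in 1:8) for (a in c(0, 0.25, 0.5, 0.75, 1)) {
    p <- case_params(i, alpha = a, mu = 1e-4)
    cs <- composite_selection(p)
    s3 <- cs$S + cs$T / 3
    if (abs(s3) < 1e-4) next
    expect_identical(sign(decay_rate_K(p) / p$mu - 1), sign(s3))
  }
})

test_that("genetic loads: endpoints, direct substitution, and quadrature", {
  p <- selfix_params(alpha = 0, sO = 0.01, sP = 0, shet = -0.02, shom = -0.03)
  expect_identical(load_infinite(0, p), 0)
  expect_equal(load_infinite(1, p), -p$shap + p$shom)
  expect_equal(load_infinite(0.5, p),
               0.5 * (-0.01 + 2 * 0.5 * (-0.02) + 0.5 * (-0.03)))

  # neutral integrand vanishes identically
  expect_equal(load_finite_mean(selfix_params(alpha = 0.2, mu = 1e-4,
                                              Ne = 30)), 0)
  # deleterious in both phases: negative mean load in raw-density mode
  pd <- selfix_params(alpha = 0.5, sO = 0.02, sP = 0.02, shet = -0.02,
                      shom = -0.03, mu = 1e-4, Ne = 30)
  expect_lt(load_finite_mean(pd), 0)

  # adaptive quadrature vs an independent fine trapezoid
  fd <- phi_flux(pd)
  qg <- seq(1 / 60, 1 - 1 / 60, length.out = 4001)
  cs <- composite_selection(pd)
  a <- 4 * 30 * cs$S; b <- 2 * 30 * cs$T
  I0 <- integrate(function(x) exp(-a * x - b * x^2), 0, 1,
                  rel.tol = 1e-12)$value
  phi_g <- vapply(qg, function(qi) {
    Iq <- integrate(function(x) exp(-a * x - b * x^2), qi, 1,
                    rel.tol = 1e-12)$value
    4 * 30 * pd$mu / (qi * (1 - qi)) * exp(a * qi + b * qi^2) * Iq / I0
  }, numeric(1))
  integrand <- load_infinite(qg, pd) * phi_g
  trap <- sum((integrand[-1] + integrand[-length(qg)]) / 2 * diff(qg))
  expect_equal(load_finite_mean(pd), trap, tolerance = 1e-6)

  # normalised variant rescales by the band mass
  mass <- sum((phi_g[-1] + phi_g[-length(qg)]) / 2 * diff(qg))
  expect_equal(load_finite_mean(pd, normalize = TRUE),
               load_finite_mean(pd) / mass, tolerance = 1e-5)
})
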