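test_that("gametophyte-only critical rate: boundary cases and closed form", {
  # 2 mu / shap = 1 puts the boundary exactly at alpha = 0
  expect_equal(critical_alpha_gametophytic(1e-4, 2e-4)$alpha_star, 0)
  # r = 0.2 -> alpha* = 2(1-r)/(2-r)
  cr <- critical_alpha_gametophytic(1e-4, 1e-3)
  expect_equal(cr$alpha_star, 2 * (1 - 0.2) / (2 - 0.2))
  expect_identical(cr$direction, "above")
  # favourable gametophytic allele fixes in any mating system
  expect_identical(critical_alpha_gametophytic(1e-4, -1e-3)$status,
                   "always-fixes")
})

test_that("sporophyte-only critical rate: validity and direction", {
  cr <- critical_alpha_sporophytic(1e-4, -1e-3, -2e-4)
  r <- (1e-4 - 2e-4) / (-1e-3)
  expect_equal(cr$alpha_star, 2 * (1 - r) / (2 - r))
  expect_identical(cr$direction, "below")   # selfing impedes fixation
  expect_true(cr$validity$holds)
  # validity condition violated -> flagged
  bad <- critical_alpha_sporophytic(1e-4, -1e-3, 2e-4)  # r < 0
  expect_false(bad$validity$holds)
  expect_identical(bad$status, "always-fixes")
})

test_that("biphasic critical rate covers antagonistic and synergistic regimes", {
  cr <- critical_alpha_biphasic(1e-5, 0.001, 0.0005, 0.0002)
  r <- (1e-5 + 2e-4) / (5e-4 + 5e-4)
  expect_equal(cr$alpha_star, 2 * (1 - r) / (2 - r))
  expect_identical(cr$direction, "above")
  # favourable in both phases
  expect_identical(critical_alpha_biphasic(1e-5, -0.001, 0.0005, 0.0002)$status,
                   "always-fixes")
  # synergistic deleterious outside the existence window
  # shet + shap/2 <= mu + shom <= 0
  expect_identical(critical_alpha_biphasic(1e-4, 0.001, -0.001, -5e-4)$status,
                   "never-fixes")
  # synergistic deleterious inside the window shet + shap/2 > mu + shom > 0
  ok <- critical_alpha_biphasic(3e-4, 0.002, -2e-4, -2e-4)
  expect_identical(ok$status, "boundary")
  expect_identical(ok$direction, "above")
})

test_that("all eight derivative-sign claims hold on frozen grids", {
  fd <- function(f, x, h) (f(x + h) - f(x - h)) / (2 * h)
  # gametophytic deleterious: d alpha*/d shap > 0, d alpha*/d mu < 0
  shap_g <- exp(seq(log(4e-4), log(2e-3), length.out = 5))
  mu_g <- exp(seq(log(2e-5), log(1e-4), length.out = 5))
  for (s in shap_g) for (m in mu_g) {
    expect_gt(fd(function(x) critical_alpha_gametophytic(m, x)$alpha_star,
                 s, s * 1e-4), 0)
    expect_lt(fd(function(x) critical_alpha_gametophytic(x, s)$alpha_star,
                 m, m * 1e-4), 0)
  }
  # sporophytic deleterious: d/d shet < 0, d/d shom > 0, d/d mu > 0
  shet_g <- -exp(seq(log(5e-4), log(2e-3), length.out = 5))
  shom_g <- -exp(seq(log(2e-4), log(4e-4), length.out = 5))
  for (he in shet_g) for (ho in shom_g) {
    m <- 1e-4
    if ((m + ho) / he < 0 || (m + ho) / he > 1) next
    expect_lt(fd(function(x) critical_alpha_sporophytic(m, x, ho)$alpha_star,
                 he, abs(he) * 1e-4), 0)
    expect_gt(fd(function(x) critical_alpha_sporophytic(m, he, x)$alpha_star,
                 ho, abs(ho) * 1e-4), 0)
    expect_gt(fd(function(x) critical_alpha_sporophytic(x, he, ho)$alpha_star,
                 m, m * 1e-4), 0)
  }
  # favourable sporophytic allele: all three signs reverse
  for (he in -shet_g) for (ho in -shom_g) {
    m <- 1e-5
    if ((m + ho) / he < 0 || (m + ho) / he > 1) next
    expect_gt(fd(function(x) critical_alpha_sporophytic(m, x, ho)$alpha_star,
                 he, he * 1e-4), 0)
    expect_lt(fd(function(x) critical_alpha_sporophytic(m, he, x)$alpha_star,
                 ho, ho * 1e-4), 0)
    expect_lt(fd(function(x) critical_alpha_sporophytic(x, he, ho)$alpha_star,
                 m, m * 1e-4), 0)
  }
})

test_that("biphasic sweeps move in the documented directions", {
  # antagonistic (all coefficients positive): alpha* rises with the
  # coefficients and falls with mu
  cc <- exp(seq(log(2e-5), log(2e-3), length.out = 8))
  for (m in c(1e-5, 1e-4)) {
    a <- vapply(cc, function(co)
      critical_alpha_biphasic(m, co, co, co)$alpha_star, numeric(1))
    keep <- !is.na(a)
    expect_true(all(diff(a[keep]) > 0))
  }
  a5 <- critical_alpha_biphasic(1e-5, 1e-3, 1e-3, 1e-3)$alpha_star
  a4 <- critical_alpha_biphasic(1e-4, 1e-3, 1e-3, 1e-3)$alpha_star
  expect_gt(a5, a4)
  # reversed signs: alpha* rises with mu
  b5 <- critical_alpha_biphasic(1e-5, -1e-3, -1e-3, -1e-3)$alpha_star
  b4 <- critical_alpha_biphasic(1e-4, -1e-3, -1e-3, -1e-3)$alpha_star
  expect_lt(b5, b4)
})

test_that("the recursion oracle confirms the analytic boundaries", {
  # neutral with mutation fixes at every selfing rate
  pn <- selfix_params(alpha = 0, mu = 1e-3)
  on <- critical_alpha_numeric(pn, alpha_tol = 0.05, grid_n = 5, max_gen = 1e5)
  expect_identical(on$uniform, "always-fixes")

  # gametophyte-only
  p1 <- selfix_params(alpha = 0, sO = 5e-4, sP = 5e-4, mu = 1e-4)
  n1 <- critical_alpha_numeric(p1, alpha_tol = 1e-3, grid_n = 11)
  expect_equal(nrow(n1$boundaries), 1L)
  expect_identical(n1$boundaries$direction, "above")
  expect_lt(abs(n1$boundaries$alpha_star -
                  critical_alpha_gametophytic(1e-4, 1e-3)$alpha_star), 1e-3)

  # sporophyte-only with the q -> 1 endpoint binding: the oracle finds the
  # lower trapping boundary and the upper boundary equal to alpha2*
  p2 <- selfix_params(alpha = 0, shet = -1e-3, shom = -1.2e-4, mu = 1e-4)
  n2 <- critical_alpha_numeric(p2, alpha_tol = 1e-3, grid_n = 11)
  a2 <- critical_alpha_sporophytic(1e-4, -1e-3, -1.2e-4)$alpha_star
  upper <- n2$boundaries[n2$boundaries$direction == "below", , drop = FALSE]
  expect_equal(nrow(upper), 1L)
  expect_lt(abs(upper$alpha_star - a2), 1e-3)

  # biphasic antagonistic
  p3 <- selfix_params(alpha = 0, sO = 5e-4, sP = 5e-4, shet = 5e-4,
                      shom = 2e-4, mu = 1e-5)
  n3 <- critical_alpha_numeric(p3, alpha_tol = 1e-3, grid_n = 11)
  a3 <- critical_alpha_biphasic(1e-5, 1e-3, 5e-4, 2e-4)$alpha_star
  expect_lt(abs(n3$boundaries$alpha_star[1] - a3), 1e-3)
})

test_that("the q->1 condition is necessary: numeric boundary never exceeds it", {
  # at these sporophytic parameters an interior dip closes the fixation
  # window before the endpoint condition does, so the recursion's upper
  # boundary sits strictly below alpha2*
  p <- selfix_params(alpha = 0, shet = -1e-3, shom = -2e-4, mu = 1e-4)
  nm <- critical_alpha_numeric(p, alpha_tol = 2e-3, grid_n = 11)
  a2 <- critical_alpha_sporophytic(1e-4, -1e-3, -2e-4)$alpha_star
  upper <- nm$boundaries[nm$boundaries$direction == "below", , drop = FALSE]
  expect_equal(nrow(upper), 1L)
  expect_lte(upper$alpha_star, a2 + 2e-3)
  # two boundaries: a lower trapping threshold plus the upper one
  expect_equal(nrow(nm$boundaries), 2L)
})
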