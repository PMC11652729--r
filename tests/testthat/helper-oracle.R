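# Brute-force one-generation oracle: enumerates parental genotypes, gamete
# types and (for outcrossing) all 3 x 3 parental pairs, instead of the
# pooled-frequency algebra used by the implementation. Used to validate
# step_generation() on arbitrary states.
bf_step <- function(st, pr, mu_on = TRUE) {
  f <- c(AA = st[["pAA"]], Aa = st[["pAa"]], aa = st[["paa"]])
  ov <- list(AA = c(A = 1, a = 0),
             Aa = c(A = 1, a = 1 - pr$sO) / (2 - pr$sO),
             aa = c(A = 0, a = 1))
  po <- list(AA = c(A = 1, a = 0),
             Aa = c(A = 1, a = 1 - pr$sP) / (2 - pr$sP),
             aa = c(A = 0, a = 1))
  wov <- c(AA = 1, Aa = 1 - pr$sO / 2, aa = 1 - pr$sO)  # ovule output
  wpo <- c(AA = 1, Aa = 1 - pr$sP / 2, aa = 1 - pr$sP)  # pollen output
  mate <- function(od, pd)
    c(AA = od[["A"]] * pd[["A"]],
      Aa = od[["A"]] * pd[["a"]] + od[["a"]] * pd[["A"]],
      aa = od[["a"]] * pd[["a"]])
  selfz <- c(AA = 0, Aa = 0, aa = 0)
  for (g in names(f)) selfz <- selfz + f[[g]] * mate(ov[[g]], po[[g]])
  om <- f * wov; om <- om / sum(om)
  pm <- f * wpo; pm <- pm / sum(pm)
  outz <- c(AA = 0, Aa = 0, aa = 0)
  for (g in names(f)) for (h in names(f))
    outz <- outz + om[[g]] * pm[[h]] * mate(ov[[g]], po[[h]])
  z <- pr$alpha * selfz + (1 - pr$alpha) * outz
  if (mu_on && pr$mu > 0) {
    m <- pr$mu
    z <- c(AA = z[["AA"]] * (1 - m)^2,
           Aa = z[["AA"]] * 2 * m * (1 - m) + z[["Aa"]] * (1 - m),
           aa = z[["AA"]] * m^2 + z[["Aa"]] * m + z[["aa"]])
  }
  w <- c(AA = 1, Aa = 1 + pr$shet, aa = 1 + pr$shom)
  z <- z * w
  z / sum(z)
}

# parameter constructor shorthand for the canonical biphasic cases
case_params <- function(i, alpha, Ne = 30, mu = 0) {
  cs <- selection_cases()
  selfix_params(alpha = alpha, sO = cs$sO[i], sP = cs$sP[i],
                shet = cs$shet[i], shom = cs$shom[i], mu = mu, Ne = Ne)
}
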