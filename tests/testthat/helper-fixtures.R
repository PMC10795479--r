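# shared fixtures and independent oracles for the test suite

# worked-example schedules (rates + nax printed to 6 d.p.)
tab1_1990 <- function(counts = FALSE) pacific_women("1990", counts = counts)
tab1_2019 <- function(counts = FALSE) pacific_women("2019", counts = counts)

# the printed decomposition column, infancy through 85+
tab1_arriaga <- c(0.34, 0.08, 0.03, 0.04, 0.06, 0.04, 0.05, 0.05, 0.07,
                  0.09, 0.19, 0.29, 0.33, 0.48, 0.58, 0.65, 0.69, 0.56, 1.05)

# hazard parameter sets bracketing the worked example's two periods
mk_base <- list(makeham = c(c = 1e-4, b = 4e-6, theta = 0.122),
                infant = c(a = 0.0075, b = 1.5))
mk_comp <- list(makeham = c(c = 5e-5, b = 1.7e-6, theta = 0.125),
                infant = c(a = 0.0035, b = 1.5))

synth_pair <- function(noise = "poisson", seeds = c(1, 2)) {
  list(synth_schedule(makeham = mk_base$makeham, infant = mk_base$infant,
                      noise = noise, seed = seeds[1]),
       synth_schedule(makeham = mk_comp$makeham, infant = mk_comp$infant,
                      noise = noise, seed = seeds[2]))
}

# a random valid schedule pair for property-based checks: multiplicative
# lognormal tilts of the two default hazards
random_pair <- function() {
  f1 <- exp(stats::rnorm(2, 0, 0.3))
  f2 <- exp(stats::rnorm(2, 0, 0.3))
  p1 <- c(mk_base$makeham[1:2] * f1[1], mk_base$makeham[3])
  p2 <- c(mk_comp$makeham[1:2] * f2[1], mk_comp$makeham[3])
  list(synth_schedule(makeham = p1,
                      infant = c(a = mk_base$infant[["a"]] * f1[2], b = 1.5),
                      noise = "poisson", seed = sample.int(1e6, 1)),
       synth_schedule(makeham = p2,
                      infant = c(a = mk_comp$infant[["a"]] * f2[2], b = 1.5),
                      noise = "poisson", seed = sample.int(1e6, 1)))
}

# -- independent finite-difference oracle -----------------------------------
# rebuilds the decomposition directly from the parameter vector
# (closed-group survival probabilities and open-group death counts),
# with nax, widths and exposures held fixed; used to differentiate the
# decomposition numerically without going through the analytic Jacobian.
oracle_lt <- function(p, Dw, sched) {
  K <- nrow(sched)
  l <- cumprod(c(1, p))
  mw <- Dw / sched$exposure[K]
  a <- sched$ax; n <- sched$n
  L <- c(n[-K] * l[-1] + a[-K] * (l[-K] - l[-1]), l[K] / mw)
  T <- rev(cumsum(rev(L)))
  list(q = c(1 - p, 1), p = c(p, 0), l = l, L = L, T = T, e = T / l,
       m = c(rep(NA, K - 1), mw), a = a, n = n)
}

oracle_decomp <- function(p1, D1, p2, D2, s1, s2) {
  lexpdecomp:::arriaga_core(oracle_lt(p1, D1, s1), oracle_lt(p2, D2, s2))
}

# central finite differences of the decomposition w.r.t. every parameter;
# returns the same dp1/dp2/dD1/dD2 layout as arriaga_jacobian()
fd_jacobian <- function(s1, s2, h_p = 1e-6, h_D = 1) {
  lt1 <- life_table(s1); lt2 <- life_table(s2)
  K <- nrow(s1)
  p1 <- lt1$p[-K]; p2 <- lt2$p[-K]
  D1 <- s1$deaths[K]; D2 <- s2$deaths[K]
  dp1 <- matrix(0, K, K - 1L); dp2 <- matrix(0, K, K - 1L)
  for (i in seq_len(K - 1L)) {
    up <- p1; up[i] <- up[i] + h_p; dn <- p1; dn[i] <- dn[i] - h_p
    dp1[, i] <- (oracle_decomp(up, D1, p2, D2, s1, s2) -
                 oracle_decomp(dn, D1, p2, D2, s1, s2)) / (2 * h_p)
    up <- p2; up[i] <- up[i] + h_p; dn <- p2; dn[i] <- dn[i] - h_p
    dp2[, i] <- (oracle_decomp(p1, D1, up, D2, s1, s2) -
                 oracle_decomp(p1, D1, dn, D2, s1, s2)) / (2 * h_p)
  }
  dD1 <- (oracle_decomp(p1, D1 + h_D, p2, D2, s1, s2) -
          oracle_decomp(p1, D1 - h_D, p2, D2, s1, s2)) / (2 * h_D)
  dD2 <- (oracle_decomp(p1, D1, p2, D2 + h_D, s1, s2) -
          oracle_decomp(p1, D1, p2, D2 - h_D, s1, s2)) / (2 * h_D)
  list(dp1 = dp1, dp2 = dp2, dD1 = dD1, dD2 = dD2)
}

# relative disagreement with an absolute floor so that finite-difference
# noise (~1e-10) against exact structural zeros does not register
max_rel_err <- function(analytic, numeric, floor = 1e-3) {
  max(abs(analytic - numeric) / pmax(abs(analytic), abs(numeric), floor))
}

expect_jacobian_matches_fd <- function(s1, s2, tol = 1e-5) {
  jac <- arriaga_jacobian(life_table(s1), life_table(s2))
  fd <- fd_jacobian(s1, s2)
  expect_lt(max_rel_err(jac$dp1, fd$dp1), tol)
  expect_lt(max_rel_err(jac$dp2, fd$dp2), tol)
  expect_lt(max_rel_err(jac$dD1, fd$dD1), tol)
  expect_lt(max_rel_err(jac$dD2, fd$dD2), tol)
}
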