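test_that("the Jacobian's sparsity pattern is exact", {
  s1 <- tab1_1990(counts = TRUE); s2 <- tab1_2019(counts = TRUE)
  jac <- arriaga_jacobian(life_table(s1), life_table(s2))
  K <- 19L
  for (x in 1:(K - 1)) {
    expect_identical(unname(jac$dp1[x, seq_len(K - 1) > x]),
                     rep(0, sum(seq_len(K - 1) > x)))
    expect_identical(unname(jac$dp2[x, seq_len(K - 1) < x]),
                     rep(0, sum(seq_len(K - 1) < x)))
  }
  expect_identical(jac$dD1[1:(K - 1)], rep(0, K - 1))
  expect_identical(unname(jac$dp2[K, ]), rep(0, K - 1))
})

test_that("identical populations give mirror-image diagonal derivatives", {
  s <- tab1_1990(counts = TRUE)
  lt <- life_table(s)
  jac <- arriaga_jacobian(lt, lt)
  expect_equal(diag(jac$dp1), -diag(jac$dp2), tolerance = 1e-12)
})

test_that("the analytic Jacobian matches finite differences (worked example)", {
  expect_jacobian_matches_fd(tab1_1990(counts = TRUE),
                             tab1_2019(counts = TRUE))
})

test_that("the analytic Jacobian matches finite differences (random pairs)", {
  set.seed(99)
  for (r in 1:10) {
    pair <- random_pair()
    expect_jacobian_matches_fd(pair[[1]], pair[[2]])
  }
})

test_that("count variances: boundaries and 1/D scaling", {
  g <- age_grid(c(0, 5, 10))
  s <- mortality_schedule(g, deaths = c(100, 200, 500), exposure = rep(1e4, 3))
  v <- count_variances(s, s)
  p <- 1 - q_from_m(s$rate[1:2], s$ax[1:2], s$n[1:2])
  expect_equal(v$var_p1, (1 - p)^2 * p / s$deaths[1:2], tolerance = 1e-14)
  expect_equal(v$var_D1, 500)

  s2 <- mortality_schedule(g, deaths = 2 * c(100, 200, 500),
                           exposure = 2 * rep(1e4, 3))
  v2 <- count_variances(s2, s2)
  expect_equal(v2$var_p1, v$var_p1 / 2, tolerance = 1e-14)

  # zero deaths in a closed group: zero variance, with warnings
  s0 <- suppressWarnings(
    mortality_schedule(g, deaths = c(0, 200, 500), exposure = rep(1e4, 3)))
  expect_warning(v0 <- count_variances(s0, s), "zero")
  expect_equal(v0$var_p1[1], 0)
})

test_that("analytic probability variance matches binomial simulation", {
  n <- 5; a <- 2.5; N <- 1e4; D <- 200
  m <- D / N
  q <- q_from_m(m, a, n)
  trials <- round(D / q)
  set.seed(123)
  qs <- stats::rbinom(5000, trials, q) / trials
  v_emp <- stats::var(qs)
  v_analytic <- (1 - (1 - q))^2 * (1 - q) / D
  expect_equal(v_emp, v_analytic, tolerance = 0.1)
})

test_that("zero parameter variances give zero standard errors", {
  s1 <- tab1_1990(counts = TRUE); s2 <- tab1_2019(counts = TRUE)
  jac <- arriaga_jacobian(life_table(s1), life_table(s2))
  v <- count_variances(s1, s2)
  v$var_p1[] <- 0; v$var_p2[] <- 0; v$var_D1 <- 0; v$var_D2 <- 0
  u <- delta_se(jac, v)
  expect_identical(unname(u$se), rep(0, 20))
})

test_that("the total SE equals the two-population e0-variance composition", {
  s1 <- tab1_1990(counts = TRUE); s2 <- tab1_2019(counts = TRUE)
  u <- delta_se(arriaga_jacobian(life_table(s1), life_table(s2)),
                count_variances(s1, s2))
  oracle <- sqrt(e0_var_delta(s1) + e0_var_delta(s2))
  expect_equal(unname(u$se["total"]), oracle, tolerance = 1e-8)
  # and on a synthetic pair
  pair <- synth_pair()
  u2 <- delta_se(arriaga_jacobian(life_table(pair[[1]]),
                                  life_table(pair[[2]])),
                 count_variances(pair[[1]], pair[[2]]))
  expect_equal(unname(u2$se["total"]),
               sqrt(e0_var_delta(pair[[1]]) + e0_var_delta(pair[[2]])),
               tolerance = 1e-8)
})

test_that("survey variances with binomial-implied SEs reproduce count variances", {
  s1 <- tab1_1990(counts = TRUE); s2 <- tab1_2019(counts = TRUE)
  implied_se <- function(s) {
    K <- nrow(s); cl <- seq_len(K - 1)
    q <- q_from_m(s$rate[cl], s$ax[cl], s$n[cl])
    se_p <- sqrt(q^2 * (1 - q) / s$deaths[cl])
    dq <- lexpdecomp:::dq_dm(s$rate[cl], s$ax[cl], s$n[cl])
    c(se_p / dq, sqrt(s$deaths[K]) / s$exposure[K])
  }
  vs <- survey_variances(s1, s2, implied_se(s1), implied_se(s2))
  vc <- count_variances(s1, s2)
  expect_equal(vs$var_p1, vc$var_p1, tolerance = 1e-12)
  expect_equal(vs$var_p2, vc$var_p2, tolerance = 1e-12)
  expect_equal(vs$var_D1, vc$var_D1, tolerance = 1e-12)

  # all-zero SEs give zero variances; missing SEs are an error
  z <- rep(0, 19)
  v0 <- survey_variances(s1, s2, z, z)
  expect_true(all(v0$var_p1 == 0) && v0$var_D2 == 0)
  expect_error(survey_variances(s1, s2, rep(NA_real_, 19), z),
               "required for every age group")
})

test_that("rate-to-probability SE conversion matches finite differences", {
  m <- 0.02; a <- 2.4; n <- 5; se_m <- 0.001
  h <- 1e-6
  fd <- (q_from_m(m + h, a, n) - q_from_m(m - h, a, n)) / (2 * h)
  expect_equal(lexpdecomp:::dq_dm(m, a, n), fd, tolerance = 1e-6)
})

test_that("delta SEs track the sampling SD of simulated decompositions", {
  s1 <- tab1_1990(counts = TRUE); s2 <- tab1_2019(counts = TRUE)
  u <- delta_se(arriaga_jacobian(life_table(s1), life_table(s2)),
                count_variances(s1, s2))
  set.seed(2024)
  reps <- 2000L
  sims <- matrix(NA_real_, reps, 19L)
  for (r in seq_len(reps)) {
    d1 <- stats::rpois(19L, s1$deaths); d2 <- stats::rpois(19L, s2$deaths)
    sims[r, ] <- lexpdecomp:::arriaga_core(
      lexpdecomp:::lt_core(d1 / s1$exposure, s1$ax, s1$n),
      lexpdecomp:::lt_core(d2 / s2$exposure, s2$ax, s2$n))
  }
  emp <- apply(sims, 2, stats::sd)
  big <- s1$deaths >= 5 & s2$deaths >= 5
  expect_true(all(abs(emp[big] / u$se[1:19][big] - 1) < 0.15))
})
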