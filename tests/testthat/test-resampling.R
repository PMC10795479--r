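test_that("replicate summaries use sd and interpolated percentiles", {
  s <- summarize_replicates(cbind(c(1, 2, 3)))
  expect_equal(unname(s$se), 1)
  expect_equal(unname(s$lower), 1.05)
  expect_equal(unname(s$upper), 2.95)

  s0 <- summarize_replicates(cbind(rep(7, 100)))
  expect_equal(unname(s0$se), 0)
  expect_equal(unname(s0$lower), 7)
  expect_equal(unname(s0$upper), 7)

  set.seed(8)
  sn <- summarize_replicates(cbind(stats::rnorm(100000)))
  expect_equal(unname(sn$lower), -1.96, tolerance = 0.05 / 1.96)
  expect_equal(unname(sn$upper), 1.96, tolerance = 0.05 / 1.96)

  expect_error(summarize_replicates(cbind(c(NA, NA))), "failed")
})

test_that("the Monte Carlo engine recovers a known normal SD", {
  g <- age_grid(c(0, 5, 10))
  v <- 4e-8
  s <- mortality_schedule(g, rate = c(0.01, 0.02, 0.1),
                          rate_se = sqrt(c(v, 0, 0)))
  u <- mc_se(s, estimator = function(x) x[[1]]$rate[1],
             config = sim_config(reps = 10000, seed = 21))
  expect_equal(unname(u$se), sqrt(v), tolerance = 0.05)
})

test_that("zero rate variances give degenerate replicates", {
  g <- age_grid(c(0, 5, 10))
  s <- mortality_schedule(g, rate = c(0.01, 0.02, 0.1), rate_se = rep(0, 3))
  u <- mc_se(list(s, s), config = sim_config(reps = 100, seed = 1))
  expect_identical(unname(u$se), rep(0, 4))
  expect_equal(u$lower, u$upper, tolerance = 1e-15)
})

test_that("every engine honours the seed contract", {
  s1 <- tab1_1990(counts = TRUE); s2 <- tab1_2019(counts = TRUE)
  for (fn in list(
    function(seed) mc_se(list(s1, s2), config = sim_config(100, seed)),
    function(seed) poisson_bootstrap(s1, s2, config = sim_config(100, seed)),
    function(seed) binomial_bootstrap(s1, s2, config = sim_config(100, seed)))) {
    a <- fn(5); b <- fn(5); c <- fn(6)
    expect_identical(a$replicates, b$replicates)
    expect_false(identical(a$replicates, c$replicates))
  }
})

test_that("bootstrap SEs shrink like one over root sample size", {
  s1 <- tab1_1990(counts = TRUE); s2 <- tab1_2019(counts = TRUE)
  big <- function(s) mortality_schedule(attr(s, "grid"),
                                        deaths = s$deaths * 100,
                                        exposure = s$exposure * 100,
                                        ax = s$ax)
  u <- poisson_bootstrap(s1, s2, config = sim_config(2000, seed = 3))
  ub <- poisson_bootstrap(big(s1), big(s2), config = sim_config(2000, seed = 3))
  ratio <- unname(ub$se["total"] / u$se["total"])
  expect_equal(ratio, 0.1, tolerance = 0.08)
})

test_that("monte carlo, poisson bootstrap and delta SEs agree at scale", {
  s1 <- tab1_1990(counts = TRUE); s2 <- tab1_2019(counts = TRUE)
  del <- delta_se(arriaga_jacobian(life_table(s1), life_table(s2)),
                  count_variances(s1, s2))
  cfg <- sim_config(4000, seed = 14)
  mc <- mc_se(list(s1, s2), config = cfg)
  pb <- poisson_bootstrap(s1, s2, config = cfg)
  expect_lt(max(abs(mc$se / del$se - 1)), 0.10)
  expect_lt(max(abs(pb$se / del$se - 1)), 0.10)
  expect_lt(max(abs(mc$se / pb$se - 1)), 0.10)
})

test_that("binomial and poisson bootstraps converge for rare deaths", {
  # q <= 0.01 everywhere, >= 50 expected deaths per group
  g <- age_grid(c(0, 5, 10, 15))
  s1 <- mortality_schedule(g, deaths = c(100, 120, 150, 400),
                           exposure = rep(1e5, 4), ax = c(2.5, 2.5, 2.5, NA))
  s2 <- mortality_schedule(g, deaths = c(60, 80, 100, 300),
                           exposure = rep(1e5, 4), ax = c(2.5, 2.5, 2.5, NA))
  cfg <- sim_config(10000, seed = 7)
  pb <- poisson_bootstrap(s1, s2, config = cfg)
  bb <- binomial_bootstrap(s1, s2, config = cfg)
  expect_lt(max(abs(bb$se / pb$se - 1)), 0.03)
})

test_that("replicates that fail are flagged and bounded by the 1% budget", {
  s1 <- tab1_1990(counts = TRUE); s2 <- tab1_2019(counts = TRUE)
  # an estimator that fails deterministically on a fraction of replicates
  flaky <- local({
    k <- 0
    function(x) {
      k <<- k + 1
      if (k %% 50 == 0) stop("boom")  # 2% failures
      lexpdecomp:::est_pair(x)
    }
  })
  expect_error(mc_se(list(s1, s2), estimator = flaky,
                     config = sim_config(500, seed = 2)),
               "more than 1%")

  # open-group Poisson zero-death replicates are flagged failures
  g <- attr(s1, "grid")
  small <- function(s) {
    d <- s$deaths; d[19] <- 6   # P(Pois(6) = 0) ~ 0.25%
    mortality_schedule(g, deaths = d, exposure = s$exposure, ax = s$ax)
  }
  u <- poisson_bootstrap(small(s1), small(s2),
                         config = sim_config(4000, seed = 123))
  expect_gt(u$failures, 0)
  expect_lt(u$failures, 40)
  expect_true(all(is.finite(u$se)))
})

test_that("the cause-level engine returns finite SEs per age and cause", {
  s1 <- synth_schedule(makeham = mk_base$makeham, infant = mk_base$infant,
                       noise = "poisson", seed = 61)
  s2 <- synth_schedule(noise = "poisson", seed = 62)
  split3 <- function(d) {
    m <- cbind(a = floor(d * 0.5), b = floor(d * 0.3))
    cbind(m, c = d - rowSums(m))
  }
  cp <- list(cause_schedule(s1, split3(s1$deaths)),
             cause_schedule(s2, split3(s2$deaths)))
  u <- mc_se(cp, config = sim_config(400, seed = 5))
  expect_length(u$se, 19 * 3 + 1)
  expect_true(all(is.finite(u$se)))
  expect_true(all(u$se[seq_len(57)] >= 0))
})

test_that("jackknife of a sample mean equals the closed form", {
  set.seed(10)
  x <- data.frame(v = rnorm(40, 10, 2))
  u <- jackknife_microdata(x, function(d) c(mean = mean(d$v)))
  expect_equal(unname(u$se)^2, stats::var(x$v) / nrow(x), tolerance = 1e-12)
})

test_that("jackknife SE of the decomposition total tracks the delta SE", {
  set.seed(303)
  g <- age_grid(c(0, 1, seq(5, 85, 5)))
  per_cell <- 55
  mk_records <- function(qd) {
    do.call(rbind, lapply(seq_len(19), function(k) {
      data.frame(age = g$start[k], death = rbinom(per_cell, 1, qd[k]),
                 py = ifelse(is.finite(g$n[k]), g$n[k], 7))
    }))
  }
  q1 <- seq(0.10, 0.45, length.out = 19)
  q2 <- seq(0.06, 0.40, length.out = 19)
  r1 <- mk_records(q1); r2 <- mk_records(q2)
  r1$pop <- 1L; r2$pop <- 2L
  rec <- rbind(r1, r2)
  est <- function(d) {
    sa <- suppressWarnings(rates_from_records(d[d$pop == 1L, ], g))
    sb <- suppressWarnings(rates_from_records(d[d$pop == 2L, ], g))
    c(total = sum(lexpdecomp:::arriaga_core(
      lexpdecomp:::lt_core(sa$rate, sa$ax, sa$n),
      lexpdecomp:::lt_core(sb$rate, sb$ax, sb$n))))
  }
  u <- jackknife_microdata(rec, est)
  sa <- suppressWarnings(rates_from_records(rec[rec$pop == 1L, ], g))
  sb <- suppressWarnings(rates_from_records(rec[rec$pop == 2L, ], g))
  del <- suppressWarnings(
    delta_se(arriaga_jacobian(life_table(sa), life_table(sb)),
             count_variances(sa, sb)))
  expect_equal(unname(u$se["total"]), unname(del$se["total"]),
               tolerance = 0.20)
})

test_that("duplicating every record scales the jackknife SE by 1/sqrt(2)", {
  set.seed(11)
  x <- data.frame(v = rnorm(300))
  est <- function(d) c(m = mean(d$v))
  u1 <- jackknife_microdata(x, est)
  u2 <- jackknife_microdata(rbind(x, x), est)
  expect_equal(unname(u2$se / u1$se), 1 / sqrt(2), tolerance = 0.02)
})

test_that("jackknife input contracts: N >= 2 and failure flagging", {
  expect_error(jackknife_microdata(data.frame(v = 1), function(d) mean(d$v)),
               "at least 2")
  # estimator that fails when a specific row is removed
  x <- data.frame(v = c(1, 2, 3, 4, 5))
  est <- function(d) { if (!any(d$v == 5)) stop("empty"); mean(d$v) }
  expect_warning(u <- jackknife_microdata(x, est), "failed")
  expect_equal(u$failures, 1L)
})
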