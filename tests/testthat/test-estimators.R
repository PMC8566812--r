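test_that("wald_ratio matches its closed form, including signs", {
  expect_equal(wald_ratio(0.1, 0.01, 0.05, 0.01), list(beta = 0.5, se = 0.1))
  expect_equal(wald_ratio(-0.1, 0.01, 0.05, 0.01), list(beta = -0.5, se = 0.1))
  expect_error(wald_ratio(0, 0.01, 0.05, 0.01, snp_id = "rs9"), "rs9")

  set.seed(11)
  for (i in 1:20) {
    x <- runif(1, -0.5, 0.5)
    if (x == 0) next
    y <- rnorm(1)
    sy <- runif(1, 0.01, 0.2)
    wr <- wald_ratio(x, NULL, y, sy)
    # independent re-computation on the log scale
    expect_equal(wr$beta, sign(y) * sign(x) * exp(log(abs(y)) - log(abs(x))),
                 tolerance = 1e-14)
    expect_equal(wr$se, exp(log(sy) - log(abs(x))), tolerance = 1e-14)
  }
})

test_that("IVW equals the WLS-through-origin oracle and collapses at K = 1", {
  h1 <- make_hset(0.12, 0.01, -0.05, 0.03)
  est1 <- mr_ivw(h1)
  wr <- wald_ratio(0.12, 0.01, -0.05, 0.03)
  expect_equal(est1$beta, wr$beta, tolerance = 1e-15)
  expect_equal(est1$se, wr$se, tolerance = 1e-15)

  for (seed in 1:25) {
    set.seed(seed)
    h <- rand_hset(sample(2:50, 1), seed + 1000)
    est <- mr_ivw(h)
    orc <- wls_origin_oracle(h$X, h$Y, h$se_Y)
    expect_equal(est$beta, orc$beta, tolerance = 1e-10)
    expect_equal(est$se, orc$se, tolerance = 1e-10)
    expect_equal(est$pvalue, 2 * pnorm(-abs(est$beta / est$se)),
                 tolerance = 1e-12)
  }
})

test_that("IVW is permutation invariant and scales exactly", {
  h <- rand_hset(12, 7)
  perm <- sample(12)
  hp <- make_hset(h$X[perm], h$se_X[perm], h$Y[perm], h$se_Y[perm],
                  snp_ids = h$snp_ids[perm])
  expect_equal(mr_ivw(hp)$beta, mr_ivw(h)$beta, tolerance = 1e-14)
  expect_equal(mr_ivw(hp)$se, mr_ivw(h)$se, tolerance = 1e-14)

  for (c_scale in c(0.5, 2, 7.3)) {
    hs <- make_hset(h$X * c_scale, h$se_X, h$Y, h$se_Y)
    expect_equal(mr_ivw(hs)$beta, mr_ivw(h)$beta / c_scale,
                 tolerance = 1e-12)
  }
})

test_that("random-effects IVW only ever widens the interval", {
  h <- rand_hset(15, 21)
  fe <- mr_ivw(h)
  re <- mr_ivw(h, random_effects = TRUE)
  expect_equal(re$beta, fe$beta)
  expect_gte(re$se, fe$se)
})

test_that("weighted median matches the CDF-inversion oracle", {
  # degenerate: all Wald ratios equal -> the common value, any weights
  hc <- make_hset(X = c(0.1, 0.2, 0.4), se_X = 0.01,
                  Y = 0.7 * c(0.1, 0.2, 0.4), se_Y = c(0.02, 0.05, 0.01))
  expect_equal(mr_weighted_median(hc, n_boot = 10, seed = 1)$beta, 0.7,
               tolerance = 1e-12)

  for (seed in 1:15) {
    h <- rand_hset(sample(3:12, 1), seed + 50)
    est <- mr_weighted_median(h, n_boot = 5, seed = 3)
    r <- h$Y / h$X
    w <- (h$X / h$se_Y)^2
    expect_equal(est$beta, weighted_median_oracle(r, w), tolerance = 1e-12)
    expect_gte(est$beta, min(r))
    expect_lte(est$beta, max(r))
  }
})

test_that("weighted median is order invariant under a fixed seed", {
  h <- rand_hset(9, 33)
  perm <- c(4, 1, 9, 2, 8, 3, 7, 5, 6)
  hp <- make_hset(h$X[perm], h$se_X[perm], h$Y[perm], h$se_Y[perm],
                  snp_ids = h$snp_ids[perm])
  a <- mr_weighted_median(h, n_boot = 200, seed = 99)
  b <- mr_weighted_median(hp, n_boot = 200, seed = 99)
  expect_equal(a$beta, b$beta)
  expect_equal(a$se, b$se)

  expect_error(mr_weighted_median(rand_hset(2, 1), seed = 1), "K >= 3")
  expect_error(mr_weighted_median(h, n_boot = 10), "seed")
})

test_that("MR-Egger recovers exact linear data and matches the WLS oracle", {
  x <- c(0.05, 0.1, 0.15, 0.22, 0.3)
  h <- make_hset(x, 0.01, 0.02 + 1.5 * x, runif(5, 0.01, 0.05))
  fit <- mr_egger(h)
  expect_equal(fit$intercept, 0.02, tolerance = 1e-10)
  expect_equal(fit$slope$beta, 1.5, tolerance = 1e-10)

  for (seed in 1:15) {
    h <- rand_hset(sample(3:20, 1), seed + 200)
    fit <- mr_egger(h)
    orc <- wls_egger_oracle(h$X, h$Y, h$se_Y)
    expect_equal(fit$slope$beta, orc$slope, tolerance = 1e-10)
    expect_equal(fit$intercept, orc$intercept, tolerance = 1e-10)
    expect_equal(fit$slope$se, orc$slope_se, tolerance = 1e-10)
    expect_equal(fit$intercept_se, orc$intercept_se, tolerance = 1e-10)
    k <- length(h$snp_ids)
    expect_equal(fit$intercept_pvalue,
                 2 * pt(-abs(fit$intercept / fit$intercept_se), k - 2),
                 tolerance = 1e-12)
  }
})

test_that("Egger is invariant to allele re-orientation of single SNPs", {
  h <- rand_hset(8, 77)
  i <- 3
  h2 <- h
  h2$X[i] <- -h2$X[i]
  h2$Y[i] <- -h2$Y[i]
  f1 <- mr_egger(h)
  f2 <- mr_egger(h2)
  expect_equal(f1$slope$beta, f2$slope$beta, tolerance = 1e-12)
  expect_equal(f1$intercept, f2$intercept, tolerance = 1e-12)
})

test_that("Egger with the intercept constrained to zero reproduces IVW", {
  for (seed in 1:10) {
    h <- rand_hset(sample(3:30, 1), seed + 400)
    ho <- h
    neg <- ho$X < 0  # constrained fit applies the same orientation
    constrained <- mr_egger(h, constrain_intercept = TRUE)
    expect_equal(constrained$beta, mr_ivw(h)$beta, tolerance = 1e-10)
  }
})

test_that("Egger input guards fire", {
  expect_error(mr_egger(rand_hset(2, 5)), "K >= 3")
  flat <- make_hset(rep(0.1, 4), 0.01, rnorm(4), 0.02)
  expect_error(mr_egger(flat), "degenerate")
})

test_that("odds-scale conversion matches quantile oracles", {
  z <- to_odds_scale(0, 0.1)
  expect_equal(z$odds_ratio, 1)
  expect_equal(z$ci_low * z$ci_high, 1, tolerance = 1e-12)  # log-symmetric
  expect_equal(to_odds_scale(log(2), 0.3)$odds_ratio, 2, tolerance = 1e-15)

  for (beta in c(-1, -0.2, 0, 0.4)) {
    for (se in c(0.01, 0.2, 1)) {
      o <- to_odds_scale(beta, se)
      expect_equal(o$ci_low, exp(beta - qnorm(0.975) * se), tolerance = 1e-10)
      expect_equal(o$ci_high, exp(beta + qnorm(0.975) * se), tolerance = 1e-10)
      ot <- to_odds_scale(beta, se, df = 5)
      expect_equal(ot$ci_high, exp(beta + qt(0.975, 5) * se), tolerance = 1e-10)
    }
  }
})

test_that("mr_estimate keeps OR and CI internally consistent", {
  e <- mr_estimate("ivw", 7, -0.46, 0.13)
  expect_equal(e$odds_ratio, exp(e$beta), tolerance = 1e-12)
  expect_lt(e$ci_low, e$odds_ratio)
  expect_gt(e$ci_high, e$odds_ratio)
  expect_equal(e$pvalue, 2 * pnorm(-abs(-0.46 / 0.13)), tolerance = 1e-12)
})
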