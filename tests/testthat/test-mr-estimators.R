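test_that("Wald ratios follow the first-order formula and flip symmetry", {
  d <- instruments(bx = 1, by = 0.5, sy = 0.1)
  wr <- wald_ratios(d)
  expect_equal(wr$ratio, 0.5)
  expect_equal(wr$ratio_se, 0.1)

  d2 <- instruments(bx = 0.02, by = -0.001, sy = 0.004)
  wr2 <- wald_ratios(d2)
  expect_equal(wr2$ratio, -0.05)
  expect_equal(wr2$ratio_se, 0.2)

  # negating both betas (allele flip) leaves the ratio unchanged
  d3 <- dplyr::mutate(d2, beta_exposure = -beta_exposure,
                      beta_outcome = -beta_outcome)
  expect_equal(wald_ratios(d3)$ratio, wr2$ratio)

  expect_error(wald_ratios(instruments(bx = 0, by = 0.1)), "zero exposure")
})

test_that("IVW equals the weighted-least-squares-through-origin oracle", {
  for (seed in 1:100) {
    d <- random_instruments(j = sample(4:30, 1), theta = runif(1, -0.5, 0.5),
                            seed = seed)
    fit <- mr_ivw(d)
    expect_equal(fit$beta, wls_origin_oracle(d), tolerance = 1e-10)
  }
})

test_that("IVW degenerates to the Wald ratio for one instrument and to the
           consensus when all ratios agree", {
  d1 <- instruments(bx = 0.1, by = 0.05, sy = 0.02)
  expect_message(fit <- mr_ivw(d1), "Wald ratio")
  expect_equal(fit$beta, 0.5)
  expect_equal(fit$se, 0.2)

  d <- instruments(bx = c(0.1, 0.2, 0.3), by = c(0.03, 0.06, 0.09),
                   sy = c(0.01, 0.03, 0.02))
  fit <- mr_ivw(d)
  expect_equal(fit$beta, 0.3, tolerance = 1e-12)
  q <- cochran_q(d)
  expect_equal(q$Q, 0, tolerance = 1e-20)
  expect_equal(q$pvalue, 1)
  # random-effects inflation never deflates below the fixed-effect SE
  expect_equal(fit$se, mr_ivw(d, model = "fixed")$se)
})

test_that("Egger slope and intercept match the weighted-regression oracle", {
  for (seed in 1:100) {
    d <- random_instruments(j = sample(5:25, 1), theta = runif(1, -0.5, 0.5),
                            seed = seed + 1000)
    fit <- mr_egger(d)
    oracle <- egger_oracle(d)
    expect_equal(fit$intercept, oracle[1], tolerance = 1e-10)
    expect_equal(fit$slope$beta, oracle[2], tolerance = 1e-10)
  }
})

test_that("Egger recovers an exact line and obeys the affine property", {
  d <- instruments(bx = c(0.05, 0.1, 0.2, 0.4), by = 0.3 * c(0.05, 0.1, 0.2, 0.4),
                   sy = c(0.01, 0.02, 0.03, 0.04))
  # suppress lm's perfect-fit chatter: the exact line is the point of the case
  fit <- suppressWarnings(mr_egger(d))
  expect_equal(fit$slope$beta, 0.3, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)

  d2 <- dplyr::mutate(d, beta_outcome = beta_outcome + 0.07)
  fit2 <- suppressWarnings(mr_egger(d2))
  expect_equal(fit2$slope$beta, fit$slope$beta, tolerance = 1e-10)
  expect_equal(fit2$intercept, fit$intercept + 0.07, tolerance = 1e-10)

  expect_error(mr_egger(d[1:2, ]), "at least 3")
})

test_that("weighted median interpolates the cumulative weight at one half", {
  # equal weights, ratios {1, 2, 9}: the interpolated weighted median is 2
  d <- instruments(bx = c(1, 1, 1), by = c(1, 2, 9), sy = c(1, 1, 1))
  fit <- mr_weighted_median(d, n_boot = 0)
  expect_equal(fit$beta, 2)

  # all ratios equal c
  d2 <- instruments(bx = c(0.1, 0.2, 0.3), by = 0.7 * c(0.1, 0.2, 0.3))
  expect_equal(mr_weighted_median(d2, n_boot = 0)$beta, 0.7, tolerance = 1e-12)

  # bootstrap SE is deterministic given the seed
  d3 <- random_instruments(8, 0.2, seed = 77)
  a <- mr_weighted_median(d3, n_boot = 300, seed = 5)
  b <- mr_weighted_median(d3, n_boot = 300, seed = 5)
  expect_identical(a$se, b$se)
  expect_error(mr_weighted_median(d3, n_boot = 100), "seed")
})

test_that("mode estimators are robust to a minority outlier and match a grid oracle", {
  # majority mode ignores the outlier
  d <- instruments(bx = rep(1, 4), by = c(1, 1, 1, 50), sy = rep(1, 4))
  expect_equal(mr_mode(d, n_boot = 0)$beta, 1)

  # all ratios equal c
  d2 <- instruments(bx = c(0.1, 0.2, 0.3), by = -0.4 * c(0.1, 0.2, 0.3))
  expect_equal(mr_mode(d2, n_boot = 0)$beta, -0.4, tolerance = 1e-12)

  # 6-ratio fixture: argmax matches a dense brute-force density scan
  d3 <- instruments(bx = rep(1, 6), by = c(0.9, 1.0, 1.1, 1.6, 2.4, 3.0),
                    sy = rep(0.5, 6))
  ratios <- d3$beta_outcome / d3$beta_exposure
  h <- 0.9 * min(sd(ratios), mad(ratios)) * 6^(-1 / 5)
  grid <- seq(min(ratios) - 3 * h, max(ratios) + 3 * h, length.out = 20001)
  dens <- vapply(grid, function(g) sum(dnorm(g, ratios, h)), numeric(1))
  oracle <- grid[which.max(dens)]
  est <- mr_mode(d3, weighted = FALSE, bandwidth_factor = 1, n_boot = 0)$beta
  expect_equal(est, oracle, tolerance = diff(range(grid)) / 20000 * 2)

  # weighted mode follows the weight mass
  d4 <- instruments(bx = c(1, 1, 1, 1), by = c(1, 1.05, 2, 2.02),
                    sy = c(0.05, 0.05, 1, 1))
  expect_lt(abs(mr_mode(d4, weighted = TRUE, n_boot = 0)$beta - 1), 0.2)
  expect_error(mr_mode(d4[1:2, ], n_boot = 0), "at least 3")
})

test_that("Cochran's Q matches the two-point closed form and calibrates on null data", {
  # two instruments, equal weights, ratios differing by d: Q = d^2 w / 2
  d <- instruments(bx = c(1, 1), by = c(0.2, 0.5), sy = c(0.1, 0.1))
  q <- cochran_q(d)
  w <- (1 / 0.1)^2
  expect_equal(q$Q, 0.3^2 * w / 2, tolerance = 1e-12)
  expect_equal(q$df, 1)

  # simulated null: Q/df approximately 1 on average
  set.seed(99)
  ratios <- replicate(500, {
    j <- 10
    gamma <- runif(j, 0.1, 0.3)
    sy <- runif(j, 0.02, 0.05)
    dd <- instruments(bx = gamma, by = rnorm(j, 0.1 * gamma, sy),
                      sx = rep(1e-6, j), sy = sy)
    qq <- cochran_q(dd)
    qq$Q / qq$df
  })
  expect_lt(abs(mean(ratios) - 1), 3 * sd(ratios) / sqrt(500))
})

test_that("leave-one-out isolates a planted outlier", {
  d <- random_instruments(10, 0.2, seed = 123)
  d$beta_outcome[4] <- d$beta_outcome[4] + 0.5
  loo <- mr_leave_one_out(d)
  expect_equal(nrow(loo), 10)
  full <- mr_ivw(d)$beta
  moves <- abs(loo$beta - full)
  expect_equal(loo$omitted[which.max(moves)], d$variant_id[4])

  # identical instruments: every entry equals the full estimate
  d2 <- instruments(bx = rep(0.2, 5), by = rep(0.06, 5), sy = rep(0.02, 5))
  loo2 <- mr_leave_one_out(d2)
  expect_true(all(abs(loo2$beta - 0.3) < 1e-12))
})

test_that("all five estimators are invariant to joint allele flips", {
  d <- random_instruments(12, 0.25, seed = 31)
  flip <- c(2, 5, 7, 11)
  d2 <- d
  d2$beta_exposure[flip] <- -d2$beta_exposure[flip]
  d2$beta_outcome[flip] <- -d2$beta_outcome[flip]
  expect_equal(mr_ivw(d2)$beta, mr_ivw(d)$beta, tolerance = 1e-12)
  expect_equal(mr_egger(d2)$slope$beta, mr_egger(d)$slope$beta, tolerance = 1e-12)
  expect_equal(mr_weighted_median(d2, n_boot = 0)$beta,
               mr_weighted_median(d, n_boot = 0)$beta, tolerance = 1e-12)
  expect_equal(mr_mode(d2, n_boot = 0)$beta, mr_mode(d, n_boot = 0)$beta,
               tolerance = 1e-10)
  expect_equal(mr_mode(d2, weighted = TRUE, n_boot = 0)$beta,
               mr_mode(d, weighted = TRUE, n_boot = 0)$beta, tolerance = 1e-10)
})

test_that("odds-ratio transform matches hand arithmetic and printed CIs", {
  o <- or_from_beta(0)
  expect_equal(o$or, 1)
  o <- or_from_beta(0.5, 0.1)
  expect_equal(o$or, exp(0.5))
  expect_equal(o$ci_low, exp(0.5 - 1.96 * 0.1))
  o <- or_from_beta(-0.0171, ci = c(-0.0277, -0.0065))
  expect_equal(round(c(o$or, o$ci_low, o$ci_high), 3), c(0.983, 0.973, 0.994))
  expect_error(or_from_beta(0.1, -0.1), "non-negative")
})

test_that("the estimator panel is a tidy five-row table with OR columns", {
  d <- random_instruments(10, 0.15, seed = 55)
  p <- mr_panel(d, n_boot = 100, seed = 2)
  expect_equal(nrow(p), 5)
  expect_setequal(p$method, c("IVW", "Egger-slope", "weighted-median",
                              "simple-mode", "weighted-mode"))
  expect_equal(p$or, exp(p$beta), tolerance = 1e-12)
  expect_true(all(p$ci_low <= p$beta & p$beta <= p$ci_high))
  expect_true(all(p$n_variants == 10))
})
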