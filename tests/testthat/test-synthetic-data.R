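test_that("the generator is byte-identical under a fixed seed", {
  a <- simulate_two_sample(sim_config(seed = 5))
  b <- simulate_two_sample(sim_config(seed = 5))
  expect_identical(a$exposure, b$exposure)
  expect_identical(a$mediator, b$mediator)
  expect_identical(a$outcome, b$outcome)
  c <- simulate_two_sample(sim_config(seed = 6))
  expect_false(identical(a$exposure$beta, c$exposure$beta))
})

test_that("config validation rejects bad inputs before any draw", {
  expect_error(sim_config(), "seed")
  expect_error(sim_config(case_fraction = 1.2, seed = 1))
  expect_error(sim_config(n_exposure = 1, seed = 1))
  expect_error(sim_config(pleiotropy = list(type = "huge"), seed = 1), "pleiotropy")
  expect_error(simulate_two_sample(list(seed = 1)), "sim_config")
})

test_that("generated p-values are the two-sided normal tails of their z-scores", {
  st <- simulate_two_sample(sim_config(n_variants = 100, seed = 8))
  for (tab in list(st$exposure, st$mediator, st$outcome)) {
    expect_equal(tab$pvalue, pmax(2 * pnorm(-abs(tab$beta / tab$se)),
                                  .Machine$double.xmin), tolerance = 1e-12)
  }
  # tables (exposure + mediator-specific variants) pass validation untouched
  v <- validate_associations(st$outcome)
  expect_equal(nrow(v), 200)
})

test_that("empirical sampling SD of betas matches the analytic SE within 5%", {
  # standardized by each run's analytic SE, the deviations are unit normal
  z <- sapply(1:1000, function(r) {
    st <- simulate_two_sample(sim_config(n_variants = 5, seed = 10000 + r))
    (st$outcome$beta - st$truth$mu_outcome) / st$truth$se_outcome
  })
  expect_lt(abs(sd(as.vector(z)) - 1), 0.05)
})

test_that("the truth object is sufficient to recompute expectations", {
  cfg <- sim_config(n_variants = 30, theta_em = -0.04, theta_mo = 0.05,
                    theta_direct = -0.01, seed = 44)
  st <- simulate_two_sample(cfg)
  tr <- st$truth
  expect_equal(tr$mu_mediator, cfg$theta_em * tr$gamma + tr$delta)
  expect_equal(tr$mu_outcome,
               (cfg$theta_direct + cfg$theta_mo * cfg$theta_em) * tr$gamma +
                 cfg$theta_mo * tr$delta + tr$alpha)
  expect_true(all(tr$gamma[tr$class == "mediator"] == 0))
  expect_true(all(tr$delta[tr$class == "exposure"] == 0))
  expect_equal(tr$theta_total, cfg$theta_direct + cfg$theta_mo * cfg$theta_em)
  expect_equal(tr$se_exposure,
               1 / sqrt(2 * tr$maf * (1 - tr$maf) * cfg$n_exposure))
})

test_that("LD blocks correlate the sampling noise and fill the LD matrix", {
  cfg <- sim_config(n_variants = 100, ld_blocks = list(size = 4, r = 0.8),
                    seed = 13)
  st <- simulate_two_sample(cfg)
  expect_equal(dim(st$ld), c(200, 200))
  expect_equal(st$ld[1, 2], 0.8)
  expect_equal(st$ld[4, 5], 0)
  # empirical within-block noise correlation across many replicates
  pairs <- sapply(1:300, function(r) {
    s <- simulate_two_sample(sim_config(n_variants = 4,
                                        ld_blocks = list(size = 4, r = 0.8),
                                        seed = 5000 + r))
    z <- (s$exposure$beta - s$truth$mu_exposure) / s$truth$se_exposure
    c(z[1] * z[2], z[1] * z[1])
  })
  expect_lt(abs(mean(pairs[1, ]) - 0.8), 0.15)
})

test_that("pleiotropy options shift the outcome means as configured", {
  bal <- simulate_two_sample(sim_config(
    n_variants = 400, pleiotropy = list(type = "balanced", sd = 0.01),
    seed = 3))
  expect_lt(abs(mean(bal$truth$alpha)), 0.002)
  expect_lt(abs(sd(bal$truth$alpha) - 0.01), 0.002)
  dir <- simulate_two_sample(sim_config(
    n_variants = 400, pleiotropy = list(type = "directional", mean = 0.02,
                                        sd = 0.005), seed = 3))
  expect_lt(abs(mean(dir$truth$alpha) - 0.02), 0.002)
})

test_that("the coloc locus simulator places signals as requested", {
  sh <- simulate_coloc_locus(60, shared = TRUE, signal_z = 8, seed = 2)
  expect_equal(sh$truth$index1, sh$truth$index2)
  z1 <- sh$trait1$beta / sh$trait1$se
  expect_equal(which.max(abs(z1)), sh$truth$index1)

  di <- simulate_coloc_locus(60, shared = FALSE, signal_z = 8, seed = 2)
  expect_false(di$truth$index1 == di$truth$index2)
  expect_error(simulate_coloc_locus(5), "n_variants >= 10")
})

test_that("the engineered fixture reproduces the designed instrument counts", {
  fx <- make_study_fixture(seed = 11)
  sig <- filter_by_pvalue(fx$mediator, 5e-8)
  expect_equal(nrow(sig), 13)

  sel <- select_instruments(fx$mediator, 5e-8, ld = fx$ld, r2_threshold = 0.001,
                            f_min = 10, annotations = fx$annotations,
                            blocked_traits = c("Low-density lipoprotein",
                                               "Coronary artery disease"))
  expect_equal(nrow(sel), 7)
  expect_setequal(sel$variant_id, fx$truth$mediator_instrument_ids)

  cis <- select_instruments(fx$exposure, 1e-4, ld = fx$ld, r2_threshold = 0.8,
                            f_min = 10)
  expect_equal(nrow(cis), 6)
  expect_setequal(cis$variant_id, fx$truth$cis_instrument_ids)
  expect_true(all(cis$f_statistic >= 10))
  expect_true(all(sel$f_statistic >= 10))
})

test_that("study tables round-trip through the TSV writer and reader", {
  st <- simulate_two_sample(sim_config(n_variants = 12, seed = 21))
  dir <- withr::local_tempdir()
  write_synthetic_study(st, dir)
  back <- read_summary_stats(file.path(dir, "exposure.tsv"))
  expect_equal(back$beta, st$exposure$beta)
  expect_equal(back$variant_id, st$exposure$variant_id)
  expect_true(file.exists(file.path(dir, "truth.json")))
  expect_true(file.exists(file.path(dir, "config.yaml")))
})
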