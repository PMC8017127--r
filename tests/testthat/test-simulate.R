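test_that("generation is deterministic in the seed", {
  cfg <- pisa_like_scenario(n_groups = 2L, persons_per_group = 80L,
                            seed = 1234)
  s1 <- simulate_scenario(cfg)
  s2 <- simulate_scenario(cfg)
  expect_identical(s1$data$responses, s2$data$responses)
  expect_identical(s1$data$times, s2$data$times)
  cfg2 <- pisa_like_scenario(n_groups = 2L, persons_per_group = 80L,
                             seed = 4321)
  s3 <- simulate_scenario(cfg2)
  expect_false(identical(s1$data$responses, s3$data$responses))
})

test_that("independent latents produce uncorrelated scores and times", {
  acc <- lapply(1:5, function(i) acc_params(1.2, 0))
  tim <- lapply(1:5, function(i) time_params(0.4, 0, 0.3, 0))
  cfg <- scenario_config(1, 5000, acc, tim, model = "M2",
                         invariance = "full",
                         latent = latent_spec(rho = 0),
                         miss_rates = rep(0, 5), seed = 2)
  sim <- simulate_scenario(cfg)
  total_score <- rowSums(sim$data$responses)
  total_logtime <- rowSums(log(sim$data$times))
  expect_lt(abs(cor(total_score, total_logtime)), 0.05)
})

test_that("weak invariance varies only intensities and residual variances", {
  cfg <- pisa_like_scenario(n_groups = 3L, persons_per_group = 30L,
                            invariance = "weak", seed = 7)
  sim <- simulate_scenario(cfg)
  lam <- vapply(sim$truth, function(s)
    vapply(s$time, `[[`, 0, "lambda"), numeric(10))
  xi <- vapply(sim$truth, function(s)
    vapply(s$time, `[[`, 0, "xi"), numeric(10))
  s2 <- vapply(sim$truth, function(s)
    vapply(s$time, `[[`, 0, "sigma2"), numeric(10))
  a <- vapply(sim$truth, function(s)
    vapply(s$acc, `[[`, 0, "a"), numeric(10))
  expect_identical(lam[, 1], lam[, 2])
  expect_identical(a[, 1], a[, 3])
  expect_false(any(xi[, 1] == xi[, 2]))
  expect_false(any(s2[, 1] == s2[, 2]))
})

test_that("the packaged scenario matches the released item descriptives", {
  cfg <- pisa_like_scenario(n_groups = 4L, persons_per_group = 400L,
                            seed = 99)
  sim <- simulate_scenario(cfg)
  mean_times <- colMeans(sim$data$times, na.rm = TRUE)
  expect_true(all(mean_times > 0.5 & mean_times < 3))
  miss <- mean(is.na(sim$data$responses))
  expect_gt(miss, 0.025)
  expect_lt(miss, 0.045)
  # missingness increases toward the end of each unit (config rates)
  units <- list(1:3, 4:7, 8:10)
  for (u in units) {
    expect_gt(cfg$miss_rates[max(u)], cfg$miss_rates[min(u)])
    obs_rate <- colMeans(is.na(sim$data$responses))[u]
    expect_gt(obs_rate[length(u)], obs_rate[1])
  }
})

test_that("empirical category frequencies approach the analytic margins", {
  cfg <- recovery_config(20000, seed = 15)
  sim <- simulate_scenario(cfg)
  gh <- jointRT:::gh_norm(61)
  for (i in c(1L, 2L, 5L)) {
    it <- sim$truth$G01$acc[[i]]
    pr <- grm_category_probs(gh$x, it)
    if (is.null(dim(pr))) pr <- matrix(pr, length(gh$x))
    marg <- colSums(gh$w * pr)
    emp <- prop.table(table(factor(sim$data$responses[, i],
                                   levels = 0:(length(it$b)))))
    expect_equal(as.numeric(emp), as.numeric(marg), tolerance = 0.015)
  }
})

test_that("time-dependent missingness hits its target rate and is MAR", {
  acc <- lapply(1:4, function(i) acc_params(1, 0))
  tim <- lapply(1:4, function(i) time_params(0.4, 0.4, 0.3, 0))
  cfg <- scenario_config(1, 20000, acc, tim, model = "M2",
                         invariance = "full",
                         latent = latent_spec(rho = 0.4),
                         miss_rates = rep(0.10, 4), seed = 6)
  sim <- simulate_scenario(cfg)
  rates <- colMeans(is.na(sim$data$responses))
  expect_lt(max(abs(rates - 0.10)), 0.01)
  # missingness rises with the (observed) response time
  i <- 1L
  miss <- is.na(sim$data$responses[, i])
  expect_gt(mean(log(sim$data$times[miss, i])),
            mean(log(sim$data$times[!miss, i])))
  # times stay observed for missing responses (mechanism is MAR given data)
  expect_false(anyNA(sim$data$times))
})
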