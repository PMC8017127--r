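test_that("person log-likelihood sums observed item terms only", {
  tj <- toy_joint("M3")
  spec <- tj$spec
  # fully missing person contributes zero
  expect_identical(person_loglik(c(NA, NA, NA), c(NA, NA, NA), 0.7, -0.2,
                                 spec), 0)
  # hand-computed two-item toy: category terms plus lognormal terms
  x <- c(1L, 0L, NA); tt <- c(1.2, NA, 0.8)
  th <- 0.4; ta <- -0.3
  logistic <- function(z) 1 / (1 + exp(-z))
  p1 <- logistic(1.2 * (th + 0.5)) - logistic(1.2 * (th - 0.7))
  p2 <- 1 - logistic(0.9 * (th - 0.3))
  f1 <- stats::dlnorm(1.2, 0.4 - 0.35 * ta + 0.15 * th, sqrt(0.30))
  f3 <- stats::dlnorm(0.8, 0.2 - 0.45 * ta + 0.20 * th, sqrt(0.35))
  expect_equal(person_loglik(x, tt, th, ta, spec),
               log(p1) + log(p2) + log(f1) + log(f3), tolerance = 1e-12)
})

test_that("M1 ignores response times entirely", {
  tj <- toy_joint("M1")
  x <- c(1L, 0L, 2L)
  expect_identical(person_loglik(x, c(1, 2, 3), 0.3, 0, tj$spec),
                   person_loglik(x, c(9, 0.1, 5), 0.3, 7, tj$spec))
  d2 <- tj$data
  spec <- tj$spec
  d_notimes <- rt_dataset(d2$responses, NULL, d2$group, n_cat = d2$n_cat)
  expect_equal(marginal_loglik(d2, spec), marginal_loglik(d_notimes, spec))
})

test_that("marginal likelihood matches the dense-grid oracle", {
  for (model in c("M1", "M2", "M3")) {
    tj <- toy_joint(model)
    ll <- marginal_loglik(tj$data, tj$spec, quad_spec(21))
    llo <- oracle_grid_loglik(tj$data, tj$spec, K = 301L)
    expect_equal(ll, llo, tolerance = 1e-6, ignore_attr = TRUE,
                 label = paste("marginal loglik", model))
  }
})

test_that("quadrature is converged at the default rule", {
  tj <- toy_joint("M3")
  ll31 <- marginal_loglik(tj$data, tj$spec, quad_spec(31))
  ll62 <- marginal_loglik(tj$data, tj$spec, quad_spec(62))
  expect_lt(abs(ll31 - ll62), 1e-8)
  # non-adaptive placement agrees too
  ll_na <- marginal_loglik(tj$data, tj$spec, quad_spec(41, adaptive = FALSE))
  expect_lt(abs(ll31 - ll_na), 1e-6)
})

test_that("M3 with zero cross-loadings coincides with M2", {
  tj <- toy_joint("M2")
  tim0 <- lapply(tj$spec$time, function(z)
    time_params(z$xi, z$lambda, z$sigma2, 0))
  lat0 <- latent_spec(0.2, 1.3, -0.1, 0.8, 0)
  m2 <- model_spec("M2", tj$spec$acc, tim0, lat0)
  m3 <- model_spec("M3", tj$spec$acc, tim0, lat0)
  expect_equal(marginal_loglik(tj$data, m2), marginal_loglik(tj$data, m3),
               tolerance = 1e-10)
})

test_that("likelihood is invariant to person and item permutations", {
  tj <- toy_joint("M3", n = 6L)
  d <- tj$data; spec <- tj$spec
  ll <- marginal_loglik(d, spec)
  perm <- c(4L, 1L, 6L, 3L, 5L, 2L)
  dp <- rt_dataset(d$responses[perm, ], d$times[perm, ], d$group[perm],
                   n_cat = d$n_cat)
  expect_equal(marginal_loglik(dp, spec), ll, tolerance = 1e-10)
  ip <- c(3L, 1L, 2L)
  di <- rt_dataset(d$responses[, ip], d$times[, ip], d$group,
                   n_cat = d$n_cat[ip])
  speci <- model_spec("M3", spec$acc[ip], spec$time[ip], spec$latent)
  expect_equal(marginal_loglik(di, speci), ll, tolerance = 1e-10)
})

test_that("a degenerate latent covariance is rejected", {
  tj <- toy_joint("M2")
  bad <- model_spec("M2", tj$spec$acc, tj$spec$time,
                    latent_spec(0, 1, 0, 1, 1))
  expect_error(marginal_loglik(tj$data, bad), "positive definite")
})
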