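# Shared small fitted objects for the estimation tests (built once).
est_env <- new.env()
est_fixture <- function() {
  if (!is.null(est_env$res)) return(est_env)
  cfg <- pisa_like_scenario(n_groups = 3L, persons_per_group = 150L,
                            invariance = "full", seed = 301L)
  sim <- simulate_scenario(cfg)
  est_env$sim <- sim
  est_env$res <- two_step_analysis(sim$data, models = c("M1", "M2"),
                                   levels = c("Full", "Strong", "Weak",
                                              "Struct"),
                                   quad = quad_spec(15),
                                   control = list(se = FALSE))
  est_env
}

test_that("parameter spaces realize the estimation framework rows", {
  n_cat <- c(3L, 2L, 2L)
  ps1 <- parameter_space("M1", "international", n_cat = n_cat)
  t1 <- ps1$table
  expect_true(all(t1$free[t1$symbol %in% c("a", "b")]))
  expect_equal(t1$value[t1$symbol == "mu_theta"], 0)
  expect_equal(t1$value[t1$symbol == "var_theta"], 1)
  expect_false(any(t1$free[t1$symbol %in% c("mu_theta", "var_theta")]))

  # anchors required and carried
  expect_error(parameter_space("M2", "international", list(), n_cat),
               "M1_international")
  acc <- list(acc_params(1.1, c(-0.4, 0.6)), acc_params(0.8, 0.1),
              acc_params(1.4, -0.2))
  fake_m1 <- structure(list(spec = model_spec("M1", acc, NULL,
                                              latent_spec())),
                       class = "rt_fit")
  ps2 <- parameter_space("M2", "international",
                         list(M1_international = fake_m1), n_cat)
  t2 <- ps2$table
  expect_false(any(t2$free[t2$symbol %in% c("a", "b")]))
  expect_equal(t2$value[t2$symbol == "a"], c(1.1, 0.8, 1.4))
  expect_true(all(t2$free[t2$symbol %in% c("xi", "lambda", "sigma2")]))
  expect_true(t2$free[t2$symbol == "rho"])
  expect_equal(t2$value[t2$symbol == "mu_tau"], 0)
  expect_false(t2$free[t2$symbol == "var_tau"])

  # M3 international fixes rho at zero and frees the cross-loadings
  ps3 <- parameter_space("M3", "international",
                         list(M1_international = fake_m1), n_cat)
  expect_false(ps3$table$free[ps3$table$symbol == "rho"])
  expect_true(all(ps3$table$free[ps3$table$symbol == "phi"]))
})

test_that("the country ladder frees the documented parameter sets", {
  n_cat <- c(2L, 2L)
  acc <- list(acc_params(1, 0), acc_params(1.2, 0.3))
  tim <- list(time_params(0.4, 0.3, 0.3, 0.1), time_params(0.6, 0.4, 0.2, 0.2))
  m1 <- structure(list(spec = model_spec("M1", acc, NULL, latent_spec())),
                  class = "rt_fit")
  m3 <- structure(list(spec = model_spec("M3", acc, tim, latent_spec())),
                  class = "rt_fit")
  m1f <- structure(list(spec = model_spec("M1", acc, NULL,
                                          latent_spec(0.3, 1.4))),
                   class = "rt_fit")
  anchors <- list(M1_international = m1, M3_international = m3,
                  M1_Full = m1f)
  free_syms <- function(ps) sort(unique(ps$table$symbol[ps$table$free]))

  psf <- parameter_space("M2", "Full",
                         list(M1_international = m1,
                              M2_international = structure(
                                list(spec = model_spec("M2", acc,
                                  lapply(tim, function(z)
                                    time_params(z$xi, z$lambda, z$sigma2)),
                                  latent_spec(rho = 0.3))),
                                class = "rt_fit")), n_cat)
  expect_equal(free_syms(psf),
               c("mu_tau", "mu_theta", "rho", "var_tau", "var_theta"))

  pss <- parameter_space("M3", "Struct", anchors, n_cat)
  expect_equal(free_syms(pss),
               c("lambda", "mu_theta", "phi", "sigma2", "xi"))
  tt <- pss$table
  # proficiency variance pinned to the group's M1_Full estimate
  expect_equal(tt$value[tt$symbol == "var_theta"], 1.4)
  expect_false(tt$free[tt$symbol == "var_theta"])
  expect_equal(tt$value[tt$symbol == "mu_tau"], 0)
  expect_equal(tt$value[tt$symbol == "var_tau"], 1)
  expect_equal(tt$value[tt$symbol == "rho"], 0)
  expect_error(parameter_space("M3", "Struct",
                               anchors[c("M1_international",
                                         "M3_international")], n_cat),
               "M1_Full")
})

test_that("a fully fixed space returns the likelihood without optimizing", {
  tj <- toy_joint("M2")
  n_cat <- tj$data$n_cat
  ps <- parameter_space("M1", "international", n_cat = n_cat)
  ps$table$free <- FALSE
  ps$table$value[ps$table$symbol == "a"] <-
    vapply(tj$spec$acc, `[[`, 0, "a")
  for (i in seq_along(tj$spec$acc))
    ps$table$value[ps$table$symbol == "b" & ps$table$item == i] <-
      tj$spec$acc[[i]]$b
  ps$table$value[ps$table$symbol == "mu_theta"] <- 0.2
  ps$table$value[ps$table$symbol == "var_theta"] <- 1.3
  f <- fit_model(tj$data, ps)
  expect_identical(f$n_free, 0L)
  m1 <- model_spec("M1", tj$spec$acc, NULL, latent_spec(0.2, 1.3))
  expect_equal(f$loglik, marginal_loglik(tj$data, m1), tolerance = 1e-10)
})

test_that("analytic gradients agree with numerical differentiation", {
  cfg <- recovery_config(120, "M3", seed = 9)
  sim <- simulate_scenario(cfg)
  d <- sim$data
  parts <- jointRT:::spec_parts(sim$truth$G01)
  q <- quad_spec(21)
  gr <- jointRT:::core_gradient(d, parts, q)
  # The analytic score is the posterior expectation of the complete-data
  # score (exact for the true integral); the finite-difference gradient
  # additionally tracks the movement of the adaptive quadrature nodes, so
  # the two agree only to quadrature accuracy.
  num <- function(get, set, eps = 1e-6) {
    p1 <- set(parts, get(parts) + eps)
    p2 <- set(parts, get(parts) - eps)
    (sum(jointRT:::core_eval(d, p1, q)$ll) -
       sum(jointRT:::core_eval(d, p2, q)$ll)) / (2 * eps)
  }
  expect_equal(gr$xi[3],
               num(function(p) p$xi[3],
                   function(p, v) { p$xi[3] <- v; p }), tolerance = 1e-3)
  expect_equal(gr$lambda[5],
               num(function(p) p$lam[5],
                   function(p, v) { p$lam[5] <- v; p }), tolerance = 1e-3)
  expect_equal(gr$phi[2],
               num(function(p) p$phi[2],
                   function(p, v) { p$phi[2] <- v; p }), tolerance = 1e-3)
  expect_equal(gr$sigma2[1],
               num(function(p) p$s2[1],
                   function(p, v) { p$s2[1] <- v; p }), tolerance = 1e-3)
  expect_equal(gr$a[4],
               num(function(p) p$a[4],
                   function(p, v) { p$a[4] <- v; p }), tolerance = 1e-3)
  expect_equal(gr$b[[2]][1],
               num(function(p) p$b[[2]][1],
                   function(p, v) { p$b[[2]][1] <- v; p }), tolerance = 1e-3)
  expect_equal(gr$mean_theta,
               num(function(p) p$mu[1],
                   function(p, v) { p$mu[1] <- v; p }), tolerance = 1e-3)
})

test_that("two-step analysis enforces its preconditions and structure", {
  cfg <- recovery_config(60, seed = 5)
  sim <- simulate_scenario(cfg)
  expect_error(two_step_analysis(sim$data), "at least 2 groups")

  env <- est_fixture()
  res <- env$res
  expect_named(res$international, c("M1", "M2"))
  expect_length(res$country, 3L)
  expect_named(res$country[[1]],
               c("M1_Full", "M2_Full", "M2_Strong", "M2_Weak", "M2_Struct"))
  expect_length(res$errors, 0L)
})

test_that("accuracy parameters are carried over exactly, never re-estimated", {
  env <- est_fixture()
  res <- env$res
  a_m1 <- vapply(res$international$M1$spec$acc, `[[`, 0, "a")
  expect_identical(vapply(res$international$M2$spec$acc, `[[`, 0, "a"),
                   a_m1)
  for (g in names(res$country)) {
    for (cell in c("M2_Full", "M2_Weak", "M2_Struct")) {
      f <- res$country[[g]][[cell]]
      expect_identical(vapply(f$spec$acc, `[[`, 0, "a"), a_m1)
      expect_identical(lapply(f$spec$acc, `[[`, "b"),
                       lapply(res$international$M1$spec$acc, `[[`, "b"))
    }
  }
})

test_that("ladder log-likelihoods are nested in the freeing order", {
  env <- est_fixture()
  res <- env$res
  for (g in names(res$country)) {
    ll <- vapply(c("M2_Full", "M2_Strong", "M2_Weak", "M2_Struct"),
                 function(cell) res$country[[g]][[cell]]$loglik, 0)
    expect_true(all(diff(ll) > -0.05),
                label = paste("nesting chain, group", g))
  }
})

test_that("freed ladder parameters recover international values under full invariance", {
  env <- est_fixture()
  res <- env$res
  s2_intl <- vapply(res$international$M2$spec$time, `[[`, 0, "sigma2")
  for (g in names(res$country)) {
    s2_g <- vapply(res$country[[g]]$M2_Strong$spec$time, `[[`, 0, "sigma2")
    expect_equal(s2_g, s2_intl, tolerance = 0.35,
                 label = paste("Strong sigma2, group", g))
  }
})

test_that("group-level M3 cells with fixed cross-loadings estimate a free correlation", {
  cfg <- pisa_like_scenario(n_groups = 2L, persons_per_group = 120L,
                            model = "M3", invariance = "full", seed = 77L)
  sim <- simulate_scenario(cfg)
  res <- two_step_analysis(sim$data, models = c("M1", "M3"),
                           levels = c("Full", "Weak"),
                           quad = quad_spec(15),
                           control = list(se = FALSE))
  expect_length(res$errors, 0L)
  # international identification: rho fixed at 0 with free cross-loadings
  expect_identical(res$international$M3$spec$latent$rho, 0)
  for (g in names(res$country)) {
    f <- res$country[[g]]$M3_Full
    tab <- f$par_table
    expect_true(tab$free[tab$symbol == "rho"])
    expect_false(any(tab$free[tab$symbol == "phi"]))
    expect_true(is.finite(f$spec$latent$rho))
  }
})

test_that("fitting is deterministic", {
  cfg <- recovery_config(100, seed = 21)
  sim <- simulate_scenario(cfg)
  d <- sim$data
  ps <- parameter_space("M1", "international", n_cat = d$n_cat)
  f1 <- fit_model(d, ps, control = list(se = FALSE))
  f2 <- fit_model(d, ps, control = list(se = FALSE))
  expect_identical(f1$loglik, f2$loglik)
  expect_identical(f1$par_table$value, f2$par_table$value)
})

test_that("standard errors shrink with sample size", {
  sims <- lapply(c(150L, 900L), function(n)
    simulate_scenario(recovery_config(n, seed = 33)))
  ses <- lapply(sims, function(s) {
    f <- fit_model(s$data, parameter_space("M1", "international",
                                           n_cat = s$data$n_cat))
    f$par_table$se[f$par_table$free]
  })
  expect_true(all(ses[[2]] < ses[[1]]))
})
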