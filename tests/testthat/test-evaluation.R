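fake_fit <- function(loglik, n_free, n_persons, converged = TRUE) {
  structure(list(loglik = loglik, n_free = n_free, n_persons = n_persons,
                 converged = converged), class = "rt_fit")
}

test_that("BIC follows its definition and refuses unconverged fits", {
  # independent arithmetic: 2*100 + 5*ln(50)
  expect_equal(bic(fake_fit(-100, 5L, 50L)), 200 + 5 * log(50),
               tolerance = 1e-12)
  expect_equal(round(bic(fake_fit(-100, 5L, 50L)), 2), 219.56)
  expect_equal(bic(fake_fit(-321.5, 0L, 50L)), 643)
  # an extra parameter without likelihood gain strictly increases BIC
  expect_gt(bic(fake_fit(-100, 6L, 50L)), bic(fake_fit(-100, 5L, 50L)))
  expect_error(bic(fake_fit(-100, 5L, 50L, converged = FALSE)),
               "converge")
  expect_equal(bic(fake_fit(-100, 5L, 50L, converged = FALSE),
                   allow_unconverged = TRUE), 200 + 5 * log(50))
})

test_that("invariance selection takes the per-row and total BIC minima", {
  tab <- data.frame(group = c("G1", "G2"),
                    Full = c(100, 200), Strong = c(90, 210),
                    Weak = c(95, 190), Struct = c(99, 260))
  tab$bic_min <- pmin(tab$Full, tab$Strong, tab$Weak, tab$Struct)
  tab$bic_max <- pmax(tab$Full, tab$Strong, tab$Weak, tab$Struct)
  tab$preferred <- c("Strong", "Weak")
  lt <- structure(tab, family = "M2",
                  levels = c("Full", "Strong", "Weak", "Struct"),
                  class = c("ladder_table", "data.frame"))
  sel <- select_invariance(lt)
  expect_equal(unname(sel$per_group), c("Strong", "Weak"))
  expect_equal(unname(sel$total_bic),
               c(300, 300, 285, 359))
  expect_equal(sel$overall, "Weak")
  # tie between Full and Strong totals resolves toward the more constrained
  tab2 <- tab
  tab2$Weak <- c(400, 400)
  lt2 <- structure(tab2, family = "M2",
                   levels = c("Full", "Strong", "Weak", "Struct"),
                   class = c("ladder_table", "data.frame"))
  expect_equal(select_invariance(lt2)$overall, "Full")
})

test_that("ladder tables carry per-group BICs, ranges and preferences", {
  cfg <- pisa_like_scenario(n_groups = 2L, persons_per_group = 120L,
                            seed = 88, invariance = "full")
  sim <- simulate_scenario(cfg)
  res <- two_step_analysis(sim$data, models = c("M1", "M2"),
                           levels = c("Full", "Weak"),
                           quad = quad_spec(15),
                           control = list(se = FALSE))
  lt <- ladder_table(res, "M2")
  expect_equal(lt$group, c("G01", "G02"))
  expect_equal(lt$bic_min, pmin(lt$Full, lt$Weak))
  expect_equal(lt$bic_max, pmax(lt$Full, lt$Weak))
  expect_true(all(lt$preferred %in% c("Full", "Weak")))
  for (r in 1:2)
    expect_equal(lt[[lt$preferred[r]]][r], lt$bic_min[r])
})

test_that("fit statistics are near zero under the generating GRM", {
  cfg <- recovery_config(2000, seed = 404)
  sim <- simulate_scenario(cfg)
  d <- rt_dataset(sim$data$responses, NULL, sim$data$group,
                  n_cat = sim$data$n_cat)
  f1 <- fit_model(d, parameter_space("M1", "international",
                                     n_cat = d$n_cat),
                  control = list(se = FALSE))
  fs <- grm_fit_statistics(d, f1$spec)
  expect_lt(fs$srmr, 0.08)
  expect_lt(fs$rmsea, 0.06)

  # a planted second factor inflates both statistics
  set.seed(405)
  n <- 2000L
  th1 <- rnorm(n); th2 <- 0.3 * th1 + sqrt(1 - 0.09) * rnorm(n)
  X <- matrix(NA_integer_, n, 10L)
  for (i in 1:10) {
    it <- sim$truth$G01$acc[[i]]
    th <- if (i <= 5) th1 else th2
    pr <- grm_category_probs(th, it)
    if (is.null(dim(pr))) pr <- matrix(pr, n)
    cum <- t(apply(pr, 1, cumsum))
    X[, i] <- rowSums(runif(n) > cum[, -ncol(cum), drop = FALSE])
  }
  d2 <- rt_dataset(X, NULL, NULL, n_cat = d$n_cat)
  f2 <- fit_model(d2, parameter_space("M1", "international",
                                      n_cat = d$n_cat),
                  control = list(se = FALSE))
  fs2 <- grm_fit_statistics(d2, f2$spec)
  expect_gt(fs2$srmr, fs$srmr)
  expect_gt(fs2$rmsea, fs$rmsea)
})
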