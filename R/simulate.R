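# Synthetic multi-group response/response-time data with the structure the
# analysis assumes: bivariate normal latents per group, graded-response
# accuracy, lognormal times, and MAR missingness that depends on item
# position and (optionally) on the observed log-time.

#' Scenario configuration for the synthetic-data generator
#'
#' @param n_groups Number of groups.
#' @param persons_per_group Scalar or per-group vector of sample sizes.
#' @param acc List of [acc_params()] (international item accuracy).
#' @param time List of [time_params()] (international item time model).
#' @param model Generating model, `"M2"` or `"M3"`.
#' @param invariance `"full"` (identical time parameters in every group),
#'   `"weak"` (group-specific time intensities and residual variances
#'   only), or `"struct"` (additionally group-specific loadings and, for
#'   M3, cross-loadings).
#' @param latent A single [latent_spec()] recycled across groups, or a
#'   list with one per group.
#' @param miss_rates Per-item missing-response probabilities in `[0, 1)`.
#' @param miss_time_dep Make response missingness depend on the item's
#'   simulated log-time (slope 0.8 per log-time SD, intercept calibrated
#'   so the marginal rate matches `miss_rates`); the time itself stays
#'   observed, so the mechanism is missing-at-random given observed data.
#' @param xi_shift_sd,logsigma2_shift_sd,loglambda_shift_sd Half-widths of
#'   the uniform group shifts used by the `weak`/`struct` scenarios.
#' @param seed Master seed; per-group substreams are derived from it
#'   deterministically.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(n_groups, persons_per_group, acc, time,
                            model = c("M2", "M3"),
                            invariance = c("full", "weak", "struct"),
                            latent = latent_spec(rho = 0.4),
                            miss_rates = rep(0.03, length(acc)),
                            miss_time_dep = TRUE,
                            xi_shift_sd = 0.25, logsigma2_shift_sd = 0.4,
                            loglambda_shift_sd = 0.3,
                            seed = 1L) {
  model <- match.arg(model)
  invariance <- match.arg(invariance)
  if (length(persons_per_group) == 1L)
    persons_per_group <- rep(persons_per_group, n_groups)
  stopifnot(length(persons_per_group) == n_groups,
            length(time) == length(acc),
            length(miss_rates) == length(acc),
            all(miss_rates >= 0), all(miss_rates < 1))
  if (inherits(latent, "latent_spec")) latent <- rep(list(latent), n_groups)
  stopifnot(length(latent) == n_groups)
  if (model == "M3" && any(vapply(latent, `[[`, 0, "rho") != 0))
    stop("an M3 generating model requires rho = 0 in every group")
  structure(list(n_groups = n_groups,
                 persons_per_group = as.integer(persons_per_group),
                 acc = acc, time = time, model = model,
                 invariance = invariance, latent = latent,
                 miss_rates = miss_rates, miss_time_dep = miss_time_dep,
                 xi_shift_sd = xi_shift_sd,
                 logsigma2_shift_sd = logsigma2_shift_sd,
                 loglambda_shift_sd = loglambda_shift_sd,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

# deterministic substream seed per group (kept below 2^31)
substream_seed <- function(master, g) {
  as.integer((as.numeric(master) + 999983 * g) %% 2147483647)
}

# intercept of the missingness logit so that the marginal rate over a
# standard-normal log-time score equals `rate`, for slope `beta`
miss_intercept <- function(rate, beta) {
  if (rate <= 0) return(-Inf)
  gh <- gh_norm(41L)
  f <- function(al) sum(gh$w * stats::plogis(al + beta * gh$x)) - rate
  stats::uniroot(f, c(-30, 10), tol = 1e-10)$root
}

#' Generate a synthetic multi-group dataset
#'
#' Draws per-person latents from each group's bivariate normal, responses
#' from the graded response model, times from the lognormal model (with
#' cross-loadings under M3), applies the group shifts of the requested
#' invariance scenario and the MAR missingness mechanism, and returns the
#' dataset together with the generating parameters for recovery tests.
#'
#' @param config A [scenario_config()].
#' @return A list with `data` (an [rt_dataset()]) and `truth` (per-group
#'   generating [model_spec()]s plus the config).
#' @export
simulate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  I <- length(config$acc)
  xi0  <- vapply(config$time, `[[`, 0, "xi")
  lam0 <- vapply(config$time, `[[`, 0, "lambda")
  s20  <- vapply(config$time, `[[`, 0, "sigma2")
  phi0 <- vapply(config$time, `[[`, 0, "phi")

  resp <- list(); times <- list(); grp <- list(); truth <- list()
  for (g in seq_len(config$n_groups)) {
    set.seed(substream_seed(config$seed, g))
    n <- config$persons_per_group[g]
    lat <- config$latent[[g]]

    xi_g <- xi0; lam_g <- lam0; s2_g <- s20; phi_g <- phi0
    if (config$invariance %in% c("weak", "struct")) {
      xi_g <- xi0 + stats::runif(I, -config$xi_shift_sd, config$xi_shift_sd)
      s2_g <- s20 * exp(stats::runif(I, -config$logsigma2_shift_sd,
                                     config$logsigma2_shift_sd))
    }
    if (config$invariance == "struct") {
      lam_g <- lam0 * exp(stats::runif(I, -config$loglambda_shift_sd,
                                       config$loglambda_shift_sd))
      if (config$model == "M3")
        phi_g <- phi0 * exp(stats::runif(I, -config$loglambda_shift_sd,
                                         config$loglambda_shift_sd))
    }
    time_g <- lapply(seq_len(I), function(i)
      time_params(xi_g[i], lam_g[i], s2_g[i],
                  if (config$model == "M3") phi_g[i] else 0))
    spec_g <- model_spec(config$model, config$acc, time_g, lat)

    # latents
    z1 <- stats::rnorm(n)
    z2 <- stats::rnorm(n)
    theta <- lat$mean_theta + sqrt(lat$var_theta) * z1
    tau <- lat$mean_tau + sqrt(lat$var_tau) *
      (lat$rho * z1 + sqrt(1 - lat$rho^2) * z2)

    X <- matrix(NA_integer_, n, I)
    Tm <- matrix(NA_real_, n, I)
    for (i in seq_len(I)) {
      pr <- grm_category_probs(theta, config$acc[[i]])
      if (is.null(dim(pr))) pr <- matrix(pr, n)
      u <- stats::runif(n)
      cum <- t(apply(pr, 1L, cumsum))
      X[, i] <- rowSums(u > cum[, -ncol(cum), drop = FALSE])
      mu_y <- xi_g[i] - lam_g[i] * tau +
        (if (config$model == "M3") phi_g[i] * theta else 0)
      Tm[, i] <- exp(stats::rnorm(n, mu_y, sqrt(s2_g[i])))
    }

    # MAR missingness on responses
    for (i in seq_len(I)) {
      rate <- config$miss_rates[i]
      if (rate <= 0) next
      if (config$miss_time_dep) {
        beta <- 0.8
        y_sd <- sqrt(lam_g[i]^2 * lat$var_tau + phi_g[i]^2 * lat$var_theta -
                     2 * lam_g[i] * phi_g[i] *
                       lat$rho * sqrt(lat$var_theta * lat$var_tau) +
                     s2_g[i])
        y_mean <- xi_g[i] - lam_g[i] * lat$mean_tau + phi_g[i] * lat$mean_theta
        al <- miss_intercept(rate, beta)
        p_miss <- stats::plogis(al + beta * (log(Tm[, i]) - y_mean) / y_sd)
      } else {
        p_miss <- rep(rate, n)
      }
      X[stats::runif(n) < p_miss, i] <- NA_integer_
    }

    resp[[g]] <- X; times[[g]] <- Tm
    grp[[g]] <- rep(sprintf("G%02d", g), n)
    truth[[sprintf("G%02d", g)]] <- spec_g
  }
  data <- rt_dataset(do.call(rbind, resp), do.call(rbind, times),
                     unlist(grp),
                     n_cat = vapply(config$acc, function(a)
                       length(a$b) + 1L, 0L))
  list(data = data, truth = truth, config = config)
}

#' Packaged default scenario emulating the PISA 2012 CBA mathematics items
#'
#' A desk-scale stand-in for the released PISA 2012 computer-based
#' mathematics log-file data: 8 groups of 600 persons, 10 items in three
#' units with 3 polytomous items (two thresholds each), time intensities
#' calibrated so item mean times match the released per-item averages
#' (0.84-2.18 minutes), per-item missing-response rates equal to the
#' released rates (0.8-9.0%, increasing toward the end of each unit,
#' overall about 3.4%), group proficiency means spread over about one SD,
#' and a latent speed-proficiency correlation of 0.4.
#'
#' @param n_groups,persons_per_group Scenario size (defaults 8 x 600).
#' @param model Generating model (`"M2"` default).
#' @param invariance Invariance scenario (default `"weak"`, the pattern the
#'   ladder analysis most often selects on the real data).
#' @param seed Master seed.
#' @return A [scenario_config()].
#' @export
pisa_like_scenario <- function(n_groups = 8L, persons_per_group = 600L,
                               model = "M2", invariance = "weak",
                               seed = 20120L) {
  # released item descriptives: mean time (minutes) and % missing responses
  mean_time <- c(1.36, 1.87, 1.98, 2.18, 0.96, 1.33, 0.84, 1.25, 1.82, 1.56)
  miss_pct  <- c(0.81, 0.93, 3.25, 1.69, 1.93, 2.55, 3.30, 3.94, 6.60, 8.96)
  pcorr     <- c(59.02, 8.43, 29.02, 29.58, 47.42, 26.91, 44.12, 67.13,
                 27.75, 23.24) / 100
  a   <- c(1.3, 1.0, 1.4, 1.5, 1.1, 1.2, 0.9, 1.3, 1.2, 1.0)
  lam <- c(0.35, 0.40, 0.45, 0.42, 0.28, 0.33, 0.25, 0.30, 0.38, 0.34)
  s2  <- c(0.25, 0.30, 0.28, 0.35, 0.22, 0.26, 0.20, 0.24, 0.32, 0.30)
  phi <- c(0.15, 0.25, 0.20, 0.30, 0.10, 0.18, 0.12, 0.22, 0.28, 0.16)
  poly <- c(2L, 3L, 4L)                       # constructed-response items
  acc <- lapply(1:10, function(i) {
    b_top <- -stats::qlogis(pcorr[i])         # full-credit threshold
    if (i %in% poly) acc_params(a[i], c(b_top - 1.2, b_top))
    else acc_params(a[i], b_top)
  })
  # mean of a lognormal with mu = xi - lambda*tau (+ phi*theta):
  # E[T] = exp(xi + (lambda^2 + phi^2 + sigma2)/2) at centred latents
  tot_var <- lam^2 + s2 + if (model == "M3") phi^2 else 0
  xi <- log(mean_time) - tot_var / 2
  tim <- lapply(1:10, function(i)
    time_params(xi[i], lam[i], s2[i], if (model == "M3") phi[i] else 0))
  mu_th <- if (n_groups == 1L) 0 else seq(-0.5, 0.5, length.out = n_groups)
  lat <- lapply(seq_len(n_groups), function(g)
    latent_spec(mean_theta = mu_th[g], var_theta = 1,
                mean_tau = 0, var_tau = 1,
                rho = if (model == "M3") 0 else 0.4))
  scenario_config(n_groups, persons_per_group, acc, tim, model = model,
                  invariance = invariance, latent = lat,
                  miss_rates = miss_pct / 100, seed = seed)
}
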