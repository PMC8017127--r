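# Independent oracles and small fixture builders used across the suite.
# The oracles deliberately avoid the package's likelihood path: plain
# logistic/normal arithmetic on dense grids.

# brute-force dense-grid marginal log-likelihood on [-6, 6]^2 (or [-6, 6]
# for M1), trapezoid rule
oracle_grid_loglik <- function(data, spec, K = 301L) {
  lt <- spec$latent
  th <- seq(-6, 6, length.out = K)
  h <- th[2L] - th[1L]
  wt <- rep(h, K); wt[c(1L, K)] <- h / 2
  I <- ncol(data$responses)
  logistic <- function(z) 1 / (1 + exp(-z))
  cat_prob <- function(i, x, thv) {
    a <- spec$acc[[i]]$a; b <- spec$acc[[i]]$b; m <- length(b)
    up <- if (x >= 1) logistic(a * (thv - b[x])) else 1
    lo <- if (x + 1 <= m) logistic(a * (thv - b[x + 1])) else 0
    up - lo
  }
  if (spec$model == "M1") {
    dens <- exp(-(th - lt$mean_theta)^2 / (2 * lt$var_theta)) /
      sqrt(2 * pi * lt$var_theta)
    tot <- 0
    for (p in seq_len(nrow(data$responses))) {
      f <- dens
      for (i in seq_len(I)) {
        x <- data$responses[p, i]
        if (!is.na(x)) f <- f * cat_prob(i, x, th)
      }
      tot <- tot + log(sum(wt * f))
    }
    return(tot)
  }
  ta <- th
  sd1 <- sqrt(lt$var_theta); sd2 <- sqrt(lt$var_tau); r <- lt$rho
  tot <- 0
  for (p in seq_len(nrow(data$responses))) {
    u1 <- (th - lt$mean_theta) / sd1
    u2 <- (ta - lt$mean_tau) / sd2
    lbvn <- outer(u1, u2, function(a1, a2)
      -(a1^2 - 2 * r * a1 * a2 + a2^2) / (2 * (1 - r^2))) -
      log(2 * pi * sd1 * sd2 * sqrt(1 - r^2))
    lf <- lbvn
    for (i in seq_len(I)) {
      x <- data$responses[p, i]
      if (!is.na(x))
        lf <- lf + log(cat_prob(i, x, th))   # constant across tau
      tt <- data$times[p, i]
      if (!is.na(tt)) {
        it <- spec$time[[i]]
        mloc <- outer(th, ta, function(a1, a2)
          it$xi - it$lambda * a2 + it$phi * a1)
        lf <- lf - (log(tt) - mloc)^2 / (2 * it$sigma2) -
          0.5 * log(2 * pi * it$sigma2) - log(tt)
      }
    }
    tot <- tot + log(sum(outer(wt, wt) * exp(lf)))
  }
  tot
}

# dense-grid posterior mean and SD of theta for one person (M2/M3)
oracle_grid_posterior <- function(x_row, t_row, spec, K = 601L) {
  lt <- spec$latent
  th <- seq(-6, 6, length.out = K)
  ta <- th
  sd1 <- sqrt(lt$var_theta); sd2 <- sqrt(lt$var_tau); r <- lt$rho
  u1 <- (th - lt$mean_theta) / sd1
  u2 <- (ta - lt$mean_tau) / sd2
  lf <- outer(u1, u2, function(a1, a2)
    -(a1^2 - 2 * r * a1 * a2 + a2^2) / (2 * (1 - r^2)))
  logistic <- function(z) 1 / (1 + exp(-z))
  for (i in seq_along(x_row)) {
    x <- x_row[i]
    if (!is.na(x)) {
      a <- spec$acc[[i]]$a; b <- spec$acc[[i]]$b; m <- length(b)
      up <- if (x >= 1) logistic(a * (th - b[x])) else 1
      lo <- if (x + 1 <= m) logistic(a * (th - b[x + 1])) else 0
      lf <- lf + log(up - lo)
    }
    tt <- t_row[i]
    if (!is.na(tt) && spec$model != "M1") {
      it <- spec$time[[i]]
      mloc <- outer(th, ta, function(a1, a2)
        it$xi - it$lambda * a2 + it$phi * a1)
      lf <- lf - (log(tt) - mloc)^2 / (2 * it$sigma2)
    }
  }
  w <- exp(lf - max(lf)); w <- w / sum(w)
  m_th <- sum(rowSums(w) * th)
  v_th <- sum(rowSums(w) * th^2) - m_th^2
  m_ta <- sum(colSums(w) * ta)
  v_ta <- sum(colSums(w) * ta^2) - m_ta^2
  list(eap_theta = m_th, psd_theta = sqrt(v_th),
       eap_tau = m_ta, psd_tau = sqrt(v_ta))
}

# small fixed toy model/data pair used in several files
toy_joint <- function(model = "M3", seed = 42L, n = 5L) {
  acc <- list(acc_params(1.2, c(-0.5, 0.7)),
              acc_params(0.9, 0.3),
              acc_params(1.5, c(-1.0, 0.2)))
  tim <- list(time_params(0.4, 0.35, 0.30, if (model == "M3") 0.15 else 0),
              time_params(0.7, 0.25, 0.25, if (model == "M3") -0.1 else 0),
              time_params(0.2, 0.45, 0.35, if (model == "M3") 0.2 else 0))
  rho <- if (model == "M2") 0.45 else 0
  lat <- latent_spec(0.2, 1.3, -0.1, 0.8, rho)
  spec <- if (model == "M1") model_spec("M1", acc, NULL, lat)
          else model_spec(model, acc, tim, lat)
  set.seed(seed)
  X <- matrix(sample(c(0:1, NA), n * 3L, replace = TRUE,
                     prob = c(0.45, 0.45, 0.1)), n, 3L)
  X[, 1L] <- sample(c(0:2, NA), n, replace = TRUE,
                    prob = c(0.3, 0.3, 0.3, 0.1))
  X[, 3L] <- sample(c(0:2, NA), n, replace = TRUE,
                    prob = c(0.3, 0.3, 0.3, 0.1))
  Tm <- matrix(exp(rnorm(n * 3L, 0.4, 0.5)), n, 3L)
  Tm[1L, 2L] <- NA
  if (n >= 4L) { X[4L, ] <- NA; Tm[4L, ] <- NA }   # fully missing person
  d <- rt_dataset(X, Tm, n_cat = c(3L, 2L, 3L))
  list(data = d, spec = spec)
}

# quick simulated recovery dataset (single homogeneous group)
recovery_config <- function(n, model = "M2", seed = 1L, miss = 0) {
  cfg <- pisa_like_scenario(n_groups = 1L, persons_per_group = n,
                            model = model, invariance = "full", seed = seed)
  cfg$miss_rates <- rep(miss, 10L)
  cfg
}
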