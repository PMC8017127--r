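# Internal marginal-likelihood engine.
#
# The joint model has log-times linear-Gaussian in the bivariate normal
# latents z = (theta, tau): y_i = xi_i + g_i' z + e_i with
# g_i = (phi_i, -lambda_i). The speed dimension therefore integrates out in
# closed form: the marginal density of the observed log-times is multivariate
# normal, the posterior of z given the times is bivariate normal, and the
# remaining integral over the accuracy part is univariate in theta. That
# univariate integral is evaluated with (adaptive) Gauss-Hermite quadrature.
#
# Gradients come from Fisher's identity: the score of the marginal
# log-likelihood equals the posterior expectation of the complete-data score,
# which reduces to posterior moments of (theta, tau) available in closed form
# from the quadrature weights and the Gaussian conditional tau | theta, y.

# Gauss-Hermite rule re-expressed for a standard normal weight:
# nodes x and weights w with sum(w) = 1 and sum(w * f(x)) ~ E[f(Z)], Z~N(0,1).
.gh_cache <- new.env(parent = emptyenv())
gh_norm <- function(n) {
  key <- as.character(n)
  if (!is.null(.gh_cache[[key]])) return(.gh_cache[[key]])
  out <- if (n == 1L) list(x = 0, w = 1) else {
    i <- seq_len(n - 1L)
    J <- matrix(0, n, n)
    J[cbind(i, i + 1L)] <- sqrt(i / 2)
    J[cbind(i + 1L, i)] <- sqrt(i / 2)
    e <- eigen(J, symmetric = TRUE)
    ord <- order(e$values)
    x <- e$values[ord]
    w <- e$vectors[1L, ord]^2        # already normalized: sum = 1
    list(x = x * sqrt(2), w = w)
  }
  .gh_cache[[key]] <- out
  out
}

# bare logistic (avoids plogis dispatch overhead in the hot path)
lgs <- function(x) 1 / (1 + exp(-x))

# flat parameter vectors from a model_spec
spec_parts <- function(spec) {
  acc_a <- vapply(spec$acc, `[[`, 0, "a")
  acc_b <- lapply(spec$acc, `[[`, "b")
  if (spec$model == "M1") {
    xi <- lam <- phi <- s2 <- NULL
  } else {
    xi  <- vapply(spec$time, `[[`, 0, "xi")
    lam <- vapply(spec$time, `[[`, 0, "lambda")
    phi <- vapply(spec$time, `[[`, 0, "phi")
    s2  <- vapply(spec$time, `[[`, 0, "sigma2")
  }
  list(model = spec$model, a = acc_a, b = acc_b, xi = xi, lam = lam,
       phi = phi, s2 = s2,
       mu = c(spec$latent$mean_theta, spec$latent$mean_tau),
       Sg = latent_cov(spec$latent))
}

# Evaluate the collapsed likelihood (and optionally posterior pieces).
#
# data: rt_data; parts: spec_parts() output; quad: quad_spec
# need_post: also return node weights/positions and conditional coefficients
# Returns list(ll, and when need_post: PI, TH, Ez, E11, E12, E22, lltime)
core_eval <- function(data, parts, quad, need_post = FALSE) {
  n <- nrow(data$responses)
  I <- ncol(data$responses)
  use_times <- parts$model != "M1"
  if (use_times && is.null(data$times))
    stop("model ", parts$model, " requires response times")
  mu <- parts$mu
  Sg <- parts$Sg
  if (abs(parts$Sg[1, 2]) >= sqrt(Sg[1, 1] * Sg[2, 2]) ||
      Sg[1, 1] <= 0 || Sg[2, 2] <= 0)
    stop("latent covariance is not positive definite")

  ll_time <- numeric(n)
  # per-person posterior-of-z-given-times summaries
  eta_m <- rep(mu[1], n)            # E[theta | times]
  eta_v <- rep(Sg[1, 1], n)         # Var[theta | times]
  # conditional tau | theta, times: tau = cc + bb * theta + noise(vv)
  bb <- rep(Sg[1, 2] / Sg[1, 1], n)
  cc <- rep(mu[2] - Sg[1, 2] / Sg[1, 1] * mu[1], n)
  vv <- rep(Sg[2, 2] - Sg[1, 2]^2 / Sg[1, 1], n)

  if (use_times) {
    Y <- log(data$times)
    miss <- is.na(Y)
    G_full <- cbind(parts$phi, -parts$lam)
    key <- as.vector(miss %*% 2^(seq_len(I) - 1L))
    Sg_inv <- solve(Sg)
    for (k in unique(key)) {
      idx <- which(key == k)
      Jt <- which(!miss[idx[1L], ])
      if (length(Jt) == 0L) next    # no observed times: prior posterior
      G <- G_full[Jt, , drop = FALSE]
      D <- parts$s2[Jt]
      S <- G %*% Sg %*% t(G) + diag(D, length(Jt))
      Lc <- chol(S)
      R <- sweep(Y[idx, Jt, drop = FALSE], 2L, parts$xi[Jt], `-`)
      Rc <- sweep(R, 2L, as.vector(G %*% mu), `-`)
      qf <- colSums(backsolve(Lc, t(Rc), transpose = TRUE)^2)
      ll_time[idx] <- -0.5 * (length(Jt) * log(2 * pi) +
                              2 * sum(log(diag(Lc))) + qf) -
        rowSums(Y[idx, Jt, drop = FALSE])
      P <- Sg_inv + t(G) %*% (G / D)
      V <- solve(P)
      M <- V %*% (matrix(Sg_inv %*% mu, 2L, length(idx)) +
                  t(G / D) %*% t(R))           # 2 x np posterior means
      eta_m[idx] <- M[1L, ]
      eta_v[idx] <- V[1, 1]
      bb[idx] <- V[1, 2] / V[1, 1]
      cc[idx] <- M[2L, ] - V[1, 2] / V[1, 1] * M[1L, ]
      vv[idx] <- V[2, 2] - V[1, 2]^2 / V[1, 1]
    }
  }

  # accuracy integral over theta; when no times inform theta (M1, or a
  # non-adaptive rule) all persons share the same nodes, so the category
  # log-probabilities are computed once per item at the Q nodes only
  gh <- gh_norm(quad$nodes)
  Q <- quad$nodes
  shared <- !use_times || !quad$adaptive
  if (shared) {
    th0 <- mu[1] + sqrt(Sg[1, 1]) * gh$x
    TH <- matrix(th0, n, Q, byrow = TRUE)
    LW <- matrix(log(gh$w), n, Q, byrow = TRUE)
    if (use_times)  # importance correction from prior nodes to posterior
      LW <- LW + stats::dnorm(TH, eta_m, sqrt(eta_v), log = TRUE) -
        stats::dnorm(TH, mu[1], sqrt(Sg[1, 1]), log = TRUE)
  } else {
    TH <- eta_m + sqrt(eta_v) %o% gh$x
    LW <- matrix(log(gh$w), n, Q, byrow = TRUE)
  }

  LA <- LW
  for (i in seq_len(I)) {
    x <- data$responses[, i]
    a <- parts$a[i]; b <- parts$b[[i]]; m <- length(b)
    obs <- which(!is.na(x))
    if (length(obs) == 0L) next
    if (shared) {
      cum <- rbind(1, lgs(a * outer(b, th0, function(bb, tt) tt - bb)), 0)
      logP <- log(pmax(cum[1:(m + 1L), , drop = FALSE] -
                       cum[2:(m + 2L), , drop = FALSE], 1e-300))
      LA[obs, ] <- LA[obs, ] + logP[x[obs] + 1L, , drop = FALSE]
    } else {
      for (cat in unique(x[obs])) {
        rows <- which(!is.na(x) & x == cat)
        THr <- TH[rows, , drop = FALSE]
        upper <- if (cat >= 1L) lgs(a * (THr - b[cat])) else 1
        lower <- if (cat + 1L <= m) lgs(a * (THr - b[cat + 1L])) else 0
        LA[rows, ] <- LA[rows, ] + log(pmax(upper - lower, 1e-300))
      }
    }
  }
  Mx <- LA[cbind(seq_len(n), max.col(LA, ties.method = "first"))]
  ll_acc <- Mx + log(rowSums(exp(LA - Mx)))
  out <- list(ll = ll_time + ll_acc)
  if (need_post) {
    PI <- exp(LA - Mx - log(rowSums(exp(LA - Mx))))  # n x Q posterior weights
    Eth  <- rowSums(PI * TH)
    Eth2 <- rowSums(PI * TH^2)
    Ez1 <- Eth
    Ez2 <- cc + bb * Eth
    E11 <- Eth2
    E12 <- cc * Eth + bb * Eth2
    E22 <- vv + cc^2 + 2 * cc * bb * Eth + bb^2 * Eth2
    out <- c(out, list(PI = PI, TH = TH, Ez1 = Ez1, Ez2 = Ez2,
                       E11 = E11, E12 = E12, E22 = E22,
                       lltime = ll_time, eta_m = eta_m, eta_v = eta_v,
                       bb = bb, cc = cc, vv = vv))
  }
  out
}

# Full analytic gradient of the total marginal log-likelihood with respect
# to the natural parameters, via Fisher's identity. Returns a list with
# components only for the requested blocks.
core_gradient <- function(data, parts, quad,
                          need_acc = TRUE, need_time = TRUE,
                          need_latent = TRUE) {
  ev <- core_eval(data, parts, quad, need_post = TRUE)
  n <- nrow(data$responses)
  I <- ncol(data$responses)
  out <- list(ll = sum(ev$ll))

  if (need_acc) {
    shared <- parts$model == "M1" || !quad$adaptive
    d_a <- numeric(I)
    d_b <- lapply(parts$b, function(bv) numeric(length(bv)))
    for (i in seq_len(I)) {
      x <- data$responses[, i]
      item <- structure(list(a = parts$a[i], b = parts$b[[i]]),
                        class = "acc_params")
      for (cat in unique(x[!is.na(x)])) {
        rows <- which(!is.na(x) & x == cat)
        if (shared) {
          th0 <- ev$TH[1L, ]
          g <- grm_log_prob_grad(th0, item, as.integer(cat))
          wq <- colSums(ev$PI[rows, , drop = FALSE])
          d_a[i] <- d_a[i] + sum(wq * g$da)
          for (j in seq_along(item$b))
            d_b[[i]][j] <- d_b[[i]][j] + sum(wq * g$db[, j])
        } else {
          THr <- ev$TH[rows, , drop = FALSE]
          g <- grm_log_prob_grad(as.vector(THr), item, as.integer(cat))
          PIr <- ev$PI[rows, , drop = FALSE]
          d_a[i] <- d_a[i] + sum(PIr * matrix(g$da, nrow(THr)))
          for (j in seq_along(item$b))
            d_b[[i]][j] <- d_b[[i]][j] +
              sum(PIr * matrix(g$db[, j], nrow(THr)))
        }
      }
    }
    out$a <- d_a; out$b <- d_b
  }

  if (need_time && parts$model != "M1") {
    Y <- log(data$times)
    d_xi <- d_lam <- d_phi <- d_s2 <- numeric(I)
    for (i in seq_len(I)) {
      obs <- which(!is.na(Y[, i]))
      if (length(obs) == 0L) next
      r <- Y[obs, i] - parts$xi[i]
      g1 <- parts$phi[i]; g2 <- -parts$lam[i]; s2 <- parts$s2[i]
      Ez1 <- ev$Ez1[obs]; Ez2 <- ev$Ez2[obs]
      E11 <- ev$E11[obs]; E12 <- ev$E12[obs]; E22 <- ev$E22[obs]
      gEz <- g1 * Ez1 + g2 * Ez2
      # E[(y - mu_i(z)) h(z)] terms
      e0 <- r - gEz
      e_th <- r * Ez1 - (g1 * E11 + g2 * E12)
      e_ta <- r * Ez2 - (g1 * E12 + g2 * E22)
      e_sq <- r^2 - 2 * r * gEz + (g1^2 * E11 + 2 * g1 * g2 * E12 +
                                   g2^2 * E22)
      d_xi[i]  <- sum(e0) / s2
      d_lam[i] <- -sum(e_ta) / s2
      d_phi[i] <- sum(e_th) / s2
      d_s2[i]  <- sum(-1 / (2 * s2) + e_sq / (2 * s2^2))
    }
    out$xi <- d_xi; out$lambda <- d_lam; out$phi <- d_phi; out$sigma2 <- d_s2
  }

  if (need_latent) {
    mu <- parts$mu; Sg <- parts$Sg; Sg_inv <- solve(Sg)
    dEz <- c(sum(ev$Ez1) - n * mu[1], sum(ev$Ez2) - n * mu[2])
    d_mu <- as.vector(Sg_inv %*% dEz)
    # sum of posterior second central moments about mu
    M11 <- sum(ev$E11) - 2 * mu[1] * sum(ev$Ez1) + n * mu[1]^2
    M12 <- sum(ev$E12) - mu[1] * sum(ev$Ez2) - mu[2] * sum(ev$Ez1) +
      n * mu[1] * mu[2]
    M22 <- sum(ev$E22) - 2 * mu[2] * sum(ev$Ez2) + n * mu[2]^2
    Mmat <- matrix(c(M11, M12, M12, M22), 2L, 2L)
    Gmat <- 0.5 * (Sg_inv %*% Mmat %*% Sg_inv - n * Sg_inv)
    vt <- Sg[1, 1]; vs <- Sg[2, 2]
    rho <- Sg[1, 2] / sqrt(vt * vs)
    dS_vt <- matrix(c(1, rho * sqrt(vs / vt) / 2,
                      rho * sqrt(vs / vt) / 2, 0), 2L, 2L)
    dS_vs <- matrix(c(0, rho * sqrt(vt / vs) / 2,
                      rho * sqrt(vt / vs) / 2, 1), 2L, 2L)
    dS_r <- matrix(c(0, sqrt(vt * vs), sqrt(vt * vs), 0), 2L, 2L)
    out$mean_theta <- d_mu[1]; out$mean_tau <- d_mu[2]
    out$var_theta <- sum(Gmat * dS_vt)
    out$var_tau <- sum(Gmat * dS_vs)
    out$rho <- sum(Gmat * dS_r)
  }
  out
}
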