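#' Lognormal response-time density
#'
#' Density of the response time of one item given the latent variables.
#' The log-time is normal with mean `xi - lambda * tau` under the
#' simple-structure model (M2) or `xi - lambda * tau + phi * theta` under
#' the cross-loading model (M3), and variance `sigma2`.
#'
#' @param t Positive response time(s), in minutes.
#' @param theta Proficiency value.
#' @param tau Speed value.
#' @param item A [time_params()] object.
#' @param model `"M2"` or `"M3"`; under M2 the cross-loading is ignored
#'   (it must be zero in a valid M2 specification).
#' @param log Return the log density.
#' @return Density value(s), vectorized over `t`.
#' @export
logtime_density <- function(t, theta, tau, item, model = c("M2", "M3"),
                            log = FALSE) {
  stopifnot(inherits(item, "time_params"))
  model <- match.arg(model)
  if (any(!is.finite(t)) || any(t <= 0))
    stop("response times must be positive")
  mu <- item$xi - item$lambda * tau + if (model == "M3") item$phi * theta else 0
  stats::dlnorm(t, meanlog = mu, sdlog = sqrt(item$sigma2), log = log)
}

#' Model-implied moments of the log response times
#'
#' Mean vector and covariance matrix of the log-times implied by an M2 or
#' M3 specification, integrating over the latent distribution. Used by the
#' rotation diagnostics and by moment-matching tests of the simulator.
#'
#' @param spec A [model_spec()] with model M2 or M3.
#' @return A list with `mean` (length-I vector) and `cov` (I x I matrix).
#' @export
implied_logtime_moments <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$model == "M1")
    stop("implied_logtime_moments is undefined for M1 (no time model)")
  lam <- vapply(spec$time, `[[`, 0, "lambda")
  phi <- vapply(spec$time, `[[`, 0, "phi")
  xi  <- vapply(spec$time, `[[`, 0, "xi")
  s2  <- vapply(spec$time, `[[`, 0, "sigma2")
  G <- cbind(phi, -lam)                 # loading of (theta, tau) on log-time
  Sg <- latent_cov(spec$latent)
  mu <- xi + G %*% c(spec$latent$mean_theta, spec$latent$mean_tau)
  V <- G %*% Sg %*% t(G) + diag(s2, length(xi))
  list(mean = drop(mu), cov = V)
}
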