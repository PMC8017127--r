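#' Joint log-likelihood of one person at fixed latent values
#'
#' Sum over items of the log category probability of the observed response
#' plus, for M2/M3, the log density of the observed response time, at given
#' proficiency and speed values. Missing entries contribute nothing
#' (missing-at-random, full-information handling); a person with no
#' observed data has log-likelihood zero.
#'
#' @param x_row Integer response vector (categories `0..m_i`, `NA` missing).
#' @param t_row Numeric time vector in minutes (`NA` missing); ignored for M1.
#' @param theta,tau Latent proficiency and speed values.
#' @param spec A [model_spec()].
#' @return The conditional log-likelihood (a single number).
#' @export
person_loglik <- function(x_row, t_row, theta, tau, spec) {
  stopifnot(inherits(spec, "model_spec"))
  I <- length(spec$acc)
  if (length(x_row) != I)
    stop("'x_row' must have one entry per item of the model")
  ll <- 0
  for (i in seq_len(I)) {
    if (!is.na(x_row[i])) {
      pr <- grm_category_probs(theta, spec$acc[[i]])
      ll <- ll + log(max(pr[x_row[i] + 1L], 1e-300))
    }
    if (spec$model != "M1" && !is.null(t_row) && !is.na(t_row[i]))
      ll <- ll + logtime_density(t_row[i], theta, tau, spec$time[[i]],
                                 model = spec$model, log = TRUE)
  }
  ll
}

#' Marginal log-likelihood of a dataset
#'
#' Sum over persons of the log of the integral of the conditional
#' likelihood over the bivariate normal latent distribution (univariate
#' over proficiency for M1). The speed dimension is integrated analytically
#' (the log-times are linear-Gaussian in the latents); the proficiency
#' dimension uses Gauss-Hermite quadrature per [quad_spec()]. The result is
#' deterministic given inputs.
#'
#' @param data An [rt_dataset()].
#' @param spec A [model_spec()] with all parameters set.
#' @param quad A [quad_spec()].
#' @return Total marginal log-likelihood (a single number).
#' @export
marginal_loglik <- function(data, spec, quad = quad_spec()) {
  stopifnot(inherits(data, "rt_data"), inherits(spec, "model_spec"),
            inherits(quad, "quad_spec"))
  if (length(spec$acc) != ncol(data$responses))
    stop("model and data disagree on the number of items")
  sum(core_eval(data, spec_parts(spec), quad)$ll)
}
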