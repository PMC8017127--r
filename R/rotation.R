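# Rotation of the cross-loading model's latent space.
#
# Under the unrotated M3 parameterization the second latent variable only
# captures time covariance not explained by proficiency, and its
# correlation with proficiency is fixed at zero. To compare with the
# simple-structure model the factor space is rotated so that the speed
# factor is the unit-variance linear combination of the two latents that
# explains the most common response-time variance. In standardized latent
# coordinates u = ((theta - mu)/sd_theta, (tau* - mu)/sd_tau) each item's
# common log-time part is a_i' u with a_i = (phi_i sd_theta,
# -lambda_i sd_tau); the rotated speed direction v is the top eigenvector
# of sum_i a_i a_i', with its sign chosen so the speed loadings are
# predominantly positive (higher speed, shorter times). The implied
# correlation between proficiency and rotated speed is the first
# coordinate of v.

#' Rotate the cross-loading model to an interpretable speed factor
#'
#' @param spec A [model_spec()] with model `"M3"` (unrotated: latent
#'   correlation 0).
#' @return An object of class `rotation_result` with elements
#'   `rotated_speed_loadings` (per item, on the rotated speed factor),
#'   `rotated_cross_loadings` (per item, on the orthogonal complement),
#'   `implied_corr` (correlation between proficiency and rotated speed),
#'   `rotation_coefficients` (the rotated speed factor as a linear
#'   combination of theta and tau*), and `explained_variance` (sum of
#'   squared loadings on the rotated factor, against `unrotated_variance`
#'   for the tau* factor).
#' @export
rotate_m3 <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$model != "M3")
    stop("rotation applies to the cross-loading model (M3) only")
  if (spec$latent$rho != 0)
    stop("rotation expects the unrotated identification with rho = 0")
  lam <- vapply(spec$time, `[[`, 0, "lambda")
  phi <- vapply(spec$time, `[[`, 0, "phi")
  sd_th <- sqrt(spec$latent$var_theta)
  sd_ta <- sqrt(spec$latent$var_tau)
  A <- cbind(phi * sd_th, -lam * sd_ta)       # a_i rows
  M <- crossprod(A)
  if (max(abs(M)) < 1e-14)
    stop("rotation undefined: no common response-time variance ",
         "(all loadings and cross-loadings are zero)")
  e <- eigen(M, symmetric = TRUE)
  v <- e$vectors[, 1L]
  sl <- -as.vector(A %*% v)
  if (sum(sl) < 0) { v <- -v; sl <- -sl }
  vperp <- c(-v[2L], v[1L])
  cl <- as.vector(A %*% vperp)
  structure(list(
    rotated_speed_loadings = sl,
    rotated_cross_loadings = cl,
    implied_corr = v[1L],
    rotation_coefficients = c(theta = v[1L] / sd_th,
                              tau_star = v[2L] / sd_ta),
    explained_variance = sum(sl^2),
    unrotated_variance = sum((lam * sd_ta)^2),
    v = v, item_names = spec$item_names),
    class = "rotation_result")
}

#' @export
print.rotation_result <- function(x, ...) {
  cat(sprintf("<rotation_result: implied corr %.3f, explained variance %.3f (unrotated %.3f)>\n",
              x$implied_corr, x$explained_variance, x$unrotated_variance))
  invisible(x)
}

#' Marginal log-likelihood of the rotated representation
#'
#' Diagnostic companion to [rotate_m3()]: evaluates the marginal
#' log-likelihood of a dataset under the rotated factor basis - latents
#' (proficiency, rotated speed) with correlation `implied_corr` and the
#' correspondingly transformed time intensities, speed loadings and
#' cross-loadings. Because the rotation is a pure reparameterization this
#' equals [marginal_loglik()] of the original specification up to
#' quadrature accuracy.
#'
#' @param data An [rt_dataset()].
#' @param spec The original M3 [model_spec()].
#' @param rot The corresponding [rotate_m3()] result.
#' @param quad A [quad_spec()].
#' @return Total marginal log-likelihood under the rotated basis.
#' @export
loglik_rotated <- function(data, spec, rot, quad = quad_spec()) {
  stopifnot(inherits(rot, "rotation_result"), inherits(spec, "model_spec"))
  v <- rot$v
  if (abs(v[2L]) < 1e-8)
    stop("rotated basis is degenerate (speed factor collinear with ",
         "proficiency); the rotated representation has no distinct speed ",
         "dimension")
  lam <- vapply(spec$time, `[[`, 0, "lambda")
  phi <- vapply(spec$time, `[[`, 0, "phi")
  xi  <- vapply(spec$time, `[[`, 0, "xi")
  s2  <- vapply(spec$time, `[[`, 0, "sigma2")
  lt <- spec$latent
  sd_th <- sqrt(lt$var_theta); sd_ta <- sqrt(lt$var_tau)
  # change of basis from (theta, tau*) to (theta, s): time mean
  # xi~ + phi~ * theta - lam~ * s, with cor(theta, s) = v1
  lam_t <- lam * sd_ta / v[2L]
  phi_t <- phi + lam_t * v[1L] / sd_th
  xi_t  <- xi - lam * lt$mean_tau - lam_t * v[1L] * lt$mean_theta / sd_th
  cv <- v[1L] * sd_th
  parts <- list(model = "M3",
                a = vapply(spec$acc, `[[`, 0, "a"),
                b = lapply(spec$acc, `[[`, "b"),
                xi = xi_t, lam = lam_t, phi = phi_t, s2 = s2,
                mu = c(lt$mean_theta, 0),
                Sg = matrix(c(lt$var_theta, cv, cv, 1), 2L, 2L))
  sum(core_eval(data, parts, quad)$ll)
}
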