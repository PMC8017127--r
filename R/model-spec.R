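#' Accuracy parameters for one item (graded response model)
#'
#' Bundles the discrimination and ordered category thresholds of a single
#' item under the graded response model. An item with `m` thresholds has
#' `m + 1` ordered score categories coded `0..m`; a dichotomous item has a
#' single threshold.
#'
#' @param a Positive discrimination (factor loading) of the item.
#' @param b Numeric vector of strictly increasing category thresholds
#'   `b[1] < ... < b[m]`, on the scale of the latent proficiency.
#' @return An object of class `acc_params`.
#' @examples
#' acc_params(1.2, c(-0.5, 0.8))
#' @export
acc_params <- function(a, b) {
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0)
    stop("discrimination 'a' must be a single positive number")
  if (!is.numeric(b) || length(b) < 1L || anyNA(b))
    stop("'b' must be a numeric vector of at least one threshold")
  if (length(b) > 1L && any(diff(b) <= 0))
    stop("thresholds must be strictly increasing (otherwise category ",
         "probabilities can be negative)")
  structure(list(a = as.numeric(a), b = as.numeric(b)),
            class = "acc_params")
}

#' Response-time parameters for one item (lognormal model)
#'
#' Parameters of the lognormal time model for a single item: the time
#' intensity `xi` (expected log-time, in log-minutes, at zero speed), the
#' speed loading `lambda`, the residual variance `sigma2` on the log scale,
#' and an optional cross-loading `phi` of proficiency on the log-time
#' (nonzero only under the cross-loading model M3).
#'
#' @param xi Time intensity (log-minutes).
#' @param lambda Speed factor loading.
#' @param sigma2 Positive residual variance of the log-time.
#' @param phi Cross-loading of proficiency on the log-time; default 0.
#' @return An object of class `time_params`.
#' @export
time_params <- function(xi, lambda, sigma2, phi = 0) {
  stopifnot(is.numeric(xi), length(xi) == 1L, is.finite(xi),
            is.numeric(lambda), length(lambda) == 1L, is.finite(lambda),
            is.numeric(phi), length(phi) == 1L, is.finite(phi))
  if (!is.numeric(sigma2) || length(sigma2) != 1L || !is.finite(sigma2) ||
      sigma2 <= 0)
    stop("'sigma2' must be a single positive number")
  structure(list(xi = as.numeric(xi), lambda = as.numeric(lambda),
                 sigma2 = as.numeric(sigma2), phi = as.numeric(phi)),
            class = "time_params")
}

#' Latent distribution of proficiency and speed
#'
#' Means and variances of the bivariate normal latent vector
#' (proficiency theta, speed tau) together with their correlation `rho`.
#' Under the unrotated cross-loading model (M3) `rho` is not identified and
#' must be fixed at zero.
#'
#' @param mean_theta,var_theta Mean and (positive) variance of proficiency.
#' @param mean_tau,var_tau Mean and (positive) variance of speed.
#' @param rho Correlation between proficiency and speed, in `[-1, 1]`.
#' @return An object of class `latent_spec`.
#' @export
latent_spec <- function(mean_theta = 0, var_theta = 1,
                        mean_tau = 0, var_tau = 1, rho = 0) {
  stopifnot(is.numeric(mean_theta), is.numeric(mean_tau),
            length(mean_theta) == 1L, length(mean_tau) == 1L)
  if (var_theta <= 0 || var_tau <= 0)
    stop("latent variances must be positive")
  if (abs(rho) > 1) stop("'rho' must lie in [-1, 1]")
  structure(list(mean_theta = as.numeric(mean_theta),
                 var_theta = as.numeric(var_theta),
                 mean_tau = as.numeric(mean_tau),
                 var_tau = as.numeric(var_tau),
                 rho = as.numeric(rho)),
            class = "latent_spec")
}

#' Joint measurement model specification
#'
#' A complete specification of one of the three measurement models:
#' \describe{
#'   \item{M1}{response accuracy only (graded response model).}
#'   \item{M2}{simple-structure hierarchical model: accuracy plus a
#'     one-factor lognormal time model, latents correlated through `rho`.}
#'   \item{M3}{cross-loading extension: the log-time mean additionally
#'     carries a direct proficiency effect `phi` per item. When the
#'     cross-loadings are freely estimated the latent correlation is not
#'     identified and the estimation scheme fixes it at zero (the
#'     unrotated identification); with fixed cross-loadings (the
#'     group-level Full/Strong/Weak cells) a free correlation is
#'     legitimate.}
#' }
#'
#' @param model One of `"M1"`, `"M2"`, `"M3"`.
#' @param acc List of [acc_params()] objects, one per item.
#' @param time List of [time_params()] objects, one per item (`NULL` for M1).
#' @param latent A [latent_spec()].
#' @param item_names Optional character vector of item names.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(model, acc, time = NULL, latent = latent_spec(),
                       item_names = NULL) {
  model <- match.arg(model, c("M1", "M2", "M3"))
  if (!is.list(acc) || !all(vapply(acc, inherits, TRUE, "acc_params")))
    stop("'acc' must be a list of acc_params objects")
  if (model == "M1") {
    if (!is.null(time))
      stop("M1 carries no time parameters")
  } else {
    if (is.null(time) || !all(vapply(time, inherits, TRUE, "time_params")))
      stop("'time' must be a list of time_params objects for M2/M3")
    if (length(time) != length(acc))
      stop("'acc' and 'time' must describe the same items")
    if (model == "M2" && any(vapply(time, `[[`, 0, "phi") != 0))
      stop("M2 requires all cross-loadings phi = 0")
  }
  if (!inherits(latent, "latent_spec")) stop("'latent' must be a latent_spec")
  # note: when the cross-loadings of M3 are freely estimated, rho is not
  # identified and the estimation scheme fixes it at zero (the unrotated
  # identification); a nonzero rho is legitimate when the cross-loadings
  # are held fixed (the group-level Full/Strong/Weak cells), so it is not
  # rejected here
  if (is.null(item_names))
    item_names <- sprintf("item%02d", seq_along(acc))
  structure(list(model = model, acc = acc, time = time, latent = latent,
                 item_names = item_names),
            class = "model_spec")
}

#' Quadrature settings for marginal likelihood evaluation
#'
#' The speed dimension of the latent space integrates out analytically
#' (log-times are linear-Gaussian in the latents), so quadrature is applied
#' to proficiency only. `nodes` Gauss-Hermite nodes are used; when
#' `adaptive = TRUE` they are centred and scaled per person on the Gaussian
#' posterior of proficiency given the observed times (or on the prior when
#' no times are observed).
#'
#' @param nodes Number of Gauss-Hermite nodes (>= 2); default 21.
#' @param adaptive Centre/scale nodes on the per-person time posterior.
#' @return An object of class `quad_spec`.
#' @export
quad_spec <- function(nodes = 21, adaptive = TRUE) {
  nodes <- as.integer(nodes)
  if (is.na(nodes) || nodes < 2L) stop("'nodes' must be an integer >= 2")
  structure(list(nodes = nodes, adaptive = isTRUE(adaptive)),
            class = "quad_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec %s: %d items", x$model, length(x$acc)))
  npoly <- sum(vapply(x$acc, function(it) length(it$b), 0L) > 1L)
  cat(sprintf(", %d polytomous>\n", npoly))
  cat(sprintf("  latent: mu_theta=%.3f var_theta=%.3f mu_tau=%.3f var_tau=%.3f rho=%.3f\n",
              x$latent$mean_theta, x$latent$var_theta,
              x$latent$mean_tau, x$latent$var_tau, x$latent$rho))
  invisible(x)
}

# number of score categories per item
n_categories <- function(spec) {
  vapply(spec$acc, function(it) length(it$b) + 1L, 0L)
}

# 2x2 latent covariance matrix
latent_cov <- function(latent) {
  sd_t <- sqrt(latent$var_theta); sd_s <- sqrt(latent$var_tau)
  cv <- latent$rho * sd_t * sd_s
  matrix(c(latent$var_theta, cv, cv, latent$var_tau), 2L, 2L)
}
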