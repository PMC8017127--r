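# EAP scoring, reliability, and cross-model score comparisons.

#' Expected a posteriori person scores
#'
#' Posterior means and posterior SDs of proficiency (and of speed for
#' M2/M3) per person under a fitted model, computed from the same
#' collapsed-quadrature machinery as the marginal likelihood. Persons with
#' no observed data receive the prior mean and SD.
#'
#' @param data An [rt_dataset()].
#' @param spec A completed [model_spec()] (typically `fit$spec`).
#' @param quad A [quad_spec()].
#' @param model,level,group Metadata labels stored with the scores.
#' @return A data.frame of class `score_set` with columns `person`,
#'   `group`, `eap_theta`, `psd_theta` and, for M2/M3, `eap_tau`,
#'   `psd_tau`.
#' @export
eap_scores <- function(data, spec, quad = quad_spec(),
                       model = spec$model, level = NA_character_,
                       group = NA_character_) {
  stopifnot(inherits(data, "rt_data"), inherits(spec, "model_spec"))
  ev <- core_eval(data, spec_parts(spec), quad, need_post = TRUE)
  n <- nrow(data$responses)
  var_th <- pmax(ev$E11 - ev$Ez1^2, 0)
  out <- data.frame(person = seq_len(n), group = as.character(data$group),
                    eap_theta = ev$Ez1, psd_theta = sqrt(var_th),
                    stringsAsFactors = FALSE)
  if (spec$model != "M1") {
    var_ta <- pmax(ev$E22 - ev$Ez2^2, 0)
    out$eap_tau <- ev$Ez2
    out$psd_tau <- sqrt(var_ta)
  }
  structure(out, model = model, level = level, group_label = group,
            class = c("score_set", "data.frame"))
}

#' EAP reliability of the proficiency scores
#'
#' The population-level EAP reliability: variance of the EAP point
#' estimates divided by the sum of that variance and the mean squared
#' posterior SD, `var(EAP) / (var(EAP) + mean(PSD^2))`. Equals 1 under
#' perfect measurement and 0 when the estimates carry no signal.
#'
#' @param scores A `score_set` from [eap_scores()].
#' @return Reliability in `[0, 1]`.
#' @export
eap_reliability <- function(scores) {
  stopifnot(inherits(scores, "score_set"))
  if (nrow(scores) < 2L)
    stop("EAP reliability is undefined for fewer than 2 persons")
  v <- stats::var(scores$eap_theta)
  v / (v + mean(scores$psd_theta^2))
}

#' Average standard error of the proficiency estimates
#'
#' Arithmetic mean of the per-person posterior SDs of proficiency.
#'
#' @param scores A `score_set` from [eap_scores()].
#' @return A positive number.
#' @export
average_se <- function(scores) {
  stopifnot(inherits(scores, "score_set"))
  if (nrow(scores) < 1L) stop("no persons to average over")
  mean(scores$psd_theta)
}

#' Correlations between EAP proficiency estimates across models
#'
#' Pearson correlation matrix of the `eap_theta` vectors of several score
#' sets covering identical persons, pooled and (optionally) per group.
#'
#' @param score_sets Named list of `score_set` objects over the same
#'   persons in the same order.
#' @param by_group Also return the per-group correlation matrices.
#' @return The pooled correlation matrix, or when `by_group = TRUE` a list
#'   with `pooled` and `by_group` components.
#' @export
score_correlations <- function(score_sets, by_group = FALSE) {
  stopifnot(is.list(score_sets), length(score_sets) >= 1L)
  ns <- vapply(score_sets, nrow, 0L)
  if (length(unique(ns)) != 1L)
    stop("score sets do not cover identical persons")
  grp <- score_sets[[1L]]$group
  for (s in score_sets)
    if (!identical(s$person, score_sets[[1L]]$person) ||
        !identical(s$group, grp))
      stop("score sets do not cover identical persons")
  if (is.null(names(score_sets)))
    names(score_sets) <- vapply(score_sets, function(s)
      attr(s, "model") %||% "model", "")
  E <- vapply(score_sets, `[[`, numeric(ns[1L]), "eap_theta")
  pooled <- stats::cor(E)
  if (!by_group) return(pooled)
  bg <- lapply(split(seq_len(nrow(E)), grp), function(ix)
    stats::cor(E[ix, , drop = FALSE]))
  list(pooled = pooled, by_group = bg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
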