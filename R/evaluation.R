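# BIC, invariance-ladder selection, and limited-information fit statistics
# for the graded response model.

#' Bayesian information criterion of a fit
#'
#' `BIC = -2 * loglik + n_free * ln(n_persons)`, with the sample size taken
#' as the number of persons in the fitted group.
#'
#' @param fit An `rt_fit` from [fit_model()].
#' @param allow_unconverged Compute the BIC even when the optimizer did not
#'   flag convergence (refused with an error by default).
#' @return A single number.
#' @export
bic <- function(fit, allow_unconverged = FALSE) {
  stopifnot(inherits(fit, "rt_fit"))
  if (!fit$converged && !allow_unconverged)
    stop("fit did not converge; BIC refused (use allow_unconverged = TRUE ",
         "to override)")
  -2 * fit$loglik + fit$n_free * log(fit$n_persons)
}

LADDER_LEVELS <- c("Full", "Strong", "Weak", "Struct")

#' Invariance-ladder BIC table for one model family
#'
#' Collects per-group BICs of the ladder fits of a family (M2 or M3) into
#' the reporting layout: one row per group with the BIC of each fitted
#' level, the BIC range, and the preferred (minimum-BIC) level, plus a
#' total row summing BICs across groups per level.
#'
#' @param result A `two_step_result` from [two_step_analysis()].
#' @param family `"M2"` or `"M3"`.
#' @param allow_unconverged Passed to [bic()]: when `FALSE` unconverged
#'   cells yield `NA`; when `TRUE` (default) their BIC is tabulated anyway.
#' @return An object of class `ladder_table`: data.frame with columns
#'   `group`, one BIC column per level, `bic_min`, `bic_max`, `preferred`.
#' @export
ladder_table <- function(result, family = c("M2", "M3"),
                         allow_unconverged = TRUE) {
  stopifnot(inherits(result, "two_step_result"))
  family <- match.arg(family)
  levels_fit <- intersect(LADDER_LEVELS, result$levels)
  rows <- list()
  for (g in names(result$country)) {
    fits <- result$country[[g]]
    bics <- vapply(levels_fit, function(lev) {
      f <- fits[[paste0(family, "_", lev)]]
      if (is.null(f)) return(NA_real_)
      tryCatch(bic(f, allow_unconverged = allow_unconverged),
               error = function(e) NA_real_)
    }, 0)
    rows[[g]] <- c(list(group = g), as.list(bics))
  }
  tab <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  bic_cols <- as.matrix(tab[, levels_fit, drop = FALSE])
  tab$bic_min <- apply(bic_cols, 1L, min, na.rm = TRUE)
  tab$bic_max <- apply(bic_cols, 1L, max, na.rm = TRUE)
  # ties resolved toward the more constrained level (earlier in the ladder)
  tab$preferred <- levels_fit[apply(bic_cols, 1L, which.min)]
  rownames(tab) <- NULL
  structure(tab, family = family, levels = levels_fit,
            class = c("ladder_table", "data.frame"))
}

#' Preferred invariance level per group and overall
#'
#' Per-group argmin of the BIC across ladder levels, and the overall
#' preference by total BIC (summed across groups per level). Ties go to
#' the more constrained level.
#'
#' @param ladder A `ladder_table`.
#' @return A list with `per_group` (named character vector), `total_bic`
#'   (named numeric vector over levels) and `overall` (one level).
#' @export
select_invariance <- function(ladder) {
  stopifnot(inherits(ladder, "ladder_table"))
  levels_fit <- attr(ladder, "levels")
  per_group <- stats::setNames(ladder$preferred, ladder$group)
  totals <- colSums(as.matrix(ladder[, levels_fit, drop = FALSE]))
  overall <- levels_fit[which.min(totals)]
  list(per_group = per_group, total_bic = totals, overall = overall)
}

#' Limited-information fit statistics for the graded response model
#'
#' Approximate overall fit of a fitted accuracy model (M1) from univariate
#' and bivariate response margins:
#' \describe{
#'   \item{SRMR}{root mean square difference between the observed and
#'     model-implied inter-item Pearson correlations of the item scores.}
#'   \item{RMSEA}{from the sum over item pairs of Pearson chi-square
#'     statistics comparing observed and model-implied bivariate category
#'     tables, with degrees of freedom `sum(C_i * C_j - 1) - n_free`:
#'     `sqrt(max(X2 - df, 0) / (df * (N - 1)))`.}
#' }
#' Both are near zero when the model generated the data; common guideline
#' cutoffs are about 0.08 for SRMR and 0.06 for RMSEA. Margins involving
#' an empty observed category are excluded from the chi-square (counted
#' out of its degrees of freedom) and reported in the result.
#'
#' @param data The [rt_dataset()] the model was fitted to.
#' @param spec The fitted M1 [model_spec()].
#' @param n_free Number of freely estimated accuracy parameters (defaults
#'   to all discriminations and thresholds).
#' @param quad_nodes Quadrature nodes for the implied moments.
#' @return A list with `srmr`, `rmsea`, `chisq`, `df` and
#'   `excluded_cells`.
#' @export
grm_fit_statistics <- function(data, spec, n_free = NULL, quad_nodes = 49L) {
  stopifnot(inherits(data, "rt_data"), inherits(spec, "model_spec"))
  X <- data$responses
  I <- ncol(X)
  ncat <- n_categories(spec)
  if (is.null(n_free))
    n_free <- I + sum(ncat - 1L)
  gh <- gh_norm(quad_nodes)
  th <- spec$latent$mean_theta + sqrt(spec$latent$var_theta) * gh$x
  P <- lapply(seq_len(I), function(i) {
    pr <- grm_category_probs(th, spec$acc[[i]])
    if (is.null(dim(pr))) pr <- matrix(pr, length(th))
    pr
  })
  # model-implied score moments
  Escore <- vapply(seq_len(I), function(i)
    sum(gh$w * (P[[i]] %*% (0:(ncat[i] - 1L)))), 0)
  Escore2 <- vapply(seq_len(I), function(i)
    sum(gh$w * (P[[i]] %*% (0:(ncat[i] - 1L))^2)), 0)
  sd_mod <- sqrt(Escore2 - Escore^2)

  chisq <- 0; df <- 0; excluded <- 0L
  sq_diff <- c()
  for (i in seq_len(I - 1L)) for (j in (i + 1L):I) {
    ok <- !is.na(X[, i]) & !is.na(X[, j])
    nij <- sum(ok)
    if (nij < 2L) next
    # observed and implied correlation of the scores
    r_obs <- suppressWarnings(stats::cor(X[ok, i], X[ok, j]))
    Exy <- sum(gh$w * (P[[i]] %*% (0:(ncat[i] - 1L))) *
                 (P[[j]] %*% (0:(ncat[j] - 1L))))
    r_mod <- (Exy - Escore[i] * Escore[j]) / (sd_mod[i] * sd_mod[j])
    if (is.finite(r_obs)) sq_diff <- c(sq_diff, (r_obs - r_mod)^2)
    # bivariate table chi-square
    O <- table(factor(X[ok, i], levels = 0:(ncat[i] - 1L)),
               factor(X[ok, j], levels = 0:(ncat[j] - 1L)))
    Pe <- matrix(0, ncat[i], ncat[j])
    for (aa in seq_len(ncat[i])) for (bb in seq_len(ncat[j]))
      Pe[aa, bb] <- sum(gh$w * P[[i]][, aa] * P[[j]][, bb])
    E <- nij * Pe
    use <- E > 0 & (rowSums(O)[row(O)] > 0) & (colSums(O)[col(O)] > 0)
    excluded <- excluded + sum(!use)
    chisq <- chisq + sum((O[use] - E[use])^2 / E[use])
    df <- df + sum(use) - 1L
  }
  df <- df - n_free
  srmr <- sqrt(mean(sq_diff))
  N <- nrow(X)
  rmsea <- sqrt(max(chisq - df, 0) / (df * (N - 1)))
  list(srmr = srmr, rmsea = rmsea, chisq = chisq, df = df,
       excluded_cells = excluded)
}
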