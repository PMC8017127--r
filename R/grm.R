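#' Cumulative category probability of the graded response model
#'
#' Probability of scoring in category `k` or higher given proficiency,
#' `Pr(X >= k | theta) = logistic(a * (theta - b_k))`, evaluated with an
#' overflow-safe logistic.
#'
#' @param theta Proficiency value(s).
#' @param item An [acc_params()] object.
#' @param k Category index, `1 <= k <= m` where `m` is the number of
#'   thresholds of the item.
#' @return Probability (vectorized over `theta`), in (0, 1).
#' @examples
#' grm_cumulative_prob(0, acc_params(1, 0), 1)   # 0.5
#' @export
grm_cumulative_prob <- function(theta, item, k) {
  stopifnot(inherits(item, "acc_params"))
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L || k > length(item$b))
    stop("category index 'k' out of range: must be in 1..", length(item$b))
  stats::plogis(item$a * (theta - item$b[k]))
}

#' Category probabilities of the graded response model
#'
#' Probabilities of each score category `0..m` given proficiency:
#' `Pr(X = k) = Pr(X >= k) - Pr(X >= k + 1)` with the boundary conventions
#' `Pr(X >= 0) = 1` and `Pr(X >= m + 1) = 0`. For a dichotomous item this
#' reduces to the two-parameter logistic model.
#'
#' @inheritParams grm_cumulative_prob
#' @return If `theta` is scalar, a numeric vector of length `m + 1` summing
#'   to one; otherwise a `length(theta) x (m + 1)` matrix.
#' @export
grm_category_probs <- function(theta, item) {
  stopifnot(inherits(item, "acc_params"))
  m <- length(item$b)
  cum <- cbind(1, stats::plogis(outer(theta, item$b, function(th, b)
    item$a * (th - b))), 0)
  pr <- cum[, 1:(m + 1L), drop = FALSE] - cum[, 2:(m + 2L), drop = FALSE]
  colnames(pr) <- as.character(0:m)
  if (length(theta) == 1L) drop(pr) else pr
}

# log category probabilities at a vector of theta values, returned as a
# (m+1) x length(theta) matrix; clamped away from log(0) for stability.
grm_log_probs <- function(theta, item) {
  pr <- grm_category_probs(theta, item)
  if (is.null(dim(pr))) pr <- matrix(pr, nrow = 1L)
  t(log(pmax(pr, 1e-300)))
}

# Derivatives of log Pr(X = k | theta) with respect to (a, b_1..b_m),
# evaluated at a vector theta for a single category k (0-based).
# Returns a list(da = vector, db = matrix length(theta) x m).
grm_log_prob_grad <- function(theta, item, k) {
  a <- item$a; b <- item$b; m <- length(b)
  psi <- function(j) if (j >= 1L && j <= m) 1 / (1 + exp(-a * (theta - b[j]))) else
    rep(if (j == 0L) 1 else 0, length(theta))
  Pk  <- psi(k) - psi(k + 1L)
  Pk  <- pmax(Pk, 1e-300)
  dk  <- if (k >= 1L) { p <- psi(k); p * (1 - p) } else rep(0, length(theta))
  dk1 <- if (k + 1L <= m) { p <- psi(k + 1L); p * (1 - p) } else rep(0, length(theta))
  da <- ((theta - if (k >= 1L) b[k] else 0) * dk -
         (theta - if (k + 1L <= m) b[k + 1L] else 0) * dk1) / Pk
  db <- matrix(0, length(theta), m)
  if (k >= 1L)      db[, k]      <- -a * dk / Pk
  if (k + 1L <= m)  db[, k + 1L] <-  a * dk1 / Pk
  list(da = da, db = db)
}
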