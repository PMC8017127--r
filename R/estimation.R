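# Estimation: fixed/free parameter schemes, marginal ML fitting, and the
# two-step international/group analysis.

SYM_LATENT <- c("mu_theta", "var_theta", "mu_tau", "var_tau", "rho")

#' Build the fixed/free parameter scheme for one analysis cell
#'
#' Realizes one row of the estimation framework: the international
#' calibration (M1 accuracy parameters free; M2/M3 time parameters free
#' with accuracy fixed to the M1 estimates) or one rung of the per-group
#' measurement-invariance ladder (`Full`, `Strong`, `Weak`, `Struct`).
#'
#' Accuracy parameters are always carried over from the international M1
#' fit in every M2/M3 cell, so the accuracy-proficiency relationship is
#' identical across models. The ladder progressively frees time parameters:
#' `Full` fixes all item time parameters to the international estimates and
#' frees only group latent moments; `Strong` additionally frees the
#' residual variances; `Weak` also frees the time intensities (with the
#' group speed mean fixed to 0 for identification); `Struct` frees all time
#' parameters (speed mean 0, variance 1), and for M3 additionally fixes the
#' latent correlation to 0 and the group proficiency variance to the
#' group's M1_Full estimate.
#'
#' @param model `"M1"`, `"M2"` or `"M3"`.
#' @param level `"international"`, `"Full"`, `"Strong"`, `"Weak"` or
#'   `"Struct"`.
#' @param anchors Named list of prerequisite [fit_model()] results:
#'   `M1_international` for any M2/M3 cell; `M2_international` /
#'   `M3_international` for the corresponding country cells; `M1_Full`
#'   (the same group's fit) for `M3` at level `Struct`.
#' @param n_cat Integer vector of score-category counts per item.
#' @param item_names Optional item names.
#' @return An object of class `param_space`.
#' @export
parameter_space <- function(model, level = "international",
                            anchors = list(), n_cat, item_names = NULL) {
  model <- match.arg(model, c("M1", "M2", "M3"))
  level <- match.arg(level, c("international", "Full", "Strong", "Weak",
                              "Struct"))
  I <- length(n_cat)
  if (is.null(item_names)) item_names <- sprintf("item%02d", seq_len(I))
  need_anchor <- function(name) {
    if (is.null(anchors[[name]]))
      stop("missing prerequisite fit '", name, "' for ", model, "_", level)
    anchors[[name]]
  }
  rows <- list()
  add <- function(symbol, item = NA_integer_, k = NA_integer_,
                  free, value = NA_real_) {
    id <- if (is.na(item)) symbol
          else if (is.na(k)) sprintf("%s[%d]", symbol, item)
          else sprintf("%s[%d,%d]", symbol, item, k)
    rows[[length(rows) + 1L]] <<- data.frame(
      id = id, symbol = symbol, item = item, k = k, free = free,
      value = value, stringsAsFactors = FALSE)
  }

  # ---- accuracy block -------------------------------------------------
  if (model == "M1" && level == "international") {
    for (i in seq_len(I)) {
      add("a", i, free = TRUE)
      for (kk in seq_len(n_cat[i] - 1L)) add("b", i, kk, free = TRUE)
    }
  } else {
    m1 <- need_anchor("M1_international")$spec
    for (i in seq_len(I)) {
      add("a", i, free = FALSE, value = m1$acc[[i]]$a)
      for (kk in seq_len(n_cat[i] - 1L))
        add("b", i, kk, free = FALSE, value = m1$acc[[i]]$b[kk])
    }
  }

  # ---- time block -----------------------------------------------------
  if (model != "M1") {
    intl <- if (level != "international")
      need_anchor(paste0(model, "_international"))$spec else NULL
    for (i in seq_len(I)) {
      iv <- function(sym) intl$time[[i]][[sym]]
      if (level == "international") {
        add("xi", i, free = TRUE)
        add("lambda", i, free = TRUE)
        add("sigma2", i, free = TRUE)
        add("phi", i, free = (model == "M3"),
            value = if (model == "M3") NA_real_ else 0)
      } else {
        free_xi  <- level %in% c("Weak", "Struct")
        free_lam <- level == "Struct"
        free_s2  <- level %in% c("Strong", "Weak", "Struct")
        free_phi <- model == "M3" && level == "Struct"
        add("xi", i, free = free_xi, value = iv("xi"))
        add("lambda", i, free = free_lam, value = iv("lambda"))
        add("sigma2", i, free = free_s2, value = iv("sigma2"))
        add("phi", i, free = free_phi,
            value = if (model == "M3") iv("phi") else 0)
      }
    }
  } else {
    for (i in seq_len(I)) {
      add("xi", i, free = FALSE, value = 0)
      add("lambda", i, free = FALSE, value = 0)
      add("sigma2", i, free = FALSE, value = 1)
      add("phi", i, free = FALSE, value = 0)
    }
  }

  # ---- latent block ---------------------------------------------------
  if (level == "international") {
    if (model == "M1") {
      add("mu_theta", free = FALSE, value = 0)
      add("var_theta", free = FALSE, value = 1)
    } else {
      add("mu_theta", free = TRUE, value = 0)
      add("var_theta", free = TRUE, value = 1)
    }
    add("mu_tau", free = FALSE, value = 0)
    add("var_tau", free = FALSE, value = 1)
    add("rho", free = (model == "M2"), value = 0)
  } else {
    intl_lat <- if (model == "M1") NULL else
      need_anchor(paste0(model, "_international"))$spec$latent
    st <- function(sym, def) if (is.null(intl_lat)) def else intl_lat[[sym]]
    if (model == "M3" && level == "Struct") {
      m1f <- need_anchor("M1_Full")$spec$latent
      add("mu_theta", free = TRUE, value = st("mean_theta", 0))
      add("var_theta", free = FALSE, value = m1f$var_theta)
    } else {
      add("mu_theta", free = TRUE, value = st("mean_theta", 0))
      add("var_theta", free = TRUE, value = st("var_theta", 1))
    }
    if (model == "M1") {
      add("mu_tau", free = FALSE, value = 0)
      add("var_tau", free = FALSE, value = 1)
      add("rho", free = FALSE, value = 0)
    } else {
      free_mu_tau <- level %in% c("Full", "Strong")
      free_var_tau <- level != "Struct"
      add("mu_tau", free = free_mu_tau, value = 0)
      add("var_tau", free = free_var_tau, value = 1)
      if (model == "M3" && level == "Struct")
        add("rho", free = FALSE, value = 0)
      else
        add("rho", free = TRUE, value = if (model == "M2") st("rho", 0) else 0)
    }
  }

  tab <- do.call(rbind, rows)
  structure(list(table = tab, model = model, level = level,
                 n_cat = as.integer(n_cat), item_names = item_names),
            class = "param_space")
}

#' @export
print.param_space <- function(x, ...) {
  cat(sprintf("<param_space %s_%s: %d parameters, %d free>\n",
              x$model, x$level, nrow(x$table), sum(x$table$free)))
  invisible(x)
}

# parts list (see likelihood-core.R) straight from a parameter table
table_to_parts <- function(tab, model, n_cat) {
  I <- length(n_cat)
  val <- function(sym) tab$value[tab$symbol == sym][order(tab$item[tab$symbol == sym])]
  a <- tab$value[tab$symbol == "a"]
  b <- lapply(seq_len(I), function(i)
    tab$value[tab$symbol == "b" & tab$item == i][order(tab$k[tab$symbol == "b" & tab$item == i])])
  lat <- function(sym) tab$value[tab$symbol == sym]
  vt <- lat("var_theta"); vs <- lat("var_tau"); rho <- lat("rho")
  cv <- rho * sqrt(vt * vs)
  list(model = model, a = a, b = b,
       xi = if (model == "M1") NULL else tab$value[tab$symbol == "xi"],
       lam = if (model == "M1") NULL else tab$value[tab$symbol == "lambda"],
       phi = if (model == "M1") NULL else tab$value[tab$symbol == "phi"],
       s2 = if (model == "M1") NULL else tab$value[tab$symbol == "sigma2"],
       mu = c(lat("mu_theta"), lat("mu_tau")),
       Sg = matrix(c(vt, cv, cv, vs), 2L, 2L))
}

# completed model_spec from a parameter table
table_to_spec <- function(tab, model, n_cat, item_names) {
  I <- length(n_cat)
  acc <- lapply(seq_len(I), function(i) {
    bb <- tab$value[tab$symbol == "b" & tab$item == i]
    acc_params(tab$value[tab$symbol == "a" & tab$item == i], bb)
  })
  lat <- function(sym) tab$value[tab$symbol == sym]
  latent <- latent_spec(lat("mu_theta"), lat("var_theta"),
                        lat("mu_tau"), lat("var_tau"), lat("rho"))
  if (model == "M1")
    return(model_spec("M1", acc, NULL, latent, item_names))
  tim <- lapply(seq_len(I), function(i)
    time_params(tab$value[tab$symbol == "xi" & tab$item == i],
                tab$value[tab$symbol == "lambda" & tab$item == i],
                tab$value[tab$symbol == "sigma2" & tab$item == i],
                tab$value[tab$symbol == "phi" & tab$item == i]))
  model_spec(model, acc, tim, latent, item_names)
}

# deterministic data-driven starting values for free entries without one
fill_starts <- function(space, data) {
  tab <- space$table
  X <- data$responses
  Y <- if (!is.null(data$times)) log(data$times) else NULL
  for (r in which(tab$free & is.na(tab$value))) {
    sym <- tab$symbol[r]; i <- tab$item[r]; kk <- tab$k[r]
    tab$value[r] <- switch(sym,
      a = 1,
      b = {
        p <- mean(X[, i] >= kk, na.rm = TRUE)
        -stats::qlogis(min(max(p, 0.02), 0.98))
      },
      xi = mean(Y[, i], na.rm = TRUE),
      lambda = 0.3,
      sigma2 = {
        v <- stats::var(Y[, i], na.rm = TRUE)
        if (!is.finite(v) || v < 1e-3) 0.5 else v
      },
      phi = 0,
      mu_theta = 0, var_theta = 1, mu_tau = 0, var_tau = 1, rho = 0)
  }
  # enforce strictly increasing threshold starts within item
  for (i in unique(tab$item[tab$symbol == "b"])) {
    rr <- which(tab$symbol == "b" & tab$item == i)
    rr <- rr[order(tab$k[rr])]
    if (any(tab$free[rr])) {
      bv <- tab$value[rr]
      for (j in seq_along(bv)[-1])
        bv[j] <- max(bv[j], bv[j - 1] + 0.2)
      tab$value[rr] <- bv
    }
  }
  space$table <- tab
  space
}

# ---- transforms between natural and unconstrained working scale --------
# variances and discriminations: log; rho: atanh; thresholds: first one
# identity, later ones log-increments (preserves ordering); rest identity.

pack_working <- function(tab) {
  w <- numeric(0); map <- list()
  done_b <- character(0)
  for (r in which(tab$free)) {
    sym <- tab$symbol[r]
    if (sym == "b") {
      key <- paste0("b_item", tab$item[r])
      if (key %in% done_b) next
      done_b <- c(done_b, key)
      rr <- which(tab$symbol == "b" & tab$item == tab$item[r] & tab$free)
      rr <- rr[order(tab$k[rr])]
      bv <- tab$value[rr]
      wv <- c(bv[1], if (length(bv) > 1) log(diff(bv)))
      map[[length(map) + 1L]] <- list(type = "b", rows = rr)
      w <- c(w, wv)
    } else {
      tr <- switch(sym, a = , sigma2 = , var_theta = , var_tau = "log",
                   rho = "atanh", "id")
      v <- tab$value[r]
      wv <- switch(tr, log = log(v),
                   atanh = atanh(min(max(v, -0.999), 0.999)), v)
      map[[length(map) + 1L]] <- list(type = tr, rows = r)
      w <- c(w, wv)
    }
  }
  list(w = w, map = map)
}

unpack_working <- function(w, map, tab) {
  pos <- 1L
  for (mp in map) {
    nr <- length(mp$rows)
    if (mp$type == "b") {
      wv <- w[pos:(pos + nr - 1L)]
      bv <- cumsum(c(wv[1], if (nr > 1) exp(pmin(wv[-1], 20))))
      tab$value[mp$rows] <- bv
      pos <- pos + nr
    } else {
      v <- w[pos]
      tab$value[mp$rows] <- switch(mp$type,
        log = exp(pmin(v, 20)), atanh = tanh(v), v)
      pos <- pos + 1L
    }
  }
  tab
}

# chain rule: gradient w.r.t. natural values of free rows -> working scale
grad_to_working <- function(gnat, w, map, tab) {
  gw <- numeric(length(w)); pos <- 1L
  for (mp in map) {
    nr <- length(mp$rows)
    if (mp$type == "b") {
      g <- gnat[mp$rows]
      gw[pos] <- sum(g)
      if (nr > 1) {
        wv <- w[(pos + 1L):(pos + nr - 1L)]
        for (j in 2:nr)
          gw[pos + j - 1L] <- exp(min(wv[j - 1L], 20)) * sum(g[j:nr])
      }
      pos <- pos + nr
    } else {
      g <- gnat[mp$rows]
      gw[pos] <- switch(mp$type,
        log = g * exp(min(w[pos], 20)),
        atanh = g * (1 - tanh(w[pos])^2),
        g)
      pos <- pos + 1L
    }
  }
  gw
}

# gradient w.r.t. natural values of every table row, from core_gradient();
# blocks that were not computed (all their parameters fixed) contribute 0
gradient_by_row <- function(gr, tab) {
  g <- numeric(nrow(tab))
  pick <- function(v, i = NULL) {
    if (is.null(v)) return(0)
    if (is.null(i)) v else v[i]
  }
  for (r in seq_len(nrow(tab))) {
    if (!tab$free[r]) next
    sym <- tab$symbol[r]; i <- tab$item[r]; kk <- tab$k[r]
    g[r] <- switch(sym,
      a = pick(gr$a, i),
      b = if (is.null(gr$b)) 0 else gr$b[[i]][kk],
      xi = pick(gr$xi, i),
      lambda = pick(gr$lambda, i),
      sigma2 = pick(gr$sigma2, i),
      phi = pick(gr$phi, i),
      mu_theta = pick(gr$mean_theta),
      var_theta = pick(gr$var_theta),
      mu_tau = pick(gr$mean_tau),
      var_tau = pick(gr$var_tau),
      rho = pick(gr$rho))
  }
  g
}

#' Fit a model by marginal maximum likelihood
#'
#' Maximizes the marginal log-likelihood over the free parameters of a
#' [parameter_space()] using a quasi-Newton optimizer on transformed
#' parameters (log scale for variances and discriminations, Fisher-z for
#' the latent correlation, log-increments for ordered thresholds), with
#' analytic gradients. Starting values are deterministic: anchored entries
#' start at their anchor values, remaining accuracy parameters at
#' discrimination 1 and inverse-logistic threshold starts from observed
#' cumulative category proportions, time intensities and residual variances
#' at observed log-time means and variances, speed loadings at 0.3, latent
#' moments at (0, 1) with correlation 0.
#'
#' Standard errors come from the observed information matrix (central
#' finite differences of the analytic gradient at the optimum). When the
#' information matrix is not positive definite the SEs are flagged
#' unavailable rather than reported.
#'
#' @param data An [rt_dataset()].
#' @param space A [parameter_space()].
#' @param quad A [quad_spec()].
#' @param control List of optimizer settings: `iter_max` (500),
#'   `eval_max` (2000), `rel_tol` (1e-9), `grad_tol` (gradient-norm
#'   threshold on the working scale for the convergence flag, default
#'   `1e-4 * n_persons`), `se` (compute standard errors, default `TRUE`).
#'   The convergence flag requires the gradient norm at the returned
#'   point to fall below `grad_tol`; non-convergence is flagged in the
#'   result, never silent.
#' @param group Optional label recorded in the result.
#' @return An object of class `rt_fit` with elements `spec` (completed
#'   [model_spec()]), `par_table` (per-parameter estimates and SEs),
#'   `loglik`, `n_persons`, `n_free`, `converged`, `gradient_norm`.
#' @export
fit_model <- function(data, space, quad = quad_spec(), control = list(),
                      group = NA_character_) {
  stopifnot(inherits(data, "rt_data"), inherits(space, "param_space"))
  ctl <- utils::modifyList(list(iter_max = 500L, eval_max = 2000L,
                                rel_tol = 1e-9, grad_tol = NULL,
                                se = TRUE), control)
  n <- nrow(data$responses)
  if (is.null(ctl$grad_tol)) ctl$grad_tol <- 1e-4 * max(1, n)
  space <- fill_starts(space, data)
  tab <- space$table
  model <- space$model
  n_cat <- space$n_cat
  need_acc <- any(tab$free & tab$symbol %in% c("a", "b"))
  need_time <- any(tab$free & tab$symbol %in% c("xi", "lambda", "sigma2",
                                                "phi"))
  need_lat <- any(tab$free & tab$symbol %in% SYM_LATENT)

  pk <- pack_working(tab)
  n_free <- sum(tab$free)

  if (n_free == 0L) {
    parts <- table_to_parts(tab, model, n_cat)
    ll <- sum(core_eval(data, parts, quad)$ll)
    tab$se <- NA_real_
    return(structure(list(
      spec = table_to_spec(tab, model, n_cat, space$item_names),
      par_table = tab, loglik = ll, n_persons = n, n_free = 0L,
      converged = TRUE, gradient_norm = 0, iterations = 0L,
      model = model, level = space$level, group = group, se_ok = FALSE),
      class = "rt_fit"))
  }

  memo <- new.env(parent = emptyenv())
  eval_at <- function(w, want_grad) {
    key_same <- !is.null(memo$w) && identical(memo$w, w)
    if (key_same && (!want_grad || !is.null(memo$gw))) return()
    tab2 <- unpack_working(w, pk$map, tab)
    parts <- table_to_parts(tab2, model, n_cat)
    if (want_grad) {
      gr <- core_gradient(data, parts, quad, need_acc = need_acc,
                          need_time = need_time, need_latent = need_lat)
      gnat <- gradient_by_row(gr, tab2)
      memo$gw <- grad_to_working(gnat, w, pk$map, tab2)
      memo$gnat <- gnat
      memo$ll <- gr$ll
    } else {
      memo$ll <- sum(core_eval(data, parts, quad)$ll)
      memo$gw <- NULL
    }
    memo$w <- w
  }
  objective <- function(w) {
    v <- tryCatch({ eval_at(w, FALSE); -memo$ll },
                  error = function(e) 1e10)
    if (!is.finite(v)) 1e10 else v
  }
  gradient <- function(w) {
    tryCatch({ eval_at(w, TRUE); -memo$gw },
             error = function(e) rep(0, length(w)))
  }

  opt <- stats::nlminb(pk$w, objective, gradient,
                       control = list(iter.max = ctl$iter_max,
                                      eval.max = ctl$eval_max,
                                      rel.tol = ctl$rel_tol))
  w_hat <- opt$par
  tab <- unpack_working(w_hat, pk$map, tab)
  eval_at(w_hat, TRUE)
  gnorm <- max(abs(memo$gw))
  # convergence is judged by the gradient norm at the returned point; the
  # optimizer's own code can report "false convergence" at a genuine
  # optimum because the adaptive-quadrature objective is only smooth to
  # quadrature accuracy
  converged <- is.finite(memo$ll) && gnorm <= ctl$grad_tol

  # observed information on the natural scale of the free parameters
  tab$se <- NA_real_
  se_ok <- FALSE
  if (isTRUE(ctl$se)) {
    free_rows <- which(tab$free)
    gfun_nat <- function(v) {
      tab2 <- tab; tab2$value[free_rows] <- v
      parts <- table_to_parts(tab2, model, n_cat)
      gr <- core_gradient(data, parts, quad, need_acc = need_acc,
                          need_time = need_time, need_latent = need_lat)
      gradient_by_row(gr, tab2)[free_rows]
    }
    v0 <- tab$value[free_rows]
    H <- matrix(0, n_free, n_free)
    h <- pmax(1e-4, 1e-4 * abs(v0))
    for (j in seq_len(n_free)) {
      vp <- v0; vp[j] <- vp[j] + h[j]
      vm <- v0; vm[j] <- vm[j] - h[j]
      H[, j] <- tryCatch((gfun_nat(vp) - gfun_nat(vm)) / (2 * h[j]),
                         error = function(e) rep(NA_real_, n_free))
    }
    H <- -(H + t(H)) / 2
    if (all(is.finite(H))) {
      ei <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
      if (min(ei) > 1e-10) {
        tab$se[free_rows] <- sqrt(diag(solve(H)))
        se_ok <- TRUE
      }
    }
    if (!se_ok)
      warning("observed information not positive definite; SEs unavailable",
              call. = FALSE)
  }

  structure(list(
    spec = table_to_spec(tab, model, n_cat, space$item_names),
    par_table = tab, loglik = memo$ll, n_persons = n, n_free = n_free,
    converged = converged, gradient_norm = gnorm,
    iterations = opt$iterations, model = model, level = space$level,
    group = group, se_ok = se_ok), class = "rt_fit")
}

#' @export
print.rt_fit <- function(x, ...) {
  cat(sprintf("<rt_fit %s_%s%s: loglik %.3f, %d free, n=%d, %s>\n",
              x$model, x$level,
              if (!is.na(x$group)) paste0(" [", x$group, "]") else "",
              x$loglik, x$n_free, x$n_persons,
              if (x$converged) "converged" else "NOT CONVERGED"))
  invisible(x)
}

#' @export
logLik.rt_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_free,
            nobs = object$n_persons, class = "logLik")
}

#' Two-step international/group analysis
#'
#' Runs the full estimation scheme: first the international calibration on
#' the pooled sample (M1, then M2 and M3 with accuracy parameters carried
#' over from M1), then per group the M1_Full fit and the requested rungs of
#' the measurement-invariance ladder for each time model family.
#'
#' @param data An [rt_dataset()] with at least two groups.
#' @param models Subset of `c("M1", "M2", "M3")`; M1 is always fitted (it
#'   anchors the others).
#' @param levels Ladder rungs to fit per group, in
#'   `c("Full", "Strong", "Weak", "Struct")`.
#' @param quad,control Passed to [fit_model()].
#' @param on_error `"continue"` records a failed cell and proceeds;
#'   `"stop"` re-raises with context naming the failing cell.
#' @param verbose Print a line per fit.
#' @return An object of class `two_step_result`: list with `international`
#'   (named fits) and `country` (per-group named fits, e.g. `M2_Weak`),
#'   plus `errors` describing any failed cells.
#' @export
two_step_analysis <- function(data, models = c("M1", "M2", "M3"),
                              levels = c("Full", "Strong", "Weak", "Struct"),
                              quad = quad_spec(), control = list(),
                              on_error = c("continue", "stop"),
                              verbose = FALSE) {
  stopifnot(inherits(data, "rt_data"))
  on_error <- match.arg(on_error)
  models <- match.arg(models, c("M1", "M2", "M3"), several.ok = TRUE)
  levels <- match.arg(levels, c("Full", "Strong", "Weak", "Struct"),
                      several.ok = TRUE)
  groups <- levels(data$group)
  if (length(groups) < 2L)
    stop("the group-level step requires at least 2 groups; got ",
         length(groups))
  n_cat <- data$n_cat
  errors <- list()
  say <- function(...) if (verbose) message(sprintf(...))
  try_fit <- function(cell, expr) {
    tryCatch(expr, error = function(e) {
      if (on_error == "stop")
        stop("fit failed for ", cell, ": ", conditionMessage(e),
             call. = FALSE)
      errors[[cell]] <<- conditionMessage(e)
      NULL
    })
  }

  intl <- list()
  say("international M1 (n=%d)", nrow(data$responses))
  intl$M1 <- fit_model(data, parameter_space("M1", "international",
                                             n_cat = n_cat,
                                             item_names = data$items),
                       quad, control)
  anchors <- list(M1_international = intl$M1)
  for (fam in intersect(c("M2", "M3"), models)) {
    say("international %s", fam)
    f <- try_fit(paste0(fam, "_international"),
                 fit_model(data, parameter_space(fam, "international",
                                                 anchors, n_cat,
                                                 data$items),
                           quad, control))
    if (!is.null(f)) {
      intl[[fam]] <- f
      anchors[[paste0(fam, "_international")]] <- f
    }
  }

  country <- list()
  for (g in groups) {
    dg <- group_subset(data, g)
    fits <- list()
    say("group %s: M1_Full (n=%d)", g, nrow(dg$responses))
    fits$M1_Full <- try_fit(paste0(g, "/M1_Full"),
      fit_model(dg, parameter_space("M1", "Full", anchors, n_cat,
                                    data$items),
                quad, control, group = g))
    anc_g <- c(anchors, list(M1_Full = fits$M1_Full))
    for (fam in intersect(c("M2", "M3"), models)) {
      if (is.null(intl[[fam]])) next
      for (lev in levels) {
        if (fam == "M3" && lev == "Struct" && is.null(fits$M1_Full)) next
        cell <- paste0(fam, "_", lev)
        say("group %s: %s", g, cell)
        fits[[cell]] <- try_fit(paste0(g, "/", cell),
          fit_model(dg, parameter_space(fam, lev, anc_g, n_cat,
                                        data$items),
                    quad, control, group = g))
      }
    }
    country[[g]] <- fits
  }
  structure(list(international = intl, country = country,
                 models = models, levels = levels, errors = errors,
                 groups = groups),
            class = "two_step_result")
}

#' @export
print.two_step_result <- function(x, ...) {
  cat(sprintf("<two_step_result: %d international fits, %d groups x %s>\n",
              length(x$international), length(x$country),
              paste(names(x$country[[1]]), collapse = "/")))
  if (length(x$errors))
    cat("  failed cells:", paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy table of estimates and standard errors
#'
#' @param x An `rt_fit` or `two_step_result`.
#' @return A data.frame keyed by model, level, group, symbol, item and
#'   threshold index, with columns `estimate`, `se` and `free`.
#' @export
estimates_table <- function(x) {
  if (inherits(x, "rt_fit")) {
    tab <- x$par_table
    return(data.frame(model = x$model, level = x$level, group = x$group,
                      symbol = tab$symbol, item = tab$item, k = tab$k,
                      estimate = tab$value, se = tab$se, free = tab$free,
                      stringsAsFactors = FALSE))
  }
  stopifnot(inherits(x, "two_step_result"))
  out <- list()
  for (nm in names(x$international))
    out[[length(out) + 1L]] <- estimates_table(x$international[[nm]])
  for (g in names(x$country))
    for (nm in names(x$country[[g]]))
      if (!is.null(x$country[[g]][[nm]]))
        out[[length(out) + 1L]] <- estimates_table(x$country[[g]][[nm]])
  do.call(rbind, out)
}
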