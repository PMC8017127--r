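# Orchestration of the full study analogue: simulate or ingest data, run
# the two-step analysis, score, select invariance levels, and emit the
# report tables (international summary, per-group ladder, time-intensity,
# group means with Wald intervals, per-group precision, EAP correlations).

#' Declarative run configuration
#'
#' @param scenario Either a [scenario_config()], or a list of arguments to
#'   [pisa_like_scenario()] (possibly empty for its defaults); ignored when
#'   `data_long` is given.
#' @param data_long Path to a long-format dataset (see [read_rt_long()]).
#' @param models Models to run, subset of `c("M1", "M2", "M3")`.
#' @param levels Ladder levels to fit per group.
#' @param quad_nodes Quadrature nodes.
#' @param score_level `"preferred"` scores each group under its BIC-preferred
#'   ladder level; otherwise one of `"Full"`, `"Strong"`, `"Weak"`,
#'   `"Struct"`.
#' @param seed Seed forwarded to the scenario when it does not set one.
#' @param out_dir Output directory for the report tables.
#' @return A list of class `study_config`.
#' @export
study_config <- function(scenario = list(), data_long = NULL,
                         models = c("M1", "M2", "M3"),
                         levels = c("Full", "Strong", "Weak", "Struct"),
                         quad_nodes = 21L, score_level = "preferred",
                         seed = 1L, out_dir = "study_output") {
  structure(list(scenario = scenario, data_long = data_long,
                 models = models, levels = levels,
                 quad_nodes = as.integer(quad_nodes),
                 score_level = score_level, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "study_config")
}

# rbind data.frames whose columns differ, filling absent ones with NA
rbind_fill <- function(lst) {
  lst <- Filter(Negate(is.null), lst)
  cols <- unique(unlist(lapply(lst, names)))
  do.call(rbind, lapply(lst, function(d) {
    for (cn in setdiff(cols, names(d))) d[[cn]] <- NA
    d[, cols, drop = FALSE]
  }))
}

# polynomial rolling hash of a string, as hex (config digest)
config_digest <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full study analogue
#'
#' Executes simulate (or ingest), fit, score, ladder selection and report
#' stages, writing delimited report tables and a JSON run manifest to the
#' configured output directory. Fit failures are isolated to their
#' group/model cell, recorded in the manifest, and do not abort the run.
#' With an identical configuration the emitted tables are byte-identical
#' across reruns.
#'
#' @param config A [study_config()], a list understood by it, or the path
#'   to a YAML file with the same fields.
#' @return Invisibly, a list with the fitted `result`
#'   (`two_step_result`), the per-model `scores`, the written `files` and
#'   the `manifest`.
#' @export
run_study <- function(config = study_config()) {
  if (is.character(config) && length(config) == 1L)
    config <- do.call(study_config, yaml::read_yaml(config))
  if (!inherits(config, "study_config"))
    config <- do.call(study_config, config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  quad <- quad_spec(config$quad_nodes)
  stage_time <- list(); files <- character(0)
  tick <- function() Sys.time()
  emit <- function(tab, name) {
    path <- file.path(config$out_dir, name)
    data.table::fwrite(as.data.frame(tab), path, sep = "\t", na = "NA",
                       quote = FALSE)
    files <<- c(files, path)
    path
  }

  # ---- stage: data ----------------------------------------------------
  t0 <- tick()
  truth <- NULL
  if (!is.null(config$data_long)) {
    data <- read_rt_long(config$data_long)
  } else {
    scen <- config$scenario
    if (!inherits(scen, "scenario_config")) {
      if (is.null(scen$seed)) scen$seed <- config$seed
      scen <- do.call(pisa_like_scenario, scen)
    }
    sim <- simulate_scenario(scen)
    data <- sim$data
    truth <- sim$truth
  }
  stage_time$data <- as.numeric(tick() - t0, units = "secs")

  # ---- stage: fit -----------------------------------------------------
  t0 <- tick()
  res <- two_step_analysis(data, models = config$models,
                           levels = config$levels, quad = quad,
                           on_error = "continue")
  stage_time$fit <- as.numeric(tick() - t0, units = "secs")
  emit(estimates_table(res), "estimates.tsv")

  # ---- stage: ladder --------------------------------------------------
  t0 <- tick()
  fams <- intersect(c("M2", "M3"), config$models)
  fams <- fams[fams %in% names(res$international)]
  ladders <- list(); selections <- list()
  for (fam in fams) {
    lt <- ladder_table(res, fam)
    ladders[[fam]] <- lt
    selections[[fam]] <- select_invariance(lt)
    emit(lt, sprintf("ladder_%s.tsv", fam))
  }
  if (length(fams)) {
    sel_tab <- do.call(rbind, lapply(fams, function(fam) {
      s <- selections[[fam]]
      rbind(data.frame(family = fam, group = names(s$per_group),
                       preferred = unname(s$per_group)),
            data.frame(family = fam, group = "TOTAL",
                       preferred = s$overall))
    }))
    emit(sel_tab, "invariance_selection.tsv")
  }
  stage_time$ladder <- as.numeric(tick() - t0, units = "secs")

  # ---- stage: score ---------------------------------------------------
  t0 <- tick()
  # international scores per model (pooled sample)
  intl_scores <- list()
  for (m in names(res$international)) {
    f <- res$international[[m]]
    intl_scores[[m]] <- eap_scores(data, f$spec, quad, model = m,
                                   level = "international")
  }
  # per-group scores under the scoring level
  pick_level <- function(fam, g) {
    if (config$score_level != "preferred") return(config$score_level)
    unname(selections[[fam]]$per_group[g])
  }
  group_scores <- list()   # [[model]][[group]]
  for (g in res$groups) {
    dg <- group_subset(data, g)
    fits <- res$country[[g]]
    if (!is.null(fits$M1_Full))
      group_scores$M1[[g]] <- eap_scores(dg, fits$M1_Full$spec, quad,
                                         model = "M1", level = "Full",
                                         group = g)
    for (fam in fams) {
      lev <- pick_level(fam, g)
      f <- fits[[paste0(fam, "_", lev)]]
      if (!is.null(f))
        group_scores[[fam]][[g]] <- eap_scores(dg, f$spec, quad,
                                               model = fam, level = lev,
                                               group = g)
    }
  }
  stage_time$score <- as.numeric(tick() - t0, units = "secs")

  # ---- stage: report --------------------------------------------------
  t0 <- tick()
  # (a) international summary: Table-5-like columns
  intl_sum <- do.call(rbind, lapply(names(intl_scores), function(m) {
    f <- res$international[[m]]
    data.frame(model = m,
               mean = f$spec$latent$mean_theta,
               variance = f$spec$latent$var_theta,
               eap_reliability = eap_reliability(intl_scores[[m]]),
               average_se = average_se(intl_scores[[m]]))
  }))
  emit(intl_sum, "international_summary.tsv")

  # (c) per-group time-intensity estimates under the preferred model
  if (length(fams)) {
    ti <- list()
    for (fam in fams) for (g in res$groups) {
      lev <- pick_level(fam, g)
      f <- res$country[[g]][[paste0(fam, "_", lev)]]
      if (is.null(f)) next
      tabf <- f$par_table
      sel <- tabf$symbol == "xi"
      ti[[length(ti) + 1L]] <- data.frame(
        family = fam, group = g, level = lev,
        item = f$spec$item_names[tabf$item[sel]],
        xi = tabf$value[sel], se = tabf$se[sel])
    }
    emit(do.call(rbind, ti), "time_intensity.tsv")
  }

  # (d) group means with Wald 95% intervals
  gm <- list()
  all_models <- c("M1", fams)
  for (m in all_models) for (g in res$groups) {
    f <- if (m == "M1") res$country[[g]]$M1_Full
         else res$country[[g]][[paste0(m, "_", pick_level(m, g))]]
    if (is.null(f)) next
    tabf <- f$par_table
    r <- which(tabf$symbol == "mu_theta")
    gm[[length(gm) + 1L]] <- data.frame(
      model = m, group = g, mean = tabf$value[r], se = tabf$se[r],
      ci_lower = tabf$value[r] - 1.96 * tabf$se[r],
      ci_upper = tabf$value[r] + 1.96 * tabf$se[r])
  }
  emit(do.call(rbind, gm), "group_means.tsv")

  # (e) per-group EAP reliabilities and average SEs per model
  prec <- list()
  for (m in all_models) for (g in names(group_scores[[m]] %||% list())) {
    s <- group_scores[[m]][[g]]
    prec[[length(prec) + 1L]] <- data.frame(
      model = m, group = g, level = attr(s, "level"),
      eap_reliability = eap_reliability(s), average_se = average_se(s))
  }
  emit(do.call(rbind, prec), "precision_by_group.tsv")

  # (f) EAP correlation tables, pooled (international) and per group
  if (length(intl_scores) >= 2L) {
    cm <- score_correlations(intl_scores)
    cm_tab <- data.frame(model = rownames(cm), as.data.frame(cm))
    emit(cm_tab, "eap_correlations_pooled.tsv")
    # per group from group-level scores (common groups across models)
    gs_models <- names(group_scores)
    common_g <- Reduce(intersect, lapply(group_scores[gs_models],
                                         names))
    bg <- list()
    for (g in common_g) {
      ss <- lapply(group_scores[gs_models], `[[`, g)
      cg <- score_correlations(ss)
      for (i in seq_len(nrow(cg) - 1L)) for (j in (i + 1L):ncol(cg))
        bg[[length(bg) + 1L]] <- data.frame(
          group = g, model_a = rownames(cg)[i], model_b = colnames(cg)[j],
          correlation = cg[i, j])
    }
    if (length(bg)) emit(do.call(rbind, bg), "eap_correlations_by_group.tsv")
  }

  # score tables
  sc_tab <- rbind_fill(lapply(names(intl_scores), function(m)
    data.frame(model = m, level = "international",
               as.data.frame(intl_scores[[m]]))))
  emit(sc_tab, "scores_international.tsv")
  gsc <- list()
  for (m in names(group_scores)) for (g in names(group_scores[[m]]))
    gsc[[length(gsc) + 1L]] <- data.frame(model = m,
                                          level = attr(group_scores[[m]][[g]],
                                                       "level"),
                                          as.data.frame(group_scores[[m]][[g]]))
  if (length(gsc)) emit(rbind_fill(gsc), "scores_by_group.tsv")
  stage_time$report <- as.numeric(tick() - t0, units = "secs")

  manifest <- list(
    package_version = as.character(utils::packageVersion("jointRT")),
    config = config[setdiff(names(config), "scenario")],
    config_digest = config_digest(paste(deparse(config), collapse = "")),
    seed = config$seed,
    n_persons = nrow(data$responses),
    n_groups = nlevels(data$group),
    stage_seconds = stage_time,
    convergence = lapply(res$country, function(fits)
      vapply(fits, function(f) if (is.null(f)) NA else f$converged, TRUE)),
    failed_cells = res$errors,
    files = c(basename(files), "manifest.json"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  files <- c(files, file.path(config$out_dir, "manifest.json"))

  invisible(list(result = res, data = data, truth = truth,
                 scores = list(international = intl_scores,
                               by_group = group_scores),
                 selections = selections, ladders = ladders,
                 files = files, manifest = manifest))
}
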