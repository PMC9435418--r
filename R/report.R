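# End-to-end pipeline run and report bundle.

#' Run the full analysis pipeline and write a report bundle
#'
#' Simulates a cohort from the ground-truth network, expands it to
#' item-level responses, simulates the noise environment and recomputes
#' every nurse's exposure from the grid, re-scores the questionnaires,
#' fits the network CPTs by EM on the (optionally incomplete) category
#' table, runs the eight delta-p evidence scenarios (exposure low/high,
#' sensitivity low/high, annoyance low/high, and joint exposure +
#' sensitivity both-low / both-high), ranks all arcs by influence value,
#' and cross-validates the quality-of-care classification.
#'
#' Writes to `out_dir`: `category_summary.csv` (frequencies, percentages
#' and mean/SD of the underlying scores per category),
#' `quality_cpt.csv` (the fitted CPT of the quality node),
#' `sensitivity_scenarios.csv` / `.json` (delta-p rows for all scenarios),
#' `influence_ranking.csv`, `validation.csv` / `validation.json`, a
#' machine-readable `report.json`, and `run_log.txt` recording seeds and
#' configuration.
#'
#' @param out_dir Output directory (created if absent).
#' @param n Cohort size (default 209).
#' @param seed Integer master seed; all stage seeds derive from it.
#' @param k Cross-validation folds.
#' @param missing_rate MCAR missing fraction injected into the category
#'   table before EM fitting.
#' @param n_points Measurement grid size.
#' @return Invisibly, a list with the cohort, noise environment, fitted
#'   network, scenario table, influence ranking and validation report.
#' @export
generate_report <- function(out_dir, n = 209, seed = 1, k = 10,
                            missing_rate = 0.05, n_points = 1510) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  cfg <- cohort_config(n_nurses = n, missing_rate = missing_rate, seed = seed)
  truth <- make_truth_network(cfg)
  cohort <- sample_cohort(truth, n, seed = seed)
  cohort <- suppressWarnings(expand_to_items(cohort, seed = seed + 1))
  env <- simulate_noise_environment(cohort, n_points = n_points, seed = seed + 2)
  noise_map <- build_noise_map(env$grid)
  expo <- nurse_exposure(noise_map, env$assignments)
  cohort$lep_d_db <- expo$lep_d_db[match(cohort$nurse_id, expo$nurse_id)]
  cohort$exposure <- expo$category[match(cohort$nurse_id, expo$nurse_id)]

  # category summary (frequencies + mean/SD of the underlying measure)
  measures <- c(exposure = "lep_d_db", sensitivity = "sensitivity_score",
                annoyance = "annoyance_score", quality = "qpcs_total",
                psychosocial = "psychosocial_score",
                communicational = "communicational_score",
                physical = "physical_score")
  summary_tab <- do.call(rbind, lapply(names(measures), function(v) {
    x <- cohort[[measures[[v]]]]
    g <- cohort[[v]]
    do.call(rbind, lapply(levels(g), function(s) {
      sel <- !is.na(g) & g == s
      data.frame(variable = v, category = s, frequency = sum(sel),
                 percent = round(100 * sum(sel) / sum(!is.na(g)), 1),
                 mean = round(mean(x[sel]), 2), sd = round(stats::sd(x[sel]), 2))
    }))
  }))
  utils::write.csv(summary_tab, file.path(out_dir, "category_summary.csv"),
                   row.names = FALSE)

  # EM fit on the category table (with MCAR missingness injected)
  nodes <- names(truth$network$variables)
  cat_tab <- cohort[, nodes]
  cat_tab <- inject_missing(cat_tab, missing_rate, seed = seed + 3,
                            columns = nodes)
  fit <- em_learn(build_study_network(), cat_tab, seed = seed + 4)
  qual_cpt <- cpt_as_table(fit, "quality")
  utils::write.csv(qual_cpt, file.path(out_dir, "quality_cpt.csv"),
                   row.names = FALSE)

  scenarios <- list(
    exposure_low = c(exposure = "low"),
    exposure_high = c(exposure = "high"),
    sensitivity_low = c(sensitivity = "low"),
    sensitivity_high = c(sensitivity = "high"),
    annoyance_low = c(annoyance = "low"),
    annoyance_high = c(annoyance = "high"),
    exposure_sensitivity_low = c(exposure = "low", sensitivity = "low"),
    exposure_sensitivity_high = c(exposure = "high", sensitivity = "high")
  )
  scen_tab <- do.call(rbind, lapply(names(scenarios), function(nm) {
    dp <- delta_p(fit, scenarios[[nm]])
    cbind(scenario = nm, as.data.frame(dp))
  }))
  utils::write.csv(scen_tab, file.path(out_dir, "sensitivity_scenarios.csv"),
                   row.names = FALSE)
  jsonlite::write_json(scen_tab, file.path(out_dir, "sensitivity_scenarios.json"),
                       dataframe = "rows", digits = NA)

  infl <- rank_influences(fit)
  utils::write.csv(infl, file.path(out_dir, "influence_ranking.csv"),
                   row.names = FALSE)

  val <- suppressWarnings(
    cross_validate(cat_tab, build_study_network(), "quality",
                   k = k, seed = seed + 5)
  )
  conf_df <- as.data.frame.matrix(as.matrix(val$confusion))
  conf_df <- cbind(actual = rownames(conf_df), conf_df)
  utils::write.csv(conf_df, file.path(out_dir, "validation.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(confusion = unclass(val$confusion),
         sensitivity = val$metrics$sensitivity,
         specificity = val$metrics$specificity,
         accuracy = val$metrics$accuracy,
         auc_per_class = as.list(val$auc$per_class),
         auc_macro = val$auc$macro,
         n_fallback = val$n_fallback),
    file.path(out_dir, "validation.json"), auto_unbox = TRUE, digits = NA)

  jsonlite::write_json(
    list(n = n, seed = seed, k = k, missing_rate = missing_rate,
         n_points = n_points,
         files = c("category_summary.csv", "quality_cpt.csv",
                   "sensitivity_scenarios.csv", "sensitivity_scenarios.json",
                   "influence_ranking.csv", "validation.csv",
                   "validation.json"),
         accuracy = val$metrics$accuracy, auc_macro = val$auc$macro),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)

  writeLines(c(
    sprintf("noisecare report run: %s", format(t0)),
    sprintf("n = %d, seed = %d, k = %d, missing_rate = %.3f, n_points = %d",
            n, seed, k, missing_rate, n_points),
    sprintf("stage seeds: cohort %d, items %d, noise %d, missing %d, em %d, cv %d",
            seed, seed + 1, seed + 2, seed + 3, seed + 4, seed + 5),
    sprintf("elapsed: %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  ), file.path(out_dir, "run_log.txt"))

  invisible(list(cohort = cohort, environment = env, exposure = expo,
                 truth = truth, fit = fit, scenarios = scen_tab,
                 influence = infl, validation = val,
                 summary = summary_tab))
}

#' Flatten one node's CPT into a table
#'
#' @param net A parameterised `bn`.
#' @param node Node name.
#' @return Data frame with one column per parent (its state), one column
#'   per child state carrying the conditional probability.
#' @export
cpt_as_table <- function(net, node) {
  stopifnot(inherits(net, "bn"))
  arr <- net$cpts[[node]]
  if (is.null(arr)) stop(sprintf("node '%s' has no CPT", node))
  pa <- net$parents[[node]]
  states <- net$variables[[node]]
  if (!length(pa)) {
    out <- as.data.frame(as.list(stats::setNames(as.numeric(arr), states)))
    return(out)
  }
  cfgs <- expand.grid(lapply(pa, function(p) net$variables[[p]]),
                      stringsAsFactors = FALSE)
  names(cfgs) <- pa
  probs <- t(vapply(seq_len(nrow(cfgs)), function(i) {
    idx <- mapply(function(s, p) match(s, net$variables[[p]]), cfgs[i, ], pa)
    as.numeric(do.call(`[`, c(list(arr), list(TRUE), as.list(idx))))
  }, numeric(length(states))))
  colnames(probs) <- states
  cbind(cfgs, as.data.frame(probs))
}
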