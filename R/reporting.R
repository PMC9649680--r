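# Base-case record, report assembly, and run manifests. All outputs are
# plain CSV/JSON so downstream plotting is optional.

#' Run the base-case analysis for one population
#'
#' Runs both arms of the cohort model and assembles a record shaped like a
#' base-case results table: per-arm discounted totals, increments, ICER, and
#' WTP classification.
#'
#' @param params an `hf_params` (e.g. from [load_parameter_set()]).
#' @return a `base_case_result` list: `population`, `arms` (data.frame of
#'   per-arm totals), `incremental` (an `incremental_result`), and the
#'   structural assumptions in force (`assumptions`).
#' @export
run_base_case <- function(params) {
  arms <- lapply(c(control = "control", empagliflozin = "empagliflozin"),
                 function(a) run_arm(params, a))
  inc <- compute_incremental(arms$empagliflozin, arms$control, params$wtp)
  arm_tab <- data.frame(
    arm = names(arms),
    total_cost = vapply(arms, `[[`, numeric(1), "total_discounted_cost"),
    total_qalys = vapply(arms, `[[`, numeric(1), "total_discounted_qalys"),
    life_years = vapply(arms, `[[`, numeric(1), "life_years"),
    cv_deaths = vapply(arms, `[[`, numeric(1), "expected_cv_deaths"),
    hospitalisations = vapply(arms, `[[`, numeric(1),
                              "expected_hospitalisations"),
    row.names = NULL)
  structure(
    list(population = params$population$label,
         arms = arm_tab,
         incremental = inc,
         assumptions = list(
           initial_nyha_mix = as.list(params$population$initial_nyha_mix),
           hosp_disutility_mode = params$utilities$hosp_disutility_mode,
           dirichlet_ess = params$psa$dirichlet_ess,
           mortality_extrapolation = params$mortality_non_cv$extrapolation)),
    class = "base_case_result")
}

#' @export
print.base_case_result <- function(x, ...) {
  cat(sprintf("Base case, %s population\n", x$population))
  tab <- x$arms
  tab$total_cost <- sprintf("%.2f", tab$total_cost)
  tab$total_qalys <- sprintf("%.4f", tab$total_qalys)
  print(tab, row.names = FALSE)
  print(x$incremental)
  invisible(x)
}

base_case_record <- function(bc) {
  list(population = bc$population,
       arms = bc$arms,
       incremental = list(delta_cost = bc$incremental$delta_cost,
                          delta_qalys = bc$incremental$delta_qalys,
                          icer = bc$incremental$icer,
                          dominance = bc$incremental$dominance,
                          wtp_class = bc$incremental$wtp_class),
       assumptions = bc$assumptions)
}

#' Assemble a structured analysis report
#'
#' Aggregates whichever analyses were run — base case, tornado table, PSA
#' draws (summarised as quadrant shares and CEAC values at the two WTP
#' thresholds), and the scenario table — into one JSON-ready list. Sections
#' not supplied are empty.
#'
#' @param base_case a `base_case_result`, or `NULL`.
#' @param owsa a tornado data.frame from [one_way_sa()], or `NULL`.
#' @param psa a `psa_result` from [run_psa()], or `NULL`.
#' @param scenarios a scenario table from [run_scenarios()], or `NULL`.
#' @param wtp thresholds at which CEAC values are reported.
#' @return a `report` list; write it with [write_report()].
#' @export
assemble_report <- function(base_case = NULL, owsa = NULL, psa = NULL,
                            scenarios = NULL, wtp = c(12652.5, 37957.5)) {
  rep <- list(base_case = list(), owsa = list(), psa = list(),
              scenarios = list())
  if (!is.null(base_case)) rep$base_case <- base_case_record(base_case)
  if (!is.null(owsa)) rep$owsa <- owsa
  if (!is.null(psa)) {
    quad <- list(
      pos_cost_pos_qaly = mean(psa$delta_cost > 0 & psa$delta_qalys > 0),
      pos_cost_neg_qaly = mean(psa$delta_cost > 0 & psa$delta_qalys <= 0),
      neg_cost_pos_qaly = mean(psa$delta_cost <= 0 & psa$delta_qalys > 0),
      neg_cost_neg_qaly = mean(psa$delta_cost <= 0 & psa$delta_qalys <= 0))
    cc <- ceac(psa, wtp)
    rep$psa <- list(n_draws = nrow(psa),
                    seed = attr(psa, "seed"),
                    quadrant_shares = quad,
                    prob_cost_effective = as.list(
                      stats::setNames(cc$prob_cost_effective,
                                      paste0("wtp_", wtp))),
                    resampled_utility_draws =
                      attr(psa, "resampled_utility_draws"))
  }
  if (!is.null(scenarios)) rep$scenarios <- scenarios
  structure(rep, class = "hfcua_report")
}

#' Write a report (and optional CSV side-tables) to disk
#'
#' @param report a report from [assemble_report()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records the configuration path and its MD5 hash, the seed, the analysis
#' name, package version, timestamp, the structural assumptions in force,
#' and the files written — enough to audit and rerun any analysis.
#'
#' @param config_path path of the YAML configuration used.
#' @param analysis analysis name (e.g. `"base_case"`, `"psa"`).
#' @param seed RNG seed used (`NA` for deterministic analyses).
#' @param outputs character vector of files written.
#' @param params the `hf_params` in force (for the assumption record).
#' @param path manifest JSON path.
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(config_path, analysis, seed, outputs, params,
                           path) {
  manifest <- list(
    analysis = analysis,
    config = config_path,
    config_md5 = if (file.exists(config_path))
      unname(tools::md5sum(config_path)) else NA_character_,
    seed = seed,
    package_version = as.character(utils::packageVersion("hfcua")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    assumptions = list(
      initial_nyha_mix = as.list(params$population$initial_nyha_mix),
      hosp_disutility_mode = params$utilities$hosp_disutility_mode,
      dirichlet_ess = params$psa$dirichlet_ess,
      mortality_extrapolation = params$mortality_non_cv$extrapolation),
    outputs = as.list(outputs))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
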