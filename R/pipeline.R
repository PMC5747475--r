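#' Read a pipeline configuration file
#'
#' YAML with sections: `paths` (registrants, output_dir), `censoring`
#' (censor_at_policy, policy_date, admin_horizon_day), `cohort`
#' (window_start, window_end), `report` (horizons, level), `seed`, and an
#' optional `scenario` section for simulation mode (preset, n_subjects,
#' plus overrides). Omitted keys take the defaults documented here.
#'
#' @param path YAML file path.
#' @return A list of class `msm_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  as_pipeline_config(raw)
}

#' @param x A named list of configuration values.
#' @rdname read_pipeline_config
#' @export
as_pipeline_config <- function(x) {
  cfg <- list(
    seed = if (is.null(x$seed)) 1L else as.integer(x$seed),
    paths = list(
      registrants = x$paths$registrants,
      output_dir = if (is.null(x$paths$output_dir)) "." else x$paths$output_dir),
    censoring = censoring_scheme(
      policy_date = if (is.null(x$censoring$policy_date)) as.Date("2014-12-04")
                    else as.Date(x$censoring$policy_date),
      censor_at_policy = isTRUE(x$censoring$censor_at_policy),
      admin_horizon_day = x$censoring$admin_horizon_day),
    cohort = list(window_start = x$cohort$window_start,
                  window_end = x$cohort$window_end),
    report = list(
      horizons = if (is.null(x$report$horizons)) c(365, 1095)
                 else as.numeric(x$report$horizons),
      level = if (is.null(x$report$level)) 0.95 else as.numeric(x$report$level)),
    scenario = x$scenario)
  if (any(cfg$report$horizons <= 0)) stop("report horizons must be positive")
  if (cfg$report$level <= 0 || cfg$report$level >= 1) {
    stop("confidence level must be in (0, 1)")
  }
  class(cfg) <- "msm_pipeline_config"
  cfg
}

scenario_from_config <- function(cfg) {
  sc <- cfg$scenario
  if (is.null(sc)) stop("configuration has no `scenario` section")
  preset <- if (is.null(sc$preset)) "registry_like" else sc$preset
  if (!identical(preset, "registry_like")) {
    stop("unknown scenario preset: ", preset)
  }
  args <- list(n_subjects = if (is.null(sc$n_subjects)) 2000L
               else as.integer(sc$n_subjects),
               seed = cfg$seed)
  scen <- do.call(scenario_registry_like, args)
  if (!is.null(sc$censoring_rate)) scen$censoring_rate <- sc$censoring_rate
  if (!is.null(sc$admin_horizon_day)) {
    scen$admin_horizon_day <- sc$admin_horizon_day
  }
  if (!is.null(sc$listing_start)) scen$listing_start <- as.Date(sc$listing_start)
  if (!is.null(sc$listing_end)) scen$listing_end <- as.Date(sc$listing_end)
  # per-transition rate overrides, entries of from/to/rate by state index
  if (!is.null(sc$rate_overrides)) {
    lookup <- transition_lookup(scen$intensities$struct)
    for (ov in sc$rate_overrides) {
      id <- lookup[ov$from, ov$to]
      if (is.na(id)) stop("rate override names a forbidden transition: ",
                          ov$from, "->", ov$to)
      scen$intensities$rates[, id] <- ov$rate
    }
  }
  scen
}

write_manifest <- function(cfg, outputs, dir) {
  manifest <- list(
    package = "waitlistMSM",
    version = as.character(utils::packageVersion("waitlistMSM")),
    seed = cfg$seed,
    outputs = outputs,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Pipeline commands
#'
#' `cmd_simulate` writes a simulated registrants file; `cmd_fit` chains
#' cohort filtering, trajectory construction, censoring and estimation and
#' writes the transition, hazard and probability files; `cmd_report` writes
#' cross-section, death-curve and dynamic-prediction reports; and
#' `cmd_summarize` writes the demographics table. Each command writes a
#' machine-readable `manifest.json` beside its outputs and returns the
#' output paths invisibly.
#'
#' @param cfg A `msm_pipeline_config`.
#' @return Invisibly, a named character vector of output paths.
#' @export
cmd_simulate <- function(cfg) {
  dir.create(cfg$paths$output_dir, showWarnings = FALSE, recursive = TRUE)
  scen <- scenario_from_config(cfg)
  cohort <- simulate_cohort(scen)
  path <- cfg$paths$registrants
  if (is.null(path)) path <- file.path(cfg$paths$output_dir, "registrants.tsv")
  write_registrants(cohort, path)
  message("cmd_simulate: wrote ", nrow(cohort), " registrants to ", path)
  write_manifest(cfg, c(registrants = path), cfg$paths$output_dir)
  invisible(c(registrants = path))
}

#' @rdname cmd_simulate
#' @export
cmd_fit <- function(cfg) {
  dir.create(cfg$paths$output_dir, showWarnings = FALSE, recursive = TRUE)
  records <- read_registrants(cfg$paths$registrants)
  if (!is.null(cfg$cohort$window_start)) {
    records <- filter_cohort(records, cfg$cohort$window_start,
                             cfg$cohort$window_end)
  }
  if (nrow(records) == 0) stop("empty cohort after filters")
  space <- build_state_space()
  struct <- build_transition_structure(space)
  table <- prepare_transition_table(records, space, struct, cfg$censoring)
  fit <- waitlist_msm(table, space, struct)
  message("cmd_fit: ", fit$n_subjects, " subjects, ",
          sum(fit$profile$dN), " events")
  traj <- predict(fit, s = 0, t = cfg$report$horizons, type = "trajectory",
                  level = cfg$report$level)
  out <- c(transitions = file.path(cfg$paths$output_dir, "transitions.tsv"),
           hazards = file.path(cfg$paths$output_dir, "hazards.tsv"),
           probabilities = file.path(cfg$paths$output_dir,
                                     "probabilities.tsv"))
  write_transition_table(table, out["transitions"])
  write_hazards(fit$hazards, out["hazards"])
  write_probabilities(traj, out["probabilities"])
  write_manifest(cfg, as.list(out), cfg$paths$output_dir)
  invisible(out)
}

#' @rdname cmd_simulate
#' @export
cmd_report <- function(cfg) {
  dir.create(cfg$paths$output_dir, showWarnings = FALSE, recursive = TRUE)
  tr_path <- file.path(cfg$paths$output_dir, "transitions.tsv")
  if (!file.exists(tr_path)) {
    stop("missing fit artifact ", tr_path, "; run cmd_fit first")
  }
  table <- read_transition_table(tr_path)
  fit <- waitlist_msm(table)
  horizons <- cfg$report$horizons
  level <- cfg$report$level
  origins <- fit$space$index[fit$space$kind == "transient"]
  cross <- do.call(rbind, lapply(horizons, function(h) {
    do.call(rbind, lapply(origins, function(o) {
      cs <- state_probabilities(fit, o, 0, h, level)
      data.frame(initial_state = o, origin_day = 0, horizon_day = h,
                 outcome = fit$space$label[cs$to_index],
                 estimate = cs$estimate, lower = cs$lower, upper = cs$upper)
    }))
  }))
  dc <- death_curves(fit, horizons = horizons, level = level)
  out <- c(cross_sections = file.path(cfg$paths$output_dir,
                                      "cross_sections.tsv"),
           death_curves = file.path(cfg$paths$output_dir, "death_curves.tsv"))
  utils::write.table(cross, out["cross_sections"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(dc, out["death_curves"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_manifest(cfg, as.list(out), cfg$paths$output_dir)
  invisible(out)
}

#' @rdname cmd_simulate
#' @export
cmd_summarize <- function(cfg) {
  dir.create(cfg$paths$output_dir, showWarnings = FALSE, recursive = TRUE)
  records <- read_registrants(cfg$paths$registrants)
  if (!is.null(cfg$cohort$window_start)) {
    records <- filter_cohort(records, cfg$cohort$window_start,
                             cfg$cohort$window_end)
  }
  pol <- as.Date(cfg$censoring$policy_date)
  pre <- records[as.Date(records$listing_date) < pol, , drop = FALSE]
  post <- records[as.Date(records$listing_date) >= pol, , drop = FALSE]
  tab <- if (nrow(pre) && nrow(post)) {
    summarize_cohorts(pre, post)
  } else {
    do.call(rbind, lapply(c("age_group", "gender", "abo", "race",
                            "esrd_diagnosis", "pra_category"),
                          function(v) as.data.frame(summarize(records, v))))
  }
  path <- file.path(cfg$paths$output_dir, "summary.tsv")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(cfg, list(summary = path), cfg$paths$output_dir)
  invisible(c(summary = path))
}
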