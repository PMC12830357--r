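# Audit orchestration and report rendering.

#' Run a full sedation audit
#'
#' Ties the pipeline together: ingests the episode template, computes
#' per-service and national footprint summaries, the IVS-eligibility screen,
#' the acclimatisation-policy success comparison, and — when site and
#' procurement data are supplied — per-site wastage estimates for the
#' eligible (non-shared-supply) sites. Missing or empty procurement input
#' downgrades gracefully to a footprint-only report with a warning; a
#' malformed episodes file is a hard error.
#'
#' A service is classed as offering routine acclimatisation when any of its
#' audited episodes is an acclimatisation procedure.
#'
#' @param episodes_path Path to the episodes CSV.
#' @param sites_path Optional path to the sites CSV.
#' @param procurement_path Optional path to the procurement CSV.
#' @param config An [audit_config()].
#' @return A list of class `n2o_audit_bundle`: `config`, `ingest` (validation
#'   report), `summaries`, `pooled`, `acclimatisation`, `wastage` (or `NULL`),
#'   `recommendations`.
#' @export
run_audit <- function(episodes_path, sites_path = NULL,
                      procurement_path = NULL, config = audit_config()) {
  stopifnot(inherits(config, "audit_config"))
  ingest <- read_episodes(episodes_path, strict = FALSE)
  episodes <- ingest$episodes
  if (nrow(episodes) == 0L) {
    stop("validation failure: no valid episodes in ", episodes_path,
         call. = FALSE)
  }
  message("audit: ", ingest$report$n_valid, " episodes ingested, ",
          ingest$report$n_excluded, " excluded")

  summaries <- summarise_services(episodes, config$constants)
  rollup <- national_rollup(summaries, anonymise = FALSE)

  policies <- data.frame(
    service_id = sort(unique(episodes$service_id)),
    stringsAsFactors = FALSE
  )
  policies$offers_acclimatisation <- vapply(policies$service_id, function(s) {
    any(episodes$procedure[episodes$service_id == s] == "acclimatisation")
  }, logical(1L))
  acclim <- success_by_acclimatisation_policy(episodes, policies)

  wastage <- NULL
  if (!is.null(sites_path) && !is.null(procurement_path)) {
    proc_usable <- file.exists(procurement_path) &&
      file.size(procurement_path) > 0L &&
      nrow(utils::read.csv(procurement_path, colClasses = "character")) > 0L
    if (!proc_usable) {
      warning("procurement data missing or empty; wastage section omitted",
              call. = FALSE)
    } else {
      sites <- read_sites(sites_path)
      proc <- read_procurement(procurement_path, config$registry)
      weeks <- period_weeks(config$collection_period_days)
      vol <- episode_volume(episodes$flow_lpm, episodes$max_n2o_fraction,
                            episodes$duration_min)
      administered <- tapply(vol, episodes$site_id, sum) / weeks
      eligible_sites <- sites$site_id[eligible_for_wastage(sites)]
      skipped <- intersect(unique(proc$site_id),
                           setdiff(sites$site_id, eligible_sites))
      if (length(skipped) > 0L) {
        message("wastage: ", length(skipped),
                " shared-manifold site(s) excluded from estimation")
      }
      target_sites <- intersect(intersect(unique(proc$site_id), eligible_sites),
                                names(administered))
      if (length(target_sites) > 0L) {
        wastage <- do.call(rbind, lapply(target_sites, function(st) {
          procured <- weekly_procured_volume(proc[proc$site_id == st, ,
                                                  drop = FALSE],
                                             config$registry)
          estimate_wastage(procured, unname(administered[[st]]),
                           threshold = config$wastage_threshold, site_id = st)
        }))
        if (any(wastage$flag == "negative_anomaly")) {
          warning("negative wastage at ",
                  sum(wastage$flag == "negative_anomaly"),
                  " site(s): administered volume exceeded pro-rata procurement",
                  call. = FALSE)
        }
      }
    }
  }

  structure(
    list(config = config, ingest = ingest$report, summaries = summaries,
         pooled = rollup$pooled, acclimatisation = acclim, wastage = wastage,
         recommendations = .recommendations(rollup$pooled, acclim, wastage,
                                            config)),
    class = "n2o_audit_bundle"
  )
}

# Recommendations checklist keyed to audit triggers.
.recommendations <- function(pooled, acclim, wastage, config) {
  rec <- character(0)
  if (!is.null(wastage) && any(wastage$flag == "investigate")) {
    rec <- c(rec, sprintf(
      paste0("Wastage over %d%% at %d site(s): investigate stock control ",
             "(expired or stolen cylinders, cylinders changed before empty) ",
             "and faulty equipment (piping leaks, faulty cylinder gauges)."),
      round(config$wastage_threshold * 100),
      sum(wastage$flag == "investigate")))
  }
  if (!is.null(wastage) && any(wastage$flag == "negative_anomaly")) {
    rec <- c(rec, paste0("Negative wastage estimates suggest the collection ",
                         "period was unusually busy; re-audit over a longer ",
                         "window."))
  }
  if (is.finite(pooled$eligibility_rate) && pooled$eligibility_rate >= 0.30) {
    rec <- c(rec, sprintf(
      paste0("%d%% of patients may be suitable for standard-technique IVS; ",
             "consider increasing access to alternatives to N2O."),
      round(pooled$eligibility_rate * 100)))
  }
  if (!is.na(acclim$offering) && !is.na(acclim$non_offering) &&
      acclim$offering <= acclim$non_offering) {
    rec <- c(rec, paste0("Routine acclimatisation visits show no success ",
                         "benefit; decide acclimatisation under sedation on ",
                         "an individual patient basis."))
  }
  rec <- c(rec, paste0("Keep flow rates and N2O titration as low as ",
                       "clinically necessary, and turn N2O off once the ",
                       "anxiety-provoking stage is finished."))
  rec
}

.fmt <- function(x, dp) formatC(round(x, dp), format = "f", digits = dp)

#' Render an audit report bundle to files
#'
#' Writes the bundle in one or more formats. All formats share one rounding
#' rule (`report_decimal_places` from the config), so the markdown report and
#' the machine-readable outputs always contain the same numbers; the JSON
#' rendering additionally preserves full-precision raw values. With
#' `anonymise = TRUE` in the config, service identifiers are replaced by the
#' stable pseudonyms of [service_pseudonyms()] in every file.
#'
#' @param bundle An `n2o_audit_bundle` from [run_audit()].
#' @param format Subset of `c("csv", "json", "markdown")`.
#' @param out_dir Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
render_report <- function(bundle, format = c("csv", "json", "markdown"),
                          out_dir = ".") {
  stopifnot(inherits(bundle, "n2o_audit_bundle"))
  bad <- setdiff(format, c("csv", "json", "markdown"))
  if (length(bad) > 0L) {
    stop("usage error: unknown report format(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dp <- bundle$config$report_decimal_places
  summaries <- bundle$summaries
  if (bundle$config$anonymise) {
    summaries$service_id <- service_pseudonyms(summaries$service_id)
  }
  num_cols <- vapply(summaries, is.numeric, logical(1L))
  rounded <- summaries
  rounded[num_cols] <- lapply(rounded[num_cols], round, digits = dp)

  wastage_tab <- NULL
  if (!is.null(bundle$wastage)) {
    wastage_tab <- bundle$wastage[c("site_id", "procured_l_per_week",
                                    "administered_l_per_week", "wastage_pct",
                                    "flag")]
    wastage_tab$procured_l_per_week <- round(wastage_tab$procured_l_per_week)
    wastage_tab$administered_l_per_week <-
      round(wastage_tab$administered_l_per_week)
  }

  pooled <- bundle$pooled
  pooled_fmt <- list(
    n_services = pooled$n_services,
    n_episodes = pooled$n_episodes,
    total_co2e_kg = .fmt(pooled$total_co2e_kg, dp),
    mean_co2e_kg_per_episode = .fmt(pooled$mean_co2e_kg_per_episode, dp),
    mean_service_total_co2e_kg = .fmt(pooled$mean_service_total_co2e_kg, dp),
    success_pct = .fmt(pooled$success_rate * 100, 0),
    eligibility_pct = .fmt(pooled$eligibility_rate * 100, 0),
    paediatric_pct = .fmt(pooled$paediatric_fraction * 100, 0)
  )

  written <- character(0)
  if ("csv" %in% format) {
    p <- file.path(out_dir, "service_summary.csv")
    utils::write.csv(rounded, p, row.names = FALSE, quote = FALSE)
    written <- c(written, p)
    if (!is.null(wastage_tab)) {
      p <- file.path(out_dir, "wastage.csv")
      utils::write.csv(wastage_tab, p, row.names = FALSE, quote = FALSE)
      written <- c(written, p)
    }
  }
  if ("json" %in% format) {
    p <- file.path(out_dir, "report.json")
    jsonlite::write_json(
      list(pooled = pooled, pooled_formatted = pooled_fmt,
           services = summaries, services_rounded = rounded,
           wastage = wastage_tab,
           acclimatisation = bundle$acclimatisation[c("offering",
                                                      "non_offering")],
           recommendations = bundle$recommendations,
           ingest = bundle$ingest[c("n_rows", "n_valid", "n_excluded")]),
      p, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
    written <- c(written, p)
  }
  if ("markdown" %in% format) {
    p <- file.path(out_dir, "report.md")
    lines <- c(
      "# N2O sedation audit report", "",
      sprintf("Episodes analysed: %d (%d excluded by validation)",
              bundle$ingest$n_valid, bundle$ingest$n_excluded),
      sprintf("Services: %d", pooled$n_services), "",
      "## Carbon footprint", "",
      sprintf("- Total administered footprint: %s kg CO2e",
              pooled_fmt$total_co2e_kg),
      sprintf("- Mean per episode: %s kg CO2e",
              pooled_fmt$mean_co2e_kg_per_episode),
      sprintf("- Mean per service (collection period): %s kg CO2e",
              pooled_fmt$mean_service_total_co2e_kg), "",
      "## Cohort", "",
      sprintf("- Success rate: %s%%", pooled_fmt$success_pct),
      sprintf("- Paediatric episodes: %s%%", pooled_fmt$paediatric_pct),
      sprintf("- Standard-IVS eligible: %s%%", pooled_fmt$eligibility_pct), "")
    if (!is.na(bundle$acclimatisation$offering) ||
        !is.na(bundle$acclimatisation$non_offering)) {
      lines <- c(lines, "## Acclimatisation policy", "",
                 sprintf("- Success in services offering routine acclimatisation: %s%%",
                         .fmt(bundle$acclimatisation$offering * 100, 0)),
                 sprintf("- Success in services not offering it: %s%%",
                         .fmt(bundle$acclimatisation$non_offering * 100, 0)),
                 "")
    }
    if (!is.null(wastage_tab)) {
      lines <- c(lines, "## Wastage", "",
                 "| site | procured L/wk | administered L/wk | wastage | flag |",
                 "|---|---|---|---|---|",
                 sprintf("| %s | %d | %d | %d%% | %s |",
                         wastage_tab$site_id, wastage_tab$procured_l_per_week,
                         wastage_tab$administered_l_per_week,
                         wastage_tab$wastage_pct, wastage_tab$flag),
                 "")
    }
    lines <- c(lines, "## Recommendations", "",
               paste0("- ", bundle$recommendations), "")
    writeLines(lines, p)
    written <- c(written, p)
  }
  invisible(written)
}
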