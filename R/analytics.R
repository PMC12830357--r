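# Cohort analytics: eligibility screen, per-service summaries, national
# rollup, acclimatisation-policy comparison.

PAEDIATRIC_MAX_AGE <- 15L  # <=15 paediatric, >=16 adult

#' Standard-technique IVS eligibility screen
#'
#' A patient may be suitable for standard-technique intravenous sedation
#' (midazolam) when aged 12 years or older with ASA physical status grade I
#' or II.
#'
#' @param age_years Non-negative integer age(s).
#' @param asa_grade Integer ASA grade(s) in 1..6.
#' @return Logical vector.
#' @examples
#' ivs_eligible(12, 2)  # TRUE (boundary of the criterion)
#' ivs_eligible(11, 1)  # FALSE
#' @export
ivs_eligible <- function(age_years, asa_grade) {
  if (any(is.na(age_years)) || any(age_years < 0)) {
    stop("`age_years` must be non-negative", call. = FALSE)
  }
  if (any(is.na(asa_grade)) || any(asa_grade < 1L) || any(asa_grade > 6L)) {
    stop("`asa_grade` must be in 1..6", call. = FALSE)
  }
  age_years >= 12L & asa_grade <= 2L
}

#' Summarise one service's audited episodes
#'
#' Aggregates the episodes of a single service into its audit summary:
#' episode count, total and mean per-episode carbon footprint over the
#' collection period, success rate, standard-IVS eligibility rate,
#' paediatric fraction, and mean administration parameters.
#'
#' @param episodes data.frame of episodes sharing one `service_id`; must be
#'   non-empty (an empty collection is an error, not a silent zero).
#' @param constants A [gas_constants()] object.
#' @return One-row data.frame (`service_summary`).
#' @export
summarise_service <- function(episodes, constants = gas_constants()) {
  if (!is.data.frame(episodes) || nrow(episodes) == 0L) {
    stop("cannot summarise an empty episode collection", call. = FALSE)
  }
  sid <- unique(episodes$service_id)
  if (length(sid) != 1L) {
    stop("episodes span ", length(sid),
         " services; summarise_service() expects exactly one", call. = FALSE)
  }
  fp <- episode_footprint(episodes, constants)
  structure(
    data.frame(
      service_id = sid,
      n_episodes = nrow(episodes),
      total_co2e_kg = sum(fp$co2e_kg),
      mean_co2e_kg_per_episode = mean(fp$co2e_kg),
      success_rate = mean(episodes$success),
      eligibility_rate = mean(ivs_eligible(episodes$age_years,
                                           episodes$asa_grade)),
      paediatric_fraction = mean(episodes$age_years <= PAEDIATRIC_MAX_AGE),
      mean_flow_lpm = mean(episodes$flow_lpm),
      mean_titration_fraction = mean(episodes$max_n2o_fraction),
      mean_duration_min = mean(episodes$duration_min),
      stringsAsFactors = FALSE
    ),
    class = c("service_summary", "data.frame")
  )
}

#' Summarise every service in an episode collection
#'
#' @param episodes data.frame of episodes from any number of services.
#' @param constants A [gas_constants()] object.
#' @return data.frame with one [summarise_service()] row per service, ordered
#'   by `service_id`.
#' @export
summarise_services <- function(episodes, constants = gas_constants()) {
  if (!is.data.frame(episodes) || nrow(episodes) == 0L) {
    stop("cannot summarise an empty episode collection", call. = FALSE)
  }
  parts <- split(episodes, episodes$service_id)
  out <- do.call(rbind, lapply(parts, summarise_service, constants = constants))
  out <- out[order(out$service_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Success rates by acclimatisation policy
#'
#' Compares sedation success between services that offer routine
#' acclimatisation visits and services that do not. The headline figures pool
#' by the unweighted mean of per-service success rates (an "average success
#' rate in services" reading); episode-weighted pooling is available via
#' `weighting = "episode"`. An empty group yields `NA`, not zero.
#'
#' @param episodes data.frame of episodes.
#' @param policies data.frame with columns `service_id` and
#'   `offers_acclimatisation` (logical), one row per service.
#' @param weighting `"service"` (default) or `"episode"`.
#' @return List with `offering` and `non_offering` pooled success rates plus
#'   a `per_service` data.frame.
#' @export
success_by_acclimatisation_policy <- function(episodes, policies,
                                              weighting = c("service", "episode")) {
  weighting <- match.arg(weighting)
  stopifnot(all(c("service_id", "offers_acclimatisation") %in% names(policies)))
  per <- do.call(rbind, lapply(split(episodes, episodes$service_id), function(e) {
    data.frame(service_id = e$service_id[1L],
               n_episodes = nrow(e),
               success_rate = mean(e$success),
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  per$offers_acclimatisation <-
    policies$offers_acclimatisation[match(per$service_id, policies$service_id)]
  if (any(is.na(per$offers_acclimatisation))) {
    stop("missing acclimatisation policy for service(s): ",
         paste(per$service_id[is.na(per$offers_acclimatisation)],
               collapse = ", "), call. = FALSE)
  }
  pool <- function(rows) {
    if (nrow(rows) == 0L) return(NA_real_)
    if (weighting == "service") mean(rows$success_rate)
    else stats::weighted.mean(rows$success_rate, rows$n_episodes)
  }
  list(
    offering = pool(per[per$offers_acclimatisation, , drop = FALSE]),
    non_offering = pool(per[!per$offers_acclimatisation, , drop = FALSE]),
    per_service = per
  )
}

#' National rollup of service summaries
#'
#' Pools service summaries into the anonymised national result: the
#' episode-weighted per-episode mean footprint (total CO2e / total episodes),
#' the per-service mean of collection-period totals, and ranges. Because it
#' is ambiguous whether a printed per-episode range runs over episodes or
#' over per-service means, the rollup reports the range of per-service means;
#' the episode-level range is available from [episode_footprint()] directly.
#'
#' @param summaries data.frame of [summarise_service()] rows.
#' @param anonymise Replace service identifiers with stable pseudonyms
#'   (`service_01`, ... assigned in sorted-identifier order).
#' @return List with `pooled` (named list of national figures) and `services`
#'   (the per-service table, possibly anonymised).
#' @export
national_rollup <- function(summaries, anonymise = TRUE) {
  if (!is.data.frame(summaries) || nrow(summaries) == 0L) {
    stop("no service summaries supplied", call. = FALSE)
  }
  pooled <- list(
    n_services = nrow(summaries),
    n_episodes = sum(summaries$n_episodes),
    total_co2e_kg = sum(summaries$total_co2e_kg),
    mean_co2e_kg_per_episode =
      sum(summaries$total_co2e_kg) / sum(summaries$n_episodes),
    mean_service_total_co2e_kg = mean(summaries$total_co2e_kg),
    service_total_co2e_range = range(summaries$total_co2e_kg),
    service_mean_co2e_range = range(summaries$mean_co2e_kg_per_episode),
    success_rate =
      stats::weighted.mean(summaries$success_rate, summaries$n_episodes),
    eligibility_rate =
      stats::weighted.mean(summaries$eligibility_rate, summaries$n_episodes),
    paediatric_fraction =
      stats::weighted.mean(summaries$paediatric_fraction, summaries$n_episodes)
  )
  services <- summaries[order(summaries$service_id), , drop = FALSE]
  rownames(services) <- NULL
  if (anonymise) {
    services$service_id <- service_pseudonyms(services$service_id)
  }
  list(pooled = pooled, services = services)
}

#' Stable service pseudonyms
#'
#' Maps service identifiers to `service_01`, `service_02`, ... assigned in
#' sorted order of the original identifiers, so the same input set always
#' yields the same mapping.
#'
#' @param service_id Character vector of identifiers.
#' @return Character vector of pseudonyms, same length and order as input.
#' @export
service_pseudonyms <- function(service_id) {
  ids <- sort(unique(service_id))
  width <- max(2L, nchar(length(ids)))
  lab <- sprintf(paste0("service_%0", width, "d"), seq_along(ids))
  lab[match(service_id, ids)]
}

#' Flow rate versus patient age export
#'
#' Two-column table for the flow-vs-age scatter; no quantitative association
#' is asserted (the audit draws no conclusion beyond the absence of a visual
#' correlation), but a Spearman rank correlation is attached as an optional
#' diagnostic.
#'
#' @param episodes data.frame of episodes.
#' @return data.frame with `age_years`, `flow_lpm`; attribute
#'   `spearman_rho` holds the rank correlation.
#' @export
flow_by_age <- function(episodes) {
  out <- episodes[c("age_years", "flow_lpm")]
  attr(out, "spearman_rho") <-
    stats::cor(episodes$age_years, episodes$flow_lpm, method = "spearman")
  out
}
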